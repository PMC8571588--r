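#' Demographic scenario for the coalescent simulator
#'
#' An event-list demography: named populations with sampled diploid counts
#' and present-day effective sizes, plus a backward-in-time event list of
#' splits (`merge`), admixtures (`admix`) and size changes (`resize`).
#' Entries in `events` (columns `time`, `prop`, `size`) and in `n` may be
#' numbers or character expressions in named parameters, to be bound later
#' with [instantiate_scenario()]; a scenario with no free parameters is
#' "concrete" and can be simulated directly.
#'
#' @param name Scenario name.
#' @param populations Tibble with columns `pop` (label), `n_sample`
#'   (sampled diploids) and `n` (present-day effective size; number or
#'   parameter expression).
#' @param events Tibble with columns `time`, `type`
#'   (`"merge"`/`"admix"`/`"resize"`), `pop` (the child / resized pop),
#'   `parent_a`, `parent_b` (admix only), `prop` (admix: probability a
#'   lineage traces to `parent_a`), `size` (resize only).
#' @param mu Mutation rate per locus per generation (stepwise model).
#' @param loci Number of unlinked loci.
#' @param note Free-text provenance note.
#' @return A `demographic_scenario` object.
#' @export
scenario <- function(name, populations, events, mu = 3.5e-4, loci = 11,
                     note = NULL) {
  populations <- tibble::as_tibble(populations)
  events <- tibble::as_tibble(events)
  for (col in c("parent_a", "parent_b", "prop", "size")) {
    if (!col %in% names(events)) events[[col]] <- NA
  }
  stopifnot(all(c("pop", "n_sample", "n") %in% names(populations)),
            all(c("time", "type", "pop") %in% names(events)))
  structure(list(name = name, populations = populations, events = events,
                 mu = mu, loci = loci, note = note),
            class = "demographic_scenario")
}

#' @export
print.demographic_scenario <- function(x, ...) {
  cat(sprintf("<demographic_scenario> %s: %d populations, %d events, mu = %g, %d loci\n",
              x$name, nrow(x$populations), nrow(x$events), x$mu, x$loci))
  invisible(x)
}

# internal: evaluate a scalar field (number or parameter expression)
eval_field <- function(v, params) {
  if (is.numeric(v)) return(v)
  vapply(as.character(v), function(s) {
    if (is.na(s)) return(NA_real_)
    val <- suppressWarnings(as.numeric(s))
    if (!is.na(val)) return(val)
    eval(parse(text = s), envir = params)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Bind parameter values into a scenario template
#'
#' @param scn A [scenario()] whose `time`/`prop`/`size`/`n` fields may be
#'   parameter expressions.
#' @param params Named list or vector of parameter values.
#' @return A concrete `demographic_scenario` with all fields numeric.
#' @export
instantiate_scenario <- function(scn, params) {
  params <- as.list(params)
  scn$populations$n <- eval_field(scn$populations$n, params)
  scn$events$time <- eval_field(scn$events$time, params)
  scn$events$prop <- eval_field(scn$events$prop, params)
  scn$events$size <- eval_field(scn$events$size, params)
  scn$events <- scn$events[order(scn$events$time), ]
  scn
}

#' Validate a concrete demographic scenario
#'
#' Checks that every sampled population has an ancestral path: processing
#' events forward through backward time, each merge/admix removes an active
#' population, and exactly one ancestral population must remain; resize
#' events must touch active populations; admixture proportions must lie in
#' `[0, 1]`; times and sizes must be non-negative.
#'
#' @param scn A concrete [scenario()].
#' @return `TRUE` invisibly, or an error describing the defect.
#' @export
validate_scenario <- function(scn) {
  ev <- scn$events
  if (!is.numeric(ev$time) || anyNA(ev$time)) {
    stop("scenario '", scn$name, "': events have unresolved times", call. = FALSE)
  }
  if (any(ev$time < 0)) stop("scenario '", scn$name, "': negative event time", call. = FALSE)
  if (any(!is.na(ev$prop) & (ev$prop < 0 | ev$prop > 1))) {
    stop("scenario '", scn$name, "': admixture proportion outside [0, 1]", call. = FALSE)
  }
  if (any(!is.na(scn$populations$n) & scn$populations$n <= 0)) {
    stop("scenario '", scn$name, "': non-positive population size", call. = FALSE)
  }
  active <- scn$populations$pop
  ev <- ev[order(ev$time), ]
  for (i in seq_len(nrow(ev))) {
    e <- ev[i, ]
    if (!e$pop %in% active) {
      stop("scenario '", scn$name, "': event at time ", e$time,
           " touches inactive population '", e$pop, "'", call. = FALSE)
    }
    if (e$type == "merge") {
      if (!e$parent_a %in% active) {
        stop("scenario '", scn$name, "': merge into inactive population '",
             e$parent_a, "'", call. = FALSE)
      }
      active <- setdiff(active, e$pop)
    } else if (e$type == "admix") {
      if (!all(c(e$parent_a, e$parent_b) %in% active)) {
        stop("scenario '", scn$name, "': admixture parent inactive", call. = FALSE)
      }
      active <- setdiff(active, e$pop)
    } else if (e$type == "resize") {
      if (is.na(e$size) || e$size <= 0) {
        stop("scenario '", scn$name, "': resize to non-positive size", call. = FALSE)
      }
    } else stop("scenario '", scn$name, "': unknown event type '", e$type, "'",
                call. = FALSE)
  }
  if (length(active) != 1) {
    stop("scenario '", scn$name, "': ", length(active),
         " populations never reach a common ancestor (lineages stranded)",
         call. = FALSE)
  }
  invisible(TRUE)
}

# internal: encode a concrete scenario for the compiled simulator
encode_scenario <- function(scn, n_sample = NULL) {
  pops <- scn$populations$pop
  samp <- if (is.null(n_sample)) scn$populations$n_sample else
    if (!is.null(names(n_sample))) n_sample[pops] else n_sample
  ev <- scn$events[order(scn$events$time), ]
  type_code <- c(merge = 1, admix = 2, resize = 3)
  em <- matrix(0, nrow(ev), 6)
  em[, 1] <- ev$time
  em[, 2] <- type_code[ev$type]
  em[, 3] <- match(ev$pop, pops) - 1L
  em[, 4] <- ifelse(is.na(ev$parent_a), 0, match(ev$parent_a, pops) - 1L)
  em[, 5] <- ifelse(is.na(ev$parent_b), 0, match(ev$parent_b, pops) - 1L)
  em[, 6] <- ifelse(ev$type == "resize", ev$size,
                    ifelse(is.na(ev$prop), 0, ev$prop))
  list(sample_sizes = as.integer(2 * samp), pop_sizes = as.numeric(scn$populations$n),
       events = em, pops = pops)
}

# internal: precompile a scenario template into a closure that binds a
# parameter row (named list) straight into the numeric encoding the
# compiled simulator consumes -- avoids per-simulation tibble work in the
# ABC hot loop
compile_scenario <- function(scn, n_sample = NULL) {
  pops <- scn$populations$pop
  samp <- if (is.null(n_sample)) scn$populations$n_sample else
    n_sample[pops]
  samp <- as.integer(2 * samp)
  type_code <- c(merge = 1, admix = 2, resize = 3)
  ev <- scn$events
  base <- matrix(0, nrow(ev), 6)
  base[, 2] <- type_code[ev$type]
  base[, 3] <- match(ev$pop, pops) - 1L
  base[, 4] <- ifelse(is.na(ev$parent_a), 0, match(ev$parent_a, pops) - 1L)
  base[, 5] <- ifelse(is.na(ev$parent_b), 0, match(ev$parent_b, pops) - 1L)
  mk <- function(v) {
    lapply(v, function(s) {
      if (is.na(s)) return(0)
      n <- suppressWarnings(as.numeric(s))
      if (!is.na(n)) n else parse(text = s)[[1]]
    })
  }
  time_e <- mk(ev$time)
  col6_e <- mk(ifelse(ev$type == "resize", as.character(ev$size),
                      as.character(ev$prop)))
  n_e <- mk(scn$populations$n)
  ev_fixed <- all(vapply(c(time_e, col6_e), is.numeric, logical(1)))
  n_fixed <- all(vapply(n_e, is.numeric, logical(1)))
  evalv <- function(es, env) {
    vapply(es, function(e) if (is.numeric(e)) e else eval(e, env), numeric(1))
  }
  if (ev_fixed) {
    base[, 1] <- unlist(time_e)
    base[, 6] <- unlist(col6_e)
    base <- base[order(base[, 1]), , drop = FALSE]
  }
  function(params) {
    em <- base
    if (!ev_fixed) {
      em[, 1] <- evalv(time_e, params)
      em[, 6] <- evalv(col6_e, params)
      em <- em[order(em[, 1]), , drop = FALSE]
    }
    list(sample_sizes = samp,
         pop_sizes = if (n_fixed) unlist(n_e) else evalv(n_e, params),
         events = em, pops = pops)
  }
}

#' Simulate one coalescent genealogy under a scenario
#'
#' @param scn A concrete [scenario()].
#' @return A list with `tmrca` (generations), `parent` / `node_time`
#'   (tree structure; tips first, root parent `-1`), `alleles` (tip allele
#'   sizes under the stepwise model at the scenario's `mu`), `tip_pop`.
#' @export
simulate_genealogy <- function(scn) {
  validate_scenario(scn)
  enc <- encode_scenario(scn)
  res <- sim_locus_cpp(enc$sample_sizes, enc$pop_sizes, enc$events, scn$mu, 200L)
  res$tip_pop <- rep(enc$pops, enc$sample_sizes)
  res
}

#' Overlay stepwise mutations on a genealogy
#'
#' Each branch receives `Poisson(mu * length)` mutations of +/-1 repeat unit
#' with equal probability; a tip allele is the ancestral size plus its net
#' root-to-tip displacement.  Sizes are never clipped.
#'
#' @param tree A list with `parent` and `node_time` as returned by
#'   [simulate_genealogy()] (tips are the first `(n+1)/2` nodes).
#' @param mu Mutation rate per generation.
#' @param ancestral_size Root allele size.
#' @return Integer vector of tip allele sizes.
#' @export
drop_mutations_smm <- function(tree, mu, ancestral_size = 200L) {
  parent <- tree$parent
  node_time <- tree$node_time
  nn <- length(parent)
  n_tips <- (nn + 1) / 2
  root <- which(parent == -1) - 1L
  size <- integer(nn)
  size[root + 1L] <- ancestral_size
  for (v in rev(seq_len(nn))) {
    if (v - 1L == root) next
    len <- node_time[parent[v] + 1L] - node_time[v]
    net <- 0L
    if (mu > 0) {
      m <- stats::rpois(1, mu * len)
      if (m > 0) net <- sum(sample(c(-1L, 1L), m, replace = TRUE))
    }
    size[v] <- size[parent[v] + 1L] + net
  }
  size[seq_len(n_tips)]
}

#' Simulate a diploid SSR dataset under a scenario
#'
#' Simulates `scn$loci` independent genealogies, drops stepwise mutations,
#' and pairs consecutive gene copies into diploid individuals.
#'
#' @param scn A concrete [scenario()].
#' @param n_sample Optional named/per-population override of sampled diploid
#'   counts.
#' @param ancestral_size Root allele size (repeat units).
#' @return A [genotype_tbl()].
#' @export
simulate_dataset <- function(scn, n_sample = NULL, ancestral_size = 200L) {
  validate_scenario(scn)
  if (scn$loci < 1) stop("need at least one locus", call. = FALSE)
  enc <- encode_scenario(scn, n_sample)
  m <- sim_dataset_cpp(enc$sample_sizes, enc$pop_sizes, enc$events, scn$mu,
                       scn$loci, as.integer(ancestral_size))
  n_ind <- sum(enc$sample_sizes) / 2
  pop_per_ind <- rep(enc$pops, enc$sample_sizes / 2)
  lset <- paste0("L", formatC(seq_len(scn$loci), width = 2, flag = "0"))
  ids <- paste0(pop_per_ind, "_", stats::ave(seq_len(n_ind), pop_per_ind,
                                             FUN = seq_along))
  a1 <- m[seq(1, 2 * n_ind, 2), , drop = FALSE]
  a2 <- m[seq(2, 2 * n_ind, 2), , drop = FALSE]
  genotype_tbl(tibble::tibble(
    id = rep(ids, times = scn$loci),
    pop = rep(pop_per_ind, times = scn$loci),
    locus = rep(lset, each = n_ind),
    a1 = as.vector(a1),
    a2 = as.vector(a2)))
}

#' Scale a mutation-scaled duration to generations
#'
#' A duration expressed as `D_g * mu` (mutation-scaled generations) divides
#' by the mutation rate to give generations, rounded to the nearest integer;
#' confidence bounds scale identically.
#'
#' @param d_gmu Point estimate (and optionally a vector of CI bounds).
#' @param mu Mutation rate per locus per generation (> 0).
#' @return Integer generations, same shape as `d_gmu`.
#' @export
scale_duration_to_generations <- function(d_gmu, mu) {
  if (!is.numeric(mu) || mu <= 0) stop("mu must be positive", call. = FALSE)
  round(d_gmu / mu)
}

#' Convert generations to years
#'
#' @param generations Number of generations (>= 0).
#' @param generation_time_years Generation time in years (default 2, a
#'   minimum bound for a woody pioneer).
#' @return Years, rounded to the nearest integer.
#' @export
generations_to_years <- function(generations, generation_time_years = 2) {
  if (any(generations < 0) || generation_time_years < 0) {
    stop("inputs must be non-negative", call. = FALSE)
  }
  round(generations * generation_time_years)
}
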