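#' Prior specification for scenario parameters
#'
#' @param params Tibble with columns `name`, `dist` (`"uniform"` or
#'   `"log-uniform"`), `lower`, `upper`.
#' @param constraints Character vector of inequality expressions over
#'   parameter names (e.g. `"t4 > t3"`), enforced by rejection.
#' @return A `prior_spec` object.
#' @export
prior_spec <- function(params, constraints = character(0)) {
  params <- tibble::as_tibble(params)
  stopifnot(all(c("name", "dist", "lower", "upper") %in% names(params)),
            all(params$dist %in% c("uniform", "log-uniform")),
            all(is.finite(params$lower)), all(is.finite(params$upper)),
            all(params$lower < params$upper))
  structure(list(params = params, constraints = constraints),
            class = "prior_spec")
}

#' Draw parameter vectors from a prior
#'
#' @param prior A [prior_spec()].
#' @param n Number of draws.
#' @return Tibble of `n` rows, one column per parameter; structural
#'   constraints hold in every row.
#' @export
sample_priors <- function(prior, n) {
  draw <- function(m) {
    out <- lapply(seq_len(nrow(prior$params)), function(i) {
      p <- prior$params[i, ]
      if (p$dist == "uniform") {
        stats::runif(m, p$lower, p$upper)
      } else {
        exp(stats::runif(m, log(p$lower), log(p$upper)))
      }
    })
    names(out) <- prior$params$name
    tibble::as_tibble(out)
  }
  if (length(prior$constraints) == 0) return(draw(n))
  acc <- NULL
  tries <- 0
  while (is.null(acc) || nrow(acc) < n) {
    tries <- tries + 1
    if (tries > 200) stop("prior constraints define a (near-)empty region", call. = FALSE)
    cand <- draw(max(n, 1000))
    ok <- rep(TRUE, nrow(cand))
    for (cs in prior$constraints) {
      ok <- ok & eval(parse(text = cs), envir = cand)
    }
    acc <- dplyr::bind_rows(acc, cand[ok, ])
  }
  acc[seq_len(n), ]
}

#' Summary-statistic design
#'
#' Declares which populations, pairs and admixture trios enter the summary
#' vector, and which statistic families are computed: per population
#' `nal` (mean allele count), `het` (mean unbiased gene diversity), `var`
#' (mean allele-size variance); per pair the pooled `nal2`/`het2`/`var2`,
#' `fst`, `das` (shared-allele distance) and `dmu2` (squared difference of
#' mean allele sizes, locus-averaged); per trio `alpha` (least-squares
#' admixture coefficient of the first population between the other two,
#' clamped to `[0, 1]`).
#'
#' @param pops Character vector of population labels (order fixes the
#'   statistic order).
#' @param pairs Two-column matrix/data frame of population pairs; default
#'   all unordered pairs.
#' @param trios List of length-3 character vectors `(admixed, parent1,
#'   parent2)`.
#' @param stats Statistic families to keep.
#' @return A `stat_design` object.
#' @export
stat_design <- function(pops, pairs = NULL, trios = list(),
                        stats = c("nal", "het", "var", "nal2", "het2", "var2",
                                  "fst", "das", "dmu2", "alpha")) {
  if (is.null(pairs)) {
    pairs <- t(utils::combn(pops, 2))
  }
  pairs <- as.matrix(pairs)
  stopifnot(all(pairs %in% pops), all(unlist(trios) %in% pops))
  structure(list(pops = pops, pairs = pairs, trios = trios, stats = stats),
            class = "stat_design")
}

# internal: full stat names in compiled output order, and the keep mask
design_layout <- function(design) {
  pops <- design$pops
  pair_lab <- apply(design$pairs, 1, paste, collapse = ".")
  nm <- c(
    as.vector(t(outer(pops, c("nal", "het", "var"), function(p, s) paste(s, p, sep = "_")))),
    as.vector(t(outer(pair_lab, c("nal2", "het2", "var2", "fst", "das", "dmu2"),
                      function(p, s) paste(s, p, sep = "_")))),
    if (length(design$trios)) {
      paste("alpha", vapply(design$trios, function(t) paste(t, collapse = "."),
                            character(1)), sep = "_")
    })
  fam <- sub("_.*$", "", nm)
  list(names = nm, keep = fam %in% design$stats)
}

#' Summary statistics of a genotype table
#'
#' Computes the deterministic, ordered statistic vector declared by a
#' [stat_design()] from observed or simulated genotypes.
#'
#' @param g A [genotype_tbl()].
#' @param design A [stat_design()]; its populations must all be present.
#' @return Named numeric vector.
#' @export
summary_statistics <- function(g, design) {
  g <- assert_genotypes(g)
  if (!all(design$pops %in% populations(g))) {
    stop("design names populations absent from the data", call. = FALSE)
  }
  gm <- gene_copy_matrix(g, pops = design$pops)
  pair_idx <- matrix(match(design$pairs, design$pops) - 1L, ncol = 2)
  trio_idx <- if (length(design$trios)) {
    matrix(unlist(lapply(design$trios, function(t) match(t, design$pops) - 1L)),
           ncol = 3, byrow = TRUE)
  } else matrix(integer(0), ncol = 3)
  v <- summary_stats_cpp(gm$m, gm$pop, length(design$pops),
                         pair_idx, trio_idx, "das" %in% design$stats)
  lay <- design_layout(design)
  stats::setNames(v, lay$names)[lay$keep]
}

# internal: stats straight from a simulated gene-copy matrix
summary_statistics_matrix <- function(m, pop_idx, design) {
  pair_idx <- matrix(match(design$pairs, design$pops) - 1L, ncol = 2)
  trio_idx <- if (length(design$trios)) {
    matrix(unlist(lapply(design$trios, function(t) match(t, design$pops) - 1L)),
           ncol = 3, byrow = TRUE)
  } else matrix(integer(0), ncol = 3)
  v <- summary_stats_cpp(m, pop_idx, length(design$pops), pair_idx, trio_idx)
  lay <- design_layout(design)
  stats::setNames(v, lay$names)[lay$keep]
}

#' ABC rejection sampling over a scenario set
#'
#' For each simulation: draws a scenario uniformly, draws parameters from
#' the shared prior (honouring constraints), simulates a dataset of the same
#' sampling design as the observed one, and computes summary statistics.
#' Retains the `retain_fraction` closest simulations by Euclidean distance
#' on statistics standardised by the simulated pool's per-statistic SD
#' (zero-variance statistics are dropped with a warning).
#'
#' @param observed Named statistic vector from [summary_statistics()].
#' @param scenarios List of scenario templates (see [scenario()]), all
#'   sharing `populations` labels.
#' @param prior A [prior_spec()] shared across scenarios.
#' @param design The [stat_design()] used for `observed`.
#' @param n_sim Total simulations (default 20000).
#' @param retain_fraction Fraction retained (default 0.01).
#' @param n_sample Named vector of sampled diploids per population.
#' @return A `gp_abc_ref` tibble: `scenario`, parameter columns, statistic
#'   columns, `distance`, `retained`; attributes carry the observed vector,
#'   design, scenario list and standardisation SDs.
#' @export
abc_rejection <- function(observed, scenarios, prior, design,
                          n_sim = 20000, retain_fraction = 0.01,
                          n_sample = NULL) {
  stopifnot(length(scenarios) >= 1)
  n_keep <- max(1, floor(n_sim * retain_fraction))
  scn_names <- vapply(scenarios, function(s) s$name, character(1))
  params <- sample_priors(prior, n_sim)
  scn_id <- sample.int(length(scenarios), n_sim, replace = TRUE)
  # honour per-scenario structural constraints (e.g. a daughter introduction
  # younger than its source's) by redrawing that scenario's parameter rows
  for (s in seq_along(scenarios)) {
    cs <- scenarios[[s]]$constraints
    rows <- which(scn_id == s)
    if (length(rows) > 0 && length(cs) > 0) {
      pr2 <- prior
      pr2$constraints <- unique(c(prior$constraints, cs))
      params[rows, ] <- sample_priors(pr2, length(rows))
    }
  }
  stat_rows <- matrix(NA_real_, n_sim, sum(design_layout(design)$keep))
  pair_idx <- matrix(match(design$pairs, design$pops) - 1L, ncol = 2)
  trio_idx <- if (length(design$trios)) {
    matrix(unlist(lapply(design$trios, function(t) match(t, design$pops) - 1L)),
           ncol = 3, byrow = TRUE)
  } else matrix(integer(0), ncol = 3)
  lay <- design_layout(design)

  # pre-validate one draw per scenario so a structurally broken scenario
  # fails fast with its name
  for (s in seq_along(scenarios)) {
    rows_s <- which(scn_id == s)
    if (length(rows_s) == 0) next
    ok <- FALSE
    for (tr in seq_len(min(5, length(rows_s)))) {
      cand <- try(validate_scenario(
        instantiate_scenario(scenarios[[s]], params[sample(rows_s, 1), ])),
        silent = TRUE)
      if (!inherits(cand, "try-error")) { ok <- TRUE; break }
    }
    if (!ok) stop("scenario '", scn_names[s], "' fails validation: ",
                  attr(cand, "condition")$message, call. = FALSE)
  }

  compiled <- lapply(scenarios, compile_scenario, n_sample = n_sample)
  do_das <- "das" %in% design$stats
  pcols <- as.list(params)
  for (i in seq_len(n_sim)) {
    s <- scn_id[i]
    prow <- lapply(pcols, function(col) col[i])
    enc <- compiled[[s]](prow)
    m <- sim_dataset_cpp(enc$sample_sizes, enc$pop_sizes, enc$events,
                         scenarios[[s]]$mu, scenarios[[s]]$loci, 200L)
    pop_idx <- rep(match(enc$pops, design$pops) - 1L, enc$sample_sizes)
    v <- summary_stats_cpp(m, pop_idx, length(design$pops), pair_idx, trio_idx,
                           do_das)
    stat_rows[i, ] <- v[lay$keep]
  }
  colnames(stat_rows) <- lay$names[lay$keep]

  sds <- apply(stat_rows, 2, stats::sd, na.rm = TRUE)
  usable <- which(is.finite(sds) & sds > 0 & names(sds) %in% names(observed))
  if (length(usable) < ncol(stat_rows)) {
    warning("dropped zero-variance or unmatched statistics: ",
            paste(setdiff(colnames(stat_rows), names(sds)[usable]), collapse = ", "))
  }
  z_sim <- sweep(stat_rows[, usable, drop = FALSE], 2, sds[usable], "/")
  z_obs <- observed[names(sds)[usable]] / sds[usable]
  z_sim[is.na(z_sim)] <- 0
  dist2 <- rowSums(sweep(z_sim, 2, z_obs, "-")^2)
  thresh <- sort(dist2)[n_keep]

  ref <- dplyr::bind_cols(
    tibble::tibble(scenario = scn_names[scn_id]),
    params,
    tibble::as_tibble(stat_rows),
    tibble::tibble(distance = sqrt(dist2),
                   retained = dist2 <= thresh))
  class(ref) <- c("gp_abc_ref", class(ref))
  attr(ref, "observed") <- observed
  attr(ref, "design") <- design
  attr(ref, "scenarios") <- scenarios
  attr(ref, "prior") <- prior
  attr(ref, "stat_sds") <- sds[usable]
  attr(ref, "n_sample") <- n_sample
  ref
}

#' Scenario posterior probabilities from a retained reference table
#'
#' Multinomial logistic regression of the scenario label on the statistics
#' centred at the observed vector, over the retained simulations; the
#' posterior probability of each scenario is the fitted probability at the
#' observed point (the regression's intercept).  95% CIs come from the
#' asymptotic covariance of the coefficients mapped through the softmax by
#' Monte Carlo.  Falls back to retained-set proportions with binomial CIs
#' (flagged in `method`) under complete separation or a singular fit.
#'
#' @param ref A [abc_rejection()] result.
#' @return Tibble: `scenario`, `n_sim`, `n_retained`, `pp`, `lo`, `hi`,
#'   `method`.
#' @export
model_posterior <- function(ref) {
  observed <- attr(ref, "observed")
  sds <- attr(ref, "stat_sds")
  ret <- ref[ref$retained, ]
  scn_all <- vapply(attr(ref, "scenarios"), function(s) s$name, character(1))
  counts <- table(factor(ret$scenario, levels = scn_all))
  n_ret <- nrow(ret)

  proportion_fallback <- function(note) {
    p <- as.numeric(counts) / n_ret
    se <- sqrt(p * (1 - p) / n_ret)
    tibble::tibble(scenario = scn_all,
                   n_sim = as.integer(table(factor(ref$scenario, levels = scn_all))),
                   n_retained = as.integer(counts),
                   pp = p,
                   lo = pmax(0, p - 1.96 * se),
                   hi = pmin(1, p + 1.96 * se),
                   method = note)
  }
  if (sum(counts > 0) < 2) return(proportion_fallback("proportion (single scenario retained)"))

  snames <- names(sds)
  X <- sweep(as.matrix(ret[, snames, drop = FALSE]), 2, observed[snames], "-")
  X <- sweep(X, 2, sds, "/")
  X[is.na(X)] <- 0
  y <- factor(ret$scenario, levels = scn_all[counts > 0])
  # linear-discriminant reduction before the logistic regression; the
  # observed point sits at the origin of the centred statistic space, so
  # its projection is the zero vector and the fitted probability there is
  # carried by the intercepts
  Z <- X
  ld <- try(suppressWarnings(MASS::lda(X, grouping = y)), silent = TRUE)
  if (!inherits(ld, "try-error")) Z <- X %*% ld$scaling
  # Epanechnikov weights on the rejection distance, so simulations closest
  # to the observed point dominate the local regression
  dret <- ret$distance
  w <- 1 - (dret / (max(dret) * 1.0001))^2
  fit <- try(suppressMessages(nnet::multinom(y ~ Z, weights = w, trace = FALSE,
                                             maxit = 500)),
             silent = TRUE)
  if (inherits(fit, "try-error")) return(proportion_fallback("proportion (regression failed)"))
  cf <- stats::coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1)
  if (any(abs(cf) > 25)) return(proportion_fallback("proportion (separation)"))
  V <- try(stats::vcov(fit), silent = TRUE)

  softmax_at_zero <- function(intercepts) {
    v <- c(0, intercepts)
    e <- exp(v - max(v))
    e / sum(e)
  }
  pp_present <- softmax_at_zero(cf[, 1])
  ch <- if (!inherits(V, "try-error") && all(is.finite(V))) {
    try(chol(V + diag(1e-8 + 1e-6 * max(abs(diag(V))), nrow(V))), silent = TRUE)
  } else structure("nope", class = "try-error")
  if (!inherits(ch, "try-error")) {
    nco <- ncol(cf)
    draws <- matrix(stats::rnorm(500 * length(cf)), 500) %*% ch
    draws <- sweep(draws, 2, as.vector(t(cf)), "+")
    int_cols <- seq(1, length(cf), by = nco)
    pp_draws <- t(apply(draws[, int_cols, drop = FALSE], 1, softmax_at_zero))
    lo_p <- apply(pp_draws, 2, stats::quantile, 0.025, na.rm = TRUE)
    hi_p <- apply(pp_draws, 2, stats::quantile, 0.975, na.rm = TRUE)
  } else {
    lo_p <- hi_p <- pp_present
  }
  present <- scn_all[counts > 0]
  pp <- lo <- hi <- stats::setNames(rep(0, length(scn_all)), scn_all)
  pp[present] <- pp_present
  lo[present] <- pmin(lo_p, pp_present)
  hi[present] <- pmax(hi_p, pp_present)
  hi[counts == 0] <- 3 / max(n_ret, 1) # absent scenarios: crude upper bound
  tibble::tibble(scenario = scn_all,
                 n_sim = as.integer(table(factor(ref$scenario, levels = scn_all))),
                 n_retained = as.integer(counts),
                 pp = unname(pp / sum(pp)),
                 lo = unname(pmax(0, lo)),
                 hi = unname(pmin(1, hi)),
                 method = "logistic")
}

# internal: parameter transform helpers
param_transform <- function(prior) {
  p <- prior$params
  list(
    fwd = function(name, x) {
      i <- match(name, p$name)
      if (p$lower[i] >= 0 && p$upper[i] <= 1) stats::qlogis(pmin(pmax(x, 1e-8), 1 - 1e-8))
      else log(pmax(x, 1e-12))
    },
    bwd = function(name, x) {
      i <- match(name, p$name)
      if (p$lower[i] >= 0 && p$upper[i] <= 1) stats::plogis(x) else exp(x)
    })
}

#' Regression-adjusted parameter posterior for one scenario
#'
#' Local-linear adjustment over the retained simulations of the chosen
#' scenario: each parameter (log scale for times/sizes, logit scale for
#' proportions) is regressed on the standardised statistics and
#' residual-shifted to the observed point.  Falls back to the unadjusted
#' rejection posterior (flagged) if the regression is singular.
#'
#' @param ref A [abc_rejection()] result.
#' @param scenario_name Scenario whose retained draws to use (default: the
#'   most retained).
#' @param min_retained Minimum retained draws required (default 200).
#' @return A `gp_abc_post` list: `samples` (tibble of adjusted parameter
#'   draws), `quantiles` (tibble: parameter, q2.5, median, q97.5),
#'   `scenario`, `adjusted` flag.
#' @export
parameter_posterior <- function(ref, scenario_name = NULL, min_retained = 200) {
  ret <- ref[ref$retained, ]
  if (is.null(scenario_name)) {
    scenario_name <- names(sort(table(ret$scenario), decreasing = TRUE))[1]
  }
  ret <- ret[ret$scenario == scenario_name, ]
  if (nrow(ret) < min_retained) {
    stop("only ", nrow(ret), " retained simulations for scenario '",
         scenario_name, "' (need ", min_retained, ")", call. = FALSE)
  }
  prior <- attr(ref, "prior")
  observed <- attr(ref, "observed")
  sds <- attr(ref, "stat_sds")
  snames <- names(sds)
  X <- sweep(as.matrix(ret[, snames, drop = FALSE]), 2, observed[snames], "-")
  X <- sweep(X, 2, sds, "/")
  X[is.na(X)] <- 0
  tr <- param_transform(prior)
  pnames <- prior$params$name
  adjusted <- TRUE
  samples <- lapply(pnames, function(pn) {
    th <- tr$fwd(pn, ret[[pn]])
    fit <- try(stats::lm.fit(cbind(1, X), th), silent = TRUE)
    if (inherits(fit, "try-error") || any(is.na(fit$coefficients))) {
      adjusted <<- FALSE
      return(tr$bwd(pn, th))
    }
    adj <- fit$coefficients[1] + fit$residuals # prediction at observed + residuals
    tr$bwd(pn, adj)
  })
  names(samples) <- pnames
  samples <- tibble::as_tibble(samples)
  # posterior draws must honour the structural constraints of the scenario
  scn_list <- attr(ref, "scenarios")
  scn_t <- scn_list[[match(scenario_name,
                           vapply(scn_list, function(s) s$name, character(1)))]]
  cs <- unique(c(prior$constraints, scn_t$constraints))
  if (length(cs) > 0) {
    ok <- rep(TRUE, nrow(samples))
    for (cexp in cs) ok <- ok & eval(parse(text = cexp), envir = samples)
    if (sum(ok) >= 20) samples <- samples[ok, ]
  }
  qs <- purrr::map_dfr(pnames, function(pn) {
    q <- stats::quantile(samples[[pn]], c(0.025, 0.5, 0.975))
    tibble::tibble(parameter = pn, q025 = q[1], median = q[2], q975 = q[3])
  })
  structure(list(samples = samples, quantiles = qs, scenario = scenario_name,
                 adjusted = adjusted),
            class = "gp_abc_post")
}

#' Posterior predictive model checking
#'
#' Simulates datasets from the fitted scenario at posterior parameter draws
#' and reports, per summary statistic, the fraction of predictive values
#' below the observed one (a statistic "fits" when the fraction lies in
#' `[0.05, 0.95]`), the overall percentage fitting, and a PCA of the
#' predictive statistics with the observed point projected (squared
#' Mahalanobis distance in the retained PC space).
#'
#' @param ref A [abc_rejection()] result.
#' @param post A [parameter_posterior()] result.
#' @param n_pred Predictive simulations (>= 100).
#' @return A `gp_abc_check` list: `tail` (tibble statistic/fraction/fits),
#'   `overall_fit_pct`, `pca` (scores + observed projection),
#'   `mahalanobis_sq`.
#' @export
model_check <- function(ref, post, n_pred = 200) {
  if (n_pred < 100) stop("need at least 100 predictive simulations", call. = FALSE)
  design <- attr(ref, "design")
  observed <- attr(ref, "observed")
  n_sample <- attr(ref, "n_sample")
  scenarios <- attr(ref, "scenarios")
  scn_t <- scenarios[[match(post$scenario,
                            vapply(scenarios, function(s) s$name, character(1)))]]
  lay <- design_layout(design)
  draws <- post$samples[sample.int(nrow(post$samples), n_pred, replace = TRUE), ]
  pair_idx <- matrix(match(design$pairs, design$pops) - 1L, ncol = 2)
  trio_idx <- if (length(design$trios)) {
    matrix(unlist(lapply(design$trios, function(t) match(t, design$pops) - 1L)),
           ncol = 3, byrow = TRUE)
  } else matrix(integer(0), ncol = 3)
  sim_stats <- matrix(NA_real_, n_pred, sum(lay$keep),
                      dimnames = list(NULL, lay$names[lay$keep]))
  comp <- compile_scenario(scn_t, n_sample = n_sample)
  do_das <- "das" %in% design$stats
  dcols <- as.list(draws)
  for (i in seq_len(n_pred)) {
    enc <- comp(lapply(dcols, function(col) col[i]))
    m <- sim_dataset_cpp(enc$sample_sizes, enc$pop_sizes, enc$events, scn_t$mu,
                         scn_t$loci, 200L)
    pop_idx <- rep(match(enc$pops, design$pops) - 1L, enc$sample_sizes)
    v <- summary_stats_cpp(m, pop_idx, length(design$pops), pair_idx, trio_idx,
                           do_das)
    sim_stats[i, ] <- v[lay$keep]
  }
  common <- intersect(colnames(sim_stats), names(observed))
  frac <- vapply(common, function(s) {
    mean(sim_stats[, s] < observed[s], na.rm = TRUE)
  }, numeric(1))
  tail_tbl <- tibble::tibble(statistic = common, fraction_below = frac,
                             fits = frac >= 0.05 & frac <= 0.95)
  keep <- apply(sim_stats[, common, drop = FALSE], 2,
                function(x) stats::sd(x, na.rm = TRUE) > 0)
  Xs <- sim_stats[, common[keep], drop = FALSE]
  Xs[is.na(Xs)] <- 0
  pc <- stats::prcomp(Xs, center = TRUE, scale. = TRUE)
  k <- max(2, min(5, sum(pc$sdev > 1e-8)))
  obs_z <- (observed[common[keep]] - pc$center) / pc$scale
  obs_proj <- as.numeric(obs_z %*% pc$rotation[, seq_len(k)])
  maha <- sum((obs_proj / pc$sdev[seq_len(k)])^2)
  structure(list(tail = tail_tbl,
                 overall_fit_pct = 100 * mean(tail_tbl$fits),
                 pca = list(scores = pc$x[, seq_len(k), drop = FALSE],
                            observed = obs_proj),
                 mahalanobis_sq = maha),
            class = "gp_abc_check")
}
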