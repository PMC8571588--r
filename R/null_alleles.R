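#' EM estimation of the null-allele frequency at one locus x population
#'
#' Fits the classic null-allele mixture under within-population HWE: an
#' apparent homozygote A/A mixes true A/A and A/null carriers, and (with
#' `include_blanks = TRUE`, the default) blank genotypes mix null/null
#' homozygotes with a co-estimated locus-wide technical failure rate.
#' With `include_blanks = FALSE` blanks are discarded and the visible
#' genotype likelihood is truncated on amplification.  Estimation is by
#' gene counting (EM); the observed-data log-likelihood is non-decreasing
#' across iterations.
#'
#' @param a1,a2 Integer allele vectors for one locus in one population
#'   (both `NA` = blank genotype).
#' @param tol Convergence tolerance on the largest frequency change
#'   (default 1e-6).
#' @param max_iter Maximum EM iterations (default 1000).
#' @param include_blanks Treat blanks as potential null homozygotes.
#' @return A list with `beta` (null frequency), `freqs` (named visible
#'   allele frequencies, summing to `1 - beta`), `failure_rate`,
#'   `iterations`, `converged`, and `loglik_trace`.
#' @export
em_null_frequency <- function(a1, a2, tol = 1e-6, max_iter = 1000,
                              include_blanks = TRUE) {
  keep_blank <- is.na(a1) & is.na(a2)
  vis <- !keep_blank
  if (!any(vis)) stop("no non-missing genotypes", call. = FALSE)
  v1 <- a1[vis]; v2 <- a2[vis]
  alleles <- sort(unique(c(v1, v2)))
  k <- length(alleles)
  i1 <- match(v1, alleles); i2 <- match(v2, alleles)
  n_vis <- length(v1)
  n_blank <- if (include_blanks) sum(keep_blank) else 0L
  n <- n_vis + n_blank

  het <- i1 != i2
  hom_counts <- tabulate(i1[!het], nbins = k)          # apparent homozygotes per allele
  het_copy_counts <- tabulate(c(i1[het], i2[het]), nbins = k)

  # init: raw visible frequencies scaled to 1 - beta0
  beta <- 0.1
  raw <- tabulate(c(i1, i2), nbins = k) / (2 * n_vis)
  p <- raw * (1 - beta)
  f <- if (include_blanks && n > 0) 0.01 else 0

  loglik <- function(p, beta, f) {
    ll <- 0
    if (any(het)) {
      ll <- ll + sum(log(pmax(2 * p[i1[het]] * p[i2[het]], 1e-300))) +
        sum(het) * log(pmax(1 - f, 1e-300))
    }
    hom_i <- i1[!het]
    if (length(hom_i)) {
      ll <- ll + sum(log(pmax(p[hom_i]^2 + 2 * p[hom_i] * beta, 1e-300))) +
        length(hom_i) * log(pmax(1 - f, 1e-300))
    }
    if (include_blanks && n_blank > 0) {
      ll <- ll + n_blank * log(pmax(f + (1 - f) * beta^2, 1e-300))
    }
    if (!include_blanks) {
      # truncated likelihood: condition on the genotype being visible
      ll <- ll - n_vis * log(pmax(1 - beta^2, 1e-300))
    }
    ll
  }

  trace <- numeric(0)
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    # E-step
    w <- ifelse(p + 2 * beta > 0, p / (p + 2 * beta), 1)  # P(true hom | apparent hom)
    count <- het_copy_counts + hom_counts * (1 + w)
    if (include_blanks) {
      pb <- f + (1 - f) * beta^2
      q <- if (pb > 0) (1 - f) * beta^2 / pb else 0       # P(null-null | blank)
      null_count <- sum(hom_counts * (1 - w)) + 2 * n_blank * q
      fail <- n_blank * (1 - q)
      G <- 2 * (n - fail)
      f_new <- if (n > 0) fail / n else 0
    } else {
      m <- if (beta < 1) n_vis * beta^2 / (1 - beta^2) else 0  # imputed hidden blanks
      null_count <- sum(hom_counts * (1 - w)) + 2 * m
      G <- 2 * (n_vis + m)
      f_new <- 0
    }
    p_new <- count / G
    beta_new <- null_count / G
    delta <- max(abs(c(p_new - p, beta_new - beta)))
    p <- p_new; beta <- beta_new; f <- f_new
    trace <- c(trace, loglik(p, beta, f))
    if (delta < tol) { converged <- TRUE; break }
  }
  list(beta = beta,
       freqs = stats::setNames(p, alleles),
       failure_rate = f,
       iterations = it,
       converged = converged,
       loglik_trace = trace)
}

#' Null-allele estimates for every locus x population
#'
#' @param g A [genotype_tbl()].
#' @inheritParams em_null_frequency
#' @return A tibble (class `null_allele_est`) with one row per locus x
#'   population: `beta`, `failure_rate`, `iterations`, `converged` and a
#'   list-column `freqs` of named visible-allele frequency vectors
#'   (summing to `1 - beta`).
#' @export
estimate_null_alleles <- function(g, tol = 1e-6, max_iter = 1000,
                                  include_blanks = TRUE) {
  g <- assert_genotypes(g)
  out <- strip_gt(g) |>
    dplyr::group_by(.data$locus, pop = .data$pop) |>
    dplyr::group_modify(function(d, key) {
      if (all(is.na(d$a1))) {
        return(tibble::tibble(beta = NA_real_, failure_rate = NA_real_,
                              iterations = 0L, converged = NA,
                              freqs = list(NULL)))
      }
      fit <- em_null_frequency(d$a1, d$a2, tol = tol, max_iter = max_iter,
                               include_blanks = include_blanks)
      tibble::tibble(beta = fit$beta, failure_rate = fit$failure_rate,
                     iterations = fit$iterations, converged = fit$converged,
                     freqs = list(fit$freqs))
    }) |>
    dplyr::ungroup()
  class(out) <- c("null_allele_est", class(out))
  out
}

#' Null-corrected expected heterozygosity per population
#'
#' Recomputes Nei's unbiased gene diversity from the EM-corrected allele
#' frequencies with the inferred null allele included as an extra allele
#' class (frequency `beta`), i.e. `He = n/(n-1) * (1 - sum(p_i^2) - beta^2)`.
#' Because apparent homozygote excess is reassigned to heterozygote classes
#' involving the null, the corrected He exceeds the uncorrected value
#' whenever `beta > 0`; with `beta = 0` it reduces to the raw statistic.
#' Loci with `beta = 1` are skipped.
#'
#' @param g A [genotype_tbl()] (for gene counts).
#' @param est Output of [estimate_null_alleles()].
#' @return Tibble with `pop`, `he_corrected` (mean over loci).
#' @export
corrected_expected_het <- function(g, est) {
  g <- assert_genotypes(g)
  counts <- g |>
    dplyr::filter(!is.na(.data$a1)) |>
    dplyr::count(.data$locus, pop = .data$pop, name = "n_ind")
  est |>
    dplyr::left_join(counts, by = c("locus", "pop")) |>
    dplyr::filter(!is.na(.data$beta), .data$beta < 1, .data$n_ind >= 1) |>
    dplyr::mutate(he = purrr::pmap_dbl(
      list(.data$freqs, .data$beta, .data$n_ind),
      function(fr, b, ni) {
        n <- 2 * ni
        if (n < 2) return(NA_real_)
        n / (n - 1) * (1 - sum(fr^2) - b^2)
      })) |>
    dplyr::group_by(.data$pop) |>
    dplyr::summarise(he_corrected = mean(.data$he, na.rm = TRUE), .groups = "drop")
}

# ---------------------------------------------------------------------------
# Weir & Cockerham theta and its ENA-corrected variant

# W&C (1984) variance components for one allele at one locus across r pops.
# n: gene-copy counts per pop (2*individuals); p: allele frequency per pop;
# h: heterozygote frequency (individuals carrying the allele once) per pop.
wc_components <- function(n_ind, p, h) {
  r <- length(p)
  n <- n_ind
  nbar <- mean(n)
  if (nbar <= 1) return(c(a = 0, b = 0, c = 0))
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2
  c(a = a, b = b, c = c_)
}

#' Weir & Cockerham's theta (FST), with optional ENA null-allele correction
#'
#' Multi-allele, multi-locus theta averaged by the ratio of summed variance
#' components.  With `est` supplied, applies the ENA scheme: per locus and
#' population the EM-corrected visible allele frequencies are used and the
#' null-allele class is excluded from the sums, with heterozygote
#' frequencies taken at their HWE expectations under the corrected
#' frequencies.
#'
#' @param g A [genotype_tbl()].
#' @param est Optional [estimate_null_alleles()] output (ENA correction).
#' @param pops Populations to include (default: all; give two for pairwise).
#' @return Theta (scalar); `NA` if no usable locus.
#' @export
ena_fst <- function(g, est = NULL, pops = NULL) {
  g <- assert_genotypes(g)
  if (is.null(pops)) pops <- populations(g)
  if (length(pops) < 2) stop("need at least two populations", call. = FALSE)
  g <- g[g$pop %in% pops, ]
  num <- 0; den <- 0
  for (l in loci(g)) {
    d <- g[g$locus == l & !is.na(g$a1), ]
    counts <- table(factor(d$pop, levels = pops))
    if (sum(counts >= 1) < 2) next
    present <- names(counts)[counts >= 1]
    d <- d[d$pop %in% present, ]
    n_ind <- as.numeric(table(factor(d$pop, levels = present)))
    if (is.null(est)) {
      alleles <- sort(unique(c(d$a1, d$a2)))
      if (length(alleles) < 2) next
      for (a in alleles) {
        p <- vapply(present, function(pp) {
          dd <- d[d$pop == pp, ]
          mean(c(dd$a1, dd$a2) == a)
        }, numeric(1))
        h <- vapply(present, function(pp) {
          dd <- d[d$pop == pp, ]
          mean((dd$a1 == a) != (dd$a2 == a))
        }, numeric(1))
        comp <- wc_components(n_ind, p, h)
        num <- num + comp["a"]; den <- den + sum(comp)
      }
    } else {
      e <- est[est$locus == l & est$pop %in% present, ]
      if (nrow(e) < length(present) || any(is.na(e$beta))) next
      e <- e[match(present, e$pop), ]
      alleles <- sort(unique(as.integer(unlist(lapply(e$freqs, names)))))
      if (length(alleles) < 2) next
      for (a in alleles) {
        p <- vapply(seq_along(present), function(j) {
          fr <- e$freqs[[j]]
          if (as.character(a) %in% names(fr)) unname(fr[as.character(a)]) else 0
        }, numeric(1))
        # HWE heterozygote frequency for the visible allele (null included
        # in the complement)
        h <- 2 * p * (1 - p)
        comp <- wc_components(n_ind, p, h)
        num <- num + comp["a"]; den <- den + sum(comp)
      }
    }
  }
  if (den == 0) return(NA_real_)
  unname(num / den)
}

#' Cavalli-Sforza & Edwards chord distance, optionally INA-corrected
#'
#' Per locus `(2/pi) * sqrt(2 * (1 - sum_a sqrt(x_a * y_a)))`, averaged over
#' loci shared by both populations.  With the INA correction the inferred
#' null allele enters each frequency vector as one extra shared allele
#' class.
#'
#' @param freq_a,freq_b Per-locus lists of named allele-frequency vectors
#'   (as produced by [freq_vectors()]).
#' @param beta_a,beta_b Optional per-locus null-frequency vectors (INA); the
#'   visible frequencies are then expected to sum to `1 - beta`.
#' @return Mean chord distance over shared loci.
#' @export
chord_distance <- function(freq_a, freq_b, beta_a = NULL, beta_b = NULL) {
  shared <- intersect(names(freq_a), names(freq_b))
  if (length(shared) == 0) stop("no shared loci", call. = FALSE)
  per_locus <- vapply(shared, function(l) {
    x <- freq_a[[l]]; y <- freq_b[[l]]
    alleles <- union(names(x), names(y))
    xv <- ifelse(alleles %in% names(x), x[alleles], 0)
    yv <- ifelse(alleles %in% names(y), y[alleles], 0)
    if (!is.null(beta_a)) {
      xv <- c(xv, beta_a[[l]])
      yv <- c(yv, beta_b[[l]])
    }
    s <- sum(sqrt(xv * yv))
    (2 / pi) * sqrt(2 * max(0, 1 - s))
  }, numeric(1))
  mean(per_locus)
}

#' Per-locus allele frequency vectors for one group
#'
#' @param freq_tbl Output of [allele_frequencies()].
#' @param group Group label.
#' @return Named list (by locus) of named frequency vectors.
#' @export
freq_vectors <- function(freq_tbl, group) {
  ft <- freq_tbl[freq_tbl$group == group, ]
  split(ft, ft$locus) |>
    lapply(function(d) stats::setNames(d$freq, d$allele))
}

# internal: per-locus corrected visible freq vectors + beta for one pop
corrected_freq_vectors <- function(est, pop) {
  e <- est[est$pop == pop & !is.na(est$beta), ]
  list(freqs = stats::setNames(e$freqs, e$locus),
       beta = stats::setNames(as.list(e$beta), e$locus))
}
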