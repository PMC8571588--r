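#' Nei's unbiased expected heterozygosity (gene diversity)
#'
#' `He = n/(n-1) * (1 - sum(p_i^2))` where `n` is the number of gene copies
#' the frequencies were estimated from.
#'
#' @param freqs Allele frequency vector summing to 1.
#' @param gene_count Number of gene copies behind `freqs` (>= 2).
#' @return Unbiased gene diversity in `[0, 1]`.
#' @export
expected_het <- function(freqs, gene_count) {
  if (gene_count < 2) stop("gene_count must be >= 2", call. = FALSE)
  if (abs(sum(freqs) - 1) > 1e-8) stop("frequencies must sum to 1", call. = FALSE)
  n <- gene_count
  n / (n - 1) * (1 - sum(freqs^2))
}

#' Observed heterozygosity at one locus in one population
#'
#' Fraction of non-missing individuals carrying two distinct alleles.
#'
#' @param g A [genotype_tbl()].
#' @param locus,population Labels selecting the cell.
#' @return A number in `[0, 1]`, or `NA` if every call is missing.
#' @export
observed_het <- function(g, locus, population) {
  g <- assert_genotypes(g)
  sub <- g[g$locus == locus & g$pop == population & !is.na(g$a1), ]
  if (nrow(sub) == 0) return(NA_real_)
  mean(sub$a1 != sub$a2)
}

#' Inbreeding coefficient from Ho and He
#'
#' @param Ho,He Observed and expected heterozygosity.
#' @return `1 - Ho/He`; `NA` when `He` is 0 (undefined under monomorphism).
#' @export
fis <- function(Ho, He) {
  ifelse(He > 0, 1 - Ho / He, NA_real_)
}

#' Rarefied allelic richness at one locus
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies: `sum_i [1 - C(N - N_i, g)/C(N, g)]` with `N` total copies and
#' `N_i` copies of allele i.  Exact (hypergeometric), no Monte Carlo.
#'
#' @param counts Integer vector of per-allele gene-copy counts.
#' @param g Standardised gene count (`g <= sum(counts)`).
#' @return Expected allele count in the subsample.
#' @export
rarefied_allelic_richness <- function(counts, g) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (g > N) stop("rarefaction size exceeds available gene copies", call. = FALSE)
  if (g < 1) stop("rarefaction size must be >= 1", call. = FALSE)
  sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
}

#' Private allele counts
#'
#' Counts alleles observed in exactly one population of the chosen partition.
#' Restrict `universe` to compare within a subset (e.g. islands only).
#'
#' @param freq_tbl Output of [allele_frequencies()].
#' @param universe Optional character vector of groups defining the
#'   comparison; defaults to all groups present.
#' @param rarefaction_genes If non-NULL, additionally reports the expected
#'   number of private alleles in a subsample of this many gene copies
#'   (the same hypergeometric scheme as [rarefied_allelic_richness()]
#'   applied to the private-allele indicator; an approximation in that
#'   privacy is assessed on the full sample).
#' @return Tibble with columns `group`, `private`, and `private_rarefied`
#'   when requested.
#' @export
private_alleles <- function(freq_tbl, universe = NULL, rarefaction_genes = NULL) {
  if (!is.null(universe)) freq_tbl <- freq_tbl[freq_tbl$group %in% universe, ]
  groups <- unique(freq_tbl$group)
  if (length(groups) < 2) {
    warning("single population: every allele is trivially private")
  }
  occ <- freq_tbl |>
    dplyr::distinct(.data$locus, .data$allele, .data$group) |>
    dplyr::count(.data$locus, .data$allele, name = "n_groups")
  priv <- freq_tbl |>
    dplyr::inner_join(occ, by = c("locus", "allele")) |>
    dplyr::filter(.data$n_groups == 1)
  out <- priv |>
    dplyr::count(.data$group, name = "private") |>
    dplyr::right_join(tibble::tibble(group = groups), by = "group") |>
    dplyr::mutate(private = dplyr::coalesce(.data$private, 0L))
  if (!is.null(rarefaction_genes)) {
    gg <- rarefaction_genes
    pr <- priv |>
      dplyr::filter(.data$gene_count >= gg) |>
      dplyr::mutate(p_seen = 1 - exp(lchoose(.data$gene_count - .data$count, gg) -
                                       lchoose(.data$gene_count, gg))) |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(private_rarefied = sum(.data$p_seen), .groups = "drop")
    out <- dplyr::left_join(out, pr, by = "group") |>
      dplyr::mutate(private_rarefied = dplyr::coalesce(.data$private_rarefied, 0))
  }
  out
}

#' Per-population diversity table
#'
#' One row per population with sample size (`n`), total distinct alleles over
#' loci (`a`), mean rarefied allelic richness (`ar`), private allele count
#' (`pa`, with `pa_rarefied`), observed and expected heterozygosity means
#' over loci (`ho`, `he`) and the multi-locus inbreeding coefficient `fis`
#' computed as `1 - mean(Ho)/mean(He)` (ratio of means).  With
#' `null_est` supplied, adds null-corrected `he_corrected`/`fis_corrected`
#' (see [corrected_expected_het()]).
#'
#' @param g A [genotype_tbl()].
#' @param rarefaction_genes Gene copies for rarefaction standardisation
#'   (160 for island-scale comparisons, 16 for region-scale ones).  Loci x
#'   populations with fewer copies are excluded from the AR mean.
#' @param null_est Optional output of [estimate_null_alleles()].
#' @return A tibble, one row per population.
#' @export
diversity_table <- function(g, rarefaction_genes = 160, null_est = NULL) {
  g <- assert_genotypes(g)
  freq <- allele_frequencies(g, by = "pop")
  pops <- populations(g)

  per_locus <- freq |>
    dplyr::group_by(.data$locus, .data$group) |>
    dplyr::summarise(
      n_alleles = dplyr::n(),
      gene_count = dplyr::first(.data$gene_count),
      he = {
        nn <- dplyr::first(.data$gene_count)
        if (nn >= 2) expected_het(.data$freq, nn) else NA_real_
      },
      ar = {
        nn <- dplyr::first(.data$gene_count)
        if (nn >= rarefaction_genes) {
          rarefied_allelic_richness(.data$count, rarefaction_genes)
        } else NA_real_
      },
      .groups = "drop")

  ho_tbl <- strip_gt(g) |>
    dplyr::filter(!is.na(.data$a1)) |>
    dplyr::group_by(.data$locus, group = .data$pop) |>
    dplyr::summarise(ho = mean(.data$a1 != .data$a2), .groups = "drop")

  per_locus <- dplyr::left_join(per_locus, ho_tbl, by = c("locus", "group"))

  pa <- private_alleles(freq, rarefaction_genes = rarefaction_genes)

  out <- per_locus |>
    dplyr::group_by(pop = .data$group) |>
    dplyr::summarise(
      a = sum(.data$n_alleles),
      ar = mean(.data$ar, na.rm = TRUE),
      ho = mean(.data$ho, na.rm = TRUE),
      he = mean(.data$he, na.rm = TRUE),
      .groups = "drop") |>
    dplyr::mutate(fis = fis(.data$ho, .data$he))

  n_tbl <- strip_gt(g) |>
    dplyr::distinct(.data$id, .data$pop) |>
    dplyr::count(pop = .data$pop, name = "n")

  out <- n_tbl |>
    dplyr::left_join(out, by = "pop") |>
    dplyr::left_join(pa |> dplyr::rename(pop = "group", pa = "private",
                                         pa_rarefied = "private_rarefied"),
                     by = "pop")

  if (!is.null(null_est)) {
    hec <- corrected_expected_het(g, null_est)
    out <- out |>
      dplyr::left_join(hec, by = "pop") |>
      dplyr::mutate(fis_corrected = fis(.data$ho, .data$he_corrected))
  }
  out[match(pops, out$pop), ]
}

#' Benjamini-Yekutieli false-discovery-rate correction
#'
#' Step-up adjustment with the harmonic-number factor `c(m) = sum(1/i)`,
#' valid under arbitrary dependence.  Thin wrapper over
#' `stats::p.adjust(method = "BY")`.
#'
#' @param pvals Vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, capped at 1.
#' @export
by_correction <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BY")
}

new_test_result <- function(statistic, p_value, method, n_permutations = NA_integer_,
                            note = NA_character_) {
  tibble::tibble(statistic = statistic, p_value = p_value,
                 p_adjusted = NA_real_, method = method,
                 n_permutations = n_permutations, note = note)
}

#' Hardy-Weinberg equilibrium test (Monte-Carlo chi-square)
#'
#' Chi-square goodness of fit of genotype counts against HWE expectations,
#' with the null distribution built by shuffling gene copies and re-pairing
#' them (conditional on the observed allele counts).
#'
#' @param g A [genotype_tbl()].
#' @param locus,population Cell to test.
#' @param n_mc Monte-Carlo replicates (default 1000).
#' @return One-row tibble (statistic, p_value, method, n_permutations);
#'   `NA` statistic for a monomorphic locus, a note when n < 5.
#' @export
hwe_test <- function(g, locus, population, n_mc = 1000) {
  g <- assert_genotypes(g)
  sub <- g[g$locus == locus & g$pop == population & !is.na(g$a1), ]
  n <- nrow(sub)
  if (n == 0) return(new_test_result(NA_real_, NA_real_, "hwe-mc", n_mc, "no data"))
  copies <- c(sub$a1, sub$a2)
  if (length(unique(copies)) < 2) {
    return(new_test_result(NA_real_, NA_real_, "hwe-mc", n_mc, "monomorphic"))
  }
  note <- if (n < 5) "low power: n < 5" else NA_character_
  chisq_stat <- function(a1, a2) {
    geno <- paste(pmin(a1, a2), pmax(a1, a2))
    obs <- table(geno)
    p <- table(c(a1, a2)) / (2 * length(a1))
    al <- as.integer(names(p))
    exp_tbl <- outer(seq_along(al), seq_along(al), function(i, j) {
      ifelse(i == j, p[i] * p[j], 2 * p[i] * p[j])
    })
    keys <- outer(al, al, function(x, y) paste(pmin(x, y), pmax(x, y)))
    keep <- upper.tri(exp_tbl, diag = TRUE)
    e <- length(a1) * exp_tbl[keep]
    k <- keys[keep]
    o <- as.numeric(obs[match(k, names(obs))])
    o[is.na(o)] <- 0
    sum((o - e)^2 / e)
  }
  obs_stat <- chisq_stat(sub$a1, sub$a2)
  ge <- 0L
  for (i in seq_len(n_mc)) {
    perm <- sample(copies)
    s <- chisq_stat(perm[seq_len(n)], perm[n + seq_len(n)])
    if (s >= obs_stat - 1e-12) ge <- ge + 1L
  }
  p <- (ge + 1) / (n_mc + 1)
  new_test_result(obs_stat, p, "hwe-mc", n_mc, note)
}

#' Genotypic linkage-disequilibrium permutation test
#'
#' Contingency chi-square of the joint single-locus genotype table for a
#' locus pair, with the null built by permuting one locus's genotypes across
#' individuals.
#'
#' @param g A [genotype_tbl()].
#' @param locus_pair Character vector of two locus names.
#' @param population Population to test within.
#' @param n_perm Permutations (default 999).
#' @return One-row test tibble; `NA` if either locus is monomorphic.
#' @export
ld_test <- function(g, locus_pair, population, n_perm = 999) {
  g <- assert_genotypes(g)
  stopifnot(length(locus_pair) == 2)
  sub <- g[g$pop == population & g$locus %in% locus_pair, ]
  geno_str <- function(d) paste(pmin(d$a1, d$a2), pmax(d$a1, d$a2))
  d1 <- sub[sub$locus == locus_pair[1], ]
  d2 <- sub[sub$locus == locus_pair[2], ]
  common <- intersect(d1$id[!is.na(d1$a1)], d2$id[!is.na(d2$a1)])
  d1 <- d1[match(common, d1$id), ]
  d2 <- d2[match(common, d2$id), ]
  g1 <- geno_str(d1); g2 <- geno_str(d2)
  if (length(unique(g1)) < 2 || length(unique(g2)) < 2) {
    return(new_test_result(NA_real_, NA_real_, "ld-perm", n_perm, "monomorphic"))
  }
  stat <- function(x, y) {
    tab <- table(x, y)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - e)^2 / e)
  }
  obs <- stat(g1, g2)
  ge <- 0L
  for (i in seq_len(n_perm)) {
    if (stat(g1, sample(g2)) >= obs - 1e-12) ge <- ge + 1L
  }
  new_test_result(obs, (ge + 1) / (n_perm + 1), "ld-perm", n_perm)
}

#' Permutation test for a difference in mean He between two populations
#'
#' Statistic: difference in mean unbiased gene diversity over loci.  Null
#' built by permuting individuals between the two groups.
#'
#' @param g A [genotype_tbl()].
#' @param pop_a,pop_b Population labels.
#' @param n_perm Permutations (default 999).
#' @return One-row test tibble; two-sided p.
#' @export
he_permutation_test <- function(g, pop_a, pop_b, n_perm = 999) {
  g <- assert_genotypes(g)
  sub <- g[g$pop %in% c(pop_a, pop_b), ]
  mean_he <- function(d, pop) {
    dd <- d[d$pop == pop & !is.na(d$a1), ]
    hes <- dd |>
      tidyr::pivot_longer(c("a1", "a2"), values_to = "allele") |>
      dplyr::group_by(.data$locus) |>
      dplyr::summarise(he = {
        n <- dplyr::n()
        if (n >= 2) expected_het(as.numeric(table(.data$allele)) / n, n) else NA_real_
      }, .groups = "drop")
    mean(hes$he, na.rm = TRUE)
  }
  obs <- mean_he(sub, pop_a) - mean_he(sub, pop_b)
  ids <- unique(sub$id)
  id_pop <- sub$pop[match(ids, sub$id)]
  ge <- 0L
  for (i in seq_len(n_perm)) {
    perm_pop <- sample(id_pop)
    d <- sub
    d$pop <- perm_pop[match(d$id, ids)]
    s <- mean_he(d, pop_a) - mean_he(d, pop_b)
    if (abs(s) >= abs(obs) - 1e-12) ge <- ge + 1L
  }
  new_test_result(obs, (ge + 1) / (n_perm + 1), "he-perm", n_perm)
}

#' Paired comparison of per-locus He vectors
#'
#' `wilcoxon`: signed-rank test on paired per-locus values.  `mood`: Mood's
#' median test (counts above/below the grand median, chi-square or Fisher).
#'
#' @param he_a,he_b Per-locus He vectors (equal length for `wilcoxon`).
#' @param method `"wilcoxon"` or `"mood"`.
#' @return One-row test tibble.
#' @export
paired_he_comparison <- function(he_a, he_b, method = c("wilcoxon", "mood")) {
  method <- match.arg(method)
  if (method == "wilcoxon") {
    if (length(he_a) != length(he_b)) {
      stop("wilcoxon requires equal-length vectors", call. = FALSE)
    }
    if (all(he_a == he_b)) {
      return(new_test_result(0, NA_real_, "wilcoxon", note = "all differences zero"))
    }
    wt <- suppressWarnings(stats::wilcox.test(he_a, he_b, paired = TRUE))
    return(new_test_result(unname(wt$statistic), wt$p.value, "wilcoxon"))
  }
  med <- stats::median(c(he_a, he_b))
  tab <- rbind(a = c(sum(he_a > med), sum(he_a <= med)),
               b = c(sum(he_b > med), sum(he_b <= med)))
  ft <- if (any(tab < 5)) stats::fisher.test(tab) else
    suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  stat <- if (is.null(ft$statistic)) NA_real_ else unname(ft$statistic)
  new_test_result(stat, ft$p.value, "mood")
}

#' Evanno delta-K from clustering log-likelihoods
#'
#' `deltaK(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd L(K)`;
#' undefined at the endpoints of the K range.  `best_k` is the argmax over
#' interior K.
#'
#' @param loglik Data frame with columns `k`, `mean_lnl`, `sd_lnl` (one row
#'   per K, from replicate clustering runs).
#' @return Tibble with `k`, `delta_k`; attribute `best_k`.
#' @export
evanno_delta_k <- function(loglik) {
  loglik <- dplyr::arrange(tibble::as_tibble(loglik), .data$k)
  if (nrow(loglik) < 3) stop("need at least 3 consecutive K values", call. = FALSE)
  if (any(diff(loglik$k) != 1)) stop("K values must be consecutive", call. = FALSE)
  m <- loglik$mean_lnl
  s <- loglik$sd_lnl
  n <- nrow(loglik)
  dk <- rep(NA_real_, n)
  for (i in 2:(n - 1)) {
    dk[i] <- if (s[i] > 0) abs(m[i + 1] - 2 * m[i] + m[i - 1]) / s[i] else NA_real_
  }
  out <- tibble::tibble(k = loglik$k, delta_k = dk)
  best <- out$k[which.max(out$delta_k)]
  attr(out, "best_k") <- if (length(best)) best else NA_integer_
  out
}
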