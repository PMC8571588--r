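test_that("unbiased gene diversity matches hand evaluation and is symmetric", {
  expect_equal(expected_het(1, 10), 0)
  expect_equal(expected_het(c(0.5, 0.5), 10), 10 / 9 * 0.5)
  p <- c(0.2, 0.3, 0.5)
  expect_equal(expected_het(p, 20), expected_het(rev(p), 20))
  expect_error(expected_het(c(0.5, 0.5), 1), "gene_count")
})

test_that("observed heterozygosity is the per-individual distinct-allele fraction", {
  g <- gt_locus(list(c(10, 12), c(10, 10)))
  expect_equal(observed_het(g, "L1", "P1"), 0.5)
  g2 <- gt_locus(list(c(10, 10), c(12, 12)))
  expect_equal(observed_het(g2, "L1", "P1"), 0)
  set.seed(3)
  g3 <- gt_random(40, list(L1 = c(`8` = 0.3, `9` = 0.5, `10` = 0.2)))
  manual <- mean(g3$a1 != g3$a2)
  expect_equal(observed_het(g3, "L1", "P1"), manual)
})

test_that("Fis covers panmixia, full inbreeding, and the mainland table row", {
  expect_equal(fis(0.5, 0.5), 0)
  expect_equal(fis(0, 0.7), 1)
  expect_equal(fis(0.291, 0.794), 0.634, tolerance = 1e-3)
  expect_true(is.na(fis(0, 0)))
})

test_that("rarefied allelic richness has exact limits and matches exhaustive enumeration", {
  counts <- c(3, 2, 1)
  expect_equal(rarefied_allelic_richness(counts, sum(counts)), 3)
  expect_equal(rarefied_allelic_richness(counts, 1), 1)
  # exhaustive oracle: mean distinct alleles over all C(N, g) subsamples,
  # for every configuration with N <= 8 gene copies
  enum_mean <- function(counts, g) {
    copies <- rep(seq_along(counts), counts)
    combs <- utils::combn(length(copies), g)
    mean(apply(combs, 2, function(ix) length(unique(copies[ix]))))
  }
  set.seed(42)
  configs <- list(c(6), c(3, 3), c(4, 2), c(2, 2, 2), c(5, 2, 1), c(4, 2, 2),
                  c(1, 1, 1, 1), c(3, 3, 2), c(2, 1, 1))
  for (cfg in configs) {
    for (g in seq_len(sum(cfg))) {
      expect_equal(rarefied_allelic_richness(cfg, g), enum_mean(cfg, g),
                   tolerance = 1e-12,
                   info = paste(paste(cfg, collapse = ","), g))
    }
  }
  expect_error(rarefied_allelic_richness(c(2, 2), 5), "exceeds")
})

test_that("private alleles count single-population alleles and agree with set differences", {
  g <- genotype_tbl(dplyr::bind_rows(
    gt_locus(list(c(10, 10), c(10, 12))),
    gt_locus(list(c(12, 14), c(14, 14)), pop = "P2") |>
      dplyr::mutate(id = paste0("j", 1:2))))
  ft <- allele_frequencies(g)
  pa <- private_alleles(ft)
  expect_equal(pa$private[pa$group == "P1"], 1) # allele 10
  expect_equal(pa$private[pa$group == "P2"], 1) # allele 14; 12 is shared

  # disjoint allele sets: every allele private
  g2 <- genotype_tbl(dplyr::bind_rows(
    gt_locus(list(c(2, 4), c(2, 2))),
    gt_locus(list(c(6, 8), c(8, 8)), pop = "P2") |>
      dplyr::mutate(id = paste0("j", 1:2))))
  pa2 <- private_alleles(allele_frequencies(g2))
  expect_equal(sort(pa2$private), c(2L, 2L))

  # brute-force set-difference oracle on random tables
  set.seed(11)
  for (rep in 1:5) {
    ga <- gt_random(15, list(L1 = c(`1` = .2, `2` = .3, `3` = .5),
                             L2 = c(`5` = .6, `6` = .4)))
    gb <- gt_random(15, list(L1 = c(`2` = .4, `3` = .3, `4` = .3),
                             L2 = c(`6` = .5, `7` = .5)), pop = "P2")
    gb$id <- paste0("j", seq_len(nrow(gb)))
    gg <- genotype_tbl(dplyr::bind_rows(ga, gb))
    ft <- allele_frequencies(gg)
    pa <- private_alleles(ft)
    brute <- function(p, q) {
      ap <- unique(paste(ft$locus, ft$allele)[ft$group == p])
      aq <- unique(paste(ft$locus, ft$allele)[ft$group == q])
      length(setdiff(ap, aq))
    }
    expect_equal(pa$private[pa$group == "P1"], brute("P1", "P2"))
    expect_equal(pa$private[pa$group == "P2"], brute("P2", "P1"))
  }
})

test_that("HWE Monte-Carlo test accepts HWE tables and rejects an all-heterozygote table", {
  set.seed(5)
  # genotype counts exactly at HWE proportions for p = q = 0.5: 25/50/25
  pairs <- c(rep(list(c(10, 10)), 25), rep(list(c(10, 12)), 50),
             rep(list(c(12, 12)), 25))
  g <- gt_locus(pairs)
  res <- hwe_test(g, "L1", "P1", n_mc = 400)
  expect_gt(res$p_value, 0.3)

  g_het <- gt_locus(rep(list(c(10, 12)), 50))
  res2 <- hwe_test(g_het, "L1", "P1", n_mc = 400)
  expect_lt(res2$p_value, 0.05)

  g_mono <- gt_locus(rep(list(c(10, 10)), 20))
  expect_true(is.na(hwe_test(g_mono, "L1", "P1")$statistic))
})

test_that("HWE Monte-Carlo p is close to the exact conditional (Levene) enumeration", {
  # n = 10 diploids, 2 alleles with 8 and 12 copies; enumerate the exact
  # distribution of the heterozygote count conditional on allele counts
  n <- 10; nA <- 8; na <- 12
  levene_p <- function(h) {
    if ((nA - h) %% 2 != 0 || h > min(nA, na)) return(0)
    exp(lfactorial(n) - lfactorial((nA - h) / 2) - lfactorial(h) -
          lfactorial((na - h) / 2) + h * log(2) -
          (lfactorial(2 * n) - lfactorial(nA) - lfactorial(na)))
  }
  hs <- 0:min(nA, na)
  probs <- vapply(hs, levene_p, numeric(1))
  expect_equal(sum(probs), 1, tolerance = 1e-10)
  chi_of_h <- function(h) {
    p <- nA / (2 * n)
    obs <- c((nA - h) / 2, h, (na - h) / 2)
    e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    sum((obs - e)^2 / e)
  }
  # observed table: 2 het (excess homozygosity)
  obs_chi <- chi_of_h(2)
  exact <- sum(probs[vapply(hs, chi_of_h, numeric(1)) >= obs_chi - 1e-12])
  pairs <- c(rep(list(c(10, 10)), 3), rep(list(c(10, 12)), 2),
             rep(list(c(12, 12)), 5))
  set.seed(9)
  mc <- hwe_test(gt_locus(pairs), "L1", "P1", n_mc = 4000)
  expect_lt(abs(mc$p_value - exact), 0.03)
})

test_that("LD permutation test detects perfect association and respects relabeling", {
  set.seed(13)
  f <- c(`10` = 0.5, `12` = 0.5)
  g1 <- gt_random(30, list(L1 = f))
  dup <- g1; dup$locus <- "L2"
  gg <- genotype_tbl(dplyr::bind_rows(g1, dup))
  res <- ld_test(gg, c("L1", "L2"), "P1", n_perm = 199)
  expect_equal(res$p_value, 1 / 200)

  # allele relabeling leaves the statistic unchanged
  rel <- gg
  rel$a1[rel$locus == "L2"] <- rel$a1[rel$locus == "L2"] + 100L
  rel$a2[rel$locus == "L2"] <- rel$a2[rel$locus == "L2"] + 100L
  set.seed(13)
  r1 <- ld_test(gg, c("L1", "L2"), "P1", n_perm = 99)
  set.seed(13)
  r2 <- ld_test(genotype_tbl(rel), c("L1", "L2"), "P1", n_perm = 99)
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p_value, r2$p_value)

  g_mono <- genotype_tbl(dplyr::bind_rows(
    gt_random(10, list(L1 = f)),
    gt_locus(rep(list(c(5, 5)), 10), locus = "L2")))
  expect_true(is.na(ld_test(g_mono, c("L1", "L2"), "P1")$statistic))
})

test_that("LD test p-values are roughly uniform for independent loci", {
  set.seed(17)
  ps <- replicate(60, {
    g <- gt_random(25, list(L1 = c(`10` = .5, `12` = .5),
                            L2 = c(`20` = .5, `22` = .5)))
    ld_test(g, c("L1", "L2"), "P1", n_perm = 99)$p_value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("BY correction matches the step-up hand computation", {
  expect_equal(by_correction(0.2), 0.2)
  expect_equal(by_correction(c(0.01, 0.02, 0.03)),
               rep(0.01 * 3 * (1 + 1 / 2 + 1 / 3), 3),
               tolerance = 1e-12)
  expect_equal(by_correction(numeric(0)), numeric(0))
  expect_error(by_correction(c(0.5, 1.2)), "0, 1")
})

test_that("He permutation test is null on identical groups and powered on divergent ones", {
  set.seed(23)
  ga <- gt_random(20, list(L1 = c(`10` = .5, `12` = .5), L2 = c(`5` = .7, `6` = .3)))
  gb <- ga
  gb$pop <- "P2"; gb$id <- paste0("j", gb$id)
  gg <- genotype_tbl(dplyr::bind_rows(ga, gb))
  res <- he_permutation_test(gg, "P1", "P2", n_perm = 99)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  glow <- gt_random(50, list(L1 = c(`10` = .9, `12` = .1),
                             L2 = c(`5` = .95, `6` = .05)))
  ghigh <- gt_random(50, list(L1 = c(`10` = .4, `12` = .3, `14` = .3),
                              L2 = c(`5` = .5, `6` = .3, `7` = .2)), pop = "P2")
  ghigh$id <- paste0("j", ghigh$id)
  gg2 <- genotype_tbl(dplyr::bind_rows(glow, ghigh))
  res2 <- he_permutation_test(gg2, "P1", "P2", n_perm = 199)
  expect_lte(res2$p_value, 0.01)
})

test_that("paired He comparisons delegate to the standard tests", {
  he <- c(0.42, 0.51, 0.38, 0.6, 0.47, 0.55, 0.33, 0.62, 0.49, 0.52, 0.44)
  same <- paired_he_comparison(he, he)
  expect_true(is.na(same$p_value))
  shift <- paired_he_comparison(he, he + 0.2)
  expect_lt(shift$p_value, 0.01)
  expect_equal(shift$p_value, stats::wilcox.test(he, he + 0.2, paired = TRUE)$p.value)
  set.seed(31)
  a <- stats::runif(30, 0.3, 0.7)
  b <- stats::runif(30, 0.3, 0.7)
  md <- paired_he_comparison(a, b, method = "mood")
  expect_gt(md$p_value, 0.05)
})

test_that("Evanno delta-K finds a constructed elbow and ignores scale", {
  lin <- tibble::tibble(k = 1:5, mean_lnl = -100 + 10 * (1:5), sd_lnl = 1)
  dk <- evanno_delta_k(lin)
  expect_true(all(dk$delta_k[2:4] == 0))

  elbow <- tibble::tibble(k = 1:6,
                          mean_lnl = c(-500, -300, -295, -290, -285, -280),
                          sd_lnl = rep(2, 6))
  dk2 <- evanno_delta_k(elbow)
  expect_equal(attr(dk2, "best_k"), 2)

  scaled <- elbow
  scaled$mean_lnl <- scaled$mean_lnl * 3
  scaled$sd_lnl <- scaled$sd_lnl * 3
  dk3 <- evanno_delta_k(scaled)
  expect_equal(dk2$delta_k, dk3$delta_k)
  expect_error(evanno_delta_k(elbow[1:2, ]), "3")
})

test_that("expected He is unbiased over multinomial resampling", {
  set.seed(37)
  p <- c(0.4, 0.3, 0.2, 0.1)
  target <- 1 - sum(p^2)
  n <- 20
  hes <- replicate(4000, {
    copies <- sample(seq_along(p), n, TRUE, p)
    f <- tabulate(copies, length(p)) / n
    expected_het(f, n)
  })
  expect_equal(mean(hes), target, tolerance = 0.01)
})

test_that("the diversity table reproduces its own per-locus means and Fis convention", {
  sl <- generate_study_like(4)
  dt <- diversity_table(sl$genotypes)
  expect_true(all(dt$ho >= 0 & dt$ho <= 1))
  expect_true(all(dt$he >= 0 & dt$he <= 1))
  expect_equal(dt$fis, 1 - dt$ho / dt$he)
  # A is at least the locus count for populations with data at every locus
  expect_true(all(dt$a >= 11))
  est <- estimate_null_alleles(sl$genotypes)
  dtc <- diversity_table(sl$genotypes, null_est = est)
  expect_true(all(dtc$he_corrected >= dtc$he - 1e-9))
})
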