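test_that("summary statistics are null for identical populations and exact on toys", {
  set.seed(47)
  ga <- gt_random(60, list(L1 = c(`10` = .5, `12` = .5), L2 = c(`5` = .4, `6` = .6)))
  gb <- ga; gb$pop <- "P2"; gb$id <- paste0("j", gb$id)
  gg <- genotype_tbl(dplyr::bind_rows(ga, gb))
  design <- stat_design(c("P1", "P2"))
  s <- summary_statistics(gg, design)
  expect_lt(abs(s[["fst_P1.P2"]]), 0.02)
  expect_equal(s[["dmu2_P1.P2"]], 0)
  expect_true(s[["das_P1.P2"]] >= 0 && s[["das_P1.P2"]] <= 1)

  # (du)^2 on hand-built one-locus data with means 10 and 13
  g1 <- gt_locus(list(c(10, 10), c(10, 10)))
  g2 <- gt_locus(list(c(13, 13), c(13, 13)), pop = "P2")
  g2$id <- paste0("j", 1:2)
  gh <- genotype_tbl(dplyr::bind_rows(g1, g2))
  sh <- summary_statistics(gh, stat_design(c("P1", "P2")))
  expect_equal(sh[["dmu2_P1.P2"]], 9)
  expect_equal(sh[["das_P1.P2"]], 1) # no shared alleles
})

test_that("the admixture coefficient hits its boundaries and interior values", {
  set.seed(53)
  p1 <- gt_random(40, list(L1 = c(`10` = .9, `12` = .1), L2 = c(`5` = .8, `6` = .2)))
  p2 <- gt_random(40, list(L1 = c(`10` = .1, `12` = .9), L2 = c(`5` = .2, `6` = .8)),
                  pop = "P2")
  p2$id <- paste0("j", p2$id)
  adm_copy <- p1; adm_copy$pop <- "ADM"; adm_copy$id <- paste0("k", adm_copy$id)
  gg <- genotype_tbl(dplyr::bind_rows(p1, p2, adm_copy))
  design <- stat_design(c("ADM", "P1", "P2"), trios = list(c("ADM", "P1", "P2")))
  s <- summary_statistics(gg, design)
  expect_gt(s[["alpha_ADM.P1.P2"]], 0.85)

  # a 50/50 mixture sits near the middle
  half <- genotype_tbl(dplyr::bind_rows(
    gt_random(50, list(L1 = c(`10` = .5, `12` = .5), L2 = c(`5` = .5, `6` = .5)),
              pop = "ADM") |> dplyr::mutate(id = paste0("k", id)),
    p1, p2))
  sh <- summary_statistics(half, design)
  expect_lt(abs(sh[["alpha_ADM.P1.P2"]] - 0.5), 0.2)
})

test_that("prior sampling honours bounds, distributions and constraints", {
  pr <- prior_spec(tibble::tibble(
    name = c("t1", "t2", "r"),
    dist = c("log-uniform", "log-uniform", "uniform"),
    lower = c(10, 10, 0), upper = c(1000, 1000, 1)),
    constraints = "t2 > t1")
  set.seed(59)
  draws <- sample_priors(pr, 500)
  expect_true(all(draws$t2 > draws$t1))
  expect_true(all(draws$t1 >= 10 & draws$t1 <= 1000))
  expect_true(all(draws$r >= 0 & draws$r <= 1))
  # log-uniform marginal (unconstrained): median near the geometric midpoint
  pr_u <- prior_spec(pr$params)
  du <- sample_priors(pr_u, 2000)
  expect_lt(abs(stats::median(du$t1) / sqrt(10 * 1000) - 1), 0.25)
})

test_that("rejection keeps everything at retain_fraction one and is seed-deterministic", {
  set.seed(61)
  ss <- stage2_scenarios()
  pr_c <- ss$prior
  pr_c$constraints <- unique(c(pr_c$constraints, ss$scenarios[[2]]$constraints))
  scn <- instantiate_scenario(ss$scenarios[[2]], sample_priors(pr_c, 1))
  design <- stat_design(c("M", "SCY", "FLO", "ISA"),
                        stats = c("nal", "var", "fst", "dmu2"))
  g <- simulate_dataset(scn)
  obs <- summary_statistics(g, design)
  set.seed(7)
  ref1 <- abc_rejection(obs, ss$scenarios[1:3], ss$prior, design,
                        n_sim = 300, retain_fraction = 1)
  expect_true(all(ref1$retained))
  set.seed(7)
  ref2 <- abc_rejection(obs, ss$scenarios[1:3], ss$prior, design,
                        n_sim = 300, retain_fraction = 1)
  expect_identical(ref1$distance, ref2$distance)
  expect_identical(ref1$scenario, ref2$scenario)
})

test_that("the generating scenario is over-represented among retained simulations", {
  set.seed(67)
  # two well-separated histories over the same populations: an old split
  # versus a very recent one
  pops <- tibble::tibble(pop = c("A", "B"), n_sample = c(15L, 15L),
                         n = c("na", "nb"))
  mk <- function(name, t_expr) {
    scenario(name, pops,
             tibble::tibble(time = t_expr, type = "merge", pop = "B",
                            parent_a = "A", parent_b = NA_character_,
                            prop = NA_character_, size = NA_character_),
             mu = 3.5e-4, loci = 11)
  }
  s_old <- mk("old_split", "told")
  s_new <- mk("new_split", "tnew")
  pr <- prior_spec(tibble::tibble(
    name = c("na", "nb", "told", "tnew"),
    dist = c("log-uniform", "log-uniform", "log-uniform", "log-uniform"),
    lower = c(200, 200, 1500, 1), upper = c(5000, 5000, 5000, 20)))
  truth <- instantiate_scenario(s_old, sample_priors(pr, 1))
  g <- simulate_dataset(truth)
  design <- stat_design(c("A", "B"), stats = c("nal", "het", "var", "fst", "dmu2"))
  obs <- summary_statistics(g, design)
  ref <- abc_rejection(obs, list(s_old, s_new), pr, design,
                       n_sim = 4000, retain_fraction = 0.02)
  ret <- ref[ref$retained, ]
  n_old <- sum(ret$scenario == "old_split")
  expect_lt(stats::binom.test(n_old, nrow(ret), 0.5, "greater")$p.value, 0.01)

  pp <- model_posterior(ref)
  expect_equal(sum(pp$pp), 1, tolerance = 0.01)
  expect_gt(pp$pp[pp$scenario == "old_split"], 0.5)
  expect_true(all(pp$lo <= pp$pp & pp$pp <= pp$hi))
})

test_that("symmetric scenarios share the posterior and absent scenarios get none", {
  set.seed(71)
  pops <- tibble::tibble(pop = c("A", "B"), n_sample = c(10L, 10L),
                         n = c("na", "nb"))
  mk <- function(name) {
    scenario(name, pops,
             tibble::tibble(time = "t1", type = "merge", pop = "B",
                            parent_a = "A", parent_b = NA_character_,
                            prop = NA_character_, size = NA_character_),
             mu = 3.5e-4, loci = 8)
  }
  twins <- list(mk("twin_a"), mk("twin_b"))
  pr <- prior_spec(tibble::tibble(
    name = c("na", "nb", "t1"), dist = rep("log-uniform", 3),
    lower = c(200, 200, 50), upper = c(3000, 3000, 500)))
  truth <- instantiate_scenario(twins[[1]], sample_priors(pr, 1))
  g <- simulate_dataset(truth)
  design <- stat_design(c("A", "B"), stats = c("nal", "het", "fst"))
  obs <- summary_statistics(g, design)
  ref <- abc_rejection(obs, twins, pr, design, n_sim = 2000,
                       retain_fraction = 0.05)
  pp <- model_posterior(ref)
  expect_lt(abs(pp$pp[1] - 0.5), 0.2)
  expect_equal(sum(pp$pp), 1, tolerance = 0.01)
})

test_that("parameter posteriors are adjusted, constrained, and tighter than rejection", {
  set.seed(73)
  ss <- final_model()
  tmpl <- ss$scenarios[[1]]
  pr2 <- ss$prior
  truep <- sample_priors(pr2, 1)
  truth <- instantiate_scenario(tmpl, truep)
  g <- simulate_dataset(truth)
  design <- stat_design(c("M", "SCY", "FLO", "ISA", "SCZ"),
                        stats = c("nal", "het", "var", "fst", "dmu2"))
  obs <- summary_statistics(g, design)
  ref <- abc_rejection(obs, ss$scenarios, ss$prior, design, n_sim = 4000,
                       retain_fraction = 0.05)
  post <- parameter_posterior(ref, min_retained = 150)
  expect_true(post$adjusted)
  # ordering constraint preserved in every posterior draw
  expect_true(all(post$samples$t4 > post$samples$t3))
  expect_true(all(post$samples$t3 > post$samples$t2))
  expect_true(all(post$samples$t2 > post$samples$t1))
  expect_true(all(post$quantiles$q025 <= post$quantiles$median &
                    post$quantiles$median <= post$quantiles$q975))
  # adjustment concentrates relative to the raw retained draws for most params
  ret <- ref[ref$retained, ]
  vr <- vapply(c("t4", "t3", "t2"), function(pn) {
    stats::var(log(post$samples[[pn]])) / stats::var(log(ret[[pn]]))
  }, numeric(1))
  expect_lt(stats::median(vr), 1)
})

test_that("model checking calibrates on self-generated data and flags gross misfit", {
  set.seed(79)
  ss <- stage2_scenarios()
  tmpl <- ss$scenarios[[2]]
  pr <- ss$prior; pr$constraints <- unique(c(pr$constraints, tmpl$constraints))
  truth <- instantiate_scenario(tmpl, sample_priors(pr, 1))
  g <- simulate_dataset(truth)
  design <- stat_design(c("M", "SCY", "FLO", "ISA"),
                        stats = c("nal", "var", "fst", "dmu2"))
  obs <- summary_statistics(g, design)
  ref <- abc_rejection(obs, ss$scenarios[2], ss$prior, design, n_sim = 2000,
                       retain_fraction = 0.1)
  post <- parameter_posterior(ref, tmpl$name, min_retained = 100)
  chk <- model_check(ref, post, n_pred = 120)
  expect_true(all(chk$tail$fraction_below >= 0 & chk$tail$fraction_below <= 1))
  expect_gt(chk$overall_fit_pct, 50)

  ref_bad <- ref
  attr(ref_bad, "observed") <- attr(ref, "observed") * 10
  chk_bad <- model_check(ref_bad, post, n_pred = 120)
  expect_lt(chk_bad$overall_fit_pct, chk$overall_fit_pct)
  expect_gt(chk_bad$mahalanobis_sq, chk$mahalanobis_sq)
  expect_error(model_check(ref, post, n_pred = 50), "100")
})
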