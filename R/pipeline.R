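#' Run the full analysis pipeline
#'
#' Orchestrates the package end to end on observed or synthetic genotypes:
#' diversity statistics (raw and null-corrected), pairwise FST matrices,
#' Nei and chord NJ trees with locus bootstraps, AMOVA, the
#' geography-vs-genetics Mantel test on mainland regions, an ABC stage over
#' the stage-2 colonization scenarios, the final-model parameter posterior,
#' and mutation-scaled time conversion of the inferred introduction times.
#' Every artefact is written under `out_dir` together with a resolved
#' configuration (seeds included).
#'
#' @param out_dir Output directory (created if needed).
#' @param g Optional [genotype_tbl()]; when `NULL` a synthetic study-shaped
#'   dataset is generated from `seed`.
#' @param seed Root seed for all randomness.
#' @param abc_budget Simulations for the ABC stage (desk-scale default
#'   2000; the study-scale analyses used hundreds of thousands).
#' @param retain_fraction ABC retention fraction.
#' @param n_boot Locus bootstraps for the NJ trees.
#' @param mu Mutation rate for time scaling.
#' @param generation_time_years Generation time for year conversion.
#' @param loglik Optional clustering log-likelihood table for
#'   [evanno_delta_k()] (columns `k`, `mean_lnl`, `sd_lnl`).
#' @return Invisibly, a named list of all computed results.
#' @export
run_full_pipeline <- function(out_dir, g = NULL, seed = 20210417,
                              abc_budget = 2000, retain_fraction = 0.05,
                              n_boot = 100, mu = 3.5e-4,
                              generation_time_years = 2, loglik = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  cfg <- list(seed = seed, abc_budget = abc_budget,
              retain_fraction = retain_fraction, n_boot = n_boot, mu = mu,
              generation_time_years = generation_time_years,
              synthetic = is.null(g))
  if (is.null(g)) {
    synth <- generate_study_like(seed)
    g <- synth$genotypes
  }
  res <- list(config = cfg)

  est <- estimate_null_alleles(g)
  res$null_alleles <- est
  readr::write_csv(est[, c("locus", "pop", "beta", "converged")],
                   file.path(out_dir, "null_allele_frequencies.csv"))

  res$diversity <- diversity_table(g, null_est = est)
  readr::write_csv(res$diversity, file.path(out_dir, "diversity_table.csv"))

  res$fst <- pairwise_fst_matrix(g)
  res$fst_ena <- pairwise_fst_matrix(g, correction = "ena", est = est)
  utils::write.csv(unclass(res$fst), file.path(out_dir, "fst_matrix.csv"))
  utils::write.csv(unclass(res$fst_ena), file.path(out_dir, "fst_matrix_ena.csv"))

  tr_nei <- bootstrap_support(g, metric = "nei", n_boot = n_boot)
  tr_chord <- bootstrap_support(g, metric = "chord", n_boot = n_boot,
                                null_est = est)
  ape::write.tree(tr_nei, file.path(out_dir, "nj_nei.nwk"))
  ape::write.tree(tr_chord, file.path(out_dir, "nj_chord_corrected.nwk"))
  res$trees <- list(nei = tr_nei, chord = tr_chord)

  res$amova <- amova(g, n_perm = 99)
  readr::write_csv(res$amova$table, file.path(out_dir, "amova.csv"))

  if ("region" %in% names(g) && all(c("lat", "lon") %in% names(g)) &&
      any(!is.na(g$region))) {
    gm <- g[!is.na(g$region), ]
    geo <- geographic_distance_matrix(gm, by = "region")
    gen <- genetic_distance_matrix(gm, metric = "nei", by = "region")
    gen <- gen[rownames(geo), rownames(geo)]
    res$mantel <- mantel_spearman(geo, new_dist_matrix(gen, "nei"),
                                  n_perm = 10000)
    readr::write_csv(res$mantel, file.path(out_dir, "mantel_regions.csv"))
  }

  if (!is.null(loglik)) {
    res$evanno <- evanno_delta_k(loglik)
    readr::write_csv(res$evanno, file.path(out_dir, "evanno_delta_k.csv"))
  }

  # staged ABC on the colonization question (desk-scale budget)
  ss <- stage2_scenarios()
  pool <- list(M = "Mainland", SCY = "SCY", FLO = "FLO", ISA = "ISA")
  gg <- g[g$pop %in% unlist(pool), ]
  gg$pop <- names(pool)[match(gg$pop, unlist(pool))]
  gg <- genotype_tbl(gg)
  design <- stat_design(c("M", "SCY", "FLO", "ISA"),
                        stats = c("nal", "var", "var2", "fst", "dmu2"))
  obs <- summary_statistics(gg, design)
  n_samp <- c(M = 15, SCY = 15, FLO = 5, ISA = 15)
  ref <- abc_rejection(obs, ss$scenarios, ss$prior, design,
                       n_sim = abc_budget, retain_fraction = retain_fraction,
                       n_sample = n_samp)
  res$abc_stage2 <- model_posterior(ref)
  readr::write_csv(res$abc_stage2, file.path(out_dir, "abc_stage2_posteriors.csv"))

  best <- res$abc_stage2$scenario[which.max(res$abc_stage2$pp)]
  post <- try(parameter_posterior(ref, best,
                                  min_retained = min(200, floor(abc_budget *
                                                                  retain_fraction / 3))),
              silent = TRUE)
  if (!inherits(post, "try-error")) {
    res$posterior <- post
    readr::write_csv(post$quantiles, file.path(out_dir, "parameter_posterior.csv"))
    tq <- post$quantiles[grepl("^t", post$quantiles$parameter), ]
    res$timing <- tq |>
      dplyr::mutate(
        generations = scale_duration_to_generations(.data$median * mu, mu),
        years = generations_to_years(.data$generations, generation_time_years),
        lo_generations = scale_duration_to_generations(.data$q025 * mu, mu),
        hi_generations = scale_duration_to_generations(.data$q975 * mu, mu))
    readr::write_csv(res$timing, file.path(out_dir, "introduction_times.csv"))
  }

  jsonlite::write_json(cfg, file.path(out_dir, "config.json"), auto_unbox = TRUE)
  invisible(res)
}
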