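#' Generate a study-shaped synthetic dataset with known ground truth
#'
#' Simulates the full sampling design of the study system: a structured
#' mainland of nine regional demes whose ancestry follows an admixture
#' cline between two diverged gene pools along the 720-km latitudinal axis
#' (so genetic divergence grows with geographic separation, emulating
#' isolation by distance), plus four
#' island populations founded through the serial colonization chain
#' mainland - San Cristobal - Floreana - Isabela with a late side branch to
#' Santa Cruz, each introduction passing through a founder-flush
#' bottleneck.  Sample sizes are (96, 95, 80, 94, 11) diploids for
#' Mainland, ISA, SCZ, SCY, FLO at 11 loci.  Null alleles are overlaid
#' post-simulation by masking (per-locus null frequency drawn uniformly on
#' `[0, 0.33]`): a heterozygote carrying one null copy becomes an apparent
#' homozygote, a null homozygote becomes a blank; 2% of genotypes are then
#' blanked at random.
#'
#' @param seed Integer seed; the dataset is fully reproducible from it.
#' @return A list: `genotypes` (a [genotype_tbl()] with `region`, `lat`,
#'   `lon` filled for mainland samples) and `truth` (generating scenario,
#'   per locus x population null frequencies, per-individual deme,
#'   missing-data rate, seed).
#' @export
generate_study_like <- function(seed = 20210417) {
  set.seed(seed)
  n_loci <- 11L
  mu <- 3.5e-4
  demes <- paste0("D", 1:9)
  # snake path over 3 latitudinal bands x 3 physiographic axes
  deme_axis <- c("Coast", "Coast", "Coast", "Highlands", "Highlands",
                 "Highlands", "Amazon", "Amazon", "Amazon")
  deme_dist <- c(120, 360, 600, 600, 360, 120, 120, 360, 600)
  deme_n <- c(11L, 11L, 11L, 11L, 11L, 11L, 10L, 10L, 10L)
  islands <- c("SCY", "FLO", "ISA", "SCZ")
  island_n <- c(SCY = 94L, FLO = 11L, ISA = 95L, SCZ = 80L)

  pops <- tibble::tibble(
    pop = c(demes, "D1anc", "ANC2", islands),
    n_sample = c(deme_n, 0L, 0L, unname(island_n)),
    n = c(rep(1500, 9), 8000, 8000, 800, 100, 1000, 2000))
  # mainland structure: an admixture cline between two diverged ancestral
  # gene pools, with each deme's ancestry proportion set by its position
  # along the north-west / south-east diagonal; genetic distance between
  # demes then grows monotonically with geographic separation (the
  # isolation-by-distance signature) without explicit migration
  axis_off <- c(Coast = 0, Highlands = 167, Amazon = 334)
  proj <- deme_dist + axis_off[deme_axis]
  alpha <- 0.02 + 0.96 * (proj - min(proj)) / (max(proj) - min(proj))
  cline <- dplyr::bind_rows(
    lapply(1:9, function(k) {
      tibble::tibble(time = "40", type = "admix", pop = demes[k],
                     parent_a = "D1anc", parent_b = "ANC2",
                     prop = as.character(1 - alpha[k]), size = NA_character_)
    }),
    tibble::tibble(time = "4000", type = "merge", pop = "ANC2",
                   parent_a = "D1anc", parent_b = NA_character_,
                   prop = NA_character_, size = NA_character_))
  ev <- dplyr::bind_rows(
    cline,
    colonize("SCY", "D1anc", "1710", "25", "0.01"),
    colonize("FLO", "SCY", "211", "6", "0.05"),
    colonize("ISA", "FLO", "119", "15", "0.05"),
    colonize("SCZ", "SCY", "34", "10", "0.1"))
  scn <- instantiate_scenario(
    scenario("study_like_truth", pops, ev, mu = mu, loci = n_loci), list())
  validate_scenario(scn)
  g <- simulate_dataset(scn)

  # relabel mainland demes as one population with region metadata
  deme_of <- g$pop
  is_main <- deme_of %in% demes
  binning <- latitudinal_binning()
  region_lab <- rep(NA_character_, nrow(g))
  region_lab[is_main] <- assign_latitudinal_region(
    deme_dist[match(deme_of[is_main], demes)],
    deme_axis[match(deme_of[is_main], demes)], binning)
  axis_lon <- c(Coast = -80.0, Highlands = -78.5, Amazon = -77.0)
  lat0 <- 1.4
  lat <- rep(NA_real_, nrow(g)); lon <- rep(NA_real_, nrow(g))
  lat[is_main] <- lat0 - deme_dist[match(deme_of[is_main], demes)] / 111.19
  lon[is_main] <- axis_lon[deme_axis[match(deme_of[is_main], demes)]]
  island_coord <- list(SCY = c(-0.90, -89.44), FLO = c(-1.30, -90.44),
                       ISA = c(-0.83, -91.13), SCZ = c(-0.64, -90.36))
  for (isl in islands) {
    sel <- deme_of == isl
    lat[sel] <- island_coord[[isl]][1]
    lon[sel] <- island_coord[[isl]][2]
  }
  g$region <- region_lab
  g$deme <- deme_of
  g$pop[is_main] <- "Mainland"
  g$lat <- lat; g$lon <- lon
  g <- genotype_tbl(g)

  # null-allele overlay: per-locus beta shared across populations
  lset <- loci(g)
  beta_l <- stats::setNames(stats::runif(n_loci, 0, 0.33), lset)
  b <- beta_l[g$locus]
  null1 <- stats::runif(nrow(g)) < b
  null2 <- stats::runif(nrow(g)) < b
  both <- null1 & null2
  g$a1[both] <- NA_integer_; g$a2[both] <- NA_integer_
  one1 <- null1 & !both
  g$a1[one1] <- g$a2[one1] # surviving copy shows as apparent homozygote
  one2 <- null2 & !both
  g$a2[one2] <- g$a1[one2]
  miss <- stats::runif(nrow(g)) < 0.02
  g$a1[miss] <- NA_integer_; g$a2[miss] <- NA_integer_

  truth_beta <- tidyr::expand_grid(locus = lset,
                                   pop = unique(g$pop)) |>
    dplyr::mutate(beta = beta_l[.data$locus])
  list(genotypes = g,
       truth = list(scenario = scn, beta = truth_beta,
                    missing_rate = 0.02, seed = seed,
                    deme = stats::setNames(deme_of, g$id)[!duplicated(g$id)]))
}

#' Labelled benchmark datasets for null-allele EM recovery
#'
#' Single-population datasets drawn under HWE with a known null-allele
#' frequency overlaid by masking, for recovery curves of
#' [em_null_frequency()].
#'
#' @param beta_grid True null frequencies (each in `[0, 0.5]`).
#' @param n Diploid individuals per dataset.
#' @param n_alleles Visible alleles per locus (frequencies drawn once per
#'   dataset from a flat Dirichlet).
#' @param seed Integer seed.
#' @return A list of elements `list(genotypes, beta, freqs)`; `genotypes`
#'   is a single-locus [genotype_tbl()].
#' @export
generate_null_allele_benchmark <- function(beta_grid = c(0, 0.1, 0.2, 0.3),
                                           n = 500, n_alleles = 5,
                                           seed = 20210417) {
  stopifnot(all(beta_grid >= 0 & beta_grid <= 0.5))
  set.seed(seed)
  lapply(beta_grid, function(beta) {
    w <- stats::rgamma(n_alleles, 1)
    f_vis <- (w / sum(w)) * (1 - beta)
    probs <- c(f_vis, beta)
    sizes <- c(100 + 2 * seq_len(n_alleles), -1L) # -1 marks the null allele
    a1 <- sample(sizes, n, replace = TRUE, prob = probs)
    a2 <- sample(sizes, n, replace = TRUE, prob = probs)
    blank <- a1 == -1 & a2 == -1
    v1 <- ifelse(a1 == -1, a2, a1)
    v2 <- ifelse(a2 == -1, v1, a2)
    v1[blank] <- NA_integer_; v2[blank] <- NA_integer_
    g <- genotype_tbl(tibble::tibble(
      id = paste0("i", seq_len(n)), pop = "P1", locus = "L1",
      a1 = as.integer(v1), a2 = as.integer(v2)))
    list(genotypes = g, beta = beta,
         freqs = stats::setNames(f_vis, sizes[seq_len(n_alleles)]))
  })
}
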