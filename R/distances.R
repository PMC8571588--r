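#' Nei's (1972) standard genetic distance
#'
#' `D = -ln( Jxy / sqrt(Jx * Jy) )` with the J identities summed over loci
#' before normalisation.
#'
#' @param freq_a,freq_b Per-locus lists of named allele-frequency vectors
#'   (see [freq_vectors()]).
#' @return Non-negative distance; `Inf` (with a warning) when the
#'   populations share no alleles.
#' @export
nei_distance <- function(freq_a, freq_b) {
  shared <- intersect(names(freq_a), names(freq_b))
  if (length(shared) == 0) stop("no shared loci", call. = FALSE)
  jx <- 0; jy <- 0; jxy <- 0
  for (l in shared) {
    x <- freq_a[[l]]; y <- freq_b[[l]]
    alleles <- union(names(x), names(y))
    xv <- ifelse(alleles %in% names(x), x[alleles], 0)
    yv <- ifelse(alleles %in% names(y), y[alleles], 0)
    jx <- jx + sum(xv^2); jy <- jy + sum(yv^2); jxy <- jxy + sum(xv * yv)
  }
  if (jxy == 0) {
    warning("no shared alleles: distance is infinite")
    return(Inf)
  }
  max(0, -log(jxy / sqrt(jx * jy)))
}

new_dist_matrix <- function(m, metric) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  diag(m) <- 0
  structure(m, class = c("dist_matrix", "matrix"), metric = metric)
}

#' Pairwise genetic distance matrix between groups
#'
#' @param g A [genotype_tbl()].
#' @param metric `"nei"` (Nei 1972) or `"chord"` (Cavalli-Sforza & Edwards,
#'   see [chord_distance()]).
#' @param by Group by `"pop"` or `"region"`.
#' @param null_est Optional [estimate_null_alleles()] output; for
#'   `metric = "chord"` applies the INA correction (null class included),
#'   and for `"nei"` uses the corrected visible frequencies renormalised.
#' @return A symmetric `dist_matrix` with zero diagonal.
#' @export
genetic_distance_matrix <- function(g, metric = c("nei", "chord"),
                                    by = c("pop", "region"), null_est = NULL) {
  metric <- match.arg(metric)
  by <- match.arg(by)
  g <- assert_genotypes(g)
  ft <- allele_frequencies(g, by = by)
  groups <- unique(ft$group)
  k <- length(groups)
  m <- matrix(0, k, k, dimnames = list(groups, groups))
  fv <- lapply(groups, function(gr) freq_vectors(ft, gr))
  names(fv) <- groups
  bl <- NULL
  if (!is.null(null_est)) {
    if (by != "pop") stop("null correction applies to population grouping", call. = FALSE)
    cf <- lapply(groups, function(p) corrected_freq_vectors(null_est, p))
    names(cf) <- groups
    fv <- lapply(cf, `[[`, "freqs")
    bl <- lapply(cf, `[[`, "beta")
    if (metric == "nei") {
      # renormalise visible frequencies for Nei's identities
      fv <- lapply(fv, function(fl) lapply(fl, function(v) v / sum(v)))
    }
  }
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    d <- if (metric == "nei") {
      nei_distance(fv[[i]], fv[[j]])
    } else if (is.null(bl)) {
      chord_distance(fv[[i]], fv[[j]])
    } else {
      shared <- intersect(names(fv[[i]]), names(fv[[j]]))
      chord_distance(fv[[i]][shared], fv[[j]][shared],
                     beta_a = bl[[i]][shared], beta_b = bl[[j]][shared])
    }
    m[i, j] <- m[j, i] <- d
  }
  new_dist_matrix(m, if (is.null(null_est)) metric else paste0(metric, "-corrected"))
}

#' Pairwise FST matrix (Weir & Cockerham's theta)
#'
#' @param g A [genotype_tbl()].
#' @param correction `"none"` or `"ena"` (requires `est`).
#' @param est [estimate_null_alleles()] output, for `correction = "ena"`.
#' @param by Group by `"pop"` or `"region"` (region relabels populations).
#' @return A symmetric `dist_matrix` of pairwise theta values.
#' @export
pairwise_fst_matrix <- function(g, correction = c("none", "ena"), est = NULL,
                                by = c("pop", "region")) {
  correction <- match.arg(correction)
  by <- match.arg(by)
  g <- assert_genotypes(g)
  if (by == "region") {
    g <- g[!is.na(g$region), ]
    g$pop <- g$region
    g <- genotype_tbl(g)
  }
  if (correction == "ena") {
    if (is.null(est)) est <- estimate_null_alleles(g)
  } else est <- NULL
  pops <- populations(g)
  k <- length(pops)
  m <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    m[i, j] <- m[j, i] <- ena_fst(g, est = est, pops = c(pops[i], pops[j]))
  }
  new_dist_matrix(m, if (correction == "ena") "fst-ena" else "fst")
}

#' Write a distance matrix to disk
#'
#' @param d A `dist_matrix` (or plain labelled symmetric matrix).
#' @param path Output path.
#' @param format `"square"` (labelled CSV) or `"phylip"` (taxon count, then
#'   one label + lower-triangle row per taxon).
#' @return `path`, invisibly.
#' @export
write_dist_matrix <- function(d, path, format = c("square", "phylip")) {
  format <- match.arg(format)
  m <- unclass(d)
  if (format == "square") {
    utils::write.csv(m, path)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(m)), con)
  for (i in seq_len(nrow(m))) {
    vals <- if (i > 1) paste(sprintf("%.6f", m[i, seq_len(i - 1)]), collapse = " ") else ""
    writeLines(trimws(sprintf("%-10s %s", rownames(m)[i], vals)), con)
  }
  invisible(path)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou & Nei NJ via `ape::nj()`.  Negative branch lengths are clamped to
#' zero with the (negative) length transferred onto the adjacent descendant
#' edges so tip-to-tip path lengths are conserved.
#'
#' @param d A `dist_matrix` (or plain symmetric matrix with labels).
#' @return An `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  m <- unclass(d)
  if (any(is.na(m) | is.nan(m))) stop("distance matrix contains NA/NaN", call. = FALSE)
  if (nrow(m) < 3) stop("need at least 3 taxa", call. = FALSE)
  tr <- ape::nj(stats::as.dist(m))
  clamp_negative_edges(tr)
}

clamp_negative_edges <- function(tr) {
  repeat {
    neg <- which(tr$edge.length < -1e-12)
    if (length(neg) == 0) break
    e <- neg[1]
    len <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    child <- tr$edge[e, 2]
    below <- which(tr$edge[, 1] == child)
    if (length(below) > 0) {
      tr$edge.length[below] <- tr$edge.length[below] + len
    } else {
      # negative terminal edge: absorb into the parent-side sibling edges
      sib <- setdiff(which(tr$edge[, 1] == tr$edge[e, 1]), e)
      tr$edge.length[sib] <- tr$edge.length[sib] + len
    }
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Locus-bootstrap support for an NJ population tree
#'
#' Resamples loci with replacement, rebuilds the distance matrix and NJ tree
#' each time, and reports, for each internal edge of the reference tree, the
#' percentage of replicate trees containing the same bipartition.
#'
#' @param g A [genotype_tbl()].
#' @param metric `"nei"` or `"chord"` (passed to
#'   [genetic_distance_matrix()]).
#' @param by `"pop"` or `"region"`.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param null_est Optional null-allele estimates (chord INA correction).
#' @return The reference `phylo` tree with `node.label` set to support
#'   percentages.
#' @export
bootstrap_support <- function(g, metric = "nei", by = "pop", n_boot = 1000,
                              null_est = NULL) {
  g <- assert_genotypes(g)
  lset <- loci(g)
  if (length(lset) < 2) stop("locus bootstrap needs at least 2 loci", call. = FALSE)
  build <- function(gg) {
    nj_tree(genetic_distance_matrix(gg, metric = metric, by = by,
                                    null_est = null_est))
  }
  ref <- build(g)
  boots <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    pick <- sample(lset, length(lset), replace = TRUE)
    # duplicate sampled loci under unique names so each draw counts
    parts <- lapply(seq_along(pick), function(i) {
      d <- g[g$locus == pick[i], ]
      d$locus <- paste0(pick[i], "#", i)
      d
    })
    gb <- genotype_tbl(dplyr::bind_rows(parts))
    if (!is.null(null_est)) {
      eb <- dplyr::bind_rows(lapply(seq_along(pick), function(i) {
        e <- null_est[null_est$locus == pick[i], ]
        e$locus <- paste0(pick[i], "#", i)
        e
      }))
      boots[[b]] <- nj_tree(genetic_distance_matrix(gb, metric = metric, by = by,
                                                    null_est = eb))
    } else {
      boots[[b]] <- build(gb)
    }
  }
  class(boots) <- "multiPhylo"
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  ref$node.label <- round(100 * counts / n_boot)
  ref
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Eigen-decomposition of the double-centred `-D^2/2` matrix.  Negative
#' eigenvalues are reported, never silently dropped; coordinates are
#' returned for the positive axes only, ordered by eigenvalue.
#'
#' @param d A symmetric distance matrix with labels.
#' @return A `gp_pcoa` list: `points` (tibble with `label` and axis
#'   columns), `eigenvalues`, `explained` (positive-axis proportions).
#' @export
pcoa <- function(d) {
  m <- unclass(d)
  if (!isSymmetric(unname(m), tol = 1e-8)) stop("distance matrix must be symmetric", call. = FALSE)
  n <- nrow(m)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (m^2) %*% J
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- which(eg$values > 1e-10)
  coords <- eg$vectors[, pos, drop = FALSE] %*% diag(sqrt(eg$values[pos]), length(pos))
  colnames(coords) <- paste0("axis_", seq_along(pos))
  labs <- rownames(m)
  if (is.null(labs)) labs <- as.character(seq_len(n))
  structure(list(
    points = dplyr::bind_cols(tibble::tibble(label = labs),
                              tibble::as_tibble(coords)),
    eigenvalues = eg$values,
    explained = eg$values[pos] / sum(eg$values[pos])
  ), class = "gp_pcoa")
}

#' Individual-level Euclidean genetic distances
#'
#' Encodes each individual as its within-individual allele frequency vector
#' (0 / 0.5 / 1 per allele per locus); missing loci are mean-imputed within
#' the individual's population before computing Euclidean distances.
#'
#' @param g A [genotype_tbl()].
#' @return A `dist_matrix` over individuals.
#' @export
individual_distance_matrix <- function(g) {
  g <- assert_genotypes(g)
  ids <- unique(g$id)
  pop_of <- g$pop[match(ids, g$id)]
  cols <- g |>
    dplyr::filter(!is.na(.data$a1)) |>
    tidyr::pivot_longer(c("a1", "a2"), values_to = "allele") |>
    dplyr::distinct(.data$locus, .data$allele) |>
    dplyr::arrange(.data$locus, .data$allele)
  key <- paste(cols$locus, cols$allele)
  X <- matrix(NA_real_, length(ids), length(key),
              dimnames = list(ids, key))
  for (i in seq_along(ids)) {
    gi <- g[g$id == ids[i], ]
    for (r in seq_len(nrow(gi))) {
      if (is.na(gi$a1[r])) next
      lcols <- which(cols$locus == gi$locus[r])
      X[i, lcols] <- 0
      k1 <- paste(gi$locus[r], gi$a1[r])
      k2 <- paste(gi$locus[r], gi$a2[r])
      X[i, k1] <- X[i, k1] + 0.5
      X[i, k2] <- X[i, k2] + 0.5
    }
  }
  for (p in unique(pop_of)) {
    rows <- which(pop_of == p)
    cm <- colMeans(X[rows, , drop = FALSE], na.rm = TRUE)
    cm[is.nan(cm)] <- 0
    for (i in rows) {
      nas <- is.na(X[i, ])
      X[i, nas] <- cm[nas]
    }
  }
  new_dist_matrix(as.matrix(stats::dist(X)), "individual-euclidean")
}

#' Three-level AMOVA for diploid genotypes
#'
#' Hierarchical variance decomposition (among populations, among individuals
#' within populations, within individuals) from allele-level sums of squares
#' with the mismatch distance (0 if same allele, 1 otherwise), computed per
#' locus and summed; missing genotypes are ignored locus-wise.
#' Significance: the among-population component is tested by permuting
#' individuals among populations, the among-individual component by
#' permuting allele copies among individuals within populations.
#'
#' @param g A [genotype_tbl()].
#' @param n_perm Permutations for the p-values (default 99; 0 to skip).
#' @return A `gp_amova` list: `table` (tibble with df, SSD, variance
#'   components, percentages, p-values), `phi` statistics.
#' @export
amova <- function(g, n_perm = 99) {
  g <- assert_genotypes(g)
  if (length(populations(g)) < 2) stop("need at least 2 populations", call. = FALSE)
  comp <- amova_components(g)
  ptab <- c(NA_real_, NA_real_, NA_real_)
  if (n_perm > 0) {
    ids <- unique(g$id)
    id_pop <- g$pop[match(ids, g$id)]
    ge_a <- 0L
    for (i in seq_len(n_perm)) {
      perm <- sample(id_pop)
      gp <- g
      gp$pop <- perm[match(gp$id, ids)]
      if (amova_components(gp)$sigma[1] >= comp$sigma[1] - 1e-12) ge_a <- ge_a + 1L
    }
    ge_b <- 0L
    for (i in seq_len(n_perm)) {
      gp <- g |>
        dplyr::group_by(.data$locus, .data$pop) |>
        dplyr::group_modify(function(d, key) {
          ok <- !is.na(d$a1)
          copies <- c(d$a1[ok], d$a2[ok])
          copies <- sample(copies)
          k <- sum(ok)
          d$a1[ok] <- copies[seq_len(k)]
          d$a2[ok] <- copies[k + seq_len(k)]
          d
        }) |>
        dplyr::ungroup()
      gp <- genotype_tbl(gp)
      if (amova_components(gp)$sigma[2] >= comp$sigma[2] - 1e-12) ge_b <- ge_b + 1L
    }
    ptab <- c((ge_a + 1) / (n_perm + 1), (ge_b + 1) / (n_perm + 1), NA_real_)
  }
  total <- sum(comp$sigma)
  tab <- tibble::tibble(
    level = c("between_populations", "among_individuals_within", "within_individuals"),
    df = comp$df,
    ssd = comp$ssd,
    sigma = comp$sigma,
    percent = 100 * comp$sigma / total,
    p_value = ptab)
  structure(list(table = tab,
                 phi = c(phi_st = comp$sigma[1] / total,
                         phi_is = comp$sigma[2] / (comp$sigma[2] + comp$sigma[3]),
                         phi_it = (comp$sigma[1] + comp$sigma[2]) / total),
                 n_perm = n_perm),
            class = "gp_amova")
}

# internal: per-locus SSDs via allele-count identities, components summed
amova_components <- function(g) {
  ssd_a <- ssd_b <- ssd_w <- 0
  df_a <- df_b <- df_w <- 0
  sig_a <- sig_b <- sig_w <- 0
  ss_within_set <- function(copies) {
    n <- length(copies)
    if (n == 0) return(0)
    (n - sum(table(copies)^2) / n) / 2
  }
  for (l in loci(g)) {
    d <- g[g$locus == l & !is.na(g$a1), ]
    if (nrow(d) == 0) next
    pops_l <- unique(d$pop)
    P <- length(pops_l)
    N <- nrow(d)
    if (P < 2) next
    all_copies <- c(d$a1, d$a2)
    ss_tot <- ss_within_set(all_copies)
    ss_w <- sum(d$a1 != d$a2) * 0.5
    ss_pop <- vapply(pops_l, function(p) {
      dd <- d[d$pop == p, ]
      ss_within_set(c(dd$a1, dd$a2))
    }, numeric(1))
    ss_b <- sum(ss_pop) - ss_w
    ss_a <- ss_tot - sum(ss_pop)
    dfa <- P - 1; dfb <- N - P; dfw <- N
    n_p <- as.numeric(table(factor(d$pop, levels = pops_l))) * 2
    n_tot <- sum(n_p)
    nprime <- (n_tot - sum(n_p^2) / n_tot) / (P - 1)
    msw <- ss_w / dfw
    msb <- if (dfb > 0) ss_b / dfb else NA_real_
    msa <- ss_a / dfa
    s_w <- msw
    s_b <- if (!is.na(msb)) (msb - s_w) / 2 else 0
    s_a <- (msa - s_w - 2 * s_b) / nprime
    ssd_a <- ssd_a + ss_a; ssd_b <- ssd_b + ss_b; ssd_w <- ssd_w + ss_w
    df_a <- df_a + dfa; df_b <- df_b + dfb; df_w <- df_w + dfw
    sig_a <- sig_a + s_a; sig_b <- sig_b + s_b; sig_w <- sig_w + s_w
  }
  list(ssd = c(ssd_a, ssd_b, ssd_w), df = c(df_a, df_b, df_w),
       sigma = c(sig_a, sig_b, sig_w))
}

#' Mantel test with Spearman correlation
#'
#' Spearman rank correlation between the off-diagonal entries of two
#' distance matrices; one-sided p for positive association from joint
#' row/column permutations of the second matrix (via `vegan::mantel`).
#'
#' @param d1,d2 Distance matrices with identical labels in the same order.
#' @param n_perm Permutations (default 10000).
#' @return One-row test tibble with the Spearman rho as statistic.
#' @export
mantel_spearman <- function(d1, d2, n_perm = 10000) {
  m1 <- unclass(d1); m2 <- unclass(d2)
  if (nrow(m1) < 4) stop("too few groups for a meaningful permutation test", call. = FALSE)
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2))) {
    stop("matrices must share labels in the same order", call. = FALSE)
  }
  mt <- vegan::mantel(stats::as.dist(m1), stats::as.dist(m2),
                      method = "spearman", permutations = n_perm)
  new_test_result(unname(mt$statistic), mt$signif, "mantel-spearman", n_perm)
}

#' Great-circle distance matrix between group centroids
#'
#' Haversine distances (Earth radius 6371 km) between the mean coordinates
#' of each group's members.
#'
#' @param g A [genotype_tbl()] with `lat`/`lon` columns, or a data frame
#'   with `group`, `lat`, `lon`.
#' @param by `"pop"` or `"region"` when `g` is a genotype table.
#' @return A `dist_matrix` in kilometres; groups without coordinates are
#'   excluded with a warning.
#' @export
geographic_distance_matrix <- function(g, by = c("pop", "region")) {
  by <- match.arg(by)
  if (inherits(g, "genotype_tbl") || all(c("id", "locus") %in% names(g))) {
    if (!all(c("lat", "lon") %in% names(g))) stop("no coordinates present", call. = FALSE)
    cent <- g |>
      dplyr::distinct(.data$id, group = .data[[by]], .data$lat, .data$lon) |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(lat = mean(.data$lat, na.rm = TRUE),
                       lon = mean(.data$lon, na.rm = TRUE), .groups = "drop")
  } else {
    cent <- tibble::as_tibble(g)
  }
  drop <- is.na(cent$lat) | is.na(cent$lon) | is.na(cent$group)
  if (any(drop)) {
    warning("groups without coordinates excluded: ",
            paste(cent$group[drop], collapse = ", "))
    cent <- cent[!drop, ]
  }
  k <- nrow(cent)
  m <- matrix(0, k, k, dimnames = list(cent$group, cent$group))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i < j) {
      d <- geosphere::distHaversine(c(cent$lon[i], cent$lat[i]),
                                    c(cent$lon[j], cent$lat[j]),
                                    r = 6371) # km
      m[i, j] <- m[j, i] <- d
    }
  }
  new_dist_matrix(m, "geographic-km")
}
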