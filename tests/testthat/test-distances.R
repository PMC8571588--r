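test_that("Nei's standard distance matches hand evaluation and is non-negative", {
  fa <- list(L1 = c(`10` = 1))
  fb <- list(L1 = c(`10` = 0.5, `12` = 0.5))
  expect_equal(nei_distance(fa, fa), 0)
  expect_equal(nei_distance(fa, fb), -log(0.5 / sqrt(1 * 0.5)),
               tolerance = 1e-12)
  set.seed(61)
  for (r in 1:10) {
    x <- stats::runif(4); x <- x / sum(x)
    y <- stats::runif(4); y <- y / sum(y)
    d <- nei_distance(list(L1 = stats::setNames(x, 1:4)),
                      list(L1 = stats::setNames(y, 1:4)))
    expect_gte(d, 0)
  }
})

test_that("pairwise FST is symmetric with zero diagonal and near zero under panmixia", {
  set.seed(67)
  scn <- scn_split(c(40, 40), c(5000, 5000), t = 1, mu = 3.5e-4, loci = 10)
  g <- simulate_dataset(scn)
  m <- pairwise_fst_matrix(g)
  expect_equal(unclass(m), t(unclass(m)))
  expect_equal(diag(unclass(m)), c(A = 0, B = 0))
  expect_lt(abs(m["A", "B"]), 0.02)
})

test_that("NJ solves the 3-taxon case in closed form and recovers additive trees", {
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d3)
  # three-point formulas: la = (dab + dac - dbc)/2 etc.
  tip_edge <- function(tr, tip) tr$edge.length[tr$edge[, 2] == match(tip, tr$tip.label)]
  expect_equal(tip_edge(tr, "a"), (3 + 4 - 5) / 2)
  expect_equal(tip_edge(tr, "b"), (3 + 5 - 4) / 2)
  expect_equal(tip_edge(tr, "c"), (4 + 5 - 3) / 2)

  # additive 4-taxon matrix: ((a:1,b:2):1.5,(c:1,d:3))
  dm <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  dm["a", "b"] <- dm["b", "a"] <- 3
  dm["a", "c"] <- dm["c", "a"] <- 1 + 1.5 + 1
  dm["a", "d"] <- dm["d", "a"] <- 1 + 1.5 + 3
  dm["b", "c"] <- dm["c", "b"] <- 2 + 1.5 + 1
  dm["b", "d"] <- dm["d", "b"] <- 2 + 1.5 + 3
  dm["c", "d"] <- dm["d", "c"] <- 4
  tr4 <- nj_tree(dm)
  # path lengths between every tip pair reproduce the input distances
  paths <- ape::cophenetic.phylo(tr4)[letters[1:4], letters[1:4]]
  expect_equal(paths, dm, tolerance = 1e-12)
  # and the topology pairs (a,b) against (c,d)
  part <- ape::prop.part(tr4)
  expect_true(any(vapply(part, function(p) setequal(tr4$tip.label[p], c("c", "d")) ||
                           setequal(tr4$tip.label[p], c("a", "b")), logical(1))))

  expect_error(nj_tree(matrix(c(0, NA, NA, 0), 2)), "NA")
})

test_that("NJ output is valid Newick that round-trips", {
  set.seed(71)
  sl <- generate_study_like(1)
  d <- genetic_distance_matrix(sl$genotypes, metric = "nei")
  tr <- nj_tree(d)
  expect_true(all(tr$edge.length >= 0))
  f <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr, f)
  tr2 <- ape::read.tree(f)
  expect_setequal(tr$tip.label, tr2$tip.label)
  expect_equal(ape::dist.topo(tr, tr2), structure(0, names = "PH85"),
               ignore_attr = TRUE)
})

test_that("locus bootstrap gives full support for duplicated loci and is seeded", {
  set.seed(73)
  base <- gt_random(20, list(L1 = c(`10` = .4, `12` = .6)))
  pops <- list(P1 = c(.4, .6), P2 = c(.9, .1), P3 = c(.1, .9), P4 = c(.6, .4))
  parts <- lapply(names(pops), function(p) {
    f <- stats::setNames(pops[[p]], c(10, 12))
    gl <- lapply(paste0("L", 1:10), function(l) {
      gt_random(15, stats::setNames(list(f), l), pop = p)
    })
    out <- dplyr::bind_rows(gl)
    out$id <- paste0(p, "_", out$id)
    out
  })
  gg <- genotype_tbl(dplyr::bind_rows(parts))
  set.seed(1)
  tr1 <- bootstrap_support(gg, metric = "nei", n_boot = 30)
  expect_true(all(tr1$node.label >= 0 & tr1$node.label <= 100))
  set.seed(1)
  tr2 <- bootstrap_support(gg, metric = "nei", n_boot = 30)
  expect_identical(ape::write.tree(tr1), ape::write.tree(tr2))

  # identical information in every locus: supports all 100
  dup <- lapply(1:8, function(i) {
    d <- gg[gg$locus == "L1", ]
    d$locus <- paste0("K", i)
    d
  })
  gdup <- genotype_tbl(dplyr::bind_rows(dup))
  # need >= 3 distinguishable taxa; P1/P4 are close so use a 1-locus signal
  trd <- bootstrap_support(gdup, metric = "nei", n_boot = 20)
  expect_true(all(trd$node.label == 100))
})

test_that("PCoA reproduces a planar configuration and reports negative eigenvalues", {
  set.seed(79)
  pts <- cbind(stats::runif(6, 0, 10), stats::runif(6, 0, 10))
  rownames(pts) <- paste0("p", 1:6)
  d <- as.matrix(stats::dist(pts))
  pc <- pcoa(d)
  rec <- as.matrix(pc$points[, c("axis_1", "axis_2")])
  # Procrustes: distances in the embedding equal the input distances
  expect_equal(as.matrix(stats::dist(rec)), d, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_lte(sum(pc$explained), 1 + 1e-12)

  # duplicated points land on identical coordinates
  d2 <- as.matrix(stats::dist(pts[c(1, 1, 2, 3), ]))
  pc2 <- pcoa(d2)
  expect_equal(unlist(pc2$points[1, -1]), unlist(pc2$points[2, -1]),
               tolerance = 1e-10)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")

  # non-Euclidean input yields reported negative eigenvalues
  dne <- matrix(c(0, 1, 1, 1,
                  1, 0, 1, 1,
                  1, 1, 0, 3,
                  1, 1, 3, 0), 4)
  pcn <- pcoa(dne)
  expect_true(any(pcn$eigenvalues < -1e-10))
})

test_that("individual-level distances put duplicate individuals at zero distance", {
  set.seed(83)
  g <- gt_random(6, list(L1 = c(`10` = .5, `12` = .5), L2 = c(`5` = .5, `7` = .5)))
  dup <- g[g$id == "i1", ]
  dup$id <- "i1copy"
  gg <- genotype_tbl(dplyr::bind_rows(g, dup))
  m <- individual_distance_matrix(gg)
  expect_equal(unclass(m)["i1", "i1copy"], 0)
  expect_equal(unclass(m), t(unclass(m)))
})

test_that("AMOVA matches a brute-force sums-of-squares oracle on a small toy", {
  set.seed(89)
  g <- genotype_tbl(dplyr::bind_rows(lapply(1:3, function(p) {
    f1 <- stats::setNames(c(.2, .8, 0)[c(p, (p %% 3) + 1, ((p + 1) %% 3) + 1)], c(10, 12, 14))
    dplyr::bind_rows(
      gt_random(4, list(L1 = f1 + 0.01), pop = paste0("P", p)),
      NULL
    ) |> dplyr::mutate(id = paste0("P", p, "_", id))
  })))
  res <- amova(g, n_perm = 0)
  # brute-force: explicit pairwise mismatch sums of squares per level
  d <- g[!is.na(g$a1), ]
  copies <- tibble::tibble(id = rep(d$id, 2), pop = rep(d$pop, 2),
                           allele = c(d$a1, d$a2))
  ssd_set <- function(x) {
    n <- length(x)
    if (n < 2) return(0)
    pairs <- utils::combn(n, 2)
    sum(x[pairs[1, ]] != x[pairs[2, ]]) / n
  }
  ssd_tot <- ssd_set(copies$allele)
  ssd_pop <- sum(vapply(split(copies$allele, copies$pop), ssd_set, numeric(1)))
  ssd_ind <- sum(vapply(split(copies$allele, copies$id), ssd_set, numeric(1)))
  expect_equal(sum(res$table$ssd),
               ssd_tot - ssd_pop + ssd_pop - ssd_ind + ssd_ind,
               tolerance = 1e-10)
  expect_equal(res$table$ssd[1], ssd_tot - ssd_pop, tolerance = 1e-10)
  expect_equal(res$table$ssd[2], ssd_pop - ssd_ind, tolerance = 1e-10)
  expect_equal(res$table$ssd[3], ssd_ind, tolerance = 1e-10)
  expect_equal(sum(res$table$percent), 100, tolerance = 0.01)
})

test_that("AMOVA separates cloned pools from fully differentiated ones", {
  set.seed(97)
  pool <- list(L1 = c(`10` = .5, `12` = .5), L2 = c(`5` = .3, `6` = .7))
  parts <- lapply(1:3, function(p) {
    gp <- gt_random(15, pool, pop = paste0("P", p))
    gp$id <- paste0("P", p, "_", gp$id)
    gp
  })
  res <- amova(genotype_tbl(dplyr::bind_rows(parts)), n_perm = 49)
  expect_lt(abs(res$table$percent[1]), 5)
  expect_gt(res$table$p_value[1], 0.05)

  fixed <- genotype_tbl(dplyr::bind_rows(
    gt_locus(rep(list(c(10, 10)), 8)),
    gt_locus(rep(list(c(12, 12)), 8), pop = "P2") |>
      dplyr::mutate(id = paste0("j", 1:8))))
  res2 <- amova(fixed, n_perm = 0)
  expect_equal(res2$table$percent[1], 100, tolerance = 1e-9)
})

test_that("Mantel with Spearman is exact on monotone transforms and null on noise", {
  set.seed(101)
  pts <- cbind(stats::runif(7), stats::runif(7))
  rownames(pts) <- paste0("g", 1:7)
  d1 <- as.matrix(stats::dist(pts))
  d2 <- sqrt(d1)
  res <- mantel_spearman(d1, d2, n_perm = 99)
  expect_equal(res$statistic, 1)
  expect_lt(res$p_value, 0.05)
  expect_error(mantel_spearman(d1[1:3, 1:3], d2[1:3, 1:3]), "few")
})

test_that("Mantel p-values are roughly uniform for independent matrices", {
  set.seed(103)
  ps <- replicate(60, {
    m1 <- as.matrix(stats::dist(stats::runif(8)))
    m2 <- as.matrix(stats::dist(stats::runif(8)))
    mantel_spearman(m1, m2, n_perm = 99)$p_value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("distance matrices export as square CSV and lower-triangle text", {
  m <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  f1 <- withr::local_tempfile(fileext = ".csv")
  write_dist_matrix(m, f1)
  back <- as.matrix(utils::read.csv(f1, row.names = 1))
  expect_equal(unname(back), unname(m))
  f2 <- withr::local_tempfile(fileext = ".dist")
  write_dist_matrix(m, f2, format = "phylip")
  lines <- readLines(f2)
  expect_equal(as.integer(trimws(lines[1])), 3)
  expect_match(lines[4], "^c\\s+2\\.0+ 3\\.0+$")
})

test_that("great-circle distances match the haversine closed form", {
  cents <- tibble::tibble(group = c("a", "b"), lat = c(0, 1), lon = c(0, 0))
  m <- geographic_distance_matrix(cents)
  expect_lt(abs(unclass(m)["a", "b"] - 111.19), 0.1)
  set.seed(107)
  cents2 <- tibble::tibble(group = paste0("g", 1:5),
                           lat = stats::runif(5, -5, 5),
                           lon = stats::runif(5, -81, -76))
  m2 <- unclass(geographic_distance_matrix(cents2))
  expect_equal(m2, t(m2))
  for (i in 1:5) for (j in 1:5) for (k in 1:5) {
    expect_lte(m2[i, j], m2[i, k] + m2[k, j] + 1e-9)
  }
})
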