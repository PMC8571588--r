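# small genotype builders used across test files

gt <- function(...) {
  rows <- list(...)
  genotype_tbl(dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(id = r[[1]], pop = r[[2]], locus = r[[3]],
                   a1 = as.integer(r[[4]]), a2 = as.integer(r[[5]]))
  })))
}

# one population, one locus, from a vector of genotype pairs
gt_locus <- function(pairs, pop = "P1", locus = "L1") {
  genotype_tbl(tibble::tibble(
    id = paste0("i", seq_along(pairs)), pop = pop, locus = locus,
    a1 = as.integer(vapply(pairs, `[`, numeric(1), 1)),
    a2 = as.integer(vapply(pairs, `[`, numeric(1), 2))))
}

# multi-locus panmictic population drawn from given allele frequencies
gt_random <- function(n, freqs_by_locus, pop = "P1") {
  rows <- lapply(names(freqs_by_locus), function(l) {
    f <- freqs_by_locus[[l]]
    sizes <- as.integer(names(f))
    draw <- function() {
      if (length(sizes) == 1) rep(sizes, n) else sample(sizes, n, TRUE, f)
    }
    tibble::tibble(id = paste0("i", seq_len(n)), pop = pop, locus = l,
                   a1 = draw(), a2 = draw())
  })
  genotype_tbl(dplyr::bind_rows(rows))
}

# a one-population constant-size scenario
scn_constant <- function(n_sample, N, mu = 0, loci = 1) {
  scenario("constant", tibble::tibble(pop = "A", n_sample = as.integer(n_sample),
                                      n = N),
           tibble::tibble(time = numeric(0), type = character(0),
                          pop = character(0)),
           mu = mu, loci = loci)
}

# two populations splitting t generations ago
scn_split <- function(n_sample, N, t, mu, loci = 1) {
  scenario("split",
           tibble::tibble(pop = c("A", "B"), n_sample = as.integer(n_sample),
                          n = N),
           tibble::tibble(time = t, type = "merge", pop = "B", parent_a = "A",
                          parent_b = NA_character_, prop = NA_real_,
                          size = NA_real_),
           mu = mu, loci = loci)
}
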