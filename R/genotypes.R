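#' Diploid SSR genotype table
#'
#' The central data container of the package: a long-format tibble with one
#' row per individual x locus, carrying the two allele sizes of a diploid
#' call (both `NA` for a missing genotype), the population label, and
#' optional region and coordinate metadata.
#'
#' @param x A data frame with columns `id`, `pop`, `locus`, `a1`, `a2` and
#'   optionally `region`, `lat`, `lon`.  Allele sizes are positive integers
#'   on the locus's repeat scale; a missing call has both alleles `NA`.
#' @return A validated `genotype_tbl` (a tibble subclass).
#' @details Invariants enforced: every non-missing call carries exactly two
#'   allele entries (a homozygote repeats the same size); a half-missing call
#'   is rejected; allele sizes must be positive integers.  Every individual
#'   belongs to exactly one population; region labels, when present, are
#'   constant within an individual.
#' @export
genotype_tbl <- function(x) {
  x <- tibble::as_tibble(x)
  required <- c("id", "pop", "locus", "a1", "a2")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("genotype table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x$id <- as.character(x$id)
  x$pop <- as.character(x$pop)
  x$locus <- as.character(x$locus)
  x$a1 <- as.integer(x$a1)
  x$a2 <- as.integer(x$a2)
  half <- xor(is.na(x$a1), is.na(x$a2))
  if (any(half)) {
    bad <- which(half)[1]
    stop(sprintf("half-missing call at id '%s', locus '%s': a genotype needs two alleles or none",
                 x$id[bad], x$locus[bad]), call. = FALSE)
  }
  ok <- is.na(x$a1) | (x$a1 > 0 & x$a2 > 0)
  if (!all(ok)) {
    bad <- which(!ok)[1]
    stop(sprintf("non-positive allele size at id '%s', locus '%s'",
                 x$id[bad], x$locus[bad]), call. = FALSE)
  }
  pop_per_id <- dplyr::n_distinct(paste(x$id, x$pop)) == dplyr::n_distinct(x$id)
  if (!pop_per_id) stop("population labels must partition individuals", call. = FALSE)
  dup <- duplicated(x[, c("id", "locus")])
  if (any(dup)) stop("duplicated id x locus rows", call. = FALSE)
  class(x) <- c("genotype_tbl", class(tibble::tibble()))
  x
}

#' @export
print.genotype_tbl <- function(x, ...) {
  cat(sprintf("<genotype_tbl> %d individuals, %d loci, %d populations\n",
              dplyr::n_distinct(x$id), dplyr::n_distinct(x$locus),
              dplyr::n_distinct(x$pop)))
  NextMethod()
}

#' Loci, individuals and populations of a genotype table
#' @param g A [genotype_tbl()].
#' @return Character vector of unique labels, in order of first appearance.
#' @export
loci <- function(g) unique(g$locus)

#' @rdname loci
#' @export
populations <- function(g) unique(g$pop)

# internal: assert class
assert_genotypes <- function(g) {
  if (!inherits(g, "genotype_tbl")) g <- genotype_tbl(g)
  g
}

# internal: drop the genotype_tbl class so derived summaries print plainly
strip_gt <- function(x) {
  class(x) <- setdiff(class(x), "genotype_tbl")
  x
}

#' Read diploid SSR genotypes
#'
#' Reads a genotype file in one of three dialects: GenePop (POP-block
#' format with 2- or 3-digit allele codes, auto-detected), wide CSV
#' (`<locus>_1`/`<locus>_2` column pairs), or long CSV
#' (`id,pop,locus,a1,a2`).  Missing codes (`0000`/`000000` in GenePop,
#' empty/`NA` in CSV) are normalised to `NA`.
#'
#' @param path File path.
#' @param dialect One of `"genepop"`, `"csv-wide"`, `"csv-long"`.
#' @param missing_code Additional string treated as missing in CSV dialects.
#' @return A [genotype_tbl()].
#' @export
read_genotypes <- function(path, dialect = c("genepop", "csv-wide", "csv-long"),
                           missing_code = "NA") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dialect <- match.arg(dialect)
  switch(dialect,
    "genepop" = read_genepop(path),
    "csv-wide" = read_csv_wide(path, missing_code),
    "csv-long" = read_csv_long(path, missing_code)
  )
}

read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  if (length(lines) < 3) stop("malformed GenePop file: too few lines", call. = FALSE)
  body <- lines[-1] # drop title line
  pop_idx <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (length(pop_idx) == 0) stop("malformed GenePop file: no POP block", call. = FALSE)
  locus_lines <- body[seq_len(pop_idx[1] - 1)]
  locus_names <- trimws(unlist(strsplit(locus_lines, ",")))
  locus_names <- locus_names[locus_names != ""]

  rows <- list()
  pop_breaks <- c(pop_idx, length(body) + 1)
  for (p in seq_along(pop_idx)) {
    ind_lines <- body[seq(pop_breaks[p] + 1, pop_breaks[p + 1] - 1)]
    ind_lines <- ind_lines[!grepl("^\\s*pop\\s*$", ind_lines, ignore.case = TRUE)]
    for (ln in ind_lines) {
      parts <- strsplit(ln, ",")[[1]]
      if (length(parts) < 2) {
        stop("malformed GenePop individual line: ", ln, call. = FALSE)
      }
      raw_id <- trimws(parts[1])
      genos <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
      if (length(genos) != length(locus_names)) {
        stop(sprintf("individual '%s' has %d genotype fields for %d loci",
                     raw_id, length(genos), length(locus_names)), call. = FALSE)
      }
      # our writer embeds the population label as "<pop>|<id>"; plain files
      # fall back to pop1, pop2, ...
      if (grepl("|", raw_id, fixed = TRUE)) {
        bits <- strsplit(raw_id, "|", fixed = TRUE)[[1]]
        pop_lab <- bits[1]; id <- paste(bits[-1], collapse = "|")
      } else {
        pop_lab <- paste0("pop", p); id <- raw_id
      }
      width <- nchar(genos[1])
      if (!width %in% c(4, 6)) {
        stop(sprintf("cannot detect allele encoding for individual '%s' (field width %d)",
                     id, width), call. = FALSE)
      }
      half <- width / 2
      a1 <- suppressWarnings(as.integer(substr(genos, 1, half)))
      a2 <- suppressWarnings(as.integer(substr(genos, half + 1, width)))
      if (anyNA(a1) || anyNA(a2)) {
        bad <- which(is.na(a1) | is.na(a2))[1]
        stop(sprintf("non-numeric genotype for individual '%s', locus '%s'",
                     id, locus_names[bad]), call. = FALSE)
      }
      a1[a1 == 0] <- NA_integer_
      a2[a2 == 0] <- NA_integer_
      # a half-zero code means the whole call is unusable
      a1[is.na(a2)] <- NA_integer_
      a2[is.na(a1)] <- NA_integer_
      rows[[length(rows) + 1]] <- tibble::tibble(
        id = id, pop = pop_lab, locus = locus_names, a1 = a1, a2 = a2)
    }
  }
  genotype_tbl(dplyr::bind_rows(rows))
}

read_csv_long <- function(path, missing_code) {
  x <- readr::read_csv(path, show_col_types = FALSE, na = c("", "NA", missing_code))
  genotype_tbl(x)
}

read_csv_wide <- function(path, missing_code) {
  x <- readr::read_csv(path, show_col_types = FALSE, na = c("", "NA", missing_code))
  meta_cols <- intersect(c("id", "pop", "region", "lat", "lon"), names(x))
  allele_cols <- setdiff(names(x), meta_cols)
  l1 <- grep("_1$", allele_cols, value = TRUE)
  locus_names <- sub("_1$", "", l1)
  if (!all(paste0(locus_names, "_2") %in% allele_cols)) {
    stop("csv-wide requires <locus>_1/<locus>_2 column pairs", call. = FALSE)
  }
  long <- tidyr::pivot_longer(x, cols = dplyr::all_of(allele_cols),
                              names_to = c("locus", "copy"), names_sep = "_(?=[12]$)",
                              values_to = "allele")
  wide <- tidyr::pivot_wider(long, names_from = "copy", values_from = "allele",
                             names_prefix = "a")
  genotype_tbl(wide)
}

#' Write diploid SSR genotypes
#'
#' @param g A [genotype_tbl()].
#' @param path Output file path.
#' @param dialect One of `"genepop"`, `"csv-wide"`, `"csv-long"`.
#' @param digits GenePop allele field width per allele (2 or 3).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, dialect = c("genepop", "csv-wide", "csv-long"),
                            digits = 3) {
  g <- assert_genotypes(g)
  dialect <- match.arg(dialect)
  if (dialect == "csv-long") {
    readr::write_csv(g, path, na = "")
    return(invisible(path))
  }
  if (dialect == "csv-wide") {
    meta <- intersect(c("id", "pop", "region", "lat", "lon"), names(g))
    wide <- g |>
      tidyr::pivot_longer(c("a1", "a2"), names_to = "copy", values_to = "allele") |>
      dplyr::mutate(copy = sub("^a", "", .data$copy)) |>
      tidyr::pivot_wider(id_cols = dplyr::all_of(meta),
                         names_from = c("locus", "copy"), values_from = "allele",
                         names_sep = "_")
    readr::write_csv(wide, path, na = "")
    return(invisible(path))
  }
  # genepop
  if (!digits %in% c(2, 3)) stop("digits must be 2 or 3", call. = FALSE)
  if (max(c(g$a1, g$a2), na.rm = TRUE) >= 10^digits) {
    stop("allele sizes exceed the chosen GenePop field width", call. = FALSE)
  }
  lset <- loci(g)
  fmt <- function(a) {
    out <- formatC(ifelse(is.na(a), 0L, a), width = digits, flag = "0")
    out
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("guavapop export", con)
  writeLines(lset, con)
  for (p in populations(g)) {
    writeLines("POP", con)
    sub <- g[g$pop == p, ]
    for (ind in unique(sub$id)) {
      gi <- sub[sub$id == ind, ]
      gi <- gi[match(lset, gi$locus), ]
      codes <- paste0(fmt(gi$a1), fmt(gi$a2))
      writeLines(sprintf("%s|%s , %s", p, ind, paste(codes, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Export genotypes for admixture-clustering programs
#'
#' Writes a whitespace-delimited matrix with two rows per individual (one per
#' allele copy), loci in columns, alleles integer-coded and missing coded -9.
#'
#' @param g A [genotype_tbl()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_matrix <- function(g, path) {
  g <- assert_genotypes(g)
  lset <- loci(g)
  pops <- populations(g)
  con <- file(path, "w")
  on.exit(close(con))
  for (ind in unique(g$id)) {
    gi <- g[g$id == ind, ]
    gi <- gi[match(lset, gi$locus), ]
    p <- match(gi$pop[1], pops)
    r1 <- ifelse(is.na(gi$a1), -9L, gi$a1)
    r2 <- ifelse(is.na(gi$a2), -9L, gi$a2)
    writeLines(paste(c(ind, p, r1), collapse = " "), con)
    writeLines(paste(c(ind, p, r2), collapse = " "), con)
  }
  invisible(path)
}

#' Latitudinal region binning
#'
#' Defines the mainland sampling design: a north-south axis divided into
#' equal-height latitudinal bands crossed with physiographic axis labels,
#' yielding band x axis region labels (9 by default).
#'
#' @param extent_km Total north-south extent in km (default 720).
#' @param n_bands Number of latitudinal bands (default 3).
#' @param band_labels Labels for the bands, north to south.
#' @param axis_labels Labels for the physiographic axis.
#' @return A `latitudinal_binning` list with the band height precomputed.
#' @export
latitudinal_binning <- function(extent_km = 720, n_bands = 3,
                                band_labels = c("North", "Center", "South"),
                                axis_labels = c("Coast", "Highlands", "Amazon")) {
  stopifnot(extent_km > 0, n_bands >= 1, length(band_labels) == n_bands)
  structure(list(extent_km = extent_km, n_bands = n_bands,
                 band_height_km = extent_km / n_bands,
                 band_labels = band_labels, axis_labels = axis_labels),
            class = "latitudinal_binning")
}

#' Assign a sample to its latitudinal region
#'
#' Bands are half-open `[a, b)`: a sample exactly on a band boundary falls in
#' the southern band; the southern extreme (`distance == extent_km`) falls in
#' the last band.
#'
#' @param distance_from_north_km Distance from the northernmost tip, in km.
#' @param axis_label One of the binning's axis labels.
#' @param binning A [latitudinal_binning()].
#' @return Character region label, `"<band> <axis>"`.  Vectorised over
#'   `distance_from_north_km` and `axis_label`.
#' @export
assign_latitudinal_region <- function(distance_from_north_km, axis_label,
                                      binning = latitudinal_binning()) {
  d <- distance_from_north_km
  if (any(d < 0 | d > binning$extent_km)) {
    stop("distance outside [0, extent_km]", call. = FALSE)
  }
  if (!all(axis_label %in% binning$axis_labels)) {
    stop("unknown axis label", call. = FALSE)
  }
  band <- pmin(floor(d / binning$band_height_km) + 1, binning$n_bands)
  paste(binning$band_labels[band], axis_label)
}

#' Allele frequencies by population or region
#'
#' Tallies allele copies per locus within each group.  A group with zero
#' non-missing calls at a locus is absent from the result (not zero-filled);
#' frequencies within each present locus x group sum to 1.
#'
#' @param g A [genotype_tbl()].
#' @param by Grouping column: `"pop"` (default) or `"region"`.
#' @return A tibble with columns `locus`, `group`, `allele`, `count`,
#'   `gene_count`, `freq`.
#' @export
allele_frequencies <- function(g, by = c("pop", "region")) {
  g <- assert_genotypes(g)
  by <- match.arg(by)
  if (by == "region" && !"region" %in% names(g)) {
    stop("genotype table has no region column", call. = FALSE)
  }
  long <- strip_gt(g) |>
    dplyr::mutate(group = .data[[by]]) |>
    dplyr::filter(!is.na(.data$group)) |>
    tidyr::pivot_longer(c("a1", "a2"), values_to = "allele") |>
    dplyr::filter(!is.na(.data$allele))
  long |>
    dplyr::count(.data$locus, .data$group, .data$allele, name = "count") |>
    dplyr::group_by(.data$locus, .data$group) |>
    dplyr::mutate(gene_count = sum(.data$count),
                  freq = .data$count / .data$gene_count) |>
    dplyr::ungroup()
}

# internal: per locus x group named frequency vectors as a nested list
freq_list <- function(freq_tbl) {
  split(freq_tbl, freq_tbl$locus) |>
    lapply(function(fl) {
      split(fl, fl$group) |>
        lapply(function(fg) stats::setNames(fg$freq, fg$allele))
    })
}

# internal: flatten genotypes to a gene-copy matrix (2 rows per individual,
# consecutive) plus 0-based population index, for the compiled statistics
gene_copy_matrix <- function(g, pops = populations(g)) {
  g <- assert_genotypes(g)
  lset <- loci(g)
  ids <- unique(g$id)
  wide1 <- tidyr::pivot_wider(g[, c("id", "locus", "a1")],
                              names_from = "locus", values_from = "a1")
  wide2 <- tidyr::pivot_wider(g[, c("id", "locus", "a2")],
                              names_from = "locus", values_from = "a2")
  wide1 <- wide1[match(ids, wide1$id), c("id", lset)]
  wide2 <- wide2[match(ids, wide2$id), c("id", lset)]
  m1 <- as.matrix(wide1[, -1]); m2 <- as.matrix(wide2[, -1])
  n <- length(ids)
  m <- matrix(NA_integer_, nrow = 2 * n, ncol = length(lset))
  m[seq(1, 2 * n, by = 2), ] <- m1
  m[seq(2, 2 * n, by = 2), ] <- m2
  storage.mode(m) <- "integer"
  pop_of_id <- g$pop[match(ids, g$id)]
  pop_idx <- rep(match(pop_of_id, pops) - 1L, each = 2)
  keep <- !is.na(pop_idx)
  list(m = m[keep, , drop = FALSE], pop = pop_idx[keep], pops = pops, loci = lset)
}
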