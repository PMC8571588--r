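#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a distance matrix into a long tibble
#'
#' @param x A `dist_matrix`.
#' @param ... Unused.
#' @return Tibble with `from`, `to`, `distance` (upper triangle only).
#' @export
tidy.dist_matrix <- function(x, ...) {
  m <- unclass(x)
  labs <- rownames(m)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(from = labs[idx[, 1]], to = labs[idx[, 2]],
                 distance = m[idx], metric = attr(x, "metric"))
}

#' Tidy an AMOVA fit
#'
#' @param x A `gp_amova`.
#' @param ... Unused.
#' @return The component table (level, df, SSD, variance, percent, p).
#' @export
tidy.gp_amova <- function(x, ...) x$table

#' @export
glance.gp_amova <- function(x, ...) {
  tibble::tibble(phi_st = x$phi[["phi_st"]], phi_is = x$phi[["phi_is"]],
                 phi_it = x$phi[["phi_it"]], n_perm = x$n_perm)
}

#' Tidy an ABC parameter posterior
#'
#' @param x A `gp_abc_post`.
#' @param ... Unused.
#' @return Quantile table (parameter, q025, median, q975).
#' @export
tidy.gp_abc_post <- function(x, ...) x$quantiles

#' @export
glance.gp_abc_post <- function(x, ...) {
  tibble::tibble(scenario = x$scenario, n_samples = nrow(x$samples),
                 adjusted = x$adjusted)
}

#' Tidy a PCoA
#'
#' @param x A `gp_pcoa`.
#' @param ... Unused.
#' @return The coordinate tibble.
#' @export
tidy.gp_pcoa <- function(x, ...) x$points

#' @export
glance.gp_pcoa <- function(x, ...) {
  tibble::tibble(n_positive_axes = length(x$explained),
                 explained_1 = x$explained[1],
                 explained_2 = if (length(x$explained) > 1) x$explained[2] else NA_real_,
                 n_negative_eigenvalues = sum(x$eigenvalues < -1e-10))
}

#' @export
print.gp_amova <- function(x, ...) {
  cat("Three-level AMOVA (mismatch distance, missing ignored)\n")
  print(x$table)
  cat(sprintf("Phi_ST = %.4f  Phi_IS = %.4f  Phi_IT = %.4f\n",
              x$phi[["phi_st"]], x$phi[["phi_is"]], x$phi[["phi_it"]]))
  invisible(x)
}
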