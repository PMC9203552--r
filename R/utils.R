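# Internal helpers shared across modules.

# stop with a classed condition so callers/tests can match on class
stop_fcb <- function(msg, class) {
  rlang::abort(msg, class = c(class, "fcbiotype_error"))
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop_fcb(sprintf("`%s` must be a single finite number in [%s, %s]",
                     name, format(lower), format(upper)),
             "fcbiotype_config_error")
  }
  invisible(x)
}

# number of FC features for R ROIs (strict upper triangle)
#' Number of unique FC features for a given ROI count
#'
#' For `R` regions of interest the functional-connectivity vector holds the
#' strict upper triangle of the ROI-by-ROI correlation matrix, i.e.
#' `R * (R - 1) / 2` entries (35,778 for the 268-node atlas).
#'
#' @param n_roi number of ROIs (>= 2).
#' @return integer count of unique ROI pairs.
#' @export
#' @examples
#' n_fc_features(268)
n_fc_features <- function(n_roi) {
  check_number(n_roi, "n_roi", lower = 2)
  as.integer(n_roi * (n_roi - 1) / 2)
}

# index map for the vectorized strict upper triangle, row-major (i < j):
# (1,2), (1,3), ..., (1,R), (2,3), ...
fc_index_map <- function(n_roi) {
  idx <- which(upper.tri(matrix(0, n_roi, n_roi)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  tibble::tibble(fc_index = seq_len(nrow(idx)),
                 roi_i = idx[, 1L], roi_j = idx[, 2L])
}

# vectorize the strict upper triangle of a square matrix in the documented
# row-major (i < j) order
upper_tri_vec <- function(m) {
  n <- nrow(m)
  map <- fc_index_map(n)
  m[cbind(map$roi_i, map$roi_j)]
}

# Fisher z transform and inverse, used to keep simulated correlations in (-1, 1)
fisher_z <- function(r) atanh(pmin(pmax(r, -0.999999), 0.999999))
fisher_z_inv <- function(z) tanh(z)

# run `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, expr)
}

# derive a stream-specific child seed from a base seed (kept below 2^31)
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream * 1009) %% 2147483647
}

#' Adjusted Rand index between two labelings
#'
#' Thin wrapper around [mclust::adjustedRandIndex()], used to score recovery
#' of planted biotypes by a clustering solution (1 = identical partitions up
#' to label renaming, 0 = chance agreement).
#'
#' @param a,b label vectors of equal length.
#' @return adjusted Rand index.
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}
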