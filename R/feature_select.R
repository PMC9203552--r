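#' Feature mask constructor
#'
#' Boolean mask over FC features with provenance of the screen that produced
#' it.
#'
#' @param selected logical vector over FC indices.
#' @param alpha significance threshold used.
#' @param provenance one of "spearman", "wilcoxon", "union".
#' @param p_min optional per-feature minimum p-value across the screen.
#' @return object of class `feature_mask`.
#' @export
feature_mask <- function(selected, alpha, provenance, p_min = NULL) {
  structure(list(selected = as.logical(selected), alpha = alpha,
                 provenance = provenance, p_min = p_min),
            class = "feature_mask")
}

#' @export
print.feature_mask <- function(x, ...) {
  cat(sprintf("<feature_mask> %d / %d features (%s screen, alpha = %g)\n",
              sum(x$selected), length(x$selected), x$provenance, x$alpha))
  invisible(x)
}

# column ranks with average ties; returns matrix
col_ranks <- function(m) apply(m, 2, rank)

# vectorized two-sided Spearman p via the t approximation on average ranks
spearman_p_matrix <- function(fc, metrics) {
  n <- nrow(fc)
  rf <- col_ranks(fc)
  rm_ <- col_ranks(metrics)
  sf <- apply(rf, 2, sd)
  sm <- apply(rm_, 2, sd)
  rf <- sweep(rf, 2, colMeans(rf))
  rm_ <- sweep(rm_, 2, colMeans(rm_))
  rho <- crossprod(rf, rm_) / (n - 1)            # p x m covariance of ranks
  rho <- rho / outer(sf, sm)                     # correlations (NaN if constant)
  rho <- pmin(pmax(rho, -1), 1)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-300))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1 - 1e-15] <- 0
  list(rho = rho, p = p)
}

#' Screen FC features by Spearman correlation with clinical metrics
#'
#' A feature is selected when it is rank-correlated with *one or more* of the
#' clinical metrics at the given threshold: the minimum two-sided Spearman
#' p-value over the metric columns is compared to `alpha` with no
#' multiplicity correction across metrics (union semantics). Ties receive
#' average ranks; p-values use the t approximation on the rank correlation.
#' Intended to be run on the training split only.
#'
#' @param fc subjects x features FC matrix (training split).
#' @param metrics data frame / matrix of clinical metric columns aligned with
#'   `fc` rows (by default the 10 alcohol metrics and 8 ASR scores; any
#'   numeric columns supplied are used).
#' @param alpha significance threshold.
#' @return a [feature_mask()] with provenance "spearman". Constant features
#'   have undefined correlation and are never selected (a warning is issued).
#' @export
spearman_screen <- function(fc, metrics, alpha) {
  fc <- as.matrix(fc)
  metrics <- as.matrix(as.data.frame(metrics)[
    , vapply(as.data.frame(metrics), is.numeric, logical(1)), drop = FALSE])
  stopifnot(nrow(fc) == nrow(metrics), ncol(metrics) >= 1)
  res <- spearman_p_matrix(fc, metrics)
  p_min <- unname(apply(res$p, 1, function(r)
    suppressWarnings(min(r, na.rm = TRUE))))
  bad <- !is.finite(p_min)
  if (any(is.na(res$p))) {
    const_fc <- apply(fc, 2, function(x) length(unique(x)) == 1L)
    if (any(const_fc)) {
      rlang::warn(sprintf(
        "%d constant FC feature(s): Spearman p undefined, not selected",
        sum(const_fc)))
    }
  }
  p_min[bad] <- NA_real_
  feature_mask(!bad & p_min < alpha, alpha, "spearman", p_min = p_min)
}

# rank-sum p for one feature; exact when both groups small and untied
ranksum_p <- function(x, g1, exact_max = 20) {
  n1 <- sum(g1); n0 <- sum(!g1)
  if (n1 <= exact_max && n0 <= exact_max) {
    return(suppressWarnings(
      stats::wilcox.test(x[g1], x[!g1], exact = TRUE)$p.value))
  }
  r <- rank(x)
  u <- sum(r[g1]) - n1 * (n1 + 1) / 2
  mu <- n1 * n0 / 2
  ties <- table(r)
  sig2 <- n1 * n0 / 12 * ((n1 + n0 + 1) -
    sum(ties^3 - ties) / ((n1 + n0) * (n1 + n0 - 1)))
  if (sig2 <= 0) return(1)
  z <- (abs(u - mu) - 0.5) / sqrt(sig2)   # continuity-corrected
  min(1, 2 * pnorm(-max(z, 0)))
}

#' Screen FC features by Wilcoxon rank-sum case-control tests
#'
#' A feature is selected when its two-sided Wilcoxon rank-sum p-value for the
#' AM-vs-control contrast falls below `alpha`. Exact p-values are used when
#' both groups have at most 20 subjects (and the data are untied); otherwise
#' the tie-corrected, continuity-corrected normal approximation. Training
#' split only.
#'
#' @param fc subjects x features FC matrix.
#' @param group logical or two-level vector marking cases (`TRUE` / `"AM"`).
#' @param alpha significance threshold.
#' @return a [feature_mask()] with provenance "wilcoxon".
#' @export
wilcoxon_screen <- function(fc, group, alpha) {
  fc <- as.matrix(fc)
  g1 <- parse_group(group, nrow(fc))
  p <- unname(apply(fc, 2, ranksum_p, g1 = g1))
  feature_mask(p < alpha, alpha, "wilcoxon", p_min = p)
}

parse_group <- function(group, n) {
  if (is.logical(group)) g1 <- group
  else g1 <- group %in% c("AM", "case", "1", 1, TRUE)
  if (length(g1) != n) {
    stop_fcb("group labels do not match the FC panel rows",
             "fcbiotype_input_error")
  }
  if (sum(g1) == 0L || sum(!g1) == 0L) {
    stop_fcb("both groups must be non-empty", "fcbiotype_input_error")
  }
  g1
}

#' Union of two feature masks
#'
#' Elementwise OR of the selections; the union of the Spearman and Wilcoxon
#' screens is the feature set carried into cluster analysis.
#'
#' @param a,b [feature_mask()] objects over the same panel width.
#' @return a [feature_mask()] with provenance "union".
#' @export
union_mask <- function(a, b) {
  stopifnot(inherits(a, "feature_mask"), inherits(b, "feature_mask"))
  if (length(a$selected) != length(b$selected)) {
    stop_fcb("masks cover panels of different widths", "fcbiotype_input_error")
  }
  feature_mask(a$selected | b$selected, max(a$alpha, b$alpha), "union",
               p_min = pmin(if (is.null(a$p_min)) 1 else a$p_min,
                            if (is.null(b$p_min)) 1 else b$p_min))
}

#' Run both screens and take their union
#'
#' Convenience wrapper: Spearman screen against the clinical metrics plus
#' Wilcoxon AM-vs-control screen, united at a common threshold.
#'
#' @param fc training FC matrix.
#' @param subjects training subject tibble (needs `group` and the clinical
#'   metric columns).
#' @param alpha significance threshold.
#' @param population which subjects enter the Spearman screen: "all"
#'   (default; controls carry metric values too) or "am".
#' @return a [feature_mask()] with provenance "union".
#' @export
screen_features <- function(fc, subjects, alpha, population = c("all", "am")) {
  population <- match.arg(population)
  met_cols <- intersect(metric_names(), names(subjects))
  if (length(met_cols) == 0) {
    stop_fcb("no clinical metric columns found in `subjects`",
             "fcbiotype_input_error")
  }
  rows <- if (population == "am") subjects$group == "AM" else rep(TRUE, nrow(subjects))
  sp <- spearman_screen(fc[rows, , drop = FALSE],
                        subjects[rows, met_cols], alpha)
  wx <- wilcoxon_screen(fc, subjects$group, alpha)
  union_mask(sp, wx)
}
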