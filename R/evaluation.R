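#' Permutation test of a classification metric
#'
#' Recomputes `metric_fn` under `n_perm` random relabelings and reports the
#' add-one permutation p-value `(1 + #{null >= observed}) / (n_perm + 1)`,
#' which is never zero and attains its minimum `1 / (n_perm + 1)` when the
#' observed metric beats every null draw. Labels are permuted independently
#' within each stratum (e.g. discovery and replication sets), preserving
#' each stratum's case fraction.
#'
#' @param metric_fn function of a label vector returning a single number;
#'   it is called once with the observed labels and once per permutation.
#'   It must be deterministic given the labels.
#' @param labels observed label vector.
#' @param strata optional factor of the same length defining permutation
#'   blocks (default: one block).
#' @param n_perm number of permutations (default 200).
#' @param seed integer seed.
#' @return object of class `permutation_result` with fields `observed`,
#'   `null` (length `n_perm`), `p`, `n_perm`, `seed`.
#' @export
permutation_test <- function(metric_fn, labels, strata = NULL,
                             n_perm = 200, seed = 1L) {
  if (n_perm < 1) stop_fcb("n_perm must be >= 1", "fcbiotype_config_error")
  if (is.null(strata)) strata <- rep(1L, length(labels))
  stopifnot(length(strata) == length(labels))
  observed <- metric_fn(labels)
  idx_by_stratum <- split(seq_along(labels), strata)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    perm <- labels
    for (i in idx_by_stratum) perm[i] <- sample(labels[i])
    metric_fn(perm)
  }, numeric(1)))
  structure(list(observed = observed, null = null,
                 p = (1 + sum(null >= observed)) / (n_perm + 1),
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> observed = %.4f, p = %.4g (%d permutations)\n",
              x$observed, x$p, x$n_perm))
  invisible(x)
}

#' @method tidy permutation_result
#' @export
tidy.permutation_result <- function(x, ...) {
  tibble::tibble(observed = x$observed, p_value = x$p, n_perm = x$n_perm,
                 null_mean = mean(x$null), null_sd = sd(x$null))
}

#' Scan-2 consistency of the biotype scoring
#'
#' Applies a scan-1-trained biotype-aware classifier to the second-scan FC
#' panel of the clustered (training) subjects and computes, for each
#' retained biotype *b*, the one-vs-rest AUC of the biotype-*b* score among
#' retained AM subjects. The overall robustness summary is the
#' subject-count-weighted mean of the per-biotype AUCs.
#'
#' @param model a biotype-mode `fcb_classifier` trained on scan 1.
#' @param scan2_fc subjects x features scan-2 FC matrix (rownames = subject
#'   IDs), residualized with the scan-appropriate training model.
#' @param solution the `biotype_solution` whose retained labels define the
#'   one-vs-rest contrasts.
#' @return object of class `consistency_report`: tibble of per-biotype sizes
#'   and AUCs with attribute `weighted_auc`.
#' @export
scan2_consistency <- function(model, scan2_fc, solution) {
  stopifnot(inherits(model, "fcb_classifier"), model$mode == "biotype",
            inherits(solution, "biotype_solution"))
  lab <- retained_labels(solution)
  ids <- intersect(names(lab), rownames(scan2_fc))
  lab <- lab[ids]
  scores <- predict(model, scan2_fc[ids, , drop = FALSE])
  per <- purrr::map_dfr(sort(unique(lab)), function(b) {
    col <- sprintf("s_%d", b)
    if (!col %in% names(scores)) {
      rlang::warn(sprintf("biotype %d has no score head; excluded", b))
      return(tibble::tibble())
    }
    if (all(lab == b) || !any(lab == b)) {
      rlang::warn(sprintf("biotype %d absent from scan-2 contrast; excluded", b))
      return(tibble::tibble())
    }
    tibble::tibble(biotype = b, n = sum(lab == b),
                   auc = auc(scores[[col]], lab == b))
  })
  weighted <- sum(per$n * per$auc) / sum(per$n)
  structure(per, weighted_auc = weighted,
            class = c("consistency_report", class(per)))
}

#' Weighted AUC of a consistency report
#'
#' @param report a `consistency_report`.
#' @return the subject-count-weighted mean per-biotype AUC.
#' @export
weighted_auc <- function(report) attr(report, "weighted_auc")
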