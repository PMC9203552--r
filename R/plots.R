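#' Plot a biotyping solution in its embedding
#'
#' Scatter of the first two embedding dimensions colored by cluster label,
#' with omitted-cluster subjects greyed out.
#'
#' @param object a `biotype_solution` carrying its embedding (as produced by
#'   [solution_grid()]).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot biotype_solution
#' @export
autoplot.biotype_solution <- function(object, ...) {
  if (is.null(object$embedding)) {
    stop_fcb("solution carries no embedding to plot", "fcbiotype_input_error")
  }
  df <- tibble::tibble(
    dim1 = object$embedding[, 1], dim2 = object$embedding[, 2],
    cluster = ifelse(object$omitted, "omitted", as.character(object$labels)))
  ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2,
                                   color = .data$cluster)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_color_manual(
      values = c(setNames(scales_hue(length(unique(object$labels))),
                          sort(unique(as.character(object$labels)))),
                 omitted = "grey70")) +
    ggplot2::labs(x = "dimension 1", y = "dimension 2",
                  title = sprintf("Biotyping solution (k = %d, %s, VRC = %.1f)",
                                  object$k, object$method, object$vrc)) +
    ggplot2::theme_minimal()
}

scales_hue <- function(n) {
  grDevices::hcl(h = seq(15, 375, length.out = n + 1)[seq_len(n)],
                 l = 65, c = 100)
}

#' Per-frame censoring plot
#'
#' FD-style step plot of kept vs censored frames.
#'
#' @param object a `censor_mask`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot censor_mask
#' @export
autoplot.censor_mask <- function(object, ...) {
  df <- tibble::tibble(frame = object$frame,
                       status = ifelse(object$kept, "kept", "censored"))
  ggplot2::ggplot(df, ggplot2::aes(.data$frame, 1, fill = .data$status)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(kept = "steelblue",
                                          censored = "firebrick")) +
    ggplot2::labs(x = "frame", y = NULL,
                  title = sprintf("%d of %d frames kept",
                                  attr(object, "n_kept"), nrow(object))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Manhattan-style plot of an association scan
#'
#' -log10 p per SNP, colored by chromosome, with the LD-adjusted Bonferroni
#' threshold drawn when a blockset is supplied.
#'
#' @param object an `association_result` from [assoc_scan()].
#' @param blockset optional `ld_blockset` for the significance line.
#' @param alpha family-wise error target for the line (default 0.05).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot association_result
#' @export
autoplot.association_result <- function(object, blockset = NULL,
                                        alpha = 0.05, ...) {
  df <- tibble::tibble(index = seq_len(nrow(object)),
                       chrom = factor(object$chrom),
                       logp = -log10(object$p))
  g <- ggplot2::ggplot(df, ggplot2::aes(.data$index, .data$logp,
                                        color = .data$chrom)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "SNP index", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
  if (!is.null(blockset)) {
    thr <- alpha / attr(blockset, "m")
    g <- g + ggplot2::geom_hline(yintercept = -log10(thr),
                                 linetype = "dashed", color = "grey30")
  }
  g
}

#' Null-distribution plot of a permutation test
#'
#' Histogram of the permutation null with the observed value marked.
#'
#' @param object a `permutation_result`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot permutation_result
#' @export
autoplot.permutation_result <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(null = object$null),
                  ggplot2::aes(.data$null)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey60") +
    ggplot2::geom_vline(xintercept = object$observed, color = "firebrick") +
    ggplot2::labs(x = "null metric",
                  title = sprintf("observed = %.3f, p = %.3g",
                                  object$observed, object$p)) +
    ggplot2::theme_minimal()
}
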