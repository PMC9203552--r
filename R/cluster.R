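#' Reduce selected FC features to a low-dimensional embedding
#'
#' Maps the masked FC panel of AM training subjects into `d` dimensions with
#' a proximity-preserving reducer. The reducer is a pluggable contract: it
#' must be deterministic under the given seed and preserve between-subject
#' proximity so that planted groups separated in feature space remain
#' separated in the embedding. The built-in default is principal component
#' analysis (deterministic, with a fixed sign convention); any function
#' `f(x, d, seed)` returning an n x d matrix — e.g. a UMAP binding — may be
#' supplied instead and is recorded in the provenance.
#'
#' @param x subjects x selected-features numeric matrix (finite values).
#' @param d target dimension, one of 2, 3, 4.
#' @param seed integer seed recorded in (and, for stochastic reducers, used
#'   by) the reducer.
#' @param reducer "pca" or a function `f(x, d, seed)`.
#' @return n x d matrix of class `fcb_embedding` with a `provenance`
#'   attribute.
#' @export
reduce_embedding <- function(x, d, seed = 1L, reducer = "pca") {
  x <- as.matrix(x)
  if (!all(is.finite(x))) {
    stop_fcb("embedding input contains non-finite values",
             "fcbiotype_input_error")
  }
  if (!d %in% 2:4) {
    stop_fcb("`d` must be 2, 3 or 4", "fcbiotype_config_error")
  }
  if (nrow(x) < d + 1) {
    stop_fcb("need at least d + 1 subjects to embed", "fcbiotype_input_error")
  }
  if (ncol(x) < d) {
    stop_fcb("fewer selected features than embedding dimensions",
             "fcbiotype_input_error")
  }
  if (is.function(reducer)) {
    emb <- reducer(x, d, seed)
    reducer_name <- "custom"
  } else if (identical(reducer, "pca")) {
    pc <- prcomp(x, center = TRUE, scale. = FALSE, rank. = d)
    emb <- pc$x[, seq_len(d), drop = FALSE]
    # sign convention: largest-|loading| entry of each component positive
    for (j in seq_len(d)) {
      l <- pc$rotation[, j]
      if (l[which.max(abs(l))] < 0) emb[, j] <- -emb[, j]
    }
    reducer_name <- "pca"
  } else {
    stop_fcb("`reducer` must be \"pca\" or a function(x, d, seed)",
             "fcbiotype_config_error")
  }
  emb <- as.matrix(emb)
  rownames(emb) <- rownames(x)
  structure(emb, provenance = list(reducer = reducer_name, d = d, seed = seed),
            class = c("fcb_embedding", class(emb)))
}

#' Cluster an embedding
#'
#' K-means (10 restarts, best inertia kept) or Ward hierarchical clustering
#' cut at `k`. Fully deterministic under the seed. If the embedding has
#' fewer distinct points than `k`, duplicates collapse to the first-index
#' assignment rather than erroring.
#'
#' @param emb n x d embedding matrix.
#' @param k number of clusters (>= 2, <= n).
#' @param method "kmeans" or "hierarchical".
#' @param seed seed for the K-means restarts.
#' @param nstart number of K-means restarts.
#' @return integer vector of cluster labels in `1..k` (named when `emb` has
#'   rownames).
#' @export
cluster_embedding <- function(emb, k, method = c("kmeans", "hierarchical"),
                              seed = 1L, nstart = 10) {
  method <- match.arg(method)
  emb <- as.matrix(emb)
  n <- nrow(emb)
  if (k < 2) stop_fcb("`k` must be at least 2", "fcbiotype_config_error")
  if (k > n) stop_fcb("`k` exceeds the number of subjects",
                      "fcbiotype_input_error")
  keys <- apply(emb, 1, paste, collapse = "\r")
  if (length(unique(keys)) < k) {
    labels <- match(keys, unique(keys))   # degenerate: first-index assignment
  } else if (method == "kmeans") {
    fit <- with_seed(seed, kmeans(emb, centers = k, nstart = nstart,
                                  iter.max = 100))
    labels <- fit$cluster
  } else {
    labels <- cutree(hclust(dist(emb), method = "ward.D2"), k = k)
  }
  labels <- as.integer(labels)
  names(labels) <- rownames(emb)
  labels
}

#' Variance Ratio Criterion (Calinski-Harabasz statistic)
#'
#' Ratio of between-cluster to within-cluster dispersion, each normalized by
#' its degrees of freedom: `[tr(B)/(k-1)] / [tr(W)/(n-k)]`. Larger is better;
#' used to choose the number of clusters.
#'
#' @param emb n x d embedding matrix.
#' @param labels cluster labels (>= 2 non-empty clusters).
#' @return positive score; `Inf` (with a warning) when the within-cluster
#'   dispersion is exactly zero.
#' @export
vrc <- function(emb, labels) {
  emb <- as.matrix(emb)
  labels <- as.vector(labels)
  stopifnot(nrow(emb) == length(labels))
  cl <- unique(labels)
  k <- length(cl)
  n <- nrow(emb)
  if (k < 2) stop_fcb("VRC needs at least 2 clusters", "fcbiotype_input_error")
  grand <- colMeans(emb)
  b <- 0; w <- 0
  for (c_ in cl) {
    rows <- emb[labels == c_, , drop = FALSE]
    ctr <- colMeans(rows)
    b <- b + nrow(rows) * sum((ctr - grand)^2)
    w <- w + sum(sweep(rows, 2, ctr)^2)
  }
  if (w == 0) {
    rlang::warn("within-cluster dispersion is zero; VRC is infinite")
    return(Inf)
  }
  (b / (k - 1)) / (w / (n - k))
}

#' Choose the number of clusters by the Variance Ratio Criterion
#'
#' Clusters the embedding at each candidate `k` and returns the solution
#' with the largest VRC; ties go to the smaller `k`.
#'
#' @param emb n x d embedding matrix.
#' @param candidates candidate cluster counts (default 2:4).
#' @param method clustering method, see [cluster_embedding()].
#' @param seed seed for K-means restarts.
#' @return list with `k`, `labels`, and the per-candidate `scores`.
#' @export
select_k <- function(emb, candidates = 2:4, method = "kmeans", seed = 1L) {
  candidates <- sort(unique(as.integer(candidates)))
  fits <- lapply(candidates, function(k)
    cluster_embedding(emb, k, method = method, seed = seed))
  scores <- vapply(seq_along(candidates),
                   function(i) suppressWarnings(vrc(emb, fits[[i]])),
                   numeric(1))
  best <- which(scores == max(scores))[1L]   # ties -> smaller k (sorted)
  list(k = candidates[best], labels = fits[[best]],
       scores = setNames(scores, candidates))
}

new_biotype_solution <- function(labels, k, method, vrc_score, alpha, d, seed) {
  structure(list(labels = labels, k = k, method = method, vrc = vrc_score,
                 alpha = alpha, d = d, seed = seed,
                 omitted = setNames(rep(FALSE, length(labels)), names(labels)),
                 min_cluster_size = NA_integer_),
            class = "biotype_solution")
}

#' @export
print.biotype_solution <- function(x, ...) {
  cat(sprintf(
    "<biotype_solution> k = %d (%s, VRC = %.2f), alpha = %g, d = %d\n",
    x$k, x$method, x$vrc, x$alpha, x$d))
  tab <- table(ifelse(x$omitted, "omitted", x$labels))
  print(tab)
  invisible(x)
}

#' Retained biotype labels of a solution
#'
#' @param solution a `biotype_solution`.
#' @return named integer labels for non-omitted subjects.
#' @export
retained_labels <- function(solution) {
  solution$labels[!solution$omitted]
}

#' Enumerate the biotyping solution grid
#'
#' For every combination of feature-mask threshold and embedding dimension
#' (3 alphas x 3 dims = 9 cells by default) the masked AM-subject panel is
#' reduced, clustered with both K-means and Ward hierarchical clustering at
#' each candidate `k`, and the cell's solution is the (method, k) pair with
#' the best Variance Ratio Criterion. Downstream, the cell itself is chosen
#' by validation classification performance.
#'
#' @param fc_am AM-training-subjects x features FC matrix (rownames =
#'   subject IDs).
#' @param masks named list of [feature_mask()] objects (names = alpha values).
#' @param dims embedding dimensions to sweep (default `c(2, 3, 4)`).
#' @param k_candidates candidate cluster counts (default 2:4).
#' @param methods clustering methods searched within each cell.
#' @param seed seed shared by reducer and clustering.
#' @param reducer passed to [reduce_embedding()].
#' @return list of `biotype_solution` objects, one per non-empty grid cell;
#'   cells whose mask selects no feature are skipped with a warning.
#' @export
solution_grid <- function(fc_am, masks, dims = c(2, 3, 4),
                          k_candidates = 2:4,
                          methods = c("kmeans", "hierarchical"),
                          seed = 1L, reducer = "pca") {
  fc_am <- as.matrix(fc_am)
  out <- list()
  for (a in names(masks)) {
    mask <- masks[[a]]
    if (sum(mask$selected) == 0) {
      rlang::warn(sprintf("mask at alpha %s selects no features; cell skipped", a))
      next
    }
    x <- fc_am[, mask$selected, drop = FALSE]
    for (d in dims) {
      if (ncol(x) < d) {
        rlang::warn(sprintf(
          "mask at alpha %s selects %d features (< %d dims); cell skipped",
          a, ncol(x), d))
        next
      }
      emb <- reduce_embedding(x, d, seed = seed, reducer = reducer)
      best <- NULL
      for (m in methods) {
        sel <- select_k(emb, candidates = k_candidates, method = m, seed = seed)
        sc <- suppressWarnings(vrc(emb, sel$labels))
        if (is.null(best) || sc > best$vrc) {
          best <- new_biotype_solution(sel$labels, sel$k, m, sc,
                                       as.numeric(a), d, seed)
        }
      }
      best$embedding <- emb
      out[[sprintf("alpha%s_d%d", a, d)]] <- best
    }
  }
  out
}

#' Omit undersized clusters from a biotyping solution
#'
#' Clusters smaller than `min_cluster_size` are flagged omitted: their
#' subjects are excluded from biotype-level analyses (biotype loss terms,
#' per-biotype AUC, trait definitions) but remain AM cases for the overall
#' AM-vs-control classification.
#'
#' @param solution a `biotype_solution`.
#' @param min_cluster_size smallest retained cluster size (default 20).
#' @return the solution with its `omitted` flags set.
#' @export
omit_small_clusters <- function(solution, min_cluster_size = 20) {
  stopifnot(inherits(solution, "biotype_solution"))
  sizes <- table(solution$labels)
  small <- as.integer(names(sizes)[sizes < min_cluster_size])
  if (length(small) == length(sizes)) {
    stop_fcb("all clusters fall below min_cluster_size",
             "fcbiotype_input_error")
  }
  solution$omitted <- solution$labels %in% small
  names(solution$omitted) <- names(solution$labels)
  solution$min_cluster_size <- as.integer(min_cluster_size)
  solution
}
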