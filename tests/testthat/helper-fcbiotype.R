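# Small fixtures built in code, shared across test files.

# compact cohort for fast end-to-end tests
small_cohort <- function(seed = 1, n_roi = 20, effect_size = 1.2,
                         n_train = 120, n_validation = 40,
                         n_replication = 40, n_snps = 60,
                         n_signal_fc = 10, n_contrast_fc = 20, ...) {
  generate_cohort(cohort_config(
    n_train = n_train, n_validation = n_validation,
    n_replication = n_replication, n_roi = n_roi,
    n_signal_fc = n_signal_fc, n_contrast_fc = n_contrast_fc,
    effect_size = effect_size, n_snps = n_snps,
    mz_pairs = 4, dz_pairs = 4, seed = seed, ...))
}

# three well-separated Gaussian blobs in feature space
make_blobs <- function(n_per = 30, p = 12, sep = 6, k = 3, seed = 1) {
  withr::with_seed(seed, {
    centers <- matrix(rnorm(k * p), k, p)
    centers <- centers / sqrt(rowSums(centers^2)) * sep
    x <- do.call(rbind, lapply(seq_len(k), function(j)
      sweep(matrix(rnorm(n_per * p), n_per, p), 2, centers[j, ], "+")))
    rownames(x) <- sprintf("B%03d", seq_len(k * n_per))
    list(x = x, labels = rep(seq_len(k), each = n_per))
  })
}

# brute-force Spearman rho and t-approximation p for one pair
brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  n <- length(x)
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(tt), n - 2))
}

# brute-force AUC by pairwise concordance
brute_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (a in pos) for (b in neg) total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}

# brute-force Calinski-Harabasz with explicit double loops
brute_vrc <- function(emb, labels) {
  emb <- as.matrix(emb)
  grand <- colMeans(emb)
  k <- length(unique(labels)); n <- nrow(emb)
  b <- 0; w <- 0
  for (cl in unique(labels)) {
    rows <- which(labels == cl)
    ctr <- colMeans(emb[rows, , drop = FALSE])
    b <- b + length(rows) * sum((ctr - grand)^2)
    for (i in rows) w <- w + sum((emb[i, ] - ctr)^2)
  }
  (b / (k - 1)) / (w / (n - k))
}
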