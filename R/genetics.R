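#' Exact Hardy-Weinberg equilibrium test
#'
#' Levene-Haldane exact test: conditioning on the allele counts, the
#' probability of each possible heterozygote count is computed in closed
#' form and the p-value sums the probabilities of all configurations no more
#' likely than the observed one (two-sided by probability ordering).
#'
#' @param n_aa,n_ab,n_bb genotype counts (major homozygote, heterozygote,
#'   minor homozygote).
#' @param midp use the mid-p correction (half weight on the observed
#'   configuration). The plain exact p-value is conservative
#'   (super-uniform) as for any discrete test; mid-p is the standard remedy
#'   when calibration matters. QC thresholding uses the plain p-value.
#' @return exact p-value in (0, 1\].
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb, midp = FALSE) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_a <- 2 * n_aa + n_ab          # rarer allele folded below
  n_b <- 2 * n_bb + n_ab
  rare <- min(n_a, n_b)
  hets <- seq(rare %% 2, rare, by = 2)
  # log-probabilities of each heterozygote count given allele counts
  logp <- vapply(hets, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- (n_a + n_b - rare - h) / 2
    lgamma(n + 1) - lgamma(hom_r + 1) - lgamma(h + 1) - lgamma(hom_c + 1) +
      h * log(2) + lgamma(rare + 1) + lgamma(n_a + n_b - rare + 1) -
      lgamma(n_a + n_b + 1)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_ab, hets)]
  if (is.na(obs)) {
    stop_fcb("heterozygote count inconsistent with allele counts",
             "fcbiotype_input_error")
  }
  p <- sum(pr[pr <= obs * (1 + 1e-9)])
  if (midp) p <- p - obs / 2
  min(1, max(p, .Machine$double.xmin))
}

# HWE p from a dosage vector (0/1/2, NA allowed)
hwe_p_dosage <- function(dosage) {
  d <- dosage[!is.na(dosage)]
  hwe_exact_p(sum(d == 0), sum(d == 1), sum(d == 2))
}

#' Minor allele frequency
#'
#' Allele frequency of the counted allele over non-missing genotypes, folded
#' to at most 0.5.
#'
#' @param dosage vector of allele dosages in \{0, 1, 2, NA\}.
#' @param population_mask optional logical mask restricting to one
#'   population.
#' @return folded frequency in \[0, 0.5\].
#' @export
maf <- function(dosage, population_mask = NULL) {
  if (!is.null(population_mask)) dosage <- dosage[population_mask]
  d <- dosage[!is.na(dosage)]
  if (length(d) == 0) return(NA_real_)
  f <- sum(d) / (2 * length(d))
  min(f, 1 - f)
}

#' SNP quality control
#'
#' Retains a SNP when (1) its call rate is at least `call_rate_min`, (2) the
#' exact Hardy-Weinberg p-value in the full tested sample is at least
#' `hwe_min`, and (3) its minor allele frequency is at least `maf_min` in
#' every population present. Flags record which rule each SNP failed; the
#' three rules commute.
#'
#' @param dosage subjects x SNPs dosage matrix (0/1/2, NA = missing).
#' @param populations per-subject population labels.
#' @param call_rate_min,hwe_min,maf_min thresholds (defaults 0.95, 1e-7,
#'   0.05).
#' @return tibble of class `snp_qc_result` with one row per SNP: `snp`,
#'   `call_rate`, `hwe_p`, per-population MAF columns, the three pass flags
#'   and `retained`.
#' @export
snp_qc <- function(dosage, populations, call_rate_min = 0.95,
                   hwe_min = 1e-7, maf_min = 0.05) {
  dosage <- as.matrix(dosage)
  stopifnot(length(populations) == nrow(dosage))
  pops <- sort(unique(populations))
  call_rate <- colMeans(!is.na(dosage))
  hwe_p <- apply(dosage, 2, hwe_p_dosage)
  maf_by_pop <- sapply(pops, function(p)
    apply(dosage, 2, maf, population_mask = populations == p))
  maf_by_pop <- matrix(maf_by_pop, ncol = length(pops),
                       dimnames = list(NULL, paste0("maf_", pops)))
  pass_call <- call_rate >= call_rate_min
  pass_hwe <- hwe_p >= hwe_min
  pass_maf <- apply(maf_by_pop >= maf_min, 1, all)
  out <- tibble::tibble(
    snp = colnames(dosage) %||% sprintf("snp%04d", seq_len(ncol(dosage))),
    call_rate = call_rate, hwe_p = hwe_p)
  out <- dplyr::bind_cols(out, tibble::as_tibble(maf_by_pop))
  out$pass_call_rate <- pass_call
  out$pass_hwe <- pass_hwe
  out$pass_maf <- pass_maf
  out$retained <- pass_call & pass_hwe & pass_maf
  if (!any(out$retained)) {
    stop_fcb(sprintf(
      "all SNPs removed by QC (call rate: %d, HWE: %d, MAF: %d failures)",
      sum(!pass_call), sum(!pass_hwe), sum(!pass_maf)),
      "fcbiotype_input_error")
  }
  class(out) <- c("snp_qc_result", class(out))
  out
}

#' Genetic relationship matrix from standardized dosages
#'
#' `K = Z Z' / m` with `Z` the per-SNP standardized dosage matrix: missing
#' genotypes imputed to the SNP mean, columns centered at `2p` and scaled by
#' `sqrt(2 p (1 - p))` where `p` is the counted-allele frequency.
#' Monomorphic SNPs carry no information and are skipped with a warning.
#' The result is symmetric with diagonal near 1 for outbred subjects,
#' entries near 1 for monozygotic pairs and near 0.5 for dizygotic pairs.
#'
#' @param dosage subjects x SNPs dosage matrix.
#' @return subjects x subjects symmetric matrix.
#' @export
compute_grm <- function(dosage) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  if (m < 50) rlang::warn("fewer than 50 SNPs: GRM will be noisy")
  freq <- colMeans(dosage, na.rm = TRUE) / 2
  mono <- freq <= 0 | freq >= 1 | !is.finite(freq)
  if (any(mono)) {
    rlang::warn(sprintf("%d monomorphic SNP(s) skipped in GRM", sum(mono)))
  }
  keep <- which(!mono)
  Z <- dosage[, keep, drop = FALSE]
  for (j in seq_along(keep)) {
    z <- Z[, j]
    z[is.na(z)] <- 2 * freq[keep[j]]
    Z[, j] <- (z - 2 * freq[keep[j]]) /
      sqrt(2 * freq[keep[j]] * (1 - freq[keep[j]]))
  }
  K <- tcrossprod(Z) / length(keep)
  (K + t(K)) / 2
}

## ---- linear mixed model (GEMMA-style eigendecomposition + REML) ----

# negative restricted log-likelihood profile in lambda = sigma_g^2 / sigma_e^2,
# in the rotated basis (d = GRM eigenvalues)
reml_profile <- function(lambda, d, ystar, Xstar) {
  v <- lambda * d + 1
  A <- crossprod(Xstar / v, Xstar)
  b <- crossprod(Xstar, ystar / v)
  beta <- solve(A, b)
  resid <- ystar - Xstar %*% beta
  rss <- sum(resid^2 / v)
  nc <- length(ystar) - ncol(Xstar)
  sigma_e2 <- rss / nc
  ll <- -0.5 * (nc * log(sigma_e2) + sum(log(v)) +
                  as.numeric(determinant(A, logarithm = TRUE)$modulus))
  list(ll = ll, beta = beta, sigma_e2 = sigma_e2, A = A)
}

#' Eigendecomposition of a GRM for reuse across SNP tests
#'
#' @param K symmetric GRM.
#' @return object of class `grm_eigen` with `values`, `vectors`.
#' @export
grm_eigen <- function(K) {
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  structure(list(values = pmax(e$values, 0), vectors = e$vectors,
                 n = nrow(K)), class = "grm_eigen")
}

#' Linear mixed-model Wald test of one SNP
#'
#' Fits `y = W a + x b + u + e` with `u ~ N(0, sg^2 K)` and
#' `e ~ N(0, se^2 I)` by profiling the variance ratio `lambda = sg^2/se^2`
#' under REML in the eigenbasis of `K` (one decomposition, reusable across
#' SNPs), then reports the Wald test of `b = 0` against chi-square with 1
#' degree of freedom. With `K = I` the fit reduces exactly to ordinary
#' least squares.
#'
#' @param trait per-subject quantitative trait.
#' @param snp_dosage per-subject dosage for the tested SNP (missing imputed
#'   to the mean).
#' @param covariates data frame of covariates (e.g. age, sex, race); factors
#'   and characters are expanded to reference-coded indicators. An intercept
#'   is always included.
#' @param K GRM matrix or a precomputed [grm_eigen()].
#' @param lambda_range log10 search interval for the variance ratio.
#' @return list with `beta`, `se`, `p`, `lambda`, `sigma_e2`.
#' @export
lmm_wald <- function(trait, snp_dosage, covariates, K,
                     lambda_range = c(-5, 5)) {
  y <- as.numeric(trait)
  x <- as.numeric(snp_dosage)
  x[is.na(x)] <- mean(x, na.rm = TRUE)
  n <- length(y)
  W <- covariate_design(covariates, n)
  X <- cbind(W, snp = x)
  if (qr(X)$rank < ncol(X)) {
    cc <- suppressWarnings(cor(X[, -1, drop = FALSE]))
    bad <- unique(unlist(apply(abs(cc) > 1 - 1e-10 & upper.tri(cc), 2,
                               function(col) rownames(cc)[col])))
    stop_fcb(paste0("covariate matrix is singular; collinear columns: ",
                    paste(c(bad, recursive = TRUE), collapse = ", ")),
             "fcbiotype_input_error")
  }
  if (n < ncol(X) + 1) {
    stop_fcb("not enough subjects for the covariate model",
             "fcbiotype_input_error")
  }
  ek <- if (inherits(K, "grm_eigen")) K else grm_eigen(K)
  ystar <- crossprod(ek$vectors, y)
  Xstar <- crossprod(ek$vectors, X)
  d <- ek$values
  obj <- function(log10l) reml_profile(10^log10l, d, ystar, Xstar)$ll
  # coarse grid then golden-section refinement; compare with the lambda -> 0
  # boundary (no genetic variance)
  grid <- seq(lambda_range[1], lambda_range[2], length.out = 21)
  ll_grid <- vapply(grid, obj, numeric(1))
  i0 <- which.max(ll_grid)
  lo <- grid[max(1, i0 - 1)]; hi <- grid[min(length(grid), i0 + 1)]
  opt <- optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-6)
  lam <- 10^opt$maximum
  fit <- reml_profile(lam, d, ystar, Xstar)
  fit0 <- reml_profile(1e-12, d, ystar, Xstar)
  if (fit0$ll >= fit$ll) { lam <- 0; fit <- fit0 }
  Ainv <- solve(fit$A)
  beta <- fit$beta[ncol(X)]
  se <- sqrt(fit$sigma_e2 * Ainv[ncol(X), ncol(X)])
  list(beta = unname(beta), se = unname(se),
       p = pchisq((beta / se)^2, df = 1, lower.tail = FALSE),
       lambda = lam, sigma_e2 = fit$sigma_e2)
}

covariate_design <- function(covariates, n) {
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != n) {
    stop_fcb("covariate rows do not match the trait length",
             "fcbiotype_input_error")
  }
  mm <- stats::model.matrix(~ ., data = covariates)
  mm
}

#' Mixed-model association scan over a SNP panel
#'
#' Runs [lmm_wald()] for every SNP against one quantitative trait (a
#' classifier biotype score, the AM score, or any per-subject trait), using
#' a single eigendecomposition of the GRM, and returns a tidy association
#' table.
#'
#' @param trait per-subject quantitative trait values.
#' @param dosage subjects x SNPs dosage matrix.
#' @param covariates covariate data frame (see [lmm_wald()]).
#' @param K GRM or [grm_eigen()].
#' @param snp_info optional tibble (id, chrom, pos) aligned with dosage
#'   columns.
#' @return tibble of class `association_result`: `snp`, `chrom`, `pos`,
#'   `maf`, `beta`, `se`, `p`.
#' @export
assoc_scan <- function(trait, dosage, covariates, K, snp_info = NULL) {
  dosage <- as.matrix(dosage)
  ek <- if (inherits(K, "grm_eigen")) K else grm_eigen(K)
  res <- purrr::map_dfr(seq_len(ncol(dosage)), function(j) {
    f <- lmm_wald(trait, dosage[, j], covariates, ek)
    tibble::tibble(beta = f$beta, se = f$se, p = f$p, lambda = f$lambda)
  })
  out <- tibble::tibble(
    snp = if (!is.null(snp_info)) snp_info$id else
      colnames(dosage) %||% sprintf("snp%04d", seq_len(ncol(dosage))),
    chrom = if (!is.null(snp_info)) snp_info$chrom else 1L,
    pos = if (!is.null(snp_info)) snp_info$pos else seq_len(ncol(dosage)),
    maf = apply(dosage, 2, maf))
  out <- dplyr::bind_cols(out, res)
  class(out) <- c("association_result", class(out))
  out
}

#' Greedy LD blocks and the independent-SNP count
#'
#' Within each chromosome, SNPs are scanned in positional order: a SNP joins
#' the current block while its squared dosage correlation with the block's
#' seed SNP is at least `r2_threshold` and it lies within `window` SNPs of
#' the seed; otherwise it starts a new block. The independent test count `m`
#' is the number of blocks (multi-SNP blocks count once; singletons count
#' individually), the denominator of the LD-adjusted Bonferroni threshold.
#'
#' @param dosage subjects x SNPs dosage matrix.
#' @param chrom per-SNP chromosome labels (default: one chromosome).
#' @param r2_threshold squared-correlation threshold (default 0.5).
#' @param window maximum index distance from the block seed (default 50).
#' @return tibble of class `ld_blockset` (chrom, start_index, end_index,
#'   size) with attribute `m`.
#' @export
ld_blocks <- function(dosage, chrom = NULL, r2_threshold = 0.5, window = 50) {
  dosage <- as.matrix(dosage)
  p <- ncol(dosage)
  if (is.null(chrom)) chrom <- rep(1L, p)
  stopifnot(length(chrom) == p)
  blocks <- list()
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    seed <- idx[1]
    start <- idx[1]
    last <- idx[1]
    for (j in idx[-1]) {
      r2 <- suppressWarnings(
        cor(dosage[, seed], dosage[, j], use = "pairwise.complete.obs"))^2
      joins <- !is.na(r2) && r2 >= r2_threshold && (j - seed) <= window
      if (joins) {
        last <- j
      } else {
        blocks[[length(blocks) + 1]] <- c(ch, start, last)
        seed <- j; start <- j; last <- j
      }
    }
    blocks[[length(blocks) + 1]] <- c(ch, start, last)
  }
  out <- tibble::tibble(
    chrom = vapply(blocks, `[`, numeric(1), 1),
    start_index = vapply(blocks, `[`, numeric(1), 2),
    end_index = vapply(blocks, `[`, numeric(1), 3))
  out$size <- out$end_index - out$start_index + 1
  structure(out, m = nrow(out), class = c("ld_blockset", class(out)))
}

#' LD-adjusted Bonferroni significance
#'
#' A SNP is significant when its p-value falls below `alpha / m`, with `m`
#' the independent-SNP count of the [ld_blocks()] set — less conservative
#' than correcting for every (correlated) SNP.
#'
#' @param pvals per-SNP p-values.
#' @param blockset an `ld_blockset` (or a plain integer `m`).
#' @param alpha family-wise error target (default 0.05).
#' @return logical vector marking significant SNPs; attribute `threshold`.
#' @export
ld_adjusted_bonferroni <- function(pvals, blockset, alpha = 0.05) {
  m <- if (inherits(blockset, "ld_blockset")) attr(blockset, "m")
       else as.integer(blockset)
  thr <- alpha / m
  structure(pvals < thr, threshold = thr, m = m)
}
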