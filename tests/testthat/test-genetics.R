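test_that("the exact HWE test matches an allele-permutation oracle", {
  # equilibrium counts keep a high p-value
  expect_gte(hwe_exact_p(25, 50, 25), 0.5)
  # tiny case: compare against Monte-Carlo pairing of the allele multiset
  counts <- c(aa = 4, ab = 2, bb = 3)
  n <- sum(counts)
  alleles <- rep(0:1, c(2 * counts[1] + counts[2], 2 * counts[3] + counts[2]))
  hets <- withr::with_seed(1, vapply(1:20000, function(i) {
    g <- matrix(sample(alleles), ncol = 2)
    sum(rowSums(g) == 1)
  }, numeric(1)))
  # exact p = probability of configurations no more likely than observed
  tab <- table(hets) / length(hets)
  obs_pr <- tab[["2"]]
  mc_p <- sum(tab[tab <= obs_pr * (1 + 1e-9)])
  expect_lt(abs(hwe_exact_p(4, 2, 3) - mc_p), 0.02)
  # enumeration probabilities sum to one: p of the likeliest config is 1
  # when every configuration is no more likely
  expect_lte(hwe_exact_p(4, 2, 3), 1)
  expect_gt(hwe_exact_p(4, 2, 3), 0)
  # strong heterozygote excess is detected
  expect_lt(hwe_exact_p(0, 100, 0), 1e-7)
  # mid-p is smaller but stays positive
  expect_lt(hwe_exact_p(4, 2, 3, midp = TRUE), hwe_exact_p(4, 2, 3))
  expect_gt(hwe_exact_p(4, 2, 3, midp = TRUE), 0)
})

test_that("minor allele frequencies fold to at most one half", {
  expect_equal(maf(rep(0, 50)), 0)
  expect_equal(maf(rep(c(0, 1, 2), c(30, 40, 30))), 0.5)
  expect_equal(maf(rep(c(0, 1, 2), c(9, 42, 49))), 0.3)   # raw 0.7 folded
  expect_equal(maf(c(0, 1, NA, 2), population_mask = c(TRUE, TRUE, TRUE, FALSE)),
               0.25)
  expect_true(is.na(maf(c(NA_integer_, NA_integer_))))
})

test_that("SNP QC applies the three rules and records failures", {
  withr::with_seed(2, {
    n <- 100
    pops <- rep(c("EA", "AA"), c(60, 40))
    good <- rbinom(n, 2, 0.3)
    low_call <- good; low_call[sample(n, 10)] <- NA       # call rate 0.90
    hwe_bad <- rep(1L, n)                                  # all heterozygous
    rare <- c(rbinom(60, 2, 0.033), rbinom(40, 2, 0.3))
    rare[1:60] <- 0; rare[1:2] <- 1                        # EA MAF 2/120 < 5%
    dosage <- cbind(good = good, low_call = low_call,
                    hwe_bad = hwe_bad, rare = rare)
  })
  qc <- snp_qc(dosage, pops)
  expect_true(qc$retained[qc$snp == "good"])
  expect_false(qc$retained[qc$snp == "low_call"])
  expect_false(qc$pass_call_rate[qc$snp == "low_call"])
  expect_false(qc$retained[qc$snp == "hwe_bad"])
  expect_false(qc$pass_hwe[qc$snp == "hwe_bad"])
  expect_false(qc$retained[qc$snp == "rare"])
  expect_false(qc$pass_maf[qc$snp == "rare"])
  expect_gte(qc$hwe_p[qc$snp == "good"], 1e-7)
  # rule order cannot matter: flags are computed independently
  expect_identical(qc$retained,
                   qc$pass_call_rate & qc$pass_hwe & qc$pass_maf)
  expect_error(snp_qc(cbind(hwe_bad = rep(1L, n)), pops),
               class = "fcbiotype_input_error")
})

test_that("the GRM reflects planted twin relatedness", {
  co <- small_cohort(seed = 4, n_snps = 500)
  expect_warning(K <- compute_grm(co$genotypes$dosage), NA)
  expect_equal(K, t(K))
  ids <- rownames(co$genotypes$dosage)
  kin <- co$truth$kinship_pairs
  for (i in seq_len(nrow(kin))) {
    a <- match(kin$subject_a[i], ids); b <- match(kin$subject_b[i], ids)
    if (kin$zygosity[i] == "MZ") {
      expect_lt(abs(K[a, b] - K[a, a]), 0.1)
    } else {
      expect_lt(abs(K[a, b] - 0.5), 0.2)
    }
  }
})

test_that("the GRM of unrelated subjects concentrates near zero off-diagonal", {
  withr::with_seed(5, {
    dosage <- sapply(runif(5000, 0.1, 0.5), function(p) rbinom(60, 2, p))
  })
  K <- compute_grm(dosage)
  off <- abs(K[upper.tri(K)])
  expect_lt(quantile(off, 0.95), 0.1)
  expect_lt(abs(mean(diag(K)) - 1), 0.1)
  # duplicating a subject reproduces its diagonal entry off-diagonal
  dup <- rbind(dosage, dosage[1, ])
  K2 <- compute_grm(dup)
  expect_equal(K2[1, 61], K2[1, 1])
  # allele-label flips leave the standardized GRM unchanged
  flipped <- dosage; flipped[, 1:2500] <- 2 - flipped[, 1:2500]
  expect_equal(compute_grm(flipped), K, tolerance = 1e-12)
  expect_warning(
    expect_warning(
      compute_grm(cbind(rep(0, 60), rbinom(60, 2, .3), rbinom(60, 2, .3))),
      "monomorphic"),
    "fewer than 50")
})

test_that("the mixed model reduces exactly to OLS at K = identity", {
  withr::with_seed(6, {
    n <- 120
    x <- rbinom(n, 2, 0.3)
    cov <- data.frame(age = runif(n, 22, 35), sex = rbinom(n, 1, 0.5),
                      race = sample(c("EA", "AA", "OTH"), n, replace = TRUE))
    y <- 0.4 * x + 0.05 * cov$age + 0.3 * (cov$race == "AA") + rnorm(n)
  })
  f <- lmm_wald(y, x, cov, diag(n))
  ols <- lm(y ~ age + sex + race + x, data = cbind(cov, x = x, y = y))
  est <- summary(ols)$coefficients["x", ]
  expect_lt(abs(f$beta - est["Estimate"]) / abs(est["Estimate"]), 1e-6)
  expect_lt(abs(f$se - est["Std. Error"]) / est["Std. Error"], 1e-6)
  p_ols <- pchisq((est["Estimate"] / est["Std. Error"])^2, 1,
                  lower.tail = FALSE)
  expect_lt(abs(f$p - p_ols) / p_ols, 1e-6)
})

test_that("the REML profile agrees with a direct full-matrix computation", {
  withr::with_seed(7, {
    n <- 30
    Z <- matrix(rbinom(n * 80, 2, 0.3), n)
    K <- compute_grm(Z)
    u <- as.vector(chol(K + diag(n) * 0.01) %*% rnorm(n)) # polygenic signal
    x <- rbinom(n, 2, 0.4)
    W <- cbind(1, runif(n))
    y <- 0.5 * x + W[, 2] + u + rnorm(n)
  })
  ek <- grm_eigen(K)
  ystar <- crossprod(ek$vectors, y)
  Xstar <- crossprod(ek$vectors, cbind(W, x))
  direct_ll <- function(lam) {
    V <- lam * K + diag(n)
    Vi <- solve(V)
    X <- cbind(W, x)
    A <- t(X) %*% Vi %*% X
    beta <- solve(A, t(X) %*% Vi %*% y)
    rss <- as.numeric(t(y - X %*% beta) %*% Vi %*% (y - X %*% beta))
    s2 <- rss / (n - ncol(X))
    -0.5 * ((n - ncol(X)) * log(s2) +
              as.numeric(determinant(V, TRUE)$modulus) +
              as.numeric(determinant(A, TRUE)$modulus))
  }
  for (lam in c(0.1, 1, 5)) {
    got <- fcbiotype:::reml_profile(lam, ek$values, ystar, Xstar)$ll
    expect_equal(got, direct_ll(lam), tolerance = 1e-6)
  }
  f <- lmm_wald(y, x, data.frame(w = W[, 2]), K)
  expect_true(is.finite(f$p) && f$p > 0 && f$p <= 1)
  expect_gt(f$se, 0)
})

test_that("collinear covariates raise a named error", {
  withr::with_seed(8, {
    n <- 50
    cov <- data.frame(age = runif(n, 22, 35))
    cov$age_copy <- cov$age
    y <- rnorm(n)
  })
  expect_error(lmm_wald(y, rbinom(n, 2, .3), cov, diag(n)),
               "collinear", class = "fcbiotype_input_error")
})

test_that("the mixed-model Wald test holds its level under the null", {
  withr::with_seed(9, {
    n <- 300
    dosage <- matrix(rbinom(n * 500, 2, 0.3), n)
    K <- compute_grm(dosage)
    y <- rnorm(n)
    cov <- data.frame(age = runif(n, 22, 35), sex = rbinom(n, 1, .5))
  })
  ek <- grm_eigen(K)
  ps <- vapply(1:500, function(j) lmm_wald(y, dosage[, j], cov, ek)$p,
               numeric(1))
  rate <- mean(ps < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("LD blocks are deterministic, within-chromosome, and count m", {
  withr::with_seed(10, {
    base <- rbinom(80, 2, 0.4)
    copies <- matrix(rep(base, 10), ncol = 10)   # perfect LD
    indep <- matrix(rbinom(80 * 30, 2, 0.4), 80, 30)
  })
  dosage <- cbind(copies, indep)
  chrom <- rep(c(1, 2), c(20, 20))
  bl <- ld_blocks(dosage, chrom)
  expect_identical(attr(bl, "m"), nrow(bl))
  # the 10 copies fold into a single block contributing 1
  first <- bl[bl$chrom == 1 & bl$start_index == 1, ]
  expect_identical(first$end_index, 10)
  # no block crosses the chromosome boundary
  expect_true(all(bl$start_index[bl$chrom == 2] >= 21))
  # simulated linkage equilibrium: m close to the SNP count
  bl2 <- ld_blocks(indep)
  expect_gte(attr(bl2, "m"), 0.95 * 30)
})

test_that("LD-adjusted Bonferroni thresholds at alpha over m", {
  p <- c(3.52e-5, 0.001, 0.2)
  expect_identical(as.logical(ld_adjusted_bonferroni(p, 1L)), p < 0.05)
  sig <- ld_adjusted_bonferroni(p, 1420L)
  expect_true(sig[1])        # 3.52e-5 < 0.05 / 1420
  expect_false(any(ld_adjusted_bonferroni(c(0.2, 0.8), 10L)))
  expect_equal(attr(sig, "threshold"), 0.05 / 1420)
})

test_that("the association scan is tidy and flags the planted SNP", {
  co <- small_cohort(seed = 12, n_snps = 120, n_train = 200)
  subj <- co$subjects
  disc <- subj$split != "replication"
  dos <- co$genotypes$dosage[disc, ]
  K <- compute_grm(dos)
  res <- assoc_scan(co$truth$trait[subj$subject_id[disc]], dos,
                    subj[disc, c("age", "sex", "race")], K,
                    snp_info = co$genotypes$snp_info)
  expect_s3_class(res, "association_result")
  expect_identical(nrow(res), 120L)
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_true(all(res$se > 0))
  expect_identical(which.min(res$p), co$truth$causal_snp_index)
})
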