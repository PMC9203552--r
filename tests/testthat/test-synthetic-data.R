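test_that("identical configurations reproduce the cohort byte for byte", {
  a <- small_cohort(seed = 7)
  b <- small_cohort(seed = 7)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c <- small_cohort(seed = 8)
  expect_false(identical(a$fc_scan1, c$fc_scan1))
})

test_that("the 268-ROI atlas yields a 35,778-column FC panel", {
  expect_identical(n_fc_features(268), 35778L)
  cfg <- cohort_config(n_train = 12, n_validation = 4, n_replication = 4,
                       n_roi = 268, n_snps = 10, mz_pairs = 1, dz_pairs = 1,
                       seed = 1)
  co <- generate_cohort(cfg)
  expect_identical(ncol(co$fc_scan1), 35778L)
  expect_identical(ncol(co$fc_scan2), 35778L)
})

test_that("cohort structure honors its configuration", {
  co <- small_cohort(seed = 3)
  subj <- co$subjects
  expect_identical(table(subj$split)[["train"]], 120L)
  # biotype labels only on AM subjects, indices within panel bounds
  expect_true(all(names(co$truth$biotype) %in%
                    subj$subject_id[subj$group == "AM"]))
  expect_true(all(unlist(co$truth$signal_fc_indices) <= ncol(co$fc_scan1)))
  expect_true(all(co$truth$contrast_fc_indices <= ncol(co$fc_scan1)))
  # disjoint per-biotype signal sets
  all_idx <- unlist(co$truth$signal_fc_indices)
  expect_identical(anyDuplicated(all_idx), 0L)
  expect_length(intersect(all_idx, co$truth$contrast_fc_indices), 0)
  # FC values inside the open correlation interval
  expect_true(all(abs(co$fc_scan1) < 1))
  # AM prevalence close to the configured fraction in each split
  for (s in unique(subj$split)) {
    frac <- mean(subj$group[subj$split == s] == "AM")
    expect_lt(abs(frac - 0.33), 0.05)
  }
})

test_that("oversized signal sets are rejected as configuration errors", {
  expect_error(cohort_config(n_roi = 5, n_signal_fc = 4, n_biotypes = 3,
                             n_contrast_fc = 0),
               class = "fcbiotype_config_error")
  expect_error(cohort_config(am_fraction = 1),
               class = "fcbiotype_config_error")
})

test_that("a null FC effect leaves AM indistinguishable from controls", {
  hits <- vapply(1:20, function(s) {
    co <- generate_cohort(cohort_config(
      n_train = 150, n_validation = 10, n_replication = 10, n_roi = 12,
      n_signal_fc = 8, n_contrast_fc = 10, effect_size = 0,
      n_snps = 10, mz_pairs = 0, dz_pairs = 0, seed = s))
    tr <- co$subjects$split == "train"
    am <- co$subjects$group[tr] == "AM"
    pooled1 <- rowMeans(co$fc_scan1[tr, unlist(co$truth$signal_fc_indices),
                                    drop = FALSE])
    t.test(pooled1[am], pooled1[!am])$p.value < 0.05
  }, logical(1))
  expect_gte(mean(!hits), 0.9)
})

test_that("a null genetic effect recovers a slope near zero", {
  ok <- vapply(1:20, function(s) {
    co <- generate_cohort(cohort_config(
      n_train = 200, n_validation = 10, n_replication = 10, n_roi = 12,
      n_signal_fc = 5, n_contrast_fc = 5, causal_beta = 0,
      n_snps = 20, mz_pairs = 0, dz_pairs = 0, seed = s))
    y <- co$truth$trait
    x <- co$genotypes$dosage[, co$truth$causal_snp_index]
    f <- summary(lm(y ~ x))$coefficients["x", ]
    abs(f["Estimate"]) < 2 * f["Std. Error"]
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("genotypes conform to Hardy-Weinberg equilibrium", {
  cfg <- cohort_config(n_train = 520, n_validation = 40, n_replication = 40,
                       n_roi = 20, n_snps = 201, mz_pairs = 0, dz_pairs = 0,
                       seed = 1)
  co <- generate_cohort(cfg)
  dos <- co$genotypes$dosage
  snps <- setdiff(seq_len(ncol(dos)), co$truth$causal_snp_index)[1:200]
  ps <- apply(dos[, snps], 2, function(d)
    hwe_exact_p(sum(d == 0), sum(d == 1), sum(d == 2), midp = TRUE))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("twin genotype sharing matches zygosity", {
  co <- small_cohort(seed = 5, n_snps = 400)
  dos <- co$genotypes$dosage
  kin <- co$truth$kinship_pairs
  share <- function(a, b) mean(dos[a, ] == dos[b, ])
  mz <- kin[kin$zygosity == "MZ", ]
  dz <- kin[kin$zygosity == "DZ", ]
  expect_true(all(mapply(share, mz$subject_a, mz$subject_b) == 1))
  dz_share <- mapply(share, dz$subject_a, dz$subject_b)
  expect_true(all(dz_share > 0.5 & dz_share < 1))
})

test_that("clinical metrics follow the planted biotype ordering", {
  # drinking frequency: biotype 3 > biotype 1 > biotype 2;
  # antisocial score elevated in biotype 2 (averaged over seeds)
  stats <- sapply(1:5, function(s) {
    co <- small_cohort(seed = s, n_train = 250)
    subj <- co$subjects
    b <- co$truth$biotype[subj$subject_id]
    freq <- rowMeans(subj[, c("freq_any_12m", "freq_any_hvy")])
    anti <- subj$asr_antisocial
    c(f3 = mean(freq[b %in% 3], na.rm = TRUE),
      f1 = mean(freq[b %in% 1], na.rm = TRUE),
      f2 = mean(freq[b %in% 2], na.rm = TRUE),
      a2 = mean(anti[b %in% 2], na.rm = TRUE),
      a13 = mean(anti[b %in% c(1, 3)], na.rm = TRUE),
      actl = mean(anti[is.na(b)], na.rm = TRUE))
  })
  m <- rowMeans(stats)
  expect_gt(m["f3"], m["f1"])
  expect_gt(m["f1"], m["f2"])
  expect_gt(m["a2"], m["a13"])
  expect_gt(m["a2"], m["actl"])
  # alcohol metrics on the normalized 0-5 severity scale
  co <- small_cohort(seed = 2)
  am_cols <- metric_names()[1:10]
  expect_true(all(as.matrix(co$subjects[, am_cols]) >= 0 &
                    as.matrix(co$subjects[, am_cols]) <= 5))
})

test_that("clinical metrics rank-correlate with planted signal features", {
  co <- small_cohort(seed = 9, n_train = 250, effect_size = 1.5)
  subj <- co$subjects
  tr <- subj$split == "train"
  b1 <- names(co$truth$biotype)[co$truth$biotype == 1]
  b1 <- intersect(b1, subj$subject_id[tr])
  idx <- co$truth$signal_fc_indices[[1]]
  sgn <- co$truth$signal_signs[[1]]
  pooled <- co$fc_scan1[b1, idx, drop = FALSE] %*% sgn
  sev <- co$truth$latent_own[b1]
  expect_gt(cor(pooled, sev, method = "spearman"), 0.3)
})

test_that("planted motion outliers cross the FD threshold exactly where placed", {
  mb <- generate_motion_and_bold(300, outlier_times = c(40, 41, 200), seed = 2)
  fd <- framewise_displacement(mb$motion)
  dv <- dvars(mb$bold)
  expect_identical(which(fd > 0.2), c(40L, 41L, 200L))
  expect_identical(which(dv > 75), c(40L, 41L, 200L))
  # clean trace keeps every frame through the censor pipeline
  clean <- generate_motion_and_bold(300, outlier_times = integer(), seed = 2)
  mask <- censor_frames(framewise_displacement(clean$motion),
                        dvars(clean$bold))
  expect_identical(attr(mask, "n_kept"), 300L)
  expect_error(generate_motion_and_bold(100, outlier_times = 150),
               class = "fcbiotype_input_error")
})

test_that("a 1200-frame run at TR 0.72 s spans 14.4 minutes", {
  mb <- generate_motion_and_bold(1200, seed = 1)
  expect_equal(nrow(mb$bold$data) * mb$bold$tr / 60, 14.4)
  expect_identical(attr(mb$motion, "tr"), 0.72)
})
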