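#' Configuration for a synthetic alcohol-misuse cohort
#'
#' Defines the study conditions a simulated cohort is drawn under: split
#' sizes, prevalence of alcohol misuse (AM), the FC panel geometry, the
#' planted biotype structure, and the genetic architecture. Defaults follow
#' the study design the pipeline targets: roughly one third of subjects meet
#' at least one AUD criterion, three planted biotypes with disjoint FC
#' signatures, twin pairs giving known kinship, and one causal SNP whose
#' minor allele raises the causal biotype's latent severity.
#'
#' @param n_train,n_validation,n_replication split sizes. The training split
#'   is used for feature screening, clustering and classifier fitting; the
#'   validation split for model selection and thresholding; the replication
#'   split is held out entirely.
#' @param am_fraction proportion of AM subjects in each split, in (0, 1).
#' @param n_roi number of ROIs; the FC panel has `n_roi * (n_roi - 1) / 2`
#'   columns (268 ROIs give 35,778 features).
#' @param n_biotypes number of planted AM biotypes.
#' @param n_signal_fc number of signal FC features *per biotype*; each
#'   biotype shifts its own disjoint feature set.
#' @param n_contrast_fc number of shared contrast FC features on which two
#'   biotypes deviate in opposite directions (one up, one down, controls in
#'   between) -- the opposite-signed connectivity effects that make pooled
#'   case-control contrasts cancel while biotypes stay separable.
#' @param effect_size standardized mean shift (in units of the FC noise SD on
#'   the Fisher-z scale) of a biotype's signal and contrast features
#'   relative to controls.
#' @param n_snps number of biallelic SNPs simulated.
#' @param causal_maf minor allele frequency of the causal SNP, in \[0.05, 0.5\].
#' @param causal_beta trait units added per minor allele to the causal
#'   biotype's latent severity trait.
#' @param causal_biotype which biotype's trait the causal SNP acts on.
#' @param mz_pairs,dz_pairs numbers of monozygotic / dizygotic twin pairs.
#' @param fc_noise_sd FC noise SD on the Fisher-z scale.
#' @param scan2_noise_sd SD of the independent Fisher-z noise added to scan-1
#'   FC to produce the second-scan panel.
#' @param seed integer seed; identical configurations reproduce the cohort
#'   bit for bit.
#' @return an object of class `cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_train = 300, n_validation = 80, n_replication = 120,
                          am_fraction = 0.33,
                          n_roi = 268, n_biotypes = 3, n_signal_fc = 20,
                          n_contrast_fc = 60, effect_size = 0.8,
                          n_snps = 500, causal_maf = 0.3, causal_beta = 0.5,
                          causal_biotype = 2L,
                          mz_pairs = 10, dz_pairs = 10,
                          fc_noise_sd = 0.3, scan2_noise_sd = 0.15,
                          seed = 1L) {
  check_number(n_train, "n_train", 10)
  check_number(n_validation, "n_validation", 4)
  check_number(n_replication, "n_replication", 4)
  check_number(n_roi, "n_roi", 3)
  check_number(n_biotypes, "n_biotypes", 1)
  check_number(n_signal_fc, "n_signal_fc", 1)
  check_number(n_contrast_fc, "n_contrast_fc", 0)
  check_number(effect_size, "effect_size", 0)
  check_number(n_snps, "n_snps", 2)
  check_number(causal_maf, "causal_maf", 0.05, 0.5)
  check_number(causal_beta, "causal_beta")
  check_number(fc_noise_sd, "fc_noise_sd", 1e-6)
  if (am_fraction <= 0 || am_fraction >= 1) {
    stop_fcb("`am_fraction` must lie strictly inside (0, 1)",
             "fcbiotype_config_error")
  }
  p <- n_fc_features(n_roi)
  if (n_signal_fc * n_biotypes + n_contrast_fc > p) {
    stop_fcb(sprintf(
      "n_signal_fc (%d) x n_biotypes (%d) + n_contrast_fc (%d) exceeds the FC panel width (%d)",
      n_signal_fc, n_biotypes, n_contrast_fc, p), "fcbiotype_config_error")
  }
  if (causal_biotype < 1 || causal_biotype > n_biotypes) {
    stop_fcb("`causal_biotype` must name one of the simulated biotypes",
             "fcbiotype_config_error")
  }
  structure(list(
    n_train = as.integer(n_train), n_validation = as.integer(n_validation),
    n_replication = as.integer(n_replication), am_fraction = am_fraction,
    n_roi = as.integer(n_roi), n_biotypes = as.integer(n_biotypes),
    n_signal_fc = as.integer(n_signal_fc),
    n_contrast_fc = as.integer(n_contrast_fc), effect_size = effect_size,
    n_snps = as.integer(n_snps), causal_maf = causal_maf,
    causal_beta = causal_beta, causal_biotype = as.integer(causal_biotype),
    mz_pairs = as.integer(mz_pairs), dz_pairs = as.integer(dz_pairs),
    fc_noise_sd = fc_noise_sd, scan2_noise_sd = scan2_noise_sd,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# canonical column names for the clinical metric table
alcohol_metric_names <- function() {
  c("drinks_per_day_12m", "freq_any_12m", "freq_5plus_12m", "freq_drunk_12m",
    "max_drinks_12m", "drinks_per_day_hvy", "freq_any_hvy", "freq_5plus_hvy",
    "freq_drunk_hvy", "max_drinks_hvy")
}

asr_metric_names <- function() {
  c("asr_depression", "asr_anxiety", "asr_somatic", "asr_avoidant",
    "asr_adhd", "asr_inattention", "asr_hyperactivity", "asr_antisocial")
}

#' Clinical metric column names used throughout the pipeline
#'
#' Ten alcohol-use severity metrics (linearly normalized to a 0--5 scale:
#' past-12-month and heaviest-period drinking frequency/quantity measures)
#' followed by eight Adult Self Report DSM-oriented scores.
#'
#' @return character vector of 18 column names.
#' @export
metric_names <- function() c(alcohol_metric_names(), asr_metric_names())

#' Generate a synthetic cohort with planted biotype, clinical and genetic structure
#'
#' Draws a full cohort under a [cohort_config()]: a subject table with
#' demographics, split labels, AM status, clinical metrics and a head-motion
#' covariate; two FC panels (scan 1 and scan 2 = scan 1 plus independent
#' noise); an HWE-conforming genotype panel with twin relatedness and one
#' causal SNP; and the planted ground truth.
#'
#' The generative model is a latent-severity chain: every subject carries a
#' latent severity score for each biotype (`causal_beta` times the causal-SNP
#' dosage enters the causal biotype's score for all subjects); AM subjects of
#' biotype *b* have that biotype's score elevated, and both their signal FC
#' features and their clinical metrics are noisy monotone functions of it,
#' which yields the Spearman structure the screening stage targets. Drinking
#' frequency is ordered biotype 3 > biotype 1 > biotype 2 and the antisocial
#' score is elevated in biotype 2. FC noise is Gaussian on the Fisher-z scale
#' and back-transformed so correlations stay in (-1, 1).
#'
#' @param config a [cohort_config()].
#' @return a list of class `fcb_cohort` with elements
#'   \describe{
#'     \item{subjects}{tibble, one row per subject: `subject_id`, `split`,
#'       `group` ("AM"/"control"), `age`, `sex`, `race`, `censored_frames`,
#'       `family_id`, `zygosity`, and the 18 clinical metric columns.}
#'     \item{fc_scan1,fc_scan2}{subjects x p FC matrices (rownames =
#'       subject IDs).}
#'     \item{genotypes}{list with `dosage` (subjects x SNPs minor-allele
#'       dosage matrix) and `snp_info` tibble (id, chrom, pos, ref, alt).}
#'     \item{truth}{planted ground truth: per-AM-subject `biotype`,
#'       `signal_fc_indices` (list per biotype), `causal_snp_index`,
#'       `causal_biotype`, `kinship_pairs`, and `trait` (the cohort-wide
#'       latent severity of the causal biotype).}
#'   }
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_train + cfg$n_validation + cfg$n_replication
  p <- n_fc_features(cfg$n_roi)
  split <- rep(c("train", "validation", "replication"),
               times = c(cfg$n_train, cfg$n_validation, cfg$n_replication))
  id <- sprintf("S%04d", seq_len(n))

  ## demographics (EA/AA/other mix of the motivating young-adult cohort)
  age <- round(runif(n, 22, 35), 1)
  sex <- rbinom(n, 1, 0.45)
  race <- sample(c("EA", "AA", "OTH"), n, replace = TRUE,
                 prob = c(0.744, 0.139, 0.117))
  censored_frames <- stats::rpois(n, 80)

  ## AM status per split (fixed count keeps split prevalences matched)
  am <- logical(n)
  for (s in unique(split)) {
    i <- which(split == s)
    n_am <- max(1L, round(length(i) * cfg$am_fraction))
    am[sample(i, n_am)] <- TRUE
  }

  ## biotype assignment for AM subjects
  biotype <- rep(NA_integer_, n)
  biotype[am] <- sample(seq_len(cfg$n_biotypes), sum(am), replace = TRUE)

  ## twin pairs: adjacent subject slots inside the training split share a family
  fam <- seq_len(n)
  zyg <- rep("none", n)
  n_pairs <- cfg$mz_pairs + cfg$dz_pairs
  if (2L * n_pairs > cfg$n_train) {
    stop_fcb("too many twin pairs for the training split size",
             "fcbiotype_config_error")
  }
  kin <- NULL
  if (n_pairs > 0) {
    pair_a <- seq(1L, by = 2L, length.out = n_pairs)
    pair_b <- pair_a + 1L
    types <- rep(c("MZ", "DZ"), times = c(cfg$mz_pairs, cfg$dz_pairs))
    fam[pair_b] <- fam[pair_a]
    zyg[pair_a] <- zyg[pair_b] <- types
    race[pair_b] <- race[pair_a]
    kin <- tibble::tibble(subject_a = id[pair_a], subject_b = id[pair_b],
                          zygosity = types)
  }

  ## genotypes: two allele draws per subject; DZ twins gene-dropped from
  ## shared simulated parents, MZ twins copied
  maf <- runif(cfg$n_snps, 0.05, 0.5)
  causal_idx <- max(1L, cfg$n_snps %/% 2L)
  maf[causal_idx] <- cfg$causal_maf
  dosage <- matrix(0L, n, cfg$n_snps, dimnames = list(id, NULL))
  draw_gamete <- function(parent) {
    pick <- rbinom(cfg$n_snps, 1, 0.5)
    ifelse(pick == 1L, parent$a1, parent$a2)
  }
  new_parent <- function() list(a1 = rbinom(cfg$n_snps, 1, maf),
                                a2 = rbinom(cfg$n_snps, 1, maf))
  done <- logical(n)
  for (i in seq_len(n)) {
    if (done[i]) next
    twin <- which(fam == fam[i] & seq_len(n) != i)
    mother <- new_parent(); father <- new_parent()
    dosage[i, ] <- draw_gamete(mother) + draw_gamete(father)
    done[i] <- TRUE
    if (length(twin) == 1L) {
      if (zyg[i] == "MZ") {
        dosage[twin, ] <- dosage[i, ]
      } else {
        dosage[twin, ] <- draw_gamete(mother) + draw_gamete(father)
      }
      done[twin] <- TRUE
    }
  }
  snp_info <- tibble::tibble(
    id = sprintf("snp%04d", seq_len(cfg$n_snps)),
    chrom = as.integer(ceiling(seq_len(cfg$n_snps) / ceiling(cfg$n_snps / 4))),
    pos = integer(cfg$n_snps), ref = "A", alt = "G", maf_sim = maf)
  snp_info$pos <- as.integer(stats::ave(seq_len(cfg$n_snps), snp_info$chrom,
                                        FUN = function(x) seq_along(x) * 5000L))

  ## latent severities: one score per biotype for every subject; the causal
  ## SNP shifts the causal biotype's score for everyone (it is the
  ## quantitative trait an association scan should recover)
  latent <- matrix(rnorm(n * cfg$n_biotypes), n, cfg$n_biotypes)
  latent[, cfg$causal_biotype] <- latent[, cfg$causal_biotype] +
    cfg$causal_beta * dosage[, causal_idx]
  own <- ifelse(am, biotype, NA_integer_)
  # AM subjects sit 1.5 SD up on their own biotype's severity scale
  lat_own <- rep(0, n)
  lat_own[am] <- latent[cbind(which(am), biotype[am])] + 1.5

  ## FC panels on the Fisher-z scale
  sigma <- cfg$fc_noise_sd
  mu <- rnorm(p, 0.3, 0.15)
  beta_age <- rnorm(p, 0, 0.003)
  beta_sex <- rnorm(p, 0, 0.04)
  beta_mot <- rnorm(p, 0, 0.0004)
  z <- matrix(rnorm(n * p, 0, sigma), n, p)
  z <- z + rep(mu, each = n) +
    outer(age - 28, beta_age) + outer(sex, beta_sex) +
    outer(censored_frames - 80, beta_mot)
  signal_sets <- split(seq_len(cfg$n_signal_fc * cfg$n_biotypes),
                       rep(seq_len(cfg$n_biotypes), each = cfg$n_signal_fc))
  names(signal_sets) <- NULL
  # distinct effect patterns: each biotype raises some of its edges and
  # lowers others (as connectivity contrasts do), fixed signs per feature
  signal_signs <- lapply(signal_sets, function(ss)
    sample(c(-1, 1), length(ss), replace = TRUE))
  for (b in seq_len(cfg$n_biotypes)) {
    members <- which(am & biotype == b)
    if (length(members) == 0) next
    # monotone in the subject's own-biotype latent, |mean shift| = effect_size * sigma
    shift <- cfg$effect_size * sigma *
      (1 + 0.2 * (lat_own[members] - mean(lat_own[members])))
    z[members, signal_sets[[b]]] <- z[members, signal_sets[[b]]] +
      outer(shift, signal_signs[[b]])
  }
  # contrast features: for each, one biotype connects more and another less
  # than controls (opposite-signed effects on a shared edge), so the pooled
  # AM-vs-control mean shift cancels while biotypes separate
  contrast_idx <- integer(0)
  contrast_pairs <- NULL
  if (cfg$n_contrast_fc > 0 && cfg$n_biotypes >= 2) {
    offset <- cfg$n_signal_fc * cfg$n_biotypes
    contrast_idx <- offset + seq_len(cfg$n_contrast_fc)
    pairs <- cbind(up = (seq_len(cfg$n_contrast_fc) - 1) %% cfg$n_biotypes + 1,
                   down = seq_len(cfg$n_contrast_fc) %% cfg$n_biotypes + 1)
    contrast_pairs <- pairs
    for (b in seq_len(cfg$n_biotypes)) {
      members <- which(am & biotype == b)
      if (length(members) == 0) next
      shift <- cfg$effect_size * sigma *
        (1 + 0.2 * (lat_own[members] - mean(lat_own[members])))
      sign_b <- ifelse(pairs[, "up"] == b, 1, ifelse(pairs[, "down"] == b, -1, 0))
      z[members, contrast_idx] <- z[members, contrast_idx] +
        outer(shift, sign_b)
    }
  }
  fc1 <- fisher_z_inv(z)
  fc2 <- fisher_z_inv(z + matrix(rnorm(n * p, 0, cfg$scan2_noise_sd), n, p))
  dimnames(fc1) <- dimnames(fc2) <- list(id, NULL)

  ## clinical metrics: monotone in the subject's own-biotype latent, with
  ## biotype-specific offsets (drinking frequency: biotype 3 > 1 > 2;
  ## antisocial: elevated in biotype 2)
  subjects <- tibble::tibble(
    subject_id = id, split = split,
    group = ifelse(am, "AM", "control"),
    age = age, sex = sex, race = race,
    censored_frames = censored_frames,
    family_id = sprintf("F%04d", fam), zygosity = zyg)
  freq_offset <- c(0.8, 0.2, 1.3, rep(0.8, max(0, cfg$n_biotypes - 3)))
  for (m in alcohol_metric_names()) {
    base <- pmin(pmax(rnorm(n, 1.3, 0.9), 0), 5)
    v <- base
    is_freq <- grepl("^freq", m)
    off <- if (is_freq) freq_offset else rep(0.9, cfg$n_biotypes)
    idx_am <- which(am)
    v[idx_am] <- base[idx_am] + off[biotype[idx_am]] +
      0.45 * (lat_own[idx_am] - 1.5) + rnorm(length(idx_am), 0, 0.3)
    subjects[[m]] <- round(pmin(pmax(v, 0), 5), 2)
  }
  for (m in asr_metric_names()) {
    v <- rnorm(n, 48, 8)
    idx_am <- which(am)
    v[idx_am] <- v[idx_am] + 1 + 1.5 * (lat_own[idx_am] - 1.5) * 0.5
    if (m == "asr_antisocial" && cfg$n_biotypes >= 2) {
      b2 <- which(am & biotype == 2L)
      v[b2] <- v[b2] + 6
    }
    subjects[[m]] <- round(v, 1)
  }

  truth <- list(
    biotype = setNames(biotype[am], id[am]),
    signal_fc_indices = signal_sets,
    signal_signs = signal_signs,
    contrast_fc_indices = contrast_idx,
    contrast_pairs = contrast_pairs,
    causal_snp_index = causal_idx,
    causal_biotype = cfg$causal_biotype,
    kinship_pairs = kin,
    trait = setNames(latent[, cfg$causal_biotype], id),
    latent_own = setNames(lat_own, id))

  structure(list(subjects = subjects, fc_scan1 = fc1, fc_scan2 = fc2,
                 genotypes = list(dosage = dosage, snp_info = snp_info),
                 truth = truth, config = cfg),
            class = "fcb_cohort")
}

#' @export
print.fcb_cohort <- function(x, ...) {
  cat(sprintf("<fcb_cohort> %d subjects (%d AM), %d FC features, %d SNPs\n",
              nrow(x$subjects), sum(x$subjects$group == "AM"),
              ncol(x$fc_scan1), ncol(x$genotypes$dosage)))
  print(table(x$subjects$split))
  invisible(x)
}

#' Simulate a motion trace and ROI time-series panel with planted outliers
#'
#' Produces a six-parameter rigid-body motion trace whose framewise
#' displacement exceeds the 0.2 mm censoring threshold exactly at
#' `outlier_times` (persistent level shifts on a smooth sub-threshold
#' baseline), and a BOLD panel whose DVARS exceeds `dvars_spike` threshold at
#' the same frames. Used to exercise the scrubbing stage with a known answer.
#'
#' @param n_frames number of frames (e.g. 1200 for a 14.4-minute run at
#'   TR = 0.72 s).
#' @param outlier_times 1-based frame indices at which outliers are planted
#'   (must be > 1 since the first frame has no differential).
#' @param n_units number of ROIs/voxels in the BOLD panel.
#' @param tr frame period in seconds.
#' @param fd_spike translation jump in mm injected at each outlier frame.
#' @param dvars_spike BOLD level jump injected at each outlier frame.
#' @param seed RNG seed.
#' @return list with `motion` (a [motion_trace()]) and `bold`
#'   (a [ts_panel()]).
#' @export
generate_motion_and_bold <- function(n_frames, outlier_times = integer(),
                                     n_units = 20, tr = 0.72,
                                     fd_spike = 0.35, dvars_spike = 110,
                                     seed = 1L) {
  check_number(n_frames, "n_frames", 2)
  outlier_times <- as.integer(outlier_times)
  if (length(outlier_times) &&
      (any(outlier_times < 2) || any(outlier_times > n_frames))) {
    stop_fcb("`outlier_times` must lie in [2, n_frames]",
             "fcbiotype_input_error")
  }
  with_seed(seed, {
    # smooth baseline: increments small enough that baseline FD < 0.2 mm
    trans <- replicate(3, cumsum(runif(n_frames, -0.008, 0.008)))
    rot <- replicate(3, cumsum(runif(n_frames, -0.00015, 0.00015)))
    for (t in outlier_times) {
      trans[t:n_frames, 1] <- trans[t:n_frames, 1] + fd_spike
    }
    motion <- motion_trace(trans[, 1], trans[, 2], trans[, 3],
                           rot[, 1], rot[, 2], rot[, 3], tr = tr)
    tt <- seq_len(n_frames) * tr
    signal <- outer(sin(2 * pi * 0.04 * tt), runif(n_units, 3, 6))
    bold <- 100 + signal + matrix(rnorm(n_frames * n_units, 0, 4),
                                  n_frames, n_units)
    for (t in outlier_times) {
      bold[t:n_frames, ] <- bold[t:n_frames, ] + dvars_spike
    }
    list(motion = motion, bold = ts_panel(bold, tr = tr))
  })
}
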