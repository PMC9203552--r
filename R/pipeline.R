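#' Run the discovery stage: screen, cluster, classify, select
#'
#' End-to-end discovery on a cohort: (1) fit the covariate residualization
#' on the training split (separately per scan) and adjust every split with
#' the frozen training model; (2) screen FC features at each threshold in
#' `alphas` (Spearman-vs-metrics union Wilcoxon case-control); (3) for every
#' (alpha, dimension) grid cell, embed the AM training subjects, cluster
#' with K-means and Ward linkage, pick k by the Variance Ratio Criterion and
#' omit undersized clusters; (4) train a biotype-aware classifier per cell
#' and a single baseline classifier; (5) select the cell with the best
#' validation AUC and freeze the decision threshold on the validation split.
#' The replication split is never touched during selection.
#'
#' @param cohort an `fcb_cohort` (or a list with the same elements built
#'   from files).
#' @param alphas screening thresholds (default `c(0.05, 0.005, 0.0005)`).
#' @param dims embedding dimensions (default `c(2, 3, 4)`).
#' @param k_candidates candidate cluster counts (default 2:4).
#' @param min_cluster_size smallest retained cluster (default 20).
#' @param screen_population subjects entering the Spearman screen ("all" or
#'   "am").
#' @param classifier named list of classifier hyperparameters
#'   (`hidden`, `code_dim`, `epochs`, `lr`, `lambda`).
#' @param reducer passed to [reduce_embedding()].
#' @param seed master seed; every stochastic stage derives its own stream.
#' @return object of class `fcb_run` holding the frozen residual models,
#'   masks, grid solutions, both classifiers, the selected cell, the
#'   decision threshold, per-cell validation AUCs, and ground-truth recovery
#'   metrics when the cohort carries planted truth.
#' @export
run_discovery <- function(cohort,
                          alphas = c(0.05, 0.005, 0.0005),
                          dims = c(2, 3, 4),
                          k_candidates = 2:4,
                          min_cluster_size = 20,
                          screen_population = "all",
                          classifier = list(),
                          reducer = "pca",
                          seed = 1L) {
  subj <- cohort$subjects
  if (!all(c("split", "group") %in% names(subj))) {
    stop_fcb("subject table must carry split and group labels",
             "fcbiotype_input_error")
  }
  cls <- utils::modifyList(list(hidden = 16, code_dim = 2, epochs = 150,
                                lr = 0.02, lambda = 1), classifier)
  tr <- subj$split == "train"
  va <- subj$split == "validation"
  cov_cols <- c("age", "sex", "censored_frames")

  rm1 <- fit_residual_model(cohort$fc_scan1[tr, , drop = FALSE], subj[tr, cov_cols])
  rm2 <- fit_residual_model(cohort$fc_scan2[tr, , drop = FALSE], subj[tr, cov_cols])
  fc1 <- apply_residual_model(rm1, cohort$fc_scan1, subj[, cov_cols])
  fc2 <- apply_residual_model(rm2, cohort$fc_scan2, subj[, cov_cols])

  masks <- lapply(alphas, function(a)
    screen_features(fc1[tr, , drop = FALSE], subj[tr, ], a,
                    population = screen_population))
  names(masks) <- as.character(alphas)

  am_tr <- tr & subj$group == "AM"
  fc_am <- fc1[am_tr, , drop = FALSE]
  rownames(fc_am) <- subj$subject_id[am_tr]
  grid <- solution_grid(fc_am, masks, dims = dims,
                        k_candidates = k_candidates,
                        seed = child_seed(seed, 1), reducer = reducer)

  train_fc <- fc1[tr, , drop = FALSE]
  rownames(train_fc) <- subj$subject_id[tr]
  val_fc <- fc1[va, , drop = FALSE]
  rownames(val_fc) <- subj$subject_id[va]
  y_tr <- subj$group[tr] == "AM"
  y_va <- subj$group[va] == "AM"

  baseline <- train_baseline(train_fc, y_tr, val_fc, y_va,
                             hidden = cls$hidden, code_dim = cls$code_dim,
                             epochs = cls$epochs, lr = cls$lr,
                             seed = child_seed(seed, 2))

  cells <- tibble::tibble()
  models <- list()
  for (nm in names(grid)) {
    sol <- tryCatch(omit_small_clusters(grid[[nm]], min_cluster_size),
                    fcbiotype_error = function(e) {
                      rlang::warn(sprintf("cell %s: %s", nm, conditionMessage(e)))
                      NULL
                    })
    if (is.null(sol)) next
    grid[[nm]] <- sol
    bio <- rep(NA_integer_, sum(tr))
    names(bio) <- subj$subject_id[tr]
    lab <- retained_labels(sol)
    bio[names(lab)] <- lab
    fit <- train_biotype_aware(train_fc, y_tr, bio, val_fc, y_va,
                               lambda = cls$lambda, hidden = cls$hidden,
                               code_dim = cls$code_dim, epochs = cls$epochs,
                               lr = cls$lr, seed = child_seed(seed, 3))
    models[[nm]] <- fit
    cells <- dplyr::bind_rows(cells, tibble::tibble(
      cell = nm, alpha = sol$alpha, d = sol$d, k = sol$k,
      method = sol$method, n_retained = sum(!sol$omitted),
      n_omitted = sum(sol$omitted), val_auc = fit$val_auc))
  }
  if (nrow(cells) == 0) {
    stop_fcb("no grid cell produced a usable biotyping solution",
             "fcbiotype_input_error")
  }
  best <- cells$cell[which.max(cells$val_auc)]
  model <- models[[best]]
  val_scores <- predict(model, val_fc)
  threshold <- choose_threshold(val_scores$combined, y_va)

  recovery <- NULL
  if (!is.null(cohort$truth)) {
    sol <- grid[[best]]
    lab <- retained_labels(sol)
    truth_b <- cohort$truth$biotype[names(lab)]
    recovery <- list(
      ari_retained = adjusted_rand(lab, truth_b),
      ari_all = adjusted_rand(sol$labels,
                              cohort$truth$biotype[names(sol$labels)]),
      k_selected = sol$k)
  }

  structure(list(
    residual_model_scan1 = rm1, residual_model_scan2 = rm2,
    masks = masks, grid = grid, cells = cells,
    baseline = baseline, biotype_model = model,
    selected_cell = best, threshold = threshold,
    fc_train_adjusted = train_fc, fc_scan2_adjusted = fc2,
    subjects = subj, recovery = recovery,
    train_ids = subj$subject_id[tr], val_ids = subj$subject_id[va],
    seed = as.integer(seed), classifier_opts = cls),
    class = "fcb_run")
}

#' @export
print.fcb_run <- function(x, ...) {
  sel <- x$cells[x$cells$cell == x$selected_cell, ]
  cat(sprintf(paste0(
    "<fcb_run> selected cell %s (alpha = %g, d = %d, k = %d, %s)\n",
    "  validation AUC: biotype-aware %.3f, baseline %.3f\n"),
    x$selected_cell, sel$alpha, sel$d, sel$k, sel$method,
    sel$val_auc, x$baseline$val_auc))
  invisible(x)
}

#' Per-cell summary of a discovery run
#'
#' @param x an `fcb_run`.
#' @param ... unused.
#' @return tibble with one row per grid cell (alpha, d, k, method, cluster
#'   counts, validation AUC).
#' @method tidy fcb_run
#' @export
tidy.fcb_run <- function(x, ...) x$cells

#' One-row summary of a discovery run
#'
#' @param x an `fcb_run`.
#' @param ... unused.
#' @return one-row tibble with the selected cell, its solution shape, both
#'   validation AUCs and the frozen threshold.
#' @method glance fcb_run
#' @export
glance.fcb_run <- function(x, ...) {
  sel <- x$cells[x$cells$cell == x$selected_cell, ]
  tibble::tibble(
    selected_cell = x$selected_cell, alpha = sel$alpha, d = sel$d,
    k = sel$k, method = sel$method,
    val_auc_biotype = sel$val_auc, val_auc_baseline = x$baseline$val_auc,
    threshold = x$threshold$threshold,
    ari_retained = if (is.null(x$recovery)) NA_real_ else x$recovery$ari_retained)
}

#' Apply frozen discovery artifacts to the replication split
#'
#' Adjusts the replication FC with the frozen training residual model,
#' scores the frozen baseline and biotype-aware classifiers, applies the
#' frozen decision threshold, and reports AUC and G-score for both models.
#' An identifier audit asserts that no replication subject contributed to
#' any fitted artifact.
#'
#' @param run an `fcb_run` from [run_discovery()].
#' @param cohort the same cohort object.
#' @return tibble of class `fcb_replication`: one row per model with `auc`,
#'   `sensitivity`, `specificity`, `gscore`.
#' @export
run_replication <- function(run, cohort) {
  stopifnot(inherits(run, "fcb_run"))
  subj <- cohort$subjects
  re <- subj$split == "replication"
  rep_ids <- subj$subject_id[re]
  seen <- c(run$train_ids, run$val_ids,
            names(run$grid[[run$selected_cell]]$labels))
  if (length(intersect(rep_ids, seen))) {
    stop_fcb("leakage audit failed: replication IDs found in fitted artifacts",
             "fcbiotype_state_error")
  }
  fc_re <- apply_residual_model(run$residual_model_scan1,
                                cohort$fc_scan1[re, , drop = FALSE],
                                subj[re, c("age", "sex", "censored_frames")])
  rownames(fc_re) <- rep_ids
  y <- subj$group[re] == "AM"
  thr <- run$threshold$threshold
  one <- function(model, name) {
    s <- predict(model, fc_re)$combined
    pred <- s > thr
    sens <- sum(pred & y) / sum(y)
    spec <- sum(!pred & !y) / sum(!y)
    tibble::tibble(model = name, auc = auc(s, y), sensitivity = sens,
                   specificity = spec, gscore = gscore(sens, spec))
  }
  out <- dplyr::bind_rows(one(run$biotype_model, "biotype_aware"),
                          one(run$baseline, "baseline"))
  class(out) <- c("fcb_replication", class(out))
  out
}

#' Permutation significance of the replication AUC
#'
#' Re-labels AM/control independently within the discovery (train +
#' validation) and replication strata, retrains the classifier per
#' permutation with the clustering solution held fixed (subjects that stay
#' AM keep their biotype labels; permuted-in AM subjects enter only the
#' overall AM loss), and compares the observed replication AUC with the
#' permutation null via the add-one p-value. The retraining budget
#' (`epochs`) is recorded in the result.
#'
#' @param run an `fcb_run`.
#' @param cohort the cohort the run was fit on.
#' @param model which model to test ("biotype_aware" or "baseline").
#' @param n_perm number of permutations (default 200).
#' @param epochs retraining budget per permutation (default: half the
#'   discovery budget).
#' @param seed integer seed.
#' @return a `permutation_result` (see [permutation_test()]) with the
#'   retraining budget in `$epochs`.
#' @export
replication_significance <- function(run, cohort,
                                     model = c("biotype_aware", "baseline"),
                                     n_perm = 200, epochs = NULL, seed = 1L) {
  model <- match.arg(model)
  subj <- cohort$subjects
  if (is.null(epochs)) epochs <- max(20L, run$classifier_opts$epochs %/% 2L)
  cls <- run$classifier_opts
  tr <- subj$split == "train"; va <- subj$split == "validation"
  re <- subj$split == "replication"
  fc1 <- apply_residual_model(run$residual_model_scan1, cohort$fc_scan1,
                              subj[, c("age", "sex", "censored_frames")])
  rownames(fc1) <- subj$subject_id
  sol <- run$grid[[run$selected_cell]]
  lab0 <- retained_labels(sol)
  metric_fn <- function(labels) {
    y_tr <- labels[tr]; y_va <- labels[va]; y_re <- labels[re]
    if (length(unique(y_va)) < 2 || length(unique(y_re)) < 2) return(NA_real_)
    fit <- if (model == "biotype_aware") {
      bio <- rep(NA_integer_, sum(tr))
      names(bio) <- subj$subject_id[tr]
      keep <- names(lab0)[y_tr[match(names(lab0), subj$subject_id[tr])]]
      bio[keep] <- lab0[keep]
      if (sum(!is.na(bio)) < 5) return(NA_real_)
      train_biotype_aware(fc1[tr, ], y_tr, bio, fc1[va, ], y_va,
                          lambda = cls$lambda, hidden = cls$hidden,
                          code_dim = cls$code_dim, epochs = epochs,
                          lr = cls$lr, seed = child_seed(seed, 7))
    } else {
      train_baseline(fc1[tr, ], y_tr, fc1[va, ], y_va,
                     hidden = cls$hidden, code_dim = cls$code_dim,
                     epochs = epochs, lr = cls$lr,
                     seed = child_seed(seed, 7))
    }
    auc(predict(fit, fc1[re, ])$combined, y_re)
  }
  labels <- subj$group == "AM"
  strata <- ifelse(re, "replication", "discovery")
  res <- permutation_test(metric_fn, labels, strata = strata,
                          n_perm = n_perm, seed = seed)
  res$epochs <- epochs
  res
}
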