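## Biotype-aware AM classifier.
##
## One subnetwork per biotype scores biotype-vs-control membership: a
## grouped linear stage maps each ROI's pairwise FC features to a small
## per-ROI code (parameters scale with p * code_dim, not p * hidden), the
## concatenated codes pass through one tanh hidden layer and a logistic
## output. Subnetworks are separate so each head stays specific to its
## biotype's connectivity pattern. The combined AM score passes the
## nonnegative (softplus) weighted sum of the biotype scores through a
## logistic link with a trained bias: it stays in [0, 1] and is monotone in
## every head. The joint objective sums the per-biotype cross-entropies
## (head b's positives are its biotype's AM subjects; its negatives are all
## controls plus the other retained biotypes, which keeps each score
## biotype-specific) and lambda times the overall AM-vs-control
## cross-entropy of the combined score.

sigmoid <- function(x) 1 / (1 + exp(-x))
softplus <- function(x) log1p(exp(pmin(x, 30))) + pmax(x - 30, 0)

clip01 <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

# ROI-wise grouping of FC indices; contiguous chunks when the panel width is
# not a full strict upper triangle
fc_groups <- function(p) {
  r <- (1 + sqrt(1 + 8 * p)) / 2
  if (abs(r - round(r)) < 1e-9) {
    r <- round(r)
    map <- fc_index_map(r)
    lapply(seq_len(r), function(i)
      map$fc_index[map$roi_i == i | map$roi_j == i])
  } else {
    n_grp <- max(2L, as.integer(ceiling(sqrt(2 * p))))
    split(seq_len(p), cut(seq_len(p), n_grp, labels = FALSE))
  }
}

# one biotype-vs-control subnetwork: grouped per-ROI linear codes -> tanh
# hidden -> logistic score
init_head <- function(groups, code_dim, hidden) {
  W <- lapply(groups, function(g)
    matrix(rnorm(length(g) * code_dim, 0, 1 / sqrt(length(g))),
           length(g), code_dim))
  nc <- length(groups) * code_dim
  list(W = W,
       b1 = numeric(nc),
       V = matrix(rnorm(nc * hidden, 0, 1 / sqrt(nc)), nc, hidden),
       b2 = numeric(hidden),
       u = rnorm(hidden, 0, 1 / sqrt(hidden)),
       c0 = 0)
}

init_params <- function(groups, code_dim, hidden, n_heads, seed) {
  with_seed(seed, list(
    heads = lapply(seq_len(n_heads), function(b)
      init_head(groups, code_dim, hidden)),
    v = numeric(n_heads),   # softplus(v) = combination weights
    v0 = -1))               # bias of the logistic combination link
}

head_forward <- function(h, Xm, groups) {
  n <- nrow(Xm)
  code_dim <- ncol(h$W[[1]])
  C <- matrix(0, n, length(groups) * code_dim)
  for (r in seq_along(groups)) {
    cols <- ((r - 1) * code_dim + 1):(r * code_dim)
    C[, cols] <- Xm[, groups[[r]], drop = FALSE] %*% h$W[[r]]
  }
  C <- sweep(C, 2, h$b1, "+")
  H <- tanh(sweep(C %*% h$V, 2, h$b2, "+"))
  s <- sigmoid(as.vector(H %*% h$u) + h$c0)
  list(C = C, H = H, s = s)
}

forward_pass <- function(params, X, groups, mode) {
  hf <- lapply(params$heads, head_forward, Xm = X, groups = groups)
  S <- do.call(cbind, lapply(hf, `[[`, "s"))
  if (mode == "baseline") {
    comb <- S[, 1]
  } else {
    w <- softplus(params$v) + 1e-6
    comb <- sigmoid(params$v0 + as.vector(S %*% w))
  }
  list(hf = hf, S = S, comb = comb)
}

# gradient of one head's subnetwork given dL/dz (pre-sigmoid score)
head_backward <- function(h, X, groups, fwh, g) {
  du <- as.vector(crossprod(fwh$H, g))
  dH <- outer(g, h$u)
  dZh <- dH * (1 - fwh$H^2)
  dV <- crossprod(fwh$C, dZh)
  dC <- dZh %*% t(h$V)
  code_dim <- ncol(h$W[[1]])
  dW <- vector("list", length(groups))
  for (r in seq_along(groups)) {
    cols <- ((r - 1) * code_dim + 1):(r * code_dim)
    dW[[r]] <- crossprod(X[, groups[[r]], drop = FALSE],
                         dC[, cols, drop = FALSE])
  }
  list(W = dW, b1 = colSums(dC), V = dV, b2 = colSums(dZh), u = du,
       c0 = sum(g))
}

# gradient of the joint objective; head_members[[b]] = row indices entering
# head b's biotype-vs-control loss, head_y[[b]] = their 0/1 targets
backward_pass <- function(params, X, groups, fw, mode,
                          head_members, head_y, y_am, lambda) {
  n <- nrow(X)
  B <- ncol(fw$S)
  G <- matrix(0, n, B)          # dL/dz_b (pre-sigmoid)
  for (b in seq_len(B)) {
    m <- head_members[[b]]
    G[m, b] <- G[m, b] + (fw$S[m, b] - head_y[[b]]) / length(m)
  }
  grad_v <- numeric(B)
  grad_v0 <- 0
  if (mode == "biotype" && lambda > 0) {
    w <- softplus(params$v) + 1e-6
    # logistic link: dCE/d(pre-link sum) = comb - y
    da <- lambda * (fw$comb - y_am) / n
    for (b in seq_len(B)) {
      G[, b] <- G[, b] + da * w[b] * fw$S[, b] * (1 - fw$S[, b])
      grad_v[b] <- sum(da * fw$S[, b]) * sigmoid(params$v[b])
    }
    grad_v0 <- sum(da)
  }
  list(heads = lapply(seq_len(B), function(b)
         head_backward(params$heads[[b]], X, groups, fw$hf[[b]], G[, b])),
       v = grad_v, v0 = grad_v0)
}

joint_loss <- function(fw, head_members, head_y, y_am, mode, lambda) {
  B <- ncol(fw$S)
  l <- 0
  for (b in seq_len(B)) {
    s <- clip01(fw$S[head_members[[b]], b])
    y <- head_y[[b]]
    l <- l - mean(y * log(s) + (1 - y) * log(1 - s))
  }
  if (mode == "biotype" && lambda > 0) {
    comb <- clip01(fw$comb)
    l <- l - lambda * mean(y_am * log(comb) + (1 - y_am) * log(1 - comb))
  }
  l
}

# flat Adam over the nested parameter list, with decoupled weight decay
adam_step <- function(params, grads, state, lr, t, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      for (nm in seq_along(p)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out$p[[nm]] <- r$p; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
      }
      out
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mh <- m / (1 - beta1^t)
      vh <- v / (1 - beta2^t)
      list(p = p - lr * (mh / (sqrt(vh) + eps) + weight_decay * p),
           m = m, v = v)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v))
}

zero_like <- function(params) {
  rapply(params, function(x) x * 0, how = "replace")
}

train_classifier_impl <- function(fc, y_am, biotype, val_fc, val_y, mode,
                                  lambda, hidden, code_dim, epochs, lr,
                                  weight_decay, eval_every, seed) {
  fc <- as.matrix(fc)
  if (length(unique(y_am)) < 2) {
    stop_fcb("training labels contain a single class", "fcbiotype_input_error")
  }
  if (length(unique(val_y)) < 2) {
    stop_fcb("validation labels contain a single class",
             "fcbiotype_input_error")
  }
  feat_mean <- colMeans(fc)
  feat_sd <- pmax(apply(fc, 2, sd), 1e-8)
  X <- sweep(sweep(fc, 2, feat_mean), 2, feat_sd, "/")
  Xv <- sweep(sweep(as.matrix(val_fc), 2, feat_mean), 2, feat_sd, "/")
  groups <- fc_groups(ncol(X))

  if (mode == "baseline") {
    head_ids <- NA_integer_
    head_members <- list(seq_len(nrow(X)))
    head_y <- list(as.numeric(y_am))
  } else {
    ids <- sort(unique(biotype[!is.na(biotype)]))
    sizes <- table(factor(biotype, levels = ids))
    drop <- ids[sizes < 5]
    if (length(drop)) {
      rlang::warn(sprintf(
        "biotype(s) %s have < 5 training subjects; merged into the AM-only loss",
        paste(drop, collapse = ", ")))
      biotype[biotype %in% drop] <- NA_integer_
      ids <- setdiff(ids, drop)
    }
    if (length(ids) < 1) {
      stop_fcb("no biotype retains >= 5 training subjects",
               "fcbiotype_input_error")
    }
    head_ids <- ids
    # head b: biotype-b AM are positives; controls and the other labeled
    # biotypes are negatives (so each score stays specific to its biotype);
    # omitted-cluster AM appear only in the overall AM term
    labeled <- which(!y_am | !is.na(biotype))
    head_members <- lapply(ids, function(b) labeled)
    head_y <- lapply(ids, function(b)
      as.numeric(!is.na(biotype[labeled]) & biotype[labeled] == b))
  }
  B <- length(head_members)
  params <- init_params(groups, code_dim, hidden, B, seed)
  state <- list(m = zero_like(params), v = zero_like(params))
  y_am_num <- as.numeric(y_am)

  best <- list(auc = -Inf, params = params, epoch = 0L)
  warmup <- max(1, floor(epochs / 3))
  for (t in seq_len(epochs)) {
    # lambda warm-up: heads specialize on their biotype-vs-control contrast
    # before the overall AM term ramps in (full joint objective thereafter)
    lambda_t <- lambda * min(1, (t - 1) / warmup)
    fw <- forward_pass(params, X, groups, mode)
    gr <- backward_pass(params, X, groups, fw, mode,
                        head_members, head_y, y_am_num, lambda_t)
    st <- adam_step(params, gr, state, lr, t, weight_decay = weight_decay)
    params <- st$params; state <- st$state
    snap_ok <- mode == "baseline" || lambda == 0 || t > warmup
    if ((t %% eval_every == 0 || t == epochs) && snap_ok) {
      fv <- forward_pass(params, Xv, groups, mode)
      a <- auc(fv$comb, val_y)
      if (a > best$auc) best <- list(auc = a, params = params, epoch = t)
    }
  }
  structure(list(
    mode = mode, B = B, biotype_ids = head_ids,
    params = best$params, groups = groups,
    feat_mean = feat_mean, feat_sd = feat_sd,
    hyper = list(lambda = lambda, hidden = hidden, code_dim = code_dim,
                 epochs = epochs, lr = lr, weight_decay = weight_decay,
                 seed = seed, best_epoch = best$epoch),
    val_auc = best$auc,
    train_ids = rownames(fc)),
    class = "fcb_classifier")
}

#' Train the baseline AM-vs-control classifier
#'
#' A single-head network (grouped per-ROI linear extractor, one tanh hidden
#' layer, logistic output) trained by full-batch Adam on the binary
#' cross-entropy, with early stopping on validation AUC. Deterministic under
#' the seed; the returned object serializes and reloads to identical scores.
#'
#' @param fc training subjects x features FC matrix (rownames = subject IDs).
#' @param labels logical (or "AM"/"control") training case labels.
#' @param val_fc,val_labels validation panel and labels used for early
#'   stopping and model selection; both classes must be present.
#' @param hidden hidden-layer width.
#' @param code_dim per-ROI code dimension of the grouped extractor.
#' @param epochs,lr,eval_every Adam training budget and validation cadence.
#' @param weight_decay decoupled (AdamW-style) L2 weight decay; the
#'   default shrinks each subnetwork toward its class-mean template, which
#'   matters with far more FC features than subjects.
#' @param seed integer seed for initialization.
#' @return object of class `fcb_classifier` (mode "baseline").
#' @export
train_baseline <- function(fc, labels, val_fc, val_labels,
                           hidden = 16, code_dim = 2, epochs = 150,
                           lr = 0.02, weight_decay = 0.1, eval_every = 5,
                           seed = 1L) {
  train_classifier_impl(fc, parse_group(labels, nrow(fc)), NULL,
                        val_fc, parse_group(val_labels, nrow(as.matrix(val_fc))),
                        mode = "baseline", lambda = 0,
                        hidden = hidden, code_dim = code_dim,
                        epochs = epochs, lr = lr,
                        weight_decay = weight_decay,
                        eval_every = eval_every, seed = seed)
}

#' Train the biotype-aware AM classifier with the joint objective
#'
#' One logistic head per retained biotype scores biotype-vs-control
#' membership; the combined AM score is the trained nonnegative
#' (softplus-parameterized) weighted sum of the heads passed through a
#' logistic link with trained bias, so it lies in \[0, 1\] and is monotone
#' nondecreasing in every biotype score. The objective is the sum of the per-biotype
#' cross-entropies (each head's positives are its biotype's AM subjects;
#' negatives are all controls and the other retained biotypes) plus
#' `lambda` times the overall AM-vs-control cross-entropy of the combined
#' score. AM subjects from omitted clusters (`biotype = NA`) enter
#' only the overall AM term; biotypes with fewer than 5 training subjects
#' are merged into the AM-only loss with a warning.
#'
#' @inheritParams train_baseline
#' @param biotype integer biotype label per training subject (`NA` for
#'   controls and omitted-cluster AM subjects).
#' @param lambda weight of the overall AM-vs-control term (default 1).
#' @return object of class `fcb_classifier` (mode "biotype") emitting one
#'   score per retained biotype plus the combined AM score.
#' @export
train_biotype_aware <- function(fc, labels, biotype, val_fc, val_labels,
                                lambda = 1, hidden = 16, code_dim = 2,
                                epochs = 150, lr = 0.02, weight_decay = 0.1,
                                eval_every = 5, seed = 1L) {
  y <- parse_group(labels, nrow(as.matrix(fc)))
  biotype <- as.integer(biotype)
  if (any(!is.na(biotype) & !y)) {
    stop_fcb("biotype labels may only be set on AM subjects",
             "fcbiotype_input_error")
  }
  train_classifier_impl(fc, y, biotype, val_fc,
                        parse_group(val_labels, nrow(as.matrix(val_fc))),
                        mode = "biotype", lambda = lambda,
                        hidden = hidden, code_dim = code_dim,
                        epochs = epochs, lr = lr,
                        weight_decay = weight_decay,
                        eval_every = eval_every, seed = seed)
}

#' @export
print.fcb_classifier <- function(x, ...) {
  cat(sprintf("<fcb_classifier> mode = %s, %d head(s), best val AUC = %.3f\n",
              x$mode, x$B, x$val_auc))
  invisible(x)
}

#' Score subjects with a trained classifier
#'
#' @param object an `fcb_classifier`.
#' @param fc subjects x features FC matrix on the same feature space the
#'   model was trained on.
#' @param ... unused.
#' @return tibble with `subject_id`, one `s_<biotype>` column per head, and
#'   `combined` (the AM score in \[0, 1\]).
#' @export
predict.fcb_classifier <- function(object, fc, ...) {
  fc <- as.matrix(fc)
  X <- sweep(sweep(fc, 2, object$feat_mean), 2, object$feat_sd, "/")
  fw <- forward_pass(object$params, X, object$groups, object$mode)
  out <- tibble::tibble(subject_id = rownames(fc) %||% as.character(seq_len(nrow(fc))))
  if (object$mode == "biotype") {
    for (i in seq_len(object$B)) {
      out[[sprintf("s_%d", object$biotype_ids[i])]] <- fw$S[, i]
    }
  } else {
    out$s_1 <- fw$S[, 1]
  }
  out$combined <- fw$comb
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Area under the ROC curve
#'
#' Probability that a random case outscores a random control, with ties
#' counted half; computed by the rank (Mann-Whitney) formula, which equals
#' brute-force pairwise concordance.
#'
#' @param scores numeric scores.
#' @param labels logical (or "AM"/"control") case labels; both classes must
#'   be present.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  y <- parse_group(labels, length(scores))
  n1 <- sum(y); n0 <- sum(!y)
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' G-score: geometric mean of sensitivity and specificity
#'
#' @param sensitivity,specificity values in \[0, 1\].
#' @return `sqrt(sensitivity * specificity)`.
#' @export
gscore <- function(sensitivity, specificity) {
  check_number(sensitivity, "sensitivity", 0, 1)
  check_number(specificity, "specificity", 0, 1)
  sqrt(sensitivity * specificity)
}

#' Choose the decision threshold balancing sensitivity and specificity
#'
#' Scans the midpoints between adjacent sorted unique validation scores and
#' returns the threshold minimizing `|specificity - sensitivity|`; ties go to
#' the higher specificity, then to the lower threshold. A score is called AM
#' when it exceeds the threshold. Chosen on the validation split only.
#'
#' @param scores validation scores.
#' @param labels validation case labels (both classes required).
#' @return list of class `decision_threshold` with `threshold`,
#'   `sensitivity`, `specificity`.
#' @export
choose_threshold <- function(scores, labels) {
  y <- parse_group(labels, length(scores))
  u <- sort(unique(scores))
  cand <- if (length(u) > 1) (head(u, -1) + tail(u, -1)) / 2 else u - 0.5
  stats_at <- function(thr) {
    pred <- scores > thr
    c(sens = sum(pred & y) / sum(y), spec = sum(!pred & !y) / sum(!y))
  }
  st <- vapply(cand, stats_at, numeric(2))
  gap <- abs(st["spec", ] - st["sens", ])
  best <- which(gap == min(gap))
  best <- best[order(-st["spec", best], cand[best])][1L]
  structure(list(threshold = cand[best],
                 sensitivity = unname(st["sens", best]),
                 specificity = unname(st["spec", best])),
            class = "decision_threshold")
}

#' @export
print.decision_threshold <- function(x, ...) {
  cat(sprintf("<decision_threshold> %.4f (sens %.3f, spec %.3f)\n",
              x$threshold, x$sensitivity, x$specificity))
  invisible(x)
}
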