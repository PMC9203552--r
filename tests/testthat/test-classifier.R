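# compact separable panel: AM subjects shifted on a planted direction
make_sep_panel <- function(n = 90, p = 45, shift = 2, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c(TRUE, FALSE), length.out = n)
    x <- matrix(rnorm(n * p), n, p)
    x[y, 1:10] <- x[y, 1:10] + shift
    rownames(x) <- sprintf("P%03d", seq_len(n))
    list(x = x, y = y)
  })
}

test_that("the baseline classifier separates a separable panel", {
  tr <- make_sep_panel(seed = 1)
  va <- make_sep_panel(seed = 2, n = 40)
  fit <- train_baseline(tr$x, tr$y, va$x, va$y, epochs = 80, hidden = 8,
                        seed = 1)
  expect_gte(auc(predict(fit, va$x)$combined, va$y), 0.95)
  sc <- predict(fit, va$x)
  expect_true(all(sc$combined >= 0 & sc$combined <= 1))
})

test_that("label permutation drives validation AUC to chance", {
  aucs <- vapply(1:10, function(s) {
    tr <- make_sep_panel(seed = s, n = 60, p = 21, shift = 2)
    va <- make_sep_panel(seed = s + 100, n = 40, p = 21, shift = 2)
    y_perm <- withr::with_seed(s, sample(tr$y))
    fit <- train_baseline(tr$x, y_perm, va$x,
                          withr::with_seed(s + 1, sample(va$y)),
                          epochs = 40, hidden = 4, seed = s)
    auc(predict(fit, va$x)$combined, va$y)
  }, numeric(1))
  expect_gte(median(aucs), 0.4)
  expect_lte(median(aucs), 0.6)
})

test_that("a saved model reloads to identical scores", {
  tr <- make_sep_panel(seed = 3)
  va <- make_sep_panel(seed = 4, n = 30)
  fit <- train_baseline(tr$x, tr$y, va$x, va$y, epochs = 30, hidden = 4,
                        seed = 3)
  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(fit, path)
  reloaded <- readRDS(path)
  expect_lt(max(abs(predict(fit, va$x)$combined -
                      predict(reloaded, va$x)$combined)), 1e-7)
  # same seed trains to identical parameters
  fit2 <- train_baseline(tr$x, tr$y, va$x, va$y, epochs = 30, hidden = 4,
                         seed = 3)
  expect_identical(predict(fit, va$x)$combined,
                   predict(fit2, va$x)$combined)
})

test_that("degenerate single-class inputs are rejected", {
  tr <- make_sep_panel(seed = 5, n = 40)
  expect_error(train_baseline(tr$x, rep(TRUE, 40), tr$x, tr$y),
               class = "fcbiotype_input_error")
})

test_that("the biotype-aware model emits per-biotype plus combined scores", {
  withr::with_seed(6, {
    n <- 120; p <- 45
    y <- rep(c(TRUE, FALSE), length.out = n)
    bio <- rep(NA_integer_, n)
    bio[y] <- rep(1:3, length.out = sum(y))
    x <- matrix(rnorm(n * p), n, p)
    for (b in 1:3) x[!is.na(bio) & bio == b, (b * 10 - 9):(b * 10)] <-
        x[!is.na(bio) & bio == b, (b * 10 - 9):(b * 10)] + 2.5
    rownames(x) <- sprintf("Q%03d", seq_len(n))
  })
  va <- make_sep_panel(seed = 7, n = 40)
  fit <- train_biotype_aware(x, y, bio, va$x, va$y, epochs = 60, hidden = 6,
                             seed = 6)
  sc <- predict(fit, x)
  expect_named(sc, c("subject_id", "s_1", "s_2", "s_3", "combined"))
  expect_true(all(as.matrix(sc[, -1]) >= 0 & as.matrix(sc[, -1]) <= 1))
  # combined is monotone nondecreasing in each biotype score
  w <- fcbiotype:::softplus(fit$params$v) + 1e-6
  expect_true(all(w > 0))
  s0 <- c(0.2, 0.5, 0.3)
  for (b in 1:3) {
    s1 <- s0; s1[b] <- s1[b] + 0.3
    f0 <- fcbiotype:::sigmoid(fit$params$v0 + sum(w * s0))
    f1 <- fcbiotype:::sigmoid(fit$params$v0 + sum(w * s1))
    expect_gte(f1, f0)
  }
  # biotype labels on controls are rejected
  bad <- bio; bad[which(!y)[1]] <- 1L
  expect_error(train_biotype_aware(x, y, bad, va$x, va$y),
               class = "fcbiotype_input_error")
})

test_that("undersized biotypes merge into the AM-only loss with a warning", {
  withr::with_seed(8, {
    n <- 60
    y <- rep(c(TRUE, FALSE), length.out = n)
    bio <- rep(NA_integer_, n)
    bio[y] <- c(rep(1L, 27), rep(2L, 3))   # biotype 2 below the floor of 5
    x <- matrix(rnorm(n * 21), n, 21)
    x[y, 1:6] <- x[y, 1:6] + 2
  })
  va <- make_sep_panel(seed = 9, n = 30, p = 21)
  expect_warning(
    fit <- train_biotype_aware(x, y, bio, va$x, va$y, epochs = 30,
                               hidden = 4, seed = 8),
    "merged")
  expect_identical(fit$B, 1L)
  expect_named(predict(fit, va$x), c("subject_id", "s_1", "combined"))
})

test_that("one biotype with lambda 0 reduces to a monotone single-head model", {
  withr::with_seed(10, {
    n <- 60
    y <- rep(c(TRUE, FALSE), length.out = n)
    bio <- ifelse(y, 1L, NA_integer_)
    x <- matrix(rnorm(n * 21), n, 21)
    x[y, 1:6] <- x[y, 1:6] + 2
  })
  va <- make_sep_panel(seed = 11, n = 30, p = 21)
  fit <- train_biotype_aware(x, y, bio, va$x, va$y, lambda = 0, epochs = 40,
                             hidden = 4, seed = 10)
  sc <- predict(fit, va$x)
  # combined is a fixed increasing transform of the single head
  expect_identical(order(sc$combined), order(sc$s_1))
})

test_that("AUC equals pairwise concordance and survives monotone transforms", {
  expect_equal(auc(c(0.9, 0.8, 0.7, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auc(c(0.9, 0.6, 0.7, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  withr::with_seed(12, {
    sc <- rnorm(200)
    lab <- rbinom(200, 1, 0.4) == 1
    sc[30:40] <- sc[41]   # deliberate ties
  })
  expect_equal(auc(sc, lab), brute_auc(sc, lab), tolerance = 1e-12)
  expect_equal(auc(sc, lab),
               as.numeric(suppressMessages(pROC::auc(lab, sc,
                                                     direction = "<"))),
               tolerance = 1e-12)
  # invariance under strictly monotone transforms
  expect_equal(auc(exp(sc / 2), lab), auc(sc, lab))
  expect_error(auc(sc, rep(TRUE, 200)), class = "fcbiotype_input_error")
  # independent scores sit at chance on average
  m <- mean(vapply(1:100, function(s) {
    withr::with_seed(s, auc(rnorm(1000), rbinom(1000, 1, 0.5) == 1))
  }, numeric(1)))
  expect_lt(abs(m - 0.5), 0.01)
})

test_that("the G-score is the geometric mean of sensitivity and specificity", {
  expect_equal(gscore(1, 1), 1)
  expect_equal(gscore(0, 0.8), 0)
  expect_equal(gscore(0.9, 0.4), 0.6)
  expect_equal(gscore(0.3, 0.7), gscore(0.7, 0.3))
  expect_lte(gscore(0.3, 0.7), (0.3 + 0.7) / 2)   # AM-GM
  expect_error(gscore(1.2, 0.5), class = "fcbiotype_config_error")
})

test_that("threshold choice minimizes |specificity - sensitivity|", {
  # brute-force scan over all candidate midpoints on a toy set
  withr::with_seed(13, {
    sc <- round(runif(30), 2)
    lab <- rbinom(30, 1, 0.5) == 1
  })
  thr <- choose_threshold(sc, lab)
  u <- sort(unique(sc))
  cand <- (head(u, -1) + tail(u, -1)) / 2
  gaps <- vapply(cand, function(tt) {
    pred <- sc > tt
    abs(sum(!pred & !lab) / sum(!lab) - sum(pred & lab) / sum(lab))
  }, numeric(1))
  expect_equal(abs(thr$specificity - thr$sensitivity), min(gaps),
               tolerance = 1e-12)

  # perfectly separated scores balance at 1/1 in the gap
  thr2 <- choose_threshold(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(thr2$sensitivity, 1)
  expect_equal(thr2$specificity, 1)
  expect_equal(thr2$threshold, 0.5)

  # symmetric score distributions balance within 0.05
  withr::with_seed(14, {
    scores <- c(rnorm(500, 1), rnorm(500, -1))
  })
  labs <- rep(c(TRUE, FALSE), each = 500)
  thr3 <- choose_threshold(scores, labs)
  expect_lte(abs(thr3$specificity - thr3$sensitivity), 0.05)
  expect_error(choose_threshold(scores, rep(TRUE, 1000)),
               class = "fcbiotype_input_error")
})
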