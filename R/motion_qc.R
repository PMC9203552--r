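#' Six-parameter rigid-body motion trace
#'
#' Container for per-frame realignment parameters: translations `dx`, `dy`,
#' `dz` in mm and rotations `rot_x`, `rot_y`, `rot_z` in radians, at a fixed
#' frame period `tr` (seconds).
#'
#' @param dx,dy,dz per-frame translations (mm).
#' @param rot_x,rot_y,rot_z per-frame rotations (radians).
#' @param tr frame period in seconds.
#' @return tibble of class `motion_trace` with a `tr` attribute.
#' @export
motion_trace <- function(dx, dy, dz, rot_x, rot_y, rot_z, tr = 0.72) {
  lens <- lengths(list(dx, dy, dz, rot_x, rot_y, rot_z))
  if (length(unique(lens)) != 1L) {
    stop_fcb("all six motion series must have equal length",
             "fcbiotype_input_error")
  }
  if (lens[1] < 2L) {
    stop_fcb("a motion trace needs at least 2 frames", "fcbiotype_input_error")
  }
  out <- tibble::tibble(frame = seq_len(lens[1]), dx = dx, dy = dy, dz = dz,
                        rot_x = rot_x, rot_y = rot_y, rot_z = rot_z)
  structure(out, tr = tr, class = c("motion_trace", class(out)))
}

#' ROI/voxel BOLD time-series panel
#'
#' @param data frames x units numeric matrix of % BOLD intensities, no
#'   missing values.
#' @param tr frame period in seconds.
#' @return object of class `ts_panel`.
#' @export
ts_panel <- function(data, tr = 0.72) {
  data <- as.matrix(data)
  if (nrow(data) < 2L) {
    stop_fcb("a time-series panel needs at least 2 frames",
             "fcbiotype_input_error")
  }
  if (anyNA(data)) {
    stop_fcb("time-series panel contains missing values",
             "fcbiotype_input_error")
  }
  structure(list(data = data, tr = tr), class = "ts_panel")
}

#' @export
print.ts_panel <- function(x, ...) {
  cat(sprintf("<ts_panel> %d frames x %d units, TR = %g s\n",
              nrow(x$data), ncol(x$data), x$tr))
  invisible(x)
}

#' Framewise displacement
#'
#' Per-frame head-motion summary: the sum of the absolute first differences
#' of the six realignment parameters,
#' `FD(t) = |d dx| + |d dy| + |d dz| + |d a| + |d b| + |d g|`,
#' with rotational differences converted to arc length on a 50 mm sphere by
#' default so the conventional 0.2 mm threshold applies. `FD(1) = 0` since
#' no differential exists at the first frame.
#'
#' @param trace a [motion_trace()].
#' @param rotation_radius sphere radius (mm) for the rotation-to-displacement
#'   conversion; set `rotation_arc = FALSE` to sum raw angular differences
#'   instead (the literal printed formula).
#' @param rotation_arc convert rotations to mm arc length (default TRUE).
#' @return nonnegative numeric vector, one value per frame.
#' @export
framewise_displacement <- function(trace, rotation_radius = 50,
                                   rotation_arc = TRUE) {
  stopifnot(inherits(trace, "motion_trace"))
  rmul <- if (rotation_arc) rotation_radius else 1
  d <- abs(apply(as.matrix(trace[, c("dx", "dy", "dz")]), 2, diff))
  r <- abs(apply(as.matrix(trace[, c("rot_x", "rot_y", "rot_z")]), 2, diff))
  fd <- rowSums(d) + rmul * rowSums(r)
  c(0, fd)
}

#' DVARS: RMS frame-to-frame BOLD change
#'
#' `DVARS(t) = sqrt(mean_units((I(t) - I(t-1))^2))`, the root of the
#' across-unit mean squared intensity change between consecutive frames.
#' `DVARS(1) = 0`.
#'
#' @param panel a [ts_panel()] or frames x units matrix.
#' @return nonnegative numeric vector, one value per frame.
#' @export
dvars <- function(panel) {
  m <- if (inherits(panel, "ts_panel")) panel$data else as.matrix(panel)
  if (nrow(m) < 2L || ncol(m) < 1L) {
    stop_fcb("dvars needs >= 2 frames and >= 1 unit", "fcbiotype_input_error")
  }
  d <- diff(m)
  c(0, sqrt(rowMeans(d^2)))
}

#' Build a frame-censoring mask from FD and DVARS
#'
#' Frames with `FD > fd_thresh` or `DVARS > dvars_thresh` are outliers; each
#' outlier censors itself plus `pre` frames before and `post` frames after.
#' Surviving contiguous runs shorter than `min_segment` frames are then
#' censored as well. The rules are idempotent: reapplying them to the kept
#' set changes nothing.
#'
#' @param fd,dvars per-frame series of equal length (see
#'   [framewise_displacement()], [dvars()]).
#' @param fd_thresh FD threshold in mm (default 0.2).
#' @param dvars_thresh DVARS threshold on the % BOLD change scale (default 75).
#' @param pre,post frames censored before/after each outlier (default 1 and 2).
#' @param min_segment minimum length of a kept run (default 5).
#' @return tibble of class `censor_mask` with columns `frame` and `kept`;
#'   attributes `n_censored` and `n_kept`.
#' @export
censor_frames <- function(fd, dvars, fd_thresh = 0.2, dvars_thresh = 75,
                          pre = 1L, post = 2L, min_segment = 5L) {
  if (length(fd) != length(dvars)) {
    stop_fcb("fd and dvars must have the same length", "fcbiotype_input_error")
  }
  n <- length(fd)
  censored <- logical(n)
  for (t in which(fd > fd_thresh | dvars > dvars_thresh)) {
    censored[max(1L, t - pre):min(n, t + post)] <- TRUE
  }
  # short-segment exclusion on the kept runs
  r <- rle(!censored)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values & r$lengths < min_segment)) {
    censored[starts[j]:ends[j]] <- TRUE
  }
  out <- tibble::tibble(frame = seq_len(n), kept = !censored)
  structure(out, n_censored = sum(censored), n_kept = sum(!censored),
            class = c("censor_mask", class(out)))
}

#' Count of censored frames in a mask
#'
#' The total number of censored frames is the head-motion covariate used in
#' FC residualization.
#'
#' @param mask a `censor_mask`.
#' @return integer count.
#' @export
n_censored <- function(mask) {
  stopifnot(inherits(mask, "censor_mask"))
  sum(!mask$kept)
}

#' Temporal band-pass filter for BOLD low-frequency fluctuations
#'
#' Zero-phase Butterworth filtering retaining 0.009 Hz < f < 0.08 Hz by
#' default, realized as an order-2 high-pass cascaded with an order-2
#' low-pass (each applied forward-backward with [signal::filtfilt()], which
#' squares the magnitude response and cancels phase). The DC component is
#' removed; pass-band sinusoids retain at least 90% amplitude and stop-band
#' sinusoids at twice the upper edge are attenuated below 20%.
#'
#' @param panel a [ts_panel()].
#' @param low,high band edges in Hz; `high` must be below the Nyquist
#'   frequency `1 / (2 * tr)`.
#' @return filtered [ts_panel()].
#' @export
bandpass <- function(panel, low = 0.009, high = 0.08) {
  stopifnot(inherits(panel, "ts_panel"))
  fs <- 1 / panel$tr
  nyq <- fs / 2
  if (high >= nyq) {
    stop_fcb(sprintf("upper band edge %g Hz is not below Nyquist %g Hz",
                     high, nyq), "fcbiotype_config_error")
  }
  if (low <= 0 || low >= high) {
    stop_fcb("band edges must satisfy 0 < low < high", "fcbiotype_config_error")
  }
  hp <- signal::butter(2, low / nyq, type = "high")
  lp <- signal::butter(2, high / nyq, type = "low")
  m <- apply(panel$data, 2, function(x) {
    x <- x - mean(x)
    x <- signal::filtfilt(hp, x)
    signal::filtfilt(lp, x)
  })
  ts_panel(m, tr = panel$tr)
}

#' FC vector from a time-series panel over uncensored frames
#'
#' Pearson correlations between all ROI pairs computed on kept frames only,
#' vectorized over the strict upper triangle in row-major order (the order
#' reported by [fc_index_map()]). Subjects with fewer than 3 kept frames
#' cannot yield a correlation and are rejected, mirroring poor-image-quality
#' exclusions.
#'
#' @param panel a [ts_panel()] whose columns are ROI series.
#' @param mask optional `censor_mask` (default: all frames kept).
#' @return numeric vector of length `n_roi * (n_roi - 1) / 2`, values in
#'   \[-1, 1\].
#' @export
fc_vector <- function(panel, mask = NULL) {
  stopifnot(inherits(panel, "ts_panel"))
  m <- panel$data
  if (ncol(m) < 2L) {
    stop_fcb("fc_vector needs at least 2 ROIs", "fcbiotype_input_error")
  }
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "censor_mask"), nrow(mask) == nrow(m))
    m <- m[mask$kept, , drop = FALSE]
  }
  if (nrow(m) < 3L) {
    stop_fcb("fewer than 3 kept frames: subject flagged for exclusion",
             "fcbiotype_exclusion_error")
  }
  upper_tri_vec(cor(m))
}

#' Fit the covariate residualization model on the training split
#'
#' Regresses each FC feature on age, sex and head motion (total censored
#' frames) by ordinary least squares over the training subjects. The model is
#' frozen: validation and replication panels are adjusted with these
#' training coefficients, never refit.
#'
#' @param train_fc training subjects x features FC matrix.
#' @param covariates data frame aligned with `train_fc` rows, with columns
#'   `age` (years), `sex` (0/1) and `censored_frames`.
#' @return object of class `residual_model` holding the per-feature
#'   coefficients and the training feature means.
#' @export
fit_residual_model <- function(train_fc, covariates) {
  train_fc <- as.matrix(train_fc)
  X <- residual_design(covariates, nrow(train_fc))
  beta <- qr.solve(X, train_fc)            # (4 x p) coefficients
  structure(list(beta = beta, train_mean = colMeans(train_fc)),
            class = "residual_model")
}

residual_design <- function(covariates, n) {
  need <- c("age", "sex", "censored_frames")
  if (!all(need %in% names(covariates))) {
    stop_fcb("covariates must contain age, sex and censored_frames",
             "fcbiotype_input_error")
  }
  if (nrow(covariates) != n) {
    stop_fcb("covariate rows do not match the FC panel", "fcbiotype_input_error")
  }
  cbind(intercept = 1, age = covariates$age, sex = covariates$sex,
        motion = covariates$censored_frames)
}

#' Apply a fitted residualization model to any split
#'
#' Adjusted feature = raw value minus the fitted covariate part, with the
#' training mean retained as the intercept, i.e.
#' `adjusted = y - X beta + mean_train`. Training residuals are orthogonal to
#' the covariates; other splits reuse the frozen training coefficients.
#'
#' @param model a `residual_model` from [fit_residual_model()].
#' @param fc subjects x features FC matrix (any split).
#' @param covariates covariate data frame aligned with `fc` rows.
#' @return adjusted FC matrix of the same shape.
#' @export
apply_residual_model <- function(model, fc, covariates) {
  if (!inherits(model, "residual_model")) {
    stop_fcb("`model` is not a fitted residual_model", "fcbiotype_state_error")
  }
  fc <- as.matrix(fc)
  X <- residual_design(covariates, nrow(fc))
  adj <- fc - X %*% model$beta
  sweep(adj, 2, model$train_mean, "+")
}
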