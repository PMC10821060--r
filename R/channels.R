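#' Preprocess a trial into its derived channel groups
#'
#' Resamples the trial to a uniform grid at its nominal rate if necessary,
#' estimates and removes gravity, and caches the four channel groups the
#' method grid draws from: linear (gravity-free) acceleration, the gravity
#' vector, the gyroscope and the magnetometer, each T x 3 in the sensor
#' frame.
#'
#' @param trial an [imu_trial()].
#' @param gravity `"six_axis"` (orientation filter, default) or `"lowpass"`
#'   (accelerometer-only estimate, used by the acceleration-only ablation).
#' @param filter_params parameters for [estimate_gravity()].
#' @param lowpass_cutoff_hz cutoff for [lowpass_gravity()].
#' @return a `channel_store` holding the channel groups plus trial metadata.
#' @export
preprocess_trial <- function(trial, gravity = c("six_axis", "lowpass"),
                             filter_params = orientation_filter_params(),
                             lowpass_cutoff_hz = 0.5) {
  gravity <- match.arg(gravity)
  trial <- resample_trial(trial)
  est <- if (gravity == "six_axis")
    estimate_gravity(trial, filter_params)
  else
    lowpass_gravity(trial, lowpass_cutoff_hz)
  structure(
    list(trial_id = trial$trial_id, task_id = trial$task_id,
         movement_type = trial$movement_type, quality = trial$quality,
         setting = trial$setting, fs = trial$fs_nominal,
         n = nrow(trial$samples),
         lin_acc = unname(est$lin_acc), grav = unname(est$gravity),
         gyro = unname(trial_gyro(trial)), mag = unname(trial_mag(trial)),
         gravity_method = gravity),
    class = "channel_store")
}

#' Assemble the channel matrix for a method configuration
#'
#' Stacks the selected channel groups column-wise in the canonical order
#' `lin_acc, grav, gyro, mag` (only those selected), yielding the T x C
#' matrix that enters dynamic time warping.
#'
#' @param store a `channel_store` from [preprocess_trial()].
#' @param channels nonempty subset of
#'   `c("lin_acc", "grav", "gyro", "mag")`, or a [method_config()] whose
#'   channel set is used.
#' @return numeric matrix with a `channels` attribute naming the columns.
#' @export
assemble_channels <- function(store, channels) {
  if (inherits(channels, "method_config")) channels <- channels$channels
  if (length(channels) == 0)
    stop("empty channel set", call. = FALSE)
  bad <- setdiff(channels, .CHANNEL_GROUPS)
  if (length(bad))
    stop("unknown channel group(s): ", paste(bad, collapse = ","),
         call. = FALSE)
  groups <- .CHANNEL_GROUPS[.CHANNEL_GROUPS %in% channels]
  m <- do.call(cbind, lapply(groups, function(g) store[[g]]))
  attr(m, "channels") <- channel_labels(groups)
  m
}

#' Per-axis normalization scales from lab reference trials
#'
#' One standard deviation per channel column, computed over the
#' concatenation of the participant's lab trials (sample convention, n-1).
#' The same lab-derived scales are later applied to home trials, keeping
#' home classification causal with respect to the reference data. A channel
#' that is constant across all lab trials gets scale 1 with a warning.
#'
#' @param mats list of channel matrices sharing one channel set.
#' @return numeric vector of strictly positive per-channel scales, class
#'   `axis_scales`.
#' @export
compute_axis_scales <- function(mats) {
  if (length(mats) == 0) stop("empty trial list", call. = FALSE)
  labels <- attr(mats[[1]], "channels")
  all_rows <- do.call(rbind, mats)
  if (nrow(all_rows) < 2)
    stop("need at least 2 total samples per channel", call. = FALSE)
  sds <- apply(all_rows, 2, stats::sd)
  zero <- sds <= 0 | !is.finite(sds)
  if (any(zero)) {
    warning("constant channel(s) ",
            paste(which(zero), collapse = ","),
            ": normalization scale set to 1", call. = FALSE)
    sds[zero] <- 1
  }
  structure(sds, channels = labels, class = "axis_scales")
}

#' Normalize a channel matrix by per-axis scales
#'
#' Division only (no centering): column c is divided by its scale.
#'
#' @param mat channel matrix from [assemble_channels()].
#' @param scales an `axis_scales` vector aligned with `mat`'s columns.
#' @return normalized matrix with the same `channels` attribute.
#' @export
normalize_channels <- function(mat, scales) {
  if (ncol(mat) != length(scales))
    stop("scale / channel mismatch", call. = FALSE)
  lm <- attr(mat, "channels")
  ls <- attr(scales, "channels")
  if (!is.null(lm) && !is.null(ls) && !identical(lm, ls))
    stop("scale / channel label mismatch", call. = FALSE)
  out <- sweep(mat, 2, as.numeric(scales), "/")
  attr(out, "channels") <- lm
  out
}

# assemble + optional normalization for a list of stores sharing a task;
# scales are always computed from the lab stores only
prepare_matrices <- function(lab_stores, other_stores = list(), method) {
  lab_mats <- lapply(lab_stores, assemble_channels, channels = method)
  other_mats <- lapply(other_stores, assemble_channels, channels = method)
  if (isTRUE(method$normalize)) {
    scales <- compute_axis_scales(lab_mats)
    lab_mats <- lapply(lab_mats, normalize_channels, scales = scales)
    other_mats <- lapply(other_mats, normalize_channels, scales = scales)
  } else {
    scales <- NULL
  }
  list(lab = lab_mats, other = other_mats, scales = scales)
}
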