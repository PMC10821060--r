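.trial_counter <- new.env(parent = emptyenv())
.trial_counter$n <- 0L

#' Construct a single IMU trial
#'
#' An `imu_trial` holds one task repetition recorded by a wrist-worn 9-axis
#' inertial measurement unit: a regularly-sampled table of accelerometer
#' (m/s^2), gyroscope (rad/s) and magnetometer (uT) readings in the sensor
#' frame, plus the trial's metadata (participant, task, setting, therapist
#' movement-type and quality annotations).
#'
#' All channels use SI units internally; [read_trial()] converts declared
#' source units on ingest.
#'
#' @param samples data frame with columns `t, ax, ay, az, gx, gy, gz,
#'   mx, my, mz`; `t` in seconds since trial start, strictly increasing.
#' @param participant_id opaque participant identifier.
#' @param task_id task identifier (integer or string).
#' @param setting `"lab"` or `"home"`.
#' @param movement_type free-text movement-type annotation (e.g. `"correct"`,
#'   `"shoulder_abduction"`). May be `""` only when `quality = "unknown"`.
#' @param quality `"correct"`, `"incorrect"` or `"unknown"` (home only).
#' @param fs_nominal nominal sampling rate, Hz.
#' @param trial_id optional unique trial identifier.
#' @return an object of class `imu_trial`.
#' @export
imu_trial <- function(samples, participant_id, task_id,
                      setting = c("lab", "home"),
                      movement_type = "", quality = c("correct", "incorrect",
                                                      "unknown"),
                      fs_nominal = 100, trial_id = NULL) {
  setting <- match.arg(setting)
  quality <- match.arg(quality)
  cols <- c("t", "ax", "ay", "az", "gx", "gy", "gz", "mx", "my", "mz")
  if (!is.data.frame(samples) || !all(cols %in% names(samples)))
    stop("samples must contain columns ", paste(cols, collapse = ","),
         call. = FALSE)
  samples <- samples[cols]
  if (nrow(samples) < 2)
    stop("a trial needs at least 2 samples", call. = FALSE)
  if (!all(vapply(samples, function(x) all(is.finite(x)), logical(1))))
    stop("non-finite sample values", call. = FALSE)
  dt <- diff(samples$t)
  if (any(dt <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  if (samples$t[1] < 0)
    stop("timestamps must be nonnegative", call. = FALSE)
  med_dt <- stats::median(dt)
  if (abs(med_dt - 1 / fs_nominal) > 0.2 / fs_nominal)
    stop("median sampling interval deviates more than 20% from nominal",
         call. = FALSE)
  if (quality != "unknown" && !nzchar(movement_type))
    stop("labeled trials need a nonempty movement_type", call. = FALSE)
  if (setting == "lab" && quality == "unknown")
    stop("lab trials must be labeled correct or incorrect", call. = FALSE)
  if (is.null(trial_id)) {
    # deterministic fallback id; callers building sessions should pass ids
    .trial_counter$n <- .trial_counter$n + 1L
    trial_id <- sprintf("%s_task%s_%06d", setting, task_id, .trial_counter$n)
  }
  structure(
    list(participant_id = as.character(participant_id),
         task_id = as.character(task_id), setting = setting,
         movement_type = as.character(movement_type), quality = quality,
         fs_nominal = fs_nominal, trial_id = as.character(trial_id),
         samples = samples),
    class = "imu_trial")
}

#' @export
print.imu_trial <- function(x, ...) {
  cat(sprintf(
    "<imu_trial %s> participant %s, task %s, %s, type '%s' (%s)\n  %d samples @ %g Hz nominal (%.2f s)\n",
    x$trial_id, x$participant_id, x$task_id, x$setting, x$movement_type,
    x$quality, nrow(x$samples), x$fs_nominal,
    x$samples$t[nrow(x$samples)] - x$samples$t[1]))
  invisible(x)
}

#' Resample a trial to its nominal rate
#'
#' Trials whose median sampling interval deviates from nominal, or that were
#' recorded on an irregular grid, are linearly interpolated onto a uniform
#' grid at `fs_nominal` so that every trial entering dynamic time warping has
#' a consistent sampling rate.
#'
#' @param trial an [imu_trial()].
#' @param tol relative deviation of the median sampling interval below which
#'   the trial is returned unchanged (default 1%).
#' @return an `imu_trial` on a uniform time grid.
#' @export
resample_trial <- function(trial, tol = 0.01) {
  s <- trial$samples
  dt_nom <- 1 / trial$fs_nominal
  dt <- diff(s$t)
  uniform <- max(abs(dt - dt_nom)) <= tol * dt_nom
  if (uniform) return(trial)
  tt <- seq(s$t[1], s$t[nrow(s)], by = dt_nom)
  out <- data.frame(t = tt)
  for (col in setdiff(names(s), "t"))
    out[[col]] <- stats::approx(s$t, s[[col]], xout = tt, rule = 2)$y
  trial$samples <- out
  trial
}

# matrix accessors (T x 3)
trial_acc <- function(trial) as.matrix(trial$samples[c("ax", "ay", "az")])
trial_gyro <- function(trial) as.matrix(trial$samples[c("gx", "gy", "gz")])
trial_mag <- function(trial) as.matrix(trial$samples[c("mx", "my", "mz")])

#' Construct a session of trials
#'
#' A session groups one participant's trials recorded in one setting. A lab
#' session is the reference set used for method selection and classification
#' and must contain, for every task, at least two movement types with at
#' least two trials each, including at least one correct and one incorrect
#' type.
#'
#' @param trials list of [imu_trial()] objects.
#' @param validate_lab enforce the lab reference-set invariants when
#'   `setting = "lab"`.
#' @return an object of class `imu_session`.
#' @export
imu_session <- function(trials, validate_lab = TRUE) {
  if (length(trials) == 0) stop("empty session", call. = FALSE)
  if (!all(vapply(trials, inherits, logical(1), "imu_trial")))
    stop("all elements must be imu_trial objects", call. = FALSE)
  pid <- unique(vapply(trials, `[[`, character(1), "participant_id"))
  if (length(pid) != 1)
    stop("all trials in a session must share one participant_id",
         call. = FALSE)
  setting <- unique(vapply(trials, `[[`, character(1), "setting"))
  if (length(setting) != 1)
    stop("all trials in a session must share one setting", call. = FALSE)
  ids <- vapply(trials, `[[`, character(1), "trial_id")
  if (anyDuplicated(ids))
    stop("duplicate trial ids in session", call. = FALSE)
  if (setting == "lab" && validate_lab) {
    for (task in unique(vapply(trials, `[[`, character(1), "task_id"))) {
      tr <- trials[vapply(trials, `[[`, character(1), "task_id") == task]
      types <- vapply(tr, `[[`, character(1), "movement_type")
      quals <- vapply(tr, `[[`, character(1), "quality")
      tab <- table(types)
      if (length(tab) < 2 || any(tab < 2))
        stop(sprintf(
          "lab task %s needs >= 2 movement types with >= 2 trials each",
          task), call. = FALSE)
      if (!all(c("correct", "incorrect") %in% quals))
        stop(sprintf("lab task %s needs correct and incorrect trials", task),
             call. = FALSE)
    }
  }
  structure(list(participant_id = pid, setting = setting, trials = trials),
            class = "imu_session")
}

#' @export
print.imu_session <- function(x, ...) {
  tasks <- vapply(x$trials, `[[`, character(1), "task_id")
  cat(sprintf("<imu_session> participant %s, %s: %d trials over %d task(s)\n",
              x$participant_id, x$setting, length(x$trials),
              length(unique(tasks))))
  invisible(x)
}

# trials of one task, in session order
session_task_trials <- function(session, task_id) {
  keep <- vapply(session$trials, `[[`, character(1), "task_id") ==
    as.character(task_id)
  session$trials[keep]
}

session_tasks <- function(session)
  unique(vapply(session$trials, `[[`, character(1), "task_id"))
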