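# quaternion utilities; q = c(w, x, y, z), unit, sensor-to-world rotation

quat_mul <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_conj <- function(q) c(q[1], -q[2], -q[3], -q[4])

quat_normalize <- function(q) q / sqrt(sum(q * q))

quat_from_rotvec <- function(v) {
  th <- sqrt(sum(v * v))
  if (th < 1e-12) quat_normalize(c(1, v / 2)) else
    c(cos(th / 2), sin(th / 2) * v / th)
}

# rotate vector v by quaternion q (sensor frame -> world frame)
quat_rotate <- function(q, v) {
  t <- 2 * cross3(q[2:4], v)
  v + q[1] * t + cross3(q[2:4], t)
}

# world frame -> sensor frame
quat_rotate_inv <- function(q, v) quat_rotate(quat_conj(q), v)

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# quaternion from rotation matrix (sensor-to-world), Shepperd's method
quat_from_matrix <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, s / 4, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, s / 4,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, s / 4)
  }
  quat_normalize(q)
}

#' Default parameters for the six-axis orientation filter
#'
#' The filter integrates the gyroscope for orientation prediction and
#' corrects the predicted tilt toward the accelerometer's gravity direction
#' with a fixed (steady-state) gain. `acc_tau` is the time constant of that
#' correction: the per-sample blend weight is `dt / (acc_tau + dt)`, i.e. a
#' larger `acc_tau` trusts the gyroscope longer. `acc_gate` disables the
#' correction when the accelerometer magnitude deviates from standard
#' gravity by more than the given fraction, so that strong movement-induced
#' acceleration does not corrupt the tilt estimate.
#'
#' @param acc_tau accelerometer-correction time constant, seconds.
#' @param acc_gate relative magnitude gate (fraction of g).
#' @return list of filter parameters.
#' @export
orientation_filter_params <- function(acc_tau = 0.5, acc_gate = 0.2) {
  stopifnot(acc_tau > 0, acc_gate > 0)
  list(acc_tau = acc_tau, acc_gate = acc_gate)
}

#' Estimate orientation and gravity from accelerometer and gyroscope
#'
#' Runs a six-axis (accelerometer + gyroscope, no magnetometer) orientation
#' filter over a trial: gyroscope rates are integrated into a unit
#' quaternion and the tilt is continuously corrected toward the measured
#' gravity direction with a fixed steady-state gain. The filter is
#' initialized from the tilt implied by the first accelerometer sample. The
#' estimated gravity vector (sensor frame, magnitude 9.80665 m/s^2) is then
#' subtracted from the accelerometer stream to obtain linear (gravity-free)
#' acceleration.
#'
#' @param trial an [imu_trial()]; duration must be at least 0.5 s.
#' @param params see [orientation_filter_params()].
#' @return list with `orientation` (T x 4 unit quaternions, sensor-to-world),
#'   `gravity` (T x 3, m/s^2, sensor frame) and `lin_acc` (T x 3, m/s^2),
#'   satisfying `gravity + lin_acc == accelerometer` exactly.
#' @export
estimate_gravity <- function(trial, params = orientation_filter_params()) {
  acc <- unname(trial_acc(trial))
  gyro <- unname(trial_gyro(trial))
  tt <- trial$samples$t
  n <- nrow(acc)
  if (tt[n] - tt[1] < 0.5)
    stop("trial shorter than 0.5 s: orientation filter cannot settle",
         call. = FALSE)
  norms <- sqrt(rowSums(acc^2))
  if (max(norms) < 1e-6)
    stop("all-zero accelerometer: orientation unobservable", call. = FALSE)

  zup <- c(0, 0, 1)
  # initialize from the first sample's tilt (yaw is unobservable and set to 0)
  a0 <- acc[1, ] / max(norms[1], 1e-12)
  ax <- cross3(a0, zup)
  s <- sqrt(sum(ax^2))
  d <- sum(a0 * zup)
  q <- if (s < 1e-12) {
    if (d > 0) c(1, 0, 0, 0) else c(0, 1, 0, 0)  # upside down: 180 deg about x
  } else {
    quat_from_rotvec(atan2(s, d) * ax / s)
  }

  quats <- matrix(0, n, 4)
  quats[1, ] <- q
  g0 <- .GRAVITY
  for (k in 2:n) {
    dt <- tt[k] - tt[k - 1]
    # gyro prediction (body rates, right multiplication)
    q <- quat_normalize(quat_mul(q, quat_from_rotvec(gyro[k - 1, ] * dt)))
    # accelerometer tilt correction, gated on magnitude
    na <- norms[k]
    if (abs(na - g0) / g0 <= params$acc_gate) {
      au <- acc[k, ] / na
      v <- quat_rotate_inv(q, zup)       # predicted gravity direction (body)
      u <- cross3(v, au)
      su <- sqrt(sum(u * u))
      if (su > 1e-12) {
        th <- atan2(su, sum(v * au))
        kk <- dt / (params$acc_tau + dt)
        # right-multiplied correction rotates the predicted direction toward
        # the measured one by the fraction kk of the error angle
        q <- quat_normalize(quat_mul(q, quat_from_rotvec(-kk * th * u / su)))
      }
    }
    quats[k, ] <- q
  }

  gravity <- t(apply(quats, 1, function(qk)
    quat_rotate_inv(qk, c(0, 0, g0))))
  lin_acc <- acc - gravity
  list(orientation = quats, gravity = gravity, lin_acc = lin_acc)
}

#' Accelerometer-only gravity estimate (low-pass)
#'
#' For devices logging only the accelerometer there is no gyroscope to drive
#' a six-axis filter; gravity is instead estimated as the slowly-varying
#' component of the accelerometer signal via a zero-phase second-order
#' Butterworth low-pass filter. Used by the acceleration-only ablation.
#'
#' @param trial an [imu_trial()].
#' @param cutoff_hz low-pass cutoff frequency (default 0.5 Hz).
#' @return list with `gravity` and `lin_acc` (both T x 3, m/s^2), with
#'   `gravity + lin_acc` equal to the raw accelerometer stream.
#' @export
lowpass_gravity <- function(trial, cutoff_hz = 0.5) {
  acc <- unname(trial_acc(trial))
  fs <- trial$fs_nominal
  bf <- signal::butter(2, cutoff_hz / (fs / 2), type = "low")
  gravity <- apply(acc, 2, function(x) signal::filtfilt(bf, x))
  lin_acc <- acc - gravity
  list(gravity = gravity, lin_acc = lin_acc)
}
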