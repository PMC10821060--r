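# minimum-jerk ramp and its derivatives w.r.t. normalized time s in [0,1]
.mj <- function(s) 10 * s^3 - 15 * s^4 + 6 * s^5
.mj1 <- function(s) 30 * s^2 - 60 * s^3 + 30 * s^4
.mj2 <- function(s) 60 * s - 180 * s^2 + 120 * s^3

# symmetric bump (zero at both ends) and derivatives
.bump <- function(s) sin(pi * s)^2
.bump1 <- function(s) pi * sin(2 * pi * s)
.bump2 <- function(s) 2 * pi^2 * cos(2 * pi * s)

# profile value and first two s-derivatives under an optional smooth time
# warp w(s) = s + eps * sin(pi * s) (monotone for |eps| < 1/pi)
profile_eval <- function(ramp, bump, s, eps = 0) {
  w <- s + eps * sin(pi * s)
  w1 <- 1 + eps * pi * cos(pi * s)
  w2 <- -eps * pi^2 * sin(pi * s)
  v <- ramp * .mj(w) + bump * .bump(w)
  d1w <- ramp * .mj1(w) + bump * .bump1(w)
  d2w <- ramp * .mj2(w) + bump * .bump2(w)
  list(v = v, d1 = d1w * w1, d2 = d2w * w1^2 + d1w * w2)
}

# vectorized elementary rotations applied to an N x 3 matrix of vectors
rot_x <- function(v, a) {
  c_ <- cos(a); s_ <- sin(a)
  cbind(v[, 1], c_ * v[, 2] - s_ * v[, 3], s_ * v[, 2] + c_ * v[, 3])
}
rot_y <- function(v, a) {
  c_ <- cos(a); s_ <- sin(a)
  cbind(c_ * v[, 1] + s_ * v[, 3], v[, 2], -s_ * v[, 1] + c_ * v[, 3])
}
rot_z <- function(v, a) {
  c_ <- cos(a); s_ <- sin(a)
  cbind(c_ * v[, 1] - s_ * v[, 2], s_ * v[, 1] + c_ * v[, 2], v[, 3])
}

# world -> body: R^T v = Rx(-roll) Ry(-pitch) Rz(-yaw) v, vectorized
world_to_body <- function(v, roll, pitch, yaw) {
  rot_x(rot_y(rot_z(v, -yaw), -pitch), -roll)
}

#' A parametric movement template
#'
#' Encodes one movement type for one task as smooth orientation and
#' translation profiles over normalized time: each Euler angle
#' (roll/pitch/yaw, ZYX convention, sensor-to-world) is a minimum-jerk ramp
#' plus a symmetric bump, and the wrist position follows a minimum-jerk
#' displacement with an optional raised (bump) path component. Compensatory
#' movement types are encoded as modifications of the correct template:
#' added pitch ramps (trunk flexion), roll offsets with a raised path
#' (shoulder abduction/hike), sharper translation with extra wrist
#' extension (compensatory grip), truncation (unable to complete), or
#' near-stationary scaled-down motion (nonparetic-hand assist).
#'
#' @param task_id task identifier.
#' @param movement_type type label (e.g. `"correct"`, `"trunk_shoulder"`).
#' @param quality `"correct"` or `"incorrect"`.
#' @param duration_mean,duration_sd trial duration, seconds
#'   (`duration_sd < duration_mean / 3`).
#' @param roll,pitch,yaw length-2 numeric `c(ramp, bump)` amplitudes,
#'   radians.
#' @param disp world-frame displacement endpoint (m), minimum-jerk.
#' @param path_bump world-frame bump component of the path (m), e.g. peak
#'   lift height in z.
#' @param truncate `NULL`, or `c(lo, hi)`: the trial stops at a uniformly
#'   drawn fraction of its full duration (incomplete movement).
#' @param amp_scale overall motion amplitude multiplier.
#' @return object of class `movement_template`.
#' @export
movement_template <- function(task_id, movement_type, quality,
                              duration_mean, duration_sd,
                              roll = c(0, 0), pitch = c(0, 0),
                              yaw = c(0, 0), disp = c(0, 0, 0),
                              path_bump = c(0, 0, 0), truncate = NULL,
                              amp_scale = 1) {
  stopifnot(duration_mean > 0, duration_sd >= 0,
            duration_sd < duration_mean / 3)
  if (!is.null(truncate))
    stopifnot(length(truncate) == 2, truncate[1] > 0,
              truncate[2] <= 1, truncate[1] <= truncate[2])
  structure(list(task_id = as.character(task_id),
                 movement_type = movement_type, quality = quality,
                 duration_mean = duration_mean, duration_sd = duration_sd,
                 roll = roll, pitch = pitch, yaw = yaw,
                 disp = disp, path_bump = path_bump,
                 truncate = truncate, amp_scale = amp_scale),
            class = "movement_template")
}

#' Sensor noise and inter-trial variability model
#'
#' Defaults are typical of consumer-grade MEMS inertial sensors and of the
#' trial-to-trial variability of repeated reaching movements: white
#' accelerometer/gyroscope/magnetometer noise, a slow gyroscope bias random
#' walk, a multiplicative amplitude jitter on the whole movement, and a
#' smooth within-trial time warp whose standard deviation controls how much
#' the movement's tempo fluctuates around the template.
#'
#' @param acc_sd accelerometer noise sd, m/s^2.
#' @param gyro_sd gyroscope noise sd, rad/s.
#' @param gyro_bias_rw gyroscope bias random-walk sd, rad/s per sqrt(s).
#' @param mag_sd magnetometer noise sd, uT.
#' @param amplitude_sd sd of the per-trial amplitude multiplier.
#' @param warp_sd sd of the per-trial time-warp coefficient.
#' @return list of class `noise_model`.
#' @export
noise_model <- function(acc_sd = 0.05, gyro_sd = 0.005,
                        gyro_bias_rw = 1e-4, mag_sd = 0.5,
                        amplitude_sd = 0.05, warp_sd = 0.03) {
  vals <- c(acc_sd, gyro_sd, gyro_bias_rw, mag_sd, amplitude_sd, warp_sd)
  stopifnot(all(vals >= 0))
  structure(list(acc_sd = acc_sd, gyro_sd = gyro_sd,
                 gyro_bias_rw = gyro_bias_rw, mag_sd = mag_sd,
                 amplitude_sd = amplitude_sd, warp_sd = warp_sd),
            class = "noise_model")
}

#' Zero-noise, zero-variability model (for physical-consistency checks)
#' @export
#' @rdname noise_model
noise_free <- function() noise_model(0, 0, 0, 0, 0, 0)

#' Ground-truth kinematics of a template
#'
#' Evaluates a template's rotation, body angular velocity, world linear
#' acceleration and the ideal (noise-free) sensor streams at the given
#' sample times. Used internally by [simulate_trial()] and available for
#' validating that emitted signals are physically consistent with the
#' underlying rigid-body motion.
#'
#' @param template a [movement_template()].
#' @param t sample times, seconds.
#' @param duration the trial's full (untruncated) duration, seconds.
#' @param warp_eps realized time-warp coefficient.
#' @param mag_yaw_deg yaw offset of the earth's magnetic field, degrees.
#' @return list: `euler` (T x 3 roll/pitch/yaw), `omega_body` (T x 3,
#'   rad/s), `acc_world` (T x 3, m/s^2), `acc_body` (ideal accelerometer:
#'   specific force in the sensor frame), `grav_body`, `mag_body`, and `R`
#'   (3 x 3 x T sensor-to-world rotations).
#' @export
template_kinematics <- function(template, t, duration, warp_eps = 0,
                                mag_yaw_deg = 0) {
  s <- t / duration
  a <- template$amp_scale
  roll <- profile_eval(a * template$roll[1], a * template$roll[2], s,
                       warp_eps)
  pitch <- profile_eval(a * template$pitch[1], a * template$pitch[2], s,
                        warp_eps)
  yaw <- profile_eval(a * template$yaw[1], a * template$yaw[2], s,
                      warp_eps)
  # angle rates w.r.t. real time
  rd <- roll$d1 / duration
  pd <- pitch$d1 / duration
  yd <- yaw$d1 / duration
  cph <- cos(roll$v); sph <- sin(roll$v)
  cth <- cos(pitch$v); sth <- sin(pitch$v)
  # body rates for ZYX Euler angles (R = Rz(yaw) Ry(pitch) Rx(roll))
  omega <- cbind(rd - yd * sth,
                 pd * cph + yd * cth * sph,
                 -pd * sph + yd * cth * cph)
  # translation: world-frame acceleration
  acc_world <- vapply(seq_len(3), function(k) {
    pe <- profile_eval(a * template$disp[k], a * template$path_bump[k], s,
                       warp_eps)
    pe$d2 / duration^2
  }, numeric(length(s)))
  acc_world <- matrix(acc_world, ncol = 3)

  g_up <- matrix(rep(c(0, 0, .GRAVITY), each = length(s)), ncol = 3)
  acc_body <- world_to_body(acc_world + g_up, roll$v, pitch$v, yaw$v)
  grav_body <- world_to_body(g_up, roll$v, pitch$v, yaw$v)
  m_world_1 <- rot_z(matrix(.MAG_EARTH, 1), mag_yaw_deg * pi / 180)
  m_world <- matrix(rep(m_world_1, each = length(s)), ncol = 3)
  mag_body <- world_to_body(m_world, roll$v, pitch$v, yaw$v)

  R <- array(0, c(3, 3, length(s)))
  I3 <- diag(3)
  for (i in seq_along(s)) {
    # row j of world_to_body(I3) is R^T e_j, i.e. row j of R
    R[, , i] <- world_to_body(I3, roll$v[i], pitch$v[i], yaw$v[i])
  }
  list(euler = cbind(roll$v, pitch$v, yaw$v), omega_body = omega,
       acc_world = acc_world, acc_body = acc_body, grav_body = grav_body,
       mag_body = mag_body, R = R)
}

# earth magnetic field, uT: 50 uT at 60 degrees inclination, z up
.MAG_EARTH <- c(50 * cos(60 * pi / 180), 0, -50 * sin(60 * pi / 180))

with_preserved_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# per-trial seed derivation: one root seed plus a counter, so any subset of
# trials regenerates identically; kept below 2^31 - 1
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + counter * 1009 + 17) %%
               2147483629)
}

#' Simulate one IMU trial from a template
#'
#' Draws the trial's duration, amplitude multiplier and time-warp
#' coefficient, builds the true rigid-body motion from the template, and
#' emits the three sensor streams: accelerometer = specific force in the
#' sensor frame (movement acceleration plus the gravity reaction, i.e. a
#' level, motionless sensor reads `(0, 0, +9.80665)` m/s^2), gyroscope =
#' body-frame angular velocity plus bias random walk, magnetometer = earth
#' field (optionally yaw-offset, emulating a different heading of the home
#' environment) in the sensor frame. White noise is added per the noise
#' model. Deterministic given `seed`.
#'
#' @param template a [movement_template()].
#' @param noise a [noise_model()].
#' @param seed integer seed (the trial is deterministic given it); `NULL`
#'   uses the current RNG stream.
#' @param fs sampling rate, Hz.
#' @param setting `"lab"` or `"home"`.
#' @param participant_id participant identifier.
#' @param mag_yaw_deg magnetic-field yaw offset, degrees.
#' @param trial_id optional identifier.
#' @param labeled attach the template's type/quality labels (lab) or mark
#'   quality unknown (home ground truth is tracked separately).
#' @return an [imu_trial()] with the realized generation parameters
#'   attached as attribute `"sim_truth"`.
#' @export
simulate_trial <- function(template, noise = noise_model(), seed = NULL,
                           fs = 100, setting = "lab",
                           participant_id = "synthetic01",
                           mag_yaw_deg = 0, trial_id = NULL,
                           labeled = TRUE) {
  with_preserved_seed(seed, {
    dm <- template$duration_mean
    tau <- min(max(rnorm(1, dm, template$duration_sd), 0.6, dm / 2),
               2 * dm)
    amp <- max(1 + rnorm(1, 0, noise$amplitude_sd), 0.2)
    eps <- max(min(rnorm(1, 0, noise$warp_sd), 0.25), -0.25)
    frac <- if (is.null(template$truncate)) 1 else
      runif(1, template$truncate[1], template$truncate[2])
    tt <- seq(0, tau * frac, by = 1 / fs)
    if (length(tt) < max(2, round(0.6 * fs)))
      tt <- seq(0, 0.6, by = 1 / fs)   # floor so the filter can settle

    rt <- template
    rt$amp_scale <- template$amp_scale * amp
    kin <- template_kinematics(rt, tt, tau, eps, mag_yaw_deg)

    n <- length(tt)
    dt <- 1 / fs
    acc <- kin$acc_body +
      matrix(rnorm(3 * n, 0, noise$acc_sd), n, 3)
    bias <- apply(matrix(rnorm(3 * n, 0, noise$gyro_bias_rw * sqrt(dt)),
                         n, 3), 2, cumsum)
    gyro <- kin$omega_body + bias +
      matrix(rnorm(3 * n, 0, noise$gyro_sd), n, 3)
    mag <- kin$mag_body + matrix(rnorm(3 * n, 0, noise$mag_sd), n, 3)

    samples <- data.frame(t = tt, ax = acc[, 1], ay = acc[, 2],
                          az = acc[, 3], gx = gyro[, 1], gy = gyro[, 2],
                          gz = gyro[, 3], mx = mag[, 1], my = mag[, 2],
                          mz = mag[, 3])
    trial <- imu_trial(
      samples, participant_id = participant_id,
      task_id = template$task_id, setting = setting,
      movement_type = if (labeled) template$movement_type else "",
      quality = if (labeled) template$quality else "unknown",
      fs_nominal = fs, trial_id = trial_id)
    attr(trial, "sim_truth") <- list(template = rt, duration = tau,
                                     warp_eps = eps, frac = frac, t = tt,
                                     mag_yaw_deg = mag_yaw_deg)
    trial
  })
}

#' Default movement templates for the four functional tasks
#'
#' Four upper-limb object-manipulation tasks (reach and lift a cup to a
#' shelf, bring a cup to the mouth, move a block with tongs across the
#' body, move a small block with a precision grip), each with a correct
#' template and one characteristic compensatory/incomplete variant: trunk
#' flexion adds a pitch ramp to the reach; shoulder abduction adds a roll
#' offset and a raised path; the tongs task's incorrect variant is an
#' incomplete (truncated) movement; the precision-grip task's variant is a
#' compensatory whole-hand grip with faster, larger-amplitude translation
#' and extra wrist extension.
#'
#' @return named list (by task id) of lists of [movement_template()]s.
#' @export
default_templates <- function() {
  list(
    "1" = list(
      movement_template("1", "correct", "correct", 3.0, 0.25,
                        roll = c(0.1, 0.2), pitch = c(0.7, 0.3),
                        yaw = c(0.1, 0), disp = c(0.35, 0, 0.25),
                        path_bump = c(0, 0, 0.15)),
      movement_template("1", "trunk_shoulder", "incorrect", 3.2, 0.25,
                        roll = c(0.5, 0.2), pitch = c(1.2, 0.6),
                        yaw = c(0.1, 0), disp = c(0.35, 0, 0.3),
                        path_bump = c(0, 0, 0.3))),
    "2" = list(
      movement_template("2", "correct", "correct", 2.5, 0.2,
                        roll = c(0.3, 0.2), pitch = c(0.4, 0.8),
                        yaw = c(0, 0.2), disp = c(0.25, 0.05, 0.2),
                        path_bump = c(0, 0, 0.25)),
      movement_template("2", "shoulder_abduction", "incorrect", 2.7, 0.2,
                        roll = c(0.9, 0.4), pitch = c(0.4, 0.5),
                        yaw = c(0, 0.2), disp = c(0.25, 0.15, 0.2),
                        path_bump = c(0, 0.1, 0.4))),
    "3" = list(
      movement_template("3", "correct", "correct", 3.5, 0.3,
                        roll = c(0.2, 0.1), pitch = c(0.3, 0.2),
                        yaw = c(0.8, 0.2), disp = c(0.3, -0.4, 0.05),
                        path_bump = c(0, 0, 0.1)),
      movement_template("3", "unable_to_complete", "incorrect", 3.5, 0.3,
                        roll = c(0.2, 0.1), pitch = c(0.3, 0.2),
                        yaw = c(0.8, 0.2), disp = c(0.3, -0.4, 0.05),
                        path_bump = c(0, 0, 0.1),
                        truncate = c(0.35, 0.65))),
    "4" = list(
      movement_template("4", "correct", "correct", 3.0, 0.25,
                        roll = c(0.15, 0.1), pitch = c(0.35, 0.15),
                        yaw = c(0.2, 0.1), disp = c(0.3, 0, 0.05),
                        path_bump = c(0, 0, 0.08)),
      movement_template("4", "compensatory_grip", "incorrect", 2.4, 0.2,
                        roll = c(0.15, 0.1), pitch = c(0.7, 0.4),
                        yaw = c(0.2, 0.1), disp = c(0.3, 0, 0.05),
                        path_bump = c(0, 0, 0.2)))
  )
}

#' Templates for a purely gyroscope-differentiated scenario
#'
#' One task whose correct and incorrect variants are pure rotations about
#' the vertical axis with no translation: the gravity vector in the sensor
#' frame stays constant and the accelerometer carries no movement
#' information, so only the gyroscope distinguishes the two classes. Used
#' to probe whether method selection recovers gyroscope-bearing channel
#' sets and to demonstrate the cost of logging acceleration only.
#'
#' @return named list with one task's templates.
#' @export
gyro_scenario_templates <- function() {
  list(
    "1" = list(
      movement_template("1", "correct", "correct", 2.0, 0.15,
                        yaw = c(1.2, 0.3)),
      movement_template("1", "excess_rotation", "incorrect", 2.0, 0.15,
                        yaw = c(2.6, 0.9)))
  )
}

#' Synthetic study configuration
#'
#' Defaults mirror the data-collection design the generator emulates: four
#' functional tasks, two labeled movement types per task in the lab with 6
#' trials per quality (a number of repetitions feasible within one therapy
#' session), 75 home trials per task, mostly performed correctly, and a
#' home environment whose magnetic-field heading differs from the lab's.
#'
#' @param tasks template lists by task, see [default_templates()].
#' @param lab_trials_per_type lab trials per movement type (2 to 20).
#' @param home_trials_per_task home trials per task.
#' @param home_correct_fraction probability a home trial follows the
#'   correct template.
#' @param noise a [noise_model()].
#' @param participant_id identifier stamped on every trial.
#' @param mag_yaw_offset_home_deg home-vs-lab magnetic heading offset.
#' @param home_only_templates optional named list (task id -> template) of
#'   movement types that appear only at home (e.g. nonparetic-hand
#'   assist), absent from the lab references.
#' @param home_only_fraction fraction of incorrect home trials drawn from
#'   the home-only template where one exists.
#' @param fs sampling rate, Hz.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(tasks = default_templates(),
                             lab_trials_per_type = 6,
                             home_trials_per_task = 75,
                             home_correct_fraction = 0.8,
                             noise = noise_model(),
                             participant_id = "synthetic01",
                             mag_yaw_offset_home_deg = 45,
                             home_only_templates = list(),
                             home_only_fraction = 0,
                             fs = 100) {
  stopifnot(lab_trials_per_type >= 2, lab_trials_per_type <= 20,
            home_trials_per_task >= 1,
            home_correct_fraction >= 0, home_correct_fraction <= 1,
            home_only_fraction >= 0, home_only_fraction <= 1)
  for (tk in names(tasks)) {
    quals <- vapply(tasks[[tk]], `[[`, character(1), "quality")
    if (!all(c("correct", "incorrect") %in% quals))
      stop("task ", tk, " needs at least one correct and one incorrect ",
           "template", call. = FALSE)
  }
  structure(list(tasks = tasks, lab_trials_per_type = lab_trials_per_type,
                 home_trials_per_task = home_trials_per_task,
                 home_correct_fraction = home_correct_fraction,
                 noise = noise, participant_id = participant_id,
                 mag_yaw_offset_home_deg = mag_yaw_offset_home_deg,
                 home_only_templates = home_only_templates,
                 home_only_fraction = home_only_fraction, fs = fs),
            class = "synthetic_config")
}

#' Simulate a participant's lab and home sessions
#'
#' Generates a labeled lab reference session (every template of every task,
#' `lab_trials_per_type` trials each) and an unlabeled home session with
#' the configured quality mix, plus the ground-truth table mapping home
#' trial ids to movement type and quality. Per-trial seeds are derived from
#' the root seed with a counter, so any subset of trials regenerates
#' identically.
#'
#' @param config a [synthetic_config()].
#' @param seed root integer seed.
#' @return list with `lab` ([imu_session()]), `home` ([imu_session()]) and
#'   `truth` (data frame `trial_id`, `task_id`, `movement_type`,
#'   `quality`).
#' @export
simulate_participant <- function(config, seed = 1) {
  counter <- 0L
  next_seed <- function() {
    counter <<- counter + 1L
    derive_seed(seed, counter)
  }
  lab <- list()
  for (tk in names(config$tasks)) {
    for (tmpl in config$tasks[[tk]]) {
      for (i in seq_len(config$lab_trials_per_type)) {
        id <- sprintf("lab_t%s_%s_%02d", tk, tmpl$movement_type, i)
        lab[[length(lab) + 1]] <-
          simulate_trial(tmpl, config$noise, seed = next_seed(),
                         fs = config$fs, setting = "lab",
                         participant_id = config$participant_id,
                         mag_yaw_deg = 0, trial_id = id, labeled = TRUE)
      }
    }
  }
  home <- list()
  truth <- list()
  for (tk in names(config$tasks)) {
    tmpls <- config$tasks[[tk]]
    quals <- vapply(tmpls, `[[`, character(1), "quality")
    correct_t <- tmpls[quals == "correct"]
    incorrect_t <- tmpls[quals == "incorrect"]
    home_only <- config$home_only_templates[[tk]]
    for (i in seq_len(config$home_trials_per_task)) {
      s <- next_seed()
      tmpl <- with_preserved_seed(s, {
        if (runif(1) < config$home_correct_fraction) {
          correct_t[[sample.int(length(correct_t), 1)]]
        } else if (!is.null(home_only) &&
                   runif(1) < config$home_only_fraction) {
          home_only
        } else {
          incorrect_t[[sample.int(length(incorrect_t), 1)]]
        }
      })
      id <- sprintf("home_t%s_%03d", tk, i)
      home[[length(home) + 1]] <-
        simulate_trial(tmpl, config$noise, seed = derive_seed(s, 1L),
                       fs = config$fs, setting = "home",
                       participant_id = config$participant_id,
                       mag_yaw_deg = config$mag_yaw_offset_home_deg,
                       trial_id = id, labeled = FALSE)
      truth[[length(truth) + 1]] <-
        data.frame(trial_id = id, task_id = tk,
                   movement_type = tmpl$movement_type,
                   quality = tmpl$quality, stringsAsFactors = FALSE)
    }
  }
  list(lab = imu_session(lab), home = imu_session(home),
       truth = do.call(rbind, truth))
}
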