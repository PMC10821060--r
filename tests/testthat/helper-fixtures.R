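# Fixture builders; everything is generated in code at test time.

G <- 9.80665

# a raw trial with constant or supplied channel streams
make_trial <- function(n = 120, fs = 100, acc = c(0, 0, G),
                       gyro = c(0, 0, 0), mag = c(30, 0, -40),
                       participant_id = "p01", task_id = "1",
                       setting = "lab", movement_type = "correct",
                       quality = "correct", trial_id = NULL) {
  expand <- function(v) if (is.matrix(v)) v else
    matrix(v, n, 3, byrow = TRUE)
  a <- expand(acc); g <- expand(gyro); m <- expand(mag)
  samples <- data.frame(t = seq(0, by = 1 / fs, length.out = n),
                        ax = a[, 1], ay = a[, 2], az = a[, 3],
                        gx = g[, 1], gy = g[, 2], gz = g[, 3],
                        mx = m[, 1], my = m[, 2], mz = m[, 3])
  imu_trial(samples, participant_id, task_id, setting, movement_type,
            quality, fs_nominal = fs, trial_id = trial_id)
}

# a preprocessed channel store with directly chosen derived channels,
# bypassing the orientation filter for precise control of distances
make_store <- function(trial_id, lin_acc, task_id = "1",
                       movement_type = "correct", quality = "correct",
                       grav = NULL, gyro = NULL, mag = NULL, fs = 100) {
  lin_acc <- as.matrix(lin_acc)
  if (ncol(lin_acc) == 1) lin_acc <- cbind(lin_acc, 0, 0)
  n <- nrow(lin_acc)
  zfill <- function(m) if (is.null(m)) matrix(0, n, 3) else {
    m <- as.matrix(m)
    if (ncol(m) == 1) cbind(m, 0, 0) else m
  }
  structure(list(trial_id = trial_id, task_id = task_id,
                 movement_type = movement_type, quality = quality,
                 setting = "lab", fs = fs, n = n,
                 lin_acc = unname(lin_acc), grav = zfill(grav),
                 gyro = zfill(gyro), mag = zfill(mag),
                 gravity_method = "six_axis"),
            class = "channel_store")
}

# two cleanly separated classes in the lin_acc channel: class A around
# level `a`, class B around level `b`, with small deterministic jitter
separated_stores <- function(n_per = 3, len = 40, a = 0, b = 5,
                             jitter = 1e-3) {
  stores <- list()
  k <- 0
  for (cls in list(list(lv = a, type = "correct", q = "correct"),
                   list(lv = b, type = "trunk_shoulder",
                        q = "incorrect"))) {
    for (i in seq_len(n_per)) {
      k <- k + 1
      sig <- matrix(cls$lv + jitter * sin(seq_len(len) + k), len, 1)
      stores[[k]] <- make_store(sprintf("s%02d", k), sig,
                                movement_type = cls$type,
                                quality = cls$q)
    }
  }
  stores
}

# small, fast synthetic study configuration for pipeline-level tests
fast_config <- function(...) {
  synthetic_config(tasks = default_templates()[1:2],
                   lab_trials_per_type = 3, home_trials_per_task = 8, ...)
}
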