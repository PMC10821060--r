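test_that("unit declarations convert on read and invert on write", {
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "t.csv")
  tab <- data.frame(t = c(0, 0.01, 0.02), ax = 0, ay = 0, az = 1,
                    gx = 0, gy = 0, gz = 180, mx = 30, my = 0, mz = -40)
  write.csv(tab, f, row.names = FALSE)
  tr <- read_trial(f, imu_units(acc = "g", gyro = "deg_s"),
                   setting = "home", quality = "unknown")
  expect_equal(tr$samples$az, rep(9.80665, 3))
  expect_equal(tr$samples$gz, rep(pi, 3))

  # g -> m/s^2 -> g round trip at 1e-9 relative tolerance
  f2 <- file.path(tmp, "t2.csv")
  write_trial(tr, f2, imu_units(acc = "g", gyro = "deg_s"))
  back <- read.csv(f2)
  expect_equal(back$az, tab$az, tolerance = 1e-9)
  expect_equal(back$gz, tab$gz, tolerance = 1e-9)

  # SI round trip is the identity on sample values
  f3 <- file.path(tmp, "t3.csv")
  write_trial(tr, f3)
  tr2 <- read_trial(f3, setting = "home", quality = "unknown")
  expect_equal(tr2$samples, tr$samples, tolerance = 1e-12)
})

test_that("malformed trial files are rejected with informative errors", {
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "bad.csv")

  tab <- data.frame(t = c(0, 0.01), ax = 0, ay = 0, az = 1,
                    gx = 0, gy = 0, gz = 0, mx = 0, my = 0)  # mz missing
  write.csv(tab, f, row.names = FALSE)
  expect_error(read_trial(f), "lacks columns")

  tab <- data.frame(t = seq(0, 0.06, by = 0.01), ax = 0, ay = 0, az = 1,
                    gx = 0, gy = 0, gz = 0, mx = 0, my = 0, mz = 0)
  tab$t[5] <- tab$t[3]  # timestamps decrease at row 5
  write.csv(tab, f, row.names = FALSE)
  expect_error(read_trial(f), "non-monotone")

  write.csv(tab[1, ], f, row.names = FALSE)
  expect_error(read_trial(f), "fewer than 2 rows")
})

test_that("trial invariants are enforced by the constructor", {
  expect_error(make_trial(movement_type = "", quality = "correct"),
               "movement_type")
  expect_error(make_trial(setting = "lab", quality = "unknown",
                          movement_type = ""), "lab trials")
  # median sampling interval off by more than 20%
  s <- data.frame(t = seq(0, 1.5, by = 0.015), ax = 0, ay = 0, az = G,
                  gx = 0, gy = 0, gz = 0, mx = 0, my = 0, mz = 0)
  expect_error(imu_trial(s, "p", "1", "lab", "correct", "correct",
                         fs_nominal = 100), "20%")
})

test_that("session manifests round-trip and session invariants hold", {
  tmp <- withr::local_tempdir()
  cfg <- fast_config()
  sim <- simulate_participant(cfg, seed = 7)

  write_session(sim$lab, file.path(tmp, "lab"))
  lab2 <- read_session(file.path(tmp, "lab", "manifest.json"))
  expect_equal(length(lab2$trials), length(sim$lab$trials))
  ids <- vapply(lab2$trials, `[[`, character(1), "trial_id")
  expect_setequal(ids, vapply(sim$lab$trials, `[[`, character(1),
                              "trial_id"))
  i <- which(ids == sim$lab$trials[[1]]$trial_id)
  expect_equal(lab2$trials[[i]]$samples, sim$lab$trials[[1]]$samples,
               tolerance = 1e-9)
  expect_equal(lab2$trials[[i]]$quality, sim$lab$trials[[1]]$quality)

  # a home session of unknown-quality trials is accepted
  write_session(sim$home, file.path(tmp, "home"))
  home2 <- read_session(file.path(tmp, "home", "manifest.json"))
  expect_equal(length(home2$trials), length(sim$home$trials))
  expect_true(all(vapply(home2$trials, `[[`, character(1), "quality") ==
                    "unknown"))

  # lab trial with unknown quality is rejected at manifest level
  man <- jsonlite::read_json(file.path(tmp, "lab", "manifest.json"))
  man$trials[[1]]$quality <- "unknown"
  bad <- file.path(tmp, "lab", "bad_manifest.json")
  jsonlite::write_json(man, bad, auto_unbox = TRUE)
  expect_error(read_session(bad), "lab trials")

  # mixed participant ids are rejected
  t1 <- make_trial(participant_id = "p01", trial_id = "a")
  t2 <- make_trial(participant_id = "p02", trial_id = "b",
                   movement_type = "trunk", quality = "incorrect")
  expect_error(imu_session(list(t1, t2), validate_lab = FALSE),
               "participant_id")

  # lab session needs >= 2 movement types with >= 2 trials each
  t3 <- make_trial(trial_id = "c")
  expect_error(imu_session(list(t1, t3)), "movement types")
})

test_that("reports round-trip through JSON and cover overall + per task", {
  tmp <- withr::local_tempdir()
  # 4 tasks, forced confusion counts
  pred <- data.frame(
    trial_id = sprintf("h%02d", 1:20),
    task_id = rep(c("1", "2", "3", "4"), each = 5),
    predicted_quality = rep(c("correct", "correct", "incorrect",
                              "incorrect", "correct"), 4),
    nearest_lab_trial = "lab", nearest_distance = 1,
    n_feasible = 3L, stringsAsFactors = FALSE)
  truth <- data.frame(
    trial_id = pred$trial_id,
    movement_type = rep(c("correct", "correct", "trunk", "correct",
                          "trunk"), 4),
    quality = rep(c("correct", "correct", "incorrect", "correct",
                    "incorrect"), 4), stringsAsFactors = FALSE)
  rep0 <- score_session(pred, truth)
  expect_length(rep0$per_task, 4)  # plus the overall matrix: 5 in total

  path <- file.path(tmp, "report.json")
  write_report(rep0, path)
  expect_true(file.exists(file.path(tmp, "report.csv")))
  back <- read_report(path)
  expect_equal(back$overall[c("TP", "FN", "FP", "TN")],
               rep0$overall[c("TP", "FN", "FP", "TN")])
  expect_equal(back$accuracy, rep0$accuracy)
  expect_equal(back$f1, rep0$f1)
  expect_equal(nrow(back$per_trial), 20)

  expect_error(score_session(pred[0, ], truth), "nothing to score")
  expect_error(write_report(structure(list(), class = "quality_report"),
                            path), "not populated")
})
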