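lab_set <- function() {
  list(make_store("L1", matrix(0 + 1e-3 * sin(1:30), 30, 1),
                  movement_type = "correct", quality = "correct"),
       make_store("L2", matrix(0 + 1e-3 * cos(1:30), 30, 1),
                  movement_type = "correct", quality = "correct"),
       make_store("L3", matrix(5 + 1e-3 * sin(1:30), 30, 1),
                  movement_type = "trunk_shoulder", quality = "incorrect"),
       make_store("L4", matrix(5 + 1e-3 * cos(1:30), 30, 1),
                  movement_type = "trunk_shoulder", quality = "incorrect"))
}

test_that("a home trial is labeled by its nearest lab reference", {
  labs <- lab_set()
  m <- method_config("lin_acc", FALSE, 30)

  # bit-identical to a correct reference: distance exactly 0
  home_c <- make_store("H1", labs[[1]]$lin_acc)
  p <- classify_trial(home_c, labs, m)
  expect_equal(p$predicted_quality, "correct")
  expect_equal(p$nearest_lab_trial, "L1")
  expect_equal(p$nearest_distance, 0)
  expect_equal(unname(p$distances["L1"]), 0)
  expect_equal(p$nearest_distance, min(p$distances))

  # identical to an incorrect reference
  p2 <- classify_trial(make_store("H2", labs[[3]]$lin_acc), labs, m)
  expect_equal(p2$predicted_quality, "incorrect")

  # exact distance ties go to the earlier reference in session order
  same_labs <- list(make_store("L1", matrix(1, 20, 1),
                               quality = "correct"),
                    make_store("L2", matrix(1, 20, 1),
                               movement_type = "trunk",
                               quality = "incorrect"))
  pt <- classify_trial(make_store("H3", matrix(1, 20, 1)), same_labs,
                       method_config("lin_acc", FALSE, 20))
  expect_equal(pt$nearest_lab_trial, "L1")
  expect_equal(pt$predicted_quality, "correct")
})

test_that("window-infeasible trials are flagged, not silently scored", {
  labs <- lab_set()  # all length 30
  m <- method_config("lin_acc", FALSE, 10)
  long_home <- make_store("H9", matrix(0, 80, 1))
  p <- classify_trial(long_home, labs, m)
  expect_true(is.na(p$predicted_quality))
  expect_true(all(is.na(p$distances)))
})

test_that("reference order only matters through the documented tie-break", {
  labs <- lab_set()
  m <- method_config("lin_acc", FALSE, 30)
  home <- make_store("H1", matrix(0.3 + 1e-3 * sin(1:30), 30, 1))
  p1 <- classify_trial(home, labs, m)
  p2 <- classify_trial(home, rev(labs), m)
  # all distances distinct here: same nearest reference either way
  expect_equal(p1$nearest_lab_trial, p2$nearest_lab_trial)
  expect_equal(p1$nearest_distance, p2$nearest_distance)
})

test_that("confusion metrics follow their defining formulas", {
  # forced counts TP=9 FN=1 FP=2 TN=8
  pred <- c(rep("correct", 9), "incorrect", rep("correct", 2),
            rep("incorrect", 8))
  truth <- c(rep("correct", 10), rep("incorrect", 10))
  cm <- confusion_matrix(pred, truth)
  expect_equal(cm[c("TP", "FN", "FP", "TN")],
               list(TP = 9L, FN = 1L, FP = 2L, TN = 8L))
  expect_equal(cm$accuracy, 0.85)
  expect_equal(cm$f1, 18 / 21)

  expect_equal(confusion_matrix(rep("correct", 5), rep("correct", 5)),
               list(TP = 5L, FN = 0L, FP = 0L, TN = 0L, accuracy = 1,
                    f1 = 1))
  anti <- confusion_matrix(c("correct", "incorrect"),
                           c("incorrect", "correct"))
  expect_equal(anti$accuracy, 0)
  expect_equal(anti$f1, 0)
})

test_that("session scoring aggregates per task and per movement type", {
  res <- run_pipeline(fast_config(), seed = 31)
  rep <- res$report
  # per-task matrices sum cell-wise to the overall matrix
  for (f in c("TP", "FN", "FP", "TN"))
    expect_equal(sum(vapply(rep$per_task, `[[`, numeric(1), f)),
                 rep$overall[[f]])
  expect_equal(rep$accuracy,
               with(rep$overall, (TP + TN) / (TP + TN + FP + FN)))
  # sensitivity rows cover exactly the incorrect home movement types
  inc_types <- sort(unique(res$truth$movement_type[
    res$truth$quality == "incorrect"]))
  expect_equal(sort(rep$sensitivity_by_type$movement_type), inc_types)
  expect_true(all(rep$sensitivity_by_type$sensitivity >= 0 &
                    rep$sensitivity_by_type$sensitivity <= 1))
  # scoring predictions against themselves is perfect
  perfect <- res$predictions
  truth_self <- data.frame(trial_id = perfect$trial_id,
                           movement_type = "x",
                           quality = perfect$predicted_quality)
  self_rep <- score_session(perfect, truth_self)
  expect_equal(self_rep$accuracy, 1)
  expect_equal(self_rep$f1, 1)

  # missing ground truth is an error
  expect_error(score_session(res$predictions, res$truth[-1, ]),
               "missing")
})

test_that("a compensatory home trial lands in its lab cluster", {
  # three lab movement types as in a cup-to-mouth task: correct,
  # shoulder abduction, unable to grasp
  tmpls <- list(
    "2" = list(
      movement_template("2", "correct", "correct", 2.5, 0.2,
                        roll = c(0.3, 0.2), pitch = c(0.4, 0.8),
                        disp = c(0.25, 0.05, 0.2),
                        path_bump = c(0, 0, 0.25)),
      movement_template("2", "shoulder_abduction", "incorrect", 2.7, 0.2,
                        roll = c(0.9, 0.4), pitch = c(0.4, 0.5),
                        disp = c(0.25, 0.15, 0.2),
                        path_bump = c(0, 0.1, 0.4)),
      movement_template("2", "unable_to_grasp", "incorrect", 1.6, 0.12,
                        roll = c(0.15, 0.1), pitch = c(0.2, 0.3),
                        disp = c(0.12, 0, 0.05))))
  cfg <- synthetic_config(tasks = tmpls, lab_trials_per_type = 6,
                          home_trials_per_task = 1)
  sim <- simulate_participant(cfg, seed = 17)
  lab_stores <- lapply(sim$lab$trials, preprocess_trial)
  home_tr <- simulate_trial(tmpls[["2"]][[2]], noise_model(), seed = 99,
                            setting = "home", mag_yaw_deg = 45,
                            trial_id = "H1", labeled = FALSE)
  m <- method_config(c("lin_acc", "grav", "gyro"), TRUE, 400)
  p <- classify_trial(preprocess_trial(home_tr), lab_stores, m)
  expect_equal(p$predicted_quality, "incorrect")
  types <- vapply(lab_stores, `[[`, character(1), "movement_type")
  mean_by <- tapply(p$distances, types, mean)
  expect_lt(mean_by["shoulder_abduction"], mean_by["correct"])
  expect_lt(mean_by["shoulder_abduction"], mean_by["unable_to_grasp"])
})

test_that("gyroscope-bearing channels beat acceleration-only data when
           only angular velocity separates the classes", {
  cfg <- synthetic_config(tasks = gyro_scenario_templates(),
                          home_trials_per_task = 16,
                          home_correct_fraction = 0.5)
  sim <- simulate_participant(cfg, seed = 303)
  ab <- ablation_compare(sim$lab, sim$home, sim$truth)
  expect_gt(ab$all_channels$accuracy, ab$accel_only$accuracy)
  expect_equal(ab$all_channels$ablation, "all_channels")
  expect_equal(ab$accel_only$ablation, "accel_only")
  # both ablations score the same trials
  expect_equal(nrow(ab$all_channels$per_trial),
               nrow(ab$accel_only$per_trial))
})
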