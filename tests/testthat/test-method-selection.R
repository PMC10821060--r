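test_that("the one-sided Welch p-value matches the closed form", {
  x <- c(1, 2, 3)
  y <- c(4, 5, 6)
  expect_equal(wristdtw:::welch_p_less(x, y), oracle_welch_p(x, y),
               tolerance = 1e-12)
  set.seed(4)
  for (i in 1:10) {
    a <- rnorm(sample(3:12, 1))
    b <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1))
    expect_equal(wristdtw:::welch_p_less(a, b), oracle_welch_p(a, b),
                 tolerance = 1e-12)
  }
  # degenerate zero-variance clusters resolve by mean comparison
  expect_equal(wristdtw:::welch_p_less(c(0, 0), c(1, 1)), 0)
  expect_equal(wristdtw:::welch_p_less(c(1, 1), c(0, 0)), 1)
})

test_that("discernability is tiny for separated classes, large for mixed", {
  stores <- separated_stores(n_per = 3, a = 0, b = 5)
  m <- method_config("lin_acc", normalize = FALSE, window_w = 40)
  expect_lt(discernability_pmax(stores, m), 1e-6)

  # both classes drawn from one distribution: nothing to discern
  set.seed(901)
  mixed <- lapply(1:6, function(k)
    make_store(sprintf("m%02d", k), matrix(rnorm(40, sd = 0.5), 40, 1),
               movement_type = if (k > 3) "trunk_shoulder" else "correct",
               quality = if (k > 3) "incorrect" else "correct"))
  expect_gt(discernability_pmax(mixed, m), 0.05)

  # p_max is invariant to trial order within a movement type
  perm <- stores[c(2, 3, 1, 6, 4, 5)]
  expect_equal(discernability_pmax(perm, m), discernability_pmax(stores, m),
               tolerance = 1e-12)

  # infeasible window -> NA
  short <- c(stores[1:5], list(make_store("s99", matrix(5, 5, 1),
                                          movement_type = "trunk_shoulder",
                                          quality = "incorrect")))
  expect_true(is.na(discernability_pmax(
    short, method_config("lin_acc", FALSE, 10))))

  # a single movement type cannot be assessed
  one_type <- stores[1:3]
  expect_error(discernability_pmax(one_type, m), "quality")
})

test_that("leave-one-trial-out accuracy behaves at the extremes", {
  m <- method_config("lin_acc", normalize = FALSE, window_w = 40)
  stores <- separated_stores(n_per = 3, a = 0, b = 5)
  expect_equal(loto_accuracy(stores, m), 1)

  # all trials identical across classes: the documented tie-break pins the
  # outcome (nearest is the earliest other trial, so everything is
  # predicted with trial 1's quality except trial 1 itself)
  same <- lapply(1:4, function(k)
    make_store(sprintf("d%d", k), matrix(1, 20, 1),
               movement_type = c("correct", "correct", "trunk",
                                 "trunk")[k],
               quality = c("correct", "correct", "incorrect",
                           "incorrect")[k]))
  expect_equal(loto_accuracy(same, m), 0.5)

  # one outlier trial sitting in the other class's cluster: (n-1)/n
  out <- separated_stores(n_per = 3, a = 0, b = 5)
  out[[3]] <- make_store("s03", matrix(5.5 + 1e-4 * sin(1:40), 40, 1),
                         movement_type = "correct", quality = "correct")
  expect_equal(loto_accuracy(out, m), 5 / 6)
})

test_that("selection applies the significance and LOTO rules in order", {
  set.seed(902)
  stores <- lapply(1:8, function(k) {
    cls <- k > 4
    # lin_acc is exchangeable noise; only the gyro channel separates
    make_store(sprintf("g%d", k),
               lin_acc = matrix(rnorm(30, sd = 0.2), 30, 1),
               gyro = matrix(if (cls) 2 + 0.01 * cos(1:30 + k)
                             else 0.01 * cos(1:30 + k), 30, 1),
               movement_type = if (cls) "excess_rotation" else "correct",
               quality = if (cls) "incorrect" else "correct")
  })
  g_gyro <- method_config("gyro", FALSE, 30)
  g_acc <- method_config("lin_acc", FALSE, 30)
  sel <- select_method(stores, grid = list(g_acc, g_gyro))
  expect_identical(sel$selected$channels, "gyro")
  expect_true(any(grepl("p_max < 0.05", sel$trace)))

  # single-method grid: selected with a minimal trace
  sel1 <- select_method(stores, grid = list(g_gyro))
  expect_identical(format(sel1$selected), format(g_gyro))

  # adding a strictly worse method never changes the selection
  worse <- method_config("lin_acc", FALSE, 25)
  sel2 <- select_method(stores, grid = list(g_acc, g_gyro, worse))
  expect_identical(format(sel2$selected), format(sel$selected))

  # selection is deterministic
  sel3 <- select_method(stores, grid = list(g_acc, g_gyro))
  expect_identical(sel3$table, sel$table)
  expect_identical(format(sel3$selected), format(sel$selected))

  expect_error(select_method(stores, grid = list()), "empty method grid")
  # trial lengths differing by more than every window: nothing feasible
  stores_mixed <- stores
  stores_mixed[[1]] <- make_store("g1", lin_acc = matrix(0, 60, 1),
                                  gyro = matrix(0, 60, 1),
                                  movement_type = "correct",
                                  quality = "correct")
  expect_error(select_method(stores_mixed,
                             grid = list(method_config("gyro", FALSE, 10))),
               "infeasible")
})

test_that("ties fall back to the documented preference rule", {
  sim <- simulate_participant(
    synthetic_config(tasks = default_templates()[1],
                     lab_trials_per_type = 4,
                     home_trials_per_task = 1), seed = 2100)
  grid <- list(method_config("gyro", TRUE, 300),
               method_config("gyro", TRUE, 400),
               method_config(c("lin_acc", "grav", "gyro"), TRUE, 300),
               method_config(c("lin_acc", "grav", "gyro"), TRUE, 400))
  sel <- select_method(sim$lab, grid = grid)
  # all four separate perfectly; preference picks the full channel set
  # with normalization at the longest window
  expect_setequal(sel$selected$channels, c("lin_acc", "grav", "gyro"))
  expect_true(sel$selected$normalize)
  expect_equal(sel$selected$window_w, 400L)
  expect_true(any(grepl("preferred lin_acc\\+grav\\+gyro", sel$trace)))
  expect_true(any(grepl("longer window", sel$trace)))
})

test_that("selection recovers gyroscope channels when only they separate", {
  cfg <- synthetic_config(tasks = gyro_scenario_templates(),
                          lab_trials_per_type = 4,
                          home_trials_per_task = 1)
  hits <- 0
  for (s in 1:3) {
    sim <- simulate_participant(cfg, seed = 200 + s)
    sel <- select_method(sim$lab)
    hits <- hits + ("gyro" %in% sel$selected$channels)
  }
  expect_equal(hits, 3)
})
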