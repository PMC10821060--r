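#' Classify one home trial against the lab references
#'
#' The home trial (as test) is aligned to every lab reference trial of the
#' same task under the selected method; the quality label of the reference
#' with the minimum projected DTW distance is assigned. Ties are broken
#' toward the reference appearing earlier in session order. Reference
#' pairs infeasible under the window are `NA` in the distance vector; a
#' trial is unclassifiable only when every distance is infeasible.
#'
#' @param home_store `channel_store` of the home trial (preprocessed with
#'   the same gravity method as the references).
#' @param lab_stores list of `channel_store`s of the lab references for the
#'   trial's task, in session order.
#' @param method the selected [method_config()].
#' @param lab_mats,home_mat optional pre-assembled (and normalized) channel
#'   matrices; when omitted they are built here, with normalization scales
#'   computed from the lab references.
#' @return list of class `trial_prediction`: `trial_id`, `task_id`,
#'   `predicted_quality` (`NA` when unclassifiable), `nearest_lab_trial`,
#'   `nearest_distance`, and `distances` (named vector over all
#'   references).
#' @export
classify_trial <- function(home_store, lab_stores, method,
                           lab_mats = NULL, home_mat = NULL) {
  if (length(lab_stores) == 0) stop("no lab references", call. = FALSE)
  if (is.null(lab_mats) || is.null(home_mat)) {
    pm <- prepare_matrices(lab_stores, list(home_store), method)
    lab_mats <- pm$lab
    home_mat <- pm$other[[1]]
  }
  d <- vapply(lab_mats, function(ref) {
    r <- .dtw_band_cpp(home_mat, ref, method$window_w, FALSE)
    if (isTRUE(r$feasible)) r$projected_distance else NA_real_
  }, numeric(1))
  names(d) <- vapply(lab_stores, `[[`, character(1), "trial_id")
  if (all(is.na(d))) {
    pred <- list(trial_id = home_store$trial_id,
                 task_id = home_store$task_id,
                 predicted_quality = NA_character_,
                 nearest_lab_trial = NA_character_,
                 nearest_distance = NA_real_, distances = d)
  } else {
    j <- which.min(d)    # earliest reference on exact ties, NAs ignored
    pred <- list(trial_id = home_store$trial_id,
                 task_id = home_store$task_id,
                 predicted_quality = lab_stores[[j]]$quality,
                 nearest_lab_trial = names(d)[j],
                 nearest_distance = unname(d[j]), distances = d)
  }
  structure(pred, class = "trial_prediction")
}

#' Classify a home session
#'
#' Applies [classify_trial()] to every home trial, task by task, using the
#' participant's lab session as the reference set and a single selected
#' method. Normalization scales are computed per task from the lab
#' references only.
#'
#' @param home_session home [imu_session()].
#' @param lab_session lab [imu_session()] of the same participant.
#' @param method a [method_config()] or a `selection_result` from
#'   [select_method()] (its selected method and gravity mode are used).
#' @param gravity,filter_params preprocessing options (overridden by a
#'   `selection_result`'s gravity mode).
#' @return data frame with one row per home trial: `trial_id`, `task_id`,
#'   `predicted_quality`, `nearest_lab_trial`, `nearest_distance`,
#'   `n_feasible`; the full prediction objects are attached as attribute
#'   `"predictions"`.
#' @export
classify_session <- function(home_session, lab_session, method,
                             gravity = "six_axis",
                             filter_params = orientation_filter_params()) {
  if (inherits(method, "selection_result")) {
    gravity <- method$gravity
    method <- method$selected
  }
  if (home_session$participant_id != lab_session$participant_id)
    stop("home and lab sessions belong to different participants",
         call. = FALSE)
  preds <- list()
  for (task in session_tasks(home_session)) {
    lab_tr <- session_task_trials(lab_session, task)
    if (length(lab_tr) == 0)
      stop("no lab references for task ", task, call. = FALSE)
    lab_stores <- as_stores(lab_tr, gravity, filter_params)
    home_tr <- session_task_trials(home_session, task)
    home_stores <- as_stores(home_tr, gravity, filter_params)
    pm <- prepare_matrices(lab_stores, home_stores, method)
    for (i in seq_along(home_stores))
      preds[[length(preds) + 1]] <-
        classify_trial(home_stores[[i]], lab_stores, method,
                       lab_mats = pm$lab, home_mat = pm$other[[i]])
  }
  out <- data.frame(
    trial_id = vapply(preds, `[[`, character(1), "trial_id"),
    task_id = vapply(preds, `[[`, character(1), "task_id"),
    predicted_quality = vapply(preds, `[[`, character(1),
                               "predicted_quality"),
    nearest_lab_trial = vapply(preds, `[[`, character(1),
                               "nearest_lab_trial"),
    nearest_distance = vapply(preds, `[[`, numeric(1), "nearest_distance"),
    n_feasible = vapply(preds, function(p) sum(!is.na(p$distances)),
                        integer(1)),
    stringsAsFactors = FALSE)
  attr(out, "predictions") <- preds
  attr(out, "method") <- method
  out
}

#' Binary confusion matrix with correct movement as the positive class
#'
#' @param predicted,truth character vectors of `"correct"` / `"incorrect"`.
#' @return list with integer counts `TP`, `FN`, `FP`, `TN` plus `accuracy`
#'   and `f1` (`F1 = 2TP / (2TP + FP + FN)`).
#' @export
confusion_matrix <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  TP <- sum(predicted == "correct" & truth == "correct")
  FN <- sum(predicted == "incorrect" & truth == "correct")
  FP <- sum(predicted == "correct" & truth == "incorrect")
  TN <- sum(predicted == "incorrect" & truth == "incorrect")
  total <- TP + FN + FP + TN
  list(TP = TP, FN = FN, FP = FP, TN = TN,
       accuracy = if (total > 0) (TP + TN) / total else NA_real_,
       f1 = if (2 * TP + FP + FN > 0) 2 * TP / (2 * TP + FP + FN)
            else NA_real_)
}

#' Score a classified home session against ground truth
#'
#' Builds the quality report: the overall confusion matrix (positive class
#' = correct movement), per-task matrices (which sum cell-wise to the
#' overall one), accuracy and F1 overall and per task, and the
#' per-movement-type sensitivity table (fraction of true-incorrect trials
#' of each annotated type predicted incorrect). Unclassifiable trials
#' (every reference infeasible under the window) are excluded from the
#' matrices and counted separately.
#'
#' @param predictions data frame from [classify_session()].
#' @param truth data frame with columns `trial_id`, `movement_type`,
#'   `quality` covering every predicted trial.
#' @param ablation tag recorded in the report (e.g. `"all_channels"`).
#' @return object of class `quality_report`.
#' @export
score_session <- function(predictions, truth, ablation = "all_channels") {
  if (nrow(predictions) == 0) stop("nothing to score", call. = FALSE)
  m <- match(predictions$trial_id, truth$trial_id)
  if (anyNA(m))
    stop("ground truth missing for trial(s): ",
         paste(utils::head(predictions$trial_id[is.na(m)], 5),
               collapse = ","), call. = FALSE)
  truth_q <- truth$quality[m]
  truth_type <- truth$movement_type[m]
  scored <- !is.na(predictions$predicted_quality)
  n_unclassifiable <- sum(!scored)
  p <- predictions[scored, , drop = FALSE]
  tq <- truth_q[scored]
  tt <- truth_type[scored]
  if (nrow(p) == 0) stop("no classifiable trials to score", call. = FALSE)

  overall <- confusion_matrix(p$predicted_quality, tq)
  per_task <- lapply(split(seq_len(nrow(p)), p$task_id), function(idx)
    confusion_matrix(p$predicted_quality[idx], tq[idx]))

  inc <- tq == "incorrect"
  sens <- if (any(inc)) {
    sp <- split(p$predicted_quality[inc] == "incorrect", tt[inc])
    data.frame(movement_type = names(sp),
               n = vapply(sp, length, integer(1)),
               sensitivity = vapply(sp, mean, numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(movement_type = character(0), n = integer(0),
               sensitivity = numeric(0), stringsAsFactors = FALSE)
  }

  per_trial <- data.frame(
    trial_id = predictions$trial_id, task_id = predictions$task_id,
    predicted_quality = predictions$predicted_quality,
    true_quality = truth_q, true_movement_type = truth_type,
    nearest_lab_trial = predictions$nearest_lab_trial,
    nearest_distance = predictions$nearest_distance,
    stringsAsFactors = FALSE)

  method <- attr(predictions, "method")
  structure(
    list(overall = overall, per_task = per_task,
         accuracy = overall$accuracy, f1 = overall$f1,
         sensitivity_by_type = sens,
         n_unclassifiable = n_unclassifiable,
         method = if (is.null(method)) NULL else format(method),
         ablation = ablation, per_trial = per_trial),
    class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> [%s] accuracy %.3f, F1 %.3f (%d trials",
              x$ablation, x$accuracy, x$f1,
              with(x$overall, TP + FN + FP + TN)))
  if (x$n_unclassifiable > 0)
    cat(sprintf(", %d unclassifiable", x$n_unclassifiable))
  cat(")\n")
  cm <- x$overall
  cat(sprintf("  overall: TP=%d FN=%d FP=%d TN=%d\n", cm$TP, cm$FN, cm$FP,
              cm$TN))
  for (tk in names(x$per_task)) {
    cm <- x$per_task[[tk]]
    cat(sprintf("  task %s: TP=%d FN=%d FP=%d TN=%d acc=%.3f F1=%.3f\n",
                tk, cm$TP, cm$FN, cm$FP, cm$TN, cm$accuracy, cm$f1))
  }
  if (nrow(x$sensitivity_by_type) > 0) {
    cat("  sensitivity by incorrect movement type:\n")
    for (i in seq_len(nrow(x$sensitivity_by_type)))
      cat(sprintf("    %-28s %3d trials  %.3f\n",
                  x$sensitivity_by_type$movement_type[i],
                  x$sensitivity_by_type$n[i],
                  x$sensitivity_by_type$sensitivity[i]))
  }
  invisible(x)
}

#' Write a quality report
#'
#' Writes the report as JSON and the per-trial prediction table as a CSV
#' next to it (same stem, `.csv` extension).
#'
#' @param report a [score_session()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (!inherits(report, "quality_report") || is.null(report$overall))
    stop("report not populated", call. = FALSE)
  obj <- unclass(report)
  per_trial <- obj$per_trial
  obj$per_trial <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  if (!is.null(per_trial))
    utils::write.csv(per_trial, sub("\\.json$", ".csv", path),
                     row.names = FALSE)
  invisible(path)
}

#' Read back a written quality report
#'
#' @param path JSON path written by [write_report()].
#' @return a `quality_report` (per-trial table re-read from the sibling
#'   CSV when present).
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$sensitivity_by_type <- as.data.frame(obj$sensitivity_by_type,
                                           stringsAsFactors = FALSE)
  csv <- sub("\\.json$", ".csv", path)
  if (file.exists(csv))
    obj$per_trial <- utils::read.csv(csv, stringsAsFactors = FALSE)
  obj$per_task <- lapply(obj$per_task, as.list)
  obj$overall <- as.list(obj$overall)
  structure(obj, class = "quality_report")
}

#' Compare the full pipeline against an acceleration-only ablation
#'
#' Runs method selection and home classification twice: once on the full
#' grid with the six-axis gravity filter, and once restricted to channel
#' sets derivable from the accelerometer alone (`lin_acc`, `grav`, with
#' gravity estimated by an accelerometer-only low-pass filter). This
#' mirrors the practical trade-off of logging only acceleration to extend
#' battery life.
#'
#' @param lab_session,home_session the participant's sessions.
#' @param truth ground-truth table for the home session (see
#'   [score_session()]).
#' @param grid full method grid; the ablation uses its acceleration-only
#'   subset.
#' @param alpha significance level for selection.
#' @return list with `quality_report`s `all_channels` and `accel_only`.
#' @export
ablation_compare <- function(lab_session, home_session, truth,
                             grid = method_grid(), alpha = 0.05) {
  sel_full <- select_method(lab_session, grid, alpha, gravity = "six_axis")
  rep_full <- score_session(
    classify_session(home_session, lab_session, sel_full), truth,
    ablation = "all_channels")

  acc_grid <- Filter(function(m)
    all(m$channels %in% c("lin_acc", "grav")), grid)
  if (length(acc_grid) == 0)
    stop("grid has no acceleration-only methods", call. = FALSE)
  sel_acc <- select_method(lab_session, acc_grid, alpha,
                           gravity = "lowpass")
  rep_acc <- score_session(
    classify_session(home_session, lab_session, sel_acc), truth,
    ablation = "accel_only")

  list(all_channels = rep_full, accel_only = rep_acc)
}
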