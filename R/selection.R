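#' A method configuration
#'
#' One point in the exploration grid: which derived channel groups enter the
#' DTW channel matrix, whether per-axis normalization is applied, and the
#' maximum warping window in samples.
#'
#' @param channels nonempty subset of `c("lin_acc", "grav", "gyro", "mag")`.
#' @param normalize logical; divide each axis by its lab-derived standard
#'   deviation.
#' @param window_w warping window, samples.
#' @return object of class `method_config`.
#' @export
method_config <- function(channels, normalize = TRUE, window_w = 400) {
  channels <- .CHANNEL_GROUPS[.CHANNEL_GROUPS %in% channels]
  if (length(channels) == 0)
    stop("method needs a nonempty channel set", call. = FALSE)
  structure(list(channels = channels, normalize = isTRUE(normalize),
                 window_w = as.integer(window_w)),
            class = "method_config")
}

#' @export
format.method_config <- function(x, ...) {
  sprintf("%s | %s | w=%d", paste(x$channels, collapse = "+"),
          if (x$normalize) "norm" else "raw", x$window_w)
}

#' @export
print.method_config <- function(x, ...) {
  cat("<method_config>", format(x), "\n")
  invisible(x)
}

#' The default method exploration grid
#'
#' All nonempty subsets of `{lin_acc, grav, gyro}` crossed with
#' normalization on/off and the warping-window grid. Windows default to
#' 0.5x, 1x, 2x, 3x and 4x the nominal 100 Hz sampling rate. The
#' magnetometer is excluded by default: its reading encodes heading
#' relative to the earth's field, which differs between the lab and the
#' home, so it carries setting rather than movement information; set
#' `include_mag = TRUE` to add magnetometer-containing subsets anyway.
#'
#' Subsets are enumerated in a fixed canonical order (by increasing
#' bitmask over the canonical channel order); this order is the final
#' deterministic tie-break in [select_method()].
#'
#' @param windows integer vector of window sizes, samples.
#' @param normalize logical values to cross with.
#' @param include_mag include magnetometer-containing channel subsets.
#' @return list of [method_config()] objects.
#' @export
method_grid <- function(windows = c(50L, 100L, 200L, 300L, 400L),
                        normalize = c(FALSE, TRUE),
                        include_mag = FALSE) {
  groups <- if (include_mag) .CHANNEL_GROUPS else setdiff(.CHANNEL_GROUPS,
                                                          "mag")
  subsets <- list()
  for (mask in seq_len(2^length(groups) - 1))
    subsets[[mask]] <- groups[bitwAnd(mask, 2^(seq_along(groups) - 1)) > 0]
  grid <- list()
  for (ch in subsets)
    for (nm in normalize)
      for (w in windows)
        grid[[length(grid) + 1]] <- method_config(ch, nm, w)
  grid
}

# one-sided Welch two-sample p-value for H1: mean(x) < mean(y).
# Degenerate zero-variance clusters fall back to a direct mean comparison.
welch_p_less <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("need >= 2 distances per cluster", call. = FALSE)
  se2 <- stats::var(x) / n1 + stats::var(y) / n2
  if (se2 <= 0)
    return(if (mean(x) < mean(y)) 0 else 1)
  stats::t.test(x, y, alternative = "less", var.equal = FALSE)$p.value
}

# distance clusters for one cross-quality movement-type pair from a full
# directed distance matrix D over one task's lab trials
pair_clusters <- function(D, types, a, b) {
  ia <- which(types == a)
  ib <- which(types == b)
  off <- function(idx) {
    M <- D[idx, idx, drop = FALSE]
    M[upper.tri(M) | lower.tri(M)]
  }
  within <- c(off(ia), off(ib))
  between <- c(as.vector(D[ia, ib]), as.vector(D[ib, ia]))
  list(within = within, between = between)
}

# all unordered movement-type pairs with differing quality labels
cross_quality_pairs <- function(types, quals) {
  ut <- unique(types)
  tq <- vapply(ut, function(t) quals[match(t, types)], character(1))
  out <- list()
  if (length(ut) >= 2) {
    cmb <- utils::combn(length(ut), 2)
    for (k in seq_len(ncol(cmb))) {
      a <- ut[cmb[1, k]]; b <- ut[cmb[2, k]]
      if (tq[[a]] != tq[[b]]) out[[length(out) + 1]] <- c(a, b)
    }
  }
  out
}

# p_max and LOTO accuracy from one task's directed distance matrix.
# Returns feasible = FALSE when any required distance is NA.
task_scores <- function(D, types, quals) {
  if (anyNA(D)) return(list(feasible = FALSE))
  pairs <- cross_quality_pairs(types, quals)
  if (length(pairs) == 0)
    stop("no movement-type pair with differing quality labels",
         call. = FALSE)
  pvals <- vapply(pairs, function(pr) {
    cl <- pair_clusters(D, types, pr[1], pr[2])
    welch_p_less(cl$within, cl$between)
  }, numeric(1))
  n <- nrow(D)
  pred <- character(n)
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf
    pred[i] <- quals[which.min(d)]   # which.min: earliest trial on ties
  }
  list(feasible = TRUE, p_max = max(pvals),
       n_correct = sum(pred == quals), n_trials = n)
}

#' Statistical discernability of movement quality for one method
#'
#' For every unordered pair of movement types with differing quality
#' labels, the projected DTW distances within each type (directed,
#' self-pairs excluded, both types pooled) are compared to the distances
#' between the two types (both directions) with a one-sided Welch t-test of
#' the alternative that within-type distances are smaller. The maximum
#' p-value over all such pairs summarizes how discernable movement quality
#' is under the method: it is small only if *every* cross-quality contrast
#' separates.
#'
#' @param lab_trials list of lab [imu_trial()] objects for one task (at
#'   least 2 movement types with >= 2 trials each), or a list of
#'   `channel_store` objects from [preprocess_trial()].
#' @param method a [method_config()].
#' @param gravity,filter_params preprocessing options, see
#'   [preprocess_trial()]; ignored when stores are supplied.
#' @return `p_max` in `[0, 1]`, or `NA` if any required trial pair is
#'   infeasible under the method's window.
#' @export
discernability_pmax <- function(lab_trials, method,
                                gravity = "six_axis",
                                filter_params = orientation_filter_params()) {
  stores <- as_stores(lab_trials, gravity, filter_params)
  mats <- prepare_matrices(stores, method = method)$lab
  D <- pairwise_distances(mats, mats, method$window_w)
  types <- vapply(stores, `[[`, character(1), "movement_type")
  quals <- vapply(stores, `[[`, character(1), "quality")
  if (anyNA(D)) return(NA_real_)
  task_scores(D, types, quals)$p_max
}

#' Leave-one-trial-out lab accuracy for one method
#'
#' Each lab trial is classified by 1-nearest-neighbor (minimum projected
#' DTW distance) against all other lab trials of the same task; accuracy is
#' the fraction whose predicted quality label matches the therapist's.
#' Distance ties are broken toward the reference trial appearing earlier in
#' session order.
#'
#' @inheritParams discernability_pmax
#' @return accuracy in `[0, 1]`, or `NA` if any trial pair is infeasible.
#' @export
loto_accuracy <- function(lab_trials, method, gravity = "six_axis",
                          filter_params = orientation_filter_params()) {
  stores <- as_stores(lab_trials, gravity, filter_params)
  mats <- prepare_matrices(stores, method = method)$lab
  D <- pairwise_distances(mats, mats, method$window_w)
  if (anyNA(D)) return(NA_real_)
  quals <- vapply(stores, `[[`, character(1), "quality")
  sc <- task_scores(D, vapply(stores, `[[`, character(1), "movement_type"),
                    quals)
  sc$n_correct / sc$n_trials
}

as_stores <- function(trials, gravity, filter_params) {
  if (inherits(trials, "imu_session")) trials <- trials$trials
  if (all(vapply(trials, inherits, logical(1), "channel_store")))
    return(trials)
  lapply(trials, preprocess_trial, gravity = gravity,
         filter_params = filter_params)
}

#' Select the best method for a participant
#'
#' Scans the method grid over the participant's lab session and applies the
#' selection rule:
#' \enumerate{
#'   \item drop methods infeasible for any lab trial pair (window smaller
#'     than some length difference);
#'   \item candidates are methods with `p_max < alpha`; if none pass, the
#'     methods attaining the smallest `p_max`;
#'   \item among candidates, keep those with maximal leave-one-trial-out
#'     accuracy;
#'   \item remaining ties are resolved by preferring the channel set
#'     `{lin_acc, grav, gyro}` with normalization, then the larger warping
#'     window, then the canonical grid order.
#' }
#' With several tasks in the session, `p_max` is the maximum over all
#' tasks' cross-quality type pairs and LOTO accuracy pools all tasks (each
#' trial is classified against the other trials of its own task), so one
#' method is selected per participant.
#'
#' @param lab_session a lab [imu_session()] (or list of lab trials).
#' @param grid list of [method_config()]s, see [method_grid()].
#' @param alpha significance level for discernability (default 0.05).
#' @param gravity,filter_params preprocessing options.
#' @return object of class `selection_result`: `selected` (the chosen
#'   [method_config()]), `table` (per-method data frame with `p_max`,
#'   `loto_accuracy`, `feasible`), and `trace` (the ordered tie-break log).
#' @export
select_method <- function(lab_session, grid = method_grid(), alpha = 0.05,
                          gravity = "six_axis",
                          filter_params = orientation_filter_params()) {
  if (length(grid) == 0) stop("empty method grid", call. = FALSE)
  trials <- if (inherits(lab_session, "imu_session")) lab_session$trials
            else lab_session
  stores <- as_stores(trials, gravity, filter_params)
  task_ids <- vapply(stores, `[[`, character(1), "task_id")
  tasks <- unique(task_ids)
  by_task <- lapply(tasks, function(tk) stores[task_ids == tk])
  names(by_task) <- tasks

  nmeth <- length(grid)
  p_max <- rep(NA_real_, nmeth)
  loto <- rep(NA_real_, nmeth)
  feasible <- rep(FALSE, nmeth)

  # group grid entries by (channels, normalize) so channel matrices and
  # scales are assembled once, and dedupe windows that exceed the longest
  # trial (the band is then unconstrained and results are identical)
  key <- vapply(grid, function(m)
    paste(paste(m$channels, collapse = "+"), m$normalize), character(1))
  for (kg in unique(key)) {
    idx <- which(key == kg)
    proto <- grid[[idx[1]]]
    task_mats <- lapply(by_task, function(st)
      prepare_matrices(st, method = proto)$lab)
    wins <- vapply(idx, function(i) grid[[i]]$window_w, integer(1))
    cap <- max(vapply(stores, `[[`, numeric(1), "n")) - 1
    weff <- pmin(wins, as.integer(cap))
    for (we in unique(weff)) {
      ok <- TRUE
      pm <- -Inf
      ncorr <- 0L
      ntot <- 0L
      for (tk in tasks) {
        st <- by_task[[tk]]
        D <- pairwise_distances(task_mats[[tk]], task_mats[[tk]], we)
        sc <- task_scores(D, vapply(st, `[[`, character(1), "movement_type"),
                          vapply(st, `[[`, character(1), "quality"))
        if (!sc$feasible) { ok <- FALSE; break }
        pm <- max(pm, sc$p_max)
        ncorr <- ncorr + sc$n_correct
        ntot <- ntot + sc$n_trials
      }
      sel <- idx[weff == we]
      if (ok) {
        feasible[sel] <- TRUE
        p_max[sel] <- pm
        loto[sel] <- ncorr / ntot
      }
    }
  }

  trace <- character(0)
  cand <- which(feasible)
  if (length(cand) == 0)
    stop("all methods infeasible for this lab session", call. = FALSE)
  trace <- c(trace, sprintf("%d of %d methods feasible", length(cand),
                            nmeth))
  pass <- cand[p_max[cand] < alpha]
  if (length(pass) > 0) {
    cand <- pass
    trace <- c(trace, sprintf("%d methods with p_max < %g", length(cand),
                              alpha))
  } else {
    best_p <- min(p_max[cand])
    cand <- cand[p_max[cand] == best_p]
    trace <- c(trace, sprintf(
      "no method passed alpha; %d method(s) at smallest p_max = %.4g",
      length(cand), best_p))
  }
  if (length(cand) > 1) {
    best_l <- max(loto[cand])
    cand <- cand[loto[cand] == best_l]
    trace <- c(trace, sprintf("%d method(s) at maximal LOTO accuracy %.3f",
                              length(cand), best_l))
  }
  if (length(cand) > 1) {
    pref <- vapply(cand, function(i)
      setequal(grid[[i]]$channels, c("lin_acc", "grav", "gyro")) &&
        grid[[i]]$normalize, logical(1))
    if (any(pref)) {
      cand <- cand[pref]
      trace <- c(trace, sprintf(
        "preferred lin_acc+grav+gyro with normalization: %d method(s)",
        length(cand)))
    }
  }
  if (length(cand) > 1) {
    wmax <- max(vapply(cand, function(i) grid[[i]]$window_w, integer(1)))
    cand <- cand[vapply(cand, function(i) grid[[i]]$window_w, integer(1)) ==
                   wmax]
    trace <- c(trace, sprintf("preferred longer window w=%d: %d method(s)",
                              wmax, length(cand)))
  }
  if (length(cand) > 1)
    trace <- c(trace, "canonical grid order decides among remaining ties")
  sel <- cand[1]
  trace <- c(trace, sprintf("selected: %s", format(grid[[sel]])))

  tab <- data.frame(
    channels = vapply(grid, function(m) paste(m$channels, collapse = "+"),
                      character(1)),
    normalize = vapply(grid, `[[`, logical(1), "normalize"),
    window_w = vapply(grid, `[[`, integer(1), "window_w"),
    p_max = p_max, loto_accuracy = loto, feasible = feasible,
    stringsAsFactors = FALSE)

  structure(list(selected = grid[[sel]], table = tab, trace = trace,
                 alpha = alpha, gravity = gravity),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result>\n  selected:", format(x$selected), "\n  trace:\n")
  cat(paste0("    ", x$trace, collapse = "\n"), "\n")
  invisible(x)
}
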