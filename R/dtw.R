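#' Windowed multivariate dynamic time warping
#'
#' Aligns a test trial's channel matrix to a reference trial's under a
#' Sakoe-Chiba-style band: warp path indices must satisfy `|i - j| <= w`.
#' The local cost is the Euclidean distance between aligned sample rows
#' across all channels; the dynamic program uses the step set
#' `{(1,1), (1,0), (0,1)}` and breaks ties deterministically (diagonal step
#' first, then the test-advancing step).
#'
#' Besides the raw accumulated cost, the result carries the pipeline's
#' working distance: the warped reference is projected onto the test trial's
#' time base (reference samples matched to each test index are averaged) and
#' the mean per-test-sample Euclidean distance is computed, so that
#' distances are comparable across trials of different durations.
#'
#' @param test,ref numeric matrices (rows = time, columns = channels)
#'   sharing one channel set.
#' @param window_w maximum index offset, in samples. Must be at least the
#'   length difference of the two inputs; otherwise no monotone path exists
#'   and an infeasible-window error is raised.
#' @return list of class `dtw_result`: `raw_cost`, `projected_distance`,
#'   `path` (L x 2 matrix of 1-based (test, reference) index pairs).
#' @export
dtw_align <- function(test, ref, window_w) {
  test <- as.matrix(test)
  ref <- as.matrix(ref)
  res <- .dtw_band_cpp(test, ref, as.integer(window_w), TRUE)
  if (!isTRUE(res$feasible))
    stop(sprintf(
      "window %d smaller than length difference |%d - %d|: no valid path",
      as.integer(window_w), nrow(test), nrow(ref)), call. = FALSE)
  structure(list(raw_cost = res$raw_cost,
                 projected_distance = res$projected_distance,
                 path = res$path, window_w = as.integer(window_w)),
            class = "dtw_result")
}

#' Test-anchored projected distance along a warp path
#'
#' For each test index i, the reference rows matched to i by the path are
#' averaged; the distance is the mean over test samples of the Euclidean
#' distance between the test row and that average. This is the distance
#' used throughout method selection and classification.
#'
#' @param test,ref channel matrices.
#' @param path L x 2 matrix of 1-based (test, reference) index pairs forming
#'   a valid monotone warp path over the pair.
#' @return nonnegative scalar distance.
#' @export
projected_distance <- function(test, ref, path) {
  test <- as.matrix(test)
  ref <- as.matrix(ref)
  path <- as.matrix(path)
  n <- nrow(test)
  if (!all(path[1, ] == c(1, 1)) ||
      !all(path[nrow(path), ] == c(n, nrow(ref))))
    stop("path must run from (1,1) to (T_test, T_ref)", call. = FALSE)
  steps <- diff(path)
  if (any(steps < 0) || any(steps > 1) || any(rowSums(steps) == 0))
    stop("invalid warp-path steps", call. = FALSE)
  rbar <- rowsum(ref[path[, 2], , drop = FALSE], path[, 1]) /
    tabulate(path[, 1], nbins = n)
  mean(sqrt(rowSums((test - rbar)^2)))
}

#' Pairwise projected DTW distances between two trial lists
#'
#' `D[a, b]` is the projected distance with `trials_a[[a]]` as the test
#' trial and `trials_b[[b]]` as the reference. The matrix is generally
#' asymmetric because the projection is test-anchored. Pairs whose length
#' difference exceeds the window are infeasible and returned as `NA`.
#'
#' @param trials_a,trials_b lists of channel matrices sharing one channel
#'   set.
#' @param window_w band width in samples.
#' @return numeric matrix `length(trials_a)` x `length(trials_b)`.
#' @export
pairwise_distances <- function(trials_a, trials_b = trials_a, window_w) {
  na <- length(trials_a)
  nb <- length(trials_b)
  D <- matrix(NA_real_, na, nb)
  self <- identical(trials_a, trials_b)
  for (a in seq_len(na)) {
    for (b in seq_len(nb)) {
      if (self && a == b) {
        D[a, b] <- 0
        next
      }
      r <- .dtw_band_cpp(trials_a[[a]], trials_b[[b]],
                         as.integer(window_w), FALSE)
      if (isTRUE(r$feasible)) D[a, b] <- r$projected_distance
    }
  }
  D
}
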