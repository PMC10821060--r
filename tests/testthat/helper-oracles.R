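# Independent oracles, deliberately naive: exhaustive recursion over all
# monotone warp paths and closed-form statistics, used to pin down the
# package's optimized implementations on small instances.

# minimal accumulated DTW cost by exhaustive forward recursion (full window)
oracle_dtw_cost <- function(x, y) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  n <- nrow(x)
  m <- nrow(y)
  cost <- function(i, j) sqrt(sum((x[i, ] - y[j, ])^2))
  rec <- function(i, j) {
    c0 <- cost(i, j)
    if (i == n && j == m) return(c0)
    best <- Inf
    if (i < n && j < m) best <- min(best, rec(i + 1, j + 1))
    if (i < n) best <- min(best, rec(i + 1, j))
    if (j < m) best <- min(best, rec(i, j + 1))
    c0 + best
  }
  rec(1, 1)
}

# all monotone paths from (1,1) to (n,m) as L x 2 matrices
oracle_all_paths <- function(n, m) {
  out <- list()
  walk <- function(path, i, j) {
    if (i == n && j == m) {
      out[[length(out) + 1]] <<- do.call(rbind, path)
      return(invisible())
    }
    if (i < n && j < m) walk(c(path, list(c(i + 1, j + 1))), i + 1, j + 1)
    if (i < n) walk(c(path, list(c(i + 1, j))), i + 1, j)
    if (j < m) walk(c(path, list(c(i, j + 1))), i, j + 1)
  }
  walk(list(c(1, 1)), 1, 1)
  out
}

# the optimal path the documented tie-break selects: among minimum-cost
# paths, the one whose reversed step sequence is lexicographically first in
# the order diagonal < test-advancing < reference-advancing (equivalent to
# backtracking with the diagonal-first preference)
oracle_dtw_path <- function(x, y) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  paths <- oracle_all_paths(nrow(x), nrow(y))
  costs <- vapply(paths, function(p)
    sum(sqrt(rowSums((x[p[, 1], , drop = FALSE] -
                        y[p[, 2], , drop = FALSE])^2))), numeric(1))
  best <- which(costs <= min(costs) + 1e-12)
  key <- vapply(best, function(k) {
    st <- diff(paths[[k]])
    digit <- ifelse(st[, 1] == 1 & st[, 2] == 1, 0L,
                    ifelse(st[, 1] == 1, 1L, 2L))
    paste(rev(digit), collapse = "")
  }, character(1))
  paths[[best[order(key)[1]]]]
}

# projected distance computed from first principles for a given path
oracle_projected <- function(x, y, path) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  d <- vapply(seq_len(nrow(x)), function(i) {
    js <- path[path[, 1] == i, 2]
    rbar <- colMeans(y[js, , drop = FALSE])
    sqrt(sum((x[i, ] - rbar)^2))
  }, numeric(1))
  mean(d)
}

# closed-form one-sided Welch t-test p-value, H1: mean(x) < mean(y)
oracle_welch_p <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  v1 <- var(x)
  v2 <- var(y)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  pt(t, df)
}

# angle in degrees between corresponding rows of two T x 3 matrices
row_angle_deg <- function(a, b) {
  ca <- rowSums(a * b) / sqrt(rowSums(a * a) * rowSums(b * b))
  acos(pmin(1, pmax(-1, ca))) * 180 / pi
}
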