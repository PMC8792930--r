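# Independent reference implementations used as oracles, plus small random
# fixture generators. These deliberately use the slowest, most literal
# formulation of each quantity and share no code with the package internals.

# IoU by counting pixels on a fine raster (exact for integer-coordinate boxes)
raster_iou <- function(a, b) {
  x_hi <- max(a[3], b[3]); y_hi <- max(a[4], b[4])
  grid_a <- matrix(FALSE, y_hi, x_hi)
  grid_b <- grid_a
  if (a[3] > a[1] && a[4] > a[2])
    grid_a[(a[2] + 1):a[4], (a[1] + 1):a[3]] <- TRUE
  if (b[3] > b[1] && b[4] > b[2])
    grid_b[(b[2] + 1):b[4], (b[1] + 1):b[3]] <- TRUE
  sum(grid_a & grid_b) / sum(grid_a | grid_b)
}

random_box <- function(max_coord = 100, min_size = 1) {
  x0 <- runif(1, 0, max_coord - min_size)
  y0 <- runif(1, 0, max_coord - min_size)
  box(x0, y0, x0 + runif(1, min_size, max_coord - x0),
      y0 + runif(1, min_size, max_coord - y0))
}

random_int_box <- function(max_coord = 12) {
  x <- sort(sample.int(max_coord + 1, 2) - 1)
  y <- sort(sample.int(max_coord + 1, 2) - 1)
  while (x[1] == x[2]) x <- sort(sample.int(max_coord + 1, 2) - 1)
  while (y[1] == y[2]) y <- sort(sample.int(max_coord + 1, 2) - 1)
  box(x[1], y[1], x[2], y[2])
}

# literal triple-loop transcription of the GRNN predictor: for each query,
# accumulate Gaussian kernel weights term by term
grnn_loop_oracle <- function(X_train, y_train, X_query, sigma) {
  n <- nrow(X_train)
  out <- numeric(nrow(X_query))
  for (i in seq_len(nrow(X_query))) {
    num <- 0; den <- 0
    for (k in seq_len(n)) {
      d_k <- 0
      for (j in seq_len(ncol(X_train)))
        d_k <- d_k + (X_query[i, j] - X_train[k, j])^2
      K <- exp(-d_k / (2 * sigma^2))
      num <- num + y_train[k] * K
      den <- den + K
    }
    out[i] <- num / den
  }
  out
}

# naive O(n r^2) sliding-window guided filter on a matrix, truncated windows
naive_guided_filter <- function(p, g, radius, eps) {
  n1 <- nrow(p); n2 <- ncol(p)
  win_mean <- function(m, i, j) {
    mean(m[max(1, i - radius):min(n1, i + radius),
           max(1, j - radius):min(n2, j + radius)])
  }
  a <- b <- matrix(0, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    mg <- win_mean(g, i, j); mp <- win_mean(p, i, j)
    vg <- max(win_mean(g * g, i, j) - mg^2, 0)
    cv <- win_mean(g * p, i, j) - mg * mp
    den <- vg + eps
    a[i, j] <- if (den > 0) cv / den else 0
    b[i, j] <- mp - a[i, j] * mg
  }
  out <- matrix(0, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2))
    out[i, j] <- win_mean(a, i, j) * g[i, j] + win_mean(b, i, j)
  pmin(pmax(out, 0), 1)
}

# exhaustive k-means optimum: minimum within-cluster sum of squares over all
# assignments of n points to at most k clusters
brute_force_inertia <- function(x, k) {
  n <- nrow(x)
  best <- Inf
  assign_vec <- rep(1L, n)
  repeat {
    inertia <- 0
    for (c in unique(assign_vec)) {
      m <- x[assign_vec == c, , drop = FALSE]
      ctr <- colMeans(m)
      inertia <- inertia + sum(sweep(m, 2, ctr)^2)
    }
    best <- min(best, inertia)
    # odometer increment over assignments in {1..k}^n
    i <- 1L
    while (i <= n && assign_vec[i] == k) { assign_vec[i] <- 1L; i <- i + 1L }
    if (i > n) break
    assign_vec[i] <- assign_vec[i] + 1L
  }
  best
}

# maximum number of prediction/ground-truth pairs matchable at the IoU
# threshold, by exhaustive assignment (class-blind; callers pass one class)
brute_force_max_matching <- function(iou_mat, thresh) {
  np <- nrow(iou_mat); ng <- ncol(iou_mat)
  recurse <- function(i, used) {
    if (i > np) return(0L)
    best <- recurse(i + 1L, used)  # leave prediction i unmatched
    for (j in seq_len(ng)) {
      if (!used[j] && iou_mat[i, j] >= thresh) {
        used[j] <- TRUE
        best <- max(best, 1L + recurse(i + 1L, used))
        used[j] <- FALSE
      }
    }
    best
  }
  recurse(1L, rep(FALSE, ng))
}

# random labelled-box scene for matching property tests
random_scene <- function(n_pred, n_gt, max_coord = 60) {
  mk <- function(n, conf) {
    if (n == 0) {
      df <- data.frame(class = character(0), x_min = numeric(0),
                       y_min = numeric(0), x_max = numeric(0),
                       y_max = numeric(0))
      if (conf) df$confidence <- numeric(0)
      return(df)
    }
    b <- t(vapply(seq_len(n), function(i) unclass(random_box(max_coord, 2)),
                  numeric(4)))
    df <- data.frame(class = sample(class_vocabulary(), n, replace = TRUE),
                     x_min = b[, 1], y_min = b[, 2], x_max = b[, 3],
                     y_max = b[, 4])
    if (conf) df$confidence <- runif(n)
    df
  }
  list(preds = mk(n_pred, TRUE), gts = mk(n_gt, FALSE))
}
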