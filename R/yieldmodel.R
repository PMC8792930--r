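# Count-to-yield stage: per-pot count aggregation, the GRNN seed-number
# model with PLSR and BPNN baselines, the ACC deviation statistic, and
# pod-type-weighted conversion of counts to grain mass.

count_cols <- function() c("n_leaf", paste0("n_pod", 1:5))

as_count_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, count_cols(), drop = FALSE])
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  storage.mode(x) <- "double"
  if (ncol(x) != 6L) stop("count vectors have 6 components (leaf + 5 pod types)")
  if (any(x < 0)) stop("counts must be non-negative")
  colnames(x) <- count_cols()
  x
}

#' Aggregate four per-view counts into a per-pot total
#'
#' Each pot is photographed from four directions 90 degrees apart; the pot's
#' count vector is the componentwise sum over the four views.
#'
#' @param views A 4-row data frame or matrix of per-view count vectors
#'   (columns `n_leaf`, `n_pod1` .. `n_pod5`).
#' @return A named numeric per-pot-total count vector.
#' @export
aggregate_views <- function(views) {
  m <- as_count_matrix(views)
  if (nrow(m) != 4L)
    stop("expected exactly 4 per-view count vectors, got ", nrow(m))
  colSums(m)
}

#' Seed number implied by a pod-type count vector
#'
#' A type-t pod holds t seeds, so the seed number is `sum(t * n_pod_t)`;
#' leaves carry none.
#'
#' @param counts Count vector(s), per-pot totals.
#' @return Numeric seed number per row.
#' @export
seed_number <- function(counts) {
  m <- as_count_matrix(counts)
  drop(m[, paste0("n_pod", 1:5), drop = FALSE] %*% (1:5))
}

# ---- GRNN ------------------------------------------------------------------

#' Fit a generalized regression neural network
#'
#' A GRNN is Nadaraya-Watson kernel regression: it memorizes the training
#' pairs and predicts the Gaussian-kernel-weighted mean of the stored targets,
#' `Y(x) = sum_k y_k K(x, x_k) / sum_k K(x, x_k)` with
#' `K(x, x_k) = exp(-d_k / (2 sigma^2))` and `d_k` the squared Euclidean
#' distance. The single bandwidth `sigma` controls smoothing: as `sigma -> 0`
#' prediction approaches the nearest neighbour's target, as `sigma -> Inf`
#' the global mean.
#'
#' Features are standardized (train mean/SD) by default so one bandwidth can
#' serve heterogeneous count scales. `sigma = "auto"` selects the bandwidth
#' minimizing leave-one-out cross-validated squared error over 25 log-spaced
#' values in \[1e-2, 1e2\] (on the standardized scale).
#'
#' @param X Numeric matrix or count data frame of training inputs (one row
#'   per pot).
#' @param y Numeric targets (seed numbers), same length as rows of `X`.
#' @param sigma Positive bandwidth, or `"auto"` for LOO-CV selection.
#' @param standardize Standardize features to train mean 0 / SD 1.
#' @return An object of class `"grnn"`.
#' @export
grnn_fit <- function(X, y, sigma = "auto", standardize = TRUE) {
  X <- input_matrix(X)
  y <- as.numeric(y)
  if (nrow(X) == 0L) stop("empty training set")
  if (length(y) != nrow(X)) stop("X and y sizes differ")
  if (any(!is.finite(y))) stop("non-finite targets")
  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2L, stats::sd)
    scl[!is.finite(scl) | scl == 0] <- 1
  } else {
    ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  }
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  if (identical(sigma, "auto")) {
    grid <- 10^seq(-2, 2, length.out = 25L)
    loo <- vapply(grid, function(s) grnn_loo_sse(Xs, y, s), numeric(1))
    sigma <- grid[which.min(loo)]
  } else {
    sigma <- as.numeric(sigma)
    if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  }
  structure(list(X = Xs, y = y, sigma = sigma, center = ctr, scale = scl),
            class = "grnn")
}

input_matrix <- function(X) {
  if (is.data.frame(X)) {
    if (all(count_cols() %in% names(X))) X <- X[, count_cols(), drop = FALSE]
    X <- as.matrix(X)
  }
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("non-finite inputs")
  X
}

# pairwise squared distances, rows of a vs rows of b
pairwise_sqdist <- function(a, b) {
  d <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
  pmax(d, 0)
}

grnn_loo_sse <- function(Xs, y, sigma) {
  n <- nrow(Xs)
  if (n < 2L) return(0)
  D <- pairwise_sqdist(Xs, Xs)
  # shift each row by its smallest off-diagonal distance to dodge underflow
  diag(D) <- Inf
  shift <- apply(D, 1L, min)
  K <- exp(-sweep(D, 1L, shift) / (2 * sigma^2))
  K[!is.finite(K)] <- 0  # Inf - Inf on the diagonal when n == 1 per row
  diag(K) <- 0
  denom <- rowSums(K)
  pred <- ifelse(denom > 0, (K %*% y) / denom, mean(y))
  sum((pred - y)^2)
}

#' Predict with a fitted GRNN
#'
#' Kernel-weighted mean of the stored targets; always lies in
#' `[min(y), max(y)]`. Underflow for distant queries is avoided by shifting
#' distances by their per-query minimum before exponentiation (the weighted
#' mean is algebraically invariant under this shift); in the extreme-
#' bandwidth limit where all shifted kernels underflow, the nearest stored
#' target is returned (the `sigma -> 0` limit).
#'
#' @param model A `"grnn"` from [grnn_fit()].
#' @param X Query inputs, one row per prediction.
#' @return Numeric predictions.
#' @export
grnn_predict <- function(model, X) {
  X <- input_matrix(X)
  Xs <- sweep(sweep(X, 2L, model$center), 2L, model$scale, "/")
  D <- pairwise_sqdist(Xs, model$X)
  shift <- apply(D, 1L, min)
  K <- exp(-sweep(D, 1L, shift) / (2 * model$sigma^2))
  denom <- rowSums(K)
  nearest <- model$y[apply(D, 1L, which.min)]
  ifelse(denom > 0, drop(K %*% model$y) / denom, nearest)
}

#' Persist and restore a GRNN model
#'
#' The model is its training pairs plus bandwidth and standardization
#' parameters, stored as documented JSON.
#'
#' @param model A `"grnn"`.
#' @param path JSON file path.
#' @return `grnn_load()` returns the restored `"grnn"`.
#' @export
grnn_save <- function(model, path) {
  jsonlite::write_json(
    list(X = model$X, y = model$y, sigma = model$sigma,
         center = model$center, scale = model$scale),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname grnn_save
#' @export
grnn_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(X = as.matrix(obj$X), y = as.numeric(obj$y),
                 sigma = obj$sigma, center = obj$center, scale = obj$scale),
            class = "grnn")
}

# ---- PLSR baseline (NIPALS) ------------------------------------------------

#' Partial least squares regression baseline
#'
#' Single-response PLSR via the NIPALS algorithm on centered/scaled data.
#' The number of latent components (at most the number of features) is
#' chosen by leave-one-out cross-validation when `ncomp = "auto"`.
#'
#' @param X Training inputs (matrix or count data frame).
#' @param y Numeric targets.
#' @param ncomp Number of latent components, or `"auto"`.
#' @return An object of class `"plsr_model"`.
#' @export
plsr_fit <- function(X, y, ncomp = "auto") {
  X <- input_matrix(X); y <- as.numeric(y)
  if (nrow(X) == 0L) stop("empty training set")
  if (length(y) != nrow(X)) stop("X and y sizes differ")
  if (any(!is.finite(y))) stop("non-finite targets")
  max_comp <- min(ncol(X), nrow(X) - 1L)
  if (identical(ncomp, "auto")) {
    if (nrow(X) < 3L) {
      ncomp <- 1L
    } else {
      cand <- seq_len(max(max_comp, 1L))
      sse <- vapply(cand, function(a) plsr_loo_sse(X, y, a), numeric(1))
      ncomp <- cand[which.min(sse)]
    }
  }
  ncomp <- max(1L, min(as.integer(ncomp), max(max_comp, 1L)))
  fit <- nipals_pls(X, y, ncomp)
  structure(fit, class = "plsr_model")
}

nipals_pls <- function(X, y, ncomp) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd); scl[!is.finite(scl) | scl == 0] <- 1
  Xc <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  ymean <- mean(y)
  yc <- y - ymean
  p <- ncol(Xc)
  W <- P <- matrix(0, p, ncomp)
  qvec <- numeric(ncomp)
  Ttot <- matrix(0, nrow(Xc), ncomp)
  E <- Xc; f <- yc
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- a - 1L; break }
    w <- w / nw
    t_score <- drop(E %*% w)
    tt <- sum(t_score^2)
    if (tt < 1e-12) { ncomp <- a - 1L; break }
    p_load <- drop(crossprod(E, t_score)) / tt
    q <- sum(f * t_score) / tt
    E <- E - tcrossprod(t_score, p_load)
    f <- f - q * t_score
    W[, a] <- w; P[, a] <- p_load; qvec[a] <- q; Ttot[, a] <- t_score
  }
  if (ncomp < 1L) {
    beta <- rep(0, p)  # constant model: X carried no usable variance
  } else {
    W <- W[, seq_len(ncomp), drop = FALSE]
    P <- P[, seq_len(ncomp), drop = FALSE]
    qvec <- qvec[seq_len(ncomp)]
    beta <- drop(W %*% solve(crossprod(P, W), qvec))
  }
  list(beta = beta, center = ctr, scale = scl, ymean = ymean,
       ncomp = max(ncomp, 0L))
}

plsr_loo_sse <- function(X, y, ncomp) {
  n <- nrow(X)
  sum(vapply(seq_len(n), function(i) {
    fit <- nipals_pls(X[-i, , drop = FALSE], y[-i],
                      min(ncomp, min(ncol(X), n - 2L)))
    (plsr_predict_raw(fit, X[i, , drop = FALSE]) - y[i])^2
  }, numeric(1)))
}

plsr_predict_raw <- function(fit, X) {
  Xc <- sweep(sweep(X, 2L, fit$center), 2L, fit$scale, "/")
  drop(Xc %*% fit$beta) + fit$ymean
}

#' @rdname plsr_fit
#' @param model A fitted `"plsr_model"`.
#' @export
plsr_predict <- function(model, X) {
  plsr_predict_raw(model, input_matrix(X))
}

# ---- BPNN baseline ---------------------------------------------------------

#' Back-propagation neural network baseline
#'
#' A single-hidden-layer feed-forward network on standardized inputs and a
#' \[0, 1\]-scaled target, fitted with [nnet::nnet()]. Initialization is
#' seeded, so the same seed reproduces the same fit exactly.
#'
#' @param X Training inputs.
#' @param y Numeric targets.
#' @param hidden Hidden layer size.
#' @param seed Integer seed for weight initialization.
#' @param maxit Maximum training iterations.
#' @param decay Weight decay regularizer.
#' @return An object of class `"bpnn_model"`.
#' @export
bpnn_fit <- function(X, y, hidden = 10L, seed = 1L, maxit = 2000L,
                     decay = 1e-3) {
  X <- input_matrix(X); y <- as.numeric(y)
  if (nrow(X) == 0L) stop("empty training set")
  if (length(y) != nrow(X)) stop("X and y sizes differ")
  if (any(!is.finite(y))) stop("non-finite targets")
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd); scl[!is.finite(scl) | scl == 0] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  ylo <- min(y); yhi <- max(y)
  yspan <- if (yhi > ylo) yhi - ylo else 1
  ys <- (y - ylo) / yspan
  net <- withr::with_seed(seed,
    nnet::nnet(Xs, ys, size = hidden, linout = TRUE, maxit = maxit,
               decay = decay, trace = FALSE))
  structure(list(net = net, center = ctr, scale = scl, ylo = ylo,
                 yspan = yspan),
            class = "bpnn_model")
}

#' @rdname bpnn_fit
#' @param model A fitted `"bpnn_model"`.
#' @export
bpnn_predict <- function(model, X) {
  X <- input_matrix(X)
  Xs <- sweep(sweep(X, 2L, model$center), 2L, model$scale, "/")
  drop(stats::predict(model$net, Xs)) * model$yspan + model$ylo
}

# ---- scoring and mass conversion ------------------------------------------

#' Prediction accuracy from relative deviation
#'
#' `ACC = mean_i (y_i - |y_i - y'_i|) / y_i`, i.e. 1 minus the mean relative
#' absolute error over pots. Equal to 1 exactly when every prediction is
#' exact; can go negative for predictions off by more than 100%.
#'
#' @param actual Positive actual values (per-pot seed numbers or masses).
#' @param predicted Predictions, same length.
#' @return ACC as a fraction (<= 1).
#' @export
acc <- function(actual, predicted) {
  if (length(actual) != length(predicted)) stop("length mismatch")
  if (length(actual) == 0L) stop("empty input")
  if (any(actual <= 0)) stop("actual values must be positive")
  mean((actual - abs(actual - predicted)) / actual)
}

#' Mean accuracy over repeated runs
#'
#' Arithmetic mean of per-run ACC values, the summary reported when a model
#' is refit on several random train/test splits.
#'
#' @param run_accs Non-empty numeric vector of per-run ACC values.
#' @return Mean ACC.
#' @export
mean_run_accuracy <- function(run_accs) {
  if (length(run_accs) == 0L) stop("no runs")
  mean(run_accs)
}

#' Per-grain seed weights
#'
#' Average grams per single grain by pod type (`w1` .. `w5`, measured per
#' 100-seed samples 5-10 days after harvest) plus the uniform all-types
#' average `w_a`. Heavier grains come from single-seed pods.
#'
#' @param w Numeric length 5, grams per grain for pod types 1..5.
#' @param w_a Uniform grams per grain.
#' @return A list of class `"seed_weights"`.
#' @export
seed_weights <- function(w = c(0.242, 0.207, 0.196, 0.189, 0.186),
                         w_a = 0.203) {
  if (length(w) != 5L || any(w <= 0) || w_a <= 0)
    stop("seed weights must be 5 positive per-type values and a positive w_a")
  structure(list(w = as.numeric(w), w_a = as.numeric(w_a)),
            class = "seed_weights")
}

#' Convert pod-type counts to grain mass
#'
#' A type-t pod contributes `t` grains. `mode = "per_type"` weighs each
#' grain by its pod type's average grain weight, `sum_t n_t * t * w_t`;
#' `mode = "uniform"` weighs every grain at the all-types average,
#' `(sum_t n_t * t) * w_a`. Leaves contribute no mass. The two modes agree
#' exactly whenever all `w_t` equal `w_a`.
#'
#' @param counts Per-pot-total count vector(s).
#' @param weights A [seed_weights()] object.
#' @param mode `"per_type"` or `"uniform"`.
#' @return Grams per row of `counts`.
#' @export
yield_grams <- function(counts, weights = seed_weights(),
                        mode = c("per_type", "uniform")) {
  mode <- match.arg(mode)
  stopifnot(inherits(weights, "seed_weights"))
  m <- as_count_matrix(counts)
  pods <- m[, paste0("n_pod", 1:5), drop = FALSE]
  if (mode == "per_type")
    drop(pods %*% ((1:5) * weights$w))
  else
    drop(pods %*% (1:5)) * weights$w_a
}
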