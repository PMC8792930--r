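# Anchor prior estimation: k-means++ clustering of labelled box (width,
# height) pairs with plain Euclidean distance, the procedure used to derive a
# detector's anchor frame scales from its training labels.

#' Cluster box dimensions into anchor priors
#'
#' Runs k-means++ seeding (first center uniform at random, each subsequent
#' center drawn with probability proportional to squared Euclidean distance to
#' the nearest chosen center) followed by Lloyd iterations until assignments
#' stop changing (or `max_iter`). Distances are plain Euclidean on raw pixel
#' (w, h) pairs, not the 1 - IoU metric some detectors use. Deterministic for
#' a given `seed`, and invariant to input row order: rows are canonically
#' sorted by (w, h) before seeding.
#'
#' @param dims Two-column numeric matrix or data frame of box widths and
#'   heights in pixels; all entries must be positive.
#' @param k Number of anchors; must not exceed the number of distinct rows.
#' @param seed Integer seed controlling seeding (and restarts).
#' @param restarts Number of independent k-means++ starts; the run with the
#'   lowest inertia wins.
#' @param max_iter Cap on Lloyd iterations per start.
#' @return An object of class `"anchor_set"`: list with `centers` (k x 2
#'   matrix, rows sorted ascending by area), `k`, `inertia` (sum of squared
#'   distances of points to their assigned center), and `trace` (per-iteration
#'   inertia of the winning start, non-increasing).
#' @examples
#' dims <- rbind(matrix(10, 5, 2), matrix(50, 5, 2))
#' cluster_anchors(dims, k = 2, seed = 1)$centers
#' @export
cluster_anchors <- function(dims, k, seed = 1L, restarts = 1L, max_iter = 300L) {
  dims <- as_dims_matrix(dims)
  if (k < 1L) stop("k must be at least 1")
  n_distinct <- nrow(unique(dims))
  if (k > n_distinct)
    stop("k (", k, ") exceeds the number of distinct dimension pairs (",
         n_distinct, ")")
  # canonical pre-sort: order independence for a fixed seed
  dims <- dims[order(dims[, 1L], dims[, 2L]), , drop = FALSE]
  best <- NULL
  for (r in seq_len(restarts)) {
    res <- withr::with_seed(seed + r - 1L, kmeans_pp_once(dims, k, max_iter))
    if (is.null(best) || res$inertia < best$inertia) best <- res
  }
  ord <- order(best$centers[, 1L] * best$centers[, 2L],
               best$centers[, 1L], best$centers[, 2L])
  structure(list(centers = best$centers[ord, , drop = FALSE], k = k,
                 inertia = best$inertia, trace = best$trace),
            class = "anchor_set")
}

as_dims_matrix <- function(dims) {
  if (is.data.frame(dims)) dims <- as.matrix(dims)
  if (is.null(dim(dims))) dims <- matrix(dims, ncol = 2L)
  storage.mode(dims) <- "double"
  if (ncol(dims) != 2L) stop("dims must have two columns (w, h)")
  if (nrow(dims) == 0L) stop("dims is empty")
  if (any(!is.finite(dims)) || any(dims <= 0))
    stop("all box dimensions must be positive and finite")
  colnames(dims) <- c("w", "h")
  dims
}

# squared Euclidean distance from each row of x to each row of centers
sqdist_to_centers <- function(x, centers) {
  d <- outer(rowSums(x^2), rowSums(centers^2), `+`) - 2 * x %*% t(centers)
  pmax(d, 0)
}

kmeans_pp_once <- function(x, k, max_iter) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, 2L)
  centers[1L, ] <- x[sample.int(n, 1L), ]
  if (k > 1L) {
    d2 <- sqdist_to_centers(x, centers[1L, , drop = FALSE])[, 1L]
    for (j in 2L:k) {
      if (all(d2 == 0)) {
        # all points coincide with chosen centers; pick uniformly
        idx <- sample.int(n, 1L)
      } else {
        idx <- sample.int(n, 1L, prob = d2)
      }
      centers[j, ] <- x[idx, ]
      d2 <- pmin(d2, sqdist_to_centers(x, centers[j, , drop = FALSE])[, 1L])
    }
  }
  assign_prev <- rep(0L, n)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    d <- sqdist_to_centers(x, centers)
    assign_new <- apply(d, 1L, which.min)  # ties break to the lower index
    for (j in seq_len(k)) {
      members <- assign_new == j
      if (!any(members)) {
        # empty-cluster repair: re-seed at the point farthest from its center
        far <- which.max(d[cbind(seq_len(n), assign_new)])
        centers[j, ] <- x[far, ]
        assign_new[far] <- j
      } else {
        centers[j, ] <- colMeans(x[members, , drop = FALSE])
      }
    }
    d <- sqdist_to_centers(x, centers)
    assign_new <- apply(d, 1L, which.min)
    trace <- c(trace, sum(d[cbind(seq_len(n), assign_new)]))
    if (identical(assign_new, assign_prev)) break
    assign_prev <- assign_new
  }
  d <- sqdist_to_centers(x, centers)
  inertia <- sum(d[cbind(seq_len(n), apply(d, 1L, which.min))])
  list(centers = centers, inertia = inertia, trace = trace)
}

#' @export
print.anchor_set <- function(x, ...) {
  cat("Anchor set: k =", x$k, " inertia =", format(x$inertia), "\n")
  print(round(x$centers, 1))
  invisible(x)
}

#' Sweep the anchor count k and report inertia
#'
#' Clusters the same dimensions at each k in `k_range`, reporting the inertia
#' so an elbow can be read off. With enough restarts inertia is non-increasing
#' in k.
#'
#' @inheritParams cluster_anchors
#' @param k_range Integer vector of k values, each within
#'   `[1, nrow(unique(dims))]`.
#' @return Data frame with columns `k` and `inertia`.
#' @export
sweep_k <- function(dims, k_range = 6:11, seed = 1L, restarts = 5L) {
  dims <- as_dims_matrix(dims)
  data.frame(
    k = as.integer(k_range),
    inertia = vapply(k_range, function(k)
      cluster_anchors(dims, k, seed = seed, restarts = restarts)$inertia,
      numeric(1))
  )
}

#' Default anchor priors
#'
#' The nine (w, h) anchor centers used by the improved pod/leaf detector,
#' shipped as a documented constant. These came from clustering a label set
#' that is not distributed with this package, so they are a usable default for
#' configuring a detector, never a reference value for testing the clustering
#' code.
#'
#' @return A 9 x 2 matrix of (w, h) pairs in pixels, sorted by area.
#' @export
default_anchors <- function() {
  m <- matrix(c(27, 21, 23, 31, 41, 52, 64, 42, 78, 90, 76, 103,
                91, 94, 106, 97, 113, 107),
              ncol = 2L, byrow = TRUE)
  colnames(m) <- c("w", "h")
  m
}

#' Read box dimensions for anchor clustering
#'
#' `read_dims_csv()` reads a two-column (w, h) CSV. `read_dims_yolo()`
#' collects dimensions from YOLO-format label files, denormalizing by the
#' image sizes in a manifest.
#'
#' @param path CSV path with columns `w` and `h`.
#' @return Two-column numeric matrix of dimensions.
#' @export
read_dims_csv <- function(path) {
  df <- utils::read.csv(path)
  as_dims_matrix(df[, c("w", "h")])
}

#' @rdname read_dims_csv
#' @param manifest Data frame (or CSV path) with columns `label_file`,
#'   `width`, `height` giving, per image, its label file and pixel size.
#' @export
read_dims_yolo <- function(manifest) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  dims <- lapply(seq_len(nrow(manifest)), function(i) {
    lb <- read_yolo_labels(manifest$label_file[i],
                           manifest$width[i], manifest$height[i])
    if (nrow(lb) == 0L) return(NULL)
    cbind(lb$x_max - lb$x_min, lb$y_max - lb$y_min)
  })
  as_dims_matrix(do.call(rbind, dims))
}

#' Write anchors in detector-config text form
#'
#' Serializes centers as the comma-separated `w,h, w,h, ...` dialect detector
#' configuration files expect, rounding to the nearest integer pixel.
#'
#' @param anchors An `anchor_set` or a two-column matrix.
#' @param path Output file; when `NULL` the string is returned invisibly
#'   without writing.
#' @return The anchor string, invisibly.
#' @export
write_anchor_text <- function(anchors, path = NULL) {
  centers <- if (inherits(anchors, "anchor_set")) anchors$centers else anchors
  s <- paste(apply(round(centers), 1L, paste, collapse = ","), collapse = ", ")
  if (!is.null(path)) writeLines(s, path)
  invisible(s)
}
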