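# Axis-aligned bounding boxes in continuous pixel coordinates.
#
# Convention: corner form c(x_min, y_min, x_max, y_max), origin at the image's
# top-left, x increasing rightward and y downward. Detector label files use
# normalized center form (cx, cy, w, h); conversion helpers are provided.

#' Construct an axis-aligned bounding box
#'
#' A box is a named numeric vector `c(x_min, y_min, x_max, y_max)` in
#' continuous pixel coordinates with strictly positive width and height.
#'
#' @param x_min,y_min,x_max,y_max Corner coordinates; `x_max > x_min` and
#'   `y_max > y_min` are required (zero-area boxes are invalid geometry).
#' @return A named numeric vector of class `"box"`.
#' @examples
#' b <- box(0, 0, 2, 2)
#' box_area(b)
#' @export
box <- function(x_min, y_min, x_max, y_max) {
  b <- c(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
         x_max = as.numeric(x_max), y_max = as.numeric(y_max))
  validate_box(b)
  class(b) <- "box"
  b
}

validate_box <- function(b) {
  if (length(b) != 4L || any(!is.finite(b)))
    stop("a box must be four finite coordinates (x_min, y_min, x_max, y_max)")
  if (b[[3L]] <= b[[1L]] || b[[4L]] <= b[[2L]])
    stop("degenerate box: x_max must exceed x_min and y_max must exceed y_min")
  invisible(b)
}

#' @rdname box
#' @param b A box.
#' @export
box_area <- function(b) {
  validate_box(b)
  (b[[3L]] - b[[1L]]) * (b[[4L]] - b[[2L]])
}

#' @rdname box
#' @export
box_center <- function(b) {
  validate_box(b)
  c(x = (b[[1L]] + b[[3L]]) / 2, y = (b[[2L]] + b[[4L]]) / 2)
}

#' Convert between corner form and center form
#'
#' Center form is `c(cx, cy, w, h)`; YOLO label files store it normalized by
#' image size. The pair of conversions round-trips exactly for coordinates
#' representable in double precision on a dyadic grid (integers, halves, ...).
#'
#' @param b A corner-form box.
#' @return `box_to_center()` a named numeric `c(cx, cy, w, h)`;
#'   `center_to_box()` a `"box"`.
#' @export
box_to_center <- function(b) {
  validate_box(b)
  c(cx = (b[[1L]] + b[[3L]]) / 2, cy = (b[[2L]] + b[[4L]]) / 2,
    w = b[[3L]] - b[[1L]], h = b[[4L]] - b[[2L]])
}

#' @rdname box_to_center
#' @param cx,cy,w,h Center coordinates and dimensions, `w, h > 0`.
#' @export
center_to_box <- function(cx, cy, w, h) {
  if (any(w <= 0) || any(h <= 0)) stop("center-form box needs w > 0 and h > 0")
  box(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
}

intersection_area <- function(a, b) {
  iw <- min(a[[3L]], b[[3L]]) - max(a[[1L]], b[[1L]])
  ih <- min(a[[4L]], b[[4L]]) - max(a[[2L]], b[[2L]])
  if (iw <= 0 || ih <= 0) return(0)
  iw * ih
}

#' Intersection over union of two boxes
#'
#' The standard similarity between a prediction box and a real box: the area
#' of their intersection divided by the area of their union. Boxes that only
#' share an edge have zero-measure intersection and hence IoU 0.
#'
#' @param a,b Boxes (corner form).
#' @return A fraction in \[0, 1\].
#' @examples
#' iou(box(0, 0, 2, 2), box(1, 1, 3, 3)) # 1/7
#' @export
iou <- function(a, b) {
  validate_box(a); validate_box(b)
  inter <- intersection_area(a, b)
  inter / (box_area(a) + box_area(b) - inter)
}

#' Distance-IoU similarity and loss
#'
#' DIoU penalizes IoU by the squared distance between box centers, normalized
#' by the squared diagonal of the smallest box enclosing both:
#' `DIoU = IoU - rho^2 / c^2`. Unlike plain IoU it separates a contained box
#' at the center from one near the edge, and stays informative (negative) for
#' disjoint boxes, so the loss `1 - DIoU` still ranks non-overlapping
#' candidates by how far apart they are.
#'
#' @param a,b Boxes (corner form).
#' @return `diou()` a value in (-1, 1\]; `diou_loss()` `1 - diou` in \[0, 2).
#' @examples
#' diou(box(0, 0, 4, 4), box(1, 1, 3, 3)) # concentric: equals the IoU, 0.25
#' diou(box(0, 0, 2, 2), box(2, 0, 4, 2)) # disjoint: -0.2
#' @export
diou <- function(a, b) {
  box_pair_geometry(a, b)$diou
}

#' @rdname diou
#' @export
diou_loss <- function(a, b) {
  1 - diou(a, b)
}

#' Full pairwise geometry of two boxes
#'
#' @param a,b Boxes (corner form).
#' @return A list with `iou`, `center_dist_sq` (squared Euclidean distance of
#'   the two centers, px^2), `enclosing_diag_sq` (squared diagonal of the
#'   minimum enclosing box, px^2), `diou`, `loss_iou = 1 - iou` and
#'   `loss_diou = 1 - diou`.
#' @export
box_pair_geometry <- function(a, b) {
  validate_box(a); validate_box(b)
  i <- iou(a, b)
  ca <- box_center(a); cb <- box_center(b)
  rho2 <- sum((ca - cb)^2)
  # enclosing box diagonal; c^2 > 0 because both boxes have positive area
  cw <- max(a[[3L]], b[[3L]]) - min(a[[1L]], b[[1L]])
  ch <- max(a[[4L]], b[[4L]]) - min(a[[2L]], b[[2L]])
  c2 <- cw^2 + ch^2
  d <- i - rho2 / c2
  list(iou = i, center_dist_sq = rho2, enclosing_diag_sq = c2,
       diou = d, loss_iou = 1 - i, loss_diou = 1 - d)
}

#' Pairwise IoU matrix between two sets of boxes
#'
#' @param a,b Numeric matrices with columns x_min, y_min, x_max, y_max, one
#'   box per row.
#' @return An `nrow(a)` x `nrow(b)` matrix of IoU values.
#' @export
iou_matrix <- function(a, b) {
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  n <- nrow(a); m <- nrow(b)
  if (n == 0L || m == 0L) return(matrix(numeric(0), n, m))
  iw <- outer(a[, 3L], b[, 3L], pmin) - outer(a[, 1L], b[, 1L], pmax)
  ih <- outer(a[, 4L], b[, 4L], pmin) - outer(a[, 2L], b[, 2L], pmax)
  inter <- pmax(iw, 0) * pmax(ih, 0)
  area_a <- (a[, 3L] - a[, 1L]) * (a[, 4L] - a[, 2L])
  area_b <- (b[, 3L] - b[, 1L]) * (b[, 4L] - b[, 2L])
  inter / (outer(area_a, area_b, `+`) - inter)
}

as_box_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, c("x_min", "y_min", "x_max", "y_max")])
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  storage.mode(x) <- "double"
  if (ncol(x) != 4L) stop("box matrix needs 4 columns")
  if (any(x[, 3L] <= x[, 1L]) || any(x[, 4L] <= x[, 2L]))
    stop("degenerate box in matrix")
  x
}
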