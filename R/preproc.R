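# Image preprocessing: guided-filter denoising, gamma enhancement, box-aware
# augmentation and train/test splitting.
#
# Images are numeric arrays in [0, 1], either h x w (grayscale) or h x w x 3,
# as returned by png::readPNG().

#' Filter parameters for denoising and enhancement
#'
#' The study's imaging sessions span dawn and dusk; the defaults brighten
#' (`gamma < 1`) and smooth lightly. All three values are exposed because the
#' appropriate strength depends on the capture conditions.
#'
#' @param radius Window half-size of the guided filter, pixels (>= 1).
#' @param eps Guided-filter regularizer, in squared intensity units on the
#'   \[0, 1\] scale; larger values smooth more aggressively.
#' @param gamma Enhancement exponent (> 0); values below 1 brighten.
#' @return A list of class `"filter_params"`.
#' @export
filter_params <- function(radius = 8L, eps = 1e-3, gamma = 0.6) {
  if (radius < 1) stop("radius must be >= 1")
  if (eps < 0) stop("eps must be >= 0")
  if (gamma <= 0) stop("gamma must be > 0")
  structure(list(radius = as.integer(radius), eps = eps, gamma = gamma),
            class = "filter_params")
}

# Sliding-window box mean with border-truncated windows, via 2-D cumulative
# sums: O(1) per pixel regardless of radius.
box_mean <- function(m, r) {
  n1 <- nrow(m); n2 <- ncol(m)
  cs <- matrix(0, n1 + 1L, n2 + 1L)  # 2-D cumulative sum, zero-padded
  cs[-1L, -1L] <- t(apply(apply(m, 2L, cumsum), 1L, cumsum))
  lo1 <- pmax(seq_len(n1) - r, 1L); hi1 <- pmin(seq_len(n1) + r, n1)
  lo2 <- pmax(seq_len(n2) - r, 1L); hi2 <- pmin(seq_len(n2) + r, n2)
  s <- cs[hi1 + 1L, hi2 + 1L, drop = FALSE] -
       cs[lo1,      hi2 + 1L, drop = FALSE] -
       cs[hi1 + 1L, lo2,      drop = FALSE] +
       cs[lo1,      lo2,      drop = FALSE]
  s / outer(hi1 - lo1 + 1L, hi2 - lo2 + 1L)
}

guided_filter_channel <- function(p, g, radius, eps) {
  mean_g <- box_mean(g, radius)
  mean_p <- box_mean(p, radius)
  corr_gp <- box_mean(g * p, radius)
  corr_gg <- box_mean(g * g, radius)
  var_g <- pmax(corr_gg - mean_g^2, 0)  # clamp rounding noise
  cov_gp <- corr_gp - mean_g * mean_p
  denom <- var_g + eps
  a <- ifelse(denom > 0, cov_gp / denom, 0)  # flat window, no regularizer
  b <- mean_p - a * mean_g
  box_mean(a, radius) * g + box_mean(b, radius)
}

#' Edge-preserving guided-filter denoise
#'
#' Classic guided image filtering: within each `(2 radius + 1)^2` window the
#' output is modelled as a local linear function of the guide,
#' `a = cov(guide, image) / (var(guide) + eps)` and
#' `b = mean(image) - a * mean(guide)`, and each pixel averages the (a, b) of
#' all windows covering it: `out = mean(a) * guide + mean(b)`. With the image
#' as its own guide this smooths noise while keeping edges (where local
#' variance is high, `a` stays near 1). Windows are truncated at image
#' borders.
#'
#' @param image Numeric array in \[0, 1\], `h x w` or `h x w x 3`.
#' @param guide Guidance image of the same shape; defaults to `image` itself.
#' @param params A [filter_params()] list (only `radius` and `eps` are used).
#' @return Filtered image, clipped to \[0, 1\], same shape as the input.
#' @export
guided_filter <- function(image, guide = image, params = filter_params()) {
  if (!identical(dim(image), dim(guide)) &&
      !(is.null(dim(image)) && is.null(dim(guide)) &&
        length(image) == length(guide)))
    stop("image and guide must have the same shape")
  f <- function(p, g) guided_filter_channel(p, g, params$radius, params$eps)
  out <- if (length(dim(image)) == 3L) {
    arr <- image
    for (ch in seq_len(dim(image)[3L]))
      arr[, , ch] <- f(image[, , ch], guide[, , ch])
    arr
  } else {
    f(as.matrix(image), as.matrix(guide))
  }
  pmin(pmax(out, 0), 1)
}

#' Gamma enhancement
#'
#' Pointwise power-law mapping `image^gamma` on the \[0, 1\] scale: monotone,
#' fixes 0 and 1, brightens midtones when `gamma < 1` and darkens them when
#' `gamma > 1`.
#'
#' @param image Numeric array in \[0, 1\].
#' @param gamma Exponent, > 0.
#' @return Enhanced image, same shape.
#' @export
gamma_correct <- function(image, gamma = 0.6) {
  if (gamma <= 0) stop("gamma must be > 0")
  if (any(image < 0 | image > 1)) stop("image values must lie in [0, 1]")
  image^gamma
}

#' Augmentation specification
#'
#' @param ops Character subset of `rotate90`, `rotate180`, `rotate270`,
#'   `mirror_h`, `mirror_v`, `scale`, `brightness`.
#' @param scale_range Length-2 multiplicative range for the `scale` op.
#' @param brightness_range Length-2 additive delta range (on \[0, 1\]
#'   intensities) for the `brightness` op.
#' @param multiplier Output size as a multiple of the input size (>= 1); each
#'   source image contributes itself plus `multiplier - 1` transformed copies.
#' @param seed Integer seed; augmentation is deterministic given it.
#' @return A list of class `"augment_spec"`.
#' @export
augment_spec <- function(ops = c("rotate90", "rotate180", "rotate270",
                                 "mirror_h", "mirror_v", "scale", "brightness"),
                         scale_range = c(0.8, 1.2),
                         brightness_range = c(-0.2, 0.2),
                         multiplier = 5L, seed = 1L) {
  known <- c("rotate90", "rotate180", "rotate270", "mirror_h", "mirror_v",
             "scale", "brightness")
  ops <- match.arg(ops, known, several.ok = TRUE)
  if (multiplier < 1) stop("multiplier must be >= 1")
  stopifnot(length(scale_range) == 2L, all(is.finite(scale_range)),
            all(scale_range > 0), length(brightness_range) == 2L,
            all(is.finite(brightness_range)))
  structure(list(ops = ops, scale_range = scale_range,
                 brightness_range = brightness_range,
                 multiplier = as.integer(multiplier), seed = as.integer(seed)),
            class = "augment_spec")
}

img_dims <- function(image) {
  d <- dim(image)
  c(h = d[1L], w = d[2L])
}

# Apply one named op to an image and its box table. Boxes are corner-form
# columns x_min, y_min, x_max, y_max (+ any extra columns carried through).
apply_aug_op <- function(image, boxes, op, param = NULL) {
  d <- img_dims(image)
  h <- d[["h"]]; w <- d[["w"]]
  three <- length(dim(image)) == 3L
  flip_rows <- function(a) if (three) a[rev(seq_len(nrow(a))), , , drop = FALSE] else a[rev(seq_len(nrow(a))), , drop = FALSE]
  flip_cols <- function(a) if (three) a[, rev(seq_len(ncol(a))), , drop = FALSE] else a[, rev(seq_len(ncol(a))), drop = FALSE]
  transpose <- function(a) {
    if (three) aperm(a, c(2L, 1L, 3L)) else t(a)
  }
  b <- boxes
  out <- switch(op,
    mirror_h = {
      if (nrow(b)) { x0 <- b$x_min; b$x_min <- w - b$x_max; b$x_max <- w - x0 }
      list(image = flip_cols(image), boxes = b)
    },
    mirror_v = {
      if (nrow(b)) { y0 <- b$y_min; b$y_min <- h - b$y_max; b$y_max <- h - y0 }
      list(image = flip_rows(image), boxes = b)
    },
    rotate90 = {  # 90 degrees clockwise: (x, y) -> (h - y, x)
      if (nrow(b)) {
        x0 <- b$x_min; x1 <- b$x_max; y0 <- b$y_min; y1 <- b$y_max
        b$x_min <- h - y1; b$x_max <- h - y0; b$y_min <- x0; b$y_max <- x1
      }
      list(image = flip_cols(transpose(image)) , boxes = b)
    },
    rotate180 = {
      if (nrow(b)) {
        x0 <- b$x_min; x1 <- b$x_max; y0 <- b$y_min; y1 <- b$y_max
        b$x_min <- w - x1; b$x_max <- w - x0; b$y_min <- h - y1; b$y_max <- h - y0
      }
      list(image = flip_rows(flip_cols(image)), boxes = b)
    },
    rotate270 = {  # 90 degrees counter-clockwise: (x, y) -> (y, w - x)
      if (nrow(b)) {
        x0 <- b$x_min; x1 <- b$x_max; y0 <- b$y_min; y1 <- b$y_max
        b$x_min <- y0; b$x_max <- y1; b$y_min <- w - x1; b$y_max <- w - x0
      }
      list(image = flip_rows(transpose(image)), boxes = b)
    },
    scale = {
      s <- param
      nh <- max(1L, round(h * s)); nw <- max(1L, round(w * s))
      ri <- pmin(h, pmax(1L, ceiling(seq_len(nh) / s - 0.5 + 1e-9)))
      ci <- pmin(w, pmax(1L, ceiling(seq_len(nw) / s - 0.5 + 1e-9)))
      img2 <- if (three) image[ri, ci, , drop = FALSE] else image[ri, ci, drop = FALSE]
      sx <- nw / w; sy <- nh / h
      if (nrow(b)) {
        b$x_min <- b$x_min * sx; b$x_max <- b$x_max * sx
        b$y_min <- b$y_min * sy; b$y_max <- b$y_max * sy
      }
      list(image = img2, boxes = b)
    },
    brightness = {
      list(image = pmin(pmax(image + param, 0), 1), boxes = b)
    },
    stop("unknown augmentation op: ", op)
  )
  out
}

#' Augment an annotated image set
#'
#' Enlarges a dataset by geometric and photometric transforms whose effect on
#' the bounding boxes is applied exactly: right-angle rotations and mirrors
#' map box corners, scaling scales coordinates, brightness leaves boxes
#' untouched. Each output item records its `source_id` so that splits can keep
#' all derivatives of one photograph together. A transformed box that falls
#' entirely outside the canvas is dropped with a warning (only possible for
#' degenerate inputs; the supported ops keep the canvas covering all boxes).
#'
#' @param items List of annotated images; each element a list with `image`
#'   (array in \[0, 1\]), `boxes` (data frame with columns `class`, `x_min`,
#'   `y_min`, `x_max`, `y_max`) and optionally `id`.
#' @param spec An [augment_spec()].
#' @return A list of `length(items) * multiplier` items, each with `image`,
#'   `boxes`, `id`, `source_id` and `op` (the transform applied, `"identity"`
#'   for originals).
#' @export
augment_dataset <- function(items, spec = augment_spec()) {
  stopifnot(inherits(spec, "augment_spec"))
  withr::with_seed(spec$seed, {
    out <- vector("list", length(items) * spec$multiplier)
    pos <- 1L
    for (i in seq_along(items)) {
      it <- items[[i]]
      src <- if (!is.null(it$id)) it$id else paste0("img", i)
      out[[pos]] <- list(image = it$image, boxes = it$boxes, id = src,
                         source_id = src, op = "identity")
      pos <- pos + 1L
      for (j in seq_len(spec$multiplier - 1L)) {
        op <- sample(spec$ops, 1L)
        param <- switch(op,
          scale = stats::runif(1L, spec$scale_range[1L], spec$scale_range[2L]),
          brightness = stats::runif(1L, spec$brightness_range[1L],
                                    spec$brightness_range[2L]),
          NULL)
        tr <- apply_aug_op(it$image, it$boxes, op, param)
        d <- img_dims(tr$image)
        if (nrow(tr$boxes)) {
          inside <- tr$boxes$x_max > 0 & tr$boxes$x_min < d[["w"]] &
                    tr$boxes$y_max > 0 & tr$boxes$y_min < d[["h"]]
          if (any(!inside)) {
            warning(sum(!inside), " transformed box(es) fell outside the image",
                    " and were dropped (", src, ", op ", op, ")")
            tr$boxes <- tr$boxes[inside, , drop = FALSE]
          }
        }
        out[[pos]] <- list(image = tr$image, boxes = tr$boxes,
                           id = paste0(src, "_aug", j), source_id = src,
                           op = op)
        pos <- pos + 1L
      }
    }
    out
  })
}

#' Random train/test split
#'
#' Splits items into disjoint, exhaustive train and test sets at the given
#' ratio, deterministically for a given seed. By default the split is
#' group-aware: all augmented derivatives of one source image (shared
#' `source_id`) land in the same side, so near-duplicates never straddle the
#' split. Setting `group_aware = FALSE` splits individual items regardless of
#' provenance (the simpler protocol of splitting after augmentation).
#'
#' @param items List (elements may carry `source_id`) or vector.
#' @param ratio Training fraction in (0, 1); e.g. 0.8 for a 4:1 split.
#' @param seed Integer seed.
#' @param group_aware Keep items with the same `source_id` together.
#' @return List with `train` and `test` subsets of `items`.
#' @export
split_dataset <- function(items, ratio = 0.8, seed = 1L, group_aware = TRUE) {
  if (length(items) == 0L) stop("items is empty")
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  groups <- if (group_aware && is.list(items)) {
    vapply(seq_along(items), function(i) {
      s <- if (is.list(items[[i]])) items[[i]]$source_id else NULL
      if (is.null(s)) paste0("item", i) else as.character(s)
    }, character(1))
  } else {
    as.character(seq_along(items))
  }
  ug <- unique(groups)
  n_train <- round(length(ug) * ratio)
  n_train <- min(max(n_train, 1L), length(ug) - 1L)
  train_groups <- withr::with_seed(seed, sample(ug, n_train))
  idx <- groups %in% train_groups
  list(train = items[idx], test = items[!idx])
}
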