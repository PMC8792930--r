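# Synthetic potted-plant scenes and count datasets.
#
# The study's images are not deposited, so this module generates data with
# the statistical structure the pipeline assumes: pots of four plants
# photographed from four directions 90 degrees apart, leaves occluding
# colour-similar pods with occlusion increasing in leaf density, and detector
# noise calibrated to a target precision/recall. Rendering is deliberately
# simple -- filled ellipses for leaves, lobed capsules for pods, overlapping
# green hues -- enough to exercise IoU matching and occlusion bookkeeping,
# not to train a detector.

#' Specification of one rendered scene
#'
#' @param width,height Canvas size in pixels.
#' @param n_leaves,n_pods Instances to place.
#' @param type_probs Multinomial probabilities over pod types 1..5 (must sum
#'   to 1); a type-t pod is drawn with t lobes.
#' @param occlusion_threshold A pod covered by leaves over at least this
#'   fraction of its pixels is treated as occluded and emits no label.
#' @param leaf_axes Range of leaf ellipse semi-axes, pixels.
#' @param pod_lobe_radius Range of pod lobe radii, pixels.
#' @param seed Integer seed; scenes are byte-identical given it.
#' @return A list of class `"scene_spec"`.
#' @export
scene_spec <- function(width = 256L, height = 256L, n_leaves = 12L,
                       n_pods = 15L,
                       type_probs = c(0.12, 0.38, 0.33, 0.13, 0.04),
                       occlusion_threshold = 0.7,
                       leaf_axes = c(14, 30), pod_lobe_radius = c(4, 7),
                       seed = 1L) {
  if (abs(sum(type_probs) - 1) > 1e-8 || length(type_probs) != 5L)
    stop("type_probs must be 5 probabilities summing to 1")
  if (occlusion_threshold <= 0 || occlusion_threshold > 1)
    stop("occlusion_threshold must be in (0, 1]")
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_leaves = as.integer(n_leaves), n_pods = as.integer(n_pods),
                 type_probs = type_probs,
                 occlusion_threshold = occlusion_threshold,
                 leaf_axes = leaf_axes, pod_lobe_radius = pod_lobe_radius,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# mask of an ellipse on the pixel grid; returns linear pixel indices
ellipse_indices <- function(cx, cy, a, b, theta, width, height) {
  x0 <- max(1L, floor(cx - max(a, b))); x1 <- min(width, ceiling(cx + max(a, b)))
  y0 <- max(1L, floor(cy - max(a, b))); y1 <- min(height, ceiling(cy + max(a, b)))
  if (x0 > x1 || y0 > y1) return(integer(0))
  xs <- x0:x1; ys <- y0:y1
  px <- rep(xs - 0.5, each = length(ys)) - cx
  py <- rep(ys - 0.5, times = length(xs)) - cy
  u <- px * cos(theta) + py * sin(theta)
  v <- -px * sin(theta) + py * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  row <- rep(ys, times = length(xs))[inside]
  col <- rep(xs, each = length(ys))[inside]
  (col - 1L) * height + row
}

#' Render a synthetic plant scene
#'
#' Places pods (lobed capsules, t lobes for a type-t pod) then leaves (filled
#' ellipses) over them, all in overlapping green hues on a soil background.
#' Because leaves are drawn last they occlude pods geometrically; a pod whose
#' pixel coverage by leaves reaches the spec's `occlusion_threshold` is
#' considered hidden and emits no ground-truth label. All leaves are
#' labelled.
#'
#' @param spec A [scene_spec()].
#' @return List with `image` (height x width x 3 array in \[0, 1\]), `boxes`
#'   (ground-truth labels for visible instances), and `occluded` (count of
#'   unlabelled, hidden pods).
#' @export
generate_scene <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"))
  w <- spec$width; h <- spec$height
  # rough footprint feasibility check before any drawing
  max_leaf <- max(spec$leaf_axes); max_pod <- 5 * 2 * max(spec$pod_lobe_radius)
  need <- spec$n_leaves * pi * prod(spec$leaf_axes) / 4 +
          spec$n_pods * pi * max(spec$pod_lobe_radius)^2
  if (w < max(2 * max_leaf, max_pod) || h < 2 * max_leaf || need > 2 * w * h)
    stop("image too small for the requested number of instances")
  withr::with_seed(spec$seed, {
    img <- array(0, dim = c(h, w, 3L))
    img[, , 1L] <- 0.42; img[, , 2L] <- 0.33; img[, , 3L] <- 0.24  # soil
    pod_masks <- vector("list", spec$n_pods)
    pod_boxes <- vector("list", spec$n_pods)
    pod_types <- integer(spec$n_pods)
    for (i in seq_len(spec$n_pods)) {
      t_seeds <- sample.int(5L, 1L, prob = spec$type_probs)
      r <- stats::runif(1L, spec$pod_lobe_radius[1L], spec$pod_lobe_radius[2L])
      span <- (t_seeds - 1L) * 1.6 * r
      theta <- stats::runif(1L, 0, pi)
      cx <- stats::runif(1L, r + span / 2 + 1, w - r - span / 2 - 1)
      cy <- stats::runif(1L, r + span / 2 + 1, h - r - span / 2 - 1)
      offs <- if (t_seeds == 1L) 0 else seq(-span / 2, span / 2, length.out = t_seeds)
      idx <- integer(0)
      for (o in offs)
        idx <- c(idx, ellipse_indices(cx + o * cos(theta), cy + o * sin(theta),
                                      r, r, 0, w, h))
      idx <- unique(idx)
      pod_masks[[i]] <- idx
      pod_types[i] <- t_seeds
      col <- (idx - 1L) %/% h + 1L; row <- (idx - 1L) %% h + 1L
      pod_boxes[[i]] <- c(min(col) - 1, min(row) - 1, max(col), max(row))
      hue <- stats::runif(1L, -0.04, 0.04)
      img[idx] <- 0.32 + hue                 # R channel
      img[idx + h * w] <- 0.52 + hue         # G channel: pod green
      img[idx + 2L * h * w] <- 0.18 + hue
    }
    leaf_cover <- logical(h * w)
    leaf_boxes <- vector("list", spec$n_leaves)
    for (i in seq_len(spec$n_leaves)) {
      a <- stats::runif(1L, spec$leaf_axes[1L], spec$leaf_axes[2L])
      b <- a * stats::runif(1L, 0.45, 0.8)
      theta <- stats::runif(1L, 0, pi)
      cx <- stats::runif(1L, a + 1, w - a - 1)
      cy <- stats::runif(1L, a + 1, h - a - 1)
      idx <- ellipse_indices(cx, cy, a, b, theta, w, h)
      leaf_cover[idx] <- TRUE
      col <- (idx - 1L) %/% h + 1L; row <- (idx - 1L) %% h + 1L
      leaf_boxes[[i]] <- c(min(col) - 1, min(row) - 1, max(col), max(row))
      hue <- stats::runif(1L, -0.05, 0.05)
      img[idx] <- 0.24 + hue
      img[idx + h * w] <- 0.47 + hue         # leaf green, near the pod hue
      img[idx + 2L * h * w] <- 0.15 + hue
    }
    covered <- vapply(pod_masks, function(idx)
      if (length(idx)) mean(leaf_cover[idx]) else 1, numeric(1))
    visible <- covered < spec$occlusion_threshold
    corner_df <- function(lst) {
      m <- do.call(rbind, lst)
      colnames(m) <- c("x_min", "y_min", "x_max", "y_max")
      as.data.frame(m)
    }
    boxes <- rbind(
      if (spec$n_leaves > 0L)
        data.frame(class = "leaf", corner_df(leaf_boxes)),
      if (any(visible))
        data.frame(class = paste0("pod", pod_types[visible]),
                   corner_df(pod_boxes[visible]))
    )
    if (is.null(boxes)) boxes <- empty_boxes()
    rownames(boxes) <- NULL
    list(image = img, boxes = boxes, occluded = sum(!visible),
         pod_types = pod_types, pod_visible = visible)
  })
}

#' Specification of a simulated pot experiment
#'
#' Defaults emulate a pot trial of four plants per pot at the pod-setting
#' stage, photographed from four directions 90 degrees apart. Per-pot leaf
#' counts are negative binomial (dispersion across varieties), pod totals
#' are Poisson scaled by a lognormal per-pot fertility factor, and pod types
#' are multinomial, peaked at two to three seeds.
#'
#' Every photograph shows the whole pot, so the same pod can be counted in
#' several views: in each view a pod is visible independently with
#' probability `exp(-lambda * L / leaf_mean)` where `L` is the pot's leaf
#' count -- denser foliage hides more pods (monotone coupling, the
#' occlusion-thinning model `1 - exp(-lambda * L / Lbar)` per pod per view).
#' Each leaf is seen from a given side with probability `leaf_side` (the
#' half of the canopy facing the camera). Per-pot totals therefore
#' over-count instances relative to the true counts, exactly as summing
#' counts over four photographs of one plant does; the count-to-seed models
#' absorb the multiplicity.
#'
#' @param leaf_mean,leaf_size Negative-binomial mean and dispersion of leaves
#'   per pot (four plants).
#' @param pod_mean Poisson mean of pods per pot at fertility 1.
#' @param fertility_sdlog Lognormal SD (log scale) of the per-pot fertility
#'   factor (mean 1); pot totals average four plants, so pot-level spread is
#'   narrower than plant-level spread.
#' @param type_probs Pod-type multinomial probabilities.
#' @param lambda Occlusion coupling strength, >= 0; 0 disables occlusion.
#' @param leaf_side Probability a leaf is visible from one side.
#' @param n_views Views per pot.
#' @param weight_noise_sd Lognormal SD of optional multiplicative per-grain
#'   weight noise used when computing the true mass; 0 disables it.
#' @return A list of class `"pot_spec"`.
#' @export
pot_spec <- function(leaf_mean = 160, leaf_size = 12, pod_mean = 300,
                     fertility_sdlog = 0.15,
                     type_probs = c(0.12, 0.38, 0.33, 0.13, 0.04),
                     lambda = 0.2, leaf_side = 0.5, n_views = 4L,
                     weight_noise_sd = 0) {
  if (lambda < 0) stop("lambda must be >= 0")
  if (leaf_side <= 0 || leaf_side > 1) stop("leaf_side must be in (0, 1]")
  if (abs(sum(type_probs) - 1) > 1e-8 || length(type_probs) != 5L)
    stop("type_probs must be 5 probabilities summing to 1")
  structure(list(leaf_mean = leaf_mean, leaf_size = leaf_size,
                 pod_mean = pod_mean, fertility_sdlog = fertility_sdlog,
                 type_probs = type_probs, lambda = lambda,
                 leaf_side = leaf_side, n_views = as.integer(n_views),
                 weight_noise_sd = weight_noise_sd),
            class = "pot_spec")
}

#' Apply detector counting noise to a count vector
#'
#' Emulates an imperfect detector at a target precision/recall: per class,
#' `detected ~ Binomial(n, recall)` of the truly visible instances are
#' found, and false positives are added as `Poisson(detected * (1 -
#' precision) / precision)`, so expected precision matches the target.
#'
#' @param counts Named count vector (or matrix/data frame of count rows).
#' @param precision,recall Target fractions in (0, 1\].
#' @param seed Optional integer seed.
#' @return Noised counts, same shape.
#' @export
detector_noise <- function(counts, precision, recall, seed = NULL) {
  if (precision <= 0 || precision > 1) stop("precision must be in (0, 1]")
  if (recall <= 0 || recall > 1) stop("recall must be in (0, 1]")
  run <- function() {
    m <- as_count_matrix(counts)
    out <- m
    for (j in seq_len(ncol(m))) {
      det <- stats::rbinom(nrow(m), m[, j], recall)
      fp <- if (precision < 1)
        stats::rpois(nrow(m), det * (1 - precision) / precision)
      else 0L
      out[, j] <- det + fp
    }
    if (is.null(dim(counts)) && !is.data.frame(counts)) drop(out) else out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a pot count dataset
#'
#' Draws per-pot true counts, determines what each of the four views sees
#' (occlusion thinning coupled to the pot's leaf density, side visibility
#' for leaves), and optionally applies detector counting noise; the per-pot
#' observed count vector is the sum over its views, mirroring how counts are
#' extracted from four photographs of the same plants.
#'
#' @param n_pots Number of pots (>= 1).
#' @param spec A [pot_spec()].
#' @param seed Integer seed; the dataset regenerates identically from it.
#' @param noise `NULL` for a perfect detector, or `list(precision =, recall
#'   =)` for counting noise.
#' @param weights [seed_weights()] used for the true mass.
#' @param dir Optional directory; when given, `counts.csv` (observed
#'   per-view counts) and `truth.csv` (per-pot truth) are written there.
#' @return List of class `"pot_dataset"` with `views` (one row per pot x
#'   view: observed and visible counts), `pots` (per-pot totals: true,
#'   visible and observed counts, `true_seeds`, `true_grams`), `spec`,
#'   `seed`.
#' @export
generate_pot_dataset <- function(n_pots = 90L, spec = pot_spec(), seed = 1L,
                                 noise = NULL, weights = seed_weights(),
                                 dir = NULL) {
  if (n_pots < 1L) stop("n_pots must be >= 1")
  stopifnot(inherits(spec, "pot_spec"))
  if (!is.null(noise) && (is.null(noise$precision) || is.null(noise$recall)))
    stop("noise must be NULL or list(precision =, recall =)")
  nv <- spec$n_views
  res <- withr::with_seed(seed, {
    view_rows <- vector("list", n_pots)
    pot_rows <- vector("list", n_pots)
    for (p in seq_len(n_pots)) {
      n_leaf <- stats::rnbinom(1L, mu = spec$leaf_mean, size = spec$leaf_size)
      fert <- stats::rlnorm(1L, meanlog = -spec$fertility_sdlog^2 / 2,
                            sdlog = spec$fertility_sdlog)
      n_pod <- stats::rpois(1L, spec$pod_mean * fert)
      types <- drop(stats::rmultinom(1L, n_pod, spec$type_probs))
      # per-view visibility: each pod hidden with probability growing in the
      # pot's foliage; each leaf seen from the camera-facing side only
      p_vis <- exp(-spec$lambda * n_leaf / spec$leaf_mean)
      vis_v <- matrix(0L, nv, 5L)
      leaf_v <- integer(nv)
      for (v in seq_len(nv)) {
        vis_v[v, ] <- stats::rbinom(5L, types, p_vis)
        leaf_v[v] <- stats::rbinom(1L, n_leaf, spec$leaf_side)
      }
      true_view <- cbind(n_leaf = rep(n_leaf, nv),
                         matrix(types, nv, 5L, byrow = TRUE))
      colnames(true_view) <- count_cols()
      vis_view <- cbind(n_leaf = leaf_v, vis_v)
      colnames(vis_view) <- count_cols()
      obs_view <- if (is.null(noise)) vis_view else
        detector_noise(vis_view, noise$precision, noise$recall)
      wt <- weights$w
      if (spec$weight_noise_sd > 0)
        wt <- wt * stats::rlnorm(5L, meanlog = -spec$weight_noise_sd^2 / 2,
                                 sdlog = spec$weight_noise_sd)
      true_tot <- c(n_leaf = n_leaf, stats::setNames(types, paste0("n_pod", 1:5)))
      view_rows[[p]] <- data.frame(
        pot_id = p, view = seq_len(nv),
        as.data.frame(obs_view),
        as.data.frame(vis_view) |>
          stats::setNames(paste0("visible_", count_cols())),
        as.data.frame(true_view) |>
          stats::setNames(paste0("true_", count_cols())))
      pot_rows[[p]] <- data.frame(
        pot_id = p,
        t(true_tot) |> as.data.frame() |>
          stats::setNames(paste0("true_", count_cols())),
        t(colSums(vis_view)) |> as.data.frame() |>
          stats::setNames(paste0("visible_", count_cols())),
        t(colSums(obs_view)) |> as.data.frame(),
        true_seeds = sum(types * (1:5)),
        true_grams = sum(types * (1:5) * wt))
    }
    list(views = do.call(rbind, view_rows), pots = do.call(rbind, pot_rows))
  })
  out <- structure(list(views = res$views, pots = res$pots, spec = spec,
                        seed = as.integer(seed), noise = noise),
                   class = "pot_dataset")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.csv(res$views[, c("pot_id", "view", count_cols())],
                     file.path(dir, "counts.csv"), row.names = FALSE)
    utils::write.csv(res$pots, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  out
}

#' @export
print.pot_dataset <- function(x, ...) {
  cat("Simulated pot dataset:", nrow(x$pots), "pots x", x$spec$n_views,
      "views (seed", x$seed, ")\n")
  cat("  mean true seeds/pot:", round(mean(x$pots$true_seeds), 1), "\n")
  invisible(x)
}

#' Simulate detector output boxes for a scene
#'
#' Produces plausible predicted boxes from ground truth at a target
#' precision/recall: each true box is found with probability `recall` (with
#' corner jitter and confidence increasing in how unoccluded it is), and
#' false positives are added at rate `found * (1 - precision) / precision`
#' as random boxes of random class.
#'
#' @param boxes Ground-truth box data frame.
#' @param image_w,image_h Canvas size.
#' @param precision,recall Target detector operating point.
#' @param jitter_sd Corner jitter SD in pixels.
#' @param seed Optional integer seed.
#' @return Prediction data frame with `confidence`.
#' @export
simulate_detections <- function(boxes, image_w, image_h, precision = 0.903,
                                recall = 0.876, jitter_sd = 1.5, seed = NULL) {
  if (precision <= 0 || precision > 1 || recall <= 0 || recall > 1)
    stop("precision and recall must be in (0, 1]")
  run <- function() {
    keep <- stats::runif(nrow(boxes)) < recall
    found <- boxes[keep, , drop = FALSE]
    if (nrow(found)) {
      j <- matrix(stats::rnorm(4L * nrow(found), 0, jitter_sd), ncol = 4L)
      found$x_min <- found$x_min + j[, 1L]; found$y_min <- found$y_min + j[, 2L]
      found$x_max <- found$x_max + j[, 3L]; found$y_max <- found$y_max + j[, 4L]
      bad <- found$x_max <= found$x_min | found$y_max <= found$y_min
      found <- found[!bad, , drop = FALSE]
      found$confidence <- stats::runif(nrow(found), 0.6, 1)
    } else {
      found$confidence <- numeric(0)
    }
    n_fp <- if (precision < 1)
      stats::rpois(1L, nrow(found) * (1 - precision) / precision) else 0L
    if (n_fp > 0L) {
      w <- stats::runif(n_fp, 8, 40); h <- stats::runif(n_fp, 8, 40)
      x0 <- stats::runif(n_fp, 0, image_w - w)
      y0 <- stats::runif(n_fp, 0, image_h - h)
      fp <- data.frame(class = sample(class_vocabulary(), n_fp, replace = TRUE),
                       x_min = x0, y_min = y0, x_max = x0 + w, y_max = y0 + h,
                       confidence = stats::runif(n_fp, 0.3, 0.8))
      found <- rbind(found, fp)
    }
    rownames(found) <- NULL
    found
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
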