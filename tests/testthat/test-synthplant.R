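test_that("scenes without leaves label every pod and hide none", {
  sp <- scene_spec(n_leaves = 0, n_pods = 5, seed = 3)
  sc <- generate_scene(sp)
  expect_equal(nrow(sc$boxes), 5L)
  expect_true(all(grepl("^pod[1-5]$", sc$boxes$class)))
  expect_equal(sc$occluded, 0L)
})

test_that("scene generation is byte-identical for a fixed seed", {
  sp <- scene_spec(seed = 11)
  a <- generate_scene(sp)
  b <- generate_scene(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$boxes, b$boxes)
  c <- generate_scene(scene_spec(seed = 12))
  expect_false(identical(a$image, c$image))
})

test_that("visible plus occluded pods equals the pods planted", {
  for (s in 1:10) {
    sc <- generate_scene(scene_spec(n_leaves = 20, n_pods = 12, seed = s))
    n_pod_boxes <- sum(sc$boxes$class != "leaf")
    expect_equal(n_pod_boxes + sc$occluded, 12L)
    expect_equal(sum(sc$pod_visible), n_pod_boxes)
  }
})

test_that("denser canopies hide more pods in rendered scenes", {
  frac_visible <- function(n_leaves) {
    mean(vapply(1:30, function(s) {
      sc <- generate_scene(scene_spec(n_leaves = n_leaves, n_pods = 10,
                                      seed = 600 + s))
      sum(sc$pod_visible) / 10
    }, numeric(1)))
  }
  f <- vapply(c(0L, 12L, 30L), frac_visible, numeric(1))
  expect_true(all(diff(f) < 0))
})

test_that("scene boxes stay inside the canvas and pods stay boxable", {
  sc <- generate_scene(scene_spec(seed = 21))
  expect_true(all(sc$boxes$x_min >= 0 & sc$boxes$x_max <= 256))
  expect_true(all(sc$boxes$y_min >= 0 & sc$boxes$y_max <= 256))
  expect_true(all(sc$boxes$x_max > sc$boxes$x_min))
  expect_error(generate_scene(scene_spec(width = 40, height = 40,
                                         n_leaves = 50, n_pods = 50)),
               "too small")
})

test_that("detector noise hits its nominal precision and recall", {
  counts <- matrix(100L, 1000, 6,
                   dimnames = list(NULL, c("n_leaf", paste0("n_pod", 1:5))))
  noised <- detector_noise(counts, precision = 0.8, recall = 0.8, seed = 5)
  # recall: detected true per cell is Binomial(100, 0.8); precision: false
  # positives Poisson(detected/4), so E[obs] = 80 / 0.8 = 100
  expect_lt(abs(mean(noised) - 100), 2)
  ident <- detector_noise(counts, precision = 1, recall = 1, seed = 5)
  expect_identical(ident, counts * 1.0)
  expect_error(detector_noise(counts, precision = 0.9, recall = 0), "recall")
  expect_error(detector_noise(counts, precision = 1.2, recall = 0.9),
               "precision")
})

test_that("detector noise components match their binomial and Poisson moments", {
  set.seed(51)
  one <- c(n_leaf = 0L, n_pod1 = 0L, n_pod2 = 100L, n_pod3 = 0L,
           n_pod4 = 0L, n_pod5 = 0L)
  draws <- t(vapply(1:1000, function(i)
    detector_noise(one, precision = 0.8, recall = 0.8),
    setNames(numeric(6), names(one))))
  obs <- draws[, "n_pod2"]
  # E[obs] = 80 + 20 = 100; SD(mean) combines Binomial and Poisson spread
  se <- sqrt((100 * 0.8 * 0.2 * (1 + 0.25)^2 + 20) / 1000)
  expect_lt(abs(mean(obs) - 100), 3 * se + 0.5)
})

test_that("a 90-pot simulation has the experiment's layout", {
  ds <- generate_pot_dataset(90, seed = 8)
  expect_equal(nrow(ds$pots), 90L)
  expect_equal(nrow(ds$views), 360L)
  expect_equal(unique(table(ds$views$pot_id)), 4L)
  # per pot: true seed number is the type-weighted pod count
  tm <- as.matrix(ds$pots[, paste0("true_n_pod", 1:5)])
  expect_equal(ds$pots$true_seeds, drop(tm %*% (1:5)))
  expect_equal(ds$pots$true_grams,
               yield_grams(setNames(ds$pots[, paste0("true_", c("n_leaf",
                 paste0("n_pod", 1:5)))], c("n_leaf", paste0("n_pod", 1:5))),
                 seed_weights(), "per_type"))
})

test_that("per-view visible counts never exceed the pot's true counts", {
  ds <- generate_pot_dataset(30, seed = 9)
  for (t in 1:5) {
    vis <- ds$views[[paste0("visible_n_pod", t)]]
    true <- ds$views[[paste0("true_n_pod", t)]]
    expect_true(all(vis <= true))
  }
  expect_true(all(ds$views$visible_n_leaf <= ds$views$true_n_leaf))
})

test_that("without occlusion or detector noise every view counts everything", {
  sp <- pot_spec(lambda = 0, leaf_side = 1)
  ds <- generate_pot_dataset(12, sp, seed = 10)
  for (col in c("n_leaf", paste0("n_pod", 1:5))) {
    expect_identical(ds$views[[col]], ds$views[[paste0("visible_", col)]])
    expect_identical(as.numeric(ds$views[[col]]),
                     as.numeric(ds$views[[paste0("true_", col)]]))
  }
})

test_that("occlusion coupling strictly thins visible pods as lambda grows", {
  mean_vis_frac <- function(lambda) {
    sp <- pot_spec(lambda = lambda)
    ds <- generate_pot_dataset(60, sp, seed = 14)
    sum(ds$pots[, paste0("visible_n_pod", 1:5)]) /
      (4 * sum(ds$pots[, paste0("true_n_pod", 1:5)]))
  }
  fr <- vapply(c(0, 0.5, 1, 2), mean_vis_frac, numeric(1))
  expect_true(all(diff(fr) < 0))
  expect_equal(fr[1], 1)
})

test_that("datasets regenerate identically from their seed and write CSVs", {
  d <- tempfile()
  ds1 <- generate_pot_dataset(15, seed = 33,
                              noise = list(precision = 0.9, recall = 0.85),
                              dir = d)
  ds2 <- generate_pot_dataset(15, seed = 33,
                              noise = list(precision = 0.9, recall = 0.85))
  expect_identical(ds1$views, ds2$views)
  expect_identical(ds1$pots, ds2$pots)
  counts <- utils::read.csv(file.path(d, "counts.csv"))
  expect_equal(nrow(counts), 60L)
  truth <- utils::read.csv(file.path(d, "truth.csv"))
  expect_equal(truth$true_seeds, ds1$pots$true_seeds)
  unlink(d, recursive = TRUE)
})

test_that("simulated detections track the requested operating point", {
  set.seed(55)
  sc <- generate_scene(scene_spec(n_leaves = 8, n_pods = 12, seed = 77))
  agg <- pool_match_counts(lapply(1:40, function(i) {
    preds <- simulate_detections(sc$boxes, 256, 256, precision = 0.9,
                                 recall = 0.85, jitter_sd = 0.5,
                                 seed = 3000 + i)
    match_detections(preds, sc$boxes, iou_thresh = 0.5)
  }))
  met <- suppressMessages(precision_recall_f1(agg))
  ov <- met[met$class == "overall", ]
  # jitter pushes a few matches below the IoU bar, so empirical rates sit
  # close to but not above the nominal point
  expect_gt(ov$recall, 0.75)
  expect_lt(abs(ov$precision - 0.9), 0.08)
})
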