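# Synthetic geometric-shapes generator: scene consistency, suite structure,
# reproducibility, and the non-triviality guard.

test_that("scenes have tight boxes, bounded values and honest empty cases", {
  set.seed(18)
  sc <- generate_scene(size = 64, n_shapes = 0)
  expect_identical(nrow(sc$boxes), 0L)
  expect_true(all(sc$mask == 0))
  expect_true(all(sc$image >= 0 & sc$image <= 1))
  for (i in 1:10) {
    sc <- generate_scene(size = 64, n_shapes = 2)
    expect_true(all(sc$image >= 0 & sc$image <= 1))
    for (sh in sc$shapes) {
      # box-mask tightness: mask extrema equal the half-open box edges
      rows <- which(apply(sh$mask, 1, any)) - 1L
      cols <- which(apply(sh$mask, 2, any)) - 1L
      expect_identical(sh$box$y0, min(rows))
      expect_identical(sh$box$y1, max(rows) + 1L)
      expect_identical(sh$box$x0, min(cols))
      expect_identical(sh$box$x1, max(cols) + 1L)
    }
  }
})

test_that("a circle's box and pixel area match the analytic geometry", {
  set.seed(19)
  for (i in 1:5) {
    r <- runif(1, 12, 20)
    cx <- runif(1, 30, 60); cy <- runif(1, 30, 60)
    m <- draw_shape_mask("circle", 96, cx, cy, r)
    expect_lt(abs(sum(m) - pi * r^2) / (pi * r^2), 0.05)
    # tight box spans the diameter to within the pixel grid
    b <- mask_to_box(m, 0L)
    expect_lte(abs((b$x1 - b$x0) - 2 * r), 2)
    expect_lte(abs((b$y1 - b$y0) - 2 * r), 2)
  }
})

test_that("scene generation is deterministic under a fixed seed", {
  set.seed(77); a <- generate_scene(64, 3)
  set.seed(77); b <- generate_scene(64, 3)
  expect_identical(a$image, b$image)
  expect_identical(a$boxes, b$boxes)
})

test_that("the default suite covers all five label types with heterogeneous geometry", {
  suite <- generate_task_suite(shapes_suite_config(seed = 3, scale = 0.08))
  types <- vapply(suite, function(t) t$spec$label_type, character(1))
  expect_setequal(unique(types), LABEL_TYPES)
  sizes <- vapply(suite, function(t) t$spec$patch_size[1], integer(1))
  expect_gte(length(unique(sizes)), 2L)
  chans <- vapply(suite, function(t) t$spec$channels, integer(1))
  expect_setequal(unique(chans), c(1L, 3L))
  lens <- vapply(suite, function(t) t$train$n, numeric(1))
  expect_gte(length(unique(lens)), 2L)
  # multilabel targets equal the scene's shape-presence indicators
  ml <- suite$shapes_mlab$train$samples[[1]]
  expect_true(all(ml$y %in% c(0, 1)))
  # detection boxes lie inside the image
  det <- suite$shapes_det$train$samples[[1]]
  if (nrow(det$boxes)) {
    expect_true(all(det$boxes$x1 <= 96 & det$boxes$y1 <= 96))
  }
})

test_that("suites are reproducible from (config, seed)", {
  s1 <- generate_task_suite(shapes_suite_config(seed = 5, scale = 0.05))
  s2 <- generate_task_suite(shapes_suite_config(seed = 5, scale = 0.05))
  sum1 <- sum(s1$shapes_cls$train$samples[[1]]$image)
  sum2 <- sum(s2$shapes_cls$train$samples[[1]]$image)
  expect_identical(sum1, sum2)
  expect_identical(s1$shapes_seg$train$samples[[2]]$mask,
                   s2$shapes_seg$train$samples[[2]]$mask)
})

test_that("volumes contain the target shape exactly when labelled positive", {
  set.seed(20)
  # brute-force slice-scan oracle: a square of texture contrasts with
  # circle distractors by its fill profile; use the generator's own masks
  # indirectly by regenerating and checking target_slices
  for (i in 1:20) {
    present <- i %% 2 == 0
    v <- generate_volume(c(24, 24, 8), target_present = present,
                         modality = if (i %% 4 < 2) "CT" else "MRI")
    expect_identical(v$label, as.integer(present))
    if (present) expect_gte(length(v$target_slices), 3)
    else expect_length(v$target_slices, 0)
    n <- normalize_intensity(v$voxels, v$modality)
    expect_true(all(n >= 0 & n <= 1))
  }
})

test_that("volume labels are recoverable by an independent slice-scan detector", {
  # brute-force oracle: the square target has long straight contour runs in
  # both directions on some slice; circle distractors do not
  longest_run <- function(b) {
    best <- 0
    for (i in seq_len(nrow(b))) {
      r <- rle(b[i, ]); runs <- r$lengths[r$values]
      if (length(runs)) best <- max(best, max(runs))
    }
    best
  }
  detect_square <- function(slice) {
    b <- slice >= stats::quantile(slice, 0.96) & slice > 0.6
    longest_run(b) >= 10 && longest_run(t(b)) >= 10
  }
  set.seed(33)
  n <- 80
  agree <- vapply(seq_len(n), function(i) {
    present <- i %% 2 == 0
    v <- generate_volume(c(32, 32, 10), target_present = present,
                         modality = sample(c("CT", "MRI"), 1))
    slices <- slice_volume(list(voxels = v$voxels, modality = v$modality))
    pred <- any(vapply(slices, detect_square, logical(1)))
    pred == present
  }, logical(1))
  expect_gte(mean(agree), 0.9)
})

test_that("mean pixel intensity alone cannot solve shape classification", {
  set.seed(21)
  n <- 120
  tc <- list(name = "x", label_type = "multiclass", num_classes = 4L, size = 48L,
             channels = 1L, n_shapes = 1L, shape_types = SHAPE_TYPES[1:4])
  samples <- lapply(seq_len(n), function(i) sample_for_task(tc))
  means <- vapply(samples, function(s) mean(s$image), numeric(1))
  y <- vapply(samples, `[[`, numeric(1), "y")
  # 1-nearest-centroid on the scalar mean intensity
  centroids <- tapply(means, y, mean)
  pred <- as.integer(names(centroids))[apply(abs(outer(means, centroids, "-")), 1,
                                             which.min)]
  expect_lt(macro_f1(pred, y), 0.9)
})

test_that("written suites carry a manifest with stable checksums", {
  dir1 <- tempfile(); dir2 <- tempfile()
  suite <- generate_task_suite(shapes_suite_config(seed = 9, scale = 0.05))
  m1 <- write_suite(suite, dir1, seed = 9)
  m2 <- write_suite(suite, dir2, seed = 9)
  expect_identical(m1$tasks$shapes_cls$md5, m2$tasks$shapes_cls$md5)
  expect_true(file.exists(file.path(dir1, "manifest.json")))
  # images re-read from PNG match to 8-bit precision
  f <- file.path(dir1, "shapes_cls", "train_0001.png")
  img <- png::readPNG(f)
  expect_equal(img, suite$shapes_cls$train$samples[[1]]$image[, , 1],
               tolerance = 1 / 255)
  # volume CSV stacks round-trip through the volume reader
  fv <- file.path(dir1, "shapes_mil", "train_0001_vol.csv")
  v <- read_volume(fv, "CT")
  ref <- suite$shapes_mil$train$samples[[1]]$volume
  expect_identical(dim(v$voxels), dim(ref)[c(1, 2, 4)])
  expect_equal(v$voxels, array(ref, dim = dim(ref)[c(1, 2, 4)]), tolerance = 1e-6)
  unlink(c(dir1, dir2), recursive = TRUE)
})
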