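# Deterministic synthetic geometric-shapes task suites.
#
# Scenes contain non-overlapping shapes (circle, square, triangle, cross,
# ring) whose interiors are intensity-matched to the background mean but
# carry a different texture variance, so no classifier can solve the tasks
# from mean brightness alone - the encoder has to learn geometry. One suite
# provides tasks of all five label types with heterogeneous image sizes,
# channel counts and dataset lengths.

SHAPE_TYPES <- c("circle", "square", "triangle", "cross", "ring")

# zero-mean structured texture: oriented stripes at a random phase and
# orientation, plus light noise. Mean-matched to the background (so scene
# brightness carries no label information) but first-order visible, unlike
# pure iid noise whose variance cue is nearly invisible to small encoders.
shape_texture <- function(size, amplitude = 0.12, period = 8) {
  th <- stats::runif(1, 0, pi)
  ph <- stats::runif(1, 0, 2 * pi)
  y <- matrix(seq_len(size), size, size)
  x <- matrix(seq_len(size), size, size, byrow = TRUE)
  amplitude * sin(2 * pi * (cos(th) * x + sin(th) * y) / period + ph) +
    stats::rnorm(size^2, sd = 0.03)
}

# 4-neighbour binary erosion (used to extract a contour band)
erode_mask <- function(m) {
  S <- nrow(m)
  shift <- function(di, dj) {
    out <- matrix(FALSE, S, S)
    ri <- max(1, 1 + di):min(S, S + di)
    rj <- max(1, 1 + dj):min(S, S + dj)
    out[ri, rj] <- m[ri - di, rj - dj]
    out
  }
  m & shift(1, 0) & shift(-1, 0) & shift(0, 1) & shift(0, -1)
}

# logical S x S mask of one shape; 0-based center (cx, cy), radius r
draw_shape_mask <- function(type, size, cx, cy, r) {
  y <- matrix(seq_len(size) - 1, size, size)          # row coordinate
  x <- matrix(seq_len(size) - 1, size, size, byrow = TRUE)
  dx <- x - cx; dy <- y - cy
  switch(type,
         circle = dx^2 + dy^2 <= r^2,
         square = abs(dx) <= r & abs(dy) <= r,
         triangle = dy >= -r & dy <= r & abs(dx) <= (dy + r) / 2,
         cross = (abs(dx) <= r / 3 & abs(dy) <= r) | (abs(dy) <= r / 3 & abs(dx) <= r),
         ring = {
           d2 <- dx^2 + dy^2
           d2 <= r^2 & d2 >= (0.55 * r)^2
         },
         stop("unknown shape type '", type, "'"))
}

mask_to_box <- function(mask, class_id) {
  rows <- which(apply(mask, 1, any)) - 1L
  cols <- which(apply(mask, 2, any)) - 1L
  data.frame(class_id = class_id, x0 = min(cols), y0 = min(rows),
             x1 = max(cols) + 1L, y1 = max(rows) + 1L)
}

#' Generate one synthetic shape scene
#'
#' Places `n_shapes` non-overlapping shapes (rejection sampling on bounding
#' boxes) on a noisy background. Shape interiors share the background mean
#' intensity (0.5) but have higher texture variance. Returns a consistent
#' image / class-mask / box triple.
#'
#' @param size image edge length in px.
#' @param n_shapes number of shapes to place (>= 0).
#' @param noise background noise standard deviation.
#' @param shape_types types to draw from (class id = position - 1).
#' @param channels 1 or 3.
#' @param contour_contrast absolute intensity offset of the 2 px contour band.
#' @param r_range radius range in px.
#' @param max_reject rejection-sampling budget; if exceeded the scene holds
#'   fewer shapes and a warning is issued.
#' @return list(image HxWxC array in [0,1], mask HxW class image (0 =
#'   background), boxes data.frame, shapes list).
#' @export
generate_scene <- function(size = 64L, n_shapes = 1L, noise = 0.05,
                           shape_types = SHAPE_TYPES[1:4], channels = 1L,
                           contour_contrast = 0.35, r_range = NULL,
                           max_reject = 1000L) {
  stopifnot(n_shapes >= 0)
  if (is.null(r_range)) r_range <- c(round(size / 8), round(size / 4))
  img <- matrix(0.5 + stats::rnorm(size^2, sd = noise), size, size)
  class_mask <- matrix(0L, size, size)
  boxes <- data.frame(class_id = integer(0), x0 = numeric(0), y0 = numeric(0),
                      x1 = numeric(0), y1 = numeric(0))
  shapes <- list()
  occupied <- matrix(FALSE, size, size)
  rejects <- 0L
  while (length(shapes) < n_shapes && rejects < max_reject) {
    type_i <- sample.int(length(shape_types), 1)
    type <- shape_types[type_i]
    r <- stats::runif(1, r_range[1], r_range[2])
    cx <- stats::runif(1, r + 1, size - r - 2)
    cy <- stats::runif(1, r + 1, size - r - 2)
    m <- draw_shape_mask(type, size, cx, cy, r)
    if (!any(m)) { rejects <- rejects + 1L; next }
    if (any(m & occupied)) { rejects <- rejects + 1L; next }
    occupied <- occupied | m
    # interior: mild mean-matched texture; contour: a bright 2 px band, so
    # shape identity is carried by boundary geometry. Scene mean intensity
    # tracks shape area, not type, so brightness alone stays uninformative.
    img[m] <- 0.5 + shape_texture(size)[m]
    contour <- m & !erode_mask(erode_mask(m))
    img[contour] <- 0.5 + contour_contrast
    class_mask[m] <- type_i
    box <- mask_to_box(m, type_i - 1L)
    boxes <- rbind(boxes, box)
    shapes[[length(shapes) + 1L]] <- list(shape_type = type,
                                          class_id = type_i - 1L,
                                          mask = m, box = box)
  }
  if (length(shapes) < n_shapes)
    warning("placed only ", length(shapes), " of ", n_shapes,
            " shapes without overlap")
  img <- pmin(pmax(img, 0), 1)
  image <- if (channels == 3L) {
    a <- array(0, dim = c(size, size, 3))
    for (c in 1:3) a[, , c] <- pmin(pmax(img + stats::rnorm(size^2, sd = noise / 2), 0), 1)
    a
  } else array(img, dim = c(size, size, 1))
  list(image = image, mask = class_mask, boxes = boxes, shapes = shapes)
}

#' Generate a synthetic 3D volume for the slice-MIL task
#'
#' A stack of 2D scenes with circle distractors; when `target_present` a
#' square appears in a random contiguous subset of slices. Voxels are
#' rescaled to a modality-appropriate raw intensity range (CT-like or
#' MRI-like) so that modality normalization is exercised on load.
#'
#' @param size c(H, W, S) with S >= 4.
#' @param target_present logical.
#' @param modality `"CT"` or `"MRI"`.
#' @param noise background noise sd.
#' @return list(voxels raw 3D array, modality, label (0/1),
#'   target_slices integer vector).
#' @export
generate_volume <- function(size = c(32L, 32L, 12L), target_present = TRUE,
                            modality = c("CT", "MRI"), noise = 0.05) {
  modality <- match.arg(modality)
  stopifnot(all(size >= c(8, 8, 4)))
  S <- size[3]
  vol <- array(0, dim = size)
  tgt <- integer(0)
  if (target_present) {
    len <- sample(3:min(6, S), 1)
    st <- sample.int(S - len + 1L, 1)
    tgt <- st:(st + len - 1L)
  }
  for (s in seq_len(S)) {
    n_d <- sample(0:2, 1)
    sc <- generate_scene(size = size[1], n_shapes = n_d, noise = noise,
                         shape_types = "circle", channels = 1L,
                         r_range = c(3, round(size[1] / 5)))
    img <- sc$image[, , 1]
    if (s %in% tgt) {
      r <- stats::runif(1, size[1] / 6, size[1] / 4)
      cx <- stats::runif(1, r + 1, size[1] - r - 2)
      cy <- stats::runif(1, r + 1, size[1] - r - 2)
      m <- draw_shape_mask("square", size[1], cx, cy, r)
      img[m] <- 0.5 + shape_texture(size[1])[m]
      contour <- m & !erode_mask(erode_mask(m))
      img[contour] <- 0.5 + 0.35
      img <- pmin(pmax(img, 0), 1)
    }
    vol[, , s] <- img
  }
  # rescale to raw modality ranges
  raw <- switch(modality,
                CT = vol * 3000 - 1000,
                MRI = vol * 800)
  list(voxels = raw, modality = modality, label = as.integer(target_present),
       target_slices = tgt)
}

## suites --------------------------------------------------------------------

#' Default shapes suite configuration
#'
#' One task of each label type, with deliberately heterogeneous image sizes
#' (48-96 px), channel counts (1 and 3) and dataset lengths, so the sampler's
#' restart logic and variable-size handling are exercised.
#'
#' @param seed master seed.
#' @param scale multiplies all dataset sizes (for quick tests).
#' @export
shapes_suite_config <- function(seed = 1L, scale = 1) {
  n <- function(x) max(8L, as.integer(round(x * scale)))
  list(seed = as.integer(seed),
       tasks = list(
         list(name = "shapes_cls", label_type = "multiclass", num_classes = 4L,
              size = 64L, channels = 1L, n_train = n(160), n_test = n(100),
              n_shapes = 1L, shape_types = SHAPE_TYPES[1:4]),
         list(name = "shapes_cls_rgb", label_type = "multiclass", num_classes = 3L,
              size = 48L, channels = 3L, n_train = n(60), n_test = n(48),
              n_shapes = 1L, shape_types = SHAPE_TYPES[1:3]),
         list(name = "shapes_mlab", label_type = "multilabel", num_classes = 4L,
              size = 64L, channels = 1L, n_train = n(120), n_test = n(80),
              n_shapes = NA, shape_types = SHAPE_TYPES[1:4]),
         list(name = "shapes_seg", label_type = "segmentation", num_classes = 4L,
              size = 64L, channels = 1L, n_train = n(100), n_test = n(40),
              n_shapes = NA, shape_types = SHAPE_TYPES[1:3]),
         list(name = "shapes_det", label_type = "detection", num_classes = 2L,
              size = 96L, channels = 1L, n_train = n(80), n_test = n(32),
              n_shapes = NA, shape_types = SHAPE_TYPES[1:2]),
         list(name = "shapes_mil", label_type = "mil_classification",
              num_classes = 2L, size = 32L, channels = 1L, n_train = n(40),
              n_test = n(24), n_shapes = NA, shape_types = "square")))
}

sample_for_task <- function(tc) {
  n_shapes <- if (is.na(tc$n_shapes)) sample(1:3, 1) else tc$n_shapes
  if (tc$label_type == "mil_classification") {
    present <- stats::runif(1) < 0.5
    modality <- sample(c("CT", "MRI"), 1)
    v <- generate_volume(c(tc$size, tc$size, 12L), target_present = present,
                         modality = modality)
    slices <- slice_volume(list(voxels = v$voxels, modality = v$modality))
    vol <- array(0, dim = c(tc$size, tc$size, 1L, length(slices)))
    for (s in seq_along(slices)) vol[, , 1, s] <- slices[[s]]
    return(list(volume = vol, y = v$label, modality = v$modality))
  }
  sc <- generate_scene(size = tc$size, n_shapes = n_shapes,
                       shape_types = tc$shape_types, channels = tc$channels)
  switch(tc$label_type,
         multiclass = {
           # scene-level class = majority (here: single) shape
           cls <- vapply(sc$shapes, `[[`, integer(1), "class_id")
           list(image = sc$image, y = as.integer(names(which.max(table(cls)))))
         },
         multilabel = {
           present <- rep(0L, tc$num_classes)
           for (s in sc$shapes) present[s$class_id + 1L] <- 1L
           list(image = sc$image, y = present)
         },
         segmentation = list(image = sc$image, mask = sc$mask),
         detection = list(image = sc$image, boxes = sc$boxes))
}

# Training-time augmentation for shape scenes: geometric flips for
# image-level labels (flip-invariant classes), photometric jitter for all.
# Dense tasks keep geometry fixed so masks and boxes stay aligned.
shapes_augmenter <- function(label_type) {
  geometric <- label_type %in% c("multiclass", "multilabel")
  function(batch) {
    if (is.null(batch$x)) return(batch)
    N <- dim(batch$x)[4]
    d <- dim(batch$x)[1:3]
    for (n in seq_len(N)) {
      a <- batch$x[, , , n, drop = TRUE]
      dim(a) <- d
      if (geometric) {
        if (stats::runif(1) < 0.5) a <- a[rev(seq_len(d[1])), , , drop = FALSE]
        if (stats::runif(1) < 0.5) a <- a[, rev(seq_len(d[2])), , drop = FALSE]
        if (stats::runif(1) < 0.5 && d[1] == d[2]) a <- aperm(a, c(2, 1, 3))
        # random translation, filled at the background mean
        sh <- round(stats::runif(2, -6, 6))
        if (any(sh != 0)) {
          out <- array(0.5, dim = d)
          src_r <- max(1, 1 - sh[1]):min(d[1], d[1] - sh[1])
          src_c <- max(1, 1 - sh[2]):min(d[2], d[2] - sh[2])
          out[src_r + sh[1], src_c + sh[2], ] <- a[src_r, src_c, ]
          a <- out
        }
      }
      batch$x[, , , n] <- augment_2d(a, "generic")
    }
    batch
  }
}

#' Generate a full multi-task suite
#'
#' Produces, for every task in the config, a [task_spec()] plus train and
#' test datasets. Training datasets carry an augmentation policy (flips for
#' image-level labels, photometric jitter everywhere) applied by the
#' training loop. Fully reproducible from (config, seed): each task draws
#' from its own derived RNG stream.
#'
#' @param config a [shapes_suite_config()].
#' @return named list per task: list(spec, train, test).
#' @export
generate_task_suite <- function(config = shapes_suite_config()) {
  out <- list()
  for (ti in seq_along(config$tasks)) {
    tc <- config$tasks[[ti]]
    set.seed((config$seed + ti * 7919L) %% .Machine$integer.max)
    tr <- lapply(seq_len(tc$n_train), function(i) sample_for_task(tc))
    te <- lapply(seq_len(tc$n_test), function(i) sample_for_task(tc))
    train <- make_memory_dataset(tr, tc$label_type)
    train$augment <- shapes_augmenter(tc$label_type)
    test <- make_memory_dataset(te, tc$label_type)
    spec <- task_spec(tc$name, tc$label_type, tc$num_classes,
                      patch_size = c(tc$size, tc$size), channels = tc$channels,
                      dataset = train)
    out[[tc$name]] <- list(spec = spec, train = train, test = test)
  }
  out
}

#' Generate a held-out downstream shape-classification task
#'
#' Same scene distribution as the suite's classification task but a fresh
#' data stream; `out_of_domain = TRUE` adds the held-out "ring" class, which
#' never occurs in the pretraining suite.
#'
#' @param seed integer seed.
#' @param n_train,n_test dataset sizes.
#' @param size image edge length.
#' @param out_of_domain include the held-out shape class.
#' @return list(spec, train, test).
#' @export
generate_downstream_task <- function(seed = 99L, n_train = 50L, n_test = 200L,
                                     size = 64L, out_of_domain = FALSE) {
  types <- if (out_of_domain) SHAPE_TYPES[c(1, 2, 3, 5)] else SHAPE_TYPES[1:4]
  tc <- list(name = if (out_of_domain) "shapes_ood" else "shapes_heldout",
             label_type = "multiclass", num_classes = length(types),
             size = as.integer(size), channels = 1L, n_shapes = 1L,
             shape_types = types)
  make_balanced <- function(n, seed_off) {
    set.seed((seed + seed_off) %% .Machine$integer.max)
    # balanced labels: cycle classes so every class appears even at small n
    lapply(seq_len(n), function(i) {
      cls <- (i - 1L) %% length(types) + 1L
      tc1 <- tc; tc1$shape_types <- types[cls]
      s <- sample_for_task(tc1)
      s$y <- cls - 1L
      s
    })
  }
  tr <- make_balanced(n_train, 0L)
  te <- make_balanced(n_test, 104729L)
  train <- make_memory_dataset(tr, "multiclass")
  test <- make_memory_dataset(te, "multiclass")
  spec <- task_spec(tc$name, "multiclass", tc$num_classes,
                    patch_size = c(size, size), channels = 1L, dataset = train)
  list(spec = spec, train = train, test = test)
}

## disk output ---------------------------------------------------------------

#' Write a generated suite to disk
#'
#' Images and masks as PNG, detection ground truth as COCO-style JSON,
#' volumes as CSV slice stacks, plus a JSON manifest with the seed and
#' per-file checksums.
#'
#' @param suite result of [generate_task_suite()].
#' @param dir output directory.
#' @param seed seed recorded in the manifest.
#' @return the manifest (invisibly).
#' @export
write_suite <- function(suite, dir, seed = NA_integer_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, tasks = list())
  for (nm in names(suite)) {
    task <- suite[[nm]]
    tdir <- file.path(dir, nm)
    dir.create(tdir, showWarnings = FALSE)
    files <- character(0)
    lt <- task$spec$label_type
    coco <- NULL
    for (split in c("train", "test")) {
      ds <- task[[split]]
      for (i in seq_len(ds$n)) {
        s <- ds$samples[[i]]
        if (lt == "mil_classification") {
          f <- file.path(tdir, sprintf("%s_%04d_vol.csv", split, i))
          d <- dim(s$volume)
          m <- matrix(s$volume, nrow = d[1] * d[2])
          utils::write.table(m, f, sep = ",", row.names = FALSE,
                             col.names = FALSE)
          files <- c(files, f)
        } else {
          f <- file.path(tdir, sprintf("%s_%04d.png", split, i))
          img <- s$image
          png::writePNG(if (dim(img)[3] == 1) img[, , 1] else img, f)
          files <- c(files, f)
          if (lt == "segmentation") {
            fm <- file.path(tdir, sprintf("%s_%04d_mask.png", split, i))
            png::writePNG(s$mask / 255, fm)
            files <- c(files, fm)
          }
        }
      }
      if (lt == "detection") {
        boxes <- lapply(ds$samples, `[[`, "boxes")
        fj <- file.path(tdir, paste0(split, "_boxes.json"))
        write_coco_boxes(boxes, rep(task$spec$patch_size[1], ds$n),
                         rep(task$spec$patch_size[2], ds$n), fj)
        files <- c(files, fj)
      }
    }
    sums <- vapply(files, function(f) unname(tools::md5sum(f)), character(1))
    manifest$tasks[[nm]] <- list(label_type = lt, files = basename(files),
                                 md5 = unname(sums))
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
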