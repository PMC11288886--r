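# Declarative task definitions, per-label-type graph assembly from the shared
# blocks, and the infinite task sampler.
#
# A Task owns only its small head (a single linear layer, or a single
# convolution for dense prediction); everything else is a reference to the
# one SharedBlocks instance, so a backward pass from any task accumulates
# into the same shared gradient buffers.

LABEL_TYPES <- c("multiclass", "multilabel", "segmentation", "detection",
                 "mil_classification")

#' Define a training task
#'
#' @param name unique task name.
#' @param label_type one of `"multiclass"`, `"multilabel"`, `"segmentation"`,
#'   `"detection"`, `"mil_classification"`.
#' @param num_classes number of classes C (>= 2 for multiclass).
#' @param patch_size c(height, width) in pixels, each within [32, 1024].
#' @param channels 1 or 3.
#' @param dataset data source handle (see [make_memory_dataset()]); may be
#'   `NULL` at definition time.
#' @param sampler_weight batches of this task per optimization round.
#' @param batch_size samples per batch.
#' @return object of class `task_spec`.
#' @export
task_spec <- function(name, label_type, num_classes, patch_size = c(64L, 64L),
                      channels = 1L, dataset = NULL, sampler_weight = 1L,
                      batch_size = 8L) {
  if (!label_type %in% LABEL_TYPES)
    stop("unknown label_type '", label_type, "' (supported: ",
         paste(LABEL_TYPES, collapse = ", "), ")")
  if (label_type == "multiclass" && num_classes < 2)
    stop("multiclass tasks need C >= 2: the log C loss normalizer is undefined for C = 1")
  if (num_classes < 1) stop("num_classes must be positive")
  if (length(patch_size) == 1) patch_size <- rep(patch_size, 2)
  if (any(patch_size < 32) || any(patch_size > 1024))
    stop("patch edge lengths must lie in [32, 1024]")
  if (!channels %in% c(1L, 3L)) stop("channels must be 1 or 3")
  if (sampler_weight < 1) stop("sampler_weight must be a positive integer")
  structure(list(name = name, label_type = label_type,
                 num_classes = as.integer(num_classes),
                 patch_size = as.integer(patch_size),
                 channels = as.integer(channels), dataset = dataset,
                 sampler_weight = as.integer(sampler_weight),
                 batch_size = as.integer(batch_size)),
            class = "task_spec")
}

#' Assemble a task's computational graph on the shared blocks
#'
#' Attaches the task-specific head to the shared blocks according to the
#' label type: classification-like heads are a single linear layer on the
#' image embedding, segmentation heads a single 1x1 convolution on the pixel
#' embeddings, and detection heads one classification and one regression
#' convolution applied to every multi-scale map (the centerness convolution
#' lives in the shared multi-scale decoder).
#'
#' @param spec a [task_spec()].
#' @param shared a `shared_blocks` object; every task must reference the same
#'   instance.
#' @return object of class `mtl_task`.
#' @export
make_task <- function(spec, shared) {
  stopifnot(inherits(spec, "task_spec"), inherits(shared, "shared_blocks"))
  C <- spec$num_classes
  E <- shared$encoder$embedding_dim
  head <- switch(
    spec$label_type,
    multiclass = ,
    multilabel = list(fc = linear(E, C, name = paste0(spec$name, ".fc"),
                                  init_sd = 0.01)),
    mil_classification = list(
      att = linear(E, 1, name = paste0(spec$name, ".att"), init_sd = 0.01),
      fc = linear(E, C, name = paste0(spec$name, ".fc"), init_sd = 0.01)),
    segmentation = list(conv = conv2d(shared$pixel_decoder$channels, C, 1,
                                      name = paste0(spec$name, ".seg"))),
    detection = {
      cls <- conv2d(shared$fpn$channels, C, 1, name = paste0(spec$name, ".det_cls"))
      cls$b$value[] <- -log(99)   # focal-loss prior: initial p ~ 0.01
      list(cls = cls,
           reg = conv2d(shared$fpn$channels, 4, 1, name = paste0(spec$name, ".det_reg")))
    },
    stop("unknown label_type"))
  graph <- switch(spec$label_type,
                  multiclass = "encoder|gap|linear",
                  multilabel = "encoder|gap|linear",
                  mil_classification = "encoder|gap|attention|linear",
                  segmentation = "encoder|pixel_decoder|conv1x1",
                  detection = "encoder|multiscale_decoder|conv1x1x2")
  structure(list(spec = spec, shared = shared, head = head, graph = graph),
            class = "mtl_task")
}

#' @export
print.mtl_task <- function(x, ...) {
  cat(sprintf("<mtl_task '%s' (%s, C=%d, %dx%d px, %d ch): %s>\n",
              x$spec$name, x$spec$label_type, x$spec$num_classes,
              x$spec$patch_size[1], x$spec$patch_size[2], x$spec$channels,
              x$graph))
  invisible(x)
}

## per-label-type loss with backpropagation ----------------------------------

#' Compute a task's loss on a batch, optionally backpropagating
#'
#' Runs the task's assembled graph forward, evaluates the normalized loss for
#' its label type, and (if `backward`) accumulates gradients into every
#' referenced parameter's buffer. Activations are local to this call and
#' released when it returns, which is what keeps the memory footprint of the
#' gradient-accumulation loop independent of the number of tasks.
#'
#' @param task an `mtl_task`.
#' @param batch batch list matching the label type (see package vignette).
#' @param backward accumulate gradients.
#' @return scalar loss (invisible list with components for detection).
#' @export
task_loss <- function(task, batch, backward = FALSE) {
  switch(task$spec$label_type,
         multiclass = .loss_clf(task, batch, backward, multiclass_loss_grad),
         multilabel = .loss_clf(task, batch, backward,
                                function(s, y, ...) multilabel_loss_grad(s, y)),
         mil_classification = .loss_mil(task, batch, backward),
         segmentation = .loss_seg(task, batch, backward),
         detection = .loss_det(task, batch, backward))
}

# embedding path shared by the classification-like graphs: global average
# pooling of the deepest level followed by a parameter-free layer norm, so
# the head sees per-sample standardized features (the usual norm-then-pool
# arrangement of transformer classifiers, folded into one place here)
.embed_fwd <- function(shared, pyramid) {
  g <- gap_fwd(pyramid$levels[[4]])
  en <- norm_fwd(.embed_norm_layer, g$out)
  list(out = en$out, g = g, en = en)
}

.embed_bwd <- function(cache, dout) {
  d <- norm_bwd(.embed_norm_layer, cache$en$cache, dout)
  gap_bwd(cache$g$cache, d)
}

.embed_norm_layer <- norm_layer("parameter_free", name = "embed_norm")

.loss_clf <- function(task, batch, backward, loss_fn) {
  px <- pad_to_stride(batch$x)
  ef <- encoder_fwd(task$shared, px$x)
  em <- .embed_fwd(task$shared, ef$pyramid)
  lf <- linear_fwd(task$head$fc, em$out)
  lg <- loss_fn(lf$out, batch$y, task$spec$num_classes)
  if (backward) {
    d <- linear_bwd(task$head$fc, lf$cache, lg$dscores)
    dl4 <- .embed_bwd(em, d)
    encoder_bwd(task$shared, ef$cache, list(NULL, NULL, NULL, dl4))
  }
  lg$loss
}

.loss_mil <- function(task, batch, backward) {
  nvol <- length(batch$volumes)
  if (nvol == 0) stop("empty MIL batch")
  E <- task$shared$encoder$embedding_dim
  bags <- matrix(0, E, nvol)
  vcache <- vector("list", nvol)
  for (v in seq_len(nvol)) {
    vol <- batch$volumes[[v]]           # H x W x C x S stack of slices
    px <- pad_to_stride(vol)
    ef <- encoder_fwd(task$shared, px$x)
    em <- .embed_fwd(task$shared, ef$pyramid)
    ml <- mil_aggregate_grad(em$out, task$head$att)
    bags[, v] <- ml$out
    vcache[[v]] <- list(ef = ef, em = em, ml = ml)
  }
  lf <- linear_fwd(task$head$fc, bags)
  lg <- multiclass_loss_grad(lf$out, batch$y, task$spec$num_classes)
  if (backward) {
    dbags <- linear_bwd(task$head$fc, lf$cache, lg$dscores)
    for (v in seq_len(nvol)) {
      cc <- vcache[[v]]
      demb <- mil_aggregate_bwd(cc$ml, dbags[, v, drop = FALSE], task$head$att)
      dl4 <- .embed_bwd(cc$em, demb)
      encoder_bwd(task$shared, cc$ef$cache, list(NULL, NULL, NULL, dl4))
    }
  }
  lg$loss
}

.loss_seg <- function(task, batch, backward) {
  px <- pad_to_stride(batch$x)
  ef <- encoder_fwd(task$shared, px$x)
  pf <- pixdec_fwd(task$shared, ef$pyramid)
  cf <- conv2d_fwd(task$head$conv, pf$out)
  H <- px$H; W <- px$W
  sc <- cf$out[seq_len(H), seq_len(W), , , drop = FALSE]
  lg <- segmentation_loss_grad(sc, batch$mask)
  if (backward) {
    dfull <- array(0, dim = dim(cf$out))
    dfull[seq_len(H), seq_len(W), , ] <- lg$dscores
    d <- conv2d_bwd(task$head$conv, cf$cache, dfull)
    dlev <- pixdec_bwd(task$shared, pf$cache, d)
    encoder_bwd(task$shared, ef$cache, dlev)
  }
  lg$loss
}

.loss_det <- function(task, batch, backward) {
  px <- pad_to_stride(batch$x)
  N <- dim(px$x)[4]
  C <- task$spec$num_classes
  ef <- encoder_fwd(task$shared, px$x)
  ff <- fpn_fwd(task$shared, ef$pyramid)
  cls_f <- lapply(ff$maps, function(m) conv2d_fwd(task$head$cls, m))
  reg_f <- lapply(ff$maps, function(m) conv2d_fwd(task$head$reg, m))
  ctr_f <- lapply(ff$maps, function(m) conv2d_fwd(task$shared$fpn$ctr, m))
  total <- 0
  dcls <- lapply(cls_f, function(f) array(0, dim = dim(f$out)))
  dreg <- lapply(reg_f, function(f) array(0, dim = dim(f$out)))
  dctr <- lapply(ctr_f, function(f) array(0, dim = dim(f$out)))
  for (n in seq_len(N)) {
    tg <- assign_detection_targets(batch$boxes[[n]], c(dim(px$x)[1], dim(px$x)[2]))
    one <- function(f) lapply(f, function(ff2) {
      a <- ff2$out[, , , n, drop = FALSE]
      dim(a) <- dim(a)[1:3]
      a
    })
    lr <- detection_maps_loss_grad(one(cls_f), one(ctr_f), one(reg_f), tg, C)
    total <- total + lr$loss / N
    for (k in seq_along(dcls)) {
      dcls[[k]][, , , n] <- lr$d_cls[[k]] / N
      dreg[[k]][, , , n] <- lr$d_reg[[k]] / N
      dctr[[k]][, , , n] <- lr$d_ctr[[k]] / N
    }
  }
  if (backward) {
    dmaps <- vector("list", length(ff$maps))
    for (k in seq_along(ff$maps)) {
      d <- conv2d_bwd(task$head$cls, cls_f[[k]]$cache, dcls[[k]])
      d <- d + conv2d_bwd(task$head$reg, reg_f[[k]]$cache, dreg[[k]])
      d <- d + conv2d_bwd(task$shared$fpn$ctr, ctr_f[[k]]$cache, dctr[[k]])
      dmaps[[k]] <- d
    }
    dlev <- fpn_bwd(task$shared, ff$cache, dmaps)
    encoder_bwd(task$shared, ef$cache, dlev)
  }
  total
}

## datasets ------------------------------------------------------------------

#' Wrap in-memory samples as a task data source
#'
#' @param samples list of per-sample lists (`image` and, depending on label
#'   type, `y`, `mask`, `boxes` or `volume`).
#' @param label_type label type of the task consuming this dataset.
#' @return a dataset handle with `$n` and `$get_batch(ids)`.
#' @export
make_memory_dataset <- function(samples, label_type) {
  force(samples); force(label_type)
  n <- length(samples)
  get_batch <- function(ids) {
    ss <- samples[ids]
    switch(label_type,
           multiclass = ,
           multilabel = list(x = stack_images(lapply(ss, `[[`, "image")),
                             y = collect_labels(ss, label_type)),
           segmentation = list(x = stack_images(lapply(ss, `[[`, "image")),
                               mask = stack_masks(lapply(ss, `[[`, "mask"))),
           detection = list(x = stack_images(lapply(ss, `[[`, "image")),
                            boxes = lapply(ss, `[[`, "boxes")),
           mil_classification = list(volumes = lapply(ss, `[[`, "volume"),
                                     y = vapply(ss, `[[`, numeric(1), "y")))
  }
  list(n = n, get_batch = get_batch, label_type = label_type, samples = samples)
}

stack_images <- function(imgs) {
  d <- dim(imgs[[1]])
  if (length(d) == 2) d <- c(d, 1L)
  out <- array(0, dim = c(d, length(imgs)))
  for (i in seq_along(imgs)) out[, , , i] <- imgs[[i]]
  out
}

stack_masks <- function(masks) {
  d <- dim(masks[[1]])
  out <- array(0L, dim = c(d, length(masks)))
  for (i in seq_along(masks)) out[, , i] <- masks[[i]]
  out
}

collect_labels <- function(ss, label_type) {
  if (label_type == "multiclass") {
    vapply(ss, `[[`, numeric(1), "y")
  } else {
    do.call(cbind, lapply(ss, function(s) as.numeric(s$y)))
  }
}

## schedule and sampler ------------------------------------------------------

#' Build a task schedule
#'
#' Under the default update policy one optimization round consists of
#' `sampler_weight` batches of every task, in the listed order, and a
#' parameter update fires after the round completes.
#'
#' @param tasks list of `mtl_task` objects with non-`NULL` datasets.
#' @param update_policy optional `function(step)` returning `TRUE` when the
#'   0-based step index is an update step.
#' @return object of class `task_schedule`.
#' @export
task_schedule <- function(tasks, update_policy = NULL) {
  if (length(tasks) == 0) stop("task schedule needs at least one task")
  nms <- vapply(tasks, function(t) t$spec$name, character(1))
  if (anyDuplicated(nms)) stop("task names must be unique within a training run")
  order <- unlist(lapply(seq_along(tasks),
                         function(i) rep(i, tasks[[i]]$spec$sampler_weight)))
  structure(list(tasks = tasks, round_order = order,
                 round_len = length(order), update_policy = update_policy),
            class = "task_schedule")
}

#' Is this step an optimization step?
#'
#' @param step 0-based step index.
#' @param schedule a [task_schedule()].
#' @return logical.
#' @export
is_update_step <- function(step, schedule) {
  stopifnot(step >= 0)
  if (!is.null(schedule$update_policy)) return(schedule$update_policy(step))
  (step + 1L) %% schedule$round_len == 0L
}

#' Create the infinite task sampler
#'
#' Yields one batch of each task per optimization round (tasks with
#' `sampler_weight > 1` contribute that many batches). Each task draws from
#' its own seeded random permutation of its dataset and restarts its data
#' loading transparently when exhausted, so no dataset length information is
#' needed and the stream never terminates.
#'
#' @param schedule a [task_schedule()].
#' @param seed integer master seed; each task derives an independent stream.
#' @return sampler object; `$next_item()` returns
#'   `list(task_index, task, ids, is_update, step)`, and `$restarts()` the
#'   per-task restart counts.
#' @export
infinite_sampler <- function(schedule, seed = 1L) {
  K <- length(schedule$tasks)
  for (t in schedule$tasks) {
    if (is.null(t$spec$dataset) || t$spec$dataset$n == 0)
      stop("task '", t$spec$name, "' has an empty dataset")
  }
  streams <- lapply(seq_len(K), function(i) {
    e <- new.env()
    e$seed <- (abs(seed) + i * 1000003L) %% .Machine$integer.max
    e$restarts <- -1L
    e$order <- integer(0)
    e$pos <- 0L
    e
  })
  reshuffle <- function(i) {
    e <- streams[[i]]
    e$restarts <- e$restarts + 1L
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed((e$seed + e$restarts) %% .Machine$integer.max)
    e$order <- sample.int(schedule$tasks[[i]]$spec$dataset$n)
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
    e$pos <- 0L
  }
  draw <- function(i, n) {
    e <- streams[[i]]
    ids <- integer(0)
    while (length(ids) < n) {
      if (e$pos >= length(e$order)) reshuffle(i)
      take <- min(n - length(ids), length(e$order) - e$pos)
      ids <- c(ids, e$order[e$pos + seq_len(take)])
      e$pos <- e$pos + take
    }
    ids
  }
  step <- -1L
  next_item <- function() {
    step <<- step + 1L
    ti <- schedule$round_order[(step %% schedule$round_len) + 1L]
    task <- schedule$tasks[[ti]]
    ids <- draw(ti, task$spec$batch_size)
    list(task_index = ti, task = task, ids = ids,
         is_update = is_update_step(step, schedule), step = step)
  }
  list(next_item = next_item,
       restarts = function() vapply(streams, function(e) max(e$restarts, 0L), integer(1)),
       schedule = schedule)
}

## config files --------------------------------------------------------------

#' Load task specifications from a YAML or JSON config file
#'
#' The file holds a list `tasks:` of entries with fields `name`,
#' `label_type`, `num_classes`, `patch_size`, `channels` and optionally
#' `sampler_weight` and `batch_size`; validation errors name the offending
#' task and field.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return list of [task_spec()] objects (without datasets attached).
#' @export
load_task_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  entries <- cfg$tasks
  if (is.null(entries)) stop("config must contain a 'tasks' list")
  if (is.data.frame(entries)) entries <- split(entries, seq_len(nrow(entries)))
  lapply(entries, function(e) {
    for (f in c("name", "label_type", "num_classes"))
      if (is.null(e[[f]])) stop("task config entry missing field '", f, "'")
    tryCatch(
      task_spec(name = e$name, label_type = e$label_type,
                num_classes = e$num_classes,
                patch_size = unlist(e$patch_size) %||% c(64L, 64L),
                channels = e$channels %||% 1L,
                sampler_weight = e$sampler_weight %||% 1L,
                batch_size = e$batch_size %||% 8L),
      error = function(err) stop("invalid task '", e$name, "': ",
                                 conditionMessage(err), call. = FALSE))
  })
}
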