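# The gradient-accumulation multi-task training loop, optimizer
# configuration, and the frozen/fine-tuning downstream evaluation harness.

#' Trainer configuration
#'
#' Pretraining uses AdamW with learning rate 0.001 and weight decay 0.05.
#' Fine-tuning uses two parameter groups: shared blocks at 1e-5 and the
#' task-specific head at 1e-4. Both downstream settings train for a fixed
#' 100 epochs with no validation set. The frozen linear probe trains only a
#' convex head, for which a larger default rate (0.01) is appropriate.
#'
#' @param steps_per_epoch task-batch steps per epoch; `NULL` = one pass over
#'   the largest task dataset per epoch.
#' @param epochs number of pretraining epochs.
#' @param learning_rate,weight_decay AdamW settings for pretraining.
#' @param finetune_shared_lr,finetune_head_lr per-group fine-tuning rates.
#' @param probe_lr learning rate for the frozen linear probe head.
#' @param epochs_downstream fixed epoch count for probe and fine-tune runs.
#' @param seed master seed.
#' @export
trainer_config <- function(steps_per_epoch = NULL, epochs = 1L,
                           learning_rate = 0.001, weight_decay = 0.05,
                           finetune_shared_lr = 1e-5, finetune_head_lr = 1e-4,
                           probe_lr = 1e-2, epochs_downstream = 100L,
                           seed = 1L) {
  stopifnot(learning_rate > 0, weight_decay >= 0, finetune_shared_lr > 0,
            finetune_head_lr > 0, probe_lr > 0)
  list(steps_per_epoch = steps_per_epoch, epochs = as.integer(epochs),
       learning_rate = learning_rate, weight_decay = weight_decay,
       finetune_shared_lr = finetune_shared_lr,
       finetune_head_lr = finetune_head_lr, probe_lr = probe_lr,
       epochs_downstream = as.integer(epochs_downstream), seed = as.integer(seed))
}

## AdamW ---------------------------------------------------------------------

#' Configure an AdamW optimizer
#'
#' Decoupled-weight-decay Adam over one or more parameter groups. Each group
#' is `list(params, lr, weight_decay)`. Registering the same parameter in
#' two groups is a configuration error.
#'
#' @param groups list of parameter groups, or a flat list of parameters (a
#'   single group using `lr`/`weight_decay`).
#' @param lr,weight_decay defaults for a flat parameter list.
#' @param beta1,beta2,eps Adam moment settings.
#' @return optimizer handle (environment).
#' @export
configure_optimizer <- function(groups, lr = 0.001, weight_decay = 0.05,
                                beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (length(groups) > 0 && inherits(groups[[1]], "mtl_param"))
    groups <- list(list(params = groups, lr = lr, weight_decay = weight_decay))
  all_ids <- unlist(lapply(groups, function(g)
    vapply(g$params, function(p) p$id, integer(1))))
  if (length(all_ids) == 0) stop("optimizer needs at least one parameter")
  if (anyDuplicated(all_ids))
    stop("duplicate parameter registration across optimizer groups")
  opt <- new.env(parent = emptyenv())
  opt$groups <- lapply(groups, function(g) {
    list(params = g$params, lr = g$lr %||% lr,
         weight_decay = g$weight_decay %||% weight_decay,
         m = lapply(g$params, function(p) p$grad * 0),
         v = lapply(g$params, function(p) p$grad * 0))
  })
  opt$beta1 <- beta1; opt$beta2 <- beta2; opt$eps <- eps
  opt$t <- 0L
  class(opt) <- "mtl_optimizer"
  opt
}

optimizer_step <- function(opt) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  c1 <- 1 - b1^opt$t; c2 <- 1 - b2^opt$t
  for (gi in seq_along(opt$groups)) {
    g <- opt$groups[[gi]]
    for (i in seq_along(g$params)) {
      p <- g$params[[i]]
      if (!isTRUE(p$trainable)) next
      grad <- p$grad
      g$m[[i]] <- b1 * g$m[[i]] + (1 - b1) * grad
      g$v[[i]] <- b2 * g$v[[i]] + (1 - b2) * grad^2
      mh <- g$m[[i]] / c1
      vh <- g$v[[i]] / c2
      p$value <- p$value - g$lr * (mh / (sqrt(vh) + opt$eps) +
                                     g$weight_decay * p$value)
    }
    opt$groups[[gi]] <- g
  }
  invisible(opt)
}

optimizer_params <- function(opt) {
  unlist(lapply(opt$groups, `[[`, "params"), recursive = FALSE)
}

clear_gradients <- function(opt) {
  zero_grads(optimizer_params(opt))
  invisible(opt)
}

## the gradient-accumulation loop --------------------------------------------

#' Train shared blocks and task heads with gradient accumulation
#'
#' For each step the sampler yields one task and one of its batches; the
#' task's loss is computed and backpropagated, accumulating into the single
#' set of gradient buffers (one buffer per shared parameter regardless of
#' task count; intermediate activations are released between tasks). When
#' the schedule signals an update step, one AdamW step is applied to the
#' summed gradients and the buffers are cleared, so the update equals a
#' single step on the sum of all task losses since the last update.
#'
#' @param shared a `shared_blocks` instance (referenced by every task).
#' @param schedule a [task_schedule()] of tasks assembled on `shared`.
#' @param config a [trainer_config()].
#' @param verbose print per-epoch mean losses.
#' @return list(shared, tasks, loss_log) where `loss_log` is a data.frame
#'   with columns step, epoch, task and loss.
#' @export
train <- function(shared, schedule, config = trainer_config(), verbose = FALSE) {
  for (t in schedule$tasks) {
    if (!identical_env_set(collect_params(t$shared), collect_params(shared)))
      stop("all tasks must be assembled on the same shared blocks instance")
  }
  heads <- lapply(schedule$tasks, `[[`, "head")
  params <- collect_params(list(shared, heads))
  opt <- configure_optimizer(list(list(params = params,
                                       lr = config$learning_rate,
                                       weight_decay = config$weight_decay)))
  spe <- config$steps_per_epoch
  if (is.null(spe)) {
    max_n <- max(vapply(schedule$tasks,
                        function(t) t$spec$dataset$n / t$spec$batch_size, numeric(1)))
    spe <- as.integer(ceiling(max_n)) * schedule$round_len
  }
  sampler <- infinite_sampler(schedule, seed = config$seed)
  total_steps <- spe * config$epochs
  log_step <- integer(0); log_task <- character(0); log_loss <- numeric(0)
  clear_gradients(opt)
  step_count <- 0L
  set.seed(config$seed + 104729L)   # augmentation stream
  while (step_count < total_steps) {
    it <- sampler$next_item()
    ds <- it$task$spec$dataset
    batch <- ds$get_batch(it$ids)
    if (is.function(ds$augment)) batch <- ds$augment(batch)
    loss <- task_loss(it$task, batch, backward = TRUE)
    if (!is.finite(loss))
      stop("non-finite loss for task '", it$task$spec$name, "' at step ", it$step)
    log_step <- c(log_step, it$step)
    log_task <- c(log_task, it$task$spec$name)
    log_loss <- c(log_loss, loss)
    if (it$is_update) {
      optimizer_step(opt)
      clear_gradients(opt)
    }
    step_count <- step_count + 1L
    if (verbose && step_count %% spe == 0) {
      ep <- step_count %/% spe
      recent <- log_loss[log_step >= (ep - 1) * spe]
      message(sprintf("epoch %d: mean loss %.4f", ep, mean(recent)))
    }
  }
  loss_log <- data.frame(step = log_step, epoch = log_step %/% max(spe, 1L) + 1L,
                         task = log_task, loss = log_loss)
  list(shared = shared, tasks = schedule$tasks, loss_log = loss_log)
}

identical_env_set <- function(a, b) {
  ia <- sort(vapply(a, function(p) p$id, integer(1)))
  ib <- sort(vapply(b, function(p) p$id, integer(1)))
  identical(ia, ib)
}

#' Write a loss log as JSONL
#'
#' One JSON object per line with fields step, epoch, task and loss.
#' @param loss_log data.frame from [train()].
#' @param path output file.
#' @export
write_loss_log <- function(loss_log, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(loss_log))) {
    writeLines(jsonlite::toJSON(as.list(loss_log[i, ]), auto_unbox = TRUE), con)
  }
  invisible(path)
}

## downstream harness --------------------------------------------------------

# embeddings of every sample of a classification-like dataset (E x n)
dataset_embeddings <- function(shared, dataset, chunk = 16L) {
  n <- dataset$n
  E <- shared$encoder$embedding_dim
  out <- matrix(0, E, n)
  i <- 1L
  while (i <= n) {
    ids <- i:min(i + chunk - 1L, n)
    b <- dataset$get_batch(ids)
    if (!is.null(b$x)) {
      px <- pad_to_stride(b$x)
      ef <- encoder_fwd(shared, px$x)
      out[, ids] <- .embed_fwd(shared, ef$pyramid)$out
    } else {
      for (j in seq_along(ids)) {
        px <- pad_to_stride(b$volumes[[j]])
        ef <- encoder_fwd(shared, px$x)
        emb <- .embed_fwd(shared, ef$pyramid)$out
        out[, ids[j]] <- rowMeans(emb)
      }
    }
    i <- i + chunk
  }
  out
}

train_linear_head <- function(head, feats, labels, loss_grad_fn, epochs, lr,
                              batch_size = 8L, seed = 1L, extra_params = NULL) {
  params <- c(collect_params(head), extra_params %||% list())
  opt <- configure_optimizer(list(list(params = params, lr = lr, weight_decay = 0)))
  n <- ncol(feats)
  set.seed(seed)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    i <- 1L
    while (i <= n) {
      ids <- ord[i:min(i + batch_size - 1L, n)]
      lf <- linear_fwd(head, feats[, ids, drop = FALSE])
      lab <- if (is.matrix(labels)) labels[, ids, drop = FALSE] else labels[ids]
      lg <- loss_grad_fn(lf$out, lab)
      linear_bwd(head, lf$cache, lg$dscores)
      optimizer_step(opt)
      zero_grads(params)
      i <- i + batch_size
    }
  }
  head
}

#' Linear probing on frozen shared blocks
#'
#' Flags every shared parameter non-trainable, extracts frozen features
#' (image embeddings for classification-like tasks, pixel embeddings for
#' segmentation), and trains only a single linear (or single 1x1
#' convolution) head for the fixed downstream epoch count. Shared
#' parameters are verified byte-identical before and after.
#'
#' @param shared `shared_blocks` (will be frozen during the probe).
#' @param spec a [task_spec()] of the target task.
#' @param train_data,test_data dataset handles.
#' @param config a [trainer_config()].
#' @param metric evaluation metric name (see [evaluate()]).
#' @return list(head, value, metric, frozen_ok, predictions).
#' @export
linear_probe <- function(shared, spec, train_data, test_data,
                         config = trainer_config(), metric = "macro_f1") {
  snap_before <- param_snapshot(shared)
  old_flags <- vapply(collect_params(shared), function(p) p$trainable, logical(1))
  set_trainable(shared, FALSE)
  on.exit({
    ps <- collect_params(shared)
    for (i in seq_along(ps)) ps[[i]]$trainable <- old_flags[i]
  })
  C <- spec$num_classes
  E <- shared$encoder$embedding_dim
  if (spec$label_type %in% c("multiclass", "multilabel", "mil_classification")) {
    feats_tr <- dataset_embeddings(shared, train_data)
    feats_te <- dataset_embeddings(shared, test_data)
    labels_tr <- probe_labels(train_data, spec$label_type)
    labels_te <- probe_labels(test_data, spec$label_type)
    head <- linear(E, C, name = "probe.fc", init_sd = 0.01)
    loss_fn <- if (spec$label_type == "multilabel") {
      function(s, y) multilabel_loss_grad(s, y)
    } else {
      function(s, y) multiclass_loss_grad(s, y, C)
    }
    head <- train_linear_head(head, feats_tr, labels_tr, loss_fn,
                              epochs = config$epochs_downstream,
                              lr = config$probe_lr, seed = config$seed)
    scores <- linear_fwd(head, feats_te)$out
    pred <- if (spec$label_type == "multilabel") scores else max.col(t(scores)) - 1L
    value <- evaluate(pred, labels_te, metric)
  } else if (spec$label_type == "segmentation") {
    head <- conv2d(shared$pixel_decoder$channels, C, 1, name = "probe.seg")
    fit <- probe_segmentation(shared, head, train_data, config)
    head <- fit$head
    ev <- probe_segmentation_eval(shared, head, test_data)
    pred <- ev$pred
    value <- evaluate(ev$pred, ev$truth, metric)
  } else {
    stop("linear probing implemented for classification-like and segmentation tasks")
  }
  snap_after <- param_snapshot(shared)
  frozen_ok <- identical(snap_before, snap_after)
  if (!frozen_ok) stop("frozen contract violated: shared parameters changed during probing")
  list(head = head, value = value, metric = metric, frozen_ok = frozen_ok,
       predictions = pred)
}

probe_labels <- function(dataset, label_type) {
  ss <- dataset$samples
  if (label_type == "multilabel")
    do.call(cbind, lapply(ss, function(s) as.numeric(s$y)))
  else vapply(ss, `[[`, numeric(1), "y")
}

probe_segmentation <- function(shared, head, train_data, config) {
  n <- train_data$n
  opt <- configure_optimizer(list(list(params = collect_params(head),
                                       lr = config$probe_lr, weight_decay = 0)))
  # frozen pixel embeddings are cached once; only the 1x1 conv head trains
  feats <- vector("list", n); masks <- vector("list", n)
  for (i in seq_len(n)) {
    b <- train_data$get_batch(i)
    px <- pad_to_stride(b$x)
    ef <- encoder_fwd(shared, px$x)
    pf <- pixdec_fwd(shared, ef$pyramid)
    feats[[i]] <- pf$out[seq_len(px$H), seq_len(px$W), , , drop = FALSE]
    masks[[i]] <- b$mask
  }
  set.seed(config$seed)
  for (ep in seq_len(config$epochs_downstream)) {
    for (i in sample.int(n)) {
      cf <- conv2d_fwd(head, feats[[i]])
      lg <- segmentation_loss_grad(cf$out, masks[[i]])
      conv2d_bwd(head, cf$cache, lg$dscores)
      optimizer_step(opt)
      zero_grads(collect_params(head))
    }
  }
  list(head = head)
}

probe_segmentation_eval <- function(shared, head, test_data) {
  preds <- list(); truths <- list()
  for (i in seq_len(test_data$n)) {
    b <- test_data$get_batch(i)
    px <- pad_to_stride(b$x)
    ef <- encoder_fwd(shared, px$x)
    pf <- pixdec_fwd(shared, ef$pyramid)
    sc <- conv2d_fwd(head, pf$out)$out[seq_len(px$H), seq_len(px$W), , 1, drop = FALSE]
    C <- dim(sc)[3]
    m <- matrix(sc, ncol = C)
    preds[[i]] <- matrix(max.col(m) - 1L, nrow = px$H)
    truths[[i]] <- b$mask[, , 1]
  }
  list(pred = preds, truth = truths)
}

#' Fine-tune all parameters starting from a probe head
#'
#' The head learned in the frozen setting initializes the task head; all
#' parameters then train with two AdamW groups (shared blocks at the small
#' rate, head at the larger rate) for the fixed downstream epoch count.
#'
#' @param shared `shared_blocks`.
#' @param spec target [task_spec()] with its dataset attached.
#' @param head_init head returned by [linear_probe()].
#' @param train_data,test_data dataset handles.
#' @param config a [trainer_config()].
#' @param metric evaluation metric name.
#' @return list(value, metric, task).
#' @export
fine_tune <- function(shared, spec, head_init, train_data, test_data,
                      config = trainer_config(), metric = "macro_f1") {
  if (is.null(head_init)) stop("fine_tune requires the probe head as initialization")
  set_trainable(shared, TRUE)
  spec$dataset <- train_data
  task <- make_task(spec, shared)
  # initialize the task head from the probe head
  if (!is.null(task$head$fc) && !is.null(head_init$W)) {
    task$head$fc$W$value <- head_init$W$value
    task$head$fc$b$value <- head_init$b$value
  } else if (!is.null(task$head$conv) && !is.null(head_init$W)) {
    task$head$conv$W$value <- head_init$W$value
    task$head$conv$b$value <- head_init$b$value
  }
  opt <- configure_optimizer(list(
    list(params = collect_params(shared), lr = config$finetune_shared_lr,
         weight_decay = 0),
    list(params = collect_params(task$head), lr = config$finetune_head_lr,
         weight_decay = 0)))
  n <- train_data$n
  bs <- spec$batch_size
  set.seed(config$seed + 1L)
  for (ep in seq_len(config$epochs_downstream)) {
    ord <- sample.int(n)
    i <- 1L
    while (i <= n) {
      ids <- ord[i:min(i + bs - 1L, n)]
      batch <- train_data$get_batch(ids)
      loss <- task_loss(task, batch, backward = TRUE)
      if (!is.finite(loss)) stop("non-finite loss during fine-tuning")
      optimizer_step(opt)
      zero_grads(optimizer_params(opt))
      i <- i + bs
    }
  }
  value <- evaluate_task(task, test_data, metric)
  list(value = value, metric = metric, task = task)
}

# evaluate a classification-like task on a dataset
evaluate_task <- function(task, test_data, metric = "macro_f1") {
  spec <- task$spec
  if (spec$label_type %in% c("multiclass", "multilabel", "mil_classification")) {
    feats <- dataset_embeddings(task$shared, test_data)
    scores <- linear_fwd(task$head$fc, feats)$out
    truth <- probe_labels(test_data, spec$label_type)
    pred <- if (spec$label_type == "multilabel") scores else max.col(t(scores)) - 1L
    evaluate(pred, truth, metric)
  } else if (spec$label_type == "segmentation") {
    ev <- probe_segmentation_eval(task$shared, task$head$conv, test_data)
    evaluate(ev$pred, ev$truth, metric)
  } else stop("evaluation of this label type is not wired into evaluate_task")
}

## fraction splits and paired tests ------------------------------------------

#' Nested, label-stratified data-fraction splits
#'
#' For each of `repeats` repeats, draws per-class random orders and takes
#' prefixes at each fraction, so every smaller split is contained in every
#' larger one and the class proportions of the full set are preserved to
#' within one sample. Fractions that would yield an empty class are raised
#' to one sample per class with a warning.
#'
#' @param labels per-sample class labels of the full training set.
#' @param fractions fractions in (0, 1]; default 1, 5, 10, 25, 50, 100%.
#' @param repeats number of repeats.
#' @param seed integer seed.
#' @return object of class `split_plan`: `membership[[repeat]][[fraction]]`
#'   holds the selected sample indices.
#' @export
make_fraction_splits <- function(labels, fractions = c(.01, .05, .10, .25, .50, 1),
                                 repeats = 5L, seed = 1L) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  fractions <- sort(fractions)
  repeats <- as.integer(repeats)
  classes <- sort(unique(labels))
  idx_by_class <- lapply(classes, function(cl) which(labels == cl))
  membership <- vector("list", repeats)
  warned <- FALSE
  for (r in seq_len(repeats)) {
    set.seed(seed + r * 1009L)
    # length-safe shuffle (sample(x) on a length-1 id would expand to 1:x)
    orders <- lapply(idx_by_class, function(o) o[sample.int(length(o))])
    membership[[r]] <- lapply(fractions, function(f) {
      sel <- unlist(lapply(orders, function(o) {
        k <- round(f * length(o))
        if (k < 1) {
          if (!warned) {
            warning("fraction ", f, " yields < 1 sample for some class; taking 1")
            warned <<- TRUE
          }
          k <- 1L
        }
        if (f == 1) k <- length(o)
        o[seq_len(k)]
      }))
      sort(sel)
    })
    names(membership[[r]]) <- sprintf("%g%%", fractions * 100)
  }
  structure(list(fractions = fractions, repeats = repeats,
                 membership = membership, labels = labels),
            class = "split_plan")
}

#' Two-sided paired t-test
#'
#' Wraps `stats::t.test(paired = TRUE)`; each element of `values_a` /
#' `values_b` is one train-test split's result for the two methods being
#' compared. Zero-variance differences are reported as a degenerate case
#' (t = 0 and p = 1 when the methods agree exactly).
#'
#' @param values_a,values_b equal-length paired results (n >= 2).
#' @param alpha significance level.
#' @return list(t, p, significant, degenerate, mean_diff, n).
#' @export
paired_t_test <- function(values_a, values_b, alpha = 0.05) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 2)
  d <- values_a - values_b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(list(t = 0, p = 1, significant = FALSE, degenerate = TRUE,
                  mean_diff = 0, n = length(d)))
    return(list(t = sign(mean(d)) * Inf, p = NA_real_, significant = NA,
                degenerate = TRUE, mean_diff = mean(d), n = length(d)))
  }
  tt <- stats::t.test(values_a, values_b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       significant = tt$p.value < alpha, degenerate = FALSE,
       mean_diff = mean(d), n = length(d))
}
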