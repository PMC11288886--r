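# Gradient accumulation, optimizer configuration, splits, paired tests and
# the downstream harness contracts.

test_that("optimizer applies the configured pretraining and fine-tuning rates", {
  p <- new_param(matrix(1, 2, 2))
  opt <- configure_optimizer(list(list(params = list(p), lr = 0.001,
                                       weight_decay = 0.05)))
  expect_equal(opt$groups[[1]]$lr, 0.001)
  expect_equal(opt$groups[[1]]$weight_decay, 0.05)
  q <- new_param(1)
  opt2 <- configure_optimizer(list(
    list(params = list(p), lr = 1e-5, weight_decay = 0),
    list(params = list(q), lr = 1e-4, weight_decay = 0)))
  expect_equal(vapply(opt2$groups, `[[`, numeric(1), "lr"), c(1e-5, 1e-4))
  expect_error(configure_optimizer(list(list(params = list(p), lr = 1),
                                        list(params = list(p), lr = 2))),
               "duplicate parameter")
  expect_error(configure_optimizer(list()), "at least one parameter")
})

test_that("AdamW decouples weight decay from the gradient", {
  p <- new_param(2)
  opt <- configure_optimizer(list(list(params = list(p), lr = 0.1,
                                       weight_decay = 0.5)))
  p$grad <- 0
  optimizer_step(opt)
  # zero gradient: the only change is the decoupled decay term -lr*wd*value
  expect_equal(p$value, 2 - 0.1 * 0.5 * 2, tolerance = 1e-12)
})

test_that("accumulated multi-task update equals the joint summed-loss gradient", {
  shared <- tiny_blocks(seed = 31)
  set.seed(31)
  specs <- list(task_spec("a", "multiclass", 3),
                task_spec("b", "multilabel", 4),
                task_spec("c", "segmentation", 3))
  tasks <- lapply(specs, make_task, shared = shared)
  batches <- list(
    list(x = rand_image_batch(N = 2L), y = c(0, 2)),
    list(x = rand_image_batch(N = 2L), y = matrix(rbinom(8, 1, .5), 4, 2)),
    list(x = rand_image_batch(N = 2L),
         mask = array(sample(0:2, 32 * 32 * 2, TRUE), dim = c(32, 32, 2))))
  params <- collect_params(list(shared, lapply(tasks, `[[`, "head")))
  zero_grads(params)
  for (i in 1:3) task_loss(tasks[[i]], batches[[i]], backward = TRUE)
  acc <- lapply(params, function(p) p$grad)
  # independent oracle: finite differences of the summed loss
  joint <- function() sum(vapply(1:3, function(i)
    task_loss(tasks[[i]], batches[[i]], backward = FALSE), numeric(1)))
  set.seed(32)
  ga <- c(); gf <- c()
  for (pi in seq_along(params)) {
    p <- params[[pi]]
    idx <- sample(seq_along(p$value), min(2, length(p$value)))
    for (i in idx) {
      h <- 1e-5; v0 <- p$value[i]
      p$value[i] <- v0 + h; lp <- joint()
      p$value[i] <- v0 - h; lm <- joint()
      p$value[i] <- v0
      ga <- c(ga, acc[[pi]][i]); gf <- c(gf, (lp - lm) / (2 * h))
    }
  }
  expect_lt(rel_err(ga, gf), 1e-5)
})

test_that("task order within an optimization round does not change the gradients", {
  shared <- tiny_blocks(seed = 33)
  set.seed(33)
  tasks <- list(make_task(task_spec("a", "multiclass", 3), shared),
                make_task(task_spec("b", "multilabel", 2), shared),
                make_task(task_spec("c", "segmentation", 2), shared))
  batches <- list(
    list(x = rand_image_batch(N = 2L), y = c(1, 2)),
    list(x = rand_image_batch(N = 2L), y = matrix(rbinom(4, 1, .5), 2, 2)),
    list(x = rand_image_batch(N = 2L),
         mask = array(sample(0:1, 32 * 32 * 2, TRUE), dim = c(32, 32, 2))))
  params <- collect_params(list(shared, lapply(tasks, `[[`, "head")))
  run_order <- function(ord) {
    zero_grads(params)
    for (i in ord) task_loss(tasks[[i]], batches[[i]], backward = TRUE)
    unlist(lapply(params, function(p) as.numeric(p$grad)))
  }
  g1 <- run_order(1:3)
  g2 <- run_order(c(3, 1, 2))
  expect_lt(rel_err(g2, g1), 1e-6)
})

test_that("shared gradient buffers do not multiply with task count", {
  shared <- tiny_blocks(seed = 35)
  n_shared <- length(collect_params(shared))
  for (K in c(1L, 2L, 5L)) {
    tasks <- lapply(seq_len(K), function(i)
      make_task(task_spec(paste0("t", i), "multiclass", 2), shared))
    all_p <- collect_params(list(shared, lapply(tasks, `[[`, "head")))
    # heads add exactly 2 parameters (W, b) each; shared set stays constant
    expect_identical(length(all_p), n_shared + 2L * K)
  }
})

test_that("the training loop runs, logs losses and reacts to degenerate configs", {
  shared <- tiny_blocks(seed = 36)
  set.seed(36)
  ds <- toy_clf_dataset(8, C = 2, seed = 37)
  task <- make_task(task_spec("t", "multiclass", 2, dataset = ds,
                              batch_size = 4), shared)
  sched <- task_schedule(list(task))
  snap <- param_snapshot(shared)
  fit <- train(shared, sched, trainer_config(steps_per_epoch = 0, epochs = 1))
  expect_identical(param_snapshot(shared), snap)   # 0 steps -> no-op
  expect_identical(nrow(fit$loss_log), 0L)
  fit <- train(shared, sched, trainer_config(steps_per_epoch = 4, epochs = 2,
                                             seed = 11))
  expect_identical(nrow(fit$loss_log), 8L)
  expect_true(all(is.finite(fit$loss_log$loss)))
  expect_false(identical(param_snapshot(shared), snap))
  # loss log serializes as JSONL
  path <- tempfile(fileext = ".jsonl")
  write_loss_log(fit$loss_log, path)
  lines <- readLines(path)
  expect_length(lines, 8L)
  expect_identical(jsonlite::fromJSON(lines[1])$task, "t")
})

test_that("nested fraction splits preserve stratification and nesting", {
  labels <- c(rep(0L, 700), rep(1L, 300))
  plan <- make_fraction_splits(labels, repeats = 5, seed = 3)
  for (r in 1:5) {
    mem <- plan$membership[[r]]
    sizes <- lengths(mem)
    expect_identical(unname(sizes[length(sizes)]), 1000L)   # 100% = full set
    for (fi in seq_along(mem)) {
      f <- plan$fractions[fi]
      # stratification within one sample per class
      n1 <- sum(labels[mem[[fi]]] == 1)
      expect_lte(abs(n1 - f * 300), 1)
      # nesting
      if (fi > 1) expect_true(all(mem[[fi - 1]] %in% mem[[fi]]))
    }
  }
  expect_identical(lengths(plan$membership[[1]]),
                   c(`1%` = 10L, `5%` = 50L, `10%` = 100L, `25%` = 250L,
                     `50%` = 500L, `100%` = 1000L))
  # same seed -> identical plans
  plan2 <- make_fraction_splits(labels, repeats = 5, seed = 3)
  expect_identical(plan, plan2)
  # tiny classes are kept at one sample with a warning
  expect_warning(make_fraction_splits(c(rep(0, 99), 1), fractions = c(0.01, 1),
                                      repeats = 1), "taking 1")
})

test_that("paired t-test matches the closed form and flags degeneracy", {
  a <- c(1, 2, 3, 4, 5)
  expect_identical(paired_t_test(a, a)$t, 0)
  expect_identical(paired_t_test(a, a)$p, 1)
  r <- paired_t_test(a + 1, a)
  expect_true(r$degenerate)
  d <- c(0.5, 0.7, 0.6, 0.4, 0.8)
  r2 <- paired_t_test(d, rep(0, 5))
  expect_equal(r2$t, mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-6)
  expect_false(r2$degenerate)
})

test_that("metrics hit their canonical values", {
  expect_equal(evaluate(matrix(0:1, 2, 2), matrix(0:1, 2, 2), "miou"), 1.0)
  # chance-level AUC for predictions independent of truth
  set.seed(38)
  truth <- rep(0:1, each = 1000)
  scores <- runif(2000)
  expect_lt(abs(evaluate(scores, truth, "auc") - 0.5), 0.03)
  expect_error(evaluate(runif(5), rep(1, 5), "auc"), "single-class")
  # detections equal to ground truth at score 1 -> mAP@0.5 = 1
  gt <- list(data.frame(class_id = c(0L, 1L), x0 = c(0, 20), y0 = c(0, 20),
                        x1 = c(10, 40), y1 = c(10, 40)))
  det <- list(cbind(gt[[1]][1:2, ], score = 1)[, c("class_id", "score",
                                                   "x0", "y0", "x1", "y1")])
  expect_equal(evaluate(det, gt, "map50"), 1.0)
  # macro-F1 is the unweighted mean of per-class F1
  pred <- c(0, 0, 1, 1, 2, 2)
  truth <- c(0, 0, 1, 1, 2, 1)
  # class 0: perfect; class 1: tp=2, fn=1; class 2: tp=1, fp=1
  f1_by_class <- c(1, 4 / 5, 2 / 3)
  expect_equal(macro_f1(pred, truth), mean(f1_by_class))
})

test_that("linear probing trains only the head and honors the frozen contract", {
  set.seed(40)
  shared <- build_shared_blocks()
  # linearly separable synthetic task: stripe orientation encodes the label
  # (orientation energy survives pooling, unlike global brightness, which
  # per-sample normalization removes)
  mk <- function(n, seed) {
    set.seed(seed)
    samples <- lapply(seq_len(n), function(i) {
      y <- (i - 1L) %% 2L
      base <- matrix(0.5, 32, 32)
      stripes <- 0.3 * sin(2 * pi * (if (y == 1) row(base) else col(base)) / 6)
      img <- array(pmin(pmax(base + stripes + rnorm(1024, sd = 0.03), 0), 1),
                   dim = c(32, 32, 1))
      list(image = img, y = y)
    })
    make_memory_dataset(samples, "multiclass")
  }
  spec <- task_spec("probe", "multiclass", 2)
  before <- param_checksum(shared)
  pr <- linear_probe(shared, spec, mk(40, 41), mk(40, 42),
                     trainer_config(epochs_downstream = 40))
  expect_identical(param_checksum(shared), before)
  expect_true(pr$frozen_ok)
  expect_gte(pr$value, 0.95)
  # an independent linear classifier confirms separability of the features
  feats <- dataset_embeddings(shared, mk(40, 41))
  y <- probe_labels(mk(40, 41), "multiclass")
  fit <- suppressWarnings(stats::glm(y ~ t(feats), family = "binomial"))
  expect_gte(mean((fitted(fit) > 0.5) == y), 0.95)
})

test_that("fine-tuning starts from the probe head and moves shared parameters", {
  shared <- tiny_blocks(seed = 43)
  set.seed(43)
  ds <- toy_clf_dataset(12, C = 2, seed = 44)
  spec <- task_spec("ft", "multiclass", 2, batch_size = 4)
  pr <- linear_probe(shared, spec, ds, ds, trainer_config(epochs_downstream = 3))
  before <- param_checksum(shared)
  # with zero fine-tuning epochs the task head equals the probe's final head
  res0 <- fine_tune(shared, spec, pr$head, ds, ds,
                    trainer_config(epochs_downstream = 0))
  expect_equal(res0$task$head$fc$W$value, pr$head$W$value)
  expect_equal(res0$task$head$fc$b$value, pr$head$b$value)
  cfg <- trainer_config(epochs_downstream = 2)
  res <- fine_tune(shared, spec, pr$head, ds, ds, cfg)
  expect_false(identical(param_checksum(shared), before))
  expect_true(res$value >= 0 && res$value <= 1)
  expect_error(fine_tune(shared, spec, NULL, ds, ds, cfg), "probe head")
})

test_that("fine-tuning can exceed frozen probing when frozen features are insufficient", {
  # construct a task whose label depends on fine spatial detail that a
  # random-init encoder's pooled embedding largely discards
  mk <- function(n, seed) {
    set.seed(seed)
    samples <- lapply(seq_len(n), function(i) {
      y <- (i - 1L) %% 2L
      img <- array(runif(32 * 32, 0.4, 0.6), dim = c(32, 32, 1))
      stripe <- if (y == 1L) seq(1, 32, by = 2) else seq(2, 32, by = 2)
      img[stripe, , 1] <- img[stripe, , 1] + 0.35
      list(image = pmin(img, 1), y = y)
    })
    make_memory_dataset(samples, "multiclass")
  }
  shared <- tiny_blocks(seed = 45)
  set.seed(45)
  spec <- task_spec("hard", "multiclass", 2, batch_size = 8)
  cfg <- trainer_config(epochs_downstream = 15, seed = 46)
  pr <- linear_probe(shared, spec, mk(32, 47), mk(64, 48), cfg)
  ft <- fine_tune(shared, spec, pr$head, mk(32, 47), mk(64, 48), cfg)
  expect_gte(ft$value, pr$value)
})
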