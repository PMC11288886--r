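# Task specs, graph assembly, the infinite sampler and update policy.

test_that("task specs validate their invariants", {
  expect_error(task_spec("t", "regression", 3), "unknown label_type")
  expect_error(task_spec("t", "multiclass", 1), "C >= 2")
  expect_error(task_spec("t", "multiclass", 3, patch_size = c(16, 64)), "\\[32, 1024\\]")
  expect_error(task_spec("t", "multiclass", 3, channels = 2), "1 or 3")
  s <- task_spec("t", "multiclass", 3, patch_size = 64)
  expect_identical(s$patch_size, c(64L, 64L))
})

test_that("classification heads are a single linear layer with the exact parameter count", {
  shared <- tiny_blocks()
  E <- shared$encoder$embedding_dim
  task <- make_task(task_spec("clf9", "multiclass", 9), shared)
  expect_identical(n_params(task$head), E * 9 + 9)
  # segmentation head: a single 1x1 convolution on pixel embeddings
  seg <- make_task(task_spec("seg", "segmentation", 3), shared)
  expect_identical(seg$graph, "encoder|pixel_decoder|conv1x1")
  dch <- shared$pixel_decoder$channels
  expect_identical(n_params(seg$head), dch * 3 + 3)
})

test_that("all tasks share the identical shared-parameter objects", {
  shared <- tiny_blocks()
  t1 <- make_task(task_spec("a", "multiclass", 2), shared)
  t2 <- make_task(task_spec("b", "segmentation", 3), shared)
  ids1 <- sort(vapply(collect_params(t1$shared), function(p) p$id, integer(1)))
  ids2 <- sort(vapply(collect_params(t2$shared), function(p) p$id, integer(1)))
  expect_identical(ids1, ids2)
  # a backward pass via one task is visible to the other
  zero_grads(collect_params(shared))
  set.seed(20)
  task_loss(t1, list(x = rand_image_batch(), y = c(0, 1)), backward = TRUE)
  g <- collect_params(t2$shared)
  expect_gt(max(vapply(g, function(p) max(abs(p$grad)), numeric(1))), 0)
})

test_that("duplicate task names are rejected and empty schedules error", {
  shared <- tiny_blocks()
  t1 <- make_task(task_spec("same", "multiclass", 2, dataset = toy_clf_dataset(4)), shared)
  t2 <- make_task(task_spec("same", "multiclass", 2, dataset = toy_clf_dataset(4)), shared)
  expect_error(task_schedule(list(t1, t2)), "unique")
  expect_error(task_schedule(list()), "at least one task")
})

test_that("default update policy fires after one batch of every task", {
  shared <- tiny_blocks()
  tasks <- lapply(c("a", "b", "c"), function(nm)
    make_task(task_spec(nm, "multiclass", 2, dataset = toy_clf_dataset(4)), shared))
  sched <- task_schedule(tasks)
  expect_identical(vapply(0:2, is_update_step, logical(1), schedule = sched),
                   c(FALSE, FALSE, TRUE))
  # degenerate single-task round: every step updates
  sched1 <- task_schedule(tasks[1])
  expect_true(all(vapply(0:5, is_update_step, logical(1), schedule = sched1)))
  # custom policy: every 2 rounds with 2 tasks -> steps 3, 7, 11
  sched2 <- task_schedule(tasks[1:2],
                          update_policy = function(step) (step + 1) %% 4 == 0)
  upd <- which(vapply(0:11, is_update_step, logical(1), schedule = sched2)) - 1L
  expect_identical(upd, c(3L, 7L, 11L))
})

test_that("sampler yields one batch per task per round and restarts exhausted tasks", {
  shared <- tiny_blocks()
  big <- make_task(task_spec("big", "multiclass", 2,
                             dataset = toy_clf_dataset(20), batch_size = 2), shared)
  small <- make_task(task_spec("small", "multiclass", 2,
                               dataset = toy_clf_dataset(3), batch_size = 2), shared)
  sched <- task_schedule(list(big, small))
  sampler <- infinite_sampler(sched, seed = 5)
  counts <- c(big = 0L, small = 0L)
  for (i in 1:10) {                      # 5 rounds
    it <- sampler$next_item()
    counts[it$task$spec$name] <- counts[it$task$spec$name] + 1L
    expect_identical(it$is_update, i %% 2 == 0)
  }
  expect_identical(unname(counts), c(5L, 5L))
  # 3 samples, batch 2, 5 rounds -> 10 draws -> at least 3 restarts
  expect_gte(sampler$restarts()["small" == c("big", "small")], 3L)
})

test_that("samplers with equal seeds emit identical batch id sequences", {
  shared <- tiny_blocks()
  mk <- function() {
    tasks <- lapply(c("a", "b"), function(nm)
      make_task(task_spec(nm, "multiclass", 2, dataset = toy_clf_dataset(7),
                          batch_size = 3), shared))
    infinite_sampler(task_schedule(tasks), seed = 42)
  }
  s1 <- mk(); s2 <- mk()
  for (i in 1:12) {
    a <- s1$next_item(); b <- s2$next_item()
    expect_identical(a$ids, b$ids)
    expect_identical(a$task_index, b$task_index)
  }
})

test_that("sampler weights > 1 yield multiple batches of that task per round", {
  shared <- tiny_blocks()
  t1 <- make_task(task_spec("w2", "multiclass", 2, dataset = toy_clf_dataset(8),
                            sampler_weight = 2), shared)
  t2 <- make_task(task_spec("w1", "multiclass", 2, dataset = toy_clf_dataset(8)), shared)
  sched <- task_schedule(list(t1, t2))
  expect_identical(sched$round_len, 3L)
  sampler <- infinite_sampler(sched, seed = 1)
  nm <- vapply(1:6, function(i) sampler$next_item()$task$spec$name, character(1))
  expect_identical(sum(nm == "w2"), 4L)
  expect_identical(sum(nm == "w1"), 2L)
})

test_that("empty datasets are a configuration error", {
  shared <- tiny_blocks()
  t1 <- make_task(task_spec("e", "multiclass", 2,
                            dataset = make_memory_dataset(list(), "multiclass")), shared)
  expect_error(infinite_sampler(task_schedule(list(t1))), "empty dataset")
})

test_that("task config files load with validation", {
  cfg <- list(tasks = list(
    list(name = "a", label_type = "multiclass", num_classes = 4,
         patch_size = c(64, 64), channels = 1),
    list(name = "b", label_type = "segmentation", num_classes = 3)))
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  specs <- load_task_config(path)
  expect_length(specs, 2)
  expect_identical(specs[[1]]$num_classes, 4L)
  # invalid entries carry the task name in the error
  bad <- list(tasks = list(list(name = "x", label_type = "multiclass",
                                num_classes = 1)))
  path2 <- tempfile(fileext = ".json")
  jsonlite::write_json(bad, path2, auto_unbox = TRUE)
  expect_error(load_task_config(path2), "invalid task 'x'")
})
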