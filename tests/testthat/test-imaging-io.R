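# Intensity normalization, volume slicing, cache semantics, augmentation and
# the MIL aggregator.

test_that("intensity normalization follows the per-modality rules", {
  expect_equal(normalize_intensity(c(0, 128, 255), "uint8"), c(0, 128 / 255, 1))
  v <- array(runif(8 * 8 * 4, -1000, 3000), dim = c(8, 8, 4))
  v[1] <- -1000; v[2] <- 3000
  n <- normalize_intensity(v, "CT")
  expect_equal(range(n), c(0, 1))
  expect_equal(n[1], 0); expect_equal(n[2], 1)
  # MRI: quantile clipping matches a direct quantile computation
  set.seed(13)
  v <- array(rnorm(4000), dim = c(10, 10, 40))
  v[1:100] <- 50    # 2.5% extreme outliers
  n <- normalize_intensity(v, "MRI")
  q <- quantile(v, c(0.025, 0.975), names = FALSE)
  expect_true(all(n >= 0 & n <= 1))
  expect_equal(n[v >= q[2]], rep(1, sum(v >= q[2])))
  mid <- v > q[1] & v < q[2]
  expect_equal(n[mid], (v[mid] - q[1]) / diff(q), tolerance = 1e-12)
  # constant volume -> 0.5, generic [0,1] input idempotent
  expect_equal(unique(as.numeric(normalize_intensity(array(7, dim = c(4, 4, 4)), "CT"))), 0.5)
  x <- array(runif(64), dim = c(8, 8))
  expect_identical(normalize_intensity(x, "generic"), x)
})

test_that("volume slicing respects axis and reassembles to the volume", {
  v <- array(runif(28^3), dim = c(28, 28, 28))
  sl <- slice_volume(v)
  expect_length(sl, 28)
  expect_identical(dim(sl[[1]]), c(28L, 28L))
  v2 <- array(runif(16 * 32 * 8), dim = c(16, 32, 8))
  sl2 <- slice_volume(v2, axis = 3)
  expect_length(sl2, 8)
  expect_identical(dim(sl2[[1]]), c(16L, 32L))
  restack <- simplify2array(sl2)
  expect_equal(restack, v2)
  expect_error(slice_volume(v2, axis = 4), "axis")
})

test_that("orientation augmentation rule follows the 2x edge-length inequality", {
  expect_true(orientation_augmentation_allowed(c(28, 28, 28)))
  expect_false(orientation_augmentation_allowed(c(64, 64, 20)))
  expect_true(orientation_augmentation_allowed(c(30, 40, 59)))   # 59 < 60
  expect_false(orientation_augmentation_allowed(c(30, 40, 60)))
})

test_that("cache is LRU-bounded, loader-sparing and augments on retrieval", {
  cache <- patch_cache(capacity = 2)
  loads <- integer(0)
  mk_loader <- function(key) function() {
    loads <<- c(loads, as.integer(key))
    matrix(key, 4, 4)
  }
  for (key in c(1, 2, 1, 2)) cache_fetch(cache, key, mk_loader(key))
  expect_identical(loads, c(1L, 2L))          # hits don't re-invoke the loader
  cache_fetch(cache, 3, mk_loader(3))         # evicts LRU key 1
  expect_lte(length(cache$store), 2)
  cache_fetch(cache, 1, mk_loader(1))
  expect_identical(loads, c(1L, 2L, 3L, 1L))
  # augmentation on retrieval: stored raw patch unchanged, views differ
  cache2 <- patch_cache(4)
  set.seed(14)
  aug <- function(p) p + stats::runif(1)
  a <- cache_fetch(cache2, "k", function() matrix(0, 2, 2), aug)
  b <- cache_fetch(cache2, "k", function() stop("should not reload"), aug)
  expect_false(isTRUE(all.equal(a, b)))
  expect_equal(cache2$store[["k"]], matrix(0, 2, 2))
  # identity augmentation -> identical fetches
  c1 <- cache_fetch(cache2, "k", function() stop("no"), identity)
  c2 <- cache_fetch(cache2, "k", function() stop("no"), identity)
  expect_identical(c1, c2)
  # loader failures carry the key
  expect_error(cache_fetch(cache2, "bad", function() stop("disk error")),
               "key 'bad'")
})

test_that("xray augmentation inverts with the configured probability", {
  x <- array(runif(16 * 16), dim = c(16, 16, 1))
  forced <- augment_2d(x, "xray", force = list(photometric = FALSE, invert = TRUE))
  expect_equal(as.numeric(forced), as.numeric(1 - x), tolerance = 1e-12)
  set.seed(15)
  n <- 4000
  inv <- vapply(seq_len(n), function(i) {
    y <- augment_2d(x, "xray", force = list(photometric = FALSE))
    isTRUE(all.equal(as.numeric(y), as.numeric(1 - x)))
  }, logical(1))
  expect_lt(abs(mean(inv) - 0.3), 0.02)
})

test_that("histology channel shuffling preserves per-channel histograms as a multiset", {
  set.seed(16)
  x <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
  y <- augment_2d(x, "histology",
                  force = list(photometric = FALSE, flip = FALSE, mirror = FALSE))
  sorted_cols <- function(a) {
    m <- apply(a, 3, sort)
    m[, order(m[1, ])]
  }
  expect_equal(sorted_cols(y), sorted_cols(x))
  # outputs stay within [0, 1] under the full stochastic policy
  for (i in 1:20) {
    z <- augment_2d(x, "histology")
    expect_true(all(z >= 0 & z <= 1))
  }
})

test_that("long-edge resizing preserves aspect, range and constant images", {
  img <- matrix(runif(60 * 30), 60, 30)
  out <- resize_long_edge(img, 120)
  expect_identical(dim(out), c(120L, 60L))
  expect_true(all(out >= min(img) - 1e-12 & out <= max(img) + 1e-12))
  # constant image stays constant under interpolation
  flat <- resize_long_edge(matrix(0.4, 20, 40), 512)
  expect_identical(dim(flat), c(256L, 512L))
  expect_equal(range(flat), c(0.4, 0.4))
  # RGB arrays keep their channels
  rgb <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  expect_identical(dim(resize_long_edge(rgb, 32)), c(32L, 32L, 3L))
})

test_that("MIL aggregation is a convex combination with normalized weights", {
  set.seed(17)
  E <- 6
  # uniform scoring -> arithmetic mean
  emb <- matrix(rnorm(E * 5), E, 5)
  att <- linear(E, 1, init_sd = 0)   # zero weights -> uniform softmax
  att$b$value[] <- 0
  r <- mil_aggregate(emb, att)
  expect_equal(r$out, rowMeans(emb), tolerance = 1e-12)
  # one slice -> its own embedding
  r1 <- mil_aggregate(emb[, 1, drop = FALSE], linear(E, 1))
  expect_equal(r1$out, emb[, 1])
  expect_equal(r1$weights, 1)
  expect_error(mil_aggregate(matrix(0, E, 0)), "empty")
  # weights sum to 1 and output in the convex hull over random bags
  att <- linear(E, 1)
  for (i in 1:100) {
    S <- sample(1:8, 1)
    emb <- matrix(rnorm(E * S), E, S)
    r <- mil_aggregate(emb, att)
    expect_equal(sum(r$weights), 1, tolerance = 1e-6)
    expect_true(all(r$weights >= 0))
    expect_true(all(r$out <= apply(emb, 1, max) + 1e-9 &
                      r$out >= apply(emb, 1, min) - 1e-9))
  }
})
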