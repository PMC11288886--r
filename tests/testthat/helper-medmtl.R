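# Shared test fixtures: a miniature shared-blocks configuration and helpers.

tiny_blocks_config <- function(norm_mode = "parameter_free") {
  shared_blocks_config(in_channels = 1L, channels = c(2L, 3L, 4L, 4L),
                       decoder_channels = 3L, fpn_channels = 4L,
                       norm_mode = norm_mode)
}

tiny_blocks <- function(seed = 1L, norm_mode = "parameter_free") {
  set.seed(seed)
  build_shared_blocks(tiny_blocks_config(norm_mode))
}

rand_image_batch <- function(H = 32L, W = 32L, C = 1L, N = 2L) {
  array(stats::runif(H * W * C * N), dim = c(H, W, C, N))
}

# central finite differences of f at x
fd_grad <- function(f, x, h = 1e-5) {
  g <- array(0, dim = dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# Compare an accumulated gradient against finite-difference directional
# derivatives of `f` along k random unit directions over all parameters.
# Directional probing keeps the derivative magnitude large relative to the
# double-precision noise floor, unlike per-coordinate differences on
# near-zero gradient entries.
ga_directional_check <- function(params, grads, f, k = 10, h = 1e-6) {
  predicted <- numeric(k); observed <- numeric(k)
  for (j in seq_len(k)) {
    dirs <- lapply(params, function(p) {
      d <- rnorm(length(p$value))
      if (!is.null(dim(p$value))) dim(d) <- dim(p$value)
      d
    })
    nrm <- sqrt(sum(vapply(dirs, function(d) sum(d^2), numeric(1))))
    dirs <- lapply(dirs, function(d) d / nrm)
    move <- function(t) for (pi in seq_along(params))
      params[[pi]]$value <- params[[pi]]$value + t * dirs[[pi]]
    move(h); lp <- f()
    move(-2 * h); lm <- f()
    move(h)
    observed[j] <- (lp - lm) / (2 * h)
    predicted[j] <- sum(vapply(seq_along(params), function(pi)
      sum(grads[[pi]] * dirs[[pi]]), numeric(1)))
  }
  list(predicted = predicted, observed = observed)
}

rel_err <- function(a, b) {
  sqrt(sum((a - b)^2)) / max(1e-12, sqrt(sum(b^2)))
}

# tiny in-memory multiclass dataset of labelled random images
toy_clf_dataset <- function(n, C = 3L, size = 32L, seed = 1L) {
  set.seed(seed)
  samples <- lapply(seq_len(n), function(i)
    list(image = array(stats::runif(size * size), dim = c(size, size, 1L)),
         y = (i - 1L) %% C))
  make_memory_dataset(samples, "multiclass")
}
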