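# Layer normalization and recursive normalization replacement.
#
# The shared blocks normalize each input sample over all of its channels and
# spatial positions, never over the batch dimension, so that statistics do not
# mix across tasks with different input distributions. The default mode is
# parameter-free, y = (x - mu) / sigma with sigma = sqrt(Var(x) + eps); the
# affine variant adds a per-channel gain gamma and bias beta.

#' Construct a normalization layer
#'
#' @param mode `"parameter_free"` (no trainable parameters) or `"affine"`
#'   (per-channel `gamma` initialized to 1 and `beta` initialized to 0).
#' @param channels number of channels of the tensors this layer will see
#'   (needed for the affine parameters).
#' @param eps variance floor guarding against division by zero on constant
#'   inputs.
#' @param name layer name.
#' @return an `mtl_layer` of kind `"layer_norm"`.
#' @export
norm_layer <- function(mode = c("parameter_free", "affine"), channels = NULL,
                       eps = 1e-5, scope = c("global", "channel"),
                       name = "norm") {
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  l <- list(kind = "layer_norm", mode = mode, eps = eps, channels = channels,
            scope = scope, name = name)
  if (mode == "affine") {
    if (is.null(channels)) stop("affine normalization needs a channel count")
    l$gamma <- new_param(rep(1, channels), name = paste0(name, ".gamma"))
    l$beta <- new_param(rep(0, channels), name = paste0(name, ".beta"))
  }
  structure(l, class = "mtl_layer")
}

# View any supported input as an M x K matrix whose columns are the
# normalization groups, plus the per-row channel index for affine scaling.
# scope "channel": statistics over the channel vector of each spatial
# position (the transformer token convention); scope "global": over all
# channels and positions of a sample.
.norm_view <- function(x, scope = "channel") {
  d <- dim(x)
  if (is.null(d)) {             # bare vector: one sample
    list(m = matrix(x, ncol = 1), d = NULL, M = length(x),
         ch = rep(1L, length(x)), nch = 1L, perm = FALSE)
  } else if (length(d) == 2) {  # features x batch; each feature is a channel
    list(m = x, d = d, M = d[1], ch = seq_len(d[1]), nch = d[1], perm = FALSE)
  } else if (length(d) == 4) {  # H x W x C x N
    if (scope == "channel") {
      p <- aperm(x, c(3, 1, 2, 4))     # C x H x W x N
      list(m = matrix(p, nrow = d[3]), d = d, M = d[3],
           ch = seq_len(d[3]), nch = d[3], perm = TRUE)
    } else {
      list(m = matrix(x, nrow = prod(d[1:3]), ncol = d[4]), d = d,
           M = prod(d[1:3]), ch = rep(seq_len(d[3]), each = d[1] * d[2]),
           nch = d[3], perm = FALSE)
    }
  } else stop("unsupported input rank for layer normalization")
}

.norm_unview <- function(m, v) {
  if (is.null(v$d)) return(as.numeric(m))
  if (isTRUE(v$perm)) {
    dim(m) <- c(v$d[3], v$d[1], v$d[2], v$d[4])
    return(aperm(m, c(2, 3, 1, 4)))
  }
  dim(m) <- v$d
  m
}

#' Apply layer normalization
#'
#' Normalizes each sample (last dimension is the batch) to zero mean and unit
#' variance over all channels and spatial positions, then applies the affine
#' per-channel transform if the layer has one. Constant inputs are mapped to
#' zero by the `eps` guard.
#'
#' @param x numeric vector, matrix (features x batch) or 4-d array
#'   (H x W x C x N).
#' @param layer a [norm_layer()].
#' @return array of the same shape as `x`.
#' @export
layer_normalize <- function(x, layer = norm_layer()) {
  norm_fwd(layer, x)$out
}

norm_fwd <- function(layer, x) {
  v <- .norm_view(x, layer$scope %||% "global")
  mu <- colMeans(v$m)
  xc <- v$m - rep(mu, each = v$M)
  sig <- sqrt(colSums(xc^2) / v$M + layer$eps)
  y <- xc / rep(sig, each = v$M)
  cache <- list(y = y, sig = sig, view = v)
  if (identical(layer$mode, "affine")) {
    g <- layer$gamma$value[v$ch]
    out <- y * g + layer$beta$value[v$ch]
  } else {
    out <- y
  }
  list(out = .norm_unview(out, v), cache = cache)
}

norm_bwd <- function(layer, cache, dout) {
  v <- cache$view
  dm <- if (isTRUE(v$perm)) matrix(aperm(dout, c(3, 1, 2, 4)), nrow = v$M)
  else matrix(dout, nrow = v$M, ncol = ncol(cache$y))
  y <- cache$y
  if (identical(layer$mode, "affine")) {
    accum_grad(layer$gamma, rowsum_by(rowSums(dm * y), v$ch, layer$channels))
    accum_grad(layer$beta, rowsum_by(rowSums(dm), v$ch, layer$channels))
    dm <- dm * layer$gamma$value[v$ch]
  }
  mean_d <- colMeans(dm)
  mean_dy <- colMeans(dm * y)
  dx <- (dm - rep(mean_d, each = v$M) - y * rep(mean_dy, each = v$M)) /
    rep(cache$sig, each = v$M)
  .norm_unview(dx, v)
}

# sum a per-element vector into per-channel bins
rowsum_by <- function(x, ch, nch) {
  as.numeric(rowsum(x, group = ch, reorder = TRUE))[seq_len(nch)]
}

## batch normalization (the layer that gets replaced) ------------------------

batch_norm <- function(channels, eps = 1e-5, name = "bn") {
  structure(list(kind = "batch_norm", channels = channels, eps = eps,
                 name = name,
                 gamma = new_param(rep(1, channels), name = paste0(name, ".gamma")),
                 beta = new_param(rep(0, channels), name = paste0(name, ".beta"))),
            class = "mtl_layer")
}

# Per-channel statistics over space and batch (training mode).
batchnorm_fwd <- function(layer, x) {
  d <- dim(x)
  stopifnot(length(d) == 4)
  perm <- aperm(x, c(1, 2, 4, 3))
  m <- matrix(perm, ncol = d[3])          # (H*W*N) x C
  mu <- colMeans(m)
  xc <- m - rep(mu, each = nrow(m))
  sig <- sqrt(colSums(xc^2) / nrow(m) + layer$eps)
  y <- xc / rep(sig, each = nrow(m))
  out <- y * rep(layer$gamma$value, each = nrow(m)) +
    rep(layer$beta$value, each = nrow(m))
  dim(out) <- dim(perm)
  list(out = aperm(out, c(1, 2, 4, 3)), cache = list(y = y, sig = sig, d = d))
}

batchnorm_bwd <- function(layer, cache, dout) {
  d <- cache$d
  dm <- matrix(aperm(dout, c(1, 2, 4, 3)), ncol = d[3])
  y <- cache$y
  accum_grad(layer$gamma, colSums(dm * y))
  accum_grad(layer$beta, colSums(dm))
  dm <- dm * rep(layer$gamma$value, each = nrow(dm))
  M <- nrow(dm)
  dx <- (dm - rep(colMeans(dm), each = M) - y * rep(colMeans(dm * y), each = M)) /
    rep(cache$sig, each = M)
  dim(dx) <- c(d[1], d[2], d[4], d[3])
  aperm(dx, c(1, 2, 4, 3))
}

norm_any_fwd <- function(layer, x) {
  switch(layer$kind,
         layer_norm = norm_fwd(layer, x),
         batch_norm = batchnorm_fwd(layer, x),
         identity = list(out = x, cache = NULL),
         stop("not a normalization layer: ", layer$kind))
}

norm_any_bwd <- function(layer, cache, dout) {
  switch(layer$kind,
         layer_norm = norm_bwd(layer, cache, dout),
         batch_norm = batchnorm_bwd(layer, cache, dout),
         identity = dout)
}

#' Recursively replace normalization layers
#'
#' Walks a module tree and replaces every normalization layer (batch
#' normalization or layer normalization) with a fresh layer-normalization
#' layer of the requested mode. In `parameter_free` mode the result
#' contributes zero trainable normalization parameters; in `affine` mode each
#' layer gets per-channel `gamma = 1`, `beta = 0`. Layers that are not
#' normalization layers pass through unchanged, and the operation is
#' idempotent.
#'
#' @param blocks a layer or nested list of layers/modules.
#' @param mode `"parameter_free"` or `"affine"`.
#' @param eps variance floor for the new layers.
#' @return the module tree with replaced layers.
#' @export
replace_normalization <- function(blocks, mode = c("parameter_free", "affine"),
                                  eps = 1e-5, scope = c("global", "channel")) {
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  walk <- function(node) {
    if (inherits(node, "mtl_layer")) {
      if (node$kind %in% c("batch_norm", "layer_norm")) {
        if (node$kind == "layer_norm" && identical(node$mode, mode) &&
            identical(node$scope, scope)) return(node)
        return(norm_layer(mode, channels = node$channels, eps = eps,
                          scope = scope, name = node$name))
      }
      return(node)
    }
    if (is.list(node)) {
      for (i in seq_along(node)) node[[i]] <- walk(node[[i]])
    }
    node
  }
  walk(blocks)
}

#' Count trainable parameters belonging to normalization layers
#' @param blocks a module tree.
#' @export
norm_param_count <- function(blocks) {
  total <- 0
  walk <- function(node) {
    if (inherits(node, "mtl_layer")) {
      if (node$kind %in% c("batch_norm", "layer_norm"))
        total <<- total + n_params(node, trainable_only = TRUE)
      return(invisible())
    }
    if (is.list(node)) for (el in node) walk(el)
  }
  walk(blocks)
  total
}
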