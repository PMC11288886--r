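# Neural layers with explicit forward/backward passes.
#
# All image tensors use the R column-major layout H x W x C x N.
# Every forward returns list(out, cache); every backward takes (layer, cache,
# dout), accumulates parameter gradients in place and returns the input
# gradient.

## convolution ---------------------------------------------------------------

conv2d <- function(in_ch, out_ch, k = 3L, stride = 1L, pad = NULL, name = "conv") {
  if (is.null(pad)) pad <- k %/% 2L
  W <- new_param(he_init(c(k, k, in_ch, out_ch), fan_in = k * k * in_ch),
                 name = paste0(name, ".W"))
  b <- new_param(numeric(out_ch), name = paste0(name, ".b"))
  structure(list(kind = "conv2d", W = W, b = b, stride = as.integer(stride),
                 pad = as.integer(pad), in_ch = in_ch, out_ch = out_ch, k = k,
                 name = name),
            class = "mtl_layer")
}

conv2d_fwd <- function(layer, x) {
  y <- conv2d_fwd_cpp(x, layer$W$value, layer$b$value, layer$stride, layer$pad)
  list(out = y, cache = list(x = x))
}

conv2d_bwd <- function(layer, cache, dout) {
  g <- conv2d_bwd_cpp(cache$x, layer$W$value, dout, layer$stride, layer$pad)
  accum_grad(layer$W, g$dW)
  accum_grad(layer$b, g$db)
  g$dx
}

## identity (no-op stand-in where a norm slot is intentionally empty) --------

identity_layer <- function(name = "identity") {
  structure(list(kind = "identity", name = name), class = "mtl_layer")
}

## linear --------------------------------------------------------------------

linear <- function(in_dim, out_dim, name = "linear", init_sd = NULL) {
  if (is.null(init_sd)) init_sd <- sqrt(1 / in_dim)
  W <- new_param(array(stats::rnorm(in_dim * out_dim, sd = init_sd),
                       dim = c(out_dim, in_dim)), name = paste0(name, ".W"))
  b <- new_param(numeric(out_dim), name = paste0(name, ".b"))
  structure(list(kind = "linear", W = W, b = b, in_dim = in_dim,
                 out_dim = out_dim, name = name),
            class = "mtl_layer")
}

# x: in_dim x N
linear_fwd <- function(layer, x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  y <- layer$W$value %*% x + layer$b$value
  list(out = y, cache = list(x = x))
}

linear_bwd <- function(layer, cache, dout) {
  accum_grad(layer$W, dout %*% t(cache$x))
  accum_grad(layer$b, rowSums(dout))
  t(layer$W$value) %*% dout
}

## relu ----------------------------------------------------------------------

relu_fwd <- function(x) {
  m <- x > 0
  list(out = x * m, cache = list(mask = m))
}

relu_bwd <- function(cache, dout) dout * cache$mask

## nearest-neighbour x2 upsampling -------------------------------------------

upsample2_fwd <- function(x) {
  d <- dim(x)
  y <- x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , , drop = FALSE]
  list(out = y, cache = list(dim_in = d))
}

upsample2_bwd <- function(cache, dout) {
  d <- cache$dim_in
  i1 <- seq(1L, 2L * d[1], by = 2L); i2 <- i1 + 1L
  j1 <- seq(1L, 2L * d[2], by = 2L); j2 <- j1 + 1L
  dout[i1, j1, , , drop = FALSE] + dout[i2, j1, , , drop = FALSE] +
    dout[i1, j2, , , drop = FALSE] + dout[i2, j2, , , drop = FALSE]
}

## channel concatenation (skip connections) ----------------------------------

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[c(1, 2, 4)] == db[c(1, 2, 4)]))
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  list(out = out, ch_a = da[3], ch_b = db[3])
}

concat_ch_split <- function(dout, ch_a) {
  list(da = dout[, , seq_len(ch_a), , drop = FALSE],
       db = dout[, , -seq_len(ch_a), , drop = FALSE])
}

## global average pooling over the spatial grid ------------------------------

# x: H x W x C x N -> C x N
gap_fwd <- function(x) {
  d <- dim(x)
  m <- matrix(x, nrow = d[1] * d[2], ncol = d[3] * d[4])
  emb <- matrix(colMeans(m), nrow = d[3], ncol = d[4])
  list(out = emb, cache = list(dim_in = d))
}

gap_bwd <- function(cache, dout) {
  d <- cache$dim_in
  array(rep(as.numeric(dout), each = d[1] * d[2]) / (d[1] * d[2]), dim = d)
}
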