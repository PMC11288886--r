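# Shared blocks: multi-scale encoder, pixel-dense (U-Net style) decoder and
# multi-scale (feature pyramid) decoder, plus embedding pooling.
#
# The encoder contract: an image (H x W x C x N, values in [0,1], H and W
# divisible by 32 after padding) maps to a 4-level feature pyramid at strides
# 4, 8, 16, 32. The default encoder is a small 4-stage CNN (two convolutions
# per stage, stride-2 downsampling); any encoder meeting the contract can be
# plugged in.

#' Default shared-blocks configuration
#'
#' @param in_channels channels the encoder consumes; grayscale inputs are
#'   replicated to this count so one encoder serves 1- and 3-channel tasks.
#' @param channels per-stage encoder widths (deepest = embedding dimension).
#' @param decoder_channels width of the pixel-dense decoder.
#' @param fpn_channels common width of the five multi-scale maps.
#' @param norm_mode `"parameter_free"` or `"affine"`.
#' @param norm_eps variance floor in the normalization layers.
#' @export
shared_blocks_config <- function(in_channels = 3L,
                                 channels = c(16L, 32L, 48L, 64L),
                                 decoder_channels = 32L,
                                 fpn_channels = 64L,
                                 norm_mode = "parameter_free",
                                 norm_eps = 1e-5,
                                 norm_scope = "global") {
  list(encoder = list(name = "small_cnn", in_channels = as.integer(in_channels),
                      channels = as.integer(channels),
                      embedding_dim = as.integer(channels[length(channels)])),
       decoder = list(channels = as.integer(decoder_channels)),
       fpn = list(channels = as.integer(fpn_channels)),
       norm = list(mode = norm_mode, epsilon = norm_eps, scope = norm_scope))
}

#' Build the shared blocks
#'
#' Constructs the single encoder + pixel-dense decoder + multi-scale decoder
#' instance that every task references. Normalization layers are built as
#' batch normalization (the default of the underlying CNN components) and
#' then recursively replaced by layer normalization of the configured mode
#' via [replace_normalization()].
#'
#' @param config list as returned by [shared_blocks_config()].
#' @return an object of class `shared_blocks`.
#' @export
build_shared_blocks <- function(config = shared_blocks_config()) {
  ec <- config$encoder
  if (!identical(ec$name, "small_cnn") && is.null(config$custom_encoder))
    stop("unknown encoder '", ec$name,
         "'; supply config$custom_encoder meeting the 4-level pyramid contract")
  ch <- ec$channels
  if (length(ch) != 4) stop("encoder must expose 4 multi-scale maps (strides 4/8/16/32)")
  # pre-norm stages: normA conditions the stage input (skipped for the raw
  # image stem, which is already intensity-normalized), normB conditions the
  # residual convolution input
  mk_stage <- function(cin, cout, s1, s2, nm, input_norm = TRUE) {
    st <- list(convA = conv2d(cin, cout, 3, stride = s1, name = paste0(nm, ".convA")),
               normB = batch_norm(cout, name = paste0(nm, ".normB")),
               convB = conv2d(cout, cout, 3, stride = s2, name = paste0(nm, ".convB")))
    st$normA <- if (input_norm) batch_norm(cin, name = paste0(nm, ".normA"))
    else identity_layer()
    st
  }
  encoder <- list(
    in_channels = ec$in_channels,
    channels = ch,
    strides = c(4L, 8L, 16L, 32L),
    embedding_dim = ec$embedding_dim,
    stages = list(
      mk_stage(ec$in_channels, ch[1], 2, 2, "enc1", input_norm = FALSE),  # stride 4
      mk_stage(ch[1], ch[2], 2, 1, "enc2"),           # stride 8
      mk_stage(ch[2], ch[3], 2, 1, "enc3"),           # stride 16
      mk_stage(ch[3], ch[4], 2, 1, "enc4")))          # stride 32

  dch <- config$decoder$channels
  mk_up <- function(cin, nm) {
    list(norm = batch_norm(cin, name = paste0(nm, ".norm")),
         conv = conv2d(cin, dch, 3, name = paste0(nm, ".conv")))
  }
  pixel_decoder <- list(
    channels = dch,
    u3 = mk_up(ch[4] + ch[3], "pix.u3"),
    u2 = mk_up(dch + ch[2], "pix.u2"),
    u1 = mk_up(dch + ch[1], "pix.u1"),
    f2 = mk_up(dch, "pix.f2"),
    f1 = mk_up(dch, "pix.f1"))

  fch <- config$fpn$channels
  fpn <- list(
    channels = fch,
    strides = c(8L, 16L, 32L, 64L, 128L),
    lat2 = conv2d(ch[2], fch, 1, name = "fpn.lat2"),
    lat3 = conv2d(ch[3], fch, 1, name = "fpn.lat3"),
    lat4 = conv2d(ch[4], fch, 1, name = "fpn.lat4"),
    smooth3 = conv2d(fch, fch, 3, name = "fpn.smooth3"),
    norm3 = batch_norm(fch, name = "fpn.norm3"),
    smooth4 = conv2d(fch, fch, 3, name = "fpn.smooth4"),
    norm4 = batch_norm(fch, name = "fpn.norm4"),
    p6 = conv2d(fch, fch, 3, stride = 2, name = "fpn.p6"),
    p7 = conv2d(fch, fch, 3, stride = 2, name = "fpn.p7"),
    ctr = conv2d(fch, 1, 1, name = "fpn.ctr"))   # centerness is shared across tasks

  blocks <- structure(list(encoder = encoder, pixel_decoder = pixel_decoder,
                           fpn = fpn, norm_mode = config$norm$mode,
                           config = config),
                      class = "shared_blocks")
  replace_normalization(blocks, config$norm$mode, eps = config$norm$epsilon,
                        scope = config$norm$scope %||% "global")
}

#' @export
print.shared_blocks <- function(x, ...) {
  cat(sprintf(paste0("<shared_blocks: %s encoder (channels %s, embedding %d), ",
                     "pixel decoder %d ch, fpn %d ch, norm '%s', %d params>\n"),
              x$config$encoder$name,
              paste(x$encoder$channels, collapse = "/"),
              x$encoder$embedding_dim, x$pixel_decoder$channels,
              x$fpn$channels, x$norm_mode, n_params(x)))
  invisible(x)
}

## padding -------------------------------------------------------------------

#' Pad an image batch to the next stride multiple
#'
#' Zero-pads bottom/right so H and W are divisible by `stride` (the deepest
#' encoder stride). Masks and boxes must be padded consistently by callers;
#' [pad_to_stride()] returns the original size so outputs can be cropped back.
#'
#' @param x H x W x C x N array.
#' @param stride the divisibility requirement (default 32).
#' @return list(x = padded array, H, W = original sizes).
#' @export
pad_to_stride <- function(x, stride = 32L) {
  d <- dim(x)
  Hp <- as.integer(ceiling(d[1] / stride) * stride)
  Wp <- as.integer(ceiling(d[2] / stride) * stride)
  if (Hp != d[1] || Wp != d[2]) {
    y <- array(0, dim = c(Hp, Wp, d[3], d[4]))
    y[seq_len(d[1]), seq_len(d[2]), , ] <- x
    x <- y
  }
  list(x = x, H = d[1], W = d[2])
}

# replicate grayscale to the encoder's channel count
match_channels <- function(x, in_channels) {
  d <- dim(x)
  if (d[3] == in_channels) return(x)
  if (d[3] == 1L) {
    return(x[, , rep(1L, in_channels), , drop = FALSE])
  }
  stop("cannot adapt ", d[3], "-channel input to a ", in_channels, "-channel encoder")
}

## encoder -------------------------------------------------------------------

# One encoder stage in pre-norm residual form: normalization conditions the
# convolution inputs while the residual stream carries unnormalized
# activations (the arrangement of pre-norm transformer / modern CNN blocks).
# Post-norm placement with parameter-free layers would pin every layer's
# output distribution and stall optimization.
#   h  = relu(convA(norm_A(x)))          downsampling path
#   out = h + convB(relu(norm_B(h)))     residual refinement (shape permitting)
stage_fwd <- function(st, x) {
  na <- norm_any_fwd(st$normA, x)
  a <- conv2d_fwd(st$convA, na$out)
  ra <- relu_fwd(a$out)
  nb <- norm_any_fwd(st$normB, ra$out)
  rb <- relu_fwd(nb$out)
  b <- conv2d_fwd(st$convB, rb$out)
  residual <- all(dim(b$out) == dim(ra$out))
  out <- if (residual) ra$out + b$out else b$out
  list(out = out,
       cache = list(na = na, a = a, ra = ra, nb = nb, rb = rb, b = b,
                    residual = residual))
}

stage_bwd <- function(st, cache, dout) {
  dskip <- if (cache$residual) dout else NULL
  d <- conv2d_bwd(st$convB, cache$b$cache, dout)
  d <- relu_bwd(cache$rb$cache, d)
  d <- norm_any_bwd(st$normB, cache$nb$cache, d)
  if (!is.null(dskip)) d <- d + dskip
  d <- relu_bwd(cache$ra$cache, d)
  d <- conv2d_bwd(st$convA, cache$a$cache, d)
  norm_any_bwd(st$normA, cache$na$cache, d)
}

encoder_fwd <- function(blocks, x) {
  enc <- blocks$encoder
  if (!is.null(blocks$custom_encoder))
    return(blocks$custom_encoder$forward(x))
  x <- match_channels(x, enc$in_channels)
  levels <- vector("list", 4L)
  caches <- vector("list", 4L)
  h <- x
  for (k in 1:4) {
    s <- stage_fwd(enc$stages[[k]], h)
    levels[[k]] <- s$out
    caches[[k]] <- s$cache
    h <- s$out
  }
  pyramid <- structure(list(levels = levels, strides = enc$strides,
                            embedding_dim = enc$embedding_dim),
                       class = "feature_pyramid")
  list(pyramid = pyramid, cache = caches)
}

# dlevels: list of 4 gradients (NULL entries allowed)
encoder_bwd <- function(blocks, cache, dlevels) {
  enc <- blocks$encoder
  d <- NULL
  for (k in 4:1) {
    if (!is.null(dlevels[[k]])) {
      d <- if (is.null(d)) dlevels[[k]] else d + dlevels[[k]]
    }
    if (is.null(d)) next
    d <- stage_bwd(enc$stages[[k]], cache[[k]], d)
  }
  invisible(d)
}

#' Run the shared encoder on an image batch
#'
#' Pads to a stride-32 multiple, replicates grayscale channels if needed, and
#' returns the 4-level feature pyramid.
#'
#' @param blocks a `shared_blocks` object.
#' @param x H x W x C x N array with values in [0,1].
#' @return a `feature_pyramid` (list of 4 level arrays + strides +
#'   embedding_dim).
#' @export
encode_image <- function(blocks, x) {
  p <- pad_to_stride(x)
  encoder_fwd(blocks, p$x)$pyramid
}

## image embedding -----------------------------------------------------------

#' Fixed-size image embedding from a feature pyramid
#'
#' Global average pooling of the deepest (stride-32) pyramid level; the
#' result length equals the embedding dimension regardless of the input
#' image size.
#'
#' @param p a `feature_pyramid`.
#' @return embedding matrix (embedding_dim x N); a vector for N = 1.
#' @export
image_embedding <- function(p) {
  emb <- gap_fwd(p$levels[[4]])$out
  if (ncol(emb) == 1L) as.numeric(emb) else emb
}

## pixel-dense decoder -------------------------------------------------------

# pre-norm decoder block: norm -> conv -> relu
up_block_fwd <- function(blk, x) {
  nm <- norm_any_fwd(blk$norm, x)
  cv <- conv2d_fwd(blk$conv, nm$out)
  rl <- relu_fwd(cv$out)
  list(out = rl$out, cache = list(nm = nm, cv = cv, rl = rl))
}

up_block_bwd <- function(blk, cache, dout) {
  d <- relu_bwd(cache$rl$cache, dout)
  d <- conv2d_bwd(blk$conv, cache$cv$cache, d)
  norm_any_bwd(blk$norm, cache$nm$cache, d)
}

pixdec_fwd <- function(blocks, pyramid, use_skips = TRUE) {
  pd <- blocks$pixel_decoder
  lv <- pyramid$levels
  skip <- function(l) if (use_skips) l else array(0, dim = dim(l))
  u4 <- upsample2_fwd(lv[[4]])
  c3 <- concat_ch(u4$out, skip(lv[[3]]))
  d3 <- up_block_fwd(pd$u3, c3$out)
  u3 <- upsample2_fwd(d3$out)
  c2 <- concat_ch(u3$out, skip(lv[[2]]))
  d2 <- up_block_fwd(pd$u2, c2$out)
  u2 <- upsample2_fwd(d2$out)
  c1 <- concat_ch(u2$out, skip(lv[[1]]))
  d1 <- up_block_fwd(pd$u1, c1$out)
  uf2 <- upsample2_fwd(d1$out)
  f2 <- up_block_fwd(pd$f2, uf2$out)
  uf1 <- upsample2_fwd(f2$out)
  f1 <- up_block_fwd(pd$f1, uf1$out)
  list(out = f1$out,
       cache = list(u4 = u4, c3 = c3, d3 = d3, u3 = u3, c2 = c2, d2 = d2,
                    u2 = u2, c1 = c1, d1 = d1, uf2 = uf2, f2 = f2,
                    uf1 = uf1, f1 = f1, use_skips = use_skips))
}

# returns dlevels (list of 4) for the encoder backward
pixdec_bwd <- function(blocks, cache, dout) {
  pd <- blocks$pixel_decoder
  dlev <- vector("list", 4L)
  d <- up_block_bwd(pd$f1, cache$f1$cache, dout)
  d <- upsample2_bwd(cache$uf1$cache, d)
  d <- up_block_bwd(pd$f2, cache$f2$cache, d)
  d <- upsample2_bwd(cache$uf2$cache, d)
  d <- up_block_bwd(pd$u1, cache$d1$cache, d)
  sp <- concat_ch_split(d, cache$c1$ch_a)
  if (cache$use_skips) dlev[[1]] <- sp$db
  d <- upsample2_bwd(cache$u2$cache, sp$da)
  d <- up_block_bwd(pd$u2, cache$d2$cache, d)
  sp <- concat_ch_split(d, cache$c2$ch_a)
  if (cache$use_skips) dlev[[2]] <- sp$db
  d <- upsample2_bwd(cache$u3$cache, sp$da)
  d <- up_block_bwd(pd$u3, cache$d3$cache, d)
  sp <- concat_ch_split(d, cache$c3$ch_a)
  if (cache$use_skips) dlev[[3]] <- sp$db
  dlev[[4]] <- upsample2_bwd(cache$u4$cache, sp$da)
  dlev
}

#' Decode per-pixel embeddings from a feature pyramid
#'
#' U-Net style upsampling with skip connections: each upsampling stage
#' concatenates the matching encoder level before its convolution. Output
#' resolution equals the (padded) input resolution.
#'
#' @param blocks `shared_blocks`.
#' @param p a `feature_pyramid`.
#' @param use_skips ablation hook; `FALSE` zeroes the skip branches.
#' @return H x W x decoder_channels x N array.
#' @export
decode_pixels <- function(blocks, p, use_skips = TRUE) {
  pixdec_fwd(blocks, p, use_skips = use_skips)$out
}

## multi-scale decoder -------------------------------------------------------

fpn_fwd <- function(blocks, pyramid) {
  fp <- blocks$fpn
  lv <- pyramid$levels
  l4 <- conv2d_fwd(fp$lat4, lv[[4]])        # stride 32
  l3 <- conv2d_fwd(fp$lat3, lv[[3]])
  l2 <- conv2d_fwd(fp$lat2, lv[[2]])
  u5 <- upsample2_fwd(l4$out)
  m4 <- l3$out + u5$out
  n4 <- norm_any_fwd(fp$norm4, m4)
  s4 <- conv2d_fwd(fp$smooth4, n4$out)
  r4 <- relu_fwd(s4$out)
  u4 <- upsample2_fwd(r4$out)
  m3 <- l2$out + u4$out
  n3 <- norm_any_fwd(fp$norm3, m3)
  s3 <- conv2d_fwd(fp$smooth3, n3$out)
  r3 <- relu_fwd(s3$out)
  p6 <- conv2d_fwd(fp$p6, l4$out)           # stride 64
  r6 <- relu_fwd(p6$out)
  p7 <- conv2d_fwd(fp$p7, r6$out)           # stride 128
  maps <- list(r3$out, r4$out, l4$out, p6$out, p7$out)
  list(maps = maps,
       cache = list(l4 = l4, l3 = l3, l2 = l2, u5 = u5, s4 = s4, n4 = n4,
                    r4 = r4, u4 = u4, s3 = s3, n3 = n3, r3 = r3, p6 = p6,
                    r6 = r6, p7 = p7))
}

# dmaps: list of 5 gradients (NULL allowed) -> dlevels for encoder
fpn_bwd <- function(blocks, cache, dmaps) {
  fp <- blocks$fpn
  d7 <- dmaps[[5]]; d6 <- dmaps[[4]]; d5 <- dmaps[[3]]
  d4 <- dmaps[[2]]; d3 <- dmaps[[1]]
  dl4out <- if (is.null(d5)) array(0, dim = dim(cache$l4$out)) else d5
  if (!is.null(d7)) {
    dr6 <- conv2d_bwd(fp$p7, cache$p7$cache, d7)
    dd <- relu_bwd(cache$r6$cache, dr6)
    d6 <- if (is.null(d6)) dd else d6 + dd
  }
  if (!is.null(d6)) {
    dl4out <- dl4out + conv2d_bwd(fp$p6, cache$p6$cache, d6)
  }
  dlev <- vector("list", 4L)
  dm3 <- NULL
  if (!is.null(d3)) {
    d <- relu_bwd(cache$r3$cache, d3)
    d <- conv2d_bwd(fp$smooth3, cache$s3$cache, d)
    dm3 <- norm_any_bwd(fp$norm3, cache$n3$cache, d)   # grad at m3 = l2 + up(r4)
  }
  dr4 <- d4                                            # grad at the r4 output
  if (!is.null(dm3)) {
    dlev[[2]] <- conv2d_bwd(fp$lat2, cache$l2$cache, dm3)
    du <- upsample2_bwd(cache$u4$cache, dm3)
    dr4 <- if (is.null(dr4)) du else dr4 + du
  }
  if (!is.null(dr4)) {
    d <- relu_bwd(cache$r4$cache, dr4)
    d <- conv2d_bwd(fp$smooth4, cache$s4$cache, d)
    dm4 <- norm_any_bwd(fp$norm4, cache$n4$cache, d)   # grad at m4 = l3 + up(l4)
    dlev[[3]] <- conv2d_bwd(fp$lat3, cache$l3$cache, dm4)
    dl4out <- dl4out + upsample2_bwd(cache$u5$cache, dm4)
  }
  dlev[[4]] <- conv2d_bwd(fp$lat4, cache$l4$cache, dl4out)
  dlev
}

#' Decode multi-scale detection feature maps
#'
#' Produces five feature maps at strides 8, 16, 32, 64 and 128 (one per
#' downsampling step, with two extra levels extended from the deepest
#' pyramid level), all with a common channel width.
#'
#' @param blocks `shared_blocks`.
#' @param p a `feature_pyramid`.
#' @return list of 5 arrays.
#' @export
decode_multiscale <- function(blocks, p) {
  fpn_fwd(blocks, p)$maps
}
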