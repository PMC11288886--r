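# Modality-aware intensity normalization, 3D-to-2D conversion, patch caching
# with augment-on-retrieval, augmentation policies, and the learned
# weighted-average slice aggregator for 3D classification.

#' Normalize image or volume intensities to [0, 1]
#'
#' 8-bit images (`modality = "uint8"`) are divided by 255; CT volumes are
#' min-max scaled; MRI volumes are clipped to their (2.5%, 97.5%) intensity
#' quantiles and rescaled; `"generic"` inputs already in [0, 1] pass through
#' unchanged, otherwise they are min-max scaled. Degenerate constant inputs
#' map to 0.5 everywhere.
#'
#' @param x numeric array of any rank.
#' @param modality `"CT"`, `"MRI"`, `"uint8"` or `"generic"`.
#' @return array of the same shape with values in [0, 1].
#' @export
normalize_intensity <- function(x, modality = c("generic", "CT", "MRI", "uint8")) {
  modality <- match.arg(modality)
  if (any(!is.finite(x))) stop("non-finite intensities")
  out <- switch(modality,
    uint8 = x / 255,
    CT = {
      rng <- range(x)
      if (diff(rng) == 0) x * 0 + 0.5 else (x - rng[1]) / diff(rng)
    },
    MRI = {
      q <- stats::quantile(x, c(0.025, 0.975), names = FALSE)
      if (diff(q) == 0) x * 0 + 0.5
      else pmin(pmax((x - q[1]) / diff(q), 0), 1)
    },
    generic = {
      rng <- range(x)
      if (rng[1] >= 0 && rng[2] <= 1) x
      else if (diff(rng) == 0) x * 0 + 0.5
      else (x - rng[1]) / diff(rng)
    })
  out
}

#' Slice a 3D volume into normalized 2D patches
#'
#' Normalizes the whole volume per its modality, then cuts it along `axis`
#' (default the last dimension).
#'
#' @param volume list with `voxels` (3D array) and `modality`, or a bare 3D
#'   array (treated as `"generic"`).
#' @param axis slicing axis (1-3).
#' @return list of 2D matrices, one per index along `axis`.
#' @export
slice_volume <- function(volume, axis = 3L) {
  if (is.list(volume)) {
    vox <- volume$voxels; modality <- volume$modality %||% "generic"
  } else {
    vox <- volume; modality <- "generic"
  }
  d <- dim(vox)
  if (length(d) != 3) stop("volume must be a 3D array")
  if (axis < 1 || axis > 3) stop("slicing axis out of range")
  vox <- normalize_intensity(vox, modality)
  lapply(seq_len(d[axis]), function(i) {
    switch(axis,
           `1` = vox[i, , ],
           `2` = vox[, i, ],
           `3` = vox[, , i])
  })
}

#' Should volume orientation be augmented?
#'
#' Orientation augmentation is allowed only for roughly isotropic volumes:
#' `max(shape) < 2 * min(shape)`.
#'
#' @param shape integer vector of 3 extents.
#' @return logical.
#' @export
orientation_augmentation_allowed <- function(shape) {
  stopifnot(length(shape) == 3, all(shape > 0))
  max(shape) < 2 * min(shape)
}

#' Read a 3D volume from disk
#'
#' Supports NIfTI files (through the RNifti package, if installed) and the
#' square CSV slice stacks written by [write_suite()] (rows = flattened
#' H x W pixels, columns = slices).
#'
#' @param path file path (`.nii`, `.nii.gz` or `.csv`).
#' @param modality modality tag attached to the result.
#' @return list(voxels = 3D array, modality) suitable for [slice_volume()].
#' @export
read_volume <- function(path, modality = "generic") {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("reading NIfTI volumes requires the RNifti package")
    vox <- as.array(RNifti::readNifti(path))
  } else if (grepl("\\.csv$", path)) {
    m <- as.matrix(utils::read.table(path, sep = ","))
    edge <- sqrt(nrow(m))
    if (edge != round(edge)) stop("CSV volume stack must hold square slices")
    vox <- array(m, dim = c(edge, edge, ncol(m)))
  } else stop("unsupported volume format: ", path)
  if (length(dim(vox)) != 3) stop("expected a 3D volume in ", path)
  list(voxels = vox, modality = modality)
}

#' Resize a 2D image so its longer edge matches a target length
#'
#' Bilinear interpolation with preserved aspect ratio; the convention used
#' to bring small radiographs to a common working resolution (around 512 px
#' on the longer edge) before patch extraction.
#'
#' @param img H x W matrix or H x W x C array in [0, 1].
#' @param target_edge longer-edge length after resizing.
#' @return resized array of the same rank.
#' @export
resize_long_edge <- function(img, target_edge = 512L) {
  d <- dim(img)
  two_d <- length(d) == 2
  if (two_d) dim(img) <- c(d, 1L)
  d <- dim(img)
  s <- target_edge / max(d[1], d[2])
  Ho <- max(1L, as.integer(round(d[1] * s)))
  Wo <- max(1L, as.integer(round(d[2] * s)))
  # source coordinates of output pixel centers
  fy <- (seq_len(Ho) - 0.5) / s + 0.5
  fx <- (seq_len(Wo) - 0.5) / s + 0.5
  y0 <- pmin(pmax(floor(fy), 1), d[1]); y1 <- pmin(y0 + 1, d[1])
  x0 <- pmin(pmax(floor(fx), 1), d[2]); x1 <- pmin(x0 + 1, d[2])
  wy <- pmin(pmax(fy - y0, 0), 1); wx <- pmin(pmax(fx - x0, 0), 1)
  w00 <- outer(1 - wy, 1 - wx); w01 <- outer(1 - wy, wx)
  w10 <- outer(wy, 1 - wx); w11 <- outer(wy, wx)
  out <- array(0, dim = c(Ho, Wo, d[3]))
  for (c in seq_len(d[3])) {
    m <- img[, , c]
    out[, , c] <- w00 * m[y0, x0, drop = FALSE] + w01 * m[y0, x1, drop = FALSE] +
      w10 * m[y1, x0, drop = FALSE] + w11 * m[y1, x1, drop = FALSE]
  }
  if (two_d) out[, , 1] else out
}

## patch cache ---------------------------------------------------------------

#' Create an LRU patch cache
#'
#' Stores raw patches keyed by (source id, region, scale) up to `capacity`
#' entries with least-recently-used eviction. Retrieval returns an augmented
#' view of the stored patch, never the raw patch itself, so load-time (3D)
#' augmentations happen once per load and patch-level (2D) augmentations on
#' every fetch.
#'
#' @param capacity maximum number of resident patches.
#' @return a `patch_cache` object.
#' @export
patch_cache <- function(capacity = 64L) {
  e <- new.env(parent = emptyenv())
  e$capacity <- as.integer(capacity)
  e$store <- list()
  e$clock <- 0L
  e$stamp <- list()
  e$loads <- 0L
  class(e) <- "patch_cache"
  e
}

#' Fetch a patch through the cache
#'
#' On a miss the `loader` is invoked (applying any load-time augmentation it
#' implements) and the result stored; on a hit the stored raw patch is
#' reused. Either way the returned value is `augment(patch)` and the cached
#' raw patch remains unmodified.
#'
#' @param cache a [patch_cache()].
#' @param key character key.
#' @param loader `function()` producing the raw patch.
#' @param augment `function(patch)` applied on every retrieval (default
#'   identity).
#' @return the (augmented) patch.
#' @export
cache_fetch <- function(cache, key, loader, augment = identity) {
  key <- as.character(key)
  if (is.null(cache$store[[key]])) {
    patch <- tryCatch(loader(),
                      error = function(err) stop("loader failed for key '", key,
                                                 "': ", conditionMessage(err),
                                                 call. = FALSE))
    cache$loads <- cache$loads + 1L
    if (length(cache$store) >= cache$capacity) {
      stamps <- unlist(cache$stamp)
      evict <- names(stamps)[which.min(stamps)]
      cache$store[[evict]] <- NULL
      cache$stamp[[evict]] <- NULL
    }
    cache$store[[key]] <- patch
  }
  cache$clock <- cache$clock + 1L
  cache$stamp[[key]] <- cache$clock
  augment(cache$store[[key]])
}

#' @export
print.patch_cache <- function(x, ...) {
  cat(sprintf("<patch_cache: %d/%d resident, %d loads>\n",
              length(x$store), x$capacity, x$loads))
  invisible(x)
}

## 2D augmentation -----------------------------------------------------------

#' Domain-specific 2D augmentation
#'
#' A compact photometric/geometric policy: brightness/contrast jitter, gamma,
#' additive gaussian noise for all domains; X-ray adds intensity inversion
#' (`1 - x`) with probability 0.3; histology adds flips/mirrors and channel
#' shuffling (robustness to stain and color variation). Outputs stay within
#' [0, 1]. All randomness comes from the current R RNG stream.
#'
#' @param patch H x W or H x W x C array in [0, 1].
#' @param domain `"generic"`, `"xray"` or `"histology"`.
#' @param invert_prob inversion probability for the X-ray domain.
#' @param force named list to force specific transforms in tests, e.g.
#'   `list(invert = TRUE)`.
#' @return augmented patch, same shape.
#' @export
augment_2d <- function(patch, domain = c("generic", "xray", "histology"),
                       invert_prob = 0.3, force = list()) {
  domain <- match.arg(domain)
  d <- dim(patch)
  x <- patch
  if (length(d) == 2) dim(x) <- c(d, 1L)
  # photometric jitter (all domains)
  if (!isFALSE(force$photometric %||% TRUE)) {
    b <- stats::runif(1, -0.05, 0.05)
    cstr <- stats::runif(1, 0.9, 1.1)
    g <- stats::runif(1, 0.9, 1.1)
    x <- pmin(pmax((x - 0.5) * cstr + 0.5 + b, 0), 1)^g
    x <- x + stats::rnorm(length(x), sd = 0.01)
  }
  if (domain == "xray") {
    inv <- force$invert %||% (stats::runif(1) < invert_prob)
    if (inv) x <- 1 - x
  }
  if (domain == "histology") {
    if (force$flip %||% (stats::runif(1) < 0.5)) x <- x[rev(seq_len(nrow(x))), , , drop = FALSE]
    if (force$mirror %||% (stats::runif(1) < 0.5)) x <- x[, rev(seq_len(ncol(x))), , drop = FALSE]
    if (length(d) == 3 && d[3] == 3) {
      perm <- force$channel_perm %||% sample(3L)
      x <- x[, , perm, drop = FALSE]
    }
  }
  x <- pmin(pmax(x, 0), 1)
  dim(x) <- d
  x
}

## MIL aggregation -----------------------------------------------------------

#' Learned weighted average of slice embeddings
#'
#' Each slice embedding receives a learned linear score; softmax over the
#' bag turns the scores into nonnegative weights summing to 1, and the bag
#' representation is the weighted average of the embeddings. The result lies
#' in the convex hull of the slice embeddings and can be fed to the same
#' linear classification head as a 2D image embedding.
#'
#' @param embeddings E x S matrix (one column per slice).
#' @param att a [linear()] scoring layer (E -> 1); if `NULL`, uniform
#'   weights are used.
#' @return list(out = length-E vector, weights = length-S weights).
#' @export
mil_aggregate <- function(embeddings, att = NULL) {
  r <- mil_aggregate_grad(embeddings, att)
  list(out = as.numeric(r$out), weights = as.numeric(r$w))
}

mil_aggregate_grad <- function(embeddings, att = NULL) {
  if (is.null(dim(embeddings))) embeddings <- matrix(embeddings, ncol = 1)
  S <- ncol(embeddings)
  if (S == 0) stop("empty slice bag")
  if (is.null(att)) {
    w <- rep(1 / S, S)
    af <- NULL
  } else {
    af <- linear_fwd(att, embeddings)
    a <- as.numeric(af$out)
    a <- a - max(a)
    w <- exp(a) / sum(exp(a))
  }
  list(out = embeddings %*% w, w = w, emb = embeddings, af = af)
}

# dout: E x 1 gradient of the bag embedding; returns gradient wrt embeddings
# and accumulates attention parameters.
mil_aggregate_bwd <- function(cache, dout, att = NULL) {
  emb <- cache$emb; w <- cache$w
  demb <- dout %*% t(w)                       # E x S direct path
  if (!is.null(att) && !is.null(cache$af)) {
    dw <- as.numeric(t(emb) %*% dout)         # S
    da <- w * (dw - sum(dw * w))              # softmax backward
    demb <- demb + linear_bwd(att, cache$af$cache, matrix(da, nrow = 1))
  }
  demb
}
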