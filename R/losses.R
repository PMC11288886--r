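# Normalized task-type losses.
#
# Each label type's objective is scaled so that its value at freshly
# initialized heads on random inputs is close to one; this keeps any single
# task from dominating the summed multi-task objective and makes the average
# loss usable for model selection.
#
# Class labels are 0-based ({0, ..., C-1}) throughout, matching the
# COCO-style annotation convention used for detection ground truth.

LOG2E <- 1.44269504088896340736  # log2(e): nats -> bits

#' Normalized multiclass cross-entropy
#'
#' Categorical cross-entropy (natural log, no label smoothing) divided by
#' `log(C)`, so that the expected loss under uniform predictions is 1
#' regardless of the number of classes. `eq1_literal = TRUE` multiplies by
#' `log(C)` instead of dividing (the literal printed form of the published
#' normalization, which makes the random-init loss `log(C)^2`).
#'
#' @param scores C x N score matrix (or length-C vector for one sample).
#' @param labels integer labels in {0, ..., C-1}, one per sample.
#' @param C number of classes (>= 2).
#' @param eq1_literal use the literal multiplicative form.
#' @return scalar loss.
#' @export
multiclass_loss <- function(scores, labels, C = NULL, eq1_literal = FALSE) {
  multiclass_loss_grad(scores, labels, C, eq1_literal)$loss
}

multiclass_loss_grad <- function(scores, labels, C = NULL, eq1_literal = FALSE) {
  if (is.null(dim(scores))) scores <- matrix(scores, ncol = 1)
  if (is.null(C)) C <- nrow(scores)
  if (C < 2) stop("multiclass loss needs C >= 2 (the log C normalizer is undefined for C = 1)")
  if (nrow(scores) != C) stop("scores must have C rows")
  N <- ncol(scores)
  if (length(labels) != N) stop("one label per sample required")
  if (any(labels < 0 | labels >= C)) stop("labels must lie in {0, ..., C-1}")
  s <- sweep(scores, 2, apply(scores, 2, max))
  e <- exp(s)
  p <- sweep(e, 2, colSums(e), "/")
  idx <- cbind(as.integer(labels) + 1L, seq_len(N))
  scale <- if (eq1_literal) log(C) else 1 / log(C)
  loss <- mean(-log(pmax(p[idx], 1e-300))) * scale
  dsc <- p
  dsc[idx] <- dsc[idx] - 1
  dsc <- dsc * (scale / N)
  list(loss = loss, dscores = dsc)
}

#' Normalized multilabel binary cross-entropy
#'
#' Mean element-wise binary cross-entropy (with logits) multiplied by
#' `log2(e) = 1.44269...`, converting nats to bits so the loss at chance
#' predictions (probability 1/2 everywhere) equals exactly 1.
#'
#' @param scores real score matrix/vector (logits).
#' @param targets binary targets of the same shape.
#' @return scalar loss.
#' @export
multilabel_loss <- function(scores, targets) {
  multilabel_loss_grad(scores, targets)$loss
}

multilabel_loss_grad <- function(scores, targets) {
  if (!all(targets %in% c(0, 1))) stop("multilabel targets must be binary")
  if (length(scores) != length(targets)) stop("scores/targets length mismatch")
  s <- as.numeric(scores); t <- as.numeric(targets)
  bce <- pmax(s, 0) - s * t + log1p(exp(-abs(s)))
  p <- 1 / (1 + exp(-s))
  loss <- mean(bce) * LOG2E
  d <- (p - t) * (LOG2E / length(s))
  if (!is.null(dim(scores))) dim(d) <- dim(scores)
  list(loss = loss, dscores = d)
}

## segmentation: equally weighted Dice + Focal -------------------------------

# softmax over the channel dimension of H x W x C x N score maps; returns the
# pixel-major probability matrix (rows = (H,W,N) pixels, cols = classes)
.seg_softmax <- function(score_maps) {
  d <- dim(score_maps)
  sm <- aperm(score_maps, c(1, 2, 4, 3))
  m <- matrix(sm, ncol = d[3])
  m <- m - apply(m, 1, max)
  e <- exp(m)
  p <- e / rowSums(e)
  list(p = p, d = d)
}

#' Segmentation loss: equally weighted Dice + Focal
#'
#' `0.5 * Dice + 0.5 * Focal` over softmax class probabilities. The soft Dice
#' term uses smoothing 1 in numerator and denominator and is averaged over
#' classes and samples; the focal term uses gamma = 2 on the true-class
#' probability, averaged over pixels.
#'
#' @param score_maps H x W x C x N class score maps.
#' @param mask H x W x N (or H x W) integer label image in {0, ..., C-1}.
#' @param gamma focal exponent.
#' @param smooth Dice smoothing constant.
#' @return scalar loss.
#' @export
segmentation_loss <- function(score_maps, mask, gamma = 2, smooth = 1) {
  segmentation_loss_grad(score_maps, mask, gamma, smooth)$loss
}

segmentation_loss_grad <- function(score_maps, mask, gamma = 2, smooth = 1) {
  d <- dim(score_maps)
  if (length(d) != 4) stop("score_maps must be H x W x C x N")
  if (length(dim(mask)) == 2) dim(mask) <- c(dim(mask), 1L)
  if (!all(dim(mask) == d[c(1, 2, 4)])) stop("mask and score map shapes do not match")
  C <- d[3]; N <- d[4]; npix <- d[1] * d[2]
  if (any(mask < 0 | mask >= C)) stop("mask labels must lie in {0, ..., C-1}")
  sx <- .seg_softmax(score_maps)
  p <- sx$p                                   # (H*W*N) x C
  lab <- as.integer(mask) + 1L                # aligned with rows of p
  onehot <- matrix(0, nrow(p), C)
  onehot[cbind(seq_along(lab), lab)] <- 1

  # soft Dice per (class, sample)
  grp <- rep(seq_len(N), each = npix)
  A <- rowsum(p * onehot, grp)                # N x C sums of p*m
  P <- rowsum(p, grp)
  M <- rowsum(onehot, grp)
  B <- P + M
  dice_cn <- 1 - (2 * A + smooth) / (B + smooth)
  dice <- mean(dice_cn)
  # d dice / d p for pixel i of sample n, class c
  g_num <- -2 * onehot * (B + smooth)[grp, , drop = FALSE]
  g_den <- (2 * A + smooth)[grp, , drop = FALSE]
  g_dice <- (g_num + g_den) / ((B + smooth)[grp, , drop = FALSE]^2) / (C * N)

  # focal on the true class
  pt <- pmin(pmax(p[cbind(seq_along(lab), lab)], 1e-12), 1 - 1e-12)
  focal <- mean(-(1 - pt)^gamma * log(pt))
  dfdpt <- (gamma * (1 - pt)^(gamma - 1) * log(pt) - (1 - pt)^gamma / pt) / length(pt)
  g_focal <- matrix(0, nrow(p), C)
  g_focal[cbind(seq_along(lab), lab)] <- dfdpt

  g <- 0.5 * g_dice + 0.5 * g_focal
  # chain through softmax: ds_j = p_j * (g_j - sum_c g_c p_c)
  ds <- p * (g - rowSums(g * p))
  dim(ds) <- c(d[1], d[2], d[4], d[3])
  ds <- aperm(ds, c(1, 2, 4, 3))
  list(loss = 0.5 * dice + 0.5 * focal, dscores = ds,
       dice = dice, focal = focal)
}

#' Centerness of a pixel within its assigned box
#'
#' `sqrt(min(l,r)/max(l,r) * min(t,b)/max(t,b))`: 1 at the box center,
#' approaching 0 at the edges; used to down-weight low-quality detections.
#' All-zero distances (degenerate) return 0.
#'
#' @param l,t,r,b nonnegative distances (vectors allowed) from a pixel to the
#'   left/top/right/bottom box edges.
#' @return value(s) in [0, 1].
#' @export
centerness <- function(l, t, r, b) {
  if (any(c(l, t, r, b) < 0)) stop("centerness distances must be nonnegative")
  mx_lr <- pmax(l, r); mx_tb <- pmax(t, b)
  out <- numeric(length(mx_lr))
  ok <- mx_lr > 0 & mx_tb > 0
  out[ok] <- sqrt((pmin(l, r)[ok] / mx_lr[ok]) * (pmin(t, b)[ok] / mx_tb[ok]))
  out
}

#' Combined detection loss
#'
#' The detection objective divides the classification component by the number
#' of classes and adds the regression and centerness components unweighted:
#' `L = L_cls / C + L_reg + L_ctr`.
#'
#' @param class_loss,regression_loss,centerness_loss nonnegative components.
#' @param C number of object classes.
#' @return scalar loss.
#' @export
detection_loss <- function(class_loss, regression_loss, centerness_loss, C) {
  stopifnot(class_loss >= 0, regression_loss >= 0, centerness_loss >= 0, C >= 1)
  class_loss / C + regression_loss + centerness_loss
}
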