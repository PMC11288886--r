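# Anchor-free detection: per-pixel target assignment on the multi-scale maps,
# the focal/IoU/centerness loss components, and box decoding with NMS.
#
# Coordinates are 0-based pixels; boxes are half-open [x0, x1) x [y0, y1).
# The pixel at row i, column j of a stride-s map sits at image location
# x = (j + 0.5) * s, y = (i + 0.5) * s.

DET_RANGES <- rbind(c(0, 64), c(64, 128), c(128, 256), c(256, 512), c(512, Inf))

# spatial sizes of the five multi-scale maps for a padded H x W input
multiscale_level_sizes <- function(H, W) {
  h5 <- H / 32; w5 <- W / 32
  sizes <- list(c(H / 8, W / 8), c(H / 16, W / 16), c(h5, w5))
  h <- h5; w <- w5
  for (k in 4:5) {
    h <- ceiling(h / 2); w <- ceiling(w / 2)
    sizes[[k]] <- c(h, w)
  }
  lapply(sizes, as.integer)
}

#' Assign anchor-free detection targets
#'
#' Every pixel of every multi-scale map receives a class target (0 =
#' background), distances (l, t, r, b) to the edges of its assigned box, and
#' a centerness target. A box is routed to the level whose regression range
#' contains its largest edge distance; when several boxes claim one pixel the
#' smallest-area box wins.
#'
#' @param boxes data.frame with columns `class_id` (0-based), `x0`, `y0`,
#'   `x1`, `y1` (half-open pixel coordinates).
#' @param image_size c(H, W) of the (padded) image.
#' @param strides map strides (default 8, 16, 32, 64, 128).
#' @param ranges matrix of per-level (lo, hi] regression ranges in px.
#' @return object of class `detection_targets`: per level, `cls` (Hl x Wl,
#'   0 = background, k = class k-1), `ltrb` (Hl x Wl x 4), `ctr` (Hl x Wl).
#' @export
assign_detection_targets <- function(boxes, image_size,
                                     strides = c(8L, 16L, 32L, 64L, 128L),
                                     ranges = DET_RANGES) {
  H <- image_size[1]; W <- image_size[2]
  if (nrow(boxes) > 0) {
    with(boxes, {
      if (any(x1 <= x0) || any(y1 <= y0)) stop("degenerate box (x1 <= x0 or y1 <= y0)")
      if (any(x0 < 0) || any(y0 < 0) || any(x1 > W) || any(y1 > H))
        stop("box outside the image bounds")
    })
  }
  area <- if (nrow(boxes)) (boxes$x1 - boxes$x0) * (boxes$y1 - boxes$y0) else numeric(0)
  sizes <- multiscale_level_sizes(H, W)
  levels <- vector("list", length(strides))
  for (k in seq_along(strides)) {
    s <- strides[k]
    Hl <- sizes[[k]][1]; Wl <- sizes[[k]][2]
    cls <- matrix(0L, Hl, Wl)
    ltrb <- array(0, dim = c(Hl, Wl, 4))
    ctr <- matrix(0, Hl, Wl)
    if (nrow(boxes) > 0) {
      xs <- (seq_len(Wl) - 0.5) * s
      ys <- (seq_len(Hl) - 0.5) * s
      best_area <- matrix(Inf, Hl, Wl)
      for (b in seq_len(nrow(boxes))) {
        l <- outer(rep(1, Hl), xs - boxes$x0[b])
        r <- outer(rep(1, Hl), boxes$x1[b] - xs)
        t <- outer(ys - boxes$y0[b], rep(1, Wl))
        bo <- outer(boxes$y1[b] - ys, rep(1, Wl))
        m <- pmax(l, pmax(r, pmax(t, bo)))
        inside <- l > 0 & r > 0 & t > 0 & bo > 0
        fits <- m > ranges[k, 1] & m <= ranges[k, 2]
        take <- inside & fits & (area[b] < best_area)
        if (!any(take)) next
        best_area[take] <- area[b]
        cls[take] <- boxes$class_id[b] + 1L
        ltrb[, , 1][take] <- l[take]
        ltrb[, , 2][take] <- t[take]
        ltrb[, , 3][take] <- r[take]
        ltrb[, , 4][take] <- bo[take]
        ctr[take] <- centerness(l[take], t[take], r[take], bo[take])
      }
    }
    levels[[k]] <- list(cls = cls, ltrb = ltrb, ctr = ctr, stride = s)
  }
  structure(list(levels = levels, image_size = c(H, W), strides = strides),
            class = "detection_targets")
}

## loss on predicted maps ----------------------------------------------------

# Per-image detection loss with gradients.
# cls_maps/ctr_maps/reg_maps: lists over levels of Hl x Wl x {C,1,4} arrays
# (single image). Regression predictions are exp(x) * stride distances.
detection_maps_loss_grad <- function(cls_maps, ctr_maps, reg_maps, targets, C,
                                     gamma = 2, alpha = 0.25) {
  nfg_total <- sum(vapply(targets$levels, function(lv) sum(lv$cls > 0), numeric(1)))
  nfg_div <- max(1, nfg_total)
  cls_loss <- 0; reg_loss <- 0; ctr_loss <- 0
  d_cls <- list(); d_ctr <- list(); d_reg <- list()
  for (k in seq_along(targets$levels)) {
    lv <- targets$levels[[k]]
    s_cls <- cls_maps[[k]]; s_ctr <- ctr_maps[[k]]; s_reg <- reg_maps[[k]]
    Hl <- nrow(lv$cls); Wl <- ncol(lv$cls)
    tmat <- array(0, dim = c(Hl, Wl, C))
    fg <- lv$cls > 0
    for (c in seq_len(C)) tmat[, , c][lv$cls == c] <- 1
    # binary focal per class map
    p <- 1 / (1 + exp(-s_cls))
    p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
    t <- tmat
    fl <- -alpha * t * (1 - p)^gamma * log(p) -
      (1 - alpha) * (1 - t) * p^gamma * log(1 - p)
    cls_loss <- cls_loss + sum(fl) / nfg_div
    dldp <- alpha * t * (gamma * (1 - p)^(gamma - 1) * log(p) - (1 - p)^gamma / p) +
      (1 - alpha) * (1 - t) * (-gamma * p^(gamma - 1) * log(1 - p) + p^gamma / (1 - p))
    d_cls[[k]] <- dldp * p * (1 - p) / nfg_div
    # centerness BCE over foreground
    sc <- s_ctr[, , 1, drop = TRUE]
    dim(sc) <- c(Hl, Wl)
    dctr <- array(0, dim = dim(s_ctr))
    if (any(fg)) {
      sfg <- sc[fg]; tfg <- lv$ctr[fg]
      bce <- pmax(sfg, 0) - sfg * tfg + log1p(exp(-abs(sfg)))
      ctr_loss <- ctr_loss + sum(bce) / nfg_div
      pc <- 1 / (1 + exp(-sfg))
      tmp <- matrix(0, Hl, Wl)
      tmp[fg] <- (pc - tfg) / nfg_div
      dctr[, , 1] <- tmp
    }
    d_ctr[[k]] <- dctr
    # IoU regression over foreground
    dreg <- array(0, dim = dim(s_reg))
    if (any(fg)) {
      idx <- which(fg)
      pr <- exp(matrix(s_reg, Hl * Wl, 4)[idx, , drop = FALSE]) * lv$stride
      tg <- matrix(lv$ltrb, Hl * Wl, 4)[idx, , drop = FALSE]
      il <- pmin(pr[, 1], tg[, 1]); it <- pmin(pr[, 2], tg[, 2])
      ir <- pmin(pr[, 3], tg[, 3]); ib <- pmin(pr[, 4], tg[, 4])
      iw <- il + ir; ih <- it + ib
      I <- iw * ih
      Ap <- (pr[, 1] + pr[, 3]) * (pr[, 2] + pr[, 4])
      At <- (tg[, 1] + tg[, 3]) * (tg[, 2] + tg[, 4])
      U <- pmax(Ap + At - I, 1e-9)
      iou <- I / U
      reg_loss <- reg_loss + sum(1 - iou) / nfg_div
      # gradients of (1 - IoU) wrt predicted distances
      dI <- cbind((pr[, 1] < tg[, 1]) * ih, (pr[, 2] < tg[, 2]) * iw,
                  (pr[, 3] < tg[, 3]) * ih, (pr[, 4] < tg[, 4]) * iw)
      dAp <- cbind(pr[, 2] + pr[, 4], pr[, 1] + pr[, 3],
                   pr[, 2] + pr[, 4], pr[, 1] + pr[, 3])
      dU <- dAp - dI
      diou <- (dI * U - I * dU) / U^2
      dpred <- -diou / nfg_div
      dscore <- dpred * pr                    # chain through exp(x) * stride
      tmp <- matrix(0, Hl * Wl, 4)
      tmp[idx, ] <- dscore
      dreg <- array(tmp, dim = dim(s_reg))
    }
    d_reg[[k]] <- dreg
  }
  total <- detection_loss(cls_loss, reg_loss, ctr_loss, C)
  for (k in seq_along(d_cls)) d_cls[[k]] <- d_cls[[k]] / C
  list(loss = total, cls = cls_loss, reg = reg_loss, ctr = ctr_loss,
       d_cls = d_cls, d_ctr = d_ctr, d_reg = d_reg)
}

## decoding ------------------------------------------------------------------

box_iou_matrix <- function(a, b) {
  n <- nrow(a); m <- nrow(b)
  out <- matrix(0, n, m)
  for (i in seq_len(n)) {
    iw <- pmax(0, pmin(a[i, 3], b[, 3]) - pmax(a[i, 1], b[, 1]))
    ih <- pmax(0, pmin(a[i, 4], b[, 4]) - pmax(a[i, 2], b[, 2]))
    inter <- iw * ih
    ua <- (a[i, 3] - a[i, 1]) * (a[i, 4] - a[i, 2]) +
      (b[, 3] - b[, 1]) * (b[, 4] - b[, 2]) - inter
    out[i, ] <- inter / pmax(ua, 1e-9)
  }
  out
}

nms_keep <- function(boxes, scores, iou_thr) {
  ord <- order(scores, decreasing = TRUE)
  keep <- integer(0)
  while (length(ord) > 0) {
    i <- ord[1]
    keep <- c(keep, i)
    if (length(ord) == 1) break
    ious <- box_iou_matrix(boxes[i, , drop = FALSE], boxes[ord[-1], , drop = FALSE])
    ord <- ord[-1][ious[1, ] <= iou_thr]
  }
  keep
}

#' Decode boxes from multi-scale detection maps
#'
#' Reconstructs boxes from per-pixel (l, t, r, b) predictions; the score of a
#' box is the classification probability multiplied by the predicted
#' centerness; overlapping boxes of the same class are suppressed at
#' `nms_iou`.
#'
#' @param cls_maps,ctr_maps,reg_maps per-level logit maps for one image
#'   (Hl x Wl x C, Hl x Wl x 1, Hl x Wl x 4); regression logits encode
#'   `exp(x) * stride` distances.
#' @param strides level strides.
#' @param image_size c(H, W) for clipping.
#' @param score_threshold minimum final score.
#' @param nms_iou suppression IoU threshold.
#' @return data.frame(class_id, score, x0, y0, x1, y1), possibly empty.
#' @export
decode_detections <- function(cls_maps, ctr_maps, reg_maps,
                              strides = c(8L, 16L, 32L, 64L, 128L),
                              image_size = NULL,
                              score_threshold = 0.05, nms_iou = 0.5) {
  rows <- list()
  for (k in seq_along(cls_maps)) {
    s <- strides[k]
    sc <- cls_maps[[k]]
    Hl <- dim(sc)[1]; Wl <- dim(sc)[2]; C <- dim(sc)[3]
    pc <- 1 / (1 + exp(-matrix(sc, Hl * Wl, C)))
    pctr <- 1 / (1 + exp(-as.numeric(ctr_maps[[k]][, , 1])))
    best <- max.col(pc, ties.method = "first")
    bscore <- pc[cbind(seq_len(Hl * Wl), best)] * pctr
    sel <- which(bscore >= score_threshold)
    if (!length(sel)) next
    reg <- exp(matrix(reg_maps[[k]], Hl * Wl, 4)[sel, , drop = FALSE]) * s
    ij <- arrayInd(sel, c(Hl, Wl))
    cx <- (ij[, 2] - 0.5) * s
    cy <- (ij[, 1] - 0.5) * s
    rows[[length(rows) + 1L]] <- data.frame(
      class_id = best[sel] - 1L, score = bscore[sel],
      x0 = cx - reg[, 1], y0 = cy - reg[, 2],
      x1 = cx + reg[, 3], y1 = cy + reg[, 4])
  }
  if (!length(rows))
    return(data.frame(class_id = integer(0), score = numeric(0), x0 = numeric(0),
                      y0 = numeric(0), x1 = numeric(0), y1 = numeric(0)))
  det <- do.call(rbind, rows)
  if (!is.null(image_size)) {
    det$x0 <- pmax(det$x0, 0); det$y0 <- pmax(det$y0, 0)
    det$x1 <- pmin(det$x1, image_size[2]); det$y1 <- pmin(det$y1, image_size[1])
  }
  keep <- integer(0)
  for (cid in unique(det$class_id)) {
    rows_c <- which(det$class_id == cid)
    bx <- as.matrix(det[rows_c, c("x0", "y0", "x1", "y1")])
    keep <- c(keep, rows_c[nms_keep(bx, det$score[rows_c], nms_iou)])
  }
  det <- det[sort(keep), , drop = FALSE]
  rownames(det) <- NULL
  det[order(det$score, decreasing = TRUE), , drop = FALSE]
}

#' Render detection targets as ideal prediction maps
#'
#' Encodes assigned targets into logit maps (saturated class logits, exact
#' centerness logits, `log(distance/stride)` regression) so that decoding
#' recovers the ground truth; used for round-trip validation of the
#' assign/decode pair.
#'
#' @param targets a `detection_targets` object.
#' @param C number of classes.
#' @return list(cls_maps, ctr_maps, reg_maps).
#' @export
detection_targets_to_maps <- function(targets, C) {
  cls_maps <- list(); ctr_maps <- list(); reg_maps <- list()
  for (k in seq_along(targets$levels)) {
    lv <- targets$levels[[k]]
    Hl <- nrow(lv$cls); Wl <- ncol(lv$cls)
    cls <- array(-20, dim = c(Hl, Wl, C))
    for (c in seq_len(C)) cls[, , c][lv$cls == c] <- 20
    ctrv <- pmin(pmax(lv$ctr, 1e-6), 1 - 1e-6)
    ctr <- array(log(ctrv / (1 - ctrv)), dim = c(Hl, Wl, 1))
    ctr[, , 1][lv$cls == 0] <- -20
    reg <- array(0, dim = c(Hl, Wl, 4))
    safe <- pmax(lv$ltrb, 1e-6)
    reg <- array(log(safe / lv$stride), dim = c(Hl, Wl, 4))
    cls_maps[[k]] <- cls; ctr_maps[[k]] <- ctr; reg_maps[[k]] <- reg
  }
  list(cls_maps = cls_maps, ctr_maps = ctr_maps, reg_maps = reg_maps)
}
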