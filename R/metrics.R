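# Evaluation metrics: macro-F1, AUC, mIoU and mAP@0.5.

macro_f1 <- function(pred, truth, classes = NULL) {
  if (is.matrix(pred)) pred <- max.col(t(pred)) - 1L
  if (is.null(classes)) classes <- sort(unique(c(pred, truth)))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

auc_metric <- function(scores, truth) {
  if (length(unique(truth)) < 2)
    stop("AUC is undefined for single-class truth")
  as.numeric(pROC::auc(pROC::roc(response = truth, predictor = as.numeric(scores),
                                 quiet = TRUE, direction = "<",
                                 levels = sort(unique(truth)))))
}

# pred/truth: lists of integer label masks (or single masks)
miou <- function(pred, truth) {
  if (!is.list(pred)) pred <- list(pred)
  if (!is.list(truth)) truth <- list(truth)
  p <- unlist(lapply(pred, as.integer))
  t <- unlist(lapply(truth, as.integer))
  classes <- sort(unique(c(p, t)))
  ious <- vapply(classes, function(cl) {
    inter <- sum(p == cl & t == cl)
    uni <- sum(p == cl | t == cl)
    if (uni == 0) return(NA_real_)
    inter / uni
  }, numeric(1))
  mean(ious, na.rm = TRUE)
}

# Average precision with 101-point interpolation at a fixed IoU threshold.
# detections: list per image of data.frame(class_id, score, x0, y0, x1, y1)
# truths: list per image of data.frame(class_id, x0, y0, x1, y1)
map50 <- function(detections, truths, iou_thr = 0.5) {
  classes <- sort(unique(unlist(lapply(truths, function(t)
    if (nrow(t)) t$class_id else integer(0)))))
  if (!length(classes)) return(NA_real_)
  aps <- vapply(classes, function(cl) {
    recs <- list()
    npos <- 0
    for (i in seq_along(truths)) {
      gt <- truths[[i]][truths[[i]]$class_id == cl, , drop = FALSE]
      dt <- detections[[i]][detections[[i]]$class_id == cl, , drop = FALSE]
      npos <- npos + nrow(gt)
      if (!nrow(dt)) next
      dt <- dt[order(dt$score, decreasing = TRUE), , drop = FALSE]
      matched <- rep(FALSE, nrow(gt))
      tp <- logical(nrow(dt))
      for (j in seq_len(nrow(dt))) {
        if (!nrow(gt)) break
        ious <- box_iou_matrix(as.matrix(dt[j, c("x0", "y0", "x1", "y1")]),
                               as.matrix(gt[, c("x0", "y0", "x1", "y1")]))[1, ]
        best <- which.max(ious)
        if (ious[best] >= iou_thr && !matched[best]) {
          tp[j] <- TRUE
          matched[best] <- TRUE
        }
      }
      recs[[length(recs) + 1L]] <- data.frame(score = dt$score, tp = tp)
    }
    if (npos == 0) return(NA_real_)
    if (!length(recs)) return(0)
    all <- do.call(rbind, recs)
    all <- all[order(all$score, decreasing = TRUE), , drop = FALSE]
    ctp <- cumsum(all$tp)
    prec <- ctp / seq_len(nrow(all))
    rec <- ctp / npos
    # 101-point interpolated AP
    rp <- seq(0, 1, by = 0.01)
    ap <- mean(vapply(rp, function(r) {
      sel <- rec >= r
      if (!any(sel)) 0 else max(prec[sel])
    }, numeric(1)))
    ap
  }, numeric(1))
  mean(aps, na.rm = TRUE)
}

#' Evaluate predictions against ground truth
#'
#' Standard metric definitions: `macro_f1` (unweighted mean of per-class F1),
#' `auc` (ROC area, binary truth required), `miou` (mean over classes of
#' intersection-over-union across all pixels), `map50` (detection mean
#' average precision at IoU 0.5 with 101-point interpolation).
#'
#' @param predictions labels, scores, masks or per-image detection frames
#'   depending on the metric.
#' @param truth matching ground truth.
#' @param metric one of `"macro_f1"`, `"auc"`, `"miou"`, `"map50"`.
#' @return scalar metric value.
#' @export
evaluate <- function(predictions, truth, metric = c("macro_f1", "auc", "miou", "map50")) {
  metric <- match.arg(metric)
  switch(metric,
         macro_f1 = macro_f1(predictions, truth),
         auc = auc_metric(predictions, truth),
         miou = miou(predictions, truth),
         map50 = map50(predictions, truth))
}
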