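#' @name metrics
#' @title Confusion-matrix evaluation metrics
#' @description
#' Per-image Dice, IoU, precision and recall from pixel confusion counts,
#' and their dataset-level per-image means (mDice, mIoU, Recall, Precision).
NULL

#' Pixel confusion counts
#'
#' @param pred probability (or binary) map.
#' @param gt binary ground-truth map of the same shape.
#' @param threshold binarization threshold; predictions `>= threshold`
#'   count as foreground.
#' @return list of class `confusionCounts` with `tp`, `tn`, `fp`, `fn`.
#' @export
confusionCounts <- function(pred, gt, threshold = 0.5) {
  if (length(pred) != length(gt)) stop("shape mismatch between pred and gt")
  p <- as.vector(pred) >= threshold
  y <- as.vector(gt) >= 0.5
  structure(list(tp = sum(p & y), tn = sum(!p & !y),
                 fp = sum(p & !y), fn = sum(!p & y)),
            class = "confusionCounts")
}

#' Scores from confusion counts
#'
#' Dice `2TP/(2TP+FP+FN)`, IoU `TP/(TP+FP+FN)`, precision `TP/(TP+FP)`,
#' recall `TP/(TP+FN)`. Degenerate cases: an empty ground truth with an
#' empty prediction scores 1 on all four; an empty ground truth with false
#' positives scores 0 on dice/iou/precision and 1 on recall (configurable).
#'
#' @param c a [confusionCounts()] (or list with tp/tn/fp/fn).
#' @param emptyScore score assigned when both prediction and ground truth
#'   are empty.
#' @return list with `dice`, `iou`, `precision`, `recall`.
#' @export
confusionScores <- function(c, emptyScore = 1) {
  tp <- c$tp; fp <- c$fp; fn <- c$fn
  if (tp + fp + fn == 0) {
    return(list(dice = emptyScore, iou = emptyScore,
                precision = emptyScore, recall = emptyScore))
  }
  list(dice = 2 * tp / (2 * tp + fp + fn),
       iou = tp / (tp + fp + fn),
       precision = if (tp + fp > 0) tp / (tp + fp) else 0,
       recall = if (tp + fn > 0) tp / (tp + fn) else 1)
}

#' Aggregate per-image scores
#'
#' Arithmetic per-image mean of each metric (the macro average used for
#' mDice / mIoU), or the micro average over pooled confusion counts.
#'
#' @param perImage list of per-image score lists (from [confusionScores()]),
#'   or, for `micro = TRUE`, of [confusionCounts()].
#' @param micro pool pixel counts before scoring instead of averaging
#'   per-image scores.
#' @return list with `dice`, `iou`, `precision`, `recall`.
#' @export
aggregateScores <- function(perImage, micro = FALSE) {
  if (length(perImage) == 0L) stop("empty score list")
  if (micro) {
    tot <- list(tp = 0, tn = 0, fp = 0, fn = 0)
    for (c in perImage) for (k in names(tot)) tot[[k]] <- tot[[k]] + c[[k]]
    return(confusionScores(tot))
  }
  keys <- c("dice", "iou", "precision", "recall")
  out <- lapply(keys, function(k) {
    mean(vapply(perImage, function(s) s[[k]], numeric(1)))
  })
  names(out) <- keys
  out
}

#' Write a metrics report
#'
#' One row per image plus a final aggregate row, as tab-separated text.
#'
#' @param perImage list of per-image score lists.
#' @param path output file.
#' @param ids optional image identifiers.
#' @return the report data frame, invisibly.
#' @export
writeMetricsReport <- function(perImage, path, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("image_%03d", seq_along(perImage))
  rows <- do.call(rbind, lapply(seq_along(perImage), function(i) {
    s <- perImage[[i]]
    data.frame(id = ids[i], dice = s$dice, iou = s$iou,
               precision = s$precision, recall = s$recall)
  }))
  agg <- aggregateScores(perImage)
  rows <- rbind(rows, data.frame(id = "aggregate", dice = agg$dice,
                                 iou = agg$iou, precision = agg$precision,
                                 recall = agg$recall))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(rows)
}
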