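metric_triplet <- function(TP, FP, FN, both_empty_f1 = 1) {
  P <- if (TP + FP == 0) 1 else TP / (TP + FP)
  R <- if (TP + FN == 0) 1 else TP / (TP + FN)
  F1 <- if (TP + FP == 0 && TP + FN == 0) both_empty_f1
    else if (P + R == 0) 0 else 2 * P * R / (P + R)
  c(precision = P, recall = R, f1 = F1)
}

#' Pair-level structure prediction metrics
#'
#' True positives are exact `(i, j)` tuple matches — no one-position slip
#' tolerance. Degenerate conventions (documented and frozen): precision is
#' 1 when nothing is predicted, recall is 1 when the reference is
#' unpaired, F1 is 1 when both structures are empty and 0 when exactly one
#' is.
#'
#' @param pred,truth `secondary_structure`s over the same length.
#' @return named vector `precision`, `recall`, `f1` plus the counts `TP`,
#'   `FP`, `FN`.
#' @export
pair_metrics <- function(pred, truth) {
  if (pred$length != truth$length) {
    fb_stop("structures have different lengths", "fb_consistency_error")
  }
  key <- function(ss) if (NROW(ss$pairs) == 0L) character(0)
    else paste(ss$pairs[, 1L], ss$pairs[, 2L])
  kp <- key(pred); kt <- key(truth)
  TP <- sum(kp %in% kt)
  FP <- length(kp) - TP
  FN <- length(kt) - TP
  c(metric_triplet(TP, FP, FN), TP = TP, FP = FP, FN = FN)
}

#' Position-level labeling metrics
#'
#' Confusion matrix over per-position paired/unpaired labels and the same
#' precision/recall/F1 formulas as the pair-level metrics. When both
#' tracks are all-zero the F1 is 1 by convention.
#'
#' @param pred_track,truth_track binary vectors of equal length.
#' @return named vector `precision`, `recall`, `f1`, `TP`, `FP`, `FN`,
#'   `TN`.
#' @export
label_metrics <- function(pred_track, truth_track) {
  if (length(pred_track) != length(truth_track)) {
    fb_stop("tracks have different lengths", "fb_consistency_error")
  }
  p <- as.integer(pred_track)
  t <- as.integer(truth_track)
  TP <- sum(p == 1L & t == 1L); FP <- sum(p == 1L & t == 0L)
  FN <- sum(p == 0L & t == 1L); TN <- sum(p == 0L & t == 0L)
  c(metric_triplet(TP, FP, FN), TP = TP, FP = FP, FN = FN, TN = TN)
}

#' Unanimity consensus labeling baseline
#'
#' Labels a position paired only when all six ensemble members agree on
#' the pairing existence — the elementwise AND of the tracks.
#'
#' @param tracks list of six binary tracks of equal length.
#' @return binary integer vector.
#' @export
consensus_labels <- function(tracks) {
  if (length(tracks) == 0L || length(unique(lengths(tracks))) != 1L) {
    fb_stop("tracks must be non-empty and of equal length",
            "fb_consistency_error")
  }
  as.integer(Reduce(`&`, lapply(tracks, function(t) t == 1L)))
}

#' League-table summary of per-RNA F1 scores
#'
#' For each test set: the median F1 per tool over its RNAs, and the tool's
#' rank by descending median (ties share the better rank: rank = 1 +
#' number of strictly better tools). Per tool across sets: the median of
#' its per-set ranks and the median of its per-set median F1s. Tools with
#' no scores for a set are omitted from that set's ranking.
#'
#' @param scores data.frame with columns `tool`, `set`, `f1` (one row per
#'   RNA).
#' @return list with `per_set` (data.frame: tool, set, median_f1, rank)
#'   and `overall` (data.frame: tool, overall_median_f1, median_rank).
#' @export
league_table <- function(scores) {
  stopifnot(all(c("tool", "set", "f1") %in% names(scores)))
  agg <- aggregate(f1 ~ tool + set, data = scores, FUN = median)
  names(agg)[names(agg) == "f1"] <- "median_f1"
  agg <- agg[order(agg$set, -agg$median_f1, agg$tool), ]
  agg$rank <- unlist(lapply(split(agg$median_f1, agg$set), function(v)
    vapply(v, function(x) 1L + sum(v > x), 1L)), use.names = FALSE)
  overall <- do.call(rbind, lapply(split(agg, agg$tool), function(d)
    data.frame(tool = d$tool[1L],
               overall_median_f1 = median(d$median_f1),
               median_rank = median(d$rank))))
  overall <- overall[order(overall$median_rank,
                           -overall$overall_median_f1), ]
  rownames(agg) <- rownames(overall) <- NULL
  list(per_set = agg, overall = overall)
}
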