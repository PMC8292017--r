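#' Scale detection scores to the unit interval
#'
#' Affine map sending the minimum to 0 and the maximum to 1; rank order is
#' preserved. A constant score vector maps to all zeros with a warning.
#'
#' @param scores numeric scores.
#' @return scaled scores in \[0, 1\].
#' @export
scale_scores <- function(scores) {
  rng <- range(scores, na.rm = TRUE)
  if (rng[1] == rng[2]) {
    warning("constant scores; mapping all to 0")
    return(rep(0, length(scores)))
  }
  (scores - rng[1]) / (rng[2] - rng[1])
}

#' Evaluation set container
#'
#' Aligned per-segment scores and binary labels plus the audio duration they
#' represent. PARTIAL segments are excluded from metric computation by
#' default (they are neither clean positives nor clean negatives); set
#' `partial_as` to fold them into a class instead.
#'
#' @param scores per-segment detection scores (NA scores are dropped).
#' @param labels per-segment states (`"POSITIVE"`/`"NEGATIVE"`/`"PARTIAL"`)
#'   or binary 0/1.
#' @param hours audio duration represented (> 0).
#' @param partial_as `"exclude"` (default), `"negative"` or `"positive"`.
#' @return an `evaluation_set` list with binary `labels`.
#' @export
evaluation_set <- function(scores, labels, hours,
                           partial_as = c("exclude", "negative", "positive")) {
  partial_as <- match.arg(partial_as)
  stopifnot(length(scores) == length(labels), hours > 0)
  if (is.character(labels)) {
    keep <- rep(TRUE, length(labels))
    if (partial_as == "exclude") keep <- labels != "PARTIAL"
    y <- as.integer(labels == "POSITIVE")
    if (partial_as == "positive") y[labels == "PARTIAL"] <- 1L
    scores <- scores[keep]; y <- y[keep]
  } else y <- as.integer(labels)
  ok <- !is.na(scores)
  structure(list(scores = scores[ok], labels = y[ok], hours = hours),
            class = "evaluation_set")
}

#' Confusion counts at a threshold
#'
#' Predictions are positive iff `score >= t`.
#'
#' @param set an [evaluation_set()].
#' @param t threshold.
#' @return named vector `c(TP, FP, FN, TN)`; counts sum to the set size.
#' @export
confusion_at_threshold <- function(set, t) {
  pred <- set$scores >= t
  y <- set$labels == 1
  c(TP = sum(pred & y), FP = sum(pred & !y),
    FN = sum(!pred & y), TN = sum(!pred & !y))
}

#' Class-prior calibrated precision
#'
#' Recall `r = TP/(TP+FN)` and false-positive rate `f = FP/(FP+TN)` are
#' measured on the evaluation set; precision is then re-expressed at a
#' reference positive-class prior `pi`:
#' `precision_cal = pi * r / (pi * r + (1 - pi) * f)`.
#' Recall is unchanged by calibration, and at the set's own empirical prior
#' the calibrated precision equals the raw precision.
#'
#' @param TP,FP,FN,TN confusion counts.
#' @param target_prior reference positive-class proportion in (0, 1).
#' @return list with `precision_cal`, `recall`, `fpr`; degenerate margins
#'   (no positives or no negatives in the set) yield `NA` markers rather
#'   than errors.
#' @export
calibrate_counts <- function(TP, FP, FN, TN, target_prior) {
  stopifnot(target_prior > 0, target_prior < 1)
  if (TP + FN == 0 || FP + TN == 0)
    return(list(precision_cal = NA_real_, recall = NA_real_, fpr = NA_real_))
  r <- TP / (TP + FN)
  f <- FP / (FP + TN)
  denom <- target_prior * r + (1 - target_prior) * f
  p_cal <- if (denom == 0) NA_real_ else target_prior * r / denom
  list(precision_cal = p_cal, recall = r, fpr = f)
}

#' Precision-recall curve over all score thresholds
#'
#' Thresholds are the distinct scores in descending order. With a
#' `target_prior`, precision is prior-calibrated via [calibrate_counts()];
#' recall is identical either way.
#'
#' @param set an [evaluation_set()] (scores already scaled to \[0, 1\] by
#'   convention).
#' @param target_prior optional reference positive-class prior.
#' @return a `pr_curve` data-frame-like object with columns `threshold`
#'   (descending), `precision`, `recall`, plus attributes `calibrated` and
#'   `target_prior`. A single-class set returns `NULL` (undefined-metric
#'   marker).
#' @export
pr_curve <- function(set, target_prior = NULL) {
  y <- set$labels
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) return(NULL)
  ord <- order(set$scores, decreasing = TRUE)
  s <- set$scores[ord]; yy <- y[ord]
  cum_tp <- cumsum(yy == 1)
  cum_fp <- cumsum(yy == 0)
  last <- !duplicated(s, fromLast = TRUE)   # last occurrence of each distinct score
  thr <- s[last]
  TP <- cum_tp[last]; FP <- cum_fp[last]
  recall <- TP / n_pos
  if (!is.null(target_prior)) {
    fpr <- FP / n_neg
    denom <- target_prior * recall + (1 - target_prior) * fpr
    precision <- ifelse(denom == 0, NA_real_, target_prior * recall / denom)
  } else {
    precision <- TP / (TP + FP)
  }
  out <- data.frame(threshold = thr, precision = precision, recall = recall)
  attr(out, "calibrated") <- !is.null(target_prior)
  attr(out, "target_prior") <- target_prior
  class(out) <- c("pr_curve", "data.frame")
  out
}

#' Area under the precision-recall curve
#'
#' Step-wise (average-precision) rule: the sum over descending thresholds of
#' `(recall_i - recall_{i-1}) * precision_i`. Invariant under strictly
#' monotone transforms of the scores.
#'
#' @param curve a [pr_curve()] result.
#' @return scalar area, or `NA` for a `NULL` (single-class) curve.
#' @export
auc_pr <- function(curve) {
  if (is.null(curve)) return(NA_real_)
  dr <- diff(c(0, curve$recall))
  sum(dr * ifelse(is.na(curve$precision), 0, curve$precision))
}

#' Peak F1 score along a precision-recall curve
#'
#' @param curve a [pr_curve()] result.
#' @return list with `f1` (max over thresholds of `2pr/(p+r)`) and
#'   `threshold` (ties broken toward the higher threshold).
#' @export
peak_f1 <- function(curve) {
  if (is.null(curve)) return(list(f1 = NA_real_, threshold = NA_real_))
  f1 <- 2 * curve$precision * curve$recall /
    pmax(curve$precision + curve$recall, 1e-300)
  f1[is.na(f1)] <- 0
  best <- which.max(f1)   # thresholds are descending; first max = highest t
  list(f1 = f1[best], threshold = curve$threshold[best])
}

#' False positives per hour of audio
#'
#' @param set an [evaluation_set()] with its `hours` field set.
#' @param t detection threshold.
#' @return false-positive detections divided by hours.
#' @export
fp_per_hour <- function(set, t) {
  unname(confusion_at_threshold(set, t)["FP"] / set$hours)
}

#' Recall as a function of the preceding inter-note interval
#'
#' Each annotated note except the first of its recording is assigned the INI
#' that precedes it; notes are binned by that INI and per-bin recall is the
#' fraction of notes detected at the threshold. A note counts as detected
#' when at least one scored segment fully containing it reaches the
#' threshold.
#'
#' @param detections a [detect_stream()]-style data frame with
#'   `segment_start_s` and `score` for one recording.
#' @param annotations the recording's [note_annotations()].
#' @param threshold detection threshold.
#' @param ini_bins numeric bin edges for the INI axis (s).
#' @param segment_duration_s segment length used for containment (s).
#' @param score_col which score column to use.
#' @return data frame with `bin_low`, `bin_high`, `n_notes`, `n_detected`,
#'   `recall` (`NA` recall marks an empty bin). Notes none of whose
#'   containing segments carry a score (e.g. inside the leading span a
#'   context-window detector cannot reach) are outside the evaluable region
#'   and are not counted.
#' @export
recall_by_ini <- function(detections, annotations, threshold, ini_bins,
                          segment_duration_s = 4, score_col = "score") {
  ord <- order(annotations$begin_s)
  ann <- annotations[ord, , drop = FALSE]
  inis <- compute_inis(ann)
  n_bins <- length(ini_bins) - 1
  out <- data.frame(bin_low = ini_bins[-length(ini_bins)],
                    bin_high = ini_bins[-1], n_notes = 0L, n_detected = 0L)
  if (nrow(inis) > 0) {
    for (j in seq_len(nrow(inis))) {
      note <- ann[inis$to_idx[j], ]
      bin <- findInterval(inis$value_s[j], ini_bins,
                          rightmost.closed = TRUE)
      if (bin < 1 || bin > n_bins) next
      starts <- detections$segment_start_s
      contains <- starts <= note$begin_s &
        note$end_s <= starts + segment_duration_s
      sc <- detections[[score_col]][contains]
      if (!any(!is.na(sc))) next         # outside the evaluable region
      detected <- any(!is.na(sc) & sc >= threshold)
      out$n_notes[bin] <- out$n_notes[bin] + 1L
      out$n_detected[bin] <- out$n_detected[bin] + as.integer(detected)
    }
  }
  out$recall <- ifelse(out$n_notes > 0, out$n_detected / out$n_notes, NA_real_)
  out
}

#' Aggregate per-fold precision-recall curves
#'
#' Interpolates each curve's precision onto a common recall grid (step
#' interpolation, matching the step-wise area rule) and takes the pointwise
#' median, as used to summarize cross-validated detectors.
#'
#' @param curves list of [pr_curve()] results.
#' @param recall_grid common recall grid.
#' @return data frame with `recall` and median `precision`.
#' @export
aggregate_folds <- function(curves, recall_grid = seq(0, 1, by = 0.01)) {
  stopifnot(length(curves) >= 1)
  pmat <- vapply(curves, function(cv) {
    # precision at the smallest threshold achieving recall >= r
    stats::approx(cv$recall, cv$precision, xout = recall_grid,
                  method = "constant", f = 1, rule = 2,
                  ties = list("ordered", min))$y
  }, numeric(length(recall_grid)))
  data.frame(recall = recall_grid,
             precision = apply(as.matrix(pmat), 1, stats::median))
}
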