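#' ROC AUC (Mann-Whitney form)
#'
#' Probability that a randomly chosen presence receives a higher score
#' than a randomly chosen background point, ties counted one half.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels (1 = presence), same length.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.7, 0.7, 0.2), c(1, 1, 0, 0))  # 0.875
roc_auc <- function(scores, labels) {
  check_two_classes(labels)
  r <- rank(scores, ties.method = "average")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

check_two_classes <- function(labels) {
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  if (length(unique(labels)) < 2) {
    stop("both classes must be present for this metric", call. = FALSE)
  }
  invisible(TRUE)
}

# 2x2 cells for prediction = score >= t
binary_cells <- function(scores, labels, t) {
  pred <- as.integer(scores >= t)
  c(tp = sum(pred == 1 & labels == 1),
    fp = sum(pred == 1 & labels == 0),
    fn = sum(pred == 0 & labels == 1),
    tn = sum(pred == 0 & labels == 0))
}

#' True skill statistic at a threshold
#'
#' `sensitivity + specificity - 1` for the binarization
#' `prediction = score >= t` (Youden's J; prevalence-insensitive).
#'
#' @inheritParams roc_auc
#' @param t Classification threshold.
#' @return TSS in `[-1, 1]`.
#' @export
tss_at_threshold <- function(scores, labels, t) {
  check_two_classes(labels)
  cells <- binary_cells(scores, labels, t)
  sens <- cells["tp"] / (cells["tp"] + cells["fn"])
  spec <- cells["tn"] / (cells["tn"] + cells["fp"])
  unname(sens + spec - 1)
}

#' Threshold maximizing the TSS
#'
#' Scans midpoints between consecutive sorted unique scores (plus one
#' candidate below the minimum and one above the maximum) and returns the
#' threshold with the highest TSS; the smallest such threshold on ties.
#' This is the conventional threshold choice for presence-background
#' binarization when no operational cutoff is prescribed.
#'
#' @inheritParams roc_auc
#' @return A list with `threshold` and `tss`.
#' @export
#' @examples
#' max_tss_threshold(c(0.1, 0.4, 0.6, 0.9), c(0, 0, 1, 1))$threshold  # 0.5
max_tss_threshold <- function(scores, labels) {
  check_two_classes(labels)
  u <- sort(unique(scores))
  cand <- if (length(u) == 1) u else (u[-length(u)] + u[-1]) / 2
  cand <- c(u[1] - 1, cand, u[length(u)] + 1)
  tss <- vapply(cand, function(t) tss_at_threshold(scores, labels, t),
                numeric(1))
  best <- which(tss >= max(tss) - 1e-15)[1]   # smallest threshold on ties
  list(threshold = cand[best], tss = tss[best])
}

#' Cohen's kappa at a threshold
#'
#' Binarizes the scores at `t` and applies the confusion-matrix kappa
#' shared with the land-cover accuracy assessment
#' ([kappa_coefficient()]).
#'
#' @inheritParams tss_at_threshold
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa_at_threshold <- function(scores, labels, t) {
  check_two_classes(labels)
  cells <- binary_cells(scores, labels, t)
  cm <- rbind(c(cells["tp"], cells["fn"]),
              c(cells["fp"], cells["tn"]))
  kappa_coefficient(confusion_matrix(cm, labels = c("presence", "background")))
}

#' Continuous Boyce index
#'
#' Presence-only calibration statistic: over overlapping suitability
#' windows spanning `[0, 1]`, the predicted-to-expected ratio
#' P/E = (fraction of presences in window) / (fraction of background in
#' window) is computed, and the Boyce index is the Spearman rank
#' correlation between window midpoints and P/E. Windows with zero
#' expected (background) fraction are skipped. A well-calibrated model
#' yields P/E increasing with suitability, hence an index near +1.
#'
#' Defaults follow the continuous (moving-window) form with a fine window:
#' 196 windows of width 0.025, stepped by 0.005 across `[0, 1]`. The narrow
#' window keeps adjacent P/E ratios nearly independent, so the index stays
#' close to zero for uncalibrated (null) models; wide windows (e.g. 0.1)
#' autocorrelate neighbouring ratios and inflate the null variance of the
#' rank correlation.
#'
#' @param presence_suit Suitability values at presence points.
#' @param background_suit Suitability values at background points.
#' @param n_windows Number of overlapping windows.
#' @param window_width Width of each window on the suitability axis.
#' @return Boyce index in `[-1, 1]`.
#' @export
boyce_index <- function(presence_suit, background_suit,
                        n_windows = 196, window_width = 0.025) {
  if (n_windows < 2) stop("need at least 2 windows", call. = FALSE)
  starts <- seq(0, 1 - window_width, length.out = n_windows)
  mids <- starts + window_width / 2
  pe <- rep(NA_real_, n_windows)
  for (i in seq_len(n_windows)) {
    lo <- starts[i]
    hi <- starts[i] + window_width
    p <- mean(presence_suit >= lo & presence_suit <= hi)
    e <- mean(background_suit >= lo & background_suit <= hi)
    if (e > 0) pe[i] <- p / e
  }
  ok <- !is.na(pe)
  if (sum(ok) < 2) {
    stop("fewer than 2 windows with a defined P/E ratio", call. = FALSE)
  }
  stats::cor(mids[ok], pe[ok], method = "spearman")
}

#' Evaluate a scorer on a labelled test set
#'
#' Convenience wrapper producing the full score card used for gating:
#' ROC AUC plus TSS and kappa at the max-TSS threshold.
#'
#' @inheritParams roc_auc
#' @return A one-row data.frame: `roc`, `tss`, `kappa`, `threshold_used`.
#' @export
eval_scores <- function(scores, labels) {
  mt <- max_tss_threshold(scores, labels)
  data.frame(
    roc = roc_auc(scores, labels),
    tss = mt$tss,
    kappa = cohen_kappa_at_threshold(scores, labels, mt$threshold),
    threshold_used = mt$threshold
  )
}

#' Column summaries of an evaluation report
#'
#' Unweighted mean and standard error (sd / sqrt(n)) of each numeric
#' metric column across species rows, the summary row conventionally
#' printed under per-species evaluation tables.
#'
#' @param report Data.frame with one row per species and numeric metric
#'   columns.
#' @return A data.frame with columns `metric`, `mean`, `se`.
#' @export
#' @examples
#' summarize_evaluation(evaluation_scores_fixture())
summarize_evaluation <- function(report) {
  if (nrow(report) < 1) stop("empty evaluation report", call. = FALSE)
  num <- vapply(report, is.numeric, logical(1))
  cols <- names(report)[num]
  if (!length(cols)) stop("no numeric metric columns", call. = FALSE)
  data.frame(
    metric = cols,
    mean = vapply(report[cols], mean, numeric(1)),
    se = vapply(report[cols], function(x) {
      if (length(x) < 2) 0 else stats::sd(x) / sqrt(length(x))
    }, numeric(1)),
    row.names = NULL
  )
}
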