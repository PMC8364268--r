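#' @include mqp.R
NULL

#' Classify one plan against its clinical ground truth
#'
#' For a positive plan (re-CT was, or should have been, ordered) the alert
#' must fall within ± `window_fractions` treatment fractions (inclusive) of
#' the re-CT decision fraction to count as a true positive; otherwise the
#' plan is a false negative — including when the only alert fired before
#' the window. For a negative plan any alert at any time is a false
#' positive, no alert a true negative. The unit of classification is the
#' plan (re-plans are separate plans with their own series).
#'
#' @param alert the plan's first [AlertEvent-class], or `NULL` for no alert.
#' @param label `"positive"` or `"negative"`.
#' @param rect_fraction re-CT decision fraction (required for positives).
#' @param window_fractions half-width of the timing window (default 3).
#' @return one of `"TP"`, `"TN"`, `"FP"`, `"FN"`.
#' @export
classifyCase <- function(alert, label, rect_fraction = NA,
                         window_fractions = 3) {
  stopifnot(label %in% c("positive", "negative"))
  if (label == "positive") {
    if (is.na(rect_fraction))
      stopPrecond("positive case requires rect_fraction")
    if (!is.null(alert) &&
        abs(triggerFraction(alert) - rect_fraction) <= window_fractions)
      "TP" else "FN"
  } else {
    if (is.null(alert)) "TN" else "FP"
  }
}

#' Classify a cohort of plans
#'
#' @param alerts named list (by `plan_id`) of first [AlertEvent-class]
#'   objects or `NULL`s, as returned by [detectAlert()].
#' @param cases data.frame of case annotations with columns `plan_id`,
#'   `label`, `rect_fraction` (see [readCaseAnnotations()]).
#' @param window_fractions timing window half-width.
#' @return named character vector of TP/TN/FP/FN, one per plan.
#' @export
classifyCases <- function(alerts, cases, window_fractions = 3) {
  out <- vapply(seq_len(nrow(cases)), function(r) {
    pid <- cases$plan_id[r]
    classifyCase(alerts[[pid]], cases$label[r], cases$rect_fraction[r],
                 window_fractions)
  }, character(1))
  names(out) <- cases$plan_id
  out
}

#' Summarise TP/TN/FP/FN classifications
#'
#' Sensitivity is TP/(TP+FN) and the false positive rate FP/(FP+TN), kept
#' at full precision (display rounds half-up to 2 decimals). With no
#' positive plans the sensitivity is undefined and returned as `NA` with a
#' warning (never 0); likewise the FPR with no negatives.
#'
#' @param classifications character vector of `"TP"`, `"TN"`, `"FP"`,
#'   `"FN"` (one per plan), or a named vector/list of the four counts.
#' @return a [ConfusionSummary-class].
#' @examples
#' s <- confusionSummary(c(tp = 26, tn = 37, fp = 22, fn = 8))
#' roundHalfUp(sensitivity(s), 2)        # 0.76
#' roundHalfUp(falsePositiveRate(s), 2)  # 0.37
#' @export
confusionSummary <- function(classifications) {
  if (!is.null(names(classifications)) &&
      all(c("tp", "tn", "fp", "fn") %in% tolower(names(classifications)))) {
    cc <- as.numeric(classifications)
    names(cc) <- tolower(names(classifications))
    tp <- cc[["tp"]]; tn <- cc[["tn"]]; fp <- cc[["fp"]]; fn <- cc[["fn"]]
  } else {
    if (length(classifications) == 0)
      stopPrecond("no classifications supplied")
    bad <- setdiff(unique(classifications), c("TP", "TN", "FP", "FN"))
    if (length(bad))
      stopPrecond("unknown classification label(s): ",
                  paste(bad, collapse = ", "))
    tp <- sum(classifications == "TP"); tn <- sum(classifications == "TN")
    fp <- sum(classifications == "FP"); fn <- sum(classifications == "FN")
  }
  sens <- if (tp + fn == 0) {
    warning("no positive plans: sensitivity undefined (NA)")
    NA_real_
  } else tp / (tp + fn)
  fpr <- if (fp + tn == 0) {
    warning("no negative plans: false positive rate undefined (NA)")
    NA_real_
  } else fp / (fp + tn)
  new("ConfusionSummary", tp = as.integer(tp), tn = as.integer(tn),
      fp = as.integer(fp), fn = as.integer(fn), sensitivity = sens,
      false_positive_rate = fpr)
}

#' ROC scan over alert threshold and failed-percentile x
#'
#' Re-runs the alert trigger and classification for every (threshold, x)
#' pair. Percentile gamma values are recomputed from the stored failed-voxel
#' values of each [CourseComparison-class]; no gamma maps are recomputed.
#' The default threshold grid is -0.30 to 0 in steps of 0.01 plus every
#' observed MQP value (so no vertex of the step-function ROC is missed).
#'
#' The scan scores a positive plan as detected when an alert fires at any
#' time (and a negative as a false positive likewise), so both sensitivity
#' and false positive rate are guaranteed non-increasing as the threshold
#' decreases. The clinical ±window timing rule of [classifyCase()] applies
#' to operating-point confusion summaries, not to the ROC sweep: timing
#' misses would make the sweep non-monotone at loose thresholds, where
#' every course triggers on its first few acquisitions.
#'
#' @param comparisons named list (by `plan_id`) of
#'   [CourseComparison-class] objects covering every plan in `cases`.
#' @param cases case-annotation data.frame (see [readCaseAnnotations()]).
#' @param thresholds numeric vector of MQP thresholds, or `NULL` for the
#'   default grid.
#' @param xs percentiles to scan (default 80).
#' @param consecutive_required alert run length (default 3).
#' @return data.frame with columns `threshold`, `x`,
#'   `false_positive_rate`, `sensitivity`, `tp`, `tn`, `fp`, `fn`.
#' @export
rocScan <- function(comparisons, cases, thresholds = NULL, xs = 80,
                    consecutive_required = 3) {
  if (is.null(names(comparisons)))
    names(comparisons) <- vapply(comparisons, planId, character(1))
  missing <- setdiff(cases$plan_id, names(comparisons))
  if (length(missing))
    stopPrecond("no comparison for plan(s): ", paste(missing, collapse = ", "))
  rows <- list()
  for (x in xs) {
    series <- lapply(comparisons[cases$plan_id], mqpSeries, x = x)
    names(series) <- cases$plan_id
    thr <- thresholds
    if (is.null(thr)) {
      observed <- unlist(lapply(series, function(s) s@entries$mqp))
      thr <- sort(unique(c(seq(-0.30, 0, by = 0.01), observed)))
    }
    for (t in thr) {
      cfg <- alertConfig(threshold = t,
                         consecutive_required = consecutive_required)
      alerts <- lapply(series, detectAlert, config = cfg)
      detected <- !vapply(alerts, is.null, logical(1))
      cls <- ifelse(cases$label == "positive",
                    ifelse(detected, "TP", "FN"),
                    ifelse(detected, "FP", "TN"))
      s <- suppressWarnings(confusionSummary(cls))
      rows[[length(rows) + 1L]] <-
        data.frame(threshold = t, x = x,
                   false_positive_rate = s@false_positive_rate,
                   sensitivity = s@sensitivity,
                   tp = s@tp, tn = s@tn, fp = s@fp, fn = s@fn)
    }
  }
  do.call(rbind, rows)
}

#' Four-quadrant timing audit: alert system versus therapist review requests
#'
#' Compares the alert system's timing with the radiation therapists' image
#' review requests using the same rules as classification: for positive
#' plans "+" means within the ± window of the re-CT fraction, for negative
#' plans "+" means any alert / any review request. Produces counts only.
#'
#' @param alerts named list of first [AlertEvent-class] or `NULL` per plan.
#' @param cases annotations including an `rt_review_fraction` column
#'   (`NA` = no review request).
#' @param window_fractions timing window half-width.
#' @return data.frame of counts by `label`, `alert` (+/-) and `rt` (+/-).
#' @export
timingAudit <- function(alerts, cases, window_fractions = 3) {
  flag <- function(frac, label, rect) {
    if (is.na(frac)) return("-")
    if (label == "negative") "+"
    else if (abs(frac - rect) <= window_fractions) "+" else "-"
  }
  al <- rt <- character(nrow(cases))
  for (r in seq_len(nrow(cases))) {
    pid <- cases$plan_id[r]
    a <- alerts[[pid]]
    al[r] <- flag(if (is.null(a)) NA else triggerFraction(a),
                  cases$label[r], cases$rect_fraction[r])
    rt[r] <- flag(cases$rt_review_fraction[r], cases$label[r],
                  cases$rect_fraction[r])
  }
  as.data.frame(table(label = cases$label, alert = al, rt = rt),
                responseName = "count")
}

# ---- case annotations -------------------------------------------------------

#' Read and write case annotations
#'
#' Tab-separated text with columns `plan_id`, `label`
#' (`positive`/`negative`), `rect_fraction` (re-CT decision fraction,
#' required for positives, `NA` otherwise), `positive_subtype`
#' (`actual_rect`, `retrospective_miss` or `too_late`) and optional
#' `rt_review_fraction`. Comment lines (`#`) may carry conventions, e.g.
#' the synthetic-cohort positivity rule.
#'
#' @param path file path.
#' @param cases data.frame in the same column layout.
#' @param comment optional comment line(s) written atop the file.
#' @return `readCaseAnnotations()` returns the data.frame.
#' @export
readCaseAnnotations <- function(path) {
  if (!file.exists(path)) stopFormat("annotations file not found: ", path)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("plan_id", "label", "rect_fraction")
  if (!all(need %in% names(df)))
    stopFormat("annotations need columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0) stopFormat("annotations file is empty: ", path)
  if (!all(df$label %in% c("positive", "negative")))
    stopFormat("labels must be positive/negative")
  bad <- df$label == "positive" & is.na(df$rect_fraction)
  if (any(bad))
    stopFormat("positive plan(s) without rect_fraction: ",
               paste(df$plan_id[bad], collapse = ", "))
  bad <- df$label == "negative" & !is.na(df$rect_fraction)
  if (any(bad))
    stopFormat("negative plan(s) must not carry rect_fraction: ",
               paste(df$plan_id[bad], collapse = ", "))
  if (!"rt_review_fraction" %in% names(df))
    df$rt_review_fraction <- NA_integer_
  if (!"positive_subtype" %in% names(df))
    df$positive_subtype <- NA_character_
  df
}

#' @rdname readCaseAnnotations
#' @export
writeCaseAnnotations <- function(cases, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  cols <- c("plan_id", "label", "rect_fraction", "positive_subtype",
            "rt_review_fraction")
  for (cl in setdiff(cols, names(cases))) cases[[cl]] <- NA
  write.table(cases[cols], con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
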