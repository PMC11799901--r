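#' Tolerance limits for PSQA verdicts
#'
#' Point metrics (ME and every DVH delta, in % of prescription) accept when
#' their absolute value is at most `point_metric_tolerance`; gamma accepts
#' when the pass rate is at least `gamma_pass_floor`.  Both boundaries are
#' inclusive.
#'
#' @param point_metric_tolerance tolerance in % (default 1).
#' @param gamma_pass_floor gamma pass-rate floor in % (default 90).
#' @return A `tolerance_set` list.
#' @export
tolerance_set <- function(point_metric_tolerance = 1, gamma_pass_floor = 90) {
  structure(list(point_metric_tolerance = point_metric_tolerance,
                 gamma_pass_floor = gamma_pass_floor),
            class = "tolerance_set")
}

#' Apply a tolerance to one metric value
#'
#' @param value metric value (point metric in %, or gamma pass rate in %).
#' @param metric_kind `"point_percent"` or `"gamma_rate"`.
#' @param tol a [tolerance_set()].
#' @return `"accept"` or `"reject"`.
#' @export
apply_tolerance <- function(value, metric_kind = c("point_percent",
                                                   "gamma_rate"),
                            tol = tolerance_set()) {
  metric_kind <- match.arg(metric_kind)
  ok <- if (metric_kind == "point_percent")
    abs(value) <= tol$point_metric_tolerance
  else value >= tol$gamma_pass_floor
  ifelse(ok, "accept", "reject")
}

#' Per-patient verdicts from a metric report table
#'
#' Applies the tolerance set to every PSQA metric column of a table of
#' [metric_report()] rows.
#'
#' @param reports data frame of metric-report rows.
#' @param tol a [tolerance_set()].
#' @return Long data frame: patient_id, reference, metric, value, decision.
#' @export
verdict_table <- function(reports, tol = tolerance_set()) {
  point_cols <- c(me_ptv = "me_ptv_pct", d2 = "delta_d2_pct",
                  d95 = "delta_d95_pct", d98 = "delta_d98_pct",
                  dmean = "delta_dmean_pct")
  rows <- list()
  for (m in names(point_cols)) {
    v <- reports[[point_cols[[m]]]]
    rows[[m]] <- data.frame(patient_id = reports$patient_id,
                            reference = reports$reference, metric = m,
                            value = v,
                            decision = apply_tolerance(v, "point_percent", tol))
  }
  if ("gamma_pass_pct" %in% names(reports) &&
      !all(is.na(reports$gamma_pass_pct))) {
    v <- reports$gamma_pass_pct
    rows$gamma <- data.frame(patient_id = reports$patient_id,
                             reference = reports$reference, metric = "gamma",
                             value = v,
                             decision = apply_tolerance(v, "gamma_rate", tol))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Confusion counts between QA verdicts and reference verdicts
#'
#' The positive event is "the sCT is accepted".  With the CT-based decision
#' as truth: TP = both accept, FN = QA rejects a truly acceptable sCT,
#' FP = QA accepts a truly failing sCT, TN = both reject.  Patients present
#' in only one list are an error unless listed in `excluded` (e.g. a QA
#' generator that automatically rejects artifact patients and produces no
#' sCT for them); excluded patients are dropped from the counts.
#'
#' @param reference_verdicts data frame with `patient_id` and `decision`
#'   (verdicts against CT, the ground truth).
#' @param qa_verdicts data frame with `patient_id` and `decision` (verdicts
#'   against a QA generator).
#' @param excluded patient ids legitimately absent from `qa_verdicts`.
#' @return A `confusion_counts` list: `tp`, `fn`, `fp`, `tn`, `n`,
#'   `excluded`.
#' @export
confusion <- function(reference_verdicts, qa_verdicts, excluded = integer(0)) {
  ref <- reference_verdicts[!reference_verdicts$patient_id %in% excluded, ]
  qa <- qa_verdicts[!qa_verdicts$patient_id %in% excluded, ]
  if (!setequal(ref$patient_id, qa$patient_id) ||
      anyDuplicated(ref$patient_id) || anyDuplicated(qa$patient_id))
    stop("reference and QA verdicts must cover the same patients exactly once")
  qa <- qa[match(ref$patient_id, qa$patient_id), ]
  ra <- ref$decision == "accept"
  qaa <- qa$decision == "accept"
  structure(list(tp = sum(qaa & ra), fn = sum(!qaa & ra),
                 fp = sum(qaa & !ra), tn = sum(!qaa & !ra),
                 n = nrow(ref), excluded = excluded),
            class = "confusion_counts")
}

#' Sensitivity and specificity of a QA generator
#'
#' `Sensitivity = TP / (TP + FN)`: the fraction of truly acceptable sCTs the
#' QA route also accepts.  When no positives exist the value is undefined
#' and reported as `NA`, never 0.  Specificity (`TN / (TN + FP)`) follows
#' the same rule.
#'
#' @param counts a [confusion()] result.
#' @return Fraction in [0, 1], or `NA` when undefined.
#' @export
sensitivity <- function(counts) {
  if (counts$tp + counts$fn == 0) return(NA_real_)
  counts$tp / (counts$tp + counts$fn)
}

#' @rdname sensitivity
#' @export
specificity <- function(counts) {
  if (counts$tn + counts$fp == 0) return(NA_real_)
  counts$tn / (counts$tn + counts$fp)
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d  FN %d  FP %d  TN %d (n = %d%s)\n",
              x$tp, x$fn, x$fp, x$tn, x$n,
              if (length(x$excluded)) paste0(", excluded ",
                                             length(x$excluded)) else ""))
  cat(sprintf("  sensitivity %.3f, specificity %s\n", sensitivity(x),
              format(specificity(x), digits = 3)))
  invisible(x)
}
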