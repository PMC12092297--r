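# Evaluation of validated longitudinal markers as sign-of-change predictors
# of symptom worsening versus improvement between two endpoint timepoints.

#' Compute endpoint-to-endpoint change records
#'
#' For each (participant, domain, feature) with both endpoints observed,
#' computes the symptom change `score(last) - score(first)` and the marker
#' change over the same window, and classifies each strictly:
#' worsening if the change is > 0, improvement if < 0, excluded if the
#' change is exactly 0 or an endpoint is missing. The default endpoints are
#' the first and last scheduled survey timepoints (one week and six months
#' post-enrolment under the default schedule).
#'
#' @param scores factor-score table.
#' @param panel aligned panel holding marker values.
#' @param endpoints length-2 vector of timepoint days; default
#'   `range(scores$timepoint_day)`.
#' @return `change_records` data frame with `delta_symptom`,
#'   `delta_marker`, `true_class`, `predicted_class` (predicted from the
#'   raw marker-change sign; direction handling for negatively associated
#'   markers is applied in [evaluate_markers()]).
#' @export
compute_changes <- function(scores, panel, endpoints = NULL) {
  days <- sort(unique(scores$timepoint_day))
  if (is.null(endpoints)) endpoints <- range(days)
  if (!all(endpoints %in% days))
    stop_("endpoints must be scheduled survey timepoints")
  e1 <- endpoints[1]; e2 <- endpoints[2]

  s1 <- scores[scores$timepoint_day == e1, c("participant_id", "domain", "score")]
  s2 <- scores[scores$timepoint_day == e2, c("participant_id", "domain", "score")]
  sm <- merge(s1, s2, by = c("participant_id", "domain"),
              suffixes = c("_first", "_last"))
  sm$delta_symptom <- sm$score_last - sm$score_first

  m1 <- panel[panel$timepoint_day == e1,
              c("participant_id", "domain", "feature", "marker_value")]
  m2 <- panel[panel$timepoint_day == e2,
              c("participant_id", "domain", "feature", "marker_value")]
  mm <- merge(unique(m1), unique(m2),
              by = c("participant_id", "domain", "feature"),
              suffixes = c("_first", "_last"))
  mm$delta_marker <- mm$marker_value_last - mm$marker_value_first

  rec <- merge(mm[c("participant_id", "domain", "feature", "delta_marker")],
               sm[c("participant_id", "domain", "delta_symptom")],
               by = c("participant_id", "domain"))
  rec$true_class <- change_class(rec$delta_symptom)
  rec$predicted_class <- change_class(rec$delta_marker)
  rec <- rec[order(rec$participant_id, rec$domain, rec$feature), ,
             drop = FALSE]
  rownames(rec) <- NULL
  class(rec) <- c("change_records", "data.frame")
  rec
}

change_class <- function(delta) {
  ifelse(is.na(delta), "excluded",
         ifelse(delta > 0, "worsening",
                ifelse(delta < 0, "improvement", "excluded")))
}

#' Confusion-matrix metrics for sign-of-change prediction
#'
#' Positive class is worsening. Records whose true or predicted class is
#' `excluded` are ignored. Any metric with a zero denominator is reported
#' missing rather than zero. Also reports the prevalence of worsening among
#' the scored records, which ties the metrics together through
#' `ppv = sens * pi / (sens * pi + (1 - spec) * (1 - pi))`.
#'
#' @param records a [compute_changes()] result (or any data frame with
#'   `true_class` and `predicted_class`).
#' @return list with counts `tp`, `fp`, `fn`, `tn`, metrics `sensitivity`,
#'   `specificity`, `ppv`, `npv`, and `prevalence`.
#' @export
confusion <- function(records) {
  keep <- records$true_class != "excluded" &
    records$predicted_class != "excluded"
  r <- records[keep, , drop = FALSE]
  if (nrow(r) == 0) stop_("no scored (non-excluded) records")
  tp <- sum(r$true_class == "worsening" & r$predicted_class == "worsening")
  fp <- sum(r$true_class == "improvement" & r$predicted_class == "worsening")
  fn <- sum(r$true_class == "worsening" & r$predicted_class == "improvement")
  tn <- sum(r$true_class == "improvement" & r$predicted_class == "improvement")
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       sensitivity = safe(tp, tp + fn),
       specificity = safe(tn, tn + fp),
       ppv = safe(tp, tp + fp),
       npv = safe(tn, tn + fn),
       prevalence = (tp + fn) / nrow(r),
       n_scored = nrow(r))
}

#' Evaluate validated longitudinal markers as change predictors
#'
#' One confusion-metrics row per validated longitudinal (feature, domain)
#' marker. For markers with a negative validated correlation the predicted
#' class is inverted (an increase in a negatively associated marker
#' predicts improvement) so that the reported metrics always refer to
#' predicting worsening.
#'
#' @param marker_table a [run_selection()] result.
#' @param records a [compute_changes()] result.
#' @return data frame mirroring the usual reporting layout: marker, domain,
#'   n and percent worsening, sensitivity, specificity, PPV, NPV.
#' @export
evaluate_markers <- function(marker_table, records) {
  val <- marker_table[marker_table$status == "validated" &
                        marker_table$association_type == "longitudinal", ,
                      drop = FALSE]
  out <- vector("list", nrow(val))
  if (nrow(val)) for (i in seq_len(nrow(val))) {
    rec <- records[records$feature == val$feature[i] &
                     records$domain == val$domain[i], , drop = FALSE]
    if (val$est_validation[i] < 0) {
      rec$predicted_class <- c(worsening = "improvement",
                               improvement = "worsening",
                               excluded = "excluded")[rec$predicted_class]
    }
    cm <- tryCatch(confusion(rec), error = function(e) NULL)
    out[[i]] <- data.frame(
      feature = val$feature[i], domain = val$domain[i],
      correlation = val$est_validation[i],
      n_worsening = if (is.null(cm)) NA_integer_ else cm$tp + cm$fn,
      pct_worsening = if (is.null(cm)) NA_real_ else 100 * cm$prevalence,
      sensitivity = if (is.null(cm)) NA_real_ else cm$sensitivity,
      specificity = if (is.null(cm)) NA_real_ else cm$specificity,
      ppv = if (is.null(cm)) NA_real_ else cm$ppv,
      npv = if (is.null(cm)) NA_real_ else cm$npv,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(feature = character(0), domain = character(0),
               correlation = numeric(0), n_worsening = integer(0),
               pct_worsening = numeric(0), sensitivity = numeric(0),
               specificity = numeric(0), ppv = numeric(0), npv = numeric(0))
  rownames(res) <- NULL
  res
}
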