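# Preprocessing filters, redundancy pruning, observation alignment, and the
# missingness diagnostic that together turn a raw feature matrix plus factor
# scores into analysis-ready paired longitudinal observations.

feature_cols <- function(matrix) {
  setdiff(names(matrix), c("participant_id", "date", "word_count"))
}

#' Drop features that are almost always zero
#'
#' Removes feature columns whose zero percentage, computed over non-missing
#' cells only, is strictly greater than `threshold` (default 90): features
#' this sparse carry too little variability to be candidate markers.
#'
#' @param matrix a feature matrix ([build_feature_matrix()]).
#' @param threshold percent zeros above which a feature is dropped.
#' @return list with the filtered `matrix` and `dropped` (character).
#' @export
filter_zero_features <- function(matrix, threshold = 90) {
  dropped <- character(0)
  for (cl in feature_cols(matrix)) {
    x <- matrix[[cl]][!is.na(matrix[[cl]])]
    if (length(x) > 0 && 100 * mean(x == 0) > threshold)
      dropped <- c(dropped, cl)
  }
  matrix[dropped] <- NULL
  list(matrix = matrix, dropped = dropped)
}

#' Mask extreme daily word counts
#'
#' Word counts strictly greater than `cap` (default 10,000) are set missing:
#' such extremes are more plausibly collection artifacts than real typing.
#' Only the count (and its normalised copy, if present) is masked; category
#' percentages for the day are retained.
#'
#' @param matrix a feature matrix with a raw `word_count` column.
#' @param cap strict upper bound on plausible daily word counts.
#' @return list with `matrix` and `n_cells_masked`.
#' @export
cap_word_count <- function(matrix, cap = 10000) {
  if (!"word_count" %in% names(matrix)) stop_("raw word_count column missing")
  bad <- !is.na(matrix$word_count) & matrix$word_count > cap
  matrix$word_count[bad] <- NA
  if ("word_count_z" %in% names(matrix)) matrix$word_count_z[bad] <- NA
  list(matrix = matrix, n_cells_masked = sum(bad))
}

#' Remove participants who switched smartphone operating system
#'
#' A participant whose device log shows two or more distinct operating
#' systems within the first `window_days` days of their first record is
#' removed entirely (keyboard behaviour is not comparable across systems).
#' Participants absent from the log are kept, with a warning.
#'
#' @param matrix a feature matrix.
#' @param device_log data frame `participant_id`, `date`, `os`.
#' @param window_days length of the observation window.
#' @return list with `matrix` and `removed` participant ids.
#' @export
drop_os_switchers <- function(matrix, device_log, window_days = 180) {
  ids <- unique(matrix$participant_id)
  if (nrow(device_log) == 0) {
    warn_("device log is empty; no participants removed")
    return(list(matrix = matrix, removed = character(0)))
  }
  unknown <- setdiff(ids, device_log$participant_id)
  if (length(unknown))
    warn_("%d participant(s) absent from device log; kept", length(unknown))
  removed <- character(0)
  for (id in intersect(ids, device_log$participant_id)) {
    dl <- device_log[device_log$participant_id == id, , drop = FALSE]
    d0 <- min(as.Date(dl$date))
    os <- unique(dl$os[as.Date(dl$date) <= d0 + window_days])
    if (length(os) >= 2) removed <- c(removed, id)
  }
  list(matrix = matrix[!matrix$participant_id %in% removed, , drop = FALSE],
       removed = removed)
}

#' Prune highly correlated (redundant) features
#'
#' Builds a graph with an edge between any two features whose pairwise
#' Spearman correlation (pairwise-complete observations) is strictly above
#' `threshold` (default 0.85). Within each connected component a single
#' representative survives: a feature named in `priority` if any (an
#' explicit interpretability override), otherwise the feature with the
#' largest mean absolute Spearman correlation between its aligned marker
#' values and the domain scores, ties broken lexicographically.
#'
#' @param matrix feature matrix.
#' @param scores factor-score table (`participant_id`, `timepoint_day`,
#'   `domain`, `score`).
#' @param schedule survey schedule used to align markers with scores.
#' @param threshold Spearman threshold (strict).
#' @param priority optional character vector of preferred survivors.
#' @return list with `matrix`, and a `report` data frame of dropped
#'   features and their retained representative.
#' @export
prune_redundant <- function(matrix, scores, schedule, threshold = 0.85,
                            priority = NULL) {
  fc <- feature_cols(matrix)
  if (length(fc) < 2) return(list(matrix = matrix,
                                  report = data.frame(dropped = character(0),
                                                      retained = character(0))))
  cm <- suppressWarnings(
    stats::cor(as.matrix(matrix[fc]), method = "spearman",
               use = "pairwise.complete.obs"))
  if (any(is.na(cm))) {
    warn_("undefined Spearman correlations (constant feature?); treated as 0")
    cm[is.na(cm)] <- 0
  }
  adj <- abs(cm) > threshold
  diag(adj) <- FALSE
  comp <- graph_components(adj)

  strength <- feature_strength(matrix, scores, schedule, fc)
  report <- list()
  drop_all <- character(0)
  for (members in comp) {
    if (length(members) == 1) next
    nm <- fc[members]
    keep <- if (!is.null(priority) && any(nm %in% priority))
      sort(nm[nm %in% priority])[1]
    else {
      st <- strength[nm]
      st[is.na(st)] <- 0
      cands <- nm[st == max(st)]
      sort(cands)[1]
    }
    dropped <- setdiff(nm, keep)
    drop_all <- c(drop_all, dropped)
    report[[length(report) + 1L]] <-
      data.frame(dropped = dropped, retained = keep)
  }
  matrix[drop_all] <- NULL
  list(matrix = matrix,
       report = if (length(report)) do.call(rbind, report)
                else data.frame(dropped = character(0), retained = character(0)))
}

graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (v in seq_len(n)) {
    if (comp[v] != 0L) next
    cur <- cur + 1L
    queue <- v
    comp[v] <- cur
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      nb <- which(adj[u, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  split(seq_len(n), comp)
}

# mean |Spearman| of each feature's aligned marker values against the
# domain scores
feature_strength <- function(matrix, scores, schedule, fc) {
  panel <- align_observations(matrix[c("participant_id", "date", "word_count",
                                       fc)], scores, schedule)
  out <- stats::setNames(numeric(length(fc)), fc)
  for (f in fc) {
    sub <- panel[panel$feature == f, , drop = FALSE]
    rs <- vapply(split(sub, sub$domain), function(d) {
      ok <- !is.na(d$symptom_score) & !is.na(d$marker_value)
      if (sum(ok) < 3) return(NA_real_)
      suppressWarnings(stats::cor(d$symptom_score[ok], d$marker_value[ok],
                                  method = "spearman"))
    }, 0)
    out[f] <- mean(abs(rs), na.rm = TRUE)
  }
  out[is.nan(out)] <- NA
  out
}

#' Align feature days with survey timepoints
#'
#' For each surveyed (participant, timepoint), the candidate marker value is
#' the mean of the feature from the day prior to and the day of symptom
#' data collection, over whichever of the two days is available (both
#' missing gives a missing marker). The result is a long panel keyed by
#' (participant, timepoint, domain, feature), holding the symptom factor
#' score and the marker value; rows where both are missing are dropped.
#'
#' @param matrix feature matrix (daily rows).
#' @param scores factor scores per (participant, timepoint, domain).
#' @param schedule data frame `participant_id`, `timepoint_day`, `date`
#'   mapping each survey timepoint to its calendar day per participant.
#' @return `aligned_panel` data frame.
#' @export
align_observations <- function(matrix, scores, schedule) {
  if (anyDuplicated(scores[c("participant_id", "timepoint_day", "domain")]))
    stop_("duplicate survey score rows per (participant, timepoint, domain)")
  fc <- feature_cols(matrix)
  mkey <- paste(matrix$participant_id, matrix$date)
  fm <- as.matrix(matrix[fc])
  i0 <- match(paste(schedule$participant_id, schedule$date), mkey)
  i1 <- match(paste(schedule$participant_id, as.Date(schedule$date) - 1), mkey)
  v0 <- fm[ifelse(is.na(i0), 1L, i0), , drop = FALSE]
  v0[is.na(i0), ] <- NA
  v1 <- fm[ifelse(is.na(i1), 1L, i1), , drop = FALSE]
  v1[is.na(i1), ] <- NA
  num <- ifelse(is.na(v1), 0, v1) + ifelse(is.na(v0), 0, v0)
  den <- (!is.na(v1)) + (!is.na(v0))
  marker <- ifelse(den == 0, NA_real_, num / den)  # mean of available days
  colnames(marker) <- fc

  doms <- sort(unique(scores$domain))
  skey <- paste(scores$participant_id, scores$timepoint_day, scores$domain)
  nS <- nrow(schedule); nF <- length(fc); nD <- length(doms)
  out <- data.frame(
    participant_id = rep(schedule$participant_id, times = nF * nD),
    timepoint_day = rep(schedule$timepoint_day, times = nF * nD),
    domain = rep(rep(doms, each = nS), times = nF),
    feature = rep(fc, each = nS * nD),
    symptom_score = NA_real_,
    marker_value = as.vector(marker[, rep(seq_len(nF), each = nD),
                                    drop = FALSE]),
    stringsAsFactors = FALSE)
  out$symptom_score <- scores$score[
    match(paste(out$participant_id, out$timepoint_day, out$domain), skey)]
  out <- out[!(is.na(out$symptom_score) & is.na(out$marker_value)), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("aligned_panel", "data.frame")
  out
}

#' Extract one (feature, domain) pair from an aligned panel
#'
#' @param panel an [align_observations()] result.
#' @param feature,domain names selecting the pair.
#' @return data frame ready for [fit_blmm()].
#' @export
pair_panel <- function(panel, feature, domain) {
  sub <- panel[panel$feature == feature & panel$domain == domain, ,
               drop = FALSE]
  rownames(sub) <- NULL
  sub
}

#' Correlate symptom severity with activity completion rates
#'
#' Computes, per (domain, activity), the Pearson correlation between each
#' participant's mean factor score and their completion rate. Weak
#' correlations (all |r| below `weak`) support treating the missingness as
#' ignorable (missing at random), which the downstream full-information
#' likelihood assumes.
#'
#' @param scores factor-score table.
#' @param completion_table data frame `participant_id`, `activity`,
#'   `completion_rate`.
#' @param weak threshold below which a correlation counts as weak.
#' @return list: `correlations` (domain, activity, r) and `mar_plausible`
#'   flag (TRUE iff every defined |r| < `weak`).
#' @export
missingness_diagnostic <- function(scores, completion_table, weak = 0.1) {
  if (length(unique(scores$participant_id)) < 2)
    stop_("correlation with completion rates is undefined for a single participant")
  pm <- stats::aggregate(score ~ participant_id + domain, scores, mean,
                         na.rm = TRUE)
  rows <- list()
  for (d in sort(unique(pm$domain))) {
    sd_ <- pm[pm$domain == d, , drop = FALSE]
    for (a in sort(unique(completion_table$activity))) {
      cr <- completion_table[completion_table$activity == a, , drop = FALSE]
      m <- merge(sd_, cr, by = "participant_id")
      r <- if (nrow(m) < 2 || stats::sd(m$completion_rate) == 0 ||
               stats::sd(m$score) == 0) NA_real_
           else stats::cor(m$score, m$completion_rate)
      rows[[length(rows) + 1L]] <- data.frame(domain = d, activity = a, r = r)
    }
  }
  tab <- do.call(rbind, rows)
  list(correlations = tab,
       mar_plausible = all(abs(tab$r) < weak, na.rm = TRUE))
}
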