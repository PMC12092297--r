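# Split-half identification/validation workflow: FDR screen on one half of
# participants, Bonferroni confirmation on the other.

#' Randomly split participants into identification and validation halves
#'
#' Uniform random equal partition (sizes differ by at most one),
#' deterministic given the seed. The split is at the participant level:
#' repeated measures within a participant are dependent, so an
#' observation-level split would leak information between halves.
#'
#' @param ids participant identifiers (>= 2).
#' @param seed integer seed.
#' @return object of class `split_assignment`: named character vector
#'   mapping each id to `"identification"` or `"validation"`, with the seed
#'   as an attribute.
#' @export
split_participants <- function(ids, seed) {
  ids <- unique(ids)
  if (length(ids) < 2) stop_("need at least 2 participants to split")
  n <- length(ids)
  idx <- with_local_seed(seed, sample.int(n, floor(n / 2)))
  out <- stats::setNames(rep("validation", n), ids)
  out[idx] <- "identification"
  structure(out, seed = seed, class = "split_assignment")
}

#' Multiple-testing adjustments used in the marker workflow
#'
#' `bh_adjust()` returns Benjamini–Hochberg step-up adjusted p-values
#' (`q_(k) = min_{j >= k} p_(j) m / j`, capped at 1, in input order), used
#' to screen candidates on the identification half. `bonferroni_adjust()`
#' returns `min(1, p * m)`, used to confirm candidates on the validation
#' half. Inputs outside \[0, 1\] are an error.
#'
#' @param pvalues numeric vector of raw p-values in \[0, 1\].
#' @param m family size for Bonferroni (defaults to `length(pvalues)`).
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  check_pvalues(pvalues)
  stats::p.adjust(pvalues, method = "BH")
}

#' @rdname bh_adjust
#' @export
bonferroni_adjust <- function(pvalues, m = length(pvalues)) {
  check_pvalues(pvalues)
  pmin(1, pvalues * m)
}

check_pvalues <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop_("p-values must lie in [0, 1] and be non-missing")
  invisible(p)
}

#' Identify and validate markers across the two halves
#'
#' Takes per-pair bivariate mixed-model results from the identification and
#' validation halves and applies the two-stage rule: a (feature, domain,
#' association-type) test is a *candidate* when its BH-adjusted p-value on
#' the identification half is below `alpha`, the adjustment family being
#' all feature x domain x type tests jointly; a candidate is *validated*
#' when its Bonferroni-adjusted p-value on the validation half is below
#' `alpha`, the family being the candidate set. Reported estimates for
#' validated markers come from the validation half. Pairs whose fit did not
#' converge in either half are excluded (count logged in the attribute
#' `n_excluded`).
#'
#' @param fits_half1,fits_half2 data frames with columns `feature`,
#'   `domain`, `rho_b`, `p_rho_b`, `rho_w`, `p_rho_w`, `converged` —
#'   one row per (feature, domain) pair, covering identical pair sets.
#'   [fit_pairs()] produces this layout.
#' @param alpha significance level for both stages.
#' @return `marker_table` data frame: one row per (feature, domain,
#'   association_type) with estimates and raw/adjusted p-values from both
#'   halves and `status` in candidate/validated/rejected.
#' @export
run_selection <- function(fits_half1, fits_half2, alpha = 0.05) {
  key1 <- paste(fits_half1$feature, fits_half1$domain)
  key2 <- paste(fits_half2$feature, fits_half2$domain)
  if (!setequal(key1, key2))
    stop_("the two fit sets must cover identical (feature, domain) pairs")
  fits_half2 <- fits_half2[match(key1, key2), , drop = FALSE]
  ok <- fits_half1$converged & fits_half2$converged &
    !is.na(fits_half1$p_rho_b) & !is.na(fits_half1$p_rho_w) &
    !is.na(fits_half2$p_rho_b) & !is.na(fits_half2$p_rho_w)
  n_excluded <- sum(!ok)
  f1 <- fits_half1[ok, , drop = FALSE]
  f2 <- fits_half2[ok, , drop = FALSE]

  long <- data.frame(
    feature = rep(f1$feature, 2),
    domain = rep(f1$domain, 2),
    association_type = rep(c("cross_sectional", "longitudinal"),
                           each = nrow(f1)),
    est_identification = c(f1$rho_b, f1$rho_w),
    p_identification = c(f1$p_rho_b, f1$p_rho_w),
    est_validation = c(f2$rho_b, f2$rho_w),
    p_validation = c(f2$p_rho_b, f2$p_rho_w),
    stringsAsFactors = FALSE)

  long$p_adj_identification <- if (nrow(long)) bh_adjust(long$p_identification)
                               else numeric(0)
  candidate <- long$p_adj_identification < alpha
  long$p_adj_validation <- rep(NA_real_, nrow(long))
  long$p_adj_validation[candidate] <-
    bonferroni_adjust(long$p_validation[candidate], m = sum(candidate))
  validated <- candidate & !is.na(long$p_adj_validation) &
    long$p_adj_validation < alpha
  long$status <- ifelse(validated, "validated",
                        ifelse(candidate, "candidate", "rejected"))
  ord <- order(long$feature, long$domain, long$association_type)
  long <- long[ord, , drop = FALSE]
  rownames(long) <- NULL
  attr(long, "n_excluded") <- n_excluded
  attr(long, "alpha") <- alpha
  class(long) <- c("marker_table", "data.frame")
  long
}

#' Fit the bivariate mixed model for every (feature, domain) pair
#'
#' Convenience driver for [run_selection()]: restricts an aligned panel to
#' each (feature, domain) pair in turn and fits [fit_blmm()], collecting
#' correlation estimates, Wald p-values and convergence flags.
#'
#' @param panel an [align_observations()] result (typically restricted to
#'   one half of the participants).
#' @param t_means,n_starts passed to [fit_blmm()].
#' @return data frame with one row per pair.
#' @export
fit_pairs <- function(panel, t_means = FALSE, n_starts = 5) {
  combos <- unique(panel[c("feature", "domain")])
  combos <- combos[order(combos$feature, combos$domain), , drop = FALSE]
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    sub <- panel[panel$feature == combos$feature[i] &
                   panel$domain == combos$domain[i], , drop = FALSE]
    fit <- tryCatch(fit_blmm(sub, t_means = t_means, n_starts = n_starts),
                    error = function(e) NULL)
    rows[[i]] <- data.frame(
      feature = combos$feature[i], domain = combos$domain[i],
      rho_b = if (is.null(fit)) NA_real_ else fit$rho_b,
      p_rho_b = if (is.null(fit)) NA_real_ else fit$p_rho_b,
      rho_w = if (is.null(fit)) NA_real_ else fit$rho_w,
      p_rho_w = if (is.null(fit)) NA_real_ else fit$p_rho_w,
      converged = !is.null(fit) && fit$converged && !fit$boundary,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
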