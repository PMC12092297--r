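# Operating-characteristic utilities: simulate a many-feature, many-domain
# cohort with a handful of planted true associations and push it through the
# split-half identification/validation workflow. Used to verify that the
# two-stage selection recovers planted markers while controlling false
# validations.

#' Simulate severity and feature panels for many (feature, domain) pairs
#'
#' Draws, from the same bivariate random-intercept model as
#' [simulate_blmm_panel()], a set of latent symptom severities (one per
#' domain) and language features (one per feature), all mutually
#' independent except for the planted pairs, for which the random
#' intercepts correlate at `rho_b` and the occasion residuals at `rho_w`.
#'
#' @param n_participants,n_timepoints panel dimensions.
#' @param n_features,n_domains numbers of features and symptom domains.
#' @param planted list of `list(feature, domain, rho_b, rho_w)`; feature
#'   indices must be distinct.
#' @param seed integer seed.
#' @return list with arrays `S` (participants x timepoints x domains) and
#'   `F` (participants x timepoints x features) plus the planted table.
#' @export
simulate_multipair_panel <- function(n_participants, n_timepoints,
                                     n_features, n_domains,
                                     planted = list(), seed = 1) {
  n <- n_participants; Tn <- n_timepoints
  with_local_seed(seed, {
    bD <- matrix(stats::rnorm(n * n_domains), n, n_domains)
    eD <- array(stats::rnorm(n * Tn * n_domains), c(n, Tn, n_domains))
    bF <- matrix(stats::rnorm(n * n_features), n, n_features)
    eF <- array(stats::rnorm(n * Tn * n_features), c(n, Tn, n_features))
    for (pp in planted) {
      fi <- pp$feature; d <- pp$domain
      bF[, fi] <- pp$rho_b * bD[, d] + sqrt(1 - pp$rho_b^2) * bF[, fi]
      eF[, , fi] <- pp$rho_w * eD[, , d] + sqrt(1 - pp$rho_w^2) * eF[, , fi]
    }
    S <- array(0, c(n, Tn, n_domains))
    F <- array(0, c(n, Tn, n_features))
    for (d in seq_len(n_domains)) S[, , d] <- bD[, d] + eD[, , d]
    for (fi in seq_len(n_features)) F[, , fi] <- bF[, fi] + eF[, , fi]
    list(S = S, F = F,
         planted = if (length(planted)) do.call(rbind, lapply(planted, function(pp)
           data.frame(feature = feat_name(pp$feature),
                      domain = dom_name(pp$domain),
                      rho_b = pp$rho_b, rho_w = pp$rho_w)))
         else NULL)
  })
}

feat_name <- function(i) sprintf("f%03d", i)
dom_name <- function(i) sprintf("domain%02d", i)

# Minimal panel-data object for one pair, bypassing data-frame assembly.
pd_from_arrays <- function(S, F, d, fi, rows_keep = NULL) {
  n <- dim(S)[1]; Tn <- dim(S)[2]
  s <- as.vector(S[, , d]); f <- as.vector(F[, , fi])
  id <- rep(seq_len(n) - 1L, Tn); tp <- rep(seq_len(Tn) - 1L, each = n)
  if (!is.null(rows_keep)) {
    id <- id[rows_keep]; tp <- tp[rows_keep]
    s <- s[rows_keep]; f <- f[rows_keep]
  }
  ord <- order(id, tp)
  list(id = id[ord], tp = tp[ord], s = s[ord], f = f[ord],
       ids = seq_len(n), tps = seq_len(Tn),
       nid = n, ntp = Tn, n_rows = length(ord))
}

#' One replicate of the split-half marker selection study
#'
#' Simulates the multi-pair panel, splits participants into identification
#' and validation halves, fits the bivariate mixed model for every
#' (feature, domain) pair on each half, and runs the two-stage selection.
#'
#' @inheritParams simulate_multipair_panel
#' @param alpha selection level.
#' @param split_seed seed of the participant split.
#' @param n_starts optimisation starts per fit (the method-of-moments start
#'   is reliable at these panel sizes, so small values are adequate).
#' @return list: `markers` (the [run_selection()] table), `planted`, and
#'   summary counts `n_true_validated` (planted pairs with at least one
#'   validated association type), `n_false_validated` (validated rows on
#'   non-planted pairs).
#' @export
selection_replicate <- function(n_participants = 160, n_timepoints = 6,
                                n_features = 40, n_domains = 10,
                                planted = list(
                                  list(feature = 1, domain = 1, rho_b = 0.5, rho_w = 0.3),
                                  list(feature = 2, domain = 4, rho_b = 0.5, rho_w = 0.3),
                                  list(feature = 3, domain = 8, rho_b = 0.5, rho_w = 0.3)),
                                alpha = 0.05, seed = 1, split_seed = NULL,
                                n_starts = 2) {
  sim <- simulate_multipair_panel(n_participants, n_timepoints, n_features,
                                  n_domains, planted, seed = seed)
  if (is.null(split_seed)) split_seed <- seed + 1L
  half <- split_participants(seq_len(n_participants), split_seed)
  id_half <- which(half == "identification")
  n <- n_participants; Tn <- n_timepoints
  in_id <- rep(seq_len(n), Tn) %in% id_half

  fit_half <- function(rows_keep) {
    out <- vector("list", n_features * n_domains)
    k <- 0L
    for (fi in seq_len(n_features)) for (d in seq_len(n_domains)) {
      pd <- pd_from_arrays(sim$S, sim$F, d, fi, rows_keep)
      pd$nid <- length(unique(pd$id))
      pd$id <- match(pd$id, sort(unique(pd$id))) - 1L
      fit <- tryCatch(
        fit_blmm_core(pd, n_starts = n_starts),
        error = function(e) NULL)
      k <- k + 1L
      out[[k]] <- data.frame(
        feature = feat_name(fi), domain = dom_name(d),
        rho_b = if (is.null(fit)) NA_real_ else fit$rho_b,
        p_rho_b = if (is.null(fit)) NA_real_ else fit$p_rho_b,
        rho_w = if (is.null(fit)) NA_real_ else fit$rho_w,
        p_rho_w = if (is.null(fit)) NA_real_ else fit$p_rho_w,
        converged = !is.null(fit) && fit$converged && !fit$boundary)
    }
    do.call(rbind, out)
  }
  f1 <- fit_half(in_id)
  f2 <- fit_half(!in_id)
  mk <- run_selection(f1, f2, alpha = alpha)

  planted_key <- if (is.null(sim$planted)) character(0) else
    paste(sim$planted$feature, sim$planted$domain)
  val <- mk[mk$status == "validated", , drop = FALSE]
  val_key <- paste(val$feature, val$domain)
  list(markers = mk, planted = sim$planted,
       n_true_validated = length(intersect(planted_key, unique(val_key))),
       n_false_validated = sum(!val_key %in% planted_key))
}
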