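#' Fit the bivariate linear mixed model for one (feature, domain) pair
#'
#' Jointly models a symptom factor-score series and a language-marker series
#' with correlated participant-level random intercepts and correlated
#' occasion-level residuals, estimated by full-information maximum likelihood
#' over whatever subset of the two values is observed at each occasion.
#' The association decomposes into a between-subject (cross-sectional)
#' correlation `rho_b` of the random intercepts and a within-subject
#' (longitudinal) correlation `rho_w` of the occasion residuals.
#'
#' The model for participant \eqn{i} at occasion \eqn{j} is
#' \deqn{s_{ij} = \mu_s + b_{si} + e_{sij}, \quad
#'       f_{ij} = \mu_f + b_{fi} + e_{fij}}
#' with \eqn{(b_{si}, b_{fi}) \sim N_2(0, D)} and
#' \eqn{(e_{sij}, e_{fij}) \sim N_2(0, \Sigma)}. Then
#' \eqn{\rho_b = D_{sf}/\sqrt{D_{ss} D_{ff}}} and
#' \eqn{\rho_w = \Sigma_{sf}/\sqrt{\Sigma_{ss}\Sigma_{ff}}}.
#' Both covariance matrices are optimised on the log-Cholesky scale so the
#' search is unconstrained; standard errors for the correlations come from
#' the observed information matrix by the delta method, with two-sided Wald
#' p-values. With `t_means = TRUE` the symptom mean is occasion-specific
#' (severity declines over follow-up); the default is a single overall mean
#' for each series.
#'
#' @param panel data frame with columns `participant_id`, `timepoint_day`,
#'   and either `symptom`/`feature` or `symptom_score`/`marker_value`.
#'   Each row is one participant-occasion; either value may be `NA`.
#' @param t_means logical; occasion-specific symptom means.
#' @param n_starts number of optimisation starts: one method-of-moments
#'   start plus deterministically jittered copies, best log-likelihood kept.
#' @param maxit,gtol optimiser iteration cap and gradient tolerance.
#' @return an object of class `blmm_fit`: parameter estimates (`mu_s`,
#'   `mu_f`, `D`, `Sigma`), derived `rho_b`/`rho_w` with standard errors and
#'   p-values, `loglik`, sample sizes, and convergence metadata.
#' @examples
#' pan <- simulate_blmm_panel(60, 5, rho_b = 0.5, rho_w = 0.3, seed = 1)
#' fit <- fit_blmm(pan)
#' c(fit$rho_b, fit$rho_w)
#' @seealso [loglik_direct()] for a brute-force likelihood oracle,
#'   [lrt_rho()] for likelihood-ratio inference.
#' @export
fit_blmm <- function(panel, t_means = FALSE, n_starts = 5,
                     maxit = 300, gtol = 1e-8) {
  pd <- blmm_panel_data(panel)
  fit_blmm_core(pd, t_means = t_means, n_starts = n_starts,
                maxit = maxit, gtol = gtol)
}

# Normalise a panel data frame into index vectors for the C++ likelihood.
# Rows are canonically sorted by (participant, occasion) so the objective is
# bit-identical under input permutation.
blmm_panel_data <- function(panel) {
  stopifnot(is.data.frame(panel))
  s_col <- intersect(c("symptom_score", "symptom"), names(panel))[1]
  f_col <- intersect(c("marker_value", "feature"), names(panel))[1]
  if (is.na(s_col) || is.na(f_col))
    stop_("panel needs symptom/symptom_score and feature/marker_value columns")
  s <- as.numeric(panel[[s_col]])
  f <- as.numeric(panel[[f_col]])
  keep <- !(is.na(s) & is.na(f))
  id_raw <- panel$participant_id[keep]
  tp_raw <- panel$timepoint_day[keep]
  s <- s[keep]; f <- f[keep]
  ord <- order(id_raw, tp_raw)
  id_raw <- id_raw[ord]; tp_raw <- tp_raw[ord]; s <- s[ord]; f <- f[ord]
  ids <- unique(id_raw)
  tps <- sort(unique(tp_raw))
  list(id = match(id_raw, ids) - 1L, tp = match(tp_raw, tps) - 1L,
       s = s, f = f, ids = ids, tps = tps,
       nid = length(ids), ntp = length(tps), n_rows = length(s))
}

blmm_validate <- function(pd) {
  if (pd$nid < 2) stop_("bivariate mixed model needs at least 2 participants")
  reps <- tabulate(pd$id + 1L, pd$nid)
  if (max(reps) < 2)
    stop_("no participant has repeated occasions: within- vs between-subject variance is unidentified")
  for (v in c("s", "f")) {
    x <- pd[[v]][!is.na(pd[[v]])]
    if (length(x) == 0 || length(unique(x)) < 2)
      stop_("series '%s' has no variance", if (v == "s") "symptom" else "feature")
  }
  invisible(pd)
}

# Method-of-moments start on the log-Cholesky scale.
blmm_mom_start <- function(pd, t_means) {
  s <- pd$s; f <- pd$f; idx <- pd$id + 1L
  mu_s <- if (t_means) {
    ms <- vapply(seq_len(pd$ntp), function(j) {
      v <- s[pd$tp == j - 1L]
      if (all(is.na(v))) mean(s, na.rm = TRUE) else mean(v, na.rm = TRUE)
    }, 0)
    ms
  } else mean(s, na.rm = TRUE)
  mu_f <- mean(f, na.rm = TRUE)
  pmean <- function(x) {
    num <- rowsum(ifelse(is.na(x), 0, x), idx)
    den <- rowsum(as.numeric(!is.na(x)), idx)
    as.numeric(num / pmax(den, 1))  # rowsum groups are sorted: 1..nid
  }
  pm_s <- pmean(s)
  pm_f <- pmean(f)
  cs <- s - pm_s[idx]
  cf <- f - pm_f[idx]
  v_ws <- stats::var(cs, na.rm = TRUE)
  v_wf <- stats::var(cf, na.rm = TRUE)
  c_w <- stats::cov(cs, cf, use = "pairwise.complete.obs")
  nbar <- mean(tabulate(idx, pd$nid))
  v_bs <- stats::var(pm_s, na.rm = TRUE) - v_ws / nbar
  v_bf <- stats::var(pm_f, na.rm = TRUE) - v_wf / nbar
  c_b <- stats::cov(pm_s, pm_f, use = "pairwise.complete.obs")
  list(mu_s = mu_s, mu_f = mu_f,
       D = clamp_pd(matrix(c(v_bs, c_b, c_b, v_bf), 2)),
       Sigma = clamp_pd(matrix(c(v_ws, c_w, c_w, v_wf), 2)))
}

# Nudge a symmetric 2x2 towards positive definiteness.
clamp_pd <- function(M, floor = 1e-3) {
  M[!is.finite(M)] <- 0
  M[1, 1] <- max(M[1, 1], floor)
  M[2, 2] <- max(M[2, 2], floor)
  lim <- 0.95 * sqrt(M[1, 1] * M[2, 2])
  M[1, 2] <- M[2, 1] <- sign(M[1, 2]) * min(abs(M[1, 2]), lim)
  M
}

# 2x2 covariance -> log-Cholesky (a, b, c): L = [[e^a, 0], [b, e^c]].
logchol <- function(M) {
  L <- t(chol(M))
  c(log(L[1, 1]), L[2, 1], log(L[2, 2]))
}

logchol_inv <- function(th) {
  L <- matrix(c(exp(th[1]), th[2], 0, exp(th[3])), 2)
  L %*% t(L)
}

rho_of_theta <- function(th) th[2] / sqrt(th[2]^2 + exp(th[3])^2)

# Deterministic jitter table for multi-start (fixed across sessions).
blmm_jitters <- function(n_starts, p) {
  if (n_starts <= 1) return(NULL)
  with_local_seed(20201107, matrix(stats::rnorm((n_starts - 1) * p, sd = 0.25),
                                   nrow = n_starts - 1))
}

fit_blmm_core <- function(pd, t_means = FALSE, n_starts = 5,
                          maxit = 300, gtol = 1e-8,
                          fix_between = FALSE, fix_within = FALSE,
                          se = TRUE) {
  blmm_validate(pd)
  mom <- blmm_mom_start(pd, t_means)
  thD <- logchol(mom$D)
  thS <- logchol(mom$Sigma)
  start <- c(mom$mu_s, mom$mu_f, thD, thS)
  nmu <- length(mom$mu_s) + 1L
  free <- rep(TRUE, length(start))
  if (fix_between) { start[nmu + 2L] <- 0; free[nmu + 2L] <- FALSE }
  if (fix_within)  { start[nmu + 5L] <- 0; free[nmu + 5L] <- FALSE }

  jit <- blmm_jitters(n_starts, sum(free))
  best <- NULL
  n_used <- 0L
  for (k in seq_len(max(1L, n_starts))) {
    st <- start
    if (k > 1) st[free] <- st[free] + jit[k - 1L, ]
    res <- cpp_blmm_fit(st, free, pd$id, pd$tp, pd$s, pd$f,
                        pd$nid, pd$ntp, t_means, maxit, gtol)
    n_used <- n_used + 1L
    if (is.null(best) || res$value < best$value - 1e-10) best <- res
  }
  par <- as.numeric(best$par_full)
  mu_s <- par[seq_len(nmu - 1L)]
  mu_f <- par[nmu]
  thD <- par[nmu + (1:3)]
  thS <- par[nmu + (4:6)]
  D <- logchol_inv(thD)
  Sigma <- logchol_inv(thS)
  rho_b <- rho_of_theta(thD)
  rho_w <- rho_of_theta(thS)
  boundary <- max(abs(rho_b), abs(rho_w)) >= 0.999

  se_b <- se_w <- p_b <- p_w <- NA_real_
  if (se && !boundary) {
    H <- cpp_blmm_hessian(par, free, pd$id, pd$tp, pd$s, pd$f,
                          pd$nid, pd$ntp, t_means, 1e-4)
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && all(is.finite(V)) && all(diag(V) > 0)) {
      fidx <- which(free)
      # analytic delta-method gradient: rho = b / sqrt(b^2 + exp(2c))
      delta_se <- function(off) {
        b <- par[nmu + off + 2L]; v <- exp(2 * par[nmu + off + 3L])
        den <- (b^2 + v)^1.5
        g <- numeric(length(fidx))
        i1 <- match(nmu + off + 2L, fidx)
        i2 <- match(nmu + off + 3L, fidx)
        if (!is.na(i1)) g[i1] <- v / den
        if (!is.na(i2)) g[i2] <- -b * v / den
        sqrt(max(0, drop(t(g) %*% V %*% g)))
      }
      se_b <- delta_se(0L)
      se_w <- delta_se(3L)
      if (is.finite(se_b) && se_b > 0) p_b <- 2 * stats::pnorm(-abs(rho_b / se_b))
      if (is.finite(se_w) && se_w > 0) p_w <- 2 * stats::pnorm(-abs(rho_w / se_w))
    }
  }

  structure(list(
    mu_s = mu_s, mu_f = mu_f, D = D, Sigma = Sigma,
    rho_b = rho_b, rho_w = rho_w,
    se_rho_b = se_b, se_rho_w = se_w,
    p_rho_b = p_b, p_rho_w = p_w,
    loglik = -best$value,
    n_participants = pd$nid, n_obs = pd$n_rows,
    converged = isTRUE(best$converged), n_starts_used = n_used,
    boundary = boundary, t_means = t_means,
    par = par, free = free, panel_data = pd
  ), class = "blmm_fit")
}

#' @export
print.blmm_fit <- function(x, ...) {
  cat("Bivariate linear mixed model (FIML)\n")
  cat(sprintf("  participants: %d, occasions: %d, logLik: %.3f%s\n",
              x$n_participants, x$n_obs, x$loglik,
              if (x$converged) "" else " [NOT CONVERGED]"))
  cat(sprintf("  between-subject rho_b = %.4f (se %.4f, p %.3g)\n",
              x$rho_b, x$se_rho_b, x$p_rho_b))
  cat(sprintf("  within-subject  rho_w = %.4f (se %.4f, p %.3g)\n",
              x$rho_w, x$se_rho_w, x$p_rho_w))
  if (x$boundary) cat("  note: correlation estimate at boundary; SEs suppressed\n")
  invisible(x)
}

#' Brute-force evaluation of the bivariate mixed-model log-likelihood
#'
#' Evaluates the same full-information Gaussian log-likelihood as
#' [fit_blmm()] by explicitly assembling each participant's dense
#' \eqn{2T \times 2T} covariance matrix \eqn{Z D Z' + I_T \otimes \Sigma}
#' and marginalising to the observed entries. No structure is exploited;
#' this is intentionally slow and exists as an independent oracle for the
#' optimised likelihood.
#'
#' @param parameters list with `mu_s` (scalar or one value per occasion),
#'   `mu_f`, and 2x2 matrices `D` and `Sigma`.
#' @param panel as in [fit_blmm()]; an empty panel yields 0.
#' @return the log-likelihood (a scalar).
#' @export
loglik_direct <- function(parameters, panel) {
  D <- parameters$D; Sigma <- parameters$Sigma
  if (any(eigen(D, symmetric = TRUE, only.values = TRUE)$values <= 0) ||
      any(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop_("D and Sigma must be positive definite")
  pd <- blmm_panel_data(panel)
  if (pd$n_rows == 0) return(0)
  mu_s <- parameters$mu_s
  if (length(mu_s) == 1) mu_s <- rep(mu_s, pd$ntp)
  mu_f <- parameters$mu_f
  ll <- 0
  for (i in seq_len(pd$nid) - 1L) {
    sel <- which(pd$id == i)
    tps <- pd$tp[sel] + 1L
    Ti <- length(sel)
    # stacked order: (s_1, f_1, s_2, f_2, ...)
    y <- as.vector(rbind(pd$s[sel], pd$f[sel]))
    mu <- as.vector(rbind(mu_s[tps], rep(mu_f, Ti)))
    Z <- do.call(rbind, rep(list(diag(2)), Ti))
    V <- Z %*% D %*% t(Z) + kronecker(diag(Ti), Sigma)
    obs <- !is.na(y)
    yo <- y[obs] - mu[obs]
    Vo <- V[obs, obs, drop = FALSE]
    ch <- chol(Vo)
    z <- backsolve(ch, yo, transpose = TRUE)
    ll <- ll - 0.5 * (sum(z^2) + 2 * sum(log(diag(ch))) +
                      length(yo) * log(2 * pi))
  }
  ll
}

#' Likelihood-ratio test for one of the two correlations
#'
#' Refits the bivariate mixed model with the selected covariance
#' cross-element (`D_sf` for `"between"`, `Sigma_sf` for `"within"`)
#' constrained to zero and compares likelihoods; the statistic is referred
#' to a chi-square distribution with 1 degree of freedom.
#'
#' @inheritParams fit_blmm
#' @param which `"between"` or `"within"`.
#' @return list with `statistic`, `p`, and the two fits.
#' @export
lrt_rho <- function(panel, which = c("between", "within"),
                    t_means = FALSE, n_starts = 5) {
  which <- match.arg(which)
  pd <- blmm_panel_data(panel)
  full <- fit_blmm_core(pd, t_means = t_means, n_starts = n_starts, se = FALSE)
  restr <- fit_blmm_core(pd, t_means = t_means, n_starts = n_starts,
                         fix_between = which == "between",
                         fix_within = which == "within", se = FALSE)
  if (!restr$converged)
    return(list(statistic = NA_real_, p = NA_real_, status = "constrained fit did not converge",
                fit_full = full, fit_null = restr))
  stat <- max(0, 2 * (full$loglik - restr$loglik))
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       status = "ok", fit_full = full, fit_null = restr)
}
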