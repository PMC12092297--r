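#' Fit a pooled one-factor measurement model by FIML
#'
#' Estimates a confirmatory one-factor Gaussian model for one symptom
#' domain from planned-missing flash-survey items, pooling all rows
#' (participant-timepoints) so loadings are invariant over timepoints.
#' For item \eqn{k}: \eqn{x_k = \nu_k + \lambda_k \eta + \epsilon_k},
#' \eqn{\eta \sim N(0, 1)}, \eqn{\epsilon_k \sim N(0, \theta_k)}.
#' The factor variance is fixed at 1 so scores share a standardised scale
#' across domains; the first loading is reported positive. Each row
#' contributes the marginal Gaussian likelihood of its observed item subset
#' (full-information maximum likelihood), grouped by missingness pattern
#' for speed. Optimisation uses `nlminb` from a covariance-based start plus
#' deterministically jittered restarts, keeping the best log-likelihood.
#'
#' @param item_table long table `participant_id`, `timepoint_day`,
#'   `item_id`, `value`; absent rows encode missingness.
#' @param items character vector of item ids defining the domain (order
#'   fixes the loading order); default all items present.
#' @param domain label stored on the fit (and on scores).
#' @param n_starts optimisation starts.
#' @return object of class `measurement_model`: `lambda`, `nu`, `theta`,
#'   `loglik`, `converged`, `n_rows`, `n_starts_used`.
#' @export
fit_measurement <- function(item_table, items = NULL, domain = "domain",
                            n_starts = 5) {
  if (is.null(items)) items <- sort(unique(item_table$item_id))
  if (length(items) < 2)
    stop_("measurement model needs at least 2 items for identification")
  X <- items_wide(item_table, items)
  if (!any(rowSums(!is.na(X)) > 0)) stop_("no observed item responses")
  K <- length(items)

  pat <- split_patterns(X)
  nll <- function(par) cfa_nll(par, pat, K)

  start <- cfa_start(X)
  jit <- with_local_seed(31415927,
                         matrix(stats::rnorm((max(1L, n_starts) - 1) * 3 * K,
                                             sd = 0.2),
                                ncol = 3 * K))
  lower <- c(rep(-Inf, 2 * K), rep(-20, K))
  upper <- c(rep(Inf, 2 * K), rep(20, K))
  best <- NULL
  for (s in seq_len(max(1L, n_starts))) {
    st <- if (s == 1) start else start + jit[s - 1L, ]
    op <- tryCatch(
      stats::nlminb(st, nll, lower = lower, upper = upper,
                    control = list(iter.max = 500, eval.max = 1000,
                                   rel.tol = 1e-12)),
      error = function(e) NULL)
    if (is.null(op)) next
    if (is.null(best) || op$objective < best$objective - 1e-10) best <- op
  }
  if (is.null(best)) stop_("measurement model failed to converge from any start")
  par <- best$par
  # nlminb's "false convergence" is common at tight tolerances; declare
  # convergence from the gradient norm at the returned optimum instead
  gmax <- max(abs(num_gradient(nll, par)))
  converged <- best$convergence == 0 || gmax < 1e-3 * (1 + abs(best$objective))
  lambda <- par[seq_len(K)]
  nu <- par[K + seq_len(K)]
  theta <- exp(par[2 * K + seq_len(K)])
  if (lambda[1] < 0) lambda <- -lambda   # sign convention
  structure(list(domain = domain, items = items,
                 lambda = stats::setNames(lambda, items),
                 nu = stats::setNames(nu, items),
                 theta = stats::setNames(theta, items),
                 loglik = -best$objective,
                 converged = converged,
                 n_rows = nrow(X), n_starts_used = max(1L, n_starts)),
            class = "measurement_model")
}

# wide item matrix with canonical row order (bit-stable under permutation)
items_wide <- function(item_table, items) {
  it <- item_table[item_table$item_id %in% items, , drop = FALSE]
  key <- paste(it$participant_id, it$timepoint_day, sep = "\r")
  ukey <- sort(unique(key))
  X <- matrix(NA_real_, length(ukey), length(items),
              dimnames = list(ukey, items))
  X[cbind(match(key, ukey), match(it$item_id, items))] <- it$value
  X
}

split_patterns <- function(X) {
  obs <- !is.na(X)
  code <- apply(obs, 1, function(r) paste(which(r), collapse = ","))
  keep <- code != ""
  lapply(split(seq_len(nrow(X))[keep], code[keep]), function(rows) {
    o <- which(!is.na(X[rows[1], ]))
    list(o = o, X = X[rows, o, drop = FALSE])
  })
}

cfa_nll <- function(par, pat, K) {
  if (any(!is.finite(par)) || any(abs(par) > 1e3)) return(1e10)
  lambda <- par[seq_len(K)]
  nu <- par[K + seq_len(K)]
  theta <- exp(par[2 * K + seq_len(K)])
  nll <- 0
  for (p in pat) {
    o <- p$o
    lo <- lambda[o]; tho <- theta[o]
    denom <- 1 + sum(lo^2 / tho)
    logdet <- sum(log(tho)) + log(denom)
    C <- sweep(p$X, 2, nu[o])
    q <- rowSums(sweep(C^2, 2, tho, "/")) -
      (C %*% (lo / tho))^2 / denom
    nll <- nll + 0.5 * (sum(q) + nrow(C) * (logdet + length(o) * log(2 * pi)))
  }
  if (!is.finite(nll)) 1e10 else nll
}

cfa_start <- function(X) {
  K <- ncol(X)
  nu <- colMeans(X, na.rm = TRUE)
  nu[is.na(nu)] <- 0
  S <- stats::cov(X, use = "pairwise.complete.obs")
  S[!is.finite(S)] <- 0
  off <- abs(S); diag(off) <- NA
  lam <- sqrt(pmax(rowMeans(off, na.rm = TRUE), 0.05))
  lam[is.na(lam)] <- 0.5
  v <- diag(S); v[!is.finite(v) | v <= 0] <- 1
  theta <- pmax(v - lam^2, 0.05)
  c(lam, nu, log(theta))
}

#' @export
print.measurement_model <- function(x, ...) {
  cat(sprintf("One-factor measurement model [%s], %d rows, logLik %.2f%s\n",
              x$domain, x$n_rows, x$loglik,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(round(rbind(lambda = x$lambda, nu = x$nu, theta = x$theta), 4))
  invisible(x)
}

#' Regression-method factor scores
#'
#' For each participant-timepoint row, the score uses only that row's
#' observed items \eqn{o}:
#' \deqn{\hat\eta = \Lambda_o' (\Lambda_o \Lambda_o' + \Theta_o)^{-1}
#'       (x_o - \nu_o)
#'     = \frac{\sum_o \lambda_k (x_k - \nu_k)/\theta_k}
#'            {1 + \sum_o \lambda_k^2/\theta_k}.}
#' Rows with no observed items get a missing score. Regression scores are
#' shrunken: their variance never exceeds the unit factor variance.
#'
#' @param model a [fit_measurement()] result.
#' @param item_table long item table as in [fit_measurement()].
#' @return data frame `participant_id`, `timepoint_day`, `domain`, `score`.
#' @export
factor_scores <- function(model, item_table) {
  X <- items_wide(item_table, model$items)
  C <- sweep(X, 2, model$nu)
  w <- model$lambda / model$theta
  num <- rowSums(sweep(C, 2, w, "*"), na.rm = TRUE)
  prec <- (!is.na(C)) %*% (model$lambda * w)
  score <- ifelse(rowSums(!is.na(C)) == 0, NA_real_, num / (1 + prec))
  if (nrow(X) == 0)
    return(data.frame(participant_id = character(0),
                      timepoint_day = numeric(0),
                      domain = character(0), score = numeric(0)))
  parts <- do.call(rbind, strsplit(rownames(X), "\r", fixed = TRUE))
  data.frame(participant_id = parts[, 1],
             timepoint_day = as.numeric(parts[, 2]),
             domain = model$domain,
             score = as.numeric(score))
}

#' Fit measurement models and score all domains
#'
#' Convenience wrapper: fits one model per domain of a domain spec and
#' stacks the factor scores.
#'
#' @param item_table long item table.
#' @param domain_spec named list; each element has `domain` and `items`.
#' @param n_starts passed to [fit_measurement()].
#' @return list with `models` (named list) and `scores` (stacked data frame).
#' @export
score_domains <- function(item_table, domain_spec, n_starts = 5) {
  models <- lapply(domain_spec, function(ds)
    fit_measurement(item_table, items = ds$items, domain = ds$domain,
                    n_starts = n_starts))
  scores <- do.call(rbind, lapply(models, factor_scores,
                                  item_table = item_table))
  rownames(scores) <- NULL
  list(models = models, scores = scores)
}
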