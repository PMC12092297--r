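# Independent oracles used across tests; deliberately naive implementations.

# Benjamini-Hochberg by direct min-over-tails definition.
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (k in seq_len(m)) {
    js <- seq(k, m)
    # product formed as (m/j) * p so rounding matches the step-up convention
    adj[ord[k]] <- min(1, min(m / js * p[ord[js]]))
  }
  adj
}

# Dense multivariate normal log-density via Cholesky.
dmvnorm_log <- function(x, mu, V) {
  ch <- chol(V)
  z <- backsolve(ch, x - mu, transpose = TRUE)
  -0.5 * (sum(z^2) + 2 * sum(log(diag(ch))) + length(x) * log(2 * pi))
}

# One-factor model log-likelihood by direct per-row dense densities.
cfa_loglik_bruteforce <- function(lambda, nu, theta, X) {
  V <- tcrossprod(lambda) + diag(theta, length(lambda))
  ll <- 0
  for (r in seq_len(nrow(X))) {
    o <- which(!is.na(X[r, ]))
    if (!length(o)) next
    ll <- ll + dmvnorm_log(X[r, o], nu[o], V[o, o, drop = FALSE])
  }
  ll
}

# Small complete word-bag fixture: 2 participants x 2 days.
tiny_bags <- function() {
  data.frame(
    participant_id = rep(c("A", "B"), each = 4),
    date = as.Date("2020-01-10") + c(0, 0, 1, 1, 0, 0, 1, 1),
    word = c("i", "happy", "i", "dog", "sad", "the", "i", "sick"),
    count = c(2L, 1L, 3L, 1L, 2L, 2L, 1L, 1L))
}

# Change records with the given confusion-cell counts.
records_fixture <- function(tp, fp, fn, tn) {
  mk <- function(truth, pred, k) if (k > 0)
    data.frame(participant_id = paste0(truth, pred, seq_len(k)),
               domain = "d", feature = "f", delta_marker = 0.1,
               delta_symptom = 0.1, true_class = truth, predicted_class = pred)
  out <- rbind(mk("worsening", "worsening", tp),
               mk("improvement", "worsening", fp),
               mk("worsening", "improvement", fn),
               mk("improvement", "improvement", tn))
  class(out) <- c("change_records", "data.frame")
  out
}

random_blmm_params <- function() {
  A <- matrix(stats::rnorm(4, sd = 0.5), 2); D <- crossprod(A) + diag(2) * .3
  B <- matrix(stats::rnorm(4, sd = 0.5), 2); S <- crossprod(B) + diag(2) * .3
  list(mu_s = stats::rnorm(1), mu_f = stats::rnorm(1), D = D, Sigma = S)
}

params_to_theta <- function(p) {
  c(p$mu_s, p$mu_f, langmarker:::logchol(p$D), langmarker:::logchol(p$Sigma))
}

blmm_internal_loglik <- function(p, panel) {
  pd <- langmarker:::blmm_panel_data(panel)
  -langmarker:::cpp_blmm_nll(params_to_theta(p), pd$id, pd$tp, pd$s, pd$f,
                             pd$nid, pd$ntp, FALSE)
}
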