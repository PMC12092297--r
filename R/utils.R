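# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library calls never perturb user
# simulations.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

warn_ <- function(...) warning(sprintf(...), call. = FALSE)

# Numeric central-difference Hessian of f at x.
num_hessian <- function(f, x, h_rel = 1e-4) {
  p <- length(x)
  h <- h_rel * (1 + abs(x))
  H <- matrix(0, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    xp <- x; xm <- x
    xp[i] <- x[i] + h[i]; xm[i] <- x[i] - h[i]
    H[i, i] <- (f(xp) + f(xm) - 2 * f0) / h[i]^2
    if (i > 1) for (j in seq_len(i - 1)) {
      xpp <- x; xpm <- x; xmp <- x; xmm <- x
      xpp[c(i, j)] <- x[c(i, j)] + h[c(i, j)]
      xmm[c(i, j)] <- x[c(i, j)] - h[c(i, j)]
      xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
      xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
      H[i, j] <- H[j, i] <-
        (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[i] * h[j])
    }
  }
  H
}

# Numeric gradient (central differences).
num_gradient <- function(f, x, h_rel = 1e-6) {
  p <- length(x)
  h <- h_rel * (1 + abs(x))
  g <- numeric(p)
  for (i in seq_len(p)) {
    xp <- x; xm <- x
    xp[i] <- x[i] + h[i]; xm[i] <- x[i] - h[i]
    g[i] <- (f(xp) - f(xm)) / (2 * h[i])
  }
  g
}
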