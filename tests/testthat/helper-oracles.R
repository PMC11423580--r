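# Shared oracles: independent, slow-but-obvious reference implementations
# that the package code is checked against.

# Rigidity via an explicit dense inverse of sum(lambda g g^T) + ridge I.
pr_oracle <- function(rows, ridge, g) {
  d <- length(rows[[1]]$grad_w)
  H <- diag(ridge, d)
  for (r in rows) H <- H + r$weight * tcrossprod(r$grad_w)
  1 / drop(crossprod(g, solve(H, g)))
}

# Random valued rows for a well-posed linear system.
random_rows <- function(n, d, noise = 0.1, weights = NULL) {
  G <- matrix(rnorm(n * d), n, d)
  tw <- rnorm(d)
  if (is.null(weights)) weights <- runif(n, 0.5, 2)
  lapply(seq_len(n), function(i)
    target_row(G[i, ], weight = weights[i], kind = "generic",
               value = sum(G[i, ] * tw) + rnorm(1, 0, noise)))
}

# Central finite difference of a scalar function of a position matrix.
fd_positions <- function(f, pos, h = 1e-6) {
  g <- matrix(0, nrow(pos), ncol(pos))
  for (i in seq_len(nrow(pos))) for (a in seq_len(ncol(pos))) {
    pp <- pos; pp[i, a] <- pp[i, a] + h
    pm <- pos; pm[i, a] <- pm[i, a] - h
    g[i, a] <- (f(pp) - f(pm)) / (2 * h)
  }
  g
}
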