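#' Generalized Gauss-Newton loss Hessian
#'
#' For the weighted squared loss `L(w) = sum_i lambda_i (g_i . w - y_i)^2 +
#' sigma2 |w|^2` of a linear-readout model, the Hessian at the optimum is
#' exactly `H = sum_i lambda_i g_i g_i^T + sigma2 I` (the generalized
#' Gauss-Newton form, which for nonlinear models drops second derivatives of
#' the model). All rigidities are quadratic forms in `H^{-1}`.
#'
#' `build_hessian` assembles `H` and caches a solve handle: a Cholesky factor
#' when `H` is positive definite, or an eigenvalue-clipped pseudo-solve when
#' `ridge = 0` leaves the data term singular or ill-conditioned (relative
#' condition number above 1e12). Degenerate data terms are the common case in
#' component-wise diagnostics, so the singular branch is deliberate: solving
#' against a vector with a component outside the data span raises an error
#' advising a positive ridge rather than returning an arbitrary number.
#'
#' @param rows list of [target_row()]s (may be empty when `ridge > 0` and `d`
#'   is given).
#' @param ridge regularization `sigma^2` folded in as `ridge * I`. `NULL`
#'   selects the scale-aware default `1e-8 * mean(diag(data term))`.
#' @param d weight dimension, required only when `rows` is empty.
#' @return An object of class `hessian_state` with elements `H`, `ridge`,
#'   `update_log` (count of rank-one modifications) and a cached factor.
#' @export
build_hessian <- function(rows = list(), ridge = NULL, d = NULL) {
  if (length(rows) > 0L) {
    rl <- rows_to_matrix(rows)
    d <- ncol(rl$G)
    Hdata <- crossprod(rl$G * sqrt(rl$lambda))
  } else {
    if (is.null(d)) stop("d must be given when rows is empty")
    Hdata <- matrix(0, d, d)
  }
  if (is.null(ridge)) ridge <- 1e-8 * mean(diag(Hdata))
  if (length(rows) == 0L && ridge <= 0)
    stop("need rows or ridge > 0")
  if (ridge < 0) stop("ridge must be nonnegative")
  H <- Hdata + diag(ridge, d)
  H <- (H + t(H)) / 2
  h <- list(H = H, ridge = ridge, update_log = 0L)
  class(h) <- "hessian_state"
  refactor(h)
}

# (Re)compute the cached solve handle. Cholesky when positive definite and
# well conditioned; otherwise a clipped eigendecomposition pseudo-solve.
refactor <- function(h) {
  ok <- FALSE
  if (h$ridge > 0) {
    R <- tryCatch(chol(h$H), error = function(e) NULL)
    if (!is.null(R)) {
      h$factor <- list(type = "chol", R = R)
      ok <- TRUE
    }
  }
  if (!ok) {
    e <- eigen(h$H, symmetric = TRUE)
    tol <- max(abs(e$values)) * 1e-12
    keep <- e$values > tol
    if (h$ridge == 0 && all(keep) &&
        min(e$values) > max(e$values) / 1e12) {
      # full rank and well conditioned even without ridge
      h$factor <- list(type = "eigen", V = e$vectors, ev = e$values,
                       keep = keep, exact = TRUE)
    } else {
      h$factor <- list(type = "eigen", V = e$vectors, ev = e$values,
                       keep = keep, exact = all(keep))
    }
  }
  h
}

#' @export
print.hessian_state <- function(x, ...) {
  cat("<hessian_state> d=", nrow(x$H), " ridge=", format(x$ridge),
      " updates=", x$update_log, " factor=", x$factor$type, "\n", sep = "")
  invisible(x)
}

hessian_solve <- function(h, b) {
  f <- h$factor
  if (f$type == "chol") {
    y <- backsolve(f$R, b, transpose = TRUE)
    return(backsolve(f$R, y))
  }
  coef <- drop(crossprod(f$V, b))
  if (!f$exact) {
    resid <- sqrt(sum(coef[!f$keep]^2))
    if (resid > 1e-8 * sqrt(sum(coef^2)))
      stop("Hessian is singular and the vector has a component outside the ",
           "data span; set ridge > 0 to regularize")
  }
  inv <- ifelse(f$keep, 1 / f$ev, 0)
  drop(f$V %*% (inv * coef))
}

#' Rank-one update of a Hessian
#'
#' Adds `lambda g g^T` for one target row and refreshes the solve handle by
#' refactoring the stored matrix, which is definitionally identical to
#' rebuilding from the concatenated row list. A negative `weight` performs the
#' algebraic downdate; note that downdates can be numerically delicate when
#' they remove most of the curvature along a direction.
#'
#' @param h a `hessian_state`.
#' @param row a [target_row()] (its `weight` may be negative for a downdate).
#' @return the updated `hessian_state`.
#' @export
rank_one_update <- function(h, row) {
  stopifnot(inherits(h, "hessian_state"))
  g <- row$grad_w
  if (length(g) != nrow(h$H))
    stop("dimension mismatch: row has length ", length(g),
         ", Hessian is ", nrow(h$H), "x", nrow(h$H))
  lam <- row$weight
  if (inherits(row, "target_row") && lam == 0) {
    h$update_log <- h$update_log + 1L
    return(h)
  }
  h$H <- h$H + lam * tcrossprod(g)
  h$H <- (h$H + t(h$H)) / 2
  h$update_log <- h$update_log + 1L
  refactor(h)
}

# Downdate helper used by tests: rank_one_update with a sign-flipped weight.
flip_weight <- function(row) {
  row$weight <- -row$weight
  class(row) <- class(row)
  row
}

#' Metric norm of a vector under the inverse Hessian
#'
#' Returns `g^T H^{-1} g`, the squared norm of `g` in the metric defined by
#' `H^{-1}`. The reciprocal of this quantity is the prediction rigidity.
#'
#' @param h a `hessian_state`.
#' @param g numeric vector.
#' @return nonnegative scalar; 0 iff `g` is the zero vector.
#' @export
metric_norm <- function(h, g) {
  stopifnot(inherits(h, "hessian_state"))
  g <- as.numeric(g)
  if (length(g) != nrow(h$H))
    stop("dimension mismatch")
  if (all(g == 0)) return(0)
  sum(g * hessian_solve(h, g))
}

# Hypothetical metric norm after adding rows, without mutating h.
# Woodbury: (H + G^T L G)^{-1} = H^{-1} - H^{-1} G^T (L^{-1} + G H^{-1} G^T)^{-1} G H^{-1}
hypothetical_metric_norm <- function(h, rows, g) {
  base <- metric_norm(h, g)
  rl <- rows_to_matrix(rows)
  nz <- rl$lambda != 0
  if (!any(nz)) return(base)
  G <- rl$G[nz, , drop = FALSE]
  lam <- rl$lambda[nz]
  s <- hessian_solve(h, g)
  A <- apply(G, 1, function(u) hessian_solve(h, u))  # d x k
  A <- matrix(A, nrow = nrow(h$H))
  M <- diag(1 / lam, length(lam)) + G %*% A
  Gs <- drop(G %*% s)
  base - drop(crossprod(Gs, solve(M, Gs)))
}
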