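#' A single scalar training target
#'
#' One row of the weighted squared loss
#' `L(w) = sum_i lambda_i (g_i . w - y_i)^2 + sigma2 |w|^2`.
#' `grad_w` is the gradient of the model prediction with respect to the
#' readout weights; for a linear model it is the (summed) feature row itself.
#'
#' @param grad_w numeric vector of length `d`.
#' @param weight nonnegative loss weight `lambda`.
#' @param kind one of `"energy"`, `"force"`, `"stress"`, `"generic"`.
#' @param value observed target value (may be `NA` when only curvature, not
#'   residuals, is needed: rigidities do not use target values).
#'
#' @return An object of class `target_row`.
#' @export
target_row <- function(grad_w, weight = 1, kind = c("generic", "energy",
                                                    "force", "stress"),
                       value = NA_real_) {
  kind <- match.arg(kind)
  grad_w <- as.numeric(grad_w)
  if (!all(is.finite(grad_w))) stop("grad_w must be finite")
  weight <- as.numeric(weight)
  if (length(weight) != 1L || is.na(weight) || weight < 0)
    stop("weight must be a single nonnegative number")
  structure(list(grad_w = grad_w, weight = weight, kind = kind,
                 value = as.numeric(value)),
            class = "target_row")
}

#' @export
print.target_row <- function(x, ...) {
  cat("<target_row> kind=", x$kind, " lambda=", format(x$weight),
      " d=", length(x$grad_w), " value=", format(x$value), "\n", sep = "")
  invisible(x)
}

rows_to_matrix <- function(rows) {
  if (length(rows) == 0L) stop("need at least one target row")
  d <- length(rows[[1]]$grad_w)
  G <- matrix(0, length(rows), d)
  for (i in seq_along(rows)) {
    gi <- rows[[i]]$grad_w
    if (length(gi) != d)
      stop("inconsistent row dimensions: row ", i, " has length ",
           length(gi), ", expected ", d)
    G[i, ] <- gi
  }
  list(G = G,
       lambda = vapply(rows, function(r) r$weight, 0),
       values = vapply(rows, function(r) r$value, 0))
}

#' Assemble the energy-style target row of a structure
#'
#' The global prediction of a structure is the sum of its environments' local
#' predictions, so its weight-space gradient is the sum of the environment
#' feature rows.
#'
#' @param fs a [feature_set()].
#' @param structure_id structure id.
#' @param weight loss weight `lambda_E`.
#' @param value observed global target (optional).
#' @return a [target_row()] with `kind = "energy"`.
#' @export
assemble_energy_row <- function(fs, structure_id, weight = 1,
                                value = NA_real_) {
  idx <- structure_envs(fs, structure_id)
  g <- colSums(fs$env_features[idx, , drop = FALSE])
  target_row(g, weight = weight, kind = "energy", value = value)
}

#' Assemble force-style target rows of a structure
#'
#' One row per Cartesian coordinate of the structure's environments, with
#' `grad_w = -sum_j d f_j / d x_alpha` (force = minus the gradient of the
#' predicted energy). Requires `env_gradients` on the feature set, laid out
#' with 3 coordinates per environment in environment order.
#'
#' @inheritParams assemble_energy_row
#' @param weight loss weight `lambda_f` applied to every coordinate row.
#' @param values optional numeric vector of observed force components, one per
#'   coordinate of the structure.
#' @return list of [target_row()]s with `kind = "force"`.
#' @export
assemble_force_rows <- function(fs, structure_id, weight = 1, values = NULL) {
  if (is.null(fs$env_gradients))
    stop("feature_set carries no env_gradients; force rows unavailable")
  idx <- structure_envs(fs, structure_id)
  coords <- as.vector(vapply(idx, function(j) (3L * (j - 1L)) + 1:3,
                             integer(3)))
  if (max(coords) > dim(fs$env_gradients)[2])
    stop("env_gradients coordinate axis too short for structure ",
         structure_id)
  if (!is.null(values) && length(values) != length(coords))
    stop("values must supply one force component per coordinate")
  lapply(seq_along(coords), function(a) {
    # d(total energy)/dw per coordinate: sum over this structure's envs
    g <- numeric(ncol(fs$env_features))
    for (j in idx) g <- g + fs$env_gradients[j, coords[a], ]
    target_row(-g, weight = weight, kind = "force",
               value = if (is.null(values)) NA_real_ else values[a])
  })
}

#' Fitted or supplied readout weights
#'
#' @param w numeric weight vector.
#' @param provenance `"fitted"` or `"supplied"`.
#' @return object of class `pr_weights`.
#' @export
pr_weights <- function(w, provenance = c("supplied", "fitted")) {
  provenance <- match.arg(provenance)
  structure(list(w = as.numeric(w), provenance = provenance),
            class = "pr_weights")
}

#' Ridge fit of the readout weights
#'
#' Minimizes `sum_i lambda_i (g_i . w - y_i)^2 + ridge * |w|^2` by solving the
#' normal equations. With `ridge = 0` the weighted normal matrix must be full
#' rank.
#'
#' @param rows list of [target_row()]s with non-`NA` values.
#' @param ridge regularization strength `sigma^2 >= 0`.
#' @return a [pr_weights()] with `provenance = "fitted"`.
#' @export
fit_ridge <- function(rows, ridge = 0) {
  rl <- rows_to_matrix(rows)
  if (any(is.na(rl$values)))
    stop("all rows must carry target values for fitting")
  if (ridge < 0) stop("ridge must be nonnegative")
  d <- ncol(rl$G)
  A <- crossprod(rl$G * sqrt(rl$lambda)) + diag(ridge, d)
  b <- crossprod(rl$G, rl$lambda * rl$values)
  if (ridge == 0) {
    qrA <- qr(A)
    if (qrA$rank < d)
      stop("rank deficient system at ridge = 0: rank ", qrA$rank,
           " < ", d, " weights; supply ridge > 0")
  }
  w <- solve(A, b)
  pr_weights(drop(w), provenance = "fitted")
}

#' Evaluate a prediction for a query vector
#'
#' Returns `g . w`, the model prediction whose weight-space gradient is the
#' query's `g` (global, local or component prediction alike, by linearity).
#'
#' @param object a [pr_weights()].
#' @param query a [query_vector()] or plain numeric vector.
#' @param ... unused.
#' @return numeric scalar.
#' @export
predict.pr_weights <- function(object, query, ...) {
  g <- if (inherits(query, "query_vector")) query$g else as.numeric(query)
  if (length(g) != length(object$w))
    stop("dimension mismatch: query has length ", length(g),
         ", weights have length ", length(object$w))
  sum(g * object$w)
}

#' Evaluate the weighted squared loss
#'
#' `L(w) = sum_i lambda_i (g_i . w - y_i)^2 + ridge |w|^2`. This is the loss
#' convention used throughout: no global factor of 1/2, so that the curvature
#' of the loss is exactly `H = sum lambda g g^T + ridge I` and the constrained
#' loss increase equals `R * delta^2`.
#'
#' @inheritParams fit_ridge
#' @param w numeric weight vector or [pr_weights()].
#' @return numeric scalar loss.
#' @export
loss_value <- function(rows, ridge, w) {
  if (inherits(w, "pr_weights")) w <- w$w
  rl <- rows_to_matrix(rows)
  if (any(is.na(rl$values)))
    stop("all rows must carry target values to evaluate the loss")
  r <- drop(rl$G %*% w) - rl$values
  sum(rl$lambda * r^2) + ridge * sum(w^2)
}
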