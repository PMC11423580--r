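#' Query vector for a rigidity evaluation
#'
#' A query vector `g` is the weight-space gradient of the prediction whose
#' robustness is being probed. Three forms are used:
#' \describe{
#'   \item{global}{`g` is the sum of a structure's environment feature rows:
#'     the gradient of the global prediction (PR).}
#'   \item{local}{`g` is a single environment's feature row: the gradient of
#'     one local prediction (LPR).}
#'   \item{component}{`g` is the global row masked to one declared column
#'     block, i.e. the gradient of that additive prediction component (CPR).}
#' }
#'
#' @param g numeric vector.
#' @param tag one of `"global"`, `"local"`, `"component"`.
#' @param block block name (required when `tag = "component"`).
#' @param subject_id structure or environment identifier for reporting.
#' @return object of class `query_vector`.
#' @export
query_vector <- function(g, tag = c("global", "local", "component"),
                         block = NULL, subject_id = NA) {
  tag <- match.arg(tag)
  if (tag == "component" && is.null(block))
    stop("component queries must name their block")
  structure(list(g = as.numeric(g), tag = tag, block = block,
                 subject_id = subject_id),
            class = "query_vector")
}

#' @rdname query_vector
#' @param fs a [feature_set()].
#' @param structure_id structure id.
#' @export
global_query <- function(fs, structure_id) {
  row <- assemble_energy_row(fs, structure_id)
  query_vector(row$grad_w, "global", subject_id = structure_id)
}

#' @rdname query_vector
#' @param env_id environment (row) index.
#' @export
local_query <- function(fs, env_id) {
  env_id <- as.integer(env_id)
  if (env_id < 1L || env_id > nrow(fs$env_features))
    stop("unknown env_id: ", env_id)
  query_vector(fs$env_features[env_id, ], "local", subject_id = env_id)
}

#' @rdname query_vector
#' @export
component_query <- function(fs, structure_id, block) {
  cols <- block_columns(fs, block)
  row <- assemble_energy_row(fs, structure_id)
  g <- numeric(length(row$grad_w))
  g[cols] <- row$grad_w[cols]
  query_vector(g, "component", block = block, subject_id = structure_id)
}

#' Prediction rigidity of a query
#'
#' The prediction rigidity is `R = 1 / (g^T H^{-1} g)`: the coefficient by
#' which the minimum loss increases when the queried prediction is constrained
#' to move by `delta` away from its unconstrained optimum
#' (`dL = R * delta^2`). Large `R` means the training data pin the prediction
#' down strongly; `1/R` is the (unit-noise) predictive variance.
#'
#' @param h a [build_hessian()] state.
#' @param q a [query_vector()] (or plain numeric vector, treated as global).
#' @return positive scalar rigidity.
#' @export
prediction_rigidity <- function(h, q) {
  g <- if (inherits(q, "query_vector")) q$g else as.numeric(q)
  if (all(g == 0))
    stop("query vector is zero: the prediction is not represented by the ",
         "model, so its rigidity is undefined")
  mn <- metric_norm(h, g)
  1 / mn
}

#' Local prediction rigidity of an environment
#'
#' @param h a [build_hessian()] state.
#' @param fs a [feature_set()].
#' @param env_id environment (row) index.
#' @return positive scalar LPR.
#' @export
local_prediction_rigidity <- function(h, fs, env_id) {
  prediction_rigidity(h, local_query(fs, env_id))
}

#' Component-wise prediction rigidity of a structure
#'
#' Rigidity of one additive component of the global prediction: the query is
#' the global row with all columns outside the named block set to zero.
#'
#' @inheritParams local_prediction_rigidity
#' @param structure_id structure id.
#' @param block block name declared in `fs$blocks`.
#' @return positive scalar CPR.
#' @export
component_prediction_rigidity <- function(h, fs, structure_id, block) {
  q <- component_query(fs, structure_id, block)
  if (all(q$g == 0))
    stop("component query is identically zero for structure ", structure_id,
         ", block '", block, "'")
  prediction_rigidity(h, q)
}

#' Last-layer prediction rigidity
#'
#' For a model that is linear in its final readout, the rigidity of a
#' prediction with last-layer features `f_star` given the training feature
#' matrix `F` is `R = 1 / (f_star^T (F^T F + sigma2 I)^{-1} f_star)`. This is
#' the generic rigidity with unit-weight rows, and the implementation is
#' required (and tested) to agree with that path to machine precision.
#'
#' @param F numeric matrix `n_train x d` of last-layer features (may have zero
#'   rows when `ridge > 0`).
#' @param f_star numeric query feature vector of length `d`.
#' @param ridge regularization `sigma^2`.
#' @return positive scalar rigidity.
#' @export
last_layer_pr <- function(F, f_star, ridge = 0) {
  F <- as.matrix(F)
  f_star <- as.numeric(f_star)
  if (nrow(F) > 0 && ncol(F) != length(f_star))
    stop("dimension mismatch: F has ", ncol(F), " columns, f_star has length ",
         length(f_star))
  d <- length(f_star)
  A <- (if (nrow(F) > 0) crossprod(F) else matrix(0, d, d)) + diag(ridge, d)
  if (all(f_star == 0)) stop("query vector is zero: rigidity undefined")
  1 / drop(crossprod(f_star, solve(A, f_star)))
}

#' Predictive variance from a rigidity
#'
#' The inverse rigidity is a (relative) predictive variance; `scale` is the
#' noise-level calibration constant `sigma_noise^2` (default 1).
#'
#' @param R positive rigidity.
#' @param scale positive variance scale.
#' @return `scale / R`.
#' @export
variance_from_pr <- function(R, scale = 1) {
  if (!is.numeric(R) || any(R <= 0)) stop("rigidity must be positive")
  scale / R
}

#' Constrained-loss curvature probe
#'
#' Empirically realizes the defining property of the rigidity: minimize the
#' loss subject to the queried prediction being displaced by `delta` from its
#' unconstrained optimum, and report the loss increase. Under the package's
#' loss convention the increase equals `R * delta^2` exactly; this function
#' computes it by actually evaluating the loss at the constrained and
#' unconstrained optima.
#'
#' @param rows list of valued [target_row()]s defining the loss.
#' @param ridge regularization `sigma^2`.
#' @param w_o the unconstrained optimum (as from [fit_ridge()]).
#' @param q a [query_vector()].
#' @param delta prediction perturbation (target units).
#' @return list of class `curvature_probe` with `delta` and `delta_loss`.
#' @export
curvature_probe <- function(rows, ridge, w_o, q, delta) {
  if (inherits(w_o, "pr_weights")) w_o <- w_o$w
  g <- q$g
  if (all(g == 0)) stop("query vector is zero: constraint infeasible")
  h <- build_hessian(rows, ridge = ridge)
  s <- hessian_solve(h, g)
  mn <- sum(g * s)
  # constrained optimum: w_o displaced along H^{-1} g
  w_c <- w_o + delta * s / mn
  dl <- loss_value(rows, ridge, w_c) - loss_value(rows, ridge, w_o)
  structure(list(delta = delta, delta_loss = dl), class = "curvature_probe")
}

#' Rigidity report over a set of queries
#'
#' @param h a [build_hessian()] state.
#' @param queries list of [query_vector()]s.
#' @return object of class `rigidity_report`: a data frame of
#'   `subject_id`, `tag`, `value` plus normalization metadata.
#' @export
rigidity_report <- function(h, queries) {
  if (length(queries) == 0L) stop("no queries supplied")
  df <- data.frame(
    subject_id = vapply(queries, function(q) as.character(q$subject_id), ""),
    tag = vapply(queries, function(q) q$tag, ""),
    value = vapply(queries, function(q) prediction_rigidity(h, q), 0),
    stringsAsFactors = FALSE)
  df$normalized <- df$value
  structure(list(values = df, normalization = "raw", reference = NA_real_,
                 ridge = h$ridge),
            class = "rigidity_report")
}

#' @export
print.rigidity_report <- function(x, ...) {
  cat("<rigidity_report> ", nrow(x$values), " queries, normalization = ",
      x$normalization, "\n", sep = "")
  print(utils::head(x$values, 10))
  invisible(x)
}

#' Normalize a rigidity report
#'
#' @param rep a [rigidity_report()].
#' @param mode `"raw"`, `"max"` (divide by the maximum observed value) or
#'   `"reference"` (divide by a supplied positive reference).
#' @param reference positive reference value (mode `"reference"`).
#' @return the report with its `normalized` column updated.
#' @export
normalize_report <- function(rep, mode = c("max", "reference", "raw"),
                             reference = NULL) {
  mode <- match.arg(mode)
  if (nrow(rep$values) == 0L) stop("empty report")
  if (mode == "max") {
    reference <- max(rep$values$value)
  } else if (mode == "reference") {
    if (is.null(reference) || reference <= 0)
      stop("reference mode needs a positive reference value")
  } else {
    reference <- 1
  }
  rep$values$normalized <- rep$values$value / reference
  rep$normalization <- mode
  rep$reference <- reference
  rep
}

#' Relative rigidity along a trajectory
#'
#' Computes the PR of each frame's query, divides by the mean of a set of
#' reference rigidities (e.g. the test-set average), and appends a trailing
#' moving average (prefix frames are averaged over the available window). Used
#' to monitor whether a simulation driven by the model stays within the
#' rigidity range the model was validated on.
#'
#' @param h a [build_hessian()] state.
#' @param frame_queries list of [query_vector()]s, or a numeric matrix whose
#'   rows are query vectors, one per frame in order.
#' @param reference_prs numeric vector of reference rigidities (nonempty).
#' @param window trailing moving-average window length (frames, >= 1).
#' @return data frame with columns `frame`, `pr`, `relative_pr`,
#'   `moving_average`.
#' @export
monitor_trajectory <- function(h, frame_queries, reference_prs, window = 200) {
  if (is.matrix(frame_queries))
    frame_queries <- lapply(seq_len(nrow(frame_queries)), function(i)
      query_vector(frame_queries[i, ], "global", subject_id = i))
  if (length(frame_queries) == 0L) stop("empty trajectory")
  if (length(reference_prs) == 0L) stop("reference_prs must be nonempty")
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  pr <- vapply(frame_queries, function(q) prediction_rigidity(h, q), 0)
  rel <- pr / mean(reference_prs)
  ma <- vapply(seq_along(rel), function(i)
    mean(rel[max(1L, i - window + 1L):i]), 0)
  data.frame(frame = seq_along(rel), pr = pr, relative_pr = rel,
             moving_average = ma)
}

#' Write a rigidity report to CSV or JSON
#'
#' @param rep a [rigidity_report()].
#' @param path output file path; format inferred from the extension
#'   (`.csv` or `.json`) unless given.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(rep, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path)) "json" else "csv"
  if (format == "csv") {
    utils::write.csv(rep$values, path, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(normalization = rep$normalization, reference = rep$reference,
           ridge = rep$ridge, values = rep$values),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
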