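#' Per-environment feature set for an additive model
#'
#' An additive model predicts a global property of a structure as the sum of
#' local predictions, one per environment (atom, bead, cluster), each of which
#' is a linear readout `w . f_j` of that environment's feature row. A
#' `feature_set` bundles the feature rows with the environment-to-structure
#' map, optional named column blocks labelling additive prediction components
#' (e.g. body orders or short-/long-range descriptors), and optional feature
#' gradients with respect to Cartesian coordinates for force-style targets.
#'
#' @param env_features numeric matrix, one row per environment, `d` columns.
#' @param structure_of_env integer vector mapping each environment (row) to a
#'   structure id in `1..n_structures`. Every environment belongs to exactly
#'   one structure.
#' @param blocks optional named list of length-2 integer vectors
#'   `c(first, last)` giving 1-based inclusive column ranges that label
#'   additive prediction components. Ranges must be disjoint and cover a
#'   prefix of (or all) columns.
#' @param env_gradients optional numeric array of dimension
#'   `n_env x n_coords x d` holding `d f_j / d x_alpha` (units 1/length). The
#'   coordinate axis enumerates all Cartesian coordinates of the feature set
#'   (3 per environment when environments are atoms).
#'
#' @return An object of class `feature_set`.
#' @export
feature_set <- function(env_features, structure_of_env, blocks = NULL,
                        env_gradients = NULL) {
  env_features <- as.matrix(env_features)
  storage.mode(env_features) <- "double"
  n_env <- nrow(env_features)
  d <- ncol(env_features)
  structure_of_env <- as.integer(structure_of_env)
  if (length(structure_of_env) != n_env)
    stop("structure_of_env must have one entry per environment (",
         n_env, " rows, got ", length(structure_of_env), " entries)")
  if (any(is.na(structure_of_env)) || any(structure_of_env < 1L))
    stop("structure_of_env entries must be positive integers")
  if (!all(is.finite(env_features)))
    stop("env_features must be finite")
  if (!is.null(blocks)) {
    if (is.null(names(blocks)) || any(!nzchar(names(blocks))))
      stop("blocks must be a named list")
    blocks <- lapply(blocks, function(b) as.integer(b))
    for (nm in names(blocks)) {
      b <- blocks[[nm]]
      if (length(b) != 2L || b[1] < 1L || b[2] > d || b[1] > b[2])
        stop("block '", nm, "' is not a valid column range within 1..", d)
    }
    covered <- sort(unname(unlist(lapply(blocks, function(b) b[1]:b[2]))))
    if (anyDuplicated(covered))
      stop("block column ranges must be disjoint")
    if (!identical(covered, seq_along(covered)))
      stop("block ranges must cover a contiguous prefix of the columns")
  }
  if (!is.null(env_gradients)) {
    env_gradients <- as.array(env_gradients)
    dg <- dim(env_gradients)
    if (length(dg) != 3L || dg[1] != n_env || dg[3] != d)
      stop("env_gradients must be an n_env x n_coords x d array matching ",
           "env_features (n_env = ", n_env, ", d = ", d, ")")
  }
  structure(
    list(env_features = env_features,
         structure_of_env = structure_of_env,
         blocks = blocks,
         env_gradients = env_gradients),
    class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat("<feature_set> ", nrow(x$env_features), " environments, ",
      length(unique(x$structure_of_env)), " structures, d = ",
      ncol(x$env_features), "\n", sep = "")
  if (!is.null(x$blocks))
    cat("  blocks:", paste0(names(x$blocks), "[",
        vapply(x$blocks, function(b) paste(b, collapse = ":"), ""), "]",
        collapse = ", "), "\n")
  if (!is.null(x$env_gradients))
    cat("  gradients: present (", dim(x$env_gradients)[2], " coordinates)\n",
        sep = "")
  invisible(x)
}

#' Environments belonging to a structure
#'
#' @param fs a [feature_set()].
#' @param structure_id integer structure id.
#' @return integer vector of environment (row) indices.
#' @export
structure_envs <- function(fs, structure_id) {
  stopifnot(inherits(fs, "feature_set"))
  idx <- which(fs$structure_of_env == as.integer(structure_id))
  if (length(idx) == 0L)
    stop("unknown structure_id: ", structure_id)
  idx
}

block_columns <- function(fs, block) {
  if (is.null(fs$blocks) || is.null(fs$blocks[[block]]))
    stop("block '", block, "' is not declared in this feature_set")
  b <- fs$blocks[[block]]
  b[1]:b[2]
}
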