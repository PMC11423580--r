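#' Rigidity gain from hypothetically adding candidate rows
#'
#' Evaluates how an objective over target rigidities would change if all of a
#' candidate's rows were added to the training set, without mutating the
#' Hessian (low-rank algebra on the cached solve handle).
#'
#' @param h a [build_hessian()] state.
#' @param candidate_rows list of [target_row()]s forming one candidate.
#' @param targets nonempty list of [query_vector()]s.
#' @param objective aggregation over targets: `"mean"` (default), `"min"` or
#'   `"sum"`.
#' @return scalar `objective(PR after) - objective(PR before)`.
#' @export
pr_gain <- function(h, candidate_rows, targets,
                    objective = c("mean", "min", "sum")) {
  objective <- match.arg(objective)
  if (length(targets) == 0L) stop("targets must be nonempty")
  agg <- switch(objective, mean = mean, min = min, sum = sum)
  before <- vapply(targets, function(q) prediction_rigidity(h, q), 0)
  after <- vapply(targets, function(q)
    1 / hypothetical_metric_norm(h, candidate_rows, q$g), 0)
  agg(after) - agg(before)
}

#' Greedy rigidity-guided dataset augmentation
#'
#' At each of `k` iterations, scores every remaining pool candidate by
#' [pr_gain()] over the target queries, selects the argmax (ties broken by the
#' lexicographically lowest candidate id), and commits its rows to the Hessian
#' with [rank_one_update()]. This is the iterative strategy of picking, from a
#' candidate pool, the structure that most increases the rigidity of the
#' target systems, updating the curvature as structures are selected.
#'
#' @param h a [build_hessian()] state (not mutated; a copy is grown).
#' @param pool named list; each element is a list of [target_row()]s (or a
#'   single `target_row`) representing one candidate structure.
#' @param targets nonempty list of [query_vector()]s.
#' @param k number of candidates to select (`k <= length(pool)`).
#' @param objective aggregation over targets, as in [pr_gain()].
#' @return object of class `selection_trace`: list with `steps` (data frame of
#'   iteration, candidate, objective before/after, gain), `pr_before` /
#'   `pr_after` matrices (step x target), `objective`, `pool_ids`, and the
#'   final `hessian`.
#' @export
greedy_augment <- function(h, pool, targets, k,
                           objective = c("mean", "min", "sum")) {
  objective <- match.arg(objective)
  if (length(pool) == 0L) stop("empty pool")
  if (is.null(names(pool)) || any(!nzchar(names(pool))))
    stop("pool must be a named list of candidates")
  if (k > length(pool)) stop("k exceeds pool size")
  pool <- lapply(pool, function(cand)
    if (inherits(cand, "target_row")) list(cand) else cand)
  agg <- switch(objective, mean = mean, min = min, sum = sum)
  remaining <- sort(names(pool))
  steps <- data.frame(iteration = integer(), candidate = character(),
                      objective_before = double(), objective_after = double(),
                      gain = double(), stringsAsFactors = FALSE)
  nt <- length(targets)
  pr_before <- matrix(NA_real_, k, nt)
  pr_after <- matrix(NA_real_, k, nt)
  for (it in seq_len(k)) {
    cur <- vapply(targets, function(q) prediction_rigidity(h, q), 0)
    obj_before <- agg(cur)
    best <- NULL
    best_obj <- -Inf
    best_prs <- NULL
    for (id in remaining) {
      prs <- vapply(targets, function(q)
        1 / hypothetical_metric_norm(h, pool[[id]], q$g), 0)
      o <- agg(prs)
      # strict comparison over sorted ids: ties go to the lowest candidate id
      if (o > best_obj) {
        best <- id
        best_obj <- o
        best_prs <- prs
      }
    }
    for (row in pool[[best]]) h <- rank_one_update(h, row)
    remaining <- setdiff(remaining, best)
    pr_before[it, ] <- cur
    pr_after[it, ] <- best_prs
    steps <- rbind(steps, data.frame(
      iteration = it, candidate = best, objective_before = obj_before,
      objective_after = best_obj, gain = best_obj - obj_before,
      stringsAsFactors = FALSE))
  }
  structure(list(steps = steps, pr_before = pr_before, pr_after = pr_after,
                 objective = objective, pool_ids = sort(names(pool)),
                 hessian = h),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("<selection_trace> objective =", x$objective, "\n")
  print(x$steps)
  invisible(x)
}

#' Rank environments by local prediction rigidity
#'
#' Ascending LPR order: the first element is the environment the model is
#' least certain about, i.e. the natural active-learning target. Ties are
#' broken by ascending environment id.
#'
#' @param h a [build_hessian()] state.
#' @param fs a [feature_set()].
#' @param env_ids environment indices to rank (default: all).
#' @return data frame with columns `env_id`, `lpr`, sorted ascending by `lpr`.
#' @export
rank_by_lpr <- function(h, fs, env_ids = NULL) {
  if (is.null(env_ids)) env_ids <- seq_len(nrow(fs$env_features))
  if (length(env_ids) == 0L) stop("env_ids must be nonempty")
  lpr <- vapply(env_ids, function(j) local_prediction_rigidity(h, fs, j), 0)
  ord <- order(lpr, env_ids)
  data.frame(env_id = env_ids[ord], lpr = lpr[ord])
}

#' LPR enhancement from named candidate sets
#'
#' For each named candidate set, computes the percent change in the LPR of a
#' chosen environment if the set's rows were added to the training set `times`
#' times over (repeated addition of the same samples is meaningful and
#' supported), without mutating the Hessian.
#'
#' @param h a [build_hessian()] state.
#' @param fs a [feature_set()].
#' @param env_id the environment whose LPR is being enhanced.
#' @param candidate_sets named list; each element a nonempty list of
#'   [target_row()]s (or a single `target_row`).
#' @param times how many copies of each set to add (default 1).
#' @return named numeric vector of percent LPR changes,
#'   `100 * (after - before) / before`.
#' @export
lpr_enhancement <- function(h, fs, env_id, candidate_sets, times = 1) {
  q <- local_query(fs, env_id)
  before <- prediction_rigidity(h, q)
  if (length(candidate_sets) == 0L) stop("no candidate sets supplied")
  vapply(candidate_sets, function(cand) {
    if (inherits(cand, "target_row")) cand <- list(cand)
    if (length(cand) == 0L) stop("empty candidate set")
    rows <- rep(cand, times)
    after <- 1 / hypothetical_metric_norm(h, rows, q$g)
    100 * (after - before) / before
  }, 0)
}

#' Write a selection trace to CSV or JSON
#'
#' @param trace a [greedy_augment()] result.
#' @param path output path (`.csv` or `.json`).
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path)) "json" else "csv"
  if (format == "csv") {
    utils::write.csv(trace$steps, path, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(objective = trace$objective, pool_ids = trace$pool_ids,
           steps = trace$steps, pr_before = trace$pr_before,
           pr_after = trace$pr_after),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
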