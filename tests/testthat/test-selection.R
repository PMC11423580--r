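test_that("pr_gain equals the rebuild difference", {
  set.seed(71)
  rows <- random_rows(20, 5)
  cand <- random_rows(3, 5)
  ridge <- 0.1
  h <- build_hessian(rows, ridge = ridge)
  targets <- lapply(1:4, function(i) query_vector(rnorm(5), "global"))
  h_after <- build_hessian(c(rows, cand), ridge = ridge)
  for (obj in c("mean", "min", "sum")) {
    agg <- switch(obj, mean = mean, min = min, sum = sum)
    before <- agg(vapply(targets, function(q) prediction_rigidity(h, q), 0))
    after <- agg(vapply(targets, function(q)
      prediction_rigidity(h_after, q), 0))
    expect_equal(pr_gain(h, cand, targets, objective = obj), after - before,
                 tolerance = 1e-9)
  }
  expect_error(pr_gain(h, cand, list()), "nonempty")
})

test_that("greedy_augment matches a brute-force reimplementation", {
  set.seed(72)
  d <- 6
  rows <- random_rows(25, d)
  ridge <- 0.05
  pool <- stats::setNames(lapply(1:12, function(i) list(target_row(rnorm(d),
                                                                   1))),
                          sprintf("c%02d", 1:12))
  targets <- lapply(1:5, function(i) query_vector(rnorm(d), "global"))
  k <- 4
  trace <- greedy_augment(build_hessian(rows, ridge = ridge), pool, targets,
                          k)
  # brute force: at each step rebuild every candidate Hessian from scratch
  chosen <- character(0)
  current <- rows
  for (it in seq_len(k)) {
    ids <- sort(setdiff(names(pool), chosen))
    objs <- vapply(ids, function(id) {
      hh <- build_hessian(c(current, pool[[id]]), ridge = ridge)
      mean(vapply(targets, function(q) prediction_rigidity(hh, q), 0))
    }, 0)
    best <- ids[which.max(objs)]
    chosen <- c(chosen, best)
    current <- c(current, pool[[best]])
    expect_equal(trace$steps$objective_after[it], max(objs),
                 tolerance = 1e-9)
  }
  expect_identical(trace$steps$candidate, chosen)
  expect_equal(trace$steps$gain,
               trace$steps$objective_after - trace$steps$objective_before)
})

test_that("greedy ties go to the lowest candidate id", {
  set.seed(73)
  rows <- random_rows(10, 3)
  g <- rnorm(3)
  pool <- list(zz = list(target_row(g, 1)), aa = list(target_row(g, 1)))
  targets <- list(query_vector(rnorm(3), "global"))
  trace <- greedy_augment(build_hessian(rows, ridge = 0.1), pool, targets, 1)
  expect_identical(trace$steps$candidate, "aa")
})

test_that("greedy_augment validates its inputs and records PRs", {
  set.seed(74)
  rows <- random_rows(10, 3)
  h <- build_hessian(rows, ridge = 0.1)
  pool <- list(a = list(target_row(rnorm(3), 1)))
  targets <- list(query_vector(rnorm(3), "global"))
  expect_error(greedy_augment(h, list(), targets, 1), "empty pool")
  expect_error(greedy_augment(h, unname(pool), targets, 1), "named")
  expect_error(greedy_augment(h, pool, targets, 2), "exceeds pool size")
  trace <- greedy_augment(h, pool, targets, 1)
  expect_equal(dim(trace$pr_before), c(1, 1))
  expect_equal(trace$pr_before[1, 1], prediction_rigidity(h, targets[[1]]))
  expect_equal(trace$pr_after[1, 1],
               prediction_rigidity(trace$hessian, targets[[1]]),
               tolerance = 1e-9)
  # a single target_row is promoted to a one-row candidate
  trace2 <- greedy_augment(h, list(a = target_row(rnorm(3), 1)), targets, 1)
  expect_equal(nrow(trace2$steps), 1)
})

test_that("rank_by_lpr sorts ascending with env-id tie-break", {
  X <- rbind(c(3, 0), c(1, 0), c(1, 0), c(2, 0))
  fs <- feature_set(X, rep(1, 4))
  h <- build_hessian(list(target_row(c(1, 0), 1), target_row(c(0, 1), 1)),
                     ridge = 0.1)
  rk <- rank_by_lpr(h, fs)
  expect_equal(rk$env_id[1], 1L)           # largest row -> least rigid
  expect_true(all(diff(rk$lpr) >= 0))
  expect_equal(rk$env_id[3:4], c(2L, 3L))  # identical rows: ascending ids
  expect_error(rank_by_lpr(h, fs, integer(0)), "nonempty")
})

test_that("lpr_enhancement is non-mutating and supports repetition", {
  set.seed(75)
  X <- matrix(rnorm(9), 3, 3)
  fs <- feature_set(X, c(1, 2, 3))
  rows <- lapply(1:3, function(s) assemble_energy_row(fs, s))
  h <- build_hessian(rows, ridge = 0.1)
  before <- local_prediction_rigidity(h, fs, 2)
  sets <- list(self = target_row(X[2, ], 1), other = target_row(rnorm(3), 1))
  pc1 <- lpr_enhancement(h, fs, 2, sets, times = 1)
  pc3 <- lpr_enhancement(h, fs, 2, sets, times = 3)
  expect_named(pc1, c("self", "other"))
  # self-addition at lambda = 1 raises the LPR by exactly 1 per copy
  expect_equal(pc1[["self"]], 100 * 1 / before, tolerance = 1e-9)
  expect_equal(pc3[["self"]], 100 * 3 / before, tolerance = 1e-9)
  expect_true(all(pc3 >= pc1))
  expect_equal(local_prediction_rigidity(h, fs, 2), before) # untouched
  expect_error(lpr_enhancement(h, fs, 2, list()), "no candidate sets")
})

test_that("selection traces write to CSV and JSON", {
  set.seed(76)
  rows <- random_rows(10, 3)
  pool <- stats::setNames(lapply(1:3, function(i)
    list(target_row(rnorm(3), 1))), c("a", "b", "c"))
  targets <- list(query_vector(rnorm(3), "global"))
  trace <- greedy_augment(build_hessian(rows, ridge = 0.1), pool, targets, 2)
  csv <- tempfile(fileext = ".csv")
  jsn <- tempfile(fileext = ".json")
  write_trace(trace, csv)
  write_trace(trace, jsn)
  expect_equal(utils::read.csv(csv)$candidate, trace$steps$candidate)
  j <- jsonlite::read_json(jsn, simplifyVector = TRUE)
  expect_equal(j$steps$candidate, trace$steps$candidate)
  expect_equal(j$objective, "mean")
})
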