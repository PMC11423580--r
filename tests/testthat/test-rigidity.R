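test_that("prediction_rigidity equals the explicit-inverse oracle", {
  set.seed(61)
  for (trial in 1:10) {
    d <- sample(2:8, 1)
    rows <- random_rows(sample(d:(d + 20), 1), d)
    ridge <- runif(1, 0.01, 0.5)
    h <- build_hessian(rows, ridge = ridge)
    g <- rnorm(d)
    expect_equal(prediction_rigidity(h, query_vector(g, "global")),
                 pr_oracle(rows, ridge, g), tolerance = 1e-9)
  }
})

test_that("zero queries are rejected everywhere", {
  h <- build_hessian(random_rows(5, 3), ridge = 0.1)
  expect_error(prediction_rigidity(h, numeric(3)), "zero")
  X <- matrix(c(1, 0, 0, 0, 0, 0), 2, 3, byrow = TRUE)
  fs <- feature_set(X, c(1, 1), blocks = list(a = c(1, 2), b = c(3, 3)))
  expect_error(component_prediction_rigidity(h, fs, 1, "b"),
               "identically zero")
})

test_that("query constructors build the right vectors", {
  X <- matrix(1:8, 2, 4)
  fs <- feature_set(X, c(1, 1), blocks = list(lo = c(1, 2), hi = c(3, 4)))
  gq <- global_query(fs, 1)
  expect_equal(gq$g, colSums(X))
  expect_equal(gq$tag, "global")
  lq <- local_query(fs, 2)
  expect_equal(lq$g, X[2, ])
  expect_equal(lq$subject_id, 2L)
  cq <- component_query(fs, 1, "hi")
  expect_equal(cq$g, c(0, 0, colSums(X)[3:4]))
  expect_equal(cq$block, "hi")
  expect_error(local_query(fs, 5), "unknown env_id")
  expect_error(component_query(fs, 1, "nope"), "not declared")
  expect_error(query_vector(1:3, "component"), "name their block")
})

test_that("LPR and CPR wrap prediction_rigidity on their queries", {
  set.seed(62)
  X <- matrix(rnorm(12), 4, 3)
  fs <- feature_set(X, c(1, 1, 2, 2), blocks = list(a = c(1, 2), b = c(3, 3)))
  rows <- lapply(1:2, function(s) assemble_energy_row(fs, s))
  h <- build_hessian(rows, ridge = 0.3)
  expect_equal(local_prediction_rigidity(h, fs, 3),
               pr_oracle(rows, 0.3, X[3, ]))
  gb <- c(0, 0, sum(X[1:2, 3]))
  expect_equal(component_prediction_rigidity(h, fs, 1, "b"),
               pr_oracle(rows, 0.3, gb))
})

test_that("last_layer_pr handles edge cases", {
  f <- c(1, 2)
  expect_equal(last_layer_pr(matrix(0, 0, 2), f, ridge = 2),
               2 / sum(f^2), tolerance = 1e-12)
  expect_error(last_layer_pr(matrix(1, 1, 3), f), "dimension mismatch")
  expect_error(last_layer_pr(matrix(1, 1, 2), c(0, 0), ridge = 1), "zero")
})

test_that("variance_from_pr inverts the rigidity with a scale", {
  expect_equal(variance_from_pr(4), 0.25)
  expect_equal(variance_from_pr(4, scale = 0.01), 0.0025)
  expect_error(variance_from_pr(-1), "positive")
})

test_that("the curvature probe scales quadratically in delta", {
  set.seed(63)
  rows <- random_rows(30, 6)
  ridge <- 0.1
  w_o <- fit_ridge(rows, ridge)
  q <- query_vector(rnorm(6), "global")
  p1 <- curvature_probe(rows, ridge, w_o, q, 0.2)
  p2 <- curvature_probe(rows, ridge, w_o, q, 0.4)
  expect_equal(p2$delta_loss / p1$delta_loss, 4, tolerance = 1e-9)
  R <- prediction_rigidity(build_hessian(rows, ridge = ridge), q)
  expect_equal(p1$delta_loss, R * 0.2^2, tolerance = 1e-9)
})

test_that("rigidity_report collects and normalizes values", {
  set.seed(64)
  X <- matrix(rnorm(12), 4, 3)
  fs <- feature_set(X, c(1, 1, 2, 2))
  rows <- lapply(1:2, function(s) assemble_energy_row(fs, s))
  h <- build_hessian(rows, ridge = 0.2)
  queries <- c(lapply(1:2, function(s) global_query(fs, s)),
               lapply(1:4, function(j) local_query(fs, j)))
  rep <- rigidity_report(h, queries)
  expect_equal(nrow(rep$values), 6)
  expect_equal(rep$values$value[3], local_prediction_rigidity(h, fs, 1))
  expect_equal(rep$normalization, "raw")
  repm <- normalize_report(rep, "max")
  expect_equal(max(repm$values$normalized), 1)
  repr <- normalize_report(rep, "reference", reference = 2)
  expect_equal(repr$values$normalized, rep$values$value / 2)
  expect_error(normalize_report(rep, "reference"), "positive reference")
  expect_error(rigidity_report(h, list()), "no queries")
})

test_that("monitor_trajectory: window 1 is the raw relative series", {
  set.seed(65)
  rows <- random_rows(25, 4)
  h <- build_hessian(rows, ridge = 0.1)
  frames <- matrix(rnorm(40), 10, 4)
  refs <- c(2, 4)
  out <- monitor_trajectory(h, frames, refs, window = 1)
  expect_equal(out$moving_average, out$relative_pr)
  expect_equal(out$relative_pr, out$pr / mean(refs))
  out3 <- monitor_trajectory(h, frames, refs, window = 3)
  expect_equal(out3$moving_average[5], mean(out3$relative_pr[3:5]))
  # prefix frames average over what is available
  expect_equal(out3$moving_average[1], out3$relative_pr[1])
  expect_error(monitor_trajectory(h, list(), refs), "empty trajectory")
  expect_error(monitor_trajectory(h, frames, numeric(0)), "nonempty")
  expect_error(monitor_trajectory(h, frames, refs, window = 0), ">= 1")
})

test_that("reports write to CSV and JSON", {
  set.seed(66)
  rows <- random_rows(10, 3)
  h <- build_hessian(rows, ridge = 0.1)
  rep <- rigidity_report(h, list(query_vector(c(1, 0, 0), "global",
                                              subject_id = 1)))
  csv <- tempfile(fileext = ".csv")
  jsn <- tempfile(fileext = ".json")
  write_report(rep, csv)
  write_report(rep, jsn)
  back <- utils::read.csv(csv)
  expect_equal(back$value, rep$values$value)
  j <- jsonlite::read_json(jsn, simplifyVector = TRUE)
  expect_equal(j$values$value, rep$values$value)
  expect_equal(j$normalization, "raw")
})
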