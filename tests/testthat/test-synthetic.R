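test_that("all generators are seed-deterministic", {
  expect_identical(gen_linear_system(seed = 9), gen_linear_system(seed = 9))
  expect_identical(gen_two_domain(seed = 9), gen_two_domain(seed = 9))
  expect_identical(gen_body_ordered(seed = 9), gen_body_ordered(seed = 9))
  expect_identical(gen_two_scale(seed = 9), gen_two_scale(seed = 9))
  expect_identical(gen_toy_clusters(seed = 9), gen_toy_clusters(seed = 9))
  # and different seeds differ
  expect_false(identical(gen_linear_system(seed = 9)$rows,
                         gen_linear_system(seed = 10)$rows))
})

test_that("gen_linear_system shapes, scales and values are consistent", {
  sys <- gen_linear_system(n_structures = 30, envs_per_structure = 2, d = 5,
                           noise_sigma = 0, seed = 3)
  fs <- sys$featureset
  expect_equal(nrow(fs$env_features), 60)
  expect_equal(length(sys$rows), 30)
  # noiseless energies equal true_w . summed features
  g <- colSums(fs$env_features[fs$structure_of_env == 7, ])
  expect_equal(sys$rows[[7]]$grad_w, g)
  expect_equal(sys$rows[[7]]$value, sum(sys$true_weights * g))
  expect_error(gen_linear_system(n_structures = 0), "positive")
})

test_that("two-domain training features are exactly collinear in A", {
  td <- gen_two_domain(seed = 4, d = 10, alpha = 0.6)
  X <- td$system$featureset$env_features
  expect_equal(X[, 10], 0.6 * X[, 1], tolerance = 1e-14)
  # targets are pure domain B (independent deficit channel) and noiseless
  for (i in seq_along(td$targets)) {
    expect_equal(td$target_rows[[i]]$value,
                 sum(td$true_weights * td$targets[[i]]$g))
  }
  # pool split: majority bulk-like, minority target-like
  expect_equal(sum(td$pool_mix >= 0.7), round(0.15 * 40))
  expect_equal(sum(td$pool_mix <= 0.05), 40 - round(0.15 * 40))
  expect_true(abs(td$true_weights[10]) >= 1 &&
                abs(td$true_weights[10]) <= 2)
  expect_error(gen_two_domain(useful_frac = 2), "useful_frac")
})

test_that("body-ordered samples occupy exactly their blocks at kappa 0", {
  sys <- gen_body_ordered(counts = c(pair = 5, triple = 5, quad = 5,
                                     quint = 5),
                          overlap_kappa = 0, block_dim = 4, seed = 6)
  fs <- sys$featureset
  lab <- sys$meta$class_of_sample
  order_of <- c(pair = 1, triple = 2, quad = 3, quint = 4)
  for (i in seq_along(lab)) {
    x <- fs$env_features[i, ]
    ord <- order_of[[lab[i]]]
    live <- seq_len(4 * ord)
    expect_true(all(x[-live] == 0))
    expect_true(all(abs(x[seq_len(4)]) > 0))
  }
})

test_that("overlap leaks lower blocks upward and shares seed artifacts", {
  sys <- gen_body_ordered(counts = c(pair = 5), overlap_kappa = 0.5,
                          block_dim = 4, seed = 6)
  X <- sys$featureset$env_features
  expect_true(all(abs(X[, 5:16]) > 0))  # pairs excite every block
  # same seed, different counts: identical class maps and test set
  a <- gen_body_ordered(counts = c(quint = 10), seed = 8)
  b <- gen_body_ordered(counts = c(pair = 3, quint = 10), seed = 8)
  expect_identical(a$meta$test, b$meta$test)
  expect_identical(a$meta$test_values, b$meta$test_values)
  expect_identical(a$true_weights, b$true_weights)
  expect_error(gen_body_ordered(overlap_kappa = 2), "\\[0, 1\\]")
  expect_error(gen_body_ordered(counts = c(pair = -1)), "nonnegative")
})

test_that("two-scale blocks behave as declared", {
  sep <- gen_two_scale(n_pairs = 20, separated = TRUE, seed = 5)
  non <- gen_two_scale(n_pairs = 20, separated = FALSE, seed = 5)
  expect_named(sep$featureset$blocks, c("sr", "lr"))
  # separated monomers have an exactly zero LR block
  lr_cols <- 7:12
  expect_true(all(sep$meta$mono$env_features[, lr_cols] == 0))
  expect_true(any(non$meta$mono$env_features[, lr_cols] != 0))
  # the same seed draws the same geometry for both variants
  expect_equal(sep$meta$separations, non$meta$separations)
  expect_equal(sep$featureset$env_features[, 1:6],
               non$featureset$env_features[, 1:6])
  expect_error(gen_two_scale(sep_range = c(5, 3)), "increasing")
})

test_that("the two-scale learning curve averages replicates", {
  lc <- two_scale_learning_curve(seed = 1, separated = TRUE,
                                 sizes = c(25, 50), n_replicates = 2)
  expect_equal(lc$n_train, c(25L, 50L))
  expect_true(all(lc$rmse > 0))
  expect_error(two_scale_learning_curve(sizes = c(50, 25)), "increasing")
})

test_that("toy clusters respect the minimum distance", {
  clusters <- gen_toy_clusters(n_structures = 5, seed = 12, min_dist = 1.1)
  for (s in clusters) {
    dmin <- min(dist(s$positions))
    expect_gte(dmin, 1.1)
    expect_equal(length(s$species), nrow(s$positions))
  }
})

test_that("the radial descriptor is translation invariant and smooth", {
  clusters <- gen_toy_clusters(n_structures = 1, atoms_range = c(4, 4),
                               seed = 13)
  fs <- radial_descriptor(clusters[[1]])
  shifted <- clusters[[1]]
  shifted$positions <- shifted$positions + 3.2
  fs2 <- radial_descriptor(shifted)
  expect_equal(fs2$env_features, fs$env_features, tolerance = 1e-12)
  # descriptor gradients match finite differences
  w <- rnorm(ncol(fs$env_features))
  k <- 2  # probe one environment
  f_at <- function(p) {
    st <- clusters[[1]]
    st$positions <- p
    sum(radial_descriptor(st)$env_features[k, ] * w)
  }
  fd <- fd_positions(f_at, clusters[[1]]$positions)
  an <- apply(fs$env_gradients[k, , ], 1, function(row) sum(row * w))
  expect_equal(an, as.vector(t(fd)), tolerance = 1e-6)
  # a dimer just inside the cutoff has vanishing features at the cutoff
  dimer <- list(species = c("C", "C"),
                positions = rbind(c(0, 0, 0), c(2.7999, 0, 0)))
  fd2 <- radial_descriptor(dimer, cutoff = 2.8)
  expect_true(all(abs(fd2$env_features) < 1e-6))
})

test_that("committee variances: degenerate cases and anticorrelation", {
  # zero noise + full data per member: all variances vanish
  sys0 <- gen_linear_system(n_structures = 40, d = 4, noise_sigma = 0,
                            seed = 14)
  v0 <- committee_variances(sys0, n_members = 4, subsample_fraction = 1,
                            ridge = 1e-8)
  expect_true(all(v0 < 1e-20))
  # general case: nonnegative, one per environment
  sys <- gen_linear_system(seed = 14)
  v <- committee_variances(sys, seed = 2)
  expect_equal(length(v), nrow(sys$featureset$env_features))
  expect_true(all(v >= 0))
  expect_error(committee_variances(sys, n_members = 1), "at least 2")
  expect_error(committee_variances(sys, subsample_fraction = 0), "\\(0, 1\\]")
})
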