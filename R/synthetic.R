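#' Synthetic linear feature systems
#'
#' Generators for desk-scale analogues of the experiment classes used to
#' exercise the rigidity machinery: plain anisotropic linear systems, a
#' two-domain augmentation task, body-ordered block systems with controllable
#' self-interaction overlap, two-length-scale systems with controllable
#' double counting, and toy atomic clusters with a smooth radial descriptor.
#' All generators are deterministic in their seed: the same seed reproduces
#' bit-identical arrays.
#'
#' @name synthetic
NULL

new_synthetic_system <- function(featureset, rows, true_weights, seed,
                                 noise_sigma, meta = list()) {
  structure(list(featureset = featureset, rows = rows,
                 true_weights = true_weights, seed = seed,
                 noise_sigma = noise_sigma, meta = meta),
            class = "synthetic_system")
}

#' @export
print.synthetic_system <- function(x, ...) {
  cat("<synthetic_system> scenario=", x$meta$scenario %||% "linear",
      " seed=", x$seed, " noise_sigma=", x$noise_sigma, "\n", sep = "")
  print(x$featureset)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Random anisotropic linear system
#'
#' Environment feature rows are drawn from an anisotropic Gaussian whose
#' column variances decay geometrically from 1 to `1/condition`, each row
#' additionally scaled by a per-environment log-normal factor
#' (`sdlog = env_scale_sdlog`). This gives a realistic spread of local
#' rigidities: common, well-covered directions and rare, weakly covered ones.
#' Structure energies are `true_w . (summed features)` plus Gaussian noise.
#'
#' @param n_structures number of structures.
#' @param envs_per_structure environments per structure.
#' @param d feature dimension.
#' @param noise_sigma energy noise standard deviation.
#' @param seed integer seed (same seed, identical bytes).
#' @param condition ratio between the largest and smallest column variance.
#' @param env_scale_sdlog log-sd of the per-environment scale factor.
#' @return a `synthetic_system` with energy target rows (unit weight).
#' @export
gen_linear_system <- function(n_structures = 200, envs_per_structure = 4,
                              d = 10, noise_sigma = 0.1, seed = 1,
                              condition = 100, env_scale_sdlog = 0.5) {
  if (n_structures < 1 || envs_per_structure < 1 || d < 1)
    stop("sizes must be positive")
  set.seed(seed)
  n_env <- n_structures * envs_per_structure
  col_sd <- condition^(-(seq_len(d) - 1) / (2 * max(1, d - 1)))
  X <- matrix(stats::rnorm(n_env * d), n_env, d)
  X <- sweep(X, 2, col_sd, `*`)
  env_scale <- stats::rlnorm(n_env, 0, env_scale_sdlog)
  X <- X * env_scale
  som <- rep(seq_len(n_structures), each = envs_per_structure)
  true_w <- stats::rnorm(d)
  fs <- feature_set(X, som)
  noise <- stats::rnorm(n_structures, 0, noise_sigma)
  rows <- lapply(seq_len(n_structures), function(s) {
    g <- colSums(X[som == s, , drop = FALSE])
    target_row(g, weight = 1, kind = "energy",
               value = sum(true_w * g) + noise[s])
  })
  new_synthetic_system(fs, rows, true_w, seed, noise_sigma,
                       meta = list(scenario = "linear",
                                   condition = condition,
                                   env_scale_sdlog = env_scale_sdlog))
}

#' Two-domain augmentation task
#'
#' Emulates extending a model trained on one family of structures (domain A)
#' to a target family (domain B). In domain A the last feature is exactly
#' collinear with the first (per environment, `f_d = alpha * f_1`), the way
#' e.g. a density-like descriptor channel is slaved to coordination inside a
#' single bulk phase. The fit therefore cannot split the two channels' weights:
#' whatever the noise realization, its estimate along the unidentified
#' direction is fixed by regularization alone, a deterministic O(1) bias. In
#' domain B the two channels vary independently, so target predictions carry
#' that bias until the training set is augmented with structures that
#' decorrelate the pair.
#'
#' The candidate pool mirrors a realistic augmentation round: most candidates
#' come from the same bulk-like regime as domain A (mixing parameter
#' `pi < 0.05`, still collinear, useless for the targets), while a minority
#' fraction `useful_frac` samples the target-like regime (`pi` in `[0.7, 1]`).
#' Candidate `i`'s environments interpolate `f_d = (1-pi) * alpha * f_1 +
#' pi * z_d` with an independent `z_d`. Target structures are pure domain B
#' and carry noiseless reference energies, so a fit's target-domain RMSE
#' directly measures whether the deficit direction was resolved. The true
#' weight of the deficit channel is drawn with magnitude in `[1, 2]` (random
#' sign) so the unresolved bias is always well above the noise floor.
#'
#' @param n_train training structures from domain A.
#' @param n_pool candidate structures.
#' @param n_targets target structures from domain B.
#' @param envs_per_structure environments per structure.
#' @param d feature dimension; the deficit channel is column `d`.
#' @param noise_sigma energy noise for training rows and pool candidates.
#' @param seed integer seed.
#' @param useful_frac fraction of the pool drawn from the target-like regime.
#' @param alpha collinearity coefficient tying the deficit channel to
#'   channel 1 in domain A.
#' @return list with `system` (training `synthetic_system`), `pool` (named
#'   list of single-row candidates with values), `pool_mix` (mixing
#'   parameters, useless candidates first), `targets` (list of global
#'   [query_vector()]s), `target_rows` (valued rows for RMSE evaluation),
#'   `true_weights`.
#' @export
gen_two_domain <- function(n_train = 60, n_pool = 40, n_targets = 20,
                           envs_per_structure = 3, d = 12,
                           noise_sigma = 0.02, seed = 1, useful_frac = 0.15,
                           alpha = 0.8) {
  if (d < 2) stop("d must be at least 2")
  if (useful_frac < 0 || useful_frac > 1)
    stop("useful_frac must lie in [0, 1]")
  set.seed(seed)
  true_w <- stats::rnorm(d)
  true_w[d] <- sample(c(-1, 1), 1) * stats::runif(1, 1, 2)
  draw_structure <- function(p) {
    z <- matrix(stats::rnorm(envs_per_structure * d), envs_per_structure, d)
    f <- z
    f[, d] <- (1 - p) * alpha * z[, 1] + p * z[, d]
    f
  }
  # training set (domain A: deficit channel fully collinear, pi = 0)
  Xs <- lapply(seq_len(n_train), function(i) draw_structure(0))
  X <- do.call(rbind, Xs)
  som <- rep(seq_len(n_train), each = envs_per_structure)
  fs <- feature_set(X, som)
  rows <- lapply(seq_len(n_train), function(s) {
    g <- colSums(Xs[[s]])
    target_row(g, 1, "energy", sum(true_w * g) + stats::rnorm(1, 0,
                                                              noise_sigma))
  })
  system <- new_synthetic_system(fs, rows, true_w, seed, noise_sigma,
                                 meta = list(scenario = "two_domain",
                                             alpha = alpha))
  # candidate pool: bulk-like majority, target-like minority
  n_useful <- round(useful_frac * n_pool)
  pool_mix <- c(stats::runif(n_pool - n_useful, 0, 0.05),
                stats::runif(n_useful, 0.7, 1))
  pool <- list()
  for (i in seq_len(n_pool)) {
    g <- colSums(draw_structure(pool_mix[i]))
    pool[[sprintf("cand_%03d", i)]] <-
      target_row(g, 1, "energy", sum(true_w * g) +
                   stats::rnorm(1, 0, noise_sigma))
  }
  # targets (domain B, pi = 1), noiseless reference values
  targets <- list()
  target_rows <- list()
  for (i in seq_len(n_targets)) {
    g <- colSums(draw_structure(1))
    targets[[i]] <- query_vector(g, "global", subject_id = i)
    target_rows[[i]] <- target_row(g, 1, "energy", sum(true_w * g))
  }
  list(system = system, pool = pool, pool_mix = pool_mix, targets = targets,
       target_rows = target_rows, true_weights = true_w, seed = seed)
}

random_orthogonal <- function(q) {
  M <- matrix(stats::rnorm(q * q), q, q)
  qr.Q(qr(M))
}

#' Body-ordered block system with controllable self-interaction overlap
#'
#' Emulates a body-ordered descriptor whose feature vector is a concatenation
#' of four blocks, one per correlation order `nu = 1..4`. An `n`-mer of class
#' `c` (pair = 1, triple = 2, quad = 3, quint = 4) has a latent geometry
#' `u ~ N(0, I)`; in the orthogonalized ("purified") basis its block `nu`
#' equals a fixed class-level orthogonal map of `u` for `nu <= c` and is
#' exactly zero for `nu > c`. Cross-block correlation through the shared
#' latent reproduces the partitioning degeneracy: a training set of quints
#' alone cannot resolve how the energy splits across blocks.
#'
#' `overlap_kappa > 0` switches to a self-interacting basis in which each
#' block additionally receives `kappa` times fixed orthogonal mixes of all
#' lower blocks, emulating spurious higher-body-order terms that reuse the
#' same atoms: pure pairs then excite every block, and adding them no longer
#' isolates the first block's weights.
#'
#' Energies are `true_w . f_purified` plus noise (the physical energy does not
#' depend on the descriptor basis). A held-out set of `n_test` quint samples
#' is generated before the training samples, so systems that share a seed
#' share both the class maps and the test set regardless of `counts`.
#'
#' @param counts named integer vector `c(pair=, triple=, quad=, quint=)`.
#' @param overlap_kappa self-interaction overlap in `[0, 1]`.
#' @param block_dim columns per block.
#' @param noise_sigma energy noise sd.
#' @param seed integer seed.
#' @param n_test held-out quint samples.
#' @return a `synthetic_system`; blocks named `nu1..nu4`; `meta` holds the
#'   class label of every training sample, plus `test` (a `feature_set` of
#'   held-out quints) and `test_values`.
#' @export
gen_body_ordered <- function(counts = c(pair = 0, triple = 0, quad = 0,
                                        quint = 200),
                             overlap_kappa = 0, block_dim = 8,
                             noise_sigma = 0, seed = 1, n_test = 20) {
  if (overlap_kappa < 0 || overlap_kappa > 1)
    stop("overlap_kappa must lie in [0, 1]")
  classes <- c("pair", "triple", "quad", "quint")
  cnt <- stats::setNames(rep(0L, 4), classes)
  cnt[names(counts)] <- as.integer(counts)
  if (any(cnt < 0)) stop("counts must be nonnegative")
  q <- block_dim
  d <- 4L * q
  set.seed(seed)
  # fixed class-level maps (drawn first: independent of counts)
  Phi <- lapply(1:4, function(c_) lapply(1:4, function(nu) {
    if (nu == 1 || nu > c_) NULL else random_orthogonal(q)
  }))
  Cmix <- lapply(1:4, function(nu) lapply(1:4, function(mu) {
    if (mu >= nu) NULL else random_orthogonal(q)
  }))
  true_w <- stats::rnorm(d)
  block_cols <- lapply(1:4, function(nu) ((nu - 1) * q + 1):(nu * q))
  purified_row <- function(class_idx, u) {
    f <- numeric(d)
    f[block_cols[[1]]] <- u
    if (class_idx >= 2)
      for (nu in 2:class_idx)
        f[block_cols[[nu]]] <- drop(Phi[[class_idx]][[nu]] %*% u)
    f
  }
  to_self_basis <- function(f) {
    if (overlap_kappa == 0) return(f)
    g <- f
    # leakage amplitude grows with the receiving block's order: the number of
    # spurious terms that re-count an atom grows with the body order
    for (nu in 2:4) {
      acc <- numeric(q)
      for (mu in 1:(nu - 1))
        acc <- acc + drop(Cmix[[nu]][[mu]] %*% f[block_cols[[mu]]])
      g[block_cols[[nu]]] <- f[block_cols[[nu]]] + overlap_kappa * nu * acc
    }
    g
  }
  gen_samples <- function(class_idx, n) {
    pure <- matrix(0, n, d)
    for (i in seq_len(n))
      pure[i, ] <- purified_row(class_idx, stats::rnorm(q))
    list(pure = pure, feat = t(apply(pure, 1, to_self_basis)))
  }
  # held-out test quints, shared across systems with the same seed
  test <- gen_samples(4L, n_test)
  test_values <- drop(test$pure %*% true_w)
  # training samples, in fixed class order
  feats <- list(); pures <- list(); labels <- character(0)
  for (ci in 1:4) {
    if (cnt[ci] > 0) {
      s <- gen_samples(ci, cnt[ci])
      feats[[length(feats) + 1]] <- s$feat
      pures[[length(pures) + 1]] <- s$pure
      labels <- c(labels, rep(classes[ci], cnt[ci]))
    }
  }
  X <- do.call(rbind, feats)
  Xp <- do.call(rbind, pures)
  n <- nrow(X)
  values <- drop(Xp %*% true_w) + stats::rnorm(n, 0, noise_sigma)
  blocks <- stats::setNames(lapply(block_cols, range),
                            paste0("nu", 1:4))
  fs <- feature_set(X, seq_len(n), blocks = blocks)
  rows <- lapply(seq_len(n), function(i)
    target_row(X[i, ], 1, "energy", values[i]))
  test_fs <- feature_set(test$feat, seq_len(n_test), blocks = blocks)
  new_synthetic_system(
    fs, rows, true_w, seed, noise_sigma,
    meta = list(scenario = "body_ordered", overlap_kappa = overlap_kappa,
                class_of_sample = labels, counts = cnt,
                test = test_fs, test_values = test_values))
}

#' Two-length-scale system with controllable double counting
#'
#' Emulates a model whose descriptor concatenates a short-range (SR) block,
#' a fixed linear encoding of each unit's few internal degrees of freedom,
#' with a long-range (LR) block carrying the inter-unit interaction, which
#' decays as `(r_min / r)^decay_power` with the separation `r`. Each training
#' sample is a "dimer" of two units separated by `r` drawn from `sep_range`;
#' its energy is the sum of the two units' internal energies plus the decaying
#' interaction energy, plus noise.
#'
#' With `separated = TRUE` the LR block contains only the interaction signal
#' and vanishes at large separation. With `separated = FALSE` the LR block
#' double-counts the short-range atoms: it additionally receives a second
#' fixed encoding of the units' internal geometry, so the SR information
#' appears in both blocks and the energy partition between them is degenerate.
#' For the held-out monomer analogues the double-counted encoding is evaluated
#' under slightly different conditions (`eval_shift` perturbs the map,
#' emulating the cell dependence of reciprocal-space evaluation), so whatever
#' share of the internal energy the fit assigned to the LR weights does not
#' transfer, producing a persistent extrapolation error.
#'
#' @param n_pairs number of dimer training samples.
#' @param sep_range separation range (length units), default 3 to 10.
#' @param separated logical; `TRUE` removes the double counting.
#' @param noise_sigma energy noise sd.
#' @param seed integer seed.
#' @param n_mono held-out monomer samples (noiseless reference values).
#' @param k_dof internal degrees of freedom per unit.
#' @param sr_dim,lr_dim block widths.
#' @param decay_power interaction decay exponent.
#' @param double_count strength of the SR leakage into the LR block when
#'   `separated = FALSE`.
#' @param eval_shift relative perturbation of the leakage map for monomers.
#' @return a `synthetic_system` with blocks `sr` and `lr`; `meta` holds
#'   `separations`, `mono` (a monomer `feature_set`) and `mono_values`.
#' @export
gen_two_scale <- function(n_pairs = 100, sep_range = c(3, 10),
                          separated = TRUE, noise_sigma = 0.02, seed = 1,
                          n_mono = 100, k_dof = 3, sr_dim = 6, lr_dim = 6,
                          decay_power = 3, double_count = 1,
                          eval_shift = 0.3) {
  if (any(sep_range <= 0) || sep_range[2] < sep_range[1])
    stop("sep_range must be positive and increasing")
  set.seed(seed)
  A <- matrix(stats::rnorm(sr_dim * k_dof), sr_dim, k_dof) / sqrt(k_dof)
  B <- matrix(stats::rnorm(lr_dim * k_dof), lr_dim, k_dof) / sqrt(k_dof)
  Dshift <- matrix(stats::rnorm(lr_dim * k_dof), lr_dim, k_dof) / sqrt(k_dof)
  h0 <- stats::rnorm(lr_dim); h0 <- h0 / sqrt(sum(h0^2))
  u <- stats::rnorm(k_dof)       # true internal-energy weights (latent space)
  e_int <- stats::rnorm(1)       # true interaction-energy coefficient
  t1 <- matrix(stats::rnorm(n_pairs * k_dof), n_pairs, k_dof)
  t2 <- matrix(stats::rnorm(n_pairs * k_dof), n_pairs, k_dof)
  r <- stats::runif(n_pairs, sep_range[1], sep_range[2])
  amp <- (sep_range[1] / r)^decay_power
  noise <- stats::rnorm(n_pairs, 0, noise_sigma)
  tmono <- matrix(stats::rnorm(n_mono * k_dof), n_mono, k_dof)
  d <- sr_dim + lr_dim
  tsum <- t1 + t2
  SR <- tsum %*% t(A)
  LR <- outer(amp, h0)
  if (!separated) LR <- LR + double_count * (tsum %*% t(B))
  X <- cbind(SR, LR)
  values <- drop(tsum %*% u) + e_int * amp + noise
  blocks <- list(sr = c(1L, sr_dim), lr = c(sr_dim + 1L, d))
  fs <- feature_set(X, seq_len(n_pairs), blocks = blocks)
  rows <- lapply(seq_len(n_pairs), function(i)
    target_row(X[i, ], 1, "energy", values[i]))
  SRm <- tmono %*% t(A)
  LRm <- if (separated) matrix(0, n_mono, lr_dim)
         else double_count * (tmono %*% t(B + eval_shift * Dshift))
  mono_fs <- feature_set(cbind(SRm, LRm), seq_len(n_mono), blocks = blocks)
  mono_values <- drop(tmono %*% u)
  new_synthetic_system(
    fs, rows, NULL, seed, noise_sigma,
    meta = list(scenario = "two_scale", separated = separated,
                separations = r, mono = mono_fs, mono_values = mono_values,
                decay_power = decay_power, double_count = double_count,
                eval_shift = eval_shift))
}

#' Monomer learning curve for the two-length-scale system
#'
#' Fits ridge models on nested subsets of [gen_two_scale()] dimer training
#' sets and evaluates the RMSE of the held-out monomer energies, averaged over
#' independent replicate systems (seeds `seed + 1000 * (1..n_replicates)`).
#' With `separated = TRUE` the monomer error decays as the training set grows;
#' with the double-counted basis (`separated = FALSE`) it stalls at the level
#' of the misassigned short-range energy share, since the leaked encoding does
#' not transfer to the monomer evaluation conditions. Averaging over
#' replicates reports the trend of the generator class rather than a single
#' noise realization.
#'
#' @param seed base integer seed.
#' @param separated logical, passed to [gen_two_scale()].
#' @param sizes increasing training-set sizes; the largest is the number of
#'   dimer pairs generated per replicate.
#' @param n_replicates independent systems to average over.
#' @param ridge regularization for the fits.
#' @param ... further arguments passed to [gen_two_scale()].
#' @return data frame with columns `n_train` and `rmse` (replicate-averaged
#'   monomer RMSE).
#' @export
two_scale_learning_curve <- function(seed = 1, separated = TRUE,
                                     sizes = c(25, 100, 400),
                                     n_replicates = 4, ridge = 1e-8, ...) {
  sizes <- as.integer(sizes)
  if (any(diff(sizes) <= 0)) stop("sizes must be strictly increasing")
  rmses <- matrix(0, n_replicates, length(sizes))
  for (r in seq_len(n_replicates)) {
    sys <- gen_two_scale(n_pairs = max(sizes), separated = separated,
                         seed = seed + 1000L * r, ...)
    mono <- sys$meta$mono
    Xm <- mono$env_features
    for (j in seq_along(sizes)) {
      w <- fit_ridge(sys$rows[seq_len(sizes[j])], ridge = ridge)
      preds <- drop(Xm %*% w$w)
      rmses[r, j] <- sqrt(mean((preds - sys$meta$mono_values)^2))
    }
  }
  data.frame(n_train = sizes, rmse = colMeans(rmses))
}

#' Random toy clusters
#'
#' Small non-periodic clusters with positions uniform in a cubic box, with a
#' minimum interatomic distance enforced by rejection. Used to exercise the
#' radial descriptor, force rows and finite-difference checks end to end.
#'
#' @param n_structures number of clusters.
#' @param atoms_range inclusive range of atoms per cluster.
#' @param box box edge (length units).
#' @param seed integer seed.
#' @param min_dist minimum allowed interatomic distance.
#' @param species species symbols sampled per atom.
#' @return list of structures, each `list(species, positions, comment)`.
#' @export
gen_toy_clusters <- function(n_structures = 4, atoms_range = c(3, 8),
                             box = 5, seed = 1, min_dist = 0.9,
                             species = c("C", "H")) {
  set.seed(seed)
  lapply(seq_len(n_structures), function(s) {
    n <- sample(atoms_range[1]:atoms_range[2], 1)
    pos <- matrix(NA_real_, n, 3)
    placed <- 0L
    tries <- 0L
    while (placed < n) {
      p <- stats::runif(3, 0, box)
      ok <- placed == 0L ||
        min(sqrt(rowSums(sweep(pos[seq_len(placed), , drop = FALSE],
                               2, p)^2))) >= min_dist
      if (ok) {
        placed <- placed + 1L
        pos[placed, ] <- p
      }
      tries <- tries + 1L
      if (tries > 10000L) stop("box too crowded for min_dist")
    }
    list(species = sample(species, n, replace = TRUE), positions = pos,
         comment = sprintf("toy_cluster=%d", s))
  })
}

cutoff_fn <- function(r, rc) ifelse(r < rc, 0.5 * (1 + cos(pi * r / rc)), 0)
cutoff_grad <- function(r, rc) ifelse(r < rc, -0.5 * pi / rc *
                                        sin(pi * r / rc), 0)

#' Smooth Gaussian radial-basis pair descriptor
#'
#' Per-atom features `f_ik = sum_{j != i} exp(-(r_ij - c_k)^2 / (2 w^2)) *
#' fcut(r_ij)` with a cosine cutoff, plus analytic gradients with respect to
#' every Cartesian coordinate, populated into the returned feature set. The
#' descriptor is invariant to translations and to permutations of identical
#' atoms, and smooth at the cutoff.
#'
#' @param structures a structure (as from [gen_toy_clusters()]) or a list of
#'   structures.
#' @param cutoff radial cutoff (length units).
#' @param centers Gaussian center positions.
#' @param width Gaussian width.
#' @return a [feature_set()] with one environment per atom, structures
#'   concatenated in order, and `env_gradients` of dimension
#'   `n_env x (3 n_env) x d` (coordinates enumerated 3 per atom in order;
#'   cross-structure entries are zero).
#' @export
radial_descriptor <- function(structures, cutoff = 2.8,
                              centers = seq(0.4, cutoff, length.out = 6),
                              width = 0.3) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (!is.null(structures$positions)) structures <- list(structures)
  natoms <- vapply(structures, function(s) nrow(s$positions), 0L)
  if (any(natoms == 0L)) stop("empty structure")
  n_env <- sum(natoms)
  dfeat <- length(centers)
  X <- matrix(0, n_env, dfeat)
  Gr <- array(0, dim = c(n_env, 3L * n_env, dfeat))
  som <- integer(n_env)
  off <- 0L
  for (s in seq_along(structures)) {
    pos <- structures[[s]]$positions
    n <- nrow(pos)
    som[off + seq_len(n)] <- s
    if (n >= 2) {
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        dvec <- pos[j, ] - pos[i, ]
        r <- sqrt(sum(dvec^2))
        if (r >= cutoff) next
        gauss <- exp(-(r - centers)^2 / (2 * width^2))
        fc <- cutoff_fn(r, cutoff)
        X[off + i, ] <- X[off + i, ] + gauss * fc
        dphi <- gauss * (-(r - centers) / width^2 * fc +
                           cutoff_grad(r, cutoff))
        unit <- dvec / r
        ci <- 3L * (off + i - 1L) + 1:3
        cj <- 3L * (off + j - 1L) + 1:3
        for (a in 1:3) {
          Gr[off + i, cj[a], ] <- Gr[off + i, cj[a], ] + dphi * unit[a]
          Gr[off + i, ci[a], ] <- Gr[off + i, ci[a], ] - dphi * unit[a]
        }
      }
    }
    off <- off + n
  }
  feature_set(X, som, env_gradients = Gr)
}

#' Committee variances of local predictions
#'
#' Fits an ensemble of ridge models on subsampled training sets and returns
#' the per-environment variance of the local predictions about the committee
#' mean. The default protocol splits the structures into `n_members` disjoint
#' folds, one member per fold; `mode = "bootstrap"` instead resamples
#' `subsample_fraction` of the structures with replacement per member. With
#' `subsample_fraction = 1` every member sees the full dataset (and, at zero
#' noise, all variances vanish).
#'
#' @param system a `synthetic_system` (or any list with `featureset` and
#'   valued `rows`, one row per structure in structure order).
#' @param n_members committee size (>= 2).
#' @param subsample_fraction fraction of structures per member; default
#'   `1/n_members` for folds, `0.5` for bootstrap.
#' @param ridge regularization; `NULL` selects the scale-aware default from
#'   the full data term. A fold too small for full rank at `ridge = 0` falls
#'   back to the default with a warning.
#' @param seed integer seed for the subsampling.
#' @param mode `"folds"` (disjoint) or `"bootstrap"`.
#' @return named numeric vector: variance per environment index.
#' @export
committee_variances <- function(system, n_members = 10,
                                subsample_fraction = NULL, ridge = NULL,
                                seed = 1, mode = c("folds", "bootstrap")) {
  mode <- match.arg(mode)
  if (n_members < 2) stop("n_members must be at least 2")
  fs <- system$featureset
  rows <- system$rows
  n_struct <- length(rows)
  d <- ncol(fs$env_features)
  if (is.null(subsample_fraction))
    subsample_fraction <- if (mode == "folds") 1 / n_members else 0.5
  if (subsample_fraction <= 0 || subsample_fraction > 1)
    stop("subsample_fraction must lie in (0, 1]")
  rl <- rows_to_matrix(rows)
  default_ridge <- 1e-8 * mean(colSums((rl$G * sqrt(rl$lambda))^2))
  if (is.null(ridge)) ridge <- default_ridge
  set.seed(seed)
  members <- vector("list", n_members)
  if (subsample_fraction == 1) {
    for (m in seq_len(n_members)) members[[m]] <- seq_len(n_struct)
  } else if (mode == "folds") {
    perm <- sample.int(n_struct)
    fold_of <- rep(seq_len(n_members), length.out = n_struct)
    for (m in seq_len(n_members)) members[[m]] <- perm[fold_of == m]
  } else {
    size <- max(1L, round(subsample_fraction * n_struct))
    for (m in seq_len(n_members))
      members[[m]] <- sample.int(n_struct, size, replace = TRUE)
  }
  W <- matrix(0, d, n_members)
  for (m in seq_len(n_members)) {
    idx <- members[[m]]
    r <- ridge
    if (r == 0 && length(idx) < d) {
      warning("subsample too small for full rank; falling back to ridge = ",
              format(default_ridge))
      r <- default_ridge
    }
    W[, m] <- fit_ridge(rows[idx], ridge = r)$w
  }
  P <- fs$env_features %*% W
  v <- apply(P, 1, stats::var)
  stats::setNames(v, seq_len(nrow(fs$env_features)))
}
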