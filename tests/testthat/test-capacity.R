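test_that("the low-rank manifold model reconstructs its points", {
  # all points identical -> zero-dimensional manifold
  m0 <- fit_manifold_model(matrix(2, 5, 8))
  expect_equal(ncol(m0$axes), 0)
  expect_equal(m0$center, rep(2, 8))
  # planted 2-D ellipse in 50 dimensions
  set.seed(1)
  U <- qr.Q(qr(matrix(rnorm(50 * 2), 50)))
  th <- seq(0, 2 * pi, length.out = 40)
  pts <- cbind(3 * cos(th), sin(th)) %*% t(U)
  mm <- fit_manifold_model(pts)
  expect_equal(ncol(mm$axes), 2)
  # principal angle between fitted and planted plane
  sv <- svd(t(mm$axes) %*% U)$d
  expect_lt(max(acos(pmin(sv, 1))), 1e-6)
  # reconstruction residual on a random cloud
  X <- matrix(rnorm(30 * 20), 30)
  mr <- fit_manifold_model(X)
  rec <- sweep(mr$coords %*% t(mr$axes), 2, mr$center, `+`)
  expect_lt(max(abs(rec - X)), 1e-8)
})

test_that("capacity of point manifolds approaches the Cover limit", {
  # many singleton manifolds at random positions: alpha -> 2 (homogeneous
  # convention; the empirical counterpart is checked in the oracle suite)
  set.seed(2)
  pts <- lapply(1:12, function(i) matrix(rnorm(60), 1))
  cfg <- capacity_config(n_gaussian_samples = 400, bias = FALSE,
                         global_centering = FALSE, max_dichotomies = 15,
                         seed = 3)
  a <- as.numeric(mean_field_capacity(pts, config = cfg))
  expect_lt(abs(a - 2) / 2, 0.2)
})

test_that("capacity is invariant under rotation and manifold order", {
  set.seed(4)
  X <- matrix(rnorm(20 * 40, 0), 20)
  Y <- matrix(rnorm(20 * 40, 0.8), 20)
  cfg <- capacity_config(n_gaussian_samples = 600, seed = 7)
  a1 <- as.numeric(mean_field_capacity(list(X, Y), config = cfg))
  R <- random_rotation(40)
  a2 <- as.numeric(mean_field_capacity(list(X %*% R, Y %*% R), config = cfg))
  a3 <- as.numeric(mean_field_capacity(list(Y, X), config = cfg))
  # invariance holds in distribution over the Gaussian samples
  expect_equal(a1, a2, tolerance = 0.08)
  expect_equal(a1, a3, tolerance = 0.08)
})

test_that("anchor points satisfy strong duality and sit on the manifolds", {
  set.seed(5)
  X <- matrix(rnorm(8 * 15, 0), 8)
  Y <- matrix(rnorm(8 * 15, 1), 8)
  out <- anchor_points(list(X, Y), T = rnorm(15), y = c(1, -1))
  expect_lt(out$duality_gap, 1e-6)
  for (mu in which(out$active)) {
    # anchor is a convex combination of that manifold's points: it lies in
    # the affine hull and within the point cloud's bounding box
    A <- list(X, Y)[[mu]]
    expect_true(all(out$anchors[mu, ] <= apply(A, 2, max) + 1e-8))
    expect_true(all(out$anchors[mu, ] >= apply(A, 2, min) - 1e-8))
  }
  # singleton manifolds: the anchor is the point itself
  x1 <- matrix(rnorm(10), 1); x2 <- matrix(rnorm(10, 2), 1)
  o2 <- anchor_points(list(x1, x2), T = rnorm(10), y = c(1, -1))
  for (mu in which(o2$active)) {
    expect_equal(o2$anchors[mu, ], as.numeric(list(x1, x2)[[mu]]),
                 tolerance = 1e-6)
  }
  # spherical manifolds, T along the center axis: the anchor lies near the
  # sphere surface in the separating direction
  set.seed(6)
  th <- seq(0, 2 * pi, length.out = 60)[-1]
  circ <- cbind(cos(th), sin(th))
  S1 <- cbind(circ, matrix(0, 59, 8));  S1[, 1] <- S1[, 1] - 4
  S2 <- cbind(circ, matrix(0, 59, 8));  S2[, 1] <- S2[, 1] + 4
  Tdir <- c(1, rep(0, 9)) * 3
  o3 <- anchor_points(list(S1, S2), T = Tdir, y = c(1, -1),
                      config = capacity_config(global_centering = TRUE,
                                               bias = FALSE))
  if (o3$active[1]) {
    a1 <- o3$anchors[1, ]
    expect_gt(a1[1], -4)          # pulled toward the opposing manifold
    expect_lt(abs(sqrt(sum((a1 - c(-4, rep(0, 9)))^2)) - 1), 0.5)
  }
})

test_that("effective measures behave as the anchor geometry dictates", {
  set.seed(7)
  N <- 80
  u <- rnorm(N); u <- u / sqrt(sum(u^2)); u <- 6 * u
  v <- rnorm(N); v <- v - sum(v * u) * u / sum(u^2); v <- 6 * v / sqrt(sum(v^2))
  mk <- function(center, sd = 1, M = 30)
    sweep(matrix(rnorm(M * N, sd = sd), M), 2, center, `+`)
  cfg <- capacity_config(n_gaussian_samples = 200, seed = 8)
  # identical centers -> center alignment 1
  em_same <- effective_measures(list(mk(u), mk(u)), cfg)
  expect_gt(em_same[["center_alignment_eff"]], 0.9)
  # orthogonal centers -> alignment near 0
  em_orth <- effective_measures(list(mk(u), mk(v)), cfg)
  expect_lt(em_orth[["center_alignment_eff"]], 0.15)
  # shrinking the covariance decreases the effective radius and does not
  # decrease capacity
  em_small <- effective_measures(list(mk(u, 0.4), mk(v, 0.4)), cfg)
  expect_lt(em_small[["radius_eff"]], em_orth[["radius_eff"]])
  expect_gte(em_small[["alpha"]], em_orth[["alpha"]])
})

test_that("the capacity fit obeys its limits and controls", {
  set.seed(9)
  X <- manifold(matrix(rnorm(30 * 60, 0), 30), label = "X")
  Y <- manifold(matrix(rnorm(30 * 60, 1), 30), label = "Y")
  cfg1 <- capacity_config(n_repeats = 1, n_gaussian_samples = 80, seed = 10)
  fit <- manifold_capacity(X, Y, config = cfg1)
  direct <- mean_field_capacity(list(X, Y),
                                config = capacity_config(
                                  n_gaussian_samples = 80, seed = 10))
  # no-subsampling limit: same alpha as the direct computation (same seed
  # stream up to the shuffle draw)
  expect_equal(fit$alpha, as.numeric(direct), tolerance = 0.35)
  # determinism under a fixed seed
  fit2 <- manifold_capacity(X, Y, config = cfg1)
  expect_identical(fit$per_repeat, fit2$per_repeat)
  # well-separated compact manifolds always beat their shuffled twin
  Xs <- manifold(matrix(rnorm(40 * 80, 0, 0.5), 40), label = "a")
  Ys <- manifold(matrix(rnorm(40 * 80, 3, 0.5), 40), label = "b")
  cfg3 <- capacity_config(n_repeats = 4, n_gaussian_samples = 60, seed = 11)
  f3 <- manifold_capacity(Xs, Ys, config = cfg3)
  expect_true(all(f3$per_repeat$alpha > f3$per_repeat$shuffle_alpha))
  # S3 surface
  expect_s3_class(fit, "manifold_capacity")
  expect_named(coef(f3)[1:2], c("alpha", "radius_eff"))
  s <- summary(f3)
  expect_output(print(s), "capacity")
  expect_error(manifold_capacity(X), "at least two")
})

test_that("the margin parameter tightens the program", {
  set.seed(12)
  X <- matrix(rnorm(15 * 40, 0), 15)
  Y <- matrix(rnorm(15 * 40, 1.5), 15)
  a0 <- as.numeric(mean_field_capacity(list(X, Y),
    config = capacity_config(n_gaussian_samples = 100, seed = 13)))
  a1 <- as.numeric(mean_field_capacity(list(X, Y),
    config = capacity_config(n_gaussian_samples = 100, margin = 2,
                             seed = 13)))
  expect_lt(a1, a0)
})
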