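test_that("manifold construction pools time bins across trials", {
  arr <- synthetic_odor_session(n_neurons = 30, n_odors = 2, n_trials = 3,
                                rate_hz = 7.5, t_total = 8, seed = 1)
  man <- build_manifolds(arr, window = c(1, 1 + 24 / 7.5))
  expect_equal(nrow(man[[1]]$points), 72)
  # single bin, single trial -> one point
  m1 <- build_manifolds(arr, window = c(1, 1 + 1 / 7.5), trials = 1)
  expect_equal(nrow(m1[[1]]$points), 1)
  # model convention: 2 s window, 100 ms bins, 4 trials -> 80 points
  arr2 <- array(rnorm(20 * 25 * 4 * 2, 5), c(20, 25, 4, 2))
  attr(arr2, "bin_s") <- 0.1; attr(arr2, "t0") <- -0.5
  m2 <- build_manifolds(arr2, window = c(0, 2))
  expect_equal(nrow(m2[[1]]$points), 80)
  expect_error(build_manifolds(arr, window = c(50, 60)), "outside")
})

test_that("euclidean distance matches the mean-then-norm oracle", {
  expect_equal(euclidean_distance(matrix(1:6, 2), matrix(1:6, 2)), 0)
  X <- rbind(c(0, 0)); Y <- rbind(c(3, 4))
  expect_equal(euclidean_distance(X, Y), 5)
  set.seed(1)
  A <- matrix(rnorm(50 * 70), 50); B <- matrix(rnorm(60 * 70, 1), 60)
  expect_equal(euclidean_distance(A, B),
               sqrt(sum((colMeans(A) - colMeans(B))^2)))
  expect_equal(euclidean_distance(A, B, squared = TRUE),
               euclidean_distance(A, B)^2)
  expect_error(euclidean_distance(A, matrix(0, 3, 5)), "dimension")
})

test_that("mahalanobis distance has the stated geometry", {
  # identity covariance reduces to Euclidean distance to the center
  set.seed(2)
  Y <- matrix(rnorm(5000 * 2), 5000)
  x <- rbind(c(3, 4))
  expect_lt(abs(mahalanobis_distance(x, Y) - 5), 0.2)
  # directional asymmetry, checked against an explicit-inverse oracle
  set.seed(3)
  ax <- c(1, 1, 0) / sqrt(2)
  Yel <- matrix(rnorm(300 * 3), 300) %*% diag(c(0.3, 0.3, 0.3)) +
    outer(rnorm(300, sd = 3), ax)          # elongated along the X-Y axis
  Xc <- matrix(rnorm(200 * 3, sd = 0.3), 200)
  Xc <- sweep(Xc, 2, c(4, 4, 0) / sqrt(2), `+`)
  dxy <- mahalanobis_distance(Xc, Yel)
  dyx <- mahalanobis_distance(Yel, Xc)
  expect_lt(dxy, dyx)
  expect_equal(dxy, dM_bruteforce(Xc, Yel), tolerance = 1e-10)
  expect_equal(dyx, dM_bruteforce(Yel, Xc), tolerance = 1e-10)
  # invariance under a shared invertible affine map
  set.seed(4)
  M <- matrix(rnorm(9), 3); M <- M + 3 * diag(3)
  b <- rnorm(3)
  aff <- function(Z) sweep(Z %*% t(M), 2, b, `+`)
  expect_equal(mahalanobis_distance(aff(Xc), aff(Yel)), dxy,
               tolerance = 1e-6)
  # singular covariance fails informatively
  Ysing <- cbind(rnorm(40), rnorm(40), 0 * rnorm(40) + 1)
  Ysing[, 3] <- Ysing[, 1] + Ysing[, 2]
  expect_error(mahalanobis_distance(Xc, Ysing[, c(1, 2, 3)] * 0 + 1),
               "singular|points")
})

test_that("dM is non-negative and zero only when X sits at the center", {
  set.seed(5)
  Y <- matrix(rnorm(100 * 4), 100)
  X0 <- matrix(rep(colMeans(Y), 3), 3, byrow = TRUE)
  expect_equal(mahalanobis_distance(X0, Y), 0, tolerance = 1e-8)
  expect_gt(mahalanobis_distance(X0 + 0.5, Y), 0)
})

test_that("distance matrices follow the subsampling protocol", {
  set.seed(6)
  mans <- lapply(1:3, function(i)
    manifold(matrix(rnorm(90 * 80, mean = i), 90), label = paste0("o", i)))
  # no-subsampling limit equals the direct computation
  d <- distance_matrices(mans, n_neurons_sub = 80, n_repeats = 1, seed = 1)
  expect_equal(d$dE["o1", "o2"], euclidean_distance(mans[[1]], mans[[2]]))
  expect_equal(d$dM["o1", "o2"],
               mahalanobis_distance(mans[[1]], mans[[2]]))
  # determinism under a fixed seed
  d1 <- distance_matrices(mans, n_neurons_sub = 70, n_repeats = 3, seed = 2)
  d2 <- distance_matrices(mans, n_neurons_sub = 70, n_repeats = 3, seed = 2)
  expect_identical(d1, d2)
  # structural invariants
  expect_equal(d1$dE, t(d1$dE))
  expect_true(all(diag(d1$dE) == 0))
  expect_true(all(d1$dM >= 0))
  expect_error(distance_matrices(mans, n_neurons_sub = 200), "reduce")
})

test_that("planted class structure is recovered in the dE block pattern", {
  set.seed(7)
  centers <- rbind(matrix(rnorm(3 * 100, 0, 0.25), 3),
                   matrix(rnorm(3 * 100, 0, 0.25), 3))
  centers[1:3, 1] <- centers[1:3, 1] + 4      # class 1 offset
  centers[4:6, 2] <- centers[4:6, 2] + 4      # class 2 offset
  mans <- lapply(1:6, function(i)
    manifold(sweep(matrix(rnorm(120 * 100, sd = 0.5), 120), 2,
                   centers[i, ], `+`), label = i))
  d <- distance_matrices(mans, n_neurons_sub = 70, n_repeats = 5, seed = 3)
  within <- c(d$dE[1, 2], d$dE[1, 3], d$dE[2, 3],
              d$dE[4, 5], d$dE[4, 6], d$dE[5, 6])
  across <- as.vector(d$dE[1:3, 4:6])
  expect_lt(max(within), min(across))
})

test_that("scaling co-scales dE but leaves dM unchanged", {
  set.seed(8)
  A <- matrix(rnorm(100 * 20), 100) + 2
  B <- matrix(rnorm(100 * 20), 100) - 2
  c0 <- 3
  expect_equal(euclidean_distance(c0 * A, c0 * B),
               c0 * euclidean_distance(A, B))
  expect_equal(mahalanobis_distance(c0 * A, c0 * B),
               mahalanobis_distance(A, B), tolerance = 1e-8)
  # global rotation of neuron space leaves both unchanged
  R <- random_rotation(20)
  expect_equal(euclidean_distance(A %*% R, B %*% R),
               euclidean_distance(A, B), tolerance = 1e-10)
  expect_equal(mahalanobis_distance(A %*% R, B %*% R),
               mahalanobis_distance(A, B), tolerance = 1e-6)
})

test_that("center displacement with matched variance growth moves dE not dM", {
  # along a planted axis, centers separate while the reference variance
  # grows proportionally: dE rises, dM stays flat; with variance fixed,
  # both rise
  set.seed(9)
  N <- 15
  ax <- c(1, rep(0, N - 1))
  base <- matrix(rnorm(200 * N), 200)
  dE_m <- dM_m <- dE_f <- dM_f <- c()
  for (delta in c(2, 4, 8)) {
    Ym <- base %*% diag(c(delta / 2, rep(1, N - 1)))  # variance co-scales
    Xm <- sweep(matrix(rnorm(200 * N), 200), 2, delta * ax, `+`)
    dE_m <- c(dE_m, euclidean_distance(Xm, Ym))
    dM_m <- c(dM_m, mahalanobis_distance(Xm, Ym))
    Yf <- base
    dE_f <- c(dE_f, euclidean_distance(Xm, Yf))
    dM_f <- c(dM_f, mahalanobis_distance(Xm, Yf))
  }
  expect_true(all(diff(dE_m) > 0))
  expect_lt(diff(range(dM_m)) / mean(dM_m), 0.25)   # flat within noise
  expect_true(all(diff(dE_f) > 0))
  expect_true(all(diff(dM_f) > 0))
})
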