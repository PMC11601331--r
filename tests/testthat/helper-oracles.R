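# Independent oracles used across the suite.  These deliberately avoid the
# package's own computational paths.

# --- linear separability -------------------------------------------------

# Homogeneous separability of signed points (rows of D = y_i * x_i):
# exists V with D V > 0  <=>  the origin is not in conv(D) (Gordan).
# Gilbert's minimum-norm-point algorithm either finds a separating
# certificate (all support values positive) or drives the norm to zero.
separable_homog <- function(D, maxit = 4000, tol = 1e-8) {
  scale <- max(sqrt(rowSums(D^2)))
  if (scale == 0) return(FALSE)
  v <- D[which.min(rowSums(D^2)), ]
  for (it in seq_len(maxit)) {
    if (sqrt(sum(v^2)) < tol * scale) return(FALSE)
    sup <- as.numeric(D %*% v)
    if (min(sup) > 0) return(TRUE)
    s <- D[which.min(sup), ]
    w <- v - s
    tt <- min(max(sum(v * w) / sum(w^2), 0), 1)
    v <- v - tt * w
  }
  sqrt(sum(v^2)) > 1e-4 * scale
}

# Critical embedding dimension of one dichotomy: separability probability
# under random Gaussian projection, scanned upward; 50% crossing by linear
# interpolation.
crossing_dim_homog <- function(signed, n_proj = 40, n_max = 200) {
  N <- ncol(signed)
  frac_at <- function(n) mean(replicate(n_proj,
    separable_homog(signed %*% matrix(rnorm(N * n), N))))
  f_prev <- frac_at(1)
  if (f_prev >= 0.5) return(1)
  for (n in 2:n_max) {
    f <- frac_at(n)
    if (f >= 0.5) return(n - 1 + (0.5 - f_prev) / (f - f_prev))
    f_prev <- f
  }
  NA_real_
}

# Empirical capacity of a list of point matrices: per-dichotomy critical
# dimensions, averaged; P / mean(n_c).  Points are globally centered the
# same way as the mean-field estimator under global_centering = TRUE.
empirical_capacity <- function(pts, max_dich = 20) {
  P <- length(pts)
  centers <- t(vapply(pts, colMeans, numeric(ncol(pts[[1]]))))
  shift <- colMeans(centers)
  pts <- lapply(pts, function(X) sweep(X, 2, shift))
  Y <- pdpmanifold:::dichotomies(P, max_dich)
  Ms <- vapply(pts, nrow, integer(1))
  mrow <- rep(seq_len(P), Ms)
  X_all <- do.call(rbind, pts)
  ncs <- apply(Y, 2, function(y) crossing_dim_homog(X_all * y[mrow]))
  P / mean(ncs)
}

# --- distances -----------------------------------------------------------

# brute-force Mahalanobis via explicit inverse
dM_bruteforce <- function(X, Y) {
  S <- cov(Y)
  Sinv <- solve(S)
  mu <- colMeans(Y)
  mean(apply(X, 1, function(x) sqrt(t(x - mu) %*% Sinv %*% (x - mu))))
}

# --- rank statistics -----------------------------------------------------

# Exact two-sided Mann-Whitney p by full enumeration of group assignments
mw_exact_enum <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  U_obs <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  combs <- combn(n1 + n2, n1)
  Us <- apply(combs, 2, function(idx) {
    aa <- pooled[idx]; bb <- pooled[-idx]
    sum(outer(aa, bb, ">")) + 0.5 * sum(outer(aa, bb, "=="))
  })
  mu <- n1 * n2 / 2
  mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-12)
}

# random orthogonal matrix
random_rotation <- function(n) {
  qr.Q(qr(matrix(rnorm(n * n), n)))
}
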