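#' Configuration for mean-field manifold capacity
#'
#' Collects the tunable parameters of the capacity estimator.  Defaults
#' follow the analysis conventions used throughout the package: global
#' centering and a bias (offset) coordinate enabled, zero margin, 50
#' subsampling repeats and 100 Gaussian samples per repeat.
#'
#' @param n_neurons_sub neurons sampled per repeat (`NULL` = all; the
#'   juvenile-geometry convention is 700, the adult-geometry one 400).
#' @param n_points_sub activity patterns sampled per manifold per repeat
#'   (`NULL` = all; juvenile 140, adult 80).
#' @param n_repeats number of subsampling repeats.
#' @param n_gaussian_samples Gaussian samples `T` per repeat.
#' @param margin classification margin `kappa >= 0` (0 reproduces the
#'   constraint set `y V'x >= 0`).
#' @param global_centering translate the mean of the manifold centers to the
#'   origin before solving the quadratic programs.
#' @param bias append a constant coordinate (excluded from Gaussian
#'   sampling) so the separating hyperplane may have an offset.
#' @param qp_tol,qp_maxit convergence tolerance and iteration cap of the
#'   dual coordinate-descent QP solver.
#' @param max_dichotomies cap on the number of label dichotomies averaged
#'   when more than two manifolds are supplied.
#' @param seed optional integer seed fixing all randomness of a fit.
#' @return A list of class `"capacity_config"`.
#' @export
capacity_config <- function(n_neurons_sub = NULL, n_points_sub = NULL,
                            n_repeats = 50L, n_gaussian_samples = 100L,
                            margin = 0, global_centering = TRUE, bias = TRUE,
                            qp_tol = 1e-7, qp_maxit = 50000L,
                            max_dichotomies = 20L, seed = NULL) {
  stopifnot(margin >= 0, n_repeats >= 1, n_gaussian_samples >= 1)
  structure(list(n_neurons_sub = n_neurons_sub, n_points_sub = n_points_sub,
                 n_repeats = as.integer(n_repeats),
                 n_gaussian_samples = as.integer(n_gaussian_samples),
                 margin = margin, global_centering = isTRUE(global_centering),
                 bias = isTRUE(bias), qp_tol = qp_tol,
                 qp_maxit = as.integer(qp_maxit),
                 max_dichotomies = as.integer(max_dichotomies), seed = seed),
            class = "capacity_config")
}

#' Low-rank model of a manifold: center, axes and coordinates
#'
#' Decomposes a point cloud as `x = u0 + sum_i s_i u_i`, where `u0` is the
#' manifold center (point mean), the `u_i` are orthonormal axes spanning the
#' centered points (K = rank) and `s` the per-point coordinates.
#'
#' @param m a [manifold] or a points matrix.
#' @param tol relative singular-value cutoff for the rank.
#' @return An object of class `"manifold_model"` with elements `center`
#'   (N-vector), `axes` (`N x K`, orthonormal columns), `coords` (`M x K`)
#'   and `points` (the original `M x N` matrix).
#' @export
fit_manifold_model <- function(m, tol = 1e-10) {
  m <- as_manifold(m)
  X <- m$points
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  sv <- svd(Xc)
  K <- sum(sv$d > tol * max(sv$d, 0) & sv$d > 0)
  axes <- sv$v[, seq_len(K), drop = FALSE]
  coords <- Xc %*% axes
  structure(list(center = center, axes = axes, coords = coords,
                 points = X, label = m$label),
            class = "manifold_model")
}

#' @export
print.manifold_model <- function(x, ...) {
  cat(sprintf("<manifold_model> %d points, N = %d, K = %d\n",
              nrow(x$points), length(x$center), ncol(x$axes)))
  invisible(x)
}

points_of <- function(x) {
  if (inherits(x, "manifold")) x$points
  else if (inherits(x, "manifold_model")) x$points
  else as.matrix(x)
}

# all sign-unique, non-constant dichotomies of P manifolds (first entry +1)
dichotomies <- function(P, max_dichotomies = 20L) {
  if (P == 2) return(matrix(c(1, -1), nrow = 2))
  full <- as.matrix(expand.grid(rep(list(c(-1, 1)), P - 1)))
  y <- cbind(1, full)                      # fix sign symmetry
  y <- y[rowSums(y == 1) < P, , drop = FALSE]  # drop the constant dichotomy
  y <- t(y)
  if (ncol(y) > max_dichotomies)
    y <- y[, sample(ncol(y), max_dichotomies), drop = FALSE]
  y
}

# Preprocess a list of point matrices into the augmented space used by the
# QPs: optional global centering (mean of manifold centers to the origin)
# and optional bias coordinate (constant 1, excluded from Gaussian sampling).
augment_points <- function(pts, config) {
  centers <- t(vapply(pts, colMeans, numeric(ncol(pts[[1]]))))
  shift <- if (config$global_centering) colMeans(centers) else
    rep(0, ncol(pts[[1]]))
  aug <- lapply(pts, function(X) {
    X <- sweep(X, 2, shift)
    if (config$bias) cbind(X, 1) else X
  })
  list(aug = aug, shift = shift, n_dim = ncol(pts[[1]]))
}

# Core sampler: solves the projection QPs for every Gaussian sample and
# dichotomy and returns the averaged squared distances plus the dual
# multipliers (for anchor points).  `pts` is a list of M_mu x N matrices.
capacity_samples <- function(pts, config, keep_lambda = TRUE) {
  P <- length(pts)
  stopifnot(P >= 2)
  ap <- augment_points(pts, config)
  aug <- ap$aug
  N <- ap$n_dim
  Ms <- vapply(aug, nrow, integer(1))
  X_all <- do.call(rbind, aug)              # (sum M) x (N[+1])
  manifold_of_row <- rep(seq_len(P), Ms)
  Y <- dichotomies(P, config$max_dichotomies)
  ns <- config$n_gaussian_samples
  # Gaussian samples: bias coordinate excluded from sampling
  Tmat <- matrix(rnorm(N * ns), nrow = N)
  if (config$bias) Tmat <- rbind(Tmat, 0)
  XT <- X_all %*% Tmat                       # rows: constraints, cols: samples
  Fmat <- matrix(NA_real_, ns, ncol(Y))
  lambdas <- if (keep_lambda) vector("list", ncol(Y)) else NULL
  conv_all <- TRUE
  for (d in seq_len(ncol(Y))) {
    yrow <- Y[manifold_of_row, d]
    A <- X_all * yrow
    G <- tcrossprod(A)
    Q <- config$margin - XT * yrow
    sol <- nnqp_batch(G, Q, maxit = config$qp_maxit, tol = config$qp_tol)
    if (!all(sol$converged == 1)) {
      conv_all <- FALSE
      bad <- which(sol$converged != 1)
      stop("QP solver did not converge at tolerance ", config$qp_tol,
           " for Gaussian sample index ", bad[1], " (dichotomy ", d, ")")
    }
    Fmat[, d] <- sol$F
    if (keep_lambda) lambdas[[d]] <- sol$lambda
  }
  list(P = P, Fmat = Fmat, alpha = P / mean(Fmat), lambdas = lambdas,
       Y = Y, manifold_of_row = manifold_of_row, Ms = Ms,
       shift = ap$shift, converged = conv_all)
}

#' Mean-field manifold capacity of a set of manifolds
#'
#' Estimates the manifold capacity `alpha` (manifolds per state-space
#' dimension) by Gaussian-sampled quadratic programming: for zero-mean
#' unit-covariance samples `T` and each label dichotomy `y`, the convex
#' program `min ||V - T||^2` over `V` satisfying `y_mu V'x >= kappa` for all
#' manifold points `x` is solved in its dual, and
#' `alpha = P / mean(||V* - T||^2)`.
#'
#' @param manifolds list of [manifold] objects, [fit_manifold_model] results
#'   or point matrices (at least two, sharing the neuron dimension).
#' @param labels optional `P x D` matrix of +/-1 dichotomies; by default the
#'   single `(+1, -1)` dichotomy for a pair, or all sign-unique non-constant
#'   dichotomies (capped) for more manifolds.
#' @param config a [capacity_config].
#' @return The capacity (numeric scalar) with attributes `F_mean` (the mean
#'   optimal squared distance) and `n_samples`.
#' @export
mean_field_capacity <- function(manifolds, labels = NULL,
                                config = capacity_config()) {
  pts <- lapply(manifolds, points_of)
  Ns <- vapply(pts, ncol, integer(1))
  if (length(unique(Ns)) != 1)
    stop("all manifolds must share the same neuron dimension")
  if (!is.null(config$seed)) set.seed(config$seed)
  if (!is.null(labels)) {
    config$max_dichotomies <- ncol(labels)
    cs <- local({
      # run with explicit labels by temporarily overriding the default set
      P <- length(pts)
      stopifnot(nrow(labels) == P)
      ap <- augment_points(pts, config)
      aug <- ap$aug
      Ms <- vapply(aug, nrow, integer(1))
      X_all <- do.call(rbind, aug)
      mrow <- rep(seq_len(P), Ms)
      ns <- config$n_gaussian_samples
      Tmat <- matrix(rnorm(ap$n_dim * ns), nrow = ap$n_dim)
      if (config$bias) Tmat <- rbind(Tmat, 0)
      XT <- X_all %*% Tmat
      Fm <- sapply(seq_len(ncol(labels)), function(d) {
        yrow <- labels[mrow, d]
        A <- X_all * yrow
        sol <- nnqp_batch(tcrossprod(A), config$margin - XT * yrow,
                          maxit = config$qp_maxit, tol = config$qp_tol)
        if (!all(sol$converged == 1)) stop("QP solver did not converge")
        sol$F
      })
      list(alpha = P / mean(Fm), Fmat = Fm)
    })
  } else {
    cs <- capacity_samples(pts, config, keep_lambda = FALSE)
  }
  structure(cs$alpha, F_mean = mean(cs$Fmat),
            n_samples = length(cs$Fmat))
}

#' Anchor points of a manifold pair for one Gaussian sample
#'
#' Solves the projection QP for a single Gaussian sample `T` and dichotomy
#' `y` and returns, per manifold, the anchor point: the convex combination of
#' that manifold's points weighted by the dual multipliers of the active
#' constraints.  Strong duality of the convex QP is verified and reported.
#'
#' @param manifolds list of manifolds / matrices.
#' @param T Gaussian sample (length N; the bias coordinate, if enabled, is
#'   appended internally as 0).
#' @param y numeric vector of +/-1 labels, one per manifold.
#' @param config a [capacity_config].
#' @param tol duality-gap tolerance (relative).
#' @return list with `anchors` (`P x N` matrix in original data coordinates;
#'   a row is `NA` if the manifold's constraints are all inactive), `active`
#'   (logical), `F` (optimal squared distance), `duality_gap`, `lambda`.
#' @export
anchor_points <- function(manifolds, T, y, config = capacity_config(),
                          tol = 1e-6) {
  pts <- lapply(manifolds, points_of)
  P <- length(pts)
  stopifnot(length(y) == P)
  ap <- augment_points(pts, config)
  X_all <- do.call(rbind, ap$aug)
  Ms <- vapply(ap$aug, nrow, integer(1))
  mrow <- rep(seq_len(P), Ms)
  Taug <- if (config$bias) c(T, 0) else T
  stopifnot(length(Taug) == ncol(X_all))
  yrow <- y[mrow]
  A <- X_all * yrow
  G <- tcrossprod(A)
  q <- config$margin - as.numeric(A %*% Taug)
  sol <- nnqp_batch(G, matrix(q, ncol = 1), maxit = config$qp_maxit,
                    tol = config$qp_tol)
  lam <- sol$lambda[, 1]
  Fv <- sol$F[1]
  # strong duality: primal 1/2||V-T||^2 must equal the dual optimum
  gap <- abs(0.5 * Fv - sol$dual[1]) / (1 + abs(sol$dual[1]))
  if (gap > tol)
    stop("strong-duality residual ", format(gap), " exceeds tolerance ", tol)
  orig <- do.call(rbind, lapply(seq_len(P), function(mu) pts[[mu]]))
  anchors <- matrix(NA_real_, P, ncol(orig))
  active <- logical(P)
  for (mu in seq_len(P)) {
    idx <- which(mrow == mu)
    s <- sum(lam[idx])
    if (s > 1e-12) {
      active[mu] <- TRUE
      anchors[mu, ] <- as.numeric(crossprod(orig[idx, , drop = FALSE],
                                            lam[idx])) / s
    }
  }
  list(anchors = anchors, active = active, F = Fv, duality_gap = gap,
       lambda = lam)
}

# Collect anchor points (original coordinates) over all Gaussian samples and
# dichotomies from a capacity_samples() result.
collect_anchors <- function(pts, cs) {
  P <- cs$P
  lapply(seq_len(P), function(mu) {
    idx <- which(cs$manifold_of_row == mu)
    Xmu <- pts[[mu]]
    out <- list()
    for (d in seq_along(cs$lambdas)) {
      L <- cs$lambdas[[d]][idx, , drop = FALSE]     # M_mu x ns
      s <- colSums(L)
      act <- s > 1e-12
      if (any(act)) {
        Amat <- crossprod(Xmu, L[, act, drop = FALSE])   # N x n_act
        out[[length(out) + 1L]] <- t(Amat) / s[act]
      }
    }
    if (length(out)) do.call(rbind, out) else
      matrix(numeric(0), 0, ncol(Xmu))
  })
}

# The five effective geometric measures as moments of the anchor-point
# distribution (original, un-centered coordinates).  Exact formulas are
# documented in the methods vignette.
measures_from_anchors <- function(anchors) {
  P <- length(anchors)
  per <- lapply(anchors, function(A) {
    if (nrow(A) < 2) return(NULL)
    ctil <- colMeans(A)
    Ac <- sweep(A, 2, ctil)
    tr <- sum(Ac^2) / nrow(A)                      # trace of anchor covariance
    GAc <- tcrossprod(Ac) / nrow(A)                # n x n Gram trick
    tr2 <- sum(GAc^2)                              # trace of covariance^2
    list(center = ctil, Ac = Ac, n = nrow(A), tr = tr, tr2 = tr2,
         radius = sqrt(tr) / sqrt(sum(ctil^2)),
         dim = if (tr2 > 0) tr^2 / tr2 else 0)
  })
  ok <- !vapply(per, is.null, logical(1))
  if (sum(ok) < 2)
    return(c(radius_eff = NA, dimension_eff = NA, center_alignment_eff = NA,
             axes_alignment_eff = NA, center_axes_alignment_eff = NA))
  radius <- mean(vapply(per[ok], `[[`, numeric(1), "radius"))
  dimn <- mean(vapply(per[ok], `[[`, numeric(1), "dim"))
  ca <- aa <- cx <- c()
  ids <- which(ok)
  for (i in ids) for (j in ids) if (i < j) {
    a <- per[[i]]; b <- per[[j]]
    ca <- c(ca, abs(sum(a$center * b$center)) /
              sqrt(sum(a$center^2) * sum(b$center^2)))
    cross <- a$Ac %*% t(b$Ac)                     # n_i x n_j
    trab <- sum(cross^2) / (a$n * b$n)            # tr(S_i S_j)
    aa <- c(aa, if (a$tr2 > 0 && b$tr2 > 0) trab / sqrt(a$tr2 * b$tr2) else 0)
    bhat <- b$center / sqrt(sum(b$center^2))
    ahat <- a$center / sqrt(sum(a$center^2))
    cx1 <- sum((a$Ac %*% bhat)^2) / a$n / a$tr
    cx2 <- sum((b$Ac %*% ahat)^2) / b$n / b$tr
    cx <- c(cx, (cx1 + cx2) / 2)
  }
  c(radius_eff = radius, dimension_eff = dimn,
    center_alignment_eff = mean(ca), axes_alignment_eff = mean(aa),
    center_axes_alignment_eff = mean(cx))
}

#' Effective geometric measures of a manifold set
#'
#' Computes the five anchor-point-based measures (effective radius,
#' dimension, center alignment, axes alignment, center-axes alignment)
#' together with the capacity, from the same Gaussian samples.
#'
#' @param manifolds list of manifolds / matrices.
#' @param config a [capacity_config].
#' @return named numeric vector: `alpha` plus the five measures.
#' @export
effective_measures <- function(manifolds, config = capacity_config()) {
  pts <- lapply(manifolds, points_of)
  if (!is.null(config$seed)) set.seed(config$seed)
  cs <- capacity_samples(pts, config, keep_lambda = TRUE)
  anc <- collect_anchors(pts, cs)
  c(alpha = cs$alpha, measures_from_anchors(anc))
}
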