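#' Euclidean distance between manifold centers
#'
#' Straight-line distance between the centers (point means) of two
#' manifolds.  The metric (square-root) convention is the default; set
#' `squared = TRUE` for the squared form.
#'
#' @param X,Y manifolds (or point matrices) sharing the neuron dimension.
#' @param squared return the squared distance.
#' @return non-negative scalar.
#' @export
euclidean_distance <- function(X, Y, squared = FALSE) {
  x <- points_of(as_manifold(X)); y <- points_of(as_manifold(Y))
  if (ncol(x) != ncol(y))
    stop("manifolds live in different neuron dimensions (",
         ncol(x), " vs ", ncol(y), ")")
  d2 <- sum((colMeans(x) - colMeans(y))^2)
  if (squared) d2 else sqrt(d2)
}

# Regularized covariance of the reference manifold.  Optional shrinkage
# toward the diagonal (for discrete spike-count data whose correlated
# fluctuations make the inverse unstable); a ridge proportional to the mean
# diagonal is added only when the condition number is degenerate.
reference_covariance <- function(Y, ridge_eps = 1e-6, cond_max = 1e10,
                                 shrink = 0) {
  S <- cov(Y)
  if (shrink > 0) S <- (1 - shrink) * S + shrink * diag(diag(S), ncol(S))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  cond <- if (min(ev) > 0) max(ev) / min(ev) else Inf
  if (cond > cond_max) {
    S <- S + ridge_eps * (sum(diag(S)) / ncol(S)) * diag(ncol(S))
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    cond <- if (min(ev) > 0) max(ev) / min(ev) else Inf
    if (!is.finite(cond) || cond > 1 / .Machine$double.eps)
      stop("reference covariance singular after regularization ",
           "(condition number ", format(cond), ")")
    attr(S, "regularized") <- TRUE
  }
  S
}

#' Mahalanobis distance from a sample manifold to a reference manifold
#'
#' The mean, over the points `x` of the sample manifold `X`, of the
#' Mahalanobis distance of `x` to the reference distribution `(mu_Y, S_Y)`
#' estimated from manifold `Y`.  Directional: `dM(X -> Y)` generally differs
#' from `dM(Y -> X)` because the reference covariances differ.
#'
#' @param X sample manifold; @param Y reference manifold.
#' @param squared use the squared (no square root) convention.
#' @param ridge_eps,cond_max regularization guard for a degenerate
#'   reference covariance.
#' @param shrink shrinkage weight in `[0, 1)` toward the diagonal of the
#'   reference covariance (0 = none; useful for discrete spike-count data).
#' @return non-negative scalar.
#' @export
mahalanobis_distance <- function(X, Y, squared = FALSE, ridge_eps = 1e-6,
                                 cond_max = 1e10, shrink = 0) {
  x <- points_of(as_manifold(X)); y <- points_of(as_manifold(Y))
  if (ncol(x) != ncol(y))
    stop("manifolds live in different neuron dimensions")
  if (nrow(y) < 2) stop("reference manifold needs at least 2 points")
  S <- reference_covariance(y, ridge_eps, cond_max, shrink)
  d2 <- mahalanobis(x, colMeans(y), S)
  if (squared) mean(d2) else mean(sqrt(pmax(d2, 0)))
}

#' Distance matrices over a set of odor manifolds with neuron subsampling
#'
#' For each repeat, one shared random subset of `n_neurons_sub` neurons is
#' drawn and both the Euclidean distance `dE` (symmetric) and the
#' Mahalanobis distance `dM` (directional; rows = sample manifold, columns =
#' reference) are computed for all manifold pairs on that subset.  Matrices
#' are averaged over repeats.  Subsampling keeps the reference covariance
#' invertible (the point count must exceed the subset size).
#'
#' @param manifolds list of [manifold] objects.
#' @param n_neurons_sub neurons per subset (default 70).
#' @param n_repeats number of subsampling repeats (default 50).
#' @param seed optional RNG seed.
#' @param squared squared-distance convention switch.
#' @param shrink diagonal shrinkage of the reference covariances (see
#'   [mahalanobis_distance]).
#' @return object of class `"manifold_distances"`: list with `dE`, `dM`,
#'   `n_neurons_sub`, `n_repeats`, `seed`, `squared`.
#' @export
distance_matrices <- function(manifolds, n_neurons_sub = 70,
                              n_repeats = 50, seed = NULL,
                              squared = FALSE, shrink = 0) {
  manifolds <- lapply(manifolds, as_manifold)
  N <- unique(vapply(manifolds, n_neurons, integer(1)))
  if (length(N) != 1) stop("manifolds must share the neuron dimension")
  if (N < n_neurons_sub)
    stop("only ", N, " neurons available; reduce n_neurons_sub ",
         "(currently ", n_neurons_sub, ")")
  Ms <- vapply(manifolds, n_points, integer(1))
  if (n_neurons_sub < N && any(Ms <= n_neurons_sub))
    stop("each manifold needs more points than n_neurons_sub for an ",
         "invertible reference covariance")
  if (!is.null(seed)) set.seed(seed)
  P <- length(manifolds)
  labs <- vapply(seq_len(P), function(i) {
    l <- manifolds[[i]]$label
    if (is.null(l)) paste0("M", i) else as.character(l)
  }, character(1))
  dE <- dM <- matrix(0, P, P, dimnames = list(labs, labs))
  for (r in seq_len(n_repeats)) {
    neu <- if (n_neurons_sub < N) sort(sample.int(N, n_neurons_sub)) else
      seq_len(N)
    sub <- lapply(manifolds, function(m) m$points[, neu, drop = FALSE])
    mus <- lapply(sub, colMeans)
    Ss <- lapply(sub, reference_covariance, shrink = shrink)
    for (i in seq_len(P)) for (j in seq_len(P)) {
      if (i == j) next
      if (j > i) {
        d2 <- sum((mus[[i]] - mus[[j]])^2)
        de <- if (squared) d2 else sqrt(d2)
        dE[i, j] <- dE[i, j] + de
        dE[j, i] <- dE[j, i] + de
      }
      m2 <- mahalanobis(sub[[i]], mus[[j]], Ss[[j]])
      dM[i, j] <- dM[i, j] + if (squared) mean(m2) else
        mean(sqrt(pmax(m2, 0)))
    }
  }
  structure(list(dE = dE / n_repeats, dM = dM / n_repeats,
                 n_neurons_sub = n_neurons_sub, n_repeats = n_repeats,
                 seed = seed, squared = squared),
            class = "manifold_distances")
}

#' @export
print.manifold_distances <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Manifold distances (%d-neuron subsets, %d repeats, %s convention)\n",
    x$n_neurons_sub, x$n_repeats,
    if (x$squared) "squared" else "metric"))
  cat("dE (symmetric):\n"); print(round(x$dE, digits))
  cat("dM (row = sample, column = reference):\n")
  print(round(x$dM, digits))
  invisible(x)
}

#' Write distance matrices to labeled CSV files
#'
#' @param x a [distance_matrices] result.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written (dE, dM, JSON metadata).
#' @export
write_distances <- function(x, dir, prefix = "distances") {
  stopifnot(inherits(x, "manifold_distances"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pe <- file.path(dir, paste0(prefix, "_dE.csv"))
  pm <- file.path(dir, paste0(prefix, "_dM.csv"))
  pj <- file.path(dir, paste0(prefix, "_meta.json"))
  write.csv(x$dE, pe)
  write.csv(x$dM, pm)
  jsonlite::write_json(list(n_neurons_sub = x$n_neurons_sub,
                            n_repeats = x$n_repeats, seed = x$seed,
                            squared = x$squared, convention =
                              if (x$squared) "squared" else "metric"),
                       pj, auto_unbox = TRUE, null = "null")
  invisible(c(pe, pm, pj))
}
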