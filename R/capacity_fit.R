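#' Fit the manifold capacity of an odor-manifold pair
#'
#' The central estimator of the package.  For a pair (or set) of neural
#' manifolds it repeatedly subsamples neurons and activity patterns,
#' estimates the mean-field manifold capacity by Gaussian-sampled quadratic
#' programming, extracts the five effective geometric measures from the
#' anchor-point distribution of the same samples, and computes a
#' label-shuffle control (points of both manifolds pooled and labels
#' reassigned at random) on the same subsamples.
#'
#' Before each repeat the subsampled points are checked for linear
#' separability (affine independence guarantees it when the number of pooled
#' points does not exceed the subspace dimension plus one); rank-deficient
#' draws are rejected and redrawn, and the rejection count is reported.
#'
#' @param ... two or more manifolds ([manifold], [fit_manifold_model] or
#'   plain point matrices), or a single list of them.
#' @param config a [capacity_config]; its `n_neurons_sub`/`n_points_sub`
#'   default to the full data (no subsampling).
#' @param shuffle compute the shuffle control (default `TRUE`).
#' @param measures compute the effective geometric measures (default `TRUE`).
#' @return An object of class `"manifold_capacity"`: a list with elements
#'   `alpha`, `measures`, `shuffle_alpha`, `per_repeat` (data frame of
#'   per-repeat values), `config`, `n_rejected`, `call`.
#' @seealso [mean_field_capacity], [effective_measures], [shuffle_labels]
#' @export
manifold_capacity <- function(..., config = capacity_config(),
                              shuffle = TRUE, measures = TRUE) {
  args <- list(...)
  if (length(args) == 1 && is.list(args[[1]]) &&
      !inherits(args[[1]], c("manifold", "manifold_model")) &&
      !is.matrix(args[[1]])) args <- args[[1]]
  labels <- vapply(seq_along(args), function(i) {
    l <- if (inherits(args[[i]], c("manifold", "manifold_model")))
      args[[i]]$label else NULL
    if (is.null(l)) paste0("M", i) else as.character(l)
  }, character(1))
  pts <- lapply(args, points_of)
  P <- length(pts)
  if (P < 2) stop("need at least two manifolds")
  N <- unique(vapply(pts, ncol, integer(1)))
  if (length(N) != 1) stop("manifolds must share the neuron dimension")
  Ms <- vapply(pts, nrow, integer(1))

  nsub <- config$n_neurons_sub
  if (is.null(nsub)) nsub <- N
  psub <- config$n_points_sub
  if (is.null(psub)) psub <- min(Ms)
  if (nsub > N)
    stop("n_neurons_sub = ", nsub, " exceeds available neurons (", N, ")")
  if (psub > min(Ms))
    stop("n_points_sub = ", psub, " exceeds available points (",
         min(Ms), ")")
  if (!is.null(config$seed)) set.seed(config$seed)

  reps <- config$n_repeats
  rows <- vector("list", reps)
  n_rejected <- 0L
  for (r in seq_len(reps)) {
    for (try in seq_len(25L)) {
      neu <- if (nsub < N) sort(sample.int(N, nsub)) else seq_len(N)
      sub <- lapply(pts, function(X) {
        ridx <- if (psub < nrow(X)) sample.int(nrow(X), psub) else
          seq_len(nrow(X))
        X[ridx, neu, drop = FALSE]
      })
      if (separable_precheck(sub, config)) break
      n_rejected <- n_rejected + 1L
      if (try == 25L) stop("could not draw a linearly separable subsample")
    }
    cs <- capacity_samples(sub, config, keep_lambda = measures)
    mres <- if (measures)
      measures_from_anchors(collect_anchors(sub, cs))
    else rep(NA_real_, 5)
    sh <- NA_real_
    if (shuffle) {
      pooled <- do.call(rbind, sub)
      perm <- sample.int(nrow(pooled))
      bnd <- cumsum(vapply(sub, nrow, integer(1)))
      shuf <- list(pooled[perm[seq_len(bnd[1])], , drop = FALSE],
                   pooled[perm[(bnd[1] + 1):bnd[2]], , drop = FALSE])
      if (P > 2) {
        shuf <- lapply(seq_len(P), function(mu) {
          lo <- if (mu == 1) 1L else bnd[mu - 1] + 1L
          pooled[perm[lo:bnd[mu]], , drop = FALSE]
        })
      }
      sh <- capacity_samples(shuf, config, keep_lambda = FALSE)$alpha
    }
    rows[[r]] <- c(alpha = cs$alpha, mres, shuffle_alpha = sh)
  }
  per_repeat <- as.data.frame(do.call(rbind, rows))
  out <- list(alpha = mean(per_repeat$alpha),
              measures = colMeans(per_repeat[, c("radius_eff",
                "dimension_eff", "center_alignment_eff",
                "axes_alignment_eff", "center_axes_alignment_eff"),
                drop = FALSE]),
              shuffle_alpha = if (shuffle) mean(per_repeat$shuffle_alpha)
                else NA_real_,
              per_repeat = per_repeat, labels = labels,
              n_neurons_sub = nsub, n_points_sub = psub,
              n_rejected = n_rejected, config = config,
              call = match.call())
  class(out) <- "manifold_capacity"
  out
}

# Affine independence of the pooled subsampled points guarantees linear
# separability of every dichotomy when (pooled points) <= dim + 1.
separable_precheck <- function(sub, config) {
  pooled <- do.call(rbind, sub)
  n <- nrow(pooled)
  d <- ncol(pooled) + as.integer(config$bias)
  if (n > d) return(FALSE)
  qr(cbind(pooled, 1))$rank == n
}

#' Capacity of label-shuffled pseudo-manifolds
#'
#' Pools the points of a manifold pair, reassigns labels at random
#' ([shuffle_labels]) and computes the mean-field capacity, repeated over
#' `n_shuffles` independent shuffles.  The analytic large-`N` limit for
#' isotropic pooled points is `2/M` for `M` points per pseudo-manifold.
#'
#' @param x,y the two manifolds (or point matrices).
#' @param n_shuffles number of shuffle realizations.
#' @param config a [capacity_config].
#' @return list with `mean`, `sd`, `per_shuffle`.
#' @export
shuffle_capacity <- function(x, y, n_shuffles = 20L,
                             config = capacity_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  config$seed <- NULL
  vals <- vapply(seq_len(n_shuffles), function(i) {
    sh <- shuffle_labels(list(as_manifold(x), as_manifold(y)))
    as.numeric(mean_field_capacity(sh, config = config))
  }, numeric(1))
  list(mean = mean(vals), sd = sd(vals), per_shuffle = vals)
}

#' @export
print.manifold_capacity <- function(x, ...) {
  cat("Mean-field manifold capacity\n")
  cat(sprintf("  manifolds: %s\n", paste(x$labels, collapse = ", ")))
  cat(sprintf("  subsample: %d neurons, %d points, %d repeats\n",
              x$n_neurons_sub, x$n_points_sub, x$config$n_repeats))
  cat(sprintf("  capacity alpha : %.4f\n", x$alpha))
  if (!is.na(x$shuffle_alpha))
    cat(sprintf("  shuffle control: %.4f\n", x$shuffle_alpha))
  invisible(x)
}

#' @export
summary.manifold_capacity <- function(object, ...) {
  s <- list(alpha = object$alpha,
            alpha_sd = sd(object$per_repeat$alpha),
            shuffle_alpha = object$shuffle_alpha,
            shuffle_sd = sd(object$per_repeat$shuffle_alpha),
            measures = object$measures,
            n_repeats = object$config$n_repeats,
            n_rejected = object$n_rejected,
            labels = object$labels)
  class(s) <- "summary.manifold_capacity"
  s
}

#' @export
print.summary.manifold_capacity <- function(x, ...) {
  cat("Mean-field manifold capacity of", paste(x$labels, collapse = " vs "),
      "\n")
  cat(sprintf("  alpha           : %.4f (SD over %d repeats: %.4f)\n",
              x$alpha, x$n_repeats, x$alpha_sd))
  if (!is.na(x$shuffle_alpha))
    cat(sprintf("  shuffled alpha  : %.4f (SD %.4f)\n",
                x$shuffle_alpha, x$shuffle_sd))
  m <- x$measures
  cat(sprintf("  radius %.3f | dimension %.2f | center align %.3f | axes align %.3f | center-axes %.3f\n",
              m[1], m[2], m[3], m[4], m[5]))
  if (x$n_rejected > 0)
    cat("  separability pre-check rejected", x$n_rejected, "subsample(s)\n")
  invisible(x)
}

#' @export
coef.manifold_capacity <- function(object, ...) {
  c(alpha = object$alpha, object$measures,
    shuffle_alpha = object$shuffle_alpha)
}

#' @export
plot.manifold_capacity <- function(x, ...) {
  pr <- x$per_repeat
  boxplot(list(alpha = pr$alpha, shuffled = pr$shuffle_alpha),
          ylab = "capacity (manifolds / dimension)", ...)
  invisible(x)
}
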