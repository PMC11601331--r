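#' Specification of a virtual odor panel
#'
#' Describes a set of virtual odors by class membership, target pairwise
#' pattern correlations and per-odor response amplitudes, for the
#' olfactory-bulb input generator [make_ob_patterns].
#'
#' @param class_labels character vector of per-odor class tags (e.g.
#'   `c("A","A","A","B","B","B")`); names become odor ids, otherwise ids are
#'   `<class><index>` (A1, A2, ...).
#' @param target_correlation either a full symmetric correlation matrix, or
#'   a list with `within` (named per-class within-class correlation, or a
#'   single number) and `across` (across-class correlation, default 0).
#' @param response_amplitude per-odor firing-rate increase of up-modulated
#'   mitral cells (Hz).
#' @return object of class `"odor_panel"`.
#' @export
odor_panel <- function(class_labels, target_correlation = list(within = 0.5,
                                                               across = 0),
                       response_amplitude = NULL) {
  n <- length(class_labels)
  ids <- names(class_labels)
  if (is.null(ids)) {
    ids <- character(n)
    for (cl in unique(class_labels)) {
      idx <- which(class_labels == cl)
      ids[idx] <- paste0(cl, seq_along(idx))
    }
  }
  if (is.list(target_correlation)) {
    w <- target_correlation$within
    a <- if (is.null(target_correlation$across)) 0 else
      target_correlation$across
    R <- matrix(a, n, n)
    for (cl in unique(class_labels)) {
      idx <- which(class_labels == cl)
      wc <- if (length(w) > 1) w[[cl]] else w
      R[idx, idx] <- wc
    }
    diag(R) <- 1
    target_correlation <- R
  }
  R <- as.matrix(target_correlation)
  if (!isTRUE(all.equal(R, t(R))) || any(abs(diag(R) - 1) > 1e-12))
    stop("target_correlation must be symmetric with unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("target_correlation is not positive semidefinite")
  if (is.null(response_amplitude)) response_amplitude <- rep(9, n)
  stopifnot(length(response_amplitude) == n)
  structure(list(n_odors = n, ids = ids, class_labels = class_labels,
                 target_correlation = R,
                 response_amplitude = response_amplitude),
            class = "odor_panel")
}

#' Default six-odor panel (two correlated classes)
#'
#' Six virtual odors in two classes, A1-A3 and B1-B3, with within-class
#' correlated and across-class uncorrelated input patterns, mimicking the
#' amino-acid / bile-acid structure of the experimental panel.  A-odors are
#' given a larger response amplitude than B-odors.
#'
#' @param r_within within-class target correlation (default 0.5).
#' @param amp_A,amp_B up-cell rate increase (Hz) for A- and B-odors.
#' @return an [odor_panel].
#' @export
default_odor_panel <- function(r_within = 0.5, amp_A = 15, amp_B = 12) {
  odor_panel(c("A", "A", "A", "B", "B", "B"),
             target_correlation = list(within = r_within, across = 0),
             response_amplitude = c(rep(amp_A, 3), rep(amp_B, 3)))
}

#' Generate mitral-cell activity patterns for a virtual odor panel
#'
#' Each odor increases the firing rate of exactly `n_up` mitral cells and
#' decreases the rate of another `n_down` cells relative to baseline.
#' Pairwise pattern correlations are tuned by a shared-subset construction:
#' all odors share a small global core of modulated cells (tuned to the
#' across-class target) and odors of the same class additionally share a
#' class core (tuned to the within-class target).  Core sizes are found by
#' bisection on the achieved correlation, which is monotone in the overlap.
#'
#' @param spec an [odor_panel].
#' @param n_mitral number of mitral cells.
#' @param baseline_rate baseline firing rate (Hz).
#' @param n_up,n_down number of up-/down-modulated cells per odor.
#' @param down_rate firing rate of down-modulated cells (Hz).
#' @param tol tolerance on |achieved - target| correlation.
#' @param seed optional RNG seed.
#' @return object of class `"ob_patterns"`: list with `rates` (`n_mitral x
#'   n_odors` Hz), `achieved_correlation`, `up_sets`, `down_sets`, `spec`.
#' @export
make_ob_patterns <- function(spec, n_mitral = 1500, baseline_rate = 6,
                             n_up = 150, n_down = 75, down_rate = 1,
                             tol = 0.05, seed = NULL) {
  stopifnot(inherits(spec, "odor_panel"))
  if (n_up + n_down > n_mitral)
    stop("n_up + n_down must not exceed n_mitral")
  if (baseline_rate <= 0) stop("baseline_rate must be positive")
  if (!is.null(seed)) set.seed(seed)
  R <- spec$target_correlation
  cls <- spec$class_labels
  n <- spec$n_odors
  # the mechanism produces a class-block structure; verify the request fits
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same <- cls[i] == cls[j]
    ref <- if (same) R[which(cls == cls[i])[1], which(cls == cls[i])[2]] else
      R[which(cls == unique(cls)[1])[1],
        which(cls == unique(cls)[length(unique(cls))])[1]]
    if (abs(R[i, j] - ref) > 1e-9)
      stop("target correlation for pair (", spec$ids[i], ", ", spec$ids[j],
           ") is unreachable with the shared-subset mechanism ",
           "(non block-constant target)")
  }
  r_across <- if (length(unique(cls)) > 1)
    R[which(cls == cls[1])[1], which(cls != cls[1])[1]] else 0

  build <- function(kg_up, kc_up) {
    # kg_up: global core size; kc_up per-class core size (up cells)
    kg_dn <- round(kg_up * n_down / n_up)
    kc_dn <- vapply(kc_up, function(k) round(k * n_down / n_up), numeric(1))
    pool <- seq_len(n_mitral)
    take <- function(m) {
      if (m <= 0) return(integer(0))
      if (m > length(pool)) stop("not enough mitral cells for the ",
                                 "requested overlap structure")
      got <- pool[seq_len(m)]
      pool <<- pool[-seq_len(m)]
      got
    }
    gcore_up <- take(kg_up); gcore_dn <- take(kg_dn)
    up_sets <- vector("list", n); dn_sets <- vector("list", n)
    for (cl in unique(cls)) {
      idx <- which(cls == cl)
      ccore_up <- take(kc_up[[cl]]); ccore_dn <- take(kc_dn[[cl]])
      for (i in idx) {
        up_sets[[i]] <- c(gcore_up, ccore_up,
                          take(n_up - kg_up - kc_up[[cl]]))
        dn_sets[[i]] <- c(gcore_dn, ccore_dn,
                          take(n_down - kg_dn - kc_dn[[cl]]))
      }
    }
    rates <- matrix(baseline_rate, n_mitral, n)
    for (i in seq_len(n)) {
      rates[up_sets[[i]], i] <- baseline_rate + spec$response_amplitude[i]
      rates[dn_sets[[i]], i] <- down_rate
    }
    list(rates = rates, up = up_sets, dn = dn_sets)
  }
  mean_corr <- function(rates, pairs) {
    if (nrow(pairs) == 0) return(NA_real_)
    mean(apply(pairs, 1, function(p) cor(rates[, p[1]], rates[, p[2]])))
  }
  classes <- unique(cls)
  within_pairs <- do.call(rbind, lapply(classes, function(cl) {
    idx <- which(cls == cl)
    if (length(idx) < 2) return(NULL)
    t(combn(idx, 2))
  }))
  across_pairs <- if (length(classes) > 1)
    do.call(rbind, apply(t(combn(seq_along(classes), 2)), 1, function(p) {
      expand.grid(which(cls == classes[p[1]]), which(cls == classes[p[2]]))
    })) else matrix(integer(0), 0, 2)
  across_pairs <- as.matrix(across_pairs)

  # bisection on the global core (across-class correlation), then on the
  # class cores (within-class); achieved correlation is monotone in both
  bisect <- function(lo, hi, f, target) {
    if (f(hi) < target) return(hi)
    if (f(lo) > target) return(lo)
    while (hi - lo > 1) {
      mid <- (lo + hi) %/% 2
      if (f(mid) < target) lo <- mid else hi <- mid
    }
    if (abs(f(lo) - target) <= abs(f(hi) - target)) lo else hi
  }
  kg_max <- n_up %/% 2
  kg <- if (nrow(across_pairs) > 0)
    bisect(0, kg_max, function(k) {
      b <- build(k, stats::setNames(rep(0, length(classes)), classes))
      mean_corr(b$rates, across_pairs)
    }, r_across) else 0
  kc <- stats::setNames(rep(0, length(classes)), classes)
  for (cl in classes) {
    idx <- which(cls == cl)
    if (length(idx) < 2) next
    pr <- t(combn(idx, 2))
    targ <- R[pr[1, 1], pr[1, 2]]
    kc[cl] <- bisect(0, n_up - kg, function(k) {
      k2 <- kc; k2[cl] <- k
      mean_corr(build(kg, k2)$rates, pr)
    }, targ)
  }
  b <- build(kg, kc)
  ach <- suppressWarnings(cor(b$rates))
  dimnames(ach) <- list(spec$ids, spec$ids)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (abs(ach[i, j] - R[i, j]) > tol)
      stop("achieved correlation ", round(ach[i, j], 3), " for pair (",
           spec$ids[i], ", ", spec$ids[j], ") misses target ", R[i, j],
           " by more than ", tol,
           " (unreachable with the shared-subset mechanism)")
  colnames(b$rates) <- spec$ids
  structure(list(rates = b$rates, achieved_correlation = ach,
                 up_sets = stats::setNames(b$up, spec$ids),
                 down_sets = stats::setNames(b$dn, spec$ids),
                 baseline_rate = baseline_rate, spec = spec),
            class = "ob_patterns")
}

#' @export
print.ob_patterns <- function(x, ...) {
  cat(sprintf("<ob_patterns> %d odors x %d mitral cells (baseline %g Hz)\n",
              ncol(x$rates), nrow(x$rates), x$baseline_rate))
  cat("achieved correlations:\n")
  print(round(x$achieved_correlation, 3))
  invisible(x)
}

#' Specification of a synthetic manifold
#'
#' @param n_neurons state-space dimension.
#' @param n_points points to draw.
#' @param center length-`n_neurons` center (rate units); a scalar is
#'   recycled.
#' @param covariance either a full covariance matrix, a scalar (isotropic
#'   variance), or a list with `eigenvalues` and optional `axes`
#'   (orthonormal columns; completed/identity if absent).
#' @param noise_model `"gaussian"` (additive) or `"lognormal"`
#'   (multiplicative rate noise with the requested log-scale covariance).
#' @param label optional label.
#' @return object of class `"synthetic_manifold_spec"`.
#' @export
synthetic_manifold_spec <- function(n_neurons, n_points, center = 0,
                                    covariance = 1,
                                    noise_model = c("gaussian", "lognormal"),
                                    label = NULL) {
  noise_model <- match.arg(noise_model)
  if (length(center) == 1) center <- rep(center, n_neurons)
  stopifnot(length(center) == n_neurons, n_points >= 2)
  structure(list(n_neurons = n_neurons, n_points = as.integer(n_points),
                 center = as.numeric(center), covariance = covariance,
                 noise_model = noise_model, label = label),
            class = "synthetic_manifold_spec")
}

cov_factor <- function(covariance, n) {
  if (is.list(covariance)) {
    ev <- covariance$eigenvalues
    U <- covariance$axes
    if (is.null(U)) U <- diag(n)[, seq_along(ev), drop = FALSE]
    if (any(ev < -1e-10 * max(abs(ev), 1)))
      stop("requested covariance is not positive semidefinite")
    return(U %*% diag(sqrt(pmax(ev, 0)), length(ev)))
  }
  if (length(covariance) == 1) return(diag(sqrt(covariance), n))
  S <- as.matrix(covariance)
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values), 1))
    stop("requested covariance is not positive semidefinite")
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), n)
}

#' Generate synthetic manifolds with controlled geometry
#'
#' Draws each manifold as `n_points` samples from the specified
#' center/covariance model.  Negative rates are clipped at zero and the
#' clipped fraction is recorded (warning above 1%).
#'
#' @param specs list of [synthetic_manifold_spec] (sharing `n_neurons`).
#' @param seed optional RNG seed.
#' @param clip clip rates at zero (default `TRUE`).
#' @return list of [manifold] objects; each carries attribute
#'   `clip_fraction`.
#' @export
make_synthetic_manifolds <- function(specs, seed = NULL, clip = TRUE) {
  if (inherits(specs, "synthetic_manifold_spec")) specs <- list(specs)
  ns <- unique(vapply(specs, `[[`, numeric(1), "n_neurons"))
  if (length(ns) != 1) stop("all specs must share n_neurons")
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    L <- cov_factor(sp$covariance, sp$n_neurons)
    Z <- matrix(rnorm(sp$n_points * ncol(L)), sp$n_points)
    X <- Z %*% t(L)
    X <- if (sp$noise_model == "lognormal")
      sweep(exp(X), 2, sp$center, `*`) else sweep(X, 2, sp$center, `+`)
    frac <- 0
    if (clip) {
      frac <- mean(X < 0)
      X <- pmax(X, 0)
      if (frac > 0.01)
        warning(sprintf("manifold %d: %.1f%% of rates clipped at zero",
                        i, 100 * frac))
    }
    m <- manifold(X, label = if (is.null(sp$label)) paste0("S", i) else
      sp$label)
    attr(m, "clip_fraction") <- frac
    m
  })
}

#' Shuffle manifold labels (pooled-relabel null control)
#'
#' Pools the points of two (or more) manifolds and reassigns them uniformly
#' at random, without replacement, into pseudo-manifolds of the original
#' sizes.  The union of points is preserved exactly.
#'
#' @param manifold_pair list of [manifold] objects (or matrices).
#' @param seed optional RNG seed.
#' @return list of pseudo-manifolds of the original sizes.
#' @export
shuffle_labels <- function(manifold_pair, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pts <- lapply(manifold_pair, points_of)
  sizes <- vapply(pts, nrow, integer(1))
  pooled <- do.call(rbind, pts)
  perm <- sample.int(nrow(pooled))
  bnd <- cumsum(sizes)
  lapply(seq_along(pts), function(mu) {
    lo <- if (mu == 1) 1L else bnd[mu - 1] + 1L
    manifold(pooled[perm[lo:bnd[mu]], , drop = FALSE],
             label = paste0("shuffle", mu))
  })
}

#' Synthetic odor-evoked activity with phasic-tonic time course
#'
#' Emulates a trial-resolved calcium-imaging style recording: per-neuron
#' odor tuning drawn from a correlated pattern model, modulated in time by a
#' phasic-tonic envelope (fast rise at odor onset, exponential decay to a
#' tonic plateau), plus trial and time-bin noise.  Useful as a stand-in for
#' imaging data when exercising [build_manifolds] and the distance/capacity
#' stages.
#'
#' @param n_neurons,n_odors,n_trials dimensions of the session.
#' @param rate_hz sampling rate (bins per second; 7.5 matches the imaging
#'   convention).
#' @param t_total total duration (s); odor onset at `t_on`.
#' @param t_on odor onset time (s).
#' @param amplitude mean evoked rate increase at peak.
#' @param tonic_frac plateau amplitude as a fraction of the peak.
#' @param tau_decay decay time constant of the phasic component (s).
#' @param noise_sd additive noise SD per bin.
#' @param baseline baseline rate.
#' @param r_within within-class tuning correlation (two odor classes).
#' @param seed optional RNG seed.
#' @return 4-d array `neurons x timebins x trials x odors` with attributes
#'   `bin_s` and `t0`, suitable for [build_manifolds].
#' @export
synthetic_odor_session <- function(n_neurons = 200, n_odors = 2,
                                   n_trials = 3, rate_hz = 7.5,
                                   t_total = 8, t_on = 1, amplitude = 1,
                                   tonic_frac = 0.4, tau_decay = 1.5,
                                   noise_sd = 0.2, baseline = 0.1,
                                   r_within = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bin_s <- 1 / rate_hz
  n_bins <- floor(t_total * rate_hz)
  tt <- (seq_len(n_bins) - 1) * bin_s
  env <- ifelse(tt < t_on, 0,
                tonic_frac + (1 - tonic_frac) * exp(-(tt - t_on) / tau_decay))
  cls <- rep(c("A", "B"), length.out = n_odors)
  shared <- lapply(unique(cls), function(cl) rnorm(n_neurons))
  names(shared) <- unique(cls)
  tuning <- vapply(seq_len(n_odors), function(o) {
    sqrt(r_within) * shared[[cls[o]]] +
      sqrt(1 - r_within) * rnorm(n_neurons)
  }, numeric(n_neurons))
  onames <- character(n_odors)
  for (cl in unique(cls)) {
    idx <- which(cls == cl)
    onames[idx] <- paste0(cl, seq_along(idx))
  }
  arr <- array(0, c(n_neurons, n_bins, n_trials, n_odors),
               dimnames = list(NULL, NULL, NULL, onames))
  for (o in seq_len(n_odors)) for (tr in seq_len(n_trials)) {
    m <- baseline + amplitude * outer(pmax(tuning[, o], 0), env)
    arr[, , tr, o] <- pmax(m + rnorm(length(m), sd = noise_sd), 0)
  }
  attr(arr, "bin_s") <- bin_s
  attr(arr, "t0") <- 0
  arr
}
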