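#' Neural manifold: a labeled point cloud in neuronal state space
#'
#' A manifold is the set of population activity vectors evoked by one
#' stimulus, pooled over trials and time bins: an `M x N` matrix of `M`
#' activity patterns over `N` neurons, together with a stimulus label and
#' (optionally) metadata about the time window the points were taken from.
#'
#' @param points numeric `M x N` matrix (rows = activity vectors).
#' @param label stimulus (odor) label.
#' @param window optional list with elements such as `start`, `duration`,
#'   `bin_s`, `trials` describing how the points were pooled.
#' @return An object of class `"manifold"`.
#' @export
manifold <- function(points, label = NULL, window = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (anyNA(points)) stop("manifold points must not contain missing values")
  structure(list(points = points, label = label, window = window),
            class = "manifold")
}

#' @export
print.manifold <- function(x, ...) {
  cat(sprintf("<manifold> %s: %d points x %d neurons\n",
              if (is.null(x$label)) "(unlabeled)" else x$label,
              nrow(x$points), ncol(x$points)))
  invisible(x)
}

as_manifold <- function(x, label = NULL) {
  if (inherits(x, "manifold")) x else manifold(x, label = label)
}

n_points  <- function(m) nrow(m$points)
n_neurons <- function(m) ncol(m$points)

#' Build trial-pooled odor manifolds from a rate array
#'
#' Pools binned population activity across trials within an analysis window,
#' yielding one manifold per stimulus.  For the imaging-style geometry (3 s
#' window at 7.5 Hz, 3 trials) this yields 72 points per manifold; for the
#' model output (2 s window, 100 ms bins, 4 trials), 80 points.
#'
#' @param rates 4-d numeric array `neurons x timebins x trials x odors`, with
#'   attribute `bin_s` (bin width, seconds) and optionally `t0` (time of the
#'   first bin's left edge, default 0).  Odor names are taken from
#'   `dimnames(rates)[[4]]`.
#' @param window numeric length-2 `c(start, end)` in seconds, relative to the
#'   recording origin; all bins whose left edge falls in `[start, end)` are
#'   used.
#' @param trials optional integer vector of trials to pool (default all).
#' @return A list of [manifold] objects, one per odor.
#' @export
build_manifolds <- function(rates, window = NULL, trials = NULL) {
  stopifnot(length(dim(rates)) == 4)
  bin_s <- attr(rates, "bin_s")
  if (is.null(bin_s)) stop("rates array must carry a 'bin_s' attribute")
  t0 <- attr(rates, "t0")
  if (is.null(t0)) t0 <- 0
  n_bins <- dim(rates)[2]
  edges <- t0 + (seq_len(n_bins) - 1) * bin_s
  if (is.null(window)) window <- c(edges[1], edges[n_bins] + bin_s)
  keep <- which(edges >= window[1] & edges < window[2])
  if (length(keep) == 0)
    stop("analysis window [", window[1], ", ", window[2],
         ") lies outside the recording")
  if (is.null(trials)) trials <- seq_len(dim(rates)[3])
  if (any(trials > dim(rates)[3]))
    stop("requested trials not available in the recording")
  odors <- dimnames(rates)[[4]]
  if (is.null(odors)) odors <- paste0("odor", seq_len(dim(rates)[4]))
  lapply(seq_len(dim(rates)[4]), function(o) {
    pts <- do.call(rbind, lapply(trials, function(tr) {
      t(rates[, keep, tr, o, drop = TRUE])   # bins x neurons
    }))
    manifold(pts, label = odors[o],
             window = list(start = window[1], duration = diff(window),
                           bin_s = bin_s, trials = trials))
  })
}
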