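#' Simulate the pDp network
#'
#' Integrates the adaptive conductance-based leaky integrate-and-fire
#' network (forward Euler for the membrane, exact exponential decay for the
#' conductances) driven by inhomogeneous-Poisson mitral-cell spike trains
#' with piecewise-constant rates.  One shared olfactory-bulb spike process
#' drives both E and I targets.
#'
#' @param conn a [build_connectivity] (possibly rewired) result.
#' @param params a [pdp_params].
#' @param ob_rates mitral rates: either a vector (length `n_ob`, constant in
#'   time) or a matrix `n_ob x n_epochs` of piecewise-constant rates (Hz).
#' @param epochs durations (s) of the epochs (lengths must match
#'   `ncol(ob_rates)`).
#' @param dt integration step (s; default 0.1 ms).
#' @param bin_s width of the rate bins (s; default 100 ms).
#' @param seed optional RNG seed.
#' @param record_spikes keep individual spike times.
#' @param v_init optional initial membrane potentials (V), length
#'   `n_e + n_i`.
#' @param record_v optional neuron index (E neurons first) whose voltage
#'   trace is returned at full temporal resolution.
#' @return object of class `"pdp_sim"`: list with `rates` (`(n_e + n_i) x
#'   n_bins` Hz, E rows first), `e_rates` (E rows only), `spikes` (data
#'   frame `t`, `id`, `pop`), `bin_s`, `dt`, `duration`.
#' @export
simulate_pdp <- function(conn, params, ob_rates, epochs, dt = 1e-4,
                         bin_s = 0.1, seed = NULL, record_spikes = TRUE,
                         v_init = NULL, record_v = NULL) {
  if (is.vector(ob_rates)) ob_rates <- matrix(ob_rates, ncol = 1)
  stopifnot(nrow(ob_rates) == params$n_ob, length(epochs) == ncol(ob_rates),
            all(ob_rates >= 0))
  duration <- sum(epochs)
  n_steps <- as.integer(round(duration / dt))
  if (abs(n_steps * dt - duration) > 1e-9)
    stop("dt must divide the total duration")
  bin_steps <- as.integer(round(bin_s / dt))
  epoch_end <- as.integer(round(cumsum(epochs) / dt))
  csr <- build_csr(conn, params)
  if (!is.null(seed)) set.seed(seed)
  out <- lif_simulate(params$n_ob, params$n_e, params$n_i,
                      csr$ptr, csr$tgt, csr$w, params[csr$par_names],
                      ob_rates, epoch_end, dt, n_steps, bin_steps,
                      record_spikes,
                      if (is.null(v_init)) numeric(0) else v_init,
                      if (is.null(record_v)) -1L else as.integer(record_v) - 1L)
  rates <- out$counts / bin_s
  spikes <- if (record_spikes)
    data.frame(t = out$spike_t,
               id = out$spike_id + 1L,
               pop = ifelse(out$spike_id < params$n_e, "E", "I"))
  else NULL
  structure(list(rates = rates, e_rates = rates[seq_len(params$n_e), ,
                                                drop = FALSE],
                 spikes = spikes,
                 ob_spikes = if (record_spikes)
                   data.frame(t = out$ob_spike_t, id = out$ob_spike_id + 1L)
                 else NULL,
                 vtrace = if (!is.null(record_v)) out$vtrace else NULL,
                 bin_s = bin_s, dt = dt, duration = duration,
                 setting = params$setting),
            class = "pdp_sim")
}

build_csr <- function(conn, params) {
  n_src <- params$n_ob + params$n_e + params$n_i
  off_src <- c(ob = 0L, e = params$n_ob, i = params$n_ob + params$n_e)
  off_tgt <- c(e = 0L, i = params$n_e)
  spec <- list(ob_e = c("ob", "e"), ob_i = c("ob", "i"),
               ee = c("e", "e"), ei = c("e", "i"),
               ie = c("i", "e"), ii = c("i", "i"))
  src <- tgt <- integer(0); w <- numeric(0)
  for (b in names(spec)) {
    ed <- conn$blocks[[b]]
    if (nrow(ed) == 0) next
    src <- c(src, ed[, "src"] + off_src[[spec[[b]][1]]])
    tgt <- c(tgt, ed[, "tgt"] + off_tgt[[spec[[b]][2]]])
    w <- c(w, rep(params$w[[b]] * 1e-12, nrow(ed)))   # pS -> S
  }
  o <- order(src)
  src <- src[o]; tgt <- tgt[o]; w <- w[o]
  ptr <- c(0L, cumsum(tabulate(src, nbins = n_src)))
  list(ptr = as.integer(ptr), tgt = as.integer(tgt - 1L), w = w,
       par_names = c("C_e", "C_i", "g_rest_e", "g_rest_i", "E_rest_e",
                     "E_rest_i", "E_exc", "E_inh", "tau_ob", "tau_exc",
                     "tau_inh", "a", "b", "tau_ad", "V_thr_e", "V_thr_i",
                     "V_reset_e", "V_reset_i", "t_ref"))
}

#' @export
print.pdp_sim <- function(x, ...) {
  ne <- nrow(x$e_rates)
  cat(sprintf("<pdp_sim> %.2f s, dt-binned at %g ms; mean E rate %.2f Hz\n",
              x$duration, 1000 * x$bin_s, mean(x$e_rates)))
  invisible(x)
}

#' Simulate a full odor panel with and without E/I assemblies
#'
#' For each network instantiation: draws a connectivity matrix, builds a
#' rewired twin carrying E/I assemblies for the requested odors, and
#' simulates all odors and trials for both networks.  Excitatory-population
#' activity is binned (100 ms default) and returned as rate arrays suitable
#' for [build_manifolds]; the analysis window is the odor period.
#'
#' @param setting weight setting id (`"A"`-`"D"`).
#' @param assemblies character vector of odor ids to "learn" (may be empty
#'   for a no-assembly control only).
#' @param panel an [odor_panel] (default [default_odor_panel]).
#' @param n_up,n_down mitral cells up-/down-modulated per odor.
#' @param n_trials trials per odor (default 4).
#' @param n_instantiations independent connectivity draws (default 2).
#' @param t_baseline,t_odor pre-odor and odor durations (s).
#' @param dt,bin_s integration step and rate-bin width (s).
#' @param seed RNG seed governing everything.
#' @param gain_ee,gain_ei,gain_ie assembly rewiring magnitudes
#'   (see [form_assemblies]).
#' @param ... parameter overrides passed to [pdp_params].
#' @return object of class `"pdp_experiment"`: per instantiation, rate
#'   arrays (`neurons x bins x trials x odors`, attributes `bin_s`,
#'   `t0 = -t_baseline`) for the `none` and (if assemblies requested)
#'   `learned` networks, plus assembly membership.
#' @export
run_experiment <- function(setting = "A", assemblies = c("A1", "A2"),
                           panel = default_odor_panel(), n_up = 150,
                           n_down = 75, n_trials = 4,
                           n_instantiations = 2, t_baseline = 0.5,
                           t_odor = 2, dt = 1e-4, bin_s = 0.1, seed = 1,
                           gain_ee = 9, gain_ei = 10, gain_ie = 3.3, ...) {
  params <- pdp_params(setting, ...)
  set.seed(seed)
  pat <- make_ob_patterns(panel, n_mitral = params$n_ob,
                          n_up = n_up, n_down = n_down)
  odors <- panel$ids
  n_bins <- as.integer(round((t_baseline + t_odor) / bin_s))
  insts <- vector("list", n_instantiations)
  for (k in seq_len(n_instantiations)) {
    conn0 <- build_connectivity(params)
    conn1 <- conn0
    asm <- list()
    for (od in assemblies) {
      fa <- form_assemblies(conn1, pat, params, odor = od,
                            gain_ee = gain_ee, gain_ei = gain_ei,
                            gain_ie = gain_ie)
      conn1 <- fa$conn
      asm[[od]] <- fa$assembly
    }
    nets <- list(none = conn0)
    if (length(assemblies)) nets$learned <- conn1
    arrs <- lapply(nets, function(cn) {
      arr <- array(0, c(params$n_e, n_bins, n_trials, length(odors)),
                   dimnames = list(NULL, NULL, NULL, odors))
      for (o in seq_along(odors)) for (tr in seq_len(n_trials)) {
        obr <- cbind(rep(pat$baseline_rate, params$n_ob),
                     pat$rates[, odors[o]])
        sim <- simulate_pdp(cn, params, obr, c(t_baseline, t_odor),
                            dt = dt, bin_s = bin_s,
                            record_spikes = FALSE)
        arr[, , tr, o] <- sim$e_rates
      }
      attr(arr, "bin_s") <- bin_s
      attr(arr, "t0") <- -t_baseline
      arr
    })
    insts[[k]] <- list(rates = arrs, assemblies = asm,
                       connectivity = nets)
  }
  structure(list(instantiations = insts, setting = setting,
                 panel = panel, patterns = pat, n_trials = n_trials,
                 t_baseline = t_baseline, t_odor = t_odor,
                 bin_s = bin_s, seed = seed,
                 gains = c(ee = gain_ee, ei = gain_ei, ie = gain_ie)),
            class = "pdp_experiment")
}

#' @export
print.pdp_experiment <- function(x, ...) {
  cat(sprintf(
    "<pdp_experiment> setting %s, %d instantiation(s), %d trials, odors: %s\n",
    x$setting, length(x$instantiations), x$n_trials,
    paste(x$panel$ids, collapse = ", ")))
  invisible(x)
}

#' Learning-induced shifts of manifold distances (model prediction)
#'
#' Contrasts the dE/dM matrices of the assembly ("learned") network against
#' the no-assembly control of the same instantiation, averaged over
#' instantiations: the model predicts that assemblies for two learned
#' odors increase dE between learned and other odors (partially
#' generalizing to the related third odor of the learned class), increase
#' dM selectively in the direction learned-class -> other class, and leave
#' distances among the other class essentially unchanged.
#'
#' @param experiment a [run_experiment] result with assemblies.
#' @param window analysis window `c(start, end)` relative to odor onset.
#' @param n_neurons_sub,n_repeats subsampling protocol of
#'   [distance_matrices]; the model analysis defaults to 40-neuron subsets,
#'   which keeps the 80-point reference covariances well conditioned.
#' @param shrink diagonal shrinkage of the reference covariances passed to
#'   [distance_matrices]; spike counts in 100 ms bins carry correlated
#'   fluctuations that destabilize the inverse of a barely-invertible
#'   covariance, and shrinkage toward the diagonal removes that artifact.
#' @param active_min_rate analysis is restricted to neurons whose mean rate
#'   is at least this (Hz) in every manifold of both networks, so that every
#'   reference covariance carries a count-noise floor in all dimensions
#'   (spiking output, unlike inferred imaging rates, contains exact zeros).
#' @param seed RNG seed for the (shared) neuron subsets.
#' @return object of class `"learning_contrast"`: per-instantiation and
#'   mean `delta_dE`/`delta_dM` matrices plus the summary contrasts used as
#'   model predictions.
#' @export
learning_contrast <- function(experiment, window = NULL,
                              n_neurons_sub = 40, n_repeats = 30,
                              active_min_rate = 1.5, shrink = 0.3,
                              seed = 1) {
  stopifnot(inherits(experiment, "pdp_experiment"))
  if (is.null(window)) window <- c(0, experiment$t_odor)
  panel <- experiment$panel
  cls <- panel$class_labels
  learned <- names(experiment$instantiations[[1]]$assemblies)
  if (length(learned) == 0) stop("experiment carries no assemblies")
  lclass <- unique(cls[match(learned, panel$ids)])
  related <- setdiff(panel$ids[cls == lclass], learned)
  others <- panel$ids[cls != lclass]
  ddE <- ddM <- list()
  for (k in seq_along(experiment$instantiations)) {
    inst <- experiment$instantiations[[k]]
    man <- lapply(inst$rates, function(a)
      build_manifolds(a, window = window))
    active <- Reduce(pmin, lapply(c(man$none, man$learned), function(m)
      colMeans(m$points))) >= active_min_rate
    if (sum(active) <= n_neurons_sub)
      stop("fewer than n_neurons_sub neurons pass the activity filter; ",
           "lower active_min_rate or n_neurons_sub")
    man <- lapply(man, function(ml) lapply(ml, function(m)
      manifold(m$points[, active, drop = FALSE], label = m$label)))
    d0 <- distance_matrices(man$none, n_neurons_sub = n_neurons_sub,
                            n_repeats = n_repeats, seed = seed + k,
                            shrink = shrink)
    d1 <- distance_matrices(man$learned, n_neurons_sub = n_neurons_sub,
                            n_repeats = n_repeats, seed = seed + k,
                            shrink = shrink)
    ddE[[k]] <- d1$dE - d0$dE
    ddM[[k]] <- d1$dM - d0$dM
  }
  mean_mat <- function(lst) Reduce(`+`, lst) / length(lst)
  dE <- mean_mat(ddE); dM <- mean_mat(ddM)
  off <- function(m, rows, cols) {
    v <- m[rows, cols, drop = FALSE]
    if (identical(rows, cols)) v <- v[upper.tri(v) | lower.tri(v)]
    mean(v)
  }
  summ <- c(
    dE_learned_other = off(dE, learned, setdiff(panel$ids, learned)),
    dE_related_other = off(dE, related, others),
    dE_BB = off(dE, others, others),
    dM_learned_to_other = off(dM, learned, others),
    dM_other_to_learned = off(dM, others, learned),
    dM_related_to_other = off(dM, related, others),
    dM_BB = off(dM, others, others))
  structure(list(delta_dE = dE, delta_dM = dM, per_instantiation =
                   list(dE = ddE, dM = ddM), summary = summ,
                 learned = learned, related = related, others = others),
            class = "learning_contrast")
}

#' @export
print.learning_contrast <- function(x, digits = 3, ...) {
  cat("Learning-induced distance shifts (assembly - control)\n")
  cat("  learned:", paste(x$learned, collapse = ", "),
      "| related:", paste(x$related, collapse = ", "),
      "| others:", paste(x$others, collapse = ", "), "\n")
  print(round(x$summary, digits))
  invisible(x)
}
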