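#' Parameters of the pDp spiking network
#'
#' Bundles all constants of the membrane, synapse and adaptation equations,
#' the Bernoulli connection probabilities and the synaptic weight table.
#' Weights follow one of four predefined settings A-D (pS); the weight
#' table is also shipped as `inst/extdata/weight_settings.csv`.  Membrane,
#' adaptation, spiking-mechanism constants and connection probabilities are
#' package defaults (configurable): they are chosen to place the network in
#' a balanced, low-rate regime and are documented in the methods vignette.
#'
#' @param setting weight setting `"A"`, `"B"`, `"C"` or `"D"`.
#' @param ... overrides of any default (see the returned list for names).
#' @return list of class `"pdp_params"`.
#' @export
pdp_params <- function(setting = c("A", "B", "C", "D"), ...) {
  setting <- match.arg(setting)
  w <- weight_table()[setting, ]
  p <- list(
    n_e = 1000L, n_i = 250L, n_ob = 1500L,
    # membrane (SI units)
    C_e = 200e-12, C_i = 100e-12,          # F
    g_rest_e = 10e-9, g_rest_i = 10e-9,    # S
    E_rest_e = -70e-3, E_rest_i = -65e-3,  # V
    E_exc = 0, E_inh = -85e-3,
    V_thr_e = -50e-3, V_thr_i = -50e-3,
    V_reset_e = -70e-3, V_reset_i = -65e-3,
    t_ref = 2e-3,
    # synaptic time constants (s)
    tau_ob = 30e-3, tau_exc = 30e-3, tau_inh = 10e-3,
    # adaptation (E cells)
    a = 2e-9, b = 50e-12, tau_ad = 0.2,
    # Bernoulli connection probabilities (source -> target)
    p_ob_e = 0.085, p_ob_i = 0.05,
    p_ee = 0.10, p_ei = 0.10, p_ie = 0.30, p_ii = 0.20,
    # weight setting (pS)
    setting = setting,
    w = c(ee = w[["ee"]], ie = w[["ie"]], ob_e = w[["ob_e"]],
          ei = w[["ei"]], ob_i = w[["ob_i"]], ii = w[["ii"]]))
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  stopifnot(p$C_e > 0, p$C_i > 0, p$g_rest_e > 0, p$g_rest_i > 0,
            all(unlist(p[c("p_ob_e", "p_ob_i", "p_ee", "p_ei",
                           "p_ie", "p_ii")]) >= 0),
            all(unlist(p[c("p_ob_e", "p_ob_i", "p_ee", "p_ei",
                           "p_ie", "p_ii")]) <= 1),
            length(p$w) == 6)
  class(p) <- "pdp_params"
  p
}

#' Synaptic weight settings A-D (pS)
#'
#' The four fitted weight-strength settings of the juvenile-scale network:
#' columns are exc->exc, inh->exc, OB->exc, exc->inh, OB->inh, inh->inh.
#'
#' @return data frame with rows A-D.
#' @export
weight_table <- function() {
  f <- system.file("extdata", "weight_settings.csv", package = "pdpmanifold")
  tab <- if (nzchar(f)) read.csv(f, row.names = 1) else
    data.frame(ee = c(95, 94, 80, 95), ie = c(410, 400, 450, 520),
               ob_e = c(128, 128, 128, 95), ei = c(58, 58, 68, 51),
               ob_i = c(68, 66, 68, 42), ii = c(180, 150, 220, 190),
               row.names = c("A", "B", "C", "D"))
  tab
}

#' @export
print.pdp_params <- function(x, ...) {
  cat(sprintf("<pdp_params> setting %s: %d E, %d I, %d OB\n",
              x$setting, x$n_e, x$n_i, x$n_ob))
  cat("weights (pS): ", paste(names(x$w), x$w, sep = "=", collapse = " "),
      "\n")
  invisible(x)
}

block_dims <- function(params) {
  with(params, list(
    ob_e = c(n_ob, n_e), ob_i = c(n_ob, n_i),
    ee = c(n_e, n_e), ei = c(n_e, n_i),
    ie = c(n_i, n_e), ii = c(n_i, n_i)))
}

block_prob <- function(params) {
  with(params, c(ob_e = p_ob_e, ob_i = p_ob_i, ee = p_ee, ei = p_ei,
                 ie = p_ie, ii = p_ii))
}

#' Draw the Bernoulli connectivity of the network
#'
#' Every potential connection of each population pair exists independently
#' with its pair's probability; existing connections carry the pair's
#' weight.  Self-connections are excluded.
#'
#' @param params a [pdp_params].
#' @param seed optional RNG seed.
#' @return object of class `"pdp_connectivity"`: a list of edge matrices
#'   (columns `src`, `tgt`, population-local 1-based indices) per block
#'   `ob_e, ob_i, ee, ei, ie, ii`, with per-block connection counts.
#' @export
build_connectivity <- function(params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dims <- block_dims(params)
  probs <- block_prob(params)
  blocks <- lapply(names(dims), function(b) {
    ns <- dims[[b]][1]; nt <- dims[[b]][2]
    p <- probs[[b]]
    if (p <= 0) return(cbind(src = integer(0), tgt = integer(0)))
    idx <- which(runif(ns * nt) < p)
    src <- (idx - 1L) %% ns + 1L
    tgt <- (idx - 1L) %/% ns + 1L
    if (b %in% c("ee", "ii")) {
      keep <- src != tgt
      src <- src[keep]; tgt <- tgt[keep]
    }
    cbind(src = src, tgt = tgt)
  })
  names(blocks) <- names(dims)
  structure(list(blocks = blocks,
                 counts = vapply(blocks, nrow, integer(1)),
                 params_setting = params$setting),
            class = "pdp_connectivity")
}

#' @export
print.pdp_connectivity <- function(x, ...) {
  cat("<pdp_connectivity> connections per block:\n")
  print(x$counts)
  invisible(x)
}

sample_absent_pairs <- function(edges, srcs, tgts, n_add, no_self = FALSE) {
  # enumerate candidate (src,tgt) pairs among the given members, drop
  # existing edges, sample n_add absent ones
  cand <- expand.grid(src = srcs, tgt = tgts)
  if (no_self) cand <- cand[cand$src != cand$tgt, ]
  key <- function(s, t) paste(s, t)
  exist <- key(edges[, "src"], edges[, "tgt"])
  cand <- cand[!(key(cand$src, cand$tgt) %in% exist), , drop = FALSE]
  if (nrow(cand) < n_add)
    stop("cannot add ", n_add, " connections: only ", nrow(cand),
         " absent pairs available (deficit ", n_add - nrow(cand), ")")
  cand[sample.int(nrow(cand), n_add), , drop = FALSE]
}

#' Impose an E/I assembly for one odor by connectivity rewiring
#'
#' The E-assembly is the 100 excitatory neurons receiving the most
#' connections from the odor's activated (up-modulated) mitral cells; the
#' I-assembly is the 25 inhibitory neurons receiving the most connections
#' from the E-assembly.  Connections are added within the E-assembly and
#' between E- and I-assembly (both directions), and an equal number of
#' connections from non-assembly to assembly neurons is removed in each
#' block, so per-block connection counts are conserved exactly.  Ties in
#' the degree ranking are broken by lowest neuron id.
#'
#' @param conn a [build_connectivity] result.
#' @param ob_pattern integer vector of activated mitral-cell ids (the odor's
#'   up-set), or an `"ob_patterns"` object together with `odor`.
#' @param params a [pdp_params].
#' @param odor odor id (when `ob_pattern` is an `ob_patterns` object).
#' @param n_assembly_e,n_assembly_i assembly sizes (defaults 100 / 25).
#' @param gain_ee,gain_ei,gain_ie rewiring magnitude: the connection density
#'   among assembly members is raised to `min(gain * p, 1)` in each enhanced
#'   block (`gain = 1` leaves the network untouched).
#' @param seed optional RNG seed.
#' @return list with `conn` (rewired connectivity) and `assembly` (list
#'   with `odor`, `E_members`, `I_members`, `n_added` per block).
#' @export
form_assemblies <- function(conn, ob_pattern, params, odor = NULL,
                            n_assembly_e = 100L, n_assembly_i = 25L,
                            gain_ee = 9, gain_ei = 10, gain_ie = 3.3,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  up <- if (inherits(ob_pattern, "ob_patterns")) {
    stopifnot(!is.null(odor))
    ob_pattern$up_sets[[odor]]
  } else as.integer(ob_pattern)
  topk <- function(deg, k) order(-deg, seq_along(deg))[seq_len(k)]
  obe <- conn$blocks$ob_e
  deg_e <- tabulate(obe[obe[, "src"] %in% up, "tgt"], nbins = params$n_e)
  E_members <- sort(topk(deg_e, n_assembly_e))
  ei <- conn$blocks$ei
  deg_i <- tabulate(ei[ei[, "src"] %in% E_members, "tgt"],
                    nbins = params$n_i)
  I_members <- sort(topk(deg_i, n_assembly_i))

  rewire <- function(block, srcs, tgts, p, gain, no_self) {
    edges <- conn$blocks[[block]]
    n_pairs <- length(srcs) * length(tgts) - if (no_self)
      length(intersect(srcs, tgts)) else 0
    if (gain <= 1) return(list(edges = edges, n_add = 0L))
    existing <- sum(edges[, "src"] %in% srcs & edges[, "tgt"] %in% tgts)
    # raise the connection density among assembly members to gain * p
    n_add <- round(min(gain * p, 1) * n_pairs) - existing
    if (n_add <= 0) return(list(edges = edges, n_add = 0L))
    add <- sample_absent_pairs(edges, srcs, tgts, n_add, no_self)
    # remove the same number of connections from non-assembly sources onto
    # assembly targets
    removable <- which(!(edges[, "src"] %in% srcs) &
                         (edges[, "tgt"] %in% tgts))
    if (length(removable) < n_add)
      stop("not enough removable connections in block ", block,
           " (deficit ", n_add - length(removable), ")")
    drop <- removable[sample.int(length(removable), n_add)]
    edges <- rbind(edges[-drop, , drop = FALSE],
                   cbind(src = add$src, tgt = add$tgt))
    list(edges = edges, n_add = n_add)
  }
  r_ee <- rewire("ee", E_members, E_members, params$p_ee, gain_ee, TRUE)
  conn$blocks$ee <- r_ee$edges
  r_ei <- rewire("ei", E_members, I_members, params$p_ei, gain_ei, FALSE)
  conn$blocks$ei <- r_ei$edges
  r_ie <- rewire("ie", I_members, E_members, params$p_ie, gain_ie, FALSE)
  conn$blocks$ie <- r_ie$edges
  conn$counts <- vapply(conn$blocks, nrow, integer(1))
  list(conn = conn,
       assembly = list(odor = odor, E_members = E_members,
                       I_members = I_members,
                       n_added = c(ee = r_ee$n_add, ei = r_ei$n_add,
                                   ie = r_ie$n_add)))
}
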