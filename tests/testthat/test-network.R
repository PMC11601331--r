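small_params <- function(...) {
  pdp_params("A", n_e = 100L, n_i = 25L, n_ob = 150L, ...)
}

test_that("Bernoulli connectivity has the right weights and counts", {
  p <- pdp_params("A")
  # zero probability -> empty matrix
  p0 <- pdp_params("A", p_ob_e = 0, p_ob_i = 0, p_ee = 0, p_ei = 0,
                   p_ie = 0, p_ii = 0)
  c0 <- build_connectivity(p0, seed = 1)
  expect_true(all(c0$counts == 0))
  # weight setting A: every existing exc->exc connection carries 95 pS
  cn <- build_connectivity(p, seed = 2)
  csr <- pdpmanifold:::build_csr(cn, p)
  src_of <- rep(seq_along(diff(csr$ptr)), diff(csr$ptr))
  is_ee <- src_of > p$n_ob & src_of <= p$n_ob + p$n_e & csr$tgt < p$n_e
  expect_equal(sum(is_ee), unname(cn$counts["ee"]))
  expect_true(all(csr$w[is_ee] == 95e-12))
  # binomial law: E->E count within 4 SD of n p (excluding the diagonal)
  n_pairs <- p$n_e * (p$n_e - 1)
  expect_lt(abs(cn$counts[["ee"]] - n_pairs * p$p_ee),
            4 * sqrt(n_pairs * p$p_ee * (1 - p$p_ee)))
  # no self-connections
  expect_true(all(cn$blocks$ee[, "src"] != cn$blocks$ee[, "tgt"]))
})

test_that("assembly rewiring conserves per-block connection counts exactly", {
  p <- pdp_params("A")
  set.seed(3)
  pat <- make_ob_patterns(default_odor_panel(), n_mitral = p$n_ob)
  cn <- build_connectivity(p)
  fa <- form_assemblies(cn, pat, p, odor = "A1", seed = 4)
  expect_identical(fa$conn$counts, cn$counts)
  expect_length(fa$assembly$E_members, 100)
  expect_length(fa$assembly$I_members, 25)
  expect_false(any(duplicated(fa$assembly$E_members)))
  # a second, overlapping assembly still conserves counts
  fa2 <- form_assemblies(fa$conn, pat, p, odor = "A2", seed = 5)
  expect_identical(fa2$conn$counts, cn$counts)
  # gain 1 in all blocks leaves the connectivity untouched
  fa0 <- form_assemblies(cn, pat, p, odor = "A1", gain_ee = 1,
                         gain_ei = 1, gain_ie = 1, seed = 6)
  expect_identical(fa0$conn$blocks, cn$blocks)
})

test_that("assembly membership equals the top-k input-degree set", {
  p <- small_params()
  cn <- build_connectivity(p, seed = 7)
  up <- 1:30
  # direct degree count on the edge list
  obe <- cn$blocks$ob_e
  deg <- tabulate(obe[obe[, "src"] %in% up, "tgt"], nbins = p$n_e)
  want_E <- sort(order(-deg, seq_along(deg))[1:10])
  fa <- form_assemblies(cn, up, p, n_assembly_e = 10L, n_assembly_i = 5L,
                        gain_ee = 1, gain_ei = 1, gain_ie = 1, seed = 8)
  expect_identical(fa$assembly$E_members, want_E)
})

test_that("rewiring fails informatively when removable connections run out", {
  p <- small_params(p_ee = 0.02)
  cn <- build_connectivity(p, seed = 9)
  expect_error(
    form_assemblies(cn, 1:30, p, n_assembly_e = 90L, n_assembly_i = 5L,
                    gain_ee = 40, gain_ei = 1, gain_ie = 1, seed = 10),
    "deficit")
})

test_that("a quiescent network stays at rest and spikes respect refractoriness", {
  p <- small_params()
  cn <- build_connectivity(p, seed = 11)
  # no input at all -> no spikes
  sim0 <- simulate_pdp(cn, p, rep(0, p$n_ob), 0.5, seed = 12)
  expect_equal(nrow(sim0$spikes), 0)
  expect_true(all(sim0$rates == 0))
  # driven: inter-spike intervals never violate the refractory period
  pat <- make_ob_patterns(odor_panel(c("A", "A"), list(within = 0.5)),
                          n_mitral = p$n_ob, n_up = 15, n_down = 8, seed = 1)
  sim <- simulate_pdp(cn, p, cbind(rep(6, p$n_ob), pat$rates[, 1]),
                      c(0.2, 0.8), seed = 13)
  if (nrow(sim$spikes) > 1) {
    isi <- unlist(tapply(sim$spikes$t, sim$spikes$id, function(tt)
      diff(sort(tt))), use.names = FALSE)
    if (length(isi)) expect_true(all(isi >= p$t_ref - 1e-12))
  }
  # mitral baseline: mean OB spike rate close to 6 Hz
  sim6 <- simulate_pdp(cn, p, rep(6, p$n_ob), 1, seed = 14)
  rate <- nrow(sim6$ob_spikes) / p$n_ob / 1
  expect_lt(abs(rate - 6), 4 * sqrt(6 / p$n_ob))
})

test_that("passive membrane relaxes with time constant C over g", {
  p <- small_params()
  cn <- build_connectivity(pdp_params("A", n_e = 100L, n_i = 25L,
                                      n_ob = 150L, p_ob_e = 0, p_ob_i = 0,
                                      p_ee = 0, p_ei = 0, p_ie = 0,
                                      p_ii = 0), seed = 1)
  p0 <- pdp_params("A", n_e = 100L, n_i = 25L, n_ob = 150L, p_ob_e = 0,
                   p_ob_i = 0, p_ee = 0, p_ei = 0, p_ie = 0, p_ii = 0,
                   a = 0, b = 0)
  v0 <- rep(c(p0$E_rest_e, p0$E_rest_i), c(100, 25))
  v0[1] <- p0$E_rest_e + 10e-3              # displace one E cell by 10 mV
  sim <- simulate_pdp(cn, p0, rep(0, p0$n_ob), 0.2, dt = 5e-5,
                      v_init = v0, record_v = 1)
  v <- sim$vtrace
  t <- (seq_along(v) - 1) * 5e-5
  # fit log-linear decay of the displacement
  d <- v - p0$E_rest_e
  keep <- d > 1e-4 * max(d)
  tau_fit <- -1 / coef(lm(log(d[keep]) ~ t[keep]))[2]
  tau_true <- p0$C_e / p0$g_rest_e
  expect_lt(abs(tau_fit - tau_true) / tau_true, 0.01)
})

test_that("experiments produce the expected rate-array layout", {
  exp <- run_experiment(setting = "B", assemblies = character(0),
                        panel = default_odor_panel(), n_trials = 2,
                        n_instantiations = 1, t_baseline = 0.2,
                        t_odor = 0.6, seed = 1,
                        n_up = 15, n_down = 8,
                        n_e = 100L, n_i = 25L, n_ob = 150L,
                        p_ob_e = 0.2)
  expect_named(exp$instantiations[[1]]$rates, "none")
  arr <- exp$instantiations[[1]]$rates$none
  expect_equal(dim(arr), c(100, 8, 2, 6))
  expect_equal(attr(arr, "t0"), -0.2)
  man <- build_manifolds(arr, window = c(0, 0.6))
  expect_equal(nrow(man[[1]]$points), 12)     # 6 bins x 2 trials
  # two instantiations with the same setting draw distinct connectivity
  e2 <- run_experiment(setting = "B", assemblies = character(0),
                       n_trials = 1, n_instantiations = 2,
                       t_baseline = 0.1, t_odor = 0.2, seed = 2,
                       n_up = 9, n_down = 4,
                       n_e = 60L, n_i = 15L, n_ob = 90L, p_ob_e = 0.2)
  c1 <- e2$instantiations[[1]]$connectivity$none
  c2 <- e2$instantiations[[2]]$connectivity$none
  expect_false(identical(c1$blocks, c2$blocks))
})
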