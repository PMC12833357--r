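# Two-state kinetic receptor model, the mutation scaling and the ALLO
# transform, validated against a brute-force ODE oracle.

test_that("pulse steady state and time constant follow the kinetic rates", {
  # reticular->relay rates with C_max = 0.5 mM: alpha C = 10 /ms
  sp <- synapse_spec("GABAA", g_syn = 0.02, alpha = 20, beta = 0.162)
  expect_equal(s_inf(sp), 10 / 10.162, tolerance = 1e-9)
  expect_equal(tau_s(sp), 1 / 10.162, tolerance = 1e-9)
  expect_error(synapse_spec("AMPA", 0.3, alpha = 0, beta = 0.1), "alpha")
  expect_error(synapse_spec("AMPA", -1, alpha = 0.1, beta = 0.1), "g_syn")
})

test_that("s_profile honours its boundary conditions and limits", {
  sp <- synapse_spec("GABAA", 0.75, alpha = 0.1, beta = 0.01)
  expect_equal(s_profile(sp, s0 = 0.2, t = 0), 0.2)
  expect_lt(s_profile(sp, 0, 5000), 1e-12)        # pure decay limit
  expect_error(s_profile(sp, 0.2, -1), "non-negative")
  ts <- seq(0, 50, by = 0.01)
  s <- s_profile(sp, 0, ts)
  expect_true(all(s >= 0 & s <= 1))
})

test_that("closed-form profile matches the brute-force ODE oracle", {
  specs <- list(
    synapse_spec("AMPA", 0.3, alpha = 0.05, beta = 0.15),
    synapse_spec("GABAA", 0.75, alpha = 0.1, beta = 0.01),
    synapse_spec("GABAA", 0.02, alpha = 20, beta = 0.162))
  for (sp in specs) {
    dt <- if (s_inf(sp) > 0.9) 1e-4 else 5e-4  # fast synapse needs finer oracle
    orc <- synapse_oracle(sp, spike_times = 0, horizon = 20, dt = dt)
    closed <- s_profile(sp, 0, orc$time)
    expect_lt(max(abs(orc$s - closed)), 1e-6)
  }
})

test_that("synaptic_current applies weight normalization and mutation scale", {
  sp <- synapse_spec("GABAA", 0.2, alpha = 20, beta = 0.162, E_syn = -80)
  expect_equal(synaptic_current(sp, s = 0.5, V = -60, n_in = 11),
               (0.2 / 11) * 0.5 * 20, tolerance = 1e-12)
  expect_equal(synaptic_current(sp, 0, -60, 11), 0)
  expect_equal(synaptic_current(sp, 0.5, -80, 11), 0)
  sp10 <- apply_mutation(sp, 0.1)
  expect_equal(synaptic_current(sp10, 0.5, -60, 11),
               0.1 * synaptic_current(sp, 0.5, -60, 11))
})

test_that("the ALLO transform applies the fixed relative changes exactly", {
  sp <- synapse_spec("GABAA", 0.09, alpha = 0.1, beta = 0.2)
  post <- apply_allo(sp)
  expect_equal(post$alpha, 0.158)
  expect_equal(post$beta, 0.148)
  expect_equal(post$g_syn, 0.0999)
  expect_equal(post$C_dur, 0.342)
  expect_equal(post$variant, "post-ALLO")
  # decay time constant 1/beta lengthens by 1/0.74
  expect_equal((1 / post$beta) / (1 / sp$beta), 1 / 0.74)
  expect_error(apply_allo(post), "already")
  expect_error(apply_allo(synapse_spec("AMPA", 0.3, 0.05, 0.15)), "GABAA")
})

test_that("mutation scaling validates its domain", {
  sp <- synapse_spec("GABAA", 0.75, alpha = 0.1, beta = 0.01)
  expect_equal(apply_mutation(sp, 0.1)$gaba_scale, 0.1)
  expect_equal(apply_mutation(sp, 1)$gaba_scale, 1)
  expect_error(apply_mutation(sp, 0), "fraction")
  expect_error(apply_mutation(synapse_spec("AMPA", 1, 0.1, 0.1), 0.5), "GABAA")
})

test_that("mutation and ALLO commute", {
  sp <- synapse_spec("GABAA", 0.75, alpha = 0.1, beta = 0.01)
  a <- apply_allo(apply_mutation(sp, 0.1))
  b <- apply_mutation(apply_allo(sp), 0.1)
  expect_equal(a, b)
})

test_that("post-ALLO synapses deliver more charge for every GABAA table row", {
  tabs <- read_synapse_tables()
  gmax <- tabs$gmax
  rows <- gmax[gmax$receptor == "GABAA", ]
  posts <- setdiff(names(gmax), c("pre", "receptor"))
  horizon <- seq(0, 500, by = 0.05)
  for (i in seq_len(nrow(rows))) {
    for (post in posts) {
      g <- rows[[post]][i]
      if (is.na(g)) next
      pre <- rows$pre[i]
      a <- tabs$alpha[tabs$alpha$pre == pre, post]
      b <- tabs$beta[tabs$beta$pre == pre, post]
      ctrl <- synapse_spec("GABAA", g, a, b)
      allo <- apply_allo(ctrl)
      q_ctrl <- sum(ctrl$g_syn * s_profile(ctrl, 0, horizon)) * 0.05
      q_allo <- sum(allo$g_syn * s_profile(allo, 0, horizon)) * 0.05
      expect_gt(q_allo, q_ctrl)
      # peak open fraction is non-decreasing under the transform
      expect_gte(max(s_profile(allo, 0, horizon)),
                 max(s_profile(ctrl, 0, horizon)))
    }
  }
})
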