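# Ionic-current formalism, gating kinetics and firing-pattern classification.

test_that("every registered gate keeps steady state in [0,1] and tau positive", {
  V <- seq(-120, 60, by = 0.5)
  for (nm in list_kinetics()) {
    kin <- gating_kinetics(nm)
    xi <- kin$steady_state(V)
    expect_true(all(xi >= 0 & xi <= 1), info = nm)
    expect_true(all(kin$time_constant(V) > 0), info = nm)
  }
})

test_that("ionic_current evaluates g m^N h^M (V - E) with the stated sign", {
  ch <- list(g_max = 0.01, E_rev = -90, N = 3, M = 1)
  expect_equal(ionic_current(ch, V = -60, m = 0.5, h = 1), 0.0375)
  # zero driving force and zero conductance
  expect_equal(ionic_current(ch, V = -90, m = 0.7, h = 0.3), 0)
  ch0 <- list(g_max = 0, E_rev = -90, N = 3, M = 1)
  expect_equal(ionic_current(ch0, V = 10, m = 1, h = 1), 0)
  # linear in g_max and in driving force at fixed gates
  ch2 <- modifyList(ch, list(g_max = 0.02))
  expect_equal(ionic_current(ch2, -60, 0.5, 1), 2 * ionic_current(ch, -60, 0.5, 1))
  expect_equal(ionic_current(ch, -30, 0.5, 1) / ionic_current(ch, -60, 0.5, 1),
               (-30 + 90) / (-60 + 90))
  expect_error(ionic_current(list(g_max = -1, E_rev = 0, N = 1, M = 0), -60),
               "negative")
})

test_that("gate_step relaxes exponentially toward the steady state", {
  kin <- gating_kinetics("km_m")
  V <- -40
  xinf <- kin$steady_state(V)
  tau <- kin$time_constant(V)
  # closed-form check: x0 = 0, dt = tau gives 1 - exp(-1) of the distance
  expect_equal(gate_step(kin, 0, V, dt = tau), xinf * (1 - exp(-1)),
               tolerance = 1e-12)
  # fixed point
  expect_equal(gate_step(kin, xinf, V, dt = 5), xinf, tolerance = 1e-12)
  # dt -> 0 limit
  expect_lt(abs(gate_step(kin, 0.2, V, dt = 1e-8) - 0.2), 1e-8)
  expect_error(gate_step(kin, 0.5, V, dt = 0), "dt")
})

test_that("exact-exponential update matches a fine-step explicit oracle", {
  # oracle: explicit midpoint integration at dt = 1e-4 ms over one 0.025 ms
  # step (Euler's O(dt) bias exceeds the tolerance for sub-ms time constants)
  for (nm in c("naf_m", "it_h", "kdr_m", "htc_m")) {
    kin <- gating_kinetics(nm)
    for (V in c(-90, -60, -30)) {
      xinf <- kin$steady_state(V)
      tau <- kin$time_constant(V)
      oracle <- 0.3
      h <- 1e-4
      for (i in 1:250) {
        k1 <- (xinf - oracle) / tau
        k2 <- (xinf - (oracle + h / 2 * k1)) / tau
        oracle <- oracle + h * k2
      }
      expect_lt(abs(gate_step(kin, 0.3, V, 0.025) - oracle), 1e-6)
    }
  }
})

test_that("gates remain in [0,1] under repeated stepping across the voltage range", {
  kin <- gating_kinetics("cat_h")
  for (V in c(-120, -70, 0, 60)) {
    x <- 0.5
    for (i in 1:200) x <- gate_step(kin, x, V, 0.5)
    expect_true(x >= 0 && x <= 1)
  }
})

test_that("cell templates carry the class-specific channel inventories", {
  expect_setequal(cell_template("TC")$channels$name,
                  c("Leak", "KLeak", "Naf", "K", "CaT", "h"))
  expect_setequal(cell_template("RE")$channels$name,
                  c("Leak", "Naf", "K", "CaT"))
  rs <- cell_template("RS")
  expect_setequal(rs$channels$name,
                  c("Leak", "Naf", "Nap", "Ka", "K2", "Kdr", "Km", "Kc",
                    "Kahp", "CaT", "CaL", "h"))
  expect_equal(rs$Cm, 0.9)
  expect_equal(cell_template("LTS")$Cm, 1.0)
  expect_error(cell_template("RS", area = 0), "area")
})

test_that("classify_firing distinguishes silence, tonic and burst patterns", {
  expect_error(classify_firing(numeric(0)), "empty")
  expect_equal(classify_firing(rep(-65, 1000)), "silent")
  expect_equal(
    classify_firing(spike_times = make_spike_train(list(type = "regular", interval = 100), 1000)),
    "regular_spiking")
  expect_equal(
    classify_firing(spike_times = make_spike_train(
      list(type = "burst", n = 3, intra = 5, inter = 300), 1500)),
    "bursting")
})

test_that("TC rebound burst requires the low-threshold calcium current", {
  hyper <- data.frame(on = 500, off = 1000, amp = -0.1)
  with_cat <- run_cell("TC", 1400, hyper)
  expect_gt(sum(with_cat$spikes > 1000 & with_cat$spikes <= 1200), 0)
  no_cat <- run_cell(cell_template("TC", c(CaT = 0)), 1400, hyper)
  expect_equal(sum(no_cat$spikes > 1000 & no_cat$spikes <= 1200), 0)
})

test_that("isolated cells settle to a fixed point or stable oscillation", {
  # no stimulus, no synapses: voltages stay bounded over a long horizon
  for (cl in cell_classes()) {
    out <- run_cell(cl, 10000)
    expect_true(all(is.finite(out$V)))
    expect_true(all(abs(out$V) < 150), info = cl)
  }
})
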