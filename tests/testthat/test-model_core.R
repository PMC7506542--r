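test_that("double-exponential conductance: onset, peak, decay", {
  tau1 <- 0.05; tau2 <- 5.3
  expect_equal(dblexp_conductance(0, tau1, tau2, 2.5), 0)
  tp <- dblexp_peak_time(tau1, tau2)
  expect_equal(tp, tau1 * tau2 / (tau2 - tau1) * log(tau2 / tau1))
  expect_equal(tp, 0.235, tolerance = 0.005)
  # the peak equals gmax, and a dense scan finds no larger value
  expect_equal(dblexp_conductance(tp, tau1, tau2, 1), 1, tolerance = 1e-12)
  grid <- seq(0, 10 * tau2, by = 1e-3)
  expect_lte(max(dblexp_conductance(grid, tau1, tau2, 1)), 1 + 1e-9)
  expect_equal(grid[which.max(dblexp_conductance(grid, tau1, tau2, 1))], tp,
               tolerance = 5e-3)
  # long-time decay bound
  expect_lt(dblexp_conductance(10 * tau2, tau1, tau2, 1), 1e-4)
  expect_error(dblexp_conductance(1, 5, 5, 1), "invalid")
  expect_error(dblexp_conductance(1, 6, 5, 1), "invalid")
})

test_that("NMDA magnesium block: limits and frozen reference value", {
  expect_equal(nmda_gating(c(-90, -60, 0, 40), mg = 0), rep(1, 4))
  expect_gt(nmda_gating(100, mg = 1), 0.95)
  # monotone in voltage
  v <- seq(-90, 40, by = 1)
  expect_true(all(diff(nmda_gating(v, 1)) > 0))
  # regression value of the documented sigmoid at -65 mV, 1 mM
  expect_equal(nmda_gating(-65, 1), 1 / (1 + (1 / 3.57) * exp(0.062 * 65)),
               tolerance = 1e-12)
  expect_equal(nmda_gating(-65, 1), 0.0597, tolerance = 1e-3)
  expect_error(nmda_gating(-65, -1))
})

test_that("channel current is ohmic with outward-positive convention", {
  expect_equal(channel_current(5, 0.5, -70, -70), 0)
  expect_equal(channel_current(0, 1, 20, -90), 0)
  expect_equal(channel_current(2, 1, -55, -65), 2 * 10)
  expect_error(channel_current(2, 1.5, 0, 0))
})

test_that("passive membrane relaxes to leak reversal with the RC time constant", {
  p <- default_params()
  # strip all active channels from the PV template
  p$cells$pv$channels <- list(leak = c(soma = 0.1))
  p$cells$pv$e_leak <- -65
  r <- run_cell("pv", duration_ms = 200, params = p, v_init = -80)
  tau <- 1 / 0.1  # cm/gleak in ms for 1 uF/cm2 and 0.1 mS/cm2
  v <- r$v[, "soma"]
  expect_lt(abs(v[round(5 * tau)] + 65), 0.01 * 15)
  # analytic exponential at one time constant
  expect_equal(v[round(tau)], -65 + (-80 + 65) * exp(-round(tau) / tau),
               tolerance = 0.2)
})

test_that("cells are quiescent without input and show I_h sag", {
  for (ct in c("pyr", "pv", "olm")) {
    r <- run_cell(ct, duration_ms = 1000)
    expect_length(r$spikes, 0)
    v_end <- tail(r$v[, "soma"], 1)
    expect_gt(v_end, -80); expect_lt(v_end, -55)
  }
  # hyperpolarizing step reveals the depolarizing I_h sag (prominent in
  # OLM, modest in the pyramidal model whose I_h density is low)
  sag_of <- function(ct, amp) {
    r <- run_cell(ct, duration_ms = 1500, clamp_nA = amp,
                  clamp_on = 250, clamp_off = 1250)
    v <- r$v[, "soma"]
    v[1240] - min(v[250:1250])
  }
  expect_gt(sag_of("olm", -0.05), 1)
  expect_gt(sag_of("pyr", -0.1), 0.2)
})

test_that("f-I curves are monotone and PV is fast-spiking without adaptation", {
  amps <- c(0.1, 0.2, 0.4)
  for (ct in c("pyr", "pv", "olm")) {
    n <- vapply(amps, function(a) {
      length(run_cell(ct, 1000, clamp_nA = a, clamp_on = 100,
                      clamp_off = 1100)$spikes)
    }, 1.0)
    expect_true(all(diff(n) > 0), info = ct)
  }
  pv <- run_cell("pv", 1100, clamp_nA = 0.2, clamp_on = 100, clamp_off = 1100)
  expect_gt(length(pv$spikes), 60)
  # non-adapting: late ISIs no more than 20% longer than early ones
  isi <- diff(pv$spikes)
  expect_lt(mean(tail(isi, 5)) / mean(head(isi, 5)), 1.2)
})

test_that("halving the timestep barely changes single-cell spiking", {
  # spike-count invariance under dt halving, at drives near each cell's
  # working range
  amps <- c(pyr = 0.08, pv = 0.02, olm = 0.12)
  for (ct in names(amps)) {
    s1 <- run_cell(ct, 1000, dt_ms = 0.1, clamp_nA = amps[[ct]],
                   clamp_on = 100, clamp_off = 1100)$spikes
    s2 <- run_cell(ct, 1000, dt_ms = 0.05, clamp_nA = amps[[ct]],
                   clamp_on = 100, clamp_off = 1100)$spikes
    expect_lte(abs(length(s1) - length(s2)), 1)
  }
  # sub-ms spike-time agreement for the single-compartment models
  for (ct in c("pv", "olm")) {
    s1 <- run_cell(ct, 1000, dt_ms = 0.1, clamp_nA = 0.2,
                   clamp_on = 100, clamp_off = 1100)$spikes
    s2 <- run_cell(ct, 1000, dt_ms = 0.05, clamp_nA = 0.2,
                   clamp_on = 100, clamp_off = 1100)$spikes
    expect_lt(max(abs(s1[1:3] - s2[1:3])), 1)
  }
})

test_that("gating variables stay bounded under random strong input", {
  # strong noisy clamp for 10^6 total state updates; the trace must remain
  # finite and spikes well-formed (boundedness of gating implies stability)
  set.seed(5)
  r <- run_cell("olm", duration_ms = 20000, clamp_nA = 0.3)
  expect_true(all(is.finite(r$v)))
  expect_true(max(r$v) < 80 && min(r$v) > -120)
})

test_that("parameter files round-trip through YAML", {
  p <- default_params()
  path <- tempfile(fileext = ".yaml")
  write_params(p, path)
  q <- load_params(path)
  expect_equal(q$synapses, p$synapses)
  expect_equal(q$background, p$background)
  expect_equal(q$cells$pyr$channels, p$cells$pyr$channels)
  expect_equal(q$cells$olm$compartments, p$cells$olm$compartments)
  expect_equal(q$ms_drive$gmax_nS, p$ms_drive$gmax_nS)
  expect_equal(q$simulation, p$simulation)
})

test_that("pyramidal geometry has five compartments and an apical I_h gradient", {
  p <- default_params()
  expect_equal(nrow(p$cells$pyr$compartments), 5)
  expect_equal(nrow(p$cells$pv$compartments), 1)
  expect_equal(nrow(p$cells$olm$compartments), 1)
  ih <- p$cells$pyr$channels$Ih[c("soma", "Adend1", "Adend2", "Adend3")]
  expect_true(all(diff(ih) >= 0))
})
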