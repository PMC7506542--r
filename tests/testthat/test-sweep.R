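test_that("sweep designs have the documented factorial sizes", {
  expect_equal(nrow(build_design("nmdar")), 175)
  expect_equal(nrow(build_design("triscaling")), 1575)
  one <- build_design("nmdar", levels = list(nmdar_olm = 1),
                      input_seeds = 1, wiring_seeds = 1)
  expect_equal(nrow(one), 1)
  expect_error(build_design("frobnicate"), "unknown design")
  # stable ordering: rerunning gives the identical frame
  expect_identical(build_design("triscaling"), build_design("triscaling"))
})

test_that("apply_scaling multiplies exactly the targeted conductances", {
  net <- build_network(scale = 0.25, wiring_seed = 1, compensate = FALSE)
  id <- apply_scaling(net, scaling_set(1, 1, 1))
  expect_identical(id$edges, net$edges)
  expect_identical(id$params$cells$pyr$channels$Ih,
                   net$params$cells$pyr$channels$Ih)

  s <- apply_scaling(net, scaling_set(nmdar_olm = 30))
  pop_of <- net$cells$pop
  sel <- net$edges$receptor == "NMDA" & pop_of[net$edges$post] == "olm"
  # PYR->OLM NMDA conductance 0.7 nS scaled to 21 nS
  expect_equal(unique(s$edges$gmax_nS[sel]), 0.7 * 30)
  expect_identical(s$edges$gmax_nS[!sel], net$edges$gmax_nS[!sel])
  # original untouched
  expect_equal(unique(net$edges$gmax_nS[sel]), 0.7)

  g <- apply_scaling(net, scaling_set(gaba_pyr = 10))
  selg <- net$edges$receptor == "GABA_A" & pop_of[net$edges$post] == "pyr"
  expect_equal(g$edges$gmax_nS[selg], net$edges$gmax_nS[selg] * 10)
  expect_identical(g$edges$gmax_nS[!selg], net$edges$gmax_nS[!selg])

  h <- apply_scaling(net, scaling_set(ih = 10))
  expect_equal(h$params$cells$pyr$channels$Ih,
               net$params$cells$pyr$channels$Ih * 10)
  expect_equal(h$params$cells$pv$channels$Ih,
               net$params$cells$pv$channels$Ih * 10)
  # I_h manipulation never touches OLM cells
  expect_identical(h$params$cells$olm$channels$Ih,
                   net$params$cells$olm$channels$Ih)

  expect_error(scaling_set(nmdar_olm = 0), "config error")
  expect_error(scaling_set(ih = -2), "config error")
})

test_that("aggregation pools over seed replicates with the direct formula", {
  toy <- data.frame(
    nmdar_olm = rep(c(1, 10), each = 3), gaba_pyr = 1, ih = 1,
    input_seed = rep(1:3, 2), wiring_seed = 1,
    nte = c(0.1, 0.2, 0.3, 0.4, 0.4, 0.4),
    gamma_power = c(1, 2, 3, 4, 5, 6)
  )
  agg <- aggregate_sweep(toy, metrics = c("nte", "gamma_power"))
  expect_equal(agg$nte_mean, c(0.2, 0.4))
  expect_equal(agg$nte_sem[1], sd(c(0.1, 0.2, 0.3)) / sqrt(3))
  expect_equal(agg$nte_sem[2], 0)
  expect_equal(agg$nte_n, c(3L, 3L))
  # single replicate: SEM undefined
  single <- aggregate_sweep(toy[c(1, 4), ], metrics = "nte")
  expect_true(all(is.na(single$nte_sem)))
  # NA metric rows are excluded with count reported
  toy$nte[2] <- NA
  agg2 <- aggregate_sweep(toy, metrics = "nte")
  expect_equal(agg2$nte_n[1], 2L)
  expect_equal(agg2$nte_mean[1], 0.2)
})

test_that("inverted-U detection requires an interior peak above both ends", {
  expect_false(detect_inverted_u(1:5, 1:5)$is_inverted_u)
  r <- detect_inverted_u(c(1, 10, 30), c(1, 3, 1))
  expect_true(r$is_inverted_u)
  expect_equal(r$peak_level, 10)
  expect_equal(r$peak_value, 3)
  # endpoints within one pooled SEM of the peak do not count
  r2 <- detect_inverted_u(c(1, 10, 30), c(2.9, 3, 2.8), sem = rep(0.5, 3))
  expect_false(r2$is_inverted_u)
  expect_error(detect_inverted_u(1:2, 1:2))
})

test_that("inverted-U detection recovers a known noisy peak", {
  set.seed(21)
  x <- c(1, 1.5, 2.5, 5, 10, 20, 30)
  truth <- -(log(x) - log(5))^2  # concave with peak at 5
  reps <- replicate(20, truth + rnorm(7, 0, 0.1))
  m <- rowMeans(reps)
  sem <- apply(reps, 1, sd) / sqrt(20)
  r <- detect_inverted_u(x, m, sem)
  expect_true(r$is_inverted_u)
  # within one grid step of the true peak
  expect_true(r$peak_level %in% c(2.5, 5, 10))
})

test_that("top-percentile band selects the secondary-metric range", {
  tab <- data.frame(nte = 1:100, gamma_power = c(1:45, 56:100, 46:55))
  r <- top_percentile_band(tab)
  expect_equal(r$n_subset, 10)
  expect_equal(r$subset_range, c(46, 55))
  expect_equal(r$full_range, c(1, 100))
  # identical rows: subset range equals full range
  same <- data.frame(nte = rep(1, 12), gamma_power = rep(2, 12))
  rs <- top_percentile_band(same)
  expect_equal(rs$subset_range, rs$full_range)
  expect_error(top_percentile_band(tab[1:5, ]), "10 rows")
})

test_that("surface interpolation is exact at nodes and bilinear between", {
  x <- c(0.1, 1, 10); y <- c(0.1, 1, 10)
  z <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 3, 3)
  s <- surface_interpolate(x, y, z, n = 5)
  # constant surface stays constant
  sc <- surface_interpolate(x, y, matrix(7, 3, 3), n = 7)
  expect_true(all(abs(sc$z - 7) < 1e-12))
  # nodes reproduced exactly (n = 5 grid hits the log-midpoints and ends)
  expect_equal(s$z[1, 1], z[1, 1])
  expect_equal(s$z[5, 5], z[3, 3])
  expect_equal(s$z[3, 1], z[2, 1])  # log-scale midpoint = middle node
  # midway between two nodes on one axis: arithmetic mean
  expect_equal(s$z[2, 1], (z[1, 1] + z[2, 1]) / 2)
  expect_error(surface_interpolate(c(1, 2), y, z), "rectangular")
  expect_error(surface_interpolate(c(-1, 1, 10), y, z), "positive")
})

test_that("run_sweep produces metric rows and resumes idempotently", {
  design <- data.frame(nmdar_olm = c(1, 5), gaba_pyr = 1, ih = 1,
                       input_seed = 1, wiring_seed = 1)
  cfg <- sim_config(duration_ms = 2500, analysis_start_ms = 500)
  dir <- tempfile()
  tab <- run_sweep(design, scale = 0.1, cfg = cfg, out_dir = dir,
                   n_nte_cells = 5, shuffles = 5)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$ok))
  expect_true(all(is.finite(tab$gamma_power)))
  expect_true(all(is.finite(tab$rate_pyr)))
  expect_length(list.files(dir, pattern = "^run_.*tsv$"), 2)
  # rerun: identical table, nothing recomputed (files untouched)
  stamps <- file.mtime(list.files(dir, full.names = TRUE))
  tab2 <- run_sweep(design, scale = 0.1, cfg = cfg, out_dir = dir)
  expect_equal(tab2$gamma_power, tab$gamma_power, tolerance = 1e-12)
  expect_identical(stamps, file.mtime(list.files(dir, full.names = TRUE)))
})
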