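#!/usr/bin/env Rscript
# Calibration of the background Poisson event rates.
#
# The connectivity and synaptic conductances of the network are fixed by the
# model's parameter tables; the background drive rates are free calibration
# constants. This script scans candidate rates around the shipped defaults,
# runs a short baseline simulation for each candidate, and prints the regime
# diagnostics used to pick the defaults frozen in default_params():
# theta peak ~7 Hz, gamma-band (25-50 Hz) peak in the 30-40 Hz range,
# pyramidal rate of a few Hz, PV in the tens of Hz.
#
# Usage: Rscript scripts/tune_background.R [--scale S] [--duration MS]

suppressMessages(library(ca3net))
args <- commandArgs(trailingOnly = TRUE)
getopt <- function(flag, default) {
  i <- match(flag, args)
  if (is.na(i)) default else as.numeric(args[i + 1])
}
scale <- getopt("--scale", 0.25)
duration <- getopt("--duration", 7000)

diagnose <- function(p, seed = 1) {
  net <- build_network(p, scale = scale, wiring_seed = seed)
  sim <- run_simulation(net, sim_config(duration_ms = duration),
                        input_seed = seed)
  w <- c(sim$config$analysis_start_ms, duration)
  lfp <- sim$lfp[(w[1] + 1):duration]
  psd <- welch_psd(lfp, sim$fs_hz)
  sp <- sim$spikes[sim$spikes$time >= w[1], ]
  c(theta_hz = band_peak(psd, 4, 12), theta_pow = band_power(psd, 4, 12),
    gamma_hz = band_peak(psd, 25, 50), gamma_pow = band_power(psd, 25, 50),
    pyr = pop_rate(sp$time[sp$pop == "pyr"], net$sizes[["pyr"]], w),
    pv = pop_rate(sp$time[sp$pop == "pv"], net$sizes[["pv"]], w),
    olm = pop_rate(sp$time[sp$pop == "olm"], net$sizes[["olm"]], w))
}

base <- default_params()
cat("default rates:\n")
print(base$background[, c("pop", "target", "receptor", "rate_hz")])
cat("\nbaseline diagnostics (seed 1):\n")
print(round(diagnose(base), 3))

# one-at-a-time scan around the defaults
cat("\nrate scan (multiplier applied to one stream at a time):\n")
for (k in seq_len(nrow(base$background))) {
  for (mult in c(0.5, 2)) {
    p <- base
    p$background$rate_hz[k] <- p$background$rate_hz[k] * mult
    d <- diagnose(p)
    cat(sprintf("%-4s %-7s %-6s x%.1f | theta %.0f Hz (%.2f) gamma %.0f Hz (%.3f) rates %.1f/%.1f/%.1f\n",
                base$background$pop[k], base$background$target[k],
                base$background$receptor[k], mult,
                d["theta_hz"], d["theta_pow"], d["gamma_hz"], d["gamma_pow"],
                d["pyr"], d["pv"], d["olm"]))
  }
}
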