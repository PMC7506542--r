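#' Welch power spectral density
#'
#' Mean of Hann-tapered periodograms over 50%-overlapping segments, after
#' removing the DC component (signal mean). One-sided density normalization:
#' the integral of the PSD over frequency approximates the signal variance.
#'
#' @param x signal trace.
#' @param fs_hz sampling rate (Hz).
#' @param segment_s segment length (s), default 1 (1 Hz resolution).
#' @param overlap overlap fraction between segments, default 0.5.
#' @return An object of class `psd`: list with `freq_hz`, `power`
#'   ((signal units)^2/Hz), and the Welch parameter echo.
#' @export
welch_psd <- function(x, fs_hz, segment_s = 1, overlap = 0.5) {
  nper <- as.integer(round(segment_s * fs_hz))
  if (length(x) < nper)
    stop(sprintf("trace too short: %d samples < one %d-sample segment",
                 length(x), nper))
  x <- x - mean(x)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, nper - 1) / nper))  # periodic Hann
  u <- sum(w^2)
  step <- max(1L, as.integer(round(nper * (1 - overlap))))
  starts <- seq(1L, length(x) - nper + 1L, by = step)
  nfreq <- nper %/% 2 + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- Mod(stats::fft(seg)[seq_len(nfreq)])^2 / (fs_hz * u)
    sp[2:(nfreq - if (nper %% 2 == 0) 1L else 0L)] <-
      2 * sp[2:(nfreq - if (nper %% 2 == 0) 1L else 0L)]
    acc <- acc + sp
  }
  structure(list(
    freq_hz = seq(0, nfreq - 1) * fs_hz / nper, power = acc / length(starts),
    fs_hz = fs_hz, segment_s = segment_s, overlap = overlap,
    n_segments = length(starts)
  ), class = "psd")
}

#' Integrated band power
#'
#' Integral of the power spectral density over the half-open band
#' `[lo_hz, hi_hz)`, so that adjacent bands add exactly.
#'
#' @param psd a `psd` object from [welch_psd()].
#' @param lo_hz,hi_hz band edges (Hz).
#' @return Band power ((signal units)^2).
#' @export
band_power <- function(psd, lo_hz, hi_hz) {
  sel <- psd$freq_hz >= lo_hz & psd$freq_hz < hi_hz
  if (!any(sel)) stop("empty frequency band")
  df <- psd$freq_hz[2] - psd$freq_hz[1]
  sum(psd$power[sel]) * df
}

#' Frequency of the band maximum
#'
#' @inheritParams band_power
#' @return Frequency (Hz) of the maximum PSD value within `[lo_hz, hi_hz)`.
#' @export
band_peak <- function(psd, lo_hz, hi_hz) {
  sel <- which(psd$freq_hz >= lo_hz & psd$freq_hz < hi_hz)
  if (length(sel) == 0) stop("empty frequency band")
  psd$freq_hz[sel[which.max(psd$power[sel])]]
}

entropy_bits <- function(counts) {
  p <- counts[counts > 0]
  p <- p / sum(p)
  -sum(p * log2(p))
}

# transfer entropy (bits) from aligned count sequences, one-bin embeddings:
# TE = I(input_past ; output_future | output_past), plug-in estimate via the
# direct conditional-probability sum over the joint contingency array
te_binned <- function(x, y) {
  n <- length(x)
  xp <- x[-n]; yp <- y[-n]; yf <- y[-1]
  p3 <- unclass(table(xp, yp, yf)) / (n - 1)
  pxy <- apply(p3, c(1, 2), sum)
  pyy <- apply(p3, c(2, 3), sum)
  py <- apply(p3, 2, sum)
  nx <- dim(p3)[1]; nz <- dim(p3)[3]
  denom <- array(0, dim(p3))
  for (k in seq_len(nz))
    denom[, , k] <- pxy * rep(ifelse(py > 0, pyy[, k] / py, 0), each = nx)
  sel <- p3 > 0
  te <- sum(p3[sel] * log2(p3[sel] / denom[sel]))
  hcond <- entropy_bits(as.numeric(pyy)) - entropy_bits(as.numeric(py))
  list(te_raw = te, hcond = hcond)
}

#' Normalized transfer entropy between binned sequences
#'
#' Directed information flow from an input count sequence to an output count
#' sequence: `TE = I(input_past ; output_future | output_past)` with one-bin
#' past/future embeddings (plug-in estimate, bits), shuffle-corrected and
#' normalized:
#' `nTE = (TE - mean(TE over input-shuffled surrogates)) /
#'  H(output_future | output_past)`.
#'
#' @param x,y integer count sequences on a common bin grid.
#' @param shuffles number of input-permutation surrogates (default 30).
#' @param seed optional seed for the shuffles; `NULL` uses the RNG state.
#' @return List of class `nte`: `nte`, `te_bits`, `shuffle_mean_bits`,
#'   `shuffle_sd_bits`, `h_cond_bits`, `defined` (FALSE when the conditional
#'   entropy of the output future is zero), `n_bins`, `shuffles`.
#' @export
nte_binned <- function(x, y, shuffles = 30, seed = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (!is.null(seed)) set.seed(seed)
  x <- as.integer(x); y <- as.integer(y)
  base <- te_binned(x, y)
  if (base$hcond <= 0) {
    return(structure(list(nte = NA_real_, te_bits = base$te_raw,
                          shuffle_mean_bits = NA_real_,
                          shuffle_sd_bits = NA_real_,
                          h_cond_bits = base$hcond, defined = FALSE,
                          n_bins = length(x), shuffles = shuffles),
                     class = "nte"))
  }
  te_sh <- vapply(seq_len(shuffles), function(i) {
    te_binned(sample(x), y)$te_raw
  }, 1.0)
  structure(list(
    nte = (base$te_raw - mean(te_sh)) / base$hcond, te_bits = base$te_raw,
    shuffle_mean_bits = mean(te_sh), shuffle_sd_bits = stats::sd(te_sh),
    h_cond_bits = base$hcond, defined = TRUE, n_bins = length(x),
    shuffles = shuffles
  ), class = "nte")
}

#' Normalized transfer entropy between spike trains
#'
#' Bins the two trains into counts on a common grid (default 15 ms) over the
#' analysis window, then computes the shuffle-corrected normalized transfer
#' entropy (see [nte_binned()]).
#'
#' @param input_times,output_times spike-time vectors (ms).
#' @param bin_ms bin width (ms), default 15.
#' @param window `c(start, end)` analysis window (ms).
#' @param shuffles,seed see [nte_binned()].
#' @return An `nte` object (see [nte_binned()]), with `bin_ms` added.
#' @export
nte <- function(input_times, output_times, bin_ms = 15, window,
                shuffles = 30, seed = NULL) {
  breaks <- seq(window[1], window[2], by = bin_ms)
  if (length(breaks) < 101)
    stop("analysis window must cover at least 100 bins")
  binned <- function(tt) {
    tt <- tt[tt >= window[1] & tt < breaks[length(breaks)]]
    tabulate(findInterval(tt, breaks), nbins = length(breaks) - 1L)
  }
  out <- nte_binned(binned(input_times), binned(output_times),
                    shuffles = shuffles, seed = seed)
  out$bin_ms <- bin_ms
  out
}

#' Modulation index from a phase-binned amplitude profile
#'
#' Kullback-Leibler-based modulation index of a mean-amplitude-per-phase-bin
#' vector: the profile is normalized to a distribution `P` and
#' `MI = (log N - H(P)) / log N`. 0 for a uniform profile, 1 when all mass is
#' in one bin.
#'
#' @param bin_means non-negative mean gamma amplitude per theta-phase bin.
#' @return MI in \[0, 1\], or `NA` (flagged undefined) for an all-zero profile.
#' @export
mi_from_profile <- function(bin_means) {
  if (any(bin_means < 0)) stop("amplitude profile must be non-negative")
  tot <- sum(bin_means)
  if (tot == 0) return(NA_real_)
  p <- bin_means / tot
  n <- length(bin_means)
  h <- -sum(ifelse(p > 0, p * log(p), 0))
  (log(n) - h) / log(n)
}

# zero-phase band-pass (2nd order Butterworth, forward-backward)
bandpass <- function(x, fs_hz, band) {
  bf <- signal::butter(2, band / (fs_hz / 2), type = "pass")
  signal::filtfilt(bf, x)
}

# analytic signal via FFT (Hilbert transform)
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Theta-gamma phase-amplitude modulation index
#'
#' Band-passes the trace to the theta band for instantaneous phase and to the
#' gamma band for the instantaneous amplitude envelope (zero-phase Butterworth
#' filtering, Hilbert transform), forms the mean amplitude per theta-phase
#' bin, and returns the entropy-based modulation index of that profile
#' (see [mi_from_profile()]).
#'
#' @param x LFP trace.
#' @param fs_hz sampling rate (Hz).
#' @param theta_band,gamma_band filter bands (Hz).
#' @param n_bins number of phase bins (default 18).
#' @return List of class `mi`: `mi`, `profile` (normalized per-bin amplitude
#'   distribution), `phase_bins`, `theta_band`, `gamma_band`, `defined`.
#' @export
modulation_index <- function(x, fs_hz, theta_band = c(4, 10),
                             gamma_band = c(25, 50), n_bins = 18) {
  theta <- bandpass(x, fs_hz, theta_band)
  gamma <- bandpass(x, fs_hz, gamma_band)
  phase <- Arg(analytic_signal(theta))
  amp <- Mod(analytic_signal(gamma))
  bins <- cut(phase, breaks = seq(-pi, pi, length.out = n_bins + 1),
              include.lowest = TRUE)
  prof <- tapply(amp, bins, mean, default = 0)
  prof[is.na(prof)] <- 0
  mi <- mi_from_profile(as.numeric(prof))
  structure(list(
    mi = mi, profile = as.numeric(prof) / max(sum(prof), .Machine$double.xmin),
    phase_bins = n_bins, theta_band = theta_band, gamma_band = gamma_band,
    defined = !is.na(mi)
  ), class = "mi")
}

#' Population synchrony (popCV)
#'
#' Coefficient of variation of the pooled interspike intervals of one
#' population: all spikes are merged into a single sorted train and
#' `popCV = sd / mean` of its consecutive intervals. Approximately 1 for
#' asynchronous Poisson populations; approaches `sqrt(N)` for `N` cells firing
#' in synchronized volleys.
#'
#' @param times spike times of the whole population: numeric vector, list of
#'   per-neuron vectors, or a spikes data.frame with a `time` column.
#' @return List of class `popcv`: `popcv`, `n_isi`, `defined` (FALSE with
#'   fewer than 2 pooled intervals).
#' @export
pop_cv <- function(times) {
  if (is.data.frame(times)) times <- times$time
  if (is.list(times)) times <- unlist(times)
  isi <- diff(sort(times))
  if (length(isi) < 2 || mean(isi) == 0) {
    return(structure(list(popcv = NA_real_, n_isi = length(isi),
                          defined = FALSE), class = "popcv"))
  }
  structure(list(popcv = stats::sd(isi) / mean(isi), n_isi = length(isi),
                 defined = TRUE), class = "popcv")
}

#' Mean population firing rate
#'
#' Total spikes divided by (number of neurons x window length).
#'
#' @param times spike times (ms): vector, list, or spikes data.frame.
#' @param n_neurons population size.
#' @param window `c(start, end)` (ms).
#' @return Rate in Hz.
#' @export
pop_rate <- function(times, n_neurons, window) {
  if (is.data.frame(times)) times <- times$time
  if (is.list(times)) times <- unlist(times)
  if (diff(window) <= 0) stop("window length must be > 0")
  n <- sum(times >= window[1] & times < window[2])
  n / (n_neurons * diff(window) / 1000)
}

#' All output measures for one simulation
#'
#' Computes the full metrics row on the analysis window: theta/gamma band
#' power and peak frequencies of the Welch PSD of the LFP, the mean
#' normalized transfer entropy from per-cell driving inputs to pyramidal
#' spike output over `n_nte_cells` sampled pyramidal cells, the theta-gamma
#' modulation index of the LFP, and per-population firing rates and popCV.
#'
#' @param sim a `ca3_sim` from [run_simulation()].
#' @param theta_band,gamma_band analysis bands (Hz); the theta peak is
#'   searched in 4-12 Hz, gamma power/peak use `gamma_band`.
#' @param bin_ms nTE bin width (ms).
#' @param n_nte_cells number of pyramidal cells sampled for nTE (evenly
#'   spaced across the population).
#' @param shuffles nTE shuffle count.
#' @param seed seed for the nTE shuffles.
#' @return One-row data.frame (a "metrics row").
#' @export
sim_metrics <- function(sim, theta_band = c(4, 12), gamma_band = c(25, 50),
                        bin_ms = 15, n_nte_cells = 25, shuffles = 30,
                        seed = 1) {
  cfg <- sim$config
  window <- c(cfg$analysis_start_ms, cfg$duration_ms)
  i0 <- as.integer(round(cfg$analysis_start_ms / 1000 * sim$fs_hz)) + 1L
  lfp <- sim$lfp[i0:length(sim$lfp)]
  psd <- welch_psd(lfp, sim$fs_hz)
  sp <- sim$spikes[sim$spikes$time >= window[1] & sim$spikes$time < window[2], ]

  n_pyr <- sim$sizes[["pyr"]]
  pick <- unique(as.integer(round(seq(1, n_pyr,
                                      length.out = min(n_nte_cells, n_pyr)))))
  set.seed(seed)
  ntes <- vapply(pick, function(cid) {
    out_t <- sp$time[sp$cell == cid]
    r <- nte(sim$drive[[cid]], out_t, bin_ms = bin_ms, window = window,
             shuffles = shuffles)
    if (isTRUE(r$defined)) r$nte else NA_real_
  }, 1.0)
  mi <- modulation_index(lfp, sim$fs_hz, theta_band = c(4, 10),
                         gamma_band = gamma_band)
  one_pop <- function(p) sp$time[sp$pop == p]
  data.frame(
    theta_power = band_power(psd, theta_band[1], theta_band[2]),
    gamma_power = band_power(psd, gamma_band[1], gamma_band[2]),
    theta_peak_hz = band_peak(psd, theta_band[1], theta_band[2]),
    gamma_peak_hz = band_peak(psd, gamma_band[1], gamma_band[2]),
    nte = mean(ntes, na.rm = TRUE), n_nte_defined = sum(!is.na(ntes)),
    mi = mi$mi,
    rate_pyr = pop_rate(one_pop("pyr"), sim$sizes[["pyr"]], window),
    rate_pv = pop_rate(one_pop("pv"), sim$sizes[["pv"]], window),
    rate_olm = pop_rate(one_pop("olm"), sim$sizes[["olm"]], window),
    popcv_pyr = pop_cv(one_pop("pyr"))$popcv,
    popcv_pv = pop_cv(one_pop("pv"))$popcv,
    popcv_olm = pop_cv(one_pop("olm"))$popcv
  )
}
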