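#' Population of independent Poisson spike trains
#'
#' Ground-truth surrogate for the population-synchrony statistic: the merged
#' train of independent homogeneous Poisson processes is itself Poisson, so
#' popCV is ~1.
#'
#' @param rate_hz per-neuron firing rate (Hz), >= 0.
#' @param n number of neurons.
#' @param duration_ms duration (ms).
#' @param seed integer seed.
#' @return Spikes data.frame (`cell`, `pop = "surrogate"`, `time` ms), the
#'   simulator's columnar dialect.
#' @export
gen_poisson_population <- function(rate_hz, n, duration_ms, seed = 1) {
  if (rate_hz < 0) stop("rate must be >= 0")
  set.seed(seed)
  trains <- gen_background_events(rate_hz, n, duration_ms)
  cells <- rep(seq_len(n), lengths(trains))
  data.frame(
    cell = cells, pop = rep("surrogate", length(cells)),
    time = as.numeric(unlist(trains)), stringsAsFactors = FALSE
  )
}

#' Spike-train pair with tunable directed dependence
#'
#' Ground truth for the transfer-entropy estimator. The input is a binned
#' Poisson train; each output bin copies the input bin `lag_bins` earlier
#' with probability `copy_prob` and is an independent Poisson bin otherwise,
#' so the strength of the directed input->output dependence is exactly
#' tunable: 0 gives independence, 1 a deterministic delayed copy.
#'
#' @param rate_hz Poisson rate of both trains (Hz).
#' @param copy_prob copy probability in \[0, 1\].
#' @param lag_bins lag of the dependence, in bins (default 1).
#' @param bin_ms bin width (ms), default 15.
#' @param duration_ms duration (ms).
#' @param seed integer seed.
#' @return List with `input`, `output` (binned counts), `input_times`,
#'   `output_times` (event times at bin centers), `bin_ms`.
#' @export
gen_coupled_pair <- function(rate_hz, copy_prob, lag_bins = 1, bin_ms = 15,
                             duration_ms = 60000, seed = 1) {
  if (copy_prob < 0 || copy_prob > 1) stop("copy_prob must be in [0, 1]")
  set.seed(seed)
  n_bins <- as.integer(floor(duration_ms / bin_ms))
  lam <- rate_hz * bin_ms / 1000
  x <- stats::rpois(n_bins, lam)
  indep <- stats::rpois(n_bins, lam)
  copied <- c(rep(0L, lag_bins), x[seq_len(n_bins - lag_bins)])
  use_copy <- stats::runif(n_bins) < copy_prob
  y <- ifelse(use_copy, copied, indep)
  centers <- (seq_len(n_bins) - 0.5) * bin_ms
  list(input = x, output = as.integer(y),
       input_times = rep(centers, x), output_times = rep(centers, y),
       bin_ms = bin_ms)
}

#' Theta carrier with tunable gamma phase-amplitude coupling
#'
#' Ground truth for the modulation-index estimator:
#' `trace = sin(2 pi f_theta t) +
#'   (1 - c + c (1 + sin(2 pi f_theta t)) / 2) * sin(2 pi f_gamma t) + noise`,
#' so coupling `c = 0` gives a gamma amplitude independent of theta phase and
#' `c = 1` maximal phase-amplitude coupling.
#'
#' @param f_theta_hz,f_gamma_hz carrier frequencies (Hz); must satisfy
#'   `f_theta < f_gamma < fs/2`.
#' @param coupling coupling strength in \[0, 1\].
#' @param duration_s duration (s).
#' @param fs_hz sampling rate (Hz).
#' @param noise_sd additive Gaussian noise SD.
#' @param seed integer seed.
#' @return List with `trace` and `fs_hz`.
#' @export
gen_pac_signal <- function(f_theta_hz = 7, f_gamma_hz = 35, coupling = 1,
                           duration_s = 5, fs_hz = 1000, noise_sd = 0.1,
                           seed = 1) {
  if (!(f_theta_hz < f_gamma_hz && f_gamma_hz < fs_hz / 2))
    stop("need f_theta < f_gamma < fs/2 (aliasing)")
  if (coupling < 0 || coupling > 1) stop("coupling must be in [0, 1]")
  set.seed(seed)
  t <- seq(0, duration_s - 1 / fs_hz, by = 1 / fs_hz)
  th <- sin(2 * pi * f_theta_hz * t)
  env <- 1 - coupling + coupling * (1 + th) / 2
  trace <- th + env * sin(2 * pi * f_gamma_hz * t) +
    stats::rnorm(length(t), 0, noise_sd)
  list(trace = trace, fs_hz = fs_hz)
}

#' Population firing in periodic volleys
#'
#' Ground truth for the synchrony limit of popCV: all `n` neurons fire once
#' per period with Gaussian timing jitter. With zero jitter the pooled-ISI
#' coefficient of variation is exactly `sqrt(n - 1)`.
#'
#' @param n number of neurons.
#' @param period_ms volley period (ms).
#' @param jitter_ms Gaussian jitter SD (ms), >= 0.
#' @param duration_ms duration (ms).
#' @param seed integer seed.
#' @return Spikes data.frame (`cell`, `pop = "surrogate"`, `time` ms).
#' @export
gen_volley_population <- function(n, period_ms, jitter_ms = 0,
                                  duration_ms = 5000, seed = 1) {
  if (jitter_ms < 0) stop("jitter must be >= 0")
  set.seed(seed)
  volleys <- seq(period_ms, duration_ms, by = period_ms)
  times <- rep(volleys, each = n) +
    stats::rnorm(length(volleys) * n, 0, jitter_ms)
  cells <- rep(seq_len(n), times = length(volleys))
  keep <- times >= 0 & times < duration_ms
  data.frame(cell = cells[keep], pop = "surrogate", time = times[keep],
             stringsAsFactors = FALSE)
}
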