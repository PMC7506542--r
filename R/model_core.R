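#' Double-exponential synaptic conductance
#'
#' Conductance time course of a synaptic event,
#' `g(t) = gmax * A * (exp(-t/tau2) - exp(-t/tau1))`, with the normalization
#' `A` chosen so that the peak equals `gmax` exactly. Events superpose
#' linearly; negative `t` (before onset) gives 0.
#'
#' @param t time since event onset (ms); vectorized.
#' @param tau1 rise time constant (ms), must satisfy `0 < tau1 < tau2`.
#' @param tau2 decay time constant (ms).
#' @param gmax peak conductance (nS).
#' @return Conductance (nS), same length as `t`.
#' @examples
#' dblexp_conductance(dblexp_peak_time(0.05, 5.3), 0.05, 5.3, 1)  # == 1
#' @export
dblexp_conductance <- function(t, tau1, tau2, gmax = 1) {
  if (tau1 <= 0 || tau1 >= tau2)
    stop("invalid synapse spec: need 0 < tau1 < tau2")
  if (gmax < 0) stop("invalid synapse spec: gmax must be >= 0")
  dblexp_eval(as.numeric(t), tau1, tau2, gmax)
}

#' Peak time of the double-exponential conductance
#'
#' @inheritParams dblexp_conductance
#' @return Time of the conductance maximum (ms),
#'   `tau1*tau2/(tau2 - tau1) * log(tau2/tau1)`.
#' @export
dblexp_peak_time <- function(tau1, tau2) {
  if (tau1 <= 0 || tau1 >= tau2)
    stop("invalid synapse spec: need 0 < tau1 < tau2")
  tau1 * tau2 / (tau2 - tau1) * log(tau2 / tau1)
}

#' NMDA receptor magnesium block factor
#'
#' Voltage dependence of the NMDA conductance under extracellular magnesium,
#' using the Jahr-Stevens sigmoid
#' `1 / (1 + (mg/3.57) * exp(-0.062 * v))`. The factor is in (0, 1], is
#' monotone increasing in `v`, and equals 1 when `mg = 0`.
#'
#' @param v membrane potential (mV); vectorized.
#' @param mg extracellular magnesium concentration (mM), default 1.
#' @return Multiplicative block factor in (0, 1].
#' @export
nmda_gating <- function(v, mg = 1) {
  if (mg < 0) stop("mg must be >= 0")
  nmda_block_cpp(as.numeric(v), mg)
}

#' Ohmic channel current
#'
#' `I = gbar * gating * (v - e_rev)`; outward current is positive (the
#' sign convention used throughout the package).
#'
#' @param gbar maximal conductance (uS or mS/cm^2; any consistent unit).
#' @param gating open fraction in \[0, 1\] (product of gating variables).
#' @param v membrane potential (mV).
#' @param e_rev reversal potential (mV).
#' @return Current in `gbar` units times mV (nA if `gbar` is in uS).
#' @export
channel_current <- function(gbar, gating, v, e_rev) {
  stopifnot(all(gating >= 0 & gating <= 1), all(gbar >= 0))
  gbar * gating * (v - e_rev)
}

#' Simulate a single isolated cell
#'
#' Runs one cell model (no network, no background) under optional somatic
#' current clamp, using the same integrator as the full network simulation.
#' Used for electrophysiological characterization: resting stability, f-I
#' curves, sag, and timestep-convergence checks.
#'
#' @param type cell type: `"pyr"`, `"pv"` or `"olm"`.
#' @param duration_ms simulated time (ms).
#' @param dt_ms integration timestep (ms).
#' @param clamp_nA current-clamp amplitude at the soma (nA).
#' @param clamp_on,clamp_off clamp window (ms).
#' @param params parameter list, see [default_params()].
#' @param v_init initial voltage (mV) for all compartments.
#' @return List with `time` (ms, 1 kHz samples), `v` matrix (samples x
#'   compartments, named), `spikes` (soma spike times, ms), `dt_ms`.
#' @export
run_cell <- function(type, duration_ms = 1000, dt_ms = 0.1, clamp_nA = 0,
                     clamp_on = 0, clamp_off = duration_ms,
                     params = default_params(), v_init = -65) {
  tmpl <- cell_template(type, params)
  n <- nrow(tmpl)
  nb <- axial_csr(tmpl$parent, tmpl$g_parent)
  soma_i <- which(tmpl$name == "soma") - 1L
  net <- list(
    cm = tmpl$cm_nF, gleak = tmpl$gleak, eleak = tmpl$eleak,
    gnaf = tmpl$gnaf, gkdr = tmpl$gkdr, gka = tmpl$gka, gih = tmpl$gih,
    gcal = tmpl$gcal, gkca = tmpl$gkca, ca_alpha = tmpl$ca_alpha,
    nb_ptr = nb$ptr, nb_idx = nb$idx, nb_g = nb$g,
    soma_comp = soma_i, lfp_pos = integer(0), lfp_neg = integer(0),
    ch_tau1 = numeric(0), ch_tau2 = numeric(0), ch_e = numeric(0),
    ch_comp = integer(0), ch_nmda = integer(0),
    ev_time = numeric(0), ev_ch = integer(0), ev_w = numeric(0),
    adj_ptr = c(0L, 0L), adj_ch = integer(0), adj_w = numeric(0),
    ic_comp = if (clamp_nA != 0) soma_i else integer(0),
    ic_amp = if (clamp_nA != 0) clamp_nA else numeric(0),
    ic_start = if (clamp_nA != 0) clamp_on else numeric(0),
    ic_end = if (clamp_nA != 0) clamp_off else numeric(0)
  )
  cfg <- list(
    dt = dt_ms, n_steps = as.integer(round(duration_ms / dt_ms)),
    record_every = max(1L, as.integer(round(1 / dt_ms))),
    delay_steps = 1L, spike_threshold = 0, lockout_ms = 1, mg = params$mg_mM,
    v_init = rep(v_init, n), record_v_comps = seq_len(n) - 1L
  )
  res <- sim_core_run(net, cfg)
  v <- res$v_traces
  colnames(v) <- tmpl$name
  list(time = seq_len(nrow(v)) * 1, v = v, spikes = res$spike_time,
       dt_ms = dt_ms)
}

# axial neighbour CSR (both directions) from parent pointers
axial_csr <- function(parent, g_parent) {
  n <- length(parent)
  nbr <- vector("list", n)
  for (i in seq_len(n)) {
    p <- parent[i]
    if (p >= 0) {
      nbr[[i]] <- rbind(nbr[[i]], c(p, g_parent[i]))
      nbr[[p + 1L]] <- rbind(nbr[[p + 1L]], c(i - 1L, g_parent[i]))
    }
  }
  cnt <- vapply(nbr, function(x) if (is.null(x)) 0L else nrow(x), 0L)
  idx <- unlist(lapply(nbr, function(x) if (is.null(x)) integer(0) else x[, 1]))
  g <- unlist(lapply(nbr, function(x) if (is.null(x)) numeric(0) else x[, 2]))
  list(ptr = as.integer(c(0, cumsum(cnt))),
       idx = as.integer(if (is.null(idx)) integer(0) else idx),
       g = as.numeric(if (is.null(g)) numeric(0) else g))
}
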