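#' Simulation configuration
#'
#' @param duration_ms total simulated time (ms).
#' @param analysis_start_ms start of the analysis window (ms); earlier spikes
#'   are retained but flagged as transient by downstream metrics.
#' @param dt_ms integration timestep (ms); values above 0.1 ms are accepted
#'   with a warning.
#' @param record_interval_ms LFP/voltage sampling interval (ms).
#' @param spike_threshold_mV somatic threshold for spike detection (mV).
#' @param synaptic_delay_ms uniform event-delivery delay for network spikes.
#' @return A `ca3_sim_config` list.
#' @export
sim_config <- function(duration_ms = 7000, analysis_start_ms = 2000,
                       dt_ms = 0.1, record_interval_ms = 1,
                       spike_threshold_mV = 0, synaptic_delay_ms = 6) {
  if (duration_ms <= 0) stop("config error: duration must be > 0")
  if (dt_ms <= 0) stop("config error: dt must be > 0")
  if (dt_ms > 0.1)
    warning(sprintf("dt = %g ms is coarser than the 0.1 ms default", dt_ms))
  if (analysis_start_ms >= duration_ms)
    stop("config error: analysis_start must be < duration")
  structure(list(
    duration_ms = duration_ms, analysis_start_ms = analysis_start_ms,
    dt_ms = dt_ms, record_interval_ms = record_interval_ms,
    spike_threshold_mV = spike_threshold_mV,
    synaptic_delay_ms = synaptic_delay_ms
  ), class = "ca3_sim_config")
}

#' Run a network simulation
#'
#' Integrates the full network at fixed timestep, detects somatic spikes
#' (upward threshold crossings with a 1 ms lockout), and synthesizes the model
#' LFP as the per-sample mean over pyramidal cells of (distal apical voltage
#' minus basal voltage). Deterministic given `(wiring_seed, input_seed, dt)`.
#'
#' @param net a `ca3_network` from [build_network()] (possibly rescaled by
#'   [apply_scaling()]).
#' @param cfg a [sim_config()].
#' @param input_seed integer seed for background and medial-septal event
#'   streams and initial-voltage jitter.
#' @param record_v global cell ids whose somatic voltage should be recorded
#'   (1 kHz), or `NULL`.
#' @return A `ca3_sim` object: `spikes` (data.frame cell/pop/time ms),
#'   `lfp` (mV at `fs_hz`), `fs_hz`, `drive` (per-pyramidal-cell background
#'   dendritic AMPA event trains, the "driving inputs" used for transfer
#'   entropy), `v_traces`, `sizes`, `config`, `input_seed`, `wiring_seed`,
#'   `scaling`.
#' @export
run_simulation <- function(net, cfg = sim_config(), input_seed = 1,
                           record_v = NULL) {
  stopifnot(inherits(net, "ca3_network"), inherits(cfg, "ca3_sim_config"))
  if (any(net$ms_drive$targets == "pyr"))
    stop("config error: medial septum does not project to pyramidal cells")
  params <- net$params
  sizes <- net$sizes
  n_cells <- sum(sizes)
  dur <- cfg$duration_ms

  # --- flatten compartments ---
  templates <- lapply(c(pyr = "pyr", pv = "pv", olm = "olm"),
                      cell_template, params = params)
  pop_of <- net$cells$pop
  n_comp_per <- vapply(templates, nrow, 1L)[pop_of]
  comp_offset <- c(0L, cumsum(n_comp_per))[seq_len(n_cells)]
  comp <- do.call(rbind, lapply(seq_len(n_cells), function(i) {
    tm <- templates[[pop_of[i]]]
    tm$cell <- i
    tm
  }))
  # global parent indices and axial CSR
  gparent <- ifelse(comp$parent < 0, -1L,
                    comp$parent + comp_offset[comp$cell])
  nb <- axial_csr(gparent, comp$g_parent)
  soma_comp <- comp_offset + vapply(pop_of, function(p) {
    which(templates[[p]]$name == "soma") - 1L
  }, 1L)
  comp_index <- function(cell_id, comp_name) {
    comp_offset[cell_id] +
      vapply(seq_along(cell_id), function(k) {
        which(templates[[pop_of[cell_id[k]]]]$name == comp_name[k]) - 1L
      }, 1L)
  }
  pyr_ids <- which(pop_of == "pyr")
  lfp_pos <- comp_index(pyr_ids, rep("Adend3", length(pyr_ids)))
  lfp_neg <- comp_index(pyr_ids, rep("Bdend", length(pyr_ids)))

  # --- synaptic channels: one double-exponential state per unique
  #     (compartment, reversal, tau1, tau2, nmda) ---
  rev <- params$reversals
  recep_e <- c(AMPA = rev$ampa, NMDA = rev$nmda, GABA_A = rev$gaba_a)
  chan <- list(comp = integer(0), tau1 = numeric(0), tau2 = numeric(0),
               e = numeric(0), nmda = integer(0))
  chan_key <- character(0)
  get_channel <- function(comp_i, receptor, tau1, tau2) {
    key <- paste(comp_i, receptor, tau1, tau2, sep = "|")
    hit <- match(key, chan_key)
    if (!is.na(hit)) return(hit)
    chan$comp[[length(chan$comp) + 1L]] <<- comp_i
    chan$tau1[[length(chan$tau1) + 1L]] <<- tau1
    chan$tau2[[length(chan$tau2) + 1L]] <<- tau2
    chan$e[[length(chan$e) + 1L]] <<- recep_e[[receptor]]
    chan$nmda[[length(chan$nmda) + 1L]] <<- as.integer(receptor == "NMDA")
    chan_key[[length(chan_key) + 1L]] <<- key
    length(chan_key)
  }

  # network edges -> channels + adjacency
  edges <- net$edges
  if (nrow(edges) > 0) {
    e_comp <- comp_index(edges$post, edges$target)
    e_key <- paste(e_comp, edges$receptor, edges$tau1, edges$tau2, sep = "|")
    ukey <- unique(e_key)
    # register channels for unique keys in order
    ord <- match(ukey, e_key)
    for (k in ord) get_channel(e_comp[k], edges$receptor[k],
                               edges$tau1[k], edges$tau2[k])
    e_chan <- match(e_key, chan_key)
  } else {
    e_chan <- integer(0)
  }

  # --- input streams (background + MS), seeded ---
  set.seed(input_seed)
  ev_time <- list(); ev_ch <- list(); ev_w <- list()
  drive <- vector("list", sizes[["pyr"]])
  bg <- net$background
  for (k in seq_len(nrow(bg))) {
    row <- bg[k, ]
    ids <- which(pop_of == row$pop)
    streams <- gen_background_events(row$rate_hz, length(ids), dur)
    comp_i <- comp_index(ids, rep(row$target, length(ids)))
    for (j in seq_along(ids)) {
      ts <- streams[[j]]
      if (length(ts) == 0) next
      ci <- get_channel(comp_i[j], row$receptor, row$tau1, row$tau2)
      ev_time[[length(ev_time) + 1L]] <- ts
      ev_ch[[length(ev_ch) + 1L]] <- rep.int(ci, length(ts))
      ev_w[[length(ev_w) + 1L]] <- rep.int(row$gmax_nS * 1e-3, length(ts))
      # the high-conductance dendritic NMDA events are the effective
      # "driving inputs" of the pyramidal population
      if (row$pop == "pyr" && row$receptor == "NMDA" && row$target != "soma")
        drive[[ids[j]]] <- sort(c(drive[[ids[j]]], ts))
    }
  }
  drive <- lapply(drive, function(x) if (is.null(x)) numeric(0) else x)

  ms <- net$ms_drive
  ms_period <- 1000 / ms$freq_hz
  ms_sd <- if (is.null(ms$period_sd_ms)) 0 else ms$period_sd_ms
  ms_volleys <- cumsum(ms_period +
                         stats::rnorm(ceiling(dur / ms_period) + 1L, 0, ms_sd))
  for (pop in ms$targets) {
    ids <- which(pop_of == pop)
    streams <- gen_ms_drive(ms$freq_hz, dur, length(ids), ms$jitter_ms,
                            ms$events_per_volley,
                            volley_times = ms_volleys)
    comp_i <- comp_index(ids, rep("soma", length(ids)))
    for (j in seq_along(ids)) {
      ts <- streams[[j]]
      if (length(ts) == 0) next
      ci <- get_channel(comp_i[j], ms$receptor, ms$tau1, ms$tau2)
      ev_time[[length(ev_time) + 1L]] <- ts
      ev_ch[[length(ev_ch) + 1L]] <- rep.int(ci, length(ts))
      ev_w[[length(ev_w) + 1L]] <- rep.int(ms$gmax_nS[[pop]] * 1e-3, length(ts))
    }
  }
  ev_time <- unlist(ev_time); ev_ch <- unlist(ev_ch); ev_w <- unlist(ev_w)
  if (is.null(ev_time)) { ev_time <- numeric(0); ev_ch <- integer(0); ev_w <- numeric(0) }
  o <- order(ev_time)
  ev_time <- ev_time[o]; ev_ch <- as.integer(ev_ch[o] - 1L); ev_w <- ev_w[o]

  # adjacency CSR over cells
  if (nrow(edges) > 0) {
    eo <- order(edges$pre)
    adj_ch <- as.integer(e_chan[eo] - 1L)
    adj_w <- edges$gmax_nS[eo] * 1e-3
    adj_ptr <- as.integer(c(0, cumsum(tabulate(edges$pre, nbins = n_cells))))
  } else {
    adj_ch <- integer(0); adj_w <- numeric(0)
    adj_ptr <- integer(n_cells + 1L)
  }

  v0 <- params$simulation$v_init_mV +
    stats::rnorm(nrow(comp), 0, params$simulation$v_init_jitter_mV)

  rec_v <- if (is.null(record_v)) integer(0) else as.integer(soma_comp[record_v])
  core_net <- list(
    cm = comp$cm_nF, gleak = comp$gleak, eleak = comp$eleak,
    gnaf = comp$gnaf, gkdr = comp$gkdr, gka = comp$gka, gih = comp$gih,
    gcal = comp$gcal, gkca = comp$gkca, ca_alpha = comp$ca_alpha,
    nb_ptr = nb$ptr, nb_idx = nb$idx, nb_g = nb$g,
    soma_comp = as.integer(soma_comp), lfp_pos = as.integer(lfp_pos),
    lfp_neg = as.integer(lfp_neg),
    ch_tau1 = chan$tau1, ch_tau2 = chan$tau2, ch_e = chan$e,
    ch_comp = as.integer(chan$comp), ch_nmda = chan$nmda,
    ev_time = ev_time, ev_ch = ev_ch, ev_w = ev_w,
    adj_ptr = adj_ptr, adj_ch = adj_ch, adj_w = adj_w,
    ic_comp = integer(0), ic_amp = numeric(0), ic_start = numeric(0),
    ic_end = numeric(0)
  )
  rec_every <- max(1L, as.integer(round(cfg$record_interval_ms / cfg$dt_ms)))
  core_cfg <- list(
    dt = cfg$dt_ms, n_steps = as.integer(round(dur / cfg$dt_ms)),
    record_every = rec_every,
    delay_steps = max(1L, as.integer(round(cfg$synaptic_delay_ms / cfg$dt_ms))),
    spike_threshold = cfg$spike_threshold_mV,
    lockout_ms = params$simulation$lockout_ms, mg = params$mg_mM,
    v_init = v0, record_v_comps = rec_v
  )
  res <- sim_core_run(core_net, core_cfg)
  fs <- 1000 / cfg$record_interval_ms

  spikes <- data.frame(
    cell = res$spike_cell + 1L,
    pop = pop_of[res$spike_cell + 1L],
    time = res$spike_time,
    stringsAsFactors = FALSE
  )
  structure(list(
    spikes = spikes, lfp = as.numeric(res$lfp), fs_hz = fs, drive = drive,
    v_traces = res$v_traces, sizes = sizes, config = cfg,
    input_seed = input_seed, wiring_seed = net$wiring_seed,
    scaling = net$scaling
  ), class = "ca3_sim")
}

#' @export
print.ca3_sim <- function(x, ...) {
  cat(sprintf("CA3 simulation: %g ms, %d spikes (%s)\n",
              x$config$duration_ms, nrow(x$spikes),
              paste(sprintf("%s %d", names(x$sizes),
                            tabulate(match(x$spikes$pop, names(x$sizes)),
                                     length(x$sizes))), collapse = ", ")))
  invisible(x)
}

#' Detect spikes in a voltage trace
#'
#' Upward crossings of `threshold` with a refractory lockout.
#'
#' @param v voltage trace (mV).
#' @param dt_ms sampling interval (ms).
#' @param threshold threshold (mV).
#' @param lockout_ms minimum inter-spike interval (ms).
#' @return Spike times (ms).
#' @export
detect_spikes <- function(v, dt_ms, threshold = 0, lockout_ms = 1) {
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold)
  if (length(up) == 0) return(numeric(0))
  times <- up * dt_ms
  keep <- times[1]
  for (t in times[-1]) if (t - keep[length(keep)] >= lockout_ms) keep <- c(keep, t)
  keep
}

#' Model LFP from compartment voltage matrices
#'
#' The model LFP proxy: per-sample mean over pyramidal cells of the distal
#' apical minus basal dendritic voltage (mean, not sum; the DC offset is
#' retained here and removed by the PSD step).
#'
#' @param apical,basal numeric matrices (samples x cells) of recorded
#'   voltages.
#' @return Numeric LFP trace (mV).
#' @export
compute_lfp <- function(apical, basal) {
  if (!all(dim(apical) == dim(basal)))
    stop("apical and basal recordings must have identical dimensions")
  rowMeans(apical - basal)
}

#' Write / read spike tables and LFP traces as columnar text
#'
#' The package's on-disk dialect: tab-separated with a header. Spike tables
#' have columns `cell`, `pop`, `time` (ms); LFP files have `time_ms`, `mV`.
#'
#' @param x a `ca3_sim`, or a spikes data.frame / LFP numeric vector.
#' @param path file path.
#' @param fs_hz LFP sampling rate (needed when `x` is a bare vector).
#' @return `path` invisibly (writers); the parsed object (readers).
#' @export
write_spike_table <- function(x, path) {
  sp <- if (inherits(x, "ca3_sim")) x$spikes else x
  utils::write.table(sp, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_table
#' @export
read_spike_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname write_spike_table
#' @export
write_lfp <- function(x, path, fs_hz = NULL) {
  if (inherits(x, "ca3_sim")) { fs_hz <- x$fs_hz; x <- x$lfp }
  if (is.null(fs_hz)) stop("fs_hz required for bare traces")
  df <- data.frame(time_ms = seq_along(x) * 1000 / fs_hz, mV = x)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_table
#' @export
read_lfp <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  fs <- 1000 / diff(df$time_ms[1:2])
  list(lfp = df$mV, fs_hz = fs)
}
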