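#' Default model parameters
#'
#' Returns the full nested parameter set for the CA3 microcircuit: cell
#' geometries and channel conductance densities, synaptic connection rules,
#' background-drive specifications, medial-septal pacing, reversal potentials,
#' and simulation defaults. Every value here can be overridden by editing the
#' returned list or a YAML parameter file (see [load_params()]).
#'
#' Conventions fixed across the package:
#' \itemize{
#'   \item channel conductance densities in mS/cm^2, synaptic peak
#'     conductances in nS, times in ms, voltages in mV, rates in Hz;
#'   \item membrane capacitance 1 uF/cm^2, axial resistivity 150 ohm cm;
#'   \item pyramidal cells have five compartments laid out as
#'     Bdend--soma--Adend1--Adend2--Adend3, with the I_h density increasing
#'     along the apical dendrite; PV basket and OLM cells are single
#'     compartments;
#'   \item synaptic reversals: AMPA/NMDA 0 mV, GABA_A -80 mV.
#' }
#'
#' Background Poisson event rates (`rate_hz` in `$background`) are model
#' calibration constants: they are not biophysical measurements but were tuned
#' once (see `scripts/tune_background.R`) so that the unmanipulated network
#' fires in the theta-nested-gamma regime, and are held fixed across all
#' manipulations.
#'
#' @return A nested list with components `cells`, `synapses`, `background`,
#'   `ms_drive`, `reversals`, `populations`, `simulation`.
#' @export
default_params <- function() {
  list(
    populations = list(pyr = 800L, pv = 200L, olm = 200L),
    reversals = list(ampa = 0, nmda = 0, gaba_a = -80, leak = -65,
                     ih = -30, na = 55, k = -90, ca = 120),
    mg_mM = 1,
    cells = list(
      pyr = list(
        compartments = data.frame(
          name = c("Bdend", "soma", "Adend1", "Adend2", "Adend3"),
          parent = c("soma", NA, "soma", "Adend1", "Adend2"),
          L_um = c(200, 20, 150, 150, 150),
          diam_um = c(2, 20, 2, 2, 2),
          stringsAsFactors = FALSE
        ),
        # densities in mS/cm^2, one column per compartment
        channels = list(
          leak = c(Bdend = 0.1, soma = 0.1, Adend1 = 0.1, Adend2 = 0.1, Adend3 = 0.1),
          NaF  = c(Bdend = 25, soma = 100, Adend1 = 25, Adend2 = 25, Adend3 = 25),
          KDR  = c(Bdend = 10, soma = 80, Adend1 = 10, Adend2 = 10, Adend3 = 10),
          KA   = c(Bdend = 10, soma = 30, Adend1 = 15, Adend2 = 20, Adend3 = 25),
          Ih   = c(Bdend = 0.0075, soma = 0.0075, Adend1 = 0.015, Adend2 = 0.03,
                   Adend3 = 0.06)
        ),
        e_leak = -65
      ),
      pv = list(
        compartments = data.frame(
          name = "soma", parent = NA, L_um = 20, diam_um = 20,
          stringsAsFactors = FALSE
        ),
        channels = list(
          leak = c(soma = 0.4), NaF = c(soma = 150), KDR = c(soma = 100),
          Ih = c(soma = 0.025)
        ),
        e_leak = -65
      ),
      olm = list(
        compartments = data.frame(
          name = "soma", parent = NA, L_um = 20, diam_um = 20,
          stringsAsFactors = FALSE
        ),
        channels = list(
          leak = c(soma = 0.05), NaF = c(soma = 100), KDR = c(soma = 70),
          Ih = c(soma = 0.15), CaL = c(soma = 0.5), KCa = c(soma = 5)
        ),
        e_leak = -65,
        ca_alpha = 0.002   # mM per nA ms calcium influx scaling
      )
    ),
    cm_uF_cm2 = 1,
    ra_ohm_cm = 150,
    # network connection rules: convergence = presynaptic partners per
    # postsynaptic cell; conductances are peak values of the
    # double-exponential (nS)
    synapses = data.frame(
      pre = c("pyr", "pyr", "pyr", "pyr", "pyr", "pyr",
              "pv", "pv", "pv", "olm"),
      post = c("pyr", "pyr", "pv", "pv", "olm", "olm",
               "pyr", "pv", "olm", "pyr"),
      receptor = c("AMPA", "NMDA", "AMPA", "NMDA", "AMPA", "NMDA",
                   "GABA_A", "GABA_A", "GABA_A", "GABA_A"),
      tau1 = c(0.05, 15, 0.05, 15, 0.05, 15, 0.07, 0.07, 0.07, 0.2),
      tau2 = c(5.3, 150, 5.3, 150, 5.3, 150, 9.1, 9.1, 9.1, 20),
      gmax_nS = c(0.02, 0.004, 0.36, 1.38, 0.36, 0.7,
                  0.72, 4.5, 0.023, 72),
      convergence = c(25L, 25L, 100L, 100L, 10L, 10L, 50L, 60L, 1L, 20L),
      target = c("Adend2", "Adend2", "soma", "soma", "soma", "soma",
                 "soma", "soma", "soma", "Adend3"),
      stringsAsFactors = FALSE
    ),
    # background Poisson drive; rate_hz calibrated, conductances fixed
    background = data.frame(
      pop = c("pyr", "pyr", "pyr", "pyr", "pyr", "pv", "pv", "olm", "olm"),
      target = c("soma", "soma", "Adend3", "Adend3", "Adend3",
                 "soma", "soma", "soma", "soma"),
      receptor = c("AMPA", "GABA_A", "AMPA", "NMDA", "GABA_A",
                   "AMPA", "GABA_A", "AMPA", "GABA_A"),
      tau1 = c(0.05, 0.07, 0.05, 15, 0.07, 0.05, 0.07, 0.05, 0.07),
      tau2 = c(5.3, 9.1, 5.3, 150, 9.1, 5.3, 9.1, 5.3, 9.1),
      gmax_nS = c(0.05, 0.012, 0.05, 6.5, 0.012, 0.02, 0.2, 0.0625, 0.2),
      rate_hz = c(150, 150, 150, 45, 150, 100, 150, 200, 150),
      stringsAsFactors = FALSE
    ),
    ms_drive = list(
      freq_hz = 6.7, jitter_ms = 6, events_per_volley = 5, period_sd_ms = 14,
      targets = c("pv", "olm"),
      receptor = "GABA_A", tau1 = 0.07, tau2 = 9.1,
      gmax_nS = c(pv = 10, olm = 10)
    ),
    simulation = list(
      duration_ms = 7000, analysis_start_ms = 2000, dt_ms = 0.1,
      record_interval_ms = 1, spike_threshold_mV = 0, lockout_ms = 1,
      synaptic_delay_ms = 6, v_init_mV = -65, v_init_jitter_mV = 2
    )
  )
}

#' Read a parameter file
#'
#' Parameter files are YAML renderings of the list returned by
#' [default_params()]; [write_params()] followed by `load_params()`
#' round-trips the parameter set exactly.
#'
#' @param path path to a YAML parameter file.
#' @return A parameter list in the layout of [default_params()].
#' @export
load_params <- function(path) {
  p <- yaml::read_yaml(path)
  # restore data.frame tables that YAML stores as column lists
  for (nm in c("synapses", "background")) {
    p[[nm]] <- as.data.frame(p[[nm]], stringsAsFactors = FALSE)
  }
  for (ct in names(p$cells)) {
    p$cells[[ct]]$compartments <-
      as.data.frame(p$cells[[ct]]$compartments, stringsAsFactors = FALSE)
    p$cells[[ct]]$channels <- lapply(p$cells[[ct]]$channels, unlist)
  }
  p$ms_drive$gmax_nS <- unlist(p$ms_drive$gmax_nS)
  p$populations <- lapply(p$populations, as.integer)
  p$synapses$convergence <- as.integer(p$synapses$convergence)
  p
}

#' Write a parameter file
#'
#' @param params parameter list as from [default_params()].
#' @param path output path (YAML).
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  # YAML drops names of atomic vectors; store named vectors as maps
  for (ct in names(params$cells)) {
    params$cells[[ct]]$channels <- lapply(params$cells[[ct]]$channels, as.list)
  }
  params$ms_drive$gmax_nS <- as.list(params$ms_drive$gmax_nS)
  yaml::write_yaml(params, path, precision = 15L)
  invisible(path)
}

# compartment table for one cell type with absolute electrical quantities:
# area (cm^2), capacitance (nF), absolute channel conductances (uS), and
# axial coupling conductance to the parent compartment (uS)
cell_template <- function(type, params = default_params()) {
  cp <- params$cells[[type]]
  geo <- cp$compartments
  area <- pi * (geo$diam_um * 1e-4) * (geo$L_um * 1e-4)   # cm^2 (cylinder side)
  cm_nF <- area * params$cm_uF_cm2 * 1e3                  # uF -> nF... (1 uF = 1000 nF)
  dens <- function(chan) {
    d <- cp$channels[[chan]]
    if (is.null(d)) return(rep(0, nrow(geo)))
    unname(d[geo$name])
  }
  # axial resistance of a half-compartment in Mohm
  half_r <- (4 * params$ra_ohm_cm * (geo$L_um * 1e-4) / 2) /
    (pi * (geo$diam_um * 1e-4)^2) / 1e6
  parent_idx <- match(geo$parent, geo$name)
  g_parent <- ifelse(is.na(parent_idx), 0,
                     1 / (half_r + half_r[parent_idx]))   # uS (1/Mohm)
  out <- data.frame(
    name = geo$name, parent = ifelse(is.na(parent_idx), -1L,
                                     as.integer(parent_idx - 1L)),
    area_cm2 = area, cm_nF = cm_nF,
    gleak = dens("leak") * area * 1e3,   # mS/cm2 * cm2 = mS -> uS
    eleak = cp$e_leak,
    gnaf = dens("NaF") * area * 1e3,
    gkdr = dens("KDR") * area * 1e3,
    gka = dens("KA") * area * 1e3,
    gih = dens("Ih") * area * 1e3,
    gcal = dens("CaL") * area * 1e3,
    gkca = dens("KCa") * area * 1e3,
    g_parent = g_parent,
    stringsAsFactors = FALSE
  )
  out$ca_alpha <- if (is.null(cp$ca_alpha)) 0 else cp$ca_alpha
  out
}
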