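#' Scaled connection rules
#'
#' The network's ten connection rules (pre population, post population,
#' receptor, double-exponential time constants, peak conductance, convergence,
#' target compartment), with population sizes and convergences multiplied by
#' `scale` (rounded, minimum 1). Convergence is the number of distinct
#' presynaptic partners per postsynaptic cell.
#'
#' @param params parameter list, see [default_params()].
#' @param scale network scale factor in (0, 1].
#' @return List with `sizes` (named integer vector) and `rules` (data.frame).
#' @export
connection_rules <- function(params = default_params(), scale = 1) {
  if (scale <= 0 || scale > 1) stop("scale must be in (0, 1]")
  sizes <- vapply(params$populations, function(n) max(1L, as.integer(round(n * scale))), 1L)
  rules <- params$synapses
  rules$convergence <- pmax(1L, as.integer(round(rules$convergence * scale)))
  list(sizes = sizes, rules = rules)
}

#' Wire one connection rule
#'
#' For every postsynaptic cell, samples exactly `convergence` distinct
#' presynaptic partners uniformly without replacement (self-connections
#' excluded when pre and post populations coincide). Deterministic per seed.
#'
#' @param rule one row of the rules table (see [connection_rules()]).
#' @param n_pre,n_post population sizes.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return data.frame with columns `pre`, `post` (1-based within-population
#'   indices) plus the rule's receptor/kinetics/conductance/target columns.
#' @export
wire_rule <- function(rule, n_pre, n_post, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  conv <- rule$convergence
  avail <- if (identical(rule$pre, rule$post)) n_pre - 1L else n_pre
  if (conv > avail)
    stop(sprintf("convergence %d exceeds available presynaptic cells (%d) for %s->%s",
                 conv, avail, rule$pre, rule$post))
  if (conv == 0L) {
    return(data.frame(pre = integer(0), post = integer(0)))
  }
  pre <- unlist(lapply(seq_len(n_post), function(j) {
    pool <- if (identical(rule$pre, rule$post)) setdiff(seq_len(n_pre), j) else seq_len(n_pre)
    sample(pool, conv)
  }))
  data.frame(
    pre = pre, post = rep(seq_len(n_post), each = conv),
    receptor = rule$receptor, tau1 = rule$tau1, tau2 = rule$tau2,
    gmax_nS = rule$gmax_nS, target = rule$target, stringsAsFactors = FALSE
  )
}

#' Build the CA3 network graph
#'
#' Constructs the three-population network (pyramidal, PV basket, OLM) with
#' randomized convergent wiring from the rules table, background Poisson drive
#' attachments, and rhythmic medial-septal inhibition onto PV and OLM cells.
#' The same `wiring_seed` always reproduces the identical edge table.
#'
#' @param params parameter list, see [default_params()].
#' @param scale scale factor in (0, 1] applied to population sizes and
#'   convergences (rounded, minimum 1).
#' @param wiring_seed integer seed for the connectivity RNG.
#' @param compensate at reduced scale, multiply each edge conductance by the
#'   ratio of full-scale to scaled convergence so that every cell's total
#'   synaptic conductance per connection type matches the full-scale network
#'   (the standard network-downscaling correction); default `TRUE`.
#' @return An object of class `ca3_network`: list with `sizes`, `cells`
#'   (global id, population), `rules`, `edges` (global pre/post ids),
#'   `background`, `ms_drive`, `params`, `scale`, `wiring_seed`, `scaling`.
#' @export
build_network <- function(params = default_params(), scale = 1,
                          wiring_seed = 1, compensate = TRUE) {
  cr <- connection_rules(params, scale)
  sizes <- cr$sizes
  offsets <- c(pyr = 0L, pv = sizes[["pyr"]],
               olm = sizes[["pyr"]] + sizes[["pv"]])
  full_conv <- params$synapses$convergence
  set.seed(wiring_seed)
  edges <- do.call(rbind, lapply(seq_len(nrow(cr$rules)), function(k) {
    rule <- cr$rules[k, ]
    e <- wire_rule(rule, sizes[[rule$pre]], sizes[[rule$post]], seed = NULL)
    e$pre <- e$pre + offsets[[rule$pre]]
    e$post <- e$post + offsets[[rule$post]]
    if (compensate && nrow(e) > 0) {
      # downscaling correction: preserve each cell's total synaptic
      # conductance per connection type when convergence is reduced
      e$gmax_nS <- e$gmax_nS * (full_conv[k] / rule$convergence)
    }
    e
  }))
  rownames(edges) <- NULL
  cells <- data.frame(
    id = seq_len(sum(sizes)),
    pop = rep(c("pyr", "pv", "olm"), times = sizes),
    stringsAsFactors = FALSE
  )
  structure(list(
    sizes = sizes, offsets = offsets, cells = cells, rules = cr$rules,
    edges = edges, background = params$background, ms_drive = params$ms_drive,
    params = params, scale = scale, wiring_seed = wiring_seed,
    scaling = c(nmdar_olm = 1, gaba_pyr = 1, ih = 1)
  ), class = "ca3_network")
}

#' @export
print.ca3_network <- function(x, ...) {
  cat(sprintf("CA3 network (scale %.3g): %d PYR, %d PV, %d OLM; %d edges\n",
              x$scale, x$sizes[["pyr"]], x$sizes[["pv"]], x$sizes[["olm"]],
              nrow(x$edges)))
  cat(sprintf("wiring seed %d; scaling nmdar_olm=%.3g gaba_pyr=%.3g ih=%.3g\n",
              x$wiring_seed, x$scaling[["nmdar_olm"]],
              x$scaling[["gaba_pyr"]], x$scaling[["ih"]]))
  invisible(x)
}

#' Homogeneous Poisson event streams
#'
#' Independent Poisson event-time vectors, one per stream, deterministic per
#' seed. These are the background-drive event trains attached to every
#' (cell, synapse) pair.
#'
#' @param rate_hz event rate (Hz).
#' @param n_streams number of independent streams.
#' @param duration_ms stream duration (ms).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return List of `n_streams` sorted event-time vectors (ms).
#' @export
gen_background_events <- function(rate_hz, n_streams, duration_ms,
                                  seed = NULL) {
  if (rate_hz < 0) stop("rate must be >= 0")
  if (duration_ms <= 0) stop("duration must be > 0")
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_streams), function(i) {
    n <- stats::rpois(1, rate_hz * duration_ms / 1000)
    sort(stats::runif(n, 0, duration_ms))
  })
}

#' Medial-septal rhythmic drive
#'
#' Inhibitory volleys at theta frequency onto every PV and OLM cell (never
#' onto pyramidal cells). Volleys occur at integer multiples of the period
#' `1000/freq_hz` ms (the first at one full period), and each cell receives a
#' Poisson-distributed number of events per volley (mean `events_per_volley`)
#' jittered by a zero-mean Gaussian of SD `jitter_ms`.
#'
#' @param freq_hz volley frequency (Hz), > 0.
#' @param duration_ms total duration (ms).
#' @param n_targets number of target cells.
#' @param jitter_ms per-cell Gaussian event jitter SD (ms).
#' @param events_per_volley mean events per volley and cell.
#' @param period_sd_ms cycle-to-cycle SD of the pacemaker period (ms), shared
#'   by all target cells; septal theta is quasi-periodic, not clockwork.
#' @param volley_times optional explicit pacemaker volley times (ms),
#'   overriding the internally drawn grid (used to share one pacemaker
#'   across several target populations).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return List of `n_targets` sorted event-time vectors (ms), clipped to
#'   `[0, duration_ms)`.
#' @export
gen_ms_drive <- function(freq_hz, duration_ms, n_targets, jitter_ms = 4,
                         events_per_volley = 1, period_sd_ms = 0,
                         volley_times = NULL, seed = NULL) {
  if (freq_hz <= 0) stop("freq must be > 0")
  if (!is.null(seed)) set.seed(seed)
  if (duration_ms <= 0) return(rep(list(numeric(0)), n_targets))
  if (is.null(volley_times)) {
    period <- 1000 / freq_hz
    n_vol <- ceiling(duration_ms / period) + 1L
    volley_times <- cumsum(period + stats::rnorm(n_vol, 0, period_sd_ms))
  }
  volleys <- volley_times[volley_times <= duration_ms]
  lapply(seq_len(n_targets), function(i) {
    times <- unlist(lapply(volleys, function(tv) {
      k <- stats::rpois(1, events_per_volley)
      if (k == 0) return(numeric(0))
      tv + stats::rnorm(k, 0, jitter_ms)
    }))
    sort(times[times >= 0 & times < duration_ms])
  })
}

#' Export the edge table as columnar text
#'
#' @param net a `ca3_network`.
#' @param path output path (tab-separated).
#' @return `path`, invisibly.
#' @export
export_edges <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an exported edge table
#'
#' @param path path written by [export_edges()].
#' @return The edge data.frame.
#' @export
read_edges <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
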