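#' Conductance scaling set
#'
#' The triplet of multiplicative factors applied to the three pharmacological
#' targets: NMDA receptor conductance on OLM cells, GABA-A receptor
#' conductance on pyramidal cells, and the I_h maximal conductance of
#' pyramidal and PV basket cells. `(1, 1, 1)` is the baseline identity.
#'
#' @param nmdar_olm,gaba_pyr,ih multiplicative factors, all > 0.
#' @param input_seed,wiring_seed seeds attached to this scaling point.
#' @return A `scaling_set` list.
#' @export
scaling_set <- function(nmdar_olm = 1, gaba_pyr = 1, ih = 1,
                        input_seed = 1, wiring_seed = 1) {
  if (any(c(nmdar_olm, gaba_pyr, ih) <= 0))
    stop("config error: scaling factors must be > 0")
  structure(list(nmdar_olm = nmdar_olm, gaba_pyr = gaba_pyr, ih = ih,
                 input_seed = as.integer(input_seed),
                 wiring_seed = as.integer(wiring_seed)),
            class = "scaling_set")
}

#' Apply conductance scalings to a network
#'
#' Returns a new network in which (a) the peak conductance of every NMDA
#' synapse onto an OLM cell is multiplied by `s$nmdar_olm`, (b) the peak
#' conductance of every GABA-A synapse onto a pyramidal cell is multiplied by
#' `s$gaba_pyr`, and (c) the I_h conductance density of pyramidal and PV
#' cells is multiplied by `s$ih`. OLM I_h and everything else are untouched;
#' the input network is not modified. Background synapses are left unscaled
#' by default (the manipulations target circuit receptors), but
#' `include_background = TRUE` scales matching background conductances too.
#'
#' @param net a `ca3_network`.
#' @param s a [scaling_set()].
#' @param include_background also scale matching background-drive synapses.
#' @return The rescaled `ca3_network`.
#' @export
apply_scaling <- function(net, s, include_background = FALSE) {
  stopifnot(inherits(net, "ca3_network"), inherits(s, "scaling_set"))
  pop_of <- net$cells$pop
  is_olm_post <- pop_of[net$edges$post] == "olm"
  is_pyr_post <- pop_of[net$edges$post] == "pyr"
  sel_nmda <- net$edges$receptor == "NMDA" & is_olm_post
  sel_gaba <- net$edges$receptor == "GABA_A" & is_pyr_post
  net$edges$gmax_nS[sel_nmda] <- net$edges$gmax_nS[sel_nmda] * s$nmdar_olm
  net$edges$gmax_nS[sel_gaba] <- net$edges$gmax_nS[sel_gaba] * s$gaba_pyr
  for (ct in c("pyr", "pv")) {
    net$params$cells[[ct]]$channels$Ih <-
      net$params$cells[[ct]]$channels$Ih * s$ih
  }
  if (include_background) {
    bsel_n <- net$background$receptor == "NMDA" & net$background$pop == "olm"
    bsel_g <- net$background$receptor == "GABA_A" & net$background$pop == "pyr"
    net$background$gmax_nS[bsel_n] <- net$background$gmax_nS[bsel_n] * s$nmdar_olm
    net$background$gmax_nS[bsel_g] <- net$background$gmax_nS[bsel_g] * s$gaba_pyr
  }
  net$scaling <- c(nmdar_olm = net$scaling[["nmdar_olm"]] * s$nmdar_olm,
                   gaba_pyr = net$scaling[["gaba_pyr"]] * s$gaba_pyr,
                   ih = net$scaling[["ih"]] * s$ih)
  net
}

#' Default scaling grids
#'
#' NMDAR-on-OLM augmentation levels span control (1x) to 30x; the
#' bidirectional GABA-A and I_h grids are log-spaced from 0.1x to 10x.
#'
#' @return Named list of numeric level vectors.
#' @export
default_levels <- function() {
  list(nmdar_olm = c(1, 1.5, 2.5, 5, 10, 20, 30),
       gaba_pyr = c(0.1, 0.33, 1, 3.3, 10),
       ih = c(0.1, 0.33, 1, 3.3, 10))
}

#' Build a sweep design
#'
#' The two factorial experiment designs: `"nmdar"` crosses 7 NMDAR-on-OLM
#' levels with 5 input seeds x 5 wiring seeds (175 runs); `"triscaling"`
#' crosses 7 NMDAR x 5 GABA-A x 5 I_h levels with 3 input x 3 wiring seeds
#' (1575 runs). Levels and seed lists are overridable; the Cartesian product
#' has a stable ordering (seeds vary fastest, then NMDAR, GABA-A, I_h).
#'
#' @param label `"nmdar"` or `"triscaling"`.
#' @param levels named list of level vectors as in [default_levels()].
#' @param input_seeds,wiring_seeds seed vectors; defaults are 1:5 for the
#'   NMDAR design and 1:3 for the tri-scaling design.
#' @return data.frame with columns `nmdar_olm`, `gaba_pyr`, `ih`,
#'   `input_seed`, `wiring_seed`, one row per simulation.
#' @export
build_design <- function(label, levels = default_levels(),
                         input_seeds = NULL, wiring_seeds = NULL) {
  if (label == "nmdar") {
    if (is.null(input_seeds)) input_seeds <- 1:5
    if (is.null(wiring_seeds)) wiring_seeds <- 1:5
    g <- expand.grid(input_seed = input_seeds, wiring_seed = wiring_seeds,
                     nmdar_olm = levels$nmdar_olm, gaba_pyr = 1, ih = 1)
  } else if (label == "triscaling") {
    if (is.null(input_seeds)) input_seeds <- 1:3
    if (is.null(wiring_seeds)) wiring_seeds <- 1:3
    g <- expand.grid(input_seed = input_seeds, wiring_seed = wiring_seeds,
                     nmdar_olm = levels$nmdar_olm, gaba_pyr = levels$gaba_pyr,
                     ih = levels$ih)
  } else {
    stop(sprintf("unknown design label '%s'", label))
  }
  g[, c("nmdar_olm", "gaba_pyr", "ih", "input_seed", "wiring_seed")]
}

#' Run a sweep of simulations
#'
#' Runs one simulation per design row (wiring rebuilt per wiring seed,
#' scalings applied, metrics computed on the analysis window) and collects
#' one metrics row per run. With `out_dir` set, each completed run is stored
#' as a TSV and skipped on restart, making interrupted sweeps resumable and
#' reruns idempotent. Individual failures are recorded (`ok = FALSE`) and the
#' sweep continues.
#'
#' @param design data.frame from [build_design()] (or any subset).
#' @param params base parameter list.
#' @param scale network scale factor (the desk-scale default is 0.25).
#' @param cfg a [sim_config()].
#' @param out_dir optional directory for per-run result files.
#' @param n_nte_cells,shuffles metric settings, see [sim_metrics()].
#' @param verbose print one line per completed run.
#' @return data.frame: design columns + metrics row per simulation + `ok`.
#' @export
run_sweep <- function(design, params = default_params(), scale = 0.25,
                      cfg = sim_config(), out_dir = NULL, n_nte_cells = 25,
                      shuffles = 30, verbose = FALSE) {
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  rows <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    d <- design[i, ]
    tag <- sprintf("run_n%g_g%g_h%g_i%d_w%d.tsv", d$nmdar_olm, d$gaba_pyr,
                   d$ih, d$input_seed, d$wiring_seed)
    if (!is.null(out_dir) && file.exists(file.path(out_dir, tag))) {
      rows[[i]] <- utils::read.table(file.path(out_dir, tag), header = TRUE,
                                     sep = "\t")
      next
    }
    res <- tryCatch({
      net <- build_network(params, scale = scale,
                           wiring_seed = d$wiring_seed)
      net <- apply_scaling(net, scaling_set(d$nmdar_olm, d$gaba_pyr, d$ih))
      sim <- run_simulation(net, cfg, input_seed = d$input_seed)
      m <- sim_metrics(sim, n_nte_cells = n_nte_cells, shuffles = shuffles,
                       seed = d$input_seed)
      cbind(d, m, ok = TRUE, row.names = NULL)
    }, error = function(e) {
      warning(sprintf("run %d failed: %s", i, conditionMessage(e)))
      cbind(d, ok = FALSE, row.names = NULL)
    })
    if (!is.null(out_dir))
      utils::write.table(res, file.path(out_dir, tag), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    rows[[i]] <- res
    if (verbose)
      message(sprintf("[%d/%d] nmdar=%g gaba=%g ih=%g seeds=(%d,%d)",
                      i, nrow(design), d$nmdar_olm, d$gaba_pyr, d$ih,
                      d$input_seed, d$wiring_seed))
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    if (!"ok" %in% names(r)) r$ok <- TRUE
    r
  }))
  rownames(out) <- NULL
  out
}

#' Aggregate a sweep table
#'
#' Mean and standard error per scaling point, pooled over seed replicates
#' only (never across scaling points). Undefined (NA) metric values are
#' excluded, with the replicate count reported per point.
#'
#' @param table sweep result table from [run_sweep()].
#' @param metrics metric column names to aggregate.
#' @return data.frame: one row per (nmdar_olm, gaba_pyr, ih) with
#'   `<metric>_mean`, `<metric>_sem`, `<metric>_n` columns. SEM is `NA` for
#'   single replicates.
#' @export
aggregate_sweep <- function(table,
                            metrics = c("nte", "mi", "gamma_power",
                                        "theta_power", "rate_pyr", "rate_pv",
                                        "rate_olm", "popcv_pyr", "popcv_pv",
                                        "popcv_olm")) {
  metrics <- intersect(metrics, names(table))
  key <- interaction(table$nmdar_olm, table$gaba_pyr, table$ih, drop = TRUE)
  pts <- !duplicated(key)
  out <- table[pts, c("nmdar_olm", "gaba_pyr", "ih")]
  for (m in metrics) {
    vals <- split(table[[m]], key)[as.character(key[pts])]
    out[[paste0(m, "_mean")]] <- vapply(vals, function(v) mean(v, na.rm = TRUE), 1.0)
    out[[paste0(m, "_sem")]] <- vapply(vals, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2) NA_real_ else stats::sd(v) / sqrt(length(v))
    }, 1.0)
    out[[paste0(m, "_n")]] <- vapply(vals, function(v) sum(!is.na(v)), 1L)
  }
  rownames(out) <- NULL
  out
}

#' Detect an inverted-U dose-response shape
#'
#' The curve is called inverted-U when the maximum lies at an interior level
#' of the ordered grid and both endpoint values fall below the peak by more
#' than one pooled standard error.
#'
#' @param x ordered scaling levels (>= 3).
#' @param y aggregated metric values at `x`.
#' @param sem per-point standard errors (optional; 0 when absent).
#' @return List: `is_inverted_u`, `peak_level`, `peak_value`.
#' @export
detect_inverted_u <- function(x, y, sem = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  o <- order(x)
  x <- x[o]; y <- y[o]
  sem <- if (is.null(sem)) rep(0, length(y)) else sem[o]
  sem[is.na(sem)] <- 0
  k <- which.max(y)
  pooled <- sqrt(mean(sem^2))
  interior <- k > 1 && k < length(y)
  below <- y[1] < y[k] - pooled && y[length(y)] < y[k] - pooled
  list(is_inverted_u = interior && below, peak_level = x[k], peak_value = y[k])
}

#' Secondary-metric range in the top percentile of a primary metric
#'
#' Selects the rows whose primary metric exceeds its `pct`-th percentile and
#' reports the min/max range of the secondary metric over that subset,
#' together with the full-table range for contrast. Used for the
#' "top-decile information flow occupies an intermediate gamma-power range"
#' analysis.
#'
#' @param table sweep result table.
#' @param metric primary metric column (default `"nte"`).
#' @param pct percentile threshold (default 90).
#' @param secondary secondary metric column (default `"gamma_power"`).
#' @return List: `subset_range`, `full_range` (each `c(lo, hi)`), `n_subset`.
#' @export
top_percentile_band <- function(table, metric = "nte", pct = 90,
                                secondary = "gamma_power") {
  v <- table[[metric]]; w <- table[[secondary]]
  keep <- !is.na(v) & !is.na(w)
  v <- v[keep]; w <- w[keep]
  if (length(v) < 10) stop("need at least 10 rows")
  thr <- stats::quantile(v, pct / 100, names = FALSE)
  sel <- v >= thr
  list(subset_range = range(w[sel]), full_range = range(w),
       n_subset = sum(sel))
}

#' Bilinear surface interpolation on a log-scaled scaling grid
#'
#' Interpolates sweep results defined on a rectangular grid of scaling levels
#' onto a dense surface for plotting; axes are log-scaled (scaling factors
#' are multiplicative) and the interpolant is exact at the grid nodes.
#'
#' @param x,y grid level vectors (strictly increasing, > 0).
#' @param z value matrix, `length(x)` rows x `length(y)` columns.
#' @param n output resolution per axis.
#' @return List with `x`, `y` (dense level vectors) and `z` (n x n matrix).
#' @export
surface_interpolate <- function(x, y, z, n = 50) {
  if (!is.matrix(z) || nrow(z) != length(x) || ncol(z) != length(y))
    stop("z must be a length(x) by length(y) matrix on a rectangular grid")
  if (any(diff(x) <= 0) || any(diff(y) <= 0) || any(c(x, y) <= 0))
    stop("grid levels must be positive and strictly increasing")
  lx <- log(x); ly <- log(y)
  xo <- seq(lx[1], lx[length(lx)], length.out = n)
  yo <- seq(ly[1], ly[length(ly)], length.out = n)
  interp1 <- function(grid, at) {
    i <- pmin(pmax(findInterval(at, grid), 1L), length(grid) - 1L)
    list(i = i, f = (at - grid[i]) / (grid[i + 1] - grid[i]))
  }
  ax <- interp1(lx, xo); ay <- interp1(ly, yo)
  zo <- matrix(0, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      i <- ax$i[a]; j <- ay$i[b]; fx <- ax$f[a]; fy <- ay$f[b]
      zo[a, b] <- (1 - fx) * (1 - fy) * z[i, j] + fx * (1 - fy) * z[i + 1, j] +
        (1 - fx) * fy * z[i, j + 1] + fx * fy * z[i + 1, j + 1]
    }
  }
  list(x = exp(xo), y = exp(yo), z = zo)
}
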