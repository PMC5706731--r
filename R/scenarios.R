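# Scenario registry and multi-seed orchestration.  Each registered
# scenario is a named set of configuration overrides reproducing one of
# the standard manipulations of the model (STO removal, kinetics changes,
# synaptic-weight and input-bound sweeps, GC population scaling).

#' Scenario registry
#'
#' @return named list; each entry has `overrides` (config keys for
#'   [sim_config()]) and a one-line `description`.
#' @export
scenario_registry <- function() {
  list(
    control = list(overrides = list(),
      description = "default network: coherent ~32 Hz gamma under odor"),
    sto_removed = list(overrides = list(mc_variant = "cat"),
      description = "MC persistent Na+ replaced by ohmic cation current (no STOs)"),
    sto_fast = list(overrides = list(mc_variant = "fast"),
      description = "fast MC STO kinetics (~44 Hz intrinsic), default 18 ms GABA decay"),
    sto_fast_gaba3 = list(
      overrides = list(mc_variant = "fast", tau_decay_gaba = 3),
      description = "fast MC STOs with 3 ms GABA_A decay (gamma restored, faster)"),
    gaba3 = list(overrides = list(tau_decay_gaba = 3),
      description = "GC->MC GABA_A decay reduced to 3 ms"),
    gaba30 = list(overrides = list(tau_decay_gaba = 30),
      description = "GC->MC GABA_A decay increased to 30 ms"),
    gc_off = list(overrides = list(w_gc_mc = 0),
      description = "GC->MC inhibition blocked"),
    wgcmc3x = list(overrides = list(w_gc_mc = 6),
      description = "threefold GC->MC inhibitory weight"),
    wgcmc3x_pgc_half = list(overrides = list(w_gc_mc = 6, w_pgc_mc = 2),
      description = "threefold GC->MC weight with halved PGC->MC weight"),
    wmcgc8 = list(overrides = list(w_mc_gc = 8),
      description = "eightfold MC->GC excitatory weight"),
    wmcgc_half = list(overrides = list(w_mc_gc = 0.5),
      description = "halved MC->GC excitatory weight"),
    pgc_off = list(overrides = list(w_pgc_mc = 0),
      description = "PGC->MC feedforward inhibition removed"),
    pgc_half = list(overrides = list(w_pgc_mc = 2),
      description = "halved PGC->MC feedforward inhibition"),
    pgc_double = list(overrides = list(w_pgc_mc = 8),
      description = "doubled PGC->MC feedforward inhibition"),
    input_narrow = list(overrides = list(us_hi = 0.4),
      description = "upper odor-input bound lowered to 0.4 nA"),
    input_strong = list(overrides = list(us_lo = 0.8),
      description = "lower odor-input bound raised to 0.8 nA"),
    ngc_225 = list(overrides = list(n_gc = 225),
      description = "225 granule cells (15x15), GABA conductance renormalized"),
    ngc_400 = list(overrides = list(n_gc = 400),
      description = "400 granule cells (20x20), GABA conductance renormalized"))
}

#' Analyze one recording into summary metrics
#'
#' Computes the standard per-run metrics: population mean firing rates,
#' sLFP spectral peak frequency and power, and the MC spike-phase
#' synchronization index.
#'
#' @param rec a [recording()].
#' @param window_ms analysis window (ms); defaults to the window stored
#'   in the recording's configuration.
#' @return one-row data.frame with `mc_rate_hz`, `gc_rate_hz`,
#'   `pgc_rate_hz`, `peak_freq_hz`, `peak_power`, `dominant`, `si`,
#'   `n_mc_spikes`.
#' @export
analyze_recording <- function(rec, window_ms = NULL) {
  if (is.null(window_ms)) {
    cfg <- rec$meta$cfg
    window_ms <- c(cfg$t_orn_ms + cfg$analysis_skip_ms, cfg$duration_ms)
  }
  lf <- compute_slfp(rec, window_ms = window_ms)
  spec <- power_spectrum(lf$slfp, lf$fs_hz)
  pk <- peak_frequency(spec)
  rates <- lapply(rec$spikes, rates_and_histograms, window_ms = window_ms)
  peaks <- slfp_peak_times(lf)$peak_t_ms
  mc_sp <- unlist(lapply(rec$spikes$mc, function(s)
    s[s >= window_ms[1] & s < window_ms[2]]), use.names = FALSE)
  ph <- spike_phases(mc_sp, peaks)
  data.frame(
    mc_rate_hz = rates$mc$mean_rate_hz,
    gc_rate_hz = if (length(rec$spikes$gc)) rates$gc$mean_rate_hz else NA,
    pgc_rate_hz = if (length(rec$spikes$pgc)) rates$pgc$mean_rate_hz else NA,
    peak_freq_hz = if (pk$dominant) pk$freq_hz else NA,
    peak_power = pk$power,
    dominant = pk$dominant,
    si = synchronization_index(ph),
    n_mc_spikes = length(mc_sp))
}

#' Run a scenario over a seed set
#'
#' Runs the engine once per seed (connectivity held fixed across seeds
#' by default, noise/odor varying), analyzes each run, and returns
#' per-seed metrics with seed-averaged summaries.
#'
#' @param name registered scenario name (see [scenario_registry()]), or
#'   `NULL` to use `overrides` alone.
#' @param overrides additional configuration overrides (applied on top of
#'   the scenario's).
#' @param seeds integer vector of master seeds (default 1:10).
#' @param quick use the reduced-cost profile (5 seeds unless `seeds` is
#'   given explicitly); the full profile uses 10 seeds and a longer odor
#'   epoch.
#' @param out_dir optional directory: per-seed summary table and resolved
#'   configuration are written there as plain text.
#' @return object of class `scenario_result`: list with `name`,
#'   `per_seed` (data.frame), `summary` (mean and sd per metric),
#'   `cfg`.
#' @export
run_scenario <- function(name = "control", overrides = list(),
                         seeds = NULL, quick = TRUE, out_dir = NULL) {
  reg <- scenario_registry()
  base <- list()
  if (!is.null(name)) {
    if (!name %in% names(reg)) {
      stop("unknown scenario `", name, "`; registered: ",
           paste(names(reg), collapse = ", "))
    }
    base <- reg[[name]]$overrides
  }
  ov <- utils::modifyList(base, overrides)
  prof <- if (quick) list(duration_ms = 2000, dt_ms = 0.02) else
    list(duration_ms = 3000, dt_ms = 0.01)
  cfg <- do.call(sim_config, utils::modifyList(prof, ov))
  if (is.null(seeds)) seeds <- if (quick) 1:5 else 1:10
  if (!length(seeds)) stop("`seeds` must be non-empty")

  rows <- vector("list", length(seeds))
  for (k in seq_along(seeds)) {
    row <- tryCatch({
      rec <- run_simulation(cfg, seed = seeds[k])
      cbind(data.frame(seed = seeds[k]), analyze_recording(rec))
    }, error = function(e) {
      warning(sprintf("seed %d failed and was excluded: %s",
                      seeds[k], conditionMessage(e)))
      NULL
    })
    rows[[k]] <- row
  }
  per_seed <- do.call(rbind, rows)
  if (is.null(per_seed) || !nrow(per_seed)) stop("all seeds failed")
  num <- per_seed[, setdiff(names(per_seed), c("seed", "dominant"))]
  summary <- data.frame(
    metric = names(num),
    mean = vapply(num, function(x) mean(x, na.rm = TRUE), numeric(1)),
    sd = vapply(num, function(x) stats::sd(x, na.rm = TRUE), numeric(1)))
  out <- list(name = name %||% "custom", per_seed = per_seed,
              summary = summary, cfg = cfg, seeds = seeds)
  class(out) <- "scenario_result"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(per_seed,
                     file.path(out_dir, paste0(out$name, "_per_seed.csv")),
                     row.names = FALSE)
    yaml::write_yaml(unclass(cfg),
                     file.path(out_dir, paste0(out$name, "_config.yaml")))
  }
  out
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s (%d seeds)\n", x$name,
              nrow(x$per_seed)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Summary value of a scenario result
#'
#' @param res a `scenario_result`.
#' @param metric metric name (e.g. `"peak_freq_hz"`).
#' @return seed-averaged value.
#' @export
scenario_mean <- function(res, metric) {
  res$summary$mean[match(metric, res$summary$metric)]
}

#' Sweep one configuration key over a set of values
#'
#' Runs a base scenario once per value, holding the connectivity seed
#' fixed across values so the sweep isolates the manipulated parameter.
#'
#' @param param documented configuration key (e.g. `"tau_decay_gaba"`).
#' @param values numeric vector of values.
#' @param name base scenario.
#' @param seeds seed set per value.
#' @param quick profile switch as in [run_scenario()].
#' @param connectivity_seed fixed wiring seed (default: derived from the
#'   first seed).
#' @return data.frame with one row per (value, metric summary), plus the
#'   per-value oscillation index normalized to the first value's seed
#'   set.
#' @export
sweep_parameter <- function(param, values, name = "control",
                            seeds = NULL, quick = TRUE,
                            connectivity_seed = NULL) {
  if (!param %in% names(sim_defaults())) {
    stop("unknown configuration key `", param, "`")
  }
  if (!length(values)) {
    return(data.frame(value = numeric(0), mc_rate_hz = numeric(0),
                      gc_rate_hz = numeric(0), peak_freq_hz = numeric(0),
                      si = numeric(0), oi = numeric(0)))
  }
  if (!is.numeric(values)) stop("`", param, "` requires numeric values")
  if (is.null(seeds)) seeds <- if (quick) 1:5 else 1:10
  if (is.null(connectivity_seed)) {
    connectivity_seed <- derive_seeds(seeds[1])$connectivity
  }
  res <- lapply(values, function(v) {
    ov <- stats::setNames(list(v, connectivity_seed),
                          c(param, "connectivity_seed"))
    run_scenario(name, overrides = ov, seeds = seeds, quick = quick)
  })
  ref_powers <- res[[1]]$per_seed$peak_power
  out <- do.call(rbind, lapply(seq_along(values), function(i) {
    r <- res[[i]]
    data.frame(
      value = values[i],
      mc_rate_hz = scenario_mean(r, "mc_rate_hz"),
      gc_rate_hz = scenario_mean(r, "gc_rate_hz"),
      pgc_rate_hz = scenario_mean(r, "pgc_rate_hz"),
      peak_freq_hz = scenario_mean(r, "peak_freq_hz"),
      si = scenario_mean(r, "si"),
      oi = oscillation_index(r$per_seed$peak_power, ref_powers))
  }))
  names(out)[1] <- param
  attr(out, "results") <- res
  out
}
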