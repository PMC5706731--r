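# Simulation driver: resolves a configuration, builds the cell and
# synapse arrays, hands them to the compiled integrator, and wraps the
# output in a `recording`.

sim_defaults <- function() {
  list(
    # network geometry / wiring
    n_mc = 25L, n_gc = 100L, p = 0.3, size_mm = 1,
    # synaptic weights (dimensionless) and GABA_A decay constants (ms)
    w_mc_gc = 1, w_mc_pgc = 1, w_gc_mc = 2, w_pgc_mc = 4,
    tau_decay_gaba = 18, tau_decay_gaba_pgc = 18,
    mg_mm = 1,
    # odor drive (nA bounds of the uniform draws) and timing (ms)
    us_lo = 0.2, us_hi = 1.0, u0_lo = 0.1, u0_hi = 0.2,
    r = 100, t_orn_ms = 500,
    duration_ms = 2000, analysis_skip_ms = 200,
    # Poisson background excitation (per cell); sparse large events on
    # MCs decorrelate spiking without much mean drive
    bg_rate_hz = 14, bg_g_ns = 3.5, bg_g_ns_gc = 0.06, bg_g_ns_pgc = 0.08,
    # cell-model variant: "default", "fast" (fast STO kinetics),
    # "cat" (persistent Na+ replaced by ohmic cation current)
    mc_variant = "default",
    # numerics
    dt_ms = 0.02, sample_ms = 0.5,
    record_gaba = FALSE,
    connectivity_seed = NULL,
    params_path = NULL)
}

#' Resolve a simulation configuration
#'
#' Merges overrides into the documented default configuration; unknown
#' keys are an error.  See the package vignette for the meaning, units
#' and provenance of every key.
#'
#' @param ... named overrides of the default keys (e.g.
#'   `tau_decay_gaba = 3`, `w_gc_mc = 0`, `n_gc = 225`).
#' @return a named list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- sim_defaults()
  ov <- list(...)
  if (length(ov) && (is.null(names(ov)) || any(names(ov) == ""))) {
    stop("configuration overrides must be named")
  }
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  }
  cfg[names(ov)] <- ov
  num_keys <- setdiff(names(cfg), c("mc_variant", "connectivity_seed",
                                    "params_path", "record_gaba"))
  for (k in num_keys) {
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1 || is.na(cfg[[k]])) {
      stop(sprintf("configuration key `%s` must be a single number", k))
    }
  }
  if (!cfg$mc_variant %in% c("default", "fast", "cat")) {
    stop("`mc_variant` must be one of \"default\", \"fast\", \"cat\"")
  }
  if (cfg$dt_ms <= 0) stop("`dt_ms` must be > 0")
  class(cfg) <- c("sim_config", "list")
  cfg
}

# Concatenate per-cell compartment tables into flat engine arrays.
# `cells` is a list of ob_cell objects; returns global arrays plus the
# per-cell compartment offsets.
flatten_cells <- function(cells) {
  ncomps <- vapply(cells, function(cl) nrow(cl$comps), integer(1))
  offset <- cumsum(c(0L, ncomps[-length(ncomps)]))
  tabs <- vector("list", length(cells))
  for (k in seq_along(cells)) {
    cc <- cells[[k]]$comps
    parent0 <- ifelse(cc$parent == 0L, -1L, cc$parent - 1L + offset[k])
    tabs[[k]] <- data.frame(
      parent = parent0,
      g_ax = ifelse(is.na(cc$g_ax_us), 0, cc$g_ax_us),
      cm = cc$cm_nf,
      gna = cc$g_na_us, gkdr = cc$g_kdr_us, gl = cc$g_leak_us,
      gnap = cc$g_nap_us, gks = cc$g_ks_us, gadp = cc$g_adp_us,
      gcat = cc$g_cat_us,
      el = cc$e_leak,
      tau_ks = cells[[k]]$chan$tau_ks_ms,
      tau_adp = cells[[k]]$chan$tau_adp_ms)
  }
  flat <- do.call(rbind, tabs)
  soma <- offset + vapply(cells, function(cl) cl$soma, integer(1)) - 1L
  list(flat = flat, offset = offset, soma_comp = soma)
}

empty_state <- function() {
  list(syn_pre = integer(0), syn_post = integer(0), syn_kind = integer(0),
       syn_g = numeric(0), syn_e = numeric(0),
       syn_alpha = numeric(0), syn_beta = numeric(0),
       gaba_col = integer(0), n_gaba_cols = 0L, mg_mm = 1,
       bg_t = numeric(0), bg_comp = integer(0), bg_g = numeric(0),
       bg_tau = 5.5,
       osn_comp = integer(0), osn_u0 = numeric(0), osn_us = numeric(0),
       osn_gain = numeric(0), osn_r = 100, osn_torn = 0,
       ic_comp = integer(0), ic_amp = numeric(0),
       ic_start = numeric(0), ic_stop = numeric(0),
       spike_thresh = 0, refract = 2)
}

state_from_flat <- function(fl, chan) {
  st <- empty_state()
  st$parent <- as.integer(fl$flat$parent)
  st$g_ax <- fl$flat$g_ax
  st$cm <- fl$flat$cm
  st$gna <- fl$flat$gna; st$gkdr <- fl$flat$gkdr; st$gl <- fl$flat$gl
  st$gnap <- fl$flat$gnap; st$gks <- fl$flat$gks; st$gadp <- fl$flat$gadp
  st$gcat <- fl$flat$gcat
  st$el <- fl$flat$el; st$tau_ks <- fl$flat$tau_ks
  st$tau_adp <- fl$flat$tau_adp
  st$ena <- chan$e_na; st$ek <- chan$e_k; st$ecat <- chan$e_cat
  st$nap_theta <- chan$nap_theta; st$nap_sigma <- chan$nap_sigma
  st$ks_theta <- chan$ks_theta; st$ks_sigma <- chan$ks_sigma
  st$adp_theta <- chan$adp_theta; st$adp_sigma <- chan$adp_sigma
  st$eadp <- chan$e_adp %||% -62
  st$soma_comp <- as.integer(fl$soma_comp)
  st
}

#' Simulate an isolated cell
#'
#' Runs one cell (no synapses) with an optional somatic current step and
#' optional background events; the calibration entry point for the
#' isolated-cell anchors (subthreshold-oscillation frequency, f-I curve,
#' dendritic propagation).
#'
#' @param cell an `ob_cell` (e.g. [build_mitral_cell()]).
#' @param i_inj_na injected current amplitude (nA).
#' @param duration_ms simulation length (ms).
#' @param dt_ms timestep (ms).
#' @param inj_comp compartment receiving the injection (name or index;
#'   default the soma).
#' @param inj_start_ms,inj_stop_ms injection window (ms).
#' @param record compartment names (or indices) whose voltage to record.
#' @param sample_ms trace sampling interval (ms).
#' @return list with `t_ms`, `v` (samples x recorded compartments, with
#'   column names), `spikes` (somatic spike times, ms).
#' @export
simulate_cell <- function(cell, i_inj_na = 0, duration_ms = 2000,
                          dt_ms = 0.02, inj_comp = NULL,
                          inj_start_ms = 0, inj_stop_ms = Inf,
                          record = "soma", sample_ms = 0.5) {
  fl <- flatten_cells(list(cell))
  st <- state_from_flat(fl, cell$chan)
  comp_idx <- function(x) {
    if (is.numeric(x)) return(as.integer(x))
    i <- match(x, cell$comps$name)
    if (any(is.na(i))) stop("unknown compartment: ", x[is.na(i)][1])
    i
  }
  if (is.null(inj_comp)) inj_comp <- cell$soma
  if (i_inj_na != 0) {
    st$ic_comp <- comp_idx(inj_comp) - 1L
    st$ic_amp <- i_inj_na
    st$ic_start <- inj_start_ms
    st$ic_stop <- min(inj_stop_ms, duration_ms)
  }
  rec <- comp_idx(record)
  st$rec_comp <- rec - 1L
  st$dt <- dt_ms; st$t_total <- duration_ms; st$sample_ms <- sample_ms
  out <- ob_engine_run(st)
  v <- out$v
  colnames(v) <- cell$comps$name[rec]
  list(t_ms = out$t, v = v, spikes = out$spike_t)
}

#' Run a network simulation
#'
#' Builds the default olfactory-bulb network (25 MC/PGC columns, 100 GCs
#' unless overridden), wires it with the configured connectivity seed,
#' draws the odor pattern and Poisson background trains from seed
#' sub-streams, and integrates the full system.
#'
#' @param cfg a [sim_config()].
#' @param seed master seed; odor and background sub-streams derive from
#'   it.  Connectivity uses `cfg$connectivity_seed` when set (so sweeps
#'   can hold the wiring fixed), otherwise its own sub-stream of `seed`.
#' @param record_dend optional data.frame (`mc`, `comp`) of extra MC
#'   dendritic compartments to record.
#' @return a [recording()].
#' @export
run_simulation <- function(cfg = sim_config(), seed = 1,
                           record_dend = NULL) {
  seeds <- derive_seeds(seed)
  params <- default_cell_params(cfg$params_path)

  mc_proto <- build_mitral_cell(params)
  if (cfg$mc_variant == "fast") mc_proto <- set_fast_sto_kinetics(mc_proto)
  if (cfg$mc_variant == "cat") mc_proto <- substitute_nap_with_cat(mc_proto)
  pgc_proto <- build_periglomerular_cell(params)

  ncfg <- network_config(n_mc = cfg$n_mc, n_gc = cfg$n_gc, p = cfg$p,
                         size_mm = cfg$size_mm, seed = seed)
  conn_seed <- cfg$connectivity_seed %||% seeds$connectivity
  conn <- build_connections(ncfg, seed = conn_seed)

  n_mc <- ncfg$n_mc; n_gc <- ncfg$n_gc; n_pgc <- ncfg$n_pgc
  spines_per_gc <- tabulate(conn$mc_gc$gc, nbins = n_gc)
  cells <- c(
    replicate(n_mc, mc_proto, simplify = FALSE),
    replicate(n_pgc, pgc_proto, simplify = FALSE),
    lapply(spines_per_gc, function(k) build_granule_cell(params, k)))
  fl <- flatten_cells(cells)
  st <- state_from_flat(fl, mc_proto$chan)
  st$mg_mm <- cfg$mg_mm

  # global compartment indices (1-based here; engine takes 0-based)
  mc_off <- fl$offset[seq_len(n_mc)]
  pgc_off <- fl$offset[n_mc + seq_len(n_pgc)]
  gc_off <- fl$offset[n_mc + n_pgc + seq_len(n_gc)]
  mc_soma <- mc_off + 1L
  mc_tuft <- mc_off + 2L
  pgc_body <- pgc_off + 1L
  pgc_spine <- pgc_off + 2L
  gc_body <- gc_off + 1L
  # spine k of GC g is compartment gc_off[g] + 1 + k
  gc_spine_of_contact <- gc_off[conn$mc_gc$gc] + 1L + conn$mc_gc$spine
  mc_dend_of_contact <- mc_off[conn$mc_gc$mc] + 2L + conn$mc_gc$comp

  ns <- 1e-3 # nS -> uS
  tau <- function(x) 1 / x
  add_syn <- function(st, pre, post, g_ns, e, tr, td, kind, gaba_col = NULL) {
    n <- length(pre)
    st$syn_pre <- c(st$syn_pre, pre - 1L)
    st$syn_post <- c(st$syn_post, post - 1L)
    st$syn_g <- c(st$syn_g, rep_len(g_ns * ns, n))
    st$syn_e <- c(st$syn_e, rep_len(e, n))
    st$syn_alpha <- c(st$syn_alpha, rep_len(tau(tr), n))
    st$syn_beta <- c(st$syn_beta, rep_len(tau(td), n))
    st$syn_kind <- c(st$syn_kind, rep_len(kind, n))
    st$gaba_col <- c(st$gaba_col,
                     if (is.null(gaba_col)) rep_len(-1L, n) else gaba_col - 1L)
    st
  }
  # MC -> GC excitation (AMPA + NMDA) onto the spine; graded GABA back
  # onto the hosting dendritic compartment (conductance renormalized for
  # GC population size).
  st <- add_syn(st, mc_dend_of_contact, gc_spine_of_contact,
                cfg$w_mc_gc * 2, 0, 1, 5.5, 0L)
  st <- add_syn(st, mc_dend_of_contact, gc_spine_of_contact,
                cfg$w_mc_gc * 1, 0, 52, 343, 1L)
  st <- add_syn(st, gc_spine_of_contact, mc_dend_of_contact,
                cfg$w_gc_mc * 2 * ncfg$gc_inh_scale, -80,
                1.25, cfg$tau_decay_gaba, 2L,
                gaba_col = if (cfg$record_gaba) conn$mc_gc$mc else NULL)
  # MC tuft <-> PGC spine reciprocal pair
  st <- add_syn(st, mc_tuft, pgc_spine, cfg$w_mc_pgc * 2, 0, 1, 5.5, 0L)
  st <- add_syn(st, mc_tuft, pgc_spine, cfg$w_mc_pgc * 1, 0, 52, 343, 1L)
  st <- add_syn(st, pgc_spine, mc_tuft, cfg$w_pgc_mc * 2, -80,
                1.25, cfg$tau_decay_gaba_pgc, 2L)
  st$n_gaba_cols <- if (cfg$record_gaba) n_mc else 0L

  # odor drive: common per-column timecourse into MC tuft and PGC spine
  set.seed(seeds$odor)
  odor <- draw_odor_pattern(n_mc, cfg$us_lo, cfg$us_hi, cfg$u0_lo,
                            cfg$u0_hi, cfg$r, cfg$t_orn_ms)
  st$osn_comp <- c(mc_tuft, pgc_spine) - 1L
  st$osn_u0 <- rep(odor$u0_na, 2)
  st$osn_us <- rep(odor$us_na, 2)
  st$osn_gain <- c(rep(1, n_mc), rep(pgc_proto$osn_gain, n_pgc))
  st$osn_r <- cfg$r
  st$osn_torn <- cfg$t_orn_ms

  # uncorrelated Poisson background onto every cell body/soma
  set.seed(seeds$noise)
  n_cells <- n_mc + n_pgc + n_gc
  trains <- poisson_background(cfg$bg_rate_hz, cfg$duration_ms, n_cells)
  target <- c(mc_soma, pgc_body, gc_body)
  gj <- c(rep(cfg$bg_g_ns, n_mc), rep(cfg$bg_g_ns_pgc, n_pgc),
          rep(cfg$bg_g_ns_gc, n_gc)) * ns
  bg <- data.frame(
    t = unlist(trains, use.names = FALSE),
    comp = rep(target, lengths(trains)) - 1L,
    g = rep(gj, lengths(trains)))
  bg <- bg[order(bg$t), , drop = FALSE]
  st$bg_t <- bg$t; st$bg_comp <- as.integer(bg$comp); st$bg_g <- bg$g

  rec_extra <- integer(0)
  extra_names <- character(0)
  if (!is.null(record_dend)) {
    rec_extra <- mc_off[record_dend$mc] + 2L + record_dend$comp
    extra_names <- sprintf("mc%03d_dend%d", record_dend$mc,
                           record_dend$comp)
  }
  st$rec_comp <- c(mc_soma, rec_extra) - 1L
  st$dt <- cfg$dt_ms; st$t_total <- cfg$duration_ms
  st$sample_ms <- cfg$sample_ms

  out <- ob_engine_run(st)

  pop_of_cell <- rep(c("mc", "pgc", "gc"), c(n_mc, n_pgc, n_gc))
  id_in_pop <- c(seq_len(n_mc), seq_len(n_pgc), seq_len(n_gc))
  spikes <- list(mc = vector("list", n_mc), gc = vector("list", n_gc),
                 pgc = vector("list", n_pgc))
  for (pop in names(spikes)) {
    spikes[[pop]] <- lapply(spikes[[pop]], function(x) numeric(0))
  }
  if (length(out$spike_cell)) {
    pp <- pop_of_cell[out$spike_cell]
    ii <- id_in_pop[out$spike_cell]
    for (pop in c("mc", "gc", "pgc")) {
      sel <- pp == pop
      sp <- split(out$spike_t[sel], ii[sel])
      for (nm in names(sp)) spikes[[pop]][[as.integer(nm)]] <- sp[[nm]]
    }
  }
  v_mc <- out$v[, seq_len(n_mc), drop = FALSE]
  extra <- NULL
  if (length(rec_extra)) {
    extra <- out$v[, n_mc + seq_along(rec_extra), drop = FALSE]
    colnames(extra) <- extra_names
  }
  recording(
    spikes = spikes, v_mc = v_mc, t_ms = out$t, dt_ms = cfg$dt_ms,
    gaba_g = if (cfg$record_gaba) out$gaba else NULL,
    extra = extra,
    meta = list(seed = seed, connectivity_seed = conn_seed,
                odor = odor, cfg = unclass(cfg)))
}

#' Default analysis window of a configured run
#'
#' The odor epoch minus the initial transient (`analysis_skip_ms` after
#' odor onset) up to the end of the simulation.
#'
#' @param cfg a [sim_config()].
#' @return two-element numeric window (ms).
#' @export
analysis_window <- function(cfg) {
  c(cfg$t_orn_ms + cfg$analysis_skip_ms, cfg$duration_ms)
}
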