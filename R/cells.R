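# Compartmental cell models.  Each cell is a small tree of cylindrical
# compartments carrying Hodgkin-Huxley-type channels: transient Na+ and
# delayed-rectifier K+ for spiking, leak, and -- in mitral cells -- a
# persistent Na+ current (instantaneous sigmoidal activation) and a slow
# K+ current (first-order activation, time constant tau_KS) whose
# interplay generates the ~29 Hz subthreshold oscillations.

area_cm2 <- function(l_um, diam_um) pi * diam_um * l_um * 1e-8

# axial conductance (uS) between centers of two cylindrical compartments
axial_g_us <- function(l1_um, d1_um, l2_um, d2_um, ra_ohm_cm) {
  half_r <- function(l_um, d_um) {
    ra_ohm_cm * (l_um / 2 * 1e-4) / (pi * (d_um / 2 * 1e-4)^2)
  }
  1e6 / (half_r(l1_um, d1_um) + half_r(l2_um, d2_um))
}

comp_row <- function(name, spec, parent, g_ax_us = NA_real_) {
  a <- area_cm2(spec$l_um, spec$diam_um)
  data.frame(
    name = name, parent = parent,
    l_um = spec$l_um, diam_um = spec$diam_um,
    area_cm2 = a,
    cm_nf = spec$cm_uf_cm2 * a * 1000,
    g_na_us = (spec$g_na %||% 0) * a * 1000,
    g_kdr_us = (spec$g_kdr %||% 0) * a * 1000,
    g_leak_us = spec$g_leak * a * 1000,
    g_nap_us = (spec$g_nap %||% 0) * a * 1000,
    g_ks_us = (spec$g_ks %||% 0) * a * 1000,
    g_adp_us = (spec$g_adp %||% 0) * a * 1000,
    g_cat_us = 0,
    e_leak = spec$e_leak,
    g_ax_us = g_ax_us,
    stringsAsFactors = FALSE)
}

#' Build a mitral cell
#'
#' Soma, apical tuft, and a lateral dendrite of exactly seven
#' compartments spanning 500 um.  The soma carries the persistent-sodium
#' and slow-potassium currents that generate subthreshold oscillations;
#' soma and dendrites carry spiking Na+/K+ channels dense enough for
#' full-amplitude action-potential propagation to the distal compartment
#' in under a millisecond.
#'
#' @param params parameter set from [default_cell_params()].
#' @return object of class `c("mitral_cell", "ob_cell")` with a
#'   compartment table (`$comps`; soma = row 1, tuft = row 2, dendrite =
#'   rows 3..9), channel constants (`$chan`) and the STO kinetics variant
#'   (`$sto_variant`).
#' @export
build_mitral_cell <- function(params = default_cell_params()) {
  validate_cell_params(params)
  p <- params$mc
  sh <- params$shared
  if (p$ks$tau_ms <= 0) stop("invalid parameter `mc$ks$tau_ms`: must be > 0")
  n_d <- p$dend$n_comp %||% 7
  dspec <- p$dend
  dspec$l_um <- p$dend$total_l_um / n_d
  rows <- list(
    comp_row("soma", p$soma, parent = 0L),
    comp_row("tuft", p$tuft, parent = 1L,
             axial_g_us(p$soma$l_um, p$soma$diam_um,
                        p$tuft$l_um, p$tuft$diam_um, sh$ra_ohm_cm)))
  for (k in seq_len(n_d)) {
    par <- if (k == 1) 1L else 2L + (k - 1L)
    par_spec <- if (k == 1) p$soma else dspec
    rows[[2 + k]] <- comp_row(
      sprintf("dend%d", k), dspec, parent = par,
      axial_g_us(par_spec$l_um, par_spec$diam_um,
                 dspec$l_um, dspec$diam_um, sh$ra_ohm_cm))
  }
  comps <- do.call(rbind, rows)
  cell <- list(
    kind = "mc",
    comps = comps,
    chan = list(
      e_na = sh$e_na, e_k = sh$e_k, e_cat = 0,
      nap_theta = p$nap$theta_mv, nap_sigma = p$nap$sigma_mv,
      ks_theta = p$ks$theta_mv, ks_sigma = p$ks$sigma_mv,
      tau_ks_ms = p$ks$tau_ms,
      adp_theta = p$adp$theta_mv %||% -25,
      adp_sigma = p$adp$sigma_mv %||% 5,
      tau_adp_ms = p$adp$tau_ms %||% 100,
      e_adp = p$adp$e_mv %||% -62),
    soma = 1L, tuft = 2L, dend = 2L + seq_len(n_d),
    sto_variant = "default",
    base_g = list(g_nap_us = comps$g_nap_us, g_ks_us = comps$g_ks_us,
                  tau_ks_ms = p$ks$tau_ms))
  class(cell) <- c("mitral_cell", "ob_cell")
  cell
}

small_cell <- function(kind, body, spine, sh, n_spines, extras = list()) {
  rows <- list(comp_row("body", body, parent = 0L))
  for (k in seq_len(n_spines)) {
    r <- comp_row(sprintf("spine%d", k), spine, parent = 1L,
                  g_ax_us = spine$neck_g_ns / 1000)
    rows[[1 + k]] <- r
  }
  comps <- do.call(rbind, rows)
  cell <- c(list(
    kind = kind, comps = comps,
    chan = list(e_na = sh$e_na, e_k = sh$e_k, e_cat = 0,
                nap_theta = 0, nap_sigma = 1, ks_theta = 0, ks_sigma = 1,
                tau_ks_ms = 10, adp_theta = -25, adp_sigma = 5,
                tau_adp_ms = 100, e_adp = -62),
    soma = 1L, spines = if (n_spines) 1L + seq_len(n_spines) else integer(0)),
    extras)
  class(cell) <- c(paste0(kind, "_cell"), "ob_cell")
  cell
}

#' Build a granule cell
#'
#' A compact body plus one spine compartment per mitral-cell contact;
#' each spine hosts the excitatory postsynaptic site and the graded
#' GABAergic presynaptic site of one reciprocal dendrodendritic synapse.
#'
#' @param params parameter set from [default_cell_params()].
#' @param n_spines number of reciprocal contacts (spines).
#' @return object of class `c("gc_cell", "ob_cell")`.
#' @export
build_granule_cell <- function(params = default_cell_params(), n_spines = 0) {
  validate_cell_params(params)
  small_cell("gc", params$gc$body, params$gc$spine, params$shared, n_spines)
}

#' Build a periglomerular cell
#'
#' A body plus the single spine forming the reciprocal synapse with the
#' column's mitral-cell tuft.  The spine also receives a share of the
#' column's OSN input (`params$pgc$osn_gain`).
#'
#' @param params parameter set from [default_cell_params()].
#' @return object of class `c("pgc_cell", "ob_cell")`.
#' @export
build_periglomerular_cell <- function(params = default_cell_params()) {
  validate_cell_params(params)
  small_cell("pgc", params$pgc$body, params$pgc$spine, params$shared, 1,
             extras = list(osn_gain = params$pgc$osn_gain %||% 1))
}

#' Cation-substitution parameters
#'
#' Ohmic cation current `I_CAT = g_CAT (v - E_CAT)` used to replace the
#' persistent sodium current when ablating subthreshold oscillations,
#' with the conductance chosen to preserve the cell's firing rates.
#'
#' @param g_cat_ms_cm2 conductance density (mS/cm2; default 0.26).
#' @param e_cat_mv reversal potential (mV; default 0).
#' @export
cation_substitution <- function(g_cat_ms_cm2 = 0.26, e_cat_mv = 0) {
  if (g_cat_ms_cm2 < 0) stop("invalid parameter `g_cat_ms_cm2`: must be >= 0")
  structure(list(g_cat_ms_cm2 = g_cat_ms_cm2, e_cat_mv = e_cat_mv),
            class = "cation_substitution")
}

#' Replace the persistent sodium current with an ohmic cation current
#'
#' Sets the I_NaP density to zero in every compartment that carried it and
#' adds `I_CAT = g_CAT (v - E_CAT)` there, removing the subthreshold
#' oscillation mechanism while (with the default `g_CAT`) preserving the
#' f-I curve within ~15%.
#'
#' @param cell a [build_mitral_cell()] result.
#' @param sub a [cation_substitution()].
#' @return the modified cell.
#' @export
substitute_nap_with_cat <- function(cell, sub = cation_substitution()) {
  if (!inherits(cell, "mitral_cell")) stop("`cell` must be a mitral cell")
  if (any(cell$comps$g_cat_us > 0)) {
    stop("cation substitution already applied")
  }
  if (all(cell$comps$g_nap_us == 0)) stop("cell has no persistent sodium current")
  had <- cell$comps$g_nap_us > 0
  cell$comps$g_cat_us[had] <- sub$g_cat_ms_cm2 * cell$comps$area_cm2[had] * 1000
  cell$comps$g_nap_us[had] <- 0
  cell$chan$e_cat <- sub$e_cat_mv
  cell$sto_variant <- "cat"
  cell
}

#' Speed up the subthreshold-oscillation kinetics
#'
#' Halves the slow-potassium activation time constant (10 ms -> 5 ms) and
#' scales the slow-potassium and persistent-sodium conductance densities
#' by 1.6 and 1.3 so that STO amplitude and firing rate are approximately
#' preserved while the intrinsic STO frequency rises from ~29 to ~44 Hz.
#'
#' @param cell a default-variant mitral cell.
#' @return the modified cell (`sto_variant == "fast"`).
#' @export
set_fast_sto_kinetics <- function(cell) {
  if (!inherits(cell, "mitral_cell")) stop("`cell` must be a mitral cell")
  if (cell$sto_variant != "default") {
    stop("fast STO kinetics require a default-variant cell")
  }
  cell$chan$tau_ks_ms <- cell$chan$tau_ks_ms / 2
  cell$comps$g_ks_us <- cell$comps$g_ks_us * 1.6
  cell$comps$g_nap_us <- cell$comps$g_nap_us * 1.3
  cell$sto_variant <- "fast"
  cell
}

#' Revert to the default subthreshold-oscillation kinetics
#'
#' @param cell a fast-variant mitral cell.
#' @return the cell with its stored default STO parameters restored.
#' @export
set_default_sto_kinetics <- function(cell) {
  if (!inherits(cell, "mitral_cell")) stop("`cell` must be a mitral cell")
  cell$comps$g_nap_us <- cell$base_g$g_nap_us
  cell$comps$g_ks_us <- cell$base_g$g_ks_us
  cell$chan$tau_ks_ms <- cell$base_g$tau_ks_ms
  cell$sto_variant <- "default"
  cell
}
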