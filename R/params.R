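# Loading and validating the plain-text (YAML) cell parameter file.

#' Load the calibrated cell parameter set
#'
#' Reads the versioned key-value parameter file shipped with the package
#' (or a user-supplied file with the same schema) and validates it.
#' Units: lengths um, conductance densities mS/cm2, potentials mV, time
#' constants ms, specific capacitance uF/cm2.
#'
#' @param path parameter file; defaults to the packaged
#'   `extdata/cell_params.yaml`.
#' @return nested list with elements `shared`, `mc`, `gc`, `pgc`.
#' @export
default_cell_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cell_params.yaml", package = "obgamma")
  }
  p <- yaml::read_yaml(path)
  validate_cell_params(p)
  p
}

#' Validate a cell parameter set
#'
#' Checks schema completeness and sign constraints; errors name the
#' offending field.
#'
#' @param p parameter list as returned by [default_cell_params()].
#' @return the validated list, invisibly.
#' @export
validate_cell_params <- function(p) {
  need <- function(x, fields, where) {
    for (f in fields) {
      if (is.null(x[[f]])) stop(sprintf("missing parameter `%s` in %s", f, where))
    }
  }
  need(p, c("shared", "mc", "gc", "pgc"), "parameter file")
  need(p$shared, c("e_na", "e_k", "ra_ohm_cm"), "shared")
  need(p$mc, c("soma", "tuft", "dend", "nap", "ks"), "mc")
  comp_fields <- c("l_um", "diam_um", "cm_uf_cm2", "g_leak", "e_leak")
  for (cname in c("soma", "tuft")) {
    need(p$mc[[cname]], comp_fields, paste0("mc$", cname))
  }
  need(p$mc$dend, c("n_comp", "total_l_um", setdiff(comp_fields, "l_um")),
       "mc$dend")
  if (p$mc$dend$n_comp != 7) stop("invalid parameter `mc$dend$n_comp`: must be 7")
  need(p$mc$ks, c("theta_mv", "sigma_mv", "tau_ms"), "mc$ks")
  need(p$mc$nap, c("theta_mv", "sigma_mv"), "mc$nap")
  if (p$mc$ks$tau_ms <= 0) stop("invalid parameter `mc$ks$tau_ms`: must be > 0")
  check_nonneg <- function(x, where) {
    for (f in grep("^g_", names(x), value = TRUE)) {
      if (x[[f]] < 0) {
        stop(sprintf("invalid parameter `%s$%s`: conductance density must be >= 0",
                     where, f))
      }
    }
    for (f in c("l_um", "diam_um", "cm_uf_cm2")) {
      if (!is.null(x[[f]]) && x[[f]] <= 0) {
        stop(sprintf("invalid parameter `%s$%s`: must be > 0", where, f))
      }
    }
  }
  check_nonneg(p$mc$soma, "mc$soma")
  check_nonneg(p$mc$tuft, "mc$tuft")
  check_nonneg(p$mc$dend, "mc$dend")
  check_nonneg(p$gc$body, "gc$body")
  check_nonneg(p$gc$spine, "gc$spine")
  check_nonneg(p$pgc$body, "pgc$body")
  check_nonneg(p$pgc$spine, "pgc$spine")
  invisible(p)
}
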