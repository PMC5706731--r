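# The `recording` container holds the output of one simulation run (real
# or surrogate): per-cell spike times, MC somatic voltage traces at a
# fixed sampling interval, and optional per-MC cumulative GABA_A
# conductance traces.

#' Construct a recording
#'
#' @param spikes named list with elements `mc`, `gc`, `pgc`, each a list
#'   of strictly increasing per-cell spike-time vectors (ms).
#' @param v_mc matrix of MC somatic voltages (samples x cells, mV).
#' @param t_ms sample times (ms), uniformly spaced.
#' @param dt_ms integration timestep used (ms).
#' @param gaba_g optional matrix (samples x MCs) of cumulative GC-mediated
#'   GABA_A conductance per MC (nS).
#' @param extra optional named list of additional traces.
#' @param meta metadata list (seed, config hash, scenario...).
#' @return object of class `recording`.
#' @export
recording <- function(spikes, v_mc, t_ms, dt_ms, gaba_g = NULL,
                      extra = NULL, meta = list()) {
  stopifnot(nrow(v_mc) == length(t_ms))
  for (pop in names(spikes)) {
    for (s in spikes[[pop]]) {
      if (length(s) > 1 && any(diff(s) <= 0)) {
        stop("spike times must be strictly increasing per cell")
      }
    }
  }
  out <- list(spikes = spikes, v_mc = v_mc, t_ms = t_ms, dt_ms = dt_ms,
              gaba_g = gaba_g, extra = extra, meta = meta)
  class(out) <- "recording"
  out
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "<recording> %d MCs / %d GCs / %d PGCs, %.0f ms @ %.3g ms sampling\n",
    length(x$spikes$mc), length(x$spikes$gc), length(x$spikes$pgc),
    max(x$t_ms), if (length(x$t_ms) > 1) diff(x$t_ms[1:2]) else NA))
  n_sp <- vapply(x$spikes, function(p) sum(lengths(p)), numeric(1))
  cat("  spikes:", paste(sprintf("%s=%d", names(n_sp), n_sp),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a recording as plain text
#'
#' Spike times go to `<dir>/spikes.tsv` (cell label, time); traces to
#' `<dir>/traces.tsv` (time plus one column per MC); metadata to
#' `<dir>/meta.yaml`.
#'
#' @param rec a `recording`.
#' @param dir output directory (created if needed).
#' @export
write_recording <- function(rec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- do.call(rbind, lapply(names(rec$spikes), function(pop) {
    sp <- rec$spikes[[pop]]
    if (!sum(lengths(sp))) return(NULL)
    data.frame(cell = rep(sprintf("%s%03d", pop, seq_along(sp)),
                          lengths(sp)),
               t_ms = unlist(sp, use.names = FALSE))
  }))
  if (is.null(rows)) rows <- data.frame(cell = character(), t_ms = numeric())
  utils::write.table(rows, file.path(dir, "spikes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr <- data.frame(t_ms = rec$t_ms, rec$v_mc)
  names(tr) <- c("t_ms", sprintf("mc%03d", seq_len(ncol(rec$v_mc))))
  utils::write.table(tr, file.path(dir, "traces.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  yaml::write_yaml(c(rec$meta, list(dt_ms = rec$dt_ms)),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname write_recording
#' @param n_cells named integer vector giving the population sizes used to
#'   reconstruct empty per-cell spike lists (defaults to the cells present
#'   in the files).
#' @export
read_recording <- function(dir, n_cells = NULL) {
  sp <- utils::read.table(file.path(dir, "spikes.tsv"), header = TRUE,
                          sep = "\t", colClasses = c("character", "numeric"))
  tr <- utils::read.table(file.path(dir, "traces.tsv"), header = TRUE,
                          sep = "\t")
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  pops <- c("mc", "gc", "pgc")
  if (is.null(n_cells)) {
    n_cells <- vapply(pops, function(p) {
      ids <- sp$cell[startsWith(sp$cell, p) &
                       !startsWith(sp$cell, if (p == "gc") "xxx" else "pgc") |
                       (p == "pgc" & startsWith(sp$cell, "pgc"))]
      if (p == "gc") ids <- sp$cell[grepl("^gc[0-9]+$", sp$cell)]
      if (p == "mc") ids <- sp$cell[grepl("^mc[0-9]+$", sp$cell)]
      if (p == "pgc") ids <- sp$cell[grepl("^pgc[0-9]+$", sp$cell)]
      if (!length(ids)) return(0L)
      max(as.integer(sub("^[a-z]+", "", ids)))
    }, integer(1))
    n_cells["mc"] <- max(n_cells["mc"], ncol(tr) - 1L)
  }
  spikes <- lapply(pops, function(p) {
    out <- vector("list", n_cells[[p]])
    pat <- sprintf("^%s[0-9]+$", p)
    rows <- sp[grepl(pat, sp$cell), , drop = FALSE]
    for (k in seq_len(n_cells[[p]])) {
      out[[k]] <- sort(rows$t_ms[rows$cell == sprintf("%s%03d", p, k)])
    }
    out
  })
  names(spikes) <- pops
  recording(spikes, as.matrix(tr[, -1, drop = FALSE]), tr$t_ms,
            dt_ms = meta$dt_ms %||% NA_real_, meta = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
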