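# Network geometry and wiring: mitral/periglomerular columns and granule
# cells are laid out on square grids over a 1 mm x 1 mm sheet wrapped onto
# a torus.  Each MC pairs with the PGC of its own column and connects
# reciprocally to a random subset of GCs (probability p); the dendritic
# compartment hosting each MC-GC contact is set by the toroidal distance
# between the MC soma and the GC.

#' Network configuration
#'
#' @param n_mc number of mitral cells (perfect square; default 25 = 5x5).
#' @param n_gc number of granule cells (perfect square; default 100 =
#'   10x10; the scaling variants use 225 and 400).
#' @param n_pgc number of periglomerular cells; must equal `n_mc` (one per
#'   column).
#' @param p MC-GC connection probability in [0, 1].
#' @param size_mm side length of the (square, toroidal) sheet in mm.
#' @param seed master seed; connectivity, odor and background-noise
#'   sub-streams are derived from it (see [derive_seeds()]).
#' @return an object of class `network_config`.  The field
#'   `gc_inh_scale` carries the granule-population conductance
#'   renormalization `100 / n_gc` applied to individual GC->MC synapses so
#'   the total inhibitory conductance per MC is independent of `n_gc`.
#' @export
network_config <- function(n_mc = 25, n_gc = 100, n_pgc = n_mc,
                           p = 0.3, size_mm = 1, seed = 1) {
  is_square <- function(n) {
    r <- round(sqrt(n))
    r * r == n
  }
  if (!is_square(n_mc)) stop("`n_mc` must be a perfect square")
  if (!is_square(n_gc)) stop("`n_gc` must be a perfect square")
  if (n_pgc != n_mc) stop("`n_pgc` must equal `n_mc` (one PGC per column)")
  if (p < 0 || p > 1) stop("`p` must lie in [0, 1]")
  cfg <- list(
    n_mc = as.integer(n_mc),
    n_gc = as.integer(n_gc),
    n_pgc = as.integer(n_pgc),
    p = p,
    size_mm = size_mm,
    seed = as.integer(seed),
    gc_inh_scale = 100 / n_gc)
  class(cfg) <- "network_config"
  cfg
}

#' Derive deterministic sub-stream seeds from a master seed
#'
#' Separate seeds for connectivity, odor draws and Poisson background let
#' parameter sweeps hold the wiring fixed while varying the noise.
#'
#' @param master master seed (integer).
#' @return named list with integer seeds `connectivity`, `odor`, `noise`.
#' @export
derive_seeds <- function(master) {
  master <- as.integer(master)
  list(connectivity = (master * 7L + 101L) %% 2147480000L,
       odor = (master * 7L + 102L) %% 2147480000L,
       noise = (master * 7L + 103L) %% 2147480000L)
}

#' Grid-to-linear index mapping
#'
#' `z = N * i + j + 1` for a cell in column `i`, row `j` of an `N x N`
#' grid (0-based grid indices, 1-based linear id).
#'
#' @param i,j 0-based column and row indices, `0 <= i, j < N`.
#' @param n grid dimension N.
#' @return 1-based linear id in `1..N^2`.
#' @export
flatten_index <- function(i, j, n) {
  if (any(i < 0 | i >= n) || any(j < 0 | j >= n)) {
    stop("grid indices out of range: need 0 <= i, j < n")
  }
  n * i + j + 1
}

#' Grid cell positions on the sheet
#'
#' Cell (i, j) of an `N x N` grid sits at `((i + 0.5)/N, (j + 0.5)/N)`
#' (scaled by the sheet size), i.e. equal spacing with no boundary cells
#' on the torus.
#'
#' @param n grid dimension.
#' @param size_mm sheet side length (mm).
#' @return data.frame with columns `id`, `i`, `j`, `x_mm`, `y_mm`, ordered
#'   by linear id.
#' @export
grid_positions <- function(n, size_mm = 1) {
  ij <- expand.grid(j = 0:(n - 1), i = 0:(n - 1))
  out <- data.frame(
    id = flatten_index(ij$i, ij$j, n),
    i = ij$i, j = ij$j,
    x_mm = (ij$i + 0.5) / n * size_mm,
    y_mm = (ij$j + 0.5) / n * size_mm)
  out[order(out$id), , drop = FALSE]
}

#' Toroidal (wraparound) Euclidean distance
#'
#' @param a,b numeric length-2 positions (mm) or two-column matrices.
#' @param size_mm torus side length (mm).
#' @return distance(s) in mm; at most `size_mm * sqrt(2) / 2`.
#' @export
toroidal_distance <- function(a, b, size_mm = 1) {
  a <- matrix(a, ncol = 2)
  b <- matrix(b, ncol = 2)
  d <- abs(a - b)
  d <- pmin(d, size_mm - d)
  sqrt(d[, 1]^2 + d[, 2]^2)
}

#' Map soma-to-granule-cell distance to a lateral dendrite compartment
#'
#' The seven-compartment MC lateral dendrite spans 500 um; the compartment
#' hosting a dendrodendritic contact is chosen by partitioning the
#' possible toroidal distances `[0, d_max]` into seven equal bins
#' (proximal compartment 1 to distal compartment 7).  The mapping is
#' deterministic and monotone non-decreasing in distance.
#'
#' @param d_mm distance between the MC soma and the GC (mm); vectorized.
#' @param d_max_mm maximal possible toroidal distance (default
#'   `sqrt(2)/2` for the unit torus).
#' @param n_comp number of dendritic compartments (default 7).
#' @return integer compartment index in `1..n_comp`.
#' @export
dendritic_compartment_for_distance <- function(d_mm,
                                               d_max_mm = sqrt(2) / 2,
                                               n_comp = 7) {
  if (any(d_mm < 0) || any(d_mm > d_max_mm + 1e-12)) {
    stop("distance out of range: need 0 <= d <= d_max")
  }
  pmin(n_comp, floor(d_mm / d_max_mm * n_comp) + 1L)
}

#' Build the reciprocal connection table
#'
#' Every MC-GC pair is connected independently with probability `p`; each
#' realized contact is reciprocal (one excitatory MC->GC site and one
#' graded inhibitory GC->MC site at the same dendritic
#' compartment / granule spine).  Each MC additionally pairs with the PGC
#' of its own column.  Deterministic given the connectivity seed.
#'
#' @param cfg a [network_config()].
#' @param seed connectivity seed; defaults to the connectivity sub-stream
#'   of `cfg$seed`.
#' @return a list of class `connection_table` with elements
#'   \describe{
#'     \item{mc_gc}{data.frame `mc`, `gc`, `comp` (1..7), `distance_mm`,
#'       `spine` (index of the contact among the GC's spines).}
#'     \item{mc_pgc}{data.frame `mc`, `pgc` (same-column pairs).}
#'     \item{mc_pos, gc_pos}{grid position tables.}
#'   }
#' @export
build_connections <- function(cfg, seed = NULL) {
  if (is.null(seed)) seed <- derive_seeds(cfg$seed)$connectivity
  n_mc_side <- as.integer(round(sqrt(cfg$n_mc)))
  n_gc_side <- as.integer(round(sqrt(cfg$n_gc)))
  mc_pos <- grid_positions(n_mc_side, cfg$size_mm)
  gc_pos <- grid_positions(n_gc_side, cfg$size_mm)
  d_max <- cfg$size_mm * sqrt(2) / 2

  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    expr
  }

  conn <- withr_seed({
    hit <- matrix(stats::runif(cfg$n_mc * cfg$n_gc) < cfg$p,
                  nrow = cfg$n_mc, ncol = cfg$n_gc)
    which(hit, arr.ind = TRUE)
  })
  mc_id <- as.integer(conn[, 1])
  gc_id <- as.integer(conn[, 2])
  ord <- order(mc_id, gc_id)
  mc_id <- mc_id[ord]
  gc_id <- gc_id[ord]
  d <- toroidal_distance(
    cbind(mc_pos$x_mm[mc_id], mc_pos$y_mm[mc_id]),
    cbind(gc_pos$x_mm[gc_id], gc_pos$y_mm[gc_id]),
    cfg$size_mm)
  comp <- dendritic_compartment_for_distance(d, d_max)
  # spine index: running count of contacts per GC, in table order
  spine <- stats::ave(seq_along(gc_id), gc_id, FUN = seq_along)
  out <- list(
    mc_gc = data.frame(mc = mc_id, gc = gc_id, comp = as.integer(comp),
                       distance_mm = d, spine = as.integer(spine)),
    mc_pgc = data.frame(mc = seq_len(cfg$n_mc), pgc = seq_len(cfg$n_mc)),
    mc_pos = mc_pos, gc_pos = gc_pos,
    seed = seed, cfg = cfg)
  class(out) <- "connection_table"
  out
}

#' Granule-population inhibitory conductance renormalization
#'
#' When the GC population is scaled up, individual GC->MC maximal
#' conductances are scaled by `100 / n_gc` so that the expected total
#' GABA_A conductance received by each MC stays constant.
#'
#' @param cfg a [network_config()] (or an `n_gc` count).
#' @return scale factor (1 at the default population of 100 GCs).
#' @export
scale_inhibition_for_size <- function(cfg) {
  n_gc <- if (inherits(cfg, "network_config")) cfg$n_gc else cfg
  if (n_gc <= 0) stop("`n_gc` must be > 0")
  100 / n_gc
}

#' Write / read a connection table as plain text
#'
#' One MC-GC contact per row (`mc_id, gc_id, compartment, distance_mm`),
#' tab-separated, for reproducibility audits.
#'
#' @param conn a `connection_table`.
#' @param path output file.
#' @export
write_connection_table <- function(conn, path) {
  utils::write.table(
    conn$mc_gc[, c("mc", "gc", "comp", "distance_mm")],
    file = path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_connection_table
#' @export
read_connection_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}
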