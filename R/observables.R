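#' Adhesive-interaction neighbour graph
#'
#' Undirected graph connecting every pair of cells whose separation is below
#' the interaction cutoff `rc` — the pairs that exert forces on each other.
#' The mean degree of this graph is the "connectivity" observable reported
#' along a trajectory.
#'
#' @param state A `tissue_state`.
#' @param params A [potential_params()]; only `rc` is used.
#' @return A `neighbor_graph`: list with `edges` (tibble `i`, `j`, `i < j`)
#'   and `degree` (integer per cell).
#' @export
neighbor_graph <- function(state, params) {
  d <- as.matrix(stats::dist(state$positions))
  adj <- d < params$rc
  diag(adj) <- FALSE
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  structure(
    list(edges = tibble(i = as.integer(idx[, 1]), j = as.integer(idx[, 2])),
         degree = as.integer(rowSums(adj))),
    class = "neighbor_graph"
  )
}

min_pair_separation <- function(state) {
  min(stats::dist(state$positions))
}

#' Total potential energy of a tissue state
#'
#' Sum over unordered cell pairs of the pair potential whose negative
#' gradient is [pair_force()], plus each cell's repulsive cavity potential.
#' With zero noise and a static cavity the overdamped dynamics performs
#' gradient descent on this quantity, so it is non-increasing per step for
#' stable time steps — the property used to validate the integrator.
#'
#' @inheritParams neighbor_graph
#' @return Scalar energy.
#' @export
total_energy <- function(state, params) {
  d <- stats::dist(state$positions)
  if (any(d < 1e-12)) stop_degenerate_pair()
  e_pairs <- sum(pair_potential(as.vector(d), params))
  dc <- sqrt(colSums((t(state$positions) - state$cavity_center)^2))
  if (state$cavity_rest > 0 && any(dc <= 0)) stop_degenerate_pair()
  inside <- dc < state$cavity_rest
  e_cav <- if (any(inside)) {
    sum(pair_potential(dc[inside], params, rest_override = state$cavity_rest,
                       repulsive_only = TRUE))
  } else 0
  e_pairs + e_cav
}

#' Packing metrics from particle positions
#'
#' Bridges the simulator to the image-derived packing metrics: each non-fixed
#' cell is treated as a disc of radius `cell_radius`, the discs are
#' rasterised into an annular region around the cavity centre, and
#' [packing_index()] / intercellular space are computed from pixel counts
#' (overlapping discs are not double-counted in the occupied area).
#'
#' By default the annulus adapts to the band actually occupied by the free
#' cells (from the innermost to the outermost free-cell radius, padded by one
#' cell radius), so compression of the band into a thinner annulus raises the
#' packing index just as confluence does in tissue sections.
#'
#' @param state A `tissue_state`.
#' @param cell_radius Disc radius per cell (length units); the default in
#'   [run_simulation()] is `r0 / 2`, so discs at rest separation just touch.
#' @param band_annulus Optional numeric length-2 `c(r_inner, r_outer)` fixing
#'   the annulus; `NULL` adapts to the occupied band.
#' @param resolution Rasterisation resolution in pixels per length unit.
#' @return A one-row `packing_result` tibble (see [packing_index()]).
#' @export
packing_from_positions <- function(state, cell_radius,
                                   band_annulus = NULL, resolution = 10) {
  if (cell_radius <= 0) {
    abort("`cell_radius` must be > 0.", class = "blastopack_domain_error")
  }
  free <- state$positions[!state$fixed, , drop = FALSE]
  if (nrow(free) == 0) {
    abort("No non-fixed cells to rasterise.", class = "blastopack_domain_error")
  }
  ctr <- state$cavity_center
  radial <- sqrt((free[, 1] - ctr[1])^2 + (free[, 2] - ctr[2])^2)
  if (is.null(band_annulus)) {
    band_annulus <- c(max(min(radial) - cell_radius, 0),
                      max(radial) + cell_radius)
  }
  r_in <- band_annulus[1]; r_out <- band_annulus[2]
  if (r_out <= r_in) {
    abort("Empty annulus: outer radius must exceed inner radius.",
          class = "blastopack_domain_error")
  }

  # pixel grid over the annulus bounding box, pixel centres at half-steps
  px <- 1 / resolution
  gx <- seq(ctr[1] - r_out + px / 2, ctr[1] + r_out, by = px)
  gy <- seq(ctr[2] - r_out + px / 2, ctr[2] + r_out, by = px)
  nx <- length(gx); ny <- length(gy)
  rad2 <- outer((gx - ctr[1])^2, (gy - ctr[2])^2, "+")
  in_annulus <- rad2 >= r_in^2 & rad2 <= r_out^2
  total_px <- sum(in_annulus)
  if (total_px == 0) {
    abort("Empty annulus: no pixels at this resolution.",
          class = "blastopack_domain_error")
  }

  occupied <- matrix(FALSE, nx, ny)
  areas <- numeric(nrow(free))
  r2 <- cell_radius^2
  for (c_i in seq_len(nrow(free))) {
    xi <- findInterval(c(free[c_i, 1] - cell_radius,
                         free[c_i, 1] + cell_radius), gx)
    yi <- findInterval(c(free[c_i, 2] - cell_radius,
                         free[c_i, 2] + cell_radius), gy)
    xs <- max(1L, xi[1]):min(nx, xi[2] + 1L)
    ys <- max(1L, yi[1]):min(ny, yi[2] + 1L)
    dx2 <- (gx[xs] - free[c_i, 1])^2
    dy2 <- (gy[ys] - free[c_i, 2])^2
    disc <- outer(dx2, dy2, "+") <= r2
    hit <- disc & in_annulus[xs, ys, drop = FALSE]
    areas[c_i] <- sum(hit)
    occupied[xs, ys] <- occupied[xs, ys] | hit
  }

  res <- packing_index(areas, total_px)
  # intercellular space from the disc union, not the per-cell sum
  res$intercellular_space_pct <-
    100 * (1 - sum(occupied & in_annulus) / total_px)
  res
}
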