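#' Simulation configuration
#'
#' Geometry, schedule and noise settings for a cavity-expansion run. The
#' defaults are the package's reference conditions: a six-ring circular band
#' of ~320 cells at unit spacing between radii 6 and 11, the outermost ring
#' fixed (the stiff vitelline membrane), and a central repulsive cavity whose
#' rest size grows linearly from 5.5 to a cap of 10.2 over 5,000 steps of
#' `dt = 0.01`, after a 2,000-step stationary burn-in.
#'
#' @param n_rings Number of concentric cell rings (`>= 1`).
#' @param inner_radius,outer_radius Radial extent of the band (length units);
#'   `outer_radius > inner_radius` unless `n_rings == 1`.
#' @param cells_per_ring Optional integer vector (length 1 or `n_rings`)
#'   overriding the per-ring cell count; by default each ring is filled at
#'   arc spacing equal to the ring gap.
#' @param spacing Target spacing between cells (length units). Defaults to
#'   the ring gap `(outer_radius - inner_radius) / (n_rings - 1)`, or `1` for
#'   a single ring.
#' @param cavity_rest_initial Initial cavity rest size (length units); must
#'   be `< inner_radius` and `>= 0`.
#' @param cavity_growth_rate Linear growth rate of the cavity rest size
#'   (length units per time unit); `0` disables expansion.
#' @param cavity_rest_max Cap on the cavity rest size (length units).
#' @param dt Time step (`> 0`).
#' @param n_steps Number of update steps (`>= 0`).
#' @param noise_sigma Amplitude of the Gaussian positional noise (length
#'   units; `>= 0`).
#' @param noise_scaling Either `"sqrt_dt"` (Brownian scaling, default: the
#'   per-step kick is `noise_sigma * sqrt(dt)`, invariant to `dt`
#'   refinement) or `"dt"` (kick `noise_sigma * dt`).
#' @param relax_steps Number of noiseless, static-cavity burn-in steps run
#'   before recording starts, so observables are measured relative to a
#'   mechanically relaxed band rather than the artificial uniform lattice.
#' @param seed Integer seed; every run is deterministic given its seed.
#' @param stride Snapshot/observable recording interval in steps.
#'
#' @return A `tissue_config` object (named list).
#' @export
tissue_config <- function(n_rings = 6, inner_radius = 6, outer_radius = 11,
                          cells_per_ring = NULL, spacing = NULL,
                          cavity_rest_initial = 5.5,
                          cavity_growth_rate = 0.12,
                          cavity_rest_max = 10.2,
                          dt = 0.01, n_steps = 5000,
                          noise_sigma = 0.05,
                          noise_scaling = c("sqrt_dt", "dt"),
                          relax_steps = 2000L,
                          seed = 1L, stride = 100L) {
  bad <- function(field, why) {
    abort(sprintf("Invalid configuration: `%s` %s.", field, why),
          class = "blastopack_config_error")
  }
  if (n_rings < 1) bad("n_rings", "must be >= 1")
  if (inner_radius <= 0) bad("inner_radius", "must be > 0")
  if (n_rings > 1 && outer_radius <= inner_radius) {
    bad("outer_radius", "must exceed inner_radius")
  }
  if (cavity_rest_initial < 0) bad("cavity_rest_initial", "must be >= 0")
  if (cavity_rest_initial >= inner_radius) {
    bad("cavity_rest_initial", "must be < inner_radius")
  }
  if (dt <= 0) bad("dt", "must be > 0")
  if (n_steps < 0) bad("n_steps", "must be >= 0")
  if (noise_sigma < 0) bad("noise_sigma", "must be >= 0")
  if (cavity_growth_rate < 0) bad("cavity_growth_rate", "must be >= 0")
  if (n_rings > 1 && cavity_rest_max >= outer_radius) {
    bad("cavity_rest_max", "must be < outer_radius (the membrane)")
  }
  if (stride < 1) bad("stride", "must be >= 1")
  if (relax_steps < 0) bad("relax_steps", "must be >= 0")
  if (!is.null(cells_per_ring)) {
    if (!length(cells_per_ring) %in% c(1L, n_rings) || any(cells_per_ring < 1)) {
      bad("cells_per_ring", "must be positive, of length 1 or n_rings")
    }
  }
  if (is.null(spacing)) {
    spacing <- if (n_rings > 1) (outer_radius - inner_radius) / (n_rings - 1) else 1
  }
  if (spacing <= 0) bad("spacing", "must be > 0")
  structure(
    list(n_rings = as.integer(n_rings), inner_radius = inner_radius,
         outer_radius = outer_radius, cells_per_ring = cells_per_ring,
         spacing = spacing, cavity_rest_initial = cavity_rest_initial,
         cavity_growth_rate = cavity_growth_rate,
         cavity_rest_max = cavity_rest_max, dt = dt,
         n_steps = as.integer(n_steps), noise_sigma = noise_sigma,
         noise_scaling = match.arg(noise_scaling),
         relax_steps = as.integer(relax_steps), seed = as.integer(seed),
         stride = as.integer(stride)),
    class = "tissue_config"
  )
}

#' Initialise the tissue state
#'
#' Places cells on concentric rings between `inner_radius` and
#' `outer_radius` with near-uniform arc spacing (alternate rings are
#' staggered by half a cell so neighbouring rings interlock). All and only
#' the outermost-ring cells are flagged fixed; the cavity sits at the band
#' centroid with rest size `cavity_rest_initial`.
#'
#' @param config A [tissue_config()] object.
#' @return A `tissue_state`: list with `positions` (n x 2 matrix), `fixed`
#'   (logical), `ring` (integer), `cavity_center`, `cavity_rest`, `time`.
#' @export
init_tissue <- function(config) {
  stopifnot(inherits(config, "tissue_config"))
  radii <- if (config$n_rings == 1) {
    config$inner_radius
  } else {
    seq(config$inner_radius, config$outer_radius, length.out = config$n_rings)
  }
  counts <- if (!is.null(config$cells_per_ring)) {
    rep_len(as.integer(config$cells_per_ring), config$n_rings)
  } else {
    pmax(3L, as.integer(round(2 * pi * radii / config$spacing)))
  }
  pos <- vector("list", config$n_rings)
  for (k in seq_len(config$n_rings)) {
    n_k <- counts[k]
    offset <- if (k %% 2 == 0) pi / n_k else 0
    theta <- 2 * pi * (seq_len(n_k) - 1) / n_k + offset
    pos[[k]] <- cbind(radii[k] * cos(theta), radii[k] * sin(theta))
  }
  positions <- do.call(rbind, pos)
  colnames(positions) <- c("x", "y")
  ring <- rep(seq_len(config$n_rings), counts)
  structure(
    list(positions = positions,
         fixed = ring == config$n_rings,
         ring = ring,
         cavity_center = c(0, 0),
         cavity_rest = config$cavity_rest_initial,
         time = 0),
    class = "tissue_state"
  )
}

#' @export
as_tibble.tissue_state <- function(x, ...) {
  pos <- x$positions
  ring <- x$ring
  fixed <- x$fixed
  tibble(cell = seq_len(nrow(pos)),
         x = pos[, 1], y = pos[, 2],
         ring = ring, fixed = fixed)
}

#' @export
print.tissue_state <- function(x, ...) {
  cat(sprintf("<tissue_state> %d cells (%d fixed), t = %.4g, cavity_rest = %.4g\n",
              nrow(x$positions), sum(x$fixed), x$time, x$cavity_rest))
  invisible(x)
}

# Pairwise separation matrix with coincidence check; diagonal set to `diag_fill`.
pair_distances <- function(positions, diag_fill = Inf) {
  dx <- outer(positions[, 1], positions[, 1], "-")
  dy <- outer(positions[, 2], positions[, 2], "-")
  d <- sqrt(dx * dx + dy * dy)
  diag(d) <- Inf
  if (any(d < 1e-12)) {
    idx <- which(d < 1e-12, arr.ind = TRUE)[1, ]
    stop_degenerate_pair(idx)
  }
  diag(d) <- diag_fill
  list(dx = dx, dy = dy, d = d)
}

#' Net force on every cell
#'
#' Sums the pairwise anharmonic forces from all other cells plus the cavity's
#' repulsion, for every cell. Forces on fixed cells are computed (and
#' reported) but those cells are never displaced by [step_tissue()].
#' Pair forces are antisymmetric by construction.
#'
#' @param state A `tissue_state`.
#' @param params A [potential_params()] object.
#' @return n x 2 matrix of force vectors.
#' @export
net_forces <- function(state, params) {
  p <- pair_distances(state$positions, diag_fill = params$rc)
  fmag <- matrix(pair_force(as.vector(p$d), params), nrow = nrow(p$d))
  # unit vectors point from j to i, so positive fmag pushes i away from j
  inv_d <- 1 / p$d
  fx <- rowSums(fmag * p$dx * inv_d)
  fy <- rowSums(fmag * p$dy * inv_d)

  dcx <- state$positions[, 1] - state$cavity_center[1]
  dcy <- state$positions[, 2] - state$cavity_center[2]
  dc <- sqrt(dcx * dcx + dcy * dcy)
  if (state$cavity_rest > 0 && any(dc <= 0)) {
    stop_degenerate_pair(which(dc <= 0))
  }
  inside <- dc < state$cavity_rest
  if (any(inside)) {
    fc <- pair_force(dc[inside], params, rest_override = state$cavity_rest,
                     repulsive_only = TRUE)
    fx[inside] <- fx[inside] + fc * dcx[inside] / dc[inside]
    fy[inside] <- fy[inside] + fc * dcy[inside] / dc[inside]
  }
  cbind(fx, fy, deparse.level = 0)
}

#' Advance the cavity rest size by one step
#'
#' Linear growth schedule: `cavity_rest + cavity_growth_rate * dt`, capped at
#' `cavity_rest_max`.
#'
#' @param cavity_rest Current rest size (`>= 0`).
#' @param config A [tissue_config()].
#' @return Updated rest size.
#' @export
grow_cavity <- function(cavity_rest, config) {
  min(cavity_rest + config$cavity_growth_rate * config$dt,
      config$cavity_rest_max)
}

#' One overdamped update step
#'
#' First-order (overdamped) dynamics with mobility absorbed into `dt`:
#' non-fixed cells move by `dt * F + kick * eta` where `eta` is standard
#' bivariate Gaussian noise and `kick` is `noise_sigma * sqrt(dt)` (default
#' Brownian scaling) or `noise_sigma * dt`. Fixed cells never move. The
#' cavity rest size is advanced by [grow_cavity()] and time by `dt`. Noise is
#' drawn from R's global RNG; [run_simulation()] seeds it per run.
#'
#' @inheritParams net_forces
#' @param config A [tissue_config()].
#' @return The updated `tissue_state`.
#' @export
step_tissue <- function(state, params, config) {
  forces <- net_forces(state, params)
  disp <- config$dt * forces
  if (config$noise_sigma > 0) {
    kick <- if (config$noise_scaling == "sqrt_dt") {
      config$noise_sigma * sqrt(config$dt)
    } else {
      config$noise_sigma * config$dt
    }
    disp <- disp + kick * matrix(rnorm(2 * nrow(disp)), ncol = 2)
  }
  disp[state$fixed, ] <- 0
  state$positions <- state$positions + disp
  state$cavity_rest <- grow_cavity(state$cavity_rest, config)
  state$time <- state$time + config$dt
  state
}

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Run a cavity-expansion simulation
#'
#' Integrates the overdamped dynamics for `config$n_steps` steps, recording a
#' snapshot and observables (packing index, mean neighbour degree, minimum
#' pair separation, total potential energy) every `config$stride` steps and
#' at the final step. Runs are bit-reproducible given `config$seed`.
#'
#' @param config A [tissue_config()].
#' @param params A [potential_params()]; defaults to the reference potential.
#' @return A `trajectory`: list with `snapshots` (list of `tissue_state`),
#'   `observables` (tibble: `step`, `time`, `cavity_rest`, `packing_index`,
#'   `mean_degree`, `min_separation`, `energy`), `config`, `params`, `seed`.
#' @examples
#' cfg <- tissue_config(n_rings = 3, inner_radius = 3, outer_radius = 5,
#'                      cavity_rest_initial = 2.5, n_steps = 50,
#'                      noise_sigma = 0)
#' traj <- run_simulation(cfg)
#' tidy(traj)
#' @export
run_simulation <- function(config, params = potential_params()) {
  stopifnot(inherits(config, "tissue_config"))
  with_seed(config$seed, {
    state <- init_tissue(config)
    if (config$relax_steps > 0) {
      # burn-in: equilibrate the artificial lattice under the run's own
      # dynamics (including its noise) with a static cavity, then reset the
      # clock, so observables start from a stationary band
      relax_cfg <- config
      relax_cfg$cavity_growth_rate <- 0
      for (i in seq_len(config$relax_steps)) {
        state <- step_tissue(state, params, relax_cfg)
      }
      state$time <- 0
    }
    record_steps <- unique(c(seq(0L, config$n_steps, by = config$stride),
                             config$n_steps))
    snapshots <- vector("list", length(record_steps))
    obs <- vector("list", length(record_steps))
    rec <- 1L
    observe <- function(state, step) {
      # packing is measured over the band region available to the cells:
      # between the cavity boundary and the fixed membrane ring
      pk <- packing_from_positions(
        state, cell_radius = params$r0 / 2,
        band_annulus = c(state$cavity_rest, config$outer_radius))
      ng <- neighbor_graph(state, params)
      tibble(step = step, time = state$time, cavity_rest = state$cavity_rest,
             packing_index = pk$packing_index,
             mean_degree = mean(ng$degree),
             min_separation = min_pair_separation(state),
             energy = total_energy(state, params))
    }
    snapshots[[rec]] <- state
    obs[[rec]] <- observe(state, 0L)
    for (step in seq_len(config$n_steps)) {
      state <- step_tissue(state, params, config)
      if (any(!is.finite(state$positions))) {
        abort(sprintf("Integration failure: non-finite coordinate at step %d.",
                      step),
              class = "blastopack_integration_failure")
      }
      if (step %in% record_steps) {
        rec <- rec + 1L
        snapshots[[rec]] <- state
        obs[[rec]] <- observe(state, step)
      }
    }
    structure(
      list(snapshots = snapshots,
           observables = dplyr::bind_rows(obs),
           config = config, params = params, seed = config$seed),
      class = "trajectory"
    )
  })
}

#' @export
print.trajectory <- function(x, ...) {
  n <- nrow(x$snapshots[[1]]$positions)
  cat(sprintf("<trajectory> %d cells, %d steps (dt = %g), %d snapshots, seed %d\n",
              n, x$config$n_steps, x$config$dt, length(x$snapshots), x$seed))
  print(utils::tail(x$observables, 3))
  invisible(x)
}
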