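#' Construct a labelled multi-channel image
#'
#' Container pairing a pixel array with optional cell/nucleus label masks and
#' ground-truth metadata (populated by the synthetic generators).
#'
#' @param channels Numeric array `h x w x c` (or a matrix, promoted to one
#'   channel).
#' @param cell_mask,nucleus_mask Optional integer label matrices
#'   (0 = background) matching the spatial dimensions.
#' @param pixel_size Optional physical pixel size (length units / pixel).
#' @param truth Optional ground-truth metadata (list or tibble).
#' @return A `labeled_image` object.
#' @export
labeled_image <- function(channels, cell_mask = NULL, nucleus_mask = NULL,
                          pixel_size = NULL, truth = NULL) {
  if (is.matrix(channels)) channels <- array(channels, dim = c(dim(channels), 1))
  spatial <- dim(channels)[1:2]
  for (m in list(cell_mask, nucleus_mask)) {
    if (!is.null(m) && !identical(dim(m), spatial)) {
      abort("Mask dimensions must match the channel array.",
            class = "blastopack_domain_error")
    }
  }
  structure(list(channels = channels, cell_mask = cell_mask,
                 nucleus_mask = nucleus_mask, pixel_size = pixel_size,
                 truth = truth),
            class = "labeled_image")
}

#' @export
print.labeled_image <- function(x, ...) {
  d <- dim(x$channels)
  n_cells <- if (is.null(x$cell_mask)) NA_integer_ else max(x$cell_mask)
  cat(sprintf("<labeled_image> %d x %d px, %d channel(s), %s cells\n",
              d[1], d[2], d[3],
              ifelse(is.na(n_cells), "no labelled", n_cells)))
  invisible(x)
}

disc_pixels <- function(n_row, n_col, cx, cy, radius) {
  rows <- max(1L, floor(cx - radius)):min(n_row, ceiling(cx + radius))
  cols <- max(1L, floor(cy - radius)):min(n_col, ceiling(cy + radius))
  d2 <- outer((rows - cx)^2, (cols - cy)^2, "+")
  idx <- which(d2 <= radius^2, arr.ind = TRUE)
  cbind(rows[idx[, 1]], cols[idx[, 2]])
}

place_centers <- function(size, n_cells, cell_radius,
                          placement, retry_budget = 1e4) {
  margin <- cell_radius + 1
  lo <- margin; hi <- size - margin
  if (hi < lo) {
    abort("Image too small for the requested cell radius.",
          class = "blastopack_placement_error")
  }
  if (placement == "jittered_grid") {
    pitch <- 2 * cell_radius + 3
    coords <- seq(lo, hi, by = pitch)
    grid <- expand.grid(cx = coords, cy = coords)
    if (nrow(grid) < n_cells) {
      abort(sprintf(
        "Infeasible density: grid holds %d cells, %d requested.",
        nrow(grid), n_cells), class = "blastopack_placement_error")
    }
    pick <- grid[sample.int(nrow(grid), n_cells), ]
    cbind(pick$cx + runif(n_cells, -1, 1), pick$cy + runif(n_cells, -1, 1))
  } else {
    centers <- matrix(NA_real_, n_cells, 2)
    placed <- 0L
    tries <- 0L
    min_sep2 <- (2 * cell_radius + 1)^2
    while (placed < n_cells && tries < retry_budget) {
      tries <- tries + 1L
      cand <- runif(2, lo, hi)
      ok <- placed == 0L || all(
        (centers[seq_len(placed), 1] - cand[1])^2 +
          (centers[seq_len(placed), 2] - cand[2])^2 >= min_sep2)
      if (ok) {
        placed <- placed + 1L
        centers[placed, ] <- cand
      }
    }
    if (placed < n_cells) {
      abort(sprintf(
        "Infeasible density: placed %d of %d cells within the retry budget.",
        placed, n_cells), class = "blastopack_placement_error")
    }
    centers
  }
}

#' Synthesise a two-channel cell image with known ground truth
#'
#' Emulates a confocal field of disc-like cells: channel 1 is a nuclear stain
#' (bright nucleus discs), channel 2 a protein stain whose per-cell
#' integrated signal is partitioned between nucleus and cytoplasm so that
#' their ratio equals `true_nc_ratio` exactly before noise. Intensity within
#' each compartment is uniform. Constant background and additive Gaussian
#' noise are applied last. Exact cell and nucleus label masks and a
#' ground-truth table are returned alongside the pixels, so every downstream
#' estimator can be scored against the generating parameters.
#'
#' @param size Image side length in pixels (square image).
#' @param n_cells Number of cells; `0` yields a pure-background image with
#'   empty masks.
#' @param cell_radius,nucleus_radius Disc radii in pixels;
#'   `nucleus_radius < cell_radius`.
#' @param true_nc_ratio Target nuclear/cytoplasmic integrated-signal ratio
#'   (`> 0`).
#' @param total_signal Per-cell integrated protein signal (intensity *
#'   pixels).
#' @param nuclear_level Nuclear-stain amplitude in channel 1.
#' @param background Constant background added to both channels.
#' @param noise_sigma Standard deviation of the additive Gaussian noise.
#' @param placement `"jittered_grid"` (cells on a jittered grid) or
#'   `"random"` (rejection-sampled non-overlapping positions, retry budget
#'   10^4).
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A [labeled_image()] whose `truth` is a tibble with one row per
#'   cell (`cell`, centre, pixel areas, `true_nc_ratio`, `total_signal`).
#' @examples
#' img <- make_cell_image(n_cells = 4, seed = 7)
#' quantify_nc(img)
#' @export
make_cell_image <- function(size = 256, n_cells = 20, cell_radius = 9,
                            nucleus_radius = 4, true_nc_ratio = 1,
                            total_signal = 1000, nuclear_level = 100,
                            background = 0, noise_sigma = 0,
                            placement = c("jittered_grid", "random"),
                            seed = 1L) {
  placement <- match.arg(placement)
  if (nucleus_radius >= cell_radius) {
    abort("`nucleus_radius` must be < `cell_radius`.",
          class = "blastopack_config_error")
  }
  if (true_nc_ratio <= 0) {
    abort("`true_nc_ratio` must be > 0.", class = "blastopack_config_error")
  }
  if (noise_sigma < 0) {
    abort("`noise_sigma` must be >= 0.", class = "blastopack_config_error")
  }
  with_seed(seed, {
    dapi <- matrix(0, size, size)
    prot <- matrix(0, size, size)
    cell_mask <- matrix(0L, size, size)
    nuc_mask <- matrix(0L, size, size)
    truth <- vector("list", n_cells)
    if (n_cells > 0) {
      centers <- place_centers(size, n_cells, cell_radius, placement)
      for (i in seq_len(n_cells)) {
        cpx <- disc_pixels(size, size, centers[i, 1], centers[i, 2],
                           cell_radius)
        npx <- disc_pixels(size, size, centers[i, 1], centers[i, 2],
                           nucleus_radius)
        cell_mask[cpx] <- i
        nuc_mask[npx] <- i
        a_cell <- nrow(cpx); a_nuc <- nrow(npx)
        a_cyto <- a_cell - a_nuc
        r <- true_nc_ratio
        sig_nuc <- total_signal * r / (1 + r)
        sig_cyto <- total_signal / (1 + r)
        prot[cpx] <- sig_cyto / a_cyto      # cytoplasm level first...
        prot[npx] <- sig_nuc / a_nuc        # ...nucleus overwrites inside
        dapi[npx] <- nuclear_level
        truth[[i]] <- tibble(cell = i, cx = centers[i, 1], cy = centers[i, 2],
                             area_cell = a_cell, area_nucleus = a_nuc,
                             true_nc_ratio = r, total_signal = total_signal)
      }
    }
    dapi <- dapi + background
    prot <- prot + background
    if (noise_sigma > 0) {
      dapi <- dapi + matrix(rnorm(size^2, sd = noise_sigma), size, size)
      prot <- prot + matrix(rnorm(size^2, sd = noise_sigma), size, size)
    }
    labeled_image(
      channels = array(c(dapi, prot), dim = c(size, size, 2)),
      cell_mask = cell_mask, nucleus_mask = nuc_mask,
      truth = dplyr::bind_rows(truth)
    )
  })
}

#' Synthesise a channel pair with a known correlation
#'
#' Two jointly Gaussian channels with population correlation `rho`, shifted
#' into the non-negative range — a calibration fixture for
#' [colocalization()]. With `rho = 1` the channels are affinely identical.
#'
#' @param rho Target population correlation in \[-1, 1\].
#' @param n_pixels Requested number of pixels; rounded up to fill a
#'   near-square image (the achieved count is in the result's `truth`).
#' @param mean_level,sd_level Marginal mean and standard deviation of each
#'   channel before the non-negativity shift.
#' @param seed Integer seed.
#' @return A two-channel [labeled_image()]; `truth` holds `rho` and
#'   `n_pixels`.
#' @export
make_coloc_pair <- function(rho, n_pixels = 1e5, mean_level = 100,
                            sd_level = 10, seed = 1L) {
  if (rho < -1 || rho > 1) {
    abort("`rho` must lie in [-1, 1].", class = "blastopack_config_error")
  }
  h <- max(1L, floor(sqrt(n_pixels)))
  w <- as.integer(ceiling(n_pixels / h))
  n <- h * w
  with_seed(seed, {
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    ch1 <- mean_level + sd_level * z1
    ch2 <- mean_level + sd_level * z2
    shift <- min(0, min(ch1), min(ch2))
    ch1 <- ch1 - shift; ch2 <- ch2 - shift
    labeled_image(
      channels = array(c(ch1, ch2), dim = c(h, w, 2)),
      truth = list(rho = rho, n_pixels = n)
    )
  })
}

#' Synthesise a grouped measurement table
#'
#' Draws per-group samples from a stated distribution family — the shape of
#' the per-embryo measurement tables behind the group-comparison statistics.
#' For the `"lognormal"` family `means`/`sds` are the target arithmetic mean
#' and standard deviation (log-scale parameters are derived); for
#' `"exponential"` the mean sets the rate and `sds` is ignored.
#'
#' @param sizes Integer vector of group sizes (each `>= 2`).
#' @param means,sds Numeric vectors (recycled to `length(sizes)`); `sds > 0`.
#' @param family `"normal"`, `"lognormal"` or `"exponential"`.
#' @param group_names Optional character names; defaults to `g1, g2, ...`.
#' @param seed Integer seed.
#' @return A tibble with columns `group` (factor) and `value`, CSV-ready.
#' @examples
#' make_group_table(c(10, 10), means = c(0, 1), sds = 1, seed = 3)
#' @export
make_group_table <- function(sizes, means = 0, sds = 1,
                             family = c("normal", "lognormal", "exponential"),
                             group_names = NULL, seed = 1L) {
  family <- match.arg(family)
  k <- length(sizes)
  if (any(sizes < 2)) {
    abort("Every group needs `size >= 2`.", class = "blastopack_config_error")
  }
  means <- rep_len(means, k)
  sds <- rep_len(sds, k)
  if (any(sds <= 0)) {
    abort("`sds` must be > 0.", class = "blastopack_config_error")
  }
  if (is.null(group_names)) group_names <- paste0("g", seq_len(k))
  with_seed(seed, {
    values <- purrr::pmap(list(sizes, means, sds), function(n, m, s) {
      switch(family,
        normal = rnorm(n, m, s),
        lognormal = {
          sdlog <- sqrt(log(1 + (s / m)^2))
          rlnorm_safe(n, log(m) - sdlog^2 / 2, sdlog)
        },
        exponential = stats::rexp(n, rate = 1 / m)
      )
    })
    tibble(
      group = factor(rep(group_names, sizes), levels = group_names),
      value = unlist(values)
    )
  })
}

rlnorm_safe <- function(n, meanlog, sdlog) {
  if (!is.finite(meanlog)) {
    abort("Lognormal family needs a positive mean.",
          class = "blastopack_config_error")
  }
  stats::rlnorm(n, meanlog, sdlog)
}
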