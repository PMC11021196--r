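# hand-built tissue states and brute-force oracles used across test files

make_state <- function(positions, fixed = NULL, cavity_center = c(0, 0),
                       cavity_rest = 0, time = 0) {
  positions <- matrix(positions, ncol = 2)
  colnames(positions) <- c("x", "y")
  n <- nrow(positions)
  structure(
    list(positions = positions,
         fixed = if (is.null(fixed)) rep(FALSE, n) else fixed,
         ring = rep(1L, n),
         cavity_center = cavity_center,
         cavity_rest = cavity_rest,
         time = time),
    class = "tissue_state"
  )
}

# independent scalar force formula, written out pairwise (never vectorised)
oracle_pair_force <- function(d, pp) {
  if (d < pp$r0) {
    pp$k_rep * ((pp$r0 - d) / pp$r0)^pp$p_rep
  } else if (d < pp$rc) {
    h2 <- ((pp$rc - pp$r0) / 2)^2
    -pp$k_adh * ((d - pp$r0) * (pp$rc - d) / h2)^pp$p_adh
  } else {
    0
  }
}

# O(n^2) double loop over all pairs plus the cavity, one cell at a time
oracle_net_forces <- function(state, pp) {
  n <- nrow(state$positions)
  out <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dvec <- state$positions[i, ] - state$positions[j, ]
      d <- sqrt(sum(dvec^2))
      out[i, ] <- out[i, ] + oracle_pair_force(d, pp) * dvec / d
    }
    dvec <- state$positions[i, ] - state$cavity_center
    d <- sqrt(sum(dvec^2))
    if (d < state$cavity_rest) {
      # cavity range is its rest size; penetration is in cell units
      f <- pp$k_rep * ((state$cavity_rest - d) / pp$r0)^pp$p_rep
      out[i, ] <- out[i, ] + f * dvec / d
    }
  }
  out
}

# random free-cell state with all pairs safely separated
random_state <- function(n, seed, cavity_rest = 0, box = 8) {
  set.seed(seed)
  repeat {
    pos <- matrix(runif(2 * n, -box, box), ncol = 2)
    if (min(dist(pos)) > 0.05 && all(sqrt(rowSums(pos^2)) > 0.05)) break
  }
  make_state(pos, cavity_rest = cavity_rest)
}

# reduced-size study configuration: same physics, smaller band; burn-in off
# by default for unit tests that only exercise mechanics or plumbing
reduced_config <- function(seed = 1L, growth_rate = 0.25, noise_sigma = 0.05,
                           n_steps = 1500L, relax_steps = 0L) {
  tissue_config(n_rings = 4, inner_radius = 4, outer_radius = 7,
                cavity_rest_initial = 3.5, cavity_growth_rate = growth_rate,
                cavity_rest_max = 6.5, dt = 0.01, n_steps = n_steps,
                noise_sigma = noise_sigma, seed = seed, stride = 250L,
                relax_steps = relax_steps)
}

# deterministic label image: rectangles of random labels on background
random_label_image <- function(seed, size = 40, n_obj = 6) {
  set.seed(seed)
  lab <- matrix(0L, size, size)
  for (k in seq_len(n_obj)) {
    w <- sample(3:8, 2)
    r0 <- sample(size - w[1], 1); c0 <- sample(size - w[2], 1)
    lab[r0:(r0 + w[1] - 1), c0:(c0 + w[2] - 1)] <- k
  }
  lab
}
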