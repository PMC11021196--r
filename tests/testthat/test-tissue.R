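test_that("initial layout places uniform rings with the outermost fixed", {
  # single ring of 8 cells: uniform angles, everything fixed
  cfg <- tissue_config(n_rings = 1, inner_radius = 1, outer_radius = 1,
                       cells_per_ring = 8, cavity_rest_initial = 0.5,
                       n_steps = 0)
  st <- init_tissue(cfg)
  expect_equal(nrow(st$positions), 8)
  expect_true(all(st$fixed))
  ang <- sort(atan2(st$positions[, 2], st$positions[, 1]) %% (2 * pi))
  expect_equal(ang, 2 * pi * (0:7) / 8, tolerance = 1e-12)
  expect_equal(sqrt(rowSums(st$positions^2)), rep(1, 8), tolerance = 1e-12)

  # three rings, explicit outer count: exactly that many fixed
  cfg3 <- tissue_config(n_rings = 3, inner_radius = 2, outer_radius = 4,
                        cells_per_ring = c(8, 16, 24),
                        cavity_rest_initial = 1, cavity_rest_max = 3,
                        n_steps = 0)
  st3 <- init_tissue(cfg3)
  expect_equal(sum(st3$fixed), 24)
  expect_equal(sum(!st3$fixed), 24)

  # default geometry: min pairwise distance >= 0.9 x intended spacing
  st_def <- init_tissue(tissue_config())
  expect_gte(min(dist(st_def$positions)), 0.9 * tissue_config()$spacing)
})

test_that("configuration errors name the offending field", {
  expect_error(tissue_config(dt = -1), "dt",
               class = "blastopack_config_error")
  expect_error(tissue_config(n_rings = 0), "n_rings",
               class = "blastopack_config_error")
  expect_error(tissue_config(outer_radius = 5, inner_radius = 6),
               "outer_radius", class = "blastopack_config_error")
  expect_error(tissue_config(cavity_rest_initial = 7, inner_radius = 6),
               "cavity_rest_initial", class = "blastopack_config_error")
  expect_error(tissue_config(noise_sigma = -0.1), "noise_sigma",
               class = "blastopack_config_error")
})

test_that("net forces match the all-pairs brute-force oracle", {
  pp <- potential_params()
  for (seed in 1:3) {
    st <- random_state(n = 20, seed = seed, cavity_rest = 3)
    expect_lt(max(abs(net_forces(st, pp) - oracle_net_forces(st, pp))), 1e-12)
  }
  # larger instance, no cavity contact
  st <- random_state(n = 80, seed = 9, cavity_rest = 0)
  expect_lt(max(abs(net_forces(st, pp) - oracle_net_forces(st, pp))), 1e-12)
})

test_that("pair forces are antisymmetric: internal forces sum to zero", {
  pp <- potential_params()
  st <- random_state(n = 30, seed = 4, cavity_rest = 0)  # no external cavity
  expect_lt(max(abs(colSums(net_forces(st, pp)))), 1e-10)
})

test_that("mirror-symmetric states produce mirror-symmetric forces", {
  pp <- potential_params()
  upper <- rbind(c(0.5, 0.4), c(1.6, 0.9), c(-0.8, 1.2))
  lower <- upper %*% diag(c(1, -1))
  st <- make_state(rbind(upper, lower), cavity_rest = 0.3)
  f <- net_forces(st, pp)
  expect_equal(f[1:3, 1], f[4:6, 1], tolerance = 1e-12)
  expect_equal(f[1:3, 2], -f[4:6, 2], tolerance = 1e-12)
})

test_that("coincident particles raise a degenerate-pair error", {
  pp <- potential_params()
  st <- make_state(rbind(c(1, 1), c(1, 1), c(3, 0)))
  expect_error(net_forces(st, pp), class = "blastopack_degenerate_pair")
  expect_error(total_energy(st, pp), class = "blastopack_degenerate_pair")
})

test_that("two free cells at rest separation feel no force and do not move", {
  pp <- potential_params()
  st <- make_state(rbind(c(5, 0), c(5 + pp$r0, 0)), cavity_rest = 0)
  expect_equal(net_forces(st, pp), matrix(0, 2, 2), ignore_attr = TRUE)
  cfg <- tissue_config(n_steps = 1, noise_sigma = 0)
  st2 <- step_tissue(st, pp, cfg)
  expect_identical(st2$positions, st$positions)
  expect_equal(st2$time, cfg$dt)
})

test_that("noiseless step displaces exactly by dt times the net force", {
  pp <- potential_params()
  cfg <- tissue_config(noise_sigma = 0, cavity_growth_rate = 0)
  st <- random_state(n = 12, seed = 5, cavity_rest = 2)
  f <- net_forces(st, pp)
  st2 <- step_tissue(st, pp, cfg)
  expect_identical(st2$positions, st$positions + cfg$dt * f)
})

test_that("fixed cells never move, even under noise", {
  pp <- potential_params()
  cfg <- tissue_config(noise_sigma = 2)
  st <- random_state(n = 10, seed = 6, cavity_rest = 2)
  st$fixed[c(1, 4, 7)] <- TRUE
  set.seed(11)
  for (i in 1:5) st <- step_tissue(st, pp, cfg)
  orig <- random_state(n = 10, seed = 6, cavity_rest = 2)
  expect_identical(st$positions[c(1, 4, 7), ], orig$positions[c(1, 4, 7), ])
  expect_false(isTRUE(all.equal(st$positions[2, ], orig$positions[2, ])))
})

test_that("cavity growth follows the capped linear schedule", {
  cfg <- tissue_config(cavity_growth_rate = 0.1, dt = 0.5,
                       cavity_rest_max = 10)
  expect_equal(grow_cavity(1.0, cfg), 1.05)
  cfg0 <- tissue_config(cavity_growth_rate = 0)
  expect_equal(grow_cavity(2, cfg0), 2)
  # closed-form sum over a run, including the cap
  cfg2 <- tissue_config(n_rings = 2, inner_radius = 2, outer_radius = 3,
                        cavity_rest_initial = 1, cavity_growth_rate = 0.2,
                        cavity_rest_max = 1.5, dt = 0.1, n_steps = 40,
                        noise_sigma = 0, stride = 40)
  traj <- run_simulation(cfg2)
  expect_equal(tidy(traj)$cavity_rest[nrow(tidy(traj))],
               min(1 + 0.2 * 0.1 * 40, 1.5))
})

test_that("runs are deterministic given the seed and keep cell identity", {
  cfg <- reduced_config(seed = 3, n_steps = 100L)
  t1 <- run_simulation(cfg)
  t2 <- run_simulation(cfg)
  last1 <- t1$snapshots[[length(t1$snapshots)]]
  last2 <- t2$snapshots[[length(t2$snapshots)]]
  expect_identical(last1$positions, last2$positions)
  expect_identical(tidy(t1), tidy(t2))
  # cell count conserved; fixed coordinates bit-identical across all snapshots
  first <- t1$snapshots[[1]]
  for (st in t1$snapshots) {
    expect_equal(nrow(st$positions), nrow(first$positions))
    expect_identical(st$positions[st$fixed, ], first$positions[first$fixed, ])
  }
})

test_that("zero-step runs return only the initialised state", {
  cfg <- reduced_config(n_steps = 0L)
  traj <- run_simulation(cfg)
  expect_length(traj$snapshots, 1)
  expect_equal(tidy(traj)$step, 0)
})

test_that("non-finite coordinates abort with an integration-failure error", {
  cfg <- reduced_config(n_steps = 5L, noise_sigma = Inf)
  expect_error(run_simulation(cfg),
               class = "blastopack_integration_failure")
})
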