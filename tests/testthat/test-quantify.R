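test_that("packing index follows the printed formula and its limits", {
  res <- packing_index(rep(10, 4), total_area = 100)
  expect_equal(res$packing_index, 0.4)
  expect_equal(res$density, 0.04)
  expect_equal(res$intercellular_space_pct, 60)

  # confluent tiling: packing exactly 1, no intercellular space
  tiling <- packing_index(rep(25, 4), total_area = 100)
  expect_identical(tiling$packing_index, 1)
  expect_identical(tiling$intercellular_space_pct, 0)

  expect_warning(res0 <- packing_index(numeric(0), 100), "Empty")
  expect_equal(res0$packing_index, 0)
  expect_error(packing_index(c(1, 2), 0), class = "blastopack_domain_error")
  expect_error(packing_index(c(-1, 2), 10), class = "blastopack_domain_error")
})

test_that("packing and intercellular space match per-pixel oracles", {
  for (seed in 1:5) {
    lab <- random_label_image(seed)
    areas <- tabulate(lab[lab > 0])
    res <- packing_index(areas, length(lab))
    # naive per-pixel oracle
    expect_equal(res$packing_index,
                 length(areas) * mean(areas) / length(lab),
                 tolerance = 1e-12)
    expect_equal(intercellular_space(lab),
                 100 * sum(lab == 0) / length(lab), tolerance = 1e-12)
  }
})

test_that("intercellular space handles full, empty and checkerboard regions", {
  full <- matrix(1L, 8, 8)
  expect_equal(intercellular_space(full), 0)
  expect_equal(intercellular_space(matrix(0L, 8, 8)), 100)
  checker <- matrix(rep(c(1L, 0L), length.out = 64), 8, 8)
  expect_equal(intercellular_space(checker), 50)
  expect_error(intercellular_space(full, roi = matrix(FALSE, 8, 8)),
               class = "blastopack_domain_error")
})

test_that("ROI integrated density subtracts per-pixel background", {
  img <- matrix(2, 20, 20)
  roi <- matrix(FALSE, 20, 20); roi[1:5, 1:5] <- TRUE
  bg <- matrix(FALSE, 20, 20); bg[10:15, 10:15] <- TRUE
  # uniform image: signal equals background
  expect_equal(roi_integrated_density(img, roi, bg), 0)

  img2 <- matrix(2, 20, 20)
  roi2 <- matrix(FALSE, 20, 20); roi2[1, 1:10] <- TRUE
  img2[1, 1:10] <- 5
  expect_equal(roi_integrated_density(img2, roi2, bg), 30)

  # random images vs the explicit per-pixel oracle
  for (seed in 1:5) {
    set.seed(seed)
    imr <- matrix(rnorm(400, 10, 3), 20, 20)
    expect_equal(roi_integrated_density(imr, roi, bg),
                 sum(imr[roi] - mean(imr[bg])), tolerance = 1e-9)
  }
  expect_error(roi_integrated_density(img, roi, roi),
               class = "blastopack_domain_error")
})

test_that("integrated density is offset-covariant raw, invariant subtracted", {
  set.seed(7)
  img <- matrix(rnorm(400, 10, 2), 20, 20)
  roi <- matrix(FALSE, 20, 20); roi[2:6, 2:6] <- TRUE
  bg <- matrix(FALSE, 20, 20); bg[12:18, 12:18] <- TRUE
  off <- 3.7
  expect_equal(sum((img + off)[roi]), sum(img[roi]) + off * sum(roi))
  expect_equal(roi_integrated_density(img + off, roi, bg),
               roi_integrated_density(img, roi, bg), tolerance = 1e-9)
})

test_that("normalisation to the control mean behaves and is idempotent", {
  expect_equal(normalize_to_control(c(2, 2, 2), c(1, 2, 3)), c(1, 1, 1))
  expect_equal(normalize_to_control(c(2, 4), c(1, 3)), c(1, 2))
  ctrl <- c(0.4, 1.3, 1.3)
  once <- normalize_to_control(ctrl, ctrl)
  expect_equal(mean(once), 1)
  expect_equal(normalize_to_control(once, once), once)
  expect_error(normalize_to_control(1:3, c(-1, 1)),
               class = "blastopack_domain_error")
})

test_that("colocalization handles identity, shifts and degenerate channels", {
  set.seed(3)
  ch1 <- matrix(runif(900, 1, 5), 30, 30)
  same <- colocalization(ch1, ch1)
  expect_equal(same$pearson_r, 1, tolerance = 1e-12)
  expect_equal(same$overlap_coefficient, 1, tolerance = 1e-12)
  expect_equal(same$n_pixels, 900L)

  shifted <- colocalization(ch1, ch1 + 2.5)
  expect_equal(shifted$pearson_r, 1, tolerance = 1e-12)

  flat <- colocalization(ch1, matrix(1, 30, 30))
  expect_true(is.na(flat$pearson_r))
  expect_equal(flat$flag, "zero_variance")
  expect_false(is.na(flat$overlap_coefficient))

  msk <- matrix(FALSE, 30, 30); msk[1:10, ] <- TRUE
  masked <- colocalization(ch1, ch1, mask = msk)
  expect_equal(masked$n_pixels, 300L)

  both <- colocalization(ch1, ch1, manders_split = TRUE)
  expect_equal(both$m1, 1)
  expect_equal(both$m2, 1)
})

test_that("nuclear/cytoplasmic ratio follows the subtraction definition", {
  prot <- matrix(1, 10, 10)
  cell <- matrix(TRUE, 10, 10)
  nuc <- matrix(FALSE, 10, 10); nuc[1:5, ] <- TRUE  # half the summed signal
  rec <- nuc_cyto_ratio(prot, nuc, cell)
  expect_equal(rec$nc_ratio, 1)
  expect_equal(rec$id_nuc, 50)
  expect_equal(rec$id_cyto, rec$id_total - rec$id_nuc)

  # all signal inside the nucleus: undefined, flagged
  prot2 <- matrix(0, 10, 10); prot2[nuc] <- 2
  rec2 <- nuc_cyto_ratio(prot2, nuc, cell)
  expect_true(is.na(rec2$nc_ratio))
  expect_equal(rec2$flag, "undefined_ratio")

  # nucleus escaping the cell mask is a consistency error
  small_cell <- matrix(FALSE, 10, 10); small_cell[3:8, 3:8] <- TRUE
  expect_error(nuc_cyto_ratio(prot, nuc, small_cell),
               class = "blastopack_mask_error")
})

test_that("nuclei are segmented from bright discs with a size filter", {
  img <- matrix(0, 64, 64)
  for (ctr in list(c(16, 16), c(45, 40))) {
    idx <- which(outer((1:64 - ctr[1])^2, (1:64 - ctr[2])^2, "+") <= 36)
    img[idx] <- 100
  }
  lab <- segment_nuclei(img, min_size = 30)
  expect_equal(max(lab), 2)
  # a sub-threshold speckle must not add a component
  img_spk <- img; img_spk[60, 5:7] <- 100
  expect_equal(max(segment_nuclei(img_spk, min_size = 30)), 2)
  # blank image: empty mask, not an error
  expect_equal(max(segment_nuclei(matrix(0, 32, 32))), 0)
})

test_that("segmentation recovers nearly all true nuclei at moderate noise", {
  # nuclear stain amplitude 100, noise sd 20: SNR 5
  img <- make_cell_image(n_cells = 25, noise_sigma = 20, nuclear_level = 100,
                         seed = 41)
  lab <- segment_nuclei(img$channels[, , 1], min_size = 10)
  truth <- img$nucleus_mask
  recovered <- vapply(seq_len(max(truth)), function(id) {
    px <- truth == id
    sum(lab[px] > 0) / sum(px) > 0.5
  }, logical(1))
  expect_gte(mean(recovered), 0.95)
})

test_that("per-cell N/C quantification recovers generative ratios", {
  # noiseless: exact recovery through the true masks
  img <- make_cell_image(n_cells = 6, true_nc_ratio = 2, seed = 5)
  rec <- quantify_nc(img)
  expect_equal(rec$nc_ratio, rep(2, 6), tolerance = 1e-9)

  # noisy at SNR 10: median within 10% for ratios spanning 0.5-4
  for (r in c(0.5, 2, 4)) {
    img_n <- make_cell_image(n_cells = 20, true_nc_ratio = r, seed = 17,
                             total_signal = 1000)
    mean_sig <- 1000 / mean(img_n$truth$area_cell)
    img_n <- make_cell_image(n_cells = 20, true_nc_ratio = r, seed = 17,
                             total_signal = 1000,
                             noise_sigma = mean_sig / 10)
    est <- median(quantify_nc(img_n)$nc_ratio, na.rm = TRUE)
    expect_lt(abs(est - r) / r, 0.1)
  }
})
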