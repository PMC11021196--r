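#' Cell packing index and related density metrics
#'
#' The packing index of a region is
#' \deqn{\mathrm{Packing\ index} = \frac{n_{cells} \times
#'   \bar{X}_{cell\ area}}{\mathrm{Total\ area}}}
#' i.e. cell count times mean cell area over the analysed area. A confluent
#' monolayer tiling the region exactly has packing index 1; overlap-free
#' sparse cells give the occupied-area fraction. The same inputs yield cell
#' density (cells per unit area) and the percentage of intercellular space,
#' `100 * (1 - sum(areas) / total_area)` clipped to \[0, 100\].
#'
#' @param cell_areas Numeric vector of per-cell areas (pixels or length^2);
#'   all `>= 0`.
#' @param total_area Total analysed area in the same units; `> 0`.
#' @return A one-row `packing_result` tibble: `n_cells`, `mean_cell_area`,
#'   `total_area`, `packing_index`, `density`, `intercellular_space_pct`.
#' @examples
#' packing_index(rep(10, 4), total_area = 100)
#' @export
packing_index <- function(cell_areas, total_area) {
  if (!is.numeric(total_area) || length(total_area) != 1 || total_area <= 0) {
    abort("`total_area` must be a single value > 0.",
          class = "blastopack_domain_error")
  }
  if (any(cell_areas < 0)) {
    abort("`cell_areas` must be >= 0.", class = "blastopack_domain_error")
  }
  n <- length(cell_areas)
  if (n == 0) {
    warn("Empty `cell_areas`; packing index is 0.")
    mean_area <- 0
  } else {
    mean_area <- mean(cell_areas)
  }
  out <- tibble(
    n_cells = n,
    mean_cell_area = mean_area,
    total_area = total_area,
    packing_index = n * mean_area / total_area,
    density = n / total_area,
    intercellular_space_pct =
      min(max(100 * (1 - sum(cell_areas) / total_area), 0), 100)
  )
  class(out) <- c("packing_result", class(out))
  out
}

as_mask <- function(x, arg = "mask") {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x > 0)
  abort(sprintf("`%s` must be a logical or label matrix.", arg),
        class = "blastopack_domain_error")
}

#' Percentage of intercellular space in a region
#'
#' Fraction (as a percentage) of region pixels not covered by any labelled
#' cell — the empty space between cell bodies in a section.
#'
#' @param cell_mask Label or logical matrix; 0/`FALSE` = background.
#' @param roi Optional logical matrix restricting the region; `NULL` uses the
#'   whole image. Must contain at least one pixel.
#' @return Scalar percentage in \[0, 100\].
#' @export
intercellular_space <- function(cell_mask, roi = NULL) {
  occ <- as_mask(cell_mask, "cell_mask")
  if (is.null(roi)) roi <- array(TRUE, dim = dim(occ))
  roi <- as_mask(roi, "roi")
  n_roi <- sum(roi)
  if (n_roi == 0) {
    abort("Empty `roi`.", class = "blastopack_domain_error")
  }
  100 * sum(roi & !occ) / n_roi
}

#' Segment nuclei from a nuclear-stain channel
#'
#' Deterministic surrogate for manual DAPI masking: global Otsu threshold,
#' hole filling, connected-component labelling, and removal of components
#' smaller than `min_size` pixels. A blank image yields an empty mask (zero
#' nuclei), not an error.
#'
#' @param dapi_channel Single-channel numeric matrix.
#' @param min_size Minimum component size in pixels (default 30).
#' @return Integer label matrix, nuclei labelled `1..K`, background 0.
#' @export
segment_nuclei <- function(dapi_channel, min_size = 30) {
  if (length(dim(dapi_channel)) != 2) {
    abort("`dapi_channel` must be a single-channel matrix.",
          class = "blastopack_domain_error")
  }
  rng <- range(dapi_channel)
  empty <- matrix(0L, nrow(dapi_channel), ncol(dapi_channel))
  if (diff(rng) == 0) return(empty)
  scaled <- (dapi_channel - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  bin <- EBImage::fillHull(EBImage::Image(scaled > thr))
  lab <- EBImage::imageData(EBImage::bwlabel(bin))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_size)
  if (length(keep) == 0) return(empty)
  relabel <- integer(length(sizes))
  relabel[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0
  out[nz] <- relabel[lab[nz]]
  out
}

#' Nuclear-to-cytoplasmic integrated-density ratio for one cell
#'
#' Computes the integrated density (sum of pixel intensities) of the protein
#' channel over the nucleus, subtracts it from the whole-cell integrated
#' density to obtain the cytoplasmic value, and reports their ratio
#' `ID_nuc / ID_cyto`. The ratio is flagged undefined when the cytoplasmic
#' integrated density is not positive.
#'
#' @param protein_channel Numeric matrix of protein-stain intensities.
#' @param nucleus_mask,cell_mask Logical (or label) matrices for this cell's
#'   nucleus and full footprint; the nucleus must lie within the cell.
#' @param object_id Identifier stored in the output row.
#' @param channel Channel name stored in the output row.
#' @return A one-row `quant_record` tibble: `object_id`, `area`, `id_nuc`,
#'   `id_total`, `id_cyto`, `nc_ratio`, `channel`, `flag` (`NA` or
#'   `"undefined_ratio"`).
#' @export
nuc_cyto_ratio <- function(protein_channel, nucleus_mask, cell_mask,
                           object_id = 1L, channel = "protein") {
  nuc <- as_mask(nucleus_mask, "nucleus_mask")
  cell <- as_mask(cell_mask, "cell_mask")
  if (sum(nuc) == 0 || sum(cell) == 0) {
    abort("`nucleus_mask` and `cell_mask` must be non-empty.",
          class = "blastopack_domain_error")
  }
  if (any(nuc & !cell)) {
    abort("Mask inconsistency: nucleus pixels outside the cell mask.",
          class = "blastopack_mask_error")
  }
  id_nuc <- sum(protein_channel[nuc])
  id_total <- sum(protein_channel[cell])
  id_cyto <- id_total - id_nuc
  undefined <- id_cyto <= 0
  out <- tibble(
    object_id = object_id,
    area = sum(cell),
    id_nuc = id_nuc,
    id_total = id_total,
    id_cyto = id_cyto,
    nc_ratio = if (undefined) NA_real_ else id_nuc / id_cyto,
    channel = channel,
    flag = if (undefined) "undefined_ratio" else NA_character_
  )
  class(out) <- c("quant_record", class(out))
  out
}

#' Per-cell N/C ratios across a labelled image
#'
#' Applies [nuc_cyto_ratio()] to every labelled cell of a [labeled_image],
#' pairing each cell with the nucleus pixels falling inside its footprint.
#'
#' @param img A `labeled_image` with `cell_mask` and `nucleus_mask`.
#' @param protein_channel Index of the protein channel (default 2).
#' @return A `quant_record` tibble with one row per cell.
#' @export
quantify_nc <- function(img, protein_channel = 2) {
  stopifnot(inherits(img, "labeled_image"))
  if (is.null(img$cell_mask) || is.null(img$nucleus_mask)) {
    abort("`img` must carry cell and nucleus label masks.",
          class = "blastopack_domain_error")
  }
  prot <- img$channels[, , protein_channel]
  ids <- sort(unique(img$cell_mask[img$cell_mask > 0]))
  rows <- purrr::map(ids, function(id) {
    cell <- img$cell_mask == id
    nuc <- img$nucleus_mask > 0 & cell
    if (sum(nuc) == 0) return(NULL)
    nuc_cyto_ratio(prot, nuc, cell, object_id = id)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("quant_record", class(out))
  out
}

#' Background-subtracted integrated density of an ROI
#'
#' Sum of pixel intensities over a region of interest, minus the mean pixel
#' intensity of a disjoint background ROI scaled by the target ROI's size
#' (per-pixel background subtraction, the ImageJ convention). May be
#' negative.
#'
#' @param image Numeric matrix.
#' @param roi,background_roi Non-empty, disjoint logical masks.
#' @return Scalar background-subtracted integrated density.
#' @export
roi_integrated_density <- function(image, roi, background_roi) {
  roi <- as_mask(roi, "roi")
  bg <- as_mask(background_roi, "background_roi")
  if (sum(roi) == 0 || sum(bg) == 0) {
    abort("`roi` and `background_roi` must be non-empty.",
          class = "blastopack_domain_error")
  }
  if (any(roi & bg)) {
    abort("`roi` and `background_roi` must be disjoint.",
          class = "blastopack_domain_error")
  }
  sum(image[roi]) - mean(image[bg]) * sum(roi)
}

#' Normalise measurements to a control group
#'
#' Divides every value by the control group's mean, so the control group's
#' own normalised mean is exactly 1.
#'
#' @param values Numeric vector of measurements.
#' @param control_values Numeric vector of control-group measurements; mean
#'   must be nonzero.
#' @return `values / mean(control_values)`.
#' @export
normalize_to_control <- function(values, control_values) {
  m <- mean(control_values)
  if (!is.finite(m) || m == 0) {
    abort("Control mean must be finite and nonzero.",
          class = "blastopack_domain_error")
  }
  values / m
}

#' Two-channel colocalization metrics
#'
#' Sample Pearson correlation and the Manders overlap coefficient
#' \deqn{R = \frac{\sum_i A_i B_i}{\sqrt{\sum_i A_i^2 \sum_i B_i^2}}}
#' over the masked pixels of two channels. Pearson is undefined (flagged,
#' `NA`) when either channel has zero variance; the overlap coefficient is
#' still returned.
#'
#' @param ch1,ch2 Numeric matrices of identical dimensions.
#' @param mask Optional logical matrix selecting pixels; `NULL` uses all.
#' @param manders_split If `TRUE`, also report the split Manders
#'   coefficients `m1 = sum(ch1[ch2 > 0]) / sum(ch1)` and symmetrically `m2`.
#' @return A one-row `coloc_result` tibble: `pearson_r`,
#'   `overlap_coefficient`, `n_pixels`, `mask_desc`, `flag` (and `m1`, `m2`
#'   when requested).
#' @export
colocalization <- function(ch1, ch2, mask = NULL, manders_split = FALSE) {
  if (!identical(dim(ch1), dim(ch2))) {
    abort("`ch1` and `ch2` must have identical dimensions.",
          class = "blastopack_domain_error")
  }
  mask_desc <- if (is.null(mask)) "all pixels" else "user mask"
  if (is.null(mask)) mask <- array(TRUE, dim = dim(ch1))
  mask <- as_mask(mask, "mask")
  a <- ch1[mask]; b <- ch2[mask]
  n <- length(a)
  if (n < 2) {
    abort("Mask must select at least 2 pixels.",
          class = "blastopack_domain_error")
  }
  zero_var <- var(a) == 0 || var(b) == 0
  r <- if (zero_var) NA_real_ else cor(a, b)
  overlap <- sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
  out <- tibble(
    pearson_r = r,
    overlap_coefficient = overlap,
    n_pixels = n,
    mask_desc = mask_desc,
    flag = if (zero_var) "zero_variance" else NA_character_
  )
  if (manders_split) {
    out$m1 <- sum(a[b > 0]) / sum(a)
    out$m2 <- sum(b[a > 0]) / sum(b)
  }
  class(out) <- c("coloc_result", class(out))
  out
}
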