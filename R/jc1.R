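#' Principal axis of an object by PCA of its pixel coordinates
#'
#' Leading eigenvector of the (optionally intensity-weighted) covariance
#' of the object's pixel (row, col) coordinates. The direction sign is
#' fixed so the row component is >= 0 (col >= 0 on ties), making the axis
#' deterministic. The extent is the projection range of the object's
#' pixels on the axis, relative to the weighted centroid.
#'
#' @param pixels n x 2 matrix of (row, col) pixel coordinates.
#' @param weights optional non-negative weights (e.g. summed channel
#'   intensity per pixel); `NULL` for unweighted PCA.
#' @return list with `centroid` (row, col), `direction` (unit vector),
#'   `extent` (`c(tmin, tmax)` projections), `eigenvalue_ratio`
#'   (major/minor, `Inf` for collinear sets), and `near_isotropic`
#'   (TRUE when the ratio is < 1.2, i.e. the axis is poorly determined).
#' @export
principal_axis <- function(pixels, weights = NULL) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 2L)
    abort_degenerate("principal axis undefined for < 2 pixels")
  w <- if (is.null(weights)) rep(1, nrow(pixels)) else as.numeric(weights)
  if (length(w) != nrow(pixels) || any(w < 0))
    abort_config("weights must be non-negative, one per pixel")
  if (sum(w) <= 0) w <- rep(1, nrow(pixels))
  w <- w / sum(w)
  ctr <- c(sum(w * pixels[, 1]), sum(w * pixels[, 2]))
  dr <- pixels[, 1] - ctr[1]; dc <- pixels[, 2] - ctr[2]
  crr <- sum(w * dr^2); ccc <- sum(w * dc^2); crc <- sum(w * dr * dc)
  if (crr + ccc <= 0)
    abort_degenerate("zero-variance pixel set: principal axis undefined")
  mid <- (crr + ccc) / 2
  disc <- sqrt(((crr - ccc) / 2)^2 + crc^2)
  l_major <- mid + disc; l_minor <- mid - disc
  # eigenvector of [[crr, crc], [crc, ccc]] for l_major
  if (abs(crc) > 1e-300) {
    d <- c(l_major - ccc, crc)
  } else if (crr >= ccc) {
    d <- c(1, 0)
  } else {
    d <- c(0, 1)
  }
  d <- d / sqrt(sum(d^2))
  if (d[1] < 0 || (d[1] == 0 && d[2] < 0)) d <- -d
  t <- dr * d[1] + dc * d[2]
  list(centroid = ctr, direction = d, extent = range(t),
       eigenvalue_ratio = if (l_minor > 0) l_major / l_minor else Inf,
       near_isotropic = is.finite(l_minor) && l_minor > 0 &&
         (l_major / l_minor) < 1.2)
}

#' Sample a channel along a principal axis
#'
#' Bilinear interpolation at points `centroid + t * direction` for `t`
#' spanning the axis extent at `step_px` spacing, endpoint-inclusive.
#'
#' @param channel numeric matrix.
#' @param axis result of [principal_axis()].
#' @param step_px sampling step in pixels (default 0.25).
#' @return list with `t_px` (positions along axis, px) and `values`.
#' @export
sample_axis <- function(channel, axis, step_px = 0.25) {
  if (diff(axis$extent) <= 0)
    abort_degenerate("axis extent must be positive")
  ts <- seq(axis$extent[1], axis$extent[2], by = step_px)
  if (ts[length(ts)] < axis$extent[2]) ts <- c(ts, axis$extent[2])
  rows <- axis$centroid[1] + ts * axis$direction[1]
  cols <- axis$centroid[2] + ts * axis$direction[2]
  list(t_px = ts, values = bilinear_sample(channel, rows, cols))
}

#' Normalize an intensity profile to its maximum
#'
#' Divides by the profile maximum so the result lies in `[0, 1]` with
#' maximum exactly 1. An all-zero profile cannot be normalized; it is
#' returned unchanged with `flagged = TRUE` rather than divided.
#'
#' @param values non-negative numeric vector.
#' @return list with `values` and `flagged`.
#' @export
normalize_profile <- function(values) {
  m <- max(values)
  if (m <= 0) return(list(values = values, flagged = TRUE))
  list(values = values / m, flagged = FALSE)
}

#' JC-1 membrane-potential profiling of one dual-channel image
#'
#' Segments mitochondria by combined red/green thresholding and
#' connected-component labeling; for each object, finds the PCA principal
#' axis (weighted by summed red+green intensity), samples both channels
#' along it with bilinear interpolation, normalizes each profile to its
#' own maximum, and computes the red/green ratio where the normalized
#' green exceeds `ratio_floor`. The pixel-wise red--green Pearson
#' correlation within the object mask ("pix PCC") and the variance of the
#' axial ratio (a mosaicism readout) are reported per object. High-
#' potential regions are red(aggregate)-dominant, low-potential regions
#' green(monomer)-dominant, so spatially segregated potential shows up as
#' negative pix PCC and a non-constant axial ratio.
#'
#' @param image a [multichannel_image()] with red and green channels.
#' @param red_role,green_role channel roles (defaults "red", "green").
#' @param step_px axial sampling step (default 0.25 px).
#' @param min_area_px objects smaller than this are skipped (default 2).
#' @param ratio_floor minimum normalized green for ratio computation
#'   (default 0.05).
#' @param mask_mode,closing_radius,connectivity,bins segmentation
#'   parameters, see [combined_channel_mask()] and [label_components()].
#' @param weighted_pca intensity-weight the axis PCA (default TRUE).
#' @return list with `profiles` (list of per-object axial profiles:
#'   `object_label`, `axis`, `positions_um`, `green_norm`, `red_norm`,
#'   `ratio`, `pix_pcc`, `ratio_variance`, flags), `summary` (one-row
#'   data.frame: object counts, mean pix PCC, fraction of objects with
#'   pix PCC < 0), and `labels`.
#' @export
jc1_pipeline <- function(image, red_role = "red", green_role = "green",
                         step_px = 0.25, min_area_px = 2L,
                         ratio_floor = 0.05,
                         mask_mode = "union", closing_radius = 0L,
                         connectivity = 8L, bins = 256L,
                         weighted_pca = TRUE) {
  red <- get_channel(image, red_role)
  green <- get_channel(image, green_role)
  mask <- combined_channel_mask(red, green, mode = mask_mode,
                                closing_radius = closing_radius, bins = bins)
  labels <- label_components(mask, connectivity = connectivity)
  n <- attr(labels, "n")
  profiles <- list()
  n_skipped <- 0L
  px <- image$pixel_size_um
  for (i in seq_len(n)) {
    idx <- which(labels == i, arr.ind = TRUE)
    if (nrow(idx) < max(2L, min_area_px)) { n_skipped <- n_skipped + 1L; next }
    w <- if (weighted_pca) red[idx] + green[idx] else NULL
    axis <- tryCatch(principal_axis(idx, weights = w),
                     fluoquant_degenerate_input = function(e) NULL)
    if (is.null(axis) || diff(axis$extent) <= 0) {
      n_skipped <- n_skipped + 1L; next
    }
    sr <- sample_axis(red, axis, step_px = step_px)
    sg <- sample_axis(green, axis, step_px = step_px)
    nr <- normalize_profile(sr$values)
    ng <- normalize_profile(sg$values)
    ratio <- rep(NA_real_, length(nr$values))
    if (!nr$flagged && !ng$flagged) {
      ok <- ng$values > ratio_floor
      ratio[ok] <- nr$values[ok] / ng$values[ok]
    }
    pcc <- tryCatch(pearson_cc(red[idx], green[idx]),
                    fluoquant_undefined_statistic = function(e) NA_real_)
    profiles[[length(profiles) + 1L]] <- list(
      object_label = i, axis = axis,
      positions_um = (sr$t_px - sr$t_px[1]) * px,
      green_norm = ng$values, red_norm = nr$values, ratio = ratio,
      pix_pcc = pcc,
      ratio_variance = if (sum(!is.na(ratio)) > 1)
        var(ratio[!is.na(ratio)]) else NA_real_,
      red_flagged = nr$flagged, green_flagged = ng$flagged,
      near_isotropic = axis$near_isotropic,
      area_px = nrow(idx))
  }
  pccs <- vapply(profiles, function(p)
    if (is.na(p$pix_pcc)) NA_real_ else p$pix_pcc, numeric(1))
  pccs <- pccs[!is.na(pccs)]
  summary <- data.frame(
    source_id = image$source_id, condition = image$condition,
    n_objects = length(profiles), n_skipped = n_skipped,
    mean_pix_pcc = if (length(pccs)) mean(pccs) else NA_real_,
    frac_pcc_negative = if (length(pccs)) mean(pccs < 0) else NA_real_,
    stringsAsFactors = FALSE)
  list(profiles = profiles, summary = summary, labels = labels,
       mask = mask)
}

#' Long-format table of JC-1 axial profiles
#'
#' @param result output of [jc1_pipeline()].
#' @return data.frame with columns `object`, `position_um`, `green_norm`,
#'   `red_norm`, `ratio`.
#' @export
jc1_profile_table <- function(result) {
  rows <- lapply(result$profiles, function(p)
    data.frame(object = p$object_label, position_um = p$positions_um,
               green_norm = p$green_norm, red_norm = p$red_norm,
               ratio = p$ratio, stringsAsFactors = FALSE))
  if (length(rows) == 0L)
    return(data.frame(object = integer(0), position_um = numeric(0),
                      green_norm = numeric(0), red_norm = numeric(0),
                      ratio = numeric(0)))
  do.call(rbind, rows)
}
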