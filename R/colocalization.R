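#' Bilinear interpolation of an image at sub-pixel points
#'
#' Pixel centers sit at integer (row, col) positions; queries are clamped
#' to the valid interpolation domain `[1, nrow] x [1, ncol]`.
#'
#' @param channel numeric matrix.
#' @param rows,cols numeric vectors of equal length.
#' @return numeric vector of interpolated values.
#' @export
bilinear_sample <- function(channel, rows, cols) {
  nr <- nrow(channel); nc <- ncol(channel)
  r <- pmin(pmax(rows, 1), nr)
  c <- pmin(pmax(cols, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  r0 <- pmax(r0, 1L); c0 <- pmax(c0, 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(r0, c0); i10 <- cbind(r0 + 1, c0)
  i01 <- cbind(r0, c0 + 1); i11 <- cbind(r0 + 1, c0 + 1)
  channel[i00] * (1 - fr) * (1 - fc) + channel[i10] * fr * (1 - fc) +
    channel[i01] * (1 - fr) * fc + channel[i11] * fr * fc
}

#' Pearson correlation of paired intensities
#'
#' Sample Pearson correlation coefficient (PCC) of two aligned intensity
#' vectors. A constant coordinate leaves the statistic undefined; this is
#' reported as an error (never coerced to 0).
#'
#' @param a,b numeric vectors of equal length (>= 2).
#' @return PCC in `[-1, 1]`.
#' @export
pearson_cc <- function(a, b) {
  if (length(a) != length(b)) abort_config("a and b must have equal length")
  keep <- !(is.na(a) | is.na(b))
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2L) abort_undefined("need >= 2 pairs for PCC")
  if (var(a) == 0 || var(b) == 0)
    abort_undefined("constant coordinate: PCC undefined")
  r <- cor(a, b)
  min(1, max(-1, r))
}

#' Manders colocalization coefficients M1 and M2
#'
#' Thresholded Manders coefficients: M1 is the fraction of channel A's
#' integrated intensity (over A's own mask) that lies inside channel B's
#' mask; M2 is symmetric with roles swapped.
#'
#' @param a,b numeric matrices of equal size.
#' @param mask_a,mask_b logical masks for channels A and B.
#' @return list with elements `m1` and `m2`, both in `[0, 1]`.
#' @export
manders <- function(a, b, mask_a, mask_b) {
  if (!identical(dim(a), dim(b))) abort_config("channel shapes differ")
  ma <- unclass_mask(mask_a); mb <- unclass_mask(mask_b)
  den1 <- sum(a[ma]); den2 <- sum(b[mb])
  if (den1 <= 0 || den2 <= 0)
    abort_undefined("zero integrated intensity in a mask: Manders undefined")
  both <- ma & mb
  list(m1 = sum(a[both]) / den1, m2 = sum(b[both]) / den2)
}

#' Intensity correlation quotient (ICQ)
#'
#' With within-mask means `a_bar`, `b_bar`, ICQ is the fraction of mask
#' pixels whose mean-deviation product `(a - a_bar)(b - b_bar)` is
#' positive, among pixels with a nonzero product, minus 0.5. Values range
#' over `[-0.5, 0.5]`: +0.5 for perfectly covarying channels, -0.5 for
#' perfectly anti-varying ones, ~0 for independent channels.
#'
#' @param a,b numeric matrices of equal size.
#' @param mask logical mask defining the analysis domain.
#' @return ICQ in `[-0.5, 0.5]`.
#' @export
icq <- function(a, b, mask) {
  m <- unclass_mask(mask)
  av <- a[m]; bv <- b[m]
  if (length(av) < 2L) abort_undefined("need >= 2 mask pixels for ICQ")
  if (var(av) == 0 || var(bv) == 0)
    abort_undefined("constant channel within mask: ICQ undefined")
  prod <- (av - mean(av)) * (bv - mean(bv))
  nz <- prod != 0
  if (!any(nz)) abort_undefined("all mean-deviation products zero")
  sum(prod > 0) / sum(nz) - 0.5
}

# Clip the infinite line through `p` with direction `d` (unit) to the
# rectangle [1, nr] x [1, nc]; returns c(tmin, tmax) or NULL.
clip_line <- function(p, d, nr, nc) {
  tmin <- -Inf; tmax <- Inf
  for (k in 1:2) {
    lo <- 1; hi <- if (k == 1) nr else nc
    if (abs(d[k]) < 1e-12) {
      if (p[k] < lo || p[k] > hi) return(NULL)
    } else {
      t1 <- (lo - p[k]) / d[k]; t2 <- (hi - p[k]) / d[k]
      tmin <- max(tmin, min(t1, t2)); tmax <- min(tmax, max(t1, t2))
    }
  }
  if (tmin >= tmax) return(NULL)
  c(tmin, tmax)
}

#' Optimize a scan line for two-channel profile extraction
#'
#' Scans `n_orientations` evenly spaced orientations in `[0, pi)` of the
#' full-image chord through the centroid of the union mask, and selects
#' the orientation maximizing the summed product of the two channels'
#' intensities sampled along the chord (bilinear interpolation at
#' `step_px` spacing). Deterministic: ties are broken by the smallest
#' orientation index, so a single orientation yields the horizontal chord.
#'
#' @param a,b numeric matrices of equal size.
#' @param mask_a,mask_b logical channel masks; their union must be
#'   non-empty.
#' @param n_orientations number of candidate orientations (default 36).
#' @param step_px sampling step along the line in pixels (default 0.5).
#' @return a `scan_line`: list with `p0`, `p1` (endpoints, (row, col)),
#'   `step_px`, `theta`, `orientation_index`, `objective_value`.
#' @export
optimize_scan_line <- function(a, b, mask_a, mask_b,
                               n_orientations = 36L, step_px = 0.5) {
  u <- unclass_mask(mask_a) | unclass_mask(mask_b)
  if (!any(u)) abort_no_signal("empty union mask: no scan line")
  idx <- which(u, arr.ind = TRUE)
  ctr <- c(mean(idx[, 1]), mean(idx[, 2]))
  nr <- nrow(a); nc <- ncol(a)
  thetas <- (seq_len(n_orientations) - 1L) * pi / n_orientations
  best <- NULL
  for (k in seq_along(thetas)) {
    # theta = 0 is the horizontal chord (varying column)
    d <- c(sin(thetas[k]), cos(thetas[k]))
    tt <- clip_line(ctr, d, nr, nc)
    if (is.null(tt)) next
    ts <- seq(tt[1], tt[2], by = step_px)
    if (ts[length(ts)] < tt[2]) ts <- c(ts, tt[2])
    rows <- ctr[1] + ts * d[1]; cols <- ctr[2] + ts * d[2]
    obj <- sum(bilinear_sample(a, rows, cols) * bilinear_sample(b, rows, cols))
    if (is.null(best) || obj > best$objective_value) {
      best <- list(p0 = c(ctr[1] + tt[1] * d[1], ctr[2] + tt[1] * d[2]),
                   p1 = c(ctr[1] + tt[2] * d[1], ctr[2] + tt[2] * d[2]),
                   step_px = step_px, theta = thetas[k],
                   orientation_index = k, objective_value = obj)
    }
  }
  structure(best, class = "scan_line")
}

#' Intensity profile along a scan line
#'
#' Bilinear interpolation of one channel at points spaced `step_px` along
#' the line, endpoint-inclusive.
#'
#' @param channel numeric matrix.
#' @param line a `scan_line` from [optimize_scan_line()], or any list
#'   with `p0`, `p1`, `step_px`.
#' @return numeric vector of sampled intensities.
#' @export
line_profile <- function(channel, line) {
  d <- line$p1 - line$p0
  len <- sqrt(sum(d^2))
  if (len <= 0) abort_config("scan line endpoints coincide")
  d <- d / len
  ts <- seq(0, len, by = line$step_px)
  if (ts[length(ts)] < len) ts <- c(ts, len)
  bilinear_sample(channel, line$p0[1] + ts * d[1], line$p0[2] + ts * d[2])
}

#' Two-channel colocalization analysis of one image
#'
#' Full pipeline for one channel pair: per-channel Otsu masks with
#' morphological closing, the union mask, an optimized scan line, then
#' PCC along the paired line profiles, pixel-wise PCC within the union
#' mask, Manders M1/M2 (each channel's own mask as domain, the other as
#' colocalization criterion) and ICQ within the union mask. Statistics
#' that are undefined on the input (e.g. a constant channel) are reported
#' as `NA` with the reason in `flags`, never as 0.
#'
#' @param image a [multichannel_image()].
#' @param role_a,role_b channel roles to compare.
#' @param closing_radius disc radius for mask closing (default 1 px).
#' @param n_orientations scan-line orientation count (default 36).
#' @param step_px scan-line sampling step (default 0.5 px).
#' @param bins Otsu histogram bins (default 256).
#' @return a `coloc_result`: list with `pcc_line`, `pcc_pixel`, `m1`,
#'   `m2`, `icq`, `n_pixels_union`, `channelA_name`, `channelB_name`,
#'   `scan_line`, `threshold_a`, `threshold_b`, `flags`.
#' @export
colocalize <- function(image, role_a, role_b, closing_radius = 1L,
                       n_orientations = 36L, step_px = 0.5, bins = 256L) {
  a <- get_channel(image, role_a)
  b <- get_channel(image, role_b)
  flags <- character(0)
  mk <- function(ch, nm) tryCatch(
    channel_mask(ch, closing_radius = closing_radius, bins = bins),
    fluoquant_degenerate_input = function(e) {
      flags <<- c(flags, sprintf("mask_%s: %s", nm, conditionMessage(e)))
      binary_mask(matrix(FALSE, nrow(ch), ncol(ch)))
    })
  mask_a <- mk(a, "a")
  mask_b <- mk(b, "b")
  u <- unclass_mask(mask_a) | unclass_mask(mask_b)
  grab <- function(expr, what) {
    tryCatch(expr, fluoquant_error = function(e) {
      flags <<- c(flags, sprintf("%s: %s", what, conditionMessage(e)))
      NA_real_
    })
  }
  line <- tryCatch(
    optimize_scan_line(a, b, mask_a, mask_b,
                       n_orientations = n_orientations, step_px = step_px),
    fluoquant_error = function(e) {
      flags <<- c(flags, sprintf("scan_line: %s", conditionMessage(e)))
      NULL
    })
  pcc_line <- if (is.null(line)) NA_real_ else
    grab(pearson_cc(line_profile(a, line), line_profile(b, line)), "pcc_line")
  pcc_pixel <- grab(pearson_cc(a[u], b[u]), "pcc_pixel")
  mm <- tryCatch(manders(a, b, mask_a, mask_b),
                 fluoquant_error = function(e) {
                   flags <<- c(flags, sprintf("manders: %s", conditionMessage(e)))
                   list(m1 = NA_real_, m2 = NA_real_)
                 })
  icq_val <- grab(icq(a, b, binary_mask(u)), "icq")
  structure(
    list(pcc_line = pcc_line, pcc_pixel = pcc_pixel,
         m1 = mm$m1, m2 = mm$m2, icq = icq_val,
         n_pixels_union = sum(u),
         channelA_name = role_a, channelB_name = role_b,
         scan_line = line,
         threshold_a = attr(mask_a, "threshold"),
         threshold_b = attr(mask_b, "threshold"),
         closing_radius = closing_radius, flags = flags,
         source_id = image$source_id, condition = image$condition),
    class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    "<coloc_result> %s vs %s: PCC(line)=%.3f PCC(pixel)=%.3f M1=%.3f M2=%.3f ICQ=%.3f (n_union=%d)\n",
    x$channelA_name, x$channelB_name, x$pcc_line, x$pcc_pixel,
    x$m1, x$m2, x$icq, x$n_pixels_union))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Flatten a coloc_result to a one-row data.frame
#'
#' @param result a `coloc_result`.
#' @return data.frame with one row of scalar fields plus scan-line
#'   provenance.
#' @export
coloc_record <- function(result) {
  sl <- result$scan_line
  data.frame(
    source_id = result$source_id, condition = result$condition,
    channelA = result$channelA_name, channelB = result$channelB_name,
    pcc_line = result$pcc_line, pcc_pixel = result$pcc_pixel,
    m1 = result$m1, m2 = result$m2, icq = result$icq,
    n_pixels_union = result$n_pixels_union,
    threshold_a = result$threshold_a, threshold_b = result$threshold_b,
    closing_radius = as.numeric(result$closing_radius),
    scan_theta = if (is.null(sl)) NA_real_ else sl$theta,
    scan_objective = if (is.null(sl)) NA_real_ else sl$objective_value,
    flags = paste(result$flags, collapse = "; "),
    stringsAsFactors = FALSE)
}
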