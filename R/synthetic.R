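with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Catmull-Rom spline through control points (n x 2), densified to a
# polyline with ~`step` spacing, then cut to exact arc length `length_px`.
# Returns the dense centerline (k x 2) whose polyline length is exactly
# length_px (the analytic ground-truth length).
catmull_rom_path <- function(ctrl, length_px, step = 0.25) {
  p <- rbind(ctrl[1, ], ctrl, ctrl[nrow(ctrl), ])
  pts <- list()
  for (i in seq_len(nrow(p) - 3L)) {
    p0 <- p[i, ]; p1 <- p[i + 1, ]; p2 <- p[i + 2, ]; p3 <- p[i + 3, ]
    seg_len <- sqrt(sum((p2 - p1)^2))
    nt <- max(2L, ceiling(seg_len / step) + 1L)
    t <- seq(0, 1, length.out = nt)
    if (i > 1L) t <- t[-1]
    a <- 2 * p1
    b <- p2 - p0
    c2 <- 2 * p0 - 5 * p1 + 4 * p2 - p3
    c3 <- -p0 + 3 * p1 - 3 * p2 + p3
    q <- 0.5 * (outer(rep(1, length(t)), a) + outer(t, b) +
                outer(t^2, c2) + outer(t^3, c3))
    pts[[i]] <- q
  }
  path <- do.call(rbind, pts)
  seg <- sqrt(rowSums((path[-1, , drop = FALSE] -
                       path[-nrow(path), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  if (cum[length(cum)] < length_px) return(NULL)  # path too short
  k <- which(cum >= length_px)[1]
  # interpolate the final point to land exactly at length_px
  excess <- cum[k] - length_px
  if (excess > 0 && k > 1L) {
    frac <- 1 - excess / seg[k - 1L]
    last <- path[k - 1L, ] + frac * (path[k, ] - path[k - 1L, ])
    path <- rbind(path[seq_len(k - 1L), , drop = FALSE], last)
  } else {
    path <- path[seq_len(k), , drop = FALSE]
  }
  path
}

# Random smooth centerline of exact arc length, inside [margin, size-margin].
# Control points follow a heading random walk with capped turning angle.
random_centerline <- function(size, length_px, margin, max_turn = 0.4,
                              ctrl_step = 6, max_tries = 30L) {
  for (try in seq_len(max_tries)) {
    start <- runif(2, margin, size - margin)
    heading <- runif(1, 0, 2 * pi)
    n_ctrl <- ceiling(1.6 * length_px / ctrl_step) + 4L
    ctrl <- matrix(NA_real_, n_ctrl, 2)
    ctrl[1, ] <- start
    ok <- TRUE
    for (i in 2:n_ctrl) {
      heading <- heading + runif(1, -max_turn, max_turn)
      ctrl[i, ] <- ctrl[i - 1, ] + ctrl_step * c(sin(heading), cos(heading))
      if (any(ctrl[i, ] < margin) || any(ctrl[i, ] > size - margin)) {
        ok <- FALSE; break
      }
    }
    if (!ok) next
    path <- catmull_rom_path(ctrl, length_px)
    if (!is.null(path) &&
        all(path >= margin - 1) && all(path <= size - margin + 1))
      return(path)
  }
  NULL
}

# Max-composite Gaussian tube rendering: at each centerline point,
# deposit amplitude * exp(-d^2 / (2 sigma^2)) in a local window, taking
# the pixel-wise maximum so the cross-section stays an exact Gaussian.
render_tube <- function(canvas, path, sigma, amplitudes) {
  size_r <- nrow(canvas); size_c <- ncol(canvas)
  w <- ceiling(3.5 * sigma)
  if (length(amplitudes) == 1L) amplitudes <- rep(amplitudes, nrow(path))
  for (i in seq_len(nrow(path))) {
    r0 <- max(1L, floor(path[i, 1] - w)); r1 <- min(size_r, ceiling(path[i, 1] + w))
    c0 <- max(1L, floor(path[i, 2] - w)); c1 <- min(size_c, ceiling(path[i, 2] + w))
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    d2 <- outer((rr - path[i, 1])^2, (cc - path[i, 2])^2, "+")
    g <- amplitudes[i] * exp(-d2 / (2 * sigma^2))
    canvas[rr, cc] <- pmax(canvas[rr, cc], g)
  }
  canvas
}

default_noise <- function() {
  list(poisson_scale = 0.1, gaussian_sd = 50, background = 100,
       background_gradient = 0)
}

#' Apply the generator's shot + read noise model
#'
#' Adds a smooth background (level plus optional linear gradient), draws
#' Poisson shot noise with mean `clean * poisson_scale` rescaled back by
#' `1 / poisson_scale`, adds Gaussian read noise, clips at 0 and
#' quantizes to 16-bit integers. `poisson_scale = Inf` and
#' `gaussian_sd = 0` give the noiseless quantized render.
#'
#' @param clean numeric matrix of noiseless signal.
#' @param noise list with `poisson_scale`, `gaussian_sd`, `background`,
#'   `background_gradient` (peak-to-peak fraction of `background` varying
#'   left to right).
#' @return numeric matrix of integers in `[0, 65535]`.
#' @export
apply_noise <- function(clean, noise = default_noise()) {
  noise <- modifyList(default_noise(), noise)
  bg <- noise$background *
    (1 + noise$background_gradient *
       (col(clean) - 1) / max(1, ncol(clean) - 1))
  img <- clean + bg
  if (is.finite(noise$poisson_scale) && noise$poisson_scale > 0)
    img <- rpois(length(img), pmax(img, 0) * noise$poisson_scale) /
      noise$poisson_scale
  if (noise$gaussian_sd > 0)
    img <- img + rnorm(length(img), 0, noise$gaussian_sd)
  img <- round(pmin(pmax(img, 0), 65535))
  matrix(img, nrow(clean), ncol(clean))
}

#' Synthetic field of curvilinear tubes with known centerline lengths
#'
#' Tubes are rendered with Gaussian cross-sections along smooth
#' Catmull-Rom centerlines of exactly known (analytic polyline) arc
#' length; shot noise, read noise and a smooth background are added
#' last. Tube placement enforces a minimum separation so that objects
#' remain resolvable; an infeasible density raises an error. The `width`
#' of a tube is its approximate full width (~2 sigma of the Gaussian
#' cross-section).
#'
#' @param n_tubes number of tubes (0 gives a background-only field).
#' @param length_um_range range of true centerline lengths (um).
#' @param width_px_range range of tube widths in pixels.
#' @param pixel_size_um calibration (default 0.1 um/px).
#' @param size field side in pixels (default 512).
#' @param amplitude peak tube intensity above background (default 1000 on
#'   the 16-bit scale).
#' @param noise noise parameters, see [apply_noise()]; `NULL` disables
#'   noise entirely (clean render, still quantized).
#' @param seed integer seed; the same seed and parameters give a
#'   bit-identical image and truth.
#' @param condition,source_id labels stored on the image.
#' @return list with `image` (a [multichannel_image()], channel `"mito"`)
#'   and `truth` (seed, per-tube centerline, sigma, width, amplitude and
#'   `true_lengths_um`, plus the noise spec).
#' @export
make_tube_field <- function(n_tubes = 12L, length_um_range = c(1, 15),
                            width_px_range = c(2, 5), pixel_size_um = 0.1,
                            size = 512L, amplitude = 1000,
                            noise = default_noise(), seed = 1L,
                            condition = "", source_id = sprintf("tubes_s%d", seed)) {
  with_seed(seed, {
    canvas <- matrix(0, size, size)
    tubes <- list()
    accepted <- NULL  # subsampled centerline points of accepted tubes
    for (i in seq_len(n_tubes)) {
      len_um <- runif(1, length_um_range[1], length_um_range[2])
      len_px <- len_um / pixel_size_um
      width <- runif(1, width_px_range[1], width_px_range[2])
      sigma <- width / 2
      margin <- ceiling(4 * sigma + 3)
      placed <- FALSE
      for (try in seq_len(40L)) {
        path <- random_centerline(size, len_px, margin)
        if (is.null(path)) next
        sub <- path[seq(1, nrow(path), by = 4L), , drop = FALSE]
        if (!is.null(accepted)) {
          dmin <- min(proxy_min_dist(sub, accepted))
          if (dmin < 3 * (sigma + max_sigma(tubes)) + 2) next
        }
        canvas <- render_tube(canvas, path, sigma, amplitude)
        accepted <- rbind(accepted, sub)
        tubes[[length(tubes) + 1L]] <- list(
          centerline = path, sigma_px = sigma, width_px = width,
          amplitude = amplitude, length_um = len_um)
        placed <- TRUE
        break
      }
      if (!placed)
        abort_density(sprintf("could not place tube %d of %d after retries",
                              i, n_tubes))
    }
    img <- if (is.null(noise)) round(pmin(pmax(canvas, 0), 65535))
           else apply_noise(canvas, noise)
    truth <- structure(list(
      seed = seed, kind = "tubes", tubes = tubes,
      true_lengths_um = vapply(tubes, `[[`, numeric(1), "length_um"),
      noise = noise, pixel_size_um = pixel_size_um),
      class = "synthetic_truth")
    list(image = multichannel_image(list(mito = img), pixel_size_um,
                                    source_id = source_id,
                                    condition = condition),
         truth = truth)
  })
}

max_sigma <- function(tubes) {
  if (length(tubes) == 0L) return(0)
  max(vapply(tubes, `[[`, numeric(1), "sigma_px"))
}

# Minimum distance from each row of a to the point set b.
proxy_min_dist <- function(a, b) {
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  sqrt(apply(d2, 1, min))
}

# Dart-throwing sampler: n points in [margin, size-margin]^2 with pairwise
# separation >= min_sep.
sample_positions <- function(n, size, min_sep, margin, max_attempts = 400L * n) {
  pts <- matrix(NA_real_, n, 2)
  got <- 0L
  for (a in seq_len(max_attempts)) {
    p <- runif(2, margin, size - margin)
    if (got > 0L) {
      d2 <- (pts[seq_len(got), 1] - p[1])^2 + (pts[seq_len(got), 2] - p[2])^2
      if (min(d2) < min_sep^2) next
    }
    got <- got + 1L
    pts[got, ] <- p
    if (got == n) return(pts)
  }
  abort_density(sprintf("could not place %d spots at separation %.1f px",
                        n, min_sep))
}

#' Synthetic two-channel punctate field with a designed overlap fraction
#'
#' `round(f * n_spots)` channel-A spots are duplicated at identical
#' positions in channel B; the remaining spots of each channel are placed
#' at disjoint positions. All distinct positions keep a minimum
#' separation of `4 * spot_sigma`. The truth records the designed
#' fraction and the analytic overlap of integrated intensities.
#'
#' @param n_spots spots per channel (default 200).
#' @param overlap_fraction designed colocalization fraction `f` in
#'   `[0, 1]`.
#' @param spot_sigma Gaussian spot sigma in px (default 2).
#' @param amplitudes length-2 peak amplitudes for channels A and B.
#' @param amp_jitter multiplicative per-spot amplitude jitter half-range
#'   (default 0.3, i.e. U(0.7, 1.3)).
#' @param size field side in px (default 512).
#' @param pixel_size_um calibration.
#' @param noise see [apply_noise()]; `NULL` disables noise.
#' @param seed integer seed.
#' @param condition,source_id labels.
#' @return list with `image` (channels `"red"` = A, `"green"` = B) and
#'   `truth` (designed `overlap_fraction`, spot positions and amplitudes,
#'   `analytic_m1`, `analytic_m2`).
#' @export
make_coloc_field <- function(n_spots = 200L, overlap_fraction = 0.5,
                             spot_sigma = 2, amplitudes = c(1000, 1000),
                             amp_jitter = 0.3, size = 512L,
                             pixel_size_um = 0.1, noise = default_noise(),
                             seed = 1L, condition = "",
                             source_id = sprintf("coloc_f%.2f_s%d",
                                                 overlap_fraction, seed)) {
  if (overlap_fraction < 0 || overlap_fraction > 1)
    abort_config("overlap_fraction must be in [0, 1]")
  with_seed(seed, {
    n_co <- round(overlap_fraction * n_spots)
    n_only <- n_spots - n_co
    total <- n_co + 2L * n_only
    margin <- ceiling(4 * spot_sigma + 2)
    pos <- sample_positions(total, size, 4 * spot_sigma, margin)
    i_co <- seq_len(n_co)
    i_a <- if (n_only > 0) n_co + seq_len(n_only) else integer(0)
    i_b <- if (n_only > 0) n_co + n_only + seq_len(n_only) else integer(0)
    jit <- function(n) runif(n, 1 - amp_jitter, 1 + amp_jitter)
    amp_a <- amplitudes[1] * jit(n_spots)   # first n_co rows are shared
    amp_b <- amplitudes[2] * jit(n_spots)
    splat <- function(idx, amps) {
      canvas <- matrix(0, size, size)
      if (length(idx))
        canvas <- render_spots(canvas, pos[idx, , drop = FALSE],
                               spot_sigma, amps)
      canvas
    }
    clean_a <- splat(c(i_co, i_a), amp_a)
    clean_b <- splat(c(i_co, i_b), amp_b)
    a <- if (is.null(noise)) round(clean_a) else apply_noise(clean_a, noise)
    b <- if (is.null(noise)) round(clean_b) else apply_noise(clean_b, noise)
    truth <- structure(list(
      seed = seed, kind = "coloc",
      overlap_fraction = overlap_fraction, n_spots = n_spots,
      n_colocalized = n_co,
      positions_shared = pos[i_co, , drop = FALSE],
      positions_a_only = pos[i_a, , drop = FALSE],
      positions_b_only = pos[i_b, , drop = FALSE],
      analytic_m1 = sum(amp_a[seq_len(n_co)]) / sum(amp_a),
      analytic_m2 = sum(amp_b[seq_len(n_co)]) / sum(amp_b),
      noise = noise, pixel_size_um = pixel_size_um),
      class = "synthetic_truth")
    list(image = multichannel_image(list(red = a, green = b),
                                    pixel_size_um, source_id = source_id,
                                    condition = condition),
         truth = truth)
  })
}

# Additive Gaussian spot splatting (spots are separated, so sums do not
# distort individual spot profiles).
render_spots <- function(canvas, pos, sigma, amplitudes) {
  size_r <- nrow(canvas); size_c <- ncol(canvas)
  w <- ceiling(4 * sigma)
  for (i in seq_len(nrow(pos))) {
    r0 <- max(1L, floor(pos[i, 1] - w)); r1 <- min(size_r, ceiling(pos[i, 1] + w))
    c0 <- max(1L, floor(pos[i, 2] - w)); c1 <- min(size_c, ceiling(pos[i, 2] + w))
    rr <- r0:r1; cc <- c0:c1
    d2 <- outer((rr - pos[i, 1])^2, (cc - pos[i, 2])^2, "+")
    canvas[rr, cc] <- canvas[rr, cc] + amplitudes[i] * exp(-d2 / (2 * sigma^2))
  }
  canvas
}

#' Synthetic dual-channel JC-1 field with designed axial intensity patterns
#'
#' Tubular objects whose red (aggregate) and green (monomer) amplitudes
#' vary along the centerline according to `mosaic_mode`:
#' `"uniform"` (both channels constant and equal — a uniform membrane
#' potential), `"half-half"` (red-dominant first half, green-dominant
#' second half — a sharp potential boundary), or `"gradient"` (red
#' decreasing, green increasing linearly along the tube). The truth
#' stores each object's designed axial dominance function.
#'
#' @param n_objects number of tubes (default 8).
#' @param mosaic_mode `"uniform"`, `"half-half"` or `"gradient"`.
#' @param length_um_range,width_px_range tube geometry ranges.
#' @param pixel_size_um,size field calibration and side.
#' @param amplitude peak channel amplitude.
#' @param low_frac amplitude fraction of the suppressed channel portion
#'   (default 0.1).
#' @param noise see [apply_noise()]; `NULL` disables noise.
#' @param seed integer seed.
#' @param condition,source_id labels.
#' @return list with `image` (channels `"red"`, `"green"`) and `truth`
#'   (per-object centerline, arc coordinate and designed red/green
#'   amplitude profiles).
#' @export
make_jc1_field <- function(n_objects = 8L,
                           mosaic_mode = c("uniform", "half-half", "gradient"),
                           length_um_range = c(3, 8),
                           width_px_range = c(2, 3), pixel_size_um = 0.1,
                           size = 256L, amplitude = 1000, low_frac = 0.1,
                           noise = default_noise(), seed = 1L,
                           condition = "",
                           source_id = sprintf("jc1_%s_s%d",
                                               mosaic_mode[1], seed)) {
  mosaic_mode <- match.arg(mosaic_mode)
  with_seed(seed, {
    red <- matrix(0, size, size)
    green <- matrix(0, size, size)
    objects <- list()
    accepted <- NULL
    for (i in seq_len(n_objects)) {
      len_um <- runif(1, length_um_range[1], length_um_range[2])
      len_px <- len_um / pixel_size_um
      width <- runif(1, width_px_range[1], width_px_range[2])
      sigma <- width / 2
      margin <- ceiling(4 * sigma + 3)
      placed <- FALSE
      for (try in seq_len(40L)) {
        path <- random_centerline(size, len_px, margin, max_turn = 0.15)
        if (is.null(path)) next
        sub <- path[seq(1, nrow(path), by = 4L), , drop = FALSE]
        if (!is.null(accepted)) {
          if (min(proxy_min_dist(sub, accepted)) < 6 * sigma + 4) next
        }
        seg <- sqrt(rowSums((path[-1, , drop = FALSE] -
                             path[-nrow(path), , drop = FALSE])^2))
        s <- c(0, cumsum(seg)); s <- s / s[length(s)]  # arc coord in [0,1]
        prof <- mosaic_amplitudes(s, mosaic_mode, low_frac)
        red <- render_tube(red, path, sigma, amplitude * prof$red)
        green <- render_tube(green, path, sigma, amplitude * prof$green)
        accepted <- rbind(accepted, sub)
        objects[[length(objects) + 1L]] <- list(
          centerline = path, arc = s, sigma_px = sigma,
          length_um = len_um, mode = mosaic_mode,
          red_profile = prof$red, green_profile = prof$green)
        placed <- TRUE
        break
      }
      if (!placed)
        abort_density(sprintf("could not place JC-1 object %d of %d", i,
                              n_objects))
    }
    r <- if (is.null(noise)) round(red) else apply_noise(red, noise)
    g <- if (is.null(noise)) round(green) else apply_noise(green, noise)
    truth <- structure(list(
      seed = seed, kind = "jc1", mosaic_mode = mosaic_mode,
      objects = objects, noise = noise, pixel_size_um = pixel_size_um),
      class = "synthetic_truth")
    list(image = multichannel_image(list(red = r, green = g),
                                    pixel_size_um, source_id = source_id,
                                    condition = condition),
         truth = truth)
  })
}

mosaic_amplitudes <- function(s, mode, low_frac) {
  switch(mode,
    "uniform" = list(red = rep(1, length(s)), green = rep(1, length(s))),
    "half-half" = {
      w <- 1 / (1 + exp(-(s - 0.5) / 0.03))   # 0 -> 1 across the midpoint
      list(red = low_frac + (1 - low_frac) * (1 - w),
           green = low_frac + (1 - low_frac) * w)
    },
    "gradient" = list(red = low_frac + (1 - low_frac) * (1 - s),
                      green = low_frac + (1 - low_frac) * s))
}
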