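gauss_kernels <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  g2 <- (x^2 - sigma^2) / sigma^4 * g
  list(g = g,
       g1 = -x / sigma^2 * g,
       g2 = g2 - mean(g2))  # zero-sum: constant images have zero Hessian
}

conv_sep <- function(img, krow, kcol) {
  out <- EBImage::filter2(img, matrix(krow, length(krow), 1L),
                          boundary = "replicate")
  as.matrix(EBImage::filter2(out, matrix(kcol, 1L, length(kcol)),
                             boundary = "replicate"))
}

#' Multi-scale Frangi tubeness filter
#'
#' Hessian-based vesselness for bright curvilinear structures. At each
#' scale sigma the image is convolved with Gaussian-derivative kernels to
#' obtain the scale-normalized Hessian (multiplied by sigma^2); with
#' eigenvalues ordered `|l1| <= |l2|`, the response is
#' `exp(-Rb^2 / (2 beta^2)) * (1 - exp(-S^2 / (2 gamma^2)))`
#' where `Rb = l1/l2` (blobness) and `S = sqrt(l1^2 + l2^2)`
#' (structureness), zeroed where `l2 >= 0` (dark or non-ridge pixels).
#' The output is the pixel-wise maximum over scales. Round blobs have
#' `Rb ~ 1` and are suppressed relative to tubes (`Rb ~ 0`).
#'
#' @param channel numeric matrix, at least 5x5.
#' @param sigmas Gaussian scales in pixels (default `1:4`).
#' @param beta blobness sensitivity (default 0.5).
#' @param gamma structureness sensitivity; `NULL` (default) auto-scales to
#'   half the maximum structureness observed per image and scale, making
#'   the response independent of bit depth.
#' @return a numeric matrix (`tubeness_map`) with attribute `sigmas`; the
#'   response is >= 0, invariant to additive intensity offsets, and
#'   monotone in multiplicative gain through the structureness term.
#' @export
frangi_tubeness <- function(channel, sigmas = 1:4, beta = 0.5,
                            gamma = NULL) {
  if (nrow(channel) < 5L || ncol(channel) < 5L)
    abort_degenerate("image must be at least 5x5 for tubeness filtering")
  support <- 2L * max(1L, ceiling(4 * max(sigmas))) + 1L
  if (support > min(dim(channel)))
    abort_degenerate(sprintf(
      "image (%dx%d) smaller than the largest kernel support (%d px)",
      nrow(channel), ncol(channel), support))
  out <- matrix(0, nrow(channel), ncol(channel))
  for (s in sigmas) {
    k <- gauss_kernels(s)
    hrr <- s^2 * conv_sep(channel, k$g2, k$g)
    hcc <- s^2 * conv_sep(channel, k$g, k$g2)
    hrc <- s^2 * conv_sep(channel, k$g1, k$g1)
    mid <- (hrr + hcc) / 2
    disc <- sqrt(((hrr - hcc) / 2)^2 + hrc^2)
    ea <- mid + disc; eb <- mid - disc
    swap <- abs(ea) > abs(eb)      # l2 = larger magnitude
    l1 <- ifelse(swap, eb, ea)
    l2 <- ifelse(swap, ea, eb)
    s2 <- l1^2 + l2^2
    # guard against FFT roundoff masquerading as structure on flat images
    if (sqrt(max(s2)) <= 1e-8 * max(abs(channel), 1)) next
    g <- if (is.null(gamma)) sqrt(max(s2)) / 2 else gamma
    if (g <= 0) next
    rb2 <- ifelse(l2 != 0, (l1 / l2)^2, 0)
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-s2 / (2 * g^2)))
    v[l2 >= 0] <- 0
    out <- pmax(out, v)
  }
  structure(out, sigmas = sigmas, class = c("tubeness_map", "matrix", "array"))
}

#' Segment a batch of tubeness maps with one global Otsu threshold
#'
#' The threshold is computed once on the pooled pixels of every map (all
#' experimental conditions together) and applied unchanged to each map,
#' preserving genuine inter-condition intensity differences that
#' per-image thresholding would erase.
#'
#' @param maps list of numeric matrices (tubeness maps).
#' @param connectivity component connectivity, 4 or 8 (default 8).
#' @param bins Otsu histogram bins.
#' @return list of `labeled_objects`, one per map, with attribute
#'   `threshold` (the shared global threshold).
#' @export
segment_batch <- function(maps, connectivity = 8L, bins = 256L) {
  thr <- global_otsu(maps, bins = bins)
  out <- lapply(maps, function(m)
    label_components(unclass_mask(m) > thr, connectivity = connectivity))
  attr(out, "threshold") <- thr
  out
}

# 8-neighbour count of each foreground pixel (matrix of same size)
neighbour_count <- function(mask) {
  m <- matrix(0, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- as.numeric(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  tot <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    tot <- tot + m[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  }
  tot
}

#' Topological skeleton of a binary object
#'
#' Guo--Hall thinning to a 1-px, 8-connected skeleton, followed by
#' pruning of 1-pixel spur branches (endpoints directly attached to a
#' junction), which suppresses digitization spurs on thick tubes.
#'
#' @param mask logical matrix.
#' @param prune_spurs prune 1-px spurs (default TRUE).
#' @return logical matrix of skeleton pixels.
#' @export
skeletonize <- function(mask, prune_spurs = TRUE) {
  m <- unclass_mask(mask)
  storage.mode(m) <- "logical"
  skel <- .gh_thin(m)
  if (prune_spurs && any(skel)) {
    nb <- neighbour_count(skel)
    endpoints <- skel & nb == 1
    junctions <- skel & nb >= 3
    if (any(endpoints) && any(junctions)) {
      jn <- neighbour_count(junctions)   # counts junction neighbours
      drop <- endpoints & jn >= 1
      skel[drop] <- FALSE
    }
  }
  skel
}

# Sum of inter-pixel step lengths over a skeleton: 1 per axial step,
# sqrt(2) per diagonal step, each adjacent pair counted once. Diagonal
# steps that short-circuit an existing axial path (both pixels share an
# axial skeleton neighbour) are skipped to avoid double counting.
skeleton_steps_px <- function(skel) {
  if (!any(skel)) return(0)
  nr <- nrow(skel); nc <- ncol(skel)
  at <- function(r, c) r >= 1 & r <= nr & c >= 1 & c <= nc &
    skel[cbind(pmin(pmax(r, 1L), nr), pmin(pmax(c, 1L), nc))]
  idx <- which(skel, arr.ind = TRUE)
  r <- idx[, 1]; c <- idx[, 2]
  n_axial <- sum(at(r, c + 1L)) + sum(at(r + 1L, c))
  se <- at(r + 1L, c + 1L) & !(at(r, c + 1L) & at(r + 1L, c))
  ne <- at(r - 1L, c + 1L) & !(at(r, c + 1L) & at(r - 1L, c))
  n_axial + sqrt(2) * (sum(se) + sum(ne))
}

#' Skeleton-based length of an object in micrometers
#'
#' Skeletonizes the object and sums the inter-pixel steps of the skeleton
#' (1 px for axial, sqrt(2) px for diagonal steps), converted to um. For
#' branched skeletons the length is the total over all branches. A
#' single-pixel object has length 0.
#'
#' @param object_mask logical matrix of one object.
#' @param pixel_size_um um per pixel.
#' @param prune_spurs passed to [skeletonize()].
#' @return length in micrometers.
#' @export
skeleton_length <- function(object_mask, pixel_size_um, prune_spurs = TRUE) {
  skel <- skeletonize(object_mask, prune_spurs = prune_spurs)
  skeleton_steps_px(skel) * pixel_size_um
}

#' Aspect ratio of an object from its second-moment ellipse
#'
#' Ratio of major to minor axis length of the intensity-unweighted
#' second-central-moment ellipse of the object's pixel set (axis length
#' `4 sqrt(eigenvalue)`, the standard ellipse-of-inertia convention). The
#' minor axis is floored at 1 px so 1-px-thin lines get a finite, large
#' ratio instead of a division by zero.
#'
#' @param object_mask logical matrix with >= 2 foreground pixels.
#' @return aspect ratio >= 1.
#' @export
aspect_ratio <- function(object_mask) {
  idx <- which(unclass_mask(object_mask), arr.ind = TRUE)
  if (nrow(idx) < 2L) abort_degenerate("need >= 2 pixels for an aspect ratio")
  n <- nrow(idx)
  mu <- colMeans(idx)
  xr <- idx[, 1] - mu[1]; xc <- idx[, 2] - mu[2]
  crr <- sum(xr^2) / n; ccc <- sum(xc^2) / n; crc <- sum(xr * xc) / n
  mid <- (crr + ccc) / 2
  disc <- sqrt(((crr - ccc) / 2)^2 + crc^2)
  major <- 4 * sqrt(max(mid + disc, 0))
  minor <- max(4 * sqrt(max(mid - disc, 0)), 1)
  max(major / minor, 1)
}

#' Filter measured objects by skeleton length
#'
#' Keeps objects whose length lies in the closed interval
#' `[min_um, max_um]`; objects outside are counted as too-small or
#' too-large (over-long objects typically correspond to fused networks
#' and are tallied separately rather than measured).
#'
#' @param objects data.frame with a `skeleton_length_um` column (or the
#'   column named in `metric`).
#' @param min_um,max_um closed length bounds in micrometers.
#' @param metric column to filter on (default `"skeleton_length_um"`).
#' @return list with `retained` (data.frame), `n_too_small`,
#'   `n_too_large`.
#' @export
size_filter <- function(objects, min_um = 1, max_um = 20,
                        metric = "skeleton_length_um") {
  if (min_um > max_um) abort_config("min_um must be <= max_um")
  if (nrow(objects) == 0L)
    return(list(retained = objects, n_too_small = 0L, n_too_large = 0L))
  len <- objects[[metric]]
  keep <- len >= min_um & len <= max_um
  list(retained = objects[keep, , drop = FALSE],
       n_too_small = sum(len < min_um),
       n_too_large = sum(len > max_um))
}

#' Measure labeled objects
#'
#' Per-object area, centroid, border contact, skeleton length and aspect
#' ratio (and the major-axis length in um, usable as an alternative
#' length metric).
#'
#' @param labels a `labeled_objects` matrix.
#' @param pixel_size_um um per pixel.
#' @param source_id,condition labels copied to every row.
#' @return data.frame, one row per object.
#' @export
measure_objects <- function(labels, pixel_size_um,
                            source_id = "", condition = "") {
  n <- attr(labels, "n")
  if (is.null(n)) n <- max(labels)
  if (n == 0L)
    return(data.frame(label = integer(0), area_px = integer(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      touches_border = logical(0),
                      skeleton_length_um = numeric(0),
                      major_axis_um = numeric(0),
                      aspect_ratio = numeric(0),
                      source_id = character(0), condition = character(0),
                      stringsAsFactors = FALSE))
  nr <- nrow(labels); nc <- ncol(labels)
  idx <- which(labels > 0L, arr.ind = TRUE)
  lab <- labels[idx]
  rows <- split(idx[, 1], lab); cols <- split(idx[, 2], lab)
  res <- lapply(seq_len(n), function(i) {
    r <- rows[[as.character(i)]]; c <- cols[[as.character(i)]]
    r0 <- min(r); r1 <- max(r); c0 <- min(c); c1 <- max(c)
    sub <- matrix(FALSE, r1 - r0 + 3L, c1 - c0 + 3L)  # 1-px pad
    sub[cbind(r - r0 + 2L, c - c0 + 2L)] <- TRUE
    ar <- if (length(r) >= 2L) aspect_ratio(sub) else 1
    # major axis from the same second-moment ellipse
    n_px <- length(r)
    mu_r <- mean(r); mu_c <- mean(c)
    crr <- sum((r - mu_r)^2) / n_px; ccc <- sum((c - mu_c)^2) / n_px
    crc <- sum((r - mu_r) * (c - mu_c)) / n_px
    major_px <- 4 * sqrt(max((crr + ccc) / 2 +
                             sqrt(((crr - ccc) / 2)^2 + crc^2), 0))
    data.frame(
      label = i, area_px = n_px,
      centroid_row = mu_r, centroid_col = mu_c,
      touches_border = any(r == 1L | r == nr | c == 1L | c == nc),
      skeleton_length_um = skeleton_length(sub, pixel_size_um),
      major_axis_um = major_px * pixel_size_um,
      aspect_ratio = ar,
      source_id = source_id, condition = condition,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Mitochondrial morphometry pipeline over a batch of images
#'
#' For each image: multi-scale Frangi tubeness on the mitochondrial
#' channel; then one batch-global Otsu threshold over all tubeness maps;
#' connected components; per-object skeleton length and aspect ratio;
#' a closed-interval length filter (default 1--20 um, excluding noise
#' specks and fused networks); and per-condition summaries.
#'
#' @param images list of [multichannel_image()] objects (all conditions of
#'   the batch together, so the global threshold spans conditions).
#' @param channel role of the mitochondrial channel in every image.
#' @param sigmas Frangi scales (default `1:4`).
#' @param min_um,max_um length filter bounds (default 1 and 20).
#' @param connectivity component connectivity (default 8).
#' @param bins Otsu bins.
#' @param length_metric `"skeleton_length_um"` (default) or
#'   `"major_axis_um"`.
#' @param include_border keep border-touching objects (default TRUE; they
#'   are flagged in the table either way).
#' @return list with `objects` (retained per-object table), `summary`
#'   (per-condition mean/median/sd length, aspect ratio, n, exclusion
#'   counts), `threshold` (global Otsu value), `n_too_small`,
#'   `n_too_large`.
#' @export
morphometry_pipeline <- function(images, channel, sigmas = 1:4,
                                 min_um = 1, max_um = 20,
                                 connectivity = 8L, bins = 256L,
                                 length_metric = "skeleton_length_um",
                                 include_border = TRUE) {
  if (length(images) == 0L) abort_config("need at least one image")
  maps <- lapply(images, function(im)
    frangi_tubeness(get_channel(im, channel), sigmas = sigmas))
  labs <- tryCatch(
    segment_batch(maps, connectivity = connectivity, bins = bins),
    fluoquant_degenerate_input = function(e) {
      # structure-free batch (pooled tubeness constant): no objects anywhere
      out <- lapply(maps, function(m)
        label_components(matrix(FALSE, nrow(m), ncol(m)),
                         connectivity = connectivity))
      attr(out, "threshold") <- NA_real_
      out
    })
  objects <- do.call(rbind, lapply(seq_along(images), function(i)
    measure_objects(labs[[i]], images[[i]]$pixel_size_um,
                    source_id = images[[i]]$source_id,
                    condition = images[[i]]$condition)))
  if (!include_border && nrow(objects) > 0L)
    objects <- objects[!objects$touches_border, , drop = FALSE]
  filt <- size_filter(objects, min_um = min_um, max_um = max_um,
                      metric = length_metric)
  retained <- filt$retained
  conds <- unique(vapply(images, `[[`, character(1), "condition"))
  summ <- summarize_by_condition(retained, objects, min_um, max_um,
                                 length_metric, conditions = conds)
  list(objects = retained, all_objects = objects, summary = summ,
       threshold = attr(labs, "threshold"),
       n_too_small = filt$n_too_small, n_too_large = filt$n_too_large)
}

summarize_by_condition <- function(retained, all_objects, min_um, max_um,
                                   metric, conditions = NULL) {
  conds <- if (is.null(conditions)) unique(all_objects$condition)
           else conditions
  rows <- lapply(conds, function(cd) {
    r <- retained[retained$condition == cd, , drop = FALSE]
    a <- all_objects[all_objects$condition == cd, , drop = FALSE]
    len <- r[[metric]]
    data.frame(
      condition = cd, n = nrow(r),
      mean_length_um = if (nrow(r)) mean(len) else NA_real_,
      median_length_um = if (nrow(r)) median(len) else NA_real_,
      sd_length_um = if (nrow(r) > 1) sd(len) else NA_real_,
      mean_aspect_ratio = if (nrow(r)) mean(r$aspect_ratio) else NA_real_,
      median_aspect_ratio = if (nrow(r)) median(r$aspect_ratio) else NA_real_,
      n_excluded_small = sum(a[[metric]] < min_um),
      n_excluded_large = sum(a[[metric]] > max_um),
      stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L)
    return(data.frame(condition = character(0), n = integer(0)))
  do.call(rbind, rows)
}
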