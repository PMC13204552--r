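#' Otsu threshold of an intensity sample
#'
#' Computes the threshold maximizing the between-class variance of a
#' 256-bin histogram spanning the observed min--max of the values. The
#' same fixed binning is used regardless of bit depth so that 8- and
#' 16-bit inputs are handled identically. Foreground is defined as
#' strictly greater than the returned threshold; ties go to background.
#'
#' @param values numeric vector/matrix of intensities (NAs dropped).
#' @param bins number of histogram bins (default 256).
#' @return the threshold, a scalar strictly inside the value range.
#' @export
otsu_threshold <- function(values, bins = 256L) {
  v <- as.numeric(values)
  v <- v[!is.na(v)]
  if (length(v) < 2L) abort_degenerate("need at least 2 values")
  lo <- min(v); hi <- max(v)
  if (lo == hi) abort_degenerate("constant input: Otsu threshold undefined")
  edges <- seq(lo, hi, length.out = bins + 1L)
  # bin i covers (edges[i], edges[i+1]]; the minimum lands in bin 1
  idx <- findInterval(v, edges, rightmost.closed = TRUE, left.open = TRUE)
  idx[idx < 1L] <- 1L
  counts <- tabulate(idx, nbins = bins)
  mids <- (edges[-1] + edges[-(bins + 1L)]) / 2
  w <- cumsum(counts)
  m <- cumsum(counts * mids)
  n <- w[bins]; mt <- m[bins]
  # candidate k: classes {bins 1..k} vs {k+1..bins}, threshold = edges[k+1]
  k <- seq_len(bins - 1L)
  w0 <- w[k]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, bins - 1L)
  mu0 <- m[k][valid] / w0[valid]
  mu1 <- (mt - m[k][valid]) / w1[valid]
  sigma_b[valid] <- (w0[valid] / n) * (w1[valid] / n) *
    (mu0 - mu1)^2
  best <- which.max(sigma_b)  # smallest index on ties
  edges[best + 1L]
}

#' Binary mask of one channel: Otsu threshold plus morphological closing
#'
#' Threshold with [otsu_threshold()] (strictly greater than), then close
#' with a disc structuring element to fill small holes and gaps. The
#' threshold and closing radius applied are recorded as provenance.
#'
#' @param channel numeric matrix.
#' @param closing_radius disc radius in pixels; `0` skips closing.
#' @param bins histogram bins for Otsu.
#' @return a `binary_mask`: logical matrix with attributes `threshold`
#'   and `closing_radius`.
#' @export
channel_mask <- function(channel, closing_radius = 1L, bins = 256L) {
  thr <- otsu_threshold(channel, bins = bins)
  mask <- channel > thr
  if (closing_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(closing_radius) + 1L, "disc")
    closed <- EBImage::closing(
      matrix(as.numeric(mask), nrow(mask), ncol(mask)), brush)
    mask <- as.matrix(closed) > 0.5
  }
  binary_mask(mask, threshold = thr, closing_radius = closing_radius)
}

binary_mask <- function(mask, threshold = NA_real_, closing_radius = NA,
                        ...) {
  structure(mask, threshold = threshold, closing_radius = closing_radius,
            ..., class = c("binary_mask", class(mask)))
}

#' Combined red/green mask for dual-channel JC-1 images
#'
#' Segments pixels bright in either dye form. The default (`"union"`)
#' takes the union of the per-channel Otsu masks so that organelles
#' dominated by only one JC-1 form (pure monomer or pure aggregate) are
#' retained; `"sum"` instead thresholds the summed channel.
#'
#' @param red,green numeric matrices of equal size.
#' @param mode `"union"` or `"sum"`.
#' @param closing_radius disc radius for closing each per-channel mask
#'   (union mode) or the sum mask; `0` (default) disables closing.
#' @param bins Otsu histogram bins.
#' @return a `binary_mask` with attributes `threshold_red`,
#'   `threshold_green` (union mode) or `threshold_sum` (sum mode).
#' @export
combined_channel_mask <- function(red, green, mode = c("union", "sum"),
                                  closing_radius = 0L, bins = 256L) {
  mode <- match.arg(mode)
  if (!identical(dim(red), dim(green)))
    abort_config("red and green channels must have equal shapes")
  if (mode == "sum") {
    m <- channel_mask(red + green, closing_radius = closing_radius,
                      bins = bins)
    return(binary_mask(unclass_mask(m), threshold_sum = attr(m, "threshold"),
                       closing_radius = closing_radius, mode = mode))
  }
  mk <- function(ch) tryCatch(
    channel_mask(ch, closing_radius = closing_radius, bins = bins),
    fluoquant_degenerate_input = function(e) NULL)
  mr <- mk(red); mg <- mk(green)
  if (is.null(mr) && is.null(mg))
    abort_degenerate("both channels constant: combined mask undefined")
  u <- if (is.null(mr)) unclass_mask(mg)
       else if (is.null(mg)) unclass_mask(mr)
       else unclass_mask(mr) | unclass_mask(mg)
  binary_mask(u,
              threshold_red = if (is.null(mr)) NA_real_ else attr(mr, "threshold"),
              threshold_green = if (is.null(mg)) NA_real_ else attr(mg, "threshold"),
              closing_radius = closing_radius, mode = mode)
}

unclass_mask <- function(m) {
  attributes(m) <- list(dim = dim(m))
  m
}

#' Batch-global Otsu threshold
#'
#' One threshold computed on the pooled pixel values of every image in a
#' batch, so the same cut is applied to all experimental conditions and
#' inter-condition intensity differences are preserved rather than
#' equalized by per-image thresholding. Invariant to batch order and to
#' splitting/merging images with the same pooled pixels.
#'
#' @param batch list of numeric matrices (or vectors).
#' @param bins Otsu histogram bins.
#' @return the pooled threshold.
#' @export
global_otsu <- function(batch, bins = 256L) {
  if (!is.list(batch) || length(batch) == 0L)
    abort_config("'batch' must be a non-empty list of intensity grids")
  pooled <- unlist(lapply(batch, as.numeric), use.names = FALSE)
  otsu_threshold(pooled, bins = bins)
}

#' Label connected foreground components
#'
#' @param mask logical matrix (or `binary_mask`).
#' @param connectivity 4 or 8 (default 8).
#' @return a `labeled_objects`: integer matrix with 0 background and
#'   labels `1..n`, attributes `n` and `connectivity`.
#' @export
label_components <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L))
    abort_config("connectivity must be 4 or 8")
  m <- unclass_mask(mask)
  storage.mode(m) <- "logical"
  lab <- .cc_label(m, as.integer(connectivity))
  structure(lab, connectivity = as.integer(connectivity),
            class = c("labeled_objects", class(lab)))
}

#' @export
print.labeled_objects <- function(x, ...) {
  cat(sprintf("<labeled_objects> %dx%d px, %d object(s), %d-connected\n",
              nrow(x), ncol(x), attr(x, "n"), attr(x, "connectivity")))
  invisible(x)
}
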