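#' Construct a multi-channel image
#'
#' Container for a calibrated 2-D multi-channel fluorescence image. All
#' channels are numeric matrices of identical size; intensities are kept
#' on their native scale (no rescaling or histogram stretching).
#'
#' @param channels named list of numeric matrices, one per channel; names
#'   are the channel roles (e.g. `"red"`, `"green"`, `"farred"`).
#' @param pixel_size_um physical pixel size in micrometers per pixel.
#' @param source_id identifier of the source image (defaults to `""`).
#' @param condition experimental-condition label (defaults to `""`).
#' @return an object of class `multichannel_image`.
#' @export
multichannel_image <- function(channels, pixel_size_um,
                               source_id = "", condition = "") {
  if (!is.list(channels) || length(channels) == 0L)
    abort_config("'channels' must be a non-empty named list of matrices")
  nm <- names(channels)
  if (is.null(nm) || anyNA(nm) || any(nm == "") || anyDuplicated(nm))
    abort_config("channel names must be unique and non-empty")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, logical(1))))
    abort_config("every channel must be a matrix")
  d0 <- dims[[1]]
  if (!all(vapply(dims, function(d) identical(d, d0), logical(1))))
    abort_config("all channels must share identical height x width")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      is.na(pixel_size_um) || pixel_size_um <= 0)
    abort_config("'pixel_size_um' must be a positive scalar")
  channels <- lapply(channels, function(ch) {
    storage.mode(ch) <- "double"
    ch
  })
  structure(
    list(channels = channels, pixel_size_um = as.numeric(pixel_size_um),
         source_id = as.character(source_id),
         condition = as.character(condition)),
    class = "multichannel_image"
  )
}

#' @export
print.multichannel_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<multichannel_image> %dx%d px, %.4g um/px, channels: %s\n",
              d[1], d[2], x$pixel_size_um,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Extract a channel matrix by role
#'
#' @param image a [multichannel_image()].
#' @param role channel role name.
#' @return numeric matrix.
#' @export
get_channel <- function(image, role) {
  stopifnot(inherits(image, "multichannel_image"))
  if (!role %in% names(image$channels))
    abort_config(sprintf("channel role '%s' not present (have: %s)", role,
                         paste(names(image$channels), collapse = ", ")))
  image$channels[[role]]
}

#' Load a multi-channel TIFF image
#'
#' Reads an 8/12/16-bit unsigned TIFF, either multi-page (one page per
#' channel) or a single page with an interleaved channel axis, and labels
#' the channels by role. Integer sample values are preserved exactly; no
#' normalization or rescaling is applied on load.
#'
#' @param path path to a TIFF file.
#' @param channel_roles character vector of role names, one per channel,
#'   in channel order.
#' @param pixel_size_um calibration in micrometers per pixel.
#' @param channel_axis for single-page planar arrays, which array axis
#'   indexes channels; `NA` (default) auto-detects the smallest axis of
#'   length <= 5.
#' @param source_id,condition metadata labels stored on the image.
#' @return a [multichannel_image()].
#' @export
load_image <- function(path, channel_roles, pixel_size_um,
                       channel_axis = NA, source_id = basename(path),
                       condition = "") {
  if (!file.exists(path))
    abort_format(sprintf("file not found: %s", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      abort_format(sprintf("unreadable TIFF '%s': %s",
                                           path, conditionMessage(e))))
  if (length(pages) > 1L) {
    chans <- lapply(pages, function(p) {
      if (length(dim(p)) != 2L)
        abort_format("multi-page TIFF with non-2-D pages is not supported")
      p
    })
  } else {
    p <- pages[[1]]
    if (length(dim(p)) == 2L) {
      chans <- list(p)
    } else if (length(dim(p)) == 3L) {
      ax <- channel_axis
      if (is.na(ax)) {
        cand <- which(dim(p) <= 5L)
        if (length(cand) == 0L)
          abort_config("cannot auto-detect channel axis; pass 'channel_axis'")
        ax <- cand[which.min(dim(p)[cand])]
      }
      chans <- lapply(seq_len(dim(p)[ax]), function(k) {
        switch(ax, p[k, , ], p[, k, ], p[, , k])
      })
    } else {
      abort_format("TIFF page has unsupported dimensionality")
    }
  }
  if (length(chans) != length(channel_roles))
    abort_config(sprintf(
      "file has %d channel(s) but %d role(s) were requested",
      length(chans), length(channel_roles)))
  names(chans) <- channel_roles
  multichannel_image(chans, pixel_size_um,
                     source_id = source_id, condition = condition)
}

#' Write a multi-channel image as a 16-bit multi-page TIFF
#'
#' Inverse of [load_image()] for integer-valued images with intensities
#' in `[0, 65535]`: one page per channel, bit-exact round trip.
#'
#' @param image a [multichannel_image()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_image <- function(image, path) {
  stopifnot(inherits(image, "multichannel_image"))
  pages <- lapply(image$channels, function(ch) {
    if (any(ch < 0) || any(ch > 65535))
      abort_config("pixel values outside [0, 65535] cannot be written as 16-bit")
    round(ch) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write result records to a CSV table
#'
#' One row per record, with header; numeric fields are serialized at full
#' double precision (`%.17g`) so a read-back reproduces the values.
#'
#' @param records a data.frame, or a list of homogeneous named lists/rows.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  if (is.data.frame(records)) {
    df <- records
  } else if (is.list(records)) {
    if (length(records) == 0L)
      abort_config("empty record list without field names; pass a data.frame")
    fields <- names(records[[1]])
    ok <- vapply(records, function(r) identical(names(r), fields), logical(1))
    if (!all(ok)) abort_config("records have heterogeneous fields")
    df <- do.call(rbind, lapply(records, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  } else {
    abort_config("'records' must be a data.frame or list of records")
  }
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  ok <- tryCatch({
    write.csv(out, path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) fq_error("fluoquant_io_error", sprintf("cannot write '%s'", path))
  invisible(path)
}

#' Read a batch manifest
#'
#' A manifest is a CSV with columns `path`, `condition`, `channels`
#' (channel roles in order, separated by `;`), and optionally
#' `pixel_size_um` (falls back to `default_pixel_size_um`).
#'
#' @param path manifest CSV path.
#' @param default_pixel_size_um calibration used for entries lacking a
#'   `pixel_size_um` column/value.
#' @return a `batch_manifest`: data.frame with columns `path`,
#'   `condition`, `channels` (list column of role vectors), `pixel_size_um`.
#' @export
read_manifest <- function(path, default_pixel_size_um = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "condition", "channels")
  if (!all(need %in% names(df)))
    abort_config(sprintf("manifest must have columns: %s",
                         paste(need, collapse = ", ")))
  if (nrow(df) == 0L) abort_config("manifest has no entries")
  roles <- strsplit(df$channels, ";", fixed = TRUE)
  if (is.null(df$pixel_size_um)) {
    if (is.null(default_pixel_size_um))
      abort_config("manifest lacks pixel_size_um and no default was given")
    df$pixel_size_um <- default_pixel_size_um
  }
  bad <- is.na(df$pixel_size_um) | df$pixel_size_um <= 0
  if (any(bad)) abort_config("manifest pixel_size_um must be positive")
  rel <- !file.exists(df$path) & file.exists(file.path(dirname(path), df$path))
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  out <- data.frame(path = df$path, condition = df$condition,
                    pixel_size_um = df$pixel_size_um,
                    stringsAsFactors = FALSE)
  out$channels <- roles
  class(out) <- c("batch_manifest", "data.frame")
  out
}

#' Write a batch manifest CSV
#'
#' @param manifest a data.frame with columns `path`, `condition`,
#'   `channels` (list of role vectors or `;`-joined strings),
#'   `pixel_size_um`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  ch <- manifest$channels
  if (is.list(ch)) ch <- vapply(ch, paste, character(1), collapse = ";")
  df <- data.frame(path = manifest$path, condition = manifest$condition,
                   channels = ch, pixel_size_um = manifest$pixel_size_um,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
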