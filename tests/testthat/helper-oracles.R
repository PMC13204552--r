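# Independent brute-force oracles used to cross-check the package's
# statistics, plus small fixture builders. These deliberately avoid the
# package's own code paths.

# Two-pass Pearson from the definition: cov / (sd_a * sd_b)
oracle_pearson <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n; mb <- sum(b) / n
  cov <- sum((a - ma) * (b - mb)) / (n - 1)
  cov / sqrt(sum((a - ma)^2) / (n - 1)) / sqrt(sum((b - mb)^2) / (n - 1))
}

oracle_manders <- function(a, b, mask_a, mask_b) {
  num1 <- 0; den1 <- 0; num2 <- 0; den2 <- 0
  for (i in seq_along(a)) {
    if (mask_a[i]) {
      den1 <- den1 + a[i]
      if (mask_b[i]) num1 <- num1 + a[i]
    }
    if (mask_b[i]) {
      den2 <- den2 + b[i]
      if (mask_a[i]) num2 <- num2 + b[i]
    }
  }
  c(m1 = num1 / den1, m2 = num2 / den2)
}

oracle_icq <- function(a, b, mask) {
  av <- a[mask]; bv <- b[mask]
  da <- av - mean(av); db <- bv - mean(bv)
  pos <- 0; nz <- 0
  for (i in seq_along(da)) {
    p <- da[i] * db[i]
    if (p != 0) {
      nz <- nz + 1
      if (p > 0) pos <- pos + 1
    }
  }
  pos / nz - 0.5
}

# Exhaustive Otsu: recompute between-class variance from the histogram for
# every interior bin edge, with naive (non-cumulative) sums.
oracle_otsu <- function(values, bins = 256L) {
  v <- as.numeric(values)
  edges <- seq(min(v), max(v), length.out = bins + 1L)
  idx <- findInterval(v, edges, rightmost.closed = TRUE, left.open = TRUE)
  idx[idx < 1L] <- 1L
  counts <- tabulate(idx, nbins = bins)
  mids <- (edges[-1] + edges[-(bins + 1L)]) / 2
  n <- sum(counts)
  best_k <- NA_integer_; best_v <- -Inf
  for (k in seq_len(bins - 1L)) {
    c0 <- counts[1:k]; c1 <- counts[(k + 1):bins]
    w0 <- sum(c0); w1 <- sum(c1)
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(c0 * mids[1:k]) / w0
    mu1 <- sum(c1 * mids[(k + 1):bins]) / w1
    vb <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
    if (vb > best_v) { best_v <- vb; best_k <- k }
  }
  edges[best_k + 1L]
}

# Recursive flood-fill labeling oracle (queue-based), small masks only.
oracle_label <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nbrs <- if (connectivity == 4L)
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  else
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  cur <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    cur <- cur + 1L
    queue <- list(c(r0, c0)); lab[r0, c0] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nbrs))) {
        r <- p[1] + nbrs[k, 1]; c <- p[2] + nbrs[k, 2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- cur
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# Naive binary dilation / erosion with an arbitrary structuring element.
oracle_dilate <- function(mask, se) {
  nr <- nrow(mask); nc <- ncol(mask)
  rr <- (nrow(se) - 1L) / 2L; rc <- (ncol(se) - 1L) / 2L
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    hit <- FALSE
    for (i in -rr:rr) for (j in -rc:rc) {
      if (!se[i + rr + 1L, j + rc + 1L]) next
      ri <- r + i; cj <- c + j
      if (ri >= 1 && ri <= nr && cj >= 1 && cj <= nc && mask[ri, cj])
        hit <- TRUE
    }
    out[r, c] <- hit
  }
  out
}

oracle_erode <- function(mask, se) {
  nr <- nrow(mask); nc <- ncol(mask)
  rr <- (nrow(se) - 1L) / 2L; rc <- (ncol(se) - 1L) / 2L
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    all_in <- TRUE
    for (i in -rr:rr) for (j in -rc:rc) {
      if (!se[i + rr + 1L, j + rc + 1L]) next
      ri <- r + i; cj <- c + j
      inside <- ri >= 1 && ri <= nr && cj >= 1 && cj <= nc && mask[ri, cj]
      if (!inside) all_in <- FALSE
    }
    out[r, c] <- all_in
  }
  out
}

# Map each ground-truth tube to the label covering most of its centerline;
# NA when the tube was not segmented.
match_truth_tubes <- function(labels, truth) {
  vapply(truth$tubes, function(tb) {
    p <- round(tb$centerline)
    p[, 1] <- pmin(pmax(p[, 1], 1L), nrow(labels))
    p[, 2] <- pmin(pmax(p[, 2], 1L), ncol(labels))
    l <- labels[p]
    l <- l[l > 0]
    if (!length(l)) return(NA_integer_)
    tab <- table(l)
    as.integer(names(tab)[which.max(tab)])
  }, integer(1))
}

# A tiny deterministic 2-channel image for I/O tests.
tiny_two_channel <- function(seed = 42L, size = 64L) {
  set.seed(seed)
  a <- matrix(sample.int(65536L, size * size, replace = TRUE) - 1L, size)
  b <- matrix(sample.int(65536L, size * size, replace = TRUE) - 1L, size)
  multichannel_image(list(red = a, green = b), pixel_size_um = 0.1,
                     source_id = "tiny", condition = "test")
}
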