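make_gauss_tube <- function(size, r0, c0, r1, c1, sigma = 1.5, amp = 500) {
  img <- matrix(0, size, size)
  n <- ceiling(sqrt((r1 - r0)^2 + (c1 - c0)^2) * 4)
  t <- seq(0, 1, length.out = n)
  for (k in seq_len(n)) {
    pr <- r0 + t[k] * (r1 - r0); pc <- c0 + t[k] * (c1 - c0)
    rr <- max(1, floor(pr - 6)):min(size, ceiling(pr + 6))
    cc <- max(1, floor(pc - 6)):min(size, ceiling(pc + 6))
    d2 <- outer((rr - pr)^2, (cc - pc)^2, "+")
    img[rr, cc] <- pmax(img[rr, cc], amp * exp(-d2 / (2 * sigma^2)))
  }
  img
}

test_that("Frangi responds on tube centerlines, not on flat fields or round blobs", {
  tube <- make_gauss_tube(64, 32, 8, 32, 56)
  tb <- frangi_tubeness(tube)
  centerline <- mean(tb[32, 12:52])
  background <- mean(tb[c(1:15, 49:64), 12:52])
  expect_gt(centerline, 10 * background)
  expect_equal(max(frangi_tubeness(matrix(5, 64, 64))), 0)
  d2 <- outer((1:64 - 32)^2, (1:64 - 32)^2, "+")
  blob <- 500 * exp(-d2 / (2 * 1.5^2))
  expect_gt(max(tb[32, 12:52]), max(frangi_tubeness(blob)))
  expect_error(frangi_tubeness(matrix(rnorm(16), 4, 4)),
               class = "fluoquant_degenerate_input")
  expect_error(frangi_tubeness(matrix(rnorm(100), 10, 10), sigmas = 1:4),
               class = "fluoquant_degenerate_input")  # kernel > image
})

test_that("Frangi is offset-invariant and gain-monotone through the structureness term", {
  tube <- make_gauss_tube(64, 20, 8, 44, 56, sigma = 2)
  base <- frangi_tubeness(tube)
  shifted <- frangi_tubeness(tube + 250)
  expect_equal(unclass(shifted), unclass(base), tolerance = 1e-6)
  # auto-scaled gamma makes the response gain-invariant; a fixed gamma
  # makes it monotone in gain
  gained <- frangi_tubeness(tube * 3)
  expect_equal(unclass(gained), unclass(base), tolerance = 1e-6)
  fixed_lo <- frangi_tubeness(tube, gamma = 500)
  fixed_hi <- frangi_tubeness(2 * tube, gamma = 500)
  expect_true(all(fixed_hi - fixed_lo >= -1e-9))
})

test_that("skeleton length measures bars, single pixels and L-shapes", {
  bar <- matrix(FALSE, 9, 27); bar[4:6, 4:24] <- TRUE   # 21 px long, 3 tall
  expect_lt(abs(skeleton_length(bar, 0.1) - 2.0), 0.2)
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_equal(skeleton_length(one, 0.1), 0)
  # two 21-px arms sharing a corner: unique centerline ~ 40 px = 4.0 um
  L <- matrix(FALSE, 30, 30)
  L[5:25, 5:7] <- TRUE; L[23:25, 5:25] <- TRUE
  expect_lt(abs(skeleton_length(L, 0.1) - 4.0), 0.6)
})

test_that("skeleton length tracks true length for straight tubes of varied width and angle", {
  set.seed(61)
  for (i in 1:25) {
    len <- runif(1, 15, 60)
    ang <- runif(1, 0, pi)
    sigma <- runif(1, 1, 2.5)
    ctr <- c(50, 50)
    r0 <- ctr[1] - len / 2 * sin(ang); r1 <- ctr[1] + len / 2 * sin(ang)
    c0 <- ctr[2] - len / 2 * cos(ang); c1 <- ctr[2] + len / 2 * cos(ang)
    tube <- make_gauss_tube(100, r0, c0, r1, c1, sigma = sigma)
    mask <- tube > 250   # half-maximum cut
    est <- skeleton_length(mask, 1)
    expect_lt(abs(est - len) / len, 0.15,
              label = sprintf("tube %d len %.1f sigma %.1f ang %.2f est %.1f",
                              i, len, sigma, ang, est))
  }
})

test_that("aspect ratio follows second-moment geometry with a floored minor axis", {
  sq <- matrix(TRUE, 12, 12)
  expect_lt(abs(aspect_ratio(sq) - 1), 0.05)
  bar <- matrix(FALSE, 12, 48); bar[5:8, 5:44] <- TRUE   # 40 x 4
  expect_lt(abs(aspect_ratio(bar) - 10) / 10, 0.15)
  line1 <- matrix(FALSE, 5, 34); line1[3, 3:32] <- TRUE  # 1-px thin, 30 long
  ar <- aspect_ratio(line1)
  expect_true(is.finite(ar))
  expect_gte(ar, 20)
  expect_error(aspect_ratio(matrix(c(TRUE, FALSE, FALSE, FALSE), 2)),
               class = "fluoquant_degenerate_input")
})

test_that("size filter keeps the closed interval and accounts for every object", {
  obj <- data.frame(label = 1:3, skeleton_length_um = c(0.5, 5, 25))
  f <- size_filter(obj, 1, 20)
  expect_equal(f$retained$label, 2L)
  expect_equal(f$n_too_small, 1L)
  expect_equal(f$n_too_large, 1L)
  # boundary values are retained (closed interval)
  edge <- data.frame(label = 1:2, skeleton_length_um = c(1.0, 20.0))
  expect_equal(nrow(size_filter(edge, 1, 20)$retained), 2L)
  empty <- size_filter(obj[0, ], 1, 20)
  expect_equal(nrow(empty$retained), 0L)
  expect_equal(empty$n_too_small + empty$n_too_large, 0L)
  expect_error(size_filter(obj, 5, 1), class = "fluoquant_config_error")
  # property: retained + excluded == total, never outside bounds
  set.seed(9)
  for (i in 1:20) {
    o <- data.frame(skeleton_length_um = runif(30, 0, 30))
    f <- size_filter(o, 1, 20)
    expect_equal(nrow(f$retained) + f$n_too_small + f$n_too_large, 30L)
    expect_true(all(f$retained$skeleton_length_um >= 1 &
                    f$retained$skeleton_length_um <= 20))
  }
})

test_that("batch segmentation shares one threshold and preserves gain differences", {
  base <- make_gauss_tube(64, 32, 8, 32, 56, amp = 300) +
    matrix(runif(4096, 0, 10), 64)
  gained <- base * 2
  labs <- segment_batch(list(base, gained))
  thr <- attr(labs, "threshold")
  expect_identical(thr, global_otsu(list(base, gained)))
  fg1 <- sum(labs[[1]] > 0); fg2 <- sum(labs[[2]] > 0)
  expect_false(fg1 == fg2)  # per-image Otsu would equalize these
  # identical duplicate maps -> identical labelings
  labs2 <- segment_batch(list(base, base))
  expect_identical(unclass(labs2[[1]])[, ], unclass(labs2[[2]])[, ])
  # permutation invariance of the shared threshold
  expect_identical(attr(segment_batch(list(gained, base)), "threshold"), thr)
})

test_that("morphometry pipeline recovers per-condition mean lengths and is duplication-stable", {
  imgs <- list()
  for (s in 1:6) {
    imgs[[s]] <- make_tube_field(n_tubes = 5, length_um_range = c(1.5, 2.5),
                                 size = 192L, seed = 400 + s,
                                 condition = "short",
                                 source_id = sprintf("s%d", s))$image
  }
  for (s in 1:6) {
    imgs[[6 + s]] <- make_tube_field(n_tubes = 4, length_um_range = c(5, 7),
                                     size = 192L, seed = 500 + s,
                                     condition = "long",
                                     source_id = sprintf("l%d", s))$image
  }
  res <- morphometry_pipeline(imgs, "mito")
  s <- res$summary
  expect_setequal(s$condition, c("short", "long"))
  m_short <- s$mean_length_um[s$condition == "short"]
  m_long <- s$mean_length_um[s$condition == "long"]
  expect_lt(abs(m_short - 2) / 2, 0.15)
  expect_lt(abs(m_long - 6) / 6, 0.15)
  expect_gt(m_long, m_short)
  # duplicating a condition under a new name reproduces its summary
  dup <- lapply(imgs[1:6], function(im) { im$condition <- "short2"; im })
  res2 <- morphometry_pipeline(c(imgs[1:6], dup), "mito")
  s2 <- res2$summary
  expect_equal(s2$mean_length_um[s2$condition == "short2"],
               s2$mean_length_um[s2$condition == "short"])
  # a structure-free (flat) image mixed into the batch yields no objects
  blank <- list(multichannel_image(
    list(mito = matrix(100, 192, 192)), 0.1,
    source_id = "blank", condition = "none"))
  res3 <- morphometry_pipeline(c(imgs[1:2], blank), "mito")
  expect_equal(sum(res3$objects$condition == "none"), 0L)
})
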