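test_that("Pearson handles exact, anti- and hand-computed correlations", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_cc(x, x), 1.0)
  expect_equal(pearson_cc(x, -x + 7), -1.0)
  a <- c(1, 2, 3, 4, 5); b <- c(2, 1, 4, 3, 6)
  expect_equal(pearson_cc(a, b), oracle_pearson(a, b), tolerance = 1e-12)
  expect_error(pearson_cc(rep(2, 5), 1:5),
               class = "fluoquant_undefined_statistic")
  expect_error(pearson_cc(1, 2), class = "fluoquant_undefined_statistic")
})

test_that("Pearson is symmetric and invariant to positive affine rescaling", {
  set.seed(5)
  for (i in 1:20) {
    a <- runif(50); b <- runif(50)
    expect_equal(pearson_cc(a, b), pearson_cc(b, a))
    expect_equal(pearson_cc(2.7 * a + 11, b), pearson_cc(a, b),
                 tolerance = 1e-12)
  }
})

test_that("Manders coefficients follow containment, disjointness and designed splits", {
  a <- matrix(runif(100, 1, 2), 10); b <- matrix(runif(100, 1, 2), 10)
  ma <- matrix(FALSE, 10, 10); ma[3:5, 3:5] <- TRUE
  mb <- matrix(FALSE, 10, 10); mb[2:6, 2:6] <- TRUE
  expect_equal(manders(a, b, ma, mb)$m1, 1.0)     # ma inside mb
  md <- matrix(FALSE, 10, 10); md[8:9, 8:9] <- TRUE
  r <- manders(a, b, ma, md)
  expect_equal(r$m1, 0.0)
  expect_equal(r$m2, 0.0)
  # designed field: exactly half of A's masked intensity inside mask_b
  a2 <- matrix(0, 4, 4)
  a2[1, 1] <- 10; a2[1, 2] <- 30; a2[2, 1] <- 25; a2[2, 2] <- 15
  ma2 <- a2 > 0
  mb2 <- matrix(FALSE, 4, 4)
  mb2[1, 1] <- TRUE; mb2[1, 2] <- TRUE   # 10 + 30 = half of the 80 total
  expect_equal(manders(a2, a2, ma2, mb2)$m1, 0.5, tolerance = 1e-12)
  expect_error(manders(matrix(0, 2, 2), a2[1:2, 1:2],
                       matrix(TRUE, 2, 2), matrix(TRUE, 2, 2)),
               class = "fluoquant_undefined_statistic")
})

test_that("M1 is monotone non-decreasing as mask_b grows", {
  set.seed(8)
  a <- matrix(runif(400, 0.1, 1), 20); b <- a
  ma <- matrix(TRUE, 20, 20)
  mb <- matrix(FALSE, 20, 20)
  prev <- 0
  for (k in c(50, 150, 300, 400)) {
    mb[sample(which(!mb), k - sum(mb))] <- TRUE
    m1 <- manders(a, b, ma, mb)$m1
    expect_gte(m1, prev)
    prev <- m1
  }
  expect_equal(prev, 1.0)
})

test_that("ICQ hits its extremes, stays near 0 for independent channels, matches oracle", {
  a <- matrix(runif(100, 1, 5), 10)
  mask <- matrix(TRUE, 10, 10)
  expect_equal(icq(a, a, mask), 0.5)
  expect_equal(icq(a, -a, mask), -0.5)
  set.seed(123)
  u <- matrix(runif(10000), 100); v <- matrix(runif(10000), 100)
  expect_lt(abs(icq(u, v, matrix(TRUE, 100, 100))), 0.02)
  expect_equal(icq(u, v, matrix(TRUE, 100, 100)),
               oracle_icq(u, v, matrix(TRUE, 100, 100)))
  # positive affine rescaling of both channels leaves ICQ unchanged
  expect_equal(icq(3 * u + 2, 0.5 * v + 9, matrix(TRUE, 100, 100)),
               icq(u, v, matrix(TRUE, 100, 100)))
  expect_error(icq(matrix(c(0, 0, 1, 1), 2), matrix(c(1, 1, 0, 0), 2),
                   matrix(c(TRUE, TRUE, FALSE, FALSE), 2)),
               class = "fluoquant_undefined_statistic")
})

test_that("line profiles are exact on linear fields and at pixel centers", {
  ramp <- outer(rep(1, 20), seq(0, 19))   # horizontal ramp, slope 1/px
  line <- list(p0 = c(10, 2), p1 = c(10, 18), step_px = 0.5)
  prof <- line_profile(ramp, line)
  expect_equal(prof, seq(1, 17, by = 0.5))
  const <- matrix(3.7, 15, 15)
  prof_const <- line_profile(const, list(p0 = c(2, 2), p1 = c(14, 14),
                                         step_px = 0.25))
  expect_equal(prof_const, rep(3.7, length(prof_const)))
  set.seed(2)
  img <- matrix(runif(100), 10)
  expect_equal(bilinear_sample(img, c(3, 7, 10), c(4, 2, 1)),
               c(img[3, 4], img[7, 2], img[10, 1]))
})

test_that("scan-line optimization finds the joint-signal orientation deterministically", {
  img <- matrix(1, 41, 41)
  # two co-located blob pairs on the anti-diagonal
  for (ctr in list(c(11, 11), c(31, 31))) {
    d2 <- outer((1:41 - ctr[1])^2, (1:41 - ctr[2])^2, "+")
    img <- img + 300 * exp(-d2 / 18)
  }
  mask <- img > 50
  sl <- optimize_scan_line(img, img, mask, mask, n_orientations = 72)
  # distance of blob centers from the selected line < 1 px
  d <- sl$p1 - sl$p0; d <- d / sqrt(sum(d^2))
  for (ctr in list(c(11, 11), c(31, 31))) {
    v <- ctr - sl$p0
    dist <- abs(v[1] * d[2] - v[2] * d[1])
    expect_lt(dist, 1)
  }
  # rotationally symmetric single blob -> tie-break orientation index 1
  d2 <- outer((1:41 - 21)^2, (1:41 - 21)^2, "+")
  blob <- 100 * exp(-d2 / 30)
  mb <- blob > 20
  sym <- optimize_scan_line(blob, blob, mb, mb, n_orientations = 8)
  expect_equal(sym$orientation_index, 1L)
  # n_orientations = 1 -> horizontal chord through the centroid
  one <- optimize_scan_line(blob, blob, mb, mb, n_orientations = 1)
  expect_equal(one$theta, 0)
  expect_equal(one$p0[1], one$p1[1])
  expect_error(optimize_scan_line(img, img, matrix(FALSE, 41, 41),
                                  matrix(FALSE, 41, 41)),
               class = "fluoquant_no_signal")
})

test_that("pixel-wise PCC inside the union mask matches a brute-force oracle", {
  set.seed(31)
  for (i in 1:100) {
    a <- matrix(runif(1024, 0, 100), 32)
    b <- matrix(runif(1024, 0, 100), 32)
    u <- matrix(runif(1024) < 0.6, 32)
    if (sum(u) < 3) next
    expect_equal(pearson_cc(a[u], b[u]), oracle_pearson(a[u], b[u]),
                 tolerance = 1e-10)
  }
})

test_that("colocalize on identical channels returns the degenerate maxima", {
  set.seed(17)
  img0 <- make_coloc_field(n_spots = 40, overlap_fraction = 1, seed = 17,
                           size = 192L, noise = NULL)$image
  img <- multichannel_image(list(red = img0$channels$red,
                                 green = img0$channels$red), 0.1)
  r <- colocalize(img, "red", "green")
  expect_equal(r$pcc_pixel, 1.0)
  expect_equal(r$pcc_line, 1.0)
  expect_equal(r$m1, 1.0)
  expect_equal(r$m2, 1.0)
  expect_equal(r$icq, 0.5)
})

test_that("colocalize on disjoint fields reports zero overlap and non-positive PCC", {
  f <- make_coloc_field(n_spots = 60, overlap_fraction = 0, seed = 23,
                        size = 256L, noise = NULL)
  r <- colocalize(f$image, "red", "green")
  expect_equal(r$m1, 0)
  expect_equal(r$m2, 0)
  expect_lte(r$pcc_pixel, 0)
})

test_that("colocalize recovers a designed overlap fraction of 0.7", {
  f <- make_coloc_field(n_spots = 200, overlap_fraction = 0.7, seed = 41,
                        noise = NULL)
  r <- colocalize(f$image, "red", "green")
  expect_lt(abs(r$m1 - 0.7), 0.05)
})

test_that("undefined statistics surface as NA with a recorded reason", {
  img <- multichannel_image(list(red = matrix(c(0, 5, 0, 5), 2),
                                 green = matrix(7, 2, 2)), 0.1)
  r <- colocalize(img, "red", "green", closing_radius = 0)
  expect_true(is.na(r$icq) || is.na(r$pcc_pixel))
  expect_gt(length(r$flags), 0)
})
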