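test_that("principal axis matches rectangle geometry and rotation equivariance", {
  rect <- as.matrix(expand.grid(r = 1:40, c = 1:4))
  ax <- principal_axis(rect)
  ang <- atan2(ax$direction[2], ax$direction[1]) * 180 / pi
  expect_lt(abs(ang), 2)
  # same rectangle rotated 30 degrees
  for (deg in c(30, 60, 120)) {
    th <- deg * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    rot <- rect %*% t(R)
    axr <- principal_axis(rot)
    angr <- atan2(axr$direction[2], axr$direction[1]) * 180 / pi
    diff <- abs(((angr - deg + 90) %% 180) - 90)  # axis is undirected
    expect_lt(diff, 2, label = sprintf("rotation %d deg", deg))
  }
  # perfect square is flagged near-isotropic
  sq <- as.matrix(expand.grid(r = 1:10, c = 1:10))
  expect_true(principal_axis(sq)$near_isotropic)
  expect_error(principal_axis(matrix(c(3, 3), 1)),
               class = "fluoquant_degenerate_input")
})

test_that("axis direction is equivariant under exact 90-degree grid rotation", {
  f <- make_jc1_field(n_objects = 3, mosaic_mode = "uniform", seed = 71,
                      size = 160L)
  red <- f$image$channels$red; green <- f$image$channels$green
  run <- function(r, g) {
    res <- jc1_pipeline(multichannel_image(list(red = r, green = g), 0.1))
    t(vapply(res$profiles, function(p) p$axis$direction, numeric(2)))
  }
  d0 <- run(red, green)
  # rotate grids by 90 degrees: (r, c) -> (c, nr + 1 - r)
  rot90 <- function(m) t(m)[, nrow(m):1, drop = FALSE]
  d90 <- run(rot90(red), rot90(green))
  expect_equal(nrow(d0), nrow(d90))
  # directions should map (dr, dc) -> (dc, -dr) up to sign and object order
  ang <- function(d) atan2(d[, 2], d[, 1]) * 180 / pi
  a0 <- sort(((ang(d0) + 90) %% 180))
  a90 <- sort((ang(d90) %% 180))
  expect_equal(a0, a90, tolerance = 2)
})

test_that("axial sampling is exact on linear and constant fields", {
  ramp <- outer(seq(0, 19), rep(1, 20))   # vertical ramp, slope 1/row
  ax <- list(centroid = c(10, 10), direction = c(1, 0), extent = c(-5, 5))
  s <- sample_axis(ramp, ax, step_px = 0.5)
  expect_equal(s$values, ramp[10, 10] + s$t_px)
  const <- matrix(2.5, 20, 20)
  expect_true(all(sample_axis(const, ax)$values == 2.5))
})

test_that("profile normalization maps to [0,1] with max exactly 1, flags all-zero", {
  n <- normalize_profile(c(2, 4, 8))
  expect_equal(n$values, c(0.25, 0.5, 1.0))
  expect_false(n$flagged)
  expect_equal(normalize_profile(c(5, 5))$values, c(1, 1))
  z <- normalize_profile(c(0, 0))
  expect_true(z$flagged)
  expect_equal(z$values, c(0, 0))
  set.seed(13)
  for (i in 1:20) {
    v <- runif(30, 0, 50)
    nv <- normalize_profile(v)$values
    expect_equal(max(nv), 1)
    expect_true(all(nv >= 0 & nv <= 1))
  }
})

test_that("uniform-potential objects give high positive pix PCC and constant ratio", {
  f <- make_jc1_field(n_objects = 5, mosaic_mode = "uniform", seed = 81,
                      size = 192L,
                      noise = list(poisson_scale = 1, gaussian_sd = 20,
                                   background = 100))
  res <- jc1_pipeline(f$image)
  expect_gte(length(res$profiles), 3)
  for (p in res$profiles) {
    expect_gt(p$pix_pcc, 0.9)
    expect_lt(p$ratio_variance, 0.1)
  }
})

test_that("identical channels yield pix PCC of exactly 1 and a constant ratio", {
  f <- make_jc1_field(n_objects = 3, mosaic_mode = "uniform", seed = 82,
                      size = 160L)
  ch <- f$image$channels$red
  img <- multichannel_image(list(red = ch, green = ch), 0.1)
  res <- jc1_pipeline(img)
  for (p in res$profiles) {
    expect_equal(p$pix_pcc, 1.0)
    r <- p$ratio[!is.na(p$ratio)]
    expect_equal(r, rep(1, length(r)))
  }
})

test_that("half-half mosaic objects give negative pix PCC and gradient ratio tracks position", {
  neg <- logical(0)
  for (s in 1:10) {
    f <- make_jc1_field(n_objects = 8, mosaic_mode = "half-half",
                        seed = 600 + s)
    res <- jc1_pipeline(f$image)
    neg <- c(neg, vapply(res$profiles, function(p) isTRUE(p$pix_pcc < 0),
                         logical(1)))
  }
  expect_gte(mean(neg), 0.95)
  sp <- numeric(0)
  for (s in 1:5) {
    f <- make_jc1_field(n_objects = 8, mosaic_mode = "gradient",
                        seed = 700 + s)
    res <- jc1_pipeline(f$image)
    for (p in res$profiles) {
      ok <- !is.na(p$ratio)
      if (sum(ok) > 10)
        sp <- c(sp, abs(cor(p$positions_um[ok], p$ratio[ok],
                            method = "spearman")))
    }
  }
  expect_gt(median(sp), 0.8)
})

test_that("a zero channel flags normalization but the pipeline completes", {
  f <- make_jc1_field(n_objects = 3, mosaic_mode = "uniform", seed = 83,
                      size = 160L, noise = NULL)
  img <- multichannel_image(list(red = matrix(0, 160, 160),
                                 green = f$image$channels$green), 0.1)
  res <- jc1_pipeline(img)
  expect_gte(length(res$profiles), 1)
  for (p in res$profiles) {
    expect_true(p$red_flagged)
    expect_false(p$green_flagged)
    expect_true(all(is.na(p$ratio)))
  }
})

test_that("per-object pix PCC equals the brute-force Pearson oracle", {
  f <- make_jc1_field(n_objects = 4, mosaic_mode = "half-half", seed = 84,
                      size = 192L)
  res <- jc1_pipeline(f$image)
  red <- f$image$channels$red; green <- f$image$channels$green
  for (p in res$profiles) {
    idx <- which(res$labels == p$object_label, arr.ind = TRUE)
    expect_equal(p$pix_pcc, oracle_pearson(red[idx], green[idx]),
                 tolerance = 1e-10)
  }
})
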