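# independent finite-difference curvature: explicit loops, replicate
# padding, same epsilon guard, formula written out term by term
oracle_curvature <- function(phi) {
  H <- nrow(phi); W <- ncol(phi)
  at <- function(i, j) phi[min(max(i, 1L), H), min(max(j, 1L), W)]
  gr <- matrix(0, H, W); gc <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    gr[i, j] <- (at(i + 1L, j) - at(i - 1L, j)) / 2
    gc[i, j] <- (at(i, j + 1L) - at(i, j - 1L)) / 2
  }
  n <- sqrt(gr^2 + gc^2 + 1e-10)
  nr <- gr / n; nc <- gc / n
  atm <- function(m, i, j) m[min(max(i, 1L), H), min(max(j, 1L), W)]
  out <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    out[i, j] <- (atm(nr, i + 1L, j) - atm(nr, i - 1L, j)) / 2 +
      (atm(nc, i, j + 1L) - atm(nc, i, j - 1L)) / 2
  }
  out
}

disk_sdf <- function(H, W, center, r) {
  outer(1:H, 1:W, function(i, j) sqrt((i - center[1])^2 + (j - center[2])^2) - r)
}

test_that("edge indicator: unit in flat regions, matches a convolution oracle at a step", {
  expect_true(all(edge_indicator(matrix(0.3, 20, 20), sigma = 1) == 1))

  img <- matrix(0, 32, 32)
  img[, 17:32] <- 1
  g <- edge_indicator(img, sigma = 1)
  expect_true(all(g > 0 & g <= 1))
  # oracle: smooth with an explicit Gaussian kernel, differentiate centrally
  k <- exp(-(-3:3)^2 / 2); k <- k / sum(k)
  sm <- matrix(0, 32, 32)
  row255 <- img[16, ] * 255
  padded <- c(rep(row255[1], 3), row255, rep(row255[32], 3))
  smrow <- sapply(1:32, function(j) sum(padded[j:(j + 6)] * k))
  m <- (smrow[18] - smrow[16]) / 2    # column gradient at the step column 17
  expect_equal(g[16, 17], 1 / (1 + m^2), tolerance = 1e-9)
})

test_that("curvature is 1/r on circles, 0 on ramps, and matches the oracle", {
  phi <- disk_sdf(64, 64, c(32, 32), 20)
  k <- curvature(phi)
  on_zero <- abs(phi) < 0.5
  expect_equal(mean(k[on_zero]), 1 / 20, tolerance = 0.1 / 20 * 10)
  expect_lt(abs(mean(k[on_zero]) - 1 / 20), 0.1 * (1 / 20))

  ramp <- outer(1:32, 1:32, function(i, j) 0.7 * i + 0.2 * j)
  kin <- curvature(ramp)[5:28, 5:28]
  expect_lt(max(abs(kin)), 1e-8)

  set.seed(3)
  z <- gauss_smooth_test(matrix(rnorm(256), 16, 16))
  expect_equal(curvature(z), oracle_curvature(z), tolerance = 1e-6)
})

test_that("geodesic step honours the time step and the row restriction", {
  sc_part <- structure(list(sline = 20L, H = 64L), class = "dgf_partition")
  phi0 <- init_level_set(dgf_contour(rbind(c(25, 20), c(25, 45), c(50, 45),
                                           c(50, 20))), c(64, 64), 2, sc_part)
  g1 <- matrix(1, 64, 64)
  cfg0 <- dgf_config(tau = 0)
  expect_identical(geodesic_step(phi0, g1, cfg0, sc_part), phi0)

  cfg <- dgf_config()
  phi <- phi0
  for (i in 1:100) phi <- geodesic_step(phi, g1, cfg, sc_part)
  expect_identical(phi[1:19, ], phi0[1:19, ])

  # monotone shrinkage of the negative-phase area on an edge-free image
  areas <- integer(51)
  phi <- phi0
  areas[1] <- sum(phi < 0)
  for (i in 1:50) {
    phi <- geodesic_step(phi, g1, cfg, sc_part)
    areas[i + 1] <- sum(phi < 0)
  }
  expect_true(all(diff(areas) <= 0))
  expect_lt(areas[51], areas[1])
})

test_that("the flow converges onto a sharp synthetic boundary", {
  # dark disk on a bright background; contour initialized well outside
  img <- matrix(0.8, 80, 80)
  img[disk_sdf(80, 80, c(45, 40), 18) < 0] <- 0.3
  part <- structure(list(sline = 2L, H = 80L), class = "dgf_partition")
  init <- dgf_contour(rbind(c(18, 12), c(18, 68), c(74, 68), c(74, 12)))
  phi0 <- init_level_set(init, c(80, 80), 2, part)
  g <- edge_indicator(img, 1.5)
  cfg <- dgf_config()
  out <- evolve_geodesic(phi0, g, cfg, part)
  ct <- resample_contour(extract_zero_contour(out$phi), 1)
  th <- seq(0, 2 * pi, length.out = 200)
  truth <- cbind(45 + 18 * sin(th), 40 + 18 * cos(th))
  expect_lte(mean_dist_to_curve(unclass(ct), truth), 1.5)

  none <- evolve_geodesic(phi0, g, dgf_config(geodesic_iters = 0), part)
  expect_identical(none$phi, phi0)
  expect_false(none$converged)
  expect_equal(none$iterations, 0L)
})

test_that("the distance-regularization term keeps the gradient norm bounded", {
  img <- matrix(0.8, 60, 60)
  img[disk_sdf(60, 60, c(32, 30), 14) < 0] <- 0.3
  part <- structure(list(sline = 2L, H = 60L), class = "dgf_partition")
  phi <- init_level_set(dgf_contour(rbind(c(12, 10), c(12, 50), c(52, 50),
                                          c(52, 10))), c(60, 60), 2, part)
  g <- edge_indicator(img, 1.5)
  cfg <- dgf_config()
  dev_band <- function(p) {
    gr <- (rbind(p[-1, ], p[nrow(p), ]) - rbind(p[1, ], p[-nrow(p), ])) / 2
    gc <- (cbind(p[, -1], p[, ncol(p)]) - cbind(p[, 1], p[, -ncol(p)])) / 2
    nn <- sqrt(gr^2 + gc^2)
    band <- abs(p) <= 3
    mean(abs(nn[band] - 1))
  }
  devs <- numeric(6)
  for (k in 1:6) {
    for (i in 1:50) phi <- geodesic_step(phi, g, cfg, part)
    devs[k] <- dev_band(phi)
  }
  # the binary initialization starts far from a signed distance function;
  # the deviation must fall monotonically and reach the bounded regime
  expect_true(all(diff(devs) < 0))
  expect_lte(devs[6], 0.3)
})

test_that("zero-contour extraction recovers analytic isolines and round trips", {
  phi <- disk_sdf(64, 64, c(32, 32), 20)
  ct <- extract_zero_contour(phi)
  rad <- sqrt((ct[, 1L] - 32)^2 + (ct[, 2L] - 32)^2)
  expect_lt(max(abs(rad - 20)), 0.5)
  expect_lt(abs(contour_length(ct) - 2 * pi * 20) / (2 * pi * 20), 0.02)

  expect_error(extract_zero_contour(matrix(2, 10, 10)), "empty contour")

  mask <- contour_to_mask(ct, c(64, 64))
  inside <- phi < 0
  mismatch <- which(mask != inside, arr.ind = TRUE)
  if (nrow(mismatch)) {
    d <- abs(sqrt((mismatch[, 1] - 32)^2 + (mismatch[, 2] - 32)^2) - 20)
    expect_lte(max(d), 1)
  } else succeed()
})
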