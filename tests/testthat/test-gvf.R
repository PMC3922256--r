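# a thin horizontal dark band inside the upper region: the standard strip
# fixture for the binary GVF (two opposing edges, like the mouth opening)
band_fixture <- function(H = 50, W = 60, rows = 20:23) {
  B <- matrix(0L, H, W)
  B[rows, ] <- 1L
  list(B = B, part = structure(list(sline = 40L, H = H), class = "dgf_partition"))
}

test_that("GVF of a constant map is identically zero", {
  f <- band_fixture()
  V0 <- compute_binary_gvf(matrix(0L, 50, 60), w = 0.2, iters = 25, part = f$part)
  expect_true(all(V0$u == 0) && all(V0$v == 0))
})

test_that("the converged GVF satisfies its fixed-point equation", {
  f <- band_fixture()
  V <- compute_binary_gvf(f$B, w = 0.2, iters = 4000, part = f$part)
  B <- matrix(as.numeric(f$B), 50, 60)
  br <- (rbind(B[-1, ], B[50, ]) - rbind(B[1, ], B[-50, ])) / 2
  bc <- (cbind(B[, -1], B[, 60]) - cbind(B[, 1], B[, -60])) / 2
  h <- br^2 + bc^2
  lap <- function(m) m[c(1, 1:49), ] + m[c(2:50, 50), ] +
    m[, c(1, 1:59)] + m[, c(2:60, 60)] - 4 * m
  ru <- 0.2 * lap(V$u) - h * (V$u - br)
  rv <- 0.2 * lap(V$v) - h * (V$v - bc)
  up <- 3:37   # interior upper rows (away from the zeroed under part)
  expect_lte(max(abs(ru[up, 5:56])), 1e-3)
  expect_lte(max(abs(rv[up, 5:56])), 1e-3)
  # diffusion reach: a pixel 10 px from the band still feels a force
  expect_gt(sqrt(V$u[33, 30]^2 + V$v[33, 30]^2), 0)
  # no force in the under part
  expect_true(all(V$u[40:50, ] == 0) && all(V$v[40:50, ] == 0))

  # with weak smoothing the reaction term pins the field to grad(B) at the
  # strongest-edge pixel
  Vw <- compute_binary_gvf(f$B, w = 5e-4, iters = 4000, part = f$part)
  idx <- which(h == max(h), arr.ind = TRUE)[1, ]
  expect_lte(sqrt((Vw$u[idx[1], idx[2]] - br[idx[1], idx[2]])^2 +
                    (Vw$v[idx[1], idx[2]] - bc[idx[1], idx[2]])^2), 1e-3)
})

test_that("the geometric term is the edge indicator times the outward normal", {
  f <- band_fixture()
  st <- snake_state(cbind(35, seq(5, 55, by = 1)), interior = c(45, 30))
  G <- geometric_term(f$B, st, sigma = 1)
  mag <- sqrt(G[, 1L]^2 + G[, 2L]^2)
  expect_true(all(mag <= 1 + 1e-12))
  mid <- which(abs(st$points[, 2L] - 30) < 3)
  expect_equal(unname(mag[mid]), rep(1, length(mid)), tolerance = 1e-3)
  expect_true(all(G[mid, 1L] < 0))  # outward = away from the interior = upward

  st_edge <- snake_state(cbind(23.5, seq(5, 55, by = 1)), interior = c(45, 30))
  Ge <- geometric_term(f$B, st_edge, sigma = 1)
  mage <- sqrt(Ge[, 1L]^2 + Ge[, 2L]^2)
  expect_lte(max(mage[abs(st_edge$points[, 2L] - 30) < 10]), 0.1)

  bad <- snake_state(cbind(35, seq(5, 55, by = 1)), interior = c(45, 30))
  bad$points[4, ] <- bad$points[2, ]   # zero central-difference tangent at 3
  expect_error(geometric_term(f$B, bad, 1), "degenerate normal")
})

test_that("snake steps respect internal-force mechanics", {
  f <- band_fixture()
  Vzero <- structure(list(u = matrix(0, 50, 60), v = matrix(0, 50, 60)),
                     class = "dgf_vector_field")
  cfg <- dgf_config()
  straight <- snake_state(cbind(30, seq(10, 50, by = 1)), interior = c(45, 30))
  s1 <- snake_step(straight, Vzero, NULL, cfg)
  expect_lt(max(abs(s1$points - straight$points)), 1e-9)

  set.seed(5)
  wavy_pts <- cbind(30 + 3 * sin(seq(0, 6 * pi, length.out = 41)), seq(10, 50, 1))
  wavy <- snake_state(wavy_pts, interior = c(45, 30))
  tot_curv <- function(p) {
    d2 <- p[c(-1, -2), ] - 2 * p[c(-1, -nrow(p)), ] + p[1:(nrow(p) - 2), ]
    sum(sqrt(rowSums(d2^2)))
  }
  st <- wavy
  curv0 <- tot_curv(st$points)
  for (i in 1:10) st <- snake_step(st, Vzero, NULL, cfg)
  expect_lt(tot_curv(st$points), curv0)

  # far from any edge the switch selects the geometric term: a straight
  # polyline is displaced along +normal by the step size (away from the
  # pinned ends, where the implicit solve tapers the displacement)
  G <- matrix(rep(c(-1, 0), each = 41), ncol = 2)
  s2 <- snake_step(straight, Vzero, G, cfg)
  inner <- 15:27
  expect_equal(unname(s2$points[inner, 1L]),
               unname(straight$points[inner, 1L]) - cfg$snake_gamma,
               tolerance = 1e-3)
})

test_that("the snake is stationary on the centerline of a thin dark band", {
  f <- band_fixture(rows = 20:22)
  cfg <- dgf_config(snake_iters = 100)
  V <- compute_binary_gvf(f$B, cfg$w, cfg$gvf_iters, f$part)
  init <- snake_state(cbind(21, seq(8, 52, by = 1)), interior = c(45, 30))
  out <- evolve_snake(init, V, f$B, cfg)
  drift <- abs(out$state$points[, 1L] - 21)
  inner <- out$state$points[, 2L] > 12 & out$state$points[, 2L] < 48
  expect_lte(max(drift[inner]), 0.5)

  same <- evolve_snake(init, V, f$B, dgf_config(snake_iters = 0))
  expect_identical(same$state$points, init$points)
  expect_equal(same$iterations, 0L)
})

test_that("the snake recovers the upper boundary of generator scenes", {
  sc <- generate_scene(scene_spec(seed = 5))
  st <- prepare_scene_stages(sc)
  cfg <- st$cfg
  V <- compute_binary_gvf(st$B, cfg$w, cfg$gvf_iters, st$part)
  init <- snake_state(rbind(st$fp$left_angular, st$fp$root, st$fp$right_angular),
                      interior = c(st$part$sline + 10, st$fp$root[2L]))
  out <- evolve_snake(init, V, st$B, cfg)
  arc_full <- sweep(out$state$points, 2L, -st$off)
  expect_lte(mean_dist_to_curve(arc_full, scene_upper_boundary(sc$spec)), 2)
})

test_that("a symmetric mouth yields a symmetric converged arc", {
  sc <- generate_scene(scene_spec(seed = 2, noise_sigma = 0))
  st <- prepare_scene_stages(sc)
  cfg <- st$cfg
  V <- compute_binary_gvf(st$B, cfg$w, cfg$gvf_iters, st$part)
  midc <- sc$spec$center_col - st$off[2L]
  init <- snake_state(rbind(st$fp$left_angular, c(st$fp$root[1L], midc),
                            st$fp$right_angular),
                      interior = c(st$part$sline + 10, midc))
  out <- evolve_snake(init, V, st$B, cfg)
  p <- out$state$points
  for (dc in c(10, 20, 30)) {
    rl <- p[which.min(abs(p[, 2L] - (midc - dc))), 1L]
    rr <- p[which.min(abs(p[, 2L] - (midc + dc))), 1L]
    expect_lte(abs(rl - rr), 1)
  }
})
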