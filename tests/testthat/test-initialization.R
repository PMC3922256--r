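test_that("angular points land near the true mouth corners", {
  for (s in c(2, 6)) {
    sc <- generate_scene(scene_spec(seed = s))
    st <- prepare_scene_stages(sc)
    for (side in c("left_angular", "right_angular")) {
      det <- st$fp[[side]] + st$off
      tru <- unlist(sc$feature_points[[side]])
      expect_lte(sqrt(sum((det - tru)^2)), 8)
    }
    expect_lt(st$fp$left_angular[2L], st$fp$right_angular[2L])
  }
  flat <- as_rgb_image(array(0.5, c(60, 60, 3)))
  expect_error(detect_angular_points(flat), "initialization failure|degenerate")
})

test_that("tip detection errs below the true tip so the curve can shrink onto it", {
  sc <- generate_scene(scene_spec(seed = 2, tip_row = 215))
  st <- prepare_scene_stages(sc)
  tip_full <- st$fp$tip + st$off
  expect_gte(tip_full[1L], 215 - 5)
  expect_gt(st$fp$tip[1L], max(st$fp$left_angular[1L], st$fp$right_angular[1L]))
  expect_lt(st$fp$root[1L], min(st$fp$left_angular[1L], st$fp$right_angular[1L]))
  # shrinking precondition: the initial lower arc tracks the true lower
  # boundary from outside, cutting inside by at most a few pixels (such
  # residual slivers are what bound the pipeline's false-negative rate),
  # and lies strictly below the true tip at the midline
  ic <- build_initial_contour(st$fp)
  low <- unclass(ic)[unclass(ic)[, 1L] >= st$part$sline, , drop = FALSE]
  truth <- scene_lower_boundary(sc$spec)
  for (k in seq(1, nrow(low), by = 5)) {
    cc <- low[k, 2L] + st$off[2L]
    j <- which.min(abs(truth[, 2L] - cc))
    if (abs(truth[j, 2L] - cc) < 1)
      expect_gte(low[k, 1L] + st$off[1L], truth[j, 1L] - 3)
  }
  expect_gte(max(low[, 1L]) + st$off[1L], max(truth[, 1L]))
})

test_that("the initial contour interpolates the four anchors", {
  fp <- feature_points(c(60, 30), c(60, 98), c(150, 64), c(40, 64))
  ct <- build_initial_contour(fp)
  expect_true(attr(ct, "closed"))
  expect_equal(max(ct[, 1L]), 150, tolerance = 0.51)
  expect_true(contour_is_simple(ct))
  # symmetry about the midline for symmetric anchors
  p <- unclass(ct)
  lower <- p[p[, 1L] > 60, ]
  for (dc in c(10, 20, 30)) {
    rl <- lower[which.min(abs(lower[, 2L] - (64 - dc))), 1L]
    rr <- lower[which.min(abs(lower[, 2L] - (64 + dc))), 1L]
    expect_lte(abs(rl - rr), 1)
  }
  expect_error(build_initial_contour(
    feature_points(c(60, 63.5), c(60, 64.5), c(150, 64), c(40, 64))),
    "degenerate")
})

test_that("the partition row is the rounded mean of the angular rows", {
  fp1 <- feature_points(c(60, 30), c(60, 98), c(150, 64), c(40, 64))
  expect_equal(partition(fp1, 200)$sline, 60L)
  fp2 <- feature_points(c(58, 30), c(62, 98), c(150, 64), c(40, 64))
  expect_equal(partition(fp2, 200)$sline, 60L)
  p <- partition(fp1, 61)
  expect_true(p$sline > 1 && p$sline < 61)
})

test_that("upper binarization isolates the dark mouth opening", {
  # 3-level toy: dark band between lip and tongue intensities
  g <- matrix(0.6, 40, 30)
  g[15:18, ] <- 0.1
  g[25:40, ] <- 0.45
  img <- array(rep(g, 3L), c(40, 30, 3))
  part <- structure(list(sline = 30L, H = 40L), class = "dgf_partition")
  B <- binarize_upper(img, part)
  expect_true(all(B[15:18, ] == 1L))
  expect_true(all(B[c(1:14, 19:29), ] == 0L))
  expect_true(all(B[30:40, ] == 0L))

  # threshold symmetry of the plain Otsu method: inverting the image
  # inverts the labels (on the rows above sline)
  set.seed(1)
  g2 <- matrix(runif(1200, 0.55, 0.65), 40, 30)
  g2[10:13, ] <- runif(4 * 30, 0.08, 0.12)
  up <- 1:29
  B1 <- binarize_upper(array(rep(g2, 3), c(40, 30, 3)), part, method = "otsu")
  B2 <- binarize_upper(array(rep(1 - g2, 3), c(40, 30, 3)), part, method = "otsu")
  expect_true(all(B1[up, ] + B2[up, ] == 1L))

  expect_error(binarize_upper(array(0.5, c(40, 30, 3)), part), "degenerate")
})

test_that("nose removal cuts twice the dark-region height above it", {
  B <- matrix(0L, 60, 40)
  B[30:40, 10:30] <- 1L
  fp <- feature_points(c(50, 5), c(50, 35), c(58, 20), c(35, 20))
  w <- remove_nose(B, fp)
  expect_equal(w$row0, 30L - 2L * 11L)  # = 8
  expect_equal(w$row1, 60L)

  expect_message(w0 <- remove_nose(matrix(0L, 60, 40), fp), "empty dark region")
  expect_equal(w0$row0, 1L)

  Btop <- matrix(0L, 60, 40)
  Btop[5:25, 10:30] <- 1L
  expect_equal(remove_nose(Btop, fp)$row0, 1L)  # clamped at the frame top
})

test_that("level-set initialization is the three-valued matrix of the region rule", {
  ct <- dgf_contour(rbind(c(5, 5), c(5, 15), c(15, 15), c(15, 5)))
  phi <- init_level_set(ct, c(20, 20), rho = 2)
  expect_setequal(unique(as.vector(phi)), c(-2, 0, 2))
  expect_equal(phi[10, 10], -2)   # strictly inside
  expect_equal(phi[5, 10], 0)     # on the contour
  expect_equal(phi[2, 2], 2)      # outside
  expect_error(init_level_set(dgf_contour(rbind(c(1, 1), c(9, 9)),
                                          closed = FALSE), c(20, 20), 2),
               "closed")
  expect_error(init_level_set(ct, c(20, 20), rho = 0), "rho")
})

test_that("the straight upper chords start inside the true tongue body", {
  for (s in c(2, 6)) {
    sc <- generate_scene(scene_spec(seed = s))
    fp <- sc$feature_points
    chord <- rbind(fp$left_angular, fp$root, fp$right_angular)
    arc <- resample_contour(dgf_contour(chord, closed = FALSE), 1)
    inner <- unclass(arc)[5:(nrow(arc) - 4), , drop = FALSE]
    hits <- sc$tongue_mask[cbind(round(inner[, 1L]), round(inner[, 2L]))]
    expect_true(all(hits == 1L))
  }
})
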