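# Shared fixtures and independent oracles. Everything here is deliberately
# written with plain loops / a different algorithm than the package code it
# checks.

# winding-number point-in-polygon with explicit on-segment handling;
# independent of the package's scanline rasterizer
oracle_point_in_poly <- function(r, c, poly, tol = 1e-7) {
  n <- nrow(poly)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    r1 <- poly[i, 1L]; c1 <- poly[i, 2L]; r2 <- poly[j, 1L]; c2 <- poly[j, 2L]
    L2 <- (r2 - r1)^2 + (c2 - c1)^2
    t <- if (L2 < 1e-24) 0 else max(0, min(1, ((r - r1) * (r2 - r1) +
                                                 (c - c1) * (c2 - c1)) / L2))
    if (sqrt((r - (r1 + t * (r2 - r1)))^2 + (c - (c1 + t * (c2 - c1)))^2) <= tol)
      return(TRUE)
  }
  ang <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a1 <- atan2(poly[i, 1L] - r, poly[i, 2L] - c)
    a2 <- atan2(poly[j, 1L] - r, poly[j, 2L] - c)
    d <- a2 - a1
    if (d > pi) d <- d - 2 * pi
    if (d < -pi) d <- d + 2 * pi
    ang <- ang + d
  }
  abs(ang) > pi
}

oracle_mask <- function(poly, shape) {
  m <- matrix(0L, shape[1L], shape[2L])
  for (r in seq_len(shape[1L])) for (c in seq_len(shape[2L]))
    if (oracle_point_in_poly(r, c, poly)) m[r, c] <- 1L
  m
}

# brute-force nearest-neighbour distances, explicit double loops
oracle_directed <- function(a, b, agg) {
  per_point <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    best <- Inf
    for (j in seq_len(nrow(b))) {
      d <- sqrt((a[i, 1L] - b[j, 1L])^2 + (a[i, 2L] - b[j, 2L])^2)
      if (d < best) best <- d
    }
    per_point[i] <- best
  }
  agg(per_point)
}
oracle_hausdorff <- function(a, b)
  max(oracle_directed(a, b, max), oracle_directed(b, a, max))
oracle_mean_distance <- function(a, b)
  (oracle_directed(a, b, mean) + oracle_directed(b, a, mean)) / 2

# independent window-objective scorer using direct sums (no integral image)
oracle_window_score <- function(map, r0, c0, r1, c1,
                                penalty = 0.5, margin_frac = 0.1, theta = 0.15) {
  H <- nrow(map); W <- ncol(map)
  mr <- max(1L, round(margin_frac * (r1 - r0 + 1L)))
  mc <- max(1L, round(margin_frac * (c1 - c0 + 1L)))
  inside <- sum(map[r0:r1, c0:c1])
  er <- max(1L, r0 - mr):min(H, r1 + mr)
  ec <- max(1L, c0 - mc):min(W, c1 + mc)
  ring <- sum(map[er, ec]) - inside
  inside - penalty * ring - theta * (r1 - r0 + 1L) * (c1 - c0 + 1L)
}

# analytic ground-truth curves of a scene spec (full-frame coordinates)
scene_lower_boundary <- function(spec) {
  cols <- seq(round(spec$center_col - spec$halfwidth),
              round(spec$center_col + spec$halfwidth))
  s <- (cols - spec$center_col) / spec$halfwidth
  arow <- ifelse(s < 0, spec$angular_row_left, spec$angular_row_right)
  cbind(spec$tip_row + (arow - spec$tip_row) * s^2, cols)
}
scene_upper_boundary <- function(spec) {
  cols <- seq(round(spec$center_col - spec$halfwidth),
              round(spec$center_col + spec$halfwidth))
  s <- (cols - spec$center_col) / spec$halfwidth
  arow <- ifelse(s < 0, spec$angular_row_left, spec$angular_row_right)
  cbind(spec$top_row + (arow - spec$top_row) * s^2, cols)
}

mean_dist_to_curve <- function(pts, curve) {
  mean(apply(pts, 1L, function(q)
    min(sqrt((curve[, 1L] - q[1L])^2 + (curve[, 2L] - q[2L])^2))))
}

# upper-arc error of a segmentation result against the true upper boundary
upper_arc_error <- function(res, scene) {
  p <- unclass(res$contour)
  up <- p[p[, 1L] < res$sline - 1, , drop = FALSE]
  mean_dist_to_curve(up, scene_upper_boundary(scene$spec))
}

# crude smoother for building random smooth test fields (box blur passes)
gauss_smooth_test <- function(m, passes = 4) {
  for (p in seq_len(passes)) {
    up <- m[c(1, seq_len(nrow(m) - 1)), ]
    dn <- m[c(seq_len(nrow(m))[-1], nrow(m)), ]
    lf <- m[, c(1, seq_len(ncol(m) - 1))]
    rt <- m[, c(seq_len(ncol(m))[-1], ncol(m))]
    m <- (m + up + dn + lf + rt) / 5
  }
  m
}

# deterministic random closed contour (star-shaped, simple by construction)
random_contour <- function(n, center, rmin, rmax) {
  th <- sort(runif(n, 0, 2 * pi))
  rad <- runif(n, rmin, rmax)
  dgf_contour(cbind(center[1L] + rad * sin(th), center[2L] + rad * cos(th)),
              closed = TRUE)
}

# mouth-scene ingredients for module-level flow tests, computed once
prepare_scene_stages <- function(scene, cfg = dgf_config(), margin = 0.15) {
  img <- scene$image
  sal <- compute_saliency_map(img)
  win <- select_tongue_window(detect_saliency_windows(sal, k = 2L))
  H <- dim(img)[1L]; W <- dim(img)[2L]
  mr <- round(margin * (win$row1 - win$row0 + 1L))
  mc <- round(margin * (win$col1 - win$col0 + 1L))
  we <- dgf_window(max(1L, win$row0 - mr), max(1L, win$col0 - mc),
                   min(H, win$row1 + mr), min(W, win$col1 + mc))
  cr <- crop(img, we)
  ang <- detect_angular_points(cr)
  tr <- detect_tip_and_root(cr, ang)
  fp <- feature_points(ang$left, ang$right, tr$tip, tr$root)
  part <- partition(fp, nrow(cr))
  B <- binarize_upper(cr, part)
  list(crop = cr, window = win, expanded = we, off = c(we$row0 - 1L, we$col0 - 1L),
       fp = fp, part = part, B = B, cfg = cfg)
}
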