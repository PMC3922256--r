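#' Tongue feature points
#'
#' The four landmarks that seed the contour: the two mouth-corner (angular)
#' points where the tongue meets the lip corners, the tongue tip below, and a
#' tongue-root point above, strictly inside the tongue body.
#'
#' @param left_angular,right_angular,tip,root `(row, col)` coordinates.
#' @return A `dgf_feature_points` list.
#' @export
feature_points <- function(left_angular, right_angular, tip, root) {
  fp <- lapply(list(left_angular = left_angular, right_angular = right_angular,
                    tip = tip, root = root), as.numeric)
  if (fp$left_angular[2L] >= fp$right_angular[2L])
    stop("left angular point must be left of the right one", call. = FALSE)
  arows <- c(fp$left_angular[1L], fp$right_angular[1L])
  if (fp$tip[1L] <= max(arows))
    stop("tongue tip must lie below the angular points", call. = FALSE)
  if (fp$root[1L] >= min(arows))
    stop("tongue root must lie above the angular points", call. = FALSE)
  structure(fp, class = "dgf_feature_points")
}

#' @export
print.dgf_feature_points <- function(x, ...) {
  cat("<dgf_feature_points>\n")
  for (k in names(x)) cat(sprintf("  %-13s (%.1f, %.1f)\n", k, x[[k]][1L], x[[k]][2L]))
  invisible(x)
}

# Otsu threshold focused on the darkest minority mode. The upper mouth
# region is multi-modal (skin, lip, tongue root, dark opening); a single
# global split can land between skin and everything else. The dark mouth
# opening is a small fraction of the region, so the Otsu split is re-applied
# to the sub-threshold population while that fraction is implausibly large.
dark_threshold <- function(vals, max_frac = 0.08, max_depth = 4L) {
  if (length(vals) < 16L || diff(range(vals)) < 1e-3)
    stop("degenerate intensity histogram: no dark mode separable", call. = FALSE)
  ots <- function(x) EBImage::otsu(EBImage::Image(matrix(x, 1L)), range = c(0, 1))
  thr <- ots(vals)
  depth <- 1L
  repeat {
    sub <- vals[vals < thr]
    if (length(sub) < 16L || diff(range(sub)) < 1e-3 || depth >= max_depth) break
    frac <- length(sub) / length(vals)
    # the dark class must be a small and compact (near-uniform) mode;
    # a large spread below the threshold means another mode was swallowed
    spread <- stats::sd(sub) /
      max(thr - stats::quantile(sub, 0.005, names = FALSE), 1e-9)
    if (frac <= max_frac && spread <= 0.25) break
    thr2 <- ots(sub)
    if (thr2 >= thr) break
    thr <- thr2
    depth <- depth + 1L
  }
  thr
}

# largest connected dark component (the mouth opening) of a gray image
dark_region <- function(gray) {
  thr <- dark_threshold(as.vector(gray))
  dark <- matrix(0L, nrow(gray), ncol(gray))
  dark[gray < thr] <- 1L
  if (!any(dark == 1L)) return(NULL)
  lab <- EBImage::bwlabel(EBImage::Image(t(dark)))  # EBImage is (x, y)
  lab <- t(EBImage::imageData(lab))
  sizes <- tabulate(lab[lab > 0L])
  comp <- lab == which.max(sizes)
  idx <- which(comp, arr.ind = TRUE)
  list(mask = comp, row0 = min(idx[, 1L]), row1 = max(idx[, 1L]),
       col0 = min(idx[, 2L]), col1 = max(idx[, 2L]))
}

harris_response <- function(gray, sigma_d = 1, sigma_i = 2, k = 0.06) {
  g <- gauss_smooth(gray, sigma_d)
  ix <- grad_col(g); iy <- grad_row(g)
  sxx <- gauss_smooth(ix * ix, sigma_i)
  syy <- gauss_smooth(iy * iy, sigma_i)
  sxy <- gauss_smooth(ix * iy, sigma_i)
  (sxx * syy - sxy^2) - k * (sxx + syy)^2
}

#' Detect the two angular (mouth-corner) points
#'
#' The corners are where the dark mouth opening tapers to nothing: a
#' quadratic is fitted to the opening's per-column height and extrapolated to
#' its zero-height roots, whose rows come from a quadratic fit of the
#' opening's bottom edge. Each extrapolated corner is then snapped to the
#' strongest nearby Harris response when one stands out (the corner is a
#' multi-region junction and fires the detector whenever the local contrast
#' allows). Only rough locations are required downstream; the extension of a
#' corner beyond the visible opening is estimated conservatively, since an
#' overshoot costs far more than a small inside wedge.
#'
#' @param image Cropped RGB tongue image.
#' @return List `(left, right)` of `(row, col)` points.
#' @export
detect_angular_points <- function(image) {
  gray <- as_gray(image)
  H <- nrow(gray); W <- ncol(gray)
  dr <- tryCatch(dark_region(gray), error = function(e) NULL)
  if (is.null(dr))
    stop("initialization failure: no dark mouth-opening region found", call. = FALSE)
  cols <- which(colSums(dr$mask) > 0)
  if (length(cols) < 8L)
    stop("initialization failure: mouth-opening region too small", call. = FALSE)
  hgt <- colSums(dr$mask)[cols]
  bot <- vapply(cols, function(cc) max(which(dr$mask[, cc])), numeric(1))
  bfit <- stats::lm(bot ~ cols + I(cols^2))
  ext <- range(cols)
  span <- diff(ext)
  # per-side linear extrapolation of the tapering height profile to zero;
  # near a corner the height decays linearly, and a local fit is robust to
  # the discretized plateau at the opening's middle
  side_root <- function(left) {
    m <- min(length(cols), max(6L, round(0.15 * length(cols))))
    sel <- if (left) seq_len(m) else seq(length(cols) - m + 1L, length(cols))
    fit <- stats::coef(stats::lm(hgt[sel] ~ cols[sel]))
    slope <- fit[2L]
    e <- if (left) ext[1L] else ext[2L]
    if (is.na(slope) || (left && slope <= 1e-6) || (!left && slope >= -1e-6))
      return(e)
    root <- -fit[1L] / slope
    # extension beyond the visible opening is capped: overshooting past the
    # true corner throws the initial arc beyond the lip band, which is far
    # costlier than the small wedge left by a conservative estimate
    lim <- 10
    if (left) min(max(root, e - lim), e) else max(min(root, e + lim), e)
  }
  corner_col <- c(side_root(TRUE), side_root(FALSE))
  corner_row <- stats::predict(bfit, data.frame(cols = corner_col))
  corner_col <- pmin(pmax(corner_col, 1), W)
  corner_row <- pmin(pmax(corner_row, 1), H)
  # refine each corner column to the outermost column that still carries a
  # strong horizontal edge below the corner row: beyond the mouth corner the
  # face is smooth skin, while inside it the tongue/lip boundary always
  # produces one
  gsm <- abs(grad_row(gauss_smooth(gray, 1)))
  edge_cols <- function(est_row, est_col, left) {
    rr <- max(1L, round(est_row) - 4L):min(H, round(est_row) + 24L)
    cand <- max(1L, round(est_col) - 12L):min(W, round(est_col) + 12L)
    s <- vapply(cand, function(cc) max(gsm[rr, cc]), numeric(1))
    strong <- s >= 0.02
    inner2 <- function(k) {
      ks <- if (left) k + 1:2 else k - 1:2
      ks <- ks[ks >= 1 & ks <= length(cand)]
      all(s[ks] >= 0.015)
    }
    ok <- which(strong & vapply(seq_along(cand), inner2, logical(1)))
    if (!length(ok)) return(est_col)
    cand[if (left) min(ok) else max(ok)]
  }
  corner_col <- c(edge_cols(corner_row[1L], corner_col[1L], TRUE),
                  edge_cols(corner_row[2L], corner_col[2L], FALSE))
  corner_row <- pmin(pmax(stats::predict(bfit, data.frame(cols = corner_col)), 1), H)
  R <- harris_response(gray)
  rmax_global <- max(R)
  if (rmax_global <= 1e-12)
    stop("initialization failure: fewer than 2 corner candidates", call. = FALSE)
  snap <- function(pt) {
    r0 <- max(1L, round(pt[1L]) - 2L):min(H, round(pt[1L]) + 2L)
    c0 <- max(1L, round(pt[2L]) - 1L):min(W, round(pt[2L]) + 1L)
    sub <- R[r0, c0, drop = FALSE]
    if (max(sub) >= 0.05 * rmax_global) {
      j <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
      c(r0[j[1L]], c0[j[2L]])
    } else c(min(max(round(pt[1L]), 1L), H), min(max(round(pt[2L]), 1L), W))
  }
  left <- snap(c(corner_row[1L], corner_col[1L]))
  right <- snap(c(corner_row[2L], corner_col[2L]))
  if (left[2L] >= right[2L])
    stop("initialization failure: corner candidates not laterally separated",
         call. = FALSE)
  list(left = left, right = right)
}

#' Detect the tongue tip and root points
#'
#' The tip is the lowest strong horizontal-edge gradient peak on the vertical
#' midline below the angular row, nudged 2 px downward so that it lies below
#' the true tip (the geodesic curve then shrinks onto the boundary). The root is placed
#' midway between the bottom of the dark mouth opening and the angular row,
#' strictly inside the tongue body.
#'
#' @param image Cropped RGB tongue image.
#' @param angular List `(left, right)` from [detect_angular_points()].
#' @param edge_thresh Minimum midline gradient magnitude (unit-intensity
#'   scale) for a tip edge (default 0.012).
#' @return List `(tip, root)` of `(row, col)` points.
#' @export
detect_tip_and_root <- function(image, angular, edge_thresh = 0.012) {
  gray <- as_gray(image)
  H <- nrow(gray); W <- ncol(gray)
  arow <- max(angular$left[1L], angular$right[1L])
  midc <- round((angular$left[2L] + angular$right[2L]) / 2)
  cols <- max(1L, midc - 2L):min(W, midc + 2L)
  prof <- rowMeans(gauss_smooth(gray[, cols, drop = FALSE], 1.5))
  dgrad <- c(0, diff(prof))
  rows <- seq(min(H, round(arow) + 10L), H)
  ag <- abs(dgrad)
  is_peak <- ag[rows] >= edge_thresh &
    ag[rows] >= ag[pmax(rows - 1L, 1L)] & ag[rows] >= ag[pmin(rows + 1L, H)]
  cand <- rows[is_peak]
  if (!length(cand))
    stop("initialization failure: no tip edge found on the midline", call. = FALSE)
  tip_row <- min(H, max(cand) + 2L)
  dr <- tryCatch(dark_region(gray), error = function(e) NULL)
  min_arow <- min(angular$left[1L], angular$right[1L])
  root_row <- if (!is.null(dr)) {
    sub <- dr$mask[, cols, drop = FALSE]
    bot <- if (any(sub)) max(which(sub, arr.ind = TRUE)[, 1L]) else dr$row1
    round((bot + min_arow) / 2)
  } else round(min_arow - 0.15 * H)
  root_row <- min(root_row, round(min_arow) - 3L)
  list(tip = c(tip_row, midc), root = c(max(1, root_row), midc))
}

#' Build the initial contour from the four feature points
#'
#' The lower half is a piecewise-quadratic arc through left angular, tip and
#' right angular (one parabola per side, apex at the tip), sampled at ~1 px
#' arc spacing; the upper half is the two straight chords angular -> root ->
#' angular, which lie inside the tongue body for a convex tongue.
#'
#' @param fp A [feature_points()] object.
#' @return A closed [dgf_contour()], ordered left angular -> tip -> right
#'   angular -> root.
#' @export
build_initial_contour <- function(fp) {
  la <- fp$left_angular; ra <- fp$right_angular; tip <- fp$tip; root <- fp$root
  if (abs(la[2L] - tip[2L]) < 1 || abs(ra[2L] - tip[2L]) < 1)
    stop("degenerate feature points: tip not between the angular points",
         call. = FALSE)
  side_arc <- function(from, tipp) {
    cols <- seq(from[2L], tipp[2L], by = if (from[2L] < tipp[2L]) 0.5 else -0.5)
    s <- (cols - tipp[2L]) / (from[2L] - tipp[2L])
    rows <- tipp[1L] + (from[1L] - tipp[1L]) * s^2
    cbind(rows, cols)
  }
  left_arc <- side_arc(la, tip)           # left angular -> tip
  right_arc <- side_arc(ra, tip)          # right angular -> tip
  pts <- rbind(left_arc,
               right_arc[rev(seq_len(nrow(right_arc))), , drop = FALSE],
               root)
  resample_contour(dgf_contour(pts, closed = TRUE), spacing = 1)
}

#' Partition the region at the angular-point row
#'
#' `sline` is the rounded mean of the two angular rows; rows above `sline`
#' form the upper (snake) part, rows from `sline` down the lower (geodesic)
#' part.
#'
#' @param fp A [feature_points()] object.
#' @param H Image height in rows.
#' @return A `dgf_partition` list with `sline` and `H`.
#' @export
partition <- function(fp, H) {
  sline <- round((fp$left_angular[1L] + fp$right_angular[1L]) / 2)
  sline <- min(max(sline, 2L), H - 1L)
  structure(list(sline = as.integer(sline), H = as.integer(H)),
            class = "dgf_partition")
}

#' Binarize the upper region, isolating the dark mouth opening
#'
#' Automatic histogram thresholding of the rows above `sline`; pixels darker
#' than the threshold map to 1, everything else (and all rows from `sline`
#' down) to 0. The default `"dark"` method computes the Otsu split over
#' below-median intensities so the threshold falls between the dark
#' mouth-opening mode and the lip/skin/tongue modes; `"otsu"` is the plain
#' global bimodal split.
#'
#' @param image Cropped RGB image (or gray matrix).
#' @param part A [partition()] object.
#' @param method `"dark"` (default) or `"otsu"`.
#' @return 0/1 integer matrix of the full image size.
#' @export
binarize_upper <- function(image, part, method = c("dark", "otsu")) {
  method <- match.arg(method)
  gray <- as_gray(image)
  up <- gray[seq_len(part$sline - 1L), , drop = FALSE]
  if (diff(range(up)) < 1e-6)
    stop("degenerate histogram: constant upper region", call. = FALSE)
  thr <- if (method == "dark") dark_threshold(as.vector(up))
  else EBImage::otsu(EBImage::Image(t(up)), range = c(0, 1))
  B <- matrix(0L, nrow(gray), ncol(gray))
  B[seq_len(part$sline - 1L), ][up < thr] <- 1L
  B
}

#' Nose-removal refinement window
#'
#' Assumes the upper lip is at most twice as thick as the dark mouth-opening
#' region below it, and cuts off everything above that allowance: the
#' returned window's top row is `dark_top - 2 * dark_height` (clamped at 1).
#' With no dark region the identity window is returned and a message logged.
#'
#' @param binary Upper binary map from [binarize_upper()].
#' @param fp A [feature_points()] object (unused by the arithmetic rule but
#'   part of the refinement contract).
#' @return A [dgf_window()] covering the retained rows (full width).
#' @export
remove_nose <- function(binary, fp) {
  H <- nrow(binary); W <- ncol(binary)
  if (!any(binary == 1L)) {
    message("remove_nose: empty dark region, keeping full window")
    return(dgf_window(1L, 1L, H, W))
  }
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(binary)))))
  sizes <- tabulate(lab[lab > 0L])
  idx <- which(lab == which.max(sizes), arr.ind = TRUE)
  top <- min(idx[, 1L]); height <- max(idx[, 1L]) - top + 1L
  dgf_window(max(1L, top - 2L * height), 1L, H, W)
}

#' Initialize the lower-region level-set matrix
#'
#' Piecewise-constant initialization: `-rho` strictly inside the contour, `0`
#' on contour pixels, `+rho` outside, so that the zero level set coincides
#' with the initial contour and the enclosed region is the negative side
#' (the curve shrinks under a positive area-term weight).
#'
#' @param contour Closed initial [dgf_contour()].
#' @param shape `c(H, W)`.
#' @param rho Positive constant (default 2).
#' @param part Optional [partition()] (recorded as an attribute).
#' @return `H x W` level-set matrix taking exactly the values
#'   `{-rho, 0, +rho}`.
#' @export
init_level_set <- function(contour, shape, rho = 2, part = NULL) {
  if (rho <= 0) stop("rho must be > 0", call. = FALSE)
  if (!is_closed(contour)) stop("level-set initialization needs a closed contour",
                                call. = FALSE)
  inside <- contour_to_mask(contour, shape)
  phi <- matrix(rho, shape[1L], shape[2L])
  phi[inside == 1L] <- -rho
  phi[outline_pixels(contour, shape)] <- 0
  attr(phi, "partition") <- part
  phi
}
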