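#' Synthetic tongue-scene specification
#'
#' Parameterizes a simplified frontal mouth scene: facial skin background, an
#' upper lip band, a thin dark mouth opening between the upper lip and the
#' tongue root, a protruding tongue body bounded by two smooth arcs that meet
#' at the mouth-corner (angular) points, a lower lip visible laterally beside
#' the protruded tongue, and an optional nose block above the upper lip. All
#' boundary curves are per-side quadratics so the ground truth is
#' pixel-perfect and the scene is fully determined by the seed.
#'
#' @param H,W Image size in pixels (default 256 x 256).
#' @param center_col Tongue midline column.
#' @param halfwidth Tongue half-width at the angular row, pixels.
#' @param angular_row_left,angular_row_right Rows of the two mouth corners.
#' @param tip_row Lowest tongue row (tongue tip).
#' @param top_row Highest tongue row (tongue root boundary, midline apex).
#' @param mouth_gap_height Dark mouth-opening height at the midline, pixels
#'   (tapers to zero at the corners).
#' @param lip_thickness Upper lip thickness at the midline, pixels.
#' @param lower_lip_thickness Lateral lower-lip band thickness, pixels.
#' @param nose `NULL`, or `c(row0, row1, col0, col1)` of a nose block above
#'   the lip.
#' @param trap `NULL`, or `TRUE` to draw a darker streak across the upper
#'   tongue (a gray-level local-minimum trap between the initial upper
#'   contour and the true boundary).
#' @param class_tag Tongue color class: `"light_white"`, `"red"`,
#'   `"purple"` or `"carmoisine"`.
#' @param colors Named list with RGB triples `tongue`, `lip`, `skin`,
#'   `mouth` (and optionally `nose`, `trap`); defaults follow `class_tag`.
#' @param noise_sigma Additive Gaussian noise s.d. (default 0.01).
#' @param seed Integer seed (default 1).
#' @param min_contrast Minimum pairwise RGB distance between region colors.
#' @return A `dgf_scene_spec` list.
#' @export
scene_spec <- function(H = 256L, W = 256L, center_col = 128, halfwidth = 65,
                       angular_row_left = 120, angular_row_right = 120,
                       tip_row = 218, top_row = 88, mouth_gap_height = 4,
                       lip_thickness = 8, lower_lip_thickness = 12,
                       nose = NULL, trap = NULL,
                       class_tag = c("red", "light_white", "purple", "carmoisine"),
                       colors = NULL, noise_sigma = 0.01, seed = 1L,
                       min_contrast = 0.02) {
  class_tag <- match.arg(class_tag)
  pal <- list(
    skin  = c(0.80, 0.60, 0.50),
    lip   = c(0.72, 0.38, 0.42),
    mouth = c(0.10, 0.05, 0.06),
    tongue = switch(class_tag,
                    light_white = c(0.88, 0.72, 0.74),
                    red         = c(0.78, 0.39, 0.45),
                    purple      = c(0.50, 0.32, 0.44),
                    carmoisine  = c(0.56, 0.18, 0.24)),
    nose  = c(0.74, 0.56, 0.44),
    trap  = c(0.60, 0.33, 0.36))
  if (!is.null(colors)) pal[names(colors)] <- colors
  spec <- list(H = as.integer(H), W = as.integer(W), center_col = center_col,
               halfwidth = halfwidth, angular_row_left = angular_row_left,
               angular_row_right = angular_row_right, tip_row = tip_row,
               top_row = top_row, mouth_gap_height = mouth_gap_height,
               lip_thickness = lip_thickness,
               lower_lip_thickness = lower_lip_thickness, nose = nose,
               trap = isTRUE(trap), class_tag = class_tag, colors = pal,
               noise_sigma = noise_sigma, seed = as.integer(seed),
               min_contrast = min_contrast)
  class(spec) <- "dgf_scene_spec"
  validate_scene_spec(spec)
  spec
}

validate_scene_spec <- function(s) {
  margin <- 5
  arow_max <- max(s$angular_row_left, s$angular_row_right)
  if (s$center_col - s$halfwidth < 1 + margin ||
      s$center_col + s$halfwidth > s$W - margin ||
      s$tip_row > s$H - margin ||
      s$top_row - s$mouth_gap_height - s$lip_thickness < 1 + margin)
    stop("infeasible scene geometry: tongue/lips do not fit the frame",
         call. = FALSE)
  if (s$mouth_gap_height < 1) stop("mouth_gap_height must be >= 1", call. = FALSE)
  if (!(s$top_row < min(s$angular_row_left, s$angular_row_right)) ||
      !(s$tip_row > arow_max))
    stop("infeasible scene geometry: require top_row < angular rows < tip_row",
         call. = FALSE)
  cols <- s$colors[c("tongue", "lip", "skin", "mouth")]
  for (i in 1:3) for (j in (i + 1):4) {
    if (sqrt(sum((cols[[i]] - cols[[j]])^2)) < s$min_contrast)
      stop("region colors ", names(cols)[i], " and ", names(cols)[j],
           " are closer than min_contrast", call. = FALSE)
  }
  invisible(s)
}

# per-column boundary rows of the scene curves; s in [-1, 1]
scene_curves <- function(spec) {
  cl <- round(spec$center_col - spec$halfwidth)
  cr <- round(spec$center_col + spec$halfwidth)
  cols <- cl:cr
  s <- (cols - spec$center_col) / spec$halfwidth
  arow <- ifelse(s < 0, spec$angular_row_left, spec$angular_row_right)
  lower <- spec$tip_row + (arow - spec$tip_row) * s^2
  upper <- spec$top_row + (arow - spec$top_row) * s^2
  gap_top <- upper - spec$mouth_gap_height * (1 - s^2)
  lip_top <- gap_top - spec$lip_thickness * (1 - 0.3 * s^2)
  llip_taper <- pmin(pmax((abs(s) - 0.15) / 0.35, 0), 1)
  list(cols = cols, s = s, lower = lower, upper = upper, gap_top = gap_top,
       lip_top = lip_top, llip = spec$lower_lip_thickness * llip_taper)
}

#' Render a synthetic tongue scene with ground truth
#'
#' @param spec A [scene_spec()].
#' @return A `dgf_scene` list: `image` (`H x W x 3`), `tongue_mask`,
#'   `nose_mask`, `feature_points` ([feature_points()]), `boundary`
#'   (closed ground-truth tongue contour), `class_tag` and `spec`.
#' @export
generate_scene <- function(spec) {
  H <- spec$H; W <- spec$W
  img <- array(rep(spec$colors$skin, each = H * W), c(H, W, 3L))
  tongue <- matrix(0L, H, W)
  nose_mask <- matrix(0L, H, W)
  if (!is.null(spec$nose)) {
    nb <- round(spec$nose)
    nose_mask[nb[1L]:nb[2L], nb[3L]:nb[4L]] <- 1L
    for (ch in 1:3) img[, , ch][nose_mask == 1L] <- spec$colors$nose[ch]
  }
  cv <- scene_curves(spec)
  paint <- function(rows0, rows1, col, color) {
    r0 <- max(1L, min(H, round(rows0))); r1 <- max(1L, min(H, round(rows1)))
    if (r1 >= r0) for (ch in 1:3) img[r0:r1, col, ch] <<- color[ch]
    c(r0, r1)
  }
  for (k in seq_along(cv$cols)) {
    col <- cv$cols[k]
    # upper lip band
    paint(cv$lip_top[k], cv$gap_top[k] - 1, col, spec$colors$lip)
    # dark mouth opening (may be empty where the gap tapers out)
    if (round(cv$upper[k]) - 1 >= round(cv$gap_top[k]))
      paint(cv$gap_top[k], cv$upper[k] - 1, col, spec$colors$mouth)
    # tongue body
    rr <- paint(cv$upper[k], cv$lower[k], col, spec$colors$tongue)
    tongue[rr[1L]:rr[2L], col] <- 1L
    # lateral lower lip
    if (cv$llip[k] >= 1)
      paint(cv$lower[k] + 1, cv$lower[k] + cv$llip[k], col, spec$colors$lip)
  }
  if (spec$trap) {
    tr0 <- round(spec$top_row + 6); tr1 <- round(spec$top_row + 9)
    tc <- round(spec$center_col + c(-25, 25))
    for (ch in 1:3) img[tr0:tr1, tc[1L]:tc[2L], ch] <- spec$colors$trap[ch]
  }
  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    img <- img + stats::rnorm(length(img), 0, spec$noise_sigma)
    img[img < 0] <- 0; img[img > 1] <- 1
  }
  fp <- feature_points(
    left_angular = c(spec$angular_row_left, round(spec$center_col - spec$halfwidth)),
    right_angular = c(spec$angular_row_right, round(spec$center_col + spec$halfwidth)),
    tip = c(spec$tip_row, round(spec$center_col)),
    root = c(round((spec$top_row + min(spec$angular_row_left,
                                       spec$angular_row_right)) / 2),
             round(spec$center_col)))
  structure(list(image = as_rgb_image(img), tongue_mask = tongue,
                 nose_mask = nose_mask, feature_points = fp,
                 boundary = mask_to_contour(tongue),
                 class_tag = spec$class_tag, spec = spec),
            class = "dgf_scene")
}

#' Generate a reproducible suite of synthetic scenes
#'
#' Geometry (position, width, corner asymmetry, gap height), per-class color
#' jitter, and nose presence are randomized under the seed; the class mix is
#' allocated deterministically by proportion.
#'
#' @param n Number of scenes (`n >= 1`).
#' @param seed Integer master seed.
#' @param class_mix Named proportions over the four class tags; defaults to
#'   an equal mix.
#' @return List of `dgf_scene` objects.
#' @export
generate_suite <- function(n, seed = 0L,
                           class_mix = c(light_white = 0.25, red = 0.25,
                                         purple = 0.25, carmoisine = 0.25)) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  tags <- names(class_mix)
  counts <- floor(class_mix / sum(class_mix) * n)
  while (sum(counts) < n) {
    i <- which.max(class_mix / sum(class_mix) * n - counts)
    counts[i] <- counts[i] + 1
  }
  classes <- rep(tags, times = counts)
  set.seed(seed)
  classes <- sample(classes)
  scene_seeds <- seed + seq_len(n) - 1L
  lapply(seq_len(n), function(i) {
    set.seed(scene_seeds[i])
    hw <- runif(1, 55, 70)
    cx <- runif(1, 0.5 * 256 - 8, 0.5 * 256 + 8)
    arl <- runif(1, 112, 126)
    asym <- if (runif(1) < 0.35) runif(1, -6, 6) else 0
    arr <- min(max(arl + asym, 108), 130)
    tip <- runif(1, max(arl, arr) + 80, 232)
    top <- runif(1, 84, 95)
    gap <- runif(1, 3, 6)
    nose <- if (runif(1) < 0.3) c(20, 44, cx - 28, cx + 28) else NULL
    jit <- function(rgb) pmin(pmax(rgb + stats::rnorm(3, 0, 0.015), 0.02), 0.98)
    base <- scene_spec(class_tag = classes[i])$colors
    spec <- scene_spec(center_col = cx, halfwidth = hw, angular_row_left = arl,
                       angular_row_right = arr, tip_row = tip, top_row = top,
                       mouth_gap_height = gap, nose = nose,
                       class_tag = classes[i],
                       colors = list(tongue = jit(base$tongue),
                                     lip = jit(base$lip), skin = jit(base$skin)),
                       seed = scene_seeds[i])
    generate_scene(spec)
  })
}
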