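#' Segment the tongue body in an RGB image
#'
#' Runs the full double geo-vector flow: saliency window detection and
#' refinement, feature-point initialization, nose-removal refinement,
#' level-set / binary-map region initialization, the row-restricted geodesic
#' flow for the lower boundary, the Geo-GVF snake for the upper boundary,
#' and the junction of the two arcs into one closed contour.
#'
#' @param image `H x W x 3` RGB array in `[0, 1]` (see [read_image()]).
#' @param cfg A [dgf_config()].
#' @param upper_map `"binary"` (default) or `"gray"`: the map driving the
#'   upper GVF; `"gray"` reproduces the gray-map comparison and is not part
#'   of the standard pipeline.
#' @param use_geometric Disable the geometric propulsion term (ablation).
#' @param window Optional precomputed [dgf_window()] (skips saliency).
#' @param margin Fractional margin added around the selected window before
#'   cropping, so the lip corners and mouth opening stay in frame
#'   (default 0.15).
#' @return A `dgf_result` list: `mask` (full-frame 0/1), `contour` (closed,
#'   full-frame), `window`, `feature_points` (full-frame), `sline`
#'   (full-frame row), `iterations`, `converged`, `config`.
#' @export
segment <- function(image, cfg = dgf_config(),
                    upper_map = c("binary", "gray"), use_geometric = TRUE,
                    window = NULL, margin = 0.15) {
  upper_map <- match.arg(upper_map)
  stages <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      cond <- structure(class = c("dgf_stage_error", "error", "condition"),
                        list(message = paste0("stage '", name, "' failed: ",
                                              conditionMessage(e)),
                             call = NULL, stages = stages))
      stop(cond)
    })
  }
  H <- dim(image)[1L]; W <- dim(image)[2L]

  if (is.null(window)) {
    sal <- run_stage("saliency", compute_saliency_map(image))
    stages$saliency <- sal
    window <- run_stage("window", {
      select_tongue_window(detect_saliency_windows(sal, k = 2L))
    })
  }
  stages$window <- window
  mr <- round(margin * (window$row1 - window$row0 + 1L))
  mc <- round(margin * (window$col1 - window$col0 + 1L))
  win_e <- dgf_window(max(1L, window$row0 - mr), max(1L, window$col0 - mc),
                      min(H, window$row1 + mr), min(W, window$col1 + mc))
  img_c <- run_stage("crop", crop(image, win_e))
  off <- c(win_e$row0 - 1L, win_e$col0 - 1L)

  ang <- run_stage("angular_points", detect_angular_points(img_c))
  tr <- run_stage("tip_root", detect_tip_and_root(img_c, ang))
  fp <- run_stage("feature_points",
                  feature_points(ang$left, ang$right, tr$tip, tr$root))
  part <- partition(fp, nrow(img_c))
  B <- run_stage("binarize", binarize_upper(img_c, part))
  nose_win <- run_stage("remove_nose", remove_nose(B, fp))
  if (nose_win$row0 > 1L) {
    cut <- nose_win$row0 - 1L
    img_c <- crop(img_c, nose_win)
    off[1L] <- off[1L] + cut
    shift <- function(p) c(p[1L] - cut, p[2L])
    fp <- feature_points(shift(fp$left_angular), shift(fp$right_angular),
                         shift(fp$tip), shift(fp$root))
    part <- partition(fp, nrow(img_c))
    B <- run_stage("binarize", binarize_upper(img_c, part))
  }
  stages$feature_points <- fp

  contour0 <- run_stage("initial_contour", build_initial_contour(fp))
  phi0 <- run_stage("init_level_set",
                    init_level_set(contour0, dim(as_gray(img_c)), cfg$rho, part))
  g <- edge_indicator(as_gray(img_c), cfg$sigma)
  geo <- run_stage("geodesic", evolve_geodesic(phi0, g, cfg, part))
  lower_all <- run_stage("zero_contour", extract_zero_contour(geo$phi))
  lower_arc <- run_stage("lower_arc", split_lower_arc(lower_all, part$sline))

  Bmap <- if (upper_map == "binary") B else {
    gr <- as_gray(img_c)
    gr[seq(part$sline, nrow(gr)), ] <- 0
    gr
  }
  V <- run_stage("gvf", compute_binary_gvf(Bmap, cfg$w, cfg$gvf_iters, part))
  init_arc <- run_stage("snake_init", snake_state(
    rbind(fp$left_angular, fp$root, fp$right_angular),
    alpha = cfg$alpha, beta = cfg$beta,
    interior = c(part$sline + 0.2 * (nrow(img_c) - part$sline),
                 (fp$left_angular[2L] + fp$right_angular[2L]) / 2)))
  snk <- run_stage("snake", evolve_snake(init_arc, V, Bmap, cfg, use_geometric))

  joined <- run_stage("join", join_arcs(lower_arc, snk$state$points))
  full_contour <- dgf_contour(cbind(joined[, 1L] + off[1L],
                                    joined[, 2L] + off[2L]), closed = TRUE)
  mask <- run_stage("rasterize", contour_to_mask(full_contour, c(H, W)))

  fp_full <- feature_points(fp$left_angular + off, fp$right_angular + off,
                            fp$tip + off, fp$root + off)
  structure(list(mask = mask, contour = full_contour, window = window,
                 feature_points = fp_full, sline = part$sline + off[1L],
                 iterations = list(geodesic = geo$iterations,
                                   gvf = cfg$gvf_iters,
                                   snake = snk$iterations),
                 converged = list(geodesic = geo$converged,
                                  snake = snk$converged),
                 config = cfg),
            class = "dgf_result")
}

#' @export
print.dgf_result <- function(x, ...) {
  cat(sprintf("<dgf_result: mask %d x %d, %d contour points, sline %d>\n",
              nrow(x$mask), ncol(x$mask), nrow(x$contour), x$sline))
  cat(sprintf("  geodesic: %d iters (converged: %s); snake: %d iters (converged: %s)\n",
              x$iterations$geodesic, x$converged$geodesic,
              x$iterations$snake, x$converged$snake))
  invisible(x)
}

# longest cyclic run of contour points at or below the partition row,
# ordered left -> right
split_lower_arc <- function(contour, sline) {
  p <- unclass(contour)
  keep <- p[, 1L] >= sline - 0.5
  if (!any(keep)) stop("no contour points below the partition line", call. = FALSE)
  if (all(keep)) return(p)
  n <- length(keep)
  # rotate so the sequence starts right after a FALSE
  start <- which(!keep)[1L]
  ord <- c(seq(start, n), seq_len(start - 1L))
  kr <- keep[ord]
  r <- rle(kr)
  ends <- cumsum(r$lengths)
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  idx <- ord[seq(ends[best] - r$lengths[best] + 1L, ends[best])]
  arc <- p[idx, , drop = FALSE]
  if (arc[1L, 2L] > arc[nrow(arc), 2L]) arc <- arc[rev(seq_len(nrow(arc))), ]
  arc
}

# closed contour from the lower (geodesic) arc and the upper (snake) arc;
# both ordered left -> right, the upper arc is walked back right -> left
join_arcs <- function(lower_arc, upper_pts) {
  up <- upper_pts[rev(seq_len(nrow(upper_pts))), , drop = FALSE]
  dgf_contour(rbind(lower_arc, up), closed = TRUE)
}

#' Evaluate a segmentation against a reference scene or mask
#'
#' @param result A `dgf_result` (or a 0/1 mask).
#' @param ref A `dgf_scene` from [generate_scene()] or a 0/1 reference mask.
#' @return A [metrics_report()].
#' @export
evaluate_segmentation <- function(result, ref) {
  auto_mask <- if (inherits(result, "dgf_result")) result$mask else result
  auto_contour <- if (inherits(result, "dgf_result")) result$contour else NULL
  ref_mask <- if (inherits(ref, "dgf_scene")) ref$tongue_mask else ref
  ref_contour <- if (inherits(ref, "dgf_scene")) ref$boundary else NULL
  metrics_report(auto_mask, ref_mask, auto_contour, ref_contour)
}
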