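#' Hausdorff distance between two contours
#'
#' Symmetric Hausdorff distance over the contour point sets: the larger of
#' the two directed maximum nearest-neighbour distances. Distances are
#' point-to-point; resample contours (e.g. with [resample_contour()]) before
#' calling if uniform 1-px coverage is wanted — [metrics_report()] does so.
#'
#' @param a,b [dgf_contour()] objects (or `n x 2` matrices).
#' @return Distance in pixels.
#' @export
hausdorff <- function(a, b) {
  d <- cross_dist(a, b)
  max(max(apply(d, 1L, min)), max(apply(d, 2L, min)))
}

#' Mean distance to the closest point between two contours
#'
#' Symmetric mean of nearest-neighbour distances, averaging the two directed
#' means.
#'
#' @inheritParams hausdorff
#' @return Distance in pixels.
#' @export
mean_distance <- function(a, b) {
  d <- cross_dist(a, b)
  (mean(apply(d, 1L, min)) + mean(apply(d, 2L, min))) / 2
}

cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!nrow(a) || !nrow(b)) stop("empty contour", call. = FALSE)
  dr <- outer(a[, 1L], b[, 1L], "-")
  dc <- outer(a[, 2L], b[, 2L], "-")
  sqrt(dr^2 + dc^2)
}

#' Normalize a pixel distance to a percentage of the image diagonal
#'
#' @param d Distance in pixels (>= 0).
#' @param shape `c(H, W)` of the image.
#' @return `100 * d / sqrt(H^2 + W^2)`.
#' @export
normalize_distance <- function(d, shape) {
  stopifnot(d >= 0)
  100 * d / sqrt(shape[1L]^2 + shape[2L]^2)
}

#' Area error volume fractions
#'
#' False-positive, false-negative and true-positive volume fractions of an
#' automatic mask against a reference mask, all expressed relative to the
#' reference area, so that `TP + FN = 100` exactly.
#'
#' @param auto,ref 0/1 matrices of the same shape; `ref` must be nonempty.
#' @return Named vector `c(fp, fn, tp)` in percent.
#' @export
volume_fractions <- function(auto, ref) {
  if (!identical(dim(auto), dim(ref))) stop("mask shapes differ", call. = FALSE)
  nref <- sum(ref == 1)
  if (nref == 0) stop("empty reference mask", call. = FALSE)
  tp <- sum(auto == 1 & ref == 1) / nref * 100
  fn <- sum(auto == 0 & ref == 1) / nref * 100
  fp <- sum(auto == 1 & ref == 0) / nref * 100
  c(fp = fp, fn = fn, tp = tp)
}

#' Full metrics report for one segmentation
#'
#' Boundary metrics (Hausdorff and mean distance, raw and normalized by the
#' image diagonal) are computed on 1-px resampled contours; area metrics on
#' the masks. Contours default to the mask boundaries when not supplied.
#'
#' @param auto,ref 0/1 masks (automatic and reference).
#' @param auto_contour,ref_contour Optional [dgf_contour()] overrides.
#' @return A `dgf_metrics` list: `norm_hd`, `norm_md`, `fp`, `fn`, `tp`
#'   (percent), `raw_hd`, `raw_md` (pixels).
#' @export
metrics_report <- function(auto, ref, auto_contour = NULL, ref_contour = NULL) {
  if (is.null(auto_contour)) auto_contour <- mask_to_contour(auto)
  if (is.null(ref_contour)) ref_contour <- mask_to_contour(ref)
  ca <- resample_contour(auto_contour, 1)
  cr <- resample_contour(ref_contour, 1)
  hd <- hausdorff(ca, cr)
  md <- mean_distance(ca, cr)
  vf <- volume_fractions(auto, ref)
  structure(list(norm_hd = normalize_distance(hd, dim(ref)),
                 norm_md = normalize_distance(md, dim(ref)),
                 fp = unname(vf["fp"]), fn = unname(vf["fn"]),
                 tp = unname(vf["tp"]), raw_hd = hd, raw_md = md),
            class = "dgf_metrics")
}

#' @export
print.dgf_metrics <- function(x, ...) {
  cat(sprintf("norm.HD %.3f%%  norm.MD %.3f%%  FN %.2f%%  FP %.2f%%  TP %.2f%%\n",
              x$norm_hd, x$norm_md, x$fn, x$fp, x$tp))
  invisible(x)
}
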