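#' Contour objects
#'
#' A contour is an ordered polyline of `(row, col)` image coordinates,
#' 1-based, row increasing downward, stored as an `n x 2` matrix with a
#' `closed` attribute. Closed contours are simple polygons; the closing
#' segment from the last to the first point is implicit (the first point is
#' not repeated).
#'
#' @param points Numeric `n x 2` matrix (or 2-column data frame) of
#'   `(row, col)` coordinates.
#' @param closed Logical flag; closed contours need at least 3 points.
#' @return A `dgf_contour` object.
#' @export
dgf_contour <- function(points, closed = TRUE) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("contour points must be an n x 2 matrix", call. = FALSE)
  storage.mode(points) <- "double"
  colnames(points) <- c("row", "col")
  # drop consecutive duplicates (including a repeated closing point)
  if (nrow(points) > 1L) {
    d <- rowSums(abs(points - points[c(nrow(points), seq_len(nrow(points) - 1L)), ])) > 1e-12
    d[1L] <- TRUE
    points <- points[d, , drop = FALSE]
    if (closed && nrow(points) > 1L &&
        sum(abs(points[1L, ] - points[nrow(points), ])) < 1e-12)
      points <- points[-nrow(points), , drop = FALSE]
  }
  if (closed && nrow(points) < 3L)
    stop("a closed contour needs at least 3 distinct points", call. = FALSE)
  if (!closed && nrow(points) < 2L)
    stop("an open contour needs at least 2 points", call. = FALSE)
  structure(points, closed = closed, class = c("dgf_contour", "matrix", "array"))
}

#' @export
print.dgf_contour <- function(x, ...) {
  cat(sprintf("<dgf_contour: %d points, %s>\n", nrow(x),
              if (isTRUE(attr(x, "closed"))) "closed" else "open"))
  invisible(x)
}

is_closed <- function(contour) isTRUE(attr(contour, "closed"))

contour_edges <- function(contour) {
  p <- unclass(contour)
  n <- nrow(p)
  if (is_closed(contour)) cbind(p, p[c(seq_len(n)[-1L], 1L), , drop = FALSE])
  else cbind(p[-n, , drop = FALSE], p[-1L, , drop = FALSE])
}

#' Contour length (perimeter for closed contours)
#' @param contour A [dgf_contour()].
#' @return Total polyline length in pixels.
#' @export
contour_length <- function(contour) {
  e <- contour_edges(contour)
  sum(sqrt((e[, 3L] - e[, 1L])^2 + (e[, 4L] - e[, 2L])^2))
}

#' Signed polygon area of a closed contour (shoelace; positive for
#' counter-clockwise orientation in (row, col) axes)
#' @param contour A closed [dgf_contour()].
#' @return Signed area in square pixels.
#' @export
contour_area <- function(contour) {
  if (!is_closed(contour)) stop("area requires a closed contour", call. = FALSE)
  e <- contour_edges(contour)
  sum(e[, 1L] * e[, 4L] - e[, 3L] * e[, 2L]) / 2
}

#' Resample a contour at (approximately) uniform arc-length spacing
#'
#' Linear interpolation along the polyline; closed contours keep their
#' orientation and stay closed.
#'
#' @param contour A [dgf_contour()].
#' @param spacing Target spacing in pixels (default 1).
#' @return A resampled `dgf_contour`.
#' @export
resample_contour <- function(contour, spacing = 1) {
  p <- unclass(contour)
  closed <- is_closed(contour)
  if (closed) p <- rbind(p, p[1L, ])
  seg <- sqrt(diff(p[, 1L])^2 + diff(p[, 2L])^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) stop("degenerate contour of zero length", call. = FALSE)
  n_out <- max(if (closed) 3L else 2L, round(total / spacing))
  t_out <- if (closed) seq(0, total, length.out = n_out + 1L)[-(n_out + 1L)]
  else seq(0, total, length.out = n_out + 1L)
  dgf_contour(cbind(stats::approx(s, p[, 1L], xout = t_out)$y,
                    stats::approx(s, p[, 2L], xout = t_out)$y), closed = closed)
}

#' Test whether a contour is simple (no self-intersections)
#'
#' Pairwise segment-intersection test with a bounding-box prefilter; adjacent
#' segments sharing an endpoint are exempt.
#'
#' @param contour A [dgf_contour()].
#' @param tol Numerical tolerance.
#' @return `TRUE` if no two non-adjacent segments intersect.
#' @export
contour_is_simple <- function(contour, tol = 1e-9) {
  e <- contour_edges(contour)
  n <- nrow(e)
  if (n < 4L) return(TRUE)
  closed <- is_closed(contour)
  cross2 <- function(ax, ay, bx, by) ax * by - ay * bx
  for (i in seq_len(n - 2L)) {
    jmax <- if (closed && i == 1L) n - 1L else n
    js <- seq(i + 2L, length.out = max(0L, jmax - i - 1L))
    if (!length(js)) next
    # bounding-box prefilter
    keep <- pmax(e[js, 1L], e[js, 3L]) >= min(e[i, 1L], e[i, 3L]) - tol &
      pmin(e[js, 1L], e[js, 3L]) <= max(e[i, 1L], e[i, 3L]) + tol &
      pmax(e[js, 2L], e[js, 4L]) >= min(e[i, 2L], e[i, 4L]) - tol &
      pmin(e[js, 2L], e[js, 4L]) <= max(e[i, 2L], e[i, 4L]) + tol
    for (j in js[keep]) {
      d1 <- cross2(e[i, 3L] - e[i, 1L], e[i, 4L] - e[i, 2L],
                   e[j, 1L] - e[i, 1L], e[j, 2L] - e[i, 2L])
      d2 <- cross2(e[i, 3L] - e[i, 1L], e[i, 4L] - e[i, 2L],
                   e[j, 3L] - e[i, 1L], e[j, 4L] - e[i, 2L])
      d3 <- cross2(e[j, 3L] - e[j, 1L], e[j, 4L] - e[j, 2L],
                   e[i, 1L] - e[j, 1L], e[i, 2L] - e[j, 2L])
      d4 <- cross2(e[j, 3L] - e[j, 1L], e[j, 4L] - e[j, 2L],
                   e[i, 3L] - e[j, 1L], e[i, 4L] - e[j, 2L])
      if (((d1 > tol && d2 < -tol) || (d1 < -tol && d2 > tol)) &&
          ((d3 > tol && d4 < -tol) || (d3 < -tol && d4 > tol))) return(FALSE)
    }
  }
  TRUE
}

# pixels (integer centers) traversed by the contour outline
outline_pixels <- function(contour, shape) {
  dense <- resample_contour(contour, spacing = 0.4)
  r <- pmin(pmax(round(dense[, 1L]), 1L), shape[1L])
  c <- pmin(pmax(round(dense[, 2L]), 1L), shape[2L])
  unique(cbind(r, c))
}

# distance from points (r, c) to segment (r1,c1)-(r2,c2), vectorized over points
point_seg_dist <- function(r, c, r1, c1, r2, c2) {
  vr <- r2 - r1; vc <- c2 - c1
  len2 <- vr^2 + vc^2
  if (len2 < 1e-24) return(sqrt((r - r1)^2 + (c - c1)^2))
  t <- pmin(pmax(((r - r1) * vr + (c - c1) * vc) / len2, 0), 1)
  sqrt((r - (r1 + t * vr))^2 + (c - (c1 + t * vc))^2)
}

#' Rasterize a closed contour to a binary mask
#'
#' A pixel is set to 1 when its (integer) center lies strictly inside the
#' polygon (even-odd scanline rule) or on its outline (distance to the
#' nearest polygon segment below `tol`).
#'
#' @param contour A closed [dgf_contour()].
#' @param shape Integer `c(H, W)` of the output mask.
#' @param tol On-boundary tolerance in pixels (default 1e-7).
#' @return An `H x W` 0/1 integer matrix.
#' @export
contour_to_mask <- function(contour, shape, tol = 1e-7) {
  if (!is_closed(contour)) stop("contour_to_mask requires a closed contour", call. = FALSE)
  H <- as.integer(shape[1L]); W <- as.integer(shape[2L])
  mask <- matrix(0L, H, W)
  e <- contour_edges(contour)
  # even-odd scanline fill at integer pixel-center rows
  for (r in seq_len(H)) {
    up <- e[, 1L] > r; dn <- e[, 3L] > r
    hit <- which(up != dn)
    if (!length(hit)) next
    xs <- e[hit, 2L] + (r - e[hit, 1L]) / (e[hit, 3L] - e[hit, 1L]) *
      (e[hit, 4L] - e[hit, 2L])
    xs <- sort(xs)
    for (k in seq(1L, length(xs) - 1L, by = 2L)) {
      c0 <- ceiling(xs[k] - tol); c1 <- floor(xs[k + 1L] + tol)
      if (c1 >= c0) {
        c0 <- max(1L, c0); c1 <- min(W, c1)
        if (c1 >= c0) mask[r, c0:c1] <- 1L
      }
    }
  }
  # boundary pass: pixel centers on the outline count as inside
  cand <- outline_pixels(contour, c(H, W))
  if (nrow(cand)) {
    on_b <- rep(FALSE, nrow(cand))
    for (i in seq_len(nrow(e))) {
      todo <- which(!on_b)
      if (!length(todo)) break
      d <- point_seg_dist(cand[todo, 1L], cand[todo, 2L],
                          e[i, 1L], e[i, 2L], e[i, 3L], e[i, 4L])
      on_b[todo[d <= tol]] <- TRUE
    }
    sel <- cand[on_b, , drop = FALSE]
    if (nrow(sel)) mask[sel] <- 1L
  }
  mask
}

#' Trace the boundary of a binary mask as a closed contour
#'
#' Marching-squares isoline of the mask at level 0.5; when the mask has
#' several components the longest boundary is returned.
#'
#' @param mask 0/1 matrix.
#' @return A closed [dgf_contour()].
#' @export
mask_to_contour <- function(mask) {
  if (!any(mask > 0)) stop("empty mask has no boundary", call. = FALSE)
  # pad so that components touching the border still yield closed loops
  pad <- matrix(0, nrow(mask) + 2L, ncol(mask) + 2L)
  pad[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  cl <- grDevices::contourLines(seq_len(nrow(pad)) - 1L, seq_len(ncol(pad)) - 1L,
                                pad, levels = 0.5)
  if (!length(cl)) stop("no boundary found", call. = FALSE)
  best <- cl[[which.max(vapply(cl, function(z) length(z$x), numeric(1)))]]
  dgf_contour(cbind(best$x, best$y), closed = TRUE)
}

#' Write a contour to CSV (columns index, row, col) or JSON
#' @param contour A [dgf_contour()].
#' @param path Output path; format chosen by extension (`.csv` or `.json`).
#' @return Invisibly, `path`.
#' @export
write_contour <- function(contour, path) {
  df <- data.frame(index = seq_len(nrow(contour)) - 1L,
                   row = contour[, 1L], col = contour[, 2L])
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(closed = is_closed(contour), points = df), path,
                         auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a contour written by [write_contour()]
#' @param path CSV or JSON path.
#' @param closed Closed flag for CSV input (JSON stores it).
#' @return A [dgf_contour()].
#' @export
read_contour <- function(path, closed = TRUE) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    dgf_contour(cbind(obj$points$row, obj$points$col), closed = isTRUE(obj$closed))
  } else {
    df <- utils::read.csv(path)
    dgf_contour(cbind(df$row, df$col), closed = closed)
  }
}
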