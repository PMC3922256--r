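#' Edge indicator map
#'
#' `g = 1 / (1 + |grad(G_sigma * I)|^2)` with the gradient evaluated on the
#' 8-bit intensity scale (`I * 255`), matching the convention of the
#' reference implementation environment in which the flow weights
#' (`lambda = 3`, `nu = 0.5`) were set; on the unit scale no realistic edge
#' would produce an order-one gradient. `g` is close to 1 in flat regions
#' and approaches 0 at strong edges.
#'
#' @param image Gray matrix in `[0, 1]` (or RGB array, converted).
#' @param sigma Gaussian smoothing s.d. in pixels.
#' @param gain Intensity scale factor applied before differentiation
#'   (default 255).
#' @return Matrix `g` in `(0, 1]` with attributes `sigma` and `gain`.
#' @export
edge_indicator <- function(image, sigma, gain = 255) {
  stopifnot(sigma > 0)
  gray <- as_gray(image)
  sm <- gauss_smooth(gray * gain, sigma)
  g <- 1 / (1 + grad_row(sm)^2 + grad_col(sm)^2)
  attr(g, "sigma") <- sigma
  attr(g, "gain") <- gain
  g
}

#' Level-set curvature field
#'
#' `kappa = div(grad(phi) / |grad(phi)|)` by central differences with an
#' epsilon-guarded norm.
#'
#' @param phi Level-set matrix.
#' @return Matrix of the same size.
#' @export
curvature <- function(phi) {
  gr <- grad_row(phi); gc <- grad_col(phi)
  n <- grad_norm(gr, gc)
  grad_row(gr / n) + grad_col(gc / n)
}

# smoothed Dirac delta concentrating updates near the zero level set
dirac_eps <- function(phi, eps = 1.5) {
  d <- matrix(0, nrow(phi), ncol(phi))
  in_band <- abs(phi) <= eps
  d[in_band] <- (1 / (2 * eps)) * (1 + cos(pi * phi[in_band] / eps))
  d
}

geodesic_rhs <- function(phi, g, cfg) {
  gr <- grad_row(phi); gc <- grad_col(phi)
  n <- grad_norm(gr, gc)
  nx <- gr / n; ny <- gc / n
  curv <- grad_row(nx) + grad_col(ny)
  lap <- laplacian(phi)
  dd <- dirac_eps(phi)
  div_gn <- grad_row(g * nx) + grad_col(g * ny)
  list(S = cfg$mu * (lap - curv) + cfg$lambda * dd * div_gn + cfg$nu * g * dd,
       terms = list(regularization = lap - curv, length = div_gn, area = g * dd))
}

#' One explicit Euler step of the row-restricted geodesic flow
#'
#' Updates `phi` by `tau` times the three-term right-hand side (distance
#' regularization, edge-weighted length, edge-weighted area) on the rows from
#' `sline` down; rows above `sline` are returned exactly as given, so the
#' upper half of the initialization is held fixed while the lower contour
#' shrinks.
#'
#' @param phi Level-set matrix.
#' @param g Edge indicator from [edge_indicator()].
#' @param cfg A [dgf_config()].
#' @param part A [partition()].
#' @return Updated level-set matrix.
#' @export
geodesic_step <- function(phi, g, cfg, part) {
  validate_config(cfg)
  rhs <- geodesic_rhs(phi, g, cfg)
  out <- phi + cfg$tau * rhs$S
  if (part$sline > 1L) {
    keep <- seq_len(part$sline - 1L)
    out[keep, ] <- phi[keep, ]
  }
  if (any(!is.finite(out))) {
    bad <- names(rhs$terms)[vapply(rhs$terms, function(t) any(!is.finite(t)),
                                   logical(1))]
    stop("geodesic flow diverged (non-finite values); offending term(s): ",
         paste(if (length(bad)) bad else "time step", collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Evolve the geodesic level-set flow to convergence
#'
#' Iterates [geodesic_step()] until the zero-level pixel set
#' (`phi < 0`) is unchanged for `patience` consecutive iterations or the
#' iteration budget is exhausted. No re-initialization to a signed distance
#' function is performed: the distance-regularization term keeps the level
#' set well-behaved throughout.
#'
#' @param phi0 Initial level set from [init_level_set()].
#' @param g Edge indicator.
#' @param cfg A [dgf_config()]; `cfg$geodesic_iters` caps the iterations.
#' @param part A [partition()].
#' @param patience Iterations of an unchanged zero set required for
#'   convergence (default 20).
#' @return List `(phi, iterations, converged)`.
#' @export
evolve_geodesic <- function(phi0, g, cfg, part, patience = 20L) {
  phi <- phi0
  prev <- phi < 0
  stable <- 0L
  iters <- 0L
  converged <- FALSE
  while (iters < cfg$geodesic_iters) {
    phi <- tryCatch(geodesic_step(phi, g, cfg, part),
                    error = function(e) stop(conditionMessage(e),
                                             " at iteration ", iters + 1L,
                                             call. = FALSE))
    iters <- iters + 1L
    cur <- phi < 0
    if (identical(cur, prev)) {
      stable <- stable + 1L
      if (stable >= patience) { converged <- TRUE; break }
    } else stable <- 0L
    prev <- cur
  }
  list(phi = phi, iterations = iters, converged = converged)
}

#' Extract the zero-level contour of a level set
#'
#' Marching-squares isoline of `phi = 0` with linear interpolation along grid
#' cell edges; when the level set has split into several loops the longest
#' one is returned, as a closed contour.
#'
#' @param phi Level-set matrix containing a sign change.
#' @return A closed [dgf_contour()].
#' @export
extract_zero_contour <- function(phi) {
  if (min(phi) >= 0 || max(phi) <= 0)
    stop("level set has no zero crossing: empty contour", call. = FALSE)
  cl <- grDevices::contourLines(seq_len(nrow(phi)), seq_len(ncol(phi)),
                                phi, levels = 0)
  if (!length(cl)) stop("level set has no zero crossing: empty contour",
                        call. = FALSE)
  lens <- vapply(cl, function(z) {
    sum(sqrt(diff(z$x)^2 + diff(z$y)^2))
  }, numeric(1))
  best <- cl[[which.max(lens)]]
  dgf_contour(cbind(best$x, best$y), closed = TRUE)
}
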