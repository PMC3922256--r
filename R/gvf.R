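#' Snake state for the upper-contour arc
#'
#' An open polyline from the left angular point to the right angular point;
#' the endpoints stay pinned throughout the evolution (they are the junction
#' with the lower geodesic contour). `interior` is a reference point inside
#' the tongue body used to orient the outward normals (away from the
#' interior, i.e. upward for the upper arc).
#'
#' @param points `n x 2` matrix of `(row, col)` coordinates (n >= 5 after
#'   resampling).
#' @param alpha,beta Internal-force weights (elasticity, rigidity).
#' @param interior `(row, col)` reference point inside the tongue.
#' @return A `dgf_snake` object.
#' @export
snake_state <- function(points, alpha = 1, beta = 1, interior = NULL) {
  contour <- resample_contour(dgf_contour(points, closed = FALSE), spacing = 1)
  if (nrow(contour) < 5L)
    stop("snake needs at least 5 points after resampling", call. = FALSE)
  if (is.null(interior))
    interior <- c(max(contour[, 1L]) + 10, mean(contour[, 2L]))
  structure(list(points = unclass(contour), alpha = alpha, beta = beta,
                 interior = as.numeric(interior)),
            class = "dgf_snake")
}

#' @export
print.dgf_snake <- function(x, ...) {
  cat(sprintf("<dgf_snake: %d points, alpha=%g, beta=%g>\n",
              nrow(x$points), x$alpha, x$beta))
  invisible(x)
}

bilinear_sample <- function(mat, r, c) {
  H <- nrow(mat); W <- ncol(mat)
  r <- pmin(pmax(r, 1), H); c <- pmin(pmax(c, 1), W)
  r0 <- pmin(floor(r), H - 1L); c0 <- pmin(floor(c), W - 1L)
  fr <- r - r0; fc <- c - c0
  mat[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    mat[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    mat[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    mat[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}

#' Gradient vector flow of a binary map
#'
#' Iterates the diffusion-reaction update
#' `dV/dt = w * lap(V) - |grad B|^2 (V - grad B)` from `V = grad B`,
#' with a constant smoothing weight `w` and reaction strength `|grad B|^2`.
#' The field lives on the upper partition rows only; rows from `sline` down
#' are held at zero (no force in the under part). The time step satisfies
#' the explicit 4-neighbour diffusion stability bound for the given `w`.
#'
#' @param B 0/1 matrix from [binarize_upper()] (or any map; a gray map may
#'   be passed to reproduce the gray-vs-binary comparison).
#' @param w Smoothing weight (> 0).
#' @param iters Number of diffusion iterations (>= 1).
#' @param part A [partition()].
#' @return A `dgf_vector_field` list with `u` (row component) and `v`
#'   (col component).
#' @export
compute_binary_gvf <- function(B, w, iters, part) {
  stopifnot(w > 0, iters >= 1)
  B <- matrix(as.numeric(B), nrow(B), ncol(B))
  br <- grad_row(B); bc <- grad_col(B)
  h <- br^2 + bc^2
  lower <- seq(part$sline, nrow(B))
  zero_lower <- function(m) { m[lower, ] <- 0; m }
  br <- zero_lower(br); bc <- zero_lower(bc); h <- zero_lower(h)
  # explicit stability: |1 - dt (8 w + h)| <= 1 for the worst Laplacian mode
  dt <- 0.9 * 2 / (8 * w + max(h))
  u <- br; v <- bc
  for (it in seq_len(iters)) {
    u <- zero_lower(u + dt * (w * laplacian(u) - h * (u - br)))
    v <- zero_lower(v + dt * (w * laplacian(v) - h * (v - bc)))
    if (it %% 50L == 0L && (any(!is.finite(u)) || any(!is.finite(v))))
      stop("GVF diverged; reduce w or the time step (explicit ",
           "stability requires dt (8 w + h) <= 2)", call. = FALSE)
  }
  if (any(!is.finite(u)) || any(!is.finite(v)))
    stop("GVF diverged; reduce w or the time step (explicit ",
         "stability requires dt (8 w + h) <= 2)", call. = FALSE)
  structure(list(u = u, v = v, w = w, dt = dt, grad_u = br, grad_v = bc, h = h),
            class = "dgf_vector_field")
}

# unit outward normals of an open polyline, oriented away from `interior`
snake_normals <- function(points, interior) {
  n <- nrow(points)
  nxt <- points[c(2:n, n), , drop = FALSE]
  prv <- points[c(1, 1:(n - 1)), , drop = FALSE]
  tr <- nxt[, 1L] - prv[, 1L]; tc <- nxt[, 2L] - prv[, 2L]
  len <- sqrt(tr^2 + tc^2)
  if (any(len < 1e-12))
    stop("degenerate normal: repeated contour points", call. = FALSE)
  nr <- -tc / len; nc <- tr / len
  flip <- (points[, 1L] - interior[1L]) * nr +
    (points[, 2L] - interior[2L]) * nc < 0
  nr[flip] <- -nr[flip]; nc[flip] <- -nc[flip]
  cbind(nr, nc)
}

#' Geometric propulsion term
#'
#' `G_B(p) = g_B(p) * n_hat(p)`: the edge indicator of the binary map times
#' the unit outward normal. Far from any binary edge `g_B` is 1 and the term
#' propels the curve outward at unit strength; on a strong edge `g_B`
#' vanishes and the term switches off.
#'
#' @param B 0/1 matrix.
#' @param contour A [snake_state()] (normals come from its polyline and
#'   interior reference).
#' @param sigma Gaussian smoothing of the edge indicator, pixels.
#' @return `n x 2` matrix of per-point force vectors (row, col components).
#' @export
geometric_term <- function(B, contour, sigma = 1.5) {
  gB <- edge_indicator(matrix(as.numeric(B), nrow(B), ncol(B)), sigma)
  p <- contour$points
  nrm <- snake_normals(p, contour$interior)
  gb <- bilinear_sample(gB, p[, 1L], p[, 2L])
  cbind(gb * nrm[, 1L], gb * nrm[, 2L])
}

# internal-force stiffness matrix (alpha C'' - beta C'''') for pinned ends;
# the one-sided 4th-difference rows use the natural mirror extension
snake_stiffness <- function(n, alpha, beta) {
  K <- matrix(0, n, n)
  add <- function(i, js, ws) for (k in seq_along(js))
    K[i, js[k]] <<- K[i, js[k]] + ws[k]
  for (i in 2:(n - 1)) add(i, (i - 1):(i + 1), alpha * c(1, -2, 1))
  if (n >= 5) {
    for (i in 3:(n - 2)) add(i, (i - 2):(i + 2), -beta * c(1, -4, 6, -4, 1))
    add(2L, 1:4, -beta * c(-2, 5, -4, 1))
    add(n - 1L, n:(n - 3), -beta * c(-2, 5, -4, 1))
  }
  K[1L, ] <- 0; K[n, ] <- 0
  K
}

#' One semi-implicit snake step
#'
#' Internal forces (`alpha C'' - beta C''''`) are treated implicitly
#' (pentadiagonal solve with pinned endpoints); the external force is
#' explicit and switches per point: the GVF force `V_B(p)` where its
#' magnitude reaches `theta_v`, the geometric propulsion `G_B(p)` where the
#' GVF is negligible (the far-field/near-field switch).
#'
#' @param state A [snake_state()].
#' @param V A `dgf_vector_field` from [compute_binary_gvf()].
#' @param G Per-point geometric term from [geometric_term()] (or `NULL` to
#'   disable it).
#' @param cfg A [dgf_config()] (`snake_gamma`, `theta_v`, `alpha`, `beta`
#'   are read; the state's `alpha`/`beta` take precedence when set).
#' @return Updated [snake_state()] (not resampled).
#' @export
snake_step <- function(state, V, G, cfg) {
  p <- state$points
  n <- nrow(p)
  gamma <- cfg$snake_gamma
  vu <- bilinear_sample(V$u, p[, 1L], p[, 2L])
  vv <- bilinear_sample(V$v, p[, 1L], p[, 2L])
  vmag <- sqrt(vu^2 + vv^2)
  use_v <- vmag >= cfg$theta_v
  Fr <- ifelse(use_v, vu, if (is.null(G)) 0 else G[, 1L])
  Fc <- ifelse(use_v, vv, if (is.null(G)) 0 else G[, 2L])
  Fr[c(1L, n)] <- 0; Fc[c(1L, n)] <- 0
  K <- snake_stiffness(n, state$alpha, state$beta)
  M <- diag(n) - gamma * K
  new_p <- tryCatch(cbind(solve(M, p[, 1L] + gamma * Fr),
                          solve(M, p[, 2L] + gamma * Fc)),
                    error = function(e) stop("singular internal-force system: ",
                                             conditionMessage(e), call. = FALSE))
  state$points <- new_p
  state
}

#' Evolve the Geo-GVF snake to convergence
#'
#' Iterates [snake_step()] with per-iteration arc-length resampling until the
#' maximum point displacement stays below 0.05 px for 10 consecutive
#' iterations, or `cfg$snake_iters` is reached.
#'
#' @param init A [snake_state()] (the straight-line arc through the root).
#' @param V GVF field.
#' @param B Binary map (for the geometric term's edge indicator).
#' @param cfg A [dgf_config()].
#' @param use_geometric Disable to reproduce the no-propulsion ablation.
#' @return List `(state, iterations, converged)`.
#' @export
evolve_snake <- function(init, V, B, cfg, use_geometric = TRUE) {
  state <- init
  gB <- if (use_geometric) edge_indicator(matrix(as.numeric(B), nrow(B), ncol(B)),
                                          cfg$sigma) else NULL
  # propulsion is only meaningful over columns where the binarized mouth
  # opening exists; beyond its lateral extent there is no boundary above to
  # stop an outward push, and the internal forces interpolate instead
  csupp <- which(colSums(B != 0) > 0)
  col_ok <- function(cols) {
    if (!length(csupp)) rep(FALSE, length(cols))
    else cols >= min(csupp) - 2 & cols <= max(csupp) + 2
  }
  stable <- 0L; iters <- 0L; converged <- FALSE
  while (iters < cfg$snake_iters) {
    G <- if (use_geometric) {
      nrm <- snake_normals(state$points, state$interior)
      gb <- bilinear_sample(gB, state$points[, 1L], state$points[, 2L]) *
        col_ok(state$points[, 2L])
      cbind(gb * nrm[, 1L], gb * nrm[, 2L])
    } else NULL
    old <- state$points
    state <- snake_step(state, V, G, cfg)
    iters <- iters + 1L
    disp <- max(sqrt(rowSums((state$points - old)^2)))
    resampled <- resample_contour(dgf_contour(state$points, closed = FALSE),
                                  spacing = 1)
    state$points <- unclass(resampled)
    if (disp < 0.05) {
      stable <- stable + 1L
      if (stable >= 10L) { converged <- TRUE; break }
    } else stable <- 0L
  }
  list(state = state, iterations = iters, converged = converged)
}
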