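#' Context-contrast saliency map
#'
#' A deliberately simple global-context saliency model: each pixel scores by
#' the CIELab distance between its color and the mean image color, the score
#' field is Gaussian-smoothed, then normalized to `[0, 1]`. Regions whose
#' color contrasts most with the scene as a whole — the dark red tongue body
#' against facial skin — score highest. (This is a documented stand-in for an
#' external salient-object detector; only its downstream contract matters:
#' the tongue is the brightest compact region of the map.)
#'
#' @param image `H x W x 3` RGB array in `[0, 1]`.
#' @param smooth_sigma Gaussian smoothing of the raw contrast field, in
#'   pixels (default 3).
#' @return `H x W` matrix in `[0, 1]`; all zeros (with attribute
#'   `flat = TRUE`) for a constant image.
#' @export
compute_saliency_map <- function(image, smooth_sigma = 3) {
  H <- dim(image)[1L]; W <- dim(image)[2L]
  rgb <- cbind(as.vector(image[, , 1L]), as.vector(image[, , 2L]),
               as.vector(image[, , 3L]))
  lab <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
  mu <- colMeans(lab)
  d <- sqrt((lab[, 1L] - mu[1L])^2 + (lab[, 2L] - mu[2L])^2 +
              (lab[, 3L] - mu[3L])^2)
  sal <- gauss_smooth(matrix(d, H, W), smooth_sigma)
  rng <- range(sal)
  if (rng[2L] - rng[1L] < 1e-9) {
    return(structure(matrix(0, H, W), flat = TRUE))
  }
  (sal - rng[1L]) / (rng[2L] - rng[1L])
}

# integral-image rectangle sums: S[r, c] = sum(map[1:r, 1:c]), padded row/col 0
integral_image <- function(map) {
  S <- matrix(0, nrow(map) + 1L, ncol(map) + 1L)
  S[-1L, -1L] <- t(apply(apply(map, 2L, cumsum), 1L, cumsum))
  S
}

rect_sum <- function(S, r0, c0, r1, c1) {
  S[cbind(r1 + 1L, c1 + 1L)] - S[cbind(r0, c1 + 1L)] -
    S[cbind(r1 + 1L, c0)] + S[cbind(r0, c0)]
}

# composition-style window objective: saliency captured inside minus a
# penalty on saliency left in a surrounding margin ring, minus a per-pixel
# area cost theta (a marginal pixel must carry at least theta saliency to be
# worth including; without it the maximizer is always the full frame, whose
# margin ring is clamped away at the borders).
window_score <- function(S, H, W, r0, c0, r1, c1, penalty = 0.5,
                         margin_frac = 0.1, theta = 0.15) {
  mr <- pmax(1L, round(margin_frac * (r1 - r0 + 1L)))
  mc <- pmax(1L, round(margin_frac * (c1 - c0 + 1L)))
  er0 <- pmax(1L, r0 - mr); ec0 <- pmax(1L, c0 - mc)
  er1 <- pmin(H, r1 + mr); ec1 <- pmin(W, c1 + mc)
  inside <- rect_sum(S, r0, c0, r1, c1)
  ring <- rect_sum(S, er0, ec0, er1, ec1) - inside
  inside - penalty * ring - theta * (r1 - r0 + 1L) * (c1 - c0 + 1L)
}

#' Detect the highest-scoring saliency windows
#'
#' Maximizes the composition objective (saliency inside minus a penalty on
#' saliency in a surrounding margin ring). Small maps (at most 50 x 50) are
#' searched exhaustively over every rectangle; larger maps use a coarse
#' position/scale grid followed by greedy boundary refinement. Successive
#' windows are required to overlap the already-selected ones by at most 30%
#' (intersection over the smaller area); candidates scoring below 10% of the
#' best window are not reported, so fewer than `k` windows may be returned.
#'
#' @param map Saliency map from [compute_saliency_map()].
#' @param k Number of windows requested (default 2).
#' @param penalty Margin-ring penalty weight (default 0.5).
#' @return List of `list(window, score)`, scores non-increasing; empty list
#'   for an all-zero map.
#' @export
detect_saliency_windows <- function(map, k = 2L, penalty = 0.5) {
  H <- nrow(map); W <- ncol(map)
  if (max(map) <= 0) return(list())
  S <- integral_image(map)
  exhaustive <- (H * W) <= 2500L
  cands <- if (exhaustive) {
    r0 <- rep(seq_len(H), each = H); r1 <- rep(seq_len(H), times = H)
    okr <- r1 >= r0
    c0 <- rep(seq_len(W), each = W); c1 <- rep(seq_len(W), times = W)
    okc <- c1 >= c0
    rp <- cbind(r0[okr], r1[okr]); cp <- cbind(c0[okc], c1[okc])
    list(r0 = rep(rp[, 1L], times = nrow(cp)), r1 = rep(rp[, 2L], times = nrow(cp)),
         c0 = rep(cp[, 1L], each = nrow(rp)), c1 = rep(cp[, 2L], each = nrow(rp)))
  } else {
    step <- max(4L, round(min(H, W) / 32))
    fr <- c(0.12, 0.2, 0.3, 0.42, 0.55, 0.7, 0.85)
    hs <- unique(pmax(4L, round(fr * H))); ws <- unique(pmax(4L, round(fr * W)))
    grid <- expand.grid(r0 = seq(1L, H, by = step), c0 = seq(1L, W, by = step),
                        h = hs, w = ws)
    grid$r1 <- grid$r0 + grid$h - 1L; grid$c1 <- grid$c0 + grid$w - 1L
    grid <- grid[grid$r1 <= H & grid$c1 <= W, ]
    list(r0 = grid$r0, r1 = grid$r1, c0 = grid$c0, c1 = grid$c1)
  }
  sc <- window_score(S, H, W, cands$r0, cands$c0, cands$r1, cands$c1, penalty)
  ord <- order(sc, decreasing = TRUE)
  refine <- function(r0, c0, r1, c1) {
    best <- window_score(S, H, W, r0, c0, r1, c1, penalty)
    repeat {
      improved <- FALSE
      for (d in c(8L, 4L, 2L, 1L)) {
        for (side in 1:4) for (sgn in c(-d, d)) {
          nr0 <- r0; nc0 <- c0; nr1 <- r1; nc1 <- c1
          if (side == 1L) nr0 <- r0 + sgn else if (side == 2L) nr1 <- r1 + sgn
          else if (side == 3L) nc0 <- c0 + sgn else nc1 <- c1 + sgn
          if (nr0 < 1L || nc0 < 1L || nr1 > H || nc1 > W || nr1 < nr0 || nc1 < nc0) next
          s2 <- window_score(S, H, W, nr0, nc0, nr1, nc1, penalty)
          if (s2 > best + 1e-12) {
            best <- s2; r0 <- nr0; c0 <- nc0; r1 <- nr1; c1 <- nc1
            improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
    list(r0 = r0, c0 = c0, r1 = r1, c1 = c1, score = best)
  }
  overlap_frac <- function(a, b) {
    ir <- max(0L, min(a$row1, b$row1) - max(a$row0, b$row0) + 1L)
    ic <- max(0L, min(a$col1, b$col1) - max(a$col0, b$col0) + 1L)
    (ir * ic) / min(window_area(a), window_area(b))
  }
  out <- list()
  best_score <- -Inf
  for (idx in ord) {
    if (length(out) >= k) break
    if (length(out) && sc[idx] < 0.1 * best_score) break
    raw <- dgf_window(cands$r0[idx], cands$c0[idx], cands$r1[idx], cands$c1[idx])
    if (length(out) &&
        any(vapply(out, function(o) overlap_frac(o$window, raw) > 0.3, logical(1))))
      next
    ref <- if (exhaustive)
      list(r0 = raw$row0, c0 = raw$col0, r1 = raw$row1, c1 = raw$col1, score = sc[idx])
    else refine(raw$row0, raw$col0, raw$row1, raw$col1)
    win <- dgf_window(ref$r0, ref$c0, ref$r1, ref$c1)
    if (length(out)) {
      if (ref$score < 0.1 * best_score) next
      if (any(vapply(out, function(o) overlap_frac(o$window, win) > 0.3, logical(1))))
        next
    }
    out[[length(out) + 1L]] <- list(window = win, score = ref$score)
    best_score <- max(best_score, ref$score)
  }
  out
}

#' Adopt the tongue window among the top saliency windows
#'
#' With two candidates the smaller-area window is adopted; with a single
#' candidate it is returned as is; equal areas fall back to the higher score.
#'
#' @param windows List of `list(window, score)` from
#'   [detect_saliency_windows()].
#' @return A [dgf_window()].
#' @export
select_tongue_window <- function(windows) {
  if (!length(windows)) stop("saliency detection returned no window", call. = FALSE)
  if (length(windows) == 1L) return(windows[[1L]]$window)
  windows <- windows[1:2]
  areas <- vapply(windows, function(w) window_area(w$window), numeric(1))
  if (areas[1L] == areas[2L]) {
    scores <- vapply(windows, function(w) w$score, numeric(1))
    return(windows[[which.max(scores)]]$window)
  }
  windows[[which.min(areas)]]$window
}
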