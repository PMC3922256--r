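# Internal finite-difference and smoothing primitives shared by the flows.
# All operate on plain H x W matrices with replicate (Neumann) boundaries,
# so that gradients vanish across the image border instead of inventing edges.

shift_up <- function(m) m[c(1L, seq_len(nrow(m) - 1L)), , drop = FALSE]
shift_down <- function(m) m[c(seq_len(nrow(m))[-1L], nrow(m)), , drop = FALSE]
shift_left <- function(m) m[, c(1L, seq_len(ncol(m) - 1L)), drop = FALSE]
shift_right <- function(m) m[, c(seq_len(ncol(m))[-1L], ncol(m)), drop = FALSE]

# central differences; d/drow and d/dcol
grad_row <- function(m) (shift_down(m) - shift_up(m)) / 2
grad_col <- function(m) (shift_right(m) - shift_left(m)) / 2

laplacian <- function(m) {
  shift_up(m) + shift_down(m) + shift_left(m) + shift_right(m) - 4 * m
}

# separable Gaussian smoothing, kernel truncated at 3 sigma, replicate padding
gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gauss_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  conv1 <- function(x, along_rows) {
    n <- if (along_rows) nrow(x) else ncol(x)
    idx_clamp <- function(i) pmin(pmax(i, 1L), n)
    out <- 0 * x
    for (o in seq(-r, r)) {
      wgt <- k[o + r + 1L]
      if (along_rows) out <- out + wgt * x[idx_clamp(seq_len(n) + o), , drop = FALSE]
      else out <- out + wgt * x[, idx_clamp(seq_len(n) + o), drop = FALSE]
    }
    out
  }
  conv1(conv1(m, TRUE), FALSE)
}

# guarded gradient magnitude helpers
EPS_NORM <- 1e-10
grad_norm <- function(gr, gc) sqrt(gr^2 + gc^2 + EPS_NORM)
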