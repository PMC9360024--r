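# Independent brute-force oracles used to verify the implementation paths.

# O(n^2) pairwise weighted Gini: sum_ij w_i w_j |v_i - v_j| / (2 W^2 mu)
gini_pairwise <- function(values, weights) {
  W <- sum(weights)
  mu <- sum(weights * values) / W
  if (mu == 0) return(0)
  sum(outer(weights, weights) * abs(outer(values, values, "-"))) /
    (2 * W^2 * mu)
}

# Brute-force circular-kernel focal mean by double loop (no edge handling
# subtleties: caller restricts comparison to cells where the full kernel is
# in-bounds, or to grids where renormalization semantics match).
focal_brute <- function(values, cell_size, radius_m) {
  nr <- nrow(values); nc <- ncol(values)
  out <- matrix(NA_real_, nr, nc)
  r_cells <- floor(radius_m / cell_size + 1e-9)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (is.na(values[i, j])) next   # nodata centers stay nodata
      acc <- 0; cnt <- 0
      for (di in -r_cells:r_cells) {
        for (dj in -r_cells:r_cells) {
          if (sqrt(di^2 + dj^2) * cell_size > radius_m + 1e-9 * cell_size)
            next
          ii <- i + di; jj <- j + dj
          if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
          v <- values[ii, jj]
          if (is.na(v)) next
          acc <- acc + v; cnt <- cnt + 1
        }
      }
      if (cnt > 0) out[i, j] <- acc / cnt
    }
  }
  out
}

# Exposed foreground edge length by scanning every cell edge.
edge_length_brute <- function(fg, cell_size) {
  nr <- nrow(fg); nc <- ncol(fg)
  total <- 0
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!isTRUE(fg[i, j])) next
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii < 1 || ii > nr || jj < 1 || jj > nc || !isTRUE(fg[ii, jj]))
          total <- total + cell_size
      }
    }
  }
  total
}

# Partial correlation by the residual-regression route: regress y and x on
# the controls, correlate the residuals.
pcor_residual <- function(y, x, controls) {
  if (is.null(controls) || NCOL(controls) == 0) return(cor(y, x))
  ry <- residuals(lm(y ~ ., data = as.data.frame(controls)))
  rx <- residuals(lm(x ~ ., data = as.data.frame(controls)))
  cor(ry, rx)
}

# Small fraction-role grid from a matrix.
fgrid <- function(m, cell_size = 100, role = "greenspace") {
  gx_grid(as.matrix(m), cell_size = cell_size, role = role)
}
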