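# Independent oracles used across the suite. These deliberately use slow,
# direct algorithms (flood fill, exhaustive enumeration, grid search) so they
# share no code with the package implementations they check.

# Flood-fill component labeling; conn = 4 or 8.
flood_label <- function(grid, conn = 8) {
  nr <- nrow(grid); nc <- ncol(grid)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  moves <- if (conn == 8)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (grid[i, j] && lab[i, j] == 0L) {
      nxt <- nxt + 1L
      stack <- list(c(i, j)); lab[i, j] <- nxt
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        for (m in seq_len(nrow(moves))) {
          r <- p[1] + moves[m, 1]; c2 <- p[2] + moves[m, 2]
          if (r >= 1 && r <= nr && c2 >= 1 && c2 <= nc &&
              grid[r, c2] && lab[r, c2] == 0L) {
            lab[r, c2] <- nxt
            stack[[length(stack) + 1L]] <- c(r, c2)
          }
        }
      }
    }
  }
  lab
}

# Euler characteristic oracle: 8-connected foreground components minus
# 4-connected background components not touching the border (holes).
euler_oracle <- function(grid) {
  grid <- matrix(as.logical(grid), nrow(grid), ncol(grid))
  ncomp <- max(flood_label(grid, 8))
  bg <- !grid
  labb <- flood_label(bg, 4)
  border <- unique(c(labb[1, ], labb[nrow(labb), ], labb[, 1], labb[, ncol(labb)]))
  holes <- length(setdiff(unique(labb[labb > 0L]), border))
  as.integer(ncomp - holes)
}

# Conditional four-way genotype probabilities at an untyped position between
# two typed flanking markers, by exhaustive enumeration of parental meioses.
haldane_oracle_r <- function(d) (1 - exp(-2 * d / 100)) / 2

fourway_midpoint_oracle <- function(code_left, code_right, d1, d2) {
  # split codes into parental allele indices (0-based): mat = a/b, pat = c/d
  mat_l <- (code_left - 1) %/% 2; pat_l <- (code_left - 1) %% 2
  mat_r <- (code_right - 1) %/% 2; pat_r <- (code_right - 1) %% 2
  cond1 <- function(s0, s2) {
    r1 <- haldane_oracle_r(d1); r2 <- haldane_oracle_r(d2)
    p <- vapply(0:1, function(m)
      (if (m == s0) 1 - r1 else r1) * (if (m == s2) 1 - r2 else r2),
      numeric(1))
    p / sum(p)
  }
  pm <- cond1(mat_l, mat_r); pp <- cond1(pat_l, pat_r)
  c(pm[1] * pp[1], pm[1] * pp[2], pm[2] * pp[1], pm[2] * pp[2])
}

# small convenience: a rasterized disk mask
disk_mask <- function(radius_px, mm_per_px = 0.1) {
  make_fruit_mask(shape_params("round", a = radius_px * mm_per_px,
                               b = radius_px * mm_per_px, n_exp = 2),
                  px_per_mm = 1 / mm_per_px)
}
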