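test_that("density maps are normalized and radially symmetric on a disk", {
  m <- disk_mask(60)
  dm <- density_map(m)
  v <- dm$values[m$grid]
  expect_equal(min(v), 0)
  expect_equal(max(v), 1)

  ctr <- colMeans(which(m$grid, arr.ind = TRUE))
  idx <- which(m$grid, arr.ind = TRUE)
  r <- sqrt((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2)
  ring <- abs(r - 30) < 0.5
  ring_vals <- dm$values[m$grid][ring]
  expect_lt(diff(range(ring_vals)), 0.02)
})

test_that("contour density is a Gaussian sum over boundary pixels", {
  m <- make_fruit_mask(shape_params("elongated", a = 12, b = 6), 4)
  dm <- density_map(m, mode = "contour")
  g <- m$grid
  bnd <- which(berrymorph:::boundary_mask(g), arr.ind = TRUE)
  sigma <- dm$bandwidth
  raw <- function(rc) sum(exp(-((bnd[, 1] - rc[1])^2 + (bnd[, 2] - rc[2])^2) /
                              (2 * sigma^2))) / (2 * pi * sigma^2)
  fg <- which(g, arr.ind = TRUE)
  probes <- fg[round(seq(1, nrow(fg), length.out = 4)), , drop = FALSE]
  brute <- apply(probes, 1, raw)
  all_raw <- apply(fg, 1, raw)
  brute_norm <- (brute - min(all_raw)) / (max(all_raw) - min(all_raw))
  got <- dm$values[probes]
  # tiny slack for the 4-sigma kernel truncation in the fast path
  expect_equal(got, brute_norm, tolerance = 1e-3)
})

test_that("annulus partition covers the foreground with ring-area weights", {
  m <- disk_mask(80)
  an <- annulus_partition(m, 4)
  lab <- an$labels[m$grid]
  expect_false(anyNA(lab))
  expect_identical(sum(!is.na(an$labels)), sum(m$grid))

  counts <- tabulate(lab, 4)
  expect_equal(counts / counts[1], c(1, 3, 5, 7), tolerance = 0.05)

  # farthest pixel sits in the closed last bin
  idx <- which(m$grid, arr.ind = TRUE)
  ctr <- colMeans(idx)
  far <- idx[which.max((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2), ]
  expect_identical(an$labels[far[1], far[2]], 4L)
})

test_that("Euler characteristic handles components and holes", {
  disk <- disk_mask(20)$grid
  expect_identical(euler_characteristic(disk), 1L)

  ring <- disk
  idx <- which(disk, arr.ind = TRUE)
  ctr <- colMeans(idx)
  hole <- (row(disk) - ctr[1])^2 + (col(disk) - ctr[2])^2 < 8^2
  ring[hole] <- FALSE
  expect_identical(euler_characteristic(ring), 0L)

  two <- matrix(FALSE, 20, 40)
  two[5:15, 5:15] <- TRUE; two[5:15, 25:35] <- TRUE
  expect_identical(euler_characteristic(two), 2L)
  expect_identical(euler_characteristic(matrix(FALSE, 5, 5)), 0L)
})

test_that("quad-count Euler characteristic equals the flood-fill oracle", {
  set.seed(77)
  for (i in seq_len(200)) {
    g <- matrix(stats::runif(32 * 32) < stats::runif(1, 0.2, 0.7), 32, 32)
    expect_identical(euler_characteristic(g), euler_oracle(g))
  }
})

test_that("ECC curves follow annulus topology", {
  m <- disk_mask(60)
  dm <- density_map(m)
  an <- annulus_partition(m, 4)
  inner <- ecc_curve(dm, an, 1)
  expect_length(inner$values, 30)
  expect_identical(inner$values[1], 1L)          # full inner disk
  mid <- ecc_curve(dm, an, 3)
  expect_identical(mid$values[1], 0L)            # full ring

  # thresholds above an annulus's max density give the empty set
  top <- max(dm$values[!is.na(an$labels) & an$labels == 4], na.rm = TRUE)
  if (top < 1) {
    curve4 <- ecc_curve(dm, an, 4)
    expect_identical(curve4$values[curve4$thresholds > top + 1e-9],
                     rep(0L, sum(curve4$thresholds > top + 1e-9)))
  }
})

test_that("PH descriptors are 120-long, deterministic, and translation invariant", {
  m <- make_fruit_mask(shape_params("bell", a = 10, b = 7, bell_k = 0.4), 4)
  v1 <- ph_descriptor(m)
  v2 <- ph_descriptor(m)
  expect_length(v1, 120)
  expect_identical(as.numeric(v1), as.numeric(v2))

  # translation: embed the same grid elsewhere in a larger canvas
  big <- matrix(FALSE, nrow(m$grid) + 30, ncol(m$grid) + 44)
  big[16:(15 + nrow(m$grid)), 23:(22 + ncol(m$grid))] <- m$grid
  v3 <- ph_descriptor(fruit_mask(big, m$mm_per_px))
  expect_identical(as.numeric(v1), as.numeric(v3))
})

test_that("PH descriptors are robust to rotation", {
  mk <- function(rot) ph_descriptor(make_fruit_mask(
    shape_params("elongated", a = 14, b = 8, rotation = rot), 5))
  a <- mk(0); b <- mk(pi / 2)
  expect_lte(sum(abs(a - b)), 0.05 * sum(abs(a)))
})

test_that("PCA handles degenerate and clustered inputs", {
  X <- matrix(rep(c(1, 2, 3, 4), each = 5), 5, 4)
  expect_warning(pc0 <- fit_pca(X), "zero-variance")
  expect_true(all(pc0$scores == 0))

  set.seed(32)
  rnd <- lapply(seq_len(10), function(i) {
    L <- stats::runif(1, 14, 16)
    make_fruit_mask(shape_params("round", a = L / 2, b = L / 2), 4)
  })
  elo <- lapply(seq_len(10), function(i) {
    L <- stats::runif(1, 16, 18)
    make_fruit_mask(shape_params("elongated", a = L / 2, b = L / 3.6), 4)
  })
  D <- ph_descriptor_matrix(c(rnd, elo))
  pc <- fit_pca(D, k = 2)
  s1 <- pc$scores[1:10, 1]; s2 <- pc$scores[11:20, 1]
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))  # no overlap on PC1

  expect_equal(sum(pc$var_explained), 1)
  expect_true(all(diff(pc$var_explained) <= 1e-12))
  # sign convention: largest-|loading| entry positive in each component
  for (j in 1:2) expect_gt(pc$loadings[which.max(abs(pc$loadings[, j])), j], 0)
})

test_that("PC1 tracks elongation but not size on an independent continuum", {
  set.seed(1)
  pars <- lapply(seq_len(150), function(i) {
    A <- stats::runif(1, 120, 260)          # area and LW sampled independently
    r <- stats::runif(1, 1.0, 1.9)
    a <- sqrt(A * r / pi)
    shape_params(if (r < 1.05) "round" else "elongated", a = a, b = a / r,
                 n_exp = 2.2)
  })
  masks <- lapply(pars, make_fruit_mask, px_per_mm = 4)
  lw <- vapply(pars, function(p) p$a / p$b, numeric(1))
  area <- vapply(masks, function(m) sum(m$grid), numeric(1))
  pc <- fit_pca(ph_descriptor_matrix(masks), k = 2)
  expect_gte(abs(stats::cor(pc$scores[, 1], lw)), 0.8)
  expect_lte(abs(stats::cor(pc$scores[, 1], area)), 0.2)
})
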