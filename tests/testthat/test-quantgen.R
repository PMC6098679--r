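test_that("genotype means average fruit and flag missing genotype-years", {
  pf <- data.frame(id = rep(c("g1", "g2", "g3"), each = 25),
                   year = 1, fruit = 1:25, trait = "t",
                   value = c(rep(7, 25), 1:25, rep(2, 25)))
  # g3 unobserved in year 2
  pf2 <- pf[pf$id != "g3", ]; pf2$year <- 2
  m <- genotype_means(rbind(pf, pf2))
  expect_identical(nrow(m), 6L)
  expect_equal(m$value[m$id == "g1" & m$year == 1], 7)
  expect_equal(m$value[m$id == "g2" & m$year == 1], 13)
  miss <- m[m$id == "g3" & m$year == 2, ]
  expect_true(is.na(miss$value))
  expect_identical(miss$n, 0L)
})

test_that("kinship has unit-scale diagonal and family-mean centering", {
  map <- sim_linkage_map(4, 60, 5)
  cross <- simulate_cross(map, 120, seed = 41)
  K <- kinship(cross)
  expect_true(isSymmetric(K$A, tol = 1e-10))
  expect_gt(mean(diag(K$A)), 0.8)
  expect_lt(mean(diag(K$A)), 1.4)
  # centered indicators force A %*% 1 = 0: relationships are family-relative
  expect_lt(max(abs(rowSums(K$A))), 1e-8)

  # duplicated individuals are exactly identical in A
  g2 <- rbind(cross$geno, cross$geno[1, ])
  K2 <- kinship(g2)
  n <- nrow(g2)
  expect_equal(K2$A[1, n], K2$A[1, 1])
  expect_equal(K2$A[n, n], K2$A[1, 1])

  # independent random genotypes: off-diagonals near zero
  set.seed(42)
  rnd <- matrix(sample(1:4, 200 * 300, replace = TRUE), 200, 300)
  Kr <- kinship(rnd)
  off <- Kr$A[upper.tri(Kr$A)]
  expect_lt(abs(mean(off)), 0.05)

  expect_error(kinship(matrix(0L, 5, 20)), "missing")
})

test_that("spectral REML matches a dense grid-search oracle on small fixtures", {
  set.seed(51)
  for (rep in 1:3) {
    n <- 12
    W <- matrix(stats::rnorm(n * 30), n)
    A <- tcrossprod(scale(W, scale = FALSE)) / 30
    A <- A / mean(diag(A))
    y <- stats::rnorm(n) + drop(chol(A + diag(1e-6, n)) %*% stats::rnorm(n))
    fit <- reml_fit(y, A)
    # oracle: profiled restricted likelihood on a dense log-lambda grid
    eg <- eigen(A, symmetric = TRUE)
    d <- pmax(eg$values, 0)
    ys <- drop(crossprod(eg$vectors, y))
    xs <- drop(crossprod(eg$vectors, rep(1, n)))
    ll <- function(loglam) {
      w <- exp(loglam) * d + 1
      xx <- sum(xs^2 / w)
      mu <- sum(xs * ys / w) / xx
      rss <- sum((ys - xs * mu)^2 / w)
      s2 <- rss / (n - 1)
      -0.5 * ((n - 1) * log(s2) + sum(log(w)) + log(xx) + (n - 1))
    }
    grid <- seq(-10, 10, length.out = 10000)
    best <- grid[which.max(vapply(grid, ll, numeric(1)))]
    expect_lt(abs(ll(log(max(fit$lambda, exp(-10)))) - ll(best)), 1e-3)
  }
})

test_that("REML recovers heritability and shrinks appropriately", {
  map <- sim_linkage_map(4, 60, 5)
  cross <- simulate_cross(map, 150, seed = 61)
  K <- kinship(cross)
  eg <- eigen(K$A, symmetric = TRUE)
  d <- pmax(eg$values, 0)

  est <- vapply(1:20, function(i) {
    set.seed(700 + i)
    u <- drop(eg$vectors %*% (sqrt(0.5 * d) * stats::rnorm(150)))
    y <- u + stats::rnorm(150, 0, sqrt(0.5))
    reml_fit(y, K)$h2
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.5), 0.1)

  # BLUP means are numerically zero and shrinkage bounds the BLUP variance
  set.seed(99)
  y <- drop(eg$vectors %*% (sqrt(0.5 * d) * stats::rnorm(150))) +
    stats::rnorm(150, 0, sqrt(0.5))
  fit <- reml_fit(y, K)
  expect_lt(abs(mean(fit$u)), 1e-6 * stats::sd(y))
  expect_lte(stats::var(fit$u), stats::var(y))

  # no genetic signal: BLUPs collapse towards zero
  null_small <- vapply(1:10, function(i) {
    set.seed(800 + i)
    yn <- stats::rnorm(150)
    f <- reml_fit(yn, K)
    sqrt(sum(f$u^2) / sum(yn^2))
  }, numeric(1))
  expect_lt(stats::median(null_small), 0.35)

  # null h2 small in most replicates
  nullh <- vapply(1:50, function(i) {
    set.seed(900 + i)
    reml_fit(stats::rnorm(150), K)$h2
  }, numeric(1))
  expect_gte(mean(nullh <= 0.1), 0.8)

  # constant response
  f0 <- reml_fit(rep(3, 150), K)
  expect_identical(f0$h2, 0)
  expect_true(all(f0$u[!is.na(f0$u)] == 0))
})

test_that("estimated h2 is monotone in simulated genetic variance", {
  map <- sim_linkage_map(3, 50, 5)
  cross <- simulate_cross(map, 120, seed = 71)
  K <- kinship(cross)
  eg <- eigen(K$A, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  mean_h2 <- vapply(c(0.1, 0.3, 0.5, 0.7), function(h2) {
    mean(vapply(1:20, function(i) {
      set.seed(h2 * 1000 + i)
      u <- drop(eg$vectors %*% (sqrt(h2 * d) * stats::rnorm(120)))
      reml_fit(u + stats::rnorm(120, 0, sqrt(1 - h2)), K)$h2
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_h2) > 0))
})

test_that("fitting genotype means of identical fruit equals fitting one fruit", {
  map <- sim_linkage_map(3, 50, 10)
  cross <- simulate_cross(map, 60, seed = 81)
  K <- kinship(cross)
  set.seed(5)
  y <- stats::rnorm(60)
  pf <- data.frame(id = rep(cross$ids, each = 4), year = 1,
                   trait = "t", value = rep(y, each = 4))
  m <- genotype_means(pf)
  y_mean <- m$value[match(cross$ids, m$id)]
  f1 <- reml_fit(y_mean, K)
  f2 <- reml_fit(y, K)
  expect_equal(f1$h2, f2$h2, tolerance = 1e-8)
  expect_equal(f1$u, f2$u, tolerance = 1e-8)
})
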