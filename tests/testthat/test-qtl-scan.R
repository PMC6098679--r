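mini_cross <- function(n = 351, n_lg = 2, len = 60, sp = 5, seed = 1) {
  simulate_cross(sim_linkage_map(n_lg, len, sp), n, seed = seed)
}

test_that("genotype probabilities honor typed markers and normalize", {
  cross <- mini_cross(50, seed = 3)
  gp <- calc_genoprob(cross, step = 2.5, error_rate = 0)
  for (l in gp$lg) {
    sums <- apply(l$probs, 1:2, sum)
    expect_lt(max(abs(sums - 1)), 1e-9)
    expect_gte(min(l$probs), 0)
  }
  # at a typed marker with zero error the observed class has probability 1
  l1 <- gp$lg[["1"]]
  k <- which(l1$pos == 0)
  obs <- cross$geno[, 1]
  expect_equal(l1$probs[cbind(seq_len(50), k, obs)], rep(1, 50))
})

test_that("probabilities at untyped positions match gamete enumeration", {
  map <- data.frame(marker = c("m1", "m2"), lg = 1, pos = c(0, 20))
  geno <- rbind(c(1L, 4L), c(1L, 1L), c(2L, 3L), c(3L, 2L), c(4L, 1L))
  cross <- structure(list(map = map, geno = geno,
                          ids = sprintf("i%d", 1:5), extra_geno = NULL),
                     class = "fourway_cross")
  gp <- calc_genoprob(cross, step = 5, error_rate = 0)
  l <- gp$lg[["1"]]
  for (at in c(5, 10, 15)) {
    k <- which(l$pos == at)
    for (i in 1:5) {
      want <- fourway_midpoint_oracle(geno[i, 1], geno[i, 2], at, 20 - at)
      expect_lt(max(abs(l$probs[i, k, ] - want)), 1e-9)
    }
  }
})

test_that("the Haley-Knott scan finds a noiseless marker signal", {
  cross <- mini_cross(351, seed = 7)
  gp <- calc_genoprob(cross, step = 1)
  expect_error(hk_scan(gp, rep(1:0, length.out = 4)), "too few|length")

  y0 <- rep(2, 351)
  expect_true(all(hk_scan(gp, y0)$lod == 0))

  mk <- which(cross$map$lg == 2 & cross$map$pos == 30)
  y <- c(0, 1, 2, 3)[cross$geno[, mk]]
  sc <- hk_scan(gp, y)
  i <- which.max(sc$lod)
  expect_identical(sc$lg[i], 2L)
  expect_lte(abs(sc$pos[i] - 30), 1)
})

test_that("scan LOD equals an explicit normal-equations oracle on a fixture", {
  map <- data.frame(marker = c("m1", "m2"), lg = 1, pos = c(0, 25))
  set.seed(13)
  geno <- matrix(sample(1:4, 24, replace = TRUE), 12, 2)
  cross <- structure(list(map = map, geno = geno,
                          ids = sprintf("i%d", 1:12), extra_geno = NULL),
                     class = "fourway_cross")
  gp <- calc_genoprob(cross, step = 0, error_rate = 1e-4)
  y <- stats::rnorm(12)
  sc <- hk_scan(gp, y)
  for (k in 1:2) {
    P <- gp$lg[["1"]]$probs[, k, 2:4]
    X <- cbind(1, P)
    beta <- solve(t(X) %*% X, t(X) %*% y)         # normal equations
    rss1 <- sum((y - X %*% beta)^2)
    rss0 <- sum((y - mean(y))^2)
    expect_equal(sc$lod[k], 12 / 2 * log10(rss0 / rss1), tolerance = 1e-9)
  }
})

test_that("LOD scores are invariant to affine transformations of y", {
  cross <- mini_cross(120, seed = 17)
  gp <- calc_genoprob(cross, step = 5)
  set.seed(18)
  y <- stats::rnorm(120)
  a <- hk_scan(gp, y)$lod
  b <- hk_scan(gp, 3.2 * y - 7)$lod
  expect_lt(max(abs(a - b)), 1e-9)
})

test_that("permutation thresholds are reproducible and quantile-type-7", {
  cross <- mini_cross(120, seed = 19)
  gp <- calc_genoprob(cross, step = 5)
  set.seed(20)
  y <- stats::rnorm(120)
  p1 <- perm_threshold(gp, y, n_perm = 100, seed = 5)
  p2 <- perm_threshold(gp, y, n_perm = 100, seed = 5)
  expect_identical(p1$T_m, p2$T_m)
  expect_identical(p1$T_m,
                   as.numeric(stats::quantile(p1$max_lods, 0.95, type = 7)))
})

test_that("covariate and no-covariate permutation paths agree", {
  cross <- mini_cross(80, seed = 21)
  gp <- calc_genoprob(cross, step = 10)
  set.seed(22)
  y <- stats::rnorm(80)
  fast <- perm_threshold(gp, y, n_perm = 100, seed = 9)
  # a constant covariate changes nothing statistically but forces the
  # general per-permutation path
  slow <- perm_threshold(gp, y, covar = cbind(z = rep(1, 80)),
                         n_perm = 100, seed = 9)
  expect_equal(fast$max_lods, slow$max_lods, tolerance = 1e-9)
})

test_that("stepwise selection recovers planted additive QTL", {
  map <- sim_linkage_map(2, 80, 5)
  found2 <- 0L
  set.seed(3000)
  for (i in 1:10) {
    cross <- simulate_cross(map, 351, seed = sample.int(2^31 - 2, 1))
    sim <- simulate_phenotypes(cross,
                               list(qtl_spec(1, 25, 0.15),
                                    qtl_spec(2, 55, 0.15)),
                               n_years = 1, seed = sample.int(2^31 - 2, 1))
    y <- sim$per_genotype$value
    gp <- calc_genoprob(cross, step = 2.5)
    pen <- perm_threshold(gp, y, n_perm = 200,
                          seed = sample.int(2^31 - 2, 1))
    m <- stepwise_additive(gp, y, penalty = pen)
    hit1 <- any(m$qtls$lg == 1 & abs(m$qtls$pos - 25) <= 10)
    hit2 <- any(m$qtls$lg == 2 & abs(m$qtls$pos - 55) <= 10)
    found2 <- found2 + (hit1 && hit2)
    # model invariants
    if (nrow(m$qtls)) {
      expect_true(all(m$qtls$ci_lo <= m$qtls$pos & m$qtls$pos <= m$qtls$ci_hi))
      expect_true(all(m$qtls$pct_var_drop1 >= 0 & m$qtls$pct_var_drop1 <= 100))
      expect_gte(m$full_model_pct_var, max(m$qtls$pct_var_drop1) - 1e-6)
    }
  }
  expect_gte(found2, 7L)
})

test_that("support intervals bracket the LOD drop", {
  tri <- data.frame(pos = seq(0, 40, 2),
                    lod = pmax(6 - abs(seq(0, 40, 2) - 20) / 2, 0))
  ci <- support_interval(tri, drop = 1.5)
  # crossings at 17 and 23; expansion to the nearest grid points outside
  expect_equal(ci, c(16, 24))

  flat <- data.frame(pos = seq(0, 40, 2), lod = rep(2, 21))
  expect_equal(support_interval(flat, drop = 1.5), c(0, 40))

  expect_equal(support_interval(tri, drop = 0), c(20, 20))

  # one-sided at the linkage-group boundary
  mono <- data.frame(pos = seq(0, 20, 2), lod = seq(0, 10, 1))
  ci2 <- support_interval(mono, drop = 1.5)
  expect_equal(ci2[2], 20)
  expect_lt(ci2[1], 20)
})

test_that("explained variance matches the classical R-squared", {
  map <- data.frame(marker = c("m1", "m2"), lg = 1, pos = c(0, 50))
  set.seed(23)
  geno <- matrix(sample(1:4, 24, replace = TRUE), 12, 2)
  cross <- structure(list(map = map, geno = geno,
                          ids = sprintf("i%d", 1:12), extra_geno = NULL),
                     class = "fourway_cross")
  gp <- calc_genoprob(cross, step = 0)
  y <- c(1, 3, 2, 5, 4, 6, 2, 8, 7, 3, 5, 4)
  m <- stepwise_additive(gp, y, penalty = 0.25, max_qtl = 1)
  if (nrow(m$qtls) == 1L) {
    k <- which(gp$lg[["1"]]$pos == m$qtls$pos)
    r2 <- summary(stats::lm(y ~ gp$lg[["1"]]$probs[, k, 2:4]))$r.squared
    expect_equal(m$full_model_pct_var, 100 * r2, tolerance = 1e-6)
  }
  empty <- stepwise_additive(gp, y, penalty = 50)
  expect_identical(nrow(empty$qtls), 0L)
  expect_equal(empty$full_model_pct_var, 0)
})

test_that("drop-one variances add up on an orthogonal design", {
  # two unlinked, fully informative markers: drop-one contributions sum to
  # at most the full-model value
  map <- data.frame(marker = c("m1", "m2"), lg = c(1, 2), pos = c(0, 0))
  set.seed(24)
  fact <- expand.grid(1:4, 1:4)          # balanced factorial: exact orthogonality
  geno <- as.matrix(fact[rep(seq_len(16), each = 6), ])
  dimnames(geno) <- NULL
  cross <- structure(list(map = map, geno = geno,
                          ids = sprintf("i%d", seq_len(96)), extra_geno = NULL),
                     class = "fourway_cross")
  gp <- calc_genoprob(cross, step = 0, error_rate = 0)
  y <- c(0, 2, 4, 6)[geno[, 1]] + c(0, 1, 2, 3)[geno[, 2]] +
    stats::rnorm(96, 0, 0.5)
  m <- stepwise_additive(gp, y, penalty = 2)
  expect_identical(nrow(m$qtls), 2L)
  expect_lte(sum(m$qtls$pct_var_drop1), m$full_model_pct_var + 1e-6)
})

test_that("collocation groups peaks under the 8 cM pairwise rule", {
  q <- data.frame(trait = "lw", year = c(2014, 2015, 2016),
                  lg = 1, pos = c(10, 12, 14))
  rep3 <- collocate(q, window_cm = 8, min_years = 3)
  expect_identical(nrow(rep3), 1L)
  expect_identical(rep3$n_years, 3L)

  q2 <- data.frame(trait = "lw", year = c(2014, 2015), lg = 1, pos = c(10, 19))
  expect_identical(nrow(collocate(q2, window_cm = 8)), 0L)
  q3 <- data.frame(trait = "lw", year = c(2014, 2015), lg = 1, pos = c(10, 18))
  expect_identical(nrow(collocate(q3, window_cm = 8)), 1L)

  single <- data.frame(trait = "lw", year = 2014, lg = 1, pos = 10)
  expect_identical(nrow(collocate(single)), 0L)

  # interval-overlap mode
  qi <- data.frame(trait = "lw", year = c(2014, 2015), lg = 1,
                   pos = c(10, 30), ci_lo = c(5, 18), ci_hi = c(20, 40))
  expect_identical(nrow(collocate(qi, mode = "interval")), 1L)
  qi$ci_lo[2] <- 25
  expect_identical(nrow(collocate(qi, mode = "interval")), 0L)
})

test_that("the covariate diallel runs ordered pairs and rejects self-covariates", {
  map <- sim_linkage_map(1, 40, 10)
  cross <- simulate_cross(map, 120, seed = 25)
  gp <- calc_genoprob(cross, step = 5)
  mk <- which(cross$map$pos == 20)
  set.seed(26)
  qtl_term <- c(-1, -1, 1, 1)[cross$geno[, mk]]
  tr <- do.call(rbind, lapply(1:2, function(y) data.frame(
    id = cross$ids, year = y,
    a = qtl_term + stats::rnorm(120, 0, 1),
    b = stats::rnorm(120))))
  expect_error(covariate_diallel(gp, tr, c("a", "a")), "own covariate")

  res <- covariate_diallel(gp, tr, c("a", "b"), n_perm = 100, seed = 7)
  expect_true(is.data.frame(res))
  expect_true(all(c("trait", "covariate", "novel") %in% names(res)))
  if (nrow(res)) expect_true(all(res$trait != res$covariate))
})
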