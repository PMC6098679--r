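test_that("rasterized silhouettes match analytic areas", {
  disk <- make_fruit_mask(shape_params("round", a = 10, b = 10), 10)
  expect_lt(abs(sum(disk$grid) / (pi * 100^2) - 1), 0.01)

  ell <- make_fruit_mask(shape_params("elongated", a = 20, b = 10), 10)
  expect_lt(abs(sum(ell$grid) / (pi * 20 * 10 * 100) - 1), 0.01)
})

test_that("bell silhouettes have an off-center centroid along the long axis", {
  m <- make_fruit_mask(shape_params("bell", a = 12, b = 8, bell_k = 0.4,
                                    rotation = 0), 8)
  idx <- which(m$grid, arr.ind = TRUE)
  bbox_mid <- mean(range(idx[, 2]))
  centroid <- mean(idx[, 2])      # long axis is the column axis at rotation 0
  expect_gt(abs(centroid - bbox_mid), 1)
})

test_that("degenerate rasterizations are refused", {
  expect_error(make_fruit_mask(shape_params("round", a = 0.3, b = 0.3), 2),
               "degenerate")
})

test_that("generated masks are simply connected across classes and rotations", {
  set.seed(11)
  for (p in random_fruits(12)) {
    m <- make_fruit_mask(p, 3)
    expect_true(validate_mask(m))
  }
})

test_that("scene composition matches the photographing protocol", {
  set.seed(3)
  fr <- random_fruits(25)
  sc <- compose_scene(scene_spec(fr), seed = 4)
  lab <- label_components(sc$image < 0.5)
  expect_identical(max(lab), 37L)    # 25 fruit + 6 reference circles per side
  expect_identical(sum(sc$truth$type == "reference"), 12L)

  empty <- compose_scene(scene_spec(list()), seed = 4)
  expect_identical(max(label_components(empty$image < 0.5)), 12L)
})

test_that("scene composition is bit-identical under a fixed seed", {
  fr <- with(list(), { set.seed(9); random_fruits(10) })
  a <- compose_scene(scene_spec(fr), seed = 21)
  b <- compose_scene(scene_spec(fr), seed = 21)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
})

test_that("cross simulation follows the Haldane model", {
  # coincident markers are identical columns
  map0 <- data.frame(marker = c("a", "b"), lg = 1, pos = c(5, 5))
  cr0 <- simulate_cross(map0, 200, seed = 2)
  expect_identical(cr0$geno[, 1], cr0$geno[, 2])

  # maternal recombination fraction across several distances, n = 10000
  for (d in c(5, 10, 20, 40, 80)) {
    map <- data.frame(marker = c("a", "b"), lg = 1, pos = c(0, d))
    cr <- simulate_cross(map, 10000, seed = 100 + d)
    mat <- (cr$geno - 1) %/% 2
    rhat <- mean(mat[, 1] != mat[, 2])
    r <- (1 - exp(-2 * d / 100)) / 2
    se <- sqrt(r * (1 - r) / 10000)
    expect_lt(abs(rhat - r), 3 * se)
  }

  # single marker segregates 1:1:1:1
  map1 <- data.frame(marker = "a", lg = 1, pos = 0)
  cr1 <- simulate_cross(map1, 10000, seed = 33)
  counts <- tabulate(cr1$geno[, 1], 4)
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("fourway-csv round-trips the cross exactly", {
  map <- sim_linkage_map(2, 40, 10)
  cr <- simulate_cross(map, 30, seed = 8, missing_rate = 0.05)
  path <- withr::local_tempfile(fileext = ".csv")
  write_fourway_csv(cr, path)
  back <- read_fourway_csv(path)
  expect_identical(unname(back$geno), unname(cr$geno))
  expect_equal(back$map$pos, cr$map$pos)
  expect_identical(back$ids, cr$ids)
})

test_that("phenotype simulation recovers the planted architecture", {
  map <- sim_linkage_map(2, 60, 5)
  cross <- simulate_cross(map, 351, seed = 5)

  # a 20%-variance QTL yields R^2 near 0.20 on the true classes
  sim <- simulate_phenotypes(cross, qtl_spec(2, 30, 0.2), n_years = 1,
                             seed = 6)
  r2 <- summary(stats::lm(sim$per_genotype$value ~
                            factor(sim$qtl_classes[, 1])))$r.squared
  expect_lt(abs(r2 - 0.20), 0.05)

  # zero residual, zero year effects: identical values across years
  sim0 <- simulate_phenotypes(cross, qtl_spec(1, 10, 0.3), n_years = 3,
                              sigma_e = 0, year_effects = c(0, 0, 0),
                              seed = 7)
  wide <- stats::reshape(sim0$per_genotype[, c("id", "year", "value")],
                         idvar = "id", timevar = "year", direction = "wide")
  expect_equal(stats::cor(wide$value.1, wide$value.3), 1)

  # over-allocated variance is a configuration error
  expect_error(simulate_phenotypes(cross, qtl_spec(1, 10, 0.7),
                                   polygenic_h2 = 0.4),
               "configuration error")
})

test_that("under the null the genotype effect is insignificant", {
  map <- sim_linkage_map(1, 40, 10)
  cross <- simulate_cross(map, 40, seed = 12)
  hits <- vapply(seq_len(60), function(i) {
    sim <- simulate_phenotypes(cross, qtl = list(), polygenic_h2 = 0,
                               n_years = 1, n_fruit = 10, seed = 500 + i)
    pf <- sim$per_fruit
    stats::anova(stats::lm(value ~ id, pf))[["Pr(>F)"]][1] < 0.01
  }, logical(1))
  expect_lte(mean(hits), 0.05)
})
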