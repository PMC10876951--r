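test_that("label_patches handles singletons, connectivity and classes", {
  g1 <- fs_grid(matrix(c(0, 0, 0, 1), 2, 2), res_m = 30)
  p <- label_patches(g1, 1)
  expect_length(p, 1)
  expect_equal(p[[1]]$area_ha, 30^2 / 1e4)
  expect_equal(p[[1]]$perimeter_m, 4 * 30)

  gd <- fs_grid(matrix(c(1, 0, 0, 1), 2, 2), res_m = 30)
  expect_length(label_patches(gd, 1, connectivity = 8), 1)
  expect_length(label_patches(gd, 1, connectivity = 4), 2)

  cb <- fs_grid(outer(1:4, 1:4, function(i, j) (i + j) %% 2), res_m = 10)
  expect_length(label_patches(cb, 1, connectivity = 4), 8)

  reg <- fs_grid(matrix(1, 2, 2), classes = c(x = 1L))
  expect_error(label_patches(reg, 9), "unknown class")
})

test_that("patch areas partition the class area and match components", {
  set.seed(7)
  for (i in 1:10) {
    g <- random_grid(12, 15, p_on = runif(1, 0.2, 0.6))
    for (conn in c(4, 8)) {
      p <- label_patches(g, 1, connectivity = conn)
      expect_equal(sum(vapply(p, function(x) nrow(x$pixels), 0L)),
                   sum(g$values == 1))
      lab <- brute_components(g$values == 1, conn)
      expect_length(p, length(setdiff(unique(as.vector(lab)), 0L)))
      for (x in p) expect_equal(brute_perimeter(x$pixels, g$res_m),
                                x$perimeter_m)
    }
  }
})

test_that("fractal_index: squares are exactly 1, known strip value, bounds", {
  for (s in c(2, 3, 5, 8)) {
    sq <- label_patches(fs_grid(matrix(1, s, s), res_m = 30), 1)[[1]]
    expect_identical(fractal_index(sq), 1)
  }
  strip <- label_patches(fs_grid(matrix(1, 1, 3), res_m = 30), 1)[[1]]
  expect_equal(fractal_index(strip), 2 * log(0.25 * 240) / log(2700),
               tolerance = 1e-12)
  expect_equal(fractal_index(strip), 1.0364, tolerance = 1e-3)
  # L-shaped patch against the edge-counting oracle
  m <- matrix(0, 3, 3); m[1:3, 1] <- 1; m[3, 2] <- 1
  L <- label_patches(fs_grid(m, res_m = 30), 1)[[1]]
  P <- brute_perimeter(L$pixels, 30)
  expect_equal(fractal_index(L), 2 * log(0.25 * P) / log(4 * 900))
  expect_error(fractal_index(list(area_ha = 1e-4 * 1e-4, perimeter_m = 4)),
               "undefined")
})

test_that("fractal_index is invariant to translation and rotation", {
  set.seed(11)
  base <- matrix(0, 12, 12)
  base[3:5, 4:8] <- 1; base[5, 9] <- 1; base[6, 4] <- 1
  f0 <- fractal_index(label_patches(fs_grid(base, res_m = 30), 1)[[1]])
  shifted <- matrix(0, 12, 12); shifted[6:9, 2:7] <- base[3:6, 4:9]
  rot <- base[nrow(base):1, ]; rot <- t(rot)
  for (m in list(shifted, rot)) {
    f <- fractal_index(label_patches(fs_grid(m, res_m = 30), 1)[[1]])
    expect_equal(f, f0)
  }
})

test_that("distance_to_class: unit/diagonal steps and brute-force equality", {
  g <- fs_grid(matrix(c(1, 0, 0, 0), 2, 2), res_m = 10)
  d <- distance_to_class(g, 1)
  expect_equal(d$values[1, 1], 0)
  expect_equal(d$values[2, 1], 10)
  expect_equal(d$values[1, 2], 10)
  expect_equal(d$values[2, 2], 10 * sqrt(2))
  expect_error(distance_to_class(fs_grid(matrix(0, 2, 2)), 1), "undefined")

  set.seed(3)
  for (i in 1:5) {
    g <- random_grid(16, 16, p_on = 0.15)
    if (!any(g$values == 1)) next
    expect_equal(distance_to_class(g, 1)$values,
                 brute_min_dist(g$values, 1, g$res_m))
  }
})

test_that("resample_majority: unanimity, strict majority, mode and padding", {
  u <- fs_grid(matrix(5, 3, 3), res_m = 10)
  expect_equal(resample_majority(u, 3)$values, matrix(5, 1, 1))
  expect_equal(resample_majority(u, 3)$res_m, 30)

  m <- matrix(c(1, 1, 1, 1, 1, 0, 0, 0, 0), 3, 3)
  expect_equal(resample_majority(fs_grid(m), 3)$values, matrix(1, 1, 1))

  m3 <- matrix(c(2, 2, 2, 2, 7, 7, 7, 9, 9), 3, 3)
  expect_equal(resample_majority(fs_grid(m3), 3)$values, matrix(2, 1, 1))

  # non-divisible dimensions pad with nodata; all-nodata blocks stay nodata
  g <- fs_grid(matrix(1, 4, 4), res_m = 10)
  out <- resample_majority(g, 3)
  expect_identical(dim(out$values), c(2L, 2L))
  expect_equal(out$values[1, 1], 1)
  expect_equal(out$values[2, 2], 1)  # single real cell wins its block
  expect_error(resample_majority(g, 1), ">= 2")
})

test_that("uniform blocks survive resample round-trip unchanged", {
  set.seed(5)
  v <- matrix(sample(1:3, 9, replace = TRUE), 3, 3)
  big <- v[rep(1:3, each = 2), rep(1:3, each = 2)]
  out <- resample_majority(fs_grid(big, res_m = 10), 2)
  expect_equal(out$values, v)
})

test_that("remove_single_pixels clears only size-1 components", {
  one <- fs_grid(matrix(c(0, 0, 0, 1), 2, 2))
  expect_equal(sum(remove_single_pixels(one)$values), 0)
  two <- fs_grid(matrix(c(1, 1, 0, 0), 2, 2))
  expect_equal(remove_single_pixels(two)$values, two$values)

  set.seed(9)
  for (i in 1:8) {
    g <- random_grid(14, 14, p_on = 0.25)
    for (conn in c(4, 8)) {
      got <- remove_single_pixels(g, connectivity = conn)$values
      lab <- brute_components(g$values == 1, conn)
      sizes <- table(lab[lab > 0])
      keep <- as.integer(names(sizes)[sizes > 1])
      expect_equal(got, array((lab %in% keep) * 1, dim(lab)))
    }
  }
})

test_that("hex_aggregate partitions area exactly", {
  zero <- fs_grid(matrix(0, 20, 20), res_m = 30)
  hz <- hex_aggregate(zero, hex_area_km2 = 0.05)
  expect_true(all(hz$damaged_ha == 0))
  expect_gt(nrow(hz), 1)

  set.seed(21)
  g <- random_grid(30, 30, p_on = 0.3, res_m = 30)
  hz <- hex_aggregate(g, hex_area_km2 = 0.03)
  expect_equal(sum(hz$damaged_ha), sum(g$values) * 30^2 / 1e4)

  single <- fs_grid(matrix(0, 10, 10), res_m = 30)
  single$values[4, 7] <- 1
  hz <- hex_aggregate(single, hex_area_km2 = 0.02)
  expect_equal(sum(hz$damaged_ha > 0), 1)
  expect_equal(max(hz$damaged_ha), 0.09)
  expect_error(hex_aggregate(single, hex_area_km2 = 0), "positive")
})
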