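mk_stack <- function(arrs, epochs, res = 10) {
  index_stack(arrs, epochs = epochs, res_m = res)
}

test_that("nbr and ndvi formulas, clamping and undefined cells", {
  expect_equal(nbr(0.5, 0.5), 0)
  expect_equal(nbr(0.5, 0.1), 0.4 / 0.6)
  expect_equal(nbr(0.3, 0), 1)
  expect_true(is.na(nbr(0, 0)))
  expect_equal(ndvi(0.6, 0.2), 0.5)
  m <- nbr(matrix(c(0.5, 0), 1), matrix(c(0.1, 0), 1))
  expect_equal(m[1, 1], 0.4 / 0.6)
  expect_true(is.na(m[1, 2]))
})

test_that("tct applies the coefficient matrix by band name", {
  b <- matrix(0.1, 2, 6,
              dimnames = list(NULL, colnames(tct_coefficients())))
  out <- tct(b)
  expect_equal(unname(out[1, "tcb"]),
               sum(0.1 * tct_coefficients()["tcb", ]))
  # column order must not matter
  out2 <- tct(b[, rev(colnames(b))])
  expect_equal(out, out2)
})

test_that("index_stack validates shape and index ranges", {
  a <- array(0.5, c(2, 2, 3))
  expect_error(index_stack(list(a), 1:3), "named")
  expect_error(mk_stack(list(nbr = a, ndvi = array(0, c(2, 2, 2))), 1:3),
               "identical dimensions")
  bad <- a; bad[1, 1, 1] <- 1.5
  expect_error(mk_stack(list(nbr = bad), 1:3), "\\[-1, 1\\]")
})

test_that("median_composite: identity, odd/even medians, NA scenes, order", {
  vals <- c(0.2, 0.9, 0.4)
  a <- array(rep(vals, each = 4), c(2, 2, 3))
  s <- mk_stack(list(nbr = a), 1:3)
  expect_equal(median_composite(s)$layers$nbr[1, 1, 1], 0.4)
  expect_equal(median_composite(s, epochs = 2)$layers$nbr[2, 2, 1], 0.9)

  a4 <- array(rep(c(0.2, 0.4, 0.6, 0.9), each = 1), c(1, 1, 4))
  s4 <- mk_stack(list(nbr = a4), 1:4)
  expect_equal(median_composite(s4)$layers$nbr[1, 1, 1], 0.5)

  perm <- mk_stack(list(nbr = a4[, , c(3, 1, 4, 2), drop = FALSE]), 1:4)
  expect_equal(median_composite(perm)$layers$nbr,
               median_composite(s4)$layers$nbr)

  a4[1, 1, 2] <- NA
  sNA <- mk_stack(list(nbr = a4), 1:4)
  expect_equal(median_composite(sNA)$layers$nbr[1, 1, 1], 0.6)
  expect_error(median_composite(s4, epochs = 99), "empty")
})

test_that("delta_composite: identity zero, antisymmetry, NA, geometry", {
  set.seed(4)
  a <- array(runif(8, -0.5, 0.5), c(2, 2, 1))
  b <- array(runif(8, -0.5, 0.5), c(2, 2, 1))
  sa <- mk_stack(list(nbr = a), "e")
  sb <- mk_stack(list(nbr = b), "e")
  expect_true(all(delta_composite(sa, sa)$layers$nbr == 0))
  expect_equal(delta_composite(sa, sb)$layers$nbr,
               -delta_composite(sb, sa)$layers$nbr)
  expect_equal(delta_composite(sa, sb)$layers$nbr, b - a)
  b2 <- b; b2[1, 1, 1] <- NA
  expect_true(is.na(delta_composite(sa, mk_stack(list(nbr = b2),
                                                 "e"))$layers$nbr[1, 1, 1]))
  expect_error(delta_composite(sa, mk_stack(list(nbr = array(0, c(3, 3, 1))),
                                            "e")), "geometry")
})

sep_delta_samples <- function(n = 120, seed = 1) {
  # linearly separable deltas: damaged dNBR <= -0.4, undisturbed >= -0.05
  set.seed(seed)
  lab <- rep(c(1, 0), each = n / 2)
  dn <- ifelse(lab == 1, runif(n, -0.8, -0.4), runif(n, -0.05, 0.05))
  nr <- 20
  idx <- sample(nr * nr, n)
  d <- array(0, c(nr, nr, 1))
  d[cbind((idx - 1) %% nr + 1, (idx - 1) %/% nr + 1, 1)] <- dn
  deltas <- index_stack(list(nbr = d, ndvi = d * 0.8), epochs = "delta",
                        res_m = 10)
  samples <- data.frame(row = (idx - 1) %% nr + 1,
                        col = (idx - 1) %/% nr + 1,
                        label = lab,
                        split = rep(c("train", "validation"), n / 2))
  list(deltas = deltas, samples = samples)
}

test_that("damage classifier: separable deltas give perfect validation", {
  d <- sep_delta_samples()
  clf <- train_damage_classifier(d$deltas, d$samples, ntree = 100, seed = 2)
  expect_equal(clf$report$overall, 1)
  expect_equal(unname(clf$report$users["damaged"]), 1)
})

test_that("damage classifier: permuted labels fall to chance", {
  d <- sep_delta_samples(n = 200, seed = 3)
  set.seed(9)
  d$samples$label <- sample(d$samples$label)
  clf <- train_damage_classifier(d$deltas, d$samples, ntree = 100, seed = 2)
  # majority share is 0.5; binomial 4-sigma band around it
  expect_lt(abs(clf$report$overall - 0.5), 4 * sqrt(0.25 / 100))
})

test_that("damage classifier is deterministic and rejects one-class sets", {
  d <- sep_delta_samples()
  c1 <- train_damage_classifier(d$deltas, d$samples, ntree = 50, seed = 7)
  c2 <- train_damage_classifier(d$deltas, d$samples, ntree = 50, seed = 7)
  g <- fs_grid(matrix(1, 20, 20), res_m = 10)
  expect_identical(predict_damage(c1, d$deltas, g)$values,
                   predict_damage(c2, d$deltas, g)$values)
  bad <- d$samples
  bad$label[bad$split == "train"] <- 1
  expect_error(train_damage_classifier(d$deltas, bad), "single class")
})

test_that("predict_damage masks non-forest and filters singletons", {
  d <- sep_delta_samples()
  clf <- train_damage_classifier(d$deltas, d$samples, ntree = 50, seed = 1)
  none <- fs_grid(matrix(0, 20, 20), res_m = 10)
  expect_equal(sum(predict_damage(clf, d$deltas, none)$values), 0)
  # an isolated positive sample pixel is removed by the noise filter
  all_forest <- fs_grid(matrix(1, 20, 20), res_m = 10)
  out <- predict_damage(clf, d$deltas, all_forest)
  expect_length(label_patches(out, 1) |>
                  Filter(f = function(p) nrow(p$pixels) == 1), 0)
  expect_error(predict_damage(list(), d$deltas, all_forest), "not fitted")
})

test_that("damage recovery on the synthetic scenario within 5% at low noise", {
  cfgs <- scenario_config(grid_rows = 64, grid_cols = 64, seed = 31,
                          trajectory_noise_sd = 0.02)
  tr <- generate_scenario(cfgs)
  deltas <- delta_composite(firescape:::single_epoch(tr$stack, 2021),
                            firescape:::single_epoch(tr$stack, 2022))
  lc <- tr$landcover_by_year[["2021"]]
  fmask <- fs_grid((lc$values == landcover_classes()[["forest"]]) * 1,
                   res_m = lc$res_m)
  pos <- which(tr$damage_2022$values == 1)
  set.seed(8)
  neg <- sample(which(tr$damage_2022$values == 0 & fmask$values == 1),
                length(pos))
  nr <- nrow(fmask$values)
  idx <- c(pos, neg)
  samples <- data.frame(row = (idx - 1) %% nr + 1,
                        col = (idx - 1) %/% nr + 1,
                        label = rep(c(1, 0), each = length(pos)),
                        split = sample(c("train", "validation"),
                                       2 * length(pos), replace = TRUE))
  clf <- train_damage_classifier(deltas, samples, ntree = 150, seed = 4)
  got <- predict_damage(clf, deltas, fmask)
  true_area <- sum(tr$damage_2022$values)
  expect_lt(abs(sum(got$values) - true_area) / true_area, 0.05)
})

test_that("damage precision and recall degrade with trajectory noise", {
  f1 <- function(noise, seed = 17) {
    cfgs <- scenario_config(grid_rows = 64, grid_cols = 64, seed = seed,
                            trajectory_noise_sd = noise)
    tr <- generate_scenario(cfgs)
    deltas <- delta_composite(firescape:::single_epoch(tr$stack, 2021),
                              firescape:::single_epoch(tr$stack, 2022))
    lc <- tr$landcover_by_year[["2021"]]
    fmask <- fs_grid((lc$values == landcover_classes()[["forest"]]) * 1,
                     res_m = lc$res_m)
    pos <- which(tr$damage_2022$values == 1)
    set.seed(1)
    neg <- sample(which(tr$damage_2022$values == 0 & fmask$values == 1),
                  length(pos))
    nr <- nrow(fmask$values)
    idx <- c(pos, neg)
    samples <- data.frame(row = (idx - 1) %% nr + 1,
                          col = (idx - 1) %/% nr + 1,
                          label = rep(c(1, 0), each = length(pos)),
                          split = sample(c("train", "validation"),
                                         2 * length(pos), replace = TRUE))
    clf <- train_damage_classifier(deltas, samples, ntree = 100, seed = 4)
    got <- predict_damage(clf, deltas, fmask)$values
    truth <- tr$damage_2022$values
    tp <- sum(got == 1 & truth == 1)
    2 * tp / (sum(got) + sum(truth))  # F1
  }
  scores <- vapply(c(0.01, 0.08, 0.2), f1, 0)
  expect_true(all(diff(scores) <= 0.02))  # monotone non-increasing (slack)
  expect_gt(scores[1], 0.95)
})
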