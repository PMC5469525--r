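test_that("Pearson similarity matches its definitional formula", {
  x <- c(1, 2, 4, 5); y <- c(1, 3, 3, 6)
  expect_equal(pearson_channel(x, y), oracle_pearson(x, y),
               tolerance = 1e-12)
  expect_equal(pearson_channel(x, x), 1)
  expect_equal(pearson_channel(x, -x), -1)
  expect_warning(r <- pearson_channel(rep(2, 4), y), "constant")
  expect_equal(r, 0)

  set.seed(21)
  agg <- rand_channel_matrix(100)
  cgg <- rand_channel_matrix(100)
  expect_equal(pearson_total(agg, cgg),
               sum(sapply(1:6, function(j)
                 oracle_pearson(agg[, j], cgg[, j]))),
               tolerance = 1e-12)
  expect_equal(pearson_total(agg, agg), 6)
  expect_equal(pearson_total(agg, -agg), -6)
  # symmetry
  expect_equal(pearson_total(agg, cgg), pearson_total(cgg, agg),
               tolerance = 1e-12)
})

test_that("variance ratio separates repeatable from unrelated cycles", {
  set.seed(22)
  one <- rnorm(100)
  expect_equal(variance_ratio_channel(rbind(one, one, one)), 0)

  hand <- matrix(c(1, 2, 0, 4, 3, 1, 2, 2, 5, 0, 1, 3), 3, 4)
  expect_equal(variance_ratio_channel(hand), oracle_vr(hand),
               tolerance = 1e-12)

  vs <- vapply(1:50, function(s) {
    set.seed(s)
    variance_ratio_channel(matrix(rnorm(300), 3, 100))
  }, numeric(1))
  expect_gt(mean(vs), 0.9)
  expect_lt(mean(vs), 1.1)

  # V sums the per-channel ratios over the cycles behind an AGG
  set.seed(23)
  stack <- replicate(3, rand_channel_matrix(40), simplify = FALSE)
  brute <- sum(sapply(1:6, function(j)
    oracle_vr(rbind(stack[[1]][, j], stack[[2]][, j], stack[[3]][, j]))))
  expect_equal(variance_ratio_total(stack), brute, tolerance = 1e-12)
  expect_equal(variance_ratio_total(list(stack[[1]], stack[[1]],
                                         stack[[1]])), 0)
})

test_that("extreme points count first-derivative sign changes", {
  ramp <- matrix(seq_len(100), 100, 6, dimnames = list(NULL, REP6))
  expect_equal(count_extreme_points(ramp), 0)

  sine <- matrix(sin(2 * pi * (0:99) / 100), 100, 6,
                 dimnames = list(NULL, REP6))
  expect_equal(count_extreme_points(sine), 12)

  rippled <- sine
  rippled[, 1] <- sine[, 1] + 0.2 * sin(2 * pi * 9 * (0:99) / 100)
  expect_gt(count_extreme_points(rippled), count_extreme_points(sine))

  # plateaus collapse to at most one extremum
  plat <- matrix(c(0, 1, 2, 2, 2, 1, 0, 0, 1, 2), 10, 6,
                 dimnames = list(NULL, REP6))
  expect_equal(count_extreme_points(plat[, 1, drop = FALSE]), 2)

  set.seed(24)
  m <- rand_channel_matrix(100)
  expect_equal(count_extreme_points(m),
               sum(sapply(1:6, function(j) oracle_extremes(m[, j]))))
})

test_that("harmonic ratio reflects even/odd harmonic balance", {
  t <- (0:99) / 100
  expect_equal(harmonic_ratio(cos(2 * pi * t)), 0, tolerance = 1e-9)
  expect_warning(h <- harmonic_ratio(cos(4 * pi * t)), "capped")
  expect_equal(h, 1e6)
  expect_equal(harmonic_ratio(cos(2 * pi * t) + cos(4 * pi * t)), 1,
               tolerance = 1e-9)

  # planted harmonic magnitudes give the analytic ratio
  x <- 2 * cos(2 * pi * t) + 1.5 * sin(4 * pi * t) +
    0.7 * cos(6 * pi * t) + 0.4 * sin(16 * pi * t)
  expect_equal(harmonic_ratio(x), (1.5 + 0.4) / (2 + 0.7),
               tolerance = 1e-9)

  agg <- matrix(0, 100, 6, dimnames = list(NULL, REP6))
  agg[, "SI-W"] <- cos(2 * pi * t) + cos(4 * pi * t)
  agg[, "AP-W"] <- cos(2 * pi * t)
  expect_equal(harmonic_total(agg), 1, tolerance = 1e-9)

  set.seed(25)
  r <- rnorm(100)
  expect_equal(harmonic_ratio(r), oracle_harmonic(r), tolerance = 1e-9)
})

test_that("step symmetry peaks for half-stride-periodic strides", {
  t <- (0:99) / 100
  half <- sin(4 * pi * t) + 0.5 * cos(8 * pi * t)
  expect_equal(symmetry_channel(half), 1, tolerance = 0.02)

  as_noise <- vapply(1:50, function(s) {
    set.seed(s)
    symmetry_channel(rnorm(100))
  }, numeric(1))
  expect_lt(mean(abs(as_noise)), 0.3)

  # scaling one step down breaks the symmetry strictly
  asym <- sin(4 * pi * t) * ifelse(t < 0.5, 1, 0.5)
  expect_lt(symmetry_channel(asym), symmetry_channel(sin(4 * pi * t)))

  # invariant to positive scaling
  set.seed(26)
  r <- rnorm(100)
  expect_equal(symmetry_channel(5.5 * r), symmetry_channel(r),
               tolerance = 1e-12)
  expect_equal(symmetry_channel(r), oracle_symmetry(r), tolerance = 1e-12)

  agg <- matrix(0, 100, 6, dimnames = list(NULL, REP6))
  agg[, "SI-W"] <- half
  agg[, "AP-W"] <- cos(4 * pi * t)
  expect_equal(symmetry_total(agg), 2, tolerance = 0.04)
})

test_that("the assembled feature vector composes its parts", {
  t <- (0:99) / 100
  m <- matrix(0, 100, 6, dimnames = list(NULL, REP6))
  for (j in 1:4) m[, j] <- sin(4 * pi * t + j / 3)
  m[, "SI-W"] <- cos(4 * pi * t)
  m[, "AP-W"] <- sin(4 * pi * t)
  agg <- as_agg(m)
  cgg <- build_cgg(list(m))
  # both waist channels are pure even harmonics, so each one warns
  expect_warning(expect_warning(fv <- gait_features(agg, cgg), "capped"),
                 "capped")
  expect_equal(unname(fv["P"]), 6, tolerance = 1e-12)
  expect_equal(unname(fv["V"]), 0)
  expect_equal(unname(fv["N"]), count_extreme_points(m))
  expect_equal(unname(fv["S"]), 2, tolerance = 0.04)
  fv2 <- suppressWarnings(gait_features(agg, cgg))
  expect_identical(fv, fv2)

  # V, N, H, S invariant under global positive scaling; P under affine
  set.seed(27)
  mm <- rand_channel_matrix(100)
  a2 <- as_agg(mm, replicate(3, rand_channel_matrix(100),
                             simplify = FALSE))
  cg <- rand_channel_matrix(100)
  f1 <- gait_features(a2, cg)
  a3 <- as_agg(mm * 4.2, lapply(attr(a2, "cycles"), function(x) x * 4.2))
  f2 <- gait_features(a3, cg)
  expect_equal(f1[c("V", "N", "H", "S")], f2[c("V", "N", "H", "S")],
               tolerance = 1e-9)
  shifted <- sweep(mm * 2.5, 2, rnorm(6), "+")
  expect_equal(pearson_total(shifted, cg), pearson_total(mm, cg),
               tolerance = 1e-9)
})
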