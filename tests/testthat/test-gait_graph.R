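test_that("cycle normalization is exact on identity and affine inputs", {
  set.seed(4)
  m <- rand_channel_matrix(100)
  out <- normalize_cycle(m, M = 100, center = FALSE)
  expect_equal(unclass(out), m, tolerance = 1e-12, ignore_attr = TRUE)

  # linear ramps resample to linear ramps, exactly
  ramp <- matrix(seq(2, 17, length.out = 73), 73, 6)
  colnames(ramp) <- REP6
  out <- normalize_cycle(ramp, M = 100, center = FALSE)
  expect_equal(out[, 1], seq(2, 17, length.out = 100), tolerance = 1e-12,
               ignore_attr = TRUE)

  # sine sampled at 173 points lands on the analytic sine at the query grid
  L <- 173
  s <- matrix(sin(2 * pi * seq(0, 1, length.out = L)), L, 6)
  colnames(s) <- REP6
  out <- normalize_cycle(s, M = 100, center = FALSE)
  expect_lt(max(abs(out[, 1] - sin(2 * pi * seq(0, 1, length.out = 100)))),
            0.01)

  # no overshoot: interpolation stays inside the input range
  set.seed(5)
  r <- rand_channel_matrix(37)
  out <- normalize_cycle(r, M = 100, center = FALSE)
  for (j in 1:6) {
    expect_gte(min(out[, j]), min(r[, j]) - 1e-12)
    expect_lte(max(out[, j]), max(r[, j]) + 1e-12)
  }

  # centering leaves every channel with zero mean
  out <- normalize_cycle(r, M = 100, center = TRUE)
  expect_lt(max(abs(colMeans(out))), 1e-9)
  expect_error(normalize_cycle(r[1:3, ], M = 100), "degenerate")
})

test_that("AGGs average consecutive cycle triples", {
  set.seed(6)
  base <- normalize_cycle(rand_channel_matrix(80))
  aggs <- build_aggs(rep(list(base), 12))
  expect_length(aggs, 4)
  for (a in aggs) expect_equal(unclass(a), unclass(base),
                               tolerance = 1e-12, ignore_attr = TRUE)

  scaled <- lapply(1:6, function(k) base * k)
  aggs <- build_aggs(scaled, n_graphs = 2)
  expect_equal(unclass(aggs[[1]]), unclass(base * 2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unclass(aggs[[2]]), unclass(base * 5), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(aggs[[2]], "source_cycles"), 4:6)

  expect_warning(aggs <- build_aggs(rep(list(base), 10)), "3 AGG")
  expect_length(aggs, 3)
  expect_error(build_aggs(list(base, base)), "at least 3")
})

test_that("the CGG is the elementwise mean of its AGGs", {
  set.seed(8)
  x <- rand_channel_matrix(50)
  expect_equal(unclass(build_cgg(list(x))), x, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(max(abs(build_cgg(list(x, -x)))), 0)

  aggs <- replicate(4, rand_channel_matrix(50), simplify = FALSE)
  m <- build_cgg(aggs)
  brute <- (aggs[[1]] + aggs[[2]] + aggs[[3]] + aggs[[4]]) / 4
  expect_equal(unclass(m), brute, tolerance = 1e-12, ignore_attr = TRUE)

  bad <- aggs
  colnames(bad[[2]])[1] <- "XX"
  expect_error(build_cgg(bad), "channel sets")
})

test_that("channel stability separates shared from idiosyncratic channels", {
  chans9 <- c("SI-L", "ML-L", "AP-L", "SI-R", "ML-R", "AP-R",
              "SI-W", "ML-W", "AP-W")
  set.seed(9)
  shared <- matrix(rnorm(100 * 9), 100, 9, dimnames = list(NULL, chans9))
  same <- replicate(5, shared, simplify = FALSE)
  rep_all <- channel_stability(same)
  expect_equal(rep_all$summary$mean_r, rep(1, 9), tolerance = 1e-12)
  expect_setequal(rep_all$selected, chans9)

  # independent ML noise per subject, everything else shared
  subj <- lapply(1:6, function(i) {
    m <- shared
    m[, c("ML-L", "ML-R", "ML-W")] <- rnorm(300)
    m
  })
  rep_ml <- channel_stability(subj)
  expect_setequal(rep_ml$selected,
                  c("SI-L", "AP-L", "SI-R", "AP-R", "SI-W", "AP-W"))

  # two subjects: every channel equals the textbook correlation
  a <- matrix(rnorm(100 * 9), 100, 9, dimnames = list(NULL, chans9))
  b <- matrix(rnorm(100 * 9), 100, 9, dimnames = list(NULL, chans9))
  rep2 <- channel_stability(list(a, b))
  for (j in 1:9)
    expect_equal(rep2$summary$mean_r[j], oracle_pearson(a[, j], b[, j]),
                 tolerance = 1e-12)

  # a constant channel scores 0 with a warning
  a[, "ML-W"] <- 1
  expect_warning(rep_c <- channel_stability(list(a, b)), "constant")
  expect_equal(rep_c$summary$mean_r[rep_c$summary$channel == "ML-W"], 0)
})

test_that("averaging commutes with channel permutation and scaling", {
  set.seed(10)
  cyc <- replicate(6, normalize_cycle(rand_channel_matrix(60)),
                   simplify = FALSE)
  perm <- sample(6)
  agg_p <- build_aggs(lapply(cyc, function(m) {
    out <- m[, perm]
    class(out) <- class(m)
    out
  }), n_graphs = 2)
  agg <- build_aggs(cyc, n_graphs = 2)
  expect_equal(unclass(agg_p[[1]]), unclass(agg[[1]][, perm]),
               tolerance = 1e-12, ignore_attr = TRUE)
  agg_s <- build_aggs(lapply(cyc, function(m) m * 3.7), n_graphs = 2)
  expect_equal(unclass(agg_s[[2]]), unclass(agg[[2]]) * 3.7,
               tolerance = 1e-12, ignore_attr = TRUE)
})
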