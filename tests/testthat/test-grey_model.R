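test_that("reference matrix, normalization and reference set follow their formulas", {
  expect_equal(build_reference_matrix(matrix(c(1, 3, 1, 3, 1, 3, 1, 3,
                                               1, 3), 2, 5)),
               rep(2, 5), ignore_attr = TRUE)
  one <- matrix(c(2, 1, 5, 0.4, 7), 1, 5)
  expect_equal(build_reference_matrix(one), as.numeric(one),
               ignore_attr = TRUE)
  expect_error(build_reference_matrix(matrix(c(1, -1, 2, 2), 2, 2)),
               "degenerate reference")

  set.seed(31)
  X <- matrix(rexp(40) + 0.5, 8, 5)
  xref <- build_reference_matrix(X)
  for (j in 1:5) expect_equal(xref[j], sum(X[, j]) / 8, tolerance = 1e-12,
                              ignore_attr = TRUE)

  # Eq.-style pointwise checks of the two-branch normalization
  xr <- c(2, 2, 2, 2, 2)
  expect_equal(as.numeric(normalize_features(rbind(xr), xr)), rep(1, 5))
  expect_equal(as.numeric(normalize_features(rbind(rep(0, 5)), xr)),
               rep(0, 5))
  expect_equal(as.numeric(normalize_features(rbind(2 * xr), xr)),
               rep(0, 5))
  expect_equal(as.numeric(normalize_features(rbind(3 * xr), xr)),
               rep(-1, 5))
  expect_error(normalize_features(rbind(c(NA, 1, 1, 1, 1)), xr),
               "non-finite")

  Z <- normalize_features(X, xref)
  for (i in 1:8) expect_equal(Z[i, ], oracle_normalize_row(X[i, ], xref),
                              tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(build_reference_set(Z), colMeans(Z), tolerance = 1e-12)
  expect_equal(build_reference_set(rbind(rep(1, 5), rep(0, 5))),
               rep(0.5, 5), ignore_attr = TRUE)
})

test_that("deviation extrema scan all rows and features", {
  R <- c(0.9, 0.8, 1, 0.7, 0.95)
  Z <- rbind(R + 0.1, R - 0.3)
  expect_equal(compute_extrema(Z, R), c(minAbs = 0.1, maxAbs = 0.3))
  expect_equal(compute_extrema(rbind(R, R), R), c(minAbs = 0, maxAbs = 0))

  set.seed(32)
  Z <- matrix(rnorm(50), 10, 5)
  ex <- compute_extrema(Z, R)
  devs <- abs(t(t(Z) - R))
  expect_equal(unname(ex), c(min(devs), max(devs)), tolerance = 1e-15)
})

test_that("fitting composes the pieces and survives serialization", {
  X4 <- matrix(rep(c(5, 1, 20, 2, 1.8), each = 4), 4, 5,
               dimnames = list(NULL, c("P", "V", "N", "H", "S")))
  m <- fit_gait_model(X4)
  expect_equal(m$minAbs, 0)
  expect_equal(m$maxAbs, 0)
  expect_equal(unname(m$R), rep(1, 5))

  set.seed(33)
  X <- matrix(rexp(80) + 0.2, 16, 5,
              dimnames = list(NULL, c("P", "V", "N", "H", "S")))
  m <- fit_gait_model(X)
  path <- tempfile(fileext = ".json")
  write_gait_model(m, path)
  back <- read_gait_model(path)
  for (f in c("xref", "R", "minAbs", "maxAbs", "gamma", "weights"))
    expect_equal(back[[f]], m[[f]], tolerance = 1e-15)
  p1 <- predict(m, X)
  p2 <- predict(back, X)
  expect_equal(p2$score, p1$score, tolerance = 1e-12)
  unlink(path)

  expect_error(fit_gait_model(X, gamma = 0), "gamma")
  expect_error(fit_gait_model(X, weights = rep(0.3, 5)), "sum to 1")
})

test_that("grey coefficients and degrees follow the defining ratios", {
  set.seed(34)
  X <- matrix(rexp(80) + 0.2, 16, 5,
              dimnames = list(NULL, c("P", "V", "N", "H", "S")))
  m <- fit_gait_model(X)

  cc <- correlation_coefficients(m$R, m)
  expect_equal(cc$xi, rep(1, 5))

  # |z - R| = maxAbs with minAbs forced to 0 and gamma 1 gives 1/2
  m0 <- m
  m0$minAbs <- 0
  z <- m$R + c(m$maxAbs, 0, 0, 0, 0)
  expect_equal(correlation_coefficients(z, m0)$xi[1], 0.5,
               tolerance = 1e-12)

  for (k in 1:25) {
    z <- m$R + rnorm(5, sd = 0.3)
    cc <- correlation_coefficients(z, m)
    expect_equal(cc$xi, oracle_xi(z, m$R, m$minAbs, m$maxAbs, m$gamma),
                 tolerance = 1e-15)
    expect_true(all(cc$xi <= 1 + 1e-15))
    expect_equal(correlation_degree(cc$xi, m$weights),
                 sum(m$weights * cc$xi), tolerance = 1e-15)
  }
  expect_equal(correlation_degree(rep(1, 5), rep(0.2, 5)), 1)
  expect_equal(correlation_degree(c(1, 0, 0, 0, 0), rep(0.2, 5)), 0.2)

  # degenerate training: zero deviation everywhere
  X4 <- matrix(rep(c(5, 1, 20, 2, 1.8), each = 4), 4, 5,
               dimnames = list(NULL, c("P", "V", "N", "H", "S")))
  md <- fit_gait_model(X4)
  expect_warning(cc <- correlation_coefficients(md$R + c(0, 0.1, 0, 0, 0),
                                                md), "degenerate")
  expect_equal(cc$xi, c(1, 0, 1, 1, 1))
})

test_that("assessment scores are bounded, monotone and permutation-stable", {
  set.seed(35)
  X <- matrix(rexp(80) + 0.2, 16, 5,
              dimnames = list(NULL, c("P", "V", "N", "H", "S")))
  m <- fit_gait_model(X)

  # rows whose normalized deviation equals maxAbs everywhere: with
  # minAbs = 0 and gamma = 1 every xi is 1/2, so the score is 50.
  # Invert the upper branch of the normalization: x = (2 - z) * xref.
  m0 <- m
  m0$minAbs <- 0
  z_target <- m$R - m$maxAbs
  G_half <- matrix(rep((2 - z_target) * m$xref, each = 4), 4, 5,
                   dimnames = list(NULL, c("P", "V", "N", "H", "S")))
  pr <- predict(m0, G_half)
  expect_equal(pr$score, 50, tolerance = 1e-9)

  # score never exceeds [0, 100] over random inputs
  set.seed(36)
  for (k in 1:200) {
    G <- matrix(rexp(20, rate = 0.3), 4, 5,
                dimnames = list(NULL, c("P", "V", "N", "H", "S")))
    s <- predict(m, G)$score
    expect_gte(s, 0)
    expect_lte(s, 100)
  }

  # widening one feature's normalized deviation from the reference set
  # never raises the score (the score peaks where Z equals R, i.e. at
  # x = R * Xref, not at Xref itself: the two-branch normalization maps
  # both sides of Xref below 1, so R < 1 sits off-center in raw units)
  prev <- Inf
  for (d in seq(0, 1.5, by = 0.2)) {
    z <- rbind(m$R, m$R, m$R, m$R)
    z[, 3] <- z[, 3] - d
    G <- sweep(2 - z, 2, m$xref, "*")   # invert the upper branch
    s <- predict(m, G)$score
    expect_lte(s, prev + 1e-12)
    prev <- s
  }

  # permuting training rows leaves the model unchanged
  set.seed(37)
  m2 <- fit_gait_model(X[sample(16), ])
  expect_equal(m2$xref, m$xref, tolerance = 1e-12)
  expect_equal(m2$R, m$R, tolerance = 1e-12)
  expect_equal(c(m2$minAbs, m2$maxAbs), c(m$minAbs, m$maxAbs),
               tolerance = 1e-12)

  # fewer than 4 rows: averaged with a warning
  expect_warning(p3 <- predict(m, X[1:2, ]), "fewer than 4")
  expect_equal(p3$score, mean(p3$Ci) * 100, tolerance = 1e-12)
})
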