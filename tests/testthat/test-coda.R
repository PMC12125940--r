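test_that("closure rescales to the total, is idempotent, and errors on zeros", {
  expect_equal(unname(close_composition(c(30, 270, 690, 450))),
               c(30, 270, 690, 450))
  expect_equal(unname(close_composition(c(1, 1, 1, 1), total = 1)), rep(0.25, 4))
  x <- close_composition(c(3, 9, 1, 8))
  expect_equal(close_composition(x), x)
  expect_error(close_composition(c(0, 1, 2, 3)), "non-positive")
  expect_message(
    y <- close_composition(c(0, 1, 2, 3), zero_policy = "replace"),
    "replaced")
  expect_true(all(y > 0) && abs(sum(y) - 1440) < 1e-9)
})

test_that("published 2019 behaviour percentages reclose to the expected minutes", {
  # the rounded percentages total 99.9, so exact closure differs from the
  # naive pct * 14.4 reading by the rounding slack only
  pct <- c(mvpa = 2.1, lipa = 19.2, sb = 47.2, spt = 31.4)
  reclosed <- close_composition(pct, 1440)
  expect_equal(sum(reclosed), 1440, tolerance = 1e-12)
  expect_equal(reclosed, pct / sum(pct) * 1440, tolerance = 1e-12)
  naive <- c(mvpa = 30.24, lipa = 276.48, sb = 679.68, spt = 452.16)  # pct * 14.4
  expect_lt(max(abs(reclosed - naive)), 0.7)
})

test_that("geometric mean composition: identity, invariances, and simulation recovery", {
  x <- close_composition(c(30, 276, 680, 454))
  expect_equal(geometric_mean_composition(rbind(x, x, x)), x)
  s <- rand_comp(50, seed = 5)
  g1 <- geometric_mean_composition(s)
  expect_equal(geometric_mean_composition(s[sample(50), ]), g1)
  s2 <- s; s2[7, ] <- s2[7, ] * 3.7  # rescaling one sample is irrelevant
  expect_equal(geometric_mean_composition(s2), g1)
  # draws around a known centre recover it in Aitchison distance
  set.seed(11)
  V <- pivot_contrast()
  zc <- ilr_transform(x, V)
  draws <- ilr_inverse(matrix(rnorm(200 * 3, 0, 0.3), 200, 3) +
                         rep(zc, each = 200), V)
  expect_lt(aitchison_distance(geometric_mean_composition(draws), x), 0.05)
  expect_error(geometric_mean_composition(s[0, ]), "at least one")
})

test_that("variation matrix matches a brute-force oracle and its invariants", {
  s <- rbind(c(30, 270, 690, 450), c(25, 300, 650, 465), c(40, 250, 700, 450))
  v <- variation_matrix(s)
  # independent two-pass computation
  for (i in 1:4) for (j in 1:4) {
    lr <- log(s[, i] / s[, j])
    expect_equal(v[i, j], sum((lr - mean(lr))^2) / 2, tolerance = 1e-12)
  }
  expect_equal(v, t(v))
  expect_equal(diag(v), rep(0, 4), ignore_attr = TRUE)
  expect_equal(unname(variation_matrix(rbind(s[1, ], s[1, ], s[1, ]))),
               matrix(0, 4, 4))
  # permutation equivariance
  p <- c(3, 1, 4, 2)
  expect_equal(unname(variation_matrix(s[, p])), unname(v[p, p]))
  expect_error(variation_matrix(s[1, , drop = FALSE]), "at least 2")
})

test_that("pivot contrast has the Egozcue coefficients and SBP construction is orthonormal", {
  V <- pivot_contrast()
  expect_equal(unname(V[1, ]),
               c(sqrt(3 / 4), -1 / sqrt(12), -1 / sqrt(12), -1 / sqrt(12)))
  expect_equal(nrow(V), 3)  # 4 parts -> 3 coordinates
  expect_equal(V %*% t(V), diag(3), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(unname(rowSums(V)), rep(0, 3), tolerance = 1e-12)
  # an arbitrary SBP is orthonormal too, and invalid ones error
  signs <- rbind(c(1, 1, -1, -1), c(1, -1, 0, 0), c(0, 0, 1, -1))
  W <- make_sbp_contrast(signs)
  expect_equal(W %*% t(W), diag(3), ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(make_sbp_contrast(rbind(c(1, 1, 1, 1), c(1, -1, 0, 0), c(0, 0, 1, -1))),
               "\\+1 group and a -1 group")
  expect_error(make_sbp_contrast(signs[1:2, ]), "D-1 rows")
})

test_that("ILR transform: zeros at the barycentre, pivot formula, scale invariance", {
  expect_equal(unname(ilr_transform(c(360, 360, 360, 360))), rep(0, 3))
  x <- c(mvpa = 30, lipa = 276, sb = 680, spt = 454)
  z <- ilr_transform(x)
  expect_equal(unname(z[1]),
               sqrt(3 / 4) * (log(30) - mean(log(c(276, 680, 454)))),
               tolerance = 1e-12)
  expect_equal(ilr_transform(x * 17.3), z, tolerance = 1e-12)
  expect_error(ilr_transform(c(0, 1, 1, 1)), "strictly positive")
})

test_that("ILR round trip is exact to 1e-10 on random compositions", {
  X <- rand_comp(100, seed = 7)
  for (V in list(pivot_contrast(),
                 make_sbp_contrast(rbind(c(1, 1, -1, -1), c(1, -1, 0, 0),
                                         c(0, 0, 1, -1))))) {
    back <- ilr_inverse(ilr_transform(X, V), V)
    expect_lt(max(abs(back - X)), 1e-10)
  }
  expect_equal(unname(ilr_inverse(c(0, 0, 0))), rep(360, 4))
})

test_that("adjusted-prediction columns survive an ILR round trip", {
  for (tgt in c(default_targets("cross_sectional"), default_targets("prospective"))) {
    expect_equal(ilr_inverse(ilr_transform(tgt)), close_composition(tgt),
                 tolerance = 1e-10)
  }
})

test_that("perturbation coherence and SBP-invariance of Aitchison distance", {
  x <- close_composition(c(30, 276, 680, 454))
  p <- close_composition(c(1, 1.2, 0.9, 1.05), total = 1)
  expect_equal(ilr_transform(perturb_composition(x, p)),
               ilr_transform(x) + ilr_transform(p), tolerance = 1e-10)
  # distances agree across bases
  y <- close_composition(c(26, 274, 684, 456))
  V2 <- make_sbp_contrast(rbind(c(-1, 1, 1, -1), c(0, 1, -1, 0), c(1, 0, 0, -1)))
  d1 <- sqrt(sum((ilr_transform(x) - ilr_transform(y))^2))
  d2 <- sqrt(sum((ilr_transform(x, V2) - ilr_transform(y, V2))^2))
  expect_equal(d1, d2, tolerance = 1e-10)
})

test_that("Mahalanobis screen flags gross outliers and is chi-square calibrated", {
  set.seed(21)
  Z <- matrix(rnorm(200 * 3), 200, 3)
  Z[17, ] <- c(8, -8, 8)
  out <- mahalanobis_outliers(Z)
  expect_true(out$outlier[17])
  # classical estimate on a clean sample flags about 2.5%
  set.seed(22)
  Zc <- matrix(rnorm(4000 * 3), 4000, 3)
  rate <- mean(mahalanobis_outliers(Zc, robust = FALSE)$outlier)
  expect_gt(rate, 0.015); expect_lt(rate, 0.035)
  expect_error(mahalanobis_outliers(Z[1:3, ]), "more observations")
})
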