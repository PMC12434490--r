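test_that("nondominated sorting matches a brute-force oracle", {
  # fixed example: (0.55, 0.06) is dominated by (0.6, 0.05)
  p <- c(0.5, 0.6, 0.4, 0.55); i <- c(0.02, 0.05, 0.01, 0.06)
  expect_identical(nondominated(p, i), c(3L, 1L, 2L))
  expect_identical(nondominated(0.3, 0.1), 1L)
  set.seed(21)
  for (k in 1:50) {
    n <- sample(1:60, 1)
    p <- round(runif(n), sample(1:3, 1))   # rounding provokes ties
    i <- round(runif(n), sample(1:3, 1))
    expect_setequal(nondominated(p, i), nondominated_oracle(p, i))
  }
  # duplicated optimum: both copies are nondominated
  expect_setequal(nondominated(c(0.5, 0.5, 0.4), c(0.1, 0.1, 0.2)), 1:2)
})

test_that("diminishing-returns walk stops when impurity cost outpaces gain", {
  # front realising the reported +9.4%/+2.9% then +2.6%/+39% steps
  an <- pareto_analysis(c(0.500, 0.547, 0.56122),
                        c(0.0200, 0.02058, 0.02861))
  expect_equal(an$steps$dp_pct, c(9.4, 2.6), tolerance = 1e-3)
  expect_equal(an$steps$di_pct, c(2.9, 39.0), tolerance = 1e-2)
  expect_identical(an$preferred_idx, 2L)
  # a tie accepts the step
  tie <- pareto_analysis(c(0.5, 0.55), c(0.10, 0.11))
  expect_identical(tie$preferred_idx, 2L)
  expect_identical(pareto_analysis(0.6, 0.05)$preferred_idx, 1L)
  # zero impurity switches to absolute changes, with a warning
  # absolute step +0.1 product vs +0.2 impurity: rejected, stay at point 1
  expect_warning(
    pz <- diminishing_returns(list(front = data.frame(
      product = c(0.4, 0.5), impurity = c(0, 0.2)))),
    "absolute")
  expect_identical(pz, 1L)
  # absolute step +0.1 product vs +0.05 impurity: accepted
  expect_warning(
    pz2 <- diminishing_returns(list(front = data.frame(
      product = c(0.4, 0.5), impurity = c(0, 0.05)))),
    "absolute")
  expect_identical(pz2, 2L)
})

test_that("LP weight inference certifies the preferred point", {
  an <- pareto_analysis(c(0.2, 0.5, 0.9), c(0.01, 0.02, 0.20))
  expect_identical(an$preferred_idx, 2L)
  w <- infer_weights(an)
  f <- scalarize(an$front$product, an$front$impurity, w)
  expect_identical(which.min(f), 2L)
  expect_true(all(f[-2] >= f[2] + w$epsilon - 1e-12))
  expect_equal(abs(w$w_amide) + w$w_enamine, 1)
  # dense grid over admissible weights confirms the margin is maximal
  grid_w <- seq(0.051, 0.949, length.out = 2000)
  eps_grid <- vapply(grid_w, function(ww) {
    fg <- scalarize(an$front$product, an$front$impurity, c(ww - 1, ww))
    min(fg[-2] - fg[2])
  }, numeric(1))
  expect_gte(w$epsilon, max(eps_grid) - 1e-6)
  # preferring the low-impurity extreme is feasible when the first step
  # trades enough impurity (weight box caps w_enamine at 0.95)
  an1 <- pareto_analysis(c(0.2, 0.5, 0.9), c(0.01, 0.05, 0.30))
  expect_identical(an1$preferred_idx, 1L)    # 150% product vs 400% impurity
  w1 <- infer_weights(an1)
  f1 <- scalarize(an1$front$product, an1$front$impurity, w1)
  expect_identical(which.min(f1), 1L)
  expect_gt(w1$w_enamine, abs(w1$w_amide))
  # collinear fronts admit no strict scalariser
  anc <- pareto_analysis(c(0.2, 0.5, 0.8), c(0.05, 0.10, 0.15))
  expect_error(infer_weights(anc, preferred_idx = 2), "non-convex")
})

test_that("scalarisation with the reported coefficient pair", {
  expect_identical(scalarize(1, 0, c(-0.2667, 0.773)), -0.2667)
  expect_identical(scalarize(0, 0, c(-0.2667, 0.773)), 0)
  expect_equal(scalarize(0.5, 0.1, c(-0.2667, 0.773)), -0.05605)
  expect_error(scalarize(1, 0, c(0.5, 0.5)), "w_amide")
  expect_error(scalar_weights(-0.01, 0.99), "active")
})

test_that("dominance implies a strictly better scalarised value", {
  set.seed(31)
  for (k in 1:200) {
    a <- runif(2); b <- runif(2)
    p <- c(max(a[1], b[1]) + 0.01, min(a[1], b[1]))  # a' dominates b'
    i <- c(min(a[2], b[2]), max(a[2], b[2]) + 0.01)
    ww <- runif(1, 0.05, 0.95)
    f <- scalarize(p, i, scalar_weights(ww - 1, ww))
    expect_lt(f[1], f[2])
  }
})

test_that("simulator front end-to-end: preferred point re-scores at rank 1", {
  p <- noiseless_params()
  cond <- conditions(240, seq(1, 4, by = 0.5), 8.71, 46, "MeCN")
  y <- true_response(cond, p)
  an <- pareto_analysis(y$product_norm, y$impurity_norm)
  w <- infer_weights(an)
  f <- scalarize(an$front$product, an$front$impurity, w)
  expect_identical(which.min(f), an$preferred_idx)
})
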