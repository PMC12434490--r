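test_that("response surface encodes the solvent-specific shapes", {
  p <- simulator_params()
  tau <- seq(1, 10, by = 0.1)
  for (s in c("dioxane", "2-MeTHF")) {
    y <- true_response(conditions(250, 1, tau, 40, s), p)$product_norm
    d <- diff(y)
    expect_equal(sum(diff(sign(d[d != 0])) != 0), 1)   # one interior max
    expect_equal(tau[which.max(y)], unname(p$tau_star[s]), tolerance = 0.11)
  }
  for (s in c("MeCN", "anisole")) {
    y <- true_response(conditions(250, 1, tau, 45, s), p)$product_norm
    expect_true(all(diff(y) >= 0))                     # sigmoidal increase
    yc <- true_response(conditions(seq(200, 350, 5), 1, 8, 45, s),
                        p)$product_norm
    expect_true(all(diff(yc) <= 0))                    # decay with conc
  }
})

test_that("impurity is linear in equivalents and flat in everything else", {
  p <- simulator_params()
  eq <- seq(1, 4, by = 0.5)
  for (s in names(p$b)) {
    i <- true_response(conditions(250, eq, 5, 40, s), p)$impurity_norm
    expect_equal(diff(i, differences = 2), rep(0, length(eq) - 2))
    expect_equal(i[1], unname(p$b[s]))                 # eq = 1 -> baseline
    expect_equal(diff(i)[1] / 0.5, p$m)
  }
  base <- true_response(conditions(250, 2, 5, 40, "MeCN"), p)$impurity_norm
  for (cc in list(c(200, 2, 5, 40), c(250, 2, 9, 40), c(250, 2, 5, 60))) {
    expect_identical(
      true_response(conditions(cc[1], cc[2], cc[3], cc[4], "MeCN"),
                    p)$impurity_norm, base)
  }
})

test_that("outputs are valid fractions with product + impurity <= 1", {
  p <- calibrated_params()
  set.seed(99)
  n <- 1e5
  cond <- conditions(runif(n, 200, 350), runif(n, 1, 4), runif(n, 1, 10),
                     runif(n, 25, 60),
                     sample(default_space()$categorical$levels, n, TRUE))
  y <- true_response(cond, p)
  expect_true(all(y$product_norm >= 0 & y$product_norm <= 1))
  expect_true(all(y$impurity_norm >= 0 & y$impurity_norm <= 1))
  expect_true(all(y$product_norm + y$impurity_norm <= 1 + 1e-12))
  yn <- observe(cond[1:1000, ], p, seed = 5)
  expect_true(all(yn$product_norm >= 0 & yn$impurity_norm >= 0 &
                    yn$product_norm + yn$impurity_norm <= 1 + 1e-12))
  # the rig cannot run out-of-bounds settings
  oob <- data.frame(concentration_mM = 400, equivalents = 2,
                    residence_time_min = 5, temperature_C = 40,
                    solvent = "MeCN", stringsAsFactors = FALSE)
  expect_error(true_response(oob, p), "outside bounds")
  nosolv <- conditions(250, 2, 5, 40, NA_character_)
  expect_error(true_response(nosolv, p), "solvent")
})

test_that("observation noise is seeded, unbiased and vanishes at sigma 0", {
  p <- calibrated_params()
  cond <- conditions(250, 2, 5, 40, "anisole")   # mid-range, far from clip
  p0 <- p; p0$sigma <- 0
  expect_identical(observe(cond, p0, seed = 1), true_response(cond, p0))
  expect_identical(observe(cond, p, seed = 42), observe(cond, p, seed = 42))
  expect_false(identical(observe(cond, p, seed = 42),
                         observe(cond, p, seed = 43)))
  reps <- observe(cond[rep(1, 1000), ], p, seed = 7)
  truth <- true_response(cond, p)$product_norm
  expect_lt(abs(mean(reps$product_norm) - truth), 3 * p$sigma / sqrt(1000))
})

test_that("calibration pins the anchors within stated tolerances", {
  p <- calibrated_params()
  res <- attr(p, "residuals")
  expect_lt(max(abs(res[grepl("yield|conv", names(res))])), 0.005)
  expect_lt(max(abs(res[grepl("ratio", names(res))])) * 10, 0.1)
  # interior optima stay inside their admissible windows
  expect_gte(p$tau_star[["2-MeTHF"]], 4); expect_lte(p$tau_star[["2-MeTHF"]], 7)
  expect_gte(p$C_star[["2-MeTHF"]], 260); expect_lte(p$C_star[["2-MeTHF"]], 300)
  # refitting from a different restart seed reaches the same solution
  p2 <- calibrate(seed = 202, restarts = 3)
  expect_lt(max(abs(attr(p2, "residuals") - res)), 1e-3)
  # infeasible anchors are reported as such
  bad <- default_anchors()
  bad$A1$target <- 1.5
  expect_error(calibrate(anchors = bad, restarts = 1, seed = 1),
               "infeasible")
})

test_that("stability protocol: two identical rounds for a stable catalyst", {
  p <- noiseless_params()
  st <- stability_protocol(p, seed = 3)
  expect_equal(nrow(unique(st[, c("round", "solvent")])), 8)  # 4 x 2 rounds
  for (s in unique(st$solvent)) {
    r1 <- st$product_norm[st$solvent == s & st$round == 1]
    r2 <- st$product_norm[st$solvent == s & st$round == 2]
    expect_equal(r1, r2)
  }
  pn <- calibrated_params()
  stn <- stability_protocol(pn, seed = 3)
  for (s in unique(stn$solvent)) {
    r1 <- stn$product_norm[stn$solvent == s & stn$round == 1]
    r2 <- stn$product_norm[stn$solvent == s & stn$round == 2]
    expect_lt(abs(mean(r1) - mean(r2)), 3 * pn$sigma / sqrt(length(r1)) * 2)
  }
  pk <- noiseless_params(); pk$kappa <- 0.1
  stk <- stability_protocol(pk, seed = 3)
  for (s in unique(stk$solvent)) {
    expect_lt(mean(stk$product_norm[stk$solvent == s & stk$round == 2]),
              mean(stk$product_norm[stk$solvent == s & stk$round == 1]))
  }
  expect_error(stability_protocol(p, total_hours = 20), "multiple")
})
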