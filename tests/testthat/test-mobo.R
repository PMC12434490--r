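test_that("2D hypervolume by sweep", {
  expect_equal(hypervolume(matrix(c(0, 0), 1), c(1, 1)), 1)
  expect_equal(hypervolume(rbind(c(0, 0.5), c(0.5, 0)), c(1, 1)), 0.75)
  expect_equal(hypervolume(rbind(c(0, 0.5), c(0.5, 0), c(0.7, 0.9)),
                           c(1, 1)), 0.75)          # dominated point ignored
  # points beyond the reference are clipped: (-0.5, 2) lies outside the box
  expect_equal(hypervolume(rbind(c(-0.5, 2), c(0, 0.5)), c(1, 1)), 0.5)
  # partial clipping: 1.5 x 0.2 strip plus 1 x 0.3 strip
  expect_equal(hypervolume(rbind(c(-0.5, 0.8), c(0, 0.5)), c(1, 1)), 0.6)
  expect_error(hypervolume(matrix(c(1.2, 1.2), 1), c(1, 1)),
               "reference point")
})

test_that("Thompson draws are deterministic and average to the posterior", {
  sp <- default_space()
  cond <- lhc_design(sp, 25, seed = 2); cond$solvent <- "MeCN"
  y <- observe(cond, calibrated_params(), seed = 3)$product_norm
  fit <- fit_gp(cond, y, sp, gp_config(restarts = 5, seed = 1))
  probe <- lhc_design(sp, 40, seed = 9); probe$solvent <- "MeCN"
  d1 <- thompson_sample(fit, 500, seed = 42)(probe)
  d2 <- thompson_sample(fit, 500, seed = 42)(probe)
  expect_identical(d1, d2)
  expect_false(identical(d1, thompson_sample(fit, 500, seed = 43)(probe)))
  draws <- vapply(1:200, function(s) thompson_sample(fit, 500, seed = s)(probe),
                  numeric(40))
  pm <- predict(fit, probe)$mean
  expect_lt(max(abs(rowMeans(draws) - pm)), 0.02)
  mc_se <- apply(draws, 1, sd) / sqrt(200)
  expect_lt(mean(abs(rowMeans(draws) - pm) / pmax(mc_se, 1e-12)), 2.5)
})

test_that("zero signal variance yields a constant draw", {
  sp <- default_space()
  cond <- lhc_design(sp, 10, seed = 2); cond$solvent <- "MeCN"
  fit <- suppressWarnings(fit_gp(cond, rep(0.4, 10), sp))
  probe <- lhc_design(sp, 20, seed = 5); probe$solvent <- "MeCN"
  d <- thompson_sample(fit, 200, seed = 1)(probe)
  expect_lt(diff(range(d)), 1e-2)
  expect_equal(mean(d), 0.4, tolerance = 0.02)
  expect_error(thompson_sample(list(), 100, 1), "lvgp")
})

test_that("TSEMO proposals are reproducible, in bounds, and robust to a
           degenerate impurity objective", {
  sp <- default_space()
  p <- calibrated_params()
  cond <- lhc_design(sp, 9, seed = 4); cond$solvent <- "MeCN"
  camp <- make_campaign(cond, p, seed = 5, stage = "stage1")
  cfg <- mobo_config(pop = 40, generations = 30, gp_restarts = 3)
  c1 <- tsemo_step(camp, sp, "MeCN", cfg, seed = 7)
  c2 <- tsemo_step(camp, sp, "MeCN", cfg, seed = 7)
  expect_identical(c1, c2)
  expect_silent(check_conditions <- flowbo:::check_conditions(c1, sp, TRUE))
  camp0 <- camp
  camp0$impurity_norm <- 0.05                  # flat second objective
  expect_warning(c3 <- tsemo_step(camp0, sp, "MeCN", cfg, seed = 8),
                 "degenerate")
  flowbo:::check_conditions(c3, sp, TRUE)
})

test_that("a short stage-1 campaign grows a monotone observed front", {
  sp <- default_space()
  p <- calibrated_params()
  camp <- run_stage1(p, sp, n_init = 5, n_iter = 3, seed = 11,
                     config = mobo_config(pop = 40, generations = 25,
                                          gp_restarts = 3))
  expect_equal(nrow(camp), 8)
  expect_true(all(camp$solvent == "MeCN"))
  flowbo:::check_conditions(camp[, c(flowbo:::cont_names(sp), "solvent")], sp)
  ref <- c(0, 1)
  hv <- vapply(seq_len(nrow(camp)), function(k) {
    hypervolume(cbind(-camp$product_norm[1:k], camp$impurity_norm[1:k]), ref)
  }, numeric(1))
  expect_true(all(diff(hv) >= -1e-12))
})
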