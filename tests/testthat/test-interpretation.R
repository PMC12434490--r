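fit_pair <- function(seed) {
  sp <- default_space()
  p <- calibrated_params()
  cond <- stratified_lhc(sp, 40, seed = seed)
  yp <- observe(cond, p, seed = seed + 500)$product_norm
  yi <- observe(cond, p, seed = seed + 600)$impurity_norm
  list(product = fit_gp(cond, yp, sp, gp_config(restarts = 5, seed = seed)),
       impurity = fit_gp(cond, yi, sp, gp_config(restarts = 5, seed = seed)))
}

test_that("lengthscale importance ranks and flags degenerate fits", {
  fits <- fit_pair(1)
  li <- lengthscale_importance(fits$product)
  expect_setequal(li$variable, default_space()$continuous$name)
  expect_true(!is.unsorted(li$lengthscale))
  expect_equal(li$log10_lengthscale, log10(li$lengthscale))
  expect_true(attr(li, "informative"))
  sp <- default_space()
  cond <- lhc_design(sp, 10, seed = 2); cond$solvent <- "MeCN"
  dfit <- suppressWarnings(fit_gp(cond, rep(1, 10), sp))
  expect_false(attr(lengthscale_importance(dfit), "informative"))
  expect_error(lengthscale_importance(list()), "lvgp")
})

test_that("latent geometry report anchors, distances and collapse flag", {
  fits <- fit_pair(2)
  geom <- latent_geometry(fits$product, fits$impurity)
  expect_equal(geom$table$solvent[1], "MeCN")
  expect_equal(geom$table$product_z1[1], 0)
  expect_equal(geom$table$product_z2[1], 0)
  expect_equal(dim(geom$dist$product), c(4, 4))
  expect_type(geom$collapsed_1d, "logical")
  expect_error(latent_geometry(fits$product, list()), "latent")
})

test_that("partial dependence sweeps respect bounds and medians", {
  fits <- fit_pair(3)
  pd <- partial_dependence(fits$product, "residence_time_min",
                           solvents = c("dioxane", "MeCN"))
  expect_equal(range(pd$value), c(1, 10))
  expect_false(anyNA(pd$mean))
  expect_equal(unique(pd$solvent), c("dioxane", "MeCN"))
  expect_error(partial_dependence(fits$product, "pressure"), "unknown")
  expect_error(partial_dependence(fits$product, "equivalents", "DMSO"),
               "unknown")
  # a variable whose lengthscale sits at the bound gives a flat curve
  sp <- default_space()
  cond <- lhc_design(sp, 12, seed = 4); cond$solvent <- "MeCN"
  dfit <- suppressWarnings(fit_gp(cond, rep(2, 12), sp))
  pdf_ <- partial_dependence(dfit, "temperature_C")
  expect_lt(diff(range(pdf_$mean)), 1e-3 * max(abs(pdf_$mean), 1))
})

test_that("report bundle is complete and byte-deterministic", {
  sp <- default_space()
  p <- calibrated_params()
  fits <- fit_pair(4)
  s1cond <- lhc_design(sp, 9, seed = 5); s1cond$solvent <- "MeCN"
  stage1 <- make_campaign(s1cond, p, seed = 5, stage = "stage1")
  w <- scalar_weights(-0.2667, 0.773)
  stage2 <- make_campaign(stratified_lhc(sp, 12, seed = 6), p, seed = 6,
                          weights = w)
  an <- pareto_analysis(stage1$product_norm, stage1$impurity_norm)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- campaign_report(stage1, stage2, fits$product, fits$impurity, an, w, d1)
  r2 <- campaign_report(stage1, stage2, fits$product, fits$impurity, an, w, d2)
  files <- c("pareto_front.csv", "pareto_percentage_changes.csv",
             "lengthscales_product.csv", "lengthscales_impurity.csv",
             "latent_coordinates.csv", "partial_dependence.csv",
             "best_by_solvent.csv", "summary.json")
  for (f in files) {
    expect_true(file.exists(file.path(d1, f)), label = f)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  expect_equal(r1$summary$best_stage2_sty_g_L_h,
               compute_sty(r1$summary$best_stage2$concentration_mM / 1000,
                           r1$summary$best_stage2$product_norm,
                           r1$summary$best_stage2$residence_time_min / 60))
  expect_error(campaign_report(NULL, stage2, fits$product, fits$impurity,
                               an, w, d1), "stage1")
})
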