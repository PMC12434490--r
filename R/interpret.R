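#' Variable importance from ARD kernel lengthscales
#'
#' Ranks the continuous variables by their fitted ARD lengthscale (unit-cube
#' scale): the smaller the lengthscale, the faster the modelled response
#' varies along that input, hence the more influential the variable. Also
#' reports log10 lengthscales for plotting, and flags the ranking as
#' non-informative when every lengthscale sits at its upper bound (targets
#' carrying no signal).
#'
#' @param fit an `lvgp` fit.
#' @return data.frame (`variable`, `lengthscale`, `log10_lengthscale`) sorted
#'   most-influential first, with attribute `informative`.
#' @export
lengthscale_importance <- function(fit) {
  if (!inherits(fit, "lvgp")) stop("need a fitted lvgp model", call. = FALSE)
  out <- data.frame(variable = names(fit$ell),
                    lengthscale = unname(fit$ell),
                    log10_lengthscale = log10(unname(fit$ell)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$lengthscale), , drop = FALSE]
  rownames(out) <- NULL
  upper <- fit$config$ell_bounds[2]
  attr(out, "informative") <- !all(out$lengthscale >= 0.99 * upper)
  out
}

#' Latent-space solvent geometry
#'
#' Tabulates the fitted 2D latent coordinates per solvent for the product and
#' impurity models, together with pairwise latent distance matrices, and
#' flags a 1D collapse when the coordinate range along the second axis is
#' below `1e-3` of the range along the first.
#'
#' @param fit_product,fit_impurity `lvgp` fits with active latent embeddings.
#' @return list with `table` (coordinates, one row per solvent), `dist`
#'   (per-model distance matrices) and `collapsed_1d` (named logical).
#' @export
latent_geometry <- function(fit_product, fit_impurity) {
  for (f in list(fit_product, fit_impurity)) {
    if (!inherits(f, "lvgp") || !f$use_latent) {
      stop("both fits must carry latent solvent embeddings", call. = FALSE)
    }
  }
  stopifnot(identical(fit_product$levels, fit_impurity$levels))
  lv <- fit_product$levels
  tab <- data.frame(
    solvent = lv,
    product_z1 = fit_product$Z[, 1], product_z2 = fit_product$Z[, 2],
    impurity_z1 = fit_impurity$Z[, 1], impurity_z2 = fit_impurity$Z[, 2],
    stringsAsFactors = FALSE)
  dmat <- function(Z) {
    d <- as.matrix(stats::dist(Z))
    dimnames(d) <- list(lv, lv)
    d
  }
  collapse <- function(Z) {
    r1 <- diff(range(Z[, 1]))
    r2 <- diff(range(Z[, 2]))
    r1 > 0 && (r2 / r1) < 1e-3
  }
  list(table = tab,
       dist = list(product = dmat(fit_product$Z),
                   impurity = dmat(fit_impurity$Z)),
       collapsed_1d = c(product = collapse(fit_product$Z),
                        impurity = collapse(fit_impurity$Z)))
}

#' Partial dependence of a GP surrogate
#'
#' Sweeps one continuous variable across its bounds while holding the other
#' continuous variables at the median of the model's training campaign, one
#' curve per requested solvent.
#'
#' @param fit an `lvgp` fit.
#' @param variable continuous variable name.
#' @param solvents character vector of solvents (default: all levels in the
#'   fit, or none for a single-solvent fit).
#' @param grid_size points along the sweep (default 50).
#' @return data.frame with columns `variable`, `value`, `solvent`, `mean`.
#' @export
partial_dependence <- function(fit, variable, solvents = NULL,
                               grid_size = 50) {
  space <- fit$space
  if (!variable %in% cont_names(space)) {
    stop("unknown continuous variable: ", variable, call. = FALSE)
  }
  solvents <- solvents %||%
    (if (fit$use_latent) fit$levels else unique(fit$cond$solvent))
  if (fit$use_latent && !all(solvents %in% fit$levels)) {
    stop("unknown solvent level(s): ",
         paste(setdiff(solvents, fit$levels), collapse = ", "), call. = FALSE)
  }
  b <- space$continuous[space$continuous$name == variable, ]
  grid <- seq(b$lower, b$upper, length.out = grid_size)
  med <- vapply(cont_names(space), function(v) stats::median(fit$cond[[v]]),
                numeric(1))
  out <- list()
  for (solv in solvents) {
    cond <- as.data.frame(as.list(med), stringsAsFactors = FALSE)
    names(cond) <- cont_names(space)
    cond <- cond[rep(1, grid_size), , drop = FALSE]
    cond[[variable]] <- grid
    cond$solvent <- solv
    pr <- predict(fit, cond, include_noise = FALSE)
    out[[solv]] <- data.frame(variable = variable, value = grid,
                              solvent = solv, mean = pr$mean,
                              stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Post-campaign report bundle
#'
#' Writes the interpretation artifacts of a completed two-stage study to
#' `out_dir`: Pareto front and percentage-change table, inferred weights,
#' best observed conditions per solvent with selectivity/conversion
#' summaries, lengthscale and latent-coordinate tables, partial-dependence
#' curves, and the space-time yield of the best stage-2 point.
#'
#' @param stage1,stage2 campaign data.frames.
#' @param fit_product,fit_impurity `lvgp` fits on the stage-2 peak areas.
#' @param analysis stage-1 `pareto_analysis`.
#' @param weights `scalar_weights` used in stage 2.
#' @param out_dir output directory (created if missing).
#' @param molar_mass_g_mol product molar mass for the STY calculation.
#' @return invisibly, a list of written file paths and the JSON summary.
#' @export
campaign_report <- function(stage1, stage2, fit_product, fit_impurity,
                            analysis, weights, out_dir,
                            molar_mass_g_mol = 191.23) {
  for (nm in c("stage1", "stage2", "fit_product", "fit_impurity",
               "analysis", "weights")) {
    if (is.null(get(nm))) stop("missing input: ", nm, call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  fmt <- function(df) {
    for (j in seq_along(df)) {
      if (is.numeric(df[[j]])) df[[j]] <- formatC(df[[j]], digits = 10,
                                                  format = "g")
    }
    df
  }
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(fmt(df), p, row.names = FALSE, quote = FALSE)
    paths[[name]] <<- p
  }

  wr(analysis$front, "pareto_front.csv")
  wr(analysis$steps, "pareto_percentage_changes.csv")
  ls_p <- lengthscale_importance(fit_product)
  ls_i <- lengthscale_importance(fit_impurity)
  wr(ls_p, "lengthscales_product.csv")
  wr(ls_i, "lengthscales_impurity.csv")
  geom <- latent_geometry(fit_product, fit_impurity)
  wr(geom$table, "latent_coordinates.csv")
  pdp <- do.call(rbind, lapply(cont_names(fit_product$space), function(v) {
    rbind(cbind(model = "product", partial_dependence(fit_product, v)),
          cbind(model = "impurity", partial_dependence(fit_impurity, v)))
  }))
  wr(pdp, "partial_dependence.csv")

  best_by_solvent <- do.call(rbind, lapply(
    split(stage2, stage2$solvent), function(d) d[which.min(d$objective_f), ]))
  wr(best_by_solvent, "best_by_solvent.csv")

  best2 <- stage2[which.min(stage2$objective_f), ]
  sty <- compute_sty(concentration_mol_L = best2$concentration_mM / 1000,
                     yield_fraction = best2$product_norm,
                     time_h = best2$residence_time_min / 60,
                     molar_mass_g_mol = molar_mass_g_mol)
  summary <- list(
    weights = list(w_amide = weights$w_amide, w_enamine = weights$w_enamine,
                   epsilon = weights$epsilon),
    preferred_front_index = analysis$preferred_idx,
    best_stage2 = as.list(best2),
    best_stage2_sty_g_L_h = sty,
    selectivity_best_stage2 = best2$product_norm /
      max(best2$impurity_norm, 1e-12),
    conversion_best_stage2 = best2$product_norm + best2$impurity_norm,
    latent_collapsed_1d = as.list(geom$collapsed_1d),
    lengthscale_ranking = list(product = ls_p$variable,
                               impurity = ls_i$variable))
  p <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths[["summary.json"]] <- p
  invisible(list(paths = paths, summary = summary))
}
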