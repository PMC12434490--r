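CAMPAIGN_HEADER <- "# flowbo campaign v1"
CAMPAIGN_COLS <- c("run_id", "stage", "clock_h", "concentration_mM",
                   "equivalents", "residence_time_min", "temperature_C",
                   "solvent", "product_norm", "impurity_norm", "objective_f",
                   "seed")

#' Campaign CSV persistence
#'
#' Campaigns are persisted as versioned CSV files: a `# flowbo campaign v1`
#' header line followed by the fixed column schema. Floats are written at 10
#' significant digits, giving lossless round trips at that precision.
#'
#' @param campaign campaign data.frame.
#' @param path file path.
#' @param space design space used to validate rows on read.
#' @return `read_campaign`: the campaign data.frame; `write_campaign`: the
#'   path, invisibly.
#' @export
write_campaign <- function(campaign, path) {
  stopifnot(all(CAMPAIGN_COLS %in% names(campaign)))
  df <- campaign[, CAMPAIGN_COLS]
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) {
      df[[j]] <- ifelse(is.na(df[[j]]), "",
                        formatC(df[[j]], digits = 10, format = "g"))
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(CAMPAIGN_HEADER, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_campaign
#' @export
read_campaign <- function(path, space = default_space()) {
  lines <- readLines(path)
  if (length(lines) == 0 || !startsWith(lines[1], "#")) {
    stop("not a campaign file (missing version header): ", path,
         call. = FALSE)
  }
  if (trimws(lines[1]) != CAMPAIGN_HEADER) {
    stop("unknown campaign header version: ", lines[1], call. = FALSE)
  }
  if (length(lines) <= 2) {
    warning("empty campaign file: ", path)
    out <- as.data.frame(stats::setNames(
      replicate(length(CAMPAIGN_COLS), character(0), simplify = FALSE),
      CAMPAIGN_COLS), stringsAsFactors = FALSE)
    return(out)
  }
  df <- utils::read.csv(text = lines[-1], stringsAsFactors = FALSE,
                        colClasses = c(stage = "character",
                                       solvent = "character"))
  if (!identical(names(df), CAMPAIGN_COLS)) {
    stop("campaign columns do not match schema v1", call. = FALSE)
  }
  num_cols <- setdiff(CAMPAIGN_COLS, c("stage", "solvent", "objective_f"))
  for (cc in num_cols) {
    bad <- which(!is.finite(df[[cc]]))
    if (length(bad)) {
      stop(sprintf("malformed row at line %d: non-finite '%s'",
                   bad[1] + 2L, cc), call. = FALSE)
    }
  }
  bad <- which(!(df$solvent %in% space$categorical$levels))
  if (length(bad)) {
    stop(sprintf("malformed row at line %d: unknown solvent '%s'",
                 bad[1] + 2L, df$solvent[bad[1]]), call. = FALSE)
  }
  df
}

#' Space-time yield
#'
#' Reactor productivity in grams of product per litre of reactor volume per
#' hour: `STY = concentration x yield x molar mass / time`. Residence time
#' enters in hours (8.4 min = 0.14 h).
#'
#' @param concentration_mol_L limiting-substrate concentration, mol/L.
#' @param yield_fraction fractional yield in `[0, 1]`.
#' @param time_h residence time (flow) or reaction time (batch), hours.
#' @param molar_mass_g_mol product molar mass, g/mol (default 191.23 for
#'   N-benzyl acetoacetamide, C11H13NO2).
#' @return STY in g L^-1 h^-1.
#' @export
compute_sty <- function(concentration_mol_L, yield_fraction, time_h,
                        molar_mass_g_mol = 191.23) {
  stopifnot(concentration_mol_L > 0, yield_fraction >= 0,
            yield_fraction <= 1, molar_mass_g_mol > 0)
  if (any(time_h <= 0)) stop("time must be positive", call. = FALSE)
  concentration_mol_L * yield_fraction * molar_mass_g_mol / time_h
}

#' Default study configuration
#'
#' All tunable settings of the two-stage in-silico study: the design space,
#' simulator defaults, stage budgets (9 + 60 + 12 + 27 = 108 experiments),
#' solver settings and the stability protocol. Serialisable to YAML with
#' [write_config()].
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  sp <- default_space()
  list(
    design_space = list(
      continuous = sp$continuous,
      solvents = sp$categorical$levels),
    simulator = unclass(simulator_params())[
      c("A", "tau_star", "t0", "r", "C_star", "omega", "gamma", "T_star",
        "sigma_T", "delta", "b", "m", "sigma", "kappa")],
    calibration = list(restarts = 5, tol_yield = 0.005, tol_ratio = 0.1),
    stability = list(hours_per_solvent = 3, total_hours = 24,
                     samples_per_hour = 2),
    stage1 = list(solvent = "MeCN", n_init = 9, n_iter = 60,
                  n_features = 500, pop = 100, generations = 100,
                  gp_restarts = 5, ref_margin = 0.1),
    stage2 = list(n_init = 12, n_iter = 27, gp_restarts = 5,
                  n_screen = 128, n_starts = 20, maxit = 25),
    weights = list(eps_floor = 1e-6),
    sty = list(molar_mass_g_mol = 191.23),
    clock = list(exp_duration_h = 31 / 108))
}

#' Read and write study configuration
#'
#' @param config configuration list (see [default_config()]).
#' @param path YAML file path.
#' @return `read_config`: the configuration list.
#' @export
write_config <- function(config, path) {
  cfg <- config
  cfg$design_space$continuous <- as.list(cfg$design_space$continuous)
  # yaml drops names on atomic vectors; keep per-solvent names via lists
  cfg$simulator <- lapply(cfg$simulator,
                          function(x) if (!is.null(names(x))) as.list(x)
                          else x)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$design_space$continuous <-
    as.data.frame(cfg$design_space$continuous, stringsAsFactors = FALSE)
  # named numeric vectors come back as lists
  unl <- function(x) if (is.list(x)) unlist(x) else x
  cfg$simulator <- lapply(cfg$simulator, unl)
  cfg
}

config_space <- function(config) {
  design_space(config$design_space$continuous, config$design_space$solvents)
}

config_params <- function(config) {
  do.call(simulator_params, config$simulator)
}

#' Run the full two-stage in-silico study
#'
#' Chains every stage of the campaign from a configuration and a single seed:
#' simulator calibration to the printed anchors, the 24 h catalyst stability
#' protocol, the stage-1 multiobjective campaign (9 + 60 experiments in
#' MeCN), Pareto analysis with diminishing-returns preferred-point selection
#' and LP weight inference, the stage-2 mixed-variable campaign (12 + 27
#' experiments across all solvents), and the interpretation report. All
#' artifacts are written under `out_dir`; a manifest records the
#' configuration hash, seed and package version, making reruns with equal
#' manifests byte-identical.
#'
#' @param config configuration list (default [default_config()]).
#' @param seed single master seed for every source of randomness.
#' @param out_dir output directory.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the calibrated parameters, campaigns,
#'   analysis, weights, fits and file paths.
#' @export
run_full_study <- function(config = default_config(), seed = 1,
                           out_dir = tempfile("flowbo_study_"),
                           quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  space <- config_space(config)
  stage_fail <- function(stage, e) {
    stop(sprintf("study aborted in stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }

  cfg_path <- file.path(out_dir, "config.yaml")
  write_config(config, cfg_path)
  manifest <- list(config_md5 = unname(tools::md5sum(cfg_path)),
                   seed = seed,
                   package_version = as.character(utils::packageVersion("flowbo")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  say("calibrating simulator to anchors ...")
  params <- tryCatch(
    calibrate(config_params(config), restarts = config$calibration$restarts,
              seed = derive_seed(seed, 1),
              tol_yield = config$calibration$tol_yield,
              tol_ratio = config$calibration$tol_ratio, space = space),
    error = function(e) stage_fail("calibrate", e))

  say("running 24 h catalyst stability protocol ...")
  stab <- tryCatch(
    stability_protocol(params,
                       hours_per_solvent = config$stability$hours_per_solvent,
                       total_hours = config$stability$total_hours,
                       samples_per_hour = config$stability$samples_per_hour,
                       seed = derive_seed(seed, 2), space = space),
    error = function(e) stage_fail("stability", e))
  utils::write.csv(stab, file.path(out_dir, "stability.csv"),
                   row.names = FALSE)

  say("stage 1: multiobjective campaign (",
      config$stage1$n_init + config$stage1$n_iter, " experiments) ...")
  mob <- mobo_config(n_features = config$stage1$n_features,
                     pop = config$stage1$pop,
                     generations = config$stage1$generations,
                     gp_restarts = config$stage1$gp_restarts,
                     ref_margin = config$stage1$ref_margin)
  stage1 <- tryCatch(
    run_stage1(params, space, solvent = config$stage1$solvent,
               n_init = config$stage1$n_init, n_iter = config$stage1$n_iter,
               seed = derive_seed(seed, 3), config = mob,
               exp_duration_h = config$clock$exp_duration_h),
    error = function(e) stage_fail("stage1", e))
  write_campaign(stage1, file.path(out_dir, "stage1.csv"))

  say("Pareto analysis and weight inference ...")
  analysis <- tryCatch({
    an <- pareto_analysis(stage1$product_norm, stage1$impurity_norm)
    an
  }, error = function(e) stage_fail("analyze-pareto", e))
  weights <- tryCatch(
    infer_weights(analysis, eps_floor = config$weights$eps_floor),
    error = function(e) stage_fail("infer-weights", e))
  jsonlite::write_json(
    list(w_amide = weights$w_amide, w_enamine = weights$w_enamine,
         epsilon = weights$epsilon,
         preferred_front_index = analysis$preferred_idx),
    file.path(out_dir, "weights.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  say("stage 2: mixed-variable campaign (",
      config$stage2$n_init + config$stage2$n_iter, " experiments) ...")
  ala <- alabo_config(gp_restarts = config$stage2$gp_restarts,
                      n_screen = config$stage2$n_screen,
                      n_starts = config$stage2$n_starts,
                      maxit = config$stage2$maxit)
  stage1_hours <- (config$stage1$n_init + config$stage1$n_iter) *
    config$clock$exp_duration_h
  stage2 <- tryCatch(
    run_stage2(params, space, weights,
               n_init = config$stage2$n_init, n_iter = config$stage2$n_iter,
               seed = derive_seed(seed, 4), config = ala,
               exp_duration_h = config$clock$exp_duration_h,
               clock_offset_h = stage1_hours),
    error = function(e) stage_fail("stage2", e))
  write_campaign(stage2, file.path(out_dir, "stage2.csv"))

  say("interpretation ...")
  result <- tryCatch({
    cond2 <- stage2[, c(cont_names(space), "solvent")]
    gcfg <- function(off) gp_config(restarts = config$stage2$gp_restarts,
                                    seed = derive_seed(seed, off))
    fit_p <- fit_gp(cond2, stage2$product_norm, space, gcfg(5))
    fit_i <- fit_gp(cond2, stage2$impurity_norm, space, gcfg(6))
    gp_to_json(fit_p, file.path(out_dir, "gp_product.json"))
    gp_to_json(fit_i, file.path(out_dir, "gp_impurity.json"))
    rep <- campaign_report(stage1, stage2, fit_p, fit_i, analysis, weights,
                           file.path(out_dir, "report"),
                           molar_mass_g_mol = config$sty$molar_mass_g_mol)
    list(fit_product = fit_p, fit_impurity = fit_i, report = rep)
  }, error = function(e) stage_fail("interpret", e))

  say("done; artifacts in ", out_dir)
  invisible(list(params = params, stability = stab, stage1 = stage1,
                 analysis = analysis, weights = weights, stage2 = stage2,
                 fit_product = result$fit_product,
                 fit_impurity = result$fit_impurity,
                 report = result$report, out_dir = out_dir,
                 manifest = manifest))
}
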