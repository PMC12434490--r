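#' Expected improvement (minimisation)
#'
#' `EI(x) = (best - mu) Phi(z) + sd phi(z)` with `z = (best - mu)/sd`; at
#' zero predictive variance this degenerates to `max(best - mu, 0)`.
#'
#' @param mean,var posterior mean and variance at the query point(s).
#' @param best incumbent (lowest observed) objective value.
#' @return nonnegative EI value(s).
#' @export
expected_improvement <- function(mean, var, best) {
  sd <- sqrt(pmax(var, 0))
  imp <- best - mean
  out <- ifelse(sd > 0,
                imp * stats::pnorm(imp / sd) + sd * stats::dnorm(imp / sd),
                pmax(imp, 0))
  pmax(out, 0)
}

#' Mixed-variable BO settings
#'
#' @param gp_restarts marginal-likelihood restarts per step.
#' @param n_screen random screening candidates per solvent before the local
#'   searches.
#' @param n_starts local EI maximisations per solvent (started from the best
#'   screened candidates).
#' @param maxit iteration cap of each local search.
#' @return list of settings.
#' @export
alabo_config <- function(gp_restarts = 5, n_screen = 128, n_starts = 20,
                         maxit = 25) {
  list(gp_restarts = gp_restarts, n_screen = n_screen, n_starts = n_starts,
       maxit = maxit)
}

#' One ALaBO-style proposal for the scalarised objective
#'
#' Recomputes the scalarised objective `f` from the stored raw observations,
#' fits a single latent-variable GP to `f`, then for every solvent level
#' maximises expected improvement over the continuous unit cube by
#' multi-start local search (L-BFGS-B from the best screened candidates).
#' Returns the best (solvent, continuous) pair. Categorical proposals are
#' always feasible because the maximisation enumerates the declared levels
#' rather than searching latent space.
#'
#' @param campaign campaign data.frame covering every solvent at least once.
#' @param space design space.
#' @param weights scalarisation weights (see [scalarize()]).
#' @param config [alabo_config()] settings.
#' @param seed integer seed.
#' @return one-row conditions data.frame.
#' @export
alabo_step <- function(campaign, space = default_space(),
                       weights, config = alabo_config(), seed = 1) {
  levels <- space$categorical$levels
  if (!all(levels %in% campaign$solvent)) {
    stop("campaign must cover every solvent at least once", call. = FALSE)
  }
  f <- scalarize(campaign$product_norm, campaign$impurity_norm, weights)
  cond <- campaign[, c(cont_names(space), "solvent")]
  fit <- fit_gp(cond, f, space,
                gp_config(restarts = config$gp_restarts,
                          seed = derive_seed(seed, 1)))
  best_f <- min(f)
  d <- space$n_continuous

  # fast EI on the unit cube: skip data.frame construction and S3 dispatch
  # inside the local searches (posterior algebra only)
  ei_u <- function(U, si2) {
    U <- matrix(U, ncol = d)
    Ks <- lvgp_kernel(fit$X, fit$si, fit$ell, fit$sf2, fit$Z, U,
                      rep.int(si2, nrow(U)))
    mu <- drop(crossprod(Ks, fit$alpha))
    V <- backsolve(fit$R, Ks, transpose = TRUE)
    var_f <- pmax(fit$sf2 - colSums(V^2), 0)
    expected_improvement(fit$ym + fit$ysd * mu, fit$ysd^2 * var_f,
                         best_f)
  }
  neg_ei_u <- function(u, solv) {
    si2 <- if (fit$use_latent) match(solv, fit$levels) else 1L
    -ei_u(pmin(pmax(u, 0), 1), si2)
  }

  best <- list(ei = -Inf, u = NULL, solvent = NULL)
  for (solv in levels) {
    U <- with_seed(derive_seed(seed, 10 + match(solv, levels)),
                   matrix(stats::runif(config$n_screen * d), ncol = d))
    si2 <- if (fit$use_latent) match(solv, fit$levels) else 1L
    ei <- ei_u(U, si2)
    starts <- U[order(-ei)[seq_len(min(config$n_starts, nrow(U)))], ,
                drop = FALSE]
    for (k in seq_len(nrow(starts))) {
      opt <- tryCatch(
        stats::optim(starts[k, ], neg_ei_u, solv = solv, method = "L-BFGS-B",
                     lower = rep(0, d), upper = rep(1, d),
                     control = list(maxit = config$maxit)),
        error = function(e) NULL)
      val <- if (!is.null(opt)) -opt$value else ei[order(-ei)[k]]
      u <- if (!is.null(opt)) opt$par else starts[k, ]
      if (val > best$ei) best <- list(ei = val, u = u, solvent = solv)
    }
  }
  if (is.null(best$u)) {
    warning("EI maximisation failed everywhere; proposing a random candidate")
    best$u <- with_seed(derive_seed(seed, 99), stats::runif(d))
    best$solvent <- levels[1 + (seed %% length(levels))]
  }
  from_unit_cube(matrix(best$u, 1), space, solvent = best$solvent)
}

#' Run the stage-2 mixed-variable campaign
#'
#' 12-point solvent-stratified Latin hypercube (3 experiments per solvent)
#' followed by `n_iter` sequential ALaBO-style proposals of the scalarised
#' objective: 39 experiments with the default budgets. The objective `f` is
#' recomputed from the stored raw peak areas, so a change of weights never
#' requires rerunning experiments.
#'
#' @param params calibrated `simulator_params`.
#' @param space design space.
#' @param weights scalarisation weights from stage 1 (or a reported pair).
#' @param n_init,n_iter stratified initial design size and sequential steps.
#' @param seed master seed.
#' @param config [alabo_config()] settings.
#' @param exp_duration_h simulated clock time per experiment, hours.
#' @param clock_offset_h campaign clock at the start of the stage, hours.
#' @return campaign data.frame with per-experiment `objective_f`.
#' @export
run_stage2 <- function(params, space = default_space(), weights,
                       n_init = 12, n_iter = 27, seed = 1,
                       config = alabo_config(),
                       exp_duration_h = 31 / 108, clock_offset_h = 0) {
  init <- stratified_lhc(space, n_init, seed = derive_seed(seed, 11))
  rows <- list()
  for (k in seq_len(n_init)) {
    clock <- clock_offset_h + k * exp_duration_h
    obs <- observe(init[k, ], params, seed = derive_seed(seed, 300 + k),
                   clock_h = clock, space = space)
    f <- scalarize(obs$product_norm, obs$impurity_norm, weights)
    rows[[k]] <- new_campaign_row(init[k, ], obs, "stage2", k, clock, seed, f)
  }
  campaign <- do.call(rbind, rows)
  for (it in seq_len(n_iter)) {
    cand <- alabo_step(campaign, space, weights, config,
                       seed = derive_seed(seed, 400 + it))
    k <- n_init + it
    clock <- clock_offset_h + k * exp_duration_h
    obs <- observe(cand, params, seed = derive_seed(seed, 300 + k),
                   clock_h = clock, space = space)
    log_experiment("stage2", k, cand, obs)
    f <- scalarize(obs$product_norm, obs$impurity_norm, weights)
    campaign <- rbind(campaign,
                      new_campaign_row(cand, obs, "stage2", k, clock, seed, f))
  }
  attr(campaign, "stage") <- "stage2"
  attr(campaign, "seed") <- seed
  campaign
}
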