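#' Approximate posterior draw by spectral features with pathwise update
#'
#' Returns a deterministic, cheaply evaluable function approximating one
#' sample from the GP posterior. The prior sample is a spectral (random
#' Fourier) feature expansion — continuous Matern-5/2 frequencies drawn from
#' the matching multivariate-t spectral density (normal scaled by an
#' inverse-chi-square factor, 5 degrees of freedom), latent squared-
#' exponential dimensions contributing Gaussian frequencies — and the data
#' are incorporated by the exact pathwise update
#' `g(x) = f0(x) + k(x)' (K + sn2 I)^-1 (y - f0(X) - e)`, `e ~ N(0, sn2 I)`,
#' so the draws average to the exact GP posterior mean. The same seed always
#' reproduces the same function.
#'
#' @param fit an `lvgp` fit.
#' @param n_features number of spectral features in the prior sample
#'   (default 500).
#' @param seed integer seed; same seed, same function.
#' @return function mapping a conditions data.frame to sampled values on the
#'   original target scale.
#' @export
thompson_sample <- function(fit, n_features = 500, seed = 1) {
  if (!inherits(fit, "lvgp")) stop("need a fitted lvgp model", call. = FALSE)
  d <- ncol(fit$X)
  m <- n_features
  dz <- if (fit$use_latent) 2L else 0L
  n <- nrow(fit$X)
  draw <- with_seed(seed, {
    # Matern 5/2 ARD: omega = z / ell * sqrt(5 / chi2_5)
    Zc <- matrix(stats::rnorm(m * d), m, d)
    g <- stats::rchisq(m, df = 5)
    Wc <- sweep(Zc, 2, fit$ell, "/") * sqrt(5 / g)
    Wz <- if (dz > 0) matrix(stats::rnorm(m * dz, sd = sqrt(2)), m, dz)
          else NULL
    bias <- stats::runif(m, 0, 2 * pi)
    w <- stats::rnorm(m)                       # prior feature weights
    eps <- stats::rnorm(n, sd = sqrt(fit$sn2)) # virtual observation noise
    list(Wc = Wc, Wz = Wz, bias = bias, w = w, eps = eps)
  })
  phi <- function(X, si) {
    A <- X %*% t(draw$Wc)
    if (dz > 0) A <- A + fit$Z[si, , drop = FALSE] %*% t(draw$Wz)
    sqrt(2 * fit$sf2 / m) * cos(sweep(A, 2, draw$bias, "+"))
  }
  f0_train <- drop(phi(fit$X, fit$si) %*% draw$w)
  resid <- fit$ys - f0_train - draw$eps
  v <- backsolve(fit$R, backsolve(fit$R, resid, transpose = TRUE))
  function(cond) {
    X2 <- to_unit_cube(cond, fit$space)
    si2 <- if (fit$use_latent) match(cond$solvent, fit$levels)
           else rep(1L, nrow(X2))
    if (fit$use_latent && anyNA(si2)) {
      stop("unknown solvent level in Thompson draw evaluation", call. = FALSE)
    }
    Ks <- lvgp_kernel(fit$X, fit$si, fit$ell, fit$sf2, fit$Z, X2, si2)
    f0 <- drop(phi(X2, si2) %*% draw$w)
    drop(fit$ym + fit$ysd * (f0 + crossprod(Ks, v)))
  }
}

#' 2D hypervolume (minimisation)
#'
#' Area dominated by the nondominated subset of `points` and bounded by the
#' reference point, both in minimisation orientation. The campaign objectives
#' (max product, min impurity) map to minimisation as `(-product, impurity)`.
#'
#' @param points numeric matrix with 2 columns (minimisation space).
#' @param ref reference point, dominated by no supplied point.
#' @return nonnegative hypervolume.
#' @export
hypervolume <- function(points, ref) {
  points <- matrix(points, ncol = 2)
  stopifnot(length(ref) == 2)
  idx <- nondominated(-points[, 1], points[, 2])   # minimise both
  front <- points[idx, , drop = FALSE]
  if (any(front[, 1] >= ref[1] & front[, 2] >= ref[2])) {
    stop("reference point lies inside the front region: it must be strictly ",
         "worse than every nondominated point", call. = FALSE)
  }
  pts <- front[order(front[, 1]), , drop = FALSE]
  hv <- 0
  y_prev <- ref[2]
  for (k in seq_len(nrow(pts))) {
    if (pts[k, 1] >= ref[1]) break            # clipped in the first objective
    if (pts[k, 2] < y_prev) {                 # clipped in the second
      hv <- hv + (ref[1] - pts[k, 1]) * (y_prev - pts[k, 2])
      y_prev <- pts[k, 2]
    }
  }
  hv
}

#' Multiobjective optimisation settings
#'
#' @param n_features spectral features per Thompson draw.
#' @param pop,generations inner NSGA-II population and generation count.
#' @param gp_restarts marginal-likelihood restarts for the per-step GP fits.
#' @param ref_margin reference point = observed nadir + `ref_margin` x range.
#' @return list of settings.
#' @export
mobo_config <- function(n_features = 500, pop = 100, generations = 100,
                        gp_restarts = 5, ref_margin = 0.1) {
  list(n_features = n_features, pop = pop, generations = generations,
       gp_restarts = gp_restarts, ref_margin = ref_margin)
}

#' One TSEMO-style proposal
#'
#' Fits one GP per objective to the campaign so far, draws one Thompson
#' sample from each posterior, solves the inner two-objective problem
#' (minimise `-product` draw, minimise impurity draw) with NSGA-II on the
#' unit cube, and returns the inner Pareto candidate with the largest
#' hypervolume improvement over the observed front.
#'
#' @param campaign campaign data.frame (see [run_stage1()]).
#' @param space design space.
#' @param solvent the fixed solvent of the continuous-variable stage.
#' @param config [mobo_config()] settings.
#' @param seed integer seed (GP restarts, draws, inner solver).
#' @return one-row conditions data.frame.
#' @export
tsemo_step <- function(campaign, space = default_space(), solvent = "MeCN",
                       config = mobo_config(), seed = 1) {
  stopifnot(nrow(campaign) >= 1)
  cond <- campaign[, c(cont_names(space), "solvent")]
  fit_p <- fit_gp(cond, campaign$product_norm, space,
                  gp_config(restarts = config$gp_restarts,
                            seed = derive_seed(seed, 1)))
  fit_i <- fit_gp(cond, campaign$impurity_norm, space,
                  gp_config(restarts = config$gp_restarts,
                            seed = derive_seed(seed, 2)))
  draw_p <- thompson_sample(fit_p, config$n_features, derive_seed(seed, 3))
  draw_i <- thompson_sample(fit_i, config$n_features, derive_seed(seed, 4))
  fn <- function(U) {
    cc <- from_unit_cube(U, space, solvent = solvent)
    cbind(-draw_p(cc), draw_i(cc))
  }
  inner <- tryCatch(
    nsga2_minimize(fn, d = space$n_continuous, pop = config$pop,
                   generations = config$generations,
                   seed = derive_seed(seed, 5)),
    error = function(e) NULL)
  if (is.null(inner) || nrow(inner$X) == 0) {
    warning("inner multiobjective solver failed; proposing a random ",
            "in-bounds candidate")
    u <- with_seed(derive_seed(seed, 6),
                   matrix(stats::runif(space$n_continuous), 1))
    return(from_unit_cube(u, space, solvent = solvent))
  }
  obs <- cbind(-campaign$product_norm, campaign$impurity_norm)
  nad <- apply(obs, 2, max)
  rng <- pmax(apply(obs, 2, max) - apply(obs, 2, min), 1e-6)
  ref <- nad + config$ref_margin * rng
  hv0 <- hypervolume(obs, ref)
  hvi <- vapply(seq_len(nrow(inner$X)), function(k) {
    hypervolume(rbind(obs, inner$F[k, ]), ref) - hv0
  }, numeric(1))
  from_unit_cube(inner$X[which.max(hvi), , drop = FALSE], space,
                 solvent = solvent)
}

new_campaign_row <- function(cond, obs, stage, run_id, clock_h, seed,
                             objective_f = NA_real_) {
  data.frame(run_id = run_id, stage = stage, clock_h = clock_h,
             concentration_mM = cond$concentration_mM,
             equivalents = cond$equivalents,
             residence_time_min = cond$residence_time_min,
             temperature_C = cond$temperature_C,
             solvent = cond$solvent,
             product_norm = obs$product_norm,
             impurity_norm = obs$impurity_norm,
             objective_f = objective_f,
             seed = seed,
             stringsAsFactors = FALSE)
}

#' Run the stage-1 multiobjective campaign
#'
#' 9-point Latin-hypercube initialisation (the 2n + 1 rule with n = 4) in a
#' single solvent, followed by `n_iter` sequential TSEMO-style proposals,
#' each evaluated through the (noisy) simulator: 69 experiments with the
#' default budgets.
#'
#' @param params calibrated `simulator_params`.
#' @param space design space.
#' @param solvent fixed solvent (default MeCN).
#' @param n_init,n_iter initial design size and number of sequential steps.
#' @param seed master seed for the whole stage.
#' @param config [mobo_config()] settings.
#' @param exp_duration_h simulated clock time per experiment, hours.
#' @return campaign data.frame with one row per experiment.
#' @export
run_stage1 <- function(params, space = default_space(), solvent = "MeCN",
                       n_init = 9, n_iter = 60, seed = 1,
                       config = mobo_config(),
                       exp_duration_h = 31 / 108) {
  init <- lhc_design(space, n_init, seed = derive_seed(seed, 10))
  init$solvent <- solvent
  rows <- list()
  for (k in seq_len(n_init)) {
    obs <- observe(init[k, ], params, seed = derive_seed(seed, 20 + k),
                   clock_h = k * exp_duration_h, space = space)
    rows[[k]] <- new_campaign_row(init[k, ], obs, "stage1", k,
                                  k * exp_duration_h, seed)
  }
  campaign <- do.call(rbind, rows)
  for (it in seq_len(n_iter)) {
    cand <- tsemo_step(campaign, space, solvent, config,
                       seed = derive_seed(seed, 100 + it))
    k <- n_init + it
    obs <- observe(cand, params, seed = derive_seed(seed, 20 + k),
                   clock_h = k * exp_duration_h, space = space)
    log_experiment("stage1", k, cand, obs)
    campaign <- rbind(campaign,
                      new_campaign_row(cand, obs, "stage1", k,
                                       k * exp_duration_h, seed))
  }
  attr(campaign, "stage") <- "stage1"
  attr(campaign, "seed") <- seed
  campaign
}
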