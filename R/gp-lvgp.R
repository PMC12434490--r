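#' Gaussian-process surrogate with latent solvent embedding
#'
#' `fit_gp` fits a GP regression model over the unit-cube continuous inputs
#' with ARD lengthscales, and — when the training data span more than one
#' solvent — a learned 2D latent coordinate per solvent entering a squared-
#' exponential kernel factor. The covariance is
#' `sf2 * Matern52_ARD(x, x') * exp(-||z_s - z_s'||^2) + sn2 * I`,
#' all hyperparameters (lengthscales, variances, latent coordinates)
#' maximising the log marginal likelihood by multi-restart L-BFGS-B with
#' analytic gradients. Targets are standardised internally; predictions are
#' returned on the original scale.
#'
#' Identifiability of the latent embedding is enforced during optimisation:
#' the first solvent level sits at the origin and the second level's second
#' coordinate is 0 (rotation/translation gauge fixing).
#'
#' @param cond conditions data.frame (training inputs).
#' @param y numeric target vector (one scalar per row of `cond`).
#' @param space design space (for unit-cube scaling).
#' @param config list from [gp_config()]: restarts, seed, bounds.
#' @return object of class `lvgp`.
#' @export
fit_gp <- function(cond, y, space = default_space(), config = gp_config()) {
  stopifnot(nrow(cond) == length(y))
  if (nrow(cond) < 3) stop("need at least 3 training points", call. = FALSE)
  X <- to_unit_cube(cond, space)
  solv <- cond$solvent
  levels_used <- space$categorical$levels[space$categorical$levels %in% solv]
  use_latent <- length(levels_used) >= 2 && !anyNA(solv)
  si <- if (use_latent) match(solv, levels_used) else rep(1L, nrow(X))

  ym <- mean(y)
  ysd <- stats::sd(y)
  degenerate <- !is.finite(ysd) || ysd < 1e-12
  if (degenerate) {
    warning("degenerate targets (zero variance); returning prior-level fit ",
            "with lengthscales at the upper bound")
    ysd <- 1
  }
  ys <- (y - ym) / ysd

  d <- ncol(X)
  nz <- if (use_latent) 2L * length(levels_used) - 3L else 0L
  lb <- c(rep(log(config$ell_bounds[1]), d), log(config$sf2_bounds[1]),
          log(config$sn2_bounds[1]), rep(-config$z_bound, nz))
  ub <- c(rep(log(config$ell_bounds[2]), d), log(config$sf2_bounds[2]),
          log(config$sn2_bounds[2]), rep(config$z_bound, nz))

  make_theta0 <- function(k) {
    if (k == 1) {
      c(rep(log(0.5), d), log(1), log(0.05), rep(0.01, nz))
    } else {
      c(stats::runif(d, log(0.05), log(5)),
        stats::runif(1, log(0.1), log(4)),
        stats::runif(1, log(1e-4), log(0.2)),
        stats::runif(nz, -1, 1))
    }
  }

  nll_fn <- function(th) lvgp_nll(th, X, si, ys, d, nz, grad = FALSE)$value
  gr_fn  <- function(th) lvgp_nll(th, X, si, ys, d, nz, grad = TRUE)$grad

  best <- NULL
  trace_init <- c()
  if (degenerate) {
    theta <- c(rep(log(config$ell_bounds[2]), d), log(config$sf2_bounds[1]),
               log(0.05), rep(0, nz))
    best <- list(par = theta, value = nll_fn(theta))
  } else {
    with_seed(config$seed, {
      for (k in seq_len(config$restarts)) {
        th0 <- pmin(ub, pmax(lb, make_theta0(k)))
        trace_init <- c(trace_init, nll_fn(th0))
        fit <- tryCatch(
          stats::optim(th0, nll_fn, gr_fn, method = "L-BFGS-B",
                       lower = lb, upper = ub,
                       control = list(maxit = config$maxit)),
          error = function(e) NULL)
        if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
          best <- fit
        }
      }
    })
    if (is.null(best)) stop("all GP restarts failed", call. = FALSE)
  }

  th <- best$par
  ell <- exp(th[1:d])
  sf2 <- exp(th[d + 1])
  sn2 <- exp(th[d + 2])
  Z <- theta_to_z(th, d, nz)
  K <- lvgp_kernel(X, si, ell, sf2, Z)
  kd <- safe_chol(K + diag(sn2, nrow(X)))
  alpha <- backsolve(kd$R, backsolve(kd$R, ys, transpose = TRUE))

  structure(
    list(X = X, si = si, cond = cond, levels = levels_used,
         use_latent = use_latent,
         y = y, ym = ym, ysd = ysd, ys = ys,
         ell = stats::setNames(ell, colnames(X)), sf2 = sf2, sn2 = sn2,
         Z = Z, R = kd$R, alpha = alpha, jitter = kd$jitter,
         nll = best$value, nll_restart_inits = trace_init,
         space = space, config = config, degenerate = degenerate),
    class = "lvgp")
}

#' GP fitting configuration
#'
#' @param restarts number of multi-start optimisations of the marginal
#'   likelihood (default 10).
#' @param seed integer seed for the restart draws.
#' @param maxit L-BFGS-B iteration cap per restart.
#' @param ell_bounds ARD lengthscale bounds on the unit cube.
#' @param sf2_bounds,sn2_bounds signal / noise variance bounds (standardised
#'   target scale).
#' @param z_bound box half-width for latent coordinates.
#' @return list of settings.
#' @export
gp_config <- function(restarts = 10, seed = 1, maxit = 200,
                      ell_bounds = c(0.01, 100),
                      sf2_bounds = c(1e-6, 100),
                      sn2_bounds = c(1e-8, 1),
                      z_bound = 3) {
  list(restarts = restarts, seed = seed, maxit = maxit,
       ell_bounds = ell_bounds, sf2_bounds = sf2_bounds,
       sn2_bounds = sn2_bounds, z_bound = z_bound)
}

# latent coordinate matrix (L x 2) from free parameters:
# z[1,] = (0,0); z[2,] = (th[1], 0); z[l >= 3,] = (th[2l-4], th[2l-3])
theta_to_z <- function(th, d, nz) {
  if (nz == 0) return(NULL)
  zf <- th[(d + 3):(d + 2 + nz)]
  L <- (nz + 3L) %/% 2L
  Z <- matrix(0, L, 2)
  Z[2, 1] <- zf[1]
  if (L >= 3) for (l in 3:L) Z[l, ] <- zf[(2 * l - 4):(2 * l - 3)]
  Z
}

# Matern 5/2 ARD x SE(latent) kernel matrix (no noise term).
lvgp_kernel <- function(X, si, ell, sf2, Z, X2 = NULL, si2 = NULL) {
  X2 <- X2 %||% X
  si2 <- si2 %||% si
  Xs <- sweep(X, 2, ell, "/")
  X2s <- sweep(X2, 2, ell, "/")
  D2 <- outer(rowSums(Xs^2), rowSums(X2s^2), "+") - 2 * tcrossprod(Xs, X2s)
  D2 <- pmax(D2, 0)
  R <- sqrt(D2)
  Kc <- (1 + sqrt(5) * R + (5 / 3) * D2) * exp(-sqrt(5) * R)
  if (!is.null(Z)) {
    E2 <- outer(rowSums(Z[si, , drop = FALSE]^2),
                rowSums(Z[si2, , drop = FALSE]^2), "+") -
      2 * tcrossprod(Z[si, , drop = FALSE], Z[si2, , drop = FALSE])
    Kc <- Kc * exp(-pmax(E2, 0))
  }
  sf2 * Kc
}

# Cholesky with escalating jitter; returns R (upper) and the jitter used.
safe_chol <- function(K) {
  jit <- 0
  for (j in c(0, 1e-10, 1e-8, 1e-6, 1e-4)) {
    R <- tryCatch(chol(K + diag(j, nrow(K))), error = function(e) NULL)
    if (!is.null(R)) return(list(R = R, jitter = j))
  }
  stop("covariance matrix not positive definite even with jitter",
       call. = FALSE)
}

# Negative log marginal likelihood and analytic gradient.
lvgp_nll <- function(th, X, si, ys, d, nz, grad = FALSE) {
  n <- nrow(X)
  ell <- exp(th[1:d])
  sf2 <- exp(th[d + 1])
  sn2 <- exp(th[d + 2])
  Z <- theta_to_z(th, d, nz)

  Xs <- sweep(X, 2, ell, "/")
  D2 <- outer(rowSums(Xs^2), rowSums(Xs^2), "+") - 2 * tcrossprod(Xs)
  D2 <- pmax(D2, 0)
  R <- sqrt(D2)
  E <- exp(-sqrt(5) * R)
  M <- (1 + sqrt(5) * R + (5 / 3) * D2) * E
  if (nz > 0) {
    Zi <- Z[si, , drop = FALSE]
    E2 <- outer(rowSums(Zi^2), rowSums(Zi^2), "+") - 2 * tcrossprod(Zi)
    E2 <- pmax(E2, 0)
    Elat <- exp(-E2)
  } else Elat <- 1
  Kf <- sf2 * M * Elat
  kd <- tryCatch(safe_chol(Kf + diag(sn2, n)), error = function(e) NULL)
  if (is.null(kd)) {
    return(list(value = 1e10, grad = rep(0, length(th))))
  }
  alpha <- backsolve(kd$R, backsolve(kd$R, ys, transpose = TRUE))
  nll <- 0.5 * sum(ys * alpha) + sum(log(diag(kd$R))) + 0.5 * n * log(2 * pi)
  if (!grad) return(list(value = nll))

  Kinv <- chol2inv(kd$R)
  W <- Kinv - tcrossprod(alpha)   # gradient = 0.5 * sum(W * dK)
  g <- numeric(length(th))
  # d/d log ell_d: dK = sf2*Elat * G * (-2 * Dd2 / 1) with
  # G = dM/dD2 = -(5/6)(1 + sqrt5 R) E, dD2/dlog ell_d = -2 (dx_d/ell_d)^2
  G <- -(5 / 6) * (1 + sqrt(5) * R) * E
  base <- sf2 * (if (nz > 0) Elat else 1) * G
  for (k in 1:d) {
    Dd2 <- outer(Xs[, k]^2, Xs[, k]^2, "+") - 2 * tcrossprod(Xs[, k])
    g[k] <- 0.5 * sum(W * (base * (-2 * pmax(Dd2, 0))))
  }
  g[d + 1] <- 0.5 * sum(W * Kf)                 # d/d log sf2
  g[d + 2] <- 0.5 * sum(diag(W)) * sn2          # d/d log sn2
  if (nz > 0) {
    L <- nrow(Z)
    # dK/dz[l,c] = Kf * (-dE2/dz[l,c]), dE2_ij = 2(z_i-z_j)_c (I(si=l)-I(sj=l))
    grad_z <- matrix(0, L, 2)
    for (l in 1:L) {
      ind <- as.numeric(si == l)
      for (cc in 1:2) {
        dz <- outer(Zi[, cc], Zi[, cc], "-")        # z_i - z_j
        dind <- outer(ind, ind, "-")                # I(si=l) - I(sj=l)
        dK <- Kf * (-2 * dz * dind)
        grad_z[l, cc] <- 0.5 * sum(W * dK)
      }
    }
    gz <- c(grad_z[2, 1])
    if (L >= 3) for (l in 3:L) gz <- c(gz, grad_z[l, 1], grad_z[l, 2])
    g[(d + 3):(d + 2 + nz)] <- gz
  }
  list(value = nll, grad = g)
}

#' Posterior prediction from a fitted latent-variable GP
#'
#' @param object an `lvgp` fit.
#' @param cond conditions data.frame of prediction points.
#' @param include_noise add the observation-noise variance to the predictive
#'   variance (default TRUE).
#' @param ... unused.
#' @return list with numeric vectors `mean` and `var` on the original target
#'   scale.
#' @export
predict.lvgp <- function(object, cond, include_noise = TRUE, ...) {
  X2 <- to_unit_cube(cond, object$space)
  if (object$use_latent) {
    if (anyNA(cond$solvent) || !all(cond$solvent %in% object$levels)) {
      stop("prediction requires solvent levels seen in training: ",
           paste(object$levels, collapse = ", "), call. = FALSE)
    }
    si2 <- match(cond$solvent, object$levels)
  } else si2 <- rep(1L, nrow(X2))
  Ks <- lvgp_kernel(object$X, object$si, object$ell, object$sf2, object$Z,
                    X2, si2)                      # n x n2
  mu <- drop(crossprod(Ks, object$alpha))
  V <- backsolve(object$R, Ks, transpose = TRUE)  # n x n2
  var_f <- pmax(object$sf2 - colSums(V^2), 0)
  if (include_noise) var_f <- var_f + object$sn2
  list(mean = object$ym + object$ysd * mu,
       var = object$ysd^2 * var_f)
}

#' @export
print.lvgp <- function(x, ...) {
  cat(sprintf("Latent-variable GP fit: n = %d, nll = %.3f\n",
              nrow(x$X), x$nll))
  cat("  ARD lengthscales (unit cube):\n")
  for (nm in names(x$ell)) cat(sprintf("    %-20s %.4g\n", nm, x$ell[[nm]]))
  cat(sprintf("  signal var %.4g, noise var %.4g (standardised scale), jitter %g\n",
              x$sf2, x$sn2, x$jitter))
  if (x$use_latent) {
    cat("  latent solvent coordinates:\n")
    for (l in seq_along(x$levels)) {
      cat(sprintf("    %-10s (% .4f, % .4f)\n", x$levels[l],
                  x$Z[l, 1], x$Z[l, 2]))
    }
  }
  invisible(x)
}

#' @export
summary.lvgp <- function(object, ...) {
  out <- list(
    n = nrow(object$X),
    nll = object$nll,
    lengthscales = object$ell,
    signal_var = object$sf2,
    noise_var = object$sn2,
    jitter = object$jitter,
    latent = if (object$use_latent) {
      data.frame(solvent = object$levels, z1 = object$Z[, 1],
                 z2 = object$Z[, 2], stringsAsFactors = FALSE)
    } else NULL)
  class(out) <- "summary.lvgp"
  out
}

#' @export
print.summary.lvgp <- function(x, ...) {
  cat(sprintf("lvgp: n = %d, nll = %.3f, sf2 = %.4g, sn2 = %.4g\n",
              x$n, x$nll, x$signal_var, x$noise_var))
  print(round(x$lengthscales, 4))
  if (!is.null(x$latent)) print(x$latent)
  invisible(x)
}

#' Serialise a fitted GP to JSON
#'
#' Writes hyperparameters and the per-solvent latent coordinate table.
#'
#' @param fit an `lvgp` object.
#' @param path output file path.
#' @export
gp_to_json <- function(fit, path) {
  obj <- list(
    lengthscales = as.list(fit$ell),
    signal_variance = fit$sf2,
    noise_variance = fit$sn2,
    target_mean = fit$ym, target_sd = fit$ysd,
    jitter = fit$jitter,
    latent = if (fit$use_latent) {
      stats::setNames(lapply(seq_along(fit$levels),
                             function(l) fit$Z[l, ]), fit$levels)
    } else NULL)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Leave-one-out cross-validation of a GP surrogate
#'
#' Refits nothing: with hyperparameters held at the full-data maximum-
#' likelihood values, the held-out posterior means follow from the standard
#' closed-form identities (`mu_-i = y_i - alpha_i / [K^-1]_ii`, the exact
#' rank-one downdate of the full fit). Reports per-point predictions and the
#' LOOCV R-squared `1 - sum((y - yhat)^2) / sum((y - ybar)^2)`.
#'
#' @inheritParams fit_gp
#' @return list with `predictions` data.frame (`y`, `yhat`, `se`) and `r2`.
#' @export
loocv <- function(cond, y, space = default_space(), config = gp_config()) {
  if (length(y) < 5) stop("LOOCV needs at least 5 points", call. = FALSE)
  if (stats::sd(y) < 1e-12) {
    stop("targets have zero variance; LOOCV R-squared is undefined",
         call. = FALSE)
  }
  fit <- fit_gp(cond, y, space, config)
  Kinv <- chol2inv(fit$R)
  dK <- diag(Kinv)
  mu_s <- fit$ys - fit$alpha / dK          # standardised held-out means
  var_s <- 1 / dK
  yhat <- fit$ym + fit$ysd * mu_s
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(predictions = data.frame(y = y, yhat = yhat,
                                se = fit$ysd * sqrt(pmax(var_s, 0))),
       r2 = r2, fit = fit)
}

#' @export
plot.lvgp <- function(x, variable = NULL, ...) {
  variable <- variable %||% names(which.min(x$ell))[1]
  pd <- partial_dependence(x, variable,
                           solvents = if (x$use_latent) x$levels else NULL)
  solvs <- unique(pd$solvent)
  graphics::matplot(
    matrix(pd$value, ncol = length(solvs)),
    matrix(pd$mean, ncol = length(solvs)),
    type = "l", lty = 1, xlab = variable, ylab = "posterior mean", ...)
  if (length(solvs) > 1 && !all(is.na(solvs))) {
    graphics::legend("topleft", legend = solvs, lty = 1,
                     col = seq_along(solvs), bty = "n")
  }
  invisible(x)
}
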