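#' Nondominated observations (max product, min impurity)
#'
#' A point dominates another when its product is >= and its impurity is <=,
#' with at least one strict. Returns the indices of points dominated by no
#' other, in order of increasing product.
#'
#' @param product,impurity numeric vectors of equal length.
#' @return integer indices of the Pareto front, ordered by increasing product.
#' @export
nondominated <- function(product, impurity) {
  stopifnot(length(product) == length(impurity), length(product) >= 1)
  n <- length(product)
  # sweep: sort by product desc (impurity asc as tie-break); a point is on the
  # front iff its impurity is strictly below every better-product impurity
  ord <- order(-product, impurity)
  best_i <- Inf
  keep <- logical(n)
  for (k in ord) {
    if (impurity[k] < best_i) {
      keep[k] <- TRUE
      best_i <- impurity[k]
    }
  }
  # duplicated coordinates: dominance needs one strict inequality, so every
  # copy of a retained point is also nondominated

  front_pts <- unique(cbind(product, impurity)[keep, , drop = FALSE])
  dup <- which(!keep)
  for (k in dup) {
    if (any(front_pts[, 1] == product[k] & front_pts[, 2] == impurity[k])) {
      keep[k] <- TRUE
    }
  }
  idx <- which(keep)
  idx[order(product[idx], impurity[idx])]
}

#' Pareto-front analysis of a campaign
#'
#' Extracts the nondominated front (ordered by increasing product), the
#' percentage-change table between consecutive front points, and the
#' diminishing-returns preferred point.
#'
#' @param product,impurity numeric objective vectors (normalised peak areas).
#' @return object of class `pareto_analysis` with elements `front_idx`,
#'   `front` (data.frame), `steps` (percentage-change table) and
#'   `preferred_idx` (index into the ordered front).
#' @export
pareto_analysis <- function(product, impurity) {
  idx <- nondominated(product, impurity)
  front <- data.frame(index = idx, product = product[idx],
                      impurity = impurity[idx])
  out <- structure(list(front_idx = idx, front = front),
                   class = "pareto_analysis")
  out$steps <- percentage_changes(front)
  out$preferred_idx <- diminishing_returns(out)
  out
}

percentage_changes <- function(front) {
  k <- nrow(front)
  if (k < 2) {
    return(data.frame(from = integer(0), to = integer(0),
                      dp_pct = numeric(0), di_pct = numeric(0)))
  }
  i1 <- seq_len(k - 1)
  data.frame(
    from = i1, to = i1 + 1,
    dp_pct = 100 * (front$product[i1 + 1] - front$product[i1]) /
      front$product[i1],
    di_pct = 100 * (front$impurity[i1 + 1] - front$impurity[i1]) /
      ifelse(front$impurity[i1] > 0, front$impurity[i1], NA_real_))
}

#' Diminishing-returns preferred point on an ordered Pareto front
#'
#' Walks the front from the lowest-product end and accepts each step while
#' the percentage gain in product is at least the percentage increase in
#' impurity (ties accept); the first rejected step stops the walk and the
#' current point is preferred. A zero impurity on the front switches that
#' step to an absolute-change comparison, with a warning.
#'
#' @param analysis a `pareto_analysis` (or anything with a `front`
#'   data.frame of `product`, `impurity` ordered by increasing product).
#' @return integer index of the preferred point within the ordered front.
#' @export
diminishing_returns <- function(analysis) {
  front <- analysis$front
  stopifnot(all(front$product >= 0))
  k <- nrow(front)
  if (k == 1) return(1L)
  cur <- 1L
  while (cur < k) {
    dp <- front$product[cur + 1] - front$product[cur]
    di <- front$impurity[cur + 1] - front$impurity[cur]
    if (front$impurity[cur] > 0 && front$product[cur] > 0) {
      dp_rel <- dp / front$product[cur]
      di_rel <- di / front$impurity[cur]
    } else {
      # a zero on the front makes a percentage change undefined
      warning("zero objective value on the front; using absolute changes ",
              "for this step")
      dp_rel <- dp
      di_rel <- di
    }
    if (dp_rel >= di_rel) cur <- cur + 1L else break
  }
  cur
}

#' Scalarisation weights
#'
#' Coefficient pair for the weighted objective
#' `f = w_amide * product + w_enamine * impurity` (lower is better):
#' `w_amide <= -0.05` rewards product, `w_enamine >= 0.05` penalises
#' impurity. Weights produced by [infer_weights()] are l1-normalised
#' (`|w_amide| + w_enamine = 1`); externally supplied pairs (such as a
#' reported coefficient pair) need only satisfy the sign constraints.
#'
#' @param w_amide nonpositive coefficient on product.
#' @param w_enamine nonnegative coefficient on impurity.
#' @param epsilon optional achieved LP margin (see [infer_weights()]).
#' @return object of class `scalar_weights`.
#' @export
scalar_weights <- function(w_amide, w_enamine, epsilon = NA_real_) {
  stopifnot(is.numeric(w_amide), is.numeric(w_enamine))
  if (w_amide > -0.05 || w_enamine < 0.05) {
    stop("weights must keep both objectives active: w_amide <= -0.05 and ",
         "w_enamine >= 0.05", call. = FALSE)
  }
  structure(list(w_amide = w_amide, w_enamine = w_enamine, epsilon = epsilon),
            class = "scalar_weights")
}

#' @export
print.scalar_weights <- function(x, ...) {
  cat(sprintf("scalarisation weights: f = %.4f * product + %.4f * impurity",
              x$w_amide, x$w_enamine))
  if (is.finite(x$epsilon)) cat(sprintf("  (LP margin %.4g)", x$epsilon))
  cat("\n")
  invisible(x)
}

#' Infer scalarisation weights by linear programming
#'
#' Reverse-engineers the weighted objective from the preferred front point:
#' maximise the margin `eps` subject to
#' `f(j) >= f(preferred) + eps` for every other front point `j`,
#' `w_amide <= -0.05`, `w_enamine >= 0.05` and `|w_amide| + w_enamine = 1`.
#' Under the l1 normalisation the LP has a single free variable, so it is
#' solved exactly by enumerating the vertices of the 1D piecewise-linear
#' program (interval endpoints and pairwise constraint intersections).
#' Errors when no strict linear scalariser exists (the preferred point lies
#' on a non-convex stretch of the front).
#'
#' @param analysis a `pareto_analysis`.
#' @param preferred_idx index into the ordered front (default: the stored
#'   diminishing-returns point).
#' @param eps_floor minimum admissible margin.
#' @return a `scalar_weights` object with the achieved margin.
#' @export
infer_weights <- function(analysis, preferred_idx = analysis$preferred_idx,
                          eps_floor = 1e-6) {
  front <- analysis$front
  if (nrow(front) < 2) stop("need at least 2 front points", call. = FALSE)
  stopifnot(preferred_idx >= 1, preferred_idx <= nrow(front))
  p_star <- front$product[preferred_idx]
  i_star <- front$impurity[preferred_idx]
  dp <- front$product[-preferred_idx] - p_star
  di <- front$impurity[-preferred_idx] - i_star
  # w_amide = w - 1, w_enamine = w, w in [0.05, 0.95]:
  # eps_j(w) = (w - 1) dp_j + w di_j = w (dp_j + di_j) - dp_j
  slope <- dp + di
  icpt <- -dp
  lo <- 0.05; hi <- 0.95
  cand <- c(lo, hi)
  nj <- length(slope)
  if (nj >= 2) {
    for (a in 1:(nj - 1)) for (b in (a + 1):nj) {
      ds <- slope[a] - slope[b]
      if (abs(ds) > 1e-14) {
        w <- (icpt[b] - icpt[a]) / ds
        if (w > lo && w < hi) cand <- c(cand, w)
      }
    }
  }
  env_min <- function(w) min(slope * w + icpt)
  vals <- vapply(cand, env_min, numeric(1))
  k <- which.max(vals)
  eps <- vals[k]
  if (eps <= eps_floor) {
    stop("no strict linear scalariser prefers this point: the preferred ",
         "solution lies on a non-convex stretch of the Pareto front ",
         sprintf("(best margin %.3g)", eps), call. = FALSE)
  }
  w <- cand[k]
  scalar_weights(w_amide = w - 1, w_enamine = w, epsilon = eps)
}

#' Scalarised objective
#'
#' `f = w_amide * product + w_enamine * impurity`; lower is better. `w` may
#' be a [scalar_weights()] object or a numeric pair
#' `c(w_amide, w_enamine)` (e.g. the reported coefficients
#' `c(-0.2667, 0.773)`).
#'
#' @param product,impurity numeric vectors (normalised peak areas).
#' @param w weights (see above).
#' @return numeric vector of objective values.
#' @export
scalarize <- function(product, impurity, w) {
  if (inherits(w, "scalar_weights")) {
    wa <- w$w_amide; we <- w$w_enamine
  } else {
    stopifnot(is.numeric(w), length(w) == 2)
    wa <- w[1]; we <- w[2]
    if (wa > 0 || we < 0) {
      stop("expected w = c(w_amide <= 0, w_enamine >= 0)", call. = FALSE)
    }
  }
  wa * product + we * impurity
}
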