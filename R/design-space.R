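#' Design space for the flow amidation campaign
#'
#' A design space couples box bounds on the continuous reactor settings with
#' the list of candidate solvents (the categorical variable). The default
#' space is the operating window of the packed-bed enzyme reactor:
#' 200--350 mM substrate, 1--4 amine equivalents, 1--10 min residence time,
#' 25--60 degC, with solvents MeCN, 2-MeTHF, anisole and dioxane.
#'
#' @param continuous data.frame with columns `name`, `lower`, `upper`, `unit`.
#' @param solvents character vector of categorical levels (unique, non-empty).
#' @return An object of class `design_space` with elements `continuous`
#'   (data.frame), `categorical` (list with `name` and `levels`) and
#'   `n_continuous`.
#' @export
design_space <- function(continuous, solvents) {
  stopifnot(is.data.frame(continuous),
            all(c("name", "lower", "upper", "unit") %in% names(continuous)))
  if (any(continuous$lower >= continuous$upper)) {
    stop("each continuous variable needs lower < upper", call. = FALSE)
  }
  solvents <- as.character(solvents)
  if (length(solvents) < 1L || anyDuplicated(solvents)) {
    stop("solvent levels must be non-empty and unique", call. = FALSE)
  }
  structure(
    list(continuous = continuous,
         categorical = list(name = "solvent", levels = solvents),
         n_continuous = nrow(continuous)),
    class = "design_space")
}

#' @rdname design_space
#' @export
default_space <- function() {
  design_space(
    continuous = data.frame(
      name  = c("concentration_mM", "equivalents", "residence_time_min",
                "temperature_C"),
      lower = c(200, 1, 1, 25),
      upper = c(350, 4, 10, 60),
      unit  = c("mM", "", "min", "degC"),
      stringsAsFactors = FALSE),
    solvents = c("MeCN", "2-MeTHF", "anisole", "dioxane"))
}

#' @export
print.design_space <- function(x, ...) {
  cat("Design space:", x$n_continuous, "continuous variables +",
      x$categorical$name, "\n")
  for (i in seq_len(nrow(x$continuous))) {
    r <- x$continuous[i, ]
    cat(sprintf("  %-20s [%g, %g] %s\n", r$name, r$lower, r$upper, r$unit))
  }
  cat("  solvent levels:", paste(x$categorical$levels, collapse = ", "), "\n")
  invisible(x)
}

cont_names <- function(space) space$continuous$name

#' Construct a table of reaction conditions
#'
#' @param concentration_mM,equivalents,residence_time_min,temperature_C
#'   numeric vectors (recycled to a common length).
#' @param solvent character vector of solvent names, or `NA` when the
#'   categorical variable is not yet assigned.
#' @param space design space used for bound checking.
#' @return data.frame with one row per condition.
#' @export
conditions <- function(concentration_mM, equivalents, residence_time_min,
                       temperature_C, solvent = NA_character_,
                       space = default_space()) {
  out <- data.frame(concentration_mM = concentration_mM,
                    equivalents = equivalents,
                    residence_time_min = residence_time_min,
                    temperature_C = temperature_C,
                    solvent = as.character(solvent),
                    stringsAsFactors = FALSE)
  check_conditions(out, space)
  out
}

check_conditions <- function(cond, space, require_solvent = FALSE) {
  for (i in seq_len(nrow(space$continuous))) {
    r <- space$continuous[i, ]
    v <- cond[[r$name]]
    if (is.null(v) || any(!is.finite(v))) {
      stop(sprintf("conditions lack finite values for '%s'", r$name),
           call. = FALSE)
    }
    tol <- 1e-9 * (r$upper - r$lower)
    if (any(v < r$lower - tol | v > r$upper + tol)) {
      stop(sprintf("'%s' outside bounds [%g, %g]", r$name, r$lower, r$upper),
           call. = FALSE)
    }
  }
  sv <- cond$solvent
  bad <- !is.na(sv) & !(sv %in% space$categorical$levels)
  if (any(bad)) {
    stop(sprintf("unknown solvent level(s): %s",
                 paste(unique(sv[bad]), collapse = ", ")), call. = FALSE)
  }
  if (require_solvent && any(is.na(sv))) {
    stop("solvent must be assigned for every condition", call. = FALSE)
  }
  invisible(cond)
}

#' Latin-hypercube sizing rule
#'
#' Initial design size as a function of the number of continuous variables,
#' using the 2n + 1 rule (n = 4 gives the 9-point initial design).
#'
#' @param n_continuous number of continuous variables (>= 1).
#' @return integer design size 2n + 1.
#' @export
lhc_size_rule <- function(n_continuous) {
  stopifnot_scalar_count(n_continuous, "n_continuous")
  if (n_continuous < 1) stop("n_continuous must be >= 1", call. = FALSE)
  as.integer(2L * n_continuous + 1L)
}

#' Latin-hypercube initial designs
#'
#' `lhc_design` draws a seeded random Latin hypercube over the continuous
#' variables (one point per equal-width bin in every dimension, uniform within
#' the bin); the solvent column is left unassigned. `stratified_lhc`
#' additionally assigns solvents so that each level receives exactly
#' `n_points / n_levels` rows, by a seeded block permutation.
#'
#' @param space a `design_space`.
#' @param n_points number of design points.
#' @param seed integer seed; the same seed reproduces the same design.
#' @return data.frame of conditions (see [conditions()]).
#' @export
lhc_design <- function(space, n_points, seed = 1L) {
  stopifnot_scalar_count(n_points, "n_points")
  if (n_points < 1) stop("n_points must be >= 1", call. = FALSE)
  u <- with_seed(seed, lhs::randomLHS(n_points, space$n_continuous))
  from_unit_cube(u, space)
}

#' @rdname lhc_design
#' @export
stratified_lhc <- function(space, n_points, seed = 1L) {
  stopifnot_scalar_count(n_points, "n_points")
  levels <- space$categorical$levels
  L <- length(levels)
  if (n_points %% L != 0L) {
    stop(sprintf(
      "n_points = %d is not divisible by the %d solvent levels (remainder %d)",
      n_points, L, n_points %% L), call. = FALSE)
  }
  cond <- lhc_design(space, n_points, seed = seed)
  assign_order <- with_seed(derive_seed(seed, 7L), sample.int(n_points))
  cond$solvent[assign_order] <- rep(levels, each = n_points %/% L)
  check_conditions(cond, space, require_solvent = TRUE)
  cond
}

#' Affine scaling between physical conditions and the unit cube
#'
#' All GP fitting and acquisition optimisation happens on `[0,1]^n`; reporting
#' is in physical units. `to_unit_cube` maps in-bounds conditions to the cube,
#' `from_unit_cube` inverts the map (and carries no solvent assignment unless
#' given one).
#'
#' @param cond data.frame of conditions.
#' @param u numeric matrix with values in `[0,1]`, one column per continuous
#'   variable.
#' @param space a `design_space`.
#' @param solvent optional character vector assigned to the output of
#'   `from_unit_cube`.
#' @return `to_unit_cube`: numeric matrix; `from_unit_cube`: conditions
#'   data.frame.
#' @export
to_unit_cube <- function(cond, space) {
  check_conditions(cond, space)
  u <- sapply(seq_len(nrow(space$continuous)), function(i) {
    r <- space$continuous[i, ]
    (cond[[r$name]] - r$lower) / (r$upper - r$lower)
  })
  u <- matrix(u, nrow = nrow(cond), ncol = space$n_continuous)
  colnames(u) <- cont_names(space)
  u
}

#' @rdname to_unit_cube
#' @export
from_unit_cube <- function(u, space, solvent = NA_character_) {
  u <- matrix(u, ncol = space$n_continuous)
  if (any(u < -1e-12 | u > 1 + 1e-12)) {
    stop("unit-cube coordinates must lie in [0, 1]", call. = FALSE)
  }
  u <- matrix(pmin(pmax(u, 0), 1), ncol = space$n_continuous)
  vals <- lapply(seq_len(nrow(space$continuous)), function(i) {
    r <- space$continuous[i, ]
    r$lower + u[, i] * (r$upper - r$lower)
  })
  names(vals) <- cont_names(space)
  out <- as.data.frame(vals, stringsAsFactors = FALSE)
  out$solvent <- as.character(solvent)
  check_conditions(out, space)
  out
}
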