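# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All user-facing randomness goes through this
# so that a single integer seed makes any operation reproducible.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

logistic <- function(x) 1 / (1 + exp(-x))

clip01 <- function(x) pmin(1, pmax(0, x))

# Deterministic child seeds derived from one master seed (kept below 2^31).
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# INFO-level campaign logging, enabled via options(flowbo.log = TRUE)
# (the command-line wrapper switches it on)
log_experiment <- function(stage, k, cond, obs) {
  if (!isTRUE(getOption("flowbo.log"))) return(invisible())
  message(sprintf(
    "INFO %s experiment %d: %.1f mM, %.2f eq, %.2f min, %.1f C, %s -> product %.4f impurity %.4f",
    stage, k, cond$concentration_mM, cond$equivalents,
    cond$residence_time_min, cond$temperature_C, cond$solvent,
    obs$product_norm, obs$impurity_norm))
}

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x)) {
    stop(sprintf("`%s` must be a single whole number", name), call. = FALSE)
  }
}
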