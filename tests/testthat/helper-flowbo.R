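# Shared fixtures, built in code. The calibrated simulator is expensive
# (~half a minute), so it is computed once per test run and cached.

.flowbo_cache <- new.env(parent = emptyenv())

calibrated_params <- function() {
  if (is.null(.flowbo_cache$params)) {
    .flowbo_cache$params <- calibrate(seed = 1)
  }
  .flowbo_cache$params
}

noiseless_params <- function() {
  p <- calibrated_params()
  p$sigma <- 0
  p
}

# small campaign data.frame from conditions + simulator observations
make_campaign <- function(cond, params, seed = 1, stage = "stage2",
                          weights = NULL) {
  obs <- observe(cond, params, seed = seed)
  f <- if (is.null(weights)) NA_real_ else
    scalarize(obs$product_norm, obs$impurity_norm, weights)
  flowbo:::new_campaign_row(cond, obs, stage, seq_len(nrow(cond)),
                            clock_h = seq_len(nrow(cond)) * 0.3,
                            seed = seed, objective_f = f)
}

# brute-force O(n^2) dominance oracle (max product, min impurity)
nondominated_oracle <- function(p, i) {
  which(vapply(seq_along(p), function(k) {
    !any(p >= p[k] & i <= i[k] & (p > p[k] | i < i[k]))
  }, logical(1)))
}

# dense-grid oracle of the true MeCN front hypervolume (minimisation space)
stage1_oracle_hv <- function(params, ref = c(0, 0.2)) {
  g <- design_grid(default_space(), "MeCN")
  y <- true_response(g, params)
  hypervolume(cbind(-y$product_norm, y$impurity_norm), ref)
}

# dense-grid oracle of the scalarised optimum across all solvents
stage2_oracle_f <- function(params, w) {
  sp <- default_space()
  min(vapply(sp$categorical$levels, function(s) {
    g <- design_grid(sp, s)
    y <- true_response(g, params, sp)
    min(scalarize(y$product_norm, y$impurity_norm, w))
  }, numeric(1)))
}
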