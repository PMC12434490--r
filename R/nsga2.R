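# Compact real-coded NSGA-II used as the inner solver on the sampled
# surrogates (cheap objective draws, box bounds on the unit cube).
# Standard components: fast nondominated ranking, crowding distance, binary
# tournament, SBX crossover, polynomial mutation.

nds_ranks <- function(F) {
  # F: n x m objective matrix (minimisation); returns integer ranks (1 = best)
  n <- nrow(F)
  ranks <- integer(n)
  remaining <- rep(TRUE, n)
  r <- 0L
  while (any(remaining)) {
    r <- r + 1L
    idx <- which(remaining)
    Fi <- F[idx, , drop = FALSE]
    nondom <- vapply(seq_along(idx), function(k) {
      le <- Fi[, 1] <= Fi[k, 1] & Fi[, 2] <= Fi[k, 2]
      lt <- Fi[, 1] < Fi[k, 1] | Fi[, 2] < Fi[k, 2]
      !any(le & lt)
    }, logical(1))
    ranks[idx[nondom]] <- r
    remaining[idx[nondom]] <- FALSE
  }
  ranks
}

crowding <- function(F) {
  n <- nrow(F)
  cd <- numeric(n)
  for (j in seq_len(ncol(F))) {
    o <- order(F[, j])
    rng <- F[o[n], j] - F[o[1], j]
    cd[o[c(1, n)]] <- Inf
    if (n > 2 && rng > 0) {
      cd[o[2:(n - 1)]] <- cd[o[2:(n - 1)]] +
        (F[o[3:n], j] - F[o[1:(n - 2)], j]) / rng
    }
  }
  cd
}

sbx_crossover <- function(p1, p2, eta = 15, pc = 0.9) {
  d <- length(p1)
  if (stats::runif(1) > pc) return(rbind(p1, p2))
  u <- stats::runif(d)
  beta <- ifelse(u <= 0.5, (2 * u)^(1 / (eta + 1)),
                 (1 / (2 * (1 - u)))^(1 / (eta + 1)))
  c1 <- 0.5 * ((1 + beta) * p1 + (1 - beta) * p2)
  c2 <- 0.5 * ((1 - beta) * p1 + (1 + beta) * p2)
  rbind(pmin(pmax(c1, 0), 1), pmin(pmax(c2, 0), 1))
}

poly_mutation <- function(x, eta = 20, pm = NULL) {
  d <- length(x)
  pm <- pm %||% (1 / d)
  hit <- stats::runif(d) < pm
  if (!any(hit)) return(x)
  u <- stats::runif(sum(hit))
  delta <- ifelse(u < 0.5, (2 * u)^(1 / (eta + 1)) - 1,
                  1 - (2 * (1 - u))^(1 / (eta + 1)))
  x[hit] <- pmin(pmax(x[hit] + delta, 0), 1)
  x
}

# fn: function(matrix n x d in [0,1]^d) -> n x 2 objective matrix (minimise)
nsga2_minimize <- function(fn, d, pop = 100, generations = 100, seed = NULL) {
  with_seed(seed, {
    P <- matrix(stats::runif(pop * d), pop, d)
    FP <- fn(P)
    for (g in seq_len(generations)) {
      ranks <- nds_ranks(FP)
      cd <- crowding(FP)
      # binary tournament on (rank, crowding)
      pick <- function() {
        a <- sample.int(pop, 2)
        if (ranks[a[1]] < ranks[a[2]] ||
            (ranks[a[1]] == ranks[a[2]] && cd[a[1]] > cd[a[2]])) a[1] else a[2]
      }
      Q <- matrix(0, pop, d)
      i <- 1L
      while (i <= pop) {
        ch <- sbx_crossover(P[pick(), ], P[pick(), ])
        ch[1, ] <- poly_mutation(ch[1, ])
        Q[i, ] <- ch[1, ]
        if (i + 1 <= pop) {
          ch[2, ] <- poly_mutation(ch[2, ])
          Q[i + 1, ] <- ch[2, ]
        }
        i <- i + 2L
      }
      FQ <- fn(Q)
      allP <- rbind(P, Q)
      allF <- rbind(FP, FQ)
      r <- nds_ranks(allF)
      sel <- integer(0)
      for (rr in sort(unique(r))) {
        idx <- which(r == rr)
        if (length(sel) + length(idx) <= pop) {
          sel <- c(sel, idx)
        } else {
          cdr <- crowding(allF[idx, , drop = FALSE])
          sel <- c(sel, idx[order(-cdr)][seq_len(pop - length(sel))])
          break
        }
      }
      P <- allP[sel, , drop = FALSE]
      FP <- allF[sel, , drop = FALSE]
    }
    on_front <- nds_ranks(FP) == 1L
    list(X = P[on_front, , drop = FALSE], F = FP[on_front, , drop = FALSE])
  })
}
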