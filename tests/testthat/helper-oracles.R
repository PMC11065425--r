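# Independent brute-force oracles used to validate the fast implementations.

# Exhaustive tick-path oracle for the photon HMM: enumerates the hidden state
# at every clock tick from the first to the last photon of one burst.
# Returns the total likelihood, per-photon posteriors and exact expected
# per-tick transition counts. Only feasible for a handful of ticks.
oracle_tick_enum <- function(pi, A, B, ticks, obs) {
  K <- length(pi)
  pos <- ticks - ticks[1] + 1
  n_ticks <- max(pos)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n_ticks)))
  probs <- apply(paths, 1, function(s) {
    p <- pi[s[1]]
    if (n_ticks > 1) {
      for (t in 2:n_ticks) p <- p * A[s[t - 1], s[t]]
    }
    for (k in seq_along(obs)) p <- p * B[s[pos[k]], obs[k] + 1]
    p
  })
  tot <- sum(probs)
  w <- probs / tot
  post <- t(sapply(seq_along(obs), function(k) {
    sapply(seq_len(K), function(i) sum(w[paths[, pos[k]] == i]))
  }))
  xi <- matrix(0, K, K)
  if (n_ticks > 1) {
    for (r in seq_len(nrow(paths))) {
      s <- paths[r, ]
      for (t in 2:n_ticks) xi[s[t - 1], s[t]] <- xi[s[t - 1], s[t]] + w[r]
    }
  }
  gam <- matrix(0, K, 3)
  for (k in seq_along(obs)) {
    for (i in seq_len(K)) {
      gam[i, obs[k] + 1] <- gam[i, obs[k] + 1] + sum(w[paths[, pos[k]] == i])
    }
  }
  list(loglik = log(tot), post = post, xi = xi, gamma_emit = gam,
       pi_post = sapply(seq_len(K), function(i) sum(w[paths[, 1] == i])),
       argmax_tick_path = paths[which.max(probs), pos])
}

# Exhaustive Viterbi oracle at photon times: enumerates state assignments at
# the photon times only, weighting gaps with the exact A^dt operator.
oracle_skeleton_viterbi <- function(pi, A, B, ticks, obs) {
  K <- length(pi)
  n <- length(obs)
  combos <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  pows <- lapply(diff(ticks), function(d) {
    P <- diag(K)
    for (i in seq_len(d)) P <- P %*% A
    P
  })
  probs <- apply(combos, 1, function(s) {
    p <- pi[s[1]] * B[s[1], obs[1] + 1]
    if (n > 1) {
      for (k in 2:n) p <- p * pows[[k - 1]][s[k - 1], s[k]] * B[s[k], obs[k] + 1]
    }
    p
  })
  list(path = combos[which.max(probs), ], logprob = log(max(probs)))
}

# Brute-force all-photon burst search: literal loop over every m-photon
# window, then union of overlapping qualifying windows.
oracle_apbs <- function(stream, bg, m = 10, F = 6) {
  n <- nrow(stream)
  if (n < m) return(list())
  ts <- stream$timestamp
  cp <- clock_period(stream)
  qual <- logical(n - m + 1)
  for (i in seq_len(n - m + 1)) {
    span <- (ts[i + m - 1] - ts[i]) * cp
    rate <- if (span > 0) m / span else Inf
    tsec <- ts[i] * cp
    w <- max(which(bg$t_start_s <= tsec))
    w <- min(w, nrow(bg))
    qual[i] <- rate >= F * bg$rate_total[w]
  }
  bursts <- list()
  cur <- NULL
  for (i in which(qual)) {
    if (is.null(cur)) {
      cur <- c(i, i + m - 1)
    } else if (i <= cur[2]) {
      cur[2] <- i + m - 1
    } else {
      bursts[[length(bursts) + 1]] <- cur
      cur <- c(i, i + m - 1)
    }
  }
  if (!is.null(cur)) bursts[[length(bursts) + 1]] <- cur
  bursts
}

# Convenience: burst photon tibble from raw vectors.
make_burst_photons <- function(burst_id, timestamp, stream,
                               clock_period = 25e-9) {
  out <- tibble::tibble(burst_id = burst_id, timestamp = timestamp,
                        stream = as.integer(stream))
  attr(out, "clock_period") <- clock_period
  class(out) <- c("burst_photons", class(out))
  out
}

# Random small row-stochastic matrix biased toward a dominant diagonal.
random_stochastic <- function(K, diag_weight = 20) {
  A <- matrix(runif(K * K), K, K) + diag_weight * diag(K)
  A / rowSums(A)
}
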