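## Independent oracles used across the suite. These never call the
## package's analytic paths for the quantity they check.

## Vectorized Gillespie simulation of many two-state CTMC trajectories over
## a window of length T; returns the fraction of time spent in state 1 and
## whether the trajectory switched at least once.
gillespieOccupancy2 <- function(k12, k21, T, n, seed = 1) {
  set.seed(seed)
  # rate out of state 1 is k21 (to state 2); out of state 2 is k12
  xd1 <- k12 / (k12 + k21)
  state <- ifelse(runif(n) < xd1, 1L, 2L)
  t1 <- numeric(n)        # accumulated time in state 1
  tl <- rep(0, n)         # elapsed time
  jumps <- integer(n)
  alive <- rep(TRUE, n)
  while (any(alive)) {
    i <- which(alive)
    rate <- ifelse(state[i] == 1L, k21, k12)
    w <- rexp(length(i), rate)
    stay <- pmin(w, T - tl[i])
    in1 <- state[i] == 1L
    t1[i][in1] <- t1[i][in1] + stay[in1]
    tl[i] <- tl[i] + stay
    switched <- w < (T - (tl[i] - stay))
    jumps[i][switched] <- jumps[i][switched] + 1L
    state[i][switched] <- 3L - state[i][switched]
    alive[i] <- switched & tl[i] < T
  }
  list(x1 = t1 / T, switched = jumps > 0)
}

## Long-run CTMC occupancy by direct jump-chain simulation for an arbitrary
## rate matrix K (K[i,j] = rate j -> i).
gillespieEquilibrium <- function(K, nJumps = 1e6, seed = 1) {
  set.seed(seed)
  n <- nrow(K)
  rateOut <- -diag(K)
  P <- K / rep(rateOut, each = n)  # jump probabilities, column-stochastic
  diag(P) <- 0
  cumP <- apply(P, 2, cumsum)
  states <- integer(nJumps)
  s <- 1L
  u <- runif(nJumps)
  for (i in seq_len(nJumps)) {
    states[i] <- s
    s <- which(u[i] <= cumP[, s])[1]
  }
  hold <- rexp(nJumps, rateOut[states])
  tapply(hold, factor(states, levels = seq_len(n)), sum,
         default = 0) / sum(hold)
}

## Random 3-state network obeying detailed balance: draw equilibrium
## fractions and symmetric fluxes, then k_ij = f_ij / x_j.
randomDetailedBalanceNetwork <- function(n = 3) {
  x <- runif(n, 0.1, 1); x <- x / sum(x)
  f <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    f[i, j] <- f[j, i] <- runif(1, 0.2, 5)
  rates <- do.call(rbind, lapply(seq_len(n), function(j) {
    do.call(rbind, lapply(setdiff(seq_len(n), j), function(i)
      data.frame(from = j, to = i, rate = f[i, j] / x[j])))
  }))
  kineticNetwork(n, rates)
}
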