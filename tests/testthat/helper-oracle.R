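# Independent direct-method SSA (Gillespie first-reaction style sampling of
# the total propensity) used purely as a cross-check oracle for the Mod-NRM
# engine.  Deliberately written against base R's RNG and the plain
# reaction_network fields, sharing no code path with the engine.
ssa_direct <- function(network, t_end, seed, initial = network$initial_state) {
  set.seed(seed)
  pop <- stats::setNames(numeric(length(network$species)), network$species)
  pop[names(initial)] <- initial
  t <- 0
  times <- numeric(0); states <- list()
  repeat {
    a <- vapply(network$reactions, propensity, numeric(1),
                populations = pop, conversion = network$conversion)
    a0 <- sum(a)
    if (a0 == 0) break
    dt <- stats::rexp(1, a0)
    if (t + dt > t_end) break
    t <- t + dt
    j <- sample.int(length(a), 1, prob = a)
    pop <- apply_reaction(pop, network$reactions[[j]])
    times <- c(times, t); states[[length(states) + 1]] <- pop
  }
  list(times = times, states = do.call(rbind, states), final = pop)
}

# time-average of one species over an event-driven path (piecewise constant;
# the value on [times[i], times[i+1]) is states[i, ])
ssa_time_average <- function(oracle, species, t_end, burn = 0, initial = 0) {
  tt <- c(0, oracle$times, t_end)
  vv <- c(initial, oracle$states[, species], NA)
  lo <- pmax(tt[-length(tt)], burn)
  hi <- pmin(tt[-1], t_end)
  w <- pmax(hi - lo, 0)
  sum(vv[-length(vv)] * w) / sum(w)
}

# mean copy number of species over a sampled trajectory matrix, after burn-in
sample_mean_after <- function(samples, species, burn) {
  mean(samples[samples[, "time"] > burn, species])
}
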