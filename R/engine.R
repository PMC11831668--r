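#' Initialize a Modified Next Reaction Method engine
#'
#' Sets every internal clock `T_j = 0`, draws each channel's first internal
#' firing time `P_j` as a unit exponential from that channel's random stream,
#' and computes the initial propensities.  Slow channels get one independent
#' stream each; all fast channels share a single stream.  Streams are
#' xorshift64* generators with explicitly serialisable state, seeded from
#' `master_seed` and a stable per-channel key (0 for the shared fast stream,
#' the channel id for slow channels), so snapshot/restore and
#' common-random-number replication are exactly reproducible.
#'
#' @param network A [reaction_network()].
#' @param initial_populations Named vector of copy numbers; defaults to the
#'   network's initial state.  Must satisfy the declared conservation laws.
#' @param master_seed Integer master seed.
#' @return An object of class `kmc_engine`.
#' @export
initialize_engine <- function(network, initial_populations = network$initial_state,
                              master_seed = 1) {
  pop <- stats::setNames(numeric(length(network$species)), network$species)
  pop[names(initial_populations)] <- initial_populations
  if (any(pop < 0) || any(pop != round(pop)))
    stop("populations must be nonnegative integers")
  for (cl in network$conservation)
    if (sum(pop[cl$species]) != cl$total)
      stop("initial populations violate conservation law ",
           paste(cl$species, collapse = "+"), " = ", cl$total)
  nchan <- length(network$reactions)
  slow_sorted <- sort(network$slow)
  stream_of <- integer(nchan)
  stream_of[network$fast] <- 1L
  stream_of[slow_sorted] <- 1L + seq_along(slow_sorted)
  keys <- c(0L, slow_sorted)
  streams <- cpp_make_streams(as.numeric(master_seed), keys)
  eng <- list(network = network, pop = pop, t = 0,
              T = numeric(nchan), P = numeric(nchan), a = numeric(nchan),
              streams = streams, stream_of = stream_of,
              slow_sorted = slow_sorted,
              step_count = 0, next_sample = 0, master_seed = master_seed)
  class(eng) <- "kmc_engine"
  for (j in seq_len(nchan)) {
    d <- cpp_draw_uniform(eng$streams, stream_of[j], 1L)
    eng$P[j] <- -log(d$values)
    eng$streams <- d$streams
  }
  eng$a <- .engine_propensities(eng)
  eng
}

.engine_propensities <- function(eng) {
  net <- eng$network
  vapply(seq_along(net$reactions), function(j) {
    switch(net$.kind[j] + 1L,
           net$.ceff[j],
           net$.ceff[j] * eng$pop[net$.r1[j] + 1L],
           net$.ceff[j] * eng$pop[net$.r1[j] + 1L] * eng$pop[net$.r2[j] + 1L],
           net$.ceff[j] * eng$pop[net$.r1[j] + 1L] * (eng$pop[net$.r1[j] + 1L] - 1) / 2)
  }, numeric(1), USE.NAMES = FALSE)
}

.engine_apply <- function(eng, res) {
  eng$pop <- stats::setNames(res$pop, eng$network$species)
  eng$t <- res$t
  eng$T <- res$T; eng$P <- res$P; eng$a <- res$a
  eng$streams <- res$streams
  eng$step_count <- eng$step_count + res$steps
  eng$next_sample <- res$next_sample
  eng
}

#' Advance the engine by exactly one reaction event
#'
#' Fires the channel minimising `(P_j - T_j) / a_j` (ties broken toward the
#' lowest channel id), advances all internal clocks by `a_j * dt`, updates the
#' populations and draws a fresh unit exponential for the fired channel.
#'
#' @param engine A `kmc_engine`.
#' @return List with elements `engine` (updated), `channel` (fired channel id,
#'   `NA` if every propensity was zero) and `t` (new KMC time).
#' @export
advance_one_step <- function(engine) {
  net <- engine$network
  res <- cpp_run(net$.delta, net$.kind, net$.ceff, net$.r1, net$.r2,
                 engine$pop, engine$t, engine$T, engine$P,
                 engine$streams, engine$stream_of,
                 t_f = Inf, max_steps = 1,
                 sample_interval = 0, next_sample = engine$next_sample,
                 record_slow = rep(TRUE, length(net$reactions)))
  fired <- if (res$exhausted) NA_integer_ else which(res$counts == 1)
  list(engine = .engine_apply(engine, res), channel = fired, t = res$t)
}

#' Propagate the engine over a KMC time window
#'
#' Advances to exactly `t_f` (the final pending reaction is not fired;
#' internal clocks are advanced consistently and the pending draws retained,
#' so pausing is statistically exact and chunked simulation agrees with an
#' unchunked one to floating-point roundoff), optionally recording species
#' samples on a fixed grid and the occurrence times of every slow-channel
#' firing.
#'
#' @param engine A `kmc_engine`.
#' @param t_f Final KMC time (`>= engine$t`); may be `Inf` if `max_steps` is
#'   finite.
#' @param record_slow_events Record firing times of slow channels?
#' @param sample_interval Species sampling cadence in KMC minutes; `0`
#'   disables sampling.
#' @param max_steps Optional cap on the number of events fired.
#' @return List with elements `engine` (updated) and `chunk`
#'   (a `trajectory_chunk`: window, samples, per-channel event times and
#'   execution counts, total steps, exhaustion flag).
#' @export
simulate_chunk <- function(engine, t_f, record_slow_events = TRUE,
                           sample_interval = 0.1, max_steps = Inf) {
  if (!is.finite(t_f) && !is.finite(max_steps))
    stop("one of t_f and max_steps must be finite")
  if (is.finite(t_f) && t_f < engine$t) stop("t_f must be >= current time")
  net <- engine$network
  t_s <- engine$t
  record <- rep(FALSE, length(net$reactions))
  if (record_slow_events) record[net$slow] <- TRUE
  res <- cpp_run(net$.delta, net$.kind, net$.ceff, net$.r1, net$.r2,
                 engine$pop, engine$t, engine$T, engine$P,
                 engine$streams, engine$stream_of,
                 t_f = t_f, max_steps = max_steps,
                 sample_interval = sample_interval,
                 next_sample = engine$next_sample,
                 record_slow = record)
  engine <- .engine_apply(engine, res)
  samples <- res$samples
  colnames(samples) <- c("time", net$species)
  chunk <- structure(list(window = c(t_s = t_s, t_f = engine$t),
                          samples = samples,
                          events = res$events,
                          counts = stats::setNames(res$counts, seq_along(res$counts)),
                          steps = res$steps,
                          exhausted = res$exhausted),
                     class = "trajectory_chunk")
  list(engine = engine, chunk = chunk)
}

#' Save a snapshot for common-random-number replication
#'
#' The snapshot captures the KMC time, populations, current rate constants
#' and the internal clocks and stream states of the slow channels only.  The
#' fast channels' clocks and shared stream are deliberately not saved: their
#' firing times are not of interest, and on restore they are re-initialized
#' with fresh draws from the (continuing) fast stream.
#'
#' @param engine A `kmc_engine`.
#' @return An object of class `kmc_snapshot` (value semantics; reusable any
#'   number of times).
#' @export
save_snapshot <- function(engine) {
  net <- engine$network
  slow <- engine$slow_sorted
  structure(list(t = engine$t, pop = engine$pop,
                 rate_constants = vapply(net$reactions, function(r) r$rate_constant,
                                         numeric(1)),
                 ceff = net$.ceff, cum_downscale = net$cum_downscale,
                 T_slow = engine$T[slow], P_slow = engine$P[slow],
                 slow_streams = engine$streams[, engine$stream_of[slow], drop = FALSE],
                 next_sample = engine$next_sample, step_count = engine$step_count,
                 species = net$species, nchan = length(net$reactions)),
            class = "kmc_snapshot")
}

#' Restore the engine to a saved snapshot
#'
#' Resets time, populations, rate constants, and the slow channels' clocks
#' and stream states; the fast channels are re-initialized with fresh unit
#' exponentials drawn from the engine's current (not restored) fast stream.
#'
#' @param engine A `kmc_engine` built on the same network topology.
#' @param snapshot A `kmc_snapshot`.
#' @return The restored engine.
#' @export
restore_snapshot <- function(engine, snapshot) {
  net <- engine$network
  if (!identical(snapshot$species, net$species) ||
      snapshot$nchan != length(net$reactions))
    stop("snapshot is incompatible with this engine's network topology")
  for (j in seq_along(net$reactions))
    net$reactions[[j]]$rate_constant <- snapshot$rate_constants[j]
  net$.ceff <- snapshot$ceff
  net$cum_downscale <- snapshot$cum_downscale
  engine$network <- net
  engine$pop <- snapshot$pop
  engine$t <- snapshot$t
  engine$next_sample <- snapshot$next_sample
  engine$step_count <- snapshot$step_count
  slow <- engine$slow_sorted
  engine$T[slow] <- snapshot$T_slow
  engine$P[slow] <- snapshot$P_slow
  engine$streams[, engine$stream_of[slow]] <- snapshot$slow_streams
  for (j in net$fast) {
    engine$T[j] <- 0
    d <- cpp_draw_uniform(engine$streams, engine$stream_of[j], 1L)
    engine$P[j] <- -log(d$values)
    engine$streams <- d$streams
  }
  engine$a <- .engine_propensities(engine)
  engine
}

#' Per-channel execution frequencies of a trajectory chunk
#'
#' @param chunk A `trajectory_chunk` with a positive-width window.
#' @return Named numeric vector, events per KMC minute per channel.
#' @export
execution_frequencies <- function(chunk) {
  w <- chunk$window[["t_f"]] - chunk$window[["t_s"]]
  if (w <= 0) stop("chunk window has zero width")
  chunk$counts / w
}

#' @export
print.kmc_engine <- function(x, ...) {
  cat("kmc_engine at t =", format(x$t), "min,", format(x$step_count),
      "steps executed\n")
  print(x$pop)
  invisible(x)
}
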