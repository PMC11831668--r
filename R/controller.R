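#' Tunable parameters of the downscaling controller
#'
#' Defaults follow the benchmark configuration: the controller is invoked
#' every `N` KMC steps, evaluates a window of `w_min`..`w_max` KMC minutes,
#' generates `n` common-random-number replicates at relative factors
#' `df_b^0 .. df_b^(n-1)`, and balances cost against error with weights
#' `alpha` and `beta`.
#'
#' @param N KMC steps between downscaling attempts.
#' @param w_min,w_max Window width bounds (KMC min).
#' @param df_b Base downscale factor (> 1).
#' @param n Number of downscaled replicates, including the df = 1 one (>= 3).
#' @param tss_min Minimum time-scale separation (orders of magnitude)
#'   required to attempt a downscaling.
#' @param alpha,beta Objective weights on cost and error.
#' @param e_max Absolute cap on the fitted IAT error norm at the chosen
#'   factor.
#' @param e_inc Maximum allowed error increase over the df = 1 baseline, in
#'   orders of magnitude.
#' @param delta Quasi-equilibrium threshold on `|N_f - N_r| / (N_f + N_r)`.
#' @param q_min Error-saturation bound: every slow channel's fitted error
#'   exponent must reach this value.
#' @param slope_thresh Sliding-window slope above which the cost law is
#'   deemed broken.
#' @param curv_thresh Threshold on the central-difference second derivative
#'   of log-cost.
#' @param fit_window Number of points per sliding-window slope fit.
#' @param sample_interval Species sampling cadence of the official
#'   trajectory (KMC min).
#' @param min_slow_firings Target firings per active slow channel used by the
#'   propensity-based window-width forecast.
#' @return A `downscale_config` list.
#' @export
downscale_config <- function(N = 1e5, w_min = 10, w_max = 15, df_b = 5, n = 9,
                             tss_min = 2, alpha = 1, beta = 2, e_max = 0.05,
                             e_inc = 2, delta = 0.05, q_min = 0.2,
                             slope_thresh = -0.9, curv_thresh = 0.05,
                             fit_window = 4, sample_interval = 0.1,
                             min_slow_firings = 5) {
  stopifnot(N >= 1, w_min > 0, w_max >= w_min, df_b > 1, n >= 3,
            alpha >= 0, beta >= 0, delta > 0, delta < 1,
            e_max > 0, e_max < 1, e_inc >= 0, q_min >= 0, fit_window >= 3)
  structure(as.list(environment()), class = "downscale_config")
}

#' Quasi-equilibrium check for a reversible pair
#'
#' A forward/reverse pair is quasi-equilibrated over a window when its
#' execution counts are balanced: `|N_f - N_r| / (N_f + N_r) <= delta`.
#' Zero total executions fail the check (insufficient sampling).
#'
#' @param N_f,N_r Forward and reverse execution counts.
#' @param delta Threshold (default 0.05).
#' @return `TRUE` if the pair is quasi-equilibrated.
#' @export
qe_check <- function(N_f, N_r, delta = 0.05) {
  if (N_f + N_r == 0) return(FALSE)
  abs(N_f - N_r) / (N_f + N_r) <= delta
}

#' Check that the anticipated fast channels are indeed the fast ones
#'
#' @param frequencies Named per-channel execution frequencies from the
#'   unscaled chunk.
#' @param fast_set,slow_set Channel-id sets of the network partition.
#' @return `TRUE` iff every fast channel fired more frequently than every
#'   slow channel (equal frequencies indicate no separation and fail).
#' @export
ordering_check <- function(frequencies, fast_set, slow_set) {
  if (length(fast_set) == 0) return(FALSE)
  min(frequencies[fast_set]) > max(frequencies[slow_set])
}

#' Time-scale separation in orders of magnitude
#'
#' `TSS = log10(min fast frequency / max slow frequency)`.  A zero maximum
#' slow frequency yields `+Inf`, which callers treat as insufficient sampling
#' rather than as a favourable separation.
#'
#' @inheritParams ordering_check
#' @return The TSS value (may be `Inf` or `-Inf`).
#' @export
compute_tss <- function(frequencies, fast_set, slow_set) {
  if (length(fast_set) == 0) return(-Inf)
  fmin <- min(frequencies[fast_set])
  smax <- max(frequencies[slow_set])
  if (smax == 0) return(Inf)
  log10(fmin / smax)
}

#' Choose the downscaling window for the current attempt
#'
#' Starts at `w_min` and widens in increments of `w_min / 2` (up to `w_max`)
#' until a propensity-based forecast predicts at least `min_slow_firings`
#' firings for every slow channel that widening can actually help: channels
#' whose current propensity is too low to reach the target even at `w_max`
#' (including zero-propensity channels) are excluded from the forecast,
#' since sufficiency for them is unattainable within the bounds.
#'
#' @param engine A `kmc_engine` positioned at the attempt's start time.
#' @param config A [downscale_config()].
#' @return Numeric `c(t_s, t_f)`.
#' @export
choose_window <- function(engine, config) {
  a_slow <- engine$a[engine$network$slow]
  a_slow <- a_slow[a_slow * config$w_max >= config$min_slow_firings]
  w <- config$w_min
  while (w < config$w_max && length(a_slow) > 0 &&
         any(a_slow * w < config$min_slow_firings))
    w <- min(w + config$w_min / 2, config$w_max)
  c(t_s = engine$t, t_f = engine$t + w)
}

#' Generate common-random-number replicates from a snapshot
#'
#' For `k = 1..n`, restores the snapshot (slow streams restored; the shared
#' fast stream continues, threaded from one replicate to the next), divides
#' the downscalable rate constants by `df_b^(k-1)` (so the k = 1 replicate
#' runs with unmodified constants) and simulates to `t_f`, recording every
#' slow-channel firing time.
#'
#' @param snapshot A `kmc_snapshot` taken at the window start.
#' @param engine The engine after generating the unscaled chunk (supplies the
#'   continuing fast stream).
#' @param config A [downscale_config()].
#' @param t_f Window end time.
#' @return List with `replicates` (list of `n` trajectory chunks, each with a
#'   `rel_factor` attribute) and `engine` (carrying the threaded fast
#'   stream).
#' @export
generate_replicates <- function(snapshot, engine, config, t_f) {
  reps <- vector("list", config$n)
  for (k in seq_len(config$n)) {
    eng_k <- restore_snapshot(engine, snapshot)
    rel <- config$df_b^(k - 1)
    if (rel > 1) eng_k$network <- scale_rate_constants(eng_k$network, rel)
    res <- simulate_chunk(eng_k, t_f, record_slow_events = TRUE,
                          sample_interval = 0)
    engine <- res$engine
    attr(res$chunk, "rel_factor") <- rel
    reps[[k]] <- res$chunk
  }
  list(replicates = reps, engine = engine)
}

#' Detect the largest downscale factor with valid cost scaling
#'
#' Two independent detectors run on the (log10 df, log10 cost) points, which
#' must be uniformly spaced in log df: (1) sliding four-point least-squares
#' fits; the first window whose slope exceeds `slope_thresh` (default -0.9)
#' marks its second-to-last point as `df_max_1`; (2) central-difference
#' second derivatives; the point before the first exceedance of `curv_thresh`
#' (default 0.05) in absolute value marks `df_max_2`.  The result is the
#' smaller of the two (or the largest df when neither fires); points beyond
#' it are to be discarded.
#'
#' @param cost_points Data frame with columns `df` and `cost` (any order;
#'   sorted internally).
#' @param config A [downscale_config()].
#' @return The df value of the last valid point.
#' @export
detect_df_max <- function(cost_points, config = downscale_config()) {
  pts <- cost_points[order(cost_points$df), , drop = FALSE]
  n <- nrow(pts)
  if (n < 4) stop("detect_df_max needs at least 4 cost points")
  x <- log10(pts$df); y <- log10(pts$cost)
  wlen <- config$fit_window
  df_max_1 <- pts$df[n]
  for (w in seq_len(n - wlen + 1)) {
    idx <- w:(w + wlen - 1)
    xc <- x[idx] - mean(x[idx])
    slope <- sum(xc * y[idx]) / sum(xc^2)
    if (slope > config$slope_thresh) {
      df_max_1 <- pts$df[w + wlen - 2]
      break
    }
  }
  df_max_2 <- pts$df[n]
  h <- mean(diff(x))
  for (i in 2:(n - 1)) {
    y2 <- (y[i + 1] - 2 * y[i] + y[i - 1]) / h^2
    if (abs(y2) > config$curv_thresh) {
      df_max_2 <- pts$df[i - 1]
      break
    }
  }
  min(df_max_1, df_max_2)
}

#' Fit the power-law cost model C(df)
#'
#' Least-squares line on (log10 df, log10 cost) over the valid points, giving
#' `C(df) = 10^intercept * df^slope`.
#'
#' @param cost_points Data frame with columns `df` and `cost` (valid points
#'   only, i.e. df <= df_max).
#' @return A `cost_model` list with `slope`, `intercept` and `predict(df)`.
#' @export
fit_cost_model <- function(cost_points) {
  if (nrow(cost_points) < 2) stop("cost fit needs at least 2 valid points")
  x <- log10(cost_points$df); y <- log10(cost_points$cost)
  fit <- stats::lm.fit(cbind(1, x), y)
  b <- unname(fit$coefficients)
  structure(list(slope = b[2], intercept = b[1],
                 predict = function(df) 10^(b[1] + b[2] * log10(df))),
            class = "cost_model")
}

#' Interarrival-time error norm between two event lists
#'
#' Converts each ordered list of firing times to interarrival times (the
#' first IAT is measured from the window start `t_s`), truncates both to the
#' common length, and returns the Euclidean norm of the IAT difference
#' vector.
#'
#' @param unscaled_events,replicate_events Increasing firing-time vectors for
#'   the same channel over the same window.
#' @param t_s Window start time.
#' @return Nonnegative norm, or `NA_real_` when either list is empty (the
#'   channel is then excluded from the attempt's error fit).
#' @export
iat_error_norm <- function(unscaled_events, replicate_events, t_s = 0) {
  if (length(unscaled_events) == 0 || length(replicate_events) == 0)
    return(NA_real_)
  tau_u <- diff(c(t_s, unscaled_events))
  tau_k <- diff(c(t_s, replicate_events))
  L <- min(length(tau_u), length(tau_k))
  sqrt(sum((tau_k[seq_len(L)] - tau_u[seq_len(L)])^2))
}

#' Fit the power-law error model E(df) and run the saturation check
#'
#' A single aggregated least-squares fit of `E(df) = p * df^q` on the
#' (log10 df, log10 norm) points of all slow channels with `df <= df_max`,
#' plus per-channel fits `(p_j, q_j)` used to detect error saturation: the
#' attempt is invalid when any channel's exponent falls below `q_min`
#' (its error no longer grows with df over the valid range, indicating an
#' inappropriate window).
#'
#' @param error_points Data frame with columns `df`, `channel`, `norm`.
#' @param df_max Largest valid downscale factor.
#' @param config A [downscale_config()].
#' @return List with `p`, `q`, `predict(df)`, `per_channel` (data frame of
#'   per-channel fits) and `saturation_ok`.
#' @export
fit_error_model <- function(error_points, df_max, config = downscale_config()) {
  pts <- error_points[!is.na(error_points$norm) & error_points$df <= df_max, ,
                      drop = FALSE]
  pts <- pts[pts$norm > 0, , drop = FALSE]
  if (nrow(pts) == 0 || length(unique(pts$df)) < 2)
    stop("error fit is degenerate: fewer than 2 distinct valid df values")
  x <- log10(pts$df); y <- log10(pts$norm)
  fit <- stats::lm.fit(cbind(1, x), y)
  b <- unname(fit$coefficients)
  per <- do.call(rbind, lapply(split(pts, pts$channel), function(d) {
    if (length(unique(d$df)) < 2) return(NULL)
    xb <- log10(d$df); yb <- log10(d$norm)
    fb <- stats::lm.fit(cbind(1, xb), yb)$coefficients
    data.frame(channel = d$channel[1], p = 10^unname(fb[1]), q = unname(fb[2]))
  }))
  saturation_ok <- !is.null(per) && nrow(per) > 0 && all(per$q >= config$q_min)
  structure(list(p = 10^b[1], q = b[2],
                 predict = function(df) 10^(b[1] + b[2] * log10(df)),
                 per_channel = per, saturation_ok = saturation_ok),
            class = "error_model")
}

#' Minimize the weighted cost-error objective
#'
#' `F(df) = alpha * C(df) + beta * E(df)` over the continuous interval
#' `[df_lo, df_max]`, with the cost model normalized so that `C(df_lo) = 1`.
#' The optimum is bracketed on a dense log-spaced grid and refined with
#' bounded scalar minimisation; it need not be a power of the base factor.
#'
#' @param cost_model A `cost_model`.
#' @param error_model An `error_model`.
#' @param alpha,beta Objective weights.
#' @param df_lo Lower bound (the attempt's starting absolute factor).
#' @param df_max Upper bound (largest valid factor).
#' @return The optimal downscale factor `df_opt`.
#' @export
minimize_objective <- function(cost_model, error_model, alpha, beta,
                               df_lo, df_max) {
  stopifnot(df_max >= df_lo, df_lo >= 1)
  c0 <- cost_model$predict(df_lo)
  f <- function(df) alpha * cost_model$predict(df) / c0 + beta * error_model$predict(df)
  if (df_max == df_lo) return(df_lo)
  grid <- 10^seq(log10(df_lo), log10(df_max), length.out = 1000)
  fv <- f(grid)
  if (any(!is.finite(fv))) stop("objective is non-finite on the search interval")
  i <- which.min(fv)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  if (lo == hi) return(lo)
  opt <- stats::optimize(f, lower = lo, upper = hi)
  if (opt$objective <= fv[i]) opt$minimum else grid[i]
}

#' Apply the absolute and relative error acceptance criteria
#'
#' The fitted error at the chosen factor must (a) not exceed `e_max` and
#' (b) not exceed the df = 1 baseline norm by more than `e_inc` orders of
#' magnitude.  A zero/absent baseline skips the relative criterion (logged);
#' the absolute criterion always applies.
#'
#' @param df_opt Candidate downscale factor.
#' @param error_model An `error_model`.
#' @param baseline_norm_at_df1 Mean per-channel IAT error norm of the df = 1
#'   replicate.
#' @param config A [downscale_config()].
#' @return List with `accept`, `E_opt`, `abs_ok`, `rel_ok`.
#' @export
evaluate_acceptance <- function(df_opt, error_model, baseline_norm_at_df1,
                                config = downscale_config()) {
  E_opt <- error_model$predict(df_opt)
  abs_ok <- E_opt <= config$e_max
  rel_ok <- if (!is.na(baseline_norm_at_df1) && baseline_norm_at_df1 > 0)
    log10(E_opt / baseline_norm_at_df1) <= config$e_inc else NA
  list(accept = abs_ok && !isFALSE(rel_ok), E_opt = E_opt,
       abs_ok = abs_ok, rel_ok = rel_ok)
}

# one full downscaling attempt; returns engine to continue from, the samples
# of the registered (official) chunk, and the attempt record
.attempt_downscale <- function(eng, config, m) {
  df_cum <- eng$network$cum_downscale
  win <- choose_window(eng, config)
  t_s <- win[["t_s"]]; t_f <- win[["t_f"]]
  snap <- save_snapshot(eng)
  u <- simulate_chunk(eng, t_f, record_slow_events = TRUE,
                      sample_interval = config$sample_interval)
  eng_u <- u$engine; chunk_u <- u$chunk
  net <- eng_u$network
  freqs <- execution_frequencies(chunk_u)

  rec <- list(index = m, window = c(t_s = t_s, t_f = t_f), df_cum_before = df_cum,
              frequencies = freqs,
              gates = c(qe = NA, ordering = NA, tss = NA, saturation = NA,
                        e_max = NA, e_inc = NA),
              tss = NA_real_, cost_points = NULL, error_points = NULL,
              df_max = NA_real_, cost_model = NULL, error_model = NULL,
              df_opt = NA_real_, E_opt = NA_real_, baseline = NA_real_,
              accepted = FALSE, abort_reason = NA_character_,
              df_cum_after = df_cum)
  abort <- function(reason) {
    rec$abort_reason <- reason
    list(engine = eng_u, samples = chunk_u$samples, record = rec)
  }

  pairs <- list()
  for (r in net$reactions)
    if (r$downscalable && r$id < r$reverse_partner)
      pairs[[length(pairs) + 1]] <- c(r$id, r$reverse_partner)
  rec$gates[["qe"]] <- all(vapply(pairs, function(p)
    qe_check(chunk_u$counts[[p[1]]], chunk_u$counts[[p[2]]], config$delta),
    logical(1)))
  if (!rec$gates[["qe"]]) return(abort("quasi-equilibrium check failed"))

  rec$gates[["ordering"]] <- ordering_check(freqs, net$fast, net$slow)
  if (!rec$gates[["ordering"]]) return(abort("frequency ordering check failed"))

  rec$tss <- compute_tss(freqs, net$fast, net$slow)
  rec$gates[["tss"]] <- is.finite(rec$tss) && rec$tss >= config$tss_min
  if (!rec$gates[["tss"]])
    return(abort(if (is.finite(rec$tss)) "insufficient time-scale separation"
                 else "slow channels not sampled"))

  gr <- generate_replicates(snap, eng_u, config, t_f)
  reps <- gr$replicates; eng_thread <- gr$engine

  ok <- !vapply(reps, function(ch) ch$exhausted, logical(1))
  df_abs <- df_cum * config$df_b^(seq_len(config$n) - 1)
  cost_points <- data.frame(df = df_abs,
                            cost = vapply(reps, function(ch) ch$steps, numeric(1)) /
                              chunk_u$steps)[ok, , drop = FALSE]
  rec$cost_points <- cost_points
  if (nrow(cost_points) < 4) return(abort("fewer than 4 valid cost points"))

  rec$df_max <- detect_df_max(cost_points, config)
  valid <- cost_points[cost_points$df <= rec$df_max, , drop = FALSE]
  if (nrow(valid) < 2 || rec$df_max <= df_cum)
    return(abort("cost law invalid beyond the current factor"))
  rec$cost_model <- fit_cost_model(valid)

  err <- do.call(rbind, lapply(which(ok), function(k) {
    norms <- vapply(net$slow, function(j)
      iat_error_norm(chunk_u$events[[j]], reps[[k]]$events[[j]], t_s), numeric(1))
    data.frame(df = df_abs[k], channel = net$slow, norm = norms)
  }))
  rec$error_points <- err
  rec$baseline <- mean(err$norm[err$df == df_abs[1]], na.rm = TRUE)

  em <- tryCatch(fit_error_model(err, rec$df_max, config), error = function(e) e)
  if (inherits(em, "error")) return(abort(conditionMessage(em)))
  rec$error_model <- em
  rec$gates[["saturation"]] <- em$saturation_ok
  if (!em$saturation_ok) return(abort("error norm saturated for some channel"))

  rec$df_opt <- minimize_objective(rec$cost_model, em, config$alpha, config$beta,
                                   df_lo = df_cum, df_max = rec$df_max)
  dec <- evaluate_acceptance(rec$df_opt, em, rec$baseline, config)
  rec$E_opt <- dec$E_opt
  rec$gates[["e_max"]] <- dec$abs_ok
  rec$gates[["e_inc"]] <- dec$rel_ok
  if (!dec$accept)
    return(abort("error criteria rejected the optimal factor"))

  # regenerate the official chunk at df_opt from the snapshot
  eng_o <- restore_snapshot(eng_thread, snap)
  eng_o$network <- scale_rate_constants(eng_o$network, rec$df_opt / df_cum)
  o <- simulate_chunk(eng_o, t_f, record_slow_events = TRUE,
                      sample_interval = config$sample_interval)
  rec$accepted <- TRUE
  rec$df_cum_after <- o$engine$network$cum_downscale
  list(engine = o$engine, samples = o$chunk$samples, record = rec)
}

#' Run a KMC simulation with the on-the-fly downscaling controller
#'
#' Propagates the system with the Modified Next Reaction Method and, every
#' `N` KMC steps, attempts a downscaling: snapshot, unscaled reference chunk,
#' quasi-equilibrium / ordering / time-scale-separation gates,
#' common-random-number replicate generation, cost and IAT-error power-law
#' fits with validity detection, objective minimisation in absolute-df
#' coordinates, and the error acceptance criteria.  On acceptance the window
#' is regenerated at the optimal factor and the reduced rate constants are
#' kept; on any failed gate the unscaled chunk is registered unchanged.
#'
#' @param network A [reaction_network()].
#' @param config A [downscale_config()].
#' @param master_seed Integer master seed for all random streams.
#' @param t_end Final KMC time (the last downscaling window may end slightly
#'   beyond it).
#' @param initial_populations Named copy-number vector.
#' @param enabled Set `FALSE` for a plain Mod-NRM run with no attempts.
#' @return A `downscale_run`: `trajectory` (time + species sample matrix),
#'   `attempts` (one record per attempt with all gate values, points, fits
#'   and decisions), `engine`, and `df_cum` (cumulative absolute downscale
#'   factor; effective downscalable constants equal the originals divided by
#'   it).
#' @export
run_with_downscaling <- function(network, config = downscale_config(),
                                 master_seed = 1, t_end,
                                 initial_populations = network$initial_state,
                                 enabled = TRUE) {
  eng <- initialize_engine(network, initial_populations, master_seed)
  traj <- list(); attempts <- list()
  repeat {
    res <- simulate_chunk(eng, t_f = t_end, record_slow_events = FALSE,
                          sample_interval = config$sample_interval,
                          max_steps = if (enabled) config$N else Inf)
    eng <- res$engine
    traj[[length(traj) + 1]] <- res$chunk$samples
    if (eng$t >= t_end || res$chunk$exhausted) break
    att <- .attempt_downscale(eng, config, m = length(attempts) + 1)
    eng <- att$engine
    traj[[length(traj) + 1]] <- att$samples
    attempts[[length(attempts) + 1]] <- att$record
    if (eng$t >= t_end) break
  }
  structure(list(trajectory = do.call(rbind, traj), attempts = attempts,
                 engine = eng, df_cum = eng$network$cum_downscale,
                 config = config, master_seed = master_seed),
            class = "downscale_run")
}

#' @export
print.downscale_run <- function(x, ...) {
  acc <- vapply(x$attempts, function(a) a$accepted, logical(1))
  cat("downscale_run: t =", format(x$engine$t), "min;",
      length(x$attempts), "attempt(s),", sum(acc), "accepted;",
      "cumulative df =", format(x$df_cum), "\n")
  for (a in x$attempts)
    cat(sprintf("  attempt %d (%.4g, %.4g): %s%s\n", a$index,
                a$window[["t_s"]], a$window[["t_f"]],
                if (a$accepted) sprintf("accepted df_opt = %.4g", a$df_opt)
                else "aborted",
                if (a$accepted) "" else paste0(" (", a$abort_reason, ")")))
  invisible(x)
}
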