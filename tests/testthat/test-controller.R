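test_that("quasi-equilibrium predicate arithmetic", {
  expect_true(qe_check(100, 100, 0.05))
  expect_true(qe_check(105, 100, 0.05))    # ratio ~ 0.0244
  expect_false(qe_check(120, 100, 0.05))   # ratio ~ 0.0909
  expect_false(qe_check(0, 0, 0.05))       # no sampling at all
})

test_that("frequency ordering and time-scale separation checks", {
  f <- c(1e6, 1e5, 1e2, 10)
  expect_true(ordering_check(f, fast_set = 1:2, slow_set = 3:4))
  expect_false(ordering_check(c(10, 1e4, 1e2, 1e5), 1:2, 3:4))
  expect_false(ordering_check(rep(7, 4), 1:2, 3:4))  # no separation
  expect_equal(compute_tss(f, 1:2, 3:4), 3)  # min fast 1e5 over max slow 1e2
  expect_equal(compute_tss(rep(7, 4), 1:2, 3:4), 0)
  expect_equal(compute_tss(c(1e5, 1e4, 0, 0), 1:2, 3:4), Inf)
})

test_that("window choice respects bounds and the sampling forecast", {
  net <- make_toy_network("birth-death", lambda = 10, mu = 1)
  eng <- initialize_engine(net, master_seed = 1)
  degen <- downscale_config(w_min = 10, w_max = 10)
  expect_equal(unname(diff(choose_window(eng, degen))), 10)
  # lambda = 10/min forecasts plenty of firings: width stays at w_min
  expect_equal(unname(diff(choose_window(eng, downscale_config()))), 10)
  # a sluggish channel that widening can help pushes the width up
  slug <- make_toy_network("birth-death", lambda = 0.4, mu = 1)
  eng2 <- initialize_engine(slug, master_seed = 1)
  w <- unname(diff(choose_window(eng2, downscale_config(w_min = 10, w_max = 15))))
  expect_gt(w, 10); expect_lte(w, 15)
})

test_that("df_max detection matches hand-computed detector outputs", {
  cfg <- downscale_config()
  # pure power law: neither detector fires, all points valid
  pure <- data.frame(df = 5^(0:8), cost = 5^-(0:8))
  expect_equal(detect_df_max(pure, cfg), 5^8)
  # cost flattens beyond 5^4: recompute both detectors independently
  kinked <- data.frame(df = 5^(0:8),
                       cost = c(5^-(0:4), rep(5^-4, 4)))
  x <- log10(kinked$df); y <- log10(kinked$cost); h <- log10(5)
  slope_fire <- NA
  for (w in 1:6) {
    s <- stats::coef(stats::lm(y[w:(w + 3)] ~ x[w:(w + 3)]))[2]
    if (s > -0.9) { slope_fire <- w; break }
  }
  expect_equal(slope_fire, 3)                   # windows 1-4, 2-5 are clean
  df1 <- kinked$df[slope_fire + 2]              # second-to-last of the window
  curv_fire <- NA
  for (i in 2:8) {
    d2 <- (y[i + 1] - 2 * y[i] + y[i - 1]) / h^2
    if (abs(d2) > 0.05) { curv_fire <- i; break }
  }
  expect_equal(curv_fire, 5)
  df2 <- kinked$df[curv_fire - 1]               # point before first exceedance
  expect_equal(detect_df_max(kinked, cfg), min(df1, df2))
  expect_equal(detect_df_max(kinked, cfg), 125)
  # canonical ordering: permuting input rows changes nothing
  perm <- kinked[sample(nrow(kinked)), ]
  expect_equal(detect_df_max(perm, cfg), 125)
  expect_error(detect_df_max(pure[1:3, ], cfg), "4 cost points")
})

test_that("cost model fitting recovers exact power laws", {
  pts <- data.frame(df = 5^(0:8), cost = 5^-(0:8))
  m <- fit_cost_model(pts)
  expect_equal(m$slope, -1, tolerance = 1e-12)
  expect_equal(m$intercept, 0, tolerance = 1e-12)
  pts2 <- data.frame(df = 5^(0:8), cost = 2 * 5^-(0:8))
  m2 <- fit_cost_model(pts2)
  expect_equal(m2$slope, -1, tolerance = 1e-12)
  expect_equal(m2$predict(1), 2, tolerance = 1e-12)
  # noisy data: slope estimate lands near the truth
  syn <- make_cost_error_points(slope = -1, noise_sd = 0.02, seed = 4)
  expect_equal(fit_cost_model(syn$cost_points)$slope, -1, tolerance = 0.05)
  expect_error(fit_cost_model(pts[1, , drop = FALSE]), "2 valid points")
})

test_that("IAT error norm follows the truncation rule", {
  expect_equal(iat_error_norm(c(1, 2, 3), c(1, 2, 3), t_s = 0), 0)
  # IAT differences (3, 4) -> Euclidean norm 5
  expect_equal(iat_error_norm(c(1, 2), c(4, 9), t_s = 0), 5)
  # unequal counts: only the first common firings enter
  u <- cumsum(rep(1, 10)); k <- cumsum(rep(1, 8))
  k[8] <- k[8] + 0.25
  expect_equal(iat_error_norm(u, k, t_s = 0), 0.25)
  expect_true(is.na(iat_error_norm(numeric(0), c(1, 2), t_s = 0)))
  # the window start anchors the first interarrival time
  expect_equal(iat_error_norm(c(5), c(6), t_s = 4), 1)
})

test_that("error model fitting, saturation detection, scale equivariance", {
  syn <- make_cost_error_points(p = 1e-3, q = 0.5, noise_sd = 0)
  em <- fit_error_model(syn$error_points, df_max = 5^8)
  expect_equal(em$p, 1e-3, tolerance = 1e-10)
  expect_equal(em$q, 0.5, tolerance = 1e-10)
  expect_true(em$saturation_ok)
  # a saturated channel (constant norms, q ~ 0 < 0.2) blocks the attempt
  sat <- rbind(syn$error_points,
               data.frame(df = 5^(0:8), channel = 2, norm = 3e-3))
  em2 <- fit_error_model(sat, df_max = 5^8)
  expect_false(em2$saturation_ok)
  expect_lt(em2$per_channel$q[em2$per_channel$channel == 2], 0.2)
  # doubling every norm doubles p and leaves q unchanged
  dbl <- syn$error_points; dbl$norm <- 2 * dbl$norm
  em3 <- fit_error_model(dbl, df_max = 5^8)
  expect_equal(em3$p, 2e-3, tolerance = 1e-10)
  expect_equal(em3$q, em$q, tolerance = 1e-10)
  # points beyond df_max are discarded before fitting
  bent <- syn$error_points
  bent$norm[bent$df > 5^4] <- 10
  em4 <- fit_error_model(bent, df_max = 5^4)
  expect_equal(em4$q, 0.5, tolerance = 1e-10)
  zero <- data.frame(df = 5^(0:4), channel = 1, norm = 0)
  expect_error(fit_error_model(zero, df_max = 5^4), "degenerate")
})

test_that("objective minimisation matches calculus and brute force", {
  costm <- fit_cost_model(data.frame(df = 5^(0:8), cost = 5^-(0:8)))
  errm <- fit_error_model(
    make_cost_error_points(p = 1e-3, q = 0.5, noise_sd = 0)$error_points,
    df_max = 5^8)
  # alpha=1, beta=2: stationary point of df^-1 + 2e-3 df^0.5 is df = 100
  expect_equal(minimize_objective(costm, errm, 1, 2, 1, 5^8), 100,
               tolerance = 0.01)
  # monotone edge cases
  expect_equal(minimize_objective(costm, errm, 1, 0, 1, 5^8), 5^8,
               tolerance = 1e-6)
  expect_equal(minimize_objective(costm, errm, 0, 1, 1, 5^8), 1,
               tolerance = 1e-6)
  # randomized instances against a dense brute-force scan
  for (seed in 1:10) {
    z <- kmcdown:::.fixture_normals(5, seed)
    slope <- -1 + 0.1 * z[1]
    p <- 10^(-3 + z[2] / 2); q <- 0.3 + 0.2 * abs(z[3])
    alpha <- 10^(z[4] / 2); beta <- 10^(z[5] / 2)
    cm <- structure(list(slope = slope, intercept = 0,
                         predict = function(df) df^slope), class = "cost_model")
    em <- structure(list(p = p, q = q,
                         predict = function(df) p * df^q), class = "error_model")
    got <- minimize_objective(cm, em, alpha, beta, 1, 390625)
    grid <- 10^seq(0, log10(390625), length.out = 1e4)
    brute <- grid[which.min(alpha * cm$predict(grid) + beta * em$predict(grid))]
    expect_equal(got, brute, tolerance = 0.011)
  }
})

test_that("acceptance criteria combine absolute and relative error caps", {
  em <- structure(list(p = 0.013, q = 0,
                       predict = function(df) 0.013), class = "error_model")
  cfg <- downscale_config()
  d <- evaluate_acceptance(81.3, em, baseline_norm_at_df1 = 0.0013, cfg)
  expect_true(d$accept)     # 0.013 < 0.05 and a factor-10 increase < 10^2
  em2 <- structure(list(predict = function(df) 0.06), class = "error_model")
  expect_false(evaluate_acceptance(10, em2, 0.01, cfg)$accept)
  em3 <- structure(list(predict = function(df) 0.1), class = "error_model")
  expect_false(evaluate_acceptance(10, em3, 1e-4,
                                   downscale_config(e_max = 0.5))$accept)
  # zero baseline: the relative criterion is skipped, absolute still applies
  d4 <- evaluate_acceptance(10, em, 0, cfg)
  expect_true(d4$accept); expect_true(is.na(d4$rel_ok))
})

test_that("CRN replicates share slow streams and scale constants geometrically", {
  net <- make_toy_network("fast-pair-slow-sink", kf = 300, kr = 300, ks = 2,
                          n0 = 15)
  eng <- initialize_engine(net, master_seed = 40)
  eng <- simulate_chunk(eng, 1, FALSE, 0)$engine
  snap <- save_snapshot(eng)
  u <- simulate_chunk(eng, 4, TRUE, 0)
  cfg <- downscale_config(n = 4, df_b = 5, w_min = 3, w_max = 3)
  reps <- generate_replicates(snap, u$engine, cfg, t_f = 4)
  expect_length(reps$replicates, 4)
  expect_equal(vapply(reps$replicates, attr, numeric(1), "rel_factor"),
               c(1, 5, 25, 125))
  # replicate step counts decay roughly like 1/df for a dominated fast pair
  steps <- vapply(reps$replicates, `[[`, numeric(1), "steps")
  expect_true(all(diff(steps) < 0))
  expect_lt(steps[3] / steps[1], 0.15)
  # on an all-slow network every replicate is bit-identical (pure CRN)
  slownet <- make_toy_network("two-slow-channels", kf = 2, kr = 1, n0 = 20)
  se <- initialize_engine(slownet, master_seed = 41)
  ssnap <- save_snapshot(se)
  sreps <- generate_replicates(ssnap, se, downscale_config(n = 3, w_min = 5,
                                                           w_max = 5), t_f = 5)
  expect_identical(sreps$replicates[[1]]$events, sreps$replicates[[2]]$events)
  expect_identical(sreps$replicates[[2]]$events, sreps$replicates[[3]]$events)
})

test_that("a disabled or fully-gated controller leaves the trajectory untouched", {
  net <- build_benchmark_network(zeta = 10)
  plain <- run_with_downscaling(net, downscale_config(), master_seed = 77,
                                t_end = 6, enabled = FALSE)
  gated <- run_with_downscaling(net, downscale_config(tss_min = Inf),
                                master_seed = 77, t_end = 6)
  expect_gt(length(gated$attempts), 0)
  expect_true(all(!vapply(gated$attempts, `[[`, logical(1), "accepted")))
  expect_equal(gated$df_cum, 1)
  # gate soundness: registered chunks are bit-identical to the unscaled path
  n <- nrow(plain$trajectory)
  expect_identical(gated$trajectory[seq_len(n), ], plain$trajectory)
})

test_that("accepted attempts keep cumulative bookkeeping consistent", {
  net <- build_benchmark_network(zeta = 1000)
  cfg <- downscale_config(w_min = 5, beta = 10)
  run <- run_with_downscaling(net, cfg, master_seed = 1, t_end = 16)
  acc <- Filter(function(a) a$accepted, run$attempts)
  expect_gt(length(acc), 0)
  # cumulative factor is the product of per-attempt relative reductions
  rel <- vapply(acc, function(a) a$df_cum_after / a$df_cum_before, numeric(1))
  expect_equal(run$df_cum, prod(rel), tolerance = 1e-12)
  expect_equal(run$df_cum, acc[[length(acc)]]$df_cum_after)
  # effective downscalable constants equal originals divided by it
  expect_equal(run$engine$network$reactions[[3]]$rate_constant,
               net$reactions[[3]]$rate_constant / run$df_cum, tolerance = 1e-9)
  expect_equal(run$engine$network$reactions[[2]]$rate_constant,
               net$reactions[[2]]$rate_constant)
  for (a in acc) {
    expect_true(a$df_opt >= a$df_cum_before && a$df_opt <= a$df_max)
    expect_gt(a$error_model$q, 0)   # error grows with df on accepted attempts
  }
  # full attempt ledger is reproducible with the same seed
  run2 <- run_with_downscaling(net, cfg, master_seed = 1, t_end = 16)
  expect_equal(vapply(run$attempts, `[[`, numeric(1), "df_cum_after"),
               vapply(run2$attempts, `[[`, numeric(1), "df_cum_after"))
  expect_identical(run$trajectory, run2$trajectory)
})

test_that("benchmark cost scaling is recovered across seeds", {
  # on the first zeta=100 window the fitted cost slope is the theoretical -1
  slopes <- vapply(1:5, function(seed) {
    run <- run_with_downscaling(build_benchmark_network(zeta = 100),
                                downscale_config(), master_seed = seed,
                                t_end = 11)
    run$attempts[[1]]$cost_model$slope
  }, numeric(1))
  expect_true(all(slopes > -1.1 & slopes < -0.9))
})
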