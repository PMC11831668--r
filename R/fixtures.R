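#' Toy reaction networks with analytic references
#'
#' Programmatic generators of small networks used to exercise the engine and
#' controller against known answers:
#' \describe{
#'   \item{`birth`}{A pure birth process (a Poisson process): `0 -> A` at rate
#'     `lambda`.}
#'   \item{`birth-death`}{`0 -> A` at `lambda`, `A -> 0` at `mu` per molecule;
#'     stationary law Poisson(`lambda/mu`).}
#'   \item{`fast-pair-slow-sink`}{`A <-> B` as a fast, downscalable reversible
#'     pair (rates `kf`, `kr` per molecule) feeding a slow sink `B -> C` at
#'     `ks`; the minimal instance of the separable fast/slow structure whose
#'     slow dynamics should be invariant under downscaling of the pair.}
#'   \item{`two-slow-channels`}{`A <-> B` with both channels slow; its empty
#'     fast set means a downscaling controller can never proceed.}
#' }
#' Each network carries a `reference` attribute with its ground-truth
#' parameters and any analytic law.
#'
#' @param template Template name.
#' @param lambda,mu,kf,kr,ks,n0 Template parameters (rates in 1/min;
#'   `lambda` in molecules/min; `n0` initial copies).
#' @return A [reaction_network()].
#' @export
make_toy_network <- function(template = c("birth", "birth-death",
                                          "fast-pair-slow-sink",
                                          "two-slow-channels"),
                             lambda = 10, mu = 1, kf = 1000, kr = 1000,
                             ks = 1, n0 = 10) {
  template <- match.arg(template)
  net <- switch(template,
    "birth" = {
      n <- reaction_network(
        species = "A",
        reactions = list(reaction(1, c(), c(A = 1), lambda)),
        fast = integer(0), slow = 1,
        initial_state = c(A = 0))
      attr(n, "reference") <- list(template = template, lambda = lambda,
                                   mean_at = function(t) lambda * t)
      n
    },
    "birth-death" = {
      n <- reaction_network(
        species = "A",
        reactions = list(reaction(1, c(), c(A = 1), lambda),
                         reaction(2, c(A = 1), c(), mu)),
        fast = integer(0), slow = 1:2,
        initial_state = c(A = 0))
      attr(n, "reference") <- list(template = template, lambda = lambda, mu = mu,
                                   stationary = list(law = "poisson",
                                                     mean = lambda / mu))
      n
    },
    "fast-pair-slow-sink" = {
      n <- reaction_network(
        species = c("A", "B", "C"),
        reactions = list(
          reaction(1, c(A = 1), c(B = 1), kf, downscalable = TRUE,
                   reverse_partner = 2),
          reaction(2, c(B = 1), c(A = 1), kr, downscalable = TRUE,
                   reverse_partner = 1),
          reaction(3, c(B = 1), c(C = 1), ks)),
        fast = 1:2, slow = 3,
        initial_state = c(A = n0))
      attr(n, "reference") <- list(template = template, kf = kf, kr = kr,
                                   ks = ks, n0 = n0,
                                   separation = log10((kf + kr) / ks))
      n
    },
    "two-slow-channels" = {
      n <- reaction_network(
        species = c("A", "B"),
        reactions = list(reaction(1, c(A = 1), c(B = 1), kf),
                         reaction(2, c(B = 1), c(A = 1), kr)),
        fast = integer(0), slow = 1:2,
        initial_state = c(A = n0))
      attr(n, "reference") <- list(template = template, kf = kf, kr = kr, n0 = n0)
      n
    })
  net
}

#' Synthetic cost and error point sets with known power laws
#'
#' Generates `cost = df^slope * 10^eps` and `norm = p * df^q * 10^eps` with
#' `eps ~ Normal(0, noise_sd)` in log10 space, on a log-uniform `df_grid`,
#' using the package's own seeded random streams (the global R RNG state is
#' untouched).  With `noise_sd = 0` the fitting routines must recover
#' `(slope, p, q)` exactly; the ground truth is returned alongside the data
#' for closed-loop recovery tests.
#'
#' @param slope Cost-law exponent (nominally -1).
#' @param p,q Error-law parameters; vectors are recycled over `channels`.
#' @param df_grid Downscale factors, uniform in log.
#' @param noise_sd Standard deviation of the log10 noise.
#' @param seed Seed for the generator stream.
#' @param channels Channel ids to emit error points for.
#' @return List with `cost_points`, `error_points` and `truth`.
#' @export
make_cost_error_points <- function(slope = -1, p = 1e-3, q = 0.5,
                                   df_grid = 5^(0:8), noise_sd = 0, seed = 1,
                                   channels = 1L) {
  nd <- length(df_grid)
  nc <- length(channels)
  p <- rep_len(p, nc); q <- rep_len(q, nc)
  n_normals <- nd * (1 + nc)
  z <- .fixture_normals(n_normals, seed) * noise_sd
  cost <- df_grid^slope * 10^z[seq_len(nd)]
  err <- do.call(rbind, lapply(seq_len(nc), function(i) {
    eps <- z[nd * i + seq_len(nd)]
    data.frame(df = df_grid, channel = channels[i],
               norm = p[i] * df_grid^q[i] * 10^eps)
  }))
  list(cost_points = data.frame(df = df_grid, cost = cost),
       error_points = err,
       truth = list(slope = slope, p = p, q = q, channels = channels,
                    noise_sd = noise_sd, seed = seed))
}

# Box-Muller normals from the package's own xorshift streams
.fixture_normals <- function(n, seed) {
  if (n == 0) return(numeric(0))
  streams <- cpp_make_streams(as.numeric(seed), 0L)
  d <- cpp_draw_uniform(streams, 1L, 2L * n)
  u <- d$values
  u1 <- u[seq_len(n) * 2 - 1]; u2 <- u[seq_len(n) * 2]
  sqrt(-2 * log(u1)) * cos(2 * pi * u2)
}
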