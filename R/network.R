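#' Define a single mass-action reaction channel
#'
#' A channel is a stoichiometric transformation with a concentration-based
#' rate constant.  The kinetic kind is inferred from the reactant
#' stoichiometry unless given explicitly: zeroth order, unimolecular,
#' bimolecular between distinct species, or bimolecular between two identical
#' molecules (which uses the exact \eqn{n(n-1)/2} combinatorics rather than
#' \eqn{n^2}).
#'
#' @param id Integer channel index (1-based; frozen to the network's channel
#'   numbering so that logs such as "channels 3-6 are fast" are unambiguous).
#' @param reactants,products Named integer vectors mapping species name to
#'   stoichiometric count.  Use an empty vector for a zeroth-order source.
#' @param rate_constant Nonnegative rate constant.  Unimolecular and zeroth
#'   order constants are in 1/min and nM/min respectively; bimolecular
#'   constants are concentration-based (1/nM/min) and are divided by the
#'   network's molecules-per-nM conversion when propensities are formed.
#' @param kind One of `"zeroth"`, `"unimolecular"`, `"bimolecular-distinct"`,
#'   `"bimolecular-identical"`, or `NULL` to infer from `reactants`.
#' @param downscalable Logical; may this channel's rate constant be reduced
#'   by the downscaling controller?  Downscalable channels must come in
#'   forward/reverse pairs (to preserve detailed balance at quasi-equilibrium).
#' @param reverse_partner Channel id of the paired reverse reaction, or `NA`.
#' @return An object of class `kmc_reaction`.
#' @export
reaction <- function(id, reactants, products, rate_constant, kind = NULL,
                     downscalable = FALSE, reverse_partner = NA_integer_) {
  reactants <- .as_stoich(reactants, "reactants")
  products <- .as_stoich(products, "products")
  if (!is.numeric(rate_constant) || length(rate_constant) != 1 ||
      is.na(rate_constant) || rate_constant < 0)
    stop("rate_constant must be a single nonnegative number")
  order <- sum(reactants)
  inferred <- if (order == 0) "zeroth"
    else if (order == 1) "unimolecular"
    else if (order == 2 && length(reactants) == 1) "bimolecular-identical"
    else if (order == 2) "bimolecular-distinct"
    else stop("reaction order > 2 is not supported (channel ", id, ")")
  if (is.null(kind)) kind <- inferred
  kind <- match.arg(kind, c("zeroth", "unimolecular", "bimolecular-distinct",
                            "bimolecular-identical"))
  if (kind != inferred)
    stop("declared kind '", kind, "' does not match reactant stoichiometry (channel ",
         id, ")")
  if (downscalable && is.na(reverse_partner))
    stop("downscalable channel ", id, " must declare a reverse_partner")
  structure(list(id = as.integer(id), reactants = reactants, products = products,
                 rate_constant = rate_constant, kind = kind,
                 downscalable = isTRUE(downscalable),
                 reverse_partner = as.integer(reverse_partner)),
            class = "kmc_reaction")
}

.as_stoich <- function(x, what) {
  if (length(x) == 0) return(stats::setNames(integer(0), character(0)))
  if (is.null(names(x)) || any(names(x) == ""))
    stop(what, " must be a named vector (species -> count)")
  if (any(x != round(x)) || any(x < 0)) stop(what, " counts must be nonnegative integers")
  stats::setNames(as.integer(x), names(x))
}

#' Assemble a well-mixed reaction network
#'
#' Validates the fast/slow partition (disjoint, covering all channels, every
#' downscalable channel fast, symmetric reverse pairing), checks that the
#' declared conservation laws hold for the initial state, and precomputes the
#' stoichiometric update matrix and copy-number propensity constants used by
#' the simulation engine.
#'
#' @param species Ordered character vector of species names.
#' @param reactions List of [reaction()] objects, ordered by channel id.
#' @param fast,slow Integer vectors of channel ids forming a disjoint
#'   partition of all channels.
#' @param conversion Molecules-per-nM conversion factor used to turn
#'   concentration-based rate constants into copy-number propensities.
#' @param conservation List of `list(species =, total =)` invariants.
#' @param initial_state Named integer vector of initial copy numbers
#'   (unnamed species default to zero).
#' @param expected_ranking Optional user-provided ordering of channel ids from
#'   fastest to slowest, from a short trial run.
#' @return An object of class `kmc_network`.
#' @export
reaction_network <- function(species, reactions, fast, slow, conversion = 1,
                             conservation = list(), initial_state = NULL,
                             expected_ranking = NULL) {
  if (!is.numeric(conversion) || length(conversion) != 1 || conversion <= 0)
    stop("conversion must be a single positive number")
  nchan <- length(reactions)
  ids <- vapply(reactions, function(r) r$id, integer(1))
  if (!identical(ids, seq_len(nchan)))
    stop("reaction ids must be 1..", nchan, " in order")
  fast <- as.integer(fast); slow <- as.integer(slow)
  if (length(intersect(fast, slow)) > 0)
    stop("fast and slow sets overlap: channel(s) ",
         paste(intersect(fast, slow), collapse = ", "))
  if (!setequal(union(fast, slow), seq_len(nchan)))
    stop("fast and slow sets must partition all ", nchan, " channels")
  for (r in reactions) {
    unknown <- setdiff(c(names(r$reactants), names(r$products)), species)
    if (length(unknown) > 0)
      stop("unknown species in channel ", r$id, ": ", paste(unknown, collapse = ", "))
    if (r$downscalable) {
      if (!(r$id %in% fast))
        stop("downscalable channel ", r$id, " must be in the fast set")
      p <- r$reverse_partner
      if (is.na(p) || p < 1 || p > nchan)
        stop("downscalable channel ", r$id, " lacks a valid reverse_partner")
      partner <- reactions[[p]]
      if (!partner$downscalable || partner$reverse_partner != r$id)
        stop("reverse pairing of channels ", r$id, " and ", p, " is not symmetric")
    }
  }
  init <- stats::setNames(numeric(length(species)), species)
  if (!is.null(initial_state)) {
    unknown <- setdiff(names(initial_state), species)
    if (length(unknown) > 0)
      stop("initial_state has unknown species: ", paste(unknown, collapse = ", "))
    init[names(initial_state)] <- initial_state
  }
  if (any(init < 0) || any(init != round(init)))
    stop("initial populations must be nonnegative integers")
  for (cl in conservation) {
    if (length(setdiff(cl$species, species)) > 0)
      stop("conservation law refers to unknown species")
    if (sum(init[cl$species]) != cl$total)
      stop("conservation law ", paste(cl$species, collapse = "+"), " = ", cl$total,
           " is violated by the initial state (sum = ", sum(init[cl$species]), ")")
  }
  net <- structure(list(species = species, reactions = reactions,
                        fast = sort(fast), slow = sort(slow),
                        conversion = conversion, conservation = conservation,
                        initial_state = init, expected_ranking = expected_ranking,
                        cum_downscale = 1),
                   class = "kmc_network")
  .network_rebuild(net)
}

# precompute engine-facing matrices/constants (delta, kind codes, effective
# copy-number constants, reactant indices)
.network_rebuild <- function(net) {
  species <- net$species
  nchan <- length(net$reactions)
  delta <- matrix(0L, nrow = length(species), ncol = nchan,
                  dimnames = list(species, NULL))
  kind_code <- integer(nchan); ceff <- numeric(nchan)
  r1 <- integer(nchan); r2 <- integer(nchan)
  for (j in seq_len(nchan)) {
    r <- net$reactions[[j]]
    for (s in names(r$reactants)) delta[s, j] <- delta[s, j] - r$reactants[[s]]
    for (s in names(r$products)) delta[s, j] <- delta[s, j] + r$products[[s]]
    kc <- switch(r$kind, zeroth = 0L, unimolecular = 1L,
                 `bimolecular-distinct` = 2L, `bimolecular-identical` = 3L)
    kind_code[j] <- kc
    ceff[j] <- switch(r$kind,
                      zeroth = r$rate_constant * net$conversion,
                      unimolecular = r$rate_constant,
                      r$rate_constant / net$conversion)
    rs <- names(r$reactants)
    r1[j] <- if (length(rs) >= 1) match(rs[1], species) - 1L else 0L
    r2[j] <- if (r$kind == "bimolecular-distinct") match(rs[2], species) - 1L else 0L
  }
  net$.delta <- delta; net$.kind <- kind_code; net$.ceff <- ceff
  net$.r1 <- r1; net$.r2 <- r2
  net$.downscalable <- vapply(net$reactions, function(r) r$downscalable, logical(1))
  net
}

#' Mass-action propensity of one channel
#'
#' @param reaction A [reaction()] object.
#' @param populations Named vector of nonnegative integer copy numbers.
#' @param conversion Molecules-per-nM conversion factor (bimolecular and
#'   zeroth-order constants are concentration-based).
#' @return Probability per unit time (1/min) that the channel fires.
#' @export
propensity <- function(reaction, populations, conversion = 1) {
  if (any(populations < 0)) stop("negative population")
  n1 <- function() populations[[names(reaction$reactants)[1]]]
  switch(reaction$kind,
         zeroth = reaction$rate_constant * conversion,
         unimolecular = reaction$rate_constant * n1(),
         `bimolecular-identical` = reaction$rate_constant / conversion *
           n1() * (n1() - 1) / 2,
         `bimolecular-distinct` = {
           ns <- names(reaction$reactants)
           reaction$rate_constant / conversion *
             populations[[ns[1]]] * populations[[ns[2]]]
         })
}

#' Apply a reaction's stoichiometry to a population vector
#'
#' @inheritParams propensity
#' @return Updated population vector.
#' @export
apply_reaction <- function(populations, reaction) {
  for (s in names(reaction$reactants))
    populations[[s]] <- populations[[s]] - reaction$reactants[[s]]
  for (s in names(reaction$products))
    populations[[s]] <- populations[[s]] + reaction$products[[s]]
  if (any(populations < 0))
    stop("reaction drove a population negative; propensity guard failed upstream")
  populations
}

#' Divide the rate constants of all downscalable channels by a factor
#'
#' Only the downscalable (fast, reversible) channels are touched; the
#' cumulative absolute factor applied since construction is tracked in
#' `$cum_downscale`.
#'
#' @param network A [reaction_network()].
#' @param factor Downscale factor, `>= 1`.
#' @return The rescaled network.
#' @export
scale_rate_constants <- function(network, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || is.na(factor) || factor < 1)
    stop("downscale factor must be a single number >= 1")
  for (j in seq_along(network$reactions)) {
    if (network$reactions[[j]]$downscalable) {
      network$reactions[[j]]$rate_constant <-
        network$reactions[[j]]$rate_constant / factor
      network$.ceff[j] <- network$.ceff[j] / factor
    }
  }
  network$cum_downscale <- network$cum_downscale * factor
  network
}

#' Nominal parameter set of the benchmark oscillator
#'
#' The benchmark mimics a cell-cycle-like biochemical oscillator: a protein X
#' whose dimer X2 binds an operator O, boosting X production 333-fold
#' (positive feedback), and an inactive/active degrader pair Yi/Y: the dimer
#' activates Yi into Y and active Y degrades X (delayed negative feedback),
#' producing relaxation oscillations with a period near 200 min.  The
#' stiffness parameter `zeta` scales the dimerisation and operator-binding
#' constants phi = 9.77*zeta and chi = 3.91*zeta (1/nM/min), which together
#' with their reverse reactions form the fast, quasi-equilibrated channels.
#'
#' @param zeta Positive dimensionless time-scale-separation control.
#' @param conversion Molecules-per-nM factor mapping concentration-based
#'   constants to copy-number propensities (1 corresponds to a reaction
#'   volume of about 1.66 fL).
#' @return Named list of parameters.
#' @export
benchmark_parameters <- function(zeta = 100, conversion = 1) {
  if (!is.numeric(zeta) || length(zeta) != 1 || zeta <= 0)
    stop("zeta must be a single positive number")
  if (!is.numeric(conversion) || length(conversion) != 1 || conversion <= 0)
    stop("conversion must be a single positive number")
  list(O_total = 10, Y_total = 1035,
       k0 = 0.15,            # 1/min, basal X production from free operator
       k1 = 50,              # 1/min, boosted X production from bound operator
       k2 = 1.88e-3,         # 1/nM/min, activation Yi -> Y catalysed by X2
       phi = 9.77 * zeta,    # 1/nM/min, deterministic dimerisation rate of 2X -> X2
       chi = 3.91 * zeta,    # 1/nM/min, operator binding O + X2 -> OX2
       a = 159.37,           # nM, operator dissociation constant (reverse rate chi*a)
       b = 5.31,             # nM, dimer dissociation constant (reverse rate phi*b)
       lambda1 = 9.38e-3,    # 1/nM/min, degradation of X by active Y
       lambda2 = 0.01,       # 1/min, deactivation Y -> Yi
       zeta = zeta, conversion = conversion)
}

#' Build the 9-reaction benchmark oscillator network
#'
#' Six species (O, X, X2, OX2, Yi, Y) with conservation laws
#' O + OX2 = O_total and Y + Yi = Y_total; channels 3-6 (dimerisation and
#' operator binding with their reverses) are fast and downscalable, so the
#' only parameters a downscaling ever touches are phi and chi.  The initial
#' state is OX2 = O_total, Yi = Y_total and everything else zero.
#'
#' The dimerisation channel's stochastic rate constant is `2*phi`: a
#' deterministic rate phi*x^2 corresponds, under the exact n(n-1)/2 pairing
#' combinatorics, to a stochastic constant of 2*phi per volume (each firing
#' consumes one of n(n-1)/2 pairs, while the deterministic convention counts
#' n^2/2 ordered pairs twice).
#'
#' @inheritParams benchmark_parameters
#' @return A [reaction_network()].
#' @export
build_benchmark_network <- function(zeta = 100, conversion = 1) {
  p <- benchmark_parameters(zeta, conversion)
  rx <- list(
    reaction(1, c(O = 1), c(O = 1, X = 1), p$k0),
    reaction(2, c(OX2 = 1), c(OX2 = 1, X = 1), p$k1),
    reaction(3, c(X = 2), c(X2 = 1), 2 * p$phi, downscalable = TRUE, reverse_partner = 4),
    reaction(4, c(X2 = 1), c(X = 2), p$phi * p$b, downscalable = TRUE, reverse_partner = 3),
    reaction(5, c(O = 1, X2 = 1), c(OX2 = 1), p$chi, downscalable = TRUE, reverse_partner = 6),
    reaction(6, c(OX2 = 1), c(O = 1, X2 = 1), p$chi * p$a, downscalable = TRUE, reverse_partner = 5),
    reaction(7, c(X2 = 1, Yi = 1), c(X2 = 1, Y = 1), p$k2),
    reaction(8, c(X = 1, Y = 1), c(Y = 1), p$lambda1),
    reaction(9, c(Y = 1), c(Yi = 1), p$lambda2))
  reaction_network(
    species = c("O", "X", "X2", "OX2", "Yi", "Y"),
    reactions = rx,
    fast = 3:6, slow = c(1, 2, 7, 8, 9),
    conversion = conversion,
    conservation = list(list(species = c("O", "OX2"), total = p$O_total),
                        list(species = c("Y", "Yi"), total = p$Y_total)),
    initial_state = c(OX2 = p$O_total, Yi = p$Y_total),
    expected_ranking = c(5, 6, 3, 4, 2, 8, 7, 9, 1))
}

#' @export
print.kmc_network <- function(x, ...) {
  cat("kmc_network:", length(x$species), "species,", length(x$reactions),
      "channels (fast:", paste(x$fast, collapse = ","), ")\n")
  cat("  conversion:", x$conversion, "molecules/nM; cumulative downscale:",
      x$cum_downscale, "\n")
  invisible(x)
}
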