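#' Read a reaction network from a YAML config file
#'
#' The config is a plain-text YAML document with fields `species`,
#' `conversion`, `reactions` (each with `reactants`, `products`,
#' `rate_constant`, optional `kind`/`downscalable`/`reverse_partner`),
#' `fast`, `slow`, `downscalable_pairs`, `conservation`, `initial_state`
#' and optional `expected_ranking`.  All structural invariants (symmetric
#' reverse pairs, disjoint fast/slow partition, conservation laws at the
#' initial state) are validated on read; `write_network_config()` followed
#' by `read_network_config()` is the identity on the semantic content.
#'
#' @param path Path to the config file.
#' @return A [reaction_network()].
#' @export
read_network_config <- function(path) {
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("cannot parse ", path, ": ",
                                           conditionMessage(e)))
  need <- c("species", "reactions", "fast", "slow")
  miss <- setdiff(need, names(doc))
  if (length(miss) > 0)
    stop(path, ": missing required field(s): ", paste(miss, collapse = ", "))
  pairs <- doc$downscalable_pairs %||% list()
  pair_fwd <- vapply(pairs, function(p) as.integer(p[[1]]), integer(1))
  pair_rev <- vapply(pairs, function(p) as.integer(p[[2]]), integer(1))
  partner <- function(id) {
    if (id %in% pair_fwd) return(pair_rev[match(id, pair_fwd)])
    if (id %in% pair_rev) return(pair_fwd[match(id, pair_rev)])
    NA_integer_
  }
  rx <- lapply(seq_along(doc$reactions), function(j) {
    r <- doc$reactions[[j]]
    id <- as.integer(r$id %||% j)
    tryCatch(
      reaction(id,
               reactants = unlist(r$reactants %||% list()),
               products = unlist(r$products %||% list()),
               rate_constant = as.numeric(r$rate_constant),
               kind = r$kind,
               downscalable = isTRUE(r$downscalable) || !is.na(partner(id)),
               reverse_partner = partner(id)),
      error = function(e) stop(path, ", reaction entry ", j, ": ",
                               conditionMessage(e)))
  })
  cons <- lapply(doc$conservation %||% list(), function(cl)
    list(species = as.character(unlist(cl$species)), total = as.numeric(cl$total)))
  init <- unlist(doc$initial_state %||% list())
  reaction_network(species = as.character(unlist(doc$species)),
                   reactions = rx,
                   fast = unlist(doc$fast), slow = unlist(doc$slow),
                   conversion = as.numeric(doc$conversion %||% 1),
                   conservation = cons,
                   initial_state = init,
                   expected_ranking = if (!is.null(doc$expected_ranking))
                     as.integer(unlist(doc$expected_ranking)))
}

#' Write a reaction network to a YAML config file
#'
#' @param network A [reaction_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_config <- function(network, path) {
  pairs <- list()
  for (r in network$reactions)
    if (r$downscalable && r$id < r$reverse_partner)
      pairs[[length(pairs) + 1]] <- c(r$id, r$reverse_partner)
  doc <- list(
    species = as.list(network$species),
    conversion = network$conversion,
    reactions = lapply(network$reactions, function(r) {
      list(id = r$id, reactants = as.list(r$reactants),
           products = as.list(r$products),
           rate_constant = r$rate_constant, kind = r$kind)
    }),
    fast = as.list(network$fast), slow = as.list(network$slow),
    downscalable_pairs = pairs,
    conservation = lapply(network$conservation, function(cl)
      list(species = as.list(cl$species), total = cl$total)),
    initial_state = as.list(network$initial_state[network$initial_state > 0]))
  if (!is.null(network$expected_ranking))
    doc$expected_ranking <- as.list(network$expected_ranking)
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
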