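#' Construct a metabolite
#'
#' @param id unique token identifying the metabolite within a network.
#' @param name human-readable name.
#' @param compartment compartment token; the conventional set is
#'   \code{ext}, \code{cyto}, \code{mito}, \code{lyso}, \code{peroxy},
#'   \code{micro} (microsome lumps ER and Golgi), but user-defined
#'   compartments are allowed.
#' @param formula optional elemental formula string.
#' @return a list of class \code{metabolite}.
#' @export
metabolite <- function(id, name = id, compartment = "cyto", formula = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  structure(list(id = id, name = name, compartment = compartment,
                 formula = formula), class = "metabolite")
}

#' Construct a reaction
#'
#' Exchange reactions are single-metabolite columns. Sign convention:
#' a designated uptake exchange has coefficient +1 (positive flux brings the
#' metabolite into the system), a release exchange has -1 (positive flux =
#' secretion). The tri-state exchange codes used in constraint tables map to
#' the \code{allowed_uptake}/\code{allowed_secretion} flags.
#'
#' @param id unique reaction token.
#' @param stoichiometry named numeric vector, metabolite id -> signed
#'   coefficient (negative = consumed).
#' @param reversible logical; irreversible reactions must have
#'   \code{lower_bound >= 0}.
#' @param lower_bound,upper_bound flux bounds in mmol.min^-1.(l cell)^-1.
#' @param is_exchange,is_transport structural flags.
#' @param allowed_uptake,allowed_secretion exchange direction annotations.
#' @return a list of class \code{reaction}.
#' @export
reaction <- function(id, stoichiometry, reversible = FALSE,
                     lower_bound = if (reversible) -default_flux_bound() else 0,
                     upper_bound = default_flux_bound(),
                     is_exchange = FALSE, is_transport = FALSE,
                     allowed_uptake = NA, allowed_secretion = NA) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!length(stoichiometry) || is.null(names(stoichiometry)))
    stop("reaction '", id, "': stoichiometry must be a non-empty named vector")
  if (lower_bound > upper_bound)
    stop("reaction '", id, "': lower_bound > upper_bound")
  if (!reversible && lower_bound < 0)
    stop("reaction '", id, "': irreversible reaction with negative lower bound")
  structure(list(id = id, stoichiometry = stoichiometry, reversible = reversible,
                 lower_bound = lower_bound, upper_bound = upper_bound,
                 is_exchange = is_exchange, is_transport = is_transport,
                 allowed_uptake = allowed_uptake,
                 allowed_secretion = allowed_secretion),
            class = "reaction")
}

#' Default cap for otherwise unconstrained fluxes
#'
#' 1000 mmol.min^-1.(l cell)^-1, the conventional COBRA-style bound.
#' @return a single number.
#' @export
default_flux_bound <- function() 1000

#' Construct and validate a metabolic network
#'
#' @param metabolites list of [metabolite()] objects.
#' @param reactions list of [reaction()] objects.
#' @param compartments character vector of compartment tokens; defaults to
#'   those used by the metabolites.
#' @param annotations free-form named list.
#' @return an object of class \code{metabolic_network}.
#' @export
metabolic_network <- function(metabolites, reactions, compartments = NULL,
                              annotations = list()) {
  met_ids <- vapply(metabolites, function(m) m$id, character(1))
  if (anyDuplicated(met_ids)) stop("duplicate metabolite ids")
  rxn_ids <- vapply(reactions, function(r) r$id, character(1))
  if (anyDuplicated(rxn_ids)) stop("duplicate reaction ids")
  comps <- unique(vapply(metabolites, function(m) m$compartment, character(1)))
  if (is.null(compartments)) compartments <- comps
  if (length(setdiff(comps, compartments)))
    stop("metabolite compartment(s) not declared: ",
         paste(setdiff(comps, compartments), collapse = ", "))
  for (r in reactions) {
    bad <- setdiff(names(r$stoichiometry), met_ids)
    if (length(bad))
      stop("reaction '", r$id, "' references undeclared metabolite(s): ",
           paste(bad, collapse = ", "))
  }
  names(metabolites) <- met_ids
  names(reactions) <- rxn_ids
  structure(list(metabolites = metabolites, reactions = reactions,
                 compartments = compartments, annotations = annotations),
            class = "metabolic_network")
}

metabolite_ids <- function(network) names(network$metabolites)
reaction_ids <- function(network) names(network$reactions)

#' Build the stoichiometric matrix N
#'
#' Rows are metabolites (in declaration order), columns reactions (in
#' declaration order); entry (i, j) is the signed coefficient of metabolite i
#' in reaction j. The steady-state condition of flux balance analysis is
#' \code{N \%*\% v = 0}.
#'
#' @param network a [metabolic_network()].
#' @return a dense numeric matrix with dimnames.
#' @export
stoich_matrix <- function(network) {
  mets <- metabolite_ids(network)
  rxns <- reaction_ids(network)
  N <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (j in seq_along(network$reactions)) {
    s <- network$reactions[[j]]$stoichiometry
    bad <- setdiff(names(s), mets)
    if (length(bad))
      stop("reaction '", rxns[j], "' references unresolved metabolite(s): ",
           paste(bad, collapse = ", "))
    N[names(s), j] <- s
  }
  N
}

reaction_bounds <- function(network) {
  lb <- vapply(network$reactions, function(r) r$lower_bound, numeric(1))
  ub <- vapply(network$reactions, function(r) r$upper_bound, numeric(1))
  list(lower = lb, upper = ub)
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("Metabolic network:", length(x$metabolites), "metabolites,",
      length(x$reactions), "reactions,",
      length(x$compartments), "compartments\n")
  invisible(x)
}

#' Summarize a network (counts of reactions, transporters, metabolites)
#'
#' @param object a [metabolic_network()].
#' @param ... unused.
#' @return a one-row data frame with columns \code{compartments},
#'   \code{reactions}, \code{transporters}, \code{metabolites}.
#' @export
summary.metabolic_network <- function(object, ...) {
  data.frame(
    compartments = length(object$compartments),
    reactions = length(object$reactions),
    transporters = sum(vapply(object$reactions, function(r)
      isTRUE(r$is_transport), logical(1))),
    metabolites = length(object$metabolites)
  )
}

#' Export the network summary as TSV
#'
#' @param network a [metabolic_network()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_network_summary <- function(network, path) {
  utils::write.table(summary(network), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Find dead-end metabolites
#'
#' A dead end is a metabolite that is only produced or only consumed across
#' all reactions; reversible reactions count as both producer and consumer of
#' every metabolite they touch.
#'
#' @param network a [metabolic_network()].
#' @return character vector of metabolite ids.
#' @export
find_deadend_metabolites <- function(network) {
  produced <- consumed <- character(0)
  for (r in network$reactions) {
    s <- r$stoichiometry
    p <- names(s)[s > 0]; c_ <- names(s)[s < 0]
    if (r$reversible) { p <- names(s); c_ <- names(s) }
    produced <- c(produced, p); consumed <- c(consumed, c_)
  }
  ids <- metabolite_ids(network)
  touched <- ids[ids %in% c(produced, consumed)]
  dead <- touched[!(touched %in% produced) | !(touched %in% consumed)]
  sort(dead)
}

#' Find blocked reactions
#'
#' A reaction is blocked if its flux is zero in every steady-state solution
#' given the allowed exchange reactions: both its maximum and minimum flux
#' over the steady-state polytope are zero within tolerance. Exchanges not
#' listed in \code{open_exchanges} are closed (bounds set to zero).
#'
#' @param network a [metabolic_network()].
#' @param open_exchanges character vector of exchange reaction ids left open.
#' @param tol flux magnitude below which a reaction counts as silent.
#' @return character vector of blocked reaction ids. If the base problem is
#'   infeasible all reactions are returned, with a warning.
#' @export
find_blocked_reactions <- function(network, open_exchanges = character(0),
                                   tol = 1e-6) {
  rxns <- reaction_ids(network)
  bad <- setdiff(open_exchanges, rxns)
  if (length(bad)) stop("unknown exchange reaction(s): ", paste(bad, collapse = ", "))
  N <- stoich_matrix(network)
  bnds <- reaction_bounds(network)
  lb <- bnds$lower; ub <- bnds$upper
  is_ex <- vapply(network$reactions, function(r) isTRUE(r$is_exchange), logical(1))
  close <- is_ex & !(rxns %in% open_exchanges)
  lb[close] <- 0; ub[close] <- 0

  n <- length(rxns)
  base <- lp_solve(rep(0, n), N, rep("=", nrow(N)), rep(0, nrow(N)), lb, ub)
  if (base$status != "optimal") {
    warning("base steady-state problem infeasible; reporting all reactions blocked")
    return(rxns)
  }
  blocked <- character(0)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- 1
    vmax <- lp_solve(-e, N, rep("=", nrow(N)), rep(0, nrow(N)), lb, ub)
    if (vmax$status == "optimal" && -vmax$objval > tol) next
    vmin <- lp_solve(e, N, rep("=", nrow(N)), rep(0, nrow(N)), lb, ub)
    if (vmin$status == "optimal" && vmin$objval < -tol) next
    blocked <- c(blocked, rxns[j])
  }
  blocked
}
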