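#' Define a metabolic-function feasibility test
#'
#' A function test constrains the exchangeable metabolites (which may be
#' taken up, which secreted — the +/-/= exchange codes of constraint tables)
#' and demands minimum fluxes through one or more objective reactions; the
#' network passes if a steady-state flux distribution exists under those
#' constraints.
#'
#' @param name test name.
#' @param category free-text classification (e.g. carbohydrate / lipid /
#'   nucleotide function groups).
#' @param allowed_uptakes metabolite ids whose uptake exchanges stay open.
#' @param allowed_secretions metabolite ids whose release exchanges stay
#'   open.
#' @param objective named numeric vector: reaction id -> minimum demanded
#'   flux (non-empty).
#' @return a list of class \code{function_test}.
#' @export
function_test <- function(name, category = "",
                          allowed_uptakes = character(0),
                          allowed_secretions = character(0),
                          objective) {
  if (!length(objective) || is.null(names(objective)))
    stop("objective must be a non-empty named vector")
  structure(list(name = name, category = category,
                 allowed_uptakes = allowed_uptakes,
                 allowed_secretions = allowed_secretions,
                 objective = objective),
            class = "function_test")
}

## exchange bounds under a test's exchange settings
.test_bounds <- function(network, ups, secs) {
  bnds <- reaction_bounds(network)
  lb <- bnds$lower; ub <- bnds$upper
  rxns <- reaction_ids(network)
  for (j in seq_along(network$reactions)) {
    r <- network$reactions[[j]]
    if (!isTRUE(r$is_exchange)) next
    met <- names(r$stoichiometry)[1]
    coef <- r$stoichiometry[[1]]
    open_up <- met %in% ups
    open_sec <- met %in% secs
    ## +1 column: positive flux = uptake; -1 column: positive flux = secretion
    ok <- if (coef > 0) open_up else open_sec
    if (!ok) { lb[j] <- 0; ub[j] <- 0 }
  }
  list(lower = lb, upper = ub)
}

#' Run a battery of function tests against a network
#'
#' Each test is solved as a feasibility LP (steady state, the test's
#' exchange settings, objective reactions bounded below by their demanded
#' fluxes). Tests referencing reactions absent from the network are reported
#' as \code{not_applicable}, not failed.
#'
#' @param network a [metabolic_network()].
#' @param tests list of [function_test()] objects.
#' @return a data frame of class \code{function_battery_report} (columns
#'   \code{name}, \code{category}, \code{status}) with attributes
#'   \code{witnesses} (named list of flux vectors for feasible tests) and
#'   \code{exit_code} (0 iff no test infeasible).
#' @export
run_function_battery <- function(network, tests) {
  N <- stoich_matrix(network)
  rxns <- colnames(N)
  res <- data.frame(name = character(0), category = character(0),
                    status = character(0), stringsAsFactors = FALSE)
  witnesses <- list()
  for (tt in tests) {
    stopifnot(inherits(tt, "function_test"))
    if (length(setdiff(names(tt$objective), rxns))) {
      res[nrow(res) + 1L, ] <- list(tt$name, tt$category, "not_applicable")
      next
    }
    b <- .test_bounds(network, tt$allowed_uptakes, tt$allowed_secretions)
    lb <- b$lower; ub <- b$upper
    for (id in names(tt$objective)) {
      j <- match(id, rxns)
      lb[j] <- max(lb[j], tt$objective[[id]])
      if (lb[j] > ub[j]) ub[j] <- lb[j]
    }
    s <- lp_solve(numeric(length(rxns)), N, rep("=", nrow(N)),
                  rep(0, nrow(N)), lb, ub)
    st <- if (s$status == "optimal") "feasible" else "infeasible"
    res[nrow(res) + 1L, ] <- list(tt$name, tt$category, st)
    if (st == "feasible")
      witnesses[[tt$name]] <- stats::setNames(s$x, rxns)
  }
  class(res) <- c("function_battery_report", "data.frame")
  attr(res, "witnesses") <- witnesses
  attr(res, "exit_code") <- if (any(res$status == "infeasible")) 1L else 0L
  res
}

#' @export
print.function_battery_report <- function(x, ...) {
  cat("Function battery:", nrow(x), "tests —",
      sum(x$status == "feasible"), "feasible,",
      sum(x$status == "infeasible"), "infeasible,",
      sum(x$status == "not_applicable"), "not applicable\n")
  NextMethod()
}

#' Prune a network to its functional subnetwork
#'
#' Removes the reactions that are blocked under the union of the tests'
#' exchange settings and asserts that every test remains feasible on the
#' pruned network — mirroring the functional-pruning step that reduces a
#' reconstruction to a subnetwork free of dead ends and blocked reactions.
#'
#' @param network a [metabolic_network()].
#' @param tests list of [function_test()]s, all feasible on the input.
#' @return the pruned [metabolic_network()].
#' @export
prune_to_functional_subnetwork <- function(network, tests) {
  before <- run_function_battery(network, tests)
  if (any(before$status == "infeasible"))
    stop("all tests must be feasible on the input network")
  ups <- unique(unlist(lapply(tests, function(t) t$allowed_uptakes)))
  secs <- unique(unlist(lapply(tests, function(t) t$allowed_secretions)))
  rxns <- reaction_ids(network)
  open <- rxns[vapply(seq_along(network$reactions), function(j) {
    r <- network$reactions[[j]]
    if (!isTRUE(r$is_exchange)) return(FALSE)
    met <- names(r$stoichiometry)[1]
    if (r$stoichiometry[[1]] > 0) met %in% ups else met %in% secs
  }, logical(1))]
  blocked <- find_blocked_reactions(network, open_exchanges = open)
  keep <- setdiff(rxns, blocked)
  pruned <- metabolic_network(network$metabolites,
                              unname(network$reactions[keep]),
                              compartments = network$compartments,
                              annotations = network$annotations)
  after <- run_function_battery(pruned, tests)
  if (any(after$status != "feasible"))
    stop("internal error: pruning broke test(s) ",
         paste(after$name[after$status != "feasible"], collapse = ", "))
  pruned
}

#' Read a function-test battery from JSON
#'
#' @param path JSON file: an array of objects with fields \code{name},
#'   \code{category}, \code{allowed_uptakes}, \code{allowed_secretions} and
#'   \code{objective} (map reaction id -> minimum flux).
#' @return list of [function_test()] objects.
#' @export
read_battery_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(doc, function(t)
    function_test(t$name, t$category %||% "",
                  allowed_uptakes = unlist(t$allowed_uptakes) %||% character(0),
                  allowed_secretions = unlist(t$allowed_secretions) %||% character(0),
                  objective = unlist(t$objective)))
}
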