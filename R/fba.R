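#' Define a flux-minimization problem
#'
#' Bundles a network with the fixed metabolic target fluxes, the set of
#' substrate uptake reactions whose sum is the total substrate uptake rate
#' v_s, the oxygen uptake reaction, and an optional substrate composition.
#' For networks produced by [build_core_network()] the uptake set, oxygen id
#' and target fluxes default to the values recorded in the network
#' annotations.
#'
#' @param network a [metabolic_network()].
#' @param target_fluxes named numeric vector of reaction fluxes pinned as
#'   equality constraints (the demanded metabolic target, e.g.
#'   \code{c(atpase = 21.6)}).
#' @param uptake_set ordered character vector of substrate uptake reaction
#'   ids (the v_m).
#' @param oxygen_id id of the oxygen uptake reaction (v_O2); must not be in
#'   \code{uptake_set}.
#' @param composition optional [composition()] giving the relative share
#'   beta_m of each substrate in v_s.
#' @param extra_bounds named list of length-2 numeric vectors overriding
#'   reaction bounds.
#' @param minimize_total_flux run the second, flux-minimization stage
#'   (minimize sum |v| with the stage-1 optimum pinned)? Default TRUE.
#' @return an object of class \code{flux_problem}.
#' @export
flux_problem <- function(network, target_fluxes = NULL, uptake_set = NULL,
                         oxygen_id = NULL, composition = NULL,
                         extra_bounds = list(), minimize_total_flux = TRUE) {
  ann <- network$annotations
  if (is.null(uptake_set)) uptake_set <- ann$uptake_set
  if (is.null(oxygen_id)) oxygen_id <- ann$oxygen_id
  if (is.null(target_fluxes)) {
    opts <- ann$options
    if (is.null(opts)) stop("target_fluxes required for this network")
    target_fluxes <- c(atpase = opts$atpase_demand)
    if (isTRUE(opts$include_lipid_targets)) {
      tf <- unlist(opts$target_fluxes)
      names(tf) <- paste0("target_", names(tf))
      target_fluxes <- c(target_fluxes, tf)
    }
  }
  rxns <- reaction_ids(network)
  bad <- setdiff(c(names(target_fluxes), uptake_set, oxygen_id,
                   names(extra_bounds)), rxns)
  if (length(bad)) stop("unknown reaction id(s): ", paste(bad, collapse = ", "))
  if (!length(uptake_set)) stop("uptake_set must be non-empty")
  if (oxygen_id %in% uptake_set)
    stop("oxygen_id must not be part of uptake_set")
  if (!is.null(composition)) {
    bad <- setdiff(names(composition$betas), uptake_set)
    if (length(bad)) stop("composition references unknown uptake(s): ",
                          paste(bad, collapse = ", "))
  }
  structure(list(network = network, target_fluxes = target_fluxes,
                 uptake_set = uptake_set, oxygen_id = oxygen_id,
                 composition = composition, extra_bounds = extra_bounds,
                 minimize_total_flux = minimize_total_flux),
            class = "flux_problem")
}

## Assemble the stage-1 LP: variables are the network reactions plus one
## auxiliary column for v_s (the total substrate uptake). Returns the pieces
## needed by lp_solve plus index bookkeeping.
.assemble_lp <- function(problem) {
  net <- problem$network
  N <- stoich_matrix(net)
  rxns <- colnames(N)
  n <- length(rxns)
  bnds <- reaction_bounds(net)
  lb <- bnds$lower; ub <- bnds$upper
  for (id in names(problem$extra_bounds)) {
    j <- match(id, rxns)
    lb[j] <- problem$extra_bounds[[id]][1]
    ub[j] <- problem$extra_bounds[[id]][2]
  }
  for (id in names(problem$target_fluxes)) {
    j <- match(id, rxns)
    lb[j] <- ub[j] <- problem$target_fluxes[[id]]
  }
  up_j <- match(problem$uptake_set, rxns)
  o2_j <- match(problem$oxygen_id, rxns)

  vs_col <- n + 1L
  A <- cbind(N, 0)
  dir <- rep("=", nrow(N))
  rhs <- rep(0, nrow(N))
  ## v_s - sum(v_m) = 0
  link <- numeric(vs_col); link[up_j] <- -1; link[vs_col] <- 1
  A <- rbind(A, link); dir <- c(dir, "="); rhs <- c(rhs, 0)
  ## additional single-flux equality pins (alternate-optima re-constraining);
  ## expressed as rows so they can contradict target pins and trigger
  ## infeasibility rather than silently replacing them
  for (id in names(problem$pinned)) {
    j <- match(id, rxns)
    row <- numeric(vs_col); row[j] <- 1
    A <- rbind(A, row); dir <- c(dir, "=")
    rhs <- c(rhs, problem$pinned[[id]])
  }
  ## composition coupling v_m - beta_m v_s = 0 ; beta = 0 pins the uptake
  comp <- problem$composition
  if (!is.null(comp)) {
    for (m in names(comp$betas)) {
      b <- comp$betas[[m]]
      j <- match(m, rxns)
      if (b == 0) { lb[j] <- 0; ub[j] <- 0 } else {
        row <- numeric(vs_col); row[j] <- 1; row[vs_col] <- -b
        A <- rbind(A, row); dir <- c(dir, "="); rhs <- c(rhs, 0)
      }
    }
  }
  lb <- c(lb, 0)
  ub <- c(ub, sum(pmax(ub[up_j], 0)))
  list(A = unname(A), dir = dir, rhs = rhs, lb = lb, ub = ub,
       rxns = rxns, n = n, vs_col = vs_col, o2_j = o2_j)
}

.stage1_objective <- function(lp) {
  obj <- numeric(lp$vs_col)
  obj[lp$vs_col] <- 1
  obj[lp$o2_j] <- obj[lp$o2_j] + 1
  obj
}

.empty_distribution <- function(status) {
  structure(list(fluxes = numeric(0), objective = NA_real_, status = status,
                 vs = NA_real_, vO2 = NA_real_, vGL = NA_real_,
                 vGS = NA_real_), class = "flux_distribution")
}

.make_distribution <- function(problem, lp, x, objective) {
  fluxes <- stats::setNames(x[seq_len(lp$n)], lp$rxns)
  get0 <- function(id) if (id %in% lp$rxns) unname(fluxes[id]) else 0
  structure(list(fluxes = fluxes, objective = objective, status = "optimal",
                 vs = sum(fluxes[problem$uptake_set]),
                 vO2 = unname(fluxes[problem$oxygen_id]),
                 vGL = get0("glycogenolysis"),
                 vGS = get0("glycogen_synthesis")),
            class = "flux_distribution")
}

#' Solve the flux-minimization problem
#'
#' Stage 1 minimizes the total substrate plus oxygen uptake (v_s + v_O2)
#' subject to steady state N v = 0, flux bounds, pinned target fluxes and,
#' when a composition is set, the coupling v_m = beta_m v_s. Stage 2
#' re-solves minimizing the total absolute flux sum |v| over all reactions
#' (reversible fluxes split into nonnegative forward/backward parts) with
#' the stage-1 optimum pinned within an absolute slack of 1e-7 — the
#' flux-minimization tiebreak that selects a parsimonious distribution among
#' the degenerate stage-1 optima. Set \code{minimize_total_flux = FALSE} on
#' the problem to return the stage-1 solution directly.
#'
#' @param problem a [flux_problem()].
#' @return a \code{flux_distribution}: named \code{fluxes}, \code{objective}
#'   (v_s + v_O2), \code{status} (\code{optimal}/\code{infeasible}/
#'   \code{unbounded}) and the convenience rates \code{vs}, \code{vO2},
#'   \code{vGL}, \code{vGS}.
#' @export
minimize_uptake <- function(problem) {
  stopifnot(inherits(problem, "flux_problem"))
  lp <- .assemble_lp(problem)
  obj1 <- .stage1_objective(lp)
  s1 <- lp_solve(obj1, lp$A, lp$dir, lp$rhs, lp$lb, lp$ub)
  if (s1$status != "optimal") return(.empty_distribution(s1$status))
  opt <- s1$objval
  if (!isTRUE(problem$minimize_total_flux))
    return(.make_distribution(problem, lp, s1$x, opt))

  ## stage 2: split columns with negative lower bounds, minimize sum|v|
  nv <- lp$vs_col
  split_j <- which(lp$lb[seq_len(lp$n)] < 0)
  n2 <- nv + length(split_j)
  A2 <- cbind(lp$A, -lp$A[, split_j, drop = FALSE])
  lb2 <- c(pmax(lp$lb, 0), pmax(-lp$ub[split_j], 0))
  ub2 <- c(lp$ub, -lp$lb[split_j])
  ub2[split_j] <- pmax(lp$ub[split_j], 0)
  ## pin stage-1 objective
  pin <- c(obj1, -obj1[split_j])
  A2 <- rbind(A2, pin, pin)
  dir2 <- c(lp$dir, "<=", ">=")
  rhs2 <- c(lp$rhs, opt + 1e-7, opt - 1e-7)
  obj2 <- c(rep(1, lp$n), 0, rep(1, length(split_j)))
  s2 <- lp_solve(obj2, A2, dir2, rhs2, lb2, ub2)
  if (s2$status != "optimal") {
    warning("flux-minimization stage infeasible; returning stage-1 solution")
    return(.make_distribution(problem, lp, s1$x, opt))
  }
  x <- s2$x[seq_len(nv)]
  x[split_j] <- x[split_j] - s2$x[nv + seq_along(split_j)]
  .make_distribution(problem, lp, x, sum(obj1 * x))
}

#' Is the problem feasible?
#'
#' Checks stage-1 feasibility only; no flux distribution is computed.
#'
#' @param problem a [flux_problem()].
#' @return TRUE/FALSE.
#' @export
check_feasible <- function(problem) {
  lp <- .assemble_lp(problem)
  s <- lp_solve(numeric(lp$vs_col), lp$A, lp$dir, lp$rhs, lp$lb, lp$ub)
  s$status == "optimal"
}

#' Flux range at the uptake optimum
#'
#' Minimum and maximum of one reaction's flux over all solutions attaining
#' the stage-1 optimal v_s + v_O2 (within an absolute slack of 1e-7). A zero
#' width identifies a uniquely determined flux.
#'
#' @param problem a [flux_problem()].
#' @param reaction_id reaction to analyse.
#' @param optimum optional precomputed stage-1 optimum; computed if NULL.
#' @return named numeric \code{c(min, max)}.
#' @export
flux_range <- function(problem, reaction_id, optimum = NULL) {
  lp <- .assemble_lp(problem)
  j <- match(reaction_id, lp$rxns)
  if (is.na(j)) stop("unknown reaction: ", reaction_id)
  obj1 <- .stage1_objective(lp)
  if (is.null(optimum)) {
    s1 <- lp_solve(obj1, lp$A, lp$dir, lp$rhs, lp$lb, lp$ub)
    if (s1$status != "optimal")
      stop("stage-1 problem is ", s1$status)
    optimum <- s1$objval
  }
  A <- rbind(lp$A, obj1, obj1)
  dir <- c(lp$dir, "<=", ">=")
  rhs <- c(lp$rhs, optimum + 1e-7, optimum - 1e-7)
  e <- numeric(lp$vs_col); e[j] <- 1
  lo <- lp_solve(e, A, dir, rhs, lp$lb, lp$ub)
  hi <- lp_solve(-e, A, dir, rhs, lp$lb, lp$ub)
  if (lo$status != "optimal" || hi$status != "optimal")
    stop("flux_range subproblem not optimal: ", lo$status, "/", hi$status)
  c(min = lo$objval, max = -hi$objval)
}

#' Maximal ATP yield per unit of substrate uptake
#'
#' Fixes one substrate uptake at a reference rate (all other substrate
#' uptakes closed), leaves oxygen free, and maximizes the flux through the
#' ATP drain at steady state. On a core network built from a yield table
#' this recovers the table's ATP yield exactly.
#'
#' @param network a [metabolic_network()] with uptake annotations (or pass
#'   \code{uptake_set} explicitly).
#' @param uptake_id the substrate uptake exchange to probe.
#' @param drain_id the ATP drain reaction (default \code{"atpase"}).
#' @param uptake reference uptake rate (default 1).
#' @param uptake_set all substrate uptake ids; defaults to the network
#'   annotation.
#' @return maximal drain flux per \code{uptake} units of substrate.
#' @export
max_atp_yield <- function(network, uptake_id, drain_id = "atpase",
                          uptake = 1, uptake_set = NULL) {
  if (is.null(uptake_set)) uptake_set <- network$annotations$uptake_set
  N <- stoich_matrix(network)
  rxns <- colnames(N)
  if (!all(c(uptake_id, drain_id) %in% rxns))
    stop("unknown reaction id(s)")
  bnds <- reaction_bounds(network)
  lb <- bnds$lower; ub <- bnds$upper
  for (id in uptake_set) {
    j <- match(id, rxns)
    v <- if (id == uptake_id) uptake else 0
    lb[j] <- v; ub[j] <- v
  }
  e <- numeric(length(rxns)); e[match(drain_id, rxns)] <- -1
  r <- lp_solve(e, N, rep("=", nrow(N)), rep(0, nrow(N)), lb, ub)
  if (r$status != "optimal") stop("yield problem is ", r$status)
  -r$objval
}

#' @export
print.flux_distribution <- function(x, digits = 4, ...) {
  cat("Flux distribution (", x$status, ")\n", sep = "")
  if (x$status == "optimal") {
    cat(sprintf("  objective (vs + vO2): %.*f\n", digits, x$objective))
    cat(sprintf("  vs = %.*f  vO2 = %.*f  vGL = %.*f  vGS = %.*f\n",
                digits, x$vs, digits, x$vO2, digits, x$vGL, digits, x$vGS))
    cat("  nonzero fluxes:", sum(abs(x$fluxes) > 1e-9), "of",
        length(x$fluxes), "\n")
  }
  invisible(x)
}

#' Write a flux distribution as TSV (reaction id, flux)
#'
#' @param dist a \code{flux_distribution}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_flux_tsv <- function(dist, path) {
  utils::write.table(
    data.frame(reaction = names(dist$fluxes), flux = unname(dist$fluxes)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Steady-state residual of a solved distribution
#'
#' @param network the network the distribution was solved on.
#' @param dist a \code{flux_distribution}.
#' @return max |N v|.
#' @export
steady_state_residual <- function(network, dist) {
  N <- stoich_matrix(network)
  max(abs(N %*% dist$fluxes[colnames(N)]))
}
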