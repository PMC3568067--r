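# Independent oracles used across the suite.

# LP oracle built on boot::simplex (an implementation unrelated to the
# package's solver): min obj'x s.t. mat x (dir) rhs, lower <= x <= upper.
oracle_lp <- function(obj, mat, dir, rhs, lower, upper) {
  n <- length(obj)
  if (is.null(mat)) mat <- matrix(0, 0, n)
  shift <- lower
  rhs2 <- rhs - as.numeric(mat %*% shift)
  A1 <- diag(n); b1 <- upper - lower            # y <= ub - lb
  A2 <- NULL; b2 <- NULL
  A3 <- NULL; b3 <- NULL
  add <- function(M, row) if (is.null(M)) matrix(row, 1) else rbind(M, row)
  for (i in seq_along(dir)) {
    row <- mat[i, ]; b <- rhs2[i]; d <- dir[i]
    if (b < 0) {  # boot::simplex requires nonnegative rhs
      row <- -row; b <- -b
      d <- switch(d, "<=" = ">=", ">=" = "<=", "=" = "=")
    }
    if (d == "<=") { A1 <- rbind(A1, row); b1 <- c(b1, b) }
    else if (d == ">=") { A2 <- add(A2, row); b2 <- c(b2, b) }
    else { A3 <- add(A3, row); b3 <- c(b3, b) }
  }
  r <- boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                     A3 = A3, b3 = b3, maxi = FALSE, eps = 1e-10)
  if (r$solved == 1)
    list(status = "optimal", x = as.numeric(r$soln) + shift,
         objval = unname(r$value) + sum(obj * shift))
  else if (r$solved == 0) list(status = "unbounded", x = NULL, objval = NULL)
  else list(status = "infeasible", x = NULL, objval = NULL)
}

# Brute-force flux variability via the oracle LP: per-reaction min and max
# over the steady-state polytope with closed non-open exchanges.
oracle_blocked <- function(network, open_exchanges, tol = 1e-6) {
  N <- stoich_matrix(network)
  rxns <- colnames(N)
  lb <- vapply(network$reactions, function(r) r$lower_bound, numeric(1))
  ub <- vapply(network$reactions, function(r) r$upper_bound, numeric(1))
  is_ex <- vapply(network$reactions, function(r) isTRUE(r$is_exchange), logical(1))
  close <- is_ex & !(rxns %in% open_exchanges)
  lb[close] <- 0; ub[close] <- 0
  blocked <- character(0)
  for (j in seq_along(rxns)) {
    e <- numeric(length(rxns)); e[j] <- 1
    lo <- oracle_lp(e, N, rep("=", nrow(N)), rep(0, nrow(N)), lb, ub)
    hi <- oracle_lp(-e, N, rep("=", nrow(N)), rep(0, nrow(N)), lb, ub)
    vmin <- if (lo$status == "optimal") lo$objval else 0
    vmax <- if (hi$status == "optimal") -hi$objval else 0
    if (abs(vmin) <= tol && abs(vmax) <= tol) blocked <- c(blocked, rxns[j])
  }
  blocked
}

# linear chain A -> B -> C with uptake and secretion exchanges
chain_network <- function() {
  metabolic_network(
    list(metabolite("A"), metabolite("B"), metabolite("C")),
    list(reaction("up_A", c(A = 1), is_exchange = TRUE, allowed_uptake = TRUE),
         reaction("r_ab", c(A = -1, B = 1)),
         reaction("r_bc", c(B = -1, C = 1)),
         reaction("ex_C", c(C = -1), is_exchange = TRUE,
                  allowed_secretion = TRUE)))
}

# random small network: n internal conversions among m metabolites, with an
# uptake for the first and a secretion for the last metabolite
random_network <- function(n_rxn, n_met, seed) {
  set.seed(seed)
  mets <- lapply(seq_len(n_met), function(i) metabolite(paste0("M", i)))
  rxns <- list(
    reaction("up_1", c(M1 = 1), is_exchange = TRUE),
    reaction(paste0("ex_", n_met),
             stats::setNames(-1, paste0("M", n_met)), is_exchange = TRUE))
  for (k in seq_len(n_rxn)) {
    ij <- sample.int(n_met, 2)
    rev <- runif(1) < 0.3
    rxns <- c(rxns, list(reaction(
      paste0("r", k),
      stats::setNames(c(-1, sample(1:2, 1)), paste0("M", ij)),
      reversible = rev)))
  }
  metabolic_network(mets, rxns)
}

# composition over the full uptake set of a core network, zeros elsewhere
full_composition <- function(network, betas) {
  us <- network$annotations$uptake_set
  b <- stats::setNames(rep(0, length(us)), us)
  b[names(betas)] <- betas
  composition(b)
}

solve_core <- function(network, betas, ...) {
  p <- flux_problem(network, ...)
  minimize_uptake(apply_composition(p, full_composition(network, betas)))
}

extdata <- function(f) system.file("extdata", f, package = "cardioflux")
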