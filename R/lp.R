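#' Solve a small dense linear program
#'
#' Two-phase primal simplex on the full tableau, with Bland's rule for
#' anti-cycling. Intended for the moderate problem sizes arising from lumped
#' metabolic networks (tens to a few hundred variables); every flux-balance,
#' variability and alternate-optima computation in this package goes through
#' this routine, so determinism matters more than raw speed here.
#'
#' Solves: minimize \code{obj \%*\% x} subject to \code{mat \%*\% x (dir) rhs}
#' and \code{lower <= x <= upper}, where \code{dir} is a vector of
#' \code{"<="}, \code{">="}, \code{"="}.
#'
#' @param obj numeric objective coefficients (length n).
#' @param mat constraint matrix (m x n); may have zero rows.
#' @param dir character vector of constraint directions.
#' @param rhs numeric right-hand sides (length m).
#' @param lower,upper variable bounds; must be finite (cap free fluxes at a
#'   large finite bound before calling).
#' @param tol feasibility tolerance.
#' @return list with \code{status} ("optimal", "infeasible" or "unbounded"),
#'   \code{x} (solution, NA if not optimal) and \code{objval}.
#' @export
lp_solve <- function(obj, mat, dir, rhs, lower, upper, tol = 1e-9) {
  n <- length(obj)
  if (is.null(mat)) mat <- matrix(0, 0, n)
  mat <- as.matrix(mat)
  m <- nrow(mat)
  stopifnot(ncol(mat) == n, length(dir) == m, length(rhs) == m,
            length(lower) == n, length(upper) == n)
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("lp_solve requires finite variable bounds")
  if (any(lower > upper + tol))
    return(list(status = "infeasible", x = rep(NA_real_, n), objval = NA_real_))

  ## shift to y = x - lower >= 0, append upper-bound rows y_j <= upper-lower
  shift <- lower
  rhs2 <- rhs - as.numeric(mat %*% shift)
  span <- upper - lower
  ub_idx <- which(is.finite(span))           # all, by the check above
  A <- rbind(mat, diag(n)[ub_idx, , drop = FALSE])
  b <- c(rhs2, span[ub_idx])
  d <- c(dir, rep("<=", length(ub_idx)))

  ## normalize rows to b >= 0
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]
  d[neg] <- ifelse(d[neg] == "<=", ">=", ifelse(d[neg] == ">=", "<=", "="))

  M <- nrow(A)
  ## columns: n structural, slacks/surplus, artificials
  slack_of <- integer(M); art_of <- integer(M)
  n_slack <- 0L; n_art <- 0L
  for (i in seq_len(M)) {
    if (d[i] == "<=") { n_slack <- n_slack + 1L; slack_of[i] <- n_slack }
    else if (d[i] == ">=") { n_slack <- n_slack + 1L; slack_of[i] <- n_slack
                             n_art <- n_art + 1L; art_of[i] <- n_art }
    else { n_art <- n_art + 1L; art_of[i] <- n_art }
  }
  ntot <- n + n_slack + n_art
  Tb <- matrix(0, M, ntot)
  Tb[, seq_len(n)] <- A
  basis <- integer(M)
  for (i in seq_len(M)) {
    if (slack_of[i] > 0L)
      Tb[i, n + slack_of[i]] <- if (d[i] == "<=") 1 else -1
    if (art_of[i] > 0L) {
      Tb[i, n + n_slack + art_of[i]] <- 1
      basis[i] <- n + n_slack + art_of[i]
    } else {
      basis[i] <- n + slack_of[i]
    }
  }

  piv <- function(Tb, b, basis, r, c) {
    pr <- Tb[r, ] / Tb[r, c]
    pb <- b[r] / Tb[r, c]
    fac <- Tb[, c]
    Tb <- Tb - outer(fac, pr)
    b <- b - fac * pb
    Tb[r, ] <- pr; b[r] <- pb
    b[b < 0 & b > -1e-11] <- 0
    basis[r] <- c
    list(Tb = Tb, b = b, basis = basis)
  }

  run_simplex <- function(Tb, b, basis, cost, allowed, tol) {
    ## price out basic columns of the reduced cost vector
    maxit <- 10000L
    for (it in seq_len(maxit)) {
      cb <- cost[basis]
      red <- cost - as.numeric(cb %*% Tb)
      red[basis] <- 0
      cand <- which(allowed & red < -tol)
      if (!length(cand)) return(list(Tb = Tb, b = b, basis = basis, status = "optimal"))
      c <- cand[1L]                      # Bland: smallest index
      col <- Tb[, c]
      pos <- which(col > tol)
      if (!length(pos)) return(list(Tb = Tb, b = b, basis = basis, status = "unbounded"))
      ratio <- b[pos] / col[pos]
      rmin <- min(ratio)
      tie <- pos[ratio <= rmin + 1e-12]
      r <- tie[which.min(basis[tie])]    # Bland on leaving variable
      st <- piv(Tb, b, basis, r, c)
      Tb <- st$Tb; b <- st$b; basis <- st$basis
    }
    stop("simplex: iteration limit reached")
  }

  ## Phase 1
  if (n_art > 0L) {
    cost1 <- c(rep(0, n + n_slack), rep(1, n_art))
    ph1 <- run_simplex(Tb, b, basis, cost1, allowed = rep(TRUE, ntot), tol = tol)
    Tb <- ph1$Tb; b <- ph1$b; basis <- ph1$basis
    obj1 <- sum(b[basis > n + n_slack])
    if (obj1 > 1e-7)
      return(list(status = "infeasible", x = rep(NA_real_, n), objval = NA_real_))
    ## drive remaining artificials out of the basis where possible
    for (r in which(basis > n + n_slack)) {
      c <- which(abs(Tb[r, seq_len(n + n_slack)]) > tol)[1L]
      if (!is.na(c)) {
        st <- piv(Tb, b, basis, r, c); Tb <- st$Tb; b <- st$b; basis <- st$basis
      }
    }
  }
  allowed <- c(rep(TRUE, n + n_slack), rep(FALSE, n_art))

  ## Phase 2
  cost2 <- c(obj, rep(0, n_slack + n_art))
  ph2 <- run_simplex(Tb, b, basis, cost2, allowed = allowed, tol = tol)
  if (ph2$status == "unbounded")
    return(list(status = "unbounded", x = rep(NA_real_, n), objval = NA_real_))
  Tb <- ph2$Tb; b <- ph2$b; basis <- ph2$basis

  y <- numeric(ntot)
  y[basis] <- b
  x <- y[seq_len(n)] + shift
  list(status = "optimal", x = x, objval = sum(obj * x))
}
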