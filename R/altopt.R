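#' Enumerate alternate optimal flux distributions
#'
#' Implements the one-flux-at-a-time re-constraining procedure: for every
#' reaction carrying flux in the original optimum v0, the problem is
#' re-solved twice with that flux pinned to 1.01 x v0 and 0.99 x v0. A
#' perturbed solution whose objective matches the original optimum within a
#' relative tolerance of 1e-6 is an alternate optimum; a flux whose
#' perturbation is infeasible in both directions is dependent (it cannot be
#' varied without violating the target). Zero fluxes are skipped, since
#' scaling zero is no perturbation. Per-flux sample variances are computed
#' over the original plus all retained alternates; fluxes with zero variance
#' are uniquely determined.
#'
#' @param problem a [flux_problem()].
#' @param v0 optional original \code{flux_distribution}; solved via
#'   [minimize_uptake()] if NULL. If supplied, its objective must match the
#'   problem's optimum (checked).
#' @param tol relative objective tolerance for accepting an alternate.
#' @return an object of class \code{altopt_report}: \code{original},
#'   \code{alternates} (list of distributions), \code{per_flux_variance},
#'   \code{unique_fraction}, \code{dependent_fluxes}, and \code{anova}
#'   (filled by [compare_distributions_anova()], NULL until then).
#' @export
enumerate_alternates <- function(problem, v0 = NULL, tol = 1e-6) {
  stopifnot(inherits(problem, "flux_problem"))
  if (is.null(v0)) v0 <- minimize_uptake(problem)
  if (v0$status != "optimal") stop("original problem is ", v0$status)
  ## re-derive the optimum and verify v0 attains it
  lp <- .assemble_lp(problem)
  s1 <- lp_solve(.stage1_objective(lp), lp$A, lp$dir, lp$rhs, lp$lb, lp$ub)
  opt <- s1$objval
  if (abs(v0$objective - opt) > tol * (1 + abs(opt)))
    stop("supplied v0 is not optimal for this problem (objective ",
         v0$objective, " vs optimum ", opt, ")")

  active <- names(v0$fluxes)[abs(v0$fluxes) > 1e-9]
  alternates <- list()
  dependent <- character(0)
  for (id in active) {
    feas_any <- FALSE
    for (f in c(1.01, 0.99)) {
      p2 <- problem
      p2$pinned <- c(p2$pinned, stats::setNames(f * v0$fluxes[[id]], id))
      d <- minimize_uptake(p2)
      if (d$status == "optimal") {
        feas_any <- TRUE
        if (abs(d$objective - opt) <= tol * (1 + abs(opt)))
          alternates[[length(alternates) + 1L]] <- d
      }
    }
    if (!feas_any) dependent <- c(dependent, id)
  }

  all_dists <- c(list(v0), alternates)
  fm <- do.call(rbind, lapply(all_dists, function(d) d$fluxes))
  per_flux_variance <- if (nrow(fm) > 1)
    apply(fm, 2, stats::var) else stats::setNames(rep(0, ncol(fm)), colnames(fm))
  unique_fraction <- mean(per_flux_variance <= 1e-12)
  structure(list(original = v0, alternates = alternates,
                 per_flux_variance = per_flux_variance,
                 unique_fraction = unique_fraction,
                 dependent_fluxes = dependent, anova = NULL),
            class = "altopt_report")
}

#' One-way ANOVA across flux distributions
#'
#' Treats each distribution (original plus alternates) as a group and the
#' per-reaction fluxes as observations, as used to test whether alternate
#' optima differ from the original distribution.
#'
#' @param report an \code{altopt_report} with at least one alternate, or a
#'   list of at least two \code{flux_distribution}s.
#' @return named numeric \code{c(F, p)}. With zero within-group variance and
#'   differing means, F is infinite and p 0 (flagged with a warning).
#' @export
compare_distributions_anova <- function(report) {
  dists <- if (inherits(report, "altopt_report"))
    c(list(report$original), report$alternates) else report
  if (length(dists) < 2) stop("at least two distributions are required")
  fm <- do.call(rbind, lapply(dists, function(d) d$fluxes))
  g <- factor(rep(seq_len(nrow(fm)), ncol(fm)))
  y <- as.numeric(fm)
  k <- nlevels(g); n <- length(y)
  gm <- tapply(y, g, mean)
  ssb <- sum(tabulate(g) * (gm - mean(y))^2)
  ssw <- sum((y - gm[g])^2)
  dfb <- k - 1; dfw <- n - k
  if (ssw <= 1e-300 * max(1, ssb)) {
    if (ssb <= 1e-12) return(c(F = 0, p = 1))
    warning("zero within-group variance; F unbounded")
    return(c(F = Inf, p = 0))
  }
  f <- (ssb / dfb) / (ssw / dfw)
  c(F = f, p = stats::pf(f, dfb, dfw, lower.tail = FALSE))
}

#' @export
print.altopt_report <- function(x, ...) {
  cat("Alternate-optima report\n")
  cat("  alternates found:", length(x$alternates), "\n")
  cat(sprintf("  unique fluxes (s = 0): %.2f%%\n", 100 * x$unique_fraction))
  cat("  dependent fluxes:", length(x$dependent_fluxes), "\n")
  if (!is.null(x$anova))
    cat(sprintf("  ANOVA: F = %.3g, p = %.3g\n", x$anova["F"], x$anova["p"]))
  invisible(x)
}

#' Write an alternate-optima report as TSV
#'
#' One row per reaction: original flux, min/max over original+alternates,
#' variance and uniqueness flag.
#'
#' @param report an \code{altopt_report}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_altopt_tsv <- function(report, path) {
  dists <- c(list(report$original), report$alternates)
  fm <- do.call(rbind, lapply(dists, function(d) d$fluxes))
  df <- data.frame(reaction = colnames(fm),
                   v0 = as.numeric(report$original$fluxes),
                   min = apply(fm, 2, min), max = apply(fm, 2, max),
                   variance = as.numeric(report$per_flux_variance),
                   unique = report$per_flux_variance <= 1e-12,
                   dependent = colnames(fm) %in% report$dependent_fluxes)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
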