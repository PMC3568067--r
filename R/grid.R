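#' Define a substrate composition
#'
#' The composition vector beta assigns each substrate uptake its relative
#' share of the total substrate uptake flux v_s; shares lie between 0 and 1
#' and sum to 1.
#'
#' @param betas named numeric vector (uptake reaction id -> beta_m).
#' @return an object of class \code{composition}.
#' @export
composition <- function(betas) {
  if (is.null(names(betas)) || any(!nzchar(names(betas))))
    stop("betas must be a fully named vector")
  if (any(betas < -1e-12) || any(betas > 1 + 1e-12))
    stop("each beta must lie in [0, 1]")
  if (abs(sum(betas) - 1) > 1e-12)
    stop("betas must sum to 1 (got ", sum(betas), ")")
  structure(list(betas = pmin(pmax(betas, 0), 1)), class = "composition")
}

#' Enumerate compositions on the unit simplex
#'
#' All vectors (a_1/k, ..., a_n/k) with nonnegative integer a summing to
#' k = 1/step, in ascending lexicographic order. There are
#' choose(k + n - 1, n - 1) of them; e.g. 4 substrates on a 0.01 grid give
#' choose(103, 3) = 176,851 compositions.
#'
#' @param n_s number of substrates (>= 1).
#' @param step grid resolution; 1/step must be integral.
#' @return numeric matrix with \code{n_s} columns, one row per composition.
#' @export
enumerate_compositions <- function(n_s, step) {
  stopifnot(n_s >= 1, step > 0, step <= 1)
  k <- 1 / step
  if (abs(k - round(k)) > 1e-9) stop("1/step must be a positive integer")
  k <- as.integer(round(k))
  counts <- .int_compositions(n_s, k)
  counts / k
}

## integer compositions of k into n ordered nonnegative parts, lexicographic
.int_compositions <- function(n, k) {
  if (n == 1L) return(matrix(k, 1L, 1L))
  blocks <- lapply(0:k, function(a)
    cbind(a, .int_compositions(n - 1L, k - a), deparse.level = 0))
  do.call(rbind, blocks)
}

#' Couple a problem to a composition
#'
#' Returns a copy of the problem with the coupling constraints
#' v_m = beta_m v_s installed (substrates with beta_m = 0 are pinned to
#' zero flux).
#'
#' @param problem a [flux_problem()].
#' @param comp a [composition()] whose names are a subset of the problem's
#'   uptake set.
#' @return the coupled [flux_problem()].
#' @export
apply_composition <- function(problem, comp) {
  stopifnot(inherits(problem, "flux_problem"))
  if (!inherits(comp, "composition")) comp <- composition(comp)
  bad <- setdiff(names(comp$betas), problem$uptake_set)
  if (length(bad)) stop("unknown uptake id(s): ", paste(bad, collapse = ", "))
  problem$composition <- comp
  problem
}

## zero bounds for substrate uptake exchanges outside `keep`, merged into
## user-supplied extra bounds (which win)
close_other_uptakes <- function(network, keep, oxygen_id = NULL,
                                extra = list()) {
  all_uptakes <- network$annotations$uptake_set
  if (is.null(all_uptakes)) {
    all_uptakes <- names(network$reactions)[vapply(network$reactions,
      function(r) isTRUE(r$is_exchange) && isTRUE(r$allowed_uptake) &&
        length(r$stoichiometry) == 1L && r$stoichiometry[[1]] > 0,
      logical(1))]
  }
  oxy <- oxygen_id %||% network$annotations$oxygen_id
  for (id in setdiff(all_uptakes, c(keep, oxy, names(extra))))
    extra[[id]] <- c(0, 0)
  extra
}

#' Configure a substrate-availability scan
#'
#' @param uptake_ids ordered substrate uptake reaction ids to vary.
#' @param step simplex grid resolution (used when \code{compositions} is
#'   NULL); 1/step must be integral.
#' @param compositions optional explicit composition matrix (columns =
#'   uptake_ids), overriding the grid.
#' @param target_fluxes,oxygen_id,extra_bounds,minimize_total_flux passed to
#'   [flux_problem()]; NULL values fall back to the network annotations.
#' @param checkpoint_file optional TSV path; completed rows are appended
#'   every \code{checkpoint_every} compositions and a restarted scan resumes
#'   after the last completed row.
#' @param checkpoint_every checkpoint interval in rows.
#' @return a list of class \code{scan_config}.
#' @export
scan_config <- function(uptake_ids, step = NULL, compositions = NULL,
                        target_fluxes = NULL, oxygen_id = NULL,
                        extra_bounds = list(), minimize_total_flux = TRUE,
                        checkpoint_file = NULL, checkpoint_every = 1000L) {
  if (is.null(step) && is.null(compositions))
    stop("one of step or compositions is required")
  if (!is.null(compositions)) {
    compositions <- as.matrix(compositions)
    if (ncol(compositions) != length(uptake_ids))
      stop("compositions must have one column per uptake id")
  }
  structure(list(uptake_ids = uptake_ids, step = step,
                 compositions = compositions, target_fluxes = target_fluxes,
                 oxygen_id = oxygen_id, extra_bounds = extra_bounds,
                 minimize_total_flux = minimize_total_flux,
                 checkpoint_file = checkpoint_file,
                 checkpoint_every = as.integer(checkpoint_every)),
            class = "scan_config")
}

#' Run a batch flux-minimization scan over substrate compositions
#'
#' One [minimize_uptake()] call per composition, in deterministic row order.
#' Infeasible compositions are recorded with their status, never dropped;
#' a solver error on one row marks that row and the scan continues.
#'
#' @param network a [metabolic_network()].
#' @param config a [scan_config()].
#' @return a data frame of class \code{scan_result}: one row per
#'   composition with the beta columns, \code{vO2}, \code{vs}, \code{vGL},
#'   \code{vGS}, \code{objective} and \code{status}.
#' @export
run_scan <- function(network, config) {
  stopifnot(inherits(config, "scan_config"))
  comps <- config$compositions
  if (is.null(comps))
    comps <- enumerate_compositions(length(config$uptake_ids), config$step)
  colnames(comps) <- config$uptake_ids
  n <- nrow(comps)

  ## the composition defines the medium: substrate uptakes outside the
  ## scanned set are closed (unless explicitly re-bounded by the caller)
  extra <- close_other_uptakes(network, config$uptake_ids,
                               config$oxygen_id, config$extra_bounds)

  base <- flux_problem(network, target_fluxes = config$target_fluxes,
                       uptake_set = config$uptake_ids,
                       oxygen_id = config$oxygen_id,
                       extra_bounds = extra,
                       minimize_total_flux = config$minimize_total_flux)

  beta_cols <- paste0("beta_", sub("^uptake_", "", config$uptake_ids))
  out <- data.frame(comps)
  names(out) <- beta_cols
  out$vO2 <- out$vs <- out$vGL <- out$vGS <- out$objective <- NA_real_
  out$status <- NA_character_
  out <- out[c(beta_cols, "vO2", "vs", "vGL", "vGS", "objective", "status")]

  start <- 1L
  ckpt <- config$checkpoint_file
  if (!is.null(ckpt) && file.exists(ckpt)) {
    prev <- utils::read.table(ckpt, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    done <- nrow(prev)
    if (done > n) stop("checkpoint has more rows than the scan")
    if (done > 0) {
      out[seq_len(done), ] <- prev
      start <- done + 1L
    }
  }

  if (start <= n) for (i in start:n) {
    row <- tryCatch({
      d <- minimize_uptake(apply_composition(base, composition(comps[i, ])))
      list(d$vO2, d$vs, d$vGL, d$vGS, d$objective, d$status)
    }, error = function(e) list(NA_real_, NA_real_, NA_real_, NA_real_,
                                NA_real_, paste0("error: ", conditionMessage(e))))
    out[i, c("vO2", "vs", "vGL", "vGS", "objective", "status")] <- row
    if (!is.null(ckpt) &&
        (i %% config$checkpoint_every == 0L || i == n))
      utils::write.table(out[seq_len(i), ], ckpt, sep = "\t", quote = FALSE,
                         row.names = FALSE)
  }
  class(out) <- c("scan_result", "data.frame")
  attr(out, "uptake_ids") <- config$uptake_ids
  out
}

#' @export
print.scan_result <- function(x, ...) {
  cat("Substrate-availability scan:", nrow(x), "compositions;",
      sum(x$status == "optimal", na.rm = TRUE), "feasible\n")
  NextMethod()
}

#' Plot oxygen demand against total substrate uptake for a scan
#'
#' @param x a \code{scan_result}.
#' @param ... passed to [graphics::plot()].
#' @export
plot.scan_result <- function(x, ...) {
  ok <- x$status == "optimal" & !is.na(x$status)
  graphics::plot(x$vs[ok], x$vO2[ok],
                 xlab = expression(v[s] ~ "[mmol" %.% "min"^-1 %.% "(l cell)"^-1 * "]"),
                 ylab = expression(v[O2] ~ "[mmol" %.% "min"^-1 %.% "(l cell)"^-1 * "]"),
                 ...)
  invisible(x)
}

#' Write a scan result as TSV
#'
#' @param scan a \code{scan_result}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_scan_tsv <- function(scan, path) {
  utils::write.table(scan, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
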