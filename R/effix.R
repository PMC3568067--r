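#' Euclidean ideal/anti-ideal efficiency index
#'
#' For a criteria matrix q (rows = solutions i, columns = criteria j, all
#' "lower is better"), the per-criterion best case q+_j is the column
#' minimum and the worst case q-_j the column maximum. Each row's Euclidean
#' distances to the ideal and anti-ideal points,
#' S+_i = sqrt(sum_j (q_ij - q+_j)^2) and S-_i = sqrt(sum_j (q_ij - q-_j)^2),
#' give the efficiency index C+_i = S-_i / (S+_i + S-_i) — the TOPSIS
#' closeness coefficient computed on raw units. No per-criterion
#' normalization is applied by default: recomputing published cardiomyocyte
#' substrate-scan indices from the raw (oxygen demand, substrate uptake)
#' pairs matches their printed values to three to four decimals, so raw
#' Euclidean distance is the procedure this index reproduces. Classic
#' vector normalization is available behind \code{normalize = TRUE}.
#'
#' @param q numeric matrix or data frame of criteria values; at least two
#'   rows (the ideals are undefined otherwise), all finite.
#' @param labels optional row labels.
#' @param normalize divide each column by its Euclidean norm first
#'   (classic TOPSIS); default FALSE.
#' @return an object of class \code{efficiency_table}: the matrix \code{q},
#'   \code{q_plus}, \code{q_minus}, \code{s_plus}, \code{s_minus},
#'   \code{c_plus}. A row with S+ + S- = 0 (all criteria degenerate) gets
#'   C+ = 1 with a warning.
#' @export
efficiency_index <- function(q, labels = NULL, normalize = FALSE) {
  q <- as.matrix(q)
  storage.mode(q) <- "double"
  if (nrow(q) < 2)
    stop("at least two solutions are required (ideals undefined)")
  if (any(!is.finite(q))) stop("criteria values must be finite")
  if (is.null(labels)) labels <- rownames(q) %||% as.character(seq_len(nrow(q)))
  if (normalize) {
    nrm <- sqrt(colSums(q^2))
    nrm[nrm == 0] <- 1
    q <- sweep(q, 2, nrm, "/")
  }
  q_plus <- apply(q, 2, min)
  q_minus <- apply(q, 2, max)
  s_plus <- sqrt(rowSums(sweep(q, 2, q_plus)^2))
  s_minus <- sqrt(rowSums(sweep(q, 2, q_minus)^2))
  denom <- s_plus + s_minus
  c_plus <- ifelse(denom == 0, 1, s_minus / denom)
  if (any(denom == 0))
    warning("degenerate criteria: all values identical for some row(s); C+ set to 1")
  structure(list(labels = labels, q = q, q_plus = q_plus, q_minus = q_minus,
                 s_plus = s_plus, s_minus = s_minus,
                 c_plus = unname(c_plus)),
            class = "efficiency_table")
}

#' Rank scanned compositions by efficiency index
#'
#' Computes C+ over the feasible rows of a scan using the chosen criteria
#' (any of the scan's numeric rate columns, typically oxygen demand
#' \code{vO2}, total substrate uptake \code{vs} and glycogenolysis
#' \code{vGL}) and returns the table sorted by C+ descending, ties broken
#' by original row order.
#'
#' @param scan a \code{scan_result} from [run_scan()], or any data frame
#'   with a \code{status} column and the criteria columns.
#' @param criteria character vector of criteria column names.
#' @return an \code{efficiency_table} whose extra \code{rows} element holds
#'   the scanned rows with \code{c_plus} and \code{rank} appended.
#' @export
rank_compositions <- function(scan, criteria = c("vO2", "vs", "vGL")) {
  miss <- setdiff(criteria, names(scan))
  if (length(miss)) stop("unknown criteria column(s): ",
                         paste(miss, collapse = ", "))
  feas <- which(scan$status == "optimal" & !is.na(scan$status))
  if (length(feas) < 2)
    stop("fewer than two feasible rows; nothing to rank")
  q <- as.matrix(as.data.frame(scan)[feas, criteria, drop = FALSE])
  et <- efficiency_index(q, labels = as.character(feas))
  ord <- order(-et$c_plus, seq_along(et$c_plus))
  rows <- as.data.frame(scan)[feas, , drop = FALSE]
  rows$c_plus <- et$c_plus
  rows <- rows[ord, , drop = FALSE]
  rows$rank <- seq_len(nrow(rows))
  et$rows <- rows
  et$labels <- et$labels[ord]
  et$q <- et$q[ord, , drop = FALSE]
  et$s_plus <- et$s_plus[ord]
  et$s_minus <- et$s_minus[ord]
  et$c_plus <- et$c_plus[ord]
  et
}

#' @export
print.efficiency_table <- function(x, digits = 4, ...) {
  cat("Efficiency index over", nrow(x$q), "solutions,",
      ncol(x$q), "criteria\n")
  df <- data.frame(label = x$labels,
                   round(x$q, digits),
                   s_plus = round(x$s_plus, digits),
                   s_minus = round(x$s_minus, digits),
                   c_plus = round(x$c_plus, digits))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Read a criteria table (label + numeric columns) from TSV
#'
#' Accepts hand-typed criteria tables so published uptake-rate tables can be
#' scored directly.
#'
#' @param path TSV with a \code{label} column and one numeric column per
#'   criterion.
#' @return list with \code{labels} and numeric matrix \code{q}.
#' @export
read_criteria_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!"label" %in% names(d)) stop("criteria TSV needs a 'label' column")
  q <- as.matrix(d[setdiff(names(d), "label")])
  list(labels = d$label, q = q)
}

#' Write an efficiency table as TSV
#'
#' @param et an \code{efficiency_table}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_efficiency_tsv <- function(et, path) {
  df <- data.frame(label = et$labels, et$q,
                   s_plus = et$s_plus, s_minus = et$s_minus,
                   c_plus = et$c_plus, rank = rank(-et$c_plus, ties.method = "first"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
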