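#' Write a network to the native JSON model format
#'
#' Lossless, diffable representation with stable key ordering: two writes of
#' the same network are byte-identical. Numbers are serialized at full
#' precision.
#'
#' @param network a [metabolic_network()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_native <- function(network, path) {
  mets <- lapply(network$metabolites, function(m)
    list(id = m$id, name = m$name, compartment = m$compartment,
         formula = m$formula))
  rxns <- lapply(network$reactions, function(r)
    list(id = r$id,
         stoichiometry = as.list(r$stoichiometry),
         reversible = r$reversible,
         lower_bound = r$lower_bound, upper_bound = r$upper_bound,
         is_exchange = r$is_exchange, is_transport = r$is_transport,
         allowed_uptake = r$allowed_uptake,
         allowed_secretion = r$allowed_secretion))
  ## annotations normalize to nested lists of scalars so a write -> read ->
  ## write cycle is byte-identical
  norm <- function(x) {
    if (is.list(x)) lapply(x, norm)
    else if (length(x) > 1) lapply(unname(x), identity)
    else x
  }
  doc <- list(format = "cardioflux-network", version = 1L,
              compartments = as.list(network$compartments),
              metabolites = unname(mets), reactions = unname(rxns),
              annotations = norm(network$annotations))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE, na = "null")
  writeLines(json, path)
  invisible(path)
}

.need <- function(x, key, where) {
  if (is.null(x[[key]]))
    stop("native model: missing '", key, "' at ", where)
  x[[key]]
}

#' Read a network from the native JSON model format
#'
#' Unknown top-level keys are preserved in the network's annotations under
#' \code{extra} rather than rejected.
#'
#' @param path path to a file written by [write_native()].
#' @return a [metabolic_network()].
#' @export
read_native <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$format, "cardioflux-network"))
    stop("native model: not a cardioflux-network document at $.format")
  mets <- lapply(seq_along(doc$metabolites), function(i) {
    m <- doc$metabolites[[i]]
    metabolite(.need(m, "id", paste0("$.metabolites[", i, "]")),
               name = m$name %||% m$id,
               compartment = m$compartment %||% "cyto",
               formula = if (is.null(m$formula)) NA_character_ else m$formula)
  })
  rxns <- lapply(seq_along(doc$reactions), function(i) {
    r <- doc$reactions[[i]]
    s <- .need(r, "stoichiometry", paste0("$.reactions[", i, "]"))
    reaction(.need(r, "id", paste0("$.reactions[", i, "]")),
             stoichiometry = unlist(s),
             reversible = isTRUE(r$reversible),
             lower_bound = r$lower_bound %||% 0,
             upper_bound = r$upper_bound %||% default_flux_bound(),
             is_exchange = isTRUE(r$is_exchange),
             is_transport = isTRUE(r$is_transport),
             allowed_uptake = r$allowed_uptake %||% NA,
             allowed_secretion = r$allowed_secretion %||% NA)
  })
  ann <- doc$annotations %||% list()
  known <- c("format", "version", "compartments", "metabolites", "reactions",
             "annotations")
  extra <- doc[setdiff(names(doc), known)]
  if (length(extra)) ann$extra <- c(ann$extra, extra)
  metabolic_network(mets, rxns,
                    compartments = unlist(doc$compartments),
                    annotations = ann)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a metabolic network from SBML
#'
#' Supports the Level 2 / Level 3 core subset used by constraint-based
#' models: \code{listOfSpecies} / \code{listOfReactions} with
#' \code{speciesReference} stoichiometries. Species with
#' \code{boundaryCondition="true"} are excluded from the mass-balance rows
#' (their reactions become exchange columns). Flux bounds are taken from fbc
#' attributes (Level 3, via referenced parameters) or from the COBRA-style
#' \code{LOWER_BOUND}/\code{UPPER_BOUND} kinetic-law parameters (Level 2)
#' when present; otherwise reversible reactions get symmetric default bounds
#' and irreversible ones \code{[0, default]}. When the reversibility flag
#' conflicts with negative bounds the flag wins and a warning is emitted.
#' Kinetic laws are otherwise ignored; unrecognized constructs are logged
#' via \code{message}, not fatal.
#'
#' @param path path to an SBML file.
#' @return a [metabolic_network()].
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse error: ", conditionMessage(e)))
  ns <- xml2::xml_ns(doc)
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model, "xml_missing")) stop("SBML: no <model> element")

  ## fbc flux-bound parameters (Level 3)
  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pval <- stats::setNames(
    as.numeric(xml2::xml_attr(params, "value")),
    xml2::xml_attr(params, "id"))

  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (!length(sp_nodes)) stop("SBML: no species found")
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  sp_bound <- tolower(xml2::xml_attr(sp_nodes, "boundaryCondition")) %in% "true"
  mets <- lapply(which(!sp_bound), function(i) {
    nm <- xml2::xml_attr(sp_nodes[i], "name")
    cp <- xml2::xml_attr(sp_nodes[i], "compartment")
    metabolite(sp_id[i],
               name = if (is.na(nm)) sp_id[i] else nm,
               compartment = if (is.na(cp)) "cyto" else cp)
  })
  boundary_ids <- sp_id[sp_bound]
  internal_ids <- sp_id[!sp_bound]

  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (!length(rx_nodes)) stop("SBML: no reactions found")
  rxns <- lapply(rx_nodes, function(node) {
    rid <- xml2::xml_attr(node, "id")
    rev <- !identical(tolower(xml2::xml_attr(node, "reversible")), "false")
    refs <- function(xp, sign) {
      sr <- xml2::xml_find_all(node, xp)
      if (!length(sr)) return(numeric(0))
      st <- xml2::xml_attr(sr, "stoichiometry")
      st[is.na(st)] <- "1"
      stats::setNames(sign * as.numeric(st), xml2::xml_attr(sr, "species"))
    }
    s <- c(refs("./listOfReactants/speciesReference", -1),
           refs("./listOfProducts/speciesReference", +1))
    if (!length(s)) stop("SBML: reaction '", rid, "' has no stoichiometry")
    s <- tapply(s, names(s), sum)                  # merge duplicated species
    s <- stats::setNames(as.numeric(s), names(s))
    touches_boundary <- any(names(s) %in% boundary_ids)
    s <- s[names(s) %in% internal_ids]
    if (!length(s)) return(NULL)                    # boundary-only shuttle

    ## bounds: fbc attributes win over kinetic-law parameters
    attrs <- xml2::xml_attrs(node)
    lb <- ub <- NA_real_
    lb_ref <- attrs[grepl("lowerFluxBound$", names(attrs))]
    ub_ref <- attrs[grepl("upperFluxBound$", names(attrs))]
    if (length(lb_ref)) lb <- unname(pval[lb_ref[1]])
    if (length(ub_ref)) ub <- unname(pval[ub_ref[1]])
    kl <- xml2::xml_find_all(node, ".//kineticLaw//parameter")
    if (length(kl)) {
      kid <- toupper(xml2::xml_attr(kl, "id"))
      kv <- as.numeric(xml2::xml_attr(kl, "value"))
      if (is.na(lb) && "LOWER_BOUND" %in% kid) lb <- kv[match("LOWER_BOUND", kid)]
      if (is.na(ub) && "UPPER_BOUND" %in% kid) ub <- kv[match("UPPER_BOUND", kid)]
    }
    if (is.na(lb)) lb <- if (rev) -default_flux_bound() else 0
    if (is.na(ub)) ub <- default_flux_bound()
    if (!rev && lb < 0) {
      warning("SBML: reaction '", rid,
              "' irreversible but lower bound ", lb, "; clamping to 0")
      lb <- 0
    }
    reaction(rid, s, reversible = rev, lower_bound = lb, upper_bound = ub,
             is_exchange = touches_boundary || length(s) == 1L)
  })
  rxns <- rxns[!vapply(rxns, is.null, logical(1))]
  extra_ns <- setdiff(names(ns), c("d1", ""))
  if (length(extra_ns))
    message("SBML: ignoring constructs from namespace(s): ",
            paste(extra_ns, collapse = ", "))
  metabolic_network(mets, rxns,
                    annotations = list(source = "sbml",
                                       model_id = xml2::xml_attr(model, "id")))
}
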