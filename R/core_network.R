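#' Default substrate yield table for the cardiomyocyte core network
#'
#' ATP yields per mole of fully oxidized substrate and the oxygen
#' stoichiometry of complete combustion of the molecular formula. The six
#' fatty-acid yields (120, 136, 134, 132, 142, 156 mol ATP for palmitate,
#' stearate, oleate, alpha-linoleate, eicosapentaenoate, docosahexaenoate)
#' follow the standard P/O-based bookkeeping for beta-oxidation; glucose is
#' taken at 36 ATP (glycerophosphate-shuttle convention), lactate at 17,
#' acetoacetate at 22 and acetate at 9, which reproduces the uptake-per-demand
#' ratios observed in perfused-heart simulations (e.g. 21.6/36 = 0.60
#' glucose uptake at the baseline ATP demand).
#'
#' @return data frame with columns \code{name}, \code{atp_yield},
#'   \code{o2_stoich}, \code{essential_for_lipids}, \code{lipid_usable}.
#' @export
default_yield_table <- function() {
  data.frame(
    name = c("glucose", "lactate", "acetoacetate", "acetate",
             "palmitate", "stearate", "oleate", "alpha_linoleate",
             "epa", "dha"),
    atp_yield = c(36, 17, 22, 9, 120, 136, 134, 132, 142, 156),
    o2_stoich = c(6, 3, 4, 2, 23, 26, 25.5, 24.5, 26.5, 29),
    essential_for_lipids = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                             TRUE, FALSE, TRUE),
    lipid_usable = c(FALSE, FALSE, FALSE, FALSE,
                     TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Read / write a yield table as TSV
#'
#' @param path file path.
#' @return [read_yield_table()] returns the yield data frame.
#' @export
read_yield_table <- function(path) {
  y <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("name", "atp_yield", "o2_stoich", "essential_for_lipids",
            "lipid_usable")
  miss <- setdiff(need, names(y))
  if (length(miss)) stop("yield table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(y$atp_yield <= 0) || any(y$o2_stoich <= 0))
    stop("yield table: atp_yield and o2_stoich must be positive")
  y[need]
}

#' @rdname read_yield_table
#' @param yields a yield data frame as returned by [default_yield_table()].
#' @export
write_yield_table <- function(yields, path) {
  utils::write.table(yields, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Options for the cardiomyocyte core network generator
#'
#' @param include_glycogen add a glycogen store: a synthesis reaction
#'   (\code{glycogen_synthesis}, costing \code{glycogen_synthesis_cost} ATP
#'   per glucosyl unit, acting as a disposal sink for excess mandated
#'   glucose) and a degradation reaction (\code{glycogenolysis}, a capped
#'   endogenous glucose source).
#' @param glycogen_synthesis_cost ATP per glucosyl unit stored (default 2:
#'   hexokinase plus UDP-glucose activation).
#' @param glycogenolysis_max cap on the glycogenolysis flux,
#'   mmol.min^-1.(l cell)^-1 (default 0.9, above the maximal observed
#'   cardiac glycogen turnover of ~0.887 so that behaviour is representable).
#' @param include_lipid_targets add phospholipid/sphingolipid target
#'   reactions (cer, cl, pc, pe, sm) with fixed synthesis rates. Recipes
#'   consume a generic acyl pool fed by any \code{lipid_usable} substrate
#'   plus named alpha-linoleate and docosahexaenoate units, which therefore
#'   behave as essential fatty acids.
#' @param target_fluxes named vector of demanded synthesis rates for the
#'   lipid targets, mmol.min^-1.(l cell)^-1. The defaults are synthetic
#'   placeholder rates of realistic magnitude; real acyl-composition data
#'   can be supplied by overriding \code{lipid_recipes}.
#' @param atpase_demand the fixed ATP hydrolysis rate representing
#'   contractile and maintenance energy expenditure (baseline
#'   21.6 mmol.min^-1.(l cell)^-1).
#' @param include_nadph add a lumped oxidative pentose-phosphate NADPH
#'   source from the glucose pool (12 NADPH per glucosyl unit) plus an
#'   NADPH drain with minimum flux \code{nadph_min}.
#' @param nadph_min minimal demanded NADPH production rate (default
#'   1.42e-5 mmol.min^-1.(l cell)^-1, the basal cardiomyocyte rate).
#' @param lipid_recipes optional named list (per target) of lists with
#'   elements \code{acyl}, \code{ala}, \code{dha}, \code{atp}: units
#'   consumed per unit of target synthesized.
#' @return a list of class \code{core_options}.
#' @export
core_options <- function(include_glycogen = FALSE,
                         glycogen_synthesis_cost = 2,
                         glycogenolysis_max = 0.9,
                         include_lipid_targets = FALSE,
                         target_fluxes = c(cer = 0.001, cl = 0.002, pc = 0.005,
                                           pe = 0.003, sm = 0.001),
                         atpase_demand = 21.6,
                         include_nadph = FALSE,
                         nadph_min = 1.42e-5,
                         lipid_recipes = NULL) {
  stopifnot(glycogen_synthesis_cost >= 0, glycogenolysis_max >= 0,
            atpase_demand >= 0, nadph_min >= 0, all(target_fluxes >= 0))
  if (include_glycogen && !is.finite(glycogenolysis_max))
    stop("glycogenolysis_max must be finite when include_glycogen")
  if (is.null(lipid_recipes))
    lipid_recipes <- list(
      cer = list(acyl = 2, ala = 0.02, dha = 0.05, atp = 2),
      cl  = list(acyl = 4, ala = 0.05, dha = 0.10, atp = 4),
      pc  = list(acyl = 2, ala = 0.10, dha = 0.15, atp = 2),
      pe  = list(acyl = 2, ala = 0.10, dha = 0.20, atp = 2),
      sm  = list(acyl = 2, ala = 0.02, dha = 0.05, atp = 2))
  structure(list(include_glycogen = include_glycogen,
                 glycogen_synthesis_cost = glycogen_synthesis_cost,
                 glycogenolysis_max = glycogenolysis_max,
                 include_lipid_targets = include_lipid_targets,
                 target_fluxes = target_fluxes,
                 atpase_demand = atpase_demand,
                 include_nadph = include_nadph,
                 nadph_min = nadph_min,
                 lipid_recipes = lipid_recipes),
            class = "core_options")
}

#' Generate the reduced cardiomyocyte core network
#'
#' Builds a lumped constraint-based model in which each substrate has an
#' uptake exchange (\code{uptake_<name>}) and a single oxidation reaction
#' (\code{ox_<name>}: substrate + o2_stoich O2 + yield ADP -> yield ATP;
#' combustion byproducts are boundary and not balanced), plus an oxygen
#' uptake exchange (\code{uptake_o2}) and an ATPase drain (\code{atpase}:
#' ATP -> ADP). Optional components per [core_options()]: a glycogen store,
#' lipid-target reactions with an acyl pool and essential fatty acids, a
#' triglyceride-storage sink for surplus acyl units, and an NADPH branch.
#'
#' The generator is deterministic: equal inputs give byte-identical native
#' JSON output.
#'
#' @param yields yield table, see [default_yield_table()].
#' @param options a [core_options()] object.
#' @return a [metabolic_network()] whose annotations record the uptake
#'   reaction ids, oxygen id, ATPase id and options used.
#' @export
build_core_network <- function(yields = default_yield_table(),
                               options = core_options()) {
  stopifnot(inherits(options, "core_options"))
  if (!nrow(yields)) stop("at least one substrate is required")
  if (options$include_lipid_targets) {
    need <- c("alpha_linoleate", "dha")
    miss <- setdiff(need, yields$name)
    if (length(miss))
      stop("lipid targets require substrate(s) absent from yield table: ",
           paste(miss, collapse = ", "))
    bad <- setdiff(names(options$target_fluxes), names(options$lipid_recipes))
    if (length(bad)) stop("no recipe for lipid target(s): ",
                          paste(bad, collapse = ", "))
  }

  mets <- list(metabolite("o2", "oxygen", "cyto", "O2"),
               metabolite("atp", "ATP", "cyto"),
               metabolite("adp", "ADP", "cyto"))
  for (i in seq_len(nrow(yields)))
    mets <- c(mets, list(metabolite(yields$name[i], yields$name[i], "cyto")))

  rxns <- list(
    reaction("uptake_o2", c(o2 = 1), is_exchange = TRUE,
             allowed_uptake = TRUE, allowed_secretion = FALSE))
  for (i in seq_len(nrow(yields))) {
    s <- yields$name[i]
    rxns <- c(rxns, list(
      reaction(paste0("uptake_", s), stats::setNames(1, s),
               is_exchange = TRUE, allowed_uptake = TRUE,
               allowed_secretion = FALSE),
      reaction(paste0("ox_", s),
               stats::setNames(c(-1, -yields$o2_stoich[i],
                                 -yields$atp_yield[i], yields$atp_yield[i]),
                               c(s, "o2", "adp", "atp")))))
  }
  rxns <- c(rxns, list(reaction("atpase", c(atp = -1, adp = 1))))

  if (options$include_glycogen) {
    ## the glycogen store itself is a boundary pool: degradation acts as a
    ## capped endogenous glucose source, synthesis as an ATP-costing sink,
    ## so net storage or net mobilization are both representable at steady
    ## state (simultaneous synthesis and degradation is a futile cycle that
    ## burns ATP and is never optimal)
    k <- options$glycogen_synthesis_cost
    rxns <- c(rxns, list(
      reaction("glycogen_synthesis",
               c(glucose = -1, atp = -k, adp = k)),
      reaction("glycogenolysis", c(glucose = 1),
               upper_bound = options$glycogenolysis_max)))
  }

  if (options$include_lipid_targets) {
    mets <- c(mets, list(metabolite("acyl", "generic acyl unit", "cyto")))
    for (i in which(yields$lipid_usable)) {
      s <- yields$name[i]
      rxns <- c(rxns, list(
        reaction(paste0("acyl_from_", s), stats::setNames(c(-1, 1),
                                                          c(s, "acyl")))))
    }
    for (t in names(options$target_fluxes)) {
      rc <- options$lipid_recipes[[t]]
      s <- c(acyl = -rc$acyl, alpha_linoleate = -rc$ala, dha = -rc$dha,
             atp = -rc$atp, adp = rc$atp)
      s <- s[s != 0]
      rxns <- c(rxns, list(reaction(paste0("target_", t), s)))
    }
    ## surplus acyl units mandated by the composition coupling can be parked
    ## in triglyceride stores (small activation cost)
    rxns <- c(rxns, list(
      reaction("tg_storage", c(acyl = -1, atp = -2, adp = 2))))
  }

  if (options$include_nadph) {
    mets <- c(mets, list(metabolite("nadph", "NADPH", "cyto")))
    rxns <- c(rxns, list(
      reaction("nadph_source", c(glucose = -1, nadph = 12)),
      reaction("nadph_drain", c(nadph = -1),
               lower_bound = options$nadph_min)))
  }

  uptake_ids <- paste0("uptake_", yields$name)
  target_ids <- c(atpase = "atpase",
                  if (options$include_lipid_targets)
                    stats::setNames(paste0("target_", names(options$target_fluxes)),
                                    names(options$target_fluxes)))
  metabolic_network(
    mets, rxns,
    annotations = list(
      generator = "build_core_network",
      uptake_set = uptake_ids,
      oxygen_id = "uptake_o2",
      atpase_id = "atpase",
      target_reactions = as.list(target_ids),
      options = c(unclass(options)[c("include_glycogen",
                                     "glycogen_synthesis_cost",
                                     "glycogenolysis_max",
                                     "include_lipid_targets", "atpase_demand",
                                     "include_nadph", "nadph_min")],
                  list(target_fluxes = as.list(options$target_fluxes)))))
}

#' Duplicate a reaction to create degenerate optima
#'
#' Adds \code{n_copies} reactions with identical stoichiometry and bounds
#' (ids suffixed \code{_copyK}), so that any flux through the original can be
#' split arbitrarily across the copies without changing the attainable
#' optimum — a controlled fixture for alternate-optima analysis.
#'
#' @param network a [metabolic_network()].
#' @param reaction_id id of the reaction to duplicate.
#' @param n_copies number of copies to add (0 returns the network unchanged).
#' @return the augmented [metabolic_network()].
#' @export
make_parallel_variant <- function(network, reaction_id, n_copies = 1L) {
  if (!reaction_id %in% reaction_ids(network))
    stop("unknown reaction: ", reaction_id)
  if (n_copies == 0L) return(network)
  orig <- network$reactions[[reaction_id]]
  new <- lapply(seq_len(n_copies), function(k) {
    r <- orig
    r$id <- paste0(reaction_id, "_copy", k)
    if (r$id %in% reaction_ids(network))
      stop("duplicate id collision: ", r$id)
    r
  })
  metabolic_network(network$metabolites,
                    c(unname(network$reactions), new),
                    compartments = network$compartments,
                    annotations = network$annotations)
}
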