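test_that("stoichiometric matrix reflects declared coefficients and order", {
  net <- metabolic_network(
    list(metabolite("A"), metabolite("B")),
    list(reaction("conv", c(A = -1, B = 1))))
  expect_equal(unname(stoich_matrix(net)), matrix(c(-1, 1), 2, 1))

  empty <- metabolic_network(list(), list())
  expect_equal(dim(stoich_matrix(empty)), c(0L, 0L))

  core <- build_core_network()
  N <- stoich_matrix(core)
  expect_equal(ncol(N), length(core$reactions))
  expect_equal(colnames(N), names(core$reactions))
  # 10 substrates: uptake + oxidation each, plus O2 uptake and ATPase
  expect_equal(ncol(N), 2 * nrow(default_yield_table()) + 2)
})

test_that("type invariants are enforced at construction", {
  expect_error(reaction("r", c(A = -1), lower_bound = 2, upper_bound = 1),
               "lower_bound")
  expect_error(reaction("r", c(A = -1), reversible = FALSE, lower_bound = -1),
               "irreversible")
  expect_error(metabolic_network(list(metabolite("A")),
                                 list(reaction("r", c(B = 1)))),
               "undeclared")
  expect_error(metabolic_network(list(metabolite("A"), metabolite("A")),
                                 list()),
               "duplicate")
})

test_that("native JSON round trip is lossless and deterministic", {
  nets <- list(chain_network(), build_core_network(),
               random_network(6, 4, seed = 7))
  for (net in nets) {
    f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
    write_native(net, f1)
    back <- read_native(f1)
    expect_equal(names(back$reactions), names(net$reactions))
    expect_equal(names(back$metabolites), names(net$metabolites))
    for (id in names(net$reactions)) {
      expect_equal(sort(names(back$reactions[[id]]$stoichiometry)),
                   sort(names(net$reactions[[id]]$stoichiometry)))
      expect_equal(back$reactions[[id]]$stoichiometry[
                     names(net$reactions[[id]]$stoichiometry)],
                   net$reactions[[id]]$stoichiometry)
      expect_equal(back$reactions[[id]]$lower_bound,
                   net$reactions[[id]]$lower_bound)
      expect_equal(back$reactions[[id]]$upper_bound,
                   net$reactions[[id]]$upper_bound)
    }
    write_native(back, f2)
    expect_identical(readLines(f1), readLines(f2))
  }
})

test_that("unknown top-level JSON keys are preserved in annotations", {
  f <- withr::local_tempfile()
  write_native(chain_network(), f)
  doc <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  doc$custom_field <- "kept"
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), f)
  net <- read_native(f)
  expect_equal(net$annotations$extra$custom_field, "kept")
})

test_that("SBML reader maps species, boundary conditions and bounds", {
  f <- extdata("example_model.xml")
  net <- read_sbml(f)
  # boundary species X is excluded from mass balance
  expect_setequal(names(net$metabolites), c("A", "B"))
  expect_equal(length(net$reactions), 2L)
  expect_true(net$reactions[["r1"]]$is_exchange)
  expect_equal(net$reactions[["r1"]]$upper_bound, 10)   # kinetic-law bound
  expect_equal(net$reactions[["r1"]]$lower_bound, 0)
  expect_true(net$reactions[["r2"]]$reversible)
  expect_equal(net$reactions[["r2"]]$lower_bound, -default_flux_bound())
  expect_equal(unname(stoich_matrix(net)["B", "r2"]), 2)
  # SBML -> native -> read round trip at id level
  g <- withr::local_tempfile()
  write_native(net, g)
  back <- read_native(g)
  expect_equal(names(back$reactions), names(net$reactions))
  expect_equal(back$reactions[["r2"]]$stoichiometry,
               net$reactions[["r2"]]$stoichiometry)
})

test_that("dead-end metabolites are only-produced or only-consumed species", {
  ab <- metabolic_network(
    list(metabolite("A"), metabolite("B")),
    list(reaction("up_A", c(A = 1), is_exchange = TRUE),
         reaction("ab", c(A = -1, B = 1))))
  expect_equal(find_deadend_metabolites(ab), "B")

  cyc <- metabolic_network(
    list(metabolite("A"), metabolite("B")),
    list(reaction("ab", c(A = -1, B = 1)),
         reaction("ba", c(B = -1, A = 1))))
  expect_equal(find_deadend_metabolites(cyc), character(0))

  # a reversible consumer rescues the dead end
  rev <- metabolic_network(
    list(metabolite("A"), metabolite("B")),
    list(reaction("ab", c(A = -1, B = 1), reversible = TRUE)))
  expect_equal(find_deadend_metabolites(rev), character(0))

  core <- build_core_network(options = core_options(
    include_glycogen = TRUE, include_lipid_targets = TRUE,
    include_nadph = TRUE))
  expect_equal(find_deadend_metabolites(core), character(0))
})

test_that("blocked reactions: chains with closed/open exits", {
  ch <- chain_network()
  expect_equal(find_blocked_reactions(ch, c("up_A", "ex_C")), character(0))
  expect_setequal(find_blocked_reactions(ch, "up_A"),
                  c("up_A", "r_ab", "r_bc", "ex_C"))
})

test_that("blocked reactions equal brute-force flux variability on random networks", {
  for (seed in c(11, 23, 31)) {
    net <- random_network(n_rxn = 8, n_met = 5, seed = seed)
    open <- c("up_1", "ex_5")
    expect_setequal(find_blocked_reactions(net, open),
                    oracle_blocked(net, open))
  }
})
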