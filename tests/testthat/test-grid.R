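test_that("composition enumeration is lexicographic with the closed-form count", {
  c2 <- enumerate_compositions(2, 0.5)
  expect_equal(unname(c2), rbind(c(0, 1), c(0.5, 0.5), c(1, 0)))

  c3 <- enumerate_compositions(3, 0.25)
  expect_equal(nrow(c3), choose(6, 2))       # 15
  expect_true(all(abs(rowSums(c3) - 1) < 1e-12))
  # lexicographic order on the raw vectors
  key <- apply(c3, 1, paste, collapse = ",")
  expect_false(is.unsorted(order(c3[, 1], c3[, 2], c3[, 3])))

  for (n in 2:5) for (k in c(2, 4, 10))
    expect_equal(nrow(enumerate_compositions(n, 1 / k)),
                 choose(k + n - 1, n - 1), info = paste(n, k))

  expect_error(enumerate_compositions(3, 0.3), "integer")
})

test_that("composition invariants are validated", {
  expect_error(composition(c(a = 0.5, b = 0.6)), "sum to 1")
  expect_error(composition(c(a = -0.1, b = 1.1)), "\\[0, 1\\]")
  expect_error(composition(c(0.5, 0.5)), "named")
})

test_that("applying a composition pins zero-share substrates and couples ratios", {
  core <- build_core_network()
  p <- flux_problem(core)
  b <- full_composition(core, c(uptake_glucose = 0.79, uptake_oleate = 0.21))
  d <- minimize_uptake(apply_composition(p, b))
  expect_equal(d$fluxes[["uptake_glucose"]] / d$fluxes[["uptake_oleate"]],
               79 / 21, tolerance = 1e-7)
  others <- setdiff(core$annotations$uptake_set,
                    c("uptake_glucose", "uptake_oleate"))
  expect_true(all(abs(d$fluxes[others]) <= 1e-9))
  expect_error(apply_composition(p, composition(c(nope = 1))), "unknown uptake")
})

test_that("a four-substrate scan covers the grid with closed-form exclusive rows", {
  core <- build_core_network()
  subs <- paste0("uptake_", c("glucose", "oleate", "acetoacetate", "lactate"))
  cfg <- scan_config(subs, step = 0.25, target_fluxes = c(atpase = 21.6))
  scan <- run_scan(core, cfg)
  expect_s3_class(scan, "scan_result")
  expect_equal(nrow(scan), choose(7, 3))     # 35
  expect_true(all(scan$status == "optimal"))
  y <- default_yield_table()
  yields <- y$atp_yield[match(c("glucose", "oleate", "acetoacetate", "lactate"),
                              y$name)]
  expect_true(all(scan$vs >= 21.6 / max(yields) - 1e-8))
  expect_true(all(scan$vs <= 21.6 / min(yields) + 1e-8))
  # exclusive rows: uptake = demand / yield
  for (i in seq_along(subs)) {
    row <- scan[abs(scan[[paste0("beta_", sub("uptake_", "", subs[i]))]] - 1) < 1e-12, ]
    expect_equal(row$vs, 21.6 / yields[i], tolerance = 1e-8)
  }
})

test_that("scanning a single composition equals a direct solve", {
  core <- build_core_network()
  subs <- core$annotations$uptake_set
  b <- full_composition(core, c(uptake_glucose = 0.3, uptake_dha = 0.7))
  cfg <- scan_config(subs, compositions = matrix(b$betas, 1),
                     target_fluxes = c(atpase = 21.6))
  scan <- run_scan(core, cfg)
  d <- minimize_uptake(apply_composition(flux_problem(core), b))
  expect_equal(scan$vs, d$vs, tolerance = 1e-10)
  expect_equal(scan$vO2, d$vO2, tolerance = 1e-10)
})

test_that("scan rows are independent of composition order", {
  core <- build_core_network()
  subs <- paste0("uptake_", c("glucose", "oleate"))
  comps <- enumerate_compositions(2, 0.25)
  cfg <- scan_config(subs, compositions = comps,
                     target_fluxes = c(atpase = 21.6))
  fwd <- run_scan(core, cfg)
  cfg$compositions <- comps[nrow(comps):1, ]
  rev <- run_scan(core, cfg)
  expect_equal(fwd$vs, rev(rev$vs))
  expect_equal(fwd$vO2, rev(rev$vO2))
})

test_that("infeasible compositions are recorded, not dropped", {
  lip <- build_core_network(options = core_options(
    include_lipid_targets = TRUE, include_glycogen = TRUE))
  subs <- lip$annotations$uptake_set
  comps <- rbind(
    full_composition(lip, c(uptake_glucose = 0.9,
                            uptake_alpha_linoleate = 0.05,
                            uptake_dha = 0.05))$betas,
    full_composition(lip, c(uptake_glucose = 0.95,
                            uptake_dha = 0.05))$betas)  # no ALA
  cfg <- scan_config(subs, compositions = comps, target_fluxes = NULL)
  scan <- run_scan(lip, cfg)
  expect_equal(scan$status, c("optimal", "infeasible"))
  expect_true(is.na(scan$vs[2]))
})

test_that("checkpointed scans resume and complete identically", {
  core <- build_core_network()
  subs <- paste0("uptake_", c("glucose", "lactate"))
  cfg0 <- scan_config(subs, step = 0.2, target_fluxes = c(atpase = 21.6))
  full <- run_scan(core, cfg0)

  ck <- withr::local_tempfile(fileext = ".tsv")
  cfg <- scan_config(subs, step = 0.2, target_fluxes = c(atpase = 21.6),
                     checkpoint_file = ck, checkpoint_every = 2L)
  # simulate a killed scan: pre-populate the checkpoint with the first rows
  utils::write.table(full[1:3, ], ck, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  resumed <- run_scan(core, cfg)
  expect_equal(resumed$vs, full$vs, tolerance = 1e-12)
  expect_equal(resumed$status, full$status)
  # checkpoint file ends complete
  final <- utils::read.table(ck, header = TRUE, sep = "\t")
  expect_equal(nrow(final), nrow(full))
})
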