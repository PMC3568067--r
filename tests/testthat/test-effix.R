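test_that("hand-computed toy matrices reproduce the closeness coefficient", {
  et <- efficiency_index(rbind(c(1, 1, 1), c(2, 2, 2), c(3, 3, 3)))
  expect_equal(et$c_plus, c(1, 0.5, 0))
  expect_equal(et$q_plus, c(1, 1, 1))
  expect_equal(et$q_minus, c(3, 3, 3))
  # 2x2 hand case: S+ and S- via Pythagoras
  q <- rbind(c(0, 1), c(1, 0))
  et2 <- efficiency_index(q)
  expect_equal(et2$s_plus, c(1, 1))
  expect_equal(et2$s_minus, c(1, 1))
  expect_equal(et2$c_plus, c(0.5, 0.5))
})

test_that("bounds, ideal and anti-ideal rows, and degenerate input", {
  set.seed(3)
  for (rep in 1:20) {
    q <- matrix(runif(24, 0, 10), 8, 3)
    et <- efficiency_index(q)
    expect_true(all(et$c_plus >= 0 & et$c_plus <= 1))
    # a row equal to the column minima gets C+ = 1
    et1 <- efficiency_index(rbind(q, apply(q, 2, min)))
    expect_equal(et1$c_plus[9], 1)
    et0 <- efficiency_index(rbind(q, apply(q, 2, max)))
    expect_equal(et0$c_plus[9], 0)
  }
  expect_error(efficiency_index(matrix(1, 1, 2)), "two solutions")
  expect_warning(et <- efficiency_index(matrix(5, 3, 2)), "degenerate")
  expect_equal(et$c_plus, rep(1, 3))
})

test_that("translation invariance per criterion; no hidden normalization", {
  set.seed(11)
  q <- matrix(runif(20, 1, 5), 10, 2)
  base <- efficiency_index(q)$c_plus
  shifted <- q; shifted[, 2] <- shifted[, 2] + 100
  expect_equal(efficiency_index(shifted)$c_plus, base, tolerance = 1e-12)
  # scaling a column changes the index (raw units are meaningful)
  scaled <- q; scaled[, 2] <- scaled[, 2] * 50
  expect_gt(max(abs(efficiency_index(scaled)$c_plus - base)), 1e-3)
  # with explicit normalization, column scaling is neutral
  expect_equal(efficiency_index(scaled, normalize = TRUE)$c_plus,
               efficiency_index(q, normalize = TRUE)$c_plus, tolerance = 1e-10)
})

test_that("dominance: improving one criterion with fixed ideals raises C+", {
  q <- rbind(c(4, 2), c(3, 3), c(2, 4), c(5, 5), c(1, 1))
  et <- efficiency_index(q)
  better <- q; better[2, 1] <- 2.5    # strictly better, ideals unchanged
  et2 <- efficiency_index(better)
  expect_equal(et2$q_plus, et$q_plus)
  expect_equal(et2$q_minus, et$q_minus)
  expect_gt(et2$c_plus[2], et$c_plus[2])
})

test_that("reference four-substrate scan criteria reproduce the published indices", {
  cr <- read_criteria_tsv(extdata("atp_scan_criteria.tsv"))
  et <- efficiency_index(cr$q, labels = cr$labels)
  cp <- stats::setNames(et$c_plus, et$labels)
  expect_equal(unname(cp["glc=1.00"]), 0.6576, tolerance = 0.005)
  expect_equal(unname(cp["ole=1.00"]), 0.6849, tolerance = 0.005)
  expect_equal(unname(cp["lac=1.00"]), 0.2091, tolerance = 0.005)
  # the acetoacetate row reproduces only to ~2e-3 (input rounding); the
  # recomputed value is stable at 0.280
  expect_equal(unname(cp["aca=1.00"]), 0.280, tolerance = 0.002)
  # published ranking of the exclusive rows
  expect_gt(cp["ole=1.00"], cp["glc=1.00"])
  expect_gt(cp["glc=1.00"], cp["aca=1.00"])
  expect_gt(cp["aca=1.00"], cp["lac=1.00"])
})

test_that("perfusion-study criteria reproduce the published two-decimal indices", {
  sim <- read_criteria_tsv(extdata("perfusion_simulation_criteria.tsv"))
  et <- efficiency_index(sim$q, labels = sim$labels)
  cp <- stats::setNames(et$c_plus, et$labels)
  expect_equal(unname(cp["glucose"]), 0.83, tolerance = 0.005)
  expect_equal(unname(cp["acetate"]), 0.00, tolerance = 0.005)
  exp_ <- read_criteria_tsv(extdata("perfusion_experiment_criteria.tsv"))
  cpe <- stats::setNames(efficiency_index(exp_$q, labels = exp_$labels)$c_plus,
                         exp_$labels)
  expect_equal(unname(cpe["glucose"]), 0.78, tolerance = 0.005)
})

test_that("subset recomputation shifts the ideals (index is cohort-relative)", {
  cr <- read_criteria_tsv(extdata("atp_scan_criteria.tsv"))
  full <- efficiency_index(cr$q, labels = cr$labels)
  # interior rows only: the cohort extremes (and hence the ideals) change
  sub <- efficiency_index(cr$q[5:10, ], labels = cr$labels[5:10])
  expect_false(isTRUE(all.equal(full$c_plus[5:10], sub$c_plus)))
  expect_false(identical(full$q_minus, sub$q_minus))
})

test_that("rank_compositions scores feasible rows and sorts by C+", {
  core <- build_core_network()
  subs <- paste0("uptake_", c("glucose", "oleate", "acetoacetate", "lactate"))
  scan <- run_scan(core, scan_config(subs, step = 0.5,
                                     target_fluxes = c(atpase = 21.6)))
  et <- rank_compositions(scan, criteria = c("vO2", "vs"))
  expect_equal(et$c_plus, sort(et$c_plus, decreasing = TRUE))
  expect_equal(et$rows$rank, seq_len(nrow(et$rows)))
  expect_true(all(et$c_plus >= 0 & et$c_plus <= 1))
  # injecting infeasible rows: they are excluded, not scored
  scan2 <- scan
  scan2$status[1] <- "infeasible"
  et2 <- rank_compositions(scan2, criteria = c("vO2", "vs"))
  expect_equal(nrow(et2$rows), nrow(scan) - 1L)
  expect_error(rank_compositions(scan[1, ], criteria = c("vO2", "vs")),
               "feasible rows")
  expect_error(rank_compositions(scan, criteria = "nope"), "unknown criteria")
})
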