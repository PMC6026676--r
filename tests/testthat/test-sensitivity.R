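# Pathway sensitivity in FBA and FVA mode.

test_that("reference fluxes prefer the short path and identity scenario is null", {
  b <- toy_model("TOY-B")
  ref <- reference_fluxes(b)
  expect_equal(unname(ref$fluxes[c("R1", "R2", "R3")]), c(10, 0, 0),
               tolerance = 1e-6)

  rep0 <- sensitivity_fba(b, list(block_scenario(character(0))))
  expect_true(all(rep0$fraction_altered == 0))

  expect_error(reference_fluxes(set_bounds(block(b, "EX_A", "full"),
                                           "BIOMASS", lb = 1)),
               "infeasible")
})

test_that("FBA-mode fractions match hand-derived values on TOY-B", {
  b <- toy_model("TOY-B")
  rep <- sensitivity_fba(b, list(block_scenario("R1"), block_scenario("R2")))
  get <- function(scen, ss) {
    rep$fraction_altered[rep$scenario_label == scen & rep$subsystem == ss]
  }
  expect_equal(get("R1", "Glycolysis"), 1.0)               # 1/1: R1 10 -> 0
  expect_equal(get("R1", "Pentose phosphate pathway"), 1.0) # 2/2: 0 -> 10
  expect_equal(get("R2", "Glycolysis"), 0.0)
  expect_equal(get("R2", "Pentose phosphate pathway"), 0.0)
  expect_false(any(rep$lethal))

  # an absurd threshold suppresses everything
  rep_hi <- sensitivity_fba(b, list(block_scenario("R1")), threshold = 1e9)
  expect_true(all(rep_hi$fraction_altered == 0))

  # relative (1 %) mode flags the same alterations here
  rep_rel <- sensitivity_fba(b, list(block_scenario("R1")),
                             threshold = 0.01, threshold_mode = "relative")
  expect_equal(rep_rel$fraction_altered,
               rep$fraction_altered[rep$scenario_label == "R1"])
})

test_that("lethal scenarios are flagged and compared to the relaxed state", {
  b <- toy_model("TOY-B")
  rep <- sensitivity_fba(b, list(block_scenario("EX_A")))
  expect_true(all(rep$lethal))
  # relaxed state is the zero-flux state: only the reference-active subsystem moves
  expect_equal(rep$fraction_altered[rep$subsystem == "Glycolysis"], 1.0)
  expect_equal(rep$fraction_altered[rep$subsystem == "Pentose phosphate pathway"], 0.0)
})

test_that("unclassified reactions stay out of the report", {
  b <- toy_model("TOY-B")
  rep <- sensitivity_fba(b, list(block_scenario("R1")))
  expect_setequal(unique(rep$subsystem),
                  c("Glycolysis", "Pentose phosphate pathway"))
})

test_that("FVA-mode detects forced reroutes and supersets the FBA-mode set", {
  b <- toy_model("TOY-B")
  scens <- list(block_scenario(character(0)), block_scenario("R1"),
                block_scenario("R2"))
  fva_rep <- sensitivity_fva(b, scens, fraction = 0.9)
  fba_rep <- sensitivity_fba(b, scens)
  g <- function(rep, scen, ss) {
    rep$fraction_altered[rep$scenario_label == scen & rep$subsystem == ss]
  }
  # blocking R1 pins the PPP reactions: ranges collapse away from reference
  expect_equal(g(fva_rep, "R1", "Pentose phosphate pathway"), 1.0)
  expect_equal(g(fva_rep, "none", "Glycolysis"), 0.0)
  expect_equal(g(fva_rep, "none", "Pentose phosphate pathway"), 0.0)
  # FVA flags at least whatever FBA flags
  both <- merge(fba_rep[, c("scenario_label", "subsystem", "fraction_altered")],
                fva_rep[, c("scenario_label", "subsystem", "fraction_altered")],
                by = c("scenario_label", "subsystem"),
                suffixes = c("_fba", "_fva"))
  expect_true(all(both$fraction_altered_fva >= both$fraction_altered_fba - 1e-9))
})

test_that("sensitivity matrix pivots and top_changers filters", {
  b <- toy_model("TOY-B")
  rep <- sensitivity_fba(b, list(block_scenario("R1"), block_scenario("R2")))
  m <- sensitivity_matrix(rep)
  expect_equal(dim(m), c(2, 2))
  expect_equal(m["R1", "Glycolysis"], 1.0)
  expect_equal(m["R2", "Pentose phosphate pathway"], 0.0)

  kept <- top_changers(rep, min_total = 1.5)
  expect_setequal(unique(kept$scenario_label), "R1")
})
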