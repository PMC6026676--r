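# Model container, exchange detection, medium application, SBML I/O.

test_that("exchange detection follows the single-boundary-metabolite rule", {
  a <- toy_model("TOY-A")
  expect_identical(detect_exchanges(a), "EX_A")

  # permuting reaction order does not change the result
  perm <- rev(seq_len(nrow(a$reactions)))
  b <- metabolic_model(a$id, a$metabolites, a$reactions[perm, ],
                       a$S[, perm], a$objective)
  expect_identical(detect_exchanges(b), detect_exchanges(a))

  # a model with no boundary metabolites has no exchanges
  mets <- data.frame(id = c("A_c", "B_c"), name = c("A_c", "B_c"),
                     compartment = "c", stringsAsFactors = FALSE)
  rxns <- data.frame(id = c("R1", "BIOMASS"), name = c("R1", "b"),
                     lower_bound = 0, upper_bound = 10,
                     subsystem = NA_character_, stringsAsFactors = FALSE)
  S <- matrix(c(-1, 1, 0, -1), 2, dimnames = list(mets$id, rxns$id))
  m <- metabolic_model("closed", mets, rxns, S, "BIOMASS")
  expect_length(detect_exchanges(m), 0)

  # biomass-style pseudo reactions are never exchanges even if single-met
  o2 <- toy_model("TOY-O2")
  expect_identical(detect_exchanges(o2), c("EX_A", "EX_Fe2", "EX_Fe3", "EX_O2"))
  expect_false("BIOMASS" %in% detect_exchanges(a))
})

test_that("apply_medium closes absent uptakes and honors anaerobiosis", {
  a <- toy_model("TOY-A")
  med <- medium_spec(c(EX_A = 10))
  m <- apply_medium(a, med)
  i <- match("EX_A", m$reactions$id)
  expect_equal(unname(m$reactions$lower_bound[i]), -10)
  expect_equal(unname(m$reactions$upper_bound[i]), 1000)

  # exchanges not in the medium lose uptake
  empty <- apply_medium(a, medium_spec())
  expect_equal(unname(empty$reactions$lower_bound[i]), 0)
  expect_equal(fba(empty)$objective_value, 0)

  # anaerobic overrides an oxygen entry in the medium
  o2m <- toy_model("TOY-O2")
  med2 <- full_medium(o2m, anaerobic = TRUE)
  expect_true("EX_O2" %in% names(med2$uptake))
  m2 <- apply_medium(o2m, med2)
  expect_equal(m2$reactions$lower_bound[match("EX_O2", m2$reactions$id)], 0)

  # a medium never widens bounds beyond the declared ones
  wide <- apply_medium(a, medium_spec(c(EX_A = 500)))
  expect_equal(wide$reactions$lower_bound[i], -10)

  expect_error(apply_medium(a, medium_spec(c(R1 = 5))), "not exchange")
  expect_error(medium_spec(c(EX_A = -3)), ">= 0")
})

test_that("block() supports full and uptake-only modes", {
  a <- toy_model("TOY-A")
  full <- block(a, "R1", "full")
  i <- match("R1", full$reactions$id)
  expect_equal(full$reactions$lower_bound[i], 0)
  expect_equal(full$reactions$upper_bound[i], 0)

  up <- block(a, "EX_A", "uptake_only")
  j <- match("EX_A", up$reactions$id)
  expect_equal(up$reactions$lower_bound[j], 0)
  expect_equal(up$reactions$upper_bound[j], 1000)
  expect_equal(fba(up)$objective_value, 0)

  expect_identical(block(a, character(0), "full"), a)
  expect_error(block(a, "R1", "uptake_only"), "exchange")
})

test_that("medium TSV round-trips including the anaerobic flag", {
  med <- medium_spec(c(EX_A = 10, EX_O2 = 5.5), anaerobic = TRUE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_medium(med, path)
  back <- read_medium(path)
  expect_equal(back$uptake, med$uptake)
  expect_true(back$anaerobic)
})

test_that("SBML round-trip preserves ids, bounds, stoichiometry, subsystems, objective", {
  for (nm in fixture_names) {
    m <- toy_model(nm)
    path <- withr::local_tempfile(fileext = ".xml")
    write_sbml(m, path)
    m2 <- read_sbml(path)
    expect_identical(m2$id, m$id)
    expect_identical(m2$reactions$id, m$reactions$id)
    expect_identical(m2$metabolites$id, m$metabolites$id)
    expect_identical(m2$metabolites$compartment, m$metabolites$compartment)
    expect_lt(max(abs(m2$reactions$lower_bound - m$reactions$lower_bound)), 1e-9)
    expect_lt(max(abs(m2$reactions$upper_bound - m$reactions$upper_bound)), 1e-9)
    expect_identical(m2$reactions$subsystem, m$reactions$subsystem)
    expect_identical(m2$objective, m$objective)
    expect_equal(as.matrix(m2$S), as.matrix(m$S))
  }
})

test_that("cobrapy reads our SBML identically (independent oracle)", {
  fx <- make_fixture("TOY-O2")
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(fx$model, path)
  out <- system2("python", c("-c", shQuote(paste0(
    "import cobra; m = cobra.io.read_sbml_model('", path, "'); ",
    "print(len(m.reactions), len(m.exchanges), round(m.slim_optimize(), 6))"))),
    stdout = TRUE, stderr = FALSE)
  got <- strsplit(tail(out, 1), " ")[[1]]
  expect_equal(as.integer(got[1]), nrow(fx$model$reactions))
  expect_equal(as.integer(got[2]), length(detect_exchanges(fx$model)))
  expect_equal(as.numeric(got[3]), fba(fx$model)$objective_value,
               tolerance = 1e-6)
})

test_that("reader falls back to Level-2 kinetic-law bounds with a warning", {
  l2 <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">',
    '<model id="mini" name="mini">',
    '<listOfCompartments><compartment id="e"/><compartment id="c"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="M_A_e" name="A" compartment="e"/>',
    '<species id="M_A_c" name="A" compartment="c"/>',
    '</listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="R_EX_A" reversible="true">',
    '<listOfReactants><speciesReference species="M_A_e" stoichiometry="1"/></listOfReactants>',
    '<kineticLaw><listOfParameters>',
    '<parameter id="LOWER_BOUND" value="-7"/><parameter id="UPPER_BOUND" value="999"/>',
    '</listOfParameters></kineticLaw>',
    '</reaction>',
    '<reaction id="R_T_A" reversible="false">',
    '<listOfReactants><speciesReference species="M_A_e"/></listOfReactants>',
    '<listOfProducts><speciesReference species="M_A_c"/></listOfProducts>',
    '</reaction>',
    '<reaction id="R_biomass" reversible="false">',
    '<listOfReactants><speciesReference species="M_A_c"/></listOfReactants>',
    '</reaction>',
    '</listOfReactions>',
    '</model></sbml>')
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(l2, path)
  expect_warning(m <- read_sbml(path), "kinetic-law")
  expect_equal(m$reactions$lower_bound[m$reactions$id == "EX_A"], -7)
  expect_equal(m$reactions$upper_bound[m$reactions$id == "EX_A"], 999)
  # default bounds and biomass naming fallback for the objective
  expect_equal(m$reactions$lower_bound[m$reactions$id == "T_A"], 0)
  expect_equal(m$reactions$upper_bound[m$reactions$id == "T_A"], 1000)
  expect_identical(m$objective, "biomass")
})

test_that("reader errors name the offending reaction and missing objective", {
  m <- toy_model("TOY-A")
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, path)
  txt <- readLines(path)
  broken <- sub('species="M_A_c" stoichiometry="1"',
                'species="M_GHOST" stoichiometry="1"', txt)
  path2 <- withr::local_tempfile(fileext = ".xml")
  writeLines(broken, path2)
  expect_error(read_sbml(path2), "unknown species")

  no_obj <- txt[!grepl("fbc:listOfObjectives|fbc:objective|fluxObjective", txt)]
  no_obj <- gsub('id="R_BIOMASS"', 'id="R_growth_a"', no_obj)
  no_obj <- gsub('id="M_B_c" name="B_c"', 'id="M_B_c" name="B"', no_obj)
  path3 <- withr::local_tempfile(fileext = ".xml")
  writeLines(no_obj, path3)
  expect_error(read_sbml(path3), "no objective")
})
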