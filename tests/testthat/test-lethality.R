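# Synthetic lethality: fixture truths, oracle equivalence, classification,
# anaerobic variant.

test_that("single and double lethals match the stored fixture truths", {
  for (nm in fixture_names) {
    fx <- make_fixture(nm)
    s <- single_lethals(fx$model)
    expect_identical(as.character(s), sort(fx$truth$singles), label = nm)
    d <- double_lethals(fx$model, s)
    expect_same_pairs(d, fx$truth$doubles)
    # no pair ever contains a single lethal
    expect_false(any(unlist(d) %in% s))
  }
})

test_that("removing the long path makes R1 essential (topology shift)", {
  a <- toy_model("TOY-A")
  a2 <- remove_reactions(a, c("R2", "R3"))
  expect_identical(as.character(single_lethals(a2)),
                   c("BIOMASS", "EX_A", "R1", "T_A"))
  expect_length(double_lethals(a2), 0)
})

test_that("pruned search equals the exhaustive oracle on random models", {
  for (sd in c(101, 102, 103)) {
    r <- make_random(n_substrates = 2, n_parallel_paths = 2, seed = sd,
                     with_byproduct = sd %% 2 == 0)
    s <- single_lethals(r$model)
    expect_identical(as.character(s), r$truth$singles)
    d <- double_lethals(r$model, s)
    expect_same_pairs(d, r$truth$doubles)
  }
})

test_that("pairs are canonical: sorted members, lexicographic, deduplicated", {
  fx <- make_fixture("TOY-O2")
  d <- double_lethals(fx$model)
  strs <- pair_strings(d)
  expect_identical(strs, sort(strs))
  expect_false(anyDuplicated(strs) > 0)
  expect_true(all(vapply(d, function(p) p[1] < p[2], TRUE)))
})

test_that("lethality threshold modes behave and dead models error", {
  ch <- chain_model(uptake = 10)
  expect_identical(as.character(single_lethals(ch)),
                   c("BIOMASS", "EX_A", "T_A"))
  # relative cutoff: same result on this all-or-nothing topology
  expect_identical(as.character(single_lethals(ch, threshold = 0.01,
                                               relative = TRUE)),
                   c("BIOMASS", "EX_A", "T_A"))
  dead <- block(ch, "EX_A", "full")
  expect_error(single_lethals(dead), "does not grow")
})

test_that("classification separates exchange and intracellular lethals", {
  fx <- make_fixture("TOY-A")
  s <- single_lethals(fx$model); d <- double_lethals(fx$model, s)
  res <- classify_lethals(fx$model, s, d)
  expect_identical(res$exchange_single_lethals, "EX_A")
  expect_length(res$pairs_with_exchange, 0)
  expect_equal(res$wild_type_growth, 10)

  fo <- make_fixture("TOY-O2")
  so <- single_lethals(fo$model); do <- double_lethals(fo$model, so)
  reso <- classify_lethals(fo$model, so, do)
  expect_identical(reso$exchange_single_lethals, c("EX_A", "EX_Fe2"))
  expect_same_pairs(reso$pairs_two_exchanges, list(c("EX_Fe3", "EX_O2")))
  expect_length(reso$pairs_with_exchange, 4)  # any pair with >= 1 exchange
})

test_that("anaerobic variant deletes oxygen exchange and shifts essentiality", {
  fo <- make_fixture("TOY-O2")
  an <- anaerobic_variant(fo$model)
  expect_false("EX_O2" %in% an$reactions$id)
  expect_match(an$id, "_anaerobic$")

  s_aero <- single_lethals(fo$model)
  s_anaero <- single_lethals(an)
  ex_aero <- intersect(s_aero, detect_exchanges(fo$model))
  ex_anaero <- intersect(s_anaero, detect_exchanges(an))
  # exactly one additional essential exchange appears without oxygen
  expect_identical(setdiff(ex_anaero, ex_aero), "EX_Fe3")
  expect_true(all(s_aero %in% s_anaero))

  expect_error(anaerobic_variant(toy_model("TOY-A")), "no oxygen exchange")
})

test_that("adding a parallel path never creates new single lethals", {
  a <- toy_model("TOY-A")
  s_before <- single_lethals(a)
  # add an independent alternative route A_c -> B_c
  rxns <- rbind(a$reactions,
                data.frame(id = "R_ALT", name = "R_ALT", lower_bound = 0,
                           upper_bound = 1000, subsystem = NA_character_))
  S <- as.matrix(a$S)
  S <- cbind(S, R_ALT = 0)
  S["A_c", "R_ALT"] <- -1; S["B_c", "R_ALT"] <- 1
  a2 <- metabolic_model("TOY-A+", a$metabolites, rxns, S, a$objective)
  s_after <- single_lethals(a2)
  expect_true(all(s_after %in% s_before))
})
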