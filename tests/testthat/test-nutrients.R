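# Minimal sufficient nutrient combination search.

test_that("base_state closes non-essential uptakes and keeps essentials open", {
  cc <- toy_model("TOY-C")
  bs <- base_state(cc, character(0))
  expect_equal(fba(bs)$objective_value, 0)
  expect_setequal(names(attr(bs, "unblock_lb")), c("EX_A", "EX_B", "EX_N"))

  # essential exchanges stay untouched
  a <- toy_model("TOY-A")
  bs2 <- base_state(a, "EX_A")
  expect_equal(fba(bs2)$objective_value, 10)
  expect_length(attr(bs2, "unblock_lb"), 0)
  res <- search_combos(bs2, k_max = 1, regime = "anaerobic")
  expect_equal(nrow(res), 0)                 # vacuous search
  expect_equal(attr(res, "base_growth"), 10) # ... because the base already grows

  expect_error(base_state(a, "R1"), "non-exchange")
})

test_that("TOY-C needs exactly the pair {EX_A, EX_B}", {
  cc <- toy_model("TOY-C")
  bs <- base_state(cc, character(0))
  res <- search_combos(bs, k_max = 2, regime = "anaerobic")
  expect_false(any(res$grows[res$k == 1]))
  grown <- res[res$grows, ]
  expect_identical(grown$combo, "EX_A|EX_B")
  expect_equal(grown$growth, 10)
  expect_true(grown$minimal)
  # exhaustive enumeration: all C(3,1) + C(3,2) combos present
  expect_equal(nrow(res), 3 + 3)
})

test_that("growth is monotone under combo supersets", {
  cc <- toy_model("TOY-C")
  bs <- base_state(cc, character(0))
  res <- search_combos(bs, k_max = 3, regime = "anaerobic")
  combos <- strsplit(res$combo, "|", fixed = TRUE)
  for (i in seq_along(combos)) {
    for (j in seq_along(combos)) {
      if (i != j && all(combos[[i]] %in% combos[[j]])) {
        expect_gte(res$growth[j], res$growth[i] - 1e-6)
      }
    }
  }
  # non-minimal growing supersets are retained but flagged
  sup <- res[res$combo == "EX_A|EX_B|EX_N", ]
  expect_true(sup$grows); expect_false(sup$minimal)
})

test_that("the grows flag flips exactly at the growth threshold", {
  above <- chain_model(uptake = 1.0000001e-5)
  below <- chain_model(uptake = 0.9999999e-5)
  for (mod in list(above, below)) {
    bs <- base_state(mod, character(0))
    res <- search_combos(bs, k_max = 1, regime = "anaerobic")
    expect_equal(res$grows, res$growth >= 1e-5)
  }
  r_above <- search_combos(base_state(above, character(0)), k_max = 1,
                           regime = "anaerobic")
  r_below <- search_combos(base_state(below, character(0)), k_max = 1,
                           regime = "anaerobic")
  expect_true(r_above$grows)
  expect_false(r_below$grows)
})

test_that("anaerobic regime excludes oxygen from candidates and keeps it shut", {
  fo <- toy_model("TOY-O2")
  bs <- base_state(fo, c("EX_A", "EX_Fe2"))   # the essential exchanges
  anaero <- search_combos(bs, k_max = 1, regime = "anaerobic")
  expect_false(any(grepl("EX_O2", anaero$combo)))
  aero <- search_combos(bs, k_max = 1, regime = "aerobic")
  expect_true(any(grepl("EX_O2", aero$combo)))
  # with Fe2 available, either O2 (oxidation) or Fe3 (uptake) restores growth
  expect_setequal(aero$combo[aero$grows], c("EX_Fe3", "EX_O2"))
  expect_identical(anaero$combo[anaero$grows], "EX_Fe3")
})

test_that("growth_rate_table pairs nutrients with designated partners", {
  res <- data.frame(
    combo = c("EX_O2|EX_X", "EX_O2|EX_Y", "EX_Fe3|EX_X", "EX_Fe3|EX_Y",
              "EX_Fe3|EX_Z"),
    k = 2L, regime = "mixed",
    growth = c(5, 2, 5, 0, 3),
    grows = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    minimal = TRUE, stringsAsFactors = FALSE)
  tab <- growth_rate_table(res, "EX_O2", "EX_Fe3")
  expect_setequal(tab$nutrient, c("EX_X", "EX_Y", "EX_Z"))
  x <- tab[tab$nutrient == "EX_X", ]
  expect_true(x$regime_indifferent)           # equal growth with both partners
  y <- tab[tab$nutrient == "EX_Y", ]
  expect_true(y$aerobic_only)                 # grows with O2 partner only
  z <- tab[tab$nutrient == "EX_Z", ]
  expect_true(is.na(z$growth_with_a) && z$grows_b)
})

test_that("the combinatorial budget guard trips", {
  cc <- toy_model("TOY-C")
  bs <- base_state(cc, character(0))
  expect_error(search_combos(bs, k_max = 2, regime = "anaerobic",
                             max_combos = 2), "budget")
})
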