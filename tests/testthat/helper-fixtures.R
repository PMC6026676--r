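# Shared helpers: fixture shortcuts and small ad-hoc model builders.

fixture_names <- c("TOY-A", "TOY-B", "TOY-C", "TOY-D", "TOY-O2")

toy_model <- function(name) make_fixture(name)$model

pair_strings <- function(pairs) {
  vapply(pairs, paste, "", collapse = "|")
}

expect_same_pairs <- function(a, b) {
  expect_identical(pair_strings(a), pair_strings(b))
}

# Minimal one-substrate chain with a tunable uptake bound: growth equals
# the uptake bound exactly, which makes threshold-boundary tests sharp.
chain_model <- function(uptake = 10, id = "CHAIN") {
  mets <- data.frame(id = c("A_e", "A_c"), name = c("A_e", "A_c"),
                     compartment = c("e", "c"), stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("EX_A", "T_A", "BIOMASS"),
    name = c("EX_A", "T_A", "biomass"),
    lower_bound = c(-uptake, 0, 0),
    upper_bound = c(1000, 1000, 1000),
    subsystem = NA_character_, stringsAsFactors = FALSE)
  S <- matrix(c(-1, 0,
                -1, 1,
                0, -1),
              nrow = 2, byrow = FALSE,
              dimnames = list(mets$id, rxns$id))
  metabolic_model(id, mets, rxns, S, "BIOMASS")
}
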