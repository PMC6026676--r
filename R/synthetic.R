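#' Toy genome-scale models with analytically known structure
#'
#' The generator emulates the structure of AGORA gut-bacterial
#' reconstructions at toy scale: an extracellular compartment `e` and a
#' cytosol `c`, boundary `EX_*` exchange reactions (uptake negative,
#' secretion positive), transporters, internal conversion paths and a
#' single biomass objective.  Each named fixture encodes one motif of the
#' analysis pipeline so that every stage can be validated against
#' hand-derived or brute-force truth without downloading any
#' reconstruction:
#'
#' * `TOY-A` — one substrate, one transporter, a single-reaction path in
#'   parallel with a two-reaction path: unique-path reactions are single
#'   lethals, the parallel paths yield exactly the double-lethal pairs
#'   \{R1,R2\} and \{R1,R3\}.
#' * `TOY-B` — `TOY-A` with subsystem labels (R1 "Glycolysis"; R2, R3
#'   "Pentose phosphate pathway") for pathway-sensitivity tests.
#' * `TOY-C` — two jointly required substrates A and B plus a useless
#'   nutrient N: the minimal sufficient nutrient combination is exactly
#'   \{EX_A, EX_B\}.
#' * `TOY-D` — `TOY-A` where the short path co-produces a byproduct P that
#'   can be secreted: a growth-coupled production envelope.
#' * `TOY-O2` — iron/oxygen coupling: biomass needs both ferrous and
#'   ferric iron; ferric iron comes either from its own exchange or from
#'   oxidation of ferrous iron by oxygen (mirroring
#'   4Fe2+ + 4H+ + O2 -> 4Fe3+ + 2H2O at toy stoichiometry), so the
#'   oxygen and ferric-iron exchanges form a double-lethal pair while the
#'   ferrous-iron exchange is single-lethal.
#'
#' @param name fixture name: `"TOY-A"`, `"TOY-B"`, `"TOY-C"`, `"TOY-D"`
#'   or `"TOY-O2"`.
#' @return list with elements `model` (a [metabolic_model()]) and `truth`
#'   (a list with at least `singles`, `doubles` — a list of sorted id
#'   pairs — `exchanges` and `max_growth`).
#' @export
make_fixture <- function(name = c("TOY-A", "TOY-B", "TOY-C", "TOY-D", "TOY-O2")) {
  name <- match.arg(name)
  switch(name,
         "TOY-A" = fixture_toy_a(),
         "TOY-B" = fixture_toy_b(),
         "TOY-C" = fixture_toy_c(),
         "TOY-D" = fixture_toy_d(),
         "TOY-O2" = fixture_toy_o2())
}

# Assemble a metabolic_model from a list of reactions given as
# stoichiometry vectors named by metabolite id.  Compartment is inferred
# from the id suffix ("_e" extracellular, otherwise cytosol).
build_toy_model <- function(id, rxns, objective) {
  met_ids <- sort(unique(unlist(lapply(rxns, function(r) names(r$mets)))))
  mets <- data.frame(
    id = met_ids, name = met_ids,
    compartment = ifelse(grepl("_e$", met_ids), "e", "c"),
    stringsAsFactors = FALSE)
  rxn_tab <- data.frame(
    id = vapply(rxns, `[[`, "", "id"),
    name = vapply(rxns, function(r) r$name %||% r$id, ""),
    lower_bound = vapply(rxns, function(r) r$lb %||% 0, 0),
    upper_bound = vapply(rxns, function(r) r$ub %||% 1000, 0),
    subsystem = vapply(rxns, function(r) r$subsystem %||% NA_character_, ""),
    stringsAsFactors = FALSE)
  S <- matrix(0, length(met_ids), length(rxns),
              dimnames = list(met_ids, rxn_tab$id))
  for (k in seq_along(rxns)) S[names(rxns[[k]]$mets), k] <- rxns[[k]]$mets
  metabolic_model(id, mets, rxn_tab, S, objective)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rx <- function(id, mets, lb = 0, ub = 1000, subsystem = NULL, name = NULL) {
  list(id = id, mets = mets, lb = lb, ub = ub, subsystem = subsystem,
       name = name)
}

toy_a_reactions <- function(subsystems = FALSE) {
  ss <- function(x) if (subsystems) x else NULL
  list(
    rx("BIOMASS", c(B_c = -1), name = "biomass pseudo-reaction"),
    rx("EX_A", c(A_e = -1), lb = -10),
    rx("R1", c(A_c = -1, B_c = 1), subsystem = ss("Glycolysis")),
    rx("R2", c(A_c = -1, M_c = 1), subsystem = ss("Pentose phosphate pathway")),
    rx("R3", c(M_c = -1, B_c = 1), subsystem = ss("Pentose phosphate pathway")),
    rx("T_A", c(A_e = -1, A_c = 1)))
}

fixture_toy_a <- function() {
  model <- build_toy_model("TOY-A", toy_a_reactions(FALSE), "BIOMASS")
  list(model = model,
       truth = list(
         singles = c("BIOMASS", "EX_A", "T_A"),
         doubles = list(c("R1", "R2"), c("R1", "R3")),
         exchanges = "EX_A",
         max_growth = 10))
}

fixture_toy_b <- function() {
  model <- build_toy_model("TOY-B", toy_a_reactions(TRUE), "BIOMASS")
  tr <- fixture_toy_a()$truth
  tr$reference_fluxes <- c(BIOMASS = 10, EX_A = -10, R1 = 10, R2 = 0,
                           R3 = 0, T_A = 10)
  list(model = model, truth = tr)
}

fixture_toy_c <- function() {
  rxns <- c(toy_a_reactions(FALSE)[-1], list(
    rx("BIOMASS", c(B_c = -1, C_c = -1), name = "biomass pseudo-reaction"),
    rx("EX_B", c(Bs_e = -1), lb = -10),
    rx("T_B", c(Bs_e = -1, Bs_c = 1)),
    rx("R4", c(Bs_c = -1, C_c = 1)),
    rx("EX_N", c(N_e = -1), lb = -10),
    rx("T_N", c(N_e = -1, N_c = 1))))
  model <- build_toy_model("TOY-C", rxns, "BIOMASS")
  list(model = model,
       truth = list(
         singles = c("BIOMASS", "EX_A", "EX_B", "R4", "T_A", "T_B"),
         doubles = list(c("R1", "R2"), c("R1", "R3")),
         exchanges = c("EX_A", "EX_B", "EX_N"),
         max_growth = 10,
         minimal_combo = c("EX_A", "EX_B")))
}

fixture_toy_d <- function() {
  rxns <- toy_a_reactions(FALSE)
  rxns[[3]] <- rx("R1", c(A_c = -1, B_c = 1, P_c = 1))  # byproduct P
  rxns <- c(rxns, list(
    rx("T_P", c(P_c = -1, P_e = 1)),
    rx("EX_P", c(P_e = -1), lb = 0)))
  model <- build_toy_model("TOY-D", rxns, "BIOMASS")
  # note: the byproduct makes the long path conditionally essential — with
  # the P drain (EX_P or T_P) blocked, R1 cannot run, so {drain, R2} and
  # {drain, R3} are lethal pairs too.
  list(model = model,
       truth = list(
         singles = c("BIOMASS", "EX_A", "T_A"),
         doubles = list(c("EX_P", "R2"), c("EX_P", "R3"),
                        c("R1", "R2"), c("R1", "R3"),
                        c("R2", "T_P"), c("R3", "T_P")),
         exchanges = c("EX_A", "EX_P"),
         max_growth = 10,
         # at mu_fix = 10: all carbon may route through R1 (max P) or
         # through R2/R3 (no P); uptake of A is saturated either way.
         envelope = list(EX_P = c(production = 10, consumption = 0),
                         EX_A = c(production = 0, consumption = 10))))
}

fixture_toy_o2 <- function() {
  rxns <- list(
    rx("BIOMASS", c(A_c = -1, Fe2_c = -0.1, Fe3_c = -0.1),
       name = "biomass pseudo-reaction"),
    rx("EX_A", c(A_e = -1), lb = -10),
    rx("EX_Fe2", c(Fe2_e = -1), lb = -10),
    rx("EX_Fe3", c(Fe3_e = -1), lb = -10),
    rx("EX_O2", c(O2_e = -1), lb = -10),
    rx("R_FEOX", c(Fe2_c = -1, O2_c = -0.25, Fe3_c = 1),
       name = "ferrous iron oxidation (O2-dependent)"),
    rx("T_A", c(A_e = -1, A_c = 1)),
    rx("T_Fe2", c(Fe2_e = -1, Fe2_c = 1)),
    rx("T_Fe3", c(Fe3_e = -1, Fe3_c = 1)),
    rx("T_O2", c(O2_e = -1, O2_c = 1)))
  model <- build_toy_model("TOY-O2", rxns, "BIOMASS")
  dbl <- list(c("EX_Fe3", "EX_O2"), c("EX_Fe3", "R_FEOX"),
              c("EX_Fe3", "T_O2"), c("EX_O2", "T_Fe3"),
              c("R_FEOX", "T_Fe3"), c("T_Fe3", "T_O2"))
  list(model = model,
       truth = list(
         singles = c("BIOMASS", "EX_A", "EX_Fe2", "T_A", "T_Fe2"),
         doubles = dbl,
         exchanges = c("EX_A", "EX_Fe2", "EX_Fe3", "EX_O2"),
         max_growth = 10))
}

#' Randomized toy models with brute-force truth
#'
#' Generates a layered substrate -> precursor -> biomass network: each of
#' `n_substrates` substrates has an exchange, a transporter and
#' `n_parallel_paths` independent conversion paths (one or two reactions
#' long, chosen at random) to its biomass precursor; biomass consumes all
#' precursors.  Exchange uptake limits are drawn uniformly between 5 and
#' 15 mmol/gDW/h.  Single- and double-lethal truth is computed at
#' generation time by exhaustive knockout enumeration
#' ([enumerate_lethals()]); generation is pure in the seed.
#'
#' @param n_substrates number of substrates (each with its own exchange).
#' @param n_parallel_paths parallel conversion paths per substrate.
#' @param with_byproduct add a secreted byproduct on the first path of the
#'   first substrate.
#' @param subsystem_labels labels cycled over internal path reactions.
#' @param seed integer seed; same seed, same model (byte-identical SBML).
#' @param compute_truth set `FALSE` to skip the brute-force enumeration.
#' @return list with `model` and `truth` (as in [make_fixture()]).
#' @export
make_random <- function(n_substrates = 2, n_parallel_paths = 2,
                        with_byproduct = FALSE,
                        subsystem_labels = c("Glycolysis",
                                             "Pentose phosphate pathway",
                                             "Amino acid metabolism"),
                        seed = 1, compute_truth = TRUE) {
  stopifnot(n_substrates >= 1, n_parallel_paths >= 1)
  set.seed(as.integer(seed))
  rxns <- list()
  biomass_mets <- c()
  lab_i <- 0L
  for (s in seq_len(n_substrates)) {
    sub_e <- sprintf("S%d_e", s); sub_c <- sprintf("S%d_c", s)
    pre_c <- sprintf("P%d_c", s)
    up <- round(stats::runif(1, 5, 15), 3)
    rxns <- c(rxns, list(
      rx(sprintf("EX_S%d", s), stats::setNames(-1, sub_e), lb = -up),
      rx(sprintf("T_S%d", s), stats::setNames(c(-1, 1), c(sub_e, sub_c)))))
    for (p in seq_len(n_parallel_paths)) {
      lab_i <- lab_i + 1L
      lab <- subsystem_labels[1L + (lab_i - 1L) %% length(subsystem_labels)]
      two_step <- stats::runif(1) < 0.5
      if (two_step) {
        mid <- sprintf("I%d_%d_c", s, p)
        rxns <- c(rxns, list(
          rx(sprintf("P%d_%da", s, p),
             stats::setNames(c(-1, 1), c(sub_c, mid)), subsystem = lab),
          rx(sprintf("P%d_%db", s, p),
             stats::setNames(c(-1, 1), c(mid, pre_c)), subsystem = lab)))
      } else {
        rxns <- c(rxns, list(
          rx(sprintf("P%d_%da", s, p),
             stats::setNames(c(-1, 1), c(sub_c, pre_c)), subsystem = lab)))
      }
    }
    biomass_mets <- c(biomass_mets, stats::setNames(-1, pre_c))
  }
  if (with_byproduct) {
    # first path of substrate 1 co-produces W, which can only be secreted
    k <- which(vapply(rxns, function(r) r$id == "P1_1a", TRUE))[1]
    rxns[[k]]$mets <- c(rxns[[k]]$mets, W_c = 1)
    rxns <- c(rxns, list(
      rx("T_W", c(W_c = -1, W_e = 1)),
      rx("EX_W", c(W_e = -1), lb = 0)))
  }
  rxns <- c(list(rx("BIOMASS", biomass_mets,
                    name = "biomass pseudo-reaction")), rxns)
  model <- build_toy_model(sprintf("RND-%d", seed), rxns, "BIOMASS")
  if (n_reactions(model) > 40) {
    stop("random model exceeds the 40-reaction brute-force cap")
  }
  truth <- list(exchanges = detect_exchanges(model))
  wt <- fba(model)
  if (wt$status != "optimal" || wt$objective_value < 1e-5) {
    stop("generated model is not viable")  # by construction unreachable
  }
  truth$max_growth <- wt$objective_value
  if (compute_truth) {
    enum <- enumerate_lethals(model)
    truth$singles <- enum$singles
    truth$doubles <- enum$doubles
  }
  list(model = model, truth = truth)
}
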