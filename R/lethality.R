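#' Synthetic lethality of reactions
#'
#' Single lethal reactions are those whose full blocking (both bounds set
#' to zero) drops maximal growth below the growth threshold; double lethal
#' pairs are pairs of individually non-lethal reactions whose joint
#' blocking does.  The search prunes the pair space with the support of
#' minimum-norm (parsimonious) optimal flux vectors, in the spirit of
#' Fast-SL: a reaction absent from some optimal solution cannot be
#' essential (that solution certifies continued growth), and a pair can
#' only be lethal if its second member carries flux in every optimum of
#' the model with the first member blocked.  The pruning is an
#' optimization, not a semantics change — [enumerate_lethals()] is the
#' exhaustive oracle and the two must agree exactly on any model.
#'
#' @param model a [metabolic_model()].
#' @param threshold growth threshold below which the model is considered
#'   dead (default `1e-5`, absolute).
#' @param relative if `TRUE`, `threshold` is interpreted as a fraction of
#'   wild-type growth instead of an absolute flux.
#' @param solver LP backend.
#' @return for `single_lethals()`, a sorted character vector of reaction
#'   ids; the number of growth LPs solved is in attribute `"n_tested"`.
#' @export
single_lethals <- function(model, threshold = 1e-5, relative = FALSE,
                           solver = getOption("fluxscope.solver", "simplex")) {
  thr <- lethal_threshold(model, threshold, relative, solver)
  sol <- fba(model, tie_break = "parsimonious", solver = solver)
  support <- names(sol$fluxes)[abs(sol$fluxes) > 1e-9]
  lethal <- character(0)
  for (id in support) {
    g <- growth_when_blocked(model, id, solver)
    if (g < thr) lethal <- c(lethal, id)
  }
  structure(sort(lethal), n_tested = length(support))
}

#' @rdname single_lethals
#' @param singles the output of [single_lethals()] for the same model.
#' @return for `double_lethals()`, a list of sorted id pairs, ordered
#'   lexicographically, with attribute `"n_tested"` (joint-blocking LPs).
#' @export
double_lethals <- function(model, singles = NULL, threshold = 1e-5,
                           relative = FALSE,
                           solver = getOption("fluxscope.solver", "simplex")) {
  thr <- lethal_threshold(model, threshold, relative, solver)
  if (is.null(singles)) {
    singles <- single_lethals(model, threshold, relative, solver)
  }
  sol <- fba(model, tie_break = "parsimonious", solver = solver)
  J <- setdiff(names(sol$fluxes)[abs(sol$fluxes) > 1e-9], singles)
  candidates <- list()
  for (i in J) {
    mi <- block(model, i, "full")
    si <- fba(mi, tie_break = "parsimonious", solver = solver)
    if (si$status != "optimal" || si$objective_value < thr) next  # cannot happen: i not single
    partners <- setdiff(names(si$fluxes)[abs(si$fluxes) > 1e-9],
                        c(singles, i))
    for (p in partners) {
      key <- paste(sort(c(i, p)), collapse = "\r")
      candidates[[key]] <- sort(c(i, p))
    }
  }
  pairs <- list()
  for (pr in candidates) {
    g <- growth_when_blocked(model, pr, solver)
    if (g < thr) pairs[[length(pairs) + 1L]] <- pr
  }
  structure(canonical_pairs(pairs), n_tested = length(candidates))
}

#' Exhaustive knockout enumeration (the oracle)
#'
#' Brute-force single and double knockouts by plain FBA, with no pruning.
#' Quadratic in the number of reactions; intended for models of at most a
#' few dozen reactions, where it defines ground truth for the pruned
#' search.
#'
#' @inheritParams single_lethals
#' @param max_reactions guard against accidental use on large models.
#' @return list with `singles` (sorted ids), `doubles` (canonical pair
#'   list) and `n_tested`.
#' @export
enumerate_lethals <- function(model, threshold = 1e-5, relative = FALSE,
                              max_reactions = 40,
                              solver = getOption("fluxscope.solver", "simplex")) {
  if (n_reactions(model) > max_reactions) {
    stop("enumerate_lethals is a brute-force oracle; model exceeds ",
         max_reactions, " reactions")
  }
  thr <- lethal_threshold(model, threshold, relative, solver)
  ids <- model$reactions$id
  n_tested <- 0L
  singles <- character(0)
  for (id in ids) {
    n_tested <- n_tested + 1L
    if (growth_when_blocked(model, id, solver) < thr) singles <- c(singles, id)
  }
  rest <- setdiff(ids, singles)
  doubles <- list()
  if (length(rest) >= 2) {
    combos <- utils::combn(sort(rest), 2, simplify = FALSE)
    for (pr in combos) {
      n_tested <- n_tested + 1L
      if (growth_when_blocked(model, pr, solver) < thr) {
        doubles[[length(doubles) + 1L]] <- pr
      }
    }
  }
  list(singles = sort(singles), doubles = canonical_pairs(doubles),
       n_tested = n_tested)
}

lethal_threshold <- function(model, threshold, relative, solver) {
  stopifnot(threshold > 0)
  wt <- fba(model, solver = solver)
  if (wt$status != "optimal" || wt$objective_value < 1e-5) {
    stop("model does not grow: wild-type growth below threshold")
  }
  if (relative) threshold * wt$objective_value else threshold
}

growth_when_blocked <- function(model, ids, solver) {
  g <- fba(block(model, ids, "full"), solver = solver)
  if (g$status == "infeasible") return(0)
  g$objective_value
}

canonical_pairs <- function(pairs) {
  if (!length(pairs)) return(list())
  pairs <- lapply(pairs, sort)
  keys <- vapply(pairs, paste, "", collapse = "\r")
  pairs <- pairs[!duplicated(keys)]
  pairs[order(vapply(pairs, `[`, "", 1), vapply(pairs, `[`, "", 2))]
}

#' Assemble and classify a lethality result
#'
#' Bundles single lethals and double-lethal pairs with their
#' exchange/intracellular classification: which single lethals are
#' nutrient exchanges, which pairs contain at least one exchange member,
#' and which consist of two exchanges.
#'
#' @param model a [metabolic_model()].
#' @param singles sorted ids from [single_lethals()].
#' @param doubles canonical pair list from [double_lethals()].
#' @param wild_type_growth optional precomputed wild-type growth.
#' @param solver LP backend.
#' @return an object of class `lethality_result`.
#' @export
classify_lethals <- function(model, singles, doubles,
                             wild_type_growth = NULL,
                             solver = getOption("fluxscope.solver", "simplex")) {
  ex <- detect_exchanges(model)
  n_ex_members <- vapply(doubles, function(p) sum(p %in% ex), 0L)
  if (is.null(wild_type_growth)) {
    wild_type_growth <- fba(model, solver = solver)$objective_value
  }
  structure(list(
    organism = model$id,
    single_lethals = singles,
    double_lethals = doubles,
    exchange_single_lethals = intersect(singles, ex),
    pairs_with_exchange = doubles[n_ex_members >= 1L],
    pairs_two_exchanges = doubles[n_ex_members == 2L],
    wild_type_growth = wild_type_growth),
    class = "lethality_result")
}

#' @export
print.lethality_result <- function(x, ...) {
  cat(sprintf("<lethality_result '%s': %d singles (%d exchange), %d pairs (%d with >=1 exchange, %d with 2)>\n",
              x$organism, length(x$single_lethals),
              length(x$exchange_single_lethals), length(x$double_lethals),
              length(x$pairs_with_exchange), length(x$pairs_two_exchanges)))
  invisible(x)
}

#' Run the full lethality analysis on one model
#'
#' @inheritParams single_lethals
#' @return a `lethality_result`.
#' @export
lethality_analysis <- function(model, threshold = 1e-5, relative = FALSE,
                               solver = getOption("fluxscope.solver", "simplex")) {
  s <- single_lethals(model, threshold, relative, solver)
  d <- double_lethals(model, s, threshold, relative, solver)
  classify_lethals(model, s, d, solver = solver)
}

#' Anaerobic model variant
#'
#' Removes the oxygen exchange reaction outright (deletion, not blocking)
#' so lethality can be re-run for an obligate-anaerobe scenario.
#'
#' @param model a [metabolic_model()] with an oxygen exchange.
#' @return the reduced model, id suffixed with `"_anaerobic"`.
#' @export
anaerobic_variant <- function(model) {
  o2 <- find_oxygen_exchange(model, required = TRUE)
  out <- remove_reactions(model, o2)
  out$id <- paste0(model$id, "_anaerobic")
  out
}
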