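#' Base state for the minimal-nutrient search
#'
#' Closes the uptake direction of every non-essential exchange reaction
#' (lower bound raised to at least 0; secretion untouched) while leaving
#' the essential (single-lethal) exchanges open, so that subsequent lack
#' of growth is attributable to the blocked non-essential nutrients
#' alone.  The original uptake bounds of the blocked exchanges are kept in
#' attribute `"unblock_lb"` so the search can restore them.
#'
#' @param model a [metabolic_model()].
#' @param singles_exchange ids of essential (single-lethal) exchange
#'   reactions, left untouched; every id must be an exchange.
#' @return the constrained model with attribute `"unblock_lb"` (named
#'   numeric: blocked exchange id -> original lower bound).
#' @export
base_state <- function(model, singles_exchange = character(0)) {
  ex <- detect_exchanges(model)
  bad <- setdiff(singles_exchange, ex)
  if (length(bad)) {
    stop("singles_exchange contains non-exchange id(s): ",
         paste(bad, collapse = ", "))
  }
  blocked <- setdiff(ex, singles_exchange)
  idx <- rxn_index(model, blocked)
  orig <- stats::setNames(model$reactions$lower_bound[idx], blocked)
  orig <- orig[orig < 0]               # only uptakes actually closed
  model$reactions$lower_bound[idx] <- pmax(0, model$reactions$lower_bound[idx])
  attr(model, "unblock_lb") <- orig
  model
}

#' Search minimal sufficient nutrient combinations
#'
#' Starting from a [base_state()] model (all non-essential uptakes
#' closed), unblocks the closed exchanges one-by-one, two-by-two, up to
#' `k_max`-by-`k_max` — restoring each exchange's original uptake bound —
#' and records which combinations restore growth above the threshold.
#' Under the anaerobic regime the oxygen exchange stays closed and is not
#' a search candidate.  Enumeration is exhaustive and lexicographic; a
#' combination is flagged `minimal` when no proper subset grows.
#'
#' @param model_base output of [base_state()].
#' @param k_max maximal combination size, 1 to 3.
#' @param regime `"aerobic"` or `"anaerobic"`.
#' @param threshold growth threshold (default 1e-5).
#' @param max_combos abort if the enumeration would exceed this many
#'   combinations (advise pre-filtering candidates instead).
#' @param solver LP backend.
#' @return data.frame with one row per tested combination: `combo`
#'   (ids joined by `|`), `k`, `regime`, `growth`, `grows`, `minimal`;
#'   sorted by (k, growth descending).  The growth of the base state
#'   itself is attribute `"base_growth"` (a base state that already grows
#'   makes the search vacuous).
#' @export
search_combos <- function(model_base, k_max = 2,
                          regime = c("anaerobic", "aerobic"),
                          threshold = 1e-5, max_combos = 100000,
                          solver = getOption("fluxscope.solver", "simplex")) {
  regime <- match.arg(regime)
  stopifnot(k_max >= 1, k_max <= 3)
  orig <- attr(model_base, "unblock_lb")
  if (is.null(orig)) stop("model_base must come from base_state()")
  candidates <- sort(names(orig))
  if (regime == "anaerobic") {
    o2 <- find_oxygen_exchange(model_base, required = FALSE)
    if (!is.na(o2)) {
      candidates <- setdiff(candidates, o2)
      i <- rxn_index(model_base, o2)
      model_base$reactions$lower_bound[i] <-
        max(0, model_base$reactions$lower_bound[i])
    }
  }
  base_growth <- fba(model_base, solver = solver)$objective_value
  total <- sum(choose(length(candidates), seq_len(min(k_max, length(candidates)))))
  if (total > max_combos) {
    stop("combinatorial budget exceeded (", total, " > ", max_combos,
         " combinations); pre-filter the candidate exchanges")
  }
  growing <- list()                    # combos that grow, for minimality
  rows <- list()
  for (k in seq_len(min(k_max, length(candidates)))) {
    for (combo in utils::combn(candidates, k, simplify = FALSE)) {
      mod <- set_bounds(model_base, combo, lb = unname(orig[combo]))
      g <- fba(mod, solver = solver)
      growth <- if (g$status == "optimal") g$objective_value else 0
      grows <- growth >= threshold
      minimal <- grows && !any(vapply(growing, function(sub)
        all(sub %in% combo), TRUE))
      if (grows) growing[[length(growing) + 1L]] <- combo
      rows[[length(rows) + 1L]] <- data.frame(
        combo = paste(combo, collapse = "|"), k = k, regime = regime,
        growth = growth, grows = grows, minimal = minimal,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(combo = character(0), k = integer(0), regime = character(0),
               growth = numeric(0), grows = logical(0), minimal = logical(0))
  out <- out[order(out$k, -out$growth, out$combo), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "base_growth") <- base_growth
  out
}

#' Growth-rate table for partner nutrients
#'
#' Summarizes pair-combination results into one row per nutrient that was
#' unblocked together with one of two designated partner exchanges
#' (canonically the oxygen exchange for the aerobic regime and the
#' ferric-iron exchange for the anaerobic one).  Nutrients growing with
#' the first partner but not the second are flagged `aerobic_only`; equal
#' growth with both partners (within `tol`) is flagged
#' `regime_indifferent`.
#'
#' @param results row-bound [search_combos()] outputs (both regimes).
#' @param partner_a,partner_b the two partner exchange ids.
#' @param tol equality tolerance for the regime-indifference flag.
#' @return data.frame: `nutrient`, `growth_with_a`, `growth_with_b`,
#'   `grows_a`, `grows_b`, `aerobic_only`, `regime_indifferent`.
#' @export
growth_rate_table <- function(results, partner_a, partner_b, tol = 1e-6) {
  pairs <- results[results$k == 2, , drop = FALSE]
  members <- strsplit(pairs$combo, "|", fixed = TRUE)
  has <- function(p) vapply(members, function(m) p %in% m, TRUE)
  other <- function(p) vapply(members, function(m) setdiff(m, p)[1], "")
  rows_a <- pairs[has(partner_a), , drop = FALSE]
  rows_a$nutrient <- other(partner_a)[has(partner_a)]
  rows_b <- pairs[has(partner_b), , drop = FALSE]
  rows_b$nutrient <- other(partner_b)[has(partner_b)]
  nutrients <- sort(union(rows_a$nutrient, rows_b$nutrient))
  ga <- stats::setNames(rep(NA_real_, length(nutrients)), nutrients)
  gb <- ga
  ga[rows_a$nutrient] <- rows_a$growth
  gb[rows_b$nutrient] <- rows_b$growth
  out <- data.frame(
    nutrient = nutrients,
    growth_with_a = unname(ga), growth_with_b = unname(gb),
    grows_a = !is.na(ga) & ga >= 1e-5,
    grows_b = !is.na(gb) & gb >= 1e-5,
    stringsAsFactors = FALSE)
  out$aerobic_only <- out$grows_a & !out$grows_b
  out$regime_indifferent <- out$grows_a & out$grows_b &
    abs(out$growth_with_a - out$growth_with_b) <= tol
  out
}
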