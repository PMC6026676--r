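#' Blocking scenarios
#'
#' A scenario blocks one or two reactions, fully (both bounds zero) or
#' uptake-only (exchanges), and carries a display label such as
#' `"EX_his"` or `"pair:EX_o2|EX_fe3"`.
#'
#' @param ids one or two reaction ids (empty set allowed for the identity
#'   scenario).
#' @param mode `"full"` or `"uptake_only"`.
#' @param label optional label; derived from the ids when absent.
#' @return an object of class `block_scenario`.
#' @export
block_scenario <- function(ids, mode = c("full", "uptake_only"),
                           label = NULL) {
  mode <- match.arg(mode)
  ids <- sort(unique(as.character(ids)))
  if (length(ids) > 2) stop("a scenario blocks at most 2 reactions")
  if (is.null(label)) {
    label <- if (!length(ids)) "none" else
      if (length(ids) == 1L) ids else paste0("pair:", paste(ids, collapse = "|"))
  }
  structure(list(ids = ids, mode = mode, label = label),
            class = "block_scenario")
}

#' Reference flux distribution
#'
#' The parsimonious FBA optimum of the unblocked model, against which all
#' blocking scenarios are compared.
#'
#' @param model a [metabolic_model()].
#' @param solver LP backend.
#' @return a `flux_solution`.
#' @export
reference_fluxes <- function(model,
                             solver = getOption("fluxscope.solver", "simplex")) {
  sol <- fba(model, tie_break = "parsimonious", solver = solver)
  if (sol$status != "optimal") stop("reference model is ", sol$status)
  sol
}

subsystem_groups <- function(model) {
  ss <- model$reactions$subsystem
  keep <- !is.na(ss) & nzchar(ss)      # unclassified pathways are ignored
  split(model$reactions$id[keep], ss[keep])
}

scenario_fluxes <- function(model, scen, threshold_growth, solver) {
  mod <- block(model, scen$ids, scen$mode)
  sol <- fba(mod, solver = solver)
  lethal <- sol$status != "optimal" || sol$objective_value < threshold_growth
  if (lethal) {
    # Blocking an essential reaction leaves no biomass-optimal flux state;
    # compare against the feasibility-relaxed state: drop the objective and
    # take the parsimonious (minimum total flux) feasible state.
    v <- pfba_fluxes(mod, pin_id = NULL, solver = solver)
  } else {
    v <- pfba_fluxes(mod, pin_id = model$objective,
                     pin_value = sol$objective_value, solver = solver)
  }
  list(fluxes = v, lethal = lethal,
       growth = if (lethal) 0 else sol$objective_value)
}

altered_flags <- function(v, v_ref, threshold, mode) {
  d <- abs(v - v_ref)
  if (mode == "absolute") d > threshold else d > threshold * abs(v_ref) + 1e-9
}

#' Pathway sensitivity by FBA
#'
#' For every scenario, the fraction of each subsystem's reactions whose
#' parsimonious-FBA flux changes relative to the reference model, either
#' by more than `threshold` mmol/gDW/h (`threshold_mode = "absolute"`,
#' default 0.01) or by more than `threshold` x the reference flux
#' (`threshold_mode = "relative"`, the ">1 % change" convention).
#' Scenarios that abolish growth are still reported, flagged
#' `lethal = TRUE`, compared against the feasibility-relaxed minimal flux
#' state.
#'
#' @param model a [metabolic_model()].
#' @param scenarios list of [block_scenario()] objects.
#' @param threshold flux-change threshold.
#' @param threshold_mode `"absolute"` or `"relative"`.
#' @param growth_threshold growth below which a scenario counts as lethal.
#' @param solver LP backend.
#' @return long-format data.frame: `scenario_label`, `subsystem`,
#'   `n_reactions`, `fraction_altered`, `lethal`, `mode`.
#' @export
sensitivity_fba <- function(model, scenarios, threshold = 0.01,
                            threshold_mode = c("absolute", "relative"),
                            growth_threshold = 1e-5,
                            solver = getOption("fluxscope.solver", "simplex")) {
  threshold_mode <- match.arg(threshold_mode)
  scenarios <- as_scenario_list(scenarios)
  ref <- reference_fluxes(model, solver = solver)
  groups <- subsystem_groups(model)
  rows <- list()
  for (scen in scenarios) {
    st <- scenario_fluxes(model, scen, growth_threshold, solver)
    alt <- altered_flags(st$fluxes, ref$fluxes, threshold, threshold_mode)
    for (ss in names(groups)) {
      ids <- groups[[ss]]
      rows[[length(rows) + 1L]] <- data.frame(
        scenario_label = scen$label, subsystem = ss,
        n_reactions = length(ids),
        fraction_altered = mean(alt[ids]),
        lethal = st$lethal, mode = "fba", stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Pathway sensitivity by FVA
#'
#' As [sensitivity_fba()], but flux states are variability ranges at
#' `fraction` of each scenario's own optimum (reference: `fraction` of the
#' unblocked optimum).  A reaction counts as altered when its range
#' midpoint shifts by more than `threshold` or its width (max - min)
#' changes by more than `threshold` — a rule that reduces to the FBA rule
#' when ranges collapse to points.  Lethal scenarios are flagged and get
#' `NA` fractions (no growth-constrained flux range exists).
#'
#' @inheritParams sensitivity_fba
#' @param fraction fraction of the scenario optimum retained (default
#'   0.90).
#' @return long-format data.frame as in [sensitivity_fba()], plus
#'   `mean_width`, `min_width`, `max_width` per subsystem.
#' @export
sensitivity_fva <- function(model, scenarios, fraction = 0.90,
                            threshold = 0.01, growth_threshold = 1e-5,
                            solver = getOption("fluxscope.solver", "simplex")) {
  scenarios <- as_scenario_list(scenarios)
  groups <- subsystem_groups(model)
  ref <- fva(model, fraction = fraction, solver = solver)
  ref_mid <- (ref$min + ref$max) / 2
  ref_wid <- ref$max - ref$min
  names(ref_mid) <- names(ref_wid) <- ref$reaction_id
  rows <- list()
  for (scen in scenarios) {
    mod <- block(model, scen$ids, scen$mode)
    g <- fba(mod, solver = solver)
    lethal <- g$status != "optimal" || g$objective_value < growth_threshold
    if (!lethal) {
      rng <- fva(mod, fraction = fraction, solver = solver)
      mid <- (rng$min + rng$max) / 2
      wid <- rng$max - rng$min
      names(mid) <- names(wid) <- rng$reaction_id
      alt <- abs(mid - ref_mid[names(mid)]) > threshold |
        abs(wid - ref_wid[names(wid)]) > threshold
    }
    for (ss in names(groups)) {
      ids <- groups[[ss]]
      rows[[length(rows) + 1L]] <- data.frame(
        scenario_label = scen$label, subsystem = ss,
        n_reactions = length(ids),
        fraction_altered = if (lethal) NA_real_ else mean(alt[ids]),
        mean_width = if (lethal) NA_real_ else mean(wid[ids]),
        min_width = if (lethal) NA_real_ else min(wid[ids]),
        max_width = if (lethal) NA_real_ else max(wid[ids]),
        lethal = lethal, mode = "fva", stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

as_scenario_list <- function(scenarios) {
  if (inherits(scenarios, "block_scenario")) return(list(scenarios))
  lapply(scenarios, function(s) {
    if (inherits(s, "block_scenario")) s else block_scenario(s)
  })
}

#' Scenario x subsystem matrix of altered fractions
#'
#' Pivots a long sensitivity report into a heatmap-ready matrix.
#'
#' @param report output of [sensitivity_fba()] or [sensitivity_fva()].
#' @return numeric matrix, scenarios in rows, subsystems in columns.
#' @export
sensitivity_matrix <- function(report) {
  labs <- unique(report$scenario_label)
  sss <- sort(unique(report$subsystem))
  m <- matrix(NA_real_, length(labs), length(sss),
              dimnames = list(labs, sss))
  for (k in seq_len(nrow(report))) {
    m[report$scenario_label[k], report$subsystem[k]] <- report$fraction_altered[k]
  }
  m
}

#' Keep only scenarios inducing high total pathway change
#'
#' Reporting filter for pair scenarios: retain scenarios whose summed
#' altered fraction over all pathways exceeds `min_total`.
#'
#' @param report long sensitivity report.
#' @param min_total minimal sum of `fraction_altered` over subsystems.
#' @return filtered report.
#' @export
top_changers <- function(report, min_total = 4) {
  tot <- tapply(report$fraction_altered, report$scenario_label,
                sum, na.rm = TRUE)
  keep <- names(tot)[tot > min_total]
  report[report$scenario_label %in% keep, , drop = FALSE]
}
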