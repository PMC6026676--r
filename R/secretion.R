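#' Maximal growth under a medium
#'
#' @param model a [metabolic_model()].
#' @param medium a [medium_spec()].
#' @param growth_threshold growth below this counts as "no growth".
#' @param solver LP backend.
#' @return the biomass optimum (numeric scalar).
#' @export
max_growth <- function(model, medium, growth_threshold = 1e-5,
                       solver = getOption("fluxscope.solver", "simplex")) {
  mod <- apply_medium(model, medium)
  sol <- fba(mod, solver = solver)
  if (sol$status != "optimal" || sol$objective_value < growth_threshold) {
    stop("medium insufficient: model '", model$id, "' does not grow")
  }
  sol$objective_value
}

#' Growth-coupled production and consumption of one exchanged metabolite
#'
#' With the biomass flux bounded below by `mu_fix` (backed off by a 1e-9
#' relative epsilon to avoid vertex infeasibility) and the medium applied,
#' maximizes and minimizes the exchange flux of the metabolite of
#' interest.  Production is the positive part of the maximal exchange
#' flux; consumption is the magnitude of the negative part of the minimal
#' exchange flux (bounded by the medium's uptake limit).
#'
#' @param model a [metabolic_model()].
#' @param medium a [medium_spec()].
#' @param mu_fix growth rate to enforce (at most the medium's maximal
#'   growth).
#' @param metabolite_exchange_id the exchange reaction to optimize.
#' @param solver LP backend.
#' @return named numeric vector `c(production = , consumption = )`.
#' @export
growth_coupled_exchange <- function(model, medium, mu_fix,
                                    metabolite_exchange_id,
                                    solver = getOption("fluxscope.solver", "simplex")) {
  ex <- detect_exchanges(model)
  if (!metabolite_exchange_id %in% ex) {
    stop("'", metabolite_exchange_id, "' is not an exchange reaction")
  }
  mod <- apply_medium(model, medium)
  j <- rxn_index(mod, mod$objective)
  floor_v <- mu_fix - max(1e-9, 1e-9 * abs(mu_fix))
  mod$reactions$lower_bound[j] <- max(mod$reactions$lower_bound[j], floor_v)
  hi <- fba(mod, objective_id = metabolite_exchange_id, direction = "max",
            solver = solver)
  lo <- fba(mod, objective_id = metabolite_exchange_id, direction = "min",
            solver = solver)
  if (hi$status != "optimal" || lo$status != "optimal") {
    stop("model infeasible at mu_fix = ", mu_fix)
  }
  c(production = max(0, hi$objective_value),
    consumption = max(0, -lo$objective_value))
}

#' Exchange profile of one organism
#'
#' Growth-coupled maximal production and consumption for every exchanged
#' metabolite at the organism's maximal growth on the given medium, with
#' the producer/consumer role classification (threshold 1e-6
#' mmol/gDW/h).
#'
#' @param model a [metabolic_model()].
#' @param medium a [medium_spec()] (its `anaerobic` flag is the regime).
#' @param mu_fix growth to enforce; defaults to [max_growth()].
#' @param solver LP backend.
#' @return data.frame: `organism`, `regime`, `exchange_id`,
#'   `metabolite`, `max_production`, `max_consumption`, `role` in
#'   producer/consumer/both/inert.
#' @export
exchange_profile <- function(model, medium, mu_fix = NULL,
                             solver = getOption("fluxscope.solver", "simplex")) {
  if (is.null(mu_fix)) mu_fix <- max_growth(model, medium, solver = solver)
  ex <- detect_exchanges(model)
  regime <- if (medium$anaerobic) "anaerobic" else "aerobic"
  met_of <- function(id) {
    col <- model$S[, id]
    model$metabolites$name[which(col != 0)[1]]
  }
  rows <- lapply(ex, function(id) {
    env <- growth_coupled_exchange(model, medium, mu_fix, id, solver = solver)
    prod <- env[["production"]]; cons <- env[["consumption"]]
    role <- if (prod > 1e-6 && cons > 1e-6) "both"
      else if (prod > 1e-6) "producer"
      else if (cons > 1e-6) "consumer" else "inert"
    data.frame(organism = model$id, regime = regime, exchange_id = id,
               metabolite = met_of(id), max_production = prod,
               max_consumption = cons, role = role,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "mu_fix") <- mu_fix
  out
}

#' Cross-organism interaction matrix
#'
#' Overlays per-organism exchange profiles into a per-metabolite summary
#' of producers and consumers, classified as `commensal` (at least one
#' producer and one distinct consumer), `competitive` (two or more
#' consumers, no producer), `shared-production` (two or more producers,
#' no consumer) or `none`.  Classification is a pure function of the
#' producer/consumer sets, hence invariant to organism order; profiles
#' are stratified by regime.
#'
#' @param profiles list of [exchange_profile()] outputs (>= 2 organisms).
#' @return data.frame: `regime`, `exchange_id`, `producers`, `consumers`
#'   (comma-joined organism ids), `n_producers`, `n_consumers`,
#'   `classification`.
#' @export
build_interaction_matrix <- function(profiles) {
  tab <- do.call(rbind, profiles)
  if (length(unique(tab$organism)) < 2) {
    stop("interaction matrix needs profiles from at least 2 organisms")
  }
  shared <- Reduce(intersect, lapply(profiles, function(p) p$exchange_id))
  if (!length(shared)) {
    stop("no shared metabolite namespace across organisms; unmatched ids: ",
         paste(utils::head(unique(tab$exchange_id), 10), collapse = ", "))
  }
  key <- interaction(tab$regime, tab$exchange_id, drop = TRUE)
  rows <- lapply(split(tab, key), function(g) {
    producers <- sort(unique(g$organism[g$role %in% c("producer", "both")]))
    consumers <- sort(unique(g$organism[g$role %in% c("consumer", "both")]))
    cls <- if (length(producers) >= 1 && length(setdiff(consumers, producers)) >= 1)
      "commensal"
    else if (length(consumers) >= 2 && length(producers) == 0) "competitive"
    else if (length(producers) >= 2 && length(consumers) == 0) "shared-production"
    else "none"
    data.frame(regime = g$regime[1], exchange_id = g$exchange_id[1],
               producers = paste(producers, collapse = ","),
               consumers = paste(consumers, collapse = ","),
               n_producers = length(producers),
               n_consumers = length(consumers),
               classification = cls, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$regime, out$exchange_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
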