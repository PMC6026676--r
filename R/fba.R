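#' Flux balance analysis
#'
#' Solves \eqn{\max / \min\; v_{obj}} subject to steady-state mass balance
#' \eqn{S v = 0} and the model's flux bounds.  With
#' `tie_break = "parsimonious"` a second LP selects, among the optimal
#' solutions, the flux vector minimizing total absolute flux
#' \eqn{\sum_i |v_i|} (classic parsimonious FBA via a positive/negative
#' flux split), which makes downstream flux comparisons well defined in
#' the face of alternate optima.  Biomass flux is reported in the raw LP
#' units of the model (conventionally 1/h for a biomass reaction,
#' mmol/gDW/h for any other flux).
#'
#' @param model a [metabolic_model()].
#' @param objective_id reaction to optimize (default: the model objective).
#' @param direction `"max"` or `"min"`.
#' @param tie_break `"none"` (single LP) or `"parsimonious"`.
#' @param solver LP backend, see [solve_lp()].
#' @return a `flux_solution`: list with `status` (`"optimal"`,
#'   `"infeasible"`, `"unbounded"`), `objective_value` and `fluxes`
#'   (named vector; `NULL` unless optimal).
#' @export
fba <- function(model, objective_id = model$objective,
                direction = c("max", "min"),
                tie_break = c("none", "parsimonious"),
                solver = getOption("fluxscope.solver", "simplex")) {
  direction <- match.arg(direction)
  tie_break <- match.arg(tie_break)
  j <- rxn_index(model, objective_id)
  n <- n_reactions(model)
  cvec <- numeric(n); cvec[j] <- 1
  lp <- lp_problem(model$S, rep(0, nrow(model$S)), cvec,
                   model$reactions$lower_bound,
                   model$reactions$upper_bound, sense = direction)
  res <- solve_lp(lp, solver = solver)
  if (res$status != "optimal") {
    return(structure(list(status = res$status,
                          objective_value = NA_real_, fluxes = NULL),
                     class = "flux_solution"))
  }
  fluxes <- stats::setNames(res$x, model$reactions$id)
  if (tie_break == "parsimonious") {
    fluxes <- pfba_fluxes(model, pin_id = objective_id,
                          pin_value = res$objective, solver = solver)
  }
  structure(list(status = "optimal", objective_value = res$objective,
                 fluxes = fluxes),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution: %s", x$status))
  if (x$status == "optimal") cat(sprintf(", objective %.6g", x$objective_value))
  cat(">\n")
  invisible(x)
}

# Minimum total absolute flux subject to S v = 0, bounds, and (optionally)
# a pinned objective flux.  Each flux is split v = p - q with p, q >= 0;
# minimizing sum(p + q) forces p*q = 0 at the optimum, so sum(p + q) is
# sum |v|.  Returns the flux vector.
pfba_fluxes <- function(model, pin_id = NULL, pin_value = NULL,
                        solver = getOption("fluxscope.solver", "simplex")) {
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  if (!is.null(pin_id)) {
    j <- rxn_index(model, pin_id)
    eps <- max(1e-9, 1e-9 * abs(pin_value))
    lb[j] <- max(lb[j], pin_value - eps)
    ub[j] <- min(ub[j], pin_value + eps)
  }
  S <- as.matrix(model$S)
  n <- ncol(S)
  A <- cbind(S, -S)
  lb2 <- c(pmax(lb, 0), pmax(-ub, 0))
  ub2 <- c(pmax(ub, 0), pmax(-lb, 0))
  lp <- lp_problem(A, rep(0, nrow(S)), rep(1, 2 * n), lb2, ub2, sense = "min")
  res <- solve_lp(lp, solver = solver)
  if (res$status != "optimal") {
    stop("parsimonious stage infeasible (pinned objective ", pin_value, ")")
  }
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  stats::setNames(v, model$reactions$id)
}

#' Flux variability analysis
#'
#' For each requested reaction, the minimal and maximal flux subject to
#' the objective retaining at least `fraction` of its unconstrained
#' optimum (the conventional "fraction of optimum" formulation; the
#' default 1.0 pins the optimum exactly, and 0.90 reproduces the
#' ">= 90 % of the reference solution" setting used for pathway reports).
#'
#' @param model a [metabolic_model()].
#' @param fraction fraction of the biomass optimum to retain, in (0, 1].
#' @param reaction_ids subset of reactions (default: all).
#' @param solver LP backend.
#' @return data.frame `reaction_id`, `min`, `max`, with the achieved
#'   optimum in attribute `"optimum"`.
#' @export
fva <- function(model, fraction = 1.0, reaction_ids = NULL,
                solver = getOption("fluxscope.solver", "simplex")) {
  stopifnot(fraction > 0, fraction <= 1)
  ref <- fba(model, solver = solver)
  if (ref$status != "optimal") {
    stop("fva: model is ", ref$status, "; cannot fix objective fraction")
  }
  reaction_ids <- reaction_ids %||% model$reactions$id
  j <- rxn_index(model, model$objective)
  floor_v <- fraction * ref$objective_value
  # back off by a relative epsilon so the vertex itself stays feasible
  floor_v <- floor_v - max(1e-9, 1e-9 * abs(floor_v))
  mod2 <- model
  mod2$reactions$lower_bound[j] <- max(mod2$reactions$lower_bound[j], floor_v)
  out <- data.frame(reaction_id = reaction_ids,
                    min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(reaction_ids)) {
    lo <- fba(mod2, objective_id = reaction_ids[k], direction = "min",
              solver = solver)
    hi <- fba(mod2, objective_id = reaction_ids[k], direction = "max",
              solver = solver)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("fva: subproblem for ", reaction_ids[k], " is ", lo$status)
    }
    out$min[k] <- lo$objective_value
    out$max[k] <- hi$objective_value
  }
  attr(out, "optimum") <- ref$objective_value
  attr(out, "fraction") <- fraction
  out
}

#' Spearman correlation between two flux distributions
#'
#' Rank correlation over the reactions carrying flux (|v| > 1e-9) in both
#' solutions — the robustness check used to compare a model's flux state
#' with and without oxygen exchange.
#'
#' @param sol_a,sol_b optimal `flux_solution` objects.
#' @return list with `rho` and `n` (number of jointly non-null fluxes).
#' @export
flux_spearman <- function(sol_a, sol_b) {
  stopifnot(inherits(sol_a, "flux_solution"), inherits(sol_b, "flux_solution"))
  if (sol_a$status != "optimal" || sol_b$status != "optimal") {
    stop("flux_spearman needs two optimal solutions")
  }
  shared <- intersect(names(sol_a$fluxes), names(sol_b$fluxes))
  a <- sol_a$fluxes[shared]; b <- sol_b$fluxes[shared]
  keep <- abs(a) > 1e-9 & abs(b) > 1e-9
  n <- sum(keep)
  if (n < 3) stop("flux_spearman: fewer than 3 jointly non-null fluxes")
  list(rho = unname(stats::cor(a[keep], b[keep], method = "spearman")), n = n)
}
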