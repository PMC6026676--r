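#' Constraint-based metabolic model container
#'
#' A `metabolic_model` bundles a stoichiometric matrix with flux bounds,
#' one biomass objective reaction, compartment assignments and per-reaction
#' subsystem (pathway) annotations, following the conventions of the AGORA
#' gut-bacterial reconstructions: compartments `"c"` (cytosol) and `"e"`
#' (extracellular), boundary exchange reactions named `EX_*` that move one
#' extracellular metabolite in or out of the system, and the sign
#' convention that negative exchange flux is uptake and positive flux is
#' secretion.
#'
#' @param id model identifier.
#' @param metabolites data.frame with columns `id`, `name`, `compartment`.
#' @param reactions data.frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `subsystem` (`NA` allowed).
#' @param S stoichiometric matrix (metabolites x reactions), dense or
#'   sparse; stored as a `Matrix::dgCMatrix` with dimnames.
#' @param objective id of the biomass (objective) reaction.
#' @param boundary_compartment compartment id treated as extracellular
#'   boundary (default `"e"`).
#' @param pseudo_prefixes id prefixes (case-insensitive) identifying
#'   biomass/DNA/RNA/protein pseudo-reactions, which are never classified
#'   as exchanges.
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, metabolites, reactions, S, objective,
                            boundary_compartment = "e",
                            pseudo_prefixes = c("biomass", "DM_", "sink_",
                                                "DNA", "RNA", "protein")) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "name", "compartment") %in% names(metabolites)),
            all(c("id", "name", "lower_bound", "upper_bound", "subsystem")
                %in% names(reactions)))
  if (anyDuplicated(metabolites$id)) stop("duplicate metabolite ids")
  if (anyDuplicated(reactions$id)) stop("duplicate reaction ids")
  if (any(!nzchar(metabolites$compartment))) {
    stop("every metabolite needs a non-empty compartment")
  }
  S <- methods::as(methods::as(Matrix::Matrix(S, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  dimnames(S) <- list(metabolites$id, reactions$id)
  if (any(reactions$lower_bound > reactions$upper_bound + 1e-12)) {
    stop("reaction lower_bound exceeds upper_bound")
  }
  if (!objective %in% reactions$id) {
    stop("objective reaction '", objective, "' not in model")
  }
  m <- structure(list(id = id, metabolites = metabolites,
                      reactions = reactions, S = S, objective = objective,
                      boundary_compartment = boundary_compartment,
                      pseudo_prefixes = pseudo_prefixes),
                 class = "metabolic_model")
  m
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model '%s': %d metabolites, %d reactions, objective '%s'>\n",
              x$id, nrow(x$metabolites), nrow(x$reactions), x$objective))
  cat(sprintf("  exchanges: %d | subsystems: %d annotated\n",
              length(detect_exchanges(x)),
              sum(!is.na(x$reactions$subsystem))))
  invisible(x)
}

n_reactions <- function(model) nrow(model$reactions)

rxn_index <- function(model, ids) {
  idx <- match(ids, model$reactions$id)
  if (anyNA(idx)) {
    stop("unknown reaction id(s): ", paste(ids[is.na(idx)], collapse = ", "))
  }
  idx
}

is_pseudo <- function(model, ids) {
  pat <- paste0("^(", paste(tolower(model$pseudo_prefixes), collapse = "|"), ")")
  grepl(pat, tolower(ids))
}

#' Detect exchange reactions
#'
#' A reaction is an exchange iff it touches exactly one metabolite (with a
#' nonzero coefficient) and that metabolite lives in the boundary
#' (extracellular) compartment.  The objective and biomass/DNA/RNA/protein
#' pseudo-reactions are never exchanges, mirroring the convention that
#' those are treated as intracellular.  The result is sorted, hence
#' invariant to reaction ordering.
#'
#' @param model a [metabolic_model()].
#' @return sorted character vector of exchange reaction ids.
#' @export
detect_exchanges <- function(model) {
  S <- model$S
  nz_per_col <- diff(S@p)
  single <- which(nz_per_col == 1L)
  if (!length(single)) return(character(0))
  met_of <- model$metabolites$compartment[S@i[S@p[single] + 1L] + 1L]
  ids <- colnames(S)[single][met_of == model$boundary_compartment]
  ids <- setdiff(ids, model$objective)
  ids <- ids[!is_pseudo(model, ids)]
  sort(ids)
}

#' Locate the oxygen exchange reaction
#'
#' Matches the reaction id against common AGORA/COBRA spellings of the O2
#' exchange (`EX_o2(e)`, `EX_o2_e`, `EX_o2[e]`, `EX_O2`), case-insensitive.
#'
#' @param model a [metabolic_model()].
#' @param required error (`TRUE`) or return `NA` (`FALSE`) when absent.
#' @return the reaction id, or `NA_character_`.
#' @export
find_oxygen_exchange <- function(model, required = TRUE) {
  ex <- detect_exchanges(model)
  hit <- ex[tolower(ex) %in% c("ex_o2", "ex_o2(e)", "ex_o2_e", "ex_o2[e]")]
  if (!length(hit)) {
    if (required) stop("model '", model$id, "' has no oxygen exchange reaction")
    return(NA_character_)
  }
  hit[1]
}

#' Set reaction bounds
#' @param model a [metabolic_model()].
#' @param ids reaction ids.
#' @param lb,ub new bounds (recycled); `NULL` leaves the bound untouched.
#' @return the modified model.
#' @export
set_bounds <- function(model, ids, lb = NULL, ub = NULL) {
  idx <- rxn_index(model, ids)
  if (!is.null(lb)) model$reactions$lower_bound[idx] <- lb
  if (!is.null(ub)) model$reactions$upper_bound[idx] <- ub
  if (any(model$reactions$lower_bound[idx] >
          model$reactions$upper_bound[idx] + 1e-12)) {
    stop("set_bounds would leave lower_bound > upper_bound")
  }
  model
}

#' Block reactions
#'
#' `mode = "full"` sets both bounds to zero (no flux in either direction);
#' `mode = "uptake_only"` closes only the uptake direction of exchange
#' reactions (lower bound raised to at least 0, secretion untouched).
#'
#' @param model a [metabolic_model()].
#' @param ids reaction ids to block (may be empty).
#' @param mode `"full"` or `"uptake_only"`.
#' @return the modified model.
#' @export
block <- function(model, ids, mode = c("full", "uptake_only")) {
  mode <- match.arg(mode)
  if (!length(ids)) return(model)
  idx <- rxn_index(model, ids)
  if (mode == "full") {
    model$reactions$lower_bound[idx] <- 0
    model$reactions$upper_bound[idx] <- 0
  } else {
    ex <- detect_exchanges(model)
    if (!all(ids %in% ex)) {
      stop("uptake_only blocking applies to exchange reactions only; not exchanges: ",
           paste(setdiff(ids, ex), collapse = ", "))
    }
    model$reactions$lower_bound[idx] <- pmax(0, model$reactions$lower_bound[idx])
  }
  model
}

#' Remove reactions from a model
#'
#' Deletes the reactions outright (used e.g. to derive an anaerobic model
#' variant by removing the oxygen exchange).  Metabolites are retained.
#'
#' @param model a [metabolic_model()].
#' @param ids reaction ids to delete.
#' @return the reduced model.
#' @export
remove_reactions <- function(model, ids) {
  idx <- rxn_index(model, ids)
  if (model$objective %in% ids) stop("cannot remove the objective reaction")
  model$reactions <- model$reactions[-idx, , drop = FALSE]
  rownames(model$reactions) <- NULL
  model$S <- model$S[, -idx, drop = FALSE]
  model
}

#' Medium specification
#'
#' A medium is a named vector of maximal uptake rates (mmol/gDW/h, all
#' `>= 0`) keyed by exchange reaction id, plus an anaerobic flag.  When
#' applied, uptake through every exchange absent from the medium is closed;
#' exchanges in the medium get lower bound `max(declared_lb, -rate)` (a
#' medium never widens a bound beyond the model's declared bounds).  Under
#' `anaerobic = TRUE` the oxygen exchange uptake is forced shut regardless
#' of the medium.
#'
#' @param uptake named numeric vector: exchange id -> max uptake rate.
#' @param anaerobic logical flag.
#' @return an object of class `medium_spec`.
#' @export
medium_spec <- function(uptake = numeric(0), anaerobic = FALSE) {
  uptake <- unlist(uptake)
  if (length(uptake)) {
    stopifnot(!is.null(names(uptake)), all(nzchar(names(uptake))))
    if (any(uptake < 0)) stop("medium uptake rates must be >= 0")
  }
  structure(list(uptake = uptake, anaerobic = isTRUE(anaerobic)),
            class = "medium_spec")
}

#' Apply a medium to a model
#'
#' @param model a [metabolic_model()].
#' @param medium a [medium_spec()].
#' @return the constrained model.
#' @export
apply_medium <- function(model, medium) {
  stopifnot(inherits(medium, "medium_spec"))
  ex <- detect_exchanges(model)
  unknown <- setdiff(names(medium$uptake), ex)
  if (length(unknown)) {
    stop("medium ids are not exchange reactions of the model: ",
         paste(unknown, collapse = ", "))
  }
  closed <- setdiff(ex, names(medium$uptake))
  idx <- rxn_index(model, closed)
  model$reactions$lower_bound[idx] <- pmax(0, model$reactions$lower_bound[idx])
  if (length(medium$uptake)) {
    idx <- rxn_index(model, names(medium$uptake))
    model$reactions$lower_bound[idx] <-
      pmax(model$reactions$lower_bound[idx], -unname(medium$uptake))
  }
  if (medium$anaerobic) {
    o2 <- find_oxygen_exchange(model, required = FALSE)
    if (!is.na(o2)) {
      i <- rxn_index(model, o2)
      model$reactions$lower_bound[i] <- max(0, model$reactions$lower_bound[i])
    }
  }
  model
}

#' Read / write a medium TSV
#'
#' Two tab-separated columns `exchange_id` and `max_uptake`, preceded by a
#' header comment line `# anaerobic: true|false`.
#'
#' @param path file path.
#' @return a [medium_spec()].
#' @export
read_medium <- function(path) {
  lines <- readLines(path)
  anaerobic <- any(grepl("^#\\s*anaerobic:\\s*true\\s*$", lines,
                         ignore.case = TRUE))
  tab <- utils::read.delim(text = lines, comment.char = "#",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("exchange_id", "max_uptake") %in% names(tab)))
  medium_spec(stats::setNames(as.numeric(tab$max_uptake), tab$exchange_id),
              anaerobic = anaerobic)
}

#' @rdname read_medium
#' @param medium a [medium_spec()].
#' @export
write_medium <- function(medium, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(sprintf("# anaerobic: %s",
                       if (medium$anaerobic) "true" else "false"),
               "exchange_id\tmax_uptake",
               sprintf("%s\t%.10g", names(medium$uptake), medium$uptake)),
             con, sep = "\n")
  invisible(path)
}

#' Default medium opening every exchange at its declared uptake bound
#'
#' Convenience for toy models: every exchange with a negative declared
#' lower bound enters the medium at rate `-lower_bound`.
#'
#' @param model a [metabolic_model()].
#' @param anaerobic logical flag.
#' @return a [medium_spec()].
#' @export
full_medium <- function(model, anaerobic = FALSE) {
  ex <- detect_exchanges(model)
  lbs <- model$reactions$lower_bound[rxn_index(model, ex)]
  keep <- lbs < 0
  medium_spec(stats::setNames(-lbs[keep], ex[keep]), anaerobic = anaerobic)
}
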