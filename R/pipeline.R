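#' Analysis configuration
#'
#' Central container for the pipeline constants: the growth threshold
#' below which a model counts as dead (1e-5), the absolute flux-change
#' threshold for FBA-mode pathway sensitivity (0.01 mmol/gDW/h), the
#' relative-change threshold used for nutrient-search pathway reports
#' (0.01, i.e. 1 %), the FVA fraction of optimum (0.90), the maximal
#' nutrient-combination size, solver choice and seed.
#'
#' @param growth_threshold absolute growth threshold (> 0).
#' @param flux_change_threshold absolute flux-change threshold (> 0).
#' @param relative_change_threshold relative flux-change threshold (> 0).
#' @param fva_fraction fraction of optimum for FVA, in (0, 1].
#' @param k_max maximal nutrient combination size, 1..3.
#' @param solver LP backend name.
#' @param seed integer seed recorded with every run.
#' @return a validated list of class `analysis_config`.
#' @export
analysis_config <- function(growth_threshold = 1e-5,
                            flux_change_threshold = 0.01,
                            relative_change_threshold = 0.01,
                            fva_fraction = 0.90, k_max = 2,
                            solver = getOption("fluxscope.solver", "simplex"),
                            seed = 1L) {
  stopifnot(growth_threshold > 0, flux_change_threshold > 0,
            relative_change_threshold > 0)
  if (!(fva_fraction > 0 && fva_fraction <= 1)) {
    stop("fva_fraction must lie in (0, 1]")
  }
  if (!(k_max >= 1 && k_max <= 3)) stop("k_max must be 1, 2 or 3")
  structure(list(growth_threshold = growth_threshold,
                 flux_change_threshold = flux_change_threshold,
                 relative_change_threshold = relative_change_threshold,
                 fva_fraction = fva_fraction, k_max = as.integer(k_max),
                 solver = solver, seed = as.integer(seed)),
            class = "analysis_config")
}

# deterministic TSV writer: fixed number formatting, LF endings
write_tsv <- function(df, path) {
  fmt <- function(col) {
    if (is.numeric(col)) sprintf("%.10g", col) else as.character(col)
  }
  out <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1L) out <- matrix(out, nrow = 1)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(names(df), collapse = "\t"),
               if (nrow(df)) apply(out, 1, paste, collapse = "\t")),
             con, sep = "\n")
  invisible(path)
}

pairs_to_df <- function(pairs, ex) {
  if (!length(pairs)) {
    return(data.frame(id_a = character(0), id_b = character(0),
                      n_exchange_members = integer(0)))
  }
  data.frame(id_a = vapply(pairs, `[`, "", 1),
             id_b = vapply(pairs, `[`, "", 2),
             n_exchange_members = vapply(pairs, function(p) sum(p %in% ex), 0L),
             stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes, per organism, the lethality analysis, pathway sensitivity in
#' FBA and FVA mode (scenarios: every single lethal, every double-lethal
#' pair and every non-essential exchange, blocked fully), the
#' minimal-nutrient combination search and the growth-coupled exchange
#' profile; then, across organisms, the shared/exclusive lethality
#' comparison and the metabolite interaction matrix.  All outputs are
#' plain TSV/JSON files with deterministic formatting: re-running with
#' the same configuration and inputs reproduces them byte for byte.
#'
#' @param models named list of [metabolic_model()]s, or a character vector
#'   of fixture names understood by [make_fixture()].
#' @param media optional named list of [medium_spec()]s keyed like
#'   `models`; organisms without an entry use [full_medium()] with the
#'   anaerobic flag set when the model lacks (or closes) oxygen exchange.
#' @param config an [analysis_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list of per-organism result bundles plus the
#'   cross-organism summary; side effect: files under `out_dir`.
#' @export
run_pipeline <- function(models, media = NULL,
                         config = analysis_config(), out_dir) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.character(models)) {
    models <- stats::setNames(lapply(models, function(nm) make_fixture(nm)$model),
                              models)
  }
  if (!length(models)) stop("run_pipeline needs at least one model")
  if (is.null(names(models)) || any(!nzchar(names(models)))) {
    names(models) <- vapply(models, `[[`, "", "id")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  solver <- config$solver
  bundles <- list()
  for (org in names(models)) {
    model <- models[[org]]
    odir <- file.path(out_dir, sbml_sanitize(org))
    dir.create(odir, showWarnings = FALSE)
    ex <- detect_exchanges(model)

    leth <- lethality_analysis(model, threshold = config$growth_threshold,
                               solver = solver)
    write_tsv(data.frame(
      reaction_id = leth$single_lethals,
      is_exchange = leth$single_lethals %in% ex,
      subsystem = model$reactions$subsystem[rxn_index(model, leth$single_lethals)],
      stringsAsFactors = FALSE), file.path(odir, "singles.tsv"))
    write_tsv(pairs_to_df(leth$double_lethals, ex),
              file.path(odir, "pairs.tsv"))
    jsonlite::write_json(list(
      organism = org,
      wild_type_growth = leth$wild_type_growth,
      n_single = length(leth$single_lethals),
      n_single_exchange = length(leth$exchange_single_lethals),
      n_pairs = length(leth$double_lethals),
      n_pairs_with_exchange = length(leth$pairs_with_exchange),
      n_pairs_two_exchanges = length(leth$pairs_two_exchanges),
      seed = config$seed),
      file.path(odir, "lethality_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)

    nonessential_ex <- setdiff(ex, leth$exchange_single_lethals)
    scenarios <- c(
      lapply(leth$single_lethals, block_scenario),
      lapply(leth$double_lethals, block_scenario),
      lapply(nonessential_ex, block_scenario))
    if (any(!is.na(model$reactions$subsystem))) {
      rep_fba <- sensitivity_fba(model, scenarios,
                                 threshold = config$flux_change_threshold,
                                 growth_threshold = config$growth_threshold,
                                 solver = solver)
      write_tsv(rep_fba, file.path(odir, "sensitivity_fba.tsv"))
      rep_fva <- sensitivity_fva(model, scenarios,
                                 fraction = config$fva_fraction,
                                 threshold = config$flux_change_threshold,
                                 growth_threshold = config$growth_threshold,
                                 solver = solver)
      write_tsv(rep_fva, file.path(odir, "sensitivity_fva.tsv"))
    } else {
      rep_fba <- rep_fva <- NULL
    }

    bs <- base_state(model, leth$exchange_single_lethals)
    regimes <- "anaerobic"
    if (!is.na(find_oxygen_exchange(model, required = FALSE))) {
      regimes <- c(regimes, "aerobic")
    }
    combos <- do.call(rbind, lapply(regimes, function(rg) {
      search_combos(bs, k_max = config$k_max, regime = rg,
                    threshold = config$growth_threshold, solver = solver)
    }))
    write_tsv(combos, file.path(odir, "nutrient_combos.tsv"))

    medium <- if (!is.null(media) && org %in% names(media)) media[[org]]
      else full_medium(model,
                       anaerobic = is.na(find_oxygen_exchange(model, FALSE)))
    profile <- exchange_profile(model, medium, solver = solver)
    write_tsv(profile, file.path(odir, "exchange_profile.tsv"))

    bundles[[org]] <- list(lethality = leth, sensitivity_fba = rep_fba,
                           sensitivity_fva = rep_fva, nutrient_combos = combos,
                           profile = profile)
  }

  cross <- NULL
  if (length(models) >= 2) {
    cross <- compare_organisms(lapply(bundles, `[[`, "lethality"))
    write_tsv(cross$per_organism, file.path(out_dir, "compare_organisms.tsv"))
    jsonlite::write_json(cross$shared, file.path(out_dir, "shared_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    profs <- lapply(bundles, `[[`, "profile")
    shared_ids <- Reduce(intersect, lapply(profs, function(p) p$exchange_id))
    if (length(shared_ids)) {
      imat <- build_interaction_matrix(profs)
      write_tsv(imat, file.path(out_dir, "interaction_matrix.tsv"))
      bundles$interaction_matrix <- imat
    }
  }
  bundles$comparison <- cross
  invisible(bundles)
}

#' Cross-organism lethality comparison
#'
#' Shared and exclusive single lethals, essential exchanges and
#' double-lethal pairs across a set of organisms.
#'
#' @param results list of `lethality_result` objects (>= 2).
#' @return list with `per_organism` (counts incl. exclusives) and
#'   `shared` (sizes of the all-organism intersections).
#' @export
compare_organisms <- function(results) {
  if (length(results) < 2) stop("compare_organisms needs >= 2 organisms")
  orgs <- vapply(results, `[[`, "", "organism")
  singles <- lapply(results, `[[`, "single_lethals")
  ex_singles <- lapply(results, `[[`, "exchange_single_lethals")
  pair_keys <- lapply(results, function(r)
    vapply(r$double_lethals, paste, "", collapse = "|"))
  shared_singles <- Reduce(intersect, singles)
  shared_ex <- Reduce(intersect, ex_singles)
  shared_pairs <- Reduce(intersect, pair_keys)
  per <- data.frame(
    organism = orgs,
    n_single = lengths(singles),
    n_single_exchange = lengths(ex_singles),
    n_pairs = lengths(pair_keys),
    n_exclusive_single = vapply(seq_along(singles), function(i)
      length(setdiff(singles[[i]], Reduce(union, singles[-i]))), 0L),
    n_exclusive_single_exchange = vapply(seq_along(ex_singles), function(i)
      length(setdiff(ex_singles[[i]], Reduce(union, ex_singles[-i]))), 0L),
    n_exclusive_pairs = vapply(seq_along(pair_keys), function(i)
      length(setdiff(pair_keys[[i]], Reduce(union, pair_keys[-i]))), 0L),
    stringsAsFactors = FALSE)
  rownames(per) <- NULL
  list(per_organism = per,
       shared = list(singles = sort(shared_singles),
                     n_shared_single = length(shared_singles),
                     exchange_singles = sort(shared_ex),
                     n_shared_single_exchange = length(shared_ex),
                     pairs = sort(shared_pairs),
                     n_shared_pairs = length(shared_pairs)))
}
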