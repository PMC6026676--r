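#' SBML input/output
#'
#' Reads and writes constraint-based models as SBML Level 3 Version 1 with
#' the Flux Balance Constraints (fbc, version 2) package — the dialect the
#' Virtual Metabolic Human database serves for AGORA reconstructions.
#' Reaction bounds travel as fbc flux-bound parameters, the biomass
#' objective as the active fbc objective, and subsystem annotations as a
#' `SUBSYSTEM:` line in the reaction notes.  Species and reaction ids are
#' written with the conventional `M_`/`R_` SBML prefixes and stripped on
#' reading.  Files without fbc bounds fall back, with a warning, to
#' Level-2-style bounds in kinetic-law parameters (`LOWER_BOUND` /
#' `UPPER_BOUND`); missing bounds default to the community convention of
#' +/-1000 mmol/gDW/h.
#'
#' @param model a [metabolic_model()].
#' @param path file path.
#' @return `write_sbml()` returns `path` invisibly; `read_sbml()` returns
#'   a [metabolic_model()].
#' @name sbml_io
NULL

sbml_sanitize <- function(x) gsub("[^A-Za-z0-9_]", "__", x)

num_attr <- function(x) sprintf("%.12g", x)

#' @rdname sbml_io
#' @export
write_sbml <- function(model, path) {
  mets <- model$metabolites
  rxns <- model$reactions
  S <- model$S
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  bounds <- sort(unique(c(rxns$lower_bound, rxns$upper_bound)))
  bid <- stats::setNames(sprintf("fb_%d", seq_along(bounds)), num_attr(bounds))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    sprintf('  <model id="%s" name="%s" fbc:strict="true">',
            sbml_sanitize(model$id), esc(model$id)),
    '    <listOfCompartments>')
  for (cmp in sort(unique(mets$compartment))) {
    lines <- c(lines, sprintf('      <compartment id="%s" constant="true"/>', cmp))
  }
  lines <- c(lines, '    </listOfCompartments>', '    <listOfSpecies>')
  for (i in seq_len(nrow(mets))) {
    lines <- c(lines, sprintf(
      paste0('      <species id="M_%s" name="%s" compartment="%s" ',
             'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
             'constant="false"/>'),
      sbml_sanitize(mets$id[i]), esc(mets$name[i]), mets$compartment[i]))
  }
  lines <- c(lines, '    </listOfSpecies>', '    <listOfParameters>')
  for (k in seq_along(bounds)) {
    lines <- c(lines, sprintf(
      '      <parameter id="%s" value="%s" constant="true"/>',
      bid[k], num_attr(bounds[k])))
  }
  lines <- c(lines, '    </listOfParameters>', '    <listOfReactions>')
  for (i in seq_len(nrow(rxns))) {
    rid <- rxns$id[i]
    col <- S[, rid]
    nz <- which(col != 0)
    reactants <- nz[col[nz] < 0]
    products <- nz[col[nz] > 0]
    lines <- c(lines, sprintf(
      paste0('      <reaction id="R_%s" name="%s" reversible="%s" fast="false" ',
             'fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
      sbml_sanitize(rid), esc(rxns$name[i]),
      if (rxns$lower_bound[i] < 0) "true" else "false",
      bid[num_attr(rxns$lower_bound[i])], bid[num_attr(rxns$upper_bound[i])]))
    if (!is.na(rxns$subsystem[i]) && nzchar(rxns$subsystem[i])) {
      lines <- c(lines,
                 '        <notes>',
                 '          <body xmlns="http://www.w3.org/1999/xhtml">',
                 sprintf('            <p>SUBSYSTEM: %s</p>', esc(rxns$subsystem[i])),
                 '          </body>',
                 '        </notes>')
    }
    if (length(reactants)) {
      lines <- c(lines, '        <listOfReactants>',
                 sprintf(paste0('          <speciesReference species="M_%s" ',
                                'stoichiometry="%s" constant="true"/>'),
                         sbml_sanitize(mets$id[reactants]),
                         num_attr(-col[reactants])),
                 '        </listOfReactants>')
    }
    if (length(products)) {
      lines <- c(lines, '        <listOfProducts>',
                 sprintf(paste0('          <speciesReference species="M_%s" ',
                                'stoichiometry="%s" constant="true"/>'),
                         sbml_sanitize(mets$id[products]),
                         num_attr(col[products])),
                 '        </listOfProducts>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines,
    '    </listOfReactions>',
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    '        <fbc:listOfFluxObjectives>',
    sprintf('          <fbc:fluxObjective fbc:reaction="R_%s" fbc:coefficient="1"/>',
            sbml_sanitize(model$objective)),
    '        </fbc:listOfFluxObjectives>',
    '      </fbc:objective>',
    '    </fbc:listOfObjectives>',
    '  </model>',
    '</sbml>')
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

strip_prefix <- function(x, prefix) {
  ifelse(startsWith(x, prefix), substring(x, nchar(prefix) + 1L), x)
}

#' @rdname sbml_io
#' @param boundary_compartment compartment treated as extracellular.
#' @export
read_sbml <- function(path, boundary_compartment = "e") {
  if (!file.exists(path)) stop("SBML file not found: ", path)
  doc <- xml2::read_xml(path)
  # namespace-agnostic queries via local-name()
  q <- function(node, name) {
    xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", name))
  }
  model_node <- q(doc, "model")
  if (!length(model_node)) stop("not an SBML file: no <model> element")
  model_node <- model_node[[1]]
  model_id <- xml2::xml_attr(model_node, "name")  # writer keeps the raw id here
  if (is.na(model_id)) model_id <- xml2::xml_attr(model_node, "id")
  if (is.na(model_id)) model_id <- tools::file_path_sans_ext(basename(path))

  sp <- q(model_node, "species")
  if (!length(sp)) stop("SBML parse error: no species")
  met_ids_raw <- xml2::xml_attr(sp, "id")
  mets <- data.frame(
    id = strip_prefix(met_ids_raw, "M_"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  strip_prefix(met_ids_raw, "M_"), xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    stringsAsFactors = FALSE)
  met_lookup <- stats::setNames(seq_along(met_ids_raw), met_ids_raw)

  params <- q(model_node, "parameter")
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))

  rxn_nodes <- xml2::xml_find_all(
    model_node, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (!length(rxn_nodes)) stop("SBML parse error: no reactions")
  nr <- length(rxn_nodes)
  rid_raw <- xml2::xml_attr(rxn_nodes, "id")
  rids <- strip_prefix(rid_raw, "R_")
  lb <- rep(NA_real_, nr); ub <- rep(NA_real_, nr)
  ss <- rep(NA_character_, nr)
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  used_l2 <- FALSE
  for (k in seq_len(nr)) {
    node <- rxn_nodes[[k]]
    at <- xml2::xml_attrs(node)
    lbid <- at[grepl("lowerFluxBound$", names(at))]
    ubid <- at[grepl("upperFluxBound$", names(at))]
    if (length(lbid)) lb[k] <- pvals[[lbid[[1]]]]
    if (length(ubid)) ub[k] <- pvals[[ubid[[1]]]]
    if (is.na(lb[k]) || is.na(ub[k])) {
      # Level-2 style: kinetic-law parameters
      kl <- q(node, "kineticLaw")
      if (length(kl)) {
        kp <- q(kl[[1]], "parameter")
        kid <- xml2::xml_attr(kp, "id")
        kv <- as.numeric(xml2::xml_attr(kp, "value"))
        if (is.na(lb[k]) && "LOWER_BOUND" %in% kid) {
          lb[k] <- kv[kid == "LOWER_BOUND"][1]; used_l2 <- TRUE
        }
        if (is.na(ub[k]) && "UPPER_BOUND" %in% kid) {
          ub[k] <- kv[kid == "UPPER_BOUND"][1]; used_l2 <- TRUE
        }
      }
    }
    if (is.na(lb[k])) {
      rev <- identical(xml2::xml_attr(node, "reversible"), "true")
      lb[k] <- if (rev) -1000 else 0
    }
    if (is.na(ub[k])) ub[k] <- 1000
    notes <- q(node, "p")
    if (length(notes)) {
      txt <- xml2::xml_text(notes)
      hit <- grep("^\\s*SUBSYSTEM:", txt, value = TRUE)
      if (length(hit)) ss[k] <- trimws(sub("^\\s*SUBSYSTEM:\\s*", "", hit[1]))
    }
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(
        node, sprintf(".//*[local-name()='%s']/*[local-name()='speciesReference']", side))
      if (length(refs)) {
        spc <- xml2::xml_attr(refs, "species")
        sto <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
        sto[is.na(sto)] <- 1
        row <- met_lookup[spc]
        if (anyNA(row)) {
          stop("SBML parse error: reaction '", rids[k],
               "' references unknown species ",
               paste(spc[is.na(row)], collapse = ", "))
        }
        trip_i <- c(trip_i, unname(row))
        trip_j <- c(trip_j, rep(k, length(row)))
        trip_x <- c(trip_x, sgn * sto)
      }
    }
  }
  if (used_l2) {
    warning("SBML file without fbc flux bounds: fell back to kinetic-law ",
            "LOWER_BOUND/UPPER_BOUND parameters")
  }
  S <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(nrow(mets), nr))

  fo <- q(model_node, "fluxObjective")
  if (length(fo)) {
    at <- xml2::xml_attrs(fo[[1]])
    objective <- strip_prefix(at[grepl("reaction$", names(at))][[1]], "R_")
  } else {
    cand <- rids[grepl("biomass", rids, ignore.case = TRUE)]
    if (length(cand) != 1) {
      stop("no objective: SBML declares no fbc objective and ",
           length(cand), " reactions match the biomass naming convention")
    }
    objective <- cand
  }
  rxns <- data.frame(
    id = rids,
    name = ifelse(is.na(xml2::xml_attr(rxn_nodes, "name")), rids,
                  xml2::xml_attr(rxn_nodes, "name")),
    lower_bound = lb, upper_bound = ub, subsystem = ss,
    stringsAsFactors = FALSE)
  metabolic_model(model_id, mets, rxns, S, objective,
                  boundary_compartment = boundary_compartment)
}
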