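# SBML reader for constraint-based models. Two dialects are accepted:
#   * Level 2 "COBRA" style: bounds as LOWER_BOUND/UPPER_BOUND kineticLaw
#     parameters, GPR as a "GENE_ASSOCIATION:" line in the reaction notes;
#   * Level 3 + fbc: bounds as fbc:lowerFluxBound/upperFluxBound parameter
#     references, GPR as fbc:geneProductAssociation trees.
# Species flagged boundaryCondition="true" are external pools and are dropped
# from the mass-balance (COBRA convention).

sbml_attr <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- match(name, sub("^.*:", "", names(at)))
  if (is.na(hit)) NA_character_ else unname(at[hit])
}

fbc_gpr_string <- function(node) {
  nm <- sub("^.*:", "", xml2::xml_name(node))
  kids <- xml2::xml_children(node)
  if (nm == "geneProductRef") return(sbml_attr(node, "geneProduct"))
  if (nm %in% c("and", "or")) {
    parts <- vapply(kids, fbc_gpr_string, character(1))
    return(paste0("(", paste(parts, collapse = paste0(" ", nm, " ")), ")"))
  }
  if (length(kids) == 1) return(fbc_gpr_string(kids[[1]]))
  stop("format error in fbc gene association: unexpected element <", nm, ">")
}

#' Read a metabolic model from SBML
#'
#' Parses SBML Level 2 (COBRA dialect) or Level 3 with the `fbc` extension.
#' Bounds absent from the file default to `[-1000, 1000]` for reactions marked
#' reversible and `[0, 1000]` otherwise. The GPR encoding found (notes field
#' or fbc) is logged in the model provenance.
#'
#' @param path path to an SBML file.
#' @param id model identifier; defaults to the SBML model id.
#' @return A validated `metabolic_model`.
#' @export
read_sbml <- function(path, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("format error: not parseable XML: ",
                                           conditionMessage(e), call. = FALSE))
  ln <- function(x) sprintf("*[local-name()='%s']", x)   # namespace-agnostic
  model_node <- xml2::xml_find_first(doc, paste0(".//", ln("model")))
  if (inherits(model_node, "xml_missing")) stop("format error: no <model> element")
  if (is.null(id)) id <- sbml_attr(model_node, "id")
  if (is.na(id) || !nzchar(id)) id <- "sbml_model"

  sp_nodes <- xml2::xml_find_all(doc, paste0(".//", ln("listOfSpecies"), "/", ln("species")))
  if (length(sp_nodes) == 0) stop("format error: no species declared")
  species <- data.frame(
    id = vapply(sp_nodes, sbml_attr, character(1), "id"),
    compartment = vapply(sp_nodes, sbml_attr, character(1), "compartment"),
    name = vapply(sp_nodes, sbml_attr, character(1), "name"),
    boundary = vapply(sp_nodes, sbml_attr, character(1), "boundaryCondition") %in%
      c("true", "1"),
    stringsAsFactors = FALSE)
  species$name[is.na(species$name)] <- species$id[is.na(species$name)]
  species$compartment[is.na(species$compartment)] <- "default"

  par_nodes <- xml2::xml_find_all(
    doc, paste0(".//", ln("model"), "/", ln("listOfParameters"), "/", ln("parameter")))
  par_val <- setNames(
    suppressWarnings(as.numeric(vapply(par_nodes, sbml_attr, character(1), "value"))),
    vapply(par_nodes, sbml_attr, character(1), "id"))

  gp_nodes <- xml2::xml_find_all(
    doc, paste0(".//", ln("listOfGeneProducts"), "/", ln("geneProduct")))
  gp_label <- setNames(vapply(gp_nodes, function(n) {
    lab <- sbml_attr(n, "label")
    if (is.na(lab)) sbml_attr(n, "id") else lab
  }, character(1)), vapply(gp_nodes, sbml_attr, character(1), "id"))

  rxn_nodes <- xml2::xml_find_all(
    doc, paste0(".//", ln("listOfReactions"), "/", ln("reaction")))
  if (length(rxn_nodes) == 0) stop("format error: no reactions declared")
  gpr_dialects <- character()

  rows <- vector("list", length(rxn_nodes))
  st_list <- vector("list", length(rxn_nodes))
  for (k in seq_along(rxn_nodes)) {
    rn <- rxn_nodes[[k]]
    rid <- sbml_attr(rn, "id")
    if (is.na(rid)) stop("format error: reaction without id (position ", k, ")")
    reversible <- !(sbml_attr(rn, "reversible") %in% c("false", "0"))

    one_side <- function(xpath, sgn) {
      refs <- xml2::xml_find_all(rn, xpath)
      if (length(refs) == 0) return(NULL)
      sp <- vapply(refs, sbml_attr, character(1), "species")
      coef <- suppressWarnings(as.numeric(vapply(refs, sbml_attr, character(1),
                                                 "stoichiometry")))
      coef[is.na(coef)] <- 1
      data.frame(reaction = rid, metabolite = sp, coef = sgn * coef,
                 stringsAsFactors = FALSE)
    }
    st <- rbind(one_side(paste0("./", ln("listOfReactants"), "/", ln("speciesReference")), -1),
                one_side(paste0("./", ln("listOfProducts"), "/", ln("speciesReference")), +1))
    if (!is.null(st)) {
      unknown <- setdiff(st$metabolite, species$id)
      if (length(unknown)) {
        stop("validation error: reaction ", rid,
             " references undeclared species: ", paste(unknown, collapse = ", "))
      }
      st <- st[!(st$metabolite %in% species$id[species$boundary]), , drop = FALSE]
    }

    # bounds: L3 fbc parameter refs, else L2 kineticLaw parameters, else defaults
    lb <- ub <- NA_real_
    lb_ref <- sbml_attr(rn, "lowerFluxBound"); ub_ref <- sbml_attr(rn, "upperFluxBound")
    if (!is.na(lb_ref) && lb_ref %in% names(par_val)) lb <- par_val[[lb_ref]]
    if (!is.na(ub_ref) && ub_ref %in% names(par_val)) ub <- par_val[[ub_ref]]
    kl_pars <- xml2::xml_find_all(
      rn, paste0(".//", ln("kineticLaw"), "//", ln("parameter")))
    if (length(kl_pars)) {
      kid <- vapply(kl_pars, sbml_attr, character(1), "id")
      kv <- suppressWarnings(as.numeric(vapply(kl_pars, sbml_attr, character(1), "value")))
      if (is.na(lb) && "LOWER_BOUND" %in% kid) lb <- kv[match("LOWER_BOUND", kid)]
      if (is.na(ub) && "UPPER_BOUND" %in% kid) ub <- kv[match("UPPER_BOUND", kid)]
    }
    if (is.na(lb)) lb <- if (reversible) -1000 else 0
    if (is.na(ub)) ub <- 1000

    # GPR: fbc tree wins, else notes "GENE_ASSOCIATION: ..."
    gpr <- ""
    ga <- xml2::xml_find_first(rn, paste0("./", ln("geneProductAssociation")))
    if (!inherits(ga, "xml_missing")) {
      kids <- xml2::xml_children(ga)
      if (length(kids) == 1) {
        gpr <- fbc_gpr_string(kids[[1]])
        for (gid in names(gp_label)) {
          gpr <- gsub(paste0("(?<![\\w.])", gid, "(?![\\w.])"), gp_label[[gid]],
                      gpr, perl = TRUE)
        }
        gpr_dialects <- c(gpr_dialects, "fbc")
      }
    } else {
      notes <- xml2::xml_find_first(rn, paste0("./", ln("notes")))
      if (!inherits(notes, "xml_missing")) {
        txt <- xml2::xml_text(notes)
        mm <- regmatches(txt, regexpr("GENE[ _]ASSOCIATION:[^\n]*", txt))
        if (length(mm)) {
          gpr <- trimws(sub("^GENE[ _]ASSOCIATION:", "", mm))
          gpr_dialects <- c(gpr_dialects, "notes")
        }
      }
    }

    rows[[k]] <- data.frame(id = rid, lb = lb, ub = ub, gpr = gpr,
                            subsystem = "", stringsAsFactors = FALSE)
    st_list[[k]] <- st
  }

  reactions <- do.call(rbind, rows)
  stoich <- do.call(rbind, st_list)
  mets <- species[!species$boundary & species$id %in% stoich$metabolite,
                  c("id", "compartment", "name")]
  dialect <- if (length(gpr_dialects) == 0) "none" else
    paste(unique(gpr_dialects), collapse = "+")
  metabolic_model(mets, reactions, stoich, id = id,
                  provenance = c(paste("read from SBML:", path),
                                 paste("GPR encoding:", dialect)))
}
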