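#' Construct a metabolic network model
#'
#' A `metabolic_model` holds the metabolite list, the reaction list (with flux
#' bounds and gene-reaction rules), and the stoichiometry as a triplet table.
#' It is the common currency of all other functions in the package.
#'
#' @param metabolites data.frame with columns `id`, `compartment`, `name`.
#' @param reactions data.frame with columns `id`, `lb`, `ub`, `gpr`,
#'   `subsystem`. `gpr` is a boolean expression over gene ids using `and`/`or`
#'   and parentheses; the empty string means no gene dependency.
#' @param stoichiometry data.frame with columns `reaction`, `metabolite`,
#'   `coef` (signed real; negative = consumed, positive = produced).
#' @param objective optional reaction id used as a default flux objective.
#' @param id model identifier (free text).
#' @param provenance character vector logging how the model was built.
#'
#' @return An object of class `metabolic_model`.
#' @seealso [validate_model()], [stoichiometric_matrix()], [read_native_model()]
#' @export
metabolic_model <- function(metabolites, reactions, stoichiometry,
                            objective = NA_character_, id = "model",
                            provenance = character()) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  stoichiometry <- as.data.frame(stoichiometry, stringsAsFactors = FALSE)
  if (is.null(reactions$subsystem)) reactions$subsystem <- ""
  if (is.null(reactions$gpr)) reactions$gpr <- ""
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  reactions$gpr[is.na(reactions$gpr)] <- ""
  m <- structure(
    list(id = id,
         metabolites = metabolites[, c("id", "compartment", "name")],
         reactions = reactions[, c("id", "lb", "ub", "gpr", "subsystem")],
         stoichiometry = stoichiometry[, c("reaction", "metabolite", "coef")],
         objective = objective,
         provenance = provenance),
    class = "metabolic_model")
  validate_model(m)
  m
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: unique reaction/metabolite ids, bounds
#' ordered `lb <= ub`, every stoichiometry entry resolving to a declared
#' metabolite and reaction, parseable gene-reaction rules, and the presence of
#' at least one boundary (exchange) reaction.
#'
#' @param model a `metabolic_model`.
#' @return The model, invisibly; signals an error describing the first
#'   violated invariant otherwise.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  met <- model$metabolites; rxn <- model$reactions; st <- model$stoichiometry
  if (anyDuplicated(met$id)) {
    stop("duplicate metabolite id(s): ",
         paste(unique(met$id[duplicated(met$id)]), collapse = ", "))
  }
  if (anyDuplicated(rxn$id)) {
    stop("duplicate reaction id(s): ",
         paste(unique(rxn$id[duplicated(rxn$id)]), collapse = ", "))
  }
  if (any(is.na(met$compartment)) || any(!nzchar(met$compartment))) {
    stop("every metabolite needs a non-empty compartment tag")
  }
  if (any(!is.finite(rxn$lb) & !is.infinite(rxn$lb)) ||
      any(!is.finite(rxn$ub) & !is.infinite(rxn$ub))) {
    stop("reaction bounds must be numeric")
  }
  bad <- rxn$id[rxn$lb > rxn$ub]
  if (length(bad)) stop("lb > ub for reaction(s): ", paste(bad, collapse = ", "))
  unknown_met <- setdiff(st$metabolite, met$id)
  if (length(unknown_met)) {
    stop("stoichiometry references undeclared metabolite(s): ",
         paste(unknown_met, collapse = ", "))
  }
  unknown_rxn <- setdiff(st$reaction, rxn$id)
  if (length(unknown_rxn)) {
    stop("stoichiometry references undeclared reaction(s): ",
         paste(unknown_rxn, collapse = ", "))
  }
  for (i in seq_len(nrow(rxn))) parse_gpr(rxn$gpr[i])  # errors if malformed
  n_side <- tapply(sign(st$coef), st$reaction, function(s) length(unique(s)))
  # a boundary reaction has all coefficients of one sign (pure source or sink)
  if (nrow(rxn) > 0 && !any(n_side == 1)) {
    stop("model has no exchange/boundary reaction (a reaction whose ",
         "coefficients are single-signed)")
  }
  invisible(model)
}

#' Assemble the stoichiometric matrix
#'
#' Returns the m x r matrix `S` with `S[i, j]` the coefficient of metabolite
#' `i` in reaction `j` (negative = consumed), the steady-state constraint
#' `S %*% v = 0` used by all flux computations.
#'
#' @param model a `metabolic_model`.
#' @return Dense numeric matrix with metabolite ids as rownames and reaction
#'   ids as colnames.
#' @export
stoichiometric_matrix <- function(model) {
  met_ids <- model$metabolites$id
  rxn_ids <- model$reactions$id
  S <- matrix(0, nrow = length(met_ids), ncol = length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  st <- model$stoichiometry
  S[cbind(match(st$metabolite, met_ids), match(st$reaction, rxn_ids))] <- st$coef
  S
}

#' All gene ids referenced by a model's gene-reaction rules
#'
#' @param model a `metabolic_model`.
#' @return Character vector of unique gene ids (possibly empty).
#' @export
model_genes <- function(model) {
  genes <- unlist(lapply(model$reactions$gpr, gpr_genes))
  sort(unique(genes))
}

#' Remove reactions from a model
#'
#' Drops the named reactions and any metabolites that are left with no
#' attached reaction (orphans).
#'
#' @param model a `metabolic_model`.
#' @param reaction_ids ids to remove; unknown ids are an error.
#' @param note provenance note appended to the model log.
#' @return The reduced `metabolic_model`.
#' @export
remove_reactions <- function(model, reaction_ids, note = NULL) {
  unknown <- setdiff(reaction_ids, model$reactions$id)
  if (length(unknown)) stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))
  keep <- !(model$reactions$id %in% reaction_ids)
  rxn <- model$reactions[keep, , drop = FALSE]
  st <- model$stoichiometry[model$stoichiometry$reaction %in% rxn$id, , drop = FALSE]
  met <- model$metabolites[model$metabolites$id %in% unique(st$metabolite), , drop = FALSE]
  prov <- c(model$provenance,
            if (is.null(note)) paste("removed reactions:", paste(reaction_ids, collapse = ", "))
            else note)
  out <- model
  out$metabolites <- met
  out$reactions <- rxn
  out$stoichiometry <- st
  if (!is.na(out$objective) && !(out$objective %in% rxn$id)) out$objective <- NA_character_
  out$provenance <- prov
  out
}

#' Set the flux bounds of one reaction
#'
#' @param model a `metabolic_model`.
#' @param reaction_id reaction to modify.
#' @param lb,ub new bounds; `NULL` leaves the existing value in place.
#' @param note optional provenance note.
#' @return The modified model; errors if the new bounds cross (`lb > ub`).
#' @export
set_bounds <- function(model, reaction_id, lb = NULL, ub = NULL, note = NULL) {
  i <- match(reaction_id, model$reactions$id)
  if (is.na(i)) stop("unknown reaction id: ", reaction_id)
  new_lb <- if (is.null(lb)) model$reactions$lb[i] else lb
  new_ub <- if (is.null(ub)) model$reactions$ub[i] else ub
  if (new_lb > new_ub) {
    stop(sprintf("bounds cross for %s: lb = %g > ub = %g", reaction_id, new_lb, new_ub))
  }
  model$reactions$lb[i] <- new_lb
  model$reactions$ub[i] <- new_ub
  model$provenance <- c(model$provenance,
                        if (is.null(note))
                          sprintf("set bounds of %s to [%g, %g]", reaction_id, new_lb, new_ub)
                        else note)
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model '%s'>  %d reactions, %d metabolites\n",
              x$id, nrow(x$reactions), nrow(x$metabolites)))
  rev <- sum(x$reactions$lb < 0 & x$reactions$ub > 0)
  cat(sprintf("  reversible: %d | with GPR: %d | objective: %s\n",
              rev, sum(nzchar(x$reactions$gpr)),
              ifelse(is.na(x$objective), "<none>", x$objective)))
  invisible(x)
}
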