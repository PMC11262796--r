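# Omics presence calling and context-specific model pruning: the deterministic
# re-implementation of a manual curation step. Genes are called absent when
# their signal falls below a platform cutoff in a majority of replicates
# (2-of-3 at n = 3, generalized to ceiling((n+1)/2)-of-n); reactions whose GPR
# becomes inactive are then removed one by one, in lexicographic id order,
# unless removal would destroy flux-carrying capacity for a protected
# function (ATP production, TCA cycle, glycolysis).

#' Call gene presence from an expression table
#'
#' A gene is called `absent` when its value is below `cutoff` in at least `k`
#' of the `n` samples, `present` otherwise. Defaults follow the platform:
#' transcript counts use cutoff 5, protein abundances cutoff 2000, and
#' `k = ceiling((n + 1) / 2)` (the 2-of-3 rule at three replicates).
#'
#' @param expr genes x samples table: a numeric matrix with gene rownames, or
#'   a data.frame whose first column is the gene id.
#' @param platform `"transcript"` or `"protein"`.
#' @param cutoff absence threshold; `NULL` picks the platform default.
#' @param k minimum number of below-cutoff samples for an absence call;
#'   `NULL` picks the majority rule.
#' @return A `presence_calls` object: named call vector plus the thresholds
#'   used and a provenance string.
#' @export
call_presence <- function(expr, platform = c("transcript", "protein"),
                          cutoff = NULL, k = NULL) {
  platform <- match.arg(platform)
  if (is.data.frame(expr)) {
    ids <- as.character(expr[[1]])
    expr <- as.matrix(expr[, -1, drop = FALSE])
    rownames(expr) <- ids
  }
  if (is.null(rownames(expr))) stop("expression table needs gene ids (rownames)")
  storage.mode(expr) <- "double"
  if (any(is.na(expr))) stop("validation error: NA values in expression table")
  if (any(expr < 0)) stop("validation error: negative expression values")
  n <- ncol(expr)
  if (n < 2) stop("need at least 2 samples per platform")
  if (is.null(cutoff)) cutoff <- switch(platform, transcript = 5, protein = 2000)
  if (is.null(k)) k <- ceiling((n + 1) / 2)
  below <- rowSums(expr < cutoff)
  calls <- ifelse(below >= k, "absent", "present")
  structure(list(
    calls = setNames(as.character(calls), rownames(expr)),
    thresholds = list(platform = platform, cutoff = cutoff, k = k, n = n),
    provenance = sprintf("%s: absent if < %g in >= %d of %d samples",
                         platform, cutoff, k, n)),
    class = "presence_calls")
}

#' Merge presence calls across platforms
#'
#' Combination rule: a gene is `absent` only if it is absent on every platform
#' where it was measured; `present` if present on any platform; `unmeasured`
#' only when measured nowhere. This is deliberately conservative against
#' incomplete annotation on one platform.
#'
#' @param transcript_calls,protein_calls `presence_calls` objects (either may
#'   be `NULL`).
#' @return A merged `presence_calls` object.
#' @export
merge_presence <- function(transcript_calls, protein_calls) {
  sets <- Filter(Negate(is.null), list(transcript_calls, protein_calls))
  if (length(sets) == 0) stop("at least one call set is required")
  for (s in sets) stopifnot(inherits(s, "presence_calls"))
  genes <- sort(unique(unlist(lapply(sets, function(s) names(s$calls)))))
  merged <- vapply(genes, function(g) {
    vals <- unlist(lapply(sets, function(s) unname(s$calls[g])))
    vals <- vals[!is.na(vals) & vals != "unmeasured"]
    if (length(vals) == 0) "unmeasured"
    else if (any(vals == "present")) "present"
    else "absent"
  }, character(1))
  structure(list(
    calls = merged,
    thresholds = lapply(sets, `[[`, "thresholds"),
    provenance = paste(c("merged (absent only if absent on every measured platform)",
                         vapply(sets, `[[`, character(1), "provenance")),
                       collapse = "; ")),
    class = "presence_calls")
}

#' @export
print.presence_calls <- function(x, ...) {
  tab <- table(factor(x$calls, levels = c("present", "absent", "unmeasured")))
  cat("<presence_calls> ", paste(names(tab), tab, sep = ": ", collapse = ", "),
      "\n  ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Prune a model to its omics-supported context
#'
#' Reactions whose gene-reaction rule evaluates to `inactive` under `calls`
#' are candidates for removal. Candidates are visited in lexicographic id
#' order; each is removed only when the remaining model still passes
#' [check_capacity()] for the protected functions, otherwise it is retained
#' (`retained_capacity`). Rules evaluating to `unknown` (all genes unmeasured)
#' are treated as active, so missing evidence never deletes a reaction.
#'
#' @param model the base `metabolic_model`; must itself pass capacity.
#' @param calls a `presence_calls` object.
#' @param protected_reactions witness reaction ids passed to [check_capacity()].
#' @param epsilon capacity threshold (flux units).
#' @return list with `model` (the context-specific model) and `log`, a
#'   data.frame with one row per base-model reaction: `reaction`,
#'   `action` (`removed` / `retained_capacity` / `retained_active`), `reason`.
#' @export
prune_model <- function(model, calls,
                        protected_reactions = c("ATPS", "CS", "GLYC"),
                        epsilon = 1e-6) {
  stopifnot(inherits(calls, "presence_calls"))
  if (!check_capacity(model, protected_reactions, epsilon)) {
    stop("base model fails capacity for protected functions; nothing pruned")
  }
  status <- vapply(model$reactions$gpr, evaluate_gpr, character(1), calls = calls)
  names(status) <- model$reactions$id
  candidates <- sort(names(status)[status == "inactive"])

  log_rows <- list()
  current <- model
  for (rid in candidates) {
    trial <- remove_reactions(current, rid,
                              note = sprintf("pruned %s (GPR inactive)", rid))
    ok <- all(protected_reactions %in% trial$reactions$id) &&
      check_capacity(trial, protected_reactions, epsilon)
    if (ok) {
      current <- trial
      log_rows[[rid]] <- data.frame(reaction = rid, action = "removed",
                                    reason = "GPR inactive; capacity preserved",
                                    stringsAsFactors = FALSE)
    } else {
      log_rows[[rid]] <- data.frame(reaction = rid, action = "retained_capacity",
                                    reason = "GPR inactive but removal breaks protected capacity",
                                    stringsAsFactors = FALSE)
    }
  }
  kept <- setdiff(model$reactions$id, candidates)
  for (rid in kept) {
    log_rows[[rid]] <- data.frame(
      reaction = rid, action = "retained_active",
      reason = sprintf("GPR %s", status[[rid]]), stringsAsFactors = FALSE)
  }
  log <- do.call(rbind, log_rows[model$reactions$id])
  rownames(log) <- NULL
  current$provenance <- c(current$provenance,
                          sprintf("pruned %d of %d GPR-inactive candidates",
                                  sum(log$action == "removed"), length(candidates)))
  list(model = current, log = log)
}

#' Report pruning order sensitivity
#'
#' Re-runs [prune_model()] with the candidate order reversed and reports
#' reactions whose removal/retention differs — a diagnostic for curation
#' outcomes that depend on visit order (alternative-route pairs).
#'
#' @inheritParams prune_model
#' @return Character vector of order-sensitive reaction ids (empty when the
#'   outcome is order-independent).
#' @export
prune_order_sensitivity <- function(model, calls,
                                    protected_reactions = c("ATPS", "CS", "GLYC"),
                                    epsilon = 1e-6) {
  fwd <- prune_model(model, calls, protected_reactions, epsilon)$log
  # reverse-order rerun: same algorithm, reversed lexicographic visit order
  status <- vapply(model$reactions$gpr, evaluate_gpr, character(1), calls = calls)
  names(status) <- model$reactions$id
  candidates <- rev(sort(names(status)[status == "inactive"]))
  current <- model
  rev_action <- setNames(rep("retained_active", nrow(model$reactions)),
                         model$reactions$id)
  for (rid in candidates) {
    trial <- remove_reactions(current, rid)
    ok <- all(protected_reactions %in% trial$reactions$id) &&
      check_capacity(trial, protected_reactions, epsilon)
    if (ok) { current <- trial; rev_action[rid] <- "removed" }
    else rev_action[rid] <- "retained_capacity"
  }
  fwd_action <- setNames(fwd$action, fwd$reaction)
  names(which(fwd_action != rev_action[names(fwd_action)]))
}
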