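# Comparative constraints and flux-distribution contrasts. The experiment
# design: model A (high Complex I, low O2 uptake — the ischemia-like
# hypothesis) gets a lower bound on Complex I at f_hi of its theoretical
# maximum and an upper bound on mitochondrial O2 transport at f_lo of its
# maximum; model B gets the mirrored constraints. Sampling both and
# contrasting per-reaction distributions surfaces shifted and sign-reversed
# reactions (the Complex II readout).

#' Bound a reaction at a fraction of its theoretical maximum
#'
#' Computes the flux-balance maximum `M` of `reaction_id` and sets the chosen
#' bound to `fraction * M`. Errors when `M <= 0` (a fractional bound is then
#' undefined) or when the new bound makes the model infeasible.
#'
#' @param model a `metabolic_model`.
#' @param reaction_id target reaction.
#' @param kind `"lower"` or `"upper"`.
#' @param fraction fraction of the theoretical maximum, in (0, 1].
#' @return The constrained model, with the maximum recorded in provenance.
#' @export
apply_fraction_bound <- function(model, reaction_id, kind = c("lower", "upper"),
                                 fraction) {
  kind <- match.arg(kind)
  stopifnot(fraction > 0, fraction <= 1)
  res <- maximize_flux(model, reaction_id)
  if (res$status != "optimal") stop("cannot bound ", reaction_id, ": model ", res$status)
  M <- res$objective_value
  if (M <= 0) {
    stop("theoretical maximum of ", reaction_id, " is ", format(M),
         " <= 0; fractional bound undefined")
  }
  out <- if (kind == "lower") {
    set_bounds(model, reaction_id, lb = fraction * M,
               note = sprintf("%s: lb = %.3g = %g * max %.6g", reaction_id,
                              fraction * M, fraction, M))
  } else {
    set_bounds(model, reaction_id, ub = fraction * M,
               note = sprintf("%s: ub = %.3g = %g * max %.6g", reaction_id,
                              fraction * M, fraction, M))
  }
  chk <- maximize_flux(out, reaction_id)
  if (chk$status != "optimal") {
    i <- match(reaction_id, out$reactions$id)
    stop(sprintf(
      "infeasible after bounding %s (%s := %.4g; existing bounds [%.4g, %.4g])",
      reaction_id, kind, fraction * M, out$reactions$lb[i], out$reactions$ub[i]))
  }
  out
}

#' Build the constrained model pair
#'
#' Applies the comparative scenario: in model A the Complex I reaction gets a
#' lower bound at `f_hi` of its theoretical maximum and the O2 transport
#' reaction an upper bound at `f_lo` of its maximum; model B gets the mirror
#' image (Complex I upper bound at `f_lo`, O2 lower bound at `f_hi`). After
#' construction the O2 lower bound of B must strictly exceed the O2 upper
#' bound of A, guaranteeing the intended ordering of oxygen consumption.
#'
#' @param model_a,model_b the two context-specific models.
#' @param ci_id Complex I reaction id (default `"CI_MitoCore"`).
#' @param o2_id O2 transport reaction id (default `"O2tm"`).
#' @param f_hi,f_lo constraint fractions (defaults 0.7 and 0.3).
#' @return list with constrained models `a` and `b` and a `maxima` data.frame
#'   logging every theoretical maximum used.
#' @export
build_constrained_pair <- function(model_a, model_b, ci_id = "CI_MitoCore",
                                   o2_id = "O2tm", f_hi = 0.7, f_lo = 0.3) {
  for (m in list(model_a, model_b)) {
    missing_rxn <- setdiff(c(ci_id, o2_id), m$reactions$id)
    if (length(missing_rxn)) {
      stop("reaction(s) absent from model '", m$id, "': ",
           paste(missing_rxn, collapse = ", "))
    }
  }
  theo_max <- function(m, rid) {
    res <- maximize_flux(m, rid)
    if (res$status != "optimal") {
      stop("cannot compute theoretical maximum of ", rid, " in '", m$id,
           "': model ", res$status)
    }
    if (res$objective_value <= 0) {
      stop("theoretical maximum of ", rid, " in '", m$id, "' is ",
           format(res$objective_value), " <= 0; fractional bound undefined")
    }
    res$objective_value
  }
  # all maxima come from the unconstrained context models, before any
  # comparative bound is applied
  max_a_ci <- theo_max(model_a, ci_id); max_a_o2 <- theo_max(model_a, o2_id)
  max_b_ci <- theo_max(model_b, ci_id); max_b_o2 <- theo_max(model_b, o2_id)
  maxima <- data.frame(
    model = rep(c(model_a$id, model_b$id), each = 2),
    reaction = rep(c(ci_id, o2_id), 2),
    max = c(max_a_ci, max_a_o2, max_b_ci, max_b_o2),
    stringsAsFactors = FALSE)

  bound_note <- function(rid, kind, val, frac, mx) {
    sprintf("%s: %s = %.4g = %g * max %.6g", rid, kind, val, frac, mx)
  }
  a <- set_bounds(model_a, ci_id, lb = f_hi * max_a_ci,
                  note = bound_note(ci_id, "lb", f_hi * max_a_ci, f_hi, max_a_ci))
  a <- set_bounds(a, o2_id, ub = f_lo * max_a_o2,
                  note = bound_note(o2_id, "ub", f_lo * max_a_o2, f_lo, max_a_o2))
  b <- set_bounds(model_b, ci_id, ub = f_lo * max_b_ci,
                  note = bound_note(ci_id, "ub", f_lo * max_b_ci, f_lo, max_b_ci))
  b <- set_bounds(b, o2_id, lb = f_hi * max_b_o2,
                  note = bound_note(o2_id, "lb", f_hi * max_b_o2, f_hi, max_b_o2))
  for (m in list(a, b)) {
    chk <- maximize_flux(m, ci_id)
    if (chk$status != "optimal") {
      stop("model '", m$id, "' infeasible under the combined comparative ",
           "bounds on ", ci_id, " and ", o2_id)
    }
  }

  o2_ub_a <- a$reactions$ub[match(o2_id, a$reactions$id)]
  o2_lb_b <- b$reactions$lb[match(o2_id, b$reactions$id)]
  if (!(o2_lb_b > o2_ub_a)) {
    stop(sprintf(
      "constraint ordering violated: O2 lower bound of '%s' (%.4g) must exceed O2 upper bound of '%s' (%.4g)",
      b$id, o2_lb_b, a$id, o2_ub_a))
  }
  list(a = a, b = b, maxima = maxima)
}

#' Compare two sets of flux samples reaction by reaction
#'
#' For every shared reaction, computes medians and interquartile ranges of
#' both sample sets, a histogram overlap coefficient (sum of bin-wise minima
#' of relative frequencies on 50 shared bins spanning the pooled 1st-99th
#' percentile range), and decision flags: `shifted` when the overlap is below
#' `overlap_threshold` and the median difference exceeds
#' `shift_threshold` x pooled IQR; `sign_flip` when the medians have opposite
#' strict signs.
#'
#' @param samples_a,samples_b `flux_samples` objects.
#' @param shift_threshold multiple of the pooled IQR a median shift must
#'   exceed (default 1.0).
#' @param overlap_threshold overlap coefficient below which distributions
#'   count as separated (default 0.2).
#' @param n_bins number of shared histogram bins (default 50).
#' @return A `reaction_shift_report` data.frame with columns `reaction`,
#'   `median_a`, `median_b`, `iqr_a`, `iqr_b`, `overlap`, `sign_flip`,
#'   `shifted`.
#' @export
compare_distributions <- function(samples_a, samples_b, shift_threshold = 1.0,
                                  overlap_threshold = 0.2, n_bins = 50) {
  stopifnot(inherits(samples_a, "flux_samples"), inherits(samples_b, "flux_samples"))
  shared <- intersect(samples_a$reaction_ids, samples_b$reaction_ids)
  if (length(shared) == 0) stop("sample sets share no reactions")
  rows <- lapply(shared, function(rid) {
    xa <- samples_a$draws[, rid]; xb <- samples_b$draws[, rid]
    med_a <- median(xa); med_b <- median(xb)
    iqr_a <- unname(diff(quantile(xa, c(.25, .75))))
    iqr_b <- unname(diff(quantile(xb, c(.25, .75))))
    pooled <- c(xa, xb)
    rng <- quantile(pooled, c(0.01, 0.99), names = FALSE)
    if (diff(rng) < 1e-12) {
      overlap <- if (abs(med_a - med_b) < 1e-12) 1 else 0
    } else {
      edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
      clip <- function(x) pmin(pmax(x, rng[1]), rng[2])
      fa <- hist(clip(xa), breaks = edges, plot = FALSE)$counts / length(xa)
      fb <- hist(clip(xb), breaks = edges, plot = FALSE)$counts / length(xb)
      overlap <- sum(pmin(fa, fb))
    }
    pooled_iqr <- unname(diff(quantile(pooled, c(.25, .75))))
    shift <- abs(med_a - med_b)
    shifted <- (overlap < overlap_threshold) && (shift > shift_threshold * pooled_iqr)
    data.frame(reaction = rid, median_a = med_a, median_b = med_b,
               iqr_a = iqr_a, iqr_b = iqr_b, overlap = overlap,
               sign_flip = (med_a * med_b) < 0, shifted = shifted,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("reaction_shift_report", class(out))
  out
}

#' Reactions shifted into reverse operation
#'
#' From a shift report, returns the reactions flagged `shifted` whose model-A
#' median is strictly negative while the model-B median is non-negative —
#' the "running in reverse under the constrained scenario" readout. Sorted by
#' absolute median shift, largest first.
#'
#' @param report a `reaction_shift_report` from [compare_distributions()].
#' @return Character vector of reaction ids (possibly empty).
#' @export
flag_reversed_reactions <- function(report) {
  stopifnot(is.data.frame(report))
  hit <- report$shifted & report$median_a < 0 & report$median_b >= 0
  ids <- report$reaction[hit]
  ids[order(abs(report$median_a[hit] - report$median_b[hit]), decreasing = TRUE)]
}

#' Sweep the constraint fractions
#'
#' Rebuilds the constrained pair over a grid of `(f_hi, f_lo)` values and
#' records the model-A flux range of a focal reaction (by flux variability),
#' a cheap sensitivity picture of how strongly the reversal prediction
#' depends on the chosen fractions. Infeasible combinations are reported, not
#' errors.
#'
#' @param model_a,model_b context models as in [build_constrained_pair()].
#' @param reaction_id focal reaction (e.g. the Complex II id).
#' @param f_hi_grid,f_lo_grid numeric grids of fractions.
#' @inheritParams build_constrained_pair
#' @return data.frame with `f_hi`, `f_lo`, `feasible`, `min_a`, `max_a`.
#' @export
constraint_sensitivity_sweep <- function(model_a, model_b, reaction_id,
                                         ci_id = "CI_MitoCore", o2_id = "O2tm",
                                         f_hi_grid = seq(0.5, 0.9, 0.1),
                                         f_lo_grid = seq(0.1, 0.5, 0.1)) {
  grid <- expand.grid(f_hi = f_hi_grid, f_lo = f_lo_grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    fh <- grid$f_hi[i]; fl <- grid$f_lo[i]
    res <- tryCatch({
      pair <- build_constrained_pair(model_a, model_b, ci_id, o2_id, fh, fl)
      fva <- flux_variability(pair$a, reaction_id)
      data.frame(f_hi = fh, f_lo = fl, feasible = TRUE,
                 min_a = fva$min, max_a = fva$max)
    }, error = function(e) {
      data.frame(f_hi = fh, f_lo = fl, feasible = FALSE,
                 min_a = NA_real_, max_a = NA_real_)
    })
    res
  })
  do.call(rbind, rows)
}
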