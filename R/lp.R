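# Linear-programming services. The flux polytope {v : S v = 0, lb <= v <= ub}
# is parameterized on the null space of S (v = N t), turning every flux LP
# into a small dense inequality-form problem max c't s.t. A t <= b, solved by
# a two-phase primal simplex with Bland's rule (deterministic, anti-cycling).
# Problem sizes here are tiny (tens of variables), so a dense tableau is the
# right tool; feasibility tolerance is 1e-9.

LP_TOL <- 1e-9

# max obj'x s.t. A x <= b, x free in sign. Returns list(status, x, value).
# status: "optimal" | "infeasible" | "unbounded".
simplex_solve <- function(obj, A, b, tol = LP_TOL) {
  m <- nrow(A); n <- ncol(A)
  if (m == 0) {
    # unconstrained: bounded only if obj == 0
    if (all(abs(obj) <= tol)) return(list(status = "optimal", x = rep(0, n), value = 0))
    return(list(status = "unbounded", x = NULL, value = Inf))
  }
  # split free variables x = u - w, add slacks; rows with b < 0 get artificials
  flip <- b < 0
  A2 <- cbind(A, -A)
  A2[flip, ] <- -A2[flip, , drop = FALSE]
  b2 <- ifelse(flip, -b, b)
  slack <- diag(m); slack[flip, ] <- -slack[flip, , drop = FALSE]
  n_art <- sum(flip)
  art <- matrix(0, m, n_art)
  if (n_art > 0) art[cbind(which(flip), seq_len(n_art))] <- 1
  Tmat <- cbind(A2, slack, art)
  ncol_t <- ncol(Tmat)
  cost2 <- c(obj, -obj, rep(0, m + n_art))  # phase-2 objective (maximize)

  basis <- integer(m)
  basis[!flip] <- 2 * n + which(!flip)
  if (n_art > 0) basis[flip] <- 2 * n + m + seq_len(n_art)

  run_phase <- function(cost, Tmat, b2, basis, max_iter = 20000L) {
    m <- nrow(Tmat)
    for (iter in seq_len(max_iter)) {
      cb <- cost[basis]
      # reduced costs for maximization: c_j - cb' B^-1 A_j; maintain via tableau
      y <- cb %*% Tmat                      # row vector
      red <- cost - as.numeric(y)
      red[basis] <- 0
      enter <- which(red > tol)
      if (length(enter) == 0) {
        return(list(ok = TRUE, Tmat = Tmat, b2 = b2, basis = basis))
      }
      j <- min(enter)                       # Bland
      col <- Tmat[, j]
      pos <- which(col > tol)
      if (length(pos) == 0) return(list(ok = FALSE, unbounded = TRUE, basis = basis))
      ratio <- b2[pos] / col[pos]
      rmin <- min(ratio)
      cand <- pos[ratio <= rmin + tol]
      i <- cand[which.min(basis[cand])]     # Bland on leaving variable
      piv <- Tmat[i, j]
      Tmat[i, ] <- Tmat[i, ] / piv; b2[i] <- b2[i] / piv
      others <- setdiff(seq_len(m), i)
      f <- Tmat[others, j]
      Tmat[others, ] <- Tmat[others, , drop = FALSE] - outer(f, Tmat[i, ])
      b2[others] <- b2[others] - f * b2[i]
      b2[b2 < 0 & b2 > -tol] <- 0
      basis[i] <- j
    }
    stop("simplex iteration limit reached")
  }

  # phase 1: drive artificials out (maximize -sum(artificials))
  if (n_art > 0) {
    cost1 <- c(rep(0, 2 * n + m), rep(-1, n_art))
    ph1 <- run_phase(cost1, Tmat, b2, basis)
    if (!isTRUE(ph1$ok)) stop("internal LP error: phase 1 unbounded")
    Tmat <- ph1$Tmat; b2 <- ph1$b2; basis <- ph1$basis
    art_idx <- 2 * n + m + seq_len(n_art)
    infeas <- sum(b2[basis %in% art_idx])
    if (infeas > 1e-7) return(list(status = "infeasible", x = NULL, value = NA_real_))
    # pivot out any artificial still basic at zero level
    for (i in which(basis %in% art_idx)) {
      row <- Tmat[i, seq_len(2 * n + m)]
      j <- which(abs(row) > tol)
      if (length(j)) {
        j <- j[1]; piv <- Tmat[i, j]
        Tmat[i, ] <- Tmat[i, ] / piv; b2[i] <- b2[i] / piv
        others <- setdiff(seq_len(nrow(Tmat)), i)
        f <- Tmat[others, j]
        Tmat[others, ] <- Tmat[others, , drop = FALSE] - outer(f, Tmat[i, ])
        b2[others] <- b2[others] - f * b2[i]
        basis[i] <- j
      }
    }
    # drop redundant rows whose artificial could not be pivoted out, then
    # discard the artificial columns entirely (they are the trailing block)
    redundant <- basis %in% art_idx
    if (any(redundant)) {
      Tmat <- Tmat[!redundant, , drop = FALSE]
      b2 <- b2[!redundant]
      basis <- basis[!redundant]
    }
    Tmat <- Tmat[, seq_len(2 * n + m), drop = FALSE]
    cost2 <- cost2[seq_len(2 * n + m)]
    ncol_t <- ncol(Tmat)
  }

  ph2 <- run_phase(cost2, Tmat, b2, basis)
  if (!isTRUE(ph2$ok)) {
    if (isTRUE(ph2$unbounded)) return(list(status = "unbounded", x = NULL, value = Inf))
    stop("internal LP error")
  }
  xfull <- rep(0, ncol_t)
  xfull[ph2$basis] <- ph2$b2
  x <- xfull[seq_len(n)] - xfull[n + seq_len(n)]
  list(status = "optimal", x = x, value = sum(obj * x))
}

# Null-space parameterization of the flux polytope.
# Returns N (r x d, orthonormal), plus the inequality system A t <= b over t.
polytope_system <- function(model) {
  S <- stoichiometric_matrix(model)
  r <- ncol(S)
  N <- if (nrow(S) == 0) diag(r) else MASS::Null(t(S))
  if (is.null(dim(N))) N <- matrix(N, nrow = r)
  d <- ncol(N)
  lb <- model$reactions$lb; ub <- model$reactions$ub
  A <- rbind(N, -N)
  b <- c(ub, -lb)
  keep <- is.finite(b)
  list(N = N, d = d, A = A[keep, , drop = FALSE], b = b[keep],
       lb = lb, ub = ub, r = r)
}

lp_status <- function(res) res$status

#' Maximize the steady-state flux of one reaction
#'
#' Flux balance analysis for a single objective: the "theoretical maximum"
#' flux of `reaction_id` subject to `S v = 0` and the model bounds.
#'
#' @param model a `metabolic_model`.
#' @param reaction_id the reaction whose flux is maximized.
#' @param minimize if `TRUE`, minimize instead.
#' @return A list of class `lp_result` with `status` (`"optimal"`,
#'   `"infeasible"`, `"unbounded"`), `objective_value`, and `flux_vector`
#'   (named, length = number of reactions; `NULL` unless optimal).
#' @export
maximize_flux <- function(model, reaction_id, minimize = FALSE) {
  j <- match(reaction_id, model$reactions$id)
  if (is.na(j)) stop("unknown reaction id: ", reaction_id)
  ps <- polytope_system(model)
  if (ps$d == 0) {
    # polytope is at most the origin
    feasible <- all(ps$lb <= LP_TOL) && all(ps$ub >= -LP_TOL)
    if (!feasible) return(structure(list(status = "infeasible",
                                         objective_value = NA_real_,
                                         flux_vector = NULL), class = "lp_result"))
    v <- setNames(rep(0, ps$r), model$reactions$id)
    return(structure(list(status = "optimal", objective_value = 0, flux_vector = v),
                     class = "lp_result"))
  }
  obj <- ps$N[j, ]
  if (minimize) obj <- -obj
  res <- simplex_solve(obj, ps$A, ps$b)
  if (res$status != "optimal") {
    return(structure(list(status = res$status, objective_value =
                            if (res$status == "unbounded") (if (minimize) -Inf else Inf)
                          else NA_real_,
                          flux_vector = NULL), class = "lp_result"))
  }
  v <- as.numeric(ps$N %*% res$x)
  v <- pmin(pmax(v, ps$lb), ps$ub)          # clip solver fuzz onto the box
  names(v) <- model$reactions$id
  structure(list(status = "optimal",
                 objective_value = unname(v[j]),
                 flux_vector = v), class = "lp_result")
}

#' @export
print.lp_result <- function(x, ...) {
  cat(sprintf("<lp_result> status: %s, objective: %s\n", x$status,
              format(x$objective_value)))
  invisible(x)
}

#' Flux variability analysis
#'
#' Minimum and maximum feasible steady-state flux for each requested reaction.
#'
#' @param model a `metabolic_model`.
#' @param reaction_ids reactions to analyze (default: all).
#' @return data.frame with columns `reaction`, `min`, `max`.
#' @export
flux_variability <- function(model, reaction_ids = model$reactions$id) {
  unknown <- setdiff(reaction_ids, model$reactions$id)
  if (length(unknown)) stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))
  res <- lapply(reaction_ids, function(rid) {
    lo <- maximize_flux(model, rid, minimize = TRUE)
    hi <- maximize_flux(model, rid, minimize = FALSE)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("FVA failed for ", rid, ": status ", lo$status, "/", hi$status)
    }
    c(lo$objective_value, hi$objective_value)
  })
  out <- data.frame(reaction = reaction_ids,
                    min = vapply(res, `[`, numeric(1), 1),
                    max = vapply(res, `[`, numeric(1), 2),
                    stringsAsFactors = FALSE)
  # numerical guard: min never above max
  sw <- out$min > out$max
  if (any(sw)) { tmp <- out$min[sw]; out$min[sw] <- out$max[sw]; out$max[sw] <- tmp }
  out
}

#' Check flux-carrying capacity of protected functions
#'
#' A model "has capacity" when every witness reaction (one per protected
#' metabolic function, e.g. ATP synthesis / TCA cycle / glycolysis) can carry
#' at least `epsilon` flux at steady state. Used as the guard during
#' context-specific pruning.
#'
#' @param model a `metabolic_model`.
#' @param protected_reactions character vector of witness reaction ids.
#'   Defaults to the toy network's witnesses (ATP synthase, citrate synthase,
#'   lumped glycolysis); supply your own ids for other models.
#' @param epsilon minimal flux that counts as "carrying" (default `1e-6`,
#'   well above LP tolerance and well below physiological flux scales).
#' @return `TRUE`/`FALSE`.
#' @export
check_capacity <- function(model, protected_reactions = c("ATPS", "CS", "GLYC"),
                           epsilon = 1e-6) {
  unknown <- setdiff(protected_reactions, model$reactions$id)
  if (length(unknown)) {
    stop("configuration error: protected reaction(s) not in model: ",
         paste(unknown, collapse = ", "))
  }
  for (rid in protected_reactions) {
    res <- maximize_flux(model, rid)
    if (res$status != "optimal" || res$objective_value < epsilon) return(FALSE)
  }
  TRUE
}

#' Strictly interior point of the flux polytope
#'
#' Chebyshev-center style LP: maximizes the uniform margin `delta` such that
#' `lb + delta <= v <= ub - delta` on all coordinates that are not pinned
#' (pinned = equal or numerically tight bounds), subject to `S v = 0`.
#'
#' @param model a `metabolic_model`.
#' @param pinned_tol coordinates whose feasible range is below this are
#'   treated as pinned and excluded from the margin.
#' @return list with `v` (named flux vector), `delta` (achieved margin),
#'   `pinned` (logical vector), and `degenerate` (`TRUE` when `delta == 0`).
#'   Errors when the polytope is empty.
#' @export
interior_point <- function(model, pinned_tol = 1e-9) {
  ps <- polytope_system(model)
  rxn_ids <- model$reactions$id
  if (ps$d == 0) {
    feasible <- all(ps$lb <= LP_TOL) && all(ps$ub >= -LP_TOL)
    if (!feasible) stop("infeasible model: empty flux polytope")
    return(list(v = setNames(rep(0, ps$r), rxn_ids), delta = 0,
                pinned = rep(TRUE, ps$r), degenerate = TRUE))
  }
  fva <- flux_variability(model)
  pinned <- (fva$max - fva$min) < pinned_tol
  if (all(pinned)) {
    v <- setNames((fva$max + fva$min) / 2, rxn_ids)
    return(list(v = v, delta = 0, pinned = pinned, degenerate = TRUE))
  }
  # variables (t, delta): maximize delta
  rows_ub <- which(is.finite(ps$ub) & !pinned)
  rows_lb <- which(is.finite(ps$lb) & !pinned)
  add_const <- function(M, k) cbind(M, rep(k, nrow(M)))
  A <- rbind(add_const(ps$N[rows_ub, , drop = FALSE], 1),
             add_const(-ps$N[rows_lb, , drop = FALSE], 1),
             add_const(ps$N[pinned, , drop = FALSE], 0),
             add_const(-ps$N[pinned, , drop = FALSE], 0),
             add_const(matrix(0, 1, ps$d), -1))  # delta >= 0
  b <- c(ps$ub[rows_ub], -ps$lb[rows_lb],
         fva$max[pinned] + pinned_tol, -(fva$min[pinned] - pinned_tol), 0)
  obj <- c(rep(0, ps$d), 1)
  res <- simplex_solve(obj, A, b)
  if (res$status == "infeasible") stop("infeasible model: empty flux polytope")
  if (res$status == "unbounded") {
    stop("interior-point LP unbounded: model has a missing bound")
  }
  t_star <- res$x[seq_len(ps$d)]
  delta <- max(0, res$x[ps$d + 1])
  v <- as.numeric(ps$N %*% t_star)
  v <- pmin(pmax(v, ps$lb), ps$ub)
  names(v) <- rxn_ids
  list(v = v, delta = delta, pinned = pinned, degenerate = delta <= pinned_tol)
}
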