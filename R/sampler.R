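# Uniform sampling of the steady-state flux polytope by hit-and-run MCMC.
# The polytope is parameterized on the null space of S; coordinates pinned by
# the constraints (equal or FVA-tight bounds) are fixed as constants and
# excluded from the walk; a rounding transform (Cholesky factor of a pilot
# run's covariance) isotropizes elongated polytopes before the main chains.

#' Draw uniform steady-state flux samples
#'
#' Hit-and-run Markov chain sampling of `{v : S v = 0, lb <= v <= ub}`. The
#' random walk runs in the (rounded) null-space coordinates; `seed` fully
#' determines the output.
#'
#' @param model a feasible `metabolic_model`.
#' @param n total number of post-warmup draws (default 5000).
#' @param seed integer RNG seed (required: no silent nondeterminism).
#' @param warmup discarded steps per chain (default 1000).
#' @param thinning steps between retained draws; default `max(1, 10 * d)`
#'   where `d` is the free dimension of the polytope.
#' @param n_chains number of independent chains (default 4); draws are split
#'   evenly across chains.
#' @param pilot_draws pilot-run draws used to estimate the rounding transform.
#' @return A `flux_samples` object: `draws` (n x r matrix, reaction ids as
#'   colnames), `chain` (chain index per row), and the sampler settings.
#' @export
sample_fluxes <- function(model, n = 5000, seed, warmup = 1000, thinning = NULL,
                          n_chains = 4, pilot_draws = 400) {
  if (missing(seed) || is.null(seed)) stop("seed is required")
  stopifnot(n >= 1, n_chains >= 1)
  set.seed(as.integer(seed))
  rxn_ids <- model$reactions$id
  r <- length(rxn_ids)

  ps <- polytope_system(model)
  ip <- interior_point(model)        # errors if infeasible
  fva <- flux_variability(model)
  pinned <- (fva$max - fva$min) < 1e-9
  mid <- (fva$max + fva$min) / 2

  single_point <- function(v) {
    warning("flux polytope has no free directions; returning a single point")
    draws <- matrix(rep(v, each = n), nrow = n, dimnames = list(NULL, rxn_ids))
    structure(list(draws = draws, reaction_ids = rxn_ids, seed = seed,
                   warmup = warmup, thinning = 1L, n_chains = 1L,
                   chain = rep(1L, n)), class = "flux_samples")
  }
  if (ps$d == 0 || all(pinned)) return(single_point(setNames(mid, rxn_ids)))

  # fix pinned coordinates: t = t0 + B2 s with N[pinned, ] %*% t == mid[pinned].
  # E can contain exact-zero rows (coordinates pinned by mass balance itself),
  # so its null space is taken from the SVD at an explicit rank tolerance.
  if (any(pinned)) {
    E <- ps$N[pinned, , drop = FALSE]
    t0 <- as.numeric(MASS::ginv(E) %*% mid[pinned])
    sv <- svd(E, nu = 0, nv = ps$d)
    rank_e <- sum(sv$d > 1e-9 * max(sv$d, 1))
    if (rank_e >= ps$d) return(single_point(setNames(mid, rxn_ids)))
    B2 <- sv$v[, (rank_e + 1):ps$d, drop = FALSE]
  } else {
    t0 <- rep(0, ps$d)
    B2 <- diag(ps$d)
  }
  v0 <- as.numeric(ps$N %*% t0)
  M <- ps$N %*% B2                   # r x d2, orthonormal columns
  d2 <- ncol(M)
  free <- !pinned
  Cfree <- M[free, , drop = FALSE]
  lo <- pmax(model$reactions$lb[free] - v0[free], -1e30)
  hi <- pmin(model$reactions$ub[free] - v0[free], 1e30)
  s0 <- as.numeric(crossprod(M, ip$v - v0))

  if (is.null(thinning)) thinning <- max(1L, 10L * d2)
  thinning <- as.integer(thinning)

  # pilot run -> rounding transform from sample covariance
  pilot <- .hit_and_run_core(Cfree, lo, hi, s0, as.integer(pilot_draws), 2L,
                             as.integer(50 + 5 * d2))
  s_c <- colMeans(pilot)
  Sig <- var(pilot)
  Sig <- Sig + diag(d2) * (1e-10 + 1e-8 * mean(diag(Sig)))
  L <- t(chol(Sig))
  C2 <- Cfree %*% L
  lo2 <- lo - as.numeric(Cfree %*% s_c)
  hi2 <- hi - as.numeric(Cfree %*% s_c)

  per_chain <- diff(round(seq(0, n, length.out = n_chains + 1)))
  z_rows <- vector("list", n_chains)
  chain_id <- integer(0)
  Linv <- solve(L)
  for (ch in seq_len(n_chains)) {
    start_s <- pilot[sample.int(nrow(pilot), 1), ]
    z_start <- as.numeric(Linv %*% (start_s - s_c))
    z <- .hit_and_run_core(C2, lo2, hi2, z_start, as.integer(per_chain[ch]),
                           thinning, as.integer(warmup))
    z_rows[[ch]] <- z
    chain_id <- c(chain_id, rep(ch, nrow(z)))
  }
  Z <- do.call(rbind, z_rows)
  Svals <- sweep(Z %*% t(L), 2, s_c, `+`)       # back to s coordinates
  V <- sweep(Svals %*% t(M), 2, v0, `+`)        # to flux space
  V[, pinned] <- matrix(rep(mid[pinned], each = nrow(V)), nrow = nrow(V))
  # clip solver-level fuzz onto the box
  V <- pmin(pmax(V, matrix(rep(model$reactions$lb, each = nrow(V)), nrow(V))),
            matrix(rep(model$reactions$ub, each = nrow(V)), nrow(V)))
  colnames(V) <- rxn_ids

  out <- structure(list(draws = V, reaction_ids = rxn_ids, seed = seed,
                        warmup = warmup, thinning = thinning,
                        n_chains = n_chains, chain = chain_id),
                   class = "flux_samples")
  assert_flux_samples(out, model)
  out
}

#' Check flux-sample invariants
#'
#' Asserts that every draw satisfies mass balance
#' (`max |S v| <= 1e-6 * max(1, max |v|)`) and the flux bounds to within
#' `1e-6`. Called automatically by [sample_fluxes()].
#'
#' @param samples a `flux_samples` object.
#' @param model the model the samples were drawn from.
#' @return `TRUE` invisibly; errors with the first offending draw otherwise.
#' @export
assert_flux_samples <- function(samples, model) {
  S <- stoichiometric_matrix(model)
  V <- samples$draws
  resid <- abs(S %*% t(V))
  tolr <- 1e-6 * pmax(1, apply(abs(V), 1, max))
  bad <- which(apply(resid, 2, max) > tolr)
  if (length(bad)) stop("mass-balance violation in draw ", bad[1])
  lb <- model$reactions$lb; ub <- model$reactions$ub
  vio <- which(apply(t(V) - lb < -1e-6, 2, any) | apply(t(V) - ub > 1e-6, 2, any))
  if (length(vio)) stop("bound violation in draw ", vio[1])
  invisible(TRUE)
}

#' @export
print.flux_samples <- function(x, ...) {
  cat(sprintf("<flux_samples> %d draws x %d reactions (seed %s, %d chain(s), thin %d)\n",
              nrow(x$draws), ncol(x$draws), format(x$seed), x$n_chains, x$thinning))
  invisible(x)
}

#' Split-chain convergence diagnostics
#'
#' Potential scale reduction (split-chain R-hat) and effective sample size for
#' every reaction. Each chain is split in half; `R-hat` is the usual
#' between/within variance ratio, and ESS uses chain-averaged autocorrelations
#' truncated at the first negative paired sum.
#'
#' @param samples a `flux_samples` object with at least 2 chains of >= 50
#'   draws each.
#' @return data.frame with columns `reaction`, `rhat`, `ess`, `note`
#'   (`"constant"` for pinned reactions, where the diagnostics are not
#'   applicable and reported as `NA`).
#' @export
convergence_diagnostics <- function(samples) {
  stopifnot(inherits(samples, "flux_samples"))
  if (samples$n_chains < 2) {
    stop("convergence diagnostics need >= 2 chains; rerun sample_fluxes() ",
         "with n_chains >= 2")
  }
  counts <- table(samples$chain)
  if (any(counts < 50)) stop("each chain needs >= 50 draws for diagnostics")
  n_half <- min(counts) %/% 2

  split_cols <- function(x) {
    # matrix n_half x (2 * n_chains) of split half-chains
    out <- NULL
    for (ch in sort(unique(samples$chain))) {
      xi <- x[samples$chain == ch]
      out <- cbind(out, xi[seq_len(n_half)], xi[n_half + seq_len(n_half)])
    }
    out
  }
  one <- function(x) {
    if (max(x) - min(x) < 1e-12) {
      return(c(rhat = NA_real_, ess = NA_real_))
    }
    H <- split_cols(x)
    m <- ncol(H); nn <- nrow(H)
    mu <- colMeans(H); s2 <- apply(H, 2, var)
    W <- mean(s2); B <- nn * var(mu)
    var_plus <- (nn - 1) / nn * W + B / nn
    rhat <- sqrt(var_plus / W)
    # chain-averaged autocorrelation, Geyer initial-positive truncation
    max_lag <- min(nn - 2, 200)
    acf_w <- rep(0, max_lag)
    for (j in seq_len(m)) {
      a <- acf(H[, j], lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[-1]
      acf_w <- acf_w + s2[j] * a / m
    }
    rho <- 1 - (W - acf_w) / var_plus
    tau <- 1; t <- 1
    while (t + 1 <= max_lag) {
      pair <- rho[t] + rho[t + 1]
      if (!is.finite(pair) || pair < 0) break
      tau <- tau + 2 * pair
      t <- t + 2
    }
    c(rhat = rhat, ess = m * nn / tau)
  }
  vals <- t(apply(samples$draws, 2, one))
  data.frame(reaction = samples$reaction_ids,
             rhat = vals[, "rhat"], ess = vals[, "ess"],
             note = ifelse(is.na(vals[, "rhat"]), "constant", ""),
             stringsAsFactors = FALSE)
}

#' Histogram of a sampled flux distribution
#'
#' @param samples a `flux_samples` object.
#' @param reaction_id reaction to summarize.
#' @param n_bins number of equal-width bins over the observed range.
#' @return list with `edges` (length `n_bins + 1`), `mids`, and `freq`
#'   (relative frequencies summing to 1).
#' @export
flux_histogram <- function(samples, reaction_id, n_bins = 30) {
  stopifnot(inherits(samples, "flux_samples"))
  j <- match(reaction_id, samples$reaction_ids)
  if (is.na(j)) stop("unknown reaction id: ", reaction_id)
  x <- samples$draws[, j]
  rng <- range(x)
  if (diff(rng) < 1e-12) {
    edges <- c(rng[1] - 0.5, rng[1] + 0.5)
    return(list(edges = edges, mids = rng[1], freq = 1))
  }
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  cnt <- hist(x, breaks = edges, plot = FALSE, include.lowest = TRUE)$counts
  list(edges = edges, mids = (edges[-1] + edges[-length(edges)]) / 2,
       freq = cnt / length(x))
}
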