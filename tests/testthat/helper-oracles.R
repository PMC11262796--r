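# Independent oracles and fixture builders used across the test files.
# Nothing here calls the code paths it is used to check: the LP oracle is
# brute-force vertex enumeration, the BH oracle is the explicit double-loop
# step-up, and models are built from literal tables.

# --- small model builders -------------------------------------------------

make_model <- function(reactions, equations, lb, ub, gpr = "", id = "test") {
  st <- do.call(rbind, lapply(seq_along(reactions), function(i) {
    fluxcontrast:::parse_equation(equations[i], reactions[i])
  }))
  mets <- unique(st$metabolite)
  metabolic_model(
    data.frame(id = mets, compartment = "c", name = mets),
    data.frame(id = reactions, lb = lb, ub = ub, gpr = gpr, subsystem = ""),
    st, id = id)
}

# linear chain:  -> A (ub u1), A -> B (ub u2), B -> (ub u3)
chain_model <- function(u1 = 10, u2 = 1000, u3 = 5) {
  make_model(c("EX_A", "AB", "EX_B"), c("-> A", "A -> B", "B ->"),
             lb = c(0, 0, 0), ub = c(u1, u2, u3), id = "chain")
}

# k parallel routes draining a fixed unit influx: the (k-1)-simplex polytope
simplex_model <- function(k = 3) {
  make_model(c("IN", paste0("R", seq_len(k))),
             c("-> X", rep("X ->", k)),
             lb = c(1, rep(0, k)), ub = c(1, rep(1000, k)),
             id = sprintf("simplex%d", k))
}

# --- LP oracle: brute-force vertex enumeration ----------------------------
# Enumerates all vertices of {t : N t <= ub, -N t >= lb} by solving every
# d x d active-constraint system, then reads off the extreme flux of one
# reaction. Only usable for small networks (finite bounds, <= ~8 reactions).

enumerate_vertices <- function(model) {
  S <- stoichiometric_matrix(model)
  N <- MASS::Null(t(S))
  if (is.null(dim(N))) N <- matrix(N, nrow = ncol(S))
  d <- ncol(N)
  lb <- model$reactions$lb; ub <- model$reactions$ub
  if (d == 0) {
    feasible <- all(lb <= 1e-9) && all(ub >= -1e-9)
    return(if (feasible) matrix(0, nrow = 1, ncol = nrow(model$reactions),
                                dimnames = list(NULL, model$reactions$id))
           else NULL)
  }
  A <- rbind(N, -N); b <- c(ub, -lb)
  keep <- is.finite(b)
  A <- A[keep, , drop = FALSE]; b <- b[keep]
  verts <- list()
  for (comb in utils::combn(nrow(A), d, simplify = FALSE)) {
    Asub <- A[comb, , drop = FALSE]
    if (abs(det(Asub)) < 1e-10) next
    t0 <- try(solve(Asub, b[comb]), silent = TRUE)
    if (inherits(t0, "try-error")) next
    if (all(A %*% t0 <= b + 1e-9)) verts[[length(verts) + 1]] <- t0
  }
  if (length(verts) == 0) return(NULL)
  V <- t(vapply(verts, function(t0) as.numeric(N %*% t0),
                numeric(nrow(N))))
  colnames(V) <- model$reactions$id
  V
}

oracle_max_flux <- function(model, reaction_id) {
  V <- enumerate_vertices(model)
  if (is.null(V)) return(NA_real_)      # empty polytope
  max(V[, reaction_id])
}

# random small network with 0 always feasible (lb <= 0 <= ub), finite bounds
random_small_model <- function(n_rxn = sample(3:8, 1), n_met = sample(2:4, 1)) {
  repeat {
    S <- matrix(sample(c(-2, -1, 0, 0, 1, 2), n_met * n_rxn, replace = TRUE),
                nrow = n_met)
    # force column 1 to be a pure source so a boundary reaction exists
    S[, 1] <- 0; S[1, 1] <- 1
    if (any(rowSums(S != 0) == 0)) next   # dead metabolite row: resample
    mets <- paste0("m", seq_len(n_met))
    rxns <- paste0("r", seq_len(n_rxn))
    st <- data.frame(reaction = rxns[col(S)[S != 0]],
                     metabolite = mets[row(S)[S != 0]],
                     coef = S[S != 0], stringsAsFactors = FALSE)
    lb <- ifelse(runif(n_rxn) < 0.5, -round(runif(n_rxn, 1, 10), 1), 0)
    ub <- round(runif(n_rxn, 0.5, 10), 1)
    m <- try(metabolic_model(
      data.frame(id = mets, compartment = "c", name = mets),
      data.frame(id = rxns, lb = lb, ub = ub, gpr = "", subsystem = ""),
      st, id = "random"), silent = TRUE)
    if (!inherits(m, "try-error")) return(m)
  }
}

# --- BH oracle: explicit min-over-tail double loop ------------------------

bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  qs <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, ps[j] * m / j)
    qs[i] <- min(1, best)
  }
  q <- numeric(m)
  q[ord] <- qs
  q
}

# --- GPR oracle: truth-table evaluation by R's own logic ------------------

gpr_truth_eval <- function(gpr, assignment) {
  # assignment: named logical vector; two-valued oracle (no unknowns)
  expr <- gsub("\\band\\b", "&&", gsub("\\bor\\b", "||", gpr, ignore.case = TRUE),
               ignore.case = TRUE)
  for (g in names(assignment)) {
    expr <- gsub(paste0("(?<![\\w.])", g, "(?![\\w.])"),
                 ifelse(assignment[[g]], "TRUE", "FALSE"), expr, perl = TRUE)
  }
  eval(parse(text = expr))
}

# --- MCMC standard errors by batch means ----------------------------------

batch_se <- function(x, n_batches = NULL) {
  n <- length(x)
  if (is.null(n_batches)) n_batches <- max(10, floor(sqrt(n)))
  bs <- floor(n / n_batches)
  means <- vapply(seq_len(n_batches),
                  function(i) mean(x[((i - 1) * bs + 1):(i * bs)]), numeric(1))
  sd(means) / sqrt(n_batches)
}

# --- SBML fixture text ----------------------------------------------------

sbml_l3_fbc_text <- function() {
'<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="mini_l3" fbc:strict="true">
    <listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>
    <listOfSpecies>
      <species id="A" compartment="c" name="met A" boundaryCondition="false" constant="false"/>
      <species id="B" compartment="c" name="met B" boundaryCondition="false" constant="false"/>
      <species id="X_ext" compartment="c" boundaryCondition="true" constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="lb_zero" value="0" constant="true"/>
      <parameter id="ub_ten" value="10" constant="true"/>
      <parameter id="lb_rev" value="-25" constant="true"/>
      <parameter id="ub_big" value="1000" constant="true"/>
    </listOfParameters>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="gp1" fbc:label="g1"/>
      <fbc:geneProduct fbc:id="gp2" fbc:label="g2"/>
      <fbc:geneProduct fbc:id="gp3" fbc:label="g3"/>
    </fbc:listOfGeneProducts>
    <listOfReactions>
      <reaction id="EX_A" reversible="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_ten">
        <listOfReactants><speciesReference species="X_ext" stoichiometry="1" constant="true"/></listOfReactants>
        <listOfProducts><speciesReference species="A" stoichiometry="1" constant="true"/></listOfProducts>
      </reaction>
      <reaction id="AB" reversible="true" fbc:lowerFluxBound="lb_rev" fbc:upperFluxBound="ub_big">
        <listOfReactants><speciesReference species="A" stoichiometry="2" constant="true"/></listOfReactants>
        <listOfProducts><speciesReference species="B" stoichiometry="1" constant="true"/></listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:or>
            <fbc:and>
              <fbc:geneProductRef fbc:geneProduct="gp1"/>
              <fbc:geneProductRef fbc:geneProduct="gp2"/>
            </fbc:and>
            <fbc:geneProductRef fbc:geneProduct="gp3"/>
          </fbc:or>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="EX_B" reversible="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_big">
        <listOfReactants><speciesReference species="B" stoichiometry="1" constant="true"/></listOfReactants>
      </reaction>
    </listOfReactions>
  </model>
</sbml>'
}

sbml_l2_notes_text <- function() {
'<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
  <model id="mini_l2">
    <listOfCompartments><compartment id="c"/></listOfCompartments>
    <listOfSpecies>
      <species id="A" compartment="c"/>
      <species id="B" compartment="c"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="EX_A" reversible="false">
        <listOfProducts><speciesReference species="A" stoichiometry="1"/></listOfProducts>
        <kineticLaw>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="0"/>
            <parameter id="UPPER_BOUND" value="8"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
      <reaction id="AB" reversible="true">
        <notes><body xmlns="http://www.w3.org/1999/xhtml">
          <p>GENE_ASSOCIATION: (g1 and g2) or g3</p>
        </body></notes>
        <listOfReactants><speciesReference species="A"/></listOfReactants>
        <listOfProducts><speciesReference species="B"/></listOfProducts>
      </reaction>
      <reaction id="EX_B" reversible="false">
        <listOfReactants><speciesReference species="B"/></listOfReactants>
      </reaction>
    </listOfReactions>
  </model>
</sbml>'
}

write_temp_sbml <- function(text) {
  f <- tempfile(fileext = ".xml")
  writeLines(text, f)
  f
}

# presence_calls object from a plain named vector (bypasses thresholds)
calls_from_vector <- function(v) {
  structure(list(calls = v, thresholds = list(), provenance = "fixture"),
            class = "presence_calls")
}
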