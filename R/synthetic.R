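# Synthetic-data generators: a fixed toy central-metabolism network whose
# constrained scenario provably admits reverse Complex II flux, plus seeded
# negative-binomial expression tables and log-normal metabolite abundances.
# These stand in for real transcriptome / proteome / metabolome inputs so the
# whole pipeline is testable end to end.

toy_metabolites <- function() {
  data.frame(
    id = c("glc_e", "glc_c", "pyr_c", "lac_c", "lac_e", "accoa_m", "cit_m",
           "akg_m", "succ_m", "fum_m", "mal_m", "oaa_m", "nad_m", "nadh_m",
           "q_m", "qh2_m", "red_m", "o2_c", "o2_m", "atp_c", "adp_c", "h_i",
           "succ_e", "mal_e"),
    compartment = c("e", "c", "c", "c", "e", "m", "m", "m", "m", "m", "m",
                    "m", "m", "m", "m", "m", "m", "c", "m", "c", "c", "m",
                    "e", "e"),
    name = c("glucose (ext)", "glucose", "pyruvate", "lactate", "lactate (ext)",
             "acetyl-CoA", "citrate", "2-oxoglutarate", "succinate", "fumarate",
             "malate", "oxaloacetate", "NAD+", "NADH", "ubiquinone", "ubiquinol",
             "reduced carrier", "O2 (cytosol)", "O2 (mito)", "ATP", "ADP",
             "proton-motive charge", "succinate (ext)", "malate (ext)"),
    stringsAsFactors = FALSE)
}

toy_reactions <- function() {
  # id, equation, lb, ub; every reaction carries a one-gene GPR "<id>_g"
  spec <- list(
    c("EX_glc",   "-> glc_e",                                     0,    5),
    c("GLCt",     "glc_e -> glc_c",                               0, 1000),
    c("GLYC",     "glc_c + 2 adp_c -> 2 pyr_c + 2 atp_c",         0, 1000),
    c("LDH",      "pyr_c -> lac_c",                               0, 1000),
    c("LACt",     "lac_c -> lac_e",                               0, 1000),
    c("EX_lac",   "lac_e ->",                                     0, 1000),
    c("PDH",      "pyr_c + nad_m -> accoa_m + nadh_m",            0, 1000),
    c("CS",       "accoa_m + oaa_m -> cit_m",                     0, 1000),
    c("IDH",      "cit_m + nad_m -> akg_m + nadh_m",              0, 1000),
    c("AKGDH",    "akg_m + nad_m -> succ_m + nadh_m",             0, 1000),
    c("CII_toy",  "succ_m + q_m <=> fum_m + qh2_m",           -1000, 1000),
    c("FUM",      "fum_m <=> mal_m",                          -1000, 1000),
    c("MDH",      "mal_m + nad_m -> oaa_m + nadh_m",              0, 1000),
    c("CI_toy",   "nadh_m + q_m -> nad_m + qh2_m + 4 h_i",        0,   20),
    c("CIII_toy", "qh2_m -> q_m + 2 red_m + 2 h_i",               0, 1000),
    c("CIV_toy",  "2 red_m + o2_m -> 4 h_i",                      0, 1000),
    c("O2tm_toy", "o2_c -> o2_m",                                 0, 1000),
    c("EX_o2",    "-> o2_c",                                      0,   10),
    c("ATPS",     "3 h_i + adp_c -> atp_c",                       0, 1000),
    c("ATPM",     "atp_c -> adp_c",                               0, 1000),
    c("SUCCt",    "succ_m -> succ_e",                             0, 1000),
    c("EX_succ",  "succ_e ->",                                    0, 1000),
    c("MALt",     "mal_e -> mal_m",                               0, 1000),
    c("EX_mal",   "-> mal_e",                                     0,   16))
  data.frame(
    id = vapply(spec, `[`, character(1), 1),
    equation = vapply(spec, `[`, character(1), 2),
    lb = as.numeric(vapply(spec, `[`, character(1), 3)),
    ub = as.numeric(vapply(spec, `[`, character(1), 4)),
    stringsAsFactors = FALSE)
}

#' Build the toy central-metabolism network
#'
#' A fixed 24-reaction, 24-metabolite model of glucose uptake, lumped
#' glycolysis, the lactate branch, a TCA loop with an explicitly reversible
#' succinate dehydrogenase (`CII_toy`), electron transport complexes
#' `CI_toy`/`CIII_toy`/`CIV_toy` feeding a proton-motive pool, ATP synthase
#' (`ATPS`) with an ATP demand (`ATPM`), O2 transport (`O2tm_toy`), and
#' exchanges for glucose, O2, lactate, succinate, and malate. Every reaction
#' carries a one-gene GPR (gene id = reaction id + `"_g"`).
#'
#' The malate uptake route plus reversible fumarase give the network a
#' fumarate supply that lets `CII_toy` run in reverse (fumarate + ubiquinol
#' -> succinate + ubiquinone) when Complex I flux is forced high while O2
#' transport is capped — the ischemia-like scenario. With `verify = TRUE`
#' (default) this is checked at build time: the model must validate, pass
#' [check_capacity()], and the constrained scenario
#' (`build_constrained_pair(f_hi = 0.7, f_lo = 0.3)`) must admit strictly
#' negative `CII_toy` flux.
#'
#' @param verify run the build-time checks (skip only in tight loops where
#'   the same fixed model is rebuilt many times).
#' @return A `metabolic_model` with objective `ATPM`.
#' @export
build_toy_network <- function(verify = TRUE) {
  rx <- toy_reactions()
  st <- do.call(rbind, lapply(seq_len(nrow(rx)), function(i) {
    parse_equation(rx$equation[i], rx$id[i])
  }))
  reactions <- data.frame(id = rx$id, lb = rx$lb, ub = rx$ub,
                          gpr = paste0(rx$id, "_g"), subsystem = "toy",
                          stringsAsFactors = FALSE)
  model <- metabolic_model(toy_metabolites(), reactions, st,
                           objective = "ATPM", id = "toy_etc",
                           provenance = "built by build_toy_network()")
  if (verify) {
    if (!check_capacity(model)) stop("internal error: toy fixture lost capacity")
    pair <- build_constrained_pair(model, model, ci_id = "CI_toy",
                                   o2_id = "O2tm_toy", f_hi = 0.7, f_lo = 0.3)
    cii <- flux_variability(pair$a, "CII_toy")
    if (!(cii$min < 0)) {
      stop("internal error: toy fixture does not admit reverse CII flux")
    }
  }
  model
}

#' Genes safe to plant as absent in toy simulations
#'
#' The lactate branch and ATP synthase: reactions that either sit off every
#' protected route (so pruning can remove them in any combination) or are a
#' protected witness themselves (so pruning must always retain them). Planted
#' absence restricted to this pool keeps sequential pruning equivalent to
#' exhaustive single-deletion testing, because none of these reactions are
#' alternative routes for one another.
#'
#' @return Character vector of gene ids.
#' @export
toy_absent_pool <- function() c("ATPS_g", "EX_lac_g", "LACt_g", "LDH_g")

#' Configuration for the toy simulation scenario
#'
#' Bundles every knob of the synthetic-data layer with the defaults used
#' throughout the package: three replicates per platform, negative-binomial
#' counts separating absent (mean 1) from present (mean 100) genes at the
#' transcript cutoff of 5 (protein values scaled by `protein_scale` so the
#' same separation holds at the protein cutoff of 2000), and log-normal
#' metabolite abundances (sigma 0.1) with a planted 5-fold succinate effect
#' plus a low-energy adenylate profile (one-third ATP, 3x AMP) in group A.
#'
#' @param seed integer seed controlling every draw made from this config.
#' @param absent_genes gene ids planted as absent (default `LDH_g`, `ATPS_g`).
#' @param mean_present,mean_absent,dispersion negative-binomial parameters
#'   for transcript counts of present/absent genes.
#' @param protein_scale multiplier mapping transcript-scale means to
#'   protein-abundance scale.
#' @param n_replicates replicates per platform and per group.
#' @param effects named list of group-A fold changes for metabolites.
#' @param base_abundance named vector of group-B mean abundances.
#' @param sigma log-normal noise (sd of log abundance).
#' @param f_hi,f_lo constraint fractions for the comparative scenario.
#' @return A list of class `toy_scenario_config`.
#' @export
toy_scenario_config <- function(seed,
                                absent_genes = c("LDH_g", "ATPS_g"),
                                mean_present = 100, mean_absent = 1,
                                dispersion = 10, protein_scale = 400,
                                n_replicates = 3,
                                effects = list(succinate = 5, ATP = 1/3, AMP = 3),
                                base_abundance = c(
                                  glucose = 80, lactate = 50, citrate = 20,
                                  succinate = 10, fumarate = 10, malate = 15,
                                  AMP = 5, ADP = 25, ATP = 100),
                                sigma = 0.1, f_hi = 0.7, f_lo = 0.3) {
  if (missing(seed) || is.null(seed)) stop("seed is required")
  if (!(mean_absent < 5 && 5 < mean_present)) {
    stop("need mean_absent < presence cutoff (5) < mean_present")
  }
  if (any(unlist(effects) <= 0)) stop("fold-change effects must be positive")
  structure(list(seed = as.integer(seed), absent_genes = absent_genes,
                 mean_present = mean_present, mean_absent = mean_absent,
                 dispersion = dispersion, protein_scale = protein_scale,
                 n_replicates = n_replicates, effects = effects,
                 base_abundance = base_abundance, sigma = sigma,
                 f_hi = f_hi, f_lo = f_lo),
            class = "toy_scenario_config")
}

#' Simulate transcript and protein expression tables
#'
#' Draws negative-binomial counts for every gene of `model` over
#' `n_replicates` samples per platform: absent genes at `mean_absent`,
#' present genes at `mean_present` (protein values scaled by
#' `protein_scale`). Fully determined by `config$seed`.
#'
#' @param model a `metabolic_model`; its GPR genes define the gene universe.
#' @param config a [toy_scenario_config()].
#' @return list with `transcript` and `protein` (gene x sample matrices) and
#'   `absent_genes` (the planted ground truth).
#' @export
simulate_expression <- function(model, config) {
  stopifnot(inherits(config, "toy_scenario_config"))
  genes <- model_genes(model)
  extra <- setdiff(config$absent_genes, genes)
  if (length(extra)) {
    stop("absent genes not in model: ", paste(extra, collapse = ", "))
  }
  if (config$dispersion <= 0 || config$mean_absent < 0 || config$mean_present <= 0) {
    stop("invalid negative-binomial parameters")
  }
  set.seed(config$seed)
  n <- config$n_replicates
  mu <- ifelse(genes %in% config$absent_genes, config$mean_absent,
               config$mean_present)
  draw <- function(scale) {
    m <- matrix(rnbinom(length(genes) * n, mu = rep(mu * scale, n),
                        size = config$dispersion),
                nrow = length(genes), ncol = n,
                dimnames = list(genes, paste0("s", seq_len(n))))
    m
  }
  list(transcript = draw(1), protein = draw(config$protein_scale),
       absent_genes = intersect(genes, config$absent_genes))
}

#' Simulate a targeted-metabolomics table
#'
#' Log-normal absolute abundances for two groups (`A` gets the planted fold
#' changes, `B` is the reference), `n_replicates` samples per group. The
#' default metabolite panel includes the adenylates and the TCA intermediates
#' used by the index statistics. Fully determined by `config$seed`.
#'
#' @param config a [toy_scenario_config()].
#' @param group_labels labels for (effect, reference) groups.
#' @return A [metabolite_table()].
#' @export
simulate_metabolomics <- function(config, group_labels = c("A", "B")) {
  stopifnot(inherits(config, "toy_scenario_config"), length(group_labels) == 2)
  effects <- config$effects
  if (length(effects) == 0) stop("effect map must be non-empty")
  unknown <- setdiff(names(effects), names(config$base_abundance))
  if (length(unknown)) {
    stop("effects reference unknown metabolite(s): ", paste(unknown, collapse = ", "))
  }
  set.seed(config$seed + 1L)   # distinct stream from simulate_expression
  mets <- names(config$base_abundance)
  n <- config$n_replicates
  fold <- setNames(rep(1, length(mets)), mets)
  fold[names(effects)] <- unlist(effects)
  if (any(fold <= 0)) stop("fold-change effects must be positive")
  one_group <- function(mult, prefix) {
    m <- matrix(rlnorm(length(mets) * n,
                       meanlog = rep(log(config$base_abundance * mult), n),
                       sdlog = config$sigma),
                nrow = length(mets),
                dimnames = list(mets, paste0(prefix, seq_len(n))))
    m
  }
  ab <- cbind(one_group(fold, paste0(group_labels[1], "_")),
              one_group(1, paste0(group_labels[2], "_")))
  metabolite_table(ab, rep(group_labels, each = n))
}
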