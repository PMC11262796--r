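# End-to-end orchestration: reconstruction -> control sampling -> constrained
# pair -> constrained sampling -> comparison -> metabolite statistics, with
# every intermediate artifact written to a run directory as tab-separated
# UTF-8 text plus a JSON manifest (settings, theoretical maxima, checksums).
# A mandatory seed makes reruns byte-identical.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  path
}

write_samples_tsv <- function(samples, path) {
  df <- as.data.frame(samples$draws)
  write_tsv(df, path)
  meta <- data.frame(key = c("seed", "warmup", "thinning", "n_chains", "n"),
                     value = c(samples$seed, samples$warmup, samples$thinning,
                               samples$n_chains, nrow(samples$draws)))
  write_tsv(meta, sub("\\.tsv$", "_meta.tsv", path))
  path
}

default_run_config <- function() {
  list(
    seed = NULL,
    out_dir = NULL,
    scenario = "toy",             # "toy" or paths below
    base_model = NULL,            # native-model directory or SBML file
    transcripts = NULL,           # named list: one table path per context
    proteins = NULL,
    metabolomics = NULL,          # abundance tsv + groups in header via group_map
    contexts = c("A", "B"),
    transcript_cutoff = 5,
    protein_cutoff = 2000,
    protected_reactions = c("ATPS", "CS", "GLYC"),
    capacity_epsilon = 1e-6,
    ci_id = "CI_toy",
    o2_id = "O2tm_toy",
    f_hi = 0.7,
    f_lo = 0.3,
    sampler = list(n = 2000, warmup = 500, n_chains = 2, thinning = NULL),
    overlap_threshold = 0.2,
    shift_threshold = 1.0,
    ratio_pairs = list(c("succinate", "fumarate"), c("citrate", "succinate"),
                       c("fumarate", "malate")))
}

load_expression_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  m
}

#' Validate and normalize a pipeline run configuration
#'
#' Fills defaults, then checks the invariants a run depends on: a seed is
#' mandatory, referenced files must exist, and fractions must be usable.
#'
#' @param config named list (or YAML file path) overriding the defaults; see
#'   [run_full()] for the recognized keys.
#' @return The completed configuration list.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cfg <- modifyList(default_run_config(), config)
  if (is.null(cfg$seed)) stop("config validation error: seed is mandatory")
  cfg$seed <- as.integer(cfg$seed)
  if (is.null(cfg$out_dir)) stop("config validation error: out_dir is required")
  if (!(cfg$f_hi > 0 && cfg$f_hi <= 1 && cfg$f_lo > 0 && cfg$f_lo <= 1)) {
    stop("config validation error: fractions must lie in (0, 1]")
  }
  if (!identical(cfg$scenario, "toy")) {
    paths <- c(cfg$base_model, unlist(cfg$transcripts), unlist(cfg$proteins),
               cfg$metabolomics)
    missing_p <- paths[!file.exists(paths)]
    if (length(missing_p)) {
      stop("config validation error: missing input file(s): ",
           paste(missing_p, collapse = ", "))
    }
  }
  cfg
}

#' Run the full comparative flux pipeline
#'
#' Executes every stage against one configuration: build or read the base
#' model; call presence from transcript and protein tables per context; prune
#' to context-specific models; sample both models unconstrained (control
#' simulation); build the constrained pair (high Complex I / low O2 in
#' context A, mirrored in B) and sample again; compare per-reaction flux
#' distributions for both simulations; and, when a metabolite table is
#' available, compute the metabolomic index statistics. All artifacts land in
#' `config$out_dir` with a JSON manifest.
#'
#' With `scenario = "toy"` (default) the inputs are generated by the
#' synthetic-data layer from the same seed, which makes the run self
#' contained.
#'
#' @param config named list or YAML path; see [validate_run_config()]. Keys:
#'   `seed` (mandatory), `out_dir`, `scenario`, `base_model`, `transcripts`,
#'   `proteins`, `metabolomics`, presence cutoffs, `protected_reactions`,
#'   `ci_id`/`o2_id`/`f_hi`/`f_lo`, `sampler` (n, warmup, n_chains,
#'   thinning), comparison thresholds, `ratio_pairs`.
#' @return The run directory path, invisibly; artifacts and `manifest.json`
#'   inside.
#' @export
run_full <- function(config) {
  cfg <- validate_run_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("fluxcontrast %s | R %s",
                         as.character(utils::packageVersion("fluxcontrast")),
                         paste(R.version$major, R.version$minor, sep = ".")),
                 sprintf("seed: %d", cfg$seed))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # --- inputs -----------------------------------------------------------
  if (identical(cfg$scenario, "toy")) {
    base <- stage("inputs", build_toy_network())
    scen <- toy_scenario_config(seed = cfg$seed, f_hi = cfg$f_hi, f_lo = cfg$f_lo)
    omics_a <- stage("inputs", simulate_expression(base, scen))
    # context B: same platform noise, nothing planted absent
    scen_b <- toy_scenario_config(seed = cfg$seed + 1000L,
                                  absent_genes = character())
    omics_b <- stage("inputs", simulate_expression(base, scen_b))
    expr_tabs <- list(A = omics_a, B = omics_b)
    met_tab <- stage("inputs", simulate_metabolomics(scen))
  } else {
    base <- stage("inputs", if (grepl("\\.(xml|sbml)$", cfg$base_model))
      read_sbml(cfg$base_model) else read_native_model(cfg$base_model))
    expr_tabs <- lapply(setNames(cfg$contexts, cfg$contexts), function(ctx) {
      list(transcript = load_expression_table(cfg$transcripts[[ctx]]),
           protein = load_expression_table(cfg$proteins[[ctx]]))
    })
    met_tab <- if (!is.null(cfg$metabolomics)) {
      df <- read.delim(cfg$metabolomics, stringsAsFactors = FALSE)
      m2 <- as.matrix(df[, -1, drop = FALSE])
      rownames(m2) <- df[[1]]
      # sample columns are named <group>_<replicate>
      metabolite_table(m2, sub("_.*$", "", colnames(m2)))
    } else NULL
  }
  write_native_model(base, file.path(out, "base_model"))
  log_lines <- c(log_lines, sprintf("base model: %d reactions, %d metabolites",
                                    nrow(base$reactions), nrow(base$metabolites)))

  # --- reconstruction ---------------------------------------------------
  contexts <- names(expr_tabs)
  models <- list(); calls_list <- list()
  for (ctx in contexts) {
    tr <- call_presence(expr_tabs[[ctx]]$transcript, "transcript",
                        cutoff = cfg$transcript_cutoff)
    pr <- call_presence(expr_tabs[[ctx]]$protein, "protein",
                        cutoff = cfg$protein_cutoff)
    merged <- merge_presence(tr, pr)
    calls_list[[ctx]] <- merged
    pruned <- stage("reconstruction",
                    prune_model(base, merged, cfg$protected_reactions,
                                cfg$capacity_epsilon))
    models[[ctx]] <- pruned$model
    models[[ctx]]$id <- paste0(base$id, "_", ctx)
    write_tsv(pruned$log, file.path(out, sprintf("prune_log_%s.tsv", ctx)))
    write_tsv(data.frame(gene = names(merged$calls), call = unname(merged$calls)),
              file.path(out, sprintf("presence_%s.tsv", ctx)))
    write_native_model(models[[ctx]], file.path(out, sprintf("model_%s", ctx)))
    log_lines <- c(log_lines,
                   sprintf("context %s: %d reactions retained (%d removed)",
                           ctx, nrow(models[[ctx]]$reactions),
                           sum(pruned$log$action == "removed")))
  }

  # --- control simulation ----------------------------------------------
  sp <- cfg$sampler
  sampler_args <- function(extra_seed) {
    list(n = sp$n, seed = cfg$seed + extra_seed, warmup = sp$warmup,
         thinning = sp$thinning, n_chains = sp$n_chains)
  }
  ctl <- list(
    A = stage("control_sampling", do.call(sample_fluxes,
              c(list(models[[1]]), sampler_args(1L)))),
    B = stage("control_sampling", do.call(sample_fluxes,
              c(list(models[[2]]), sampler_args(2L)))))
  write_samples_tsv(ctl$A, file.path(out, "samples_control_A.tsv"))
  write_samples_tsv(ctl$B, file.path(out, "samples_control_B.tsv"))

  # --- constrained pair + simulation ------------------------------------
  pair <- stage("constraints",
                build_constrained_pair(models[[1]], models[[2]],
                                       ci_id = cfg$ci_id, o2_id = cfg$o2_id,
                                       f_hi = cfg$f_hi, f_lo = cfg$f_lo))
  write_tsv(pair$maxima, file.path(out, "theoretical_maxima.tsv"))
  log_lines <- c(log_lines, sprintf(
    "theoretical maxima: %s",
    paste(sprintf("%s[%s]=%.6g", pair$maxima$reaction, pair$maxima$model,
                  pair$maxima$max), collapse = ", ")))
  con <- list(
    A = stage("constrained_sampling", do.call(sample_fluxes,
              c(list(pair$a), sampler_args(3L)))),
    B = stage("constrained_sampling", do.call(sample_fluxes,
              c(list(pair$b), sampler_args(4L)))))
  write_samples_tsv(con$A, file.path(out, "samples_constrained_A.tsv"))
  write_samples_tsv(con$B, file.path(out, "samples_constrained_B.tsv"))

  # --- comparison -------------------------------------------------------
  rep_ctl <- stage("comparison",
                   compare_distributions(ctl$A, ctl$B,
                                         shift_threshold = cfg$shift_threshold,
                                         overlap_threshold = cfg$overlap_threshold))
  rep_con <- stage("comparison",
                   compare_distributions(con$A, con$B,
                                         shift_threshold = cfg$shift_threshold,
                                         overlap_threshold = cfg$overlap_threshold))
  write_tsv(rep_ctl, file.path(out, "shift_report_control.tsv"))
  write_tsv(rep_con, file.path(out, "shift_report_constrained.tsv"))
  reversed <- flag_reversed_reactions(rep_con)
  write_tsv(data.frame(reaction = reversed), file.path(out, "reversed_reactions.tsv"))
  log_lines <- c(log_lines,
                 sprintf("constrained simulation: %d shifted, reversed: %s",
                         sum(rep_con$shifted),
                         if (length(reversed)) paste(reversed, collapse = ", ")
                         else "<none>"))

  # --- metabolite statistics -------------------------------------------
  if (!is.null(met_tab)) {
    ratio_rows <- lapply(cfg$ratio_pairs, function(pr) {
      rs <- intra_sample_ratio(met_tab, pr[1], pr[2])
      lv <- names(rs$mean)
      data.frame(numerator = pr[1], denominator = pr[2],
                 mean_1 = rs$mean[[1]], sd_1 = rs$sd[[1]],
                 mean_2 = rs$mean[[2]], sd_2 = rs$sd[[2]],
                 t = rs$t, p = rs$p, stringsAsFactors = FALSE)
    })
    ratios <- do.call(rbind, ratio_rows)
    ratios$q <- bh_with_na(ratios$p)    # one family: the ratio panel
    write_tsv(ratios, file.path(out, "metabolite_ratios.tsv"))
    energy <- adenylate_indices(met_tab)
    write_tsv(energy$summary, file.path(out, "adenylate_indices.tsv"))
    fc <- fold_changes(met_tab)
    write_tsv(fc, file.path(out, "fold_changes.tsv"))
    log_lines <- c(log_lines, "metabolite statistics: written")
  } else {
    log_lines <- c(log_lines, "metabolite statistics: no input table (skipped)")
  }

  # --- manifest ---------------------------------------------------------
  files <- sort(setdiff(list.files(out, recursive = TRUE),
                        c("manifest.json", "run_log.txt")))
  manifest <- list(
    package_version = as.character(utils::packageVersion("fluxcontrast")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "out_dir")],
    theoretical_maxima = pair$maxima,
    files = data.frame(
      file = files,
      md5 = unname(tools::md5sum(file.path(out, files))),
      stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out, "run_log.txt"))
  invisible(out)
}

#' Render report tables from a completed run
#'
#' Reads the artifacts of a [run_full()] directory and writes a `report/`
#' subdirectory: per-reaction histogram data (control and constrained, both
#' models) for the electron-transport reactions plus any reversed reactions,
#' and a plain-text summary. Regeneration is idempotent: no values are
#' computed that the run artifacts do not already contain, beyond binning.
#'
#' @param run_dir directory produced by [run_full()].
#' @param reactions reactions to render histograms for; defaults to the
#'   constrained-report reactions flagged shifted plus the reversed set.
#' @param n_bins histogram bins.
#' @return The report directory path, invisibly.
#' @export
render_report <- function(run_dir, reactions = NULL, n_bins = 30) {
  need <- c("shift_report_constrained.tsv", "shift_report_control.tsv",
            "reversed_reactions.tsv", "samples_constrained_A.tsv",
            "samples_constrained_B.tsv", "manifest.json")
  missing_f <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing_f)) {
    stop("incomplete run; missing artifact(s): ", paste(missing_f, collapse = ", "))
  }
  rep_con <- read.delim(file.path(run_dir, "shift_report_constrained.tsv"))
  reversed <- read.delim(file.path(run_dir, "reversed_reactions.tsv"))$reaction
  if (is.null(reactions)) {
    reactions <- union(rep_con$reaction[rep_con$shifted], reversed)
  }
  rdir <- file.path(run_dir, "report")
  dir.create(rdir, showWarnings = FALSE)
  read_samples <- function(f) as.matrix(read.delim(file.path(run_dir, f)))
  sets <- list(constrained_A = read_samples("samples_constrained_A.tsv"),
               constrained_B = read_samples("samples_constrained_B.tsv"))
  for (f in c("samples_control_A.tsv", "samples_control_B.tsv")) {
    if (file.exists(file.path(run_dir, f))) {
      sets[[sub("samples_(.*)\\.tsv", "\\1", f)]] <- read_samples(f)
    }
  }
  for (rid in reactions) {
    rows <- list()
    for (nm in names(sets)) {
      V <- sets[[nm]]
      if (!(rid %in% colnames(V))) next
      x <- V[, rid]
      rng <- range(x)
      if (diff(rng) < 1e-12) {
        rows[[nm]] <- data.frame(set = nm, mid = rng[1], freq = 1)
      } else {
        edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
        cnt <- hist(x, breaks = edges, plot = FALSE)$counts
        rows[[nm]] <- data.frame(set = nm,
                                 mid = (edges[-1] + edges[-length(edges)]) / 2,
                                 freq = cnt / length(x))
      }
    }
    write_tsv(do.call(rbind, rows),
              file.path(rdir, sprintf("histogram_%s.tsv", rid)))
  }
  summary_lines <- c(
    sprintf("reactions shifted (constrained simulation): %d", sum(rep_con$shifted)),
    sprintf("reactions reversed (A negative, B non-negative): %s",
            if (length(reversed)) paste(reversed, collapse = ", ") else "<none>"),
    if (file.exists(file.path(run_dir, "metabolite_ratios.tsv")))
      "metabolite statistics: metabolite_ratios.tsv, adenylate_indices.tsv, fold_changes.tsv"
    else "metabolite statistics: absent (no input table)")
  writeLines(summary_lines, file.path(rdir, "summary.txt"))
  invisible(rdir)
}
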