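#!/usr/bin/env Rscript
# Stage 1: generate the study inputs. Builds the toy central-metabolism
# network (glycolysis, TCA loop with reversible SDH, ETC complexes, ATP
# synthase, O2 transport) and simulates the omics layers for two contexts:
# context A carries planted absent genes (lactate branch + ATP synthase) and
# the ischemia-like metabolite profile (5x succinate, low ATP, high AMP);
# context B is the unmodified reference. Everything is derived from one seed.

suppressPackageStartupMessages(library(fluxcontrast))

seed <- 17L
out <- "results/analysis/01_inputs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

toy <- build_toy_network()      # build-time verification on
message(sprintf("toy network: %d reactions, %d metabolites; capacity ok",
                nrow(toy$reactions), nrow(toy$metabolites)))
write_native_model(toy, file.path(out, "base_model"))

cfg_a <- toy_scenario_config(seed = seed)
cfg_b <- toy_scenario_config(seed = seed + 1000L, absent_genes = character())
omics_a <- simulate_expression(toy, cfg_a)
omics_b <- simulate_expression(toy, cfg_b)
for (ctx in c("A", "B")) {
  om <- if (ctx == "A") omics_a else omics_b
  for (platform in c("transcript", "protein")) {
    df <- data.frame(gene = rownames(om[[platform]]), om[[platform]])
    write.table(df, file.path(out, sprintf("%s_%s.tsv", platform, ctx)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
}
message(sprintf("context A planted absent genes: %s",
                paste(omics_a$absent_genes, collapse = ", ")))

met <- simulate_metabolomics(cfg_a)
df <- data.frame(metabolite = rownames(met$abundances), met$abundances)
write.table(df, file.path(out, "metabolomics.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(c(sprintf("seed\t%d", seed),
             sprintf("absent_genes\t%s", paste(omics_a$absent_genes,
                                               collapse = ","))),
           file.path(out, "ground_truth.tsv"))
message("inputs written to ", out)
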