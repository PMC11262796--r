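test_that("the toy network is the fixed 24-reaction construction", {
  toy <- build_toy_network()        # verify = TRUE runs the build-time checks
  expect_equal(nrow(toy$reactions), 24)
  expect_equal(nrow(toy$metabolites), 24)
  expect_true(all(c("CI_toy", "CII_toy", "CIII_toy", "CIV_toy", "O2tm_toy",
                    "ATPS", "ATPM", "GLYC", "CS") %in% toy$reactions$id))
  # designed feasible: ATP demand can carry flux
  expect_gt(maximize_flux(toy, "ATPM")$objective_value, 0)
  # SDH is the only reversible TCA step
  i <- match("CII_toy", toy$reactions$id)
  expect_equal(toy$reactions$lb[i], -1000)
  # one-gene GPRs throughout
  expect_equal(toy$reactions$gpr, paste0(toy$reactions$id, "_g"))
})

test_that("the constrained scenario admits reverse CII by construction", {
  toy <- build_toy_network(verify = FALSE)
  pair <- build_constrained_pair(toy, toy, ci_id = "CI_toy", o2_id = "O2tm_toy",
                                 f_hi = 0.7, f_lo = 0.3)
  cii <- flux_variability(pair$a, "CII_toy")
  expect_lt(cii$min, 0)
})

test_that("expression simulation separates absent from present genes", {
  toy <- build_toy_network(verify = FALSE)
  cfg <- toy_scenario_config(seed = 1, absent_genes = c("LDH_g", "ATPS_g"))
  sim <- simulate_expression(toy, cfg)
  expect_equal(dim(sim$transcript), c(24, 3))
  expect_equal(dim(sim$protein), c(24, 3))
  expect_setequal(sim$absent_genes, c("LDH_g", "ATPS_g"))
  # NB tails at the configured parameters: an absent gene (mean 1, size 10)
  # falls below the cutoff of 5 in any one replicate with probability
  # pnbinom(4, mu = 1, size = 10) > 0.996, so all three being below has
  # probability > 0.95 — check the analytic bound, then the realization
  p_below <- pnbinom(4, mu = 1, size = 10)
  expect_gt(p_below^3, 0.95)
  expect_true(all(sim$transcript["LDH_g", ] < 5))
  # present genes at mean 100 are essentially never called absent
  expect_lt(pnbinom(4, mu = 100, size = 10), 1e-6)
  expect_true(all(sim$transcript["GLYC_g", ] >= 5))

  sim2 <- simulate_expression(toy, cfg)
  expect_identical(sim, sim2)                        # seed-deterministic
  cfg2 <- toy_scenario_config(seed = 2, absent_genes = c("LDH_g", "ATPS_g"))
  expect_false(identical(sim$transcript, simulate_expression(toy, cfg2)$transcript))

  expect_error(simulate_expression(toy, toy_scenario_config(
    seed = 1, absent_genes = "not_a_gene")), "not in model")
  bad <- toy_scenario_config(seed = 1); bad$dispersion <- -1
  expect_error(simulate_expression(toy, bad), "negative-binomial")
})

test_that("metabolomics simulation plants group effects deterministically", {
  cfg <- toy_scenario_config(seed = 9)
  tab <- simulate_metabolomics(cfg)
  expect_s3_class(tab, "metabolite_table")
  expect_equal(dim(tab$abundances), c(9, 6))
  expect_identical(tab$abundances, simulate_metabolomics(cfg)$abundances)

  # a null effect map leaves fold changes near 1
  null_cfg <- toy_scenario_config(seed = 9, n_replicates = 30,
                                  effects = list(succinate = 1))
  fc <- fold_changes(simulate_metabolomics(null_cfg), "A")
  expect_true(all(abs(fc$fold_change - 1) < 0.15))

  bad <- toy_scenario_config(seed = 9); bad$effects <- list(succinate = -2)
  expect_error(simulate_metabolomics(bad), "positive")
  bad2 <- toy_scenario_config(seed = 9); bad2$effects <- list()
  expect_error(simulate_metabolomics(bad2), "non-empty")
})

test_that("config construction validates the separability invariant", {
  expect_error(toy_scenario_config(), "seed")
  expect_error(toy_scenario_config(seed = 1, mean_absent = 7), "cutoff")
  expect_error(toy_scenario_config(seed = 1, effects = list(ATP = 0)),
               "positive")
})

test_that("the full toy pipeline recovers the planted reversal", {
  # reduced single-seed smoke test of the whole chain; the multi-seed version
  # is the acceptance suite's job
  toy <- build_toy_network(verify = FALSE)
  cfg <- toy_scenario_config(seed = 3)
  sim <- simulate_expression(toy, cfg)
  calls <- merge_presence(call_presence(sim$transcript, "transcript"),
                          call_presence(sim$protein, "protein"))
  ctx <- prune_model(toy, calls)$model
  pair <- build_constrained_pair(ctx, toy, ci_id = "CI_toy", o2_id = "O2tm_toy")
  sa <- sample_fluxes(pair$a, n = 600, seed = 30, warmup = 200, n_chains = 2)
  sb <- sample_fluxes(pair$b, n = 600, seed = 31, warmup = 200, n_chains = 2)
  reversed <- flag_reversed_reactions(compare_distributions(sa, sb))
  expect_true("CII_toy" %in% reversed)
})
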