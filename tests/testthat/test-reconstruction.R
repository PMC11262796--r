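test_that("presence calling applies the majority-below-cutoff rule", {
  tab <- rbind(lowish = c(4, 3, 10),     # 2 of 3 below 5 -> absent
               expressed = c(6, 7, 8),   # none below -> present
               border = c(5, 5, 5))      # cutoff is strict '<': present
  colnames(tab) <- paste0("s", 1:3)
  pc <- call_presence(tab, "transcript")
  expect_equal(unname(pc$calls[c("lowish", "expressed", "border")]),
               c("absent", "present", "present"))
  expect_equal(pc$thresholds$cutoff, 5)
  expect_equal(pc$thresholds$k, 2)

  prot <- rbind(p1 = c(1500, 2500, 1800))
  colnames(prot) <- paste0("s", 1:3)
  expect_equal(unname(call_presence(prot, "protein")$calls), "absent")

  # majority rule generalizes: 3-of-4 needed at n = 4
  tab4 <- rbind(g = c(1, 1, 9, 9))
  colnames(tab4) <- paste0("s", 1:4)
  expect_equal(unname(call_presence(tab4, "transcript")$calls), "present")

  neg <- rbind(g = c(-1, 2, 3)); colnames(neg) <- paste0("s", 1:3)
  expect_error(call_presence(neg, "transcript"), "negative")
})

test_that("platform merge is absent-only-if-absent-everywhere-measured", {
  tr <- calls_from_vector(c(a = "absent", b = "absent", c = "unmeasured",
                            d = "present"))
  pr <- calls_from_vector(c(a = "present", b = "unmeasured", c = "unmeasured",
                            e = "absent"))
  merged <- merge_presence(tr, pr)
  expect_equal(unname(merged$calls[c("a", "b", "c", "d", "e")]),
               c("present",     # measured present on one platform wins
                 "absent",      # absent on the only measured platform
                 "unmeasured",  # measured nowhere
                 "present", "absent"))
})

test_that("pruning removes inactive reactions only while capacity survives", {
  toy <- build_toy_network(verify = FALSE)
  # LDH off the protected routes: removable; ATPS is a witness: must stay
  calls <- calls_from_vector(setNames(
    ifelse(model_genes(toy) %in% c("LDH_g", "ATPS_g"), "absent", "present"),
    model_genes(toy)))
  res <- prune_model(toy, calls)
  expect_false("LDH" %in% res$model$reactions$id)
  expect_true("ATPS" %in% res$model$reactions$id)
  log <- res$log
  expect_equal(log$action[log$reaction == "LDH"], "removed")
  expect_equal(log$action[log$reaction == "ATPS"], "retained_capacity")
  # every base reaction appears exactly once in the log
  expect_setequal(log$reaction, toy$reactions$id)
  expect_equal(anyDuplicated(log$reaction), 0)
  # context model is a subset and still has capacity
  expect_true(all(res$model$reactions$id %in% toy$reactions$id))
  expect_true(check_capacity(res$model))
  # no orphan metabolites survive
  expect_setequal(res$model$metabolites$id,
                  unique(res$model$stoichiometry$metabolite))
})

test_that("unknown GPR status never deletes a reaction", {
  toy <- build_toy_network(verify = FALSE)
  calls <- calls_from_vector(setNames(
    ifelse(model_genes(toy) == "LDH_g", "unmeasured", "present"),
    model_genes(toy)))
  res <- prune_model(toy, calls)
  expect_true("LDH" %in% res$model$reactions$id)
  expect_equal(res$log$action[res$log$reaction == "LDH"], "retained_active")
})

test_that("pruning is deterministic and its order sensitivity is reported", {
  toy <- build_toy_network(verify = FALSE)
  genes <- model_genes(toy)
  calls <- calls_from_vector(setNames(
    ifelse(genes %in% c("LDH_g", "LACt_g", "EX_lac_g"), "absent", "present"),
    genes))
  r1 <- prune_model(toy, calls)
  r2 <- prune_model(toy, calls)
  expect_identical(r1$log, r2$log)
  # the planted pool is interaction-free: no order sensitivity
  expect_length(prune_order_sensitivity(toy, calls), 0)
  # an alternative-route pair (both succinate sinks absent) is order-sensitive
  # in outcome terms: sequential pruning keeps exactly one of the two
  calls2 <- calls_from_vector(setNames(
    ifelse(genes %in% c("CII_toy_g", "SUCCt_g"), "absent", "present"), genes))
  res2 <- prune_model(toy, calls2)
  kept <- intersect(c("CII_toy", "SUCCt"), res2$model$reactions$id)
  expect_length(kept, 1)
})

test_that("pruning a base model without capacity errors before any removal", {
  toy <- build_toy_network(verify = FALSE)
  crippled <- remove_reactions(toy, "GLYC")
  calls <- calls_from_vector(setNames(rep("present", length(model_genes(toy))),
                                      model_genes(toy)))
  expect_error(prune_model(crippled, calls, protected_reactions =
                             c("ATPS", "CS", "GLYC")),
               "protected")
})

test_that("presence calling recovers planted absent genes from seeded counts", {
  toy <- build_toy_network(verify = FALSE)
  n_absent_true <- 0; n_absent_called <- 0
  n_present_true <- 0; n_present_miscalled <- 0
  for (seed in 1:20) {
    set.seed(seed)   # governs which pool genes are planted this round
    cfg <- toy_scenario_config(seed = seed,
                               absent_genes = sample(toy_absent_pool(), 2))
    sim <- simulate_expression(toy, cfg)
    tr <- call_presence(sim$transcript, "transcript")
    pr <- call_presence(sim$protein, "protein")
    merged <- merge_presence(tr, pr)
    truth_absent <- sim$absent_genes
    truth_present <- setdiff(model_genes(toy), truth_absent)
    n_absent_true <- n_absent_true + length(truth_absent)
    n_absent_called <- n_absent_called +
      sum(merged$calls[truth_absent] == "absent")
    n_present_true <- n_present_true + length(truth_present)
    n_present_miscalled <- n_present_miscalled +
      sum(merged$calls[truth_present] == "absent")
  }
  expect_gte(n_absent_called / n_absent_true, 0.95)
  expect_lte(n_present_miscalled / n_present_true, 0.02)
})
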