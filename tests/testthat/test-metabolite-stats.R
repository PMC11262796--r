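mk_table <- function(mat, groups) metabolite_table(mat, groups)

test_that("intra-sample ratios summarize within groups", {
  ab <- rbind(succinate = c(10, 12, 11, 2, 2, 2),
              fumarate = c(2, 2, 2, 2, 2, 2))
  colnames(ab) <- paste0("s", 1:6)
  tab <- mk_table(ab, rep(c("P", "W"), each = 3))
  rs <- intra_sample_ratio(tab, "succinate", "fumarate")
  expect_equal(unname(rs$mean["P"]), 5.5)    # mean of (5, 6, 5.5)
  expect_equal(unname(rs$mean["W"]), 1)
  expect_equal(unname(rs$ratios[1:3]), c(5, 6, 5.5))
  # identical numerator and denominator: all ratios 1, zero spread
  rs2 <- intra_sample_ratio(tab, "fumarate", "fumarate")
  expect_true(all(rs2$ratios == 1))
  expect_equal(unname(rs2$sd), c(0, 0))

  ab0 <- ab; ab0["fumarate", 4] <- 0
  expect_error(intra_sample_ratio(mk_table(ab0, rep(c("P", "W"), each = 3)),
                                  "succinate", "fumarate"), "s4")
  expect_error(intra_sample_ratio(tab, "succinate", "citrate"), "not in table")
})

test_that("ratios cancel per-sample normalization factors", {
  set.seed(8)
  ab <- matrix(rlnorm(4 * 6, log(20), 0.3), nrow = 4,
               dimnames = list(paste0("met", 1:4), paste0("s", 1:6)))
  groups <- rep(c("P", "W"), each = 3)
  r1 <- intra_sample_ratio(mk_table(ab, groups), "met1", "met2")
  scaled <- sweep(ab, 2, runif(6, 0.5, 2), `*`)   # per-sample scale factors
  r2 <- intra_sample_ratio(mk_table(scaled, groups), "met1", "met2")
  expect_equal(r1$ratios, r2$ratios, tolerance = 1e-12)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
})

test_that("the t statistic matches the Student equal-variance form", {
  ab <- rbind(m = c(5, 6, 7, 1, 2, 3), one = rep(1, 6))
  colnames(ab) <- paste0("s", 1:6)
  rs <- intra_sample_ratio(mk_table(ab, rep(c("P", "W"), each = 3)), "m", "one")
  ref <- t.test(c(5, 6, 7), c(1, 2, 3), var.equal = TRUE)
  expect_equal(rs$t, unname(ref$statistic))
  expect_equal(rs$p, ref$p.value)
})

test_that("adenylate indices implement the Atkinson definitions", {
  ab <- rbind(AMP = c(1, 1, 0, 1), ADP = c(1, 1, 0, 2), ATP = c(1, 1, 5, 4))
  colnames(ab) <- paste0("s", 1:4)
  tab <- mk_table(ab, c("P", "P", "W", "W"))
  res <- adenylate_indices(tab)
  ps <- res$per_sample
  expect_equal(unname(ps["energy_charge", 1]), 0.5)        # equal pools
  expect_equal(unname(ps["amp_fraction", 1]), 1 / 3)
  expect_equal(unname(ps["atp_adp_ratio", 1]), 1)
  expect_equal(unname(ps["energy_charge", 4]), 5 / 7)      # (4 + 0.5*2)/7
  expect_equal(unname(ps["energy_charge", 3]), 1)          # ADP = AMP = 0
  expect_equal(unname(ps["amp_fraction", 3]), 0)
  # q mirrors BH on the testable indices; untestable (constant/Inf) stay NA
  ok <- !is.na(res$summary$p)
  expect_equal(res$summary$q[ok], bh_adjust(res$summary$p[ok]))
  expect_true(all(is.na(res$summary$q[!ok])))
  ab0 <- ab; ab0[, 2] <- 0
  expect_error(adenylate_indices(mk_table(ab0, c("P", "P", "W", "W"))),
               "pool")
})

test_that("energy charge stays in [0, 1] over fuzzed inputs", {
  set.seed(31)
  for (i in 1:500) {
    amp <- runif(1, 0, 100); adp <- runif(1, 0, 100); atp <- runif(1, 0, 100)
    ec <- (atp + 0.5 * adp) / (atp + adp + amp)
    expect_gte(ec, 0); expect_lte(ec, 1)
  }
  # equality at 1 iff ADP = AMP = 0
  ab <- rbind(AMP = c(0, 0, 0, 0), ADP = c(0, 0, 0, 0), ATP = c(3, 4, 5, 6))
  colnames(ab) <- paste0("s", 1:4)
  res <- adenylate_indices(mk_table(ab, c("P", "P", "W", "W")))
  expect_true(all(res$per_sample["energy_charge", ] == 1))
})

test_that("fold changes are group-mean ratios with explicit zero flags", {
  ab <- rbind(a = c(2, 2, 4, 4), b = c(3, 3, 3, 3), z = c(1, 1, 0, 0))
  colnames(ab) <- paste0("s", 1:4)
  tab <- mk_table(ab, c("P", "P", "W", "W"))
  fc <- fold_changes(tab, numerator_group = "P")
  expect_equal(fc$fold_change[fc$metabolite == "a"], 0.5)
  expect_equal(fc$fold_change[fc$metabolite == "b"], 1)
  expect_true(fc$undefined[fc$metabolite == "z"])
  expect_true(is.na(fc$fold_change[fc$metabolite == "z"]))
  one_group <- mk_table(ab[, 1:2], c("P", "P"))
  expect_error(fold_changes(one_group), "two groups")
})

test_that("BH adjustment matches the brute-force step-up on random vectors", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  set.seed(77)
  for (i in 1:200) {
    p <- runif(sample(1:30, 1))
    if (i %% 5 == 0) p[sample(length(p), 1)] <- p[1]  # force ties sometimes
    q <- bh_adjust(p)
    expect_equal(q, bh_brute_force(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15) && all(q <= 1))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("pi-value ranking combines effect size and significance", {
  expect_equal(pi_value_rank(2, 0.01), 4)
  expect_equal(pi_value_rank(5, 1), 0)
  expect_equal(pi_value_rank(-1, 0.1), -1)
  # monotone decreasing in p for fixed positive lfc
  p <- c(0.5, 0.1, 0.01)
  expect_true(all(diff(pi_value_rank(rep(2, 3), p)) > 0))
  expect_error(pi_value_rank(1, 0), "floor")
})

test_that("planted metabolomic ratio effects are recovered within 10%", {
  # the 10% criterion needs the estimator SE below ~3% of the target; with
  # sigma = 0.1 the per-sample ratio SD is ~14%, so 20 replicates per group
  # put the band beyond 3 standard errors (see the methods vignette)
  hits <- 0
  for (seed in 1:100) {
    cfg <- toy_scenario_config(seed = seed, n_replicates = 20,
                               effects = list(succinate = 5))
    tab <- simulate_metabolomics(cfg)
    rs <- intra_sample_ratio(tab, "succinate", "fumarate")
    if (abs(rs$mean[["A"]] - 5) / 5 <= 0.10) hits <- hits + 1
  }
  expect_gte(hits, 95)
})
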