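test_that("fractional bounds apply the 70%/30% arithmetic", {
  m <- chain_model(u1 = 10, u2 = 1000, u3 = 10)   # max through AB = 10
  lo <- apply_fraction_bound(m, "AB", "lower", 0.7)
  expect_equal(lo$reactions$lb[match("AB", lo$reactions$id)], 7)
  expect_equal(lo$reactions$ub[match("AB", lo$reactions$id)], 1000)
  hi <- apply_fraction_bound(m, "AB", "upper", 0.3)
  expect_equal(hi$reactions$ub[match("AB", hi$reactions$id)], 3)
  # a contradictory pre-existing bound on the reaction triggers an error
  floored <- set_bounds(m, "AB", lb = 4)           # ub := 0.3 * 10 = 3 < lb
  expect_error(apply_fraction_bound(floored, "AB", "upper", 0.3),
               "cross|nfeasible")
  # non-positive maxima make the fraction undefined
  dead <- set_bounds(m, "AB", ub = 0)
  expect_error(apply_fraction_bound(dead, "AB", "lower", 0.7), "<= 0")
})

test_that("the constrained pair mirrors bounds and checks the O2 ordering", {
  toy <- build_toy_network(verify = FALSE)
  pair <- build_constrained_pair(toy, toy, ci_id = "CI_toy", o2_id = "O2tm_toy")
  max_ci <- pair$maxima$max[pair$maxima$reaction == "CI_toy"][1]
  max_o2 <- pair$maxima$max[pair$maxima$reaction == "O2tm_toy"][1]
  ra <- pair$a$reactions; rb <- pair$b$reactions
  expect_equal(ra$lb[match("CI_toy", ra$id)], 0.7 * max_ci)
  expect_equal(ra$ub[match("O2tm_toy", ra$id)], 0.3 * max_o2)
  expect_equal(rb$ub[match("CI_toy", rb$id)], 0.3 * max_ci)
  expect_equal(rb$lb[match("O2tm_toy", rb$id)], 0.7 * max_o2)
  # both constrained models remain feasible with capacity
  expect_true(check_capacity(pair$a))
  expect_true(check_capacity(pair$b))
  # symmetric fractions break the strict O2 ordering
  expect_error(build_constrained_pair(toy, toy, ci_id = "CI_toy",
                                      o2_id = "O2tm_toy",
                                      f_hi = 0.5, f_lo = 0.5),
               "ordering")
  expect_error(build_constrained_pair(toy, toy, ci_id = "CI_missing",
                                      o2_id = "O2tm_toy"), "absent")
})

test_that("identical sample sets produce no shifts; separation is flagged", {
  m <- simplex_model(3)
  s <- sample_fluxes(m, n = 800, seed = 31, warmup = 200, n_chains = 2)
  rep_same <- compare_distributions(s, s)
  expect_true(all(rep_same$overlap == 1))
  expect_false(any(rep_same$shifted))

  # constructed separation: all-negative vs all-positive for one reaction
  s2 <- s
  s2$draws[, "R1"] <- -s2$draws[, "R1"] - 1
  rep2 <- compare_distributions(s2, s)
  row <- rep2[rep2$reaction == "R1", ]
  expect_true(row$sign_flip)
  expect_equal(row$overlap, 0)
  expect_true(row$shifted)
  # sign_flip implies medians of opposite strict sign
  expect_lt(row$median_a * row$median_b, 0)
})

test_that("the overlap coefficient is symmetric and affine-invariant", {
  m <- simplex_model(3)
  sa <- sample_fluxes(m, n = 500, seed = 71, warmup = 200, n_chains = 2)
  sb <- sample_fluxes(m, n = 500, seed = 72, warmup = 200, n_chains = 2)
  r_ab <- compare_distributions(sa, sb)
  r_ba <- compare_distributions(sb, sa)
  expect_equal(r_ab$overlap, r_ba$overlap, tolerance = 1e-12)
  # common affine rescaling of both sets leaves the overlap unchanged
  sa2 <- sa; sb2 <- sb
  sa2$draws <- sa$draws * 3 + 2
  sb2$draws <- sb$draws * 3 + 2
  r_scaled <- compare_distributions(sa2, sb2)
  expect_equal(r_scaled$overlap, r_ab$overlap, tolerance = 1e-12)
})

test_that("the constrained toy scenario reverses Complex II", {
  toy <- build_toy_network(verify = FALSE)
  pair <- build_constrained_pair(toy, toy, ci_id = "CI_toy", o2_id = "O2tm_toy")
  sa <- sample_fluxes(pair$a, n = 800, seed = 55, warmup = 200, n_chains = 2)
  sb <- sample_fluxes(pair$b, n = 800, seed = 56, warmup = 200, n_chains = 2)
  rep <- compare_distributions(sa, sb)
  row <- rep[rep$reaction == "CII_toy", ]
  expect_true(row$shifted)
  expect_lt(row$median_a, 0)
  # the constrained-A median sits below the control median of the same model
  ctl <- sample_fluxes(toy, n = 800, seed = 57, warmup = 200, n_chains = 2)
  expect_lt(row$median_a, median(ctl$draws[, "CII_toy"]))
  reversed <- flag_reversed_reactions(rep)
  expect_true("CII_toy" %in% reversed)
})

test_that("reversal flags demand a strict negative-to-nonnegative pattern", {
  rep <- data.frame(
    reaction = c("up", "down", "both_pos"),
    median_a = c(-2, -3, 1), median_b = c(1, -0.5, 4),
    iqr_a = 1, iqr_b = 1, overlap = 0,
    sign_flip = c(TRUE, FALSE, FALSE),
    shifted = c(TRUE, TRUE, TRUE))
  expect_equal(flag_reversed_reactions(rep), "up")
  rep$shifted <- FALSE
  expect_length(flag_reversed_reactions(rep), 0)
})

test_that("the sensitivity sweep reports feasibility over the fraction grid", {
  toy <- build_toy_network(verify = FALSE)
  sweep <- constraint_sensitivity_sweep(
    toy, toy, "CII_toy", ci_id = "CI_toy", o2_id = "O2tm_toy",
    f_hi_grid = c(0.6, 0.7), f_lo_grid = c(0.3, 0.6))
  expect_equal(nrow(sweep), 4)
  hit <- sweep$f_hi == 0.7 & sweep$f_lo == 0.3
  expect_true(sweep$feasible[hit])
  expect_lt(sweep$max_a[hit], 0)     # reverse CII forced at the study fractions
  # f_lo >= f_hi breaks the O2 ordering: infeasible, reported not raised
  expect_false(any(sweep$feasible[sweep$f_lo >= sweep$f_hi]))
})
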