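test_that("model construction enforces the structural invariants", {
  m <- chain_model()
  expect_s3_class(m, "metabolic_model")
  expect_equal(nrow(m$reactions), 3)
  expect_equal(nrow(m$metabolites), 2)

  # duplicate reaction ids
  expect_error(
    make_model(c("R1", "R1"), c("-> A", "A ->"), lb = c(0, 0), ub = c(1, 1)),
    "duplicate reaction")
  # crossed bounds
  expect_error(
    make_model(c("R1", "R2"), c("-> A", "A ->"), lb = c(5, 0), ub = c(1, 1)),
    "lb > ub")
  # stoichiometry referencing an undeclared metabolite
  expect_error(
    metabolic_model(
      data.frame(id = "A", compartment = "c", name = "A"),
      data.frame(id = "R1", lb = 0, ub = 1, gpr = "", subsystem = ""),
      data.frame(reaction = "R1", metabolite = "ghost", coef = 1)),
    "undeclared metabolite")
})

test_that("stoichiometric matrix follows the sign convention", {
  m <- make_model(c("EX_A", "R", "EX_B"),
                  c("-> A", "2 A -> B", "B ->"),
                  lb = c(0, 0, 0), ub = c(10, 10, 10))
  S <- stoichiometric_matrix(m)
  expect_equal(dim(S), c(2, 3))
  expect_equal(S["A", "R"], -2)       # consumed with coefficient 2
  expect_equal(S["B", "R"], 1)
  expect_equal(unname(S[, "EX_A"]), c(1, 0))  # boundary source: single +1
  # exchange columns are single-signed
  expect_true(all(S[, "EX_A"] >= 0) || all(S[, "EX_A"] <= 0))
})

test_that("GPR evaluation implements three-valued AND/OR semantics", {
  calls <- calls_from_vector(c(g1 = "present", g2 = "absent", g3 = "unmeasured"))
  expect_equal(evaluate_gpr("g1 and g2", calls), "inactive")
  expect_equal(evaluate_gpr("g2 or g1", calls), "active")
  expect_equal(evaluate_gpr("", calls), "active")          # no gene dependency
  expect_equal(evaluate_gpr("g1 and g3", calls), "unknown")
  expect_equal(evaluate_gpr("g3 or g1", calls), "active")  # sibling resolves
  expect_equal(evaluate_gpr("g3 or g2", calls), "unknown")
  expect_equal(evaluate_gpr("(g1 and g2) or g1", calls), "active")
  # unknown genes missing from the call set behave as unmeasured
  expect_equal(evaluate_gpr("never_seen", calls), "unknown")
  expect_error(evaluate_gpr("g1 and", calls), "syntax")
  expect_error(evaluate_gpr("g1 g2", calls), "syntax")
  expect_error(evaluate_gpr("(g1 or g2", calls), "syntax")
})

test_that("GPR evaluation matches brute-force truth tables", {
  rules <- c("g1 and g2", "g1 or g2", "(g1 and g2) or (g3 and g4)",
             "g1 and (g2 or g3) and (g4 or (g5 and g6))",
             "((g1 or g2) and g3) or (g4 and (g5 or g6) and g7)")
  set.seed(101)
  for (rule in rules) {
    genes <- sort(unique(unlist(regmatches(rule, gregexpr("g[0-9]+", rule)))))
    k <- length(genes)
    for (bits in 0:(2^k - 1)) {
      vals <- as.logical(bitwAnd(bits, 2^(seq_len(k) - 1)))
      names(vals) <- genes
      calls <- calls_from_vector(setNames(ifelse(vals, "present", "absent"), genes))
      got <- evaluate_gpr(rule, calls)
      want <- if (gpr_truth_eval(rule, vals)) "active" else "inactive"
      expect_equal(got, want, info = sprintf("%s | %s", rule,
                                             paste(vals, collapse = ",")))
    }
  }
})

test_that("native tabular format round-trips a model exactly", {
  toy <- build_toy_network(verify = FALSE)
  dir <- withr::local_tempdir()
  write_native_model(toy, dir)
  back <- read_native_model(dir)
  expect_equal(back$reactions$id, toy$reactions$id)
  expect_equal(back$reactions$lb, toy$reactions$lb)
  expect_equal(back$reactions$ub, toy$reactions$ub)
  expect_equal(back$reactions$gpr, toy$reactions$gpr)
  expect_equal(stoichiometric_matrix(back), stoichiometric_matrix(toy))

  # empty GPR fields survive the round trip
  m <- chain_model()
  dir2 <- withr::local_tempdir()
  write_native_model(m, dir2)
  back2 <- read_native_model(dir2)
  expect_equal(back2$reactions$gpr, c("", "", ""))

  # missing bounds column is a parse error
  rx <- read.delim(file.path(dir2, "reactions.tsv"))
  rx$lb <- NULL
  write.table(rx, file.path(dir2, "reactions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_native_model(dir2), "missing column")
})

test_that("SBML level 3 + fbc files parse with bounds, GPR, boundary species", {
  f <- write_temp_sbml(sbml_l3_fbc_text())
  m <- read_sbml(f)
  expect_equal(nrow(m$reactions), 3)
  expect_equal(nrow(m$metabolites), 2)     # boundary species X_ext dropped
  i <- match("AB", m$reactions$id)
  expect_equal(m$reactions$lb[i], -25)
  expect_equal(m$reactions$ub[i], 1000)
  expect_equal(m$reactions$ub[match("EX_A", m$reactions$id)], 10)
  # fbc gene tree mapped to labels
  calls <- calls_from_vector(c(g1 = "present", g2 = "absent", g3 = "present"))
  expect_equal(evaluate_gpr(m$reactions$gpr[i], calls), "active")
  calls2 <- calls_from_vector(c(g1 = "present", g2 = "absent", g3 = "absent"))
  expect_equal(evaluate_gpr(m$reactions$gpr[i], calls2), "inactive")
  expect_match(paste(m$provenance, collapse = " "), "fbc")
  S <- stoichiometric_matrix(m)
  expect_equal(S["A", "AB"], -2)
})

test_that("SBML level 2 notes dialect parses with default bounds", {
  f <- write_temp_sbml(sbml_l2_notes_text())
  m <- read_sbml(f)
  i <- match("AB", m$reactions$id)
  expect_equal(m$reactions$lb[i], -1000)   # reversible default
  expect_equal(m$reactions$ub[i], 1000)
  expect_equal(m$reactions$lb[match("EX_B", m$reactions$id)], 0)  # irreversible
  expect_equal(m$reactions$ub[match("EX_A", m$reactions$id)], 8)  # kineticLaw
  expect_equal(sort(gpr_genes(parse_gpr(m$reactions$gpr[i]))),
               c("g1", "g2", "g3"))
  expect_match(paste(m$provenance, collapse = " "), "notes")
})

test_that("broken SBML is rejected with a useful message", {
  bad <- sub('species="B" stoichiometry="1" constant="true"',
             'species="GHOST" stoichiometry="1" constant="true"',
             sbml_l3_fbc_text())
  f <- write_temp_sbml(bad)
  expect_error(read_sbml(f), "GHOST")
  expect_error(read_sbml(tempfile()), "not found")
})

test_that("SBML -> native -> reread preserves structure and GPR truth table", {
  f <- write_temp_sbml(sbml_l3_fbc_text())
  m1 <- read_sbml(f)
  dir <- withr::local_tempdir()
  write_native_model(m1, dir)
  m2 <- read_native_model(dir)
  expect_equal(nrow(m2$reactions), nrow(m1$reactions))
  expect_equal(nrow(m2$metabolites), nrow(m1$metabolites))
  expect_equal(m2$reactions$lb, m1$reactions$lb)
  expect_equal(m2$reactions$ub, m1$reactions$ub)
  # GPR truth tables agree over all assignments
  genes <- c("g1", "g2", "g3")
  for (bits in 0:7) {
    vals <- as.logical(bitwAnd(bits, 2^(0:2)))
    calls <- calls_from_vector(setNames(ifelse(vals, "present", "absent"), genes))
    i1 <- match("AB", m1$reactions$id); i2 <- match("AB", m2$reactions$id)
    expect_equal(evaluate_gpr(m2$reactions$gpr[i2], calls),
                 evaluate_gpr(m1$reactions$gpr[i1], calls))
  }
})
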