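test_that("model constructor enforces structural invariants", {
  m <- tm1_model()
  expect_s3_class(m, "metabolic_model")
  expect_equal(n_reactions(m), 5)
  expect_equal(n_metabolites(m), 3)
  expect_equal(sum(m$reactions$is_exchange), 2)

  mets <- m$metabolites; rxns <- m$reactions; st <- m$stoichiometry
  expect_error(metabolic_model(rbind(mets, mets[1, ]), rxns, st),
               "duplicate metabolite")
  rx2 <- rbind(rxns, rxns[2, ])
  expect_error(metabolic_model(mets, rx2, st), "duplicate reaction")
  rx3 <- rxns; rx3$lower_bound[1] <- 50
  expect_error(metabolic_model(mets, rx3, st), "lower_bound > upper_bound")
  st2 <- st; st2$R_AB <- c(A = -1, Z = 1)
  expect_error(metabolic_model(mets, rxns, st2), "undeclared metabolites")
  st3 <- st; st3$R_AB <- numeric(0)
  expect_error(metabolic_model(mets, rxns, st3), "empty stoichiometry")
})

test_that("JSON round-trip reproduces the model exactly", {
  m <- tm1_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  m2 <- load_model(path, "json")
  expect_equal(m2$metabolites, m$metabolites)
  expect_equal(m2$reactions, m$reactions)
  expect_equal(m2$stoichiometry[names(m$stoichiometry)], m$stoichiometry)
  expect_setequal(m2$genes, m$genes)
})

test_that("SBML round-trip preserves network, bounds and GPR content", {
  m <- make_toy_model(3, 3)
  m$reactions$gpr[m$reactions$id == "R1_1"] <- "(g1 and g2) or g3"
  path <- withr::local_tempfile(fileext = ".xml")
  write_model_sbml(m, path)
  m2 <- load_model(path, "sbml")
  expect_equal(m2$metabolites$id, m$metabolites$id)
  expect_equal(m2$reactions$id, m$reactions$id)
  expect_equal(m2$reactions$lower_bound, m$reactions$lower_bound)
  expect_equal(m2$reactions$upper_bound, m$reactions$upper_bound)
  expect_equal(m2$reactions$pathway, m$reactions$pathway)
  expect_equal(m2$stoichiometry[names(m$stoichiometry)], m$stoichiometry)
  # GPR survives up to parenthesization
  ev <- function(g) evaluate_gpr(g, c(g1 = "high", g2 = "moderate",
                                      g3 = "low"))
  expect_equal(ev(m2$reactions$gpr[m2$reactions$id == "R1_1"]),
               ev("(g1 and g2) or g3"))
})

test_that("malformed SBML is rejected with a parse error", {
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines(c("<sbml><model><listOfSpecies>",
               '<species id="A" compartment="c"/>',
               "</listOfSpecies><listOfReactions>",
               '<reaction id="R1"><listOfReactants>',
               '<speciesReference species="GHOST"/>',
               "</listOfReactants></reaction>",
               "</listOfReactions></model></sbml>"), bad)
  expect_error(load_model(bad, "sbml"), "undeclared metabolites")
  empty <- withr::local_tempfile(fileext = ".xml")
  writeLines("<notsbml/>", empty)
  expect_error(load_model(empty, "sbml"), "model")
  expect_error(load_model("does-not-exist.xml"), "not found")
})

test_that("classic Level 2 SBML (kinetic-law bounds, note GPRs) is read", {
  l2 <- test_path("fixtures", "mini_recon_style_l2.xml")
  m <- load_model(l2, "sbml")
  expect_equal(n_metabolites(m), 4)
  expect_equal(n_reactions(m), 4)
  expect_equal(m$reactions$lower_bound[m$reactions$id == "R_HEX1"], 0)
  expect_equal(m$reactions$upper_bound[m$reactions$id == "R_HEX1"], 1000)
  expect_equal(m$reactions$lower_bound[m$reactions$id == "R_EX_glc"], -5)
  expect_equal(m$reactions$pathway[m$reactions$id == "R_HEX1"],
               "Glycolysis")
  expect_equal(evaluate_gpr(m$reactions$gpr[m$reactions$id == "R_HEX1"],
                            c(HGNC_4195 = "low", HGNC_4922 = "high")),
               "high")
  # boundary species do not enter the stoichiometry: exchanges detected
  expect_true(m$reactions$is_exchange[m$reactions$id == "R_EX_glc"])
})

test_that("cobrapy agrees with the SBML writer on network dimensions", {
  m <- make_toy_model(3, 2)
  path <- withr::local_tempfile(fileext = ".xml")
  write_model_sbml(m, path)
  cobra <- reticulate::import("cobra", convert = FALSE)
  cm <- cobra$io$read_sbml_model(path)
  expect_equal(reticulate::py_to_r(reticulate::py_len(cm$reactions)),
               n_reactions(m))
  expect_equal(reticulate::py_to_r(reticulate::py_len(cm$metabolites)),
               n_metabolites(m))
})

test_that("liver modifications add exactly biomass + two demands", {
  m <- tm1_model()
  m2 <- add_liver_modifications(m, glycogen_id = "glycogen_c",
                                apo_glycogenin_id = "apo_glycogenin_c")
  expect_equal(n_reactions(m2), n_reactions(m) + 3)
  expect_lte(n_metabolites(m2) - n_metabolites(m), 2)
  dm <- m2$reactions[m2$reactions$id == "DM_glycogen_c", ]
  expect_equal(dm$lower_bound, 0)  # irreversible sink
  expect_true(m2$reactions$is_exchange[m2$reactions$id == "DM_glycogen_c"])
  # applying twice collides on reaction ids
  expect_error(add_liver_modifications(m2), "already present")
  # existing species are reused, not duplicated
  m3 <- add_liver_modifications(m, glycogen_id = "A",
                                apo_glycogenin_id = "B")
  expect_equal(n_metabolites(m3), n_metabolites(m))
})

test_that("GPR evaluation follows min/max semantics", {
  expect_equal(evaluate_gpr("g1 and g2", c(g1 = "high", g2 = "low")), "low")
  expect_equal(evaluate_gpr("g1 or g2", c(g1 = "high", g2 = "low")), "high")
  expect_equal(
    evaluate_gpr("(g1 and g2) or g3",
                 c(g1 = "high", g2 = "moderate", g3 = "low")),
    "moderate")
  expect_equal(evaluate_gpr("", c(g1 = "high")), "moderate")
  expect_error(evaluate_gpr("g1 and gX", c(g1 = "high")), "gX")
  expect_error(parse_gpr("g1 and or g2"), "malformed")
  expect_error(parse_gpr("(g1 and g2"), "malformed")
})

test_that("GPR evaluation is monotone in every gene's state", {
  gprs <- c("g1 and g2", "g1 or g2", "(g1 and g2) or (g3 and g4)",
            "g1 and (g2 or g3) and g4")
  lv <- c("low", "moderate", "high")
  set.seed(42)
  for (gpr in gprs) {
    genes <- gpr_gene_ids(gpr)
    for (rep in 1:25) {
      st <- stats::setNames(sample(lv, length(genes), TRUE), genes)
      base <- evaluate_gpr(gpr, st)
      g <- sample(genes, 1)
      if (st[[g]] == "high") next
      st2 <- st
      st2[[g]] <- lv[match(st[[g]], lv) + 1]
      expect_gte(match(evaluate_gpr(gpr, st2), lv), match(base, lv))
    }
  }
})

test_that("reaction states map GPRs over the network", {
  m <- tm1_model()
  st <- reaction_expression_states(m, c(g1 = "high", g2 = "low",
                                        g3 = "high"))
  expect_equal(unname(st[c("R_AB", "R_AC", "R_BC", "EX_A", "EX_C")]),
               c("high", "low", "high", "moderate", "moderate"))
  st2 <- reaction_expression_states(
    m, c(g1 = "moderate", g2 = "moderate", g3 = "moderate"))
  expect_true(all(st2 == "moderate"))
  expect_warning(
    st3 <- reaction_expression_states(m, c(g1 = "high", g2 = "low")),
    "missing")
  expect_equal(unname(st3["R_BC"]), "moderate")
})
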