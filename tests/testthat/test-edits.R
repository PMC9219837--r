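test_that("edits apply in order without mutating the source model", {
  m <- build_mini_model("M1")
  edits <- list(
    model_edit("set_bounds", rxn = "UPT", ub = 6, label = "cap uptake"),
    model_edit("scale_bounds", rxn = "UPT", factor = 0.5, label = "halve"))
  m2 <- apply_edits(m, edits)
  expect_equal(m2$reactions[["UPT"]]$upper_bound, 3)
  expect_equal(m$reactions[["UPT"]]$upper_bound, 10)    # source untouched
  expect_true(gabaflux:::model_equal(m, apply_edits(m, list())))
})

test_that("deletion fixes bounds to zero and scaling has an inverse", {
  m <- core_wt()
  del <- apply_edits(m, model_edit("delete_reaction", rxn = "SUCOAS",
                                   label = "delta-sucCD"))
  expect_equal(del$reactions[["SUCOAS"]]$lower_bound, 0)
  expect_equal(del$reactions[["SUCOAS"]]$upper_bound, 0)
  expect_true("SUCOAS" %in% reaction_ids(del))   # retained for reporting

  sc <- apply_edits(m, list(
    model_edit("scale_bounds", rxn = "AKGDH", factor = 2),
    model_edit("scale_bounds", rxn = "AKGDH", factor = 0.5)))
  expect_true(gabaflux:::model_equal(m, sc))
})

test_that("edit errors carry the edit label", {
  m <- build_mini_model("M1")
  expect_error(
    apply_edits(m, model_edit("delete_reaction", rxn = "NOPE",
                              label = "delta-xyz")),
    "delta-xyz")
  expect_error(model_edit("set_bounds", label = "no payload"),
               "requires payload")
  expect_error(model_edit("add_reaction", reaction = "not a reaction"),
               "must be a reaction object")
})

test_that("deleting a reaction is equivalent to zero bounds for the
           optimum", {
  with_shunt <- build_core_model(core_model_params(include_gaba_shunt = TRUE))
  without <- build_core_model(core_model_params(include_gaba_shunt = FALSE))
  zeroed <- apply_edits(with_shunt, list(
    model_edit("delete_reaction", rxn = "ABTA"),
    model_edit("delete_reaction", rxn = "SSALDH")))
  expect_flux_equal(fba(zeroed)$objective_value,
                    fba(without)$objective_value)
})

test_that("set_medium applies uptake equalities, opens free exchanges and
           closes the rest to uptake", {
  m <- core_wt()
  med <- medium_spec(fixed_uptakes = c(EX_glc = 4.67),
                     free_exchanges = c("EX_o2", "EX_co2", "EX_nh3",
                                        "EX_h2o", "EX_pi", "EX_so3"),
                     keep = "EX_biomass")
  m2 <- set_medium(m, med)
  expect_equal(m2$reactions[["EX_glc"]]$lower_bound, -4.67)
  expect_equal(m2$reactions[["EX_glc"]]$upper_bound, -4.67)
  expect_equal(m2$reactions[["EX_o2"]]$lower_bound, -1000)
  expect_equal(m2$reactions[["EX_o2"]]$upper_bound, 1000)
  expect_error(set_medium(m, medium_spec(fixed_uptakes = c(EX_xyz = 1))),
               "EX_xyz")
  expect_error(medium_spec(fixed_uptakes = c(EX_glc = -1)), ">= 0")

  # no carbon in, no growth out
  m0 <- set_medium(m, medium_spec(fixed_uptakes = c(EX_glc = 0),
                                  free_exchanges = c("EX_o2", "EX_co2",
                                                     "EX_nh3", "EX_h2o",
                                                     "EX_pi", "EX_so3"),
                                  keep = "EX_biomass"))
  # zero maintenance is required for feasibility at zero carbon
  m0 <- set_bounds(m0, "ATPM", lb = 0)
  s <- fba(m0)
  expect_equal(s$status, "optimal")
  expect_flux_equal(s$objective_value, 0)
})

test_that("elemental balance checking flags corrupted coefficients and
           skips formula-free reactions", {
  m <- core_wt()
  bal <- check_mass_balance(m)
  expect_equal(nrow(bal$imbalanced), 0L)
  expect_equal(bal$skipped, "BIOMASS")   # biomass product has no formula

  bad <- m
  bad$reactions[["CS"]]$stoichiometry[["cit_c"]] <-
    bad$reactions[["CS"]]$stoichiometry[["cit_c"]] + 1
  balbad <- check_mass_balance(bad)
  expect_true("CS" %in% balbad$imbalanced$reaction)

  nofor <- build_mini_model("M1")
  baln <- check_mass_balance(nofor)
  expect_equal(nrow(baln$imbalanced), 0L)
  expect_setequal(baln$skipped, c("R_AB", "R_AC", "BIO"))
})

test_that("the GAD pathway addition installs exactly the decarboxylation,
           transport and exchange", {
  m <- core_wt()
  m2 <- add_gaba_pathway(m)
  expect_length(m2$reactions, length(m$reactions) + 3L)
  gad <- m2$reactions[[reaction_by_role(m2, "GAD")]]
  expect_equal(gad$stoichiometry[c("glu_c", "gaba_c", "co2_c")],
               c(glu_c = -1, gaba_c = 1, co2_c = 1))
  expect_lt(gad$lower_bound, 0)   # reversible decarboxylation
  expect_equal(reaction_by_role(m2, "GABA_EXPORT"), "EX_gaba")
  # all pre-existing reactions untouched
  for (id in reaction_ids(m))
    expect_identical(m2$reactions[[id]], m$reactions[[id]])
  expect_error(add_gaba_pathway(m2), "role GAD")
  expect_error(add_gaba_pathway(m, species_id_map(glu = "nope_c")),
               "cannot resolve")
  # no new elemental imbalance
  expect_equal(nrow(check_mass_balance(m2)$imbalanced), 0L)
})

test_that("the butyrolactam branch conserves the CoA moiety and exports", {
  m <- core_producer()
  m2 <- add_butyrolactam_pathway(m)
  act <- m2$reactions[[reaction_by_role(m2, "ACT")]]
  # CoA in as acetyl-CoA, out as free CoA: Z balance is zero
  bal <- gabaflux:::reaction_element_balance(
    act, lapply(m2$metabolites, function(x)
      if (is.null(x$formula)) NULL else parse_formula(x$formula)))
  expect_equal(unname(bal["Z"]), 0)
  expect_equal(nrow(check_mass_balance(m2)$imbalanced), 0L)

  # butyrolactam is exportable after the edit
  st <- pfba(m2, "EX_btl")
  expect_equal(st$status, "optimal")
  expect_gt(st$objective_value, 0)

  noacc <- build_mini_model("M1")
  expect_error(add_butyrolactam_pathway(noacc), "cannot resolve")
})
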