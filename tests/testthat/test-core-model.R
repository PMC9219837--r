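test_that("the core model is balanced, grows, and respects its flags", {
  core <- core_wt()
  bal <- check_mass_balance(core)
  expect_equal(nrow(bal$imbalanced), 0L)
  expect_gt(fba(core)$objective_value, 0)

  noshunt <- build_core_model(core_model_params(include_gaba_shunt = FALSE))
  expect_null(reaction_by_role(noshunt, "GABA_SHUNT_T", required = FALSE))
  expect_null(reaction_by_role(noshunt, "GABA_SHUNT_D", required = FALSE))
  noglx <- build_core_model(core_model_params(include_glyoxylate = FALSE))
  expect_null(reaction_by_role(noglx, "ACEA", required = FALSE))

  # glyoxylate reactions exist but are closed by default (glucose
  # repression); the activation flag opens them
  expect_equal(core$reactions[["ICL"]]$upper_bound, 0)
  act <- build_core_model(core_model_params(glyoxylate_active = TRUE))
  expect_gt(act$reactions[["ICL"]]$upper_bound, 0)
})

test_that("core model parameters are validated", {
  expect_error(core_model_params(biomass_stoich = c(g6p_c = 1)),
               "succinyl-CoA")
  bm <- c(g6p_c = 0.5, succoa_c = -1)
  expect_error(core_model_params(biomass_stoich = bm), ">= 0")
  expect_error(core_model_params(po_ratio = 0))
})

test_that("building is deterministic: equal params give byte-identical
           serializations", {
  p1 <- tempfile(fileext = ".json"); p2 <- tempfile(fileext = ".json")
  save_model(build_core_model(), p1)
  save_model(build_core_model(), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("the producer sanity suite holds on the core model", {
  core <- core_wt()
  prod <- core_producer()
  # growth and production are both possible
  expect_gt(fba(core)$objective_value, 0)
  y <- theoretical_max_yield(prod, "EX_gaba", "EX_glc")
  expect_gt(y$yield, 0)
  expect_lte(y$yield, 1.5)

  # sucCD deletion alone retains growth (AKGDH still feeds the
  # succinyl-CoA biomass demand; anaplerosis regenerates OAA)
  dsuc <- apply_edits(core, model_edit("delete_reaction", rxn = "SUCOAS",
                                       label = "delta-sucCD"))
  expect_gt(fba(dsuc)$objective_value, 0)

  # with glyoxylate and anaplerosis also blocked, no OAA-regeneration
  # route remains and growth collapses to zero
  dead <- apply_edits(core, list(
    model_edit("delete_reaction", rxn = "SUCOAS"),
    model_edit("delete_reaction", rxn = "ICL"),
    model_edit("delete_reaction", rxn = "MALS"),
    model_edit("delete_reaction", rxn = "PPC")))
  expect_flux_equal(growth_capacity(dead), 0)
  expect_gt(growth_capacity(dsuc), 0)

  # GAD knockout zeroes GABA export in any strain
  nogad <- apply_edits(prod, model_edit("delete_reaction", rxn = "GAD"))
  expect_flux_equal(pfba(nogad, "EX_gaba")$objective_value, 0)
})

test_that("mini fixtures carry machine-checkable expected properties", {
  for (nm in c("M1", "M1_product", "cycle", "akg_node")) {
    fx <- attr(build_mini_model(nm), "fixture_spec")
    expect_equal(fx$name, nm)
    for (p in fx$expected_properties) {
      expect_true(is.character(p$op))
      expect_true(is.numeric(p$tol) && p$tol > 0)
    }
  }
  expect_error(build_mini_model("nope"))
})

test_that("bound perturbation is seeded, bounded and structure-
           preserving", {
  m <- build_mini_model("M1_product")
  a <- perturb_model(m, seed = 42, magnitude = 0.2)
  b <- perturb_model(m, seed = 42, magnitude = 0.2)
  expect_true(gabaflux:::model_equal(a, b))
  expect_false(gabaflux:::model_equal(a, m))
  expect_true(gabaflux:::model_equal(m, perturb_model(m, 7, 0)))
  # stoichiometry untouched
  expect_identical(stoich_matrix(a), stoich_matrix(m))
  bd <- flux_bounds(a)
  expect_true(all(bd$lb <= bd$ub))
})
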