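test_that("FBA finds the forced optimum on M1 and reports solver states
           honestly", {
  m1 <- build_mini_model("M1")
  s <- fba(m1)
  expect_equal(s$status, "optimal")
  expect_flux_equal(s$objective_value, 5)      # conservation: equal split

  # no uptake, no growth, still optimal
  s0 <- fba(set_bounds(m1, "UPT", ub = 0))
  expect_equal(s0$status, "optimal")
  expect_flux_equal(s0$objective_value, 0)

  # conflicting equalities are infeasible, never silent zeros
  bad <- set_bounds(set_bounds(m1, "UPT", lb = 5, ub = 5),
                    "R_AB", lb = 6, ub = 6)
  expect_equal(fba(bad)$status, "infeasible")
  expect_true(is.na(fba(bad)$objective_value))

  # an unbounded objective is reported as such
  unb <- metabolic_model("unb", list(metabolite("A")), list(
    reaction("IN", c(A = 1), 0, Inf),
    reaction("OUT", c(A = -1), 0, Inf)), objective = c(OUT = 1))
  expect_equal(fba(unb)$status, "unbounded")
})

test_that("optimal states satisfy steady state and bounds on every model
           in the fixture suite", {
  models <- list(build_mini_model("M1"), build_mini_model("cycle"),
                 build_mini_model("akg_node"), core_wt(), core_producer(),
                 build_reduced_producer())
  for (m in models) {
    st <- fba(m)
    expect_equal(st$status, "optimal")
    S <- stoich_matrix(m)
    expect_lte(max(abs(S %*% st$fluxes)),
               1e-6 * max(1, max(abs(st$fluxes))))
    bd <- flux_bounds(m)
    expect_true(all(st$fluxes >= bd$lb - 1e-6))
    expect_true(all(st$fluxes <= bd$ub + 1e-6))
  }
})

test_that("both LP backends agree on the fixture suite", {
  for (nm in c("M1", "M1_product", "cycle", "akg_node")) {
    m <- build_mini_model(nm)
    expect_flux_equal(fba(m)$objective_value,
                      fba(m, backend = "boot")$objective_value)
  }
  red <- build_reduced_producer()
  expect_flux_equal(fba(red)$objective_value,
                    fba(red, backend = "boot")$objective_value)
})

test_that("pFBA preserves the optimum, minimizes total flux and silences
           isolated cycles", {
  m1 <- build_mini_model("M1")
  plain <- fba(m1)
  parsim <- pfba(m1)
  expect_flux_equal(parsim$objective_value, plain$objective_value)
  expect_lte(parsim$meta$total_flux, sum(abs(plain$fluxes)) + 1e-6)

  cyc <- build_mini_model("cycle")
  pc <- pfba(cyc)
  expect_flux_equal(pc$fluxes[["C1"]], 0)
  expect_flux_equal(pc$fluxes[["C2"]], 0)
  expect_flux_equal(pc$objective_value, fba(cyc)$objective_value)

  prod <- core_producer()
  expect_flux_equal(pfba(prod, "EX_gaba")$objective_value,
                    fba(prod, "EX_gaba")$objective_value)
})

test_that("FVA brackets contain the pFBA flux and expose undetermined
           cycles", {
  m1 <- build_mini_model("M1")
  fv <- fva(m1, objective_fraction = 1.0)
  p <- pfba(m1)
  expect_true(all(fv$min_flux <= p$fluxes[fv$reaction] + 1e-6))
  expect_true(all(fv$max_flux >= p$fluxes[fv$reaction] - 1e-6))
  # fully determined at the optimum
  expect_flux_equal(fv$min_flux[fv$reaction == "R_AB"], 5)
  expect_flux_equal(fv$max_flux[fv$reaction == "R_AB"], 5)
  expect_flux_equal(fv$min_flux[fv$reaction == "UPT"], 10)

  cyc <- build_mini_model("cycle")
  fc <- fva(cyc, reactions = "C1")
  expect_flux_equal(fc$min_flux, -1000)
  expect_flux_equal(fc$max_flux, 1000)
})

test_that("producer-mode optimization honors the biomass floor", {
  mp <- build_mini_model("M1_product")
  st <- production_fba(mp, production_constraint("EX_P", 0.2))
  expect_flux_equal(st$fluxes[["BIO"]], 1)     # 0.2 x 5
  expect_flux_equal(st$objective_value, 8)     # remaining 8 A to product
  expect_flux_equal(st$meta$mu_star, 5)

  # fraction 1: product equals its FVA max at optimal biomass
  s1 <- production_fba(mp, production_constraint("EX_P", 1.0))
  fv <- fva(mp, reactions = "EX_P", objective_fraction = 1.0)
  expect_flux_equal(s1$objective_value, fv$max_flux)

  # fraction 0: the constraint is vacuous
  s0 <- production_fba(mp, production_constraint("EX_P", 0))
  expect_flux_equal(s0$objective_value, 10)

  # degenerate floor
  dead <- set_bounds(mp, "UPT", ub = 0)
  expect_error(production_fba(dead, production_constraint("EX_P", 0.2)),
               "degenerate")
  expect_error(production_constraint("EX_P", 1.2))
})

test_that("product flux is non-increasing in the biomass fraction", {
  mp <- build_mini_model("M1_product")
  fr <- seq(0, 1, by = 0.1)
  prod <- vapply(fr, function(f)
    production_fba(mp, production_constraint("EX_P", f))$objective_value,
    0)
  expect_true(all(diff(prod) <= 1e-6))

  core <- core_producer()
  frc <- c(0, 0.25, 0.5, 0.75, 1)
  pc <- vapply(frc, function(f)
    production_fba(core, production_constraint("EX_gaba", f))$objective_value,
    0)
  expect_true(all(diff(pc) <= 1e-6))
})

test_that("uptake normalization divides by the absolute uptake and pins
           the uptake to one", {
  # split uptake of 4.67 with a capped branch of 2.335
  m <- metabolic_model("split", lapply(c("A", "B", "C"), metabolite), list(
    reaction("EX_A", c(A = 1), 4.67, 4.67),
    reaction("R_AB", c(A = -1, B = 1), 0, 2.335),
    reaction("R_AC", c(A = -1, C = 1), 0, 1000),
    reaction("EX_B", c(B = -1), 0, 1000),
    reaction("EX_C", c(C = -1), 0, 1000),
    reaction("R_0", c(B = -1, C = 1), 0, 1000)),
    objective = c(EX_B = 1))
  st <- pfba(m)
  expect_flux_equal(st$fluxes[["R_AB"]], 2.335)
  nz <- normalize_to_uptake(st, "EX_A")
  expect_equal(unname(nz[["R_AB"]]), 0.5)
  expect_identical(unname(nz[["EX_A"]]), 1.0)
  expect_equal(unname(nz[["R_0"]]), 0)

  z <- fba(set_bounds(m, "EX_A", lb = 0, ub = 0))
  expect_error(normalize_to_uptake(z, "EX_A"), "normalization error")
})

test_that("theoretical yields release the biomass floor and respect the
           carbon bound", {
  prod <- core_producer()
  y <- theoretical_max_yield(prod, "EX_gaba", "EX_glc")
  expect_gt(y$yield, 0)
  expect_lte(y$yield, 1.5)   # 6 C in glucose, 4 C in GABA

  # no product route, no yield
  cut <- apply_edits(prod, model_edit("delete_reaction", rxn = "GAD"))
  st <- pfba(cut, "EX_gaba")
  expect_flux_equal(st$objective_value, 0)
})

test_that("deleting any reaction never increases the optimum", {
  set.seed(42)
  for (m in list(build_mini_model("M1_product"), core_producer())) {
    base <- fba(m)$objective_value
    ids <- reaction_ids(m)
    for (id in sample(ids, min(8, length(ids)))) {
      del <- apply_edits(m, model_edit("delete_reaction", rxn = id))
      s <- fba(del)
      if (s$status == "optimal")
        expect_lte(s$objective_value, base + 1e-6)
    }
  }
})
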