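test_that("the multiplier scan anchors at k = 1 and matches the per-cell
           oracle on the reduced producer", {
  red <- build_reduced_producer()
  sc <- acn_scan(red)
  expect_equal(ncol(sc$delta_matrix), length(sc$spec$multipliers))
  expect_equal(sc$acn_reference, pfba(red, "BIO")$fluxes[["CSA"]])

  # consistency anchor: the k = 1 state equals an independent producer
  # run under the same equality constraint
  m1 <- set_bounds(red, "CSA", lb = sc$acn_reference,
                   ub = sc$acn_reference)
  anchor <- production_fba(m1, production_constraint("EX_gaba", 0.2))
  expect_flux_equal(sc$product_trace[1], anchor$objective_value)
  expect_lt(max(abs(sc$states[[1]]$fluxes - anchor$fluxes)), 1e-5)

  # every feasible cell agrees with the vertex oracle
  mu_star <- sc$states[[1]]$meta$mu_star
  for (i in seq_along(sc$spec$multipliers)) {
    k <- sc$spec$multipliers[i]
    cell <- set_bounds(set_bounds(red, "CSA", lb = k * sc$acn_reference,
                                  ub = k * sc$acn_reference),
                       "BIO", lb = 0.2 * mu_star)
    o <- oracle_solve(cell, objective = "EX_gaba")
    if (is.null(sc$states[[i]])) {
      expect_equal(o$status, "infeasible")
    } else {
      expect_flux_equal(sc$product_trace[i], o$objective_value)
    }
  }

  # over-forced aconitase flux recruits the GABA shunt
  shunt <- vapply(sc$states, function(s)
    if (is.null(s)) NA_real_ else s$fluxes[["SHUNT"]], 0)
  expect_gte(shunt[length(shunt)], shunt[1])
  expect_gt(shunt[length(shunt)], 0)

  # trace never exceeds the unconstrained theoretical maximum
  y <- theoretical_max_yield(red, "EX_gaba", "EX_glc")
  expect_true(all(sc$product_trace <= y$yield * 4.67 + 1e-6,
                  na.rm = TRUE))
  # deterministic tie-break: best multiplier attains the trace maximum
  expect_flux_equal(max(sc$product_trace, na.rm = TRUE),
                    sc$product_trace[match(sc$best_multiplier,
                                           sc$spec$multipliers)])
})

test_that("the scan records infeasible cells and rejects an undefined
           reference", {
  red <- build_reduced_producer()
  sc <- acn_scan(red, scan_spec(multipliers = c(1, 6)))
  expect_true(is.na(sc$product_trace[2]))
  expect_null(sc$states[[2]])
  expect_equal(sc$best_multiplier, 1)

  # aconitase silenced with glucose as a capacity: growth 0 is optimal,
  # so the reference flux is 0 and the scan must refuse
  dead <- set_bounds(set_bounds(red, "CSA", lb = 0, ub = 0),
                     "EX_glc", lb = -4.67, ub = 0)
  expect_error(acn_scan(dead), "reference undefined")
})

test_that("delta maps classify directions and reject mismatched
           universes", {
  st <- producer_state()
  self <- delta_map(st, st, "EX_glc")
  expect_true(all(self$direction == "unchanged"))
  expect_true(all(abs(self$delta_normalized) < 1e-12))

  # a reversible reaction driven in opposite directions is 'reversed'
  m <- metabolic_model("rev", lapply(c("A", "B"), metabolite), list(
    reaction("EX_A", c(A = 1), -10, 10),
    reaction("R", c(A = -1, B = 1), -10, 10),
    reaction("EX_B", c(B = -1), -10, 10)))
  fwd <- pfba(set_bounds(m, "EX_A", lb = 2, ub = 2), "EX_B")
  bwd <- pfba(set_bounds(m, "EX_B", lb = -2, ub = -2),
              c(EX_A = -1))
  dm <- delta_map(fwd, bwd, "EX_A")
  expect_equal(dm$direction[dm$reaction == "R"], "reversed")

  other <- pfba(build_mini_model("M1"))
  expect_error(delta_map(st, other, "EX_glc"), "universes")
})

test_that("the wild-type to producer comparison rewires the TCA entry
           upward", {
  dm <- delta_map(wt_state(), producer_state(), "EX_glc")
  expect_equal(dm$direction[dm$reaction == "CS"], "up")
  expect_equal(dm$direction[dm$reaction == "GAD"], "up")
  # EMP up, oxidative PPP down in the producer
  expect_equal(dm$direction[dm$reaction == "PGI"], "up")
  expect_equal(dm$direction[dm$reaction == "G6PDH"], "down")
})

test_that("node splits are direction-aware fractions that sum to one", {
  akg <- build_mini_model("akg_node")
  st <- production_fba(akg, production_constraint("EX_GABA", 0.2))
  ns <- node_split(st, akg, "AKG")
  expect_flux_equal(sum(ns), 1)
  expect_flux_equal(ns[["GDH_M"]], 0.9)   # hand-enumerable split
  expect_flux_equal(ns[["AKGDH_M"]], 0.1)

  # oracle cross-check of the underlying fluxes
  cell <- set_bounds(akg, "BIO", lb = 2)
  o <- oracle_solve(cell, objective = "EX_GABA")
  expect_flux_equal(o$fluxes[["GDH_M"]] /
                      (o$fluxes[["GDH_M"]] + o$fluxes[["AKGDH_M"]]), 0.9)

  # single consumer means fraction one
  m1 <- pfba(build_mini_model("M1"))
  expect_equal(unname(node_split(m1, build_mini_model("M1"), "B")), 1)
  # producer alpha-KG node on the core model
  core_ns <- node_split(producer_state(), core_producer(), "akg_c")
  expect_flux_equal(sum(core_ns), 1)
  expect_error(node_split(m1, build_mini_model("M1"), "nope"), "unknown")
  zero <- fba(set_bounds(build_mini_model("M1"), "UPT", ub = 0))
  expect_error(node_split(zero, build_mini_model("M1"), "B"),
               "undefined node")
})

test_that("the double-robustness surface is corner-peaked and masked
           where infeasible", {
  red <- build_reduced_producer()
  mu_star <- fba(red, "BIO")$objective_value
  surf <- double_robustness(red, "AKGDH",
                            growth_values = seq(0, mu_star, length.out = 6),
                            flux_values = seq(0, 1, length.out = 5))
  expect_equal(dim(surf$objective_matrix), c(6L, 5L))
  # global maximum at the zero-growth, zero-flux corner
  expect_flux_equal(surf$max_cell$growth, 0)
  expect_flux_equal(surf$max_cell$flux, 0)
  y <- theoretical_max_yield(red, "EX_gaba", "EX_glc")
  expect_flux_equal(surf$max_cell$product, y$yield * 4.67)

  # oracle agreement on two characteristic cells
  corner <- oracle_solve(set_bounds(set_bounds(red, "BIO", lb = 0, ub = 0),
                                    "AKGD", lb = 0, ub = 0),
                         objective = "EX_gaba")
  expect_flux_equal(surf$objective_matrix[1, 1], corner$objective_value)
  top <- oracle_solve(set_bounds(set_bounds(red, "BIO", lb = mu_star,
                                            ub = mu_star),
                                 "AKGD", lb = 0, ub = 0),
                      objective = "EX_gaba")
  expect_flux_equal(surf$objective_matrix[6, 1], top$objective_value)
  expect_flux_equal(top$objective_value, 0)  # biomass takes all carbon

  # monotone non-increasing along the growth axis at fixed flux
  for (j in seq_along(surf$flux_values)) {
    col <- surf$objective_matrix[, j]
    col <- col[!is.na(col)]
    expect_true(all(diff(col) <= 1e-6))
  }
})

test_that("the strain series evaluates every strain and records per-
           strain failures", {
  prod <- core_producer()
  wt <- wt_state()
  series <- load_strain_series(model = prod, reference_state = wt)
  expect_length(series, 9L)
  expect_error(strain_series(prod, series[c(1, 1)]), "unique")

  tab <- strain_series(prod, series)
  expect_equal(tab$label, c(paste0("GABA-", 1:6), paste0("BLM-", 1:3)))
  expect_true(all(tab$status == "optimal"))
  expect_true(all(tab$growth_max > 0))
  expect_true(all(tab$product_flux > 0))
  # sucCD deletion retains growth
  expect_gt(tab$growth_max[tab$label == "GABA-4"], 0)

  # a failing strain is recorded, the series continues
  broken <- c(series[1:2],
              list(strain_spec("broken",
                               list(model_edit("delete_reaction",
                                               rxn = "NOPE",
                                               label = "bad edit")))))
  tab2 <- strain_series(prod, broken)
  expect_match(tab2$status[3], "bad edit")
  expect_equal(tab2$status[1:2], c("optimal", "optimal"))
})

test_that("strain tables are identical across runs and backends on an
           oracle-scale model", {
  red <- build_reduced_producer()
  series <- list(
    strain_spec("base"),
    strain_spec("akgd-cap",
                list(model_edit("set_bounds", rxn = "AKGD", lb = 0,
                                ub = 0.5, label = "cap"))),
    strain_spec("no-shunt",
                list(model_edit("delete_reaction", rxn = "SHUNT",
                                label = "delta-shunt"))))
  pc <- production_constraint("EX_gaba", 0.2)
  t1 <- strain_series(red, series, pc)
  t2 <- strain_series(red, series, pc)
  expect_identical(t1, t2)
  t3 <- strain_series(red, series, pc, backend = "boot")
  expect_true(all(abs(t1$growth_max - t3$growth_max) < 1e-6))
  expect_true(all(abs(t1$product_flux - t3$product_flux) < 1e-6))
})
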