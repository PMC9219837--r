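test_that("OD600 converts to cell dry weight by the calibrated factor", {
  expect_equal(cdw_from_od(12), 3.24)
  expect_equal(cdw_from_od(0), 0)
  expect_equal(cdw_from_od(76.8), 20.736)
  expect_error(cdw_from_od(-1), "non-negative")
})

test_that("flux TSVs round-trip and are byte-deterministic", {
  st <- producer_state()
  p1 <- tempfile(fileext = ".tsv"); p2 <- tempfile(fileext = ".tsv")
  write_flux_tsv(st, p1)
  write_flux_tsv(st, p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- read_flux_tsv(p1)
  expect_equal(names(back), names(st$fluxes))
  # 6 significant digits survive the round trip
  expect_true(all(abs(back - st$fluxes) <=
                    1e-5 * pmax(1, abs(st$fluxes))))
})

test_that("scan TSVs carry direction classes and flag infeasible cells", {
  red <- build_reduced_producer()
  sc <- acn_scan(red, scan_spec(multipliers = c(1, 2, 6)))
  p <- tempfile(fileext = ".tsv")
  write_scan_tsv(sc, p)
  df <- read_flux_tsv(p)
  expect_setequal(unique(df$multiplier), c(1, 2, 6))
  expect_true(all(df$direction[df$multiplier == 6] == "infeasible"))
  expect_true(all(df$direction[df$multiplier != 6] %in%
                    c("up", "down", "unchanged", "reversed")))
})

test_that("surface TSVs keep the full grid with masked cells flagged", {
  red <- build_reduced_producer()
  surf <- double_robustness(red, "AKGDH",
                            growth_values = seq(0, 3.736, length.out = 4),
                            flux_values = c(0, 0.5, 1))
  p <- tempfile(fileext = ".tsv")
  write_surface_tsv(surf, p)
  lines <- readLines(p)
  expect_length(lines, 1L + 12L)
  df <- read_flux_tsv(p)
  expect_equal(sum(is.na(df$product)),
               sum(!surf$feasible_mask))
})

test_that("report bundles are deterministic, self-describing and
           readable by the package's own readers", {
  red <- build_reduced_producer()
  results <- list(
    producer = production_fba(red, production_constraint("EX_gaba", 0.2)),
    scan = acn_scan(red),
    strains = strain_series(red, list(strain_spec("base")),
                            production_constraint("EX_gaba", 0.2)))
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  cfg <- list(biomass_fraction = 0.2, multipliers = c(1, 1.5, 2, 2.5, 3))
  f1 <- write_report(results, d1, config = cfg)
  f2 <- write_report(results, d2, config = cfg)
  for (i in seq_along(f1))
    expect_identical(readLines(f1[i]), readLines(f2[i]))
  js <- jsonlite::read_json(file.path(d1, "summary.json"))
  expect_match(js$config_hash, "^[0-9a-f]{8}$")
  expect_equal(js$scan$best_multiplier, 2.5)
  for (p in grep("tsv$", f1, value = TRUE))
    expect_silent(read_flux_tsv(p))

  # empty strain series gives a header-only table
  empty <- strain_series(red, list(),
                         production_constraint("EX_gaba", 0.2))
  pe <- tempfile(fileext = ".tsv")
  write_flux_tsv(empty, pe)
  expect_length(readLines(pe), 1L)
})
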