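# Shared fixtures, built in code and memoized across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

core_wt <- function() cached("core_wt", build_core_model())

core_producer <- function() cached("core_producer",
                                   add_gaba_pathway(build_core_model()))

# wild-type flux distribution on the producer model (biomass objective;
# the GAD route is present but unused by the wild type), so WT and
# producer states share one reaction universe
wt_state <- function() cached("wt_state", pfba(core_producer(), "BIOMASS"))

producer_state <- function() cached("producer_state",
  production_fba(core_producer(),
                 production_constraint("EX_gaba", 0.2)))

# minimal 3-reaction JSON model written to a temp file
write_toy_json <- function(path = tempfile(fileext = ".json")) {
  doc <- list(
    id = "toy3",
    metabolites = list(
      list(id = "A", compartment = "c"),
      list(id = "B", compartment = "c"),
      list(id = "C", compartment = "c")),
    reactions = list(
      list(id = "R1", stoichiometry = list(A = 1), lower_bound = 0,
           upper_bound = 10),
      list(id = "R2", stoichiometry = list(A = -1, B = 1, C = 1)),
      list(id = "R3", stoichiometry = list(B = -1, C = -1))),
    objective = list(R3 = 1))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  path
}

expect_flux_equal <- function(a, b, tol = 1e-6) {
  expect_lt(abs(a - b), tol)
}
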