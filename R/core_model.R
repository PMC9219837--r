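## Synthetic core-carbon model of C. glutamicum.
##
## A ~35-reaction, carbon-balanced abstraction of central metabolism:
## PTS glucose uptake, EMP at 3-reaction resolution, a lumped oxidative PPP
## with non-oxidative return, PDH, the full TCA cycle (CS-ACN-ICD-AKGDH-
## SUCOAS-SDH-FUM-MDH), the glyoxylate shunt (closed by default: aceA/aceB
## are glucose-repressed in C. glutamicum and activate only as a bypass),
## PEP-carboxylase anaplerosis, NADPH-dependent glutamate dehydrogenase,
## the GABA shunt and GABA uptake, a lumped oxidative phosphorylation
## honoring a configurable P/O ratio, ATP maintenance, and a biomass
## reaction with an explicit succinyl-CoA demand.  The heterologous GAD
## route and the butyrolactam branch are added by add_gaba_pathway() /
## add_butyrolactam_pathway().
##
## Conventions: hydrogen is omitted from formulas (free protons are not
## modeled); CoA and the dinucleotide/adenosine carriers are tracked as
## pseudo-elements (Z, Nad, Ndp, Ad) so moiety conservation is checkable.
## Freely-diffusing small molecules (O2, CO2, NH3, Pi, H2O) live in a
## single compartment and exchange directly.

#' Parameters of the synthetic core model
#'
#' @param biomass_stoich Named vector of precursor demands (mmol per gCDW):
#'   must include a positive succinyl-CoA (`succoa_c`) coefficient plus
#'   OAA, glutamate, pyruvate, G6P- and pentose-level precursors, ATP and
#'   NADPH. Defaults are order-of-magnitude values (~46 mmol C/gCDW) with
#'   the alpha-ketoglutarate-derived demands sized so the wild-type TCA
#'   entry flux is a genuine bottleneck for production.
#' @param atp_maintenance Non-growth ATP demand, mmol/gCDW/h (lower bound
#'   on the maintenance reaction).
#' @param po_ratio ATP formed per NADH oxidized in the respiratory lump.
#' @param akgdh_max Flux capacity of the AKGDH complex, mmol/gCDW/h;
#'   the complex is tightly regulated (OdhA/OdhI) and is modeled with a
#'   finite capacity above the wild-type optimum.
#' @param include_glyoxylate Build the glyoxylate shunt reactions
#'   (closed, i.e. bounds (0,0), unless `glyoxylate_active`).
#' @param glyoxylate_active Open the glyoxylate shunt bounds (default
#'   `FALSE`: aceA/aceB are repressed during growth on glucose).
#' @param include_gaba_shunt Build the GABA shunt (gabT/gabD).
#' @param include_gaba_uptake Build the GABA uptake transporter (gabP).
#' @param glucose_uptake Fixed glucose uptake rate, mmol/gCDW/h.
#' @return A `core_model_params` object.
#' @export
core_model_params <- function(biomass_stoich = c(g6p_c = 0.55,
                                                 ru5p_c = 0.55,
                                                 pyr_c = 2.7,
                                                 accoa_c = 3.6,
                                                 oaa_c = 1.8,
                                                 glu_c = 2.8,
                                                 succoa_c = 0.85,
                                                 nh3_c = 6,
                                                 atp_c = 40,
                                                 nadph_c = 15),
                              atp_maintenance = 2,
                              po_ratio = 2,
                              akgdh_max = 3,
                              include_glyoxylate = TRUE,
                              glyoxylate_active = FALSE,
                              include_gaba_shunt = TRUE,
                              include_gaba_uptake = TRUE,
                              glucose_uptake = 4.67) {
  if (any(biomass_stoich < 0)) stop("biomass coefficients must be >= 0")
  if (is.na(biomass_stoich["succoa_c"]) || biomass_stoich[["succoa_c"]] <= 0)
    stop("biomass_stoich must include a positive succinyl-CoA demand ",
         "(succoa_c)")
  stopifnot(atp_maintenance >= 0, po_ratio > 0, akgdh_max > 0,
            glucose_uptake >= 0)
  structure(list(biomass_stoich = biomass_stoich,
                 atp_maintenance = atp_maintenance, po_ratio = po_ratio,
                 akgdh_max = akgdh_max,
                 include_glyoxylate = include_glyoxylate,
                 glyoxylate_active = glyoxylate_active,
                 include_gaba_shunt = include_gaba_shunt,
                 include_gaba_uptake = include_gaba_uptake,
                 glucose_uptake = glucose_uptake),
            class = "core_model_params")
}

core_metabolites <- function() {
  m <- function(id, name, comp, formula)
    metabolite(id, name, comp, formula)
  list(
    m("glc_e", "D-glucose (extracellular)", "e", "C6O6"),
    m("g6p_c", "glucose 6-phosphate", "c", "C6O9P"),
    m("f6p_c", "fructose 6-phosphate", "c", "C6O9P"),
    m("gap_c", "glyceraldehyde 3-phosphate", "c", "C3O6P"),
    m("pep_c", "phosphoenolpyruvate", "c", "C3O6P"),
    m("pyr_c", "pyruvate", "c", "C3O3"),
    m("ru5p_c", "ribulose 5-phosphate", "c", "C5O8P"),
    m("accoa_c", "acetyl-CoA", "c", "C2OZ"),
    m("coa_c", "coenzyme A", "c", "Z"),
    m("cit_c", "citrate", "c", "C6O7"),
    m("icit_c", "isocitrate", "c", "C6O7"),
    m("akg_c", "alpha-ketoglutarate", "c", "C5O5"),
    m("succoa_c", "succinyl-CoA", "c", "C4O3Z"),
    m("succ_c", "succinate", "c", "C4O4"),
    m("fum_c", "fumarate", "c", "C4O4"),
    m("mal_c", "malate", "c", "C4O5"),
    m("oaa_c", "oxaloacetate", "c", "C4O5"),
    m("glx_c", "glyoxylate", "c", "C2O3"),
    m("glu_c", "L-glutamate", "c", "C5NO4"),
    m("gaba_c", "4-aminobutyrate", "c", "C4NO2"),
    m("gaba_e", "4-aminobutyrate (extracellular)", "e", "C4NO2"),
    m("ssa_c", "succinate semialdehyde", "c", "C4O3"),
    m("nh3_c", "ammonia", "c", "N"),
    m("co2_c", "carbon dioxide", "c", "CO2"),
    m("o2_c", "oxygen", "c", "O2"),
    m("h2o_c", "water", "c", "O"),
    m("pi_c", "phosphate", "c", "O4P"),
    m("so3_e", "sulfite (extracellular)", "e", "O3S"),
    m("atp_c", "ATP", "c", "AdO3P"),
    m("adp_c", "ADP", "c", "Ad"),
    m("nad_c", "NAD+", "c", "Nad"),
    m("nadh_c", "NADH", "c", "Nad"),
    m("nadp_c", "NADP+", "c", "Ndp"),
    m("nadph_c", "NADPH", "c", "Ndp"),
    m("biomass_c", "biomass", "c", NULL))
}

#' Build the synthetic core-carbon model
#'
#' A pure function of its parameters: equal params give byte-identical
#' serializations. The returned model passes [check_mass_balance()] with
#' zero violations (the biomass pseudo-reaction, whose product has no
#' elemental formula, is the only skipped reaction).
#'
#' @param params A [core_model_params()].
#' @return A `metabolic_model` with all role tags assigned and the biomass
#'   objective set.
#' @export
build_core_model <- function(params = core_model_params()) {
  stopifnot(inherits(params, "core_model_params"))
  po <- params$po_ratio
  r <- function(id, st, lb, ub, name = id, role = NULL, subsystem = NULL)
    reaction(id, st, lower_bound = lb, upper_bound = ub, name = name,
             role = role, subsystem = subsystem)
  glyox_ub <- if (params$glyoxylate_active) DEFAULT_BOUND else 0
  rxns <- list(
    r("EX_glc", c(glc_e = -1), -params$glucose_uptake,
      -params$glucose_uptake, "glucose exchange", role = "GLC_UPTAKE",
      subsystem = "exchange"),
    r("EX_o2",  c(o2_c = -1), -DEFAULT_BOUND, DEFAULT_BOUND,
      "O2 exchange", subsystem = "exchange"),
    r("EX_co2", c(co2_c = -1), -DEFAULT_BOUND, DEFAULT_BOUND,
      "CO2 exchange", subsystem = "exchange"),
    r("EX_nh3", c(nh3_c = -1), -DEFAULT_BOUND, DEFAULT_BOUND,
      "NH3 exchange", subsystem = "exchange"),
    r("EX_h2o", c(h2o_c = -1), -DEFAULT_BOUND, DEFAULT_BOUND,
      "H2O exchange", subsystem = "exchange"),
    r("EX_pi",  c(pi_c = -1), -DEFAULT_BOUND, DEFAULT_BOUND,
      "phosphate exchange", subsystem = "exchange"),
    r("EX_so3", c(so3_e = -1), -DEFAULT_BOUND, DEFAULT_BOUND,
      "sulfite exchange", subsystem = "exchange"),
    r("EX_biomass", c(biomass_c = -1), 0, DEFAULT_BOUND,
      "biomass drain", subsystem = "exchange"),
    r("PTS", c(glc_e = -1, pep_c = -1, g6p_c = 1, pyr_c = 1), 0,
      DEFAULT_BOUND, "glucose PTS", subsystem = "EMP"),
    r("PGI", c(g6p_c = -1, f6p_c = 1), -DEFAULT_BOUND, DEFAULT_BOUND,
      "phosphoglucose isomerase", subsystem = "EMP"),
    r("PFK", c(f6p_c = -1, atp_c = -1, gap_c = 2, adp_c = 1), 0,
      DEFAULT_BOUND, "phosphofructokinase + aldolase (lumped)",
      subsystem = "EMP"),
    r("GAPD", c(gap_c = -1, adp_c = -1, pi_c = -1, nad_c = -1,
                pep_c = 1, atp_c = 1, nadh_c = 1, h2o_c = 1), 0,
      DEFAULT_BOUND, "GAPDH..enolase (lumped)", subsystem = "EMP"),
    r("PYK", c(pep_c = -1, adp_c = -1, pyr_c = 1, atp_c = 1), 0,
      DEFAULT_BOUND, "pyruvate kinase", subsystem = "EMP"),
    r("G6PDH", c(g6p_c = -1, nadp_c = -2, h2o_c = -1, ru5p_c = 1,
                 co2_c = 1, nadph_c = 2), 0, DEFAULT_BOUND,
      "oxidative PPP (lumped)", subsystem = "PPP"),
    r("PPP_nonox", c(ru5p_c = -3, f6p_c = 2, gap_c = 1), -DEFAULT_BOUND,
      DEFAULT_BOUND, "non-oxidative PPP (lumped)", subsystem = "PPP"),
    r("PDH", c(pyr_c = -1, coa_c = -1, nad_c = -1, accoa_c = 1,
               co2_c = 1, nadh_c = 1), 0, DEFAULT_BOUND,
      "pyruvate dehydrogenase", subsystem = "TCA"),
    r("CS", c(accoa_c = -1, oaa_c = -1, h2o_c = -1, cit_c = 1,
              coa_c = 1), 0, DEFAULT_BOUND, "citrate synthase (gltA)",
      subsystem = "TCA"),
    r("ACN", c(cit_c = -1, icit_c = 1), -DEFAULT_BOUND, DEFAULT_BOUND,
      "aconitase (acn)", role = "ACN", subsystem = "TCA"),
    r("ICD", c(icit_c = -1, nadp_c = -1, akg_c = 1, co2_c = 1,
               nadph_c = 1), 0, DEFAULT_BOUND,
      "isocitrate dehydrogenase (icd, NADPH)", subsystem = "TCA"),
    r("AKGDH", c(akg_c = -1, coa_c = -1, nad_c = -1, succoa_c = 1,
                 co2_c = 1, nadh_c = 1), 0, params$akgdh_max,
      "alpha-ketoglutarate dehydrogenase complex", role = "AKGDH",
      subsystem = "TCA"),
    r("SUCOAS", c(succoa_c = -1, adp_c = -1, pi_c = -1, succ_c = 1,
                  atp_c = 1, coa_c = 1), -DEFAULT_BOUND, DEFAULT_BOUND,
      "succinyl-CoA synthetase (sucCD)", role = "SUCOAS",
      subsystem = "TCA"),
    r("SDH", c(succ_c = -1, o2_c = -0.5, fum_c = 1, h2o_c = 1), 0,
      DEFAULT_BOUND, "succinate dehydrogenase (respiration lumped)",
      subsystem = "TCA"),
    r("FUM", c(fum_c = -1, h2o_c = -1, mal_c = 1), -DEFAULT_BOUND,
      DEFAULT_BOUND, "fumarase", subsystem = "TCA"),
    r("MDH", c(mal_c = -1, nad_c = -1, oaa_c = 1, nadh_c = 1),
      -DEFAULT_BOUND, DEFAULT_BOUND, "malate dehydrogenase",
      subsystem = "TCA"),
    r("PPC", c(pep_c = -1, co2_c = -1, h2o_c = -1, oaa_c = 1, pi_c = 1),
      0, DEFAULT_BOUND, "PEP carboxylase", subsystem = "anaplerosis"),
    r("GDH", c(akg_c = -1, nh3_c = -1, nadph_c = -1, glu_c = 1,
               nadp_c = 1, h2o_c = 1), -DEFAULT_BOUND, DEFAULT_BOUND,
      "glutamate dehydrogenase (gdh, NADPH)", subsystem = "nitrogen"),
    r("OXPHOS", c(nadh_c = -1, o2_c = -0.5, adp_c = -po, pi_c = -po,
                  nad_c = 1, atp_c = po, h2o_c = 1 + po), 0,
      DEFAULT_BOUND, "NADH respiration + ATP synthase (lumped)",
      subsystem = "energy"),
    r("ATPM", c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1),
      params$atp_maintenance, DEFAULT_BOUND, "ATP maintenance",
      subsystem = "energy"))
  if (params$include_glyoxylate) rxns <- c(rxns, list(
    r("ICL", c(icit_c = -1, succ_c = 1, glx_c = 1), 0, glyox_ub,
      "isocitrate lyase (aceA)", role = "ACEA", subsystem = "glyoxylate"),
    r("MALS", c(glx_c = -1, accoa_c = -1, h2o_c = -1, mal_c = 1,
                coa_c = 1), 0, glyox_ub, "malate synthase (aceB)",
      role = "ACEB", subsystem = "glyoxylate")))
  if (params$include_gaba_shunt) rxns <- c(rxns, list(
    r("ABTA", c(gaba_c = -1, akg_c = -1, ssa_c = 1, glu_c = 1), 0,
      DEFAULT_BOUND, "GABA transaminase (gabT)", role = "GABA_SHUNT_T",
      subsystem = "GABA shunt"),
    r("SSALDH", c(ssa_c = -1, nad_c = -1, h2o_c = -1, succ_c = 1,
                  nadh_c = 1), 0, DEFAULT_BOUND,
      "succinate-semialdehyde dehydrogenase (gabD)",
      role = "GABA_SHUNT_D", subsystem = "GABA shunt")))
  if (params$include_gaba_uptake) rxns <- c(rxns, list(
    r("GABAup", c(gaba_e = -1, gaba_c = 1), 0, DEFAULT_BOUND,
      "GABA uptake symporter (gabP)", role = "GABA_UPTAKE",
      subsystem = "transport")))
  ## biomass: precursor drain; carrier by-products returned
  bm <- params$biomass_stoich
  st <- -bm
  names(st) <- names(bm)
  carriers <- c(atp_c = "adp_c", nadph_c = "nadp_c")
  extra <- c(biomass_c = 1)
  if (!is.na(bm["atp_c"])) {
    extra[["adp_c"]] <- bm[["atp_c"]]
    extra[["pi_c"]] <- bm[["atp_c"]]
    st[["h2o_c"]] <- -(bm[["atp_c"]])      # ATP + H2O -> ADP + Pi
  }
  if (!is.na(bm["nadph_c"])) extra[["nadp_c"]] <- bm[["nadph_c"]]
  coa_back <- sum(bm[c("accoa_c", "succoa_c")], na.rm = TRUE)
  if (coa_back > 0) extra[["coa_c"]] <- coa_back
  rxns <- c(rxns, list(
    r("BIOMASS", c(st, extra), 0, DEFAULT_BOUND,
      "biomass formation", role = "BIOMASS", subsystem = "biomass")))
  mets <- core_metabolites()
  used <- unique(unlist(lapply(rxns, function(x) names(x$stoichiometry))))
  mets <- mets[vapply(mets, function(m) m$id %in% used, TRUE)]
  model <- metabolic_model("cglu_core", mets, rxns,
                           objective = c(BIOMASS = 1))
  bal <- check_mass_balance(model)
  if (nrow(bal$imbalanced))
    stop("internal error: core model is not elementally balanced (",
         paste(unique(bal$imbalanced$reaction), collapse = ", "), ")")
  model
}

#' Build a mini fixture model
#'
#' Small, analytically tractable models for oracle-backed testing. Each
#' carries a `fixture_spec` attribute listing machine-checkable expected
#' properties.
#'
#' \describe{
#'   \item{M1}{uptake of A capped at 10, A->B, A->C, biomass B+C -> (sink);
#'     conservation forces max biomass 5.}
#'   \item{M1_product}{M1 plus a product exchange draining C; at a 0.2
#'     biomass floor, biomass 1 and product 8.}
#'   \item{cycle}{M1 plus an isolated 2-reaction internal loop carrying no
#'     objective; pFBA zeroes it.}
#'   \item{akg_node}{6-reaction abstraction of the alpha-ketoglutarate
#'     branch point: source -> AKG, AKGDH-like drain, GDH -> GLU -> GABA ->
#'     export, biomass 0.5 GLU + 0.5 SUC.}
#' }
#'
#' @param name Fixture name.
#' @return A `metabolic_model` with attribute `fixture_spec`.
#' @export
build_mini_model <- function(name = c("M1", "M1_product", "cycle",
                                      "akg_node")) {
  name <- match.arg(name)
  r <- function(id, st, lb = 0, ub = DEFAULT_BOUND, role = NULL)
    reaction(id, st, lower_bound = lb, upper_bound = ub, role = role)
  m <- function(ids) lapply(ids, function(i) metabolite(i, compartment = "c"))
  model <- switch(name,
    M1 = metabolic_model("M1", m(c("A", "B", "C")), list(
      r("UPT", c(A = 1), 0, 10),
      r("R_AB", c(A = -1, B = 1)),
      r("R_AC", c(A = -1, C = 1)),
      r("BIO", c(B = -1, C = -1), role = "BIOMASS")),
      objective = c(BIO = 1)),
    M1_product = metabolic_model("M1_product", m(c("A", "B", "C")), list(
      r("UPT", c(A = 1), 0, 10),
      r("R_AB", c(A = -1, B = 1)),
      r("R_AC", c(A = -1, C = 1)),
      r("BIO", c(B = -1, C = -1), role = "BIOMASS"),
      r("EX_P", c(C = -1))),
      objective = c(BIO = 1)),
    cycle = metabolic_model("cycle", m(c("A", "B", "X", "Y")), list(
      r("UPT", c(A = 1), 0, 10),
      r("R_AB", c(A = -1, B = 1)),
      r("BIO", c(B = -1), role = "BIOMASS"),
      r("C1", c(X = -1, Y = 1), -DEFAULT_BOUND, DEFAULT_BOUND),
      r("C2", c(Y = -1, X = 1), -DEFAULT_BOUND, DEFAULT_BOUND)),
      objective = c(BIO = 1)),
    akg_node = metabolic_model("akg_node",
      m(c("AKG", "SUC", "GLU", "GABA")), list(
      r("SRC", c(AKG = 1), 0, 10),
      r("AKGDH_M", c(AKG = -1, SUC = 1), role = "AKGDH"),
      r("GDH_M", c(AKG = -1, GLU = 1)),
      r("GAD_M", c(GLU = -1, GABA = 1), role = "GAD"),
      r("EX_GABA", c(GABA = -1), role = "GABA_EXPORT"),
      r("BIO", c(GLU = -0.5, SUC = -0.5), role = "BIOMASS")),
      objective = c(BIO = 1)))
  attr(model, "fixture_spec") <- mini_fixture_spec(name)
  model
}

#' Build the reduced producer model
#'
#' An oracle-tractable (~11 free reactions) condensation of the producer
#' core model: lumped glycolysis to pyruvate, anaplerosis, a combined
#' CS+ACN+ICD entry into the TCA cycle (tagged `ACN`, the scan's control
#' reaction), a capacity-limited oxidative TCA return (tagged `AKGDH`),
#' the glutamate/GABA branch with export, a lumped GABA shunt returning
#' carbon to the C4 pool, and a three-precursor biomass. Small enough for
#' [oracle_solve()], yet it reproduces the qualitative scan behavior of
#' the full core model (productivity maximum at an intermediate aconitase
#' multiplier, GABA-shunt recruitment when the flux is over-forced).
#'
#' @param akgdh_max Capacity of the oxidative TCA return lump.
#' @param glucose_uptake Fixed glucose uptake rate (mmol/gCDW/h).
#' @return A `metabolic_model` with roles `GLC_UPTAKE`, `ACN`, `AKGDH`,
#'   `GAD`, `GABA_EXPORT`, `GABA_SHUNT_T`, `BIOMASS`.
#' @export
build_reduced_producer <- function(akgdh_max = 1, glucose_uptake = 4.67) {
  m <- function(ids) lapply(ids, function(i) metabolite(i, compartment = "c"))
  r <- function(id, st, lb = 0, ub = DEFAULT_BOUND, role = NULL)
    reaction(id, st, lower_bound = lb, upper_bound = ub, role = role)
  metabolic_model("reduced_producer",
    m(c("glc", "pyr", "accoa", "oaa", "akg", "glu", "gaba", "co2")),
    list(
      r("EX_glc", c(glc = -1), -glucose_uptake, -glucose_uptake,
        role = "GLC_UPTAKE"),
      r("EX_co2", c(co2 = -1), 0, DEFAULT_BOUND),
      r("GLYC", c(glc = -1, pyr = 2)),
      r("PDHX", c(pyr = -1, accoa = 1, co2 = 1)),
      r("ANA", c(pyr = -1, oaa = 1)),
      r("CSA", c(accoa = -1, oaa = -1, akg = 1, co2 = 1), role = "ACN"),
      r("AKGD", c(akg = -1, oaa = 1, co2 = 1), ub = akgdh_max,
        role = "AKGDH"),
      r("GDHX", c(akg = -1, glu = 1)),
      r("GADX", c(glu = -1, gaba = 1, co2 = 1), role = "GAD"),
      r("EX_gaba", c(gaba = -1), role = "GABA_EXPORT"),
      r("SHUNT", c(gaba = -1, oaa = 1), role = "GABA_SHUNT_T"),
      r("BIO", c(glu = -0.5, oaa = -0.5, pyr = -1), role = "BIOMASS")),
    objective = c(BIO = 1))
}

mini_fixture_spec <- function(name) {
  props <- switch(name,
    M1 = list(list(op = "fba", property = "objective_value", value = 5,
                   tol = 1e-6)),
    M1_product = list(
      list(op = "production_fba", property = "biomass_at_floor_0.2",
           value = 1, tol = 1e-6),
      list(op = "production_fba", property = "product_at_floor_0.2",
           value = 8, tol = 1e-6)),
    cycle = list(list(op = "pfba", property = "cycle_flux", value = 0,
                      tol = 1e-6)),
    akg_node = list(
      list(op = "production_fba", property = "product_at_floor_0.2",
           value = 8, tol = 1e-6),
      list(op = "node_split", property = "AKG_fraction_to_GDH_M",
           value = 0.9, tol = 1e-6)))
  list(name = name, description = paste("mini fixture", name),
       expected_properties = props)
}

#' Deterministically jitter a model's finite bounds
#'
#' Property-testing helper: adds seeded multiplicative noise to every
#' finite nonzero bound (stoichiometry untouched), preserving
#' `lb <= ub`. The same seed gives an identical model; magnitude 0 is the
#' identity.
#'
#' @param model A `metabolic_model`.
#' @param seed Integer seed.
#' @param magnitude Relative jitter amplitude (>= 0), e.g. 0.1.
#' @return The perturbed model.
#' @export
perturb_model <- function(model, seed, magnitude = 0.1) {
  stopifnot(magnitude >= 0)
  if (magnitude == 0) return(model)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(as.integer(seed))
  for (id in reaction_ids(model)) {
    rr <- model$reactions[[id]]
    lb <- rr$lower_bound; ub <- rr$upper_bound
    if (is.finite(lb) && lb != 0)
      lb <- lb * (1 + magnitude * (stats::runif(1) - 0.5))
    if (is.finite(ub) && ub != 0)
      ub <- ub * (1 + magnitude * (stats::runif(1) - 0.5))
    if (lb > ub) { tmp <- lb; lb <- ub; ub <- tmp }
    model <- set_bounds(model, id, lb = lb, ub = ub)
  }
  model
}
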