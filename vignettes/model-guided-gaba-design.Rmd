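---
title: "Model-guided flux analysis for GABA and butyrolactam strain design"
author: "gabaflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-guided flux analysis for GABA and butyrolactam strain design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gabaflux)
```

## The problem

Gamma-aminobutyric acid (GABA) is made from L-glutamate in a single
decarboxylation catalyzed by glutamate decarboxylase (GAD), and is in turn
the precursor of butyrolactam (2-pyrrolidone). In *Corynebacterium
glutamicum*, glutamate sits one transamination away from the TCA-cycle
intermediate α-ketoglutarate, so GABA production competes directly with
the oxidative TCA branch (α-ketoglutarate dehydrogenase, AKGDH, followed
by succinyl-CoA synthetase, SUCOAS) for the α-ketoglutarate pool.
`gabaflux` implements the constraint-based analyses used to reason about
this competition: which TCA edits redirect carbon toward GABA, how far the
redirection can go before it hurts, and what the stoichiometric ceiling of
the producer is.

## Flux balance analysis and its canonical form

All analyses solve linear programs over steady-state flux vectors:
maximize $c^\top v$ subject to $S v = 0$ and $lb \le v \le ub$, where $S$
is the stoichiometric matrix and $v$ the flux vector (mmol/gCDW/h).
Exchange reactions use the standard sign convention (negative flux =
uptake). Because an LP optimum is generally a non-unique vertex, every
*reported* flux distribution is canonicalized by parsimonious FBA
(`pfba()`): total absolute flux is minimized at the fixed optimal
objective, which makes distributions reproducible across solvers and
pivot orders. Plain `fba()` remains available but its flux vector is
flagged non-canonical; `fva()` brackets the alternate optima per
reaction.

No LP package ships with the environments this package targets, so the
solver is part of the package: a dense two-phase primal simplex (Dantzig
pricing with a Bland's-rule fallback that guarantees termination) applied
to a standard-form translation with shifted variables and slack rows for
finite upper bounds. A second backend wraps `boot::simplex` on the same
standard form; the two backends must agree to $10^{-6}$ on the fixture
suite, and both are cross-checked against `oracle_solve()`, an exhaustive
vertex-enumeration oracle that is feasible for models with at most ~12
free reactions and is independent of both simplex implementations.
Numerical settings: solver pivot/feasibility tolerance $10^{-9}$;
reporting and assertion tolerance $10^{-6}$; every optimal state is
verified to satisfy $\max_i |(Sv)_i| \le 10^{-6}\,\max(1, \max_j |v_j|)$
and its bounds to $10^{-6}$ before it is returned. Infeasible and
unbounded programs are reported as statuses, never as silent zeros, so
scans can record masked cells.

## The producer formulation

The wild type maximizes the biomass reaction. The *producer* maximizes
GABA export subject to a biomass floor of 20% of the theoretical maximum
(`production_fba()`, `biomass_fraction = 0.2`). The floor is encoded as a
lower bound on the biomass reaction — the simplest equivalent encoding of
the constraint. In the multiplier scan the floor is computed once from
the unconstrained model, so all scan cells share the same biomass
requirement rather than each cell referencing its own constrained
maximum.

## The synthetic core model

The packaged model (`build_core_model()`) is a ~34-reaction,
elementally-balanced abstraction of *C. glutamicum* central carbon
metabolism: PTS glucose uptake at a fixed 4.67 mmol/gCDW/h; EMP at
three-reaction resolution; a lumped oxidative PPP with reversible
non-oxidative return; PDH; the full TCA cycle (CS–ACN–ICD–AKGDH–SUCOAS–
SDH–FUM–MDH); the glyoxylate shunt; PEP-carboxylase anaplerosis;
NADPH-dependent glutamate dehydrogenase; the GABA shunt (gabT/gabD) and
GABA uptake (gabP); a lumped respiratory chain honoring a configurable
P/O ratio; ATP maintenance; and a biomass reaction with an explicit
succinyl-CoA demand. CO₂, H₂O, NH₃, phosphate, sulfite and O₂ exchange
freely. The heterologous GAD route (`add_gaba_pathway()`: the reversible
decarboxylation Glu ↔ GABA + CO₂ plus transport and a secretion-only
exchange) and the acetyl-CoA-dependent butyrolactam branch
(`add_butyrolactam_pathway()`: a lumped CoA-transfer/cyclization reaction
conserving the CoA moiety) are installed as edits, not built in.

Choices a maintainer should know about:

* **Lumping granularity.** EMP is kept at three reactions and the
  oxidative PPP at one so that every row group of a flux-change heatmap
  (EMP, PPP, TCA, glyoxylate, GABA shunt) has a distinct reaction.
* **Formulas omit hydrogen.** Free protons are not modeled; elemental
  bookkeeping covers C/N/O/P/S plus pseudo-elements for conserved
  moieties (CoA, NAD(H), NADP(H), the adenosine-phosphate core), so
  `check_mass_balance()` verifies carbon balance and carrier conservation
  exactly. The biomass product is the one species without a formula; the
  biomass reaction is therefore skipped (and listed as skipped) rather
  than misreported.
* **Biomass composition.** Coefficients are order-of-magnitude values
  (~46 mmol C/gCDW, 40 mmol ATP/gCDW, 15 mmol NADPH/gCDW) chosen once;
  the glutamate (2.8) and succinyl-CoA (0.85) demands are sized so that
  the wild-type TCA entry flux is a genuine bottleneck: the resulting
  wild-type growth is 0.47 h⁻¹ at the fixed glucose uptake, in the
  physiological range for glucose minimal medium. They carry no claim of
  matching any genome-scale reconstruction's biomass equation.
* **AKGDH capacity.** The AKGDH complex is tightly regulated
  (OdhA/OdhI); it carries a finite capacity of 3 mmol/gCDW/h, several
  fold above the wild-type optimum (~0.4), so it never constrains normal
  growth but caps how much α-ketoglutarate the oxidative branch can
  absorb when aconitase flux is over-forced.
* **Glyoxylate shunt closed by default.** aceA/aceB are
  glucose-repressed in *C. glutamicum*; the reactions are present with
  (0, 0) bounds and the packaged ΔsucCD strain pairs the deletion with a
  bound edit opening them, mirroring the observed aceA/aceB upregulation
  in that background. An always-open shunt would also act as a
  carbon-efficient bypass that masks the GABA-shunt recruitment the scan
  is designed to expose.
* **Deletions retain reactions at (0, 0) bounds**, so delta maps and
  strain tables keep a fixed reaction universe across strains; tests
  verify that this is optimum-equivalent to structural removal.
* **GAD is reversible**; the GABA exchange is secretion-only, with a
  separate uptake transporter so the gabP→potE transport rewiring is
  expressible as independent edits.

What the synthetic model emulates — and what it does not: it reproduces
the *stoichiometric* phenomenology (carbon competition at the
α-ketoglutarate node, the producer's EMP-up/PPP-down shift, shunt
recruitment under over-forcing, lethality structure of OAA-regeneration
knockouts). It contains no kinetics or regulation, so passing tests say
nothing about rates, titers, or why shunt/transport deletions help in
vivo; a genome-scale reconstruction with its own biomass equation will
give different numbers while the qualitative analyses carry over.

## The analyses

**Wild-type vs producer delta map** (`delta_map()`): per-reaction flux
changes normalized to glucose uptake, classified `up`, `down`,
`unchanged` or `reversed` (nonzero fluxes of opposite sign). On the core
model the producer raises TCA entry and EMP flux and cuts the oxidative
PPP — NADPH demand falls with biomass, and ICD supplies the NADPH for
glutamate synthesis.

**Node splits** (`node_split()`): stoichiometry-weighted,
direction-aware consumption fractions at a metabolite. At the producer's
α-ketoglutarate node, 98% of consumption goes to the glutamate/GABA
branch. A note on interpretation: this is the fraction of *node outflow*
taken by the branch; the fraction of α-ketoglutarate carbon ultimately
leaving as exported GABA is lower whenever the GABA shunt recycles. Both
readings can be computed from the same split plus the shunt flux.

**Aconitase multiplier scan** (`acn_scan()`): the aconitase flux is
fixed by equality at $k \in \{1, 1.5, 2, 2.5, 3\}$ times its wild-type
canonical value — the reference is the pFBA wild-type flux, since no
other canonicalization is defined — and the producer optimization is
re-run per cell. "Overexpression" in the strain series uses the same
equality-at-a-multiple encoding (default 2×). On the core model the
trace rises while the forced flux is below the producer optimum, peaks
at an interior multiplier, and collapses beyond it as the GABA shunt is
recruited: over-forced TCA entry must regenerate oxaloacetate by burning
α-ketoglutarate-derived carbon back to succinate, which is exactly the
shunt's net reaction (AKGDH is at capacity and glyoxylate is repressed).
Normalization of the heatmap matrix is uptake-scaled, not per-reaction
max-scaled; the TSV export carries both the normalized delta and the
direction class.

**Double robustness** (`double_robustness()`): optimal GABA export over
a grid of (growth, AKGDH or SUCOAS flux) pairs, both fixed by equality
(a bound mode is available via `mode = "upper"`). Grids default to 21
even points spanning `[0, μ*]` and `[0, max feasible flux]`. Infeasible
cells are masked, never interpolated. The surface is non-increasing
along the growth axis and peaks at the zero-growth, zero-flux corner:
maximal productivity wants both competitors at zero.

**Strain series** (`strain_series()` with the packaged
`strains_gaba_blm.json`): nine analogs — the GAD-cassette base strain,
aconitase and then isocitrate-dehydrogenase overexpression, ΔsucCD with
glyoxylate activation, ΔgabTD, the gabP::potE transport swap, and the
three butyrolactam (Act-branch) derivatives evaluated on butyrolactam
export. Per-strain failures are recorded in the table's status column
without aborting the series. Two deliberate properties of the results:
deletions can never raise an FBA optimum, so the shunt/transport edits
leave the in-silico product flux unchanged (their experimental benefit
is kinetic/regulatory and out of scope); and strain viability is
assessed with `growth_capacity()`, which relaxes fixed-uptake equalities
to capacities and maintenance floors to zero so that a lethal design
reports growth 0 instead of an infeasible program.

## Problem sizes and determinism

The packaged analyses are desk-scale by construction: the core model has
34–37 reactions, scans solve 5 producer LPs, the robustness surfaces
21 × 21 cells, and the oracle cross-validation enumerates vertices of
four ≤ 6-reaction fixtures plus 50 seeded bound-jittered variants each.
`build_core_model()` is a pure function of its parameters (byte-identical
serializations), `perturb_model()` is seeded, and all TSV writers use a
fixed 6-significant-digit format so repeated runs are byte-identical.

## Known limitations

* The simplex is dense and intended for models up to a few hundred
  reactions; genome-scale models load and edit fine, but solving them is
  not the package's design point.
* `boot::simplex` (the second backend) is reliable only at fixture
  scale; backend-agreement guarantees are therefore stated on the
  fixture suite.
* The oracle requires finite bounds and ≤ ~12 free reactions.
* No thermodynamic or loopless constraints; isolated cycles are handled
  by pFBA canonicalization, and no MILP-based design methods
  (knockout-optimization) are included.
* SBML support targets Level 3 with FBC-style bounds as written by this
  package and by common constraint-based tools; exotic serializations of
  external reconstructions may need the JSON dialect plus the
  role/id-mapping arguments (`species_id_map()`).
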