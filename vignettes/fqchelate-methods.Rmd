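---
title: "Models and methods behind fqchelate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fqchelate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fqchelate)
```

## The problem

Oral fluoroquinolone (FQ) antibiotics chelate multivalent metal cations —
aluminum, magnesium and calcium from antacids (Maalox, Titralac), sucralfate,
didanosine buffers and supplements — through the 3-carboxyl and 4-keto
oxygens of their common 4-oxo-quinoline core. The resulting complexes are
poorly absorbed, so coadministration can cut systemic exposure (AUC) by
anywhere from ~15% to ~98% depending on the drug and the metal source.
`fqchelate` packages the quantitative machinery for studying this
interaction: extraction of absorption rate constants from concentration-time
data, physicochemical descriptors from structure, bookkeeping of computed
chelation energetics, and the univariate structure-property regressions that
relate AUC reduction to descriptors and binding energies.

## One-compartment oral absorption kinetics

A single oral dose with first-order absorption ($k_a$) and elimination
($k_e$) gives the Bateman concentration profile

$$C(t) = \frac{F\,D\,k_a}{V_d\,(k_a-k_e)}\left(e^{-k_e t}-e^{-k_a t}\right),$$

with bioavailability $F$, dose $D$ and volume of distribution $V_d$
(`bateman_concentration()`; the removable singularity at $k_a=k_e$ is
replaced by its series limit, threshold $10^{-10}$ relative). The peak time
satisfies

$$T_{max} = \frac{\ln(k_a/k_e)}{k_a-k_e},$$

and the half-life relation $t_{1/2} = \ln 2 / k_e$ (the familiar 0.693
shortcut is the same identity at three digits). Literature PK tables rarely
report $k_a$ directly, so the package recovers it by inverting the
$T_{max}$ relation given $T_{max}$ and $k_e$ (`solve_ka()`).

**Branch choice.** The inversion is ambiguous: observing $T_{max}$ and a
terminal slope cannot distinguish $k_a > k_e$ (conventional,
absorption-limited kinetics) from $k_a < k_e$ (flip-flop kinetics, plausible
for long half-life FQs such as sparfloxacin). For fixed $k_e$ the relation is
monotone in $k_a$ and passes through $1/k_e$ at $k_a = k_e$, so the two
regimes correspond to $T_{max}$ on opposite sides of the bound $1/k_e$: the
absorption-limited root exists iff $T_{max} < 1/k_e$, the flip-flop root iff
$T_{max} > 1/k_e$. The default is `absorption_limited`, flip-flop is opt-in,
and every solved value is annotated with its branch so downstream tables
surface the assumption rather than hiding it. Root finding is bracketed
Brent iteration in $\log k_a$ over $[k_e(1+10^{-9}),\,10^6 k_e]$ (or the
mirrored lower bracket), globally convergent because each branch is
monotone; tolerance $10^{-12}$ with a Newton polish.

## Curve extraction

When only a digitized concentration-time table is available,
`extract_pk()` reproduces the tabulated-parameter workflow:

* **Terminal phase**: all samples strictly after the observed peak with
  positive concentration, minimum three (`select_terminal_phase()`). The
  strictly-after rule is the simplest reproducible convention; no automatic
  lag-point exclusion is attempted, and callers may pass explicit indices.
* **Elimination rate**: ordinary least squares of $\log_{10} C$ on $t$; on a
  decadic axis the elimination phase has slope $-k_e/2.303$
  ($2.303 = \ln 10$), so $k_e = -\text{slope}\times\ln 10$.
* **Tmax**: the observed-peak time, unless a tabulated value is supplied
  (`tmax_source = "provided"`), which then takes precedence — tabulated
  parameters are treated as better than grid-limited observed peaks.
* **AUC**: linear trapezoid over the sampled range plus the log-linear
  extrapolated tail $C_{last}/k_e$. The tail term makes synthetic AUCs
  comparable to the closed form $F D/(V_d k_e)$; for transcribed literature
  AUCs the tabulated value should be used directly.

## Descriptors from SMILES

`parse_smiles()` converts SMILES to a hydrogen-explicit kekulized graph via
Open Babel, then applies the package's own ring perception (bounded simple
cycle enumeration, sizes 3-8) and aromaticity model, so one documented
convention underlies all descriptors:

* **Aromaticity** is Hueckel 4n+2 counting per 5-7 membered ring of
  C/N/O/S: an atom with a double bond to another ring atom contributes one
  electron, a pyrrole-type N or divalent O/S two, and a carbon bearing an
  exocyclic C=O contributes zero. Under this convention the
  pyridin-4(1H)-one ring of the FQ core is aromatic, which is the
  perception that reproduces the packaged reference TPSA values (e.g.
  ciprofloxacin 74.57 rather than the lower value the non-aromatic
  enaminone perception would give). The switch
  `options(fqchelate.oxo_ring_aromatic = FALSE)` selects the alternative
  perception.
* **Monoisotopic mass** sums most-abundant-isotope masses; the reference
  table's "MW" column corresponds to monoisotopic, not average, masses, so
  the abundance-weighted quantity is deliberately exposed under the separate
  name `average_mass()`.
* **TPSA** is the Ertl fragment-contribution sum with N, O, S and P treated
  as polar. Environments missing from the published fragment table fall
  back to the published single-atom estimation rule
  ($30.5 - 8.2X + 1.5H$ for N, $28.5 - 8.6X + 1.5H$ for O, floored at 0,
  with $X$ the heavy-atom attachments) and emit a message.
* **logP** is the Wildman-Crippen atom-contribution model: every atom
  (hydrogens included) is assigned the first matching class of the
  published hierarchy and the typed contributions are summed. Atoms fitting
  no specific class receive the published wildcard contribution for their
  element, with a message.

Descriptors are computed on the neutral as-drawn structures; the cationic
protonation state used for the energetics (below) is a separate modeling
choice. All descriptor values are invariant to the atom ordering of the
input SMILES (regression-tested against randomized spellings).

## Chelation energetics

The modeled reaction displaces two waters from the octahedral hexahydrate:

$$\mathrm{FQH^+} + \mathrm{M(H_2O)_6^{n+}} \longrightarrow
  [\mathrm{FQ\cdot M(H_2O)_4}]^{(n+1)+} + 2\,\mathrm{H_2O}.$$

The FQ is modeled as the N-protonated cation (un-ionized 3-carboxyl,
protonated terminal piperazinyl N), reflecting acidic gastric conditions;
metals are Mg(2+)/Ca(2+)/Al(3+). The displaced-water count is a parameter
(`n_water_displaced`) so alternative reference states can be tested; two is
the count implied by a bidentate bite on a six-coordinate center.

`build_chelate_geometry()` constructs starting structures: donor oxygens are
found by a substructure rule (carboxyl carbonyl O = the H-free oxygen on a
carbon bearing two oxygens; keto O = a terminal oxygen on a carbon bearing
one), the carboxyl torsion is flipped into the binding pocket if the input
conformer points it away, the metal is placed equidistant from both donors
at an element-dependent distance (Al 1.9, Mg 2.1, Ca 2.4 Angstrom), and
four waters complete the octahedron. A steric screen rejects any non-bonded
pair under 0.7 Angstrom. `enumerate_conformer_starts()` enumerates named
torsions on fixed grids, deduplicates by superposition RMSD (< 0.05
Angstrom, Kabsch alignment) and optionally ranks starts by a supplied
force-field adapter; the electronic-structure engine itself stays behind
the staged job-specification interface.

Energies follow a three-stage protocol encoded by `qm_jobspec()`:
geometry optimization and 310 K frequencies at PBE-D3BJ/6-31G(d), then a
PBE-D3BJ/6-31+G(d,p) single point in PCM water. The electronic binding
energy uses the solvated single points; the Gibbs binding energy adds the
gas-phase 310 K thermal correction to the same single point at the
optimization geometry (no solvent re-optimization) — the literal staged
composition, kept deliberately simple. Unit conversion uses
1 hartree = 627.5095 kcal/mol exactly. `binding_energy()` refuses any
reaction that does not conserve element counts and total charge.

Live density-functional runs are out of desk scope: the package emits
engine-agnostic job specifications and consumes parsed energy ledgers. The
packaged ledger `cipro_metal_energies_synthetic.json` is a synthetic
stand-in whose hand-chosen hartree components reproduce the reference
Gibbs binding energies (Al -16.1, Mg -5.3, Ca +0.9 kcal/mol) through the
same bookkeeping, so the stability ordering Al < Mg < Ca is exercised end
to end without a quantum-chemistry engine.

## The structure-property regressions

`assemble_auc_dataset()` selects one percent-AUC-change value per FQ from
the packaged study table: aluminum hydroxide rows first (preferring the
crossover-study reference tag "71" when a drug has two), Maalox as
fallback, and drugs with neither source excluded (moxifloxacin, which has
only sucralfate and calcium rows — an alternative preference list can bring
it in). `qspr_regressions()` then fits simple univariate OLS of percent AUC
change on MW, TPSA, logP and (when a ledger is supplied) the electronic
binding energy, reporting $R^2 = 1 - SS_{res}/SS_{tot}$ at full precision
and rounded to two decimals.

Because ofloxacin and levofloxacin are the same structure (racemate and its
S-enantiomer) they carry identical descriptor triples and nearly identical
AUC changes; keeping both double-weights one molecule.
`collapse_duplicates = TRUE` keeps a single point (levofloxacin's). With
the printed two-decimal descriptor table, the default 12-point assembly
gives $R^2$ = 0.25 (MW), 0.00 (TPSA) and 0.22 (logP); the collapsed
11-point variant gives 0.25 / 0.00 / 0.23. The package treats the collapsed
variant as the one that reproduces the reference values for all three
descriptors and documents the one-point-in-the-second-decimal sensitivity
of the logP panel rather than hiding it.

## The synthetic-data generator

`simulation_scenario()` fixes ground truth for a control-versus-treatment
interaction study: Bateman parameters, a sampling schedule (validated to
extend at least three half-lives past $T_{max}$ so a terminal phase
exists), a noise model, and treatment-arm effect multipliers `f_mult` on
bioavailability and `ka_mult` on the absorption rate. Defaults (ka 1/h,
ke 0.1/h, dose 200 mg, F 0.9, Vd 100 L, a 14-point clinical-style schedule
to 48 h, 5% proportional noise scale) are in the range typical of the FQ
studies this emulates.

In this model AUC equals $F D/(V_d k_e)$ independently of $k_a$, so the
analytic truth is $\%\Delta AUC = 100(f_{mult}-1)$ and
$\%\Delta k_a = 100(ka_{mult}-1)$: the generator can represent the
dissociation between large AUC reductions and even *increased* absorption
rate constants that the study table contains (e.g. AUC down 85% with
$k_a$ up 158%).

Noise conventions: proportional lognormal noise is median-preserving by
default (multiply by $e^{\sigma Z}$); a mean-preserving variant (divide by
$e^{\sigma^2/2}$) is selectable, and both are tested against the lognormal
moment formula. Seeding derives one deterministic substream per subject and
arm from the scenario's master seed, so growing a cohort never reshuffles
earlier subjects, and simulation never perturbs the caller's RNG state.

What passing tests show — and what they do not: the generator draws
independent multiplicative noise around an exact one-compartment profile.
Real curves carry absorption lag, enterohepatic wiggles, correlated
assay error, between-subject parameter variability and multi-compartment
distribution, none of which are emulated. Recovery results here validate
the estimator plumbing, not its field accuracy on clinical data.

## Numerical choices and test problem sizes

Degenerate $k_a \approx k_e$ handling uses a $10^{-10}$ relative threshold
into the series limit. The terminal fit requires at least three positive
post-peak points. The property suite sizes are: 1000 random
$(k_a, k_e)$ round-trip inversions (relative error under $10^{-8}$),
200 noisy synthetic extraction scenarios (median $k_a$ error under 10%,
$k_e$ under 3%), 10,000 replicates for the lognormal moment checks, and
$2\times10^5$-point trapezoid grids for the exposure mass-balance check
(0.1%). These sizes make the full suite run in well under a minute while
leaving the stochastic margins wide.

## Known limitations

* Aromaticity perception covers the fused bicyclic heteroaromatics found
  in quinolone chemistry; exotic systems (N-oxides inside rings, charged
  carbon aromatics) fall back to non-aromatic perception.
* The chelate builder produces idealized octahedral starting geometries,
  not optimized structures; donor-metal distances equal their starting
  values until an engine refines them.
* The regression layer is deliberately univariate; no multivariate QSPR,
  cross-validation or machine-learning extension is attempted.
* Transition metals (Fe, Cu) and 2:1/3:1 chelate stoichiometries are out
  of scope.
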