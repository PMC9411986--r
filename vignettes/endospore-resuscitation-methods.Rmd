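---
title: "Models and methods behind sporeburst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sporeburst}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sporeburst)
```

`sporeburst` analyzes heat-induced resuscitation experiments: permanently
cold marine sediment, pasteurized and incubated at high temperature, in
which dormant thermophilic endospores germinate, bloom and reorganize the
community. This vignette is the package's own account of the models it
implements, the parameters that matter, and the design decisions taken
where more than one reasonable choice existed.

## 1. Growth model and SRR kinetics

Each population is a `population_spec`: a density `n0` (cells cm⁻³) at its
germination onset, a doubling time `t_d`, and a per-cell metabolic rate.
Active biomass is

$$A(t) = \begin{cases} 0 & t < t_\mathrm{onset} \\
N_0 \cdot 2^{(t - t_\mathrm{onset})/t_d} & t \ge t_\mathrm{onset}
\end{cases}$$

and the volumetric sulfate reduction rate is
$\mathrm{SRR}(t) = \sum_i \mathrm{csSRR}_i \cdot A_i(t)$, converted to
nmol cm⁻³ d⁻¹ (1 fmol = 10⁻⁶ nmol; time is in hours everywhere).
Dormant spores are treated as metabolically silent: before onset a
population contributes nothing. This matters numerically — with realistic
censuses the late population outnumbers the early one by two orders of
magnitude, and a "dormant baseline" proportional to `n0` would bury the
early exponential phase entirely.

**Phase detection** (`detect_exponential_phases()`) enumerates all
contiguous windows of at least `min_points = 4` strictly positive,
strictly log-increasing rates, scores each by OLS of ln(rate) on time, and
keeps windows with positive slope and R² ≥ 0.95. Windows contained in a
longer qualifying window are dropped; survivors are admitted greedily
(longest first, ties to higher R², then earlier start) subject to
disjointness, up to two phases. Strict monotonicity is what prevents a
single spurious window from spanning both phases across the plateau
between them; zero rates never join a window (a zero inside a candidate
disqualifies it rather than receiving a pseudo-count). Duplicate
radiotracer measurements at one timepoint are averaged before fitting, as
is standard practice for such assays.

**Census back-extrapolation** (`estimate_population()`) divides the fitted
exponential, evaluated at t = 0, by a cell-specific rate model
(`cs_srr_from_biovolume()`): csSRR = biovolume × biomass density ×
per-biomass rate. The default model is a 1.0 μm³ cell at 1.0 pg μm⁻³
reducing 10 fmol SO₄²⁻ pg⁻¹ d⁻¹, i.e. csSRR = 10 fmol cell⁻¹ d⁻¹ — a
mid-range literature value for mesophilic and thermophilic SRB. The
estimate scales exactly as 1/csSRR, so alternative biovolume assumptions
shift censuses by a known factor without touching the kinetics. Whether to
extrapolate from the fitted intercept at t = 0 or from the first in-window
rate is a genuine choice; the intercept is the default because it uses the
whole window, and `extrapolation_time` exposes the alternative.

The second phase is fitted **on raw rates**, without subtracting the first
population's residual signal. That mirrors how such curves are usually
read, and it carries a known, documented bias: the early population's
plateau/decay elevates the low end of the late window, steepening or
flattening the fit by a few percent and inflating the back-extrapolated
census by ≈ 20 % in the default scenario. The tests accept the late
doubling time within 15 % and censuses within a factor 1.5 for exactly
this reason.

## 2. The default scenario and its calibration

`default_scenario()` encodes the study conditions the package is built
around: a 216-h incubation sampled on the grid 0, 3, 6, 9, 12, 18, 24, 30,
36, 48, 54, 60, 72, 84, 96, 120, 144, 168, 192, 216 h (every 3–12 h early,
every 12–48 h late), sulfate at 15.6 mM, six VFAs amended at 4.2 mM each,
and three populations:

* an **early SRB** (doubling time 1.5 h, measurable growth from 9 h)
  consuming lactate and formate (4/3 + 4/3 per SO₄²⁻, acetate 4/3 out —
  incomplete lactate oxidation, complete formate oxidation, blended so
  both pools would co-exhaust);
* a **late SRB** (doubling time 8.0 h, from 47 h) consuming butyrate and
  propionate (0.5 + 1.0 per SO₄²⁻, acetate 2.0 out);
* a **succinate fermenter** (doubling time 6 h, from 48 h, csSRR = 0)
  converting succinate to propionate 1:1 at 92 fmol cell⁻¹ d⁻¹.

Censuses are reported in the field as *back-extrapolated t = 0 intercepts
under the assumption that germination coincides with the start of the
incubation*, while the scenario places growth onset at the detected 9/47 h.
The generator therefore stores onset densities of
`census · 2^(onset/t_d)`, calibrated so that the package's own estimator,
applied to the noiseless scenario, recovers censuses of 1.6 × 10² and
4.5 × 10⁴ cells cm⁻³ — the convention, not a fit to data.

Two halting mechanisms end exponential growth. Substrate exhaustion is the
primary one: the late SRB runs out of butyrate + propionate at ≈ 122 h and
the fermenter exhausts succinate at ≈ 72 h, both emerging from the
stoichiometry rather than being imposed. The early population is different:
its census-scale biomass integrates to only ~10⁻² μmol SO₄²⁻ cm⁻³ by 23 h,
three orders of magnitude below the millimolar lactate/formate pools, so
no realistic per-cell rate lets bulk exhaustion terminate its phase where
the observed window ends. Its growth is therefore ended explicitly at 24 h
(`growth_end_h`) with a 3-h activity decay — a phenomenological stand-in
for micro-scale substrate limitation or germination asynchrony. This is
the one place where the bulk-geochemistry picture and the
radiotracer-kinetics picture of such experiments cannot be reconciled by a
single parameter set, and the package keeps the kinetics faithful while
letting the bulk sulfate drawdown (≈ 8.4 mM here) be carried by the late
population.

## 3. Concentration bookkeeping and conservation

Concentrations advance on the output grid by trapezoidal integration of
each population's driver rate times its stoichiometric coefficients
(1 nmol cm⁻³ d⁻¹ = 10⁻³/24 mM h⁻¹). Because the bookkeeping uses the same
emitted rate series a user sees, sulfate consumed equals the trapezoidal
time-integral of the emitted SRR *exactly* in every noiseless run — a
conservation property the tests check to 10⁻⁶ relative.

When a step would overdraw a pool, the consuming populations' end-of-step
rates are scaled so that the pool reaches exactly zero one step later (the
scaled rate's trapezoidal tail), after which those populations are
inactive; a population without an electron donor does not keep reducing
sulfate, and conservation survives the halt. A step whose *committed*
start-of-step rates already overdraw a pool cannot be repaired and raises
an error naming the analyte and time.

Observation noise is multiplicative log-normal with `meanlog = log(truth)`
(median-preserving), CV 5 % by default for SRR and concentrations. The
median convention makes log-scale statistics — the log-linear fits and
replicate geometric means — unbiased, which is the property the analyses
rely on. Noise magnitudes for radiotracer and chromatography assays are
package choices (no standard values exist); they are parameters of the
config, not constants.

## 4. Amplicon rules, rarefaction, UniFrac, ordination

The occurrence rule is non-strict ("at least 0.1 %": 24 reads of 24,000
pass, 23 fail) and the enrichment rule strict ("more than 1 %"), mirroring
how the criteria are stated in practice. Enrichment additionally requires
absence below the occurrence threshold in every unheated sediment library.
Whether the > 1 % clause may be met in *any* incubated library or must
hold per treatment is ambiguous in the usual phrasing; the union reading
is the default and `incubated_scope = "per_treatment"` the alternative.
Relative abundances for these calls use unrarefied counts; rarefaction is
reserved for diversity analyses.

`rarefy_counts()` is a single without-replacement draw per library
(multivariate hypergeometric), so column sums hit the target depth
exactly; the seed is mandatory in pipelines. Weighted UniFrac follows the
branch-mass definition: raw distance Σ l_b |A_b − B_b| over branches, the
normalized variant (default) divided by Σ l_b (A_b + B_b) so values lie in
[0, 1]. The implementation is a single postorder accumulation; the test
suite checks it against a brute-force per-branch oracle on random trees of
up to six leaves at 10⁻¹². PCoA is classical Gower scaling with negative
eigenvalues retained in the report but excluded from coordinates.

The synthetic community emulates the rare-biosphere premise: ~150
background ASVs from a log-normal rank-abundance curve hold > 99 % of the
t = 0 community; 21 designated spore-former ASVs start at 0.02 % each and
follow logistic trajectories (anchored so the t = 0 share is exact) to
per-treatment maxima chosen to reproduce the qualitative succession —
fermentative Clostridia and one dominant early sulfate reducer by 12–24 h,
late-rising populations after 72 h, and a roughly tenfold
amended/unamended contrast in sulfate-reducer class abundance. Because
background shares only shrink as bloomers rise, no background ASV can pass
the enrichment rule, and on the default scenario exactly the 21 bloomers
are called enriched.

## 5. Geochemical segmentation and the stoichiometric audit

`segment_phases()` classifies between-timepoint slopes against a
±0.01 mM h⁻¹ dead band and merges same-direction runs; windows tile the
time axis and snap to grid points, matching the interval language in which
such results are reported. `net_change()` propagates endpoint SDs in
quadrature under independence.

`stoichiometric_balance()` solves min ‖Δ_obs − S ξ‖ for ξ ≥ 0 by
non-negative least squares (reactions run forward only — thermodynamic
directionality under sulfate-replete conditions). The default reaction set
is incomplete oxidation by SRB (2 lactate + SO₄ → 2 acetate; 4 formate +
SO₄; 2 butyrate + SO₄ → 4 acetate; 4 propionate + 3 SO₄ → 4 acetate) plus
fermentative succinate decarboxylation (succinate → propionate 1:1). The
report gives per-analyte residuals, the implied sulfate demand and the
acetate yield; acetate produced from sediment organics rather than amended
VFAs appears as unexplained residual, deliberately left unattributed.

## 6. Metabolite profiling

`normalize_fractional()` computes, per metabolite within a treatment, the
mean over technical replicates at each timepoint, expresses those means as
fractions of the metabolite's summed means across timepoints (rows sum to
one pre-log), then takes log10 with a 10⁻⁶ pseudo-fraction. This shows
each compound's temporal shape and is invariant to global intensity
rescaling; a per-sample-total alternative sits behind `by = "sample"`.
Pattern classification uses a tolerance band of 10 % of the profile's
range: differences inside the band count as no change, and the sign
sequence of the rest maps to decrease / increase / increase-then-decrease /
flat / fluctuate. The label is invariant to monotone transforms up to the
band discretization.

The clustering test is a one-way PERMANOVA on Euclidean distances of
log-transformed profiles with seeded label permutations and
p = (1 + #{F* ≥ F}) / (1 + n_perm); 999 permutations is the default. The
choice of PERMANOVA is the package's own — it is the field standard for
"samples cluster by group on a distance matrix" claims. Its type-I error
at α = 0.05 is verified over 1,000 null simulations in the test suite.
Note the attainable minimum p is limited by the number of distinct group
splits at small n, not only by n_perm.

## 7. Problem sizes, determinism, limitations

The test suite and acceptance script run everything at desk scale: 20-point
time grids, 171-ASV communities at 24,000 reads per library, 10⁴-replicate
moment checks for the multinomial and hypergeometric samplers, 100 noisy
replicates for parameter recovery, and 1,000 null PERMANOVA runs at 199
permutations — a few minutes on one CPU in total. All randomness flows
through explicit seeds (`withr::with_seed`), so identical configs produce
byte-identical outputs, and the pipeline manifest records per-stage seeds
and MD5 checksums so a run can be verified or reproduced stage by stage.

What passing tests on synthetic data do **not** show: the generator makes
no attempt at chimeras, contamination, compositional count overdispersion
beyond multinomial sampling, copy-number variation among 16S genes,
spatial heterogeneity of slurries, or germination asynchrony beyond hard
onsets — so detection thresholds tuned here should be revisited on real
libraries. Bulk geochemistry and radiotracer kinetics are reconciled only
qualitatively (Section 2). Temperature and pH are experimental constants,
not state variables, and amplicon simulation starts and ends at ASV
counts; raw-read simulation, denoising and taxonomy assignment are out of
scope.
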