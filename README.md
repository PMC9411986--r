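# sporeburst

Cold marine sediments harbor enormous numbers of dormant thermophilic
endospores — "misplaced microbes" dispersed from warm subsurface habitats
that cannot grow at ambient temperature. Heating such sediment (e.g.
pasteurized slurries incubated at 50 °C) resuscitates these spores and sets
off a reproducible ecological succession: fermentative *Clostridia* attack
amino acids and other sediment organics within hours, and their volatile
fatty acid (VFA) products cross-feed two waves of spore-forming
sulfate-reducing bacteria (*Desulfotomaculia*). `sporeburst` is an R
toolkit for analyzing these incubation experiments — and for simulating
them, so every analysis stage is testable without any external data.

It is written for microbial ecologists and biogeochemists working with
three kinds of time series from one incubation: radiotracer sulfate
reduction rates (SRR), sulfate/VFA concentrations, and 16S rRNA gene
amplicon libraries, optionally plus untargeted metabolite intensities.

## The core computation

During an exponential germination-and-growth phase the volumetric sulfate
reduction rate tracks the active population:

    SRR(t) = csSRR · N(t),      N(t) = N0 · 2^(t / t_d)

where csSRR is the cell-specific sulfate reduction rate
(fmol SO₄²⁻ cell⁻¹ d⁻¹) and t_d the doubling time. Ordinary least squares
of ln SRR on t inside a detected exponential window gives the specific
growth rate μ (t_d = ln 2 / μ), and back-extrapolating the fitted line to
t = 0 — germination assumed at the start of the incubation — converts an
SRR time series into an *in situ* census of the dormant spore population:

    N0 = exp(intercept) / csSRR

with csSRR built from a cell biovolume V (μm³), a biomass density
ρ (pg μm⁻³) and a per-biomass rate (fmol SO₄²⁻ pg⁻¹ d⁻¹). Exponential
windows are found automatically: maximal runs of strictly log-increasing
rates whose log-linear fit reaches R² ≥ 0.95 (≥ 4 points, up to two
disjoint phases).

Around this sit the other stages: the 0.1 % occurrence and > 1 %
enrichment rules for ASVs, rarefaction, weighted UniFrac + PCoA for
community succession, depletion/accumulation segmentation of geochemical
series with a non-negative least-squares audit of cross-feeding
stoichiometry, and log-normalized fractional metabolite profiles with a
PERMANOVA clustering test.

## Worked example

Simulate the default VFA-amended scenario (two sulfate-reducing
populations: measurable growth from 9 h and 47 h, doubling times 1.5 h and
8.0 h) without observation noise, then detect, fit and back-extrapolate:

```r
library(sporeburst)

cfg        <- default_scenario(noise_cv = 0, seed = 1)
experiment <- simulate_germination_growth(cfg)
srr        <- subset(experiment$srr, time_h <= 126)
analyze_srr(srr)[, c("phase", "t_start", "t_end", "doubling_time", "n0", "r_squared")]
#>   phase t_start t_end doubling_time    n0 r_squared
#> 1     1       9    24          1.50   160     1.000
#> 2     2      36   120          8.45 53447     0.985
```

Phase 1 recovers the fast early population exactly: doubling time 1.5 h
and a census of 1.6 × 10² endospores cm⁻³. Phase 2 is fitted on raw rates,
so the early population's residual signal biases its doubling time (8.45 h
vs the configured 8.0 h) and census (5.3 × 10⁴ vs 4.5 × 10⁴ cm⁻³) upward
by a few percent — the same bias the back-extrapolation method itself
carries on real composite data.

The amplicon side of the same scenario builds a rare biosphere in which
all 21 configured spore-former ASVs start below the 0.1 % occurrence
threshold and bloom after heating:

```r
tab   <- simulate_asv_counts(cfg, default_community_trajectories(cfg))
calls <- classify_enriched(tab)
sum(calls$enriched)
#> [1] 21
```

`rarefy_counts()`, `unifrac_matrix()` and `pcoa_ordination()` take it from
there; `segment_phases()`, `net_change()` and `stoichiometric_balance()`
handle the geochemistry; `normalize_fractional()`,
`classify_temporal_patterns()` and `cluster_significance()` the
metabolites. `run_pipeline()` chains everything and writes per-stage JSON
reports plus a checksummed manifest.

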