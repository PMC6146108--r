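# nsip

Detection of per-taxon isotopic enrichment in nitrogen DNA
stable-isotope-probing (SIP) experiments, and ¹⁵N tracer uptake /
new-production budgets for the same incubations.

## What it does, and for whom

Marine microbial ecologists use two complementary measurements to ask *who
is using which nitrogen source*: bulk ¹⁵N tracer incubations (how much NH₄⁺,
NO₃⁻, urea and N₂ the community takes up) and DNA-SIP (which taxa band at a
higher buoyant density after growing on a ¹⁵N-labeled substrate in a CsCl
gradient). `nsip` implements the analysis chain for both.

**SIP enrichment calling.** For each OTU in each gradient, read counts are
converted to relative abundance per fraction, then to ng DNA via the
measured bulk-DNA distribution, and the band's weighted mean buoyant
density (WMD) is estimated,

  ρ̄ = Σᵢ ρᵢwᵢ / Σᵢ wᵢ,  s² = Σᵢ wᵢ(ρᵢ − ρ̄)² / Σᵢ wᵢ,  n_eff = (Σw)²/Σw²,

with weights wᵢ the OTU's DNA mass in fraction i and n_eff the Kish
effective sample size. Band tails are trimmed to a common density window
across the gradients being compared. All of an OTU's unlabeled controls are
pooled (unlabeled N cannot change buoyant density), and each labeled
treatment is tested against the pooled control with Welch's *t*-test on the
weighted summaries, one-sided for a positive shift. Benjamini–Hochberg
correction at FDR 0.1 plus a ≥ 30 % percent-enrichment rule
(100·Δρ/Δρ_max, Δρ_max = 0.016 g ml⁻¹ at full labeling) yields the final
per-OTU × treatment enrichment calls. Only bands of the same OTU are ever
compared, so GC-content differences between organisms cancel.

**Uptake budget.** Tracer uptake rates follow the atom-percent-excess
formulation ρ = (A_tf − A_t0)/(A_diss − A_t0) · PN/t, with the dissolved
pool enrichment from the spike/ambient mixing ratio and a linear
standards-based IRMS size/drift correction. Rates are depth-integrated
(trapezoid, surface extension) over the euphotic zone and assembled into a
new-vs-regenerated production budget: f-ratio
(ρNO₃ + ρN₂)/(ρNO₃ + ρN₂ + ρNH₄ + ρurea) and Redfield C equivalents
(C:N = 106:16).

A seeded synthetic-data generator (`simulate_sip_experiment()`,
`simulate_uptake_obs()`) emulates gradient fractionation, Gaussian DNA
bands with GC- and label-dependent centers, multinomial amplicon sampling,
bulk-DNA quantification noise and IRMS noise, so the whole pipeline is
testable without sequencing data.

## Worked example

```r
library(nsip)

trt <- data.frame(substrate = "NH4", light_level = "50")
cfg <- sim_config(seed = 42)
community <- simulate_community(
  40, trt, assimilators = list(NH4.50 = sprintf("otu_%03d", 1:8)),
  atom_fraction = 0.5, config = cfg)
sim <- simulate_sip_experiment(community, cfg, controls_per_treatment = 3)

fit <- sip_enrich(sim$counts, sim$fractions, sim$otus)
fit
#> SIP enrichment analysis
#>   40 OTU x treatment comparisons over 4 gradients
#>   excluded: 0 (none)
#>   enriched: 8 at FDR 0.1 with >= 30% enrichment
#>   median shift among enriched: 0.0079 g/ml (49.1% of full label)
```

All 8 simulated assimilators (half-labeled, so a true shift of
0.016/2 = 0.008 g ml⁻¹) are recovered, with estimated percent enrichment
clustering at ~49 % of full label and no false positives among the 32
unlabeled OTUs:

```r
head(subset(fit$results, enriched,
            select = c(otu_id, shift, percent_enrichment, q_value)))
#>    otu_id       shift percent_enrichment     q_value
#> 1 otu_001 0.008065293           50.40808 0.009207060
#> 2 otu_002 0.007514095           46.96309 0.009933794
#> 3 otu_003 0.007847462           49.04664 0.009207060
#> ...
```

`summary(fit)` tabulates enriched OTUs per substrate × light level split by
prokaryotes vs eukaryotic chloroplasts; `plot(fit)` draws shift vs −log₁₀ q.

The budget side, fed with euphotic-zone depth-integrated rates
(mmol N m⁻² d⁻¹):

```r
n_budget(list(urea = 3.4, NO3 = 3.1, NH4 = 2.4, N2 = 0.19))
#> Depth-integrated N uptake budget
#>  substrate N uptake (mmol N m-2 d-1) fraction C equivalent (mmol C m-2 d-1)
#>        NH4                      2.40   0.2640                         15.90
#>        NO3                      3.10   0.3410                         20.50
#>       urea                      3.40   0.3740                         22.50
#>         N2                      0.19   0.0209                          1.26
#> Total: 9.09 mmol N m-2 d-1 (~60.2 mmol C m-2 d-1); f-ratio 0.36
```

Urea and nitrate dominate the nitrogen supply; the f-ratio says ~37 % of
production is fueled by new nitrogen (nitrate + N₂ fixation), the rest by
regenerated forms.

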