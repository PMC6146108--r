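---
title: "Detecting isotopic enrichment in nitrogen DNA-SIP gradients"
author: "nsip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting isotopic enrichment in nitrogen DNA-SIP gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsip)
```

## The measurement and the model

DNA stable-isotope probing (SIP) identifies which taxa assimilate a labeled
substrate by centrifuging community DNA to equilibrium in a CsCl gradient:
DNA that incorporated a heavy isotope bands at a higher buoyant density.
Gradients are displaced from below and collected densest-first as ~50
fractions of ~100 µl; each fraction gets a refractometer density reading, a
fluorometric bulk-DNA mass, and (for fractions with enough DNA to amplify)
an amplicon library that yields per-OTU read counts.

For one OTU in one gradient the package reconstructs the DNA band as

1. per-fraction relative abundance, `reads / total reads` (fractions below
   `min_fraction_reads` total reads are dropped — a handful of reads can
   move an apparent band by whole fractions);
2. ng DNA per fraction, relative abundance × measured bulk DNA, so OTU
   masses sum back to the bulk measurement exactly;
3. the band's weighted mean density (WMD)
   $$\bar\rho = \frac{\sum_i \rho_i w_i}{\sum_i w_i},\qquad
     s^2 = \frac{\sum_i w_i(\rho_i-\bar\rho)^2}{\sum_i w_i},$$
   with weights $w_i$ the OTU's ng DNA in fraction $i$. Weights are masses,
   not reads, because the bulk-DNA conversion is what makes fractions
   comparable across a gradient.

Because a weighted mean has no literal sample size, the Welch test below
uses the Kish effective sample size $n_\mathrm{eff} = (\sum w)^2 / \sum
w^2$, the standard survey-statistics notion of how many equally weighted
observations the band is worth. Equal weights over $k$ fractions give
exactly $k$.

## Band trimming and the common window

Sequencing coverage at the extreme tails of a band differs between
gradients, so each OTU's profiles are trimmed to a common density window
before comparison. Per gradient, the window is the density-contiguous run
of fractions, anchored at the peak-mass fraction, where mass stays at or
above `band_tail_pct` (default 2%) of the peak. The windows of all
gradients being compared for that OTU are then merged.

The merge is the **union** of the per-gradient windows by default. We also
implement the stricter intersection (`window_combine = "intersect"`), but
found it biased: when the labeled band is displaced by more than a fraction
width, the intersection clips the top of the labeled band and the bottom of
the control band, attenuating the estimated shift by roughly a third at
half-labeling and dragging percent-enrichment estimates well below their
true value. The union still trims both tails (nothing beyond any band's 2%
support is kept), still evaluates every profile over identical densities,
and leaves the shift estimate unbiased; it is therefore the default.
Within the window, masses are renormalized to percent of the OTU's DNA
("reintegrated"); we interpret reintegration as this renormalization, the
only operational reading consistent with percentages per fraction.

## Pooled controls, Welch's test, and the decision rule

Unlabeled nitrogen does not change buoyant density, so all of an OTU's
control fractions — over every substrate and light level — are pooled into
one weighted density estimate, giving a well-constrained mean and variance
for its native DNA. Each labeled treatment is then compared to that pooled
control with Welch's *t*-test on the weighted summaries:
$$t = \frac{\bar\rho_L - \bar\rho_C}
           {\sqrt{s_L^2/n_L + s_C^2/n_C}},$$
with Welch–Satterthwaite degrees of freedom and $n$ the Kish effective
sizes. The test is one-sided for a positive shift by default:
incorporation of a heavy isotope can only increase density, so the
two-sided option (available via `alternative`) spends power on a direction
that is physically impossible. Zero-variance ties give $p = 1$;
zero-variance separated means are reported as degenerate with a warning
rather than silently dropped.

Comparisons whose labeled or pooled-control band carries fewer than
`min_otu_reads` (default 500) reads are excluded *before* the
Benjamini–Hochberg step, so they never dilute the testing family. BH is
applied at FDR 0.1 over all remaining OTU × treatment tests of the run. A
positive call finally requires all three of:

* $q \le$ `fdr` (default 0.1),
* a positive shift, and
* percent enrichment $100\,\Delta\rho / \Delta\rho_{max} \ge$
  `min_percent` (default 30%, the precedent threshold for nitrogen SIP;
  set 0 for a pure-FDR mode).

The conjunction is deliberate: the FDR step controls false discovery under
sampling noise, while the percent rule guards against statistically firm
but biologically negligible shifts. $\Delta\rho_{max}$, the density gain
at 100 atom% ¹⁵N, defaults to 0.016 g ml⁻¹ and is configurable; percent
enrichment is a linear proxy for atom fraction, not a quantitative
growth-rate model.

## What the simulator emulates — and what it does not

`simulate_sip_experiment()` generates the full set of pipeline tables with
the statistical structure the analysis assumes:

* an even density grid from 1.77 down to 1.66 g ml⁻¹ over 50 fractions,
  read with refractometer noise (sd 2×10⁻⁴ g ml⁻¹);
* Gaussian equilibrium bands (sd 0.006 g ml⁻¹) centered at the classic
  linear GC relation $\rho = 1.660 + 0.098\,GC$ plus
  $\Delta\rho_{max} \cdot a$ for an OTU at atom fraction $a$; band mass is
  integrated exactly over each fraction's density interval;
* community abundances drawn lognormal (sdlog 0.75) — moderately
  heavy-tailed, representative of amplicon libraries after the customary
  upstream removal of rare OTUs — and GC uniform on [0.35, 0.65];
* multinomial reads per fraction (default 20,000, a typical per-sample
  MiSeq depth) proportional to OTU mass, with fractions under 0.01 ng
  measured DNA left unsequenced, as template-poor fractions fail to
  amplify;
* bulk-DNA quantification with 5% multiplicative (lognormal) noise on a
  2000 ng load, and IRMS atom% observations built by inverting the tracer
  rate equation, with optional Gaussian instrument noise.

It does **not** simulate PCR/primer bias, sequencing error or chimeras,
multi-modal bands, diffusion against the gradient, or isotope
fractionation chemistry. Passing tests therefore demonstrate that the
estimator chain is correct and well-calibrated *under the stated sampling
model*; they do not certify robustness to amplification artifacts or
non-Gaussian banding in real gradients. All randomness flows from one
integer seed, split deterministically per gradient, so every fixture is
reproducible.

Under these conditions the caller is strongly conservative for nulls (the
Welch variance treats the band's physical width as uncertainty, which
dominates the much smaller multinomial noise of the WMD) and detects
half-labeled assimilators with high probability; the percent-enrichment
estimate centers near 50 when atom fraction is 0.5. The test suite checks
an unlabeled 200-OTU community (5,000 reads per fraction) for false calls
and a 50-of-200 half-labeled community for recovery; both run in seconds.

## Tracer uptake rates and the production budget

The uptake module is the standard ¹⁵N tracer formulation. The dissolved
pool enrichment is the spike/ambient mixing ratio
$(S A_{spike} + C A_{nat})/(S + C)$ with natural abundance 0.366 atom%;
the uptake rate is
$$\rho = \frac{A_{tf} - A_{t0}}{A_{diss} - A_{t0}} \cdot \frac{PN}{t},$$
floored at zero (with a warning) when instrument noise sends the numerator
negative. IRMS size-effect and drift corrections are applied as a linear
standards-based model, $corrected = raw - (a\,size + b\,drift)$, with
coefficients fit by least squares from reference standards — the simplest
correction consistent with routine IRMS practice. 24 h incubations are
treated as net daily rates.

Volumetric rates are depth-integrated by the trapezoidal rule, extending
the shallowest measurement unchanged to the surface (standard oceanographic
practice) and stopping at the deepest sampled depth — here the 1% light
level at 35 m; both bounds are configurable. The budget divides production
into *new* (nitrate uptake + N₂ fixation) and *regenerated* (ammonium +
urea) nitrogen:
$$f = \frac{\rho_{NO_3} + \rho_{N_2}}
           {\rho_{NO_3} + \rho_{N_2} + \rho_{NH_4} + \rho_{urea}},$$
and converts N to supportable C fixation at Redfield stoichiometry
C:N = 106:16. When a published total production differs from the component
sum because of rounding, `f_ratio(total = )` accepts the reported total as
the denominator; `n_budget()` itself always normalizes fractions to the
computed total so they close to 1.

## Numerical choices and limitations

* Thresholds (`min_fraction_reads` 100, `min_otu_reads` 500,
  `min_band_fractions` 3, `band_tail_pct` 2%, `min_effective_n` 2) are
  explicit arguments, logged in the fit object, and chosen so that a band
  informative enough to test is also wide enough for the
  Welch–Satterthwaite approximation to be meaningful.
* Single-fraction bands get variance 0 and effective n 1 and are flagged
  low-information rather than erroring.
* Exclusions (`no_control`, `band_undefined`, `low_reads`,
  `low_effective_n`) are reported per comparison with reasons, never
  silently dropped, and excluded tests never enter the BH family.
* The per-OTU comparison is strictly within-OTU, so GC-driven density
  differences between organisms never enter a test statistic.
* The percent-enrichment proxy assumes the linear density–atom-fraction
  relation of the simulator; real full-label shifts vary somewhat with
  genome composition, which is why the quantity is a screening index, not
  an atom-fraction measurement.
* Test and acceptance simulations use 200-OTU communities with 1 labeled
  and 3 control gradients per treatment — large enough for stable operating
  characteristics while keeping the whole suite inside a few seconds.

## Worked example

```{r example}
trt <- data.frame(substrate = "NH4", light_level = "50")
cfg <- sim_config(seed = 42)
community <- simulate_community(
  40, trt, assimilators = list(NH4.50 = sprintf("otu_%03d", 1:8)),
  atom_fraction = 0.5, config = cfg)
sim <- simulate_sip_experiment(community, cfg, controls_per_treatment = 3)

fit <- sip_enrich(sim$counts, sim$fractions, sim$otus)
fit
summary(fit)
```

```{r budget}
budget <- n_budget(list(urea = 3.4, NO3 = 3.1, NH4 = 2.4, N2 = 0.19))
budget
```
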