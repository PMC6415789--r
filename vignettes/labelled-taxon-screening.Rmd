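---
title: "Screening DNA-SIP experiments for labelled taxa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening DNA-SIP experiments for labelled taxa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siplabel)
```

## The statistical model

A DNA-SIP screening design yields, per treatment, four amplicon samples: the
light and heavy gradient fraction of a ¹²C control incubation and of a ¹³C
incubation. For each taxon this gives a pair of 2×2 tables, one per isotope
stratum, with cells (G_H, nG_H, G_L, nG_L): reads belonging / not belonging
to the taxon in the heavy / light fraction sample. The per-stratum odds
ratio OR = (G_H/nG_H)/(G_L/nG_L) measures how strongly the taxon's reads
favour the heavy fraction. Isotope labelling should raise OR in the ¹³C
stratum only, so the screen tests *homogeneity of the two odds ratios* with
the Breslow-Day statistic:

* the Mantel-Haenszel common odds ratio ψ = Σ_s(a_s d_s/N_s) / Σ_s(b_s c_s/N_s)
  pools both strata;
* in each stratum the fitted focal-heavy count ã solves
  ψ = ã(N − r₁ − c₁ + ã) / ((r₁ − ã)(c₁ − ã)), with r₁ the heavy-sample
  total and c₁ the taxon's column total;
* the statistic Σ_s (a_s − ã_s)² / Var_s, with
  Var_s = (1/ã + 1/(r₁−ã) + 1/(c₁−ã) + 1/(N−r₁−c₁+ã))⁻¹, is referred to
  χ²(strata − 1); two strata give 1 degree of freedom.

The sampling model this assumes — each sample an independent multinomial
draw over taxa, so each taxon's four counts are product-binomial with margins
fixed at the sample totals — is exactly what amplicon sequencing of pooled
fraction DNA produces, which is why raw counts are used without rarefaction
or relative-abundance transformation: subsampling would only discard
information, and the test's power grows with per-sample depth.

Family-wise error over the n tested taxa of a treatment is controlled by
Holm's step-down rule with the strict inequality p(k) < α/(n + 1 − k): the
k-th smallest p-value is compared to its threshold and the procedure stops
at the first failure. Significant taxa are classified by the direction of
the odds-ratio difference: OR(¹³C) > OR(¹²C) ⇒ *labelled*, the reverse ⇒
*unlabelled* (displaced toward the light fraction), exact equality ⇒ no
direction.

## Decisions taken where the procedure is underdetermined

Several details of such a screen are not fixed by the test itself; the
package's choices are:

* **Zero cells.** Taxa absent from one fraction produce zero cells, where
  the odds ratio and the Breslow-Day variance degenerate. The default
  `correction = "haldane"` adds 0.5 to *all four* cells of any stratum table
  containing a zero — applied identically to the per-stratum ORs, the
  Mantel-Haenszel pooled OR and the Breslow-Day inputs — keeping every taxon
  testable without discarding rare organisms. `correction = "strict"`
  refuses such tables instead.
* **Which taxa enter the family.** `min_total = 0` tests every taxon with at
  least one read across the four samples; taxa with zero reads everywhere
  are skipped (they carry no information), and the Holm n is the number of
  taxa actually tested. A `min_total` threshold is available because
  tiny-count Breslow-Day statistics are unstable, but it is off by default.
* **Granularity.** Tests run per OTU; aggregation to a higher rank happens
  *after* the calls (`aggregate_labelled_taxa()`), summing ¹³C-heavy reads
  of labelled taxa per group and normalising over labelled taxa.
* **Ties and determinism.** Holm ranks break p-value ties stably by
  lexicographic `otu_id`; a p-value exactly equal to its threshold is *not*
  rejected; equal odds ratios yield direction `none`. Output rows are
  ordered by Holm rank.
* **Tarone's adjustment** to the Breslow-Day statistic is implemented but
  off by default; the classical statistic is the reference behaviour.
* **Report stars.** The report's significance stars (`*`, `**`, `***`) are
  Holm-adjusted decisions recomputed at α = 0.05, 0.01, 0.001 — not raw-p
  bins — so a starred row is one that survives the full step-down at that
  level.

## Numerical choices

The fitted count ã is the admissible root of a quadratic; the closed form
handles ψ = 1 (the linear case r₁c₁/N) separately and selects the root
inside [max(0, r₁ + c₁ − N), min(r₁, c₁)]. The test suite and the acceptance
script verify the closed form against an independent `uniroot()` search to
1e-12 on randomized Haldane-corrected tables (agreement is ~1e-12, bound
1e-8). The statistic is clamped at 0 against floating-point jitter for
exactly homogeneous strata. Degenerate margins (an empty row or column in a
stratum) raise a classed error pointing at the correction policy rather than
returning NaN.

## What the simulator emulates

`simulate_community()` + `simulate_sip_experiment()` generate the study
conditions the screen assumes:

* **Community**: lognormal relative abundances (`sdlog = 2`, long-tailed, as
  in real 16S surveys with thousands of OTUs); default 500 taxa for
  statistical tests, 12,000 for the capacity check.
* **Buoyant density**: ρ = 1.660 + 0.098·GC + 0.036·AFE g mL⁻¹ — the
  standard linear GC dependence of CsCl buoyant density plus a full-labelling
  (¹³C atom fraction excess, AFE = 1) shift of 0.036 g mL⁻¹.
* **GC content**: uniform on (0.30, 0.50) by default. This window is implied
  by the fraction pair the screen targets: a light fraction at 1.700 g mL⁻¹
  represents the unlabelled community only if that community bands near it,
  i.e. GC ≈ 30–50%; in practice sequencing fractions are chosen where the
  community's DNA actually bands, and groundwater communities rich in
  reduced-genome candidate-phyla organisms sit in this low-to-mid GC range.
* **Gradient**: 12 equal fractions over 1.66–1.78 g mL⁻¹ (left-closed bins,
  so the selected densities 1.700 and 1.725 each fall in exactly one
  fraction); within-taxon band spread Gaussian with σ_ρ = 0.006 g mL⁻¹,
  truncated to the gradient and renormalised.
* **Sequencing**: each of the four samples is an independent multinomial
  draw of 50,000 reads from its fraction's abundance-weighted composition.
  The ¹²C samples are built with every atom excess forced to zero, so the
  control is generatively identical whether or not taxa are flagged
  labelled; labelling a taxon defaults to AFE = 1 (fully labelled substrate,
  >97 atom% ¹³C), and 5% of taxa are labelled by default.

Under this model the package's own validation (test suite and
`scripts/acceptance.R`) finds per-taxon type-I error ≈ 0.05 on null
experiments (2,000+ taxon-tests with expected heavy count ≥ 10), power ≥ 0.9
for fully labelled taxa above 0.5% relative abundance at 50,000
reads/sample, and ≤ 1 falsely labelled taxon per experiment after Holm
correction (20 seeds each).

What the simulator does **not** emulate — and what passing tests therefore
do not establish about real data: PCR and primer bias, chimeras,
replicate-level biological variance (samples are pooled, as in the
pooled-ultracentrifugation design), gradient formation physics, qPCR-weighted
per-fraction abundances, and cross-feeding (an organism labelled via
metabolites of a degrader is indistinguishable from the degrader — a known
limit of DNA-SIP itself). Two systematic effects the model *does* reproduce
are worth knowing: strongly labelled DNA displaces unlabelled taxa from the
heavy fraction, so truly unlabelled organisms can be *significantly* called
`unlabelled` — that is a real compositional effect, not an error; and a
fully labelled high-GC taxon can band *above* the heavy fraction, escaping
a two-fraction screen — power claims hold for the GC window the fractions
were chosen for.

## Enzyme and carbon-budget companions

The fluorometric assay chain converts plate-reader MUF fluorescence to
activities: OLS standard curve (refusing non-positive slopes), point-wise
inversion (negative back-calculated concentrations near the blank are kept,
not clipped, so null assays stay unbiased), OLS rate over the full series by
default (a maximum-slope sliding window is available for substrate-depleted
late phases), optional point-wise blank subtraction, and the unit chain
µM h⁻¹ × assay volume (default 200 µL: 50 µL sample + 50 µL substrate +
100 µL buffer) → mol h⁻¹ → amol h⁻¹ per 16S gene copy.

The carbon-budget helpers use the anhydro-sugar monomer basis (162.14 g/mol,
6 C) at natural isotope abundance — the convention under which 150 mg of
glucan is 5.55 mmol C; the ¹³C-enriched monomer mass (~168 g/mol) is *not*
used for dose arithmetic. The summary-statistics t-test defaults to Welch's
unequal-variance form with Welch-Satterthwaite degrees of freedom (the
pooled-variance Student flavour sits behind `var_equal = TRUE`), with n = 5
replicates per treatment as the working default of the microcosm design.

## Problem sizes

The test suite and acceptance script run: 100 randomized tables for the
Breslow-Day oracle check; null calibration until 2,000 qualifying
taxon-tests (≈ 14 experiments of 500 taxa); 20 seeds × 500 taxa for power;
1,000 random p-vectors for Holm; one 12,000-taxon screen for capacity. The
whole suite completes in well under a minute on a single core.
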