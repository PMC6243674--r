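---
title: "Transcriptome SIP: model, simulator and enrichment factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptome SIP: model, simulator and enrichment factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sipef)
```

## The problem

RNA stable-isotope probing feeds a microbial community a ^13^C-labeled
substrate. Organisms that assimilate the substrate synthesize RNA whose
buoyant density is measurably higher, so isopycnic centrifugation in a
CsTFA gradient physically separates the RNA of active consumers ("heavy"
fractions) from the rest ("light" fractions). Sequencing total RNA from
heavy and light pools of a labeled and an unlabeled control incubation —
four libraries — lets one ask, feature by feature, *who consumed the
substrate* (rRNA taxa) and *which genes they expressed while doing so*
(mRNA transcripts).

`sipef` implements the downstream arithmetic of such an experiment on
pre-classified count tables, and a synthetic generator of the entire
experiment with known ground truth. The generator is not a convenience
fixture: it is the package's instrument for validating the enrichment
statistic by parameter recovery, and is tested to the same standard as the
analysis code.

## The enrichment factor

For a feature with relative abundances $h_{13}, l_{13}$ in the heavy and
light pools of the ^13^C gradient and $h_{12}, l_{12}$ in the control
gradient,

$$EF = \frac{h_{13}}{l_{13}} - \frac{h_{12}}{l_{12}}.$$

The second ratio is the feature's *intrinsic* density behavior — GC-rich
RNA bands slightly heavier even without labeling — so subtracting it
isolates the isotopic shift. $EF > 0$ is interpreted as labeled; $EF < 0$
as preferential detection in the light fraction. EF is strictly increasing
in $h_{13}$, strictly decreasing in $l_{13}$, antitone in $h_{12}$, and
exactly 0 whenever the two ratios agree, at any abundance scale.

Choices the formula leaves open, and what this package does:

* **Normalization basis.** "Relative abundance" needs a denominator. Taxa
  are normalized to the library's SSU rRNA reads, transcripts to its
  mRNA-identified reads, matching the separate treatment of the two read
  populations; reads not classifiable at the requested lineage level form
  an explicit `unclassified` bucket that stays in the denominator but is
  never ranked. A `classified_only` flag provides the other convention.
* **Zeros.** A feature absent from a light pool would have an infinite
  ratio. Rather than report infinities, `ef_ranking()` adds a
  pseudo-abundance — by default half the smallest nonzero proportion in
  the four libraries — to all four terms; with `pseudo = 0` such features
  are reported as `undefined`.
* **Hierarchy.** EFs at a coarser level (family, pathway) are computed
  from counts re-aggregated at that level. Ratios do not average: a family
  EF is *not* the mean of its genus EFs, and the test suite pins a
  counter-example.
* **Filters.** Taxa are reported above 1% mean relative abundance
  (strictly `> 0.01`, so exactly 1% is dropped); transcripts at `>= 20`
  total reads (20 kept, 19 dropped). The mean is taken over the four
  libraries of the analyzed set. Amplified and unamplified libraries are
  never mixed within one EF.
* **Calling.** EF is semi-quantitative; no significance test is attached.
  Where the pipeline must produce a binary call (the run summary's
  confusion counts), a feature is called labeled when its EF exceeds
  `ef_call = 1` *and* it passes the reporting filter. One full ratio unit
  is far above the counting-noise scale of well-sampled features, and
  below the filter a handful of reads can produce arbitrarily large noise
  ratios; in null simulations (no labeled taxa) this rule produces no
  calls in ≥ 19/20 seeds.

## The generative model

`simulate_experiment()` chains six stages, each independently seeded from
the root seed (`derive_seed()`), so any stage can be reproduced alone.

**Community** (`make_community`). $n$ taxa with abundances from a
symmetric Dirichlet($0.5$) — heavy-tailed, so a few families dominate, as
in real contaminated-aquifer communities; exactly $k$ taxa are fully
labeled ($\alpha_{13C} = 1$). rRNA GC ~ N(55, 2) truncated to (45, 65).
Each taxon expresses 3–6 transcripts drawn from a shared function pool
(so pathways recur across taxa) with Dirichlet(0.7) expression weights;
transcript GC ~ N(55, 5) truncated to (40, 70). Read classes default to
(SSU, LSU, mRNA, other) = (0.35, 0.64, 0.009, 0.001): rRNA dominates a
total RNA library and roughly 1% of reads are non-ribosomal.

**Buoyant density** (`density_model`, `mean_density`). Linear in the
^13^C atom fraction and GC:
$\rho = \rho_0 + \Delta_{max}\,\alpha + \gamma\,(GC - GC_{ref})$, with
$\rho_0 = 1.7785$ and $\Delta_{max} = 0.0475$ g/ml calibrated so that
unlabeled and fully labeled RNA band at 1.7785 and 1.8260 g/ml — the
midpoints of typical ^12^C-light (1.778–1.779) and ^13^C-heavy
(1.824–1.828) pool windows; $\gamma = 4\times10^{-4}$ g/ml per GC%
(a weak effect, consistent with a ~1.5% GC rise across a 0.05 g/ml
density span) around $GC_{ref} = 55$; within-species band SD
$\sigma = 0.008$ g/ml spreads a species over 2–3 of 7 fractions.

**Fractionation** (`fractionate`). The gradient spans 1.750–1.855 g/ml in
7 equal fractions (width 0.015), collected densest-first. Each species'
mass in a fraction is the Gaussian integral over the fraction's density
interval, renormalized over the span so the loaded mass (default 1500 ng
per gradient) is conserved; a span that fails to cover every band mean
±3σ triggers a warning. The span is chosen exactly wide enough that the
default bands — including GC extremes — satisfy that coverage rule.

**qPCR** (`simulate_qpcr`). Fraction RNA is quantified with multiplicative
lognormal noise, mean-unbiased, CV 0.2 by default; the measured signal is
expressed on the ng scale (a calibrated assay) so mass thresholds can act
on it.

**Pooling** (`select_pools`). Direct sequencing of total RNA needs a
minimum pooled mass (~120 ng). Pools grow greedily from a gradient end
inward until the cumulative *measured* mass reaches the threshold:
^13^C-heavy from the dense end among fractions at or above the 1.815 g/ml
cutoff, ^13^C-light from the light end, and both ^12^C pools without a
cutoff — unlabeled RNA never reaches the heavy window, so the control
takes the *heaviest fractions from which sufficient RNA can be obtained*.
When a ^13^C gradient has no labeled RNA either (a null experiment), the
pipeline applies the same relaxation and records it. Duplicate gradients
are merged by density, not by fraction index, before selection (fraction
densities need not align across replicate tubes); density ties break
toward the lower fraction index (the heavier collection position). Fixed
density `windows` can replace the greedy rule when pool composition must
stay comparable across experiments.

**Reads and amplification** (`sample_reads`,
`apply_amplification_bias`). Reads are multinomial at depth $10^5$ by
default — real libraries run to tens of millions of reads, but the
relative-abundance structure, which is all the EF uses, is preserved at
this size, and the full test suite stays inside interactive runtimes.
Probabilities are proportional to pooled species mass × class mix ×
(for mRNA) expression weight. Linear amplification is modeled as a
GC-tilt on mRNA proportions, $w \propto \exp(-\kappa\,(GC - 50))$,
followed by multinomial resampling at the same depth; rRNA is untouched,
and $\kappa = 0$ is the identity. For a normal GC spread the tilt shifts
the mean by $-\kappa\sigma_{GC}^2$; the default $\kappa = 0.1$ per GC%
therefore produces an expected mRNA GC reduction around 2%, the magnitude
reported for MessageAmp-style amplification. The ≥300-fold mass gain of
amplification affects input mass, not counts, and is kept as metadata.

## What the simulator does and does not emulate

It emulates the *statistical* structure: dominance of a few families,
complete labeling of a subset of taxa, density separation with GC
confounding, minimum-mass pooling constraints (including the asymmetric
control-pool problem), the rRNA/mRNA read-class mix, undetectably rare
features, and amplification GC bias. It does not emulate nucleotide
sequences, classifier error (reads are assigned to their true feature),
chimeras, partial labeling heterogeneity within a taxon, tRNA (the
`other` class is unstructured), or depth-dependent library composition
biases. Passing parameter-recovery tests therefore demonstrates the
correctness and sensitivity of the statistic under the stated generative
assumptions — not robustness to misclassification, which happens upstream
of this package's inputs.

## Validation experiments

The acceptance suite runs these experiments at fixed seed sets:

* **Recovery.** 20 taxa, 5 labeled, depth $10^5$, adaptive pools: in
  ≥ 19/20 seeds, every *detected* labeled taxon's genus EF is positive
  and exceeds every unlabeled taxon's EF. (The Dirichlet prior
  occasionally draws a labeled taxon at ~$10^{-6}$ abundance; an organism
  that yields zero reads has no EF row, so recovery is assessed over
  detected taxa.) Null runs (no labeling) produce no labeled calls at the
  default thresholds.
* **Dose response.** With pooled density windows held fixed (heavy =
  upper four fractions, light = bottom two), the median labeled-taxon EF
  increases strictly across $\alpha \in \{0, 0.5, 1\}$. Windows are fixed
  because comparing EFs across labeling levels requires comparable
  density ranges: adaptive selection is infeasible above the heavy cutoff
  at low $\alpha$, and with the narrow adaptive windows the statistic
  saturates (a fully separated band leaves zero labeled reads in the
  light pool at any $\alpha \geq 0.5$, hiding the dose).
* **Diversity.** Shannon (natural log) of the ^13^C-heavy library is
  below the ^13^C-light library in ≥ 95% of seeds — only the labeled
  subcommunity reaches the heavy fractions. Chao1 uses the
  bias-corrected form $S_{obs} + F_1(F_1-1)/(2(F_2+1))$, defined even
  without doubletons. No rarefaction is applied; library depth is
  recorded so users can subsample upstream if needed.
* **Amplification.** Across 20 seeds the amplified libraries' mRNA GC is
  lower than their unamplified counterparts (sign test, p < 0.05), SSU GC
  is exactly unchanged, and $\kappa = 0$ produces no shift.

## Numerical and degenerate-input choices

* Gaussian band integrals use `pnorm` differences; tests verify them
  against an independent composite-trapezoid quadrature on a $10^4$-point
  grid to $10^{-6}$, and per-species mass conservation to $10^{-9}$.
* A band centred exactly on a fraction boundary splits its mass equally
  between the adjacent fractions (up to span truncation).
* Zero-variance inputs to the paired t-test are handled explicitly
  (all-zero differences: $t = 0, p = 1$; nonzero mean: $p = 0$ reported
  as an explicit edge rather than an error).
* GC is carried per feature and count-weighted, not per read: count
  tables are the exchange format, and per-read GC is classifier-level
  detail that never reaches this package.
* All randomness is a pure function of `(inputs, seed)`; per-stage
  sub-streams come from a string-hash of the stage name, so re-running a
  single stage from intermediate files reproduces downstream outputs
  exactly (`run_pipeline` outputs are byte-identical across runs).
* p-values from the accounting t-tests are reported raw; with three
  planned comparisons in the motivating design there is no
  multiple-testing correction to apply.

## Known limitations

* EFs carry no uncertainty: with one library per pool there are no
  replicates, and the package deliberately does not bootstrap counts
  (resampling a multinomial cannot recover between-gradient variance).
* The pseudo-abundance rule bounds, rather than estimates, ratios for
  light-absent features; their EF magnitudes are floor-dependent and
  should be read as "large", not as point estimates.
* The density model is linear and species-homoscedastic; real gradients
  show mild curvature and fraction-to-fraction volume variation that the
  simulator does not reproduce.
* `run_pipeline`'s confusion counts treat filtered-out rare labeled taxa
  as missed (false negatives); that is a property of the reporting
  filter, not of the EF.

```{r example}
exp <- simulate_experiment(run_config(seed = 7))
ef <- ef_ranking(unamplified(exp$libraries), "taxon", "genus")
head(as.data.frame(ef)[, c("feature_id", "ef", "mean_rel_abundance")], 5)
```
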