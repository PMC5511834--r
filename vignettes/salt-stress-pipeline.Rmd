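---
title: "Evaluating salt-stress treatments and screening salt-responsive genes"
author: "saltstress package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating salt-stress treatments and screening salt-responsive genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltstress)
```

# The analysis in one paragraph

A salt-tolerance screening experiment has two coupled questions. First, *which
treatment condition should be used at all* — which NaCl concentration, applied
for how long, stresses the plant strongly enough to separate tolerant from
sensitive material without simply killing it? Second, given tissue from the
chosen condition, *which genes and pathways respond*? This package implements
the full desk-side analysis: multi-criteria ranking of candidate conditions
from physiological indicator panels (TOPSIS), FPKM-based differential-
expression calling with an FDR-controlled filter cascade, hypergeometric
pathway over-representation, expression-profile clustering for heat maps, and
2^−ΔΔCt qPCR verification. Because raw measurements from such experiments are
rarely published, the package ships a seeded synthetic-data generator with
planted ground truth for every stage; all claims the test suite makes are
claims about recovering that planted truth.

# Ranking treatment conditions

## Indicator screening

Candidate conditions (say 0–250 mM NaCl, or 7–23 d of treatment) are scored on
a panel of physiological indicators: plant height and leaf blade number (which
fall under stress) and the antioxidant enzyme activities POD, SOD and CAT
(which rise). `pearson_screen()` correlates each indicator with the numeric
treatment level and reports Pearson r, a two-sided p-value from the t
approximation with $m-2$ degrees of freedom, and the conventional `**`
(p < 0.01) / `*` (p < 0.05) tiers. Indicators with p < 0.05 are flagged as
selected. A zero-variance indicator has no defined correlation; it is reported
as `NA` with a `degenerate` flag rather than silently treated as 0.

## TOPSIS

`topsis()` ranks the $m$ conditions on the $n$ selected indicators by the
Technique for Order Preference by Similarity to Ideal Solution:

1. decision matrix $x_{ij}$ (condition $i$, indicator $j$), all entries
   positive in native units;
2. vector normalization $r_{ij} = x_{ij} / \sqrt{\sum_i x_{ij}^2}$ — each
   column gets unit Euclidean norm, making units comparable;
3. weighting $v_{ij} = w_j\, r_{ij}$ with $\sum_j w_j = 1$;
4. ideal solutions: per criterion, $A^+_j$ is the best weighted value across
   conditions (max for a benefit criterion, min for a cost criterion) and
   $A^-_j$ the worst;
5. separations $d_i^\pm = \sqrt{\sum_j (v_{ij} - A^\pm_j)^2}$;
6. relative closeness $R_i = d_i^- / (d_i^+ + d_i^-)$, ranked descending.

Some notational conventions in the literature conflate the alternative and
criterion indices across steps 3–5; this implementation uses the only
self-consistent reading — normalization runs over alternatives within a
criterion, distances run over criteria within an alternative — which is also
the reading that reproduces published worked examples.

Design choices made where the method leaves room:

* **Weights.** Published condition-evaluation tables rarely disclose the
  weight vector. The default is equal weights $1/n$, the only defensible
  choice absent disclosure; any weight vector summing to 1 can be supplied.
  With noiseless monotone indicators the top rank is invariant to the choice
  (the extreme stress condition attains the ideal on every criterion).
* **Orientation.** Whether an indicator is benefit or cost is inferred by
  default from the sign of its Pearson correlation with the treatment level
  (`orientations = "auto"`): enzyme activities correlate positively and are
  treated as benefit, growth traits negatively and are treated as cost. This
  makes "closeness to the ideal" mean "strength of the stress response",
  which is what a tolerance screen wants to maximize. Explicit per-criterion
  orientations override the inference.
* **Ties.** Rank ties in $R$ are broken by smaller $d^+$, then input order —
  ranking is fully deterministic.
* **Rounding.** Report tables round half-up to 4 decimal places, matching the
  convention of published tables; fitted objects keep full precision.

The scale-invariance of $R$ (multiplying a raw indicator column by any
positive constant changes nothing, since normalization divides it out) and
the orientation-reversal property (flipping every criterion's orientation
exactly reverses the ranking, since $A^+$ and $A^-$ swap and $R \mapsto 1-R$)
are verified as properties in the test suite.

# Differential expression

The pipeline's entry point is a gene-level count matrix with gene lengths and
a two-condition, three-replicate design. `de_analysis()` computes

* **FPKM** $= c_{gs} \cdot 10^9 / (\ell_g \cdot N_s)$ with $N_s$ the column
  sum of counts — counts are the declared entry point, so no mapped-read or
  effective-length refinement is attempted;
* **log2 ratio** of condition-mean FPKM with a pseudocount of 0.125 FPKM
  added to both means, keeping ratios finite when one mean is zero while
  preserving the sign of the change;
* a **per-gene variance analysis**: Welch's two-sample t-test on
  log2(FPKM + 1) across replicates. This is the simplest defensible test
  honouring a 3 vs 3 replicated design; it makes no claim of matching any
  particular RNA-seq tool, and `de_analysis(test_fun = ...)` accepts any
  replacement with the same signature. When both groups are constant and
  equal the statistic is undefined and the p-value is 1 by convention
  (flagged); negative-binomial GLM testing is deliberately out of scope;
* **BH adjustment** (`bh_adjust()`, the standard step-up procedure);
* the **filter cascade**: a gene is called up-regulated when
  log2 ratio ≥ +1 *and* p < 0.05 *and* q ≤ 0.001, down-regulated
  symmetrically. Applying the raw-p and the FDR threshold jointly is the
  conservative reading when both are quoted for the same analysis; each
  threshold is configurable.
* the **key-gene screen**: significant genes additionally need FPKM > 0.05
  in at least one condition and |log2 fold change| ≥ 1.

Volcano coordinates use −log10 of the *raw* p-value on the y axis, the
conventional choice. Category tallies (`tally_categories()`) count a gene in
every category it is annotated to and report unannotated genes as
`unclassified`.

# Pathway enrichment

`enrich()` tests each gene set for over-representation of the DE genes with
the hypergeometric upper tail $P(X \ge k)$ for $X \sim
\mathrm{Hyper}(N, K, n)$ — equivalent to the one-sided Fisher exact test and
the standard behind KEGG-style enrichment reports. Two conventions are
exposed for the universe $N$: all genes in the count matrix (what the
pipeline uses, since the synthetic annotation covers every gene), or only
annotated genes, by passing the appropriate `universe` vector. Following the
common practice of reporting raw pathway p-values with a P < 0.05 split, no
multiple-testing correction is applied by default; `adjust = TRUE` switches
the significance flag to BH-adjusted values. Rows are sorted by ascending p
with ties preserving input order. Monotonicity in the set size (padding a
pathway with non-DE genes can only raise its p) is verified as a property.

# Expression profiles

For heat-map display, `expression_profiles()` takes log2(FPKM + 1) of the key
genes, z-scores each row (sample standard deviation, $n-1$; constant rows are
dropped with a warning because they have no scale), and clusters rows with
average linkage on Euclidean distance — a common heat-map default; both are
configurable. Rows are sorted by gene id before clustering so that the
dendrogram is invariant to input order even in the presence of tied
distances. Direction (up/down) is the sign of the log2 ratio, and agrees with
the DE status for every significant gene by construction. The dendrogram
exports to Newick via `write_newick()`.

# qPCR verification

`ddct()` implements 2^−ΔΔCt relative quantification: technical-replicate Ct
values are arithmetically averaged within each gene × group before any
differencing (the usual convention; a geometric alternative is deliberately
not offered), ΔCt = Ct(target) − Ct(reference) per group,
ΔΔCt = ΔCt(salt) − ΔCt(control), fold = 2^−ΔΔCt. Amplification efficiency is
fixed at 2 — that is what the method's name asserts — so no standard-curve
correction is applied. The reference gene is kept in the output as a trivial
row with fold exactly 1, a quick sanity check on the normalization.
`concordance()` calls a gene concordant when the sign of its qPCR log2 fold
agrees with the sign of its RNA-seq log2 ratio, and reports the concordant
fraction; genes present on only one platform are excluded and listed.

# The synthetic-data generator

Every input is generated, seeded, with planted truth:

* **Indicator panels** (`gen_indicator_panel()`): linear trends per indicator
  across the treatment levels — growth down, enzymes up — with additive
  Gaussian noise truncated just above zero (activities and heights are
  non-negative). `noise_sd` is expressed in units of each criterion's
  per-step effect so one knob is meaningful across criteria; the default 0.3
  gives visibly noisy but clearly monotone panels. At `noise_sd = 0` every
  indicator is exactly linear in the level index, so its Pearson r is ±1 and
  the TOPSIS winner is the extreme stress level for any positive weights.
  Default levels 0–250 mM NaCl in steps of 50; baselines and steps are set
  to plausible tomato-seedling values (height 12 cm falling 1.6 cm per step,
  POD/SOD/CAT activities rising tens of units per step).
* **Counts** (`gen_count_matrix()`): log-normal baseline abundances,
  negative-binomial counts with mean `lib_size × abundance` (Poisson at
  dispersion 0). DE genes are planted with fold change $2^{\pm\mathrm{lfc}}$.
  Because FPKM normalizes by the realized column sum, planted ratios are only
  exact if the expected total fragment flow matches between conditions; the
  generator achieves this by rescaling the baseline abundances of the down
  set so the up-shift and down-shift cancel exactly. The rescaling is applied
  to both conditions, so it changes no gene's ratio. With a single DE
  direction no such balance exists and treated totals drift by the planted
  signal. Defaults — 2000 genes, 10% DE, |lfc| = 3, 39.5% of DE genes up,
  dispersion 0.01, 2×10⁷ fragments per sample — describe a strong,
  down-dominated salt response in low-variability pooled seedling material;
  they were chosen once as a realistic strong-response scenario in which a
  3 vs 3 t-test has useful power against the stringent q ≤ 0.001 cascade.
* **Pathways** (`gen_pathways()`): enriched pathways draw half their members
  (configurable) from the DE genes — a large, unambiguous excess over the
  10% background — and the rest from the nulls; non-enriched pathways sample
  uniformly from all genes, so their DE overlap is exactly hypergeometric
  under the null and the nominal test level is interpretable.
* **Ct tables** (`gen_ct_table()`): per-gene control baselines uniform in
  23–29 cycles, a salt-group shift of −(signed lfc) cycles (one PCR cycle per
  doubling), a reference gene fixed at 20 cycles, Gaussian cycle noise
  (default sd 0.2, a typical technical scatter). At zero noise the
  round-trip through `ddct()` returns planted folds exactly.

One global seed feeds per-generator substreams (a deterministic hash of the
generator name), so changing one generator's parameters never perturbs
another's draws, and the whole pipeline is bit-reproducible for a fixed seed.

What the generator does **not** emulate — and hence what passing tests do not
show about real data: compositional/normalization artefacts beyond library
size, GC and length bias, batch effects, outlier samples, correlated genes,
overlapping real pathway structure, annotation incompleteness, or
amplification-efficiency differences between primers. Recovery rates on
planted truth are upper bounds on what the same thresholds achieve on real
experiments.

# Validation problem sizes

The test suite and the acceptance script validate at desk scale, chosen so the
full suite runs in well under a minute per stage: worked TOPSIS examples at
m = 5–6 alternatives; the hypergeometric implementation against exhaustive
combinatorial enumeration for every valid configuration with N ≤ 30 (tens of
thousands of cases); BH against the step-up definition on 1000 random
p-vectors of lengths 1–500; planted-truth DE recovery on 1000 genes at
dispersion 0 and |lfc| = 4 (sensitivity ≥ 0.95, null false-positive rate
≤ 0.05 under the full cascade); enrichment flag rates over 100 simulated
collections of 25 pathways; and exact qPCR round-trips. These sizes are the
package's own validation choices; all scale linearly if larger checks are
wanted.

# Known limitations

* The DE test is a log-FPKM t-test, underpowered relative to
  negative-binomial likelihood methods at small fold changes and low counts;
  it is a verification baseline, not a replacement for DESeq2/edgeR-class
  tools on real data.
* The q ≤ 0.001 cascade is stringent for 3 vs 3 designs; with realistic
  biological dispersion it will call only strong responders (this is visible
  in the default pipeline run).
* TOPSIS output depends on the weight vector whenever indicators disagree;
  the equal-weight default is a convention, not an estimate.
* Enrichment p-values are raw by default by design; treat the P < 0.05 split
  as descriptive unless `adjust = TRUE` is used.

# End-to-end run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(out_dir = "saltstress_out", seed = 1)
manifest <- run_pipeline(cfg)
res <- attr(manifest, "results")
res$condition_eval$table   # condition ranking
res$de                     # DE summary
res$enrichment             # pathway table
attr(res$concordance, "fraction_concordant")
```

All stage outputs are headered TSV/CSV/GMT, read back by the package's own
readers, and checksummed into `manifest.tsv` for provenance.
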