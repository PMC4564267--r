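---
title: "Cross-disease expression meta-analysis: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-disease expression meta-analysis: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossdeg)
```

`crossdeg` integrates several case/control expression microarray studies
that span related diseases and asks which genes are differentially
expressed across *several* of those diseases at once. This vignette is the
package's own account of the methods: the models and their assumptions,
the parameters that matter, what the simulator does and does not emulate,
and the places where the design was genuinely open and a choice had to be
made.

## The pipeline and its assumptions

The input is one log-scale expression matrix per study (probes × samples),
a case/control label per sample, a probe→gene table per platform, and a
manifest mapping studies to diseases. Expression values are assumed
already normalised and log-transformed as deposited; the package performs
no re-normalisation and rejects missing values outright rather than
imputing them. Gene symbols are matched case-insensitively (upper-cased at
load time) with no alias resolution.

**Probe collapse.** When several probes map to one gene, the probe with
the largest interquartile range of expression across all samples
represents the gene — the IQR rewards probes that actually vary, and the
retained row is one real probe's measurements rather than an average of
probes with different dynamic ranges. Quartiles use linear interpolation
between order statistics (the common "type 7" rule); exact IQR ties keep
the probe appearing first in file order, making the result deterministic.

**Panel intersection.** Different platforms profile different genes, so
all studies are restricted to the common gene set, placed in one C-locale
lexicographic order. Everything downstream assumes this canonical order.

**Rank-sum filtering.** Un-expressed and un-informative genes only
contribute false discoveries. Within each study, genes are ranked by mean
intensity (rank 1 = smallest, average ranks on ties) and the ranks summed
across studies; the `floor(0.30 · G)` genes with the smallest rank sums
are removed as un-expressed. The procedure is then repeated with standard
deviations on the survivors (i.e. the second 30% is taken of the
*post-stage-1* gene count — the two stages are sequential, not parallel).
Mean and SD use all samples of a study, cases and controls alike, because
filtering precedes any group comparison and must not peek at the labels.
Rank-sum ties are broken by gene symbol so removal is reproducible. Both
fractions are tunable (`frac_mean`, `frac_sd`, defaults 0.30); rank 1 is
the *smallest* intensity, which is what makes "smallest rank sum" mean
"least expressed".

**Moderated t.** With tens of samples and thousands of genes, gene-wise
variance estimates are noisy; the empirical-Bayes moderated t-statistic
shrinks each gene's pooled variance toward a prior value $s_0^2$ with
weight $d_0$ (prior degrees of freedom):
$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},\qquad
  t_g = \frac{M_g}{\tilde s_g\sqrt{1/n_1 + 1/n_2}},$$
referred to $t_{d_0+d_g}$. The hyperparameters come from the closed-form
moment method on $z_g=\log s_g^2$: with
$e_g = z_g - \psi(d_g/2) + \log(d_g/2)$, solve
$\psi'(d_0/2) = \mathrm{var}(e) - \overline{\psi'(d_g/2)}$ by Newton
inversion of the trigamma function and set
$s_0^2 = \exp(\bar e + \psi(d_0/2) - \log(d_0/2))$. When the right-hand
side falls below $10^{-8}$ the log-variances are no more dispersed than
sampling noise alone explains, $d_0$ is taken as infinite, and
$s_0^2 = \exp(\bar e)$ (all genes then share one variance and the
reference becomes standard normal). Genes with exactly zero pooled
variance are excluded from the fit but still receive moderated statistics
— shrinkage gives them a positive $\tilde s^2$ whenever $d_0>0$.
P-values are two-sided; ranking ties on identical p-values are broken by
gene symbol so top-$k$ lists are deterministic.

**Similarity profiling.** Each study is summarised by its expression
variation profile, $\mathrm{sign}(t_j)\,\log(p_j)$ per gene: zero for
null genes, large in magnitude for strong differential expression, signed
by direction. The natural log is used; because study profiles are
compared only through *rank* correlations (Kendall tau-b or Spearman),
the base of the log — or flipping the sign convention globally — cannot
change any correlation, a property the tests assert numerically. Studies
are clustered on the dissimilarity $1-r$ with average linkage; the
correlation-vs-distance ambiguity that heatmap tools leave implicit is
made explicit here and recorded in the tree's metadata attributes. Study
order is canonicalised before clustering, so permuting the input yields
the identical tree.

**Common genes.** Two complementary per-study significance criteria are
applied: membership in the top 100 ranked genes (boundary inclusive:
rank ≤ 100), and BH-adjusted p strictly below 0.01. A gene hits a
*disease* if it is significant in at least one of that disease's studies
— a disease with two datasets is never double-counted. Genes hitting at
least 3 diseases under a criterion are selected, and the final list is
the union over the two criteria with per-gene provenance. Increasing $k$,
$\alpha$ or decreasing `min_diseases` can only grow the selection
(monotonicity is property-tested).

**Meta-analysis.** Per gene, the *raw* per-study moderated-t p-values are
combined — combining already-BH-adjusted values would double-correct and
is statistically incoherent, so BH is applied once, across genes, to the
combined p-values of each method. Fisher's $X=-2\sum\ln p_i$ against
$\chi^2_{2k}$ detects genes driven by any one very small study p-value;
the maximum-p statistic $(\max_i p_i)^k$ (the Beta$(k,1)$ upper order
statistic) detects genes consistently small in every study. Before any
logarithm, p-values are clamped to a floor of $10^{-20}$ (configurable):
platform-level p-values below that are not meaningfully distinguishable
and an exact zero would make both the Fisher statistic and the variation
scores infinite.

**Enrichment.** The final gene list is tested against user-supplied GMT
gene sets by the hypergeometric upper tail. The universe defaults to the
post-filter gene panel — the selection was made from that universe, and
testing against the whole genome would manufacture enrichment from the
filtering itself. Sets are restricted to universe members before testing;
sets with no universe member are not tested at all.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `frac_mean`, `frac_sd` | 0.30, 0.30 | fraction of genes removed per filter stage |
| `k` | 100 | top-ranked genes per study (criterion 1) |
| `alpha` | 0.01 | strict BH-adjusted cutoff (criterion 2) |
| `min_diseases` | 3 | diseases a common gene must hit |
| `p_floor` | 1e-20 | clamp before logs (scores, Fisher, max-p) |
| `cor_method` | spearman | profile correlation (kendall also supported) |

## What the simulator emulates — and what it does not

`generate_collection()` exists so that every stage can be validated
against a known truth without downloading anything. Its default design is
six blood datasets over four diseases with the case/control sizes
18/15, 20/11 (RA), 11/6, 21/45 (SLE), 106/33 (OA) and 16/16 (AS), on four
platforms (two shared), mirroring the collection the pipeline was designed
around.

The generative model matches the moderated-t assumptions on purpose, so
that hyperparameter recovery is a meaningful test: gene variances
$\sigma_g^2 \sim s_0^2 d_0/\chi^2_{d_0}$ with $d_0=4$, $s_0^2=0.05$;
log-intensities Normal with per-gene baselines $\mathcal N(7,1)$; cases of
affected diseases shifted by $\delta\sigma_g$ with $\delta=1.5$ and one
sign per gene (configurably mixed across diseases). The default planting
is one 25-gene set affecting three of the four diseases — the shared
signal the common-gene stage must recover — plus a 40-gene
disease-specific signature per disease, which is what makes same-disease
dataset pairs genuinely more similar than cross-disease pairs in the
clustering. 150 "dead" genes with low baseline ($\mathcal N(4,0.3)$) and
near-zero variance give the rank-sum filter something real to remove.

Three generator choices deserve their rationale spelled out:

* **Planted genes are expressed and informative.** Their baselines and
  variances are drawn from the upper ~60% of the null distributions.
  Real disease signatures are, tautologically, transcripts that passed
  exactly this kind of expression/information filter; planting markers in
  the un-expressed tail would only measure the filter, not the detector.
* **Probes are additive.** A probe row is the gene signal plus a constant
  probe offset ($\mathcal N(0, 0.3)$) and small per-cell noise
  (sd 0.05). The offset exercises mean-level probe diversity without
  touching variances; a multiplicative probe gain was deliberately
  rejected because largest-IQR selection would then systematically pick
  high-gain probes and bias the recovered variance prior upward.
* **Planted and dead genes sit on every platform**, while null genes are
  subsampled at the `platform_overlap` fraction (default 0.85). A shared
  marker that is not commonly profiled is undiscoverable by construction;
  what the overlap machinery must be exercised on is the null background.

Under these defaults the post-intersection panel is ≈1 700 genes and
≈850 survive filtering. What the simulator does *not* emulate: microarray
physics (background, saturation), batch effects, non-Gaussian heavy
tails, correlated genes, and probe-level cross-hybridisation. Passing
tests therefore demonstrate that the pipeline's logic and calibration are
correct under its own model assumptions — not that any particular real
collection satisfies those assumptions.

## Numerical choices and degenerate inputs

* IQR quartiles: type 7 (linear interpolation); ties → first probe in
  file order.
* Rank-sum ties → lexicographic gene symbol; gene ordering everywhere is
  C-locale lexicographic, independent of the session locale.
* Trigamma inversion: Newton iteration on the nearly linear scale
  $1/\psi'$, convergence $10^{-12}$ relative, with asymptotic fallbacks
  for extreme arguments; the infinite-$d_0$ threshold is $10^{-8}$.
* P-values are kept strictly positive (floored at the smallest double)
  so BH and log-based scores never receive an exact zero.
* Zero-variance genes: allowed through summaries, excluded from the
  hyperparameter fit, moderated like any other gene.
* Hard errors, never silent repair: missing samples, non-numeric or NA
  cells, duplicate feature/probe ids, empty panel intersections, gene
  universe mismatches in the meta stage, selected genes outside the
  enrichment universe.
* TSV output prints 17 significant digits, so a write/read round trip
  reproduces doubles exactly.

## Validation problem sizes

The shipped checks run at sizes chosen to make their statistical
assertions stable: null calibration of the combined p-values uses 10 000
genes × 6 studies (Kolmogorov–Smirnov distance < 0.02); variance-prior
recovery uses 5 000 simulated gene variances (within 20% of
$d_0=4$, $s_0^2=0.05$); the end-to-end recovery study runs the full
default six-study design over 50 seeds and requires mean sensitivity
≥ 0.8 and mean false-discovery proportion ≤ 0.2 for the planted
three-disease genes, with same-disease dataset pairs clustering as
siblings in ≥ 90% of replicates. Monte-Carlo assertions about an
*expectation* (e.g. that the BH false-discovery proportion at level 0.05
has expectation ≤ 0.05 under a global null — it is exactly 0.05 there,
by the Simes identity) allow two Monte-Carlo standard errors, since a
finite-replicate mean exceeds its expectation about half the time.

## Known limitations

* No covariate adjustment, paired designs, multi-group contrasts or
  variance trend in the DE stage.
* No batch correction or re-normalisation; inputs are trusted as
  deposited, and a per-study "already-log" convention is assumed rather
  than checked.
* Disease-level aggregation ("significant in ≥1 dataset of the disease")
  deliberately ignores how many datasets a disease has; a disease with
  two studies gets two chances to hit.
* The meta-analysis offers exactly Fisher and maximum-p — no weighted or
  random-effects combination — because those two span the
  any-study/all-studies contrast the pipeline is built to expose.
* Enrichment does no ontology propagation; gene sets are taken as given.
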