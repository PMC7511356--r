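---
title: "RIP-Seq binder calling and CPE motif analysis: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RIP-Seq binder calling and CPE motif analysis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripcpe)
```

`ripcpe` answers two linked questions about an RNA-binding protein assayed
by RIP-Seq: *which transcripts does it bind* (IP-vs-control count
enrichment), and *what distinguishes the bound 3′-UTRs* (CPE element
content, density, and length). This vignette documents the statistical
models, the tunable parameters, the synthetic-data generator that stands in
for non-deposited raw data, and the design decisions taken where more than
one defensible choice existed.

## The enrichment model

Counts for transcript $t$ in sample $s$ are modelled as negative binomial
with mean $\mu_{ts} = f_s q_{tg(s)}$ and variance
$\mu_{ts} + \alpha \mu_{ts}^2$, where $f_s$ is a sample size factor,
$g(s) \in \{\mathrm{IP}, \mathrm{control}\}$, and $\alpha$ is the
dispersion.

**Size factors** are median-of-ratios: the median over transcripts (with a
positive geometric mean across samples) of $k_{ts} / (\prod_s k_{ts})^{1/S}$,
rescaled to geometric mean 1 so that a single-sample matrix gets factor 1.
If no transcript is positive in every sample, geometric means are taken
over positive counts only. The rescaling convention changes nothing
downstream (only ratios of factors matter) but makes factors comparable
across runs.

**Dispersion** is estimated per transcript by method of moments on
normalized counts, $\hat\alpha_t = \max(\alpha_{\min}, (s^2 - \bar m)/\bar
m^2)$ with within-group moments combined across the two groups weighted by
their degrees of freedom, and a floor $\alpha_{\min} = 10^{-8}$ for
numerical stability. With three replicates per group this estimator is
unbiased in expectation but extremely noisy (roughly four degrees of
freedom), and plugging it straight into a normal-reference Wald test gives
heavy-tailed statistics: in our null simulations the fraction of p-values
below 0.05 was about 0.12 rather than 0.05. `rip_enrichment()` therefore
moderates by default (`moderate_dispersion()`, `method = "common"`),
replacing every per-transcript value by the **mean** of the per-transcript
estimates over expressed transcripts. The mean, unlike the median, is close
to unbiased for this right-skewed estimator (the median under-covers by
~20%, which left the test anticonservative at ~0.075); with the mean the
null fraction below 0.05 sits at ~0.05. Per-transcript plug-in remains
available (`dispersion_method = "per_transcript"`) for data with strongly
heterogeneous dispersion, at the cost of calibration at small replicate
numbers.

**The test** is a Wald test on
$\widehat{\mathrm{LFC}} = \log_2\frac{\bar m_{\mathrm{IP}} + c}{\bar
m_{\mathrm{control}} + c}$ with pseudocount $c = 0.5$ normalized counts
(bounding log-ratios for sparse transcripts), standard error from the
delta-method variance of the log ratio of group means,
$\mathrm{Var}(\bar m_g) = n_g^{-2} \sum_{s \in g} (q_g / f_s + \alpha
q_g^2)$, and a standard-normal reference. All-zero transcripts are reported
with `pvalue = NA`, excluded from the Benjamini–Hochberg batch, and never
called binders. This is deliberately simpler than a full NB GLM with
dispersion shrinkage, outlier handling, and independent filtering: no LFC
shrinkage is applied, and the acceptance of the test rests on measured
properties (null calibration within [0.03, 0.07] at 3v3; sensitivity ≥ 0.8
and false-discovery proportion ≤ 0.05 at 4-fold enrichment) rather than on
numeric agreement with any particular GLM implementation.

**Classification** uses strict thresholds `log2fc > lfc_min` (default 0)
and `qvalue < fdr_max` (default 0.01). The defaults encode "any enrichment
direction, FDR below 1%"; a looser `P < 0.05`-style rule is reachable by
setting the flags. The denominator group is whatever the sample sheet
labels `control` — IgG pulldown and input chromatin are statistically
interchangeable here, so the package does not distinguish them.

## Motif scanning

The four element classes are literal RNA pattern sets: CPEC
(`UUUUAU`/`UUUUAAU`, the expansion of the consensus `UUUUA(1–2)U` reading
the repeat as 1–2 adenosines), CPENC (`UUUUAAAU`/`UUUUACU`/`UUUUCAU`), Hex
(`AAUAAA`/`AUUAAA`), and PBE (`UGUAAAUA`/`UGUAUAUA`). Scanning is
sense-strand only (CPEs are defined on the mRNA), counts **distinct start
positions per class** — overlapping matches at different starts all count,
a start matched by two patterns of the same class counts once — and
ambiguity characters survive normalization but can never match. Whether one
should count overlapping or non-overlapping occurrences is a genuine
convention choice; distinct-start counting is the contract here, and the
test suite pins the scanner to an independent character-by-character
sliding-window implementation, exactly, over thousands of random sequences.

Densities are `count × 1000 / utr_length` (per kilobase). Coordinates are
1-based inclusive throughout the package; BED output converts to 0-based
half-open. `motif_map()` pools all classes and reports maximal clusters of
matches whose consecutive starts differ by at most `cluster_gap` (default
400 nt — small enough to split the two regulatory clusters seen in
multi-kilobase UTRs of validated targets, configurable per run).

## Comparative statistics

For each class, transcripts are cross-tabulated as binder/non-binder ×
(count > k)/(count ≤ k) with k = 3 ("more than three elements"), applied per
class, on raw per-transcript counts. The Fisher exact p-value uses the
minimum-likelihood two-sided rule (sum of hypergeometric probabilities not
exceeding the observed table's); this is the common convention but not the
only one — the doubling rule can disagree — so it is stated here and pinned
by enumeration tests to 1e-12. The odds ratio is the sample odds ratio
$ad/bc$ (infinite when $bc = 0$ with $ad > 0$, 1 when both products
vanish), not the conditional MLE that `stats::fisher.test()` reports.

Rank-sum comparisons (CPEC density, CPENC density, UTR length) use the
Mann–Whitney U with midranks; the two-sided p-value is exact (full
enumeration, doubling rule) when the pooled sample size is at most 12 with
no ties, and otherwise a normal approximation with tie correction and
continuity correction. Zero-count transcripts are included in the density
comparisons.

## The binder-probability score

The observation that binders have longer UTRs and more CPEs invites a
predictive reading, which the package makes explicit as an optional,
clearly-labelled extension: a logistic regression of the binder flag on
log10 UTR length and the four per-kb densities, fit by maximizing the
penalized mean log-likelihood with an L2 penalty (λ = 10⁻³ by default,
intercept unpenalized) via Newton iterations with step halving. The penalty
removes perfect-separation failures; the mean-likelihood scaling makes the
fit invariant to duplicating the data. Held-out probabilities come from
deterministic 5-fold splits assigned cyclically by row order — fully
reproducible, at the price of folds that follow input order (inputs with
ordered structure should be shuffled by the caller first). Constant
features are dropped with a warning; with no informative features the score
collapses to the base rate.

## The synthetic-data generator

The generator emulates the structure the analysis assumes, with ground
truth: UTR lengths log-normal per group (defaults: medians 1200 nt for
binders vs 800 nt for non-binders — a 1.5× median ratio — with sdlog 0.6,
floored at 50 nt to avoid degenerate densities); background residues i.i.d.
from a mildly AU-rich composition (A = U = 0.3, C = G = 0.2); motifs
planted as literal substitutions at uniform positions at per-kb rates that
default to 2× in binders (CPEC 1.0 vs 0.5, CPENC 0.6 vs 0.3, Hex 1.0 vs
0.5, PBE 0.4 vs 0.2 per kb), never overwriting a previous plant (100
retries, then skip with a warning); counts negative binomial around a
log-normal expression profile scaled to 2×10⁶ reads per sample, dispersion
0.1, 4-fold IP enrichment for binders, 3 IP vs 3 control replicates
(replicate counts beyond the typical two IP lanes of such experiments are
a package default, not an empirical fact), and log-normal library-size
jitter (sdlog 0.05). Each generator call consumes one random stream fully
determined by the seed (the count generator offsets the seed by 1 so
sequences and counts are independent streams).

What the generator does *not* emulate: read-level artifacts (it produces
counts, not FASTQ), GC or positional bias, batch effects, correlated
expression, dispersion heterogeneity across transcripts, and any
sequence-composition structure beyond i.i.d. background plus planted
motifs. Passing tests on this generator therefore demonstrate that the
statistics recover planted structure under the stated model — not that the
model captures every property of real RIP-Seq libraries.

Because planting substitutes into random background, scanned counts can
exceed planted counts (background can spell a motif by chance) but never
fall below them; the low-background test of the planting rate uses a C/G-
rich composition where chance motifs are rare enough to compare against the
planted expectation within Monte-Carlo error.

## Problem sizes and numerical choices

The test suite and acceptance script run at the sizes the analyses are
designed around: 5,000 transcripts × (3+3) samples for calibration and
recovery, 2,000 transcripts for the comparative statistics (repeated across
100 seeds in the acceptance suite), 1,000 random sequences up to 5 kb for
scanner–oracle equivalence — sizes at which every check completes in
minutes on a single core while leaving Monte-Carlo error well inside the
asserted tolerances. Other numerical choices: dispersion floor 10⁻⁸;
pseudocount 0.5; Fisher minimum-likelihood comparisons use a 1 + 10⁻⁷
relative tolerance when comparing hypergeometric probabilities (guarding
against floating-point ties, the same guard used by standard
implementations); rank-sum exact/approximate switch at pooled n = 12;
`fdr_max`/`lfc_min` comparisons are strict inequalities.

## Known limitations

- The Wald test with common dispersion assumes dispersion is shared across
  transcripts; strongly heterogeneous real data would call for shrinkage
  toward a mean-dependent trend, which is out of scope here.
- Literal pattern sets cannot express degenerate motifs (IUPAC or PWM
  models are intentionally excluded).
- The comparative statistics treat transcripts as independent; shared
  3′-UTRs among isoforms would violate this.
- Binder calling and motif statistics are joined by transcript identifier;
  transcripts without a UTR sequence are retained for calling but silently
  absent from motif statistics (the count is logged and recorded in the
  manifest).
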