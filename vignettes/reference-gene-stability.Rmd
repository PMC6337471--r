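---
title: "Evaluating qRT-PCR reference genes with refstab: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating qRT-PCR reference genes with refstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

Quantitative reverse-transcription PCR (qRT-PCR) reports a quantification
cycle Ct per gene and sample: the cycle at which amplification fluorescence
crosses a threshold. Lower Ct means more template. Target-gene expression is
only interpretable relative to one or more *reference* (housekeeping) genes
assumed stable across the conditions compared; a poorly chosen reference
re-labels its own regulation as regulation of the target. `refstab`
implements the standard battery used to vet candidate references —
comparative delta-Ct, BestKeeper, geNorm and a NormFinder-style estimator —
plus consensus rank aggregation across the four, exhaustive scoring of
reference-gene *combinations* against a control condition, and
multi-reference normalization of target genes. A synthetic-data generator
with known ground truth makes every stage testable end to end.

## From Ct to relative quantities

Amplification multiplies template by an efficiency $E$ per cycle (perfect
doubling: $E = 2$). $E$ is estimated per assay from a dilution series: the
OLS slope of Ct against $\log_{10}$ input gives $E = 10^{-1/\text{slope}}$
(`efficiency_from_dilution()`). Plausible assays fall in roughly
$1.85 \le E \le 2.15$; the readers bounds-check $(1, 2.2]$ and default to
$E = 2$ for genes without an estimate.

`relative_quantities()` converts Ct to relative template amounts
$$Q_{gs} = E_g^{\min_{s'} Ct_{gs'} - Ct_{gs}},$$
anchored so each gene's maximum quantity is exactly 1 (the sample with the
most template). With $E = 2$ this is the familiar $2^{-\Delta Ct}$
transformation. Anchoring makes $Q$ invariant to any constant shift of a
gene's Ct, which is why assay-specific offsets (amplicon length, primer
chemistry) never enter the stability statistics. Calibrator-anchored
quantities are deliberately confined to the normalization step.

## The four per-gene stability statistics

**Comparative delta-Ct** (`delta_ct_msd()`). For each ordered gene pair the
SD across samples of the pairwise Ct difference is taken (n−1 denominator,
as everywhere in the package); a gene's mSD is the mean of its 13 (or
$G-1$) pairwise SDs. Stable pairs keep a constant offset, so lower is
stabler.

**BestKeeper** (`bestkeeper()`). Descriptive statistics on raw Ct: the mean
(AM), the "SD" — by default the mean absolute deviation about AM, the
original tool's convention, with `sd_mode = "classic"` for the ordinary SD
— and CV% = 100·SD/AM. The BestKeeper index is the per-sample geometric
mean Ct over all candidates; genes are ranked by their Pearson correlation
$r$ with the index (higher is stabler). A zero-variance gene has undefined
$r$; it is reported as `NA`, ranked last, and flagged with a warning rather
than silently dropped. No SD pre-filter is applied before building the
index, so the ranking is a pure function of the input panel.

**geNorm** (`genorm()`). On log2 quantities, the pairwise variation
$V_{jk}$ is the SD across samples of $\log_2(Q_j/Q_k)$ and a gene's
M-value is its mean $V$ against all other remaining candidates. The
highest-M gene is removed and M recomputed until two remain; those two are
mutually indistinguishable and tie at ranks 1–2. The score reported for
each gene is its M at the step of its removal (for the final pair, their
mutual $V$). On equal M during exclusion the gene later in input order is
removed and the tie is recorded in the trace. Genes with $M \ge 1.5$ are
flagged as unstable. `genorm_v_curve()` then asks how many references are
needed: with $NF_n$ the per-sample geometric mean of the $n$ most stable
genes, $V_{n/n+1} = \mathrm{SD}_s\,\log_2(NF_n/NF_{n+1})$, and the smallest
$n$ with $V_{n/n+1} < 0.15$ (the conventional threshold, configurable) is
recommended; if none drops below the threshold, $N-1$ is returned and
flagged.

**NormFinder-style stability value** (`normfinder()`). Each sample's
across-gene mean log2 quantity is subtracted first, removing shared
loading. Ungrouped, the stability value is the residual SD with a
$\sqrt{G/(G-1)}$ small-panel correction. With condition groups (each
needing at least three samples), the value combines per group the absolute
deviation of the gene's group mean from its grand mean (inter-group bias)
with the intra-group sampling error $\sqrt{s^2_g/n_g}$, averaged over
groups. This additive bias-plus-error form follows the published
estimator's structure; exact numerical equality with the original tool's
variance-shrinkage implementation is not claimed.

Delta-Ct and BestKeeper operate on raw Ct; geNorm and NormFinder on log2
efficiency-corrected quantities, each matching its original definition.
One useful identity follows: with all $E = 2$,
$\mathrm{SD}(\log_2 Q_j/Q_k) = \mathrm{SD}(Ct_k - Ct_j)$, so the full-panel
geNorm M equals the delta-Ct mSD gene by gene. The test suite asserts this
to $10^{-9}$ on 200 random matrices, and the identity is also why
published delta-Ct and geNorm tables computed at $E=2$ can print identical
whole-panel columns.

## Consensus across algorithms

The four statistics rank on different scales, so consensus is formed on
the rankings themselves. The objective is the summed (optionally weighted)
Spearman footrule distance — the sum over genes of absolute rank
differences — between the consensus and each input list.
`aggregate_exhaustive()` enumerates all permutations up to 8 genes and is
the oracle; `aggregate_ce()` is a cross-entropy Monte-Carlo search for
larger panels. It keeps a gene × position probability matrix (initialized
uniform), samples candidate permutations position by position without
replacement (sequential renormalization, implemented by Gumbel-max draws),
refits the matrix to the elite fraction, and smooths
$P \leftarrow (1-w)\hat P + wP$ with $w = 0.25$. Defaults —
`samples_per_iter = max(2000, 40n)`, elite fraction 0.1, stagnation limit
15, 200-iteration cap — were sized once for panels of up to ~20 genes,
where the sampler visits a large share of the plausible orderings each
iteration. The input lists are scored in the first iteration, so the
returned consensus can never be worse than any input list; with a fixed
seed the whole search is bit-reproducible, and its RNG use is isolated
from the caller's stream. BestKeeper's list enters the aggregation ranked
by $r$ by default (`bestkeeper_key = "SD"` switches to the
dispersion-based ordering, since both conventions exist in the
literature).

## Scoring reference-gene combinations

Because multi-gene normalization factors are the recommended practice,
`graynorm()` scores *combinations* rather than single genes: for a subset
$C$, $NF_s = (\prod_{g \in C} Q_{gs})^{1/|C|}$, rescaled so the control
group's mean NF is exactly 1. Per group the mean and CV of $1/NF$ are
recorded, and the score is the mean over non-control groups of
$|\overline{1/NF} - 1|$: a combination whose NF itself responds to
treatment drags $1/NF$ away from 1 and scores badly. This is the simplest
statistic consistent with the "mean $1/NF$ close to 1" principle, and it
is declared openly so results are auditable; ties break by ascending mean
CV of $1/NF$, then lexicographically. All $2^n - 1$ subsets can be
enumerated (guarded at $n \le 20$); the pipeline default evaluates all
size-3 combinations, three references being the usual recommendation.

**A known limitation.** Scores built on group means of $1/NF$ cannot
distinguish reference-gene response from *condition-correlated loading*:
if per-sample loading offsets are large relative to a shift diluted into
the combination ($\delta/|C|$), the between-group fluctuation of mean
loading dominates the score, and with arithmetic means a Jensen-type bias
($\mathbb{E}[1/NF] > 1/\mathbb{E}[NF]$ under dispersion) can even favor
combinations containing mildly up-shifted genes. The package's own
simulations exercise exactly this regime (loading SD 0.5 log2 units,
three samples per group) and the combination score's best-subset recovery
collapses there, while the four per-gene statistics — which cancel or
model loading explicitly — are unaffected. In practice this is the case
for equalizing RNA input across reactions before trusting
combination-level scores; the per-gene rankings are the robust signal
under loading noise.

## Normalizing target genes

`normalization_factor()` builds $NF_s$ from a chosen reference set,
anchored so the calibrator (control) group's mean NF is 1.
`relative_expression()` computes the target's raw relative quantity
against the calibrator-group mean Ct, $RQ_s = E_t^{\overline{Ct}_{cal} -
Ct_s}$, divides by $NF_s$, and rescales so the calibrator group's mean
fold is exactly 1 — group-mean anchoring being more robust than
single-sample anchoring. Group summaries report mean fold ± SE over the
biological replicates (SD/$\sqrt{n}$, n−1 SD). Loading artifacts shared by
the target and its references cancel exactly in the ratio; the raw
(non-normalized) $RQ$ is kept alongside for comparison.

## What the synthetic generator emulates

`synthetic_spec()` encodes the benchmark conditions the package is
validated under, modeled on a multi-condition reference-gene screen in a
non-model tree (tissue panels, hormone time courses): latent log2
expression $L_{gs} = \beta_{g,\mathrm{group}(s)} + \lambda_s +
\varepsilon_{gs}$ with lognormal (Normal-on-log2) biological noise, a
shared per-sample loading offset $\lambda_s \sim N(0, 0.5^2)$ emulating
input/RT variation, and $Ct_{gs} = C0_g - L_{gs}\ln 2/\ln E_g$ with
baseline Ct drawn in 18–30 cycles and efficiencies in 1.85–2.05, reported
truthfully (a mis-specification mode reports $E = 2$ regardless, for
sensitivity checks). The default panel is 3 stable genes
($\sigma = 0.1$ log2), 3 mild responders (±1 log2 in the first treatment
group) and 2 strong responders (±3 log2 in the second), across three
groups of three biological replicates with the first group as control,
plus one target gene at fold 4. Responder signs alternate because real
treatments induce some transcripts and repress others; an all-induced
panel would also make the BestKeeper index itself track the responders,
masking exactly the instability the statistic is meant to expose. Noise
is Normal on the log2 scale (multiplicative on quantity), matching qPCR
error structure; Ct-scale additive noise is deliberately not offered.

What passing these simulations does **not** show: the generator draws
independent noise per gene (no co-regulation), loading offsets independent
of condition, no technical-replicate structure, no missing wells, and no
inter-run calibration drift. Recovery rates on this generator are
evidence the algorithms are implemented correctly, not a claim about any
particular organism's panel.

## Numerical and degenerate-input choices

All SDs use the n−1 denominator. Ct values are validated into $(0, 45]$
(a 45-cycle run); missing cells are a hard error by default, with an
explicit `drop_incomplete_samples` escape that removes whole samples so
every algorithm sees the same complete matrix — pairwise-complete
computation is deliberately not offered. Technical replicates collapse by
arithmetic mean (median available). Zero-variance genes: pairwise SDs of 0
are legitimate everywhere; only BestKeeper's $r$ becomes undefined and is
handled as described. Probability-matrix entries in the CE sampler are
floored at $10^{-12}$ to keep renormalization defined after aggressive
elite updates. The exhaustive aggregator breaks objective ties
lexicographically in the gene order of the first input list, making it
deterministic.

## Problem sizes used in the shipped checks

The package's tests and the acceptance script run, by design, at desk
scale: 200 random matrices (5–14 genes × 4–20 samples) for the
delta-Ct/geNorm identity; 50 random 5–6-gene instances for CE-vs-oracle
equivalence; 100 generator seeds each for stable-gene recovery, the
$V_{2/3}$ rule (with $\sigma_{stable} = 0.05$) and fold-change recovery;
and the four published 14-gene rank lists bundled under `inst/extdata`
for the consensus reproduction. These sizes give stable pass/fail margins
while keeping a full run in well under a minute per stage.

## Limitations

Beyond the combination-score caveat above: the NormFinder-style estimator
is structural, not a bit-level port; BestKeeper p-values are not computed;
instrument-native export parsing, amplification-curve processing and
single-curve efficiency estimation are out of scope; and the rank
aggregation offers the footrule objective (with a Kendall-style extension
left to the user via per-list weights) rather than the full menu of the
original aggregation literature.
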