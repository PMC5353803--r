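---
title: "Uncertainty-aware 16S taxonomy classification with multinomial K-mer models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-aware 16S taxonomy classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microtax)
```

## The problem

Profiling a microbial community from amplicon sequencing reduces to
assigning very many 16S rRNA reads to taxonomic bins — usually genera —
against a reference of full-length sequences. Three things make this
harder than a textbook classification task: there are thousands of
classes, many of them represented by a handful (sometimes one) of
reference sequences; reads are fragments of varying length and quality;
and any real sample contains sequences the reference has never seen.
This package implements a fast multinomial K-mer classifier together
with two uncertainty scores that separate the two distinct failure
modes: *boundary* cases (the runner-up genus is almost as good) and
*novelty* cases (nothing in the reference looks like this read).

## The multinomial model

Every sequence is encoded as integers (`A,C,G,T/U → 0..3`); any other
character becomes the sentinel `-4^15`. K-mer indices are inner products
of each sliding window with `c(4^(K-1), ..., 4, 1)`; a window containing
a sentinel has a negative index (the sentinel magnitude dominates any
positive contribution for K ≤ 15) and is discarded. We cap K at 12 for
memory sanity (`4^12 ≈ 1.7e7` columns); ambiguity codes are treated like
`N` rather than fractionally counted — the speed of pure integer logic
outweighs the information in the rare informative ambiguity code.

Training pools the K-mer counts of all sequences of a taxon into a row
of an `M × 4^K` matrix and converts it to log2-probabilities with a
total pseudo-count mass `P` spread uniformly over words:

$$Q_{gj} = \log_2\frac{x_{gj} + P/4^K}{\sum_j x_{gj} + P}.$$

Pseudo-counts are *added*: additive (Laplace-style) smoothing keeps every
row a proper multinomial (`Σ_j 2^{Q_gj} = 1`, asserted to 1e-9 in the
tests) and is well defined for sparse rows, where a subtractive variant
would produce negative probabilities. An all-zero row degrades to the
uniform distribution.

Classification streams: for each valid K-mer of a query the matching
column of `Q` is added to the score vector, with multiplicity — each
window counts. This is algebraically the count-vector–`Qᵀ` product (the
test suite checks equality to 1e-9 against that explicit oracle) but
costs `(n−K+1)·M` column additions instead of `4^K·M` multiplications;
the break-even word length solves `4^K = n − K`, about `K = 5.27` at
`n = 1500`, so K = 8 is comfortably on the streaming side. Ties at the
argmax go to the first taxon in training order (deterministic; the
d-score is 0 there anyway). Queries shorter than K or consisting only of
alien characters are flagged `unscorable` and carried through as `NA`
rows — output cardinality always equals input cardinality. The posterior
uses a flat prior over taxa: reference class frequencies reflect
database curation, not community composition. An optional
`both_strands` flag scores the reverse complement too and keeps the
better orientation; it is off by default because 16S pipelines orient
reads upstream.

Defaults `K = 8`, `P = 100` are applied by `build_taxmachine()`; the
lower-level functions require explicit values. K = 9 or 10 buys little
genus-level accuracy for a large cost in memory and time, and P = 100 is
a robust compromise across read lengths.

## Length normalization and the d-score

The maximum posterior log-probability `p1` is a sum of one negative term
per window, so it drifts linearly with read length and its spread grows
with length as well. `build_taxmachine()` samples one fragment per
training sequence — length uniform between 100 bases and the full
length, start uniform — classifies them, and fits two linear
regressions: the mean of `p1` against length on all pairs, and the SD
against length on per-bin SDs (bins of 50 bases with at least 10
members). The SD observations are computed from the *residuals* of the
mean fit: within a 50-base bin the mean trend itself moves by about 50
times the slope, which would otherwise swamp the true scatter. With
both models, any score normalizes to `p̃ = (p − p̂_l)/ŝ_l`; the
package refuses to fit on fewer than 100 fragments or on fragments that
span fewer than two length bins, and refuses to normalize where the
extrapolated SD is non-positive. Lengths outside the fitted range are
allowed but flagged `extrapolated-length`.

The d-score is `d = p̃1 − p̃2`. Both scores are normalized at the same
length, i.e. by the same affine map, so `d ≥ 0` and adding any constant
to both raw scores cancels. `d ≈ 0` marks a decision boundary; `d > 1`
is used as the conventional safe threshold in the evaluation summaries.

One fragment per sequence (rather than several) keeps the fit data
independent across sequences; with at least 100 training sequences the
two regressions are already stable.

## Genus statistics, the r-score and its probability

From the same classified fragments, grouped by their *true* genus, we
compute each genus's mean `p̄_g` and raw SD `s_g` of the normalized
score. Genus sizes in real references are heavily skewed — many genera
hold one sequence, where `s_g` does not even exist — so raw SDs are
grouped by genus size, averaged, and smoothed against size with loess
(span 0.75, degree 2, raw size scale). The smoothed size-specific SD
`s_n` is combined with the raw SD by

$$\bar s_g = \sqrt{\frac{(n-1)\,s_g^2 + s_n^2}{n}},$$

which returns exactly `s_n` for singletons and essentially `s_g` for
large genera (both limits are asserted in the tests, along with the
worked value `√2.5` for `n = 2, s_g = 1, s_n = 2`). Smoothed predictions
are clamped positive, and sizes outside the smooth's support use the
nearest fitted size. On tiny communities with fewer than five distinct
genus sizes a loess fit is not meaningful, and the per-size mean SDs are
used directly — full-scale references always take the loess path.

The r-score of a query is `r = (p̃1 − p̄_g)/\bar s_g` with the
*predicted* genus as plug-in (the true genus is unknown at
classification time). Using the same fragment protocol for the
normalization and the genus statistics keeps r-scores centred near zero
for ordinary reads of any length; fitting the statistics on full-length
sequences instead would shift fragment r-scores systematically negative.

The training r-scores are stored sorted, and
`r_probability()` returns `Pr(r_train ≤ r)` with the Weibull plotting
position `rank/(N+1)`, so probabilities live strictly inside `(0, 1)`:
a read below the training minimum gets `1/(N+1)` and the flag `unusual`,
never an impossible zero. Here the ECDF is fitted on the same training
set as the classifier — with a synthetic community there is no larger
companion reference to borrow, so both components share one set; with a
real reference one can fit the ECDF on a larger sequence collection by
calling `fit_genus_stats()` on it directly. We deliberately avoid a
normal-theory tail probability: the training r-score distribution is
left-skewed and an empirical tail is the honest summary.

## The word-presence comparison classifier

`train_rdp()`/`classify_rdp()` implement the classic word-presence naive
Bayes: word prior `p_j = (n_j + 0.5)/(N + 1)`, genus conditional
`(m_{gj} + p_j)/(M_g + 1)`, scored over the *distinct* words of a query
(duplicates count once — asserted against a brute-force oracle). The
bootstrap confidence machinery of the original tool is deliberately
omitted; the d/r columns are `NA` for this method. It exists for
comparison: on well-separated synthetic communities it lands within a
few accuracy points of the multinomial classifier.

## The synthetic community generator

`generate_community()` emulates the structure of a curated full-length
16S reference: a shared random ancestor, genus centroids drawn by i.i.d.
substitutions from it (optionally through intermediate "order"-like
group ancestors), members drawn by i.i.d. substitutions from their
centroid, skewed genus sizes (`1 + NB(size 1.2, μ 7)` by default: many
small genera, singletons included, occasional large ones), and
~1500-base sequences. All generation is a pure function of the
parameters and the seed; reruns are byte-identical.

The default divergences — 0.5% ancestor-to-centroid, 0.5% within genus,
2% between the ten coarse groups — were calibrated once so that the
default community reproduces the operating regime a genus-level 16S
classifier faces in practice: read-length error rates of roughly 12%,
1–2% and <0.1% at 120–150, 270–300 and 450–500 bases, d-score AUC above
0.9, and ≥98% accuracy at 1% substitution corruption. Real genera are
several percent divergent overall but concentrate their differences in
variable regions; an i.i.d. substitution model spreads them uniformly,
so matching the *discriminability* regime requires a lower nominal
divergence than real pairwise distances would suggest.

What the generator does *not* emulate: conserved/variable region
structure, rate heterogeneity, realistic indel processes, chimeras, and
reference taxonomies with mislabelled sequences. Tests passing on this
community therefore demonstrate the correctness and the qualitative
behaviour of the machinery — not field accuracy on real amplicon data.
One consequence is visible in the corruption experiment: at 5%
substitutions the synthetic accuracy falls far below the >90% a real
reference retains, because uniformly ~1%-divergent genera leave less
margin than real taxa; the monotone degradation and the leftward
r-score shift are the transferable findings.

Read corruption uses exact counts (`round(rate · n)` positions, each
substituted by a *different* base) so small fixtures have deterministic
effect sizes; a Bernoulli per-position mode is available. Indel
corruption picks `round(rate · n)` anchors, inserts or deletes (50/50)
a fixed-length block at each, applied right-to-left so anchors refer to
the original coordinates, with deletions truncated at the sequence end.

## Evaluation design

`evaluate_fragments()` mirrors the read-length experiment: 10 fragments
per sequence per length range (120–150, 270–300, 450–500 bases), error
percentage, ROC AUC of the d-score as a correctness ranker (via pROC;
the tests cross-check a rank-based Mann–Whitney oracle), and the error
rate among `d > 1` calls. `evaluate_unknown_taxa()` performs taxon-wise
holdout at the genus and coarse-group level. Because the per-taxon
multinomial rows are independent, deleting a taxon's row of `Q` is
mathematically identical to retraining without it, so fragments are
scored once against the full matrix and the holdout is applied as a
mask at argmax time; the genus statistics need no refit since a masked
genus can never be the predicted plug-in. `evaluate_corruption()` runs
the substitution/indel conditions at 450–500 bases. All three are
pure functions of their seed.

Problem sizes throughout the package's own experiments — 50 genera in
10 groups, a few hundred sequences, 10 fragments per sequence — are the
package's chosen desk-scale study conditions; they complete in seconds
while leaving every qualitative contrast (length monotonicity, d-score
discrimination, novelty ordering, corruption robustness) with a wide
margin.

## Known limitations

* Genus-level only per model; classify at another rank by training on
  that rank's labels.
* The r-score ECDF inherits the training set's composition; strongly
  unbalanced references skew the tail probabilities.
* The i.i.d. generator limitations above: treat synthetic accuracies as
  regime checks, not benchmarks.
* No chimera simulation; heavily chimeric reads surface only indirectly
  through low r-scores.
* Serialized models store dense `Q` matrices; at `K = 12` these are
  large (M × 1.7e7 doubles) — K = 8 is the intended operating point.
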