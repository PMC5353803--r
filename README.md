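# microtax

Genus-level taxonomic classification of 16S rRNA gene sequences with
explicit uncertainty quantification, for microbiome profiling pipelines
that need both an assignment *and* a defensible statement of how much to
trust it.

## The method

**Classifier.** Sequences are reduced to overlapping K-mers (default
K = 8). For each taxon *g* a multinomial model is trained from the pooled
K-mer counts `x_gj` of its training sequences, smoothed with a total
pseudo-count mass *P* (default 100) spread uniformly over the 4^K words:

    Q[g, j] = log2( (x_gj + P/4^K) / (Σ_j x_gj + P) )

A query of length *n* is scored against every taxon by *streaming*: each
of its ≤ n−K+1 valid K-mers adds one column of **Q** to the score vector,
so the 4^K-long count vector is never materialized, and the query is
assigned to the taxon with maximum posterior log-probability `p1`
(runner-up `p2`). Windows containing `N` or other ambiguity codes are
discarded via an integer sentinel (−4^15) that makes their positional
index negative. For full-length 16S (n ≈ 1500) streaming wins over
explicit count-vector scoring for K > 5.27.

**Uncertainty.** Two complementary scores are attached to every call:

* **d-score** — `p1` and `p2` are standardized against linear models of
  the score mean and SD versus read length (fitted on random-length
  fragments of the training set), and `d = p̃1 − p̃2`. A d-score near 0
  means the query sits on a decision boundary; `d > 1` is a conventional
  "safe" threshold.
* **r-score** — the standardized residual `r = (p̃1 − p̄_g) / s̄_g` of the
  query against the score distribution of its predicted genus, where
  `s̄_g = sqrt(((n−1)s_g² + s_n²)/n)` shrinks the raw genus SD toward a
  loess-smoothed, genus-size-specific SD `s_n` (singleton genera get
  `s_n` exactly). Large negative r-scores flag sequences unlike anything
  in the training data — sequencing error, chimeras, or novel taxa. An
  empirical CDF of the training r-scores converts `r` into
  `Pr(r_train ≤ r)`, with the Weibull convention `rank/(N+1)` so the
  probability is never exactly 0 or 1.

A bootstrap-free naive-Bayes word-presence classifier (RDP-style) is
included for comparison, and a synthetic 16S community generator
(genus centroids around a common ancestor, optional coarser grouping,
skewed genus sizes with singletons, fragment sampling, substitution and
indel corruption) makes every part testable without any sequence
download.

## Worked example

```r
library(microtax)
community <- generate_community(n_genera = 30, seq_length = 1500, seed = 7)
machine   <- build_taxmachine(community, K = 8, pseudo = 100, seed = 7)
glance(machine)
#> # A tibble: 1 × 8
#>   name         K pseudo n_taxa n_sequences length_min length_max n_r_train
#> 1 training     8    100     30         198        102       1493       198

reads <- tibble::tibble(
  id = c("read1", "read2"),
  sequence = c(sample_fragment(community$sequence[1],  250, 250),
               corrupt_substitutions(
                 sample_fragment(community$sequence[42], 450, 450), 0.05)))
classify_with_uncertainty(reads, machine)
#> # A tibble: 2 × 9
#>   query_id taxon    d_score  r_score r_probability flags       p1 p_tilde length
#> 1 read1    genus001   4.69    -0.648       0.246   ""      -2637.   -1.19    250
#> 2 read2    genus028   0.908 -277.          0.00503 "unusu… -6588.  -50.8     450
```

`read1` is a clean 250-base fragment of a `genus001` training sequence:
correctly assigned, comfortably away from the decision boundary
(d = 4.7), and typical for its genus (r = −0.65, probability 0.25).
`read2` is a `genus004` fragment corrupted at 5% substitutions: the
assignment (to `genus028`) is both boundary-near (d = 0.9) and wildly
atypical (r = −277, flagged `unusual`) — exactly the calls a profiling
pipeline should down-weight or discard.

```r
evaluate_fragments(machine, community, fragments_per_seq = 5, seed = 99)
#> # A tibble: 3 × 6
#>   range       n error_pct auc_d n_d_gt1 error_pct_d_gt1
#> 1 120-150   990    24.5   0.971     677           0.443
#> 2 270-300   990     4.55  0.992     916           0
#> 3 450-500   990     0.808 0.999     978           0
```

Errors fall steeply with read length; ranking calls by d-score separates
correct from incorrect assignments (AUC ≥ 0.97), and restricting to
d > 1 nearly eliminates errors at every length.

A thin command-line wrapper is installed at `exec/microtax`
(`microtax simulate | train | classify | evaluate`), writing results as
TSV with `NA` markers and `#` provenance comments.

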