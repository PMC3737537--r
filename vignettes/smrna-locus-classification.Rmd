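---
title: "Classifying small RNA-seq loci by their read pileups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying small RNA-seq loci by their read pileups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Small RNA sequencing (smRNA-seq) captures the short RNA fragments that
cells produce by processing longer precursor transcripts. Different
classes of non-coding RNA (ncRNA) are processed by different enzymatic
machinery, and that machinery leaves fingerprints in the read pileup: the
lengths of the fragments, how precisely their 5' and 3' ends are cleaved,
whether the locus is transcribed on both strands, the base composition of
the products, and how stably the surrounding genomic sequence folds. This
package classifies transcribed loci into six ncRNA functional classes --
lincRNA, miRNA, scRNA, C/D box snoRNA, snRNA and transposon-derived RNA --
using only those pileup fingerprints, so it can annotate loci in organisms
or tissues where sequence-homology annotation is thin.

The pipeline is: merge aligned reads into transcribed loci; discard loci
covered by fewer than 15 reads; label the remainder by overlap with known
annotations; compute a fixed 25-dimensional feature vector per locus; and
train a multi-class random forest with backwards feature elimination.

## The 25 features

For a locus $i$ spanning $[a, b)$ with $\mathrm{Length}(i) = b - a$:

* **Length spectrum, `L14`..`L30`.** For each read span $L \in 14..30$,
  the raw feature is
  $f_L = \sum_k N_{L,k} / \mathrm{Length}(i)$, where $N_{L,k}$ is the
  multiplicity-weighted number of sense-strand reads of span $L$ covering
  base $k \in [a, b)$ — i.e. read counts weighted by how much of the locus
  they cover. Raw features are converted to proportions with a pseudocount
  scaled to the feature's units ($c = 1/\mathrm{Length}(i)$, $\alpha = 0.5$
  by default),
  $p_L = (f_L + \alpha c) / (\sum_{L'} f_{L'} + 17 \alpha c)$, and
  reported as log-odds $\log_2 p_L / (1 - p_L)$. A locus with no in-range
  sense reads therefore collapses to the uniform value
  $\log_2 (1/16) = -4$ for all 17 features.
* **Antisense expression.** $q = (n_{anti} + \alpha) / (n_{total} +
  2\alpha)$, reported as $\log_2 q/(1-q)$.
* **Positional entropy, 5' and 3'.** Shannon entropy (bits) of the
  multiplicity-weighted distribution of sense-read 5' (respectively 3')
  end coordinates. On a minus-strand locus the 5' end of a read is its
  maximum genomic coordinate. Low entropy means precise cleavage (mature
  miRNA 5' ends are the canonical example); end positions falling outside
  the locus bounds still count, because they are real cleavage sites.
* **Base composition, `nuc_A`..`nuc_T`.** Expression-weighted nucleotide
  frequencies over all sense-read bases (each read contributes
  length × multiplicity bases; `N` ignored), with pseudocount $\alpha$,
  as log-odds against equal frequencies, $\log_2 f_b / 0.25$.
* **Folding score, `mfe`.** The sense-strand genomic sequence of the locus
  extended by 40 bp on either side is folded. The default backend calls
  ViennaRNA's `RNAfold` (kcal/mol); when it is unavailable the `nussinov`
  backend scores minus the maximum number of nested base pairs
  (Watson–Crick plus G·U wobble, minimum hairpin loop 3) by exact dynamic
  programming — monotone with fold stability but not in kcal/mol; a
  `table` backend reads precomputed per-locus values. One backend is used
  per feature matrix, because a model's features must be homogeneous.

## Design choices where the procedure was genuinely open

* **Log-odds normalisation of the length features.** We define the
  normalisation as the log-odds of pseudocounted proportions,
  $\log_2 p_L/(1-p_L)$, with the pseudocount scaled by $1/\mathrm{Length}$
  so that it lives in the same units as $f_L$. This is the standard
  log-odds transform, keeps all 17 values finite for empty spectra, and
  makes the proportions sum to one.
* **Per-base counting.** $N_{L,k}$ counts a read at every base it covers
  inside the locus (coverage interpretation) rather than only at its 5'
  start; dividing by $\mathrm{Length}(i)$ is only meaningful under that
  reading. Reads overhanging the locus contribute only their in-locus
  bases.
* **Read length = reference span** (`end - start`). Soft-clipped bases are
  excluded; this is the only definition available for BED input.
* **Sense-strand restriction.** Length, entropy and base-composition
  features use sense-strand reads only; antisense reads feed the antisense
  feature. This keeps each feature about the locus's own product.
* **Bases and units.** All log-odds are base 2; entropies are in bits.
* **Segmentation defaults.** The coverage threshold and gap parameters of
  the locus segmenter are exposed (`min_coverage`, `max_gap`) with the
  most permissive defaults (1 and 0); the synthetic-data pipeline uses
  `max_gap = 50` so that sparsely covered locus interiors do not split,
  while planted loci at least 100 bp apart can never merge.
* **Locus strand** is the majority read strand, ties to `+`.
* **Annotation overlap.** A locus takes the class of the largest-overlap
  annotation; ties break by a fixed priority (miRNA first, as the most
  compact annotation type) and then by name, so labelling is
  deterministic. Overlap is strand-aware by default.
* **Cross-validation.** "Cross-validated" performance defaults to
  stratified 10-fold with feature selection re-run inside each training
  fold (`selection = "nested"`), which avoids selection bias; the
  optimistic legacy behaviour (selection on the pooled data before CV) is
  available as `selection = "pooled"` and its bias is demonstrated in the
  test suite on label-permuted data.
* **Random forest settings.** `ntree = 1000`; `mtry = floor(sqrt(p))`
  with an `mtry_factor` multiplier exposed (values up to 4 gave
  indistinguishable accuracy in our checks, so the square-root
  recommendation is the default). Feature elimination drops
  `floor(0.35 p)` of the current features per step, recomputing
  permutation importance each step, down to 2 features, and selects the
  smallest set within one standard error of the minimum out-of-bag error.
  Gini importance is available as an option.
* **Class imbalance** is left untouched by default (real smRNA-seq class
  counts are wildly imbalanced and the reported metrics are per-class);
  no reweighting is applied.

## What the synthetic generator emulates

Real training data require genome-scale alignments and curated
annotations, so the package ships a generator whose class profiles encode
the qualitative pileup signatures of the six classes: miRNA -- sharp 22 nt
span peak, precise 5' and looser 3' cleavage, strongly folding hairpin
(mean folding score -35); C/D box snoRNA -- long products (peak 28 nt with
a minor short component), imprecise cleavage at both ends; transposon --
short products (peak 17 nt), precise cleavage, 25% antisense reads, weak
folding (-8); lincRNA -- short dispersed degradation-like products;
scRNA -- 27 nt peak, weak folding; snRNA -- 14 nt peak from U-rich (T-rich
in DNA) transcripts. Cleavage dispersion is modelled as a discretised
normal whose standard deviation is `locus_length / concentration`; each
read anchors its 5' end with probability $c_5/(c_5+c_3)$ (otherwise its 3'
end), and the opposite end follows at span distance, so the realised span
histogram is exactly the class multinomial. Folding scores are drawn from
per-class normals and consumed through the `table` backend by default,
which keeps tests independent of any folding engine; an end-to-end mode
folds the synthetic genome with the `nussinov` backend instead.

The generator does **not** emulate sequencing error, quality strings,
multi-mapping, expression-level differences between tissues, or genomic
repeat structure. Consequently the synthetic classes are cleanly separable
and near-perfect synthetic accuracy shows that the pipeline's plumbing and
statistics are correct — not that real tissues, where published accuracy
is nearer 80%, would behave as well.

A separability dial (`sweep_separability()`) interpolates every profile
toward the pooled mean; at `scale = 0` the classes are identical and
cross-validated accuracy falls to the permutation baseline
$\sum_k p_k^2$, which the test suite verifies.

## Problem sizes used by the validation suite

The packaged checks use: 1000 random pileups against brute-force feature
oracles; 200 random sequences (length <= 12) against exhaustive structure
enumeration; 500 random read sets against a dense coverage-array
segmenter; six-class recovery and the permutation baseline on 200
loci/class (nested 10-fold CV, 1000 trees; 100-tree forests inside the
25-permutation baseline); selection stability over 100 repeated runs on a
fixture of 8 planted informative features (the planted class is a mixture
of eight subgroups, each shifted by ±3 standard deviations in exactly one
feature, so every informative feature is individually necessary and the
one-standard-error rule retains all eight) plus 17 noise features; and a
cross-"tissue" transfer between two datasets drawn from identical
profiles with different seeds.

## Numerical notes and limitations

* All stochastic steps take explicit seeds and restore the caller's RNG
  state; repeated runs are bit-identical, and the command-line interface
  writes numeric output with 17 significant digits so files round-trip
  exactly.
* Positional entropy of a locus with no sense reads is 0 by convention
  (logged); length features then fall back to the uniform pseudocount.
* `PPV` is undefined (`NA`) for a class never predicted.
* The nussinov score counts base pairs; it is **not** comparable to
  kcal/mol values, and a feature matrix must not mix backends.
* BED input carries no multi-mapping information; `unique_only` is a
  no-op there (with a warning). Collapsed-read multiplicity is read from
  `name_xN` suffixes.
* The classifier inherits random-forest behaviour on extrapolation:
  features far outside the training range are predicted at the nearest
  training leaf, with no warning.
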