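---
title: "Methods: multi-omics gene regulatory network inference and benchmarking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics gene regulatory network inference and benchmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omixgrn)
```

## The problem

Gene regulatory networks (GRNs) are usually inferred from transcriptome
data alone, on the assumption that a transcription factor's (TF) mRNA level
is a usable proxy for the abundance of its active protein. That assumption
is weak: translation is buffered and regulated, so mRNA and protein levels
of the same gene can decouple substantially. Ribosome profiling (Ribo-seq)
measures the translatome — the ribosome-engaged mRNA pool — which tracks
protein output much more closely than total mRNA does.

omixgrn implements the resulting inference design on paired
transcriptome/translatome expression atlases. Three network types are
distinguished by which omics layer supplies the regulator profile and
which supplies the target profile:

* **mmGRN** — TF mRNA vs target mRNA (classic transcriptome-only network);
* **TTGRN** — TF translatome vs target translatome;
* **TmGRN** — TF translatome vs target mRNA (inter-omics). This is the
  biologically motivated pairing: TF *protein* (approximated by its
  translational abundance) drives target *transcription*.

The package covers the full workflow: atlas quality control, tree-ensemble
network inference, network algebra (union, intersection, high-confidence
merging, topology, sub-networks), benchmarking against a ChIP-seq-like
gold standard, and a synthetic atlas generator with known ground truth so
that every stage is testable without external data.

## The synthetic atlas generator

`generate_truth_network()` draws a TF-to-target network with heavy-tailed
out-degrees (lognormal degree weights rescaled to a target mean; a few hub
TFs, many small ones) and signed effect sizes (positive with probability
0.75, magnitudes uniform on [0.5, 2] — activation dominating over
repression, as is typical for curated plant regulons).

`simulate_atlas()` then generates FPKM-scale matrices for
`n_tissues` tissues in labeled categories:

1. TF mRNA is lognormal: gene baseline `N(log 8, 1)`, tissue effect
   `N(0, 0.3)`, gene-by-tissue variation `N(0, 0.7)`. These scales give
   FPKM-like magnitudes (most values between ~0.5 and ~200) and
   tissue-variable profiles.
2. Translational efficiency (TE) is i.i.d. per gene and tissue,
   `log TE ~ N(0, te_sigma)`, clipped to [0.25, 4] — the range reported
   for real paired atlases. `te_sigma` is the single dial that decouples
   the two omics layers; at 0 they coincide exactly.
3. Target mRNA is `fpkm_scale * softplus(alpha_g + sum_f beta_fg s_ft +
   eps)`, where `s_ft` is the standardized log1p TF *translatome* profile
   and `eps ~ N(0, noise_sd)`. The softplus link keeps abundances positive
   while preserving monotone regulator effects; no additive generative
   model on the raw FPKM scale can do both. Crucially, targets respond to
   TF translation, not TF mRNA — this is the mechanism whose recovery the
   benchmarks measure.
4. Target translatome is target mRNA times the target's own TE.
5. Observed sources: two replicates with independent lognormal noise
   (log-sd `noise_sd`), and a bulked sample formed as the mean of three
   hidden replicates, mirroring a pooled-library design.
6. A `specific_fraction` of genes is expressed in one tissue category
   only, and each entry drops to zero with probability
   `detection_dropout`, so that detection/SEG analyses have realistic
   structure.

Defaults (`te_sigma = 1`, `noise_sd = 0.25`, `detection_dropout = 0.02`,
`specific_fraction = 0.05`, 21 tissues in nine categories) were fixed once
as a realistic operating point: they give median per-gene cross-omics
correlations around 0.4–0.6 across tissues, replicate correlations above
0.9, and a few percent of undetected entries.

What the generator deliberately does **not** emulate: read-level count
noise (negative binomial), gene length/GC effects, shared TE structure
across tissues (TE here is independent per gene-tissue pair, a
conservative worst case for cross-omics coupling), TF-TF cooperativity,
and indirect regulation chains. Passing tests therefore demonstrate that
the machinery recovers planted direct regulation under lognormal
FPKM-level noise — not that it resolves direct from indirect targets in
real atlases, which expression-based GRNs cannot do.

`make_gold_standard()` degrades the truth into ChIP-seq-like evidence:
per TF it keeps `round(observed_fraction * d)` true targets and adds
`round(spurious_fraction * observed)` non-targets (binding without
regulation). With `observed_fraction = 1, spurious_fraction = 0` the gold
standard is the truth itself.

## Quality control

* `filter_grn_genes()` applies the network-construction filter: maximum
  FPKM at least 1 in some sample and non-zero values in at least 3
  samples (both configurable). The filter is monotone in both thresholds.
* `select_regulators()` keeps TFs passing the filter in **both** omics
  layers of a source; targets are taken from the transcriptome filter.
  Within a data source all three network types then share one regulator
  set and one target set, so type-level comparisons (overlap counts,
  chi-square contrasts) are over identical pair universes. This was a
  genuinely open design point; sharing the universes is what makes the
  cross-type statistics interpretable.
* `compute_te()` is the plain ratio translatome/transcriptome with no
  pseudocount; entries with RNA below `detect_min` (default 1 FPKM) are
  masked with a reason rather than propagated as infinities.
* `detect_segs()` calls a gene specifically expressed in a category, per
  layer, when it is detected in at least one sample of that category and
  none of any other. "Detected" defaults to FPKM > 0; the threshold is
  exposed because replicate-agreement rules and cutoffs are not settled
  conventions. Mean SEG counts divide by the category's sample count to
  remove sampling-depth bias. SEG sets are disjoint across categories by
  construction.
* `correlation_report()` masks zero-variance profiles and pairs with
  fewer than 3 observations instead of erroring — real atlases contain
  constant rows.

## Network inference

`rank_regulators_for_target()` fits, per target gene, an ensemble of
regression trees on bootstrap samples of the tissues (bagging). At each
node `k` candidate regulators are drawn (default `sqrt` of the regulator
count, the canonical random-forest heuristic) and the split maximizing the
variance reduction is taken. A regulator's raw importance is the summed
per-sample sum-of-squares reduction of its splits, `(SS(node) - SS(left) -
SS(right)) / n`, averaged over trees. The per-target importance vector is
then normalized to sum to 1, so an edge weight is the share of the
target's explainable variance attributed to that regulator. This
normalization makes weights comparable across targets and matches the
magnitude of commonly used weight thresholds (with ~1800 regulators, a
uniform share is ~0.00056; meaningful edges sit between 0.0003 and 0.01
and a stringent cut at 0.05).

Numerical and reproducibility choices:

* Trees are grown to purity (`max_depth = 0`); depth-1 stumps are exposed
  for oracle testing, where a single tree's importance must equal the
  exhaustive best-split variance reduction.
* Split thresholds are midpoints between adjacent distinct values; ties
  between equally good splits resolve to the candidate drawn first, so
  every result is a pure function of the seed. The C++ engine uses its
  own Mersenne Twister stream, independent of R's RNG state.
* Per-target seeds derive from the user seed and the target id only —
  not from the matrices — so the three network types use identical
  randomization per target. With `te_sigma = 0` and `noise_sd = 0` the
  layers coincide and mm/TT/Tm rankings are forced identical, a property
  the tests assert.
* Expression enters on the raw FPKM scale by default with an opt-in
  `log_transform`; tree splits are invariant to monotone transforms of
  single regulators, so this mainly affects bootstrap variance weighting.
* Global edge ranking breaks weight ties by regulator then target id —
  reproducibility over arbitrariness. `truncate_edges()` thresholds are
  inclusive (weight >= value).
* A TF appearing among targets never serves as its own regulator;
  constant target profiles yield flagged all-zero importances.

Defaults `n_trees = 1000`, `k = "sqrt"` follow standard tree-ensemble GRN
practice; the test suite and the acceptance script use 20–100 trees on
20-TF/200-target/12-tissue atlases, sizes chosen so the full study runs in
tens of seconds while leaving the rank stability across seeds above 0.9.

## Network algebra

* `union_networks()` deduplicates on (regulator, target); the retained
  weight defaults to the **max** over members (the merge is reported as
  pair counts, so the aggregation rule is free; max preserves "best
  evidence"), with `mean` available. Provenance flags record membership.
* `build_high_confidence()` intersects the three types within each data
  source (each truncated to `top_k`, default one million edges) and then
  unions the per-source intersections: an edge qualifies when all three
  omics pairings agree in at least one source.
* `topology_metrics()` works on the undirected simple projection:
  transitivity (3 x triangles / connected triples), average shortest-path
  length over reachable pairs (the common convention for fragmented
  networks), and module count as connected components with >= `min_nodes`
  (default 5) nodes. Community detection is an explicit non-goal; if
  "modules" were communities rather than components the counts would
  differ, so results are labeled as component counts.
* `tissue_specific_subgrn()` keeps edges whose regulator is specifically
  *translated* in a category and whose target is specifically expressed
  (either layer) there.

## Benchmarking

* `overlap_gold()` counts shared pairs over TFs present in both network
  and gold standard.
* `random_overlap_null()` redraws, per TF and iteration, the same number
  of targets uniformly without replacement from the declared target
  universe (minus the TF itself) — a degree-preserving null with analytic
  per-TF expectation `k * m / N`, which the tests verify at 1000
  iterations.
* `chisq_overlap()` compares observed vs null-mean overlap as a 2x2 table
  (overlapping / non-overlapping x observed / expected) with df = 1 and
  no continuity correction. The exact contingency construction behind
  published overlap p-values is rarely stated; this one is documented
  here as the package's reading, and a zero expected cell masks the
  result rather than failing.
* `roc_pr_scores()` defines the candidate set per TF as the declared
  target universe minus the TF; candidate pairs absent from the network
  score 0. AUROC uses the rank-sum (Mann-Whitney) formulation with
  midrank ties — proven equal to the all-pairs comparison oracle in the
  tests — and AUPR uses stepwise non-interpolated integration with tied
  scores processed as one group. Per-TF averages exclude TFs lacking a
  positive or a negative. A uniform-random ranking scores 0.500 by
  construction, the baseline the acceptance script recomputes.
* `compare_weights()` restricts each network type to its top-k edges,
  takes pairs present in all three, and applies two-sided paired t tests
  pairwise. Fewer than 3 shared pairs, or zero-variance differences with
  nonzero mean, are masked with a reason; identical vectors give t = 0,
  p = 1 (the closed form is computed directly so the degenerate cases
  are controlled, and it is cross-checked against `t.test` in the tests).

## Pipeline

`run_pipeline()` drives simulate → QC → six inferences (mm/TT/Tm x
mean/bulked) → truncation → union and high-confidence merging → topology
→ benchmarking from a single validated configuration (nested list or
YAML; unknown keys rejected; resolved config serialized with the
outputs). One user seed is split into named substreams (simulation,
per-target inference, benchmark null), so re-running with only the
benchmark seed changed leaves every upstream artifact byte-identical —
the manifest's md5 hashes make this checkable, and the tests check it.

## Known limitations

* Expression-based GRNs cannot separate direct from indirect regulation;
  edge weights order hypotheses, they do not certify binding.
* The generator's independence assumptions (TE independent per
  gene-tissue, no TF cooperativity) make recovery neither trivially easy
  nor adversarial; real atlases violate them in both directions.
* Benchmarks at desk scale use tens of TFs and hundreds of targets;
  absolute AUROC/overlap values scale with universe size and are not
  comparable to atlas-scale studies, only the *contrasts* between network
  types are.
* The bulked source simulates pooling at the abundance level (mean of
  hidden replicates), not library-construction effects of physical
  pooling.
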