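# omixgrn

Multi-omics gene regulatory network (GRN) inference and benchmarking for
paired transcriptome (RNA-seq) / translatome (Ribo-seq) expression
atlases.

## The problem

Transcriptome-only GRNs assume that a transcription factor's (TF) mRNA
level tracks the abundance of its active protein. It often does not:
translation is buffered, and mRNA and protein levels decouple. The
translatome — ribosome-engaged mRNA measured by Ribo-seq — is a much
closer proxy for protein output. omixgrn infers and compares three
network types from a paired atlas of FPKM matrices:

| type  | regulator profile | target profile | reading |
|-------|-------------------|----------------|---------|
| mmGRN | TF mRNA           | target mRNA    | classic transcriptome-only |
| TTGRN | TF translatome    | target translatome | intra-omics, translation level |
| TmGRN | TF translatome    | target mRNA    | inter-omics: TF *protein* drives target *transcription* |

Edges are scored GENIE3-style: per target gene, an ensemble of regression
trees predicts the target profile from all regulator profiles across
tissues; a regulator's weight is its normalized share of the
variance-reduction importance,

```
w(f, g) = I_f / sum_f' I_f',   I_f = mean over trees of
          sum over f's splits of (SS(node) - SS(left) - SS(right)) / n
```

so each target's weights sum to 1. Networks are truncated (top-k or
inclusive weight threshold), merged into a union GRN and a
high-confidence GRN (edges on which all three types agree within a data
source), characterized topologically, and benchmarked against a
ChIP-seq-like gold standard with overlap counts, a degree-preserving
randomized null with chi-square enrichment, per-TF normalized overlaps,
AUROC/AUPR, and paired weight comparisons. A synthetic atlas generator
with known ground-truth regulation makes the whole pipeline testable
end-to-end.

Intended users: systems biologists comparing omics layers for regulatory
inference, and method developers who need a fully specified, seeded,
desk-scale GRN benchmarking harness.

## Worked example

```r
library(omixgrn)

truth <- generate_truth_network(n_tf = 20, n_target = 200,
                                mean_out_degree = 20, seed = 1)
#> <grn_truth> 20 TFs, 200 targets, 399 edges (seed 1)

atlas <- simulate_atlas(truth, n_tissues = 12, te_sigma = 1, seed = 1)
rna  <- atlas_layer(atlas, "rna",  "mean")
ribo <- atlas_layer(atlas, "ribo", "mean")

regulators <- select_regulators(truth$regulators, rna, ribo)  # 19 TFs
targets    <- intersect(filter_grn_genes(rna), truth$targets) # 190 genes

# translational decoupling: cross-omics per-gene correlation is well below 1
median(correlation_report(rna, ribo, axis = "per_gene")$r, na.rm = TRUE)
#> [1] 0.5604045

tm <- infer_grn(ribo, rna, regulators, targets, grn_type = "Tm",
                source = "mean", n_trees = 100, seed = 1)
mm <- infer_grn(rna, rna, regulators, targets, grn_type = "mm",
                source = "mean", n_trees = 100, seed = 1)
head(tm, 3)
#> # A tibble: 3 × 6
#>   regulator target weight  rank grn_type source
#> 1 TF004     G00179  0.323     1 Tm       mean
#> 2 TF007     G00018  0.311     2 Tm       mean
#> 3 TF015     G00032  0.277     3 Tm       mean

gold <- make_gold_standard(truth, observed_fraction = 1,
                           spurious_fraction = 0, seed = 1)
roc_pr_scores(tm, gold)
#> <roc_report> scope per_tf: AUROC 0.783, AUPR 0.468 (20 TFs)
roc_pr_scores(mm, gold)
#> <roc_report> scope per_tf: AUROC 0.604, AUPR 0.214 (20 TFs)
```

The inter-omics TmGRN recovers the planted regulation far better than the
transcriptome-only mmGRN (AUROC 0.78 vs 0.60) because, in the generative
model as in the underlying biology, targets respond to TF translational
abundance. Enrichment over a randomized null:

```r
top_tm <- truncate_edges(tm, "top_k", 1000)
ov   <- overlap_gold(top_tm, gold)
#> <grn_overlap> 243 / 1000 network pairs overlap gold (19 TFs)
null <- random_overlap_null(top_tm, gold, n_iter = 1000, seed = 1)
#> <overlap_null> 1000 iterations: mean 110.28 (observed 243)
chisq_overlap(ov$total, null$mean, ov$n_pairs)
#> # A tibble: 1 × 5
#>    chi2        p    df masked reason
#> 1  60.6 7.15e-15     1 FALSE  <NA>
```

The observed overlap is 2.2x the null mean (p = 7e-15): the network is
strongly enriched for true regulation. `run_pipeline()` drives the whole
workflow (six networks, union and high-confidence merging, topology,
benchmarking) from one seeded configuration and writes a hashed artifact
manifest; `vignettes/multiomics-grn-methods.Rmd` documents every model
and design choice.

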