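# circlr

Desk-scale circular RNA (circRNA) analysis with ground truth: backsplice
junction (BSJ) discovery, junction-contig quantification with
circular-to-linear ratios, negative-binomial differential expression, and
dual-rank feature selection feeding an SVM classifier — exercised
end-to-end on synthetic genomes, reads and cohorts generated by a bundled
simulator that knows exactly what was planted.

## The problem

circRNAs are covalently closed RNAs produced when the spliceosome joins a
downstream splice donor back to an upstream acceptor. The only sequence
evidence for a circRNA in RNA-seq is its backsplice junction — a
non-colinear exon–exon junction — so the analysis chain is: find BSJs de
novo in RNase R-enriched libraries (RNase R degrades linear RNA and spares
circles), then quantify each junction in untreated libraries and relate it
to its linear host. The core quantities are

- **#BSJ** — fragments covering ≥ 8 nt of a 10 nt window centred on the
  backsplice in a contig built from 100 nt of genomic sequence on each side
  of the junction;
- **CLR = #BSJ / (mean(#FSJ) + 1)** — the circular-to-linear ratio, with
  #FSJ counted the same way at the two adjacent forward splice junctions;
- **cumulative circularization** — the per-replicate sum of CPM-normalized
  BSJ counts, with **diversity** the number of distinct expressed species;
- a simplified negative-binomial Wald test (median-of-ratios size factors,
  method-of-moments dispersion, BH adjustment) for differential circRNA
  expression, and a permutation test for differential CLR;
- information-gain and random-forest-importance rankings combined by rank
  sum to select features for a tuned SVM, evaluated by ROC/AUC with
  stratified 10-fold cross-validation.

Discovery uses two detectors — anchor realignment of non-colinear mates
(with a GT..AG splice-signal requirement) and an annotation-guided variant
that snaps breakpoints to exon boundaries — filtered to junctions 50 nt to
100 kb apart inside one gene with ≥ 2 supporting fragments, and merged by
coordinate union.

## Worked example

A complete run — simulate, discover, quantify, test, classify — from one
configuration:

```r
library(circlr)
cfg <- pipeline_config(seed = 5, outdir = "run1", n_genes = 20, n_circ = 8,
                       cohort = list(n_features = 100, n_per_class = 15,
                                     n_informative = 8, effect_log2fc = 2,
                                     dispersion = 0.1))
rep <- run_pipeline(cfg)
#> simulate: 20 genes, 8 circRNAs
#> discover: scanning 602 fragments
#> quantify: 8 circRNAs x 6 samples
#> differential: 2 robust circRNAs
#> classify: cohort 100 features, 2 x 15 samples
nrow(rep$catalog)           # 8  -- all planted junctions recovered
sum(rep$catalog$ambiguous)  # 1  -- one junction flagged as linear-mimicked
rep$metrics$per_stage
#>             stage cumulative_cpm diversity normalized_load
#> 1:     progenitor       10848.81  5.000000        2169.761
#> 2: differentiated       18848.42  5.333333        3529.119
rep$roc$auc                 # 1  -- planted cohort effect is separable
```

The catalog lists each junction in 1-based `chr:start-end` notation with
its host gene, support, detector provenance and an ambiguity flag (loci
whose backsplice window is sequence-mimicked by a linear junction are
excluded from load statistics); `rep$metrics` holds the per-replicate and
per-stage cumulative circularization (a 1.7× stage ratio at this toy
scale, reflecting the planted global increase under heavy small-sample
noise — the reference-scale run in `analysis/` recovers 2.9 vs a planted
2.8), and `rep$roc` the pooled cross-validated probabilities. All stage outputs are
also written under `outdir` (FASTA/GTF/FASTQ/BED/TSV plus a JSON manifest
with sub-seeds and checksums), and a rerun with the same config is
byte-identical.

The `analysis/` directory holds the same workflow as five numbered
narrative scripts (simulate → discover → quantify → differential →
classify) at the reference scale (100 genes, 60 circRNAs, 3 replicates per
state), writing their tables under `results/run/`.

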