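#!/usr/bin/env Rscript
# Stage 2 — de novo backsplice-junction discovery.
#
# Runs both detectors (anchor realignment with GT/AG requirement, and
# annotation-guided with breakpoint snapping) on the RNase R-treated pool,
# filters to single-gene junctions 50 nt - 100 kb apart with >= 2 supporting
# fragments, takes the union, and scores it against the planted truth.

suppressMessages({ library(circlr); library(data.table) })
run <- file.path("results", "run")
dir.create(run, recursive = TRUE, showWarnings = FALSE)
sim <- file.path("scratch", "run", "sim")

genome_fa <- read_genome_fasta(file.path(sim, "genome.fa"))
ann <- read_annotation_gtf(file.path(sim, "annotation.gtf"))
genome <- structure(list(chromosomes = genome_fa, genes = ann$genes,
                         exons = ann$exons), class = "GenomeModel")
truths <- fread(file.path(sim, "circ_truth.tsv"))
treated <- read_fastq_pair(file.path(sim, "treated_pool"))

cfg <- detector_config()
index <- index_genome(genome, cfg$anchor_len)
anchor <- detect_anchor_backsplices(treated, index, cfg)
annotated <- detect_annotated_backsplices(treated, index, genome, cfg)
catalog <- union_catalogs(filter_candidates(anchor, genome, cfg),
                          filter_candidates(annotated, genome, cfg))
catalog <- flag_ambiguous_junctions(catalog, genome)

write_catalog(catalog, file.path(run, "catalog.bed"),
              file.path(run, "catalog.tsv"))

truth_keys <- truths[, paste(chrom, bsj_start, bsj_end)]
found_keys <- catalog[, paste(chrom, start, end)]
stats <- data.table(
  n_planted = nrow(truths), n_called = nrow(catalog),
  recall = mean(truth_keys %in% found_keys),
  precision = mean(found_keys %in% truth_keys),
  n_ambiguous_flagged = sum(catalog$ambiguous))
fwrite(stats, file.path(run, "discovery_stats.tsv"), sep = "\t")
message(sprintf(
  "called %d junctions (planted %d): recall %.3f, precision %.3f; %d flagged ambiguous",
  stats$n_called, stats$n_planted, stats$recall, stats$precision,
  stats$n_ambiguous_flagged))
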