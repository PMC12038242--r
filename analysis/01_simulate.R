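#!/usr/bin/env Rscript
# Stage 1 — synthetic study data.
#
# Builds the reference genome with multi-exon gene models, plants 60
# circRNAs with known backsplice coordinates and circular-to-linear ratios
# (with a 2.8-fold global circular increase in the differentiated state),
# and simulates the sequencing libraries: one pooled RNase R-treated
# discovery library and 3 untreated replicates per state.

suppressMessages({ library(circlr); library(data.table) })
run <- file.path("results", "run")
sim <- file.path("scratch", "run", "sim")
dir.create(sim, recursive = TRUE, showWarnings = FALSE)
seed <- 20240901
s <- derive_seed(seed, "simulate")

states <- c("progenitor", "differentiated")
genome <- generate_genome(1, 100, seed = s)
truths <- plant_circrnas(genome, 60, seed = s + 1, states = states,
                         state_multiplier = c(progenitor = 1,
                                              differentiated = 2.8),
                         fsj_coverage = 40)
set.seed(s + 2)
truths[, copies.discovery := runif(.N, 15, 40)]

write_genome_fasta(genome, file.path(sim, "genome.fa"))
write_annotation_gtf(genome, file.path(sim, "annotation.gtf"))
fwrite(truths, file.path(sim, "circ_truth.tsv"), sep = "\t")

design <- CJ(state = states, replicate = 1:3, sorted = FALSE)
design[, sample_id := sprintf("%s_r%d", state, replicate)]
design[, time := state]
fwrite(design, file.path(sim, "design.tsv"), sep = "\t")

treated <- simulate_library(genome, truths, state = "discovery",
                            rnase_r = TRUE, seed = s + 10)
write_fastq_pair(treated, file.path(sim, "treated_pool"))
message(sprintf("discovery library: %d fragments (%d backsplice-spanning)",
                nrow(treated), sum(treated$spans_bsj)))

for (i in seq_len(nrow(design))) {
  lib <- simulate_library(genome, truths, state = design$state[i],
                          rnase_r = FALSE, seed = s + 20 + i,
                          fsj_coverage = 40)
  write_fastq_pair(lib, file.path(sim, design$sample_id[i]))
  message(sprintf("%s: %d fragments", design$sample_id[i], nrow(lib)))
}
message("planted CLR range: ",
        paste(signif(range(truths$clr_truth), 3), collapse = " - "))
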