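#!/usr/bin/env Rscript
# Stage 3 — junction-library quantification in the untreated replicates.
#
# Builds BSJ contigs (100 nt each side of the backsplice) and FSJ contigs
# for every annotated linear junction, places each mate on genome+contigs
# (<= 2 mismatches, multimaps retained), counts fragments by the 8-of-10
# window rule, applies the robust-expression filter, and derives CLR, CPM,
# cumulative circularization and diversity per replicate and stage.

suppressMessages({ library(circlr); library(data.table) })
run <- file.path("results", "run")
sim <- file.path("scratch", "run", "sim")

genome_fa <- read_genome_fasta(file.path(sim, "genome.fa"))
ann <- read_annotation_gtf(file.path(sim, "annotation.gtf"))
genome <- structure(list(chromosomes = genome_fa, genes = ann$genes,
                         exons = ann$exons), class = "GenomeModel")
design <- fread(file.path(sim, "design.tsv"))
catalog <- fread(file.path(run, "catalog.tsv"))
catalog <- cbind(
  convert_coordinates(catalog[, .(
    circ_id, chrom = sub(":.*", "", region),
    start = as.integer(sub(".*:(\\d+)-.*", "\\1", region)),
    end = as.integer(sub(".*-(\\d+)$", "\\1", region)))], "report_to_internal"),
  catalog[, .(strand, gene_id)])
catalog <- flag_ambiguous_junctions(catalog, genome)
quant_cat <- catalog[ambiguous == FALSE]
message(nrow(quant_cat), " of ", nrow(catalog),
        " circRNAs quantified (ambiguous junctions excluded)")

bsj_lib <- build_junction_library(quant_cat, genome)
fsj_lib <- build_fsj_library(genome)
fsj_map <- adjacent_fsjs(quant_cat, fsj_lib)
index <- index_genome(c(genome$chromosomes,
                        setNames(bsj_lib$sequence, bsj_lib$circ_id),
                        setNames(fsj_lib$sequence, fsj_lib$fsj_id)), 20)

cids <- quant_cat$circ_id
bsj <- fsj5 <- fsj3 <- matrix(0L, length(cids), nrow(design),
                              dimnames = list(cids, design$sample_id))
lib_sizes <- setNames(numeric(nrow(design)), design$sample_id)
for (i in seq_len(nrow(design))) {
  lib <- read_fastq_pair(file.path(sim, design$sample_id[i]))
  pl <- assign_fragments(lib, genome, bsj_lib, fsj_lib, index = index)
  bc <- count_bsj(pl, bsj_lib)
  fc <- count_fsj(pl, fsj_lib, fsj_map)
  bsj[, i] <- bc$bsj_count[match(cids, bc$circ_id)]
  fsj5[, i] <- fc$fsj5_count[match(cids, fc$circ_id)]
  fsj3[, i] <- fc$fsj3_count[match(cids, fc$circ_id)]
  lib_sizes[i] <- pl$library_size
  message(design$sample_id[i], ": ", pl$library_size, " fragments placed, ",
          sum(bsj[, i]), " backsplice fragments")
}

robust <- robust_filter(bsj, design)
message(nrow(robust), " of ", nrow(bsj), " circRNAs robustly expressed")
cpm <- compute_cpm(bsj, lib_sizes)
clr <- vapply(seq_len(ncol(bsj)), function(j)
  compute_clr(bsj[, j], fsj5[, j], fsj3[, j]), numeric(nrow(bsj)))
dimnames(clr) <- dimnames(bsj)
metrics <- circ_metrics(cpm, design, raw_mat = bsj, stage_col = "state")

fwrite(data.table(sample_id = names(lib_sizes), library_size = lib_sizes),
       file.path(run, "library_sizes.tsv"), sep = "\t")
write_count_matrix(bsj, design, file.path(run, "bsj"))
write_count_matrix(fsj5, design, file.path(run, "fsj5"))
write_count_matrix(fsj3, design, file.path(run, "fsj3"))
fwrite(data.table(circ_id = rownames(clr), clr), file.path(run, "clr.tsv"),
       sep = "\t")
fwrite(metrics$per_replicate, file.path(run, "metrics_per_replicate.tsv"),
       sep = "\t")
fwrite(metrics$per_stage, file.path(run, "metrics_per_stage.tsv"), sep = "\t")

ps <- metrics$per_stage
message(sprintf(
  "cumulative CPM: %s = %.0f, %s = %.0f (ratio %.2f; planted 2.8)",
  ps$stage[1], ps$cumulative_cpm[1], ps$stage[2], ps$cumulative_cpm[2],
  ps$cumulative_cpm[ps$stage == "differentiated"] /
    ps$cumulative_cpm[ps$stage == "progenitor"]))
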