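library(data.table)

# Hand-built two-gene genome for exact-coordinate tests. Gene A (+) has
# exons [100,200), [500,600), [900,1050); gene B (-) has exons [1500,1700),
# [2000,2200). Intron splice signals are stamped to match gene strand.
make_toy_genome <- function(seed = 42) {
  chrom <- circlr:::with_seed(seed, circlr:::rand_dna(2600))
  exons <- data.table(
    gene_id = c("gA", "gA", "gA", "gB", "gB"),
    chrom = "chrT",
    strand = c("+", "+", "+", "-", "-"),
    exon_idx = c(1L, 2L, 3L, 1L, 2L),
    start = c(100L, 500L, 900L, 1500L, 2000L),
    end = c(200L, 600L, 1050L, 1700L, 2200L))
  genes <- exons[, .(chrom = chrom[1], strand = strand[1],
                     start = min(start), end = max(end)), by = gene_id]
  for (g in genes$gene_id) {
    ex <- exons[gene_id == g]
    don <- if (genes[gene_id == g, strand] == "+") "GT" else "CT"
    acc <- if (genes[gene_id == g, strand] == "+") "AG" else "AC"
    for (j in seq_len(nrow(ex) - 1)) {
      a <- ex$end[j]; b <- ex$start[j + 1]
      substr(chrom, a + 1, a + 2) <- don
      substr(chrom, b - 1, b) <- acc
    }
  }
  structure(list(chromosomes = c(chrT = chrom), genes = genes, exons = exons),
            class = "GenomeModel")
}

# A junction-wrapping read for the circle [s, e) on the toy genome:
# `left` nt ending at e followed by (len - left) nt starting at s.
toy_bsj_read <- function(genome, s, e, left = 70, len = 150) {
  chrom <- genome$chromosomes[[1]]
  paste0(substr(chrom, e - left + 1, e), substr(chrom, s + 1, s + (len - left)))
}

toy_colinear_read <- function(genome, pos, len = 150) {
  substr(genome$chromosomes[[1]], pos + 1, pos + len)
}

as_readset <- function(mate1, mate2 = NULL) {
  n <- length(mate1)
  if (is.null(mate2)) mate2 <- circlr:::revcomp(mate1)
  data.table(read_id = sprintf("t%04d", seq_len(n)), mate1 = mate1,
             mate2 = mate2, src = "test", src_id = "test", gene_id = "test",
             spans_bsj = NA)
}

# Shared medium-size simulation reused by discovery/quant tests.
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- generate_genome(1, 30, seed = 301)
      tr <- plant_circrnas(g, 15, seed = 302, states = c("a", "b"),
                           state_multiplier = c(a = 1, b = 2.8),
                           fsj_coverage = 20, clr_range = c(0.05, 2))
      tr[, copies.disc := circlr:::with_seed(303, runif(.N, 15, 30))]
      cache <<- list(genome = g, truths = tr,
                     index = index_genome(g, 20))
    }
    cache
  }
})
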