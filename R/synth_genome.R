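#' Generate a synthetic genome with multi-exon gene models
#'
#' Lays non-overlapping genes along one or more random-sequence chromosomes
#' (GC content 0.5). Introns carry canonical splice signals in transcription
#' orientation (GT...AG; on minus-strand genes the genomic forward strand
#' therefore reads CT...AC), so that splice-signal-aware backsplice detection
#' behaves as it would on a real genome.
#'
#' Coordinates are 0-based half-open throughout the package; see
#' [convert_coordinates()] for the 1-based inclusive reporting convention.
#'
#' @param n_chrom number of chromosomes.
#' @param n_genes total number of genes (placed round-robin on chromosomes).
#' @param seed integer RNG seed; generation is a pure function of the
#'   arguments and this seed.
#' @param n_exons_range integer range of exons per gene.
#' @param exon_len_range exon length range (nt); minimum allowed is 20.
#' @param intron_len_range intron length range (nt); minimum allowed is 30.
#' @param gap_range intergenic gap range (nt).
#' @param chrom_len optional fixed chromosome length; an error is raised if
#'   the genes do not fit.
#' @param p_minus probability a gene lies on the minus strand.
#' @return A `GenomeModel`: list with `chromosomes` (named character vector),
#'   `genes` (data.table: gene_id, chrom, strand, start, end) and `exons`
#'   (data.table: gene_id, chrom, strand, exon_idx, start, end).
#' @export
generate_genome <- function(n_chrom = 1, n_genes = 10, seed,
                            n_exons_range = c(3L, 6L),
                            exon_len_range = c(150L, 350L),
                            intron_len_range = c(200L, 600L),
                            gap_range = c(500L, 1500L),
                            chrom_len = NULL, p_minus = 0.5) {
  stopifnot(n_chrom >= 1)
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (missing(seed)) stop("seed must be given")
  if (exon_len_range[1] < 20) stop("exon length must be >= 20 nt")
  if (intron_len_range[1] < 30) stop("intron length must be >= 30 nt")

  with_seed(seed, {
    chrom_of <- rep_len(paste0("chr", seq_len(n_chrom)), n_genes)
    genes <- vector("list", n_genes)
    exons <- vector("list", n_genes)
    cursor <- setNames(rep(0L, n_chrom), paste0("chr", seq_len(n_chrom)))
    for (g in seq_len(n_genes)) {
      chrom <- chrom_of[g]
      gap <- sample(gap_range[1]:gap_range[2], 1)
      n_ex <- sample(n_exons_range[1]:n_exons_range[2], 1)
      ex_len <- sample(exon_len_range[1]:exon_len_range[2], n_ex, replace = TRUE)
      in_len <- if (n_ex > 1) {
        sample(intron_len_range[1]:intron_len_range[2], n_ex - 1, replace = TRUE)
      } else integer(0)
      gstart <- cursor[[chrom]] + gap
      starts <- gstart + cumsum(c(0L, head(ex_len, -1) + in_len))
      ends <- starts + ex_len
      strand <- if (runif(1) < p_minus) "-" else "+"
      gid <- sprintf("gene%03d", g)
      genes[[g]] <- data.table(gene_id = gid, chrom = chrom, strand = strand,
                               start = starts[1], end = ends[n_ex])
      exons[[g]] <- data.table(gene_id = gid, chrom = chrom, strand = strand,
                               exon_idx = seq_len(n_ex), start = starts, end = ends)
      cursor[[chrom]] <- ends[n_ex]
    }
    genes <- rbindlist(genes)
    exons <- rbindlist(exons)

    lens <- sapply(paste0("chr", seq_len(n_chrom)), function(ch) {
      used <- if (any(genes$chrom == ch)) max(genes[chrom == ch, end]) else 0L
      used + sample(gap_range[1]:gap_range[2], 1)
    })
    if (!is.null(chrom_len)) {
      if (any(lens > chrom_len)) {
        stop("genes do not fit chromosome of length ", chrom_len)
      }
      lens[] <- chrom_len
    }
    chromosomes <- setNames(vapply(lens, rand_dna, ""), names(lens))

    # stamp canonical splice signals at intron boundaries
    for (g in seq_len(nrow(genes))) {
      ex <- exons[gene_id == genes$gene_id[g]]
      if (nrow(ex) < 2) next
      ch <- genes$chrom[g]
      seq <- chromosomes[[ch]]
      don <- if (genes$strand[g] == "+") "GT" else "CT"   # intron 5' (genomic)
      acc <- if (genes$strand[g] == "+") "AG" else "AC"   # intron 3' (genomic)
      for (j in seq_len(nrow(ex) - 1)) {
        a <- ex$end[j]; b <- ex$start[j + 1]               # intron [a, b)
        substr(seq, a + 1, a + 2) <- don
        substr(seq, b - 1, b) <- acc
      }
      chromosomes[[ch]] <- seq
    }

    structure(list(chromosomes = chromosomes, genes = genes, exons = exons),
              class = "GenomeModel")
  })
}

#' Plant circRNAs with known backsplice coordinates and abundances
#'
#' Selects contiguous exon windows of multi-exon genes as circularized
#' intervals, subject to the genomic-distance constraint (default 50 nt to
#' 100 kb between backsplice coordinates). Each circRNA gets a planted
#' circular-to-linear ratio (CLR) drawn log-uniformly from `clr_range`, and
#' expected backsplice-junction (BSJ) fragment counts per biological state:
#'
#' `copies_per_state[s] = clr * (fsj_coverage + 1) * state_multiplier[s]`
#'
#' so that at linear per-junction coverage `fsj_coverage` the measured
#' CLR = #BSJ/(mean(#FSJ)+1) recovers `clr * state_multiplier` in
#' expectation. A state multiplier > 1 plants a global circularization
#' increase with unchanged linear output.
#'
#' @param genome a `GenomeModel`.
#' @param n_circ number of circRNAs to plant.
#' @param seed RNG seed.
#' @param clr_range range of planted CLRs (log-uniform). Default reflects
#'   circRNA steady-state levels well below their linear hosts.
#' @param min_distance,max_distance genomic distance constraint (nt).
#' @param max_per_gene maximum circRNAs planted per gene.
#' @param states character vector of state names.
#' @param state_multiplier named multiplier on circular output per state
#'   (linear output is state-independent).
#' @param fsj_coverage expected linear fragments spanning one forward splice
#'   junction window, the reference for converting CLR to copies.
#' @param internal_only restrict circles to internal exons (default TRUE):
#'   a backsplice donor needs a downstream intron and the acceptor an
#'   upstream one, so circles bounded by terminal exons are not produced.
#' @return data.table of `CircTruth` rows: circ_id, gene_id, chrom, strand,
#'   bsj_start, bsj_end, exon_first, exon_last, clr_truth and one
#'   `copies.<state>` column per state.
#' @export
plant_circrnas <- function(genome, n_circ, seed,
                           clr_range = c(0.01, 0.2),
                           min_distance = 50, max_distance = 100000,
                           max_per_gene = 1L,
                           states = "s1",
                           state_multiplier = setNames(rep(1, length(states)), states),
                           fsj_coverage = 10, internal_only = TRUE) {
  if (max_distance < min_distance) stop("bad distance range")
  exons <- genome$exons
  min_ex <- if (internal_only) 3L else 2L
  multi <- exons[, .N, by = gene_id][N >= min_ex, gene_id]
  if (length(multi) * max_per_gene < n_circ) {
    stop("not enough multi-exon genes to plant ", n_circ, " circRNAs")
  }
  with_seed(seed, {
    genes <- sample(multi)
    out <- list(); used <- integer(0); names(used) <- character(0)
    gi <- 1
    while (length(out) < n_circ) {
      if (gi > length(genes)) {
        genes <- c(genes, sample(multi))  # second pass if max_per_gene > 1
      }
      gid <- genes[gi]; gi <- gi + 1
      n_used <- if (is.na(used[gid])) 0L else used[[gid]]
      if (n_used >= max_per_gene) next
      ex <- exons[gene_id == gid][order(exon_idx)]
      n_ex <- nrow(ex)
      combos <- CJ(i = seq_len(n_ex), j = seq_len(n_ex))[i <= j]
      if (internal_only) combos <- combos[i >= 2 & j <= n_ex - 1]
      combos[, dist := ex$end[j] - ex$start[i]]
      combos <- combos[dist >= min_distance & dist <= max_distance]
      if (nrow(combos) == 0) next
      pick <- combos[sample(.N, 1)]
      clr <- exp(runif(1, log(clr_range[1]), log(clr_range[2])))
      row <- data.table(
        circ_id = sprintf("circ%03d", length(out) + 1L),
        gene_id = gid, chrom = ex$chrom[1], strand = ex$strand[1],
        bsj_start = ex$start[pick$i], bsj_end = ex$end[pick$j],
        exon_first = pick$i, exon_last = pick$j, clr_truth = clr)
      for (s in states) {
        row[[paste0("copies.", s)]] <- clr * (fsj_coverage + 1) * state_multiplier[[s]]
      }
      out[[length(out) + 1L]] <- row
      used[gid] <- n_used + 1L
    }
    truths <- rbindlist(out)[order(circ_id)]
    stopifnot(all(truths$bsj_end - truths$bsj_start >= min_distance),
              all(truths$bsj_end - truths$bsj_start <= max_distance))
    setattr(truths, "fsj_coverage", fsj_coverage)
    truths[]
  })
}
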