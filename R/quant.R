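#' Build the backsplice junction-contig library
#'
#' For every circRNA in the catalog, 100 nt of genomic sequence at each side
#' of the backsplice are merged into a contig (upstream flank ends at the
#' circle 3' end, downstream flank starts at the circle 5' start), so that a
#' read wrapping the BSJ aligns colinearly across `junction_offset`. Circles
#' shorter than 200 nt use halves of floor(len/2) nt taken along the
#' circular sequence so no base is duplicated.
#'
#' @param catalog a `BsjCatalog`.
#' @param genome a `GenomeModel` or named character vector of chromosomes.
#' @param flank flank length (nt, default 100).
#' @return data.table of `JunctionContig` rows: circ_id, sequence,
#'   junction_offset.
#' @export
build_junction_library <- function(catalog, genome, flank = 100) {
  chroms <- if (inherits(genome, "GenomeModel")) genome$chromosomes else genome
  stopifnot(all(catalog$end - catalog$start >= 50))
  res <- catalog[, {
    seq <- chroms[[chrom]]
    len <- end - start
    half <- min(flank, floor(len / 2))
    up <- substr(seq, end - half + 1, end)
    down <- substr(seq, start + 1, start + half)
    .(sequence = paste0(up, down), junction_offset = half)
  }, by = .(circ_id, chrom, start, end)]
  res[, .(circ_id, sequence, junction_offset)]
}

#' Build forward-splice-junction contigs from the annotation
#'
#' One contig per annotated linear exon-exon junction: up to 100 nt of the
#' donor exon 3' end joined to up to 100 nt of the acceptor exon 5' start,
#' representing the spliced linear alignment across that junction.
#'
#' @param annotation a `GenomeModel` or list with an `exons` data.table.
#' @param genome chromosome sequences (defaults to `annotation$chromosomes`).
#' @param flank flank length (nt).
#' @return data.table: fsj_id, gene_id, donor_end, acceptor_start, sequence,
#'   junction_offset.
#' @export
build_fsj_library <- function(annotation, genome = NULL, flank = 100) {
  chroms <- if (!is.null(genome)) {
    if (inherits(genome, "GenomeModel")) genome$chromosomes else genome
  } else annotation$chromosomes
  ex <- annotation$exons[order(gene_id, exon_idx)]
  jn <- ex[, if (.N > 1) .(
    jidx = seq_len(.N - 1), chrom = chrom[1],
    don_start = start[-.N], donor_end = end[-.N],
    acceptor_start = start[-1], acc_end = end[-1]), by = gene_id]
  if (nrow(jn) == 0) {
    return(data.table(fsj_id = character(0), gene_id = character(0),
                      donor_end = integer(0), acceptor_start = integer(0),
                      sequence = character(0), junction_offset = integer(0)))
  }
  jn[, fsj_id := sprintf("%s:fsj%d", gene_id, jidx)]
  jn[, `:=`(
    up_len = pmin(flank, donor_end - don_start),
    down_len = pmin(flank, acc_end - acceptor_start))]
  jn[, sequence := {
    seq <- chroms[[chrom]]
    paste0(substring(seq, donor_end - up_len + 1, donor_end),
           substring(seq, acceptor_start + 1, acceptor_start + down_len))
  }, by = chrom]
  jn[, junction_offset := up_len]
  jn[, .(fsj_id, gene_id, donor_end, acceptor_start, sequence, junction_offset)]
}

#' Map circRNAs to their adjacent forward splice junctions
#'
#' The 5' adjacent FSJ is the nearest annotated linear junction upstream of
#' the circle start (its acceptor exon begins at or before the circle 5'
#' boundary); the 3' adjacent FSJ is the nearest junction downstream of the
#' circle end. A circle starting at the gene's first exon or ending at its
#' last has that junction absent (NA), not zero.
#'
#' @param catalog a `BsjCatalog`.
#' @param fsj_lib output of [build_fsj_library()].
#' @return data.table: circ_id, fsj5_id, fsj3_id (NA when absent).
#' @export
adjacent_fsjs <- function(catalog, fsj_lib) {
  catalog[, {
    jn <- fsj_lib[fsj_lib$gene_id == .BY$gene_id]
    up <- jn[acceptor_start <= start & donor_end <= start]
    dn <- jn[donor_end >= end & acceptor_start >= end]
    .(fsj5_id = if (nrow(up)) up[which.max(acceptor_start), fsj_id] else NA_character_,
      fsj3_id = if (nrow(dn)) dn[which.min(donor_end), fsj_id] else NA_character_)
  }, by = .(circ_id, gene_id, start, end)][, .(circ_id, fsj5_id, fsj3_id)]
}

#' Flag circRNAs whose backsplice window is mimicked by linear splicing
#'
#' A linear read across an annotated forward splice junction (donor end d,
#' acceptor start a) is sequence-identical to a backsplice read of a circle
#' (end e, start s) over `min(L1,5) + min(L2,5)` nt of the counting window,
#' where L1 is the length of the common genomic suffix of the flanks ending
#' at d and e, and L2 the common prefix of the flanks starting at a and s.
#' When that reaches the 8-of-10 counting threshold, BSJ counts at this
#' locus absorb linear reads and are unreliable; such circRNAs are flagged
#' so that ratio and load statistics can exclude them.
#'
#' @param catalog a `BsjCatalog`.
#' @param annotation a `GenomeModel` or list with an `exons` data.table.
#' @param genome chromosome sequences (defaults to `annotation$chromosomes`).
#' @param min_ov window overlap (nt) at which a linear junction mimics the
#'   backsplice (default 8, matching the counting rule).
#' @param max_mm mismatch tolerance of the placement step (default 2).
#' @param ctx flanking context (nt) used for the mimic-read alignment.
#' @return the catalog with a logical `ambiguous` column.
#' @export
flag_ambiguous_junctions <- function(catalog, annotation, genome = NULL,
                                     min_ov = 8, max_mm = 2, ctx = 30) {
  chroms <- if (!is.null(genome)) {
    if (inherits(genome, "GenomeModel")) genome$chromosomes else genome
  } else annotation$chromosomes
  ex <- annotation$exons[order(gene_id, exon_idx)]
  jn <- ex[, if (.N > 1) .(chrom = chrom[1], d = end[-.N], a = start[-1]),
           by = gene_id]
  out <- copy(catalog)
  out[, ambiguous := FALSE]
  for (i in seq_len(nrow(out))) {
    seq <- chroms[[out$chrom[i]]]
    e <- out$end[i]; s0 <- out$start[i]
    cl <- min(ctx, floor((e - s0) / 2))
    ctg <- paste0(substr(seq, e - cl + 1, e), substr(seq, s0 + 1, s0 + cl))
    cand <- jn[gene_id == out$gene_id[i]]
    for (j in seq_len(nrow(cand))) {
      # hypothetical junction-aligned linear read across (d, a), trimmed by
      # the same local-alignment rule the placement step applies
      rd <- paste0(substr(seq, cand$d[j] - cl + 1, cand$d[j]),
                   substr(seq, cand$a[j] + 1, cand$a[j] + cl))
      tr <- trim_alignments(rd, ctg)
      if (tr$mm <= max_mm && tr$to > 0) {
        ov <- min(tr$to, cl + 5) - max(tr$from - 1, cl - 5)
        if (ov >= min_ov) {
          out[i, ambiguous := TRUE]
          break
        }
      }
    }
  }
  out[]
}

#' Place fragments on the genome-plus-contig junction library
#'
#' Each mate is placed, in both orientations, at all loci (genome
#' chromosomes, BSJ contigs, FSJ contigs) reachable by exact-anchor seeding
#' with at most `max_mm` substitutions; multi-mapped placements are all
#' retained, and placements extending past a contig end are clipped to the
#' contig.
#'
#' @param reads a `ReadSet` (untreated library).
#' @param genome a `GenomeModel`.
#' @param bsj_lib junction-contig table from [build_junction_library()].
#' @param fsj_lib FSJ contigs from [build_fsj_library()] (optional).
#' @param k anchor length.
#' @param max_mm maximum substitutions per mate.
#' @param index optional prebuilt combined `GenomeIndex` (genome + contigs).
#' @return A `FragmentPlacements` list: `placements` data.table (read_id,
#'   mate, target, target_type, astart, aend, strand, mm), `library_size`
#'   (fragments with >= 1 placement) and `n_unplaced`.
#' @export
assign_fragments <- function(reads, genome, bsj_lib, fsj_lib = NULL,
                             k = 20, max_mm = 2, index = NULL) {
  targets_type <- c(
    setNames(rep("genome", length(genome$chromosomes)), names(genome$chromosomes)),
    setNames(rep("bsj", nrow(bsj_lib)), bsj_lib$circ_id),
    if (!is.null(fsj_lib)) setNames(rep("fsj", nrow(fsj_lib)), fsj_lib$fsj_id))
  if (is.null(index)) {
    targets <- c(genome$chromosomes, setNames(bsj_lib$sequence, bsj_lib$circ_id),
                 if (!is.null(fsj_lib)) setNames(fsj_lib$sequence, fsj_lib$fsj_id))
    index <- index_genome(targets, k)
  }
  mates <- c(reads$mate1, reads$mate2)
  n <- nrow(reads)
  pl <- place_mates(mates, index, max_mm = max_mm)
  pl[, `:=`(read_id = rep(reads$read_id, 2)[qi],
            mate = ifelse(qi <= n, 1L, 2L))]
  pl[, target_type := targets_type[target]]
  placed <- unique(pl$read_id)
  structure(list(
    placements = pl[, .(read_id, mate, target, target_type, astart, aend,
                        strand, mm)],
    library_size = length(placed),
    n_unplaced = n - length(placed)), class = "FragmentPlacements")
}

# 8-of-10 window rule: does a clipped placement interval cover >= min_ov nt
# of the 10 nt window centred on the junction offset?
window_covered <- function(astart, aend, offset, min_ov = 8, window = 10) {
  half <- window / 2
  pmin(aend, offset + half) - pmax(astart, offset - half) >= min_ov
}

#' Count BSJ-spanning fragments per circRNA
#'
#' A fragment (read pair) is counted once for a circRNA if either mate's
#' contig placement covers at least 8 nt of the 10 nt window centred on the
#' backsplice (5 nt each side). Multi-mapped fragments count toward every
#' contig they hit.
#'
#' @param placements a `FragmentPlacements` (or its placements data.table).
#' @param contigs the junction-contig table (circ_id, junction_offset).
#' @return data.table(circ_id, bsj_count) covering every catalog circRNA.
#' @export
count_bsj <- function(placements, contigs) {
  pl <- if (inherits(placements, "FragmentPlacements")) placements$placements else placements
  on_c <- pl[target %in% contigs$circ_id]
  on_c <- merge(on_c, contigs[, .(circ_id, junction_offset)],
                by.x = "target", by.y = "circ_id")
  on_c <- on_c[window_covered(astart, aend, junction_offset)]
  cnt <- on_c[, .(bsj_count = uniqueN(read_id)), by = .(circ_id = target)]
  out <- merge(contigs[, .(circ_id)], cnt, by = "circ_id", all.x = TRUE)
  out[is.na(bsj_count), bsj_count := 0L]
  out[]
}

#' Count fragments over the adjacent forward splice junctions
#'
#' Applies the same 8-of-10 window rule on the FSJ contigs (spliced linear
#' alignment across each junction), then maps each circRNA to its 5' and 3'
#' adjacent junction counts. An absent adjacent junction (circle bounded by
#' a terminal exon) is reported NA, not zero.
#'
#' @param placements a `FragmentPlacements`.
#' @param fsj_lib FSJ contig table.
#' @param fsj_map circ -> adjacent junction map from [adjacent_fsjs()].
#' @return data.table(circ_id, fsj5_count, fsj3_count).
#' @export
count_fsj <- function(placements, fsj_lib, fsj_map) {
  pl <- if (inherits(placements, "FragmentPlacements")) placements$placements else placements
  on_f <- pl[target %in% fsj_lib$fsj_id]
  on_f <- merge(on_f, fsj_lib[, .(fsj_id, junction_offset)],
                by.x = "target", by.y = "fsj_id")
  on_f <- on_f[window_covered(astart, aend, junction_offset)]
  cnt <- on_f[, .(n = uniqueN(read_id)), by = .(fsj_id = target)]
  look <- function(ids) {
    v <- cnt$n[match(ids, cnt$fsj_id)]
    v[!is.na(ids) & is.na(v)] <- 0L
    v
  }
  data.table(circ_id = fsj_map$circ_id,
             fsj5_count = look(fsj_map$fsj5_id),
             fsj3_count = look(fsj_map$fsj3_id))
}

#' Robust-expression filter
#'
#' Keeps features with at least `min_count` reads in at least `min_reps`
#' replicates of at least one time point.
#'
#' @param mat features x samples count matrix.
#' @param design data.table with sample_id and time columns matching
#'   `colnames(mat)`.
#' @param min_count,min_reps filter parameters (defaults 2 reads, 3 replicates).
#' @param time_col name of the time-point column in `design`.
#' @return The row-subset matrix of robustly expressed features.
#' @export
robust_filter <- function(mat, design, min_count = 2, min_reps = 3,
                          time_col = "time") {
  tp <- design[[time_col]][match(colnames(mat), design$sample_id)]
  eligible <- names(which(table(tp) >= min_reps))
  if (length(eligible) == 0) {
    warning("no time point has >= ", min_reps, " replicates; empty result")
    return(mat[integer(0), , drop = FALSE])
  }
  ok <- rep(FALSE, nrow(mat))
  for (t in eligible) {
    sub <- mat[, tp == t, drop = FALSE]
    ok <- ok | rowSums(sub >= min_count) >= min_reps
  }
  mat[ok, , drop = FALSE]
}

#' Circular-to-linear ratio
#'
#' CLR = #BSJ / (mean(#FSJ) + 1), with the mean taken over the available
#' adjacent FSJs: one value if one junction is absent (NA), zero if both are
#' absent, so a circle bounded by terminal exons has CLR = #BSJ / 1.
#'
#' @param bsj_count,fsj5_count,fsj3_count integer vectors (NA = absent FSJ).
#' @return numeric CLR vector.
#' @export
compute_clr <- function(bsj_count, fsj5_count, fsj3_count) {
  mean_fsj <- mapply(function(a, b) {
    v <- c(a, b)[!is.na(c(a, b))]
    if (length(v) == 0) 0 else mean(v)
  }, fsj5_count, fsj3_count)
  bsj_count / (mean_fsj + 1)
}

#' Counts-per-million normalization
#'
#' @param mat features x samples count matrix.
#' @param library_sizes per-sample totals (default: total placed fragments
#'   should be supplied by the caller; falls back to column sums).
#' @return CPM matrix: count / library_size * 1e6.
#' @export
compute_cpm <- function(mat, library_sizes = colSums(mat)) {
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  sweep(mat, 2, library_sizes, "/") * 1e6
}
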