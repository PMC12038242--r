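# File-format round-trips: FASTA via Biostrings, GTF via rtracklayer,
# paired FASTQ via Biostrings, tables via data.table TSV.

#' Write / read genome FASTA
#' @param genome a `GenomeModel` (or named character vector of sequences).
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- if (inherits(genome, "GenomeModel")) genome$chromosomes else genome
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write / read gene annotation as GTF
#'
#' Exon models are written as 9-column GTF (1-based inclusive) with gene_id
#' and transcript_id attributes; reading reconstructs the package's 0-based
#' half-open exon table.
#' @param genome a `GenomeModel`.
#' @param path GTF file path.
#' @export
write_annotation_gtf <- function(genome, path) {
  ex <- genome$exons
  gr <- GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(start = ex$start + 1, end = ex$end),
    strand = ex$strand, type = "exon",
    gene_id = ex$gene_id, transcript_id = paste0(ex$gene_id, ".t1"),
    exon_number = ex$exon_idx)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' @rdname write_annotation_gtf
#' @export
read_annotation_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  ex <- data.table(gene_id = gr$gene_id,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   strand = as.character(GenomicRanges::strand(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  ex <- ex[order(gene_id, start)]
  ex[, exon_idx := seq_len(.N), by = gene_id]
  genes <- ex[, .(chrom = chrom[1], strand = strand[1],
                  start = min(start), end = max(end)), by = gene_id]
  list(genes = genes, exons = ex)
}

#' Write / read a paired-end library as gzipped FASTQ
#'
#' Read names carry the simulation truth
#' (`<read_id>;src=<lin|circ>;id=<origin>;gene=<gene>;bsj=<0|1>`), which
#' `read_fastq_pair()` parses back into a `ReadSet`.
#' @param reads a `ReadSet`.
#' @param prefix output prefix; writes `<prefix>_1.fastq.gz` and
#'   `<prefix>_2.fastq.gz`.
#' @export
write_fastq_pair <- function(reads, prefix) {
  nm <- sprintf("%s;src=%s;id=%s;gene=%s;bsj=%d", reads$read_id, reads$src,
                reads$src_id, reads$gene_id, as.integer(reads$spans_bsj))
  for (m in 1:2) {
    seqs <- Biostrings::DNAStringSet(reads[[paste0("mate", m)]])
    names(seqs) <- nm
    quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(seqs)))
    Biostrings::writeXStringSet(seqs, sprintf("%s_%d.fastq.gz", prefix, m),
                                format = "fastq", compress = TRUE,
                                qualities = quals)
  }
  invisible(prefix)
}

#' @rdname write_fastq_pair
#' @export
read_fastq_pair <- function(prefix) {
  m1 <- Biostrings::readDNAStringSet(sprintf("%s_1.fastq.gz", prefix), format = "fastq")
  m2 <- Biostrings::readDNAStringSet(sprintf("%s_2.fastq.gz", prefix), format = "fastq")
  f <- tstrsplit(names(m1), ";")
  val <- function(x) sub("^[a-z]+=", "", x)
  reads <- data.table(read_id = f[[1]], mate1 = as.character(m1),
                      mate2 = as.character(m2), src = val(f[[2]]),
                      src_id = val(f[[3]]), gene_id = val(f[[4]]),
                      spans_bsj = val(f[[5]]) == "1")
  bad <- reads[src == "circ" & !grepl("^circ", src_id)]
  if (nrow(bad) > 0) stop("unparseable truth names in FASTQ")
  reads[]
}

#' Write a BSJ catalog as BED6 and as a 1-based report table
#'
#' The BED file is 0-based half-open; the TSV reports 1-based inclusive
#' coordinates (`chrom:start-end` as `region`).
#' @param catalog a `BsjCatalog`.
#' @param bed_path,tsv_path output paths (either may be NULL).
#' @export
write_catalog <- function(catalog, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    bed <- catalog[, .(chrom, start, end, name = circ_id,
                       score = pmin(support, 1000L), strand)]
    fwrite(bed, bed_path, sep = "\t", col.names = FALSE)
  }
  if (!is.null(tsv_path)) {
    rep_ <- convert_coordinates(catalog, "internal_to_report")
    rep_[, region := sprintf("%s:%d-%d", chrom, start, end)]
    fwrite(rep_[, .(circ_id, region, strand, gene_id, support, detector)],
           tsv_path, sep = "\t")
  }
  invisible(catalog)
}

#' Write / read a count matrix with its design sidecar
#' @param mat features x samples matrix.
#' @param design data.table of per-sample metadata (must contain sample_id).
#' @param prefix file prefix; writes `<prefix>_counts.tsv` and
#'   `<prefix>_design.tsv`.
#' @export
write_count_matrix <- function(mat, design, prefix) {
  dt <- data.table(feature_id = rownames(mat))
  for (j in colnames(mat)) dt[[j]] <- mat[, j]
  fwrite(dt, paste0(prefix, "_counts.tsv"), sep = "\t")
  fwrite(design, paste0(prefix, "_design.tsv"), sep = "\t")
  invisible(prefix)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(prefix) {
  dt <- fread(paste0(prefix, "_counts.tsv"))
  mat <- as.matrix(dt[, -1])
  rownames(mat) <- dt$feature_id
  list(counts = mat, design = fread(paste0(prefix, "_design.tsv")))
}
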