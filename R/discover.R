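#' Detector configuration
#'
#' Houses the coordinate constraints of the discovery step: backsplice
#' coordinates at most 100 kb and at least 50 nt apart, within one annotated
#' gene, with a minimum read support.
#'
#' @param anchor_len exact-match anchor length (nt, >= 12).
#' @param max_mismatches maximum substitutions per read across the breakpoint.
#' @param min_distance,max_distance genomic distance constraint (nt).
#' @param min_support_reads minimum distinct fragments supporting a BSJ.
#' @param require_gt_ag anchor-mode candidates must show GT..AG intronic
#'   dinucleotides in transcription orientation.
#' @param snap_tol snapping tolerance (nt) for the annotation-guided detector.
#' @return A `DetectorConfig` list.
#' @export
detector_config <- function(anchor_len = 20, max_mismatches = 2,
                            min_distance = 50, max_distance = 100000,
                            min_support_reads = 2, require_gt_ag = TRUE,
                            snap_tol = 2) {
  if (anchor_len < 12) stop("anchor_len must be >= 12")
  if (min_distance >= max_distance) stop("min_distance must be < max_distance")
  structure(list(anchor_len = anchor_len, max_mismatches = max_mismatches,
                 min_distance = min_distance, max_distance = max_distance,
                 min_support_reads = min_support_reads,
                 require_gt_ag = require_gt_ag, snap_tol = snap_tol),
            class = "DetectorConfig")
}

empty_scan <- function() {
  data.table(frag_id = character(0), chrom = character(0), start = integer(0),
             end = integer(0), strand = character(0), gtag = logical(0),
             annotated = logical(0))
}

# Core anchor realignment: for every mate that is not colinearly alignable,
# map the terminal anchors; if the 3' anchor lands upstream of the 5' anchor
# the two alignments are extended toward each other to the breakpoint with
# the fewest mismatches. Equal-mismatch breakpoints are resolved by
# preferring annotated exon boundaries, then GT/AG splice signals, then the
# leftmost position. Mates whose anchors support several distinct
# breakpoints are dropped as ambiguous (tallied in attr "n_ambiguous").
scan_backsplices <- function(reads, index, config, annotation = NULL) {
  k <- config$anchor_len
  max_mm <- config$max_mismatches
  mates <- c(reads$mate1, reads$mate2)
  frag <- rep(reads$read_id, 2)
  if (length(mates) == 0) return(setattr(empty_scan(), "n_ambiguous", 0L))
  L <- nchar(mates[1])
  if (k > L / 2) stop("anchor_len exceeds half the read length")

  colin <- place_mates(mates, index, max_mm = max_mm, anchor_offsets = 0L)
  colin_qi <- unique(colin[cmplen == L]$qi)
  todo <- setdiff(seq_along(mates), colin_qi)

  starts_by_chr <- ends_by_chr <- NULL
  if (!is.null(annotation)) {
    ex <- annotation$exons
    starts_by_chr <- split(unique(ex[, .(chrom, start)])$start,
                           unique(ex[, .(chrom, start)])$chrom)
    ends_by_chr <- split(unique(ex[, .(chrom, end)])$end,
                         unique(ex[, .(chrom, end)])$chrom)
  }
  # breakpoint within snap tolerance of an annotated boundary?
  near_pool <- function(x, pool, tol) {
    if (is.null(pool) || length(pool) == 0) return(rep(FALSE, length(x)))
    i <- findInterval(x, pool)
    lo <- pool[pmax(i, 1)]; hi <- pool[pmin(i + 1, length(pool))]
    pmin(abs(x - lo), abs(hi - x)) <= tol
  }
  tlen <- nchar(index$targets)
  n_ambiguous <- 0L

  # one batched anchor lookup for all mates x orientations x {prefix,suffix};
  # the per-read loop below then works on plain vectors only.
  fwd <- mates[todo]; rev_ <- revcomp(fwd)
  oriented <- list("+" = fwd, "-" = rev_)   # indexed by position in `todo`
  anchors <- rbindlist(list(
    data.table(qi = todo, ori = "+", wh = "p", kmer = substr(fwd, 1, k)),
    data.table(qi = todo, ori = "+", wh = "s", kmer = substr(fwd, L - k + 1, L)),
    data.table(qi = todo, ori = "-", wh = "p", kmer = substr(rev_, 1, k)),
    data.table(qi = todo, ori = "-", wh = "s", kmer = substr(rev_, L - k + 1, L))))
  hits <- index$kmers[anchors, on = "kmer", nomatch = NULL,
                      allow.cartesian = TRUE]
  h_ori <- hits$ori; h_wh <- hits$wh; h_target <- hits$target; h_pos <- hits$pos
  by_qi <- split(seq_len(nrow(hits)), factor(hits$qi, levels = todo))

  o_frag <- o_chrom <- o_strand <- character(0)
  o_start <- o_end <- integer(0)
  o_gtag <- o_annot <- logical(0)
  qs <- k:(L - k)

  for (ti in seq_along(todo)) {
    rows <- by_qi[[ti]]
    if (length(rows) == 0) next
    f_chrom <- f_strand <- character(0)
    f_start <- f_end <- integer(0)
    f_gtag <- f_annot <- logical(0)
    for (ori_ in c("+", "-")) {
      sel <- rows[h_ori[rows] == ori_]
      pa <- sel[h_wh[sel] == "p"]
      sb <- sel[h_wh[sel] == "s"]
      if (length(pa) == 0 || length(pa) > 8 ||
          length(sb) == 0 || length(sb) > 8) next
      rint <- utf8ToInt(oriented[[ori_]][ti])
      for (a in pa) for (b in sb) {
        if (h_target[a] != h_target[b]) next
        tg <- h_target[a]; p1 <- h_pos[a]; p2 <- h_pos[b]
        dist <- p1 - p2 + L - k
        if (dist < config$min_distance || dist > config$max_distance) next
        if (p2 + k - L < 0 || p1 + L > tlen[[tg]]) next
        chrseq <- index$targets[[tg]]
        cum1 <- cumsum(rint != utf8ToInt(substr(chrseq, p1 + 1, p1 + L)))
        cum2 <- cumsum(rint != utf8ToInt(substr(chrseq, p2 + k - L + 1, p2 + k)))
        tot <- cum1[qs] + cum2[L] - cum2[qs]
        best <- min(tot)
        if (best > max_mm) next
        cq <- qs[tot == best]
        s0 <- p2 + k - L + cq
        e0 <- p1 + cq
        plus_sig <- substring(chrseq, e0 + 1, e0 + 2) == "GT" &
          substring(chrseq, s0 - 1, s0) == "AG"
        minus_sig <- substring(chrseq, e0 + 1, e0 + 2) == "CT" &
          substring(chrseq, s0 - 1, s0) == "AC"
        ann_ok <- if (is.null(starts_by_chr)) rep(FALSE, length(cq)) else
          near_pool(s0, starts_by_chr[[tg]], config$snap_tol) &
          near_pool(e0, ends_by_chr[[tg]], config$snap_tol)
        pick <- order(!ann_ok, !(plus_sig | minus_sig), cq)[1]
        f_chrom <- c(f_chrom, tg)
        f_start <- c(f_start, s0[pick]); f_end <- c(f_end, e0[pick])
        f_strand <- c(f_strand,
                      if (plus_sig[pick]) "+" else if (minus_sig[pick]) "-" else ori_)
        f_gtag <- c(f_gtag, plus_sig[pick] || minus_sig[pick])
        f_annot <- c(f_annot, ann_ok[pick])
      }
    }
    if (length(f_chrom) == 0) next
    keep <- !duplicated(paste(f_chrom, f_start, f_end))
    if (sum(keep) > 1) { n_ambiguous <- n_ambiguous + 1L; next }
    w <- which(keep)[1]
    o_frag <- c(o_frag, frag[todo[ti]])
    o_chrom <- c(o_chrom, f_chrom[w]); o_strand <- c(o_strand, f_strand[w])
    o_start <- c(o_start, f_start[w]); o_end <- c(o_end, f_end[w])
    o_gtag <- c(o_gtag, f_gtag[w]); o_annot <- c(o_annot, f_annot[w])
  }
  out <- if (length(o_frag) > 0) {
    data.table(frag_id = o_frag, chrom = o_chrom, start = o_start,
               end = o_end, strand = o_strand, gtag = o_gtag,
               annotated = o_annot)
  } else empty_scan()
  setattr(out, "n_ambiguous", n_ambiguous)
  out
}

aggregate_candidates <- function(scan, detector) {
  if (nrow(scan) == 0) {
    out <- data.table(chrom = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      support = integer(0), detector = character(0),
                      splice_signal = character(0))
    return(out)
  }
  # the BSJ interval is strand-symmetric and the library unstranded, so
  # candidates are grouped by coordinates; the strand is taken from the
  # splice signal when one is present, else from the first alignment.
  scan[, .(support = uniqueN(frag_id),
           strand = if (any(gtag)) strand[gtag][1] else strand[1],
           splice_signal = if (any(gtag)) "GT/AG" else "none"),
       by = .(chrom, start, end)][, detector := detector][
         , .(chrom, strand, start, end, support, detector, splice_signal)][]
}

#' Anchor-based de novo backsplice detection
#'
#' Realigns non-colinear mates by their terminal anchors and emits BSJ
#' candidates whose acceptor coordinate is the circle start and donor
#' coordinate the circle end; by default candidates must be flanked by
#' GT..AG intronic dinucleotides in transcription orientation.
#'
#' @param reads a `ReadSet` (RNase R-treated library for discovery).
#' @param index a `GenomeIndex` over the genome with `k = anchor_len`.
#' @param config a `DetectorConfig`.
#' @param scan optional precomputed result of the internal anchor scan, to
#'   share work between detectors.
#' @return data.table of `BsjCandidate` rows (chrom, strand, start, end,
#'   support, detector, splice_signal), 0-based half-open, with attribute
#'   `n_ambiguous` (mates dropped for ambiguous breakpoints).
#' @export
detect_anchor_backsplices <- function(reads, index, config = detector_config(),
                                      scan = NULL) {
  if (is.null(scan)) scan <- scan_backsplices(reads, index, config)
  keep <- if (config$require_gt_ag) scan[gtag == TRUE] else scan
  out <- aggregate_candidates(keep, "anchor")
  setattr(out, "n_ambiguous", attr(scan, "n_ambiguous") %||% 0L)
  out
}

#' Annotation-guided backsplice detection
#'
#' Same anchor realignment, but breakpoints are snapped to the nearest
#' annotated exon start (circle 5') and exon end (circle 3') within
#' `snap_tol` nt; candidates that cannot be snapped are dropped.
#'
#' @inheritParams detect_anchor_backsplices
#' @param annotation a `GenomeModel` or a list with an `exons` data.table.
#' @export
detect_annotated_backsplices <- function(reads, index, annotation,
                                         config = detector_config(), scan = NULL) {
  if (is.null(scan)) scan <- scan_backsplices(reads, index, config, annotation)
  if (nrow(scan) > 0) {
    ex <- annotation$exons
    snap_to <- function(x, pool) {
      if (length(pool) == 0) return(rep(NA_integer_, length(x)))
      i <- findInterval(x, pool, all.inside = FALSE)
      lo <- pool[pmax(i, 1)]; hi <- pool[pmin(i + 1, length(pool))]
      near <- ifelse(abs(x - lo) <= abs(hi - x), lo, hi)
      ifelse(abs(near - x) <= 2, near, NA_integer_)
    }
    scan <- copy(scan)
    for (ch in unique(scan$chrom)) {
      sp <- sort(unique(ex[chrom == ch, start]))
      ep <- sort(unique(ex[chrom == ch, end]))
      scan[chrom == ch, `:=`(start = snap_to(start, sp), end = snap_to(end, ep))]
    }
    scan <- scan[!is.na(start) & !is.na(end)]
  }
  out <- aggregate_candidates(scan, "annotation-exact")
  setattr(out, "n_ambiguous", attr(scan, "n_ambiguous") %||% 0L)
  out
}

#' Filter BSJ candidates into a catalog
#'
#' Keeps candidates whose breakpoints lie inside exactly one gene's span,
#' whose genomic distance is within the configured range, and whose support
#' meets `min_support_reads`; assigns the host gene and its strand.
#'
#' @param cands candidate table from a detector.
#' @param annotation a `GenomeModel` or list with a `genes` data.table.
#' @param config a `DetectorConfig`.
#' @return A `BsjCatalog` data.table (circ_id, chrom, strand, start, end,
#'   gene_id, support, detector, splice_signal).
#' @export
filter_candidates <- function(cands, annotation, config = detector_config()) {
  genes <- annotation$genes
  out <- copy(cands)
  out <- out[end - start >= config$min_distance &
             end - start <= config$max_distance &
             support >= config$min_support_reads]
  if (nrow(out) > 0) {
    gmap <- genes[out[, .(chrom, start, end, key_ = .I)],
                  on = .(chrom, start <= start, end >= end),
                  .(key_ = i.key_, gene_id = x.gene_id, gstrand = x.strand),
                  allow.cartesian = TRUE]
    gmap <- gmap[!is.na(gene_id)]
    ngene <- gmap[, .N, by = key_]
    keep <- ngene[N == 1, key_]
    gmap <- gmap[key_ %in% keep]
    out <- out[gmap$key_]
    out[, `:=`(gene_id = gmap$gene_id, strand = gmap$gstrand)]
  } else {
    out[, gene_id := character(0)]
  }
  out <- unique(out, by = c("chrom", "strand", "start", "end"))
  out[, circ_id := sprintf("%s:%d-%d", chrom, start + 1L, end)]
  setcolorder(out, c("circ_id", "chrom", "strand", "start", "end", "gene_id",
                     "support", "detector", "splice_signal"))
  setattr(out, "class", c("BsjCatalog", class(out)))
  setattr(out, "coords", "0-based-half-open")
  out[]
}

#' Union of BSJ catalogs
#'
#' Set union on (chrom, strand, start, end); support summed, detector
#' provenance concatenated. Idempotent and commutative; the empty catalog is
#' the identity.
#'
#' @param ... two or more `BsjCatalog` tables (or a single list of them).
#' @return A merged `BsjCatalog`.
#' @export
union_catalogs <- function(...) {
  cats <- list(...)
  if (length(cats) == 1 && is.list(cats[[1]]) && !is.data.frame(cats[[1]])) {
    cats <- cats[[1]]
  }
  coords <- unique(unlist(lapply(cats, function(x) attr(x, "coords") %||%
                                   "0-based-half-open")))
  if (length(coords) > 1) stop("catalogs use different coordinate systems")
  all_ <- rbindlist(cats, fill = TRUE)
  if (nrow(all_) == 0) {
    out <- all_
  } else {
    out <- all_[, .(
      gene_id = gene_id[1],
      support = sum(support),
      detector = paste(sort(unique(unlist(strsplit(detector, ",")))), collapse = ","),
      splice_signal = if (any(splice_signal == "GT/AG")) "GT/AG" else "none"),
      by = .(chrom, strand, start, end)]
    out[, circ_id := sprintf("%s:%d-%d", chrom, start + 1L, end)]
    setcolorder(out, c("circ_id", "chrom", "strand", "start", "end", "gene_id",
                       "support", "detector", "splice_signal"))
    setorder(out, chrom, start, end)
  }
  setattr(out, "class", c("BsjCatalog", class(out)))
  setattr(out, "coords", "0-based-half-open")
  out[]
}
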