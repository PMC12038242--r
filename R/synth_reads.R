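# Spliced sequences and fragment-window geometry for the read simulator.

spliced_seq <- function(genome, gid) {
  ex <- genome$exons[gene_id == gid][order(exon_idx)]
  seq <- genome$chromosomes[[ex$chrom[1]]]
  paste0(substring(seq, ex$start + 1, ex$end), collapse = "")
}

circle_seq <- function(genome, truth_row) {
  ex <- genome$exons[gene_id == truth_row$gene_id][order(exon_idx)]
  ex <- ex[exon_idx >= truth_row$exon_first & exon_idx <= truth_row$exon_last]
  seq <- genome$chromosomes[[ex$chrom[1]]]
  paste0(substring(seq, ex$start + 1, ex$end), collapse = "")
}

# Fraction of fragment start positions whose read pair covers >= min_ov nt of
# the 10 nt window at a junction. `jo` = junction offsets within a linear
# sequence of length len; for circles (circular=TRUE) the junction sits at
# every multiple of len along the unrolled sequence.
window_hit_fraction <- function(len, jo, frag_len, read_len, circular = FALSE,
                                min_ov = 8, window = 10) {
  half <- window / 2
  ov_at <- function(a0, a1, w0) pmin(a1, w0 + half) - pmax(a0, w0 - half)
  if (circular) {
    u <- 0:(len - 1)
    hit <- rep(FALSE, len)
    for (m in list(c(0, read_len), c(frag_len - read_len, frag_len))) {
      a0 <- u + m[1]; a1 <- u + m[2]
      for (k in seq_len(ceiling((len + frag_len) / len))) {
        hit <- hit | ov_at(a0, a1, k * len) >= min_ov
      }
    }
    mean(hit)
  } else {
    n_u <- len - frag_len + 1
    if (n_u <= 0) return(0)
    u <- 0:(n_u - 1)
    hit <- rep(FALSE, n_u)
    for (m in list(c(0, read_len), c(frag_len - read_len, frag_len))) {
      for (j in jo) hit <- hit | ov_at(u + m[1], u + m[2], j) >= min_ov
    }
    mean(hit)
  }
}

inject_errors <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0) return(seqs)
  L <- nchar(seqs[1])
  n_err <- rbinom(length(seqs), L, error_rate)
  for (i in which(n_err > 0)) {
    pos <- sample.int(L, n_err[i])
    ch <- strsplit(seqs[i], "")[[1]]
    ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    seqs[i] <- paste0(ch, collapse = "")
  }
  seqs
}

#' Simulate a paired-end sequencing library
#'
#' Draws 150 nt paired-end fragments from the spliced linear transcripts and
#' from the circular sequences of planted circRNAs (junction fragments wrap
#' the backsplice; circles shorter than the fragment length are read from a
#' tandem concatenation of the circular sequence). Expected BSJ-spanning
#' fragment counts are proportional to the planted `copies.<state>` values;
#' expected linear coverage of each forward-splice-junction window equals
#' `fsj_coverage` (in Poisson mode).
#'
#' RNase R treatment is modelled as uniform linear survival: with
#' `rnase_r = TRUE` linear fragment counts are multiplied by
#' `rnase_survival` (default 0.02) while circular fragments are untouched.
#'
#' Two depth modes: `depth = NULL` (Poisson) draws each source's fragment
#' count as Poisson around its expectation, so absolute coverages hold;
#' integer `depth` draws exactly `depth` fragments multinomially from the
#' untreated source weights (RNase R then thins the linear fragments, so a
#' treated library holds fewer than `depth` fragments).
#'
#' @param genome a `GenomeModel`.
#' @param truths circRNA truth table from [plant_circrnas()] (may be empty).
#' @param state which `copies.<state>` column drives circular abundance.
#' @param rnase_r logical; RNase R-treated library.
#' @param depth total fragment count (multinomial mode) or NULL (Poisson).
#' @param error_rate per-base substitution rate, in [0, 0.05).
#' @param seed RNG seed.
#' @param fsj_coverage expected linear fragments over one FSJ window; must
#'   match the value used when planting for CLRs to be calibrated.
#' @param read_len,frag_len read and mean fragment length (nt).
#' @param rnase_survival linear fragment survival under RNase R.
#' @return A `ReadSet`: data.table with read_id, mate1, mate2, src
#'   ("lin"/"circ"), src_id, gene_id, spans_bsj; sample metadata stored as
#'   attributes (state, rnase_r, seed).
#' @export
simulate_library <- function(genome, truths, state = "s1", rnase_r = FALSE,
                             depth = NULL, error_rate = 0, seed,
                             fsj_coverage = 10, read_len = 150, frag_len = 260,
                             rnase_survival = 0.02) {
  if (!is.null(depth) && depth < 0) stop("depth must be >= 0")
  if (error_rate < 0 || error_rate >= 0.05) stop("error_rate must be in [0, 0.05)")
  copies_col <- paste0("copies.", state)
  has_circ <- !is.null(truths) && nrow(truths) > 0
  if (has_circ && !copies_col %in% names(truths)) {
    stop("truths lack column ", copies_col)
  }

  with_seed(seed, {
    # ---- source table: one row per linear transcript and per circle
    gids <- genome$genes$gene_id
    lin <- data.table(src = "lin", src_id = gids, gene_id = gids,
                      seq = vapply(gids, function(g) spliced_seq(genome, g), ""))
    lin[, len := nchar(seq)]
    lin <- lin[len >= read_len]
    lin[, jo := lapply(src_id, function(g) {
      ex <- genome$exons[gene_id == g][order(exon_idx)]
      if (nrow(ex) < 2) return(numeric(0))
      cumsum(ex$end - ex$start)[-nrow(ex)]
    })]
    # per-junction hit probability (averaged over the gene's junctions), so
    # that `weight` fragments give each junction window ~fsj_coverage hits
    lin[, f := mapply(function(l, j) {
      fl <- min(frag_len, l)
      if (length(j) == 0) return(290 / max(l - fl + 1, 1))
      mean(vapply(j, function(j1)
        window_hit_fraction(l, j1, fl, read_len), 0))
    }, len, jo)]
    lin[, weight := fsj_coverage / pmax(f, 1e-9)]

    src <- lin[, .(src, src_id, gene_id, seq, len, weight)]
    if (has_circ) {
      circ <- data.table(src = "circ", src_id = truths$circ_id,
                         gene_id = truths$gene_id,
                         seq = vapply(seq_len(nrow(truths)),
                                      function(i) circle_seq(genome, truths[i]), ""))
      circ[, len := nchar(seq)]
      circ[, f := vapply(len, function(l) {
        window_hit_fraction(l, 0, min(frag_len, max(l, read_len)), read_len,
                            circular = TRUE)
      }, 0)]
      circ[, weight := truths[[copies_col]] / pmax(f, 1e-9)]
      src <- rbind(src, circ[, .(src, src_id, gene_id, seq, len, weight)])
    }

    # ---- fragment counts per source
    if (is.null(depth)) {
      w <- src$weight
      if (rnase_r) w[src$src == "lin"] <- w[src$src == "lin"] * rnase_survival
      counts <- rpois(nrow(src), w)
    } else if (depth == 0) {
      counts <- rep(0L, nrow(src))
    } else {
      counts <- as.vector(stats::rmultinom(1, depth, src$weight / sum(src$weight)))
      if (rnase_r) {
        is_lin <- src$src == "lin"
        counts[is_lin] <- rbinom(sum(is_lin), counts[is_lin], rnase_survival)
      }
    }

    # ---- draw fragments
    rows <- vector("list", nrow(src))
    for (i in which(counts > 0)) {
      n <- counts[i]; sseq <- src$seq[i]; L <- src$len[i]
      circular <- src$src[i] == "circ"
      fl <- if (circular) frag_len else min(frag_len, L)
      if (circular) {
        u <- sample.int(L, n, replace = TRUE) - 1L
        tandem <- paste0(rep(sseq, ceiling((L + fl) / L) + 1L), collapse = "")
        frag <- substring(tandem, u + 1, u + fl)
        # truth: does either mate cover >= 8 nt of a BSJ window (junctions at
        # multiples of L along the unrolled sequence)?
        spans <- rep(FALSE, n)
        for (m in list(c(0, read_len), c(fl - read_len, fl))) {
          for (k in seq_len(ceiling((L + fl) / L))) {
            ov <- pmin(u + m[2], k * L + 5) - pmax(u + m[1], k * L - 5)
            spans <- spans | ov >= 8
          }
        }
      } else {
        u <- sample.int(L - fl + 1, n, replace = TRUE) - 1L
        frag <- substring(sseq, u + 1, u + fl)
        spans <- rep(FALSE, n)
      }
      m1 <- substring(frag, 1, read_len)
      m2 <- revcomp(substring(frag, fl - read_len + 1, fl))
      flip <- runif(n) < 0.5   # unstranded library: random fragment orientation
      tmp <- m1[flip]
      m1[flip] <- revcomp(m2[flip]); m2[flip] <- revcomp(tmp)
      rows[[i]] <- data.table(src = src$src[i], src_id = src$src_id[i],
                              gene_id = src$gene_id[i], mate1 = m1, mate2 = m2,
                              spans_bsj = spans)
    }
    reads <- rbindlist(rows)
    if (nrow(reads) == 0) {
      reads <- data.table(read_id = character(0), mate1 = character(0),
                          mate2 = character(0), src = character(0),
                          src_id = character(0), gene_id = character(0),
                          spans_bsj = logical(0))
    } else {
      reads <- reads[sample(.N)]
      reads[, read_id := sprintf("f%06d", .I)]
      reads[, mate1 := inject_errors(mate1, error_rate)]
      reads[, mate2 := inject_errors(mate2, error_rate)]
      setcolorder(reads, c("read_id", "mate1", "mate2", "src", "src_id",
                           "gene_id", "spans_bsj"))
    }
    setattr(reads, "state", state)
    setattr(reads, "rnase_r", rnase_r)
    setattr(reads, "seed", seed)
    setattr(reads, "read_len", read_len)
    reads[]
  })
}
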