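#' Build an exact-match k-mer index over target sequences
#'
#' Indexes every forward-strand k-mer of the targets (chromosomes and/or
#' junction contigs). Lookups for a query k-mer return all positions; minus
#' strand hits are found by querying the reverse complement.
#'
#' @param targets named character vector of sequences, or a `GenomeModel`.
#' @param k k-mer length (the detector anchor length).
#' @return A `GenomeIndex`: list with `kmers` (keyed data.table kmer ->
#'   target, pos 0-based), `targets` and `k`.
#' @export
index_genome <- function(targets, k = 20) {
  if (inherits(targets, "GenomeModel")) targets <- targets$chromosomes
  if (k < 12) stop("anchor length must be >= 12")
  tabs <- lapply(names(targets), function(nm) {
    s <- targets[[nm]]
    L <- nchar(s)
    if (L < k) return(NULL)
    pos <- 0:(L - k)
    data.table(kmer = substring(s, pos + 1, pos + k), target = nm, pos = pos)
  })
  kmers <- rbindlist(tabs)
  setkey(kmers, kmer)
  structure(list(kmers = kmers, targets = targets, k = k),
            class = "GenomeIndex")
}

#' Look up a k-mer in a genome index
#'
#' @param index a `GenomeIndex`.
#' @param query query k-mer (length must equal `index$k`).
#' @return data.table(target, pos, strand): forward hits on "+", hits of the
#'   reverse complement on "-".
#' @export
lookup_kmer <- function(index, query) {
  stopifnot(nchar(query) == index$k)
  fw <- index$kmers[data.table(kmer = query), on = "kmer",
                    nomatch = NULL][, .(target, pos, strand = "+")]
  rc <- index$kmers[data.table(kmer = revcomp(query)), on = "kmer",
                    nomatch = NULL][, .(target, pos, strand = "-")]
  rbind(fw, rc)
}

# Place mate sequences on the indexed targets by exact-anchor seeding and
# mismatch-counted extension, in both orientations. Placements hanging over
# a target end are clipped (the in-bounds part must satisfy max_mm).
# Returns data.table(qi, target, start, astart, aend, strand, mm, cmplen):
# start = unclipped 0-based placement start, [astart, aend) = clipped span.
place_mates <- function(seqs, index, max_mm = 2, anchor_offsets = NULL) {
  k <- index$k
  L <- nchar(seqs[1])
  if (length(seqs) == 0) {
    return(data.table(qi = integer(0), target = character(0), start = integer(0),
                      astart = integer(0), aend = integer(0), strand = character(0),
                      mm = integer(0), cmplen = integer(0)))
  }
  stopifnot(all(nchar(seqs) == L), k <= L / 2)
  if (is.null(anchor_offsets)) {
    anchor_offsets <- unique(c(0L, as.integer((L - k) / 2), L - k))
  }
  tlen <- nchar(index$targets)
  cand <- list()
  for (ori in c("+", "-")) {
    s <- if (ori == "+") seqs else revcomp(seqs)
    for (off in anchor_offsets) {
      q <- data.table(kmer = substring(s, off + 1, off + k), qi = seq_along(s))
      hits <- index$kmers[q, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
      if (nrow(hits) == 0) next
      hits[, `:=`(start = pos - off, strand = ori)]
      cand[[length(cand) + 1L]] <- hits[, .(qi, target, start, strand)]
    }
  }
  cand <- if (length(cand)) unique(rbindlist(cand)) else
    data.table(qi = integer(0), target = character(0), start = integer(0),
               strand = character(0))
  if (nrow(cand) == 0) {
    return(cand[, .(qi, target, start, astart = integer(0), aend = integer(0),
                    strand, mm = integer(0), cmplen = integer(0))])
  }
  cand[, `:=`(astart = pmax(start, 0L), aend = pmin(start + L, tlen[target]))]
  cand <- cand[aend - astart >= k]
  out <- vector("list", length(unique(cand$target)))
  i <- 0
  for (tg in unique(cand$target)) {
    sub <- cand[target == tg]
    g <- substring(index$targets[[tg]], sub$astart + 1, sub$aend)
    qseq <- ifelse(sub$strand == "+", seqs[sub$qi], revcomp(seqs[sub$qi]))
    r <- substring(qseq, sub$astart - sub$start + 1, sub$aend - sub$start)
    tr <- trim_alignments(r, g)
    sub[, `:=`(astart = astart + tr$from - 1L, aend = astart + tr$to,
               mm = tr$mm)]
    sub[, cmplen := aend - astart]
    i <- i + 1
    out[[i]] <- sub[mm <= max_mm & cmplen >= k]
  }
  rbindlist(out)
}

# Soft-clip emulation: for equal-length string pairs, keep the
# maximal-scoring contiguous sub-interval (match +1, mismatch -3), so that
# chance-matching overhangs at clipped placement ends are trimmed the way an
# aligner would clip them. Vectorized Kadane scan across pairs; returns
# 1-based [from, to] within the pair and the mismatch count inside it.
trim_alignments <- function(a, b) {
  n <- length(a)
  if (n == 0) return(list(from = integer(0), to = integer(0), mm = integer(0)))
  lens <- nchar(a)
  from <- to <- mm <- integer(n)
  for (len in unique(lens)) {
    idx <- which(lens == len)
    am <- matrix(utf8ToInt(paste0(a[idx], collapse = "")), nrow = len)
    bm <- matrix(utf8ToInt(paste0(b[idx], collapse = "")), nrow = len)
    neq <- am != bm
    m <- length(idx)
    best <- cur <- cn <- numeric(m)
    start_cur <- rep(1L, m); cn_start <- numeric(m)
    bs <- be <- rep(0L, m); cn_bs <- cn_be <- numeric(m)
    for (r in seq_len(len)) {
      s <- ifelse(neq[r, ], -3, 1)
      fresh <- cur <= 0
      start_cur[fresh] <- r
      cn_start[fresh] <- cn[fresh]
      cur <- ifelse(fresh, s, cur + s)
      cn <- cn + neq[r, ]
      upd <- cur > best
      best[upd] <- cur[upd]
      bs[upd] <- start_cur[upd]; be[upd] <- r
      cn_bs[upd] <- cn_start[upd]; cn_be[upd] <- cn[upd]
    }
    none <- be == 0L          # no positive-scoring interval at all
    bs[none] <- 1L; be[none] <- 0L
    from[idx] <- bs; to[idx] <- be
    mm[idx] <- as.integer(cn_be - cn_bs)
  }
  list(from = from, to = to, mm = mm)
}
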