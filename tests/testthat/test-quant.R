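toy_catalog <- function(g, start, end, gene_id) {
  data.table(circ_id = sprintf("%s:%d-%d", "chrT", start + 1L, end),
             chrom = "chrT", strand = "+", start = start, end = end,
             gene_id = gene_id)
}

test_that("junction contigs follow the 100 nt merge rule", {
  g <- make_toy_genome()
  chrom <- g$chromosomes[[1]]
  lib <- build_junction_library(toy_catalog(g, 100L, 600L, "gA"), g)
  expect_equal(lib$sequence, paste0(substr(chrom, 501, 600), substr(chrom, 101, 200)))
  expect_equal(lib$junction_offset, 100)
  # short circle: halves of floor(len/2), no duplicated bases
  lib2 <- build_junction_library(toy_catalog(g, 100L, 220L, "gA"), g)
  expect_equal(nchar(lib2$sequence), 120)
  expect_equal(lib2$junction_offset, 60)
  expect_equal(lib2$sequence, paste0(substr(chrom, 161, 220), substr(chrom, 101, 160)))
  # two circles sharing a start get distinct contigs
  two <- rbind(toy_catalog(g, 100L, 600L, "gA"), toy_catalog(g, 100L, 1050L, "gA"))
  expect_equal(uniqueN(build_junction_library(two, g)$circ_id), 2)
})

test_that("adjacent FSJs are the nearest annotated junctions outside the circle", {
  g <- make_toy_genome()
  fsj <- build_fsj_library(g)
  expect_equal(nrow(fsj), 3)   # gA has 2 junctions, gB has 1
  # circle over gA exon 2 only: fsj5 = junction 1, fsj3 = junction 2
  map_mid <- adjacent_fsjs(toy_catalog(g, 500L, 600L, "gA"), fsj)
  expect_equal(map_mid$fsj5_id, "gA:fsj1")
  expect_equal(map_mid$fsj3_id, "gA:fsj2")
  # circle starting at the gene's first exon: fsj5 absent
  map_first <- adjacent_fsjs(toy_catalog(g, 100L, 600L, "gA"), fsj)
  expect_true(is.na(map_first$fsj5_id))
  expect_equal(map_first$fsj3_id, "gA:fsj2")
})

test_that("the 8-of-10 window rule counts fragments exactly", {
  contigs <- data.table(circ_id = "c1", junction_offset = 100L)
  mk_pl <- function(astart, aend, read_id = "r1", mate = 1L) {
    data.table(read_id = read_id, mate = mate, target = "c1",
               target_type = "bsj", astart = astart, aend = aend,
               strand = "+", mm = 0L)
  }
  # covering [offset-8, offset+3): 8 nt inside the centred window -> counted
  expect_equal(count_bsj(mk_pl(92L, 103L), contigs)$bsj_count, 1)
  # covering [offset-7, offset+2): only 7 nt inside -> not counted
  expect_equal(count_bsj(mk_pl(93L, 102L), contigs)$bsj_count, 0)
  # both mates of one pair over the window count once
  both <- rbind(mk_pl(90L, 110L, "r1", 1L), mk_pl(88L, 108L, "r1", 2L))
  expect_equal(count_bsj(both, contigs)$bsj_count, 1)
  # multi-mapped fragments count toward every contig
  c2 <- data.table(circ_id = c("c1", "c2"), junction_offset = c(100L, 100L))
  multi <- rbind(mk_pl(90L, 110L), mk_pl(90L, 110L))
  multi$target <- c("c1", "c2")
  expect_equal(count_bsj(multi, c2)$bsj_count, c(1, 1))
})

test_that("count_bsj matches a brute-force overlap enumeration", {
  set.seed(401)
  contigs <- data.table(circ_id = sprintf("c%02d", 1:5),
                        junction_offset = sample(60:140, 5))
  n <- 1000
  pl <- data.table(
    read_id = sprintf("r%04d", sample(600, n, replace = TRUE)),
    mate = sample(1:2, n, replace = TRUE),
    target = sample(contigs$circ_id, n, replace = TRUE),
    target_type = "bsj",
    astart = sample(0:150, n, replace = TRUE))
  pl[, aend := astart + sample(20:150, n, replace = TRUE)]
  pl[, `:=`(strand = "+", mm = 0L)]
  got <- count_bsj(pl, contigs)
  # independent oracle: per-fragment loop over every placement
  for (ci in contigs$circ_id) {
    jo <- contigs[circ_id == ci, junction_offset]
    w0 <- jo - 5; w1 <- jo + 5
    frags <- unique(pl[target == ci, read_id])
    n_exp <- sum(vapply(frags, function(f) {
      rows <- pl[target == ci & read_id == f]
      any(pmin(rows$aend, w1) - pmax(rows$astart, w0) >= 8)
    }, TRUE))
    expect_equal(got[circ_id == ci, bsj_count], n_exp)
  }
})

test_that("FSJ counting uses the window rule and reports absent junctions as NA", {
  g <- make_toy_genome()
  fsj <- build_fsj_library(g)
  cat1 <- toy_catalog(g, 100L, 600L, "gA")   # fsj5 absent, fsj3 = gA:fsj2
  fmap <- adjacent_fsjs(cat1, fsj)
  jo <- fsj[fsj_id == "gA:fsj2", junction_offset]
  pl <- data.table(read_id = c("r1", "r2"), mate = 1L,
                   target = "gA:fsj2", target_type = "fsj",
                   astart = c(jo - 8L, jo - 7L), aend = c(jo + 3L, jo + 2L),
                   strand = "+", mm = 0L)
  cnt <- count_fsj(pl, fsj, fmap)
  expect_true(is.na(cnt$fsj5_count))
  expect_equal(cnt$fsj3_count, 1)            # only r1 reaches 8 nt overlap
})

test_that("junction-wrapping reads are placed on their contig across the junction", {
  fx <- shared_sim()
  g <- fx$genome; tr <- fx$truths
  catal <- tr[, .(circ_id = sprintf("%s:%d-%d", chrom, bsj_start + 1, bsj_end),
                  chrom, strand, start = bsj_start, end = bsj_end, gene_id)]
  bsj_lib <- build_junction_library(catal, g)
  fsj_lib <- build_fsj_library(g)
  lib <- simulate_library(g, tr, state = "a", rnase_r = FALSE, seed = 320,
                          fsj_coverage = 20)
  pl <- assign_fragments(lib, g, bsj_lib, fsj_lib)
  counts <- count_bsj(pl, bsj_lib)
  # simulator truth is the oracle: every BSJ-window-spanning fragment of a
  # planted circle is recovered by contig counting
  truth <- lib[src == "circ", .(expected = sum(spans_bsj)), by = src_id]
  truth[, circ_id := catal$circ_id[match(src_id, tr$circ_id)]]
  m <- merge(counts, truth, by = "circ_id")
  expect_gt(nrow(m), 5)
  # loci where a linear junction shares enough flanking sequence with the
  # backsplice absorb forward-splice reads into the BSJ window; those reads
  # are correctly counted by the window rule though they are not circular
  amb_ids <- flag_ambiguous_junctions(catal, g)[ambiguous == TRUE, circ_id]
  clean <- m[!circ_id %in% amb_ids]
  expect_equal(clean$bsj_count, clean$expected)
  expect_true(all(m$bsj_count >= m$expected))
  # linear reads never reach the BSJ window of unambiguous loci
  lin_ids <- lib[src == "lin", read_id]
  lin_on_bsj <- pl$placements[read_id %in% lin_ids & target_type == "bsj" &
                              !target %in% amb_ids]
  if (nrow(lin_on_bsj) > 0) {
    lin_on_bsj <- merge(lin_on_bsj, bsj_lib, by.x = "target", by.y = "circ_id")
    expect_false(any(circlr:::window_covered(lin_on_bsj$astart, lin_on_bsj$aend,
                                             lin_on_bsj$junction_offset)))
  }
})

test_that("estimated CLR tracks the planted circular-to-linear ratios", {
  # >= 20x junction coverage: CLRs from 0.2 at 50x linear junction coverage
  # put at least ~10 expected BSJ fragments on every circle per replicate;
  # the median CLR over three replicates is compared with the planted truth
  fx <- shared_sim()
  g <- fx$genome
  tr <- plant_circrnas(g, 15, seed = 330, clr_range = c(0.2, 2),
                       fsj_coverage = 50)
  catal <- tr[, .(circ_id = sprintf("%s:%d-%d", chrom, bsj_start + 1, bsj_end),
                  chrom, strand, start = bsj_start, end = bsj_end, gene_id,
                  clr_truth)]
  catal <- flag_ambiguous_junctions(catal, g)[ambiguous == FALSE]
  bsj_lib <- build_junction_library(catal, g)
  fsj_lib <- build_fsj_library(g)
  fmap <- adjacent_fsjs(catal, fsj_lib)
  qidx <- index_genome(c(g$chromosomes,
                         setNames(bsj_lib$sequence, bsj_lib$circ_id),
                         setNames(fsj_lib$sequence, fsj_lib$fsj_id)), 20)
  cids <- count_bsj(data.table(read_id = character(0), mate = integer(0),
                               target = character(0), target_type = character(0),
                               astart = integer(0), aend = integer(0),
                               strand = character(0), mm = integer(0)),
                    bsj_lib)$circ_id
  clr_reps <- vapply(1:3, function(r) {
    lib <- simulate_library(g, tr, state = "s1", rnase_r = FALSE,
                            seed = 330 + r, fsj_coverage = 50)
    pl <- assign_fragments(lib, g, bsj_lib, fsj_lib, index = qidx)
    bc <- count_bsj(pl, bsj_lib)
    stopifnot(identical(bc$circ_id, cids))
    fc <- count_fsj(pl, fsj_lib, fmap)
    compute_clr(bc$bsj_count, fc$fsj5_count[match(cids, fc$circ_id)],
                fc$fsj3_count[match(cids, fc$circ_id)])
  }, numeric(nrow(catal)))
  est <- apply(clr_reps, 1, median)
  truth <- catal$clr_truth[match(cids, catal$circ_id)]
  rho <- cor(est, truth, method = "spearman")
  expect_gte(rho, 0.8)
})

test_that("junction-ambiguity flagging detects shared flank sequence", {
  # construct a genome where the exon downstream of the circle starts with
  # the same 4 bases as the circle's first exon
  chrom <- strrep("T", 1000)
  put <- function(s, at, what) { substr(s, at, at + nchar(what) - 1) <- what; s }
  chrom <- put(chrom, 101, paste0("ATTGAC", strrep("C", 94)))   # exon 1 (circle)
  chrom <- put(chrom, 301, paste0("GGGGGG", strrep("G", 94)))   # exon 2 (circle)
  chrom <- put(chrom, 501, paste0("ATTGTC", strrep("A", 94)))   # exon 3 (after)
  ann <- list(
    chromosomes = c(chrC = chrom),
    exons = data.table(gene_id = "g1", chrom = "chrC", strand = "+",
                       exon_idx = 1:3,
                       start = c(100L, 300L, 500L), end = c(200L, 400L, 600L)),
    genes = data.table(gene_id = "g1", chrom = "chrC", strand = "+",
                       start = 100L, end = 600L))
  catal <- data.table(circ_id = "c1", chrom = "chrC", strand = "+",
                      start = 100L, end = 400L, gene_id = "g1")
  flagged <- flag_ambiguous_junctions(catal, ann)
  expect_true(flagged$ambiguous)   # exon2->exon3 reads mimic the BSJ window
  # breaking the shared prefix removes the flag
  ann2 <- ann
  ann2$chromosomes[["chrC"]] <- put(chrom, 501, "CCCGGA")
  expect_false(flag_ambiguous_junctions(catal, ann2)$ambiguous)
})

test_that("robust filter reproduces the >=2 reads in >=3 replicates rule", {
  design <- data.table(sample_id = sprintf("s%d", 1:9),
                       time = rep(c("d0", "d5", "d12"), each = 3))
  mat <- rbind(
    kept_d5 = c(0, 0, 0, 2, 2, 2, 0, 0, 0),
    dropped_two_of_three = c(2, 2, 0, 2, 2, 0, 2, 2, 0),
    dropped_low = c(1, 1, 1, 1, 1, 1, 1, 1, 1),
    kept_high = c(9, 9, 9, 0, 0, 0, 0, 0, 0))
  colnames(mat) <- design$sample_id
  out <- robust_filter(mat, design)
  expect_identical(rownames(out), c("kept_d5", "kept_high"))
  # idempotent and a subset of the input
  expect_identical(robust_filter(out, design), out)
  # all-small design warns and returns empty
  d2 <- data.table(sample_id = c("s1", "s2"), time = c("d0", "d0"))
  expect_warning(r2 <- robust_filter(mat[, 1:2], d2), "replicates")
  expect_equal(nrow(r2), 0)
})

test_that("CLR follows #BSJ/(mean(#FSJ)+1) with absent-junction handling", {
  expect_equal(compute_clr(10, 4, 6), 10 / 6, tolerance = 1e-12)
  expect_equal(compute_clr(0, 7, 3), 0)
  expect_equal(compute_clr(5, NA, NA), 5)
  expect_equal(compute_clr(6, 3, NA), 6 / 4)
  set.seed(402)
  b <- rpois(500, 5); f5 <- rpois(500, 8); f3 <- rpois(500, 8)
  expect_equal(compute_clr(b, f5, f3), b / ((f5 + f3) / 2 + 1))
})

test_that("CPM normalization is exact and scale-invariant", {
  m <- matrix(c(5, 0, 15, 20), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(compute_cpm(m, c(1e6, 1e6))["a", "s1"], 5)
  expect_equal(compute_cpm(m, c(100, 100)), compute_cpm(2 * m, c(200, 200)))
  expect_error(compute_cpm(m, c(0, 100)), "positive")
  # sum of CPM over counted features equals 1e6 when the library size is the
  # counted total
  expect_equal(colSums(compute_cpm(m, colSums(m))), c(s1 = 1e6, s2 = 1e6))
})

test_that("circularization metrics aggregate replicates per stage", {
  cpm <- matrix(c(60, 40, 150, 50, 10, 0), nrow = 2,
                dimnames = list(c("c1", "c2"), c("r1", "r2", "r3")))
  raw <- matrix(c(3, 2, 9, 3, 1, 0), nrow = 2,
                dimnames = dimnames(cpm))
  design <- data.table(sample_id = c("r1", "r2", "r3"),
                       stage = c("early", "early", "late"))
  met <- circ_metrics(cpm, design, raw_mat = raw)
  expect_equal(met$per_replicate$cumulative_cpm, c(100, 200, 10))
  expect_equal(met$per_replicate$diversity, c(2, 2, 1))
  expect_equal(met$per_stage[stage == "early", cumulative_cpm], 150)
  expect_equal(met$per_replicate$normalized_load[3], 10)
})

test_that("coherence quadrants classify sign pairs and exclude zeros", {
  q <- coherence_quadrants(c(1, -1, 1, -2), c(1, -1, -1, -0.5))
  expect_equal(q$coherent_fraction, 3 / 4)
  expect_equal(unname(q$counts), c(1, 2, 1, 0))
  expect_equal(coherence_quadrants(c(1, 2), c(3, 4))$coherent_fraction, 1)
  qz <- coherence_quadrants(c(1, 0, 1), c(1, 1, 2))
  expect_equal(qz$n_used, 2)
  expect_equal(qz$n_excluded, 1)
})
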