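#' Convert between internal and reported coordinates
#'
#' Internal coordinates are 0-based half-open; reports use 1-based inclusive
#' ("chrN: start-end"). The round trip is the identity.
#'
#' @param record data.table (or list) with `start` and `end` fields.
#' @param direction "internal_to_report" or "report_to_internal".
#' @return the record with converted coordinates.
#' @export
convert_coordinates <- function(record, direction = c("internal_to_report",
                                                      "report_to_internal")) {
  direction <- match.arg(direction)
  rec <- if (is.data.table(record)) copy(record) else as.data.table(record)
  if (direction == "internal_to_report") {
    if (any(rec$start >= rec$end)) stop("empty or inverted interval")
    rec[, start := start + 1L]
  } else {
    if (any(rec$start > rec$end)) stop("inverted interval")
    rec[, start := start - 1L]
  }
  rec[]
}

#' Assemble a pipeline configuration
#'
#' All thresholds of the analysis (distance constraints, 8-of-10 window,
#' robust filter, significance cuts) live here with their standard defaults;
#' every stochastic stage derives its own sub-seed from the global seed by
#' stable hashing of the stage name. The configuration round-trips through
#' YAML.
#'
#' @param seed global seed.
#' @param outdir output directory.
#' @param n_chrom,n_genes,n_circ genome/truth sizes.
#' @param states the two biological states contrasted by the pipeline.
#' @param state_multiplier global circular-output multiplier per state.
#' @param n_reps untreated replicates per state.
#' @param fsj_coverage linear per-junction fragment coverage.
#' @param discovery_copies expected BSJ fragments per circRNA in the pooled
#'   RNase R-treated discovery library.
#' @param error_rate per-base substitution rate.
#' @param cohort classify-stage cohort settings (features, per-class n,
#'   informative, effect, dispersion).
#' @param detector a [detector_config()].
#' @param thresholds a [de_thresholds()].
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(seed = 1, outdir = tempfile("circlr_run_"),
                            n_chrom = 1, n_genes = 30, n_circ = 15,
                            states = c("progenitor", "differentiated"),
                            state_multiplier = c(progenitor = 1,
                                                 differentiated = 2.8),
                            n_reps = 3, fsj_coverage = 10,
                            discovery_copies = c(15, 40), error_rate = 0,
                            cohort = list(n_features = 200, n_per_class = 20,
                                          n_informative = 10,
                                          effect_log2fc = 2, dispersion = 0.1),
                            detector = detector_config(),
                            thresholds = de_thresholds()) {
  structure(list(seed = seed, outdir = outdir, n_chrom = n_chrom,
                 n_genes = n_genes, n_circ = n_circ, states = states,
                 state_multiplier = state_multiplier, n_reps = n_reps,
                 fsj_coverage = fsj_coverage,
                 discovery_copies = discovery_copies, error_rate = error_rate,
                 cohort = cohort, detector = detector,
                 thresholds = thresholds), class = "PipelineConfig")
}

#' Write / read a pipeline configuration as YAML
#' @param config a `PipelineConfig`.
#' @param path YAML file.
#' @export
write_config <- function(config, path) {
  out <- unclass(rapply(config, unclass, how = "replace"))
  out$state_multiplier <- as.list(out$state_multiplier)  # keep names in YAML
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (nm in names(raw)) cfg[[nm]] <- raw[[nm]]
  cfg$state_multiplier <- unlist(cfg$state_multiplier)
  cfg$detector <- do.call(detector_config, as.list(cfg$detector))
  cfg$thresholds <- do.call(de_thresholds, as.list(cfg$thresholds))
  cfg
}

stage_done <- function(files) all(file.exists(files))

#' Run the full pipeline: simulate, discover, quantify, test, classify
#'
#' Orchestrates the end-to-end analysis from a single configuration. Every
#' stage writes its outputs (FASTA/GTF/FASTQ/BED/TSV) under `outdir` and is
#' recorded in a manifest (file checksums, sub-seeds); with `resume = TRUE`
#' stages whose outputs already exist are skipped.
#'
#' @param config a `PipelineConfig`.
#' @param resume skip stages with complete outputs.
#' @param quiet suppress progress messages.
#' @return A `RunReport` list: manifest, file paths and key in-memory
#'   results (catalog, counts, metrics, DE tables, ROC).
#' @export
run_pipeline <- function(config, resume = FALSE, quiet = FALSE) {
  out <- config$outdir
  dirs <- file.path(out, c("sim", "discover", "quant", "de", "classify"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  manifest <- list(seed = config$seed, stages = list())
  report <- list()

  # ---- stage: simulate ---------------------------------------------------
  sseed <- derive_seed(config$seed, "simulate")
  sim_dir <- file.path(out, "sim")
  genome_fa <- file.path(sim_dir, "genome.fa")
  gtf <- file.path(sim_dir, "annotation.gtf")
  truth_tsv <- file.path(sim_dir, "circ_truth.tsv")
  design_tsv <- file.path(sim_dir, "design.tsv")
  genome <- generate_genome(config$n_chrom, config$n_genes, seed = sseed)
  truths <- plant_circrnas(genome, config$n_circ, seed = sseed + 1L,
                           states = config$states,
                           state_multiplier = config$state_multiplier,
                           fsj_coverage = config$fsj_coverage)
  with_seed(sseed + 2L, {
    truths[, copies.discovery := runif(.N, config$discovery_copies[1],
                                       config$discovery_copies[2])]
  })
  design <- CJ(state = config$states, replicate = seq_len(config$n_reps),
               sorted = FALSE)
  design[, sample_id := sprintf("%s_r%d", state, replicate)]
  design[, `:=`(time = state, rnase_r = FALSE)]
  fq_prefixes <- file.path(sim_dir, c("treated_pool", design$sample_id))
  sim_files <- c(genome_fa, gtf, truth_tsv, design_tsv,
                 paste0(rep(fq_prefixes, each = 2), "_", 1:2, ".fastq.gz"))
  if (!(resume && stage_done(sim_files))) {
    say("simulate: ", config$n_genes, " genes, ", config$n_circ, " circRNAs")
    write_genome_fasta(genome, genome_fa)
    write_annotation_gtf(genome, gtf)
    fwrite(truths, truth_tsv, sep = "\t")
    fwrite(design, design_tsv, sep = "\t")
    treated <- simulate_library(genome, truths, state = "discovery",
                                rnase_r = TRUE, error_rate = config$error_rate,
                                seed = sseed + 10L,
                                fsj_coverage = config$fsj_coverage)
    write_fastq_pair(treated, file.path(sim_dir, "treated_pool"))
    for (i in seq_len(nrow(design))) {
      lib <- simulate_library(genome, truths, state = design$state[i],
                              rnase_r = FALSE, error_rate = config$error_rate,
                              seed = sseed + 20L + i,
                              fsj_coverage = config$fsj_coverage)
      write_fastq_pair(lib, file.path(sim_dir, design$sample_id[i]))
    }
  } else say("simulate: resumed")
  manifest$stages$simulate <- list(seed = sseed, files = sim_files)

  # ---- stage: discover ---------------------------------------------------
  dseed <- derive_seed(config$seed, "discover")
  disc_dir <- file.path(out, "discover")
  bed <- file.path(disc_dir, "catalog.bed")
  cat_tsv <- file.path(disc_dir, "catalog.tsv")
  treated <- read_fastq_pair(file.path(sim_dir, "treated_pool"))
  gindex <- index_genome(genome, k = config$detector$anchor_len)
  if (!(resume && stage_done(c(bed, cat_tsv)))) {
    say("discover: scanning ", nrow(treated), " fragments")
    scan <- scan_backsplices(treated, gindex, config$detector, annotation = genome)
    anchor <- detect_anchor_backsplices(treated, gindex, config$detector, scan = scan)
    annot <- detect_annotated_backsplices(treated, gindex, genome,
                                          config$detector, scan = scan)
    catalog <- union_catalogs(
      filter_candidates(anchor, genome, config$detector),
      filter_candidates(annot, genome, config$detector))
    write_catalog(catalog, bed, cat_tsv)
  } else {
    catalog <- fread(cat_tsv)
    catalog <- convert_coordinates(
      catalog[, .(circ_id, chrom = sub(":.*", "", region),
                  start = as.integer(sub(".*:(\\d+)-.*", "\\1", region)),
                  end = as.integer(sub(".*-", "", region)), strand, gene_id,
                  support, detector)], "report_to_internal")
    say("discover: resumed")
  }
  manifest$stages$discover <- list(seed = dseed, files = c(bed, cat_tsv),
                                   n_bsj = nrow(catalog))


  # ---- stage: quantify ---------------------------------------------------
  quant_dir <- file.path(out, "quant")
  counts_prefix <- file.path(quant_dir, "bsj")
  clr_tsv <- file.path(quant_dir, "clr.tsv")
  metrics_tsv <- file.path(quant_dir, "metrics.tsv")
  say("quantify: ", nrow(catalog), " circRNAs x ", nrow(design), " samples")
  catalog <- flag_ambiguous_junctions(catalog, genome)
  report$catalog <- catalog
  quant_cat <- catalog[ambiguous == FALSE]
  bsj_lib <- build_junction_library(quant_cat, genome)
  fsj_lib <- build_fsj_library(genome)
  fsj_map <- adjacent_fsjs(quant_cat, fsj_lib)
  qindex <- index_genome(c(genome$chromosomes,
                           setNames(bsj_lib$sequence, bsj_lib$circ_id),
                           setNames(fsj_lib$sequence, fsj_lib$fsj_id)),
                         k = config$detector$anchor_len)
  bsj_mat <- matrix(0L, nrow(quant_cat), nrow(design),
                    dimnames = list(quant_cat$circ_id, design$sample_id))
  fsj5_mat <- fsj3_mat <- bsj_mat
  lib_sizes <- setNames(numeric(nrow(design)), design$sample_id)
  for (i in seq_len(nrow(design))) {
    lib <- read_fastq_pair(file.path(sim_dir, design$sample_id[i]))
    pl <- assign_fragments(lib, genome, bsj_lib, fsj_lib, index = qindex,
                           k = config$detector$anchor_len)
    bsj_mat[, i] <- count_bsj(pl, bsj_lib)[match(quant_cat$circ_id, circ_id), bsj_count]
    fsj <- count_fsj(pl, fsj_lib, fsj_map)
    fsj5_mat[, i] <- fsj[match(quant_cat$circ_id, circ_id), fsj5_count]
    fsj3_mat[, i] <- fsj[match(quant_cat$circ_id, circ_id), fsj3_count]
    lib_sizes[i] <- pl$library_size
  }
  robust <- robust_filter(bsj_mat, design, time_col = "time")
  cpm <- compute_cpm(bsj_mat, lib_sizes)
  clr_mat <- vapply(seq_len(ncol(bsj_mat)), function(j)
    compute_clr(bsj_mat[, j], fsj5_mat[, j], fsj3_mat[, j]),
    numeric(nrow(bsj_mat)))
  dimnames(clr_mat) <- dimnames(bsj_mat)
  metrics <- circ_metrics(cpm, design, raw_mat = bsj_mat, stage_col = "state")
  write_count_matrix(bsj_mat, design, counts_prefix)
  fwrite(data.table(circ_id = rownames(clr_mat), clr_mat), clr_tsv, sep = "\t")
  fwrite(metrics$per_replicate, metrics_tsv, sep = "\t")
  manifest$stages$quantify <- list(files = c(paste0(counts_prefix, "_counts.tsv"),
                                             clr_tsv, metrics_tsv),
                                   library_sizes = as.list(lib_sizes))
  report <- c(report, list(bsj = bsj_mat, fsj5 = fsj5_mat, fsj3 = fsj3_mat,
                           clr = clr_mat, cpm = cpm, robust = robust,
                           metrics = metrics, lib_sizes = lib_sizes,
                           design = design, truths = truths, genome = genome))

  # ---- stage: differential -----------------------------------------------
  de_dir <- file.path(out, "de")
  de_tsv <- file.path(de_dir, "de_results.tsv")
  declr_tsv <- file.path(de_dir, "de_clr.tsv")
  groups <- factor(design$state, levels = config$states)
  de_res <- NULL
  if (nrow(robust) >= 1) {
    say("differential: ", nrow(robust), " robust circRNAs")
    de_res <- nb_wald_test(robust, groups)
    write_de_results(de_res, de_tsv)
    declr <- differential_clr(clr_mat[rownames(robust), , drop = FALSE], groups,
                              seed = derive_seed(config$seed, "de"))
    write_de_results(declr, declr_tsv)
    report$de <- de_res
    report$de_clr <- declr
    manifest$stages$de <- list(files = c(de_tsv, declr_tsv))
  }

  # ---- stage: classify (synthetic two-class cohort) ----------------------
  cseed <- derive_seed(config$seed, "classify")
  cls_dir <- file.path(out, "classify")
  co <- config$cohort
  say("classify: cohort ", co$n_features, " features, 2 x ", co$n_per_class,
      " samples")
  cohort <- simulate_cohort_matrix(co$n_features, co$n_per_class,
                                   co$n_informative, co$effect_log2fc,
                                   co$dispersion, seed = cseed)
  xmat <- t(compute_cpm(cohort$counts))
  ranks <- rank_features(xmat, cohort$classes, seed = cseed)
  fwrite(ranks, file.path(cls_dir, "feature_ranks.tsv"), sep = "\t")
  top <- ranks$feature_id[seq_len(min(10, nrow(ranks)))]
  cv <- kfold_cv_classify(xmat[, top, drop = FALSE], cohort$classes,
                          k = min(10, nrow(xmat)), seed = cseed)
  fwrite(cv$roc, file.path(cls_dir, "roc_points.tsv"), sep = "\t")
  jsonlite::write_json(
    list(selected_features = top, auc = cv$auc,
         informative_truth = cohort$informative),
    file.path(cls_dir, "model_card.json"), auto_unbox = TRUE, digits = NA)
  report$roc <- cv
  report$cohort <- cohort
  manifest$stages$classify <- list(
    seed = cseed, files = file.path(cls_dir, c("feature_ranks.tsv",
                                               "roc_points.tsv",
                                               "model_card.json")),
    auc = cv$auc)

  # ---- manifest ----------------------------------------------------------
  all_files <- unlist(lapply(manifest$stages, `[[`, "files"))
  manifest$checksums <- as.list(tools::md5sum(all_files[file.exists(all_files)]))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  report$manifest <- manifest
  class(report) <- "RunReport"
  report
}
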