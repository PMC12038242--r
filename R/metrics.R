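#' Global circularization metrics
#'
#' Per replicate: cumulative circularization (sum of CPM-normalized BSJ
#' counts over all circRNAs), diversity (number of distinct circRNA species
#' expressed, default raw count >= 1) and the diversity-normalized load
#' (cumulative CPM / diversity). Per stage: means over replicates.
#'
#' @param cpm_mat circRNAs x samples CPM matrix.
#' @param design data.table with sample_id and stage columns.
#' @param raw_mat raw count matrix used for the expression threshold
#'   (defaults to thresholding the CPM matrix at > 0).
#' @param expression_threshold minimum raw count for a species to count as
#'   expressed.
#' @param stage_col name of the stage column in `design`.
#' @return A `CircMetrics` list: `per_replicate` (sample_id, stage,
#'   cumulative_cpm, diversity, normalized_load) and `per_stage` (means).
#' @export
circ_metrics <- function(cpm_mat, design, raw_mat = NULL,
                         expression_threshold = 1, stage_col = "stage") {
  stage <- design[[stage_col]][match(colnames(cpm_mat), design$sample_id)]
  expressed <- if (is.null(raw_mat)) cpm_mat > 0 else raw_mat >= expression_threshold
  per_rep <- data.table(
    sample_id = colnames(cpm_mat), stage = stage,
    cumulative_cpm = colSums(cpm_mat),
    diversity = colSums(expressed))
  per_rep[, normalized_load := ifelse(diversity > 0, cumulative_cpm / diversity, NA_real_)]
  per_stage <- per_rep[, .(cumulative_cpm = mean(cumulative_cpm),
                           diversity = mean(diversity),
                           normalized_load = mean(normalized_load, na.rm = TRUE)),
                       by = stage]
  structure(list(per_replicate = per_rep, per_stage = per_stage),
            class = "CircMetrics")
}

#' Quadrant analysis of circular vs linear changes
#'
#' Classifies paired log2 changes (circRNA vs host/FSJ) into the four sign
#' quadrants and reports the coherent fraction (up/up + down/down among
#' pairs where both members are nonzero and defined).
#'
#' @param circ_changes,linear_changes paired numeric log2-change vectors.
#' @return list with `counts` (up_up, down_down, up_down, down_up),
#'   `n_used`, `n_excluded` and `coherent_fraction`.
#' @export
coherence_quadrants <- function(circ_changes, linear_changes) {
  stopifnot(length(circ_changes) == length(linear_changes))
  ok <- is.finite(circ_changes) & is.finite(linear_changes) &
    circ_changes != 0 & linear_changes != 0
  cc <- circ_changes[ok]; ll <- linear_changes[ok]
  counts <- c(up_up = sum(cc > 0 & ll > 0),
              down_down = sum(cc < 0 & ll < 0),
              up_down = sum(cc > 0 & ll < 0),
              down_up = sum(cc < 0 & ll > 0))
  list(counts = counts, n_used = sum(ok), n_excluded = sum(!ok),
       coherent_fraction = if (sum(ok) > 0)
         unname((counts["up_up"] + counts["down_down"]) / sum(ok)) else NA_real_)
}
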