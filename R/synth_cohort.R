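#' Simulate a two-class cohort count matrix with planted informative features
#'
#' Counts are negative binomial (variance = mu + dispersion * mu^2) around
#' log-normal baseline means. The first `n_informative` features carry a
#' class effect of `effect_log2fc` (class B mean = baseline * 2^effect).
#'
#' @param n_features number of features (rows).
#' @param n_per_class samples per class (classes "A" and "B").
#' @param n_informative number of features with a planted class effect.
#' @param effect_log2fc planted log2 fold change (B vs A).
#' @param dispersion NB dispersion alpha (>= 0).
#' @param seed RNG seed.
#' @param base_mean_meanlog,base_mean_sdlog log-normal baseline parameters.
#' @return list with `counts` (features x samples integer matrix),
#'   `classes` (factor of "A"/"B" per sample) and `informative`
#'   (character vector of planted feature ids).
#' @export
simulate_cohort_matrix <- function(n_features, n_per_class, n_informative,
                                   effect_log2fc = 2, dispersion = 0.1, seed,
                                   base_mean_meanlog = log(50),
                                   base_mean_sdlog = 0.8) {
  if (n_informative > n_features) stop("n_informative > n_features")
  if (dispersion < 0) stop("dispersion must be >= 0")
  with_seed(seed, {
    n <- 2 * n_per_class
    classes <- factor(rep(c("A", "B"), each = n_per_class))
    base <- exp(rnorm(n_features, base_mean_meanlog, base_mean_sdlog))
    mu <- matrix(base, n_features, n, byrow = FALSE)
    if (n_informative > 0) {
      mu[seq_len(n_informative), classes == "B"] <-
        mu[seq_len(n_informative), classes == "B"] * 2^effect_log2fc
    }
    counts <- if (dispersion == 0) {
      matrix(rpois(length(mu), mu), n_features, n)
    } else {
      matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion), n_features, n)
    }
    rownames(counts) <- sprintf("feat%04d", seq_len(n_features))
    colnames(counts) <- sprintf("%s_%02d", classes, unlist(lapply(
      table(classes), seq_len)))
    list(counts = counts, classes = classes,
         informative = rownames(counts)[seq_len(n_informative)])
  })
}

#' Simulate paired circular/linear log2 changes with known coherence
#'
#' Generates per-feature (circRNA change, host linear change) pairs in which
#' a fixed fraction is concordant in sign by construction, as ground truth
#' for the quadrant/coherence analysis.
#'
#' @param n number of feature pairs.
#' @param p_coherent probability a pair is sign-concordant.
#' @param seed RNG seed.
#' @param sd magnitude scale of the changes.
#' @return data.table with feature_id, circ_change, linear_change, coherent.
#' @export
simulate_coherent_changes <- function(n, p_coherent = 0.75, seed, sd = 1.5) {
  with_seed(seed, {
    mag_c <- abs(rnorm(n, 0, sd)) + 0.05
    mag_l <- abs(rnorm(n, 0, sd)) + 0.05
    sign_c <- sample(c(-1, 1), n, replace = TRUE)
    coh <- runif(n) < p_coherent
    sign_l <- ifelse(coh, sign_c, -sign_c)
    data.table(feature_id = sprintf("feat%04d", seq_len(n)),
               circ_change = sign_c * mag_c,
               linear_change = sign_l * mag_l,
               coherent = coh)
  })
}
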