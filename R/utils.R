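#' @import data.table
#' @importFrom stats rpois rbinom rnbinom rnorm runif median var pnorm p.adjust predict sd quantile
#' @importFrom utils combn head tail
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(old <- get0(".Random.seed", globalenv(), ifnotfound = NULL))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Derive a stage-specific sub-seed from a global seed
#'
#' Stable polynomial hash of the stage name folded into the global seed, so
#' that each stochastic pipeline stage gets its own reproducible RNG stream
#' independent of execution order.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return An integer below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  h <- 0
  for (v in utf8ToInt(stage)) h <- (h * 131 + v) %% 1000000007
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629L)
}

revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- NULL
  out
}

# Per-pair Hamming distance between equal-length string pairs (lengths may
# vary across pairs). 'N' in either string never matches unless both 'N'.
str_mismatches <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- nchar(a)
  if (any(n != nchar(b))) stop("str_mismatches: unequal lengths within a pair")
  out <- integer(length(a))
  for (len in unique(n)) {
    idx <- which(n == len)
    if (len == 0L) { out[idx] <- 0L; next }
    am <- matrix(utf8ToInt(paste0(a[idx], collapse = "")), nrow = len)
    bm <- matrix(utf8ToInt(paste0(b[idx], collapse = "")), nrow = len)
    out[idx] <- as.integer(colSums(am != bm))
  }
  out
}

rand_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste0(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
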