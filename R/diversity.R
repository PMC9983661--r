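## Occupation rates and transcriptome Shannon entropy ("liberality").
## A sample whose expression is concentrated on few genes (differentiated
## tissue) has low entropy; a flattened profile (dedifferentiating
## culture) has high entropy.

#' Occupation rates of genes in one sample
#'
#' Normalizes a non-negative count vector to the per-gene share of total
#' expressed transcripts, the probability vector over which entropy is
#' computed. Order is preserved; zeros pass through.
#'
#' @param counts non-negative numeric vector of gene counts.
#' @param sampleId identifier used in error messages.
#' @return numeric probability vector summing to 1, names preserved.
#' @examples
#' occupationRates(c(10, 30, 60))
#' @export
occupationRates <- function(counts, sampleId = "sample") {
  if (any(!is.finite(counts) | counts < 0))
    liberalityError("validation_error",
      "counts for %s contain negative or non-finite entries", sampleId)
  total <- sum(counts)
  if (total <= 0)
    liberalityError("empty_library_error",
      "empty library: all counts are zero for %s", sampleId)
  counts / total
}

#' Shannon entropy of an occupation profile
#'
#' `H = -sum(p_i * log(p_i))` over the genes with `p_i > 0`; terms with
#' `p_i = 0` contribute nothing (no pseudocounts). Base 2 gives bits,
#' the package default throughout.
#'
#' @param p probability vector (occupation rates); must be non-negative
#'   and sum to 1 within `1e-9`.
#' @param base logarithm base; 2 for bits (default), `exp(1)` for nats.
#' @return entropy, a non-negative scalar.
#' @examples
#' shannonEntropy(rep(1/4, 4))         # 2 bits
#' shannonEntropy(c(0.5, 0.25, 0.25))  # 1.5 bits
#' @export
shannonEntropy <- function(p, base = 2) {
  if (any(!is.finite(p) | p < 0))
    liberalityError("validation_error",
      "occupation rates must be finite and >= 0")
  if (abs(sum(p) - 1) > 1e-9)
    liberalityError("validation_error",
      "occupation rates must sum to 1 (got %.12g)", sum(p))
  p <- p[p > 0]
  -sum(p * log(p)) / log(base)
}

#' Miller-Madow bias correction for the plug-in entropy estimator
#'
#' The plug-in estimator is negatively biased at finite library size;
#' the first-order correction adds `(m - 1) / (2 N)` nats, i.e.
#' `(m - 1) / (2 N ln 2)` bits, where `m` is the number of observed
#' (non-zero) genes and `N` the library size.
#'
#' @param H plug-in entropy estimate, in units of `base`.
#' @param m observed (non-zero) gene count, >= 1.
#' @param N library size (total counts), >= 1.
#' @param base logarithm base of `H`.
#' @return the corrected entropy, same units as `H`.
#' @export
millerMadow <- function(H, m, N, base = 2) {
  if (N < 1)
    liberalityError("validation_error", "library size N must be >= 1")
  if (m < 1)
    liberalityError("validation_error", "observed gene count m must be >= 1")
  if (H < 0)
    liberalityError("validation_error", "entropy must be >= 0")
  H + (m - 1) / (2 * N * log(base))
}

#' Per-sample transcriptome diversity table
#'
#' Computes, for every sample of a count matrix, the Shannon entropy of
#' its occupation rates plus derived indices: Pielou-style evenness
#' `H / log2(m)` and the effective number of genes `2^H` (for base 2),
#' the count of equally-expressed genes giving the same entropy.
#'
#' Entropy is scale-invariant per sample, so raw and library-size
#' normalized counts give identical results. An optional per-gene weight
#' vector (e.g. inverse transcript length) reweights counts before
#' normalization.
#'
#' @param counts a `SummarizedExperiment` with a `"counts"` assay, or a
#'   numeric matrix with dimnames (genes x samples).
#' @param estimator `"plugin"` (default) or `"miller_madow"`.
#' @param base logarithm base; 2 (bits) by default.
#' @param geneWeights optional positive per-gene weights, length
#'   `nrow(counts)`.
#' @return a `data.frame` with one row per sample and columns
#'   `sample_id`, `H_bits` (named `H_nats` for `base = exp(1)`,
#'   `H` otherwise), `estimator`, `G_total`, `m`, `N`, `evenness`,
#'   `effective_genes`.
#' @examples
#' m <- cbind(A = rep(1, 8), B = c(8, rep(0, 7)))
#' rownames(m) <- paste0("g", 1:8)
#' diversityTable(m)
#' @export
diversityTable <- function(counts, estimator = c("plugin", "miller_madow"),
                           base = 2, geneWeights = NULL) {
  estimator <- match.arg(estimator)
  counts <- validateCounts(counts)
  m <- SummarizedExperiment::assay(counts, "counts")
  if (!is.null(geneWeights)) {
    if (length(geneWeights) != nrow(m) || any(geneWeights <= 0))
      liberalityError("validation_error",
        "geneWeights must be positive and match the gene count")
    m <- m * geneWeights
  }
  res <- lapply(colnames(m), function(sid) {
    p <- occupationRates(m[, sid], sampleId = sid)
    H <- shannonEntropy(p, base = base)
    mObs <- sum(p > 0)
    N <- sum(SummarizedExperiment::assay(counts, "counts")[, sid])
    if (estimator == "miller_madow")
      H <- millerMadow(H, mObs, N, base = base)
    data.frame(sample_id = sid, H = H, estimator = estimator,
               G_total = nrow(m), m = mObs, N = N,
               evenness = if (mObs >= 2) H / (log(mObs) / log(base)) else NA_real_,
               effective_genes = base^H,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  names(out)[names(out) == "H"] <-
    if (base == 2) "H_bits" else if (isTRUE(all.equal(base, exp(1)))) "H_nats" else "H"
  rownames(out) <- NULL
  out
}
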