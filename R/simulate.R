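## Synthetic experiment generator: a tempered Zipf expression model with
## multinomial read sampling. A Zipf rank-abundance base profile stands in
## for the skewed transcriptome of differentiated tissue; raising it to
## 1/tau ("temperature") flattens it towards uniform, tracing the
## differentiated -> dedifferentiated continuum on the entropy scale.

entropyBits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Zipf rank-abundance profile
#'
#' Occupation rates proportional to `i^-s` over gene ranks
#' `i = 1..G`; `s = 0` gives the uniform profile, larger `s` a more
#' skewed (more "differentiated") one.
#'
#' @param G number of genes, >= 2.
#' @param s rank-abundance exponent, >= 0.
#' @return probability vector of length `G`.
#' @examples
#' zipfProfile(3, 1)  # 6/11, 3/11, 2/11
#' @export
zipfProfile <- function(G, s) {
  if (G < 2)
    liberalityError("validation_error", "G must be >= 2 (got %s)", format(G))
  if (s < 0)
    liberalityError("validation_error", "s must be >= 0")
  w <- seq_len(G)^(-s)
  w / sum(w)
}

#' Temper an occupation profile
#'
#' Returns the profile with `p_i` proportional to `q_i^(1/tau)`,
#' computed in log space for numerical stability. `tau = 1` is the
#' identity; `tau -> Inf` flattens towards uniform over the support;
#' `tau -> 0` concentrates on the maximal entries. Zeros stay zero.
#'
#' @param q probability vector.
#' @param tau temperature, > 0.
#' @return tempered probability vector, same length and support as `q`.
#' @export
temperProfile <- function(q, tau) {
  if (!is.finite(tau) || tau <= 0)
    liberalityError("validation_error", "tau must be > 0 (got %s)",
                    format(tau))
  p <- numeric(length(q))
  pos <- q > 0
  lq <- log(q[pos]) / tau
  v <- exp(lq - max(lq))
  p[pos] <- v / sum(v)
  p
}

#' Solve the temperature attaining a target entropy
#'
#' Entropy of `temperProfile(q, tau)` is non-decreasing in `tau`, from
#' `log2(#maximal entries)` as `tau -> 0` up to `log2(m)` (uniform over
#' the `m` support genes) as `tau -> Inf`. This bisects on `log(tau)`
#' until the entropy is within `tol` bits of the target.
#'
#' @param q base probability vector.
#' @param Htarget target entropy, bits; must lie strictly inside the
#'   attainable range.
#' @param tol tolerance in bits; default `1e-6`.
#' @param tauRange search interval for `tau`; targets outside the
#'   entropies attainable on this interval raise a range error that
#'   reports the attainable bounds.
#' @return the temperature `tau`.
#' @export
solveTemperature <- function(q, Htarget, tol = 1e-6,
                             tauRange = c(1e-4, 1e6)) {
  pos <- q > 0
  m <- sum(pos)
  Hsup <- log2(m)
  Hlo <- entropyBits(temperProfile(q, tauRange[1]))
  Hhi <- entropyBits(temperProfile(q, tauRange[2]))
  if (Htarget < Hlo - tol || Htarget > Hhi + tol)
    liberalityError("range_error",
      "target entropy %.6g bits outside attainable range [%.6g, %.6g] (support max %.6g)",
      Htarget, Hlo, Hhi, Hsup)
  lo <- log(tauRange[1]); hi <- log(tauRange[2])
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    H <- entropyBits(temperProfile(q, exp(mid)))
    if (abs(H - Htarget) <= tol) return(exp(mid))
    if (H < Htarget) lo <- mid else hi <- mid
  }
  exp((lo + hi) / 2)
}

#' Simulate a synthetic entropy--dose experiment
#'
#' For each covariate level `d` and replicate, draws a target entropy
#' `H0 + beta * d + eps` with `eps ~ N(0, noiseSd^2)`, clips it to the
#' attainable range (clipping is flagged, never silent), solves the
#' temperature whose tempered Zipf profile attains it, and samples `N`
#' reads from that profile by multinomial sampling. With a positive
#' contaminant fraction `c`, the sampling profile becomes the mixture
#' `(1-c) * host + c * uniform` over a disjoint contaminant gene block
#' (ids prefixed `contam_`), emulating viral transcripts in an infected
#' culture.
#'
#' A single RNG stream seeded from `config@seed` is consumed in a fixed
#' sample order (per sample: the entropy noise draw, then the
#' multinomial draw), so identical configurations reproduce counts
#' exactly.
#'
#' @param config a [SimulationConfig-class].
#' @param covariate `"dose"` (levels are dilution fractions; treatment
#'   is `"mulberry"` at positive dose, `"control"` at zero, `time_h`
#'   fixed at 90) or `"time_h"` (levels are hours; dose 0, treatment
#'   `"control"`).
#' @param strain strain label recorded in the sample sheet.
#' @return a `SummarizedExperiment` with assay `"counts"`; `colData`
#'   holds the sample sheet plus per-sample truth (`H_target` before
#'   clipping, `H_true` the exact entropy of the sampling profile,
#'   `tau`, `clipped`); `metadata()$truth` holds the true sampling
#'   profiles (genes x samples) and the config.
#' @examples
#' se <- simulateExperiment(SimulationConfig(genes = 200, libSize = 5000))
#' SummarizedExperiment::colData(se)[, c("sample_id", "dose", "H_true")]
#' @export
simulateExperiment <- function(config = SimulationConfig(),
                               covariate = c("dose", "time_h"),
                               strain = "p50") {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  covariate <- match.arg(covariate)
  G <- config@genes
  cfrac <- config@contaminantFraction
  Gc <- if (cfrac > 0) config@contaminantGenes else 0L
  q <- zipfProfile(G, config@zipfExponent)

  tauRange <- c(1e-4, 1e6)
  Hmin <- entropyBits(temperProfile(q, tauRange[1]))
  Hmax <- entropyBits(temperProfile(q, tauRange[2]))
  noiseless <- config@baselineEntropy + config@doseEffect * config@doses
  if (any(noiseless <= Hmin) || any(noiseless >= Hmax))
    liberalityError("range_error",
      "noiseless entropy targets [%.6g, %.6g] leave the attainable range (%.6g, %.6g); adjust H0/beta/doses",
      min(noiseless), max(noiseless), Hmin, Hmax)

  set.seed(config@seed, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")

  levels <- rep(config@doses, each = config@reps)
  nS <- length(levels)
  ids <- sprintf("S%02d", seq_len(nS))
  geneIds <- c(sprintf("gene_%05d", seq_len(G)),
               if (Gc > 0) sprintf("contam_%04d", seq_len(Gc)))
  counts <- matrix(0, nrow = G + Gc, ncol = nS,
                   dimnames = list(geneIds, ids))
  profiles <- matrix(0, nrow = G + Gc, ncol = nS,
                     dimnames = list(geneIds, ids))
  Htarget <- Htrue <- tau <- numeric(nS)
  clipped <- logical(nS)

  for (j in seq_len(nS)) {
    eps <- rnorm(1, 0, config@noiseSd)
    Htarget[j] <- config@baselineEntropy + config@doseEffect * levels[j] + eps
    h <- min(max(Htarget[j], Hmin), Hmax)
    clipped[j] <- h != Htarget[j]
    tau[j] <- solveTemperature(q, h, tol = 1e-6, tauRange = tauRange)
    host <- temperProfile(q, tau[j])
    prof <- if (Gc > 0) c(host * (1 - cfrac), rep(cfrac / Gc, Gc))
            else host
    profiles[, j] <- prof
    Htrue[j] <- entropyBits(prof)
    counts[, j] <- rmultinom(1, config@libSize, prof)
  }

  cd <- S4Vectors::DataFrame(
    sample_id = ids, strain = strain,
    treatment = if (covariate == "dose")
      ifelse(levels > 0, "mulberry", "control") else "control",
    dose = if (covariate == "dose") levels else 0,
    time_h = if (covariate == "time_h") levels else 90,
    H_target = Htarget, H_true = Htrue, tau = tau, clipped = clipped,
    row.names = ids)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd,
    rowData = S4Vectors::DataFrame(gene_id = geneIds,
      contaminant = startsWith(geneIds, "contam_")))
  S4Vectors::metadata(se) <- list(
    truth = list(profiles = profiles, H_true = Htrue, config = config))
  se
}

#' Extract the sample sheet from a simulated experiment
#'
#' @param se a `SummarizedExperiment` from [simulateExperiment()].
#' @return a `data.frame` with the five sample-sheet columns.
#' @export
simulatedSampleSheet <- function(se) {
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  rownames(cd) <- NULL
  cd[, c("sample_id", "strain", "treatment", "dose", "time_h")]
}

#' Write a simulated experiment to disk
#'
#' Emits the formats [readCounts()] and [readSampleSheet()] consume:
#' `<prefix>_counts.tsv`, `<prefix>_samples.csv`, a `<prefix>_truth.tsv`
#' table of per-sample ground truth, and a flat `key=value`
#' `<prefix>_config.txt` for provenance.
#'
#' @param se a `SummarizedExperiment` from [simulateExperiment()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix; default `"sim"`.
#' @return invisibly, a named character vector of the paths written.
#' @export
writeSimulation <- function(se, dir, prefix = "sim") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, paste0(prefix, "_counts.tsv")),
    samples = file.path(dir, paste0(prefix, "_samples.csv")),
    truth = file.path(dir, paste0(prefix, "_truth.tsv")),
    config = file.path(dir, paste0(prefix, "_config.txt")))
  writeCounts(se, paths["counts"], format = "tsv")
  sheet <- simulatedSampleSheet(se)
  write.table(sheet, paths["samples"], sep = ",", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  rownames(cd) <- NULL
  writeTable(cd[, c("sample_id", "H_target", "H_true", "tau", "clipped")],
             paths["truth"])
  cfg <- S4Vectors::metadata(se)$truth$config
  kv <- c(genes = cfg@genes, libSize = cfg@libSize,
          zipfExponent = cfg@zipfExponent,
          baselineEntropy = cfg@baselineEntropy,
          doseEffect = cfg@doseEffect, noiseSd = cfg@noiseSd,
          doses = paste(cfg@doses, collapse = ","), reps = cfg@reps,
          contaminantFraction = cfg@contaminantFraction,
          contaminantGenes = cfg@contaminantGenes, seed = cfg@seed)
  writeLines(paste0(names(kv), "=", kv), paths["config"])
  invisible(paths)
}
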