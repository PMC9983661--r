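#' Slope test for entropy against a covariate
#'
#' Result of an ordinary least-squares fit of per-sample transcriptome
#' entropy (bits) against a scalar covariate (extract dose as a dilution
#' fraction, or culture time in hours), with a two-sided t-test on the
#' slope. Produced by [fitSlope()] and [entropyTrendTest()].
#'
#' @slot contrast human-readable label of the samples/covariate tested.
#' @slot n number of samples in the fit.
#' @slot betaHat slope estimate, bits per covariate unit.
#' @slot interceptHat intercept, bits.
#' @slot seBeta standard error of the slope.
#' @slot tStat t statistic, `betaHat / seBeta`.
#' @slot df residual degrees of freedom, `n - 2`.
#' @slot pValue two-sided p-value for the null hypothesis of zero slope.
#' @slot perfectFit `TRUE` when the residual sum of squares is zero while
#'   the slope is not; the p-value is then reported as 0.
#' @slot encoding covariate encoding used (`"fraction"` or `"log10"`).
#'
#' @seealso [fitSlope()], [entropyTrendTest()]
#' @export
setClass("SlopeTest",
  representation(
    contrast     = "character",
    n            = "integer",
    betaHat      = "numeric",
    interceptHat = "numeric",
    seBeta       = "numeric",
    tStat        = "numeric",
    df           = "numeric",
    pValue       = "numeric",
    perfectFit   = "logical",
    encoding     = "character"
  )
)

setValidity("SlopeTest", function(object) {
  msg <- character()
  if (object@df != object@n - 2L || object@df < 1)
    msg <- c(msg, "df must equal n - 2 and be >= 1")
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    msg <- c(msg, "pValue must lie in [0, 1]")
  if (is.finite(object@seBeta) && object@seBeta > 0 &&
      abs(object@tStat - object@betaHat / object@seBeta) >
        1e-8 * max(1, abs(object@tStat)))
    msg <- c(msg, "tStat must equal betaHat / seBeta")
  if (length(msg)) msg else TRUE
})

#' Configuration of a synthetic entropy--dose experiment
#'
#' Parameters of the synthetic-data generator in [simulateExperiment()].
#' The generator draws, for each dose level and replicate, a target
#' entropy `H0 + beta * dose + noise`, solves the temperature of a
#' tempered Zipf expression profile attaining it, and samples a read
#' library from that profile by multinomial sampling.
#'
#' @slot genes number of annotated genes G.
#' @slot libSize reads per sample N.
#' @slot zipfExponent rank-abundance exponent s of the base profile
#'   (`q_i` proportional to `i^-s`).
#' @slot baselineEntropy H0, control-sample entropy target in bits.
#' @slot doseEffect beta, bits of entropy per covariate unit.
#' @slot noiseSd replicate-level standard deviation of the entropy
#'   target, bits.
#' @slot doses covariate levels (dilution fractions, or hours when
#'   simulating a time course).
#' @slot reps replicates per covariate level.
#' @slot contaminantFraction fraction of reads drawn from a disjoint
#'   uniform contaminant gene block (viral transcripts in an infected
#'   culture), in [0, 1).
#' @slot contaminantGenes size of the contaminant block.
#' @slot seed integer RNG seed; identical configurations with identical
#'   seeds reproduce counts exactly.
#'
#' @seealso [simulateExperiment()]
#' @export
setClass("SimulationConfig",
  representation(
    genes               = "integer",
    libSize             = "integer",
    zipfExponent        = "numeric",
    baselineEntropy     = "numeric",
    doseEffect          = "numeric",
    noiseSd             = "numeric",
    doses               = "numeric",
    reps                = "integer",
    contaminantFraction = "numeric",
    contaminantGenes    = "integer",
    seed                = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@genes < 2) msg <- c(msg, "genes must be >= 2")
  if (object@libSize < 1) msg <- c(msg, "libSize must be >= 1")
  if (object@zipfExponent < 0) msg <- c(msg, "zipfExponent must be >= 0")
  if (object@baselineEntropy <= 0 ||
      object@baselineEntropy > log2(object@genes))
    msg <- c(msg, "baselineEntropy must lie in (0, log2(genes)]")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(object@doses) < 1 || any(object@doses < 0))
    msg <- c(msg, "doses must be non-negative")
  if (object@reps < 1) msg <- c(msg, "reps must be >= 1")
  if (object@contaminantFraction < 0 || object@contaminantFraction >= 1)
    msg <- c(msg, "contaminantFraction must lie in [0, 1)")
  if (object@contaminantGenes < 1)
    msg <- c(msg, "contaminantGenes must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn SimulationConfig-class Constructor with study-shaped
#'   defaults: about fourteen thousand genes, a control plus 1/1000 and
#'   1/100 dilutions with three replicates each, and an entropy decrease
#'   with dose.
#' @param genes,libSize,zipfExponent,baselineEntropy,doseEffect,noiseSd
#'   see slots.
#' @param doses,reps,contaminantFraction,contaminantGenes,seed see slots.
#' @export
SimulationConfig <- function(genes = 14000L, libSize = 1000000L,
                             zipfExponent = 1, baselineEntropy = 10,
                             doseEffect = -50, noiseSd = 0.05,
                             doses = c(0, 0.001, 0.01), reps = 3L,
                             contaminantFraction = 0,
                             contaminantGenes = 100L, seed = 1L) {
  new("SimulationConfig",
      genes = as.integer(genes), libSize = as.integer(libSize),
      zipfExponent = as.numeric(zipfExponent),
      baselineEntropy = as.numeric(baselineEntropy),
      doseEffect = as.numeric(doseEffect), noiseSd = as.numeric(noiseSd),
      doses = as.numeric(doses), reps = as.integer(reps),
      contaminantFraction = as.numeric(contaminantFraction),
      contaminantGenes = as.integer(contaminantGenes),
      seed = as.integer(seed))
}
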