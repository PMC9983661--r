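#' @rdname SlopeTest-class
#' @param object a `SlopeTest` or `SimulationConfig`.
#' @export
setGeneric("betaHat", function(object) standardGeneric("betaHat"))

#' @rdname SlopeTest-class
#' @export
setGeneric("seBeta", function(object) standardGeneric("seBeta"))

#' @rdname SlopeTest-class
#' @export
setGeneric("tStat", function(object) standardGeneric("tStat"))

#' @rdname SlopeTest-class
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @rdname SlopeTest-class
#' @export
setGeneric("degreesOfFreedom",
           function(object) standardGeneric("degreesOfFreedom"))

setMethod("betaHat", "SlopeTest", function(object) object@betaHat)
setMethod("seBeta", "SlopeTest", function(object) object@seBeta)
setMethod("tStat", "SlopeTest", function(object) object@tStat)
setMethod("pValue", "SlopeTest", function(object) object@pValue)
setMethod("degreesOfFreedom", "SlopeTest", function(object) object@df)

setMethod("show", "SlopeTest", function(object) {
  cat("Entropy trend test (OLS slope, two-sided t)\n")
  cat("  contrast: ", object@contrast, "\n", sep = "")
  cat(sprintf("  n = %d, covariate encoding = %s\n",
              object@n, object@encoding))
  cat(sprintf("  slope = %.6g bits/unit (se = %.6g), intercept = %.6g bits\n",
              object@betaHat, object@seBeta, object@interceptHat))
  cat(sprintf("  t = %.6g on %d df, p = %.6g%s\n",
              object@tStat, as.integer(object@df), object@pValue,
              if (object@perfectFit) "  [perfect fit]" else ""))
  invisible(object)
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  %d genes, %d reads/sample, Zipf exponent %.3g\n",
              object@genes, object@libSize, object@zipfExponent))
  cat(sprintf("  entropy: H0 = %.3g bits, dose effect = %.3g bits/unit, noise sd = %.3g bits\n",
              object@baselineEntropy, object@doseEffect, object@noiseSd))
  cat(sprintf("  design: doses {%s} x %d reps; contaminant fraction %.3g (%d genes); seed %d\n",
              paste(signif(object@doses, 4), collapse = ", "),
              object@reps, object@contaminantFraction,
              object@contaminantGenes, object@seed))
  invisible(object)
})

#' Coerce a SlopeTest to a one-row data.frame
#'
#' @param x a `SlopeTest`.
#' @param ... ignored.
#' @return a one-row `data.frame` with the table columns written by
#'   [writeTable()]: contrast_name, n, beta_hat, se_beta, t_stat, df,
#'   p_two_sided, covariate_encoding.
#' @export
as.data.frame.SlopeTest <- function(x, ...) {
  data.frame(contrast_name = x@contrast, n = x@n,
             beta_hat = x@betaHat, intercept_hat = x@interceptHat,
             se_beta = x@seBeta, t_stat = x@tStat, df = x@df,
             p_two_sided = x@pValue,
             covariate_encoding = x@encoding,
             stringsAsFactors = FALSE)
}

#' Confidence interval for the slope
#'
#' @param object a `SlopeTest`.
#' @param parm ignored (the slope is the only parameter).
#' @param level confidence level; default 0.95.
#' @param ... ignored.
#' @return a 1 x 2 matrix with the lower and upper bounds for the slope.
#' @importFrom stats confint qt
#' @export
confint.SlopeTest <- function(object, parm = "beta", level = 0.95, ...) {
  crit <- qt(1 - (1 - level) / 2, df = object@df)
  out <- matrix(object@betaHat + c(-1, 1) * crit * object@seBeta,
                nrow = 1,
                dimnames = list("beta", sprintf("%g %%",
                  c((1 - level) / 2, 1 - (1 - level) / 2) * 100)))
  out
}
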