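## Simple linear model of per-sample entropy against a covariate (extract
## dose or culture time) with a two-sided t-test on the slope, computed
## from first principles via centred sums. stats::lm is deliberately not
## called; it serves as an independent cross-check in the test suite.

#' Two-sided Student-t p-value
#'
#' `p = I_x(df/2, 1/2)` with `x = df / (df + t^2)`, the regularized
#' incomplete beta form of the two-sided tail probability of the t
#' distribution; symmetric in the sign of `t`. For `df = 1` the exact
#' Cauchy form `1 - 2 atan(|t|) / pi` is used (analytically equal,
#' numerically exact at e.g. `t = 1`).
#'
#' @param t t statistic.
#' @param df degrees of freedom, >= 1.
#' @return the two-sided p-value; vectorized over `t`.
#' @examples
#' studentTTwoSidedP(1, 1)   # 0.5 (Cauchy)
#' studentTTwoSidedP(0, 7)   # 1
#' @export
studentTTwoSidedP <- function(t, df) {
  if (df < 1)
    liberalityError("validation_error", "df must be >= 1 (got %s)",
                    format(df))
  p <- if (df == 1) 1 - 2 * atan(abs(t)) / pi
       else pbeta(df / (df + t^2), df / 2, 0.5)
  p[!is.finite(t)] <- 0
  p[t == 0] <- 1
  p
}

#' Ordinary least-squares slope with t-test
#'
#' Fits `y = intercept + beta * x` by centred sums
#' (`beta = Sxy / Sxx`), with `se_beta = sqrt(SSE / (n - 2) / Sxx)`,
#' `t = beta / se_beta` and a two-sided p-value from
#' [studentTTwoSidedP()]. This is the inferential step used to ask
#' whether extract concentration (or culture time) affects transcriptome
#' entropy: the null hypothesis is a zero slope.
#'
#' Degenerate inputs: a constant `y` yields `beta = 0`, `t = 0`,
#' `p = 1` (no signal). A perfect fit (`SSE = 0` with a non-zero slope)
#' reports `p = 0` with a warning and `perfectFit = TRUE` rather than
#' erroring, so simulation sweeps never abort.
#'
#' @param x covariate vector (dose fraction or hours), >= 2 distinct
#'   values.
#' @param y entropy vector, bits; same length as `x`, `n >= 3`.
#' @param contrast label stored in the result.
#' @param encoding covariate encoding label stored in the result.
#' @return a [SlopeTest-class] object.
#' @examples
#' fitSlope(c(0, 1, 2, 3), c(1, 2, 1, 4))
#' @export
fitSlope <- function(x, y, contrast = "entropy ~ covariate",
                     encoding = "fraction") {
  n <- length(x)
  if (length(y) != n)
    liberalityError("validation_error", "x and y differ in length")
  if (n < 3)
    liberalityError("insufficient_data_error",
      "need >= 3 samples to test a slope (got %d)", n)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    liberalityError("validation_error", "x and y must be finite")
  xc <- x - mean(x)
  yc <- y - mean(y)
  Sxx <- sum(xc^2)
  if (Sxx == 0)
    liberalityError("zero_variance_error",
      "covariate is constant (single level: %s); slope undefined",
      format(x[1]))
  Sxy <- sum(xc * yc)
  Syy <- sum(yc^2)
  beta <- Sxy / Sxx
  intercept <- mean(y) - beta * mean(x)
  SSE <- max(0, Syy - beta * Sxy)
  df <- n - 2L
  if (Syy == 0) {                      # constant response: no signal
    se <- 0; tval <- 0; p <- 1; perfect <- FALSE
  } else if (SSE <= 1e-12 * Syy) {     # exact linear relation
    se <- 0; tval <- sign(beta) * Inf; p <- 0; perfect <- TRUE
    liberalityWarning("perfect_fit_warning",
      "perfect linear fit (SSE = 0); p-value reported as 0")
  } else {
    se <- sqrt(SSE / df / Sxx)
    tval <- beta / se
    p <- studentTTwoSidedP(tval, df)
    perfect <- FALSE
  }
  new("SlopeTest", contrast = contrast, n = as.integer(n),
      betaHat = beta, interceptHat = intercept, seBeta = se,
      tStat = tval, df = as.numeric(df), pValue = p,
      perfectFit = perfect, encoding = encoding)
}

#' Entropy trend test on a selected sample subset
#'
#' Joins a per-sample diversity table to a sample sheet by `sample_id`,
#' applies strain/treatment filters, and regresses entropy on the chosen
#' covariate. This reproduces the study design's contrasts: within one
#' strain, control plus the extract dilutions against `dose`, or the
#' culture time course against `time_h` (midgut/cabbage arms are
#' excluded from dose regressions by the treatment filter).
#'
#' @param diversity a `data.frame` from [diversityTable()] (column
#'   `H_bits`, or `H_nats`/`H` for other bases).
#' @param sheet a sample sheet `data.frame` (see [readSampleSheet()]).
#' @param covariate `"dose"` or `"time_h"`.
#' @param strain optional strain label to keep.
#' @param treatments optional treatment labels to keep (e.g.
#'   `c("control", "mulberry")` for a dose regression).
#' @param encoding `"fraction"` uses the covariate as recorded;
#'   `"log10"` uses `log10(covariate + d0)` (a pure log scale is
#'   precluded by the zero-dose controls).
#' @param d0 offset for the `"log10"` encoding; default the smallest
#'   positive covariate value divided by 10.
#' @return a [SlopeTest-class] object.
#' @export
entropyTrendTest <- function(diversity, sheet,
                             covariate = c("dose", "time_h"),
                             strain = NULL, treatments = NULL,
                             encoding = c("fraction", "log10"),
                             d0 = NULL) {
  covariate <- match.arg(covariate)
  encoding <- match.arg(encoding)
  hcol <- intersect(c("H_bits", "H_nats", "H"), names(diversity))[1]
  if (is.na(hcol))
    liberalityError("schema_error",
      "diversity table lacks an entropy column (H_bits/H_nats/H)")
  missing <- setdiff(diversity$sample_id, sheet$sample_id)
  if (length(missing))
    liberalityError("join_error",
      "samples absent from sheet: %s", paste(missing, collapse = ", "))
  sel <- merge(diversity, sheet, by = "sample_id", sort = FALSE)
  if (!is.null(strain)) sel <- sel[sel$strain %in% strain, , drop = FALSE]
  if (!is.null(treatments))
    sel <- sel[sel$treatment %in% treatments, , drop = FALSE]
  if (nrow(sel) < 3)
    liberalityError("insufficient_data_error",
      "subset selects %d samples; need >= 3", nrow(sel))
  xraw <- sel[[covariate]]
  if (encoding == "log10") {
    if (is.null(d0)) {
      pos <- xraw[xraw > 0]
      if (!length(pos))
        liberalityError("zero_variance_error",
          "log10 encoding needs at least one positive covariate value")
      d0 <- min(pos) / 10
    }
    x <- log10(xraw + d0)
  } else x <- xraw
  label <- sprintf("%s ~ %s [%s%s], n=%d", hcol, covariate,
                   if (is.null(strain)) "all strains"
                   else paste(strain, collapse = "/"),
                   if (is.null(treatments)) ""
                   else paste0("; ", paste(treatments, collapse = "/")),
                   nrow(sel))
  fitSlope(x, sel[[hcol]], contrast = label, encoding = encoding)
}
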