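## Classed conditions so callers (and the CLI) can dispatch on failure
## category instead of matching message text.

liberalityError <- function(class, fmt, ..., call = sys.call(-1)) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "liberality_error"),
                      call = call))
}

liberalityWarning <- function(class, fmt, ...) {
  warning(warningCondition(sprintf(fmt, ...),
                           class = c(class, "liberality_warning")))
}

#' @importFrom methods is new validObject show
#' @importFrom stats rnorm rmultinom runif pbeta
#' @importFrom utils read.table write.table
#' @importFrom tools file_ext
#' @importFrom rlang .data
NULL
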