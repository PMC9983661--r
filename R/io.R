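## Count-matrix and sample-sheet import/export plus the mapping-quality
## check applied before any entropy analysis. All text formats are UTF-8,
## tab/comma delimited, "." decimal separator.

#' Read a gene x sample count matrix
#'
#' Reads gene-level expression counts into a
#' [SummarizedExperiment::SummarizedExperiment] with a single `"counts"`
#' assay. For `tsv`/`csv` the first column holds gene identifiers and the
#' header row holds sample identifiers. For `mtx` (MatrixMarket) two
#' sidecar text files supply the identifiers, one per line.
#'
#' Counts may be non-integer (estimated counts from upstream quantifiers
#' are admitted); downstream entropy treats them as weights. Row and
#' column order is preserved from the file.
#'
#' @param path path to the counts file.
#' @param format one of `"tsv"`, `"csv"`, `"mtx"`; default guessed from
#'   the file extension.
#' @param geneFile,sampleFile sidecar identifier files for `mtx` input;
#'   default `<path without .mtx>.genes.txt` / `.samples.txt`.
#' @return a `SummarizedExperiment` with assay `"counts"`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\tS1\tS2", "g1\t10\t0", "g2\t30\t5", "g3\t60\t5"), tf)
#' se <- readCounts(tf)
#' SummarizedExperiment::assay(se)
#' @export
readCounts <- function(path, format = c("auto", "tsv", "csv", "mtx"),
                       geneFile = NULL, sampleFile = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    liberalityError("io_error", "counts file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, tsv = "tsv", txt = "tsv", csv = "csv",
                     mtx = "mtx",
                     liberalityError("io_error",
                       "cannot guess format from extension '%s'", ext))
  }
  if (format == "mtx") {
    stem <- sub("\\.mtx$", "", path)
    if (is.null(geneFile)) geneFile <- paste0(stem, ".genes.txt")
    if (is.null(sampleFile)) sampleFile <- paste0(stem, ".samples.txt")
    for (f in c(geneFile, sampleFile))
      if (!file.exists(f))
        liberalityError("io_error", "missing MTX sidecar file: %s", f)
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(geneFile)
    samples <- readLines(sampleFile)
    if (nrow(m) != length(genes) || ncol(m) != length(samples))
      liberalityError("validation_error",
        "MTX dimensions (%d x %d) do not match sidecars (%d genes, %d samples)",
        nrow(m), ncol(m), length(genes), length(samples))
    rownames(m) <- genes
    colnames(m) <- samples
    return(validateCounts(makeCountsSE(m)))
  }
  sep <- if (format == "tsv") "\t" else ","
  if (file.size(path) == 0)
    liberalityError("parse_error", "empty counts file: %s", path)
  header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  if (length(header) < 2)
    liberalityError("parse_error",
      "malformed header at line 1 of %s: need a gene-id column and >= 1 sample",
      path)
  df <- tryCatch(
    read.table(path, sep = sep, header = TRUE, check.names = FALSE,
               colClasses = c("character", rep("numeric",
                                               length(header) - 1L)),
               quote = "", comment.char = ""),
    error = function(e) liberalityError("parse_error",
      "cannot parse %s: %s", path, conditionMessage(e)))
  if (nrow(df) == 0)
    liberalityError("parse_error", "counts file has no data rows: %s", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  colnames(m) <- header[-1]
  validateCounts(makeCountsSE(m))
}

makeCountsSE <- function(m) {
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m),
    rowData = S4Vectors::DataFrame(gene_id = rownames(m)))
}

#' Validate a count container
#'
#' Checks the count-matrix invariants: entries non-negative and finite,
#' gene and sample identifiers present and unique, dimensions consistent.
#' Errors name the first offending cell or identifier.
#'
#' @param x a `SummarizedExperiment` with a `"counts"` assay, or a
#'   numeric matrix with dimnames.
#' @return the validated object (a `SummarizedExperiment`), invisibly
#'   usable in a pipeline.
#' @export
validateCounts <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x)))
      liberalityError("validation_error",
        "counts must carry gene (row) and sample (column) identifiers")
    x <- makeCountsSE(x)
  }
  if (!is(x, "SummarizedExperiment"))
    liberalityError("validation_error",
      "expected a SummarizedExperiment or matrix")
  m <- SummarizedExperiment::assay(x, "counts")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    liberalityError("validation_error",
      "counts must carry gene (row) and sample (column) identifiers")
  if (anyDuplicated(rownames(m)))
    liberalityError("validation_error", "duplicate gene ids: %s",
      paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  if (anyDuplicated(colnames(m)))
    liberalityError("validation_error", "duplicate sample ids: %s",
      paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  bad <- which(!is.finite(m) | m < 0)
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(m))
    liberalityError("validation_error",
      "invalid count at gene '%s', sample '%s': %s",
      rownames(m)[i[1]], colnames(m)[i[2]], format(m[bad[1]]))
  }
  x
}

#' Read a sample sheet
#'
#' CSV with required columns `sample_id`, `strain`, `treatment`, `dose`,
#' `time_h`. `dose` is a decimal dilution fraction (a 1/100 dilution is
#' 0.01; controls are 0) and `time_h` culture hours; both must be
#' non-negative. Extra columns are preserved.
#'
#' @param path path to the CSV file.
#' @return a `data.frame`, one row per sample.
#' @export
readSampleSheet <- function(path) {
  if (!file.exists(path))
    liberalityError("io_error", "sample sheet not found: %s", path)
  df <- tryCatch(
    read.table(path, sep = ",", header = TRUE, check.names = FALSE,
               quote = "\"", comment.char = "",
               stringsAsFactors = FALSE),
    error = function(e) liberalityError("parse_error",
      "cannot parse %s: %s", path, conditionMessage(e)))
  required <- c("sample_id", "strain", "treatment", "dose", "time_h")
  missing <- setdiff(required, names(df))
  if (length(missing))
    liberalityError("schema_error",
      "sample sheet missing required column(s): %s",
      paste(missing, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$dose <- as.numeric(df$dose)
  df$time_h <- as.numeric(df$time_h)
  if (anyDuplicated(df$sample_id))
    liberalityError("validation_error", "duplicate sample ids: %s",
      paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (any(!is.finite(df$dose) | df$dose < 0))
    liberalityError("validation_error",
      "negative or non-numeric dose for sample(s): %s",
      paste(df$sample_id[!is.finite(df$dose) | df$dose < 0], collapse = ", "))
  if (any(!is.finite(df$time_h) | df$time_h < 0))
    liberalityError("validation_error",
      "negative or non-numeric time_h for sample(s): %s",
      paste(df$sample_id[!is.finite(df$time_h) | df$time_h < 0],
            collapse = ", "))
  df
}

#' Check that a count matrix and a sample sheet describe the same samples
#'
#' @param counts a validated `SummarizedExperiment` (see [readCounts()]).
#' @param sheet a sample sheet `data.frame` (see [readSampleSheet()]).
#' @return invisibly `TRUE`; errors list the offending sample ids.
#' @export
joinValidate <- function(counts, sheet) {
  cs <- colnames(counts)
  ss <- sheet$sample_id
  onlyCounts <- setdiff(cs, ss)
  onlySheet <- setdiff(ss, cs)
  if (length(onlyCounts) || length(onlySheet))
    liberalityError("join_error",
      "sample-id mismatch; only in counts: {%s}; only in sheet: {%s}",
      paste(onlyCounts, collapse = ", "),
      paste(onlySheet, collapse = ", "))
  invisible(TRUE)
}

#' Multi-hit mapping rate quality check
#'
#' Computes, per sample, the fraction of reads mapping ambiguously to
#' multiple reference transcripts and flags samples whose rate exceeds
#' the threshold (strictly). A multi-hit rate above 30% is the
#' conventional ground for rejecting a reference transcript set.
#'
#' @param uniqueCounts per-sample uniquely-mapped read totals.
#' @param multiCounts per-sample multi-mapped read totals.
#' @param threshold flagging threshold on the multi-hit fraction;
#'   default 0.30.
#' @param sampleIds sample identifiers; default taken from names.
#' @return a `data.frame` with columns `sample_id`, `multihit_rate`,
#'   `library_size`, `flagged`.
#' @examples
#' multihitQC(c(A = 70, B = 60), c(A = 30, B = 40))
#' @export
multihitQC <- function(uniqueCounts, multiCounts, threshold = 0.30,
                       sampleIds = NULL) {
  if (length(uniqueCounts) != length(multiCounts))
    liberalityError("validation_error",
      "uniqueCounts and multiCounts differ in length")
  if (any(uniqueCounts < 0) || any(multiCounts < 0))
    liberalityError("validation_error", "mapping totals must be >= 0")
  if (is.null(sampleIds))
    sampleIds <- names(uniqueCounts)
  if (is.null(sampleIds))
    sampleIds <- paste0("S", seq_along(uniqueCounts))
  total <- uniqueCounts + multiCounts
  if (any(total == 0))
    liberalityError("undefined_rate_error",
      "multi-hit rate undefined (zero mapped reads) for sample(s): %s",
      paste(sampleIds[total == 0], collapse = ", "))
  rate <- multiCounts / total
  data.frame(sample_id = sampleIds, multihit_rate = unname(rate),
             library_size = unname(total),
             flagged = unname(rate > threshold),
             stringsAsFactors = FALSE)
}

#' Write a result table as TSV
#'
#' Tab-separated with a header row, stable column order, and full float
#' precision (15 significant digits) so that [readResultTable()]
#' round-trips values exactly up to float formatting. An empty record
#' set yields a header-only file.
#'
#' @param records a `data.frame` (or a `SlopeTest`, coerced via
#'   [as.data.frame.SlopeTest()]).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeTable <- function(records, path) {
  if (is(records, "SlopeTest")) records <- as.data.frame(records)
  if (!is.data.frame(records) || ncol(records) == 0)
    liberalityError("validation_error",
      "records must be a data.frame with at least one column")
  out <- records
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.15g", out[[j]])
  ok <- tryCatch({
    suppressWarnings(
      write.table(out, path, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = TRUE))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    liberalityError("io_error", "cannot write %s: %s", path,
                    conditionMessage(ok))
  invisible(path)
}

#' Read a TSV result table written by [writeTable()]
#'
#' @param path path to the TSV file.
#' @return a `data.frame`.
#' @export
readResultTable <- function(path) {
  if (!file.exists(path))
    liberalityError("io_error", "table not found: %s", path)
  read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
             quote = "", comment.char = "", stringsAsFactors = FALSE)
}

#' Write a count matrix
#'
#' Inverse of [readCounts()] for the `tsv`/`csv` formats; the first
#' column is `gene_id`, remaining columns are samples.
#'
#' @param counts a `SummarizedExperiment` or numeric matrix with dimnames.
#' @param path output path.
#' @param format `"tsv"` or `"csv"`.
#' @return invisibly, `path`.
#' @export
writeCounts <- function(counts, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  counts <- validateCounts(counts)
  m <- SummarizedExperiment::assay(counts, "counts")
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.15g", df[[j]])
  write.table(df, path, sep = if (format == "tsv") "\t" else ",",
              quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}
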