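## Figure idioms of the entropy analysis: per-sample stacked occupancy
## bar charts (most genes vanish into the dark low-rank region of a
## differentiated sample) and entropy-vs-covariate scatter plots.
## Both plots are built from an explicit render-data frame so tests
## compare numbers, not pixels.

#' Render data for an occupancy bar chart
#'
#' @param counts a `SummarizedExperiment` or matrix accepted by
#'   [validateCounts()].
#' @return a `data.frame` with columns `sample_id`, `rank` (1 = most
#'   expressed), `gene_id`, `height` (occupation rate); heights sum to 1
#'   within each sample.
#' @export
occupancyRenderData <- function(counts) {
  counts <- validateCounts(counts)
  m <- SummarizedExperiment::assay(counts, "counts")
  out <- lapply(colnames(m), function(sid) {
    p <- occupationRates(m[, sid], sampleId = sid)
    o <- order(p, decreasing = TRUE)
    data.frame(sample_id = sid, rank = seq_along(o),
               gene_id = rownames(m)[o], height = unname(p[o]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Stacked occupancy bar chart
#'
#' One stacked bar per sample; segments are the occupation rates of the
#' genes sorted descending within the sample (the sort is per-sample, so
#' a segment at the same position in two bars is generally a different
#' gene). Segment colors are a deterministic function of rank, light at
#' rank 1 shading to black, so a skewed (differentiated) transcriptome
#' shows a few large light blocks over a black mass of rare genes.
#'
#' @param counts a `SummarizedExperiment` or matrix.
#' @return a `ggplot` object; its `$data` is [occupancyRenderData()]'s
#'   output.
#' @export
plotOccupancy <- function(counts) {
  dat <- occupancyRenderData(counts)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$sample_id,
                                    y = .data$height,
                                    group = -.data$rank,
                                    fill = log10(.data$rank))) +
    ggplot2::geom_col(width = 0.8, show.legend = FALSE) +
    ggplot2::scale_fill_gradient(low = "grey85", high = "black") +
    ggplot2::labs(x = "sample", y = "occupation rate") +
    ggplot2::theme_classic()
}

#' Entropy versus covariate scatter plot
#'
#' One point per sample at (covariate, entropy), optionally overlaid
#' with the ordinary least-squares line from [fitSlope()] on the same
#' samples.
#'
#' @param diversity a `data.frame` from [diversityTable()].
#' @param sheet a sample sheet `data.frame`.
#' @param covariate `"dose"` or `"time_h"`.
#' @param fit overlay the fitted line (default `TRUE`; needs >= 3
#'   samples and a non-constant covariate).
#' @return a `ggplot`; its `$data` holds one row per sample with
#'   columns `sample_id`, `x`, `H`; attribute `"fit"` carries the
#'   [SlopeTest-class] when a line is overlaid.
#' @export
plotEntropyScatter <- function(diversity, sheet,
                               covariate = c("dose", "time_h"),
                               fit = TRUE) {
  covariate <- match.arg(covariate)
  hcol <- intersect(c("H_bits", "H_nats", "H"), names(diversity))[1]
  if (is.na(hcol))
    liberalityError("schema_error",
      "diversity table lacks an entropy column (H_bits/H_nats/H)")
  missing <- setdiff(diversity$sample_id, sheet$sample_id)
  if (length(missing))
    liberalityError("join_error",
      "samples absent from sheet: %s", paste(missing, collapse = ", "))
  mg <- merge(diversity, sheet, by = "sample_id", sort = FALSE)
  dat <- data.frame(sample_id = mg$sample_id, x = mg[[covariate]],
                    H = mg[[hcol]], stringsAsFactors = FALSE)
  g <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$H)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = if (covariate == "dose") "extract dose (dilution fraction)"
          else "culture time (h)",
      y = switch(hcol, H_bits = "entropy (bits)",
                 H_nats = "entropy (nats)", "entropy")) +
    ggplot2::theme_classic()
  if (fit && nrow(dat) >= 3 && length(unique(dat$x)) >= 2) {
    st <- fitSlope(dat$x, dat$H,
                   contrast = sprintf("%s ~ %s", hcol, covariate))
    g <- g + ggplot2::geom_abline(intercept = st@interceptHat,
                                  slope = st@betaHat, linetype = 2)
    attr(g, "fit") <- st
  }
  g
}

#' Save a plot to PNG or SVG
#'
#' Thin wrapper choosing the device from the file extension; SVG is
#' text and therefore diff-friendly.
#'
#' @param plot a `ggplot`.
#' @param path output path ending in `.png` or `.svg`.
#' @param width,height size in inches.
#' @param dpi raster resolution for PNG.
#' @return invisibly, `path`.
#' @export
writePlot <- function(plot, path, width = 6, height = 4, dpi = 150) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("png", "svg"))
    liberalityError("validation_error",
      "unsupported image format '.%s' (use .png or .svg)", ext)
  dev <- if (ext == "png") {
    function(filename, ...) grDevices::png(filename, width = width,
      height = height, units = "in", res = dpi, type = "cairo")
  } else {
    function(filename, ...) grDevices::svg(filename, width = width,
                                           height = height)
  }
  ggplot2::ggsave(path, plot = plot, device = dev, width = width,
                  height = height, dpi = dpi)
  invisible(path)
}
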