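## viz: significance-aware sequence logos and heatmaps for DAU results.

#' Stacked-glyph data behind a DAU logo
#'
#' Only significant cells are drawn. Within each column, over-represented
#' symbols are stacked above the axis and under-represented symbols mirrored
#' below it; glyphs are ordered by decreasing height so the largest sits
#' nearest the axis. The default height metric is the percentage-point
#' frequency difference `|diff| * 100`; `"neglog10p"` uses `-log10(p)`
#' instead.
#'
#' @param result A `dau_result`.
#' @param metric `"diff_pct"` (default) or `"neglog10p"`.
#' @return A tibble with one row per drawn glyph: `column`, `offset`,
#'   `symbol`, `direction` (+1 over, -1 under), `height`, `ymin`, `ymax`.
#' @export
logo_data <- function(result, metric = c("diff_pct", "neglog10p")) {
  metric <- match.arg(metric)
  cells <- result$table
  cells <- cells[!is.na(cells$significant) & cells$significant &
                   !is.na(cells$diff) & cells$diff != 0, , drop = FALSE]
  if (nrow(cells) == 0) {
    return(tibble(column = integer(), offset = integer(),
                  symbol = character(), direction = numeric(),
                  height = numeric(), ymin = numeric(), ymax = numeric()))
  }
  cells$direction <- sign(cells$diff)
  cells$height <- if (metric == "diff_pct") abs(cells$diff) * 100 else
    -log10(pmax(cells$p_value, .Machine$double.xmin))
  cells |>
    dplyr::group_by(.data$column, .data$direction) |>
    dplyr::arrange(dplyr::desc(.data$height), .by_group = TRUE) |>
    dplyr::mutate(
      ymax_abs = cumsum(.data$height),
      ymin_abs = .data$ymax_abs - .data$height,
      ymin = ifelse(.data$direction > 0, .data$ymin_abs, -.data$ymax_abs),
      ymax = ifelse(.data$direction > 0, .data$ymax_abs, -.data$ymin_abs)
    ) |>
    dplyr::ungroup() |>
    dplyr::select("column", "offset", "symbol", "direction", "height",
                  "ymin", "ymax")
}

scheme_palette <- function(result, scheme = NULL) {
  scheme <- scheme %||% tryCatch(aa_scheme(result$metadata$scheme),
                                 error = function(e) NULL)
  if (is.null(scheme)) {
    syms <- result$metadata$symbols
    return(setNames(grDevices::hcl.colors(length(syms), "Dark 3"), syms))
  }
  setNames(scheme$color, scheme$symbol)
}

#' Plot a DAU result as a significance-aware sequence logo
#'
#' Significant over-represented symbols are stacked above the axis and
#' under-represented ones below it; glyph height is the percentage-point
#' frequency difference (or `-log10 p`). When no cell is significant an
#' axis-only plot is returned with a notice.
#'
#' @param object,result A `dau_result`.
#' @param metric Height metric, `"diff_pct"` or `"neglog10p"`.
#' @param labels Column label style, `"offset"` (default, 0 at the anchor) or
#'   `"protease"` (P15..P1, P1'..P15').
#' @param scheme Optional `aa_scheme` providing glyph colors; defaults to the
#'   scheme recorded in the result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.dau_result <- function(object, metric = c("diff_pct", "neglog10p"),
                                labels = c("offset", "protease"),
                                scheme = NULL, ...) {
  metric <- match.arg(metric)
  labels <- match.arg(labels)
  data <- logo_data(object, metric = metric)
  pal <- scheme_palette(object, scheme)
  lab <- position_labels(object, style = labels)
  ylab <- if (metric == "diff_pct") "frequency difference (% points)" else
    expression(-log[10] ~ p)
  p <- ggplot2::ggplot() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.4) +
    ggplot2::scale_x_continuous(breaks = seq_len(object$metadata$L),
                                labels = lab,
                                limits = c(0.5, object$metadata$L + 0.5)) +
    ggplot2::labs(x = "position", y = ylab) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid.minor = ggplot2::element_blank(),
                   legend.position = "none")
  if (nrow(data) == 0) {
    return(p +
             ggplot2::annotate("text", x = (object$metadata$L + 1) / 2, y = 0,
                               vjust = -1,
                               label = "no significant differential usage") +
             ggplot2::ylim(-1, 1))
  }
  p +
    ggplot2::geom_rect(
      data = data,
      ggplot2::aes(xmin = .data$column - 0.45, xmax = .data$column + 0.45,
                   ymin = .data$ymin, ymax = .data$ymax,
                   fill = .data$symbol),
      color = "white", linewidth = 0.2
    ) +
    ggplot2::geom_text(
      data = data,
      ggplot2::aes(x = .data$column, y = (.data$ymin + .data$ymax) / 2,
                   label = .data$symbol,
                   size = pmin(.data$height, 12)),
      color = "grey15", fontface = "bold"
    ) +
    ggplot2::scale_size_identity() +
    ggplot2::scale_fill_manual(values = pal)
}

#' @rdname autoplot.dau_result
#' @export
plot_dau_logo <- function(result, metric = c("diff_pct", "neglog10p"),
                          labels = c("offset", "protease"), scheme = NULL) {
  autoplot.dau_result(result, metric = metric, labels = labels,
                      scheme = scheme)
}

#' Plot a DAU result as a heatmap
#'
#' An L x K tile grid (row = symbol, column = position) colored by the test
#' statistic (Z-score in Z mode) or by the frequency difference, with a
#' diverging palette centered at zero. NA cells (e.g. columns with no
#' countable residues) are drawn in grey.
#'
#' @param result A `dau_result`.
#' @param value `"statistic"` or `"diff"`.
#' @param labels Column label style (see [autoplot.dau_result()]).
#' @return A ggplot object.
#' @export
plot_dau_heatmap <- function(result, value = c("statistic", "diff"),
                             labels = c("offset", "protease")) {
  value <- match.arg(value)
  labels <- match.arg(labels)
  cells <- result$table
  cells$fill_value <- cells[[value]]
  cells$fill_value[is.infinite(cells$fill_value)] <- NA_real_
  cells$symbol <- factor(cells$symbol,
                         levels = rev(result$metadata$symbols))
  lab <- position_labels(result, style = labels)
  lim <- max(abs(cells$fill_value), na.rm = TRUE)
  if (!is.finite(lim) || lim == 0) lim <- 1
  ggplot2::ggplot(cells,
                  ggplot2::aes(x = .data$column, y = .data$symbol,
                               fill = .data$fill_value)) +
    ggplot2::geom_tile(color = "grey90", linewidth = 0.2) +
    ggplot2::scale_x_continuous(breaks = seq_len(result$metadata$L),
                                labels = lab, expand = c(0, 0)) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0,
                                  limits = c(-lim, lim),
                                  na.value = "grey70",
                                  name = if (value == "statistic") "Z" else
                                    "diff") +
    ggplot2::labs(x = "position", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
}

open_device <- function(path, width, height, dpi) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    svg = grDevices::svg(path, width = width, height = height),
    png = grDevices::png(path, width = width * dpi, height = height * dpi,
                         res = dpi, type = "cairo"),
    pdf = grDevices::pdf(path, width = width, height = height),
    abort(paste0("Unsupported figure format \".", ext,
                 "\"; use svg, png or pdf."))
  )
}

render_to_file <- function(plot, path, width, height, dpi) {
  open_device(path, width, height, dpi)
  on.exit(grDevices::dev.off(), add = TRUE)
  print(plot)
  invisible(path)
}

#' Render a DAU logo or heatmap to a file
#'
#' The output format follows the file extension: `.svg` (cairo, no embedded
#' timestamps), `.png`, or `.pdf`.
#'
#' @inheritParams autoplot.dau_result
#' @param path Output file path.
#' @param width,height Figure size in inches.
#' @param dpi Raster resolution for PNG.
#' @return `path`, invisibly.
#' @export
render_logo <- function(result, path, metric = c("diff_pct", "neglog10p"),
                        labels = c("offset", "protease"), scheme = NULL,
                        width = 9, height = 4.5, dpi = 150) {
  data <- logo_data(result, metric = match.arg(metric))
  if (nrow(data) == 0) {
    inform("No significant cells; rendering an axis-only logo.")
  }
  render_to_file(plot_dau_logo(result, metric = metric, labels = labels,
                               scheme = scheme),
                 path, width, height, dpi)
}

#' @rdname plot_dau_heatmap
#' @inheritParams render_logo
#' @param path Output file path.
#' @export
render_heatmap <- function(result, path, value = c("statistic", "diff"),
                           labels = c("offset", "protease"),
                           width = 9, height = 5, dpi = 150) {
  render_to_file(plot_dau_heatmap(result, value = value, labels = labels),
                 path, width, height, dpi)
}
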