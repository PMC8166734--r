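# Serialization of deviation matrices: plain CSV, color-coded HTML tables,
# and the per-size projection line charts.

#' Default color scheme for deviation bins
#'
#' A sequential white-to-dark-red ramp over the ten bins "0", "1", ...,
#' "8", ">8", increasing with severity. Signed bins produced under
#' `report_side = "both"` are colored by magnitude.
#'
#' @return named character vector mapping bin label to a hex color.
#' @export
#' @examples
#' deviation_colors()[c("0", "4", ">8")]
deviation_colors <- function() {
  labels <- c(as.character(0:8), ">8")
  stats::setNames(grDevices::colorRampPalette(c("#FFFFFF", "#67000D"))(10L),
                  labels)
}

# look up cell colors for a bin-label matrix (signed labels use |steps|)
.bin_color <- function(labels, scheme) {
  key <- sub("^<?-", "", labels)       # "-3" -> "3", "<-8" -> "8" then ">8"
  key[labels %in% c(">8", "<-8")] <- ">8"
  missing <- setdiff(unique(key), names(scheme))
  if (length(missing) > 0L) {
    stop("color scheme has no entry for bin(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  scheme[key]
}

# deviation cell text: exactly one decimal, half away from zero
.cell_text <- function(x) sprintf("%.1f", round_half_away(x, 1L))

#' Write a deviation matrix as CSV
#'
#' Emits an RFC-4180-style CSV (comma separator, `.` decimal, UTF-8, LF line
#' endings): header row of error percents, first column the component sizes
#' in mm, every cell the deviation in mm with exactly one decimal (rounded
#' half away from zero). A parallel file with suffix `_bins` holds the bin
#' labels of the same cells. Output is byte-identical across runs.
#'
#' @param matrix a [build_matrix()] result.
#' @param path destination for the value CSV.
#' @param bins_path destination for the bin-label CSV; default replaces the
#'   `.csv` extension of `path` with `_bins.csv`. `NA` suppresses it.
#' @return invisibly, a character vector of the file(s) written.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_matrix_csv(build_matrix(scenario_preset("group1")), f)
write_matrix_csv <- function(matrix, path,
                             bins_path = sub("(\\.csv)?$", "_bins.csv",
                                             path, ignore.case = TRUE)) {
  stopifnot(inherits(matrix, "deviation_matrix"))
  emit <- function(cells, dest) {
    lines <- c(
      paste(c("size_mm", colnames(cells)), collapse = ","),
      vapply(seq_len(nrow(cells)), function(i)
        paste(c(rownames(cells)[i], cells[i, ]), collapse = ","),
        character(1L))
    )
    con <- tryCatch(suppressWarnings(file(dest, open = "wb")),
                    error = function(e) stop("cannot write '", dest, "': ",
                                             conditionMessage(e), call. = FALSE))
    on.exit(close(con))
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
    dest
  }
  vals <- matrix$deviation_mm
  vals[] <- .cell_text(matrix$deviation_mm)
  written <- emit(vals, path)
  if (!is.na(bins_path)) written <- c(written, emit(matrix$bins, bins_path))
  invisible(written)
}

#' Read back a deviation-value CSV
#'
#' Inverse of the value file written by [write_matrix_csv()]; used for
#' round-trip checks and for consuming exported tables.
#'
#' @param path CSV file written by [write_matrix_csv()].
#' @return numeric matrix of deviations (mm, one decimal) with size/error
#'   dimnames.
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  names(dimnames(m)) <- c("size", "error_pct")
  m
}

#' Write a deviation matrix as a color-coded HTML table
#'
#' One standalone HTML file: rows are component sizes, columns calibration
#' errors, each cell shows the deviation in mm to one decimal on a
#' background colored by its component-size bin, with a legend. Output is
#' deterministic.
#'
#' @param matrix a [build_matrix()] result.
#' @param path destination `.html` file.
#' @param scheme named color vector as from [deviation_colors()].
#' @return invisibly, `path`.
#' @export
write_matrix_html <- function(matrix, path, scheme = deviation_colors()) {
  stopifnot(inherits(matrix, "deviation_matrix"))
  colors <- .bin_color(matrix$bins, scheme)
  dim(colors) <- dim(matrix$bins)
  text <- .cell_text(matrix$deviation_mm)
  dim(text) <- dim(matrix$bins)
  header <- paste0(
    "<tr><th>size (mm)</th>",
    paste0("<th>", colnames(matrix$deviation_mm), "%</th>", collapse = ""),
    "</tr>")
  rows <- vapply(seq_along(matrix$sizes), function(i) paste0(
    "<tr><th>", rownames(matrix$deviation_mm)[i], "</th>",
    paste0("<td style=\"background:", colors[i, ], "\">", text[i, ], "</td>",
           collapse = ""),
    "</tr>"), character(1L))
  legend <- paste0(
    "<p>Cell color = deviation in component sizes: ",
    paste0("<span style=\"background:", scheme, "\">&nbsp;", names(scheme),
           "&nbsp;</span>", collapse = " "),
    "</p>")
  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\">",
    "<title>Templated cup size deviation from optimal size (mm)</title>",
    "<style>table{border-collapse:collapse}td,th{border:1px solid #999;",
    "padding:2px 6px;text-align:right;font-family:sans-serif}</style>",
    "</head><body>",
    "<h1>Expected component selection error</h1>",
    paste0("<p>Deviation of the templated cup from the optimal size in mm ",
           "(one decimal), by true component size and calibration error.</p>"),
    "<table>", header, rows, "</table>", legend, "</body></html>")
  con <- tryCatch(suppressWarnings(file(path, open = "wb")),
                  error = function(e) stop("cannot write '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(html, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Plot the projection curves
#'
#' Line chart of the linear calibration-error effect: x = calibration error
#' (%), y = projected component size (mm), one line per catalog size.
#'
#' @param series a [figure_series()] data.frame.
#' @return a ggplot object.
#' @export
#' @examples
#' plot_projection_curves(figure_series(scenario_preset("group1")))
plot_projection_curves <- function(series) {
  stopifnot(is.data.frame(series), nrow(series) > 0L,
            all(c("size_mm", "error_pct", "projected_mm") %in% names(series)))
  ggplot2::ggplot(
    series,
    ggplot2::aes(x = .data$error_pct, y = .data$projected_mm,
                 group = .data$size_mm,
                 color = factor(.data$size_mm))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Calibration error (%)",
                  y = "Projected component size (mm)",
                  color = "Component\nsize (mm)") +
    ggplot2::theme_minimal()
}

#' Write the projection curves to an image file
#'
#' @param series a [figure_series()] data.frame.
#' @param path destination file; format chosen by extension (`.png` or
#'   `.svg`).
#' @param width,height device size in inches.
#' @return invisibly, `path`.
#' @export
write_projection_plot <- function(series, path, width = 7, height = 5) {
  ext <- tolower(sub(".*\\.", "", path))
  open_dev <- switch(ext,
    png = function() grDevices::png(path, width = width, height = height,
                                    units = "in", res = 150),
    svg = function() grDevices::svg(path, width = width, height = height),
    stop("unsupported plot format '.", ext,
         "'; supported formats: .png, .svg", call. = FALSE)
  )
  open_dev()
  on.exit(grDevices::dev.off())
  print(plot_projection_curves(series))
  invisible(path)
}
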