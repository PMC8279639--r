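# Plain-text export of 2-D grids (spectrograms, RDF tables) with axis headers.

#' Write a 2-D grid with labelled axes to plain text
#'
#' The file carries two `#`-prefixed header lines with the axis names, units
#' and values, followed by one row of the grid per line. Values are printed
#' with 17 significant digits so the paired [read_matrix()] round-trips
#' bit-identically.
#'
#' @param grid numeric matrix (nrow x ncol)
#' @param row_axis numeric vector of length nrow(grid)
#' @param col_axis numeric vector of length ncol(grid)
#' @param path output path
#' @param row_name,col_name axis labels, e.g. \code{"frequency_cm-1"},
#'   \code{"time_fs"}
#' @return invisibly, \code{path}
#' @export
write_matrix <- function(grid, row_axis, col_axis, path,
                         row_name = "row", col_name = "col") {
  grid <- as.matrix(grid)
  if (length(row_axis) != nrow(grid))
    stop("row axis length (", length(row_axis), ") != grid rows (", nrow(grid), ")")
  if (length(col_axis) != ncol(grid))
    stop("col axis length (", length(col_axis), ") != grid cols (", ncol(grid), ")")
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(v) paste(sprintf("%.17g", v), collapse = " ")
  writeLines(sprintf("# %s: %s", row_name, fmt(row_axis)), con)
  writeLines(sprintf("# %s: %s", col_name, fmt(col_axis)), con)
  for (i in seq_len(nrow(grid))) writeLines(fmt(grid[i, ]), con)
  invisible(path)
}

#' Read a grid written by [write_matrix()]
#'
#' @param path file path
#' @return list with \code{grid}, \code{row_axis}, \code{col_axis},
#'   \code{row_name}, \code{col_name}
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  if (length(hdr) < 2) stop("not a write_matrix file (missing axis headers): ", path)
  parse_hdr <- function(h) {
    h <- sub("^#\\s*", "", h)
    nm <- sub(":.*$", "", h)
    vals <- as.numeric(strsplit(trimws(sub("^[^:]*:", "", h)), "\\s+")[[1]])
    list(name = nm, values = vals)
  }
  a1 <- parse_hdr(hdr[1]); a2 <- parse_hdr(hdr[2])
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  grid <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  if (nrow(grid) != length(a1$values) || ncol(grid) != length(a2$values))
    stop("grid shape does not match axis headers in ", path)
  list(grid = grid, row_axis = a1$values, col_axis = a2$values,
       row_name = a1$name, col_name = a2$name)
}
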