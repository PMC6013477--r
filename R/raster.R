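#' Lightweight single-layer raster
#'
#' A `sea_raster` holds one regular, axis-aligned grid layer: a numeric
#' matrix whose first row is the northernmost row, a square cell size in
#' metres, and the projected (x, y) coordinate of the lower-left *cell
#' centre*. Missing cells are `NA`. A bathymetry grid (elevation in metres,
#' negative below datum) is simply a `sea_raster` whose values are depths.
#'
#' @param values Numeric matrix; row 1 is the northernmost row.
#' @param cell_size Cell edge length in metres (single positive number).
#' @param origin Length-2 numeric, (x, y) of the lower-left cell centre.
#' @param name Optional layer name.
#' @return An object of class `sea_raster`.
#' @export
sea_raster <- function(values, cell_size, origin = c(0, 0), name = "layer") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1 || !is.finite(cell_size) ||
      cell_size <= 0) {
    stop("`cell_size` must be a single positive number", call. = FALSE)
  }
  if (length(origin) != 2 || !all(is.finite(origin))) {
    stop("`origin` must be two finite numbers (x, y)", call. = FALSE)
  }
  values[!is.finite(values)] <- NA_real_
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), name = as.character(name)),
    class = "sea_raster"
  )
}

#' @export
dim.sea_raster <- function(x) dim(x$values)

#' @export
print.sea_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<sea_raster '%s'> %d rows x %d cols, cell %g m, origin (%g, %g)\n",
              x$name, nrow(v), ncol(v), x$cell_size, x$origin[1], x$origin[2]))
  cat(sprintf("  values: [%g, %g], %d NA cells\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  invisible(x)
}

raster_compatible <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$cell_size - b$cell_size) < tol &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_incompatible <- function(rasters) {
  ref <- rasters[[1]]
  ok <- vapply(rasters, raster_compatible, logical(1), b = ref)
  if (!all(ok)) {
    stop("rasters are not co-registered (shape, cell size or origin differ)",
         call. = FALSE)
  }
  invisible(TRUE)
}

# Cell-centre coordinates. Internal row 1 is the northernmost row, so the
# y of matrix row i is origin_y + (nrow - i) * cell_size.
cell_centers <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  list(x = r$origin[1] + (seq_len(nc) - 1) * r$cell_size,
       y = r$origin[2] + (nr - seq_len(nr)) * r$cell_size)
}

# Map projected coordinates to matrix (row, col) of the containing cell.
# Points outside the grid get NA row/col.
xy_to_rowcol <- function(r, x, y) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  col <- as.integer(round((x - r$origin[1]) / r$cell_size)) + 1L
  row <- nr - as.integer(round((y - r$origin[2]) / r$cell_size))
  bad <- col < 1L | col > nc | row < 1L | row > nr
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  list(row = row, col = col)
}

#' Convert a raster to a tibble of cell centres
#'
#' One row per valid (non-`NA`) cell with columns `x`, `y`, `value`; handy
#' for ggplot2 raster plots and tidy summaries.
#'
#' @param x A [sea_raster].
#' @param ... Unused.
#' @return A tibble with columns `x`, `y`, `value`.
#' @export
as_tibble.sea_raster <- function(x, ...) {
  cc <- cell_centers(x)
  xs <- rep(cc$x, each = nrow(x$values))
  ys <- rep(cc$y, times = ncol(x$values))
  vals <- as.vector(x$values)
  out <- tibble::tibble(x = xs, y = ys, value = vals)
  dplyr::filter(out, !is.na(.data$value))
}

#' Read an ESRI ASCII grid
#'
#' Parses the plain-text ArcInfo ASCII raster format (`ncols`, `nrows`,
#' `xllcorner`/`xllcenter`, `yllcorner`/`yllcenter`, `cellsize`,
#' `NODATA_value` header followed by north-to-south rows of values).
#'
#' @param path File path.
#' @param name Layer name to attach.
#' @return A [sea_raster].
#' @export
read_ascii_grid <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 0
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && grepl("^[A-Za-z_]+$", parts[1]) &&
        !is.na(suppressWarnings(as.numeric(parts[2])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2]); i <- i + 1
    } else break
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("not an ESRI ASCII grid: missing header fields", call. = FALSE)
  }
  nodata <- hdr[["nodata_value"]] %||% -9999
  vals <- scan(text = paste(lines[-seq_len(i)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    stop("ASCII grid body does not match declared dimensions", call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  # header gives lower-left corner or centre; store the cell-centre origin
  cs <- hdr$cellsize
  x0 <- if (!is.null(hdr$xllcenter)) hdr$xllcenter else (hdr$xllcorner %||% 0) + cs / 2
  y0 <- if (!is.null(hdr$yllcenter)) hdr$yllcenter else (hdr$yllcorner %||% 0) + cs / 2
  sea_raster(m, cs, c(x0, y0), name = name)
}

#' Write an ESRI ASCII grid
#'
#' Writes a [sea_raster] in the plain-text ArcInfo ASCII format with
#' `NODATA_value -9999`, row 1 northernmost.
#'
#' @param r A [sea_raster].
#' @param path Output file path.
#' @param digits Significant digits for values.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(r, path, digits = 7) {
  m <- r$values
  m[is.na(m)] <- -9999
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcenter %.6f", r$origin[1]),
    sprintf("yllcenter %.6f", r$origin[2]),
    sprintf("cellsize %.6f", r$cell_size),
    "NODATA_value -9999"
  )
  body <- apply(m, 1, function(row) paste(signif(row, digits), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
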