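#' Write a raster layer to an ESRI ASCII grid file
#'
#' Layers are stored in the plain-text ESRI ASCII grid (`.asc`) format:
#' a six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by one line of cell values per row, top row
#' first. Continuous rasters are written with 17 significant digits so that
#' finite values round-trip bit-for-bit; categorical rasters and masks are
#' written as integers. A non-empty `crs_label` is stored in a `.prj`
#' sidecar file next to the grid.
#'
#' @param x An [iev_raster()], [categorical_raster()] or [region_mask()].
#' @param path Output file path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @seealso [read_asc()]
#' @export
write_asc <- function(x, path) {
  if (inherits(x, "iev_raster")) {
    m <- x$values; m[!x$valid] <- NA; int <- FALSE
  } else if (inherits(x, "iev_categorical")) {
    m <- x$levels; m[!x$valid] <- NA; int <- TRUE
  } else if (inherits(x, "iev_mask")) {
    m <- x$member + 0L; int <- TRUE
  } else {
    stop_config("write_asc expects a raster, categorical raster or mask")
  }
  g <- x$grid
  nodata <- -9999
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop_data("cannot open '", path, "' for writing")
  })
  on.exit(close(con))
  yll <- g$origin[2] - g$n_rows * g$cell_size
  writeLines(c(
    paste("ncols", g$n_cols),
    paste("nrows", g$n_rows),
    paste("xllcorner", sprintf("%.17g", g$origin[1])),
    paste("yllcorner", sprintf("%.17g", yll)),
    paste("cellsize", sprintf("%.17g", g$cell_size)),
    paste("NODATA_value", nodata)
  ), con)
  fmt <- if (int) "%d" else "%.17g"
  for (i in seq_len(g$n_rows)) {
    row <- m[i, ]
    txt <- ifelse(is.na(row), as.character(nodata), sprintf(fmt, row))
    writeLines(paste(txt, collapse = " "), con)
  }
  if (nzchar(g$crs_label)) {
    writeLines(g$crs_label, sub("\\.[^.]*$", "", path) |> paste0(".prj"))
  }
  invisible(path)
}

#' Read an ESRI ASCII grid file
#'
#' Parses a single-band `.asc` grid written by [write_asc()] (or any
#' conforming writer). Cells equal to the declared `NODATA_value` become
#' invalid. A `.prj` sidecar, if present, populates the grid's `crs_label`.
#'
#' @param path Path to the `.asc` file.
#' @return An [iev_raster()]. Use [as_categorical()] to reinterpret integer
#'   state layers, or [read_mask()] for 0/1 masks.
#' @export
read_asc <- function(path) {
  if (!file.exists(path)) stop_data("raster file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(parts) != 2) stop_data("malformed header line in ", path)
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop_data("missing georeferencing header (",
              paste(setdiff(need, names(hdr)), collapse = ", "), ") in ", path)
  }
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               what = numeric(), quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop_data("expected ", nr * nc, " cell values in ", path,
              " but found ", length(vals))
  }
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA
  prj <- sub("\\.[^.]*$", "", path) |> paste0(".prj")
  crs <- if (file.exists(prj)) readLines(prj, warn = FALSE)[1] else ""
  g <- iev_grid(nr, nc, hdr$cellsize,
                origin = c(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize),
                crs_label = crs)
  iev_raster(vals, g)
}

#' Read a 0/1 mask from an ASCII grid file
#'
#' @param path Path to a mask written by [write_asc()].
#' @return A [region_mask()]; cells equal to 1 are members.
#' @export
read_mask <- function(path) {
  r <- read_asc(path)
  m <- r$values
  m[!r$valid] <- 0
  region_mask(m == 1, r$grid)
}
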