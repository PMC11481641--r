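#' In-memory georeferenced raster grid
#'
#' A lightweight single-band raster: a numeric matrix with lower-left
#' origin, square cell size and a coordinate-system identifier. Row 1 of
#' the matrix is the northernmost row; cell centers are the prediction
#' locations.
#'
#' @param origin `c(x, y)` of the lower-left corner of the grid (metres).
#' @param cellsize Cell edge length (> 0, metres).
#' @param nrow,ncol Grid dimensions.
#' @param values Numeric matrix `nrow x ncol` (default all `NA`).
#' @param crs Coordinate-system identifier (free text, e.g. `"EPSG:23700"`).
#' @param nodata Sentinel written to file for missing cells.
#' @return An object of class `wq_raster`.
#' @export
raster_grid <- function(origin, cellsize, nrow, ncol,
                        values = matrix(NA_real_, nrow, ncol),
                        crs = NA_character_, nodata = -9999) {
  if (cellsize <= 0) stop("cellsize must be > 0", call. = FALSE)
  values <- matrix(as.numeric(values), nrow, ncol)
  structure(
    list(origin = as.numeric(origin), cellsize = cellsize,
         nrow = as.integer(nrow), ncol = as.integer(ncol),
         values = values, crs = crs, nodata = nodata),
    class = "wq_raster"
  )
}

#' Build a grid specification covering a set of wells
#'
#' Bounding box of the points padded by a fraction on each side, at the
#' requested resolution (defaults: 10% padding, 50 m cells).
#'
#' @param data Data frame with `x`, `y` columns.
#' @param cellsize Cell size in metres.
#' @param pad Fractional padding of the bounding box per side.
#' @param crs Coordinate-system identifier carried to outputs.
#' @return An empty `wq_raster` covering the padded extent.
#' @export
grid_from_points <- function(data, cellsize = 50, pad = 0.1,
                             crs = attr(data, "crs") %||% NA_character_) {
  rx <- range(data$x); ry <- range(data$y)
  px <- diff(rx) * pad; py <- diff(ry) * pad
  x0 <- rx[1] - px; y0 <- ry[1] - py
  ncol <- max(1L, ceiling((diff(rx) + 2 * px) / cellsize))
  nrow <- max(1L, ceiling((diff(ry) + 2 * py) / cellsize))
  raster_grid(c(x0, y0), cellsize, nrow, ncol, crs = crs)
}

#' Cell-center coordinates of a raster grid
#'
#' @param grid A `wq_raster`.
#' @return A tibble with `row`, `col`, `x`, `y` (row 1 = northernmost).
#' @export
grid_coords <- function(grid) {
  stopifnot(inherits(grid, "wq_raster"))
  rows <- seq_len(grid$nrow); cols <- seq_len(grid$ncol)
  tidyr::expand_grid(row = rows, col = cols) |>
    dplyr::mutate(
      x = grid$origin[1] + (.data$col - 0.5) * grid$cellsize,
      y = grid$origin[2] + (grid$nrow - .data$row + 0.5) * grid$cellsize
    )
}

#' @export
print.wq_raster <- function(x, ...) {
  cat("<wq_raster> ", x$nrow, "x", x$ncol, " cells of ", x$cellsize,
      " m, origin (", x$origin[1], ", ", x$origin[2], "), crs ",
      x$crs, "\n", sep = "")
  v <- x$values[!is.na(x$values)]
  if (length(v)) cat("values: ", signif(min(v), 4), "..", signif(max(v), 4),
                     " (", length(v), " non-missing)\n", sep = "")
  invisible(x)
}

#' Classify a continuous index raster into the five ranks
#'
#' Maps every non-missing cell through [classify_wqi()] or [classify_cd()].
#' Negative cells (which can arise from interpolation overshoot) are set to
#' nodata and counted.
#'
#' @param grid A continuous `wq_raster`.
#' @param index `"wqi"` or `"cd"`.
#' @return A categorical `wq_raster` (integer ranks 1--5) with attributes
#'   `index`, `labels` and `n_negative`.
#' @export
classify_raster <- function(grid, index = c("wqi", "cd")) {
  index <- match.arg(index)
  stopifnot(inherits(grid, "wq_raster"))
  v <- grid$values
  neg <- !is.na(v) & v < 0
  if (any(neg)) {
    warning(sum(neg), " negative cell(s) set to nodata before classification")
    v[neg] <- NA_real_
  }
  cls <- if (index == "wqi") classify_wqi(as.numeric(v)) else
    classify_cd(as.numeric(v))
  out <- raster_grid(grid$origin, grid$cellsize, grid$nrow, grid$ncol,
                     matrix(cls, grid$nrow, grid$ncol),
                     crs = grid$crs, nodata = grid$nodata)
  attr(out, "index") <- index
  attr(out, "labels") <- if (index == "wqi") wqi_rank_scale()$label else
    cd_rank_scale()$label
  attr(out, "n_negative") <- sum(neg)
  out
}

#' Write / read a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format readable by every GIS. Values are written
#' at full double precision so a write/read round trip is bit-exact; the
#' coordinate-system identifier goes to a sidecar `.prj.txt` file (the
#' format itself has no CRS slot).
#'
#' @param grid A `wq_raster`.
#' @param path Output path (conventionally `.asc`).
#' @return `write_esri_ascii()` returns `path` invisibly;
#'   `read_esri_ascii()` returns a `wq_raster`.
#' @export
write_esri_ascii <- function(grid, path) {
  stopifnot(inherits(grid, "wq_raster"))
  v <- grid$values
  v[is.na(v)] <- grid$nodata
  header <- c(
    paste("ncols", grid$ncol),
    paste("nrows", grid$nrow),
    paste("xllcorner", format(grid$origin[1], digits = 17)),
    paste("yllcorner", format(grid$origin[2], digits = 17)),
    paste("cellsize", format(grid$cellsize, digits = 17)),
    paste("NODATA_value", format(grid$nodata, digits = 17))
  )
  body <- apply(v, 1, function(row) {
    paste(format(row, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = " ")
  })
  writeLines(c(header, body), path)
  if (!is.na(grid$crs)) {
    writeLines(as.character(grid$crs), paste0(path, ".prj.txt"))
  }
  invisible(path)
}

#' @param path Path to an `.asc` file written by [write_esri_ascii()].
#' @rdname write_esri_ascii
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  kv <- stats::setNames(vapply(hdr, `[`, "", 2), vapply(hdr, `[`, "", 1))
  ncol <- as.integer(kv[["ncols"]]); nrow <- as.integer(kv[["nrows"]])
  nodata <- as.numeric(kv[["nodata_value"]])
  vals <- matrix(
    as.numeric(unlist(strsplit(trimws(lines[-(1:6)]), "\\s+"))),
    nrow = nrow, ncol = ncol, byrow = TRUE
  )
  vals[vals == nodata] <- NA_real_
  prj <- paste0(path, ".prj.txt")
  crs <- if (file.exists(prj)) readLines(prj)[1] else NA_character_
  raster_grid(c(as.numeric(kv[["xllcorner"]]), as.numeric(kv[["yllcorner"]])),
              as.numeric(kv[["cellsize"]]), nrow, ncol, vals,
              crs = crs, nodata = nodata)
}
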