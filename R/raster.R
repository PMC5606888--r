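#' Lightweight in-memory raster grid
#'
#' A minimal single-band raster: a numeric matrix with row 1 the
#' northernmost row, plus a geotransform (lower-left corner, square cell
#' size). Nodata cells are stored as `NA`. All layers in an analysis must
#' share the grid exactly; alignment is validated, never resampled.
#'
#' @param values numeric matrix, row 1 = northernmost row.
#' @param xll,yll coordinates (m) of the lower-left *corner* of the grid.
#' @param cellsize cell edge length in meters (square cells).
#' @return an object of class `hs_raster`.
#' @export
hs_raster <- function(values, xll = 0, yll = 0, cellsize = 250) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(is.finite(xll), is.finite(yll), cellsize > 0)
  structure(list(values = values, xll = xll, yll = yll, cellsize = cellsize),
            class = "hs_raster")
}

#' @export
print.hs_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<hs_raster %d x %d, cell %g m, origin (%g, %g), %d nodata>\n",
              nrow(v), ncol(v), x$cellsize, x$xll, x$yll, sum(is.na(v))))
  invisible(x)
}

#' @export
dim.hs_raster <- function(x) dim(x$values)

geotransform_string <- function(r) {
  sprintf("ncols=%d nrows=%d xll=%g yll=%g cellsize=%g",
          ncol(r$values), nrow(r$values), r$xll, r$yll, r$cellsize)
}

#' Test two rasters for exact grid agreement
#' @param a,b `hs_raster` objects.
#' @return `TRUE` or `FALSE`.
#' @export
same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$xll, a$yll, a$cellsize), c(b$xll, b$yll, b$cellsize),
                     tolerance = 1e-9))
}

assert_same_grid <- function(a, b, what = "layer") {
  if (!same_grid(a, b)) {
    stop(sprintf("grid mismatch for %s: [%s] vs [%s]", what,
                 geotransform_string(a), geotransform_string(b)), call. = FALSE)
  }
  invisible(TRUE)
}

## row/col of the cells containing points; NA row for out-of-extent points
cell_index <- function(r, x, y) {
  nr <- nrow(r$values); nc <- ncol(r$values); cs <- r$cellsize
  col <- floor((x - r$xll) / cs) + 1L
  row_from_bottom <- floor((y - r$yll) / cs) + 1L
  row <- nr - row_from_bottom + 1L
  bad <- !is.finite(x) | !is.finite(y) | col < 1L | col > nc | row < 1L | row > nr
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Extract raster values at point locations
#'
#' @param r an `hs_raster`.
#' @param x,y point coordinates in the raster's projected CRS (meters).
#' @return numeric vector; `NA` for points outside the extent or on nodata
#'   cells. The attribute `"in_extent"` is a logical vector separating the
#'   two cases.
#' @export
extract_values <- function(r, x, y) {
  idx <- cell_index(r, x, y)
  ok <- !is.na(idx$row)
  out <- rep(NA_real_, length(x))
  out[ok] <- r$values[cbind(idx$row[ok], idx$col[ok])]
  attr(out, "in_extent") <- ok
  out
}

#' Coordinates of all cell centers
#' @param r an `hs_raster`.
#' @return data.frame with columns `x`, `y`, `row`, `col` in column-major
#'   cell order (matching `as.vector(r$values)`).
#' @export
cell_centers <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values); cs <- r$cellsize
  row <- rep(seq_len(nr), times = nc)
  col <- rep(seq_len(nc), each = nr)
  data.frame(x = r$xll + (col - 0.5) * cs,
             y = r$yll + (nr - row + 0.5) * cs,
             row = row, col = col)
}

#' Read an ESRI ASCII grid
#'
#' Supports `xllcorner`/`yllcorner` and `xllcenter`/`yllcenter` headers and
#' an optional `NODATA_value`. Values are stored top row first, as in the
#' file.
#'
#' @param path path to an `.asc` file.
#' @return an `hs_raster`.
#' @export
read_raster <- function(path) {
  lines <- readLines(path, n = 7L)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "xllcenter",
                   "yllcenter", "cellsize", "nodata_value")) {
      hdr[[key]] <- as.numeric(parts[2]); n_hdr <- n_hdr + 1L
    } else break
  }
  if (is.null(hdr$ncols) || is.null(hdr$nrows) || is.null(hdr$cellsize))
    stop("not an ESRI ASCII grid: ", path, call. = FALSE)
  cs <- hdr$cellsize
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - cs / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - cs / 2
  vals <- scan(path, what = double(), skip = n_hdr, quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop(sprintf("expected %d values, found %d in %s", nr * nc, length(vals),
                 path), call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  hs_raster(m, xll = xll, yll = yll, cellsize = cs)
}

#' Write an ESRI ASCII grid
#' @param r an `hs_raster`.
#' @param path output path.
#' @param nodata value written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_raster <- function(r, path, nodata = -9999) {
  m <- r$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(m)),
               sprintf("nrows %d", nrow(m)),
               sprintf("xllcorner %.10g", r$xll),
               sprintf("yllcorner %.10g", r$yll),
               sprintf("cellsize %.10g", r$cellsize),
               sprintf("NODATA_value %g", nodata)), con)
  m[is.na(m)] <- nodata
  writeLines(apply(m, 1L, function(row) paste(format(row, digits = 9,
                                                     trim = TRUE,
                                                     scientific = FALSE),
                                              collapse = " ")), con)
  invisible(path)
}

#' Bundle co-registered predictor layers
#'
#' A predictor stack holds named rasters on one common grid with a
#' continuous/categorical flag per layer and a shared nodata mask (a cell is
#' masked if any layer is nodata there).
#'
#' @param layers named list of `hs_raster` objects.
#' @param kinds named character vector, `"continuous"` or `"categorical"`,
#'   one per layer; defaults to all continuous.
#' @return an object of class `hs_stack`.
#' @export
predictor_stack <- function(layers, kinds = NULL) {
  stopifnot(length(layers) >= 1, !is.null(names(layers)),
            all(nzchar(names(layers))))
  if (is.null(kinds)) {
    kinds <- stats::setNames(rep("continuous", length(layers)), names(layers))
  }
  kinds <- kinds[names(layers)]
  stopifnot(all(kinds %in% c("continuous", "categorical")))
  ref <- layers[[1]]
  for (nm in names(layers)) {
    assert_same_grid(ref, layers[[nm]], what = nm)
    if (kinds[[nm]] == "categorical") {
      v <- layers[[nm]]$values
      if (any(v[!is.na(v)] != round(v[!is.na(v)])))
        stop("categorical layer '", nm, "' holds non-integer codes",
             call. = FALSE)
    }
  }
  mask <- Reduce(`|`, lapply(layers, function(l) is.na(l$values)))
  structure(list(layers = layers, kinds = kinds, grid = ref[c("xll", "yll",
                                                              "cellsize")],
                 mask = mask),
            class = "hs_stack")
}

#' @export
print.hs_stack <- function(x, ...) {
  cat(sprintf("<hs_stack: %d layers (%d categorical), %d x %d cells>\n",
              length(x$layers), sum(x$kinds == "categorical"),
              nrow(x$mask), ncol(x$mask)))
  cat(" ", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' Extract a stack's layer values at points as a data.frame
#' @param stack an `hs_stack`.
#' @param x,y point coordinates (m).
#' @return data.frame with one column per layer; masked cells yield `NA`.
#' @export
extract_stack <- function(stack, x, y) {
  out <- lapply(stack$layers, function(l) {
    v <- extract_values(l, x, y); attributes(v) <- NULL; v
  })
  as.data.frame(out, optional = TRUE)
}

## stack values as a cells x layers matrix over unmasked cells
stack_matrix <- function(stack) {
  keep <- !as.vector(stack$mask)
  m <- vapply(stack$layers, function(l) as.vector(l$values)[keep],
              numeric(sum(keep)))
  colnames(m) <- names(stack$layers)
  attr(m, "cell_keep") <- keep
  m
}
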