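#' Minimal georeferenced grid container
#'
#' An `env_grid` holds a single environmental layer: a numeric matrix whose
#' first row is the northernmost line of cells, together with the coordinates
#' of the lower-left corner and a square cell size in decimal degrees
#' (WGS84, cell-center registration). `NA` cells are masked (invalid).
#'
#' @param values numeric matrix; rows run north to south, columns west to east.
#' @param xmin,ymin coordinates (degrees) of the lower-left corner of the grid.
#' @param cellsize cell edge length in degrees; must be positive.
#' @return an object of class `env_grid`.
#' @export
env_grid <- function(values, xmin, ymin, cellsize) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (!is.finite(cellsize) || cellsize <= 0)
    stop("'cellsize' must be a positive number")
  if (!is.finite(xmin) || !is.finite(ymin))
    stop("'xmin' and 'ymin' must be finite")
  structure(
    list(values = values, xmin = xmin, ymin = ymin, cellsize = cellsize),
    class = "env_grid"
  )
}

#' @export
print.env_grid <- function(x, ...) {
  e <- grid_extent(x)
  cat(sprintf(
    "env_grid: %d rows x %d cols, cellsize %g deg\n  extent: lon [%g, %g], lat [%g, %g]\n  valid cells: %d / %d\n",
    nrow(x$values), ncol(x$values), x$cellsize,
    e["xmin"], e["xmax"], e["ymin"], e["ymax"],
    sum(!is.na(x$values)), length(x$values)
  ))
  invisible(x)
}

#' Extent of a grid
#'
#' @param g an `env_grid`.
#' @return named numeric vector `xmin, xmax, ymin, ymax` (cell edges).
#' @export
grid_extent <- function(g) {
  c(
    xmin = g$xmin, xmax = g$xmin + ncol(g$values) * g$cellsize,
    ymin = g$ymin, ymax = g$ymin + nrow(g$values) * g$cellsize
  )
}

#' Cell-center coordinates
#'
#' Coordinates of every cell center, in the same (column-major) order as
#' `as.vector(g$values)`.
#'
#' @param g an `env_grid`.
#' @return data.frame with columns `lon`, `lat`.
#' @export
grid_coords <- function(g) {
  nr <- nrow(g$values); nc <- ncol(g$values)
  ymax <- g$ymin + nr * g$cellsize
  lon <- g$xmin + (seq_len(nc) - 0.5) * g$cellsize
  lat <- ymax - (seq_len(nr) - 0.5) * g$cellsize
  data.frame(
    lon = rep(lon, each = nr),
    lat = rep(lat, times = nc)
  )
}

#' Locate points on a grid
#'
#' @param g an `env_grid`.
#' @param lon,lat numeric vectors of point coordinates (degrees).
#' @return integer matrix with columns `row`, `col`; `NA` for points outside
#'   the grid extent.
#' @export
cell_of <- function(g, lon, lat) {
  e <- grid_extent(g)
  col <- floor((lon - g$xmin) / g$cellsize) + 1L
  row <- floor((e["ymax"] - lat) / g$cellsize) + 1L
  # points exactly on the top/right edge belong to the outermost cell
  col[lon == e["xmax"]] <- ncol(g$values)
  row[lat == e["ymin"]] <- nrow(g$values)
  bad <- lon < e["xmin"] | lon > e["xmax"] | lat < e["ymin"] | lat > e["ymax"]
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Extract grid values at point locations
#'
#' @inheritParams cell_of
#' @return numeric vector; `NA` for points outside the extent or on masked
#'   cells.
#' @export
extract_at <- function(g, lon, lat) {
  rc <- cell_of(g, lon, lat)
  out <- rep(NA_real_, nrow(rc))
  ok <- !is.na(rc[, 1])
  out[ok] <- g$values[cbind(rc[ok, 1], rc[ok, 2])]
  out
}

#' Test whether two grids share geometry
#'
#' @param a,b `env_grid` objects.
#' @param tol numeric tolerance on origin and cell size.
#' @return logical.
#' @export
same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$xmin - b$xmin) < tol &&
    abs(a$ymin - b$ymin) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

#' Write a grid as an ESRI ASCII raster (.asc)
#'
#' Plain-text single-band raster; the text sibling of a single-band GeoTIFF.
#'
#' @param g an `env_grid`.
#' @param path output file path.
#' @param nodata value used to encode masked cells.
#' @export
write_asc <- function(g, path, nodata = -9999) {
  v <- g$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", g$xmin),
    sprintf("yllcorner %.10g", g$ymin),
    sprintf("cellsize %.10g", g$cellsize),
    sprintf("NODATA_value %g", nodata)
  ), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII raster (.asc)
#'
#' @param path file path.
#' @return an `env_grid`; cells equal to the file's NODATA value become `NA`.
#' @export
read_asc <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "[[:space:]]+")
  keys <- tolower(vapply(kv, `[`, "", 1))
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% keys))
    stop("malformed .asc header in ", path)
  v <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(v) <- NULL
  if (!identical(dim(v), c(as.integer(vals["nrows"]), as.integer(vals["ncols"]))))
    stop("grid body dimensions disagree with header in ", path)
  if ("nodata_value" %in% keys)
    v[v == vals["nodata_value"]] <- NA_real_
  env_grid(v, vals[["xllcorner"]], vals[["yllcorner"]], vals[["cellsize"]])
}

#' Bundle 12 monthly layers of one variable
#'
#' @param kind one of `"MIR"`, `"DTLST"`, `"NTLST"`, `"NDVI"`, `"EVI"`.
#' @param grids list of 12 `env_grid` layers (January to December) sharing
#'   geometry and valid-cell mask.
#' @return object of class `monthly_stack`.
#' @export
monthly_stack <- function(kind, grids) {
  kind <- match.arg(kind, c("MIR", "DTLST", "NTLST", "NDVI", "EVI"))
  if (length(grids) != 12)
    stop("a monthly stack needs exactly 12 layers, got ", length(grids))
  ref <- grids[[1]]
  for (i in seq_along(grids)) {
    if (!inherits(grids[[i]], "env_grid"))
      stop("layer ", i, " is not an env_grid")
    if (!same_geometry(ref, grids[[i]]))
      stop("layer ", i, " does not share the stack geometry")
    if (!identical(is.na(ref$values), is.na(grids[[i]]$values)))
      stop("layer ", i, " does not share the stack's valid-cell mask")
  }
  structure(list(kind = kind, grids = grids), class = "monthly_stack")
}

#' @export
print.monthly_stack <- function(x, ...) {
  cat(sprintf("monthly_stack '%s' (12 layers)\n", x$kind))
  print(x$grids[[1]])
  invisible(x)
}

# cells x 12 matrix of a stack's values (column-major cell order)
stack_matrix <- function(stack) {
  vapply(stack$grids, function(g) as.vector(g$values),
         numeric(length(stack$grids[[1]]$values)))
}
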