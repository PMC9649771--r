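#' Define a raster grid geometry
#'
#' A `grid_spec` describes a regular geographic grid of square cells in
#' degrees. `(origin_lon, origin_lat)` is the north-west corner of the grid;
#' rows count southward from 0, columns eastward from 0. Cell `(r, c)` covers
#' the half-open box
#' `[origin_lon + c*cell_size, origin_lon + (c+1)*cell_size)` in longitude and
#' `(origin_lat - (r+1)*cell_size, origin_lat - r*cell_size]` in latitude, so
#' a point on an interior cell edge belongs to the cell south/east of it and
#' points on the outer east/south edge are out of extent.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param origin_lon,origin_lat North-west corner, decimal degrees.
#' @param cell_size Cell edge length in degrees (> 0).
#' @param crs_label Label for the coordinate system; coordinates are taken as
#'   given and never reprojected.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, origin_lon, origin_lat, cell_size,
                      crs_label = "WGS84") {
  if (!(is.numeric(n_rows) && n_rows >= 1 && n_rows == as.integer(n_rows)) ||
      !(is.numeric(n_cols) && n_cols >= 1 && n_cols == as.integer(n_cols))) {
    ts_abort("n_rows and n_cols must be positive integers", "grid_invalid")
  }
  if (!is.numeric(cell_size) || cell_size <= 0) {
    ts_abort("cell_size must be > 0", "grid_invalid")
  }
  structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      origin_lon = as.numeric(origin_lon), origin_lat = as.numeric(origin_lat),
      cell_size = as.numeric(cell_size), crs_label = crs_label
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d x %d cells of %g deg, NW corner (%g, %g), %s\n",
    x$n_rows, x$n_cols, x$cell_size, x$origin_lon, x$origin_lat, x$crs_label
  ))
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$origin_lon - b$origin_lon) < tol &&
    abs(a$origin_lat - b$origin_lat) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

#' Map points to grid cells
#'
#' Floor-based assignment under the half-open cell convention: row 0 is the
#' northernmost row, points on an interior edge fall in the cell to the
#' south/east, and points on the outer east/south edge (or anywhere outside
#' the extent) get `NA` indices rather than an error.
#'
#' @param grid A [grid_spec()].
#' @param lon,lat Numeric vectors of equal length, decimal degrees.
#' @return A tibble with columns `lon`, `lat`, `row`, `col`, `in_extent`.
#'   `row`/`col` are 0-based and `NA` when out of extent.
#' @export
point_to_cell <- function(grid, lon, lat) {
  stopifnot(inherits(grid, "grid_spec"), length(lon) == length(lat))
  col <- floor((lon - grid$origin_lon) / grid$cell_size)
  row <- floor((grid$origin_lat - lat) / grid$cell_size)
  # The north edge of the grid (lat == origin_lat) belongs to row 0.
  row[lat == grid$origin_lat] <- 0
  inside <- row >= 0 & row < grid$n_rows & col >= 0 & col < grid$n_cols
  tibble::tibble(
    lon = lon, lat = lat,
    row = ifelse(inside, row, NA_integer_),
    col = ifelse(inside, col, NA_integer_),
    in_extent = inside
  )
}

#' Coordinates of cell centres
#'
#' @param grid A [grid_spec()].
#' @param row,col 0-based cell indices.
#' @return A tibble with columns `row`, `col`, `lon`, `lat`.
#' @export
cell_center <- function(grid, row, col) {
  stopifnot(inherits(grid, "grid_spec"))
  tibble::tibble(
    row = as.integer(row), col = as.integer(col),
    lon = grid$origin_lon + (col + 0.5) * grid$cell_size,
    lat = grid$origin_lat - (row + 0.5) * grid$cell_size
  )
}

# Linear (column-major) matrix index for 0-based (row, col) pairs.
cell_index <- function(grid, row, col) {
  as.integer(col) * grid$n_rows + as.integer(row) + 1L
}

#' Construct an environmental raster stack
#'
#' Bundles named environmental layers that share one grid, plus a validity
#' mask. Values at masked-out cells are ignored by every consumer in the
#' package. The configuration used throughout the worked analyses carries the
#' layers `cmi` (climatic moisture index), `ppt_wt` (winter precipitation),
#' `rh` (relative humidity), `td` (continentality) and `stream_order`
#' (Strahler order, 0 off-stream).
#'
#' @param grid A [grid_spec()].
#' @param layers Named list of numeric matrices (`n_rows x n_cols`).
#' @param valid_mask Logical matrix of the same dimensions; defaults to the
#'   conjunction of non-`NA` cells across layers.
#' @return An object of class `env_stack`.
#' @export
env_stack <- function(grid, layers, valid_mask = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  if (is.null(names(layers)) || any(!nzchar(names(layers)))) {
    ts_abort("layers must be a named list", "stack_invalid")
  }
  for (nm in names(layers)) {
    lay <- layers[[nm]]
    if (!is.matrix(lay) || nrow(lay) != grid$n_rows || ncol(lay) != grid$n_cols) {
      ts_abort(
        sprintf("layer '%s' does not match the grid dimensions (%d x %d)",
                nm, grid$n_rows, grid$n_cols),
        "dim_mismatch"
      )
    }
  }
  if (is.null(valid_mask)) {
    valid_mask <- Reduce(`&`, lapply(layers, function(m) !is.na(m)))
  }
  stopifnot(is.matrix(valid_mask), dim(valid_mask)[1] == grid$n_rows)
  structure(
    list(grid = grid, layers = layers, valid_mask = valid_mask),
    class = "env_stack"
  )
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf(
    "<env_stack> %d layers [%s] on %d x %d grid, %d valid cells\n",
    length(x$layers), paste(names(x$layers), collapse = ", "),
    x$grid$n_rows, x$grid$n_cols, sum(x$valid_mask)
  ))
  invisible(x)
}

# Raw layer values at 0-based (row, col) cells: one matrix row per cell.
extract_cells <- function(env, cells, layers = names(env$layers)) {
  idx <- cell_index(env$grid, cells$row, cells$col)
  out <- vapply(layers, function(nm) env$layers[[nm]][idx], numeric(length(idx)))
  if (length(idx) == 1L) out <- matrix(out, nrow = 1, dimnames = list(NULL, layers))
  out
}

## ---- Plain-text raster I/O (ESRI ASCII grid) --------------------------------

#' Write a raster layer to an ESRI ASCII grid file
#'
#' Single-band plain-text rasters; integer layers round-trip bit-exactly
#' through [read_raster()]. `NA` cells are written as the nodata value.
#'
#' @param values Numeric matrix matching the grid dimensions.
#' @param grid A [grid_spec()].
#' @param path Output file path (conventionally `.asc`).
#' @param nodata Nodata sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_raster <- function(values, grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.matrix(values) || nrow(values) != grid$n_rows ||
      ncol(values) != grid$n_cols) {
    ts_abort("values matrix does not match the grid dimensions", "dim_mismatch")
  }
  num <- function(x) sprintf("%.15g", x)
  header <- c(
    paste("ncols", grid$n_cols),
    paste("nrows", grid$n_rows),
    paste("xllcorner", num(grid$origin_lon)),
    paste("yllcorner", num(grid$origin_lat - grid$n_rows * grid$cell_size)),
    paste("cellsize", num(grid$cell_size)),
    paste("NODATA_value", num(nodata))
  )
  vals <- values
  vals[is.na(vals)] <- nodata
  body <- apply(vals, 1, function(r) paste(num(r), collapse = " "))
  ok <- tryCatch(
    {
      writeLines(c(header, body), path)
      TRUE
    },
    error = function(e) FALSE
  )
  if (!ok) ts_abort(sprintf("cannot write raster to '%s'", path), "io")
  invisible(path)
}

#' Read an ESRI ASCII grid file
#'
#' @param path Path to a `.asc` file.
#' @param crs_label Coordinate-system label to attach to the grid.
#' @return A list with elements `values` (matrix, nodata mapped to `NA`) and
#'   `grid` (a [grid_spec()]).
#' @export
read_raster <- function(path, crs_label = "WGS84") {
  if (!file.exists(path)) {
    ts_abort(sprintf("raster file '%s' does not exist", path), "io")
  }
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  needed <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(needed %in% names(hdr))) {
    ts_abort(sprintf("'%s' is not an ASCII grid (missing header keys)", path), "io")
  }
  nodata <- hdr[["nodata_value"]] %||% -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows)
  nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    ts_abort(sprintf("'%s': expected %d values, found %d", path, nr * nc,
                     length(vals)), "io")
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  grid <- grid_spec(
    n_rows = nr, n_cols = nc,
    origin_lon = hdr$xllcorner,
    origin_lat = hdr$yllcorner + nr * hdr$cellsize,
    cell_size = hdr$cellsize, crs_label = crs_label
  )
  list(values = m, grid = grid)
}

#' Read a set of raster layers into an environmental stack
#'
#' All rasters must share dimensions and georeferencing; the stack's validity
#' mask is the conjunction of the per-layer nodata masks.
#'
#' @param paths Character vector of raster file paths.
#' @param names Layer names, same length as `paths`.
#' @return An [env_stack()].
#' @export
read_env_stack <- function(paths, names) {
  stopifnot(length(paths) == length(names), length(paths) >= 1)
  first <- read_raster(paths[[1]])
  layers <- stats::setNames(vector("list", length(paths)), names)
  layers[[1]] <- first$values
  if (length(paths) > 1) {
    for (k in 2:length(paths)) {
      r <- read_raster(paths[[k]])
      if (!grids_equal(r$grid, first$grid)) {
        ts_abort(
          sprintf("layer '%s' (%s) does not match the grid of '%s'",
                  names[[k]], paths[[k]], names[[1]]),
          "dim_mismatch"
        )
      }
      layers[[k]] <- r$values
    }
  }
  env_stack(first$grid, layers)
}

## ---- Scenarios --------------------------------------------------------------

#' Label a climate scenario
#'
#' A scenario is a (GCM, RCP, period) triple. The baseline uses
#' `period = "current"` with the sentinel `"none"` for GCM and RCP.
#'
#' @param gcm General circulation model label (e.g. `"gfdl-cm3"`).
#' @param rcp `"4.5"` or `"8.5"` (`"none"` for the baseline).
#' @param period `"current"`, `"2050s"` or `"2080s"`.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(gcm = "none", rcp = "none", period = "current") {
  period <- as.character(period)
  rcp <- as.character(rcp)
  if (!period %in% c("current", "2050s", "2080s")) {
    ts_abort("period must be one of current/2050s/2080s", "scenario_invalid")
  }
  if (period == "current") {
    if (!(gcm == "none" && rcp == "none")) {
      ts_abort("the current scenario must use gcm = rcp = 'none'",
               "scenario_invalid")
    }
  } else if (!rcp %in% c("4.5", "8.5")) {
    ts_abort("rcp must be '4.5' or '8.5' for future scenarios",
             "scenario_invalid")
  }
  structure(list(gcm = gcm, rcp = rcp, period = period),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec>", scenario_label(x), "\n")
  invisible(x)
}

#' @rdname scenario_spec
#' @param scenario A `scenario_spec`.
#' @export
scenario_label <- function(scenario) {
  if (scenario$period == "current") return("current")
  paste(scenario$gcm, paste0("rcp", scenario$rcp), scenario$period, sep = "_")
}

scenario_fields <- function(scenario) {
  tibble::tibble(gcm = scenario$gcm, rcp = scenario$rcp,
                 period = scenario$period,
                 scenario = scenario_label(scenario))
}

#' The default scenario grid
#'
#' Baseline plus 12 future scenarios: three GCMs crossed with RCP 4.5/8.5 and
#' the 2050s/2080s periods.
#'
#' @param gcms Character vector of GCM labels.
#' @return A list of [scenario_spec()] objects, baseline first.
#' @export
default_scenarios <- function(gcms = c("inm-cm4", "mpi-esm-lr", "gfdl-cm3")) {
  out <- list(scenario_spec())
  for (gcm in gcms) {
    for (rcp in c("4.5", "8.5")) {
      for (period in c("2050s", "2080s")) {
        out[[length(out) + 1L]] <- scenario_spec(gcm, rcp, period)
      }
    }
  }
  out
}

## ---- Occurrence tables ------------------------------------------------------

POPULATIONS <- c("southern", "central", "northern")

#' Validate an occurrence table
#'
#' One row per genotype: its field coordinates, genetic population, and
#' greenhouse leaf-out day (Julian day of year, the genetically based trait).
#'
#' @param x A data frame with columns `genotype_id`, `lon`, `lat`,
#'   `population`, `leafout_day`.
#' @return The validated table as a tibble (class `occurrence_table`).
#' @export
occurrence_table <- function(x) {
  required <- c("genotype_id", "lon", "lat", "population", "leafout_day")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    ts_abort(paste("missing occurrence columns:",
                   paste(missing_cols, collapse = ", ")), "occ_invalid")
  }
  x <- tibble::as_tibble(x)
  x$genotype_id <- as.character(x$genotype_id)
  x$leafout_day <- as.integer(x$leafout_day)
  dup <- x$genotype_id[duplicated(x$genotype_id)]
  if (length(dup) > 0) {
    ts_abort(paste("duplicated genotype_id:", paste(unique(dup), collapse = ", ")),
             "occ_invalid")
  }
  bad_day <- which(is.na(x$leafout_day) | x$leafout_day < 1 | x$leafout_day > 366)
  if (length(bad_day) > 0) {
    ts_abort(sprintf("leafout_day outside [1, 366] at row(s) %s",
                     paste(bad_day, collapse = ", ")), "occ_invalid")
  }
  bad_pop <- which(!x$population %in% POPULATIONS)
  if (length(bad_pop) > 0) {
    ts_abort(sprintf("unknown population label at row(s) %s (allowed: %s)",
                     paste(bad_pop, collapse = ", "),
                     paste(POPULATIONS, collapse = ", ")), "occ_invalid")
  }
  class(x) <- c("occurrence_table", class(x))
  x
}

#' Read an occurrence CSV
#'
#' Expects a header with columns `genotype_id`, `lon`, `lat`, `population`,
#' `leafout_day`; rows are validated as in [occurrence_table()].
#'
#' @param path Path to a CSV file.
#' @return An `occurrence_table` tibble.
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) {
    ts_abort(sprintf("occurrence file '%s' does not exist", path), "io")
  }
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  occurrence_table(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
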