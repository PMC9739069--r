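#' Six-class land-cover legend
#'
#' Default legend used throughout the package: 1 cultivated land, 2 forest,
#' 3 grassland, 4 water, 5 built up, 6 deserted land. Codes are stored as the
#' names of the returned character vector.
#'
#' @return Named character vector mapping code (as name) to class name.
#' @export
lulc_legend <- function() {
  c(`1` = "Cultivated land", `2` = "Forest", `3` = "Grassland",
    `4` = "Water", `5` = "Built up", `6` = "Deserted land")
}

#' Construct a categorical land-cover grid
#'
#' A `lulc_grid` is an integer matrix of class codes plus metadata: cell size
#' in metres, a free-text date/epoch label, a legend, and a simple
#' origin-based geotransform (row 1 is the northernmost row, cell (1,1) the
#' north-west corner). Nodata cells are stored as `NA`; on disk they are
#' written as code 0.
#'
#' @param codes Integer matrix; every non-`NA` value must be a legend code.
#' @param cell_size Cell side length in metres (default 500).
#' @param label Date/epoch tag, e.g. `"2020"`.
#' @param legend Named character vector, code -> class name.
#' @param origin Numeric length-2 `(x, y)` of the lower-left corner.
#' @return Object of class `lulc_grid`.
#' @export
lulc_grid <- function(codes, cell_size = 500, label = "",
                      legend = lulc_legend(), origin = c(0, 0)) {
  if (!is.matrix(codes)) stop("`codes` must be a matrix")
  storage.mode(codes) <- "integer"
  if (nrow(codes) < 1L || ncol(codes) < 1L) stop("grid must be at least 1x1")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  vals <- unique(codes[!is.na(codes)])
  bad <- setdiff(vals, as.integer(names(legend)))
  if (length(bad))
    stop("codes not in legend: ", paste(sort(bad), collapse = ", "))
  structure(list(codes = codes, cell_size = cell_size, label = label,
                 legend = legend, origin = as.numeric(origin)),
            class = "lulc_grid")
}

#' @export
print.lulc_grid <- function(x, ...) {
  cat(sprintf("<lulc_grid %dx%d, %g m cells, label '%s'>\n",
              nrow(x$codes), ncol(x$codes), x$cell_size, x$label))
  tab <- class_areas(x)
  print(tab, row.names = FALSE)
  invisible(x)
}

is_lulc_grid <- function(x) inherits(x, "lulc_grid")

#' Check two grids share shape, cell size and legend
#' @noRd
check_congruent <- function(a, b) {
  if (!identical(dim(a$codes), dim(b$codes)))
    stop("grids have different shapes: ",
         paste(dim(a$codes), collapse = "x"), " vs ",
         paste(dim(b$codes), collapse = "x"))
  if (!isTRUE(all.equal(a$cell_size, b$cell_size)))
    stop("grids have different cell sizes")
  if (length(intersect(names(a$legend), names(b$legend))) == 0L)
    stop("grids have disjoint legends")
  invisible(TRUE)
}

#' Reclassify a Globeland30 raster to the six-class system
#'
#' Maps the Globeland30 level-1 codes onto the working legend:
#' 10 (cultivated) -> 1; 20 (forest) -> 2; 30 grassland, 40 shrub land and
#' 50 wetland -> 3; 60 (water bodies) -> 4; 80 (artificial surfaces) -> 5;
#' 90 bare land and 100 permanent snow/ice -> 6. `NA` (and raw 0) is kept as
#' nodata; any other code is an error.
#'
#' @param raw Integer matrix of Globeland30 codes.
#' @inheritParams lulc_grid
#' @return A [lulc_grid].
#' @export
reclassify_globeland30 <- function(raw, cell_size = 500, label = "") {
  if (!is.matrix(raw)) stop("`raw` must be a matrix")
  storage.mode(raw) <- "integer"
  raw[!is.na(raw) & raw == 0L] <- NA_integer_
  map <- c(`10` = 1L, `20` = 2L, `30` = 3L, `40` = 3L, `50` = 3L,
           `60` = 4L, `80` = 5L, `90` = 6L, `100` = 6L)
  known <- as.integer(names(map))
  bad <- !is.na(raw) & !(raw %in% known)
  if (any(bad)) {
    tab <- table(raw[bad])
    stop("unmapped Globeland30 code(s): ",
         paste(sprintf("%s (%d cells)", names(tab), as.integer(tab)),
               collapse = ", "))
  }
  out <- matrix(map[as.character(raw)], nrow(raw), ncol(raw))
  lulc_grid(out, cell_size = cell_size, label = label)
}

#' Per-class area table
#'
#' Counts cells per class and converts to hectares
#' (`cell_size^2 / 1e4` ha per cell) and percent of valid area. Nodata cells
#' are excluded. Only classes present in the grid are listed.
#'
#' @param grid A [lulc_grid].
#' @return data.frame with columns `class`, `name`, `cells`, `area_ha`, `pct`.
#' @export
class_areas <- function(grid) {
  stopifnot(is_lulc_grid(grid))
  v <- grid$codes[!is.na(grid$codes)]
  if (length(v) == 0L) stop("empty landscape: all cells are nodata")
  tab <- table(factor(v, levels = sort(unique(v))))
  cells <- as.integer(tab)
  cell_ha <- grid$cell_size^2 / 1e4
  data.frame(class = as.integer(names(tab)),
             name = unname(grid$legend[names(tab)]),
             cells = cells,
             area_ha = cells * cell_ha,
             pct = 100 * cells / sum(cells))
}

#' Per-class cell counts over the full legend (absent classes = 0)
#' @noRd
class_counts <- function(grid) {
  lv <- as.integer(names(grid$legend))
  as.integer(table(factor(grid$codes[!is.na(grid$codes)], levels = lv)))
}

#' Write / read a land-cover grid as an Esri ASCII grid with JSON sidecar
#'
#' The `.asc` file holds the integer codes (nodata written as 0); a
#' `<path>.json` sidecar stores label, legend and cell size so that a
#' round trip reproduces the grid exactly.
#'
#' @param grid A [lulc_grid].
#' @param path Output path (conventionally ending in `.asc`).
#' @return `write_lulc`: `path`, invisibly. `read_lulc`: a [lulc_grid].
#' @export
write_lulc <- function(grid, path) {
  stopifnot(is_lulc_grid(grid))
  m <- grid$codes
  m[is.na(m)] <- 0L
  hdr <- c(sprintf("ncols %d", ncol(m)),
           sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %.10g", grid$origin[1]),
           sprintf("yllcorner %.10g", grid$origin[2]),
           sprintf("cellsize %.10g", grid$cell_size),
           "NODATA_value 0")
  body <- apply(m, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  jsonlite::write_json(
    list(label = grid$label, legend = as.list(grid$legend),
         cell_size = grid$cell_size, origin = grid$origin),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lulc
#' @export
read_lulc <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, " "), hdr, ignore.case = TRUE)]
    strsplit(trimws(ln), "\\s+")[[1]][2]
  }
  nc <- as.integer(val("ncols")); nr <- as.integer(val("nrows"))
  body <- lines[-(1:6)]
  m <- matrix(as.integer(unlist(strsplit(trimws(body), "\\s+"))),
              nrow = nr, ncol = nc, byrow = TRUE)
  m[m == 0L] <- NA_integer_
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  legend <- if (length(meta$legend)) {
    stats::setNames(unlist(meta$legend), names(meta$legend))
  } else lulc_legend()
  lulc_grid(m,
            cell_size = if (length(meta$cell_size)) meta$cell_size
                        else as.numeric(val("cellsize")),
            label = if (length(meta$label)) meta$label else "",
            legend = legend,
            origin = if (length(meta$origin)) unlist(meta$origin)
                     else c(as.numeric(val("xllcorner")),
                            as.numeric(val("yllcorner"))))
}
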