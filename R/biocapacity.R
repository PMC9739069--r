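# Biocapacity accounting: BC = sum_i A_i * YF_i * EQF_i over land classes,
# in global hectares. YF scales local productivity of a land type to the
# world average for that type; EQF converts to all-land world-average
# productivity. Built-up and deserted land carry YF = 0.

#' Bundled yield / equivalence factor table
#'
#' Reads the packaged factor file (epochs 2000/2010/2020/2030; the 2030
#' factors equal the 2020 ones by assumption). Cultivated land, forest,
#' grassland and water carry positive factors; built-up and deserted land
#' have YF = 0, reflecting their negligible natural productivity.
#'
#' @param path Optional path to a user CSV with columns
#'   `class`, `name`, `epoch`, `YF`, `EQF`.
#' @return data.frame with an added `BF = YF * EQF` column (gha/ha).
#' @export
bc_factors <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "bc_factors.csv", package = "lulcsim")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("class", "epoch", "YF", "EQF")
  if (!all(need %in% names(tab)))
    stop("factor table must have columns ", paste(need, collapse = ", "))
  if (any(tab$YF < 0) || any(tab$EQF < 0)) stop("negative factor")
  tab$BF <- tab$YF * tab$EQF
  tab
}

#' Biocapacity report for one land-cover map
#'
#' Per class i: BC_i = A_i (ha) x YF_i x EQF_i (gha); the total is the sum.
#' Optionally also returns the per-pixel BC lattice (each cell contributes
#' its class's BF times the cell area in hectares).
#'
#' @param grid A [lulc_grid].
#' @param factors Factor table from [bc_factors()].
#' @param epoch Epoch label matching the table (default: the grid label).
#' @param per_pixel Also compute the per-pixel lattice?
#' @return Object of class `bc_report`: `table` (per-class data.frame),
#'   `total` (gha), `epoch`, optionally `pixel` (matrix, gha per cell).
#' @export
biocapacity_report <- function(grid, factors = bc_factors(),
                               epoch = grid$label, per_pixel = FALSE) {
  stopifnot(is_lulc_grid(grid))
  fac <- factors[factors$epoch == epoch, ]
  if (!nrow(fac)) stop("no factors for epoch '", epoch, "'")
  areas <- class_areas(grid)
  miss <- setdiff(areas$class, fac$class)
  if (length(miss))
    stop("class(es) ", paste(miss, collapse = ", "),
         " present in grid but absent from factor table for epoch '",
         epoch, "'")
  i <- match(areas$class, fac$class)
  tab <- data.frame(class = areas$class, name = areas$name,
                    area_ha = areas$area_ha,
                    YF = fac$YF[i], EQF = fac$EQF[i], BF = fac$BF[i])
  tab$BC_gha <- tab$area_ha * tab$BF
  out <- list(table = tab, total = sum(tab$BC_gha), epoch = epoch)
  if (per_pixel) {
    bf <- stats::setNames(fac$BF, fac$class)
    cell_ha <- grid$cell_size^2 / 1e4
    px <- matrix(bf[as.character(grid$codes)] * cell_ha,
                 nrow(grid$codes), ncol(grid$codes))
    out$pixel <- px
  }
  structure(out, class = "bc_report")
}

#' @export
print.bc_report <- function(x, ...) {
  cat(sprintf("<bc_report epoch %s: total %.4g gha>\n", x$epoch, x$total))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Biocapacity time series and linear trend
#'
#' Computes a [biocapacity_report()] per dated map and least-squares linear
#' trends of BC against calendar year (gha per year), per class and total.
#' Dates are taken from grid labels (or `years`); a single date yields no
#' trend, with a warning.
#'
#' @param grids List of [lulc_grid]s with numeric-parsable labels.
#' @param factors Factor table from [bc_factors()].
#' @param years Optional numeric years overriding the labels.
#' @return List: `by_date` (data.frame class x date BC), `total_by_date`,
#'   `trend` (data.frame class/total slopes in gha/a, `NULL` if one date).
#' @export
bc_timeseries <- function(grids, factors = bc_factors(), years = NULL) {
  stopifnot(is.list(grids), length(grids) >= 1L)
  if (is.null(years))
    years <- vapply(grids, function(g) as.numeric(g$label), numeric(1))
  if (any(!is.finite(years))) stop("grid labels must parse as years")
  reps <- lapply(grids, function(g) biocapacity_report(g, factors))
  classes <- sort(unique(unlist(lapply(reps, function(r) r$table$class))))
  bc <- vapply(reps, function(r)
    r$table$BC_gha[match(classes, r$table$class)], numeric(length(classes)))
  bc <- matrix(bc, nrow = length(classes))
  bc[is.na(bc)] <- 0
  by_date <- data.frame(class = classes, bc,
                        check.names = FALSE)
  names(by_date) <- c("class", as.character(years))
  totals <- vapply(reps, function(r) r$total, numeric(1))
  trend <- NULL
  if (length(unique(years)) < 2L) {
    warning("single date: trend omitted")
  } else {
    slope <- function(y) unname(stats::coef(stats::lm(y ~ years))[2])
    trend <- data.frame(
      class = c(classes, NA),
      name = c(vapply(as.character(classes), function(k)
        unname(lulc_legend()[k]), character(1)), "TOTAL"),
      slope_gha_per_a = c(apply(bc, 1, slope), slope(totals)))
  }
  list(by_date = by_date,
       total_by_date = stats::setNames(totals, years),
       trend = trend)
}
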