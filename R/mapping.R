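#' Predict relative intensity of use on a prediction grid
#'
#' Applies the fitted RSF with offset zero (one survey-year scale) to a grid
#' of unit-sized cells covering the study area; the result is a relative
#' intensity surface, sufficient for decile classification and abundance
#' scaling because normalization cancels the offset.
#'
#' @param fit an [rsf_nb()] fit.
#' @param grid data frame of grid cells carrying every covariate of the
#'   final model (and optionally centre coordinates).
#' @return \code{grid} with an \code{intensity} column appended.
#' @export
predict_grid <- function(fit, grid) {
  vars <- all.vars(stats::delete.response(stats::terms(fit$rsf$formula)))
  miss <- setdiff(vars, names(grid))
  if (length(miss))
    stop("grid lacks model covariates: ", paste(miss, collapse = ", "))
  bad <- !stats::complete.cases(grid[vars])
  if (any(bad))
    stop("missing covariate values in grid cells: ",
         paste(utils::head(which(bad), 10), collapse = ", "),
         if (sum(bad) > 10) " ...")
  grid$intensity <- predict(fit, grid, type = "intensity")
  grid
}

#' Classify grid intensities into equal-area decile classes
#'
#' Class 1 holds the lowest-intensity tenth of cells, class 10 the highest.
#' Cells sharing an intensity value always share a class (the lowest class
#' any of them would stably receive), so class sizes differ from equal
#' counts by at most the tie-group size.
#'
#' @param x intensity values.
#' @param n_classes number of equal-area classes (default 10).
#' @return integer class vector.
#' @export
classify_deciles <- function(x, n_classes = 10) {
  if (length(x) < n_classes)
    stop("need at least ", n_classes, " cells")
  cls <- rank_bins(x, n_classes)
  # tied values share the smallest class among them
  mn <- tapply(cls, x, min)
  cls <- as.integer(mn[match(as.character(x), names(mn))])
  if (length(unique(x)) == 1)
    warning("all intensities identical: a single class was assigned")
  cls
}

#' Scale the prediction map to a regional abundance total
#'
#' Distributes a study-area population total over grid cells in proportion
#' to relative intensity: cell expectations are
#' \eqn{T \cdot \lambda_i / \sum_k \lambda_k}, so the map sums to the total
#' and intensity ranks (hence decile classes) are preserved.  Optional
#' sub-region polygons are summarized by summing cells whose centre point
#' falls inside the polygon.
#'
#' @param grid data frame with an \code{intensity} column (see
#'   [predict_grid()]) and, if regions are given, centre coordinates
#'   \code{center_x}, \code{y}.
#' @param total population total for the whole mapped area (e.g. a
#'   survey-based abundance estimate such as 29,757 eagles).
#' @param regions optional named list of polygons (two-column x/y matrices).
#' @return list: \code{grid} with an \code{abundance} column, and
#'   \code{regions} (data frame of region sums) when polygons are given.
#' @export
scale_to_abundance <- function(grid, total, regions = NULL) {
  if (total <= 0) stop("total must be positive")
  if (!"intensity" %in% names(grid))
    stop("grid needs an 'intensity' column (run predict_grid first)")
  wt <- grid$intensity / sum(grid$intensity)
  grid$abundance <- total * wt
  out <- list(grid = grid, regions = NULL)
  if (!is.null(regions)) {
    stopifnot(all(c("center_x", "y") %in% names(grid)))
    pts <- cbind(grid$center_x, grid$y)
    sums <- vapply(regions, function(poly) {
      inside <- mgcv::in.out(as.matrix(poly), pts)
      if (!any(inside)) {
        warning("region polygon contains no grid-cell centres")
        return(0)
      }
      sum(grid$abundance[inside])
    }, numeric(1))
    out$regions <- data.frame(region = names(regions), abundance = sums,
                              row.names = NULL)
  }
  out
}

#' Build a unit-sized prediction grid over a landscape
#'
#' Tiles the landscape with unit-dimension cells and extracts covariates,
#' ready for [predict_grid()].
#'
#' @param land a [landscape()].
#' @param cell_length_km,cell_width_km cell dimensions (defaults 10 x 2, the
#'   sampling-unit size).
#' @return data frame of cells with \code{center_x}, \code{y}, \code{x0},
#'   \code{x1} and covariates.
#' @export
prediction_grid <- function(land, cell_length_km = 10, cell_width_km = 2) {
  xs <- seq(0, land$extent_km[1] - cell_length_km, by = cell_length_km)
  ys <- seq(cell_width_km / 2, land$extent_km[2] - cell_width_km / 2,
            by = cell_width_km)
  g <- expand.grid(x0 = xs, y = ys)
  g$x1 <- g$x0 + cell_length_km
  g$center_x <- g$x0 + cell_length_km / 2
  cbind(g, extract_covariates(g, land, width_km = cell_width_km,
                              geometry = FALSE))
}
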