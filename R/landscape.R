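#' Synthetic landscapes for survey simulation
#'
#' The simulator works on a planar, equal-area km grid (x east, y north).
#' Covariates are gridded fields: smooth Gaussian-correlated surfaces for
#' continuous variables (elevation, solar radiation, ...), logistic
#' transforms of smooth surfaces for land-cover proportions, distances to
#' randomly placed road lines, and fields derived from other fields (slope
#' and aspect from the elevation gradient, NDVI as a forest-linked proxy).
#'
#' @name landscape-module
NULL

# smooth Gaussian-correlated field on an ny x nx grid; white noise convolved
# with a separable Gaussian kernel (circular edges), standardized to mean 0 sd 1
gaussian_field <- function(nx, ny, range_km, cell_km) {
  z <- matrix(stats::rnorm(nx * ny), ny, nx)
  sigma <- max(range_km / cell_km / 2, 0.5)
  half <- max(1L, ceiling(3 * sigma))
  smooth1 <- function(m) {  # filter rows circularly
    n <- ncol(m)
    h <- min(half, n - 1L)  # kernel cannot exceed the grid
    k <- stats::dnorm(seq(-h, h), sd = sigma)
    k <- k / sum(k)
    t(apply(m, 1, function(v) {
      vv <- c(v[(n - h + 1):n], v, v[1:h])
      as.numeric(stats::filter(vv, k, sides = 2))[(h + 1):(h + n)]
    }))
  }
  z <- smooth1(z)
  z <- t(smooth1(t(z)))
  (z - mean(z)) / stats::sd(z)
}

#' Specify a synthetic covariate field
#'
#' @param type one of \code{"continuous"} (Gaussian field rescaled to a given
#'   mean/sd), \code{"proportion"} (logistic transform of a Gaussian field,
#'   targeting a given mean share), \code{"distance"} (km to the nearest of
#'   \code{n_lines} random axis-parallel road lines), or \code{"derived"}
#'   (function of previously generated fields).
#' @param mean,sd target mean and spread (continuous), or mean share
#'   (proportion).
#' @param range_km spatial correlation range of the underlying field.
#' @param spread logit-scale sd for proportion fields (controls patchiness).
#' @param n_lines number of road lines for distance fields.
#' @param fun for derived fields: \code{function(fields, landscape)} returning
#'   a matrix of the grid dimensions.
#' @return a covariate spec, to be passed to [landscape()].
#' @export
covariate_spec <- function(type = c("continuous", "proportion", "distance",
                                    "derived"),
                           mean = 0, sd = 1, range_km = 60, spread = 1.5,
                           n_lines = 5, fun = NULL) {
  type <- match.arg(type)
  if (type == "derived" && !is.function(fun))
    stop("derived covariate needs a 'fun'")
  structure(list(type = type, mean = mean, sd = sd, range_km = range_km,
                 spread = spread, n_lines = n_lines, fun = fun),
            class = "covariate_spec")
}

#' Default synthetic covariate set
#'
#' Synthetic analogues of the landscape covariates used in the worked
#' analysis: median elevation (m), solar radiation (Wh m^-2 day^-1), wind
#' speed class (1--7), land-cover proportions (forest, developed, grassland,
#' shrub), NDVI generated as a forest-linked proxy (so the two are strongly
#' correlated, as in real land-cover data), slope and ruggedness derived from
#' the elevation surface (again mutually correlated), and distances to
#' primary/secondary roads.
#'
#' @return named list of [covariate_spec()] objects.
#' @export
default_covariates <- function() {
  list(
    elevation = covariate_spec("continuous", mean = 1800, sd = 500,
                               range_km = 80),
    solar     = covariate_spec("continuous", mean = 4000, sd = 400,
                               range_km = 150),
    wind_class = covariate_spec("derived", fun = function(f, ls)
      1 + 6 * stats::plogis(1.2 * gaussian_field(ls$nx, ls$ny, 120,
                                                 ls$cell_km))),
    forest    = covariate_spec("proportion", mean = 0.25, range_km = 50,
                               spread = 2),
    developed = covariate_spec("proportion", mean = 0.03, range_km = 40,
                               spread = 1.5),
    grassland = covariate_spec("proportion", mean = 0.3, range_km = 60,
                               spread = 1.5),
    shrub     = covariate_spec("proportion", mean = 0.25, range_km = 60,
                               spread = 1.5),
    ndvi      = covariate_spec("derived", fun = function(f, ls)
      0.25 + 0.5 * f$forest +
        0.08 * gaussian_field(ls$nx, ls$ny, 50, ls$cell_km)),
    slope     = covariate_spec("derived", fun = function(f, ls)
      slope_field(f$elevation, ls$cell_km)),
    ruggedness = covariate_spec("derived", fun = function(f, ls) {
      s <- slope_field(f$elevation, ls$cell_km)
      r <- s / max(s) + 0.25 * abs(gaussian_field(ls$nx, ls$ny, 30,
                                                  ls$cell_km))
      pmin(r / max(r), 1)
    }),
    road1 = covariate_spec("distance", n_lines = 4),
    road2 = covariate_spec("distance", n_lines = 10)
  )
}

# slope (degrees) from central differences of an elevation grid
slope_field <- function(elev, cell_km) {
  ny <- nrow(elev); nx <- ncol(elev)
  dx <- (elev[, c(2:nx, nx)] - elev[, c(1, 1:(nx - 1))]) / (2 * cell_km * 1000)
  dy <- (elev[c(2:ny, ny), ] - elev[c(1, 1:(ny - 1)), ]) / (2 * cell_km * 1000)
  atan(sqrt(dx^2 + dy^2)) * 180 / pi
}

# aspect quadrant (N/S/E/W) of steepest descent; NA where flat
aspect_field <- function(elev, cell_km) {
  ny <- nrow(elev); nx <- ncol(elev)
  dx <- (elev[, c(2:nx, nx)] - elev[, c(1, 1:(nx - 1))]) / (2 * cell_km)
  dy <- (elev[c(2:ny, ny), ] - elev[c(1, 1:(ny - 1)), ]) / (2 * cell_km)
  out <- matrix(NA_character_, ny, nx)
  ew <- abs(dx) >= abs(dy)
  out[ew & dx < 0] <- "E"   # descends to the west -> faces east... keep simple
  out[ew & dx > 0] <- "W"
  out[!ew & dy > 0] <- "S"
  out[!ew & dy < 0] <- "N"
  out  # |grad| == 0 stays NA (flat)
}

#' Generate a synthetic landscape
#'
#' @param extent_km c(width, height) of the study rectangle in km.
#' @param cell_km covariate grid resolution in km.
#' @param covariates named list of [covariate_spec()]s;
#'   defaults to [default_covariates()].
#' @param seed integer RNG seed (optional; the caller may also set the seed).
#' @return an object of class \code{"landscape"}: grid-cell centre coordinates
#'   \code{$xc}, \code{$yc}, named field matrices \code{$fields} (rows index
#'   y, columns x), road line positions \code{$roads}, and the configuration.
#' @export
landscape <- function(extent_km = c(1000, 700), cell_km = 2,
                      covariates = default_covariates(), seed = NULL) {
  if (length(extent_km) != 2 || any(extent_km <= 0))
    stop("extent_km must be two positive lengths")
  if (cell_km <= 0) stop("cell_km must be positive")
  if (!is.null(seed)) set.seed(seed)
  nx <- max(2L, floor(extent_km[1] / cell_km))
  ny <- max(2L, floor(extent_km[2] / cell_km))
  xc <- (seq_len(nx) - 0.5) * cell_km
  yc <- (seq_len(ny) - 0.5) * cell_km
  ls <- list(extent_km = extent_km, cell_km = cell_km, nx = nx, ny = ny,
             xc = xc, yc = yc, fields = list(), roads = list(),
             specs = covariates)
  for (nm in names(covariates)) {
    sp <- covariates[[nm]]
    ls$fields[[nm]] <- switch(sp$type,
      continuous = sp$mean + sp$sd * gaussian_field(nx, ny, sp$range_km,
                                                    cell_km),
      proportion = stats::plogis(stats::qlogis(sp$mean) +
        sp$spread * gaussian_field(nx, ny, sp$range_km, cell_km)),
      distance = {
        # axis-parallel road lines: distance separates into x and y parts
        vert <- stats::runif(sp$n_lines, 0, extent_km[1])
        horiz <- stats::runif(max(1, sp$n_lines %/% 2), 0, extent_km[2])
        ls$roads[[nm]] <- list(x = vert, y = horiz)
        dv <- do.call(pmin, lapply(vert, function(v) abs(xc - v)))
        dh <- do.call(pmin, lapply(horiz, function(h) abs(yc - h)))
        pmin(matrix(dh, ny, nx), matrix(dv, ny, nx, byrow = TRUE))
      },
      derived = sp$fun(ls$fields, ls))
  }
  if ("elevation" %in% names(ls$fields))
    ls$fields$aspect <- aspect_field(ls$fields$elevation, cell_km)
  class(ls) <- "landscape"
  ls
}

#' @export
print.landscape <- function(x, ...) {
  cat("Synthetic landscape:", x$extent_km[1], "x", x$extent_km[2],
      "km,", x$cell_km, "km cells\n")
  cat("Covariate fields:", paste(names(x$fields), collapse = ", "), "\n")
  invisible(x)
}
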