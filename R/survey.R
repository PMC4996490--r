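#' Aerial survey design parameters
#'
#' @param transect_length_km nominal transect length (east-west).
#' @param spacing_km spacing between transect rows (north-south) and gap
#'   between successive transects along a row (east-west).
#' @param n_years number of survey years.
#' @param miss_probability per transect-year probability that the transect is
#'   not flown (weather, fires); the default 0.04 gives a mean effort of
#'   about 4.8 of 5 years.
#' @param unit_length_km,unit_width_km sampling-unit dimensions; the width
#'   reflects the 1,000 m searched on each side of the line.
#' @param agl_forest_threshold units whose forest proportion exceeds this are
#'   flown at 150 m above ground level (forested/rugged terrain), others at
#'   107 m.
#' @return a \code{"survey_design"} list.
#' @export
survey_design <- function(transect_length_km = 100, spacing_km = 60,
                          n_years = 5, miss_probability = 0.04,
                          unit_length_km = 10, unit_width_km = 2,
                          agl_forest_threshold = 0.4) {
  stopifnot(transect_length_km > 0, spacing_km > 0,
            miss_probability >= 0, miss_probability < 1,
            n_years >= 1, unit_length_km > 0, unit_width_km > 0)
  structure(list(transect_length_km = transect_length_km,
                 spacing_km = spacing_km, n_years = n_years,
                 miss_probability = miss_probability,
                 unit_length_km = unit_length_km,
                 unit_width_km = unit_width_km,
                 agl_forest_threshold = agl_forest_threshold),
            class = "survey_design")
}

#' True generating model for synthetic eagle counts
#'
#' Defines the latent intensity surface used by [simulate_eagles()]: per
#' unit-year group counts are NB2 with mean \eqn{\exp(X\beta)} and dispersion
#' \eqn{\theta}.  Coefficient magnitudes of the default are of the order seen
#' in late-summer golden eagle surveys once covariates are standardized
#' (slopes roughly 0.3--0.9 in absolute value, strong negative forest and
#' developed effects, a concave elevation response), with an intercept giving
#' about 0.6 detection-adjusted eagles per unit over five survey years.
#'
#' @param formula one-sided formula in the landscape covariate names (the
#'   simulator standardizes nothing: write transforms explicitly, e.g.
#'   \code{~ elevation_s + I(elevation_s^2) + forest}).
#' @param beta named coefficients; names must match
#'   \code{colnames(model.matrix(formula, ...))}, including
#'   \code{"(Intercept)"}.
#' @param theta NB2 dispersion (> 0); variance is
#'   \eqn{\mu + \mu^2/\theta}.
#' @param group_size_probs probabilities over group sizes 1, 2, ... .
#' @param p_flying probability a latent group is flying (vs perched) when the
#'   aircraft passes.
#' @return a \code{"true_model"} list.
#' @export
true_model <- function(formula = ~ elevation_s + I(elevation_s^2) + solar_s +
                         I(solar_s^2) + forest + developed + wind_class_s,
                       beta = c("(Intercept)" = -2.2,
                                elevation_s = 0.9, "I(elevation_s^2)" = -0.35,
                                solar_s = 0.45, "I(solar_s^2)" = -0.3,
                                forest = -0.55, developed = -0.3,
                                wind_class_s = 0.27),
                       theta = 1.5,
                       group_size_probs = c(`1` = 0.8, `2` = 0.15, `3` = 0.05),
                       p_flying = 0.25) {
  stopifnot(theta > 0, all(group_size_probs >= 0),
            p_flying >= 0, p_flying <= 1)
  if (is.null(names(beta)) || !"(Intercept)" %in% names(beta))
    stop("beta must be named and include '(Intercept)'")
  group_size_probs <- group_size_probs / sum(group_size_probs)
  structure(list(formula = formula, beta = beta, theta = theta,
                 group_size_probs = group_size_probs, p_flying = p_flying),
            class = "true_model")
}

#' Lay out systematic east-west transects with a random start
#'
#' Transect rows run east-west every \code{spacing_km} northwards from a
#' uniform random offset; along each row, transects of the configured length
#' are separated by gaps of \code{spacing_km}, again from a random offset.
#' Transects are truncated at the study-area boundary.
#'
#' @param extent_km c(width, height) in km, or a [landscape()] object.
#' @param design a [survey_design()].
#' @param seed optional integer seed.
#' @return data frame with columns \code{transect_id}, \code{x0}, \code{x1},
#'   \code{y}, \code{length_km}.
#' @export
generate_transects <- function(extent_km, design = survey_design(),
                               seed = NULL) {
  if (inherits(extent_km, "landscape")) extent_km <- extent_km$extent_km
  if (!is.null(seed)) set.seed(seed)
  if (extent_km[1] <= design$spacing_km)
    stop("extent narrower than one spacing east-west")
  if (extent_km[2] <= design$spacing_km)
    stop("extent narrower than one spacing north-south")
  period <- design$transect_length_km + design$spacing_km
  y0 <- stats::runif(1, 0, design$spacing_km)
  x_off <- stats::runif(1, 0, period)
  ys <- seq(y0, extent_km[2], by = design$spacing_km)
  starts <- seq(x_off - period, extent_km[1], by = period)
  out <- do.call(rbind, lapply(ys, function(y) {
    x0 <- pmax(starts, 0)
    x1 <- pmin(starts + design$transect_length_km, extent_km[1])
    keep <- x1 > x0
    data.frame(x0 = x0[keep], x1 = x1[keep], y = y)
  }))
  out <- out[order(out$y, out$x0), , drop = FALSE]
  out$transect_id <- seq_len(nrow(out))
  out$length_km <- out$x1 - out$x0
  rownames(out) <- NULL
  out[, c("transect_id", "x0", "x1", "y", "length_km")]
}

# fixed 10-km segmentation of transects used as simulation cells
transect_segments <- function(transects, design) {
  len <- design$unit_length_km
  segs <- do.call(rbind, lapply(seq_len(nrow(transects)), function(i) {
    tr <- transects[i, ]
    n <- floor(tr$length_km / len)
    if (n < 1) return(NULL)
    s0 <- tr$x0 + (seq_len(n) - 1) * len
    data.frame(transect_id = tr$transect_id, x0 = s0, x1 = s0 + len,
               y = tr$y)
  }))
  segs$center_x <- (segs$x0 + segs$x1) / 2
  segs$unit_id <- seq_len(nrow(segs))
  segs
}

# per transect-year flown indicator
flown_log <- function(transects, design, n_years = design$n_years) {
  g <- expand.grid(transect_id = transects$transect_id,
                   year = seq_len(n_years))
  g$flown <- stats::runif(nrow(g)) >= design$miss_probability
  g
}

#' Simulate latent eagle groups and their detection along transects
#'
#' For every 10-km transect segment and flown year, draws a latent NB2 group
#' count with mean \eqn{\exp(X\beta)} from the [true_model()], places groups
#' uniformly along the segment, assigns group size, flying/perched state,
#' aircraft side (equiprobable) and the segment's above-ground-level stratum,
#' then detects each group independently with its stratum probability.
#'
#' @param transects from [generate_transects()].
#' @param land a [landscape()].
#' @param truth a [true_model()].
#' @param design a [survey_design()].
#' @param detection a [detection_table()] supplying the detection
#'   probabilities.
#' @param seed optional integer seed.
#' @return list with \code{observations} (detected groups: transect_id,
#'   position_km (absolute x), y, year, group_size, obs_type, side,
#'   position), \code{groups} (all latent groups incl. a \code{detected}
#'   flag), \code{truth} (latent group/individual totals per segment-year),
#'   \code{segments} (with covariates), and \code{flown} (transect-year log).
#' @export
simulate_eagles <- function(transects, land, truth = true_model(),
                            design = survey_design(),
                            detection = default_detection(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  segs <- transect_segments(transects, design)
  segcov <- extract_covariates(segs, land,
                               width_km = design$unit_width_km)
  X <- stats::model.matrix(truth$formula, data = segcov)
  miss <- setdiff(colnames(X), names(truth$beta))
  if (length(miss))
    stop("true_model beta lacks coefficients for: ",
         paste(miss, collapse = ", "))
  mu1 <- exp(drop(X %*% truth$beta[colnames(X)]))  # per-year mean
  fl <- flown_log(transects, design)
  uy <- merge(segs, fl[fl$flown, c("transect_id", "year")],
              by = "transect_id")
  uy$mu <- mu1[match(uy$unit_id, segs$unit_id)]
  n_lat <- stats::rnbinom(nrow(uy), mu = uy$mu, size = truth$theta)
  idx <- rep(seq_len(nrow(uy)), n_lat)
  gs_support <- as.integer(names(truth$group_size_probs))
  ng <- length(idx)
  groups <- data.frame(
    transect_id = uy$transect_id[idx],
    unit_id = uy$unit_id[idx],
    year = uy$year[idx],
    position_km = uy$x0[idx] + stats::runif(ng, 0, design$unit_length_km),
    y = uy$y[idx],
    group_size = if (ng) sample(gs_support, ng, replace = TRUE,
                                prob = truth$group_size_probs) else integer(0),
    stringsAsFactors = FALSE)
  agl150 <- segcov$forest[match(groups$unit_id, segcov$unit_id)] >
    design$agl_forest_threshold
  flying <- stats::runif(ng) < truth$p_flying
  groups$obs_type <- ifelse(flying, "flying",
                            ifelse(agl150, "perched150", "perched107"))
  groups$side <- sample(c("left", "right"), ng, replace = TRUE)
  groups$position <- obs_position(groups$side)
  p <- detection_lookup(groups$obs_type, groups$position, detection)
  groups$detected <- stats::runif(ng) < p
  # per segment-year latent totals (including zero rows)
  gagg <- if (ng) stats::aggregate(
    cbind(latent_groups = 1L, latent_individuals = groups$group_size,
          detected_groups = as.integer(groups$detected)) ~ unit_id + year,
    data = groups, FUN = sum) else
    data.frame(unit_id = integer(0), year = integer(0),
               latent_groups = integer(0), latent_individuals = integer(0),
               detected_groups = integer(0))
  truth_tab <- merge(uy[, c("unit_id", "year", "transect_id", "mu")], gagg,
                     by = c("unit_id", "year"), all.x = TRUE)
  for (cc in c("latent_groups", "latent_individuals", "detected_groups"))
    truth_tab[[cc]][is.na(truth_tab[[cc]])] <- 0L
  obs <- groups[groups$detected,
                c("transect_id", "position_km", "y", "year", "group_size",
                  "obs_type", "side", "position")]
  rownames(obs) <- NULL
  list(observations = obs, groups = groups, truth = truth_tab,
       segments = segcov, flown = fl)
}

#' Simulate a complete synthetic survey
#'
#' Convenience orchestrator: lays out transects, simulates eagles and
#' detection, draws sampling units along transects, assigns effort and
#' observations, extracts unit covariates, and accumulates pseudocounts.
#' The result is ready for [rsf_nb()].
#'
#' @param land a [landscape()].
#' @param truth a [true_model()].
#' @param design a [survey_design()].
#' @param detection a [detection_table()].
#' @param n_points number of random points drawn along transects.
#' @param min_years effort floor below which units are excluded.
#' @param seed optional integer seed governing the whole simulation.
#' @return object of class \code{"eagle_survey"}: \code{$units} (modeling
#'   table: unit geometry, effort, covariates, raw_sum, pseudocount),
#'   \code{$observations}, \code{$unit_obs} (observations replicated per
#'   containing unit), \code{$groups}, \code{$truth}, \code{$transects},
#'   \code{$flown}, \code{$detection}, \code{$design}.
#' @export
simulate_survey <- function(land, truth = true_model(),
                            design = survey_design(),
                            detection = default_detection(),
                            n_points = 2000, min_years = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- generate_transects(land, design)
  sim <- simulate_eagles(tr, land, truth, design, detection)
  un <- sample_units(tr, n_points, unit_length_km = design$unit_length_km,
                     unit_width_km = design$unit_width_km)
  un <- assign_effort(un, sim$flown, min_years = min_years)
  un <- cbind(un, extract_covariates(un, land,
                                     width_km = design$unit_width_km,
                                     geometry = FALSE))
  uo <- assign_observations(sim$observations, un)
  un <- accumulate_units(uo, detection, un)
  structure(list(units = un, observations = sim$observations, unit_obs = uo,
                 groups = sim$groups, truth = sim$truth, transects = tr,
                 flown = sim$flown, detection = detection, design = design,
                 true_model = truth),
            class = "eagle_survey")
}

#' @export
print.eagle_survey <- function(x, ...) {
  cat("Synthetic aerial survey\n")
  cat("  transects:", nrow(x$transects), "totalling",
      round(sum(x$transects$length_km)), "km\n")
  cat("  sampling units:", nrow(x$units),
      sprintf("(mean effort %.2f years)", mean(x$units$n_years)), "\n")
  cat("  detected groups:", nrow(x$observations),
      " latent groups:", nrow(x$groups), "\n")
  cat("  total pseudocount:", sum(x$units$pseudocount), "\n")
  invisible(x)
}
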