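# equal-count decile assignment, ties broken stably by input order
rank_bins <- function(pred, bins = 10) {
  n <- length(pred)
  sizes <- diff(floor(seq(0, n, length.out = bins + 1)))
  bin_sorted <- rep(seq_len(bins), sizes)
  out <- integer(n)
  out[order(pred, seq_len(n))] <- bin_sorted
  out
}

#' Utilization by prediction bin
#'
#' Ranks units into \code{bins} equal-count bins of predicted relative
#' intensity (bin 10 holds the top decile), takes the median prediction
#' \eqn{w(x_i)} per bin, and converts to utilizations
#' \deqn{U(x_i) = w(x_i) / \sum_k w(x_k),}
#' each bin's share of total predicted use.  \eqn{\sum_i U(x_i) = 1} by
#' construction, and \eqn{U} is invariant to positive rescaling of the
#' predictions.
#'
#' @param pred predicted relative intensities, one per unit.
#' @param bins number of equal-area bins (default 10).
#' @return list with \code{bin} (per-unit bin index), and a \code{table}
#'   data frame (bin, n, w, U).
#' @export
bin_utilization <- function(pred, bins = 10) {
  if (length(pred) < bins)
    stop("need at least ", bins, " units with finite predictions")
  if (any(!is.finite(pred))) stop("predictions must be finite")
  b <- rank_bins(pred, bins)
  w <- as.numeric(tapply(pred, b, stats::median))
  tab <- data.frame(bin = seq_len(bins),
                    n = as.integer(table(b)),
                    w = w,
                    U = w / sum(w))
  list(bin = b, table = tab)
}

#' Expected detection-adjusted counts per bin and year
#'
#' \eqn{N_{ij} = N_{\cdot j} U(x_i)}: the adjusted total for year \eqn{j}
#' spread over bins in proportion to their utilization.  Column sums equal
#' the year totals exactly.
#'
#' @param U utilization vector (sums to 1).
#' @param totals named vector of adjusted year totals \eqn{N_{\cdot j}}.
#' @return bins x years matrix.
#' @export
expected_counts <- function(U, totals) {
  if (abs(sum(U) - 1) > 1e-8) stop("U must sum to 1")
  if (any(totals < 0)) stop("year totals must be non-negative")
  outer(U, totals)
}

#' Observed-vs-expected validation regression
#'
#' Pools bins across years and regresses observed on expected values by
#' ordinary least squares.  Predictions are proportional to realized density
#' when the intercept CI contains 0 and the slope CI contains 1 (default 90\%
#' intervals).  Spearman rank correlations are computed per year.
#'
#' @param expected,observed bins x years matrices (or vectors for one year).
#' @param level confidence level for the interval criteria.
#' @return list: \code{intercept}, \code{slope}, \code{ci_intercept},
#'   \code{ci_slope}, \code{pass_intercept}, \code{pass_slope}, \code{pass},
#'   \code{spearman} (per year), \code{model} (the \code{lm}).
#' @export
validate_regression <- function(expected, observed, level = 0.90) {
  expected <- as.matrix(expected)
  observed <- as.matrix(observed)
  stopifnot(all(dim(expected) == dim(observed)))
  if (stats::sd(expected) == 0)
    stop("expected values have zero variance")
  m <- stats::lm(as.vector(observed) ~ as.vector(expected))
  ci <- stats::confint(m, level = level)
  rs <- vapply(seq_len(ncol(expected)), function(j)
    stats::cor(expected[, j], observed[, j], method = "spearman"),
    numeric(1))
  names(rs) <- colnames(expected)
  est <- stats::coef(m)
  list(intercept = unname(est[1]), slope = unname(est[2]),
       ci_intercept = unname(ci[1, ]), ci_slope = unname(ci[2, ]),
       pass_intercept = ci[1, 1] <= 0 && 0 <= ci[1, 2],
       pass_slope = ci[2, 1] <= 1 && 1 <= ci[2, 2],
       pass = (ci[1, 1] <= 0 && 0 <= ci[1, 2]) &&
         (ci[2, 1] <= 1 && 1 <= ci[2, 2]),
       spearman = rs, model = m)
}

#' Utilization-bin validation against held-out survey years
#'
#' The six-step procedure: (1) predict relative intensity for every sampling
#' unit and rank units into 10 equal-area bins; (2) take the median
#' prediction per bin; (3) convert to utilizations; (4) sum
#' detection-adjusted (inflated, unrounded) observed counts per bin for each
#' held-out year; (5) compute expected adjusted counts per bin and year from
#' the utilizations and year totals; (6) compare observed to expected with
#' pooled linear regression and per-year Spearman rank correlation.
#'
#' By default both axes are proportions of the year totals (expected
#' proportion = utilization), which makes pooling across years scale-free;
#' \code{mode = "count"} regresses the raw adjusted counts instead.
#'
#' @param fit an [rsf_nb()] fit.
#' @param units unit table with covariates (defaults to the fitting units).
#' @param val_obs held-out observations assigned to units
#'   ([assign_observations()]): \code{unit_id}, \code{year},
#'   \code{group_size}, \code{obs_type}, \code{position} or \code{side}.
#' @param detection a [detection_table()].
#' @param mode \code{"proportion"} or \code{"count"}.
#' @param level CI level for the regression criteria.
#' @return object of class \code{"rsf_validation"}: bin \code{table},
#'   \code{observed} and \code{expected} matrices, \code{totals},
#'   \code{regression} (see [validate_regression()]), \code{spearman}.
#' @export
validate_rsf <- function(fit, units = fit$rsf$data, val_obs, detection,
                         mode = c("proportion", "count"), level = 0.90) {
  mode <- match.arg(mode)
  pred <- predict(fit, units, type = "intensity")
  bu <- bin_utilization(pred)
  years <- sort(unique(val_obs$year))
  if (!length(years)) stop("no validation observations")
  obs <- matrix(0, 10, length(years),
                dimnames = list(NULL, as.character(years)))
  infl <- inflate_observation(val_obs, detection)
  ubin <- bu$bin[match(val_obs$unit_id, units$unit_id)]
  if (anyNA(ubin)) stop("validation observations reference unknown units")
  for (k in seq_along(years)) {
    sel <- val_obs$year == years[k]
    s <- tapply(infl[sel], ubin[sel], sum)
    obs[as.integer(names(s)), k] <- as.numeric(s)
  }
  totals <- colSums(obs)
  expd <- expected_counts(bu$table$U, totals)
  if (mode == "proportion") {
    ok <- totals > 0
    reg <- validate_regression(sweep(expd[, ok, drop = FALSE], 2,
                                     totals[ok], "/"),
                               sweep(obs[, ok, drop = FALSE], 2,
                                     totals[ok], "/"), level)
  } else {
    reg <- validate_regression(expd, obs, level)
  }
  structure(list(table = bu$table, bin = bu$bin, observed = obs,
                 expected = expd, totals = totals, regression = reg,
                 spearman = reg$spearman, mode = mode),
            class = "rsf_validation")
}

#' @export
print.rsf_validation <- function(x, ...) {
  r <- x$regression
  cat("Utilization-bin validation (", x$mode, " mode)\n", sep = "")
  cat(sprintf("  slope %.3f [%.3f, %.3f]%s\n", r$slope, r$ci_slope[1],
              r$ci_slope[2], if (r$pass_slope) "  contains 1" else ""))
  cat(sprintf("  intercept %.3f [%.3f, %.3f]%s\n", r$intercept,
              r$ci_intercept[1], r$ci_intercept[2],
              if (r$pass_intercept) "  contains 0" else ""))
  cat("  Spearman r_s by year:",
      paste(sprintf("%s: %.2f", names(x$spearman), x$spearman),
            collapse = ", "), "\n")
  invisible(x)
}
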