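# one truncated-normal draw per detection stratum, support (lo, 1]
draw_detection <- function(detection, lo = 0.01, max_tries = 1000) {
  p <- detection$p_bar
  se <- detection$se
  out <- stats::rnorm(length(p), p, se)
  bad <- out <= lo | out > 1
  tries <- 0
  while (any(bad) && tries < max_tries) {
    out[bad] <- stats::rnorm(sum(bad), p[bad], se[bad])
    bad <- out <= lo | out > 1
    tries <- tries + 1
  }
  out[bad] <- pmin(pmax(p[bad], lo + 1e-6), 1)  # se = 0 or pathological
  out
}

# units x strata matrix of summed group sizes (for fast pseudocount rebuild)
stratum_matrix <- function(unit_obs, detection, units) {
  key <- paste(detection$obs_type, detection$position)
  m <- matrix(0, nrow(units), nrow(detection),
              dimnames = list(NULL, key))
  if (NROW(unit_obs)) {
    pos <- if ("position" %in% names(unit_obs)) unit_obs$position else
      obs_position(unit_obs$side)
    i <- match(unit_obs$unit_id, units$unit_id)
    j <- match(paste(unit_obs$obs_type, pos), key)
    if (anyNA(i) || anyNA(j))
      stop("observations reference unknown units or strata")
    for (k in seq_len(nrow(unit_obs)))
      m[i[k], j[k]] <- m[i[k], j[k]] + unit_obs$group_size[k]
  }
  m
}

#' Transect bootstrap confidence intervals for RSF coefficients
#'
#' Each iteration (i) resamples whole transects with replacement (keeping the
#' original number of transects) and takes every sampling unit on the drawn
#' transects, duplicating units of transects drawn more than once; (ii) draws
#' one detection probability per stratum from
#' \eqn{N(\bar{P}_t, SE(\bar{P}_t))} truncated to (0.01, 1], representing
#' uncertainty in the stratum means; (iii) recomputes detection-adjusted
#' pseudocounts; and (iv) refits the fixed final model structure (no
#' reselection).  The central 90\% of the converged draws gives each
#' coefficient's percentile confidence interval.
#'
#' @param fit the final-model [rsf_nb()] fit (its formula, effort column and
#'   unit table are reused).
#' @param unit_obs observations assigned to units
#'   ([assign_observations()] output: \code{unit_id}, \code{group_size},
#'   \code{obs_type}, \code{position} or \code{side}).
#' @param detection a [detection_table()] with standard errors.
#' @param n_iter bootstrap iterations (the analysis this mirrors used 1,000).
#' @param level central interval coverage (default 0.90).
#' @param p_floor lower truncation of detection draws.
#' @param seed optional seed.
#' @param max_fail_frac error if more than this fraction of iterations fails
#'   to converge.
#' @return object of class \code{"rsf_boot"}: \code{$draws} (iterations x
#'   coefficients, converged only), \code{$ci} (2 x p percentile bounds),
#'   \code{$point}, \code{$n_iter}, \code{$failures}.
#' @export
bootstrap_rsf <- function(fit, unit_obs, detection, n_iter = 1000,
                          level = 0.90, p_floor = 0.01, seed = NULL,
                          max_fail_frac = 0.2) {
  stopifnot(inherits(fit, "rsf_nb"))
  if (!is.null(seed)) set.seed(seed)
  units <- fit$rsf$data
  if (!"transect_id" %in% names(units))
    stop("unit table needs a transect_id column for transect resampling")
  resp <- fit$rsf$response
  m <- stratum_matrix(unit_obs, detection, units)
  tids <- unique(units$transect_id)
  by_tr <- split(seq_len(nrow(units)), units$transect_id)
  rhs <- attr(stats::terms(fit$rsf$formula), "term.labels")
  f <- if (length(rhs)) stats::reformulate(rhs, resp) else
    stats::as.formula(paste(resp, "~ 1"))
  draws <- matrix(NA_real_, n_iter, length(stats::coef(fit)),
                  dimnames = list(NULL, names(stats::coef(fit))))
  failures <- 0L
  for (it in seq_len(n_iter)) {
    pick <- sample(as.character(tids), length(tids), replace = TRUE)
    rows <- unlist(by_tr[pick], use.names = FALSE)
    p <- draw_detection(detection, lo = p_floor)
    raw <- drop(m[rows, , drop = FALSE] %*% (1 / p))
    d <- units[rows, , drop = FALSE]
    d[[resp]] <- as.integer(round_half_up(raw))
    res <- tryCatch(
      rsf_nb(f, d, effort = fit$rsf$effort,
             init.theta = fit$theta, start = stats::coef(fit)),
      error = function(e) NULL)
    if (is.null(res)) failures <- failures + 1L else
      draws[it, ] <- stats::coef(res)
  }
  if (failures > max_fail_frac * n_iter)
    stop(failures, " of ", n_iter, " bootstrap iterations failed")
  draws <- draws[stats::complete.cases(draws), , drop = FALSE]
  alpha <- (1 - level) / 2
  ci <- apply(draws, 2, stats::quantile, probs = c(alpha, 1 - alpha))
  structure(list(draws = draws, ci = ci, point = stats::coef(fit),
                 level = level, n_iter = n_iter, failures = failures),
            class = "rsf_boot")
}

#' @export
print.rsf_boot <- function(x, ...) {
  cat("Transect bootstrap:", nrow(x$draws), "converged of", x$n_iter,
      "iterations\n")
  out <- cbind(estimate = x$point, t(x$ci))
  print(out)
  invisible(x)
}

#' Marginal intensity curve for one covariate
#'
#' Relative intensity \eqn{\exp(X\hat\beta)} along a grid of one covariate,
#' all other covariates held at their medians (factors at their modal
#' level), scaled so the maximum is 1.0.
#'
#' @param fit an [rsf_nb()] fit.
#' @param name covariate to vary (must appear in the model).
#' @param grid values to evaluate at; default 50 points spanning the
#'   observed range.
#' @param data covariate table for medians; defaults to the fitting data.
#' @return data frame with columns \code{name} and \code{intensity}
#'   (max 1.0).
#' @export
marginal_curve <- function(fit, name, grid = NULL, data = fit$rsf$data) {
  vars <- all.vars(stats::delete.response(stats::terms(fit$rsf$formula)))
  if (!name %in% vars)
    stop("'", name, "' is not a covariate of the fitted model")
  if (is.null(grid))
    grid <- seq(min(data[[name]]), max(data[[name]]), length.out = 50)
  nd <- as.data.frame(lapply(data[vars], function(v) {
    if (is.numeric(v)) stats::median(v) else
      factor(names(which.max(table(v))), levels = levels(v))
  }))
  nd <- nd[rep(1, length(grid)), , drop = FALSE]
  nd[[name]] <- grid
  intensity <- predict(fit, nd, type = "intensity")
  out <- data.frame(grid, intensity / max(intensity))
  names(out) <- c(name, "intensity")
  out
}

#' Turning point of a quadratic covariate response
#'
#' For a response \eqn{\beta_1 x + \beta_2 x^2} the vertex is at
#' \eqn{-\beta_1 / (2\beta_2)}: a maximum when \eqn{\beta_2 < 0} (intensity
#' rises to the vertex then falls), a minimum otherwise.
#'
#' @param beta_linear,beta_quadratic coefficients, or a single [rsf_nb()]
#'   fit plus the covariate \code{name}.
#' @param name covariate name when a fit is supplied.
#' @return list with \code{vertex} and \code{type}
#'   (\code{"maximum"}/\code{"minimum"}).
#' @export
quadratic_vertex <- function(beta_linear, beta_quadratic = NULL,
                             name = NULL) {
  if (inherits(beta_linear, "rsf_nb")) {
    if (is.null(name)) stop("supply the covariate name")
    cf <- stats::coef(beta_linear)
    qn <- paste0("I(", name, "^2)")
    if (!all(c(name, qn) %in% names(cf)))
      stop("fit has no linear+quadratic pair for '", name, "'")
    beta_quadratic <- cf[[qn]]
    beta_linear <- cf[[name]]
  }
  if (is.null(beta_quadratic) || beta_quadratic == 0)
    stop("quadratic coefficient is zero: no vertex")
  list(vertex = -beta_linear / (2 * beta_quadratic),
       type = if (beta_quadratic < 0) "maximum" else "minimum")
}
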