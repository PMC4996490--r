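#' Fit an effort-offset negative binomial resource selection function
#'
#' Models rounded, detection-adjusted pseudocounts \eqn{y_i} on sampling
#' units with a log-link NB2 regression
#' \deqn{\ln E[y_i] = \ln(\mathrm{years}_i) + \beta_0 + \beta_1 x_{1i} +
#'   \dots + \beta_p x_{pi},}
#' where the fixed offset \eqn{\ln(\mathrm{years}_i)} scales the response by
#' survey effort, and the NB2 variance is \eqn{\mu + \mu^2/\theta}.
#' Estimation is maximum likelihood via [MASS::glm.nb()] with alternating
#' \eqn{\theta} updates (log-likelihood convergence 1e-8).  Because the
#' effort enters as an offset, coefficients are per-year intensities;
#' predictions at \code{type = "intensity"} use offset zero and are relative
#' intensities of use.
#'
#' @param formula model formula in covariate terms, e.g.
#'   \code{pseudocount ~ elevation_s + I(elevation_s^2) + forest}.  Do not
#'   include the offset; it is added from \code{effort}.
#' @param data modeling table (one row per sampling unit) containing the
#'   response, covariates and the effort column.
#' @param effort name of the effort (years surveyed) column, entered as
#'   \code{offset(log(effort))}.
#' @param ... passed to [MASS::glm.nb()] (e.g. \code{init.theta},
#'   \code{start}).
#' @return object of class \code{"rsf_nb"} extending \code{"negbin"}; usual
#'   methods (\code{coef}, \code{summary}, \code{residuals}, \code{predict},
#'   \code{simulate}, \code{plot}) apply.  Extra fields: \code{$bic} (with
#'   \eqn{\theta} counted as a parameter and n = number of modelled units)
#'   and \code{$rsf} (bookkeeping used by [backwards_bic()] and
#'   [bootstrap_rsf()]).
#' @examples
#' land <- landscape(c(400, 300), seed = 1)
#' sv <- simulate_survey(land, n_points = 400, seed = 2)
#' fit <- rsf_nb(pseudocount ~ elevation_s + forest, sv$units)
#' coef(fit)
#' @export
rsf_nb <- function(formula, data, effort = "n_years", ...) {
  if (!effort %in% names(data))
    stop("effort column '", effort, "' not found in data")
  resp <- all.vars(formula[[2]])
  y <- data[[resp]]
  if (is.null(y)) stop("response '", resp, "' not found in data")
  if (any(y < 0) || any(y != floor(y)))
    stop("pseudocounts must be non-negative integers")
  if (all(y == 0))
    stop("all-zero response: no eagles to model (a Poisson/NB fit is ",
         "degenerate; check detection assignment and effort)")
  if (any(!is.finite(log(data[[effort]]))))
    stop("effort must be positive and finite")
  full <- stats::update(formula,
    stats::as.formula(paste0(". ~ . + offset(log(", effort, "))")))
  environment(full) <- environment()
  fit <- tryCatch(
    withCallingHandlers(
      MASS::glm.nb(full, data = data,
                   control = stats::glm.control(epsilon = 1e-8, maxit = 50),
                   ...),
      warning = function(w) {
        if (grepl("iteration limit reached", conditionMessage(w)))
          invokeRestart("muffleWarning")
      }),
    error = function(e) {
      # theta estimation diverges when the data are equi- or underdispersed;
      # the NB2 likelihood is then maximized at the Poisson boundary
      dots <- list(...)
      pf <- do.call(stats::glm,
                    c(list(full, family = MASS::negative.binomial(1e8),
                           data = data),
                      dots[names(dots) %in% "start"]))
      pf$theta <- Inf
      pf$boundary_theta <- TRUE
      pf
    })
  p1 <- length(stats::coef(fit))
  if (nrow(data) <= p1 + 1)
    stop("need more units than parameters (n = ", nrow(data),
         ", parameters incl. dispersion = ", p1 + 1, ")")
  if (!fit$converged)
    stop("NB fit did not converge (", fit$iter, " IWLS iterations); ",
         "final deviance ", format(fit$deviance))
  # convention: theta counts as an estimated parameter in BIC, always
  fit$bic <- bic_value(as.numeric(stats::logLik(fit)), p1 + 1, nrow(data))
  fit$rsf <- list(formula = formula, effort = effort, data = data,
                  response = resp)
  class(fit) <- c("rsf_nb", class(fit))
  fit
}

#' @export
print.rsf_nb <- function(x, ...) {
  cat("Negative binomial RSF (offset: log(", x$rsf$effort, "))\n", sep = "")
  cat("Formula:", deparse(x$rsf$formula), "\n")
  cat("Units:", nrow(x$rsf$data), "  theta:", format(x$theta, digits = 4),
      "  logLik:", format(as.numeric(stats::logLik(x)), digits = 6),
      "  BIC:", format(x$bic, digits = 6), "\n")
  cat("Coefficients:\n")
  print(stats::coef(x))
  invisible(x)
}

#' @export
summary.rsf_nb <- function(object, ...) {
  s <- NextMethod()
  s$bic <- object$bic
  s
}

#' Predict from an RSF fit
#'
#' @param object an [rsf_nb()] fit.
#' @param newdata optional data frame of covariates.  For
#'   \code{type = "intensity"} the effort column may be absent: the offset is
#'   set to zero (one survey-year scale), giving relative intensity of use
#'   \eqn{\exp(X\hat\beta)}.
#' @param type \code{"intensity"} (offset-free relative intensity, the scale
#'   used for mapping and validation), \code{"response"} (expected
#'   pseudocount at the data's effort) or \code{"link"}.
#' @param ... passed on.
#' @export
predict.rsf_nb <- function(object, newdata = NULL,
                           type = c("intensity", "response", "link"), ...) {
  type <- match.arg(type)
  if (type == "intensity") {
    if (is.null(newdata)) newdata <- object$rsf$data
    newdata[[object$rsf$effort]] <- 1   # offset log(1) = 0
    cls <- class(object)
    class(object) <- setdiff(cls, "rsf_nb")
    return(as.numeric(exp(stats::predict(object, newdata = newdata,
                                         type = "link"))))
  }
  NextMethod(type = type)
}

#' Simulate pseudocounts from a fitted RSF
#'
#' Draws NB2 responses at the fitted (or newly predicted) means with the
#' estimated dispersion; used for parametric checks and validation closure
#' experiments.
#'
#' @param object an [rsf_nb()] fit.
#' @param nsim number of replicate response vectors.
#' @param seed optional seed.
#' @param newdata optional covariate table (must include the effort column,
#'   or effort 1 is assumed).
#' @param ... unused.
#' @export
simulate.rsf_nb <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                            ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- if (is.null(newdata)) stats::fitted(object) else {
    if (!object$rsf$effort %in% names(newdata))
      newdata[[object$rsf$effort]] <- 1
    eff <- newdata[[object$rsf$effort]]
    predict(object, newdata, type = "intensity") * eff
  }
  draw <- if (is.finite(object$theta))
    function() stats::rnbinom(length(mu), mu = mu, size = object$theta)
  else function() stats::rpois(length(mu), mu)  # theta at Poisson boundary
  out <- as.data.frame(replicate(nsim, draw()))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.rsf_nb <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  r <- stats::residuals(x, type = "deviance")
  graphics::plot(log1p(stats::fitted(x)), r,
                 xlab = "log(1 + fitted)", ylab = "Deviance residual",
                 main = "Residuals vs fitted", ...)
  graphics::abline(h = 0, lty = 2)
  stats::qqnorm(r, main = "Deviance residual Q-Q")
  stats::qqline(r)
  invisible(x)
}

#' BIC under the package's convention
#'
#' \eqn{-2\ell + k \ln n} with \eqn{k} the number of estimated parameters
#' including the NB dispersion, and \eqn{n} the number of modelled units.
#' This matches [stats::BIC()] on a [MASS::glm.nb()] fit.
#'
#' @param loglik maximized log-likelihood.
#' @param n_params parameter count (slopes + intercept + dispersion).
#' @param n number of units.
#' @export
bic_value <- function(loglik, n_params, n) -2 * loglik + n_params * log(n)

# terms whose removal keeps the hierarchy (linear stays while its square is in)
removable_terms <- function(labels) {
  quad_parent <- sub("^I\\((.*)\\^2\\)$", "\\1", labels)
  is_quad <- quad_parent != labels
  blocked <- labels %in% quad_parent[is_quad]
  labels[!blocked]
}

#' Backwards model selection by BIC with a linear-before-quadratic rule
#'
#' Starting from the full model, repeatedly deletes the single term whose
#' removal lowers BIC the most, stopping when no deletion lowers it.  A
#' linear term cannot be removed while its quadratic (\code{I(x^2)}) remains;
#' factor covariates are removed as whole blocks.  Near-ties (BIC within
#' \code{tie_tol}) are broken by removing the term with the smallest
#' |coefficient / SE|, so traces are deterministic.  Coefficient and SE
#' stability of the surviving terms is monitored at every step, as a
#' multicollinearity check.
#'
#' @param fit a full-model [rsf_nb()] fit.
#' @param tie_tol BIC tie tolerance.
#' @param verbose print each removal.
#' @return object of class \code{"rsf_backwards"}: \code{$fit} (final
#'   [rsf_nb()]), \code{$removed}, and \code{$trace} (one row per step: term
#'   removed, BIC before/after, max relative change in surviving coefficients
#'   and SEs).
#' @export
backwards_bic <- function(fit, tie_tol = 1e-6, verbose = FALSE) {
  stopifnot(inherits(fit, "rsf_nb"))
  data <- fit$rsf$data
  effort <- fit$rsf$effort
  resp <- fit$rsf$response
  refit <- function(labels) {
    f <- if (length(labels)) stats::reformulate(labels, resp) else
      stats::as.formula(paste(resp, "~ 1"))
    rsf_nb(f, data, effort = effort)
  }
  cur <- fit
  cur_labels <- attr(stats::terms(fit$rsf$formula), "term.labels")
  trace <- list()
  removed <- character(0)
  step <- 0L
  repeat {
    cand <- removable_terms(cur_labels)
    if (!length(cand)) break
    fits <- lapply(cand, function(tm) refit(setdiff(cur_labels, tm)))
    bics <- vapply(fits, function(f) f$bic, numeric(1))
    best <- min(bics)
    if (best >= cur$bic) break
    near <- which(bics <= best + tie_tol)
    pick <- if (length(near) > 1) {
      # tie: drop the weakest term by |z| in the current fit
      z <- summary(cur)$coefficients
      asgn <- attr(stats::model.matrix(cur), "assign")
      cur_lab <- attr(stats::terms(stats::formula(cur)), "term.labels")
      zmin <- vapply(cand[near], function(tm) {
        cols <- which(asgn == match(tm, cur_lab))
        if (!length(cols)) return(0)
        min(abs(z[cols, "Estimate"] / z[cols, "Std. Error"]))
      }, numeric(1))
      near[which.min(zmin)]
    } else near
    new_fit <- fits[[pick]]
    step <- step + 1L
    shared <- intersect(names(stats::coef(cur)), names(stats::coef(new_fit)))
    se_cur <- summary(cur)$coefficients[, "Std. Error"]
    se_new <- summary(new_fit)$coefficients[, "Std. Error"]
    relchg <- function(new, old) max(abs((new - old) /
                                           ifelse(old == 0, 1, old)))
    trace[[step]] <- data.frame(
      step = step, removed = cand[pick],
      bic_before = cur$bic, bic_after = new_fit$bic,
      delta_bic = new_fit$bic - cur$bic,
      max_rel_coef_change = relchg(stats::coef(new_fit)[shared],
                                   stats::coef(cur)[shared]),
      max_rel_se_change = relchg(se_new[shared], se_cur[shared]),
      stringsAsFactors = FALSE)
    if (verbose)
      cat("step", step, "removed", cand[pick], "BIC",
          format(new_fit$bic, digits = 7), "\n")
    removed <- c(removed, cand[pick])
    cur_labels <- setdiff(cur_labels, cand[pick])
    cur <- new_fit
  }
  structure(list(fit = cur, removed = removed,
                 trace = if (step) do.call(rbind, trace) else
                   data.frame()),
            class = "rsf_backwards")
}

#' @export
print.rsf_backwards <- function(x, ...) {
  cat("Backwards BIC selection:", length(x$removed), "terms removed",
      if (length(x$removed)) paste0("(", paste(x$removed, collapse = ", "),
                                    ")"), "\n")
  print(x$fit)
  invisible(x)
}

#' Deviance goodness-of-fit test
#'
#' The residual deviance (sum of squared deviance residuals) is referred to
#' the upper tail of a chi-square on the residual degrees of freedom
#' (n minus the number of regression coefficients).  The approximation
#' relies on moderately large fitted means.
#'
#' @param fit an [rsf_nb()] fit.
#' @return an \code{"htest"}.
#' @export
gof_deviance <- function(fit) {
  stat <- stats::deviance(fit)
  df <- stats::df.residual(fit)
  structure(list(statistic = c(`X-squared` = stat),
                 parameter = c(df = df),
                 p.value = stats::pchisq(stat, df, lower.tail = FALSE),
                 method = "Deviance goodness-of-fit test (NB2 RSF)",
                 data.name = deparse(fit$rsf$formula)),
            class = "htest")
}

#' Moran's I for model residuals over a distance radius
#'
#' Binary neighbour weights: \eqn{w_{ij} = 1} iff
#' \eqn{0 < d_{ij} \le} \code{radius_km} between unit centres (planar km),
#' optionally row-standardized.  Values above \code{flag} indicate residual
#' spatial autocorrelation violating the independence assumption; under the
#' null of exchangeable residuals \eqn{E[I] = -1/(n-1)}.
#'
#' @param values residuals (one per unit).
#' @param x,y unit-centre coordinates in km.
#' @param radius_km neighbourhood radius (default 200).
#' @param row_standardize divide each row of weights by its sum.
#' @param flag threshold above which \code{flagged} is TRUE (default 0.20).
#' @return list with \code{I}, \code{expected}, \code{n_pairs},
#'   \code{flagged}.
#' @export
morans_i <- function(values, x, y, radius_km = 200, row_standardize = FALSE,
                     flag = 0.2) {
  n <- length(values)
  stopifnot(length(x) == n, length(y) == n)
  if (n < 2) stop("need at least two units")
  d <- as.matrix(stats::dist(cbind(x, y)))
  w <- (d > 0 & d <= radius_km) * 1
  if (!any(w > 0)) stop("no neighbour pairs within ", radius_km, " km")
  if (row_standardize) {
    rs <- rowSums(w)
    w[rs > 0, ] <- w[rs > 0, ] / rs[rs > 0]
  }
  z <- values - mean(values)
  i_val <- (n / sum(w)) * sum(w * outer(z, z)) / sum(z^2)
  list(I = i_val, expected = -1 / (n - 1), n_pairs = sum(w > 0),
       flagged = i_val > flag)
}
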