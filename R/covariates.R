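#' Summarize landscape covariates within sampling units
#'
#' Continuous fields are summarized by the median of grid cells whose centre
#' falls in the unit rectangle (half-open on the north and east edges, so
#' adjacent units never share a cell); land-cover fields by the mean cell
#' share; road distances are measured from the unit centre to the nearest
#' road line; aspect is the modal non-flat quadrant (reference "N" when the
#' whole unit is flat).  For every continuous (non-proportion, non-distance)
#' covariate a standardized copy \code{<name>_s}, centred and scaled by the
#' field-wide mean and standard deviation, is appended; the same scaling is
#' therefore used for every set of units drawn from a given landscape.
#'
#' @param units data frame with unit extents: columns \code{x0}, \code{x1}
#'   (east-west) and \code{y} (centre line north-south).
#' @param land a [landscape()].
#' @param width_km unit width (north-south), default 2.
#' @param geometry if TRUE, return the input columns alongside the
#'   covariates.
#' @return data frame, one row per unit.
#' @export
extract_covariates <- function(units, land, width_km = 2, geometry = TRUE) {
  stopifnot(inherits(land, "landscape"),
            all(c("x0", "x1", "y") %in% names(units)))
  n <- nrow(units)
  specs <- land$specs
  numeric_fields <- names(specs)[vapply(specs, function(s)
    s$type %in% c("continuous", "derived"), logical(1))]
  prop_fields <- names(specs)[vapply(specs, function(s)
    s$type == "proportion", logical(1))]
  dist_fields <- names(specs)[vapply(specs, function(s)
    s$type == "distance", logical(1))]
  out <- list()
  for (nm in c(numeric_fields, prop_fields))
    out[[nm]] <- numeric(n)
  for (nm in dist_fields) out[[nm]] <- numeric(n)
  has_aspect <- "aspect" %in% names(land$fields)
  if (has_aspect) out$aspect <- character(n)
  cy0 <- units$y - width_km / 2
  cy1 <- units$y + width_km / 2
  cx <- (units$x0 + units$x1) / 2
  for (i in seq_len(n)) {
    ix <- which(land$xc >= units$x0[i] & land$xc < units$x1[i])
    iy <- which(land$yc >= cy0[i] & land$yc < cy1[i])
    if (!length(ix) || !length(iy))
      stop("no grid cells intersect unit at x=[", units$x0[i], ",",
           units$x1[i], "], y=", units$y[i])
    for (nm in numeric_fields)
      out[[nm]][i] <- stats::median(land$fields[[nm]][iy, ix])
    for (nm in prop_fields)
      out[[nm]][i] <- mean(land$fields[[nm]][iy, ix])
    for (nm in dist_fields) {
      rd <- land$roads[[nm]]
      out[[nm]][i] <- min(abs(cx[i] - rd$x), abs(units$y[i] - rd$y))
    }
    if (has_aspect) {
      a <- land$fields$aspect[iy, ix]
      a <- a[!is.na(a)]
      out$aspect[i] <- if (length(a)) names(which.max(table(a))) else "N"
    }
  }
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  if (has_aspect)
    out$aspect <- factor(out$aspect, levels = c("N", "S", "E", "W"))
  # standardized copies, scaled by the field-wide moments
  for (nm in numeric_fields) {
    f <- land$fields[[nm]]
    s <- stats::sd(f)
    out[[paste0(nm, "_s")]] <- if (s > 0) (out[[nm]] - mean(f)) / s else
      out[[nm]] * 0
  }
  if (geometry) cbind(units, out, row.names = NULL) else out
}

#' Screen covariate pairs for multicollinearity
#'
#' Pearson correlations among all numeric covariates; pairs with
#' \eqn{|r| >} \code{threshold} are flagged.  Highly correlated covariates
#' should not both enter the full model; which member of a flagged pair to
#' drop is the analyst's call (biological relevance is not computable).
#'
#' @param x data frame of unit covariates (non-numeric columns ignored).
#' @param threshold absolute correlation above which a pair is flagged.
#' @return data frame of all pairs with columns \code{var1}, \code{var2},
#'   \code{r}, \code{flagged}, ordered by decreasing \eqn{|r|}.
#' @export
screen_correlation <- function(x, threshold = 0.6) {
  num <- x[vapply(x, is.numeric, logical(1))]
  if (ncol(num) < 2) stop("need at least two numeric covariates")
  if (nrow(num) < 3) stop("need at least three units")
  sds <- vapply(num, stats::sd, numeric(1))
  if (any(sds == 0)) {
    warning("zero-variance covariates excluded from screening: ",
            paste(names(num)[sds == 0], collapse = ", "))
    num <- num[sds > 0]
  }
  r <- stats::cor(num)
  ut <- upper.tri(r)
  out <- data.frame(var1 = rownames(r)[row(r)[ut]],
                    var2 = colnames(r)[col(r)[ut]],
                    r = r[ut], stringsAsFactors = FALSE)
  out$flagged <- abs(out$r) > threshold
  out <- out[order(-abs(out$r)), ]
  rownames(out) <- NULL
  out
}

#' Compare two correlated candidate covariates by univariate AIC
#'
#' Fits two single-covariate effort-offset NB models and reports their AICs;
#' the lower-AIC candidate is preferred.  AIC (not BIC) is used because
#' overfitting is not a concern with one covariate.
#'
#' @param data modeling table with the response, effort and both candidates.
#' @param a,b candidate covariate names.
#' @param response,effort column names (defaults \code{"pseudocount"},
#'   \code{"n_years"}).
#' @return list with \code{aic} (named pair), \code{preferred}, and
#'   \code{tie} (TRUE when AICs agree to 1e-6).
#' @export
compare_univariate <- function(data, a, b, response = "pseudocount",
                               effort = "n_years") {
  fit1 <- rsf_nb(stats::reformulate(a, response), data, effort = effort)
  fit2 <- rsf_nb(stats::reformulate(b, response), data, effort = effort)
  aic <- c(stats::AIC(fit1), stats::AIC(fit2))
  names(aic) <- c(a, b)
  tie <- abs(diff(aic)) < 1e-6
  list(aic = aic, preferred = if (tie) NA_character_ else
    names(aic)[which.min(aic)], tie = tie)
}

#' Specify an RSF model structure
#'
#' @param linear character vector of linear covariate terms.
#' @param quadratic covariates that also get a quadratic term; each must
#'   appear in \code{linear} (the linear term must be present for the
#'   quadratic to be allowed -- a structural rule also enforced during
#'   backwards selection).
#' @param categorical factor covariates (e.g. \code{"aspect"}; first level is
#'   the reference).
#' @param response,effort response and effort column names.
#' @return a \code{"rsf_spec"} with the model [formula].
#' @export
rsf_spec <- function(linear, quadratic = NULL, categorical = NULL,
                     response = "pseudocount", effort = "n_years") {
  bad <- setdiff(quadratic, linear)
  if (length(bad))
    stop("quadratic terms without their linear parent: ",
         paste(bad, collapse = ", "))
  terms <- c(linear, if (length(quadratic))
    paste0("I(", quadratic, "^2)"), categorical)
  f <- stats::reformulate(terms, response)
  structure(list(formula = f, linear = linear, quadratic = quadratic,
                 categorical = categorical, response = response,
                 effort = effort), class = "rsf_spec")
}

#' Build the design matrix for an RSF specification
#'
#' Expands categorical covariates to indicator columns against their first
#' (reference) level and appends quadratic columns tied to their linear
#' parents.
#'
#' @param data unit covariate table.
#' @param spec an [rsf_spec()].
#' @return numeric design matrix including the intercept column.
#' @export
build_design <- function(data, spec) {
  stopifnot(inherits(spec, "rsf_spec"))
  f <- stats::reformulate(attr(stats::terms(spec$formula), "term.labels"))
  stats::model.matrix(f, data = data)
}
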