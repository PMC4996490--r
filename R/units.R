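#' Draw random sampling units along transects
#'
#' Points are drawn uniformly, with replacement, over the total transect
#' length (so duplicate and overlapping units are legal and treated as
#' independent draws).  Each point becomes the centre of a
#' \code{unit_length_km} x \code{unit_width_km} rectangle along its
#' transect; units whose east-west extent would run past either transect end
#' are discarded.
#'
#' @param transects from [generate_transects()].
#' @param n_points number of random points (the survey analysed here drew
#'   2,000).
#' @param unit_length_km,unit_width_km unit dimensions (defaults 10 x 2).
#' @param seed optional integer seed.
#' @return data frame of retained units: \code{unit_id}, \code{transect_id},
#'   \code{center_x} (absolute east-west km), \code{x0}, \code{x1},
#'   \code{y}.
#' @export
sample_units <- function(transects, n_points = 2000, unit_length_km = 10,
                         unit_width_km = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_points >= 1)
  if (all(transects$length_km < unit_length_km))
    stop("all transects shorter than one unit length (",
         unit_length_km, " km)")
  tot <- sum(transects$length_km)
  pos <- stats::runif(n_points, 0, tot)          # position along concatenation
  cum <- cumsum(transects$length_km)
  ti <- findInterval(pos, c(0, cum), rightmost.closed = TRUE)
  within <- pos - c(0, cum)[ti]                  # km from transect west end
  half <- unit_length_km / 2
  keep <- within >= half & within <= transects$length_km[ti] - half
  ti <- ti[keep]; within <- within[keep]
  out <- data.frame(
    unit_id = seq_len(sum(keep)),
    transect_id = transects$transect_id[ti],
    center_x = transects$x0[ti] + within,
    y = transects$y[ti])
  out$x0 <- out$center_x - half
  out$x1 <- out$center_x + half
  out
}

#' Assign survey effort to sampling units
#'
#' A year counts toward a unit's effort only if the unit's transect was flown
#' that year (whole-transect granularity: the effort offset in the model is
#' in whole years).  Units below the effort floor are dropped.
#'
#' @param units from [sample_units()].
#' @param flown transect-year log with columns \code{transect_id},
#'   \code{year}, \code{flown}.
#' @param min_years effort floor; units surveyed fewer years are excluded
#'   (default 2, the observed minimum in the survey this design mirrors).
#' @return \code{units} with an \code{n_years} column, filtered to the floor.
#' @export
assign_effort <- function(units, flown, min_years = 2) {
  if (nrow(flown) == 0 || !any(flown$flown)) {
    warning("empty flown log: all units excluded")
    units$n_years <- integer(nrow(units))
    return(units[0, ])
  }
  eff <- stats::aggregate(flown ~ transect_id, data = flown, FUN = sum)
  units$n_years <- eff$flown[match(units$transect_id, eff$transect_id)]
  units$n_years[is.na(units$n_years)] <- 0L
  drop <- units$n_years < min_years
  if (any(units$n_years == 0))
    warning(sum(units$n_years == 0), " units with zero effort excluded")
  units[!drop, , drop = FALSE]
}

#' Assign observations to the sampling units containing them
#'
#' Membership is by along-transect interval: an observation belongs to every
#' unit on its transect whose east-west extent contains its recorded
#' position.  Because units are independent with-replacement draws,
#' observations falling in overlapping units are counted in each (each unit
#' is its own draw).
#'
#' @param observations records with \code{transect_id} and \code{position_km}
#'   (absolute east-west km).
#' @param units from [sample_units()].
#' @return observations replicated per containing unit, with a
#'   \code{unit_id} column; observations in no unit are dropped.
#' @export
assign_observations <- function(observations, units) {
  if (NROW(observations) == 0) {
    observations$unit_id <- integer(0)
    return(observations)
  }
  hits <- lapply(seq_len(nrow(units)), function(i) {
    j <- which(observations$transect_id == units$transect_id[i] &
               observations$position_km >= units$x0[i] &
               observations$position_km <= units$x1[i])
    if (length(j)) cbind(obs = j, unit = i) else NULL
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) {
    out <- observations[0, , drop = FALSE]
    out$unit_id <- integer(0)
    return(out)
  }
  out <- observations[hits[, "obs"], , drop = FALSE]
  out$unit_id <- units$unit_id[hits[, "unit"]]
  rownames(out) <- NULL
  out
}
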