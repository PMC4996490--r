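#' Build and validate a detection-probability table
#'
#' A detection table holds the mean probability of detection and its standard
#' error for each survey stratum, where a stratum is the combination of an
#' observation type (\code{"perched107"}, \code{"perched150"}, \code{"flying"};
#' the number is the aircraft altitude in metres above ground level) and an
#' observer position (\code{"back-left"}, \code{"right"}, \code{"front-right"}).
#' The \code{"right"} column is the combined front- and back-right observer
#' pair; \code{"front-right"} applies when only a single right-side observer
#' was aboard.
#'
#' @param x a data frame with columns \code{obs_type}, \code{position},
#'   \code{p_bar} and \code{se}, covering all nine strata.
#' @return the validated data frame, with class \code{"detection_table"}.
#' @seealso [default_detection()] for the table used throughout the examples,
#'   [inflate_observation()] for its use.
#' @export
detection_table <- function(x) {
  need <- c("obs_type", "position", "p_bar", "se")
  if (!is.data.frame(x) || !all(need %in% names(x)))
    stop("detection table needs columns: ", paste(need, collapse = ", "))
  x$obs_type <- as.character(x$obs_type)
  x$position <- as.character(x$position)
  bad_t <- setdiff(x$obs_type, c("perched107", "perched150", "flying"))
  if (length(bad_t)) stop("unknown obs_type: ", paste(bad_t, collapse = ", "))
  bad_p <- setdiff(x$position, c("back-left", "right", "front-right"))
  if (length(bad_p)) stop("unknown position: ", paste(bad_p, collapse = ", "))
  full <- expand.grid(obs_type = c("perched107", "perched150", "flying"),
                      position = c("back-left", "right", "front-right"),
                      stringsAsFactors = FALSE)
  have <- paste(x$obs_type, x$position)
  miss <- setdiff(paste(full$obs_type, full$position), have)
  if (length(miss)) stop("missing strata: ", paste(miss, collapse = "; "))
  if (anyDuplicated(have)) stop("duplicated strata in detection table")
  if (any(x$p_bar <= 0) || any(x$p_bar > 1))
    stop("p_bar must lie in (0, 1]")
  if (any(x$se < 0)) stop("se must be non-negative")
  class(x) <- c("detection_table", "data.frame")
  x
}

#' Default detection-probability table
#'
#' Stratum-specific mean detection probabilities (with standard errors) for a
#' three-observer fixed-wing crew surveying at 107 or 150 m above ground
#' level, as estimated for the late-summer golden eagle survey the package's
#' examples are built around.  These values are inputs to the analysis, not
#' quantities the package estimates.
#'
#' @return a [detection_table()].
#' @export
default_detection <- function() {
  detection_table(data.frame(
    obs_type = rep(c("perched107", "perched150", "flying"), each = 3),
    position = rep(c("back-left", "right", "front-right"), times = 3),
    p_bar    = c(0.467, 0.588, 0.456,
                 0.280, 0.396, 0.280,
                 0.380, 0.472, 0.301),
    se       = c(0.026, 0.029, 0.026,
                 0.047, 0.051, 0.045,
                 0.066, 0.058, 0.038),
    stringsAsFactors = FALSE
  ))
}

#' Read a detection table from CSV
#'
#' @param path path to a CSV file with columns \code{obs_type},
#'   \code{position}, \code{p_bar}, \code{se}.
#' @return a [detection_table()].
#' @export
read_detection <- function(path) {
  detection_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Map aircraft side to observer-position stratum
#'
#' Left-side detections belong to the back-left observer.  Right-side
#' detections default to the combined right-side (front plus back) stratum;
#' set \code{two_observer = TRUE} for crews with a single front-right
#' observer.
#'
#' @param side character vector, \code{"left"} or \code{"right"}.
#' @param two_observer logical; use the front-right-only stratum for
#'   right-side detections.
#' @return character vector of observer positions.
#' @export
obs_position <- function(side, two_observer = FALSE) {
  side <- as.character(side)
  bad <- setdiff(side, c("left", "right"))
  if (length(bad)) stop("side must be 'left' or 'right', got: ",
                        paste(unique(bad), collapse = ", "))
  ifelse(side == "left", "back-left",
         if (two_observer) "front-right" else "right")
}

# stratum lookup: returns p_bar (or se) aligned with records
detection_lookup <- function(obs_type, position, detection, field = "p_bar") {
  key <- paste(detection$obs_type, detection$position)
  idx <- match(paste(obs_type, position), key)
  if (anyNA(idx)) {
    miss <- unique(paste0("(", obs_type[is.na(idx)], ", ",
                          position[is.na(idx)], ")"))
    stop("no detection stratum for: ", paste(miss, collapse = "; "))
  }
  detection[[field]][idx]
}

#' Inflate observed groups by detection probability
#'
#' Each detected group of size \eqn{s} in stratum \eqn{t} represents an
#' estimated \eqn{s / \bar{P}_t} groups' worth of individuals actually
#' present (Horvitz--Thompson inflation).  Groups are inflated as whole
#' groups, not per individual.
#'
#' @param records a data frame of observation records with columns
#'   \code{group_size}, \code{obs_type} and either \code{position} or
#'   \code{side} (converted via [obs_position()]).
#' @param detection a [detection_table()].
#' @param two_observer passed to [obs_position()] when only \code{side} is
#'   available.
#' @return numeric vector of inflated counts, one per record; each is at
#'   least the group size.
#' @examples
#' det <- default_detection()
#' recs <- data.frame(group_size = c(1, 2, 1),
#'                    obs_type = c("flying", "perched107", "perched107"),
#'                    position = c("back-left", "right", "right"))
#' sum(inflate_observation(recs, det))  # 7.734
#' @export
inflate_observation <- function(records, detection, two_observer = FALSE) {
  records <- as.data.frame(records)
  if (!"position" %in% names(records)) {
    if (!"side" %in% names(records))
      stop("records need a 'position' or 'side' column")
    records$position <- obs_position(records$side, two_observer)
  }
  if (any(records$group_size < 1))
    stop("group_size must be >= 1")
  p <- detection_lookup(records$obs_type, records$position, detection)
  records$group_size / p
}

# round half away from zero (pseudocounts are >= 0, but keep the general rule)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Accumulate detection-adjusted pseudocounts per sampling unit
#'
#' Sums inflated counts of all records assigned to each sampling unit across
#' years, then rounds the sum (half away from zero by default) to give an
#' integer pseudocount suitable as a count-regression response.  Units with
#' no records get pseudocount zero.
#'
#' @param records observation records with a \code{unit_id} column plus the
#'   columns required by [inflate_observation()].  May be empty.
#' @param detection a [detection_table()].
#' @param units a data frame with one row per sampling unit: \code{unit_id}
#'   and effort \code{n_years}.
#' @param round_rule \code{"half-up"} (half away from zero) or
#'   \code{"half-even"} (banker's rounding via [round()]).
#' @param two_observer passed to [inflate_observation()].
#' @return \code{units} with columns \code{raw_sum} (unrounded inflated sum)
#'   and \code{pseudocount} appended.
#' @export
accumulate_units <- function(records, detection, units,
                             round_rule = c("half-up", "half-even"),
                             two_observer = FALSE) {
  round_rule <- match.arg(round_rule)
  if (!all(c("unit_id", "n_years") %in% names(units)))
    stop("units needs 'unit_id' and 'n_years' columns")
  raw <- numeric(nrow(units))
  if (NROW(records) > 0) {
    if (!"unit_id" %in% names(records))
      stop("records need a 'unit_id' column")
    idx <- match(records$unit_id, units$unit_id)
    if (anyNA(idx))
      stop("records reference unknown unit_id: ",
           paste(unique(records$unit_id[is.na(idx)]), collapse = ", "))
    infl <- inflate_observation(records, detection, two_observer)
    agg <- tapply(infl, idx, sum)
    raw[as.integer(names(agg))] <- as.numeric(agg)
  }
  units$raw_sum <- raw
  units$pseudocount <- if (round_rule == "half-up") {
    as.integer(round_half_up(raw))
  } else {
    as.integer(round(raw))
  }
  units
}
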