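#' Genetic (recombination) map
#'
#' HapMap-style recombination map: 1-based physical positions with a local
#' recombination rate (cM/Mb) and a non-decreasing cumulative genetic
#' position (cM).
#'
#' @param positions 1-based coordinates, strictly increasing, >= 2 points.
#' @param rate local recombination rate in cM/Mb at each position (>= 0).
#' @param cumulative_cM non-decreasing cumulative genetic position.
#' @return an object of class `genetic_map`.
#' @export
genetic_map <- function(positions, rate, cumulative_cM) {
  if (length(positions) < 2)
    stop("a genetic map needs at least 2 points for interpolation")
  if (length(rate) != length(positions) ||
      length(cumulative_cM) != length(positions))
    stop("positions, rate and cumulative_cM must have equal length")
  if (any(diff(positions) <= 0)) stop("map positions must be strictly increasing")
  if (any(rate < 0)) stop("recombination rates must be >= 0")
  if (any(diff(cumulative_cM) < 0)) stop("cumulative cM must be non-decreasing")
  structure(list(positions = as.numeric(positions), rate = as.numeric(rate),
                 cumulative_cM = as.numeric(cumulative_cM)),
            class = "genetic_map")
}

#' Interpolated local recombination rate
#'
#' Linear interpolation of the cM/Mb rate column between flanking map points;
#' positions outside the map clamp to the nearest end's rate.
#'
#' @param map a [genetic_map].
#' @param position query coordinate(s), 1-based.
#' @return numeric rate(s) in cM/Mb.
#' @export
interpolate_rate <- function(map, position) {
  stats::approx(map$positions, map$rate, xout = position, rule = 2)$y
}

#' Mean recombination rate of a region window
#'
#' The window is the region extended by `flank_bp` on both sides (clamped at
#' coordinate 0).  The mean rate is `(delta cM over window) / (delta bp over
#' window) * 1e6`, with cumulative cM linearly interpolated at the window
#' endpoints (clamped to the map ends).
#'
#' @param map a [genetic_map].
#' @param start,end region bounds, 0-based half-open.
#' @param flank_bp symmetric flank in bp (default 50000).
#' @return mean rate in cM/Mb.
#' @export
mean_window_rate <- function(map, start, end, flank_bp = 50000) {
  w0 <- max(0, start - flank_bp)
  w1 <- end + flank_bp
  if (w1 <= w0) stop("window has zero width")
  # a 0-based boundary b sits half way between 1-based bp b and b+1, so the
  # cumulative map (indexed by 1-based bp) is evaluated at b + 0.5
  cm <- stats::approx(map$positions, map$cumulative_cM,
                      xout = c(w0, w1) + 0.5, rule = 2)$y
  (cm[2] - cm[1]) / (w1 - w0) * 1e6
}
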