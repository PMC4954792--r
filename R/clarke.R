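#' Clarke error grid zone classification
#'
#' Assigns each (reference, sensor) glucose pair to one of the five zones of
#' the canonical Clarke error grid, the classic partition of the
#' reference-versus-estimate plane by the clinical danger of acting on the
#' estimate. With `x` the reference and `y` the sensor estimate (mg/dl), the
#' piecewise-linear boundaries are:
#' \itemize{
#'   \item A: `|y - x| <= 0.2 x`, or both values in the hypoglycemic corner
#'     (`x < 70` and `y < 70`) -- clinically accurate;
#'   \item E: `x <= 70 & y >= 180` or `x >= 180 & y <= 70` -- hypo/hyper
#'     confusion, opposite treatment;
#'   \item C: `70 <= x <= 290 & y >= x + 110` (overcorrection high) or
#'     `130 <= x <= 180 & y <= 7/5 x - 182` (overcorrection low);
#'   \item D: `x >= 240 & 70 <= y <= 180`, or `x <= 175/3 & 70 <= y <= 180`,
#'     or `175/3 <= x <= 70 & y >= 6/5 x` -- dangerous failure to detect;
#'   \item B: everything else -- benign deviation.
#' }
#' Zones are checked in the order A, E, C, D, B; the first matching zone is
#' assigned, which resolves boundary overlaps toward the more specific zone
#' exactly as the canonical grid does.
#'
#' @param reference,sensor numeric vectors (mg/dl), recycled to a common
#'   length; all values must be positive.
#' @return character vector of zones `"A"`-`"E"`.
#' @export
clarke_zone <- function(reference, sensor) {
  n <- max(length(reference), length(sensor))
  x <- rep_len(as.numeric(reference), n)
  y <- rep_len(as.numeric(sensor), n)
  if (any(!is.finite(x) | !is.finite(y) | x <= 0 | y <= 0)) {
    stop("Clarke grid requires positive finite glucose values", call. = FALSE)
  }
  zone <- rep(NA_character_, n)
  a <- (x < 70 & y < 70) | (abs(y - x) <= 0.2 * x)
  e <- (x <= 70 & y >= 180) | (x >= 180 & y <= 70)
  c_up <- x >= 70 & x <= 290 & y >= x + 110
  c_lo <- x >= 130 & x <= 180 & y <= (7 / 5) * x - 182
  d_hi <- x >= 240 & y >= 70 & y <= 180
  d_lo1 <- x <= 175 / 3 & y >= 70 & y <= 180
  d_lo2 <- x >= 175 / 3 & x <= 70 & y >= (6 / 5) * x
  zone[a] <- "A"
  zone[is.na(zone) & e] <- "E"
  zone[is.na(zone) & (c_up | c_lo)] <- "C"
  zone[is.na(zone) & (d_hi | d_lo1 | d_lo2)] <- "D"
  zone[is.na(zone)] <- "B"
  zone
}

#' Clarke zone distribution of a set of pairs
#'
#' @param reference,sensor numeric vectors (mg/dl).
#' @return named numeric vector: percentage of pairs in zones A-E (sums to
#'   100 up to rounding; reported to full precision).
#' @export
clarke_distribution <- function(reference, sensor) {
  z <- clarke_zone(reference, sensor)
  tab <- table(factor(z, levels = c("A", "B", "C", "D", "E")))
  out <- as.numeric(tab) / length(z) * 100
  names(out) <- names(tab)
  out
}
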