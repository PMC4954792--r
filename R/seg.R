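# Surveillance-style clinical risk surface.
#
# The published Surveillance Error Grid distributes a full-resolution risk
# surface as external software; replicating it bit-exactly is out of scope
# here. This module provides a synthetic surface with the same documented
# qualitative structure: risk 0 on the identity diagonal, risk growing
# monotonically as the sensor estimate moves away from the reference, and
# maximal risk in the corners of extreme hypo/hyper discordance. It is built
# from a clinical-action score and bundled as a coarse anchor grid queried
# by bilinear interpolation.

# Clinical-action score: a monotone piecewise-linear map from glucose to the
# intensity of the treatment response it would trigger (negative = raise
# glucose, positive = lower glucose). Node placement follows the usual ICU
# action landmarks (severe/moderate hypoglycemia at 40/70, target band
# around 80-150, moderate/severe hyperglycemia at 180+).
.seg_action_nodes <- list(
  glucose = c(20, 40, 70, 80, 120, 160, 180, 250, 350, 600),
  action = c(-3, -2, -1, -0.5, 0, 0.5, 1, 1.5, 2, 3)
)

#' @noRd
.seg_action <- function(g) {
  stats::approx(.seg_action_nodes$glucose, .seg_action_nodes$action,
                xout = g, rule = 2)$y
}

# Exact (pre-interpolation) risk: absolute difference of the action scores
# of reference and estimate, capped at 4. Scale: 0 no risk .. 4 extreme.
#' @noRd
.seg_risk_exact <- function(reference, sensor) {
  pmin(4, abs(.seg_action(reference) - .seg_action(sensor)))
}

# Coarse anchor grid, parameterised as (reference, error = sensor - reference)
# so that the error = 0 anchor row is exactly zero and bilinear interpolation
# is therefore exactly zero on the whole identity diagonal.
.seg_cache <- new.env(parent = emptyenv())

#' The bundled risk-surface anchor grid
#'
#' @return list with `reference` (anchor reference values, mg/dl), `error`
#'   (anchor sensor-minus-reference errors, mg/dl) and `risk` (matrix,
#'   reference x error, risk on the 0-4 scale).
#' @export
seg_surface <- function() {
  if (!is.null(.seg_cache$surface)) return(.seg_cache$surface)
  ref <- c(20, 30, 40, 50, 60, 70, 80, 90, 100, 110, 120, 140, 160, 180,
           200, 225, 250, 300, 350, 400, 500, 600)
  err <- c(-580, -480, -400, -330, -280, -230, -180, -140, -110, -80, -60,
           -50, -40, -30, -20, -10, 0,
           10, 20, 30, 40, 50, 60, 80, 110, 140, 180, 230, 280, 330, 400,
           480, 580)
  risk <- outer(ref, err, function(r, e) {
    .seg_risk_exact(r, pmin(600, pmax(20, r + e)))
  })
  .seg_cache$surface <- list(reference = ref, error = err, risk = risk)
  .seg_cache$surface
}

#' Clinical risk of a sensor estimate against its reference
#'
#' Interpolates the bundled synthetic risk surface (see [seg_surface()])
#' bilinearly in (reference, error) coordinates. Risk is 0 exactly on the
#' identity diagonal and non-decreasing as the estimate moves away from the
#' reference; the scale runs 0 (none) to 4 (extreme). Values outside the
#' 20-600 mg/dl surface domain are clamped with a warning.
#'
#' @param reference,sensor numeric vectors (mg/dl), recycled.
#' @return numeric vector of risk scores in `[0, 4]`.
#' @export
seg_risk <- function(reference, sensor) {
  n <- max(length(reference), length(sensor))
  x <- rep_len(as.numeric(reference), n)
  y <- rep_len(as.numeric(sensor), n)
  if (any(x < 20 | x > 600 | y < 20 | y > 600)) {
    warning("values outside the 20-600 mg/dl risk-surface domain were clamped",
            call. = FALSE)
    x <- pmin(600, pmax(20, x))
    y <- pmin(600, pmax(20, y))
  }
  s <- seg_surface()
  e <- y - x
  ix <- pmin(pmax(findInterval(x, s$reference), 1), length(s$reference) - 1)
  ie <- pmin(pmax(findInterval(e, s$error), 1), length(s$error) - 1)
  x0 <- s$reference[ix]; x1 <- s$reference[ix + 1]
  e0 <- s$error[ie]; e1 <- s$error[ie + 1]
  tx <- ifelse(x1 > x0, (x - x0) / (x1 - x0), 0)
  te <- ifelse(e1 > e0, (e - e0) / (e1 - e0), 0)
  r00 <- s$risk[cbind(ix, ie)]
  r10 <- s$risk[cbind(ix + 1, ie)]
  r01 <- s$risk[cbind(ix, ie + 1)]
  r11 <- s$risk[cbind(ix + 1, ie + 1)]
  (1 - tx) * (1 - te) * r00 + tx * (1 - te) * r10 +
    (1 - tx) * te * r01 + tx * te * r11
}

#' Color zone of a risk score
#'
#' Thresholds at 0.5, 1.5, 2.5 and 3.5 on the 0-4 risk scale map scores to
#' the five color categories `none`, `slight`, `moderate`, `great`,
#' `extreme`.
#'
#' @param risk numeric vector of risk scores (see [seg_risk()]).
#' @return factor with levels `none < slight < moderate < great < extreme`.
#' @export
seg_zone <- function(risk) {
  cut(risk, breaks = c(-Inf, 0.5, 1.5, 2.5, 3.5, Inf),
      labels = c("none", "slight", "moderate", "great", "extreme"),
      ordered_result = TRUE)
}

#' Risk-surface summary over a set of pairs
#'
#' @param reference,sensor numeric vectors (mg/dl).
#' @return list with `mean_risk`, `max_risk` and `zone_pct` (named vector of
#'   color-zone percentages).
#' @export
seg_summary <- function(reference, sensor) {
  r <- seg_risk(reference, sensor)
  z <- seg_zone(r)
  tab <- table(z) / length(r) * 100
  list(mean_risk = mean(r), max_risk = max(r),
       zone_pct = stats::setNames(as.numeric(tab), names(tab)))
}
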