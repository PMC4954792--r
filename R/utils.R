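# Internal helpers shared across the package.

# Canonical time zone for all timestamps; the device cadence is 1/min so all
# times are floored to the minute on entry.
.tz <- "UTC"

#' @noRd
as_minute <- function(x, warn = TRUE) {
  if (inherits(x, "POSIXct")) {
    secs <- as.numeric(x)
  } else if (is.character(x) || is.factor(x)) {
    ch <- as.character(x)
    secs <- rep(NA_real_, length(ch))
    for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%dT%H:%M",
                  "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M")) {
      need <- which(is.na(secs) & !is.na(ch))
      if (!length(need)) break
      secs[need] <- as.numeric(as.POSIXct(ch[need], tz = .tz, format = fmt))
    }
  } else if (is.numeric(x)) {
    secs <- x
  } else {
    stop("unsupported timestamp type: ", class(x)[1], call. = FALSE)
  }
  if (warn && any(!is.na(secs) & secs %% 60 != 0)) {
    warning("sub-minute timestamps floored to minute resolution", call. = FALSE)
  }
  out <- .POSIXct(floor(secs / 60) * 60, tz = .tz)
  out
}

# Minutes since epoch as integer-valued double (exact for any realistic date).
#' @noRd
minute_index <- function(ts) floor(as.numeric(ts) / 60)

#' @noRd
minutes_to_posix <- function(m) .POSIXct(m * 60, tz = .tz)

# Half-up rounding to `digits` decimals; base round() is half-even, the
# reporting convention here is half-up (as in the tables this mirrors).
#' @noRd
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards so generators never disturb user RNG flow.
#' @noRd
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' @noRd
median_iqr <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(c(median = NA_real_, q1 = NA_real_, q3 = NA_real_))
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(median = q[2], q1 = q[1], q3 = q[3])
}

#' @noRd
fmt_miqr <- function(x, digits = 1) {
  m <- median_iqr(x)
  sprintf("%.*f [%.*f/%.*f]", digits, m["median"], digits, m["q1"], digits, m["q3"])
}
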