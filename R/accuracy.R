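#' Mean absolute relative difference (MARD) with 95 % confidence interval
#'
#' MARD is the arithmetic mean of per-pair absolute relative differences,
#' `|reference - sensor| / reference * 100`. The default confidence interval
#' is the normal approximation `mard +/- 1.96 * sd(ARD)/sqrt(n)`; a seeded
#' nonparametric bootstrap (percentile interval) is available as an
#' alternative.
#'
#' @param pairs a `cgm_pairs` data.frame, or a numeric vector of ARDs (%).
#' @param ci `"normal"` (default) or `"bootstrap"`.
#' @param boot_n bootstrap replicates (bootstrap CI only).
#' @param seed RNG seed for the bootstrap.
#' @return list with `mard`, `ci95` (length-2: lower, upper), `n`.
#' @export
mard <- function(pairs, ci = c("normal", "bootstrap"), boot_n = 2000, seed = 1) {
  ci <- match.arg(ci)
  ards <- if (is.data.frame(pairs)) pairs$ard_pct else as.numeric(pairs)
  if (!length(ards)) stop("no pairs: MARD undefined", call. = FALSE)
  m <- mean(ards)
  n <- length(ards)
  if (n < 2) {
    return(list(mard = m, ci95 = c(NA_real_, NA_real_), n = n))
  }
  if (ci == "normal") {
    se <- stats::sd(ards) / sqrt(n)
    lim <- c(m - 1.96 * se, m + 1.96 * se)
  } else {
    lim <- with_seed(seed, {
      reps <- replicate(boot_n, mean(sample(ards, n, replace = TRUE)))
      stats::quantile(reps, c(0.025, 0.975), names = FALSE)
    })
  }
  list(mard = m, ci95 = lim, n = n)
}

#' Consensus point-accuracy criteria for ICU continuous glucose monitors
#'
#' The three 2013 consensus criteria for CGM point accuracy in critically
#' ill patients:
#' \enumerate{
#'   \item at least 98 % of readings within 12.5 % of the reference (or
#'     within +/-10 mg/dl when the reference is below 100 mg/dl),
#'   \item the remaining readings all within 20 % of the reference,
#'   \item MARD below 14 %.
#' }
#' A MARD above 18 % is additionally flagged as poor accuracy. Band
#' membership is inclusive (deviation equal to the limit counts as within).
#'
#' @param pairs a `cgm_pairs` data.frame.
#' @return list with `pct_within_12_5`, `pct_within_20`, `mard`, logical
#'   `c1`, `c2`, `c3`, overall `pass` (all three), and `poor` (MARD > 18 %).
#' @export
consensus_check <- function(pairs) {
  stopifnot(is.data.frame(pairs), nrow(pairs) >= 1)
  ref <- pairs$reference_mgdl
  sen <- pairs$sensor_mgdl
  rel <- abs(ref - sen) / ref * 100
  in_12_5 <- ifelse(ref < 100, abs(ref - sen) <= 10, rel <= 12.5)
  in_20 <- rel <= 20
  m <- mean(rel)
  pct_12_5 <- mean(in_12_5) * 100
  c1 <- pct_12_5 >= 98
  c2 <- all(in_20[!in_12_5])
  c3 <- m < 14
  list(pct_within_12_5 = pct_12_5,
       pct_within_20 = mean(in_12_5 | in_20) * 100,
       mard = m, c1 = c1, c2 = c2, c3 = c3,
       pass = c1 && c2 && c3, poor = m > 18)
}

#' Bland-Altman bias and limits of agreement
#'
#' Differences are `reference - sensor`; the bias is their mean and the 95 %
#' limits of agreement are `bias +/- 1.96 * sd(diff)` (sample standard
#' deviation, n - 1). Under approximate normality 95 % of differences fall
#' between the limits.
#'
#' @param pairs a `cgm_pairs` data.frame.
#' @return list with `bias`, `loa_lower`, `loa_upper`, `sd_diff`, `n`.
#' @export
bland_altman <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  if (nrow(pairs) < 2) stop("Bland-Altman needs at least 2 pairs", call. = FALSE)
  d <- pairs$reference_mgdl - pairs$sensor_mgdl
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
       sd_diff = s, n = length(d))
}

#' Spearman rank correlation between reference and sensor glucose
#'
#' @param pairs a `cgm_pairs` data.frame (needs at least 3 pairs).
#' @return list with `rho`, `p`, `r_squared` (= rho^2), `n`.
#' @export
rank_correlation <- function(pairs) {
  stopifnot(is.data.frame(pairs), nrow(pairs) >= 3)
  if (stats::sd(pairs$reference_mgdl) == 0 || stats::sd(pairs$sensor_mgdl) == 0) {
    stop("rank correlation undefined for constant input", call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(pairs$reference_mgdl, pairs$sensor_mgdl, method = "spearman",
                    exact = FALSE))
  rho <- unname(ct$estimate)
  list(rho = rho, p = ct$p.value, r_squared = rho^2, n = nrow(pairs))
}

#' Full point-accuracy report
#'
#' Convenience wrapper running [mard()], [consensus_check()],
#' [bland_altman()], [rank_correlation()], the Clarke error grid
#' ([clarke_distribution()]) and the surveillance-style risk surface
#' ([seg_summary()]) on one set of comparative pairs.
#'
#' @param pairs a `cgm_pairs` data.frame.
#' @param ci,seed passed to [mard()].
#' @return object of class `cgm_accuracy`.
#' @export
accuracy_report <- function(pairs, ci = "normal", seed = 1) {
  stopifnot(is.data.frame(pairs), nrow(pairs) >= 3)
  m <- mard(pairs, ci = ci, seed = seed)
  structure(list(
    n_pairs = nrow(pairs),
    mard = m$mard, mard_ci95 = m$ci95,
    consensus = consensus_check(pairs),
    bland_altman = bland_altman(pairs),
    spearman = rank_correlation(pairs),
    clarke = clarke_distribution(pairs$reference_mgdl, pairs$sensor_mgdl),
    seg = seg_summary(pairs$reference_mgdl, pairs$sensor_mgdl),
    pairs = pairs
  ), class = "cgm_accuracy")
}

#' @export
print.cgm_accuracy <- function(x, ...) {
  cat("<cgm_accuracy>", x$n_pairs, "comparative readings\n")
  cat(sprintf("  MARD %.1f %% (95 %% CI %.1f-%.1f %%)%s\n",
              x$mard, x$mard_ci95[1], x$mard_ci95[2],
              if (x$consensus$poor) "  [poor: > 18 %]" else ""))
  cat(sprintf("  within 12.5 %% (or 10 mg/dl < 100): %.1f %%; within 20 %%: %.1f %%\n",
              x$consensus$pct_within_12_5, x$consensus$pct_within_20))
  cat(sprintf("  consensus criteria: c1 %s, c2 %s, c3 %s -> %s\n",
              x$consensus$c1, x$consensus$c2, x$consensus$c3,
              if (x$consensus$pass) "PASS" else "FAIL"))
  cat(sprintf("  Bland-Altman bias %+.2f mg/dl, LoA %+.1f / %+.1f mg/dl\n",
              x$bland_altman$bias, x$bland_altman$loa_upper, x$bland_altman$loa_lower))
  cat(sprintf("  Spearman rho %.3f (p %s), r^2 %.3f\n", x$spearman$rho,
              format.pval(x$spearman$p, digits = 3), x$spearman$r_squared))
  cat("  Clarke zones (%):",
      paste(sprintf("%s %.1f", names(x$clarke), x$clarke), collapse = ", "), "\n")
  cat(sprintf("  Risk surface: mean risk %.2f; zones (%%): %s\n",
              x$seg$mean_risk,
              paste(sprintf("%s %.1f", names(x$seg$zone_pct), x$seg$zone_pct),
                    collapse = ", ")))
  invisible(x)
}

#' @export
summary.cgm_accuracy <- function(object, ...) print(object)

#' Plot method for accuracy reports
#'
#' `which = "bland_altman"` draws the difference-versus-reference plot with
#' bias and limits of agreement; `which = "clarke"` draws the paired values
#' on the Clarke error grid with its zone boundaries.
#'
#' @param x a `cgm_accuracy` object.
#' @param which `"bland_altman"` or `"clarke"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cgm_accuracy <- function(x, which = c("bland_altman", "clarke"), ...) {
  which <- match.arg(which)
  p <- x$pairs
  if (which == "bland_altman") {
    d <- p$reference_mgdl - p$sensor_mgdl
    graphics::plot((p$reference_mgdl + p$sensor_mgdl) / 2, d,
                   xlab = "Mean of reference and sensor (mg/dl)",
                   ylab = "Reference - sensor (mg/dl)", ...)
    graphics::abline(h = c(x$bland_altman$bias, x$bland_altman$loa_lower,
                           x$bland_altman$loa_upper),
                     lty = c(1, 2, 2), col = "grey40")
  } else {
    graphics::plot(p$reference_mgdl, p$sensor_mgdl, xlim = c(0, 400),
                   ylim = c(0, 400), xlab = "Reference glucose (mg/dl)",
                   ylab = "Sensor glucose (mg/dl)", ...)
    graphics::abline(0, 1, col = "grey70")
    graphics::abline(0, 1.2, lty = 3, col = "grey70")
    graphics::abline(0, 0.8, lty = 3, col = "grey70")
    graphics::abline(h = c(70, 180), v = c(70, 180), lty = 3, col = "grey85")
  }
  invisible(x)
}
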