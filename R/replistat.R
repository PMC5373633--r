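# The trimmed-fraction signal/background statistic for labelled populations.
#
# With labelled fraction F, the (F - 0.1) most-labelled nuclei are taken as
# the replicating group R (the 0.1 buffer excludes borderline nuclei) and
# the (0.9 - F) least-labelled nuclei as the non-replicating group non-R;
# the statistic is the ratio of the two group means.

# Round half away from zero: both group sizes are defined this way so that
# e.g. 0.34 * 10000 -> 3400 regardless of platform rounding mode.
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

check_f <- function(f) {
  if (!(f > 0.1 && f < 0.9))
    stop("f must lie strictly inside (0.1, 0.9); got ", f)
}

#' R/non-R ratio: trimmed-fraction signal-to-background statistic
#'
#' Computes the ratio between the average nuclear signal of the `(f - 0.1)`
#' most-labelled nuclei (the replicating group, R) and that of the
#' `(0.9 - f)` least-labelled nuclei (the non-replicating group, non-R),
#' where `f` is the fraction of labelled (S-phase) cells. The 0.1 margins on
#' both sides exclude nuclei near the class boundary, making the statistic
#' robust to the exact placement of the labelled/unlabelled split. Ratios
#' above 3-4 indicate clear separation of replicating from non-replicating
#' cells.
#'
#' Group sizes are `round((f - 0.1) * n)` and `round((0.9 - f) * n)`
#' (half away from zero), each clamped to at least one nucleus. Sorting is
#' stable and descending, so ties at a group boundary are broken by input
#' order; since tied values are equal this cannot change either group mean.
#'
#' @param signals Numeric vector of per-nucleus signal values (a.u.).
#' @param f Labelled fraction in (0.1, 0.9). Default 0.44, the fraction
#'   labelled by a 30-minute pulse.
#' @return An object of class `rnonr_result`: a list with `f_used`,
#'   `n_total`, `n_top`, `n_bottom`, `r_mean`, `nonr_mean` and `ratio`
#'   (`= r_mean / nonr_mean`).
#' @examples
#' r_nonr_ratio(c(10, 10, 10, 9, 1, 1, 1, 1, 1, 1), f = 0.4)
#' @export
r_nonr_ratio <- function(signals, f = 0.44) {
  check_f(f)
  signals <- as.numeric(signals)
  if (anyNA(signals)) stop("signals must not contain NA")
  n <- length(signals)
  need <- max(ceiling(1 / (f - 0.1)), ceiling(1 / (0.9 - f)))
  if (n < need)
    stop("need at least ", need, " nuclei for f = ", f, "; got ", n)
  n_top <- max(1L, as.integer(round_half_up((f - 0.1) * n)))
  n_bottom <- max(1L, as.integer(round_half_up((0.9 - f) * n)))
  sorted <- signals[order(-signals)]  # radix order: stable
  r_mean <- mean(sorted[seq_len(n_top)])
  nonr_mean <- mean(sorted[seq.int(n - n_bottom + 1L, n)])
  if (nonr_mean == 0) stop("non-replicating mean is zero; ratio undefined")
  structure(list(f_used = f, n_total = n, n_top = n_top, n_bottom = n_bottom,
                 r_mean = r_mean, nonr_mean = nonr_mean,
                 ratio = r_mean / nonr_mean),
            class = "rnonr_result")
}

#' @export
print.rnonr_result <- function(x, ...) {
  cat(sprintf("R/non-R ratio: %.3f (f = %.2f)\n", x$ratio, x$f_used))
  cat(sprintf("  R group:     n = %d, mean = %.2f a.u.\n", x$n_top, x$r_mean))
  cat(sprintf("  non-R group: n = %d, mean = %.2f a.u.\n",
              x$n_bottom, x$nonr_mean))
  cat(sprintf("  nuclei evaluated: %d\n", x$n_total))
  invisible(x)
}

#' Signal intensity of the labelled population
#'
#' The average nuclear signal of the `(f - 0.1)` most-labelled nuclei, i.e.
#' the R-group mean of [r_nonr_ratio()] on the same input.
#'
#' @inheritParams r_nonr_ratio
#' @return Mean signal (a.u.) of the top group.
#' @export
signal_intensity <- function(signals, f = 0.44) {
  check_f(f)
  signals <- as.numeric(signals)
  n <- length(signals)
  if (n < ceiling(1 / (f - 0.1)))
    stop("need at least ", ceiling(1 / (f - 0.1)), " nuclei for f = ", f)
  n_top <- max(1L, as.integer(round_half_up((f - 0.1) * n)))
  mean(sort(signals, decreasing = TRUE)[seq_len(n_top)])
}

# Otsu's threshold for a numeric vector: the bin boundary maximising the
# between-class variance of the histogram.
otsu_threshold <- function(x, n_bins = 256) {
  rng <- range(x)
  if (diff(rng) == 0) return(NA_real_)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(findInterval(x, breaks, all.inside = TRUE), n_bins)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w <- cumsum(counts)
  m <- cumsum(counts * mids)
  total_w <- w[n_bins]; total_m <- m[n_bins]
  w0 <- w[-n_bins]; w1 <- total_w - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- m[-n_bins] / w0
  mu1 <- (total_m - m[-n_bins]) / w1
  between <- w0 * w1 * (mu0 - mu1)^2
  between[!valid] <- -Inf
  breaks[which.max(between) + 1L]
}

#' Estimate the labelled fraction F from per-nucleus signals
#'
#' Splits the signal distribution into labelled and unlabelled classes by
#' Otsu's method on `log(signal + 1)` and returns the fraction of nuclei
#' above the threshold. The estimate is flagged unreliable when the ratio of
#' the two class means (raw scale) is below 3, echoing the guideline that a
#' signal/background ratio of 3-4 is needed for clear separation.
#'
#' @param signals Numeric vector of per-nucleus signal values (>= 100
#'   nuclei).
#' @param min_separation Class-mean ratio below which the estimate is
#'   flagged unreliable (default 3).
#' @return An object of class `f_estimate`: list with `f_hat`, `threshold`
#'   (raw signal scale), `separation` (ratio of class means) and `reliable`.
#' @export
estimate_f <- function(signals, min_separation = 3) {
  signals <- as.numeric(signals)
  if (length(signals) < 100)
    stop("need at least 100 nuclei to estimate F; got ", length(signals))
  if (any(signals < 0)) stop("signals must be nonnegative")
  lx <- log(signals + 1)
  thr <- otsu_threshold(lx)
  if (is.na(thr)) stop("no separation; F undefined (all signals identical)")
  above <- lx > thr
  if (!any(above) || all(above))
    stop("no separation; F undefined (threshold does not split the data)")
  separation <- mean(signals[above]) / mean(signals[!above])
  structure(list(f_hat = mean(above), threshold = exp(thr) - 1,
                 separation = separation,
                 reliable = separation >= min_separation),
            class = "f_estimate")
}

#' @export
print.f_estimate <- function(x, ...) {
  cat(sprintf("Estimated labelled fraction F = %.3f\n", x$f_hat))
  cat(sprintf("  threshold = %.1f a.u.; class-mean separation = %.2f (%s)\n",
              x$threshold, x$separation,
              if (x$reliable) "reliable" else "below the 3-4 guideline"))
  invisible(x)
}

#' Normalise values to a reference condition
#'
#' Expresses each value as a percentage of a reference measurement, the
#' convention used to report e.g. stabilisation series relative to the
#' 2%-formaldehyde condition (= 100%).
#'
#' @param values Numeric vector (a.u.).
#' @param reference Reference value (> 0, same units).
#' @return `100 * values / reference` (percent).
#' @export
normalise_to_reference <- function(values, reference) {
  if (!(is.numeric(reference) && length(reference) == 1 && reference > 0))
    stop("reference must be a single positive value")
  100 * values / reference
}
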