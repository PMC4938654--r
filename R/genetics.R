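#' Chi-square goodness-of-fit test for a two-class segregation ratio
#'
#' Tests observed phenotype counts against an expected Mendelian ratio
#' (default 3:1 for a recessive trait in an F2).  With
#' `continuity = TRUE` (default) the Yates-corrected statistic
#' `sum(max(|O-E| - 0.5, 0)^2 / E)` is used; the uncorrected Pearson
#' statistic is always reported alongside.  The p-value is the upper
#' tail of the chi-square distribution with 1 degree of freedom.
#'
#' @param observed two observed counts.
#' @param ratio two positive expected weights (default `c(3, 1)`).
#' @param continuity apply the Yates continuity correction (default
#'   TRUE).
#' @return Object of class `bsa_segtest`: observed, expected, chisq,
#'   p_value (for the selected mode) plus chisq_corrected /
#'   chisq_uncorrected and both p-values.
#' @examples
#' segregation_chisq(c(262, 71))  # chi2 = 2.21, p = 0.137
#' @export
segregation_chisq <- function(observed, ratio = c(3, 1), continuity = TRUE) {
  if (length(observed) != 2 || length(ratio) != 2) {
    stop("segregation test supports exactly two phenotype classes",
         call. = FALSE)
  }
  if (any(ratio <= 0)) stop("ratio weights must be positive", call. = FALSE)
  if (sum(observed) < 1) stop("need at least one observation", call. = FALSE)
  expected <- sum(observed) * ratio / sum(ratio)
  if (any(expected == 0)) stop("zero expected count", call. = FALSE)
  dev <- abs(observed - expected)
  chisq_u <- sum(dev^2 / expected)
  chisq_c <- sum(pmax(dev - 0.5, 0)^2 / expected)  # clamp guards |O-E| < 0.5
  chisq <- if (continuity) chisq_c else chisq_u
  structure(list(observed = observed, expected = expected, ratio = ratio,
                 continuity = continuity,
                 chisq = chisq,
                 p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
                 chisq_corrected = chisq_c,
                 p_corrected = stats::pchisq(chisq_c, 1, lower.tail = FALSE),
                 chisq_uncorrected = chisq_u,
                 p_uncorrected = stats::pchisq(chisq_u, 1, lower.tail = FALSE)),
            class = "bsa_segtest")
}

#' @export
print.bsa_segtest <- function(x, ...) {
  cat(sprintf("Segregation test: %d : %d observed vs %g:%g expected\n",
              x$observed[1], x$observed[2], x$ratio[1], x$ratio[2]))
  cat(sprintf("  chi-square = %.3f, P = %.3f (%s)\n", x$chisq, x$p_value,
              if (x$continuity) "continuity-corrected" else "uncorrected"))
  cat(sprintf("  [corrected %.3f, P %.3f; uncorrected %.3f, P %.3f]\n",
              x$chisq_corrected, x$p_corrected,
              x$chisq_uncorrected, x$p_uncorrected))
  invisible(x)
}

#' Seed-setting summary of a cross
#'
#' Per-panicle seed-setting rates (100 * seeds / spikelets) with their
#' mean and sample standard deviation over panicles, plus the pooled
#' rate over all spikelets.  With a single panicle the SD is undefined
#' and reported as 0 with `n1_flag = TRUE`.
#'
#' @param spikelets spikelet counts per panicle (>= 1 each).
#' @param seeds hybrid seed counts per panicle (0 <= seeds <= spikelets).
#' @return Object of class `bsa_cross`: n_panicles, rates, mean_rate,
#'   sd_rate, pooled_rate, n1_flag.
#' @examples
#' cross_summary(spikelets = c(100, 100), seeds = c(10, 30))
#' @export
cross_summary <- function(spikelets, seeds) {
  if (length(spikelets) == 0) stop("no panicles given", call. = FALSE)
  if (length(seeds) != length(spikelets)) {
    stop("spikelets and seeds must have one entry per panicle",
         call. = FALSE)
  }
  if (any(spikelets < 1)) stop("each panicle needs >= 1 spikelet",
                               call. = FALSE)
  if (any(seeds < 0 | seeds > spikelets)) {
    stop("seeds must satisfy 0 <= seeds <= spikelets", call. = FALSE)
  }
  rates <- 100 * seeds / spikelets
  n <- length(rates)
  structure(list(n_panicles = n,
                 rates = rates,
                 mean_rate = mean(rates),
                 sd_rate = if (n > 1) stats::sd(rates) else 0,
                 n1_flag = n == 1,
                 pooled_rate = 100 * sum(seeds) / sum(spikelets)),
            class = "bsa_cross")
}

#' @export
print.bsa_cross <- function(x, ...) {
  cat(sprintf("Cross summary over %d panicle(s):\n", x$n_panicles))
  cat(sprintf("  seed setting rate %.1f%% +/- %.1f%% (mean +/- SD%s); pooled %.1f%%\n",
              x$mean_rate, x$sd_rate,
              if (x$n1_flag) ", single panicle" else "", x$pooled_rate))
  invisible(x)
}
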