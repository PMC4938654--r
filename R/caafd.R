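#' CAAFD of one window of markers
#'
#' The cubic average allele frequency difference of a set of markers is
#' \deqn{\left\{\frac{1}{n}\sum_{i=1}^{n}\left(\frac{m_{1i}}{m_{1i}+m_{2i}}
#'  - \frac{n_{1i}}{n_{1i}+n_{2i}}\right)\right\}^3}
#' where `m1`/`m2` count the MH86 and 93-11 alleles in the M-pool and
#' `n1`/`n2` the same in the N-pool.  Note the cube is applied to the
#' window mean, not averaged over per-marker cubes.  Cubing preserves the
#' sign and ranking of the mean difference while sharpening peaks
#' relative to background.
#'
#' @param m1,m2,n1,n2 oriented allele counts for the markers in one
#'   window; every marker must have positive depth in both pools.
#' @return A single value in \[-1, 1\].
#' @examples
#' caafd(c(12, 8), c(0, 2), c(4, 2), c(6, 8))  # 0.6^3 = 0.216
#' @export
caafd <- function(m1, m2, n1, n2) {
  n <- length(m1)
  if (n == 0) stop("empty window: no markers", call. = FALSE)
  if (any(m1 + m2 <= 0) || any(n1 + n2 <= 0)) {
    stop("caafd requires positive pool depths at every marker",
         call. = FALSE)
  }
  mean(m1 / (m1 + m2) - n1 / (n1 + n2))^3
}

#' Sliding-window CAAFD scan of the genome
#'
#' Computes CAAFD in windows of `window_size` bp advanced by `step` bp
#' across every chromosome.  Window centers sit on the step grid (0,
#' step, 2*step, ... while below the chromosome's marker extent); each
#' window spans `[center - window_size/2, center + window_size/2)` in
#' 0-based half-open coordinates, truncated at position 0 and at the
#' observed marker extent.  Windows containing no marker are omitted.
#' The scan uses rolling cumulative sums; it is numerically identical to
#' recomputing each window from scratch.
#'
#' @param markers marker data.frame sorted by (chrom, pos) with columns
#'   chrom, pos (1-based bp), m1, m2, n1, n2; typically the output of
#'   [select_markers()].
#' @param window_size window width in bp (default 2,000,000).
#' @param step step length in bp (default 10,000).
#' @return data.frame of class `bsa_scan`: chrom, center, start, end
#'   (start/end 0-based half-open), n (markers in window), caafd.
#' @export
scan_genome <- function(markers, window_size = 2e6, step = 1e4) {
  if (!(window_size >= step && step > 0)) {
    stop("need window_size >= step > 0", call. = FALSE)
  }
  if (nrow(markers) == 0) {
    return(structure(data.frame(chrom = character(0), center = numeric(0),
                                start = numeric(0), end = numeric(0),
                                n = integer(0), caafd = numeric(0)),
                     class = c("bsa_scan", "data.frame")))
  }
  chroms <- unique(markers$chrom)
  if (any(markers$chrom != rep(chroms, times = table(factor(markers$chrom, chroms))))) {
    stop("markers must be grouped by chromosome", call. = FALSE)
  }
  half <- window_size / 2
  out <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    mk <- markers[markers$chrom == chroms[ci], , drop = FALSE]
    if (is.unsorted(mk$pos)) {
      stop("markers must be sorted by position within each chromosome",
           call. = FALSE)
    }
    pos <- mk$pos
    extent <- max(pos)
    d <- mk$m1 / (mk$m1 + mk$m2) - mk$n1 / (mk$n1 + mk$n2)
    cs <- c(0, cumsum(d))
    centers <- seq(0, by = step, length.out = ceiling(extent / step))
    ws <- pmax(0, centers - half)
    we <- centers + half
    # marker at 1-based p occupies 0-based base p-1; in window iff
    # ws <= p-1 < we, i.e. pos >= ws+1 and pos <= we for integer bounds
    lo <- findInterval(ws + 0.5, pos) + 1L
    hi <- findInterval(we + 0.5, pos)
    n <- hi - lo + 1L
    keep <- n >= 1L
    val <- ((cs[hi[keep] + 1L] - cs[lo[keep]]) / n[keep])^3
    out[[ci]] <- data.frame(chrom = chroms[ci],
                            center = centers[keep],
                            start = ws[keep],
                            end = pmin(we[keep], extent),
                            n = n[keep],
                            caafd = val)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("bsa_scan", "data.frame")
  res
}

#' Call the peak target region from a CAAFD scan
#'
#' The peak is the window with the largest |CAAFD| (ties broken by
#' genomic order).  The region is the maximal run of consecutive windows
#' on the peak's chromosome whose CAAFD has the peak's sign and whose
#' magnitude is at least `alpha` times the peak magnitude.  The highest
#' peak is taken as the target region harboring the causal locus.
#'
#' @param scores a `bsa_scan` data.frame from [scan_genome()].
#' @param alpha region threshold as a fraction of the peak magnitude
#'   (default 0.5).
#' @return Object of class `bsa_region`: list with chrom, start, end
#'   (bp, spanning the region's windows), peak_center, peak_caafd,
#'   n_windows.
#' @export
call_peak_region <- function(scores, alpha = 0.5) {
  if (is.null(scores) || nrow(scores) == 0) {
    stop("cannot call a peak from an empty scan", call. = FALSE)
  }
  o <- order(match(scores$chrom, unique(scores$chrom)), scores$center)
  scores <- scores[o, , drop = FALSE]
  i <- which.max(abs(scores$caafd))   # first max = smallest chrom/center
  pk <- scores[i, ]
  thr <- alpha * abs(pk$caafd)
  sgn <- sign(pk$caafd)
  on_chrom <- which(scores$chrom == pk$chrom)
  j <- match(i, on_chrom)
  ok <- sign(scores$caafd[on_chrom]) == sgn &
    abs(scores$caafd[on_chrom]) >= thr
  lo <- j
  while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
  hi <- j
  while (hi < length(on_chrom) && ok[hi + 1L]) hi <- hi + 1L
  run <- scores[on_chrom[lo:hi], , drop = FALSE]
  structure(list(chrom = pk$chrom,
                 start = min(run$start), end = max(run$end),
                 peak_center = pk$center, peak_caafd = pk$caafd,
                 n_windows = nrow(run), alpha = alpha),
            class = "bsa_region")
}

#' @export
print.bsa_region <- function(x, ...) {
  cat(sprintf("CAAFD target region: %s:%.0f-%.0f (%.2f Mb, %d windows)\n",
              x$chrom, x$start, x$end, (x$end - x$start) / 1e6, x$n_windows))
  cat(sprintf("  peak CAAFD %.4f at %s:%.0f\n",
              x$peak_caafd, x$chrom, x$peak_center))
  invisible(x)
}
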