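# Independent oracles and fixture builders shared across test files.

# Brute-force window scan: recomputes every window by direct subsetting
# and mean(), independently of the package's rolling cumulative sums.
naive_scan <- function(markers, window_size = 2e6, step = 1e4) {
  half <- window_size / 2
  out <- list()
  for (cn in unique(markers$chrom)) {
    mk <- markers[markers$chrom == cn, ]
    extent <- max(mk$pos)
    d <- mk$m1 / (mk$m1 + mk$m2) - mk$n1 / (mk$n1 + mk$n2)
    centers <- seq(0, by = step, length.out = ceiling(extent / step))
    for (cc in centers) {
      ws <- max(0, cc - half)
      sel <- mk$pos >= ws + 1 & mk$pos <= cc + half
      if (!any(sel)) next
      out[[length(out) + 1]] <- data.frame(
        chrom = cn, center = cc, n = sum(sel), caafd = mean(d[sel])^3)
    }
  }
  do.call(rbind, out)
}

# Random oriented marker fixture over a couple of chromosomes.
random_marker_fixture <- function(n = 200, n_chrom = 2, span = 5e6,
                                  depth = 20) {
  chrom <- sort(sample(paste0("chr", seq_len(n_chrom)), n, replace = TRUE))
  pos <- unlist(lapply(table(chrom), function(k) {
    sort(sample.int(span, k))
  }), use.names = FALSE)
  dm <- pmax(1L, stats::rpois(n, depth))
  dn <- pmax(1L, stats::rpois(n, depth))
  m1 <- stats::rbinom(n, dm, stats::runif(n))
  n1 <- stats::rbinom(n, dn, stats::runif(n))
  data.frame(chrom = chrom, pos = pos,
             m1 = m1, m2 = dm - m1, n1 = n1, n2 = dn - n1)
}

# Minimal raw-variant row builder for the parental-call / presence tests.
raw_variant_row <- function(chrom = "chr1", pos = 100,
                            m = c(0, 0), n = c(0, 0),
                            p1 = c(0, 0), p2 = c(0, 0),
                            ref = "A", alt = "T") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             m_ref = m[1], m_alt = m[2], n_ref = n[1], n_alt = n[2],
             p1_ref = p1[1], p1_alt = p1[2],
             p2_ref = p2[1], p2_alt = p2[2])
}

# A tiny fast experiment used by several end-to-end tests.
tiny_config <- function(seed = 1L, ...) {
  sim_config(chromosomes = data.frame(name = c("chr1", "chr2"),
                                      length = 6e6),
             marker_spacing = 50000,
             causal_locus = list(chrom = "chr2", pos = 3e6),
             n_f2 = 320, seed = seed, ...)
}
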