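#' Recombination fraction from selected homozygous-recessive plants
#'
#' In an F2, every phenotypically mutant (homozygous recessive) plant
#' carries two mutation-bearing gametes, so each plant contributes two
#' informative gametes at a linked marker: a 93-11 allele on such a
#' gamete is a recombination event.  With marker genotypes A (homozygous
#' MH86), H (heterozygous) and B (homozygous 93-11) among mutants, the
#' recombinant count is R = H + 2B out of G = 2(A+H+B) gametes and the
#' maximum-likelihood estimate is r = R/G (capped at 0.5; the cap can
#' only bind for imported data since R <= G by construction).
#'
#' @param A,H,B genotype counts among mutant plants.
#' @return list of class `bsa_recomb`: A, H, B, R, G, r_hat, lod.
#' @examples
#' estimate_r_selected(188, 10, 1)  # r_hat ~ 0.0302, lod ~ 96
#' @export
estimate_r_selected <- function(A, H, B) {
  if (any(c(A, H, B) < 0)) stop("genotype counts must be >= 0", call. = FALSE)
  if (A + H + B < 1) {
    stop("no genotyped plants (all counts zero)", call. = FALSE)
  }
  R <- H + 2 * B
  G <- 2 * (A + H + B)
  r_hat <- min(R / G, 0.5)
  structure(list(A = A, H = H, B = B, R = R, G = G, r_hat = r_hat,
                 lod = lod_selected(R, G, r_hat)),
            class = "bsa_recomb")
}

#' LOD score of linkage for selected-gamete counts
#'
#' Base-10 log likelihood ratio of the binomial gamete model at `r`
#' against free recombination (r = 0.5):
#' `R*log10(r/0.5) + (G-R)*log10((1-r)/0.5)`.  When R = 0 the first term
#' is zero by convention (so complete cosegregation of G gametes scores
#' `G*log10(2)`).
#'
#' @param R recombinant gametes.
#' @param G total gametes.
#' @param r recombination fraction at which to evaluate (default the MLE
#'   R/G).
#' @return LOD score (>= 0 at the MLE).
#' @examples
#' lod_selected(0, 10)  # 10*log10(2) = 3.0103
#' @export
lod_selected <- function(R, G, r = R / G) {
  t1 <- if (R > 0) R * log10(r / 0.5) else 0
  t2 <- if (G - R > 0) (G - R) * log10((1 - r) / 0.5) else 0
  t1 + t2
}

#' Kosambi mapping function
#'
#' Converts a recombination fraction to map distance,
#' `d = 25 * ln((1+2r)/(1-2r))` cM.  Strictly increasing on \[0, 0.5),
#' diverging as r approaches 0.5.
#'
#' @param r recombination fraction(s) in \[0, 0.5).
#' @return map distance(s) in cM.
#' @examples
#' kosambi(0.2)  # 21.182 cM
#' @export
kosambi <- function(r) {
  if (any(r < 0)) stop("recombination fraction must be >= 0", call. = FALSE)
  if (any(r >= 0.5)) {
    stop("r >= 0.5 corresponds to infinite map distance", call. = FALSE)
  }
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Inverse Kosambi mapping function
#'
#' Recovers the recombination fraction from a Kosambi map distance:
#' `r = (e^(d/25) - 1) / (2 (e^(d/25) + 1))`, i.e. `0.5*tanh(d/50)`.
#'
#' @param d map distance(s) in cM, >= 0.
#' @return recombination fraction(s) in \[0, 0.5).
#' @export
kosambi_inverse <- function(d) {
  if (any(d < 0)) stop("map distance must be >= 0", call. = FALSE)
  0.5 * tanh(d / 50)
}

#' Per-marker linkage table from a mutant fine-mapping panel
#'
#' Counts A/H/B genotypes per marker over the panel's mutant plants,
#' dropping missing genotypes per marker (with a message), and derives
#' recombinant counts, the recombination fraction, Kosambi map distance
#' and LOD score against the trait locus.
#'
#' @param panel fine-mapping panel data.frame (plant_id, phenotype, one
#'   A/H/B column per marker), mutants only.
#' @param marker_positions data.frame(id, chrom, pos) giving the
#'   physical order of the panel's markers.
#' @return data.frame (ordered by position): id, chrom, pos, A, H, B,
#'   n_missing, R, G, r_hat, cM, lod.
#' @export
finemap_markers <- function(panel, marker_positions) {
  ids <- marker_positions$id
  missing_cols <- setdiff(ids, names(panel))
  if (length(missing_cols)) {
    stop("panel lacks marker column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  o <- order(match(marker_positions$chrom, unique(marker_positions$chrom)),
             marker_positions$pos)
  mp <- marker_positions[o, , drop = FALSE]
  rows <- lapply(seq_len(nrow(mp)), function(j) {
    g <- panel[[mp$id[j]]]
    n_missing <- sum(is.na(g))
    g <- g[!is.na(g)]
    A <- sum(g == "A"); H <- sum(g == "H"); B <- sum(g == "B")
    est <- estimate_r_selected(A, H, B)
    data.frame(id = mp$id[j], chrom = mp$chrom[j], pos = mp$pos[j],
               A = A, H = H, B = B, n_missing = n_missing,
               R = est$R, G = est$G, r_hat = est$r_hat,
               cM = if (est$r_hat < 0.5) kosambi(est$r_hat) else Inf,
               lod = est$lod)
  })
  tab <- do.call(rbind, rows)
  if (sum(tab$n_missing) > 0) {
    message("dropped ", sum(tab$n_missing),
            " missing genotype call(s) across markers")
  }
  rownames(tab) <- NULL
  tab
}

#' Delimit the candidate interval from per-marker recombinant counts
#'
#' Finds the contiguous block of markers with the fewest recombinants
#' (ideally zero: complete cosegregation with the trait) and returns the
#' innermost pair of markers with at least one recombinant that bracket
#' it.  A side with no recombinant-bearing marker is reported as open,
#' never silently clipped.
#'
#' @param marker_table output of [finemap_markers()] (physically
#'   ordered); only columns id, pos and R are used.
#' @return Object of class `bsa_interval`: left/right flanking marker id
#'   and position (NA when open), `cosegregating` (ids of
#'   zero-recombinant markers in the core block), `core` (ids of the
#'   minimum-recombinant block), `length_bp` (NA when open) and
#'   `open_left`/`open_right` flags.
#' @export
delimit_interval <- function(marker_table) {
  r <- marker_table$R
  if (nrow(marker_table) < 2) {
    stop("need at least two markers to delimit an interval", call. = FALSE)
  }
  if (all(r == 0)) {
    stop("interval unresolvable: no marker shows any recombinant",
         call. = FALSE)
  }
  m0 <- min(r)
  first_min <- which(r == m0)[1]
  lo <- first_min
  while (lo > 1L && r[lo - 1L] == m0) lo <- lo - 1L
  hi <- first_min
  while (hi < length(r) && r[hi + 1L] == m0) hi <- hi + 1L

  open_left <- lo == 1L
  open_right <- hi == length(r)
  left <- if (open_left) NA_integer_ else lo - 1L
  right <- if (open_right) NA_integer_ else hi + 1L
  if (open_left || open_right) {
    warning("interval is open on the ",
            paste(c("left", "right")[c(open_left, open_right)],
                  collapse = " and "),
            " side: no flanking recombinant marker")
  }
  structure(list(
    left_id = if (open_left) NA_character_ else marker_table$id[left],
    left_pos = if (open_left) NA_real_ else marker_table$pos[left],
    right_id = if (open_right) NA_character_ else marker_table$id[right],
    right_pos = if (open_right) NA_real_ else marker_table$pos[right],
    chrom = marker_table$chrom[first_min],
    core = marker_table$id[lo:hi],
    cosegregating = marker_table$id[lo:hi][r[lo:hi] == 0],
    min_recombinants = m0,
    length_bp = if (open_left || open_right) NA_real_ else
      marker_table$pos[right] - marker_table$pos[left],
    open_left = open_left, open_right = open_right),
    class = "bsa_interval")
}

#' @export
print.bsa_interval <- function(x, ...) {
  l <- if (x$open_left) "(open)" else sprintf("%s @ %.0f", x$left_id, x$left_pos)
  r <- if (x$open_right) "(open)" else sprintf("%s @ %.0f", x$right_id, x$right_pos)
  cat("Candidate interval:", l, "--", r)
  if (!is.na(x$length_bp)) cat(sprintf("  (%.0f kb)", x$length_bp / 1e3))
  cat("\n")
  if (length(x$cosegregating)) {
    cat("  cosegregating markers:", paste(x$cosegregating, collapse = ", "),
        "\n")
  }
  invisible(x)
}
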