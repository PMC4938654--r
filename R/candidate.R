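#' Allele presence calls for candidate variants
#'
#' For each of the four sample groups (M-pool, N-pool, parent 1, parent
#' 2) decides which alleles are genuinely present.  An allele counts as
#' present when it has at least `min_support` reads and its read
#' fraction exceeds `max_contam_fraction` (so a stray error read in an
#' otherwise pure sample is treated as noise).  A group with zero depth
#' — or in which no allele reaches the thresholds — is reported as
#' `"no_data"`, never silently as absence.
#'
#' The alt allele is the candidate mutant allele ("-"), the ref allele
#' the wild type ("+").
#'
#' @param variants raw variant data.frame with count columns m_ref,
#'   m_alt, n_ref, n_alt, p1_ref, p1_alt, p2_ref, p2_alt.
#' @param min_support minimum reads supporting a present allele
#'   (default 2).
#' @param max_contam_fraction allele fractions at or below this are
#'   treated as contamination/noise (default 0.05).
#' @return data.frame with one call per group (columns m_pool, n_pool,
#'   parent1, parent2), each one of "mutant_only", "wildtype_only",
#'   "both", "no_data".
#' @export
classify_presence <- function(variants, min_support = 2,
                              max_contam_fraction = 0.05) {
  call_group <- function(ref, alt) {
    depth <- ref + alt
    pres_ref <- ref >= min_support & ref / pmax(depth, 1L) > max_contam_fraction
    pres_alt <- alt >= min_support & alt / pmax(depth, 1L) > max_contam_fraction
    out <- rep("no_data", length(ref))
    out[pres_ref & !pres_alt] <- "wildtype_only"
    out[pres_alt & !pres_ref] <- "mutant_only"
    out[pres_ref & pres_alt] <- "both"
    out
  }
  data.frame(
    m_pool = call_group(variants$m_ref, variants$m_alt),
    n_pool = call_group(variants$n_ref, variants$n_alt),
    parent1 = call_group(variants$p1_ref, variants$p1_alt),
    parent2 = call_group(variants$p2_ref, variants$p2_alt))
}

#' Presence-pattern filter for the causal variant
#'
#' Inside the mapped interval, the causal recessive variant must show
#' the mutant allele ("-") alone in the M-pool, both alleles in the
#' N-pool (which mixes +/+ and -/+ plants), and the wild-type allele
#' alone in both sequenced parents (the mutation arose after the
#' parental lines, so neither carries it).  Variants matching that exact
#' presence pattern are kept; variants for which any group returned
#' `"no_data"` are set aside in an `undetermined` table rather than
#' rejected.
#'
#' @inheritParams classify_presence
#' @return list of class `bsa_candidates` with `candidates` (matching
#'   variants, genomic order), `undetermined` and `calls` (the full
#'   presence table).
#' @export
filter_candidates <- function(variants, min_support = 2,
                              max_contam_fraction = 0.05) {
  if (nrow(variants) == 0) {
    return(structure(list(candidates = variants, undetermined = variants,
                          calls = classify_presence(variants)),
                     class = "bsa_candidates"))
  }
  o <- order(match(variants$chrom, unique(variants$chrom)), variants$pos)
  variants <- variants[o, , drop = FALSE]
  calls <- classify_presence(variants, min_support, max_contam_fraction)
  match_pattern <- calls$m_pool == "mutant_only" &
    calls$n_pool == "both" &
    calls$parent1 == "wildtype_only" &
    calls$parent2 == "wildtype_only"
  any_nodata <- apply(calls == "no_data", 1L, any)
  res <- structure(list(
    candidates = variants[match_pattern, , drop = FALSE],
    undetermined = variants[!match_pattern & any_nodata, , drop = FALSE],
    calls = calls),
    class = "bsa_candidates")
  rownames(res$candidates) <- NULL
  rownames(res$undetermined) <- NULL
  res
}

#' @export
print.bsa_candidates <- function(x, ...) {
  cat(sprintf("Candidate screen: %d variant(s) match the presence pattern",
              nrow(x$candidates)))
  if (nrow(x$undetermined)) {
    cat(sprintf(" (%d undetermined)", nrow(x$undetermined)))
  }
  cat("\n")
  if (nrow(x$candidates)) {
    print(x$candidates[, c("chrom", "pos", "ref", "alt")], row.names = FALSE)
  }
  invisible(x)
}

#' Cosegregation test of a candidate variant in an F2 panel
#'
#' Checks whether the candidate genotype segregates perfectly with the
#' phenotype: every mutant plant must be homozygous for the mutant
#' allele (-/-) and every normal plant heterozygous (-/+) or homozygous
#' wild type (+/+).
#'
#' @param panel data.frame with columns plant_id, phenotype
#'   ("mutant"/"normal") and genotype ("-/-", "-/+", "+/+").
#' @return Object of class `bsa_coseg`: genotype-by-phenotype count
#'   table, `concordant` flag and `discordant_ids`.
#' @export
cosegregation_test <- function(panel) {
  if (is.null(panel) || nrow(panel) == 0) {
    stop("cosegregation panel is empty", call. = FALSE)
  }
  if (anyNA(panel$genotype) || anyNA(panel$phenotype)) {
    stop("every plant needs both a genotype and a phenotype", call. = FALSE)
  }
  counts <- table(phenotype = factor(panel$phenotype,
                                     c("mutant", "normal")),
                  genotype = factor(panel$genotype,
                                    c("-/-", "-/+", "+/+")))
  bad <- (panel$phenotype == "mutant" & panel$genotype != "-/-") |
    (panel$phenotype == "normal" & panel$genotype == "-/-")
  structure(list(counts = counts,
                 concordant = !any(bad),
                 discordant_ids = panel$plant_id[bad]),
            class = "bsa_coseg")
}

#' @export
print.bsa_coseg <- function(x, ...) {
  cat("Cosegregation test:",
      if (x$concordant) "CONCORDANT" else
        paste0("discordant (", length(x$discordant_ids), " plant(s): ",
               paste(x$discordant_ids, collapse = ", "), ")"), "\n")
  print(x$counts)
  invisible(x)
}
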