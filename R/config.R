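#' Configuration for a synthetic BSA-seq experiment
#'
#' Describes the genome layout, the causal locus, the F2 population and
#' bulk sizes, sequencing depths and error rates of a simulated
#' bulked-segregant experiment.  The defaults reproduce the design of a
#' typical rice F2 mapping cross: bulks of 50 mutant and 50 phenotypically
#' normal plants sequenced at ~12x per pool, parents at ~50x and ~30x.
#'
#' @param chromosomes data.frame with columns `name` and `length` (bp).
#'   Default: five 30-Mb chromosomes.
#' @param marker_spacing distance in bp between simulated markers
#'   (parental SNP/InDel polymorphisms) along each chromosome.
#' @param causal_locus list with elements `chrom` and `pos` (bp): the
#'   position of the recessive causal mutation.  The mutation sits on the
#'   mutant-parent-derived (MH86) haplotype; the sequenced parents are both
#'   wild type at this site.
#' @param n_f2 number of F2 plants to simulate.
#' @param bulk_size_mutant,bulk_size_normal number of plants pooled into
#'   the M-pool and N-pool.
#' @param depth_pool mean sequencing depth per marker per pool (Poisson).
#' @param depth_parent1,depth_parent2 mean depths for parent 1 (MH86) and
#'   parent 2 (93-11).
#' @param base_error probability that a sampled read reports the wrong
#'   allele.
#' @param phenotyping_error probability that a plant's phenotype label is
#'   flipped before bulking.
#' @param cm_per_mb genetic-to-physical scale in cM per Mb.  The default 4
#'   (1 cM = 250 kb) is a rice-typical order of magnitude.
#' @param seed integer seed for the simulator's random number stream.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_f2 = 200, seed = 42)
#' cfg$causal_locus
#' @export
sim_config <- function(chromosomes = data.frame(name = paste0("chr", 1:5),
                                                length = 30e6),
                       marker_spacing = 5000,
                       causal_locus = list(chrom = "chr4", pos = 25e6),
                       n_f2 = 300,
                       bulk_size_mutant = 50,
                       bulk_size_normal = 50,
                       depth_pool = 12,
                       depth_parent1 = 50,
                       depth_parent2 = 30,
                       base_error = 0.01,
                       phenotyping_error = 0,
                       cm_per_mb = 4,
                       seed = 1L) {
  cfg <- structure(list(chromosomes = chromosomes,
                        marker_spacing = marker_spacing,
                        causal_locus = causal_locus,
                        n_f2 = n_f2,
                        bulk_size_mutant = bulk_size_mutant,
                        bulk_size_normal = bulk_size_normal,
                        depth_pool = depth_pool,
                        depth_parent1 = depth_parent1,
                        depth_parent2 = depth_parent2,
                        base_error = base_error,
                        phenotyping_error = phenotyping_error,
                        cm_per_mb = cm_per_mb,
                        seed = as.integer(seed)),
                   class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks every field of a [sim_config()] and stops with the offending
#' field name on the first violation.
#'
#' @param cfg a `sim_config` object (or plain list with the same fields).
#' @return `cfg`, invisibly, if valid.
#' @export
validate_sim_config <- function(cfg) {
  fail <- function(field, why) {
    stop("invalid sim_config field '", field, "': ", why, call. = FALSE)
  }
  ch <- cfg$chromosomes
  if (is.null(ch) || !is.data.frame(ch) ||
      !all(c("name", "length") %in% names(ch)) || nrow(ch) < 1) {
    fail("chromosomes", "need a data.frame with columns 'name' and 'length'")
  }
  if (anyDuplicated(ch$name)) fail("chromosomes", "duplicated chromosome names")
  if (any(ch$length <= 0)) fail("chromosomes", "lengths must be > 0")
  if (is.null(cfg$marker_spacing) || cfg$marker_spacing <= 0) {
    fail("marker_spacing", "must be > 0")
  }
  cl <- cfg$causal_locus
  if (is.null(cl) || is.null(cl$chrom) || is.null(cl$pos)) {
    fail("causal_locus", "need list(chrom=, pos=)")
  }
  if (!cl$chrom %in% ch$name) {
    fail("causal_locus", paste0("chromosome '", cl$chrom, "' not in genome"))
  }
  if (cl$pos < 1 || cl$pos > ch$length[match(cl$chrom, ch$name)]) {
    fail("causal_locus", "position outside its chromosome")
  }
  for (f in c("n_f2", "bulk_size_mutant", "bulk_size_normal",
              "depth_pool", "depth_parent1", "depth_parent2", "cm_per_mb")) {
    if (is.null(cfg[[f]]) || !is.numeric(cfg[[f]]) || cfg[[f]] <= 0) {
      fail(f, "must be > 0")
    }
  }
  for (f in c("base_error", "phenotyping_error")) {
    if (is.null(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] >= 0.5) {
      fail(f, "must be in [0, 0.5)")
    }
  }
  if (is.null(cfg$seed) || is.na(cfg$seed)) fail("seed", "must be an integer")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("BSA-seq simulation config\n")
  cat(sprintf("  genome: %d chromosome(s), %.1f Mb total, markers every %g bp\n",
              nrow(x$chromosomes), sum(x$chromosomes$length) / 1e6,
              x$marker_spacing))
  cat(sprintf("  causal locus: %s:%d (recessive, on MH86 haplotype)\n",
              x$causal_locus$chrom, as.integer(x$causal_locus$pos)))
  cat(sprintf("  F2 plants: %d; bulks %d mutant / %d normal\n",
              x$n_f2, x$bulk_size_mutant, x$bulk_size_normal))
  cat(sprintf("  depths: pools %gx, parents %gx/%gx; base error %g; seed %d\n",
              x$depth_pool, x$depth_parent1, x$depth_parent2,
              x$base_error, x$seed))
  invisible(x)
}
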