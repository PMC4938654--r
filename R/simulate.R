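#' Simulate an F2 population from a heterozygous F1
#'
#' Forward-simulates `n_f2` plants, each the fusion of two independent
#' gametes drawn from an F1 that is heterozygous genome-wide (one
#' MH86-derived haplotype carrying the recessive mutation, one
#' 93-11-derived haplotype).  Crossovers follow a no-interference model:
#' along the evaluation grid the gamete allele is a two-state Markov chain
#' whose switch probability between adjacent positions is the Haldane
#' recombination fraction for their genetic distance — the exact marginal
#' of a Poisson-count, uniform-position crossover process at those
#' positions.
#'
#' The evaluation grid is the regular marker grid (every
#' `marker_spacing` bp) plus the causal position itself, so the causal
#' genotype is exact even when the locus falls between markers.
#' A plant is phenotypically mutant iff it is homozygous for the
#' MH86-derived allele at the causal locus; the recorded label is then
#' flipped with probability `phenotyping_error`.
#'
#' @param config a [sim_config()].
#' @return An object of class `bsa_population`: a list with the marker
#'   grid (`grid`: chrom, pos, is_causal), haplotype matrices `hap1` and
#'   `hap2` (grid rows x plants; 1 = MH86-derived allele, 0 = 93-11),
#'   `causal_geno` (copies of the mutant allele, 0/1/2), `phenotype_true`
#'   and `phenotype` ("mutant"/"normal"), and the config.
#' @seealso [make_bulks()], [simulate_pool_counts()], [simulate_panels()]
#' @export
simulate_f2_population <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  grid <- marker_grid(config)
  n_gam <- 2L * config$n_f2
  morgans_per_bp <- config$cm_per_mb / 1e6 / 100

  hap <- matrix(0L, nrow(grid), n_gam)
  for (cn in config$chromosomes$name) {
    rows <- which(grid$chrom == cn)
    hap[rows, ] <- sim_gametes_chrom(grid$pos[rows], morgans_per_bp, n_gam)
  }
  hap1 <- hap[, seq(1L, n_gam, by = 2L), drop = FALSE]
  hap2 <- hap[, seq(2L, n_gam, by = 2L), drop = FALSE]

  crow <- which(grid$is_causal)
  causal_geno <- hap1[crow, ] + hap2[crow, ]
  phenotype_true <- ifelse(causal_geno == 2L, "mutant", "normal")
  phenotype <- phenotype_true
  if (config$phenotyping_error > 0) {
    flip <- stats::runif(config$n_f2) < config$phenotyping_error
    phenotype[flip] <- ifelse(phenotype_true[flip] == "mutant",
                              "normal", "mutant")
  }

  structure(list(grid = grid, hap1 = hap1, hap2 = hap2,
                 causal_geno = causal_geno,
                 phenotype_true = phenotype_true,
                 phenotype = phenotype,
                 config = config),
            class = "bsa_population")
}

# Evaluation grid: regular markers plus the causal position (flagged).
marker_grid <- function(config) {
  parts <- lapply(seq_len(nrow(config$chromosomes)), function(i) {
    cn <- config$chromosomes$name[i]
    len <- config$chromosomes$length[i]
    pos <- seq(config$marker_spacing, len, by = config$marker_spacing)
    data.frame(chrom = cn, pos = pos, is_causal = FALSE)
  })
  grid <- do.call(rbind, parts)
  cl <- config$causal_locus
  hit <- grid$chrom == cl$chrom & grid$pos == cl$pos
  if (any(hit)) {
    grid$is_causal[hit] <- TRUE
  } else {
    grid <- rbind(grid, data.frame(chrom = cl$chrom, pos = cl$pos,
                                   is_causal = TRUE))
  }
  grid <- grid[order(match(grid$chrom, config$chromosomes$name), grid$pos), ]
  rownames(grid) <- NULL
  grid
}

# One chromosome's gametes as a positions x gametes 0/1 matrix.
# Adjacent switch probabilities are Haldane r's, so any pair of positions
# recombines at the Haldane fraction of their genetic distance.
sim_gametes_chrom <- function(pos, morgans_per_bp, n_gam) {
  k <- length(pos)
  start <- sample(c(0L, 1L), n_gam, replace = TRUE)
  if (k == 1L) return(matrix(start, 1L, n_gam))
  r_adj <- 0.5 * (1 - exp(-2 * diff(pos) * morgans_per_bp))
  sw <- matrix(stats::rbinom((k - 1L) * n_gam, 1L, rep(r_adj, times = n_gam)),
               k - 1L, n_gam)
  cum <- apply(sw, 2L, cumsum)
  rbind(start, (cum + rep(start, each = k - 1L)) %% 2L, deparse.level = 0)
}

#' @export
print.bsa_population <- function(x, ...) {
  cat(sprintf("F2 population: %d plants, %d grid positions (%d mutant / %d normal)\n",
              x$config$n_f2, nrow(x$grid),
              sum(x$phenotype == "mutant"), sum(x$phenotype == "normal")))
  invisible(x)
}

#' Draw the mutant and normal DNA bulks
#'
#' Samples `bulk_size_mutant` plants uniformly without replacement from
#' the plants labelled mutant and `bulk_size_normal` from those labelled
#' normal, emulating the pooling of leaf samples into the M-pool and
#' N-pool.  Uses the current RNG stream (seed once per experiment, e.g.
#' via [simulate_f2_population()] or [simulate_experiment()]).
#'
#' @param pop a `bsa_population`.
#' @param config the [sim_config()] used to create it.
#' @return list with integer plant-index vectors `mutant` and `normal`.
#' @export
make_bulks <- function(pop, config = pop$config) {
  mut <- which(pop$phenotype == "mutant")
  nor <- which(pop$phenotype == "normal")
  if (length(mut) < config$bulk_size_mutant) {
    stop("cannot form M-pool: need ", config$bulk_size_mutant,
         " mutant plants but the population has only ", length(mut),
         call. = FALSE)
  }
  if (length(nor) < config$bulk_size_normal) {
    stop("cannot form N-pool: need ", config$bulk_size_normal,
         " normal plants but the population has only ", length(nor),
         call. = FALSE)
  }
  list(mutant = sort(sample(mut, config$bulk_size_mutant)),
       normal = sort(sample(nor, config$bulk_size_normal)))
}

# True MH86-allele frequency of a plant set at every grid row.
bulk_freq <- function(pop, plants) {
  (rowSums(pop$hap1[, plants, drop = FALSE]) +
     rowSums(pop$hap2[, plants, drop = FALSE])) / (2 * length(plants))
}

#' Simulate pooled sequencing allele counts over the marker grid
#'
#' For every (non-causal) marker and each pool, read depth is
#' Poisson(`depth_pool`); each read samples one of the bulk's
#' `2 x bulk size` haplotypes uniformly and reports its allele correctly
#' with probability `1 - base_error`.  Parents are sequenced from fixed
#' homozygous genotypes (parent 1 = MH86 allele, parent 2 = the other) at
#' their own depths.  Marker ref/alt bases are random and the MH86 allele
#' is randomly ref or alt, so downstream orientation is exercised.
#'
#' @param pop a `bsa_population`.
#' @param bulks result of [make_bulks()].
#' @param config the [sim_config()].
#' @return Object of class `bsa_marker_table`: list with `markers` (one
#'   row per marker: chrom, pos, mh86_allele, other_allele, m1, m2, n1,
#'   n2, p1_ref_count, p1_alt_count, p2_ref_count, p2_alt_count, ref,
#'   alt) and `truth` (chrom, pos, true_fm, true_fn — exact bulk
#'   MH86-allele frequencies).
#' @export
simulate_pool_counts <- function(pop, bulks, config = pop$config) {
  keep <- !pop$grid$is_causal
  fm <- bulk_freq(pop, bulks$mutant)[keep]
  fn <- bulk_freq(pop, bulks$normal)[keep]
  n <- sum(keep)
  e <- config$base_error

  noisy_counts <- function(freq, depth_mean) {
    depth <- stats::rpois(n, depth_mean)
    a <- stats::rbinom(n, depth, freq * (1 - e) + (1 - freq) * e)
    cbind(a, depth - a)
  }
  mc <- noisy_counts(fm, config$depth_pool)
  nc <- noisy_counts(fn, config$depth_pool)
  p1 <- noisy_counts(rep(1, n), config$depth_parent1)  # MH86 is homozygous MH86-allele
  p2 <- noisy_counts(rep(0, n), config$depth_parent2)

  bases <- c("A", "C", "G", "T")
  mh86_allele <- sample(bases, n, replace = TRUE)
  other_allele <- vapply(mh86_allele,
                         function(b) sample(setdiff(bases, b), 1L), "")
  mh86_is_ref <- sample(c(TRUE, FALSE), n, replace = TRUE)

  markers <- data.frame(
    chrom = pop$grid$chrom[keep],
    pos = pop$grid$pos[keep],
    mh86_allele = mh86_allele,
    other_allele = other_allele,
    m1 = mc[, 1], m2 = mc[, 2],
    n1 = nc[, 1], n2 = nc[, 2],
    p1_ref_count = ifelse(mh86_is_ref, p1[, 1], p1[, 2]),
    p1_alt_count = ifelse(mh86_is_ref, p1[, 2], p1[, 1]),
    p2_ref_count = ifelse(mh86_is_ref, p2[, 1], p2[, 2]),
    p2_alt_count = ifelse(mh86_is_ref, p2[, 2], p2[, 1]),
    ref = ifelse(mh86_is_ref, mh86_allele, other_allele),
    alt = ifelse(mh86_is_ref, other_allele, mh86_allele))

  truth <- data.frame(chrom = markers$chrom, pos = markers$pos,
                      true_fm = fm, true_fn = fn)
  structure(list(markers = markers, truth = truth), class = "bsa_marker_table")
}

#' Convert an oriented marker table to four-sample raw variant counts
#'
#' Reshapes the simulator's oriented counts (MH86/other) into the ref/alt
#' layout a variant caller would emit, the input format of
#' [select_markers()]/[prepare_markers()].
#'
#' @param mt a `bsa_marker_table` (or its `markers` data.frame).
#' @return data.frame with chrom, pos, ref, alt and ref/alt counts for
#'   m_pool, n_pool, parent1, parent2.
#' @export
as_raw_variants <- function(mt) {
  m <- if (inherits(mt, "bsa_marker_table")) mt$markers else mt
  mh86_is_ref <- m$ref == m$mh86_allele
  data.frame(
    chrom = m$chrom, pos = m$pos, ref = m$ref, alt = m$alt,
    m_ref = ifelse(mh86_is_ref, m$m1, m$m2),
    m_alt = ifelse(mh86_is_ref, m$m2, m$m1),
    n_ref = ifelse(mh86_is_ref, m$n1, m$n2),
    n_alt = ifelse(mh86_is_ref, m$n2, m$n1),
    p1_ref = m$p1_ref_count, p1_alt = m$p1_alt_count,
    p2_ref = m$p2_ref_count, p2_alt = m$p2_alt_count)
}

#' Simulate the fine-mapping and cosegregation genotyping panels
#'
#' The fine-mapping panel contains only mutant plants (as selected for
#' recessive fine mapping) with marker genotypes coded A (homozygous
#' MH86), H (heterozygous), B (homozygous 93-11) read from the true
#' haplotypes.  The cosegregation panel is a uniform random sample of F2
#' plants with the genotype at the causal variant (-/-, -/+, +/+) and the
#' phenotype label.
#'
#' @param pop a `bsa_population`.
#' @param config the [sim_config()].
#' @param n_finemap number of mutant plants to genotype (default 199).
#' @param n_coseg size of the random cosegregation sample (default 280).
#' @param panel_markers data.frame(id, chrom, pos) of markers to type in
#'   the fine-mapping panel; positions must lie on the simulated grid.
#'   Default: grid markers nearest to a ladder of offsets around the
#'   causal locus.
#' @return list with data.frames `finemap` (plant_id, phenotype, one
#'   column per marker) and `coseg` (plant_id, phenotype, genotype), plus
#'   `panel_markers`.
#' @export
simulate_panels <- function(pop, config = pop$config,
                            n_finemap = 199, n_coseg = 280,
                            panel_markers = NULL) {
  if (is.null(panel_markers)) {
    panel_markers <- default_panel_markers(pop, config)
  }
  rows <- match_grid_rows(pop, panel_markers)

  mut <- which(pop$phenotype == "mutant")
  if (length(mut) < n_finemap) {
    stop("fine-mapping panel needs ", n_finemap,
         " mutant plants but the population has only ", length(mut),
         call. = FALSE)
  }
  if (config$n_f2 < n_coseg) {
    stop("cosegregation panel needs ", n_coseg,
         " plants but the population has only ", config$n_f2, call. = FALSE)
  }

  fm_plants <- sort(sample(mut, n_finemap))
  geno <- pop$hap1[rows, fm_plants, drop = FALSE] +
    pop$hap2[rows, fm_plants, drop = FALSE]
  code <- matrix(c("B", "H", "A")[geno + 1L], nrow(geno), ncol(geno))
  finemap <- data.frame(plant_id = fm_plants,
                        phenotype = pop$phenotype[fm_plants])
  for (j in seq_len(nrow(panel_markers))) {
    finemap[[panel_markers$id[j]]] <- code[j, ]
  }

  cs_plants <- sort(sample(config$n_f2, n_coseg))
  coseg <- data.frame(
    plant_id = cs_plants,
    phenotype = pop$phenotype[cs_plants],
    genotype = c("+/+", "-/+", "-/-")[pop$causal_geno[cs_plants] + 1L])

  list(finemap = finemap, coseg = coseg, panel_markers = panel_markers)
}

default_panel_markers <- function(pop, config) {
  cl <- config$causal_locus
  offsets <- c(-2, -1, -0.5, -0.25, 0.25, 0.5, 1, 2) * 1e6
  target <- cl$pos + offsets
  on_chrom <- pop$grid[pop$grid$chrom == cl$chrom & !pop$grid$is_causal, ]
  target <- target[target >= min(on_chrom$pos) & target <= max(on_chrom$pos)]
  pos <- unique(vapply(target, function(p) {
    on_chrom$pos[which.min(abs(on_chrom$pos - p))]
  }, numeric(1)))
  pos <- sort(pos)
  data.frame(id = paste0("PM_", seq_along(pos)), chrom = cl$chrom, pos = pos)
}

match_grid_rows <- function(pop, panel_markers) {
  key <- paste(pop$grid$chrom, pop$grid$pos)
  rows <- match(paste(panel_markers$chrom, panel_markers$pos), key)
  if (anyNA(rows)) {
    bad <- panel_markers$id[is.na(rows)]
    stop("panel markers not on the simulated grid: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  rows
}

#' Run the full synthetic experiment in one call
#'
#' Seeds the RNG once from the config, then simulates the population,
#' draws the bulks and generates pooled allele counts, so a fixed seed
#' yields a bit-identical marker table.
#'
#' @param config a [sim_config()].
#' @return list with `pop`, `bulks` and `counts` (a `bsa_marker_table`).
#' @export
simulate_experiment <- function(config) {
  pop <- simulate_f2_population(config)  # seeds the stream
  bulks <- make_bulks(pop, config)
  counts <- simulate_pool_counts(pop, bulks, config)
  list(pop = pop, bulks = bulks, counts = counts)
}

#' Simulate candidate variants inside a mapped region
#'
#' Generates four-sample allele counts for `n_background` background
#' variants plus the implanted causal variant inside a called region, for
#' testing the presence-pattern candidate filter.  Background variants
#' are a mixture of ordinary MH86/93-11 polymorphisms (alt allele on the
#' 93-11 haplotype), variants private to the MH86 parent (alt on the MH86
#' haplotype), and sequencing-noise sites with no true alt allele.  Only
#' the causal variant is absent from both parents yet carried by the
#' mutation haplotype.  All sites are synthetic; a `truth` column labels
#' each row.
#'
#' @param pop a `bsa_population`.
#' @param bulks result of [make_bulks()].
#' @param region a `bsa_region` (from [call_peak_region()]) or any list
#'   with `chrom`, `start`, `end` in bp.
#' @param n_background number of background variants (default 500).
#' @param depth_pool,depth_parent1,depth_parent2,base_error sequencing
#'   model parameters; default to the population's config.
#' @return data.frame of raw variants (chrom, pos, ref, alt, truth, and
#'   ref/alt counts per sample) sorted by position.
#' @export
simulate_candidate_variants <- function(pop, bulks, region,
                                        n_background = 500,
                                        depth_pool = pop$config$depth_pool,
                                        depth_parent1 = pop$config$depth_parent1,
                                        depth_parent2 = pop$config$depth_parent2,
                                        base_error = pop$config$base_error) {
  cl <- pop$config$causal_locus
  if (region$chrom != cl$chrom || cl$pos < region$start || cl$pos > region$end) {
    warning("causal locus is outside the given region; only background ",
            "variants will be generated")
    causal_pos <- numeric(0)
  } else {
    causal_pos <- cl$pos
  }
  span <- max(region$start, 1):region$end
  pos_bg <- sort(sample(setdiff(span, causal_pos), n_background))
  type <- sample(c("parental_poly", "parent1_private", "noise"),
                 n_background, replace = TRUE, prob = c(0.6, 0.2, 0.2))
  pos <- c(pos_bg, causal_pos)
  type <- c(type, rep("causal", length(causal_pos)))
  o <- order(pos)
  pos <- pos[o]; type <- type[o]

  # mutation-haplotype frequency at the nearest grid marker (grid spacing
  # is genetically negligible relative to these distances)
  on_chrom <- which(pop$grid$chrom == region$chrom)
  near <- on_chrom[findInterval(pos, pop$grid$pos[on_chrom],
                                all.inside = TRUE)]
  fm_loc <- bulk_freq(pop, bulks$mutant)[near]
  fn_loc <- bulk_freq(pop, bulks$normal)[near]

  # alt-allele frequency per sample group, by variant type
  alt_m <- ifelse(type == "causal", fm_loc,
           ifelse(type == "parental_poly", 1 - fm_loc,
           ifelse(type == "parent1_private", fm_loc, 0)))
  alt_n <- ifelse(type == "causal", fn_loc,
           ifelse(type == "parental_poly", 1 - fn_loc,
           ifelse(type == "parent1_private", fn_loc, 0)))
  alt_p1 <- ifelse(type == "parent1_private", 1, 0)
  alt_p2 <- ifelse(type == "parental_poly", 1, 0)

  n <- length(pos)
  e <- base_error
  draw <- function(freq, depth_mean) {
    depth <- stats::rpois(n, depth_mean)
    a <- stats::rbinom(n, depth, freq * (1 - e) + (1 - freq) * e)
    cbind(depth - a, a)  # ref, alt
  }
  m <- draw(alt_m, depth_pool); nn <- draw(alt_n, depth_pool)
  p1 <- draw(alt_p1, depth_parent1); p2 <- draw(alt_p2, depth_parent2)

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  data.frame(chrom = region$chrom, pos = pos, ref = ref, alt = alt,
             truth = type,
             m_ref = m[, 1], m_alt = m[, 2],
             n_ref = nn[, 1], n_alt = nn[, 2],
             p1_ref = p1[, 1], p1_alt = p1[, 2],
             p2_ref = p2[, 1], p2_alt = p2[, 2])
}
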