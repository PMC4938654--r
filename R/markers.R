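#' Call parental alleles and orientation for raw variants
#'
#' A variant is usable as a mapping marker only if it shows an explicit
#' polymorphism between the two parents: each parent must have total
#' depth `>= min_parent_depth` with at least a fraction `purity` of its
#' reads on one allele, and the two parents' majority alleles must
#' differ.  The accepted orientation labels which of ref/alt is the MH86
#' (parent 1) allele.
#'
#' @param raw data.frame of raw biallelic variants with columns chrom,
#'   pos, ref, alt, m_ref, m_alt, n_ref, n_alt, p1_ref, p1_alt, p2_ref,
#'   p2_alt (parent 1 = MH86, parent 2 = 93-11).
#' @param purity minimum majority-allele fraction per parent (default 0.9).
#' @param min_parent_depth minimum per-parent depth (default 10).
#' @return `raw` with added columns `accepted` (logical), `reject_reason`
#'   (NA when accepted) and `mh86_is_ref`.
#' @export
call_parental_alleles <- function(raw, purity = 0.9, min_parent_depth = 10) {
  d1 <- raw$p1_ref + raw$p1_alt
  d2 <- raw$p2_ref + raw$p2_alt
  maj1_ref <- raw$p1_ref >= raw$p1_alt
  maj2_ref <- raw$p2_ref >= raw$p2_alt
  pur1 <- pmax(raw$p1_ref, raw$p1_alt) / pmax(d1, 1L)
  pur2 <- pmax(raw$p2_ref, raw$p2_alt) / pmax(d2, 1L)

  reason <- rep(NA_character_, nrow(raw))
  reason[maj1_ref == maj2_ref] <- "monomorphic"
  reason[pur2 < purity] <- "low_purity_parent2"
  reason[pur1 < purity] <- "low_purity_parent1"
  reason[d2 < min_parent_depth] <- "low_depth_parent2"
  reason[d1 < min_parent_depth] <- "low_depth_parent1"

  raw$accepted <- is.na(reason)
  raw$reject_reason <- reason
  raw$mh86_is_ref <- maj1_ref
  raw
}

#' Orient accepted variants into MH86/93-11 allele counts
#'
#' Keeps variants accepted by [call_parental_alleles()] and relabels
#' their pool counts so that `m1`/`n1` count the MH86 allele and
#' `m2`/`n2` the 93-11 allele — the orientation used by the CAAFD
#' statistic.
#'
#' @param called output of [call_parental_alleles()].
#' @return data.frame with chrom, pos, mh86_allele, other_allele, m1,
#'   m2, n1, n2.
#' @export
orient_counts <- function(called) {
  stopifnot(all(c("accepted", "mh86_is_ref") %in% names(called)))
  v <- called[called$accepted, , drop = FALSE]
  data.frame(
    chrom = v$chrom, pos = v$pos,
    mh86_allele = ifelse(v$mh86_is_ref, v$ref, v$alt),
    other_allele = ifelse(v$mh86_is_ref, v$alt, v$ref),
    m1 = ifelse(v$mh86_is_ref, v$m_ref, v$m_alt),
    m2 = ifelse(v$mh86_is_ref, v$m_alt, v$m_ref),
    n1 = ifelse(v$mh86_is_ref, v$n_ref, v$n_alt),
    n2 = ifelse(v$mh86_is_ref, v$n_alt, v$n_ref))
}

#' MH86-allele frequencies of a marker in the two pools
#'
#' fM = m1/(m1+m2) and fN = n1/(n1+n2).  Markers with zero total depth
#' in either pool are unusable: their frequencies are NA and
#' `usable = FALSE`.
#'
#' @param m1,m2,n1,n2 oriented allele counts (vectors).
#' @return data.frame with fm, fn, usable.
#' @export
pool_frequencies <- function(m1, m2, n1, n2) {
  dm <- m1 + m2
  dn <- n1 + n2
  usable <- dm > 0 & dn > 0
  data.frame(fm = ifelse(dm > 0, m1 / dm, NA_real_),
             fn = ifelse(dn > 0, n1 / dn, NA_real_),
             usable = usable)
}

#' Select mapping markers by pool depth and mean allele frequency
#'
#' Keeps oriented markers whose pools both reach `min_pool_depth` and
#' whose mean MH86-allele frequency over the two pools,
#' (fM + fN)/2, lies in the closed interval
#' `[freq_low, freq_high]` (default 0.3–0.7).  Genomic order is
#' preserved; per-reason rejection tallies are attached.
#'
#' @param markers oriented marker data.frame (columns chrom, pos, m1,
#'   m2, n1, n2), e.g. from [orient_counts()] or a previous selection.
#' @param freq_low,freq_high closed bounds on the mean pool frequency.
#' @param min_pool_depth minimum depth per pool (default 4).
#' @return The selected subset with added columns fm, fn, mean_f, and an
#'   attribute `"rejections"` (named integer vector).
#' @export
select_markers <- function(markers, freq_low = 0.3, freq_high = 0.7,
                           min_pool_depth = 4) {
  if (nrow(markers) == 0) {
    out <- cbind(markers, fm = numeric(0), fn = numeric(0),
                 mean_f = numeric(0))
    attr(out, "rejections") <- c(zero_depth = 0L, low_pool_depth = 0L,
                                 mean_freq_out_of_range = 0L)
    return(out)
  }
  fq <- pool_frequencies(markers$m1, markers$m2, markers$n1, markers$n2)
  mean_f <- (fq$fm + fq$fn) / 2
  depth_ok <- markers$m1 + markers$m2 >= min_pool_depth &
    markers$n1 + markers$n2 >= min_pool_depth
  freq_ok <- !is.na(mean_f) & mean_f >= freq_low & mean_f <= freq_high

  keep <- fq$usable & depth_ok & freq_ok
  rej <- c(zero_depth = sum(!fq$usable),
           low_pool_depth = sum(fq$usable & !depth_ok),
           mean_freq_out_of_range = sum(fq$usable & depth_ok & !freq_ok))

  out <- markers[keep, , drop = FALSE]
  out$fm <- fq$fm[keep]
  out$fn <- fq$fn[keep]
  out$mean_f <- mean_f[keep]
  rownames(out) <- NULL
  attr(out, "rejections") <- rej
  out
}

#' Raw variants to selected markers in one step
#'
#' Convenience wrapper: [call_parental_alleles()] then [orient_counts()]
#' then [select_markers()], returning the selected marker set and the
#' combined rejection tallies.
#'
#' @inheritParams call_parental_alleles
#' @inheritParams select_markers
#' @return list with `markers` (selected, oriented, with fm/fn/mean_f)
#'   and `rejections` (named integer vector over all filtering stages).
#' @export
prepare_markers <- function(raw, purity = 0.9, min_parent_depth = 10,
                            freq_low = 0.3, freq_high = 0.7,
                            min_pool_depth = 4) {
  called <- call_parental_alleles(raw, purity, min_parent_depth)
  parental_rej <- table(called$reject_reason)
  oriented <- orient_counts(called)
  sel <- select_markers(oriented, freq_low, freq_high, min_pool_depth)
  rej <- c(stats::setNames(as.integer(parental_rej), names(parental_rej)),
           attr(sel, "rejections"))
  list(markers = sel, rejections = rej)
}

#' Read raw four-sample variants from TSV or VCF
#'
#' TSV input must carry the columns documented in
#' [call_parental_alleles()].  VCF input (4.2, one AD field per sample)
#' is parsed with the vcfR package; `samples` maps the four roles to VCF
#' sample names.  Multi-allelic sites are excluded with a message.
#'
#' @param path input file.
#' @param format "auto" (by extension), "tsv" or "vcf".
#' @param samples named list/vector with entries m_pool, n_pool,
#'   parent1, parent2 giving VCF sample names (VCF only).
#' @return raw variant data.frame.
#' @export
read_raw_variants <- function(path, format = c("auto", "tsv", "vcf"),
                              samples = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (format == "tsv") {
    raw <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "ref", "alt", "m_ref", "m_alt", "n_ref",
              "n_alt", "p1_ref", "p1_alt", "p2_ref", "p2_alt")
    missing <- setdiff(need, names(raw))
    if (length(missing)) {
      stop("variant TSV lacks columns: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    multi <- grepl(",", raw$alt, fixed = TRUE)
    if (any(multi)) {
      message("excluding ", sum(multi), " multi-allelic site(s)")
      raw <- raw[!multi, , drop = FALSE]
    }
    return(raw)
  }
  read_raw_variants_vcf(path, samples)
}

read_raw_variants_vcf <- function(path, samples) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package", call. = FALSE)
  }
  if (is.null(samples)) {
    stop("VCF input needs a 'samples' role mapping ",
         "(m_pool, n_pool, parent1, parent2)", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ad <- vcfR::extract.gt(v, element = "AD")
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    message("excluding ", sum(multi), " multi-allelic site(s)")
  }
  keep <- !multi
  split_ad <- function(role) {
    col <- samples[[role]]
    if (is.null(col) || !col %in% colnames(ad)) {
      stop("VCF sample for role '", role, "' not found", call. = FALSE)
    }
    parts <- strsplit(ad[keep, col], ",", fixed = TRUE)
    cbind(as.integer(vapply(parts, `[`, "", 1L)),
          as.integer(vapply(parts, `[`, "", 2L)))
  }
  m <- split_ad("m_pool"); nn <- split_ad("n_pool")
  p1 <- split_ad("parent1"); p2 <- split_ad("parent2")
  data.frame(chrom = fix[keep, "CHROM"],
             pos = as.integer(fix[keep, "POS"]),
             ref = fix[keep, "REF"], alt = fix[keep, "ALT"],
             m_ref = m[, 1], m_alt = m[, 2],
             n_ref = nn[, 1], n_alt = nn[, 2],
             p1_ref = p1[, 1], p1_alt = p1[, 2],
             p2_ref = p2[, 1], p2_alt = p2[, 2])
}

#' Write raw variants as a minimal four-sample VCF 4.2
#'
#' Emits one AD (allele depth) field per sample in the order M-pool,
#' N-pool, parent1 (MH86), parent2 (93-11).
#'
#' @param raw raw variant data.frame (see [call_parental_alleles()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(raw, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=bsamap",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "M_pool", "N_pool", "parent1", "parent2", sep = "\t")),
    con)
  body <- paste(raw$chrom, raw$pos, ".", raw$ref, raw$alt, ".", "PASS", ".",
                "AD",
                paste0(raw$m_ref, ",", raw$m_alt),
                paste0(raw$n_ref, ",", raw$n_alt),
                paste0(raw$p1_ref, ",", raw$p1_alt),
                paste0(raw$p2_ref, ",", raw$p2_alt), sep = "\t")
  writeLines(body, con)
  invisible(path)
}
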