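# Plain-text writers/readers for the pipeline's stage files.  TSVs carry
# a leading comment line stating the file kind and coordinate system;
# bedGraph/BED use 0-based half-open coordinates as the formats require.

write_stage_tsv <- function(df, path, kind, coords = "1-based inclusive") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bsamap %s; coordinates: %s", kind, coords), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a bsamap stage TSV
#'
#' Reads any TSV written by the pipeline (leading `#` comment lines are
#' skipped).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_stage_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write a CAAFD scan as bedGraph
#'
#' One record per window step interval (0-based half-open), value =
#' CAAFD, for genome-browser display.
#'
#' @param scores a `bsa_scan` from [scan_genome()].
#' @param path output file.
#' @param step the scan step in bp (interval width per record).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(scores, path, step = 1e4) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# bsamap CAAFD profile; coordinates: 0-based half-open",
               "track type=bedGraph name=CAAFD"), con)
  writeLines(paste(scores$chrom,
                   format(scores$center, scientific = FALSE, trim = TRUE),
                   format(scores$center + step, scientific = FALSE,
                          trim = TRUE),
                   format(scores$caafd, digits = 10), sep = "\t"), con)
  invisible(path)
}

#' Write a called region as a BED line
#'
#' @param region a `bsa_region` from [call_peak_region()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_region_bed <- function(region, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# bsamap target region; coordinates: 0-based half-open",
               paste(region$chrom,
                     format(region$start, scientific = FALSE, trim = TRUE),
                     format(region$end, scientific = FALSE, trim = TRUE),
                     "CAAFD_peak_region",
                     format(region$peak_caafd, digits = 10),
                     ".", sep = "\t")), con)
  invisible(path)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
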