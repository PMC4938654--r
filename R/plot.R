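#' Genome-wide CAAFD profile plot
#'
#' One panel per chromosome, window center against CAAFD, optionally
#' shading the called target region.
#'
#' @param scores a `bsa_scan` from [scan_genome()] (or the scan TSV read
#'   back with [read_stage_tsv()]).
#' @param region optional `bsa_region` to shade.
#' @return a ggplot object.
#' @export
plot_caafd_profile <- function(scores, region = NULL) {
  if (is.null(scores) || nrow(scores) == 0) {
    stop("cannot plot an empty scan", call. = FALSE)
  }
  scores$chrom <- factor(scores$chrom, unique(scores$chrom))
  gg <- ggplot2::ggplot(scores,
                        ggplot2::aes(x = .data$center / 1e6,
                                     y = .data$caafd)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(colour = "steelblue4") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "CAAFD") +
    ggplot2::theme_bw()
  if (!is.null(region)) {
    shade <- data.frame(chrom = factor(region$chrom,
                                       levels(scores$chrom)),
                        xmin = region$start / 1e6,
                        xmax = region$end / 1e6)
    gg <- gg + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax),
      ymin = -Inf, ymax = Inf, fill = "firebrick", alpha = 0.15,
      inherit.aes = FALSE)
  }
  gg
}

#' Save a CAAFD profile figure
#'
#' Convenience wrapper around [plot_caafd_profile()] + [ggplot2::ggsave()].
#'
#' @inheritParams plot_caafd_profile
#' @param path output image file (extension picks the device).
#' @param width,height figure size in inches.
#' @return `path`, invisibly.
#' @export
save_caafd_profile <- function(scores, path, region = NULL,
                               width = 10, height = 3) {
  gg <- plot_caafd_profile(scores, region)
  ggplot2::ggsave(path, gg, width = width, height = height, dpi = 150)
  invisible(path)
}
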