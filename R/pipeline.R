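#' Configuration for an end-to-end pipeline run
#'
#' Bundles the simulation config with every analysis-stage parameter so
#' a run is fully described by one object (serializable to YAML).
#'
#' @param sim a [sim_config()].
#' @param window_size,step CAAFD scan window and step in bp.
#' @param alpha region threshold fraction for [call_peak_region()].
#' @param purity,min_parent_depth parental-call thresholds
#'   ([call_parental_alleles()]).
#' @param freq_low,freq_high,min_pool_depth marker-selection thresholds
#'   ([select_markers()]).
#' @param min_support,max_contam_fraction presence-call thresholds
#'   ([classify_presence()]).
#' @param n_finemap,n_coseg panel sizes ([simulate_panels()]).
#' @param n_background background variants for the candidate screen.
#' @param candidate_depth pool depth for the candidate-screen counts
#'   (default: the simulation's pool depth).
#' @param seed global pipeline seed, deterministically split per stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            window_size = 2e6, step = 1e4, alpha = 0.5,
                            purity = 0.9, min_parent_depth = 10,
                            freq_low = 0.3, freq_high = 0.7,
                            min_pool_depth = 4,
                            min_support = 2, max_contam_fraction = 0.05,
                            n_finemap = 199, n_coseg = 280,
                            n_background = 500,
                            candidate_depth = NULL,
                            seed = sim$seed) {
  validate_sim_config(sim)
  structure(list(sim = sim, window_size = window_size, step = step,
                 alpha = alpha, purity = purity,
                 min_parent_depth = min_parent_depth,
                 freq_low = freq_low, freq_high = freq_high,
                 min_pool_depth = min_pool_depth,
                 min_support = min_support,
                 max_contam_fraction = max_contam_fraction,
                 n_finemap = n_finemap, n_coseg = n_coseg,
                 n_background = n_background,
                 candidate_depth = candidate_depth,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Small demonstration configuration
#'
#' A two-chromosome, 10-Mb-per-chromosome experiment that runs the whole
#' pipeline in a few seconds: 400 F2 plants, bulks of 50/50 at 12x, a
#' causal locus at chr2:6,000,000, and reduced panel sizes.
#'
#' @param seed pipeline seed.
#' @return a [pipeline_config()].
#' @export
demo_config <- function(seed = 1L) {
  pipeline_config(
    sim = sim_config(
      chromosomes = data.frame(name = c("chr1", "chr2"), length = 10e6),
      marker_spacing = 20000,
      causal_locus = list(chrom = "chr2", pos = 6e6),
      n_f2 = 400, seed = seed),
    n_finemap = 60, n_coseg = 80, n_background = 200,
    seed = seed)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @return `read_pipeline_config()` returns a `pipeline_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim
  sim_args$chromosomes <- do.call(rbind, lapply(sim_args$chromosomes,
                                                as.data.frame))
  y$sim <- do.call(sim_config, sim_args)
  do.call(pipeline_config, y)
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  y <- unclass(config)
  y$sim <- unclass(y$sim)
  y$sim$chromosomes <- lapply(seq_len(nrow(y$sim$chromosomes)), function(i) {
    list(name = y$sim$chromosomes$name[i],
         length = y$sim$chromosomes$length[i])
  })
  yaml::write_yaml(y, path)
  invisible(path)
}

stage_log <- function(stage, ...) {
  message(sprintf("[bsamap:%s] %s", stage, paste0(...)))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full BSA-seq mapping pipeline
#'
#' Executes simulate -> select markers -> CAAFD scan -> peak region ->
#' fine mapping -> candidate screen -> cosegregation, writing every
#' stage output under `out_dir` plus a JSON run manifest with file
#' digests.  One global seed is split deterministically into per-stage
#' seeds, so identical config + seed reproduces every stage file
#' byte-for-byte.
#'
#' @param config a [pipeline_config()] or path to a YAML file.
#' @param out_dir output directory (created if needed).
#' @param seed optional override of the config seed.
#' @return Invisibly, a list with the manifest and key result objects
#'   (`region`, `interval`, `candidates`, `coseg`) plus `paths`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)

  set.seed(config$seed)
  stage_seeds <- sample.int(.Machine$integer.max, 3)

  stage_log("simulate", "F2 experiment, seed ", stage_seeds[1])
  sim_cfg <- config$sim
  sim_cfg$seed <- stage_seeds[1]
  exp <- run_stage("simulate", {
    e <- simulate_experiment(sim_cfg)
    write_stage_tsv(e$counts$markers, p("marker_table.tsv"), "marker table")
    write_stage_tsv(e$counts$truth, p("truth.tsv"),
                    "truth sidecar (exact bulk allele frequencies)")
    write_stage_tsv(as_raw_variants(e$counts), p("raw_variants.tsv"),
                    "raw variant counts")
    e
  })

  stage_log("select", "marker selection")
  sel <- run_stage("select", {
    raw <- as_raw_variants(exp$counts)
    s <- prepare_markers(raw, config$purity, config$min_parent_depth,
                         config$freq_low, config$freq_high,
                         config$min_pool_depth)
    write_stage_tsv(s$markers, p("selected_markers.tsv"), "selected markers")
    write_stage_tsv(data.frame(reason = names(s$rejections),
                               n = as.integer(s$rejections)),
                    p("rejections.tsv"), "marker rejection summary")
    s
  })
  stage_log("select", nrow(sel$markers), " markers selected")

  stage_log("scan", "CAAFD window scan")
  scan <- run_stage("scan", {
    sc <- scan_genome(sel$markers, config$window_size, config$step)
    write_stage_tsv(as.data.frame(sc), p("scan.tsv"), "CAAFD windows",
                    coords = "start/end 0-based half-open; center in bp")
    write_bedgraph(sc, p("caafd.bedgraph"), step = config$step)
    sc
  })
  region <- run_stage("scan", {
    rg <- call_peak_region(scan, config$alpha)
    write_region_bed(rg, p("region.bed"))
    write_json_file(unclass(rg), p("region.json"))
    rg
  })
  stage_log("scan", sprintf("peak %.4f at %s:%.0f", region$peak_caafd,
                            region$chrom, region$peak_center))

  stage_log("finemap", "panels and interval")
  fm <- run_stage("finemap", {
    set.seed(stage_seeds[2])
    panels <- simulate_panels(exp$pop, sim_cfg,
                              n_finemap = config$n_finemap,
                              n_coseg = config$n_coseg)
    write_stage_tsv(panels$finemap, p("finemap_panel.tsv"),
                    "fine-mapping panel (mutant plants, A/H/B)")
    write_stage_tsv(panels$coseg, p("coseg_panel.tsv"),
                    "cosegregation panel")
    tab <- finemap_markers(panels$finemap, panels$panel_markers)
    write_stage_tsv(tab, p("finemap_table.tsv"), "per-marker linkage table")
    interval <- tryCatch(suppressWarnings(delimit_interval(tab)),
                         error = function(e) NULL)
    if (!is.null(interval)) {
      write_json_file(unclass(interval), p("interval.json"))
    }
    list(panels = panels, table = tab, interval = interval)
  })

  stage_log("candidate", "presence-pattern screen")
  cand <- run_stage("candidate", {
    set.seed(stage_seeds[3])
    depth <- if (is.null(config$candidate_depth)) sim_cfg$depth_pool else
      config$candidate_depth
    vars <- simulate_candidate_variants(exp$pop, exp$bulks, region,
                                        n_background = config$n_background,
                                        depth_pool = depth)
    write_stage_tsv(vars, p("region_variants.tsv"),
                    "candidate-region variants (synthetic)")
    flt <- filter_candidates(vars, config$min_support,
                             config$max_contam_fraction)
    write_stage_tsv(flt$candidates, p("candidates.tsv"),
                    "presence-pattern candidates")
    flt
  })
  stage_log("candidate", nrow(cand$candidates), " candidate(s)")

  coseg <- run_stage("coseg", {
    cs <- cosegregation_test(fm$panels$coseg)
    write_json_file(list(concordant = cs$concordant,
                         discordant_ids = cs$discordant_ids,
                         counts = as.data.frame(cs$counts)),
                    p("cosegregation.json"))
    cs
  })
  stage_log("coseg", if (coseg$concordant) "concordant" else "discordant")

  stage_files <- c("marker_table.tsv", "truth.tsv", "raw_variants.tsv",
                   "selected_markers.tsv", "rejections.tsv", "scan.tsv",
                   "caafd.bedgraph", "region.bed", "region.json",
                   "finemap_panel.tsv", "coseg_panel.tsv",
                   "finemap_table.tsv", "region_variants.tsv",
                   "candidates.tsv", "cosegregation.json")
  if (!is.null(fm$interval)) stage_files <- c(stage_files, "interval.json")
  digests <- as.list(tools::md5sum(file.path(out_dir, stage_files)))
  names(digests) <- stage_files
  manifest <- list(tool = "bsamap",
                   version = as.character(utils::packageVersion("bsamap")),
                   seed = config$seed,
                   stage_seeds = stage_seeds,
                   timestamp = format(Sys.time(), tz = "UTC"),
                   config = jsonlite::fromJSON(jsonlite::toJSON(
                     unclass_deep(config), auto_unbox = TRUE, digits = NA)),
                   digests = digests)
  write_json_file(manifest, p("manifest.json"))

  invisible(list(manifest = manifest, region = region,
                 interval = fm$interval, finemap_table = fm$table,
                 candidates = cand, coseg = coseg,
                 paths = stats::setNames(file.path(out_dir, stage_files),
                                         stage_files)))
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x) && !is.data.frame(x)) x <- lapply(x, unclass_deep)
  x
}
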