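test_that("parental allele calls follow the purity and depth rules", {
  v <- rbind(
    raw_variant_row(pos = 1, p1 = c(48, 1), p2 = c(0, 29)),   # clean polymorphism
    raw_variant_row(pos = 2, p1 = c(30, 0), p2 = c(25, 1)),   # both majority ref
    raw_variant_row(pos = 3, p1 = c(40, 0), p2 = c(3, 0)),    # parent2 too shallow
    raw_variant_row(pos = 4, p1 = c(20, 10), p2 = c(0, 30)))  # parent1 impure
  called <- call_parental_alleles(v, purity = 0.9, min_parent_depth = 10)
  expect_identical(called$accepted, c(TRUE, FALSE, FALSE, FALSE))
  expect_true(called$mh86_is_ref[1])
  expect_identical(called$reject_reason[2:4],
                   c("monomorphic", "low_depth_parent2",
                     "low_purity_parent1"))
})

test_that("orientation maps pool counts onto the MH86 allele", {
  # MH86 majority allele is ALT here, so counts must swap
  v <- raw_variant_row(m = c(3, 9), n = c(5, 5), p1 = c(1, 40), p2 = c(28, 0))
  oriented <- orient_counts(call_parental_alleles(v))
  expect_identical(oriented$mh86_allele, "T")
  expect_identical(oriented$m1, 9)
  expect_identical(oriented$m2, 3)
  expect_identical(oriented$n1, 5)
})

test_that("pool frequencies are MH86-allele fractions, NA at zero depth", {
  fq <- pool_frequencies(c(12, 6, 0, 0), c(0, 6, 10, 0),
                         c(4, 5, 10, 3), c(6, 5, 0, 3))
  expect_equal(fq$fm, c(1.0, 0.5, 0.0, NA))
  expect_equal(fq$fn, c(0.4, 0.5, 1.0, 0.5))
  expect_identical(fq$usable, c(TRUE, TRUE, TRUE, FALSE))
})

test_that("selection keeps mean pool frequency in the closed 0.3-0.7 band", {
  mk <- data.frame(chrom = "chr1", pos = c(10, 20, 30, 40, 50),
                   m1 = c(18, 20, 10, 6, 3),
                   m2 = c(2, 0, 10, 14, 7),
                   n1 = c(8, 12, 10, 6, 3),
                   n2 = c(12, 8, 10, 14, 7))
  # mean f: (0.9+0.4)/2=0.65, (1.0+0.6)/2=0.8, 0.5, 0.3, 0.3
  sel <- select_markers(mk, min_pool_depth = 4)
  expect_identical(sel$pos, c(10, 30, 40, 50))
  expect_equal(sel$mean_f, c(0.65, 0.5, 0.3, 0.3))
  rej <- attr(sel, "rejections")
  expect_identical(unname(rej["mean_freq_out_of_range"]), 1L)

  # boundary 0.7 is inclusive too
  hi <- data.frame(chrom = "c", pos = 1, m1 = 8, m2 = 2, n1 = 6, n2 = 4)
  expect_identical(nrow(select_markers(hi)), 1L)
})

test_that("selection is idempotent and symmetric under allele re-orientation", {
  set.seed(8)
  mk <- random_marker_fixture(300)
  sel1 <- select_markers(mk)
  sel2 <- select_markers(sel1)
  expect_equal(sel2[names(mk)], sel1[names(mk)])
  expect_equal(nrow(sel2), nrow(sel1))

  flipped <- transform(mk, m1 = m2, m2 = m1, n1 = n2, n2 = n1)
  self <- select_markers(flipped)
  expect_identical(paste(self$chrom, self$pos),
                   paste(sel1$chrom, sel1$pos))
})

test_that("empty input yields an empty selection, not an error", {
  empty <- random_marker_fixture(0)
  sel <- select_markers(empty)
  expect_identical(nrow(sel), 0L)
})

test_that("low-depth pools are filtered with tallied reasons", {
  mk <- data.frame(chrom = "c", pos = 1:3,
                   m1 = c(2, 10, 0), m2 = c(1, 10, 0),
                   n1 = c(5, 5, 4), n2 = c(5, 5, 4))
  sel <- select_markers(mk, min_pool_depth = 4)
  expect_identical(sel$pos, 2L)
  rej <- attr(sel, "rejections")
  expect_identical(unname(rej["low_pool_depth"]), 1L)
  expect_identical(unname(rej["zero_depth"]), 1L)
})

test_that("on clean high-depth simulated data virtually all markers pass", {
  cfg <- tiny_config(seed = 81, depth_pool = 200, base_error = 0)
  e <- simulate_experiment(cfg)
  prep <- prepare_markers(as_raw_variants(e$counts))
  expect_gt(nrow(prep$markers) / nrow(e$counts$markers), 0.97)
  # near the causal locus the mean frequency sits around (1 + 1/3)/2
  near <- prep$markers$chrom == "chr2" &
    abs(prep$markers$pos - 3e6) < 2e5
  expect_true(abs(mean(prep$markers$mean_f[near]) - 2 / 3) < 0.1)
})

test_that("VCF round-trip preserves all four samples' allele depths", {
  skip_if_not_installed("vcfR")
  set.seed(9)
  mk <- random_marker_fixture(40)
  raw <- data.frame(chrom = mk$chrom, pos = mk$pos, ref = "A", alt = "G",
                    m_ref = mk$m1, m_alt = mk$m2,
                    n_ref = mk$n1, n_alt = mk$n2,
                    p1_ref = 30L, p1_alt = 0L, p2_ref = 0L, p2_alt = 25L)
  path <- tempfile(fileext = ".vcf")
  write_variants_vcf(raw, path)
  back <- read_raw_variants(path, samples = list(
    m_pool = "M_pool", n_pool = "N_pool",
    parent1 = "parent1", parent2 = "parent2"))
  expect_equal(back$m_ref, raw$m_ref)
  expect_equal(back$p2_alt, raw$p2_alt)
  expect_equal(back$pos, raw$pos)
})

test_that("multi-allelic TSV records are excluded at parse time", {
  raw <- rbind(raw_variant_row(pos = 1), raw_variant_row(pos = 2))
  raw$alt[2] <- "T,G"
  path <- tempfile(fileext = ".tsv")
  utils::write.table(raw, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(got <- read_raw_variants(path), "multi-allelic")
  expect_identical(nrow(got), 1L)
})
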