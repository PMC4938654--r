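test_that("config validation reports the offending field", {
  expect_error(sim_config(marker_spacing = 0), "marker_spacing")
  expect_error(sim_config(causal_locus = list(chrom = "chrX", pos = 1)),
               "causal_locus")
  expect_error(sim_config(causal_locus = list(chrom = "chr1", pos = 40e6)),
               "causal_locus")
  expect_error(sim_config(base_error = 0.6), "base_error")
  expect_error(sim_config(n_f2 = -1), "n_f2")
  cfg <- sim_config()
  cfg$causal_locus <- NULL
  expect_error(validate_sim_config(cfg), "causal_locus")
})

test_that("mutant fraction in a 400-plant F2 is binomial around 1/4", {
  cfg <- sim_config(chromosomes = data.frame(name = "chr1", length = 2e6),
                    marker_spacing = 1e6,
                    causal_locus = list(chrom = "chr1", pos = 1.5e6),
                    n_f2 = 400, phenotyping_error = 0, seed = 11)
  pop <- simulate_f2_population(cfg)
  frac <- mean(pop$phenotype == "mutant")
  expect_true(abs(frac - 0.25) < 0.065)  # 3 binomial SD for n = 400
  expect_identical(pop$phenotype, pop$phenotype_true)
  # phenotype is determined by the causal genotype
  expect_identical(pop$phenotype == "mutant", unname(pop$causal_geno == 2L))
})

test_that("single-marker chromosomes transmit intact parental haplotypes", {
  cfg <- sim_config(chromosomes = data.frame(name = c("c1", "c2"),
                                             length = c(1e6, 1e6)),
                    marker_spacing = 1e6,
                    causal_locus = list(chrom = "c1", pos = 5e5),
                    n_f2 = 50, seed = 3)
  pop <- simulate_f2_population(cfg)
  expect_true(all(pop$hap1 %in% c(0L, 1L)))
  expect_equal(dim(pop$hap1), c(nrow(pop$grid), 50))
})

test_that("recombinant gamete fraction matches the Haldane map function", {
  # two markers 1 Morgan apart; expected r = (1 - exp(-2))/2
  cfg <- sim_config(chromosomes = data.frame(name = "chr1", length = 2e6),
                    marker_spacing = 1e6,
                    causal_locus = list(chrom = "chr1", pos = 1234567),
                    n_f2 = 5000, cm_per_mb = 100, seed = 5)
  pop <- simulate_f2_population(cfg)
  rows <- which(!pop$grid$is_causal)
  gam <- cbind(pop$hap1[rows, ], pop$hap2[rows, ])  # 2 x 10000 gametes
  obs_r <- mean(gam[1, ] != gam[2, ])
  exp_r <- (1 - exp(-2)) / 2
  se <- sqrt(exp_r * (1 - exp_r) / ncol(gam))
  expect_true(abs(obs_r - exp_r) < 3 * se)
})

test_that("bulks are drawn from the right phenotype classes, reproducibly", {
  cfg <- tiny_config(seed = 21)
  pop <- simulate_f2_population(cfg)
  set.seed(99); b1 <- make_bulks(pop, cfg)
  set.seed(99); b2 <- make_bulks(pop, cfg)
  expect_identical(b1, b2)
  expect_length(b1$mutant, cfg$bulk_size_mutant)
  expect_true(all(pop$phenotype[b1$mutant] == "mutant"))
  expect_true(all(pop$phenotype[b1$normal] == "normal"))

  small <- sim_config(chromosomes = data.frame(name = "chr1", length = 2e6),
                      marker_spacing = 1e6,
                      causal_locus = list(chrom = "chr1", pos = 1e6),
                      n_f2 = 60, seed = 4)
  pop2 <- simulate_f2_population(small)
  expect_error(make_bulks(pop2, small), "M-pool.*50 mutant")
})

test_that("causal-locus bulk frequencies: 1 in the M-pool, ~1/3 in the N-pool", {
  cfg <- tiny_config(seed = 31)
  pop <- simulate_f2_population(cfg)
  bulks <- make_bulks(pop, cfg)
  crow <- which(pop$grid$is_causal)
  fm <- (sum(pop$hap1[crow, bulks$mutant]) + sum(pop$hap2[crow, bulks$mutant])) /
    (2 * length(bulks$mutant))
  fn <- (sum(pop$hap1[crow, bulks$normal]) + sum(pop$hap2[crow, bulks$normal])) /
    (2 * length(bulks$normal))
  expect_identical(fm, 1)
  # normal plants are 2:1 het : hom-wildtype; per-plant frequency has
  # mean 1/3 and variance 1/18, so 3 SD over 50 plants is ~0.10
  expect_true(abs(fn - 1 / 3) < 3 * sqrt(1 / 18 / 50))
})

test_that("pool counts have Poisson depths and error-flipped frequencies", {
  cfg <- sim_config(chromosomes = data.frame(name = "chr1", length = 60e6),
                    marker_spacing = 5000,   # 12,000 markers
                    causal_locus = list(chrom = "chr1", pos = 30e6),
                    n_f2 = 400, depth_pool = 12, base_error = 0.01,
                    seed = 41)
  e <- simulate_experiment(cfg)
  depth_m <- e$counts$markers$m1 + e$counts$markers$m2
  n <- length(depth_m)
  expect_gte(n, 10000)
  # Poisson mean check, 3 SE band
  expect_true(abs(mean(depth_m) - 12) < 3 * sqrt(12 / n))
  # markers truly fixed for the MH86 allele in the mutant bulk should
  # show a 0.99 MH86-read fraction (error flips), binomial 3 SD
  fixed <- e$counts$truth$true_fm == 1
  tot <- sum(depth_m[fixed])
  expect_gte(tot, 300)
  frac <- sum(e$counts$markers$m1[fixed]) / tot
  expect_true(abs(frac - 0.99) < 3 * sqrt(0.99 * 0.01 / tot))
})

test_that("error-free counts at fixed markers carry only the MH86 allele", {
  cfg <- tiny_config(seed = 51, base_error = 0)
  e <- simulate_experiment(cfg)
  fixed <- e$counts$truth$true_fm == 1
  expect_gt(sum(fixed), 0)
  expect_true(all(e$counts$markers$m2[fixed] == 0))
})

test_that("a fixed seed reproduces the marker table bit for bit", {
  e1 <- simulate_experiment(tiny_config(seed = 61))
  e2 <- simulate_experiment(tiny_config(seed = 61))
  expect_identical(e1$counts, e2$counts)
  e3 <- simulate_experiment(tiny_config(seed = 62))
  expect_false(identical(e1$counts$markers$m1, e3$counts$markers$m1))
})

test_that("truth frequencies decay with distance from the causal locus", {
  # expectation over seeds: rank correlation of mean mutant-bulk truth
  # frequency with genetic distance on the carrier chromosome
  cfg0 <- sim_config(chromosomes = data.frame(name = "chr1", length = 10e6),
                     marker_spacing = 250000,
                     causal_locus = list(chrom = "chr1", pos = 5e6),
                     n_f2 = 300, seed = 1)
  acc <- NULL
  pos <- NULL
  for (s in 1:20) {
    cfg <- cfg0; cfg$seed <- s
    pop <- simulate_f2_population(cfg)
    bulks <- make_bulks(pop, cfg)
    counts <- simulate_pool_counts(pop, bulks, cfg)
    if (is.null(acc)) {
      acc <- counts$truth$true_fm
      pos <- counts$truth$pos
    } else {
      acc <- acc + counts$truth$true_fm
    }
  }
  mean_fm <- acc / 20
  dist <- abs(pos - cfg0$causal_locus$pos)
  rho <- stats::cor(mean_fm, dist, method = "spearman")
  expect_lt(rho, -0.8)
})

test_that("fine-mapping panel is mutants-only with Mendelian unlinked markers", {
  cfg <- sim_config(chromosomes = data.frame(name = c("chr1", "chr2"),
                                             length = c(4e6, 4e6)),
                    marker_spacing = 1e6,
                    causal_locus = list(chrom = "chr2", pos = 2e6),
                    n_f2 = 900, seed = 71)
  pop <- simulate_f2_population(cfg)
  panel_markers <- data.frame(id = c("LINK", "UNLINK"),
                              chrom = c("chr2", "chr1"),
                              pos = c(2e6, 2e6))
  panels <- simulate_panels(pop, cfg, n_finemap = 199, n_coseg = 280,
                            panel_markers = panel_markers)
  expect_equal(nrow(panels$finemap), 199)
  expect_true(all(panels$finemap$phenotype == "mutant"))
  # marker at the causal position: selection fixes it to A
  expect_true(all(panels$finemap$LINK == "A"))
  # unlinked marker segregates 1:2:1; 3-SD multinomial bands at n = 199
  cnt <- table(factor(panels$finemap$UNLINK, c("A", "H", "B")))
  p <- c(0.25, 0.5, 0.25)
  bands <- 3 * sqrt(p * (1 - p) * 199)
  expect_true(all(abs(cnt - 199 * p) < bands))
  # cosegregation panel: with no phenotyping error, -/- iff mutant
  expect_identical(panels$coseg$genotype == "-/-",
                   panels$coseg$phenotype == "mutant")
  expect_error(simulate_panels(pop, cfg, n_finemap = 5000),
               "mutant plants")
})
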