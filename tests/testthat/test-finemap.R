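test_that("selected-recessive recombination counting matches gamete logic", {
  e <- estimate_r_selected(188, 10, 1)
  expect_identical(e$R, 12)
  expect_identical(e$G, 398)
  expect_equal(e$r_hat, 12 / 398, tolerance = 1e-12)
  # complete cosegregation
  expect_identical(estimate_r_selected(25, 0, 0)$r_hat, 0)
  # all heterozygous: half the gametes recombinant, no cap needed
  expect_identical(estimate_r_selected(0, 40, 0)$r_hat, 0.5)
  expect_error(estimate_r_selected(0, 0, 0), "zero")
  expect_error(estimate_r_selected(-1, 2, 0), ">= 0")
})

test_that("LOD equals the binomial likelihood ratio against r = 0.5", {
  expect_equal(lod_selected(0, 10), 10 * log10(2), tolerance = 1e-12)
  expect_equal(lod_selected(0, 10), 3.0103, tolerance = 1e-4)
  expect_identical(lod_selected(5, 10), 0)  # r_hat = 0.5
  # independent oracle: log10 ratio of binomial likelihoods
  # (coefficients cancel)
  for (RG in list(c(12, 398), c(3, 50), c(40, 100))) {
    R <- RG[1]; G <- RG[2]; r <- R / G
    oracle <- log10(stats::dbinom(R, G, r) / stats::dbinom(R, G, 0.5))
    expect_equal(lod_selected(R, G), oracle, tolerance = 1e-9)
  }
  expect_equal(lod_selected(12, 398), 96.4, tolerance = 0.1)
  # monotone decreasing in r_hat for fixed G with R = r*G
  G <- 400
  lods <- vapply(seq(0, 0.5, by = 0.05),
                 function(r) lod_selected(r * G, G, r), numeric(1))
  expect_true(all(diff(lods) < 0))
})

test_that("Kosambi map function and its inverse are exact", {
  expect_identical(kosambi(0), 0)
  expect_equal(kosambi(0.2), 21.182, tolerance = 1e-4)
  expect_equal(kosambi(0.1), 10.137, tolerance = 1e-4)
  expect_error(kosambi(0.5), "infinite")
  expect_error(kosambi(-0.1), ">= 0")
  expect_identical(kosambi_inverse(0), 0)
  expect_equal(kosambi_inverse(21.182), 0.2, tolerance = 1e-4)
  set.seed(16)
  r <- stats::runif(100, 0, 0.49)
  expect_lt(max(abs(kosambi_inverse(kosambi(r)) - r)), 1e-12)
  # map distance never below the recombination fraction in cM
  rr <- seq(0.01, 0.49, by = 0.01)
  expect_true(all(kosambi(rr) >= 100 * rr))
})

test_that("interval delimitation brackets the zero-recombinant block", {
  tab <- data.frame(id = paste0("M", 1:5), chrom = "chr4",
                    pos = c(1, 2, 3, 4, 5) * 1e5,
                    R = c(5, 2, 0, 0, 3))
  iv <- delimit_interval(tab)
  expect_identical(iv$left_id, "M2")
  expect_identical(iv$right_id, "M5")
  expect_identical(iv$cosegregating, c("M3", "M4"))
  expect_equal(iv$length_bp, 3e5)
  expect_false(iv$open_left || iv$open_right)

  # no zero-recombinant marker: bracket the minimum instead
  tab2 <- transform(tab, R = c(5, 2, 1, 1, 3))
  iv2 <- delimit_interval(tab2)
  expect_identical(iv2$left_id, "M2")
  expect_identical(iv2$right_id, "M5")
  expect_identical(iv2$cosegregating, character(0))

  # open side flagged, not clipped
  tab3 <- transform(tab, R = c(0, 0, 1, 2, 3))
  expect_warning(iv3 <- delimit_interval(tab3), "open")
  expect_true(iv3$open_left)
  expect_identical(iv3$right_id, "M3")

  expect_error(delimit_interval(transform(tab, R = 0)), "unresolvable")
})

test_that("r_hat is unbiased on simulated selected panels", {
  # marker 1 Mb (4 cM) from the causal locus; Haldane truth
  cfg <- sim_config(chromosomes = data.frame(name = "chr1", length = 4e6),
                    marker_spacing = 1e6,
                    causal_locus = list(chrom = "chr1", pos = 2e6),
                    n_f2 = 600, seed = 0)
  true_r <- 0.5 * (1 - exp(-2 * 0.04))
  r_hats <- numeric(30)
  for (s in 1:30) {
    cfg$seed <- s
    pop <- simulate_f2_population(cfg)
    panels <- simulate_panels(pop, cfg, n_finemap = 100, n_coseg = 10,
                              panel_markers = data.frame(
                                id = "MK", chrom = "chr1", pos = 3e6))
    g <- panels$finemap$MK
    est <- estimate_r_selected(sum(g == "A"), sum(g == "H"), sum(g == "B"))
    r_hats[s] <- est$r_hat
  }
  se <- sqrt(true_r * (1 - true_r) / 200) / sqrt(30)
  expect_lt(abs(mean(r_hats) - true_r), 3 * se)
})

test_that("per-marker linkage tables handle missing genotypes", {
  panel <- data.frame(plant_id = 1:6, phenotype = "mutant",
                      MA = c("A", "A", "A", "H", "A", "A"),
                      MB = c("A", NA, "A", "A", "B", "A"))
  mp <- data.frame(id = c("MA", "MB"), chrom = "chr1", pos = c(100, 200))
  expect_message(tab <- finemap_markers(panel, mp), "missing")
  expect_identical(tab$G, c(12, 10))
  expect_identical(tab$R, c(1, 2))
  expect_identical(tab$n_missing, c(0L, 1L))
  expect_equal(tab$lod[1], lod_selected(1, 12), tolerance = 1e-12)
  expect_error(finemap_markers(panel, data.frame(id = "ZZ", chrom = "c",
                                                 pos = 1)),
               "ZZ")
})
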