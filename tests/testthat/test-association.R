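test_that("binned density correlation detects planted monotone trends", {
  # strictly increasing planted densities -> rho = 1
  bg <- data.frame(covariate = rep(1:20, each = 40),
                   edited = unlist(lapply(0:19, function(b)
                     rep(c(TRUE, FALSE), c(b, 40 - b)))))
  res <- binned_density_correlation(bg, n_bins = 20)
  expect_equal(res$rho, 1)
  expect_equal(res$bins$density, (0:19) / 40)
  expect_equal(res$bins$density_per_million, (0:19) / 40 * 1e6)
  # identical densities: rho reported 0 with a tie flag
  flat <- data.frame(covariate = rep(1:20, each = 10),
                     edited = rep(c(TRUE, rep(FALSE, 9)), 20))
  resf <- binned_density_correlation(flat, n_bins = 20)
  expect_equal(resf$rho, 0)
  expect_true(resf$tie_flag)
  # a positive gradient planted by the generator is recovered
  set.seed(51)
  n <- 6000
  relpos <- runif(n)
  bg2 <- data.frame(covariate = relpos,
                    edited = rbinom(n, 1, 0.02 + 0.10 * relpos) == 1)
  res2 <- binned_density_correlation(bg2, n_bins = 20)
  expect_gt(res2$rho, 0)
  expect_lt(res2$p_value, 0.05)
  # level-weighted variant uses the level sums
  bg2$level <- ifelse(bg2$edited, 0.5, 0)
  resw <- binned_density_correlation(bg2, n_bins = 20,
                                     weighting = "level_weighted")
  expect_equal(resw$bins$density, res2$bins$density * 0.5, tolerance = 1e-12)
})

test_that("half-gene paired test behaves at the null and under rear enrichment", {
  flat <- expand.grid(bin = 1:20, half = c("front", "rear"),
                      idx = 1:30, KEEP.OUT.ATTRS = FALSE)
  flat$edited <- flat$idx <= 3
  res <- halfgene_paired_test(flat)
  expect_equal(res$t_statistic, 0)
  expect_equal(res$p_value, 1)
  set.seed(52)
  enr <- expand.grid(bin = 1:20, half = c("front", "rear"),
                     idx = 1:200, KEEP.OUT.ATTRS = FALSE)
  enr$edited <- rbinom(nrow(enr), 1, ifelse(enr$half == "rear", 0.10, 0.05)) == 1
  res2 <- halfgene_paired_test(enr)
  expect_gt(sum(res2$bins$rear > res2$bins$front), 17)
  expect_lt(res2$p_value, 0.05)
  expect_error(halfgene_paired_test(flat[flat$bin <= 2, ]), "usable bins")
})

test_that("coverage-matched conservation contrast isolates the phyloP effect", {
  set.seed(53)
  n <- 8000
  bgnull <- data.frame(coverage = rnbinom(n, mu = 20, size = 2),
                       phylop = rnorm(n), edited = rbinom(n, 1, 0.05) == 1)
  res <- matched_conservation_contrast(bgnull)
  expect_lt(abs(mean(res$bins$ratio, na.rm = TRUE) - 1), 0.35)
  # editing twice as likely at conserved sites
  phylop <- rnorm(n)
  bgalt <- data.frame(coverage = rnbinom(n, mu = 20, size = 2), phylop = phylop,
                      edited = rbinom(n, 1, ifelse(phylop > 0, 0.10, 0.05)) == 1)
  res2 <- matched_conservation_contrast(bgalt)
  expect_gt(sum(res2$bins$ratio < 1, na.rm = TRUE), 17)
  expect_lt(res2$p_value, 0.001)
  # all edited sites conserved -> non-conserved density 0, ratio 0
  bgz <- bgalt
  bgz$edited <- bgz$edited & bgz$phylop > 1
  res3 <- matched_conservation_contrast(bgz)
  expect_true(all(res3$bins$non_conserved == 0))
})

test_that("hairpin enrichment p-values agree with the binomial tail", {
  hp <- data.frame(chrom = "c", start = 1L, end = 1000L)
  bg_all_in <- data.frame(chrom = "c", pos = sample(1:1000, 400, TRUE))
  sites_in <- data.frame(chrom = "c", pos = sample(1:1000, 50, TRUE))
  res <- structure_enrichment_test(sites_in, hp, bg_all_in, n_replicates = 200)
  expect_equal(res$observed, 50)
  expect_equal(res$null_median, 50)
  expect_equal(res$p_value, 1)
  # 10% of background in hairpins, all 100 observed sites inside ->
  # empirical p at the (r+1)/(n+1) floor, consistent with the exact tail
  bg10 <- data.frame(chrom = "c", pos = c(sample(1:1000, 100, TRUE),
                                          sample(2000:11000, 900, TRUE)))
  obs50 <- data.frame(chrom = "c", pos = sample(1:1000, 100, TRUE))
  res2 <- structure_enrichment_test(obs50[1:100, , drop = FALSE], hp, bg10,
                                    n_replicates = 1000, seed = 4)
  expect_lt(res2$p_value, 0.005)
  expect_gt(pbinom(49, 100, 0.1, lower.tail = FALSE), 0)  # tail defined
  # determinism under a fixed seed
  res3 <- structure_enrichment_test(obs50, hp, bg10, n_replicates = 300, seed = 9)
  res4 <- structure_enrichment_test(obs50, hp, bg10, n_replicates = 300, seed = 9)
  expect_identical(res3, res4)
})

test_that("library clustering groups by the dominant planted effect", {
  set.seed(54)
  n_sites <- 200
  base <- rbeta(n_sites, 2, 4)
  # site-specific condition responses shared by both sexes (a constant shift
  # would be invisible to Pearson correlation); sex adds only small noise
  temp_profile <- replicate(4, rnorm(n_sites, 0, 0.04))
  libs <- list()
  for (s in 1:2) for (t in 1:4) {
    libs[[paste0("S", s, "T", t)]] <-
      pmin(1, pmax(0, base + temp_profile[, t] + rnorm(n_sites, 0, 0.01)))
  }
  m <- do.call(cbind, libs)
  res <- cluster_libraries(m, coverage = matrix(50, n_sites, 8), coverage_min = 20)
  expect_true(isSymmetric(res$distance))
  expect_equal(unname(diag(res$distance)), rep(0, 8))
  groups <- cutree(res$hclust, k = 4)
  # same-temperature libraries (across sexes) always merge together
  for (t in 1:4) {
    expect_equal(groups[paste0("S1T", t)], groups[paste0("S2T", t)],
                 ignore_attr = TRUE)
  }
  expect_true(grepl("^\\(", res$newick))
  # identical libraries merge first at distance 0
  m2 <- cbind(a = base, b = base, c = rev(base))
  res2 <- cluster_libraries(m2)
  expect_equal(res2$distance["a", "b"], 0, tolerance = 1e-12)
  expect_equal(res2$hclust$merge[1, ], c(-1, -2))
  expect_error(cluster_libraries(m[, 1, drop = FALSE]), "at least 2")
})

test_that("temperature-shift summaries recover planted category effects", {
  set.seed(55)
  n <- 400
  shifts <- data.frame(
    site_id = paste0("s", 1:n), gene_id = paste0("g", rep(1:80, 5)),
    category = rep(c("N", "silent"), each = n / 2),
    level_control = rbeta(n, 2, 4))
  planted <- ifelse(shifts$category == "N", -0.01, -0.05)
  shifts$level_treated <- pmin(1, pmax(0, shifts$level_control + planted +
                                         rnorm(n, 0, 0.02)))
  res <- temperature_shift_analysis(shifts)
  cs <- res$category_summary
  nrow_ <- cs[cs$category == "N", ]
  sil <- cs[cs$category == "silent", ]
  expect_lt(abs(nrow_$mean_delta - (-0.01)), 3 * nrow_$se + 0.003)
  expect_lt(abs(sil$mean_delta - (-0.05)), 3 * sil$se + 0.003)
  expect_gt(nrow_$mean_delta, sil$mean_delta)
  # a second species with the same planted shifts correlates positively
  other <- data.frame(site_id = shifts$site_id,
                      delta = planted + rnorm(n, 0, 0.02))
  res2 <- temperature_shift_analysis(shifts, other_species = other)
  expect_gt(res2$cross_species$r, 0)
  expect_lt(res2$cross_species$p, 0.05)
  # identical conditions: all deltas zero, correlations not applicable
  same <- shifts
  same$level_treated <- same$level_control
  res3 <- temperature_shift_analysis(same, other_species = other)
  expect_equal(res3$category_summary$mean_delta, c(0, 0))
  expect_true(is.na(res3$cross_species$r))
  expect_equal(res3$cross_species$note, "not applicable")
})
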