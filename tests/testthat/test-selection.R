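test_that("neutral background tallies CDS adenosines exactly", {
  # ATG AAA TAA: ATG pos1 N; AAA -> N, N, S; stop codon excluded
  fix <- toy_gene(cds = "ATGAAATAA")
  bg <- neutral_ns_expectation(fix$genes, fix$genome)
  expect_equal(bg$background_N, 3)
  expect_equal(bg$background_S, 1)
  expect_equal(bg$expected_ratio, 3.0)
  # a CDS without adenosines is degenerate
  fix0 <- toy_gene(cds = "GGCGGCGGC", utr5 = "CC", utr3 = "GG")
  expect_error(neutral_ns_expectation(fix0$genes, fix0$genome), "degenerate")
})

test_that("neutral background equals the brute-force oracle on random genes", {
  set.seed(8)
  syn <- small_synthetic(seed = 8, n_genes = 12)
  bg <- neutral_ns_expectation(syn$ref$genes, syn$ref$genome)
  oracle <- table(unlist(lapply(
    unique(syn$ref$genes$gene_id[syn$ref$genes$feature == "CDS"]),
    function(gid) cds_effect_oracle(editome:::cds_sequence(syn$ref$genes,
                                                           syn$ref$genome, gid)))))
  expect_equal(bg$background_N, unname(oracle["N"]))
  expect_equal(bg$background_S, unname(oracle["S"]))
  # conserved-site filter restricts the tally
  ad <- enumerate_cds_adenosines(syn$ref$genes, syn$ref$genome)
  keep <- site_key(ad$chrom, ad$pos)[seq(1, nrow(ad), by = 2)]
  bg2 <- neutral_ns_expectation(syn$ref$genes, syn$ref$genome,
                                conserved_sites = keep)
  expect_lt(bg2$background_N + bg2$background_S,
            bg$background_N + bg$background_S)
})

test_that("N/S test reproduces the published worked rows", {
  bg38 <- neutral_background(expected_ratio = 3.80)
  total <- observed_ns_test(N = 678, S = 144, background = bg38, seed = 1)
  expect_equal(round(total$observed_ratio, 2), 4.71)
  expect_equal(round(total$alpha, 2), 0.19)
  b2 <- observed_ns_test(N = 300, S = 48, background = bg38, seed = 1)
  expect_equal(round(b2$observed_ratio, 2), 6.25)
  expect_equal(round(b2$alpha, 2), 0.39)
  cons <- observed_ns_test(N = 494, S = 86,
                           background = neutral_background(expected_ratio = 4.18),
                           seed = 1)
  expect_equal(round(cons$observed_ratio, 2), 5.74)
  expect_equal(round(cons$alpha, 2), 0.27)
})

test_that("alpha is zero iff observed equals expected; S = 0 degenerates", {
  bg <- neutral_background(background_N = 38, background_S = 10)
  r <- observed_ns_test(N = 38, S = 10, background = bg, seed = 1)
  expect_equal(r$alpha, 0)
  d <- observed_ns_test(N = 7, S = 0, background = bg)
  expect_true(d$degenerate)
  expect_equal(d$alpha, 1)
  expect_true(all(is.na(d$ratio_ci)))
})

test_that("Fisher p equals exhaustive hypergeometric enumeration", {
  set.seed(2)
  bgs <- matrix(sample(1:30, 80, replace = TRUE), ncol = 4)
  for (i in seq_len(nrow(bgs))) {
    a <- bgs[i, 1]; b <- bgs[i, 2]; cc <- bgs[i, 3]; d <- bgs[i, 4]
    r <- observed_ns_test(N = a, S = b, n_boot = 2,
                          background = neutral_background(cc, d))
    expect_equal(r$fisher_p, fisher_oracle(a, b, cc, d), tolerance = 1e-10)
  }
})

test_that("binomial bootstrap is distributionally the label resampling", {
  set.seed(9)
  N <- 120; S <- 40; n <- N + S
  labels <- c(rep(1, N), rep(0, S))
  explicit <- replicate(4000, sum(sample(labels, n, replace = TRUE)))
  r <- observed_ns_test(N = N, S = S, n_boot = 4000, seed = 99,
                        background = neutral_background(expected_ratio = 3))
  boot_N <- round(r$boot_ratio * n / (1 + r$boot_ratio))
  expect_lt(abs(mean(explicit) - mean(boot_N)), 3 * sd(explicit) / sqrt(4000) * 2)
  expect_lt(abs(sd(explicit) - sd(boot_N)) / sd(explicit), 0.1)
})

test_that("bootstrap ratio CI covers the true ratio about 95% of the time", {
  set.seed(17)
  p_true <- 0.78
  n_sites <- 200
  true_ratio <- p_true / (1 - p_true)
  hits <- vapply(seq_len(500), function(r) {
    N <- rbinom(1, n_sites, p_true)
    res <- observed_ns_test(N = N, S = n_sites - N, n_boot = 400,
                            background = neutral_background(expected_ratio = 1))
    res$ratio_ci[1] <= true_ratio && true_ratio <= res$ratio_ci[2]
  }, logical(1))
  expect_gt(mean(hits), 0.92)
  expect_lt(mean(hits), 0.985)
})

test_that("PSEB classification follows the per-gene ratio rule", {
  sites <- data.frame(
    gene_id = c(rep("g1", 7), rep("g2", 3), rep("g3", 6)),
    category = c(rep("N", 6), "S",          # g1: 6/1 -> PSEB
                 rep("N", 3),               # g2: 3/0 -> PSEB
                 rep("N", 3), rep("S", 3))) # g3: 3/3 -> not
  ps <- classify_pseb(sites)
  expect_setequal(ps$pseb_genes, c("g1", "g2"))
  expect_equal(unname(ps$pseb_counts), c(9, 1))
  expect_equal(unname(ps$non_pseb_counts), c(3, 3))
  # published pooled PSEB ratio check: 447/8 -> 55.9
  expect_equal(round(447 / 8, 1), 55.9)
})

test_that("stratified tests run per stratum and flag problems", {
  bg <- neutral_background(background_N = 380, background_S = 100)
  sites <- data.frame(category = c(rep("N", 30), rep("S", 10), rep("N", 5)),
                      stratum = c(rep("X", 20), rep("auto", 20), rep("degen", 5)))
  res <- stratified_ns(sites, bg, n_boot = 50, seed = 1)
  expect_named(res, c("X", "auto", "degen"))
  expect_true(res$degen$degenerate)
  sites2 <- data.frame(category = "UTR3", stratum = "empty")
  expect_warning(res2 <- stratified_ns(sites2, bg), "omitted")
  expect_length(res2, 0)
})

test_that("the N/S ratio rises with the editing-level cutoff when N levels are higher", {
  set.seed(31)
  n <- 4000
  sites <- data.frame(
    category = c(rep("N", n * 0.7), rep("S", n * 0.3)),
    level = c(rbeta(n * 0.7, 2, 4), rbeta(n * 0.3, 1.2, 6)))
  cuts <- c(0, 0.1, 0.2, 0.3, 0.4, 0.5)
  ratios <- vapply(cuts, function(cut) {
    sub <- sites[sites$level >= cut, ]
    sum(sub$category == "N") / sum(sub$category == "S")
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("fixed vs polymorphic comparison rescales to a common background", {
  # equal backgrounds: no adjustment, plain Fisher test
  same <- fixed_vs_polymorphic_test(100, 10, 50, 20, 4, 4)
  expect_equal(same$adjusted_poly_S, 20)
  expect_equal(same$fisher_p, fisher_oracle(100, 10, 50, 20), tolerance = 1e-10)
  # the female all-sites row: fixed 109/13 vs polymorphic 89/54, backgrounds
  # 4.18 vs 3.80: the adjusted table remains strongly significant
  adj <- fixed_vs_polymorphic_test(109, 13, 89, 54, 4.18, 3.80)
  expect_equal(adj$adjusted_poly_S, round(54 * 3.80 / 4.18))
  expect_lt(adj$fisher_p, 1e-4)
})

test_that("expression split halves the edited genes deterministically", {
  rpkm <- data.frame(gene_id = paste0("g", 1:10), rpkm = c(1:5, 5, 7:10))
  sp <- split_by_expression(rpkm)
  expect_equal(sum(sp$expression_group == "Highly"), 5)
  expect_equal(sp$expression_group[rpkm$rpkm == 10], "Highly")
})
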