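test_that("the generator is fully deterministic under its seed", {
  cfg <- generator_config(n_genes = 8, seed = 99)
  r1 <- generate_reference(cfg)
  r2 <- generate_reference(cfg)
  expect_identical(as.character(r1$genome), as.character(r2$genome))
  expect_identical(r1$genes, r2$genes)
  t1 <- generate_editome(r1, cfg)
  t2 <- generate_editome(r2, cfg)
  expect_identical(t1$sites, t2$sites)
  s1 <- simulate_counts(t1, cfg)
  s2 <- simulate_counts(t2, cfg)
  expect_identical(s1$observations, s2$observations)
})

test_that("every generated CDS is structurally valid", {
  cfg <- generator_config(n_genes = 12, seed = 23)
  ref <- generate_reference(cfg)
  expect_silent(validate_gene_models(ref$genes))
  for (gid in unique(ref$genes$gene_id)) {
    cds <- editome:::cds_sequence(ref$genes, ref$genome, gid)
    expect_equal(nchar(cds) %% 3, 0)
    expect_equal(substr(cds, 1, 3), "ATG")
    prot <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    # exactly one stop, at the end
    expect_equal(substr(prot, nchar(prot), nchar(prot)), "*")
    expect_false(grepl("\\*", substr(prot, 1, nchar(prot) - 1)))
  }
  # both strands represented
  sp <- gene_spans(ref$genes)
  expect_true(all(c("+", "-") %in% sp$strand))
})

test_that("reference base composition is approximately uniform", {
  cfg <- generator_config(n_genes = 100, seed = 77)
  ref <- generate_reference(cfg)
  counts <- Biostrings::alphabetFrequency(ref$genome[[1]])[c("A", "C", "G", "T")]
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
})

test_that("editome truth respects its construction rules", {
  cfg <- generator_config(n_genes = 15, seed = 31)
  ref <- generate_reference(cfg)
  truth <- generate_editome(ref, cfg)
  ed <- truth$sites[truth$sites$edited, ]
  # edited sites are transcript-strand adenosines with positive levels
  expect_true(all(ed$true_level > 0))
  ann <- annotate_sites(ed[, c("chrom", "pos")], ref$genes, ref$genome)
  expect_equal(ann$category, ed$category)
  # zero editing rate -> empty truth
  cfg0 <- generator_config(n_genes = 5, editing_rate = 0,
                           noncoding_rate_factor = 0, seed = 31)
  ref0 <- generate_reference(cfg0)
  truth0 <- generate_editome(ref0, cfg0)
  expect_equal(sum(truth0$sites$edited), 0)
  # sharing probability 1 -> every edited site conserved in all species
  cfg1 <- generator_config(n_genes = 8, p_share_sibling = 1,
                           p_share_outgroup = 1, seed = 31)
  ref1 <- generate_reference(cfg1)
  truth1 <- generate_editome(ref1, cfg1)
  ed1 <- truth1$sites[truth1$sites$edited, ]
  expect_true(all(ed1$present_sibling & ed1$present_outgroup))
  # PSEB genes have higher realized per-gene N/S in expectation
  cfgp <- generator_config(n_genes = 40, pseb_fraction = 0.3,
                           pseb_n_factor = 10, pseb_s_factor = 0.1,
                           editing_rate = 0.03, seed = 41)
  refp <- generate_reference(cfgp)
  truthp <- generate_editome(refp, cfgp)
  edp <- truthp$sites[truthp$sites$edited & truthp$sites$category %in% c("N", "S"), ]
  edp$pseb <- truthp$genes$pseb[match(edp$gene_id, truthp$genes$gene_id)]
  ns <- function(x) sum(x$category == "N") / max(1, sum(x$category == "S"))
  expect_gt(ns(edp[edp$pseb, ]), ns(edp[!edp$pseb, ]))
})

test_that("simulated counts trace back to the truth and obey the read model", {
  cfg <- generator_config(n_genes = 10, seed = 63)
  ref <- generate_reference(cfg)
  truth <- generate_editome(ref, cfg)
  sim <- simulate_counts(truth, cfg, include_null_pair = TRUE)
  obs <- sim$observations
  expect_true(all(site_key(obs$chrom, obs$pos) %in% truth$sites$site_id))
  expect_true(all(obs$edited_count <= obs$coverage))
  # the editing-null mutant shows only error-level signal
  mut <- obs[obs$library_id == "mutant", ]
  expect_lt(sum(mut$edited_count) / max(1, sum(mut$coverage)), 0.01)
  # l = 1 with no sequencing error gives L = C everywhere
  cfg2 <- generator_config(n_genes = 5, eps_true = 0, seed = 64,
                           temp_effect_silent = 0, temp_effect_N = 0,
                           level_shape_N = c(1e6, 1e-6),
                           level_shape_S = c(1e6, 1e-6),
                           level_shape_noncoding = c(1e6, 1e-6))
  ref2 <- generate_reference(cfg2)
  truth2 <- generate_editome(ref2, cfg2)
  truth2$sites$true_level[truth2$sites$edited] <- 1
  sim2 <- simulate_counts(truth2, cfg2)
  obs2 <- sim2$observations
  ed_keys <- truth2$sites$site_id[truth2$sites$edited]
  ed_obs <- obs2[site_key(obs2$chrom, obs2$pos) %in% ed_keys, ]
  expect_true(all(ed_obs$edited_count == ed_obs$coverage))
})

test_that("default marginals match the intended study conditions", {
  cfg <- generator_config(n_genes = 40, seed = 3)
  ref <- generate_reference(cfg)
  truth <- generate_editome(ref, cfg)
  sim <- simulate_counts(truth, cfg)
  med_cov <- stats::median(sim$observations$coverage)
  expect_gte(med_cov, 5)
  expect_lte(med_cov, 9)
  ed <- truth$sites[truth$sites$edited, ]
  expect_gt(mean(ed$true_level[ed$category == "N"]),
            mean(ed$true_level[ed$category == "S"]))
})

test_that("the population panel plants polymorphic and fixed sites as labelled", {
  cfg <- generator_config(n_genes = 15, editing_rate = 0.02, seed = 47)
  ref <- generate_reference(cfg)
  truth <- generate_editome(ref, cfg)
  panel <- generate_population_panel(truth, cfg)
  lab <- panel$truth_labels
  obs <- panel$observations
  poly <- lab[lab$status == "polymorphic", ]
  expect_gt(nrow(poly), 0)
  for (i in seq_len(min(5, nrow(poly)))) {
    ed_str <- strsplit(poly$edited_strains[i], ",")[[1]]
    sub <- obs[obs$site_id == poly$site_id[i] & !(obs$strain %in% ed_str), ]
    # non-edited strains carry at most error-level signal
    expect_lt(sum(sub$edited_count) / max(1, sum(sub$coverage)), 0.02)
  }
  # fixed sites are the outgroup-edited set
  expect_setequal(panel$outgroup_detected, lab$site_id[lab$status == "fixed"])
  # without the outgroup no site can be called fixed
  fx <- obs[obs$site_id %in% panel$outgroup_detected & obs$sex == "F", ]
  res <- call_fixed_sites(fx, outgroup_detected = character(0))
  expect_false(any(res$fixed))
})
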