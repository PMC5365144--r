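make_ortho <- function(site_id, species, C, L, n_lib = length(C)) {
  data.frame(site_id = site_id, species = species,
             library_id = paste0(species, seq_len(n_lib)),
             coverage = C, edited_count = L, stringsAsFactors = FALSE)
}

test_that("conservation patterns classify present, absent and undetermined", {
  focal <- data.frame(site_id = c("c:1", "c:2", "c:3"),
                      level = c(0.3, 0.2, 0.4))
  ortho <- rbind(
    # c:1 edited in both species
    make_ortho("c:1", "sibling", c(150, 150), c(40, 35)),
    make_ortho("c:1", "outgroup", c(150, 150), c(30, 50)),
    # c:2 edited in sibling; outgroup covered 500x, zero edited reads
    make_ortho("c:2", "sibling", c(150, 150), c(30, 25)),
    make_ortho("c:2", "outgroup", c(250, 250), c(0, 0)),
    # c:3 poorly covered elsewhere
    make_ortho("c:3", "sibling", 50, 10),
    make_ortho("c:3", "outgroup", 30, 0))
  res <- call_conservation_patterns(focal, ortho,
                                    config = absence_config(absence_cutoff = 2e-4))
  expect_equal(res$pattern[res$site_id == "c:1"], "conserved")
  expect_equal(res$pattern[res$site_id == "c:2"], "absent_in_outgroup")
  expect_equal(res$outgroup_status[res$site_id == "c:2"], "absent")
  expect_equal(res$pattern[res$site_id == "c:3"], "undetermined")
  # sites below the focal level floor are excluded
  lowlev <- data.frame(site_id = "c:9", level = 0.01)
  expect_equal(nrow(call_conservation_patterns(lowlev, ortho)), 0)
})

test_that("polymorphic calls require reliable presence plus confident absence", {
  obs <- rbind(
    # p:1 detected in one strain at 0.4, zero in four strains at 50x
    data.frame(site_id = "p:1", strain = paste0("s", 1:5),
               coverage = c(60, 50, 50, 50, 50),
               edited_count = c(24, 0, 0, 0, 0)),
    # p:2 detected everywhere (no zero strain): not a candidate
    data.frame(site_id = "p:2", strain = paste0("s", 1:5),
               coverage = rep(50, 5), edited_count = rep(12, 5)),
    # p:3 zero everywhere (no detection): not a candidate
    data.frame(site_id = "p:3", strain = paste0("s", 1:5),
               coverage = rep(50, 5), edited_count = rep(0, 5)))
  res <- call_polymorphic_sites(obs)
  expect_equal(res$site_id, "p:1")
  expect_true(res$polymorphic_I)
  expect_lt(res$P_D0_I, (0.6)^200 * 2)  # near the eps = 0 closed form
  # assumed levels: mean of detected strains, capped at 0.05 for Level II
  obs2 <- data.frame(site_id = "p:4", strain = paste0("s", 1:5),
                     coverage = rep(100, 5),
                     edited_count = c(20, 30, 10, 0, 0))
  res2 <- call_polymorphic_sites(obs2)
  expect_equal(res2$assumed_level_I, 0.2)
  expect_equal(res2$assumed_level_II, 0.05)
  # a site edited in the outgroup is excluded up front
  expect_null(call_polymorphic_sites(obs[obs$site_id == "p:1", ],
                                     exclude_sites = "p:1"))
})

test_that("fixed calls require support in every strain plus the outgroup", {
  mk <- function(id, L) data.frame(site_id = id, strain = paste0("s", 1:5),
                                   coverage = rep(50, 5), edited_count = L)
  obs <- rbind(mk("f:1", c(10, 8, 6, 12, 9)),    # strong everywhere
               mk("f:2", c(10, 8, 6, 12, 1)),    # one weak strain
               mk("f:3", c(10, 8, 6, 12, 9)))    # strong but no outgroup
  res <- call_fixed_sites(obs, outgroup_detected = c("f:1", "f:2"))
  expect_true(res$fixed[res$site_id == "f:1"])
  expect_false(res$fixed[res$site_id == "f:2"])
  expect_false(res$fixed[res$site_id == "f:3"])
  # an uncovered strain makes the site uncallable
  un <- mk("f:4", c(10, 8, 6, 12, 0))
  un$coverage[5] <- 0
  res2 <- call_fixed_sites(un, outgroup_detected = "f:4")
  expect_false(res2$callable)
  expect_false(res2$fixed)
})

test_that("SNP association needs concordant direction and significance in both sexes", {
  strains <- paste0("s", 1:5)
  lv <- function(sid, sx, l) data.frame(site_id = sid, sex = sx,
                                        strain = strains, level = l)
  gt <- function(g) data.frame(snp_id = "snp1", chrom = "c", pos = 1200L,
                               strain = strains, genotype = g)
  sites <- data.frame(site_id = "e:1", chrom = "c", pos = 1000L)
  lev_sep <- c(0.1, 0.1, 0.1, 0.4, 0.4)
  # perfect separation, same direction in both sexes -> associated
  res <- snp_level_association(rbind(lv("e:1", "F", lev_sep),
                                     lv("e:1", "M", lev_sep)),
                               gt(c(0, 0, 0, 1, 1)), sites)
  expect_equal(nrow(res$pairs), 1)
  expect_equal(res$per_site$n_snps, 1)
  expect_equal(res$per_site$nearest_distance, 200)
  # opposite direction in males -> rejected
  res2 <- snp_level_association(rbind(lv("e:1", "F", lev_sep),
                                      lv("e:1", "M", rev(lev_sep))),
                                gt(c(0, 0, 0, 1, 1)), sites)
  expect_equal(nrow(res2$pairs), 0)
  # constant levels -> no association
  res3 <- snp_level_association(rbind(lv("e:1", "F", rep(0.2, 5)),
                                      lv("e:1", "M", rep(0.2, 5))),
                                gt(c(0, 0, 0, 1, 1)), sites)
  expect_equal(nrow(res3$pairs), 0)
  # monomorphic SNP skipped
  res4 <- snp_level_association(rbind(lv("e:1", "F", lev_sep),
                                      lv("e:1", "M", lev_sep)),
                                gt(rep(0, 5)), sites)
  expect_equal(nrow(res4$pairs), 0)
  # the exact permutation option: 10 distinct orderings of a 2/3 genotype
  # split, two of which reach |r| = 1, so p = 0.2 and no call at 0.05
  res5 <- snp_level_association(rbind(lv("e:1", "F", lev_sep),
                                      lv("e:1", "M", lev_sep)),
                                gt(c(0, 0, 0, 1, 1)), sites,
                                method = "permutation")
  expect_equal(nrow(res5$pairs), 0)
  # SNPs outside the 10 kb window are never tested
  far <- gt(c(0, 0, 0, 1, 1)); far$pos <- 40000L
  res6 <- snp_level_association(rbind(lv("e:1", "F", lev_sep),
                                      lv("e:1", "M", lev_sep)), far, sites)
  expect_equal(nrow(res6$pairs), 0)
})
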