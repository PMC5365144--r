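#' Thresholds for absence, conservation and population calls
#'
#' @param level_source `"level_I"` (assumed level = mean across strains with
#'   reliable editing) or `"level_II"` (that mean capped at 0.05).
#' @param detect_p_e1 Per-strain `P_k(E1)` required to call editing reliably
#'   detected when screening for polymorphism (default 0.999).
#' @param fixed_p_e1 Per-strain `P_k(E1)` required in *every* strain for a
#'   fixed call (default 0.95).
#' @param absence_fdr BH FDR level on joint `P(D0)` for absence calls
#'   (default 0.05); used when `absence_cutoff` is NULL.
#' @param absence_cutoff Optional fixed joint `P(D0)` cutoff (the
#'   conservation analysis uses 2e-4); overrides the FDR rule.
#' @param min_focal_level Minimum focal-species editing level for a site to
#'   enter the conservation gain/loss analysis (default 0.05).
#' @param min_ortho_coverage Minimum total raw reads per non-focal species
#'   (default 200).
#' @param species_fdr FDR for cross-species joint detection (default 0.05).
#' @return List of class `absence_config`.
#' @export
absence_config <- function(level_source = c("level_I", "level_II"),
                           detect_p_e1 = 0.999, fixed_p_e1 = 0.95,
                           absence_fdr = 0.05, absence_cutoff = NULL,
                           min_focal_level = 0.05, min_ortho_coverage = 200,
                           species_fdr = 0.05) {
  structure(list(level_source = match.arg(level_source),
                 detect_p_e1 = detect_p_e1, fixed_p_e1 = fixed_p_e1,
                 absence_fdr = absence_fdr, absence_cutoff = absence_cutoff,
                 min_focal_level = min_focal_level,
                 min_ortho_coverage = min_ortho_coverage,
                 species_fdr = species_fdr),
            class = "absence_config")
}

#' Conservation gain/loss patterns over a three-species tree
#'
#' For focal-species editing sites (level at least `min_focal_level`) with
#' orthologous observations in a sibling and an outgroup species
#' (tree `((focal, sibling), outgroup)`), classifies each species as
#' *present* (joint detection at `species_fdr`), *absent* (joint `P(D0)`
#' below the configured significance, assuming the focal editing level), or
#' *undetermined*, and maps the triple to a parsimony pattern: `conserved`
#' (all three), `absent_in_outgroup` (focal + sibling edited, outgroup
#' confidently unedited), `focal_specific` (both others confidently
#' unedited), otherwise `undetermined`.
#'
#' @param focal Data frame of focal sites: `site_id`, `level` (mean focal
#'   editing level).
#' @param ortho_obs Long data frame of orthologous observations: `site_id`,
#'   `species` (`"sibling"` or `"outgroup"`), `library_id`, `coverage`,
#'   `edited_count`. Sites absent from the map are undetermined.
#' @param eps Per-read A-to-G error probability.
#' @param config An [absence_config()].
#' @return Per-site data frame: `site_id`, `level`, per-species status
#'   (`sibling_status`, `outgroup_status` in present/absent/undetermined),
#'   `pattern`, `reason`.
#' @export
call_conservation_patterns <- function(focal, ortho_obs,
                                       eps = scaled_error_rate(),
                                       config = absence_config()) {
  focal <- focal[focal$level >= config$min_focal_level, , drop = FALSE]
  species_status <- function(sp) {
    sub <- ortho_obs[ortho_obs$species == sp, , drop = FALSE]
    ids <- focal$site_id
    cov_tot <- tapply(sub$coverage, factor(sub$site_id, levels = ids), sum)
    cov_tot[is.na(cov_tot)] <- 0
    usable <- cov_tot >= config$min_ortho_coverage
    jp <- vapply(ids, function(id) {
      s <- sub[sub$site_id == id & sub$coverage > 0, , drop = FALSE]
      if (!nrow(s)) return(NA_real_)
      joint_editing_prob(s$coverage, s$edited_count, eps)$P_E0
    }, numeric(1))
    q <- rep(NA_real_, length(ids))
    q[usable & !is.na(jp)] <- fdr_adjust(jp[usable & !is.na(jp)])
    detected <- !is.na(q) & q <= config$species_fdr
    # absence: joint P(D0) over zero-signal libraries at the focal level
    pd0 <- vapply(seq_along(ids), function(i) {
      s <- sub[sub$site_id == ids[i] & sub$coverage > 0 &
                 sub$edited_count == 0, , drop = FALSE]
      if (!nrow(s)) return(NA_real_)
      joint_nondetection_prob(s$coverage, focal$level[i], eps)$P_D0
    }, numeric(1))
    absent <- rep(FALSE, length(ids))
    cand <- usable & !detected & !is.na(pd0)
    if (any(cand)) {
      if (!is.null(config$absence_cutoff)) {
        absent[cand] <- pd0[cand] < config$absence_cutoff
      } else {
        qq <- fdr_adjust(pd0[cand])
        absent[cand] <- qq <= config$absence_fdr
      }
    }
    status <- rep("undetermined", length(ids))
    status[detected] <- "present"
    status[absent] <- "absent"
    status[!usable] <- "undetermined"
    status
  }
  sib <- species_status("sibling")
  out <- species_status("outgroup")
  pattern <- rep("undetermined", nrow(focal))
  pattern[sib == "present" & out == "present"] <- "conserved"
  pattern[sib == "present" & out == "absent"] <- "absent_in_outgroup"
  pattern[sib == "absent" & out == "absent"] <- "focal_specific"
  data.frame(site_id = focal$site_id, level = focal$level,
             sibling_status = sib, outgroup_status = out,
             pattern = pattern, stringsAsFactors = FALSE)
}

#' Call polymorphic editing sites across strains
#'
#' A site (within one sex) is a polymorphism candidate when editing is
#' reliably detected in at least one strain (`P_k(E1) > 0.999`) and at least
#' one covered strain shows zero edited reads; sites edited in the outgroup
#' species are excluded first. The joint non-detection probability `P(D0)`
#' over the zero-signal strains is computed under two assumed-level rules:
#' Level I uses the mean level of the detected strains; Level II caps that
#' mean at 0.05. A candidate is called polymorphic when its `P(D0)` is
#' significant (BH FDR over candidates by default, or a fixed cutoff).
#'
#' @param obs Long data frame: `site_id`, `strain`, `coverage`,
#'   `edited_count` (one sex).
#' @param exclude_sites Site ids edited in the outgroup species (removed
#'   before candidate screening).
#' @param eps Per-read A-to-G error probability.
#' @param config An [absence_config()].
#' @return Per-candidate data frame with per-level assumed levels, `P_D0`,
#'   q-values and `polymorphic_I` / `polymorphic_II` calls, plus `n_detected`
#'   and `n_zero` strain counts.
#' @export
call_polymorphic_sites <- function(obs, exclude_sites = character(0),
                                   eps = scaled_error_rate(),
                                   config = absence_config()) {
  obs <- obs[!(obs$site_id %in% exclude_sites) & obs$coverage > 0, , drop = FALSE]
  if (!nrow(obs)) return(NULL)
  obs$p_e1 <- 1 - per_library_error_prob(obs$coverage, obs$edited_count, eps)
  res <- lapply(split(obs, obs$site_id), function(s) {
    det <- s$p_e1 > config$detect_p_e1
    zero <- s$edited_count == 0
    if (!any(det) || !any(zero)) return(NULL)
    mean_level <- mean(s$edited_count[det] / s$coverage[det])
    l1 <- mean_level
    l2 <- min(mean_level, 0.05)
    data.frame(site_id = s$site_id[1], n_detected = sum(det), n_zero = sum(zero),
               assumed_level_I = l1, assumed_level_II = l2,
               P_D0_I = joint_nondetection_prob(s$coverage[zero], l1, eps)$P_D0,
               P_D0_II = joint_nondetection_prob(s$coverage[zero], l2, eps)$P_D0,
               stringsAsFactors = FALSE)
  })
  cand <- do.call(rbind, res)
  if (is.null(cand)) return(NULL)
  rownames(cand) <- NULL
  if (!is.null(config$absence_cutoff)) {
    cand$q_I <- NA_real_; cand$q_II <- NA_real_
    cand$polymorphic_I <- cand$P_D0_I < config$absence_cutoff
    cand$polymorphic_II <- cand$P_D0_II < config$absence_cutoff
  } else {
    cand$q_I <- fdr_adjust(cand$P_D0_I)
    cand$q_II <- fdr_adjust(cand$P_D0_II)
    cand$polymorphic_I <- cand$q_I <= config$absence_fdr
    cand$polymorphic_II <- cand$q_II <= config$absence_fdr
  }
  cand
}

#' Call editing sites fixed across strains
#'
#' Fixed means editing is supported in every strain (`P_k(E1) > 0.95` in each,
#' all strains covered) *and* the orthologous site is edited in the same-sex
#' sample of the outgroup species (guarding against reference-strain
#' artifacts given the small strain panel).
#'
#' @param obs Long data frame: `site_id`, `strain`, `coverage`,
#'   `edited_count` (one sex).
#' @param outgroup_detected Site ids with editing in the same-sex outgroup.
#' @param n_strains Number of strains expected in the panel (default 5).
#' @param eps Per-read A-to-G error probability.
#' @param config An [absence_config()].
#' @return Per-site data frame: `site_id`, `callable` (all strains covered),
#'   `min_P_E1`, `outgroup_edited`, `fixed`.
#' @export
call_fixed_sites <- function(obs, outgroup_detected, n_strains = 5,
                             eps = scaled_error_rate(),
                             config = absence_config()) {
  res <- lapply(split(obs, obs$site_id), function(s) {
    covered <- s$coverage > 0
    callable <- sum(covered) >= n_strains
    min_p <- if (callable) {
      min(1 - per_library_error_prob(s$coverage[covered],
                                     s$edited_count[covered], eps))
    } else NA_real_
    og <- s$site_id[1] %in% outgroup_detected
    data.frame(site_id = s$site_id[1], callable = callable, min_P_E1 = min_p,
               outgroup_edited = og,
               fixed = callable && !is.na(min_p) &&
                 min_p > config$fixed_p_e1 && og,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# All distinct permutations of a small vector (n <= 7), as a list.
all_permutations <- function(x) {
  n <- length(x)
  if (n <= 1) return(list(x))
  out <- list()
  for (i in seq_len(n)) {
    for (p in all_permutations(x[-i])) out[[length(out) + 1L]] <- c(x[i], p)
  }
  unique(out)
}

# Correlation test of level vs genotype; returns r and p (NA if degenerate).
genotype_level_test <- function(level, genotype, method) {
  if (length(unique(genotype)) < 2 || stats::sd(level) == 0) {
    return(c(r = NA_real_, p = NA_real_))
  }
  r_obs <- stats::cor(level, genotype)
  if (method == "pearson") {
    if (abs(r_obs) >= 1 - 1e-12) return(c(r = r_obs, p = 0))
    p <- stats::cor.test(level, genotype)$p.value
  } else {
    perms <- all_permutations(genotype)
    rs <- vapply(perms, function(g) stats::cor(level, g), numeric(1))
    p <- mean(abs(rs) >= abs(r_obs) - 1e-12)
  }
  c(r = r_obs, p = p)
}

#' Associate SNP genotypes with editing-level variation across strains
#'
#' For each polymorphic editing site shared by both sexes, tests every SNP
#' within `window` bp for association between its 0/1 genotype across the
#' strain panel and the per-strain editing level, separately per sex. A
#' (site, SNP) pair is reported only when the effect direction agrees between
#' the sexes and both tests reach `p < alpha`. Monomorphic SNPs are skipped.
#'
#' The default test is the Pearson correlation t-test; an exact permutation
#' p-value over all distinct orderings of the genotype vector is available
#' with `method = "permutation"`.
#'
#' @param levels Long data frame: `site_id`, `sex` (`"F"`/`"M"`), `strain`,
#'   `level`.
#' @param genotypes Long data frame: `snp_id`, `chrom`, `pos`, `strain`,
#'   `genotype` (0 = reference, 1 = alternative).
#' @param sites Data frame `site_id`, `chrom`, `pos` for the focal sites.
#' @param window Flanking window in bp (default 10000).
#' @param method `"pearson"` (default) or `"permutation"`.
#' @param alpha Per-sex significance threshold (default 0.05).
#' @return List with `pairs` (associated site-SNP pairs with per-sex `r` and
#'   `p` and the SNP distance) and `per_site` (SNP count and nearest
#'   associated SNP distance per site).
#' @export
snp_level_association <- function(levels, genotypes, sites, window = 10000,
                                  method = c("pearson", "permutation"),
                                  alpha = 0.05) {
  method <- match.arg(method)
  pairs <- list()
  for (i in seq_len(nrow(sites))) {
    sid <- sites$site_id[i]
    snps <- genotypes[genotypes$chrom == sites$chrom[i] &
                        abs(genotypes$pos - sites$pos[i]) <= window, , drop = FALSE]
    if (!nrow(snps)) next
    for (snp in unique(snps$snp_id)) {
      g <- snps[snps$snp_id == snp, , drop = FALSE]
      res <- lapply(c("F", "M"), function(sx) {
        lv <- levels[levels$site_id == sid & levels$sex == sx, , drop = FALSE]
        m <- merge(lv, g[, c("strain", "genotype")], by = "strain")
        if (nrow(m) < 3) return(c(r = NA_real_, p = NA_real_))
        genotype_level_test(m$level, m$genotype, method)
      })
      rF <- res[[1]]["r"]; pF <- res[[1]]["p"]
      rM <- res[[2]]["r"]; pM <- res[[2]]["p"]
      ok <- !is.na(rF) && !is.na(rM) && sign(rF) == sign(rM) &&
        !is.na(pF) && !is.na(pM) && pF < alpha && pM < alpha
      if (ok) {
        pairs[[length(pairs) + 1L]] <- data.frame(
          site_id = sid, snp_id = snp,
          distance = abs(g$pos[1] - sites$pos[i]),
          r_F = unname(rF), p_F = unname(pF),
          r_M = unname(rM), p_M = unname(pM), stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(site_id = character(), snp_id = character(), distance = numeric(),
               r_F = numeric(), p_F = numeric(), r_M = numeric(), p_M = numeric())
  per_site <- if (nrow(pairs)) {
    do.call(rbind, lapply(split(pairs, pairs$site_id), function(p) {
      data.frame(site_id = p$site_id[1], n_snps = nrow(p),
                 nearest_distance = min(p$distance), stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(site_id = character(), n_snps = integer(),
               nearest_distance = numeric())
  }
  rownames(per_site) <- NULL
  list(pairs = pairs, per_site = per_site)
}
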