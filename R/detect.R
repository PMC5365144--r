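#' Detection thresholds for the five-class confidence scheme
#'
#' Defaults reproduce the published criteria: Class I at FDR 0.001 with
#' maximum per-library coverage `C_max >= 10`, summed coverage
#' `C_total >= 40` and detection in at least two libraries; Class II (among
#' the remaining multi-library sites) at FDR 0.01 with `C_max >= 5`,
#' `C_total >= 16`; Class III for remaining sites with joint `P(E1) > 0.99`;
#' Class IV detected in at least one library with `P(E1) <= 0.99`; Class V
#' covered but with no detection. Per-library "detection" means passing the
#' high-confidence filter: level > 0.01, coverage >= 5, at least 2 edited
#' alleles and `P_k(E0) < 1e-4`.
#'
#' @param fdr_class1,fdr_class2 FDR thresholds on BH q-values.
#' @param cmax_class1,ctotal_class1,cmax_class2,ctotal_class2 Coverage gates.
#' @param min_libraries Libraries with detection required for Classes I/II.
#' @param p_e1_class3 Joint `P(E1)` threshold separating Class III from IV.
#' @param level_min,cov_min,edited_min,p_e0_max Per-library high-confidence
#'   filter thresholds.
#' @return A list of thresholds (class `detection_config`).
#' @export
detection_config <- function(fdr_class1 = 0.001, cmax_class1 = 10, ctotal_class1 = 40,
                             fdr_class2 = 0.01, cmax_class2 = 5, ctotal_class2 = 16,
                             min_libraries = 2, p_e1_class3 = 0.99,
                             level_min = 0.01, cov_min = 5, edited_min = 2,
                             p_e0_max = 1e-4) {
  structure(list(fdr_class1 = fdr_class1, cmax_class1 = cmax_class1,
                 ctotal_class1 = ctotal_class1, fdr_class2 = fdr_class2,
                 cmax_class2 = cmax_class2, ctotal_class2 = ctotal_class2,
                 min_libraries = min_libraries, p_e1_class3 = p_e1_class3,
                 level_min = level_min, cov_min = cov_min,
                 edited_min = edited_min, p_e0_max = p_e0_max),
            class = "detection_config")
}

#' Per-library high-confidence detection filter
#'
#' TRUE when a single library's observation by itself supports editing:
#' editing level above `level_min`, coverage and edited-allele counts above
#' their floors, and a per-library error tail `P_k(E0)` below `p_e0_max`.
#' Vectorised over observations.
#'
#' @param C,L Coverage and edited count vectors.
#' @param eps Per-read A-to-G error probability.
#' @param config A [detection_config()].
#' @return Logical vector.
#' @examples
#' per_library_highconf_filter(100, 5)  # TRUE
#' per_library_highconf_filter(100, 2)  # FALSE: error tail too heavy
#' @export
per_library_highconf_filter <- function(C, L, eps = scaled_error_rate(),
                                        config = detection_config()) {
  n <- max(length(C), length(L))
  C <- rep_len(C, n); L <- rep_len(L, n)
  ok <- C > 0 & C >= config$cov_min & L >= config$edited_min
  ok[ok] <- (L[ok] / C[ok]) > config$level_min &
    per_library_error_prob(C[ok], L[ok], eps) < config$p_e0_max
  ok
}

#' Detect editing sites across libraries
#'
#' The joint-probability detection pipeline: per-site, per-library error tails
#' are combined in log space into the joint `P(E0)`/`P(E1)`, BH-adjusted into
#' q-values over all expressed candidates (ordered by genomic coordinate for
#' determinism), coverage summaries and per-library detections are computed,
#' and each expressed site is assigned one of the five exclusive confidence
#' classes.
#'
#' @param obs Observation table from [load_site_observations()] (SNP-masked).
#' @param eps Per-read A-to-G error probability.
#' @param config A [detection_config()].
#' @return Per-site data frame: `chrom`, `pos`, `site_id`, `P_E0`, `P_E1`,
#'   `q_value`, `C_max`, `C_total`, `n_covered`, `n_detected`, `max_level`,
#'   `mean_level` (over detected libraries, NA if none), `expressed`,
#'   `site_class` (`"I"`..`"V"`, NA when unexpressed).
#' @export
detect_editing_sites <- function(obs, eps = scaled_error_rate(),
                                 config = detection_config()) {
  obs <- obs[order(obs$chrom, obs$pos, obs$library_id), , drop = FALSE]
  key <- site_key(obs$chrom, obs$pos)
  f <- factor(key, levels = unique(key))
  covered <- obs$coverage > 0
  lp_row <- rep(0, nrow(obs))
  lp_row[covered] <- per_library_error_prob(obs$coverage[covered],
                                            obs$edited_count[covered],
                                            eps, log.p = TRUE)
  det_row <- per_library_highconf_filter(obs$coverage, obs$edited_count, eps, config)
  lev_row <- ifelse(covered, obs$edited_count / obs$coverage, NA_real_)

  agg <- function(x, fun) as.numeric(tapply(x, f, fun))
  out <- data.frame(
    chrom = tapply(obs$chrom, f, `[`, 1L),
    pos = as.integer(tapply(obs$pos, f, `[`, 1L)),
    stringsAsFactors = FALSE
  )
  out$site_id <- levels(f)
  out$log_P_E0 <- agg(lp_row, sum)
  out$C_max <- agg(obs$coverage, max)
  out$C_total <- agg(obs$coverage, sum)
  out$n_covered <- agg(covered, sum)
  out$n_detected <- agg(det_row, sum)
  out$max_level <- suppressWarnings(agg(ifelse(covered, lev_row, -Inf), max))
  out$max_level[out$n_covered == 0] <- NA_real_
  mean_det <- vapply(split(ifelse(det_row, lev_row, NA_real_), f),
                     function(x) mean(x, na.rm = TRUE), numeric(1))
  out$mean_level <- ifelse(out$n_detected > 0, as.numeric(mean_det), NA_real_)
  out$expressed <- out$n_covered > 0
  out$P_E0 <- exp(out$log_P_E0)
  out$P_E1 <- -expm1(out$log_P_E0)
  out$P_E0[!out$expressed] <- NA_real_
  out$P_E1[!out$expressed] <- NA_real_
  out$q_value <- NA_real_
  out$q_value[out$expressed] <- fdr_adjust(out$P_E0[out$expressed])
  rownames(out) <- NULL
  classify_sites(out, config)
}

#' Assign the five exclusive confidence classes
#'
#' Operates on the per-site summary produced by [detect_editing_sites()]
#' (or an equivalent table with `q_value`, `P_E1`, `C_max`, `C_total`,
#' `n_detected`, `expressed`). Classes are exclusive and assigned in order;
#' unexpressed sites get NA.
#'
#' @param sites Per-site summary data frame.
#' @param config A [detection_config()].
#' @return `sites` with a `site_class` column.
#' @export
classify_sites <- function(sites, config = detection_config()) {
  cl <- rep(NA_character_, nrow(sites))
  e <- sites$expressed
  c1 <- e & sites$q_value <= config$fdr_class1 &
    sites$C_max >= config$cmax_class1 & sites$C_total >= config$ctotal_class1 &
    sites$n_detected >= config$min_libraries
  cl[c1] <- "I"
  c2 <- e & is.na(cl) & sites$n_detected >= config$min_libraries &
    sites$q_value <= config$fdr_class2 &
    sites$C_max >= config$cmax_class2 & sites$C_total >= config$ctotal_class2
  cl[c2] <- "II"
  c3 <- e & is.na(cl) & sites$P_E1 > config$p_e1_class3
  cl[c3] <- "III"
  c4 <- e & is.na(cl) & sites$n_detected >= 1
  cl[c4] <- "IV"
  cl[e & is.na(cl)] <- "V"
  sites$site_class <- cl
  sites
}

#' False-positive rate from a wild-type / editing-null pair
#'
#' `N1` counts called sites with editing detected in the wild-type control,
#' `N2` counts those that also show an A-to-G signal in the editing-deficient
#' mutant; the FPR estimate is `N2/N1` (signals surviving in the mutant cannot
#' be editing).
#'
#' @param calls Character vector of called site ids (`"chrom:pos"`).
#' @param wildtype_detected,mutant_detected Site-id sets with editing signal
#'   in the wild-type and mutant samples.
#' @return List with `N1`, `N2`, `rate` (NA with a warning when `N1` is 0).
#' @examples
#' estimate_fpr(paste0("x:", 1:5), paste0("x:", 1:4), paste0("x:", 4:5))
#' @export
estimate_fpr <- function(calls, wildtype_detected, mutant_detected) {
  shared <- intersect(calls, wildtype_detected)
  n1 <- length(shared)
  n2 <- length(intersect(shared, mutant_detected))
  if (n1 == 0) {
    warning("no called site detected in the wild-type control; FPR undefined")
    return(list(N1 = 0L, N2 = 0L, rate = NA_real_))
  }
  list(N1 = n1, N2 = n2, rate = n2 / n1)
}

#' Cluster editing sites within 100 nt
#'
#' Single-linkage chaining per chromosome: consecutive sites closer than
#' `max_gap` nucleotides join the same cluster. Singletons are reported but
#' excluded from the cluster count.
#'
#' @param sites Data frame with `chrom` and `pos`.
#' @param max_gap Distance threshold (default 100); gaps strictly smaller
#'   than this chain sites together.
#' @return List with `members` (data frame `chrom`, `pos`, `cluster`, where
#'   `cluster` is NA for singletons), `n_clusters` (clusters of size >= 2) and
#'   `n_clustered_sites`.
#' @examples
#' cluster_sites(data.frame(chrom = "2L", pos = c(100, 150, 300)))
#' @export
cluster_sites <- function(sites, max_gap = 100) {
  if (!nrow(sites)) {
    return(list(members = cbind(sites, cluster = integer(0)),
                n_clusters = 0L, n_clustered_sites = 0L))
  }
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  newc <- c(TRUE, diff(sites$pos) >= max_gap | sites$chrom[-1] != sites$chrom[-nrow(sites)])
  cid <- cumsum(newc)
  size <- table(cid)
  keep <- size[as.character(cid)] >= 2
  members <- data.frame(chrom = sites$chrom, pos = sites$pos,
                        cluster = ifelse(keep, cid, NA_integer_),
                        stringsAsFactors = FALSE)
  kept_ids <- unique(members$cluster[!is.na(members$cluster)])
  members$cluster <- match(members$cluster, kept_ids)
  list(members = members, n_clusters = length(kept_ids),
       n_clustered_sites = sum(!is.na(members$cluster)))
}
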