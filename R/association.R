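#' Equal-sized rank bins with deterministic tie-breaking
#'
#' Ranks `x` (ties broken by input order, which callers should make genomic
#' order) and cuts the ranks into `n_bins` equal-sized groups.
#'
#' @param x Numeric covariate.
#' @param n_bins Number of bins (default 20).
#' @return Integer bin index, 1 (lowest) .. `n_bins`.
#' @export
rank_bins <- function(x, n_bins = 20) {
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r / (length(x) / n_bins)))
}

#' Editing density vs a covariate over rank bins
#'
#' Bins background adenosines by a covariate (gene expression, site coverage,
#' relative transcript position, dN, phyloP, ...) into `n_bins` equal-sized
#' rank bins and computes the editing density per bin: edited sites over
#' total adenosines (or the sum of editing levels over adenosines for the
#' level-weighted variant). The trend is summarised by a Spearman rank
#' correlation of density against the bin's median covariate.
#'
#' @param background Data frame of background adenosines with columns
#'   `covariate`, `edited` (logical) and, for the weighted variant, `level`
#'   (0 for unedited sites).
#' @param n_bins Number of bins (default 20).
#' @param weighting `"count"` or `"level_weighted"`.
#' @param per_million Also report densities per million adenosines.
#' @return List with `bins` (per-bin `n`, `n_edited`, `density`,
#'   `density_per_million`, `covariate_median`), `rho`, `p_value`, and
#'   `tie_flag` (TRUE when >20% of densities tie).
#' @export
binned_density_correlation <- function(background, n_bins = 20,
                                       weighting = c("count", "level_weighted"),
                                       per_million = TRUE) {
  weighting <- match.arg(weighting)
  b <- rank_bins(background$covariate, n_bins)
  f <- factor(b, levels = seq_len(n_bins))
  n <- as.integer(table(f))
  num <- if (weighting == "count") {
    tapply(background$edited, f, sum)
  } else {
    tapply(background$level, f, sum)
  }
  num[is.na(num)] <- 0
  bins <- data.frame(bin = seq_len(n_bins), n = n,
                     n_edited = as.numeric(num),
                     covariate_median = as.numeric(
                       tapply(background$covariate, f, stats::median)))
  empty <- bins$n == 0
  if (any(empty)) {
    warning(sum(empty), " empty bin(s) dropped")
    bins <- bins[!empty, , drop = FALSE]
  }
  bins$density <- bins$n_edited / bins$n
  if (per_million) bins$density_per_million <- bins$density * 1e6
  tie_flag <- mean(duplicated(bins$density)) > 0.2
  if (length(unique(bins$density)) == 1) {
    rho <- 0; p <- NA_real_
  } else {
    ct <- suppressWarnings(stats::cor.test(bins$covariate_median, bins$density,
                                           method = "spearman"))
    rho <- unname(ct$estimate); p <- ct$p.value
  }
  list(bins = bins, rho = rho, p_value = p, tie_flag = tie_flag)
}

#' Paired 5' vs 3' half-gene density contrast
#'
#' Given adenosine sites labelled with their gene half (`"front"` = 5',
#' `"rear"` = 3') and a bin index (half-gene expression bins or site-coverage
#' bins), computes the editing density per (bin, half) and a paired t-test of
#' rear vs front densities across bins. A rear excess that survives binning
#' by coverage argues the 5'->3' editing gradient is not a depth artifact.
#'
#' @param sites Data frame with `bin`, `half` (`"front"`/`"rear"`) and
#'   `edited` (logical).
#' @param min_bins Minimum usable bins (default 3).
#' @return List with `bins` (per-bin front/rear densities and rear/front
#'   ratio), `t_statistic`, `p_value`, `n_bins_used`.
#' @export
halfgene_paired_test <- function(sites, min_bins = 3) {
  dens <- function(sub) if (nrow(sub)) mean(sub$edited) else NA_real_
  rows <- lapply(split(sites, sites$bin), function(s) {
    data.frame(bin = s$bin[1],
               front = dens(s[s$half == "front", , drop = FALSE]),
               rear = dens(s[s$half == "rear", , drop = FALSE]))
  })
  bins <- do.call(rbind, rows)
  drop <- is.na(bins$front) | is.na(bins$rear)
  if (any(drop)) {
    message(sum(drop), " bin(s) dropped with an empty half")
    bins <- bins[!drop, , drop = FALSE]
  }
  if (nrow(bins) < min_bins) stop("fewer than ", min_bins, " usable bins")
  bins$ratio <- ifelse(bins$front > 0, bins$rear / bins$front, NA_real_)
  if (all(bins$rear == bins$front)) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- stats::t.test(bins$rear, bins$front, paired = TRUE)
  }
  list(bins = bins, t_statistic = unname(tt$statistic), p_value = tt$p.value,
       n_bins_used = nrow(bins))
}

#' Conservation contrast matched on sequencing coverage
#'
#' Ranks nonsynonymous background adenosines by coverage into `n_bins` bins,
#' splits each bin at its median phyloP into conserved and non-conserved
#' halves, and compares the editing densities of the halves with a paired
#' t-test. A density excess in the conserved half that persists within
#' coverage bins cannot be explained by expression-linked detection bias.
#'
#' @param background Data frame with `coverage`, `phylop`, `edited`.
#' @param n_bins Number of coverage bins (default 20).
#' @return List with `bins` (per-bin conserved/non-conserved densities and
#'   their ratio), `t_statistic`, `p_value`.
#' @export
matched_conservation_contrast <- function(background, n_bins = 20) {
  background$bin <- rank_bins(background$coverage, n_bins)
  rows <- lapply(split(background, background$bin), function(s) {
    hi <- s$phylop > stats::median(s$phylop)
    # median split with deterministic assignment of ties to the lower half
    data.frame(bin = s$bin[1],
               conserved = mean(s$edited[hi]),
               non_conserved = mean(s$edited[!hi]))
  })
  bins <- do.call(rbind, rows)
  drop <- is.na(bins$conserved) | is.na(bins$non_conserved)
  bins <- bins[!drop, , drop = FALSE]
  bins$ratio <- ifelse(bins$conserved > 0,
                       bins$non_conserved / bins$conserved, NA_real_)
  if (all(bins$non_conserved == bins$conserved)) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- stats::t.test(bins$non_conserved, bins$conserved, paired = TRUE)
  }
  list(bins = bins, t_statistic = unname(tt$statistic), p_value = tt$p.value)
}

#' Permutation test of editing-site enrichment in hairpin structures
#'
#' Counts how many editing sites fall inside precomputed stable-hairpin
#' intervals, then draws `n_replicates` samples of the same number of
#' positions (with replacement) from the background adenosines and counts
#' their overlaps, giving a null distribution and an empirical enrichment
#' p-value with `(r + 1) / (n + 1)` smoothing.
#'
#' @param sites Data frame `chrom`, `pos` of (exonic) editing sites.
#' @param hairpins Data frame `chrom`, `start`, `end` of hairpin intervals
#'   (1-based closed; e.g. from [read_intervals_bed()]).
#' @param background Data frame `chrom`, `pos` of background adenosines.
#' @param n_replicates Number of random draws (default 1000).
#' @param seed Integer seed.
#' @return List: `observed`, `null_median`, `null_ci` (2.5/97.5% quantiles),
#'   `p_value`.
#' @export
structure_enrichment_test <- function(sites, hairpins, background,
                                      n_replicates = 1000, seed = 1L) {
  hp <- GenomicRanges::GRanges(hairpins$chrom,
                               IRanges::IRanges(hairpins$start, hairpins$end))
  count_in <- function(chrom, pos) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
    sum(IRanges::overlapsAny(gr, hp))
  }
  observed <- count_in(sites$chrom, sites$pos)
  bg_in <- IRanges::overlapsAny(
    GenomicRanges::GRanges(background$chrom,
                           IRanges::IRanges(background$pos, background$pos)), hp)
  set.seed(seed)
  n_draw <- nrow(sites)
  null_counts <- vapply(seq_len(n_replicates), function(r) {
    sum(sample(bg_in, n_draw, replace = TRUE))
  }, numeric(1))
  list(observed = observed,
       null_median = stats::median(null_counts),
       null_ci = stats::quantile(null_counts, c(0.025, 0.975), names = FALSE),
       p_value = (sum(null_counts >= observed) + 1) / (n_replicates + 1))
}

#' Read genomic intervals from BED
#'
#' Imports a BED file with [rtracklayer::import()] and returns 1-based closed
#' intervals matching the package's convention.
#'
#' @param path BED file path.
#' @return Data frame `chrom`, `start`, `end`.
#' @export
read_intervals_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Cluster libraries by their editing-level profiles
#'
#' Restricts to sites with at least `coverage_min` raw reads in every library
#' (the caller supplies the coverage matrix), computes pairwise Pearson
#' correlations of editing levels, and clusters the libraries by average
#' linkage on the distance `1 - r`. The dendrogram is returned and can be
#' written as newick.
#'
#' @param levels Numeric matrix, sites x libraries (complete; no NA).
#' @param coverage Optional matrix of raw coverages matching `levels`; rows
#'   with any library below `coverage_min` are dropped.
#' @param coverage_min Per-library coverage floor (default 20).
#' @return List: `correlation` (library x library Pearson r), `distance`
#'   (1 - r, as matrix), `hclust`, `newick` (character), `n_sites_used`.
#' @export
cluster_libraries <- function(levels, coverage = NULL, coverage_min = 20) {
  if (ncol(levels) < 2) stop("need at least 2 libraries")
  if (!is.null(coverage)) {
    keep <- apply(coverage >= coverage_min, 1, all)
    levels <- levels[keep, , drop = FALSE]
  }
  if (nrow(levels) < 2) stop("fewer than 2 sites pass the coverage filter")
  r <- stats::cor(levels, method = "pearson")
  d <- 1 - r
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  nwk <- ape::write.tree(ape::as.phylo(hc))
  list(correlation = r, distance = d, hclust = hc, newick = nwk,
       n_sites_used = nrow(levels))
}

#' Temperature-shift analysis of editing levels
#'
#' Summarises per-site editing-level changes between a control and a
#' heat-treated condition (`delta = l_treated - l_control`) by functional
#' category (nonsynonymous vs silent), optionally correlates the shifts with
#' a second species' shifts at orthologous sites, and correlates
#' nonsynonymous shifts with host-gene expression log-fold-changes under a
#' grid of expression cutoffs.
#'
#' @param shifts Data frame: `site_id`, `category` (`"N"` or `"silent"`),
#'   `level_control`, `level_treated`, optionally `gene_id`.
#' @param other_species Optional data frame `site_id`, `delta` for the
#'   orthologous sites of a second species.
#' @param expression Optional data frame `gene_id`, `lfc`, `rpkm` (host-gene
#'   expression change and level).
#' @param rpkm_cutoffs Expression cutoffs for the correlation grid.
#' @return List: `category_summary` (mean delta and s.e. per category),
#'   `cross_species` (Pearson r and p, or NULL), `expression_correlation`
#'   (per-cutoff r/p for N sites, or NULL). Degenerate correlations (zero
#'   variance) are reported as NA with `note = "not applicable"`.
#' @export
temperature_shift_analysis <- function(shifts, other_species = NULL,
                                       expression = NULL,
                                       rpkm_cutoffs = c(1, 3, 5, 10)) {
  if (!nrow(shifts)) stop("no shared sites between conditions")
  shifts$delta <- shifts$level_treated - shifts$level_control
  cs <- do.call(rbind, lapply(split(shifts, shifts$category), function(s) {
    data.frame(category = s$category[1], n = nrow(s),
               mean_delta = mean(s$delta),
               se = stats::sd(s$delta) / sqrt(nrow(s)))
  }))
  rownames(cs) <- NULL
  safe_cor <- function(x, y, method = "pearson") {
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(list(r = NA_real_, p = NA_real_, note = "not applicable"))
    }
    ct <- suppressWarnings(stats::cor.test(x, y, method = method))
    list(r = unname(ct$estimate), p = ct$p.value, note = NA_character_)
  }
  cross <- NULL
  if (!is.null(other_species)) {
    m <- merge(shifts[, c("site_id", "delta")], other_species, by = "site_id",
               suffixes = c("", "_other"))
    cross <- c(safe_cor(m$delta, m$delta_other), n = nrow(m))
  }
  expr <- NULL
  if (!is.null(expression) && "gene_id" %in% names(shifts)) {
    nsites <- shifts[shifts$category == "N", , drop = FALSE]
    m <- merge(nsites, expression, by = "gene_id")
    expr <- do.call(rbind, lapply(rpkm_cutoffs, function(cut) {
      sub <- m[m$rpkm >= cut, , drop = FALSE]
      ct <- safe_cor(sub$delta, sub$lfc)
      data.frame(rpkm_cutoff = cut, n = nrow(sub), r = ct$r, p = ct$p)
    }))
  }
  list(category_summary = cs, cross_species = cross,
       expression_correlation = expr)
}
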