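#' Neutral N/S expectation from background adenosines
#'
#' Tallies every CDS adenosine (transcript strand) of the supplied genes —
#' conventionally the genes carrying at least one editing event — into
#' nonsynonymous-if-edited (N) vs synonymous-if-edited (S) counts. Their ratio
#' is the N/S expected if editing hit CDS adenosines at random, the yardstick
#' of the selection test. Stop-codon positions are excluded. An optional
#' conserved-adenosine filter restricts the tally to sites conserved between a
#' species pair (the stricter backgrounds used for cross-species site sets).
#'
#' @param genes Gene-model data frame.
#' @param genome [Biostrings::DNAStringSet] named by chromosome.
#' @param gene_ids Optional subset of genes (e.g. the edited genes).
#' @param conserved_sites Optional character vector of `"chrom:pos"` keys;
#'   only adenosines in it are tallied.
#' @param scope Label describing the background set.
#' @return A `neutral_background` list: `background_N`, `background_S`,
#'   `expected_ratio`, `scope`.
#' @export
neutral_ns_expectation <- function(genes, genome, gene_ids = NULL,
                                   conserved_sites = NULL,
                                   scope = "all edited genes") {
  ad <- enumerate_cds_adenosines(genes, genome, gene_ids)
  if (!is.null(conserved_sites)) {
    ad <- ad[site_key(ad$chrom, ad$pos) %in% conserved_sites, , drop = FALSE]
  }
  n <- sum(ad$category == "N")
  s <- sum(ad$category == "S")
  if (s == 0 || n == 0) stop("degenerate background: N=", n, ", S=", s)
  structure(list(background_N = n, background_S = s,
                 expected_ratio = n / s, scope = scope),
            class = "neutral_background")
}

#' Construct a neutral background from known counts
#'
#' For published backgrounds (e.g. the expectation 3.80 over all edited genes)
#' where only the ratio or the counts are available.
#'
#' @param background_N,background_S Counts of N- and S-type background
#'   adenosines; alternatively give `expected_ratio` directly.
#' @param expected_ratio Optional precomputed ratio (counts then unused).
#' @param scope Label.
#' @return A `neutral_background` list.
#' @export
neutral_background <- function(background_N = NA_integer_,
                               background_S = NA_integer_,
                               expected_ratio = NULL, scope = "supplied") {
  if (is.null(expected_ratio)) {
    if (background_S == 0) stop("degenerate background")
    expected_ratio <- background_N / background_S
  }
  structure(list(background_N = background_N, background_S = background_S,
                 expected_ratio = expected_ratio, scope = scope),
            class = "neutral_background")
}

# Quantiles robust to +Inf replicates: infinite values are ordered above all
# finite ones; with any non-finite value present the inverse-CDF (type 1)
# definition is used so no interpolation with Inf occurs.
quantile_inf <- function(x, probs) {
  if (all(is.finite(x))) {
    stats::quantile(x, probs, names = FALSE)
  } else {
    stats::quantile(x, probs, names = FALSE, type = 1)
  }
}

#' The N/S selection test with adaptive fraction and bootstrap CIs
#'
#' Compares the observed counts of nonsynonymous (N) and synonymous (S)
#' editing sites against the neutral background via a two-sided Fisher exact
#' test on the 2x2 table \code{[[N, S], [background_N, background_S]]}, and
#' estimates the adaptive fraction
#' \deqn{\alpha = 1 - (N/S)_{expected} / (N/S)_{observed},}
#' the proportion of N sites in excess of the neutral expectation. Bootstrap
#' 95% intervals for the ratio and for alpha come from resampling the N+S
#' site labels with replacement `n_boot` times (implemented as binomial draws
#' of the N count, which is distributionally identical). Replicates with zero
#' resampled S sites yield a ratio of `+Inf`, ordered above all finite values
#' when taking quantiles.
#'
#' @param sites Either a data frame with a `category` column (rows with
#'   `"N"`/`"S"` are counted) or `NULL` when giving counts directly.
#' @param background A `neutral_background`.
#' @param N,S Direct counts (used when `sites` is NULL).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Optional integer seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @return A `selection_result` list: observed counts and ratio, expected
#'   ratio, `fisher_p`, `alpha`, `ratio_ci`, `alpha_ci`, `boot_ratio`
#'   (replicate ratios), and `degenerate` (TRUE when observed S = 0: the ratio
#'   is infinite, alpha is 1 and no CI is reported).
#' @examples
#' bg <- neutral_background(expected_ratio = 3.80)
#' res <- observed_ns_test(N = 678, S = 144, background = bg, seed = 1)
#' round(c(res$observed_ratio, res$alpha), 2)
#' @export
observed_ns_test <- function(sites = NULL, background, N = NULL, S = NULL,
                             n_boot = 1000, seed = NULL, conf = 0.95) {
  if (!is.null(sites)) {
    N <- sum(sites$category == "N")
    S <- sum(sites$category == "S")
  }
  stopifnot(is.numeric(N), is.numeric(S))
  exp_ratio <- background$expected_ratio
  if (S == 0) {
    return(structure(list(observed_N = N, observed_S = S,
                          observed_ratio = Inf, expected_ratio = exp_ratio,
                          fisher_p = NA_real_, alpha = 1,
                          ratio_ci = c(NA_real_, NA_real_),
                          alpha_ci = c(NA_real_, NA_real_),
                          boot_ratio = NULL, degenerate = TRUE),
                     class = "selection_result"))
  }
  obs_ratio <- N / S
  alpha <- 1 - exp_ratio / obs_ratio
  fisher_p <- if (is.finite(background$background_N) &&
                  is.finite(background$background_S)) {
    stats::fisher.test(matrix(c(N, S, background$background_N,
                                background$background_S),
                              nrow = 2, byrow = TRUE))$p.value
  } else NA_real_
  if (!is.null(seed)) set.seed(seed)
  n_sites <- N + S
  boot_N <- stats::rbinom(n_boot, n_sites, N / n_sites)
  boot_ratio <- ifelse(boot_N == n_sites, Inf, boot_N / (n_sites - boot_N))
  boot_alpha <- 1 - exp_ratio / boot_ratio
  lo <- (1 - conf) / 2
  list(observed_N = N, observed_S = S, observed_ratio = obs_ratio,
       expected_ratio = exp_ratio, fisher_p = fisher_p, alpha = alpha,
       ratio_ci = quantile_inf(boot_ratio, c(lo, 1 - lo)),
       alpha_ci = quantile_inf(boot_alpha, c(lo, 1 - lo)),
       boot_ratio = boot_ratio, degenerate = FALSE) |>
    structure(class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("N/S selection test\n")
  cat(sprintf("  observed: N = %d, S = %d, N/S = %.3g\n",
              x$observed_N, x$observed_S, x$observed_ratio))
  cat(sprintf("  expected (neutral): %.3g\n", x$expected_ratio))
  if (!is.na(x$fisher_p)) cat(sprintf("  Fisher P = %.3g\n", x$fisher_p))
  if (x$degenerate) {
    cat("  observed S = 0: ratio infinite, alpha = 1, no CI\n")
  } else {
    cat(sprintf("  alpha = %.3f [%.3f, %.3f]; ratio CI [%.3g, %.3g]\n",
                x$alpha, x$alpha_ci[1], x$alpha_ci[2],
                x$ratio_ci[1], x$ratio_ci[2]))
  }
  invisible(x)
}

#' Classify genes with positively selected editing (PSEB)
#'
#' A gene qualifies when its per-gene editing N/S ratio exceeds `ratio_min`
#' (default 5); genes with S = 0 and at least one N site have an unbounded
#' ratio and qualify. Callers should restrict `sites` to high-confidence
#' (Class I+II) CDS editing sites.
#'
#' @param sites Data frame with `gene_id` and `category` columns.
#' @param ratio_min Per-gene N/S threshold.
#' @return List with `genes` (per-gene `N`, `S`, `ratio`, `pseb`),
#'   `pseb_genes` (character vector), and pooled N/S counts for the PSEB and
#'   non-PSEB sets.
#' @export
classify_pseb <- function(sites, ratio_min = 5) {
  cds <- sites[sites$category %in% c("N", "S"), , drop = FALSE]
  if (!nrow(cds)) stop("no CDS editing sites to classify")
  tab <- table(factor(cds$gene_id), factor(cds$category, levels = c("N", "S")))
  genes <- data.frame(gene_id = rownames(tab), N = as.integer(tab[, "N"]),
                      S = as.integer(tab[, "S"]), stringsAsFactors = FALSE)
  genes <- genes[genes$N + genes$S > 0, , drop = FALSE]
  genes$ratio <- ifelse(genes$S == 0, Inf, genes$N / genes$S)
  genes$pseb <- genes$ratio > ratio_min
  pseb <- genes$gene_id[genes$pseb]
  pooled <- function(ids) {
    sub <- cds[cds$gene_id %in% ids, , drop = FALSE]
    c(N = sum(sub$category == "N"), S = sum(sub$category == "S"))
  }
  list(genes = genes, pseb_genes = pseb,
       pseb_counts = pooled(pseb),
       non_pseb_counts = pooled(setdiff(genes$gene_id, pseb)))
}

#' Stratified N/S selection tests
#'
#' Runs [observed_ns_test()] within strata (X vs autosome, expression groups,
#' PSEB vs non-PSEB, editing-level cutoffs, ...), each against its own (or a
#' shared) neutral background. Empty strata are dropped with a warning;
#' strata with S = 0 are returned flagged as degenerate.
#'
#' @param sites Data frame with `category` and a `stratum` column.
#' @param backgrounds Either one `neutral_background` shared by all strata or
#'   a named list keyed by stratum.
#' @param ... Passed to [observed_ns_test()] (e.g. `n_boot`, `seed`).
#' @return Named list of `selection_result` objects.
#' @export
stratified_ns <- function(sites, backgrounds, ...) {
  strata <- unique(sites$stratum)
  out <- list()
  for (s in strata) {
    sub <- sites[sites$stratum == s & sites$category %in% c("N", "S"), , drop = FALSE]
    if (!nrow(sub)) {
      warning("stratum '", s, "' has no N/S sites; omitted")
      next
    }
    bg <- if (inherits(backgrounds, "neutral_background")) backgrounds
          else backgrounds[[s]]
    out[[as.character(s)]] <- observed_ns_test(sub, bg, ...)
  }
  out
}

#' Compare fixed vs polymorphic N/S counts with background adjustment
#'
#' Fixed and polymorphic editing sites are judged against different neutral
#' backgrounds (fixed calls use the cross-species conserved-adenosine
#' background). Before the two site classes are compared to each other, the
#' polymorphic S count is rescaled by the ratio of the two neutral
#' expectations, so both classes sit on the fixed background's scale; the
#' test is then a two-sided Fisher exact test on the adjusted 2x2 table.
#' This rescaling is a stated convention, not an inference.
#'
#' @param fixed_N,fixed_S Counts among fixed editing sites.
#' @param poly_N,poly_S Counts among polymorphic editing sites.
#' @param fixed_expected,poly_expected The neutral N/S expectations of the
#'   two backgrounds (e.g. 4.18 and 3.80).
#' @return List with the adjusted polymorphic S count and `fisher_p`.
#' @export
fixed_vs_polymorphic_test <- function(fixed_N, fixed_S, poly_N, poly_S,
                                      fixed_expected, poly_expected) {
  adj_S <- round(poly_S * poly_expected / fixed_expected)
  p <- stats::fisher.test(matrix(c(fixed_N, fixed_S, poly_N, adj_S),
                                 nrow = 2, byrow = TRUE))$p.value
  list(adjusted_poly_S = adj_S, fisher_p = p)
}

#' Median split of edited genes by expression
#'
#' Ranks the genes carrying editing events by RPKM within a library and
#' labels the upper half "Highly" and the lower half "Lowly" expressed.
#'
#' @param rpkm Data frame with `gene_id` and `rpkm`.
#' @return `rpkm` with an `expression_group` column.
#' @export
split_by_expression <- function(rpkm) {
  r <- rank(rpkm$rpkm, ties.method = "first")
  rpkm$expression_group <- ifelse(r > stats::median(r), "Highly", "Lowly")
  rpkm
}
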