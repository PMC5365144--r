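#' Extract the 7-mer context around a site on the transcript strand
#'
#' Returns the `N-3 N-2 N-1 A N+1 N+2 N+3` window centered on a genomic
#' position, reverse-complemented for minus-strand genes so the context is
#' always 5'->3' on the edited strand. Sites within 3 nt of a sequence end
#' return NA.
#'
#' @param genome [Biostrings::DNAStringSet] named by chromosome.
#' @param chrom,pos,strand Vectors of site coordinates and strands.
#' @return Character vector of 7-mers (NA where unavailable).
#' @export
site_context_7mer <- function(genome, chrom, pos, strand) {
  n <- length(pos)
  out <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    seqlen <- length(genome[[chrom[i]]])
    if (pos[i] - 3 < 1 || pos[i] + 3 > seqlen) next
    s <- as.character(Biostrings::extractAt(
      genome[[chrom[i]]], IRanges::IRanges(pos[i] - 3, pos[i] + 3)))
    if (strand[i] == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    out[i] <- s
  }
  out
}

#' Build a position probability matrix from editing-site contexts
#'
#' Counts the bases at the six flanking positions (-3..-1, +1..+3; the central
#' adenosine carries no information and is excluded) of the supplied 7-mers
#' and converts counts to probabilities,
#' `(count + pseudocount) / (total + 4 * pseudocount)`. The default
#' pseudocount of 0 matches direct frequency estimation; scores of unseen
#' bases are then `-Inf`, and a pseudocount of 0.5 is advisable for small
#' site sets.
#'
#' @param kmers Character vector of 7-mers with a central A. Entries with NA
#'   or ambiguous bases are dropped with a warning.
#' @param pseudocount Added to every cell (default 0).
#' @param min_sites Minimum usable contexts required (default 10); fewer is
#'   an error since the frequencies are then too noisy to score with.
#' @return List of class `ppm` with `prob` and `counts` (4 x 6 matrices,
#'   rows A/C/G/T, columns -3..-1, +1..+3), `n_sites`, `pseudocount`.
#' @export
build_ppm <- function(kmers, pseudocount = 0, min_sites = 10) {
  kmers <- toupper(kmers)
  ok <- !is.na(kmers) & nchar(kmers) == 7 & grepl("^[ACGT]{7}$", kmers) &
    substr(kmers, 4, 4) == "A"
  if (any(!ok)) warning(sum(!ok), " context(s) dropped (NA, ambiguous or non-A center)")
  kmers <- kmers[ok]
  if (length(kmers) < min_sites) {
    stop("insufficient sites for a PPM (need >= ", min_sites, ")")
  }
  bases <- c("A", "C", "G", "T")
  cols <- c(-3, -2, -1, 1, 2, 3)
  counts <- sapply(c(1:3, 5:7), function(j) {
    table(factor(substr(kmers, j, j), levels = bases))
  })
  dimnames(counts) <- list(bases, as.character(cols))
  prob <- (counts + pseudocount) / (length(kmers) + 4 * pseudocount)
  stopifnot(abs(colSums(prob) - 1) < 1e-9)
  structure(list(prob = prob, counts = counts, n_sites = length(kmers),
                 pseudocount = pseudocount), class = "ppm")
}

#' Log-odds score of an A-centered 7-mer under a PPM
#'
#' \deqn{score = \sum_i \log_2 \frac{P_i(N_i)}{0.25}} over the six flanking
#' positions; 0 for a uniform matrix, `-Inf` when a base has probability 0
#' (pseudocount 0). Vectorised; the central base must be A.
#'
#' @param kmers Character vector of 7-mers.
#' @param ppm A [build_ppm()] object.
#' @return Numeric scores (NA for ambiguous/short inputs, skipped with a
#'   warning).
#' @export
score_7mer <- function(kmers, ppm) {
  kmers <- toupper(kmers)
  out <- rep(NA_real_, length(kmers))
  ok <- !is.na(kmers) & grepl("^[ACGT]{7}$", kmers)
  if (any(ok & substr(kmers, 4, 4) != "A")) stop("central base must be A")
  if (any(!ok)) warning(sum(!ok), " sequence(s) skipped (ambiguous base or wrong length)")
  idx <- which(ok)
  if (!length(idx)) return(out)
  pr <- ppm$prob
  sc <- numeric(length(idx))
  for (k in seq_along(c(1:3, 5:7))) {
    j <- c(1:3, 5:7)[k]
    b <- substr(kmers[idx], j, j)
    sc <- sc + log2(pr[cbind(b, rep(colnames(pr)[k], length(idx)))] / 0.25)
  }
  out[idx] <- sc
  out
}

#' Compare N/S among high-scoring sites to matched background contexts
#'
#' Scores the editing sites and every A-centered 7-mer in the background
#' (mRNAs of the edited genes), takes the score cutoff retaining the top
#' `quantile` of editing sites (empirical inverse-CDF quantile of the site
#' scores, so ties at the cutoff are included), and reports: the fraction of
#' background windows above the cutoff, and the observed vs
#' context-conditioned expected N/S with a two-sided Fisher test, both
#' computed over above-cutoff sites only. This asks whether the selection
#' signal survives conditioning on local sequence preference.
#'
#' @param site_scores Data frame: `score` and `category` for the editing
#'   sites.
#' @param background_scores Data frame: `score` and `category` (N/S for CDS
#'   adenosines; other categories ignored in the ratio) for background
#'   windows.
#' @param quantile Fraction of editing sites to retain (default 0.90).
#' @return List: `cutoff`, `n_sites_retained`, `background_fraction_above`,
#'   `observed` (N, S, ratio), `expected` (N, S, ratio), `fisher_p`.
#' @export
scan_background_and_ns <- function(site_scores, background_scores,
                                   quantile = 0.90) {
  if (!nrow(background_scores)) stop("empty background")
  cutoff <- stats::quantile(site_scores$score, probs = 1 - quantile,
                            names = FALSE, type = 1)
  keep_s <- site_scores$score >= cutoff
  keep_b <- background_scores$score >= cutoff
  obs <- c(N = sum(site_scores$category[keep_s] == "N"),
           S = sum(site_scores$category[keep_s] == "S"))
  exp <- c(N = sum(background_scores$category[keep_b] == "N", na.rm = TRUE),
           S = sum(background_scores$category[keep_b] == "S", na.rm = TRUE))
  fisher_p <- if (all(c(obs, exp) >= 0) && sum(obs) > 0 && sum(exp) > 0) {
    stats::fisher.test(matrix(c(obs, exp), nrow = 2, byrow = TRUE))$p.value
  } else NA_real_
  list(cutoff = cutoff, n_sites_retained = sum(keep_s),
       background_fraction_above = mean(keep_b),
       observed = c(obs, ratio = if (obs["S"] > 0) unname(obs["N"] / obs["S"]) else Inf),
       expected = c(exp, ratio = if (exp["S"] > 0) unname(exp["N"] / exp["S"]) else Inf),
       fisher_p = fisher_p)
}

#' All A-centered 7-mer windows of a transcript sequence
#'
#' Background generator for [scan_background_and_ns()]: every adenosine in
#' the given mRNA sequence with a full 3-nt flank on each side, each window
#' counted once.
#'
#' @param seq A single 5'->3' mRNA sequence (character).
#' @return Data frame `offset` (position of the A within `seq`) and `kmer`.
#' @export
transcript_a_windows <- function(seq) {
  seq <- toupper(seq)
  a_pos <- which(strsplit(seq, "")[[1]] == "A")
  a_pos <- a_pos[a_pos > 3 & a_pos <= nchar(seq) - 3]
  if (!length(a_pos)) {
    return(data.frame(offset = integer(0), kmer = character(0)))
  }
  data.frame(offset = a_pos,
             kmer = substring(seq, a_pos - 3, a_pos + 3),
             stringsAsFactors = FALSE)
}
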