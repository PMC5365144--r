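#' Scale a platform error rate to the A-to-G mismatch class
#'
#' Illumina platforms misread a base at a rate \eqn{\epsilon_0} (default 0.5%),
#' spread across the three possible wrong bases. Because only A-to-G mismatches
#' are retained as editing candidates (reads carrying other mismatch types are
#' discarded upstream), the per-read error rate relevant to an A site is
#' \deqn{\epsilon = \frac{\epsilon_0 / 3}{1 - (2/3)\,\epsilon_0}}
#' i.e. the chance of an A-to-G miscall conditional on the read surviving the
#' other-mismatch filter.
#'
#' @param eps0 Per-base platform error probability. Default 0.005.
#' @return The scaled A-to-G error probability (about 0.00167 at the default).
#' @examples
#' scaled_error_rate()          # ~0.00167
#' scaled_error_rate(0.002)
#' @export
scaled_error_rate <- function(eps0 = 0.005) {
  stopifnot(is.numeric(eps0), eps0 > 0, eps0 < 1)
  (eps0 / 3) / (1 - (2 / 3) * eps0)
}

#' Per-library probability that an A-to-G signal is sequencing error
#'
#' For a site covered by `C` reads of which `L` carry G, computes
#' \eqn{P_k(E_0) = P[X \ge L]} with \eqn{X \sim Binomial(C, \epsilon)}: the
#' probability of seeing at least the observed number of edited alleles from
#' sequencing error alone. `P_k(E1) = 1 - P_k(E0)` is the per-library editing
#' probability. Vectorised over `C` and `L`.
#'
#' A site with zero coverage carries no evidence and returns 1.
#'
#' @param C Integer vector of read coverages (non-negative).
#' @param L Integer vector of edited (G) allele counts, `0 <= L <= C`.
#' @param eps Per-read A-to-G error probability; see [scaled_error_rate()].
#' @param log.p Return the natural log of the tail probability.
#' @return Numeric vector of upper binomial tail probabilities.
#' @examples
#' per_library_error_prob(10, 0)    # 1: no edited reads, no evidence
#' per_library_error_prob(5, 1)     # ~0.0083
#' per_library_error_prob(100, 5)   # deep coverage, strong evidence
#' @export
per_library_error_prob <- function(C, L, eps = scaled_error_rate(), log.p = FALSE) {
  n <- max(length(C), length(L))
  C <- rep_len(as.numeric(C), n)
  L <- rep_len(as.numeric(L), n)
  if (any(C < 0) || any(L < 0)) stop("coverage and edited counts must be non-negative")
  if (any(L > C)) stop("edited count exceeds coverage (L > C)")
  out <- stats::pbinom(L - 1, C, eps, lower.tail = FALSE, log.p = log.p)
  # zero coverage: tail from zero successes is 1 regardless
  out[C == 0] <- if (log.p) 0 else 1
  out
}

#' Joint cross-library editing probability for one site
#'
#' Combines the per-library error tails across all libraries covering a site:
#' \eqn{P(E_0) = \prod_k P_k(E_0)}, the probability that every A-to-G signal at
#' the site is sequencing error, and \eqn{P(E_1) = 1 - P(E_0)}, the probability
#' the site is edited in at least one library. The product is accumulated in
#' log space so that many small per-library tails do not underflow.
#'
#' Libraries with zero coverage contribute a factor of 1 (no evidence). A site
#' with no covered library at all is not expressed and is flagged as such.
#'
#' @param C,L Coverage and edited-allele count per library (equal length).
#' @param eps Per-read A-to-G error probability.
#' @return A list with `P_E0`, `P_E1`, `log_P_E0`, `n_covered`, and
#'   `expressed` (FALSE when no library covers the site; probabilities are
#'   then `NA`).
#' @examples
#' joint_editing_prob(c(50, 40, 60), c(3, 0, 2))
#' @export
joint_editing_prob <- function(C, L, eps = scaled_error_rate()) {
  stopifnot(length(C) == length(L))
  covered <- C > 0
  if (!any(covered)) {
    return(list(P_E0 = NA_real_, P_E1 = NA_real_, log_P_E0 = NA_real_,
                n_covered = 0L, expressed = FALSE))
  }
  lp <- sum(per_library_error_prob(C[covered], L[covered], eps, log.p = TRUE))
  list(P_E0 = exp(lp), P_E1 = -expm1(lp), log_P_E0 = lp,
       n_covered = sum(covered), expressed = TRUE)
}

#' Probability of observing zero edited reads at a truly edited site
#'
#' When a site edited at level `l` shows no G allele in a library of depth `C`,
#' either the edited molecules were not sampled or every edited read was
#' miscalled back by sequencing error. The per-library probability is
#' \deqn{P_m(D_0) = \sum_{i=0}^{C} \binom{C}{i} l^i (1-l)^{C-i}
#'   \epsilon^i (1-\epsilon)^{C-i}}
#' which collapses, by the binomial theorem, to
#' \eqn{(l\epsilon + (1-l)(1-\epsilon))^C}; that closed form is evaluated in
#' log space. At \eqn{\epsilon = 0} this is simply \eqn{(1-l)^C}.
#'
#' Small values of the joint `P(D0)` across libraries support calling the site
#' confidently *not* edited (used for conservation loss and strain
#' polymorphism calls).
#'
#' @param C Depth per library (vectorised).
#' @param l Assumed true editing level, in `[0, 1]` (vectorised).
#' @param eps Per-read A-to-G error probability.
#' @param log.p Return the natural log.
#' @return Numeric vector of non-detection probabilities.
#' @examples
#' nondetection_prob(10, 0.5, eps = 0)    # 0.5^10
#' nondetection_prob(200, 0.05, eps = 0)  # (0.95)^200
#' @export
nondetection_prob <- function(C, l, eps = scaled_error_rate(), log.p = FALSE) {
  n <- max(length(C), length(l))
  C <- rep_len(as.numeric(C), n)
  l <- rep_len(as.numeric(l), n)
  if (any(l < 0) || any(l > 1)) stop("assumed editing level must be in [0, 1]")
  if (any(C < 0)) stop("coverage must be non-negative")
  lp <- C * log(l * eps + (1 - l) * (1 - eps))
  if (log.p) lp else exp(lp)
}

#' Joint non-detection probability across libraries
#'
#' Product of [nondetection_prob()] over the libraries (or strains) in which
#' zero edited reads were observed, accumulated in log space.
#'
#' @param C Depths of the non-detecting libraries.
#' @param l Assumed editing level (recycled across libraries).
#' @param eps Per-read A-to-G error probability.
#' @return A list with `P_D0` and `log_P_D0`.
#' @export
joint_nondetection_prob <- function(C, l, eps = scaled_error_rate()) {
  lp <- sum(nondetection_prob(C, l, eps, log.p = TRUE))
  list(P_D0 = exp(lp), log_P_D0 = lp)
}

#' Benjamini-Hochberg adjustment of joint error probabilities
#'
#' Thin, deterministic wrapper around [stats::p.adjust()] with
#' `method = "BH"`. Input order is preserved; callers that need reproducible
#' site ordering should sort candidates by genomic coordinate before
#' computing probabilities (the adjustment itself is order-invariant).
#'
#' @param p Vector of per-site `P(E0)` values (NA allowed; returned as NA).
#' @return Monotone step-up BH q-values, same length and order as `p`.
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
fdr_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  stats::p.adjust(p, method = "BH")
}
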