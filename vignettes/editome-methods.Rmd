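---
title: "Models and methods behind editome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind editome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical machinery: the
models, their assumptions, the defaults and why they are set where they are,
the numerical conventions, and what the synthetic-data tests do and do not
demonstrate about real data.

## The detection model

The unit of observation is a site–library pair: at a genomic adenosine
(transcript strand), a library contributes coverage $C_k$ and an edited
(A→G) read count $L_k$, with editing level $l_k = L_k/C_k$. The null is that
all $L_k$ G-reads are sequencing error. With a per-base platform error rate
$\varepsilon_0$ (default 0.005, the middle of the usual Illumina range) and
reads carrying non-A→G mismatches discarded upstream, the error rate for the
A→G class is

$$\varepsilon = \frac{\varepsilon_0/3}{1 - \tfrac{2}{3}\varepsilon_0}
  \approx 0.00167,$$

and the per-library null probability is the binomial tail
$P_k(E_0) = P[X \ge L_k]$, $X \sim \mathrm{Bin}(C_k, \varepsilon)$, computed
with `pbinom`'s survival form (never by naive summation, which loses
precision in deep libraries). Libraries are combined multiplicatively,
$P(E_0) = \prod_k P_k(E_0)$ — editing in *at least one* library is the
alternative — accumulated in log space so a hundred small tails cannot
underflow. Zero-coverage libraries carry no evidence and contribute a factor
of 1; sites covered nowhere are "not expressed" and excluded from multiple
testing. $P(E_0)$ values are BH-adjusted across all expressed candidates.

Assumptions worth keeping in mind: $\varepsilon$ is a single global scalar
(no per-base quality integration — the upstream mapping-quality and
mismatch-class filters are assumed to have been applied to the count table);
libraries are independent; and the candidate list is taken as given (the
package starts from counts, not BAMs).

### Confidence classes and the per-library filter

Sites are tiered into five exclusive classes, assigned in order:

| class | criteria (defaults) |
|---|---|
| I | q ≤ 0.001, $C_{max}$ ≥ 10, $C_{total}$ ≥ 40, detected in ≥ 2 libraries |
| II | remaining sites detected in ≥ 2 libraries with q ≤ 0.01, $C_{max}$ ≥ 5, $C_{total}$ ≥ 16 |
| III | remaining sites with joint $P(E_1) > 0.99$ |
| IV | detected in ≥ 1 library, $P(E_1) \le 0.99$ |
| V | covered, no detection |

"Detected in a library" means the per-library high-confidence filter passes:
level > 0.01, coverage ≥ 5, edited alleles ≥ 2 and $P_k(E_0) < 10^{-4}$. The
raw-signal alternative ($L_k > 0$) would let single error reads count as
detections; the filtered definition is what makes Classes I/II denote
reproducible editing. q-values are computed once over all expressed
candidates and thresholded at both FDR levels; recomputing BH on the Class-I
remainder would make Class II depend on the order of operations without
changing its meaning.

All thresholds sit in `detection_config()` and are plain numbers; the
defaults are the published criteria and there is no hidden coupling between
them.

## The selection test

For the genes carrying at least one editing event, every CDS adenosine is
classified by what an A→G change would do to the protein: nonsynonymous (N),
synonymous (S), `stop_retained` or `stop_lost` (stop-codon positions are
excluded from the N/S tallies and reported separately). The background
counts give the N/S ratio expected if editing hit CDS adenosines uniformly;
the test statistic is the observed ratio of N to S *editing* sites against
that expectation, via a two-sided Fisher exact test on the 2×2 count table.
Two-sided because depletion (purifying selection) is as interpretable as
excess. The adaptive fraction

$$\alpha = 1 - \frac{(N/S)_{expected}}{(N/S)_{observed}}$$

estimates the proportion of N sites in excess of neutrality. Bootstrap 95%
intervals for the ratio and α come from one resampling pass over the N+S
site labels; since a with-replacement resample of $n$ labels is a binomial
draw of the N count, the implementation uses `rbinom(n_boot, n, N/n)` —
distributionally identical and much faster (verified against explicit label
resampling in the tests). Replicates with zero resampled S sites have ratio
$+\infty$; infinite values are ordered above all finite ones, and quantiles
switch to the inverse-CDF (type 1) definition whenever any replicate is
non-finite so no interpolation with infinity occurs.

PSEB genes ("positively selected editing in brains") are genes whose own
editing N/S exceeds 5; a gene with N ≥ 1 and S = 0 has an unbounded ratio
and qualifies. Stratified tests (X vs autosome, Highly/Lowly expressed by
median split of RPKM-ranked edited genes, level-cutoff grids) reuse the same
machinery with per-stratum backgrounds.

## Detection-bias simulations

Because S sites are edited at lower levels than N sites, finite depth
censors them more often, inflating observed N/S. Two resampling schemes
quantify this. Per-site: each site's edited count is redrawn as
$\mathrm{Bin}(C_j, L_j/C_j)$ — exactly resampling its $C_j$ reads with
replacement, without storing reads — and the site is kept when the simulated
level clears $l_{min}$; grids over $C_{min}$ (5–20) and $l_{min}$
(0.01/0.02/0.05) show how the inflation shrinks with depth. Pooled: all
libraries are merged and each site downsampled to $\mathrm{round}(fC)$ reads
($f$ from 0.05 to 1; round-half-even, so tables are bit-reproducible).
Replicate ratios with no surviving S site are kept as $+\infty$ in the
quantiles. Note the observed-level pre-filter means even $f = 1$ retains a
small upward residual — resampled levels can cross the cutoff — which is
part of the bias being measured, not an artifact.

## Confident absence, conservation, populations

A truly edited site can show zero edited reads through sampling and
back-error. The per-library probability is

$$P_m(D_0) = \sum_{i=0}^{C}\binom{C}{i} l^i (1-l)^{C-i}
  \varepsilon^i (1-\varepsilon)^{C-i}
  = \big(l\varepsilon + (1-l)(1-\varepsilon)\big)^C,$$

evaluated through the closed form in log space (the tests verify the literal
series up to $C = 30$ and the $\varepsilon = 0$ reduction $(1-l)^C$ up to
$C = 1000$). This formula couples the sampling and error terms inside one
sum and ignores error-generated G reads on unedited molecules; it is
implemented as stated rather than "fixed", because its outputs are compared
against published behaviour and the discrepancy is negligible at realistic
$\varepsilon$.

Cross-species conservation calls assume the orthologous site is edited at
the focal species' level, require ≥ 200 raw reads in each non-focal species
and focal level ≥ 0.05, and classify each species as present (joint
detection at FDR 0.05), absent (joint $P(D_0)$ below a fixed $2\times10^{-4}$
cutoff or BH FDR 0.05 — both available; the fixed cutoff is the default for
this analysis), or undetermined. Parsimony over the ((focal, sibling),
outgroup) tree maps the triple to conserved / absent-in-outgroup /
focal-specific; ambiguous single-presence patterns stay "undetermined"
rather than being forced into a gain or loss.

Strain-panel polymorphism calls require reliable presence in ≥ 1 strain
($P_k(E_1) > 0.999$), zero edited reads in ≥ 1 covered strain, exclusion of
sites edited in the outgroup species, and a significant joint $P(D_0)$ over
the zero strains — BH FDR 0.05 over candidates by default, since no explicit
strain-level cutoff is standard. The assumed level is the mean over detected
strains (Level I) or that mean capped at 0.05 (Level II, conservative when a
site is strongly edited where present). Fixed calls require
$P_k(E_1) > 0.95$ in *every* strain plus same-sex detection in the outgroup.

The SNP association test correlates per-strain editing levels with 0/1
genotypes within ±10 kb, separately per sex, and reports a pair only when
the direction agrees and $p < 0.05$ in both sexes. With five strains an
exact permutation null is very coarse (ten distinct orderings of a 2/3
genotype split, so the smallest achievable p is 0.1); the default is
therefore the Pearson correlation t-test, with the exact permutation
p-value available via `method = "permutation"` for users who prefer coarse
but assumption-free inference.

## Sequence context

The ±3 nt context model is a position probability matrix over the six
flanking positions (the central A is constant and excluded), with log-odds
scoring $\sum_i \log_2 P_i(N_i)/0.25$. The pseudocount defaults to 0 —
direct frequencies, with $-\infty$ scores allowed for unseen bases — and
+0.5 is offered for small site sets. The score cutoff retaining the top 90%
of editing sites uses the empirical inverse-CDF (type 1) quantile, so ties
at the cutoff are included and the retained count is at least
$\lceil 0.9 n \rceil$. Flanks are always read 5'→3' on the transcript
strand. Background scans count every A-centered 7-mer of the edited genes'
mRNAs once, without deduplicating identical windows.

## Association analyses

All binning is equal-sized by rank with first-occurrence tie-breaking, so a
table sorted by genomic coordinate always bins identically. Editing density
is edited / total adenosines per bin (a level-weighted variant divides the
sum of levels instead; both raw and per-million scalings are emitted).
Trends are Spearman correlations over 20 bins, with a tie flag when more
than 20% of densities coincide. The half-gene and phyloP-matched contrasts
are paired t-tests across bins — pairing within expression or coverage bins
is what removes the depth confounder. Empirical permutation p-values use
$(r+1)/(n+1)$ smoothing so they are never exactly zero. Library clustering
uses $1 - r$ (Pearson) distance with average linkage — unspecified upstream,
chosen as the least-assuming standard pair — and emits newick through `ape`.

## The synthetic-data generator

The generator emulates the statistical structure the pipeline assumes: genes
with UTR/CDS/intron structure on both strands (random codons, no internal
stops; internal stops arising during sampling are resampled to ATA/ATG in a
1:2 ratio, which restores exactly the base counts the stops carried, keeping
composition uniform); editing sites placed on transcript-strand adenosines
with category-specific rates; an adaptive excess planted directly as
$\text{rate}_N = \text{rate}_S/(1-\alpha)$ so the planted α is recoverable;
true levels Beta(2,4) for N vs Beta(1.2,6) for S (means 0.33 vs 0.17,
matching the direction and rough magnitude of real category differences);
negative-binomial coverage (mean 7, size 2 — median per-site coverage lands
in the 5–9 read range); and per-read error applied in both directions,
$P(\text{G read}) = l(1-\varepsilon) + (1-l)\varepsilon$, which is richer
than the detection model's one-sided error and deliberately stress-tests it.
Strain panels plant polymorphic sites (level 0.2 in 2 of 5 strains) and
fixed sites (edited everywhere plus the outgroup), with linked SNPs whose
alternative allele tracks the edited strains.

What the generator does **not** emulate: mapping and PCR-duplicate
artifacts, per-base quality variation, non-uniform coverage along
transcripts (unless the position-gradient knob is turned on), isoform
complexity beyond one canonical transcript, linkage between SNPs, and codon
usage of any real genome (its neutral N/S expectation is ~2.6 rather than a
fly-like 3.8). Passing calibration tests therefore demonstrates internal
statistical correctness — FDR control, power, unbiased α recovery at the
planted conditions — not robustness to alignment artifacts, which must be
handled upstream of the count tables.

## Calibration problem sizes

The acceptance-level calibration tests run at deliberately modest sizes,
chosen to give stable Monte-Carlo behaviour: null FDR over 100 replicate
count tables (~300 candidate sites × 8 libraries each); Class I+II recovery
on one editome at coverage 30 and levels near 0.3; α recovery as the mean
over 10 editomes of ~1000 categorised sites (the single-editome sampling
s.d. of α at 1000 sites is ≈ 0.06, so the mean over 10 is the right scale
for a ±0.05 check); and polymorphic/fixed recovery over 20 five-strain
panels at panel coverage ~50 with level-0.2 plants and moderate coverage
overdispersion (NB size 10 — deep panels are tight-dispersion by design).

## Numerical conventions

* Coordinates are 1-based closed everywhere, the R/Bioconductor convention;
  GFF3, VCF and the tab-separated count tables are already 1-based, so no
  conversion layer exists to get wrong.
* All probability products are accumulated as sums of `log.p = TRUE` tails;
  `P(E1)` is computed as `-expm1(log P(E0))`.
* SNP masking is applied when counts are loaded, before any probability is
  computed.
* Quantiles over bootstrap/simulation replicates use type 7 when all values
  are finite and type 1 otherwise; $+\infty$ sorts above all finite values.
* Fractional depths use `round()` (round-half-even).
* Every stochastic routine takes an explicit seed (or a seeded config);
  identical seed + config reproduce outputs bit for bit.

## Known limitations

* The error model is a single global $\varepsilon$; base-quality-aware
  models and DNA-genotype likelihoods are out of scope.
* Annotation uses the canonical transcript only; positions intronic in the
  canonical isoform but exonic in others are reported as intronic.
* When a position falls in several genes, CDS wins over UTR over intron;
  multi-gene overlap resolution beyond that precedence is a convention, not
  an inference.
* The fixed-vs-polymorphic background adjustment rescales one margin of the
  2×2 table by the ratio of the two neutral expectations before the Fisher
  test; this is a stated convention where no standard operationalisation
  exists.
* RNA folding, orthology-map construction, dN/dS computation and expression
  estimation are consumed as inputs (BED intervals, mapping tables, RPKM
  tables), never recomputed.
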