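# Independent oracles: literal summations, exhaustive enumerations and
# whole-sequence translations, kept deliberately separate from the package's
# own computational routes.

# Upper binomial tail by literal summation of the defining series.
tail_oracle <- function(C, L, eps) {
  if (L > C) stop("L > C")
  if (C == 0) return(1)
  i <- L:C
  sum(choose(C, i) * eps^i * (1 - eps)^(C - i))
}

# Non-detection probability by literal summation of the printed series.
pd0_oracle <- function(C, l, eps) {
  i <- 0:C
  sum(choose(C, i) * l^i * (1 - l)^(C - i) * eps^i * (1 - eps)^(C - i))
}

# Two-sided Fisher p by exhaustive hypergeometric enumeration over the
# support with fixed margins (a b / c d rows).
fisher_oracle <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  lo <- max(0, k - n)
  hi <- min(k, m)
  x <- lo:hi
  probs <- dhyper(x, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Effect of each A->G change in a CDS by mutating the full sequence and
# translating whole proteins (route independent of per-codon lookup).
cds_effect_oracle <- function(cds_seq) {
  bases <- strsplit(cds_seq, "")[[1]]
  ref_prot <- strsplit(as.character(
    Biostrings::translate(Biostrings::DNAString(cds_seq))), "")[[1]]
  a_idx <- which(bases == "A")
  vapply(a_idx, function(i) {
    mut <- bases
    mut[i] <- "G"
    alt_prot <- strsplit(as.character(suppressWarnings(
      Biostrings::translate(Biostrings::DNAString(paste(mut, collapse = ""))))),
      "")[[1]]
    codon <- (i - 1) %/% 3 + 1
    ra <- ref_prot[codon]
    aa <- alt_prot[codon]
    if (ra == "*") {
      if (aa == "*") "stop_retained" else "stop_lost"
    } else if (ra == aa) "S" else "N"
  }, "")
}

# A tiny single-gene fixture: one plus-strand gene with UTRs and an
# intron-free CDS, genome built from the given transcript pieces.
toy_gene <- function(cds = "ATGAAATGA", utr5 = "CCCCC", utr3 = "GGGGG",
                     strand = "+", gene_id = "g1", chrom = "chrT") {
  pre <- paste0(utr5, cds, utr3)
  gseq <- if (strand == "+") pre else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(pre)))
  L <- nchar(pre)
  map <- function(a, b) if (strand == "+") c(a, b) else c(L - b + 1, L - a + 1)
  u5 <- nchar(utr5); cl <- nchar(cds)
  rows <- rbind(
    data.frame(feature = "five_prime_UTR", t(map(1, u5))),
    data.frame(feature = "CDS", t(map(u5 + 1, u5 + cl))),
    data.frame(feature = "three_prime_UTR", t(map(u5 + cl + 1, L))),
    data.frame(feature = "exon", t(map(1, L))))
  names(rows) <- c("feature", "start", "end")
  genes <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                      feature = rows$feature, start = rows$start,
                      end = rows$end, stringsAsFactors = FALSE)
  genome <- Biostrings::DNAStringSet(gseq)
  names(genome) <- chrom
  list(genes = genes, genome = genome, cds_genomic = map(u5 + 1, u5 + cl))
}

# Random valid CDS for fixtures: ATG + non-stop codons + one stop.
random_cds_for_test <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  codons <- character(n_codons - 2)
  for (i in seq_along(codons)) {
    repeat {
      cd <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE), collapse = "")
      if (!cd %in% stops) break
    }
    codons[i] <- cd
  }
  paste0("ATG", paste(codons, collapse = ""), sample(stops, 1))
}

# Small deterministic synthetic dataset shared by several test files.
small_synthetic <- function(seed = 11, n_genes = 15, ...) {
  cfg <- generator_config(n_genes = n_genes, seed = seed, ...)
  ref <- generate_reference(cfg)
  truth <- generate_editome(ref, cfg)
  list(cfg = cfg, ref = ref, truth = truth)
}
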