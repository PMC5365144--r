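#' Configuration of the synthetic editome generator
#'
#' Defaults emulate the study conditions the rest of the package assumes:
#' eight brain libraries (two sexes by four rearing conditions), per-site
#' coverage that is negative-binomial with a median in the 5-9 read range,
#' beta-distributed true editing levels with nonsynonymous sites drawn from a
#' higher-mean distribution than synonymous ones, an adaptive excess of N
#' sites parameterised directly by the planted adaptive fraction
#' (`rate_N = rate_S / (1 - adaptive_fraction)`), cross-species sharing
#' around 45%/20% for the sibling/outgroup species, and per-read A-to-G
#' error.
#'
#' @param n_genes Number of genes.
#' @param cds_codon_range Uniform range of CDS length in codons.
#' @param utr5_range,utr3_range,intron_range,intergenic_range Uniform length
#'   ranges (nt) of the other gene parts.
#' @param intron_prob Probability a gene carries one intron (inside its CDS).
#' @param editing_rate Per-adenosine editing probability for S-category
#'   (baseline) sites.
#' @param adaptive_fraction Planted adaptive fraction of N sites; sets the
#'   N-site rate to `editing_rate / (1 - adaptive_fraction)`.
#' @param noncoding_rate_factor UTR/intron site rate relative to baseline.
#' @param pseb_fraction Fraction of coding genes with concentrated adaptive
#'   editing; their N rate is multiplied by `pseb_n_factor` and S rate by
#'   `pseb_s_factor`.
#' @param pseb_n_factor,pseb_s_factor PSEB rate multipliers.
#' @param beta_position Log-linear effect of relative transcript position on
#'   the editing rate (positive = 3' enrichment; default 0).
#' @param beta_phylop Log-linear effect of the latent conservation score on
#'   the editing rate (default 0).
#' @param level_shape_N,level_shape_S,level_shape_noncoding Beta shape pairs
#'   of true editing levels per category.
#' @param coverage_mean,coverage_dispersion Negative-binomial mean and size
#'   of per-site per-library coverage.
#' @param eps_true Per-read A-to-G sequencing error in the generator (applied
#'   in both directions: unedited molecules misread as G, edited molecules
#'   misread back).
#' @param n_libraries Number of libraries (metadata mirrors two sexes across
#'   four temperature conditions when 8).
#' @param temp_effect_silent,temp_effect_N Editing-level change applied under
#'   the 48-h heat condition (half under 14 h) for silent and N sites.
#' @param p_share_sibling,p_share_outgroup Per-site probability that editing
#'   is shared with the sibling/outgroup species (outgroup presence nested
#'   within sibling presence).
#' @param snp_rate Per-base SNP rate for the masked-polymorphism track.
#' @param background_multiplier Unedited candidate adenosines included in
#'   count tables, as a multiple of the edited-site count.
#' @param panel_coverage_mean Coverage mean for the strain panel.
#' @param poly_level,poly_n_strains Planted polymorphic sites are edited at
#'   this level in this many of the 5 strains (0 elsewhere).
#' @param qtl_fraction Fraction of polymorphic sites given a linked SNP
#'   (within 10 kb) whose alternative allele tracks editing presence.
#' @param seed Master seed; all stages derive their streams from it.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_genes = 60,
                             cds_codon_range = c(100, 500),
                             utr5_range = c(50, 200),
                             utr3_range = c(100, 300),
                             intron_prob = 0.6,
                             intron_range = c(60, 300),
                             intergenic_range = c(200, 800),
                             editing_rate = 0.01,
                             adaptive_fraction = 0.2,
                             noncoding_rate_factor = 1,
                             pseb_fraction = 0.2,
                             pseb_n_factor = 5,
                             pseb_s_factor = 0.2,
                             beta_position = 0,
                             beta_phylop = 0,
                             level_shape_N = c(2, 4),
                             level_shape_S = c(1.2, 6),
                             level_shape_noncoding = c(1.5, 5),
                             coverage_mean = 7,
                             coverage_dispersion = 2,
                             eps_true = scaled_error_rate(),
                             n_libraries = 8,
                             temp_effect_silent = -0.05,
                             temp_effect_N = -0.01,
                             p_share_sibling = 0.45,
                             p_share_outgroup = 0.20,
                             snp_rate = 0.002,
                             background_multiplier = 2,
                             panel_coverage_mean = 50,
                             poly_level = 0.2,
                             poly_n_strains = 2,
                             qtl_fraction = 0.5,
                             seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$editing_rate >= 0, cfg$editing_rate <= 1,
            cfg$adaptive_fraction >= 0, cfg$adaptive_fraction < 1,
            cfg$p_share_sibling >= 0, cfg$p_share_sibling <= 1,
            cfg$p_share_outgroup >= 0, cfg$p_share_outgroup <= 1)
  structure(cfg, class = "generator_config")
}

# iid-uniform random DNA of length n.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# CDS of n_codons: ATG start, iid-uniform internal bases, one terminal stop.
# Internal stop codons are replaced by ATA (1/3) or ATG (2/3): that mixture
# returns exactly the T/A/G counts the removed stops carried, so the base
# composition of the CDS stays uniform.
random_cds <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  internal <- n_codons - 2L
  codons <- vapply(seq_len(internal), function(i) random_dna(3), "")
  is_stop <- codons %in% stops
  if (any(is_stop)) {
    codons[is_stop] <- sample(c("ATA", "ATG"), sum(is_stop), replace = TRUE,
                              prob = c(1, 2) / 3)
  }
  paste0("ATG", paste(codons, collapse = ""), sample(stops, 1))
}

#' Generate a synthetic reference genome and gene models
#'
#' Builds `n_genes` genes laid head-to-tail on one chromosome with random
#' intergenic spacers: each gene has a 5' UTR, a CDS (random codons, no
#' internal stop, ATG start, one stop), optionally one intron at a codon
#' boundary, and a 3' UTR; strands are assigned ~50/50 and minus-strand genes
#' are reverse-complemented into the genome. Fully deterministic under the
#' config seed.
#'
#' @param config A [generator_config()].
#' @return List with `genome` ([Biostrings::DNAStringSet]) and `genes`
#'   (gene-model data frame).
#' @export
generate_reference <- function(config = generator_config()) {
  set.seed(config$seed)
  runif_len <- function(rg) sample(rg[1]:rg[2], 1)
  chrom <- "chrS"
  seqs <- character(0)
  feats <- list()
  cursor <- 1L
  for (g in seq_len(config$n_genes)) {
    gid <- sprintf("gene%03d", g)
    strand <- sample(c("+", "-"), 1)
    u5 <- runif_len(config$utr5_range)
    u3 <- runif_len(config$utr3_range)
    n_codons <- runif_len(config$cds_codon_range)
    cds <- random_cds(n_codons)
    clen <- nchar(cds)
    has_intron <- stats::runif(1) < config$intron_prob
    ilen <- if (has_intron) runif_len(config$intron_range) else 0L
    # intron at a codon boundary strictly inside the CDS
    cut <- if (has_intron) 3L * sample(seq_len(n_codons - 1L), 1) else clen
    pre <- paste0(random_dna(u5),
                  substr(cds, 1, cut),
                  if (has_intron) random_dna(ilen) else "",
                  substr(cds, cut + 1, clen),
                  random_dna(u3))
    L <- nchar(pre)
    gseq <- if (strand == "+") pre else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(pre)))
    # transcript-coordinate intervals [a, b] -> genomic
    g0 <- cursor
    map <- function(a, b) {
      if (strand == "+") c(g0 + a - 1L, g0 + b - 1L) else c(g0 + L - b, g0 + L - a)
    }
    iv <- list(five_prime_UTR = c(1L, u5),
               CDS1 = c(u5 + 1L, u5 + cut),
               three_prime_UTR = c(u5 + cut + ilen + (clen - cut) + 1L, L))
    if (has_intron) {
      iv$CDS2 <- c(u5 + cut + ilen + 1L, u5 + cut + ilen + (clen - cut))
      iv$exon1 <- c(1L, u5 + cut)
      iv$exon2 <- c(u5 + cut + ilen + 1L, L)
    } else {
      iv$exon1 <- c(1L, L)
    }
    for (nm in names(iv)) {
      gc <- map(iv[[nm]][1], iv[[nm]][2])
      feats[[length(feats) + 1L]] <- data.frame(
        gene_id = gid, chrom = chrom, strand = strand,
        feature = sub("[0-9]+$", "", nm), start = gc[1], end = gc[2],
        stringsAsFactors = FALSE)
    }
    seqs <- c(seqs, gseq, random_dna(runif_len(config$intergenic_range)))
    cursor <- cursor + L + nchar(seqs[length(seqs)])
  }
  genome <- Biostrings::DNAStringSet(paste(seqs, collapse = ""))
  names(genome) <- chrom
  genes <- do.call(rbind, feats)
  genes <- genes[order(genes$gene_id, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  validate_gene_models(genes)
  list(genome = genome, genes = genes)
}

#' Plant a ground-truth editome on a synthetic reference
#'
#' Enumerates every transcript-strand adenosine, assigns per-site editing
#' probabilities by category (with the planted adaptive excess of N sites,
#' optional PSEB genes, and optional position/conservation covariate
#' effects), draws the edited sites and their true beta-distributed levels,
#' the cross-species presence pattern, latent per-gene expression and
#' divergence covariates, and a SNP track to be masked.
#'
#' @param reference Output of [generate_reference()].
#' @param config A [generator_config()].
#' @return List of class `synthetic_truth`: `sites` (every adenosine with
#'   `edited`, `true_level`, presence flags, covariates), `genes` (latent
#'   `rpkm`, `dn`, `pseb`), `snps`, and the neutral `background` counts of
#'   the reference.
#' @export
generate_editome <- function(reference, config = generator_config()) {
  set.seed(config$seed + 1L)
  ad <- enumerate_gene_adenosines(reference$genes, reference$genome)
  spans <- gene_spans(reference$genes)
  coding <- spans$gene_id[spans$coding]
  genes <- data.frame(gene_id = spans$gene_id,
                      rpkm = stats::rlnorm(nrow(spans), meanlog = 2, sdlog = 1),
                      dn = stats::rlnorm(nrow(spans), meanlog = -4.2, sdlog = 0.6),
                      stringsAsFactors = FALSE)
  genes$pseb <- genes$gene_id %in%
    sample(coding, round(config$pseb_fraction * length(coding)))
  ad$phylop <- stats::rnorm(nrow(ad))
  sp <- spans[match(ad$gene_id, spans$gene_id), ]
  relpos <- (ad$pos - sp$start) / pmax(1, sp$end - sp$start)
  ad$relpos <- ifelse(ad$strand == "+", relpos, 1 - relpos)
  rate_S <- config$editing_rate
  rate_N <- rate_S / (1 - config$adaptive_fraction)
  rate <- rep(rate_S * config$noncoding_rate_factor, nrow(ad))
  rate[ad$category == "N"] <- rate_N
  rate[ad$category == "S"] <- rate_S
  rate[ad$category %in% c("stop_retained", "stop_lost")] <- 0
  is_pseb <- genes$pseb[match(ad$gene_id, genes$gene_id)]
  rate[is_pseb & ad$category == "N"] <- rate_N * config$pseb_n_factor
  rate[is_pseb & ad$category == "S"] <- rate_S * config$pseb_s_factor
  rate <- pmin(1, rate * exp(config$beta_position * (ad$relpos - 0.5) +
                               config$beta_phylop * ad$phylop))
  ad$edited <- stats::rbinom(nrow(ad), 1, rate) == 1
  shp <- function(cat) switch(cat, N = config$level_shape_N,
                              S = config$level_shape_S,
                              config$level_shape_noncoding)
  ad$true_level <- 0
  for (cat in unique(ad$category[ad$edited])) {
    idx <- which(ad$edited & ad$category == cat)
    s <- shp(cat)
    ad$true_level[idx] <- stats::rbeta(length(idx), s[1], s[2])
  }
  ad$present_sibling <- FALSE
  ad$present_outgroup <- FALSE
  ed <- which(ad$edited)
  ad$present_sibling[ed] <- stats::rbinom(length(ed), 1, config$p_share_sibling) == 1
  p_out_given_sib <- if (config$p_share_sibling > 0) {
    min(1, config$p_share_outgroup / config$p_share_sibling)
  } else 0
  sib <- which(ad$edited & ad$present_sibling)
  ad$present_outgroup[sib] <- stats::rbinom(length(sib), 1, p_out_given_sib) == 1
  ad$site_id <- site_key(ad$chrom, ad$pos)
  # SNPs anywhere in the genome except edited positions
  glen <- length(reference$genome[[1]])
  n_snp <- stats::rbinom(1, glen, config$snp_rate)
  snp_pos <- sample(setdiff(seq_len(glen), ad$pos[ad$edited]), n_snp)
  snps <- data.frame(chrom = names(reference$genome)[1], pos = sort(snp_pos),
                     stringsAsFactors = FALSE)
  bg <- table(factor(ad$category, levels = c("N", "S")))
  structure(list(sites = ad, genes = genes, snps = snps,
                 background = c(N = unname(bg["N"]), S = unname(bg["S"]))),
            class = "synthetic_truth")
}

# Library metadata mirroring the brain design: two sexes x four conditions.
default_library_meta <- function(n_libraries, species = "focal") {
  temps <- rep(c("25C", "25C", "30C_14h", "30C_48h"), length.out = ceiling(n_libraries / 2))
  ids <- sprintf("L%02d", seq_len(n_libraries))
  library_meta(ids, species = species,
               sex = rep(c("F", "M"), each = ceiling(n_libraries / 2))[seq_len(n_libraries)],
               temperature = rep(temps, 2)[seq_len(n_libraries)])
}

#' Simulate per-library allele-count tables from a planted truth
#'
#' For each candidate site (every edited site plus a background sample of
#' unedited adenosines) and each library, draws coverage from a negative
#' binomial and the edited-read count from
#' `Binomial(C, l(1-eps) + (1-l)eps)` — edited molecules can be misread back
#' and unedited molecules misread as G, so unedited sites carry error-only
#' reads. Heat-condition libraries have their true levels shifted by the
#' configured temperature effects (silent sites more than N sites). A
#' matched editing-null library pair (wild-type vs mutant with all levels 0)
#' can be appended for false-positive-rate estimation.
#'
#' @param truth A [generate_editome()] result.
#' @param config A [generator_config()].
#' @param meta Optional [library_meta()]; defaults to the 8-library brain
#'   design.
#' @param include_null_pair Append `wt`/`mutant` libraries.
#' @return List: `observations` (long count table), `meta`, `candidates`
#'   (site ids included), and `truth_link` (candidate rows of the truth).
#' @export
simulate_counts <- function(truth, config = generator_config(), meta = NULL,
                            include_null_pair = FALSE) {
  set.seed(config$seed + 2L)
  if (is.null(meta)) meta <- default_library_meta(config$n_libraries)
  sites <- truth$sites
  ed <- which(sites$edited)
  n_bg <- min(length(which(!sites$edited)),
              round(config$background_multiplier * length(ed)))
  bg <- sample(which(!sites$edited), n_bg)
  cand <- sites[sort(c(ed, bg)), , drop = FALSE]
  temp_shift <- function(temperature, category) {
    eff <- ifelse(category == "N", config$temp_effect_N, config$temp_effect_silent)
    switch(temperature, "30C_48h" = eff, "30C_14h" = eff / 2, 0 * eff)
  }
  rows <- lapply(seq_len(nrow(meta)), function(k) {
    lev <- pmin(1, pmax(0, cand$true_level +
                          ifelse(cand$edited,
                                 temp_shift(meta$temperature[k], cand$category), 0)))
    C <- stats::rnbinom(nrow(cand), mu = config$coverage_mean,
                        size = config$coverage_dispersion)
    p <- lev * (1 - config$eps_true) + (1 - lev) * config$eps_true
    data.frame(chrom = cand$chrom, pos = cand$pos,
               library_id = meta$library_id[k],
               coverage = C, edited_count = stats::rbinom(nrow(cand), C, p),
               stringsAsFactors = FALSE)
  })
  if (include_null_pair) {
    for (lab in c("wt", "mutant")) {
      lev <- if (lab == "wt") cand$true_level else 0
      C <- stats::rnbinom(nrow(cand), mu = config$coverage_mean,
                          size = config$coverage_dispersion)
      p <- lev * (1 - config$eps_true) + (1 - lev) * config$eps_true
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = cand$chrom, pos = cand$pos, library_id = lab,
        coverage = C, edited_count = stats::rbinom(nrow(cand), C, p),
        stringsAsFactors = FALSE)
      meta <- rbind(meta, library_meta(lab, species = "focal", sex = "mixed"))
    }
  }
  obs <- do.call(rbind, rows)
  list(observations = obs, meta = meta,
       candidates = site_key(cand$chrom, cand$pos), truth_link = cand)
}

#' Simulate a five-strain population panel with planted polymorphisms
#'
#' Splits the truth's edited sites into *fixed* sites (those shared with the
#' sibling species: edited at their true level in every strain and in the
#' outgroup) and *polymorphic* candidates (focal-specific sites: edited at
#' `poly_level` in `poly_n_strains` of the five strains, zero elsewhere).
#' Counts are simulated per strain and sex at panel coverage. A fraction of
#' polymorphic sites receives a linked SNP within 10 kb whose alternative
#' allele marks the edited strains in both sexes; unlinked noise SNPs are
#' added for the remainder.
#'
#' @param truth A [generate_editome()] result.
#' @param config A [generator_config()].
#' @return List: `observations` (`site_id`, `chrom`, `pos`, `sex`, `strain`,
#'   `coverage`, `edited_count`), `genotypes` (long 0/1 per strain),
#'   `outgroup_detected` (site ids edited in the outgroup, per sex),
#'   `truth_labels` (per-site planted status and edited strains).
#' @export
generate_population_panel <- function(truth, config = generator_config()) {
  set.seed(config$seed + 3L)
  strains <- c("B12", "I17", "N10", "T07", "ZW155")
  sx <- c("F", "M")
  sites <- truth$sites[truth$sites$edited, , drop = FALSE]
  fixed <- sites[sites$present_sibling, , drop = FALSE]
  poly <- sites[!sites$present_sibling & !sites$present_outgroup, , drop = FALSE]
  lab <- rbind(
    if (nrow(fixed)) data.frame(site_id = fixed$site_id, status = "fixed",
                                stringsAsFactors = FALSE),
    if (nrow(poly)) data.frame(site_id = poly$site_id, status = "polymorphic",
                               stringsAsFactors = FALSE))
  edited_strains <- lapply(seq_len(nrow(poly)), function(i) {
    sample(strains, config$poly_n_strains)
  })
  sim_counts <- function(site, level_by_strain) {
    do.call(rbind, lapply(sx, function(s) {
      C <- stats::rnbinom(length(strains), mu = config$panel_coverage_mean,
                          size = config$coverage_dispersion)
      p <- level_by_strain * (1 - config$eps_true) +
        (1 - level_by_strain) * config$eps_true
      data.frame(site_id = site$site_id, chrom = site$chrom, pos = site$pos,
                 sex = s, strain = strains, coverage = C,
                 edited_count = stats::rbinom(length(strains), C, p),
                 stringsAsFactors = FALSE)
    }))
  }
  obs <- list()
  for (i in seq_len(nrow(fixed))) {
    obs[[length(obs) + 1L]] <- sim_counts(fixed[i, ],
                                          rep(fixed$true_level[i], length(strains)))
  }
  for (i in seq_len(nrow(poly))) {
    lv <- ifelse(strains %in% edited_strains[[i]], config$poly_level, 0)
    obs[[length(obs) + 1L]] <- sim_counts(poly[i, ], lv)
  }
  obs <- do.call(rbind, obs)
  # outgroup edits the fixed sites (both sexes)
  outgroup <- fixed$site_id
  # genotypes: linked QTL SNPs for a fraction of polymorphic sites
  geno <- list()
  for (i in seq_len(nrow(poly))) {
    linked <- stats::runif(1) < config$qtl_fraction
    offset <- sample(c(-1, 1), 1) * sample(200:9800, 1)
    g <- if (linked) as.integer(strains %in% edited_strains[[i]]) else
      stats::rbinom(length(strains), 1, 0.4)
    geno[[length(geno) + 1L]] <- data.frame(
      snp_id = paste0("snp_", poly$site_id[i]), chrom = poly$chrom[i],
      pos = poly$pos[i] + offset, strain = strains, genotype = g,
      linked = linked, stringsAsFactors = FALSE)
  }
  genotypes <- if (length(geno)) do.call(rbind, geno) else NULL
  if (nrow(poly)) {
    lab$edited_strains <- c(rep(NA_character_, nrow(fixed)),
                            vapply(edited_strains, paste, "", collapse = ","))
    lab$linked_snp <- c(rep(NA, nrow(fixed)),
                        vapply(geno, function(g) g$linked[1], logical(1)))
  }
  list(observations = obs, genotypes = genotypes,
       outgroup_detected = outgroup, truth_labels = lab)
}

#' Write a minimal SNP VCF
#'
#' Emits the generator's SNP track as a small VCFv4.2 file (site positions
#' only; A reference, G alternative placeholder alleles) for consumption by
#' [read_snp_mask()].
#'
#' @param snps Data frame `chrom`, `pos`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(snps, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\tA\tG\t.\tPASS\t.", snps$chrom, snps$pos)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write the synthetic genome as FASTA
#'
#' @param genome [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}
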