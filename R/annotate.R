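#' Functional effect of an A-to-G change within a codon
#'
#' Given a transcript-strand codon containing an A at `pos_in_codon`, returns
#' the effect of editing that A to G: `N` (amino acid changes), `S` (silent),
#' `stop_retained` (stop codon stays a stop, e.g. UAA>UGA) or `stop_lost`
#' (a stop codon becomes coding). An A-to-G change can never create a stop
#' from a non-stop codon.
#'
#' @param ref_codon Character vector of 3-letter codons (transcript strand).
#' @param pos_in_codon Integer vector in 1..3; the codon position of the A.
#' @return Data frame with `category`, `ref_codon`, `alt_codon`, `ref_aa`,
#'   `alt_aa`.
#' @export
classify_codon_change <- function(ref_codon, pos_in_codon) {
  n <- max(length(ref_codon), length(pos_in_codon))
  ref_codon <- toupper(rep_len(ref_codon, n))
  pos_in_codon <- rep_len(as.integer(pos_in_codon), n)
  base_at <- substr(ref_codon, pos_in_codon, pos_in_codon)
  if (any(base_at != "A")) stop("codon position is not an adenosine")
  alt_codon <- ref_codon
  substr(alt_codon, pos_in_codon, pos_in_codon) <- rep_len("G", n)
  gc <- Biostrings::GENETIC_CODE
  ref_aa <- unname(gc[ref_codon])
  alt_aa <- unname(gc[alt_codon])
  category <- ifelse(ref_aa == "*",
                     ifelse(alt_aa == "*", "stop_retained", "stop_lost"),
                     ifelse(ref_aa == alt_aa, "S", "N"))
  data.frame(category = category, ref_codon = ref_codon, alt_codon = alt_codon,
             ref_aa = ref_aa, alt_aa = alt_aa, stringsAsFactors = FALSE)
}

#' Annotate candidate editing sites with their functional effect
#'
#' Assigns each genomic position one category from `N`, `S`, `stop_retained`,
#' `stop_lost`, `UTR5`, `UTR3`, `intron`, `ncRNA`, `intergenic`, using the
#' canonical transcript models only. When a position falls in several genes,
#' precedence is CDS > UTR > ncRNA exon > intron. A genic site whose
#' transcript-strand base is not adenosine is rejected (`category` NA with a
#' `reason`); an intergenic position is kept when the genomic base is A or T
#' (an adenosine on either strand).
#'
#' @param sites Data frame with `chrom` and `pos` (1-based).
#' @param genes Gene-model data frame (see [gene-models]).
#' @param genome A [Biostrings::DNAStringSet] named by chromosome.
#' @return `sites` with columns `category`, `gene_id`, `strand`, `ref_codon`,
#'   `alt_codon`, `ref_aa`, `alt_aa`, `reason` appended.
#' @export
annotate_sites <- function(sites, genes, genome) {
  validate_gene_models(genes)
  spans <- gene_spans(genes)
  n <- nrow(sites)
  out <- data.frame(category = rep(NA_character_, n), gene_id = NA_character_,
                    strand = NA_character_, ref_codon = NA_character_,
                    alt_codon = NA_character_, ref_aa = NA_character_,
                    alt_aa = NA_character_, reason = NA_character_,
                    stringsAsFactors = FALSE)
  # cache per-gene CDS maps lazily
  cds_cache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    chrom <- sites$chrom[i]; pos <- sites$pos[i]
    hit <- spans[spans$chrom == chrom & spans$start <= pos & spans$end >= pos, , drop = FALSE]
    if (!nrow(hit)) {
      b <- strand_base(genome, chrom, pos, "+")
      if (b %in% c("A", "T")) {
        out$category[i] <- "intergenic"
      } else {
        out$reason[i] <- "not an adenosine on either strand"
      }
      next
    }
    # categorise within each overlapping gene, then apply precedence
    cats <- character(nrow(hit))
    for (j in seq_len(nrow(hit))) {
      g <- genes[genes$gene_id == hit$gene_id[j], , drop = FALSE]
      inc <- function(f) any(g$feature == f & g$start <= pos & g$end >= pos)
      cats[j] <- if (inc("CDS")) "CDS"
        else if (inc("five_prime_UTR")) "UTR5"
        else if (inc("three_prime_UTR")) "UTR3"
        else if (inc("exon") && !hit$coding[j]) "ncRNA"
        else "intron"
    }
    prec <- c(CDS = 1, UTR5 = 2, UTR3 = 2, ncRNA = 3, intron = 4)
    j <- which.min(prec[cats])
    gid <- hit$gene_id[j]; strand <- hit$strand[j]
    if (strand_base(genome, chrom, pos, strand) != "A") {
      out$reason[i] <- "not an adenosine on the transcript strand"
      next
    }
    out$gene_id[i] <- gid; out$strand[i] <- strand
    if (cats[j] != "CDS") {
      out$category[i] <- cats[j]
      next
    }
    key <- gid
    if (is.null(cds_cache[[key]])) {
      cds_cache[[key]] <- list(pos = cds_positions(genes, gid),
                               seq = cds_sequence(genes, genome, gid))
    }
    cm <- cds_cache[[key]]
    idx <- match(pos, cm$pos)  # 1-based index into transcript-order CDS
    codon_idx <- (idx - 1L) %/% 3L + 1L
    pos_in_codon <- (idx - 1L) %% 3L + 1L
    codon <- substr(cm$seq, (codon_idx - 1L) * 3L + 1L, codon_idx * 3L)
    eff <- classify_codon_change(codon, pos_in_codon)
    out$category[i] <- eff$category
    out$ref_codon[i] <- eff$ref_codon; out$alt_codon[i] <- eff$alt_codon
    out$ref_aa[i] <- eff$ref_aa; out$alt_aa[i] <- eff$alt_aa
  }
  cbind(sites, out)
}

#' Enumerate all CDS adenosines of a gene set with their A-to-G effect
#'
#' Walks every codon of each (coding) gene's canonical CDS and classifies each
#' adenosine position on the transcript strand. This is the workhorse behind
#' the neutral N/S expectation and the synthetic-data generator's site truth.
#'
#' @param genes Gene-model data frame.
#' @param genome A [Biostrings::DNAStringSet] named by chromosome.
#' @param gene_ids Optional subset of genes to enumerate.
#' @return Data frame with `gene_id`, `chrom`, `pos` (genomic, 1-based),
#'   `strand`, `cds_index`, `category` (N/S/stop_retained/stop_lost).
#' @export
enumerate_cds_adenosines <- function(genes, genome, gene_ids = NULL) {
  ids <- unique(genes$gene_id[genes$feature == "CDS"])
  if (!is.null(gene_ids)) ids <- intersect(ids, gene_ids)
  res <- lapply(ids, function(gid) {
    gpos <- cds_positions(genes, gid)
    seq <- cds_sequence(genes, genome, gid)
    bases <- strsplit(seq, "")[[1]]
    ia <- which(bases == "A")
    if (!length(ia)) return(NULL)
    codon_idx <- (ia - 1L) %/% 3L + 1L
    pic <- (ia - 1L) %% 3L + 1L
    codons <- substring(seq, (codon_idx - 1L) * 3L + 1L, codon_idx * 3L)
    eff <- classify_codon_change(codons, pic)
    g <- genes[genes$gene_id == gid, , drop = FALSE]
    data.frame(gene_id = gid, chrom = g$chrom[1], pos = gpos[ia],
               strand = g$strand[1], cds_index = ia,
               category = eff$category, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), chrom = character(), pos = integer(),
                      strand = character(), cds_index = integer(),
                      category = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Enumerate transcript adenosines of a gene (all features)
#'
#' Lists every transcript-strand adenosine in a gene's pre-mRNA span,
#' categorised as for [annotate_sites()] but restricted to that gene. Used by
#' the synthetic generator and for background scans.
#'
#' @inheritParams enumerate_cds_adenosines
#' @return Data frame `gene_id`, `chrom`, `pos`, `strand`, `category`.
#' @export
enumerate_gene_adenosines <- function(genes, genome, gene_ids = NULL) {
  spans <- gene_spans(genes)
  if (!is.null(gene_ids)) spans <- spans[spans$gene_id %in% gene_ids, , drop = FALSE]
  res <- lapply(seq_len(nrow(spans)), function(k) {
    gid <- spans$gene_id[k]; strand <- spans$strand[k]; chrom <- spans$chrom[k]
    pos <- spans$start[k]:spans$end[k]
    b <- strand_base(genome, chrom, pos, strand)
    pos <- pos[b == "A"]
    if (!length(pos)) return(NULL)
    g <- genes[genes$gene_id == gid, , drop = FALSE]
    cat <- rep("intron", length(pos))
    in_feat <- function(f) {
      fr <- g[g$feature == f, , drop = FALSE]
      if (!nrow(fr)) return(rep(FALSE, length(pos)))
      Reduce(`|`, lapply(seq_len(nrow(fr)), function(i) pos >= fr$start[i] & pos <= fr$end[i]))
    }
    cat[in_feat("five_prime_UTR")] <- "UTR5"
    cat[in_feat("three_prime_UTR")] <- "UTR3"
    is_cds <- in_feat("CDS")
    if (any(is_cds)) {
      cds <- enumerate_cds_adenosines(genes, genome, gid)
      cat[is_cds] <- cds$category[match(pos[is_cds], cds$pos)]
    }
    if (!spans$coding[k]) cat[in_feat("exon")] <- "ncRNA"
    data.frame(gene_id = gid, chrom = chrom, pos = pos, strand = strand,
               category = cat, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
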