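#' Gene models as a flat feature table
#'
#' The package represents gene models of the canonical transcript as a plain
#' data frame with one row per feature interval and columns `gene_id`,
#' `chrom`, `strand` ("+"/"-"), `feature` (one of `exon`, `CDS`,
#' `five_prime_UTR`, `three_prime_UTR`) and 1-based closed `start`/`end`.
#' Introns are implicit: positions inside the gene span but outside every
#' exon. A gene without CDS rows is treated as non-coding (ncRNA).
#'
#' @name gene-models
#' @keywords internal
NULL

FEATURE_TYPES <- c("exon", "CDS", "five_prime_UTR", "three_prime_UTR")

#' Read canonical-transcript gene models from GFF3
#'
#' Imports a GFF3 file with [rtracklayer::import()] and flattens the
#' `exon`/`CDS`/`five_prime_UTR`/`three_prime_UTR` features into the package's
#' gene-model table. The parent gene identifier is taken from the `gene_id`
#' attribute when present, otherwise from `Parent`, otherwise `ID`. The file
#' is expected to describe one (canonical) transcript per gene.
#'
#' @param path Path to a GFF3 file.
#' @return A gene-model data frame (see [gene-models]).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in% FEATURE_TYPES
  gr <- gr[keep]
  mc <- S4Vectors::mcols(gr)
  gid <- if (!is.null(mc$gene_id)) {
    as.character(mc$gene_id)
  } else if (!is.null(mc$Parent)) {
    vapply(mc$Parent, function(x) if (length(x)) as.character(x[[1]]) else NA_character_, "")
  } else {
    as.character(mc$ID)
  }
  gid <- sub("^(transcript:|gene:)", "", gid)
  out <- data.frame(
    gene_id = gid,
    chrom   = as.character(GenomicRanges::seqnames(gr)),
    strand  = as.character(GenomicRanges::strand(gr)),
    feature = as.character(gr$type),
    start   = GenomicRanges::start(gr),
    end     = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  validate_gene_models(out)
  out[order(out$gene_id, out$start), , drop = FALSE]
}

#' Write gene models to GFF3
#'
#' Exports the flat feature table through [rtracklayer::export()], emitting a
#' `gene` row spanning each gene plus its feature rows, so the file round-trips
#' through [read_gene_models()].
#'
#' @param genes Gene-model data frame.
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  validate_gene_models(genes)
  spans <- gene_spans(genes)
  gene_rows <- GenomicRanges::GRanges(
    spans$chrom, IRanges::IRanges(spans$start, spans$end), strand = spans$strand,
    type = "gene", ID = spans$gene_id, Parent = NA_character_,
    gene_id = spans$gene_id, phase = NA_integer_
  )
  # CDS phase in transcript order: offset to the next codon start
  phase <- rep(NA_integer_, nrow(genes))
  for (gid in unique(genes$gene_id)) {
    idx <- which(genes$gene_id == gid & genes$feature == "CDS")
    if (!length(idx)) next
    idx <- idx[order(genes$start[idx])]
    if (genes$strand[idx[1]] == "-") idx <- rev(idx)
    lens <- genes$end[idx] - genes$start[idx] + 1L
    phase[idx] <- as.integer((3L - cumsum(c(0L, lens[-length(lens)])) %% 3L) %% 3L)
  }
  feat_rows <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end), strand = genes$strand,
    type = genes$feature, ID = NA_character_, Parent = genes$gene_id,
    gene_id = genes$gene_id, phase = phase
  )
  gr <- suppressWarnings(c(gene_rows, feat_rows))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Validate a gene-model table
#'
#' Checks the feature vocabulary, that intervals are well-formed and
#' non-overlapping within a gene/feature, and that every coding gene's total
#' CDS length is divisible by 3.
#'
#' @param genes Gene-model data frame.
#' @return `genes`, invisibly; stops on violation.
#' @export
validate_gene_models <- function(genes) {
  need <- c("gene_id", "chrom", "strand", "feature", "start", "end")
  if (!all(need %in% names(genes))) {
    stop("gene models need columns: ", paste(need, collapse = ", "))
  }
  if (!all(genes$feature %in% FEATURE_TYPES)) {
    stop("unknown feature type(s): ",
         paste(setdiff(unique(genes$feature), FEATURE_TYPES), collapse = ", "))
  }
  if (any(genes$end < genes$start)) stop("feature with end < start")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  cds <- genes[genes$feature == "CDS", , drop = FALSE]
  if (nrow(cds)) {
    len <- tapply(cds$end - cds$start + 1L, cds$gene_id, sum)
    bad <- names(len)[len %% 3L != 0L]
    if (length(bad)) {
      stop("CDS length not divisible by 3 for gene(s): ", paste(bad, collapse = ", "))
    }
  }
  for (g in split(genes, paste(genes$gene_id, genes$feature))) {
    if (nrow(g) > 1) {
      g <- g[order(g$start), ]
      if (any(g$start[-1] <= g$end[-nrow(g)])) {
        stop("overlapping ", g$feature[1], " intervals in gene ", g$gene_id[1])
      }
    }
  }
  invisible(genes)
}

#' Per-gene genomic spans
#' @param genes Gene-model data frame.
#' @return Data frame with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `coding`.
#' @export
gene_spans <- function(genes) {
  sp <- do.call(rbind, lapply(split(genes, genes$gene_id), function(g) {
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1], strand = g$strand[1],
               start = min(g$start), end = max(g$end),
               coding = any(g$feature == "CDS"), stringsAsFactors = FALSE)
  }))
  rownames(sp) <- NULL
  sp
}

# Genomic positions of a gene's CDS in transcript (5'->3') order.
cds_positions <- function(genes, gene_id) {
  cds <- genes[genes$gene_id == gene_id & genes$feature == "CDS", , drop = FALSE]
  if (!nrow(cds)) return(integer(0))
  cds <- cds[order(cds$start), , drop = FALSE]
  pos <- unlist(lapply(seq_len(nrow(cds)), function(i) cds$start[i]:cds$end[i]))
  if (cds$strand[1] == "-") pos <- rev(pos)
  pos
}

# Genomic positions of a gene's exons in transcript order.
exon_positions <- function(genes, gene_id) {
  ex <- genes[genes$gene_id == gene_id & genes$feature == "exon", , drop = FALSE]
  if (!nrow(ex)) return(integer(0))
  ex <- ex[order(ex$start), , drop = FALSE]
  pos <- unlist(lapply(seq_len(nrow(ex)), function(i) ex$start[i]:ex$end[i]))
  if (ex$strand[1] == "-") pos <- rev(pos)
  pos
}

# Transcript-strand base(s) at genomic positions (character vector).
strand_base <- function(genome, chrom, pos, strand) {
  seq <- genome[[chrom]]
  b <- strsplit(as.character(Biostrings::extractAt(
    seq, IRanges::IRanges(pos, pos))), "")
  b <- vapply(b, `[`, "", 1L)
  if (strand == "-") b <- chartr("ACGT", "TGCA", b)
  b
}

#' Spliced transcript (mRNA) sequence of a gene
#'
#' Concatenates the exon sequence in transcript order, reverse-complemented
#' for minus-strand genes.
#'
#' @param genes Gene-model data frame.
#' @param genome A [Biostrings::DNAStringSet] named by chromosome.
#' @param gene_id Gene identifier.
#' @return A single character string (5'->3' mRNA sequence).
#' @export
transcript_sequence <- function(genes, genome, gene_id) {
  ex <- genes[genes$gene_id == gene_id & genes$feature == "exon", , drop = FALSE]
  if (!nrow(ex)) stop("gene has no exon rows: ", gene_id)
  ex <- ex[order(ex$start), , drop = FALSE]
  s <- paste(as.character(Biostrings::extractAt(
    genome[[ex$chrom[1]]], IRanges::IRanges(ex$start, ex$end))), collapse = "")
  if (ex$strand[1] == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}

# CDS sequence on the transcript strand.
cds_sequence <- function(genes, genome, gene_id) {
  pos <- cds_positions(genes, gene_id)
  if (!length(pos)) return("")
  g <- genes[genes$gene_id == gene_id, , drop = FALSE]
  b <- strand_base(genome, g$chrom[1], sort(pos), "+")
  s <- paste(b, collapse = "")
  if (g$strand[1] == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}

# "chrom:pos" site keys used throughout.
site_key <- function(chrom, pos) paste0(chrom, ":", pos)
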