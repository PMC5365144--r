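#' Library metadata table
#'
#' Small constructor/validator for the per-library metadata used throughout:
#' one row per sequencing library with its species, sex, age label,
#' temperature condition and strain.
#'
#' @param library_id Unique library identifiers.
#' @param species,sex,age_days,temperature,strain Per-library labels
#'   (recycled). `sex` must be one of `"F"`, `"M"`, `"mixed"`.
#' @return Data frame of class `library_meta`.
#' @examples
#' library_meta(c("B1", "B2"), sex = c("F", "F"), temperature = "25C")
#' @export
library_meta <- function(library_id, species = "Dmel", sex = "mixed",
                         age_days = "1-5", temperature = "25C", strain = "ref") {
  library_id <- as.character(library_id)
  if (anyDuplicated(library_id)) stop("library_id must be unique")
  n <- length(library_id)
  sex <- rep_len(sex, n)
  if (!all(sex %in% c("F", "M", "mixed"))) stop("sex must be F, M or mixed")
  out <- data.frame(library_id = library_id, species = rep_len(species, n),
                    sex = sex, age_days = rep_len(age_days, n),
                    temperature = rep_len(temperature, n),
                    strain = rep_len(strain, n), stringsAsFactors = FALSE)
  class(out) <- c("library_meta", "data.frame")
  out
}

#' Load per-site per-library allele counts
#'
#' Reads a tab-separated table with columns `chrom`, `pos`, `library_id`,
#' `coverage`, `edited_count` (positions 1-based), validates it against the
#' library metadata, and drops rows at masked SNP positions. The number of
#' masked rows dropped is recorded in the `n_masked` attribute and reported
#' via `message()`.
#'
#' @param path Path to the tab-separated count table (header required), or a
#'   data frame with the same columns.
#' @param meta A [library_meta()] table; rows with unknown `library_id` are an
#'   error.
#' @param mask Optional SNP mask: a data frame with `chrom`/`pos` (e.g. from
#'   [read_snp_mask()]).
#' @return Data frame of observations with an added `level` column
#'   (`edited_count / coverage`, NA at zero coverage), ordered by
#'   chrom/pos/library.
#' @export
load_site_observations <- function(path, meta = NULL, mask = NULL) {
  obs <- if (is.data.frame(path)) path else
    utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "library_id", "coverage", "edited_count")
  if (!all(need %in% names(obs))) {
    stop("count table needs columns: ", paste(need, collapse = ", "))
  }
  obs <- obs[need]
  bad <- which(!is.finite(obs$pos) | !is.finite(obs$coverage) |
                 !is.finite(obs$edited_count))
  if (length(bad)) stop("malformed count row(s) at line(s): ",
                        paste(utils::head(bad + 1L, 5), collapse = ", "))
  bad <- which(obs$edited_count > obs$coverage)
  if (length(bad)) {
    stop("edited_count exceeds coverage at line(s): ",
         paste(utils::head(bad + 1L, 5), collapse = ", "))
  }
  if (any(obs$coverage < 0) || any(obs$edited_count < 0)) {
    stop("negative counts in table")
  }
  if (!is.null(meta)) {
    unknown <- setdiff(unique(obs$library_id), meta$library_id)
    if (length(unknown)) stop("unknown library_id: ", paste(unknown, collapse = ", "))
  }
  n_masked <- 0L
  if (!is.null(mask) && nrow(mask)) {
    drop <- site_key(obs$chrom, obs$pos) %in% site_key(mask$chrom, mask$pos)
    n_masked <- sum(drop)
    if (n_masked) message("dropped ", n_masked, " observation(s) at masked SNP positions")
    obs <- obs[!drop, , drop = FALSE]
  }
  obs$level <- ifelse(obs$coverage > 0, obs$edited_count / obs$coverage, NA_real_)
  obs <- obs[order(obs$chrom, obs$pos, obs$library_id), , drop = FALSE]
  rownames(obs) <- NULL
  attr(obs, "n_masked") <- n_masked
  obs
}

#' Write a site-observation (or annotated site) table
#'
#' Tab-separated, header, no quoting or row names; the stable on-disk dialect
#' of the package. Writing then re-reading with [load_site_observations()]
#' reproduces identical observations.
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SNP mask from VCF
#'
#' Extracts the (chrom, pos) positions of a VCF via [vcfR::read.vcfR()].
#' Positions in the mask are excluded from all candidate lists before any
#' probability computation.
#'
#' @param path Path to an (uncompressed or gzipped) VCF.
#' @return Data frame with `chrom` and `pos` (1-based).
#' @export
read_snp_mask <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  data.frame(chrom = as.character(fix[, "CHROM"]),
             pos = as.integer(fix[, "POS"]), stringsAsFactors = FALSE)
}
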