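# Format readers and writers shared by all stages. Coordinates are 1-based
# closed internally (the R/Bioconductor convention); BED output is converted
# to 0-based half-open and VCF input is already 1-based.

#' Read FASTA sequences
#'
#' @param path FASTA file (CRLF endings and lowercase bases tolerated;
#'   sequences are uppercased).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Read a variant TSV (sequence_id, pos, ref, alt)
#'
#' Positions are 1-based. A `pos_1based` column name is also accepted.
#'
#' @param path Tab-separated file with a header.
#' @return data.frame with `sequence_id`, `pos`, `ref`, `alt`.
#' @export
read_variants_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("pos_1based" %in% names(df) && !"pos" %in% names(df)) {
    names(df)[names(df) == "pos_1based"] <- "pos"
  }
  need <- c("sequence_id", "pos", "ref", "alt")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop(sprintf("variant table lacks column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  df$pos <- as.integer(df$pos)
  df$ref <- toupper(df$ref)
  df$alt <- toupper(df$alt)
  df
}

#' Read SNVs from a VCF
#'
#' Keeps biallelic single-nucleotide records only; anything else (indels,
#' multi-allelic rows) is skipped with a message. POS stays 1-based.
#'
#' @param path VCF file (plain text).
#' @return data.frame with `sequence_id`, `pos`, `ref`, `alt`.
#' @export
read_vcf_snvs <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  out <- data.frame(sequence_id = fix$CHROM, pos = as.integer(fix$POS),
                    ref = toupper(fix$REF), alt = toupper(fix$ALT),
                    stringsAsFactors = FALSE)
  snv <- grepl("^[ACGT]$", out$ref) & grepl("^[ACGT]$", out$alt)
  if (any(!snv)) {
    message(sprintf("read_vcf_snvs: skipped %d non-SNV record(s)", sum(!snv)))
  }
  out[snv, , drop = FALSE]
}

#' Read an association TSV with configurable column names
#'
#' @param path Tab-separated file with a header.
#' @param col_map Named character vector mapping internal names
#'   (`sequence_id`, `pos`, `ref`, `alt`, `effect`, `p`, `p_adj`, `gene`,
#'   `beta`) to the file's column names; identity for names not listed.
#' @return data.frame with internal column names.
#' @export
read_association_tsv <- function(path, col_map = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (internal in names(col_map)) {
      src <- col_map[[internal]]
      if (!src %in% names(df)) {
        stop(sprintf("column '%s' (mapped to %s) not found", src, internal),
             call. = FALSE)
      }
      names(df)[names(df) == src] <- internal
    }
  }
  if ("pos" %in% names(df)) df$pos <- as.integer(df$pos)
  df
}

#' Write sites as BED6
#'
#' BED is 0-based half-open; the score column is `round(1000 * affinity)`.
#'
#' @param sites Site data.frame from [scan_sequence()].
#' @param file Output path.
#' @param name Feature name column (default the pattern name if present).
#' @return The path, invisibly.
#' @export
write_site_bed <- function(sites, file, name = "site") {
  bed <- data.frame(chrom = sites$sequence_id,
                    start = sites$start - 1L,
                    end = sites$end,
                    name = name,
                    score = as.integer(round(1000 * sites$affinity)),
                    strand = sites$strand,
                    stringsAsFactors = FALSE)
  utils::write.table(bed, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read a BED6 site file back into the internal representation
#'
#' @param path BED file written by [write_site_bed()].
#' @return data.frame with 1-based `start`/`end` plus `name`, `score`,
#'   `strand`.
#' @export
read_site_bed <- function(path) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(bed)[1:6] <- c("sequence_id", "start0", "end", "name", "score", "strand")
  data.frame(sequence_id = bed$sequence_id, start = bed$start0 + 1L,
             end = bed$end, name = bed$name, score = bed$score,
             strand = bed$strand, stringsAsFactors = FALSE)
}

#' Write a data.frame as TSV (atomic)
#'
#' Writes to a temporary file in the target directory and renames, so no
#' partially written output is ever left behind.
#'
#' @param df data.frame.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_tsv <- function(df, file) {
  tmp <- tempfile(tmpdir = dirname(file))
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, file)
  invisible(file)
}

#' Write a run report / sidecar as JSON
#'
#' @param x List to serialise (enrichment reports have their variant table
#'   dropped to keep sidecars small unless `include_variants = TRUE`).
#' @param file Output path.
#' @param include_variants Keep the per-variant table in the JSON.
#' @return The path, invisibly.
#' @export
write_json_report <- function(x, file, include_variants = FALSE) {
  if (inherits(x, "enrichment_report") && !include_variants) {
    x$variants <- NULL
  }
  x <- rapply(unclass(x), function(v) if (is.function(v)) NULL else v, how = "replace")
  tmp <- tempfile(tmpdir = dirname(file))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  file.rename(tmp, file)
  invisible(file)
}
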