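# PBM 8-mer relative-affinity tables.
#
# A protein binding microarray (PBM) measures a transcription factor's binding
# signal for every possible 8-mer. Dividing each 8-mer's median intensity by
# the maximal median intensity gives a "relative affinity" in (0, 1], with the
# optimal 8-mer at exactly 1.00. Functional enhancer sites typically sit well
# below 1 (suboptimal / low-affinity sites), so the table must resolve the
# low tail faithfully rather than thresholding it away.

new_pbm_table <- function(affinities, tf_name) {
  structure(list(tf_name = tf_name, k = 8L, affinities = affinities),
            class = "pbm_table")
}

#' @export
print.pbm_table <- function(x, ...) {
  cat(sprintf("PBM relative-affinity table for %s: %d 8-mer keys, max = %g\n",
              x$tf_name, length(x$affinities), max(x$affinities)))
  invisible(x)
}

#' Build a PBM relative-affinity table from raw intensities
#'
#' Normalises raw (median) intensities to the maximum so that the optimal
#' 8-mer scores exactly 1. Non-positive or missing intensities are dropped
#' with a message; both each 8-mer and (optionally) its reverse complement
#' are keyed.
#'
#' @param kmers Character vector of 8-mers (A/C/G/T).
#' @param intensities Numeric vector of raw intensities, same length.
#' @param tf_name Label for the transcription factor.
#' @param rc_kmers Optional reverse-complement 8-mer column; keyed with the
#'   same value as the forward 8-mer of its row.
#' @return A `pbm_table` object.
#' @export
pbm_table <- function(kmers, intensities, tf_name = "TF", rc_kmers = NULL) {
  kmers <- toupper(kmers)
  assert_kmer(kmers, what = "8-mer")
  if (length(intensities) != length(kmers)) {
    stop("kmers and intensities must have the same length", call. = FALSE)
  }
  drop <- is.na(intensities) | intensities <= 0
  if (any(drop)) {
    message(sprintf("pbm_table: dropped %d row(s) with missing or non-positive intensity",
                    sum(drop)))
    kmers <- kmers[drop == FALSE]
    intensities <- intensities[drop == FALSE]
    if (!is.null(rc_kmers)) rc_kmers <- rc_kmers[drop == FALSE]
  }
  if (length(kmers) == 0) stop("PBM table is empty after filtering", call. = FALSE)

  # Duplicate forward 8-mers are only tolerated when their intensities agree.
  if (anyDuplicated(kmers)) {
    spl <- split(intensities, kmers)
    conflict <- vapply(spl, function(v) max(v) - min(v) > 0, logical(1))
    if (any(conflict)) {
      stop(sprintf("duplicate 8-mer with conflicting intensities: %s",
                   names(spl)[conflict][1]), call. = FALSE)
    }
    keep <- !duplicated(kmers)
    kmers <- kmers[keep]
    intensities <- intensities[keep]
    if (!is.null(rc_kmers)) rc_kmers <- rc_kmers[keep]
  }

  rel <- intensities / max(intensities)
  aff <- stats::setNames(rel, kmers)

  if (!is.null(rc_kmers)) {
    rc_kmers <- toupper(rc_kmers)
    assert_kmer(rc_kmers, what = "reverse-complement 8-mer")
    mism <- sum(rc_kmers != revcomp(kmers))
    if (mism > 0) {
      message(sprintf(
        "pbm_table: %d row(s) whose reverse-complement column disagrees with the forward 8-mer; both keys kept",
        mism))
    }
    new_keys <- !(rc_kmers %in% names(aff))
    extra <- stats::setNames(rel[new_keys], rc_kmers[new_keys])
    # A key present in both columns with different values is resolved at
    # lookup (max over orientations), so keeping the first is enough here.
    aff <- c(aff, extra)
  }
  new_pbm_table(aff, tf_name)
}

#' Read a UniProbe-dialect 8-mer table
#'
#' Parses the UniProbe "8mers" tab-separated layout (8-mer,
#' reverse-complement 8-mer, E-score, median intensity, Z-score; header row
#' optional) and converts median intensities to relative affinities by
#' dividing by the maximal median intensity. Column detection: every column
#' whose values are all 8-mers is treated as a k-mer column (first = forward,
#' second = reverse complement); the intensity column is taken from
#' `intensity_col` if given, otherwise a header name matching "median",
#' otherwise the second numeric column (UniProbe order is E-score then
#' median), falling back to the only numeric column.
#'
#' @param file Path to a tab-separated file, or a connection.
#' @param tf_name Transcription-factor label stored in the table.
#' @param intensity_col Optional column index or (header) name selecting the
#'   intensity column explicitly.
#' @return A [pbm_table()] object whose maximal 8-mer has affinity exactly 1.
#' @export
read_uniprobe_table <- function(file, tf_name = "TF", intensity_col = NULL) {
  lines <- if (inherits(file, "connection")) readLines(file) else readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("PBM table is empty", call. = FALSE)

  first <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  has_header <- !any(grepl("^[ACGTacgt]{8}$", first))
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          header = has_header, stringsAsFactors = FALSE)

  kmer_cols <- which(vapply(df, function(col) {
    is.character(col) && all(grepl("^[ACGTacgt]{8}$", col))
  }, logical(1)))
  if (length(kmer_cols) == 0) stop("no 8-mer column found in PBM table", call. = FALSE)
  fwd_col <- kmer_cols[1]
  rc_col <- if (length(kmer_cols) >= 2) kmer_cols[2] else NA_integer_

  num_cols <- setdiff(which(vapply(df, is.numeric, logical(1))), kmer_cols)
  if (!is.null(intensity_col)) {
    icol <- if (is.character(intensity_col)) match(intensity_col, names(df)) else intensity_col
    if (is.na(icol) || icol > ncol(df)) stop("intensity_col not found", call. = FALSE)
  } else if (has_header && any(grepl("median", names(df), ignore.case = TRUE))) {
    icol <- grep("median", names(df), ignore.case = TRUE)[1]
  } else if (length(num_cols) >= 2) {
    icol <- num_cols[2]
  } else if (length(num_cols) == 1) {
    icol <- num_cols[1]
  } else {
    stop("no numeric intensity column found in PBM table", call. = FALSE)
  }

  pbm_table(kmers = df[[fwd_col]],
            intensities = as.numeric(df[[icol]]),
            tf_name = tf_name,
            rc_kmers = if (!is.na(rc_col)) df[[rc_col]] else NULL)
}

#' Relative binding affinity of an 8-mer
#'
#' Looks up an 8-mer in a PBM table. The lookup is strand symmetric: the
#' value is the maximum over the 8-mer and its reverse complement, so a site
#' scores identically whichever strand it was read from.
#'
#' @param kmer Character vector of 8-mers.
#' @param table A [pbm_table()].
#' @return Numeric vector of relative affinities in (0, 1].
#' @export
#' @examples
#' tab <- pbm_table(c("CCGGAAGT", "ACGGAAGT"), c(100, 40))
#' relative_affinity("CCGGAAGT", tab)      # 1
#' relative_affinity(revcomp("ACGGAAGT"), tab)  # 0.4 (strand symmetric)
relative_affinity <- function(kmer, table) {
  stopifnot(inherits(table, "pbm_table"))
  kmer <- toupper(kmer)
  assert_kmer(kmer, k = table$k, what = "query 8-mer")
  fwd <- unname(table$affinities[kmer])
  rev <- unname(table$affinities[revcomp(kmer)])
  out <- pmax(fwd, rev, na.rm = TRUE)
  missing <- is.na(fwd) & is.na(rev)
  if (any(missing)) {
    stop(sprintf("8-mer not present in PBM table (either orientation): %s",
                 kmer[missing][1]), call. = FALSE)
  }
  out
}

#' Write a PBM table as a two-column TSV cache
#'
#' Writes `8mer<TAB>relative_affinity` with full double precision so that
#' re-reading via [read_uniprobe_table()] reproduces every affinity exactly.
#'
#' @param table A [pbm_table()].
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_pbm_table <- function(table, file) {
  stopifnot(inherits(table, "pbm_table"))
  df <- data.frame(kmer = names(table$affinities),
                   relative_affinity = format(unname(table$affinities), digits = 17),
                   stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = c("8mer", "relative_affinity"))
  invisible(file)
}
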