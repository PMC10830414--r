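# Degenerate TFBS core patterns and both-strand window scanning.
#
# Binding-site families are described by a length-8 degenerate consensus over
# {A,C,G,T,N,W,K,M}. Built-ins follow the core definitions used for ETS
# (NNGGAWNN), AP-1 (NTKANNMA) and IRF (NWNNGANA) sites. A scan reports every
# 8-base window, on either strand, whose motif-orientation 8-mer matches the
# pattern, together with its PBM relative affinity.

MOTIF_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  N = c("A", "C", "G", "T"),
  W = c("A", "T"),
  K = c("G", "T"),
  M = c("A", "C")
)

BUILTIN_MOTIFS <- c(ETS = "NNGGAWNN", `AP-1` = "NTKANNMA", IRF = "NWNNGANA")

#' Define a degenerate binding-site pattern
#'
#' @param name Pattern name. `"ETS"`, `"AP-1"` and `"IRF"` are built in; any
#'   other name requires `consensus`.
#' @param consensus Length-8 string over A, C, G, T, N (any), W (A/T),
#'   K (G/T), M (A/C). Ignored for built-in names unless supplied.
#' @return A `motif_pattern` object.
#' @export
#' @examples
#' motif_pattern("ETS")
#' motif_pattern("HOX-like", "NTAAWNNN")
motif_pattern <- function(name, consensus = NULL) {
  if (is.null(consensus)) {
    if (!name %in% names(BUILTIN_MOTIFS)) {
      stop(sprintf("no built-in consensus for '%s'; supply one", name), call. = FALSE)
    }
    consensus <- BUILTIN_MOTIFS[[name]]
  }
  consensus <- toupper(consensus)
  if (nchar(consensus) != 8 || !grepl("^[ACGTNWKM]{8}$", consensus)) {
    stop("consensus must be 8 characters over {A,C,G,T,N,W,K,M}", call. = FALSE)
  }
  structure(list(name = name, consensus = consensus,
                 regex = pattern_regex_(consensus)),
            class = "motif_pattern")
}

pattern_regex_ <- function(consensus) {
  chars <- strsplit(consensus, "", fixed = TRUE)[[1]]
  parts <- vapply(chars, function(ch) {
    set <- MOTIF_CODES[[ch]]
    if (length(set) == 1) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1))
  paste0("^", paste(parts, collapse = ""), "$")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("motif_pattern %s: %s\n", x$name, x$consensus))
  invisible(x)
}

#' Does an 8-mer match a degenerate pattern?
#'
#' @param kmer Character vector of 8-mers over {A,C,G,T}.
#' @param pattern A [motif_pattern()].
#' @return Logical vector.
#' @export
matches_pattern <- function(kmer, pattern) {
  stopifnot(inherits(pattern, "motif_pattern"))
  kmer <- toupper(kmer)
  assert_kmer(kmer, what = "kmer")
  grepl(pattern$regex, kmer)
}

empty_sites <- function() {
  data.frame(sequence_id = character(), start = integer(), end = integer(),
             strand = character(), kmer = character(), affinity = numeric(),
             stringsAsFactors = FALSE)
}

#' Scan a sequence for motif windows on both strands
#'
#' Every 8-base window is tested in forward orientation (+ strand) and as its
#' reverse complement (- strand); the reported `kmer` is always read in motif
#' orientation. Windows containing `N` are skipped. Overlapping windows and
#' windows matching on both strands are all reported (one Site per strand).
#'
#' @param seq A single DNA string (A/C/G/T/N; case ignored).
#' @param pattern A [motif_pattern()].
#' @param table A [pbm_table()] used to attach relative affinities.
#' @param sequence_id Identifier stored in the output.
#' @return A data.frame of sites (`sequence_id`, `start`, `end` 1-based
#'   inclusive, `strand`, `kmer`, `affinity`) sorted by start, `+` before `-`.
#' @export
scan_sequence <- function(seq, pattern, table, sequence_id = "seq") {
  stopifnot(inherits(pattern, "motif_pattern"), inherits(table, "pbm_table"))
  seq <- clean_sequence(seq)
  L <- nchar(seq)
  if (L < 8) return(empty_sites())
  starts <- seq_len(L - 7L)
  win <- substring(seq, starts, starts + 7L)
  ok <- !grepl("N", win, fixed = TRUE)
  win <- win[ok]
  starts <- starts[ok]
  if (length(win) == 0) return(empty_sites())

  rc <- revcomp(win)
  plus <- grepl(pattern$regex, win)
  minus <- grepl(pattern$regex, rc)

  out <- rbind(
    data.frame(sequence_id = rep(sequence_id, sum(plus)), start = starts[plus],
               end = starts[plus] + 7L, strand = rep("+", sum(plus)),
               kmer = win[plus], stringsAsFactors = FALSE),
    data.frame(sequence_id = rep(sequence_id, sum(minus)), start = starts[minus],
               end = starts[minus] + 7L, strand = rep("-", sum(minus)),
               kmer = rc[minus], stringsAsFactors = FALSE)
  )
  if (nrow(out) == 0) return(empty_sites())
  out$affinity <- relative_affinity(out$kmer, table)
  out <- out[order(out$start, match(out$strand, c("+", "-"))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count sites after merging overlapping windows
#'
#' Collapses overlapping/adjacent matched windows (both strands pooled) into
#' maximal runs and counts the runs — a companion number to the raw window
#' count, for comparison with site tallies that merge overlaps.
#'
#' @param sites Site data.frame from [scan_sequence()].
#' @return Integer count of merged site regions.
#' @export
merged_site_count <- function(sites) {
  if (nrow(sites) == 0) return(0L)
  ir <- IRanges::IRanges(start = sites$start, end = sites$end)
  length(IRanges::reduce(ir))
}

# Map ungapped positions to alignment columns for one aligned (gapped) string.
alignment_projection <- function(aligned) {
  chars <- strsplit(aligned, "", fixed = TRUE)[[1]]
  which(chars != "-")
}

#' Pair sites conserved across a pairwise alignment
#'
#' Projects each site's start through a gapped pairwise alignment and pairs
#' sites from the two sequences when their projected starts differ by at most
#' `loc_tol` columns and their affinities by at most `aff_tol`. Pairing is
#' greedy by smallest projected distance (ties to the lower projected
#' coordinate); each site joins at most one pair.
#'
#' @param aln Character vector of length 2: the aligned sequences (gap `-`),
#'   in the same order as `sites_a`, `sites_b`.
#' @param sites_a,sites_b Site data.frames from [scan_sequence()] on the two
#'   ungapped sequences.
#' @param loc_tol Maximum projected start distance, in alignment columns.
#' @param aff_tol Maximum absolute affinity difference.
#' @return data.frame of conserved pairs with projected coordinates and the
#'   per-pair distance.
#' @export
map_sites_through_alignment <- function(aln, sites_a, sites_b,
                                        loc_tol = 0, aff_tol = 0.05) {
  if (length(aln) != 2) stop("aln must contain exactly two aligned sequences", call. = FALSE)
  if (nchar(aln[1]) != nchar(aln[2])) {
    stop("aligned sequences must have equal (gapped) length", call. = FALSE)
  }
  proj_a <- alignment_projection(toupper(aln[1]))
  proj_b <- alignment_projection(toupper(aln[2]))
  if (nrow(sites_a) > 0 && max(sites_a$end) > length(proj_a)) {
    stop("sites_a extend beyond the ungapped length of aln[1]", call. = FALSE)
  }
  if (nrow(sites_b) > 0 && max(sites_b$end) > length(proj_b)) {
    stop("sites_b extend beyond the ungapped length of aln[2]", call. = FALSE)
  }
  empty <- data.frame(idx_a = integer(), idx_b = integer(),
                      proj_start_a = integer(), proj_start_b = integer(),
                      distance = integer(), affinity_a = numeric(),
                      affinity_b = numeric(), stringsAsFactors = FALSE)
  if (nrow(sites_a) == 0 || nrow(sites_b) == 0) return(empty)

  pa <- proj_a[sites_a$start]
  pb <- proj_b[sites_b$start]
  cand <- expand.grid(idx_a = seq_len(nrow(sites_a)), idx_b = seq_len(nrow(sites_b)))
  cand$proj_start_a <- pa[cand$idx_a]
  cand$proj_start_b <- pb[cand$idx_b]
  cand$distance <- abs(cand$proj_start_a - cand$proj_start_b)
  cand$affinity_a <- sites_a$affinity[cand$idx_a]
  cand$affinity_b <- sites_b$affinity[cand$idx_b]
  cand <- cand[cand$distance <= loc_tol &
                 abs(cand$affinity_a - cand$affinity_b) <= aff_tol, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)

  cand <- cand[order(cand$distance, pmin(cand$proj_start_a, cand$proj_start_b),
                     cand$idx_a, cand$idx_b), , drop = FALSE]
  used_a <- logical(nrow(sites_a))
  used_b <- logical(nrow(sites_b))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ia <- cand$idx_a[i]; ib <- cand$idx_b[i]
    if (!used_a[ia] && !used_b[ib]) {
      keep[i] <- TRUE
      used_a[ia] <- TRUE
      used_b[ib] <- TRUE
    }
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
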