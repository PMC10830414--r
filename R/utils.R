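`%||%` <- function(x, y) if (is.null(x)) y else x

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character strings. `N` is kept
#' as `N`; case is preserved.
#'
#' @param x Character vector of DNA strings (alphabet A/C/G/T/N).
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "GGAA"))
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTacgtN", "TGCAtgcaN", x))
}

# Validate a vector of fixed-length DNA k-mers over {A,C,G,T}.
assert_kmer <- function(x, k = 8L, what = "kmer") {
  if (!is.character(x) || length(x) == 0) {
    stop(sprintf("%s must be a non-empty character vector", what), call. = FALSE)
  }
  ok <- !is.na(x) & grepl(sprintf("^[ACGT]{%d}$", k), x)
  if (!all(ok)) {
    bad <- x[!ok][1]
    stop(sprintf("invalid %s '%s': must be %d bases over {A,C,G,T}", what, bad, k),
         call. = FALSE)
  }
  invisible(x)
}

assert_probability <- function(p, what = "p") {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop(sprintf("%s values must be probabilities in [0, 1]", what), call. = FALSE)
  }
  invisible(p)
}

# Uppercase a sequence and check its alphabet ({A,C,G,T,N} by default).
clean_sequence <- function(seq, allow_n = TRUE) {
  if (!is.character(seq) || length(seq) != 1 || is.na(seq)) {
    stop("sequence must be a single character string", call. = FALSE)
  }
  seq <- toupper(seq)
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  if (!grepl(pat, seq)) stop("sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  seq
}

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
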