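# SNV application, per-window ref/alt affinity folds, and classification.
#
# Each SNV is scored against every 8-base window covering it, on both
# strands. A window is retained when its reference 8-mer or its alternate
# 8-mer matches the motif pattern; when both match, the window's fold change
# is alt affinity / ref affinity. A variant is "affinity optimizing" when any
# dual-match window reaches the configured fold (1.59x for ETS; 1.5x for
# AP-1/IRF), "neutral in site" when every dual-match fold sits inside the
# 0.8-1.25x band, and so on per the precedence in classify_snv().

VARIANT_LABELS <- c("affinity_optimizing", "affinity_neutral_in_site",
                    "affinity_decreasing", "affinity_subthreshold",
                    "de_novo_site", "site_ablating", "not_in_site")

#' Classification thresholds for SNV fold changes
#'
#' @param opt_fold Minimum alt/ref fold for an affinity-optimizing call.
#'   Defaults to 1.59 (the ETS rule); for AP-1 and IRF use 1.5, see
#'   [default_thresholds()]. A relaxed rule (any fold > 1.0) can be expressed
#'   here for sparse mutagenesis datasets.
#' @param neutral_band Inclusive fold interval treated as "does not change
#'   affinity"; default `c(0.8, 1.25)`.
#' @return A `class_thresholds` object.
#' @export
class_thresholds <- function(opt_fold = 1.59, neutral_band = c(0.8, 1.25)) {
  if (!(is.numeric(opt_fold) && length(opt_fold) == 1 && opt_fold > 0) ||
      !(is.numeric(neutral_band) && length(neutral_band) == 2)) {
    stop("opt_fold must be a positive scalar and neutral_band a length-2 numeric",
         call. = FALSE)
  }
  if (!(opt_fold > neutral_band[2] && neutral_band[2] > neutral_band[1] &&
        neutral_band[1] > 0)) {
    stop("need opt_fold > upper neutral bound > lower neutral bound > 0", call. = FALSE)
  }
  structure(list(opt_fold = opt_fold, neutral_band = neutral_band),
            class = "class_thresholds")
}

#' Default thresholds by transcription-factor family
#'
#' ETS uses a 1.59-fold optimizing threshold; AP-1 and IRF use 1.5-fold.
#' All share the 0.8-1.25 neutral band.
#'
#' @param pattern_name `"ETS"`, `"AP-1"` or `"IRF"` (anything else gets the
#'   1.5-fold rule).
#' @return A [class_thresholds()] object.
#' @export
default_thresholds <- function(pattern_name) {
  if (identical(pattern_name, "ETS")) class_thresholds(opt_fold = 1.59)
  else class_thresholds(opt_fold = 1.5)
}

#' Apply a single-nucleotide variant to a sequence
#'
#' @param seq DNA string.
#' @param pos 1-based position of the variant.
#' @param ref,alt Single reference / alternate bases; `seq[pos]` must equal
#'   `ref` (guards coordinate-convention bugs).
#' @return The edited sequence.
#' @export
apply_snv <- function(seq, pos, ref, alt) {
  seq <- clean_sequence(seq)
  ref <- toupper(ref); alt <- toupper(alt)
  if (!grepl("^[ACGT]$", ref) || !grepl("^[ACGT]$", alt) || ref == alt) {
    stop("ref and alt must be distinct single bases in {A,C,G,T}", call. = FALSE)
  }
  if (pos < 1 || pos > nchar(seq)) stop("variant position outside sequence", call. = FALSE)
  have <- substring(seq, pos, pos)
  if (have != ref) {
    stop(sprintf("reference mismatch at position %d: expected %s, sequence has %s",
                 pos, ref, have), call. = FALSE)
  }
  paste0(substring(seq, 1, pos - 1), alt, substring(seq, pos + 1, nchar(seq)))
}

# All (window, strand) records covering each variant, vectorised over a
# variant table. Internal engine behind variant_window_effects() and
# classify_variants(). Returns one row per retained window with the motif-
# orientation ref/alt 8-mers, match flags, affinities and fold.
variant_window_table <- function(seq, variants, pattern, table) {
  stopifnot(inherits(pattern, "motif_pattern"), inherits(table, "pbm_table"))
  seq <- clean_sequence(seq)
  n <- nrow(variants)
  pos <- as.integer(variants$pos)
  ref <- toupper(variants$ref)
  alt <- toupper(variants$alt)
  if (any(pos < 1 | pos > nchar(seq))) stop("variant position outside sequence", call. = FALSE)
  have <- substring(seq, pos, pos)
  bad <- which(have != ref)
  if (length(bad)) {
    stop(sprintf("reference mismatch at position %d: expected %s, sequence has %s",
                 pos[bad[1]], ref[bad[1]], have[bad[1]]), call. = FALSE)
  }

  L <- nchar(seq)
  vi <- rep(seq_len(n), times = 8L)
  off <- rep(0:7, each = n)
  start <- pos[vi] - off
  keep <- start >= 1L & start + 7L <= L
  vi <- vi[keep]; off <- off[keep]; start <- start[keep]

  ref_win <- substring(seq, start, start + 7L)
  alt_win <- paste0(substring(ref_win, 1, off), alt[vi],
                    substring(ref_win, off + 2L, 8L))
  usable <- !grepl("N", ref_win, fixed = TRUE)
  vi <- vi[usable]; off <- off[usable]; start <- start[usable]
  ref_win <- ref_win[usable]; alt_win <- alt_win[usable]

  rows <- function(strand) {
    if (strand == "+") {
      rk <- ref_win; ak <- alt_win
    } else {
      rk <- revcomp(ref_win); ak <- revcomp(alt_win)
    }
    rm_ <- grepl(pattern$regex, rk)
    am_ <- grepl(pattern$regex, ak)
    sel <- rm_ | am_
    if (!any(sel)) return(NULL)
    data.frame(variant = vi[sel], start = start[sel], strand = strand,
               ref_kmer = rk[sel], alt_kmer = ak[sel],
               ref_match = rm_[sel], alt_match = am_[sel],
               stringsAsFactors = FALSE)
  }
  out <- rbind(rows("+"), rows("-"))
  if (is.null(out) || nrow(out) == 0) {
    return(data.frame(variant = integer(), start = integer(), strand = character(),
                      ref_kmer = character(), alt_kmer = character(),
                      ref_match = logical(), alt_match = logical(),
                      ref_affinity = numeric(), alt_affinity = numeric(),
                      fold = numeric(), stringsAsFactors = FALSE))
  }
  out$ref_affinity <- NA_real_
  out$alt_affinity <- NA_real_
  if (any(out$ref_match)) {
    out$ref_affinity[out$ref_match] <- relative_affinity(out$ref_kmer[out$ref_match], table)
  }
  if (any(out$alt_match)) {
    out$alt_affinity[out$alt_match] <- relative_affinity(out$alt_kmer[out$alt_match], table)
  }
  out$fold <- ifelse(out$ref_match & out$alt_match,
                     out$alt_affinity / out$ref_affinity, NA_real_)
  out <- out[order(out$variant, out$start, match(out$strand, c("+", "-"))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-window affinity effects of one SNV
#'
#' Enumerates the (up to) eight 8-base windows covering the variant on both
#' strands, keeps windows whose ref or alt 8-mer matches the pattern, and
#' computes alt/ref affinity folds for dual-match windows.
#'
#' @inheritParams apply_snv
#' @param pattern A [motif_pattern()].
#' @param table A [pbm_table()].
#' @return A `variant_effect` object: `$windows` (per-window detail),
#'   `$best_fold` (max fold over dual-match windows, NA if none),
#'   `$ref_best_affinity` / `$alt_best_affinity` (affinities at the
#'   best-fold window; if no dual-match window, the max over ref-matching /
#'   alt-matching windows respectively), `$label` (unset until
#'   [classify_snv()]).
#' @export
variant_window_effects <- function(seq, pos, ref, alt, pattern, table) {
  variants <- data.frame(pos = pos, ref = toupper(ref), alt = toupper(alt),
                         stringsAsFactors = FALSE)
  if (variants$ref == variants$alt) stop("ref and alt must differ", call. = FALSE)
  win <- variant_window_table(seq, variants, pattern, table)
  dual <- win[!is.na(win$fold), , drop = FALSE]
  if (nrow(dual) > 0) {
    b <- which.max(dual$fold)
    best_fold <- dual$fold[b]
    ref_best <- dual$ref_affinity[b]
    alt_best <- dual$alt_affinity[b]
  } else {
    best_fold <- NA_real_
    ref_best <- if (any(win$ref_match)) max(win$ref_affinity[win$ref_match]) else NA_real_
    alt_best <- if (any(win$alt_match)) max(win$alt_affinity[win$alt_match]) else NA_real_
  }
  structure(list(variant = list(pos = pos, ref = toupper(ref), alt = toupper(alt)),
                 pattern_name = pattern$name, windows = win,
                 best_fold = best_fold,
                 ref_best_affinity = ref_best, alt_best_affinity = alt_best,
                 label = NA_character_),
            class = "variant_effect")
}

# Label precedence shared by classify_snv() and classify_variants().
# `folds` are the dual-match folds; the flags say whether any single-match
# window of each kind exists.
label_from_windows <- function(folds, any_alt_only, any_ref_only, any_window, th) {
  if (!any_window) return("not_in_site")
  if (length(folds) == 0) {
    if (any_alt_only) return("de_novo_site")
    return("site_ablating")
  }
  if (any(folds >= th$opt_fold)) return("affinity_optimizing")
  if (all(folds >= th$neutral_band[1] & folds <= th$neutral_band[2])) {
    return("affinity_neutral_in_site")
  }
  if (any(folds < th$neutral_band[1])) return("affinity_decreasing")
  "affinity_subthreshold"
}

analysis_group_of <- function(label) {
  ifelse(label == "affinity_optimizing", "optimizing",
         ifelse(label == "affinity_neutral_in_site", "in_site_no_change", "all_other"))
}

#' Classify an SNV's affinity effect
#'
#' Applies the fold-change rules: (1) affinity_optimizing if any dual-match
#' window reaches `opt_fold`; (2) de_novo_site if only alt-match windows
#' exist; (3) site_ablating if only ref-match windows exist; (4)
#' affinity_neutral_in_site if every dual-match fold is inside the neutral
#' band; (5) affinity_decreasing if any fold falls below the band (and none
#' optimizes); (6) affinity_subthreshold for increases above the band but
#' below `opt_fold`; (7) not_in_site when no window matches at all. The
#' three-way analysis grouping used for enrichment (optimizing /
#' in_site_no_change / all_other) is attached as `$analysis_group`.
#'
#' @param effect A `variant_effect` from [variant_window_effects()].
#' @param th A [class_thresholds()].
#' @return The effect with `$label` and `$analysis_group` set.
#' @export
classify_snv <- function(effect, th = class_thresholds()) {
  stopifnot(inherits(effect, "variant_effect"), inherits(th, "class_thresholds"))
  win <- effect$windows
  folds <- win$fold[!is.na(win$fold)]
  effect$label <- label_from_windows(
    folds,
    any_alt_only = any(win$alt_match & !win$ref_match),
    any_ref_only = any(win$ref_match & !win$alt_match),
    any_window = nrow(win) > 0,
    th = th
  )
  effect$analysis_group <- analysis_group_of(effect$label)
  effect
}

#' Classify every SNV in a variant table
#'
#' Vectorised classification of many SNVs against one sequence; the engine
#' behind the MPRA/eQTL pipelines.
#'
#' @param seq DNA string.
#' @param variants data.frame with columns `pos` (1-based), `ref`, `alt`.
#' @param pattern A [motif_pattern()].
#' @param table A [pbm_table()].
#' @param th A [class_thresholds()].
#' @return `variants` with added columns `n_windows`, `best_fold`,
#'   `ref_best_affinity`, `alt_best_affinity`, `label`, `analysis_group`.
#' @export
classify_variants <- function(seq, variants, pattern, table, th = class_thresholds()) {
  n <- nrow(variants)
  win <- variant_window_table(seq, variants, pattern, table)
  out <- variants
  out$n_windows <- 0L
  out$best_fold <- NA_real_
  out$ref_best_affinity <- NA_real_
  out$alt_best_affinity <- NA_real_
  out$label <- "not_in_site"

  if (nrow(win) > 0) {
    tab <- table(factor(win$variant, levels = seq_len(n)))
    out$n_windows <- as.integer(tab)
    for (v in unique(win$variant)) {
      w <- win[win$variant == v, , drop = FALSE]
      folds <- w$fold[!is.na(w$fold)]
      out$label[v] <- label_from_windows(
        folds,
        any_alt_only = any(w$alt_match & !w$ref_match),
        any_ref_only = any(w$ref_match & !w$alt_match),
        any_window = TRUE, th = th
      )
      if (length(folds) > 0) {
        b <- which.max(w$fold)
        out$best_fold[v] <- w$fold[b]
        out$ref_best_affinity[v] <- w$ref_affinity[b]
        out$alt_best_affinity[v] <- w$alt_affinity[b]
      } else {
        if (any(w$ref_match)) out$ref_best_affinity[v] <- max(w$ref_affinity[w$ref_match])
        if (any(w$alt_match)) out$alt_best_affinity[v] <- max(w$alt_affinity[w$alt_match])
      }
    }
  }
  out$analysis_group <- analysis_group_of(out$label)
  out
}

#' Drop SNVs whose position sits in two or more overlapping sites
#'
#' Used for enhancers in which overlapping binding sites make single-site
#' attribution ambiguous: only variants lying in at most one distinct site
#' (distinct start/strand/pattern combination) from the supplied site list
#' are retained.
#'
#' @param variants data.frame with a `pos` column (1-based).
#' @param sites Site data.frame (rbind sites from all patterns under study;
#'   a `pattern` column is used if present, else all rows count as one
#'   pattern).
#' @return list with `kept` and `excluded` data.frames and `n_excluded`.
#' @export
exclude_overlapping_site_snvs <- function(variants, sites) {
  if (nrow(sites) == 0) {
    return(list(kept = variants, excluded = variants[0, , drop = FALSE], n_excluded = 0L))
  }
  pat <- if ("pattern" %in% names(sites)) sites$pattern else "site"
  key <- paste(sites$start, sites$strand, pat, sep = "/")
  n_cover <- vapply(variants$pos, function(p) {
    length(unique(key[sites$start <= p & sites$end >= p]))
  }, integer(1))
  drop <- n_cover >= 2L
  if (any(drop)) {
    message(sprintf("excluded %d SNV(s) lying in >=2 overlapping sites", sum(drop)))
  }
  list(kept = variants[!drop, , drop = FALSE],
       excluded = variants[drop, , drop = FALSE],
       n_excluded = sum(drop))
}
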