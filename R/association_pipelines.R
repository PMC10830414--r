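# End-to-end enrichment pipelines: MPRA variant-effect tables and eQTL
# association tables joined to affinity classifications, compared across the
# three analysis groups (affinity-optimizing SNVs, in-site SNVs that do not
# change affinity, all other SNVs).

variant_key <- function(df) {
  paste(df$sequence_id, df$pos, df$ref, df$alt, sep = ":")
}

# Shared tail of both pipelines: takes a per-variant data.frame that already
# carries analysis_group, p_adj, direction, effect and signed_logp, and
# produces the grouped comparisons / GOF / fold-enrichment report.
enrichment_core <- function(variants, pattern_name, th, alpha, mwu_variable) {
  variants$gof <- is_gof(variants$p_adj, variants$direction, alpha)
  metric <- switch(mwu_variable,
                   signed_logp = variants$signed_logp,
                   effect = variants$effect,
                   stop("mwu_variable must be 'signed_logp' or 'effect'", call. = FALSE))

  groups <- c("optimizing", "in_site_no_change", "all_other")
  grp <- factor(variants$analysis_group, levels = groups)

  group_counts <- as.list(table(grp))
  group_stats <- lapply(groups, function(g) box_stats(metric[grp == g]))
  names(group_stats) <- groups

  cmp <- function(g) {
    a <- metric[grp == g]
    b <- metric[grp != g]
    if (length(a) == 0 || length(b) == 0) {
      return(structure(list(n_a = length(a), n_b = length(b), U = NA_real_,
                            p_one_tailed = NA_real_, method = "not_applicable"),
                       class = "mwu_result"))
    }
    mwu_one_tailed(a, b)
  }
  comparisons <- list(optimizing_vs_other = cmp("optimizing"),
                      in_site_no_change_vs_other = cmp("in_site_no_change"))

  gof_rates <- vapply(groups, function(g) {
    n <- sum(grp == g)
    if (n == 0) NA_real_ else mean(variants$gof[grp == g])
  }, numeric(1))
  gof_rate_all <- mean(variants$gof)

  n_opt <- sum(grp == "optimizing")
  if (n_opt > 0 && gof_rate_all > 0 && n_opt < nrow(variants)) {
    counts <- rbind(c(sum(variants$gof[grp == "optimizing"]),
                      sum(!variants$gof[grp == "optimizing"])),
                    c(sum(variants$gof[grp != "optimizing"]),
                      sum(!variants$gof[grp != "optimizing"])))
    enr <- tryCatch(fold_enrichment(gof_rates[["optimizing"]], gof_rate_all, counts),
                    error = function(e) list(fold = NA_real_,
                                             rate_subset = gof_rates[["optimizing"]],
                                             rate_all = gof_rate_all,
                                             fisher_p = NA_real_))
  } else {
    enr <- list(fold = NA_real_,
                rate_subset = if (n_opt > 0) gof_rates[["optimizing"]] else NA_real_,
                rate_all = gof_rate_all, fisher_p = NA_real_)
  }

  structure(list(pattern = pattern_name,
                 thresholds = th,
                 alpha = alpha,
                 mwu_variable = mwu_variable,
                 n_analysed = nrow(variants),
                 group_counts = group_counts,
                 group_stats = group_stats,
                 comparisons = comparisons,
                 gof_rates = as.list(gof_rates),
                 gof_rate_all = gof_rate_all,
                 fold_enrichment = enr,
                 variants = variants),
            class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf("Enrichment report (%s pattern, opt fold >= %.3g, alpha = %g)\n",
              x$pattern, x$thresholds$opt_fold, x$alpha))
  cat(sprintf("  analysed SNVs: %d (optimizing %d / in-site-no-change %d / all-other %d)\n",
              x$n_analysed, x$group_counts$optimizing,
              x$group_counts$in_site_no_change, x$group_counts$all_other))
  p1 <- x$comparisons$optimizing_vs_other$p_one_tailed
  p2 <- x$comparisons$in_site_no_change_vs_other$p_one_tailed
  cat(sprintf("  MWU optimizing vs other:      p = %s\n", format(p1, digits = 4)))
  cat(sprintf("  MWU no-change vs other:       p = %s\n", format(p2, digits = 4)))
  cat(sprintf("  GOF rate: optimizing %.3g vs all %.3g (fold %.3g, Fisher p %s)\n",
              x$fold_enrichment$rate_subset, x$fold_enrichment$rate_all,
              x$fold_enrichment$fold, format(x$fold_enrichment$fisher_p, digits = 4)))
  invisible(x)
}

# Validate/normalise an association table and drop non-SNV rows.
prepare_association_rows <- function(associations, required) {
  missing <- setdiff(required, names(associations))
  if (length(missing) > 0) {
    stop(sprintf("association table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  associations$ref <- toupper(associations$ref)
  associations$alt <- toupper(associations$alt)
  snv <- grepl("^[ACGT]$", associations$ref) & grepl("^[ACGT]$", associations$alt) &
    associations$ref != associations$alt
  if (any(!snv)) {
    message(sprintf("dropped %d non-SNV association row(s)", sum(!snv)))
    associations <- associations[snv, , drop = FALSE]
  }
  if (nrow(associations) == 0) stop("no SNV rows to analyse", call. = FALSE)
  associations
}

classify_across_sequences <- function(sequences, associations, pattern, table, th) {
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  unknown <- setdiff(unique(associations$sequence_id), names(sequences))
  if (length(unknown) > 0) {
    stop(sprintf("association rows name unknown sequence(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  parts <- lapply(split(associations, associations$sequence_id), function(chunk) {
    classify_variants(sequences[[chunk$sequence_id[1]]], chunk, pattern, table, th)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' MPRA enrichment of gain-of-function expression in affinity-optimizing SNVs
#'
#' Classifies every SNV in an MPRA variant-effect table against a motif
#' pattern and PBM table, adjusts p-values (Benjamini-Hochberg, unless the
#' table already carries a `p_adj` column, which is then used as-is), derives
#' expression direction from the sign of the effect, and compares the
#' direction-signed -log10(p_adj) metric across the three analysis groups
#' with one-tailed Mann-Whitney U tests. GOF rates per group and the fold
#' enrichment of the optimizing GOF rate over the overall GOF rate (with
#' Fisher's exact p) complete the report.
#'
#' @param sequences Named character vector (or `DNAStringSet`) of enhancer
#'   sequences.
#' @param associations data.frame with columns `sequence_id`, `pos`
#'   (1-based), `ref`, `alt`, `effect` (signed expression change) and `p`
#'   (raw p) or `p_adj` (already-adjusted p).
#' @param pattern A [motif_pattern()].
#' @param table A [pbm_table()].
#' @param th [class_thresholds()]; defaults to the pattern family's rule.
#' @param alpha GOF significance level (strict; default 0.05).
#' @param exclude_overlapping_sites If TRUE, SNVs lying in two or more
#'   overlapping sites (scanned with `site_patterns`) are excluded first —
#'   the rule used for compact enhanceosome-style enhancers. Off by default.
#' @param site_patterns List of patterns used for the overlap exclusion scan
#'   (defaults to `list(pattern)`).
#' @param mwu_variable Metric compared between groups: `"signed_logp"`
#'   (default) or the raw `"effect"`.
#' @return An `enrichment_report`; `$variants` holds the annotated rows.
#' @export
run_mpra_enrichment <- function(sequences, associations, pattern, table,
                                th = default_thresholds(pattern$name),
                                alpha = 0.05,
                                exclude_overlapping_sites = FALSE,
                                site_patterns = list(pattern),
                                mwu_variable = c("signed_logp", "effect")) {
  mwu_variable <- match.arg(mwu_variable)
  has_padj <- "p_adj" %in% names(associations)
  req <- c("sequence_id", "pos", "ref", "alt", "effect", if (has_padj) "p_adj" else "p")
  associations <- prepare_association_rows(associations, req)

  if (exclude_overlapping_sites) {
    if (methods::is(sequences, "DNAStringSet")) {
      sequences <- stats::setNames(as.character(sequences), names(sequences))
    }
    sites <- do.call(rbind, lapply(names(sequences), function(id) {
      do.call(rbind, lapply(site_patterns, function(p) {
        s <- scan_sequence(sequences[[id]], p, table, sequence_id = id)
        s$pattern <- rep(p$name, nrow(s))
        s
      }))
    }))
    parts <- lapply(split(associations, associations$sequence_id), function(chunk) {
      exclude_overlapping_site_snvs(
        chunk, sites[sites$sequence_id == chunk$sequence_id[1], , drop = FALSE])$kept
    })
    associations <- do.call(rbind, parts)
    rownames(associations) <- NULL
    if (nrow(associations) == 0) stop("all SNVs excluded by the overlap rule", call. = FALSE)
  }

  variants <- classify_across_sequences(sequences, associations, pattern, table, th)
  if (has_padj) {
    message("using the adjusted-p column provided by the study")
  } else {
    message("no adjusted-p column found; applying Benjamini-Hochberg to raw p")
    variants$p_adj <- bh_adjust(variants$p)
  }
  variants$direction <- ifelse(variants$effect > 0, "up",
                               ifelse(variants$effect < 0, "down", "none"))
  variants$signed_logp <- signed_logp(variants$p_adj, variants$direction)
  enrichment_core(variants, pattern$name, th, alpha, mwu_variable)
}

#' Keep each variant's most significant gene association
#'
#' For eQTL variants associated with several genes, retains the record with
#' the smallest adjusted p; ties break by smallest raw p, then lexicographic
#' gene label.
#'
#' @param records data.frame with columns `variant_key`, `gene`, `p_adj` and
#'   optionally `p` (raw).
#' @return One row per variant, input order of first appearance preserved.
#' @export
select_top_association <- function(records) {
  stopifnot(all(c("variant_key", "gene", "p_adj") %in% names(records)))
  p_raw <- if ("p" %in% names(records)) records$p else records$p_adj
  ord <- order(match(records$variant_key, unique(records$variant_key)),
               records$p_adj, p_raw, records$gene)
  sorted <- records[ord, , drop = FALSE]
  dup <- duplicated(sorted$variant_key)
  if (any(dup)) {
    message(sprintf("select_top_association: reduced %d multi-gene row(s)", sum(dup)))
  }
  out <- sorted[!dup, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' eQTL enrichment of positive-beta associations in affinity-optimizing SNVs
#'
#' As [run_mpra_enrichment()] but for eQTL association tables: p-values are
#' Bonferroni-adjusted with the full family size `m_tests` (all
#' genotype-gene associations tested), the most significant gene is kept per
#' variant, direction comes from the sign of beta, and an extra stratified
#' report tests progressively higher fold-change cutoffs for the optimizing
#' group.
#'
#' @inheritParams run_mpra_enrichment
#' @param eqtl data.frame with columns `sequence_id`, `pos`, `ref`, `alt`,
#'   `gene`, `beta`, `p`.
#' @param m_tests Total number of association tests for the Bonferroni
#'   family.
#' @param fold_cutoffs Increasing fold-change cutoffs for the stratified
#'   comparisons (default 1.25, 1.5, 2).
#' @return An `enrichment_report` with an additional `$stratified`
#'   data.frame (`cutoff`, `n_group`, `U`, `p_one_tailed`).
#' @export
run_eqtl_enrichment <- function(sequences, eqtl, pattern, table,
                                th = default_thresholds(pattern$name),
                                m_tests, alpha = 0.05,
                                fold_cutoffs = c(1.25, 1.5, 2),
                                mwu_variable = c("signed_logp", "effect")) {
  mwu_variable <- match.arg(mwu_variable)
  eqtl <- prepare_association_rows(eqtl, c("sequence_id", "pos", "ref", "alt",
                                           "gene", "beta", "p"))
  eqtl$p_adj <- bonferroni_adjust(eqtl$p, m_tests)
  eqtl$variant_key <- variant_key(eqtl)
  eqtl <- select_top_association(eqtl)

  variants <- classify_across_sequences(sequences, eqtl, pattern, table, th)
  variants$effect <- variants$beta
  variants$direction <- ifelse(variants$beta > 0, "up",
                               ifelse(variants$beta < 0, "down", "none"))
  variants$signed_logp <- signed_logp(variants$p_adj, variants$direction)
  report <- enrichment_core(variants, pattern$name, th, alpha, mwu_variable)

  metric <- switch(mwu_variable, signed_logp = variants$signed_logp,
                   effect = variants$effect)
  strat <- lapply(sort(fold_cutoffs), function(cutoff) {
    in_grp <- !is.na(variants$best_fold) & variants$best_fold >= cutoff
    if (sum(in_grp) == 0 || sum(!in_grp) == 0) {
      return(data.frame(cutoff = cutoff, n_group = sum(in_grp),
                        U = NA_real_, p_one_tailed = NA_real_))
    }
    m <- mwu_one_tailed(metric[in_grp], metric[!in_grp])
    data.frame(cutoff = cutoff, n_group = sum(in_grp),
               U = m$U, p_one_tailed = m$p_one_tailed)
  })
  report$stratified <- do.call(rbind, strat)
  report
}
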