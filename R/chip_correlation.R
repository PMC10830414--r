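# PBM affinity versus ChIP signal: average per-base signal over motif
# windows, bin sites by relative affinity (0-0.1, 0.1-0.2, ..., 0.9-1.0),
# average the window means per (bin, chromosome), and Spearman-correlate bin
# midpoint with mean signal over all points.

AFFINITY_BIN_BREAKS <- seq(0, 1, by = 0.1)

# Half-open [lo, hi) bins with the final bin closed at 1.0.
affinity_bin_index <- function(affinity) {
  if (any(affinity < 0 | affinity > 1)) stop("affinity outside [0, 1]", call. = FALSE)
  pmin(floor(affinity * 10), 9L) + 1L
}

#' Build a per-base signal track from bedGraph data
#'
#' @param x Path to a bedGraph text file, or a `GRanges` with a `score`
#'   column (bedGraph intervals are assumed non-overlapping).
#' @return A `signal_track` holding per-chromosome value and coverage runs.
#' @export
bedgraph_track <- function(x) {
  gr <- if (is.character(x)) rtracklayer::import(x, format = "bedGraph") else x
  structure(list(values = GenomicRanges::coverage(gr, weight = "score"),
                 covered = GenomicRanges::coverage(gr)),
            class = "signal_track")
}

#' Mean signal over one site window
#'
#' Arithmetic mean of per-base track values over the window. Under the
#' default `"skip"` policy a window with any uncovered base yields `NA` (the
#' site is dropped upstream); `"partial"` averages over the covered bases
#' only.
#'
#' @param track A [bedgraph_track()].
#' @param chrom Chromosome / sequence name.
#' @param start,end 1-based inclusive window bounds.
#' @param policy `"skip"` or `"partial"`.
#' @return Mean signal, or `NA_real_`.
#' @export
mean_window_signal <- function(track, chrom, start, end, policy = c("skip", "partial")) {
  policy <- match.arg(policy)
  stopifnot(inherits(track, "signal_track"))
  if (!chrom %in% names(track$values)) return(NA_real_)
  v <- track$values[[chrom]]
  cv <- track$covered[[chrom]]
  n <- end - start + 1L
  tlen <- length(v)
  in_start <- max(start, 1L)
  in_end <- min(end, tlen)
  if (in_start > in_end) return(NA_real_)
  vals <- as.numeric(S4Vectors::window(v, in_start, in_end))
  cov <- as.integer(S4Vectors::window(cv, in_start, in_end)) > 0
  n_cov <- sum(cov) # bases outside the track length count as uncovered
  if (policy == "skip") {
    if (n_cov < n) return(NA_real_)
    mean(vals)
  } else {
    if (n_cov == 0) return(NA_real_)
    sum(vals[cov]) / n_cov
  }
}

#' Attach window-mean signals to a site table
#'
#' @param sites Site data.frame (needs `sequence_id`, `start`, `end`).
#' @param track A [bedgraph_track()].
#' @inheritParams mean_window_signal
#' @return `sites` with a `signal` column; sites whose window could not be
#'   scored are dropped with a message.
#' @export
site_signal_means <- function(sites, track, policy = c("skip", "partial")) {
  policy <- match.arg(policy)
  sites$signal <- vapply(seq_len(nrow(sites)), function(i) {
    mean_window_signal(track, sites$sequence_id[i], sites$start[i], sites$end[i],
                       policy = policy)
  }, numeric(1))
  n_skip <- sum(is.na(sites$signal))
  if (n_skip > 0) {
    message(sprintf("site_signal_means: skipped %d site(s) with uncovered windows", n_skip))
    sites <- sites[!is.na(sites$signal), , drop = FALSE]
  }
  rownames(sites) <- NULL
  sites
}

#' Per-(affinity bin, chromosome) mean signal
#'
#' @param sites Site data.frame with `sequence_id` (used as the chromosome
#'   label), `affinity` and `signal` columns.
#' @return data.frame with `bin_low`, `bin_high`, `bin_mid`, `chromosome`,
#'   `mean_signal`, `n_sites`; empty (bin, chromosome) groups are omitted.
#' @export
summarize_bins <- function(sites) {
  stopifnot(all(c("sequence_id", "affinity", "signal") %in% names(sites)))
  if (nrow(sites) == 0) {
    return(data.frame(bin_low = numeric(), bin_high = numeric(), bin_mid = numeric(),
                      chromosome = character(), mean_signal = numeric(),
                      n_sites = integer(), stringsAsFactors = FALSE))
  }
  bin <- affinity_bin_index(sites$affinity)
  key <- interaction(bin, sites$sequence_id, drop = TRUE)
  agg <- lapply(split(seq_len(nrow(sites)), key), function(idx) {
    data.frame(bin_low = AFFINITY_BIN_BREAKS[bin[idx[1]]],
               bin_high = AFFINITY_BIN_BREAKS[bin[idx[1]] + 1L],
               bin_mid = AFFINITY_BIN_BREAKS[bin[idx[1]]] + 0.05,
               chromosome = sites$sequence_id[idx[1]],
               mean_signal = mean(sites$signal[idx]),
               n_sites = length(idx),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$bin_low, out$chromosome), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Spearman correlation of affinity bin against mean signal
#'
#' Rank correlation (average ranks on ties) between bin midpoint and
#' per-(bin, chromosome) mean signal, over all points.
#'
#' @param summaries Output of [summarize_bins()]; at least 3 rows.
#' @return The Spearman rho; `NA` with a warning when the signal is constant.
#' @export
spearman_over_bins <- function(summaries) {
  if (nrow(summaries) < 3) stop("need at least 3 (bin, chromosome) points", call. = FALSE)
  if (stats::sd(summaries$mean_signal) == 0) {
    warning("mean signal is constant across all points; rho undefined")
    return(NA_real_)
  }
  stats::cor(summaries$bin_mid, summaries$mean_signal, method = "spearman")
}

#' Full affinity-vs-ChIP correlation stage
#'
#' @param sites Site data.frame with affinities (e.g. from
#'   [scan_sequence()] per chromosome).
#' @param track A [bedgraph_track()].
#' @inheritParams mean_window_signal
#' @return list with `sites` (scored), `summaries`, `rho`, `n_points`.
#' @export
chip_affinity_correlation <- function(sites, track, policy = c("skip", "partial")) {
  policy <- match.arg(policy)
  scored <- site_signal_means(sites, track, policy = policy)
  summaries <- summarize_bins(scored)
  rho <- spearman_over_bins(summaries)
  list(sites = scored, summaries = summaries, rho = rho, n_points = nrow(summaries))
}
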