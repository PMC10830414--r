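# Synthetic-data generator: every input class the pipeline consumes, with
# known ground truth, at desk scale.
#
# The PBM table is built from a per-mismatch multiplicative decay against a
# consensus 8-mer (minimised over strand), which guarantees a
# strand-symmetric table with a unique optimum and a tunable low-affinity
# tail — mirroring real enhancers whose functional sites sit at roughly
# 0.12-0.39 of the optimal sequence. Enhancers carry planted motif windows
# of requested affinities on a rejection-cleaned background; MPRA/eQTL
# tables simulate a replicate measurement model so that p-values arise from
# an explicit test rather than being drawn directly.

#' Configuration for the synthetic-data generator
#'
#' @param seed Integer seed; fixing it makes every generated artifact
#'   byte-identical across runs.
#' @param consensus_kmer The optimal 8-mer of the synthetic transcription
#'   factor (must match `NNGGAWNN` when used with the ETS pattern so planted
#'   sites are scannable).
#' @param affinity_decay Per-mismatch multiplicative factor in (0, 1); a
#'   scalar, or a length-8 vector for position-specific decays (gives a
#'   graded SNV fold spectrum).
#' @param enhancer_length Enhancer length in bases.
#' @param planted_sites data.frame with `offset` (1-based start), `strand`,
#'   `target_affinity`; sites must fit without overlapping. Defaults to six
#'   non-overlapping sites with targets spanning the suboptimal 0.15-0.39
#'   range.
#' @param n_snvs Number of SNVs for the association tables; `NULL` means the
#'   full saturation set (3 per base).
#' @param gof_fraction Probability that an affinity-optimizing SNV carries
#'   the planted expression effect.
#' @param effect_size Planted shift in units of the standard deviation of
#'   the per-SNV observed effect (biological + replicate-mean noise).
#' @param noise_sd SD of the per-SNV baseline biological effect.
#' @param rep_noise_sd SD of per-replicate measurement noise.
#' @param n_replicates Replicates averaged per SNV for the z-test.
#' @param m_tests Bonferroni family size for eQTL tables; `NULL` means the
#'   number of association rows.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             consensus_kmer = "CCGGAAGT",
                             affinity_decay = 0.55,
                             enhancer_length = 360L,
                             planted_sites = NULL,
                             n_snvs = NULL,
                             gof_fraction = 1,
                             effect_size = 1,
                             noise_sd = 1,
                             rep_noise_sd = 1,
                             n_replicates = 3L,
                             m_tests = NULL) {
  assert_kmer(consensus_kmer, what = "consensus_kmer")
  if (!length(affinity_decay) %in% c(1L, 8L) ||
      any(affinity_decay <= 0 | affinity_decay >= 1)) {
    stop("affinity_decay must be a scalar or length-8 vector in (0, 1)", call. = FALSE)
  }
  if (is.null(planted_sites)) {
    planted_sites <- data.frame(
      offset = c(30L, 80L, 130L, 190L, 250L, 310L),
      strand = c("+", "+", "-", "+", "-", "+"),
      target_affinity = c(0.15, 0.17, 0.20, 0.25, 0.30, 0.39),
      stringsAsFactors = FALSE)
  }
  if (nrow(planted_sites) > 0) {
    if (any(planted_sites$offset < 1 |
            planted_sites$offset + 7L > enhancer_length)) {
      stop("planted sites do not fit inside the enhancer", call. = FALSE)
    }
    ord <- order(planted_sites$offset)
    o <- planted_sites$offset[ord]
    if (any(diff(o) < 8L)) stop("planted sites overlap", call. = FALSE)
  }
  bad_frac <- c(gof_fraction) < 0 | c(gof_fraction) > 1
  if (any(bad_frac)) stop("gof_fraction must be in [0, 1]", call. = FALSE)
  structure(list(seed = as.integer(seed), consensus_kmer = toupper(consensus_kmer),
                 affinity_decay = affinity_decay,
                 enhancer_length = as.integer(enhancer_length),
                 planted_sites = planted_sites, n_snvs = n_snvs,
                 gof_fraction = gof_fraction, effect_size = effect_size,
                 noise_sd = noise_sd, rep_noise_sd = rep_noise_sd,
                 n_replicates = as.integer(n_replicates), m_tests = m_tests),
            class = "generator_config")
}

all_kmers_grid <- function() {
  g <- expand.grid(rep(list(DNA_BASES), 8), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  names(g) <- paste0("p", 1:8)
  g
}

# Decay score of every 8-mer against one orientation of the consensus.
decay_scores <- function(grid, consensus, decay) {
  cons <- strsplit(consensus, "", fixed = TRUE)[[1]]
  if (length(decay) == 1) decay <- rep(decay, 8)
  s <- rep(1, nrow(grid))
  for (j in 1:8) s <- s * ifelse(grid[[j]] == cons[j], 1, decay[j])
  s
}

#' Generate a strand-symmetric PBM table by Hamming decay
#'
#' Every 8-mer's affinity is `prod(decay[j])` over its mismatches to the
#' consensus, maximised over the two orientations, so the consensus scores
#' exactly 1 and affinity falls off geometrically with distance. Optionally
#' writes the table as a UniProbe-dialect file (forward 8-mer, reverse
#' complement, E-score stand-in, median intensity, Z-score stand-in; one row
#' per 8-mer/reverse-complement pair) that round-trips through
#' [read_uniprobe_table()].
#'
#' @param cfg A [generator_config()].
#' @param file Optional path for the UniProbe-dialect file.
#' @return A [pbm_table()] covering all 65,536 8-mers.
#' @export
gen_pbm_table <- function(cfg = generator_config(), file = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  grid <- all_kmers_grid()
  kmers <- do.call(paste0, grid)
  fwd <- decay_scores(grid, cfg$consensus_kmer, cfg$affinity_decay)
  # score of revcomp(kmer) against the consensus == score of kmer against a
  # "mirrored" consensus: complement of reversed consensus, reversed decays.
  rc_cons <- revcomp(cfg$consensus_kmer)
  rc_decay <- if (length(cfg$affinity_decay) == 1) cfg$affinity_decay else rev(cfg$affinity_decay)
  rev_ <- decay_scores(grid, rc_cons, rc_decay)
  aff <- pmax(fwd, rev_)
  names(aff) <- kmers
  # the two orientation products multiply identical factors in different
  # orders; a final max over the reverse-complement index makes the table
  # strand symmetric to the last bit
  rc <- revcomp(kmers)
  aff <- pmax(aff, aff[rc])
  names(aff) <- kmers
  tab <- new_pbm_table(aff, tf_name = "synthTF")

  if (!is.null(file)) {
    canonical <- kmers <= rc
    intensity <- aff[canonical] * 50000
    df <- data.frame(kmer = kmers[canonical], rc = rc[canonical],
                     escore = round(aff[canonical] * 0.5 - 0.0001, 6),
                     median = format(intensity, digits = 17),
                     zscore = round((aff[canonical] - mean(aff)) / stats::sd(aff), 6),
                     stringsAsFactors = FALSE)
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = c("8-mer", "8-mer.1", "E-score", "Median", "Z-score"))
  }
  tab
}

# Pick the pattern-matching 8-mer whose table affinity is nearest the
# target; candidates whose reverse complement also matches the pattern are
# avoided when possible so a planted window yields exactly one site.
nearest_affinity_kmer <- function(target, pattern, table) {
  keys <- names(table$affinities)
  cand <- keys[grepl(pattern$regex, keys)]
  if (length(cand) == 0) stop("no 8-mer in the table matches the pattern", call. = FALSE)
  single <- cand[!grepl(pattern$regex, revcomp(cand))]
  if (length(single) > 0) cand <- single
  aff <- relative_affinity(cand, table)
  d <- abs(aff - target)
  pick <- cand[order(d, cand)][1]
  list(kmer = pick, affinity = relative_affinity(pick, table))
}

#' Generate an enhancer with planted motif sites
#'
#' Draws a uniform random background, overwrites the planted windows with
#' pattern-matching 8-mers whose affinities are nearest the requested
#' targets, then iteratively re-randomises background bases that create
#' accidental motif matches until [scan_sequence()] recovers exactly the
#' planted sites.
#'
#' @param cfg A [generator_config()].
#' @param pattern A [motif_pattern()] (planted kmers must be expressible in
#'   it).
#' @param table A [pbm_table()], typically from [gen_pbm_table()].
#' @param fasta Optional path; the enhancer is written as FASTA.
#' @param truth_bed Optional path; planted sites are written as BED6.
#' @return list with `sequence`, `sequence_id` and `truth` (the planted-site
#'   data.frame with achieved kmers/affinities).
#' @export
gen_enhancer <- function(cfg = generator_config(), pattern, table,
                         fasta = NULL, truth_bed = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed, {
    L <- cfg$enhancer_length
    chars <- sample(DNA_BASES, L, replace = TRUE)

    planted <- cfg$planted_sites
    truth <- NULL
    planted_mask <- logical(L)
    if (nrow(planted) > 0) {
      rows <- lapply(seq_len(nrow(planted)), function(i) {
        hit <- nearest_affinity_kmer(planted$target_affinity[i], pattern, table)
        kmer_on_seq <- if (planted$strand[i] == "+") hit$kmer else revcomp(hit$kmer)
        data.frame(offset = planted$offset[i], strand = planted$strand[i],
                   target_affinity = planted$target_affinity[i],
                   kmer = hit$kmer, affinity = hit$affinity,
                   kmer_on_seq = kmer_on_seq, stringsAsFactors = FALSE)
      })
      truth <- do.call(rbind, rows)
      for (i in seq_len(nrow(truth))) {
        idx <- truth$offset[i]:(truth$offset[i] + 7L)
        chars[idx] <- strsplit(truth$kmer_on_seq[i], "", fixed = TRUE)[[1]]
        planted_mask[idx] <- TRUE
      }
    } else {
      truth <- data.frame(offset = integer(), strand = character(),
                          target_affinity = numeric(), kmer = character(),
                          affinity = numeric(), kmer_on_seq = character(),
                          stringsAsFactors = FALSE)
    }

    planted_key <- if (nrow(truth)) paste(truth$offset, truth$strand) else character()
    for (iter in 1:200) {
      seq <- paste(chars, collapse = "")
      sites <- scan_sequence(seq, pattern, table, sequence_id = "synthetic_enhancer")
      extra <- sites[!paste(sites$start, sites$strand) %in% planted_key, , drop = FALSE]
      if (nrow(extra) == 0) break
      redraw <- unique(unlist(lapply(seq_len(nrow(extra)), function(i) {
        extra$start[i]:(extra$start[i] + 7L)
      })))
      redraw <- setdiff(redraw, which(planted_mask))
      if (length(redraw) == 0) {
        stop("accidental motif match made entirely of planted bases; choose other targets",
             call. = FALSE)
      }
      chars[redraw] <- sample(DNA_BASES, length(redraw), replace = TRUE)
    }
    seq <- paste(chars, collapse = "")
    check <- scan_sequence(seq, pattern, table, sequence_id = "synthetic_enhancer")
    if (!setequal(paste(check$start, check$strand), planted_key)) {
      stop("could not clean background of accidental motif matches", call. = FALSE)
    }

    if (!is.null(fasta)) {
      writeLines(c(">synthetic_enhancer", seq), fasta)
    }
    if (!is.null(truth_bed) && nrow(truth) > 0) {
      write_site_bed(data.frame(sequence_id = "synthetic_enhancer",
                                start = truth$offset, end = truth$offset + 7L,
                                strand = truth$strand, kmer = truth$kmer,
                                affinity = truth$affinity,
                                stringsAsFactors = FALSE),
                     truth_bed, name = pattern$name)
    }
    list(sequence = seq, sequence_id = "synthetic_enhancer", truth = truth)
  })
}

#' Replicate measurement model shared by the MPRA and eQTL generators
#'
#' Observed effect = mean over `n_replicates` of `N(mu, rep_noise_sd)`, with
#' `mu` a `N(0, noise_sd)` baseline plus the planted shift for effect
#' carriers (optimizing SNVs drawn with probability `gof_fraction`); p comes
#' from a two-sided z-test of the replicate mean. Exposed so calibration
#' runs can re-simulate effects over a fixed classification. Seeding is the
#' caller's responsibility.
#'
#' @param is_optimizing Logical vector flagging the affinity-optimizing SNVs.
#' @param cfg A [generator_config()].
#' @return list with `effect`, `p`, `carrier` vectors.
#' @export
simulate_expression_effects <- function(is_optimizing, cfg) {
  n <- length(is_optimizing)
  obs_sd <- sqrt(cfg$noise_sd^2 + cfg$rep_noise_sd^2 / cfg$n_replicates)
  carrier <- is_optimizing & stats::runif(n) < cfg$gof_fraction
  mu <- stats::rnorm(n, 0, cfg$noise_sd) +
    ifelse(carrier, cfg$effect_size * obs_sd, 0)
  reps <- matrix(stats::rnorm(n * cfg$n_replicates, mean = rep(mu, cfg$n_replicates),
                              sd = cfg$rep_noise_sd),
                 nrow = n)
  obs <- rowMeans(reps)
  se <- cfg$rep_noise_sd / sqrt(cfg$n_replicates)
  z <- obs / se
  list(effect = obs, p = 2 * stats::pnorm(-abs(z)), carrier = carrier)
}

#' Enumerate the saturation-mutagenesis SNV set of a sequence
#'
#' All 3L single-base substitutions (or a sorted random sample of `n_snvs`
#' of them; sampling uses the current RNG state).
#'
#' @param seq DNA string.
#' @param n_snvs Optional subsample size.
#' @return data.frame with `sequence_id`, `pos`, `ref`, `alt`.
#' @export
saturation_variants <- function(seq, n_snvs = NULL) {
  L <- nchar(seq)
  refs <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- rep(seq_len(L), each = 3)
  ref <- rep(refs, each = 3)
  alt <- unlist(lapply(refs, function(b) setdiff(DNA_BASES, b)), use.names = FALSE)
  v <- data.frame(sequence_id = "synthetic_enhancer", pos = pos, ref = ref, alt = alt,
                  stringsAsFactors = FALSE)
  if (!is.null(n_snvs) && n_snvs < nrow(v)) {
    v <- v[sort(sample(nrow(v), n_snvs)), , drop = FALSE]
    rownames(v) <- NULL
  }
  v
}

#' Generate a saturation-mutagenesis MPRA table with known truth
#'
#' Enumerates all 3L SNVs of the enhancer (or a sample of `n_snvs`),
#' classifies them against the pattern/table to find the affinity-optimizing
#' set, and simulates expression effects: optimizing SNVs carry a planted
#' positive shift with probability `gof_fraction`, all SNVs get baseline
#' biological noise, and p-values come from a z-test of simulated replicate
#' means.
#'
#' @param cfg A [generator_config()].
#' @param enhancer Output of [gen_enhancer()] (or a list with `sequence`).
#' @param table,pattern The PBM table and motif pattern.
#' @param th [class_thresholds()] used for the ground-truth labels.
#' @param file Optional path; the association table is written as TSV.
#' @return list with `associations` (sequence_id, pos, ref, alt, effect, p)
#'   and `truth` (adds label, analysis_group, carrier).
#' @export
gen_mpra_table <- function(cfg = generator_config(), enhancer, table, pattern,
                           th = default_thresholds(pattern$name), file = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed + 1L, {
    variants <- saturation_variants(enhancer$sequence, cfg$n_snvs)
    truth <- classify_variants(enhancer$sequence, variants, pattern, table, th)
    sim <- simulate_expression_effects(truth$label == "affinity_optimizing", cfg)
    assoc <- variants
    assoc$effect <- sim$effect
    assoc$p <- sim$p
    truth$effect <- sim$effect
    truth$p <- sim$p
    truth$carrier <- sim$carrier
    if (!is.null(file)) {
      utils::write.table(assoc, file, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(associations = assoc, truth = truth)
  })
}

#' Generate an eQTL association table with known truth
#'
#' As [gen_mpra_table()] but with the observed effect reported as a signed
#' beta and a gene label per row; a fraction of variants receive a second,
#' independent (null) gene association to exercise most-significant-gene
#' selection.
#'
#' @inheritParams gen_mpra_table
#' @param multi_gene_fraction Fraction of variants given a second gene row.
#' @return list with `associations` (adds `gene`, `beta`), `truth`, and
#'   `m_tests` (the Bonferroni family size: total rows unless configured).
#' @export
gen_eqtl_table <- function(cfg = generator_config(), enhancer, table, pattern,
                           th = default_thresholds(pattern$name),
                           multi_gene_fraction = 0.1, file = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed + 2L, {
    variants <- saturation_variants(enhancer$sequence, cfg$n_snvs)
    truth <- classify_variants(enhancer$sequence, variants, pattern, table, th)
    sim <- simulate_expression_effects(truth$label == "affinity_optimizing", cfg)
    assoc <- variants
    assoc$gene <- sprintf("gene_%04d", seq_len(nrow(assoc)))
    assoc$beta <- sim$effect
    assoc$p <- sim$p
    truth$beta <- sim$effect
    truth$p <- sim$p
    truth$carrier <- sim$carrier

    n_multi <- floor(multi_gene_fraction * nrow(assoc))
    if (n_multi > 0) {
      idx <- sample(nrow(assoc), n_multi)
      extra <- assoc[idx, , drop = FALSE]
      extra$gene <- paste0(extra$gene, "b")
      extra$beta <- stats::rnorm(n_multi, 0, cfg$noise_sd)
      extra$p <- stats::runif(n_multi)
      assoc <- rbind(assoc, extra)
      rownames(assoc) <- NULL
    }
    m_tests <- cfg$m_tests %||% nrow(assoc)
    if (!is.null(file)) {
      utils::write.table(assoc, file, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(associations = assoc, truth = truth, m_tests = m_tests)
  })
}

#' Generate a per-base signal track monotonically linked to site affinity
#'
#' Per-base signal over each site window is `link(affinity)` plus Gaussian
#' noise; bases outside sites get the background baseline. Emitted in
#' bedGraph form (0-based half-open intervals, one row per base).
#'
#' @param cfg A [generator_config()] (its seed drives the noise).
#' @param sites Site data.frame with `sequence_id`, `start`, `end`,
#'   `affinity`.
#' @param noise_sd SD of the per-base Gaussian noise.
#' @param link Monotone increasing link function (default identity).
#' @param baseline Background signal level.
#' @param file Optional bedGraph output path.
#' @return data.frame in bedGraph column order (`chrom`, `start` 0-based,
#'   `end`, `value`).
#' @export
gen_signal_track <- function(cfg = generator_config(), sites, noise_sd = 0.05,
                             link = identity, baseline = 0, file = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed + 3L, {
    rows <- lapply(seq_len(nrow(sites)), function(i) {
      width <- sites$end[i] - sites$start[i] + 1L
      value <- link(sites$affinity[i]) + baseline +
        stats::rnorm(width, 0, noise_sd)
      data.frame(chrom = sites$sequence_id[i],
                 start = sites$start[i] - 1L + 0:(width - 1L),
                 end = sites$start[i] + 0:(width - 1L),
                 value = value, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (!is.null(file)) {
      utils::write.table(format(out, scientific = FALSE, trim = TRUE), file,
                         sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
    out
  })
}

#' Generate synthetic motif sites across chromosomes
#'
#' Convenience companion to [gen_signal_track()]: `n_sites` windows with
#' affinities drawn uniformly on (0, 1\], spread evenly over `n_chrom`
#' chromosome labels at non-overlapping positions.
#'
#' @param cfg A [generator_config()].
#' @param n_sites Total number of sites.
#' @param n_chrom Number of chromosome labels.
#' @return Site data.frame (`sequence_id`, `start`, `end`, `strand`,
#'   `affinity`).
#' @export
gen_chip_sites <- function(cfg = generator_config(), n_sites = 500, n_chrom = 4) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed + 4L, {
    chrom <- rep(paste0("chr", seq_len(n_chrom)), length.out = n_sites)
    per <- as.integer(table(factor(chrom, levels = unique(chrom))))
    start <- unlist(lapply(per, function(k) 1L + 20L * (seq_len(k) - 1L)))
    data.frame(sequence_id = chrom[order(chrom)], start = start,
               end = start + 7L, strand = "+",
               affinity = stats::runif(n_sites),
               stringsAsFactors = FALSE)
  })
}
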