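test_that("apply_snv edits one base and guards the reference", {
  expect_identical(apply_snv("ACGT", 2, "C", "G"), "AGGT")
  # involution: applying then reverting restores the original
  s <- apply_snv("ACGTACGT", 5, "A", "T")
  expect_identical(apply_snv(s, 5, "T", "A"), "ACGTACGT")
  expect_error(apply_snv("ACGT", 2, "A", "G"), "reference mismatch")
  expect_error(apply_snv("ACGT", 2, "C", "C"), "distinct")
  expect_error(apply_snv("ACGT", 9, "C", "G"), "outside")
})

test_that("per-window effects agree with brute-force window enumeration", {
  tab <- pbm_fixture()
  ets <- ets_fixture()
  # SNV at a degenerate (N) position between two overlapping GGAW cores
  seq <- "CCAAGGAATGGAAATC"
  pos <- 4; ref <- substring(seq, pos, pos); alt <- "T"
  eff <- variant_window_effects(seq, pos, ref, alt, ets, tab)

  # independent oracle: enumerate the 8 covering windows on both strands
  alt_seq <- apply_snv(seq, pos, ref, alt)
  oracle <- list()
  for (st in max(1, pos - 7):min(pos, nchar(seq) - 7)) {
    rw <- substring(seq, st, st + 7); aw <- substring(alt_seq, st, st + 7)
    for (strand in c("+", "-")) {
      rk <- if (strand == "+") rw else revcomp(rw)
      ak <- if (strand == "+") aw else revcomp(aw)
      rm <- matches_pattern(rk, ets); am <- matches_pattern(ak, ets)
      if (rm || am) {
        oracle[[length(oracle) + 1]] <- data.frame(
          start = st, strand = strand, ref_match = rm, alt_match = am,
          fold = if (rm && am) relative_affinity(ak, tab) / relative_affinity(rk, tab)
                 else NA_real_)
      }
    }
  }
  oracle <- do.call(rbind, oracle)
  oracle <- oracle[order(oracle$start, match(oracle$strand, c("+", "-"))), ]
  expect_identical(eff$windows$start, oracle$start)
  expect_identical(eff$windows$strand, oracle$strand)
  expect_equal(eff$windows$fold, oracle$fold, tolerance = 1e-12)
  expect_equal(eff$best_fold, max(oracle$fold, na.rm = TRUE), tolerance = 1e-12)
})

test_that("SNVs in motif-free context report no windows", {
  tab <- pbm_fixture()
  eff <- variant_window_effects(strrep("C", 30), 15, "C", "A", ets_fixture(), tab)
  expect_identical(nrow(eff$windows), 0L)
  eff <- classify_snv(eff)
  expect_identical(eff$label, "not_in_site")
  expect_identical(eff$analysis_group, "all_other")
})

test_that("classification precedence follows the fold-change rules", {
  th <- class_thresholds(opt_fold = 1.59, neutral_band = c(0.8, 1.25))
  fake <- function(folds, alt_only = FALSE, ref_only = FALSE) {
    n <- length(folds) + alt_only + ref_only
    win <- data.frame(
      variant = rep(1L, n), start = seq_len(n), strand = "+",
      ref_kmer = "x", alt_kmer = "x",
      ref_match = c(rep(TRUE, length(folds)), !alt_only, ref_only)[seq_len(n)],
      alt_match = c(rep(TRUE, length(folds)), alt_only, !ref_only)[seq_len(n)],
      ref_affinity = 1, alt_affinity = 1, fold = c(folds, rep(NA_real_, n - length(folds))))
    structure(list(variant = list(), pattern_name = "ETS", windows = win,
                   best_fold = suppressWarnings(max(folds)), label = NA_character_),
              class = "variant_effect")
  }
  lab <- function(e) classify_snv(e, th)$label
  expect_identical(lab(fake(c(1.0, 1.6))), "affinity_optimizing")   # any window suffices
  expect_identical(lab(fake(1.59)), "affinity_optimizing")          # threshold inclusive
  expect_identical(lab(fake(1.0)), "affinity_neutral_in_site")
  expect_identical(lab(fake(c(0.8, 1.25))), "affinity_neutral_in_site")  # band inclusive
  expect_identical(lab(fake(0.5)), "affinity_decreasing")
  expect_identical(lab(fake(c(1.4, 0.5))), "affinity_decreasing")
  expect_identical(lab(fake(1.4)), "affinity_subthreshold")
  expect_identical(lab(fake(numeric(0), alt_only = TRUE)), "de_novo_site")
  expect_identical(lab(fake(numeric(0), ref_only = TRUE)), "site_ablating")
})

test_that("the 1.6-fold worked case and the relaxed >1.0 rule classify correctly", {
  # a dual-match window at fold 1.6 crosses the 1.59 ETS rule
  tab <- pbm_table(c("AAGGAAAT", "AAGGAAGT"), c(15, 24))
  seq <- paste0("CC", "AAGGAAAT", "CC")
  eff <- classify_snv(variant_window_effects(seq, 9, "A", "G", ets_fixture(), tab))
  expect_equal(eff$best_fold, 1.6, tolerance = 1e-12)
  expect_identical(eff$label, "affinity_optimizing")

  # sparse-mutagenesis configuration: any fold above 1.0 optimizes
  relaxed <- class_thresholds(opt_fold = 1.01, neutral_band = c(0.99, 1.005))
  tab2 <- pbm_table(c("AAGGAAAT", "AAGGAAGT"), c(20, 24))
  eff2 <- classify_snv(variant_window_effects(seq, 9, "A", "G", ets_fixture(), tab2),
                       relaxed)
  expect_identical(eff2$label, "affinity_optimizing")
})

test_that("swapping ref and alt inverts every dual-match fold", {
  tab <- pbm_fixture()
  ets <- ets_fixture()
  enh <- enhancer_fixture()
  variants <- data.frame(pos = c(30:37, 190:197))
  variants$ref <- substring(enh$sequence, variants$pos, variants$pos)
  alts <- c("A", "C", "G", "T")
  variants$alt <- vapply(variants$ref, function(r) setdiff(alts, r)[1], "")
  for (i in seq_len(nrow(variants))) {
    fwd <- variant_window_effects(enh$sequence, variants$pos[i], variants$ref[i],
                                  variants$alt[i], ets, tab)
    alt_seq <- apply_snv(enh$sequence, variants$pos[i], variants$ref[i], variants$alt[i])
    bwd <- variant_window_effects(alt_seq, variants$pos[i], variants$alt[i],
                                  variants$ref[i], ets, tab)
    f1 <- fwd$windows$fold[!is.na(fwd$windows$fold)]
    f2 <- bwd$windows$fold[!is.na(bwd$windows$fold)]
    expect_equal(sort(f1), sort(1 / f2), tolerance = 1e-12)
  }
})

test_that("classification is invariant under reverse complementing the sequence", {
  tab <- pbm_fixture()
  ets <- ets_fixture()
  enh <- enhancer_fixture()
  L <- nchar(enh$sequence)
  rc_seq <- revcomp(enh$sequence)
  pos <- c(30:37, 130:137, 250:257)
  ref <- substring(enh$sequence, pos, pos)
  alt <- vapply(ref, function(r) setdiff(c("A", "C", "G", "T"), r)[1], "")
  for (i in seq_along(pos)) {
    a <- classify_snv(variant_window_effects(enh$sequence, pos[i], ref[i], alt[i],
                                             ets, tab))
    b <- classify_snv(variant_window_effects(rc_seq, L - pos[i] + 1,
                                             chartr("ACGT", "TGCA", ref[i]),
                                             chartr("ACGT", "TGCA", alt[i]), ets, tab))
    expect_identical(a$label, b$label)
    expect_equal(a$best_fold, b$best_fold, tolerance = 1e-12)
  }
})

test_that("every SNV on a motif-free sequence is not_in_site", {
  tab <- pbm_fixture()
  seq <- strrep("C", 40)
  variants <- data.frame(sequence_id = "s", pos = rep(1:40, each = 3),
                         ref = "C", alt = c("A", "G", "T"))
  cls <- classify_variants(seq, variants, ets_fixture(), tab)
  # a single substitution in poly-C cannot assemble a GGAW core on either strand
  expect_true(all(cls$label == "not_in_site"))
  expect_true(all(cls$analysis_group == "all_other"))
})

test_that("batch classification agrees with the single-variant path", {
  tab <- pbm_fixture()
  ets <- ets_fixture()
  enh <- enhancer_fixture()
  variants <- data.frame(sequence_id = "e", pos = c(10, 31, 33, 132, 193, 251, 340))
  variants$ref <- substring(enh$sequence, variants$pos, variants$pos)
  variants$alt <- vapply(variants$ref, function(r) setdiff(c("A", "C", "G", "T"), r)[2], "")
  batch <- classify_variants(enh$sequence, variants, ets, tab)
  for (i in seq_len(nrow(variants))) {
    single <- classify_snv(variant_window_effects(
      enh$sequence, variants$pos[i], variants$ref[i], variants$alt[i], ets, tab))
    expect_identical(batch$label[i], single$label)
    expect_equal(batch$best_fold[i], single$best_fold, tolerance = 1e-12)
  }
})

test_that("overlap exclusion drops SNVs covered by two or more sites", {
  sites <- data.frame(start = c(10L, 14L, 40L), end = c(17L, 21L, 47L),
                      strand = c("+", "+", "-"))
  variants <- data.frame(pos = c(5L, 12L, 15L, 20L, 42L))  # 15, 20 sit in overlap? 15..17 both
  res <- suppressMessages(exclude_overlapping_site_snvs(variants, sites))
  expect_identical(res$kept$pos, c(5L, 12L, 20L, 42L))
  expect_identical(res$excluded$pos, 15L)
  expect_identical(res$n_excluded, 1L)
})
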