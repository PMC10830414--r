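mpra_fixture <- function(seed = 11, ...) {
  cfg <- generator_config(seed = seed, ...)
  tab <- pbm_fixture()
  enh <- gen_enhancer(cfg, ets_fixture(), tab)
  mp <- gen_mpra_table(cfg, enh, tab, ets_fixture())
  list(cfg = cfg, tab = tab, enh = enh, mp = mp,
       seqs = stats::setNames(enh$sequence, enh$sequence_id))
}

test_that("MPRA pipeline detects a planted optimizing effect and not a neutral one", {
  fx <- mpra_fixture(seed = 11, effect_size = 1.5)
  rep <- suppressMessages(run_mpra_enrichment(fx$seqs, fx$mp$associations,
                                              ets_fixture(), fx$tab))
  expect_lt(rep$comparisons$optimizing_vs_other$p_one_tailed, 0.01)
  expect_gt(rep$comparisons$in_site_no_change_vs_other$p_one_tailed, 0.05)
  expect_gt(rep$fold_enrichment$fold, 1)
})

test_that("the three analysis groups partition the analysed SNVs", {
  fx <- mpra_fixture(seed = 12)
  rep <- suppressMessages(run_mpra_enrichment(fx$seqs, fx$mp$associations,
                                              ets_fixture(), fx$tab))
  counts <- unlist(rep$group_counts)
  expect_identical(sum(counts), rep$n_analysed)
  expect_identical(rep$n_analysed, nrow(fx$mp$associations))
  expect_setequal(unique(rep$variants$analysis_group),
                  c("optimizing", "in_site_no_change", "all_other"))
})

test_that("shuffling association rows changes no reported number", {
  fx <- mpra_fixture(seed = 13)
  rep1 <- suppressMessages(run_mpra_enrichment(fx$seqs, fx$mp$associations,
                                               ets_fixture(), fx$tab))
  set.seed(1)
  shuffled <- fx$mp$associations[sample(nrow(fx$mp$associations)), ]
  rep2 <- suppressMessages(run_mpra_enrichment(fx$seqs, shuffled,
                                               ets_fixture(), fx$tab))
  expect_identical(rep1$group_counts, rep2$group_counts)
  expect_identical(rep1$comparisons$optimizing_vs_other$p_one_tailed,
                   rep2$comparisons$optimizing_vs_other$p_one_tailed)
  expect_identical(rep1$fold_enrichment, rep2$fold_enrichment)
  expect_identical(rep1$gof_rates, rep2$gof_rates)
})

test_that("a provided adjusted-p column is used as-is; otherwise BH is applied", {
  fx <- mpra_fixture(seed = 14)
  assoc <- fx$mp$associations
  expect_message(run_mpra_enrichment(fx$seqs, assoc, ets_fixture(), fx$tab),
                 "Benjamini-Hochberg")
  assoc$p_adj <- assoc$p  # pretend the study published adjusted values
  assoc$p <- NULL
  expect_message(rep <- run_mpra_enrichment(fx$seqs, assoc, ets_fixture(), fx$tab),
                 "provided by the study")
  expect_identical(rep$variants$p_adj[order(rep$variants$pos, rep$variants$alt)],
                   fx$mp$associations$p[order(fx$mp$associations$pos,
                                              fx$mp$associations$alt)])
})

test_that("zero optimizing SNVs yields a not-applicable comparison, not a crash", {
  tab <- pbm_fixture()
  seq <- strrep("A", 60)  # motif-free
  variants <- data.frame(sequence_id = "s", pos = 10:29, ref = "A", alt = "C",
                         effect = rnorm(20), p = runif(20))
  rep <- suppressMessages(run_mpra_enrichment(
    stats::setNames(seq, "s"), variants, ets_fixture(), tab))
  expect_identical(rep$comparisons$optimizing_vs_other$method, "not_applicable")
  expect_true(is.na(rep$comparisons$optimizing_vs_other$p_one_tailed))
  expect_true(is.na(rep$fold_enrichment$fold))
})

test_that("non-SNV association rows are dropped with a message", {
  fx <- mpra_fixture(seed = 15)
  assoc <- fx$mp$associations[1:10, ]
  assoc$ref[1] <- "AT"  # indel-like
  assoc$alt[2] <- "-"
  msgs <- capture_messages(
    rep <- run_mpra_enrichment(fx$seqs, assoc, ets_fixture(), fx$tab))
  expect_match(paste(msgs, collapse = " "), "2 non-SNV")
  expect_identical(rep$n_analysed, 8L)
})

test_that("most significant gene is kept per variant with deterministic ties", {
  records <- data.frame(
    variant_key = c("v1", "v2", "v2", "v3", "v3", "v3"),
    gene = c("g1", "gA", "gB", "gZ", "gM", "gA"),
    p_adj = c(0.5, 0.01, 0.2, 0.3, 0.3, 0.3),
    p = c(0.5, 0.001, 0.02, 0.03, 0.02, 0.02))
  out <- suppressMessages(select_top_association(records))
  expect_identical(out$variant_key, c("v1", "v2", "v3"))
  expect_identical(out$gene[2], "gA")          # smallest p_adj
  expect_identical(out$gene[3], "gA")          # p_adj tie -> p tie -> gene label
})

test_that("eQTL pipeline applies Bonferroni, keeps top gene, and stratifies", {
  cfg <- generator_config(seed = 21, effect_size = 1.5)
  tab <- pbm_fixture()
  enh <- gen_enhancer(cfg, ets_fixture(), tab)
  eq <- gen_eqtl_table(cfg, enh, tab, ets_fixture())
  seqs <- stats::setNames(enh$sequence, enh$sequence_id)
  rep <- suppressMessages(run_eqtl_enrichment(seqs, eq$associations, ets_fixture(),
                                              tab, m_tests = eq$m_tests))
  # one record per variant after top-association selection
  expect_identical(rep$n_analysed, length(unique(
    paste(eq$associations$pos, eq$associations$ref, eq$associations$alt))))
  expect_lt(rep$comparisons$optimizing_vs_other$p_one_tailed, 0.01)
  # hand-checkable Bonferroni on a toy subset
  toy <- eq$associations[1:10, ]
  expect_equal(bonferroni_adjust(toy$p, 100), pmin(1, toy$p * 100), tolerance = 1e-12)
  # stratified report covers the requested cutoffs in order
  expect_identical(rep$stratified$cutoff, c(1.25, 1.5, 2))
  expect_true(all(is.na(rep$stratified$p_one_tailed) |
                    rep$stratified$p_one_tailed <= 1))
})

test_that("stratified enrichment sharpens with the fold cutoff on graded tables", {
  # per-position decays give a graded fold spectrum so the cutoffs separate
  decays <- c(0.35, 0.45, 0.3, 0.3, 0.3, 0.5, 0.6, 0.7)
  cfg <- generator_config(seed = 22, affinity_decay = decays, effect_size = 2)
  tab <- gen_pbm_table(cfg)
  enh <- gen_enhancer(cfg, ets_fixture(), tab)
  eq <- gen_eqtl_table(cfg, enh, tab, ets_fixture())
  seqs <- stats::setNames(enh$sequence, enh$sequence_id)
  rep <- suppressMessages(run_eqtl_enrichment(seqs, eq$associations, ets_fixture(),
                                              tab, m_tests = eq$m_tests,
                                              fold_cutoffs = c(1.3, 1.59)))
  p <- rep$stratified$p_one_tailed
  expect_true(all(!is.na(p)))
  expect_lt(p[2], 0.05)
})

test_that("all-zero betas produce no GOF records", {
  cfg <- generator_config(seed = 23)
  tab <- pbm_fixture()
  enh <- gen_enhancer(cfg, ets_fixture(), tab)
  eq <- gen_eqtl_table(cfg, enh, tab, ets_fixture())
  assoc <- eq$associations
  assoc$beta <- 0
  seqs <- stats::setNames(enh$sequence, enh$sequence_id)
  rep <- suppressMessages(run_eqtl_enrichment(seqs, assoc, ets_fixture(), tab,
                                              m_tests = eq$m_tests))
  expect_identical(rep$gof_rate_all, 0)
  expect_true(all(rep$variants$direction == "none"))
})

test_that("the overlap-exclusion flag removes multi-site SNVs before analysis", {
  tab <- pbm_fixture()
  # two overlapping ETS windows: AAGGAA TGGAAATC -> sites at 3 and 9 overlap
  seq <- paste0(strrep("A", 2), "GGAATGGAAATT", strrep("A", 30))
  sites <- scan_sequence(seq, ets_fixture(), tab)
  expect_gte(nrow(sites), 2)
  overlap_pos <- sites$start[2]:(sites$end[1])
  variants <- data.frame(sequence_id = "s", pos = c(overlap_pos[1], 40, 41),
                         ref = substring(seq, c(overlap_pos[1], 40, 41),
                                         c(overlap_pos[1], 40, 41)),
                         alt = NA, effect = c(1, -1, 2), p = c(0.01, 0.5, 0.2))
  variants$alt <- vapply(variants$ref,
                         function(r) setdiff(c("A", "C", "G", "T"), r)[1], "")
  rep <- suppressMessages(run_mpra_enrichment(
    stats::setNames(seq, "s"), variants, ets_fixture(), tab,
    exclude_overlapping_sites = TRUE))
  expect_identical(rep$n_analysed, 2L)
})
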