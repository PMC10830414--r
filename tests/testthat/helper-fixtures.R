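# Shared fixtures built in code. The full synthetic PBM table (65,536
# 8-mers) is built once per test file that needs it via pbm_fixture().

.fixture_env <- new.env(parent = emptyenv())

pbm_fixture <- function(seed = 1, ...) {
  key <- paste0("pbm_", seed, "_", paste(unlist(list(...)), collapse = "_"))
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- gen_pbm_table(generator_config(seed = seed, ...))
  }
  .fixture_env[[key]]
}

ets_fixture <- function() {
  if (is.null(.fixture_env$ets)) .fixture_env$ets <- motif_pattern("ETS")
  .fixture_env$ets
}

# A tiny hand-buildable table: 3 intensities 10/20/40 -> 0.25/0.5/1.
tiny_table <- function() {
  pbm_table(c("AAGGAAAT", "CAGGAAGT", "CCGGAAGT"), c(10, 20, 40), tf_name = "tiny")
}

enhancer_fixture <- function(seed = 1) {
  key <- paste0("enh_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- gen_enhancer(generator_config(seed = seed),
                                        ets_fixture(), pbm_fixture())
  }
  .fixture_env[[key]]
}

# Independent oracle: step-up BH computed from the textbook definition.
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  ranked <- p[ord] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[ord] <- adj
  out
}

# Independent oracle: exact one-tailed MWU p by enumerating every assignment
# of the pooled values to group a (requires no ties for a clean null).
mwu_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  u_of <- function(av, bv) sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  u_obs <- u_of(a, b)
  combos <- utils::combn(n, na)
  us <- apply(combos, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  mean(us >= u_obs - 1e-12)
}

# Independent oracle: two-sided Fisher p for a 2x2 table via the
# hypergeometric distribution written out with choose().
fisher_2x2_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(ks, function(k) {
    exp(lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(n, c1))
  }, numeric(1))
  p_obs <- probs[ks == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
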