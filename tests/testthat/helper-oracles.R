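# Independent oracles and fixture builders shared across tests.

# Brute-force peak segmentation: enumerate every contiguous index range,
# keep the maximal all-passing runs of sufficient length, then merge
# qualifying runs by explicit pairwise gap inspection.  Written without rle
# so it shares no code path with probe_runs().
brute_force_runs <- function(positions, pvalues, cutoff, min_probes,
                             merge_gap) {
  n <- length(pvalues)
  pass <- pvalues <= cutoff
  runs <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (all(pass[i:j]) &&
          (i == 1 || !pass[i - 1]) &&
          (j == n || !pass[j + 1]) &&
          (j - i + 1) >= min_probes) {
        runs[[length(runs) + 1]] <- i:j
      }
    }
  }
  if (length(runs) < 2) return(runs)
  merged <- list(runs[[1]])
  for (k in 2:length(runs)) {
    last <- merged[[length(merged)]]
    if (positions[runs[[k]][1]] - positions[last[length(last)]] <= merge_gap)
      merged[[length(merged)]] <- c(last, runs[[k]])
    else merged[[length(merged) + 1]] <- runs[[k]]
  }
  merged
}

# Naive step-1 CpG-class oracle: every window of both strands scored with
# plain vector sums (no cumulative-sum trick), thresholds as in the package.
oracle_classify <- function(seq, window_bp = 500) {
  score_strand <- function(s) {
    L <- length(s)
    w <- min(window_bp, L)
    t(vapply(seq_len(L - w + 1), function(a) {
      win <- s[a:(a + w - 1)]
      ok <- win %in% c("A", "C", "G", "T")
      if (mean(!ok) > 0.1) return(c(NA_real_, NA_real_))
      nc <- sum(win == "C"); ng <- sum(win == "G")
      ncg <- sum(win[-w] == "C" & win[-1] == "G")
      gc <- (nc + ng) / sum(ok)
      oe <- if (nc == 0 || ng == 0) 0 else ncg * sum(ok) / (nc * ng)
      c(gc, oe)
    }, numeric(2)))
  }
  s <- strsplit(toupper(seq), "")[[1]]
  rc <- rev(chartr("ACGTacgt", "TGCAtgca", s))
  m <- rbind(score_strand(s), score_strand(rc))
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (!nrow(m)) return("LCP")
  if (any(m[, 1] > 0.55 & m[, 2] > 0.75)) "HCP"
  else if (!any(m[, 2] > 0.48)) "LCP"
  else "ICP"
}

# Exhaustive hypergeometric upper tail by enumerating every possible draw
# (combn); feasible for small N and n only.
enum_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # members 1..K are "in the set"
  mean(hits >= k)
}

# Independent tail from first-principles counting (no phyper / dhyper).
count_hyper_tail <- function(N, K, n, k) {
  i <- seq(max(k, 0), min(K, n))
  if (!length(i)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Construct a ratio_set directly from a ratio matrix.
mk_ratio_set <- function(ratios, positions, gene_ids, groups,
                         chrom = "chr1") {
  n <- nrow(ratios)
  colnames(ratios) <- sprintf("%s_rep%d", groups,
                              stats::ave(seq_along(groups), groups,
                                         FUN = seq_along))
  probes <- data.frame(
    probe_id = sprintf("P%04d", seq_len(n)), chrom = chrom,
    position = positions, gene_id = gene_ids, stringsAsFactors = FALSE)
  rownames(ratios) <- probes$probe_id
  design <- data.frame(
    array_id = colnames(ratios), group = groups,
    replicate = stats::ave(seq_along(groups), groups, FUN = seq_along),
    stringsAsFactors = FALSE)
  structure(list(probes = probes, ratios = ratios, design = design),
            class = "ratio_set")
}

# A peak-table row with every DEP criterion comfortably satisfied;
# fields overridden per test case.
passing_peak <- function(...) {
  row <- data.frame(
    chrom = "chr1", start = 100L, end = 800L, gene_id = "G1",
    n_probes = 4L, probe_ids = "a,b,c,d", median_control = 0.1,
    median_treated = 0.5, median_mprime = 0.4, cv_pass_frac = 1,
    peak_score = 3.5, peak_p = 0.001, direction = "hyper",
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) row[[nm]] <- over[[nm]]
  row
}

# Small end-to-end simulated experiment.
small_sim <- function(seed = 1, n_promoters = 200, ...) {
  cfg <- sim_config(n_promoters = n_promoters, seed = seed, ...)
  ann <- generate_annotation(cfg)
  sim <- simulate_intensities(cfg, ann)
  list(cfg = cfg, ann = ann, sim = sim,
       rs = build_ratio_set(sim$tables, sim$design))
}

random_dna <- function(n, probs = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}
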