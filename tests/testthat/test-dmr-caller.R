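test_that("probe statistics follow their closed forms", {
  # constant replicates: M' = 1.2 - 0.4, CVs identically 0
  ratios <- cbind(matrix(0.4, 2, 3), matrix(1.2, 2, 3))
  rs <- mk_ratio_set(ratios, positions = c(100L, 200L),
                     gene_ids = "G1",
                     groups = rep(c("control", "treated"), each = 3))
  st <- compute_probe_stats(rs)
  expect_equal(st$mprime, c(0.8, 0.8))
  expect_equal(st$cv_control, c(0, 0))
  expect_equal(st$cv_treated, c(0, 0))

  # treated == control per replicate: M' = 0
  rs2 <- mk_ratio_set(matrix(c(0.1, 0.5, 0.9, 0.1, 0.5, 0.9), 1),
                      positions = 100L, gene_ids = "G1",
                      groups = rep(c("control", "treated"), each = 3))
  expect_equal(compute_probe_stats(rs2)$mprime, 0)

  # hand case: CVs computed on linear-scale ratios
  rs3 <- mk_ratio_set(matrix(c(0, 0.5, 1, 1, 1.5, 2), 1),
                      positions = 100L, gene_ids = "G1",
                      groups = rep(c("control", "treated"), each = 3))
  st3 <- compute_probe_stats(rs3)
  expect_equal(st3$mprime, 1)
  lin_c <- 2^c(0, 0.5, 1)
  lin_t <- 2^c(1, 1.5, 2)
  expect_equal(st3$cv_control, sd(lin_c) / mean(lin_c))
  expect_equal(st3$cv_treated, sd(lin_t) / mean(lin_t))
})

test_that("run segmentation matches brute-force enumeration", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(3:12, 1)
    positions <- sort(sample.int(2000, n))
    pvals <- runif(n)^sample(1:3, 1)  # skew towards small p sometimes
    cutoff <- sample(c(0.05, 0.1, 0.3, 0.6), 1)
    min_probes <- sample(1:3, 1)
    merge_gap <- sample(c(100, 500, 1500), 1)
    got <- probe_runs(positions, pvals, cutoff, min_probes, merge_gap)
    want <- brute_force_runs(positions, pvals, cutoff, min_probes,
                             merge_gap)
    expect_equal(unname(got), unname(want),
                 info = sprintf("fixture %d", rep))
  }
  expect_error(probe_runs(c(5, 1), c(0.01, 0.01)), "sorted")
})

test_that("a flat profile yields no peaks", {
  ratios <- matrix(0.5, 16, 6)
  rs <- mk_ratio_set(ratios, positions = as.integer(1:16 * 200),
                     gene_ids = rep(c("G1", "G2"), each = 8),
                     groups = rep(c("control", "treated"), each = 3))
  expect_equal(nrow(find_peaks(rs)), 0L)
})

test_that("a noiseless central spike is recovered as one exact peak", {
  # 40 null promoters to anchor the experiment-wide reference distribution,
  # plus one promoter whose middle 4 probes carry M' = 1
  x <- small_sim(seed = 6, n_promoters = 41, noise_sd = 0.05,
                 effect_size = 1, frac_dmr = 0)
  rs <- x$rs
  target <- "G00001"
  idx <- which(rs$probes$gene_id == target)
  spike <- idx[3:6]
  treated_cols <- which(rs$design$group == "treated")
  rs$ratios[spike, treated_cols] <- rs$ratios[spike, treated_cols] + 1
  peaks <- find_peaks(rs)
  target_peaks <- peaks[peaks$gene_id == target, ]
  expect_equal(nrow(target_peaks), 1L)
  expect_equal(target_peaks$n_probes, 4L)
  expect_equal(strsplit(target_peaks$probe_ids, ",")[[1]],
               rs$probes$probe_id[spike])
  expect_equal(target_peaks$direction, "hyper")
})

test_that("run merging honours the merge gap", {
  positions <- c(0L, 200L, 400L, 1600L, 1800L)
  pvals <- c(0.01, 0.01, 0.9, 0.01, 0.01)
  # gap between runs = 1600 - 200 = 1400 bp
  two <- probe_runs(positions, pvals, cutoff = 0.1, min_probes = 2,
                    merge_gap = 500)
  expect_length(two, 2)
  one <- probe_runs(positions, pvals, cutoff = 0.1, min_probes = 2,
                    merge_gap = 1400)
  expect_length(one, 1)
  expect_equal(one[[1]], c(1L, 2L, 4L, 5L))  # gap probe 3 excluded
})

test_that("the DEP filter applies each criterion exactly", {
  expect_equal(nrow(filter_deps(passing_peak())), 1L)
  # criterion (i): best group median below / above 0.3
  expect_equal(nrow(filter_deps(passing_peak(median_control = 0.2,
                                             median_treated = 0.2))), 0L)
  expect_equal(nrow(filter_deps(passing_peak(median_control = -0.1,
                                             median_treated = 0.31))), 1L)
  # zero median M' has no direction
  expect_equal(nrow(filter_deps(passing_peak(median_mprime = 0))), 0L)
  # criterion (ii): CV pass fraction
  expect_equal(nrow(filter_deps(passing_peak(cv_pass_frac = 0.25))), 0L)
  expect_equal(nrow(filter_deps(passing_peak(cv_pass_frac = 0.5))), 1L)
  # peak score and p
  expect_equal(nrow(filter_deps(passing_peak(peak_score = 1.9))), 0L)
  expect_equal(nrow(filter_deps(passing_peak(peak_p = 0.02))), 0L)
  # direction reassigned from median M'
  out <- filter_deps(passing_peak(median_mprime = -0.4,
                                  median_control = 0.5,
                                  median_treated = 0.1,
                                  direction = "hyper"))
  expect_equal(out$direction, "hypo")
})

test_that("raising any threshold never increases the number of DMRs", {
  x <- small_sim(seed = 12, n_promoters = 300)
  peaks <- find_peaks(x$rs)
  n_default <- nrow(filter_deps(peaks))
  expect_lte(nrow(filter_deps(peaks, min_median_ratio = 0.5)), n_default)
  expect_lte(nrow(filter_deps(peaks, min_cv_pass = 0.9)), n_default)
  expect_lte(nrow(filter_deps(peaks, min_peak_score = 3)), n_default)
  expect_lte(nrow(filter_deps(peaks, max_peak_p = 0.001)), n_default)
})

test_that("swapping group labels flips directions but not geometry", {
  x <- small_sim(seed = 13, n_promoters = 250)
  fwd <- call_dmrs(x$rs)
  rev <- call_dmrs(x$rs, control = "treated", treated = "control")
  expect_gt(nrow(fwd), 0)
  expect_equal(nrow(fwd), nrow(rev))
  key <- function(d) paste(d$chrom, d$start, d$end)
  expect_setequal(key(fwd), key(rev))
  rev <- rev[match(key(fwd), key(rev)), ]
  expect_equal(rev$median_mprime, -fwd$median_mprime)
  expect_equal(rev$median_control, fwd$median_treated)
  expect_equal(rev$peak_score, fwd$peak_score)
  expect_equal(rev$peak_p, fwd$peak_p)
  expect_true(all(rev$direction != fwd$direction))
})

test_that("DMR tables round-trip through TSV and BED", {
  dmrs <- rbind(passing_peak(), passing_peak(gene_id = "G2", start = 2000L,
                                             end = 2600L,
                                             median_mprime = -0.5,
                                             direction = "hypo"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_dmr_table(dmrs, tsv, bed)
  back <- read_dmr_table(tsv)
  expect_equal(back, dmrs)
  gr <- rtracklayer::import(bed)
  expect_equal(length(gr), 2L)
  expect_equal(GenomicRanges::start(gr), dmrs$start + 1L)
  expect_equal(gr$name, paste(dmrs$gene_id, dmrs$direction, sep = "|"))
  expect_equal(gr$score, pmin(1000, round(100 * dmrs$peak_score)))

  # empty call set: header-only TSV, empty BED
  empty <- dmrs[0, ]
  write_dmr_table(empty, tsv, bed)
  expect_equal(nrow(read_dmr_table(tsv)), 0L)
  expect_equal(file.size(bed), 0)
})
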