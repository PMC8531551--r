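test_that("probe layout respects the promoter window on both strands", {
  cfg <- sim_config(n_promoters = 40, probes_per_promoter = 8, seed = 5)
  ann <- generate_annotation(cfg)
  expect_equal(nrow(ann$promoters), 40L)
  expect_equal(nrow(ann$probes), 320L)
  for (i in seq_len(40)) {
    p <- ann$promoters[i, ]
    probes <- ann$probes[ann$probes$promoter_id == p$promoter_id, ]
    if (p$strand == "+") {
      expect_true(all(probes$position >= p$tss - 1300 &
                        probes$position <= p$tss + 500))
    } else {
      expect_true(all(probes$position >= p$tss - 500 &
                        probes$position <= p$tss + 1300))
    }
  }
  # minus-strand probe offsets mirror the plus-strand offsets around the TSS
  plus <- ann$promoters$strand == "+"
  off <- function(rows) {
    m <- matrix(ann$probes$position, nrow = cfg$probes_per_promoter)
    sweep(m[, rows, drop = FALSE], 2, ann$promoters$tss[rows])
  }
  expect_equal(sort(unique(as.vector(off(plus)))),
               sort(unique(as.vector(-off(!plus)))))
})

test_that("degenerate layouts behave as specified", {
  cfg1 <- sim_config(n_promoters = 1, probes_per_promoter = 1, seed = 2)
  ann1 <- generate_annotation(cfg1)
  # single probe at the window midpoint (-1300..+500 -> -400 from TSS)
  expect_equal(abs(ann1$probes$position - ann1$promoters$tss), 400)

  cfg_bad <- sim_config(n_promoters = 1, probes_per_promoter = 50,
                        window_start = -20, window_end = 20, seed = 1)
  expect_error(generate_annotation(cfg_bad), "too small")
})

test_that("identical configs give byte-identical outputs", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- sim_config(n_promoters = 30, seed = 7)
  simulate_experiment(cfg, d1)
  simulate_experiment(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("config invariants are enforced", {
  expect_error(sim_config(effect_size = -1), "effect_size")
  expect_error(sim_config(frac_dmr = 1.5), "frac_dmr")
  expect_error(sim_config(cpg_class_mix = c(HCP = 0.5, ICP = 0.6,
                                            LCP = -0.1)), "cpg_class_mix")
  expect_error(sim_config(n_promoters = 0), "n_promoters")
})

test_that("noiseless spike-in gives M' exactly +/- effect_size", {
  x <- small_sim(seed = 4, n_promoters = 50, noise_sd = 0,
                 effect_size = 1.0, frac_dmr = 0.2)
  stats <- compute_probe_stats(x$rs)
  spiked <- stats$gene_id %in% x$sim$truth$promoter_id
  dir <- x$sim$truth$direction[match(stats$gene_id[spiked],
                                     x$sim$truth$promoter_id)]
  expect_equal(stats$mprime[spiked], ifelse(dir == "hyper", 1, -1))
  expect_equal(stats$mprime[!spiked], rep(0, sum(!spiked)))
  expect_equal(stats$cv_control, rep(0, nrow(stats)))
})

test_that("null simulations stay calibrated across repeated experiments", {
  called <- 0L
  total <- 0L
  for (s in 1:20) {
    x <- small_sim(seed = 100 + s, n_promoters = 150, effect_size = 0,
                   frac_dmr = 0)
    dmrs <- call_dmrs(x$rs)
    called <- called + length(unique(dmrs$gene_id))
    total <- total + 150L
  }
  expect_lte(called / total, 0.02)
})

test_that("engineered sequence classes agree with the classifier", {
  cfg_h <- sim_config(n_promoters = 5, seed = 9,
                      cpg_class_mix = c(HCP = 1, ICP = 0, LCP = 0))
  ann <- generate_annotation(cfg_h)
  sq <- generate_sequences(cfg_h, ann)
  expect_equal(classify_promoters(sq$sequences)$class, rep("HCP", 5))

  cfg_l <- sim_config(n_promoters = 5, seed = 9,
                      cpg_class_mix = c(HCP = 0, ICP = 0, LCP = 1))
  sq_l <- generate_sequences(cfg_l, generate_annotation(cfg_l))
  expect_equal(classify_promoters(sq_l$sequences)$class, rep("LCP", 5))

  # mixed classes: intended class recovered for >= 95% of promoters
  cfg_m <- sim_config(n_promoters = 300, seed = 10)
  sq_m <- generate_sequences(cfg_m, generate_annotation(cfg_m))
  got <- classify_promoters(sq_m$sequences)
  agree <- got$class == sq_m$class_truth$class[
    match(got$promoter_id, sq_m$class_truth$promoter_id)]
  expect_gte(mean(agree), 0.95)
})

test_that("synthetic qPCR tables recover their configured effects", {
  # flat means, no noise: ANOVA finds nothing
  flat <- generate_qpcr(dct_means = c(NC.CD = 6, NC.HFD = 6, DIO.CD = 6,
                                      DIO.HFD = 6),
                        noise_sd = 0, ct_reference_sd = 0, seed = 3)
  an <- two_way_anova(flat$ct_target - flat$ct_reference,
                      flat$maternal_diet, flat$offspring_diet)
  expect_equal(an$table$F[an$table$effect != "residuals"], rep(0, 3))

  # +1 Ct in maternal-DIO cells, no noise: fold change exactly 0.5
  shifted <- generate_qpcr(dct_means = c(NC.CD = 6, NC.HFD = 6, DIO.CD = 7,
                                         DIO.HFD = 7),
                           noise_sd = 0, ct_reference_sd = 0, seed = 3)
  folds <- relative_expression(shifted)
  expect_equal(unique(folds$fold[folds$maternal_diet == "DIO"]), 0.5)

  # a 2-SD interaction term is detectable at n = 8 per cell
  inter <- generate_qpcr(dct_means = c(NC.CD = 6, NC.HFD = 6, DIO.CD = 6,
                                       DIO.HFD = 6.6),
                         noise_sd = 0.3, seed = 8)
  an2 <- two_way_anova(inter$ct_target - inter$ct_reference,
                       inter$maternal_diet, inter$offspring_diet)
  expect_lt(an2$table$p[an2$table$effect == "interaction"], 0.05)
})
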