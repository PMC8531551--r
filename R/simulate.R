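#' Configuration for a synthetic MeDIP-chip experiment
#'
#' Defaults emulate a scaled-down promoter tiling array: 2,000 promoters with
#' 8 evenly spaced probes over a strand-aware -1300..+500 bp window around
#' each TSS, two groups (control vs treated) with 3 replicate arrays each,
#' and a 5% spike-in of promoters whose treated-group MeDIP signal is shifted
#' by `effect_size` on the log2 scale (direction hyper or hypo, 50/50).
#' The full-size geometry (22,327 promoters, ~180,000 probes) is a config
#' choice, not a different code path.
#'
#' Intensity model: every probe has an affinity baseline (log2 scale, shared
#' by both channels and all arrays, so it cancels from the MeDIP/Input
#' ratio); every promoter has a baseline methylation enrichment
#' `base_enrichment` added to its MeDIP channel; i.i.d. Gaussian noise of sd
#' `noise_sd` (log2 scale) is added per channel per array.
#'
#' @param n_promoters number of promoters.
#' @param probes_per_promoter probes tiled per promoter window.
#' @param window_start,window_end promoter window as signed offsets around
#'   the TSS, bp (default -1300 and +500).
#' @param n_replicates replicate arrays per group.
#' @param effect_size log2-scale shift added to the MeDIP channel of spiked
#'   promoters in the treated group; must be >= 0 (direction is encoded
#'   separately in the truth set).
#' @param frac_dmr fraction of promoters spiked, in `[0, 1]`.
#' @param noise_sd sd of the per-channel log2-scale intensity noise.
#' @param base_enrichment baseline log2(MeDIP/Input) enrichment of every
#'   promoter; keeps hypomethylated spike-ins detectable under the
#'   median-ratio filter, as for a genuinely methylated promoter compartment.
#' @param baseline_log2_mean,baseline_log2_sd distribution of the per-probe
#'   affinity baseline (log2 intensity units).
#' @param cpg_class_mix named fractions of HCP/ICP/LCP promoter sequences;
#'   must sum to 1.
#' @param seed integer seed; identical configs (including seed) reproduce
#'   byte-identical outputs.
#' @return validated `sim_config` list.
#' @export
sim_config <- function(n_promoters = 2000,
                       probes_per_promoter = 8,
                       window_start = -1300,
                       window_end = 500,
                       n_replicates = 3,
                       effect_size = 1.0,
                       frac_dmr = 0.05,
                       noise_sd = 0.25,
                       base_enrichment = 1.0,
                       baseline_log2_mean = 10,
                       baseline_log2_sd = 1,
                       cpg_class_mix = c(HCP = 1/3, ICP = 1/3, LCP = 1/3),
                       seed = 1) {
  cfg <- list(n_promoters = as.integer(n_promoters),
              probes_per_promoter = as.integer(probes_per_promoter),
              window_start = as.integer(window_start),
              window_end = as.integer(window_end),
              n_replicates = as.integer(n_replicates),
              effect_size = effect_size, frac_dmr = frac_dmr,
              noise_sd = noise_sd, base_enrichment = base_enrichment,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              cpg_class_mix = cpg_class_mix, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_promoters > 0, cfg$probes_per_promoter > 0,
            cfg$n_replicates > 0)
  if (cfg$window_end <= cfg$window_start)
    stop("promoter window is empty", call. = FALSE)
  if (cfg$effect_size < 0)
    stop("effect_size must be >= 0; direction is encoded in the truth set",
         call. = FALSE)
  if (cfg$frac_dmr < 0 || cfg$frac_dmr > 1)
    stop("frac_dmr must be in [0, 1]", call. = FALSE)
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  mix <- cfg$cpg_class_mix
  if (!setequal(names(mix), c("HCP", "ICP", "LCP")) ||
      abs(sum(mix) - 1) > 1e-8 || any(mix < 0))
    stop("cpg_class_mix must be named HCP/ICP/LCP fractions summing to 1",
         call. = FALSE)
  invisible(cfg)
}

#' Generate promoter annotation and probe layout
#'
#' Promoters are placed on chr1..chr19 (round-robin, 100 kb apart) with
#' random strand; each promoter window spans `window_start..window_end`
#' around its TSS on the transcribed strand, and probes are evenly spaced
#' inside the window (probe k at offset fraction (k - 0.5)/n). Minus-strand
#' promoters mirror the plus-strand probe offsets around the TSS.
#'
#' @param config a [sim_config()].
#' @return list with `promoters` (promoter_id, gene_id, chrom, tss, strand,
#'   start, end; 1-based inclusive window coordinates) and `probes`
#'   (probe_id, chrom, position, gene_id, promoter_id).
#' @export
generate_annotation <- function(config) {
  validate_sim_config(config)
  n <- config$n_promoters
  np <- config$probes_per_promoter
  wlen <- config$window_end - config$window_start
  if (np > wlen)
    stop(sprintf("promoter window (%d bp) too small for %d probes",
                 wlen, np), call. = FALSE)
  withr::with_seed(stage_seed(config$seed, "annotation"), {
    chrom <- paste0("chr", ((seq_len(n) - 1L) %% 19L) + 1L)
    slot <- (seq_len(n) - 1L) %/% 19L
    tss <- 50000L + slot * 100000L
    strand <- sample(c("+", "-"), n, replace = TRUE)
  })
  promoter_id <- sprintf("G%05d", seq_len(n))
  win_lo <- ifelse(strand == "+", config$window_start, -config$window_end)
  win_hi <- ifelse(strand == "+", config$window_end, -config$window_start)
  promoters <- data.frame(
    promoter_id = promoter_id, gene_id = promoter_id,
    chrom = chrom, tss = tss, strand = strand,
    start = tss + win_lo, end = tss + win_hi,
    stringsAsFactors = FALSE
  )
  # probe offsets on the transcribed strand, mirrored for minus strand
  frac <- (seq_len(np) - 0.5) / np
  off <- round(config$window_start + frac * wlen)
  probes <- data.frame(
    probe_id = sprintf("P%07d", seq_len(n * np)),
    chrom = rep(chrom, each = np),
    position = as.integer(rep(tss, each = np) +
                            as.vector(vapply(strand, function(s)
                              if (s == "+") off else -off, numeric(np)))),
    gene_id = rep(promoter_id, each = np),
    promoter_id = rep(promoter_id, each = np),
    stringsAsFactors = FALSE
  )
  list(promoters = promoters, probes = probes)
}

# --- promoter sequence generation -----------------------------------------

# i.i.d. sequence with given letter probabilities, then CpG depletion:
# the G of each CpG is mutated to A with probability (1 - retain).  Mutating
# G -> A can never create a new CpG, so the retained fraction sets the
# observed/expected ratio directly.
random_promoter_seq <- function(len, probs, cpg_retain) {
  s <- sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = probs)
  if (cpg_retain < 1) {
    cpg <- which(s[-len] == "C" & s[-1] == "G")
    if (length(cpg)) {
      kill <- cpg[runif(length(cpg)) > cpg_retain]
      s[kill + 1L] <- "A"
    }
  }
  paste(s, collapse = "")
}

#' Generate promoter sequences with controlled CpG-class mix
#'
#' Emits one sequence per promoter (length = promoter window), engineered per
#' intended class: HCP sequences are GC-rich (~60%) with undepleted CpGs
#' (observed/expected ~1); ICP sequences have ~46% GC with CpGs depleted to
#' o/e ~0.6; LCP sequences have ~40% GC with CpGs depleted to o/e ~0.05 so
#' no 500 bp window exceeds the 0.48 o/e bound.
#'
#' @param config a [sim_config()].
#' @param annotation output of [generate_annotation()].
#' @return list with `sequences` (named character vector, one per promoter)
#'   and `class_truth` (data.frame promoter_id, class).
#' @export
generate_sequences <- function(config, annotation) {
  validate_sim_config(config)
  n <- config$n_promoters
  len <- config$window_end - config$window_start
  mix <- config$cpg_class_mix[c("HCP", "ICP", "LCP")]
  counts <- diff(c(0, round(cumsum(mix) * n)))  # exact partition of n
  classes <- rep(c("HCP", "ICP", "LCP"), counts)
  pars <- list(
    HCP = list(probs = c(.20, .30, .30, .20), retain = 1.00),
    ICP = list(probs = c(.26, .24, .24, .26), retain = 0.60),
    LCP = list(probs = c(.30, .20, .20, .30), retain = 0.05)
  )
  withr::with_seed(stage_seed(config$seed, "sequences"), {
    classes <- sample(classes)
    seqs <- vapply(classes, function(cl)
      random_promoter_seq(len, pars[[cl]]$probs, pars[[cl]]$retain), "")
  })
  names(seqs) <- annotation$promoters$promoter_id
  list(sequences = seqs,
       class_truth = data.frame(promoter_id = names(seqs), class = classes,
                                stringsAsFactors = FALSE))
}

#' Simulate two-channel intensities with spiked methylation differences
#'
#' For each of the `2 * n_replicates` arrays, every probe gets
#' `input = 2^(baseline + noise)` and
#' `medip = 2^(baseline + enrichment + noise)`, where `baseline` is a
#' per-probe affinity shared by both channels and all arrays, and
#' `enrichment` is `base_enrichment` plus, for spiked promoters in the
#' treated group only, `+effect_size` (hyper) or `-effect_size` (hypo).
#'
#' @param config a [sim_config()].
#' @param layout output of [generate_annotation()].
#' @return list with `tables` (named list of per-array probe data.frames;
#'   names like `control_rep1`), `design` (array_id, group, replicate) and
#'   `truth` (data.frame promoter_id, direction for spiked promoters).
#' @export
simulate_intensities <- function(config, layout) {
  validate_sim_config(config)
  probes <- layout$probes
  n_pr <- nrow(probes)
  n_prom <- nrow(layout$promoters)
  nrep <- config$n_replicates

  withr::with_seed(stage_seed(config$seed, "intensities"), {
    n_dmr <- round(config$frac_dmr * n_prom)
    spiked <- sort(sample.int(n_prom, n_dmr))
    direction <- sample(c("hyper", "hypo"), n_dmr, replace = TRUE)
    baseline <- rnorm(n_pr, config$baseline_log2_mean, config$baseline_log2_sd)

    shift <- setNames(rep(0, n_prom), layout$promoters$promoter_id)
    shift[spiked] <- ifelse(direction == "hyper", 1, -1) * config$effect_size
    probe_shift <- shift[probes$promoter_id]

    groups <- c("control", "treated")
    tables <- list()
    design <- data.frame(array_id = character(), group = character(),
                         replicate = integer(), stringsAsFactors = FALSE)
    for (g in groups) {
      for (r in seq_len(nrep)) {
        enr <- config$base_enrichment +
          if (g == "treated") probe_shift else rep(0, n_pr)
        noise_in <- rnorm(n_pr, 0, config$noise_sd)
        noise_me <- rnorm(n_pr, 0, config$noise_sd)
        id <- sprintf("%s_rep%d", g, r)
        tables[[id]] <- data.frame(
          probe_id = probes$probe_id, chrom = probes$chrom,
          position = probes$position, gene_id = probes$gene_id,
          medip = 2^(baseline + enr + noise_me),
          input = 2^(baseline + noise_in),
          stringsAsFactors = FALSE
        )
        design <- rbind(design, data.frame(array_id = id, group = g,
                                           replicate = r,
                                           stringsAsFactors = FALSE))
      }
    }
  })
  truth <- data.frame(
    promoter_id = layout$promoters$promoter_id[spiked],
    direction = direction, stringsAsFactors = FALSE)
  list(tables = tables, design = design, truth = truth)
}

#' Generate a synthetic qPCR Ct table
#'
#' Balanced 2x2 design (maternal diet NC/DIO x offspring diet CD/HFD) with
#' `n_per_cell` samples per cell. Reference-gene Ct values are drawn around
#' `ct_reference_mean`; target Ct = reference Ct + the cell's delta-Ct mean +
#' Gaussian noise.
#'
#' @param dct_means named numeric of per-cell delta-Ct means, names
#'   `NC.CD, NC.HFD, DIO.CD, DIO.HFD`.
#' @param n_per_cell samples per cell (default 8, a typical rodent cohort).
#' @param gene gene label for the table.
#' @param ct_reference_mean,ct_reference_sd reference-gene Ct distribution.
#' @param noise_sd sd of the target-gene Ct noise (cycles).
#' @param seed integer seed.
#' @return data.frame with columns `sample`, `maternal_diet`,
#'   `offspring_diet`, `gene`, `ct_target`, `ct_reference`.
#' @export
generate_qpcr <- function(dct_means = c(NC.CD = 6, NC.HFD = 7,
                                        DIO.CD = 7, DIO.HFD = 7.5),
                          n_per_cell = 8, gene = "GeneX",
                          ct_reference_mean = 18, ct_reference_sd = 0.2,
                          noise_sd = 0.3, seed = 1) {
  cells <- expand.grid(maternal_diet = c("NC", "DIO"),
                       offspring_diet = c("CD", "HFD"),
                       stringsAsFactors = FALSE)
  key <- paste(cells$maternal_diet, cells$offspring_diet, sep = ".")
  if (!all(key %in% names(dct_means)))
    stop("dct_means must name all cells: ", paste(key, collapse = ", "),
         call. = FALSE)
  withr::with_seed(stage_seed(seed, "qpcr"), {
    rows <- lapply(seq_len(nrow(cells)), function(i) {
      ref <- rnorm(n_per_cell, ct_reference_mean, ct_reference_sd)
      tgt <- ref + dct_means[[key[i]]] + rnorm(n_per_cell, 0, noise_sd)
      data.frame(
        sample = sprintf("%s_%s_s%d", cells$maternal_diet[i],
                         cells$offspring_diet[i], seq_len(n_per_cell)),
        maternal_diet = cells$maternal_diet[i],
        offspring_diet = cells$offspring_diet[i],
        gene = gene, ct_target = tgt, ct_reference = ref,
        stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, rows)
}

#' Generate synthetic gene sets (GMT)
#'
#' Random gene sets over the simulated gene universe, plus a few sets
#' deliberately enriched for the spiked (truly differentially methylated)
#' genes so downstream over-representation analysis has signal to find.
#'
#' @param config a [sim_config()].
#' @param annotation output of [generate_annotation()].
#' @param truth truth data.frame from [simulate_intensities()].
#' @param n_random,n_enriched numbers of random and spike-enriched sets.
#' @return named list of character vectors (gene ids per set).
#' @export
generate_gene_sets <- function(config, annotation, truth,
                               n_random = 40, n_enriched = 5) {
  genes <- annotation$promoters$gene_id
  dmr_genes <- truth$promoter_id
  withr::with_seed(stage_seed(config$seed, "gene_sets"), {
    sets <- list()
    for (i in seq_len(n_random)) {
      sz <- min(sample(10:100, 1), length(genes))
      sets[[sprintf("RANDOM_SET_%02d", i)]] <- sample(genes, sz)
    }
    for (i in seq_len(n_enriched)) {
      n_hit <- min(length(dmr_genes), sample(10:25, 1))
      hit <- if (n_hit) sample(dmr_genes, n_hit) else character()
      sets[[sprintf("DMR_ENRICHED_SET_%02d", i)]] <-
        unique(c(hit, sample(genes, min(30, length(genes)))))
    }
  })
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of gene-id vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Simulate and write a complete experiment to disk
#'
#' Runs every generator and writes: promoter annotation (BED6, 0-based
#' half-open, strand in column 6), per-array probe tables (tab-delimited,
#' filename = group_repN.tsv), promoter FASTA, truth DMRs (BED6 with the
#' spike direction in the name field), truth CpG classes (TSV), gene sets
#' (GMT) and a qPCR Ct table (CSV).
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return invisible named list of output paths plus the in-memory `truth`.
#' @export
simulate_experiment <- function(config, out_dir) {
  validate_sim_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ann <- generate_annotation(config)
  seqs <- generate_sequences(config, ann)
  sim <- simulate_intensities(config, ann)

  paths <- list()
  p <- ann$promoters
  paths$annotation <- file.path(out_dir, "promoters.bed")
  write_bed6(p$chrom, p$start - 1L, p$end, p$promoter_id,
             0L, p$strand, paths$annotation)

  paths$arrays <- character()
  for (id in names(sim$tables)) {
    f <- file.path(out_dir, paste0(id, ".tsv"))
    write_probe_table(sim$tables[[id]], f)
    paths$arrays[id] <- f
  }
  paths$design <- file.path(out_dir, "design.tsv")
  write.table(sim$design, paths$design, sep = "\t", quote = FALSE,
              row.names = FALSE)

  paths$fasta <- file.path(out_dir, "promoters.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs$sequences), paths$fasta)

  paths$class_truth <- file.path(out_dir, "truth_classes.tsv")
  write.table(seqs$class_truth, paths$class_truth, sep = "\t",
              quote = FALSE, row.names = FALSE)

  paths$truth_dmrs <- file.path(out_dir, "truth_dmrs.bed")
  ti <- match(sim$truth$promoter_id, p$promoter_id)
  write_bed6(p$chrom[ti], p$start[ti] - 1L, p$end[ti],
             sim$truth$direction, 0L, p$strand[ti], paths$truth_dmrs)

  paths$gmt <- file.path(out_dir, "gene_sets.gmt")
  write_gmt(generate_gene_sets(config, ann, sim$truth), paths$gmt)

  paths$qpcr <- file.path(out_dir, "qpcr.csv")
  write.csv(generate_qpcr(seed = config$seed), paths$qpcr, row.names = FALSE)

  paths$truth <- sim$truth
  invisible(paths)
}
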