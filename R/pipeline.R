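#' Default pipeline configuration
#'
#' Full nested configuration for [run_pipeline()] with every stage threshold
#' at its default (median-ratio 0.3, probe CV 0.8, peak score 2, peak p
#' 0.01; pathway rule FDR 0.05 / fold 1.50, ontology rule P 0.01 / fold
#' 1.10). Override fields directly or via a YAML file with the same
#' structure.
#'
#' @param seed top-level seed; all stage RNGs derive from it.
#' @param out_dir run output directory.
#' @return nested configuration list.
#' @export
default_run_config <- function(seed = 1, out_dir = "meditile_run") {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = c("simulate", "normalize", "call", "classify", "summarize",
               "enrich", "qpcr"),
    sim = list(n_promoters = 2000, probes_per_promoter = 8,
               window_start = -1300, window_end = 500, n_replicates = 3,
               effect_size = 1.0, frac_dmr = 0.05, noise_sd = 0.25,
               base_enrichment = 1.0),
    normalize = list(method = "none"),
    call = list(window_bp = 750, min_probes = 2, probe_p_cutoff = 0.1,
                merge_gap = 500, max_cv = 0.8, min_median_ratio = 0.3,
                min_cv_pass = 0.5, min_peak_score = 2, max_peak_p = 0.01),
    classify = list(window_bp = 500, step = 5),
    enrich = list(kind = "pathway", min_genes = 2, fdr_max = 0.05,
                  fold_min = 1.50),
    qpcr = list(ref_maternal = "NC", ref_offspring = "CD"),
    # external inputs, used for stages whose producing stage is disabled
    inputs = list(arrays = NULL, design = NULL, fasta = NULL, gmt = NULL,
                  qpcr = NULL)
  )
}

#' Load a pipeline configuration from YAML
#'
#' Fields present in the file override the defaults; everything else keeps
#' its default value.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  modify <- function(base, new) {
    for (nm in names(new)) {
      base[[nm]] <- if (is.list(new[[nm]]) && is.list(base[[nm]]))
        modify(base[[nm]], new[[nm]]) else new[[nm]]
    }
    base
  }
  modify(cfg, user)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  # out_dir is a location, not an analysis parameter
  config$out_dir <- NULL
  yaml::write_yaml(config, f)
  unname(tools::md5sum(f))
}

require_stage <- function(done, stage, needs) {
  missing <- setdiff(needs, done)
  if (length(missing))
    stop(sprintf("stage '%s' requires output of disabled stage(s): %s",
                 stage, paste(missing, collapse = ", ")), call. = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order (simulate, normalize, call,
#' classify, summarize, enrich, qpcr), writing every stage's outputs under
#' `config$out_dir` and a JSON manifest (`manifest.json`) with the package
#' version, a configuration hash and per-stage output row counts. Identical
#' configuration (including seed) reproduces byte-identical outputs. A
#' stage whose upstream stage is disabled fails fast unless the
#' corresponding `config$inputs` path is supplied.
#'
#' @param config a configuration list from [default_run_config()] /
#'   [read_run_config()], or a path to a YAML file.
#' @return invisible manifest list.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  done <- character()
  manifest <- list(package = "meditile",
                   version = as.character(packageVersion("meditile")),
                   config_hash = config_hash(config),
                   seed = config$seed, stages = list())
  note <- function(stage, outputs, counts) {
    manifest$stages[[stage]] <<- list(outputs = outputs, rows = counts)
    done <<- c(done, stage)
    message(sprintf("[meditile] %-9s %s", stage,
                    paste(sprintf("%s=%d", names(counts),
                                  unlist(counts)), collapse = " ")))
  }

  sim_paths <- NULL
  truth <- NULL
  if ("simulate" %in% stages) {
    scfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
    sim_paths <- simulate_experiment(scfg, file.path(out_dir, "sim"))
    truth <- sim_paths$truth
    note("simulate",
         list(dir = "sim"),
         list(promoters = scfg$n_promoters,
              arrays = length(sim_paths$arrays),
              spiked = nrow(truth)))
  }

  rs <- NULL
  if ("normalize" %in% stages) {
    if (!is.null(sim_paths)) {
      array_files <- sim_paths$arrays
      design <- read.delim(sim_paths$design, stringsAsFactors = FALSE)
    } else if (!is.null(config$inputs$arrays)) {
      array_files <- config$inputs$arrays
      design <- read.delim(config$inputs$design, stringsAsFactors = FALSE)
      if (is.null(names(array_files)))
        names(array_files) <- design$array_id[
          match(basename(array_files),
                paste0(design$array_id, ".tsv"))]
    } else {
      require_stage(done, "normalize", "simulate")
    }
    tables <- lapply(array_files, read_probe_table)
    rs <- build_ratio_set(tables, design, normalize = config$normalize$method)
    f <- file.path(out_dir, "ratios.tsv")
    write.table(cbind(rs$probes, as.data.frame(rs$ratios)), f, sep = "\t",
                quote = FALSE, row.names = FALSE)
    note("normalize", list(ratios = "ratios.tsv"),
         list(probes = nrow(rs$probes)))
  }

  dmrs <- NULL
  if ("call" %in% stages) {
    require_stage(done, "call", "normalize")
    dmrs <- do.call(call_dmrs, c(list(rs), config$call))
    write_dmr_table(dmrs, file.path(out_dir, "dmrs.tsv"),
                    file.path(out_dir, "dmrs.bed"))
    note("call", list(tsv = "dmrs.tsv", bed = "dmrs.bed"),
         list(dmrs = nrow(dmrs)))
  }

  classes <- NULL
  if ("classify" %in% stages) {
    fasta <- if (!is.null(sim_paths)) sim_paths$fasta else
      config$inputs$fasta
    if (is.null(fasta)) require_stage(done, "classify", "simulate")
    classes <- classify_fasta(fasta, window_bp = config$classify$window_bp,
                              step = config$classify$step)
    write.table(classes, file.path(out_dir, "classes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    note("classify", list(tsv = "classes.tsv"),
         list(promoters = nrow(classes)))
  }

  if ("summarize" %in% stages) {
    require_stage(done, "summarize", c("call", "classify"))
    rep <- summarize_dmrs(dmrs, classes)
    f <- file.path(out_dir, "summary.tsv")
    combined <- rbind(
      cbind(partition = "direction", rep$by_direction),
      cbind(partition = "cpg_class", rep$by_class),
      cbind(partition = "chromosome", rep$by_chrom))
    write.table(combined, f, sep = "\t", quote = FALSE, row.names = FALSE)
    note("summarize", list(tsv = "summary.tsv"),
         list(total_dmrs = rep$total))
  }

  if ("enrich" %in% stages) {
    require_stage(done, "enrich", "call")
    gmt <- if (!is.null(config$inputs$gmt)) config$inputs$gmt else
      if (!is.null(sim_paths)) sim_paths$gmt else
        require_stage(done, "enrich", "simulate")
    sets <- read_gene_sets(gmt)
    background <- unique(rs$probes$gene_id)
    genes <- unique(dmrs$gene_id)
    enr <- if (length(genes)) {
      run_enrichment(genes, sets, background, kind = config$enrich$kind,
                     min_genes = config$enrich$min_genes,
                     fdr_max = config$enrich$fdr_max,
                     fold_min = config$enrich$fold_min)
    } else {
      data.frame()
    }
    write.table(enr, file.path(out_dir, "enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    note("enrich", list(tsv = "enrichment.tsv"),
         list(sets = nrow(enr),
              significant = if (nrow(enr)) sum(enr$significant) else 0L))
  }

  if ("qpcr" %in% stages) {
    qp <- if (!is.null(config$inputs$qpcr)) config$inputs$qpcr else
      if (!is.null(sim_paths)) sim_paths$qpcr else
        require_stage(done, "qpcr", "simulate")
    records <- read_qpcr_table(qp)
    folds <- relative_expression(records,
                                 ref_maternal = config$qpcr$ref_maternal,
                                 ref_offspring = config$qpcr$ref_offspring)
    write.table(folds, file.path(out_dir, "qpcr_folds.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    anova_rows <- lapply(split(folds, folds$gene), function(d) {
      res <- two_way_anova(d$dct, d$maternal_diet, d$offspring_diet)
      cbind(gene = d$gene[1], res$table)
    })
    anova_tab <- do.call(rbind, anova_rows)
    write.table(anova_tab, file.path(out_dir, "qpcr_anova.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    note("qpcr", list(folds = "qpcr_folds.tsv", anova = "qpcr_anova.tsv"),
         list(samples = nrow(folds)))
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
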