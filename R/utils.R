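# internal helpers shared across modules

# Deterministic per-stage seed derived from the top-level seed.  Offsets keep
# stages decoupled so e.g. changing qPCR settings never perturbs the arrays.
stage_seed <- function(seed, stage) {
  offsets <- c(annotation = 11L, sequences = 23L, intensities = 37L,
               qpcr = 53L, gene_sets = 71L, misc = 97L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) %% 20000000L) * 100L + offsets[[stage]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a BED6 file (0-based half-open) from 1-based inclusive coordinates.
write_bed6 <- function(chrom, start0, end, name, score, strand, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end),
    strand = ifelse(strand == ".", "*", strand)
  )
  gr$name <- rep_len(name, length(gr))
  gr$score <- rep_len(score, length(gr))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

stop_with_row <- function(msg, row) {
  stop(sprintf("%s (row %d)", msg, row), call. = FALSE)
}
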