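#' CpG observed/expected ratio of a sequence window
#'
#' `(#CpG dinucleotides x L) / (#C x #G)`, where `L` is the number of
#' unambiguous (A/C/G/T) bases in the window; returns 0 when the window has
#' no C or no G. Non-ACGT characters are excluded from all counts.
#'
#' @param seq a single character string (DNA).
#' @return the observed/expected CpG ratio.
#' @examples
#' cpg_observed_expected("CGCGCGCG")  # 2
#' cpg_observed_expected("CCCCGGGG")  # 0.5
#' @export
cpg_observed_expected <- function(seq) {
  s <- seq_chars(seq)
  n_c <- sum(s == "C")
  n_g <- sum(s == "G")
  if (n_c == 0 || n_g == 0) return(0)
  n_cg <- sum(s[-length(s)] == "C" & s[-1] == "G")
  len <- sum(s %in% c("A", "C", "G", "T"))
  n_cg * len / (n_c * n_g)
}

seq_chars <- function(seq) {
  if (length(seq) != 1 || !nzchar(seq)) stop("empty sequence", call. = FALSE)
  strsplit(toupper(seq), "", fixed = TRUE)[[1]]
}

# Sliding-window GC fraction and CpG o/e for one strand, via cumulative
# sums; windows with > max_n_frac ambiguous bases are dropped.
window_stats <- function(s, window_bp, step, max_n_frac = 0.1) {
  L <- length(s)
  w <- min(window_bp, L)
  starts <- unique(c(seq.int(1L, L - w + 1L, by = step), L - w + 1L))
  isC <- cumsum(c(0L, s == "C"))
  isG <- cumsum(c(0L, s == "G"))
  isACGT <- cumsum(c(0L, s %in% c("A", "C", "G", "T")))
  cg <- cumsum(c(0L, 0L, s[-L] == "C" & s[-1] == "G"))  # CpG starting at i<L
  ends <- starts + w - 1L
  n_c <- isC[ends + 1L] - isC[starts]
  n_g <- isG[ends + 1L] - isG[starts]
  n_ok <- isACGT[ends + 1L] - isACGT[starts]
  n_cg <- cg[ends + 1L] - cg[starts + 1L]  # CpGs fully inside [start, end]
  keep <- (w - n_ok) / w <= max_n_frac & n_ok > 0
  gc <- ifelse(n_ok > 0, (n_c + n_g) / n_ok, 0)
  oe <- ifelse(n_c > 0 & n_g > 0, n_cg * n_ok / (n_c * n_g), 0)
  data.frame(start = starts, end = ends, gc = gc, oe = oe)[keep, ,
                                                           drop = FALSE]
}

revcomp_chars <- function(s) {
  rev(chartr("ACGTacgt", "TGCAtgca", s))
}

#' Classify a promoter sequence by CpG density
#'
#' Scans 500 bp windows (step `step`, both the given strand and its reverse
#' complement) for GC fraction and CpG observed/expected ratio, then applies
#' the three-class rule: HCP if any window has GC > 0.55 and o/e > 0.75;
#' LCP if no window has o/e > 0.48; ICP otherwise. Sequences shorter than
#' the window are scored as a single whole-length window. Windows with more
#' than 10% ambiguous bases are skipped.
#'
#' @param seq a single DNA string.
#' @param window_bp window width (default 500).
#' @param step scan step in bp (default 5; use 1 for an exhaustive scan).
#' @param gc_min,oe_high,oe_low class thresholds (HCP GC bound, HCP o/e
#'   bound, LCP o/e bound).
#' @return list with `class` (`"HCP"`, `"ICP"` or `"LCP"`) and `best_window`
#'   (start, end, gc_fraction, cpg_oe of the max-o/e window on either
#'   strand; coordinates on the given strand).
#' @export
classify_promoter <- function(seq, window_bp = 500, step = 5,
                              gc_min = 0.55, oe_high = 0.75, oe_low = 0.48) {
  s <- seq_chars(seq)
  fwd <- window_stats(s, window_bp, step)
  rc <- window_stats(revcomp_chars(s), window_bp, step)
  if (nrow(rc)) {
    # map reverse-complement window coordinates back to the given strand
    L <- length(s)
    tmp <- L - rc$end + 1L
    rc$end <- L - rc$start + 1L
    rc$start <- tmp
  }
  win <- rbind(fwd, rc)
  if (!nrow(win))
    return(list(class = "LCP",
                best_window = data.frame(start = NA_integer_,
                                         end = NA_integer_,
                                         gc_fraction = NA_real_,
                                         cpg_oe = NA_real_)))
  cls <- if (any(win$gc > gc_min & win$oe > oe_high)) "HCP"
         else if (!any(win$oe > oe_low)) "LCP"
         else "ICP"
  best <- win[order(-win$oe, -win$gc), ][1, ]
  list(class = cls,
       best_window = data.frame(start = best$start, end = best$end,
                                gc_fraction = best$gc, cpg_oe = best$oe))
}

#' Classify a set of promoter sequences
#'
#' @param seqs named character vector or `Biostrings::DNAStringSet`.
#' @inheritParams classify_promoter
#' @return data.frame: `promoter_id`, `class`, `window_start`, `window_end`,
#'   `gc_fraction`, `cpg_oe`.
#' @export
classify_promoters <- function(seqs, window_bp = 500, step = 5,
                               gc_min = 0.55, oe_high = 0.75,
                               oe_low = 0.48) {
  if (inherits(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs))) stop("sequences must be named", call. = FALSE)
  rows <- lapply(names(seqs), function(id) {
    r <- classify_promoter(seqs[[id]], window_bp, step, gc_min, oe_high,
                           oe_low)
    data.frame(promoter_id = id, class = r$class,
               window_start = r$best_window$start,
               window_end = r$best_window$end,
               gc_fraction = r$best_window$gc_fraction,
               cpg_oe = r$best_window$cpg_oe, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify promoters straight from a FASTA file
#'
#' @param fasta_path promoter FASTA (record id = promoter id).
#' @inheritParams classify_promoter
#' @return see [classify_promoters()].
#' @export
classify_fasta <- function(fasta_path, window_bp = 500, step = 5) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  classify_promoters(seqs, window_bp = window_bp, step = step)
}

#' Summarize a DMR call set
#'
#' Counts and percentages of DMRs by direction (hyper/hypo), by CpG class of
#' the host promoter (HCP/ICP/LCP) and by chromosome. Percentages are
#' `100 * count / total` rounded to 2 decimals; with an empty call set all
#' counts are 0 and percentages `NA`.
#'
#' @param dmrs DMR table (needs `gene_id`, `direction`, `chrom`).
#' @param classifications data.frame with `promoter_id` and `class` (e.g.
#'   from [classify_promoters()]); every DMR promoter must be classified.
#' @return list with `total` and data.frames `by_direction`, `by_class`,
#'   `by_chrom` (columns level, count, pct).
#' @export
summarize_dmrs <- function(dmrs, classifications) {
  total <- nrow(dmrs)
  tab <- function(values, levels) {
    counts <- as.integer(table(factor(values, levels = levels)))
    data.frame(level = levels, count = counts,
               pct = if (total > 0) round(100 * counts / total, 2)
                     else rep(NA_real_, length(levels)),
               stringsAsFactors = FALSE)
  }
  cls <- classifications$class[match(dmrs$gene_id,
                                     classifications$promoter_id)]
  if (total > 0 && anyNA(cls))
    stop("unclassified promoter(s): ",
         paste(unique(dmrs$gene_id[is.na(cls)])[1:3], collapse = ", "),
         call. = FALSE)
  list(
    total = total,
    by_direction = tab(dmrs$direction, c("hyper", "hypo")),
    by_class = tab(cls, c("HCP", "ICP", "LCP")),
    by_chrom = if (total > 0) tab(dmrs$chrom, sort(unique(dmrs$chrom)))
               else data.frame(level = character(), count = integer(),
                               pct = numeric(), stringsAsFactors = FALSE)
  )
}
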