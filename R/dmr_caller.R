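#' Per-probe group statistics and the M' difference
#'
#' For each probe: per-group means and medians of the log2(MeDIP/Input)
#' ratios across replicate arrays, the between-group difference
#' `M' = mean(treated) - mean(control)`, and the per-group coefficient of
#' variation computed on linear-scale ratios `2^log2ratio` (sd/mean across
#' replicates; the CV of a log ratio near 0 is ill-defined).
#'
#' @param x a `ratio_set` from [build_ratio_set()].
#' @param control,treated group labels in `x$design$group`.
#' @return data.frame with one row per probe: annotation columns plus
#'   `mean_control`, `mean_treated`, `median_control`, `median_treated`,
#'   `mprime`, `cv_control`, `cv_treated`.
#' @export
compute_probe_stats <- function(x, control = "control", treated = "treated") {
  ci <- which(x$design$group == control)
  ti <- which(x$design$group == treated)
  if (length(ci) < 2 || length(ti) < 2)
    stop("need >= 2 replicate arrays per group", call. = FALSE)
  rc <- x$ratios[, ci, drop = FALSE]
  rt <- x$ratios[, ti, drop = FALSE]
  lc <- 2^rc
  lt <- 2^rt
  cv <- function(m) apply(m, 1, sd) / rowMeans(m)
  out <- x$probes
  out$mean_control <- rowMeans(rc)
  out$mean_treated <- rowMeans(rt)
  out$median_control <- apply(rc, 1, median)
  out$median_treated <- apply(rt, 1, median)
  out$mprime <- out$mean_treated - out$mean_control
  out$cv_control <- cv(lc)
  out$cv_treated <- cv(lt)
  out
}

#' Per-probe enrichment p-values (windowed KS statistic)
#'
#' For each probe, the replicate-paired differences (treated minus control
#' log2 ratio, replicate r paired with replicate r) of all probes of the same
#' promoter within `window_bp` (centred on the probe) form the local sample.
#' A one-sample Kolmogorov-Smirnov statistic compares that sample with the
#' experiment-wide empirical distribution of the same differences; the
#' one-sided tail `exp(-2 m D^2)` is taken in the better-supported direction
#' and doubled (capped at 1) to account for testing both shifts. Small values
#' flag probes whose local neighbourhood is shifted relative to the
#' experiment as a whole, in either direction.
#'
#' @param x a `ratio_set`.
#' @param window_bp full window width in bp (default 750).
#' @param control,treated group labels.
#' @return numeric vector of p-values, one per probe (canonical order).
#' @export
compute_probe_pvalues <- function(x, window_bp = 750,
                                  control = "control", treated = "treated") {
  D <- pair_differences(x, control, treated)
  g <- sort(as.vector(D))
  pos <- x$probes$position
  half <- window_bp / 2
  p <- numeric(nrow(D))
  for (ii in split(seq_len(nrow(D)), x$probes$gene_id)) {
    ppos <- pos[ii]
    for (j in seq_along(ii)) {
      sel <- ii[abs(ppos - ppos[j]) <= half]
      p[ii[j]] <- ks_shift_pvalue(as.vector(D[sel, , drop = FALSE]), g)
    }
  }
  p
}

# Doubled one-sided KS tail of a local sample w against the experiment-wide
# reference distribution (sorted vector g): D taken in the better-supported
# shift direction, tail bound exp(-2 m D^2), doubled for the two directions.
# Both ECDFs are evaluated at their right-continuous values and left limits
# so tied values (w is a subset of g) are handled exactly.
ks_shift_pvalue <- function(w, g) {
  ws <- sort(w)
  m <- length(ws)
  N <- length(g)
  u <- unique(ws)
  fw_le <- findInterval(u, ws) / m
  fw_lt <- findInterval(u, ws, left.open = TRUE) / m
  fg_le <- findInterval(u, g) / N
  fg_lt <- findInterval(u, g, left.open = TRUE) / N
  d <- max(0, abs(fg_le - fw_le), abs(fg_lt - fw_lt))
  min(1, 2 * exp(-2 * m * d^2))
}

# Replicate-paired treated-minus-control differences (probes x pairs)
pair_differences <- function(x, control = "control", treated = "treated") {
  ci <- which(x$design$group == control)
  ti <- which(x$design$group == treated)
  ci <- ci[order(x$design$replicate[ci])]
  ti <- ti[order(x$design$replicate[ti])]
  np <- min(length(ci), length(ti))
  if (np < 2) stop("need >= 2 replicate arrays per group", call. = FALSE)
  x$ratios[, ti[seq_len(np)], drop = FALSE] -
    x$ratios[, ci[seq_len(np)], drop = FALSE]
}

#' Maximal qualifying probe runs
#'
#' Segments one promoter's (position-sorted) probes into candidate peaks:
#' maximal runs of consecutive probes with `p <= cutoff` of length
#' `>= min_probes`; qualifying runs whose end-to-start distance is
#' `<= merge_gap` bp are merged. Exposed separately so the segmentation can
#' be checked against exhaustive enumeration.
#'
#' @param positions sorted probe positions (bp).
#' @param pvalues per-probe p-values.
#' @param cutoff probe-level p cutoff.
#' @param min_probes minimum run length.
#' @param merge_gap maximum bp gap between merged runs.
#' @return list of integer index vectors (probe indices per peak, gap probes
#'   between merged runs excluded).
#' @export
probe_runs <- function(positions, pvalues, cutoff = 0.1, min_probes = 2,
                       merge_gap = 500) {
  if (is.unsorted(positions))
    stop("probe positions must be sorted", call. = FALSE)
  pass <- pvalues <= cutoff
  r <- rle(pass)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_probes
  runs <- Map(seq.int, starts[keep], ends[keep])
  if (length(runs) < 2) return(runs)
  merged <- list(runs[[1]])
  for (k in 2:length(runs)) {
    prev <- merged[[length(merged)]]
    gap <- positions[runs[[k]][1]] - positions[prev[length(prev)]]
    if (gap <= merge_gap) {
      merged[[length(merged)]] <- c(prev, runs[[k]])
    } else {
      merged[[length(merged) + 1L]] <- runs[[k]]
    }
  }
  merged
}

#' Sliding-window peak finding
#'
#' Computes probe stats and windowed enrichment p-values, then segments each
#' promoter into candidate peaks with [probe_runs()]. Per peak it reports:
#' within-peak per-group median log2 ratio (over all member probe x replicate
#' values), the median M' of member probes, the fraction of member probes
#' whose linear-scale CV is `<= max_cv` in both groups, a peak-level
#' p-value (`peak_p`: the doubled one-sided KS test of the replicate-pair
#' differences of all probes within the peak span extended by half a window,
#' against the experiment-wide distribution -- a single test rather than a
#' combination of the heavily dependent member-probe p-values), the mean of
#' `-log10(probe p)` (`peak_score`), and the direction implied by the sign
#' of the median M'.
#'
#' @param x a `ratio_set`.
#' @param window_bp sliding-window width in bp.
#' @param min_probes minimum probes per peak.
#' @param probe_p_cutoff probe-level p cutoff for run membership.
#' @param merge_gap maximum bp gap between merged runs.
#' @param max_cv probe-level CV bound used for the reported pass fraction.
#' @param control,treated group labels.
#' @return data.frame of peaks: `chrom`, `start`, `end` (0-based half-open),
#'   `gene_id`, `n_probes`, `probe_ids`, `median_control`, `median_treated`,
#'   `median_mprime`, `cv_pass_frac`, `peak_score`, `peak_p`, `direction`.
#' @export
find_peaks <- function(x, window_bp = 750, min_probes = 2,
                       probe_p_cutoff = 0.1, merge_gap = 500, max_cv = 0.8,
                       control = "control", treated = "treated") {
  stats <- compute_probe_stats(x, control, treated)
  pvals <- compute_probe_pvalues(x, window_bp, control, treated)
  ci <- which(x$design$group == control)
  ti <- which(x$design$group == treated)
  D <- pair_differences(x, control, treated)
  g <- sort(as.vector(D))

  res <- list()
  for (ii in split(seq_len(nrow(stats)), stats$gene_id)) {
    runs <- probe_runs(stats$position[ii], pvals[ii],
                       cutoff = probe_p_cutoff, min_probes = min_probes,
                       merge_gap = merge_gap)
    for (run in runs) {
      idx <- ii[run]
      pp <- pvals[idx]
      span <- range(stats$position[idx])
      ext <- ii[stats$position[ii] >= span[1] - window_bp / 2 &
                  stats$position[ii] <= span[2] + window_bp / 2]
      peak_p <- ks_shift_pvalue(as.vector(D[ext, , drop = FALSE]), g)
      med_mp <- median(stats$mprime[idx])
      res[[length(res) + 1L]] <- data.frame(
        chrom = stats$chrom[idx[1]],
        start = min(stats$position[idx]) - 1L,
        end = max(stats$position[idx]),
        gene_id = stats$gene_id[idx[1]],
        n_probes = length(idx),
        probe_ids = paste(stats$probe_id[idx], collapse = ","),
        median_control = median(x$ratios[idx, ci]),
        median_treated = median(x$ratios[idx, ti]),
        median_mprime = med_mp,
        cv_pass_frac = mean(stats$cv_control[idx] <= max_cv &
                              stats$cv_treated[idx] <= max_cv),
        peak_score = mean(-log10(pmax(pp, 1e-300))),
        peak_p = peak_p,
        direction = if (med_mp > 0) "hyper" else "hypo",
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(res)) return(empty_peak_table())
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_peak_table <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             gene_id = character(), n_probes = integer(),
             probe_ids = character(), median_control = numeric(),
             median_treated = numeric(), median_mprime = numeric(),
             cv_pass_frac = numeric(), peak_score = numeric(),
             peak_p = numeric(), direction = character(),
             stringsAsFactors = FALSE)
}

#' Filter candidate peaks into DMRs
#'
#' Applies the differential-enrichment criteria: (i) at least one group's
#' within-peak median log2(MeDIP/Input) must reach `min_median_ratio` and the
#' peak's median M' must be nonzero (its sign sets the hyper/hypo direction);
#' (ii) at least `min_cv_pass` of the member probes must have CV within
#' `max_cv` in both groups (the pass fraction is computed by [find_peaks()]);
#' plus `peak_score >= min_peak_score` and `peak_p <= max_peak_p`.
#'
#' @param peaks peak table from [find_peaks()] (or any data.frame with the
#'   same columns).
#' @param min_median_ratio threshold on the larger group median (default 0.3).
#' @param min_cv_pass minimum fraction of CV-passing probes (default 0.5).
#' @param min_peak_score minimum peak score (default 2).
#' @param max_peak_p maximum combined peak p (default 0.01).
#' @return the surviving rows, with `direction` reassigned from the sign of
#'   `median_mprime`.
#' @export
filter_deps <- function(peaks, min_median_ratio = 0.3, min_cv_pass = 0.5,
                        min_peak_score = 2, max_peak_p = 0.01) {
  if (!nrow(peaks)) return(peaks)
  keep <- pmax(peaks$median_control, peaks$median_treated) >= min_median_ratio &
    abs(peaks$median_mprime) > 0 &
    peaks$cv_pass_frac >= min_cv_pass &
    peaks$peak_score >= min_peak_score &
    peaks$peak_p <= max_peak_p
  out <- peaks[keep, , drop = FALSE]
  if (nrow(out))
    out$direction <- ifelse(out$median_mprime > 0, "hyper", "hypo")
  rownames(out) <- NULL
  out
}

#' Call DMRs from a ratio set
#'
#' Convenience wrapper: [find_peaks()] followed by [filter_deps()].
#'
#' @inheritParams find_peaks
#' @inheritParams filter_deps
#' @return DMR table (see [filter_deps()]).
#' @export
call_dmrs <- function(x, window_bp = 750, min_probes = 2,
                      probe_p_cutoff = 0.1, merge_gap = 500, max_cv = 0.8,
                      min_median_ratio = 0.3, min_cv_pass = 0.5,
                      min_peak_score = 2, max_peak_p = 0.01,
                      control = "control", treated = "treated") {
  peaks <- find_peaks(x, window_bp = window_bp, min_probes = min_probes,
                      probe_p_cutoff = probe_p_cutoff, merge_gap = merge_gap,
                      max_cv = max_cv, control = control, treated = treated)
  filter_deps(peaks, min_median_ratio = min_median_ratio,
              min_cv_pass = min_cv_pass, min_peak_score = min_peak_score,
              max_peak_p = max_peak_p)
}

#' Write a DMR table as TSV (and optionally BED6)
#'
#' The TSV holds the full peak table; the BED6 name field is
#' `gene_id|direction` and the score is `min(1000, round(100 * peak_score))`.
#' No peak-level multiple-testing adjustment is applied (none is part of the
#' calling procedure); a header comment in the TSV records this.
#'
#' @param dmrs DMR table from [call_dmrs()] / [filter_deps()].
#' @param tsv_path output TSV path.
#' @param bed_path optional output BED path.
#' @export
write_dmr_table <- function(dmrs, tsv_path, bed_path = NULL) {
  con <- file(tsv_path, "w")
  writeLines("# meditile DMR table; peak_p is unadjusted across peaks", con)
  write.table(dmrs, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  if (!is.null(bed_path)) {
    if (nrow(dmrs)) {
      write_bed6(dmrs$chrom, dmrs$start, dmrs$end,
                 paste(dmrs$gene_id, dmrs$direction, sep = "|"),
                 pmin(1000, round(100 * dmrs$peak_score)),
                 rep(".", nrow(dmrs)), bed_path)
    } else {
      file.create(bed_path)
    }
  }
  invisible(tsv_path)
}

#' Read a DMR table written by [write_dmr_table()]
#' @param tsv_path path to the TSV.
#' @return the DMR data.frame.
#' @export
read_dmr_table <- function(tsv_path) {
  read.delim(tsv_path, comment.char = "#", stringsAsFactors = FALSE)
}
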