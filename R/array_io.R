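#' Read a two-channel probe intensity table
#'
#' Parses one array's tab-delimited probe table with the canonical header
#' `PROBE_ID, CHR, POSITION, GENE_ID, MEDIP_SIGNAL, INPUT_SIGNAL`
#' (one row per probe; positions are 1-based). Intensities must be strictly
#' positive and probe ids unique within the array.
#'
#' @param path path to a tab-delimited probe table.
#' @return A `data.frame` with columns `probe_id`, `chrom`, `position`,
#'   `gene_id`, `medip`, `input`.
#' @seealso [write_probe_table()], [build_ratio_set()]
#' @export
read_probe_table <- function(path) {
  if (!file.exists(path)) stop("probe table not found: ", path, call. = FALSE)
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  wanted <- c("PROBE_ID", "CHR", "POSITION", "GENE_ID",
              "MEDIP_SIGNAL", "INPUT_SIGNAL")
  missing <- setdiff(wanted, names(d))
  if (length(missing))
    stop("probe table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- data.frame(
    probe_id = as.character(d$PROBE_ID),
    chrom    = as.character(d$CHR),
    position = as.integer(d$POSITION),
    gene_id  = as.character(d$GENE_ID),
    medip    = as.numeric(d$MEDIP_SIGNAL),
    input    = as.numeric(d$INPUT_SIGNAL),
    stringsAsFactors = FALSE
  )
  bad <- which(!is.finite(out$medip) | out$medip <= 0)
  if (length(bad))
    stop(sprintf("non-positive MEDIP_SIGNAL for probe '%s' (row %d)",
                 out$probe_id[bad[1]], bad[1]), call. = FALSE)
  bad <- which(!is.finite(out$input) | out$input <= 0)
  if (length(bad))
    stop(sprintf("non-positive INPUT_SIGNAL for probe '%s' (row %d)",
                 out$probe_id[bad[1]], bad[1]), call. = FALSE)
  dup <- which(duplicated(out$probe_id))
  if (length(dup))
    stop(sprintf("duplicate probe id '%s' (row %d)",
                 out$probe_id[dup[1]], dup[1]), call. = FALSE)
  out
}

#' Write a probe intensity table
#'
#' Inverse of [read_probe_table()]; emits the canonical tab-delimited header.
#'
#' @param probes data.frame as returned by [read_probe_table()].
#' @param path output path.
#' @export
write_probe_table <- function(probes, path) {
  d <- data.frame(
    PROBE_ID = probes$probe_id, CHR = probes$chrom,
    POSITION = probes$position, GENE_ID = probes$gene_id,
    MEDIP_SIGNAL = probes$medip, INPUT_SIGNAL = probes$input
  )
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-probe log2 enrichment ratio
#'
#' `log2(MeDIP / Input)` for strictly positive channel intensities; the core
#' enrichment readout of a two-colour MeDIP array.
#'
#' @param medip,input positive intensity vectors (recycled as usual).
#' @return numeric vector of log2 ratios.
#' @examples
#' compute_log2_ratio(16, 8)  # 1
#' @export
compute_log2_ratio <- function(medip, input) {
  if (any(!is.finite(medip) | medip <= 0))
    stop("medip intensities must be positive and finite", call. = FALSE)
  if (any(!is.finite(input) | input <= 0))
    stop("input intensities must be positive and finite", call. = FALSE)
  log2(medip / input)
}

#' Normalize an array's log2 ratios
#'
#' `"median"` subtracts the per-array median so the array's median log-ratio
#' is exactly 0 (idempotent); `"none"` returns the input unchanged and is the
#' default for synthetic data, whose channels are already on a common scale.
#'
#' @param ratios numeric vector of finite log2 ratios.
#' @param method `"median"` or `"none"`.
#' @return numeric vector of the same length.
#' @export
normalize_array <- function(ratios, method = c("none", "median")) {
  method <- match.arg(method)
  if (any(!is.finite(ratios))) stop("ratios must be finite", call. = FALSE)
  switch(method,
    none = ratios,
    median = ratios - median(ratios)
  )
}

#' Assemble replicate arrays into a ratio set
#'
#' Validates that all arrays share one probe set, canonicalizes probe order
#' by (chrom, position, probe id), computes per-array log2(MeDIP/Input) and
#' applies the chosen normalization. The result is the container consumed by
#' the DMR caller.
#'
#' @param tables named list of probe data.frames (see [read_probe_table()]);
#'   names are array ids.
#' @param design data.frame with columns `array_id`, `group`, `replicate`;
#'   `array_id` must match `names(tables)`.
#' @param normalize normalization method passed to [normalize_array()].
#' @return An object of class `ratio_set`: a list with `probes` (annotation
#'   data.frame in canonical order), `ratios` (probes x arrays matrix of
#'   log2 ratios) and `design`.
#' @export
build_ratio_set <- function(tables, design, normalize = c("none", "median")) {
  normalize <- match.arg(normalize)
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    stop("'tables' must be a named list of arrays", call. = FALSE)
  if (!all(c("array_id", "group", "replicate") %in% names(design)))
    stop("design needs columns array_id, group, replicate", call. = FALSE)
  if (!setequal(design$array_id, names(tables)))
    stop("design array_id does not match names(tables)", call. = FALSE)
  design <- design[match(names(tables), design$array_id), , drop = FALSE]

  ref <- tables[[1]]
  ord <- order(ref$chrom, ref$position, ref$probe_id)
  probes <- ref[ord, c("probe_id", "chrom", "position", "gene_id")]
  rownames(probes) <- NULL

  ratios <- matrix(NA_real_, nrow(probes), length(tables),
                   dimnames = list(probes$probe_id, names(tables)))
  for (a in names(tables)) {
    t <- tables[[a]]
    if (!setequal(t$probe_id, probes$probe_id))
      stop("array '", a, "' has a different probe set", call. = FALSE)
    idx <- match(probes$probe_id, t$probe_id)
    ratios[, a] <- normalize_array(
      compute_log2_ratio(t$medip[idx], t$input[idx]), normalize)
  }
  structure(list(probes = probes, ratios = ratios, design = design),
            class = "ratio_set")
}

#' @export
print.ratio_set <- function(x, ...) {
  cat(sprintf("ratio_set: %d probes x %d arrays (%s)\n",
              nrow(x$probes), ncol(x$ratios),
              paste(sprintf("%s=%d", names(table(x$design$group)),
                            as.integer(table(x$design$group))),
                    collapse = ", ")))
  invisible(x)
}
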