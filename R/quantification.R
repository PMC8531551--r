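#' Read a qPCR Ct table
#'
#' CSV with columns `sample, maternal_diet, offspring_diet, gene,
#' ct_target, ct_reference`. Ct values outside the usual 10-40 cycle range
#' trigger a warning (they usually indicate failed wells).
#'
#' @param path CSV path.
#' @return data.frame of Ct records.
#' @export
read_qpcr_table <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "maternal_diet", "offspring_diet", "gene",
            "ct_target", "ct_reference")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("qPCR table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  ct <- c(d$ct_target, d$ct_reference)
  if (any(!is.finite(ct))) stop("non-finite Ct values", call. = FALSE)
  if (any(ct < 10 | ct > 40))
    warning("Ct values outside the typical 10-40 cycle range")
  d
}

#' Comparative-Ct (2^-ddCt) relative expression
#'
#' Per sample: `dCt = ct_target - ct_reference`; `ddCt = dCt - mean(dCt)` of
#' the reference group (default maternal NC, offspring CD); fold change
#' `2^-ddCt`. Computed per gene. By construction the reference group's fold
#' changes have geometric mean 1.
#'
#' @param records Ct data.frame (see [read_qpcr_table()]).
#' @param ref_maternal,ref_offspring factor levels defining the reference
#'   group.
#' @return the input with `dct`, `ddct` and `fold` columns appended.
#' @export
relative_expression <- function(records, ref_maternal = "NC",
                                ref_offspring = "CD") {
  records$dct <- records$ct_target - records$ct_reference
  out <- lapply(split(records, records$gene), function(d) {
    ref <- d$maternal_diet == ref_maternal &
      d$offspring_diet == ref_offspring
    if (!any(ref))
      stop("empty reference group for gene ", d$gene[1], call. = FALSE)
    d$ddct <- d$dct - mean(d$dct[ref])
    d$fold <- 2^(-d$ddct)
    d
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' MeDIP-qPCR percent-of-input enrichment
#'
#' `%input = 100 * 2^((ct_input - log2(dilution_factor)) - ct_ip)`: the
#' immunoprecipitated material as a percentage of the input DNA after
#' correcting the input Ct for its dilution. Monotone decreasing in
#' `ct_ip`.
#'
#' @param ct_ip Ct of the immunoprecipitated sample.
#' @param ct_input Ct of the (diluted) input sample.
#' @param dilution_factor fraction of input assayed, e.g. 10 for a 1:10
#'   dilution; must be > 0.
#' @return percentage (vectorized).
#' @export
percent_input <- function(ct_ip, ct_input, dilution_factor = 1) {
  if (any(dilution_factor <= 0))
    stop("dilution_factor must be > 0", call. = FALSE)
  100 * 2^((ct_input - log2(dilution_factor)) - ct_ip)
}

#' Two-factor ANOVA with type-II sums of squares
#'
#' The group-comparison model used throughout: main effects of the two
#' factors (e.g. maternal diet and offspring diet) and their interaction,
#' with type-II sums of squares so unbalanced designs are handled (for
#' balanced designs type I/II/III coincide). Also reports per-cell mean,
#' SEM and n.
#'
#' @param values numeric response vector.
#' @param factor_a,factor_b factors (or coercible); every a x b cell must
#'   contain at least 2 observations.
#' @return list with `table` (data.frame: effect, sumsq, df, F, p) and
#'   `cells` (data.frame: level_a, level_b, n, mean, sem).
#' @export
two_way_anova <- function(values, factor_a, factor_b) {
  a <- factor(factor_a)
  b <- factor(factor_b)
  counts <- table(a, b)
  if (any(counts < 2))
    stop("every factor-level cell needs >= 2 observations", call. = FALSE)
  fit <- lm(values ~ a * b)
  # car refuses a perfect fit (zero residual SS); the sequential table is
  # exact there (and equals type II for the balanced fixtures it arises in)
  an <- tryCatch(car::Anova(fit, type = 2),
                 error = function(e) suppressWarnings(stats::anova(fit)))
  eff <- rownames(an)
  lab <- c(a = "factor_a", b = "factor_b", `a:b` = "interaction",
           Residuals = "residuals")
  tab <- data.frame(effect = unname(lab[eff]), sumsq = an[["Sum Sq"]],
                    df = an[["Df"]], F = an[["F value"]],
                    p = an[["Pr(>F)"]], stringsAsFactors = FALSE)
  # a zero effect sum of squares is "no effect" even when the residual SS is
  # also zero (flat data would otherwise give 0/0)
  degen <- tab$effect != "residuals" & tab$sumsq < 1e-12
  tab$F[degen] <- 0
  tab$p[degen] <- 1
  cells <- expand.grid(level_a = levels(a), level_b = levels(b),
                       stringsAsFactors = FALSE)
  cells$n <- NA_integer_
  cells$mean <- NA_real_
  cells$sem <- NA_real_
  for (i in seq_len(nrow(cells))) {
    v <- values[a == cells$level_a[i] & b == cells$level_b[i]]
    cells$n[i] <- length(v)
    cells$mean[i] <- mean(v)
    cells$sem[i] <- sd(v) / sqrt(length(v))
  }
  list(table = tab, cells = cells)
}
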