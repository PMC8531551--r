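---
title: "Methods: differential methylation on MeDIP promoter tiling arrays"
author: "meditile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential methylation on MeDIP promoter tiling arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement model

A two-colour MeDIP-chip hybridizes immunoprecipitated methylated DNA (Cy5)
against total input DNA (Cy3) on a promoter tiling array. The enrichment
readout for probe $p$ on array $a$ is

$$r_{pa} = \log_2 \frac{\mathrm{MeDIP}_{pa}}{\mathrm{Input}_{pa}},$$

which cancels probe affinity because both channels see the same probe.
With replicate arrays in a control and a treated group, the per-probe
between-group statistic is

$$M'_p = \overline{r_p^{\,\mathrm{treated}}} - \overline{r_p^{\,\mathrm{control}}},$$

the difference of the group means of the log2 enrichment ratios. Positive
$M'$ means hypermethylation in the treated group; negative means
hypomethylation. Replicate consistency per probe is summarized by the
coefficient of variation of the *linear-scale* ratios $2^{r_{pa}}$
(sd/mean across replicates, per group); the CV of log ratios near zero is
ill-defined, which is why the linear scale is used.

`normalize_array()` offers per-array median centering; the default for
synthetic data is `"none"` because the simulated channels are already on a
common scale. Scanner-software normalization pipelines are proprietary and
no equivalence with any of them is claimed.

# Probe-level evidence: a windowed KS statistic

Peak finding needs a per-probe significance measure. For each probe we
collect the replicate-paired differences (treated minus control log2
ratio, replicate $r$ paired with replicate $r$) of all probes of the same
promoter within a 750 bp window centred on the probe, and compare this
local sample against the experiment-wide empirical distribution of the
same differences with a Kolmogorov–Smirnov statistic. The reported
p-value is the one-sided tail bound $\exp(-2 m D^2)$ (with $m$ the local
sample size and $D$ the KS distance in the better-supported shift
direction), doubled and capped at 1 so that testing both directions does
not make the null anti-conservative. Because the local sample is a subset
of the reference sample, ties are exact: both empirical CDFs are compared
at their right-continuous values *and* their left limits, so identical
data give $D = 0$ and $p = 1$ rather than a spurious rejection.

Using the experiment-wide distribution as the reference makes the test
self-calibrating: array-wide scale changes affect both sides equally.
The trade-off is that with a very large spiked fraction the reference is
contaminated by true signal, which is conservative.

# Peaks and the DEP filter

Candidate peaks are maximal runs of at least `min_probes` (default 2)
consecutive probes with probe $p \le 0.1$; qualifying runs separated by at
most 500 bp are merged (the failing gap probes are not counted as
members). Per peak we report:

* per-group median log2 ratio over all member probe $\times$ replicate
  values, and the median $M'$ of member probes;
* `cv_pass_frac`: the fraction of member probes whose linear-scale CV is
  $\le 0.8$ in *both* groups;
* `peak_score`: the mean of $-\log_{10}(\text{probe } p)$ over member
  probes (the conventional tiling-array peak score);
* `peak_p`: a single KS test (as above) of the replicate-pair differences
  of all probes inside the peak span extended by half a window, against
  the experiment-wide distribution.

`peak_p` is deliberately *not* a Fisher combination of the member-probe
p-values. Member probes share most of their window values, so their
p-values are strongly positively dependent; on null simulations a Fisher
combination reached nominal values near $10^{-6}$ and inflated the false
call rate several-fold. A single test over the peak's extended span uses
each observation once and needs no independence assumption; in null
simulations it keeps the fraction of promoters called below 1% at the
default thresholds.

A peak becomes a differentially methylated region (DMR) when all of the
following hold (each threshold is a config key, defaults shown):

1. the larger of the two within-peak group medians is $\ge 0.3$ — at
   least one group must be genuinely enriched;
2. the median $M'$ is nonzero, and its sign assigns the hyper/hypo
   direction (both directions are admitted; a one-sided reading would
   forbid hypomethylation calls);
3. at least half of the member probes pass the CV bound in both groups;
4. `peak_score` $\ge 2$ and `peak_p` $\le 0.01$.

No multiple-testing adjustment is applied across peaks; the output header
records this. Raising any threshold can only shrink the call set, and
swapping the group labels negates every $M'$ and flips every direction
while leaving peak boundaries, scores and p-values unchanged — both
properties are enforced by tests.

# CpG-density classes

Promoters are classified from sequence alone with 500 bp windows: the CpG
observed/expected ratio of a window of effective length $L$ (ambiguous
bases excluded) is $\#\mathrm{CpG} \cdot L / (\#C \cdot \#G)$, zero when
$C$ or $G$ is absent. A promoter is **HCP** if any window has GC fraction
$> 0.55$ and o/e $> 0.75$; **LCP** if no window has o/e $> 0.48$; **ICP**
otherwise — the standard three-class promoter scheme. Windows are scanned
at a 5 bp step by default on both the sequence and its reverse complement
(CpG is palindromic, but window placement at the edges is not); the final
window is always included. Windows with more than 10% ambiguous bases are
skipped; sequences shorter than the window are scored whole. A step-1
scan is available and is used as the exhaustive oracle in the tests; the
stepped scan may miss a marginal window, so tests assert it never crosses
the HCP/LCP divide relative to the step-1 scan.

# Gene-set over-representation

Differentially methylated genes (a DMR maps to its promoter's gene;
multiple DMRs in one gene count once) are tested against user-supplied
GMT collections with the hypergeometric upper tail
$P(X \ge k)$, fold enrichment $(k/n)/(K/N)$, and Benjamini–Hochberg
adjustment. The background is the set of genes represented on the array
— the only defensible universe for a promoter-array design. Significance
follows a dual scheme: pathway-type collections require at least 2 hit
genes, BH FDR $< 0.05$ and fold $\ge 1.50$; ontology-type collections
require at least 2 hit genes, raw $P < 0.01$ and fold $\ge 1.10$ (the FDR
column is still reported). The raw-P rule for ontology collections is a
deliberate choice where the two published descriptions of the scheme
disagree; both columns are emitted so either rule can be re-applied. An
EASE-penalised variant (overlap reduced by one) is available behind a
flag but off by default.

# qPCR quantification

* **Relative expression**: $\Delta Ct = Ct_\mathrm{target} -
  Ct_\mathrm{reference}$ per sample; $\Delta\Delta Ct$ subtracts the mean
  $\Delta Ct$ of the reference group (default maternal-NC/offspring-CD,
  the conventional baseline cell); fold $= 2^{-\Delta\Delta Ct}$. The
  reference group's folds have geometric mean exactly 1.
* **MeDIP-qPCR**: the percent-of-input readout
  $100 \times 2^{(Ct_\mathrm{input} - \log_2 d) - Ct_\mathrm{IP}}$ with
  dilution factor $d$; this standard form is used because enrichment
  units are otherwise undefined, and it is labelled as such in output.
* **Group comparisons**: two-factor ANOVA (factor A $\times$ factor B
  with interaction) using type-II sums of squares so unbalanced designs
  are handled; for balanced designs all SS types coincide. Flat data
  (zero effect *and* zero residual SS) reports $F = 0$, $p = 1$ rather
  than 0/0. Cell means $\pm$ SEM are reported alongside.

# The synthetic-array generator

The generator emulates a scaled-down promoter tiling design: 2,000
promoters, 8 probes each, evenly spaced over a strand-aware
$-1300..+500$ bp TSS window, 3 replicate arrays per group — sizes chosen
so a full pipeline run takes well under a minute while preserving the
probe spacing (~225 bp) that the 750 bp window scan sees on the full
22,327-promoter geometry, which remains a configuration choice.

Intensity model (all on the log2 scale): per-probe affinity baseline
$\beta_p \sim N(10, 1)$ shared by both channels and all arrays (so it
cancels from the ratio — the reason MeDIP/Input ratios are used at all);
a baseline methylation enrichment of 1.0 added to every promoter's MeDIP
channel; i.i.d. Gaussian channel noise with sd 0.25. A fraction
(default 5%) of promoters is spiked in the treated group only, by
$\pm 1.0$ log2 units (hyper/hypo 50/50). The baseline enrichment of 1.0
models a genuinely methylated promoter compartment; without it a
hypomethylation spike would leave both group medians near zero and the
median-ratio filter would silently discard every hypo call, which would
contradict the two-sided design of the filter. `noise_sd` and
`effect_size` are both log2-scale quantities, kept on one scale
deliberately. No public noise calibration exists for the real arrays, so
these are plausible-scale choices, not fitted ones.

Sequences are generated per intended CpG class: HCP ~60% GC with
undepleted CpGs (o/e near 1); ICP ~46% GC with CpGs retained at 60%
(o/e ~0.6); LCP ~40% GC with CpGs retained at 5% (o/e ~0.05). Depletion
mutates the G of a CpG to A, which can never create a new CpG, so the
retention rate maps directly to the o/e ratio. The intended class is
recovered by the classifier for $\ge 95\%$ of promoters (in practice
~100%).

qPCR tables are a balanced 2x2 design (maternal $\times$ offspring diet,
default 8 samples per cell) with per-cell $\Delta Ct$ means, Gaussian Ct
noise (0.3 cycles) around a reference gene at ~18 cycles.

Determinism: one top-level seed; every stage derives its own RNG stream
from it, so changing e.g. qPCR settings never perturbs the arrays, and
identical configurations reproduce byte-identical files.

**What the generator does not model**: dye bias, spatial array
artifacts, GC-dependent probe affinity, probe cross-hybridization,
biological replicate heterogeneity beyond i.i.d. noise, and correlated
methylation between neighbouring promoters. Passing spike-in benchmarks
therefore demonstrates the correctness and calibration of the pipeline's
statistics under this idealized model, not performance on real arrays.

# Numerical choices and degenerate inputs

* Probe order is canonicalized by (chromosome, position, probe id);
  input tables are 1-based, all emitted BED is 0-based half-open.
* Probe p-values are floored at $10^{-300}$ before $-\log_{10}$.
* Runs are maximal; a probe belongs to exactly one peak; merged runs
  exclude the failing gap probes from membership but span them
  genomically.
* A peak's median $M'$ of exactly 0 is direction-less and filtered out.
* Empty DMR sets propagate: header-only TSV, empty BED, composition
  percentages reported as `NA`.
* With unequal replicate counts the pairing uses the first
  $\min(n_1, n_2)$ replicates of each group in replicate order.

# Problem sizes used in the checks

The packaged tests and the acceptance script use 2,000-promoter
experiments (16,000 probes, 6 arrays) for spike-in recovery over ten
seeds plus a null run, 150–300-promoter experiments for pipeline and
calibration properties, 200 random small fixtures for the segmentation
oracle, and 100 random 800 bp sequences for the classification oracle.
These sizes give stable empirical rates while keeping a full run fast.

# Known limitations

* No bit-compatibility with any vendor peak caller is claimed; the probe
  and peak p-values are this package's own definitions, documented above.
* No inter-array loess/quantile normalization or background correction;
  arrays are assumed individually sane.
* Genome-wide CpG-island detection and repeat masking are out of scope;
  classification is confined to the supplied promoter windows.
* Peak-level p-values are unadjusted across peaks.
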