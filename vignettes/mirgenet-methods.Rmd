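---
title: "Methods: miRNA-mRNA network inference and liquid-biopsy triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA-mRNA network inference and liquid-biopsy triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirgenet)
library(dplyr)
```

## The problem

miRNAs repress gene expression post-transcriptionally, and miRNAs released
into body fluids (plasma, serum, exosomes) are attractive non-invasive
cancer biomarkers. Given paired tumor/normal small-RNA and mRNA profiles
from the same patients, `mirgenet` nominates candidate biomarker miRNAs in
four stages:

1. **Differential expression.** Features are normalized to reads per
   million (RPM) and tested for a tumor-vs-normal shift; candidates must
   pass adjusted $P < 0.05$ and linear $|FC| > 2$, both strict.
2. **Fold-change correlation.** For each up-regulated miRNA and each DE
   gene, Pearson's $r$ is computed between the two per-patient
   $\log_2 FC$ vectors. Repression shows up as anticorrelation across
   patients; pairs with $r < -0.5$ and $P < 0.05$ (both strict) are
   selected.
3. **Catalogue confirmation.** Selected pairs are retained only when the
   interaction is supported by a catalogue of experimentally validated or
   predicted miRNA-target interactions, and the confirmed pairs form a
   directed bipartite miRNA $\to$ gene network per cancer type.
4. **Biomarker triage.** Network miRNAs are checked against a large-cohort
   evidence table, then against fluid-detection levels, yielding
   circulating (`c`), exosomal (`e`) and bronchoalveolar-lavage (`l`)
   flags and a final liquid-biopsy signature.

Every stage is a data-frame-in / tibble-out function, so the pipeline can
be driven interactively with pipes, from a YAML config via
`run_pipeline()`, or from the shell via `inst/scripts/mirgenet.R`.

## Statistical components

### The DE test is a declared stand-in

External count-model DE callers sit outside this package's scope. The
built-in test is deliberately simple and fully specified: per patient
$p$, $\mathrm{log_2FC}_{f,p} = \log_2\!\frac{\mathrm{RPM}^{tumor}_{f,p} +
c}{\mathrm{RPM}^{normal}_{f,p} + c}$ with pseudocount $c = 1$ RPM by
default; the cohort effect is the mean over patients; the p-value is a
two-sided one-sample t-test of the per-patient values against zero; and
multiplicity is adjusted by Benjamini-Hochberg within each assay. The
pipeline only consumes `(log2fc, p_adj, direction)`, so results from a
negative-binomial caller can be substituted via `import_de_table()`
without touching anything downstream.

Numerical edge cases are fixed rather than left to NaN propagation: a
feature whose per-patient fold changes are all equal and non-zero gets
$p = 0$ (with a message); all equal and zero gets $p = 1$. A pseudocount
of zero is allowed only when no RPM value is zero.

### Correlation and its p-value

`pearson_r()` is the standard product-moment coefficient; constant vectors
raise an error naming the feature. `pearson_pvalue()` uses the exact
t-transform $t = r\sqrt{(n-2)/(1-r^2)}$ with $n-2$ degrees of freedom, and
$p = 0$ at $r = \pm 1$. At $n = 8$ patients the joint selection
$r < -0.5 \wedge P < 0.05$ is dominated by the significance bound, which
corresponds to $|r| > 0.707$: the selection region is one tail of a
two-sided test, so its null rate is at most $\alpha/2$.

Correlation p-values are **not** multiplicity-adjusted by default: the
selection is a screening step whose output is immediately intersected
with an external interaction catalogue, which is the error-control step
that matters. `select_negative(..., adjust = "bh")` is available for users
who prefer adjusted screening.

The bound is implemented as strictly $r < -0.5$, with $r = -1$ retained:
an exact $-1$ on measured data is a measure-zero event, and excluding it
would discard only perfect anticorrelation, the strongest possible signal.

### Confirmation arithmetic

A pair is confirmed when it appears in the catalogue under *either*
evidence class (experimental or predicted); requiring both would need a
semantics the catalogue format does not encode. Identifiers are matched
exactly after a normalization hook (whitespace trimmed, Unicode dashes
unified to ASCII hyphen); no alias resolution is attempted. The reported
percentage is rounded half away from zero to one decimal.

### Network conventions

Edges are directed miRNA $\to$ gene, encoding repression. Nodes and edges
are kept in C-locale lexicographic order so GraphML and TSV exports are
byte-stable across machines and re-imports reconstruct identical objects.
`combined_summary()` **sums** per-network counts by default, matching the
convention of per-cohort totals in which a feature shared by two cancers
is counted once per cancer; `dedupe = TRUE` gives the cross-network union
instead (on the packaged lung tables the two differ because one miRNA and
one gene occur in both networks).

### Detection bins and the biomarker flags

Fluid RPM levels map to symbols as $[0, 10) \to$ `-`, $[10, 100] \to$ `+`,
$(100, 1000] \to$ `++`, $(1000, \infty) \to$ `+++`. The published legend
leaves the open intervals $(100, 101)$ and $(1000, 1001)$ undefined; the
bins here close each boundary on the lower class so that every
non-negative RPM has exactly one symbol. The flags are then
`c = plasma > "-" | serum > "-"`, `e = exosomes > "-"`,
`l = bronchoalveolar > "-"`, and `liquid_eligible = c | e` —
bronchoalveolar lavage alone never qualifies because the sampling is
itself invasive. The packaged symbol table stores one row per miRNA and
fluid; its segmentation of the published run-together symbol strings was
chosen to be consistent with the published per-miRNA flags, and only the
flags (not symbol magnitudes) drive any downstream result.

`cohort_filter()` treats a missing evidence row as *retain with warning*:
absence of evidence in an external cohort database is not evidence of
absence. The packaged evidence table has explicit rows for every
candidate, so fixture-driven results never hit this branch. Tumor labels
in the final signature come from the evidence table (the cancers in which
the large cohort confirms the expression change), not from network
membership, which is why a miRNA found in only one cancer's network can
carry a two-cancer label.

## The cohort simulator

`simulate_cohort()` generates the kind of data the pipeline consumes: two
count matrices (miRNA and mRNA) over the same patients, two samples per
patient, fully paired, with known ground truth.

**Mechanism.** Each up-regulated miRNA $m$ draws a patient-level shift
$L_{m,p} \sim N(\mu_{up}, \sigma_{pat})$ (log2 units). Each planted pair
$(m, g)$ sets the gene's shift to $-\beta L_{m,p} + N(0, \sigma_{res})$;
independent DE genes draw their own shifts with random sign; all other
features are flat. Normal-sample means come from a log-uniform baseline
draw, tumor means are baseline $\times\, 2^{shift}$, each column is rescaled
so its expected total equals the library size, and counts are negative
binomial with variance $\mu + \alpha\mu^2$.

**Why the defaults look the way they do.** The defaults are chosen for
testability at the cohort size the pipeline targets (8 patients), not for
biological realism:

* $\mu_{up} = 4$ (16-fold) with $\sigma_{pat} = 2$: at $n = 8$ the
  selection bound needs $|r| > 0.707$ and the BH-adjusted DE gate at
  $m$ of several hundred features needs per-feature $|t|$ well above 4;
  both require patient-level signal variance that dominates every noise
  source.
* Differential features draw their baselines from low sub-ranges
  (miRNA 20-200 RPM, genes 50-500 RPM) while flat features span
  100-50000 / 200-20000 RPM. RPM is compositional: every feature's
  observed fold change absorbs $-\log_2$ of the per-patient total-mass
  ratio, and with 16-fold shifts the lognormal inflation of
  $E[2^{shift}]$ would otherwise make this common-mode term large enough
  to corrupt both the DE means and the correlations. Keeping differential
  features a small fraction of library mass bounds the term; it also
  mirrors the biological observation that strongly tumor-induced miRNAs
  are typically rare in normal tissue.
* Dispersion $\alpha = 0.002$ and library size $10^7$: the dispersion
  here is technical count noise only — biological patient-to-patient
  variability is carried explicitly by the patient-level shifts, not
  folded into the NB variance as in cohort-level count models.

**Reproducibility.** A single seed drives hierarchical streams: one for
the design (which features shift, which pairs are planted) and one per
feature for value and count draws, so identical parameters give
bit-identical cohorts and adding features leaves earlier features'
baseline and shift draws untouched. (Count *values* still change when
features are added, because per-column library scaling couples the means;
that coupling is what keeps column sums at the library size.)

**What the simulator does not emulate.** Sequencing reads, adapters and
alignment; isomiR structure; batch effects; unpaired or missing samples;
count-level correlation between miRNA and mRNA libraries beyond the
planted couplings; and realistic effect-size distributions. Passing the
recovery tests therefore demonstrates that the pipeline's statistics do
what they claim under the stated model — not that real cohorts of 7-8
patients carry this much signal.

## Test and verification sizes

The test suite and the acceptance script use: packaged published tables
for all fixture checks (instantaneous); 20 simulated cohorts (300 miRNAs,
600 genes, 8 patients) for planted-pair recall at $\beta = 1$,
$\sigma_{res} = 0.1$; 200 null cohorts (40 miRNAs, 80 genes) for the
selection's null calibration; exhaustive permutation oracles up to
$n = 6$ (720 permutations); and Benjamini-Hochberg reference comparisons
up to $m = 10^4$. Recall is defined over planted pairs whose two members
pass their DE filters — a planted pair whose miRNA or gene fails DE never
reaches the correlation stage, by design.

## Known limitations

* The DE stand-in is a t-test on log-ratios, which is anti-conservative
  for very low counts; for real cohorts, import results from a count
  model instead.
* Per-pair patient intersection assumes the same patient identifiers
  across assays; there is no fuzzy matching.
* The confirmation step is only as good as the supplied catalogue; no
  target prediction is performed.
* `tumor_secretion_flag()` implements only the comparison rule (strict
  inequality of exosomal RPM from tumor vs healthy tissue) on
  user-supplied numbers; it does not model measurement uncertainty.
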