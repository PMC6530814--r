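---
title: "TF-gene scores, confounders, and expression models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TF-gene scores, confounders, and expression models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Predictive models of gene expression built from transcription factor (TF)
binding evidence are widely used to nominate regulators: genes are rows, TFs
are columns, and the coefficients of a sparse regression of expression on
the TF-gene scores are read as regulatory importance. The catch is that
TF-gene scores derived from either TF ChIP-seq peaks or from motif
affinities in open chromatin share strong per-gene components — how many
peaks a gene has, how long they are, how strong the accessibility signal is
— that have nothing to do with any particular TF. A model can predict
expression well from this shared chromatin signal alone, so good
performance does not certify that the per-TF coefficients mean anything.
`regscore` implements the scoring variants, the permutation null, the
normalizations and the diagnostics needed to tell these situations apart.

## Scores

All scores aggregate peak-level evidence over a window of `window` bp
(default 50 kb) centered on the gene's most 5' TSS, weighting each peak by
`exp(-d / d0)` where `d` is the distance from the peak midpoint to the TSS
and `d0 = 5000` bp by default. A peak is admitted to the window by any
overlap (midpoint containment would silently drop long boundary peaks).

With `c_p` a ChIP peak score, `a_{p,t}` the TRAP affinity of TF `t` in
open-chromatin peak `p`, `s_p` the accessibility signal, `|p|` the peak
length and `w_p` the decay weight:

| Variant | TF columns                                   | Aggregate columns |
|---------|----------------------------------------------|-------------------|
| C       | `sum c_p w_p`                                | —                 |
| CN      | C divided per gene by `Peak_Count`           | `Peak_Count`, `Peak_Length` |
| CPF     | —                                            | `Peak_Count`, `Peak_Length` |
| D       | `sum a_{p,t} w_p`                            | —                 |
| DS      | `sum a_{p,t} s_p w_p`                        | —                 |
| DN      | `sum a_{p,t} / max(|p|-|m|+1, 1) w_p`        | `Peak_Count`, `Peak_Length` |
| DSN     | as DN                                        | + `Peak_Signal`   |
| DPF     | —                                            | `Peak_Count`, `Peak_Length` |
| DPFS    | —                                            | + `Peak_Signal`   |

`Peak_Count = sum w_p`, `Peak_Length = sum |p| w_p`,
`Peak_Signal = sum s_p w_p` — all distance-weighted, and for the ChIP
aggregates summed over the peaks of every assayed TF. The DN/DSN division
by the number of candidate binding sites `|p| - |m| + 1` (`|m|` = motif
width; clamped at 1 for peaks shorter than the motif, whose affinity is 0
anyway) removes the mechanical advantage long peaks have when affinities
sum over all windows. Genes with no peaks get 0 in CN rather than NaN —
their numerators are 0 too.

## TRAP affinities

`peak_affinity()` computes the expected number of bound TF molecules: for
every window of motif width on **both** strand orientations, a logistic
occupancy `1 / (1 + exp(E/lambda - ln R0))` of the window's summed
position-specific mismatch energies, summed over windows. Windows touching
`N` contribute zero (an unknown base cannot support a confident energy
sum), and no per-site threshold is applied — affinity is continuous.
When a PSEM file does not carry its own parameters we use the reference
TRAP parameterization `lambda = 0.7`, `ln R0 = 0.584 |m| - 5.66`. The PSEM
text grammar (`>NAME [lambda=..] [ln_r0=..]` followed by `|m|` rows of four
energies) is this package's own, since no standard grammar exists.
The scan is implemented in C++ and verified against a brute-force window
enumeration oracle to 1e-9.

## The expression model

Features and response are `log2(x + 1)`-transformed; rows are the genes
shared between the feature matrix and the expression table (sorted by id).
`fit_evaluate()` runs a Monte-Carlo outer loop (default 10 random 80/20
splits): within each split, features *and* response are centered and scaled
using training rows only — per-fold standardization is the only reading
that cannot leak held-out information — and `(alpha, lambda)` are selected
by minimizing the 6-fold inner cross-validation MSE over an `alpha` grid
and a per-`alpha` path of 100 log-spaced `lambda` values spanning four
decades below the smallest all-zeroing value (the `lambda.min` rule).
Coefficients are refit on the full training split at the chosen pair. The
penalty is written as `lambda * (alpha ||b||_2^2 + (1-alpha) ||b||_1)`, so
`alpha = 1` is ridge and `alpha = 0` lasso; this is the reverse of the
glmnet convention and is mapped internally. The headline test metric is the
Spearman correlation between predicted and observed held-out expression
(MSE is reported alongside); a constant prediction scores 0.

## Permutation null and diagnostics

`permute_rows()` shuffles each gene's feature values independently,
destroying TF identity while conserving every per-gene marginal — exactly
the confounders under suspicion. The default scope leaves the 2–4 aggregate
columns untouched when present (shuffling a tiny aggregate block into TF
positions is not a meaningful null for per-TF information); `all_columns`
reproduces whole-row shuffling and is what the end-to-end
original-versus-permuted contrast uses, because that contrast is about the
entire matrix. Diagnostics: `pairwise_correlation()` (median off-diagonal
Spearman between TF columns), `feature_confounder_correlation()` (each TF
column against each aggregate), `coefficient_stability()` (across-fold sd),
`expressed_top_tf_check()` (are the model's top regulators expressed?),
`gold_standard_eval()` (precision/recall of the coefficient ranking against
a trusted regulator set) and `overlap_fraction()` (peak-set coverage).

For `gold_standard_eval()` ties are grouped at a single operating point and
the area under the precision-recall curve uses nonlinear interpolation
(false positives grow linearly in true positives between operating points,
and the resulting precision integral has a closed form). Ranking is by
signed coefficient by default; `absolute = TRUE` ranks by magnitude. TFs
with zero coefficients count as not retrieved; gold-standard members never
retrieved are false negatives, so maximal recall can stay below 1.

## The synthetic benchmark

`generate_fixture()` builds a complete dataset — genome, genes, peaks,
motifs, expression — with known ground truth. What it emulates:

* a latent per-gene regulatory **activity** (log-normal, sd 0.6 on the log
  scale) that drives peak count (Poisson, mean 4 per 50 kb window, at least
  one peak per gene), accessibility signal (activity times log-normal
  noise, sd 0.4) and — scaled by the `length_confounding` dial, default
  0.5 — peak length (log-normal around 300 bp, residual spread 0.1);
* random width-10 energy matrices with the reference TRAP binding constant,
  giving a consensus-site occupancy of about 0.55 and appreciable
  background affinity, so raw TF scores inherit the peak-length and
  peak-count confounding that the diagnostics are meant to expose;
* per (gene, TF) planting: with probability 0.15 a gene receives 2–4
  consensus sites of that TF in one promoter-proximal peak (within `d0` of
  the TSS). The decay-weighted binding evidence lands in the feature
  matrix; the *dose* that enters expression is the raw affinity gain, kept
  free of the peak geometry so that causal effects are independent of
  chromatin activity by construction;
* expression, linear on the log2 scale (matching the regression model
  class, so parameter recovery is a fair test): standardized log-dose of
  each of the 5 causal TFs (weight 1) plus the standardized log-activity
  (weight 1.5) plus Gaussian noise with sd equal to 0.5 times the sd of
  the systematic part; the result is exponentiated to a TPM-like scale.

What it does **not** emulate: realistic nucleotide composition, motif
families and co-binding, indirect (tethered) binding, replicate-level
technical noise, or ENCODE-scale data volumes. Passing tests on this
fixture show the machinery is correct and that the documented qualitative
behaviors (permutation contrast, grouping effect, confounder reduction by
site-count normalization) hold where they are planted — not that any
particular biological dataset will show them at the same magnitude.

Everything is reproducible from the seed, including byte-identical files
when an output directory is given.

## Numerical and design choices

* Distance is measured from the peak midpoint (`floor((start+end)/2)`),
  symmetric under peak extension; coordinates are 0-based half-open
  internally, converted on GTF read.
* One window per gene at the most 5' transcript start; genes without
  transcript records use their own record's 5' end; conflicting strands
  within a gene id are an error.
* log base 2 with pseudo-count 1 for both features and expression; the base
  only rescales coefficients uniformly.
* Degenerate inputs: constant response is an error; a constant feature
  column standardizes to zeros; constant columns are excluded (with a
  warning) from correlation medians; a Spearman correlation of a constant
  prediction is reported as 0.
* The benchmark in the test suite and the acceptance script runs 2000
  genes and 50 TFs with 10 outer folds and an `alpha` grid of
  0, 0.25, ..., 1; the package default grid is the finer 0.01 step stated
  with the model, and the benchmark's coarser grid is part of its stated
  problem size. The confounder-dial experiment runs at 1500 genes and
  20 TFs.

## Known limitations

* Affinity annotation is exact but exhaustive; for genome-scale inputs with
  hundreds of motifs the scan is the dominant cost (C++, single-threaded).
* The AUPR interpolation convention matters in the third decimal place for
  short rankings; comparisons against numbers computed with step-function
  or linear-in-recall conventions should re-derive the curve from the
  reported TP/FP points.
* The permutation null keeps rows independent; it does not model
  gene-gene correlation (e.g. co-regulated clusters sharing windows).
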