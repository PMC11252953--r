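---
title: "Methods: differential co-abundance networks from affinity proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential co-abundance networks from affinity proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(sfggm)
```

# Overview

`sfggm` implements a differential co-abundance network analysis for
aptamer-based affinity proteomics of clinical samples across disease
groups. The pipeline runs, in order:

1. **Preprocessing** — limit-of-detection (LOD) quality control from buffer
   wells, three sequential aptamer filters, log2 transformation, and
   repeatability coefficients from replicate sample pairs.
2. **Differential abundance** — batched linear mixed-effect models with
   group contrasts and t-based confidence intervals.
3. **Feature selection** — the top aptamers by absolute log2 fold change.
4. **Joint graphical-model estimation** — a two-group Gaussian graphical
   model (GGM) fitted by joint node-wise group-lasso regression, with BIC
   regularization selection and stability selection over variable subsets.
5. **Network characterization** — shared/unique edge partition, degree and
   betweenness centralities, consensus Louvain communities, protein-class
   annotation.
6. **Cross-platform validation** — overlap filters, per-protein
   correlation, and fold-change comparison against mass-spectrometry (MS)
   protein quantification.

A synthetic-data generator with full ground truth (network structure,
true effects, annotation defects) supports calibration and recovery
testing throughout.

# Preprocessing

The LOD for each aptamer is computed on the log2 scale from buffer (blank)
wells as mean + 5 SD (sample SD, $n-1$ denominator). Aptamers are then
filtered in three sequential stages: (1) no UniProt mapping, (2) target
organism not human, (3) log2 signal below the LOD in *any* study sample.
An aptamer failing several criteria is counted at its first failing stage,
so stage counts always sum to input minus retained.

Repeatability coefficients are computed from replicate sample pairs. With
$d_i$ the within-pair log2 difference over $m$ pairs, the within-pair SD
is $s_w = \sqrt{\sum_i d_i^2 / (2m)}$, the repeatability coefficient is
$RC = 1.96\sqrt{2}\, s_w$ (log2 scale), reported on the fold scale as
$100\,(2^{RC}-1)$ percent. Only aptamers above the LOD in every replicate
sample are eligible; ineligible aptamers are excluded from the output
rather than reported as zero.

```{r lod-example}
buf <- intensity_matrix(
  matrix(c(2, 4, 8, 16), 4, 1,
         dimnames = list(paste0("b", 1:4), "apt_0001")), "linear")
compute_lod(buf)$lod   # 2.5 + 5 * sd(1:4) = 8.955
```

# Differential abundance

Fitting one mixed model over all aptamers at once is infeasible, so a
random permutation of the aptamers is chunked into batches of 50 and one
linear mixed model is fitted per batch on long-format data:

```
value ~ seq_id * (group + sex + age) + (1 | subject_id)
```

by REML. The random intercept accounts for the clustering of aptamer
measurements within a donor. Adjusted group means and
treatment-versus-control contrasts against the reference (healthy) group
come from `emmeans`, with Satterthwaite degrees of freedom by default
(Kenward–Roger available via `pbkrtest`). When the mixed fit fails or is
singular — always the case for a single-aptamer batch, where one
observation per subject confounds the intercept with the residual — a
fixed-effects-only model is used and flagged, and contrast degrees of
freedom fall back to the residual df.

An aptamer is called differential when its confidence interval excludes
zero; proteins are counted as differential when any of their aptamers is.

# Joint Gaussian graphical model

For groups $k = 1, \dots, K$ with standardized data $X^{(k)}$
($n_k \times p$), the estimator minimizes

$$
\sum_k \frac{1}{2 n_k}\bigl\|X^{(k)} - X^{(k)}(\Omega + \Gamma^{(k)})\bigr\|_F^2
 + \lambda_1 \sum_{i<j}\bigl\|(\Omega_{ij},\Omega_{ji})\bigr\|_2
 + \lambda_2 \sum_k \sum_{i<j}\bigl\|(\Gamma^{(k)}_{ij},\Gamma^{(k)}_{ji})\bigr\|_2
$$

over coefficient matrices with zero diagonals. $\Omega$ carries the
structure common to all groups and $\Gamma^{(k)}$ the group-specific
deviations; the group penalty over symmetric coefficient pairs enforces
symmetric edge activation. The solver (C++, block coordinate descent from
zero initialization) cycles common blocks in lexicographic $(i,j)$ order,
then specific blocks per group. Each 2-coefficient block has a closed-form
group-soft-threshold solution, with the scaling factor found by a
monotone bisection. An edge is present in group $k$ when either
coefficient of $\Theta^{(k)} = \Omega + \Gamma^{(k)}$ in its symmetric
pair is nonzero.

With $\lambda_1 = \lambda_2 = 0$ the stationary point reproduces
node-wise ordinary least squares, which the test suite verifies to 1e-6.

## Regularization selection

A two-stage BIC search scans $\lambda_1$ with $\lambda_2$ held fixed,
then scans $\lambda_2$ at the chosen $\lambda_1$:

$$
BIC = \sum_k \Bigl[\sum_j n_k \log(RSS_{jk}/n_k)\Bigr] + \log(n_k)\,2 E_k
$$

where $E_k$ is the number of active edges in group $k$. Each active edge
block contributes **two** free coefficients per group, hence the factor 2
in the model dimension; counting blocks instead of coefficients
systematically underpenalizes and selects visibly denser graphs in our
synthetic calibration.

The appropriate scale of $\lambda$ depends on $n$ and $p$ (for a
universal-threshold heuristic, $\lambda \sim \sqrt{\log p / n}$): study
defaults in `run_config()` are (0.1, 0.001), appropriate for
$p \approx 800$, $n \approx 12$; at synthetic calibration scale
($p = 30$, $n = 150$/group), the BIC search over grids
$\lambda_1 \in \{0.1, \dots, 0.5\}$, $\lambda_2 \in \{0.05, \dots, 0.4\}$
selects approximately (0.3, 0.2). Small $\lambda_2$ leaves the
group-specific matrices effectively unpenalized at large $n$, so the BIC
stage-two scan matters.

## Stability selection

For each of $B$ resamples a uniform random subset of
$\lceil 0.8\,p \rceil$ variables is drawn and the joint model refitted on
the restricted matrices. An edge's stability frequency is its presence
count divided by the number of resamples in which both endpoints were
present; edges with frequency $\ge \pi = 0.8$ are retained. On the
calibration fixture, stability selection strictly removes false positives
relative to the single fit at the same penalty while keeping the true
support.

# Network characterization

Per-group aptamer graphs are collapsed to the protein level (union of
edges, self-loops dropped), partitioned into shared and group-unique edge
sets, and characterized by degree and betweenness (unnormalized,
unweighted, via `igraph`). Communities come from consensus Louvain: 20
runs under distinct sub-seeds, the most frequent label-free partition is
reported (ties broken by modularity, then canonical order), and
communities with at least 3 members are labeled A, B, C, … by decreasing
size.

# Cross-platform validation

MS protein tables are intersected with the network proteins, then
filtered sequentially: no proteotypic peptide, at most one stripped
peptide, and not strictly more than 50 percent non-missing sample values.
Pearson correlation per protein is computed on z-scored log2 values
(pairwise complete; at least 3 complete pairs), which makes the result
invariant to affine rescaling of either platform. Fold changes are
compared by refitting the batched mixed model on the MS protein
quantities and pairing contrasts per protein (the aptamer with the
smallest standard error represents a multi-aptamer protein).

# The synthetic generator

`synthetic_config()` fixes every generative parameter;
`make_precision_matrices()` draws disjoint shared and group-unique edge
positions, assigns partial correlations $\rho_{ij}$ (magnitudes in
`partial_corr_range`, random sign, shared edges identical across groups),
sets $\omega_{ij} = -\rho_{ij}$ on a unit diagonal and enforces positive
definiteness by diagonal loading to a minimum eigenvalue of 0.1. Loading
preserves the zero pattern exactly, but shrinks the *effective* partial
correlations: assigned magnitudes 0.3–0.6 realize roughly 0.22–0.42 after
loading, which is what recovery difficulty is calibrated against.

`sample_dataset()` draws correlated multivariate normal log2 vectors per
group, plus per-aptamer baselines, true group shifts, sex and age effects
on a subset of aptamers, and one subject random intercept per sample.
Buffer wells are i.i.d. noise around a floor; replicate pairs re-noise
existing samples. Output is on the linear scale so the log2
transformation is exercised.

Default rationale:

- `sigma_subject = 0.1` — modest, because median normalization removes
  most sample-level offsets; the mixed model still has a real variance
  component to estimate.
- `sigma_noise = 0.5` — partial correlations are scale-invariant, so this
  only sets the scale of the correlated component relative to effects.
- `sigma_replicate_log2 = 0.09` — reproduces a repeatability coefficient
  near 13 percent.
- `effect_range_late` larger than `effect_range` — late-stage disease
  shows much larger fold changes than early degeneration.
- Annotation defect fractions default to about 0.5 percent unmapped and
  3.6 percent non-human, with deterministic counts `round(frac * p)`.
- Determinism: the generator derives all randomness from `seed`
  (structure) and `seed + 1` (data); pipeline stages use `seed + 1 ...
  seed + 4` so stages can be re-run in isolation.

# Problem sizes and runtime

Desk-scale settings (minutes on one CPU): $p \le 200$ variables in the
GGM with $B \le 200$ stability resamples; mixed-model batches of 50
aptamers over a few hundred samples; betweenness and Louvain on graphs of
hundreds of nodes. Full study scale ($p = 800$, $B = 1000$) takes hours
for stability selection; the code path is identical.

# Limitations

- The generator draws group networks with disjoint shared/unique edge
  positions and equal shared edge values; real biology is messier.
- The group-lasso objective estimates regression coefficients, not a
  positive-definite precision matrix; only the support is interpreted.
- BIC selection is greedy (two one-dimensional scans, not a full grid).
- Louvain consensus reports the modal partition; for graphs with many
  near-optimal partitions the mode can be unstable across seed sets.
- Cross-platform comparison assumes shared sample identifiers and log2
  scales on both platforms.

# A worked example

```{r worked, eval = TRUE}
cfg <- synthetic_config(p = 40, n_per_group = c(healthy = 20, mild = 20),
                        n_shared_edges = 30, n_unique_edges_per_group = 4,
                        n_differential = 8, n_buffer = 3, seed = 42)
out <- file.path(tempdir(), "run")
res <- run_pipeline(run_config(out, synth = cfg, top_n = 25,
                               lambda1 = 0.3, lambda2 = 0.2, B = 50,
                               seed = 42, ms = TRUE))
res$preprocess$report
head(res$contrasts[, c("seq_id", "contrast", "log2fc", "ci_low", "ci_high")])
res$network$diff$counts
```
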