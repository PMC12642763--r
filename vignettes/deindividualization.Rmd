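---
title: "De-individualizing parcellated task fMRI: model, distances, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De-individualizing parcellated task fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deindfmri)
```

## The problem

A task-fMRI session yields, after atlas parcellation, a *parent scan*
$S \in \mathbb{R}^{m \times n}$: $m$ region-averaged BOLD time series over
$n$ time points, containing several contiguous *task scans* (blocks during
which the subject performed one condition). Unsupervised clustering of task
scans can target two very different labels:

* **who** — scans from the same individual share a fingerprint: per-region
  mean BOLD offsets that barely move between that subject's task blocks,
  and a stable inter-region correlation structure;
* **what** — scans of the same task share a spatial activation pattern
  that is much weaker than the individual fingerprint.

The package implements three pairwise comparisons that select between these
signals, embeds the resulting distance matrix with Isomap, and scores
k-means clusterings of the embedding with chance-adjusted partition scores.

## Distances

**Raw Frobenius.** $d_F(A, B) = \lVert A - B \rVert_F$ between task scans.
A constant offset $c$ on one scan contributes $\sqrt{mn}\,|c|$, so this
distance is dominated by the per-subject mean offsets and clusters scans by
individual.

**Bures between connectomes.** Each task scan is summarized as its Pearson
correlation *functional connectome* (an $m \times m$ PSD matrix), and
connectomes are compared with the Bures distance

$$ d_B(A,B) = \sqrt{\operatorname{tr} A + \operatorname{tr} B
   - 2\sqrt{F(A,B)}}, \qquad
   F(A,B) = \left[\operatorname{tr}\left(A^{1/2} B A^{1/2}\right)^{1/2}\right]^2, $$

the geodesic distance on the PSD manifold, with $F$ the fidelity of quantum
information theory. Because correlation removes each region's mean and
scale, this route is immune to sensor-level offset differences yet still
clusters by individual — through the correlation fingerprint.

**dM.** To expose the *task* signal, both fingerprints are removed from the
parent scan before extraction:

1. *standardization*: $\bar S = S - \frac{1}{n} S \mathbf{1}\mathbf{1}^\top$
   removes each region's session mean;
2. *Mahalanobis (ZCA) whitening*: $S_w = W^{-1/2} \bar S$ with
   $W = \operatorname{cov}(\bar S, \bar S)$, after which the rows of $S_w$
   have identity covariance — unit variance per region, no inter-region
   correlation.

Task scans $T_{1,w}, T_{2,w}$ are then extracted from the *whitened*
parents and compared with the Frobenius distance:
$d_M(T_1, T_2) = d_F(T_{1,w}, T_{2,w})$. The whitening matrix is estimated
per session from the whole parent scan — never per task block — so all
blocks of one session undergo the same transform. $d_M$ is symmetric and
vanishes on identical inputs but **can violate the triangle inequality**;
the package treats it as a dissimilarity and never asserts metric axioms
for it. A separate variance-rescaling stage after de-meaning would be
redundant because whitening already fixes every region's standard
deviation at 1, so no such stage exists here.

## Embedding and evaluation

Isomap: build the $k$-nearest-neighbour graph of the distance matrix
(union-symmetrized, ties to the lower index), replace non-neighbour
distances by graph geodesics, double-center the squared distances into
$B = -\tfrac12 J \hat D^{(2)} J$, and use the top $d$ nonnegative
eigenpairs as coordinates $X = V_d \Lambda_d^{1/2}$. Quantitative
clustering runs on a 20-dimensional embedding (2-D is for plots only).
Embeddings are scored by k-means (k-means++ initialization, Lloyd
iterations, best of 10 restarts, fixed seed) against subject labels (k =
number of subjects) and task labels (k = number of tasks), using the
adjusted Rand score and adjusted mutual information. Both scores are
chance-adjusted — expected value 0 under random labelings, maximum 1
exactly at partition identity — so a score of, say, 0.75 on an 8-class
problem indicates much better than "75% accuracy".

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `ridge` | 0 | diagonal loading of $W$ before inversion; 0 means *fail loudly* on ill-conditioned covariance rather than silently regularize, because a silent ridge changes every $d_M$ value irreproducibly |
| `condition_threshold` | 1e12 | condition number of $W$ beyond which whitening refuses to proceed |
| `k` (Isomap) | 10 | neighbourhood size; must exceed the size of the tightest cluster or the graph disconnects (which is an error, not a silent subsetting — a `--largest-component`-style fallback would corrupt downstream label evaluation) |
| `d` | 2 (plots) / 20 (clustering) | embedding dimension |
| `n_restarts` | 10 | k-means restarts |
| AMI normalizer | arithmetic mean of entropies | the modern convention; `"max"` is available |

## Numerical choices

* $W^{-1/2}$ and all PSD square roots use the symmetric eigensolver with
  eigenvalues clamped at a relative floor ($10^{-12}\lambda_{\max}$): the
  fractional power is only defined for PD matrices and near-singular
  estimates are routine at $n$ not much larger than $m$.
* Bures radicands within $10^{-12}(\operatorname{tr}A+\operatorname{tr}B)$
  of zero are clamped to 0 so $d_B(A,A)=0$ holds exactly despite
  eigensolver roundoff; only distances below $\sim 10^{-6}$ on unit-scale
  inputs are affected.
* Graph geodesics use repeated Dijkstra (via igraph) rather than a literal
  Floyd–Warshall triple loop — identical results for nonnegative weights
  (the test suite checks equality against a brute-force cubic oracle) at
  far better scaling. Direct neighbours always keep their raw distance.
* Isomap retains eigenvalues at or above $10^{-12}\lambda_{\max}$;
  numerical zeros (e.g. the centering null direction) are excluded so the
  retained dimension count is deterministic, and fewer-than-requested
  dimensions produce a warning, not an error.
* Covariance uses the $1/(n-1)$ normalizer throughout; the whitening
  contract $\operatorname{cov}(S_w) = I$ holds under any normalizer used
  consistently.
* Unequal task-scan lengths are an error under $d_F$/$d_M$ by default;
  an explicit truncate-to-shortest policy (from the start of each block,
  with a warning) is available, preserving contiguity.

## The synthetic cohort generator

Real working-memory fMRI at application scale (hundreds of subjects, 268
regions) is access-restricted, so the generator produces cohorts that
carry exactly the three structures the distances detect, at desk scale
(defaults: 20 subjects × 8 tasks, 30 regions, 40 time points per task):

* **mean offsets** — each subject draws per-region offsets around a
  baseline of 100 with spread `subject_mean_scale = 10` (10% of baseline).
  Within a subject, block means then differ only through noise averaging,
  roughly two orders of magnitude less than the between-subject spread —
  the "small but consistent" statistical differences the raw Frobenius
  route exploits;
* **correlation fingerprint** — block columns are drawn with covariance
  $C_s = (1-w) I + w\, Q_s \Lambda Q_s^\top$, $w =$
  `subject_cov_strength = 0.6`, $Q_s$ a seeded random orthogonal matrix
  and $\Lambda$ a trace-normalized geometric spectrum (ratio 0.8), giving
  a few strong subject-specific correlation modes of the kind connectome
  fingerprinting studies report;
* **task signal** — per task, a unit-norm spatial pattern (orthonormalized
  across tasks, shared by all subjects) scaled by
  `task_signal_strength = 5` — about a 1% peak per-region signal change at
  baseline 100, a textbook task-fMRI effect size — and modulated by a
  raised-cosine temporal bump over the block. The smooth waveform avoids
  making task detection artificially easy through raw block-mean shifts.
  `noise_sd = 0.5` adds i.i.d. sensor noise at half the neural-fluctuation
  scale.

Retest sessions contain the same task blocks in a fixed permuted order
(the canonical 8-condition orders of the working-memory protocol when
`n_tasks = 8`) with fresh noise; subject profiles and task patterns are
session-invariant. All draws descend from one master seed through a
hierarchical `(seed, role, subject, task)` split, so cohorts are
bit-reproducible and independent of generation order.

**What a green test does and does not establish.** The generator's world is
Gaussian, stationary within blocks, and free of head motion, physiological
noise, scanner drift and hemodynamic dynamics. Green end-to-end tests
establish that the pipeline recovers each label from the structure that is
supposed to carry it, and nothing about performance on real BOLD data.

```{r null-model}
# zeroing a knob removes exactly its structure: no subject structure left
cfg <- cohort_config(n_subjects = 4, n_tasks = 4, m_regions = 10,
                     timepoints_per_task = 30, subject_mean_scale = 0,
                     subject_cov_strength = 0, seed = 1)
co <- generate_cohort(cfg)
run_pipeline(co, "frobenius_raw", k = 8, d = 8, seed = 1)$scores
```

## Design decisions that were genuinely open

* **Bures on correlation, not covariance, connectomes** — correlation is
  the connectome definition used for the fingerprint argument (it
  "eliminates differences in mean and standard deviation"); covariance
  remains available via `connectome(kind = "covariance")`.
* **Printed-formula reconstruction** — the source display of the Bures
  distance reads $d_B = \operatorname{tr}A + \operatorname{tr}B - 2F$,
  which is dimensionally inconsistent with the standard Bures distance it
  cites; the package implements the standard radical form above and
  documents the discrepancy as a typesetting artifact.
* **kNN symmetrization by union** maximizes connectivity; the alternative
  (intersection) disconnects small clusters much earlier.
* **Grid benchmark neighbourhood** — with `k = 4` a square grid's kNN
  graph is the axis-aligned lattice, its geodesics are Manhattan
  distances, and no 2-D Euclidean embedding correlates with them above
  ~0.97; the geodesic-faithfulness check therefore runs at `k = 8`, where
  diagonal neighbours enter the graph.
* **AMI oracle scale** — the exhaustive expected-MI cross-check runs over
  *all* partition pairs up to $N = 5$ and seeded samples from the
  exhaustive partition lists at $N = 6, 7$; the full $N = 7$ cross product
  (Bell$(7)^2 \approx 7.7 \times 10^5$ pairs) would dominate the suite's
  runtime without adding coverage.
* **UMAP** is delegated to the external \pkg{uwot} backend when installed
  and is otherwise a clear error; it is never reimplemented and never a
  silent fallback.

## Known limitations

* $d_M$ requires equal task-scan lengths (or explicit truncation); the
  application protocol has equal-length blocks, so this rarely binds.
* Whitening needs $n > m$ comfortably; at $n \lesssim m$ the covariance is
  singular and the package stops with advice rather than guessing.
* The pairwise Bures matrix costs one $m \times m$ eigendecomposition per
  pair after caching the per-connectome square roots — fine for hundreds
  of scans, slow for tens of thousands.
* Scores on the synthetic cohort are *qualitative analogs* of the
  application-scale results, not reproductions of them.
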