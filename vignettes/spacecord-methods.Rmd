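---
title: "Models and methods behind spacecord"
author: "spacecord authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spacecord}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spacecord)
```

`spacecord` reimplements, as a tested pipeline, a bulk-microarray analysis
of mouse lumbar spinal cord across three conditions — ground control (C),
spaceflight (S) and post-flight recovery (R) — at the very small sample
size such missions yield (two animals per group). This vignette is the
package's own account of its models: what each stage assumes, which
parameters matter and why their defaults are what they are, what the
synthetic-data generator does and does not emulate, and where the methods
genuinely run out of power.

## The synthetic-data generator

Every stage is exercised on generated data with known ground truth.
`generate_expression()` draws raw intensities as

$$X_{gij} = 2^{\,b_g + \delta_{g}\,[i \in \text{effect group}] +
\varepsilon_{gij}} + B_{gij},$$

with per-gene log2 baselines $b_g \sim N(\mu_b, \sigma_b^2)$, planted
effects $\delta_g = \pm\,\text{effect\_lfc}$ on a chosen subset of genes
(in the recovery group by default, so R-vs-C and R-vs-S carry signal
while S-vs-C is null, mirroring where such studies find their changes),
per-probe biological noise $\varepsilon \sim N(0, \sigma_{bio}^2)$, and
additive array background $B \sim N(\mu_{bg}, \sigma_{bg}^2)$ (an
optional exponential tail via `bg_alpha` completes the
normal+exponential family). Each gene is emitted as `probes_per_gene`
replicate probes with independent noise; control probes are
background-only. Identical config and seed give bit-identical output.

Default parameters and their reasoning:

* `groups = C, S, R`, `n_per_group = 2` — the study design; the generator
  accepts any `n` for power studies.
* `effect_lfc = 4`, `n_de` = 5% of genes — effects at the pipeline's own
  call threshold scale (|log2FC| > 2 with 4-fold margin), sparse enough
  that normalization is not destabilized.
* `sigma_bio = 1` on the log2 scale — typical between-replicate spread
  for this platform class.
* `baseline_mu = 12`, `baseline_sd = 1.5` (log2), `bg_mu = 80`,
  `bg_sigma = 5` (intensity units) — a median signal of ~4,096 against a
  background of ~80. The baseline is deliberately placed well above
  background so that planted effects are identifiable: a 4-fold
  down-regulated gene still sits an order of magnitude above $\mu_{bg}$.
  With a lower baseline (say $\mu_b = 10$), down-regulated genes fall to
  the background level and no correction can recover their fold change
  without bias; the generator is meant to test the pipeline, not to make
  its planted truth unrecoverable by construction.

The generator emulates: replicate probes, control probes, additive
background, group structure, planted gene sets
(`generate_genesets()`: enriched terms draw ≥ 80% of members from
planted genes; namespaces cycle BP/MF/CC/HP) and a planted all-ones block
in a weighted binary incidence matrix (`generate_incidence()`). It does
**not** emulate scanner artifacts, spatial trends, dye effects, probe
GC-content bias, or correlated gene modules — so green tests here say the
pipeline's statistics behave as designed under a clean generative model,
not that real arrays are free of artifacts these stages never see.

## Preprocessing

Background correction uses the conditional expectation under
$X = S + B$, $S \sim \text{Exp}(\alpha)$, $B \sim N(\mu, \sigma^2)$:

$$E[S \mid X = x] = m + \sigma\,\frac{\varphi(m/\sigma)}{\Phi(m/\sigma)},
\qquad m = x - \mu - \sigma^2/\alpha,$$

computed on the log scale of $\varphi/\Phi$ for tail stability; outputs
are strictly positive and monotone in $x$. Parameters are estimated per
array from the control probes (mean/SD; lower decile as fallback), with
$\alpha = \max(\bar x - \mu, \text{floor})$. A plain subtract-and-floor
corrector is available behind `method = "subtract"`. The log2 transform
adds +1 before the log so near-zero corrected values cannot explode.

Quantile normalization maps every column onto the vector of per-rank
column means; ties receive the mean of the reference values their
positions span — a fixed, documented convention that makes the operation
idempotent and the sorted columns *exactly* equal. Replicate collapsing
(arithmetic mean per gene symbol, after control removal) happens last,
matching the stated order: correction and normalization before probe
filtering and averaging. Note a real consequence of quantile
normalization quantified during development: with 3% of genes planted at
|log2FC| = 4, the forced common distribution compresses the extreme tails
and attenuates recovered effects by roughly 0.3 log2 units. This is a
property of the normalizer (any implementation), so the generator's
identifiability checks run on background-corrected, un-normalized data.

## Moderated differential expression

Per gene, a group-means OLS fit gives coefficients (group means), residual
variance $s^2_g$ on $d = n - k$ df ($d = 3$ here). The empirical-Bayes
prior follows the scaled-inverse-χ² model: with
$e_g = \log s^2_g - \psi(d/2) + \log(d/2)$,

$$\operatorname{var}(e) = \psi'(d/2) + \psi'(d_0/2), \qquad
\operatorname{mean}(e) = \log s_0^2 - \psi(d_0/2) + \log(d_0/2),$$

so $d_0$ comes from inverting the trigamma (Newton iteration, tolerance
1e-10) on the excess variance, with $d_0 = \infty$ (and
$s_0^2 = e^{\overline{e}}$) when the excess is non-positive. The
moderated statistic per contrast $w$ is
$\tilde t = w^\top\hat\beta / \sqrt{\tilde s^2 \sum_j w_j^2/n_j}$ on
$d_0 + d$ df (standard normal at $d_0 = \infty$). The tests agree with
the established empirical-Bayes implementation to ~1e-10 in the
finite-$d_0$ case (checked in the suite); at $d_0 = \infty$ the prior
variance convention here is $e^{\overline{e}}$, which differs from that
implementation's by a fraction of a percent.

Design choices: BH is applied within each contrast separately (the
standard per-fit behavior for a three-comparison analysis); both DE
cutoffs are strict inequalities (`p_FDR < 0.05`, `|log2FC| > 2`); the
top-50 panel ranks genes by their smallest adjusted p over the union of
contrasts, ties broken by |log2FC| then gene id — a rule chosen here and
documented, since "top 50" alone does not fix one.

## Sample structure

Clustering is agglomerative with complete linkage on Euclidean distances
over collapsed genes (collapsed, not probe-level — the cleaner object
once replicates are averaged). PCA centers each gene and decomposes by
SVD without variance scaling, because intensities are already on one
log2 scale; component signs are fixed (largest-magnitude loading
positive) to make outputs reproducible. "Hierarchical biclustering" of
the top-gene heatmap is read as independent row and column hierarchical
clustering — the standard heatmap convention — since no joint algorithm
is implied for a display ordering.

## Enrichment

Overrepresentation uses the hypergeometric upper tail
$P(X \ge k)$ for an overlap of $k$ between a DE list of size $n$ and a
term of size $K$ in a universe of $N$, with BH within namespace
(mirroring per-namespace reporting) and size bounds 2–2000. The universe
is all genes surviving preprocessing, not the whole genome: the DE list
was selected from exactly that set, and a larger universe would inflate
significance. BH replaces service-specific multiple-testing corrections
(the one g:Profiler-style interface applies is simulation-calibrated and
not reproducible offline); BH is also the procedure used everywhere else
in this pipeline.

The second engine trains a random-forest classifier of samples by group
on gene features (1,000 trees, √p features per split, bootstrap
resampling — fixed, documented defaults) and scores genes by mean
decrease in Gini impurity. Term scores are the arithmetic mean importance
of mapped genes; their p-values come from gene-set permutations (same
size, sampled without replacement, `(1 + #{perm ≥ obs})/(n_perm + 1)`).
The downstream filters are: top 1,000 genes by importance, BP terms with
p < 0.01 (strict) and ≥ 10 mapped genes.

**A structural limitation, quantified.** Gini decrease depends only on
the class partition a split achieves, never on its margin. With six
samples, a pure-noise gene places the two R samples at the two extremes
of its six values with probability $2/\binom{6}{2} = 2/15 \approx 13\%$
— and such a gene then ties *exactly* with a planted 7-sigma separator at
every split, in every tree (the separation is a property of the fixed
data). Importance therefore spreads over ~1,300 lucky-noise genes plus
the planted ones, and no number of trees changes the expectation. The
consequences, measured in the test suite: at n = 2 per group, planted
enriched terms do not reliably outrank null terms, and median planted
importance does not exceed the 95th percentile of null importance. At
n = 4 per group the tie fraction is small enough that both properties
hold robustly — the suite demonstrates the engine's signal-vs-null
separation there, and reports the n = 2 behavior as what it is: an
exploratory screen at this design, not a reliable ranking.

## Hot-spot biclustering

The hot spot is a pair (gene subset $G$, term subset $T$) maximizing

$$S(G, T) = \sum_{g \in G}\sum_{t \in T} w_g\,
\bigl[B_{gt} - \gamma\,(1 - B_{gt})\bigr],$$

present links reward the gene's weight, absent links inside the selection
cost $\gamma$ times it. This is the minimal objective whose two
coordinate-wise maximizations are exact and closed-form: fixing $T$, the
optimal $G$ is exactly the genes with positive row gain (and symmetric
for $T$), so the alternating search ascends monotonically to a fixed
point that no single-side change can improve. Restarts run from every
column (plus one all-columns seed, which lets $\gamma = 0$ reach the
union of disconnected components); ties break by area then lexicographic
gene ids, making the whole search deterministic. An exhaustive
enumeration oracle (`brute_force_hotspot()`, feasible to 22 rows+columns)
validates the search: ≥ 95% exact agreement on random 6×5 instances.

Numerical conventions: strictly-positive gain for inclusion (zero-weight
genes are never selected); the empty selection scores 0 and is admitted
as a candidate in the oracle too, so "best" is well-defined on all-zero
matrices; `max_iter = 100` caps pathological cycling (never observed —
each half-step is a deterministic function of the other side).

One honest caveat at the default $\gamma = 1$: a background row carrying
ones in ≥ 3 of 4 planted columns *strictly increases* the objective
(gain $3 - 1 = 2$), and with a 40×20 matrix at background density 0.1
about 11% of instances contain such a row. Exact recovery of a planted
8×4 block therefore plateaus near ~88% — for any correct maximizer of
this objective, as the oracle confirms — while recovery up to that
one-row slack is essentially certain. A penalty of $\gamma \ge 3$ pushes
exact recovery above 99%, but $\gamma = 1$ is kept as the default
balance between density and coverage.

## Orchestration, determinism and problem sizes

`run_all()` executes simulate → preprocess → DE → explore → enrich →
hot spot from one config, writing TSVs and a manifest with per-stage
seeds derived from the global seed by a fixed affine map
(`stage_seed()`), so any stage can be rerun in isolation. All writers
emit full-precision text; identical config + seed reruns are
byte-identical.

The test suite and the acceptance script size their simulations to run
comfortably on one CPU: the flagship scenarios use 10,000 genes ×
triplicate probes × 6 arrays (single runs and 50-seed sweeps), prior
recovery uses 20,000 simulated variances × 25 seeds, the oracle
comparisons use 200 random 6×5 instances and 100 planted-block
instances. These sizes give Monte-Carlo error well inside every asserted
margin.

## Known limitations

* The noise model is a stand-in: nothing here claims the real mission
  arrays follow a lognormal-plus-normal-background law.
* Two-color aspects of the platform are not modeled (single-channel
  intensities throughout).
* The RF enrichment stage is structurally underpowered at n = 2 per
  group (see above); its output there is exploratory.
* Gene sets arrive pre-flattened (GMT); no ontology DAG propagation or
  DAG-aware testing.
* The hot-spot objective is this package's concrete instantiation of
  "binary biclustering by bivariate maximization"; other objectives
  (e.g. Bimax-style maximal biclusters) are out of scope.
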