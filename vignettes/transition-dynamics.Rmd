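---
title: "Detecting differential variance and co-expression along a cell-state transition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting differential variance and co-expression along a cell-state transition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dvcscan)
```

## The model

A dynamical system close to a critical transition shows characteristic early
warning signals: rising variance of its components and rising correlation
between them. A population of stem cells about to differentiate is such a
system — genes coupled into the regulatory circuits that hold the
undifferentiated state fluctuate strongly and coherently across replicate
cultures, and both the fluctuation and the coherence collapse once the
population commits to a lineage.

`dvcscan` turns this idea into a gene-level screen over a replicated,
state-ordered expression matrix:

1. **Modules.** At the reference state (the undifferentiated population),
   genes are clustered by average linkage on the correlation distance
   `d = 1 - PCC` computed across the reference replicates, and modules are
   cut out of the dendrogram with a hybrid dynamic tree cut (minimum module
   size 100 by default).
2. **Per-state statistics.** For every module gene and every state:
   the sample SD across the state's replicates; the mean absolute PCC with
   the other genes of its module (`mpcc`); the mean absolute PCC with all
   genes outside the module (`opcc`); and the composite index
   `I = mpcc * SD / opcc`. The index is large when a gene is variable,
   tightly coupled to its module, and decoupled from the rest of the
   transcriptome — the early-warning configuration.
3. **System transition score.** `score = max over post-reference states s of
   ln(I_ref / I_s)`. A high score means the early-warning configuration was
   present at the reference and lost at some later state. Genes scoring more
   than two sample SDs above the mean score are called **DVC genes**
   (differential variance and correlation).
4. **Companion analysis.** Welch t-tests with a global fold-change rule call
   differentially expressed (DE) genes; variance-ratio F-tests call
   differentially variable (DV) genes; both use Benjamini–Hochberg adjustment
   within each state's test family. Hypergeometric tests quantify gene-set
   enrichment and, through an ortholog map, the overlap of DVC calls between
   two datasets (e.g. two species).

## What the synthetic generator emulates

`simulate_dataset()` draws `x[g, s, r] = mu_g + lambda_g * f[m(g), s, r] +
delta * 1(g DE, s >= onset) + eps`, with one latent factor `f` per module
(`f ~ N(0, tau[m, s]^2)`), loadings `lambda ~ U(0.8, 1.2)`, and iid noise
`eps ~ N(0, sigma^2)`. This is the simplest generative model that couples
variance and correlation the way the score assumes: within a module the
population correlation is `lambda^2 tau^2 / (lambda^2 tau^2 + sigma^2)` and
the per-gene SD is `sqrt(lambda^2 tau^2 + sigma^2)`, so a factor-SD collapse
(`tau` large at the reference, small afterwards) produces jointly high
correlation and SD at the reference only — a planted transition module.

The packaged reference conditions are: two transition modules of 120 genes
(`tau` = 2.0 at the reference, 0.2 afterwards), one stable module of 120
genes (`tau` = 1.0 throughout), 800 independent background genes, 40 DE genes
drawn from the background (mean shift `delta` = 2.0 from the first
post-reference state), noise `sigma` = 0.5, baselines `U(6, 12)` on the log2
intensity scale, 4 states with 8 replicates each, seed 17. Sizes and rates
follow the verification design of the package; the replicate count matches
the kind of time-course study the method targets. Because DE genes are drawn
from the background only, DE and DVC calls have disjoint planted truth,
which gives a specificity check for both analyses.

The generator does **not** emulate probe-level microarray artefacts, batch
effects, count noise, overlapping modules, or partially collapsing factors.
Passing the recovery tests therefore demonstrates that the implementation
detects the variance–correlation signature it formalises, not that the
method is robust to every nuisance process in real data.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_size` | 100 | minimum module size in the tree cut |
| `deep_split` | 1 | split sensitivity (0–4); sets the gap/scatter fractions |
| `tight_scatter` | 0.4 | absolute core-scatter ceiling (mean core correlation >= 0.6) |
| `epsilon` | 1e-6 | floor for `opcc` denominators and log arguments |
| `sd_k` | 2 | SD multiplier of the DVC score threshold |
| `alpha` | 0.05 | adjusted-p cutoff for DE/DV calls (strict `<`) |
| `fc_k` | 2 | SD multiplier of the global fold-change threshold |
| `presence_frac` | 0.5 | presence-call fraction required per state (strict `>`) |
| `network_threshold` | 0.95 | PCC cutoff for exported network edges |

## Numerical and design choices

* **Z-score scope.** Genes are standardized across *all* samples jointly,
  not within each state, although per-state standardization is the more
  literal reading of the preprocessing convention this pipeline follows:
  standardizing within each state would force SD = 1 at every state and
  annihilate the differential-variance signal the score then measures. The
  transition score is invariant to any per-gene affine rescaling (verified
  to 1e-10 in the tests), so this choice cannot change DVC calls — it only
  sets the scale of the reported SDs.
* **Absolute correlations.** `mpcc` and `opcc` average |PCC|. A signed
  outside-module average is approximately zero by symmetry, which would make
  the `opcc` denominator explode; the absolute convention is the only
  numerically coherent reading, and a `signed_pcc` switch restores the
  signed one.
* **Natural log, epsilon floors.** The score's log base only rescales all
  scores and cannot change a mean + k·SD call. Flooring `I` at `epsilon`
  inside the log keeps scores finite and order-preserving when a correlation
  or SD vanishes.
* **Signed distance.** Clustering uses `1 - PCC` (anti-correlated genes kept
  apart); `unsigned = TRUE` switches to `1 - |PCC|`.
* **Tie-breaks.** Argmax ties across states resolve to the earliest state in
  the design order; module labels are ranked by decreasing size with ties
  broken by smallest member index; edge lists are canonicalised
  lexicographically so outputs are byte-deterministic.
* **Per-state test families.** BH adjustment is applied within each state's
  p-value vector: each post-reference day is a separate comparison family.
  DE requires the adjusted p-value (< 0.05) *and* a fold change above the
  global mean + 2·SD of |log2 FC| pooled over genes and states.
* **Degenerate inputs.** Zero variance in both Welch groups yields p = 1
  (equal means) or p = 0 (unequal); a zero reference variance is an error for
  the F-test (the per-state variance filter removes such genes upstream);
  constant score vectors yield an empty DVC set.

## The hybrid tree cut

No dynamic tree-cut implementation ships with base R, so the package authors
one: bottom-up branch identification followed by distance-based assignment of
stray leaves. A branch is locked as a module at the merge where it is
absorbed into the rest of the tree if it (i) has at least `min_size` leaves,
(ii) shows a *core gap* — its absorption height minus the height at which its
first `min_size` members had assembled — of at least the gap threshold, and
(iii) has a *core scatter* (mean height of its earliest internal merges) below
both the deep-split scatter ceiling and the absolute `tight_scatter` ceiling.
Measuring gap and scatter on the branch **core** matters: with eight
replicates, chance correlations are large (the null SD of a PCC is about
0.38), so background genes attach to a genuine module branch continuously and
an attachment-gap criterion measured at the branch top would never fire.
Branches that reach the cut height undivided are locked on size and tightness
alone, since no gap can be demonstrated for them; the absolute tightness
requirement is what keeps a continuum of chance merges from being declared a
module. The gap threshold is floored at 0.01 distance units so that
degenerate trees whose entire height range is numerical noise are not split.
A stray leaf is then assigned to the module of smallest average distance if
it lies at most 50% farther from the module than the module's own most
peripheral member.

Two consequences are worth knowing. First, with very few replicates the
chance-correlation continuum itself can satisfy the tightness ceiling, so
sparsely sampled background can form modules — mirroring how hybrid tree
cuts behave on real few-replicate data, where essentially all genes end up
in modules. Such modules are harmless to the score (their genes carry no
differential signal) and they enlarge the scored universe. Second, the
null-assignment guarantee (iid noise yields no modules) is tested at 50
samples, where distances concentrate; it is not claimed at 8.

## What the verification computes

The test suite and `scripts/acceptance.R` recompute, from scratch, on the
reference conditions: the number of detected modules; the adjusted Rand
index between detected and planted labels over planted-module genes; DVC
sensitivity on transition genes and the false-positive rate elsewhere; DE
sensitivity on planted DE genes; F-test DV sensitivity; the DE/DVC Jaccard
overlap; the strongest per-module DV enrichment; and the DVC rate under null
conditions (all states identically distributed, 20 seeds). Oracle tests
verify the per-state statistics, UPGMA heights, quantile normalization
(including its tie rule), BH adjustment, and the hypergeometric tail against
independent brute-force implementations.

One property deserves an honest caveat. A mean + 2·SD threshold can only
separate a high-scoring group that is a *minority* of the scored population:
for a two-component mixture with high fraction `p`, the high mean exceeds
`mean + 2 SD` only when `1 - p > 2 sqrt(p (1 - p))`, i.e. `p < 0.2`. The
reference conditions plant 240 transition genes among at most 1160 scored
(20.7%), and module-0 genes are excluded from scoring besides, so the DVC
threshold sits above the transition genes' scores and sensitivity on these
conditions is low (the acceptance script reports the measured value). This
is a property of the threshold rule under a signal-dense simulation, not of
the score: the score itself separates the groups cleanly (transition genes
score ≈ 2.3, stable ≈ 0.1, background ≈ 0.6 under the reference
conditions), and in genome-scale data, where DVC genes are a few percent of
the transcriptome, the rule behaves as intended.

## Problem sizes

The packaged analyses run on 1160 genes x 32 samples (seconds on one CPU);
the null calibration uses 20 seeds of 500 genes x 32 samples; oracle checks
use 10–60 element instances where brute force is exact. These sizes make
every planted effect detectable while keeping the whole verification suite
fast.

## Limitations

* Scores exist only for genes inside a module; a gene whose module
  membership is missed is invisible to the screen.
* The score compares each post-reference state to the reference separately
  and takes the max; there is no pooled post-reference mode.
* Replicate-level correlation estimates with n = 8 are noisy; module
  detection and `mpcc`/`opcc` inherit that noise.
* The presence-call filter needs an external call matrix; the package
  generates proxy calls for testing but does not compute calls from raw
  probe data.
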