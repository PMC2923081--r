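---
title: "Models and methods behind pgpcrm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pgpcrm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgpcrm)
```

pgpcrm predicts which ~1 kbp stretches of a gene's control region act as
cis-regulatory modules (CRMs) for spatial patterning, and which
transcription factors (TFs) drive each CRM. This vignette describes the
underlying models, the choices we made where the design was genuinely open,
and what the synthetic-data validation does and does not establish.

## Coordinate conventions

Genomic intervals are 0-based half-open throughout (BED convention; a GFF
export, if ever added, would convert to 1-based). The body axis is divided
into `B = 100` equal bins, indexed 1 (most anterior) to 100 (most
posterior). Expression patterns are binary vectors over bins; TF
concentrations and predicted activities are continuous values in [0, 1].
Raw intensity traces are binarized by averaging positions into 100 equal
bins (position `p` of `L` falls in bin `ceiling(100 p / L)`) and calling a
bin expressed when its mean exceeds `threshold_frac` (default 0.25) times
the maximum bin mean. The threshold rule is our own: it is scale-free,
returns an all-zero profile for an all-zero trace, and its single parameter
has an interpretable unit (fraction of peak intensity); upstream image
processing is out of scope.

## HMM motif window scoring

A window is scored against a two-state generative model. At each decision
point the model emits one background base (probability `1 − q`, emission
from an order-0 background distribution) or enters a motif site
(probability `q/2` per strand) that emits `W` bases from the PWM columns,
reverse-complemented on the minus strand; sites cannot overlap. The score
of a window is

`log P(seq | site model) − log P(seq | background only)`,

computed by a forward recursion in log space (implemented in C++; no
probability-space underflow is possible). `N` bases are emitted with
probability 1 under both states, so they contribute exactly 0 — an all-`N`
window scores 0.

The site-entry probability `q` is fitted per window by maximizing the 1-D
likelihood over `[0, q_max]` with `q_max = 0.1`, using golden-section
search plus explicit endpoint checks. `q = 0` collapses the model onto the
background, so the fitted score is never negative. We chose direct 1-D
maximization over an EM iteration because the two find the same optimum of
the same likelihood and the direct search is simpler to verify; the
exhaustive-enumeration oracle in the test suite (summing over every legal
site placement on small sequences) pins the likelihood itself to within
1e-10 relative accuracy. Defaults: 500 bp windows shifted by 250 bp for
genome-style profiles; whole-window scoring for CRMs and 1 kbp scan
windows. The background model is order-0; higher orders would slot into the
same emission interface but are not implemented.

Window z-scores for a profile are taken against the mean and *population*
standard deviation of all windows in the scan; windows more than 2 SD above
the genomic mean are labelled `significant`, positive ones `weak`, the rest
`absent`.

## Brownian-motion averaging of orthologous scores

Orthologous window scores from several species are combined either by the
plain mean or by treating the score as a trait evolving by Brownian motion
(BM) on the phylogeny and computing the expected *time-average* of the
trait over all branches given the leaf values:

`E[(1/T) ∫ X(t) dt | leaves]`, `T = Σ branch lengths`.

Because the conditional expectation of a Brownian bridge's time-average is
the mean of its endpoints, this equals
`Σ_b τ_b (m_parent(b) + m_child(b)) / 2 / T` where `m_v` is the posterior
mean of the trait at node `v`. Those means are computed by one upward
(pruning) pass and one downward pass of Gaussian message passing, each
linear in the number of nodes. The O(n²) reference implementation
(`bm_tree_average_oracle`) instead builds the full node covariance (shared
root-path length), conditions by a linear solve, and must agree to 1e-9 —
the acceptance suite checks 1,000 random trees.

Open choices, and what we picked:

* **Root prior.** None is stated for this kind of averaging, so we use a
  diffuse (flat) root. This makes the answer independent of the BM rate —
  the rate rescales all covariances and cancels from every conditional
  mean — and hence also invariant to rescaling all branch lengths, which
  the tests assert.
* **Missing species** are marginalized (treated as unobserved), never
  imputed as zero: a missing ortholog is absence of evidence, not evidence
  of a zero score.
* **Zero-length branches** tie parent and child means (a degenerate
  bridge), handled by infinite-precision messages.
* At least two observed leaves are required; with one, there is no
  phylogenetic information to average and the caller falls back to the
  single-species score (as `combine_profiles` does for windows without
  orthologs).

A consequence worth knowing: on any *two*-leaf tree the branch-weighted
temporal average algebraically collapses to the plain mean of the two leaf
values regardless of branch lengths — asymmetry only matters with three or
more species.

## The expression model and its fitting

CRM activity is modelled as a logistic function of weighted
concentration-times-score covariates plus a per-CRM basal level (see the
README for the formula). The per-CRM baseline absorbs both unmodelled
ubiquitous regulators and the arbitrary scale of binary targets. Covariates
of order 2 (the square of a covariate) are allowed only when the matching
order-1 term is present, and are intended for the anterior gradient factor,
whose effective response is non-monotone; arbitrary interaction terms are
deliberately excluded.

Binary targets are fitted under a Bernoulli likelihood by iteratively
reweighted least squares with a small ridge (`lambda = 1e-6` on all
coefficients) and step-halving. The ridge matters: noise-free binary
targets derived from thresholded logistic predictions are *perfectly
separable*, so the unpenalized ML solution diverges. With the ridge, the
optimum is unique and finite; the fitted direction is a max-margin-like
compromise whose element-wise deviation from the generating weights can be
~20% even though every sign is recovered — callers should read the weights
as directions and relative magnitudes, not as calibrated effect sizes.
Convergence is declared at a relative log-likelihood change below 1e-8
(cap: 100 iterations); fits are deterministic. Covariates with zero
variance across all CRM × bin cells are dropped with a warning; likely
separation is flagged (`separation = TRUE`) when fitted linear predictors
exceed ±30. Standard errors come from the inverse penalized Fisher
information, and `z = w/SE` with two-sided normal p-values.

Goodness of fit reports RMSE over all CRM × bin cells, the mean per-CRM
Pearson correlation between prediction and target (CRMs with zero variance
in either vector are excluded and counted), and
`AIC = 2k − 2·logLik` with `k` = TF terms + baselines.

`cross_validate` runs replicated 2-fold cross-validation at the level of
individual CRM × bin cells: each replicate splits the cells in half, trains
on each half and averages the two test RMSEs. With `shuffle = TRUE` the
CRM-to-profile assignment is permuted first; comparing the real and
shuffled RMSE distributions (rank-sum) is the overfitting check. Everything
is seeded and reproducible.

## The PGP score

`PGP = 0.5 + 0.5 (reward − 3·penalty)` with reward/penalty the mean
prediction over expressed/non-expressed bins. The 3× penalty weight is a
named configuration constant (`penalty_weight = 3` by default): false
positive expression is treated as three times worse than missed expression,
which biases discovery toward precise, sub-pattern-driving windows rather
than broadly active ones. The linear `0.5 + 0.5x` rescaling is notational
only, mapping the raw range [−3, 1] onto [−1, 1].

For multi-domain genes, `select_domains` evaluates PGP for every non-empty
subset of expression domains, with *unselected* domains excluded from both
the reward and the penalty ("don't care"), and keeps the maximizing subset.
We chose don't-care semantics over counting unselected domains as
non-expression because the latter would penalize a CRM for the domains it
does not drive, defeating the purpose of sub-domain matching. Subset search
is exhaustive up to 12 domains (4,095 subsets; real A/P patterns have
far fewer) and greedy add-one beyond. Ties are broken deterministically —
fewer domains first, then the anterior-most combination — so results are
seedless and stable.

## Discovery and significance

A control region is scanned with 1 kbp windows every 500 bp (the window
width follows standard CRM scale; the 50% overlap step is our choice so
that a CRM straddling a window boundary is still covered by some window).
Scanned windows have no trained baseline, so predictions use the mean of
the training baselines — the least-informative choice. Window PGP scores
are converted to empirical p-values against a null of PGP scores from a
background scan using the add-one rule `p = (1 + #{null ≥ s}) / (1 + N)`,
which can never return 0 and is uniform on (0, 1] under the null.
Candidates must pass the activator-presence filter (z > 0 for at least one
designated activator) and the p-threshold (default 0.015); overlapping
surviving windows are merged, keeping the best-p representative.

One property of this construction deserves emphasis. If the null set is a
scan of plain background sequence, the windows of a plant-free locus are
statistically exchangeable with the null windows, so each carries
probability ≈ `p_threshold` of qualifying and a 43-window locus yields
~0.6 expected false calls. A genome-wide null is different in kind: it
contains the genome's own regulatory sequence, so its upper tail is heavier
and the same threshold is far more conservative against background loci.
With purely synthetic background nulls the package therefore measures, and
the tests confirm, calibrated uniform p-values — not a vanishing false-call
rate.

`sibling_enrichment` wraps the two-sided Fisher exact test for 2×2
contingency tables of CRM-architecture counts.

## Regulatory edges

An edge TF→CRM is scored by RMSE between the wild-type prediction and the
true pattern, compared to the RMSEs after randomly permuting the TF's
100-bin concentration profile (default 1,000 permutations, sampling without
replacement). `p = (1 + #{null ≤ RMSE_wt}) / (1 + n_perm)`; ties count as
extreme, so a TF with zero motif score in the CRM — whose permutations
cannot change the prediction at all — gets exactly p = 1 rather than a
spuriously small value. Each (TF, CRM) pair uses its own RNG stream derived
from the master seed, so results are reproducible regardless of evaluation
order. Edge signs are read from the sign of the TF's fitted weight.
Knockdowns simply zero one TF's concentration profile and re-predict.

## The synthetic generators

The generators produce every input the pipeline consumes, with planted
ground truth and full determinism under a seed:

* `make_motif(seed, width, strength)` builds PWMs whose per-column
  information content equals `strength` bits exactly (consensus base with
  probability `1 − e`, others `e/3`, `e` solved by root finding).
* `make_locus` draws i.i.d. background of a given GC content and plants
  PWM-sampled sites (random strand) at non-overlapping positions inside
  designated CRM intervals, returning the plant coordinates and true motif
  scores.
* `make_concentrations` supplies the canonical A/P profile shapes: anterior
  and posterior exponential gradients, interior stripes with exact support,
  and a terminal-high / terminal-low pair that sums to 1 per bin
  (complementary terminal factors).
* `simulate_expression` applies the logistic model forward, thresholds at
  0.5 (≥ 0.5 → expressed; the convention matters only for the measure-zero
  boundary) and applies independent per-bin flip noise.
* `evolve_orthologs` evolves sequences along a tree under Jukes–Cantor
  substitution (per-branch change probability `3/4 (1 − e^{−4rt/3})`),
  without indels, so ortholog maps stay positional.

The standard study conditions used by the validation suite are 10 TFs × 46
CRMs × 100 bins for model fitting (three activators, seven repressors, with
score rows redrawn until each CRM's clean pattern is non-degenerate —
real training CRMs are patterned, not uniformly on or off), a 3-TF × 6-CRM
wired network in which every planted edge has a visible consequence on the
pattern, and 22 kbp discovery loci with one 1 kbp planted CRM carrying 8
activator sites, scanned against a 150 kbp background null (299 windows).
These sizes keep the full suite within a few minutes on one CPU while
matching the training dimensions above.

**What the synthetic validation shows — and does not.** It establishes
internal correctness (oracle equivalence of both BM algorithms and of the
HMM likelihood, agreement of IWLS with an independent optimizer) and
recovery power under the generators' assumptions: i.i.d. background,
independent planted sites, noise as independent bin flips, no indels, no
correlated TF binding. Real genomes violate all of these to some degree —
compositional heterogeneity, homotypic site clustering in non-functional
regions, image-derived pattern noise that is spatially correlated — so
passing these tests bounds implementation error, not real-data accuracy.

## Known limitations

* Order-0 background only; no motif discovery; orthology maps are an input,
  not computed (no whole-genome alignment).
* The expression model is heuristic (concentration × score products through
  a logistic link), not a thermodynamic occupancy model; no cooperativity,
  no temporal dynamics.
* Fitted weights on separable data are direction-calibrated only (see
  above).
* Empirical p-values inherit the composition of the supplied null scan;
  a background-only null yields calibrated uniformity, not genome-scale
  stringency.
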