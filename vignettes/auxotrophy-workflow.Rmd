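---
title: "Predicting amino-acid auxotrophies and their community-level consequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting amino-acid auxotrophies and their community-level consequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(auxoflux)
```

## The scientific question

Many gut bacteria cannot synthesize all twenty proteinogenic amino acids
and depend on uptake from their environment — they are *auxotrophic*.
auxoflux implements a desk-scale version of the workflow that asks three
questions about such auxotrophies:

1. **Which amino acids can a genome not make?**  Answered per genome by
   flux balance analysis (FBA) on its genome-scale metabolic model: the
   model is asked to produce biomass on a full growth medium and on the
   same medium with one amino acid removed.  If growth survives the full
   medium but not the drop-out, the genome is called auxotrophic for that
   amino acid.
2. **Do auxotrophies co-occur with fermentation by-products?**  Amino-acid
   biosynthesis and fermentation share precursors (pyruvate most
   prominently), so losing a biosynthesis route can redirect precursor
   flux into secreted products.  Growth-normalized secretion (mmol/gDW) is
   predicted per genome and tested against auxotrophy status with Fisher
   exact tests.
3. **Do community auxotrophy loads track diversity, temporal stability
   and host metabolites?**  Per-sample statistics built from relative
   abundances `p_ij` and binary auxotrophy calls `b_ik` — the frequency
   `y_jk = sum_i p_ij b_ik`, the weighted count `y_j = sum_i a_i p_ij`,
   the mean pairwise Hamming distance of co-occurring profiles, the
   Shannon index — are correlated with each other, with `1 - UniFrac`
   stability between paired time points, and with serum-like metabolite
   levels via partial Spearman correlations adjusted for age, sex and
   BMI, with Benjamini-Hochberg correction per screen.

## The flux balance model

A metabolic model is a stoichiometric matrix `S` (metabolites x
reactions) with flux bounds and a biomass reaction.  FBA maximizes the
biomass flux subject to the steady state `S v = 0` and `lb <= v <= ub`;
the optimum is the growth rate in 1/hr.  Exchange reactions connect
extracellular metabolites to the environment with the standard sign
convention (negative flux = uptake, positive = secretion); applying a
medium sets each exchange's lower bound to minus its uptake limit and
closes every other exchange's uptake while always allowing secretion.

The linear programs are solved by a dense bounded-variable two-phase
primal simplex written for this package (Rcpp).  Its design choices:
Dantzig pricing with a switch to Bland's rule after an iteration budget
(guaranteeing termination under degeneracy), explicit handling of
variables nonbasic at either bound, a feasibility tolerance of 1e-9, and
a post-solve verification that the returned point satisfies `S v = 0`
and the bounds to 1e-6 (a violation is reported as a failed status,
never as a silent zero).  The test suite cross-checks optima against an
independently formulated LP solved by an external implementation on
randomly generated networks.

Degenerate optima are the norm in FBA, so exchange fluxes are never read
from a raw FBA solution.  `solve_pfba()` fixes biomass at (a fraction
of) the optimum and minimizes total absolute flux, split into
nonnegative forward/backward parts so the problem stays a pure LP.  The
package uses `optimum_fraction = 1` before reading by-products; this is
a deterministic representative of the optimal face.  The chassis model's
two lactate enantiomer routes remain interchangeable even under
parsimonious FBA — only their sum is pinned — which is exactly why
D- and L-lactate are combined before thresholding.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| `growth_threshold` | 1e-6 | 1/hr | well above the LP feasibility tolerance (1e-9), far below any biologically meaningful growth rate |
| `production_cutoff` | 1 | mmol/gDW | producer call uses a strict `>`; growth-normalized secretion at exactly the cutoff is not production |
| `min_completeness` | 85 | % | inclusive boundary; incomplete genomes lose biosynthesis genes and inflate auxotrophy counts |
| `max_contamination` | 2 | % | inclusive boundary |
| `presence_threshold` | 0 | relative abundance | any positive abundance counts a genome as present for the Hamming mean; exposed because a nonzero floor is equally defensible |
| `unifrac_variant` | weighted_normalized | — | the stability analysis weights by relative abundances; the unweighted variant is available by flag |
| medium uptake limits | 10 | mmol/gDW/hr | conventional default for a rich medium |

The drop-out screen removes exactly one amino acid at a time (20 single
tests, 21 LP solves per genome).  A genome that fails to grow on the
full medium is excluded and logged rather than called 20-fold
auxotrophic, because the auxotrophy definition conditions on growth in
the original medium.  The full medium is required to contain all 20
amino acids, so every auxotrophy is in principle observable.

## Statistics

* **Fisher exact 2x2**: two-sided p by the point-probability convention
  (sum of hypergeometric probabilities no larger than the observed
  table's), as in `stats::fisher.test`; the reported effect is the
  sample log2 odds ratio with the Haldane-Anscombe +0.5 correction when
  any cell is zero.  The sample OR was chosen over the conditional-MLE
  OR because it is closed-form and only its sign and magnitude are
  interpreted.  Tables with an empty margin are flagged untestable and
  excluded from the correction family.
* **Partial Spearman**: rank-transform everything (average ranks on
  ties), residualize the x- and y-ranks on the confounder ranks by least
  squares, correlate the residuals; p from the t approximation with
  `n - 2 - k` degrees of freedom.  With zero confounders this reduces
  exactly to plain Spearman.  Binary confounders (sex) are rank-coded
  like any numeric vector; constant confounders drop out via the
  rank-deficient fit.
* **BH-FDR**: `stats::p.adjust` applied within one family per screen
  (by-product screen, metabolome screen, per-amino-acid stability
  family), mirroring per-figure correction; headline two-test contrasts
  (diversity, stability) are reported uncorrected.  The family split is
  configurable because the original analysis does not pin its family
  boundaries.
* **UniFrac**: computed on the genome phylogeny by accumulating
  per-branch abundance masses in postorder.  Unweighted = unique branch
  length over spanned branch length; weighted-normalized =
  `sum(l |A-B|) / sum(l (A+B))`.  Both are in [0, 1], symmetric, and
  invariant to rescaling branch lengths; agreement with an independent
  implementation is part of the test suite.  Unrooted trees are
  midpoint-rooted first for determinism.

## What the synthetic data emulate — and what they do not

The generator replaces three things the original study takes from
outside: a reference genome catalog, cohort metagenomes, and a serum
metabolome.

**Chassis models.**  Each genome is a small network built around
pyruvate: glucose splits into pyruvate, a second generic precursor, and
ATP; each amino acid has a lumped one-step biosynthesis from one of the
two pools (Ala/Ile/Leu/Val from pyruvate at 2:1, the rest from the
generic pool at 1:1), an exchange and a transporter; biomass consumes
all twenty amino acids (0.05 each) plus ATP (2.5); lactate branches
drain pyruvate and an acetate branch drains the other pool.  Growth is
ATP-limited by construction, so pyruvate not spent on biosynthesis must
leave as lactate: the prototroph secretes 0.85 mmol/gDW and each healed
pyruvate-family knockout adds 0.1, crossing the producer cutoff at two
knockouts.  This reproduces the mechanistic BCAA-to-lactate redirect
with one lumped reaction per pathway; it does not attempt realistic
stoichiometry, cofactor balancing, or gene-to-reaction structure.

**Cohorts.**  Each sample has a latent community-auxotrophy load that
tilts which genomes are present and how evenly abundance spreads
(Dirichlet weights with load-dependent concentration).  Both links are
controlled by one `diversity_effect` knob (0 = no link); the abundance
tilt is kept mild because a strong tilt concentrates mass and works
against the evenness link.  Longitudinal pairs replace a fraction of
community mass with a freshly drawn community, the fraction decreasing
in the subject's weighted auxotrophy count (`stability_slope`).  The
metabolome is linear in selected `y_jk` plus confounder loadings and
noise; BMI is negatively coupled to the total auxotrophy load so the
screen has a genuine confounding path to remove.  Effect sizes default
to values giving clear recovery at the study's sample sizes (185
cross-sectional samples, 100 subjects); they are study conditions, not
tuning knobs.

Passing tests on these data show that the pipeline recovers planted
structure through every stage — they do not show that real gut genomes
are this clean.  Real reconstructions carry gap-filling artifacts,
medium-prediction uncertainty and annotation noise that the chassis
family deliberately omits; the screen's published validation against
in vitro auxotrophies is the check this synthetic layer cannot replace.

**Completeness bias.**  With `completeness_coupling > 0`, genomes with
lower simulated completeness receive extra knockouts, reproducing the
negative completeness-versus-auxotrophy-count correlation that motivates
the >= 85% completeness filter.  The coupling applies to the models and
the truth table alike, so the QC statistic — not the screen — is what
detects it.

## Numerical and design choices

* Reproducibility: all generators run under a locally scoped
  Mersenne-Twister seed; a fixed `cohort_spec` seed yields byte-identical
  files.  The analysis stages themselves are deterministic.
* The genome catalog is generated once and held fixed across replicate
  cohorts (as a reference catalog would be); replicate analyses reuse the
  persisted auxotrophy profiles through the pipeline's profile-reuse
  path, which the test suite verifies equals a full rerun.
* Desk-scale problem sizes: 200 genomes (~70 reactions each), 185
  samples, 100 subjects; a full pipeline run is a few tens of seconds on
  one core.  These sizes were chosen so the whole analysis, including
  replicate and permutation checks, runs comfortably on a laptop.
* Degenerate inputs are reported, not patched: fewer than two present
  genomes yields a missing Hamming value; constant statistics yield NA
  correlations flagged as undefined; a medium metabolite without an
  exchange reaction warns and is skipped.

## Known limitations

* Gene-protein-reaction rules, thermodynamics and kinetic constraints
  are out of scope; the screen sees only network topology and bounds.
* Vitamin and nucleotide auxotrophies are not modeled.
* Community metabolism is treated genome-by-genome; no joint
  community-FBA or explicit cross-feeding flux is computed — the Hamming
  statistic is an indicator of cross-feeding *potential* only.
* The UniFrac variant used in the original analysis is not stated; the
  default here is the abundance-weighted normalized form, with the
  unweighted form available and both exercised in the tests.
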