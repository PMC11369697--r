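---
title: "Feature engineering for metabolite-protein interaction prediction from metabolic phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature engineering for metabolite-protein interaction prediction from metabolic phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxmpi)
```

## The model behind the features

The flux of a reaction catalysed by a single enzyme factorizes as
$v = k_{cat}\,E\,\eta(\mathbf{x}, \mathbf{k})$, where $E$ is enzyme
abundance, $k_{cat}$ the turnover number, and $\eta \in [0, 1]$ the fraction
of catalytic capacity realized as flux. Whatever the kinetic law, the
regulatory action of metabolites — substrate saturation, allosteric
activation, inhibition — is exerted through $\eta$: it is a function of
metabolite concentrations and kinetic parameters that differ per reaction
and are rarely known. `fluxmpi` avoids assuming a kinetic form. It
estimates $\eta$ empirically from matched fluxes and proteomics,

$$k_{app,i,j} = \frac{|v_{i,j}|}{E_{i,j}}, \qquad
  k_{cat,i} = \max_j k_{app,i,j}, \qquad
  \eta_{i,j} = \frac{k_{app,i,j}}{k_{cat,i}} \in [0,1],$$

and pairs it with a constraint-based proxy for metabolite concentration,
the flux sum

$$M_{k,j} = \tfrac12 \sum_r |S_{k,r}\,v_{r,j}|,$$

half the total absolute flux through metabolite $k$ (equal to both its total
production and total consumption at steady state). If metabolite $k$
regulates the enzyme of reaction $i$, the condition profile of
$\eta_i$ should co-vary with that of $M_k$; if not, the two profiles are
unrelated. Classifying (metabolite, reaction) pairs on features built from
the two profiles turns MPI identification into supervised learning, and GPR
rules translate predictions to (metabolite, protein) pairs.

Assumptions worth keeping in mind: the $k_{cat}$ proxy assumes each reaction
reaches (near-)saturation in at least one condition, so $\max_j \eta = 1$ by
construction; $|v|$ is used so reversible reactions carrying negative flux
still yield a positive apparent turnover (the estimate is direction
agnostic); and flux sums stand in for concentrations only up to a monotone,
condition-dependent relationship.

## Stage by stage

**Flux estimation.** `pfba()` is a two-stage LP: stage 1 fixes biomass — to
the measured growth rate when the condition provides one (`lb = ub`,
treating the measurement as exact), else to the maximal objective value —
and stage 2 minimizes $\sum_r |v_r|$ at that biomass with the standard
split $v = v^+ - v^-$, $v^\pm \ge 0$. `apply_condition()` first overwrites
bounds with the condition's uptake and measured-flux bounds and closes
reactions whose GPR is unsatisfiable under the knockouts (every isozyme
unit hits a knocked-out gene). Externally estimated fluxes can be loaded
with `read_fluxes()` instead, bypassing pFBA entirely.

The LPs are solved by an internal two-phase dense primal simplex with
Bland's anti-cycling rule (`R/lp.R`). Variables fixed by their bounds
(`ub - lb <= 1e-6`) are eliminated before solving, which keeps the tableaus
small; feasibility and steady state are verified at $10^{-6}$
(`max |S v| \le 10^{-6}`), and the simplex pivots at $10^{-9}$. Alternative
pFBA optima are possible in principle; the returned solution is the
deterministic one the pivoting rule selects, and nothing downstream depends
on which optimum is returned beyond $\sum|v|$ and the flux sums (the
package's own tests use toy models with unique optima).

**Reaction-level abundance.** Gene-level proteomics maps to reactions as
minimum over AND-units (a complex is limited by its scarcest subunit) and
sum over OR-units (isozyme pools add). The underlying data rarely say how
multi-subunit abundance should be aggregated; this convention is the common
one in proteomics-constrained modelling and is the package default
(`reaction_enzyme_abundance()`), with reactions lacking any fully measured
unit left undefined rather than imputed.

**Normalization and filtering.** Profiles are max-normalized
($\tilde\eta = \eta / \max_j \eta$, $\tilde M = M / \max_j M$); all-zero
profiles cannot be normalized and are dropped with a reason. The
coefficient of variation (sample standard deviation over mean, `ddof = 1`;
the estimator choice is ours, the convention in the field is unstated) is
computed per normalized profile, and a pair is kept only if both
$CV_{\eta_i}$ and $CV_{M_k}$ reach the threshold — flat profiles carry no
information and make classifiers latch onto noise. The threshold is a
tunable (`cv_threshold`, default 1, dimensionless); the synthetic validation
runs use 0.5 so that filter strictness and signal recovery are probed
separately rather than conflated. Distance features need a complete profile
in every condition, so remaining undefined entries are removed greedily —
whichever single reaction or condition carries the largest fraction of
undefined entries is dropped, repeatedly, with every removal logged.

**Pair features.** Each condition $j$ places a pair at
$(\tilde\eta_{i,j}, \tilde M_{k,j})$ in the unit square. The feature vector
concatenates, row-major, the upper triangle (diagonal excluded — its
entries are identically zero and carry nothing) of the $J \times J$
condition-pair Euclidean distance matrix: $J(J-1)/2$ values in
$[0, \sqrt 2]$. Two ablation variants probe where the signal lives:
`"concatenated"` ($[\tilde\eta_i, \tilde M_k]$, length $2J$) and
`"constant"`, which replaces the flux-sum difference with a constant $c$
(default 0, a tunable) so only $\eta$ information remains.

**Gold standards.** Interaction scores use the 0–1000 convention with a
strict cutoff (> 500) for positives. Negatives come from four strategies:
*potential-negative* PU-style voting (partition the assumed negatives into
$t = \lfloor n_{neg}/n_{pos}\rfloor$ subsets, train one RBF-SVM per subset
against all positives, keep pairs that all $t-1$ held-out classifiers call
negative; leftover pairs after the integer division are spread round-robin
so subsets differ by at most one and each pair is trained on exactly once);
*score-based* labelling (unscored/low-scored pairs whose metabolite and
protein both occur among positives); *Tanimoto* labelling (pairs whose
metabolite has zero fingerprint similarity to a known binder of the same
protein; two all-zero fingerprints get similarity 0 with a warning); and
direct labels. The voting SVM uses `e1071::svm()` defaults (RBF kernel,
cost 1) — the hyperparameters are exposed but the scheme's outcome should
not hinge on them, since only unanimous negatives are kept.

**Classification.** `balanced_cv()` implements the evaluation protocol:
stratified $k$-fold splits (default 5) repeated (default 100; the validation
suite uses 20 repetitions to keep a full run in tens of seconds at the
synthetic problem sizes), training folds balanced by keeping all positives
and subsampling an equal number of negatives, test folds evaluated as-is.
Hyperparameters are tuned per outer fold by an inner 3-fold grid search on
the balanced training set; a single-combination grid skips tuning, which is
how the validation suite runs (at ~45 positives the inner split leaves
~15 positives per inner fold — too few for a stable selection, and the
selection noise measurably hurts the outer estimate). Default grids are in
`default_grid()` and are plain-R configurable. AUC is the Mann–Whitney rank
statistic with half credit for ties; AUPR is average precision over
distinct-score thresholds; weighted F1 and the confusion matrix use the
classifier's native hard prediction (probability 0.5 for RF/MLP, decision
value sign for SVM). Confusion matrices are averaged over repetitions in
the exported aggregates, noted in the output metadata. One master seed
drives per-repetition derived seeds for folds, subsampling and model fits,
so identical configurations are bit-identical.

**Random-label control.** The chance-level baseline draws a *fresh*
balanced random labelling per repetition (`random_label_control()`). With a
single fixed random labelling the repetition mean converges to a
labelling-specific value (repetitions only resample folds), not to 0.5;
re-randomizing per repetition is what makes the control converge to
chance, which is the property the baseline exists to demonstrate.

**Ranking.** Out-of-fold predictions are aggregated per pair; a pair counts
as predicted interacting when positive in at least a configurable fraction
of the repetitions that tested it (default 0.5 — the aggregation rule is a
package choice). `rank_metabolites()` then counts distinct regulated
reactions per metabolite.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` builds a complete study with known ground truth.
Defaults: a 4-branch toy model with 15 enzyme-catalysed steps per branch,
$J = 12$ conditions, 40 planted interactions, log-normal abundance noise
$\sigma = 0.2$, 400 decoy pairs.

The toy model is one cytoplasm plus an extracellular compartment: a shared
trunk carbon source, and per branch an own primary substrate, an upper
chain forking into two sub-chains that each end in a biomass precursor and
receive their own mid-chain auxiliary carbon source, side drains on every
interior metabolite, overflow valves, and a trunk sink. GPR rules are 80%
single-gene, 10% two-gene complex, 10% two-gene isozyme pair. Conditions
force uptake levels drawn as jittered log-spaced series spanning one order
of magnitude, shuffled independently per branch — a designed
carbon-limitation series, which guarantees the spread for any seed (i.i.d.
log-uniform draws can cluster into a much narrower range and leave every
normalized profile too flat to pass the CV filter). Auxiliary sources are
present with probability 0.7 at 0.3–1.2 times the branch uptake; drains
consume a spiky random 30–60% of each branch's carbon; a quarter of
conditions carry a single-gene knockout that is structurally checked (and
retried, with fallback) so no GPR becomes unsatisfiable. This topology is
deliberate: with proportional fluxes every normalized profile collapses to
one shape and the pair features carry no per-metabolite signal at all,
while fully independent branches with forked sub-chains give each
metabolite a recognizably distinct flux-sum profile — the property the
distance features need. Metabolites on the *same* sub-chain remain highly
correlated, which is realistic (adjacent pathway intermediates co-vary) and
is the main source of residual classifier confusion.

Planted regulation: 40 chain reactions get one regulator metabolite each
(a single regulator keeps recovery identifiable; multi-regulator $\eta$
compositions are out of scope), with
$\eta_{true} = \hat M^\alpha / (K^\alpha + \hat M^\alpha)$ for activation
and $K^\alpha / (K^\alpha + \hat M^\alpha)$ for inhibition, $\alpha \in
\{2, 3, 4\}$, $K \sim U(0.25, 0.55)$ for activators and $U(0.15, 0.35)$ for
inhibitors — a mid-range $K$ would leave an inhibited $\eta$ near its
maximum across most conditions, a flat profile the CV filter would remove.
Unregulated reactions draw spiky clipped log-normal profiles
($\sigma_{profile} = 1.5$ on the log scale) so they, too, pass the filter.
Abundances are back-computed as $E = |v| / (k_{cat}\,\eta_{true})$ times
$e^{\sigma z}$ noise and distributed over genes by inverting the GPR
aggregation policy (knocked-out genes get 0; enzymes of momentarily idle
reactions stay expressed at a baseline). Scores are 501–1000 for truth
pairs, 100–500 for decoys; decoys are stratified so every positive's
metabolite and protein also occur among them; fingerprints form two
disjoint-half bit clusters so zero-similarity pairs exist.

At $\sigma = 0$ the pipeline's recovered $\eta$ equals the planted
$\eta_{true}$ up to the per-reaction rescaling by its maximum over active
conditions — the closed-loop identity the test suite checks to $10^{-9}$.

What passing these tests does *not* show about real data: the generator has
exact steady-state fluxes (no flux-estimation error), one compartment of
interest, single-regulator kinetics, no shared enzymes between reactions,
no systematic proteomics biases (only i.i.d. log-normal noise), and a truth
that is expressible in the feature space by construction. Real gold
standards also contain label noise of their own; the synthetic decoys are
clean non-interactions except for the deliberate pathway-correlation
ambiguity described above.

## Numerical choices and degenerate inputs

* LP feasibility/steady-state tolerance $10^{-6}$; simplex pivot tolerance
  $10^{-9}$; Bland's rule for determinism and anti-cycling.
* Fixed variables (`lb == ub` within $10^{-6}$) are eliminated from LPs.
* `max_normalize()` refuses all-zero profiles (drop signal, not silent 0/0).
* `compute_eta()` drops reactions with no defined $k_{app}$ or
  $k_{cat} = 0$; the greedy row/column removal prefers dropping the
  reaction on ties, keeping conditions (features) intact.
* CV filter requires at least 2 shared conditions (CV is undefined below).
* `cv_filter` retains a pair only if *both* CVs pass — removal reasons are
  recorded per pair.
* Inner tuning ties resolve to the first grid combination (declaration
  order), deterministically.
* `tanimoto()` of two all-zero fingerprints is 0 by documented convention.
* Balanced subsampling uses `min(n_pos, n_neg)` per class, so the training
  set stays exactly balanced even if negatives are scarcer than positives.

## Problem sizes in the validation suite

The test and acceptance runs use the default synthetic bundle (roughly 65
retained metabolites x 60 reactions, ~370 labelled pairs, 66 distance
features) with 20 repetitions of fivefold CV and single-combination RF
grids (`ntree = 300`); the complete suite runs in about a minute on one
CPU. The classification protocol itself defaults to 100 repetitions and
full grids for real analyses.

## Known limitations

* pFBA assumes the biomass objective describes each condition; conditions
  violating it (stress, overflow regimes) bias $v$, hence $M$ and $\eta$.
* The $k_{cat}$ proxy is a lower bound realized only if some condition
  saturates the enzyme; systematically unsaturated enzymes compress
  $\eta$ toward 1 and lose contrast.
* Classifiers are organism- and dataset-specific: features are tied to the
  model and the condition panel, so trained models do not transfer across
  organisms.
* Metabolites sharing a pathway have correlated flux sums; predictions
  cannot distinguish regulators within a tightly correlated group, on
  synthetic or real data alike.
* The distance construction discards condition identity (only pairwise
  geometry is kept); the concatenated variant keeps it and is provided for
  comparison, with RF feature importances (`feature_importance()`) to
  inspect which side carries the weight.
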