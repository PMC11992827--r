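---
title: "Valuing effective compounds of an herbal formula: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valuing effective compounds of an herbal formula: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctpdn)
```

Multi-component herbal formulas act through many compounds binding many
protein targets, and picking out the handful of compounds that actually
drive an observed therapeutic effect is the central screening problem this
package addresses. It implements three cooperating analysis chains: a
weighted compound--target--pathway--disease network (CTPDN) ranked by
shortest paths, a feature-based compound--target interaction (CTI)
classifier, and an untargeted serum-metabolomics differential screen. A
synthetic-data module generates every input with planted ground truth, so
all three chains are testable offline at desk scale.

## The weighted network model

The network has four node layers -- compounds, protein targets, signalling
pathways, diseases -- and four edge classes (CTI, TTI, TPI, PDI). Raw edge
scores are put on a common footing in three steps:

1. **Raw score `S`.** For compound--target edges, `S = s_i / s_m`: the
   docking interaction score of the candidate relative to the native
   reference ligand of the same target (docking is consumed as input, never
   executed here). For target--target edges the STRING-style combined score
   in (0, 1] is used directly; for target--pathway edges membership scores 1;
   pathway--disease links are existence edges.
2. **Length `L = 1/S`**, with `+Inf` for absent interactions (for example
   a failed docking).
3. **Weight `W = 1/(1 + exp(-L))`**, except that pathway--disease edges are
   pinned at `W = 1` exactly. Any finite positive length lands strictly in
   (0.5, 1).

The symmetric adjacency matrix (diagonal 0, `+Inf` off-diagonal for absent
pairs) feeds a Floyd--Warshall all-pairs shortest-path pass with next-hop
path reconstruction. A compound's value is its **mean shortest-path length
over all disease nodes**, ranked ascending; reconstructed paths are
classified as `C-T-P-D`, `C-T-T-P-D` (one PPI relay), or `other`, and
per-node usage counts over all shortest paths identify the load-bearing
targets and pathways.

```{r network-example}
fix <- gen_network(sim_spec(seed = 42))
net <- build_network(fix$compounds, fix$docking, fix$ppi, fix$pathways)
rk <- suppressWarnings(rank_compounds(net))
head(rk$ranking, 3)
head(node_usage_counts(rk$paths, net, "target"), 3)
```

### Design choices that were genuinely open

* **TTI score direction.** PPI-derived weights are often described as
  "reciprocal combined scores", but the length step here *already* takes a
  reciprocal; applying both would make strong PPI edges *long*. The
  default therefore feeds the combined score directly into the uniform
  `L = 1/S` step (strong interaction, short edge);
  `tti_mode = "reciprocal"` restores the double reciprocal for
  comparison.
* **TPI weighting.** Pathway membership is treated as an existence edge
  (`S = 1`) by default; `tpi_mode = "qweight"` uses `-log10(q)` clipped to
  `[1e-3, 1e3]` for workflows that want enrichment-confidence weighting.
* **Directionality.** The network is modelled undirected (symmetric
  matrix); the path-shape classifier tags layer-order-violating walks as
  `other` rather than excluding them from the distance computation.
* **Tie-breaking.** Node ids are sorted lexicographically, Floyd--Warshall
  only replaces a path on strict improvement, and ranking ties are broken
  by compound id -- results are deterministic for a given input.
* **Duplicate edges** keep the largest raw score (strongest interaction),
  with a warning.

A consequence of the literal weighting worth stating plainly: every
canonical `C-T-P-D` path has length strictly between 2.0 and 3.0, because
the two non-PDI hops each weigh more than 0.5 and the PDI hop exactly 1.
Mean path lengths below 2 are unreachable under this weighting; the
`sigmoid_sign = "negative"` switch (weights in (0, 0.5)) is provided for
sensitivity analysis but is not the default and is not treated as
equivalent.

## The compound--target interaction classifier

Each compound--target pair is described by a fixed-order descriptor block:

| block | columns | source |
|---|---|---|
| fingerprint | 167 (MACCS) or 2048 (ECFP6) | OpenBabel via ChemmineR |
| ADMET levels | 5 (AS, BBB, CYP2D6, hepatotoxicity, PPB) | consumed as input |
| protein descriptors | 29 | computed from sequence |

The MACCS block is emitted as 167 positions with position 0 present but
unused, so bit index equals MACCS key number; this layout is what makes the
dataset arithmetic come out at 167 + 5 + 29 = 201 columns (MACCS-based) and
2048 + 5 + 29 = 2082 (ECFP6-based). ECFP6 is the radius-3
extended-connectivity fingerprint hashed by OpenBabel and folded (bitwise
OR of halves) to 2048 bits. The 29 protein descriptors are the 20
amino-acid composition counts, theoretical pI (bisection on the
Henderson--Hasselbalch net charge with the Bjellqvist pKa set), the two
280 nm extinction coefficients (Edelhoch/Pace increments; cystine pairs
`floor(nC/2)`), three N-end-rule half-lives (Expasy table; open-ended
entries encoded as their bound, minutes as fractional hours; the unlisted
E. coli value for N-terminal Pro is encoded as the modal bound 10 h), the
Guruprasad instability index, Ikai's aliphatic index, and Kyte--Doolittle
GRAVY. All constant tables are the standard published ones, embedded in
the package source. Four dataset kinds combine the two fingerprints with
full-length (`*F`) or motif (`*M`) sequence variants; motif sequences are
inputs (motif discovery is out of scope). Exactly duplicated descriptor
columns can be removed with `drop_duplicate_columns()` (first occurrence
kept); conformance counts are quoted before removal, and both counts are
reported.

The classifier is **discrete AdaBoost** (SAMME-style): weak learners are
rpart classification trees grown on the weighted sample and pruned back to
at most `max_splits = 20` splits via the complexity table; the ensemble
decision is `sign(sum_k alpha_k G_k(x))` with
`alpha_k = lr * 0.5 * log((1-err_k)/err_k)` and `lr = 0.1`, 30 learners.
A score of exactly zero predicts negative (documented tie policy).
Normalization is min--max to [0, 1] by default (z-score selectable),
fitted on training data only and replayed at prediction time; replayed
values outside [0, 1] are allowed. Cross-validation is stratified 10-fold;
fold assignment is keyed to the seed *and to row contents* (rows are
canonically ordered before assignment), so permuting input rows cannot
change the reported metrics. Metrics are precision, recall, F1, the rank
AUC `(sum of positive ranks - M(M+1)/2)/(MN)` with average ranks on ties,
and MCC with the zero-denominator convention MCC = 0. The per-target
screen reports the percentage of compounds predicted to interact with each
target ("rate of successful CTI").

```{r cti-example}
ds <- gen_cti_dataset(sim_spec(seed = 11, n_pairs = 400))
ft <- assemble_feature_table(ds$pairs, ds$compounds, ds$sequences, "MF")
model <- fit_adaboost(ft, seed = 1)
model
```

## The metabolomics screen

The preprocessing chain runs in a fixed order, each stage logged with its
survivor count: features missing in more than 80% of samples are removed
and remaining gaps imputed with the feature mean; features with QC
relative standard deviation above 20% are removed; the 40% of features
with the lowest raw-scale standard deviation are dropped (ties broken by
feature id; exactly `ceiling(0.6 F)` survive); then each sample is
sum-normalized to the median total, log10-transformed with a pseudo-count
of half the smallest positive scaled intensity, and mean-centred per
feature (unit-variance scaling behind `autoscale = TRUE`).

Differential metabolites are called by three simultaneous criteria:
PLS-DA VIP > 1 (in-package NIPALS implementation; the VIP definition used
satisfies `mean(VIP^2) = 1` identically), two-sided Welch t-test p < 0.05
on the log scale (raw p by default; BH adjustment is deliberately not
applied, matching common practice in this workflow), and bidirectional
fold change `max(FC, 1/FC) > 1` computed on the pre-log sum-normalized
scale. The screening convention "absolute fold change > 1", read literally
on a ratio, would select up-regulation only even though both directions
are of interest; the bidirectional form is therefore the default, with the
threshold configurable. An orthogonalized variant of the discriminant model adds
nothing to the VIP-thresholding criterion and is out of scope. Biomarker
panels are the top-k features by random-forest importance aggregated over
repeated stratified cross-validation; panel performance (accuracy, rank
AUC) is estimated without leakage by re-selecting the panel inside every
training fold, and panels from different group contrasts can be
intersected.

Two behaviours of the chain deserve explicit statement. First,
sum-normalization introduces compositional closure: a very large group
effect on one feature slightly shifts every other feature's normalized
value in the opposite direction. Second, the raw-scale SD filter is
abundance-driven -- low-abundance features have small absolute SDs
regardless of effect size, so a genuinely differential but faint feature
can be variance-filtered away. Both are properties of the chain as
specified, not artefacts; the package's power and calibration simulations
therefore exercise the screen with the variance filter disabled
(`drop_fraction = 0` is a supported setting whose identity behaviour is
tested) so that they measure the screen itself.

## What the synthetic generators emulate

`gen_network()` draws reference docking scores `s_m ~ U(20, 60)`, score
ratios `U(0.5, 1.5)`, docking success at rate 0.3 (whole-formula success
rates in this setting are typically 20--35%), PPI edges at density 0.3
with combined scores `U(0.4, 0.99)`, and random pathway membership and
disease links, guaranteeing every disease is reachable. The planted
compound docks every target with ratio `planted_multiplier` times the
per-target maximum of all other compounds; because weights are strictly
decreasing in the score, any multiplier > 1 makes it provably rank 1.

`gen_cti_dataset()` builds 966 labelled pairs by default (a typical
docking-labelled set size at formula scale) from ~60 compounds whose SMILES come
from a small fragment grammar (rings, chains, O/N substitutions --
fingerprints need diversity, not pharmacological realism) and 20 random
protein sequences of length 50--300 (uniform or background residue
frequencies). Labels follow the planted rule *MACCS bit b set AND target
GRAVY above median*, with b chosen as the bit whose prevalence is closest
to 0.7 (yielding class balance near 0.35, inside the contracted
[0.3, 0.7] band), XOR independent label noise.

`gen_peak_table()` draws log-normal intensities (log10 baseline
`U(4, 7)`, within-group SD 0.15 -- typical for serum LC-MS peak areas),
three biological groups of 6 (control, model, treatment, matching a
standard rodent design) plus 6 pooled QC injections at 5% relative SD,
5% missingness completely at random in biological samples, and planted
features shifting the model group by `effect_size` within-group SDs on the
log scale (treatment stays at control level, emulating reversal). Ground
truth is emitted alongside every fixture.

What passing these simulations does *not* show: real serum data have
correlated features, heteroscedastic and intensity-dependent noise,
non-random missingness, batch drift, and real molecules have far richer
substructure than the grammar generates. The simulations validate the
machinery -- filters, statistics, ranking, recovery of planted signal at
stated effect sizes -- not field performance on any particular dataset.

## Numerical conventions and problem sizes

* `+Inf` encodes absent interactions throughout; JSON serialization writes
  the literal string `"inf"`.
* Floyd--Warshall updates on strict improvement only; path-length
  consistency is asserted to 1e-9.
* pI bisection runs to net charge below 1e-3 (well inside the 0.01 pH
  convention); logistic weights saturate to 1.0 in double precision for
  lengths above ~36, which only affects degenerate near-zero scores.
* The test and acceptance simulations use 12-node graphs (100 replicates)
  for the shortest-path oracle, 1000 random score sets for the AUC
  identity, 100 seeds for planted-network recovery, 1000 pairs for
  classifier recovery, and 100 replicates of 200-feature null tables for
  screen calibration -- sizes chosen so the whole suite runs in well under
  a minute per chain on one CPU while keeping the binomial bands tight.
* Degenerate inputs have defined behaviour: empty files load as empty
  tables with a warning; single-class labels, all-missing features,
  zero-variance features, unreachable compounds and empty pathway
  memberships are either errors with informative messages or documented
  fallbacks (VIP 0, MCC 0, exclusion with warning).

## Known limitations

Docking, ADMET prediction, motif discovery, database retrieval and raw
spectra processing are all consumed as inputs by design. Real-data
performance of a CTI classifier depends entirely on the docking-labelled
pair set behind it; the package validates the modelling machinery on
planted-rule data instead. The metabolomics chain implements
single-factor two-group contrasts; covariate adjustment and batch
correction are out of scope.
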