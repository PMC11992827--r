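# ctpdn

Screening the *effective compounds* of a multi-component herbal formula is
hard because the formula acts through many compounds, many protein targets
and several pathways at once. `ctpdn` implements a desk-scale toolkit for
this problem, built around three cooperating analysis chains:

1. **Weighted compound–target–pathway–disease network (CTPDN).**
   Compound–target edges score `S = s_i / s_m` (candidate docking score
   over the native-ligand reference), target–target edges use the PPI
   combined score, target–pathway edges membership, and every score is
   standardized via the length `L = 1/S` (`+Inf` for no interaction) and
   the weight

   `W = 1 / (1 + exp(-L))`, with pathway–disease edges pinned at `W = 1`.

   Compounds are then valued by the **Floyd–Warshall** all-pairs shortest
   path: the rank statistic is the mean path length from a compound to each
   disease node, and reconstructed paths (`C-T-P-D` or `C-T-T-P-D`) yield
   per-target / per-pathway usage counts.

2. **Feature-based compound–target interaction (CTI) classifier.**
   Pairs are described by a molecular fingerprint (MACCS, 167 positions,
   or ECFP6, 2048 bits), five ADMET levels, and 29 sequence-derived protein
   descriptors (composition, pI, extinction coefficients, N-end-rule
   half-lives, instability index, aliphatic index, GRAVY) — 201 or 2082
   columns in total. A discrete AdaBoost ensemble
   `f(x) = sign(Σ_k α_k G_k(x))` (trees with ≤ 20 splits, 30 learners,
   learning rate 0.1) is trained and evaluated by stratified 10-fold CV
   with precision, recall, F1, rank-AUC and MCC.

3. **Serum-metabolomics screen.** Missingness (> 80 %) filter with mean
   imputation, QC-RSD (> 20 %) filter, low-SD (40 %) variance filter, sum /
   log10 / mean-centre normalization, then a differential screen at
   VIP > 1 (NIPALS PLS-DA), Welch p < 0.05 and bidirectional fold change
   > 1, plus random-forest biomarker panels with leakage-free CV and panel
   intersection.

A synthetic-data module (`sim_spec()`, `gen_network()`, `gen_cti_dataset()`,
`gen_peak_table()`) generates every input format with planted ground truth,
so the whole pipeline runs and is tested without any external database.

## Worked example

```r
library(ctpdn)

# --- network chain on a synthetic fixture with a planted best compound
fix <- gen_network(sim_spec(seed = 42))
net <- build_network(fix$compounds, fix$docking, fix$ppi, fix$pathways)
net
#> Compound-target-pathway-disease network
#>   nodes: 24 (compound 10, target 8, pathway 4, disease 2)
#>   edges: 61 (CTI 23, TTI 11, TPI 19, PDI 8)

rk <- rank_compounds(net)
head(rk$ranking, 3)
#>   compound_id mean_length rank
#> 1         C01    2.314233    1
#> 2         C05    2.392929    2
#> 3         C04    2.393544    3
```

The planted compound `C01` (its docking ratios are twice the per-target
maximum of the others) attains the smallest mean shortest-path length and
ranks first; a canonical `C-T-P-D` path such as `C01->T02->P01->D01` has
length 2.31 — the sum of two logistic edge weights in (0.5, 1) plus the
pathway–disease weight of exactly 1.

```r
# --- CTI classifier on a planted labelling rule
ds <- gen_cti_dataset(sim_spec(seed = 11, n_pairs = 400))
ft <- assemble_feature_table(ds$pairs, ds$compounds, ds$sequences, "MF")
ft
#> CTI feature table (MF): 400 pair(s) x 201 descriptor column(s)
#>   labels: 142 positive / 258 negative
model <- fit_adaboost(ft, seed = 1)
head(screen_targets(model, ds$compounds, ds$sequences, "MF"), 3)
#>   target_id n_compounds success_rate
#> 1      T001          60     73.33333
#> 2      T002          60     73.33333
#> 3      T003          60     73.33333
```

`success_rate` is the percentage of compounds the model predicts to
interact with each target; under the planted rule (fingerprint bit AND
high-GRAVY target) high-GRAVY targets sit near the planted bit's
prevalence and low-GRAVY targets near 0.

```r
# --- metabolomics screen with three 4-SD planted features
gen <- gen_peak_table(sim_spec(seed = 7, n_features = 60, n_per_group = 10))
pt  <- normalize_table(filter_qc_rsd(filter_missing(gen$peaks)))
scr <- differential_screen(pt)         # Con vs Mod
head(scr[order(scr$p), ], 3)
#>   feature_id      vip            p       fc passes
#> 3      F0003 4.078908 1.199862e-09 4.227840   TRUE
#> 2      F0002 3.608776 1.318623e-08 3.974255   TRUE
#> 1      F0001 4.036604 5.453838e-08 4.300966   TRUE
```

The three planted features (`F0001`–`F0003`) pass all three criteria with
fold changes near `10^(4 * 0.15) ≈ 4`, exactly as constructed.

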