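# pathsurv

Pathway-informed sparse neural networks for survival analysis and tumor
pathology classification from metabolite concentration profiles.

## The problem

Intraoperative metabolomics (e.g. HRMAS NMR of resected glioma tissue)
yields, per tissue sample, a short vector of quantified metabolite
concentrations — typically a few dozen features for a few hundred
patients. Two clinically useful predictions from this vector are the
patient's survival risk and the tumor's pathology (aggressive vs benign).
Deep networks overfit badly at this sample size; `pathsurv` implements the
remedy of building biological structure into the architecture: the first
layer is masked by a binary metabolite × pathway incidence matrix
**M** ∈ {0,1}^{P×Q}, so a connection from metabolite *i* to hidden unit
*j* exists only if metabolite *i* belongs to pathway *j*. Each first-layer
unit is then a metabolic *pathway activation*

&nbsp;&nbsp;&nbsp;&nbsp;PA = ReLU(X (W ⊙ M) + b),

which cuts first-layer parameters from P·Q to the number of memberships
(468 instead of 5106 at the 37 × 138 scale) and makes the hidden layer
interpretable. Subsequent dense ReLU layers and a linear head produce
either a Cox risk score h(x), discrete-time hazard masses, piecewise
hazard rates, or a class probability.

The survival head is trained with the negative log Cox partial likelihood

&nbsp;&nbsp;&nbsp;&nbsp;−∑_{i: e_i=1} [ h(x_i) − log ∑_{j: t_j ≥ t_i} exp(h(x_j)) ],

(Breslow ties), or alternatively with a DeepHit-style discrete-time
likelihood + ranking loss or a piecewise-constant-hazard likelihood.
Models are evaluated by the Harrell and time-dependent (Antolini)
concordance indices, the latter scoring each comparable pair by predicted
survival S(t_i | x) at the earlier event time (Cox-type models compose
their risk with a training-fold Breslow baseline hazard). Shapley-value
attribution (exact enumeration or permutation sampling) quantifies the
importance of each input metabolite and of each pathway unit.

The package also ships the full experimental harness: patient-disjoint
repeated cross-validation (test fold *i*, validation fold *(i+1) mod k*),
the mask ablation suite (width-matched dense baseline, edge-count-matched
random mask, row-shuffled mask, dropout sweep, sample-size sweep), and a
generator of pathway-structured proportional-hazards cohorts with known
ground truth (log-normal concentrations, exponential baseline hazard,
calibrated uniform censoring, risk-linked malignancy labels).

## Worked example

```r
library(pathsurv)

# 1. Pathway incidence matrix (synthetic example mapping shipped in the
#    package: 37 metabolites x 138 pathways, 468 memberships)
pm <- example_pathway_matrix()

# 2. Simulate a glioma-scale cohort: 384 samples, ~30% censored, three
#    active pathways driving a proportional-hazards event process
cohort <- simulate_cohort(simulation_config(n = 384, pm = pm, seed = 42))
oracle_cindex(cohort)   # concordance ceiling of this cohort

# 3. Patient-disjoint 5-fold CV, repeated 3 times, pathway-masked vs a
#    width-matched dense baseline (time-dependent concordance)
ds <- cohort$data
folds <- make_folds(ds, k = 5, repeats = 3, seed = 1)
cfg   <- risk_model_config(input_dim = 37, depth = 3, pathway_informed = TRUE,
                           loss = "cox", seed = 10)
dense <- risk_model_config(input_dim = 37, depth = 3, first_width = 138,
                           loss = "cox", seed = 10)
run_cv(ds, cfg, pm, folds = folds, model_label = "pathway-informed")
run_cv(ds, dense, NULL, folds = folds, model_label = "dense-138")

# 4. Fit on the full cohort and rank pathways by mean |Shapley| importance
model <- fit_risk_model(build_risk_model(cfg, pm), ds)
pathway_importance(model, ds$features[1:50, ], ds$features[51:150, ],
                   n_permutations = 20, seed = 1)
```

Output:

```
<pathway_matrix> 37 metabolites x 138 pathways, 468 edges
oracle c-index (ceiling): 0.805
<experiment_result> pathway-informed | 15 iterations | median antolini 0.7106 (IQR 0.0747)
<experiment_result> dense-138        | 15 iterations | median antolini 0.6882 (IQR 0.0541)
<attribution_report> 138 features x 50 samples
  top features (mean |Shapley|):
   Glycine, serine and threonine metabolism      8.154
   HIF-1 signaling pathway                       7.3
   ...
```

Reading the numbers: the cohort's own generating risk could at best reach
a concordance of 0.805 on these realized event times; the pathway-masked
network reaches a median test concordance of 0.711 across the 15 CV
iterations versus 0.688 for the dense baseline with the same first-layer
width — the mask's sparsity pattern, not its size, is what helps. The
attribution report ranks pathway units by mean absolute Shapley value of
the predicted risk; at the full 138-pathway scale many pathway scores are
strongly correlated (they share metabolites), so credit is shared among
correlated units — see the vignette for when planted pathways are exactly
recoverable.

## Command line

A thin CLI wraps the same functions:

```sh
pathsurv=$(Rscript -e 'cat(system.file("cli/pathsurv", package = "pathsurv"))')
Rscript $pathsurv simulate --out-dir demo --seed 4
Rscript $pathsurv cv --features demo/features.csv --labels demo/labels.csv \
        --mapping demo/mapping.tsv --out demo/cv.tsv
Rscript $pathsurv build-matrix --mapping demo/mapping.tsv \
        --features demo/features.csv --out demo/matrix.tsv
```

Subcommands: `build-matrix`, `simulate`, `train`, `cv`, `ablate`,
`explain`; see `--help`. All outputs carry the seed; identical configs
reproduce identical tables.

## Data formats

* **Features**: delimited text (comma or tab, auto-detected), header row,
  first column = sample id, one column per metabolite.
* **Labels**: columns `sample_id`, `event` (1 = deceased), `duration_days`,
  optional `malignancy` (1 = aggressive), optional `patient_id`. Files are
  joined by sample id, not row order.
* **Mapping**: two-column `metabolite<TAB>pathway` edge list or GMT
  (`pathway<TAB>description<TAB>members...`).

The shipped mapping `inst/extdata/pathway_mapping_synthetic.tsv` is a
*synthetic* stand-in: real metabolite panel and KEGG pathway names, but
generated membership structure at the realistic 37 × 138 / 468-edge
scale. It exists so examples, simulations and tests run self-contained;
do not interpret it biologically.
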