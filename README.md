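# attnddg

Sequence-only prediction of antibody–antigen binding-affinity changes
(ΔΔG, kcal/mol) upon mutation.

Antibody engineering screens many candidate substitutions for their effect
on binding. The observable is the change in binding Gibbs free energy,

```
ΔΔG_bind = ΔG_mut − ΔG_wild,     ΔG = −RT ln(1/Kd) = RT ln Kd,
```

with positive ΔΔG meaning weakened binding. Structure-based predictors
need a reliable complex structure, which antibodies often lack. `attnddg`
implements a sequence-only regressor: frozen per-residue embeddings of the
four sequences involved — wild-type and mutant antibody and antigen — are
refined by a convolution-gated, rotary-position-embedded **dual multi-head
cross-attention** module (antibody queries attend over antigen keys and
vice versa, for both complexes), pooled to complex-level vectors
f_ab/f_ag, concatenated as `f = (f_ab^wt + f_ag^wt, f_ab^mt + f_ag^mt)`,
and regressed to ΔΔG by three fully connected layers. The attention
weights double as a per-residue interpretability signal: for a mutated
antibody position, the attended antigen residues rank its putative
interaction partners.

The package is written for R users in computational antibody engineering
and structural bioinformatics. It ships:

* AB-bind/SKEMPI-style CSV parsing with validation and rejection reports
  (`read_mutation_dataset()`), mutation-code handling (`CHAIN:WposM`),
  FASTA I/O and the thermodynamic conversions (`delta_g()`, `ddg()`);
* a pluggable frozen embedder contract with a deterministic mock embedder
  (`embedder_spec()`), so everything runs offline; protein-language-model
  backends plug in as adapter functions;
* the model itself (`attention_config()`, `attnddg_fit()`, `predict()`,
  broom-style `tidy()`/`glance()`/`augment()`, `autoplot()`);
* the three evaluation protocols used for such predictors: k-fold
  (`kfold_split()`), sequence-identity clustering at 30%
  (`identity_split()`), and mutation-depth extrapolation
  (`mutation_depth_split()`), with RMSE/R²/PCC/Spearman metrics;
* an attention-ablation harness (`ablation_run()`), attention-map
  extraction and interaction reports (`extract_attention()`,
  `top_interactions()`, `interaction_report()`);
* a synthetic-data generator with known additive + interaction ground
  truth (`generate_synthetic()`), used by the package's own end-to-end
  checks;
* a CLI (`inst/exec/attnddg`) with `simulate`, `fit` and `explain`
  subcommands.

## Worked example

```r
library(attnddg)

syn <- generate_synthetic(synth_config(n_complexes = 4, records_per_complex = 25,
                                       noise_sd = 0.2, seed = 42))
records <- syn$records
records
#> # A tibble: 100 × 5
#>   complex_id ab_chains ag_chains mutations           ddg
#>   <chr>      <list>    <list>    <list>            <dbl>
#> 1 SYN001     <chr [1]> <chr [1]> <tibble [1 × 4]> -0.696
#> 2 SYN001     <chr [1]> <chr [1]> <tibble [1 × 4]>  1.70
#> 3 SYN001     <chr [1]> <chr [1]> <tibble [1 × 4]> -1.52
#> # i 97 more rows
```

Each row is one labelled variant: wild-type chains, a mutation table
(1–7 substitutions) and the ΔΔG label in kcal/mol. Fit on 80 records and
evaluate on the remaining 20 (a deliberately quick demonstration fit —
30 epochs, a few seconds):

```r
fit <- attnddg_fit(
  records[1:80, ],
  spec   = embedder_spec(d = 32, seed = 1),      # deterministic mock embedder
  config = attention_config(d_model = 32, n_heads = 4, dropout = 0),
  train  = train_config(learning_rate = 3e-3, batch_size = 64,
                        max_epochs = 30, patience = 50, seed = 1))
glance(fit)
#> # A tibble: 1 × 8
#>   variant d_model n_heads n_params epochs best_epoch best_val_mse learning_rate
#>   <chr>     <int>   <int>    <int>  <int>      <int>        <dbl>         <dbl>
#> 1 full         32       4    15909     30          6         2.96         0.003

evaluate_model(fit, records[81:100, ])
#> # A tibble: 1 × 6
#>       n  rmse      r2   pcc spearman note
#>   <int> <dbl>   <dbl> <dbl>    <dbl> <chr>
#> 1    20  1.46 -0.0686 0.343   0.0316 <NA>
```

RMSE is in kcal/mol; R² can be negative when a model is worse than
predicting the label mean. Held-out accuracy at this desk scale is
modest by design — the methods vignette's limitations section explains
why (and why the mock embedder cannot show real-data accuracy). For
interpretability,
rank the antigen/antibody residues most attended from a record's mutated
position, with the mutant-minus-wild attention shift:

```r
interaction_report(fit, records[81, ], k = 3)
#> # A tibble: 3 × 8
#>   mutation  rank chain   pos aa    label  score       delta
#>   <chr>    <int> <chr> <int> <chr> <chr>  <dbl>       <dbl>
#> 1 A:Y2A        1 H         8 L     H:8L  0.0589  0.0000651
#> 2 A:Y2A        2 H        11 L     H:11L 0.0589  0.0000326
#> 3 A:Y2A        3 H        13 L     H:13L 0.0589 -0.00000700
```

(The focal mutation here is on the antigen chain A, so partners are
antibody residues; scores are head-averaged attention weights, near-uniform
for this barely-trained model.) `autoplot()` renders training histories
and attention heatmaps; see the methods vignette (`vignettes/methods.Rmd`)
for the model definition, the design decisions and the limits of what the
mock embedder can show.

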