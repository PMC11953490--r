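# pcrfed

Personalized contrastive-regularized federated learning for binary
medical-image segmentation, as a desk-scale R simulator.

## The problem

Imaging sites cannot pool raw data, and their data are not exchangeable:
scanners and populations shift each site's intensity distribution, and
cohort sizes differ by an order of magnitude. Plain federated averaging
(FedAvg) trains one global model across such sites; under this
non-IID-ness the single model can underserve individual sites, while
training each site alone wastes the federation and overfits the small
cohorts. `pcrfed` implements a *personalized* federated framework that keeps
part of each client's network local and regularizes local training with a
weighted model-contrastive loss, so every site ends up with its own model
that still absorbs the federation's shared knowledge.

It is aimed at methods researchers who want a fully deterministic,
CPU-scale federated-segmentation sandbox: every component — U-Net with
manual backpropagation, losses, site embedding, federated loop, baselines,
non-IID data generator — is in the package and unit-tested against
independent oracles.

## The method

Each client `k` holds `n_k` image/mask pairs and a U-Net whose parameters
are split as `w_k = w_k^s ∪ w_k^p` (shared / personalized; default:
normalization layers are personalized). Per communication round the server
broadcasts shared parameters, each client minimizes

    L = L_Dice + mu * L_BCE + alpha * L_con

for `E` local epochs of Adam, and the server aggregates
`w_g = Σ_k (n_k / N) w_k^s` (FedAvg weighting, `N = Σ n_k`). The
regularizer compares parameter-free poolings `xi = F(R(x))` of the bridge
representation under three models — live local, received global, and the
client's previous round —

    L_con = -beta * log[ exp(sim(xi, xi_g)/tau) /
                         (exp(sim(xi, xi_g)/tau) + exp(sim(xi, xi_b)/tau)) ],
    beta  = exp(-n_k / N),

with `sim` = cosine similarity and `F` = channel-wise spatial average- plus
max-pooling, concatenated. `beta` strengthens the pull toward the global
model exactly for the data-poor clients. Setting `alpha = 0` with an empty
partition reproduces textbook FedAvg (verified against an independent
implementation in the tests).

See `vignettes/pcrfed-methods.Rmd` for assumptions, conventions and design
rationale.

## Worked example

Four synthetic sites with quantity skew (60/50/30/20 samples) and distinct
intensity profiles; 20 communication rounds:

```r
library(pcrfed)

datasets <- fixture_datasets("toy4", seed = 1)   # generate + normalize + split
net <- network_config(depth = 2, base_channels = 8)
fed <- federation_config(rounds = 20, local_epochs = 1, batch_size = 32,
                         learning_rate = 1e-3, seed = 1)

run <- run_federation(datasets, net, fed)
evaluate_run(run, "test")
#> # A tibble: 4 × 3
#>   client   n_k  dice
#>    <int> <int> <dbl>
#> 1      1    42 0.897
#> 2      2    36 0.894
#> 3      3    22 0.903
#> 4      4    14 0.939

run_baseline("local_only", datasets, net, fed)
#> # A tibble: 4 × 4
#>   method     client   n_k  dice
#>   <chr>       <int> <int> <dbl>
#> 1 local_only      1    42 0.896
#> 2 local_only      2    36 0.891
#> 3 local_only      3    22 0.703
#> 4 local_only      4    14 0.806
```

Per-client test Dice is the fraction-of-overlap score `2|A∩B|/(|A|+|B|)` of
the thresholded prediction against the reference mask; `n_k` is the site's
training-split size. The federated, personalized run lifts the two
data-poor sites (clients 3 and 4) far above isolated local training (0.903
vs 0.703 and 0.939 vs 0.806) while matching it on the data-rich sites —
the data-scarcity mitigation the contrastive weight `beta` targets.
`tidy(run)`, `glance(run)` and `autoplot(run)` expose the per-round training
log; `sweep_hyperparameter("alpha", c(0.5, 0.8, 1.0, 1.2, 1.5), ...)` runs
ablation grids.

A thin command-line interface wraps the same functions
(`inst/cli/pcrfed.R simulate-data | train | evaluate | sweep`, YAML
configs, PNG/NIfTI site dumps).

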