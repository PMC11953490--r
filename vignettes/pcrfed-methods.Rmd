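---
title: "Personalized contrastive-regularized federated segmentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized contrastive-regularized federated segmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Hospitals and imaging sites cannot pool raw scans, yet a segmentation model
trained on one site's data rarely transfers to another: scanners, protocols
and patient populations shift both the intensity distribution of the images
(feature skew) and the number of available cases per site (quantity skew).
Federated learning (FL) trains across sites without moving data — a central
server repeatedly broadcasts model parameters, each client trains locally,
and the server aggregates the updates — but a single global model fit to
non-IID clients can serve every one of them poorly.

`pcrfed` implements a *personalized* federated scheme for binary
segmentation that attacks both skews at once:

1. **Parameter partitioning.** Each client's U-Net parameters are split into
   a shared part (broadcast and aggregated) and a personalized part (never
   transmitted). One model per client results.
2. **Weighted model-contrastive regularization.** During local training, a
   parameter-free embedding of the network's bridge representation is pulled
   towards the embedding produced by the received global model and pushed
   away from the embedding produced by the client's own previous-round
   model, with a strength that adapts to the client's data share.

Everything runs at desk scale on synthetic multi-site data, so the full
pipeline — data generation, federated training, baselines, sweeps — is
testable on one CPU.

## Model and losses

The backbone is a classic U-Net: `depth` levels of double 3x3
convolutions with normalization and ReLU, 2x2 max-pool downsampling, a
bridge (bottleneck) block, 2x2 transposed-convolution upsampling with skip
connections, and a final 1x1 convolution that emits pixel logits. The
sigmoid lives in the losses and metrics, not the network, for numerical
stability. `R(x)` denotes the bridge block's output (post-activation) — the
deepest, most compressed description of the input, shaped
`(H/2^depth, W/2^depth, base_channels * 2^depth)`.

**Supervised loss.** For predicted probabilities `p` and a binary mask `y`,

```
L_sup = L_Dice + mu * L_BCE
L_Dice = mean_i [ 1 - 2 |y_i * p_i| / (|y_i| + |p_i| + eps) ]
L_BCE  = mean_i mean_pixels [ -(y log p + (1-y) log(1-p)) ]
```

with `mu = 1` by default. `eps` (default `1e-6`) is added to the Dice
denominator *only*, so nonempty masks are scored essentially exactly while
the degenerate empty-vs-empty case stays defined (it evaluates to loss 1;
the evaluation-time `dice_score()` instead scores empty-vs-empty as 1,
the usual convention for a correctly absent foreground — training and
evaluation conventions are deliberately separate).

**Site embedding.** `site_embedding()` maps `R(x)` to a vector by
channel-wise spatial average pooling and max pooling. The two statistics are
concatenated (`2C` entries: all means, then all maxima). Concatenation was
chosen over element-wise summation because it preserves both statistics
losslessly and, like summation, adds no learnable parameters; the summed
variant remains available via `fusion = "sum"`. The embedding is not
L2-normalized — the cosine similarity used downstream normalizes internally.

**Weighted contrastive loss.** With `xi` the live local embedding, `xi_g`
the embedding under the received global model and `xi_b` the embedding under
the client's previous-round parameters,

```
L_con = -beta * log[ exp(sim(xi, xi_g)/tau) /
                     (exp(sim(xi, xi_g)/tau) + exp(sim(xi, xi_b)/tau)) ]
beta  = exp(-n_k / N)
```

where `sim` is cosine similarity, `tau` the temperature, `n_k` the client's
training-sample count and `N` the federation-wide total. `beta` is the
data-scarcity dial: a client holding little data gets `beta` near 1 and is
pulled strongly towards the global consensus; a data-rich client is left
freer to fit its own distribution. The loss is computed in log-sum-exp form
(`log(1 + exp((s_b - s_g)/tau))`), so small temperatures cannot overflow.
Per batch, per-sample losses are averaged unweighted, matching the sample
mean in the supervised terms. A zero-norm embedding raises an error rather
than scoring zero similarity: an all-zero embedding means dead features
upstream, and silent zeros would hide that bug.

**Total local objective:** `L = L_sup + alpha * L_con`, `alpha = 1` default.

## The federated loop

Each communication round: the server broadcasts the shared partition; every
client (full participation, ascending id) runs `local_epochs` of minibatch
Adam on `L`; the server then aggregates shared parameters as the
sample-size-weighted mean `sum_k (n_k / N) w_k`. Key mechanics:

* **Anchor snapshots.** `xi_g` comes from the received global shared
  parameters merged over the client's *own* personalized parameters (the
  global model has no personalized part of its own; reusing the client's is
  the minimal completion that yields a runnable network). `xi_b` comes from
  the parameters cached at the end of the client's previous round. Both
  snapshots are frozen in evaluation mode; no gradient flows into them. The
  live `xi` uses the training-mode model, through which gradients flow into
  the encoder and bridge.
* **First round.** The previous-round cache is initialized to the initial
  global parameters. Both anchors then coincide, the two-way softmax is
  exactly 1/2, and `L_con = beta * log 2` with identically zero gradient:
  the regularizer is provably inert in round 1 (the test suite checks the
  constant, the vanishing finite-difference gradient, and that the round-1
  trajectory is bit-identical with `alpha` 0 or 1).
* **Personalized partition.** Patterns select parameter names; the default
  `"norm"` keeps all normalization parameters local, the closest
  widely-used personalization mechanism for intensity-shifted sites, and the
  partition is freely configurable (`character(0)` shares everything).
  Shared normalization statistics, when they exist (batch norm) and are
  shared, aggregate like any other array.
* **Determinism.** Every RNG stream derives from
  `(seed, round, client, epoch)` via `derive_seed()`, so client order cannot
  affect results and identical configurations reproduce byte-identical
  logs. Resuming from a checkpoint replays the identical trajectory.

`run_baseline("fedavg")` is the exact `alpha = 0`, empty-partition special
case (verified against an independently coded FedAvg loop in the tests);
`run_baseline("local_only")` trains each client alone on a matched gradient
step budget (`rounds * local_epochs` epochs).

## Tunable parameters

| parameter | default | meaning / why this default |
|---|---|---|
| `mu` | 1.0 | Dice and BCE contribute equally to the supervised loss |
| `alpha` | 1.0 | contrastive weight; 0 recovers plain supervised FL |
| `tau` | 0.5 | contrastive temperature; 0.1–0.5 is the useful range, sweepable |
| `learning_rate` | 1e-4 | Adam step size for production-scale schedules (hundreds of rounds) |
| `rounds` | 200 | production-scale communication budget |
| `local_epochs` | 1 | local epochs per round; more epochs trade communication for drift |
| `batch_size` | 32 | minibatch size; clients with fewer samples fall back to full batch |
| `adam_betas` | (0.9, 0.999) | standard Adam moments |
| `partition_patterns` | `"norm"` | personalize normalization layers |
| `norm_kind` | `"instance"` | per-sample statistics avoid cross-site batch-statistic clashes |
| `threshold` | 0.5 | probability cut for mask prediction |

The desk-scale benchmark configuration used throughout the tests and the
acceptance script is the `toy4` fixture (four sites, 60/50/30/20 samples,
64x64 images), a depth-2, width-8 network, 20 rounds, one local epoch and
`learning_rate = 1e-3`. The raised learning rate is the package's choice for
this regime: a ~25k-parameter network on a high-contrast synthetic task has
a ~120-step budget, where 1e-4 would barely leave initialization while 1e-3
is a standard small-network Adam setting. Problem sizes were chosen so a
full three-seed comparison (personalized vs FedAvg vs local-only) completes
in minutes on one CPU.

## The synthetic generator

`generate_site()` draws, per image, one organ-like foreground shape — an
oriented ellipse or a star-convex "blob" (base radius modulated by low-order
angular harmonics) — filled at the site's foreground intensity over a
site-specific background level, plus Gaussian pixel noise. Per-sample
min-max normalization to [0, 1] follows (a constant image maps to zeros).
The fixtures spread background level, foreground contrast, noise, shape
family and size range across sites, so the *normalized* pixel marginals
differ measurably between sites (the suite checks pairwise
Kolmogorov–Smirnov distance > 0.1); sample counts supply quantity skew.
`prostate_counts` and `cervical_counts` mirror published six-site
(421/384/468/175/261/158) and eight-center (total 1033) cohort sizes.

Training augmentation applies small random rotations (±10°, bilinear for
images, nearest-neighbor re-binarized for masks), horizontal flips
(p = 0.5), and a random crop to 7/8 of the side padded back in place.

What the generator does **not** emulate: real anatomy and texture, 3-D
geometry and through-plane resolution, scanner physics and artifacts, label
noise, and production image sizes (384x384 / 256x256). Passing the
desk-scale benchmark therefore demonstrates that the machinery — losses,
partitioning, aggregation, regularization — is implemented correctly and
that personalization helps data-poor synthetic sites; it is *not* evidence
of clinical-scale performance, and published full-scale Dice figures are
out of reach (and out of scope) at this problem size. On this easy synthetic
task all federated variants converge to high Dice, so the
personalized-vs-FedAvg margin is small; the clearest desk-scale signal is
the gap to local-only training on the smallest site.

## Numerical and convention choices

* Arrays are column-major `(H, W, C, N)`; masks are 0/1 with 1 = foreground,
  row-major coordinates `(row, col)` from the top-left.
* Dice smoothing in the denominator only; BCE clamps probabilities to
  `[eps, 1 - eps]` at the API, while training uses the equivalent
  logit-space gradient `(p - y)/m` (the two agree within 1e-5 on clamped
  inputs, and the gradient path is verified against central finite
  differences).
* ReLU backpropagation uses subgradient 0 at exactly 0. With
  zero-initialized biases a freshly built unnormalized network has entire
  channels sitting on the kink, where two-sided finite differences
  legitimately disagree with any chosen subgradient; gradient tests
  therefore jitter parameters first.
* Instance normalization computes per-sample statistics in both training
  and evaluation mode (it has no running state); batch normalization keeps
  running means/variances (momentum 0.1) that are used in evaluation mode
  and treated as ordinary (non-gradient) parameter arrays for partitioning
  and aggregation.
* Splits use floor(`0.15 n`) for validation and test, remainder for
  training (the 7 : 1.5 : 1.5 rule), after a seeded shuffle.
* Checkpoints store parameters via native serialization plus a JSON
  metadata block (network configuration, partition patterns, round, seed);
  the round-trip is bit-exact.
* Ties in max pooling and in the embedding's max path resolve to the first
  (lowest linear index) element.

## Known limitations

* Single-process, CPU-only; no client sampling, secure aggregation or
  communication compression — full participation every round.
* Binary segmentation only (`out_channels = 1`), 2-D inputs, sizes
  divisible by `2^depth`.
* The pattern-based parameter partition is static; no data-driven selection
  of which parameters to personalize.
* Only the two reference baselines (FedAvg, local-only) are built in; other
  federated optimizers are out of scope.
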