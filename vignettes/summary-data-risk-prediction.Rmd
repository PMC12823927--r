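---
title: "Deep genetic risk prediction from LD summary matrices: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep genetic risk prediction from LD summary matrices: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldrisk)
```

## The problem

Individual-level genotype matrices are frequently unshareable; the linkage
disequilibrium (LD) matrix of a genetic region — the scaled Gram matrix
$R = \tfrac{1}{n} G^\top G$ of column-standardized additive dosages — often
is. `ldrisk` asks how much predictive information about a quantitative trait
survives when a deep model sees only $R$, and provides the machinery to
answer it: simulation of realistic SNP panels, LD construction, six model
families that run in both an *individual* mode (one output per sample) and a
*summary* mode (LD input), and an error estimate for the summary mode.

## Summary-mode training

A model in summary mode takes the training-set LD matrix
$R_{tr} = \tfrac{1}{n_{tr}} G_{tr}^\top G_{tr}$ as its single input example
and has $n_{tr}$ output units $O_1, \dots, O_{n_{tr}}$ — one per training
sample. Parameters are fit by ADAM to minimize

$$ L(O, Y) \;=\; \frac{1}{n_{tr}} \sum_{i=1}^{n_{tr}} (O_i - Y_i)^2 . $$

Because the training set is a single (input, target-vector) pair, an "epoch"
is exactly one gradient step and the configured batch size is recorded but
inert; this is the only reading under which the quoted per-family epoch
counts make sense, and `fit_summary()` implements it. With enough capacity
the target vector is memorizable (the training error can be driven near
zero), which the test suite verifies on a 50-sample toy.

### Bootstrap test error

At test time the *test* LD matrix is fed through the trained network,
producing $n_{tr}$ outputs. There is no given pairing between those outputs
and the $n_{te}$ test responses, so test error is approximated by
resampling: draw $n_{te}$ outputs uniformly with replacement, pair the
$i$-th draw with $y_i$, record the MSE $TE_b$, repeat $B$ times
(default $B = 1000$), and report
$\widehat{TE} = \tfrac{1}{B}\sum_b TE_b$ with its Monte-Carlo standard
error. Under this pairing rule each $TE_b$ is exchangeable over $i$, and the
estimator's expectation for every $B$ — and its $B \to \infty$ limit — is
the all-pairs mean

$$ \frac{1}{n_{tr} n_{te}} \sum_{j}\sum_{i} (O_j - y_i)^2
   \;=\; \mathrm{Var}(O) + \mathrm{Var}(y) + (\bar O - \bar y)^2, $$

implemented exactly by `allpairs_oracle()` and used as the estimator's test
oracle. The identity explains two regimes seen in practice: a summary model
whose outputs are near-constant at the trait mean lands at
$\widehat{TE} \approx \mathrm{Var}(y)$, while one that reproduces a sample
with the trait's own spread lands near $2\,\mathrm{Var}(y)$.

## The synthetic panel

`simulate_genotypes()` replaces a sequencing-derived reference panel with a
latent-Gaussian threshold model chosen to reproduce the two properties the
downstream stages actually consume: a controllable minor-allele-frequency
spectrum and blockwise local LD.

* Per-SNP MAF is uniform on `maf_range` (default `[0.001, 0.5)`, matching
  the common-variant filter threshold at the low end).
* Each of two haplotypes per individual thresholds a standard-normal latent
  variable at the MAF quantile, so dosages are Binomial(2, maf) marginally.
* SNPs in the same block of `block_length` consecutive sites share a latent
  factor with correlation `within_block_corr`; blocks are independent.
  Defaults are 20 SNPs per block at correlation 0.7 — a haplotype-block
  scale and LD strength typical of a 1 Mb common-variant panel; neither
  value is pinned by the study design, so they were fixed once on that
  prior reasoning.

Columns are standardized to mean 0 and sd $1/\sqrt{p}$
(`standardize_genotypes()`); the *population* sd convention (divide by $n$)
is the default because it makes each diagonal entry of the full-sample LD
matrix exactly the column mean square ($1/p$); the $n-1$ convention is a
flag. Scaling is computed on the full matrix before splitting — the split
then extracts rows, which is how the LD construction is described — and a
training-rows-only scaling flag exists for leakage-free practice.

The trait is linear and polygenic:
$Y_i = \sum_{k=1}^{K} w_k\, g_{i,k} + \varepsilon_i$ with
$K = \mathrm{round}(0.3\,p)$ causal SNPs drawn without replacement
(round-half-up, so $K$ does not depend on banker's rounding),
$w_k \sim N(0, 0.6^2)$ and $\varepsilon_i \sim N(0,1)$. On the standardized
scale with independent SNPs this gives
$\mathrm{Var}(Y) \approx 1 + 0.3 \times 0.36 \approx 1.11$. The split is
uniform with $n_{tr} = \lfloor 0.8\,n \rfloor$; at $n = 1092$ that is
873/219. The MAF filter uses the full-sample frequency (whether it should be
training-only is not specified anywhere; full-sample is the simpler and
stated choice).

What the generator does *not* emulate: realistic allele-frequency spectra
(no excess of rare variants), long-range LD decay within a block (the
correlation is block-constant), population structure, and any nonlinear
genotype–trait relationship. Passing tests therefore demonstrate that the
machinery is correct and that the linear-trait conclusions reproduce; they
do not certify performance on real panels.

## Model families and their conventions

All presets end in a linear output unit (width 1 individual, $n_{tr}$
summary). Hidden activations are ReLU throughout — stated only for the
convolutional stacks in the source architectures, adopted for the dense
stack as well since its cited ancestor uses ReLU.

* **DNN** (`dnn-paper`): dense 231–77–22–5, dropout 0.2 after layer 1 and
  0.5 after layer 3. Summary input: the row-major upper triangle of $R$,
  diagonal included (whether the diagonal was included is unstated; it is
  informative — column mean squares — so the default keeps it).
* **CNN** (`cnn-sim-*`, `cnn-real-*` and their `-2d` twins): the wide-panel
  structures use 50 filters of length 500 and one or five dense-50 layers,
  no pooling (none is stated), stride 1; the small-panel variants use
  32×5 (+ pool 2) and a 32×5 + three 64×3 stack, each convolution followed
  by pool 2. Summary mode reads diagonal LD blocks as images with the
  kernels' 2D twins (50×50, 5×5/3×3 with 2×2 pooling).
* **LSTM / BiLSTM** (`lstm-paper`, `bilstm-paper`): five stacked LSTM layers
  of 10 units / two bidirectional layers of 10 units, then a dense layer.
  Individual input is the SNP sequence, one value per timestep; summary
  input treats row $t$ of the LD matrix as the step-$t$ feature vector
  ($p$ timesteps × $p$ features).
* **Transformer** (`transformer-paper`): individual mode slices the SNP
  sequence into windows (1000 wide, stride 500 — 15 windows at $p = 8299$),
  embeds each scalar position-wise, applies a 6-head attention block, and
  averages attention outputs over positions and windows before a 64-unit
  feedforward. Summary mode flattens each diagonal LD block into a token,
  embeds to 128, adds sinusoidal positional encoding, applies two blocks of
  {6-head attention, dropout 0.1, residual, layer norm}, mean-pools tokens,
  then two dense-128 layers with dropout 0.1 and layer norm. The individual
  (64) and summary (128) feedforward widths differ in the source
  configurations and both are kept as printed.

Design points that were genuinely open:

* **Attention head width.** A 128-dim embedding with 6 heads does not divide
  evenly; the per-head key dimension is its own parameter
  (`ceiling(d_model/heads)` by default) with an output projection back to
  `d_model`, the convention of the Keras attention layer this stack implies.
* **CNN summary blocks.** Whether the 43 diagonal blocks form one example
  (features averaged) or 43 examples sharing a target is unstated;
  averaging per-block features before the dense head is the default —
  mirroring the transformer's stated averaging — and `blocks_as =
  "examples"` provides the alternative. Averaging also makes every
  block-consuming preset accept any number of blocks without rebuild.
* **Windows that do not tile.** At $p = 8299$, strided windows end at SNP
  8000; the default appends a flagged final window ending at $p$ so no SNP
  is silently dropped, and `strict_paper = TRUE` reproduces the exact
  15-window configuration with its uncovered tail.
* **Non-divisible block sizes** zero-pad the final diagonal block (flagged),
  keeping block tensors rectangular.
* **Initialization** is fan-based (Glorot) with the forget-gate bias opened
  at 1, deterministic given the build seed; the source gives no scheme.
* **Learning-rate decay** (`initial_lr * decay^epoch`) is applied per epoch,
  not per step; the per-step granularity is nowhere stated and per-epoch is
  the Keras default the quoted schedule mirrors.

Training presets carry the printed schedules: DNN 100 epochs / batch 256 /
lr 0.001 / decay 0.96; CNN 200 / 32 / 0.1 / 0.98; LSTM 10 and BiLSTM 5
epochs at batch 256, lr 0.001, decay 0.96; transformer 10 epochs at batch 8
(its learning rate is unstated; the ADAM default 0.001 is used). ADAM runs
with standard moment parameters (0.9, 0.999).

The layer stack (dense, convolutions, pooling, recurrent cells, attention,
normalization) is implemented natively in the package; the LSTM time
recurrence runs in compiled code because a step-by-step loop is the one
computation vectorized R cannot express efficiently. Every layer's backward
pass is validated against central finite differences in the test suite, and
dropout is active only during fitting — two evaluation passes are
bit-identical.

## BLUP benchmark

The baseline is best linear unbiased prediction under
$y = \mathbf{1}\mu + Zu + \varepsilon$, $u \sim N(0, \sigma_u^2 I_p)$,
$\varepsilon \sim N(0, \sigma_e^2 I_n)$, with the intercept as the only
fixed effect (the simulated trait has no covariates). Variance components
are REML estimates obtained by profiling the restricted likelihood over
$\delta = \sigma_e^2/\sigma_u^2$ in the eigenbasis of the centered kernel
$ZZ^\top$ — exact and fast at $n \approx 10^3$ — with a Haseman–Elston
moment fallback if the 1-D optimization fails. Predictions are
$\bar y + Z_{te} Z_{tr}^\top (Z_{tr} Z_{tr}^\top + \lambda I)^{-1}(y - \bar y)$
with $\lambda = \sigma_e^2/\sigma_u^2$, identical to ridge regression by the
Woodbury identity (asserted to 1e-8 in the tests). Because the simulated
trait is linear in the genotypes, BLUP is expected to be the strongest
predictor on this design, and the suite checks it beats the constant-mean
predictor in at least 90% of replicates.

## Numerical and reproducibility choices

* All generators, builds and fits are bit-reproducible given their seeds;
  the phenotype uses a stream offset from the genotype seed so effects are
  independent of the panel draw.
* `split_data()` guards the `floor(f * n)` computation against
  floating-point undershoot (0.8 × 1092 must be 873, not 872).
* LD matrices are symmetrized exactly after the Gram product; eigenvalues
  are checked nonnegative to 1e-8 of the largest.
* A non-finite training loss aborts with the epoch and learning rate in the
  message rather than propagating NaNs.
* Pipeline reports embed the master seed and a hash of the full
  configuration; reruns with the same config are byte-identical.

## Problem sizes used by the checks

The replication harness runs the full design (n = 1092, p = 8299, 500
repetitions) only with a real reference panel, which is access-restricted;
the packaged checks run the same code paths at sizes chosen to finish in
minutes on one core while keeping every regime intact: the recurrent
near-constant-output check uses n = 600, p = 1000 over 4 repeated splits;
the summary-mode stable-cell check uses n = 300, p = 200; variance-component
recovery uses n = 500, p = 200 over 50 replicates; the BLUP benchmark in
`scripts/acceptance.R` runs at the full n = 1092, p = 8299 on the synthetic
panel. The structural constants (43 blocks of 193 at p = 8299, 15 windows of
1000 at stride 500, the 873/219 split) are size-exact and checked as such.

## Limitations

Summary mode estimates test error only up to the resampling approximation —
it cannot attribute predictions to individuals. The diagonal-block inputs
discard between-block LD by construction. No hyperparameter search is
included: presets are fixed configurations, not tuned-per-dataset choices.
The simulator's trait is linear, so comparisons here cannot show the
nonlinear advantages deep models are motivated by; and CNN training at the
printed learning rate (0.1) is intentionally faithful even though it often
drives the convolutional stacks toward degenerate flat solutions — that
behavior is part of what the replication reproduces, not a defect to fix.
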