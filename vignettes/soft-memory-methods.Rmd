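---
title: "Methods: soft memory in recurrent gene regulatory networks"
author: "softmem authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: soft memory in recurrent gene regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(softmem)
```

## The scientific question

Bacteria process time-dependent information: *E. coli* can associate a
temperature rise with a later drop in oxygen, and stress responses depend on
environmental history. One mechanistic proposal is that the transcriptional
regulatory network itself acts as a *reservoir computer*: its recurrent core
— the genes that regulate each other in cycles — holds a fading trace of
past inputs in its transient dynamical state ("soft" memory, as opposed to
memory hard-wired into connection changes), and downstream feedforward genes
read this trace out. This package quantifies how much soft memory such a
network holds, and how that capacity depends on three structural knobs:

1. the **global dynamical regime**, set by the spectral radius of the
   recurrent weight matrix (order vs chaos);
2. the **activation/repression balance** of the regulatory interactions;
3. the **local motif content** — self-loops, mutual-regulation pairs and
   feedforward loops (FFLs), the smallest feedback and feedforward circuits.

The *E. coli* reference statistics used throughout are: whole network 3236
genes and 8366 interactions (mean degree 5.17, 24% repression), recurrent
core 70 genes and 317 interactions (mean degree 9.05, 41% repression). The
underlying curated network itself is not redistributed; all computations run
on random surrogates matched to these statistics (see "What the surrogate
captures" below).

## The model

### Reservoir dynamics

A signed digraph is turned into a discrete-time echo-state network,

$$x_t = \tanh(W^{in} u_t + W x_{t-1}),$$

where `W[i, j]` is nonzero exactly when the graph has an edge `j -> i`, with
magnitude drawn i.i.d. from U(0, 1) and sign given by the interaction
(activation +, repression −). `W` is rescaled to a prescribed spectral
radius ρ — the largest eigenvalue modulus, computed by dense eigendecomposition
(networks here have at most ~100 nodes) and matched to within 1e-9. Entries
of `W^{in}` are ±0.05 equiprobably; by default every reservoir gene receives
input (an `input_nodes` mask restricts this, e.g. for delay-line fixtures).
The initial state is the origin, and matrix orientation (edge `j -> i` means
entry `(i, j)`) is a package convention.

### Readout

Outputs are linear in the instantaneous state, `Y = W_out X`, trained by
ridge regression

$$W^{out} = Y^{target} X^{\top} (X X^{\top} + \gamma^2 I)^{-1}.$$

The solver uses a Cholesky factorisation of the regularised Gram matrix and
falls back to QR on the augmented least-squares system when states are
numerically collinear (a saturated reservoir can produce a semidefinite Gram
matrix even though the ridge problem is well posed). The default
regularisation is `gamma = 1e-6`, exposed everywhere and recorded in every
output table. Training concatenates the training series after discarding the
first 100 steps of each (washout); the washout length is a convention for
transient removal, not a fitted quantity.

### Benchmarks

* **Memory capacity.** A single input `u_t ~ U(-1, 1)` drives the reservoir;
  a readout is trained to reproduce `u_{t-k}`. The per-delay score is
  $MC_k = \mathrm{cov}^2(u_{t-k}, y_t) / (\sigma^2(u_{t-k}) \sigma^2(y_t))$,
  the squared Pearson correlation (the standard short-term memory statistic,
  bounded in [0, 1]). The **critical memory capacity** k* is the largest
  delay with $MC_k > 0.5$ — the literal "largest", even across non-monotone
  profiles; a first-crossing rule is available as an option. The protocol is
  10 series of 1000 steps, 9 for training and 1 held out, and all delays
  k = 1..30 reuse the same state matrices (only the target shifts).
* **NARMA-10.** The 10th-order nonlinear autoregressive moving-average
  system $y(t+1) = 0.3 y(t) + 0.05 y(t) \sum_{i=0}^{9} y(t-i) +
  1.5 s(t-9) s(t) + 0.1$ with `s(t) ~ U(0, 0.5)` and zero initial history.
  Performance is the normalised root-mean-squared error
  $\mathrm{NRMSE} = \sqrt{\langle (y - y^{target})^2 \rangle_t /
  \langle (y^{target} - \langle y^{target} \rangle_t)^2 \rangle_t}$ on the
  held-out series, with the population (divide-by-T) variance so that the
  constant mean predictor scores exactly 1. The recursion diverges for rare
  input draws; such series are resampled with the next derived sub-seed and
  the event is logged.
* **Delayed AND.** Two pulse-train inputs (pulses of unit height, 3 steps
  long, 600-step series); the target fires when input 1 pulsed k = 6 steps
  before input 2. The readout output is binarised at 0.5 and the binarised
  series is scored with the same NRMSE. Pulse statistics are not fully
  constrained by the task definition; the package uses a per-step onset rate
  of 0.02 thinned by a refractory gap of `pulse_duration + 6` steps, and
  plants an input-2 pulse at lag k after 50% of input-1 pulses so that both
  AND classes occur several times per series. All three knobs are arguments.

### Measuring chaos

The maximum Lyapunov exponent is estimated by two-trajectory
renormalisation: a companion trajectory is displaced from the reference by
`gamma0 = 1e-8` in a random direction, both receive identical input, and
after every step the log separation ratio is accumulated and the companion
is renormalised back to distance `gamma0` along the current difference
vector. The exponent is the mean log expansion per step over steps 101-1000.
Separations underflowing 1e-300 are floored with a warning (extreme
contraction). By default the estimate is taken under the same U(-1, 1)
drive as the memory task, so that the exponent and k* refer to the same
operating condition; a zero-input option gives the autonomous exponent,
which satisfies the linearisation identity λ = ln ρ for ρ ≤ 1 (states decay
to the origin, where the Jacobian is W) and is used as the correctness
oracle in the tests.

### Motif census and null model

Self-loops are counted as edges (v, v); mutual regulation as unordered
pairs with both directed edges present; FFLs as ordered triples (driver,
intermediate, target) of distinct nodes with all three edges present — under
this convention a fully bidirectionally connected triangle contains 6 FFLs.
Counts are sign-blind. The null model is the uniform directed graph with the
same node and edge counts (no multi-edges, self-loops allowed), and z-scores
follow $(N_{real} - \langle N \rangle_{rand}) / \sigma_{rand}$ with the
sample (n−1) standard deviation over 1000 draws. Normalised counts divide
the real count by the null mean, substituting the closed-form uniform-model
expectation if a small ensemble happens to have mean zero. At the published
network sizes this null reproduces the published randomized-network columns
for self-loops and mutual regulation (3 ± 2 and 3 ± 2 at 3236/8366; 5 ± 2
and 10 ± 3 at 70/317). The published reservoir FFL null (73 ± 10) sits
*below* the uniform-model expectation (~93 at 70/317); the extra constraint
behind that number is not specified in the source material, so the uniform
null is used and the discrepancy is documented rather than resolved.

### Sub-reservoir sampling

Sub-networks are harvested by iterated random node removal: delete one
uniformly chosen node, prune to the recurrent core, keep the giant weakly
connected component, and record every intermediate graph down to 3 nodes;
100 independent runs from the 70-node surrogate yield a library of a few
thousand sub-reservoirs spanning 3-69 nodes, duplicates retained. "Giant
connected component" is interpreted weakly (signals still propagate along
directed edges within it); a strong mode is available. The performance
filter used in size-performance analyses keeps values within 1.25 sample
standard deviations of the mean. "Good size-performance trade-off" is
operationalised as Pareto efficiency on (size, k*, NARMA NRMSE, delayed-AND
NRMSE), since no sharper selection rule is available.

## The surrogate generator: what it captures and what it does not

`ecoli_core_surrogate()` draws uniform random signed digraphs with exactly
70 nodes, 317 edges and 130 repressing edges (41%), resampled until fully
recurrent and weakly connected — the defining statistics of the real
recurrent core. Sign counts are exact rather than Bernoulli, so
composition sweeps carry no sampling noise in the repression fraction. What
the surrogate does **not** capture is the real network's degree
heterogeneity (global regulators with large out-degree), its motif
enrichment, and any correlation between sign and position. Consequences
observed with this package's own sweeps:

* the surrogate holds *more* memory than the published network (mean k* up
  to ~24 at ρ ≈ 0.95, vs ~14 reported for the real core) and solves NARMA-10
  better (NRMSE ~0.35 vs ~0.7) — uniform graphs are simply good reservoirs;
* the qualitative laws reproduce: k* rises with ρ, peaks just below/at the
  order-chaos transition and collapses in the chaotic regime; both task
  scores vary non-monotonically with the repression fraction;
* one quantitative optimum shifts: the NARMA-optimal repression fraction
  sits near 20-30% on uniform surrogates (vs 40-60% reported on the real
  topology), while the k*-optimal fraction spans a flat 30-70% plateau.
  Degree heterogeneity appears to be what makes the balance matter
  strongly, and the uniform surrogate lacks it by construction.

A separate estimator subtlety concerns *where* the order-to-chaos
transition is located. Under the weak (±0.05-scaled) input drive, the
common input synchronises the two trajectories and pins the measured λ
just below zero across a broad plateau (ρ ≈ 1.0-1.6), so the first sign
change of the driven exponent is ill-defined and lands far above the
transition. The autonomous exponent has no such degeneracy: with zero
input the reference trajectory sits at the origin fixed point, the
companion probes the Jacobian W directly, λ = ln ρ identically, and the
sign change falls at exactly ρ = 1 — consistent with the role of the
spectral radius as the stability parameter of the undriven network. The
package therefore locates the transition with the autonomous exponent
(`mle_input = "zero"` in `sweep_spectral_radius`), while `max_lyapunov`
keeps the driven estimate as its default for studying the driven dynamics
themselves. Passing tests demonstrate the mechanism — memory maximal near
the transition — not numerical agreement with the published curves, which
would require the undeposited curated network.

## Numerical and design choices

* **Determinism.** Every stochastic function takes a seed and is
  bit-reproducible given it; sweeps derive per-realization sub-seeds from a
  master seed (kept below 2^31). Grid sweeps use common random numbers —
  realization i shares its weights, drive and series at every grid point —
  so grid contrasts are paired and optimum locations are not blurred by
  between-point sampling noise.
* **Degenerate inputs.** Acyclic graphs cannot be normalised to a spectral
  radius (the raw radius is 0) and raise an error; a readout whose held-out
  output has zero variance scores MC = 0 with a warning; a constant NRMSE
  target is an error (zero denominator); a zero null s.d. yields an
  infinite z-score with a `degenerate` flag.
* **Duplicate edges** in input files collapse to the last row seen, with a
  warning — edge lists exported from curated databases occasionally repeat
  pairs with updated signs.
* **Problem sizes.** The test suite runs the full published protocol where
  it is cheap (10×1000-step series, 1000-draw null ensembles, 0.1-step ρ
  grids with 10 realizations, 11-point repression sweeps with 20
  realizations) and miniature versions (3×300-step series, 2 realizations)
  where only the plumbing is under test; each test states its own scale.

## Known limitations

* Only the discrete tanh update is implemented — no leaky or
  continuous-time variant, and only ridge readouts (no evolutionary or
  online training).
* The null model fixes n and m only; no degree-preserving rewiring.
* Motif subtypes (coherent vs incoherent FFLs) are not distinguished; the
  census is sign-blind by design.
* Conclusions transfer to the real *E. coli* network only at the level of
  mechanisms and trends, per the surrogate caveats above.
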