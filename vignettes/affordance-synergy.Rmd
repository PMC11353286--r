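---
title: "Capacity-limited encoding of multimodal affordances: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Capacity-limited encoding of multimodal affordances: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affsyn)
```

## The model

An affordance landscape is an `m x n` real matrix `A` whose axes are two
ambient energy arrays with observation states `O_B = (o_1..o_m)` and
`O_C = (o_1..o_n)` (integers `1..m`, `1..n` by default). Cells are jointly
uniform: every `(b, c)` has probability `1/(mn)`, and every derived random
variable (signals, estimates, the affordance value itself) gets its
distribution from the frequency of its values under that uniform measure.

Each axis is observed through a deterministic encoder `E: o -> z` with a
signal alphabet of size `L` (signals are labelled `0..L-1`; the regime of
interest is `L` smaller than the number of observation states, i.e. a
transmission rate `log2 L` below the axis entropy). For a fixed encoder
pair the decoder is the conditional expectation: a signal pair `(i, j)`
decodes to the mean of `A` over the Cartesian product of the two signal
preimages. This decoder is MSE-optimal for fixed encoders, which the test
suite checks by finite perturbation of every decoder cell. Alongside the
full affordance estimate the package tracks two auxiliary reconstructions
per axis: the *sensory estimate* (mean observation value over a signal's
preimage) and the *unidimensional affordance estimate* (mean of the
row/column affordance expectation over the preimage).

The processing chain `A -> O -> Z -> Ahat` is Markov, so
`I(A; Ahat) <= I(Z_B, Z_C; A) <= I(O_B, O_C; A)` — a data-processing
property asserted on random landscapes in the tests.

## Encoding strategies

The **direct** strategy formalizes the claim that affordance information is
picked up per modality: each encoder minimizes the MSE between its axis's
affordance-expectation vector and the per-signal reconstruction. (This
stands in for maximizing `I(A_B; Ahat_B)`: with the axis entropy fixed, a
Gaussian surrogate for the conditional turns information maximization into
MSE minimization.) The **indirect** strategy minimizes the full-matrix
reconstruction MSE for the encoder *pair* jointly, leaving it to the
decoder to recombine the two signal streams.

Both objectives are optimized by stochastic hill climbing with random
restarts: assignments start uniform over signals; per step each encoder
proposes moving one uniformly chosen observation to a uniformly chosen
signal; proposals are accepted only if the objective *strictly* decreases
(equal-value moves are rejected), so every run trace is non-increasing.
Two choices here were genuinely open and are fixed as follows:

* the per-signal decoded value in the direct objective is the mean of the
  *unidimensional affordance expectations* over the preimage, not of the
  raw observation indices — only this reading is consistent with the worked
  4x4 example, where the direct optimum reconstructs the row expectations
  exactly;
* in the indirect strategy the two encoders' proposals within a step are
  accepted or rejected *as a unit* after evaluating the joint objective,
  rather than per encoder. The joint rule is the cleaner reading of a
  jointly defined objective; it makes single steps slightly more
  conservative, which the step budget compensates.

An exhaustive-search oracle certifies hill-climbing results wherever the
assignment space does not exceed `1e6` (the toy problem has 16 per-axis
assignments and 256 indirect pairs). Hill climbing carries no optimality
guarantee in general; on the toy problem it attains the enumerated optimum
in at least 95 of 100 seeded repetitions (asserted in the tests), and the
optimizer is a pure function of its seed (no clock seeding, seeds are
required arguments).

## Information measures

All logarithms are base 2 and all information is in bits; `0 log 0 := 0`.
Probability tables are sparse (absent tuples carry zero mass), validated to
`1e-9` on normalization, and never renormalized silently.

**Synergy.** For sources `Z_B`, `Z_C` and target `A` (the raw affordance
value), union information is the minimum of `I*(Z_B, Z_C; A)` over joint
distributions preserving both pairwise `(Z_i, A)` marginals; synergy is the
joint mutual information minus that minimum. The solver parameterizes the
feasible polytope by the null space of the marginal constraints (so
equality feasibility is exact by construction, not penalized), restricts to
the support forced positive by the constraints, starts from the
conditional-independence distribution `p(a) p(z_B|a) p(z_C|a)` — always
feasible and strictly positive on that support — and minimizes the convex
objective with a log-barrier interior-point method (`stats::constrOptim`,
BFGS with analytic gradients) under barrier continuation
`mu = 1e-4, 1e-6, 1e-8`. Degenerate polytopes (zero free dimensions) are
returned directly. Diagnostics carry the iteration count and the final
constraint residual; the residual is at machine precision because
feasibility is structural. Two sources are the primary case; more are
accepted by the solver (the test suite uses a third, duplicated source to
check that redundant sources cannot increase synergy) but the brute-force
oracle below is the certification path only for small problems.

The companion **grid oracle** zooms a full-factorial grid over the free
polytope coordinates (8 rounds, shrinking the box around the incumbent),
refusing supports above 64 cells or more than 10 free dimensions. Solver
and oracle agree within `1e-2` bits on every shipped fixture. Bracketing
bounds are also computed: WholeMinusSum (below) and Smax via specific
informations (above).

**Spatial entropy.** `H_Cl = -sum_i d_i p_i log2 p_i` with `d_i` the mean
Euclidean distance from support point `i` to all others. The coordinate
space is not uniquely determined by the construct; here the support points
are the *unique decoded estimate values*, placed at their numeric value on
the (1-D) observation axis, and a single-point support has `d := 0` and
hence entropy 0. This makes the fully collapsed direct code score 0 and the
two-point indirect toy code score 2.0. The measure is
translation-invariant and scales linearly with the coordinates, which the
tests assert.

## Synthetic data

The generators define the study conditions; all stochastic ones are pure
functions of `(parameters, seed)`.

* `toy_landscape()` — the fixed 4x4 symmetric fixture whose row and column
  expectations take only the values 0.5 and 0.75, so 1-bit encoders face a
  genuine strategy choice; `toy_swapped()` exchanges `a[4,2]` and `a[2,3]`,
  which aligns the direct-optimal *row* partition with the indirect one.
* `xor_landscape()` / `xor_table()` — the canonical fully synergistic
  system.
* `random_synergistic_landscape()` — block labels on each axis combined
  through a modular (XOR-style) interaction, with a `noise` fraction of
  cells resampled; ground-truth block encoders are recorded.
* `separable_landscape()` — `a[b,c] = f(b) + g(c)` with continuous i.i.d.
  `f, g`: the affordance value determines each axis's contribution almost
  surely, so these landscapes carry no synergy and serve as the negative
  control (optimal direct and indirect MSEs coincide, which the tests
  verify by exhaustive search).
* `blob_image_landscape()` — emulates small grayscale photographs of
  standing figures: 1-3 vertically elongated Gaussian blobs (horizontal sd
  3-8% of width, vertical sd 25-45% of height, amplitude 0.7-1) over
  Gaussian background noise of sd 0.1, then value-quantized to 5 unique
  levels by 1-D k-means (Lloyd, seeded, multi-start; quantized values are
  the cluster *centroids*, not indices, because the conditional-expectation
  decoder averages them). Vertical elongation concentrates column variance
  in few columns while spreading row variance — the axis asymmetry that
  separates the strategies — and the tests assert the top-8-column variance
  share exceeds the top-8-row share in at least 90 of 100 seeds. What these
  landscapes do *not* emulate: natural image statistics beyond that
  asymmetry (textures, multi-object scenes, class semantics), so passing
  results show the strategy gap under controlled synergistic structure,
  not performance on photographs. An optional PNG loader (Rec. 601 luma
  conversion) lets users supply real images.

## The batch experiment

`run_batch()` compares the strategies across seeded landscapes: per
landscape both strategies are optimized, scored with the full metric set,
and paired; the directional hypotheses (indirect attains lower affordance
MSE, indirect attains higher synergy) are tested with one-sided paired
Wilcoxon signed-rank tests. The signed-rank test is this package's choice
of paired comparison; it assumes exchangeable paired differences under the
null and nothing about their distribution. Defaults: thirty 32x32 blob
landscapes at 5 levels, 8 signals per encoder (3 bits out of the 5 bits an
axis of 32 states would need), hill climbing with 10 restarts of 3000
steps per strategy. These sizes keep a full batch to a few minutes on one
CPU while leaving the optimizer comfortably converged at toy scale and
well-converged at 32x32 (the indirect search space is `8^64`, so its
optima are approximate by construction). Per-landscape seeds derive
deterministically from the base seed (`base_seed + 1000 i`), every record
carries its seed, and identical configurations produce identical reports.
A PID solver failure on a landscape flags the record, excludes it from the
pairing and is logged, rather than aborting the batch.

## Numerical choices and degenerate inputs

* Observation axes are 1-based (`1..m`) so preimage means are interpretable
  observation values; signals are 0-based (`0..L-1`).
* Decoder cells whose preimage product is empty are marked unused rather
  than defined; they can exist transiently during optimization (hill
  climbing may vacate a signal) but looking one up is an error, and by
  construction no landscape cell ever maps to one.
* Mutual informations within `1e-12` of zero are floored at zero; synergy
  is clipped into `[0, joint MI]` only when the violation is within the
  solver tolerance, otherwise the solver errors out.
* Quantization with `k` at least the number of unique values returns the
  input unchanged with a warning flag (each value is its own cluster).
* Ties in the hill climb are rejected (strict decrease only), making
  traces non-increasing and runs reproducible.

## Known limitations

Encoders and decoders are deterministic; observation priors are uniform;
exactly two modalities are modelled. The union-information solver is an
interior-point approximation — accurate to well under `1e-2` bits on all
certified fixtures, but without a formal optimality certificate on large
supports. Hill climbing is a local method; away from enumerable scales its
results are best-found, not provably optimal. The rate--distortion function
itself is never computed: the capacity constraint enters only through the
signal-alphabet size `L`.
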