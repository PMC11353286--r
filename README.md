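# affsyn

Information-theoretic modelling of multimodal affordance perception under
capacity limits.

## The problem

An affordance (a possibility for action — climbability, graspability) is
often co-specified by several ambient energy arrays at once: what light says
about the scene and what sound says about it only determine the affordance
*jointly*. `affsyn` models this situation as lossy communication. An
affordance landscape is an `m x n` real matrix `A`; its two axes are energy
arrays observed by two separate sensory channels. Each channel is a
deterministic encoder limited to `L` signals (a rate of `R = log2 L` bits,
with `R < H(O)` so states must share signals), and a downstream decoder maps
each signal pair to the conditional mean of `A` over the encoders' preimages
— the MSE-optimal decoder for fixed encoders:

    D(z_i, z_j) = mean{ a_bc : E_B(b) = z_i, E_C(c) = z_j }

Two encoding strategies compete:

* **direct** — each encoder maximizes affordance information on its own,
  i.e. minimizes the MSE of the per-axis affordance expectation
  `A_B[b] = mean_c a_bc` against its per-signal reconstruction;
* **indirect** — the encoder pair jointly minimizes the full reconstruction
  error `MSE(A, Ahat)`, which in practice makes the signals track the
  sensory states themselves.

The strategies are scored with discrete information measures: entropy and
mutual information; the BROJA partial-information-decomposition synergy

    I_syn({Z_B, Z_C}; A) = I(Z_B, Z_C; A) - I_union,
    I_union = min { I*(Z_B, Z_C; A) : Pr*(Z_i, A) = Pr(Z_i, A) for both i }

computed by convex minimization over the marginal-preserving polytope
(with WholeMinusSum and Smax as bracketing bounds and a brute-force grid
oracle for certification); and the distance-weighted spatial entropy
`H_Cl = -sum_i d_i p_i log2 p_i` of the decoded sensory estimates. When the
landscape is synergistic — the affordance lives in the interaction of the
axes — the direct strategy destroys exactly the sensory information the
decoder would need, and indirect encoding wins.

## Worked example

The package ships a 4x4 synergistic fixture whose every intermediate value
can be checked by hand. `run_toy()` evaluates the canonical direct encoders
(observation states `{1,4} -> 0`, `{2,3} -> 1` on both axes) and indirect
encoders (`{1,2} -> 0`, `{3,4} -> 1`), then re-derives both by hill
climbing and certifies the indirect optimum by enumerating all 256 encoder
pairs:

```r
library(affsyn)
print(run_toy())
#> Strategy	MSE(A,Ahat)	synergy	I(OB;OBhat)	I(OC;OChat)	I(AB;ABhat)	I(AC;AChat)
#> Direct	0.44	0.25	0	0	1	1
#> Indirect	0.09	1.00	1	1	0	0
#> status: ok (indirect exhaustive optimum 0.09375)
```

Reading the rows: the direct pair reconstructs the affordance poorly
(MSE 0.44) while capturing each axis's expected affordance perfectly
(`I(AB;ABhat) = 1`) and no sensory information at all (`I(OB;OBhat) = 0`);
the indirect pair transmits the full bit of sensory information per axis,
captures all 1 bit of synergy, and more than halves the distortion
(MSE 0.09).

The same comparison at scale, on thirty synthetic 32x32 quantized
blob-image landscapes with 3-bit encoders:

```r
rep <- run_batch(experiment_config(kind = "blobs", n_landscapes = 30,
                                   base_seed = 1))
print(rep)
#> batch experiment: 30 paired landscapes (0 excluded)
#>   affordance MSE: direct 0.0108 vs indirect 0.0095 (p = 9.13e-07)
#>   synergy: direct 0.2087 vs indirect 0.2653 (p = 1.51e-06)
```

A thin command-line front end over the same functions lives in
`inst/scripts/affsyn-cli.R` (subcommands `toy`, `pid`, `synth`, `optimize`,
`experiment`).

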