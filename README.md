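# decbct — dual-energy cone-beam CT electron-density imaging

Adaptive radiotherapy needs accurate electron densities (ρe) at the
treatment position, but the cone-beam CT (CBCT) images acquired on the
linac suffer from beam hardening, and the usual HU→ρe calibration curve is
ambiguous because the CT number depends on the effective atomic number as
well as on ρe. `decbct` implements and simulates a projection-domain
dual-energy method that measures ρe directly, end to end:

1. polychromatic forward projection of analytic cylinder phantoms at a
   high (120 kVp) and a low (70 kVp) tube potential,
2. basis-material decomposition of the paired log-projections,
3. filtered-backprojection reconstruction of the basis-coefficient images,
4. voxel-wise electron-density synthesis and quantitative evaluation
   (ROI statistics, cupping metrics).

## The model

In the diagnostic range the linear attenuation coefficient of any tissue
is well approximated by a two-material basis expansion

    μ(E) ≈ b₁ μ₁(E) + b₂ μ₂(E)

with graphite (tissue-like) and aluminium (bone-like) as basis materials.
A ray through the object measures, for each spectrum S(E),

    g = −ln ∫ S(E) exp(−B₁ μ₁(E) − B₂ μ₂(E)) dE,   Bᵢ = ∫ bᵢ dl.

A path through d₁ mm of graphite and d₂ mm of aluminium produces the same
pair (g_H, g_L); a look-up table of this two-slab forward model, inverted
per pixel (damped Newton on the smooth model, analytic Jacobian), converts
measured (g_H, g_L) into (B₁, B₂). Because the table is built with the full
polychromatic physics, the beam-hardening effect is absorbed by the
inversion. Reconstructing B₁ and B₂ gives b₁ and b₂, and

    ρe = b₁ ρe₁ + b₂ ρe₂.

Electron densities are reported in units of N_A/2 electrons per cm³
(ρe = 2 ρ Σ wᵢ Zᵢ/Aᵢ), in which water at 1.000 g/cm³ is 1.1102 and
graphite at 1.700 g/cm³ is 1.6984.

## Worked example

The default configuration is the desk-scale virtual-phantom study: a
256 mm water cylinder with four 40 mm inserts (silicon, PMMA,
polyethylene, graphite), noiseless 360-view fan-beam acquisition on a
512-pixel 1 mm detector row (SAD 1000 mm, SDD 1536 mm), and 256²
reconstruction at 1 mm voxels:

```r
library(decbct)
res <- run_pipeline(pipeline_config())
print(res)
```

```
Electron-density evaluation (N_A/2 units)
 material calculated theoretical error_pct
  silicon     2.3180      2.3229      0.21
     pmma     1.2820      1.2837      0.14
       pe     1.0574      1.0608      0.32
 graphite     1.6983      1.6984      0.01
    water     1.1101      1.1102      0.01
Pearson correlation (calculated vs theoretical): 1.0000
Cupping metric BH: 4.99 (low kVp) / 4.75 (high kVp) / -0.03 (dual)
```

Every reconstructed electron density agrees with theory to well under 1 %,
and the cupping metric BH = (peripheral − central ROI mean)/central × 100
collapses from ~5 % on the single-energy attenuation images to ~0 on the
dual-energy ρe image — the hardening has been removed in the projection
domain, not by post-hoc correction.

A thin CLI over the same functions is installed at
`inst/scripts/decbct` (`decbct run-all --preset desk --out results/`).

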