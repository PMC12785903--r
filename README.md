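# starchkinetics

Quantitative analysis of in vitro starch digestion kinetics and of the
supramolecular structure of starch–lipid–protein complexes, for food
scientists and carbohydrate chemists studying slowly digestible starch.

Thermally processed starch can self-assemble with lipids and proteins into
binary and ternary complexes whose compact, ordered structure shields
glycosidic bonds from amylolytic enzymes. The package implements the
standard quantitative toolchain used to characterize that slowdown:

* **Digestible fractions (Englyst arithmetic).** With glucose released by
  20 and 120 min (`G20`, `G120`, mg), free glucose `GF` and total starch
  `TS`:
  `RDS = (G20 − GF)·0.9/TS·100`, `SDS = (G120 − G20)·0.9/TS·100`,
  `RS = 100 − RDS − SDS` (0.9 = 162/180, glucose → anhydroglucose).
* **Log-of-slope (LOS) multi-phase kinetics.** Hydrolysis follows
  piecewise first-order dynamics `C(t) = C_i + C_i∞(1 − e^{−k_i t})`; the
  transform `y = ln(ΔC/Δt)` vs midpoint time linearizes each phase with
  slope `−k_i` and intercept `ln(C_i∞ k_i)`. Phases are found by
  exhaustive breakpoint search with BIC model selection; the area under
  the curve `AUC = C∞(t_f − t_0) − (C∞/k)(1 − e^{−k(t_f − t_0)})`,
  hydrolysis index `HI = 100·AUC_sample/AUC_reference` and estimated
  glycemic index `EGI = 39.71 + 0.549·HI` follow.
* **SAXS lamellar analysis.** The 1-D correlation function
  `L(r) = ∫I(q)q²cos(qr)dq / ∫I(q)q²dq` with standard low-q and Porod
  extrapolations; long period `d` from the first correlation maximum,
  split into amorphous/crystalline thicknesses (`d = d_a + d_c`); low-q
  power-law fit `I ∝ q^α` with mass fractal dimension `D_m = −α` for
  `α ∈ (−3, −1)`.
* **Structure metrics.** FTIR 1047/1022 cm⁻¹ short-range order ratio, XRD
  relative crystallinity (rolling-ball amorphous halo), AFM RMS roughness
  `Rq`, GLCM texture features (energy, contrast, homogeneity, entropy) and
  the differential box-counting fractal dimension.
* **Seeded synthetic generators** for digestion curves, lamellar
  scattering (with a brute-force real-space autocorrelation oracle),
  spectra and height maps, so every analysis stage is verifiable without
  laboratory data.

The methods vignette
(`vignettes/starch-digestion-and-structure.Rmd`) documents the models,
numerical choices and known estimator biases in detail.

## Worked example

Simulate a noise-free two-phase digestion curve with the kinetic
parameters of a high-SI amylopectin ternary complex
(k₁ = 2.43×10⁻², C₁∞ = 60.21 %, breakpoint 200 min;
k₂ = 1.44×10⁻², C₂∞ = 61.06 %), then recover them with the LOS pipeline:

```r
library(starchkinetics)

ternary <- list(
  phase_spec(k = 2.43e-2, C_inf = 60.21, t_end = 200),
  phase_spec(k = 1.44e-2, C_inf = 61.06, t_end = 540)
)
crv <- gen_digestion_curve(ternary, times_uniform(5))
analyze_digestion(crv, reference = default_reference_curve())
#> LOS analysis: 2 phase(s), breakpoints at 200 min
#> Phase 0-200 min: k = 0.0243 1/min, C_inf = 60.25 % (r2 = 1.0000, n = 40)
#> Phase 200-540 min: k = 0.0144 1/min, C_inf = 61.07 % (r2 = 1.0000, n = 68)
#> First-order fit: C_inf = 62.30 %, k = 0.02196 1/min, r2 = 0.9948
#> AUC[0, 540] = 28740.1 %.min (final-phase)
#> HI = 53.88, EGI = 69.29
```

The segmentation finds exactly two phases with the breakpoint on the
generating 200-min boundary; the recovered rate constants equal the
generating ones (uniform sampling makes the discrete LOS slope exact) and
the per-phase `C_inf` values carry only the tiny, closed-form
discretization bias (+0.06 % here). The single-phase "classical" `k`
falls between k₂ and k₁, as it should for genuinely two-stage kinetics.
HI/EGI here are computed against the package's synthetic reference curve
(a documented stand-in, not measured white bread), so they are internally
consistent rather than comparable to published tables.

Fraction arithmetic and the EGI line:

```r
crv2 <- digestion_curve(c(0, 20, 120, 540), c(0, 24.48, 67.76, 70))
rds_sds_rs(curve_to_glucose(crv2, TS = 200))
#> RDS 24.48 %  SDS 43.28 %  RS 32.24 %
egi(71.83)
#> [1] 79.14467
```

Lamellar analysis of a synthetic semicrystalline stack (5.33 nm
crystalline + 5.55 nm amorphous layers, 10 % thickness jitter):

```r
sp <- stack_spec(5.33, 5.55, sigma_c = 0.533, sigma_a = 0.555,
                 n_repeats = 32)
sim <- gen_lamellar_scattering(sp, seq(0.01, 0.5, by = 0.001),
                               n_realizations = 16, seed = 11)
cf <- correlation_function(sim$curve, r_max = 33, n_r = 331)
lamellar_params(cf, assign_thinner_to = "d_a")
#> Lamellae: d = 10.90 nm (d_a = 5.06, d_c = 5.84 nm)
```

The long period lands within 0.2 % of the generating 10.88 nm, and
`sim$cf` carries the brute-force real-space oracle the pipeline is
validated against (maximum deviation ≤ 0.05 in the tests).

Surface texture of a generated height map with prescribed roughness:

```r
hm <- gen_height_map(height_map_spec(n_pixels = 128, target_rq = 8.01,
                                     corr_length = 60, seed = 1))
texture_metrics(hm)
#> Rq 8.01 nm | energy 0.0408 contrast 0.5392 homogeneity 0.7663 entropy 3.4984 | D 2.208
```

`Rq` equals the prescribed 8.01 nm exactly (the generator rescales to the
target), and the GLCM/fractal descriptors respond monotonically to
surface disorder.

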