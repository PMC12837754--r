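# valvesens

Which features of mitral valve geometry control the residual systolic
orifice area? In mitral regurgitation the leak through the incompletely
closed valve is quantified by the effective regurgitant orifice area, and
that area depends on a tangle of anatomical factors: annular dimensions,
leaflet lengths and proportions, saddle height, commissural shape.
`valvesens` implements a complete simulation-and-analysis chain for
ranking those factors:

- a **twelve-parameter valve parameterization** (anteroposterior diameter
  `AP_D`, intercommissural ratio `IC_D_R`, leaflet length ratios `AL_R`,
  `PL_R`, commissure ratio `CL_R`, bluntness, saddle heights `AH`/`PH`,
  D-shape, septal flatness, commissure location/curvature) with
  physiological uniform ranges and the unnormalization
  `AP = AP_D`, `IC = IC_D_R·AP`, `AL = AP/AL_R`, `PL = PL_R·(AP−AL)`,
  `CL = CL_R·(PL−PH)`, `SF_shape = SF_Shape_R·IC`;
- a deterministic **kinematic closure emulator** (a cheap, analytically
  checkable stand-in for finite-element closure simulation) producing
  mid-systole free-edge curves and a residual gap profile
  `g(s) = max(0, d(s) − λ(q)·(a(s)+p(s)))`;
- the **gap-length orifice-area algorithm**: 40 equally spaced
  cross-sectional planes perpendicular to the local coaptation line,
  minimum in-plane distance between the edge intersections (zero on
  contact/overlap), area = Σ gᵢ·Δx;
- **Gaussian Process regression** with the automatic relevance
  determination kernel
  `k(xᵢ,xⱼ) = exp(−½ Σ_d (x_{i,d}−x_{j,d})²/l_d²)`, fixed noise `σ²`,
  length scales by log-marginal-likelihood maximization with the initial
  guess chosen by 5-fold cross-validation, and an ordinary-least-squares
  baseline scored by R² and MAPE over five random 350/90 train/test
  splits;
- **first-order Sobol indices** `S_i = V_i/Var(y)`,
  `V_i = Var(E[Y|X_i])`, by the dimension-fixing Monte Carlo scheme
  (outer draws fix one physical coordinate, inner draws vary the rest);
- **total-variation distances** `TV(p,q) = ½∫|p−q|dx` between
  orifice-area densities of the emulator, the 12-parameter surrogate, and
  the surrogate with only the influential parameters varying.

Everything is tibble-in/tibble-out and composes with the pipe; fitted
objects support `tidy()`/`glance()` and result objects have `autoplot()`
methods.

## Worked example

```r
library(valvesens)

cfg <- experiment_config(sobol_n_outer = 500, sobol_n_inner = 500, seed = 11)
bundle <- run_experiment(cfg)
print(bundle)
#> <valve_experiment> n = 440 samples, 5 splits
#> # A tibble: 2 × 3
#>   model  mean_r2 mean_mape
#>   <chr>    <dbl>     <dbl>
#> 1 gp       0.998    0.0794
#> 2 linear   0.828    0.574
#> influential parameters: CL, IC, PL, AL
#> # A tibble: 3 × 2
#>   pair         tv
#>   <chr>     <dbl>
#> 1 sim_gp12 0.0467
#> 2 sim_gp4  0.144
#> 3 gp4_gp12 0.141
```

Reading the output: the GP surrogate explains ~99.8% of held-out
orifice-area variance where the linear baseline manages ~83% (and makes
~7× smaller relative errors) — the geometry-to-area map is genuinely
nonlinear. The Sobol ranking identifies the intercommissural diameter and
the three leaflet lengths (IC, AL, PL, CL) as the influential subset, and
the total-variation distance between the full 12-parameter surrogate
distribution and the 4-parameter reduced one is small (~0.14), so those
four measurements — all extractable from routine echocardiography —
carry most of the geometric information about the orifice area.

Individual stages are available on their own, e.g.:

```r
d <- generate_dataset(440, seed = 1)          # emulated closure "simulations"
gp <- fit_gp(d)                               # ARD-kernel GP surrogate
tidy(gp)                                      # per-parameter length scales
cl <- emulate_closure(build_valve_curves(sample_physical(1, seed = 2)))
gap_length_area(edge_curve(cl, "anterior"), edge_curve(cl, "posterior"))
```

A thin CLI wrapper lives at `inst/scripts/run_pipeline.R`
(`Rscript run_pipeline.R run --seed 1 --outdir out`).

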