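# ipcFlow

Interstitial fluid pressure and drug penetration in peritoneal tumor
nodules during intraperitoneal chemotherapy (IPC), driven by DCE-MRI.

During IPC a cytotoxic drug (cisplatin here) bathes the tumor surface and
must penetrate against outward convection driven by elevated interstitial
fluid pressure (IFP). `ipcFlow` is an R implementation of the full
image-to-prediction chain for researchers in computational oncology and
physiologically based drug transport: it quantifies tumor vascular
heterogeneity from dynamic contrast-enhanced MRI, turns it into a
spatially varying Starling source map, and solves the coupled
pressure/transport problem on the voxelised tumor geometry.

## The model

**Kinetics (imaging → vasculature).** Per voxel, the interstitial tracer
concentration follows a two-compartment exchange with the plasma,

    φ dc/dt = PS/V (c_AIF − c) + Jv/V (1−σ) c_AIF,

forced by a bi-exponential arterial input function fitted from candidate
blood voxels (with hematocrit correction `c_AIF = c_b/(1−Hct)`).
Concentrations come from the exact algebraic inversion of the spoiled
gradient-echo signal equation; native T1 from a four-TR
saturation-recovery fit. Fitted filtration rates are rescaled to a
Starling coefficient map

    (LpS/V)_i = Lp0 · SV0 · (Jv/V)_i / (Jv/V)avg,   Lp0·SV0 = 4.2e-7 (Pa s)⁻¹,

with viable/hypoxic/necrotic zones classified from curve shape.

**Fluid mechanics.** Steady Darcy flow with Starling filtration and no
lymphatics,

    u = −K ∇Pi,    −K ∇²Pi = LpS/V (Pe − Pi),    Pe = Pv − σ(πv − πi),

Dirichlet `Pi = 0` on the tumor surface. `Pe` is the maximal sustainable
IFP (≈1530 Pa with the baseline constants).

**Drug transport.** Implicit finite-volume advection–diffusion–reaction
over the 30-minute therapy,

    ∂C/∂t = D ∇²C − ∇·(uC) − S,

with `C = 0.113 mol/m³` held at the surface, first-order sink, and upwind
advection (provably bounded: `0 ≤ C ≤ C_boundary`).

**Metrics.** Per probing axis and side: maximal pressure, LP50
(edge-to-half-maximum distance), absolute penetration depth (APD, deepest
contiguous point above the IC50), relative penetrated length (PD%);
per tumor: penetrated volume fraction (Pvol%) and the solid-stress
residual `P_measured − P_max,simulated`.

A synthetic phantom module generates ellipsoidal tumors with interior
zones, ground-truth kinetics, analytic AIFs and raw signal series, so the
whole chain is validated by recovery tests (see the methods vignette in
`vignettes/ipcFlow-methods.Rmd`).

## Worked example

The default configuration builds a 3 × 2.5 × 2 mm two-zone phantom
(necrotic core), simulates the DCE study, and runs the chain end to end
(about 10 s on one core):

```r
library(ipcFlow)
res <- runPipeline(defaultConfig(), verbose = TRUE)
#> phantom: 7892 tumor voxels, 590 slice voxels, plane 12
#> aif: fitted 0.792 exp(-0.02 t) + 0.2 exp(-0.002 t), arrival 60.48 s
#> kinetics: necrotic 96, viable 494
#> lpsv per 3-D zone: 4.2e-07, 0
#> ifp: max 1520 Pa (effective pressure 1532 Pa)
#> transport: final max 0.1124 mol/m^3, worst budget closure 2.85e-09
print(res$report)
#> PenetrationReport
#>   per-axis metrics:
#>   axis side axisLength pmax   lp50   apd pdPct
#> 1   LA    L      6.158 1520 0.3465 6.158 50.25
#> 2   LA    R      6.158 1520 0.3467 6.158 50.25
#> 3   SA    L      5.132 1512 0.2675 5.132 50.25
#> 4   SA    R      5.132 1512 0.2675 5.132 50.25
#>   per-tumor metrics:
#>   volume interiorVolume pvolPct pmaxGlobal piMax pmeas ssPressure
#> 1  63.14           4.16     100       1520  1532    NA         NA
```

Reading the output: the fitted AIF reproduces the generator's
bi-exponential; the 96 necrotic slice voxels are detected from their
no-washout curves and the necrotic 3-D zone gets LpS/V = 0 while the
viable shell averages exactly Lp0·SV0 = 4.2e-7 (Pa s)⁻¹; the simulated
peak IFP (1520 Pa) presses against its theoretical ceiling
`Pe = 1531.9 Pa`; LP50 of ~0.27–0.35 mm quantifies the steep pressure
shoulder at the rim. With the default placeholder IC50
(5e-3 mol/m³ ≈ 4% of the instillate concentration) this small nodule is
fully penetrated after 30 min (APD spans the axes, Pvol 100%); penetration
metrics are functions of the IC50 argument, so tighter thresholds can be
explored directly, e.g. `computePvol(res$solution, ic50 = 0.05)`.

Passing `outDir = "out"` additionally writes `report.csv`, `report.json`,
NIfTI pressure/drug maps, a legacy-ASCII VTK file with all fields, and a
run log. `readPipelineConfig("my.yaml")` overlays YAML settings on the
defaults; `validateConfig()` reports range/unit/cross-field issues before
anything runs.

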