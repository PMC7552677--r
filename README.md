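# bmhvflow

Desk-scale in-silico hemodynamics of a bileaflet mechanical heart valve
(BMHV) with concomitant subaortic stenosis (SAS), and the diagnostic
accuracy of Doppler-echocardiographic criteria for valve dysfunction.

Prosthetic-valve surveillance relies on Doppler surrogates — transvalvular
peak velocity (Vpeak), mean transvalvular pressure gradient from the
simplified Bernoulli relation (TPGmean = mean of 4·V², mmHg with V in
m/s), Doppler velocity index (DVI = V_LVOT / Vpeak) and effective orifice
area (EOA = Q / Vpeak) — screened against guideline thresholds
(Vpeak ≥ 3 or 4 m/s, TPGmean ≥ 20 or 35 mmHg, DVI ≤ 0.35/0.30/0.25,
EOA ≤ 1.2/0.8 cm²). A narrowed left ventricular outflow tract (LVOT)
below the prosthesis accelerates flow upstream of the valve and distorts
exactly these surrogates. `bmhvflow` rebuilds that diagnostic problem as a
reproducible pipeline:

* **study grid** — 45 cases: LVOT hydraulic diameter {27, 25, 23, 21,
  19} mm × one-leaflet opening restriction {0, 50, 100}% × cardiac output
  {3, 5, 7} L/min, at 70 bpm with a 0.3 s systole; blood ρ = 1060 kg/m³,
  μ = 0.0035 Pa·s;
* **geometry** — parametric 2D outflow tract: tunnel SAS, conical
  expansion to the 27 mm annulus, two rigid leaflets at
  dysfunction-dependent angles, sinus bulge, aorta; rasterized to a
  masked-cell Cartesian grid;
* **flow solver** — staggered-grid fractional-step (projection) method
  (Rcpp core) with pulsatile plug inflow, adaptive sub-stepping, optional
  standard k–ω eddy-viscosity closure, divergence and mass-conservation
  control, cycle-periodicity monitoring;
* **field analysis** — vorticity, viscous and modeled turbulent
  (Reynolds) shear stress, region/time peak search, jet counting;
* **Doppler metrics and accuracy** — the four surrogates per case, and
  sensitivity/specificity of each guideline criterion for two severity
  groupings (mild-to-severe: 50% + 100% positives; moderate-to-severe:
  100% only);
* **synthetic data** — half-sine pulsatile waveform, exact oscillatory
  channel (Womersley) solutions, and jet fields with prescribed maxima so
  the downstream stages are testable without the solver.

See `vignettes/bmhv-hemodynamics.Rmd` for the model, its assumptions and
the design decisions.

## Worked example

```r
library(bmhvflow)

# one case of the grid: healthy 27 mm valve, normal cardiac output
cs <- case_spec(27, 0, 5)
wf <- pulsatile_waveform(cs)
round(max(wf$q), 1)          # 22.4  peak systolic flow, L/min
round(inlet_velocity(wf, 27, 0.15), 2)  # 0.65  peak plug velocity, m/s

# coarse simulation (0.9 mm grid, two cardiac cycles)
run <- run_case(cs, geometry_params(grid_spacing_mm = 0.9),
                solver_config(n_cycles = 2))
rep <- doppler_report(run)
round(c(v_peak = rep$v_peak, v_lvot = rep$v_lvot, dvi = rep$dvi,
        eoa = rep$eoa, tpg_mean = rep$tpg_mean), 3)
#>   v_peak   v_lvot      dvi      eoa tpg_mean
#>    0.963    0.690    0.717    3.885    2.110
```

The peak transvalvular velocity (0.96 m/s) sits below every dysfunction
threshold, DVI ≈ 0.72 and EOA ≈ 3.9 cm² are in the unobstructed range,
and the valve-plane speed profile shows the three jets (one central, two
lateral) of a fully open bileaflet valve:

```r
pk <- which.max(sapply(run$snapshots,
                       function(s) max(cell_velocity(s, run$mask)$speed)))
jet_count(run$snapshots[[pk]], run$mask)
#> [1] 3
```

With full closure of one leaflet (`case_spec(27, 100, 5)`) the lateral
orifice on the affected side disappears, the jet becomes dominantly
lateral, Vpeak roughly doubles and EOA drops — the monotone trends the
diagnostic criteria rely on. Grid-level drivers (`run_grid`,
`accuracy_from_metrics`) produce per-case metrics CSVs and the accuracy /
per-diameter summary tables; a thin CLI wrapper lives in
`inst/cli/bmhvflow.R` (`verify`, `run-case`, `run-grid`, `metrics`,
`accuracy`, `report`).

Simulated magnitudes at this deliberately coarse resolution are
qualitative: a first-order 2D solver at 0.9 mm under-resolves the jets, so
velocities run low compared to fine-mesh 3D CFD of the same
configuration. The monotone trends, the flow-independence of DVI/EOA and
the jet arrangements are the reproducible content (see the vignette).

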