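# DXTracker

Analysis toolkit for **diffracted X-ray tracking (DXT)** of single-molecule
rotational dynamics, built around the ligand-gated motion of the nicotinic
acetylcholine receptor (nAChR) on living muscle cells.

In DXT, a gold nanocrystal bound to one receptor subunit produces a Bragg
diffraction spot under a broadband X-ray beam. As the protein reorients,
the spot moves on the detector: radial motion reports **tilt** (θ) of the
labelled domain, azimuthal motion reports **twist** (χ) about the beam
axis. Tracking many short spot trajectories (sub-millisecond lifetimes,
100 µs frames) and pooling their displacements yields per-axis ensemble
mean-square-displacement (MSD) curves,

MSD(Δt) = 2σ² + 2D·Δt,

whose slope measures the rotational diffusion coefficient *D* and whose
intercept measures the static localisation noise σ². Comparing an agonist
condition (carbamylcholine, CCh) against an antagonist condition
(α-bungarotoxin, BGT) quantifies which rotational mode the antagonist
blocks: twist is strongly suppressed, tilt is not, and the blocked twist
excursions beyond 10 mrad (≈ 0.6°) are the signature of channel gating.

The package provides, as composable S4 components:

* **geometry** — Bragg condition, ring-band arithmetic for Au(111)/Au(200),
  detector↔polar transforms, tilt/twist decomposition, dose and unit
  helpers (`braggAngle`, `ringBand`, `detectorToPolar`,
  `angularDisplacement`, `xrayDose`, `mradToDegrees`);
* **tracking** — Crocker–Grier spot detection and exact minimum-cost
  bipartite linking with no gap closing (`detectSpots`, `linkSpots`,
  `filterTrajectories`);
* **kinetics** — pooled-pair ensemble MSD, weighted linear fits,
  displacement distributions, 2D density maps and condition difference
  maps (`ensembleMSD`, `fitMSDLinear`, `displacementDistribution`,
  `tailFraction`, `densityMap2D`, `differenceMap`);
* **synthetic data** — a calibrated generator of angular trajectories and
  rendered detector movies for both ligand conditions
  (`cchModel`, `bgtModel`, `simulateAngularTrajectories`, `renderMovie`,
  `makeDataset`);
* **pipeline** — YAML-configured orchestration and CSV/TIFF/JSON I/O
  (`defaultRunConfig`, `runCondition`, `compareConditions`), plus a thin
  CLI at `inst/scripts/dxt.R`.

## Worked example

```r
library(DXTracker)

# simulate the agonist condition at its packaged defaults
ats <- simulateAngularTrajectories(cchModel(), seed = 0)
ats
#> AngularTrajectorySet 'CCh': 157 trajectories, mean span 0.699 ms (tau = 0.1 ms)

# ensemble MSD on the twist axis, weighted linear fit over 0.1-0.7 ms
fitMSDLinear(ensembleMSD(ats, "chi", maxLagFrames = 7))
#> MSDFit 'CCh' (chi): slope 19.59 +/- 1.56 mrad^2/ms,
#>   intercept 14.3 +/- 0.614 mrad^2 (lags 0.1-0.7 ms)

# full two-condition comparison
cmp <- compareConditions(defaultRunConfig(seed = 0), "CCh", "BGT")
cmp$report$slope_ratios$chi        # 10.32
cmp$report$chi_suppressed          # TRUE
cmp$report$theta_suppressed        # FALSE
cmp$report$tail_fraction_a$chi     # 0.0658  (CCh twist pairs > 10 mrad)
cmp$report$tail_fraction_b$chi     # 0       (BGT: none)
cmp$report$diff_band_mass_10_50    # 0.0658  (CCh-enriched 10-50 mrad twist)
```

The fitted twist slope (19.6 mrad²/ms here) estimates 2·D_χ of the
generative model (18.45); the suppression flags encode the ligand
contrast: the CCh/BGT twist-slope ratio exceeds 4 with separated 3 SE
intervals while tilt does not, and the difference map concentrates its
positive mass in the 10–50 mrad twist band — the gating-associated motion
blocked by the antagonist.

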