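---
title: "Methods: diffracted X-ray tracking analysis with DXTracker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diffracted X-ray tracking analysis with DXTracker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DXTracker)
```

## The measurement model

Diffracted X-ray tracking (DXT) infers the orientation changes of a single
protein from the motion of a Bragg diffraction spot produced by a gold
nanocrystal attached to it. Under a quasi-monochromatic beam of peak energy
$E$ with fractional bandwidth $w = \Delta E/E$, a crystal plane of spacing
$d$ diffracts whenever its Bragg-matched wavelength
$\lambda = 2d\sin\theta_B$ falls inside the band
$[\,hc/E(1+w/2),\; hc/E(1-w/2)\,]$. On a flat detector at camera length $L$
the spot sits at radius $r = L\tan 2\theta_B$ and azimuth $\chi$. DXTracker
models the two gold rings Au(111) ($d = 2.3546$ Å) and Au(200)
($d = 2.0391$ Å); at the default 15.8 keV and $L = 50$ mm these project to
17.40 mm and 20.39 mm, broadened by the $w = 0.08$ bandwidth into the
radial bands [16.67, 18.19] mm and [19.52, 21.35] mm.

Crystal rotation decomposes into two detector-observable axes:

* **tilt ($\theta$)** — rotation that changes the Bragg angle, moving the
  spot radially. We use $\Delta\theta = \Delta(2\theta_{spot})/2$, since the
  scattering angle changes by twice the lattice tilt.
* **twist ($\chi$)** — rotation about the beam axis, moving the spot
  azimuthally 1:1.

Cross-talk between the axes is neglected; at the displacement scales
analysed here (≤ 100 mrad) the small-angle approximation holds to better
than 1%. Azimuth differences are wrapped into $(-\pi, \pi]$ and twist
trajectories accumulate wrapped frame-to-frame steps, so tracks straddling
the $\chi = \pm\pi$ seam are handled exactly.

The band profile is modelled as rectangular: a spot is visible iff its
instantaneous Bragg wavelength lies in band. The bandwidth figure is read
as a dimensionless fractional full width (0.08 of 15.8 keV), the only
reading consistent with the stated peak energy (0.08 *nm* would be larger
than the 0.785 Å wavelength itself).

## Spot detection and linking

Detection is a Crocker–Grier-style pipeline, re-implemented here so the
computation is owned by the package: Gaussian low-pass (default
$\sigma = 1$ px) minus a boxcar background over a
$(2\,\mathrm{minSeparation}+1)$-px window; candidate pixels are local
maxima of the band-passed image exceeding
$\mathrm{median} + k\cdot\mathrm{MAD}$ (default $k = 5$; the MAD is taken
on the *unclipped* band-pass so it estimates the noise scale even when most
pixels are background). Candidates closer than `minSeparation` (default
5 px) are pruned keeping the brighter; each survivor's subpixel position is
the intensity-weighted centroid over the window, computed on the low-pass
image minus the frame's flat background level (centroiding on the
boxcar-subtracted image would bias positions by removing part of the spot's
own mass asymmetrically). On noise-free synthetic frames this centroid is
accurate to < 0.05 px; with Poisson noise at the default photon budget,
< 0.2 px.

Linking solves, between each pair of consecutive frames, the
minimum-cost bipartite assignment with cost = squared displacement, pairs
farther than `maxDisplacement` (default 10 px) forbidden, and an
opportunity cost of `maxDisplacement`² per unmatched spot — the standard
non-link penalty, which trades a link against track termination. The solver
is an exact $O(n^3)$ Jonker–Volgenant implementation (no linear-assignment
solver exists in the dependency set); equal-cost optima are broken toward
low (frame, spot-index) pairs by an infinitesimal perturbation, making runs
deterministic. There is **no gap closing** (memory = 0): with mean track
lifetimes of only 7 frames, closing gaps would risk splicing unrelated
crystals into spuriously long tracks. The test suite proves the solver
equal to exhaustive enumeration of all matchings on instances up to 4
spots/frame.

Trajectories keep a ring label when ≥ 80% of their spots fall inside one
band (majority vote), else they are labelled `none` and discarded together
with tracks shorter than `min_length` (default 2 frames). Kept/discarded
counts and mean track span are logged so spot conservation can be audited
from logs alone.

## MSD estimation and fitting

Angular trajectories are referenced to their first observed sample. The
ensemble MSD at lag $k\tau$ pools the squared axis displacement over *all*
ordered in-trajectory sample pairs $(i, i+k)$ across all trajectories
(time-and-ensemble average); Au(111) and Au(200) tracks are pooled after
per-ring conversion. Lags run 1–7 frames (0.1–0.7 ms), matching the mean
trackable span: beyond 0.7 ms the pair counts collapse and the estimate is
dominated by a few long tracks.

The MSD curve is fitted by weighted least squares with weights proportional
to per-lag pair counts; for simple rotational diffusion the slope is $2D$
and the intercept $2\sigma^2$, with $\sigma$ the static localisation noise.
Parameter standard errors are the conventional weighted-LSQ covariance
scaled by residual variance. Two caveats, both documented because they
matter for interpretation:

* the full intercept is attributed to measurement noise; unresolved fast
  motion below the 0.1 ms frame interval would inflate it
  indistinguishably;
* the 7 MSD points share trajectories and overlapping pairs, so their
  errors are strongly correlated: the residual-based SE understates the
  replicate-to-replicate variability of the slope (by a factor ~3–5 under
  the default conditions). Where the package itself makes replicate-level
  claims (parameter-recovery tests, the acceptance protocol), it therefore
  uses replicate means over 5 generator seeds and replicate-based SEs with
  a $t_4$ small-sample quantile, rather than the single-fit SE.

Displacement distributions at fixed $\Delta t$ (default 0.7 ms) histogram
absolute pooled displacements on 60 log-spaced bins over
$[10^{-2}, 10^3]$ mrad with an explicit underflow/overflow pair; the
two-axis maps histogram $(|\Delta\theta|, |\Delta\chi|)$ jointly on the
same edges, clamping out-of-range values into the edge bins so each map
sums to exactly 1 and condition differences sum to exactly 0. All pooled
pairs at the lag contribute, whether or not the parent track survives the
full 0.7 ms — the alternative (only tracks ≥ 0.7 ms) discards over half
the data and conditions the distribution on longevity.

## The synthetic generator

The raw trajectories behind the reference experiment are not deposited, so
the package ships a generative stand-in whose defaults *are* the study
conditions; they are calibrated once, from the printed ensemble MSD fits,
via slope = $2D$ and intercept = $2\sigma^2$, and are not meant to be
tuned:

| condition | n | $D_\theta$ | $D_\chi$ | $\sigma^2_\theta$ | $\sigma^2_\chi$ |
|---|---|---|---|---|---|
| CCh (agonist, 2 µM) | 157 | 10.35 | 9.225 | 3.5715 | 7.398 |
| BGT (antagonist, 0.2 µM) | 176 | 7.385 | 1.1555 | 2.5735 | 3.103 |

(diffusion coefficients in mrad²/ms, noise variances in mrad²; 0.1 ms
frames; 10 ms maximum records.)

Each trajectory draws a lifetime in frames from a geometric (memoryless)
law with mean 7 frames, clipped to [2, 100]; a track of $n$ frames is
reported as $n \times 0.1$ ms of trackable span, reproducing the 0.7 ms
mean. The latent path is independent per-axis Brownian rotation with
per-step variance $2D\tau$; observations add i.i.d. Gaussian noise of SD
$\sigma$ and are re-zeroed to the first observed sample, so the expected
ensemble MSD is exactly $2\sigma^2 + 2D\,\Delta t$. This is the *minimal*
model consistent with a linear MSD and positive intercept: no state
switching, no anomalous exponent, no axis coupling. Passing tests on this
generator therefore demonstrate estimator correctness and pipeline
fidelity — not that real receptor motion is a one-state Brownian process.
An optional two-population CCh variant (`cchGatingModel()`) keeps the
ensemble twist slope while concentrating fast twist in a 30% "gating"
subpopulation, for heavy-tail experiments.

Randomness is hierarchical: a 31-bit stream id is derived from
(seed, condition label, trajectory index), so any subset of trajectories
is reproducible independently of the rest, and identical seeds give
byte-identical datasets.

Movie mode renders each trajectory as a diffraction spot: ring assigned
from the trajectory's label, initial azimuth uniform (or caller-specified),
initial tilt at the peak-energy Bragg angle; spots are 2D Gaussians
(default $\sigma = 1.5$ px, 2000 photons) with optional Poisson shot noise
over Poisson background, and vanish when the tilt-implied wavelength
leaves the energy band — the physical track-termination channel. Two
renderer caveats: band exit adds a second termination channel on top of
the geometric lifetime (at the calibrated tilt scales it shortens the mean
span only marginally, and no compensating correction is applied), and the
outer edge of the Au(200) band (21.35 mm) slightly exceeds the default
detector half-width (20.48 mm) along the axes, so spots there clip off the
detector.

## The condition comparison

`compareConditions()` reproduces the ligand contrast: per-axis slope
ratios, tail fractions beyond 10 mrad at $\Delta t = 0.7$ ms, and the
CCh − BGT difference map with its net mass in the 10–50 mrad twist band.
A direction is flagged *suppressed* when the slope ratio exceeds a
configurable factor (default 4) **and** the two slopes' 3 SE intervals do
not overlap. Under the default models the twist ratio is ~8 (18.45/2.311)
and robustly flagged, while tilt (ratio 1.4) never reaches the factor —
the operational form of "twist suppressed by the antagonist, tilt not".
We use this operational flag rather than a raw interval-overlap test for
tilt because, with the naive fit SEs discussed above, interval overlap
between two genuinely different tilt slopes is itself a coin flip; the
suppression factor encodes the scientifically meaningful contrast.

## Numerical and protocol choices

* Problem sizes: parameter-recovery and contrast tests run the full
  157/176-trajectory conditions on 5 seeds (a few seconds each);
  property tests use reduced sizes (≤ 2000 trajectories, ≤ 4 spots/frame
  for the exhaustive linking oracle, 64–512 px frames) chosen so each
  oracle stays exact.
* The geometric lifetime law is validated with a chi-square
  goodness-of-fit test on the discrete track-length pmf (a KS test is
  invalid for discrete data).
* Degenerate inputs: zero-bandwidth bands collapse to a single radius;
  points at the beam centre raise an undefined-azimuth error rather than
  returning NaN; blank frames return zero spots (the detection threshold
  keeps a relative floor so noise-free frames do not trip on FFT residue);
  fits require ≥ 2 lags in range and report zero SEs for exactly linear
  curves.
* Dose arithmetic is linear at 1.13 kGy/ms (113 kGy per 100 ms exposure);
  the 10 mrad twist threshold corresponds to 0.57° ≈ 0.6°.

## Known limitations

* The generator cannot represent kinetic open/closed state switching,
  intensity blinking, detector distortion, or mosaic-crystal effects; all
  claims validated on it are claims about the analysis chain.
* The weighted-LSQ slope SE is a within-fit quantity; replicate-level
  uncertainty is ~3–5× larger under the default conditions. The BGT twist
  slope (2.311 mrad²/ms) is small enough that even a 5-seed mean carries
  ~18% relative SD — recovery checks for it are bounded by replicate SEs,
  not by a fixed percentage.
* Pixelation is ignored in the forward model (spots are sampled, not
  integrated, per pixel); at $\sigma_{PSF} = 1.5$ px the induced centroid
  bias is below 0.05 px.
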