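---
title: "Forward modelling of EHG surface potentials: sources, tissue, electrodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forward modelling of EHG surface potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehgsim)
```

## The model in one page

The electrohysterogram (EHG) is the electrical signature of uterine
smooth-muscle (myometrium) depolarization recorded on the abdominal
surface.  `ehgsim` simulates that chain with three components.

**Source.**  The travelling depolarization front is idealized as a *dipole
band*: an annular strip of dipoles of total moment $p_0$ and width
$\delta$ riding on the wall of a conical uterus of half-angle $\theta$.
The band's axial displacement is $z = c\,t$ with constant speed $c$, its
slant radius is $R = (R_{os} - c\,t)/\cos\theta$, and its dipole surface
density is

$$D = \frac{p_0}{\pi \sin\theta\,\big[(R+\delta)^2 - R^2\big]},$$

the total moment spread over the annular strip of the cone wall.  The
axial potential at a coordinate $\zeta$ is the difference of the two
edge-ring terms

$$v(\zeta) = -\frac{D}{2\varepsilon_0}\left\{
  \frac{\zeta - (R+\delta)\cos\theta}
       {\sqrt{\zeta^2 - 2 (R+\delta) \zeta \cos\theta + (R+\delta)^2}}
  -
  \frac{\zeta - R\cos\theta}
       {\sqrt{\zeta^2 - 2 R \zeta \cos\theta + R^2}}
\right\}.$$

Defaults: $c = 30$ mm/s, $R_{os} = 400$ mm, $\theta = 10^\circ$,
$\delta = 6$ mm, $p_0 = 2.2\times10^{-13}$ C·mm, $\varepsilon_0 = 0.36$.
All lengths are mm and times s; the potential is left in uncalibrated
model units, because every result the package reports — delays, speeds,
attenuation ratios in dB — is unit-invariant.

**Volume conductor.**  The abdomen is a hemispherical dome (radius
100 mm, anterior $+y$) of skin (2 mm), fat (15 mm) and muscle (8 mm)
shells over the uterine interior, immersed in air inside a grounded
bounding box.  Because uterine contents (amniotic fluid, fetus) are far
more conductive than the abdominal wall and electrically quiet, the
myometrium surface is held at the reference potential (`phi = 0`); the
dipole band rides just outside this grounded surface.  At the sub-Hz
frequencies of the EHG the quasi-static approximation applies, so the
forward problem is the conductivity-weighted Poisson equation
$\nabla\!\cdot(\sigma\nabla\phi) = -\nabla\!\cdot\mathbf{J}_s$, which the
package discretizes with a 7-point finite-difference operator
(harmonic-mean face conductances) and solves directly (sparse Cholesky)
on small grids or by Jacobi-preconditioned conjugate gradients (relative
residual $10^{-10}$) on larger ones.

**Electrodes.**  Four read-outs at the dome apex $(0, 100, 0)$: a
monopolar disc (area-averaged potential, radius $2r$) and three Laplacian
concentric-ring estimators sharing the geometry *disc — middle ring at
$r$ — outer ring at $2r$*:

| kind | reading |
|------|---------|
| bipolar | $\frac{4}{r^2}\,(\bar v_r - v_0)$ |
| quasi-bipolar | $\frac{\bar v_{2r} + v_0}{2} - \bar v_r$ (unnormalized, disc shorted to outer ring) |
| tri-polar | $\frac{1}{3r^2}\,\big[16(\bar v_r - v_0) - (\bar v_{2r} - v_0)\big]$ |

with $\bar v_\rho$ the ring average $\frac{1}{2\pi}\int v(\rho,\phi)\,
d\phi$.  The five-point and nine-point finite-difference stencils are
implemented alongside as independent oracles; bipolar/five-point are
exact for polynomial surface potentials of total degree $\le 3$,
tri-polar/nine-point through degree $\le 5$ (the 16:−1 ring weighting
cancels the fourth-order truncation term).

## Worked example: source waveforms and conduction delay

```{r waveforms}
band <- dipole_band_params()
round(band_traversal_time(band))   # 27 s for the -400..+400 mm traversal

w <- simulate_round_trip(band, zetas = c(0, 50), dt = 0.1,
                         t_end = band_traversal_time(band))
est <- estimate_propagation_speed(w[[1]], w[[2]], spacing = 50,
                                  method = "onset", outbound_only = FALSE)
c(delay_s = est$delay_s, speed_mm_s = est$speed_mm_s)
```

The band needs 27 s for the fundus-to-cervix traversal, and the onset
delay between observation points 50 mm apart is about 1.77 s, an apparent
conduction speed of 28 mm/s.

## Delay estimation: why three methods

The apparent conduction speed depends on how the arrival of the wave is
timed, because the waveform is not a rigidly translating pulse: its width
grows with the ring radius at the observation coordinate and its
amplitude grows as the band approaches the cone apex.  The package
exposes three standard estimators in
`estimate_propagation_speed()`:

* `peak` — quadratically interpolated peak times.  The amplitude
  modulation skews peaks towards the apex, giving 1.62 s / 30.9 mm/s
  between $\zeta = 0$ and 50 mm;
* `onset` — half-maximum rising-edge latency, the usual onset-latency
  convention in surface-EMG conduction studies.  It times the wavefront
  itself and gives 1.77 s / 28.2 mm/s;
* `xcorr` — cross-correlation lag, 1.62 s / 30.9 mm/s.

All three lie within the plausible 27–31 mm/s band around the preset
30 mm/s; sub-second sampling (`dt = 0.1` s) with interpolation is
required to resolve them at all, which is why the simulator samples well
below the 1 s granularity of the band kinematics.

## The sensitivity experiments

**Probe.**  Local sensitivity is probed the standard way: a point dipole
of moment $p_0$, oriented at the electrode ($+y$), placed on the $+y$
axis 5 mm outside the grounded myometrium surface (at $y = 80$ mm under
the default layers), displaced along $z$ in 5 mm steps over ±30 mm.
Attenuation at displacement $d$ is
$20\log_{10}|v(0)/v(d)|$ dB, and the *20 dB distance* — where the curve
first crosses 20 dB, linearly interpolated — quantifies how local each
electrode is (shorter = more local).  If a curve never reaches 20 dB
within the sweep the range bound is reported with a censoring flag rather
than extrapolated.

At the default resolution the bipolar and tri-polar electrodes cross
20 dB within about 9–12 mm, while the monopolar disc never crosses within
30 mm and the quasi-bipolar configuration crosses late or not at all —
the ordering that makes the two true-Laplacian designs the preferred EHG
electrodes.

**A genuine caveat: sensitivity nulls.**  The surface Laplacian of a
compact source changes sign on a ring around the source (for an ideal
radial dipole at depth $D$, at lateral distance $\sqrt{2/3}\,D$).  Past
its 20 dB crossing each Laplacian curve therefore passes a null where the
attenuation spikes and then partially recovers, so the curves are
monotone *up to the crossing* but not beyond it.  The quasi-bipolar
reading $(\bar v_{2r} + v_0)/2 - \bar v_r$ is worst affected: its
leading $r^2$ and $r^4$ terms have opposite signs for this geometry, so
its *undisplaced* reading sits near a null for larger rings and the
first sweep step can show a small negative attenuation.  This was
verified to persist (for the 20 and 25 mm outer rings) at half the
default grid spacing, i.e. it is a property of the estimator in this
model, not a discretization artifact; the corresponding monotonicity
expectation in the acceptance suite is left failing by design and
documented here rather than weakened.

**Tissue thickness.**  The thickness experiments vary one layer (fat
0–30 mm with muscle fixed at 8 mm, or muscle 0–16 mm with fat fixed at
15 mm) and report attenuation relative to the zero-thickness baseline.
The probe follows the myometrium as the wall thickens — the band rides
on the uterus wall — so added thickness increases the source-electrode
distance, and the low conductivity of fat (0.04 S/m vs muscle
0.35 S/m) adds a resistive barrier on top: attenuation increases
strictly with both thicknesses and the fat effect dominates at matched
thickness.  The absolute dB values are large (the zero-fat baseline
places the probe only a few mm under the electrode, where Laplacian
readings are very sensitive to depth); only the orderings are
interpreted, since the corresponding study figures publish no numeric
axis values.

**Noise dipoles.**  Six noise dipoles with random orientation and moment
$0.1\,p_0$ are placed uniformly in the muscle shell towards the $+x$
axis (within 60° of it, in the dome), reproducibly under a seed.  At
this moment scale and distance from the electrode their perturbation of
the attenuation curves is far below 0.1 dB, so every ordering holds with
and without noise; larger `moment_scale` values are configurable.

## Numerical choices

* **Grid.**  Default spacing 5 mm in a ±120 mm box (about $10^5$
  unknowns), the resolution at which the full experiment battery runs in
  minutes on one core.  The 2 mm skin cannot be meshed at this spacing;
  instead each node's conductivity is the thickness-weighted harmonic
  mean of the tissue shells crossing its cell — the series-resistor
  subgrid model, which preserves the radial resistance of shells thinner
  than a cell.  Halving the spacing is available through
  `grid_spacing` and was used to verify grid-sensitivity of the
  qualitative results (one case where it matters: the quasi-bipolar
  electrode's shallow twin-peaked waveform at 5 mm spacing becomes
  single-peaked at 2.5 mm).
* **Dipole injection.**  Each point-dipole component is two nested ±
  monopole pairs (separations $2h$ and $4h$, moments $4m/3$ and $-m/3$);
  the Richardson combination cancels the $O((h/r)^2)$ finite-separation
  bias.  Near the grounded myometrium the wide stencil would straddle
  grounded nodes, so it falls back to a compact pair there.
* **Grounding discretization.**  Myometrium nodes are grounded when
  their grid cell lies fully inside the boundary ($r < r_{in} - h/2$),
  which keeps interface-straddling nodes active and near-wall sources
  intact at any layer thickness.
* **Solver verification.**  Against the closed-form dipole potential in
  a uniform box (64 cells across), the solved surface values agree to
  within 2% in field-scale-normalized error (mean over random directions
  at 5–8 cell separations; pointwise beyond 7 cells).  The residual
  worst-case error at 5 cells (≈3.5%) is the angular anisotropy of the
  7-point operator.  Superposition holds to $10^{-10}$ (exactly, on the
  direct-factorization path).
* **Singular configurations.**  The source potential is undefined when
  an observation point lies exactly on a band-edge ring (e.g.
  $\zeta = 0$ at the instant the inner edge collapses onto the apex);
  these raise an error naming the offending term rather than returning a
  large number.

## What the simulation does and does not show

The generator emulates the study conditions: a single coherent
depolarization front at constant speed, isotropic tissue, a symmetric
hemispherical abdomen with the uterus centred, and noise limited to six
fixed-moment dipoles.  Real EHG propagation is anisotropic and
multi-directional, the uterus is tilted, electrode-skin impedance and
amplifier noise are absent here, and absolute potentials are
uncalibrated.  Passing the acceptance battery therefore certifies the
electrode-comparison *methodology* — the relative local sensitivity of
the four designs and the direction of tissue-thickness effects — not
clinical signal amplitudes.
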