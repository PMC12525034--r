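---
title: "Methods: SWIR spatial frequency domain imaging from photons to hydration maps"
author: "swirsfdi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SWIR spatial frequency domain imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
transport model behind the lookup table, the demodulation and calibration
algebra, the inversion and unmixing procedures, what the synthetic data
generator does and does not emulate, and the numerical and design choices
made where the method leaves them open.

## 1. The measurement model

SFDI illuminates a turbid half-space with a planar pattern (spatial
frequency $f_x = 0$, "DC") and a sinusoidal pattern ($f_x = 0.1$ mm$^{-1}$,
"AC"). The diffusely reflected amplitude at each frequency is a different
functional of absorption $\mu_a$ and reduced scattering
$\mu_s' = \mu_s(1-g)$: the DC response integrates the whole point-spread
function, while the AC response is low-pass filtered by lateral photon
migration. The pair $(R_{DC}, R_{AC})$ at a pixel therefore determines
$(\mu_a, \mu_s')$ at that pixel, given a forward model.

In the SWIR band the dominant absorbers of soft tissue are water and lipid.
With $\mu_a$ measured at 970, 1050 and 1200 nm — wavelengths bracketing the
water peak near 970 nm, the inter-peak minimum, and the lipid/water features
near 1200 nm — the linear system
$\mu_a(\lambda) = \varepsilon_w(\lambda) C_w + \varepsilon_l(\lambda) C_l$
yields water and lipid volume fractions by least squares (three equations,
two unknowns).

## 2. Monte Carlo transport and the White-MC lookup table

`simulateRadialReflectance` implements standard variance-reduced photon
transport in a semi-infinite homogeneous medium: a pencil beam normally
incident at the origin; specular entry reflection removed before launch
(the launch weight is $1 - R_{sp}$, matching the cross-polarized detection
geometry that rejects specular light); exponential step sampling with
$\mu_t = \mu_a + \mu_s$; absorption by albedo weighting; Henyey–Greenstein
deflection with anisotropy $g$; angle-resolved unpolarized Fresnel
reflection at the boundary decided by a single random draw; Russian roulette
(threshold $10^{-4}$, survival 1/10). Escaping weight is recorded with its
exit radius and total pathlength. The energy ledger (escaped + absorbed +
roulette-adjusted terminated weight = launched weight) balances to better
than $10^{-6}$ and is asserted in the tests.

**Parameters the data do not fix.** The method's specification of the
samples does not constrain $g$ or the refractive indices, and the lookup
table axis is $\mu_s'$ precisely because, in the diffusive regime, media
with equal $\mu_s'$ but different $g$ reflect almost identically (the
similarity relation; verified to 3% in the tests). Defaults are the
soft-tissue conventions $g = 0.9$, $n = 1.33$ for liquid phantoms and 1.4
for skin; the indices are recorded in the table metadata and a table is only
valid for samples with matching $n$.

**Frequency domain.** The spatial-frequency response is the zero-order
Hankel transform of the radial point response,
$R(f_x) = 2\pi \int R(r) J_0(2\pi f_x r)\, r\, dr$. `hankelReflectance`
evaluates this on the binned profile (2000 uniform bins to
$r_{max} = 100$ mm). The table builder instead uses the per-photon
estimator $\frac{1}{N}\sum_i w_i J_0(2\pi f_x r_i)$ — the same integral
against the unbinned empirical measure — which avoids binning error and
makes $R(f_x) \le R(0)$ exact term by term. The two estimators agree to
well under a percent and are cross-checked in the tests.

**White Monte Carlo.** `buildLUT` runs one *zero-absorption* simulation per
$\mu_s'$ node and fills the entire $\mu_a$ axis by reweighting each escaped
photon with $\exp(-\mu_a L)$. This makes a dense $\mu_a$ grid essentially
free and makes the table *exactly* strictly decreasing in $\mu_a$ for the DC
entries. Every $\mu_s'$ node deliberately reuses the **same RNG substream**:
with identical draws, trajectories at different $\mu_s$ are exact spatial
rescalings of one another (step lengths scale as $1/\mu_s$, all angles and
Fresnel decisions are identical), so the table's monotonic increase in
$\mu_s'$ is structural rather than statistical. This is why tables built at
modest photon counts still pass strict monotonicity assertions.

**Pathlength control.** With $\mu_a = 0$ a photon's escape is certain (the
depth coordinate performs a recurrent one-dimensional walk) but the expected
number of steps is unbounded. White-mode runs therefore apply Russian
roulette on the *optical* pathlength (checkpoints every 5000 mean free
paths, survival 1/10, weight ×10) — unbiased, and because the optical
pathlength depends only on the RNG draw sequence, the roulette decisions
are identical across $\mu_s'$ nodes and the common-random-number scaling is
preserved exactly. A hard cap at $\tau_{max} = 10^5$ mean free paths
(practically never reached once roulette is active) bounds the worst case;
capped weight is counted into the total diffuse reflectance but excluded
from the rescaling records, and is reported in the table metadata. Direct
(non-white) runs at $\mu_a = 0$ use no roulette so that the
energy-conservation check is exact rather than statistical.

**Monotone projection.** The DC slab is monotone by construction, but AC
entries can carry sub-noise wiggles (order $10^{-5}$ at $10^4$ photons)
where the true slope vanishes near the gamut edge, because the
oscillating-$J_0$ far field contributes terms of both signs. Since the
physical surface is monotone, each frequency slab is projected onto the
doubly-monotone cone (alternating pool-adjacent-violators passes, then an
exact running-min/max snap); the projection is the standard isotonic
estimator for a monotone truth, its maximum adjustment is recorded in the
table metadata, and it is what lets the build-time invariant assertions be
exact rather than tolerance-laden at any photon count.

**Grids.** Defaults are log-spaced, $\mu_a \in [0.001, 0.5]$ mm$^{-1}$
(48 points) and $\mu_s' \in [0.25, 5]$ mm$^{-1}$ (48 points), covering the
Intralipid dilutions (lowest value needed: the 5% dilution at 1200 nm,
$\mu_s' \approx 0.43$ mm$^{-1}$) and skin with margin. The lower $\mu_s'$
bound is a physical limit, not a convenience: once the transport mean free
path approaches the projected period ($\mu_s' \lesssim 0.1$ mm$^{-1}$ at
$f_x = 0.1$ mm$^{-1}$), the AC response ceases to be monotone in $\mu_a$
(the White-MC estimator shows it *increasing* at small $\mu_a$), and a
non-monotone table is not invertible. The builder also warns when the grid
corner violates $\mu_s' \ge 10\,\mu_a$, where the table leaves the regime
validated against the diffusion oracle.

**Diffusion oracle.** `diffusionRd` is the closed-form semi-infinite
diffusion-approximation reflectance with scalar attenuation
$\mu_{eff}' = \sqrt{3\mu_a\mu_{tr} + (2\pi f_x)^2}$ and an
extrapolated-boundary constant $A$ from the Groenhuis internal-reflection
parameter. It is deterministic and independent of the transport code, and
the two agree within 10% for $\mu_s'/\mu_a \ge 100$ and
$f_x \le 0.1$ mm$^{-1}$ — the package's main physics acceptance check.

## 3. Demodulation and calibration

DC demodulation is the light-on/light-off difference; negative pixels
(possible under read noise) are clamped to zero and counted. AC
demodulation uses the four-phase quadrature formula
$\tfrac12\sqrt{(I_2-I_4)^2 + (I_1-I_3)^2}$, which recovers the envelope
amplitude exactly for ideal sinusoids at any spatial phase (tested to
$10^{-10}$ relative) and is invariant to a common phase offset.

Calibration is per pixel:
$R_{sample} = R_{phantom}^{pred} \cdot M_{sample}/M_{phantom}$, with the
phantom's reflectance predicted from the lookup table at its known optical
properties. Dividing pixelwise flat-fields the illumination profile out of
the result (a ±30% profile cancels to $10^{-6}$ in the tests). Degenerate
pixels — phantom signal below 1% of its median (configurable), or
calibrated reflectance above 1.2 — are masked invalid rather than clipped,
and masks propagate through every later stage with reason codes.

## 4. Inversion

The table is used bidirectionally. The inverse direction minimizes
$(\hat R_{DC}(\mu_a,\mu_s') - R_{DC})^2 + (\hat R_{AC}(\mu_a,\mu_s') - R_{AC})^2$
where $\hat R$ is bilinear interpolation in $\log\mu_a \times \log\mu_s'$
coordinates (the surface is most nearly linear there). The minimizer is
found by exhaustive seeding on the node grid followed by a shrinking 3×3
pattern search, terminating at a relative step of $10^{-6}$ — deterministic,
derivative-free, and robust to the interpolant's facet edges. Candidate
moves are ordered so exact ties resolve toward smaller $\mu_a$
(conservative absorption). Pixels whose best residual exceeds $10^{-3}$ in
reflectance are flagged out-of-gamut and excluded rather than extrapolated.
Noiseless forward–inverse round trips recover 200 random interior points to
0.5% per axis; with 1% multiplicative reflectance noise the median errors
stay within 5% ($\mu_a$) and 3% ($\mu_s'$).

## 5. Unmixing and percent normalization

Per-pixel ordinary least squares on the 3×2 extinction design matrix. The
fit is deliberately unconstrained: negative concentrations are retained and
flagged, because clipping would hide calibration or model failures.
Concentrations are volume fractions; `toPercent` multiplies by 100, with
100% water ≡ 55.6 M and 100% lipid ≡ 0.9 g/mL as the molar/density
equivalences when converting literature spectra. The shipped extinction
values at 970/1050/1200 nm are approximate digitizations of the standard
pure-water and soybean-oil series (provenance recorded in the CSV); they
are replaceable data, and the design-matrix condition number is computed
and reported on load.

## 6. What the synthetic generator emulates — and what it does not

`renderRaw` inverts the acquisition: scene composition → optical properties
(linear mixing for $\mu_a$; power-law scattering
$\mu_s'(\lambda) = a(\lambda/\lambda_0)^{-b}$) → LUT reflectance → raw
frames $I_k = \text{illum}\cdot\text{gain}\cdot(R_{DC} + R_{AC}\sin(2\pi
f_x x + \phi_k)) + \text{ambient} + \text{noise}$, quantized to 16 bits. The
noise model is Gaussian read noise (30 counts) plus a signal-proportional
shot-like term ($\sigma = \sqrt{\text{counts}}$), chosen as typical of
cooled InGaAs cameras; the gain (30 000 counts per unit reflectance) puts
typical signals mid-range of the 16-bit ADC. Setting `bit_depth = NA`
renders continuous frames for exactness checks.

Scenario generators encode the three study designs:

* **Dilutions**: homogeneous scenes at 5/10/15/20% lipid (water
  95/90/85/80%), $\mu_s'$ proportional to lipid fraction from a 10%
  Intralipid reference (1.2 mm$^{-1}$ at 970 nm, slope $b = 1.6$ — config
  data with provenance, not measured values).
* **Desiccation**: 4 hourly timepoints losing 2% of water over the series
  (the generator exposes both the relative and absolute-points reading of
  "2%", defaulting to relative), with scattering coupled through a single
  coefficient $k$: relative $\mu_s'$ change $= k \times$ relative water
  change. $k = 2$ by default. This coupling is a mechanistic *stand-in* for
  collagen-packing physics, not a fitted law: it reproduces the qualitative
  signature (large $\mu_s'$ change, small $\mu_a$ change per unit water
  loss) whenever $k$ exceeds the Beer's-law absorption sensitivity.
* **Exercise**: 3–5 baseline timepoints, a step drop in dermal water (3%
  relative by default) at the exercise boundary, exponential recovery
  toward baseline, and a static in-frame phantom region that the schedule
  never touches — the drift control.

The generator does **not** emulate: inter-frame motion or registration
error, surface curvature and profilometry effects, projector/camera MTF
roll-off, sweat-duct-resolved heterogeneity, chromophores beyond water and
lipid, or layered skin structure. Passing the end-to-end tests therefore
demonstrates the correctness and noise behavior of the *processing chain*,
not instrument-level accuracy on real tissue.

## 7. Problem sizes and reproducibility

The test suite builds a 12×12-node table at $10^4$ photons/node for
pipeline consistency checks (forward rendering and inversion share the
table, so table noise cancels) and a 24×24-node table at $10^5$
photons/node for the acceptance properties; the diffusion comparison runs
$10^6$ photons. These sizes were chosen so the full verification runs on a
single core in minutes while leaving every tolerance comfortably
non-binding; production tables simply increase both numbers. Every source
of randomness — the transport kernel (own xoshiro256++ stream, independent
of R's RNG), noise draws, and sampled test points — derives from explicit
seeds, and identical seeds reproduce results bit for bit, including
rendered TIFF bytes.

## 8. Known limitations

* Homogeneous semi-infinite forward model only; no layered media or
  tomographic sectioning.
* Two spatial frequencies; the inversion is not formulated for $>2$.
* The AC response's loss of monotonicity below
  $\mu_s' \approx 0.1$ mm$^{-1}$ bounds the table gamut from below.
* Extinction coefficients are digitized approximations; absolute
  concentration accuracy on real data inherits their error.
* ROI analytics assume pre-registered time series.
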