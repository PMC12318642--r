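---
title: "Polarisation-based spectral modulation: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polarisation-based spectral modulation: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polsmv)
```

## The measurement model

A Lyot stage — a birefringent retarder of retardance $\lambda_0 = \delta n
\cdot d$ between linear polarisers — transmits normally incident light with

$$T(\lambda) = \cos^2\!\left(\frac{\pi\lambda_0}{\lambda}\right)
  = \tfrac12\left(1 + \cos\Lambda\nu\right),
  \qquad \Lambda = \frac{2\pi\lambda_0}{c},$$

a raised cosine in optical frequency. Spectrally modulated detection built
from such stages compresses a spectrum $I_i(\nu)$ into a *spectral
modulation vector* (SMV)

$$V_k \;=\; \frac{\int I_i(\nu)\,P_k(\nu)\,d\nu}{\int I_i(\nu)\,d\nu},
  \qquad k = 1,\dots,N,$$

for a family of bounded modulation functions $P_k$. The SMV generalises the
spectral phasor (the $\{\cos,\sin\}$ pair): any set of continuous,
pairwise-orthogonal functions works, and cosine harmonics
$\cos k\Lambda\nu$ are what polarisation optics realise cheaply. Two
consequences drive all downstream analysis:

* **Boundedness** — every component of a non-negative spectrum lies in
  $[-1, 1]$;
* **Linearity** — the SMV of a mixture is the power-weighted mean of the
  component SMVs, which is what makes gating and linear unmixing valid on
  SMV coordinates.

Two single-shot configurations are modelled. The *four-detector* layout
splits the input into orthogonal polarisation components, modulates them
with retardances $\lambda_0$ and $2\lambda_0$, and detects both outputs of
both stages; its channel quartet yields the $(\cos\Lambda\nu,
\cos 2\Lambda\nu)$ pair and is lossless in principle. The *mosaic-camera*
layout passes polarised light through two identical retarders (axes at
45° and 0°) onto a division-of-focal-plane sensor whose 2×2 pixel mosaic
analyses at 0°, 45°, 90°, 135°; the channel ratios

$$V_1 = \frac{I_0 - I_{90}}{I_0 + I_{90}}, \qquad
  V_2 = \frac{I_{45} - I_{135}}{I_{45} + I_{135}}$$

realise the $(\cos\Lambda\nu, \sin^2\Lambda\nu)$ pair. For monochromatic
input these coordinates satisfy $V_2 = 1 - V_1^2$ identically, so the
instrument response to a swept narrowband source traces a parabola — the
"rainbow response curve" used for calibration, implemented by
`theoretical_irf()` and `measure_irf()` and inverted for the retardance by
`fit_retardance()`.

The closed-form channel models (`polarsens_channels()`,
`four_detector_channels()`) are verified against an independent
Jones-calculus oracle (`jones_oracle_channels()`) that propagates the field
through explicit complex 2×2 matrices wavelength by wavelength; the two
routes agree to better than $10^{-10}$ relative error on random spectra.

## Conventions and numerics

**Frequency-domain quadrature.** Spectra are sampled on a wavelength grid
(that is what instruments provide) but every modulation integral is
evaluated in optical frequency, using the reduced frequency
$u = \nu/c = 1/\lambda$ (nm$^{-1}$): the speed of light cancels in every
normalised quantity and the retarder phase is simply
$\delta = 2\pi\lambda_0 u$. The Jacobian $I_u = I_\lambda \lambda^2$ is
applied and integrals are trapezoidal on the (non-uniform) $u$ samples.
Because pointwise channel kernels sum to unity, conservation identities
($I_0 + I_{90} = I_{45} + I_{135} = \int I_i\,d\nu$) hold to round-off in
this quadrature, and the pipeline identity — channel ratios of a rendered
scene equal `compute_smv()` of the pixel spectrum — is exact by
construction. Trapezoidal quadrature of spectra that vanish at the band
edges is extremely accurate here (Euler–Maclaurin boundary terms vanish);
for a 3 nm-FWHM line the residual departure of the measured curve from the
ideal parabola is dominated by the *physical* line width,
$\approx (\Lambda\sigma_u)^2 \le 1.7\times10^{-4}$ at the 450 nm edge, not
by quadrature.

**Key parameters.**

| parameter | default | units | role |
|---|---|---|---|
| `retardance_nm` | 335 | nm | base retardance $\lambda_0$; 335 nm = half-wave at 670 nm, matching off-the-shelf half-wave plates for that design wavelength. Higher retardance: finer spectral resolution, shorter unambiguous range. |
| grid | 450–650 at 0.5 | nm | visible band of the calibration sweep; fine enough to resolve 3 nm lines |
| `extinction_ratio` | `Inf` | — | analyser contrast; finite scalar mixes crossed channels at the sensor, a `function(lambda)` models roll-off inside the channel integrals (real mosaic sensors degrade toward long wavelengths) |
| `mosaic_layout` | `[[90,45],[135,0]]` | deg | 2×2 superpixel assignment; the four angles are fixed physics, their geometric arrangement is a camera convention |
| `min_frac` | 1e-3 | — | SMV validity threshold as a fraction of the image maximum; the SMV is undefined at zero power, so low-signal pixels are masked, never clamped, and 0/0 never propagates |
| `photon_scale`, `read_noise_sd` | 1, 0 | counts | sensor model: Poisson shot noise on expected counts plus Gaussian read noise, fully seeded |

**Demosaicking** is exact superpixel extraction (half resolution): each
channel is taken from its own site, keeping the quartet algebra
bit-faithful and `remosaic(demosaic(x))` an identity. Interpolating
demosaics are deliberately not applied — they would be lossy and break the
channel contracts the tests rely on.

**Retardance fitting** minimises the squared residual of
$V_1(\lambda) = \cos(2\pi\lambda_0/\lambda)$ with a dense 0.25 nm grid
search (the cosine makes the objective multimodal) followed by
golden-section refinement; attainable precision is limited by
`optimize()` to $\sim\sqrt{\varepsilon}$, i.e. $\sim10^{-6}$ nm on ideal
curves — far below the 0.1 nm the calibration claims need.

**Orthogonality** of a modulation family is exact only over an integer
number of base periods $1/\lambda_0$ in reduced frequency. Over an
instrument band like 450–650 nm it is approximate, so
`check_orthogonality()` *reports* the Gram matrix (warning on
non-integer-period windows) rather than asserting zeros.

**The response-curve apex.** With $\lambda_0 = 335$ nm the zero crossing of
$V_1$ sits at $\lambda_0/0.75 = 446.7$ nm, marginally below the 450 nm edge
of the calibration sweep; the acceptance script locates it by root-finding
the forward-modelled $V_1(\lambda)$ over a slightly padded sweep and
evaluates $V_2 = 1$ there.

## Synthetic scenes: what they emulate, what they do not

`make_two_fluorophore_scene()` emulates a fluorescence field of view with
two populations of blob-like emitters over a dim uniform background (such
as mounting-medium autofluorescence). No reference emission spectra are
prescribed for such samples, so the defaults are stand-ins chosen once:
Gaussian emitters at 545/18 nm and 605/20 nm — a realistic ~60 nm peak
separation with strong overlap — and a broad 500/45 nm background at 5% of
the blob photon budget (10^4 photons/pixel by default, a typical widefield
CMOS exposure). `make_absorption_scene()` emulates a stained section in
transmission: flat illuminant, Beer–Lambert attenuation by three synthetic
chromophores (absorbance peaks 460/530/600 nm, OD 0.4–1.2) over blob
regions, and an unstained strip as white-balance reference.

Both generators are pure functions of their seed (the RNG state of the
caller is saved and restored), and ground truth (labels, abundances or OD
maps) rides along for evaluation.

They deliberately *omit*: microscope PSF blur, fluorophore photophysics
(bleaching, saturation), retarder dispersion ($\delta n(\lambda)$ is taken
constant, as the cosine channel models assume), off-normal incidence,
dark-current drift, and sub-image registration or flat-fielding of a real
mosaic sensor. Passing tests therefore demonstrate correctness of the
modulation algebra, the noise propagation, and the analysis chain — not
robustness to those instrument effects; the wavelength-dependent
extinction-ratio hook is the one realism knob exposed for the observed
band-edge departures of real response curves.

## Analysis-chain choices

**Gating** is polygonal with closed boundaries (a point on an edge belongs
to the gate) and priority-resolved overlaps; real masks are free-drawn, and
polygons are their faithful digital form. `nearest_reference_gates()`
constructs the Voronoi cells of supplied reference points (clipped to the
SMV bounding box), turning reference SMVs into an exhaustive gate set —
this is geometry around *given* references, not automated cluster finding,
which is out of scope.

**Unmixing** solves $\sum_k f_k R_k = V$, $\sum_k f_k = 1$ exactly for
$K = N+1$ references (per-pixel linear solve, vectorised), and as an
equality-constrained least-squares (KKT) problem for $K < N+1$. Negative
fractions — noise or points outside the reference simplex — are clipped and
renormalised by default; a simplex-constrained NNLS variant is available
and labelled slower. Degenerate reference sets are rejected naming the
offending references.

**Pseudocolour synthesis** divides each component's intensity contribution
by its mean over a white-reference region and jointly rescales to [0, 1];
reference pixels come out grey, pure components as pure primaries. The
exact balancing recipe of the hardware workflow is not public; division by
white-region channel means is this package's own documented convention (a
faithful-intent stand-in), and the CLI defaults to balancing over all valid
pixels.

**Serialisation.** Rasters travel as 32-bit float TIFF, which is defined on
[0, 1]: arrays are stored divided by a sidecar-recorded `intensity_scale`
(SMV components additionally half-shifted), so round trips are
single-precision (~10^-9 relative), not bit-identical. All metadata — grid,
seed, layout, noise — lives in JSON sidecars because TIFF tags are
dialect-prone; curves are CSV.

## Problem sizes

The test suite and the acceptance script run, by choice, at sizes where
every behaviour is already fully expressed: 16–48 px scenes for algebraic
identities, 128×128 at 10^4 photons/pixel for the end-to-end
classification study (three clusters, positive silhouette, ≥95% gating
agreement against ground truth), 50-point sweeps for noisy retardance
recovery, 100 random spectra/states for the oracle and efficiency
properties, and 1000 random simplex draws for the unmixing round trip.

## Known limitations

* The cosine channel models neglect retarder dispersion; real stages
  deviate at band edges, and the model attributes any such deviation to the
  extinction-ratio hook only.
* Wavelength inversion of the response curve is single-valued only within a
  monotonic sub-band (range/resolution trade-off of the retardance); no
  phase unwrapping is attempted.
* SMV-space mixing is linear for *emission*; for absorbing samples
  (Beer–Lambert is multiplicative) unmixing onto transmitted-spectrum
  references is an approximation that degrades with optical density.
* The uncooled-sensor thermal behaviour, ADC quantisation and vendor raw
  formats are not modelled.
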