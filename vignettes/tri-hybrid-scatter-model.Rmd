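---
title: "The tri-hybrid patient-scatter model: methods, sampling and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The tri-hybrid patient-scatter model: methods, sampling and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

On-treatment EPID (electronic portal imaging device) images are formed by
the primary transmitted beam plus photons scattered inside the patient.  If
the patient-generated scatter fluence entering the imager can be predicted
quickly and accurately, it can be removed from the image and the remaining
primary signal used for in vivo dose reconstruction.  Full Monte Carlo
transport predicts this scatter essentially exactly but takes hours per
field; `epidscatter` implements a tri-hybrid (TH) estimator that splits the
scatter into three physically distinct components and treats each with the
cheapest method that is accurate for it:

* **singly scattered photons** (one Compton interaction): a deterministic
  analytic integration (ANA) over in-field voxels, energy bins and pixels;
* **multiply scattered photons** (two or more interactions): a hybrid (HB)
  scheme — a Monte Carlo run with only thousands of histories extracts the
  phase space of every interaction vertex whose outgoing photon has scatter
  order two or more, and a next-event-style analytic projection carries
  each vertex to every pixel;
* **electron-interaction-generated (EIG) photons** (positron annihilation
  following pair production, optionally bremsstrahlung): precomputed
  pencil-beam scatter kernels (PBSK) indexed by water-equivalent thickness
  and air gap, superposed over the incident fluence.

All images are *normalized energy fluence* (NEF): energy fluence entering
the imager divided by the incident energy fluence entering the patient on
the central axis.  Everything is validated against an in-package analog
photon Monte Carlo that tags each plane crossing by scatter category — the
same role a tagging full-MC tool plays for the published method.

## Shared physics

Compton scattering is modeled on free electrons with the Klein–Nishina
differential cross section

$$\frac{d\sigma}{d\Omega} = \frac{r_e^2}{2}\left(\frac{E'}{E}\right)^2
\left(\frac{E'}{E} + \frac{E}{E'} - \sin^2\theta\right),
\qquad E' = \frac{E}{1 + (E/m_ec^2)(1-\cos\theta)},$$

with the closed-form total cross section used wherever a normalization is
needed.  Mass attenuation tables for water, air, lung, soft tissue and
cortical bone live on a 30-point log grid over 0.05–20 MeV, partitioned
into Compton, photoelectric and pair-production coefficients, and are
interpolated log-log.  The Compton column is *computed* from the
Klein–Nishina total cross section times each material's electron density,
so the analytic estimators and the Monte Carlo engine share identical
Compton physics by construction; the photoelectric and pair columns are
compact smooth parametrizations with magnitudes representative of tissue
and bone at megavoltage energies.  Coherent (Rayleigh) scattering, Doppler
broadening and binding corrections are excluded — negligible at MV
energies for this application.  Because the same tables drive both the TH
estimators and the oracle, comparisons between them are meaningful even
though absolute cross-section fidelity to any external library is not
claimed.

The two fixture spectra are parametric stand-ins for 6 and 18 MV linac
spectra: a gamma-type fluence density $E^2 e^{-2E/E_{mode}}$ with mode at
one third of the nominal energy and support from 0.25 MeV to the nominal
energy, binned natively at 0.25 MeV.  Representative bin energies are
fluence-weighted in-bin means, which makes rebinning (0.25 → 0.5 → 1 MeV)
preserve the spectrum mean energy exactly; the binning study then isolates
the nonlinearity of the scatter response across a bin, not a drift of the
mean.

## Geometry and fixtures

The coordinate system is right-handed with the point source at the origin
and the central axis $+z$ toward the imager; SSD 90 cm, SID 140 cm, field
sizes defined at the 100 cm isocenter plane, and a scoring plane exactly
tiled by square pixels.  Voxel ownership is half-open and rays running
exactly along voxel faces are nudged $10^{-10}$ cm into the grid interior
before traversal, which removes the classic degenerate case of exact
Siddon traversal deterministically.

Three procedural phantom classes stand in for the published test set: a
homogeneous water slab (20 or 40 cm thick), a pelvis-like fixture
(elliptical soft-tissue body with circular cortical-bone inserts in air)
and a thorax-like fixture (body, two elliptical lungs, spine and sternum).
They match the material/density inventory of realistic CT phantoms — air
0.0012, lung 0.26, soft tissue 1.0, cortical bone 1.85 g/cm³ — while being
fully deterministic and parameterized in code.  Only the heterogeneity
class matters for the sampling questions studied here; no claim is made
about anatomical realism.

## The estimators

**ANA.**  For every voxel whose center lies inside the divergent field
pyramid (closed boundary — a voxel whose center falls just outside the
beam edge is excluded, exactly the partial-volume behavior the voxel-size
study probes), each energy bin $b$ and pixel $p$:

$$\Delta\Psi = \frac{w_b e^{-\tau_{in}}}{4\pi d_{sv}^2}\,
\rho_e V \frac{d\sigma}{d\Omega}(E_b, \theta_{vp})\,
\frac{\cos\alpha}{d_{vp}^2}\, E'\, e^{-\tau_{out}},$$

summed over voxels and bins and divided by the incident energy fluence
$\sum_b w_b E_b / (4\pi\,\mathrm{SSD}^2)$.  Both attenuation factors are
evaluated along rays to the *voxel center* (entrance-vs-center is an
undefined choice in the published description; the difference vanishes
under refinement).  The interaction strength uses the thin-scatter kernel
$\rho_e V\, d\sigma/d\Omega$ rather than $\mu_c \Delta l$ along the ray,
matching the straight-line single-scatter picture.  The pixel solid angle
is approximated by $A_{pix}\cos\alpha/d^2$, accurate to $<10^{-4}$ at the
50+ cm voxel-to-pixel distances that occur here.

**HB.**  The phase-space stage records, at every Compton vertex of a
non-EIG photon with incoming order ≥ 1, the pre-collision position,
direction, energy and weight, plus the outgoing order.  Vertices of
incoming order 0 are deliberately *not* recorded — their outgoing photons
are single scatter and owned by ANA; this is the bridge that prevents
double counting.  The projection stage applies the standard next-event
estimator conditioned on the Compton channel:

$$\Delta\Psi = w\,\frac{d\sigma/d\Omega(E,\theta)}{\sigma_{KN}(E)}\,
\frac{\cos\alpha}{d^2}\, E'\, e^{-\tau(E')},$$

normalized per history and by the incident fluence.  The division is by
the total Klein–Nishina cross section (not total attenuation) because the
record exists conditionally on the vertex being a Compton scatter.  The
site-to-pixel attenuation is evaluated at the scattered energy toward that
specific pixel, not at the MC-sampled outgoing energy.  Summed over all
recorded orders, this estimates exactly the oracle's multiple-scatter
category, because every multiple-scatter plane crossing is the unscattered
continuation of its final vertex.

**PBSK.**  Kernels are generated by running the same MC engine with a
parallel pencil beam on water slabs and scoring only EIG-tagged crossings,
normalized per unit incident pencil energy and radially averaged (the
generation geometry is cylindrically symmetric, so averaging suppresses
noise without bias).  The annihilation halo is broad — isotropic 0.511 MeV
photons from depth spread over tens of centimeters — so kernels default to
a 70 cm lateral extent; truncating at 20 cm loses roughly two thirds of
the kernel integral.  The library is indexed by (water-equivalent
thickness, air gap) and interpolated bilinearly; the default nodes
{5, 10, 20, 30, 40} × {10, 20, 30, 40, 50} cm bracket all fixtures.  The
superposition samples the incident field into divergent pencils on a
0.5 cm lattice at the phantom entrance, looks up each pencil's kernel by
its own ray-traced thickness and gap, and deposits the kernel at the
pencil's projected plane position without tilt correction (the EIG fluence
is strongly forward-directed, so tilt is a second-order effect).  For
heterogeneous phantoms a `coverage = "clamp"` policy optionally clamps
queries to the node hull: grazing rays with centimeter-scale thickness
produce negligible EIG fluence, and refusing them (the default) would
otherwise make whole-field runs impossible.

**EIG physics scope.**  By default EIG means positron-annihilation photons
only (pair production terminates the photon, deposits $E - 2m_ec^2$
locally, and emits two 0.511 MeV photons back-to-back isotropically with a
sticky EIG tag).  Bremsstrahlung requires electron transport, which is out
of scope; since kernels and oracle share the same engine and the same
setting, TH-vs-oracle comparisons remain self-consistent.

## The Monte Carlo oracle

Analog transport on the voxel grid: free paths by accumulating optical
depth along the exact traversal, interaction channel by the partial
attenuation coefficients, Klein–Nishina angles by Kahn's
composition-rejection method (validated against quadrature moments in the
test suite), photoelectric absorption, pair production as above, and a
0.05 MeV photon cutoff (booked as local absorption; chosen below any
EPID-relevant fluence contribution).  Outside the grid is vacuum for both
the oracle and the estimators, so air-gap attenuation cancels identically
in comparisons.  Every plane crossing is tallied by category — order 0
primary, 1 single, ≥ 2 multiple, EIG flag overriding — into energy and
number fluence images; per-pixel mean energy is their ratio.  Statistical
uncertainty comes from 25 batches.  Per-history energy conservation
(plane + absorbed + escaped = initial) is verified to better than
$10^{-9}$ relative in the tests.

The RNG is xoshiro256++ with a splitmix64-derived stream per history
index, so any run is bit-exact reproducible from (seed, history index)
regardless of scheduling, and all stochastic entry points refuse to run
without an explicit seed.

Source photons are emitted uniformly per solid angle within the field
pyramid (by rejection on the aperture rectangle) and tallies are weighted
by $\Omega/4\pi$, putting the oracle on the same per-isotropic-source-
photon normalization as the analytic estimators; the solid angle cancels
in the NEF ratio.

## Sampling parameters and defaults

| Parameter | Default | Why |
|---|---|---|
| ANA voxel size | 0.5 cm below 10×10 cm² fields, 1 cm at/above | beam-edge partial-volume error scales with voxel size relative to field size |
| energy bin size | 1 MeV | sub-2% effect once representatives are fluence-weighted |
| MCHHB (HB histories) | 20 000 | the component stays inside its 5% budget; more histories buy precision slowly |
| scatter-order range | [2, ∞) | truncation saves almost nothing (high orders are rare) |
| PBSK lattice | 0.5 cm | EIG is small and smooth; finer sampling is wasted |
| photon cutoff | 0.05 MeV | below any EPID-relevant contribution |
| kernel extent | 70 cm | the annihilation halo converges slowly with lateral extent |

The error budget motivating the component tolerances assumes scatter is
70% single, 20% multiple, 10% EIG; allocating a 1% share of total-scatter
error to each gives per-component tolerances 1.4%, 5% and 10% and a
quadrature total near 1.7%.

## Validation design and problem sizes

The package's validation study is a scaled-down, self-consistent version
of the published one: the 20-cm water slab, the 6 MV-like spectrum, a
10×10 cm² field, and a reduced 21×21 plane of 2-cm pixels, with the
in-package oracle in the gold-standard role.  The acceptance script runs
the oracle with 2×10⁸ histories (per-pixel relative sigma on total scatter
about 0.5% median), the tri-hybrid at the recommended settings, the ANA
voxel study against an internal 0.25-cm reference, and the energy-bin
study at 0.5-cm voxels; the test suite uses 10⁸ oracle histories for the
same comparisons.  At desk scale an analog oracle cannot reach 0.3%
per-pixel sigma in reasonable time; the residual oracle noise contributes
under 0.03% to the mean percent difference (it averages down over 441
pixels) and is the dominant share of the percent-difference standard
deviation, i.e. it makes the precision comparison strictly harder, never
easier.  Percent-difference images use the oracle's total-scatter pixel
value as denominator so that component errors are commensurate with the
error budget; pixels whose oracle noise exceeds a stated threshold are
excluded and counted.  For the purely deterministic ANA studies the
fine-sampling single-scatter image itself is the denominator — a
conservative choice, since single scatter is only ~70% of the total the
published numbers are expressed against.

What passing these comparisons shows — and what it does not: the fixtures
exercise divergent-beam geometry, polyenergetic spectra, heterogeneity
classes and the full estimator chain, but they are not real CT anatomy,
the spectra are parametric stand-ins, and the cross sections are the
package's own tables.  Agreement with the in-package oracle demonstrates
the internal consistency and sampling behavior of the method, not absolute
agreement with EGSnrc or with measurements.

## Numerical choices and degenerate inputs

Zero-length chords (< 10⁻¹² cm) are dropped; segments missing the grid
return empty paths; a field so small or displaced that no voxel center
falls inside it raises a `degenerate-field` error rather than returning
silence; rebinning to a size finer than the native grid, energies outside
the 0.05–20 MeV tables, kernel queries outside the node hull, and
phase-space records paired with a different phantom (checksum mismatch)
all fail loudly.  Cross-section lookups inside the compute kernels go
through a dense 8192-point cache of the log-log tables (relative error
about 10⁻⁶ against direct interpolation), shared by every estimator and
the oracle.

## Known limitations

No electron condensed-history transport (hence no bremsstrahlung EIG by
default), no coherent scattering, no EPID detector response or dose
conversion, no DICOM import, isotropic voxels only, and centered
rectangular fields only.  Published absolute CPU-time columns are not
reproduction targets; efficiency comparisons are made with locally
measured times.  At desk-scale oracle statistics the efficiency optimum
over MCHHB is dominated by oracle noise rather than HB noise, so the
location of the published optimum (20 K) is reported rather than asserted.
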