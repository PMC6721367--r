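---
title: "Coupled optical-thermal dosimetry for transcranial near-infrared stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled optical-thermal dosimetry for transcranial near-infrared stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnirsim)
```

## The problem

Transcranial near-infrared stimulation (tNIRS) delivers red or
near-infrared light through the scalp in the hope of modulating cortical
activity. Two candidate mechanisms have to be disentangled before the
technique can be dosed rationally:

* **photothermal effects** — light absorbed by water, lipid and
  hemoglobin heats tissue, and even sub-degree temperature changes can
  alter neural excitability;
* **photobiomodulation** — photons absorbed by cytochrome c oxidase
  (CCO), Complex IV of the mitochondrial respiratory chain, may modulate
  ATP synthesis without meaningful heating.

`tnirsim` quantifies both pathways on a synthetic layered head: it
resolves how much light of a given wavelength survives the extracranial
layers, which chromophore absorbs it in the brain, and how much steady
heating the absorbed power produces.

## Model

### Photon transport

Light propagation in strongly scattering tissue is modeled by the P1
(diffusion) approximation to the radiative transfer equation. At steady
state the fluence rate $\phi$ (W/m$^2$) obeys

$$-\nabla \cdot D(\mathbf r)\nabla\phi + \mu_a(\mathbf r)\,\phi = Q_0(\mathbf r),
\qquad D = \frac{1}{3(\mu_a + \mu_s')},$$

with $\mu_a$ the absorption coefficient (1/m), $\mu_s' = \mu_s(1-g)$ the
reduced scattering coefficient, and $g = 0.89$ the anisotropy factor
assumed for every layer. The asymptotic decay rate of $\phi$ with depth
is the effective attenuation coefficient
$\mu_{\mathrm{eff}} = \sqrt{\mu_a/D}$.

The air-tissue surface carries the standard partial-current (Robin)
closure $\phi + 2AD\,\partial\phi/\partial n = 0$ with $A = 1$: the
boundary is treated as index matched because surface reflection is
deliberately excluded from the model. A mismatched boundary
($A \approx 3$ for tissue-like indices) would retain two to three times
more fluence; this is a known, deliberate source of conservatism in the
penetration numbers below.

The collimated beam is replaced by an isotropic source buried one
transport mean free path $1/\mu_s'$ below the entry point — the standard
diffusion-theory regularization of a surface beam.

### Chromophore decomposition

A tissue's absorption coefficient is the sum of its chromophores'
contributions. The package ships per-chromophore absorption tables for
gray and white matter at 630, 700 and 810 nm covering water, lipid
("fat"), oxy- and deoxyhemoglobin and the oxidized and reduced states of
CCO, together with the lumped ("whole tissue") values; the gray-matter
chromophore columns sum to the whole-tissue values exactly, the
white-matter columns to within 0.05 1/m of rounding. Generic composition
rules (`chromophore_contribution()`) are exposed for user-supplied
spectra: volume fraction for water, dry-weight mass fraction times
density for lipid, blood volume fraction at a mixed arterio-venous
oxygen saturation for hemoglobin, and millimolar concentration for CCO.

Single-chromophore transport runs (`per_chromophore_run()`) replace the
brain-layer $\mu_a$ with one chromophore's contribution while keeping
every layer's scattering — scattering is a property of tissue
microstructure and does not change with the absorber under study — and
keeping the full extracranial optics, so the attenuation attributable to
each absorber can be ranked.

### Bioheat transfer

Absorbed optical power $Q_r = \mu_a\phi$ (W/m$^3$) enters the Pennes
bioheat equation

$$\rho c\,\frac{\partial T}{\partial t} = K\nabla^2 T +
\rho_b \omega_b c_b\,(T_a - T) + Q_{\mathrm{met}} + Q_r,$$

with conduction $K$, blood perfusion acting as a distributed sink toward
the arterial temperature $T_a = 37\,^\circ$C, and metabolic heat
$Q_{\mathrm{met}}$. The scalp surface loses heat by convection,
$-K\,\partial T/\partial n = h\,(T - T_{\mathrm{amb}})$ with
$h = 4$ W/m$^2\cdot{}^\circ$C against 25 $^\circ$C air; the lateral and
deep boundaries are insulated (the deep tissue then settles at the
perfusion-metabolic equilibrium
$T_a + Q_{\mathrm{met}}/(\rho_b\omega_b c_b) = 37.0345\,^\circ$C for the
brain parameters, a closed form the tests use as an oracle).

Two conventions matter and are worth making explicit:

* **What counts as the heat source.** The default coupled pipeline
  applies the optical load in the brain layers (gray and white matter):
  the protocol under study asks what the light that *reaches the brain*
  does to brain temperature. `heat_source()` will happily build the
  full-domain load (`tissues = NULL`); with the default 0.5 W source the
  full load predicts several degrees of scalp heating at the entry
  point — a continuous-wave point source of that power parked on skin is
  simply not thermally benign, and reporting sub-0.1-degree scalp rises
  for it would require a much weaker source.
* **What "temperature rise" means.** The rise is measured against the
  *no-source steady state* (a second solve with $Q_r = 0$), not against
  a flat 37 $^\circ$C. Convective cooling pulls the scalp surface to
  about 36 $^\circ$C even in the dark, so differences against 37 would
  conflate the light's effect with the boundary condition's.

### Monte Carlo oracle

An independent voxel Monte Carlo transport model (Rcpp) cross-checks the
diffusion solver: weighted photon packets with implicit capture,
Henyey-Greenstein scattering at the same $g$ (with
$\mu_s = \mu_s'/(1-g)$), Russian roulette below weight $10^{-4}$ with
survival probability 0.1, and an absorbed-energy fluence tally
$\phi = E_{\mathrm{dep}}/(\mu_a V)$. The generator is a seeded
xoshiro256++ stream, so identical seeds give bit-identical results
independent of R's RNG state. Voxel traversal tracks indices
incrementally (DDA): the walked index advances by exactly one per face
crossing, which guarantees progress even when floating-point rounding
parks a packet on a voxel face.

In homogeneous gray matter at 810 nm the Monte Carlo fluence around an
interior point source sits 3-10% below the diffusion Green's function
$P e^{-\mu_{\mathrm{eff}} r}/(4\pi D r)$ over one to five transport mean
free paths — the expected P1 overprediction at $\mu_a/\mu_s' \approx
0.08$ — and converges toward it farther out. In the layered head with
the *tabulated* CSF scattering ($\mu_s' = 250$ 1/m, transport mean free
path 4 mm against a 7 mm layer) the two solvers agree in the CSF layer
to about 1%; the diffusion approximation only breaks down there once the
CSF is made genuinely low-scattering (reducing $\mu_s'$ tenfold drives
the discrepancy to ~50%, a sensitivity the test suite exercises). Real
CSF is closer to the second case than the first, so layered-head fluence
beneath the CSF should be read as approximate.

## The synthetic phantom

The anatomical head is replaced by a four-layer stack — combined
scalp+skull, CSF, gray matter, white matter — on structured grids
(1D slab, axisymmetric $(r,z)$, or 3D voxels; the axisymmetric grid is
the workhorse since a point source on a layered half-space is an
axisymmetric problem). Default thicknesses are 13, 7 and 4 mm with white
matter filling the remainder, placing the gray-matter interface 20 mm
below the surface; they are stated assumptions (consistent with light
having to cross more than 20 mm of extracranial tissue), configurable
throughout. What the phantom does **not** emulate: surface curvature,
gyral folding, anatomical thickness variation around the stimulation
site, and tetrahedral-mesh discretization — so passing tests bound the
physics on an idealized geometry, not on any individual head.

## Numerical choices

* Finite volumes, cell-centered, harmonic-mean face conductances: the
  scheme is locally conservative (absorbed + escaped = injected to
  solver precision, an invariant the tests assert at $10^{-8}$) and an
  M-matrix, so fluence and temperature rises are non-negative without
  clipping.
* The regularized source is spread with a fixed-width Gaussian kernel
  ($\sigma$ = 0.5 mm, truncated at $3\sigma$, renormalized on the grid)
  rather than dumped in one cell; a point-in-cell source changes its
  effective geometry with the grid and spoils convergence under
  refinement. The far-field amplitude bias of the smearing is
  $e^{(\mu_{\mathrm{eff}}\sigma)^2/2}$, under 2% for all tissues here.
* Sparse symmetric systems are solved directly (CHOLMOD); the largest
  grids in routine use (~10^5 cells) factor in seconds, and the relative
  residual is verified against $10^{-8}$.
* Transients march with backward Euler (unconditionally stable), one
  factorization reused across steps. Steady results are independent of
  the heat capacities; only transients feel them.
* Cutlines sample cell centers by linear interpolation; values *on* a
  layer interface mix the two media and are therefore excluded from
  grid-convergence comparisons (interior cutline fluence changes by
  under 2% between 0.5 and 0.25 mm spacings).

### Parameter defaults worth knowing

| parameter | default | note |
|---|---|---|
| irradiance | 5000 W/m$^2$ (500 mW/cm$^2$) | through a 1 cm$^2$ aperture: 0.5 W |
| anisotropy $g$ | 0.89 | all layers |
| refractive index | 1.37 | informational; $A = 1$ regardless (no reflection) |
| CSF density | 1007 kg/m$^3$ | tabulated value (0) is impossible; `as_printed = TRUE` restores it |
| brain density | 1040 kg/m$^3$ | tabulated value (0.08) is impossible |
| specific heats | 3391 / 1313 / 4096 / 3630 J/kg$\cdot{}^\circ$C | scalp / skull / CSF / brain; literature values, absent from the source tables |
| blood specific heat | 3600 J/kg$\cdot{}^\circ$C | a 3664 variant circulates; selectable |
| scalp share of the merged layer | 5/13 | thickness-weighted merge of separate scalp and skull rows |
| brain perfusion $\omega_b$ | 0.08 1/s | as tabulated; ~10x typical literature values, but it is what fixes the 37.03 $^\circ$C equilibrium |

## What the default experiment shows

On the default phantom (0.5 mm spacing, 60 mm radius and depth — the
problem sizes used throughout the reported numbers; all solves are
seconds-scale):

* **Penetration.** About 0.2% of the entry-cell fluence survives to the
  gray-matter interface at 810 nm (0.23% on the default grid), ordered
  810 > 700 > 630 nm — the NIR optical window.
* **Heating.** With the brain-layer heat load at 0.5 W, the maximum
  scalp-surface rise is ~0.003 $^\circ$C and the maximum gray-matter
  rise ~0.014 $^\circ$C — far inside the 0.25 and 0.04 $^\circ$C bounds
  quoted for this protocol. The rise at the CSF/gray-matter interface on
  the beam axis is 0.013 $^\circ$C; values near 0.03 $^\circ$C reported
  for anatomical meshes are the same order but a factor ~2.5 above the
  slab-geometry result, a gap consistent with unknown local layer
  thicknesses and the reflectionless boundary (both push this artifact
  low).
* **Volume averages.** White matter averages 37.03 $^\circ$C — the
  perfusion-metabolic equilibrium. Gray matter averages 37.02
  $^\circ$C: the superficial brain sits ~0.02 $^\circ$C *below*
  equilibrium because surface convection penetrates the weakly perfused
  scalp-skull (screening length ~19 mm) and the unperfused CSF. A
  gray-matter average *above* equilibrium (e.g. 37.04) is only possible
  if no surface cooling reaches the brain; with the convective boundary
  in force it cannot occur on this geometry, and we report the cooled
  value.
* **Chromophores.** Ranking attenuation at fixed scattering reproduces
  the absorption tables: at 630 nm deoxyhemoglobin leads, oxidized CCO
  second; at 810 nm oxyhemoglobin leads and the two CCO-adjacent
  absorbers (deoxyhemoglobin, oxidized CCO) are nearly tied in gray
  matter — their simulated order is then decided by their very different
  white-matter contributions. Across all three wavelengths the two CCO
  redox states are major brain-layer absorbers beyond water, lipid and
  hemoglobin, which is the photobiomodulation-relevant observation.

## Limitations

* Idealized slab geometry; no anatomical variation or curvature.
* The diffusion solution inside and beneath a *realistic* (low-
  scattering) CSF layer is unreliable; the shipped CSF parameters are
  diffusive and do not exhibit the failure.
* No melanin or lipofuscin in the scalp layer, no radiative surface
  loss, no thermoregulatory feedback, and no time-resolved optics.
* The index-matched boundary underestimates retained fluence; treat the
  penetration fractions as conservative.
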