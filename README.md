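# tnirsim

Coupled optical–thermal dosimetry for transcranial near-infrared
stimulation (tNIRS) on synthetic layered head phantoms.

tNIRS places a red/near-infrared source on the scalp hoping to modulate
cortical activity, and two questions decide whether a protocol is
sensible: how much light actually reaches the gray matter through the
scalp, skull and cerebrospinal fluid, and whether the absorbed power
heats the tissue enough to matter ("photothermal" effects) or instead
acts through chromophore photochemistry — chiefly cytochrome c oxidase
(CCO), Complex IV of the mitochondrial respiratory chain
("photobiomodulation"). `tnirsim` answers both on a desk-scale model,
for modelers and experimenters who want dosimetry numbers with all
assumptions inspectable.

## What it computes

* **Chromophore-resolved absorption.** Tissue absorption composed as the
  sum of chromophore contributions (water, lipid, oxy-/deoxyhemoglobin,
  oxidized/reduced CCO), with packaged per-tissue tables at 630, 700 and
  810 nm and generic composition rules for user spectra.
* **Steady-state photon diffusion.** The P1 approximation of radiative
  transfer, `-div(D grad phi) + mu_a phi = Q0` with
  `D = 1/(3(mu_a + mu_s'))`, solved by a conservative finite-volume
  scheme on 1D slab, axisymmetric or 3D voxel phantoms with a
  partial-current surface boundary; fluence profiles, penetration
  fractions and per-chromophore attenuation rankings.
* **Pennes bioheat transfer.** `rho c dT/dt = K lap(T) +
  rho_b w_b c_b (T_a - T) + Q_met + Q_r` with the optical heat source
  `Q_r = mu_a phi`, convective scalp cooling, steady and implicit
  transient solvers, and per-tissue temperature-rise summaries against
  the no-source baseline.
* **A voxel Monte Carlo oracle** (Rcpp): weighted photons,
  Henyey–Greenstein scattering, Russian roulette — an independent
  cross-check of the diffusion solver with seeded, bit-reproducible
  results.
* **An experiment pipeline** (`run_experiment()`, plus the
  `inst/scripts/tnirsim` command line) orchestrating multi-wavelength,
  per-chromophore, thermal and MC-comparison runs with CSV/JSON/VTK
  artifacts and embedded provenance.

## Worked example

The default study conditions: a four-layer phantom (combined scalp+skull
13 mm, CSF 7 mm, gray matter 4 mm, white matter below; gray-matter
interface at 20 mm), a 500 mW/cm² source through a 1 cm² aperture
(0.5 W) at 810 nm, tabulated optical/thermal/perfusion parameters.

```r
library(tnirsim)
phantom <- build_phantom(spacing = 5e-4)
phantom
#> <nir_phantom> axisymmetric_2d grid, spacing 0.5 mm, 120 x 120 cells
#>   layer interfaces at 13.0, 20.0, 24.0 mm depth

props <- assign_properties(phantom, 810)
field <- solve_diffusion(phantom, props, source_spec())
field
#> <nir_fluence> 810 nm, axisymmetric_2d grid; injected 0.5 W, absorbed 0.166 W, escaped 0.334 W

round(100 * fluence_fraction_at(field, 0.020), 2)  # % reaching gray matter
#> [1] 0.23

thermal <- assign_thermal(phantom)
Qr <- heat_source(props$mu_a, field,
                  tissues = c("gray_matter", "white_matter"))
temp <- solve_steady_bioheat(phantom, thermal, Qr)
summ <- temperature_rise_summary(temp)
summ$per_tissue
#>         tissue    max_dT_C    mean_dT_C volume_avg_T_C
#> 1  scalp_skull 0.005327483 6.310148e-04       36.45152
#> 2          csf 0.012897165 8.734392e-04       36.83013
#> 3  gray_matter 0.013798940 7.684771e-04       37.01570
#> 4 white_matter 0.005041129 2.202365e-05       37.03441

round(summ$surface_max_dT_C, 4)
#> [1] 0.0026
```

Reading the numbers: about 0.23% of the entry fluence survives the
20 mm to the gray matter at 810 nm (the near-infrared window; 700 and
630 nm give 0.15% and 0.11%), and the light reaching the brain raises
gray matter by at most ~0.014 °C — far below thresholds of
physiological concern — while the white matter rests at the
perfusion–metabolic equilibrium 37.03 °C and the scalp surface sits
near 36.5 °C because of convective cooling to room air. The
temperature *rise* is always reported against a second, no-light solve,
not against a flat 37 °C.

The same run from a shell:

```sh
Rscript inst/scripts/tnirsim thermal --wavelengths 810 --out runs/demo
```

## Layout

* `R/` — chromophore model, phantom generator, finite-volume diffusion
  and bioheat solvers, Monte Carlo wrapper, pipeline and CLI.
* `src/` — the Monte Carlo transport kernel (Rcpp).
* `inst/extdata/` — the tissue parameter tables (CSV).
* `vignettes/tnirs-dosimetry.Rmd` — the model, its assumptions, the
  numerical choices, and known limitations.
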