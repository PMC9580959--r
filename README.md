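# spectralSMLM

Analysis toolbox for multidimensional (x, y, z, t, λ) single-molecule
localization microscopy on a dual-camera spectral setup.

## The problem

Single-molecule localization microscopy (SMLM) and single-particle tracking
(SPT) localize isolated fluorophores to tens of nanometers, but imaging
several molecular species *simultaneously* normally costs photons (dichroic
splitting), time (sequential acquisition) or field of view. A dual-objective
spectral configuration avoids that trade-off: a second detection path
carrying a low-dispersion prism images every molecule a second time,
laterally shifted in proportion to its mean emission wavelength. Pairing the
localizations of the two synchronized cameras measures that shift $d$
(spectral-channel pixels) per molecule and per frame, and the emission
wavelength follows from the linear dispersion law

$$\lambda \;=\; \lambda_0 + \alpha\, d ,$$

with $\lambda_0$ the reference wavelength of the registration fiducial and
$\alpha$ the dispersion coefficient (nm/pixel). The spatial-channel
coordinates are never altered, so multicolor comes at no cost in
localization precision — and when two spectrally distinct emitters overlap
within one PSF on the spatial camera, their two distinct spectral-channel
spots reveal the emitter count and initialize a two-component fit
(*spectrally-informed multi-Gaussian fitting*).

The package implements the full analysis chain for users of such
instruments — and, for method development, a dual-camera simulator with
ground truth:

* wavelet (à-trous B3-spline) spot detection and pixel-integrated
  elliptical-Gaussian fitting, with astigmatism-based z assignment;
* third-order polynomial channel registration (10 coefficients per axis),
  fiducial drift correction, session offset updates;
* dispersion calibration, zone-based localization pairing (exact
  minimum-cost assignment), wavelength assignment and species
  classification;
* spectrally-informed single/double-emitter fitting for overlapping
  molecules;
* trajectory linking (exact assignment, optional simulated annealing), MSD
  curves and per-species diffusion coefficients;
* ground-truth simulation of both cameras with an EMCCD-surrogate noise
  model, plus benchmark drivers reproducing the method's published figures
  of merit.

## Worked example

Calibrate the dispersion from the three emission peaks of multicolor beads,
then run the closed loop: simulate a three-species mixture, localize both
channels, pair, assign wavelengths, classify.

```r
library(spectralSMLM)

peaks <- data.frame(displacement_px = c(0, 9.69, 20.90),
                    wavelength_nm   = c(683, 607, 514))
cal <- calibrate_dispersion(peaks, lambda0_nm = 683)
sprintf("alpha = %.2f +/- %.2f nm/px", cal$alpha_nm_per_px,
        cal$uncertainty_nm_per_px)
#> "alpha = -8.09 +/- 0.13 nm/px"

optics <- optics_model(field_px = 128)
scen <- make_multispecies_scenario(wavelengths = c(605, 655, 705),
                                   n_emitters = 12, n_frames = 5,
                                   field_px = 128, seed = 42)
sim  <- render_dual_stacks(scen, optics, camera_noise_model(), seed = 42)
spat <- localize_stack(sim$spatial,  detection_params(roi_radius_px = 4))
spec <- localize_stack(sim$spectral, detection_params(roi_radius_px = 4))
zone   <- zone_from_wavelengths(optics$dispersion, 585, 725)
paired <- pair_localizations(spat, spec, optics$transform, zone,
                             optics$dispersion)
paired <- classify_species(paired,
  data.frame(label = c("605", "655", "705"),
             lambda_min = c(590, 640, 690),
             lambda_max = c(620, 670, 720)))
table(paired$species)
#>        605        655        705 unassigned
#>          8         16         30          6

localization_error(paired, sim$truth, match_radius_nm = 300)$mean_error_nm
#> 30.8
```

The 60 rendered emitter appearances yield 54 wavelength-classified
localizations (the remainder found no spectral partner in the search zone
or fell between the 30 nm classification windows); within a species the
assigned wavelengths scatter by ~3 nm (sd), far tighter than the 40–50 nm
species spacing, and the matched spatial localizations sit ~30 nm from
ground truth — the photon budget's precision limit, untouched by the
spectral assignment.

Batch processing of file sets is available through YAML-configured commands
(`cmd_simulate`, `cmd_localize`, `cmd_spectral`, `cmd_track`, `cmd_batch`)
or the thin CLI wrapper in `inst/cli/ssmlm.R`; the methods vignette
(`vignettes/spectral-smlm-methods.Rmd`) documents every model, parameter
and design decision.

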