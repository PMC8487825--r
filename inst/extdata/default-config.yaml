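# sonovas default run configuration.
#
# Every key here is a package default, resolvable and overridable from the
# command line. Values marked [published] are carried from the study design
# this pipeline mirrors; everything marked [invented] is a package default
# chosen for clinical plausibility only — do not read invented values as
# published measurements.

phantom:                    # synthetic vessel phantom [invented throughout]
  image_height: 128         # pixels
  image_width: 128          # pixels
  pixel_size: 0.1           # mm/pixel
  wall_depth: 3.0           # mm, near-wall intima depth
  imt: 0.8                  # mm
  lumen_diameter: 6.0       # mm (d2)
  plaques:
    - center_x: 6.4         # mm
      length: 3.0           # mm
      protrusion: 3.0       # mm -> ground-truth stenosis rate 50%
      echo_level: 210
  background_level: 60
  wall_level: 190
  lumen_level: 15

noise:                      # speckle surrogate [invented]
  speckle_shape: 10         # gamma shape k; multiplier mean 1, variance 1/k
  gaussian_sigma: 4         # gray units

nlmeans:                    # denoiser defaults [invented; none published]
  h: 10                     # gray units
  patch_radius: 2           # pixels
  search_radius: 10         # pixels
  sigma_patch: 1.0          # pixels
  self_weight: natural

texture:
  block: 32                 # block side L, pixels [invented]
  ng: 8                     # gray levels [invented]
  d: 1                      # displacement, pixels [invented]
  thetas: [0, 45, 90, 135]  # degrees
  average_thetas: false
  symmetric: false

cohort:
  n_per_group: 30           # [published: 30 subjects per group]
  # Distributional preset: demographics and the grade >= I / >= II
  # prevalence masses (A/B/C) are [published]; per-segment IMT, plaque
  # probabilities, diameters, PSV/RI/PI and the II/III/IV split are
  # [invented]. See ?default_cohort_preset; overriding the preset here is
  # possible by mirroring its nested structure under `preset:`.
  preset: default
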