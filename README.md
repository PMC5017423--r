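# pillarbeat

Quantifying cardiomyocyte contractility from micropillar-array microscopy.

Cardiomyocytes cultured on an array of soft, slender PDMS micropillars
(microposts) grip the pillar tops and bend them with every beat. A slender
cylindrical pillar loaded at its tip behaves as a linear cantilever spring,

    k = 3 π E D⁴ / (64 L³),        F = k · d,        d = Xᵢ − X_ref,

where *E* is the Young's modulus of the elastomer, *D* and *L* the pillar
diameter and length, *d* the tip deflection of the pillar top from its
relaxed reference position *X_ref*, and *F* the contraction force. Tracking
the pillar tops in a time-lapse recording therefore turns each pillar into a
calibrated force gauge at the single-cell scale. For a typical 16 μm × 48 μm
PDMS pillar at E = 0.5 MPa, k ≈ 0.04 N/m, so a 3 μm deflection reports
roughly 0.12 μN of contractile force.

`pillarbeat` implements the whole measurement chain for R:

* **mechanics** — `spring_constant()`, `force_from_deflection()`,
  `deflection_from_force()`: closed-form Euler–Bernoulli beam mechanics
  (μm/MPa in, N/m and μN out).
* **simulate** — `make_lattice()`, `twitch_waveform()`, `render_stack()`,
  `default_fixture()`: a synthetic beating-pillar video generator with
  per-frame ground truth, so every downstream stage is testable without a
  microscope.
* **detect** — `detect_pillars()` (blob detection + non-maximum suppression
  + sub-pixel centroids), `accept_manual_seeds()`, `fit_lattice()`.
* **track** — `track_pillars()` (normalized cross-correlation with
  parabolic sub-pixel peak localization), `estimate_reference()`,
  `to_displacement()`, `to_force()`.
* **beat** — `segment_beats()`, `beat_frequency()`, `beat_direction()`,
  `alignment_summary()` (directional resultant R and axial order parameter
  R₂ on doubled angles, the right statistic for back-and-forth beating
  along one axis).
* **stats** — `summarize_group()` (mean ± SEM), `compare_groups()`
  (Student's t, Welch optional), `normalize_drug_response()` (percent
  decrease after e.g. a Ca²⁺ channel blocker).
* **io / pipeline** — multi-page TIFF IO (`read_stack()`/`write_stack()`),
  flat key/value configs (`read_config()`), `run_pipeline()` and a CLI
  (`system.file("cli", "pillarbeat.R", package = "pillarbeat")`) with
  `simulate`, `detect`, `track`, `analyze`, `compare`, `run` and
  `springconst` subcommands.

All functions share one convention: image x grows rightward, y downward,
origin at the centre of the top-left pixel; angles are counterclockwise
from +x in the physical (y-up) frame, so an on-screen upward deflection is
90°.

## Worked example

```r
library(pillarbeat)

# stiffness of the reference pillar geometry
k <- spring_constant(pillar_geometry(16, 48), elastic_material(0.5))
print(k)
#> Pillar spring constant: 0.0436332 N/m

# a synthetic 5x5 array beating at 1 Hz, 3 um amplitude, SNR ~ 10
sim <- default_fixture(noise_sd = 0.06, seed = 1, duration_s = 10)
print(sim$stack)
#> Image stack: 250 frames of 252 x 252 px, 0.5 um/px, 25 fps (10.00 s)

res <- run_pipeline(sim, analysis_config(), out_dir = "demo", seed = 1)
nrow(res$pillars); nrow(res$beats)
#> 25
#> 250
mean(res$beats$amp_um)        # 3.040 um  (true amplitude 3 um)
mean(res$beats$peak_force_un) # 0.1326 uN (3.04 um x 0.0436 N/m)
alignment_summary(res$beats$angle_deg)
#> Alignment of 250 beat vectors: R = 1.000 (circular mean 90.0 deg),
#> axial R2 = 1.000, axis 90.0 deg
beat_frequency(res$beats[res$beats$pillar_id == 1, ], 10)$freq_hz
#> 1
```

The pipeline found all 25 pillars, 10 beats on each, recovered the 3 μm
twitch amplitude to ~1%, the 1 Hz pacing exactly, and reports perfect
axial alignment along the simulated 90° contraction axis. `demo/` now
holds `pillars.csv`, `tracks.csv`, `beats.csv`, `summary.json`, the
effective `config.json` and a `manifest.json` with the config hash and
seed.

Group-level analysis of per-experiment summaries works the same way as in
a drug study:

```r
compare_groups(plain_forces, grooved_forces)   # Student's t, % difference
normalize_drug_response(pre_drug, post_drug)   # percent decrease +/- SEM
```

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/pillarbeat.R", package="pillarbeat"))')
Rscript $CLI springconst --diameter-um 16 --length-um 48 --modulus-mpa 0.5
Rscript $CLI simulate --rows 5 --cols 5 --amp-um 3 --seconds 10 --seed 1 --out stack.tif
Rscript $CLI run --stack stack.tif --out results/
```
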