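# migrascreen

Simulation and analysis toolkit for high-throughput migration screens of
fast immune cells recorded on a multi-lens array video microscope.

Neutrophils — the most abundant white blood cells — migrate autonomously
at tens of µm/min, and changes in that motility are both a diagnostic
signal and a drug target. Measuring it requires time-lapse video at one
frame per 8 s followed by single-cell tracking, which conventional
single-lens microscopes cannot deliver at screening throughput. An array
microscope with 16 lenses at 96-well pitch images 16 wells simultaneously
(or 64 wells of a 384-well plate via four 4.5 mm stage steps per 8 s
interval), making 1000-compound motility screens practical. This package
implements the computational pipeline around such an instrument, with a
synthetic ground-truthed data generator in place of real movies:

* **Optics/bandwidth budget** — Abbe resolution λ/(2·NA),
  magnification/FOV/pixel-size relations, raw and reduced sensor bit
  rates, ping-pong frame-buffer sizing.
* **Acquisition simulator** — Tenengrad sharpness scoring, sharpest-frame
  selection in free-running and triggered autofocus modes, per-well
  focus-position maps, XYZ stage cycle scheduling checked against the
  8 s frame interval.
* **Synthetic data** — persistent-random-walk cell tracks with stable
  per-cell speeds and an inactive fraction, rendered time-lapse stacks
  with defocus blur, and whole compound screens with planted hits.
* **EMD tracking** — per-frame detections as area-weighted point sets,
  exact Earth Mover's Distance (transportation-problem) matching between
  consecutive frames with a 20 µm displacement gate, majority-mass
  flow-to-link rule, and the ≥ 8-frame track filter.
* **Screen analytics** — per-track speed/displacement/confinement
  metrics, per-well summaries, per-round normalization to the stimulated
  fMLP control (control ≡ 1.0), hit calling (> 40% speed reduction,
  20–40% reduction, > 20% enhancement, > 20% activity reduction),
  class 1/2/3 sorting, polar-plot coordinates, round planning.
* **Evaluation** — frame-pair error counting against ground truth and
  the track-correctness statistic
  `100 · (created − erroneous) / (created + untracked)`.

## Worked example

```r
library(migrascreen)

budget_table()
#>              quantity       value   unit
#> 1          resolution 917.0000000     nm
#> 2           fov_width 825.8283772     um
#> 3          fov_height 516.1427358     um
#> 4          pixel_size   0.6451784  um/px
#> 5            raw_rate  13.7300000 Gbit/s
#> 6        reduced_rate   3.3000000 Gbit/s
#> 7    buffer_triggered  28.1250000    MiB
#> 8 buffer_free_running  42.1875000    MiB
```

A 550 nm, NA 0.3 lens resolves 917 nm; the 16-sensor raw stream runs at
13.73 binary Gbit/s and is reduced on the FPGA to a 3.3 Gbit/s 8-bit
grayscale stream buffered in 28.125 MiB of ping-pong memory.

```r
truth <- simulate_prw_tracks(prw_params(n_frames = 30), n_cells = 150,
                             seed = 42)
stack <- render_stack(truth, seed = 42)   # 1280 x 794 px frames
tracking <- track_movie(stack)            # segment + EMD match + link
mets <- tracks_metrics(tracking$tracks)

nrow(mets)
#> [1] 154
mean(mets$mean_speed[mets$migrating])
#> [1] 15.1       # um/min; generator mean was 15
mean(mets$migrating)
#> [1] 0.60       # generator active fraction was 0.7

cs <- correctness_stats(evaluate_frame_pairs(tracking, truth$tracks))
cs$track_correct_pct
#> [1] 99.53
```

The pipeline re-detects and re-links the simulated cells, recovering the
generator's mean speed to within a few percent; the migrating fraction
reads slightly low on a short 4-minute movie because slow active cells
have not yet displaced the 10 µm migration criterion. 99.53% of
frame-to-frame links are correct against the ground truth.

A screen is simulated, analyzed and hit-called the same way:

```r
sim <- simulate_screen(screen_sim_params(n_compounds = 61,
                                         speed_multiplier = c(0.5, rep(1, 60)),
                                         seed = 1))
tab <- screen_pipeline(sim, n_frames = 40, cells_per_well = 200)
subset(tab, strong_inhibitor, c(compound, relative_speed, class))
```

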