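# cytotox3d

Area-based image quantification of immune-cell cytotoxicity in 3D hydrogel
cultures.

## The problem

Cytotoxic lymphocytes (NK cells, T cells) evaluated for cancer
immunotherapy are usually scored in 2D co-culture, where nothing stands
between effector and target. In a 3D assay, target cells are embedded in a
collagen gel and effectors must *infiltrate* before they can kill, so two
questions have to be answered from the same multi-channel fluorescence
images: how deep do effectors get, and how much killing happens where?
This package implements the complete quantification pipeline for such
assays — from raw channel stacks (target, effector, dead-stain such as
propidium iodide) to infiltration profiles, percent-killed statistics, and
single-cell killing kinetics — together with a seeded synthetic-scene
generator with exported ground truth, so the whole pipeline is testable
without microscopy data.

## The method

For each channel, the z-projected image is binarized at the **mean
auto-threshold** (foreground strictly above the mean of all pixel
intensities). Cell numbers are estimated from areas, not instances:

- effector count = foreground area / calibrated mean single-cell area;
- dead targets are rounded and smaller than extended live targets, so dead
  area is converted with the calibrated ratio
  *r* = mean live area / mean dead area, and

  **% killed = 100 · r·A_dead / (A_live + r·A_dead)**

Calibration pools manually measured single-cell areas (reference design:
five raters × 20 cells = 100 cells per type). A 700-µm square ROI at the
gel–media interface is split into seven 100-µm depth bins **R0–R6**;
profiles report every bin, while the pooled statistic uses **R1–R5** only
(the boundary bins sit in meniscus-distorted territory). For time-lapse
data, each kill event's **time for killing** is the interval from first
effector–target contact (mask adjacency) to sustained dead-stain uptake,
and conditions are compared with the classical pooled-variance two-tailed
Student's t-test.

## Worked example

```r
library(cytotox3d)

params <- scene_params(seed = 42)        # 700x700 um, 120 targets (30% dead),
scene  <- generate_scene(params)         # 150 effectors, decay length 150 um
result <- quantify_scene(scene)
result$profile[, c("bin", "effector_count", "percent_killed")]
#>   bin effector_count percent_killed
#> 1  R0          56.43           41.2
#> 2  R1          33.97           21.3
#> 3  R2          20.75           34.4
#> 4  R3          19.93           30.5
#> 5  R4           6.85           13.2
#> 6  R5           6.51           32.4
#> 7  R6           1.16           32.4
result$overall                           # percent killed pooled over R1-R5
#> [1] 26.98   (ground truth for this seed: 27.9)
```

The effector count falls monotonically with depth — the infiltration
gradient the generator was told to produce (exponential, 150-µm decay
length) — and the pooled percent killed recovers the generated 30% dead
fraction to within a few points (per-seed truth here is 27.9%).

Kinetics on a synthetic time-lapse:

```r
sim    <- generate_timelapse(timelapse_params(seed = 42,
            kill_probability_per_contact = 1, n_frames = 30))
events <- extract_kill_events(sim$timelapse)
head(events, 3)
#>   effector_track_id target_track_id contact_time pi_time time_for_killing
#> 1               162               7           90     150               60
#> 2                14               8           40      90               50
#> 3                22              13           60     110               50
mean(events$time_for_killing)            # generator's PI delay mean: 40 min
#> [1] 46.7    (quantized up by ~half a 10-min frame, as expected)

compare_groups(c(1, 2, 3), c(4, 5, 6))
#> Student's t-test (pooled variance, two-tailed): a (n=3, mean 2.00) vs b (n=3, mean 5.00)
#>   t = -3.6742, df = 4, p = 0.02131 *
```

## Command line

A four-subcommand front end is installed under `inst/cli/`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/cytotox3d.R", package="cytotox3d"))') \
    report --config assay.yaml --out results/
```

Subcommands: `simulate` (scene TIFFs + truth CSV), `quantify` (profile /
summary / overall CSVs + mask TIFFs), `kinetics` (event table CSV),
`report` (full pipeline + comparison + report JSON). Configs are YAML; see
`?validate_config` for keys, defaults, and domains. Exit codes: 0 success,
1 user error, 2 internal error.

## Layout

- `R/` — imaging I/O (built-in baseline TIFF reader/writer), segmentation,
  quantification, spatial profiling, kill kinetics, synthetic scenes,
  pipeline/config.
- `src/` — Rcpp kernels: connected components, dilation/erosion, median
  despeckle.
- `vignettes/methods.Rmd` — models, parameter rationale, what the
  synthetic world does and does not emulate, numerical choices, known
  limitations.
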