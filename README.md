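# eggcandler

Machine-vision classification of incubated duck eggs from candling
(transillumination) images, for hatcheries that need to remove
non-viable eggs around embryonic day 12. Each egg photographed in a
dark box is located in the frame, cropped, and classified as
**unfertilized** (pale amber-yellow), **live embryo** (dark red with
black blood vessels), or **abnormal** (dead embryo with dark foci or a
blackened mass, or a yolk-dispersed egg with uniform yellow interior).

The package implements the whole pipeline in R, with no deep-learning
framework dependency:

* **Synthetic candling images** (`render_egg_image()`,
  `generate_dataset()`): seeded, labelled scenes with the structure the
  pipeline cares about — dark-box background, elliptical
  transilluminated egg, class-specific interiors, a wall-reflection
  patch at gray 180–200, shell light leakage at 254–255, Gaussian and
  impulse noise — plus ground-truth egg boxes for testing.
* **Egg localisation** (`preprocess_egg()`): grayscale → median filter
  → Otsu threshold with a manual **+100 offset** → largest 8-connected
  foreground component → **1.1×** bounding-box crop of the original
  colour image → bilinear resize. The Otsu criterion maximizes the
  between-class variance σ²_B(T) = ω₀(T)ω₁(T)[μ₀(T) − μ₁(T)]²; the
  offset lifts the threshold above wall reflections while the bright
  egg stays in the foreground.
* **Residual network with attention** (`build_classifier()`): the
  canonical 34-layer design of basic blocks y = F(x, {Wᵢ}) + W_s x,
  with a channel/spatial attention module inserted in every block —
  CBAM (M_c = σ(MLP(AvgPool F) + MLP(MaxPool F)) then
  M_s = σ(f⁷ˣ⁷[AvgPool; MaxPool])), SE, or coordinate attention —
  forward *and* backward passes hand-built on BLAS matrix operations.
* **Protocol** (`candle_net()`, `evaluate_model()`,
  `compare_attention_variants()`): stratified 6:2:2 split, flips /
  center crop / normalization, mini-batch Adam (batch 16, lr 0.001,
  cross-entropy, 50 epochs by default), per-epoch validation tracking,
  stability statistics (mean accuracy; overall, first-10 and last-10
  epoch variances), confusion matrices and macro precision/recall/F1
  over repeated test rounds.

## Worked example

```r
library(eggcandler)

ds   <- generate_dataset(c(unfertilized = 20, live = 20, abnormal = 20),
                         generator_params(), seed = 42)
prep <- prepare_dataset(ds, preprocess_config(input_size = 96))
prep$audit[1:3, c("class", "T_otsu", "otsu_offset", "T_effective", "x", "y", "w", "h")]
#>          class T_otsu otsu_offset T_effective   x  y   w   h
#> 1 unfertilized     17         100         117 118 76 211 138
#> 2 unfertilized     17         100         117 175 48 238 145
#> 3 unfertilized     18         100         118 213 56 195 164

fit <- candle_net(prep, attention = "cbam",
                  spec   = model_spec(width_factor = 0.25, input_size = 96),
                  config = candle_config(epochs = 5, seed = 1))
fit
#> Candling classifier: ResNet34 + cbam (1,348,145 parameters)
#>   classes: unfertilized, live, abnormal
#>   trained 5 epochs (15 optimizer steps), final val accuracy 0.7500

evaluate_model(fit, prep$x[fit$split$test], prep$y[fit$split$test],
               rounds = 10, seed = 1)
#> <eval_report> accuracy 0.9167 | macro P 0.9333 R 0.9167 F1 0.9153 | 10-round variance 0.004444 (bootstrap)
#> confusion (rows = true):
#>               predicted
#> true           unfertilized live abnormal
#>   unfertilized            4    0        0
#>   live                    0    4        0
#>   abnormal                0    1        3
```

The audit rows show the localisation at work: the adaptive threshold
lands at the top of the dark-box background (T ≈ 17), the +100 offset
lifts it above clutter, and the crop boxes are the 1.1×-scaled
bounding boxes of the selected component. The fit/evaluation lines are
a deliberately small run (60 images, 5 epochs, quarter-width network
at 96×96); `plot(fit)` draws the loss/accuracy curves and
`summary(fit)` adds the stability statistics once at least 20 epochs
have run.

A command-line wrapper with `generate`, `preprocess`, `train`,
`evaluate` and `compare` subcommands is installed at
`inst/cli/eggcandler`; every stage writes PNG/CSV/JSON/YAML artifacts
and any run is reproducible from its saved config snapshot and seed.

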