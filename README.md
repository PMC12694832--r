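# segnet

A biologically constrained model of the primate ventral stream for
attention-conditioned figure-ground segmentation, implemented as an R
package with its own convolutional engine (no deep-learning framework
required).

## The scientific problem

Neurons in early visual cortex respond more strongly to image elements
of a *figure* than to identical elements of the *background*
(figure-ground modulation, FGM), and this enhancement grows when the
figure is attended. Feedback connections from higher areas are thought
to carry these effects, but unlike feedforward connections they are
*modulatory*: they scale the activity of neurons that are already driven
and cannot activate silent ones. `segnet` implements a minimal network
that shows how such modulatory feedback can produce accurate,
attention-selectable object segmentations, and reproduces the temporal
signatures observed in monkey V1: a fast stimulus-driven transient,
delayed figure-ground modulation, and an even later attentional
enhancement.

## The model

* **Feedforward pathway (driving)**: image → V1m (20×56×56) → V2m
  (50×28×28) → V4m (100×14×14) → ITm (500) → FCm (12 classes), with
  three conv–batch-norm–ReLU blocks (3×3, skip connections) per area and
  stride-2 2×2 convolutions between areas. Class scores are independent
  sigmoids (several objects may be present). Attention never touches
  this pathway.
* **Feedback pathway (modulatory)**: a one-hot attention vector gates
  the class scores; a driving head maps the gated vector back to a
  100×7×7 drive (fully connected mirror, transposed convolution,
  concatenation with the feedforward 7×7 tensor into 200×7×7, 1×1
  fusion). Every feedforward unit in V4m/V2m/V1m has a mirrored
  feedback unit obeying

      b = max(0, a * (z + beta)),     c = b - a

  where `a` is the feedforward activity of the same unit, `z` the drive
  from the next-higher feedback layer, and `beta` a learned offset.
  Feedback can scale `a` but never drive a silent unit. A learned 1×1
  read-out of the V1m mirror's feedback signal `c` gives the 56×56
  segmentation map.
* **Training** is two-phase: multi-label classification first (Adam,
  lr 0.001, weight decay 5e-4, sigmoid+BCE), then the feedback pathway
  alone with the feedforward weights frozen, on pixel-wise BCE that
  ignores pure-texture background pixels.
* **Time-stepped simulation**: activity is propagated one connection
  per step from a white-noise initial state with the attention template
  pre-activated, yielding figure/edge/ground time-courses, FGM, and
  space–time profiles.

The package also generates its own SegMNIST-style stimuli: 56×56
oriented-texture backgrounds with 1–3 objects (texture-defined squares
and rectangles, procedural digit glyphs 0–9), multi-hot labels and
pixel-accurate masks. Real MNIST digits can be substituted from local
IDX files; no download is required.

## Worked example

```r
library(segnet)

# a scene with a texture square and a digit on an oriented background
stim <- compose_scene(
  list(figure_spec("square", c(20, 20), c(18, 18), rotation = 30,
                   texture = texture_spec(135)),
       glyph_spec(5, c(40, 40), scale = 1, seed = 7)),
  background = texture_spec(45), seed = 1)
print(stim)
#> <stimulus> 56x56, objects: square, 5

net <- seg_network(seg_config(), seed = 1)   # full-width architecture
ff  <- feedforward_pass(net, stim)
dim(ff$activities$v1.b1)                     # 3136 pixels x 20 features
#> [1] 3136   20
round(range(ff$scores), 3)                   # per-class scores in [0,1]

fb <- feedback_pass(net, ff, attention_vector("square"))
dim(fb$map)                                  # 56x56 segmentation map
#> [1] 56 56
```

Training and simulation at a desk scale (square/rectangle task; a few
minutes on one CPU):

```r
ds  <- generate_dataset(2000, c("square", "rectangle"), seed = 1)
net <- seg_network(seg_config(features = c(4L, 8L, 16L), itm = 32L), seed = 1)
f1  <- train_feedforward(net, ds[1:1800],
         train_config("ff", epochs = 6, batch_size = 32, seed = 1),
         val_stimuli = ds[1801:2000])
f2  <- train_feedback(f1$net, ds[1:1800],
         train_config("fb", epochs = 8, batch_size = 32, seed = 2))
evaluate_segmentation(f2$net, ds[1801:2000])

tr <- run_timecourse(f2$net, ds[1801:1860], attend = "square",
                     schedule_config("area", total_steps = 14), seed = 3)
head(fgm(tr))   # per-step figure-ground modulation
```

The full-width, 12-class replication recipe (50,000 stimuli, 2,500
epochs per phase, batch 1024/256) is what the reference protocol used;
it is far beyond a single-CPU session but can be launched with the same
functions (or the CLI below) by changing the configuration arguments.

A thin command-line interface wraps these functions:

```sh
Rscript inst/cli/segnet.R gen-data --n 2000 --classes square,rectangle --seed 1 --out data/
Rscript inst/cli/segnet.R train-ff --data data/ --out runs/ff --epochs 6 --batch 32 --features 4,8,16 --itm 32
Rscript inst/cli/segnet.R train-fb --data data/ --ff-ckpt runs/ff/ff_checkpoint.rds --out runs/fb --epochs 8 --batch 32
Rscript inst/cli/segnet.R eval     --ckpt runs/fb/full_checkpoint.rds --data data/
Rscript inst/cli/segnet.R simulate --ckpt runs/fb/full_checkpoint.rds --n 60 --attend figure --seed 1 --out runs/sim
```

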