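# uapsim

Universal adversarial perturbations (UAPs) against small image
classifiers, in the cross-domain setting.

## The problem

A UAP is a single perturbation array ρ with a small norm,
‖ρ‖ₚ ≤ ξ (p ∈ {2, ∞}), that causes systematic misclassification when
added to *arbitrary* inputs of a classifier. The threat model this
package studies: the attacker cannot access the classifier's training
domain (the realistic situation for, e.g., medical image models, whose
training data is private), but *can* run the UAP algorithm over images
from a different, public domain. When the victim classifier was built
by transfer learning from that public domain, such out-of-domain UAPs
remain effective — the security hole this package reproduces and
measures at desk scale, entirely on synthetic data.

For a classifier C over K classes and test set X, the package computes:

- fooling rate `Rf = |X|⁻¹ Σ 1[C(x) ≠ C(clip(x+ρ))]` (against clean
  predictions);
- targeted success rate `Rs = |X|⁻¹ Σ 1[C(clip(x+ρ)) = y]` with its
  clean baseline (≈ 1/K on a balanced set);
- row-normalized confusion transition matrices and the dominant class;
- the predicted-label composition of an image pool.

Budgets are expressed as ζ, the ratio of ξ to the mean image norm of
the target training set. Attacks are the classical iterative scheme:
seeded passes over the input set, one fast-gradient-sign step
(strength ε) per not-yet-fooled image, projection onto the Lp ball
after every update; targeted attacks descend the target-class loss and
skip on-target images. Random perturbations sampled on the ξ-sphere
serve as controls.

Everything is implemented in plain R (the CNNs included — im2col
convolutions, analytic backprop — since no deep-learning framework is
assumed), with `Matrix` as the only numerical dependency.

## Worked example

```r
library(uapsim)

spec <- domain_spec()                      # K = 4, 32x32, seeded
data <- generate_target_dataset(spec)      # labelled train/test
pool <- generate_source_pool(              # unlabelled, out-of-domain,
  domain_spec(n_images = 800))             # 2x the training-set size

clf <- train_for_cell(data, pool, "transfer", "small",
                      epochs = 8, batch_size = 32, seed = 1)
clf$test_accuracy
#> [1] 0.995

xi <- zeta_to_xi(0.08, data$train, Inf)    # zeta = 8% -> absolute budget
cfg <- attack_config(p = Inf, xi = xi, i_max = 10, seed = 1)
uap <- generate_uap_nontargeted(clf, pool, cfg, reference = data$train)
uap
#> <perturbation> p=inf xi=0.07942 ||rho||=0.07942 source=source_pool

fooling_rate(clf, data$test, uap)
#> [1] 0.27
fooling_rate(clf, data$test,
             random_uap(image_shape(data$train), xi, Inf, seed = 99))
#> [1] 0.005
```

A perturbation crafted *without any target-domain image* fools 27% of
held-out test images, against 0.5% for a random control of identical
norm: the transfer-learned features make the out-of-domain attack
work. Crafting from the (normally private) training images themselves
raises Rf further (0.425 at the same budget), and targeted variants
drive most test images into a chosen class (`generate_uap_targeted`).

The grid driver reproduces the full contrast table:

```r
cfg <- experiment_config(init_modes = "transfer",
                         targeted_classes = c(0L, 1L), seeds = 1:3)
tab <- run_experiment(cfg)
summarize_experiment(tab)   # means ± sd, Spearman Rf-vs-zeta trends
```

A command-line interface wrapping the same stages (generate-data /
train / attack / evaluate / experiment) is installed at
`inst/cli/uapsim.R`.

## Layout

- `R/synthetic.R` — two-domain texture image generator (the world model
  is documented in `vignettes/uapsim-methods.Rmd`)
- `R/cnn.R`, `R/classifier.R` — the CNN engine; transfer / scratch
  training; prediction and input-gradient contracts
- `R/attack.R` — UAP loops, FGSM step, Lp projection, random controls,
  ζ→ξ conversion, ε sweep
- `R/evaluation.R` — Rf, Rs + baseline, confusion transitions, label
  composition
- `R/pipeline.R` — experiment grid, summaries, trend statistics
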