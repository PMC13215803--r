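# pulvinet

Gated thalamocortical skip connections in convolutional vision models.

The pulvinar — the largest higher-order visual thalamic nucleus — forms
cortico-thalamo-cortical loops that are thought to regulate the *gain* of
cortico-cortical communication and the *criterion* by which weak sensory
evidence becomes a decision, rather than relaying sensory content.
`pulvinet` implements a minimal computational analog of this motif and the
full apparatus needed to measure its consequences, for computational
neuroscientists who want to study gain control, representational stability
and near-threshold decision-making in small, fully controlled vision models.

## The model

A three-block CNN trunk (3x3 conv → ReLU → 2x2 max-pool; widths
3→64→128→256; global average pooling and an affine softmax readout) is
shared by four architectures:

* **cortical** — the feedforward baseline, `h(l) = pool(relu(W_l * h(l-1) + b_l))`.
* **pulvinar** — a long-range pathway from block *m* = 1 to the input of
  block *n* = 3: a projector `r = resample(W_p * h(m) + b_p)` (1x1
  convolution + bilinear down-sampling), a squeeze-and-excitation-style gate
  `g = sigmoid(W_g2 relu(W_g1 gap(r) + b_g1) + b_g2)` in (0,1) per channel,
  and a learned per-channel convex fusion

  `h~(n-1) = (1 - alpha) h(n-1) + alpha (g ⊙ r)`,  `alpha = sigmoid(a)`.

  At `alpha = 0` the model reduces exactly to the cortical baseline.
* **se_control** — within-layer squeeze-and-excitation (`h ⊙ s`) on block 2;
  channel attention without long-range routing.
* **skip_control** — the same projector added with a fixed, non-learned
  scale: `h(n-1) + beta r`.

Representational metrics quantify what the pathway does to the code:
**S** (direction invariance) is the mean pairwise cosine similarity of
pooled features across contrast-scaled copies `sigma x`,
`sigma ∈ {0.2, 0.6, 1.0}`; **HL** (gain linearity) is the mean
`log(max(eps, ΔF/Δsigma))` of the mean feature norm `F(sigma)`.  Composite
losses `CE`, `CE − λ_S S − λ_H HL`, and the full regime with gate/fusion
regularizers `λ_G (mean g − G*)²` and `λ_α mean((alpha − α*)²)` are all
differentiable end to end (hand-derived gradients, finite-difference
verified).

A near-threshold psychophysics simulator (1/f-noise backgrounds with mean
luminance 0.5, circular Weber increments over a 17-level contrast ladder
from 0.005% to 4%), a signal-detection layer (confusion counts, hit/false
alarm rates, d′, criterion c, psychometric curves, (BG, R) grid and quadrant
analyses, z > 1 enrichment), the study's statistics (Welch/Cohen, exact
Wilcoxon signed-rank, Kruskal–Wallis/Dunn), and Hit-minus-Miss layer probes
(V1/V4/PFC analogs) complete the pipeline.

## Worked example

Train both observers on one stimulus condition (high noise, large target)
and compare them with signal-detection metrics:

```r
library(pulvinet)

tc <- train_config(learning_rate = 3e-3, batch_size = 32L,
                   n_epochs = 30L, seed = 11L)
res <- run_experiment2(bg_values = 2.5, r_values = 13L,
                       variants = c("cortical", "pulvinar"), tc = tc,
                       n_per_contrast = 50L, n_eval_per_contrast = 50L,
                       seed = 8L)

for (m in c("cortical", "pulvinar")) {
  sel <- res$predictions[res$predictions$model == m, ]
  sm  <- sdt_metrics(confusion_counts(sel$predicted, sel$label))
  cat(sprintf("%-8s acc %.3f  d' %.2f  c %+.2f  HR %.3f  FA %.3f\n",
              m, sm$accuracy, sm$dprime, sm$criterion, sm$HR, sm$FA))
}
```

```
cortical acc 0.841  d' 2.07  c +0.27  HR 0.779  FA 0.096
pulvinar acc 0.882  d' 2.59  c +0.43  HR 0.807  FA 0.042
```

Both naive observers detect most of the contrast ladder (pooled accuracy
~84–88%), and the pulvinar-augmented observer shows higher sensitivity (d′)
— the regime in which the pathway's contribution is expressed.  A
psychometric curve for one observer:

```r
sel <- res$predictions[res$predictions$model == "pulvinar", ]
head(psychometric_curve(sel), 4)
```

```
  contrast_pct n_present hit_rate
1        0.005        25     0.00
2        0.010        25     0.04
3        0.025        25     0.12
4        0.050        25     0.60
```

(The lowest ladder levels sit at or below threshold; the curve rises through
the lower quartile of the ladder and saturates above ~0.1% contrast, which
is what pools to ~85% accuracy over all 17 levels.)

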