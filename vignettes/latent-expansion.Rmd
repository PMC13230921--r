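---
title: "Latent-space data expansion for small imaging cohorts: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-space data expansion for small imaging cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(latentmix)
```

## The problem

Inherited retinal diseases such as retinitis pigmentosa (RP) are rare, and
single-institution fundus-photograph cohorts rarely exceed a few hundred
images. Deep image classifiers -- for instance, models that try to tell
autosomal from X-linked inheritance on colour fundus photographs -- are
data-starved in this regime. `latentmix` implements a data-expansion strategy
that operates in the latent space of a variational autoencoder (VAE): instead
of synthesising images from nothing, it perturbs or recombines the latent
representations of *real* training images, and decodes the results into new,
provenance-tracked training samples. The package also implements the full
evaluation protocol needed to test whether such expansion helps: patient-
grouped resampling cross-validation, pooled ROC AUC, Fréchet feature
distances, latent-distribution overlap, and age-binned subgroup metrics.

## The codec

The latent space is provided by a compact convolutional VAE trained from
scratch on the training images of each split. The encoder maps an image
$x \in [0,1]^{S\times S\times 3}$ to a posterior $q(z\mid x) =
\mathcal N(\mu(x), \operatorname{diag} e^{\ell(x)})$ over $\mathbb R^d$;
the decoder maps $z$ back to image space. Training minimises the ELBO

$$\mathcal L = \underbrace{\tfrac1{|x|}\lVert x - \hat x\rVert^2}_{\text{pixel-wise MSE}}
 \;+\; \beta \cdot \underbrace{\tfrac12\sum_{i=1}^d\left(\mu_i^2 + e^{\ell_i} - 1 - \ell_i\right)}_{\text{closed-form KL to } \mathcal N(0, I)}$$

with AdamW and a linear learning-rate decay. The log-variance $\ell$ is
clamped to $[-20, 20]$ for numeric safety; in the clamped zero-variance limit
the reparameterised sample $z = \mu + e^{\ell/2}\varepsilon$ collapses to
$\mu$ exactly as the tests require.

The codec is a *plug-in contract* (`encode` / `decode` / `latent_dim`): the
compact VAE is one implementation, the deterministic `linear_codec()` (a
fixed random orthogonal projection) is another used in tests, and a
pretrained backbone could be slotted in without touching the expansion code.
The expansion mathematics is codec-agnostic by design.

Why a compact from-scratch VAE rather than a pretrained autoencoder? The
original workflow this package operationalises used large pretrained
backbones. Those require downloaded weights; here every component is
trainable from scratch so the whole pipeline is self-contained and
reproducible from a seed. The consequence — decoded images are smoother than
their sources, since an MSE-trained small VAE cannot reproduce fine texture —
is discussed under *Limitations*.

## The expansion schemes

**Gen 1 (random-noise perturbation).** For each real training image, one
noise family is drawn uniformly from {constant, Gaussian, uniform,
sinusoidal} and a strength $s \sim U(0.05, 1)$; the perturbed latent mean
$\mu + \eta$ is decoded into exactly one synthetic image. Appending the
output therefore doubles the training pool (a two-fold expansion). The
constant family sets every component to $\pm s$ with one shared seeded sign;
the sinusoidal family uses component $i \mapsto s\sin(2\pi f i/d + \phi)$
with seeded $f \in \{1,\dots,4\}$ and phase $\phi$. These two families are
conventions of this package: the scheme names them but does not define them.

**Gen 2 (pairwise combinatorial mixing).** Within each label class, every
unordered pair $(A, B)$ of training images contributes composite latents
$z = r\,\mu_A + (1-r)\,\mu_B$ for mixing ratios
$r \in \{0.1, 0.3, 0.5, 0.7, 0.9\}$, each decoded into a synthetic image.
Two pair modes are provided: `all_ratios` decodes every ratio
($|R| \cdot C(n,2)$ synthetics per class) and `one_ratio_per_pair` draws one
seeded ratio per pair ($C(n,2)$ per class). Unordered pairs without
self-pairs are used: mixing is symmetric under $(A,B,r) \to (B,A,1-r)$ and
the ratio set is symmetric about $\tfrac12$, so ordered duplicates would be
redundant; self-pairs would reduce to reconstructions. Mixing operates on
the latent mean $\mu$, not on a sampled $z$: synthesis is then a
deterministic function of the codec and the parents, which makes every
synthetic image exactly reproducible from its provenance record.

**DCGAN baseline.** A standard deep convolutional GAN (alternating
binary-cross-entropy updates, non-saturating generator loss) provides the
unconditional-synthesis baseline the latent schemes are compared against.
At paper-parity settings it maps a 100-dimensional latent to 224 px RGB
images; the benchmark uses a smaller configuration.

Every synthetic record carries provenance: scheme, parent record ids, noise
kind and strength or mixing ratio, the constructed latent vector, codec id,
and seed. Synthetics inherit the label of their parent(s); Gen 2 parents are
same-class by construction.

## The evaluation protocol

Patients, never images, are the unit of splitting: both eyes of a patient
always fall on the same side. "Cross-validation by re-sampling" is
implemented as $k$ repeated stratified grouped 80/20 splits rather than a
$k$-way partition — the only reading consistent with both an 80/20 split and
five folds. Per resample the pipeline runs: grouped split → class balancing
by patient-preserving undersampling on the training side → codec training on
the training reals → arm-specific expansion → leakage-guarded attachment →
classifier training → prediction on the real test images. Synthetics whose
parents include a test-side patient raise a hard leakage error; a
property-style test sweeps 100 seeded splits and a hand-constructed
violation.

The codec is retrained per resample on that resample's training reals. The
protocol this mirrors is silent on the point; retraining is the conservative
choice because a codec fitted on all images would leak test-patient
appearance into the training arms through the synthetics.

Pooled AUC concatenates out-of-fold labels and scores across all resamples
and computes one Mann–Whitney AUC (ties counted one half). Confusion-matrix
metrics use threshold 0.5 (unstated in the source protocol; declared here)
and report undefined ratios as missing rather than zero. The positive class
for binary reporting is `x_linked`, declared in every prediction set, since
the protocol never fixes the polarity.

Feature realism is measured with the Fréchet distance between Gaussian fits
of feature distributions. The default feature extractor is a fixed-seed
random convolutional projection: absolute values are **not** comparable to
published FID numbers computed with ImageNet features — only within-run
rankings are meaningful — and a pretrained extractor can be plugged in
behind the same contract. The matrix square root uses the symmetric form
$\operatorname{Tr}\sqrt{S_1^{1/2} S_2 S_1^{1/2}}$ with an eigenvalue floor
at zero and a $10^{-8}$ diagonal jitter on sample covariances.

Latent-distribution overlap operationalises a density comparison that the
source figure shows without defining a statistic: both latent sets are
projected on the first principal axis of the real set and the overlap
coefficient $\sum_i \min(\hat p_i, \hat q_i)$ is computed over 32 shared
histogram bins spanning the pooled range. For the VAE schemes the synthetic
latents are the *constructed* latents (the perturbed or mixed $\mu$ recorded
in provenance): that is where the synthetic sample lives in the codec's
latent space, whereas re-encoding its decoded image would conflate the
comparison with codec reconstruction error. GAN samples have no VAE-space
latent by construction and are embedded through the encoder.

Age-binned subgroup metrics restrict predictions to bins (default 10–20 and
50–60 years) and report per-class precision and F1; single-class bins are
flagged rather than reported as perfect.

## The phantom generator

Real cohorts of this kind are private. The phantom module renders fundus-like
images so the full workflow is exercisable and testable end-to-end: a
circular field, an optic disc on the nasal side (mirrored for right eyes,
which are rendered pre-flip so laterality normalization has real work),
a macula, branching vessels, and patient-level pigmentation and illumination
variation. The class signal lives in two peripheral features chosen as RP
analogues — dark speckle (a bone-spicule stand-in) and mid-peripheral ring
attenuation — whose class-conditional means are separated by `effect_size`
on a latent-feature scale. Key properties, all under test:

* `effect_size = 0` makes the class appearance distributions identical
  (two-sample KS test on a peripheral-darkness statistic is non-significant);
* separability of that statistic increases monotonically with `effect_size`
  over $\{0, 0.5, 1, 2\}$;
* speckle size scales with resolution, so the calibration is independent of
  `image_side`;
* fellow eyes share a patient latent with correlation 0.8, so patient-grouped
  splitting is genuinely necessary;
* simulated ages are class-conditional (X-linked younger: mean 26 vs ~51
  years, matching the demographic structure of the motivating cohort) but
  never influence rendering except through the class, so age-matched
  subgroup analyses can isolate image signal.

The default `effect_size = 1` gives a peripheral-darkness AUC of roughly
0.8 at the whole-cohort level — a moderately separable, not trivial, task.
What phantoms do **not** emulate: real acquisition optics, disease-stage
heterogeneity, camera artefacts, or any genotype-specific morphology.
Passing tests on phantoms therefore demonstrates that the machinery is
correct and that expansion moves performance in the expected direction under
a controlled signal; it does not certify performance on real fundus images.

## The benchmark and problem sizes

The direction-of-effect benchmark (`run_direction_benchmark()`) uses
2 classes × 12 patients (two eyes each) at 64 px, k = 5 grouped resamples,
and several master seeds. The codec is a one-level VAE (d = 48, 24 epochs);
the classifier is a narrow conv-residual network (widths 4-8-16, 16 epochs,
AdamW, linear decay, crop/flip augmentation — settings under which the base
arm genuinely learns the phantom signal); Gen 2 runs in `one_ratio_per_pair`
mode so the synthetic pool stays proportional to $C(n,2)$. These sizes are
the package's scaled-down benchmark conditions on ~38 balanced training
images per resample. The same configuration backs `scripts/acceptance.R`.

What the benchmark shows, and honestly does not show, with this codec: the
latent-overlap comparison behaves as expected (Gen 2 synthetics lie inside
the real latent distribution, DCGAN samples far outside), and Gen 2
synthetics measurably carry the class signal — mixing same-class latents
averages out patient-level nuisance, so the peripheral-darkness statistic
separates synthetic classes *better* than real ones. But the pooled-AUC
improvement of Gen-2-expanded training over the base arm does **not**
reproduce at this scale — consistent with decoded synthetics occupying a
smoother image domain than the sharp reals, so that with a roughly 9:1
synthetic-to-real pool the texture-domain shift outweighs the signal
benefit. The workflow this package operationalises obtained its
positive effect with a large pretrained autoencoder whose reconstructions
preserve texture; reproducing that direction of effect is expected to
require plugging such a codec into the codec contract, not a larger phantom
cohort.

## Numerical and design choices

* log-variance clamp $[-20, 20]$; KL in closed form (non-negative, zero iff
  the posterior equals the prior — under test against a Monte-Carlo
  estimate);
* AdamW with linear decay to zero and no warmup; per-parameter moments
  updated by a small C++ kernel; convolutions are C++ im2col/col2im plus a
  single BLAS product, verified against numerical gradients layer by layer;
* round-half-up on per-class patient counts in grouped splits, remainder to
  train (favours training data in tiny cohorts); stratification by class at
  patient level is on by default (`stratify = FALSE` available) to prevent
  empty-class test folds, although the source protocol does not state it;
* acquisition-date deduplication keeps all files of a patient's most recent
  date (ties keep everything from that date);
* class balancing drops whole patients, never single eyes, until each class
  is within one patient's image count of the minority class;
* binary decision threshold 0.5; histogram overlap with 32 bins; FID
  covariance with $n-1$ denominator.

## Limitations

The compact MSE-trained VAE cannot reproduce high-frequency texture, so
decoded synthetics are smoother than real images; with a strong pretrained
codec the expansion schemes would inherit its fidelity (the codec contract
exists for exactly that upgrade). Absolute Fréchet distances from the
default random-projection extractor are not comparable across extractors.
The benchmark's pooled AUCs are computed from small test sets and are noisy
at the single-seed level; directional claims are therefore made across
master seeds, not per seed. Phantom realism is deliberately limited (see
above), and nothing in this package should be read as clinical validation.
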