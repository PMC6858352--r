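---
title: "Patch-based metastasis mapping for DUV fluorescence frames: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patch-based metastasis mapping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(duvmap)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, what the
synthetic generator does and does not emulate, the numerical choices, and
the places where the design was genuinely open. It states no empirical
result that the test suite and `scripts/acceptance.R` do not themselves
compute.

## 1. The pipeline and its assumptions

The diagnostic question is binary per lymph-node image: does the frame
contain metastatic carcinoma? The pipeline decomposes it into three
stages, each with an explicit contract.

**Patch classification.** A frame (natively 2,592 × 2,048 px at
0.46 µm/px) is tiled into non-overlapping 278 × 278 patches from the
top-left origin; residual margins are discarded, so the native frame
yields 9 × 7 = 63 tiles. Each patch is normalized by the single scalar
maximum over all pixels and channels — absolute exposure is removed, the
channel *ratios* (blue DNA vs green RNA signal) are preserved; this is
the feature family the classifier is expected to use. Labeling follows
the asymmetric policy of the source protocol: a patch from a
metastasis-negative node is always a negative example; a patch from a
positive node is positive only if it contains tumor (by default any
mask pixel; `min_tumor_fraction` makes the rule stricter), and otherwise
*excluded* — non-tumor tissue from a positive node is not a vetted
negative, so it is never recycled. Splits are randomized over node
identifiers, not patches: within-node correlation (staining, patient,
section) would otherwise leak between train and test.

**Dense mapping.** The frame is mirror-padded by `patch/2 = 139` px per
side so that windows centred on border pixels exist and border lesions
survive the later vote. A 278-px window slides at stride `s` ∈ {10, 35,
70}; the classifier's probability is binarized (≥ 0.5 → positive; the
round-off rule is ambiguous at exactly 0.5 and the tie is fixed to
positive, documented in `mapper_config`) and written at the window
centre. The grid has `floor((L − 278)/s) + 1` cells per axis — the
inclusive fencepost convention. For the native frame at stride 10 this
gives 260 × 205 = 53,300 predictions, which uniquely pins down the
convention; the alternative `floor((L − 278)/s)` ("truncate") appears in
one printed description of the same geometry (259 × 204, and a padded
height printed as 2,325 instead of 2,048 + 278 = 2,326) and is provided
behind `convention = "truncate"` for comparison rather than silently
"fixed". The centre of an even 278-px window is defined as offset +139
from its top-left corner, which makes all coordinates integral and
aligns map pixel (i, j) with source pixel (i·s, j·s).

**Majority decision.** Independent per-window errors at patch accuracy
`a` scatter `E = n(1 − a)` wrong pixels over a map of `n` windows
(`expected_error_count()`; 53,300 × 0.012 = 639.6 ≈ 640 per native
frame). Because a true lesion paints a *contiguous* blob roughly
`(lesion + 278)/s` map pixels across while independent errors are
sparse, a windowed vote separates them: a `w × w` window (lookup
{10: 27, 35: 8, 70: 4}; see §4) slides one map pixel at a time over
valid positions, and an output pixel is positive iff the positive
fraction strictly exceeds the threshold. The image call is positive iff
any filtered pixel remains. The assumptions are: errors approximately
independent (violated by systematic confounders such as histiocyte
nodules — exactly the failure mode the trained classifier must handle),
and lesions of diagnostic interest at least about one vote window
across in map units.

## 2. Parameters that matter

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `patch_size` | 278 | px | classifier input; 128 µm of tissue |
| `pad` | 139 | px | exactly patch/2; preserves border lesions |
| `step` | 10 / 35 / 70 | px | speed–resolution trade-off; map pixel = step px |
| `decision_threshold` | 0.5 | prob. | the 0/1 round-off; ties positive |
| `vote_window` | 27 / 8 / 4 | map px | ≈ patch/step: span of one lesion-sized blob |
| vote `threshold` | 0.4–0.9 | fraction | strict-greater; 0.7 is the operating point |
| `min_tumor_fraction` | 0 (= any pixel) | fraction | labeling rule; tiny foci were legitimate positives in the source protocol |

Raising the vote threshold trades sensitivity for specificity
monotonically: positive pixels can only be lost, never gained
(`majority_vote` output at t₂ ≥ t₁ is a subset of the output at t₁; this
is a tested invariant, and the per-class true-rate direction is asserted
on synthetic sweeps).

## 3. The synthetic world

The generator (`scene_spec()`/`generate_image()`) emulates what drives
the diagnosis, not the physics:

* **lymphocytes** — dense small round nuclei (7 µm default), blue-dominant,
  negligible cytoplasm; density 80 nuclei per (100 µm)², a packed nodal
  field;
* **metastatic lesions** — elliptical footprints (default 100–400 µm
  across; the small-lesion regime of ≈ 55 × 43 µm is exercised in tests)
  filled with 12-µm-nucleus cells carrying abundant green cytoplasm and
  1–2 bright green nucleolus spots, arranged in glandular (cell rings
  around empty lumina), cribriform (punctured sheet) or solid packings;
* **histiocyte nodules** — the confounder: intermediate 10-µm nuclei,
  green but dimmer cytoplasm, *no* nucleoli, and **never** in the mask;
* **imaging artifacts** — additive Gaussian noise (2 % of full scale) and
  a ±5 % multiplicative illumination ramp in a random direction.

The tumor mask equals the union of lesion footprints exactly (cell
rendering is clipped to the footprint), which makes mask-level
assertions exact. Placement is rejection sampling with a 1,000-retry cap;
an over-constrained scene raises a dedicated `duvmap_placement_error`,
distinct from invalid-spec errors. Determinism is strict: the same spec
(including seed) is bit-identical, and dataset seeds derive from
(base seed, image index) so images regenerate independently.

What the generator does **not** emulate — and therefore what a green test
does *not* establish: real chromatin texture, nuclear pleomorphism,
stain variability between laboratories, optics (PSF, vignetting beyond a
linear ramp), photobleaching, or the full hardness of the
histiocyte-vs-carcinoma discrimination (real epithelioid cells can be
far closer to carcinoma in appearance than the parametric contrast used
here). Consequently the end-to-end acceptance result (trained CNN,
≥ 9/10 correct image calls per class) is a *mechanism* check — the
pipeline recovers a recoverable signal — not a clinical performance
claim. Quantitative channel intensities are free parameters: no printed
intensity statistics exist to calibrate against, so contrasts were
chosen once to be plausibly separable and are not tuned thereafter.

## 4. Numerical and design choices

* **Fencepost vs truncate.** The grid convention is the one that
  reproduces 53,300 (§1); both printed variants of the geometry cannot
  be right simultaneously, and the discrepancy is surfaced as an option
  rather than hidden.
* **Vote-window lookup.** 278/step rounds to 27.8 → 27, 7.94 → 8,
  3.97 → 4: no single rounding rule yields all three published window
  sizes, so the three pairs are a verbatim lookup table and
  `round(patch/step)` is the documented fallback for other strides.
* **Strict vote comparison.** "Exceeds the threshold" is implemented as
  strictly greater; the boundary case (fraction exactly equal, e.g.
  300/729 at threshold 300/729) emits 0 and is pinned by a test.
* **Even windows.** Neither the 278-px analysis window nor the 8/4-px
  vote windows have a central pixel. The analysis-window centre is
  defined as +139 from the top-left; vote output index (i, j) is the
  window with top-left (i, j), and overlay rendering carries the
  (w − 1)/2 offset explicitly.
* **Reflection dialect.** Mirroring excludes the edge pixel
  (`[1 2 3]` + pad 2 → `[3 2 | 1 2 3 | 2 1]`); the source material does
  not specify the dialect, and this is the symmetric convention under
  which `pad = patch/2` keeps all arithmetic integral. A consequence:
  `pad` must be strictly smaller than the image dimension.
* **All-zero patches.** Max-normalization of an all-zero patch is the
  identity plus a warning — a documented degenerate case instead of a
  divide-by-zero.
* **Per-window normalization.** The mapper normalizes every window with
  the same `normalize_patch` used at training time; the mapping stage
  feeds the same model, so the transform must match.
* **Noisy-oracle randomness.** Flip decisions come from one seeded
  uniform stream laid out over the grid in row-major order: per-image
  error counts are exactly Binomial(n, rate) and every call is
  reproducible given (seed, geometry, position). The whole-grid path
  used for speed is asserted identical to the per-window path.
* **JSON configs.** Run configurations are JSON (jsonlite) rather than
  YAML; the dependency contract of the target environment includes a
  JSON reader but no YAML parser, and the config structure is identical.
* **Built-in PNG codec.** No image-I/O package is part of the dependency
  contract, so the package carries a minimal 8-bit gray/RGB PNG
  writer/reader (filter 0 on write, filters 0–4 on read, zlib via base
  R's compression, CRC-32 obtained from zlib's gzip trailer). It is
  cross-validated against an independent decoder (Pillow) in the tests.

### The trainable classifier

The classifier contract is one function: normalized patch → probability
in [0, 1]. The reference training protocol — ImageNet-pretrained
backbones, global average pooling into a 2-node head, SGD, dropout 0.5,
two-phase schedule (head first, then everything), checkpoint at minimum
validation loss — is preserved structurally in a desk-scale model:
block-mean ×4 downsampling stem, two 3 × 3 conv blocks (8 and 16
filters, ReLU, 2 × 2 max-pool), GAP, dropout 0.5, 2-node softmax. Pure
vectorized R (im2col + GEMM); no deep-learning runtime.

Two training choices deviate from the obvious transcription and are
deliberate. First, inputs are centred (x − 0.5) in the stem: normalized
patches are all-positive with a dark-background mean, which makes
first-layer gradients strongly collinear and stalls SGD at practical
rates (observed as collapse to the class prior). Second, the default
schedule is lr = 0.1/0.05 over 10 + 40 epochs with batch 4 — at tens of
training patches and from-scratch weights, the transfer-learning-sized
schedule (lr 0.01, 10 + 10) performs only a few dozen parameter updates
and underfits badly; the hyperparameters are free parameters of the
protocol and are set so that the model actually trains at this scale.
Both phases share the min-validation-loss checkpoint, and the returned
state never has a higher validation loss than any epoch (tested).

## 5. Open design points, resolved

* **"Theoretically detect 0.5-µm tumors":** a claim of the source
  narrative that does not follow from the stated geometry (one map pixel
  at stride 10 spans 10 px ≈ 4.6 µm). Recorded, not implemented.
* **The acceptance criterion "lesions ≥ 3× the vote-window footprint"**
  is read in map units: the lesion must span at least 3 vote windows
  across, i.e. diameter ≥ (3·w·s − 278) px, which at stride 70 means
  ≥ 562 px ≈ 260 µm; the end-to-end test generates 270–320 µm lesions.
  The containment side ("prediction area exceeds the lesion by at most
  the window-centre dilation margin") is checked in map space: a
  filtered pixel may only fire where its vote window touches a window
  that truly contains tumor — the margin is patch/2 from centre
  assignment plus the vote extent, which is what the geometry permits.
* **Image-level decision without the filter** uses the raw map (any
  positive window ⇒ positive call), matching the "at least one pixel"
  rule of the no-filter comparison row in the sweep table.

## 6. Known limitations

Pure-R training is desk-scale: hundreds of patches and minutes of CPU,
not the tens of thousands of patches of the clinical study; the
pluggable contract admits external models for anything larger. The PNG
codec reads the subset it writes (plus standard filters) — it is not a
general-purpose decoder. Stage timings are logged but never asserted:
published wall-clock numbers are hardware-bound and are non-targets.
Clinical accuracies (patch accuracy ≈ 98 %, AUC 0.999, 96/100 image
rates) require the patient image sets and pretrained backbones and are
explicitly out of scope; the acceptance suite targets the reproducible
geometry, arithmetic and mechanism properties instead.
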