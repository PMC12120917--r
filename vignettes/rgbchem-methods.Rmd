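---
title: "Encoding molecules as RGB images for convolutional property regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encoding molecules as RGB images for convolutional property regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgbchem)
```

## The idea

A molecule with $N$ atoms, given as element symbols and Cartesian
coordinates, is turned into a square three-channel image. Pair
properties fill off-diagonal pixels $(i, j)$, per-atom properties fill
the diagonal $(i, i)$, and each of the three color channels carries one
or two properties. A convolutional network then regresses a scalar
property — here the HOMO–LUMO gap in eV — directly from the image. The
attraction is that every ingredient is cheap: no quantum-chemical
calculation is needed beyond the geometry itself.

Three pair descriptors and two atom descriptors are available:

* **Distance**: $R_{ij} = \lVert \mathbf{r}_i - \mathbf{r}_j \rVert$ in
  Å, zero on the diagonal.
* **Coulomb matrix**: $0.5\,Z_i^{2.4}$ on the diagonal and
  $Z_i Z_j / R_{ij}$ off it ("full"); the "reduced" variant zeroes the
  diagonal because the self-interaction terms are numerically much
  larger than the pair terms and would otherwise dominate a jointly
  scaled channel.
* **Bond order** (ReaxFF-style, uncorrected):
  $BO'_{ij} = e^{p_{bo1}(r_{ij}/r_0^\sigma)^{p_{bo2}}} +
  e^{p_{bo3}(r_{ij}/r_0^\pi)^{p_{bo4}}} +
  e^{p_{bo5}(r_{ij}/r_0^{\pi\pi})^{p_{bo6}}}$, per element pair. A
  reference radius of $-1$ (or any non-positive value) disables its
  term, and O–F, F–N, F–H (and by default F–F) pairs are sentineled this
  way because fluorine essentially only bonds to carbon in the CHONF
  chemical space targeted here. No cutoff, taper or valence correction
  is applied: the raw three-term sum is the descriptor, not a
  force-field energy.
* **First ionization energy** and **atomic number**, diagonal only.

The six generation types A–F assign these to red/green/blue. For
example type A is red = distance + ionization (disjoint cells),
green = reduced Coulomb, blue = bond order; E is purely
atom-descriptor red/blue around a full-Coulomb green. The types form a
lattice in which neighboring types differ in exactly one channel — a
property the test suite asserts, since it is what makes ablation
comparisons between types meaningful.

### Parameter provenance

Element constants ship as a versioned CSV (eV, three decimals). The
bond-order pair parameters ship as a plain-text block file that is
**synthetic**: hand-assembled values with the magnitudes and signs
typical of published CHON parameterizations, clearly labelled as such.
The bond-order channel is therefore structurally faithful (correct
functional form, correct sentinel rules) but not numerically identical
to images produced from any particular force-field distribution, whose
parameter values are not public in the source we follow.

## Normalization and canvas policies

Each property is min–max scaled to $[0, 255]$ over the cells it
occupies, independently per image (a constant property maps to 0).
Combined channels scale their off-diagonal and diagonal properties
separately — joint scaling would let the numerically large diagonal
flatten the pair structure, which is the same artifact that motivates
the reduced Coulomb matrix. Both choices are configurable: fixed global
ranges give cross-molecule comparability at the cost of per-image
contrast, and a `combined_joint` flag restores joint scaling.
Normalization happens **before** margin filling, so the average-fill
margin equals the mean of the already-scaled block; the opposite order
would change the fill value and is not offered.

Molecules differ in $N$ while the network wants a fixed $S \times S$
input. Three policies unify the size: bilinear **resize** of the
$N \times N$ block (half-pixel-centered sampling, so $S = N$ is exactly
the identity), **black** zero-fill, and **average** per-channel mean
fill, the latter two with the block fixed at the top-left corner or at
a uniformly random offset. Random offsets do not apply to resize. The
float pipeline quantizes round-half-up to 8-bit at emission; training
can consume either form.

## Atom-order shuffling as augmentation

The image depends on the (arbitrary) atom order of the input file, yet
the molecule does not. Reordering atoms permutes rows and columns of
every descriptor simultaneously — the encoder is permutation
*equivariant*, which the suite checks bit-exactly — so each ordering
yields an equally valid, generally distinct image of the same molecule
with the same label. Four strategies of increasing entropy are
provided: `none` (file order), `groups` (permute only within identical
elements), `partial` (permute within the heavy-atom set and within the
hydrogens), and `full`. Permutations act on positions within each
class, so `groups` never changes which element sits at a position and
`partial` never moves a hydrogen into a heavy slot.

Generating $k$ images per molecule multiplies a corpus of $n$ molecules
into $n \times k$ training points. Draws are deduplicated while the
molecule admits enough distinct orderings (counted as
$\prod_c n_c!$ for `groups`, $n_\mathrm{heavy}!\,n_\mathrm{H}!$ for
`partial`, $N!$ for `full`); beyond that, duplicates are emitted with a
warning, which matters only for very small or fully symmetric
molecules. Held-out molecules are encoded once with `none` by default,
so evaluation is deterministic.

## The compact networks

`s1cnn` and `s2cnn` are deliberately small: one (respectively two)
stages of 3×3 valid convolution + ReLU + 2×2 max pooling, then three
fully connected layers ending in one scalar. Published layer widths are
not available for these architectures, so the defaults here are chosen
to land the parameter counts in the intended bands at 32×32 input:
98,897 for S2CNN (target ≈ 0.1 M) and 190,921 for S1CNN (target
≈ 0.2 M) — the parameter budget, not the specific widths, is the
design claim, and the count is always verified against the constructed
weight arrays. The forward/backward passes are written as im2col plus
BLAS matrix products in base R; at these sizes an epoch over ~2,000
images takes a few seconds on one CPU, so no compiled code or
deep-learning framework is needed.

Training uses Adam (β₁ playing the role of momentum, β₂ = 0.999),
MAE loss by default to match the reported metric (MSE selectable), and
early stopping with Δ = 0: an epoch counts as improving only if the
validation loss strictly decreases, and training stops after
`patience` consecutive non-improving epochs, restoring the
best-validation weights. Labels are centered and scaled internally
during optimization (predictions are mapped back), because with a
sign-gradient MAE loss the output bias would otherwise need thousands
of steps just to drift to the label mean. `patience = Inf` reduces to
plain training to `max_epochs`.

## The synthetic corpus

Because the real 133,885-molecule database cannot be bundled, a
generator emulates its envelope: 1–9 heavy atoms drawn from
C/N/O/F (weights 0.70/0.12/0.13/0.05, leaning on carbon like organic
chemical space), grown as a connected tree with tabulated covalent
bond lengths jittered ±3%, hydrogens filling open valences, and a
0.5 Å minimum interatomic distance. The label is
$11.5 - 2.0 \cdot \overline{R} + \varepsilon$, where $\overline{R}$ is
the mean of the distance matrix and
$\varepsilon \sim N(0, 0.15\ \mathrm{eV})$: a gap-like 2–9 eV value
whose signal component (spread ≈ 1 eV) is recoverable from the image —
molecular extent is visible both in the block size and in the distance
channel — while the noise floor keeps the task honest. The geometry is
plausible, not physical: no conformer search, no valence-perfect
bonding. Consequently, passing tests demonstrate that the encoding
preserves and the network recovers geometric/compositional information
under the stated noise, not that chemical accuracy on real
quantum-chemistry labels is achieved.

## Problem sizes and numerical choices

The learning experiments in the test suite and the acceptance script
use 300 molecules (240 train / 30 validation), 32×32 type-A images
with black margins, `groups` shuffling at $k \in \{1, 8\}$, batch 32,
up to 35 epochs with patience 10, across 3 seeds — large enough for
the direction of the augmentation effect to be stable, small enough to
run on one CPU in minutes. Two findings are asserted: the S2CNN at
least halves the MAE of the best constant predictor (the median of the
training labels), and $k = 8$ training is at least as good as $k = 1$
in at least 2 of 3 seeds. These are direction-of-effect checks; no
effect size on real data is claimed.

Other numerical choices: descriptor symmetry is enforced by computing
each unordered pair once; coincident distinct atoms are an error for
the Coulomb matrix (division by zero) but merely give huge distances
elsewhere; missing bond-order pairs degrade to zero with a warning
rather than failing an entire corpus; ties in max pooling route the
gradient to the first maximum in scan order; and the bilinear resize
convention is pinned so that outputs are reproducible bit-for-bit
across runs of this package (bit-exactness against other image
libraries is explicitly not promised).

## Known limitations

* The bond-order channel uses representative synthetic parameters (see
  above); absolute pixel values in that channel are not comparable to
  images generated from proprietary parameter sets.
* Per-image normalization discards absolute scale: two molecules with
  proportional descriptor matrices encode identically. Fixed-range
  normalization is available when that matters.
* The compact networks are regressors for small square inputs
  (roughly 12–64 px); external backbones (ResNet-class models) are out
  of scope here — the architecture interface accepts only the SnCNN
  family.
* Split accounting follows an 80/10/10 default; published
  train/test-size conventions for the real database vary and can be
  reproduced by adjusting `run_config(split =, denominator =)`.
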