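---
title: "The ternary PPI model: masked multi-parallel convolution, training and attribution"
author: "TrioPPI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ternary PPI model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

TrioPPI predicts whether two proteins physically interact from their
sequences alone, and does it as a *three*-class problem rather than the
usual binary one. The classes are: interacting pair, non-interacting
pair, and *single protein* — a real sequence paired with a completely
masked partner. The third class exists to teach the model that
interaction is a relative property of a pair, not an intrinsic property
of one sequence, and it doubles as the mechanism behind the per-residue
attribution described below. Single-protein cases are used only in
training; evaluation is always binary (interacting vs negative).

The architecture is a Siamese pair of identical branches with shared
weights:

1. **Encoding.** A sequence of length $L$ becomes a one-hot matrix
   $X \in \{0,1\}^{L_{\max} \times 23}$ over a 22-letter amino-acid
   alphabet (the 20 standard residues plus selenocysteine U and
   pyrrolysine O) with a 23rd *mask* channel. Padding positions beyond
   the sequence, whole sequences in single-protein cases, and single
   occluded residues are all expressed as mask one-hots, so one
   mechanism handles all three masking scenarios.
2. **Embedding.** $E = X W_e$ with a trainable $W_e \in
   \mathbb{R}^{23\times d}$. The mask row of $W_e$ is pinned at zero
   and excluded from updates, so a masked position embeds to the zero
   vector.
3. **Multi-parallel convolution.** $N$ parallel filter banks with
   window lengths $l_n$, strides $s_n$ and $M_n$ kernels each compute
   strided valid convolutions of $E$ *without bias*, followed by ReLU
   and global max pooling:
   $h_m^{(n)} = \max_k \max(0, T^{(n)}_{k,m})$. The pooled vectors are
   concatenated into $H_{\mathrm{conc}} \in \mathbb{R}^{\sum_n M_n}$.
4. **Merge and head.** The two branches are merged by element-wise
   *addition* — not multiplication — and passed through two dense
   layers into a 3-class softmax.

These choices interlock: because masked positions embed to zero, the
convolution has no bias, and pooling is floored at zero by the ReLU, a
fully masked protein contributes an exactly-zero pooled vector, and the
additive merge then reduces bit-for-bit to the unmasked partner alone.
Were the merge multiplicative, a single-protein case would annihilate
the merged vector instead. The package's tests assert this chain
exactly (zero vector, bit-identical single-input reduction), not
within a tolerance.

### The final nonlinearity

The model's printed form applies a ReLU to the second dense layer's
output before the softmax. Implementing and training both variants
showed that the rectified form is unusable for learning: the uniform
prediction is a stationary point with a large basin — AMSGrad drives
all three logits negative within a few epochs, every ReLU gate closes
for every example, the gradient becomes identically zero, and the loss
freezes at $\ln 3$. The package therefore defaults to feeding the
*linear* logits to softmax (`finalRelu = FALSE` in
`networkConfig()`), and keeps the rectified head available behind the
switch for forward-pass use. All structural properties (mask
neutrality, symmetry, softmax normalization) hold under both.

## Negative-sample generation

Negatives are built from positives by shuffling one randomly chosen
member of each interacting pair so that its first residue stays fixed
and the dipeptide (2-let) counts of the remainder are preserved
*exactly*, then pairing the shuffled sequence with the untouched
partner. Composition and local dipeptide statistics are thereby
conserved, so a classifier cannot separate the classes on composition
alone; only the arrangement changes.

The sampler is the Euler-path construction (Altschul–Erickson style):
the suffix's $(k-1)$-gram transition multigraph is given a uniformly
random last-out-edge arborescence towards its terminal vertex
(rejection-sampled for connectivity), remaining out-edges are permuted
uniformly, and the Euler path is read off. This draws uniformly from
the set of valid shuffles; tests verify that on short sequences the
sampler's support exactly equals the brute-force-enumerated valid set.
Two boundary decisions are ours: if a draw returns the input sequence
itself, it is redrawn up to `attempts` times and then accepted with a
warning (some sequences admit exactly one valid arrangement); and
"preserved dipeptides" is read as *exact on the suffix* — the single
junction dipeptide spanning positions 1–2 may change, which is why
whole-sequence dipeptide frequencies are only approximately conserved.

## Training

Training minimizes the mean cross-entropy of shuffled minibatches
(clipping probabilities at $10^{-12}$ before the logarithm) with
AMSGrad at the conventional settings: learning rate 0.001,
$\beta_1 = 0.9$, $\beta_2 = 0.999$. We use the Keras semantics of
AMSGrad — running maximum of the second-moment estimate, bias-corrected
step size — and pin a unit test to two hand-computed steps on a
one-parameter quadratic. Weights are initialized Glorot-uniform,
$U(-a, a)$ with $a = \sqrt{6/(\mathrm{fan_{in}} +
\mathrm{fan_{out}})}$; fans are rows/columns for dense and embedding
matrices and $l_n d$ / $M_n$ for a kernel bank. The backward pass is
written alongside the forward pass in this package and is validated
against central finite differences to $10^{-4}$ relative error on
every parameter array (observed: $\sim 10^{-6}$).

One single-protein case is added per unique training sequence, mixed
into the same shuffled stream as the pair cases, with the masked
partner alternating between the two Siamese slots. During
cross-validation the augmentation is derived from the training folds'
sequences only; a leakage audit in the test suite checks this by
reconstructing every augmented sequence and confirming it occurs among
training-fold sequences.

Defaults the source text does not fix, chosen once and documented
here: batch size 32, 30 epochs, no early stopping, dropout 0.2 after
the first dense activation (inference-disabled), embedding dimension
$d = 12$, three filter banks $(l, s, M) = (2,1,64), (6,1,64),
(12,1,64)$, first dense width 128. The window lengths are chosen to
straddle typical short linear motif lengths (2–12 residues).

## Occlusion attribution

The effect of residue $i$ of protein A on the prediction against
partner B is the occlusion difference
$U_i = P_{\mathrm{neg}}(\hat A_i, B) - P_{\mathrm{neg}}(A, B)$, where
$\hat A_i$ is $A$ with position $i$ masked. Positive scores mean the
residue supports the interaction call; scores are differences of
probabilities and hence bounded in $[-1, 1]$. `importanceProfile()`
computes the partner's pooled vector and the baseline once and reuses
them — an optimization that is bit-identical to position-at-a-time
`residueEffect()` calls, which a test asserts. Profiles are invariant
to the amount of trailing padding. Maps are rendered 20 squares per
line with a per-protein symmetric diverging scale (reds positive,
blues negative); per-protein scaling was chosen over an absolute scale
because occlusion deltas shrink as sequences grow, which would wash
out long proteins on a shared scale.

## The synthetic benchmark

Real training corpora for this model family are interaction databases
at a scale (tens of thousands of pairs, GPU-scale training) outside a
test suite's reach, so the package ships a generator in which the
ground truth is constructed: member A of an interacting pair carries a
planted motif (`KRKRKRKR` by default), member B carries a second motif
(`DEDEDEDE`), and negatives cycle through the three failure modes
(motif A only, motif B only, neither). Backgrounds are uniform over
the 20 standard residues and rejection-sampled to be motif-free, so
recorded motif positions always index true occurrences and negatives
genuinely lack the missing motif. Lengths are drawn from 150–300: the
floor matches the corpus filtering convention for this model family,
and the cap keeps a full training run within a test suite's time
budget. Optional label noise flips a seeded, rounded fraction of
labels per class.

What passing at this scale shows — and does not. The benchmark is
separable by construction; a default network reaching $\ge 0.95$
held-out accuracy after 30 epochs on 200 training pairs demonstrates
that the architecture, gradients and optimizer work end-to-end, and
the attribution checks (motif positions outscore background in
held-out positives; most of the top-10 residues fall inside an
8-residue motif) demonstrate that occlusion recovers known
determinants. None of this certifies performance on real interactomes,
where the signal is weaker, compositional confounds exist, and
homology structures the data.

## Numerical and degenerate-input decisions

* Softmax subtracts the running maximum before exponentiation.
* Global max pooling breaks ties towards the lowest window index.
* Binary calls break the $P_\mathrm{int} = P_\mathrm{neg}$ tie
  conservatively towards "negative".
* Metrics with zero denominators are reported as `NA` with a warning,
  never silently as 0; F1 uses the count form $2TP/(2TP+FP+FN)$,
  which is defined whenever any of TP, FP, FN is positive.
* Average precision is the step-wise interpolated form (mean precision
  at the positive ranks); AUC is the normalized Mann–Whitney statistic
  with ties at half weight. Both class orientations of AP are
  reported.
* Fold summaries use the sample (n−1) standard deviation.
* Masking every residue of an encoding is defined to reproduce the
  empty-sequence encoding bit-exactly (its recorded length drops to
  zero), so "fully occluded" and "blank partner" are the same object.
* Positions are 1-based everywhere in the R interface and all reports.
* Checkpoints are JSON with weights serialized as `%.17g` strings,
  which round-trip doubles bit-exactly.
* One user seed is expanded into per-component sub-seeds by seeding
  R's generator and drawing integers below $2^{31}$; every stochastic
  step (initialization, epoch shuffling, dropout, generator sampling,
  shuffle draws, fold assignment) flows from these.

## Known limitations

* Training is plain R (vectorized per-example forward/backward); it is
  comfortable at the shipped benchmark scale (hundreds of pairs,
  $L_{\max}$ a few hundred) and not intended for corpus-scale runs.
* Exact masking semantics rely on the bias-free convolution; adding
  biases would break the zero-contribution guarantee and is not
  supported.
* The 22-letter alphabet rejects ambiguity codes (B, J, X, Z) by
  default; a skip-with-warning policy is the only alternative.
* Hyperparameter search is out of scope; the configuration file is the
  tuning interface.
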