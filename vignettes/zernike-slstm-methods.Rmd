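---
title: "Predicting self-interacting proteins from sequence profiles: methods and design notes"
author: "zernSIP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting self-interacting proteins from sequence profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zernSIP)
```

## The problem

A self-interacting protein (SIP) is one whose copies bind each other,
forming homodimers or higher homooligomers. Homo-oligomerisation matters
for enzyme activation, signalling and the stability of the protein itself,
but experimental detection is slow and biased toward well-studied
proteins. zernSIP implements a sequence-only predictor: it never looks at
interaction partners, co-expression or localisation (which are undefined
or uninformative for a protein interacting with itself), only at the
evolutionary profile of the single sequence.

The pipeline has four stages:

1. **Profile**: each protein is represented by its position-specific
   weight matrix (PSWM/PSSM), a $Y \times 20$ matrix of per-position
   amino-acid log-odds scores, normally produced by PSI-BLAST (3
   iterations, e-value 0.001) against a large database. The package
   parses the standard ASCII PSSM layout; it never runs PSI-BLAST itself.
2. **Features**: the profile is treated as a small grey-level image,
   mapped into the unit disk, and summarised by the magnitudes of its
   Zernike moments up to order 30 — 240 rotation-invariant descriptors.
3. **Reduction**: principal component analysis takes the 240 magnitudes
   to 150 coordinates, fitted on the training split only.
4. **Classification**: a stacked LSTM with peephole memory blocks
   (3 hidden layers of 16 blocks, softmax head) is trained with dropout,
   Nadam and early stopping.

## Dataset curation

`curateRecords()` encodes the benchmark-construction rules. Sequences
shorter than 50 or longer than 5000 residues are removed. A surviving
protein is a **positive** when at least one of the following holds: (a)
two or more large-scale experiments, or one small-scale experiment,
demonstrate the self-interaction; (b) the protein is annotated as a
homooligomer; (c) more than one publication reports the self-interaction.
**Negatives** are proteins with no self-interaction evidence of any kind.

Records that carry *some* evidence (a single large-scale experiment, a
single publication) but meet none of the criteria are returned as a
separate *ambiguous* set rather than being folded into the negatives.
Treating weakly-evidenced proteins as negatives would contaminate the
negative class with likely positives; quarantining them is the
conservative reading, and the four output sets always partition the
input exactly.

## Zernike moments of a profile

The Zernike basis over the unit disk is
$V_{nm}(\rho, \theta) = R_{nm}(\rho)\, e^{im\theta}$ with
$n \ge |m|$, $n - |m|$ even, and the radial polynomial

$$R_{nm}(\rho) = \sum_{s=0}^{(n-|m|)/2} (-1)^s
  \frac{(n-s)!}{s!\left(\frac{n+|m|}{2}-s\right)!\left(\frac{n-|m|}{2}-s\right)!}
  \rho^{n-2s},$$

normalised so $R_{nm}(1) = 1$. The discrete moments of an image $f$
sampled inside the disk are
$A_{nm} = \frac{n+1}{\pi} \sum_{\rho \le 1} f(\rho,\theta)\,
V^*_{nm}(\rho,\theta)$, and $|A_{nm}|$ is invariant to rotation of the
image — a useful property for a descriptor that should not care about
arbitrary orientation conventions of the profile.

### Numerical evaluation of the radial polynomial

The factorial sum above is mathematically exact but numerically
treacherous: at $n = 30$ its coefficients alternate in sign and reach
magnitude $\sim 3 \times 10^9$, so evaluating it in double precision near
$\rho = 1$ loses about seven significant digits to cancellation.
`radialPolynomial()` therefore evaluates

$$R_{nm}(\rho) = (-1)^{(n-m)/2}\, \rho^{m}\, P_{(n-m)/2}^{(m,0)}(1 - 2\rho^2)$$

through the three-term Jacobi recurrence, which is numerically stable for
all orders used here. The test suite checks this evaluation against the
factorial sum with exact integer coefficients carried in compensated
(double-double) arithmetic, and the two agree to better than $10^{-10}$
relative for every valid index up to $n = 30$.

### Mapping a $Y \times 20$ matrix into the disk

Profiles are long and narrow. The package inscribes the full matrix in
$[-1,1]^2$ — pixel rows and columns are scaled *anisotropically* so the
matrix centre is the origin and both axes span the square — and then
masks the points with $\rho > 1$, which take no part in the sums. The
alternative (inscribing the circle inside the matrix) would discard the
majority of sequence positions for long proteins; anisotropic inscription
keeps every amino-acid column informative at the cost of distorting
aspect ratio, which the magnitude features do not care about.

Log-odds scores are unbounded, and moment magnitudes scale linearly with
the image values, so profiles of different score ranges would otherwise
live on incomparable feature scales. By default every entry is squashed
through the logistic $1/(1+e^{-x})$ before mapping, bounding the image in
$(0,1)$; `squash = FALSE` switches to raw values for callers who have
already normalised their profiles.

### The 240 features and the exclusion rules

The retained feature indices are $1 \le n \le 30$, $m \ge 1$,
$n - m$ even, in n-major/m-ascending order. Negative repetitions are
excluded because $A_{n,-m} = \overline{A_{nm}}$ carries no new magnitude
information, and all $m = 0$ moments (including the zeroth order) are
excluded as near-constant radial averages with no discriminative value
under this reading; this enumeration — and only this one — yields exactly
240 features at the order cap of 30 (dropping solely $n=0$ would give
255). The cap of 30 trades detail against dimension: lower orders carry
coarse structure, higher orders fine texture, and beyond order 30 the
discrete grid of a 20-column profile cannot support meaningfully finer
angular detail.

### PCA

`fitFeaturePCA()` centres and projects using the training split only;
validation and test profiles are transformed with the frozen projection.
Fitting the projection on all data would leak held-out structure into the
representation and flatter every downstream estimate. The default keeps
150 of 240 components.

## The stacked peephole-LSTM classifier

Each hidden layer is a bank of memory blocks with input, forget and
output gates and peephole connections that let gates read the cell state:

$$i_t = \sigma(W_i [C_{t-1}, x_t, h_{t-1}] + b_i), \qquad
  f_t = \sigma(W_f [C_{t-1}, x_t, h_{t-1}] + b_f),$$
$$\tilde{C}_t = \tanh(W_C [x_t, h_{t-1}] + b_C), \qquad
  C_t = C_{t-1} * f_t + \tilde{C}_t * i_t,$$
$$o_t = \sigma(W_o [C_t, x_t, h_{t-1}] + b_o), \qquad
  h_t = \tanh(C_t) * o_t,$$

where $*$ is the element-wise product; input and forget gates peek at the
*previous* cell state, the output gate at the *current* one. The block
output used here is the standard $h_t = \tanh(C_t) * o_t$. A variant that
adds $\tilde{C}_t * i_t$ to the output appears in some descriptions of
this architecture; it double-counts the candidate contribution and is
inconsistent with every established LSTM formulation, but it is preserved
behind the `eq12AsPrinted` flag so the two can be compared. All of the
forward pass, backpropagation through time and the Nadam optimiser are
implemented in the package in plain R; at these layer sizes (16 blocks)
the batched matrix arithmetic is entirely adequate.

### Design choices that were genuinely open

- **Input as a length-1 sequence.** Each protein contributes one fixed
  feature vector, not a time series, so the default treats the 150-dim
  vector as a single timestep with zero initial state. The recurrent
  machinery is still exercised exactly once per layer. A `chunks`
  option splits the vector into a longer synthetic sequence (e.g. 10
  steps of 15 dims) for callers who want actual recurrence; the default
  is 1.
- **Input width.** The architecture is often quoted as
  *200–16–16–16–2*, which is incompatible with 150-dimensional reduced
  features; the package sizes the input layer to the actual feature
  dimension and treats the 200 as an inconsistency, not a target.
- **Dropout probability.** Unstated upstream; the default is the
  canonical $p = 0.5$, applied to hidden-layer outputs only (not to
  inputs or recurrent connections). Training zeroes units with
  probability $p$ *without* rescaling; at test time outputs are scaled
  by the retention probability $1-p$, the weight-scaling ensemble rule.
- **Early stopping.** Patience of 10 epochs on validation loss with
  best-weight restoration; the epoch cap is 200.
- **Nadam.** Step size $2 \times 10^{-3}$, moment decays 0.9/0.999,
  $\epsilon = 10^{-8}$; Nesterov-corrected first moment.
- **Initialisation.** Uniform fan-in-scaled weights, forget-gate bias 1
  (so cells initially retain state), all seeded; training is exactly
  reproducible from the seed.
- **Class imbalance.** Optional inverse-frequency class weighting of the
  loss exists but is off by default: the claim under test is that the
  model itself resists skew, so reweighting would change the question.
- **Prediction threshold.** Positive when the softmax positive-class
  probability is $\ge 0.5$; the tie at exactly 0.5 goes to the positive
  class.

## Evaluation

`computeMetrics()` reports ACC, TPR (sensitivity), SPC (specificity),
PPV (precision) and the Matthews correlation coefficient

$$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
 {\sqrt{(TP+FN)(TP+FP)(TN+FN)(TN+FP)}},$$

the phi coefficient of the confusion table. The subtracted numerator is
the standard definition; a summed variant sometimes seen in print is not
bounded by 1 and does not equal the phi coefficient, so the package pins
the subtractive form with a test against the Pearson-correlation oracle.
Metrics with vanishing denominators (e.g. PPV when nothing is predicted
positive) are returned as `NaN` with a flag rather than raising — batch
evaluations over degenerate folds keep going. AUC uses the tie-corrected
rank statistic, equal to the pairwise Wilcoxon–Mann–Whitney probability.

## The synthetic benchmark generator

`generateDataset()` makes PSWM-shaped matrices in which the positive
class carries a planted pattern built from a fixed set of low-order
Zernike basis functions (orders 2–5), scaled by `signalStrength` and
buried in i.i.d. Gaussian noise; negatives are pure noise. Because the
signal lives in the span of the feature extractor's own basis, the full
pipeline — disk mapping, moments, 240-dim magnitudes, PCA, classifier —
can recover it by construction, giving a closed feedback loop that tests
the whole chain rather than any single stage.

Defaults mirror the published benchmark conditions where they exist: the
class skew is 92 positives to 708 negatives (the 710:5511 yeast ratio of
about 1:7.7 at a desk-scale total of 800), the split is a stratified
40/30/30 train/validation/test partition, and profile lengths are drawn
from 50–300 residues, inside the curation window. Signal amplitude 3 and
noise scale 1 were chosen once as a regime where the planted structure is
clearly present per profile yet far from noiseless; amplitude 0 is the
null control. Generated profiles written to disk use the same ASCII
dialect the parser reads, with scores rounded to integers exactly as
PSI-BLAST prints them — the round trip is part of what the tests cover.

What the generator does *not* emulate: real evolutionary profiles
(column covariances induced by substitution matrices, conservation
gradients along domains), amino-acid composition biases, or any
relationship between the planted pattern and actual homodimerisation
determinants. A pipeline that passes the synthetic recovery test is
demonstrably able to transport class-dependent profile structure through
to the classifier; how much such structure real SIP profiles carry is an
empirical question the synthetic benchmark cannot answer.

## Problem sizes and numerical tolerances

The test suite validates moments against brute-force projection sums on
32×32 images to order 10 (relative $10^{-10}$), radial polynomials
against the extended-precision factorial oracle for all indices to order
30 at 50 radii ($10^{-10}$), memory-block steps against an independent
transcription of the gate equations over 100 random parameterisations
($10^{-12}$), backpropagation against central finite differences, MCC
against the phi-coefficient oracle and AUC against the $O(n^2)$ pairwise
count ($10^{-12}$). The end-to-end recovery check runs the full pipeline
on the 800-profile benchmark: with the default planted signal the
held-out AUC must reach at least 0.95, and with a null signal it must
stay in $[0.4, 0.6]$. These problem sizes keep a full run of the suite in
the minutes range on a single CPU while leaving every stage exercised at
the study conditions.

## Known limitations

- The package parses PSI-BLAST profiles; producing them (and hence all
  database- and version-dependent variability) is out of scope.
- The published benchmark accuracies on the yeast and human SIP datasets
  require those curated datasets and NR-scale profiles; nothing at desk
  scale can or should reproduce them, and the package's acceptance
  checks are property-based instead.
- Training is plain-R CPU code sized for hundreds-to-thousands of
  150-dim samples; it is not a general-purpose deep-learning stack.
- The logistic squashing default is a normalisation convention, not a
  fitted choice; callers comparing against other PSSM feature schemes
  should check both switches.
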