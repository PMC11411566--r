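---
title: "Predicting lncRNA subcellular localization with lncBoost: models and methods"
author: "lncBoost authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting lncRNA subcellular localization with lncBoost}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncBoost)
```

# The problem

Long non-coding RNAs act in the compartment they occupy: nuclear lncRNAs
scaffold chromatin complexes and steer splicing, cytoplasmic ones titrate
miRNAs and tune translation. Experimental localization assays (e.g.
RNA-FISH) are slow and expensive, so sequence-based prediction is
attractive. lncBoost predicts one of five compartments — nucleus, cytoplasm,
cytosol, ribosome, exosome — from the primary sequence alone. Two
properties of real localization data shape the design: the classes are
heavily imbalanced (nucleus outnumbers exosome by more than an order of
magnitude), and part of the signal appears to live not in raw composition
but in reading-frame-specific composition and secondary-structure
stability.

# Feature model

Each sequence of length $M$ (over A/C/G/U after T→U normalization; minimum
5 nt so every frame holds a triplet) is mapped to 257 numbers:

* **3-mer block (64).** Frequencies of all overlapping trinucleotides,
  counts over the $M-2$ windows divided by $M-2$. Lexicographic A<C<G<U
  order, fixed everywhere.
* **Reading-frame blocks (3 × 64).** Non-overlapping triplet frequencies
  from start offsets 1, 2, 3; trailing partial triplets are dropped and each
  frame is normalized by its own triplet count. The three frames jointly
  count exactly the $M-2$ overlapping windows, so the blocks are a
  decomposition, not a redundancy, of the 3-mer signal.
* **MFE (1).** The minimum free energy of the predicted secondary structure,
  raw kcal/mol (an option divides by $M$; the default is raw because a
  longer molecule genuinely has more stacking energy available, and the
  boosted trees are scale-free anyway).

We use frequencies rather than counts throughout so that sequences of
different lengths are comparable; each 64-block sums to 1. This choice also
matters downstream: synthetic oversampled points are convex combinations of
real points, and convexity preserves the per-block normalization exactly.

# Secondary structure

The built-in folder is a deliberately simplified Zuker-style interval
dynamic program. Every admissible structure is nested (no pseudoknots),
pairs are AU/UA/CG/GC plus GU/UG wobbles, hairpin loops hold at least 3
unpaired bases, and the energy of a structure is the sum over its loops:
stacking for directly nested pairs, bulge/interior penalties linear in loop
size, a flat hairpin penalty, and an affine multiloop penalty
(base + per-branch). The default parameters are small integers (stacking
−3/−2/−1 kcal/mol by pair strength; hairpin +3; bulge/interior 2 + 0.5·size;
multiloop 4 + 1·branches). They are **not** the Turner thermodynamic
parameters and are not meant to be: they are chosen so that exhaustive
enumeration over all nested structures can certify the dynamic program
exactly, which the test suite does on random sequences up to 12 nt. For
biological fidelity, import real RNAfold output with `readRnafoldOutput()`;
the two backends produce the same data layout and are interchangeable in
`assembleFeatures()` and the substructure analysis.

Numerical choices: bulge/interior loops are capped at 30 unpaired
nucleotides (a model field; the cap bounds the DP at $O(n^2 c^2)$ and is
far above any loop the toy penalties would favour), traceback ties are
resolved deterministically (unpaired-external first, then hairpin, then
two-loops in increasing gap order), and a sequence admitting no pair
returns energy 0 with an all-dot structure, so the reported MFE is never
positive.

For the structure–composition analysis, every 3-character window of a
dot-bracket string is classified as **loop** (`...`), **stem** (`(((` or
`)))`) or **junction** (anything mixed, including `(.)`, `..(`, `)..`), and
triplet frequencies are tabulated *per category*: each category column is a
distribution over the 64 triplets summing to 100%. The uniform baseline is
therefore 100/64 ≈ 1.563% per triplet, which is also what the tabulation
reproduces on uniform-random sequences. The per-category denominator is the
only reading under which that baseline is meaningful, which is why it was
chosen.

# Class balancing

Training folds (never test folds) are rebalanced in three steps:

1. **Borderline-SMOTE / ADASYN.** Both oversamplers synthesize minority
   points as exact interpolations `parentA + u (parentB − parentA)`,
   `u ~ U(0,1)`, between a minority point and one of its `smoteK = 5`
   nearest minority neighbours. Borderline-SMOTE1 interpolates only from
   the DANGER set (minority points whose `dangerM = 5` neighbourhood is at
   least half majority but not all majority), falling back to classic SMOTE
   when DANGER is empty; ADASYN allocates the deficit proportionally to the
   per-point difficulty `r_i` = majority fraction of the neighbourhood,
   with rounding residues given to the most difficult points. All
   neighbourhoods are Euclidean after standardizing the MFE column — on the
   raw feature scale the kcal/mol column would dominate all 256 frequency
   features combined.
2. **Uncertainty filtering.** The literature on confidence-weighted
   filtering of synthetic points does not pin down a single formula, so the
   package states its interpretation openly: 25 depth-2 trees are trained
   on bootstrap resamples of the *real* data, each synthetic point receives
   the ensemble vote entropy $H = -\sum_c p_c \ln p_c$, and points with
   $H > \tau$ (default $\tau = 0.75 \ln k$ nats) or whose majority vote
   contradicts their assigned class are discarded. Both knobs are
   configurable and reported.
3. **Outlier / near-duplicate removal** (optional, diagnostic): per class,
   points farther than mean + 3 sd from the class centroid are dropped, and
   near-duplicates (within 1e-9) are collapsed. K-means (k-means++ seeding,
   10 restarts) with a 2-component PCA projection provides a quick visual
   check that balanced classes occupy coherent regions.

The default plan raises every minority class toward the *second-largest*
class count, capped at 20× the original class size — raising everything to
the largest class would let the single dominant class dictate the synthetic
load, and a handful of real points should not seed an arbitrarily large
synthetic cloud.

# The boosted classifier

The model is a multiclass AdaBoost over depth-limited weighted-Gini
decision trees (default depth 2). With uniform initial weights
$\omega_{1,i} = 1/N$, round $t$ fits a tree to the weighted data, computes
the weighted error $\varepsilon_t$, and sets

$$\alpha_t = \tfrac12 \ln\frac{1-\varepsilon_t}{\varepsilon_t} + \ln(k-1),$$

the SAMME-style coefficient with the extra $\ln(k-1)$ term; for $k = 2$ it
reduces to the classic binary coefficient. Correct samples are scaled by
$e^{-\alpha_t}$, mistakes by $e^{+\alpha_t}$, and the weights are
renormalized to sum to 1 each round. Prediction is the
$\alpha$-weighted vote, ties resolved by class-set order.

Two boundary choices deserve a note. First, the positivity boundary of this
coefficient is $\varepsilon = (k-1)^2/((k-1)^2+1)$ (≈ 0.941 for $k=5$),
which is *weaker* than the often-quoted "better than $1/k$" requirement;
the package enforces the coefficient's own boundary (training stops when
$\alpha_t \le 0$) because that is what the formula implies, and documents
the discrepancy rather than silently tightening it. Second,
$\varepsilon_t$ is clamped to $[10^{-10}, 1-10^{-10}]$ so a perfectly fit
round keeps a finite coefficient; such a round ends training, since every
later round would refit the same tree. The tree fitter breaks split ties
deterministically (lowest feature index, then lowest threshold), making
training a pure function of the data order.

# Evaluation

Reports are per-class one-vs-rest: Sn = TP/(TP+FN), Sp = TN/(TN+FP), MCC
(0 when its denominator vanishes), per-class AUC by the rank
(Mann–Whitney) formulation with midpoint tie handling, and one overall
accuracy = trace of the confusion matrix over the total. A printed source
formula for ACC that reduces to (TP+FN)/total is treated as a typo and the
standard definition is used. Feature importance uses the F-score

$$F_i = \frac{\sum_j (\bar x_i^{(j)} - \bar x_i)^2}
       {\sum_j \frac{1}{n_j - 1}\sum_k (x_{k,i}^{(j)} - \bar x_i^{(j)})^2},$$

between-class over within-class scatter per feature, which is invariant to
affine rescaling of a feature; an all-constant feature scores exactly 0 via
a $10^{-12}$ denominator guard.

Cross-validation is stratified; balancing runs *inside* each training fold
only, so synthetic samples can never leak into a test fold and every real
sample is tested exactly once. A class with fewer members than folds is
spread over as many folds as it has members (with a warning) rather than
forcing a smaller k — the imbalance regime under study has exactly such
classes, and shrinking k would change the protocol for every class because
one is small. Because balancing happens strictly inside folds, accuracies
under this protocol are conservative relative to any protocol that
balances before splitting.

# The synthetic benchmark

`benchmark5Class()` generates five classes with counts 200/120/45/30/8
(majority:minority 25:1, emulating the shape — not the size — of real
localization data), lengths 200–600 nt, each class enriched by a factor
ρ = 6 in two class-specific triplets. Sequences are built *triplet-wise*:
successive non-overlapping triplets are drawn from the 64-triplet
distribution proportional to the background composition with the class's
triplets up-weighted, plus a uniform 0–2 nt tail. Triplet-wise generation
plants the signal at full strength in the overlapping 3-mer and frame-1
features while frames 2 and 3 see it only through codon-boundary overlap —
the same triplet can therefore rank differently per frame, as observed in
real data. Sizes were chosen once for a desk-scale runtime (the full
pipeline on the benchmark, including folding all 403 sequences and two
10-fold CV runs, completes in a few minutes on one CPU) and are fully
configurable.

What passing on this benchmark does and does not show: the generator
produces planted, well-separated composition signals with i.i.d. noise. It
validates the machinery — feature extraction, balancing bookkeeping,
boosting, fold hygiene, ranking — not localization biology. Notably, the
planted signal is strong enough that the n = 8 class is recoverable even
*without* oversampling, so the benchmark cannot demonstrate the rescue of
a drowned minority class that motivates oversampling on real data; on real
sequence sets the minority signal is far weaker and overlaps the majority,
which is exactly the regime the balancing stage exists for. The benchmark
also plants no secondary-structure signal, so the MFE feature contributes
length-correlated but class-uninformative variance here.

# Known limitations

* The built-in energy model is a transparent toy; any analysis that depends
  on realistic folding should import RNAfold output.
* The redundancy filter is a greedy word-containment clustering, not CD-HIT;
  it reproduces the *rule* (80% identity, longest representative) with a
  containment similarity whose word size (5) and greedy order are this
  package's choices, stated in the documentation.
* Multi-compartment lncRNAs are out of scope; one label per sequence.
* The uncertainty filter and the near-duplicate "de-correlation" step are
  documented interpretations where the literature underdetermines the
  method; both are flagged at their call sites and configurable.
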