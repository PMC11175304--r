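---
title: "Methods: voltammetric e-tongue preprocessing and cluster-to-classes classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voltammetric e-tongue preprocessing and cluster-to-classes classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etongue)
```

## The problem

A voltammetric electronic tongue records cyclic-voltammetry (CV) scans of a
liquid food sample with an array of low-selectivity electrochemical sensors;
the joint response pattern, processed by multivariate methods, fingerprints
the sample. This package implements such a pipeline for discriminating tomato
puree cultivars with three screen-printed carbon electrode (SPCE)
modifications:

* **CNP** (copper nanoparticles) and **GNP** (gold nanoparticles), both
  electrocatalytic for the non-enzymatic oxidation of soluble monosaccharides
  (glucose + fructose);
* **PEDOT** (a gold/poly(3,4-ethylenedioxythiophene) composite),
  electrocatalytic for ascorbic-acid oxidation.

Each electrode is disposable: it records 20 consecutive CV scans of one
sample aliquot (one *measurement*) and is then discarded; six electrodes per
cultivar/sensor condition give 3 cultivars × 3 sensors × 6 electrodes × 20
scans = 1080 scans, in 54 measurements.

Because the raw laboratory acquisitions are not publicly deposited, the
package ships a synthetic generator that reproduces the acquisition structure
and the signal phenomenology the preprocessing stage is designed to
neutralize. Everything downstream (preprocessing, classification,
evaluation) is agnostic to whether data are synthetic or read from CSV.

## The synthetic signal model

A scan is a triangular potential sweep (lower bound → upper bound → lower
bound) with current

$$
I(V) = b\,(V - V_{\min}) \;\pm\; C \;+\; A\,
  e^{-(V - V_c)^2 / 2w^2} \;+\; \varepsilon,
\qquad \varepsilon \sim \mathcal N(0, \sigma^2),
$$

where the capacitive offset $C$ is added on the forward branch and subtracted
on the backward one (so every interior potential shows hysteresis, as real CV
does), and the backward branch carries a displaced, attenuated copy of the
Gaussian oxidation peak. The peak amplitude is

$$
A = s \cdot L \cdot g \cdot (1 + i)^{-\delta},
$$

with sensitivity $s$, analyte load $L$ (glucose + fructose in g/100 g for CNP
and GNP; ascorbic acid in arbitrary units for PEDOT), per-electrode lognormal
gain $g$, scan index $i$ and decay exponent $\delta$. This is deliberately
the simplest model exhibiting every property the preprocessing must handle:
class-dependent peak amplitude, scan-to-scan amplitude decay, hysteresis,
electrode-to-electrode variability and additive noise. It is **not** an
electrochemical simulation — no Butler–Volmer kinetics, no Randles–Ševčík
scaling, no fouling chemistry.

### Default parameters and why

| Parameter | Default | Rationale |
|---|---|---|
| glucose/fructose per cultivar | 2.62/2.41, 3.37/4.02, 3.92/4.17 g/100 g | reference ion-chromatography determinations for the three cultivars |
| ascorbic acid per cultivar | 1.0, 1.6, 2.2 a.u. | not quantified by the reference technique; chosen distinct and class-separating because the ascorbic-acid sensor is the most discriminating one; exposed in `tomato_cultivars()` for override |
| potential windows | CNP 0→+1 V, GNP −0.5→+0.6 V, PEDOT −0.5→+0.5 V | the acquisition protocol's sweep windows |
| points per scan | 28000 / 27650 / 27650 | the sampling rate is not documented (the stated per-scan timing is internally inconsistent with the sweep windows at 50 mV/s), so lengths are free; these make `floor(n/35)` sum to the documented 2380-feature instance (800 + 790 + 790) |
| decay exponent $\delta$ | 0.5 | diffusion-limited decay, matching the attribution of the amplitude loss to diffusion phenomena |
| sensitivities | 12, 8, 30 µA per unit load | give oxidation peaks of tens of µA, typical of SPCE voltammetry of sugars/ascorbate |
| noise σ | 0.5 µA | ~1% of peak height, a realistic potentiostat + matrix noise floor |
| electrode gain sd | 0.02 (lognormal log-sd) | a few percent between disposable electrodes of one batch |
| capacitive offset / baseline slope | 2 µA / 5 µA·V⁻¹ | visible hysteresis and a non-flat background for the normalization to work against |

The generator's defaults define the study conditions; they were fixed once,
before any evaluation, and all reported numbers are computed under them.

### What the generator does not emulate

Real CV of a food matrix has multiple overlapping redox processes,
potential-dependent capacitance, electrode fouling that changes peak *shape*
(not only amplitude), drift between aliquots, and possibly much larger
electrode-to-electrode variability. In the synthetic data the only
class-dependent quantity is peak amplitude, so class separation is easier
than in the laboratory. Consequently, passing the evaluation here shows the
pipeline is *correct* (it recovers the class signal the generator planted,
through decay, hysteresis, range mismatch and noise); it does not certify the
headline accuracy on real acquisitions.

## Preprocessing

1. **Sequence conversion** (`to_sequence()`). Because current is not a
   single-valued function of potential, each scan becomes current vs sequence
   number (acquisition index).
2. **Normalization to the first scan** (`normalize_to_first()`). Every scan
   $s$ of a measurement is affinely mapped onto the range of the
   measurement's first scan $f$:
   $s^N = \big(\max f - \min f\big)\,\dfrac{s - \min s}{\max s - \min s} + \min f.$
   The extrema $\min s,\max s$ are those of the scan being normalized — the
   only reading under which the map lands on $f$'s range; the first scan is a
   fixed point. This neutralizes amplitude decay and turns each scan into an
   independent training instance.
3. **Cross-sensor range equalization** (`fit_range_stats()`,
   `equalize_ranges()`). GNP and PEDOT currents span a much smaller range
   than CNP, which would bias range-sensitive learners. Each non-reference
   sensor is affinely mapped from its **training-set** global range onto the
   CNP training-set range. The statistics are fitted on training scans only
   and frozen for test data (no leakage); an individual test scan's mapped
   range may therefore differ slightly from the CNP range, while the training
   set's global extrema match exactly.
4. **Window-average subsampling** (`subsample_mean()`). Disjoint windows of
   length $k$ are averaged, giving $\lfloor n/k \rfloor$ points per scan and
   discarding the $n \bmod k$ trailing points. Disjoint (not sliding)
   windows are used because the documented output length
   $\lfloor n/k\rfloor$ forces that reading. The default $k = 35$ is the
   protocol's optimized window.
5. **Concatenation** (`build_instances()`). Scans are grouped into triples —
   one scan per sensor sharing (cultivar, electrode slot, scan index), the
   pairing rule being a package choice since only "one scan per sensor" is
   documented — and concatenated in the fixed order CNP ‖ GNP ‖ PEDOT:
   360 instances × 2380 features at the default scale.

Because the equalization map is affine and window averaging is linear, the
two commute; `build_instances()` exploits this by caching unequalized blocks
plus each scan's full-resolution normalized extrema, so per-split refits of
the range statistics cost a rescale of the cached blocks rather than a full
reprocessing. A test verifies the fast path equals the explicit pipeline.

## Classifiers

**Projection + KMeans cluster-to-classes** (the package's core). A linear
transformation matrix $T$ ($m$ features × $c$ components) is fitted on
training data and applied as $(X - \bar x)\,T$; KMeans (as many clusters as
classes by default, 10 restarts) clusters the projected training scores; each
cluster is labeled with the majority class of its members; test points
inherit the label of the nearest centroid (Euclidean distance). For three
classes LDA admits $c \le 2$ components.

*LDA solver.* With $m = 2380$ features and 252 training instances the
within-class scatter is singular. The package uses the standard SVD solver:
within-class centering, per-feature within-class standardization, thin SVD,
and **rank truncation** of singular values below $10^{-8}$ of the largest
(the logged regularizer, `tol`), followed by an SVD of the whitened class
means. This is exact on the span of the data and numerically stable; no
explicit shrinkage parameter is needed. Columns of $T$ are unit-normalized
(after recording explained-variance fractions) so coefficient magnitudes are
comparable across components in relevance plots.

*PCA* uses `stats::prcomp`; *KMeans* uses `stats::kmeans`. All tie-breaks —
cluster-majority ties, nearest-centroid ties, majority-vote ties — resolve
to the lowest index and are reported.

**Comparators.** Random forest (`randomForest`: 100 trees, Gini impurity —
the only criterion that library offers, which is also the protocol's — and no
depth limit) and SVM (`e1071::svm`: polynomial kernel of degree 6, inputs
passed unscaled). An RNN comparator (dropout 0.6, softmax output, 30%
validation split) is declared in `classifier_spec()` for completeness, but no
recurrent-network backend is available to this package, so fitting it raises
an informative error; it is optional everywhere and no headline quantity
depends on it.

## Evaluation protocol

`repeated_evaluation()` performs `n_runs` (default 100) independent random
splits with 30% of instances held out. Per run: split → refit range
statistics on the training portion → fit classifier (seed = base seed + run)
→ predict the test portion → macro-averaged recall, precision, F1 and
fraction-correct accuracy (macro averaging is the natural choice here because
classes are balanced, where macro ≈ micro), plus the measurement-level
majority-vote accuracy (test predictions grouped by cultivar × electrode
slot, modal class per group). Summaries are arithmetic means over runs.

Two split granularities are provided. The default splits at the instance
(scan-triple) level, matching the scan-as-instance protocol; since the 20
scans of one electrode then typically appear on both sides of the split, the
classifier has seen every electrode during training, which inflates scores
relative to true electrode-level generalization. `split = "measurement"`
holds out whole electrodes instead. Both are implemented; the default
follows the documented protocol, and no claim is made about which the
original laboratory analysis used.

`ablate_sensor()` removes one sensor's block (e.g. PEDOT, the
highest-relevance block) to test whether sugars alone separate the cultivars;
`anova_monosaccharides()` provides the complementary compositional check — a
classical one-way ANOVA on replicate glucose + fructose sums, with the
degenerate cases handled explicitly (identical group means give F = 0, and
p = 1 when the data are entirely constant).

## Numerical choices and degenerate inputs

* Constant scans cannot be min–max normalized and raise a degenerate-scan
  error naming the scan; degenerate range statistics (max = min) likewise.
* Subsampling rejects windows longer than the scan.
* KMeans occasionally returns empty clusters; the fit is retried with a
  shifted seed up to five times before erroring.
* A class absent from a test split has undefined recall; it is reported as 0
  with a warning. A class absent from a *training* split skips the run with
  a warning and an adjusted denominator.
* Every random step (generation, splits, KMeans restarts, comparators) is
  seeded; identical configuration and seed reproduce every report byte for
  byte.

## Problem sizes used by the shipped checks

The package's own test suite evaluates the full default scale (1080 scans,
360 × 2380 instances) with 100 splits for the LDA + KMeans headline and
ablation numbers and 20 splits for the four-method comparison, which keeps
the whole suite within a few minutes on one CPU while leaving the run-count
of the headline quantities at the protocol's 100. Unit tests use shrunken
scans (hundreds of points) with the same structure.

## Known limitations

* The synthetic class signal lives in peak amplitude only; shape-based
  discrimination, which real matrices may offer (or confound), is untested.
* Ascorbic-acid loadings are synthetic placeholders.
* The no-preprocessing baseline must make raw variable-length scans
  rectangular; the package truncates each sensor to its shortest scan, one
  defensible choice among several, since the original representation is
  undocumented.
* Instance-level splitting measures the documented protocol, not
  field-deployment generalization to unseen electrodes; use
  `split = "measurement"` for the stricter estimate.
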