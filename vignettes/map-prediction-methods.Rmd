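---
title: "Methods: the combined MAP predictor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the combined MAP predictor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the model behind `mapredict`, the choices that
were genuinely open when it was built, and what its synthetic benchmarks
do and do not demonstrate.

## The prediction problem

Microtubule-associated proteins (MAPs) bind microtubules or tubulins
directly, but as a class they are sequence-diverse: no universal domain
or motif identifies them. The predictor therefore assumes only that

* MAPs are *enriched* for many individually weak degenerate sequence
  motifs (short patterns with fixed anchor residues and internal
  wildcard positions, e.g. `SxIP`);
* MAPs share mild overall compositional signal (notably an
  over-representation of positively charged residues near binding
  regions) that pair-composition features can capture; and
* close homologs of known MAPs are themselves likely MAPs, which a
  homology search against the positive training set detects directly.

No single signal suffices: homology is precise but conservative, motif
and composition classifiers generalize to weak or absent homology. The
combined predictor fuses all three.

## Components

### Motif discovery and selection

Candidate motifs are enumerated exhaustively from the data: every window
of a positive sequence, at lengths 2–6 and with up to 2 internal
positions replaced by wildcards (first and last positions stay fixed so
matches are anchored), yields a candidate pattern. Patterns matching at
least `min_pos_support` (default 5%) of positives and at most
`max_neg_support` (default 2%) of negatives are kept and scored by the
support difference. The defaults produce a large, deliberately redundant
candidate pool on realistic inputs without exhausting memory; both are
exposed in `discover_motifs()`. Because enumeration is data-driven it is
exactly equivalent to scanning the full degenerate-pattern space, and
the output is invariant to record order.

The pool is then reduced by greedy mRMR in the MID (difference) form:
the first feature maximizes mutual information with the label, each next
feature maximizes relevance minus mean redundancy against the selected
set. MID rather than MIQ avoids division by zero for uncorrelated
features and is the canonical default of the method. Mutual information
uses plug-in estimates in bits with the `0 log 0 = 0` convention. The
default of 463 retained motif features matches the size of the motif
feature set the approach was originally tuned to; when fewer candidates
are discovered, all are kept.

### CKSAAP encoding

The composition of k-spaced amino-acid pairs counts, for each spacing
k = 0..k_max and ordered residue pair (a, b), positions where a and b
occur k residues apart, normalized by the number of k-spaced windows so
each 400-feature block is a proper composition. `k_max = 1` is the
default spacing limit. Pairs touching the unknown residue `X` are
excluded from numerator and denominator alike, which keeps block sums at
1 and avoids fabricating pair identities. Ambiguity codes are collapsed
before encoding (B→D, Z→E, J→L, U→C, O→K); sequences shorter than
k_max + 2 are rejected at dataset assembly.

### Laplacian SVM

Both classifiers are Laplacian SVMs solved in the primal with squared
hinge loss over a representer expansion on all labeled and unlabeled
points:

$$\frac{1}{l}\sum_i w_i \max(0, 1 - y_i f(x_i))^2
  + \gamma_A \lVert f\rVert_K^2
  + \frac{\gamma_I}{(l+u)^2} \mathbf{f}^\top L \mathbf{f},$$

where $L$ is the unnormalized Laplacian of a symmetric kNN graph
(default 7 neighbors) with RBF edge weights sharing the kernel width.
These are the canonical defaults of the original manifold-regularization
framework; all are exposed in `lapsvm_config()`. The squared hinge makes
the objective piecewise quadratic, so deterministic Newton active-set
iterations converge in a few steps with no stochastic elements. Because
$L$ annihilates constants, the bias term is unaffected by the manifold
penalty.

Setting $\gamma_I = 0$ with no unlabeled points recovers a supervised
squared-hinge SVM exactly; `train_svm()`'s cost parameter maps onto the
ambient regularizer as $\gamma_A = 1/(2Cl)$. The test suite asserts this
degeneracy to 1e-6 and cross-checks predictions against an independent
LIBSVM fit. Class imbalance (the 1:10 training ratio) is handled by
per-class loss weights inversely proportional to class frequency,
switchable via `balance_classes` since an unweighted fit is also a
legitimate protocol.

Default kernel width is `1/n_features`. The regularization defaults
(`gamma_A = 1e-4`, `gamma_I = 1e-2`) are sensible starting points for
binary/compositional features on the synthetic benchmark; for real data
they should be re-tuned with `tune_5fold()`, which runs a seeded,
stratified 5-fold cross-validation over a config grid and selects by
mean AUC (ties to the earlier grid entry).

### Homology score

The best-hit E-value against the positive training database is
transformed by the piecewise map pEv (200 below 1e-200, −log10 in
between, −3 above 1e3 or with no hit), which is continuous at both
breakpoints and bounded in [−3, 200]. Self-hits (identical query and
subject identifiers) are excluded so that scoring training members does
not trivially saturate the scale. Two backends provide hits: a
precomputed tabular backend (the default in all tests — deterministic
and binary-free) and an external BLAST+ backend. A separate reporting
filter (E < 1e-4) lists database homologs for annotation; it plays no
role in best-hit extraction.

### Fusion and thresholds

The fused score averages the tanh-normalized classifier margins and
pEv/10 with weights (0.35, 0.5, 0.15). Normalization uses
`tanh(Ds/2)`, algebraically identical to `(1−e^−Ds)/(1+e^−Ds)` but
immune to overflow at large |Ds|. The default stringency thresholds
(0.121, 0.019, −0.008, −0.042) target 99/95/90/80% specificity; a score
exactly at a threshold is called MAP (the boundary rule is applied
consistently in classification, confusion counting and calibration).
`calibrate_thresholds()` re-derives thresholds on user data — the
smallest observed threshold whose measured specificity reaches each
target — because fixed thresholds travel poorly across datasets with
different score distributions.

### Evaluation

AUC uses the Mann–Whitney mid-rank form (ties counted one half) rather
than trapezoidal integration, so small samples are exact and the value
equals the probability that a random positive outscores a random
negative. MCC is defined as 0 when any denominator factor vanishes,
keeping evaluation total on degenerate confusion tables.

## Dataset assembly

`pairwise_identity()` is Needleman–Wunsch global alignment identity
(match 1, mismatch 0, linear gap −1; identity = matches / alignment
columns, end gaps included). Identity can differ between co-optimal
alignments; the implementation reports the identity of the alignment the
aligner selects, and the test oracle checks membership in the set of
optimal-alignment identities. Redundancy filtering is greedy —
positives first, then by decreasing length, ties by identifier — with an
intraclass 25% and interclass 80% identity cutoff by default. Visiting
positives first means a cross-class conflict always removes the
non-positive member: positives are the scarce, hand-curated class and
should survive filtering. This greedy definition is deterministic and
order-independent but is not a bit-exact reproduction of any particular
external clustering tool. `assemble_at_ratio()` then takes all positives
plus a seeded, exact `ratio`-fold sample of negatives (1:10 for
training, 1:50 for testing).

## The synthetic generator

`synth_generate()` emulates the statistical structure the predictor
assumes: negatives are i.i.d. residues from a background table
(uniform 1/20 by default, because uniformity makes analytic match-rate
oracles exact; a natural-frequency table is available), positives get a
K/R frequency boost (default 1.5) and planted motifs (default `SxIP`
and `KRxKP` at rate 0.8 per motif — one exemplar of the canonical
EB1-binding pattern, one charge-rich pattern echoing the composition
bias), and unlabeled sequences receive half the boost and half the plant
rate, matching their assumed position between the classes. Sequence
lengths are uniform on 80–200 residues — long enough for composition
estimates, short enough for fast benchmarks. `synth_homology_tsv()`
emulates the homology search: records that actually received a planted
motif get a log-uniform best hit (1e-50..1e-5) against a planted
database member; everything else gets no row and falls to pEv = −3.

What passing synthetic benchmarks shows: the full pipeline recovers
plantable signal end to end, every component is wired correctly, and no
stage leaks label information. What it does not show: performance on
real proteomes. Real MAP motifs are weaker, sparser and correlated with
domain architecture and disorder, which the i.i.d. generator does not
model; synthetic AUCs near 1 are expected and say nothing about
real-world sensitivity.

The signal-recovery benchmark in the test suite trains on 120 positives
at the 1:10 ratio with 60 unlabeled records and evaluates on a held-out
set of 40 positives at 1:10, averaged over 5 seeds; these sizes keep the
full suite comfortably fast while leaving the class structure intact.
The permutation-null control shuffles class labels among the labeled
training records and expects held-out AUC near 0.5. Two details make
this control meaningful: the discovery negative-support filter is
released under the null (otherwise no candidate passes and the pipeline
legitimately refuses to train), and the homology term is withheld,
because the synthetic hit oracle is tied to the planting itself — a
sequence property that no label permutation can erase — rather than to
anything learned. The learned components are thus tested for leakage
directly.

## Numerical and degenerate-input choices

* `transform_pev` rejects non-positive E-values; `NA` means no hit.
* CKSAAP blocks with no valid pair (all windows touch `X`) are all-zero
  rather than an error.
* Empty unlabeled sets are permitted everywhere (supervised case);
  single-class labeled sets are errors.
* The Newton solver caps at 50 active-set iterations; in practice it
  converges in fewer than 10.
* Model files are versioned JSON with coefficients at 17 significant
  digits, so save/load round-trips predictions exactly.
* Unreachable specificity targets return the maximum score plus a small
  offset, with a warning, rather than failing.

## Known limitations

* The motif-discovery procedure is a fully specified stand-in for the
  original pair of discovery heuristics, which are not publicly
  documented; it preserves the downstream contract (a large pool of
  binary, positively enriched motif features) but not necessarily the
  original candidate set.
* Optimized hyperparameter values for the two classifiers on the
  original curated data are not available; defaults here must be re-tuned
  per dataset with `tune_5fold()`.
* Greedy redundancy filtering approximates, but does not replicate,
  external clustering tools.
* PSI-BLAST profile searches are out of scope; profile-derived E-values
  can be supplied through the tabular backend.
* The headline benchmark figures of the original study require its
  curated sequence sets and full BLAST databases and are not reproducible
  from this package alone; the package's own guarantees are the oracle
  equivalences and synthetic-recovery results asserted by its test suite.
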