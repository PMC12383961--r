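---
title: "Methods: visibility-graph topology of ERPs and ensemble classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: visibility-graph topology of ERPs and ensemble classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Overview

`wvgerp` implements a pipeline for discriminating two subject groups from
multichannel event-related potentials (ERPs): preprocessing into
block-averaged band-limited series, conversion of each series into a
*weighted visibility graph* (WVG), extraction of graph-topological features,
leakage-safe feature selection, and classification — singly or by a
majority-vote ensemble over non-overlapping trial subgroups. The motivating
application is the separation of preclinical Alzheimer's disease (preAD,
amyloid-positive but cognitively normal) from normal-old (NO) controls using
a word-repetition ERP paradigm, where the late positive (P600-like)
repetition effect is attenuated in preAD.

Because the clinical recordings such a study uses are access-restricted, the
package ships a synthetic cohort generator that reproduces the *statistical
structure* the pipeline assumes, so every stage can be exercised, calibrated
and falsified on data with a known ground truth.

## The synthetic cohort generator

`cohort_spec()` fixes the recording geometry at the study's values: 20
subjects per group, 15 scalp channels (midline Fz/Cz/Pz, lateral frontal,
temporal, peri-sylvian language sites, occipital), 6 task conditions (all
new AN, new congruous NC, new incongruous NI, all old AO, old congruous OC,
old incongruous OI), 72 trials per condition, 4-s epochs (−2 s … +2 s around
word onset) sampled at 250 Hz.

Each trial is

\[ x(t) \;=\; \eta(t) + a_E\, G_E(t - \delta_E) + a_L\, G_L(t - \delta_L), \]

where

* \(\eta\) is band-limited Gaussian background noise with a \(1/(1+f)\)
  amplitude profile over 0.3–45 Hz, scaled to `noise_sd` (default 10 µV —
  single-trial EEG noise dwarfs ERP components; the components only emerge
  in trial averages). One noise realisation per (condition, trial) is shared
  across channels through a topographic gain, so channels correlate as on a
  real scalp.
* \(G_E, G_L\) are Gabor atoms (Gaussian-windowed cosines): a negative
  component peaking 400 ms post-onset (width 100 ms, 2.5 Hz; N400-like,
  largest for incongruous words) and a positive component peaking 600 ms
  (width 150 ms, 1.5 Hz; P600-like, largest for repeated words). Gabor atoms
  are the simplest waveforms that give ERP-shaped averages with band-specific
  energy.
* \(a_E, a_L\) combine the component amplitude (−5 / +8 µV), a fixed
  channel topography with midline maxima, a condition gain, and a
  per-subject log-normal amplitude factor (SD 0.1) that makes subjects
  exchangeable draws rather than clones.
* \(\delta_E, \delta_L \sim N(0, 20\,\mathrm{ms})\) are per-trial latency
  jitters, so trial averages are never noise-free replicas of the template.
* The **group effect** enters in exactly one place: for preAD subjects the
  late-component amplitude is multiplied by \(1 - \texttt{effect\_size}\).
  `effect_size = 0` therefore makes the two groups distributionally
  identical (the null used for calibration tests); `effect_size = 1` removes
  the late component entirely. The default 0.5 represents a marked but not
  total reduction of the repetition effect.

What the generator does **not** emulate: biophysical head volume conduction,
eye-blink/EMG artifacts, non-stationary drifts, or behavioural responses.
Tests passing on synthetic cohorts therefore demonstrate that the pipeline's
*mechanics* (selection calibration, leakage safety, signal recovery) are
sound — not that any particular accuracy transfers to clinical recordings.
Artifact handling on real data (ICA, rejection) is a documented hook, out of
scope here.

The ambiguity of "72 trials across each condition" (per condition vs total)
is resolved as 72 *per condition* and exposed as `n_trials`.

## Preprocessing

Per (channel, condition): trials are averaged pointwise; the 4-s average is
mirror-padded to 8 s (reflection without duplicating the boundary sample);
band-pass filtered; cropped to −1 s … +2 s; and block-averaged in 80-ms
(20-sample) bins. All stages are linear, so averaging before filtering is
exactly equivalent to filtering each trial first — the cheaper order is
used and the equivalence is covered by a linearity property test.

Filters are zero-phase Hamming-windowed sinc FIRs, high-pass then low-pass,
with the five canonical bands δ 1–4, θ 4–8, α 8–13, β 13–30, γ 30–45 Hz plus
the unfiltered `raw` series. Transition bandwidths follow the
25 %-of-passband-edge rule with a 2-Hz floor capped at the edge itself
(hence 1 Hz for the 1-Hz δ edge, 2 Hz for the 4-Hz edge); kernel length is
`ceil(3.3 / (tb / fs))` forced odd, and each stage's −6 dB point sits at the
centre of its transition band. Zero phase is realised by delay-compensating
the symmetric kernel in a single pass, which reproduces the −6 dB
specification exactly; an FFT gain oracle and a cross-correlation test pin
the passband gain and the zero-lag property.

750 cropped samples / 20 per block = 37.5 blocks; the trailing half block is
dropped (deterministic and conservative), giving 37 points per series. The
`raw` band is the unfiltered epoch as recorded (no detrending).

## Weighted visibility graphs

Each 37-point series becomes a graph whose nodes are time points on the
integer grid \(t_i = i\). Nodes \(i < j\) connect iff every intermediate
sample lies strictly below the chord — the natural-visibility criterion with
strict inequality, so collinear intermediates block visibility. Edge weights
are \(w_{ij} = |\arctan((x_i - x_j)/(i - j))| \in [0, \pi/2)\). Index time
units make the weights dimensionless and reproducible (the arctangent is
scale-sensitive, and no physical time unit is canonical after block
averaging). Equal-valued adjacent points remain edges in the binary
adjacency with weight 0, so binary features see them while strength-based
features ignore them naturally. Construction is a dense \(O(N^2)\)
running-maximum scan, verified against an \(O(N^3)\) brute-force oracle on
random short series.

## Graph features

Sixteen single-channel features per (channel, band, condition) graph, plus
one cross-channel feature per (band, condition):

* **AWD** mean node strength; **DD** Poisson rate fitted to the binary
  degrees (maximum likelihood = mean degree; a least-squares histogram fit
  is available as config); **NE** Shannon entropy (natural log) of the
  empirical degree distribution; **M** Louvain modularity of the weighted
  graph, with \(Q\) re-evaluated from the Newman definition on the final
  partition; **APL** mean hop count over ordered pairs.
* Legacy binary-graph features pinned to the standard definitions of their
  names: CC (mean local clustering), GIC (\(4c(1-c)\) on the normalised
  largest adjacency eigenvalue), LE (mean neighbourhood efficiency), GE
  (mean inverse hop distance), SW (\((C/C_{rand})/(L/L_{rand})\) against an
  analytic Erdős–Rényi reference, \(C_{rand} = \) density,
  \(L_{rand} = \ln N / \ln \bar k\), avoiding rewiring nondeterminism), GD
  (density), SMaC (exact maximum clique), IN (exact independence number),
  SMiC (global minimum cut, unit capacities), VCN (exact chromatic number:
  clique lower bound, greedy/DSATUR upper bounds, backtracking only when
  they disagree), CTSP (closed-tour cost on hop distances from a
  nearest-neighbour start at node 1 followed by best-improvement 2-opt —
  a pinned deterministic heuristic, and the one feature that is a heuristic
  rather than an exact invariant).
* **CCSS**: for each (band, condition), the mean Pearson correlation over
  all unordered channel pairs of the node-wise clustering-coefficient
  sequences. The similarity functional is not canonical; mean pairwise
  Pearson correlation is the pinned, documented choice, constant sequences
  contribute 0 (logged), and all channels in the active configuration
  participate.

The exact NP-hard quantities are feasible because \(N = 37\); SMaC, IN, VCN,
SMiC and CTSP agree with exhaustive search on all tested graphs with
\(N \le 7\). At the standard configuration the vector has
\(15 \cdot 6 \cdot 16 \cdot 6 + 6 \cdot 6 = 8676\) entries; incomplete grids
raise errors listing the missing keys rather than imputing.

Feature/substrate assignment: AWD and M use the weighted adjacency (their
definitions are weighted); all other single-channel features use the binary
adjacency.

## Selection, projection, and classifiers

For each of 100 random splits, 85 % of subjects train and 15 % test, with
the test set group-matched (40 subjects → 3 + 3 test). Feature selection is
a per-feature two-tailed pooled-variance Student t-test *on training
subjects only* with threshold \(p < 0.01\) (Welch available by config);
features constant in both groups get \(p = 1\). PCA (centred; unit-variance
scaling optional, off by default) then maps the selected features to 11
dimensions using training statistics only. Degenerate splits are handled
without crashing: if nothing passes the threshold the 11 smallest-p features
are used (logged); numerically-null principal directions are dropped.
Mutating held-out rows or labels provably changes no fitted object — the
leakage guard is asserted bit-level in the tests.

Classifiers (pinned hyperparameters): unpenalised binomial logistic
regression; linear SVM with cost 1; LDA; 3-nearest-neighbour (Euclidean);
random forest with 100 trees; and a one-hidden-layer ReLU network
(11→32→2, softmax cross-entropy, full-batch gradient descent, 300 epochs,
learning rate 0.05, standardised inputs). All stochastic fits are
seed-controlled. `preAD` is the positive class throughout.

## Trial-subgroup ensemble

The 72 trials per condition are partitioned into 31 non-overlapping
subgroups (21 of size 2, 10 of size 3), by contiguous blocks in trial order
(interleaved and seeded-random assignments available). Each member averages
only its own trials, extracts its own feature table, and re-runs selection +
PCA + classifier fitting inside the training subjects — the only
leakage-safe reading of "independently trained" members. Subject-level
predictions are the majority vote (31 members ⇒ no ties; even committees
break ties toward the positive class); the ensemble AUROC uses the mean
member score, which is finer-grained than the 32-level vote fraction.

Reduced-acquisition configurations mirror the clinical-efficiency analyses:
`channels5` (Fz, Pz, Cz, Wl, Wr; 2916 features), `trials30` (first 30
trials per condition), `bands3` (raw, δ, γ; 4338 features). Stratified
8-fold cross-validation plans (`make_kfold()`) are provided as an
alternative to repeated splits.

## Numerical and design choices

* Poisson fit by MLE, not histogram least squares: closed-form and
  deterministic (the alternative is config).
* Louvain is delegated to igraph's implementation with a seed-fixed visit
  order; \(Q\) is recomputed from the definition so the reported value does
  not depend on the optimiser's internal bookkeeping. On 8-node two-clique
  benchmarks the partition's \(Q\) is within 0.02 of the exhaustive-partition
  optimum.
* Tie-breaks: nearest-neighbour TSP ties go to the lowest node index;
  DSATUR ties to highest saturation, then degree, then index.
* Degenerate inputs error early and loudly: empty trial lists, ragged
  lengths, windows outside the epoch, non-finite series, disconnected
  graphs (impossible for visibility graphs, asserted), zero-weight graphs
  passed to Louvain.

## Simulation sizes used by the tests and acceptance script

The calibration suites choose sizes that make the statistical assertions
sharp while keeping a desk-scale runtime:

* The 8676-feature counting identity and the ~1 % null selection rate run at
  the full configuration (40 subjects, 15 channels, 6 bands, 6 conditions);
  the selection-rate band is the binomial 3σ interval around
  \(0.01 \times 8676 \approx 87\), averaged over 50 splits.
* Chance-level (effect 0) and signal-recovery (effect 0.9, noise 1 µV)
  accuracy checks run on a reduced acquisition — 2 channels (Fz, Pz), raw
  band, 2 conditions, 62 trials — so that the 31-member ensemble can be
  re-evaluated over ≥50 (null) and 20 (signal) splits for all six
  classifiers. The null check asserts every classifier's mean accuracy lies
  within 3 standard errors of 0.5; the signal check asserts ensemble
  accuracy ≥ 0.9 and ensemble ≥ single − 0.02 (paired).

## Known limitations

* Synthetic cohorts cannot validate clinical accuracy claims; they validate
  pipeline mechanics under a known generative model.
* CTSP is a deterministic local optimum, not the exact TSP cost, and is the
  one feature not invariant to node relabelling by construction (fixed start
  node); on visibility graphs of short random series it matched exhaustive
  search in all tested cases.
* The legacy feature formulas are defined in the literature only by name;
  the pinned definitions here are explicit choices, documented above, not
  claims about any other group's code.
* With 6-subject test sets, per-split metrics are coarse (multiples of 1/6);
  means over many splits are the meaningful quantities, and their SDs are
  intrinsically large.
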