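---
title: "Models and methods behind cntselex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cntselex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cntselex` analyses SELEX-style selection experiments that enrich
single-stranded DNA (ssDNA) sequences with high binding affinity for
single-walled carbon nanotubes (SWCNTs). The experimental pipeline it
mirrors has four arms: (i) iterative selection of a random 30-nt library
on the nanotube surface, read out by high-throughput sequencing and k-mer
enrichment profiles; (ii) surfactant-displacement kinetics, where adding
sodium cholate blue-shifts the nanotube fluorescence peak as DNA leaves
the surface, and the shift's time constant measures binding affinity;
(iii) coarse-grained bead trajectories of DNA on the tube, summarised by
intramolecular hydrogen-bond statistics and mobility; and (iv) machine
learning that predicts binding and, by transfer learning, affinity class
from sequence alone. Because the study's sequencing libraries and
measured time constants are not publicly deposited, the package ships a
synthetic-data module that emulates each measurement process; every
analysis stage is exercised end to end on that synthetic data.

## The synthetic selection model

The physical affinity function of a 30-mer for the nanotube surface is
unknown; the generator stands in for it with an additive score

$$s(x) = \sum_{i} w_{\mathrm{base}}(x_i) + \sum_{i} w_{\mathrm{dimer}}(x_i x_{i+1})
       + \sum_{(m, p)} w_m \,[x_{p..p+2} = m],$$

a sum of per-base weights, overlapping dimer weights, and
position-anchored trimer motif weights. The motif term is essential: it
makes affinity depend on base *order*, reflecting the experimental
observation that scrambling a high-affinity sequence while preserving its
composition destroys most of its affinity. Selection is modelled as
Boltzmann-weighted multinomial resampling: a round draws `n_draw`
molecules with replacement with probability proportional to
$c_i e^{s_i/T}$, where $c_i$ is the current count and the temperature $T$
sets stringency. PCR amplification noise is multiplicative lognormal on
counts with a chosen coefficient of variation. These are the simplest
mechanisms that produce the observed phenomenology — monotone
round-over-round enrichment of favoured bases with gradually collapsing
library diversity — and no thermodynamic realism is claimed.

Two stringency regimes are used in the shipped checks, chosen from the
design side of each question. Enrichment-shape checks use base weights
$\pm 0.1$ at $T = 1$: six rounds then raise the pooled A+C monomer
frequency in the top-20,000 profile by >0.05, the qualitative shape of
the sequencing readout. The learnability-by-round check instead uses
$T = 3$: under the harsher regime the binding-versus-random task is
already saturated by round 3 (AUC ≈ 0.94), and a trend across rounds
3–6 has no room to exist; at $T = 3$ the library is still evolving in
that window (AUC rising ≈ 0.75 → 0.84), which is the regime the original
experiment was in (its round-wise AUC rose similarly towards ≈ 0.92).

Round sizes in tests (50,000 unique sequences, 50,000 draws) are far
below the experimental scale of ~10^16 molecules; they are chosen so the
top-20,000 profile is meaningful while multinomial diversity loss over
six rounds still leaves several thousand unique sequences. The study's
own round-0 description is internally inconsistent about depth (6×10^16
molecules described as ≈10% of the 1.2×10^18 space, which is actually
5%); the generator makes no attempt to match that scale.

## Library analysis

Reads are parsed with Biostrings; the 66-nt construct is
`forward primer (18 nt) + N30 + reverse region (18 nt)`. Insert
extraction anchors both 18-mers with at most one Hamming mismatch each
(both anchors configurable — the published reverse-primer sequences are
mutually inconsistent at one base, and one mismatch absorbs either
variant), tries the reverse complement when the given orientation fails,
and rejects reads with a non-30-nt span or an N in the insert. Ranking
is by descending count with ascending lexicographic tie-break, so the
top-N boundary is deterministic. One visible consequence: in a round-0
library where every count is 1, the "top N" are simply the
lexicographically smallest sequences, so its profile is mildly A-biased
(A sorts first); from round 1 on, counts dominate and the artifact
vanishes. K-mer profiles use overlapping windows
(29 dimers per 30-mer), cover all $4^k$ keys including zeros, and default
to weighting each unique sequence once, matching profiles quoted over
"the top 20,000 sequences"; count-weighted profiles are available.

## Displacement kinetics

A trace is the fluorescence peak wavelength (the tracked ~1129 nm peak)
sampled every 20 s, with surfactant added at 100 s. The model is
first-order exponential decay to a plateau,
$\lambda(t) = \lambda_\infty + (\lambda_0 - \lambda_\infty)
e^{-(t - t_\mathrm{add})/\tau}$, fitted by Levenberg–Marquardt least
squares with all three parameters free. Initialisation: $\lambda_0$ from
the pre-addition mean, $\lambda_\infty$ from the last point, $\tau$ from
the log-linear slope, clamped into [window/100, 3·window] because
initial values outside the resolvable range give a numerically singular
Jacobian.

Censoring (an "INF" time constant — no measurable displacement,
i.e. very strong binding) is declared when the shift the fitted curve
*realises within the observation window*,
$|\lambda_0 - \lambda_\infty|\,(1 - e^{-(t_{\max}-t_\mathrm{add})/\tau})$,
is below `shift_min_nm` (default 1 nm, the instrument-noise scale of
such traces). The realised-shift form matters: on a flat noisy trace the
optimiser can park in a large-amplitude, very-slow-$\tau$ minimum whose
nominal amplitude is huge while the curve barely moves within the
window; judging the nominal amplitude would under-censor. When the fit
cannot run at all, the trace is censored if a noise-robust observed
shift (pre-addition mean minus the mean of the last three points) is
below threshold, and reported as a fit error otherwise.

Affinity labelling uses the 90-s threshold with `tau >= 90` or censored
counting as high; the boundary itself is labelled high, a choice the
threshold's provenance (a gap in the measured distribution) makes
inconsequential. The enthalpy-sum affinity estimate is a plain per-base
sum over a user-supplied table (the per-base dissociation enthalpies come
from calorimetric literature and are deliberately not bundled), and its
association with time constants is plain Pearson correlation on the
linear τ scale with censored values excluded upstream.

## Trajectory statistics

Trajectories are bead-level (coarse-grained): each nucleotide has a
backbone and a base bead, and the nanotube is a cylinder of radius 0.6 nm
along z, periodic in z (the tube is bonded across the boundary, so
pairwise distances use the minimum-image convention along that axis
only). A hydrogen bond is any pair of base beads within 0.35 nm whose
nucleotide indices differ by at least 2 — contiguous neighbours are
covalently tethered and would trivially satisfy the cutoff, so they are
excluded by default (`min_seq_sep = 0` disables this). A bonded pair is
"near" the surface when the *smaller* of its two beads' surface
distances is below 0.6 nm, the conservative reading of nearness; the
boundary value 0.6 nm itself classifies as far. Percentages are
`near/(near+far)`; when no bonds exist both are reported as `NA`, never
silently as zero. Per-position means average, over the analysis window
(default the last 2,000 frames), the number of bonds each position
participates in.

MSD is computed on the centre of mass of a bead selection after
unwrapping z across the periodic boundary. The default estimator
averages over all time origins,
$\mathrm{MSD}(\ell) = \langle |r(t+\ell) - r(t)|^2 \rangle_t$, which is
the standard low-variance choice; a strict single-origin mode
($|r(\ell) - r(0)|^2$) is provided, and the two coincide at the maximal
lag. The multi-origin implementation is checked against an explicit
double-loop brute force to 1e-10.

The toy trajectory generator is geometry, not physics: the DNA chain
wraps the tube helically with base beads spaced ≥0.8 nm apart, and
selected base pairs are "planted" within 0.3 nm of each other at a
prescribed surface distance. This makes the downstream statistics
exactly predictable (planted pairs are the only bonds), which is the
point — the package tests the analysis, not MARTINI dynamics. Passing
these tests shows the statistics are computed correctly, not that real
trajectories would show any particular H-bond pattern.

## Machine learning

Two encodings: overlapping k-mer count/frequency vectors ($4^k$ columns
in lexicographic order; 2-mers are the default for RF and MLP, the best
performing k in the original experiments) and 30×4 one-hot matrices
(positions along the sequence, bases A/C/G/T as channels). Five model
families: random forest (via `ranger`, 500 trees), and four neural
families — MLP (128, 64), a 5-layer 1D CNN (64 filters, kernel 5, ReLU,
same padding), a GRU (hidden 64, last-state readout) and a 2-block
transformer encoder (4 heads, model dim 64, learned positional
encoding, mean-pool readout). No deep-learning backend is available to
R in this project's dependency set, so the neural families run on a
compact engine written in the package: hand-derived reverse-mode
gradients for every layer (dense, same-padded conv, GRU cell,
multi-head attention with layer norm) and an Adam optimiser. Every
analytic gradient is validated against central finite differences in the
test suite; training uses cross-entropy, learning rate 1e-3, batch 64,
and early stopping on validation AUC (patience 10, max 200 epochs). All
of these are repository choices, not claims about the original models,
whose hyperparameters were not published.

One deliberate architectural choice: the CNN readout is
flatten-into-dense rather than a global pooling layer. Convolutions are
translation-equivariant, so any global pool (max or mean) makes the
network provably blind to *where* a motif sits — yet position-anchored
motifs are exactly the order signal the affinity problem contains (and
the description of the original network mentions only convolutional
layers and a fully connected layer, no pooling). Flattening preserves
position at modest parameter cost at length 30.

The binding task pairs the top-N ranked library sequences (positives)
with uniform random 30-mers rejection-sampled against the positive set
(negatives; the check is against the positives only, as specified for
the original design). Evaluation repeats stratified 60/20/20 splits;
a split that accidentally loses a class is re-drawn with a derived seed
and logged. Metrics are accuracy/precision/recall/F1 at threshold 0.5
plus AUC computed by the Mann–Whitney rank statistic with midranks —
the suite verifies it equals trapezoidal ROC area exactly, ties
included.

Transfer learning mirrors the original protocol: the binding CNN's first
`n_freeze = 3` conv layers are frozen and the rest fine-tuned on the
72-sequence affinity panel under repeated stratified 4-fold CV, pooling
out-of-fold probabilities per repeat into one ROC. Frozen parameters
are asserted bit-identical before and after fine-tuning. The shuffling
ablation evaluates a fitted model on composition-preserving per-sequence
permutations of the test set; the paired comparison across shuffle
replicates is an exact sign-flip permutation test on the AUC
differences (the original work reports significance without naming the
test). Censored panel sequences enter the affinity data as
high-affinity, per the labelling rule.

Because the measured 72-sequence panel is not public, the package's
panel is synthetic (`simulate_affinity_table()`): 20 high / 52 low at
the 90-s threshold with 3 censored INF sequences, time constants
log-linked to the ground-truth score so that a model pre-trained on a
library evolved under the same ground truth can recover the labels.
Reported transfer AUCs on this panel therefore demonstrate protocol
correctness and self-consistent recovery, not the published performance
on the real measurements.

## Numerical conventions and degenerate inputs

* All randomness flows through an explicit per-call seed; derived seeds
  stay below 2^31. Identical seeds give bit-identical outputs for every
  generator, and RF plus all data handling are bit-reproducible;
  neural training is reproducible in the single-threaded deterministic
  mode the engine always runs in.
* The library-space calculator uses exact base-10^4 big-integer
  multiplication, since 4^30 exceeds the integer range where doubles
  carry every decimal digit.
* Peak extraction refines the windowed maximum by a three-point
  parabola, falling back to the grid point at window edges or when the
  parabola degenerates.
* `cut_ratio` refuses the 0/0 case; k-mer profiles keep explicit zeros
  so rows always sum to 1; one-hot rows sum to exactly 1 per position.

## Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` run the full pipeline at
reduced sizes chosen to keep the stochastic properties comfortably
resolvable: selection at 50,000 sequences over 6 rounds; 200 simulated
traces per kinetics check; a 2,000–5,000-frame random walk for the MSD
oracle; binding datasets of 2,000 + 2,000 (4,000 + 4,000 for the
separability check); and a 1,000 + 1,000 pre-training set with 16-filter
CNNs for the transfer protocol. These sizes are statements about where
the synthetic effects are unambiguous, and all are parameters the user
can raise.

## Known limitations

The generator has no sequencing-error model, no chirality-resolved
multi-peak spectra, and no thermodynamics; trajectories are fixtures.
Gel band intensities arrive as numbers (no densitometry). Feature
attribution for the RF model is limited to ranger's permutation
importance (`model_spec("rf", importance = "permutation")`); no
Boruta-SHAP. Conclusions about *real* libraries require the
real sequencing data and measured time constants, which must be obtained
from the original authors.
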