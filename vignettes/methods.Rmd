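---
title: "Methods: vigilance-state spectral analysis, editing quantification, and 3D plaque phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vigilance-state spectral analysis, editing quantification, and 3D plaque phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`sleepedit` implements the computational half of a brain genome-editing
study: EEG/EMG sleep phenotyping with a specific epoching, binning, and
normalization scheme; amplicon-sequencing quantification of prime
editing; open-field locomotion kinematics; and quantification of
amyloid plaques and plaque-associated microglia in cleared-hemisphere
probability volumes.  Every stage is exercisable end to end on
synthetic data produced by the package's own generators, which is how
the test suite and the acceptance script validate it.  This vignette
records the models, the tunable parameters, and the design decisions
taken where the methods left genuine freedom.

## EEG/EMG spectral pipeline

**Preprocessing.** Raw signals (e.g. 512 Hz) are band-pass filtered —
0.1–48 Hz for EEG, 10–30 Hz for EMG — and decimated to 128 Hz.  The
band-pass is a 4th-order Butterworth high-pass followed by a 4th-order
Butterworth low-pass, each applied forward–backward for zero phase.
Two numerical choices matter here.  First, the filters are factored
into second-order sections (biquads): at a 0.1 Hz edge on a 512 Hz
signal the direct-form denominator has poles at $|p| \approx 0.9995$,
and direct-form `filtfilt` visibly fails (a DC input leaks through
essentially unfiltered).  Second, the channel mean is removed before
filtering, because forward–backward filtering has edge transients that
decay over $\sim 1/(1-|p|)$ samples and would otherwise re-introduce a
large offset at the record edges.

**Epoch spectra.** Spectral power is computed per 4-s epoch at 0.25 Hz
resolution.  At 128 Hz a 4-s epoch holds exactly 512 samples, so a
Welch estimate with non-overlapping Hann windows at that resolution
degenerates to a *single* windowed periodogram per epoch; that is the
only configuration consistent with the stated parameters, and it is
implemented as one Hann-windowed FFT per epoch with the standard
window power correction ($\sum w_n^2$), so that the one-sided PSD
integrates to the signal variance (checked by a Parseval test on white
noise, within 5%).

**Hybrid binning.** Quarter-Hz bins are averaged pairwise into 0.5 Hz
bins covering 0.5–5 Hz (10 bins) and in groups of four into 1 Hz bins
spanning 5.25–25 Hz (20 bins), 30 bins total.  Bin labels are **upper
edges**: the 0.5 Hz bin labelled $f$ averages the quarter-bins at
$f-0.25$ and $f$; the 1 Hz bin labelled $g$ averages $g-0.75 \dots g$.
The label convention is not dictated by the method description; it is
documented here and fixed throughout the package, and band membership
is inclusive at both edges in label space (delta 1.0–4.5 Hz resolves
to labels $\{1.0, 1.5, \dots, 4.5\}$; sigma 10–15 Hz to
$\{10, \dots, 15\}$; theta 6–9 Hz to $\{6, \dots, 9\}$).

**Scoring.** Machine-learning scorers are out of scope; `score()` is a
transparent rule-based stand-in.  Per epoch: WAKE if the EMG RMS
exceeds `k_emg` (default 1.5) times the median epoch EMG RMS of the
recording; otherwise REM if the theta/delta power ratio is at least
`rem_ratio` (default 2.0), NREM if at most `nrem_ratio` (default 1.0),
and TREM — transition to REM, an epoch of mixed slow-wave and theta
activity — in between.  All three thresholds are exposed.  Note that
the median-EMG baseline presumes a sleep-majority recording: if the
animal is awake more than half the time, the median epoch lands in the
wake distribution and the rule degrades.  The synthetic generator's
default architecture is chosen accordingly (below).

**TREM semantics.** TREM epochs count toward total REM sleep duration
in architecture summaries but are excluded from the spectra of both
NREM and REM everywhere in the package (band powers, normalizations,
SWA).  This exclusion is enforced in code (`band_power` and the
normalizations refuse `state = "TREM"`), not left to callers.

**Normalizations.** Two schemes are implemented.  *Cross-state*: for
each frequency bin, a state's mean power is divided by the summed
power of that bin across NREM, REM, and wakefulness in the 12-h light
phase of recording day 1, times 100.  The "summed power" is read as
the sum of the three state means (default); a pooled-epochs reading is
also offered (`reference = "pooled"`) since the phrase is ambiguous,
but only the default satisfies the per-bin 100% identity on the
reference window.  *Within-state*: each bin as a percentage of the
state's total power over the 30 bins, summing to 100% by
construction.  Both are scale-invariant.  *SWA timecourse*: NREM
delta power per interval, normalized to the mean NREM delta power in
ZT8–12 of day 1.  The delta band for SWA defaults to 1.0–4.5 Hz (the
slow-wave-activity definition); 1.5–4.5 Hz is available as
`band_def("delta_sig")` since the narrower range is used for some
spectral contrasts.  The parietal derivation is the default channel
for spectra, with frontal equally supported; recordings are assumed
to start at lights-on (ZT0), with `start_zt` as an override.

## Synthetic sleep data

The generator exists so that every downstream stage can be tested
against known ground truth; it emulates the *statistics* the pipeline
consumes, not biological waveforms.

**Hypnogram.** A per-epoch Markov chain over
{WAKE, NREM, REM, TREM} with separate light- and dark-phase transition
matrices under a 12:12 cycle.  TREM is reachable only from NREM and
leaves only to REM or WAKE (transition epochs border NREM and are
brief).  The default matrices were chosen analytically — from the
chains' stationary distributions, before any signal-level testing —
to give (i) about two thirds of total sleep in the light phase, the
qualitative structure of a nocturnal mouse; (ii) roughly 535/270 min
of light/dark sleep and ~85 min of light-phase REM, i.e. a
deep-sleeping laboratory mouse at the upper end of the normal range
(~13.5 h/day); and (iii) a sleep-majority day (~56% of epochs
asleep), which the scorer's median-EMG baseline requires.  The choice
couples generator and scorer deliberately: the generator defines the
study conditions under which the rule-based scorer is a valid
stand-in.

**EEG synthesis.** Per state, the target PSD is a $1/f^{\alpha}$
background (default $\alpha = 1$) plus Gaussian band bumps: NREM a
delta bump (2.5 Hz, width 1 Hz), REM a theta bump (7.5 Hz, width
0.75 Hz), TREM a weaker mixture of both (placing its theta/delta
ratio between the scorer's NREM and REM thresholds), WAKE broadband.
Each epoch is synthesized in the frequency domain with random phases
and stitched with a 0.25-s linear crossfade to avoid edge clicks —
spectra, not waveforms, are what downstream assertions consume.  EMG
is white noise whose per-epoch RMS is lognormal around the state
level (median 4.0 for WAKE vs 1.0/0.7 for NREM/REM, geometric SD 1.3
vs 1.1): muscle tone fluctuates within states, and the separation
makes EMG-based wake detection reliable without being trivial.  The
generator does **not** emulate movement/chewing artifacts, electrode
drift, spindles or slow-oscillation events, or inter-individual
spectral differences beyond what its parameters express — so passing
tests certify the pipeline's arithmetic and its state logic, not
robustness to real-world artifacts.

## Amplicon editing quantification

Reads are classified against a reference and an *edit specification*:
the programmed substitution set (the desired edit, possibly with
silent mutations) plus a half-open window on the reference for indel
calling.  Alignment is optimal global alignment with affine gaps
(match +2, mismatch −1, gap open −6, gap extend −1; a gap of length
$L$ costs $6 + L$), delegated to Biostrings' pairwise aligner and
verified in the tests against an independently coded full-matrix
Gotoh DP.  Classification precedence is total and deterministic:
**indel** (any insertion/deletion overlapping the window) >
**edited** (all programmed substitutions present and *no other
difference anywhere in the window* — for multi-substitution specs a
partial install is not "edited") > **other_sub** (any other
substitution in the window) > **unedited**.  Differences outside the
window never affect the category; the treatment of outside-window
substitutions varies between versions of the standard tools, so the
package pins the simplest consistent rule.  Rates are percentages of
total aligned reads: editing% = reads containing only the desired
edit / total; indel% = indel-containing reads / total.  Identical
reads are deduplicated before alignment, so cost scales with distinct
sequences.

The read simulator draws each read as edited (probability `p_edit`),
indel-bearing (`p_indel`, mutually exclusive), or unedited, then
applies per-base substitution errors at `p_error`.  Indels (1–6 nt by
default) are placed within ±20 nt of the edit site, mirroring where
nicking-induced indels arise; quantification of simulated data
therefore uses a window of ±30 nt around the edit so that every
programmed indel falls inside it.  Read qualities are constant
(quality modeling is out of scope).

## Open-field kinematics

Instantaneous velocity uses a trailing 4-frame sliding window: the
speed at frame $i$ is the path length over frames $i-3 \dots i$
divided by the window duration (window alignment is not dictated by
the method description; trailing is chosen and fixed).  Running
episodes are maximal runs of frames with velocity *strictly* above
the 5 cm/s threshold, and the average running speed is running
distance divided by running time (undefined when the animal never
runs).  Centre time counts frames in the closed central rectangle
(default the central 50% of the arena).  Tracking itself is out of
scope — input is a calibrated coordinates CSV.  The trajectory
simulator moves at piecewise-constant programmed speeds with a
drifting heading, reflecting off walls; reflections preserve path
length up to the fold at the boundary, which is why the path-length
recovery test allows 1%.

## Cleared-hemisphere plaque quantification

Probability maps are binarized at 0.2 (*strictly* greater than —
a voxel exactly at threshold is background), labelled by 26-connected
components (igraph over an index-shifted adjacency; flood fill is the
test oracle), and summarized per candidate: voxel count, centroid,
and the total/mean/population-SD of the probability.  Candidates are
retained iff $2 \le \text{voxels} \le 10000$ and
$\sigma/\mu \ge 0.1$, all bounds inclusive (the method statement
gives minima/maxima without strictness; inclusive is chosen and
documented — it matters only exactly at the bounds).  Population
rather than sample SD is used; the difference is visible only for
tiny components and the filter threshold applies to their ratio, so
the convention is stated rather than consequential.  A plaque is
*engulfed* if at least one member voxel lies in the binarized
microglia mask (no minimum overlap fraction is imposed), and the
global microglia-overlap metric is the overlapping plaque volume as a
fraction of total plaque volume.  Filtering operates at full
resolution: candidate classification precedes the alignment-related
preprocessing.  That preprocessing — 2×2×2 averaging downsample (after
cropping to even extents), intensity capping, then an isotropic
Gaussian blur with σ = 2 voxels — is provided as the registration
front-end; registration itself is replaced by accepting a precomputed
region-label volume, against which plaques are assigned by nearest-
voxel centroid lookup (label 0 = unassigned).  The blur uses a
separable kernel truncated at 4σ with replicate-edge padding, so
constants are preserved exactly and the interior response matches the
closed-form sampled Gaussian.

The volume simulator places well-separated Gaussian blobs (peak
probability 0.6–0.95, radius 2–4 voxels by default) over sub-threshold
uniform background noise, overlaps a programmed fraction with
microglia blobs, and records ground truth — including *realized*
engulfment, since a randomly placed microglion may also touch a
plaque.  Placement uses bounded rejection sampling and errors out if
the requested packing is impossible.

## Editing-phenotype association

`pearson_ci()` implements the product-moment correlation with the
textbook inference reported alongside editing-vs-phenotype panels:
two-sided $p$ from $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df, and a 95%
CI from the Fisher transform $\tanh(\operatorname{atanh} r \pm
z_{0.975}/\sqrt{n-3})$.  It is verified against `stats::cor.test` to
$10^{-10}$.  Group summaries report sample SD ($n-1$) and SEM.
Mixed-model ANOVA and post-hoc machinery are deliberately not
re-implemented: they are off-the-shelf in any statistics package and
not a contribution of this codebase.

## Problem sizes and determinism

Every generator is a pure function of its integer seed (an internal
RNG scope restores the caller's RNG state), and the acceptance script
derives all of its seeds from a single `--seed`.  The cohort-level
experiment — two groups of 8 animals, one with the NREM delta bump
reduced by 20%, compared on dark-phase cross-state-normalized NREM
delta power over 100 replicates — runs the full signal pipeline
(synthesis → PSD → scoring → normalization) per animal on a
phase-balanced sample of 300 light + 300 dark epochs drawn evenly
across the day, a size at which the pipeline's per-animal delta
estimate is stable (the observed group separation is ~3 percentage
points against within-group SDs well below that) while keeping the
whole experiment to a few minutes.  Scorer-recovery checks use full
24-h recordings.  These sizes are the package's validation design,
stated here so they can be scaled in either direction.

## Known limitations

* The scorer is a stand-in: it validates the pipeline around it, not
  machine-learning scoring, and it assumes sleep-majority recordings.
* Cross-state normalization requires all three reference states in
  the day-1 light phase and fails loudly otherwise.
* EDF and NRRD containers are not read or written; signals,
  hypnograms and trajectories travel as columnar CSV, volumes as
  multi-page 32-bit-float TIFF.
* pegRNA-scaffold integrations are not detected separately; such
  reads classify as indels.  Demultiplexing, paired-end merging and
  quality trimming are upstream of this package.
* Atlas registration is out of scope; region assignment expects a
  label volume already on the data grid.
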