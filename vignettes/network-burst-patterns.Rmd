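---
title: "Detecting and comparing network-burst propagation patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and comparing network-burst propagation patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meaburst)
```

## The problem

Dissociated cortical networks cultured on planar multi-electrode arrays
(MEAs; here the standard 8×8 layout with 200 µm pitch, 59 recording sites
and one internal reference) develop synchronized network bursts (NBs) from
the third week in vitro. An NB is an array-wide barrage of single-channel
bursts. NBs are not spatially random: each one starts at a *leader*
electrode, a small pool of *major leaders* (MLs) initiates most of them,
and the rank order in which electrodes activate — the *propagation
pattern* — recurs in a few stereotyped classes per culture. The package
quantifies this structure in spontaneous activity and asks whether
electrical stimulation re-evokes the same endogenous patterns.

This vignette documents the models and procedures, the parameters that
matter, the synthetic data the package tests itself against, and the
numerical choices made where the underlying methods leave latitude.

## Burst and network-burst detection

Single-channel bursts are found with the logISI method. For each channel
with at least 10 inter-spike intervals we build a histogram of log10(ISI)
(10 bins per decade, smoothed with a 3-bin moving average). Bursty channels
show a bimodal histogram: an intra-burst peak at short ISIs (required below
100 ms) and one or more peaks at longer intervals. Scanning the later peaks
in ascending ISI, the first valley whose *void parameter*

$$v = 1 - \frac{h_{min}}{\sqrt{h_{peak1}\, h_{peak2}}}$$

reaches 0.7 sets the channel's intra-burst ISI threshold; channels without
such a valley fall back to 100 ms. Scanning for the *first* qualifying
valley (rather than the globally deepest one) keeps thresholds tight to the
intra-burst peak, which matters because every millisecond of threshold is a
window in which a stray background spike can attach itself to the front of
a burst and masquerade as an earlier activation. A burst is then a maximal
run of at least 3 spikes with consecutive ISIs at or below the threshold.

Network bursts chain single-channel bursts that overlap or follow within
`nb_chain_ms` (default 100 ms — "quasi-synchronous" is not a quantity, so
this is an explicit, config-exposed choice). A chain is an NB when it
spans at least ⌈0.20 × active channels⌉ distinct channels, where a channel
is *active* if its firing rate strictly exceeds 0.1 spikes/s. Each
participant's activation time is the first spike of its earliest burst in
the chain; the first-activated electrode is the leader, delays are measured
from it, and the activation order (ties broken by label, flagged) is the
pattern used everywhere downstream. Channels that spike without bursting
are not part of the pattern.

Leadership scores are percentages of NBs led; the ML rule (LS ≥ 4%) is
inclusive at the boundary, as are the 20% participation rule and the ≥ 50%
response-reliability rule, while the 0.1 spikes/s activity rule and the
"area lower than 1" exclusion are strict. These boundary conventions are
asserted verbatim in the test suite.

## Stimulus-response analysis

PSTHs use a 500 ms window with 2 ms bins, averaged over trials, per
(stimulating electrode × recording electrode). The PSTH area is the mean
number of in-window spikes per stimulus; channels with area below 1 are
excluded as non-responding. Two complementary normalizations serve two
comparisons: dividing each channel's areas across stimulating sites by the
channel maximum compares *stimulation from* MLs versus followers; dividing
each site's areas across channels by the site maximum compares *responses
of* MLs versus followers. First-spike latencies reuse the identical
machinery.

Evoked responses have an early, directly driven component (first tens of
ms, few channels, high reliability) and a late network-wide component. The
separation is adaptive per stimulating electrode: the network PSTH (sum of
responding channels) is smoothed with a 20 ms moving average (centered
10-bin window on the 2 ms grid, truncated at the edges), local maxima are
detected (plateau-aware, with a minimum height of 5% of the global maximum
to suppress ripple — the underlying procedure says only "detected all
peaks", so the prominence floor is our explicit choice, config-exposed),
and the highest peak at ≤ 50 ms and the highest later peak delimit the
search for the lowest local minimum between them. The separation index
`s = 1 − h_min/√(h_peak1 h_peak2)` accepts the split at s ≥ 0.3; the
minimum's position `x_min` then becomes the early/late boundary for all
responding channels of that site. Evoked NB patterns are extracted per
trial from the (x_min, 500] window with the same burst machinery and the
same 20% participation rule, delays measured from stimulus onset; a
stimulated channel is analyzed further only if at least half of its pulses
evoke a pattern.

## Normalized pattern distance

The raw dissimilarity between two activation orders is the unit-cost
Levenshtein edit distance (insertions, deletions, substitutions), bounded
by the longer length. Because raw distances depend on the two lengths and
on how many electrodes the patterns share, each pair is normalized against
its own permutation null: both sequences are independently shuffled 200
times, and the normalized distance is the fraction of null distances at or
below the observed one — a permutation p-value. Small values mean the pair
is more similar than chance; 0.05 is the significance level throughout.

Two implementation decisions deserve explanation:

* **Tie handling.** The edit distance between shuffled sequence pairs is
  strongly discrete — for two random orders of similar length the null
  often concentrates on three or four integer values. If null distances
  *equal* to the observed one are not counted (the "strict" reading of
  "distances lower than the original"), the boundary mass makes the test
  anti-conservative: we measured ~11% of chance pairs flagged at the 5%
  level, and fully disjoint patterns — where every shuffle ties the
  observed distance — come out maximally *similar* (p = 0). Counting ties
  (the standard permutation-test convention) restores validity (~3%
  empirical rate at the 5% level, measured in the test suite) and sends
  disjoint patterns to p = 1, which is the behavior every downstream ratio
  assumes. `tie_counting = "inclusive"` is therefore the default, with
  `"strict"` available for comparison. Identical patterns are defined to be
  at distance 0 (identity), regardless of counting mode.
* **Null caching.** The null depends only on the two lengths and the
  shared-symbol count (verified as a property test), so null samples are
  cached on that key with a per-key derived seed; entries are then
  independent of evaluation order. `cache_nulls = FALSE` reproduces exact
  per-pair nulls.

Spontaneous distance matrices are truncated to the first 2500 NBs in time;
per-pair sub-stream seeding makes matrices bit-reproducible for a fixed
master seed.

## Pattern clustering

Clustering is two-stage. *Core finding*: the pattern with the most
significant neighbours (normalized distance < 0.05) seeds a core of itself
plus those neighbours. Since a fraction α of unrelated pairs is significant
by construction, the candidate core is pruned for consistency — members
significantly similar to fewer than half of the other members are dropped
until stable — and retained if at least `min_core_size` (default 5) members
remain; the procedure repeats on the remainder. *Template matching*: each
remaining pattern joins the core with the smallest median normalized
distance to the core's members, provided that median is below 0.05;
otherwise it stays unclassified and is excluded from every downstream
ratio. The median (rather than distance to a single centroid) is robust to
core outliers and is config-switchable. Per-cluster delay maps take each
electrode's median delay over the members it participates in, flagging
electrodes present in fewer than half the members as low-support.

## Evaluation

Group similarity is always the ratio of significantly similar pairs over
all pairs (within-group: unordered pairs; between-group: cross pairs).
Chance levels come from shuffle controls that permute each pattern's symbol
order and recompute the target ratio (default 100 repeats; their 95th
percentile is the reference line). Spontaneous-vs-evoked similarity is
computed per stimulated channel as the maximum cross-ratio over spontaneous
clusters; channels above the conservative 10% threshold (strict) are
classed as evoking a spontaneous-like pattern, and the matched spontaneous
cluster is the arg-max. ML involvement metrics cover the relative
recruitment order of each ML in evoked patterns (normalized rank, 0 =
first; raw rank available via `relative_order = FALSE`), the per-site
normalized early-response PSTH area (bins at or below x_min), and the
stimulated-electrode-to-ML distance in µm; an ML "drives" a cluster when it
leads at least 10% of that cluster's bursts. Group comparisons check
normality first (Kolmogorov–Smirnov at 0.01) and otherwise use
Mann–Whitney or Kruskal–Wallis with Holm-corrected pairwise rank tests.
Classical MDS (`cmdscale`) provides the 2-D embeddings with a normalized
stress value.

## The synthetic-data generator

The generator emulates the population statistics the analysis assumes:
~19 NB/min spontaneous rate (renewal process: gamma shape 2 on top of a
300 ms refractory floor, so consecutive NBs never merge in ground truth),
pseudo-lognormal background rates (default mean 1.5 spikes/s, so that
background plus in-burst spikes lands near the observed ~4.5 spikes/s mean
channel rate), a small pool of planted leaders, a few recurring propagation
templates, and stimulation sessions of pulses at 0.2 Hz with early
responses at 2–20 ms on the stimulated electrode's neighbourhood followed
by a late NB drawn from the template whose leader pool is geometrically
closest to the stimulation site.

Design choices that emerged as load-bearing during validation:

* **Templates are distinct motifs by construction.** A template's
  propagation order is redrawn until its shuffle-normalized distance to
  every earlier template is at chance (≥ 0.5). Without this, roughly one
  in five random template pairs is genuinely similar by chance and no
  clustering method could recover the planted labels.
* **Leaders open the motif.** Leader-pool electrodes take delays 0, 1.5,
  3 ms; all other members start at 15 ms or later, well above the default
  5 ms activation jitter, so the sampled leader is also the realized
  first-firing electrode. Delays sit on the 0.1 ms acquisition grid
  (10 kHz) and ground-truth orders are computed after snapping to it, so a
  noise-free simulation reproduces template orders exactly through the
  whole detection chain.
* **Intra-burst ISIs are 5–20 ms** (truncated exponential, ~10 ms mean).
  Heavier ISI tails push the logISI valley — and with it the window in
  which background spikes can prepend a burst — far to the right, which
  corrupts realized leadership.

What the generator does *not* emulate: dead or weakly coupled electrodes
(in simulations essentially all 59 channels are active, versus ~50 in real
cultures), rate-dependent burst structure (background is homogeneous
Poisson, so very hot channels can assemble spurious chance-NBs — visible as
a small extra cluster in the worked example), electrode noise, and any
biophysics of propagation. Passing recovery tests therefore demonstrates
that the chain is correct and well-calibrated under its stated assumptions,
not that it is robust to every pathology of real recordings.

## Validation conditions and problem sizes

The test suite validates, among others: exhaustive agreement of the edit
distance with a recursive oracle (all distinct-symbol sequences over a
4-letter alphabet, plus randomized cases with repeats and 1000
metric-axiom triples, plus `utils::adist` as an independent
implementation); null calibration on 500 chance pairs of common 30-symbol
permutations at 200 shuffles; NB recall and precision ≥ 0.95 with exact
planted-ML identification on 10-minute simulations at 20 NB/min, 5 ms
jitter, 10% dropout, 0.5 spikes/s background; clustering recovery of K = 4
templates over ~200 NBs at adjusted Rand index ≥ 0.9 (60 shuffles in the
test profile); early/late threshold recovery inside the planted 20–60 ms
gap in ≥ 95% of 40 sessions; end-to-end positive controls (stimulation
sharing spontaneous templates classed similar, above the shuffle control's
95th percentile) and negative controls (distinct templates classed
different); and byte-identical pipeline reruns under a fixed seed. These
sizes keep the default suite within a few minutes while leaving each check
statistically meaningful; all of them scale up through the same functions.

## Known limitations

Per-NB leader identification degrades gracefully with background rate (a
stray spike within one intra-burst threshold of a burst's first spike
claims the lead); aggregated leadership scores are robust to this, which is
why ML identification is defined on scores, not single events. The
normalized distance inherits the discreteness of the edit distance; ratios
between short patterns (few shared symbols) are lumpy and should be read
with their shuffle controls, not against the nominal 5% level alone. The
clustering seed-selection rule and minimum core size are heuristics; both
are exposed in the configuration and the recovery tests quantify their
behavior only under the generator's assumptions.
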