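---
title: "Minimum-spanning-tree connectivity of brain and gut-microbiota networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimum-spanning-tree connectivity of brain and gut-microbiota networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutbrainmst)
```

## The question and the statistic

The package compares the connectivity of two networks — resting-state
brain cortex activity (BCA) and gut microbiota (GM) composition — between
children with High and Low animal protein/lipid intake. Both systems are
reduced to weighted undirected graphs and summarised by a single number,
the total weight of the minimum spanning tree (MST):

$$ W(T^{*}) \;=\; \min_{T \in \mathcal{T}(G)} \sum_{(i,j)\in T} w_{ij}, $$

where $\mathcal{T}(G)$ is the set of spanning trees. The MST is attractive
for cross-system comparisons because it is invariant to node relabeling,
uses every node exactly once, and — unlike degree- or centrality-based
summaries — does not change meaning with network scale. Groups are
compared by

$$ \Delta\% \;=\; 100\,\frac{W_\mathrm{high}-W_\mathrm{low}}{W_\mathrm{high}}, $$

with the high-intake group as baseline, so a positive value means the
low-intake group's backbone is lighter. The baseline choice is a
convention; we fix it once and report signed values (some bands can come
out negative).

## Intake estimation and the mean split

Monthly grams of animal protein and lipid are accumulated from
food-frequency portions as
$(30\,d + \tfrac{30}{7}\,w)\times \text{g/portion}$, summed over the eight
tracked foods (milk, yogurt, pork, beef, chicken, egg, butter, fish). The
30 and 30/7 factors are the package's convention for a 30-day month; both
are arguments of `compute_monthly_intake()`.

Children are split at the sample mean: strictly above the mean is High,
everything else Low. A value exactly at the mean therefore falls to Low —
the tie rule follows from defining High as "above the mean". The split is
deliberately crude (it is how small-cohort field studies often
dichotomise) and the per-group $n$, mean and SD are returned so the reader
can judge the separation. Group differences use Welch's unequal-variance
$t$ by default: with the unequal group sizes the mean split produces,
pooled-variance $t$ would overstate the statistic, and
`welch_t_summary()` reproduces published group-summary statistics far
more closely than a pooled version does. The Mann-Whitney $U$ option
(`group_compare()`) reports the smaller of the two $U$ orientations with
midranked ties.

## qEEG band power

The band-power chain is deliberately plain:

1. **Filter** 1–40 Hz, 4th-order Butterworth applied forward and backward
   (zero phase, ~48 dB/octave effective rolloff).
2. **Epoch** into non-overlapping 2-s windows. Epoch length is a
   compromise: long enough for a 0.5 Hz resolution (so the 1–3 Hz delta
   band spans five bins), short enough that dropping an epoch costs little
   data. It is an argument, not a constant.
3. **Reject** epochs whose per-channel variance z-score (computed across
   epochs, per channel) exceeds 3 on any channel. Variance is the right
   scale for the gross movement/electrode artifacts this stage targets;
   the threshold is one-sided because artifacts inflate variance. The
   stage warns when fewer than 39 s of clean data remain — the minimum
   retained duration the analysis is designed around.
4. **Band power** per channel: Hann-tapered periodogram per epoch,
   normalised so bin powers sum to the windowed signal variance; power is
   summed over bins whose centre frequency lies in Delta (1–3), Theta
   (4–7), Alpha (8–14) or Beta (15–30 Hz), edges inclusive, then averaged
   over epochs. Power is absolute (µV²), not relative.
5. **ROI log power**: arithmetic mean of each ROI's three electrodes'
   absolute power, then natural log. Averaging before the log keeps the
   ROI value interpretable as log mean power; the alternative order
   (mean of logs) differs by Jensen's gap and is easy to obtain by mapping
   `log()` earlier if wanted. Natural log is a fixed convention — any
   monotone rescaling would only shift the MI inputs.

The five ROIs are fixed electrode triples of the 10–20 montage: left
anterior (Fp1, F3, F7), right anterior (Fp2, F4, F8), left posterior
(P3, T7, O1), right posterior (P4, T8, O2), midline (Fz, Cz, Pz).

## The MI network and its estimator

For one band, eye condition and intake group, the network's edge weights
are mutual information between ROI log-power vectors **across the group's
subjects** (one observation per child). This across-subject reading is the
only one that yields one network per band × condition × group, matching
how per-group brain networks are compared; it means edge weights are
population-level dependence estimates on 9–22 observations, which is why a
bias-corrected estimator and a null model matter.

`bcmi()` estimates MI by Gaussian-product-kernel density estimation at the
sample points with a jackknife bias correction:

$$ \widehat{I}_{BC} = n\,\widehat{I}_n - (n-1)\,\overline{\widehat{I}_{n-1}}, $$

where $\overline{\widehat{I}_{n-1}}$ averages leave-one-out estimates.
The correction removes the leading $O(1/n)$ bias, so independent data
scatter around zero and **negative estimates are legitimate** — they are
kept, both as matrix entries and as MST edge weights (they simply sort
first in Kruskal's algorithm).

Two numerical choices are the package's own:

- **Bandwidth** $h = 1.35\,\min(\mathrm{sd}, \mathrm{IQR}/1.349)\,
  n^{-1/5}$ per variable, a scaled Silverman rule. The factor 1.35 (vs
  Silverman's 0.9) was fixed during estimator design so that the two
  calibration properties hold simultaneously: mean estimate within
  ±0.02 nats of zero for independent Gaussian pairs at $n = 100$, and
  agreement with the closed form $-\tfrac12\log(1-\rho^2)$ within a few
  percent at $\rho = 0.9$, $n = 5000$. Smaller factors leave a positive
  residual bias on independent data; larger ones oversmooth the joint
  density and pull the dependent-data estimate down.
- **Degenerate inputs**: constant vectors are an error (the estimator has
  no meaningful answer), and near-zero leave-one-out densities are clamped
  at the smallest positive double before the log.

Exact numerical parity with any particular published MI implementation is
not claimed; the estimator is specified by the formulas above and
validated against the Gaussian closed form.

## Kruskal's MST and determinism

`minimum_spanning_tree()` implements Kruskal's algorithm with a stable
sort on (weight, lexicographic node pair), so tied weights — common with
integer co-occurrence counts — always resolve the same way and reruns are
bit-identical. Negative weights need no special casing. Disconnected
inputs are an error that lists the components; the GM wrapper (`gm_mst()`)
instead restricts to the largest connected component with a message,
because zero co-occurrence legitimately disconnects sparse groups. The
implementation is tested against exhaustive enumeration of all spanning
trees on graphs of up to 6 nodes and against an independent graph
library's MST.

## The gut-microbiota network

Counts are rarefied to a fixed depth (21,000 reads by default) by seeded
subsampling without replacement; shallower samples are dropped with a
warning. Alpha diversity (Shannon in nats, observed ASVs) with Welch tests
between intake groups is reported as a compositional sanity check — the
connectivity comparison is meaningful precisely when composition looks
similar.

A random forest classifying High vs Low intake screens ASVs by Mean
Decrease Gini; the count of ASVs with importance strictly greater than
zero is reported as the "informative" count. Strictly-positive is the
natural reading of "contributes information" but the cutoff is recorded
here as a choice; the full importance table is returned so any other
threshold can be applied. The forest is an exploratory screen only — the
network uses the complete ASV set, because the screen shows the intake
signal is distributed rather than concentrated in a few taxa.

Within each group, presence is `count >= 1` after rarefaction
(configurable), and each ASV pair's observed co-occurrence count $j$ is
referred to the hypergeometric law given the incidences $N_1, N_2$ in $N$
samples:

$$ P(j) = \frac{\binom{N_1}{j}\binom{N-N_1}{N_2-j}}{\binom{N}{N_2}}. $$

The **edge weight is the observed co-occurrence count** itself. This is
the most direct "co-occurrence matrix as weights" construction; the
centred alternative (observed − expected) is available behind
`weight_type = "obs_minus_exp"`. Each group's network is built on its own
present ASVs, so node counts can differ between groups — which is exactly
the situation the null model below addresses.

## The random-subnetwork null

With 31 children split 11/20 (protein) or 9/22 (lipid), any group
difference could in principle reflect group size alone: under homogeneous
weights the expected MST weight *grows* with node count (a property the
test suite checks by Monte-Carlo), and the larger group here is the
low-intake one. `random_split_null()` therefore resamples subjects: for
each of $k$ replicates it randomly partitions the cohort into sizes $n$
and $m$, recomputes the full statistic (band power subset → MI matrix →
MST weight) on each side, and records the difference. The one-sided
empirical p value uses the add-one correction $(r+1)/(k+1)$. Resampling
subjects — not edges — is the only construction that honours "randomly
divide the data into two groups", because the MI matrix must be recomputed
per replicate. Note the size argument also explains why a *smaller*
high-intake group with a *heavier* MST is the interesting direction: the
size effect works against it.

## The synthetic cohort

The generators exist so the whole pipeline is testable without the study's
recordings. Defaults mirror the study conditions: 31 children (11 High /
20 Low), 19-channel 10–20 EEG at 512 Hz, both eye conditions, ASV tables
deep enough for 21,000-read rarefaction, and planted monthly protein
levels of 407.48 (High) and 211.94 g/month (Low) — the published group
means.

- **EEG**: each band carries band-limited noise (white noise filtered into
  the band — matching the Fourier pipeline and avoiding the spectral
  leakage a sum of sinusoids would concentrate at single bins). Channels
  of one ROI share a common series (fixed mixing 0.7); the group's
  coupling $c$ enters twice: as a subject-level shared series mixed into
  every ROI with fraction $c$, and as a shared component (fraction $c$) of
  the per-band log-amplitude across ROIs. The second mechanism is what
  makes ROI *band powers* dependent across subjects — the quantity the MI
  network measures — and makes the planted dependence an analytically
  controllable knob: the across-subject correlation of log ROI power is
  approximately $c$.
- **ASV tables**: within each group, exactly half of the samples carry a
  latent community state; each ASV's presence copies its sample's state
  with probability equal to the group's co-occurrence strength, otherwise
  it is an independent coin flip. Fixing the number of state-carrying
  samples (rather than drawing it binomially) removes a variance component
  that would otherwise let a small group's planted association collapse by
  chance. Counts are multinomial over a shared log-normal abundance
  profile at exactly `depth` reads. At strength 1 pairs are fully linked;
  at strength 0 all pairs are independent.
- **FFQ**: random sparse portion frequencies scaled so implied protein hits
  the child's planted level; lipid follows through the composition table,
  with butter (protein-free) varied independently so the two nutrient
  splits correlate without coinciding. The planted SD is 40 g/month —
  chosen so the two levels are separable enough that the mean split
  recovers planted membership for ≥95% of children, which is the property
  the generator exists to provide; published within-group spreads are
  somewhat wider, so recovery on real data would be less clean.

What the synthetic cohort does **not** emulate: real EEG artifacts beyond
variance outliers (no blinks, muscle, line noise), volume conduction,
taxonomic structure or realistic abundance distributions, and any
child-level correlation between diet and brain/microbiota beyond the
planted group labels. Passing tests therefore demonstrate that the
pipeline recovers effects of the planted kind and stays calibrated without
them — not that effects of this kind exist in any particular real cohort.

## Problem sizes used in tests and the acceptance script

Unit tests run the EEG chain at 128 Hz for 12–20 s per subject and
microbiome tables of 30–80 ASVs; the acceptance script runs the full
31-child cohort at 128 Hz / 20 s with the full 21,000-read rarefaction
depth, 199 null replicates, and 50 seeded replicates for effect-recovery
rates. These sizes are the package's simulation choices: the band-power
and MI stages are invariant to sampling rate and duration beyond estimator
noise, so nothing scientific hinges on the full 512 Hz / 5 min recordings,
while the microbiome stage runs at full size throughout.

## Known limitations

- MI across subjects on 9–22 observations is noisy; the jackknife makes it
  approximately unbiased but not precise. The null model, not the point
  estimate, carries the inferential weight.
- The mean split discards intake magnitude; with skewed intake the groups
  are unbalanced by construction.
- Raw co-occurrence counts scale with group size; the per-group MSTs are
  therefore compared against the size-aware null rather than taken at
  face value.
- `rarefy_counts()` subsamples once per seed; averaging over repeated
  rarefactions is not implemented.
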