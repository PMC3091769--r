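---
title: "Promoter chromatin states from tiled ChIP microarrays: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter chromatin states from tiled ChIP microarrays: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promstate)
```

## The problem

Promoter tiling arrays (ChIP-chip) measure the enrichment of
immunoprecipitated chromatin — here for three histone modifications,
H3K4me3, AcH3 and H3K27me3, plus total histone H3 — on ~50-mer probes
tiled at ~100 bp across a window around each annotated transcription
start site (TSS). In myeloid differentiation studies, monocytes (MO) are
cultured into macrophages (MF) or dendritic cells (DC), and the question
is how the combinatorial state of these three marks at each promoter
relates to transcription and how it changes during differentiation.

`promstate` implements the complete analysis chain for such a design:
probe normalization, permutation peak calling, peak-to-promoter
assignment, TSS metaprofiles, 8-way combinatorial state classification,
state-transition dynamics, and expression statistics — together with a
seeded synthetic-data generator that plants known ground truth, so that
every stage can be validated quantitatively without access to any
platform data.

## Signal model and normalization

Probe intensities are positive, linear-scale values per
(cell type, antibody) channel. Normalization has three stages:

1. **Background scaling** (`background_normalize`). Each channel is
   multiplied so that the median intensity of its random genomic
   (background) probes equals the grand median of all channels'
   background medians. The target ("normalized to random genomic
   background") names what is removed, not an estimator; we chose a
   multiplicative median scaling because intensities are ratio-scale and
   a multiplicative per-channel gain is the dominant inter-array
   artifact. An additive variant was considered and rejected: it can
   produce non-positive intensities, which break the log-ratio stage.
2. **H3 normalization** (`h3_normalize`). The track value at each probe
   is `log2(modification) − log2(H3)`, controlling for nucleosome
   occupancy and probe behaviour. No pseudocount is added; non-positive
   intensities are rejected rather than floored, because a silent floor
   distorts exactly the low-signal probes that matter for the repressive
   mark.
3. **Differentiation delta** (`differentiation_delta`). For dynamics,
   the monocyte track is subtracted probe-wise from the MF or DC track
   of the same modification, giving gain (positive) or loss (negative).

The composition of stages 1–2 is invariant to any per-channel rescaling
of the input (the common reference cancels in the log ratio); this is a
tested property, not an assumption.

## Peak calling

Peaks are found by a transparent sliding-window permutation scan
(`call_peaks`), replacing the closed-source scanner traditionally used
with this array type:

* windows of `min_probes = 4` consecutive probes within one promoter
  tile, scored by their mean track value;
* a null distribution of window scores obtained by permuting probe
  values within each chromosome (`n_permutations = 200`, seeded);
* the smallest score threshold whose estimated false-discovery
  proportion — mean permuted windows at or above it per permutation over
  observed windows at or above it — is ≤ `fdr = 0.05`;
* significant windows sharing at least one probe merge into a peak whose
  score is the mean over merged probes. Ties with the threshold count
  against significance.

Two consequences are worth knowing. First, permuting *within
chromosome* keeps genuinely enriched probes in the null pool, so the
null is conservative on arrays where a large fraction of promoters carry
a mark; empirical FDR on synthetic data is therefore far below the
nominal 0.05, at some cost in sensitivity for the most prevalent mark.
Second, window scores are means, so adding a constant to every probe
shifts every peak score by that constant and never changes which peaks
are called (shift monotonicity; tested).

`gene_delta_score` applies the same windowed mean to a delta track and
reports, per promoter, the windowed mean of largest magnitude with its
sign — the per-gene gain/loss statistic used for cluster summaries.
Promoters with no probes are reported "uncallable", which is distinct
from "unmarked".

## From peaks to states

A promoter is **marked** by a modification when any peak overlaps its
window — 2000 bp upstream to 500 bp downstream of the TSS,
strand-aware, 0-based half-open — by at least 1 bp (`assign_peaks`).
The three boolean marks give one of eight combinatorial states
(`classify_states`): none, K4, Ac, K27, K4+Ac, K4+K27 (the bivalent
state), Ac+K27, K4+Ac+K27. `state_frequencies`, `mark_correlation`
(Pearson, on binary calls by default or on continuous scores),
`transitions` and `persistence_summary` quantify composition,
co-occurrence and dynamics. `expression_enrichment` ranks genes by mean
expression, takes top-*n* and bottom-*n* sets (ties broken by stable
gene-id order) and tests the 2×2 set-by-mark table with the two-sided
exact hypergeometric (Fisher) test; the test choice is ours — the
original analyses of this design do not name theirs — and it is
verified against exhaustive enumeration on all small instances.

## Expression analysis

`rank_invariant_normalize` scales each array to a reference using the
median signal ratio over genes whose expression rank matches the
reference within 5% of the gene count. Because ranks are invariant
under a global scaling, the iteration converges immediately; it still
verifies convergence defensively. `call_differential` uses the ratio of
arithmetic means (linear scale) as fold change and a two-sided
two-sample t-test on log2 replicates; calls require fold ≥ 2 (inclusive)
and p < 0.05, with no multiple-testing correction by default — the
selection criterion is deliberately the raw fold + P pair, and a
Benjamini–Hochberg option exists for users who want it.

The t-test defaults to the **pooled** (equal-variance) form rather than
Welch. With 2–3 replicates per group the Welch degrees-of-freedom
estimate is extremely noisy and the test runs well below its nominal
size (empirically ~0.037 at 3v3 for nominal 0.05), whereas the pooled
test is exactly calibrated when replicate counts are equal and
variances comparable — which is the design here. `var_equal = FALSE`
restores Welch for genuinely heteroscedastic designs.

## The synthetic-data generator

`simulate_dataset` emulates the study design; its defaults *are* the
study conditions, chosen once and not revisited:

* **Geometry.** 2.5 kb promoter windows (−2000..+500), 50-mer probes at
  100 bp spacing (25 probes/promoter), background probes in gene-free
  chromosome head regions; TSS spacing guarantees windows never overlap.
* **States.** 8-state priors for monocytes with marginals K4 ≈ 44%,
  Ac ≈ 31%, K27 ≈ 24%, no mark ≈ 36%, K4+Ac ≈ 26%, K4+K27 ≈ 5.5%,
  K27-alone ≈ 16%. Published genome-wide percentages for this system
  are rounded and mutually over-constrained, so these priors are an
  emulation that reproduces the magnitudes, not a fit. Derived cell
  types are drawn gene-wise from the *monocyte* state through an 8×8
  row-stochastic kernel — a star topology, because MF and DC are both
  derived from MO and compared to it independently, not sequentially.
  The default kernel makes the K4+Ac double mark persistent (0.75
  retained), lone K4 and lone Ac unstable (80% and 85% leave,
  mostly to "none" or to the double mark), and lone K27 stable (0.85).
* **Signal.** Lognormal baseline with geometric mean 1000; active marks
  gain `peak_height = 2` log2 units in two lobes at −800..−200 and
  +100..+400 bp around the TSS with a 50% dip (`tss_dip_depth = 0.5`)
  in between, reproducing the bimodal active-mark metaprofile with its
  TSS dip; H3K27me3 enrichment is uniform over the window; Gaussian
  noise of sd 0.5 on the log2 scale per probe and channel.
* **Expression.** Three replicates per cell type (donor/replicate
  counts for such designs are rarely stated; three is a typical array
  study size and the package requires at least two), lognormal around
  per-state log2 means ordered K4+Ac > K4 ≈ Ac > bivalent > none > K27,
  sd 0.5.

What the generator does **not** model: probe sequence effects and
cross-hybridization, dye/scanner physics, spatial artifacts,
correlated noise between neighbouring probes, multi-isoform TSSs, and
copy-number variation. Passing recovery tests therefore demonstrates
the correctness and calibration of the algorithms under the declared
signal model, not performance on any particular laboratory dataset.

## Numerical choices and degenerate inputs

* All interval logic is 0-based half-open, including the ±1
  bookkeeping for minus-strand promoter windows
  (`[tss − 499, tss + 2001)`); windows clip at position 0.
* Probe midpoints are the binning coordinate for metaprofiles
  (bin width 50 bp); empty bins report NA means with n = 0.
* Zero-variance vectors in `mark_correlation` yield NA entries with a
  warning, never a silent 0.
* Transition tables exclude genes lacking a state in either endpoint
  and report the excluded count; empty starting states give NA
  fractions, flagged rather than dropped.
* Permutation ties at the peak threshold are non-significant
  (conservative); `n_permutations < 50` is rejected.
* Problem sizes used by the validation suite — up to 2000 genes ×
  3 cell types × 4 channels for end-to-end runs, 20000 genes for
  marginal-recovery checks, 10000 genes for null calibration — were
  chosen so the complete suite characterizes every stage at
  well-resolved Monte-Carlo error on a single CPU.

## Known limitations

* The permutation null is conservative when a mark is very prevalent
  (see above); sensitivity for such marks is correspondingly lower at a
  fixed nominal FDR.
* One promoter per gene id is assumed; arrays mapping several promoters
  to one expression-array gene need pre-collapsing.
* The hypergeometric enrichment test treats mark calls as exchangeable
  across genes; co-regulation within genomic clusters mildly violates
  this, which is why cluster-level statements use `cluster_delta_summary`
  rather than promoter-level P-values.
* Peak scores are windowed means of log2 ratios; they are comparable
  within a track, and across tracks only after the shared background
  scaling.
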