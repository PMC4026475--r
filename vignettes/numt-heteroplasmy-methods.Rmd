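---
title: "Separating numts, heteroplasmy and polymerase error in cloned control-region sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating numts, heteroplasmy and polymerase error in cloned control-region sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numtscan)
```

## The problem

When the mitochondrial control region is PCR-amplified with universal
primers, cloned and sequenced, the resulting clone set is a mixture of three
signal sources:

* **authentic mtDNA haplotypes**, possibly heteroplasmic — one individual can
  carry point-variant haplotypes (sequence heteroplasmy) and variants
  differing in the copy number of the R2 tandem-repeat array of the CSB
  domain (length heteroplasmy);
* **numts** — nuclear copies of the control region that co-amplify with the
  mitochondrial target. Ancient numts have diverged substantially from their
  mitochondrial counterparts but, because the nuclear substitution rate is
  roughly an order of magnitude below the control-region rate, they
  accumulate little variation after translocation;
* **polymerase and cloning artefacts** — every clone is the descendant of a
  single template molecule, so Taq errors are not averaged out the way they
  are in direct sequencing.

`numtscan` implements one analysis stage per signal source, and a simulator
that generates clone sets with known ground truth so every stage can be
validated end to end.

## R2 array decomposition

The R2 array is an alternation of 11-bp motif classes (built-in inventory
`A`–`E`; members differ by one or two substitutions). `decompose_repeats()`
finds the best window of a clone parseable as full units — each within edit
distance 2 of an inventory motif — optionally interrupted by interior
literal segments shorter than one unit (a 5-bp partial unit occurs in
published arrays). The parse maximises, lexicographically, full units, then
exact-class units, then the fewest literal bases, with ties resolved to the
leftmost window; fuzzy units are assigned to the nearest class (ties to the
earlier label) and flagged. The invariants `array_length = 11·N + Σ|literals|`
and exact re-concatenation of the array substring hold for every
decomposition and are asserted in the test suite against an
exhaustive-phase brute-force oracle.

Numerical choices worth noting:

* **Unit tolerance 2**: the motif classes themselves differ by 1–2 bp, so a
  stricter tolerance fragments arrays while a looser one merges classes.
* **A window needs at least 2 full units**; the chance of two consecutive
  near-motif 11-mers in non-repetitive sequence is ~10⁻⁶ per position, so
  numt cores reliably return `N = 0`.
* **Boundary literals are not inferred**: published structures and the
  simulator only produce interior partials; a structure that genuinely ends
  mid-unit round-trips its full-unit content.
* Period inference (`infer_period()`) counts exact k-mer recurrences
  (default k = 8) at each candidate spacing 5–50 and requires at least three
  supporting recurrences, so i.i.d. sequence returns `NA`.

## Distances and clades

K2P distances are computed with pairwise deletion after masking the R2
region (which cannot be aligned): `d = −½ln(1−2P−Q) − ¼ln(1−2Q)`, with the
per-pair transition (P) and transversion (Q) proportions retained for
audit. Net between-group divergence follows Nei:
`d_net = mean(between) − (mean(within_X) + mean(within_Y))/2`. Both the net
and the plain between-group means are reported, because published
divergence figures do not always state which of the two they are.

Clades are recovered by average-linkage clustering cut at the largest
relative gap between successive merge heights, accepted only when the mean
between-clade distance exceeds `min_ratio` (default 5) times the mean
within-clade distance. The deep numt/mtDNA splits in this problem are an
order of magnitude above within-clade variation, so any reasonable
partitioner recovers them; the gate exists so that weakly structured data
degrade to a single clade rather than to arbitrary splits. Bayesian tree
inference is deliberately not reproduced — posterior supports add nothing
to a partition this well separated, and model-based tree search is outside
the package's scope.

Haplotype relationships are displayed as a minimum spanning network over
mutational steps (substitutions, plus one step per contiguous gap run —
an indel of any length is one event). All co-minimal edges are kept, i.e.
the network is the union of all minimum spanning trees; the test suite
checks this against explicit spanning-tree enumeration. Statistical
parsimony connection limits are not implemented; for step counts between
haplotype groups the tie-keeping network serves the same role. Note the
gap-run convention makes step counts non-metric in degenerate all-gap
comparisons; within a clade of aligned cores this does not arise.

## Numt calling

A clade is called **numt** when at least 90% of its members lack the R2
array and the clade contains no anchor (an independently verified mtDNA
sequence, e.g. derived from long-range PCR). Anchors dominate: a clade
containing one is never called numt. Without anchors, the clade with the
highest repeat-bearing fraction is presumed mitochondrial. The 0.9
threshold rather than 1.0 tolerates decomposer edge cases without changing
calls in practice. Mean within-clade mutational steps are reported as
corroborating (not decisive) evidence, numts being expected to show fewer
steps because of their reduced post-translocation rate.

## Heteroplasmy calling and the error model

Per-clone polymerase errors are modelled as Poisson with
`λ = rate × length × cycles`; at the commonly assumed Taq rate of
7.2×10⁻⁵ /bp/cycle, a 724-bp fragment and 34 cycles give λ ≈ 1.77 — the
large majority of clones then carry at least one artefactual substitution,
so raw haplotype counting would call almost every individual heteroplasmic.
`call_heteroplasmy()` therefore cleans the clone set of one individual in
two steps before counting core (R2-masked) haplotypes:

1. **Site-support correction.** A clone's difference from the per-site
   majority consensus shared by fewer than 2 clones is reverted, provided
   the clone carries no more than `ceiling(λ + 2√λ)` such private sites
   (mean + 2 SD of the Poisson; ≈ 5 at λ = 1.77). True heteroplasmic
   variants recur in every clone of the minor haplotype and are untouched.
2. **Singleton collapse.** Haplotypes still supported by one clone and
   within the same threshold of the nearest multi-clone haplotype are
   folded into it. A haplotype supported by two or more clones is never
   removed, and a singleton beyond the threshold survives as a genuinely
   divergent haplotype (the pattern expected from paternal leakage is
   thereby reported, not suppressed).

The design question here was whether collapse alone suffices. It does not:
with λ ≈ 1.2 on the core, only ~29% of clones are error-free, so a planted
minor haplotype rarely appears as two identical clones and its
error-bearing singletons would always collapse into the major haplotype.
The site-support step restores the information that heteroplasmic variants
are *shared across clones* even when each carrying clone also has private
errors. At the default study conditions the simulator measures sensitivity
of about 0.94 with essentially no false positives.

Length heteroplasmy is called from the decomposed array lengths directly
(two or more distinct lengths among the individual's mtDNA clones); Taq
errors are substitutions only and cannot perturb it.

`summarize_recloning()` supports the experimental control for the error
model: re-cloning a single cloned fragment isolates artefacts, and every
difference from the clone-set consensus is an error. The Poisson zero class
`e^{−λ}` then predicts the fraction of clones identical to the consensus.

## The simulator and what it does (not) emulate

`simulate_dataset()` generates the study regime the analysis assumes: a
four-taxon history `((East,Hainan),(Central,septentrionalis))` sampled for
18 individuals (7/4/3/4), a stem lineage above the root split on which one
or two ancient translocations found numt lineages, heteroplasmic minor
haplotypes, slippage copy-number variation, and per-clone Poisson errors.
Key defaults and their reasoning:

* **Core 724 bp** — the length of the repeat-masked alignment the error
  model is quoted for.
* **Stem 0.22 expected subs/site, translocations at stem fractions 0.65 and
  0.90, numt rate factor 0.1** — chosen via the clock-model identities so
  the expected numt-vs-mtDNA net divergences sit near the published
  17–22% range; the between-numt divergence is then structurally smaller
  than either, reproducing the published ordering. A strict single-lineage
  clock cannot simultaneously match all three published percentages, so
  only the ordering (not the values) is asserted anywhere.
* **Numts lose the array at translocation.** The observable is that numts
  carry no tandem repeats; deletion at insertion is the simplest mechanism
  producing it. A decay mode would need parameters the data cannot inform.
* **numt-2 is the older lineage and receives amplification weight 0.8** —
  the older numt is closer to the universal-primer consensus, emulating the
  observed dominance of one numt clade in clone counts.
* **Minor haplotype frequency 0.4, differing at 2 core positions** — a
  minor variant must be common to be sampled among ~10 clones, and
  intra-individual variants are typically seen at one or two positions.
* **Slippage: geometric event count (p = 0.65), ±1 unit per event** — the
  observed within-individual copy-number classes differ by a few units;
  no published process model exists, so the simplest stepwise model is
  used.
* **Clones: 10 per fragment size class** — within the published 8–12 range.

Deliberate non-features: no core indels (the alignment's gap columns come
from the padded array region only), no substitution within repeat units
(motif-class evolution is not modelled; arrays change by copy number only),
no per-cycle PCR branching ("jackpot" errors), no chromatogram-level
double-peak emulation, and no paternal-leakage scenario — the analysis side
reports a divergent intra-individual haplotype when one occurs, but the
generator does not plant one. Passing tests therefore demonstrate correct
behaviour under this idealised regime, not robustness to alignment error or
recombination in real data.

## Problem sizes used in validation

The bundled validation runs use 20 simulated data sets of 364 clones each
(18 individuals × 2 fragment size classes × 10 clones + 4 anchors), full
K2P matrices over all clones, decomposition of every clone, and
per-individual heteroplasmy calls; plus 500 fuzzed arrays against the
brute-force decomposition oracle and spanning-tree enumeration up to six
haplotypes. These sizes keep the full suite around two minutes on one CPU
while leaving every assertion statistically comfortable.

## Known limitations

* The decomposer is built for control-region R2 arrays (unit length ~11,
  arrays up to a few hundred bp), not as a genome-scale tandem-repeat
  finder, and does not handle the R1 repeat of the ETAS domain.
* Distance-based clade partitioning assumes clade separation well above
  within-clade variation, which ancient numts provide; recent numts
  (divergence comparable to intraspecific variation) would require the
  anchor evidence to dominate.
* `call_heteroplasmy()` assumes clones of one individual share one
  alignment frame on the masked core; it does not realign.
* The published structure table ships verbatim; three of its rows are
  arithmetically inconsistent (run counts that contradict the printed `N`
  and length) and are flagged `consistent = FALSE` by `published_structures()`
  rather than silently corrected.
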