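---
title: "Simulating and detecting catastrophic genome rearrangements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and detecting catastrophic genome rearrangements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromocast)
```

## Background

Chromothripsis is a one-off catastrophic event in which a chromosome (or
chromosome arm) shatters into many fragments that are lost or rejoined in
essentially random order and orientation. Its genomic footprint is
distinctive: a dense cluster of rearrangement breakpoints confined to one
chromosome, junction orientations spread evenly over the four possible join
types, and a copy-number profile that oscillates between a small number of
integer states (typically two, because each lost fragment removes exactly one
copy from the affected homolog). Breakage–fusion–bridge (BFB) cycles, in
contrast, produce a stepwise *staircase* of copy-number increases toward the
affected chromosome end, terminal loss, and fold-back inversions — head-head
or tail-tail junctions whose two ends nearly coincide. Whole-genome doubling
(tetraploidization) leaves yet another arithmetical trace: structural variants
acquired *before* the doubling are themselves doubled and manifest as
copy-number switches of magnitude 2, whereas variants acquired afterwards
switch by 1.

`chromocast` implements this whole chain as testable, seedable code:

1. a **rearrangement simulator** operating on derivative chromosomes (ordered,
   oriented reference fragments) with exact ground truth for copy number and
   junctions;
2. a **sequencing emulator** producing the three observable layers used in
   cell-line screens — low-pass binned read depth, mate-pair junction calls
   with support and mapping-quality fields, and phased SNP allele counts;
3. a **segmentation and screening layer** (circular binary segmentation,
   integer copy-number calling, switch counting, the clustered-alteration
   flag);
4. the **chromothripsis caller** applying the three published criteria with
   temporal ordering relative to BFB and tetraploidization;
5. **haplotype-specific copy number** from phased allelic ratios; and
6. **cohort statistics** (exact Fisher, Welch *t*, permutation and exact
   multinomial tests).

## The simulator

A `cell_genome` holds one derivative chromosome per homolog, each an ordered
list of oriented reference fragments in 0-based half-open coordinates. Every
stochastic operation draws (or accepts) a seed and appends itself to an event
log, so `replay_events()` reproduces any genome bit-identically.

*Chromothripsis* (`simulate_chromothripsis()`) cuts a region of one homolog at
`n` uniformly drawn breakpoints, keeps each of the `n + 1` fragments with a
Bernoulli retention probability (re-drawn if everything would be lost — a
fully deleted region is a whole-arm loss, not chromothripsis), permutes the
survivors uniformly, flips each with probability 1/2, and reassembles them
between the intact flanks. Region coordinates are *derivative* coordinates, so
the event can be layered onto an already-rearranged homolog (e.g. after BFB).
The uniform-breakpoint and Bernoulli-retention assumptions are exposed as
parameters; nothing is known empirically about either distribution in real
catastrophes.

*BFB* (`simulate_bfb_cycles()`) is modelled per cycle as a terminal truncation
(the bridge break that unprotects the end) followed by appending a reversed
copy of a uniformly drawn terminal suffix (the sister fusion), emitting one
fold-back junction whose ends coincide; one extra truncation after the final
cycle leaves the end broken and deleted. This reproduces the staircase
amplification with terminal loss. Centromere mechanics are not modelled.

*Junction orientation* follows the side convention used in rearrangement
screens: a fragment's *head* is its low-coordinate side, its *tail* the
high-coordinate side. For an intra-chromosomal junction with left locus
$\ell <$ right locus $r$: (tail of $\ell$, head of $r$) is the T-H deletion
type, (head, tail) the H-T duplication type, (head, head) and (tail, tail)
the two inversion types, and any cross-chromosome join is "inter". Under this
convention a deletion emits one T-H junction, a tandem duplication one H-T,
an inversion one H-H plus one T-T, and a BFB fusion a fold-back H-H/T-T with
coinciding ends — properties the test suite checks by enumeration.

## The emulator

Read depth is Poisson: a bin of size $b$ at copy number $c$ receives
$\mathrm{Pois}(u\,c)$ reads with $u = \text{coverage} \cdot b /
(\text{read length} \cdot \text{ploidy})$. No GC or mappability bias is
modelled (real pipelines normalise these away upstream). Junction support is
Poisson in the spanning (physical) coverage times junction multiplicity per
homolog; end positions are jittered (Normal, default SD 300 bp) without ever
changing side labels or class; false positives appear at a configurable rate
(default 0.1/Mb, a free parameter — post-filter false-positive profiles are
not published). Phased sites follow a Poisson process (default 1/kb); site
depth scales with total copy number and the haplotype-A count is binomial in
the haplotype fraction.

Call curation mirrors standard mate-pair practice and keeps the published
thresholds: support of at least 4 pairs with median mapping quality at least
20 (both inclusive); calls of the same class merge when both endpoints differ
by less than 5 kb *and* their spans overlap reciprocally by more than 50%
(point-like fold-back calls and inter-chromosomal calls merge on endpoint
distance alone); somatic subtraction removes calls matching a control set
under the same identity rule.

## Segmentation

`cbs_segment()` is a circular binary segmentation: at each level the arc
$(i, j]$ maximising the two-sample mean-difference statistic is found (ties
broken toward the smallest index) and accepted when a permutation test gives
$p < \alpha$ (defaults $\alpha = 0.01$, 1000 nominal permutations). The
permutation loop stops early in both directions: once the exceedance count
guarantees $p > \alpha$ at the nominal permutation number, or once 200+
permutations have produced no exceedance (upper bound on $\hat p$ already
below $\alpha$). For segments longer than 1000 markers the arc search runs on
a decimated grid with the winning boundaries refined by an exact local
search; the permutation null uses the same gridded statistic, so the test
compares like with like. After recursion, adjacent segments whose means
differ by less than `undo_sd` robust noise SDs are merged back (smallest
difference first — this greedy order makes the segment count provably
monotone in the threshold), with the noise SD estimated as
$1.4826 \cdot \mathrm{median}|\Delta x| / \sqrt 2$. Segments below the marker
minimum merge into the neighbour with the closer mean.

Integer copy number anchors the per-copy ratio unit on the length-weighted
modal segment mean divided by the genome ploidy — the modal state of a genome
*is* its ploidy — and rounds half-to-even. Copy-number switches are counted
between consecutive segments of at least 500 kb; chromosomes with ≥ 10
switches are flagged as clustered-alteration candidates. Whether the 500 kb
rule applies to segment length or switch spacing is ambiguous in the
literature we follow; segment length is used here, and both thresholds are
configurable.

## The chromothripsis call

`call_chromothripsis()` is the package's central fit; it returns a classed
object with `print()`, `summary()` and `plot()` methods. Per chromosome:

* **Criterion 1 — breakpoint clustering.** All junction ends on the
  chromosome are tested against Uniform(0, length) with a one-sample KS test
  (exact null for $n \le 50$), Bonferroni-corrected across chromosomes with
  at least 3 breakpoints. Testing inter-breakpoint spacings against an
  exponential would be an alternative reading; the uniform-position test was
  chosen for its deterministic exact null.
* **Criterion 2 — randomness of joins.** The four intra-chromosomal class
  counts are tested against equal probabilities 1/4 with an exact multinomial
  test (total probability of all outcomes no more likely than the observed
  one; exhaustive enumeration up to $n = 60$, seeded Monte Carlo beyond).
  Random rejoining must *not* be rejected. Inter-chromosomal junctions count
  toward breakpoints (both ends) but are excluded from the multinomial, which
  is defined on the four intra-chromosomal types.
* **Criterion 3 — oscillation.** Within the affected span (the breakpoint
  range), the two most frequent integer CN states must cover at least 80% of
  the segmented span *and* alternate at least 5 times with at least two
  distinct states present. The alternation requirement is this package's
  choice: a flat chromosome trivially satisfies any coverage rule with a
  single state, so coverage alone cannot distinguish oscillation from
  quiescence.

A chromosome is called when it carries at least 10 breakpoints and satisfies
all three criteria. Chromosomes without segmentation are reported
`insufficient`; everything else is `no_call`. Defaults (`cast_config()`):
`min_breakpoints = 10`, `alpha_clust = 0.05` (Bonferroni),
`alpha_emt = 0.05`, `osc_coverage = 0.8`, `min_osc_alternations = 5`. These
are deliberately configurable: the full criterion text behind published
screens is not standardised.

**Temporal ordering.** For each junction the integer CN of the segments
enclosing its two ends gives the copy-number *jump*; a zero-jump fraction of
at least 0.7 classifies the event as having struck a previously intact
chromosome, otherwise a previously rearranged one. The lookup steps 1.5
median marker spacings *into* the joined fragment rather than querying the
breakpoint coordinate itself — segmentation places boundaries with roughly
one-marker uncertainty, and a query at the exact edge would land on the wrong
side of the boundary for a large fraction of ends. Ends in segments with
fewer than 5 markers are excluded. Fold-back junctions demarcating a
staircase that exceeds the chromosome's modal CN and ends in terminal loss
flag prior BFB cycles. Genome-wide, a hyperploid genome whose switch
magnitudes are dominated (≥ 0.7) by 1 indicates doubling *before* the
rearrangements; dominance of magnitude 2 indicates doubling after; the
annotation is NA for diploid genomes.

## Haplotype-specific copy number

Phased allelic ratios (haplotype-B read share; the axis convention is ours)
are segmented with the same CBS engine (1-SD undo rule, minimum five markers
per segment, sites with fewer than four reads or flagged as rare variants
removed — the rare flag is an input column, no population database is
consulted). Diagnostic segments anchor the per-copy coverage unit: allelic
ratio ≈ 0 or 1 at total CN 2 (a 2:0 haplotype) or ratio ≈ 1/3 or 2/3 at total
CN 3 (2:1), with tolerance 0.05 (no tolerance is published; 0.05 spans
binomial noise at the depths involved). Each segment then gets
$CN_h = \mathrm{round}(\text{mean haplotype coverage} / \text{unit})$. If no
diagnostic segment exists the unit is unresolvable and estimates are
withheld rather than guessed. Estimates are exactly symmetric under swapping
the haplotype labels. Subclonal mixtures are not modelled; a mixed segment
simply fails to match a diagnostic ratio and is carried with its fractional
evidence.

Ploidy can be inferred from BAF modes jointly with coverage ratios against a
diploid control ({1/2} for 2n, {1/3, 2/3} for 3n, {1/4, 1/2, 3/4} for 4n;
binomial mixtures scored with a Gaussian coverage term, best model by BIC).

## Validation scenarios and what they show

The packaged scenarios (`scenario_detection()`, `scenario_wgd_timing()`,
`scenario_prior_state()`, `scenario_haplotype_bfb()`) define the simulation
study the test suite and the acceptance script run. Conditions were fixed
once: 50 Mb chromosomes; 0.1× coverage in 50 kb bins (the screening design
range is 0.05–0.1×; at 50 kb a CN-2 bin expects ~100 reads, giving 3-SD
separation between adjacent integer states while keeping a 500 kb segment at
10 markers); 20× spanning coverage with 300 bp jitter and 0.1 false calls
per Mb. Detection plants 40 breakpoints at retention 0.5 in the middle 40% of
one of three chromosomes — clustering is only testable when the shattered
region is a proper sub-region. The temporal scenarios use 15 breakpoints over
30 Mb (≈ 2 Mb fragments): per-fragment CN assignment, which temporal ordering
needs and detection does not, requires fragments resolvable at the binning,
whereas the 40-breakpoint detection condition leaves many sub-bin fragments.
The pre-rearranged variant runs four BFB cycles with fusion fractions
0.20–0.40 before shattering the distal half, so that the staircase actually
spans the shattered region — otherwise the replicate would not model
chromothripsis of a rearranged chromosome at all.
The haplotype scenario runs five BFB cycles plus chromothripsis on one
haplotype with a diagnostic 2:1 duplication elsewhere.

Passing these simulations shows that the inference recovers what the
generative model encodes at screening-realistic noise. It does not establish
performance on real genomes, whose read depth carries GC and mappability
structure, whose junction callers have correlated artifacts, and whose
tumors are impure and subclonal — none of which the emulator models.

## Numerical and degenerate-input choices

Constant segments never split (zero variance is detected before the
permutation test); non-finite inputs are rejected. Noiseless
piecewise-constant input has a zero robust noise SD, so the undo rule merges
nothing and recovered boundaries are exact. The multinomial enumeration
compares log-probabilities with a $10^{-9}$ tolerance so ties (outcomes
exactly as likely as the observed one) are counted, which exactness for
vectors like (3,3,3,3) requires. Monte Carlo branches use the add-one
correction and a caller-supplied seed. All file formats are plain text with
0-based half-open coordinates; BEDPE strands encode junction sides
(head = `+`, tail = `-`), with class and median mapping quality in extra
columns.

## Known limitations

No nucleotide-level sequence, breakpoint microhomology, or double-minute
circularisation; BFB without centromere mechanics; clonal genomes only;
depth without positional bias; the exact multinomial beyond $n = 60$ and the
clustering test beyond $n = 50$ fall back to Monte Carlo/asymptotics. The
per-clone switch-count comparisons published for the original cell-line
cohorts require per-clone supplementary data and are therefore covered here
as property checks on simulated cohorts rather than numerical reproductions.
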