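# chromocast

Simulation and detection of chromothripsis and other catastrophic genome
rearrangements from low-pass whole-genome and mate-pair sequencing data.

## The problem

Cell-line screens for complex DNA rearrangements work by perturbing cells,
selecting transformed clones, and sequencing them shallowly (0.05–0.1×) to
find clustered copy-number alterations, then deeply by mate-pair libraries to
characterise the rearrangement junctions. Deciding that a chromosome
underwent *chromothripsis* — a one-off shattering event — rather than an
accumulation of sequential rearrangements requires statistical criteria, and
ordering the catastrophe relative to breakage–fusion–bridge (BFB) cycles and
whole-genome doubling requires reading arithmetic traces out of the
copy-number profile. `chromocast` implements the full computational chain for
people building or evaluating such screens: a genome rearrangement simulator
with exact ground truth, an emulator of the observable sequencing layers, and
the inference machinery.

## The criteria at its core

For a chromosome with breakpoint positions $x_1,\dots,x_n$ on a chromosome of
length $L$, junction class counts $(n_{TH}, n_{HT}, n_{HH}, n_{TT})$, and
integer copy-number segments:

1. **Breakpoint clustering** — one-sample Kolmogorov–Smirnov test of
   $x_i$ against Uniform$(0, L)$, Bonferroni-corrected across chromosomes;
   clustering must be significant.
2. **Randomness of joins** — exact multinomial test of the four
   intra-chromosomal join classes against cell probabilities 1/4 each
   ($p = \sum_{\{v:\, P(v) \le P(\text{obs})\}} P(v)$); randomness must *not*
   be rejected.
3. **Copy-number oscillation** — the two most frequent integer CN states must
   cover ≥ 80% of the affected span and alternate repeatedly.

Temporal ordering: copy-number *jumps* $|CN_A - CN_B|$ across junctions
(zero-dominated ⇒ shattering of a previously intact chromosome); fold-back
junctions demarcating staircase amplification with terminal loss ⇒ prior BFB;
switch magnitudes in a hyperploid genome (2 ⇒ rearrangements before
doubling, 1 ⇒ after). Cohort-level association uses exact Fisher tests on
ploidy × event tables.

## Worked example

Simulate a three-chromosome genome with chromothripsis planted on one
homolog of chromosome 1, emulate the sequencing layers, and run the caller:

```r
library(chromocast)

spec <- genome_spec(c(chr1 = 5e7, chr2 = 5e7, chr3 = 5e7))
g <- cell_genome(spec)
g <- simulate_chromothripsis(g, "chr1_A1", region = c(15e6, 35e6),
                             n_breakpoints = 40, retention_prob = 0.5,
                             seed = 11)

cn    <- truth_copy_number(g, bin_size = 50000)
depth <- emit_read_depth(cn, target_coverage = 0.1, seed = 12)
calls <- emit_junction_calls(truth_junctions(g), spec$chrom_lengths,
                             spanning_coverage = 25, seed = 13)
calls <- merge_junction_calls(filter_junction_calls(calls))

segs <- segment_read_depth(normalize_bins(depth), seed = 14)
segs <- estimate_integer_cn(segs, base_ploidy = 2)

res <- call_chromothripsis(segs, calls, spec$chrom_lengths, seed = 15)
res
#> Chromothripsis calls: 1 of 3 chromosome(s); genome ploidy 2
#>
#>  chrom n_breakpoints ks_p_adj emt_p fraction_diagonal osc_coverage
#>   chr1            40  0.00109     1               0.7            1
#>   chr2             0       NA    NA                NA           NA
#>   chr3             0       NA    NA                NA           NA
#>            call
#>  chromothripsis
#>         no_call
#>         no_call
```

Reading the table: chromosome 1 carries 40 rearrangement breakpoints whose
clustering rejects uniformity (Bonferroni-adjusted KS `p = 0.0011`), the four
join classes are compatible with random rejoining (exact multinomial
`p = 1`), 70% of junctions connect segments of equal integer copy number
(shattering of a previously intact chromosome; at this breakpoint density
many fragments fall below the 50 kb binning, which caps the diagonal
fraction), and the two modal CN states
tile the affected span — chromothripsis. The unrearranged chromosomes show
no breakpoints and stay `no_call`. `summary(res)` adds the temporal
annotations and co-shattering partners; `plot(res)` draws the copy-number
profile with junction arcs colour-coded by orientation class.

Cohort statistics use the same interface as the per-clone flags:

```r
fisher_exact(matrix(c(9, 49, 0, 40), 2, byrow = TRUE))$p_value
#> [1] 0.009775136
```

## File formats

All exchanged formats are plain text, 0-based half-open: bedGraph for binned
read depth, BED for copy-number segments (score column = integer CN), a
4-column TSV for phased allele counts, and BEDPE for junctions. Because BEDPE
side-encoding varies across tools, note the dialect: the two strand columns
encode junction *sides* (head = `+`, tail = `-`), the name column holds the
orientation class (`T-H`, `H-T`, `H-H`, `T-T`, `inter`), the score column the
supporting pair count, and an 11th column the median mapping quality.

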