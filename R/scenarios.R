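## Canned simulation studies: the package's validation scenarios, built from
## the simulator + emulator under the study's emulation settings (low-pass
## 0.1x depth in 50 kb bins, 50 bp reads, mate-pair spanning coverage with
## 300 bp positional jitter and 0.1 false calls per Mb). Each function is
## deterministic given its seed.

study_emulation <- function(genome, seed, coverage = 0.1, bin = 50000,
                            spanning = 20, ploidy = NULL) {
  base_ploidy <- genome$spec$base_ploidy
  ploidy <- ploidy %||% base_ploidy   # analyst-side ploidy for integer CN
  cn <- truth_copy_number(genome, bin)
  depth <- emit_read_depth(cn, coverage, 50, base_ploidy, seed = seed)
  segs <- segment_read_depth(normalize_bins(depth), seed = seed + 1L)
  segs <- estimate_integer_cn(segs, ploidy)
  calls <- emit_junction_calls(truth_junctions(genome),
                               genome$spec$chrom_lengths, spanning, 300, 0.1,
                               base_ploidy, seed = seed + 2L)
  calls <- merge_junction_calls(filter_junction_calls(calls))
  list(genome = genome, segments = segs, junctions = calls,
       chrom_lengths = genome$spec$chrom_lengths)
}

#' Detection scenario: one shattered chromosome in a three-chromosome genome
#'
#' Simulates a 3 x 50 Mb diploid genome, optionally plants a chromothripsis
#' event (40 breakpoints, retention probability 0.5, affecting the middle 40%
#' of chromosome 1 on one homolog), and emulates the observable layers:
#' low-pass depth segmented to integer CN and filtered/merged mate-pair
#' junction calls at 20x spanning coverage.
#'
#' @param seed Integer seed.
#' @param with_event Plant the chromothripsis event (`FALSE` gives a
#'   rearrangement-free replicate).
#' @param n_breakpoints,retention_prob Event parameters.
#' @return `list(genome, segments, junctions, chrom_lengths)`, ready for
#'   [call_chromothripsis()].
#' @export
scenario_detection <- function(seed, with_event = TRUE, n_breakpoints = 40,
                               retention_prob = 0.5) {
  lens <- c(chr1 = 5e7, chr2 = 5e7, chr3 = 5e7)
  g <- cell_genome(genome_spec(lens))
  if (with_event)
    g <- simulate_chromothripsis(g, "chr1_A1", c(15e6, 35e6), n_breakpoints,
                                 retention_prob, seed = seed)
  study_emulation(g, seed + 10L)
}

#' Whole-genome-doubling timing scenario
#'
#' Four 2.5 Mb one-copy deletions on one homolog of a 50 Mb chromosome,
#' applied either before or after tetraploidization. Deletions preceding the
#' doubling are doubled with the genome and leave copy-number switches of
#' magnitude 2 (4 vs 2); deletions acquired afterwards leave magnitude 1
#' (4 vs 3). Returns the segmented observation and the switch-magnitude
#' timing call.
#'
#' @param order `"wgd_first"` (doubling precedes the deletions) or
#'   `"wgd_last"`.
#' @param seed Integer seed.
#' @return `list(segments, wgd_prior)`; `wgd_prior` is `"yes"` when the
#'   profile indicates doubling before the rearrangements.
#' @export
scenario_wgd_timing <- function(order = c("wgd_first", "wgd_last"), seed) {
  order <- match.arg(order)
  g <- cell_genome(genome_spec(c(chr1 = 5e7)))
  add_dels <- function(g) {
    for (s in c(8e6, 18e6, 30e6, 40e6))
      g <- apply_simple_rearrangement(g, "deletion", "chr1_A1",
                                      start = s, end = s + 2.5e6)
    g
  }
  g <- if (order == "wgd_first") add_dels(apply_wgd(g)) else apply_wgd(add_dels(g))
  obs <- study_emulation(g, seed, ploidy = 4)
  prof <- switch_magnitude_profile(obs$segments, ploidy = 4)
  list(segments = obs$segments, wgd_prior = prof$wgd_prior)
}

#' Prior-state scenario: chromothripsis on an intact vs pre-rearranged chromosome
#'
#' `"intact"` shatters a previously unrearranged homolog (15 breakpoints over
#' a 30 Mb region); `"bfb_first"` first runs four breakage-fusion-bridge
#' cycles and then shatters the distal half of the rearranged derivative, so
#' the joined fragments span different copy-number states. Returns the
#' copy-number jump classification of the shattered chromosome.
#'
#' @param kind `"intact"` or `"bfb_first"`.
#' @param seed Integer seed.
#' @return `list(interpretation, fraction_diagonal, segments, junctions)`.
#' @export
scenario_prior_state <- function(kind = c("intact", "bfb_first"), seed) {
  kind <- match.arg(kind)
  g <- cell_genome(genome_spec(c(chr1 = 5e7)))
  if (kind == "intact") {
    g <- simulate_chromothripsis(g, "chr1_A1", c(10e6, 40e6), 15, 0.5,
                                 seed = seed)
  } else {
    ## broad fusions so the staircase spans most of the distal half: the
    ## shattered region must itself be rearranged for the scenario to model
    ## chromothripsis on a previously rearranged chromosome
    g <- simulate_bfb_cycles(g, "chr1_A1", 4, seed = seed,
                             fusion_frac = c(0.20, 0.40))
    D <- derivative_length(g$derivatives$chr1_A1)
    g <- simulate_chromothripsis(g, "chr1_A1", c(0.45 * D, 0.98 * D), 15, 0.5,
                                 seed = seed + 1L)
  }
  obs <- study_emulation(g, seed + 10L)
  jxi <- obs$junctions[obs$junctions$chromA == "chr1" &
                       obs$junctions$chromB == "chr1", , drop = FALSE]
  jump <- cn_jump_distribution(jxi, obs$segments)
  list(interpretation = jump$interpretation,
       fraction_diagonal = jump$fraction_diagonal,
       segments = obs$segments, junctions = obs$junctions)
}

#' Haplotype-resolved BFB + chromothripsis scenario
#'
#' The single-haplotype catastrophe: five BFB cycles followed by
#' chromothripsis, all on the B homolog of chromosome 1, leaving haplotype A
#' untouched, the B haplotype amplified in a staircase and terminally lost. A
#' second chromosome carries a duplication on haplotype A providing a
#' diagnostic 2:1 segment that anchors the per-copy coverage unit. Phased
#' allele counts at ~1 site/kb and 30x mean depth are segmented and converted
#' to haplotype-specific copy numbers.
#'
#' @param seed Integer seed.
#' @param site_density Heterozygous sites per kb.
#' @return `list(hap_cn, truth_intervals, genome)` where `hap_cn` is the
#'   estimated haplotype segment table and `truth_intervals` the exact truth.
#' @export
scenario_haplotype_bfb <- function(seed, site_density = 1) {
  g <- cell_genome(genome_spec(c(chr1 = 5e7, chr2 = 5e7)))
  g <- simulate_bfb_cycles(g, "chr1_B1", 5, seed = seed)
  D <- derivative_length(g$derivatives$chr1_B1)
  g <- simulate_chromothripsis(g, "chr1_B1", c(0.4 * D, 0.95 * D), 12, 0.6,
                               seed = seed + 1L)
  g <- apply_simple_rearrangement(g, "tandem_duplication", "chr2_A1",
                                  start = 5e6, end = 25e6)
  sites <- filter_phased_sites(
    emit_phased_allele_counts(g, site_density, 30, seed = seed + 2L))
  hseg <- segment_allele_ratio(sites, seed = seed + 3L)
  obs <- study_emulation(g, seed + 4L)
  hcn <- estimate_haplotype_cn(hseg, sites, obs$segments)
  list(hap_cn = hcn, truth_intervals = truth_cn_intervals(g), genome = g)
}

#' Truth haplotype copy number at the midpoint of each estimated segment
#'
#' @param hap_cn Estimated haplotype segment table.
#' @param truth_intervals Exact truth intervals (as returned in
#'   [scenario_haplotype_bfb()]).
#' @return `data.frame(cn_A, cn_B)` aligned with `hap_cn` rows.
#' @export
hap_truth_at_segments <- function(hap_cn, truth_intervals) {
  mid <- (hap_cn$start + hap_cn$end) / 2
  idx <- vapply(seq_along(mid), function(i) {
    which(truth_intervals$chrom == hap_cn$chrom[i] &
          truth_intervals$start <= mid[i] & mid[i] < truth_intervals$end)[1]
  }, integer(1))
  truth_intervals[idx, c("cn_A", "cn_B")]
}
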