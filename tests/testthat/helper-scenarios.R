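## Shared fixture builders: tiny genomes and the full observation pipeline.

toy_spec <- function(n_chrom = 1, len = 1e6, ploidy = 2) {
  lens <- rep(len, n_chrom)
  names(lens) <- paste0("chr", seq_len(n_chrom))
  genome_spec(lens, ploidy)
}

study_spec <- function(n_chrom = 3, len = 5e7) {
  lens <- rep(len, n_chrom)
  names(lens) <- paste0("chr", seq_len(n_chrom))
  genome_spec(lens)
}

## Per-base coverage oracle: brute-force counting over an integer position
## grid, independent of the interval arithmetic in the package.
per_base_cn_oracle <- function(genome, chrom, haplotype = NULL) {
  L <- genome$spec$chrom_lengths[[chrom]]
  v <- integer(L)
  for (der in genome$derivatives) {
    if (!is.null(haplotype) && der$haplotype != haplotype) next
    f <- der$frags[der$frags$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(f))) {
      v[(f$start[i] + 1):f$end[i]] <- v[(f$start[i] + 1):f$end[i]] + 1L
    }
  }
  v
}

## Depth -> integer-CN segments for a simulated genome at the study's
## emulation settings (0.1x, 50 bp reads, 50 kb bins).
observe_segments <- function(genome, seed, bin = 50000, coverage = 0.1,
                             base_ploidy = NULL) {
  base_ploidy <- base_ploidy %||% genome$spec$base_ploidy
  cn <- truth_copy_number(genome, bin)
  depth <- emit_read_depth(cn, coverage, 50, base_ploidy, seed = seed)
  segs <- segment_read_depth(normalize_bins(depth), seed = seed + 1L)
  estimate_integer_cn(segs, base_ploidy)
}

## Truth junctions -> filtered, merged junction calls at mate-pair settings.
observe_junctions <- function(genome, seed, spanning = 25, jitter = 300,
                              fp_rate = 0.1) {
  calls <- emit_junction_calls(truth_junctions(genome),
                               genome$spec$chrom_lengths, spanning, jitter,
                               fp_rate, genome$spec$base_ploidy, seed = seed)
  merge_junction_calls(filter_junction_calls(calls))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
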