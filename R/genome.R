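## Genome containers: a genome specification (chromosome names/lengths and base
## ploidy), derivative chromosomes as ordered lists of oriented reference
## fragments, and the cell genome tying them together with an event log.
## Coordinates are 0-based, half-open, integer base pairs throughout.

#' Genome specification
#'
#' Defines the reference chromosomes a simulated cell genome is built from:
#' chromosome names with lengths in bp and a base ploidy (homolog copies per
#' chromosome).
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#'   Names must be unique, lengths positive integers.
#' @param base_ploidy Integer number of homologs per chromosome (default 2).
#' @return An object of class `genome_spec`.
#' @examples
#' genome_spec(c(chr1 = 5e7, chr2 = 5e7))
#' @export
genome_spec <- function(chrom_lengths, base_ploidy = 2L) {
  if (is.null(names(chrom_lengths)) || anyDuplicated(names(chrom_lengths)))
    stop("chromosome names must be present and unique")
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0) ||
      any(chrom_lengths != floor(chrom_lengths)))
    stop("chromosome lengths must be positive integers (bp)")
  stop_if_not_scalar_count(base_ploidy, "base_ploidy")
  if (base_ploidy < 1) stop("base_ploidy must be >= 1")
  structure(list(chrom_lengths = chrom_lengths,
                 base_ploidy = as.integer(base_ploidy)),
            class = "genome_spec")
}

## A fragment table: data.frame(chrom, start, end, rev). rev = TRUE means the
## fragment is traversed end -> start in the derivative.
new_frags <- function(chrom, start, end, rev) {
  data.frame(chrom = as.character(chrom), start = as.numeric(start),
             end = as.numeric(end), rev = as.logical(rev),
             stringsAsFactors = FALSE)
}

validate_frags <- function(frags, spec) {
  if (nrow(frags) == 0L) stop("derivative chromosome must be non-empty")
  lens <- spec$chrom_lengths[frags$chrom]
  if (any(is.na(lens))) stop("fragment on unknown chromosome")
  bad <- frags$start < 0 | frags$start >= frags$end | frags$end > lens
  if (any(bad))
    stop(sprintf("invalid fragment %s:[%s,%s)", frags$chrom[bad][1L],
                 frags$start[bad][1L], frags$end[bad][1L]))
  invisible(frags)
}

#' Initialise a cell genome
#'
#' Creates an unrearranged cell genome: `base_ploidy` collinear homologs per
#' chromosome, with haplotype tags alternating A/B (so a diploid gets one A and
#' one B homolog and a triploid gets composition AAB). The genome carries an
#' event log; every subsequent stochastic operation appends an entry holding
#' its parameters and seed, which makes the genome replayable bit-identically
#' (see [replay_events()]).
#'
#' @param spec A [genome_spec()].
#' @return An object of class `cell_genome`.
#' @examples
#' g <- cell_genome(genome_spec(c(chr1 = 1e6)))
#' names(g$derivatives)
#' @export
cell_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  ders <- list()
  for (chrom in names(spec$chrom_lengths)) {
    tags <- rep_len(c("A", "B"), spec$base_ploidy)
    for (i in seq_len(spec$base_ploidy)) {
      label <- sprintf("%s_%s%d", chrom, tags[i], sum(tags[seq_len(i)] == tags[i]))
      ders[[label]] <- list(
        label = label, haplotype = tags[i],
        frags = new_frags(chrom, 0, spec$chrom_lengths[[chrom]], FALSE))
    }
  }
  structure(list(spec = spec, derivatives = ders, events = list()),
            class = "cell_genome")
}

#' @export
print.cell_genome <- function(x, ...) {
  cat(sprintf("<cell_genome> %d chromosome(s), %d derivative homolog(s), %d event(s)\n",
              length(x$spec$chrom_lengths), length(x$derivatives), length(x$events)))
  invisible(x)
}

derivative_length <- function(der) sum(der$frags$end - der$frags$start)

log_event <- function(genome, op, params) {
  genome$events[[length(genome$events) + 1L]] <- c(list(op = op), params)
  genome
}

get_derivative <- function(genome, homolog) {
  der <- genome$derivatives[[homolog]]
  if (is.null(der)) stop(sprintf("unknown homolog '%s'", homolog))
  der
}

## Split a fragment table at derivative-coordinate positions (sorted, unique).
## Positions at existing boundaries are no-ops.
split_frags_at <- function(frags, positions) {
  positions <- sort(unique(positions))
  lens <- frags$end - frags$start
  bounds <- cumsum(c(0, lens))
  out <- vector("list", nrow(frags))
  for (i in seq_len(nrow(frags))) {
    lo <- bounds[i]; hi <- bounds[i + 1L]
    cuts <- positions[positions > lo & positions < hi] - lo
    f <- frags[i, , drop = FALSE]
    if (length(cuts) == 0L) { out[[i]] <- f; next }
    offs <- c(0, cuts, hi - lo)
    pieces <- vector("list", length(offs) - 1L)
    for (k in seq_len(length(offs) - 1L)) {
      a <- offs[k]; b <- offs[k + 1L]
      if (!f$rev) {
        pieces[[k]] <- new_frags(f$chrom, f$start + a, f$start + b, FALSE)
      } else {
        pieces[[k]] <- new_frags(f$chrom, f$end - b, f$end - a, TRUE)
      }
    }
    out[[i]] <- do.call(rbind, pieces)
  }
  do.call(rbind, out)
}

## Reverse-complement of a derivative piece: reverse row order, flip strands.
reverse_frags <- function(frags) {
  f <- frags[rev(seq_len(nrow(frags))), , drop = FALSE]
  f$rev <- !f$rev
  rownames(f) <- NULL
  f
}

## Row index range of fragments spanning derivative interval [s, e) after the
## table has been split at s and e.
frag_rows_in <- function(frags, s, e) {
  bounds <- cumsum(c(0, frags$end - frags$start))
  starts <- bounds[-length(bounds)]
  which(starts >= s & starts < e)
}

#' Replay an event log
#'
#' Reapplies a recorded event log to a fresh genome built from `spec`. Because
#' every stochastic operation records its seed, replaying yields a
#' bit-identical `cell_genome`.
#'
#' @param spec A [genome_spec()].
#' @param events An event log as found in `genome$events`.
#' @return A `cell_genome`.
#' @export
replay_events <- function(spec, events) {
  genome <- cell_genome(spec)
  for (ev in events) {
    genome <- switch(ev$op,
      chromothripsis = simulate_chromothripsis(genome, ev$homolog, ev$region,
        ev$n_breakpoints, ev$retention_prob, seed = ev$seed),
      bfb = simulate_bfb_cycles(genome, ev$homolog, ev$n_cycles, seed = ev$seed,
        trunc_frac = ev$trunc_frac, fusion_frac = ev$fusion_frac),
      wgd = apply_wgd(genome),
      simple = apply_simple_rearrangement(genome, ev$kind, ev$homolog,
        start = ev$start, end = ev$end, pos = ev$pos, partner = ev$partner,
        partner_pos = ev$partner_pos, seed = ev$seed),
      stop(sprintf("unknown event op '%s'", ev$op)))
  }
  genome
}
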