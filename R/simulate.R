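## Rearrangement simulator: catastrophic shattering (chromothripsis),
## breakage-fusion-bridge cycles, whole-genome doubling and simple structural
## variants, applied to derivative chromosomes with exact ground truth.

#' Simulate a chromothripsis event on one homolog
#'
#' Shatters a region of a single derivative chromosome into `n_breakpoints + 1`
#' fragments, retains each fragment independently with probability
#' `retention_prob` (re-drawn if every fragment would be lost, since a fully
#' deleted region is a whole-arm loss rather than chromothripsis), uniformly
#' permutes the retained fragments, flips each with probability 1/2, and
#' reassembles them between the preserved flanks.
#'
#' The region is given in *derivative* coordinates (identical to reference
#' coordinates on an unedited homolog), so chromothripsis can be layered onto a
#' previously rearranged derivative, e.g. after BFB cycles.
#'
#' @param genome A [cell_genome()].
#' @param homolog Label of the derivative homolog to shatter.
#' @param region Numeric length-2 vector, 0-based half-open interval in
#'   derivative coordinates.
#' @param n_breakpoints Number of distinct breakpoints, drawn uniformly inside
#'   the region. `0` leaves the genome unchanged.
#' @param retention_prob Per-fragment retention probability in \[0, 1\].
#' @param seed Integer seed; drawn and recorded automatically when `NULL`.
#' @return The modified `cell_genome` (event appended to the log).
#' @seealso [truth_junctions()], [truth_copy_number()]
#' @export
simulate_chromothripsis <- function(genome, homolog, region, n_breakpoints,
                                    retention_prob, seed = NULL) {
  stopifnot(inherits(genome, "cell_genome"))
  der <- get_derivative(genome, homolog)
  D <- derivative_length(der)
  if (length(region) != 2L || region[1] < 0 || region[2] > D ||
      region[1] >= region[2])
    stop(sprintf("region [%s,%s) outside homolog span [0,%s)",
                 region[1], region[2], D))
  stop_if_not_scalar_count(n_breakpoints, "n_breakpoints")
  if (n_breakpoints >= region[2] - region[1])
    stop("n_breakpoints must be smaller than the region length in bp")
  if (retention_prob < 0 || retention_prob > 1)
    stop("retention_prob must be in [0, 1]")
  seed <- draw_seed(seed)
  genome <- log_event(genome, "chromothripsis",
                      list(homolog = homolog, region = as.numeric(region),
                           n_breakpoints = as.numeric(n_breakpoints),
                           retention_prob = retention_prob, seed = seed))
  if (n_breakpoints == 0L) return(genome)

  s <- region[1]; e <- region[2]
  frags <- with_seed(seed, {
    bps <- s + sample.int(e - s - 1L, n_breakpoints)
    f <- split_frags_at(der$frags, c(s, bps, e))
    idx <- frag_rows_in(f, s, e)
    m <- length(idx)
    keep <- if (retention_prob == 0) {
      k <- logical(m); k[sample.int(m, 1L)] <- TRUE; k
    } else {
      repeat {
        k <- stats::runif(m) < retention_prob
        if (any(k)) break
      }
      k
    }
    kept <- idx[keep]
    ord <- sample(length(kept))
    shuffled <- lapply(kept[ord], function(i) {
      fr <- f[i, , drop = FALSE]
      if (stats::runif(1) < 0.5) fr$rev <- !fr$rev
      fr
    })
    left <- f[seq_len(min(idx) - 1L), , drop = FALSE]
    right <- f[setdiff(seq_len(nrow(f)), c(seq_len(min(idx) - 1L), idx)), , drop = FALSE]
    out <- do.call(rbind, c(list(left), shuffled, list(right)))
    rownames(out) <- NULL
    out
  })
  genome$derivatives[[homolog]]$frags <- validate_frags(frags, genome$spec)
  genome
}

#' Simulate breakage-fusion-bridge cycles on one homolog
#'
#' Models BFB at the single-homolog level. Each cycle removes a uniformly drawn
#' terminal amount (the bridge break that leaves the chromosome end
#' unprotected) and then appends a reversed copy of a uniformly drawn terminal
#' suffix (the sister-chromatid fusion), which emits one fold-back (head-head
#' or tail-tail) junction whose two ends coincide. After the final cycle an
#' additional terminal truncation leaves the derivative with a broken, deleted
#' end. The resulting truth copy number shows the canonical staircase rising
#' toward the affected chromosome end followed by terminal loss.
#'
#' @inheritParams simulate_chromothripsis
#' @param n_cycles Number of BFB cycles; `0` leaves the genome unchanged.
#' @param trunc_frac Length-2 range: each truncation removes a uniform fraction
#'   of the current derivative length drawn from this range.
#' @param fusion_frac Length-2 range for the uniform fraction duplicated by the
#'   sister fusion.
#' @return The modified `cell_genome`.
#' @export
simulate_bfb_cycles <- function(genome, homolog, n_cycles, seed = NULL,
                                trunc_frac = c(0.02, 0.10),
                                fusion_frac = c(0.05, 0.25)) {
  stopifnot(inherits(genome, "cell_genome"))
  der <- get_derivative(genome, homolog)
  stop_if_not_scalar_count(n_cycles, "n_cycles")
  seed <- draw_seed(seed)
  genome <- log_event(genome, "bfb",
                      list(homolog = homolog, n_cycles = as.numeric(n_cycles),
                           trunc_frac = trunc_frac, fusion_frac = fusion_frac,
                           seed = seed))
  if (n_cycles == 0L) return(genome)

  frags <- with_seed(seed, {
    f <- der$frags
    truncate_tail <- function(f, amount) {
      D <- sum(f$end - f$start)
      amount <- max(1, min(round(amount), D - 1))
      f <- split_frags_at(f, D - amount)
      f[frag_rows_in(f, 0, D - amount), , drop = FALSE]
    }
    for (cyc in seq_len(n_cycles)) {
      D <- sum(f$end - f$start)
      f <- truncate_tail(f, stats::runif(1, trunc_frac[1], trunc_frac[2]) * D)
      D <- sum(f$end - f$start)
      s <- max(1, min(round(stats::runif(1, fusion_frac[1], fusion_frac[2]) * D), D - 1))
      f <- split_frags_at(f, D - s)
      suffix <- f[frag_rows_in(f, D - s, D), , drop = FALSE]
      f <- rbind(f, reverse_frags(suffix))
    }
    D <- sum(f$end - f$start)
    f <- truncate_tail(f, stats::runif(1, trunc_frac[1], trunc_frac[2]) * D)
    rownames(f) <- NULL
    f
  })
  genome$derivatives[[homolog]]$frags <- validate_frags(frags, genome$spec)
  genome
}

#' Whole-genome doubling
#'
#' Duplicates every derivative homolog with haplotype tags preserved; truth
#' copy number doubles everywhere. Structural variants applied before doubling
#' subsequently show copy-number switch magnitude 2, those applied after show
#' magnitude 1 -- the signature used to time hyperploidization.
#'
#' @inheritParams simulate_chromothripsis
#' @return The modified `cell_genome`.
#' @export
apply_wgd <- function(genome) {
  stopifnot(inherits(genome, "cell_genome"))
  genome <- log_event(genome, "wgd", list())
  dup <- lapply(genome$derivatives, function(der) {
    der$label <- paste0(der$label, ".2")
    der
  })
  names(dup) <- vapply(dup, `[[`, "", "label")
  genome$derivatives <- c(genome$derivatives, dup)
  genome
}

#' Apply a simple structural rearrangement
#'
#' The four canonical single edits with their canonical junction signatures:
#' deletion (one tail-head junction, copy number -1 inside), tandem duplication
#' (one head-tail junction, +1 inside), inversion (one head-head and one
#' tail-tail junction, copy number unchanged) and reciprocal translocation
#' between homologs of different chromosomes (two inter-chromosomal
#' junctions). Coordinates are derivative coordinates of the named homolog.
#'
#' @inheritParams simulate_chromothripsis
#' @param kind One of `"deletion"`, `"tandem_duplication"`, `"inversion"`,
#'   `"translocation"`.
#' @param start,end Interval for deletion/duplication/inversion.
#' @param pos,partner,partner_pos For translocation: the breakpoint on
#'   `homolog`, the partner homolog label (must lie on a different chromosome),
#'   and the breakpoint on the partner. The two suffixes are exchanged.
#' @return The modified `cell_genome`.
#' @export
apply_simple_rearrangement <- function(genome, kind, homolog, start = NULL,
                                       end = NULL, pos = NULL, partner = NULL,
                                       partner_pos = NULL, seed = NULL) {
  stopifnot(inherits(genome, "cell_genome"))
  kind <- match.arg(kind, c("deletion", "tandem_duplication", "inversion",
                            "translocation"))
  der <- get_derivative(genome, homolog)
  D <- derivative_length(der)
  genome <- log_event(genome, "simple",
                      list(kind = kind, homolog = homolog, start = start,
                           end = end, pos = pos, partner = partner,
                           partner_pos = partner_pos, seed = seed))
  if (kind == "translocation") {
    if (is.null(partner) || identical(partner, homolog))
      stop("translocation partners must be distinct homologs")
    der2 <- get_derivative(genome, partner)
    D2 <- derivative_length(der2)
    if (is.null(pos) || pos <= 0 || pos >= D) stop("pos outside homolog")
    if (is.null(partner_pos) || partner_pos <= 0 || partner_pos >= D2)
      stop("partner_pos outside partner homolog")
    f1 <- split_frags_at(der$frags, pos)
    f2 <- split_frags_at(der2$frags, partner_pos)
    head1 <- f1[frag_rows_in(f1, 0, pos), , drop = FALSE]
    tail1 <- f1[frag_rows_in(f1, pos, D), , drop = FALSE]
    head2 <- f2[frag_rows_in(f2, 0, partner_pos), , drop = FALSE]
    tail2 <- f2[frag_rows_in(f2, partner_pos, D2), , drop = FALSE]
    genome$derivatives[[homolog]]$frags <- validate_frags(rbind(head1, tail2), genome$spec)
    genome$derivatives[[partner]]$frags <- validate_frags(rbind(head2, tail1), genome$spec)
    return(genome)
  }
  if (is.null(start) || is.null(end) || start < 0 || end > D || start >= end)
    stop(sprintf("coordinates [%s,%s) outside homolog span [0,%s)", start, end, D))
  f <- split_frags_at(der$frags, c(start, end))
  mid_idx <- frag_rows_in(f, start, end)
  pre <- f[seq_len(min(mid_idx) - 1L), , drop = FALSE]
  mid <- f[mid_idx, , drop = FALSE]
  post <- f[setdiff(seq_len(nrow(f)), c(seq_len(min(mid_idx) - 1L), mid_idx)), , drop = FALSE]
  newf <- switch(kind,
    deletion = rbind(pre, post),
    tandem_duplication = rbind(pre, mid, mid, post),
    inversion = rbind(pre, reverse_frags(mid), post))
  rownames(newf) <- NULL
  genome$derivatives[[homolog]]$frags <- validate_frags(newf, genome$spec)
  genome
}

## ---- ground truth -----------------------------------------------------------

## Exact per-haplotype copy-number intervals: a breakpoint sweep over all
## fragment boundaries per chromosome. Returns data.frame(chrom, start, end,
## cn_A, cn_B, cn_total) tiling each chromosome.
truth_cn_intervals <- function(genome) {
  stopifnot(inherits(genome, "cell_genome"))
  all_frags <- do.call(rbind, lapply(genome$derivatives, function(d) {
    cbind(d$frags, hap = d$haplotype, stringsAsFactors = FALSE)
  }))
  out <- vector("list", length(genome$spec$chrom_lengths))
  for (k in seq_along(genome$spec$chrom_lengths)) {
    chrom <- names(genome$spec$chrom_lengths)[k]
    L <- genome$spec$chrom_lengths[[k]]
    fr <- all_frags[all_frags$chrom == chrom, , drop = FALSE]
    bps <- sort(unique(c(0, L, fr$start, fr$end)))
    starts <- bps[-length(bps)]; ends <- bps[-1L]
    cn_for <- function(hap) {
      frh <- fr[fr$hap == hap, , drop = FALSE]
      if (nrow(frh) == 0L) return(numeric(length(starts)))
      cov <- numeric(length(starts))
      pos <- starts
      for (i in seq_len(nrow(frh)))
        cov <- cov + (pos >= frh$start[i] & pos < frh$end[i])
      cov
    }
    a <- cn_for("A"); b <- cn_for("B")
    out[[k]] <- data.frame(chrom = chrom, start = starts, end = ends,
                           cn_A = a, cn_B = b, cn_total = a + b,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Truth copy-number track
#'
#' Bins each chromosome with `bin_size` and reports, per haplotype and summed,
#' the number of derivative fragments covering each bin midpoint -- the exact
#' simulator ground truth.
#'
#' @param genome A [cell_genome()].
#' @param bin_size Bin width in bp (>= 1).
#' @return `data.frame(chrom, start, end, cn_A, cn_B, cn_total)`.
#' @export
truth_copy_number <- function(genome, bin_size) {
  stop_if_not_scalar_count(bin_size, "bin_size")
  if (bin_size < 1) stop("bin_size must be >= 1")
  iv <- truth_cn_intervals(genome)
  out <- vector("list", length(genome$spec$chrom_lengths))
  for (k in seq_along(genome$spec$chrom_lengths)) {
    chrom <- names(genome$spec$chrom_lengths)[k]
    L <- genome$spec$chrom_lengths[[k]]
    starts <- seq(0, L - 1, by = bin_size)
    ends <- pmin(starts + bin_size, L)
    mid <- (starts + ends) / 2
    ivc <- iv[iv$chrom == chrom, , drop = FALSE]
    idx <- findInterval(mid, ivc$start)
    out[[k]] <- data.frame(chrom = chrom, start = starts, end = ends,
                           cn_A = ivc$cn_A[idx], cn_B = ivc$cn_B[idx],
                           cn_total = ivc$cn_total[idx],
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## Orientation classes follow the side-mapping convention: for an
## intra-chromosomal junction with left locus l < right locus r,
## (tail of l, head of r) = T-H deletion type; (head, tail) = H-T duplication
## type; (head, head) = H-H; (tail, tail) = T-T; cross-chromosome = inter.
classify_junction <- function(chromA, posA, sideA, chromB, posB, sideB) {
  ifelse(chromA != chromB, "inter",
    ifelse(sideA == "tail" & sideB == "head", "T-H",
    ifelse(sideA == "head" & sideB == "tail", "H-T",
    ifelse(sideA == "head", "H-H", "T-T"))))
}

## Canonical end order: (chromA, posA) <= (chromB, posB).
canonicalize_junctions <- function(j) {
  if (nrow(j) == 0L) return(j)
  swap <- j$chromA > j$chromB | (j$chromA == j$chromB & j$posA > j$posB)
  if (any(swap)) {
    tmp <- j[swap, c("chromA", "posA", "sideA")]
    j[swap, c("chromA", "posA", "sideA")] <- j[swap, c("chromB", "posB", "sideB")]
    j[swap, c("chromB", "posB", "sideB")] <- tmp
  }
  j$class <- classify_junction(j$chromA, j$posA, j$sideA, j$chromB, j$posB, j$sideB)
  ord <- order(j$chromA, j$posA, j$chromB, j$posB, j$sideA, j$sideB)
  j <- j[ord, , drop = FALSE]
  rownames(j) <- NULL
  j
}

#' Truth junctions of a cell genome
#'
#' Enumerates rearrangement junctions: one per adjacent fragment pair in any
#' derivative chromosome that is not reference-adjacent in matching
#' orientation. A fragment's *head* is its low-coordinate side and its *tail*
#' the high-coordinate side; a forward fragment is exited through its tail and
#' entered through its head (reversed for flipped fragments). Ends are stored
#' in canonical order and identical junctions across homologs are collapsed
#' with their multiplicity recorded.
#'
#' @param genome A [cell_genome()].
#' @return `data.frame(chromA, posA, sideA, chromB, posB, sideB, class,
#'   multiplicity)` with `class` in `T-H`, `H-T`, `H-H`, `T-T`, `inter`.
#' @export
truth_junctions <- function(genome) {
  stopifnot(inherits(genome, "cell_genome"))
  rows <- list()
  for (der in genome$derivatives) {
    f <- der$frags
    n <- nrow(f)
    if (n < 2L) next
    for (i in seq_len(n - 1L)) {
      f1 <- f[i, ]; f2 <- f[i + 1L, ]
      ref_adj <- f1$chrom == f2$chrom &&
        ((!f1$rev && !f2$rev && f1$end == f2$start) ||
         (f1$rev && f2$rev && f1$start == f2$end))
      if (ref_adj) next
      endA <- if (!f1$rev) list(f1$chrom, f1$end, "tail") else list(f1$chrom, f1$start, "head")
      endB <- if (!f2$rev) list(f2$chrom, f2$start, "head") else list(f2$chrom, f2$end, "tail")
      rows[[length(rows) + 1L]] <- data.frame(
        chromA = endA[[1]], posA = endA[[2]], sideA = endA[[3]],
        chromB = endB[[1]], posB = endB[[2]], sideB = endB[[3]],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(chromA = character(), posA = numeric(), sideA = character(),
                      chromB = character(), posB = numeric(), sideB = character(),
                      class = character(), multiplicity = integer(),
                      stringsAsFactors = FALSE))
  j <- canonicalize_junctions(do.call(rbind, rows))
  key <- paste(j$chromA, j$posA, j$sideA, j$chromB, j$posB, j$sideB)
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  j <- j[!duplicated(key), , drop = FALSE]
  j$multiplicity <- agg$Freq[match(paste(j$chromA, j$posA, j$sideA,
                                         j$chromB, j$posB, j$sideB), agg$key)]
  rownames(j) <- NULL
  j
}
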