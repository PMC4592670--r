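## Copy-number segmentation: normalization of binned read depth, circular
## binary segmentation (CBS) with a permutation split test and an "sdundo"
## merge rule, integer copy-number calling, switch counting and the
## clustered-alteration screen.

#' Segmentation parameters
#'
#' @param alpha Split significance level for the permutation test.
#' @param nperm Nominal permutation count (>= 100).
#' @param undo_sd Undo threshold: adjacent segments whose means differ by less
#'   than `undo_sd` robust noise SDs are merged back ("sdundo" rule).
#' @param min_markers Minimum markers per segment; smaller segments are merged
#'   into the neighbour with the closer mean.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(alpha = 0.01, nperm = 1000, undo_sd = 1,
                                min_markers = 3) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (nperm < 100) stop("nperm must be >= 100")
  structure(list(alpha = alpha, nperm = as.integer(nperm), undo_sd = undo_sd,
                 min_markers = as.integer(min_markers)),
            class = "segmentation_params")
}

#' Normalize binned read counts
#'
#' Divides per-bin counts by a matched control track, or by the global median
#' count when no control is given. Bins with zero control counts are masked
#' (dropped from the output).
#'
#' @param track `data.frame(chrom, start, end, count)`.
#' @param control Optional control track with identical bins.
#' @return The track with a `ratio` column; masked bins removed.
#' @export
normalize_bins <- function(track, control = NULL) {
  if (is.null(control)) {
    med <- stats::median(track$count)
    if (!is.finite(med) || med <= 0) stop("all-zero read-depth track")
    out <- track
    out$ratio <- track$count / med
    return(out)
  }
  if (nrow(control) != nrow(track) ||
      !all(control$chrom == track$chrom & control$start == track$start))
    stop("control track bins do not match")
  keep <- control$count > 0
  out <- track[keep, , drop = FALSE]
  out$ratio <- track$count[keep] / control$count[keep]
  rownames(out) <- NULL
  out
}

## Robust noise SD from first differences: MAD-scaled, divided by sqrt(2)
## because differencing doubles the variance.
robust_noise_sd <- function(x) {
  d <- diff(x)
  if (length(d) == 0L) return(0)
  1.4826 * stats::median(abs(d)) / sqrt(2)
}

#' Circular binary segmentation of an ordered value sequence
#'
#' Recursive CBS: at each level the arc split maximizing the two-sample
#' mean-difference statistic is located (ties broken toward the smallest split
#' index) and accepted when its sequentially stopped permutation p-value is
#' below `alpha`; accepted splits are recursed into. Afterwards adjacent
#' segments whose means differ by less than `undo_sd` robust noise SDs (MAD of
#' first differences scaled by 1.4826/sqrt(2)) are merged back, smallest
#' difference first, and segments with fewer than `min_markers` markers are
#' merged into the neighbour with the closer mean.
#'
#' @param values Numeric vector ordered along a chromosome; must be finite.
#' @param params A [segmentation_params()].
#' @param seed Integer seed for the permutation test, or `NULL`.
#' @return `data.frame(idx_start, idx_end, mean, n_markers)` (1-based,
#'   inclusive) tiling the input exactly.
#' @export
cbs_segment <- function(values, params = segmentation_params(), seed = NULL) {
  if (length(values) < 1L) stop("need at least one value")
  if (any(!is.finite(values))) stop("non-finite values in input")
  with_seed(seed, {
    boundaries <- cbs_recurse(values, 1L, length(values), params)
    segs <- boundaries_to_segments(values, boundaries)
    segs <- undo_merge(values, segs, params$undo_sd)
    segs <- enforce_min_markers(values, segs, params$min_markers)
    segs
  })
}

## Returns sorted vector of boundary indices b meaning a change between
## position b and b+1 (1-based).
cbs_recurse <- function(x, lo, hi, params) {
  m <- hi - lo + 1L
  if (m < 2L) return(integer())
  early_accept <- max(100L, ceiling(2 / params$alpha))
  sc <- .cbs_scan(x[lo:hi], params$nperm, params$alpha, early_accept)
  if (is.null(sc$stat) || sc$p >= params$alpha) return(integer())
  i <- sc$i; j <- sc$j   # arc (i, j] in 0-based offsets within lo:hi
  cuts <- integer()
  if (i > 0L) cuts <- c(cuts, lo + i - 1L)
  if (j < m) cuts <- c(cuts, lo + j - 1L)
  if (length(cuts) == 0L) return(integer())
  pieces <- cbind(c(lo, cuts + 1L), c(cuts, hi))
  out <- cuts
  for (r in seq_len(nrow(pieces)))
    out <- c(out, cbs_recurse(x, pieces[r, 1L], pieces[r, 2L], params))
  sort(unique(out))
}

boundaries_to_segments <- function(x, boundaries) {
  starts <- c(1L, boundaries + 1L)
  ends <- c(boundaries, length(x))
  data.frame(idx_start = starts, idx_end = ends,
             mean = vapply(seq_along(starts),
                           function(k) mean(x[starts[k]:ends[k]]), numeric(1)),
             n_markers = ends - starts + 1L)
}

## Greedy smallest-difference-first merging guarantees that raising the undo
## threshold can only extend the merge sequence, so the segment count is
## monotone non-increasing in undo_sd.
undo_merge <- function(x, segs, undo_sd) {
  thr <- undo_sd * robust_noise_sd(x)
  repeat {
    if (nrow(segs) < 2L) return(segs)
    d <- abs(diff(segs$mean))
    k <- which.min(d)
    if (!(d[k] < thr)) return(segs)
    segs <- merge_pair(x, segs, k)
  }
}

merge_pair <- function(x, segs, k) {
  segs$idx_end[k] <- segs$idx_end[k + 1L]
  segs$n_markers[k] <- segs$idx_end[k] - segs$idx_start[k] + 1L
  segs$mean[k] <- mean(x[segs$idx_start[k]:segs$idx_end[k]])
  segs[-(k + 1L), , drop = FALSE]
}

enforce_min_markers <- function(x, segs, min_markers) {
  repeat {
    small <- which(segs$n_markers < min_markers)
    if (length(small) == 0L || nrow(segs) < 2L) break
    k <- small[1L]
    if (k == 1L) segs <- merge_pair(x, segs, 1L)
    else if (k == nrow(segs)) segs <- merge_pair(x, segs, k - 1L)
    else {
      left_d <- abs(segs$mean[k] - segs$mean[k - 1L])
      right_d <- abs(segs$mean[k] - segs$mean[k + 1L])
      segs <- merge_pair(x, segs, if (left_d <= right_d) k - 1L else k)
    }
  }
  rownames(segs) <- NULL
  segs
}

#' Segment a normalized read-depth track per chromosome
#'
#' Applies [cbs_segment()] to the `ratio` column chromosome by chromosome and
#' converts marker indices to genomic coordinates.
#'
#' @param track Normalized track from [normalize_bins()] (needs `chrom, start,
#'   end, ratio`).
#' @inheritParams cbs_segment
#' @return `data.frame(chrom, start, end, mean, n_markers)`; per chromosome
#'   the segments tile the binned extent without overlap.
#' @export
segment_read_depth <- function(track, params = segmentation_params(),
                               seed = NULL) {
  with_seed(seed, {
    out <- lapply(unique(track$chrom), function(chrom) {
      tr <- track[track$chrom == chrom, , drop = FALSE]
      segs <- cbs_segment(tr$ratio, params)
      data.frame(chrom = chrom, start = tr$start[segs$idx_start],
                 end = tr$end[segs$idx_end], mean = segs$mean,
                 n_markers = segs$n_markers, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

## Length-weighted modal segment mean: the heaviest 5%-wide cluster of segment
## means, averaged with length weights. Anchors the per-copy ratio unit.
weighted_modal_mean <- function(means, weights) {
  best_w <- -1; best <- NA_real_
  for (c0 in means) {
    sel <- abs(means - c0) <= 0.05 * max(c0, 1e-9)
    w <- sum(weights[sel])
    if (w > best_w) {
      best_w <- w
      best <- sum(means[sel] * weights[sel]) / w
    }
  }
  best
}

#' Assign integer copy numbers to segments
#'
#' The per-copy ratio unit is the length-weighted modal segment mean divided by
#' `base_ploidy` (the modal copy-number state of a genome is its ploidy);
#' integer CN is the segment mean divided by the unit, rounded half-to-even and
#' floored at 0.
#'
#' @param segments Segment table from [segment_read_depth()].
#' @param base_ploidy Ploidy of the modal genomic state.
#' @return The segment table with a `cn` integer column.
#' @export
estimate_integer_cn <- function(segments, base_ploidy = 2) {
  if (nrow(segments) == 0L) stop("no segments")
  w <- segments$end - segments$start
  unit <- weighted_modal_mean(segments$mean, w) / base_ploidy
  if (!is.finite(unit) || unit <= 0) stop("degenerate per-copy unit")
  segments$cn <- pmax(0, round(segments$mean / unit))
  segments
}

#' Count copy-number switches
#'
#' Discards segments shorter than `min_segment_len`, then counts boundaries
#' between consecutive retained segments with different integer CN, per
#' chromosome and genome-wide.
#'
#' @param segments Segment table with integer `cn` column.
#' @param min_segment_len Minimum segment length in bp (default 500 kb).
#' @return `list(per_chromosome = named integer vector, total = integer,
#'   magnitudes = integer vector of |CN differences| at the switches)`.
#' @export
count_cn_switches <- function(segments, min_segment_len = 5e5) {
  if (is.null(segments$cn)) stop("integer CN not assigned; run estimate_integer_cn()")
  chroms <- unique(segments$chrom)
  counts <- integer(length(chroms))
  names(counts) <- chroms
  mags <- integer()
  for (k in seq_along(chroms)) {
    s <- segments[segments$chrom == chroms[k] &
                  (segments$end - segments$start) >= min_segment_len, , drop = FALSE]
    if (nrow(s) < 2L) next
    d <- abs(diff(s$cn))
    counts[k] <- sum(d != 0)
    mags <- c(mags, d[d != 0])
  }
  list(per_chromosome = counts, total = sum(counts), magnitudes = mags)
}

#' Flag chromosomes with clustered copy-number alterations
#'
#' The low-pass screening rule: chromosomes carrying at least `threshold`
#' copy-number switches are flagged as candidates for catastrophic
#' rearrangement.
#'
#' @param switch_counts Named per-chromosome switch counts (from
#'   [count_cn_switches()]`$per_chromosome`).
#' @param threshold Minimum switch count (default 10).
#' @return Character vector of flagged chromosome names.
#' @export
flag_clustered_chromosomes <- function(switch_counts, threshold = 10) {
  names(switch_counts)[switch_counts >= threshold]
}
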