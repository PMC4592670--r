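## Sequencing emulator: converts simulator ground truth into the three
## observable data layers -- low-pass binned read depth, mate-pair junction
## calls with support/mapping-quality fields, and phased SNP allele counts.

#' Emit a low-pass read-depth track
#'
#' Per-bin read counts are drawn Poisson with mean `u * CN(bin)` where
#' `u = target_coverage * bin_size / (read_length * base_ploidy)`, i.e. the
#' expected reads per bin and per chromosome copy at the requested genome-wide
#' coverage fraction. No GC or mappability bias is modelled.
#'
#' @param cn_track Truth copy-number track from [truth_copy_number()] (columns
#'   `chrom, start, end, cn_total`).
#' @param target_coverage Genome coverage fraction, e.g. `0.1` for 0.1x.
#' @param read_length Read length in bp (default 50, single-end low-pass).
#' @param base_ploidy Copies at which coverage equals `target_coverage`.
#' @param seed Integer seed or `NULL`.
#' @return `data.frame(chrom, start, end, count)`.
#' @export
emit_read_depth <- function(cn_track, target_coverage, read_length = 50,
                            base_ploidy = 2, seed = NULL) {
  if (!all(c("chrom", "start", "end", "cn_total") %in% names(cn_track)))
    stop("cn_track must have columns chrom, start, end, cn_total")
  if (target_coverage <= 0) stop("target_coverage must be > 0")
  bin_size <- cn_track$end - cn_track$start
  u <- target_coverage * bin_size / (read_length * base_ploidy)
  counts <- with_seed(seed, stats::rpois(nrow(cn_track), u * cn_track$cn_total))
  data.frame(chrom = cn_track$chrom, start = cn_track$start,
             end = cn_track$end, count = counts, stringsAsFactors = FALSE)
}

#' Emit phased SNP allele counts
#'
#' Site positions follow a Poisson process along each chromosome. Per site the
#' total depth is Poisson with mean `mean_depth * (CN_A + CN_B) / base_ploidy`
#' and the haplotype-A count is Binomial(depth, CN_A / (CN_A + CN_B)); sites
#' where both haplotypes are lost emit depth 0.
#'
#' @param genome A [cell_genome()].
#' @param site_density Heterozygous sites per kb (Poisson rate).
#' @param mean_depth Mean total site depth at copy number `base_ploidy`.
#' @param base_ploidy Reference ploidy for the depth scale.
#' @param rare_frac Fraction of sites flagged as rare variants (flag only; the
#'   filter consumes it, no population database is involved).
#' @param seed Integer seed or `NULL`.
#' @return `data.frame(chrom, pos, hapA, hapB, rare)` with positions strictly
#'   increasing per chromosome.
#' @export
emit_phased_allele_counts <- function(genome, site_density = 1, mean_depth = 30,
                                      base_ploidy = NULL, rare_frac = 0,
                                      seed = NULL) {
  stopifnot(inherits(genome, "cell_genome"))
  if (site_density <= 0 || mean_depth <= 0)
    stop("site_density and mean_depth must be > 0")
  base_ploidy <- base_ploidy %||% genome$spec$base_ploidy
  iv <- truth_cn_intervals(genome)
  with_seed(seed, {
    out <- list()
    for (chrom in names(genome$spec$chrom_lengths)) {
      L <- genome$spec$chrom_lengths[[chrom]]
      n <- stats::rpois(1, L * site_density / 1000)
      if (n == 0L) next
      pos <- sort(unique(floor(stats::runif(n, 0, L))))
      ivc <- iv[iv$chrom == chrom, , drop = FALSE]
      idx <- findInterval(pos, ivc$start)
      cnA <- ivc$cn_A[idx]; cnB <- ivc$cn_B[idx]
      tot <- cnA + cnB
      depth <- ifelse(tot == 0, 0L,
                      stats::rpois(length(pos), mean_depth * tot / base_ploidy))
      pA <- ifelse(tot == 0, 0, cnA / pmax(tot, 1))
      hapA <- stats::rbinom(length(pos), depth, pA)
      out[[chrom]] <- data.frame(
        chrom = chrom, pos = pos, hapA = hapA, hapB = depth - hapA,
        rare = stats::runif(length(pos)) < rare_frac, stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Emit mate-pair junction calls from truth junctions
#'
#' Each truth junction receives Poisson support with mean
#' `spanning_coverage * multiplicity / base_ploidy` (junctions present on more
#' homologs gather proportionally more spanning pairs); junctions drawing zero
#' support are not called. End positions are jittered by a Normal(0,
#' `position_jitter_sd`) offset; side labels and orientation class are carried
#' through unchanged. False positives are placed uniformly at `fp_rate` calls
#' per Mb with random sides, support `Poisson(1) + 1`, and uniform random
#' mapping quality.
#'
#' @param junctions Truth junction table from [truth_junctions()].
#' @param chrom_lengths Named vector of chromosome lengths (for jitter
#'   clamping and false-positive placement).
#' @param spanning_coverage Mate-pair spanning (physical) coverage.
#' @param position_jitter_sd Positional noise SD in bp.
#' @param fp_rate Expected false-positive calls per Mb of genome.
#' @param base_ploidy Copies over which spanning coverage is spread.
#' @param seed Integer seed or `NULL`.
#' @return A junction-call `data.frame` with columns `chromA, posA, sideA,
#'   chromB, posB, sideB, class, n_supporting_pairs, median_mapq`.
#' @export
emit_junction_calls <- function(junctions, chrom_lengths, spanning_coverage = 25,
                                position_jitter_sd = 300, fp_rate = 0.1,
                                base_ploidy = 2, seed = NULL) {
  if (spanning_coverage <= 0) stop("spanning_coverage must be > 0")
  with_seed(seed, {
    calls <- junctions
    if (nrow(calls) > 0L) {
      support <- stats::rpois(nrow(calls),
                              spanning_coverage * calls$multiplicity / base_ploidy)
      keep <- support > 0
      calls <- calls[keep, , drop = FALSE]
      support <- support[keep]
      jit <- function(pos, chrom) {
        p <- round(pos + stats::rnorm(length(pos), 0, position_jitter_sd))
        pmax(0, pmin(p, chrom_lengths[chrom]))
      }
      calls$posA <- jit(calls$posA, calls$chromA)
      calls$posB <- jit(calls$posB, calls$chromB)
      ## keep sides and class; re-order ends canonically only
      swap <- calls$chromA > calls$chromB |
        (calls$chromA == calls$chromB & calls$posA > calls$posB)
      if (any(swap)) {
        tmp <- calls[swap, c("chromA", "posA", "sideA")]
        calls[swap, c("chromA", "posA", "sideA")] <- calls[swap, c("chromB", "posB", "sideB")]
        calls[swap, c("chromB", "posB", "sideB")] <- tmp
      }
      calls$n_supporting_pairs <- support
      calls$median_mapq <- round(stats::runif(nrow(calls), 37, 60))
      calls$multiplicity <- NULL
    } else {
      calls <- empty_junction_calls()
    }
    n_fp <- stats::rpois(1, fp_rate * sum(chrom_lengths) / 1e6)
    if (n_fp > 0L) {
      chroms <- sample(names(chrom_lengths), n_fp, replace = TRUE,
                       prob = chrom_lengths / sum(chrom_lengths))
      pA <- floor(stats::runif(n_fp, 0, chrom_lengths[chroms]))
      pB <- floor(stats::runif(n_fp, 0, chrom_lengths[chroms]))
      sA <- sample(c("head", "tail"), n_fp, replace = TRUE)
      sB <- sample(c("head", "tail"), n_fp, replace = TRUE)
      fp <- data.frame(chromA = chroms, posA = pmin(pA, pB), sideA = sA,
                       chromB = chroms, posB = pmax(pA, pB), sideB = sB,
                       stringsAsFactors = FALSE)
      fp$class <- classify_junction(fp$chromA, fp$posA, fp$sideA,
                                    fp$chromB, fp$posB, fp$sideB)
      fp$n_supporting_pairs <- stats::rpois(n_fp, 1) + 1L
      fp$median_mapq <- round(stats::runif(n_fp, 0, 60))
      calls <- rbind(calls, fp)
    }
    calls <- calls[order(calls$chromA, calls$posA, calls$chromB, calls$posB), ,
                   drop = FALSE]
    rownames(calls) <- NULL
    calls
  })
}

empty_junction_calls <- function() {
  data.frame(chromA = character(), posA = numeric(), sideA = character(),
             chromB = character(), posB = numeric(), sideB = character(),
             class = character(), n_supporting_pairs = numeric(),
             median_mapq = numeric(), stringsAsFactors = FALSE)
}

#' Filter junction calls on support and mapping quality
#'
#' Keeps calls with at least `min_pairs` supporting read pairs *and* median
#' mapping quality of at least `min_median_mapq`; both boundaries inclusive.
#'
#' @param calls Junction-call table.
#' @param min_pairs Minimum supporting pairs (default 4).
#' @param min_median_mapq Minimum median mapping quality (default 20).
#' @return Filtered calls.
#' @export
filter_junction_calls <- function(calls, min_pairs = 4, min_median_mapq = 20) {
  keep <- calls$n_supporting_pairs >= min_pairs &
    calls$median_mapq >= min_median_mapq
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Identity rule shared by merging and somatic subtraction: same class, both
## endpoint distances < max_endpoint_dist, and (for intra-chromosomal calls
## with non-degenerate spans) reciprocal overlap of the [min(pos), max(pos)]
## intervals > min_reciprocal_overlap. Inter-chromosomal and point-like
## (fold-back) calls match on endpoint distance alone.
junctions_match <- function(a, b, max_endpoint_dist, min_reciprocal_overlap) {
  if (a$class != b$class) return(FALSE)
  if (a$chromA != b$chromA || a$chromB != b$chromB) return(FALSE)
  if (abs(a$posA - b$posA) >= max_endpoint_dist) return(FALSE)
  if (abs(a$posB - b$posB) >= max_endpoint_dist) return(FALSE)
  if (a$class == "inter") return(TRUE)
  la <- abs(a$posB - a$posA); lb <- abs(b$posB - b$posA)
  if (la == 0 || lb == 0) return(TRUE)
  ov <- min(max(a$posA, a$posB), max(b$posA, b$posB)) -
    max(min(a$posA, a$posB), min(b$posA, b$posB))
  ov > min_reciprocal_overlap * la && ov > min_reciprocal_overlap * lb
}

#' Merge redundant junction calls
#'
#' Same-class calls whose two endpoints each differ by less than
#' `max_endpoint_dist` and whose spans overlap reciprocally by more than
#' `min_reciprocal_overlap` are merged: support is summed and the merged
#' position is the support-weighted mean of the members. Merging is transitive
#' (connected components under the identity rule).
#'
#' @inheritParams filter_junction_calls
#' @param max_endpoint_dist Endpoint distance bound in bp (default 5000;
#'   matches a long-range paired-end insert size).
#' @param min_reciprocal_overlap Reciprocal-overlap bound (default 0.5).
#' @return Merged calls in canonical order.
#' @export
merge_junction_calls <- function(calls, max_endpoint_dist = 5000,
                                 min_reciprocal_overlap = 0.5) {
  n <- nrow(calls)
  if (n <= 1L) return(calls)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  ord <- order(calls$class, calls$chromA, calls$chromB, calls$posA)
  for (a_i in seq_len(n - 1L)) {
    i <- ord[a_i]
    for (b_i in (a_i + 1L):n) {
      j <- ord[b_i]
      if (calls$class[j] != calls$class[i] || calls$chromA[j] != calls$chromA[i] ||
          calls$chromB[j] != calls$chromB[i]) break
      if (calls$posA[j] - calls$posA[i] >= max_endpoint_dist) break
      if (junctions_match(calls[i, ], calls[j, ], max_endpoint_dist,
                          min_reciprocal_overlap))
        parent[find(i)] <- find(j)
    }
  }
  grp <- vapply(seq_len(n), find, integer(1))
  merged <- lapply(split(seq_len(n), grp), function(idx) {
    g <- calls[idx, , drop = FALSE]
    w <- g$n_supporting_pairs
    data.frame(chromA = g$chromA[1], posA = round(sum(g$posA * w) / sum(w)),
               sideA = g$sideA[1], chromB = g$chromB[1],
               posB = round(sum(g$posB * w) / sum(w)), sideB = g$sideB[1],
               class = g$class[1], n_supporting_pairs = sum(w),
               median_mapq = round(sum(g$median_mapq * w) / sum(w)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$chromA, out$posA, out$chromB, out$posB), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subtract control (germline/artifact) junction calls
#'
#' Removes every call matching a control call under the merge identity rule --
#' the somatic subtraction step applied against unrearranged control genomes.
#'
#' @inheritParams merge_junction_calls
#' @param control_calls Junction calls observed in control genomes.
#' @return Calls with control matches removed.
#' @export
subtract_control <- function(calls, control_calls, max_endpoint_dist = 5000,
                             min_reciprocal_overlap = 0.5) {
  if (nrow(calls) == 0L || nrow(control_calls) == 0L) return(calls)
  somatic <- vapply(seq_len(nrow(calls)), function(i) {
    for (j in seq_len(nrow(control_calls))) {
      if (junctions_match(calls[i, ], control_calls[j, ], max_endpoint_dist,
                          min_reciprocal_overlap)) return(FALSE)
    }
    TRUE
  }, logical(1))
  out <- calls[somatic, , drop = FALSE]
  rownames(out) <- NULL
  out
}
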