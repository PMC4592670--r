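## Chromothripsis inference: per-chromosome application of the three criteria
## (breakpoint clustering, randomness of joins, copy-number jump/oscillation
## structure) plus temporal ordering relative to BFB cycles and whole-genome
## doubling.

#' Breakpoint clustering test (criterion 1)
#'
#' One-sample Kolmogorov-Smirnov test of breakpoint positions against
#' Uniform(0, chromosome length): a significant deviation indicates breakpoint
#' clustering. The exact null distribution is used for n <= 50, the asymptotic
#' one beyond.
#'
#' @param positions Breakpoint positions in bp.
#' @param chrom_length Chromosome length in bp.
#' @return `list(n, statistic, p_value, insufficient)`; with fewer than 3
#'   positions no test is run and `insufficient` is `TRUE`.
#' @export
breakpoint_clustering_test <- function(positions, chrom_length) {
  if (any(positions < 0 | positions > chrom_length))
    stop("positions outside [0, chrom_length]")
  n <- length(positions)
  if (n < 3L)
    return(list(n = n, statistic = NA_real_, p_value = NA_real_,
                insufficient = TRUE))
  kt <- suppressWarnings(
    stats::ks.test(positions, "punif", 0, chrom_length, exact = n <= 50))
  list(n = n, statistic = unname(kt$statistic), p_value = kt$p.value,
       insufficient = FALSE)
}

## log multinomial pmf with equal cell probabilities 1/4
log_multinom_pmf <- function(counts) {
  n <- sum(counts)
  lgamma(n + 1) - sum(lgamma(counts + 1)) - n * log(4)
}

#' Exact multinomial test of join-class randomness (criterion 2)
#'
#' Tests the counts of the four intra-chromosomal join classes (T-H, H-T, H-H,
#' T-T) against the null of equal class probabilities 1/4. The p-value is the
#' total null probability of all outcomes no more probable than the observed
#' one, computed by exhaustive enumeration of count vectors for `n <=
#' exact_max_n` and by seeded Monte Carlo beyond. Under genuinely random
#' rejoining of shattered fragments this test should *not* reject.
#'
#' @param counts Integer vector of 4 class counts.
#' @param exact_max_n Largest total count enumerated exactly (default 60).
#' @param nsim Monte Carlo draws beyond that (default 1e5).
#' @param seed Seed for the Monte Carlo branch.
#' @return `list(n, p_value, insufficient)`.
#' @export
join_randomness_test <- function(counts, exact_max_n = 60, nsim = 1e5,
                                 seed = NULL) {
  if (length(counts) != 4L || any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be 4 non-negative integers")
  n <- sum(counts)
  if (n == 0L)
    return(list(n = 0L, p_value = NA_real_, insufficient = TRUE))
  lp_obs <- log_multinom_pmf(counts)
  tol <- 1e-9
  if (n <= exact_max_n) {
    grid <- expand.grid(a = 0:n, b = 0:n, c = 0:n)
    grid <- grid[grid$a + grid$b + grid$c <= n, , drop = FALSE]
    grid$d <- n - grid$a - grid$b - grid$c
    lp <- lgamma(n + 1) - (lgamma(grid$a + 1) + lgamma(grid$b + 1) +
                           lgamma(grid$c + 1) + lgamma(grid$d + 1)) - n * log(4)
    p <- sum(exp(lp[lp <= lp_obs + tol]))
    return(list(n = n, p_value = min(1, p), insufficient = FALSE))
  }
  with_seed(seed, {
    draws <- stats::rmultinom(nsim, n, rep(0.25, 4))
    lp <- lgamma(n + 1) - colSums(lgamma(draws + 1)) - n * log(4)
    p <- (sum(lp <= lp_obs + tol) + 1) / (nsim + 1)
    list(n = n, p_value = p, insufficient = FALSE)
  })
}

## Segment lookup for a junction end: a tail end looks into the fragment to its
## left, a head end to its right, offset by `end_offset` bp so that segment
## boundaries placed with one-marker uncertainty do not corrupt the lookup.
## Only confidently segmented enclosing segments (>= min_markers_conf markers)
## yield a CN.
cn_at_end <- function(segments, chrom, pos, side, min_markers_conf,
                      end_offset = 1) {
  s <- segments[segments$chrom == chrom, , drop = FALSE]
  if (nrow(s) == 0L) return(NA_real_)
  q <- if (side == "tail") pos - end_offset else pos + end_offset - 1
  hit <- which(s$start <= q & q < s$end)
  if (length(hit) != 1L) return(NA_real_)
  if (s$n_markers[hit] < min_markers_conf) return(NA_real_)
  s$cn[hit]
}

#' Copy-number jump distribution of junctions (criterion 3)
#'
#' For each junction, the integer CN of the segments enclosing its two ends
#' (ends falling into segments with fewer than `min_markers_conf` markers are
#' excluded) and the absolute jump between them. A preponderance of zero jumps
#' ("points on the diagonal") indicates shattering of a previously intact
#' chromosome; off-diagonal jumps indicate chromothripsis on a previously
#' rearranged chromosome.
#'
#' @param junctions Junction-call table.
#' @param segments Segment table with integer `cn`.
#' @param min_markers_conf Confidence threshold in markers (default 5).
#' @param diag_threshold Fraction of zero jumps at or above which the
#'   interpretation is `"on_intact"` (default 0.7).
#' @param end_offset Lookup offset into the joined fragment, in bp. `NULL`
#'   (default) uses 1.5 median marker spacings estimated from the segments, so
#'   boundary placement noise of about one marker cannot flip the enclosing
#'   segment; pass `1` for exact (noise-free) segment tables.
#' @return `list(records, fraction_diagonal, n_excluded, interpretation)`.
#' @export
cn_jump_distribution <- function(junctions, segments, min_markers_conf = 5,
                                 diag_threshold = 0.7, end_offset = NULL) {
  if (is.null(segments$cn)) stop("integer CN not assigned")
  if (is.null(end_offset)) {
    spacing <- stats::median((segments$end - segments$start) / segments$n_markers)
    end_offset <- max(1, round(1.5 * spacing))
  }
  n <- nrow(junctions)
  cnA <- cnB <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    cnA[i] <- cn_at_end(segments, junctions$chromA[i], junctions$posA[i],
                        junctions$sideA[i], min_markers_conf, end_offset)
    cnB[i] <- cn_at_end(segments, junctions$chromB[i], junctions$posB[i],
                        junctions$sideB[i], min_markers_conf, end_offset)
  }
  ok <- !is.na(cnA) & !is.na(cnB)
  records <- data.frame(junction = which(ok), cn_A = cnA[ok], cn_B = cnB[ok],
                        jump = abs(cnA[ok] - cnB[ok]))
  frac <- if (nrow(records) > 0L) mean(records$jump == 0) else NA_real_
  interp <- if (is.na(frac)) NA_character_
            else if (frac >= diag_threshold) "on_intact" else "on_prerearranged"
  list(records = records, fraction_diagonal = frac,
       n_excluded = sum(!ok), interpretation = interp)
}

#' Copy-number oscillation profile of one chromosome
#'
#' Counts distinct integer CN states over segments of at least `min_seg_len`
#' and the alternations between the two most frequent states (adjacent
#' differing pairs in the CN sequence restricted to those two states).
#' Chromothripsis produces profiles oscillating between two states; stepwise
#' staircases (e.g. BFB amplification) produce many states with few
#' alternations.
#'
#' @param segments Segments of a single chromosome with integer `cn`.
#' @param min_seg_len Minimum segment length considered (default 0).
#' @return `list(n_states, states, top2, alternations)`.
#' @export
oscillation_profile <- function(segments, min_seg_len = 0) {
  s <- segments[(segments$end - segments$start) >= min_seg_len &
                !is.na(segments$cn), , drop = FALSE]
  if (nrow(s) == 0L)
    return(list(n_states = 0L, states = integer(), top2 = integer(),
                alternations = 0L))
  cn_seq <- s$cn
  tab <- sort(table(cn_seq), decreasing = TRUE)
  states <- as.integer(names(tab))
  top2 <- states[seq_len(min(2L, length(states)))]
  sub <- cn_seq[cn_seq %in% top2]
  alt <- if (length(sub) > 1L) sum(diff(sub) != 0) else 0L
  list(n_states = length(states), states = states, top2 = top2,
       alternations = as.integer(alt))
}

#' Switch-magnitude profile and timing of whole-genome doubling
#'
#' Histogram of |CN differences| across copy-number switches genome-wide. In a
#' hyperploid genome, rearrangements that preceded tetraploidization were
#' doubled along with the genome and show switch magnitude 2, whereas
#' rearrangements acquired afterwards show magnitude 1. If the fraction of
#' magnitude-1 switches is at least `wgd_threshold` the doubling is inferred to
#' have preceded the rearrangements (`wgd_prior = "yes"`); if magnitude-2
#' switches dominate, to have followed them (`"no"`). Not applicable (`NA`) to
#' diploid genomes.
#'
#' @param segments Genome-wide segments with integer `cn`.
#' @param ploidy Inferred or known genome ploidy.
#' @param min_segment_len Minimum segment length for switch counting.
#' @param wgd_threshold Dominance threshold (default 0.7).
#' @return `list(histogram, wgd_prior)` with `wgd_prior` in
#'   `"yes"/"no"/NA`.
#' @export
switch_magnitude_profile <- function(segments, ploidy,
                                     min_segment_len = 5e5,
                                     wgd_threshold = 0.7) {
  mags <- count_cn_switches(segments, min_segment_len)$magnitudes
  hist <- table(factor(mags, levels = sort(unique(mags))))
  if (ploidy < 3.5 || length(mags) == 0L)
    return(list(histogram = hist, wgd_prior = NA_character_))
  frac1 <- mean(mags == 1)
  frac2 <- mean(mags == 2)
  wgd <- if (frac1 >= wgd_threshold) "yes"
         else if (frac2 >= frac1) "no"
         else NA_character_
  list(histogram = hist, wgd_prior = wgd)
}

#' Configuration of the chromothripsis caller
#'
#' Bundles every threshold of the screening and calling layers with its
#' default. The full criterion text behind the published three-criterion
#' scheme is configurable here.
#'
#' @param min_breakpoints Minimum breakpoints on a chromosome for a call.
#' @param alpha_clust Clustering-test level, Bonferroni-corrected across the
#'   chromosomes tested.
#' @param alpha_emt Level for the randomness-of-joins test; randomness must
#'   *not* be rejected for a chromothripsis call.
#' @param diag_threshold Zero-jump fraction separating `on_intact` from
#'   `on_prerearranged`.
#' @param osc_coverage Minimum fraction of the affected span covered by the
#'   two most frequent CN states.
#' @param min_osc_alternations Minimum alternation count between the two
#'   modal states inside the affected span (a flat chromosome trivially has
#'   one state covering everything; an oscillation requires switching).
#' @param wgd_threshold Magnitude-1 dominance threshold for WGD timing.
#' @param min_segment_len Segment length floor for switch counting (bp).
#' @param min_markers_conf Marker floor for confident CN assignment at
#'   junction ends.
#' @param foldback_max_dist Maximum end separation of a fold-back junction
#'   (bp).
#' @param min_coshatter_junctions Shared inter-chromosomal junctions required
#'   to report two chromosomes as co-shattered.
#' @param emt_exact_max_n,emt_nsim Exact-enumeration bound and Monte Carlo
#'   size of [join_randomness_test()].
#' @return A named list of class `cast_config`.
#' @export
cast_config <- function(min_breakpoints = 10, alpha_clust = 0.05,
                        alpha_emt = 0.05, diag_threshold = 0.7,
                        osc_coverage = 0.8, min_osc_alternations = 5,
                        wgd_threshold = 0.7, min_segment_len = 5e5,
                        min_markers_conf = 5, foldback_max_dist = 25000,
                        min_coshatter_junctions = 3,
                        emt_exact_max_n = 60, emt_nsim = 1e5) {
  structure(list(min_breakpoints = min_breakpoints, alpha_clust = alpha_clust,
                 alpha_emt = alpha_emt, diag_threshold = diag_threshold,
                 osc_coverage = osc_coverage,
                 min_osc_alternations = min_osc_alternations,
                 wgd_threshold = wgd_threshold,
                 min_segment_len = min_segment_len,
                 min_markers_conf = min_markers_conf,
                 foldback_max_dist = foldback_max_dist,
                 min_coshatter_junctions = min_coshatter_junctions,
                 emt_exact_max_n = emt_exact_max_n, emt_nsim = emt_nsim),
            class = "cast_config")
}

## Fold-back junctions demarcating a staircase amplification that ends in
## terminal loss: the BFB signature.
detect_bfb <- function(seg_chr, jx_chr, chrom_length, config) {
  fb <- jx_chr[jx_chr$class %in% c("H-H", "T-T") &
               abs(jx_chr$posB - jx_chr$posA) <= config$foldback_max_dist, ,
               drop = FALSE]
  if (nrow(fb) == 0L || nrow(seg_chr) == 0L || is.null(seg_chr$cn))
    return(FALSE)
  w <- seg_chr$end - seg_chr$start
  modal_cn <- seg_chr$cn[which.max(vapply(seg_chr$cn, function(c0)
    sum(w[seg_chr$cn == c0]), numeric(1)))]
  for (i in seq_len(nrow(fb))) {
    p <- (fb$posA[i] + fb$posB[i]) / 2
    toward_end <- p > chrom_length / 2
    term <- if (toward_end) seg_chr[seg_chr$end > p, , drop = FALSE]
            else seg_chr[seg_chr$start < p, , drop = FALSE]
    if (nrow(term) == 0L) next
    amp <- max(term$cn)
    terminal_cn <- if (toward_end) term$cn[nrow(term)] else term$cn[1L]
    if (amp > modal_cn && terminal_cn < amp) return(TRUE)
  }
  FALSE
}

#' Call chromothripsis per chromosome with temporal ordering
#'
#' The central inference. For every chromosome it collects the rearrangement
#' breakpoints (both ends of intra-chromosomal junctions, the local end of
#' inter-chromosomal ones) and applies the criteria: (i) at least
#' `min_breakpoints` breakpoints, (ii) significant breakpoint clustering (KS
#' test against uniformity, Bonferroni-corrected across chromosomes with at
#' least 3 breakpoints), (iii) randomness of the four intra-chromosomal join
#' classes *not* rejected by the exact multinomial test, and (iv) an
#' oscillating copy-number profile: the two most frequent CN states cover at
#' least `osc_coverage` of the affected span with at least
#' `min_osc_alternations` alternations. Chromosomes satisfying all criteria
#' are called `chromothripsis`; chromosomes without segmentation are
#' `insufficient`; everything else is `no_call`.
#'
#' Temporal annotations: the copy-number jump distribution classifies the
#' shattered chromosome as previously intact or previously rearranged;
#' fold-back junctions demarcating a staircase amplification with terminal
#' loss flag prior BFB cycles; the genome-wide switch-magnitude profile times
#' whole-genome doubling relative to the rearrangements. Pairs of called (or
#' near-called) chromosomes sharing at least `min_coshatter_junctions`
#' inter-chromosomal junctions are reported as co-shattered.
#'
#' @param segments Genome-wide segment table with integer `cn` (see
#'   [estimate_integer_cn()]).
#' @param junctions Filtered/merged junction-call table.
#' @param chrom_lengths Named chromosome lengths in bp.
#' @param config A [cast_config()].
#' @param ploidy Genome ploidy; when `NULL`, the length-weighted modal CN of
#'   the segments.
#' @param seed Seed for the Monte Carlo branch of the multinomial test.
#' @return An object of class `cast_call`; see [print.cast_call()],
#'   [summary.cast_call()], [plot.cast_call()].
#' @export
call_chromothripsis <- function(segments, junctions, chrom_lengths,
                                config = cast_config(), ploidy = NULL,
                                seed = NULL) {
  if (is.null(segments) || nrow(segments) == 0L)
    stop("missing segmentation: no segments supplied")
  if (is.null(segments$cn)) stop("integer CN not assigned; run estimate_integer_cn()")
  if (is.null(junctions)) stop("missing junction calls")
  chroms <- names(chrom_lengths)
  if (is.null(ploidy)) {
    w <- segments$end - segments$start
    ploidy <- segments$cn[which.max(vapply(segments$cn, function(c0)
      sum(w[segments$cn == c0]), numeric(1)))]
  }

  bp_list <- lapply(chroms, function(chrom) {
    c(junctions$posA[junctions$chromA == chrom],
      junctions$posB[junctions$chromB == chrom])
  })
  names(bp_list) <- chroms
  n_tested <- sum(vapply(bp_list, length, integer(1)) >= 3L)

  wgd <- switch_magnitude_profile(segments, ploidy, config$min_segment_len,
                                  config$wgd_threshold)

  rows <- list(); details <- list()
  for (chrom in chroms) {
    seg_chr <- segments[segments$chrom == chrom, , drop = FALSE]
    jx_intra <- junctions[junctions$chromA == chrom & junctions$chromB == chrom, ,
                          drop = FALSE]
    jx_chr <- junctions[junctions$chromA == chrom | junctions$chromB == chrom, ,
                        drop = FALSE]
    bps <- bp_list[[chrom]]
    n_bp <- length(bps)

    if (nrow(seg_chr) == 0L) {
      rows[[chrom]] <- data.frame(
        chrom = chrom, n_breakpoints = n_bp, ks_D = NA_real_, ks_p = NA_real_,
        ks_p_adj = NA_real_, emt_p = NA_real_, n_TH = NA_integer_,
        n_HT = NA_integer_, n_HH = NA_integer_, n_TT = NA_integer_,
        fraction_diagonal = NA_real_, n_states = NA_integer_,
        alternations = NA_integer_, osc_coverage = NA_real_,
        call = "insufficient", prior_state = NA_character_,
        bfb_prior = NA, wgd_prior = wgd$wgd_prior, stringsAsFactors = FALSE)
      next
    }

    ks <- breakpoint_clustering_test(bps, chrom_lengths[[chrom]])
    ks_p_adj <- if (ks$insufficient) NA_real_ else min(1, ks$p_value * n_tested)

    cls <- c("T-H", "H-T", "H-H", "T-T")
    counts <- vapply(cls, function(cl) sum(jx_intra$class == cl), integer(1))
    emt <- join_randomness_test(counts, config$emt_exact_max_n,
                                config$emt_nsim, seed = seed)

    jump <- cn_jump_distribution(jx_intra, segments, config$min_markers_conf,
                                 config$diag_threshold)

    span_ok <- n_bp >= 2L
    if (span_ok) {
      span <- range(bps)
      in_span <- seg_chr[seg_chr$end > span[1] & seg_chr$start < span[2], ,
                         drop = FALSE]
      if (nrow(in_span) > 0L) {
        clip_len <- pmin(in_span$end, span[2]) - pmax(in_span$start, span[1])
        state_len <- tapply(clip_len, in_span$cn, sum)
        top2 <- as.integer(names(sort(state_len, decreasing = TRUE)))
        top2 <- top2[seq_len(min(2L, length(top2)))]
        osc_cov <- sum(state_len[as.character(top2)]) / sum(clip_len)
        sub <- in_span$cn[in_span$cn %in% top2]
        alternations <- if (length(sub) > 1L) sum(diff(sub) != 0) else 0L
        n_states <- length(state_len)
      } else span_ok <- FALSE
    }
    if (!span_ok) {
      osc_cov <- NA_real_; alternations <- 0L; n_states <- 0L
    }

    is_ct <- !ks$insufficient && !emt$insufficient &&
      n_bp >= config$min_breakpoints &&
      ks_p_adj < config$alpha_clust &&
      emt$p_value > config$alpha_emt &&
      !is.na(osc_cov) && osc_cov >= config$osc_coverage &&
      n_states >= 2L && alternations >= config$min_osc_alternations

    bfb <- detect_bfb(seg_chr, jx_intra, chrom_lengths[[chrom]], config)

    rows[[chrom]] <- data.frame(
      chrom = chrom, n_breakpoints = n_bp,
      ks_D = ks$statistic %||% NA_real_, ks_p = ks$p_value, ks_p_adj = ks_p_adj,
      emt_p = emt$p_value, n_TH = counts[1], n_HT = counts[2],
      n_HH = counts[3], n_TT = counts[4],
      fraction_diagonal = jump$fraction_diagonal,
      n_states = n_states, alternations = alternations, osc_coverage = osc_cov,
      call = if (is_ct) "chromothripsis" else "no_call",
      prior_state = jump$interpretation, bfb_prior = bfb,
      wgd_prior = wgd$wgd_prior, stringsAsFactors = FALSE)
    details[[chrom]] <- list(jump_records = jump$records,
                             n_jump_excluded = jump$n_excluded)
  }

  table <- do.call(rbind, rows)
  rownames(table) <- NULL

  ## co-shattering: called/near-called chromosome pairs sharing translocations
  inter <- junctions[junctions$class == "inter", , drop = FALSE]
  candidates <- table$chrom[table$call == "chromothripsis" |
    (!is.na(table$ks_p_adj) & table$ks_p_adj < config$alpha_clust &
     table$n_breakpoints >= config$min_breakpoints)]
  coshattered <- list()
  if (length(candidates) >= 1L && nrow(inter) > 0L) {
    pairs <- table(paste(pmin(inter$chromA, inter$chromB),
                         pmax(inter$chromA, inter$chromB)))
    for (p in names(pairs)[pairs >= config$min_coshatter_junctions]) {
      cp <- strsplit(p, " ")[[1]]
      if (any(cp %in% candidates)) coshattered[[length(coshattered) + 1L]] <- cp
    }
  }

  structure(list(table = table, details = details, coshattered = coshattered,
                 wgd = wgd, ploidy = ploidy, config = config,
                 segments = segments, junctions = junctions,
                 chrom_lengths = chrom_lengths),
            class = "cast_call")
}

#' @describeIn call_chromothripsis Compact per-chromosome overview.
#' @param x,object A `cast_call` object.
#' @param ... Unused.
#' @export
print.cast_call <- function(x, ...) {
  n_ct <- sum(x$table$call == "chromothripsis")
  cat(sprintf("Chromothripsis calls: %d of %d chromosome(s); genome ploidy %s\n\n",
              n_ct, nrow(x$table), format(x$ploidy)))
  show <- x$table[, c("chrom", "n_breakpoints", "ks_p_adj", "emt_p",
                      "fraction_diagonal", "osc_coverage", "call")]
  show$ks_p_adj <- signif(show$ks_p_adj, 3)
  show$emt_p <- signif(show$emt_p, 3)
  show$fraction_diagonal <- round(show$fraction_diagonal, 2)
  show$osc_coverage <- round(show$osc_coverage, 2)
  print(show, row.names = FALSE)
  invisible(x)
}

#' @describeIn call_chromothripsis Full report including temporal ordering and
#'   co-shattering.
#' @export
summary.cast_call <- function(object, ...) {
  print(object)
  called <- object$table[object$table$call == "chromothripsis", , drop = FALSE]
  if (nrow(called) > 0L) {
    cat("\nTemporal ordering of called chromosomes:\n")
    for (i in seq_len(nrow(called))) {
      cat(sprintf("  %s: %s%s; WGD prior: %s\n", called$chrom[i],
                  called$prior_state[i],
                  if (isTRUE(called$bfb_prior[i])) " (BFB signature present)" else "",
                  called$wgd_prior[i] %||% "NA"))
    }
  }
  if (length(object$coshattered) > 0L) {
    cat("\nCo-shattered chromosome pairs:\n")
    for (cp in object$coshattered) cat(sprintf("  %s + %s\n", cp[1], cp[2]))
  }
  invisible(object)
}

#' @describeIn call_chromothripsis Copy-number profile with junction arcs,
#'   colour-coded by orientation class (red T-H, green H-T, blue H-H, purple
#'   T-T, grey inter-chromosomal).
#' @param chrom Chromosome to plot (default: first called, else first).
#' @export
plot.cast_call <- function(x, chrom = NULL, ...) {
  if (is.null(chrom)) {
    called <- x$table$chrom[x$table$call == "chromothripsis"]
    chrom <- if (length(called) > 0L) called[1L] else x$table$chrom[1L]
  }
  seg <- x$segments[x$segments$chrom == chrom, , drop = FALSE]
  jx <- x$junctions[x$junctions$chromA == chrom & x$junctions$chromB == chrom, ,
                    drop = FALSE]
  if (nrow(seg) == 0L) stop(sprintf("no segments on %s", chrom))
  top <- max(seg$cn) + 1.5
  plot(NA, xlim = c(0, x$chrom_lengths[[chrom]]), ylim = c(-0.2, top),
       xlab = sprintf("%s position (bp)", chrom), ylab = "integer copy number",
       main = sprintf("%s: %s", chrom,
                      x$table$call[x$table$chrom == chrom]), ...)
  graphics::segments(seg$start, seg$cn, seg$end, seg$cn, lwd = 3, col = "red3")
  cols <- c("T-H" = "red", "H-T" = "forestgreen", "H-H" = "blue",
            "T-T" = "purple", inter = "grey50")
  if (nrow(jx) > 0L) {
    for (i in seq_len(nrow(jx))) {
      xm <- (jx$posA[i] + jx$posB[i]) / 2
      r <- abs(jx$posB[i] - jx$posA[i]) / 2
      theta <- seq(0, pi, length.out = 50)
      graphics::lines(xm + r * cos(theta),
                      max(seg$cn) + 0.2 + 1.0 * sin(theta) *
                        (0.3 + 0.7 * r / (x$chrom_lengths[[chrom]] / 2)),
                      col = cols[jx$class[i]])
    }
  }
  invisible(x)
}
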