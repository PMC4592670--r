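## Haplotype-specific copy number from phased allele counts: site filtering,
## allelic-ratio segmentation, diagnostic 2:0 / 2:1 anchoring of the per-copy
## coverage unit, and ploidy inference from BAF plus coverage ratios.

#' Filter phased sites
#'
#' Removes sites covered by fewer than `min_depth` reads and sites flagged as
#' rare variants (the flag is an input column; no population database is
#' consulted).
#'
#' @param sites `data.frame(chrom, pos, hapA, hapB, rare)`.
#' @param min_depth Minimum total read depth (default 4, inclusive).
#' @return Filtered site table.
#' @export
filter_phased_sites <- function(sites, min_depth = 4) {
  rare <- if (is.null(sites$rare)) rep(FALSE, nrow(sites)) else sites$rare
  keep <- (sites$hapA + sites$hapB) >= min_depth & !rare
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Segment phased allelic ratios
#'
#' Computes the per-site haplotype-B read fraction and segments it with the
#' CBS engine ([cbs_segment()], "sdundo" rule with a 1-SD undo threshold by
#' default). Segments defined by fewer than five markers are merged away;
#' chromosomes with fewer than five usable sites yield no segments (with a
#' warning).
#'
#' @param sites Filtered site table from [filter_phased_sites()].
#' @param params A [segmentation_params()]; `min_markers` defaults to 5 here.
#' @param seed Seed for the permutation split test.
#' @return `data.frame(chrom, start, end, n_sites, mean_frac)` -- haplotype
#'   segments in genomic coordinates (start/end from the first/last member
#'   site).
#' @export
segment_allele_ratio <- function(sites,
                                 params = segmentation_params(min_markers = 5),
                                 seed = NULL) {
  with_seed(seed, {
    out <- list()
    for (chrom in unique(sites$chrom)) {
      s <- sites[sites$chrom == chrom, , drop = FALSE]
      depth <- s$hapA + s$hapB
      s <- s[depth > 0, , drop = FALSE]
      if (nrow(s) < 5L) {
        warning(sprintf("fewer than 5 usable sites on %s; no segments", chrom))
        next
      }
      frac <- s$hapB / (s$hapA + s$hapB)
      segs <- cbs_segment(frac, params)
      segs <- segs[segs$n_markers >= 5L, , drop = FALSE]
      if (nrow(segs) == 0L) next
      out[[chrom]] <- data.frame(
        chrom = chrom, start = s$pos[segs$idx_start],
        end = s$pos[segs$idx_end] + 1, n_sites = segs$n_markers,
        mean_frac = segs$mean, stringsAsFactors = FALSE)
    }
    if (length(out) == 0L)
      return(data.frame(chrom = character(), start = numeric(),
                        end = numeric(), n_sites = integer(),
                        mean_frac = numeric(), stringsAsFactors = FALSE))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Estimate haplotype-specific copy numbers
#'
#' Anchors a per-copy site-coverage unit on diagnostic segments -- allelic
#' ratio approximately 0 or 1 with total CN 2 (a 2:0 haplotype, complete loss
#' of one parental haplotype) or ratio approximately 1/3 or 2/3 with total CN
#' 3 (a 2:1 haplotype) -- and assigns each segment
#' `CN_h = round(mean haplotype coverage / unit)`.
#'
#' @param hap_segments Haplotype segments from [segment_allele_ratio()].
#' @param sites The filtered site table the segments were derived from.
#' @param cn_segments Read-depth segments with integer `cn` supplying total
#'   copy number (matched by segment midpoint).
#' @param tol Diagnostic tolerance on the allelic ratio (default 0.05).
#' @return `hap_segments` with columns `total_cn, mean_covA, mean_covB, cn_A,
#'   cn_B`. If no diagnostic segment exists the unit is unresolvable: CN
#'   estimates are withheld (`NA`) with a warning.
#' @export
estimate_haplotype_cn <- function(hap_segments, sites, cn_segments,
                                  tol = 0.05) {
  if (is.null(cn_segments$cn)) stop("cn_segments must carry integer CN")
  n <- nrow(hap_segments)
  covA <- covB <- total <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    s <- sites[sites$chrom == hap_segments$chrom[i] &
               sites$pos >= hap_segments$start[i] &
               sites$pos < hap_segments$end[i], , drop = FALSE]
    covA[i] <- mean(s$hapA); covB[i] <- mean(s$hapB)
    mid <- (hap_segments$start[i] + hap_segments$end[i]) / 2
    hit <- which(cn_segments$chrom == hap_segments$chrom[i] &
                 cn_segments$start <= mid & mid < cn_segments$end)
    if (length(hit) == 1L) total[i] <- cn_segments$cn[hit]
  }
  frac <- hap_segments$mean_frac
  diag20 <- !is.na(total) & total == 2 & (frac <= tol | frac >= 1 - tol)
  diag21 <- !is.na(total) & total == 3 &
    (abs(frac - 1 / 3) <= tol | abs(frac - 2 / 3) <= tol)
  hap_segments$total_cn <- total
  hap_segments$mean_covA <- covA
  hap_segments$mean_covB <- covB
  if (!any(diag20 | diag21)) {
    warning("no diagnostic 2:0 or 2:1 segment found; haplotype CN withheld")
    hap_segments$cn_A <- hap_segments$cn_B <- NA_real_
    return(hap_segments)
  }
  major_cov <- pmax(covA, covB)
  diag <- diag20 | diag21
  w <- hap_segments$n_sites[diag]
  unit <- sum((major_cov[diag] / 2) * w) / sum(w)
  hap_segments$cn_A <- pmax(0, round(covA / unit))
  hap_segments$cn_B <- pmax(0, round(covB / unit))
  hap_segments
}

#' Infer genome ploidy from BAF and coverage ratios
#'
#' Scores diploid, triploid and tetraploid models against heterozygous-site
#' B-allele frequencies (mixture of binomial BAF modes: \{1/2\} for 2n,
#' \{1/3, 2/3\} for 3n, \{1/4, 1/2, 3/4\} for 4n) jointly with coverage ratios
#' relative to a diploid control (expected scale ploidy/2). The best model by
#' BIC wins.
#'
#' @param baf Per-site B-allele frequencies.
#' @param depth Per-site total depths.
#' @param cov_ratio Coverage ratios (sample vs diploid control), any length.
#' @param min_sites Minimum informative sites (default 100).
#' @return `list(ploidy_call, ploidy, bic)` with `ploidy_call` in
#'   `"diploid"/"triploid"/"tetraploid"`, or `NULL` ploidy with too few sites.
#' @export
infer_ploidy_from_baf_coverage <- function(baf, depth, cov_ratio,
                                           min_sites = 100) {
  ok <- is.finite(baf) & is.finite(depth) & depth > 0
  baf <- baf[ok]; depth <- depth[ok]
  if (length(baf) < min_sites)
    return(list(ploidy_call = NA_character_, ploidy = NULL, bic = NULL))
  b <- round(baf * depth)
  modes <- list(`2` = 1 / 2, `3` = c(1 / 3, 2 / 3), `4` = c(1 / 4, 1 / 2, 3 / 4))
  bic <- vapply(names(modes), function(P) {
    mm <- modes[[P]]
    ll_site <- vapply(seq_along(b), function(i) {
      log(mean(stats::dbinom(b[i], depth[i], mm)) + 1e-300)
    }, numeric(1))
    mu <- as.numeric(P) / 2
    s <- sqrt(mean((cov_ratio - mu)^2))
    ll_cov <- sum(stats::dnorm(cov_ratio, mu, max(s, 1e-6), log = TRUE))
    -2 * (sum(ll_site) + ll_cov) + log(length(b) + length(cov_ratio))
  }, numeric(1))
  best <- names(modes)[which.min(bic)]
  list(ploidy_call = c(`2` = "diploid", `3` = "triploid",
                       `4` = "tetraploid")[[best]],
       ploidy = as.integer(best), bic = bic)
}
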