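test_that("breakpoint clustering test matches closed-form ECDF cases", {
  ## 9 evenly spaced points: D = 0.1, far from rejection
  r <- breakpoint_clustering_test((1:9) / 10 * 1e6, 1e6)
  expect_equal(r$statistic, 0.1, tolerance = 1e-12)
  expect_gt(r$p_value, 0.99)
  ## 20 points inside the first 5%: massive clustering
  r2 <- breakpoint_clustering_test(seq(1e3, 4.9e4, length.out = 20), 1e6)
  expect_gte(r2$statistic, 0.95)
  expect_lt(r2$p_value, 1e-10)
  ## too few points -> insufficient, no p
  r3 <- breakpoint_clustering_test(c(1, 2) * 1e5, 1e6)
  expect_true(r3$insufficient)
  expect_true(is.na(r3$p_value))
  expect_error(breakpoint_clustering_test(c(-1, 2, 3), 10), "outside")
})

test_that("clustering p-values are uniform under the null", {
  set.seed(9)
  p <- replicate(400, breakpoint_clustering_test(runif(20, 0, 1e6), 1e6)$p_value)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.03)
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

## Independent oracle: count sequences in the 4^n sample space whose
## count-vector probability is at most that of the observed vector.
emt_oracle <- function(counts) {
  n <- sum(counts)
  p_obs <- dmultinom(counts, prob = rep(0.25, 4))
  total <- 0
  for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
    v <- c(a, b, cc, n - a - b - cc)
    pv <- dmultinom(v, prob = rep(0.25, 4))
    if (pv <= p_obs + 1e-12) total <- total + pv
  }
  total
}

test_that("exact multinomial test reproduces its defining cases", {
  expect_equal(join_randomness_test(c(3, 3, 3, 3))$p_value, 1.0)
  expect_equal(join_randomness_test(c(8, 0, 0, 0))$p_value, 4 * 0.25^8,
               tolerance = 1e-12)
  expect_equal(join_randomness_test(c(8, 0, 0, 0))$p_value, 6.1035e-5,
               tolerance = 1e-4)
  expect_true(join_randomness_test(c(0, 0, 0, 0))$insufficient)
  ## spot-check against the sequence-space counting oracle
  for (v in list(c(1, 0, 0, 0), c(2, 1, 1, 0), c(5, 1, 1, 1), c(4, 3, 2, 1),
                 c(0, 0, 3, 7))) {
    expect_equal(join_randomness_test(v)$p_value, emt_oracle(v),
                 tolerance = 1e-10)
  }
  ## Monte Carlo branch approximates the exact value and is seed-reproducible
  big <- c(30, 20, 15, 5)
  exact <- join_randomness_test(big)$p_value
  mc <- join_randomness_test(big, exact_max_n = 10, seed = 11)$p_value
  expect_lt(abs(mc - exact), 0.01)
  expect_equal(mc, join_randomness_test(big, exact_max_n = 10, seed = 11)$p_value)
})

test_that("copy-number jump records classify intact vs pre-rearranged shattering", {
  segs <- data.frame(chrom = "chr1",
                     start = c(0, 2e6, 4e6, 6e6), end = c(2e6, 4e6, 6e6, 8e6),
                     mean = c(1, 0.5, 1, 1.5), n_markers = c(40, 40, 40, 3),
                     cn = c(2, 1, 2, 3))
  jx <- data.frame(chromA = "chr1", posA = c(2e6, 1e6, 7e6),
                   sideA = c("tail", "tail", "tail"),
                   chromB = "chr1", posB = c(4e6, 2.5e6, 7.5e6),
                   sideB = c("head", "head", "head"),
                   class = "T-H", stringsAsFactors = FALSE)
  out <- cn_jump_distribution(jx, segs, end_offset = 1)
  ## junction 3 has both ends in the 3-marker segment -> excluded
  expect_equal(nrow(out$records), 2)
  expect_equal(out$records$jump, c(0, 1))
  expect_equal(out$fraction_diagonal, 0.5)
  expect_equal(out$interpretation, "on_prerearranged")
  all_eq <- cn_jump_distribution(jx[1, ], segs, end_offset = 1)
  expect_equal(all_eq$fraction_diagonal, 1.0)
  expect_equal(all_eq$interpretation, "on_intact")
})

test_that("oscillation profile counts states and alternations", {
  mk <- function(cn) data.frame(chrom = "chr1", start = seq_along(cn) * 1e6 - 1e6,
                                end = seq_along(cn) * 1e6, mean = cn / 2,
                                n_markers = 20, cn = cn)
  flat <- oscillation_profile(mk(c(2, 2, 2)))
  expect_equal(flat$n_states, 1)
  expect_equal(flat$alternations, 0)
  osc <- oscillation_profile(mk(c(2, 3, 2, 3, 2)))
  expect_equal(osc$n_states, 2)
  expect_equal(osc$alternations, 4)
  stair <- oscillation_profile(mk(c(2, 3, 4, 5)))
  expect_equal(stair$n_states, 4)
  expect_lt(stair$alternations, 3)
})

test_that("switch magnitudes time whole-genome doubling", {
  mk <- function(cn) data.frame(chrom = "chr1", start = seq_along(cn) * 1e6 - 1e6,
                                end = seq_along(cn) * 1e6, mean = cn / 4,
                                n_markers = 20, cn = cn)
  pre <- switch_magnitude_profile(mk(c(4, 2, 4, 2, 4)), ploidy = 4)
  expect_equal(pre$wgd_prior, "no")
  post <- switch_magnitude_profile(mk(c(4, 3, 4, 3, 4)), ploidy = 4)
  expect_equal(post$wgd_prior, "yes")
  dip <- switch_magnitude_profile(mk(c(2, 1, 2)), ploidy = 2)
  expect_true(is.na(dip$wgd_prior))
  none <- switch_magnitude_profile(mk(c(4, 4)), ploidy = 4)
  expect_true(is.na(none$wgd_prior))
  expect_equal(length(none$histogram), 0)
})

test_that("caller flags the shattered chromosome and nothing else", {
  spec <- study_spec()
  g <- simulate_chromothripsis(cell_genome(spec), "chr1_A1", c(15e6, 35e6),
                               40, 0.5, seed = 21)
  segs <- observe_segments(g, seed = 22)
  jx <- observe_junctions(g, seed = 23)
  res <- call_chromothripsis(segs, jx, spec$chrom_lengths, seed = 24)
  expect_s3_class(res, "cast_call")
  expect_equal(res$table$call[res$table$chrom == "chr1"], "chromothripsis")
  expect_true(all(res$table$call[res$table$chrom != "chr1"] == "no_call"))
  expect_output(print(res), "chromothripsis")
  expect_output(summary(res), "Temporal ordering")
})

test_that("serial tandem duplications are not mistaken for chromothripsis", {
  spec <- study_spec(1)
  g <- cell_genome(spec)
  set.seed(31)
  for (s in sort(runif(12, 5e6, 45e6))) {
    D <- sum(with(g$derivatives$chr1_A1$frags, end - start))
    g <- apply_simple_rearrangement(g, "tandem_duplication", "chr1_A1",
                                    start = min(s, D - 3e6), end = min(s + 2e6, D - 1))
  }
  segs <- observe_segments(g, seed = 32)
  jx <- observe_junctions(g, seed = 33)
  res <- call_chromothripsis(segs, jx, spec$chrom_lengths, seed = 34)
  ## all joins are duplication-type: the randomness test rejects
  expect_equal(res$table$call[1], "no_call")
  expect_lt(res$table$emt_p[1], 0.05)
})

test_that("unrearranged genomes yield no_call everywhere", {
  spec <- study_spec()
  segs <- observe_segments(cell_genome(spec), seed = 41)
  jx <- observe_junctions(cell_genome(spec), seed = 42)
  res <- call_chromothripsis(segs, jx, spec$chrom_lengths, seed = 43)
  expect_true(all(res$table$call == "no_call"))
})

test_that("calls are invariant to chromosome relabeling and junction order", {
  spec <- study_spec()
  g <- simulate_chromothripsis(cell_genome(spec), "chr2_A1", c(15e6, 35e6),
                               30, 0.5, seed = 51)
  segs <- observe_segments(g, seed = 52)
  jx <- observe_junctions(g, seed = 53)
  res1 <- call_chromothripsis(segs, jx, spec$chrom_lengths, seed = 54)
  ## shuffle junction rows
  set.seed(55)
  res2 <- call_chromothripsis(segs, jx[sample(nrow(jx)), ], spec$chrom_lengths,
                              seed = 54)
  expect_equal(res1$table$call, res2$table$call)
  ## relabel chromosomes consistently
  relab <- c(chr1 = "k3", chr2 = "k1", chr3 = "k2")
  segs2 <- transform(segs, chrom = unname(relab[chrom]))
  jx2 <- transform(jx, chromA = unname(relab[chromA]), chromB = unname(relab[chromB]))
  lens2 <- setNames(spec$chrom_lengths, unname(relab[names(spec$chrom_lengths)]))
  res3 <- call_chromothripsis(segs2, jx2, lens2, seed = 54)
  expect_equal(res3$table$call[res3$table$chrom == "k1"],
               res1$table$call[res1$table$chrom == "chr2"])
})

test_that("caller reports insufficient without segmentation and errors without inputs", {
  spec <- study_spec(1)
  jx <- observe_junctions(cell_genome(spec), seed = 61)
  segs <- data.frame(chrom = "chrX", start = 0, end = 5e7, mean = 1,
                     n_markers = 1000, cn = 2)
  res <- call_chromothripsis(segs, jx, c(chr1 = 5e7, chrX = 5e7))
  expect_equal(res$table$call[res$table$chrom == "chr1"], "insufficient")
  expect_error(call_chromothripsis(segs[0, ], jx, spec$chrom_lengths), "missing seg")
  segs_nocn <- segs
  segs_nocn$cn <- NULL
  expect_error(call_chromothripsis(segs_nocn, jx, spec$chrom_lengths), "integer CN")
})
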