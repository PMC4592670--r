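test_that("read-depth counts follow the Poisson coverage model", {
  spec <- toy_spec(1, 1e8)
  cn <- truth_copy_number(cell_genome(spec), 1e4)   # 1e4 bins at CN 2
  depth <- emit_read_depth(cn, 0.05, 50, 2, seed = 1)
  u <- 0.05 * 1e4 / (50 * 2)  # expected reads per bin per copy
  mu <- u * 2
  se <- sqrt(mu / nrow(depth))
  expect_lt(abs(mean(depth$count) - mu), 3 * se)
  ## CN 0 regions emit exactly zero
  g0 <- apply_simple_rearrangement(cell_genome(toy_spec()), "deletion",
                                   "chr1_A1", start = 0, end = 1e6 - 10)
  g0 <- apply_simple_rearrangement(g0, "deletion", "chr1_B1", start = 10, end = 1e6)
  cn0 <- truth_copy_number(g0, 1e4)
  d0 <- emit_read_depth(cn0, 0.1, 50, 2, seed = 2)
  expect_true(all(d0$count[cn0$cn_total == 0] == 0))
  ## 0.05x / 50 Mb / 10 kb bins leaves >= 50 bins per minimal 500 kb segment
  expect_gte(5e5 / 1e4, 50)
})

test_that("phased allele counts reflect haplotype-specific copy number", {
  spec <- toy_spec(1, 5e6)
  ## (1,1) -> hapA fraction 1/2; (2,1) after duplicating A -> 2/3; (2,0) -> 1
  g <- apply_simple_rearrangement(cell_genome(spec), "tandem_duplication",
                                  "chr1_A1", start = 0, end = 5e6 - 1)
  sites <- emit_phased_allele_counts(g, site_density = 1, mean_depth = 40, seed = 3)
  expect_gt(nrow(sites), 1000)
  expect_true(all(diff(sites$pos) > 0))
  frac <- sum(sites$hapA) / sum(sites$hapA + sites$hapB)
  expect_lt(abs(frac - 2 / 3), 0.01)
  gb <- apply_simple_rearrangement(cell_genome(spec), "deletion", "chr1_B1",
                                   start = 0, end = 5e6 - 1)
  gb <- apply_simple_rearrangement(gb, "tandem_duplication", "chr1_A1",
                                   start = 0, end = 5e6 - 1)
  sb <- emit_phased_allele_counts(gb, 1, 40, seed = 4)
  expect_true(all(sb$hapB == 0))
})

test_that("junction emission preserves class and matches the support model", {
  spec <- toy_spec(1, 1e7)
  g <- simulate_chromothripsis(cell_genome(spec), "chr1_A1", c(1e6, 9e6),
                               10, 0.7, seed = 5)
  tj <- truth_junctions(g)
  ## jitter-free, fp-free emission reproduces truth coordinates and classes
  calls <- emit_junction_calls(tj, spec$chrom_lengths, 25, 0, 0, 2, seed = 6)
  key <- function(d) paste(d$chromA, d$posA, d$sideA, d$chromB, d$posB, d$sideB, d$class)
  expect_true(all(key(calls) %in% key(tj)))
  ## support means scale with spanning coverage over replicates
  supp <- replicate(200, {
    c2 <- emit_junction_calls(tj[1, ], spec$chrom_lengths, 30, 0, 0, 2)
    if (nrow(c2)) c2$n_supporting_pairs else 0
  })
  expect_lt(abs(mean(supp) - 15), 3 * sqrt(15 / 200))
  ## class untouched by jitter
  cj <- emit_junction_calls(tj, spec$chrom_lengths, 25, 500, 0, 2, seed = 7)
  expect_setequal(unique(cj$class), unique(tj$class))
  ## spanning-coverage Poisson tail for the >= 4-pair filter (single copy,
  ## diploid): mean 10 at 20x, mean 15 at 30x
  expect_equal(1 - ppois(3, 10), 0.98966, tolerance = 1e-4)
  expect_gt(1 - ppois(3, 15), 0.999)
})

test_that("support/mapq filtering applies inclusive boundaries", {
  calls <- data.frame(chromA = "chr1", posA = c(1, 2, 3, 4), sideA = "tail",
                      chromB = "chr1", posB = c(10, 20, 30, 40), sideB = "head",
                      class = "T-H", n_supporting_pairs = c(3, 4, 4, 10),
                      median_mapq = c(60, 20, 19, 60), stringsAsFactors = FALSE)
  out <- filter_junction_calls(calls)
  expect_equal(out$posA, c(2, 4))  # support 3 removed; mapq 19 removed; boundaries kept
  expect_equal(nrow(filter_junction_calls(calls[0, ])), 0)
})

test_that("merging applies the 5 kb / 50% reciprocal-overlap identity rule", {
  mk <- function(posA, posB, support = 5) {
    data.frame(chromA = "chr1", posA = posA, sideA = "tail", chromB = "chr1",
               posB = posB, sideB = "head", class = "T-H",
               n_supporting_pairs = support, median_mapq = 60,
               stringsAsFactors = FALSE)
  }
  ## exact duplicates -> one call, support summed, weighted position
  dup <- rbind(mk(1e5, 2e5, 4), mk(1e5, 2e5, 6))
  m <- merge_junction_calls(dup)
  expect_equal(nrow(m), 1)
  expect_equal(m$n_supporting_pairs, 10)
  expect_equal(m$posA, 1e5)
  ## 4.9 kb apart with ~95% reciprocal overlap -> merged
  near <- rbind(mk(1e5, 2e5), mk(1e5 + 4900, 2e5 + 4900))
  expect_equal(nrow(merge_junction_calls(near)), 1)
  ## 6 kb apart -> not merged
  far <- rbind(mk(1e5, 2e5), mk(1e5 + 6000, 2e5 + 6000))
  expect_equal(nrow(merge_junction_calls(far)), 2)
  ## close endpoints but < 50% reciprocal overlap -> not merged
  shallow <- rbind(mk(1e5, 1e5 + 3000), mk(1e5 + 2800, 1e5 + 12000))
  expect_equal(nrow(merge_junction_calls(shallow)), 2)
  ## different classes never merge
  mixed <- rbind(mk(1e5, 2e5), transform(mk(1e5, 2e5), class = "H-T", sideA = "head", sideB = "tail"))
  expect_equal(nrow(merge_junction_calls(mixed)), 2)
})

test_that("filter then merge is idempotent on emulated call sets", {
  spec <- toy_spec(2, 2e7)
  g <- simulate_chromothripsis(cell_genome(spec), "chr1_A1", c(2e6, 18e6),
                               20, 0.5, seed = 8)
  calls <- emit_junction_calls(truth_junctions(g), spec$chrom_lengths,
                               25, 300, 0.5, 2, seed = 9)
  once <- merge_junction_calls(filter_junction_calls(calls))
  twice <- merge_junction_calls(filter_junction_calls(once))
  expect_equal(twice, once)
})

test_that("somatic subtraction removes calls matching controls under the identity rule", {
  mk <- function(posA, posB) {
    data.frame(chromA = "chr1", posA = posA, sideA = "tail", chromB = "chr1",
               posB = posB, sideB = "head", class = "T-H",
               n_supporting_pairs = 5, median_mapq = 60, stringsAsFactors = FALSE)
  }
  calls <- rbind(mk(1e5, 3e5), mk(5e6, 5.4e6))
  expect_equal(nrow(subtract_control(calls, calls)), 0)
  ctrl_far <- mk(8e6, 9e6)
  expect_equal(subtract_control(calls, ctrl_far), calls)
  ctrl_near <- mk(1e5 + 2000, 3e5 + 2000)
  expect_equal(subtract_control(calls, ctrl_near)$posA, 5e6)
})
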