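test_that("genome construction validates its invariants", {
  expect_error(genome_spec(c(1e6, 2e6)), "names")
  expect_error(genome_spec(c(a = 1e6, a = 2e6)), "unique")
  expect_error(genome_spec(c(a = -5)), "positive")
  spec <- toy_spec(2, 1e6, 3)
  g <- cell_genome(spec)
  expect_length(g$derivatives, 6)
  expect_equal(sort(table(vapply(g$derivatives, `[[`, "", "haplotype"))),
               sort(c(A = 4, B = 2)), ignore_attr = TRUE)
  cn <- truth_copy_number(g, 1e5)
  expect_true(all(cn$cn_total == 3))
})

test_that("chromothripsis identity and full-retention cases match the adjacency oracle", {
  spec <- toy_spec()
  g0 <- cell_genome(spec)
  g <- simulate_chromothripsis(g0, "chr1_A1", c(1e5, 9e5), 0, 0.5, seed = 1)
  expect_identical(g$derivatives, g0$derivatives)
  expect_equal(nrow(truth_junctions(g)), 0)

  g <- simulate_chromothripsis(g0, "chr1_A1", c(1e5, 9e5), 5, 1.0, seed = 7)
  frags <- g$derivatives$chr1_A1$frags
  ## all 6 interior fragments retained: total length conserved, flat truth CN
  expect_equal(sum(frags$end - frags$start), 1e6)
  cn <- truth_copy_number(g, 1e4)
  expect_true(all(cn$cn_total == 2))
  ## junction count = adjacent pairs not reference-adjacent in orientation
  n_adj <- sum(vapply(seq_len(nrow(frags) - 1L), function(i) {
    !(frags$rev[i] == frags$rev[i + 1] &&
      ((!frags$rev[i] && frags$end[i] == frags$start[i + 1]) ||
       (frags$rev[i] && frags$start[i] == frags$end[i + 1])))
  }, logical(1)))
  expect_equal(sum(truth_junctions(g)$multiplicity), n_adj)
})

test_that("retention losses reduce copy number by exactly one on a single homolog", {
  spec <- toy_spec()
  g <- simulate_chromothripsis(cell_genome(spec), "chr1_A1", c(1e5, 9e5),
                               40, 0.5, seed = 3)
  cn <- truth_copy_number(g, 1000)
  expect_true(all(cn$cn_total %in% c(1, 2)))
  expect_true(any(cn$cn_total == 1))
  ## haplotype B untouched
  expect_true(all(cn$cn_B == 1))
})

test_that("truth copy number equals brute-force per-base counting on an edited toy genome", {
  spec <- toy_spec(2, 2e5)
  g <- cell_genome(spec)
  g <- simulate_chromothripsis(g, "chr1_A1", c(2e4, 1.8e5), 10, 0.6, seed = 11)
  g <- simulate_bfb_cycles(g, "chr2_B1", 2, seed = 12)
  g <- apply_simple_rearrangement(g, "tandem_duplication", "chr2_A1",
                                  start = 5e4, end = 9e4)
  for (chrom in c("chr1", "chr2")) {
    oracle <- per_base_cn_oracle(g, chrom)
    cn <- truth_copy_number(g, 500)
    cn <- cn[cn$chrom == chrom, ]
    mid <- floor((cn$start + cn$end) / 2)
    expect_equal(cn$cn_total, oracle[mid + 1L])
    oracleA <- per_base_cn_oracle(g, chrom, "A")
    expect_equal(cn$cn_A, oracleA[mid + 1L])
  }
})

test_that("fragment length is conserved as the integral of truth copy number", {
  spec <- toy_spec(2, 5e5)
  g <- cell_genome(spec)
  g <- simulate_chromothripsis(g, "chr1_A1", c(5e4, 4.5e5), 20, 0.4, seed = 21)
  g <- simulate_bfb_cycles(g, "chr2_A1", 3, seed = 22)
  iv <- chromocast:::truth_cn_intervals(g)
  total_frag <- sum(vapply(g$derivatives, function(d)
    sum(d$frags$end - d$frags$start), numeric(1)))
  expect_equal(sum(iv$cn_total * (iv$end - iv$start)), total_frag)
})

test_that("event replay reproduces the genome bit-identically", {
  spec <- toy_spec(2, 1e6)
  g <- cell_genome(spec)
  g <- simulate_chromothripsis(g, "chr1_A1", c(1e5, 9e5), 12, 0.5, seed = 31)
  g <- simulate_bfb_cycles(g, "chr2_B1", 2, seed = 32)
  g <- apply_wgd(g)
  g <- apply_simple_rearrangement(g, "deletion", "chr1_B1", start = 2e5, end = 3e5)
  g2 <- replay_events(spec, g$events)
  expect_identical(g$derivatives, g2$derivatives)
  ## seeds are drawn and recorded when omitted, so replay still works
  g3 <- simulate_chromothripsis(cell_genome(spec), "chr1_A1", c(0, 1e6 - 1), 5, 0.9)
  g4 <- replay_events(spec, g3$events)
  expect_identical(g3$derivatives, g4$derivatives)
})

test_that("canonical junction signatures: deletion T-H, duplication H-T, inversion H-H+T-T", {
  spec <- toy_spec()
  del <- apply_simple_rearrangement(cell_genome(spec), "deletion", "chr1_A1",
                                    start = 2e5, end = 4e5)
  j <- truth_junctions(del)
  expect_equal(j$class, "T-H")
  expect_equal(c(j$posA, j$posB), c(2e5, 4e5))
  cn <- truth_copy_number(del, 1e4)
  expect_equal(unique(cn$cn_total[cn$start >= 2e5 & cn$end <= 4e5]), 1)

  dup <- apply_simple_rearrangement(cell_genome(spec), "tandem_duplication",
                                    "chr1_A1", start = 2e5, end = 4e5)
  j <- truth_junctions(dup)
  expect_equal(j$class, "H-T")
  cn <- truth_copy_number(dup, 1e4)
  expect_equal(unique(cn$cn_total[cn$start >= 2e5 & cn$end <= 4e5]), 3)

  inv <- apply_simple_rearrangement(cell_genome(spec), "inversion", "chr1_A1",
                                    start = 2e5, end = 4e5)
  j <- truth_junctions(inv)
  expect_setequal(j$class, c("H-H", "T-T"))
  cn <- truth_copy_number(inv, 1e4)
  expect_true(all(cn$cn_total == 2))

  g2 <- toy_spec(2)
  tra <- apply_simple_rearrangement(cell_genome(g2), "translocation",
                                    "chr1_A1", pos = 3e5, partner = "chr2_A1",
                                    partner_pos = 6e5)
  expect_equal(truth_junctions(tra)$class, c("inter", "inter"))
})

test_that("single BFB cycle leaves one proximal fold-back, a gained and a lost interval", {
  spec <- toy_spec()
  g <- simulate_bfb_cycles(cell_genome(spec), "chr1_B1", 1, seed = 41)
  j <- truth_junctions(g)
  expect_equal(nrow(j), 1)
  expect_true(j$class %in% c("H-H", "T-T"))
  expect_equal(j$posA, j$posB)
  iv <- chromocast:::truth_cn_intervals(g)
  expect_true(any(iv$cn_B == 2))               # sister-fusion duplication
  expect_true(iv$cn_B[nrow(iv)] == 0)          # terminal loss
  expect_true(all(iv$cn_A == 1))
  ## identity case
  g0 <- simulate_bfb_cycles(cell_genome(spec), "chr1_B1", 0, seed = 42)
  expect_identical(g0$derivatives, cell_genome(spec)$derivatives)
})

test_that("multi-cycle BFB builds a staircase rising toward the broken end", {
  spec <- toy_spec(1, 5e6)
  g <- simulate_bfb_cycles(cell_genome(spec), "chr1_B1", 5, seed = 43)
  iv <- chromocast:::truth_cn_intervals(g)
  expect_gte(max(iv$cn_B), 3)
  expect_equal(iv$cn_B[nrow(iv)], 0)
  j <- truth_junctions(g)
  expect_gte(sum(j$class %in% c("H-H", "T-T") & j$posA == j$posB), 5)
})

test_that("WGD doubles every homolog and sets the switch magnitude of prior edits to 2", {
  spec <- toy_spec()
  g <- apply_wgd(cell_genome(spec))
  cn <- truth_copy_number(g, 1e5)
  expect_true(all(cn$cn_total == 4))
  expect_length(g$derivatives, 4)
  ## deletion before WGD -> jump of 2; after -> jump of 1
  before <- apply_wgd(apply_simple_rearrangement(cell_genome(spec), "deletion",
                                                 "chr1_A1", start = 2e5, end = 4e5))
  cnb <- truth_copy_number(before, 1e4)
  expect_equal(sort(unique(cnb$cn_total)), c(2, 4))
  after <- apply_simple_rearrangement(apply_wgd(cell_genome(spec)), "deletion",
                                      "chr1_A1", start = 2e5, end = 4e5)
  cna <- truth_copy_number(after, 1e4)
  expect_equal(sort(unique(cna$cn_total)), c(3, 4))
})

test_that("junction classification round-trips and is self-consistent on simulated genomes", {
  spec <- toy_spec(2, 1e6)
  for (seed in 1:5) {
    g <- cell_genome(spec)
    g <- simulate_chromothripsis(g, "chr1_A1", c(1e5, 9e5), 15, 0.5, seed = seed)
    j <- truth_junctions(g)
    ## canonical order and class/side consistency
    expect_true(all(j$chromA < j$chromB |
                    (j$chromA == j$chromB & j$posA <= j$posB)))
    expect_equal(j$class,
                 chromocast:::classify_junction(j$chromA, j$posA, j$sideA,
                                                j$chromB, j$posB, j$sideB))
  }
})

test_that("simulator rejects invalid requests", {
  spec <- toy_spec()
  g <- cell_genome(spec)
  expect_error(simulate_chromothripsis(g, "nope", c(0, 1e5), 3, 1), "unknown homolog")
  expect_error(simulate_chromothripsis(g, "chr1_A1", c(0, 2e6), 3, 1), "outside")
  expect_error(simulate_chromothripsis(g, "chr1_A1", c(0, 10), 10, 1), "smaller")
  expect_error(simulate_bfb_cycles(g, "nope", 1), "unknown homolog")
  expect_error(apply_simple_rearrangement(g, "deletion", "chr1_A1",
                                          start = 5e5, end = 2e6), "outside")
  expect_error(apply_simple_rearrangement(g, "translocation", "chr1_A1",
                                          pos = 1e5, partner = "chr1_A1",
                                          partner_pos = 2e5), "distinct")
})
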