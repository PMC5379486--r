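test_that("pairwise r2 matches hand-computed haplotype tables", {
  mk <- function(a, b) genotypeMatrix(
    rbind(a, b), chrom = c("chr1", "chr1"), pos = c(100L, 200L))
  # identical columns: perfect LD
  a <- rep(c(0L, 2L), each = 10)
  expect_equal(pairwiseR2(mk(a, a), 1, 2), 1)
  # counts AB=2, Ab=2, aB=2, ab=2: independence
  a2 <- c(2L, 2L, 2L, 2L, 0L, 0L, 0L, 0L)
  b2 <- c(2L, 2L, 0L, 0L, 2L, 2L, 0L, 0L)
  expect_equal(pairwiseR2(mk(a2, b2), 1, 2), 0)
  # counts AB=40, Ab=10, aB=10, ab=40: r2 = 0.36
  a3 <- rep(c(2L, 2L, 0L, 0L), c(40, 10, 10, 40))
  b3 <- rep(c(2L, 0L, 2L, 0L), c(40, 10, 10, 40))
  expect_equal(pairwiseR2(mk(a3, b3), 1, 2), 0.36, tolerance = 1e-12)
  # monomorphic in the complete-pair subset: undefined, not zero
  a4 <- c(2L, 2L, 2L, 2L)
  b4 <- c(2L, 0L, 2L, 0L)
  expect_true(is.na(pairwiseR2(mk(a4, b4), 1, 2)))
})

test_that("pairwise r2 equals the brute-force oracle with het/missing", {
  for (s in 1:8) {
    set.seed(s)
    a <- sample(c(0L, 1L, 2L, NA), 40, TRUE, c(0.4, 0.1, 0.4, 0.1))
    b <- sample(c(0L, 1L, 2L, NA), 40, TRUE, c(0.4, 0.1, 0.4, 0.1))
    gm <- genotypeMatrix(rbind(a, b), c("chr1", "chr1"), c(1L, 2L))
    got <- pairwiseR2(gm, 1, 2)
    want <- bruteR2(a, b)
    if (is.na(want)) expect_true(is.na(got))
    else expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("greedy block finding recovers planted LD structure", {
  set.seed(10)
  n <- 40L
  core <- sample(c(0L, 2L), n, TRUE)
  indep <- function() sample(c(0L, 2L), n, TRUE)
  d <- rbind(indep(), indep(), core, core, core, core, core,
             indep(), indep())
  colnames(d) <- paste0("l", 1:n)
  gm <- genotypeMatrix(d, rep("chr1", 9), (1:9) * 1000L)
  hb <- findHaplotypeBlocks(gm, r2_min = 0.4)
  expect_length(hb, 1L)
  expect_equal(hb$first_marker, 3L)
  expect_equal(hb$last_marker, 7L)
  expect_equal(hb$n_snps, 5L)

  # mutually independent markers: no blocks at all
  set.seed(11)
  d2 <- t(replicate(10, sample(c(0L, 2L), 200, TRUE)))
  colnames(d2) <- paste0("l", 1:200)
  gm2 <- genotypeMatrix(d2, rep("chr1", 10), (1:10) * 1000L)
  expect_length(findHaplotypeBlocks(gm2, r2_min = 0.4), 0L)
})

test_that("blocks partition markers without overlap on real-shaped panels", {
  fx <- panelFixture()
  hb <- findHaplotypeBlocks(fx$gm)
  expect_true(all(hb$n_snps >= 2L))
  # non-overlapping within chromosomes
  expect_equal(sum(GenomicRanges::countOverlaps(hb, hb) != 1L), 0L)
  # marker index ranges are disjoint and sorted
  for (chr in unique(as.character(GenomicRanges::seqnames(hb)))) {
    sub <- hb[as.character(GenomicRanges::seqnames(hb)) == chr]
    o <- order(sub$first_marker)
    expect_true(all(diff(sub$first_marker[o]) > 0))
    expect_true(all(sub$first_marker[o][-1] >
                      sub$last_marker[o][-length(sub)]))
  }
})

test_that("block identity applies the 85% rule at the boundary", {
  m <- 20L
  a <- rep(2L, m)
  b17 <- a; b17[1:3] <- 0L   # 17 of 20 match = 0.85
  b16 <- a; b16[1:4] <- 0L   # 16 of 20 match = 0.80
  d <- cbind(A = a, B = b17, C = b16)
  gm <- genotypeMatrix(d, rep("chr1", m), (1:m) * 100L)
  block <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1L, m * 100L))
  expect_equal(blockIdentity(gm, block, "A", "A"), 1)
  expect_equal(blockIdentity(gm, block, "A", "B"), 0.85)
  expect_gte(blockIdentity(gm, block, "A", "B"), 0.85)  # conserved
  expect_equal(blockIdentity(gm, block, "A", "C"), 0.80)
  # symmetry
  expect_equal(blockIdentity(gm, block, "A", "C"),
               blockIdentity(gm, block, "C", "A"))
})

test_that("origin tracing equals exhaustive enumeration on hand pedigrees", {
  ped <- handPedigree()
  gm <- handBlockGenotypes(ped)
  blocks <- handBlockRanges()
  rec <- traceOrigin(blocks, gm, ped)

  # block 1: identical across the whole trunk; the chain spans all four
  # upstream trunk cultivars (R3, R2, R1, F1)
  expect_true(rec$traceable[1])
  expect_equal(rec$origin_cultivar[1], "F1")
  expect_equal(rec$conserved_generation_count[1], 4L)
  # block 2: introduced by the donor of generation 3
  expect_true(rec$traceable[2])
  expect_equal(rec$origin_cultivar[2], "D3")
  expect_equal(rec$conserved_generation_count[2], 1L)
  # block 3: novel in the focal line
  expect_false(rec$traceable[3])
  # block 4: early match but broken chain -> not traceable
  expect_false(rec$traceable[4])

  # full agreement with the independent enumeration oracle
  idm <- sapply(pedigreeNodes(ped)$name, function(ln)
    vapply(seq_along(blocks), function(b)
      blockIdentity(gm, blocks[b], ln, "R4"), numeric(1)))
  rownames(idm) <- blocks$block_id
  donors <- vapply(flowOrder(ped), function(r) {
    p <- parentsOf(ped, r)["donor"]
    if (is.na(p)) NA_character_ else unname(p)
  }, character(1))
  oracle <- bruteTrace(idm, flowOrder(ped), donors, "R4")
  for (b in seq_along(blocks)) {
    expect_equal(rec$traceable[b], oracle[[b]]$traceable)
    expect_equal(rec$conserved_generation_count[b], oracle[[b]]$count)
    if (oracle[[b]]$traceable)
      expect_equal(rec$origin_cultivar[b], oracle[[b]]$origin)
  }
  expect_error(traceOrigin(blocks, gm, ped, focal = "nope"), "focal")
})

test_that("cHTB calling reads 'more than three generations' strictly", {
  rec <- data.frame(block_id = c("a", "b", "c"),
                    traceable = c(TRUE, TRUE, FALSE),
                    origin_cultivar = c("x", "y", NA),
                    origin_year = c(1950L, 1960L, NA),
                    conserved_generation_count = c(4L, 3L, 0L),
                    is_chtb = FALSE)
  out <- callCHTB(rec)
  expect_equal(out$is_chtb, c(TRUE, FALSE, FALSE))
  out1 <- callCHTB(rec, min_generations = 1L)
  expect_equal(out1$is_chtb, rec$traceable)
})

test_that("raising the identity threshold is monotone", {
  fx <- panelFixture()
  hb <- findHaplotypeBlocks(fx$gm)
  r_lo <- traceOrigin(hb, fx$gm, fx$ped, threshold = 0.75)
  r_hi <- traceOrigin(hb, fx$gm, fx$ped, threshold = 0.95)
  expect_lte(sum(r_hi$traceable), sum(r_lo$traceable))
  expect_true(all(r_hi$conserved_generation_count <=
                    r_lo$conserved_generation_count))
})

test_that("derivative conservation cross-classifies blocks", {
  m <- 10L
  base <- rep(2L, m)
  varied <- base; varied[1:3] <- 0L   # identity 0.7 < 0.85
  d <- cbind(focal = base, q1 = base, q2 = base, y1 = base, y2 = varied)
  gm <- genotypeMatrix(d, rep("chr1", m), (1:m) * 100L)
  blocks <- GenomicRanges::GRanges("chr1",
                                   IRanges::IRanges(1L, m * 100L),
                                   block_id = "HB1")
  groups <- list(quality = c("q1", "q2"), yield = c("y1", "y2"))
  dc <- derivativeConservation(blocks, gm, groups, focal = "focal")
  expect_equal(dc$classification$class, "varied_in_yield_only")

  d2 <- d; d2[, "y2"] <- base
  gm2 <- genotypeMatrix(d2, rep("chr1", m), (1:m) * 100L)
  dc2 <- derivativeConservation(blocks, gm2, groups, focal = "focal")
  expect_equal(unname(dc2$proportions["consistent_in_both"]), 1)
  expect_warning(
    derivativeConservation(blocks, gm, list(quality = c("q1", "zz"),
                                            yield = "y1"), "focal"),
    "skipped")
})
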