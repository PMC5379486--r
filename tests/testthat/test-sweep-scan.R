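test_that("window statistics match the brute-force oracle to 1e-10", {
  for (s in 1:5) {
    set.seed(s)
    n_sites <- 50L; n_lines <- 20L
    d <- matrix(sample(c(0L, 1L, 2L, NA), n_sites * n_lines, TRUE,
                       prob = c(0.42, 0.08, 0.42, 0.08)),
                n_sites, n_lines,
                dimnames = list(NULL, paste0("l", 1:n_lines)))
    gm <- genotypeMatrix(d, chrom = rep("chr1", n_sites),
                         pos = sort(sample.int(9000, n_sites)))
    ws <- windowStats(gm, window_bp = 10000)
    expect_length(ws, 1L)
    br <- bruteWindow(d)
    expect_equal(ws$n_snps, br$S)
    expect_equal(ws$pi, br$pi, tolerance = 1e-10)
    expect_equal(ws$theta_w, br$theta, tolerance = 1e-10)
    if (is.na(br$D)) expect_true(is.na(ws$tajima_d))
    else expect_equal(ws$tajima_d, br$D, tolerance = 1e-10)
  }
})

test_that("Watterson's theta and D behave on textbook cases", {
  # 4 haplotypes (2 inbred lines), 3 segregating sites:
  # theta_W = 3 / (1 + 1/2 + 1/3)
  d <- matrix(c(0L, 2L,
                0L, 2L,
                2L, 0L,
                0L, 0L), 4, 2, byrow = TRUE,
              dimnames = list(NULL, c("a", "b")))
  gm <- genotypeMatrix(d, rep("chr1", 4), c(10L, 20L, 30L, 40L))
  ws <- windowStats(gm, window_bp = 1000)
  expect_equal(ws$theta_w, 3 / (1 + 1 / 2 + 1 / 3), tolerance = 1e-12)
  expect_equal(ws$n_snps, 3L)

  # 10 haplotypes, 5 sites all singletons: excess of rare variants, D < 0
  d2 <- matrix(0L, 5, 5, dimnames = list(NULL, paste0("l", 1:5)))
  for (i in 1:5) d2[i, i] <- 1L   # one heterozygote = one rare haplotype
  gm2 <- genotypeMatrix(d2, rep("chr1", 5), (1:5) * 10L)
  ws2 <- windowStats(gm2, window_bp = 1000)
  expect_lt(ws2$tajima_d, 0)

  # monomorphic window: pi = 0, theta = 0, D undefined
  d3 <- matrix(2L, 4, 6, dimnames = list(NULL, paste0("l", 1:6)))
  gm3 <- genotypeMatrix(d3, rep("chr1", 4), (1:4) * 10L)
  ws3 <- windowStats(gm3, window_bp = 1000)
  expect_equal(ws3$pi, 0)
  expect_equal(ws3$theta_w, 0)
  expect_true(is.na(ws3$tajima_d))

  expect_error(windowStats(gm3, window_bp = 0), "positive")
})

test_that("sweep calling applies the quantile cut-off and 5-kb merge rule", {
  mk <- function(starts, D, chrom = "chr1", width = 10000L)
    GenomicRanges::GRanges(chrom,
                           IRanges::IRanges(starts, starts + width - 1L),
                           n_snps = 5L, pi = 1, theta_w = 1,
                           tajima_d = D, n_hap = 20L)
  # 100 windows with distinct D values: exactly 5 pass at quantile 0.05
  ws <- mk(seq(1, by = 10000L, length.out = 100), D = sample(1:100))
  sw <- callSweeps(ws, quantile = 0.05, merge_gap_bp = 0L)
  expect_equal(sum(sw$n_windows), 5L)

  # gap of 4999 merges, gap of 5001 does not (38 neutral filler windows
  # put the 5% threshold between the two planted windows and the rest)
  two <- function(gap) {
    w <- mk(c(1L, 10000L + gap + 1L), D = c(-3, -3))
    extra <- mk(seq(1e6, by = 10000L, length.out = 38),
                D = seq(1, 38))
    callSweeps(c(w, extra), quantile = 0.05, merge_gap_bp = 5000L)
  }
  expect_length(two(4999L), 1L)
  expect_length(two(5001L), 2L)

  # monotonicity: lowering the quantile never adds passing windows
  ws2 <- mk(seq(1, by = 10000L, length.out = 200),
            D = rnorm(200))
  n_passing <- vapply(c(0.2, 0.1, 0.05, 0.01), function(q)
    sum(callSweeps(ws2, quantile = q, merge_gap_bp = 0L)$n_windows),
    numeric(1))
  expect_true(all(diff(n_passing) <= 0))

  # merging is idempotent: blocks re-merged are unchanged
  sw2 <- callSweeps(ws2, quantile = 0.10)
  re <- GenomicRanges::reduce(sw2, min.gapwidth = 5001L)
  expect_equal(GenomicRanges::granges(re), GenomicRanges::granges(sw2),
               ignore_attr = TRUE)

  # all-NA D: warning and empty result
  ws3 <- mk(1L, D = NA_real_)
  expect_warning(sw3 <- callSweeps(ws3), "undefined")
  expect_length(sw3, 0L)
})

test_that("temporal clustering finds planted change-point years", {
  # 30 lines, years 1990..2019; 12 blocks of 10 markers each on chr1;
  # blocks 1-6 conserved from 2000 on, blocks 7-12 never conserved
  set.seed(42)
  n_lines <- 30L; m <- 10L; n_blocks <- 12L
  years <- 1990:2019
  lines <- sprintf("L%02d", seq_len(n_lines))
  focal <- lines[n_lines]
  d <- matrix(sample(c(0L, 2L), n_blocks * m * n_lines, TRUE),
              n_blocks * m, n_lines, dimnames = list(NULL, lines))
  target <- ifelse(d[, focal] == 0L, 2L, 0L)
  for (b in 1:6) {
    i <- ((b - 1) * m + 1):(b * m)
    d[i, years >= 2000] <- d[i, focal]        # conserved after 2000
    d[i, years < 2000] <- target[i]           # different before
  }
  for (b in 7:12) {
    i <- ((b - 1) * m + 1):(b * m)
    d[i, lines != focal] <- target[i]         # always different
  }
  gm <- genotypeMatrix(d, rep("chr1", nrow(d)),
                       pos = seq_len(nrow(d)) * 500L,
                       lineData = data.frame(name = lines, year = years,
                                             role = "receptor"))
  blocks <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(((seq_len(n_blocks) - 1) * m + 1) * 500L,
                     (seq_len(n_blocks) * m) * 500L))
  cl <- clusterTemporalPatterns(blocks, gm, focal, k = 2)
  expect_length(unique(cl$labels), 2L)
  # the conserved-after-2000 cluster's change point is within one
  # cultivar position of the planted year
  cl_cons <- cl$labels[1]
  expect_true(all(cl$labels[1:6] == cl_cons))
  expect_true(all(cl$labels[7:12] != cl_cons))
  cp <- cl$changepoint_year[paste0("cluster", cl_cons)]
  expect_lte(abs(cp - 2000), 1)
  expect_error(clusterTemporalPatterns(blocks, gm, focal, k = 13),
               "exceeds")
})

test_that("degenerate conservation profiles warn but still cluster", {
  lines <- sprintf("L%d", 1:6)
  d <- matrix(2L, 20, 6, dimnames = list(NULL, lines))
  gm <- genotypeMatrix(d, rep("chr1", 20), (1:20) * 100L,
                       lineData = data.frame(name = lines,
                                             year = 2000:2005,
                                             role = "receptor"))
  blocks <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1L, 1001L), c(1000L, 2000L)))
  expect_warning(cl <- clusterTemporalPatterns(blocks, gm, "L6", k = 2),
                 "identical")
  expect_length(cl$labels, 2L)
})

test_that("gene annotation uses inclusive-coordinate any-overlap", {
  gff <- tempfile(fileext = ".gff3")
  genes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(100L, 2000L, 5000L, 5501L, 9000L, 12000L,
                       15000L, 18000L, 21000L, 24000L),
                     width = c(300L, 400L, 200L, 100L, 500L, 300L,
                               200L, 100L, 50L, 400L)),
    type = "gene")
  genes$ID <- paste0("g", 1:10)
  rtracklayer::export(genes, gff, format = "GFF3")
  # block 5000..5500: g3 (5000-5199) inside, g4 starts at block end + 1
  block <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(5000L, 5500L))
  ann <- annotateBlocks(block, gff)
  expect_equal(sort(ann$genes[[1]]), "g3")
  # gene abutting the block end (gene.start == block.end) is included
  block2 <- GenomicRanges::GRanges("chr1",
                                   IRanges::IRanges(5000L, 5501L))
  ann2 <- annotateBlocks(block2, gff)
  expect_setequal(ann2$genes[[1]], c("g3", "g4"))
  # two genes inside a wide block
  block3 <- GenomicRanges::GRanges("chr1",
                                   IRanges::IRanges(1L, 2500L))
  expect_equal(annotateBlocks(block3, gff)$n_genes[[1]], 2L)
})
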