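test_that("marker filtering applies strict MAF and missingness rules", {
  # 10 markers x 10 lines: marker 1 MAF exactly 0.05 (1 alt allele of
  # 20), marker 2 fully missing-heavy, marker 3 monomorphic; rest clean
  set.seed(1)
  d <- matrix(sample(c(0L, 2L), 100, TRUE), 10, 10,
              dimnames = list(NULL, paste0("l", 1:10)))
  d[1, ] <- c(1L, rep(0L, 9))            # MAF = 0.05 exactly
  d[2, 1:9] <- NA                        # missing fraction 0.9
  d[3, ] <- 2L                           # monomorphic
  d[4, ] <- rep(c(0L, 2L), 5)            # MAF 0.5, fully called
  gm <- genotypeMatrix(d, rep("chr1", 10), (1:10) * 100L)
  kept <- markerFilter(gm)
  expect_equal(nrow(kept), 7L)
  kept_pos <- markerInfo(kept)$pos
  expect_false(any(c(100L, 200L, 300L) %in% kept_pos))
  expect_true(400L %in% kept_pos)
  expect_error(markerFilter(gm, min_maf = 0.99), "no markers")
})

test_that("association scan finds a planted QTL and is deterministic", {
  fx <- panelFixture()
  mi <- markerInfo(fx$gm)
  spec <- archetypeQTLSpec(fx$gm, "MAJOR", seed = 4)
  ph <- simulatePhenotypes(fx$gm, spec, seed = 5)
  qt <- associateQTL(fx$gm, ph, trait = "MAJOR", n_permutations = 100,
                     seed = 9)
  expect_gt(nrow(qt), 0L)
  # the top peak lies within the planted QTL's LD neighborhood
  top <- qt[which.min(qt$p_value), ]
  expect_equal(top$chrom, spec@qtls$chrom[1])
  expect_lt(abs(top$pos - spec@qtls$pos[1]), 5e5)
  # permutation threshold reproducible for a fixed seed
  qt2 <- associateQTL(fx$gm, ph, trait = "MAJOR", n_permutations = 100,
                      seed = 9)
  expect_identical(attr(qt, "perm_threshold"),
                   attr(qt2, "perm_threshold"))
  # constant phenotype: warning, no QTLs
  flat <- ph; flat$value <- 1
  expect_warning(q0 <- associateQTL(fx$gm, flat, trait = "MAJOR",
                                    n_permutations = 0), "constant")
  expect_equal(nrow(q0), 0L)
})

test_that("original PVE is the single-marker coefficient of determination", {
  pan <- simulatePanmicticLines(120, 300, c(chr1 = 1e6), seed = 31)
  mi <- markerInfo(pan)
  i <- which(markerMAF(pan) > 0.3)[1]
  # noise-free single-QTL trait: R^2 = 1
  spec <- qtlSpec(data.frame(trait = "t", chrom = mi$chrom[i],
                             pos = mi$pos[i], target_pve = 1,
                             favorable_allele = "alt"), h2 = 1)
  ph <- simulatePhenotypes(pan, spec, n_replicates = 1, seed = 1)
  expect_equal(suppressWarnings(originalPVE(pan, ph, marker = i,
                                            trait = "t")), 1,
               tolerance = 1e-9)
  # dosage orthogonal to the trait: R^2 near 0
  y <- stats::setNames(rnorm(ncol(pan)), colnames(dosage(pan)))
  expect_lt(originalPVE(pan, y, marker = i), 0.1)
  # monomorphic marker: undefined
  d <- dosage(pan); d[7, ] <- 0L
  gm2 <- genotypeMatrix(d, mi$chrom, mi$pos)
  expect_error(originalPVE(gm2, y, marker = 7), "monomorphic")
})

test_that("corrected PVE decomposition keeps its exact identities", {
  pan <- simulatePanmicticLines(150, 300, c(chr1 = 1e6), seed = 32)
  mi <- markerInfo(pan)
  ix <- which(markerMAF(pan) > 0.3)[c(1, 20, 40)]
  spec <- qtlSpec(data.frame(trait = "t", chrom = mi$chrom[ix],
                             pos = mi$pos[ix],
                             target_pve = c(0.3, 0.2, 0.1),
                             favorable_allele = "alt"))
  ph <- simulatePhenotypes(pan, spec, seed = 2)
  y <- phenotypeMeans(ph)
  q <- data.frame(marker = rownames(mi)[ix])
  cp <- correctedPVE(pan, y, q)
  # shares sum exactly to the full-model R^2
  expect_equal(sum(cp), attr(cp, "full_r2"), tolerance = 1e-9)
  # iid markers are near-orthogonal: corrected tracks original
  orig <- unname(vapply(ix, function(i) originalPVE(pan, y, i),
                        numeric(1)))
  expect_equal(as.numeric(cp), orig, tolerance = 0.06)
  # a single QTL's corrected PVE equals its original PVE exactly
  cp1 <- correctedPVE(pan, y, q[1, , drop = FALSE])
  expect_equal(as.numeric(cp1), orig[1], tolerance = 1e-9)
  # duplicated marker: aliased, share 0, with a warning
  expect_warning(
    cp2 <- correctedPVE(pan, y, data.frame(marker = q$marker[c(1, 1)])),
    "aliased")
  expect_equal(as.numeric(cp2[2]), 0)
  expect_equal(sum(cp2), attr(cp2, "full_r2"), tolerance = 1e-9)
})

test_that("trait classification implements the four-group rules", {
  mk <- function(orig, corr) data.frame(original_pve = orig,
                                        corrected_pve = corr)
  expect_equal(classifyTrait(mk(0.8, 0.8)), "MAJOR")
  expect_equal(classifyTrait(mk(c(0.35, 0.08, 0.07, 0.06, 0.09),
                                c(0.35, 0.08, 0.07, 0.06, 0.09))),
               "MAJOR_PLUS_MINOR")
  expect_equal(classifyTrait(mk(c(0.5, 0.2), c(0.5, -0.1))),
               "COMPLEX_INTERACTION")
  expect_equal(classifyTrait(mk(c(0.1, 0.08), c(0.1, 0.08))), "LOW_PVE")
  # a major QTL whose companions are all below the minor threshold
  expect_equal(classifyTrait(mk(c(0.4, 0.03), c(0.4, 0.03))), "MAJOR")
  # negative corrected PVE takes precedence over a major QTL
  expect_equal(classifyTrait(mk(c(0.8, 0.2), c(0.9, -0.05))),
               "COMPLEX_INTERACTION")
  # order invariance
  q <- mk(c(0.35, 0.08, 0.07), c(0.35, 0.08, 0.07))
  expect_equal(classifyTrait(q), classifyTrait(q[c(3, 1, 2), ]))
  expect_warning(cl <- classifyTrait(mk(numeric(0), numeric(0))),
                 "no QTLs")
  expect_equal(cl, "LOW_PVE")
})

test_that("accumulated PVE trajectories track favorable-allele gains", {
  ped <- handPedigree()
  lines <- pedigreeNodes(ped)$name
  # five QTL markers; favorable allele (dosage 2) arrives step by step:
  # the major at R1, the four minors at R2..R4 and one only in R4
  d <- matrix(0L, 5, length(lines), dimnames = list(NULL, lines))
  d[1, c("R1", "R2", "R3", "R4")] <- 2L
  d[2, c("R2", "R3", "R4")] <- 2L
  d[3, c("R3", "R4")] <- 2L
  d[4, c("R4")] <- 2L
  d[5, c("R4")] <- 2L
  gm <- genotypeMatrix(d, rep("chr1", 5), (1:5) * 1e5L,
                       lineData = pedigreeNodes(ped))
  qtls <- data.frame(marker = rownames(markerInfo(gm)),
                     favorable_allele = "alt",
                     corrected_pve = c(0.40, 0.05, 0.05, 0.05, -0.02))
  traj <- accumulatedPVETrajectory(qtls, gm, ped)
  expect_equal(traj$accumulated_pve[traj$line == "F1"], 0)
  expect_equal(traj$accumulated_pve[traj$line == "R1"], 0.40)
  expect_equal(traj$accumulated_pve[traj$line == "R4"], 0.55)
  # negative corrected PVE is clamped in the display column but kept in
  # the signed version
  expect_equal(traj$accumulated_pve_signed[traj$line == "R4"], 0.53)
  # the major QTL produces the large early jump
  inc <- diff(traj$accumulated_pve)
  expect_equal(which.max(inc), 1L)
})

test_that("ancestral consistency separates simple from complex traits", {
  ped <- generatePedigree(12, 0, 0, 1940, seed = 2)
  nodes <- pedigreeNodes(ped)
  lines <- nodes$name
  d_same <- matrix(2L, 6, length(lines), dimnames = list(NULL, lines))
  gm_same <- genotypeMatrix(d_same, rep("chr1", 6), (1:6) * 1e5L,
                            lineData = nodes)
  qtls <- data.frame(marker = rownames(markerInfo(gm_same)))
  ac <- ancestralConsistency(qtls, gm_same, ped, n_ancestors = 10)
  expect_equal(ac$fraction, 1)
  # every pair of lines differs at >= 2 QTLs (each line's index encoded
  # in doubled binary digits): fraction exactly 0
  bits <- sapply(seq_along(lines), function(j)
    as.integer(intToBits(j))[1:5])
  d_diff <- 2L * rbind(bits, bits)
  colnames(d_diff) <- lines
  gm_diff <- genotypeMatrix(d_diff, rep("chr1", 10), (1:10) * 1e5L,
                            lineData = nodes)
  qtls10 <- data.frame(marker = rownames(markerInfo(gm_diff)))
  ac2 <- ancestralConsistency(qtls10, gm_diff, ped, n_ancestors = 10)
  expect_equal(ac2$fraction, 0)
  expect_warning(
    ancestralConsistency(qtls, gm_same, ped, n_ancestors = 100),
    "ancestors")
})
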