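test_that("the S-curve maps PVE to selection probability as specified", {
  p0 <- 0.05
  expect_equal(selectionProbability(0.05), p0)
  expect_equal(selectionProbability(0.10), p0)
  expect_equal(selectionProbability(0.25), 1)
  expect_equal(selectionProbability(0.30), 1)
  # smoothstep midpoint
  expect_equal(selectionProbability(0.175), p0 + (1 - p0) * 0.5,
               tolerance = 1e-12)
  # continuous and monotone non-decreasing
  grid <- selectionProbability(seq(0, 1, by = 0.005))
  expect_true(all(diff(grid) >= 0))
  expect_error(
    selectionProbability(0.2, list(lower = 0.3, upper = 0.1,
                                   floor = 0.05)),
    "ordered")
})

test_that("simulation configs are validated", {
  expect_error(simConfig(1), "population_size")
  expect_error(simConfig(100, h2 = 0), "h2")
  expect_error(simConfig(100, replaced_fraction = 1), "replaced_fraction")
  expect_error(simConfig(100, qtl = data.frame(pve = 1.5, init_freq = 0)),
               "fraction")
  cfg <- simConfig(100, seed = 3)
  expect_s3_class(cfg, "SimConfig")
  expect_output(print(cfg), "N=100")
})

test_that("initial populations are Hardy-Weinberg draws", {
  cfg0 <- simConfig(200, qtl = data.frame(pve = 0.2, init_freq = 0))
  set.seed(1)
  pop0 <- initPopulation(cfg0)
  expect_true(all(pop0$A == 0L) && all(pop0$B == 0L))

  cfg <- simConfig(10000, qtl = data.frame(pve = 0.2, init_freq = 0.5))
  set.seed(2)
  pop <- initPopulation(cfg)
  het <- mean((pop$A + pop$B) == 1L)
  expect_equal(het, 0.5, tolerance = 0.015)
  set.seed(7); a <- initPopulation(cfg)
  set.seed(7); b <- initPopulation(cfg)
  expect_identical(a, b)
})

test_that("phenotype evaluation respects the heritability noise model", {
  # all genetic variance on the QTL at h2 = 1: phenotype == genetic value
  cfg <- simConfig(500, h2 = 1, qtl = data.frame(pve = 1,
                                                 init_freq = 0.5))
  set.seed(3)
  pop <- initPopulation(cfg)
  ev <- evaluatePhenotypes(pop, cfg)
  expect_equal(ev$phenotype, ev$genetic)
  # all loci fixed: phenotype variance is environmental only
  cfg2 <- simConfig(2000, h2 = 0.5, qtl = data.frame(pve = 0.5,
                                                     init_freq = 1))
  set.seed(4)
  pop2 <- initPopulation(cfg2)
  ev2 <- evaluatePhenotypes(pop2, cfg2)
  expect_equal(var(ev2$genetic), 0)
  expect_equal(var(ev2$phenotype), 1 / 0.5 - 0.5, tolerance = 0.1)
})

test_that("one generation of selection behaves at the degenerate limits", {
  cfg <- simConfig(100, replaced_fraction = 0,
                   qtl = data.frame(pve = 0.3, init_freq = 0.5))
  set.seed(5)
  pop <- initPopulation(cfg)
  ev <- evaluatePhenotypes(pop, cfg)
  expect_identical(stepGeneration(pop, ev$phenotype, cfg), pop)

  # no mutation and favorable allele absent: it can never appear
  cfg2 <- simConfig(200, mutation_rate = 0,
                    qtl = data.frame(pve = 0.3, init_freq = 0))
  set.seed(6)
  pop2 <- initPopulation(cfg2)
  for (g in 1:5) {
    ev2 <- evaluatePhenotypes(pop2, cfg2)
    pop2 <- stepGeneration(pop2, ev2$phenotype, cfg2)
    expect_equal(nrow(pop2$A), 200L)    # population size constant
    expect_true(all(pop2$A == 0L) && all(pop2$B == 0L))
  }
})

test_that("selection raises favorable frequency and is reproducible", {
  cfg <- simConfig(300, n_generations = 40, n_replicates = 8,
                   qtl = data.frame(pve = 0.4, init_freq = 0.1),
                   seed = 11)
  res <- runSimulation(cfg)
  expect_true(all(res$freq >= 0 & res$freq <= 1))
  expect_gt(res$freq[41, 1], 0.9)
  expect_true(all(diff(res$accumulated_pve) >= 0))
  res2 <- runSimulation(cfg)
  expect_identical(res[names(res) != "config"],
                   res2[names(res2) != "config"])
})

test_that("neutral loci drift without a mean trend", {
  cfg <- simConfig(100, n_generations = 25, n_replicates = 40,
                   qtl = data.frame(pve = 0, init_freq = 0.5),
                   mutation_rate = 0, seed = 5)
  res <- runSimulation(cfg)
  # binomial standard error of the replicate-mean frequency
  se <- sqrt(0.5 * 0.5 / (2 * 100 * 40))
  # drift variance accumulates, use a generous 3-sigma envelope on the
  # across-replicate mean at every generation
  drift_se <- sqrt(cumsum(rep(0.25 / (2 * 100), 26)) / 40 + se^2)
  expect_true(all(abs(res$freq[, 1] - 0.5) <= 3 * pmax(drift_se, se)))
})

test_that("response is monotone in pve, heritability and population size", {
  base <- function(pve, N = 300, h2 = 1, seed = 21)
    simConfig(N, n_generations = 60, n_replicates = 15, h2 = h2,
              qtl = data.frame(pve = pve, init_freq = 0), seed = seed)
  final_freq <- function(cfg) {
    r <- runSimulation(cfg)
    r$freq[cfg$n_generations + 1, 1]
  }
  f_pve <- vapply(c(0.10, 0.25, 0.40), function(p)
    final_freq(base(p)), numeric(1))
  expect_true(all(diff(f_pve) >= -0.05))
  expect_gt(f_pve[3], f_pve[1])
  f_N <- vapply(c(100, 2000), function(N)
    final_freq(base(0.25, N = N)), numeric(1))
  expect_gte(f_N[2], f_N[1] - 0.05)
  f_h2 <- vapply(c(0.2, 1), function(h)
    final_freq(base(0.25, h2 = h)), numeric(1))
  expect_gte(f_h2[2], f_h2[1] - 0.05)
})

test_that("the generation update matches a brute-force reimplementation", {
  # distributional equivalence on a 2-locus, N = 50 scenario
  cfg <- simConfig(50, replaced_fraction = 0.5, mutation_rate = 1e-3,
                   qtl = data.frame(pve = c(0.3, 0.2),
                                    init_freq = c(0.3, 0.5)))
  eff <- breedtrace:::.sim_effects(cfg)
  run_one <- function(seed, impl) {
    set.seed(seed)
    pop <- initPopulation(cfg)
    for (g in 1:10) {
      ev <- evaluatePhenotypes(pop, cfg)
      pop <- if (impl == "pkg")
        stepGeneration(pop, ev$phenotype, cfg)
      else
        bruteStep(pop$A, pop$B, ev$phenotype, 0.5, eff$mu_eff)
    }
    colSums(pop$A + pop$B) / (2 * 50)
  }
  f_pkg <- t(vapply(1:300, function(s) run_one(s, "pkg"), numeric(2)))
  f_brute <- t(vapply(301:600, function(s) run_one(s, "brute"),
                      numeric(2)))
  for (l in 1:2) {
    ks <- suppressWarnings(stats::ks.test(f_pkg[, l], f_brute[, l]))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("minimum-PVE search scans ascending grids correctly", {
  cfg <- simConfig(400, n_generations = 60, n_replicates = 12, seed = 31)
  expect_error(minimumPVE(cfg, numeric(0)), "empty")
  expect_error(minimumPVE(cfg, c(0.3, 0.1)), "ascending")
  m <- minimumPVE(cfg, c(0.30, 0.40))
  expect_false(is.na(m))
  tab <- attr(m, "table")
  expect_true(all(tab$decided))
  expect_equal(tab$pve[which(tab$success_fraction >= 0.5)[1]],
               as.numeric(m))
})

test_that("parameter sweeps tabulate breedability endpoints", {
  cfg <- simConfig(200, n_generations = 50, n_replicates = 10,
                   qtl = data.frame(pve = 0.3, init_freq = 0),
                   seed = 41)
  sw <- sweepExperiment("population_size", c(100, 800), cfg)
  expect_equal(nrow(sw), 2L)
  expect_true(all(c("success_fraction", "mean_fixation_generation",
                    "final_accumulated_pve", "genetic_gain")
                  %in% colnames(sw)))
  # larger populations fix sooner
  expect_lte(sw$mean_fixation_generation[2],
             sw$mean_fixation_generation[1] + 5)
  expect_error(sweepExperiment("bogus", 1, cfg), "arg")
})
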