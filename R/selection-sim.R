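#' Configure a forward-time artificial-selection simulation
#'
#' The simulator follows the classical four-module scheme of artificial
#' selection evaluation: (1) an initial population of `population_size`
#' diploids drawn from Hardy-Weinberg proportions at each QTL; (2)
#' phenotypes computed from QTL effects plus noise; (3) truncation
#' selection replacing the least fit `replaced_fraction` of the
#' population with (4) offspring of the survivors, produced by random
#' mating with Mendelian segregation at unlinked loci, every transmitted
#' allele mutating at the *modified* rate - the natural mutation rate
#' times the selection probability of the locus, where the selection
#' probability is an S-shaped function of the QTL's share of phenotypic
#' variance (see [selectionProbability()]).
#'
#' Variance scale: the total genetic variance of the trait is normalized
#' to 1, QTL `j` contributing `pve_j` of it; at heritability `h2` the
#' phenotype adds Gaussian noise of variance `1/h2 - sum(pve)`
#' (unmodeled polygenic background plus environment, redrawn each
#' generation). Allele effects are calibrated at the initial frequency,
#' or at frequency 0.5 when the favorable allele starts absent or fixed.
#' The S-curve receives `pve * h2`, the QTL's realized share of
#' *phenotypic* variance.
#'
#' @param population_size diploid individuals N (>= 2), constant.
#' @param n_generations generations G (default 100).
#' @param n_replicates independent runs averaged (default 100).
#' @param h2 heritability in (0, 1]; 0 is rejected (the phenotype would
#'   carry no signal).
#' @param mutation_rate natural per-allele per-generation mutation rate
#'   (default 1e-4, the rate at which new favorable variants enter a
#'   breeding program).
#' @param replaced_fraction fraction replaced each generation (default
#'   0.5; must leave at least one survivor).
#' @param qtl `data.frame` with columns `pve` (per-QTL fraction of
#'   genetic variance) and `init_freq` (initial favorable-allele
#'   frequency; default 0 - favorable variants must arise by mutation).
#' @param interactions optional `data.frame` (`qtl_i`, `qtl_j`, `pve`
#'   signed) of pairwise epistatic terms entering the genetic value as
#'   `w * (g_i/2) * (g_j/2)`.
#' @param s_curve list with `lower`, `upper`, `floor` (defaults 0.10,
#'   0.25, 0.05).
#' @param fixation_freq frequency at which a locus counts as fixed
#'   (default 0.99).
#' @param directional_mutation if `TRUE` (default) mutation flips only
#'   unfavorable to favorable alleles (selected variants entering the
#'   program); `FALSE` gives symmetric mutation.
#' @param seed integer; replicate `r` uses `seed + r`.
#' @return a validated `SimConfig` list.
#' @export
simConfig <- function(population_size, n_generations = 100L,
                      n_replicates = 100L, h2 = 1,
                      mutation_rate = 1e-4, replaced_fraction = 0.5,
                      qtl = data.frame(pve = 0.25, init_freq = 0),
                      interactions = NULL,
                      s_curve = list(lower = 0.10, upper = 0.25,
                                     floor = 0.05),
                      fixation_freq = 0.99,
                      directional_mutation = TRUE, seed = 1L) {
  if (population_size < 2) stop("population_size must be >= 2")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (h2 <= 0 || h2 > 1)
    stop("h2 must be in (0, 1]: at 0 the phenotype carries no signal")
  if (mutation_rate < 0 || mutation_rate > 1)
    stop("mutation_rate must be a fraction")
  if (replaced_fraction < 0 || replaced_fraction >= 1)
    stop("replaced_fraction must be in [0, 1): at 1 no survivors remain")
  if (round(replaced_fraction * population_size) >= population_size)
    stop("replaced_fraction leaves no survivors")
  if (!all(c("pve", "init_freq") %in% names(qtl)))
    qtl$init_freq <- qtl$init_freq %||% 0
  if (any(qtl$pve < 0 | qtl$pve > 1) ||
      any(qtl$init_freq < 0 | qtl$init_freq > 1))
    stop("qtl pve and init_freq must be fractions")
  if (sum(qtl$pve) > 1 + 1e-9)
    stop("total QTL pve exceeds the genetic variance budget (1)")
  if (!(s_curve$lower < s_curve$upper))
    stop("s_curve inflection points must be ordered (lower < upper)")
  if (s_curve$floor < 0 || s_curve$floor > 1)
    stop("s_curve floor must be a fraction")
  structure(list(
    population_size = as.integer(population_size),
    n_generations = as.integer(n_generations),
    n_replicates = as.integer(n_replicates),
    h2 = h2, mutation_rate = mutation_rate,
    replaced_fraction = replaced_fraction,
    qtl = qtl, interactions = interactions,
    s_curve = s_curve, fixation_freq = fixation_freq,
    directional_mutation = directional_mutation,
    seed = as.integer(seed)), class = "SimConfig")
}

#' @export
print.SimConfig <- function(x, ...) {
  cat(sprintf(
    "SimConfig: N=%d, G=%d, %d replicates, h2=%.2f, mu=%.1e, replaced=%.2f\n",
    x$population_size, x$n_generations, x$n_replicates, x$h2,
    x$mutation_rate, x$replaced_fraction))
  cat(sprintf("  %d QTL(s), pve: %s; init freq: %s\n", nrow(x$qtl),
              paste(x$qtl$pve, collapse = ", "),
              paste(x$qtl$init_freq, collapse = ", ")))
  invisible(x)
}

#' S-shaped map from PVE to selection probability
#'
#' The probability that phenotype-based selection acts on a QTL rises
#' sigmoidally with the share of phenotypic variance the QTL explains:
#' a floor probability `p0` up to the lower inflection, 1 from the upper
#' inflection, and cubic smoothstep interpolation
#' `p0 + (1 - p0) (3 t^2 - 2 t^3)` in between - continuous and monotone
#' non-decreasing.
#'
#' @param pve fraction(s) in `[0, 1]`.
#' @param s_curve list with `lower` (default 0.10), `upper` (default
#'   0.25) and `floor` (default 0.05).
#' @return selection probabilities, same length as `pve`.
#' @examples
#' selectionProbability(c(0.05, 0.175, 0.30))
#' @export
selectionProbability <- function(pve,
                                 s_curve = list(lower = 0.10,
                                                upper = 0.25,
                                                floor = 0.05)) {
  if (!(s_curve$lower < s_curve$upper))
    stop("s_curve inflection points must be ordered (lower < upper)")
  stopifnot(all(pve >= 0 & pve <= 1))
  t <- pmin(pmax((pve - s_curve$lower) /
                   (s_curve$upper - s_curve$lower), 0), 1)
  s_curve$floor + (1 - s_curve$floor) * (3 * t^2 - 2 * t^3)
}

# allele effects and noise sd implied by a config
.sim_effects <- function(config) {
  p_ref <- config$qtl$init_freq
  p_ref[p_ref <= 0 | p_ref >= 1] <- 0.5
  a <- sqrt(config$qtl$pve / (2 * p_ref * (1 - p_ref)))
  used <- sum(config$qtl$pve)
  if (!is.null(config$interactions))
    used <- used + sum(abs(config$interactions$pve))
  noise_sd <- sqrt(max(0, 1 / config$h2 - used))
  mu_eff <- config$mutation_rate *
    selectionProbability(pmin(config$qtl$pve * config$h2, 1),
                         config$s_curve)
  list(a = a, noise_sd = noise_sd, mu_eff = mu_eff)
}

#' Draw the initial population
#'
#' `N` diploid genotypes at the QTL loci, each locus sampled
#' independently in Hardy-Weinberg proportions at its initial favorable
#' frequency (two independent Bernoulli alleles per individual).
#'
#' @param config a [simConfig()] object.
#' @return population: list of two `N x L` 0/1 haplotype matrices `A`
#'   and `B` (favorable allele = 1).
#' @export
initPopulation <- function(config) {
  N <- config$population_size
  L <- nrow(config$qtl)
  p <- config$qtl$init_freq
  list(A = matrix(rbinom(N * L, 1L, rep(p, each = N)), N, L),
       B = matrix(rbinom(N * L, 1L, rep(p, each = N)), N, L))
}

#' Evaluate phenotypes of a population
#'
#' Genetic value `sum_j a_j g_j` (plus any epistatic terms) with Gaussian
#' noise of variance `1/h2 - sum(pve)`, redrawn at every call.
#'
#' @param population from [initPopulation()] / [stepGeneration()].
#' @param config a [simConfig()] object.
#' @return list with `phenotype` and `genetic` numeric vectors.
#' @export
evaluatePhenotypes <- function(population, config) {
  eff <- .sim_effects(config)
  g <- population$A + population$B
  G <- drop(g %*% eff$a)
  if (!is.null(config$interactions)) {
    for (r in seq_len(nrow(config$interactions))) {
      ii <- config$interactions$qtl_i[r]
      jj <- config$interactions$qtl_j[r]
      term <- (g[, ii] / 2) * (g[, jj] / 2)
      w <- sign(config$interactions$pve[r]) *
        sqrt(abs(config$interactions$pve[r]) / 0.25)
      G <- G + w * term
    }
  }
  ph <- G + rnorm(length(G), sd = eff$noise_sd)
  list(phenotype = ph, genetic = G)
}

#' Advance the population one generation
#'
#' Individuals are ranked by phenotype (ties broken by stable index);
#' the top `(1 - replaced_fraction) N` survive unchanged, and offspring
#' fill the remainder: each offspring draws two parents uniformly (with
#' replacement, selfing permitted) from the survivors, inherits one
#' allele per locus per parent, and every transmitted allele mutates at
#' the locus's modified rate `mu * selectionProbability(pve * h2)` -
#' by default directionally, unfavorable to favorable only.
#'
#' @param population current population.
#' @param phenotypes phenotype vector from [evaluatePhenotypes()].
#' @param config a [simConfig()] object.
#' @return the next population (same size).
#' @export
stepGeneration <- function(population, phenotypes, config) {
  N <- config$population_size
  n_off <- round(config$replaced_fraction * N)
  if (n_off == 0L) return(population)
  n_s <- N - n_off
  eff <- .sim_effects(config)
  ord <- order(-phenotypes, seq_along(phenotypes))
  surv <- ord[seq_len(n_s)]
  A <- population$A; B <- population$B
  L <- ncol(A)

  draw_gametes <- function(par) {
    ha <- A[par, , drop = FALSE]
    hb <- B[par, , drop = FALSE]
    pick <- matrix(runif(n_off * L) < 0.5, n_off, L)
    ha[pick] <- hb[pick]
    ha
  }
  p1 <- surv[sample.int(n_s, n_off, replace = TRUE)]
  p2 <- surv[sample.int(n_s, n_off, replace = TRUE)]
  childA <- draw_gametes(p1)
  childB <- draw_gametes(p2)
  for (l in seq_len(L)) {
    mu <- eff$mu_eff[l]
    if (mu <= 0) next
    for (hap in c("A", "B")) {
      h <- if (hap == "A") childA[, l] else childB[, l]
      z <- which(h == 0L)
      if (length(z)) h[z[runif(length(z)) < mu]] <- 1L
      if (!config$directional_mutation) {
        o <- which(h == 1L & !(seq_along(h) %in% z))
        if (length(o)) h[o[runif(length(o)) < mu]] <- 0L
      }
      if (hap == "A") childA[, l] <- h else childB[, l] <- h
    }
  }
  list(A = rbind(A[surv, , drop = FALSE], childA),
       B = rbind(B[surv, , drop = FALSE], childB))
}

# one replicate; returns trajectories unless decide_only
.sim_replicate <- function(config, rep_seed, decide_only = FALSE) {
  set.seed(rep_seed)
  G <- config$n_generations
  L <- nrow(config$qtl)
  pop <- initPopulation(config)
  N2 <- 2 * config$population_size
  freq <- matrix(NA_real_, G + 1L, L)
  gen_mean <- numeric(G + 1L)
  freq[1L, ] <- (colSums(pop$A) + colSums(pop$B)) / N2
  ever_fixed <- freq[1L, ] >= config$fixation_freq
  fix_gen <- ifelse(ever_fixed, 0L, NA_integer_)
  acc <- numeric(G + 1L)
  acc[1L] <- sum(config$qtl$pve[ever_fixed])
  eff <- .sim_effects(config)
  gen_mean[1L] <- mean(drop((pop$A + pop$B) %*% eff$a))
  for (g in seq_len(G)) {
    ev <- evaluatePhenotypes(pop, config)
    pop <- stepGeneration(pop, ev$phenotype, config)
    f <- (colSums(pop$A) + colSums(pop$B)) / N2
    newly <- !ever_fixed & f >= config$fixation_freq
    fix_gen[newly] <- g
    ever_fixed <- ever_fixed | newly
    freq[g + 1L, ] <- f
    acc[g + 1L] <- sum(config$qtl$pve[ever_fixed])
    gen_mean[g + 1L] <- mean(drop((pop$A + pop$B) %*% eff$a))
    if (all(ever_fixed) && decide_only) break
    if (all(ever_fixed) && all(f >= config$fixation_freq) &&
        config$directional_mutation) {
      # fixed loci cannot revert under directional mutation: latch
      if (g < G) {
        freq[(g + 2L):(G + 1L), ] <- rep(f, each = G - g)
        acc[(g + 2L):(G + 1L)] <- acc[g + 1L]
        gen_mean[(g + 2L):(G + 1L)] <- gen_mean[g + 1L]
      }
      break
    }
  }
  success <- all(ever_fixed)
  if (decide_only) return(list(success = success))
  list(success = success, freq = freq, acc = acc, gen_mean = gen_mean,
       fix_gen = fix_gen)
}

#' Run a replicated selection simulation
#'
#' Runs `n_replicates` independent replicates of `n_generations`
#' generations (replicate `r` seeded with `seed + r`) and averages the
#' trajectories. A replicate *succeeds* when every QTL reaches the
#' fixation frequency within the run; accumulated PVE latches per
#' replicate at fixation, so its replicate average rises smoothly.
#'
#' @param config a [simConfig()] object.
#' @return a `SimResult` list: `freq` (mean favorable-allele frequency,
#'   `(G+1) x L`, generation 0 first), `accumulated_pve`, `mean_genetic`
#'   (mean genetic value per generation), `success_fraction`, `fix_gen`
#'   (replicate x locus fixation generations, NA when not fixed), and
#'   the `config`.
#' @examples
#' cfg <- simConfig(200, n_generations = 30, n_replicates = 10,
#'                  qtl = data.frame(pve = 0.4, init_freq = 0), seed = 1)
#' res <- runSimulation(cfg)
#' res$success_fraction
#' @export
runSimulation <- function(config) {
  R <- config$n_replicates
  L <- nrow(config$qtl)
  G <- config$n_generations
  freq <- matrix(0, G + 1L, L)
  acc <- numeric(G + 1L)
  gen_mean <- numeric(G + 1L)
  fix_gen <- matrix(NA_integer_, R, L)
  succ <- logical(R)
  for (r in seq_len(R)) {
    one <- .sim_replicate(config, config$seed + r)
    freq <- freq + one$freq
    acc <- acc + one$acc
    gen_mean <- gen_mean + one$gen_mean
    fix_gen[r, ] <- one$fix_gen
    succ[r] <- one$success
  }
  structure(list(freq = freq / R, accumulated_pve = acc / R,
                 mean_genetic = gen_mean / R,
                 success_fraction = mean(succ),
                 fix_gen = fix_gen, config = config),
            class = "SimResult")
}

#' @export
print.SimResult <- function(x, ...) {
  G <- x$config$n_generations
  cat(sprintf(
    "SimResult: %d replicates, success fraction %.2f\n",
    x$config$n_replicates, x$success_fraction))
  cat(sprintf("  final mean frequency: %s; final accumulated PVE %.3f\n",
              paste(sprintf("%.3f", x$freq[G + 1L, ]), collapse = ", "),
              x$accumulated_pve[G + 1L]))
  invisible(x)
}

#' Minimum PVE breedable at a given population size
#'
#' Scans a PVE grid in ascending order and returns the smallest value at
#' which the success fraction (all loci fixed within the run) reaches
#' `success_threshold`. Replicates for a grid value stop as soon as the
#' success/failure decision is settled, which cannot change the
#' decision; the search stops at the first succeeding value since the
#' response is monotone in PVE.
#'
#' @param config a [simConfig()] object; its `qtl` table is replaced by
#'   a single QTL at each grid value (initial frequency taken from the
#'   config's first QTL).
#' @param pve_grid ascending grid of PVE values.
#' @param success_threshold required success fraction (default 0.5).
#' @param scan_all if `TRUE`, evaluate every grid value fully instead of
#'   stopping at the first success (slower; full response curve).
#' @return the smallest succeeding PVE (`NA` if none succeeds), with
#'   attribute `table` (`data.frame`: pve, success_fraction based on the
#'   replicates run, n_replicates_run, decided).
#' @export
minimumPVE <- function(config, pve_grid = seq(0.05, 0.40, by = 0.01),
                       success_threshold = 0.5, scan_all = FALSE) {
  if (!length(pve_grid)) stop("pve_grid is empty")
  if (is.unsorted(pve_grid)) stop("pve_grid must be ascending")
  R <- config$n_replicates
  need <- ceiling(success_threshold * R)
  rows <- list()
  found <- NA_real_
  for (i in seq_along(pve_grid)) {
    cfg <- config
    cfg$qtl <- data.frame(pve = pve_grid[i],
                          init_freq = config$qtl$init_freq[1L])
    base_seed <- config$seed + 100000L * i
    s <- 0L; f <- 0L
    for (r in seq_len(R)) {
      res <- .sim_replicate(cfg, base_seed + r, decide_only = TRUE)
      if (res$success) s <- s + 1L else f <- f + 1L
      if (s >= need || f > R - need) break
    }
    rows[[i]] <- data.frame(pve = pve_grid[i],
                            success_fraction = s / (s + f),
                            n_replicates_run = s + f,
                            decided = s >= need || f > R - need)
    if (s >= need) { found <- pve_grid[i]; if (!scan_all) break }
  }
  structure(found, table = do.call(rbind, rows))
}

#' Parameter sweep over the simulator
#'
#' Reruns [runSimulation()] varying one of `population_size`,
#' `heritability` or `mutation_rate`, everything else held fixed, and
#' tabulates the endpoints that summarize breedability: success
#' fraction, mean fixation generation (over fixed replicate-loci), final
#' accumulated PVE, and the genetic gain (final minus initial mean
#' genetic value).
#'
#' @param parameter one of `"population_size"`, `"heritability"`,
#'   `"mutation_rate"`.
#' @param values values to scan (non-empty).
#' @param config base [simConfig()] object.
#' @return `data.frame` with one row per value; the full `SimResult`s
#'   are in the `results` attribute.
#' @export
sweepExperiment <- function(parameter, values, config) {
  parameter <- match.arg(parameter,
                         c("population_size", "heritability",
                           "mutation_rate"))
  if (!length(values)) stop("values is empty")
  results <- list()
  rows <- list()
  for (i in seq_along(values)) {
    cfg <- config
    if (parameter == "population_size")
      cfg$population_size <- as.integer(values[i])
    else if (parameter == "heritability") cfg$h2 <- values[i]
    else cfg$mutation_rate <- values[i]
    cfg$seed <- config$seed + 1000L * i
    res <- runSimulation(cfg)
    G <- cfg$n_generations
    rows[[i]] <- data.frame(
      parameter = parameter, value = values[i],
      success_fraction = res$success_fraction,
      mean_fixation_generation = mean(res$fix_gen, na.rm = TRUE),
      final_accumulated_pve = res$accumulated_pve[G + 1L],
      genetic_gain = res$mean_genetic[G + 1L] - res$mean_genetic[1L],
      final_freq = mean(res$freq[G + 1L, ]))
    results[[i]] <- res
  }
  out <- do.call(rbind, rows)
  attr(out, "results") <- results
  out
}
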