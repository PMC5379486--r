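#' Gene-drop genotypes down a breeding pedigree
#'
#' Founders and donors are drawn as fully homozygous haplotypes from a
#' panmictic pool; each cross produces an inbred child by recombining the
#' two parental haplotypes (Poisson crossover count per chromosome,
#' uniform placement, no interference) and fixing the recombinant to
#' homozygosity - the single-haplotype equivalent of repeated selfing. A
#' configurable fraction of the genome is biased toward the recurrent
#' parent, mimicking the backcross-style structure of elite-line
#' improvement. Residual heterozygosity and missing calls are injected at
#' chip-like rates so that downstream filters are exercised.
#'
#' @param pedigree a [PedigreeGraph-class].
#' @param n_markers total marker count, allocated to chromosomes in
#'   proportion to length (>= 2 per chromosome).
#' @param chrom_lengths numeric vector of chromosome lengths in bp; names
#'   become chromosome names (default `chr1`, `chr2`, ...).
#' @param founder_diversity in (0, 1]: founder-pool allele frequencies are
#'   drawn uniformly from `0.5 +/- 0.45 * founder_diversity`.
#' @param recomb_rate per-bp crossover rate per meiosis (default 4e-8,
#'   about 4 cM/Mb).
#' @param rp_bias expected fraction of the child genome inherited from the
#'   recurrent parent (0.5 = unbiased Mendelian; 1 = clonal copy of the
#'   recurrent parent).
#' @param het_rate residual heterozygote rate per call (default 0.01).
#' @param missing_rate missing-call rate per call (default 0.02).
#' @param seed integer seed.
#' @return a [GenotypeMatrix-class] covering every pedigree node.
#' @examples
#' ped <- generatePedigree(4, 0, 0, 1950, seed = 1)
#' gm <- simulateGenotypes(ped, n_markers = 200,
#'                         chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
#'                         seed = 1)
#' gm
#' @export
simulateGenotypes <- function(pedigree, n_markers = 2000L,
                              chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
                              founder_diversity = 1, recomb_rate = 4e-8,
                              rp_bias = 0.75, het_rate = 0.01,
                              missing_rate = 0.02, seed = 1L) {
  stopifnot(is(pedigree, "PedigreeGraph"))
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  set.seed(seed)

  n_chr <- round(n_markers * chrom_lengths / sum(chrom_lengths))
  n_chr[length(n_chr)] <- n_markers - sum(n_chr[-length(n_chr)])
  if (any(n_chr < 2)) stop("need at least 2 markers per chromosome")
  chrom <- rep(names(chrom_lengths), n_chr)
  pos <- unlist(lapply(seq_along(chrom_lengths), function(i)
    sort(sample.int(chrom_lengths[i], n_chr[i]))), use.names = FALSE)

  nodes <- pedigreeNodes(pedigree)
  edges <- pedigreeEdges(pedigree)
  pool_p <- runif(n_markers, 0.5 - 0.45 * founder_diversity,
                  0.5 + 0.45 * founder_diversity)

  hap <- matrix(NA_integer_, n_markers, nrow(nodes),
                dimnames = list(NULL, nodes$name))
  founders <- setdiff(nodes$name, unique(edges$child))
  for (f in founders)
    hap[, f] <- rbinom(n_markers, 1L, pool_p)

  chr_idx <- split(seq_len(n_markers), factor(chrom, names(chrom_lengths)))
  drop_child <- function(rh, dh) {
    out <- integer(n_markers)
    for (ci in seq_along(chr_idx)) {
      idx <- chr_idx[[ci]]
      p <- pos[idx]
      len <- chrom_lengths[ci]
      k <- rpois(1L, len * recomb_rate)
      cuts <- sort(runif(k, 1, len))
      seg <- findInterval(p, cuts)           # segment index per marker
      from_rec <- (seg + sample(0:1, 1L)) %% 2L == 0L
      # bias donor segments toward the recurrent parent so that the
      # expected recurrent fraction equals rp_bias
      if (rp_bias >= 0.5) {
        flip <- runif(k + 1L) < (2 * rp_bias - 1)
        from_rec <- from_rec | flip[seg + 1L]
      } else {
        flip <- runif(k + 1L) < (1 - 2 * rp_bias)
        from_rec <- from_rec & !flip[seg + 1L]
      }
      out[idx] <- ifelse(from_rec, rh[idx], dh[idx])
    }
    out
  }

  todo <- setdiff(nodes$name, founders)
  todo <- todo[order(nodes$year[match(todo, nodes$name)])]
  for (child in todo) {
    par <- parentsOf(pedigree, child)
    if (anyNA(hap[1L, par]))
      stop("parent genotypes not available for ", child)
    hap[, child] <- drop_child(hap[, par["recurrent"]], hap[, par["donor"]])
  }

  d <- 2L * hap
  if (het_rate > 0) {
    i <- which(runif(length(d)) < het_rate)
    d[i] <- 1L
  }
  if (missing_rate > 0) {
    i <- which(runif(length(d)) < missing_rate)
    d[i] <- NA_integer_
  }
  genotypeMatrix(d, chrom = chrom, pos = pos, lineData = nodes)
}

#' Plant ground-truth selective sweeps and conserved blocks
#'
#' Overwrites regions of a simulated [GenotypeMatrix-class] with the
#' signatures the scan and tracing stages are designed to detect, and
#' returns the truth intervals for test assertions.
#'
#' Within each *sweep region*, every line approved in or after
#' `sweep_cutoff_year` is overwritten with the focal cultivar's haplotype;
#' a fraction of sites then receive a rare derived allele carried by a
#' single swept line, producing the excess of low-frequency variants
#' (negative Tajima's D) characteristic of a selective sweep. Within each
#' *conserved block*, all trunk receptors from `conserved_from_generation`
#' onward (and the focal line) are overwritten with the focal haplotype,
#' creating a block traceable through that many sequential generations;
#' every other line receives either the focal haplotype or its
#' complement (fair coin per line), making the planted region a
#' two-haplotype LD block like the conserved regions of real panels.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param pedigree the matching [PedigreeGraph-class].
#' @param sweep_regions,conserved_blocks [GenomicRanges::GRanges] of truth
#'   intervals (may be empty). Regions of different kinds must not overlap.
#' @param sweep_cutoff_year lines with `year >=` this are swept (default:
#'   the earliest year, i.e. all lines).
#' @param singleton_rate fraction of sweep-region sites receiving one rare
#'   derived allele (default 0.5).
#' @param conserved_from_generation 1-based index into the flow order from
#'   which receptors carry the focal haplotype (default 1 = whole trunk).
#' @param seed integer seed.
#' @return list with elements `genotypes` (modified matrix) and `truth`
#'   (list of the two GRanges, for interval-recovery checks).
#' @export
plantFeatures <- function(genotypes, pedigree,
                          sweep_regions = GRanges(),
                          conserved_blocks = GRanges(),
                          sweep_cutoff_year = NULL,
                          singleton_rate = 0.5,
                          conserved_from_generation = 1L,
                          seed = 1L) {
  stopifnot(is(genotypes, "GenotypeMatrix"), is(pedigree, "PedigreeGraph"))
  if (length(sweep_regions) && length(conserved_blocks) &&
      length(suppressWarnings(findOverlaps(sweep_regions,
                                           conserved_blocks))))
    stop("sweep and conserved truth intervals must not overlap")
  set.seed(seed)
  d <- dosage(genotypes)
  rr <- rowRanges(genotypes)
  li <- lineInfo(genotypes)
  focal <- focalLine(pedigree)
  if (!(focal %in% colnames(d))) stop("focal line absent from genotypes")

  if (length(sweep_regions)) {
    cutoff <- sweep_cutoff_year %||% min(li$year, na.rm = TRUE)
    swept <- li$name[!is.na(li$year) & li$year >= cutoff]
    hits <- unique(S4Vectors::queryHits(findOverlaps(rr, sweep_regions)))
    common <- d[hits, focal]
    common[is.na(common) | common == 1L] <- 0L
    d[hits, swept] <- matrix(common, length(hits), length(swept))
    rare <- hits[runif(length(hits)) < singleton_rate]
    for (i in rare) {
      ln <- sample(swept, 1L)
      d[i, ln] <- 2L - d[i, ln]            # flip to the other homozygote
    }
  }

  if (length(conserved_blocks)) {
    fo <- flowOrder(pedigree)
    carriers <- fo[seq(from = min(conserved_from_generation, length(fo)),
                       to = length(fo))]
    carriers <- intersect(carriers, colnames(d))
    hits <- unique(S4Vectors::queryHits(findOverlaps(rr, conserved_blocks)))
    common <- d[hits, focal]
    common[is.na(common) | common == 1L] <- 2L
    d[hits, carriers] <- matrix(common, length(hits), length(carriers))
    # remaining lines carry one of the two segregating haplotypes, so a
    # planted conserved region is a detectable LD block, as real
    # conserved regions are
    others <- setdiff(colnames(d), carriers)
    carries_focal <- runif(length(others)) < 0.5
    for (k in seq_along(others))
      d[hits, others[k]] <- if (carries_focal[k]) common else 2L - common
  }

  mi <- markerInfo(genotypes)
  list(genotypes = genotypeMatrix(d, chrom = mi$chrom, pos = mi$pos,
                                  ref = mi$ref, alt = mi$alt,
                                  lineData = li),
       truth = list(sweeps = sweep_regions, conserved = conserved_blocks))
}

#' Simulate an unstructured panel of inbred lines
#'
#' Draws fully independent homozygous lines from a panmictic pool - the
#' neutral no-pedigree counterpart of [simulateGenotypes()], used to
#' calibrate statistics that assume exchangeable samples (genome-wide
#' Tajima's D near zero, nominal association type-I error). With
#' `freq_dist = "neutral"` the pool allele frequencies follow the
#' standing neutral spectrum (density proportional to 1/p), under which
#' pi and Watterson's theta have equal expectation; `"uniform"` draws
#' frequencies uniformly on `(maf_min, 1 - maf_min)`.
#'
#' @param n_lines number of inbred lines.
#' @param n_markers total marker count.
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param freq_dist `"neutral"` or `"uniform"`.
#' @param maf_min lower bound of pool frequencies (default 0.002;
#'   keep well below `1/(2 n_lines)` so the sampled spectrum is
#'   effectively untruncated).
#' @param het_rate,missing_rate per-call noise rates (defaults 0).
#' @param inbred if `TRUE` (default) lines are homozygous doubled
#'   haploids; if `FALSE` the two haplotypes are drawn independently
#'   (Hardy-Weinberg diploids) - required for Tajima's D to be centered,
#'   since doubling inbred haplotypes deflates Watterson's theta.
#' @param seed integer seed.
#' @return a [GenotypeMatrix-class] (years/roles are NA).
#' @export
simulatePanmicticLines <- function(n_lines, n_markers = 2000L,
                                   chrom_lengths = c(chr1 = 5e6),
                                   freq_dist = c("neutral", "uniform"),
                                   maf_min = 0.002, het_rate = 0,
                                   missing_rate = 0, inbred = TRUE,
                                   seed = 1L) {
  freq_dist <- match.arg(freq_dist)
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  set.seed(seed)
  n_chr <- round(n_markers * chrom_lengths / sum(chrom_lengths))
  n_chr[length(n_chr)] <- n_markers - sum(n_chr[-length(n_chr)])
  if (any(n_chr < 2)) stop("need at least 2 markers per chromosome")
  chrom <- rep(names(chrom_lengths), n_chr)
  pos <- unlist(lapply(seq_along(chrom_lengths), function(i)
    sort(sample.int(chrom_lengths[i], n_chr[i]))), use.names = FALSE)
  p <- if (freq_dist == "neutral") {
    maf_min^(1 - runif(n_markers))     # inverse CDF of density 1/p
  } else runif(n_markers, maf_min, 1 - maf_min)
  hap <- matrix(rbinom(n_markers * n_lines, 1L, rep(p, n_lines)),
                n_markers, n_lines)
  d <- if (inbred) 2L * hap else
    hap + matrix(rbinom(n_markers * n_lines, 1L, rep(p, n_lines)),
                 n_markers, n_lines)
  if (het_rate > 0) {
    i <- which(runif(length(d)) < het_rate)
    d[i] <- 1L
  }
  if (missing_rate > 0) {
    i <- which(runif(length(d)) < missing_rate)
    d[i] <- NA_integer_
  }
  colnames(d) <- paste0("line", seq_len(n_lines))
  genotypeMatrix(d, chrom = chrom, pos = pos)
}
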