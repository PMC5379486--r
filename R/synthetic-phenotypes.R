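#' Construct a QTLSpec
#'
#' @param qtls `data.frame` with columns `trait`, `chrom`, `pos`,
#'   `target_pve` (fraction of phenotypic variance explained at full
#'   heritability), `favorable_allele` (`"alt"` if the alternate-allele
#'   dosage increases the trait, else `"ref"`).
#' @param interactions optional `data.frame` with columns `trait`,
#'   `qtl_i`, `qtl_j` (indices into the trait's rows of `qtls`, in
#'   `qtls`-row order) and `interaction_pve` (signed fraction; negative
#'   values encode antagonistic epistasis).
#' @param h2 per-trait heritability: either one number recycled to all
#'   traits or a named vector.
#' @return a [QTLSpec-class].
#' @export
qtlSpec <- function(qtls, interactions = NULL, h2 = 1) {
  traits <- unique(qtls$trait)
  if (is.null(names(h2))) h2 <- stats::setNames(rep(h2, length.out = length(traits)), traits)
  if (is.null(interactions))
    interactions <- data.frame(trait = character(), qtl_i = integer(),
                               qtl_j = integer(), interaction_pve = numeric())
  new("QTLSpec", qtls = as.data.frame(qtls),
      interactions = as.data.frame(interactions), h2 = h2)
}

# favorable-allele dosage of a marker (0..2), NA mean-imputed
.favorable_dosage <- function(d, favorable) {
  g <- if (identical(favorable, "ref")) 2L - d else d
  g <- as.numeric(g)
  g[is.na(g)] <- mean(g, na.rm = TRUE)
  g
}

.match_marker <- function(genotypes, chrom, pos) {
  mi <- markerInfo(genotypes)
  i <- which(mi$chrom == chrom & mi$pos == pos)
  if (!length(i)) stop(sprintf("no marker at %s:%d", chrom, pos))
  i[1L]
}

#' Simulate replicated phenotypes from a QTL architecture
#'
#' The genetic value of line *l* for a trait is
#' \deqn{G_l = \sum_i a_i g_{il} + \sum_{ij} w_{ij} (g_{il}/2)(g_{jl}/2),}
#' with `g` the favorable-allele dosage. Effects `a_i` are solved from the
#' target PVE at the *realized* allele frequencies
#' (`2 p q a^2 = target_pve`), and `|w|` from `|interaction_pve|` and the
#' realized variance of the product term, with the sign applied.
#' Variances are on a scale where the total phenotypic variance is 1:
#' genetic variance not attributed to listed QTLs (`h2 - sum(pve)`) is
#' added as a per-line polygenic background drawn once, and environmental
#' noise with variance `1 - h2` is drawn independently per replicate
#' (equivalently, `V_E = V_G (1 - h2)/h2` with total genetic variance
#' normalized to `h2`).
#'
#' QTLs monomorphic at their realized frequency cannot attain their target
#' PVE; they are dropped with a warning and listed in the `dropped`
#' attribute of the result.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param spec a [QTLSpec-class]; QTL positions must exist in the marker map.
#' @param n_replicates replicates per line (default 3, a typical
#'   randomized-block field design).
#' @param seed integer seed.
#' @return long `data.frame` with columns `line`, `trait`, `replicate`,
#'   `value`; attribute `genetic` holds the line-by-trait genetic values
#'   and attribute `dropped` the monomorphic QTLs that were removed.
#' @examples
#' ped <- generatePedigree(4, 0, 0, 1950, seed = 1)
#' gm <- simulateGenotypes(ped, 200, c(chr1 = 1e6), seed = 1,
#'                         missing_rate = 0)
#' spec <- qtlSpec(data.frame(trait = "GL", chrom = "chr1",
#'                            pos = markerInfo(gm)$pos[50],
#'                            target_pve = 0.5, favorable_allele = "alt"))
#' ph <- simulatePhenotypes(gm, spec, seed = 1)
#' head(ph)
#' @export
simulatePhenotypes <- function(genotypes, spec, n_replicates = 3L,
                               seed = 1L) {
  stopifnot(is(genotypes, "GenotypeMatrix"), is(spec, "QTLSpec"))
  set.seed(seed)
  d <- dosage(genotypes)
  lines <- colnames(d)
  out <- list()
  dropped <- list()
  genetic <- list()
  for (tr in unique(spec@qtls$trait)) {
    q <- spec@qtls[spec@qtls$trait == tr, , drop = FALSE]
    h2 <- spec@h2[tr]
    if (is.na(h2)) h2 <- spec@h2[1L]
    midx <- vapply(seq_len(nrow(q)), function(k)
      .match_marker(genotypes, q$chrom[k], q$pos[k]), integer(1))
    gmat <- sapply(seq_len(nrow(q)), function(k)
      .favorable_dosage(d[midx[k], ], q$favorable_allele[k]))
    gmat <- matrix(gmat, nrow = length(lines))
    # interaction terms act on the alternate-allele dosage scale
    amat <- sapply(midx, function(i) .favorable_dosage(d[i, ], "alt"))
    amat <- matrix(amat, nrow = length(lines))
    vg <- apply(gmat, 2L, stats::var)
    mono <- vg <= 0
    if (any(mono)) {
      warning(sprintf("trait '%s': dropping %d monomorphic QTL(s)", tr,
                      sum(mono)))
      dropped[[tr]] <- q[mono, , drop = FALSE]
      q <- q[!mono, , drop = FALSE]
      gmat <- gmat[, !mono, drop = FALSE]
      amat <- amat[, !mono, drop = FALSE]
      vg <- vg[!mono]
    }
    # realized dosage variance (2pq(1+F) in an inbred panel), so the
    # planted PVE is recoverable by regression regardless of inbreeding
    a <- sqrt(q$target_pve / vg)
    G <- if (ncol(gmat)) drop(gmat %*% a) else numeric(length(lines))
    used_pve <- sum(q$target_pve)
    ia <- spec@interactions[spec@interactions$trait == tr, , drop = FALSE]
    for (r in seq_len(nrow(ia))) {
      if (ia$qtl_i[r] > ncol(amat) || ia$qtl_j[r] > ncol(amat)) next
      term <- (amat[, ia$qtl_i[r]] / 2) * (amat[, ia$qtl_j[r]] / 2)
      vt <- stats::var(term)
      if (vt <= 0) { warning("degenerate interaction term skipped"); next }
      w <- sign(ia$interaction_pve[r]) * sqrt(abs(ia$interaction_pve[r]) / vt)
      G <- G + w * term
      used_pve <- used_pve + abs(ia$interaction_pve[r])
    }
    bg_var <- max(0, h2 - used_pve)
    G <- G + rnorm(length(lines), sd = sqrt(bg_var))
    genetic[[tr]] <- G
    env_sd <- sqrt(max(0, 1 - h2))
    for (rep_i in seq_len(n_replicates)) {
      out[[length(out) + 1L]] <- data.frame(
        line = lines, trait = tr, replicate = rep_i,
        value = G + rnorm(length(lines), sd = env_sd))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "genetic") <- as.data.frame(genetic, optional = TRUE,
                                        row.names = lines)
  attr(res, "dropped") <- dropped
  res
}

#' Per-line replicate means of a long phenotype table
#'
#' @param phenotypes long `data.frame` (`line`, `trait`, `replicate`,
#'   `value`) as produced by [simulatePhenotypes()] or [readPhenotypes()].
#' @param trait trait to extract (default: the single trait present).
#' @return named numeric vector of line means.
#' @export
phenotypeMeans <- function(phenotypes, trait = NULL) {
  if (is.null(trait)) {
    trait <- unique(phenotypes$trait)
    if (length(trait) != 1L)
      stop("several traits present; choose one")
  }
  ph <- phenotypes[phenotypes$trait == trait, , drop = FALSE]
  tapply(ph$value, ph$line, mean, na.rm = TRUE)
}

#' QTL-architecture archetypes of the four trait groups
#'
#' Builds a [QTLSpec-class] representing one of the four empirical
#' trait-architecture groups on a given genotype panel, choosing
#' suitable markers from the panel itself:
#' * `MAJOR` - one large-effect QTL (PVE 0.55);
#' * `MAJOR_PLUS_MINOR` - a major QTL (0.40) plus two minor QTLs (0.14)
#'   in low mutual LD;
#' * `COMPLEX_INTERACTION` - a major QTL (0.50) plus a small QTL (0.08) in strong
#'   positive LD with it whose favorable allele points the other way,
#'   tied by a negative epistatic term: in a joint model the second
#'   QTL's coefficient opposes its marginal covariance with the trait,
#'   the suppression signature that drives corrected PVE negative;
#' * `LOW_PVE` - three small QTLs (0.10, 0.08, 0.08), no major effect.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param group one of the four group labels.
#' @param trait trait name (default the group label).
#' @param min_maf marker eligibility MAF (default 0.25).
#' @param seed integer seed for marker choice.
#' @return a [QTLSpec-class] with `h2 = 1`.
#' @export
archetypeQTLSpec <- function(genotypes,
                             group = c("MAJOR", "MAJOR_PLUS_MINOR",
                                       "COMPLEX_INTERACTION", "LOW_PVE"),
                             trait = NULL, min_maf = 0.25, seed = 1L) {
  group <- match.arg(group)
  trait <- trait %||% group
  set.seed(seed)
  d <- dosage(genotypes)
  mi <- markerInfo(genotypes)
  maf <- markerMAF(genotypes)
  cand <- which(!is.na(maf) & maf > min_maf & rowMeans(is.na(d)) < 0.1)
  if (length(cand) < 6) stop("too few informative markers")

  # pedigree panels carry long-range kinship correlations, so near-zero
  # dosage correlation (not just haplotype r^2) is required between the
  # chosen QTLs; the bound relaxes if the panel cannot satisfy it
  pick_low_ld <- function(n, thr = 0.10) {
    chosen <- sample(cand, 1L)
    tries <- 0L
    while (length(chosen) < n) {
      trial <- sample(cand, 1L)
      cc <- vapply(chosen, function(m)
        abs(stats::cor(as.numeric(d[m, ]), as.numeric(d[trial, ]),
                       use = "pairwise.complete.obs")), numeric(1))
      if (all(!is.na(cc) & cc < thr)) chosen <- c(chosen, trial)
      tries <- tries + 1L
      if (tries > 2000L) { thr <- thr + 0.05; tries <- 0L }
    }
    chosen
  }
  qrow <- function(i, pve, fav)
    data.frame(trait = trait, chrom = mi$chrom[i], pos = mi$pos[i],
               target_pve = pve, favorable_allele = fav)

  if (group == "MAJOR") {
    i <- sample(cand, 1L)
    return(qtlSpec(qrow(i, 0.55, "alt")))
  }
  if (group == "MAJOR_PLUS_MINOR") {
    ix <- pick_low_ld(3L)
    return(qtlSpec(rbind(qrow(ix[1], 0.40, "alt"),
                         qrow(ix[2], 0.14, "alt"),
                         qrow(ix[3], 0.14, "alt"))))
  }
  if (group == "LOW_PVE") {
    ix <- pick_low_ld(3L)
    return(qtlSpec(rbind(qrow(ix[1], 0.10, "alt"),
                         qrow(ix[2], 0.08, "alt"),
                         qrow(ix[3], 0.08, "alt"))))
  }
  # COMPLEX_INTERACTION: a correlated pair with antagonistic directions
  for (i in sample(cand)) {
    near <- cand[cand != i & mi$chrom[cand] == mi$chrom[i] &
                   abs(mi$pos[cand] - mi$pos[i]) < 1e6]
    if (!length(near)) next
    r2s <- vapply(near, function(j) .r2_cols(d[i, ], d[j, ]), numeric(1))
    ok <- which(!is.na(r2s) & r2s >= 0.55 & r2s <= 0.95)
    if (!length(ok)) next
    j <- near[ok[which.max(r2s[ok])]]
    r2 <- r2s[ok[which.max(r2s[ok])]]
    cc <- stats::cor(as.numeric(d[i, ]), as.numeric(d[j, ]),
                     use = "complete.obs")
    fav1 <- if (cc >= 0) "alt" else "ref"  # major favorable dosage must
    # correlate positively with the suppressed QTL's alternate dosage
    return(qtlSpec(rbind(qrow(i, 0.50, fav1), qrow(j, 0.08, "ref")),
                   interactions = data.frame(trait = trait, qtl_i = 1L,
                                             qtl_j = 2L,
                                             interaction_pve = -0.02)))
  }
  stop("no suitably correlated marker pair found for COMPLEX_INTERACTION")
}
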