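#' Filter markers on missingness and minor allele frequency
#'
#' Retains markers with a missing fraction strictly below `max_missing`
#' and a minor allele frequency strictly above `min_maf` (frequencies on
#' non-missing dosages), the standard chip-data quality filter.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param max_missing maximum missing fraction (default 0.80).
#' @param min_maf minimum MAF, exclusive (default 0.05).
#' @return the filtered [GenotypeMatrix-class].
#' @export
markerFilter <- function(genotypes, max_missing = 0.80, min_maf = 0.05) {
  d <- dosage(genotypes)
  miss <- rowMeans(is.na(d))
  maf <- markerMAF(genotypes)
  keep <- miss < max_missing & !is.na(maf) & maf > min_maf
  if (!any(keep))
    stop("no markers pass the filters; review max_missing/min_maf")
  genotypes[keep, ]
}

# line-mean phenotype aligned to genotype columns
.aligned_means <- function(genotypes, phenotype, trait = NULL) {
  y <- if (is.data.frame(phenotype)) phenotypeMeans(phenotype, trait)
       else phenotype
  lines <- colnames(dosage(genotypes))
  if (is.null(names(y))) {
    stopifnot(length(y) == length(lines))
    names(y) <- lines
  }
  y[lines]
}

# mean-imputed dosage matrix (lines x markers)
.imputed_t <- function(d) {
  x <- t(d)
  mu <- colMeans(x, na.rm = TRUE)
  idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(idx)) x[idx] <- mu[idx[, 2L]]
  x
}

#' Simplified association scan: OLS with genotype-PC covariates
#'
#' Per marker, fits `trait ~ dosage + PC1..PCk` on line-mean phenotypes
#' (dosages mean-imputed) and keeps markers with `p <= p_threshold`.
#' This is a deliberately simple stand-in for a mixed-model GWAS: the
#' principal components absorb population structure, kinship is not
#' modeled. An adaptive permutation test (phenotype shuffling against the
#' fixed covariates, stopping early once the observed best p can no
#' longer be genome-wide significant) supplies an empirical threshold
#' reported alongside. Significant markers within `clump_bp` of each
#' other are clumped into one QTL peak (best p), one peak per LD
#' neighborhood.
#'
#' @param genotypes a [GenotypeMatrix-class] (>= 20 lines).
#' @param phenotype long phenotype `data.frame` or a named vector of line
#'   means.
#' @param trait trait name (for long tables with several traits).
#' @param n_pcs number of genotype principal components (default 3).
#' @param p_threshold nominal per-test threshold (default 1e-4).
#' @param n_permutations permutations for the empirical threshold
#'   (default 1000; 0 disables).
#' @param clump_bp significant markers closer than this are one peak
#'   (default 250000).
#' @param seed integer seed for the permutations.
#' @return `data.frame` of QTL records: `trait`, `marker`, `chrom`,
#'   `pos`, `p_value`, `beta`, `favorable_allele` (`"alt"` when the
#'   alternate-allele dosage increases the trait), `original_pve`,
#'   `corrected_pve`. Attributes: `perm_threshold` (empirical 5% quantile
#'   of the permutation minimum p), `perm_p` (permutation p of the best
#'   observed marker), `n_perm_used`, `p_values` (full scan).
#' @export
associateQTL <- function(genotypes, phenotype, trait = NULL, n_pcs = 3L,
                         p_threshold = 1e-4, n_permutations = 1000L,
                         clump_bp = 250000L, seed = 1L) {
  d <- dosage(genotypes)
  if (ncol(d) < 20L) stop("need at least 20 lines")
  y <- .aligned_means(genotypes, phenotype, trait)
  keep <- !is.na(y)
  y <- y[keep]
  X <- .imputed_t(d[, keep, drop = FALSE])
  n <- length(y)
  if (stats::sd(y) == 0) {
    warning("constant phenotype; no QTLs")
    return(.empty_qtl_frame())
  }
  n_pcs <- min(n_pcs, n - 3L)
  covars <- if (n_pcs > 0) {
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    pc$x[, seq_len(n_pcs), drop = FALSE]
  } else NULL

  # residualize on [1, covars]; per-marker p from the partial correlation
  Q <- qr(cbind(1, covars))
  ry <- qr.resid(Q, y)
  RX <- qr.resid(Q, X)
  df <- n - 2L - n_pcs
  pfun <- function(yy) {
    num <- crossprod(RX, yy)
    den <- sqrt(colSums(RX^2) * sum(yy^2))
    r <- ifelse(den > 0, num / den, 0)
    tt <- r * sqrt(df / pmax(1 - r^2, 1e-12))
    2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  }
  p <- as.numeric(pfun(ry))
  beta <- as.numeric(crossprod(RX, ry) / pmax(colSums(RX^2), 1e-12))

  # adaptive permutation: empirical genome-wide null of min p
  perm_thr <- NA_real_
  perm_p <- NA_real_
  used <- 0L
  if (n_permutations > 0) {
    set.seed(seed)
    obs_min <- min(p, na.rm = TRUE)
    alpha_n <- ceiling(0.05 * n_permutations)
    minp <- numeric(0)
    exceed <- 0L
    for (b in seq_len(n_permutations)) {
      mp <- min(pfun(sample(ry)), na.rm = TRUE)
      minp <- c(minp, mp)
      exceed <- exceed + (mp <= obs_min)
      used <- b
      # stop once the observed minimum can no longer reach 5% genome-wide
      # significance (or is guaranteed to): the decision is settled
      if (exceed > alpha_n || (b - exceed) > n_permutations - alpha_n)
        break
    }
    perm_thr <- unname(stats::quantile(minp, 0.05, type = 7))
    perm_p <- (exceed + 1) / (used + 1)
  }

  mi <- markerInfo(genotypes)
  sig <- which(p <= p_threshold)
  peaks <- integer(0)
  if (length(sig)) {
    o <- sig[order(mi$chrom[sig], mi$pos[sig])]
    grp <- cumsum(c(1L, as.integer(
      mi$chrom[o[-1]] != mi$chrom[o[-length(o)]] |
        mi$pos[o[-1]] - mi$pos[o[-length(o)]] > clump_bp)))
    peaks <- vapply(split(o, grp), function(ix) ix[which.min(p[ix])],
                    integer(1))
  }
  res <- if (length(peaks)) {
    data.frame(
      trait = trait %||% "trait",
      marker = rownames(mi)[peaks],
      chrom = mi$chrom[peaks], pos = mi$pos[peaks],
      p_value = p[peaks], beta = beta[peaks],
      favorable_allele = ifelse(beta[peaks] >= 0, "alt", "ref"),
      original_pve = vapply(peaks, function(i)
        originalPVE(genotypes, y, marker = i), numeric(1)))
  } else .empty_qtl_frame()
  if (nrow(res)) {
    res <- res[order(-res$original_pve, res$chrom, res$pos), ]
    rownames(res) <- NULL
    res$corrected_pve <- correctedPVE(genotypes, y, res)
  }
  attr(res, "perm_threshold") <- perm_thr
  attr(res, "perm_p") <- perm_p
  attr(res, "n_perm_used") <- used
  attr(res, "p_values") <- p
  res
}

.empty_qtl_frame <- function() {
  data.frame(trait = character(), marker = character(),
             chrom = character(), pos = integer(), p_value = numeric(),
             beta = numeric(), favorable_allele = character(),
             original_pve = numeric(), corrected_pve = numeric())
}

#' Original PVE: single-QTL coefficient of determination
#'
#' R-squared of the linear regression of the line-mean phenotype on the
#' QTL marker dosage, on lines with both values present.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param phenotype long table or named vector of line means.
#' @param marker marker row index or rowname.
#' @param trait trait name for long tables.
#' @return fraction in `[0, 1]`.
#' @export
originalPVE <- function(genotypes, phenotype, marker, trait = NULL) {
  y <- .aligned_means(genotypes, phenotype, trait)
  g <- dosage(genotypes)[marker, ]
  keep <- !is.na(y) & !is.na(g)
  g <- g[keep]; y <- y[keep]
  if (stats::var(g) == 0) stop("monomorphic marker: PVE undefined")
  summary(stats::lm(y ~ g))$r.squared
}

#' Corrected PVE: joint multi-locus variance decomposition
#'
#' Fits the multi-locus linear model containing all listed QTLs and
#' attributes to QTL *k* the share
#' \deqn{\hat\beta_k \, \widehat{cov}(g_k, y) / \widehat{var}(y),}
#' the classical decomposition whose terms sum exactly to the full-model
#' R-squared. Shares are negative when a QTL's joint-model coefficient
#' opposes its marginal covariance with the trait - the signature of
#' antagonistic interaction or collinearity among QTLs that motivates the
#' correction. For a single QTL, or mutually orthogonal QTLs, each share
#' equals the QTL's original PVE. Aliased (perfectly collinear) QTLs are
#' dropped to a share of 0 with a warning.
#'
#' Missing dosages are mean-imputed so that all QTLs are fitted on the
#' same lines.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param phenotype long table or named vector of line means.
#' @param qtls `data.frame` with a `marker` column (rownames of the
#'   genotype matrix) or `chrom`/`pos` columns.
#' @param trait trait name for long tables.
#' @return numeric vector of signed corrected PVEs, one per QTL row;
#'   attribute `full_r2` holds the full-model R-squared.
#' @export
correctedPVE <- function(genotypes, phenotype, qtls, trait = NULL) {
  y <- .aligned_means(genotypes, phenotype, trait)
  keep <- !is.na(y)
  y <- y[keep]
  idx <- .qtl_marker_index(genotypes, qtls)
  G <- .imputed_t(dosage(genotypes)[idx, keep, drop = FALSE])
  fit <- stats::lm(y ~ G)
  beta <- stats::coef(fit)[-1L]
  if (anyNA(beta)) {
    warning(sum(is.na(beta)), " aliased QTL(s) dropped (share 0)")
    beta[is.na(beta)] <- 0
  }
  yc <- y - mean(y)
  shares <- vapply(seq_along(idx), function(k) {
    gc <- G[, k] - mean(G[, k])
    unname(beta[k] * sum(gc * yc) / sum(yc^2))
  }, numeric(1))
  attr(shares, "full_r2") <- summary(fit)$r.squared
  shares
}

.qtl_marker_index <- function(genotypes, qtls) {
  if (!is.null(qtls$marker)) {
    idx <- match(qtls$marker, rownames(dosage(genotypes)))
    if (anyNA(idx)) stop("unknown marker name(s) in qtls")
    idx
  } else {
    vapply(seq_len(nrow(qtls)), function(k)
      .match_marker(genotypes, qtls$chrom[k], qtls$pos[k]), integer(1))
  }
}

#' Classify a trait's genetic architecture
#'
#' Operationalizes the four empirical architecture groups from the
#' distributions of original and corrected PVE of a trait's QTLs:
#' * `COMPLEX_INTERACTION` - any corrected PVE below `negative_max`
#'   (takes precedence);
#' * `MAJOR` - a QTL with original PVE at or above `major_min` and every
#'   other corrected PVE below `minor_min`;
#' * `MAJOR_PLUS_MINOR` - a major QTL plus at least one other corrected
#'   PVE in `[minor_min, major_min)`;
#' * `LOW_PVE` - otherwise (no major QTL).
#' The classification does not depend on the order of the QTL list.
#'
#' @param qtls `data.frame` with `original_pve` and `corrected_pve`
#'   columns (one trait).
#' @param major_min original-PVE threshold for a major QTL (default
#'   0.30).
#' @param minor_min corrected-PVE threshold for a minor QTL (default
#'   0.05).
#' @param negative_max corrected-PVE threshold for a negative
#'   interaction (default -0.01).
#' @return one of `"MAJOR"`, `"MAJOR_PLUS_MINOR"`,
#'   `"COMPLEX_INTERACTION"`, `"LOW_PVE"`.
#' @export
classifyTrait <- function(qtls, major_min = 0.30, minor_min = 0.05,
                          negative_max = -0.01) {
  if (!nrow(qtls)) {
    warning("no QTLs; trait classified LOW_PVE")
    return("LOW_PVE")
  }
  if (any(qtls$corrected_pve < negative_max))
    return("COMPLEX_INTERACTION")
  top <- which.max(qtls$original_pve)
  if (qtls$original_pve[top] >= major_min) {
    others <- qtls$corrected_pve[-top]
    if (!length(others) || all(others < minor_min)) return("MAJOR")
    if (any(others >= minor_min & others < major_min))
      return("MAJOR_PLUS_MINOR")
    return("MAJOR")
  }
  "LOW_PVE"
}

#' Accumulated PVE along the pedigree flow
#'
#' For each trunk receptor in year order, sums the positive corrected
#' PVEs of the QTLs whose favorable genotype the receptor carries (a line
#' carries the favorable genotype when it is homozygous for the favorable
#' allele; missing calls do not count). A signed version summing raw
#' corrected PVEs is reported alongside.
#'
#' @param qtls QTL `data.frame` with `marker` (or `chrom`/`pos`),
#'   `favorable_allele` and `corrected_pve`.
#' @param genotypes a [GenotypeMatrix-class].
#' @param pedigree a [PedigreeGraph-class].
#' @return `data.frame`: `line`, `year`, `accumulated_pve`,
#'   `accumulated_pve_signed`, `n_qtls_carried`.
#' @export
accumulatedPVETrajectory <- function(qtls, genotypes, pedigree) {
  d <- dosage(genotypes)
  fo <- intersect(flowOrder(pedigree), colnames(d))
  yr <- stats::setNames(pedigreeNodes(pedigree)$year,
                        pedigreeNodes(pedigree)$name)
  idx <- .qtl_marker_index(genotypes, qtls)
  fav2 <- ifelse(qtls$favorable_allele == "alt", 2L, 0L)
  out <- lapply(fo, function(ln) {
    g <- d[idx, ln]
    carries <- !is.na(g) & g == fav2
    data.frame(line = ln, year = unname(yr[ln]),
               accumulated_pve = sum(pmax(qtls$corrected_pve[carries], 0)),
               accumulated_pve_signed = sum(qtls$corrected_pve[carries]),
               n_qtls_carried = sum(carries))
  })
  res <- do.call(rbind, out)
  res[order(res$year), ]
}

#' Genotype consistency with the most recent ancestors
#'
#' For every cultivar with at least `n_ancestors` pedigree ancestors, the
#' `n_ancestors` most recent ones (by year) are compared at the trait's
#' QTL markers; an ancestor is *consistent* when it differs at no more
#' than `max_diff` QTL dosages. Reports the fraction of consistent
#' (cultivar, ancestor) pairs per trait and the per-cultivar series -
#' traits whose QTLs interact antagonistically show markedly lower
#' consistency than major-effect traits.
#'
#' @param qtls QTL `data.frame` (one trait) with `marker` or
#'   `chrom`/`pos`.
#' @param genotypes a [GenotypeMatrix-class].
#' @param pedigree a [PedigreeGraph-class].
#' @param n_ancestors ancestors compared per cultivar (default 10).
#' @param max_diff maximum differing QTLs for consistency (default 1).
#' @return list with `fraction` (overall consistent-pair fraction),
#'   `per_cultivar` (`data.frame`: line, year, n_consistent,
#'   n_ancestors). Empty result with a warning when no cultivar has
#'   enough ancestors.
#' @export
ancestralConsistency <- function(qtls, genotypes, pedigree,
                                 n_ancestors = 10L, max_diff = 1L) {
  d <- dosage(genotypes)
  idx <- .qtl_marker_index(genotypes, qtls)
  nd <- pedigreeNodes(pedigree)
  yr <- stats::setNames(nd$year, nd$name)
  rows <- list()
  for (ln in intersect(nd$name, colnames(d))) {
    anc <- intersect(ancestorsOf(pedigree, ln), colnames(d))
    if (length(anc) < n_ancestors) next
    anc <- anc[order(-yr[anc])][seq_len(n_ancestors)]
    g0 <- d[idx, ln]
    ndiff <- vapply(anc, function(a) {
      ga <- d[idx, a]
      sum(!is.na(g0) & !is.na(ga) & g0 != ga)
    }, integer(1))
    rows[[ln]] <- data.frame(line = ln, year = unname(yr[ln]),
                             n_consistent = sum(ndiff <= max_diff),
                             n_ancestors = length(anc))
  }
  if (!length(rows)) {
    warning("no cultivar has ", n_ancestors, " genotyped ancestors")
    return(list(fraction = NA_real_,
                per_cultivar = data.frame(line = character(),
                                          year = integer(),
                                          n_consistent = integer(),
                                          n_ancestors = integer())))
  }
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  list(fraction = sum(per$n_consistent) / sum(per$n_ancestors),
       per_cultivar = per[order(per$year), ])
}
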