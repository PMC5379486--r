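#' Tajima's D from S, pi and the haplotype sample size
#'
#' Standard normalization of the difference between the mean pairwise
#' diversity and Watterson's estimator, using the 1989 variance estimate.
#' Returns `NA` when `S == 0` or `n < 4`.
#'
#' @param S number of segregating sites.
#' @param pi sum of per-site mean pairwise differences.
#' @param n haplotype sample size.
#' @return numeric scalar (or vector, the arguments recycle).
#' @export
tajimaD <- function(S, pi, n) {
  out <- rep(NA_real_, max(length(S), length(pi), length(n)))
  S <- rep_len(S, length(out)); pi <- rep_len(pi, length(out))
  n <- rep_len(n, length(out))
  ok <- !is.na(S) & !is.na(n) & S > 0 & n >= 4
  if (!any(ok)) return(out)
  a1 <- vapply(n[ok], function(m) sum(1 / seq_len(m - 1)), numeric(1))
  a2 <- vapply(n[ok], function(m) sum(1 / seq_len(m - 1)^2), numeric(1))
  nn <- n[ok]
  b1 <- (nn + 1) / (3 * (nn - 1))
  b2 <- 2 * (nn^2 + nn + 3) / (9 * nn * (nn - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (nn + 2) / (a1 * nn) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  vd <- e1 * S[ok] + e2 * S[ok] * (S[ok] - 1)
  out[ok] <- (pi[ok] - S[ok] / a1) / sqrt(vd)
  out
}

# per-site quantities shared by windowStats and its callers:
# haplotype sample size, derived count, pairwise diversity, theta weight
.site_stats <- function(d) {
  nn <- 2L * rowSums(!is.na(d))
  ds <- rowSums(d, na.rm = TRUE)
  seg <- nn >= 2L & ds > 0L & ds < nn
  pi_site <- ifelse(nn >= 2L, 2 * ds * (nn - ds) / (nn * (nn - 1)), 0)
  a1 <- rep(NA_real_, length(nn))
  u <- unique(nn[seg])
  for (m in u) a1[seg & nn == m] <- sum(1 / seq_len(m - 1))
  theta_site <- ifelse(seg, 1 / a1, 0)
  list(n = nn, seg = seg, pi = pi_site, theta = theta_site)
}

#' Windowed diversity statistics (pi, Watterson's theta, Tajima's D)
#'
#' Tiles each chromosome with windows of `window_bp` starting at position
#' 1 (`step_bp < window_bp` gives overlapping sliding windows) and
#' computes, per window: the number of segregating sites, the sum of
#' per-site mean pairwise differences (pi), Watterson's theta
#' (`sum over segregating sites of 1/a1(n)`, accommodating per-site
#' missingness), and Tajima's D. Heterozygous dosage 1 contributes one
#' haplotype of each allele; missing calls are excluded per site, so the
#' haplotype sample size `n` varies by site - D's variance term uses the
#' median per-site `n` over the window's segregating sites.
#'
#' @param genotypes a [GenotypeMatrix-class] (at least 4 lines for D to be
#'   defined).
#' @param window_bp window width in bp (default 10000).
#' @param step_bp distance between window starts (default = `window_bp`,
#'   i.e. non-overlapping tiles).
#' @return [GenomicRanges::GRanges] of windows with metadata columns
#'   `n_snps` (segregating sites), `n_sites` (markers in window), `pi`,
#'   `theta_w`, `tajima_d` (NA where undefined), `n_hap`.
#' @examples
#' ped <- generatePedigree(4, 0, 0, 1950, seed = 1)
#' gm <- simulateGenotypes(ped, 400, c(chr1 = 5e5), seed = 1)
#' ws <- windowStats(gm, window_bp = 10000)
#' head(as.data.frame(ws))
#' @export
windowStats <- function(genotypes, window_bp = 10000L,
                        step_bp = window_bp) {
  stopifnot(is(genotypes, "GenotypeMatrix"))
  if (window_bp <= 0 || step_bp <= 0)
    stop("window_bp and step_bp must be positive")
  d <- dosage(genotypes)
  mi <- markerInfo(genotypes)
  ss <- .site_stats(d)

  res <- list()
  for (chr in unique(mi$chrom)) {
    idx <- which(mi$chrom == chr)
    pos <- mi$pos[idx]
    starts <- seq.int(1L, max(pos), by = step_bp)
    ends <- starts + window_bp - 1L
    lo <- findInterval(starts - 1L, pos) + 1L   # first marker >= start
    hi <- findInterval(ends, pos)               # last marker <= end
    n_win <- length(starts)
    S <- pi <- th <- numeric(n_win)
    nh <- ns <- integer(n_win)
    for (w in seq_len(n_win)) {
      if (lo[w] > hi[w]) next
      j <- idx[lo[w]:hi[w]]
      ns[w] <- length(j)
      S[w] <- sum(ss$seg[j])
      pi[w] <- sum(ss$pi[j])
      th[w] <- sum(ss$theta[j])
      nh[w] <- if (S[w] > 0)
        as.integer(round(stats::median(ss$n[j][ss$seg[j]]))) else
        as.integer(round(stats::median(ss$n[j])))
    }
    res[[chr]] <- data.frame(chrom = chr, start = starts, end = ends,
                             n_snps = S, n_sites = ns, pi = pi,
                             theta_w = th,
                             tajima_d = tajimaD(S, pi, nh), n_hap = nh)
  }
  df <- do.call(rbind, res)
  GRanges(df$chrom, IRanges(df$start, df$end), n_snps = df$n_snps,
          n_sites = df$n_sites, pi = df$pi, theta_w = df$theta_w,
          tajima_d = df$tajima_d, n_hap = df$n_hap)
}

#' Call selective-sweep blocks from windowed Tajima's D
#'
#' Windows whose D lies at or below the genome-wide empirical `quantile`
#' of defined D values are kept, and kept windows separated by a gap of at
#' most `merge_gap_bp` are merged into sweep blocks.
#'
#' @param stats window [GenomicRanges::GRanges] from [windowStats()].
#' @param quantile empirical quantile cut-off in (0, 1) (default 0.05).
#' @param merge_gap_bp maximum gap merged (default 5000); the gap between
#'   windows `[.., e]` and `[s, ..]` is `s - e - 1`.
#' @return [GenomicRanges::GRanges] of sweep blocks with metadata columns
#'   `block_id`, `n_windows`, `min_tajima_d`; the D threshold is stored in
#'   `metadata(result)$threshold`.
#' @export
callSweeps <- function(stats, quantile = 0.05, merge_gap_bp = 5000L) {
  stopifnot(length(stats) > 0)
  if (quantile <= 0 || quantile >= 1) stop("quantile must be in (0, 1)")
  D <- stats$tajima_d
  if (all(is.na(D))) {
    warning("all Tajima's D values undefined; no sweeps called")
    out <- GRanges()
    metadata(out)$threshold <- NA_real_
    return(out)
  }
  thr <- unname(stats::quantile(D, quantile, na.rm = TRUE))
  keep <- stats[!is.na(D) & D <= thr]
  blocks <- reduce(granges(keep), min.gapwidth = merge_gap_bp + 1L)
  ov <- findOverlaps(blocks, keep)
  blocks$block_id <- sprintf("SSW%04d", seq_along(blocks))
  blocks$n_windows <- as.integer(table(factor(S4Vectors::queryHits(ov),
                                              seq_along(blocks))))
  mins <- tapply(keep$tajima_d[S4Vectors::subjectHits(ov)],
                 factor(S4Vectors::queryHits(ov), seq_along(blocks)), min)
  blocks$min_tajima_d <- as.numeric(mins)
  metadata(blocks)$threshold <- thr
  blocks
}

#' Block-by-line conservation matrix relative to the focal cultivar
#'
#' For every block and line, the fraction of the block's markers at which
#' the line's dosage equals the focal cultivar's (both non-missing) is
#' compared to `identity_min`: 1 if at or above, 0 below, `NA` when no
#' marker is jointly called.
#'
#' @param blocks [GenomicRanges::GRanges] of block intervals.
#' @param genotypes a [GenotypeMatrix-class].
#' @param focal focal cultivar name.
#' @param identity_min identity threshold (default 0.85).
#' @return integer matrix, blocks x lines.
#' @export
conservationMatrix <- function(blocks, genotypes, focal,
                               identity_min = 0.85) {
  d <- dosage(genotypes)
  if (!(focal %in% colnames(d))) stop("focal line absent from genotypes")
  ov <- findOverlaps(rowRanges(genotypes), blocks)
  M <- matrix(NA_integer_, length(blocks), ncol(d),
              dimnames = list(NULL, colnames(d)))
  f <- d[, focal]
  for (b in seq_along(blocks)) {
    i <- S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == b]
    if (!length(i)) next
    sub <- d[i, , drop = FALSE]
    joint <- (!is.na(sub)) & !is.na(f[i])
    match_n <- colSums(sub == f[i] & joint, na.rm = TRUE)
    joint_n <- colSums(joint)
    id <- ifelse(joint_n > 0, match_n / joint_n, NA_real_)
    M[b, ] <- ifelse(is.na(id), NA_integer_,
                     as.integer(id >= identity_min))
  }
  M
}

#' Cluster temporal conservation patterns of sweep blocks
#'
#' Builds the block-by-line conservation matrix (columns ordered by
#' approval year), clusters block rows by average-linkage hierarchical
#' clustering on Hamming distance, cuts at `k` clusters, and for each
#' cluster finds the change-point year that minimizes the within-segment
#' variance of the cluster's mean conservation profile.
#'
#' @param blocks sweep blocks ([GenomicRanges::GRanges]).
#' @param genotypes a [GenotypeMatrix-class] with line years in its
#'   `colData` (or supply `years`).
#' @param focal focal cultivar name.
#' @param k number of clusters (default 4; must not exceed the number of
#'   blocks).
#' @param years optional named integer vector of per-line years.
#' @param identity_min identity threshold for "conserved" (default 0.85).
#' @return list with `labels` (cluster per block), `changepoint_year`
#'   (named by cluster), `profiles` (cluster x line mean-conservation
#'   matrix), `line_order`, and the conservation `matrix` itself.
#' @export
clusterTemporalPatterns <- function(blocks, genotypes, focal, k = 4L,
                                    years = NULL, identity_min = 0.85) {
  if (k < 2) stop("k must be >= 2")
  if (k > length(blocks)) stop("k exceeds the number of blocks")
  li <- lineInfo(genotypes)
  if (is.null(years)) years <- stats::setNames(li$year, li$name)
  if (anyNA(years)) stop("every line needs a year")
  ord <- names(sort(years))
  M <- conservationMatrix(blocks, genotypes, focal, identity_min)[, ord,
                                                                  drop = FALSE]
  A <- !is.na(M) & M == 1L
  B <- !is.na(M) & M == 0L
  mism <- A %*% t(B) + B %*% t(A)
  valid <- (A + B) %*% t(A + B)
  Dm <- ifelse(valid > 0, mism / valid, 0)
  if (max(Dm) == 0)
    warning("all blocks have identical conservation profiles")
  hc <- stats::hclust(stats::as.dist(Dm), method = "average")
  labels <- stats::cutree(hc, k = k)

  cp <- stats::setNames(rep(NA_integer_, k), paste0("cluster", seq_len(k)))
  profiles <- matrix(NA_real_, k, ncol(M),
                     dimnames = list(names(cp), ord))
  for (cl in seq_len(k)) {
    prof <- colMeans(M[labels == cl, , drop = FALSE], na.rm = TRUE)
    profiles[cl, ] <- prof
    keep <- which(is.finite(prof))    # lines with no block data drop out
    pk <- prof[keep]
    m <- length(pk)
    if (m < 2L) next
    sse <- vapply(seq_len(m - 1L), function(j) {
      l <- pk[1:j]; r <- pk[(j + 1L):m]
      sum((l - mean(l))^2) + sum((r - mean(r))^2)
    }, numeric(1))
    j <- which.min(sse)
    cp[cl] <- unname(years[ord[keep[j + 1L]]])  # first year, new regime
  }
  list(labels = labels, changepoint_year = cp, profiles = profiles,
       line_order = ord, matrix = M)
}

#' Attach overlapping genes to blocks
#'
#' Any-overlap intersection of block intervals with gene annotation
#' (1-based inclusive coordinates on both sides, so a gene starting at the
#' block's end position is included).
#'
#' @param blocks [GenomicRanges::GRanges].
#' @param gff a GFF3 file path or a [GenomicRanges::GRanges] of features;
#'   features with `type == "gene"` are used when a `type` column exists.
#' @return list with `genes` (per-block character vector of gene
#'   identifiers), `n_genes` (per-block counts) and `total_genes` (unique
#'   genes hit).
#' @export
annotateBlocks <- function(blocks, gff) {
  g <- if (is.character(gff)) readGFF(gff) else gff
  if ("type" %in% colnames(S4Vectors::mcols(g)) &&
      any(g$type == "gene"))
    g <- g[g$type == "gene"]
  ids <- NULL
  for (col in c("ID", "Name", "gene_id", "locus_tag"))
    if (col %in% colnames(S4Vectors::mcols(g))) {
      ids <- as.character(S4Vectors::mcols(g)[[col]]); break
    }
  if (is.null(ids)) ids <- paste0("gene", seq_along(g))
  ov <- findOverlaps(blocks, g)
  genes <- split(ids[S4Vectors::subjectHits(ov)],
                 factor(S4Vectors::queryHits(ov), seq_along(blocks)))
  genes <- lapply(genes, unique)
  list(genes = genes, n_genes = lengths(genes),
       total_genes = length(unique(unlist(genes))))
}
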