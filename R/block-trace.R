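#' Pairwise linkage disequilibrium r-squared between two markers
#'
#' Inbred lines are treated as known-phase haplotypes: heterozygous or
#' missing calls at either marker are excluded pairwise, the remaining
#' homozygous dosages define one haplotype per line, and
#' \deqn{r^2 = (p_{AB} - p_A p_B)^2 / (p_A p_a p_B p_b).}
#' Markers monomorphic in the complete-pair subset give `NA` (undefined),
#' not 0.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param marker_a,marker_b marker row indices (or rownames).
#' @return r-squared in `[0, 1]`, or `NA` when undefined.
#' @export
pairwiseR2 <- function(genotypes, marker_a, marker_b) {
  d <- dosage(genotypes)
  .r2_cols(d[marker_a, ], d[marker_b, ])
}

# r^2 between two dosage vectors (internal, vectors of equal length)
.r2_cols <- function(a, b) {
  keep <- !is.na(a) & !is.na(b) & a != 1L & b != 1L
  if (sum(keep) < 2L) return(NA_real_)
  x <- a[keep] / 2   # allele of the single haplotype per inbred line
  y <- b[keep] / 2
  pA <- mean(x); pB <- mean(y)
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) return(NA_real_)
  pAB <- mean(x * y)
  (pAB - pA * pB)^2 / (pA * (1 - pA) * pB * (1 - pB))
}

#' Detect haplotype blocks by greedy r-squared extension
#'
#' Markers are scanned in map order within each chromosome. A block starts
#' at the first unassigned marker and is extended while the candidate
#' marker's *median* r-squared against the markers already in the block is
#' at least `r2_min` (undefined pairs are excluded from the median; a
#' candidate with no defined pair stops the block). Single-marker blocks
#' are discarded. The partition is deterministic and blocks never overlap.
#'
#' This greedy contiguous rule is a deterministic stand-in for
#' confidence-interval-based block definitions; the cut-off is the
#' conventional r-squared 0.4.
#'
#' @param genotypes a [GenotypeMatrix-class] with markers sorted by
#'   position.
#' @param r2_min r-squared threshold (default 0.4).
#' @param max_span_markers optional cap on the number of block markers a
#'   candidate is compared against (most recent first; default all).
#' @return [GenomicRanges::GRanges] of blocks with metadata columns
#'   `block_id`, `first_marker`, `last_marker` (global row indices),
#'   `n_snps`.
#' @examples
#' ped <- generatePedigree(4, 0, 0, 1950, seed = 1)
#' gm <- simulateGenotypes(ped, 300, c(chr1 = 2e6), seed = 2)
#' findHaplotypeBlocks(gm)
#' @export
findHaplotypeBlocks <- function(genotypes, r2_min = 0.4,
                                max_span_markers = Inf) {
  stopifnot(is(genotypes, "GenotypeMatrix"))
  d <- dosage(genotypes)
  mi <- markerInfo(genotypes)
  blocks <- list()
  for (chr in unique(mi$chrom)) {
    idx <- which(mi$chrom == chr)
    b_start <- 1L
    i <- 2L
    flush <- function(from, to) {
      if (to > from) {
        gi <- idx[from:to]
        blocks[[length(blocks) + 1L]] <<- data.frame(
          chrom = chr, start = mi$pos[gi[1L]],
          end = mi$pos[gi[length(gi)]],
          first_marker = gi[1L], last_marker = gi[length(gi)],
          n_snps = length(gi))
      }
    }
    while (i <= length(idx)) {
      members <- idx[b_start:(i - 1L)]
      if (length(members) > max_span_markers)
        members <- members[(length(members) - max_span_markers + 1L):
                             length(members)]
      r2 <- vapply(members, function(m) .r2_cols(d[m, ], d[idx[i], ]),
                   numeric(1))
      r2 <- r2[!is.na(r2)]
      if (length(r2) && stats::median(r2) >= r2_min) {
        i <- i + 1L
      } else {
        flush(b_start, i - 1L)
        b_start <- i
        i <- i + 1L
      }
    }
    flush(b_start, length(idx))
  }
  if (!length(blocks)) {
    out <- GRanges()
    out$block_id <- character()
    return(out)
  }
  df <- do.call(rbind, blocks)
  GRanges(df$chrom, IRanges(df$start, df$end),
          block_id = sprintf("HB%04d", seq_len(nrow(df))),
          first_marker = df$first_marker, last_marker = df$last_marker,
          n_snps = df$n_snps)
}

#' Genotype identity of a block between two lines
#'
#' Fraction of the block's markers at which both lines are non-missing
#' and their dosages are equal (heterozygote vs homozygote counts as a
#' mismatch), over the jointly called markers. `NA` when no marker is
#' jointly called.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param block one element of the [findHaplotypeBlocks()] result (or any
#'   GRanges interval).
#' @param line_a,line_b line names.
#' @return fraction in `[0, 1]`, or `NA`.
#' @export
blockIdentity <- function(genotypes, block, line_a, line_b) {
  d <- dosage(genotypes)
  stopifnot(line_a %in% colnames(d), line_b %in% colnames(d))
  i <- S4Vectors::queryHits(findOverlaps(rowRanges(genotypes), block))
  .identity_cols(d[i, line_a], d[i, line_b])
}

.identity_cols <- function(a, b) {
  joint <- !is.na(a) & !is.na(b)
  if (!any(joint)) return(NA_real_)
  mean(a[joint] == b[joint])
}

# block x line identity fractions vs the focal line, one matrix pass
.block_identity_matrix <- function(genotypes, blocks, focal) {
  d <- dosage(genotypes)
  ov <- findOverlaps(rowRanges(genotypes), blocks)
  f <- d[, focal]
  out <- matrix(NA_real_, length(blocks), ncol(d),
                dimnames = list(blocks$block_id, colnames(d)))
  for (b in seq_along(blocks)) {
    i <- S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == b]
    if (!length(i)) next
    sub <- d[i, , drop = FALSE]
    joint <- (!is.na(sub)) & !is.na(f[i])
    eq <- sub == f[i] & joint
    jn <- colSums(joint)
    out[b, ] <- ifelse(jn > 0, colSums(eq, na.rm = TRUE) / jn, NA_real_)
  }
  out
}

#' Trace haplotype-block origins through the pedigree flow
#'
#' Walks the trunk receptors backward from the focal cultivar. A block
#' remains traceable while the receptor's block identity with the focal
#' cultivar stays at or above `threshold` at *every consecutive* receptor
#' (one sub-threshold receptor terminates the chain even if an earlier
#' cultivar matches - the sequential-inheritance adjustment against
#' false positives). The origin is the earliest cultivar of the unbroken
#' chain; if the donor parent of the earliest matching receptor also
#' matches while the preceding receptor does not, the donor is reported
#' as the origin (the block entered through that cross). Donors do not
#' add to the generation count.
#'
#' @param blocks [GenomicRanges::GRanges] from [findHaplotypeBlocks()].
#' @param genotypes a [GenotypeMatrix-class].
#' @param pedigree a [PedigreeGraph-class].
#' @param focal focal cultivar (default [focalLine()] of the pedigree).
#' @param threshold identity threshold (default 0.85; the comparison is
#'   `>=`).
#' @return `data.frame` with one row per block: `block_id`, `traceable`,
#'   `origin_cultivar`, `origin_year`, `conserved_generation_count`
#'   (receptor generations, the focal line not counted), `is_chtb`
#'   (initialized `FALSE`; see [callCHTB()]).
#' @export
traceOrigin <- function(blocks, genotypes, pedigree,
                        focal = focalLine(pedigree), threshold = 0.85) {
  stopifnot(is(pedigree, "PedigreeGraph"))
  if (!(focal %in% pedigreeNodes(pedigree)$name))
    stop("focal cultivar not in the pedigree")
  fo <- flowOrder(pedigree)
  upstream <- rev(setdiff(fo, focal))       # nearest receptor first
  donors <- vapply(c(fo), function(r) {
    p <- parentsOf(pedigree, r)["donor"]
    if (is.na(p)) NA_character_ else p
  }, character(1))
  names(donors) <- fo
  idm <- .block_identity_matrix(
    genotypes, blocks,
    focal = focal)
  yr <- stats::setNames(pedigreeNodes(pedigree)$year,
                        pedigreeNodes(pedigree)$name)

  res <- data.frame(block_id = blocks$block_id,
                    traceable = FALSE,
                    origin_cultivar = NA_character_,
                    origin_year = NA_integer_,
                    conserved_generation_count = 0L,
                    is_chtb = FALSE)
  for (b in seq_along(blocks)) {
    chain <- character()
    for (r in upstream) {
      id <- if (r %in% colnames(idm)) idm[b, r] else NA_real_
      if (!is.na(id) && id >= threshold) chain <- c(chain, r) else break
    }
    if (!length(chain)) next
    earliest <- chain[length(chain)]
    # receptor just before the earliest matching one broke the chain (or
    # the chain reached the trunk end); check the donor of the cross that
    # produced the earliest matching receptor
    origin <- earliest
    dn <- donors[earliest]
    if (!is.na(dn) && dn %in% colnames(idm) &&
        !is.na(idm[b, dn]) && idm[b, dn] >= threshold)
      origin <- unname(dn)
    res$traceable[b] <- TRUE
    res$origin_cultivar[b] <- origin
    res$origin_year[b] <- unname(yr[origin])
    res$conserved_generation_count[b] <- length(chain)
  }
  res
}

#' Call conserved traceable blocks (cHTBs)
#'
#' A traceable block conserved across at least `min_generations`
#' sequential receptor generations is a conserved traceable block. The
#' default 4 reads "more than three breeding generations" strictly.
#'
#' @param records `data.frame` from [traceOrigin()].
#' @param min_generations minimum chain length (default 4).
#' @return the records with `is_chtb` filled in.
#' @export
callCHTB <- function(records, min_generations = 4L) {
  records$is_chtb <- records$traceable &
    records$conserved_generation_count >= min_generations
  records
}

#' Conservation of cHTBs in derivative cultivars
#'
#' For each derivative group, a conserved block is `consistent` when every
#' group member's block identity with the focal cultivar is at or above
#' `threshold` (identity below threshold in any member makes the block
#' `varied` for that group; lines with undefined identity are treated as
#' varied). With two groups the blocks are cross-classified as consistent
#' in both, varied in one group only, or varied in both.
#'
#' @param chtbs blocks ([GenomicRanges::GRanges]) of the cHTB records to
#'   classify.
#' @param genotypes a [GenotypeMatrix-class].
#' @param derivative_groups named list of line-name vectors (default: the
#'   pedigree's groups).
#' @param focal focal cultivar name.
#' @param threshold identity threshold (default 0.85).
#' @return list with `classification` (`data.frame`: block_id, one
#'   logical `consistent_<group>` column per group, and `class` for the
#'   two-group cross-classification), `proportions` (named fractions per
#'   class) and `overlap_fraction` (consistent-in-both as a fraction of
#'   each group's consistent blocks).
#' @export
derivativeConservation <- function(chtbs, genotypes, derivative_groups,
                                   focal, threshold = 0.85) {
  if (!length(derivative_groups)) stop("derivative_groups is empty")
  d <- dosage(genotypes)
  groups <- lapply(derivative_groups, function(g) {
    miss <- setdiff(g, colnames(d))
    if (length(miss)) {
      warning("derivative line(s) not genotyped, skipped: ",
              paste(miss, collapse = ", "))
    }
    intersect(g, colnames(d))
  })
  idm <- .block_identity_matrix(genotypes, chtbs, focal)
  cls <- data.frame(block_id = chtbs$block_id)
  for (gn in names(groups)) {
    sub <- idm[, groups[[gn]], drop = FALSE]
    ok <- apply(sub, 1L, function(x) all(!is.na(x) & x >= threshold))
    cls[[paste0("consistent_", gn)]] <- as.logical(ok)
  }
  if (length(groups) == 2L) {
    g1 <- names(groups)[1L]; g2 <- names(groups)[2L]
    a <- cls[[paste0("consistent_", g1)]]
    b <- cls[[paste0("consistent_", g2)]]
    cls$class <- ifelse(a & b, "consistent_in_both",
                 ifelse(!a & b, paste0("varied_in_", g1, "_only"),
                 ifelse(a & !b, paste0("varied_in_", g2, "_only"),
                        "varied_in_both")))
    props <- table(factor(cls$class,
      c("consistent_in_both", paste0("varied_in_", g1, "_only"),
        paste0("varied_in_", g2, "_only"), "varied_in_both")))
    props <- as.numeric(props) / max(1L, nrow(cls))
    names(props) <- c("consistent_in_both",
                      paste0("varied_in_", g1, "_only"),
                      paste0("varied_in_", g2, "_only"), "varied_in_both")
    overlap <- vapply(c(g1, g2), function(gn) {
      cons <- cls[[paste0("consistent_", gn)]]
      if (!any(cons)) return(NA_real_)
      sum(a & b) / sum(cons)
    }, numeric(1))
  } else {
    props <- overlap <- NULL
  }
  list(classification = cls, proportions = props,
       overlap_fraction = overlap)
}
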