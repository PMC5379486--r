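#' Construct a GenotypeMatrix
#'
#' @param dosage integer matrix, markers x lines, values 0/1/2 (alternate
#'   allele count) or NA; rownames optional, colnames are line names.
#' @param chrom,pos character / integer vectors of marker coordinates
#'   (1-based); must be sorted with strictly increasing positions within a
#'   chromosome.
#' @param ref,alt allele labels (defaults `"A"`/`"B"` chip-style).
#' @param lineData optional `data.frame` with columns `name`, `year`,
#'   `role`; matched to `colnames(dosage)` by `name`.
#' @return a [GenotypeMatrix-class].
#' @examples
#' gm <- genotypeMatrix(
#'   matrix(c(0L, 2L, 2L, 0L, 0L, 2L), nrow = 3,
#'          dimnames = list(NULL, c("lineA", "lineB"))),
#'   chrom = rep("chr1", 3), pos = c(100L, 200L, 300L))
#' dosage(gm)
#' @export
genotypeMatrix <- function(dosage, chrom, pos, ref = NULL, alt = NULL,
                           lineData = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  stopifnot(length(chrom) == nrow(dosage), length(pos) == nrow(dosage))
  if (is.null(ref)) ref <- rep("A", nrow(dosage))
  if (is.null(alt)) alt <- rep("B", nrow(dosage))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- paste0("line", seq_len(ncol(dosage)))
  rr <- GRanges(chrom, IRanges(as.integer(pos), width = 1L),
                ref = ref, alt = alt)
  rn <- rownames(dosage)
  if (is.null(rn) || anyDuplicated(rn) || any(!nzchar(rn)))
    rn <- make.unique(paste0(chrom, "_", as.integer(pos)))
  names(rr) <- rn
  rownames(dosage) <- rn
  if (is.null(lineData)) {
    cd <- DataFrame(name = colnames(dosage),
                    year = NA_integer_, role = NA_character_)
  } else {
    i <- match(colnames(dosage), lineData$name)
    if (anyNA(i)) stop("lineData is missing some lines: ",
                       paste(colnames(dosage)[is.na(i)], collapse = ", "))
    cd <- DataFrame(name = lineData$name[i],
                    year = as.integer(lineData$year[i]),
                    role = as.character(lineData$role[i]))
  }
  rownames(cd) <- colnames(dosage)
  new("GenotypeMatrix",
      SummarizedExperiment(assays = list(dosage = dosage),
                           rowRanges = rr, colData = cd))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname dosage
#' @export
setMethod("dosage", "GenotypeMatrix", function(x) assay(x, "dosage"))

#' @rdname markerInfo
#' @export
setMethod("markerInfo", "GenotypeMatrix", function(x) {
  rr <- rowRanges(x)
  data.frame(chrom = as.character(seqnames(rr)), pos = start(rr),
             ref = rr$ref, alt = rr$alt, row.names = names(rr))
})

#' @rdname lineInfo
#' @export
setMethod("lineInfo", "GenotypeMatrix", function(x)
  as.data.frame(colData(x)))

setMethod("show", "GenotypeMatrix", function(object) {
  d <- dosage(object)
  het <- mean(d == 1L, na.rm = TRUE)
  mis <- mean(is.na(d))
  cat(sprintf(
    "GenotypeMatrix: %d markers x %d lines (%d chromosome%s)\n",
    nrow(object), ncol(object),
    length(unique(as.character(seqnames(rowRanges(object))))),
    if (length(unique(as.character(seqnames(rowRanges(object))))) == 1L) ""
    else "s"))
  cat(sprintf("  heterozygote fraction %.3f, missing fraction %.3f\n",
              het, mis))
})

#' Fraction of heterozygous calls per line
#'
#' @param x a [GenotypeMatrix-class].
#' @return named numeric vector over lines.
#' @export
hetFraction <- function(x) {
  d <- dosage(x)
  colMeans(d == 1L, na.rm = TRUE)
}

#' Minor allele frequency per marker
#'
#' Computed on non-missing dosages, heterozygotes contributing one copy of
#' each allele.
#'
#' @param x a [GenotypeMatrix-class].
#' @return numeric vector over markers (NA where no calls).
#' @export
markerMAF <- function(x) {
  d <- dosage(x)
  n <- 2L * rowSums(!is.na(d))
  p <- rowSums(d, na.rm = TRUE) / n
  pmin(p, 1 - p)
}
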