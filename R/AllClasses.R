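#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#'   reduce granges
#' @importFrom IRanges IRanges subsetByOverlaps
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges
#'   colData assayNames
NULL

#' GenotypeMatrix: marker-by-line dosage calls for an inbred panel
#'
#' A thin extension of [SummarizedExperiment::RangedSummarizedExperiment]
#' holding a single `"dosage"` assay (markers in rows, lines in columns,
#' values 0/1/2 counting the alternate allele, `NA` for missing), marker
#' coordinates as the `rowRanges` (1-based positions, `ref`/`alt` allele
#' labels in the metadata columns) and line metadata (`name`, `year`,
#' `role`) as the `colData`.
#'
#' Lines from elite inbred breeding programs are expected to be almost
#' completely homozygous; a small residual heterozygote fraction (dosage 1)
#' is tolerated and several statistics expand a heterozygote into one
#' haplotype of each allele.
#'
#' @slot ... inherited from `RangedSummarizedExperiment`.
#' @seealso [genotypeMatrix()] for the constructor, [dosage()],
#'   [markerInfo()], [lineInfo()].
#' @export
setClass("GenotypeMatrix", contains = "RangedSummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  if (!("dosage" %in% assayNames(object)))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- assay(object, "dosage")
    bad <- d[!is.na(d)]
    if (length(bad) && !all(bad %in% c(0L, 1L, 2L)))
      msg <- c(msg, "dosage values must be 0, 1, 2 or NA")
  }
  rr <- rowRanges(object)
  if (length(rr)) {
    if (any(width(rr) != 1L))
      msg <- c(msg, "marker ranges must have width 1 (SNP positions)")
    ps <- split(start(rr), as.character(seqnames(rr)))
    if (any(vapply(ps, function(p) any(diff(p) <= 0), logical(1))))
      msg <- c(msg, "positions must be strictly increasing within a chromosome")
  }
  if (!all(c("name", "year", "role") %in% colnames(colData(object))))
    msg <- c(msg, "colData must contain 'name', 'year' and 'role'")
  if (length(msg)) msg else TRUE
})

#' PedigreeGraph: the cross structure of a recurrent-parent breeding program
#'
#' A directed acyclic graph of crosses. Every non-founder cultivar has
#' exactly one *recurrent* parent (the elite line being improved) and one
#' *donor* parent (the line contributing a target trait). The trunk of the
#' pedigree is the ordered chain of receptors leading from the earliest
#' founder to the focal cultivar; this "pedigree flow" is the path along
#' which haplotype blocks are traced.
#'
#' @slot nodes `DataFrame` with columns `name`, `year` (integer approval
#'   year), `role` (one of `"founder"`, `"receptor"`, `"donor"`,
#'   `"derivative"`).
#' @slot edges `DataFrame` with columns `child`, `parent`, `parent_role`
#'   (`"recurrent"` or `"donor"`).
#' @slot flow_order character: trunk cultivars ordered from the earliest
#'   founder to (and including) the focal cultivar.
#' @slot focal character scalar, the focal cultivar name.
#' @slot derivative_groups named list of character vectors: derivative
#'   cultivars grouped by breeding objective (e.g. `quality`, `yield`).
#' @seealso [pedigreeGraph()], [generatePedigree()], [flowOrder()],
#'   [focalLine()], [ancestorsOf()].
#' @export
setClass("PedigreeGraph",
  representation(
    nodes = "DataFrame",
    edges = "DataFrame",
    flow_order = "character",
    focal = "character",
    derivative_groups = "list"
  )
)

setValidity("PedigreeGraph", function(object) {
  msg <- character()
  nd <- object@nodes
  ed <- object@edges
  if (!all(c("name", "year", "role") %in% colnames(nd)))
    msg <- c(msg, "nodes must have 'name', 'year', 'role'")
  if (anyDuplicated(nd$name))
    msg <- c(msg, "duplicated node names")
  if (nrow(ed)) {
    if (!all(c("child", "parent", "parent_role") %in% colnames(ed)))
      msg <- c(msg, "edges must have 'child', 'parent', 'parent_role'")
    if (!all(ed$parent_role %in% c("recurrent", "donor")))
      msg <- c(msg, "parent_role must be 'recurrent' or 'donor'")
    if (!all(c(ed$child, ed$parent) %in% nd$name))
      msg <- c(msg, "edge endpoints must be nodes")
    tab <- table(ed$child, ed$parent_role)
    if (any(tab != 1L))
      msg <- c(msg, "every non-founder needs exactly one recurrent and one donor parent")
    # acyclicity + year monotonicity along child -> parent links
    yr <- stats::setNames(nd$year, nd$name)
    if (any(yr[ed$child] < yr[ed$parent]))
      msg <- c(msg, "years must be non-decreasing from parent to child")
    if (.has_cycle(ed$child, ed$parent))
      msg <- c(msg, "pedigree must be acyclic")
  }
  if (length(object@focal) != 1L || !(object@focal %in% nd$name))
    msg <- c(msg, "focal must name one node")
  if (!all(object@flow_order %in% nd$name))
    msg <- c(msg, "flow_order entries must be nodes")
  if (length(object@flow_order) &&
      object@flow_order[length(object@flow_order)] != object@focal)
    msg <- c(msg, "flow_order must end at the focal cultivar")
  if (length(msg)) msg else TRUE
})

.has_cycle <- function(child, parent) {
  # Kahn's algorithm on the child -> parent edge list
  nodes <- unique(c(child, parent))
  deg <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(child)
  deg[names(tab)] <- as.integer(tab)
  repeat {
    leaves <- names(deg)[deg == 0L]
    if (!length(leaves)) break
    keep <- !(parent %in% leaves)
    drop_n <- table(child[!keep])
    deg[names(drop_n)] <- deg[names(drop_n)] - as.integer(drop_n)
    deg <- deg[!(names(deg) %in% leaves)]
    child <- child[keep]; parent <- parent[keep]
    if (!length(child)) return(FALSE)
  }
  length(deg) > 0L
}

#' QTLSpec: the genetic architecture used to simulate phenotypes
#'
#' Describes, for one or more traits, the QTLs (marker position, target
#' phenotypic variance explained at heritability 1, favorable allele),
#' optional signed pairwise interaction terms, and the trait heritability.
#' Variances are expressed on a scale where the total genetic variance of
#' the trait is `h2` and the total phenotypic variance is 1; genetic
#' variance not attributed to the listed QTLs is treated as an unmodeled
#' polygenic background.
#'
#' @slot qtls `data.frame` with columns `trait`, `chrom`, `pos`,
#'   `target_pve`, `favorable_allele` (`"ref"` or `"alt"`).
#' @slot interactions `data.frame` with columns `trait`, `qtl_i`, `qtl_j`
#'   (row indices into `qtls` of the same trait), `interaction_pve`
#'   (signed fraction).
#' @slot h2 named numeric, per-trait narrow-sense heritability in (0, 1].
#' @seealso [qtlSpec()], [simulatePhenotypes()].
#' @export
setClass("QTLSpec",
  representation(qtls = "data.frame", interactions = "data.frame",
                 h2 = "numeric")
)

setValidity("QTLSpec", function(object) {
  msg <- character()
  q <- object@qtls
  need <- c("trait", "chrom", "pos", "target_pve", "favorable_allele")
  if (!all(need %in% colnames(q)))
    msg <- c(msg, paste("qtls must have columns:", paste(need, collapse = ", ")))
  else {
    if (any(q$target_pve <= 0 | q$target_pve > 1))
      msg <- c(msg, "target_pve must be in (0, 1]")
    if (any(!object@h2 > 0) || any(object@h2 > 1))
      msg <- c(msg, "h2 must be in (0, 1]")
    for (tr in unique(q$trait)) {
      tot <- sum(q$target_pve[q$trait == tr])
      if (nrow(object@interactions))
        tot <- tot + sum(abs(object@interactions$interaction_pve[
          object@interactions$trait == tr]))
      if (tot > 1 + 1e-9)
        msg <- c(msg, sprintf("variance contributions for '%s' exceed 1", tr))
      h2t <- object@h2[tr]
      if (!is.na(h2t) && tot > h2t + 1e-9)
        msg <- c(msg, sprintf(
          "QTL variance for '%s' exceeds its heritability budget", tr))
    }
  }
  if (length(msg)) msg else TRUE
})
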