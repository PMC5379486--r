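#' Read genotypes from VCF or TSV
#'
#' VCF (v4.2) `GT` fields are converted to alternate-allele dosages
#' (`0/0` to 0, `0/1` or `1/0` to 1, `1/1` to 2, `./.` to missing);
#' multi-allelic sites are dropped with a message giving the count. The
#' TSV format is the one written by [writeGenotypesTSV()]: columns
#' `chrom`, `pos`, `ref`, `alt`, then one column per line with dosage
#' values or `NA`.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @param lineData optional `data.frame` (`name`, `year`, `role`) or a
#'   [PedigreeGraph-class] supplying line metadata.
#' @return a [GenotypeMatrix-class].
#' @export
readGenotypes <- function(path, format = c("auto", "vcf", "tsv"),
                          lineData = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (is(lineData, "PedigreeGraph")) lineData <- pedigreeNodes(lineData)
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    multi <- grepl(",", fix[, "ALT"])
    if (any(multi))
      message(sum(multi), " multi-allelic site(s) dropped")
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gt[!multi, , drop = FALSE]
    fix <- fix[!multi, , drop = FALSE]
    gt <- gsub("\\|", "/", gt)
    dos <- matrix(NA_integer_, nrow(gt), ncol(gt),
                  dimnames = dimnames(gt))
    dos[gt == "0/0"] <- 0L
    dos[gt %in% c("0/1", "1/0")] <- 1L
    dos[gt == "1/1"] <- 2L
    ord <- order(fix[, "CHROM"], as.integer(fix[, "POS"]))
    genotypeMatrix(dos[ord, , drop = FALSE],
                   chrom = fix[ord, "CHROM"],
                   pos = as.integer(fix[ord, "POS"]),
                   ref = fix[ord, "REF"], alt = fix[ord, "ALT"],
                   lineData = lineData)
  } else {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "ref", "alt")
    if (!all(need %in% colnames(tab)))
      stop("malformed genotype TSV: expected columns ",
           paste(need, collapse = ", "))
    d <- as.matrix(tab[, setdiff(colnames(tab), need), drop = FALSE])
    storage.mode(d) <- "integer"
    genotypeMatrix(d, chrom = tab$chrom, pos = tab$pos, ref = tab$ref,
                   alt = tab$alt, lineData = lineData)
  }
}

#' Write genotypes as a dosage TSV
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenotypesTSV <- function(genotypes, path) {
  mi <- markerInfo(genotypes)
  tab <- cbind(mi[, c("chrom", "pos", "ref", "alt")],
               as.data.frame(dosage(genotypes)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write genotypes as VCF v4.2
#'
#' One sample per line, GT field only; dosage 0/1/2 becomes `0/0`,
#' `0/1`, `1/1`, missing becomes `./.`. Single-character allele labels
#' are emitted as-is (the chip-style default `A`/`B` is valid VCF).
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenotypesVCF <- function(genotypes, path) {
  mi <- markerInfo(genotypes)
  d <- dosage(genotypes)
  gt <- matrix("./.", nrow(d), ncol(d))
  gt[!is.na(d) & d == 0L] <- "0/0"
  gt[!is.na(d) & d == 1L] <- "0/1"
  gt[!is.na(d) & d == 2L] <- "1/1"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=breedtrace",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", colnames(d)), collapse = "\t")), con)
  body <- cbind(mi$chrom, mi$pos, rownames(mi), mi$ref, mi$alt, ".",
                "PASS", ".", "GT", gt)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Write intervals as BED
#'
#' Internal 1-based inclusive intervals `[s, e]` become 0-based
#' half-open BED records `(s-1, e)`, sorted by chromosome and start. A
#' `name` metadata column (or `block_id`) and a numeric `score` column
#' are carried into BED columns 4-5 (score clamped to 0-1000).
#'
#' @param intervals a [GenomicRanges::GRanges].
#' @param path output path.
#' @param score_col optional metadata column used as the BED score.
#' @return `path`, invisibly.
#' @export
writeIntervalsBED <- function(intervals, path, score_col = NULL) {
  if (!length(intervals)) {
    file.create(path)
    return(invisible(path))
  }
  o <- order(as.character(seqnames(intervals)), start(intervals))
  gr <- intervals[o]
  nm <- if ("name" %in% colnames(S4Vectors::mcols(gr))) gr$name
        else if ("block_id" %in% colnames(S4Vectors::mcols(gr)))
          gr$block_id
        else paste0("iv", seq_along(gr))
  sc <- if (!is.null(score_col)) {
    s <- S4Vectors::mcols(gr)[[score_col]]
    as.integer(pmin(pmax(round(s), 0), 1000))
  } else rep(0L, length(gr))
  tab <- data.frame(as.character(seqnames(gr)), start(gr) - 1L,
                    end(gr), nm, sc)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read intervals from BED
#'
#' @param path BED file (0-based half-open); converted to internal
#'   1-based inclusive coordinates.
#' @return a [GenomicRanges::GRanges] with a `name` column when present.
#' @export
readIntervalsBED <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  gr
}

#' Read gene annotation from GFF3
#'
#' Thin wrapper over `rtracklayer::import` (GFF coordinates are 1-based
#' inclusive, matching the package's internal convention). Unparseable
#' input raises an error naming the file.
#'
#' @param path GFF3 file.
#' @return a [GenomicRanges::GRanges].
#' @export
readGFF <- function(path) {
  tryCatch(rtracklayer::import(path, format = "GFF3"),
           error = function(e)
             stop("failed to parse GFF3 '", path, "': ",
                  conditionMessage(e)))
}

#' Write a pedigree as TSV
#'
#' Columns: `cultivar`, `recurrent_parent`, `donor_parent`, `year`,
#' `role`, `derivative_group`, `is_focal`. Founders and donors have
#' empty parent fields.
#'
#' @param pedigree a [PedigreeGraph-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePedigreeTSV <- function(pedigree, path) {
  nd <- pedigreeNodes(pedigree)
  par <- t(vapply(nd$name, function(n) parentsOf(pedigree, n),
                  character(2)))
  grp <- rep(NA_character_, nrow(nd))
  for (gn in names(derivativeGroups(pedigree)))
    grp[nd$name %in% derivativeGroups(pedigree)[[gn]]] <- gn
  tab <- data.frame(cultivar = nd$name,
                    recurrent_parent = par[, "recurrent"],
                    donor_parent = par[, "donor"],
                    year = nd$year, role = nd$role,
                    derivative_group = grp,
                    is_focal = nd$name == focalLine(pedigree))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a pedigree from TSV
#'
#' @param path TSV written by [writePedigreeTSV()] (or hand-made with
#'   the same columns; `derivative_group`/`is_focal` optional).
#' @param focal focal cultivar; default: the `is_focal` column, else the
#'   latest receptor.
#' @return a [PedigreeGraph-class].
#' @export
readPedigreeTSV <- function(path, focal = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("cultivar", "recurrent_parent", "donor_parent", "year",
            "role")
  if (!all(need %in% colnames(tab)))
    stop("malformed pedigree TSV: expected columns ",
         paste(need, collapse = ", "))
  nodes <- data.frame(name = tab$cultivar, year = tab$year,
                      role = tab$role)
  has_par <- !is.na(tab$recurrent_parent)
  edges <- data.frame(
    child = rep(tab$cultivar[has_par], 2L),
    parent = c(tab$recurrent_parent[has_par],
               tab$donor_parent[has_par]),
    parent_role = rep(c("recurrent", "donor"), each = sum(has_par)))
  if (is.null(focal) && "is_focal" %in% colnames(tab) &&
      any(tab$is_focal %in% TRUE))
    focal <- tab$cultivar[which(tab$is_focal)[1L]]
  groups <- list()
  if ("derivative_group" %in% colnames(tab))
    for (gn in unique(stats::na.omit(tab$derivative_group)))
      groups[[gn]] <- tab$cultivar[!is.na(tab$derivative_group) &
                                     tab$derivative_group == gn]
  pedigreeGraph(nodes, edges, focal = focal,
                derivative_groups = groups)
}

#' Write phenotypes as long-format TSV
#'
#' @param phenotypes long `data.frame` (`line`, `trait`, `replicate`,
#'   `value`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePhenotypesTSV <- function(phenotypes, path) {
  utils::write.table(
    phenotypes[, c("line", "trait", "replicate", "value")], path,
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read long-format phenotypes
#'
#' @param path TSV with columns `line`, `trait`, `replicate`, `value`.
#' @return long `data.frame`.
#' @export
readPhenotypes <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("line", "trait", "replicate", "value")
  if (!all(need %in% colnames(tab)))
    stop("malformed phenotype TSV: expected columns ",
         paste(need, collapse = ", "))
  tab
}
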