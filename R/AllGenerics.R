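#' Extract the dosage matrix
#'
#' @param x a [GenotypeMatrix-class].
#' @return integer matrix, markers x lines, values 0/1/2/NA.
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' Marker coordinates and alleles
#'
#' @param x a [GenotypeMatrix-class].
#' @return `data.frame` with `chrom`, `pos`, `ref`, `alt`.
#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))

#' Line metadata
#'
#' @param x a [GenotypeMatrix-class].
#' @return `data.frame` with `name`, `year`, `role`.
#' @export
setGeneric("lineInfo", function(x) standardGeneric("lineInfo"))

#' Pedigree-flow order of the trunk
#'
#' @param x a [PedigreeGraph-class].
#' @return character vector, earliest founder first, focal cultivar last.
#' @export
setGeneric("flowOrder", function(x) standardGeneric("flowOrder"))

#' Focal cultivar of a pedigree
#'
#' @param x a [PedigreeGraph-class].
#' @return character scalar.
#' @export
setGeneric("focalLine", function(x) standardGeneric("focalLine"))

#' Derivative groups of a pedigree
#'
#' @param x a [PedigreeGraph-class].
#' @return named list of character vectors (e.g. `quality`, `yield`).
#' @export
setGeneric("derivativeGroups", function(x) standardGeneric("derivativeGroups"))

#' All pedigree ancestors of a cultivar
#'
#' @param x a [PedigreeGraph-class].
#' @param line cultivar name.
#' @return character vector of ancestor names (unordered).
#' @export
setGeneric("ancestorsOf", function(x, line) standardGeneric("ancestorsOf"))
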