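#' Construct a PedigreeGraph
#'
#' @param nodes `data.frame` with columns `name`, `year`, `role`.
#' @param edges `data.frame` with columns `child`, `parent`, `parent_role`
#'   (`"recurrent"`/`"donor"`); founders and donors have no incoming edges.
#' @param focal focal cultivar name. Defaults to the latest receptor.
#' @param flow_order trunk order (earliest founder to focal). If `NULL` it
#'   is reconstructed by following recurrent-parent links back from the
#'   focal cultivar.
#' @param derivative_groups named list of character vectors.
#' @return a [PedigreeGraph-class].
#' @export
pedigreeGraph <- function(nodes, edges, focal = NULL, flow_order = NULL,
                          derivative_groups = list()) {
  nodes <- DataFrame(name = as.character(nodes$name),
                     year = as.integer(nodes$year),
                     role = as.character(nodes$role))
  edges <- DataFrame(child = as.character(edges$child),
                     parent = as.character(edges$parent),
                     parent_role = as.character(edges$parent_role))
  if (is.null(focal)) {
    rec <- nodes[nodes$role == "receptor", , drop = FALSE]
    if (!nrow(rec)) stop("no receptors: cannot infer a focal cultivar")
    focal <- rec$name[which.max(rec$year)]
  }
  if (is.null(flow_order))
    flow_order <- .trunk_chain(edges, focal)
  new("PedigreeGraph", nodes = nodes, edges = edges,
      flow_order = flow_order, focal = focal,
      derivative_groups = derivative_groups)
}

# follow recurrent-parent links upward from the focal line
.trunk_chain <- function(edges, focal) {
  chain <- focal
  cur <- focal
  repeat {
    i <- which(edges$child == cur & edges$parent_role == "recurrent")
    if (!length(i)) break
    cur <- edges$parent[i[1L]]
    chain <- c(cur, chain)
  }
  chain
}

#' @rdname flowOrder
#' @export
setMethod("flowOrder", "PedigreeGraph", function(x) x@flow_order)

#' @rdname focalLine
#' @export
setMethod("focalLine", "PedigreeGraph", function(x) x@focal)

#' @rdname derivativeGroups
#' @export
setMethod("derivativeGroups", "PedigreeGraph", function(x)
  x@derivative_groups)

#' @rdname ancestorsOf
#' @export
setMethod("ancestorsOf", "PedigreeGraph", function(x, line) {
  stopifnot(line %in% x@nodes$name)
  anc <- character()
  frontier <- line
  while (length(frontier)) {
    par <- unique(x@edges$parent[x@edges$child %in% frontier])
    par <- setdiff(par, anc)
    anc <- c(anc, par)
    frontier <- par
  }
  anc
})

#' Parents of a cultivar
#'
#' @param x a [PedigreeGraph-class].
#' @param line cultivar name.
#' @return named character vector with elements `recurrent` and `donor`
#'   (NA for founders/donors).
#' @export
parentsOf <- function(x, line) {
  i <- x@edges$child == line
  out <- c(recurrent = NA_character_, donor = NA_character_)
  out[x@edges$parent_role[i]] <- x@edges$parent[i]
  out
}

#' Node table of a pedigree
#'
#' @param x a [PedigreeGraph-class].
#' @return `data.frame` of nodes (`name`, `year`, `role`).
#' @export
pedigreeNodes <- function(x) as.data.frame(x@nodes)

#' Edge table of a pedigree
#'
#' @param x a [PedigreeGraph-class].
#' @return `data.frame` of edges (`child`, `parent`, `parent_role`).
#' @export
pedigreeEdges <- function(x) as.data.frame(x@edges)

setMethod("show", "PedigreeGraph", function(object) {
  nd <- object@nodes
  cat(sprintf(
    "PedigreeGraph: %d cultivars (%d receptors, %d donors), years %d-%d\n",
    nrow(nd), sum(nd$role == "receptor"), sum(nd$role == "donor"),
    min(nd$year), max(nd$year)))
  cat(sprintf("  focal: %s; trunk depth %d; derivative groups: %s\n",
              object@focal, length(object@flow_order),
              if (length(object@derivative_groups))
                paste(sprintf("%s (%d)", names(object@derivative_groups),
                              lengths(object@derivative_groups)),
                      collapse = ", ")
              else "none"))
})
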