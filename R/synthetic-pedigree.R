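#' Generate a synthetic recurrent-parent breeding pedigree
#'
#' Builds a pedigree with the shape of an elite-line improvement program:
#' a trunk chain of receptors, each produced by crossing the previous
#' receptor (recurrent parent) with a fresh donor; an optional branch chain
#' that merges into the trunk by serving as the donor of the final trunk
#' cross; and two groups of derivative cultivars (`quality` and `yield`)
#' descending from the focal cultivar, each again a focal x donor cross.
#'
#' Years advance by 4-8 years per trunk generation (seeded), mimicking the
#' multi-decade span of real programs; derivatives follow the focal year.
#'
#' @param n_trunk_generations number of trunk receptors (>= 2).
#' @param n_branch number of branch receptors (0 disables the branch).
#' @param n_derivatives total derivative cultivars, split between the
#'   `quality` (floor half) and `yield` groups.
#' @param year_start founder year.
#' @param seed integer seed; the result is deterministic for a fixed seed.
#' @return a [PedigreeGraph-class]; the focal cultivar is the last trunk
#'   receptor.
#' @examples
#' ped <- generatePedigree(9, 7, 11, 1948, seed = 7)
#' ped
#' @export
generatePedigree <- function(n_trunk_generations, n_branch = 0L,
                             n_derivatives = 0L, year_start = 1950L,
                             seed = 1L) {
  if (n_trunk_generations < 2)
    stop("n_trunk_generations must be >= 2")
  if (n_branch < 0 || n_derivatives < 0)
    stop("n_branch and n_derivatives must be non-negative")
  set.seed(seed)
  nodes <- data.frame(name = "F1", year = year_start, role = "founder")
  edges <- data.frame(child = character(), parent = character(),
                      parent_role = character())
  add_node <- function(name, year, role)
    nodes <<- rbind(nodes, data.frame(name = name, year = year, role = role))
  add_cross <- function(child, recurrent, donor)
    edges <<- rbind(edges,
      data.frame(child = child, parent = c(recurrent, donor),
                 parent_role = c("recurrent", "donor")))

  step_years <- function(n) cumsum(sample(4:8, n, replace = TRUE))

  # branch chain (its last receptor becomes the donor of the final trunk cross)
  branch_last <- NULL
  if (n_branch > 0) {
    yrs <- year_start + step_years(n_branch)
    prev <- "F1"
    for (g in seq_len(n_branch)) {
      bd <- sprintf("BD%d", g); br <- sprintf("BR%d", g)
      add_node(bd, yrs[g], "donor")
      add_node(br, yrs[g], "receptor")
      add_cross(br, prev, bd)
      prev <- br
    }
    branch_last <- prev
  }

  yrs <- year_start + step_years(n_trunk_generations)
  if (n_branch > 0) # the merge cross must not precede the branch tip
    yrs[n_trunk_generations] <-
      max(yrs[n_trunk_generations],
          nodes$year[nodes$name == branch_last] + 1L)
  prev <- "F1"
  for (g in seq_len(n_trunk_generations)) {
    r <- sprintf("R%d", g)
    if (g == n_trunk_generations && !is.null(branch_last)) {
      d <- branch_last                       # branch merges into the trunk
    } else {
      d <- sprintf("D%d", g)
      add_node(d, yrs[g], "donor")
    }
    add_node(r, yrs[g], "receptor")
    add_cross(r, prev, d)
    prev <- r
  }
  focal <- prev

  groups <- list()
  if (n_derivatives > 0) {
    n_q <- n_derivatives %/% 2L
    labels <- c(rep("quality", n_q), rep("yield", n_derivatives - n_q))
    dyrs <- max(yrs) + sample(2:8, n_derivatives, replace = TRUE)
    for (i in seq_len(n_derivatives)) {
      dv <- sprintf("%s%d", ifelse(labels[i] == "quality", "Q", "Y"),
                    sum(labels[seq_len(i)] == labels[i]))
      dd <- paste0("DD", i)
      add_node(dd, dyrs[i], "donor")
      add_node(dv, dyrs[i], "derivative")
      add_cross(dv, focal, dd)
      groups[[labels[i]]] <- c(groups[[labels[i]]], dv)
    }
  }

  pedigreeGraph(nodes, edges, focal = focal,
                flow_order = c("F1", sprintf("R%d", seq_len(n_trunk_generations))),
                derivative_groups = groups)
}
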