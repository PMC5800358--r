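## Species trees: a rooted phylogenetic tree on the species set, augmented
## with a planted root above the crown so that duplications and transfers
## predating the first speciation have an edge to map to.

#' Plant an augmenting root above a species tree
#'
#' Adds one extra vertex above the most recent common ancestor of all
#' species, together with the edge joining them.  Duplication and transfer
#' vertices of a gene tree map to edges of the species tree, and events
#' older than the first speciation need this extra edge.  Augmenting an
#' already-augmented tree is a no-op.
#'
#' @param raw a `rooted_tree` on the species set (leaves are species).
#' @return an object of class `species_tree` (also a `rooted_tree`), with
#'   the planted root available via [tree_root()].
#' @examples
#' s <- augment_species_root(rooted_tree(data.frame(
#'   parent = c("R", "R", "X", "X"), child = c("X", "C", "A", "B"))))
#' tree_root(s)
#' @export
augment_species_root <- function(raw) {
  if (inherits(raw, "species_tree")) return(raw)
  stopifnot(inherits(raw, "rooted_tree"))
  n <- n_vertices(raw)
  if (length(raw$leaves) < 1L) stop("species tree needs at least one leaf")
  nch <- vapply(raw$children, length, 1L)
  if (n > 1L && nch[raw$root] == 1L) {
    ## structurally already augmented
    return(as_species_tree(raw))
  }
  bad <- which(nch == 1L)
  if (length(bad)) {
    stop("not a phylogenetic tree: vertex '", raw$ids[bad[1L]],
         "' has a single child")
  }
  rho <- "RHO"
  while (tree_has(raw, rho)) rho <- paste0(rho, "_")
  ids <- c(raw$ids, rho)
  parent <- c(raw$parent, 0L)
  parent[raw$root] <- n + 1L
  as_species_tree(new_rooted_tree(ids, parent))
}

as_species_tree <- function(tree) {
  nch <- vapply(tree$children, length, 1L)
  if (n_vertices(tree) > 1L && nch[tree$root] != 1L) {
    stop("a species tree must have a planted root with a single child")
  }
  bad <- which(nch == 1L)
  bad <- setdiff(bad, tree$root)
  if (length(bad)) {
    stop("not a phylogenetic tree: vertex '", tree$ids[bad[1L]],
         "' has a single child")
  }
  class(tree) <- c("species_tree", "rooted_tree")
  tree
}

#' Species labels of a species tree
#' @param s a `species_tree`.
#' @return character vector of species (the leaves).
#' @export
species_of <- function(s) tree_leaves(s)

#' @export
print.species_tree <- function(x, ...) {
  cat(sprintf("<species_tree: %d species, planted root '%s'>\n",
              length(x$leaves), tree_root(x)))
  invisible(x)
}
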