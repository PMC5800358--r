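## Rooted-tree substrate.
##
## Vertices are stable string ids; internally every vertex also has an
## integer index (position in `ids`).  Edges are directed away from the root
## and are addressed by their child endpoint, which is unique because every
## non-root vertex has exactly one parent.  The ancestor partial order is
## extended from vertices to edges: for e = (u,v),
##   x < e  iff  x <= v,      e < x  iff  u <= x,
## and for edges e = (u,v), f = (a,b):  e <= f  iff  v <= b.
## Trees are immutable after construction; LCA preprocessing (binary
## lifting) is built once by the constructor.

new_rooted_tree <- function(ids, parent) {
  n <- length(ids)
  stopifnot(is.character(ids), length(parent) == n)
  if (anyDuplicated(ids)) {
    stop("duplicated vertex ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  root <- which(parent == 0L)
  if (length(root) != 1L) stop("tree must have exactly one root")
  children <- vector("list", n)
  for (v in seq_len(n)) children[[v]] <- integer(0)
  for (v in seq_len(n)) {
    p <- parent[v]
    if (p > 0L) children[[p]] <- c(children[[p]], v)
  }
  ## preorder + depth; also detects cycles / disconnected vertices
  depth <- rep.int(NA_integer_, n)
  preorder <- integer(n)
  depth[root] <- 0L
  stack <- integer(n)
  stack[1L] <- root
  top <- 1L
  k <- 0L
  while (top > 0L) {
    v <- stack[top]
    top <- top - 1L
    k <- k + 1L
    preorder[k] <- v
    for (w in children[[v]]) {
      depth[w] <- depth[v] + 1L
      top <- top + 1L
      stack[top] <- w
    }
  }
  if (k != n || anyNA(depth)) stop("edge relation is not connected and acyclic")
  leaves <- which(vapply(children, length, 1L) == 0L)
  ## binary lifting table for O(log n) LCA / ancestor queries
  maxd <- max(depth)
  K <- max(1L, ceiling(log2(maxd + 1)) + 1L)
  up <- matrix(0L, nrow = n, ncol = K)
  up[, 1L] <- parent
  if (K > 1L) {
    for (j in 2:K) {
      prev <- up[, j - 1L]
      nz <- prev > 0L
      up[nz, j] <- up[prev[nz], j - 1L]
    }
  }
  idx <- new.env(parent = emptyenv(), size = n)
  for (v in seq_len(n)) assign(ids[v], v, envir = idx)
  structure(
    list(ids = ids, parent = parent, children = children, root = root,
         depth = depth, preorder = preorder, leaves = leaves, up = up,
         idx = idx),
    class = "rooted_tree"
  )
}

#' Build a rooted tree from a parent/child edge table
#'
#' @param edges two-column data frame or matrix of character ids,
#'   first column the parent, second the child, edges directed away from
#'   the root.
#' @return an object of class `rooted_tree`.
#' @examples
#' tr <- rooted_tree(data.frame(parent = c("R", "R", "X", "X"),
#'                              child  = c("X", "C", "A", "B")))
#' tree_lca(tr, c("A", "B"))
#' @export
rooted_tree <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop("edges must have two columns (parent, child)")
  pa <- as.character(edges[[1L]])
  ch <- as.character(edges[[2L]])
  if (length(pa) == 0L) stop("empty edge set; a tree needs at least one vertex")
  ids <- unique(c(pa, ch))
  parent <- rep.int(0L, length(ids))
  pi <- match(pa, ids)
  ci <- match(ch, ids)
  if (anyDuplicated(ci)) stop("a vertex appears with more than one parent")
  parent[ci] <- pi
  new_rooted_tree(ids, parent)
}

## A single-vertex tree (used for degenerate single-leaf inputs).
singleton_tree <- function(id) new_rooted_tree(id, 0L)

tree_index <- function(tree, ids) {
  out <- vapply(ids, function(id) {
    v <- get0(id, envir = tree$idx, inherits = FALSE)
    if (is.null(v)) stop("vertex '", id, "' is not in the tree")
    v
  }, 1L)
  unname(out)
}

tree_has <- function(tree, id) {
  !is.null(get0(id, envir = tree$idx, inherits = FALSE))
}

n_vertices <- function(tree) length(tree$ids)

#' Leaf labels of a rooted tree
#' @param tree a `rooted_tree`.
#' @return character vector of leaf ids.
#' @export
tree_leaves <- function(tree) tree$ids[tree$leaves]

#' Root label of a rooted tree
#' @param tree a `rooted_tree`.
#' @return the root vertex id.
#' @export
tree_root <- function(tree) tree$ids[tree$root]

#' Parent of a vertex
#' @param tree a `rooted_tree`.
#' @param id a vertex id.
#' @return the parent id, or `NA` for the root.
#' @export
tree_parent <- function(tree, id) {
  p <- tree$parent[tree_index(tree, id)]
  if (p == 0L) NA_character_ else tree$ids[p]
}

#' Children of a vertex
#' @param tree a `rooted_tree`.
#' @param id a vertex id.
#' @return character vector of child ids (possibly empty).
#' @export
tree_children <- function(tree, id) {
  tree$ids[tree$children[[tree_index(tree, id)]]]
}

#' @export
print.rooted_tree <- function(x, ...) {
  cat(sprintf("<rooted_tree: %d vertices, %d leaves, root '%s'>\n",
              n_vertices(x), length(x$leaves), tree_root(x)))
  invisible(x)
}

## integer-index ancestor machinery ---------------------------------------

## ancestor of v at depth d (d <= depth[v]), via binary lifting
ancestor_at_depth <- function(tree, v, d) {
  k <- tree$depth[v] - d
  j <- 1L
  while (k > 0L) {
    if (bitwAnd(k, 1L) == 1L) v <- tree$up[v, j]
    k <- bitwShiftR(k, 1L)
    j <- j + 1L
  }
  v
}

## a is ancestor-or-equal of b (vertex indices)
anc_idx <- function(tree, a, b) {
  tree$depth[a] <= tree$depth[b] && ancestor_at_depth(tree, b, tree$depth[a]) == a
}

lca_idx2 <- function(tree, a, b) {
  if (tree$depth[a] > tree$depth[b]) { tmp <- a; a <- b; b <- tmp }
  b <- ancestor_at_depth(tree, b, tree$depth[a])
  if (a == b) return(a)
  for (j in rev(seq_len(ncol(tree$up)))) {
    if (tree$up[a, j] != tree$up[b, j]) {
      a <- tree$up[a, j]
      b <- tree$up[b, j]
    }
  }
  tree$up[a, 1L]
}

lca_idx <- function(tree, vs) Reduce(function(a, b) lca_idx2(tree, a, b), vs)

#' Least common ancestor
#'
#' Returns the unique most-recent common ancestor of a non-empty set of
#' vertices.  Satisfies `lca({u}) = u` and
#' `lca(A u B) = lca(lca(A), lca(B))`.  Individual queries are answered in
#' O(log n) after the one-time binary-lifting preprocessing done at tree
#' construction.
#'
#' @param tree a `rooted_tree`.
#' @param nodes non-empty character vector of vertex ids.
#' @return a vertex id.
#' @export
tree_lca <- function(tree, nodes) {
  if (length(nodes) == 0L) stop("lca of an empty vertex set is undefined")
  tree$ids[lca_idx(tree, tree_index(tree, unique(nodes)))]
}

## tree points -------------------------------------------------------------

#' Points of a tree: vertices and edges
#'
#' A tree point is either a vertex or an edge; edges are identified by
#' their child endpoint.  Points are the codomain of reconciliation maps.
#'
#' @param id a vertex id; for `edge_point` the child endpoint of the edge.
#' @return an object of class `tree_point`.
#' @export
vertex_point <- function(id) {
  structure(list(kind = "vertex", id = as.character(id)), class = "tree_point")
}

#' @rdname vertex_point
#' @export
edge_point <- function(id) {
  structure(list(kind = "edge", id = as.character(id)), class = "tree_point")
}

as_tree_point <- function(p) {
  if (inherits(p, "tree_point")) return(p)
  if (is.character(p) && length(p) == 1L) return(vertex_point(p))
  stop("not a tree point")
}

#' @export
print.tree_point <- function(x, ...) {
  cat(if (x$kind == "vertex") sprintf("<vertex %s>\n", x$id)
      else sprintf("<edge into %s>\n", x$id))
  invisible(x)
}

#' @export
format.tree_point <- function(x, ...) {
  if (x$kind == "vertex") x$id else paste0("->", x$id)
}

point_equal <- function(a, b) a$kind == b$kind && a$id == b$id

## b <= a under the edge-extended ancestor order (a, b tree points)
point_leq <- function(tree, b, a) {
  bi <- tree_index(tree, b$id)
  ai <- tree_index(tree, a$id)
  if (a$kind == "vertex" && b$kind == "vertex") {
    anc_idx(tree, ai, bi)
  } else if (a$kind == "vertex" && b$kind == "edge") {
    ## edge (u, v) < x  iff  u <= x
    u <- tree$parent[bi]
    if (u == 0L) stop("the root has no incoming edge")
    anc_idx(tree, ai, u)
  } else if (a$kind == "edge" && b$kind == "vertex") {
    ## x < (u, v)  iff  x <= v
    anc_idx(tree, ai, bi)
  } else {
    ## (p,q) <= (u,v)  iff  q <= v
    anc_idx(tree, ai, bi)
  }
}

check_point <- function(tree, p) {
  p <- as_tree_point(p)
  if (!tree_has(tree, p$id)) stop("point '", p$id, "' is not in the tree")
  if (p$kind == "edge" && tree$parent[tree_index(tree, p$id)] == 0L) {
    stop("no edge into the root '", p$id, "'")
  }
  p
}

#' Ancestor test under the edge-extended order
#'
#' Tests whether point `a` is an ancestor of (or equal to) point `b` in the
#' order extended from vertices to edges: an edge `(u,v)` lies strictly
#' between `u` and `v`.  Two points are comparable iff
#' `is_ancestor(tree, a, b) || is_ancestor(tree, b, a)`.
#'
#' @param tree a `rooted_tree`.
#' @param a,b tree points (see [vertex_point()], [edge_point()]); bare
#'   strings are taken as vertex points.
#' @return logical.
#' @export
is_ancestor <- function(tree, a, b) {
  a <- check_point(tree, a)
  b <- check_point(tree, b)
  point_leq(tree, b, a)
}

points_comparable <- function(tree, a, b) {
  point_leq(tree, b, a) || point_leq(tree, a, b)
}

## strict b < a
point_lt <- function(tree, b, a) point_leq(tree, b, a) && !point_equal(a, b)
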