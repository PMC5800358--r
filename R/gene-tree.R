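## Event-labeled gene trees.
##
## A gene tree carries an event label per vertex -- speciation ("spe"),
## duplication ("dup"), horizontal transfer ("hgt"), or "leaf" -- a
## transfer flag per edge (addressed by the child endpoint; only out-edges
## of hgt vertices may be flagged), and the assignment sigma of each gene
## (leaf) to the species it resides in.

EVENTS <- c("spe", "dup", "hgt", "leaf")

#' Construct an event-labeled gene tree
#'
#' @param tree a `rooted_tree` on the gene set (leaves are genes).
#' @param events named character vector over the internal vertex ids with
#'   values `"spe"`, `"dup"` or `"hgt"`; leaves are labeled `"leaf"`
#'   automatically (supplying them is allowed but they must be `"leaf"`).
#' @param sigma named character vector mapping each leaf id to a species
#'   label.
#' @param transfer character vector of child endpoints of transfer edges
#'   (or a named logical vector over child endpoints).  Only edges whose
#'   parent is an `"hgt"` vertex may be flagged.
#' @return an object of class `gene_tree`.
#' @export
gene_tree <- function(tree, events, sigma, transfer = character(0)) {
  stopifnot(inherits(tree, "rooted_tree"))
  ev <- rep.int(NA_character_, n_vertices(tree))
  names(ev) <- tree$ids
  ev[tree$leaves] <- "leaf"
  if (length(events)) {
    pos <- match(names(events), tree$ids)
    if (anyNA(pos)) {
      stop("event label for unknown vertex '", names(events)[is.na(pos)][1L], "'")
    }
    ev[pos] <- as.character(unlist(events, use.names = FALSE))
  }
  if (anyNA(ev)) {
    stop("missing event label for internal vertex '",
         names(ev)[which(is.na(ev))[1L]], "'")
  }
  if (!all(ev %in% EVENTS)) stop("event labels must be one of ",
                                 paste(EVENTS, collapse = "/"))
  is_leaf <- seq_len(n_vertices(tree)) %in% tree$leaves
  if (any((ev == "leaf") != is_leaf)) {
    stop("'leaf' labels must coincide exactly with the leaf set")
  }
  if (is.logical(transfer)) transfer <- names(transfer)[transfer]
  transfer <- as.character(transfer)
  tr <- rep.int(FALSE, n_vertices(tree))
  names(tr) <- tree$ids
  if (length(transfer)) {
    tri <- match(transfer, tree$ids)
    if (anyNA(tri)) stop("transfer flag on unknown vertex '",
                         transfer[is.na(tri)][1L], "'")
    pa <- tree$parent[tri]
    if (any(pa == 0L)) {
      stop("no edge into the root '", transfer[which(pa == 0L)[1L]], "'")
    }
    bad <- unname(ev[pa]) != "hgt"
    if (any(bad)) {
      stop("transfer flag on edge into '", transfer[bad][1L],
           "' but its parent is not an hgt vertex")
    }
    tr[tri] <- TRUE
  }
  lv <- tree$ids[tree$leaves]
  sg <- match(lv, names(sigma))
  if (anyNA(sg)) {
    stop("sigma missing for gene(s): ",
         paste(lv[is.na(sg)], collapse = ", "))
  }
  sigma <- stats::setNames(as.character(unlist(sigma, use.names = FALSE))[sg], lv)
  structure(list(tree = tree, events = ev, transfer = tr, sigma = sigma),
            class = "gene_tree")
}

#' @export
print.gene_tree <- function(x, ...) {
  cat(sprintf(
    "<gene_tree: %d genes in %d species; %d spe, %d dup, %d hgt, %d transfer edges>\n",
    length(x$tree$leaves), length(unique(x$sigma)),
    sum(x$events == "spe"), sum(x$events == "dup"), sum(x$events == "hgt"),
    sum(x$transfer)))
  invisible(x)
}

#' Genes of a gene tree
#' @param g a `gene_tree`.
#' @return character vector of gene (leaf) ids.
#' @export
genes_of <- function(g) tree_leaves(g$tree)

## transfer-free forest ----------------------------------------------------

#' Delete all transfer edges
#'
#' Removing the transfer edges from a gene tree yields a forest whose
#' components inherit the ancestor order.  For each vertex `u` the set of
#' component leaves below it, and their species (`sigma_TE(u)`), are the
#' basic quantities used by reconciliation maps.
#'
#' @param g a `gene_tree`.
#' @return an object of class `transfer_forest` with per-vertex component
#'   ids, component roots, component leaf sets and species sets.
#' @export
remove_transfer_edges <- function(g) {
  tree <- g$tree
  n <- n_vertices(tree)
  cut <- unname(g$transfer[tree$ids])        # by child endpoint, aligned
  comp <- integer(n)
  roots <- integer(0)
  for (v in tree$preorder) {                  # parents before children
    p <- tree$parent[v]
    if (p == 0L || cut[v]) {
      roots <- c(roots, v)
      comp[v] <- length(roots)
    } else {
      comp[v] <- comp[p]
    }
  }
  sig_at <- character(n)
  sig_at[tree$leaves] <- unname(g$sigma[tree$ids[tree$leaves]])
  leafidx <- vector("list", n)
  sigsets <- vector("list", n)
  for (v in rev(tree$preorder)) {             # children before parents
    if (length(tree$children[[v]]) == 0L) {
      leafidx[[v]] <- v
    } else {
      keep <- tree$children[[v]][!cut[tree$children[[v]]]]
      li <- unlist(leafidx[keep], use.names = FALSE)
      leafidx[[v]] <- if (is.null(li)) integer(0) else li
    }
    sigsets[[v]] <- sort(unique(sig_at[leafidx[[v]]]))
  }
  leafsets <- lapply(leafidx, function(i) tree$ids[i])
  names(leafsets) <- tree$ids
  names(sigsets) <- tree$ids
  structure(list(comp = comp, roots = tree$ids[roots],
                 leafsets = leafsets, sigma_sets = sigsets, gene = g),
            class = "transfer_forest")
}

#' @export
print.transfer_forest <- function(x, ...) {
  cat(sprintf("<transfer_forest: %d components>\n", length(x$roots)))
  invisible(x)
}

#' Species below a vertex within its transfer-free component
#' @param forest a `transfer_forest` (see [remove_transfer_edges()]).
#' @param id a vertex id of the gene tree.
#' @return character vector of species labels (`sigma_TE(id)`).
#' @export
sigma_TE <- function(forest, id) {
  if (is.null(forest$sigma_sets[[id]])) stop("unknown vertex '", id, "'")
  forest$sigma_sets[[id]]
}

## comparability within the transfer-free forest: same component and
## ancestor in the full tree
leq_TE <- function(forest, u, v) {
  tree <- forest$gene$tree
  ui <- tree_index(tree, u); vi <- tree_index(tree, v)
  forest$comp[ui] == forest$comp[vi] && anc_idx(tree, vi, ui)
}

## observability conditions ------------------------------------------------

#' Observability condition O1: no unobservable unary events
#'
#' Every internal non-root vertex must have total degree at least 3
#' (i.e. at least two children) and the root at least two children, so
#' that every recorded event leaves descendants in at least two subtrees.
#'
#' @param g a `gene_tree`.
#' @return logical.
#' @export
check_O1 <- function(g) {
  tree <- g$tree
  nch <- vapply(tree$children, length, 1L)
  internal <- setdiff(which(nch > 0L), tree$root)
  all(nch[internal] >= 2L) &&
    (length(tree$children[[tree$root]]) == 0L || nch[tree$root] >= 2L)
}

#' Observability condition O2: transfers leave traces on both sides
#'
#' Every hgt vertex must have at least one transfer out-edge and at least
#' one non-transfer out-edge: otherwise either the transfer or the donor
#' lineage left no observable descendant.
#'
#' @param g a `gene_tree`.
#' @return logical.
#' @export
check_O2 <- function(g) {
  tree <- g$tree
  for (v in which(unname(g$events[tree$ids]) == "hgt")) {
    kids <- tree$ids[tree$children[[v]]]
    fl <- unname(g$transfer[kids])
    if (!any(fl) || all(fl)) return(FALSE)
  }
  TRUE
}

#' Speciation separation condition (Sigma1)
#'
#' A speciation vertex must have two distinct children whose
#' transfer-free species sets are disjoint; otherwise there is no
#' historical trace justifying a speciation at that vertex.  Requires O2,
#' which guarantees the species sets are non-empty.
#'
#' @param g a `gene_tree`.
#' @param forest optionally a precomputed [remove_transfer_edges()] result.
#' @return character vector of violating speciation vertex ids (empty if
#'   the tree passes).
#' @export
check_sigma1 <- function(g, forest = NULL) {
  if (!check_O2(g)) {
    stop("O2 fails for this tree; run check_O2() first ",
         "(transfer-free species sets may be empty)")
  }
  if (is.null(forest)) forest <- remove_transfer_edges(g)
  tree <- g$tree
  bad <- character(0)
  for (v in which(unname(g$events[tree$ids]) == "spe")) {
    kids <- tree$children[[v]]
    ok <- FALSE
    if (length(kids) >= 2L) {
      sets <- forest$sigma_sets[kids]
      for (i in seq_along(kids)) {
        for (j in seq_along(kids)) {
          if (i < j && length(intersect(sets[[i]], sets[[j]])) == 0L) {
            ok <- TRUE
            break
          }
        }
        if (ok) break
      }
    }
    if (!ok) bad <- c(bad, tree$ids[v])
  }
  bad
}

#' Transfer separation condition (Sigma2)
#'
#' The donor-side and recipient-side transfer-free species sets of every
#' transfer edge must be disjoint: a transfer whose endpoints share a
#' species would have to be placed at comparable species-tree positions
#' and would not be recognizable as a transfer.  Requires O2.
#'
#' @inheritParams check_sigma1
#' @return data frame of violating transfer edges (columns `from`, `to`);
#'   zero rows if the tree passes.
#' @export
check_sigma2 <- function(g, forest = NULL) {
  if (!check_O2(g)) {
    stop("O2 fails for this tree; run check_O2() first ",
         "(transfer-free species sets may be empty)")
  }
  if (is.null(forest)) forest <- remove_transfer_edges(g)
  tree <- g$tree
  from <- character(0); to <- character(0)
  for (w in tree$ids[unname(g$transfer[tree$ids])]) {
    v <- tree_parent(tree, w)
    if (length(intersect(sigma_TE(forest, v), sigma_TE(forest, w)))) {
      from <- c(from, v); to <- c(to, w)
    }
  }
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

## gene-family aggregation -------------------------------------------------

#' Aggregate several gene families into one gene tree
#'
#' Joins a list of event-labeled gene trees under an artificial
#' duplication root, so that a single time-consistent reconciliation with
#' one species tree can be sought for all families simultaneously.  If
#' vertex ids clash across families, every vertex of family `i` is
#' renamed by appending the 0-based family index.
#'
#' @param gs non-empty list of `gene_tree` objects over a common species
#'   set.
#' @return a `gene_tree` whose root is a duplication with one child per
#'   input family.
#' @export
aggregate_gene_trees <- function(gs) {
  if (length(gs) == 0L) stop("cannot aggregate an empty list of gene trees")
  stopifnot(all(vapply(gs, inherits, TRUE, "gene_tree")))
  all_ids <- unlist(lapply(gs, function(g) g$tree$ids), use.names = FALSE)
  rename <- anyDuplicated(all_ids) > 0L
  sep <- ""
  if (rename) {
    ## plain 0-based suffixes unless those still collide, then "_i"
    cand <- unlist(lapply(seq_along(gs), function(i) {
      paste0(gs[[i]]$tree$ids, i - 1L)
    }), use.names = FALSE)
    if (anyDuplicated(cand)) sep <- "_"
  }
  root_id <- "rho"
  nm <- function(id, i) if (rename) paste0(id, sep, i - 1L) else id
  repeat {
    taken <- if (rename) {
      unlist(lapply(seq_along(gs), function(i) nm(gs[[i]]$tree$ids, i)))
    } else all_ids
    if (!root_id %in% taken) break
    root_id <- paste0(root_id, "_")
  }
  parts_p <- vector("list", length(gs)); parts_c <- vector("list", length(gs))
  parts_ev <- vector("list", length(gs)); parts_sg <- vector("list", length(gs))
  parts_tr <- vector("list", length(gs))
  for (i in seq_along(gs)) {
    g <- gs[[i]]
    tree <- g$tree
    ids_i <- nm(tree$ids, i)
    nonroot <- which(tree$parent > 0L)
    parts_p[[i]] <- c(root_id, ids_i[tree$parent[nonroot]])
    parts_c[[i]] <- c(nm(tree_root(tree), i), ids_i[nonroot])
    int <- which(unname(g$events[tree$ids]) != "leaf")
    parts_ev[[i]] <- stats::setNames(unname(g$events[tree$ids[int]]), ids_i[int])
    sg <- g$sigma
    names(sg) <- nm(names(sg), i)
    parts_sg[[i]] <- sg
    parts_tr[[i]] <- ids_i[unname(g$transfer[tree$ids])]
  }
  edges_p <- unlist(parts_p); edges_c <- unlist(parts_c)
  events <- unlist(parts_ev); sigma <- unlist(parts_sg)
  transfer <- unlist(parts_tr, use.names = FALSE)
  events[root_id] <- "dup"
  gene_tree(rooted_tree(data.frame(parent = edges_p, child = edges_c)),
            events = events, sigma = sigma, transfer = transfer)
}
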