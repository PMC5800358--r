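## Reconciliation maps: the lca-map, the canonical (pointwise-lowest)
## reconciliation, and validation against the axioms:
##   (M1)   leaves map to the species they reside in;
##   (M2i)  speciations map to the lca of their transfer-free species set;
##   (M2ii) duplications/transfers map to species-tree edges;
##   (M2iii)the two endpoints of a transfer edge map to incomparable points;
##   (M3)   the ancestor order within transfer-free components is preserved,
##          strictly whenever a speciation or leaf is involved.

#' The lca-map of a gene tree into a species tree
#'
#' Computes, for every gene-tree vertex `u`, the species-tree vertex
#' `lca_S(sigma_TE(u))`: the most recent species that could have contained
#' the ancestral gene, given the species of the transfer-free descendant
#' leaves.  Computed bottom-up over non-transfer edges only, so the whole
#' map costs O(|V(T)| log |V(S)|).
#'
#' @param g a `gene_tree`.
#' @param s a `species_tree`; every species in `sigma` must be one of its
#'   leaves.
#' @return named character vector (class `lca_map`) from gene-tree vertex
#'   ids to species-tree vertex ids.
#' @export
lca_map <- function(g, s) {
  stopifnot(inherits(g, "gene_tree"), inherits(s, "species_tree"))
  missing_sp <- setdiff(unique(unname(g$sigma)), species_of(s))
  if (length(missing_sp)) {
    stop("species not in the species tree: ",
         paste(missing_sp, collapse = ", "))
  }
  tree <- g$tree
  n <- n_vertices(tree)
  cut <- unname(g$transfer[tree$ids])
  sig_at <- character(n)
  sig_at[tree$leaves] <- unname(g$sigma[tree$ids[tree$leaves]])
  ell <- integer(n)
  for (v in rev(tree$preorder)) {            # children before parents
    kids <- tree$children[[v]]
    if (length(kids) == 0L) {
      ell[v] <- tree_index(s, sig_at[v])
    } else {
      keep <- kids[!cut[kids]]
      if (length(keep) == 0L) {
        stop("vertex '", tree$ids[v], "' has only transfer out-edges; ",
             "the tree violates O2")
      }
      ell[v] <- lca_idx(s, ell[keep])
    }
  }
  structure(stats::setNames(s$ids[ell], tree$ids), class = "lca_map")
}

## recon_map ---------------------------------------------------------------

#' Assemble a reconciliation map object
#'
#' @param gene,kind,species parallel character vectors: the gene-tree
#'   vertex, the image kind (`"vertex"` or `"edge"`), and the species-tree
#'   vertex (for edges, the child endpoint).
#' @return a data frame of class `recon_map`.
#' @export
recon_map <- function(gene, kind, species) {
  stopifnot(length(gene) == length(kind), length(kind) == length(species),
            all(kind %in% c("vertex", "edge")))
  df <- data.frame(gene = as.character(gene), kind = as.character(kind),
                   species = as.character(species), stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene)) stop("duplicate gene vertex in map")
  class(df) <- c("recon_map", "data.frame")
  df
}

## fast lookup vectors for a recon_map
mu_lookup <- function(mu) {
  list(kind = stats::setNames(mu$kind, mu$gene),
       sp = stats::setNames(mu$species, mu$gene))
}

mu_point_of <- function(lk, u) {
  if (lk$kind[[u]] == "vertex") vertex_point(lk$sp[[u]]) else edge_point(lk$sp[[u]])
}

#' Image of a gene-tree vertex under a reconciliation map
#' @param mu a `recon_map`.
#' @param u a gene-tree vertex id.
#' @return a `tree_point` in the species tree.
#' @export
mu_point <- function(mu, u) {
  i <- match(u, mu$gene)
  if (is.na(i)) stop("vertex '", u, "' has no image in the map")
  if (mu$kind[i] == "vertex") vertex_point(mu$species[i]) else edge_point(mu$species[i])
}

#' @export
print.recon_map <- function(x, ...) {
  cat(sprintf("<recon_map on %d gene vertices>\n", nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

#' The canonical (pointwise-lowest) reconciliation map
#'
#' Maps each leaf to its species, each speciation vertex to the lca of its
#' transfer-free species set, and each duplication/transfer vertex to the
#' species-tree edge immediately above that lca.  By the lower bound
#' `mu(u) >= lca_S(sigma_TE(u))` that every reconciliation map must obey,
#' this is the lowest map permitted at every vertex.
#'
#' @param g a `gene_tree`.
#' @param s a `species_tree`.
#' @param ell optionally a precomputed [lca_map()].
#' @return a `recon_map`.
#' @export
canonical_reconciliation <- function(g, s, ell = lca_map(g, s)) {
  tree <- g$tree
  ids <- tree$ids
  ev <- unname(g$events[ids])
  kind <- ifelse(ev %in% c("dup", "hgt"), "edge", "vertex")
  sp <- unname(ell[ids])
  sp[ev == "leaf"] <- unname(g$sigma[ids[ev == "leaf"]])
  dh <- which(ev %in% c("dup", "hgt"))
  for (v in dh) {
    if (s$parent[tree_index(s, sp[v])] == 0L) {
      stop("lca-map of duplication/transfer vertex '", ids[v],
           "' is the planted species root; no parent edge exists")
    }
  }
  recon_map(ids, kind, sp)
}

#' Validate a reconciliation map
#'
#' Checks the map against (M1), (M2i)-(M2iii) and (M3), the latter along
#' the parent-child pairs of the transfer-free forest together with the
#' global lower bound `mu(u) >= lca_S(sigma_TE(u))`; order preservation
#' along component edges extends to all comparable pairs by transitivity.
#'
#' @param g a `gene_tree`.
#' @param s a `species_tree`.
#' @param mu a `recon_map`, total on the gene-tree vertices.
#' @return a list with `valid` (logical) and `violations`, a data frame
#'   with columns `condition` and `witness`.
#' @export
validate_reconciliation <- function(g, s, mu) {
  tree <- g$tree
  ids <- tree$ids
  ord <- match(ids, mu$gene)
  if (anyNA(ord)) {
    stop("map is not total; missing image for: ",
         paste(ids[is.na(ord)], collapse = ", "))
  }
  kind_v <- mu$kind[ord]           # aligned with tree ids
  sp_v <- mu$species[ord]
  bad_sp <- !vapply(sp_v, function(x) tree_has(s, x), TRUE)
  if (any(bad_sp)) {
    i <- which(bad_sp)[1L]
    stop("image '", sp_v[i], "' of '", ids[i],
         "' is not a point of the species tree")
  }
  spi <- vapply(sp_v, function(x) tree_index(s, x), 1L)
  bad_edge <- kind_v == "edge" & s$parent[spi] == 0L
  if (any(bad_edge)) {
    i <- which(bad_edge)[1L]
    stop("image of '", ids[i], "' names an edge into the root '",
         sp_v[i], "'; no such edge exists")
  }
  point_at <- function(i) {
    if (kind_v[i] == "vertex") vertex_point(sp_v[i]) else edge_point(sp_v[i])
  }
  forest <- remove_transfer_edges(g)
  cond <- list(); wit <- list()
  add <- function(co, wi) {
    k <- length(cond) + 1L
    cond[[k]] <<- co; wit[[k]] <<- wi
  }
  ev <- unname(g$events[ids])
  sig_leaf <- character(length(ids))
  sig_leaf[tree$leaves] <- unname(g$sigma[ids[tree$leaves]])
  for (i in seq_along(ids)) {
    if (ev[i] == "leaf") {
      if (kind_v[i] != "vertex" || sp_v[i] != sig_leaf[i]) add("M1", ids[i])
    } else if (ev[i] == "spe") {
      sig <- forest$sigma_sets[[i]]
      if (kind_v[i] != "vertex" || length(sig) == 0L ||
          sp_v[i] != tree_lca(s, sig)) add("M2i", ids[i])
    } else {
      if (kind_v[i] != "edge") add("M2ii", ids[i])
    }
  }
  ## M2iii: transfer endpoints incomparable
  cut <- unname(g$transfer[ids])
  for (wi in which(cut)) {
    vi <- tree$parent[wi]
    if (points_comparable(s, point_at(vi), point_at(wi))) {
      add("M2iii", paste0(ids[vi], "->", ids[wi]))
    }
  }
  ## M3 along transfer-free parent-child pairs
  for (vi in seq_along(ids)) {
    p <- tree$parent[vi]
    if (p == 0L || cut[vi]) next
    pv <- point_at(vi); pw <- point_at(p)
    if (ev[vi] %in% c("dup", "hgt") && ev[p] %in% c("dup", "hgt")) {
      if (!point_leq(s, pv, pw)) add("M3i", paste0(ids[vi], "<", ids[p]))
    } else {
      if (!point_lt(s, pv, pw)) add("M3ii", paste0(ids[vi], "<", ids[p]))
    }
  }
  ## lower bound mu(u) >= lca_S(sigma_TE(u)) (holds for every valid map)
  for (i in seq_along(ids)) {
    sig <- forest$sigma_sets[[i]]
    if (length(sig) == 0L) next                 # only possible when O2 fails
    lb <- vertex_point(tree_lca(s, sig))
    if (!point_leq(s, lb, point_at(i))) add("M3bound", ids[i])
  }
  viol <- data.frame(condition = unlist(c(cond, list(character(0)))),
                     witness = unlist(c(wit, list(character(0)))),
                     stringsAsFactors = FALSE)
  list(valid = nrow(viol) == 0L, violations = viol)
}
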