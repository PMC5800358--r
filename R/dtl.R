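## DTL-scenarios: the classical vertex-to-vertex reconciliation formalism
## for fully resolved binary gene and species trees, and its equivalence
## with the edge-image reconciliation maps used elsewhere in the package.
## The planted species root, an artifact of allowing pre-speciation
## duplications to map onto an edge, is exempt from the binary check and
## is never the image of a gene vertex.

check_binary_gene <- function(g) {
  nch <- vapply(g$tree$children, length, 1L)
  internal <- which(nch > 0L)
  if (!all(nch[internal] == 2L)) {
    stop("DTL-scenarios are defined for binary gene trees only")
  }
}

check_binary_species <- function(s) {
  nch <- vapply(s$children, length, 1L)
  internal <- setdiff(which(nch > 0L), s$root)
  if (!all(nch[internal] == 2L)) {
    stop("DTL-scenarios are defined for binary species trees only")
  }
}

#' Validate a DTL-scenario
#'
#' Checks a vertex-to-vertex map `gamma` from a binary event-labeled gene
#' tree into a binary species tree against the DTL axioms:
#' (I) leaves map to their species; (IIa) no vertex maps to a proper
#' descendant of a child image, (IIb) at least one child image is a
#' descendant of the vertex image; (III) an edge is a transfer edge
#' exactly when its endpoint images are incomparable; (IVa) a vertex is
#' an hgt event exactly when one of its out-edges is a transfer,
#' (IVb) a speciation maps to the lca of its child images, which are
#' incomparable, (IVc) a duplication maps at or above the lca of its
#' child images.
#'
#' @param g a binary `gene_tree`.
#' @param s a binary `species_tree` (planted root exempt).
#' @param gamma named character vector mapping every gene-tree vertex id
#'   to a species-tree vertex id.
#' @return list with `valid` and a `violations` data frame.
#' @export
validate_dtl <- function(g, s, gamma) {
  check_binary_gene(g)
  check_binary_species(s)
  tree <- g$tree
  ids <- tree$ids
  missing_v <- setdiff(ids, names(gamma))
  if (length(missing_v)) {
    stop("gamma is not total; missing: ", paste(missing_v, collapse = ", "))
  }
  for (u in ids) {
    if (!tree_has(s, gamma[[u]])) {
      stop("gamma('", u, "') = '", gamma[[u]], "' is not a species vertex")
    }
  }
  cond <- character(0); wit <- character(0)
  add <- function(co, wi) { cond <<- c(cond, co); wit <<- c(wit, wi) }
  gi <- function(u) tree_index(s, gamma[[u]])
  ev <- g$events
  for (u in ids) {
    kids <- tree$ids[tree$children[[tree_index(tree, u)]]]
    if (length(kids) == 0L) {
      if (gamma[[u]] != g$sigma[[u]]) add("I", u)
      next
    }
    v <- kids[1L]; w <- kids[2L]
    ## (IIa) gamma(u) not a proper descendant of a child image
    if ((anc_idx(s, gi(v), gi(u)) && gi(v) != gi(u)) ||
        (anc_idx(s, gi(w), gi(u)) && gi(w) != gi(u))) {
      add("IIa", u)
    }
    ## (IIb) at least one child image below gamma(u)
    if (!anc_idx(s, gi(u), gi(v)) && !anc_idx(s, gi(u), gi(w))) add("IIb", u)
    ## (IVa) hgt iff some out-edge is a transfer
    has_tr <- any(unname(g$transfer[kids]))
    if ((ev[[u]] == "hgt") != has_tr) add("IVa", u)
    ## (IVb)/(IVc)
    lca_vw <- s$ids[lca_idx2(s, gi(v), gi(w))]
    if (ev[[u]] == "spe") {
      comparable <- anc_idx(s, gi(v), gi(w)) || anc_idx(s, gi(w), gi(v))
      if (gamma[[u]] != lca_vw || comparable) add("IVb", u)
    } else if (ev[[u]] == "dup") {
      if (!anc_idx(s, tree_index(s, lca_vw), gi(u))) add("IVc", u)
    }
  }
  ## (III) transfer edge iff incomparable endpoint images
  for (vi in seq_along(ids)) {
    p <- tree$parent[vi]
    if (p == 0L) next
    u <- ids[p]; v <- ids[vi]
    incomp <- !(anc_idx(s, gi(u), gi(v)) || anc_idx(s, gi(v), gi(u)))
    if (incomp != unname(g$transfer[[v]])) add("III", paste0(u, "->", v))
  }
  viol <- viol_df(cond, wit)
  list(valid = nrow(viol) == 0L, violations = viol)
}

#' Project a reconciliation map to a DTL-scenario
#'
#' Vertex images are kept; an edge image `(x, y)` is replaced by its
#' child endpoint `y`.  For binary trees the result satisfies the DTL
#' axioms whenever `mu` is valid.
#'
#' @param g a binary `gene_tree`.
#' @param s a binary `species_tree`.
#' @param mu a valid `recon_map`.
#' @return named character vector `gamma`.
#' @export
mu_to_gamma <- function(g, s, mu) {
  check_binary_gene(g)
  check_binary_species(s)
  stats::setNames(mu$species, mu$gene)
}

#' Lift a DTL-scenario to a reconciliation map
#'
#' Speciations and leaves keep their vertex image; a duplication or
#' transfer vertex `u` is mapped to the edge `(parent(gamma(u)),
#' gamma(u))`.  For a valid DTL-scenario the result is a valid
#' reconciliation map, and projecting back with [mu_to_gamma()] recovers
#' `gamma`.
#'
#' @param g a binary `gene_tree`.
#' @param s a binary `species_tree`.
#' @param gamma a valid DTL-scenario (see [validate_dtl()]).
#' @return a `recon_map`.
#' @export
gamma_to_mu <- function(g, s, gamma) {
  check_binary_gene(g)
  check_binary_species(s)
  ids <- g$tree$ids
  ev <- unname(g$events[ids])
  kind <- ifelse(ev %in% c("dup", "hgt"), "edge", "vertex")
  sp <- vapply(ids, function(u) as.character(gamma[[u]]), "")
  for (i in which(kind == "edge")) {
    if (s$parent[tree_index(s, sp[i])] == 0L) {
      stop("gamma maps duplication/transfer vertex '", ids[i],
           "' to the planted root; no parent edge exists")
    }
  }
  recon_map(ids, kind, unname(sp))
}
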