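## Time-consistency of reconciliation maps.
##
## A reconciliation is time-consistent when gene-tree and species-tree
## time maps exist such that speciations/leaves are simultaneous with
## their images (C1) and duplications/transfers fall strictly inside the
## time span of their image edge (C2).  Both the check for a *given* map
## and the existence question for *some* map reduce to acyclicity of a
## directed constraint graph on V(T) u V(S):
##   (A1) gene-tree edges, with speciation/leaf endpoints replaced by
##        their species-tree images;
##   (A2) species-tree edges;
##   (A3) a duplication/transfer vertex u precedes lca_S(sigma_TE(u));
##   (A4) the joint lca of a transfer edge's species sets precedes the
##        transfer vertex;
##   (A5) a duplication/transfer vertex lies strictly between the
##        endpoints of its image edge.
## The A1-graph (rules A1, A2, A5) characterizes time-consistency of the
## given map; the A2-graph (rules A1-A4) characterizes existence of some
## time-consistent map and does not depend on where duplications and
## transfers were placed.

aux_T <- function(id) paste0("T:", id)
aux_S <- function(id) paste0("S:", id)

aux_label <- function(v) sub("^[TS]:", "", v)
aux_tree <- function(v) ifelse(startsWith(v, "T:"), "gene", "species")

#' Build the time-constraint auxiliary graph
#'
#' @param g a `gene_tree`.
#' @param s a `species_tree`.
#' @param mu a valid `recon_map` (validated unless `validate = FALSE`).
#' @param mode `"A1"` for the graph whose acyclicity is equivalent to
#'   time-consistency of `mu` itself (rules A1, A2, A5), `"A2"` for the
#'   graph deciding whether any time-consistent map exists (rules A1-A4).
#' @param validate check `mu` first and error when it is invalid.
#' @return an object of class `aux_graph`: a list with `edges` (data
#'   frame `from`, `to`, `class`, vertices namespaced `T:`/`S:`),
#'   `vertices`, and `mode`.  Edges contributed by several rules appear
#'   once per rule; self-loops are retained (a self-loop is a cycle).
#' @export
build_auxiliary_graph <- function(g, s, mu, mode = c("A2", "A1"),
                                  validate = TRUE) {
  mode <- match.arg(mode)
  if (validate) {
    rep <- validate_reconciliation(g, s, mu)
    if (!rep$valid) {
      stop("mu is not a valid reconciliation map (first violation: ",
           rep$violations$condition[1L], " at ", rep$violations$witness[1L], ")")
    }
  }
  tree <- g$tree
  ids <- tree$ids
  ev <- unname(g$events[ids])
  ord <- match(ids, mu$gene)
  sp_v <- mu$species[ord]                    # aligned with tree ids
  forest <- remove_transfer_edges(g)
  is_dh <- ev %in% c("dup", "hgt")
  merged_v <- ifelse(is_dh, aux_T(ids), aux_S(sp_v))
  ## (A1) gene edges with merged endpoints; (A2) species edges
  nonroot <- which(tree$parent > 0L)
  s_nonroot <- which(s$parent > 0L)
  from <- c(merged_v[tree$parent[nonroot]], aux_S(s$ids[s$parent[s_nonroot]]))
  to <- c(merged_v[nonroot], aux_S(s$ids[s_nonroot]))
  cls <- c(rep("A1", length(nonroot)), rep("A2", length(s_nonroot)))
  dh <- which(is_dh)
  ell_of <- function(i) tree_lca(s, forest$sigma_sets[[i]])
  if (mode == "A2") {
    ## (A3) u precedes lca_S(sigma_TE(u))
    if (length(dh)) {
      from <- c(from, aux_T(ids[dh]))
      to <- c(to, aux_S(vapply(dh, ell_of, "")))
      cls <- c(cls, rep("A3", length(dh)))
    }
    ## (A4) joint lca of a transfer edge precedes the transfer vertex
    cut <- which(unname(g$transfer[ids]))
    for (wi in cut) {
      ui <- tree$parent[wi]
      z <- tree_lca(s, c(forest$sigma_sets[[ui]], forest$sigma_sets[[wi]]))
      from <- c(from, aux_S(z)); to <- c(to, aux_T(ids[ui]))
      cls <- c(cls, "A4")
    }
  } else {
    ## (A5) u strictly inside its image edge
    if (length(dh)) {
      y <- sp_v[dh]
      x <- s$ids[s$parent[vapply(y, function(id) tree_index(s, id), 1L)]]
      from <- c(from, aux_S(x), aux_T(ids[dh]))
      to <- c(to, aux_T(ids[dh]), aux_S(y))
      cls <- c(cls, rep("A5", 2L * length(dh)))
    }
  }
  vertices <- sort(unique(c(aux_S(s$ids), aux_T(ids[dh]), from, to)))
  structure(list(edges = data.frame(from = from, to = to, class = cls,
                                    stringsAsFactors = FALSE),
                 vertices = vertices, mode = mode),
            class = "aux_graph")
}

#' @export
print.aux_graph <- function(x, ...) {
  cat(sprintf("<aux_graph (%s-mode): %d vertices, %d edges>\n",
              x$mode, length(x$vertices), nrow(unique(x$edges[1:2]))))
  invisible(x)
}

## deterministic Kahn topological sort -------------------------------------

## A binary min-heap over integers (lexicographic ranks), in closures.
int_heap <- function(capacity) {
  h <- integer(capacity)
  n <- 0L
  push <- function(x) {
    n <<- n + 1L
    h[n] <<- x
    i <- n
    while (i > 1L) {
      p <- i %/% 2L
      if (h[p] <= h[i]) break
      tmp <- h[p]; h[p] <<- h[i]; h[i] <<- tmp
      i <- p
    }
  }
  pop <- function() {
    top <- h[1L]
    h[1L] <<- h[n]
    n <<- n - 1L
    i <- 1L
    repeat {
      l <- 2L * i; r <- l + 1L
      m <- i
      if (l <= n && h[l] < h[m]) m <- l
      if (r <= n && h[r] < h[m]) m <- r
      if (m == i) break
      tmp <- h[m]; h[m] <<- h[i]; h[i] <<- tmp
      i <- m
    }
    top
  }
  list(push = push, pop = pop, size = function() n)
}

## Kahn's algorithm with lexicographic tie-breaking on vertex names.
## `first`: a vertex forced to be taken first among the initial sources.
## Returns list(order = character vector (complete iff acyclic),
##              acyclic = logical).
kahn_order <- function(vertices, edges, first = NULL) {
  vertices <- sort(vertices)
  n <- length(vertices)
  ei <- match(edges$from, vertices)
  ej <- match(edges$to, vertices)
  keep <- !duplicated(as.numeric(ei) * (n + 1) + ej)
  ei <- ei[keep]; ej <- ej[keep]
  if (any(ei == ej)) return(list(order = character(0), acyclic = FALSE))
  indeg <- tabulate(ej, nbins = n)
  adj <- split(ej, factor(ei, levels = seq_len(n)))
  heap <- int_heap(n)
  forced <- if (is.null(first)) 0L else match(first, vertices)
  for (v in which(indeg == 0L)) {
    if (!identical(v, forced)) heap$push(v)
  }
  out <- integer(n)
  k <- 0L
  if (forced > 0L) {
    if (indeg[forced] != 0L) stop("forced first vertex is not a source")
    k <- 1L
    out[1L] <- forced
    for (w in adj[[forced]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) heap$push(w)
    }
  }
  while (heap$size() > 0L) {
    v <- heap$pop()
    k <- k + 1L
    out[k] <- v
    for (w in adj[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) heap$push(w)
    }
  }
  list(order = vertices[out[seq_len(k)]], acyclic = k == n)
}

## Extract one deterministic cycle from a non-acyclic aux graph, as a data
## frame with the namespaced vertex, the bare label and which tree it
## belongs to.  Uses strongly connected components; among all cyclic SCCs
## the one containing the lexicographically smallest vertex is reported,
## walking smallest-successor-first.
extract_cycle <- function(aux) {
  ed <- unique(aux$edges[, c("from", "to")])
  gr <- igraph::graph_from_data_frame(ed, directed = TRUE,
                                      vertices = aux$vertices)
  loops <- ed$from[ed$from == ed$to]
  scc <- igraph::components(gr, mode = "strong")
  memb <- scc$membership
  cyc_comps <- which(scc$csize >= 2L)
  cand <- names(memb)[memb %in% cyc_comps]
  cand <- sort(unique(c(cand, loops)))
  if (length(cand) == 0L) stop("graph is acyclic; no cycle to extract")
  start <- cand[1L]
  if (start %in% loops) {
    path <- start
  } else {
    comp <- names(memb)[memb == memb[[start]]]
    succ <- split(ed$to, ed$from)
    path <- start
    v <- start
    repeat {
      nxt <- sort(intersect(succ[[v]], comp))
      ## within an SCC every vertex has a successor in the SCC
      v <- nxt[1L]
      if (v %in% path) {
        path <- path[seq.int(match(v, path), length(path))]
        break
      }
      path <- c(path, v)
    }
  }
  data.frame(vertex = aux_label(path), tree = aux_tree(path),
             aux = path, stringsAsFactors = FALSE)
}

## edge classes along a cycle (closing edge included)
cycle_edge_classes <- function(aux, cycle) {
  f <- cycle$aux
  t <- c(cycle$aux[-1L], cycle$aux[1L])
  vapply(seq_along(f), function(i) {
    cl <- aux$edges$class[aux$edges$from == f[i] & aux$edges$to == t[i]]
    paste(sort(unique(cl)), collapse = "+")
  }, "")
}

#' Is a given reconciliation map time-consistent?
#'
#' Equivalent to acyclicity of the A1-mode auxiliary graph.  On success a
#' deterministic topological order of the constraint graph is returned as
#' a witness; on failure one explicit cycle.
#'
#' @param g a `gene_tree`.
#' @param s a `species_tree`.
#' @param mu a valid `recon_map` (an invalid map is an error).
#' @return a list with `consistent` (logical) and either `order`
#'   (character vector) or `cycle` (data frame with columns `vertex`,
#'   `tree`, `aux`, `class`).
#' @export
is_time_consistent_map <- function(g, s, mu) {
  aux <- build_auxiliary_graph(g, s, mu, mode = "A1")
  res <- kahn_order(aux$vertices, aux$edges)
  if (res$acyclic) {
    list(consistent = TRUE, order = res$order)
  } else {
    cyc <- extract_cycle(aux)
    cyc$class <- cycle_edge_classes(aux, cyc)
    list(consistent = FALSE, cycle = cyc)
  }
}

#' Does any time-consistent reconciliation map exist?
#'
#' Equivalent to acyclicity of the A2-mode auxiliary graph built on any
#' valid anchor map: rules A1-A4 only involve the forced images of
#' speciations and leaves, so the verdict does not depend on where the
#' duplication/transfer vertices of the anchor were placed.
#'
#' @inheritParams is_time_consistent_map
#' @param mu any valid `recon_map` between `g` and `s`.
#' @return a list with `exists` (logical) and either `order` or `cycle`
#'   as in [is_time_consistent_map()].
#' @export
exists_time_consistent_map <- function(g, s, mu) {
  aux <- build_auxiliary_graph(g, s, mu, mode = "A2")
  res <- kahn_order(aux$vertices, aux$edges)
  if (res$acyclic) {
    list(exists = TRUE, order = res$order)
  } else {
    cyc <- extract_cycle(aux)
    cyc$class <- cycle_edge_classes(aux, cyc)
    list(exists = FALSE, cycle = cyc)
  }
}

#' Derive explicit time maps from an acyclic auxiliary graph
#'
#' Vertices receive their 0-based rank along a deterministic topological
#' order (planted species root first, then Kahn's algorithm with
#' lexicographic tie-breaking) as raw times; speciation and leaf vertices
#' of the gene tree inherit the value of their image (C1); finally both
#' maps are rescaled affinely so that the gene root sits at time 0 and
#' the planted species root at time -1.
#'
#' @param aux an acyclic `aux_graph` built on `mu`.
#' @param g,s,mu the trees and map the graph was built on.
#' @return an object of class `time_map_pair`: list with named numeric
#'   vectors `tau_T` (gene vertices) and `tau_S` (species vertices).
#' @export
derive_time_maps <- function(aux, g, s, mu) {
  res <- kahn_order(aux$vertices, aux$edges, first = aux_S(tree_root(s)))
  if (!res$acyclic) {
    stop("auxiliary graph is cyclic; no time maps exist")
  }
  rank_of <- function(keys) match(keys, res$order) - 1
  tau_S <- stats::setNames(rank_of(aux_S(s$ids)), s$ids)
  ids <- g$tree$ids
  ev <- unname(g$events[ids])
  sp_v <- mu$species[match(ids, mu$gene)]
  raw_T <- stats::setNames(
    rank_of(ifelse(ev %in% c("spe", "leaf"), aux_S(sp_v), aux_T(ids))), ids)
  r0 <- tau_S[[tree_root(s)]]
  r1 <- raw_T[[tree_root(g$tree)]]
  if (r1 <= r0) stop("internal error: gene root not after species root")
  rescale <- function(x) (x - r1) / (r1 - r0)
  structure(list(tau_T = rescale(raw_T), tau_S = rescale(tau_S)),
            class = "time_map_pair")
}

#' @export
print.time_map_pair <- function(x, ...) {
  cat(sprintf("<time_map_pair: %d gene times, %d species times>\n",
              length(x$tau_T), length(x$tau_S)))
  invisible(x)
}

#' Relocate duplication/transfer vertices onto time-compatible edges
#'
#' Given time maps satisfying the between-tree conditions (D1)-(D3) for
#' the anchors of `mu`, moves every duplication/transfer vertex `u` onto
#' the unique species edge `(y, z)` on the path from
#' `lca_S(sigma_TE(u))` to the planted root whose time span strictly
#' contains `tau_T(u)`.  Speciation and leaf images are unchanged.  The
#' result satisfies (C1) and (C2) with the given time maps.
#'
#' @param g a `gene_tree`.
#' @param s a `species_tree`.
#' @param mu a valid `recon_map`.
#' @param tau a `time_map_pair`.
#' @return a `recon_map`.
#' @export
relocate_map <- function(g, s, mu, tau) {
  forest <- remove_transfer_edges(g)
  ids <- g$tree$ids
  ev <- unname(g$events[ids])
  ord <- match(ids, mu$gene)
  kind <- mu$kind[ord]
  sp <- mu$species[ord]
  tauS_at <- unname(tau$tau_S[s$ids])        # aligned with s indices
  tauT_at <- unname(tau$tau_T[ids])
  for (i in which(ev %in% c("dup", "hgt"))) {
    tu <- tauT_at[i]
    z <- tree_index(s, tree_lca(s, forest$sigma_sets[[i]]))
    found <- FALSE
    while (s$parent[z] != 0L) {
      y <- s$parent[z]
      if (tauS_at[y] < tu && tu < tauS_at[z]) {
        sp[i] <- s$ids[z]
        found <- TRUE
        break
      }
      z <- y
    }
    if (!found) {
      stop("no species edge above '", s$ids[z], "' brackets the time of '",
           ids[i], "'; the supplied time maps violate (D2)/(D3)")
    }
  }
  recon_map(ids, kind, sp)
}

#' Reconcile a gene tree with a species tree, time-consistently
#'
#' The complete decision-and-construction pipeline: verify the
#' observability conditions, build the lca-map and the canonical
#' reconciliation, test existence of a time-consistent map via the
#' A2-mode auxiliary graph, and in the positive case derive time maps
#' from its topological order and relocate the duplication/transfer
#' vertices onto time-compatible edges.
#'
#' @param g a `gene_tree` expected to pass O2, Sigma1 and Sigma2.
#' @param s a `species_tree`.
#' @return an object of class `reconciliation_result` with `status` one of
#'   * `"consistent"`: fields `mu` (time-consistent `recon_map`), `tau`
#'     (a `time_map_pair`), `ell` (the [lca_map()]);
#'   * `"inconsistent"`: no time-consistent map exists; field `cycle`
#'     carries the certificate (a cycle of the A2-mode graph);
#'   * `"invalid"`: the input violates the observability conditions or
#'     admits no reconciliation map at all; fields `reason`, `violations`.
#' @export
reconcile <- function(g, s) {
  stopifnot(inherits(g, "gene_tree"), inherits(s, "species_tree"))
  fail <- function(reason, violations = NULL) {
    structure(list(status = "invalid", reason = reason,
                   violations = violations),
              class = "reconciliation_result")
  }
  if (!check_O2(g)) {
    return(fail("gene tree violates O2 (an hgt vertex lacks a transfer or a non-transfer out-edge)"))
  }
  forest <- remove_transfer_edges(g)
  s1 <- check_sigma1(g, forest)
  if (length(s1)) {
    return(fail(paste0("gene tree violates Sigma1 at: ",
                       paste(s1, collapse = ", ")),
                data.frame(condition = "Sigma1", witness = s1)))
  }
  s2 <- check_sigma2(g, forest)
  if (nrow(s2)) {
    return(fail(paste0("gene tree violates Sigma2 at transfer edge(s): ",
                       paste(paste0(s2$from, "->", s2$to), collapse = ", ")),
                data.frame(condition = "Sigma2",
                           witness = paste0(s2$from, "->", s2$to))))
  }
  ell <- lca_map(g, s)
  mu0 <- canonical_reconciliation(g, s, ell)
  rep <- validate_reconciliation(g, s, mu0)
  if (!rep$valid) {
    return(fail("no valid reconciliation map exists (canonical map violates the axioms)",
                rep$violations))
  }
  aux <- build_auxiliary_graph(g, s, mu0, mode = "A2", validate = FALSE)
  dec <- kahn_order(aux$vertices, aux$edges)
  if (!dec$acyclic) {
    cyc <- extract_cycle(aux)
    cyc$class <- cycle_edge_classes(aux, cyc)
    return(structure(list(status = "inconsistent",
                          reason = "No time-consistent reconciliation map exists",
                          cycle = cyc, mu = mu0, ell = ell),
                     class = "reconciliation_result"))
  }
  tau <- derive_time_maps(aux, g, s, mu0)
  mu <- relocate_map(g, s, mu0, tau)
  structure(list(status = "consistent", mu = mu, tau = tau, ell = ell),
            class = "reconciliation_result")
}

#' @export
print.reconciliation_result <- function(x, ...) {
  cat(sprintf("<reconciliation_result: %s>\n", x$status))
  if (x$status == "inconsistent") {
    cat("  cycle:", paste(x$cycle$vertex, collapse = " -> "), "\n")
  } else if (x$status == "invalid") {
    cat(" ", x$reason, "\n")
  }
  invisible(x)
}
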