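## Validators for the three equivalent systems of timing conditions:
## (C1)-(C2) on a pair of time maps and a reconciliation, (D1)-(D3)
## relating a species time map to the gene tree, and (T1)-(T3) expressed
## on the gene-tree time map alone.

viol_df <- function(cond, wit) {
  data.frame(condition = cond, witness = wit, stringsAsFactors = FALSE)
}

## strict time-map property: x strictly below y  =>  tau(x) > tau(y)
timemap_violations <- function(tree, tau, label) {
  cond <- character(0); wit <- character(0)
  for (vi in seq_along(tree$ids)) {
    p <- tree$parent[vi]
    if (p == 0L) next
    if (!(tau[[tree$ids[vi]]] > tau[[tree$ids[p]]])) {
      cond <- c(cond, label)
      wit <- c(wit, paste0(tree$ids[p], "->", tree$ids[vi]))
    }
  }
  viol_df(cond, wit)
}

#' Check the defining conditions (C1)-(C2) of time-consistency
#'
#' (C1): speciations and leaves are simultaneous with their species-tree
#' images.  (C2): a duplication/transfer vertex mapped to the edge
#' `(x, y)` has its time strictly between the times of `x` and `y`.
#' Both time maps are also checked to be strictly order-reversing on
#' their trees.
#'
#' @param g a `gene_tree`.
#' @param s a `species_tree`.
#' @param mu a `recon_map`.
#' @param tau a `time_map_pair`.
#' @return list with `valid` and a `violations` data frame.
#' @export
check_C <- function(g, s, mu, tau) {
  lk <- mu_lookup(mu)
  out <- rbind(timemap_violations(g$tree, tau$tau_T, "tauT"),
               timemap_violations(s, tau$tau_S, "tauS"))
  for (u in g$tree$ids) {
    if (g$events[[u]] %in% c("spe", "leaf")) {
      if (tau$tau_T[[u]] != tau$tau_S[[lk$sp[[u]]]]) {
        out <- rbind(out, viol_df("C1", u))
      }
    } else {
      if (lk$kind[[u]] != "edge") {
        out <- rbind(out, viol_df("C2", u))
      } else {
        y <- lk$sp[[u]]
        x <- tree_parent(s, y)
        if (!(tau$tau_S[[x]] < tau$tau_T[[u]] && tau$tau_T[[u]] < tau$tau_S[[y]])) {
          out <- rbind(out, viol_df("C2", u))
        }
      }
    }
  }
  list(valid = nrow(out) == 0L, violations = out)
}

#' Check the species-time conditions (D1)-(D3)
#'
#' (D1): a gene vertex mapped onto a species vertex is simultaneous with
#' it.  (D2): every species vertex at or below `lca_S(sigma_TE(u))` of a
#' duplication/transfer vertex `u` is strictly younger than `u`.  (D3):
#' every species vertex at or above the joint lca of a transfer edge's
#' species sets is strictly older than the transfer vertex.
#'
#' @inheritParams check_C
#' @return list with `valid` and a `violations` data frame.
#' @export
check_D <- function(g, s, mu, tau) {
  lk <- mu_lookup(mu)
  forest <- remove_transfer_edges(g)
  out <- viol_df(character(0), character(0))
  ids <- g$tree$ids
  for (u in ids) {
    if (lk$kind[[u]] == "vertex" &&
        tau$tau_T[[u]] != tau$tau_S[[lk$sp[[u]]]]) {
      out <- rbind(out, viol_df("D1", u))
    }
  }
  for (u in ids[unname(g$events[ids]) %in% c("dup", "hgt")]) {
    top <- tree_lca(s, sigma_TE(forest, u))
    for (x in s$ids) {
      if (is_ancestor(s, top, x) && !(tau$tau_S[[x]] > tau$tau_T[[u]])) {
        out <- rbind(out, viol_df("D2", paste0(u, "|", x)))
      }
    }
  }
  for (w in ids[unname(g$transfer[ids])]) {
    u <- tree_parent(g$tree, w)
    z <- tree_lca(s, c(sigma_TE(forest, u), sigma_TE(forest, w)))
    for (x in s$ids) {
      if (is_ancestor(s, x, z) && !(tau$tau_T[[u]] > tau$tau_S[[x]])) {
        out <- rbind(out, viol_df("D3", paste0(u, "|", x)))
      }
    }
  }
  list(valid = nrow(out) == 0L, violations = out)
}

#' Check the gene-tree-only timing conditions (T1)-(T3)
#'
#' A time map on the gene tree alone certifies time-consistency when:
#' (T1a) speciations/leaves with equal images are simultaneous and (T1b)
#' those with strictly ordered images are ordered oppositely in time;
#' (T2) a speciation/leaf whose image is at or below
#' `lca_S(sigma_TE(v))` of a duplication/transfer `v` is strictly younger
#' than `v`; (T3) a transfer vertex `u` is strictly older than any vertex
#' `w` whose `lca_S(sigma_TE(w))` is at or above the joint lca of the
#' transfer edge.
#'
#' @inheritParams check_C
#' @param tau_T named numeric vector of gene-vertex times (a
#'   `time_map_pair` is also accepted).
#' @return list with `valid` and a `violations` data frame.
#' @export
check_T <- function(g, s, mu, tau_T) {
  if (inherits(tau_T, "time_map_pair")) tau_T <- tau_T$tau_T
  lk <- mu_lookup(mu)
  forest <- remove_transfer_edges(g)
  ids <- g$tree$ids
  ev <- unname(g$events[ids])
  out <- rbind(timemap_violations(g$tree, tau_T, "tauT"))
  sl <- ids[ev %in% c("spe", "leaf")]
  dh <- ids[ev %in% c("dup", "hgt")]
  ell <- lca_map(g, s)
  for (u in sl) {
    pu <- vertex_point(lk$sp[[u]])
    for (v in sl) {
      pv <- vertex_point(lk$sp[[v]])
      if (point_equal(pu, pv)) {
        if (tau_T[[u]] != tau_T[[v]]) out <- rbind(out, viol_df("T1a", paste0(u, "|", v)))
      } else if (point_lt(s, pu, pv)) {
        if (!(tau_T[[u]] > tau_T[[v]])) out <- rbind(out, viol_df("T1b", paste0(u, "|", v)))
      }
    }
    for (v in dh) {
      if (point_leq(s, pu, vertex_point(ell[[v]])) &&
          !(tau_T[[u]] > tau_T[[v]])) {
        out <- rbind(out, viol_df("T2", paste0(u, "|", v)))
      }
    }
  }
  for (w2 in ids[unname(g$transfer[ids])]) {
    u <- tree_parent(g$tree, w2)
    z <- tree_lca(s, c(sigma_TE(forest, u), sigma_TE(forest, w2)))
    for (w in ids) {
      if (is_ancestor(s, ell[[w]], z) && !(tau_T[[u]] > tau_T[[w]])) {
        out <- rbind(out, viol_df("T3", paste0(u, "|", w)))
      }
    }
  }
  list(valid = nrow(out) == 0L, violations = out)
}
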