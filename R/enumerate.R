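## Systematic enumeration of small observable instances, deduplicated up
## to isomorphism (jointly: relabeling of genes, of internal vertices,
## and any permutation of the species set applied to both trees).  Used
## as the exhaustive test bed for the theorem suites.

## unlabeled rooted binary shapes with n leaves, as nested lists
## (a leaf is the symbol "L")
binary_shapes <- function(n, memo = new.env()) {
  key <- as.character(n)
  got <- get0(key, envir = memo, inherits = FALSE)
  if (!is.null(got)) return(got)
  out <- if (n == 1L) list("L") else {
    acc <- list()
    for (i in seq_len(n %/% 2L)) {
      left <- binary_shapes(i, memo)
      right <- binary_shapes(n - i, memo)
      for (a in seq_along(left)) {
        bs <- if (2L * i == n) a:length(right) else seq_along(right)
        for (b in bs) acc[[length(acc) + 1L]] <- list(left[[a]], right[[b]])
      }
    }
    acc
  }
  assign(key, out, envir = memo)
  out
}

## all labeled rooted binary topologies over a character leaf set
labeled_topologies <- function(leaves) {
  if (length(leaves) == 1L) return(list(leaves))
  rest <- leaves[-1L]
  acc <- list()
  for (k in 0:(length(rest) - 1L)) {
    for (pick in if (k == 0L) list(character(0)) else utils::combn(rest, k, simplify = FALSE)) {
      left_set <- c(leaves[1L], pick)
      right_set <- setdiff(leaves, left_set)
      for (lt in labeled_topologies(left_set)) {
        for (rt in labeled_topologies(right_set)) {
          acc[[length(acc) + 1L]] <- list(lt, rt)
        }
      }
    }
  }
  acc
}

## flatten a nested shape into parent/child integer vectors; returns
## list(parent, nleaf, leaf_order): vertices numbered in preorder,
## leaves identified by the order they appear left-to-right
shape_to_parent <- function(shape) {
  parent <- integer(0)
  is_leaf <- logical(0)
  rec <- function(node, par) {
    v <- length(parent) + 1L
    parent[v] <<- par
    is_leaf[v] <<- !is.list(node)
    if (is.list(node)) for (ch in node) rec(ch, v)
  }
  rec(shape, 0L)
  list(parent = parent, is_leaf = is_leaf)
}

## species tree object from a nested labeled topology
topology_to_species <- function(topo) {
  sp <- shape_to_parent(topo)
  labs <- unlist(topo)
  ids <- character(length(sp$parent))
  ids[sp$is_leaf] <- labs
  ids[!sp$is_leaf] <- paste0("x", seq_len(sum(!sp$is_leaf)))
  augment_species_root(new_rooted_tree(ids, sp$parent))
}

## canonical serialization of a gene tree under a species relabeling map
canon_gene <- function(parent, is_leaf, ev, sig, trflag, relab) {
  kids <- split(seq_along(parent), factor(parent, levels = 0:length(parent)))
  rec <- function(v) {
    pre <- if (trflag[v]) "t!" else ""
    if (is_leaf[v]) return(paste0(pre, "L", relab[[sig[[v]]]]))
    parts <- sort(vapply(kids[[as.character(v)]], rec, ""))
    paste0(pre, ev[[v]], "(", paste(parts, collapse = ","), ")")
  }
  rec(kids[["0"]])
}

canon_species_topo <- function(topo, relab) {
  rec <- function(node) {
    if (!is.list(node)) return(relab[[node]])
    paste0("(", paste(sort(vapply(node, rec, "")), collapse = ","), ")")
  }
  rec(topo)
}

all_perms <- function(x) {
  if (length(x) <= 1L) return(list(x))
  acc <- list()
  for (i in seq_along(x)) {
    for (p in all_perms(x[-i])) acc[[length(acc) + 1L]] <- c(x[i], p)
  }
  acc
}

#' Enumerate all small observable instances
#'
#' Systematically generates every pair of a binary event-labeled gene
#' tree and a binary species tree within the given limits that passes
#' O1, O2, Sigma1 and Sigma2, with sigma surjective onto the species
#' set, deduplicated up to isomorphism (including species relabeling)
#' and returned in a deterministic order.
#'
#' @param max_gene_leaves at most 6.
#' @param max_species at most 4.
#' @param max_transfers at most 2.
#' @return list of instances, each a list with `gene` and `species`.
#' @export
enumerate_small_instances <- function(max_gene_leaves = 4L, max_species = 3L,
                                      max_transfers = 2L) {
  if (max_gene_leaves > 6L || max_species > 4L || max_transfers > 2L) {
    stop("limits too large: at most 6 gene leaves, 4 species, 2 transfers")
  }
  if (max_gene_leaves < 2L || max_species < 1L) {
    stop("need at least 2 gene leaves and 1 species")
  }
  seen <- new.env(parent = emptyenv())
  keys <- character(0)
  out <- list()
  shape_memo <- new.env()
  for (k in seq_len(max_species)) {
    sp_labels <- LETTERS[seq_len(k)]
    perms <- all_perms(sp_labels)
    topos <- if (k == 1L) list(sp_labels) else labeled_topologies(sp_labels)
    species_objs <- lapply(topos, topology_to_species)
    for (n in 2:max_gene_leaves) {
      if (n < k) next                      # sigma cannot be surjective
      for (shape in binary_shapes(n, shape_memo)) {
        sp <- shape_to_parent(shape)
        parent <- sp$parent
        is_leaf <- sp$is_leaf
        leaves <- which(is_leaf)
        internal <- which(!is_leaf)
        kids <- split(seq_along(parent), factor(parent, levels = 0:length(parent)))
        sig_grid <- as.matrix(expand.grid(rep(list(sp_labels), n),
                                          stringsAsFactors = FALSE))
        keep_s <- apply(sig_grid, 1L, function(r) length(unique(r)) == k)
        sig_grid <- sig_grid[keep_s, , drop = FALSE]
        ev_grid <- as.matrix(expand.grid(rep(list(c("spe", "dup", "hgt")),
                                             length(internal)),
                                         stringsAsFactors = FALSE))
        keep_e <- apply(ev_grid, 1L, function(r) sum(r == "hgt") <= max_transfers)
        ev_grid <- ev_grid[keep_e, , drop = FALSE]
        for (si in seq_len(nrow(sig_grid))) {
          sig <- character(length(parent))
          sig[leaves] <- sig_grid[si, ]
          for (ei in seq_len(nrow(ev_grid))) {
            ev <- character(length(parent))
            ev[internal] <- ev_grid[ei, ]
            ev[leaves] <- "leaf"
            hgts <- internal[ev[internal] == "hgt"]
            ## one of the two out-edges of each hgt vertex is the transfer
            flag_opts <- expand.grid(rep(list(1:2), length(hgts)))
            if (length(hgts) == 0L) flag_opts <- data.frame(x = 1)[, 0, drop = FALSE]
            for (fi in seq_len(max(1L, nrow(flag_opts)))) {
              trflag <- logical(length(parent))
              for (j in seq_along(hgts)) {
                trflag[kids[[as.character(hgts[j])]][flag_opts[fi, j]]] <- TRUE
              }
              inst <- build_enum_instance(parent, is_leaf, ev, sig, trflag)
              if (is.null(inst)) next
              for (spi in seq_along(topos)) {
                g <- inst
                s <- species_objs[[spi]]
                if (!enum_passes(g, s)) next
                key <- min(vapply(perms, function(p) {
                  relab <- stats::setNames(p, sp_labels)
                  paste0(canon_gene(parent, is_leaf, ev, sig, trflag, relab),
                         "||", canon_species_topo(topos[[spi]], relab))
                }, ""))
                if (is.null(get0(key, envir = seen, inherits = FALSE))) {
                  assign(key, TRUE, envir = seen)
                  keys <- c(keys, key)
                  out[[length(out) + 1L]] <- list(gene = g, species = s)
                }
              }
            }
          }
        }
      }
    }
  }
  out[order(keys)]
}

## build the gene_tree object for one enumerated labeling, or NULL if it
## is structurally inadmissible (O2 by construction always holds here)
build_enum_instance <- function(parent, is_leaf, ev, sig, trflag) {
  ids <- character(length(parent))
  ids[is_leaf] <- paste0("g", seq_len(sum(is_leaf)))
  ids[!is_leaf] <- paste0("i", seq_len(sum(!is_leaf)))
  tree <- new_rooted_tree(ids, parent)
  events <- stats::setNames(ev[!is_leaf], ids[!is_leaf])
  sigma <- stats::setNames(sig[is_leaf], ids[is_leaf])
  gene_tree(tree, events = events, sigma = sigma,
            transfer = ids[trflag])
}

## observability filter for enumerated instances (O1 is automatic for
## binary trees; O2 holds by construction of the transfer flags)
enum_passes <- function(g, s) {
  forest <- remove_transfer_edges(g)
  length(check_sigma1(g, forest)) == 0L && nrow(check_sigma2(g, forest)) == 0L
}
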