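## Independent brute-force oracles.  These deliberately avoid the
## package's production code paths (binary lifting, auxiliary graphs,
## Kahn's algorithm): LCA by explicit root paths, time-consistency by
## exhaustive search over rank assignments, existence by enumerating all
## candidate reconciliation maps.

## path from the root to a vertex, as ids
root_path <- function(tree, id) {
  v <- tree_index(tree, id)
  path <- character(0)
  while (v != 0L) {
    path <- c(tree$ids[v], path)
    v <- tree$parent[v]
  }
  path
}

## naive LCA: deepest common element of root paths
naive_lca <- function(tree, nodes) {
  paths <- lapply(nodes, function(x) root_path(tree, x))
  common <- Reduce(intersect, paths)
  common[length(common)]
}

## naive ancestor test on vertices
naive_anc <- function(tree, a, b) a %in% root_path(tree, b)

## naive transfer-free component leaf sets: delete transfer edges, then
## collect descendants reachable without crossing a deleted edge
naive_sigma_TE <- function(g, u) {
  tree <- g$tree
  acc <- character(0)
  walk <- function(id) {
    kids <- tree_children(tree, id)
    if (length(kids) == 0L) {
      acc <<- c(acc, g$sigma[[id]])
      return()
    }
    for (k in kids) if (!g$transfer[[k]]) walk(k)
  }
  walk(u)
  sort(unique(acc))
}

naive_lca_map <- function(g, s) {
  vapply(g$tree$ids, function(u) {
    sig <- naive_sigma_TE(g, u)
    naive_lca(s, sig)
  }, "")
}

## all candidate reconciliation maps: speciation/leaf images forced,
## duplication/transfer vertices ranging over the edges on the path from
## lca_S(sigma_TE(u)) to the planted root (any other image violates the
## lower bound of every valid map); filtered by validate_reconciliation
enumerate_valid_maps <- function(g, s) {
  ids <- g$tree$ids
  ev <- g$events
  forced <- list()
  choices <- list()
  for (u in ids) {
    if (ev[[u]] == "leaf") {
      forced[[u]] <- list(kind = "vertex", sp = g$sigma[[u]])
    } else if (ev[[u]] == "spe") {
      forced[[u]] <- list(kind = "vertex", sp = naive_lca(s, naive_sigma_TE(g, u)))
    } else {
      ell_u <- naive_lca(s, naive_sigma_TE(g, u))
      path <- root_path(s, ell_u)          # RHO ... ell_u
      choices[[u]] <- path[-1L]            # child endpoints of path edges
    }
  }
  dh <- names(choices)
  combos <- if (length(dh) == 0L) list(integer(0)) else {
    do.call(expand.grid, c(lapply(choices, seq_along), stringsAsFactors = FALSE))
  }
  out <- list()
  nc <- if (is.data.frame(combos)) nrow(combos) else 1L
  for (i in seq_len(nc)) {
    kind <- character(length(ids)); sp <- character(length(ids))
    for (j in seq_along(ids)) {
      u <- ids[j]
      if (!is.null(forced[[u]])) {
        kind[j] <- forced[[u]]$kind; sp[j] <- forced[[u]]$sp
      } else {
        kind[j] <- "edge"
        sp[j] <- choices[[u]][combos[i, u]]
      }
    }
    mu <- recon_map(ids, kind, sp)
    if (validate_reconciliation(g, s, mu)$valid) out[[length(out) + 1L]] <- mu
  }
  out
}

## exhaustive rank-assignment oracle for time-consistency of a given map:
## merge speciation/leaf vertices with their images, then search for a
## strict total order of the merged vertex set satisfying the timing
## constraints implied directly by the definitions (time maps on both
## trees, simultaneity C1 via merging, betweenness C2).  Exhaustive
## depth-first search over placements with memoization on the placed set.
oracle_time_consistent <- function(g, s, mu) {
  lk <- list(kind = stats::setNames(mu$kind, mu$gene),
             sp = stats::setNames(mu$species, mu$gene))
  merged <- function(u) {
    if (g$events[[u]] %in% c("spe", "leaf")) paste0("S:", lk$sp[[u]])
    else paste0("T:", u)
  }
  elems <- c(paste0("S:", s$ids),
             paste0("T:", g$tree$ids[g$events[g$tree$ids] %in% c("dup", "hgt")]))
  elems <- sort(unique(elems))
  before <- list()   # pairs: a must precede b
  add <- function(a, b) before[[length(before) + 1L]] <<- c(a, b)
  for (xi in seq_along(s$ids)) {
    p <- s$parent[xi]
    if (p > 0L) add(paste0("S:", s$ids[p]), paste0("S:", s$ids[xi]))
  }
  tree <- g$tree
  for (vi in seq_along(tree$ids)) {
    p <- tree$parent[vi]
    if (p > 0L) add(merged(tree$ids[p]), merged(tree$ids[vi]))
  }
  for (u in tree$ids) {
    if (g$events[[u]] %in% c("dup", "hgt")) {
      y <- lk$sp[[u]]
      x <- tree_parent(s, y)
      add(paste0("S:", x), paste0("T:", u))
      add(paste0("T:", u), paste0("S:", y))
    }
  }
  if (any(vapply(before, function(p) p[1L] == p[2L], TRUE))) return(FALSE)
  n <- length(elems)
  pred <- lapply(elems, function(e) {
    unique(vapply(Filter(function(p) p[2L] == e, before), `[[`, "", 1L))
  })
  names(pred) <- elems
  failed <- new.env(parent = emptyenv())
  search <- function(placed) {
    if (all(placed)) return(TRUE)
    key <- paste0("k", paste(which(placed), collapse = ","))
    if (!is.null(get0(key, envir = failed, inherits = FALSE))) return(FALSE)
    for (i in which(!placed)) {
      ps <- pred[[elems[i]]]
      if (all(ps %in% elems[placed])) {
        placed[i] <- TRUE
        if (search(placed)) return(TRUE)
        placed[i] <- FALSE
      }
    }
    assign(key, TRUE, envir = failed)
    FALSE
  }
  search(rep(FALSE, n))
}

## brute-force existence of a time-consistent reconciliation
oracle_exists_tc <- function(g, s) {
  for (mu in enumerate_valid_maps(g, s)) {
    if (oracle_time_consistent(g, s, mu)) return(TRUE)
  }
  FALSE
}

## brute-force existence of a valid DTL-scenario (binary instances):
## enumerate all maps of the internal vertices into V(S) minus the
## planted root, leaves forced by condition (I)
oracle_exists_dtl <- function(g, s) {
  ids <- g$tree$ids
  internal <- ids[g$events[ids] != "leaf"]
  targets <- setdiff(s$ids, tree_root(s))
  gamma <- stats::setNames(character(length(ids)), ids)
  for (lf in genes_of(g)) gamma[lf] <- g$sigma[[lf]]
  if (length(internal) == 0L) {
    return(validate_dtl(g, s, gamma)$valid)
  }
  combos <- do.call(expand.grid,
                    c(rep(list(targets), length(internal)),
                      stringsAsFactors = FALSE))
  for (i in seq_len(nrow(combos))) {
    gamma[internal] <- unlist(combos[i, ])
    if (validate_dtl(g, s, gamma)$valid) return(TRUE)
  }
  FALSE
}

## random rooted binary tree on n leaves (ids g1..gn, internal i1..)
random_rooted_tree <- function(n_leaves) {
  stopifnot(n_leaves >= 2L)
  edges_p <- character(0); edges_c <- character(0)
  ## grow by splitting a random pendant slot
  slots <- "i1"
  next_int <- 2L
  repeat {
    if (length(slots) == n_leaves) break
    pick <- sample(seq_along(slots), 1L)
    v <- slots[pick]
    for (j in 1:2) {
      ch <- paste0("tmp", next_int, "_", j)
      edges_p <- c(edges_p, v); edges_c <- c(edges_c, ch)
      slots <- c(slots, ch)
    }
    next_int <- next_int + 1L
    slots <- slots[-pick]
  }
  ## rename: slots become leaves, others internal
  all_ids <- unique(c(edges_p, edges_c, "i1"))
  internal <- setdiff(all_ids, slots)
  map <- c(stats::setNames(paste0("g", seq_along(slots)), slots),
           stats::setNames(paste0("i", seq_along(internal)), internal))
  if (length(edges_p) == 0L) return(singleton_tree("g1"))
  rooted_tree(data.frame(parent = map[edges_p], child = map[edges_c]))
}

## simulator instances for property suites, with a deterministic seed
sim_instances <- function(n, seed, cfg_args = list()) {
  out <- vector("list", n)
  for (i in seq_len(n)) {
    args <- utils::modifyList(list(seed = seed + i, max_genes = 24L,
                                   n_species = 5L), cfg_args)
    out[[i]] <- simulate_scenario(do.call(scenario_config, args))
  }
  out
}

## structural JSON-schema check used by the CLI tests
matches_report_schema <- function(report, schema) {
  req <- unlist(schema$required)
  if (!all(req %in% names(report))) return(FALSE)
  if (!report$command %in% unlist(schema$properties$command$enum)) return(FALSE)
  if (!report$exit_code %in% unlist(schema$properties$exit_code$enum)) return(FALSE)
  is.character(report$status)
}
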