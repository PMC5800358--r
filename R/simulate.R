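## Forward simulation of gene-family evolution along a dated species
## tree, followed by observability pruning.  The simulator produces
## event-labeled gene trees that satisfy the observability conditions by
## construction -- every emitted event leaves surviving descendants in at
## least two subtrees, every transfer keeps survivors on both the donor
## and the recipient side, and transfer recipients are restricted to
## lineages incomparable to the donor at the moment of transfer -- along
## with the true reconciliation map and the true event times.

#' Simulation settings for gene-family scenarios
#'
#' Rates are dimensionless probabilities per traversal of a species-tree
#' edge by a gene lineage: on entering an edge a lineage undergoes at
#' most one of duplication, transfer or loss (children restart the draw,
#' so several events per edge are possible).
#'
#' @param n_species number of extant species.
#' @param duplication,transfer,loss per-edge-traversal event
#'   probabilities; their sum must be at most 1.
#' @param seed integer seed driving all randomness of
#'   [simulate_scenario()]; `NULL` leaves the RNG state alone.
#' @param max_genes cap on the number of gene-tree nodes; once reached,
#'   no further duplications or transfers occur.
#' @return a list of class `scenario_config`.
#' @export
scenario_config <- function(n_species = 6, duplication = 0.2, transfer = 0.2,
                            loss = 0.1, seed = NULL, max_genes = 64) {
  rates <- c(duplication = duplication, transfer = transfer, loss = loss)
  if (any(rates < 0) || any(rates > 1) || sum(rates) > 1) {
    stop("duplication, transfer and loss must lie in [0,1] and sum to at most 1")
  }
  if (n_species < 1) stop("need at least one species")
  structure(list(n_species = as.integer(n_species),
                 duplication = duplication, transfer = transfer, loss = loss,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 max_genes = as.integer(max_genes)),
            class = "scenario_config")
}

#' Sample a dated species tree
#'
#' Uniform ranked topology: starting from the crown, at each step a
#' uniformly chosen extant lineage splits; the i-th split happens at time
#' i/n, all leaves are contemporary at time 1, and the planted root sits
#' at time -1.
#'
#' @param n_species number of leaves.
#' @return list with `tree` (a `species_tree`) and `times` (named
#'   numeric vector over its vertices).
#' @export
sample_species_tree <- function(n_species) {
  n <- as.integer(n_species)
  leaf_name <- function(i) {
    if (n <= 26L) LETTERS[i] else sprintf("S%03d", i)
  }
  if (n == 1L) {
    s <- augment_species_root(singleton_tree(leaf_name(1L)))
    times <- stats::setNames(c(-1, 1), c(tree_root(s), leaf_name(1L)))
    return(list(tree = s, times = times))
  }
  ## placeholder nodes; a split turns a placeholder into an internal vertex
  parent <- integer(1); time <- NA_real_
  active <- 1L
  nnode <- 1L
  for (i in seq_len(n - 1L)) {
    v <- if (length(active) == 1L) active else active[sample.int(length(active), 1L)]
    time[v] <- (i - 1) / n
    for (j in 1:2) {
      nnode <- nnode + 1L
      parent[nnode] <- v
      time[nnode] <- NA_real_
      active <- c(active, nnode)
    }
    active <- setdiff(active, v)
  }
  time[active] <- 1
  ids <- character(nnode)
  ids[active] <- leaf_name(seq_along(active))
  internal <- setdiff(seq_len(nnode), active)
  ids[internal] <- paste0("X", seq_along(internal))
  raw <- new_rooted_tree(ids, parent)
  s <- augment_species_root(raw)
  times <- stats::setNames(time[match(s$ids, ids)], s$ids)
  times[tree_root(s)] <- -1
  list(tree = s, times = times)
}

#' A dated, perfectly balanced species tree
#'
#' @param n_leaves a power of two.
#' @return list with `tree` and `times` as in [sample_species_tree()].
#' @export
balanced_species_tree <- function(n_leaves) {
  d <- log2(n_leaves)
  if (d != round(d)) stop("n_leaves must be a power of two")
  d <- as.integer(d)
  parent_id <- character(0); child_id <- character(0)
  times <- c()
  build <- function(id, depth) {
    if (depth == d) {
      times[id] <<- 1
      return()
    }
    times[id] <<- depth / (d + 1)
    for (side in c("0", "1")) {
      ch <- paste0(id, side)
      parent_id <<- c(parent_id, id); child_id <<- c(child_id, ch)
      build(ch, depth + 1L)
    }
  }
  build("I", 0L)
  raw <- if (d == 0L) singleton_tree("I") else {
    rooted_tree(data.frame(parent = parent_id, child = child_id))
  }
  s <- augment_species_root(raw)
  times[tree_root(s)] <- -1
  list(tree = s, times = times[s$ids])
}

#' Simulate an observable gene-family scenario
#'
#' Evolves a single gene lineage forward along a dated species tree:
#' speciations copy the gene into every daughter species; along edges,
#' duplication, transfer and loss strike with the configured per-edge
#' probabilities, transfers landing on a uniformly chosen species edge
#' that overlaps the event time and is incomparable to the donor edge.
#' Extinct lineages are pruned, unary vertices suppressed, and scenarios
#' in which a transfer's donor-side lineage left no survivors are
#' rejected and resampled, so the observable tree always satisfies
#' O1/O2/Sigma1/Sigma2 and the true reconciliation map is valid and
#' time-consistent.
#'
#' @param cfg a [scenario_config()].
#' @param timed_species optionally a fixed dated species tree, a list
#'   with `tree` and `times` (see [sample_species_tree()]); when `NULL`
#'   one is sampled per attempt.
#' @param retries maximum number of attempts before giving up.
#' @return list of class `scenario` with components `gene` (observable
#'   `gene_tree`), `species` (`species_tree`), `mu` (true `recon_map`),
#'   `tau` (true `time_map_pair`, rescaled to the standard anchors) and
#'   `history` (data frame of all true nodes, including losses).
#' @export
simulate_scenario <- function(cfg, timed_species = NULL, retries = 100L) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  for (att in seq_len(retries)) {
    ts <- if (is.null(timed_species)) sample_species_tree(cfg$n_species)
          else timed_species
    out <- sim_once(cfg, ts$tree, ts$times)
    if (!is.null(out)) return(out)
  }
  stop("no observable scenario in ", retries,
       " attempts (all lineages lost or every transfer hidden); ",
       "lower the loss rate")
}

sim_once <- function(cfg, s, st) {
  p_ev <- cfg$duplication + cfg$transfer + cfg$loss
  ## node store
  type <- character(0); kind <- character(0); species <- character(0)
  time <- numeric(0); parent <- integer(0); trf <- logical(0)
  new_node <- function(ty, ki, sp, tm, pa, tr) {
    type <<- c(type, ty); kind <<- c(kind, ki); species <<- c(species, sp)
    time <<- c(time, tm); parent <<- c(parent, pa); trf <<- c(trf, tr)
    length(type)
  }
  crown <- tree_children(s, tree_root(s))[1L]
  ## lineage stack: list of (edge child endpoint, current time, parent node, transfer flag)
  stack <- list(list(z = crown, t0 = st[[tree_root(s)]], par = 0L, tr = FALSE))
  while (length(stack)) {
    ln <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    z <- ln$z
    tz <- st[[z]]
    capped <- length(type) >= cfg$max_genes
    if (!capped && p_ev > 0 && stats::runif(1) < p_ev) {
      te <- stats::runif(1, ln$t0, tz)
      ty <- sample(c("dup", "hgt", "loss"), 1L,
                   prob = c(cfg$duplication, cfg$transfer, cfg$loss))
      if (ty == "loss") {
        new_node("loss", "edge", z, te, ln$par, ln$tr)
        next
      }
      if (ty == "dup") {
        u <- new_node("dup", "edge", z, te, ln$par, ln$tr)
        stack[[length(stack) + 1L]] <- list(z = z, t0 = te, par = u, tr = FALSE)
        stack[[length(stack) + 1L]] <- list(z = z, t0 = te, par = u, tr = FALSE)
        next
      }
      ## transfer: recipient edges overlapping te, incomparable to z
      zi <- tree_index(s, z)
      cand <- character(0)
      for (y in s$ids) {
        yi <- tree_index(s, y)
        p <- s$parent[yi]
        if (p == 0L) next
        if (!(st[[s$ids[p]]] < te && te < st[[y]])) next
        if (anc_idx(s, yi, zi) || anc_idx(s, zi, yi)) next
        cand <- c(cand, y)
      }
      if (length(cand) == 0L) {
        ## no co-existing incomparable lineage (e.g. on the planted edge):
        ## the transfer cannot happen observably; lineage continues
        stack[[length(stack) + 1L]] <- list(z = z, t0 = te, par = ln$par, tr = ln$tr)
        next
      }
      y <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
      u <- new_node("hgt", "edge", z, te, ln$par, ln$tr)
      stack[[length(stack) + 1L]] <- list(z = z, t0 = te, par = u, tr = FALSE)
      stack[[length(stack) + 1L]] <- list(z = y, t0 = te, par = u, tr = TRUE)
      next
    }
    ## no event: reach the bottom vertex of the edge
    if (length(tree_children(s, z)) == 0L) {
      new_node("leaf", "vertex", z, tz, ln$par, ln$tr)
    } else {
      u <- new_node("spe", "vertex", z, tz, ln$par, ln$tr)
      for (c in tree_children(s, z)) {
        stack[[length(stack) + 1L]] <- list(z = c, t0 = tz, par = u, tr = FALSE)
      }
    }
  }
  nn <- length(type)
  history <- data.frame(node = seq_len(nn), type = type, kind = kind,
                        species = species, time = time, parent = parent,
                        transfer = trf, stringsAsFactors = FALSE)
  ## prune to survivors
  surv <- type == "leaf"
  for (v in rev(seq_len(nn))) {       # creation order: parents before children
    if (surv[v] && parent[v] > 0L) surv[parent[v]] <- TRUE
  }
  if (sum(surv & type == "leaf") < 2L) return(NULL)
  kids <- vector("list", nn)
  for (v in seq_len(nn)) {
    if (surv[v] && parent[v] > 0L && surv[parent[v]]) {
      kids[[parent[v]]] <- c(kids[[parent[v]]], v)
    }
  }
  ## reject hidden transfers: an hgt vertex whose donor-side (non-transfer)
  ## lineage left no survivors
  for (v in which(surv & type == "hgt")) {
    fl <- trf[kids[[v]]]
    if (all(fl)) return(NULL)
  }
  ## suppress unary vertices, propagating the in-edge transfer flag
  eff_parent <- parent; eff_trf <- trf
  keep <- surv & (type == "leaf" | vapply(kids, length, 1L) >= 2L)
  for (v in seq_len(nn)) {            # parents processed before children
    if (!surv[v]) next
    p <- eff_parent[v]
    while (p > 0L && !keep[p]) {
      ## a suppressed vertex passes its own in-edge flag upward only if
      ## the spliced edge is not itself a transfer continuation
      eff_trf[v] <- eff_trf[v] || eff_trf[p]
      p <- eff_parent[p]
    }
    eff_parent[v] <- p
  }
  ## observable root: the kept vertex with no kept parent
  roots <- which(keep & eff_parent == 0L)
  if (length(roots) != 1L) return(NULL)
  kept <- which(keep)
  ## hidden transfer via suppression would put a transfer flag under a
  ## non-hgt parent; the rejection above makes this impossible, assert it
  for (v in kept) {
    if (eff_trf[v] && eff_parent[v] > 0L && type[eff_parent[v]] != "hgt") {
      return(NULL)
    }
  }
  ids <- character(nn)
  nint <- 0L; nleaf <- 0L
  for (v in kept) {
    if (type[v] == "leaf") { nleaf <- nleaf + 1L; ids[v] <- paste0("g", nleaf) }
    else { nint <- nint + 1L; ids[v] <- paste0("n", nint) }
  }
  edges_p <- ids[eff_parent[setdiff(kept, roots)]]
  edges_c <- ids[setdiff(kept, roots)]
  tr <- rooted_tree(data.frame(parent = edges_p, child = edges_c))
  events <- stats::setNames(type[kept], ids[kept])
  events <- events[events != "leaf"]
  sigma <- stats::setNames(species[kept], ids[kept])[tree_leaves(tr)]
  transfer <- ids[kept][eff_trf[kept] & eff_parent[kept] > 0L]
  g <- gene_tree(tr, events = events, sigma = sigma, transfer = transfer)
  ## A retained speciation always keeps two children in distinct daughter
  ## species, so Sigma1 cannot fail here; a scenario that nevertheless
  ## violated it (which would require relabeling the vertex as a
  ## duplication, off the vertex time point) is rejected defensively.
  if (length(check_sigma1(g))) return(NULL)
  ## true reconciliation map and times, rescaled to the standard anchors
  mu <- recon_map(ids[kept],
                  ifelse(type[kept] %in% c("spe", "leaf"), "vertex", "edge"),
                  species[kept])
  r1 <- time[roots]
  rescale <- function(x) (x - r1) / (r1 + 1)
  tau <- structure(list(
    tau_T = stats::setNames(rescale(time[kept]), ids[kept]),
    tau_S = rescale(stats::setNames(unname(st[s$ids]), s$ids))),
    class = "time_map_pair")
  structure(list(gene = g, species = s, mu = mu, tau = tau,
                 history = history),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario: %d observable genes, %d transfer edges>\n",
              length(genes_of(x$gene)), sum(x$gene$transfer)))
  invisible(x)
}
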