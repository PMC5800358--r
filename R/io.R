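## File formats.
##
## Species trees: plain Newick (read via ape; branch lengths tolerated
## and ignored; internal labels preserved; unlabeled internal vertices
## get deterministic generated ids from their preorder position).
## Gene trees: Newick with NHX-style comments per node,
##   [&&NHX:ev=spe|dup|hgt|leaf:trans=0|1]
## where `trans` flags the edge to the parent; parsed by a small
## recursive-descent reader since NHX key/value comments are not
## preserved by the standard parsers.  sigma comes from an `S=` NHX tag,
## a leaf-name suffix (configurable separator, last field wins), or an
## explicit two-column TSV.
## Writers canonicalize: children sorted lexicographically by vertex id,
## no branch lengths.  TSV round trips are bit-exact.

## phylo -> rooted_tree ----------------------------------------------------

phylo_to_rooted_tree <- function(phy) {
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  labels <- character(ntip + nnode)
  labels[seq_len(ntip)] <- phy$tip.label
  if (!is.null(phy$node.label)) {
    nl <- phy$node.label
    nl[is.na(nl)] <- ""
    labels[ntip + seq_len(nnode)] <- nl
  }
  parent <- integer(ntip + nnode)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  root <- which(parent == 0L)
  ## deterministic ids for unlabeled internal vertices: preorder position
  ord <- integer(0)
  stack <- root
  kids <- split(phy$edge[, 2L], factor(phy$edge[, 1L], levels = seq_along(labels)))
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    ord <- c(ord, v)
    stack <- c(stack, rev(kids[[v]]))
  }
  pos <- match(seq_along(labels), ord)
  for (v in seq_along(labels)) {
    if (labels[v] == "") {
      cand <- paste0("n", pos[v])
      while (cand %in% labels) cand <- paste0(cand, "_")
      labels[v] <- cand
    }
  }
  new_rooted_tree(labels, parent)
}

#' Read a species tree from a Newick file
#'
#' @param path path to a Newick file (or a literal Newick string ending
#'   in `;`).  Branch lengths are tolerated and ignored.
#' @return a `species_tree` (augmented with a planted root).
#' @export
read_species_tree <- function(path) {
  txt <- if (grepl("[(;]", path)) path else {
    paste(readLines(path, warn = FALSE), collapse = "")
  }
  if (grepl("^\\s*\\(?[^(),:;]*;\\s*$", txt) && !grepl("\\(", txt)) {
    ## single-leaf tree: "A;"
    leaf <- sub(";.*$", "", trimws(txt))
    return(augment_species_root(singleton_tree(leaf)))
  }
  phy <- ape::read.tree(text = txt)
  if (is.null(phy)) stop("could not parse Newick input")
  augment_species_root(phylo_to_rooted_tree(phy))
}

## canonical newick writer -------------------------------------------------

newick_string <- function(tree, start, decorate = function(id) "") {
  rec <- function(v) {
    id <- tree$ids[v]
    kids <- tree$children[[v]]
    if (length(kids) == 0L) return(paste0(id, decorate(id)))
    parts <- vapply(kids, rec, "")
    parts <- parts[order(tree$ids[kids])]
    paste0("(", paste(parts, collapse = ","), ")", id, decorate(id))
  }
  paste0(rec(start), ";")
}

#' Write a species tree as canonical Newick
#'
#' The planted root is omitted (it is re-added on read); children are
#' sorted lexicographically so output is deterministic.
#'
#' @param s a `species_tree`.
#' @param path output file, or `NULL` to return the string.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_species_tree <- function(s, path = NULL) {
  start <- if (n_vertices(s) > 1L) s$children[[s$root]][1L] else s$root
  txt <- newick_string(s, start)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

## NHX parser --------------------------------------------------------------

parse_nhx <- function(txt) {
  txt <- gsub("[[:space:]]", "", txt)
  pos <- 1L
  n <- nchar(txt)
  peek <- function() if (pos <= n) substr(txt, pos, pos) else ""
  nodes <- list()   # each: list(label, comment, children = integer ids)
  new_node <- function(label, comment, children) {
    nodes[[length(nodes) + 1L]] <<- list(label = label, comment = comment,
                                         children = children)
    length(nodes)
  }
  read_while <- function(stopchars) {
    start <- pos
    while (pos <= n && !substr(txt, pos, pos) %in% stopchars) pos <<- pos + 1L
    substr(txt, start, pos - 1L)
  }
  read_comment <- function() {
    if (peek() != "[") return("")
    start <- pos
    while (pos <= n && substr(txt, pos, pos) != "]") pos <<- pos + 1L
    if (pos > n) stop("unterminated comment starting at character ", start)
    pos <<- pos + 1L
    substr(txt, start + 1L, pos - 2L)
  }
  read_suffix <- function() {
    ## label? comment? (:length)? comment?
    label <- read_while(c("[", ":", ",", ")", ";", "("))
    comment <- read_comment()
    if (peek() == ":") {
      pos <<- pos + 1L
      read_while(c("[", ",", ")", ";"))
      c2 <- read_comment()
      if (comment == "") comment <- c2
    }
    list(label = label, comment = comment)
  }
  subtree <- function() {
    if (peek() == "(") {
      pos <<- pos + 1L
      children <- c(subtree())
      while (peek() == ",") {
        pos <<- pos + 1L
        children <- c(children, subtree())
      }
      if (peek() != ")") stop("expected ')' at character ", pos)
      pos <<- pos + 1L
      sfx <- read_suffix()
      new_node(sfx$label, sfx$comment, children)
    } else {
      sfx <- read_suffix()
      if (sfx$label == "") stop("empty leaf label at character ", pos)
      new_node(sfx$label, sfx$comment, integer(0))
    }
  }
  root <- subtree()
  if (peek() != ";") stop("expected ';' at character ", pos)
  list(nodes = nodes, root = root)
}

nhx_tags <- function(comment) {
  if (!startsWith(comment, "&&NHX")) return(character(0))
  body <- sub("^&&NHX:?", "", comment)
  if (body == "") return(character(0))
  parts <- strsplit(body, ":", fixed = TRUE)[[1L]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  stats::setNames(vapply(kv, function(x) if (length(x) > 1L) x[2L] else "", ""),
                  vapply(kv, `[[`, "", 1L))
}

#' Read an event-labeled gene tree from NHX-annotated Newick
#'
#' Every internal node must carry an `ev` tag (`spe`, `dup` or `hgt`);
#' `trans=1` flags the edge to the node's parent as a transfer (only
#' under an hgt parent).  The gene-to-species map is taken from, in this
#' order: the `sigma` argument (a two-column data frame or a TSV path,
#' gene then species), an `S=` NHX tag on the leaf, or the leaf-name
#' suffix after the last `sep`.
#'
#' @param path path to the file, or a literal Newick string containing `;`.
#' @param sigma optional data frame or TSV path with columns gene, species.
#' @param sep separator for the leaf-name suffix convention.
#' @return a `gene_tree`.
#' @export
read_gene_tree <- function(path, sigma = NULL, sep = "_") {
  txt <- if (grepl("[(;]", path)) path else {
    paste(readLines(path, warn = FALSE), collapse = "")
  }
  parsed <- parse_nhx(txt)
  nodes <- parsed$nodes
  nn <- length(nodes)
  labels <- vapply(nodes, `[[`, "", "label")
  ## generated ids for unlabeled internal nodes (preorder position)
  preord <- integer(0)
  stack <- parsed$root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    preord <- c(preord, v)
    stack <- c(stack, rev(nodes[[v]]$children))
  }
  pos <- match(seq_len(nn), preord)
  for (v in seq_len(nn)) {
    if (labels[v] == "") {
      cand <- paste0("n", pos[v])
      while (cand %in% labels) cand <- paste0(cand, "_")
      labels[v] <- cand
    }
  }
  parent <- integer(nn)
  for (v in seq_len(nn)) for (w in nodes[[v]]$children) parent[w] <- v
  tree <- new_rooted_tree(labels, parent)
  events <- character(0); transfer <- character(0)
  smap <- character(0)
  for (v in seq_len(nn)) {
    tags <- nhx_tags(nodes[[v]]$comment)
    is_leaf <- length(nodes[[v]]$children) == 0L
    if (!is_leaf) {
      if (!"ev" %in% names(tags)) {
        stop("internal node '", labels[v], "' lacks an ev= tag")
      }
      events[labels[v]] <- tags[["ev"]]
    } else {
      if ("S" %in% names(tags)) smap[labels[v]] <- tags[["S"]]
    }
    if (identical(unname(tags["trans"]), "1")) transfer <- c(transfer, labels[v])
  }
  if (!is.null(sigma)) {
    if (is.character(sigma) && length(sigma) == 1L) sigma <- read_sigma(sigma)
    smap <- stats::setNames(as.character(sigma[[2L]]), as.character(sigma[[1L]]))
  } else {
    for (lf in tree_leaves(tree)) {
      if (!lf %in% names(smap)) {
        parts <- strsplit(lf, sep, fixed = TRUE)[[1L]]
        if (length(parts) < 2L) {
          stop("cannot infer the species of gene '", lf,
               "': no S= tag and no '", sep, "' suffix")
        }
        smap[lf] <- parts[length(parts)]
      }
    }
  }
  gene_tree(tree, events = events, sigma = smap, transfer = transfer)
}

#' Write an event-labeled gene tree as canonical NHX Newick
#'
#' Children are sorted lexicographically; every node carries its `ev`
#' tag, every non-root node a `trans` flag, and every leaf an `S=`
#' species tag, so the file round-trips without a side-channel.
#'
#' @param g a `gene_tree`.
#' @param path output file, or `NULL` to return the string.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_gene_tree <- function(g, path = NULL) {
  tree <- g$tree
  decorate <- function(id) {
    tags <- paste0("ev=", g$events[[id]])
    if (g$events[[id]] == "leaf") tags <- paste0(tags, ":S=", g$sigma[[id]])
    if (tree$parent[tree_index(tree, id)] != 0L) {
      tags <- paste0(tags, ":trans=", as.integer(g$transfer[[id]]))
    }
    paste0("[&&NHX:", tags, "]")
  }
  txt <- newick_string(tree, tree$root, decorate)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

## TSV formats -------------------------------------------------------------

#' Read/write a gene-to-species assignment
#' @param path TSV path with columns `gene`, `species`.
#' @return data frame with columns `gene`, `species`.
#' @export
read_sigma <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  df
}

#' @rdname read_sigma
#' @param sigma named character vector (gene -> species).
#' @export
write_sigma <- function(sigma, path) {
  utils::write.table(data.frame(gene = names(sigma), species = unname(sigma)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a reconciliation map from TSV
#'
#' Columns `gene_node`, `kind` (`vertex`|`edge`), `species_node` (for
#' edges the child endpoint).  [write_recon_map()] round-trips bit-exactly.
#'
#' @param path TSV path.
#' @return a `recon_map`.
#' @export
read_recon_map <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  need <- c("gene_node", "kind", "species_node")
  if (!all(need %in% names(df))) {
    stop("reconciliation map TSV needs columns: ", paste(need, collapse = ", "))
  }
  recon_map(df$gene_node, df$kind, df$species_node)
}

#' @rdname read_recon_map
#' @param mu a `recon_map`.
#' @export
write_recon_map <- function(mu, path) {
  utils::write.table(
    data.frame(gene_node = mu$gene, kind = mu$kind, species_node = mu$species),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read/write time maps as TSV
#'
#' Columns `tree` (`gene`|`species`), `node`, `time` (decimal).
#'
#' @param path TSV path.
#' @return a `time_map_pair`.
#' @export
read_time_maps <- function(path) {
  df <- utils::read.delim(path, colClasses = c("character", "character", "numeric"))
  tg <- df[df$tree == "gene", ]
  ts <- df[df$tree == "species", ]
  structure(list(tau_T = stats::setNames(tg$time, tg$node),
                 tau_S = stats::setNames(ts$time, ts$node)),
            class = "time_map_pair")
}

#' @rdname read_time_maps
#' @param tau a `time_map_pair`.
#' @export
write_time_maps <- function(tau, path) {
  df <- rbind(
    data.frame(tree = "gene", node = names(tau$tau_T),
               time = format(unname(tau$tau_T), digits = 15, trim = TRUE)),
    data.frame(tree = "species", node = names(tau$tau_S),
               time = format(unname(tau$tau_S), digits = 15, trim = TRUE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read/write a DTL-scenario as TSV
#' @param path TSV path with columns `gene_node`, `species_node`.
#' @return named character vector `gamma`.
#' @export
read_dtl_map <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  stats::setNames(df$species_node, df$gene_node)
}

#' @rdname read_dtl_map
#' @param gamma named character vector.
#' @export
write_dtl_map <- function(gamma, path) {
  utils::write.table(
    data.frame(gene_node = names(gamma), species_node = unname(gamma)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
}
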