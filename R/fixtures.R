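## Named instance fixtures used across the documentation and test
## suites: a transfer-free family (G0S0), a single-transfer family that
## admits a time-consistent reconciliation (G1S0), and a two-transfer
## family whose transfers are mutually crossing, so that every
## reconciliation forces a cycle of timing constraints (G2S1).

fixture_species <- function(which) {
  raw <- switch(which,
    S0 = rooted_tree(data.frame(
      parent = c("R", "R", "X", "X"),
      child  = c("X", "C", "A", "B"))),
    S1 = rooted_tree(data.frame(
      parent = c("R", "R", "X", "X", "Y", "Y"),
      child  = c("X", "Y", "A", "B", "C", "D"))),
    stop("unknown species fixture '", which, "'"))
  augment_species_root(raw)
}

fixture_gene <- function(which) {
  switch(which,
    G0 = gene_tree(
      rooted_tree(data.frame(parent = c("r", "r", "u", "u"),
                             child  = c("u", "c", "a", "b"))),
      events = c(r = "spe", u = "spe"),
      sigma = c(a = "A", b = "B", c = "C")),
    G1 = gene_tree(
      rooted_tree(data.frame(parent = c("r", "r", "v", "v"),
                             child  = c("a", "v", "b", "c"))),
      events = c(r = "spe", v = "hgt"),
      sigma = c(a = "A", b = "B", c = "C"),
      transfer = "c"),
    G2 = gene_tree(
      rooted_tree(data.frame(
        parent = c("w2", "w2", "v1", "v1", "w1", "w1", "v2", "v2", "z2", "z2"),
        child  = c("b", "v1", "a", "w1", "c", "v2", "d", "z2", "a2", "b2"))),
      events = c(w2 = "spe", w1 = "spe", z2 = "spe", v1 = "hgt", v2 = "hgt"),
      sigma = c(a = "A", b = "B", c = "C", d = "D", a2 = "A", b2 = "B"),
      transfer = c("w1", "z2")),
    stop("unknown gene fixture '", which, "'"))
}

#' Built-in example instances
#'
#' Returns one of the package's named gene-tree/species-tree pairs:
#' * `"G0S0"`: transfer-free three-gene family; trivially time-consistent.
#' * `"G1S0"`: one transfer; time-consistent.
#' * `"G2S1"`: two crossing transfers between the two sides of the
#'   species tree; passes every observability check yet admits no
#'   time-consistent reconciliation (the auxiliary graph contains the
#'   cycle X -> v1 -> Y -> v2 -> X).
#'
#' @param name one of `"G0S0"`, `"G1S0"`, `"G2S1"`.
#' @return list with components `gene` (a `gene_tree`) and `species`
#'   (a `species_tree`).
#' @examples
#' fx <- named_fixture("G1S0")
#' reconcile(fx$gene, fx$species)$status
#' @export
named_fixture <- function(name) {
  parts <- regmatches(name, regexec("^(G[0-9]+)(S[0-9]+)$", name))[[1L]]
  if (length(parts) != 3L) stop("unknown fixture '", name, "'")
  list(gene = fixture_gene(parts[2L]), species = fixture_species(parts[3L]))
}
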