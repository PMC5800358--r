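g0 <- named_fixture("G0S0")$gene
g1 <- named_fixture("G1S0")$gene
g2 <- named_fixture("G2S1")$gene

test_that("removing transfer edges yields the expected components", {
  f1 <- remove_transfer_edges(g1)
  expect_length(f1$roots, 2L)
  comp_leaves <- lapply(f1$roots, function(r) sort(f1$leafsets[[r]]))
  expect_setequal(vapply(comp_leaves, paste, "", collapse = ","),
                  c("a,b", "c"))
  f0 <- remove_transfer_edges(g0)
  expect_length(f0$roots, 1L)
  expect_setequal(f0$leafsets[[f0$roots]], c("a", "b", "c"))
  f2 <- remove_transfer_edges(g2)
  expect_length(f2$roots, 3L)
  comp_leaves <- lapply(f2$roots, function(r) sort(f2$leafsets[[r]]))
  expect_setequal(vapply(comp_leaves, paste, "", collapse = ","),
                  c("a,b", "c,d", "a2,b2"))
  expect_setequal(sigma_TE(remove_transfer_edges(g1), "v"), "B")
})

test_that("O1 and O2 detect unobservable vertices and transfers", {
  expect_true(check_O1(g1))
  expect_true(check_O2(g1))
  ## internal vertex with a single child violates O1
  unary <- gene_tree(
    rooted_tree(data.frame(parent = c("r", "r", "u"), child = c("a", "u", "b"))),
    events = c(r = "spe", u = "spe"), sigma = c(a = "A", b = "B"))
  expect_false(check_O1(unary))
  ## hgt vertex with both out-edges flagged transfer violates O2
  both <- gene_tree(g1$tree, events = c(r = "spe", v = "hgt"),
                    sigma = g1$sigma, transfer = c("b", "c"))
  expect_false(check_O2(both))
  expect_true(check_O1(both))
})

test_that("Sigma1 and Sigma2 flag exactly the unobservable labelings", {
  expect_length(check_sigma1(g1), 0L)
  expect_identical(nrow(check_sigma2(g1)), 0L)
  ## transfer target in a species already present on the donor side
  g1b <- gene_tree(g1$tree, events = c(r = "spe", v = "hgt"),
                   sigma = c(a = "A", b = "B", c = "B"), transfer = "c")
  s2 <- check_sigma2(g1b)
  expect_identical(s2$from, "v")
  expect_identical(s2$to, "c")
  ## speciation separating nothing: both children in species A
  same <- gene_tree(
    rooted_tree(data.frame(parent = c("r", "r"), child = c("a", "b"))),
    events = c(r = "spe"), sigma = c(a = "A", b = "A"))
  expect_identical(check_sigma1(same), "r")
  ## Sigma checks insist on O2 first
  both <- gene_tree(g1$tree, events = c(r = "spe", v = "hgt"),
                    sigma = g1$sigma, transfer = c("b", "c"))
  expect_error(check_sigma1(both), "O2")
  expect_error(check_sigma2(both), "O2")
})

test_that("gene_tree enforces the transfer-edge labeling invariant", {
  expect_error(
    gene_tree(g1$tree, events = c(r = "spe", v = "dup"),
              sigma = g1$sigma, transfer = "c"),
    "not an hgt vertex")
  expect_error(
    gene_tree(g1$tree, events = c(r = "spe"), sigma = g1$sigma),
    "missing event label")
  expect_error(
    gene_tree(g1$tree, events = c(r = "spe", v = "hgt"),
              sigma = c(a = "A", b = "B")),
    "sigma missing")
})

test_that("gene families aggregate under an artificial duplication root", {
  agg <- aggregate_gene_trees(list(g0, g1))
  expect_length(genes_of(agg), 6L)
  rt <- tree_root(agg$tree)
  expect_identical(unname(agg$events[rt]), "dup")
  expect_setequal(tree_children(agg$tree, rt), c("r0", "r1"))
  expect_identical(unname(agg$events[c("r0", "r1")]), c("spe", "spe"))
  ## single family: labels kept as-is
  agg1 <- aggregate_gene_trees(list(g1))
  expect_identical(tree_children(agg1$tree, tree_root(agg1$tree)), "r")
  ## component count merges the root components through the new root
  fa <- remove_transfer_edges(agg)
  expect_length(fa$roots, 2L)
  expect_error(aggregate_gene_trees(list()), "empty")
})

test_that("component leaf sets partition the genes whenever O2 holds", {
  ## Lemma-1 behaviour, on fixtures and simulated trees
  for (g in c(list(g0, g1, g2), lapply(sim_instances(20, 500), `[[`, "gene"))) {
    expect_true(check_O2(g))
    f <- remove_transfer_edges(g)
    all_leaves <- unlist(lapply(f$roots, function(r) f$leafsets[[r]]))
    expect_setequal(all_leaves, genes_of(g))
    expect_false(anyDuplicated(all_leaves) > 0L)
  }
})

test_that("transfer-free species sets are monotone along components", {
  for (sc in sim_instances(10, 600)) {
    g <- sc$gene
    f <- remove_transfer_edges(g)
    tree <- g$tree
    for (vi in seq_along(tree$ids)) {
      p <- tree$parent[vi]
      if (p == 0L || g$transfer[[tree$ids[vi]]]) next
      expect_true(all(f$sigma_sets[[vi]] %in% f$sigma_sets[[p]]))
    }
  }
})
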