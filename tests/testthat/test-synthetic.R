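test_that("named fixtures behave as designed", {
  expect_error(named_fixture("G9S9"), "unknown")
  fx1 <- named_fixture("G1S0")
  expect_true(check_O1(fx1$gene) && check_O2(fx1$gene))
  expect_length(check_sigma1(fx1$gene), 0L)
  expect_identical(nrow(check_sigma2(fx1$gene)), 0L)
  ## the crossing-transfer fixture passes every observability check but is
  ## not time-consistently reconcilable
  fx2 <- named_fixture("G2S1")
  expect_true(check_O1(fx2$gene) && check_O2(fx2$gene))
  expect_length(check_sigma1(fx2$gene), 0L)
  expect_identical(nrow(check_sigma2(fx2$gene)), 0L)
  mu2 <- canonical_reconciliation(fx2$gene, fx2$species)
  expect_true(validate_reconciliation(fx2$gene, fx2$species, mu2)$valid)
  expect_false(exists_time_consistent_map(fx2$gene, fx2$species, mu2)$exists)
  expect_identical(reconcile(named_fixture("G0S0")$gene,
                             named_fixture("G0S0")$species)$status,
                   "consistent")
})

test_that("scenario_config validates its rates", {
  expect_error(scenario_config(duplication = 0.6, transfer = 0.5), "sum")
  expect_error(scenario_config(loss = -0.1), "\\[0,1\\]")
  expect_error(scenario_config(n_species = 0), "at least one")
})

test_that("a pure-speciation scenario reproduces the species tree", {
  sc <- simulate_scenario(scenario_config(seed = 1, duplication = 0,
                                          transfer = 0, loss = 0,
                                          n_species = 3))
  g <- sc$gene
  expect_length(genes_of(g), 3L)
  expect_true(all(g$events[g$events != "leaf"] == "spe"))
  expect_setequal(unname(g$sigma), species_of(sc$species))
  expect_identical(sum(g$transfer), 0L)
})

test_that("without loss and transfer every lineage survives in every
           descendant species", {
  sc <- simulate_scenario(scenario_config(seed = 5, duplication = 0.3,
                                          transfer = 0, loss = 0,
                                          n_species = 4, max_genes = 40))
  g <- sc$gene
  ## every species retains at least one copy, and every duplication that
  ## predates a speciation is carried into all daughter species: each
  ## component root below a speciation covers that species subtree
  expect_setequal(unique(unname(g$sigma)), species_of(sc$species))
  f <- remove_transfer_edges(g)
  tree <- g$tree
  for (vi in which(unname(g$events[tree$ids]) == "spe")) {
    kid_sets <- f$sigma_sets[tree$children[[vi]]]
    all_kids <- unlist(kid_sets, use.names = FALSE)
    expect_identical(f$sigma_sets[[vi]], sort(unique(all_kids)))
    ## with no transfers, the daughter species sets are pairwise disjoint
    expect_identical(sort(all_kids), sort(unique(all_kids)))
  }
})

test_that("simulated scenarios are observable and carry a valid,
           time-consistent true history", {
  for (sc in sim_instances(50, 1300)) {
    g <- sc$gene; s <- sc$species
    expect_true(check_O1(g))
    expect_true(check_O2(g))
    expect_length(check_sigma1(g), 0L)
    expect_identical(nrow(check_sigma2(g)), 0L)
    expect_true(validate_reconciliation(g, s, sc$mu)$valid)
    expect_true(check_C(g, s, sc$mu, sc$tau)$valid)
    expect_true(is_time_consistent_map(g, s, sc$mu)$consistent)
    expect_identical(sc$tau$tau_S[[tree_root(s)]], -1)
    expect_identical(sc$tau$tau_T[[tree_root(g$tree)]], 0)
  }
})

test_that("simulation is reproducible from the seed", {
  a <- simulate_scenario(scenario_config(seed = 99))
  b <- simulate_scenario(scenario_config(seed = 99))
  expect_identical(write_gene_tree(a$gene), write_gene_tree(b$gene))
  expect_identical(a$tau, b$tau)
})

test_that("the enumerator guards its limits and emits a deterministic,
           observable family", {
  expect_error(enumerate_small_instances(7, 3, 2), "too large")
  expect_error(enumerate_small_instances(4, 5, 2), "too large")
  fam <- enumerate_small_instances(2, 2, 0)
  ## the speciation cherry over two species is present
  has_cherry <- any(vapply(fam, function(inst) {
    g <- inst$gene
    length(genes_of(g)) == 2L && all(g$events[g$events != "leaf"] == "spe") &&
      length(unique(unname(g$sigma))) == 2L
  }, TRUE))
  expect_true(has_cherry)
  fam2 <- enumerate_small_instances(3, 2, 1)
  expect_identical(length(fam2), length(enumerate_small_instances(3, 2, 1)))
  for (inst in fam2) {
    expect_true(check_O1(inst$gene))
    expect_true(check_O2(inst$gene))
    expect_length(check_sigma1(inst$gene), 0L)
    expect_identical(nrow(check_sigma2(inst$gene)), 0L)
  }
})
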