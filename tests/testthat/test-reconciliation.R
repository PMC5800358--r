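fx1 <- named_fixture("G1S0")
fx0 <- named_fixture("G0S0")
fx2 <- named_fixture("G2S1")

test_that("the lca-map matches the naive leafset oracle on the fixtures", {
  ell <- lca_map(fx1$gene, fx1$species)
  expect_identical(unname(ell[c("a", "b", "c", "v", "r")]),
                   c("A", "B", "C", "B", "X"))
  expect_identical(unclass(ell)[order(names(ell))],
                   naive_lca_map(fx1$gene, fx1$species)[order(names(ell))])
  ell0 <- lca_map(fx0$gene, fx0$species)
  expect_identical(unname(ell0[c("u", "r")]), c("X", "R"))
  ell2 <- lca_map(fx2$gene, fx2$species)
  expect_identical(unname(ell2[c("w2", "v1", "w1", "v2", "z2")]),
                   c("X", "A", "Y", "D", "X"))
})

test_that("lca-map names missing species", {
  g <- gene_tree(fx1$gene$tree, events = c(r = "spe", v = "hgt"),
                 sigma = c(a = "A", b = "B", c = "Q"), transfer = "c")
  expect_error(lca_map(g, fx1$species), "Q")
})

test_that("the canonical reconciliation is the pointwise-lowest map", {
  mu <- canonical_reconciliation(fx1$gene, fx1$species)
  expect_identical(mu$species[match(c("r", "v", "a", "b", "c"), mu$gene)],
                   c("X", "B", "A", "B", "C"))
  expect_identical(mu$kind[match(c("r", "v"), mu$gene)], c("vertex", "edge"))
  mu0 <- canonical_reconciliation(fx0$gene, fx0$species)
  expect_true(all(mu0$kind == "vertex"))
  expect_identical(mu0$species[match(c("r", "u"), mu0$gene)], c("R", "X"))
  mu2 <- canonical_reconciliation(fx2$gene, fx2$species)
  expect_identical(mu2$species[match(c("w2", "v1", "w1", "v2", "z2"), mu2$gene)],
                   c("X", "A", "Y", "D", "X"))
  expect_identical(mu2$kind[match(c("w2", "v1", "w1", "v2", "z2"), mu2$gene)],
                   c("vertex", "edge", "vertex", "edge", "vertex"))
})

test_that("validation accepts the canonical maps and pinpoints violations", {
  expect_true(validate_reconciliation(fx1$gene, fx1$species,
                                      canonical_reconciliation(fx1$gene, fx1$species))$valid)
  ## a duplication/transfer vertex pushed above the planted edge breaks M3
  mu2 <- canonical_reconciliation(fx2$gene, fx2$species)
  mu2$species[mu2$gene == "v1"] <- "R"       # edge (RHO, R)
  rep2 <- validate_reconciliation(fx2$gene, fx2$species, mu2)
  expect_false(rep2$valid)
  expect_true(any(rep2$violations$condition == "M3ii" &
                  grepl("v1", rep2$violations$witness)))
  ## comparable transfer endpoints break M2iii
  mu1 <- canonical_reconciliation(fx1$gene, fx1$species)
  mu1$species[mu1$gene == "v"] <- "C"        # edge (R, C), comparable to mu(c)=C
  rep1 <- validate_reconciliation(fx1$gene, fx1$species, mu1)
  expect_false(rep1$valid)
  expect_true(any(rep1$violations$condition == "M2iii" &
                  rep1$violations$witness == "v->c"))
  ## totality and image checks are hard errors
  expect_error(validate_reconciliation(fx1$gene, fx1$species,
                                       recon_map("r", "vertex", "X")),
               "not total")
  bad <- canonical_reconciliation(fx1$gene, fx1$species)
  bad$species[bad$gene == "r"] <- "nope"
  expect_error(validate_reconciliation(fx1$gene, fx1$species, bad),
               "not a point")
})

test_that("the lca-map agrees with the naive oracle on random instances", {
  for (sc in sim_instances(40, 700)) {
    ell <- lca_map(sc$gene, sc$species)
    nv <- naive_lca_map(sc$gene, sc$species)
    expect_identical(unclass(ell)[names(nv)], nv)
  }
})

test_that("the lca-map is monotone along transfer-free components", {
  for (sc in sim_instances(10, 800)) {
    g <- sc$gene; s <- sc$species
    ell <- lca_map(g, s)
    tree <- g$tree
    for (vi in seq_along(tree$ids)) {
      p <- tree$parent[vi]
      if (p == 0L || g$transfer[[tree$ids[vi]]]) next
      expect_true(is_ancestor(s, ell[[tree$ids[p]]], ell[[tree$ids[vi]]]))
    }
  }
})

test_that("the canonical map is valid whenever any valid map exists, and
           every brute-force valid map respects the lca lower bound", {
  fam <- enumerate_small_instances(3, 3, 2)
  for (inst in fam) {
    g <- inst$gene; s <- inst$species
    mus <- enumerate_valid_maps(g, s)
    canon_ok <- validate_reconciliation(g, s, canonical_reconciliation(g, s))$valid
    expect_identical(canon_ok, length(mus) > 0L)
    f <- remove_transfer_edges(g)
    for (mu in mus) {
      for (u in g$tree$ids) {
        lb <- vertex_point(tree_lca(s, sigma_TE(f, u)))
        expect_true(hgtrecon:::point_leq(s, lb, mu_point(mu, u)))
      }
    }
  }
})

test_that("reconciliation maps round-trip through TSV bit-exactly", {
  mu <- canonical_reconciliation(fx2$gene, fx2$species)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_recon_map(mu, path)
  first <- readLines(path)
  mu2 <- read_recon_map(path)
  expect_identical(as.data.frame(mu2), as.data.frame(mu))
  write_recon_map(mu2, path)
  expect_identical(readLines(path), first)
})
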