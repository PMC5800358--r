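fx1 <- named_fixture("G1S0")
fx0 <- named_fixture("G0S0")
fx2 <- named_fixture("G2S1")
mu1 <- canonical_reconciliation(fx1$gene, fx1$species)
mu0 <- canonical_reconciliation(fx0$gene, fx0$species)
mu2 <- canonical_reconciliation(fx2$gene, fx2$species)

aux_edge_set <- function(aux) {
  unique(paste0(aux$edges$from, ">", aux$edges$to))
}

test_that("the auxiliary graph contains exactly the rule-generated edges", {
  aux <- build_auxiliary_graph(fx1$gene, fx1$species, mu1, mode = "A2")
  es <- aux_edge_set(aux)
  expect_true(all(c("S:X>T:v", "T:v>S:B", "T:v>S:C", "S:R>T:v") %in% es))
  ## all species edges present (A2)
  expect_true(all(c("S:RHO>S:R", "S:R>S:X", "S:R>S:C", "S:X>S:A", "S:X>S:B")
                  %in% es))
  ## no A5 edges in A2-mode, no A3/A4 in A1-mode
  expect_false(any(aux$edges$class == "A5"))
  aux1 <- build_auxiliary_graph(fx1$gene, fx1$species, mu1, mode = "A1")
  expect_false(any(aux1$edges$class %in% c("A3", "A4")))
  expect_error(build_auxiliary_graph(fx1$gene, fx1$species, mu1, mode = "Z"))
})

test_that("time-consistency of a given map is decided with a witness", {
  tc1 <- is_time_consistent_map(fx1$gene, fx1$species, mu1)
  expect_true(tc1$consistent)
  expect_true(length(tc1$order) > 0L)
  expect_true(oracle_time_consistent(fx1$gene, fx1$species, mu1))
  tc2 <- is_time_consistent_map(fx2$gene, fx2$species, mu2)
  expect_false(tc2$consistent)
  expect_identical(tc2$cycle$vertex, c("X", "v1", "Y", "v2"))
  expect_false(oracle_time_consistent(fx2$gene, fx2$species, mu2))
  tc0 <- is_time_consistent_map(fx0$gene, fx0$species, mu0)
  expect_true(tc0$consistent)
  ## invalid maps are rejected up front
  bad <- mu1
  bad$species[bad$gene == "v"] <- "C"
  expect_error(is_time_consistent_map(fx1$gene, fx1$species, bad),
               "not a valid reconciliation")
})

test_that("existence of some time-consistent map is decided via the A2 graph", {
  expect_true(exists_time_consistent_map(fx1$gene, fx1$species, mu1)$exists)
  expect_true(oracle_exists_tc(fx1$gene, fx1$species))
  ex2 <- exists_time_consistent_map(fx2$gene, fx2$species, mu2)
  expect_false(ex2$exists)
  expect_identical(ex2$cycle$vertex, c("X", "v1", "Y", "v2"))
  expect_false(oracle_exists_tc(fx2$gene, fx2$species))
  expect_true(exists_time_consistent_map(fx0$gene, fx0$species, mu0)$exists)
})

test_that("derived time maps honor the anchors and the strict orderings", {
  aux <- build_auxiliary_graph(fx1$gene, fx1$species, mu1, mode = "A2")
  tau <- derive_time_maps(aux, fx1$gene, fx1$species, mu1)
  expect_identical(tau$tau_S[["RHO"]], -1)
  expect_identical(tau$tau_T[["r"]], 0)
  expect_identical(tau$tau_T[["r"]], tau$tau_S[["X"]])
  expect_true(tau$tau_S[["X"]] < tau$tau_T[["v"]])
  expect_true(tau$tau_T[["v"]] < min(tau$tau_S[["B"]], tau$tau_S[["C"]]))
  ## transfer-free case: equalities forced by C1
  aux0 <- build_auxiliary_graph(fx0$gene, fx0$species, mu0, mode = "A2")
  tau0 <- derive_time_maps(aux0, fx0$gene, fx0$species, mu0)
  expect_identical(tau0$tau_T[["r"]], tau0$tau_S[["R"]])
  expect_identical(tau0$tau_T[["r"]], 0)
  expect_identical(tau0$tau_T[["u"]], tau0$tau_S[["X"]])
  expect_true(tau0$tau_T[["u"]] > 0)
  ## cyclic graph: refusal
  aux2 <- build_auxiliary_graph(fx2$gene, fx2$species, mu2, mode = "A2")
  expect_error(derive_time_maps(aux2, fx2$gene, fx2$species, mu2), "cyclic")
})

test_that("relocation picks the unique time-compatible edge", {
  aux <- build_auxiliary_graph(fx1$gene, fx1$species, mu1, mode = "A2")
  tau <- derive_time_maps(aux, fx1$gene, fx1$species, mu1)
  mu_r <- relocate_map(fx1$gene, fx1$species, mu1, tau)
  expect_identical(mu_r$species[mu_r$gene == "v"], "B")  # edge (X,B), unchanged
  ## time pushed above X: the transfer vertex moves to the edge (R, X)
  tau_hi <- tau
  tau_hi$tau_T[["v"]] <- (tau$tau_S[["R"]] + tau$tau_S[["X"]]) / 2
  mu_hi <- relocate_map(fx1$gene, fx1$species, mu1, tau_hi)
  expect_identical(mu_hi$species[mu_hi$gene == "v"], "X")
  expect_identical(mu_hi$kind[mu_hi$gene == "v"], "edge")
  ## time below the global lower anchor: no edge brackets it
  tau_bad <- tau
  tau_bad$tau_T[["v"]] <- tau$tau_S[["RHO"]] - 1
  expect_error(relocate_map(fx1$gene, fx1$species, mu1, tau_bad), "no species edge")
})

test_that("the C/D/T validators accept pipeline output and reject boundary
           violations", {
  r <- reconcile(fx1$gene, fx1$species)
  expect_true(check_C(fx1$gene, fx1$species, r$mu, r$tau)$valid)
  expect_true(check_D(fx1$gene, fx1$species, r$mu, r$tau)$valid)
  expect_true(check_T(fx1$gene, fx1$species, r$mu, r$tau)$valid)
  ## C2 forbids boundary equality
  tau_eq <- r$tau
  tau_eq$tau_T[["v"]] <- tau_eq$tau_S[["B"]]
  cc <- check_C(fx1$gene, fx1$species, r$mu, tau_eq)
  expect_false(cc$valid)
  expect_true(any(cc$violations$condition == "C2" & cc$violations$witness == "v"))
  ## C1/D1 force equality for speciations
  r0 <- reconcile(fx0$gene, fx0$species)
  tau_ne <- r0$tau
  tau_ne$tau_T[["u"]] <- tau_ne$tau_T[["u"]] + 0.25
  cc0 <- check_C(fx0$gene, fx0$species, r0$mu, tau_ne)
  dd0 <- check_D(fx0$gene, fx0$species, r0$mu, tau_ne)
  expect_true(any(cc0$violations$condition == "C1" & cc0$violations$witness == "u"))
  expect_true(any(dd0$violations$condition == "D1" & grepl("u", dd0$violations$witness)))
})

test_that("the full pipeline decides and constructs, with certificates", {
  r1 <- reconcile(fx1$gene, fx1$species)
  expect_identical(r1$status, "consistent")
  expect_true(validate_reconciliation(fx1$gene, fx1$species, r1$mu)$valid)
  expect_true(check_C(fx1$gene, fx1$species, r1$mu, r1$tau)$valid)
  r2 <- reconcile(fx2$gene, fx2$species)
  expect_identical(r2$status, "inconsistent")
  expect_identical(r2$cycle$vertex, c("X", "v1", "Y", "v2"))
  r0 <- reconcile(fx0$gene, fx0$species)
  expect_identical(r0$status, "consistent")
  expect_identical(as.data.frame(r0$mu),
                   as.data.frame(canonical_reconciliation(fx0$gene, fx0$species)))
  ## determinism: identical output across runs
  r1b <- reconcile(fx1$gene, fx1$species)
  expect_identical(r1$mu, r1b$mu)
  expect_identical(r1$tau, r1b$tau)
})

test_that("the pipeline refuses trees failing the observability conditions", {
  ## Sigma2 failure: transfer into a species already on the donor side
  g1b <- gene_tree(fx1$gene$tree, events = c(r = "spe", v = "hgt"),
                   sigma = c(a = "A", b = "B", c = "B"), transfer = "c")
  r <- reconcile(g1b, fx1$species)
  expect_identical(r$status, "invalid")
  expect_match(r$reason, "Sigma2")
  ## O2 failure
  both <- gene_tree(fx1$gene$tree, events = c(r = "spe", v = "hgt"),
                    sigma = fx1$gene$sigma, transfer = c("b", "c"))
  expect_identical(reconcile(both, fx1$species)$status, "invalid")
})

test_that("the existence verdict does not depend on the anchor map", {
  fam <- enumerate_small_instances(4, 3, 2)
  set.seed(31)
  n_checked <- 0L
  for (inst in sample(fam, 60L)) {
    mus <- enumerate_valid_maps(inst$gene, inst$species)
    if (length(mus) < 2L) next
    verdicts <- vapply(mus, function(mu) {
      exists_time_consistent_map(inst$gene, inst$species, mu)$exists
    }, TRUE)
    expect_length(unique(verdicts), 1L)
    n_checked <- n_checked + 1L
  }
  expect_gt(n_checked, 5L)
})

test_that("a gene-tree time map constructed from any time-consistent map
           passes the T-conditions", {
  fam <- enumerate_small_instances(3, 3, 2)
  checked <- 0L
  for (inst in fam) {
    g <- inst$gene; s <- inst$species
    for (mu in enumerate_valid_maps(g, s)) {
      if (!oracle_time_consistent(g, s, mu)) next
      aux <- build_auxiliary_graph(g, s, mu, mode = "A1", validate = FALSE)
      tau <- derive_time_maps(aux, g, s, mu)
      expect_true(check_C(g, s, mu, tau)$valid)
      expect_true(check_T(g, s, mu, tau$tau_T)$valid)
      checked <- checked + 1L
      break
    }
  }
  expect_gt(checked, 10L)
})

test_that("whenever the pipeline succeeds on simulated instances, all three
           condition systems hold", {
  for (sc in sim_instances(15, 900)) {
    r <- reconcile(sc$gene, sc$species)
    expect_identical(r$status, "consistent")  # the true scenario is consistent
    expect_true(validate_reconciliation(sc$gene, sc$species, r$mu)$valid)
    expect_true(check_C(sc$gene, sc$species, r$mu, r$tau)$valid)
    expect_true(check_D(sc$gene, sc$species, r$mu, r$tau)$valid)
    expect_true(check_T(sc$gene, sc$species, r$mu, r$tau)$valid)
  }
})
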