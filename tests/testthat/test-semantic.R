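# Chain fixture used throughout: disease A sits at R.P.A, disease B at R.P,
# so A's DAG is r -> p -> A (with p owned by B) and B's DAG is r -> B.
chain_universe <- function() {
  list(a = disease_record("A", "R.P.A"),
       b = disease_record("B", "R.P"))
}

test_that("DAG construction closes prefixes and collapses owned codes", {
  u <- chain_universe()
  dagA <- build_dag(u$a, u)
  expect_setequal(dagA$nodes, c("R", "b", "a"))
  expect_equal(dagA$children[["R"]], "b")
  expect_equal(dagA$children[["b"]], "a")
  # multi-rooted DAG from two tree numbers
  rec <- disease_record("X", c("C04.588", "C08.381"))
  dagX <- build_dag(rec, list(x = rec))
  expect_setequal(dagX$nodes, c("C04", "C08", "x"))
  expect_setequal(dagX$children[["C04"]], "x")
  expect_setequal(dagX$children[["C08"]], "x")
  # diamond: two paths to the same disease give it two parents
  rec2 <- disease_record("Y", c("C04.588.945", "C12.294.945"))
  dagY <- build_dag(rec2, list(y = rec2))
  parents <- names(Filter(function(kids) "y" %in% kids, dagY$children))
  expect_setequal(parents, c("C04.588", "C12.294"))
})

test_that("SV1 contributions follow the decay recursion", {
  u <- chain_universe()
  cA <- sv1_contributions(build_dag(u$a, u), alpha = 0.5)
  expect_equal(cA[["a"]], 1)
  expect_equal(cA[["b"]], 0.5)
  expect_equal(cA[["R"]], 0.25)
  # singleton DAG
  solo <- disease_record("S", "Z9")
  expect_equal(unname(sv1_contributions(build_dag(solo), 0.5)), 1)
  # diamond: both paths give the root the same decayed value
  rec <- disease_record("Y", c("C1.P1.L", "C1.P2.L"))
  cY <- sv1_contributions(build_dag(rec, list(y = rec)), 0.5)
  expect_equal(cY[["C1"]], 0.25)
  expect_equal(semantic_value(cY), 1 + 0.5 + 0.5 + 0.25)
})

test_that("information-content contribution and beta factor evaluate as defined", {
  expect_equal(sv2_contribution(8, 8), 0)
  expect_equal(sv2_contribution(1, exp(1)), 1)
  expect_equal(sv2_contribution(2, 8), -log(0.25))
  expect_error(sv2_contribution(0, 8), "at least one")
  # corpus of 4 diseases sharing one root; leaf terms occur once each
  u <- lapply(1:4, function(i)
    disease_record(sprintf("d%d", i), sprintf("ROOT.%03d", i)))
  names(u) <- sprintf("d%d", 1:4)
  corp <- dag_corpus(u)
  expect_equal(beta_factor("ROOT", corp), 0)      # most frequent term
  expect_equal(beta_factor("d1", corp), 3 / 4)
  # single-disease corpus: every term has beta 0
  solo <- list(s = disease_record("s", "A.B"))
  corp1 <- dag_corpus(solo)
  expect_true(all(vapply(corp1$dags$s$nodes, beta_factor, numeric(1),
                         corpus = corp1) == 0))
})

test_that("SV3 reduces to SV1 when beta is zero and applies per-node factors", {
  # single-disease corpus forces beta = 0 everywhere
  solo <- list(s = disease_record("s", c("A.B.C.D", "A.E.D")))
  corp <- dag_corpus(solo)
  dag <- corp$dags$s
  expect_equal(sv3_contributions(dag, 0.5, corp), sv1_contributions(dag, 0.5))
  # chain with heterogeneous beta: hand-computed path products
  u <- chain_universe()
  u$c <- disease_record("C", "R.Q")  # makes R more frequent than P/Q
  corp2 <- dag_corpus(u)
  dagA <- corp2$dags$a
  # counts: R in 3 DAGs, b (code R.P) in 2, a in 1; so beta(R)=0, beta(b)=1/3
  bR <- beta_factor("R", corp2); bP <- beta_factor("b", corp2)
  expect_equal(bR, 0)
  expect_equal(bP, 1 / 3)
  c3 <- sv3_contributions(dagA, 0.5, corp2)
  expect_equal(c3[["b"]], 0.5 + bP)
  expect_equal(c3[["R"]], (0.5 + bR) * (0.5 + bP))
})

test_that("SV3 contributions are not clamped when alpha + beta exceeds 1", {
  # four siblings make the root frequent; Q is rare, so beta(Q) = 4/5
  u <- lapply(1:4, function(i) disease_record(sprintf("d%d", i),
                                              sprintf("R.C%d", i)))
  names(u) <- sprintf("d%d", 1:4)
  u$d5 <- disease_record("d5", "R.Q.X")
  corp <- dag_corpus(u)
  expect_equal(beta_factor("R.Q", corp), 4 / 5)
  c5 <- sv3_contributions(corp$dags$d5, 0.5, corp)
  expect_equal(c5[["R.Q"]], 1.3)  # exceeds the child value 1
})

test_that("semantic similarity matches the hand-worked chain fixture", {
  u <- chain_universe()
  cA <- sv1_contributions(build_dag(u$a, u), 0.5)
  cB <- sv1_contributions(build_dag(u$b, u), 0.5)
  expect_equal(semantic_similarity(cA, cB), 2.25 / 3.25)
  expect_equal(semantic_similarity(cA, cA), 1)
  # disjoint DAGs share nothing
  cZ <- sv1_contributions(build_dag(disease_record("Z", "X9.Y1")), 0.5)
  expect_equal(semantic_similarity(cA, cZ), 0)
})

test_that("sweep equals the brute-force all-paths oracle on random DAGs", {
  withr::local_seed(11)
  for (rep in 1:40) {
    u <- random_universe(n = sample(3:5, 1))
    corp <- dag_corpus(u)
    for (key in names(u)) {
      dag <- corp$dags[[key]]
      expect_identical(sv1_contributions(dag, 0.5),
                       sv_bruteforce(dag, function(t, k) 0.5))
      expect_identical(
        sv3_contributions(dag, 0.5, corp),
        sv_bruteforce(dag, function(t, k) 0.5 + beta_factor(t, corp)))
    }
  }
})

test_that("similarity matrices are symmetric, unit-diagonal and in [0,1]", {
  withr::local_seed(5)
  for (variant in c("SV1", "SV2", "SV3")) {
    u <- random_universe(n = 6)
    S <- disease_similarity_matrix(u, model_params(contribution_variant = variant))
    expect_silent(validate_similarity(S))
  }
})

test_that("adding a shared ancestor never decreases similarity", {
  withr::local_seed(21)
  for (rep in 1:20) {
    u <- random_universe(n = 2)
    S0 <- disease_similarity_matrix(u, model_params(contribution_variant = "SV1"))
    u2 <- lapply(u, function(r)
      disease_record(r$name, paste0("SHAREDROOT.", r$tree_numbers)))
    S1 <- disease_similarity_matrix(u2, model_params(contribution_variant = "SV1"))
    expect_gte(S1[1, 2] + 1e-12, S0[1, 2])
  }
})
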