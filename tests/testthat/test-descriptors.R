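# Closed-form spectra and the dense-eigensolver oracle anchor all four
# matrix descriptors; the lead-like scores are pinned only to their m/k
# arithmetic.

test_that("VE1_L matches closed-form spectra on tiny graphs", {
  # P2: L = [[1,-1],[-1,1]], top eigenvector (1, -1)/sqrt(2)
  expect_equal(ve1_laplacian(parse_smiles("CC")), sqrt(2), tolerance = 1e-10)
  # star S3 (isobutane skeleton): lambda = 4 eigenvector (3,-1,-1,-1)/sqrt(12)
  expect_equal(ve1_laplacian(parse_smiles("CC(C)C")), 6 / sqrt(12),
               tolerance = 1e-10)
  expect_error(ve1_laplacian(parse_smiles("C")), "single-atom")
})

test_that("VE1_L smallest-nonzero convention uses the Fiedler vector", {
  g <- parse_smiles("CCC")  # P3: lambda = 1, eigenvector (1,0,-1)/sqrt(2)
  expect_equal(ve1_laplacian(g, which = "smallest_nonzero"), sqrt(2),
               tolerance = 1e-10)
})

test_that("SpPos_A matches the cycle spectrum and the zero/bipartite cases", {
  # C6 eigenvalues 2cos(2 pi k/6): positives sum to 4
  expect_equal(sppos_adjacency(parse_smiles("c1ccccc1")), 4, tolerance = 1e-10)
  expect_equal(sppos_adjacency(parse_smiles("C")), 0)
  expect_equal(sppos_adjacency(parse_smiles("CC")), 1, tolerance = 1e-10)
  # bipartite graphs: SpPos = graph energy / 2
  for (smi in c("CCCC", "CC(C)C", "C1CCCCC1", "CCOC(=O)C")) {
    g <- parse_smiles(smi)
    ev <- eigen(oracle_adjacency(g), symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sppos_adjacency(g), sum(abs(ev)) / 2, tolerance = 1e-10)
  }
})

test_that("SpMax2_Bh(v) matches the analytic 2x2 case and the dense oracle", {
  # all-carbon P2: B = [[1, 0.11], [0.11, 1]] -> eigenvalues 1.11, 0.89
  expect_equal(spmax2_burden(parse_smiles("CC")), 0.89, tolerance = 1e-12)
  props <- atom_properties()
  for (g in fixture_graphs(20)) {
    ev <- eigen(oracle_burden(g, props), symmetric = TRUE,
                only.values = TRUE)$values
    expect_equal(spmax2_burden(g, props), ev[2], tolerance = 1e-10)
  }
})

test_that("H_Dz(p) collapses to the Harary index on carbon skeletons", {
  # P3, all carbon single bonds: distances {1, 1, 2} -> 1 + 1 + 1/2
  expect_equal(harary_barysz(parse_smiles("CCC")), 2.5, tolerance = 1e-12)
  # P4: distances {1,1,1,2,2,3} -> 3 + 1 + 1/3
  expect_equal(harary_barysz(parse_smiles("CCCC")), 3 + 1 + 1 / 3,
               tolerance = 1e-12)
})

test_that("H_Dz(p) agrees with the Floyd-Warshall matrix oracle", {
  props <- atom_properties()
  for (g in fixture_graphs(20)) {
    expect_equal(harary_barysz(g, props), oracle_harary(g, props),
                 tolerance = 1e-10)
  }
})

test_that("a heavier terminal heteroatom strictly increases H_Dz(p)", {
  # replacing terminal C by S (polarizability > carbon) shortens incident
  # edges, so every reciprocal distance through it can only grow
  expect_gt(harary_barysz(parse_smiles("CCCS")),
            harary_barysz(parse_smiles("CCCC")))
  expect_gt(harary_barysz(parse_smiles("CCBr")),
            harary_barysz(parse_smiles("CCC")))
})

test_that("matrix descriptors are invariant under atom reindexing", {
  props <- atom_properties()
  set.seed(42)
  for (g in fixture_graphs(20)) {
    perm <- sample(nrow(g$atoms))
    gs <- shuffle_graph(g, perm)
    expect_equal(ve1_laplacian(gs), ve1_laplacian(g), tolerance = 1e-9)
    expect_equal(sppos_adjacency(gs), sppos_adjacency(g), tolerance = 1e-9)
    expect_equal(spmax2_burden(gs, props), spmax2_burden(g, props),
                 tolerance = 1e-9)
    expect_equal(harary_barysz(gs, props), harary_barysz(g, props),
                 tolerance = 1e-9)
  }
})

test_that("the smallest Laplacian eigenvalue is zero on connected graphs", {
  for (g in fixture_graphs(20)) {
    ev <- oracle_laplacian_spectrum(g)$values
    expect_lt(abs(min(ev)), 1e-10)
  }
})

test_that("unsupported elements raise a named error", {
  g <- make_graph(c("C", "Xx"), data.frame(i = 1, j = 2, order = 1,
                                           aromatic = FALSE))
  expect_error(spmax2_burden(g), "Xx")
  expect_error(harary_barysz(g), "Xx")
})

test_that("lead-like scores take only m/k values and drop per violation", {
  rules <- lls_rulesets()
  graphs <- fixture_graphs(20)
  for (g in graphs) {
    s6 <- leadlike_score(g, rules$congreve6)
    s8 <- leadlike_score(g, rules$monge8)
    expect_true(s6 %in% ((0:6) / 6))
    expect_true(s8 %in% ((0:8) / 8))
  }
  # a permissive rule set scores 1; impossible bounds score 0; exactly two
  # violated of eight scores 0.75
  g <- parse_smiles("CCCCCCCCO")
  all_pass <- lls_rulesets(
    monge8 = tibble::tibble(property = rep("mw", 8), min = -Inf, max = Inf)
  )$monge8
  expect_equal(leadlike_score(g, all_pass), 1)
  none_pass <- tibble::tibble(property = rep("mw", 8), min = Inf, max = Inf)
  expect_equal(leadlike_score(g, none_pass), 0)
  two_fail <- tibble::tibble(
    property = c("mw", "hbd", rep("heavy_atoms", 6)),
    min = c(Inf, Inf, rep(-Inf, 6)), max = Inf
  )
  expect_equal(leadlike_score(g, two_fail), 0.75)
})

test_that("the batch driver fills all six descriptors and reports failures", {
  tab <- mol_descriptors(tibble::tibble(smiles = c("c1ccccc1", "CC")))
  expect_equal(nrow(tab), 2)
  expect_true(all(descriptor_names() %in% names(tab)))
  expect_false(anyNA(tab[descriptor_names()]))
  expect_equal(tab$SpPos_A, c(4, 1), tolerance = 1e-10)
  expect_true(all(tab$LLS_01 >= 0 & tab$LLS_01 <= 1))
  expect_true(all(tab$LLS_02 >= 0 & tab$LLS_02 <= 1))

  empty <- mol_descriptors(tibble::tibble(smiles = character()))
  expect_equal(nrow(empty), 0)
  expect_true(all(descriptor_names() %in% names(empty)))

  mixed <- mol_descriptors(tibble::tibble(smiles = c("CCO", "not_a_smiles")))
  expect_equal(nrow(mixed), 1)
  fails <- attr(mixed, "failures")
  expect_equal(nrow(fails), 1)
  expect_match(fails$smiles, "not_a_smiles")
})
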