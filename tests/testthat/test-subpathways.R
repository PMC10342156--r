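test_that("distance-k cliques on hand-checked topologies", {
  # path a-b-c-d-e has diameter 4: one subpathway at k = 4
  p5 <- pathway_graph("p5", rbind(c("a", "b"), c("b", "c"), c("c", "d"),
                                  c("d", "e")))
  sp <- extract_k_clique_subpathways(p5, k = 4)
  expect_length(sp, 1)
  expect_identical(sp[[1]]$genes, c("a", "b", "c", "d", "e"))
  expect_identical(sp[[1]]$subpathway_id, "p5_1")

  # two disjoint triangles at k = 2: exactly the two triangles
  tri <- pathway_graph("tt", rbind(c("a", "b"), c("b", "c"), c("a", "c"),
                                   c("x", "y"), c("y", "z"), c("x", "z")))
  sp2 <- extract_k_clique_subpathways(tri, k = 2)
  expect_length(sp2, 2)
  expect_setequal(lapply(sp2, `[[`, "genes"),
                  list(c("a", "b", "c"), c("x", "y", "z")))

  # a single edge never reaches the size floor
  expect_length(extract_k_clique_subpathways(
    pathway_graph("e", rbind(c("a", "b"))), k = 4, min_size = 3), 0)
})

test_that("extractor agrees with the brute-force subset oracle", {
  set.seed(13)
  for (i in 1:60) {
    n <- sample(4:10, 1)
    k <- sample(1:4, 1)
    g <- random_pathway_graph("rg", n, edge_prob = stats::runif(1, 0.15, 0.5))
    if (!nrow(g$edges)) next
    pg <- pathway_graph("rg", g$edges, nodes = g$nodes)
    got <- lapply(extract_k_clique_subpathways(pg, k = k, min_size = 3),
                  `[[`, "genes")
    want <- oracle_k_clique(pg$nodes, pg$edges, k = k, min_size = 3)
    expect_setequal(got, want)
  }
})

test_that("Welch t statistics: orientation, degenerate inputs", {
  stage <- rep(c("primordial", "primary"), each = 3)
  v <- rbind(flat = rep(2, 6),
             up = c(1, 2, 3, 4, 5, 6),
             novar = c(0, 0, 0, 1, 1, 1))
  colnames(v) <- sprintf("c%d", 1:6)
  mat <- toy_matrix(v, stage = stage)
  a <- sprintf("c%d", 1:3); b <- sprintf("c%d", 4:6)
  expect_warning(t <- gene_t_scores(mat, a, b), "zero-variance")
  expect_equal(unname(t["flat"]), 0)
  # hand Welch: means 2 vs 5, var 1 each, se = sqrt(2/3)
  expect_equal(unname(t["up"]), 3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(unname(t["up"]), 3.674, tolerance = 1e-3)
  expect_identical(unname(t["novar"]), Inf)
  expect_error(gene_t_scores(mat, a[1], b), "2 cells")
})

test_that("activity is the mean of finite t scores", {
  expect_equal(as.numeric(subpathway_activity(rep(2, 5))), 2)
  expect_equal(as.numeric(subpathway_activity(c(1, -1))), 0)
  expect_equal(as.numeric(subpathway_activity(c(3, 0, 0))), 1)
  a <- subpathway_activity(c(2, Inf, 4))
  expect_equal(as.numeric(a), 3)
  expect_identical(attr(a, "n"), 2L)
  expect_error(subpathway_activity(c(Inf, -Inf)), "finite")
})

test_that("permutation p is degenerate when the set exhausts the pool", {
  set.seed(2)
  stage <- rep(c("primordial", "primary"), each = 5)
  v <- matrix(rnorm(40, 3), 4, 10,
              dimnames = list(sprintf("G%d", 1:4), sprintf("c%d", 1:10)))
  mat <- toy_matrix(pmax(v, 0), stage = stage)
  p <- permutation_pvalue(mat, sprintf("G%d", 1:4),
                          sprintf("c%d", 1:5), sprintf("c%d", 6:10),
                          B = 50, seed = 1)
  expect_identical(p, 1)
  expect_error(permutation_pvalue(mat, "nope", sprintf("c%d", 1:5),
                                  sprintf("c%d", 6:10), B = 10, seed = 1),
               "no measured genes")
})

test_that("activity table is seeded and reproducible", {
  sim <- simulate_dataset(simulation_config(seed = 8, n_pc_genes = 150,
                                            n_lnc_genes = 10,
                                            n_planted_de_lnc = 2,
                                            n_pathways = 2))
  m <- sim$expression
  sp <- unlist(lapply(sim$pathways, extract_k_clique_subpathways),
               recursive = FALSE)
  a_cells <- cells_for(m, "follicle", "primordial")
  b_cells <- cells_for(m, "follicle", "primary")
  t1 <- subpathway_activity_table(m, sp, a_cells, b_cells, B = 100, seed = 3)
  t2 <- subpathway_activity_table(m, sp, a_cells, b_cells, B = 100, seed = 3)
  expect_identical(t1, t2)
  # activity equals an independent mean-of-t recomputation
  tall <- suppressWarnings(gene_t_scores(m, a_cells, b_cells))
  for (i in seq_len(nrow(t1))) {
    genes <- sp[[match(t1$subpathway_id[i],
                       vapply(sp, `[[`, "", "subpathway_id"))]]$genes
    expect_equal(t1$activity[i], mean(tall[intersect(genes, names(tall))]),
                 tolerance = 1e-12)
  }
  expect_true(all(t1$perm_p >= 1 / 101))
})

test_that("specificity: uniform matrix, two-type ratio, conservation", {
  # uniform expression: specificity identically 1
  u <- matrix(3, 4, 6, dimnames = list(sprintf("G%d", 1:4),
                                       sprintf("c%d", 1:6)))
  mat <- toy_matrix(u)
  types <- rep(c("A", "B", "C"), each = 2)
  sp <- list(list(subpathway_id = "s1", genes = c("G1", "G2")))
  out <- pathway_specificity(mat, sp, types)
  expect_equal(unname(out$specificity["s1", ]), c(1, 1, 1))

  # two equal types with E1 = 2 E2 -> specificities (4/3, 2/3)
  v <- matrix(0, 1, 6, dimnames = list("G1", sprintf("c%d", 1:6)))
  v[1, ] <- c(2, 2, 2, 1, 1, 1)
  m2 <- toy_matrix(v)
  out2 <- pathway_specificity(m2, list(list(subpathway_id = "s", genes = "G1")),
                              rep(c("hi", "lo"), each = 3))
  expect_equal(unname(out2$specificity["s", ]), c(4 / 3, 2 / 3))

  # all-zero subpathway flagged undefined
  z <- toy_matrix(matrix(0, 1, 4, dimnames = list("G1", sprintf("c%d", 1:4))))
  out3 <- pathway_specificity(z, list(list(subpathway_id = "z", genes = "G1")),
                              rep(c("A", "B"), 2))
  expect_identical(out3$undefined, "z")
  expect_true(all(is.na(out3$specificity)))

  # conservation on simulated data: sum_j (n_j/N) spec_ij = 1
  sim <- simulate_dataset(simulation_config(seed = 3, n_pc_genes = 150,
                                            n_lnc_genes = 10,
                                            n_planted_de_lnc = 2,
                                            n_pathways = 2))
  subs <- unlist(lapply(sim$pathways, extract_k_clique_subpathways),
                 recursive = FALSE)
  ct <- interaction(sim$expression$cell_lineage, sim$expression$cell_stage,
                    drop = TRUE)
  res <- pathway_specificity(sim$expression, subs, ct)
  w <- res$n_cells / sum(res$n_cells)
  defined <- setdiff(rownames(res$specificity), res$undefined)
  for (id in defined)
    expect_equal(sum(w * res$specificity[id, ]), 1, tolerance = 1e-10)
})

test_that("ssGSEA: boundary set, determinism, top-rank maximality", {
  v <- matrix(c(8:1, 1:8), 8, 2,
              dimnames = list(sprintf("G%d", 1:8), c("c1", "c2")))
  mat <- toy_matrix(v)
  expect_warning(all_set <- ssgsea_scores(mat, list(all = rownames(v))),
                 "every measured gene")
  expect_equal(unname(all_set["all", ]), c(0, 0))

  # identical cells get identical scores
  v2 <- matrix(rep(c(5, 3, 2, 7, 1, 4, 6, 8), 2), 8, 2,
               dimnames = list(sprintf("G%d", 1:8), c("c1", "c2")))
  s2 <- ssgsea_scores(toy_matrix(v2), list(s = c("G1", "G4", "G8")))
  expect_identical(s2[1, 1], s2[1, 2])

  # a set occupying the top |S| ranks maximizes the score over all subsets
  sets <- utils::combn(rownames(v), 3, simplify = FALSE)
  names(sets) <- vapply(sets, paste, "", collapse = "_")
  scores <- ssgsea_scores(mat, sets)[, "c1"]
  top <- paste(c("G1", "G2", "G3"), collapse = "_")  # top-3 in c1
  expect_identical(names(which.max(scores)), top)

  # missing set reported as NA
  na_set <- ssgsea_scores(mat, list(gone = c("nope1", "nope2")))
  expect_true(all(is.na(na_set["gone", ])))
})
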