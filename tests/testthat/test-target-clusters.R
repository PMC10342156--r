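test_that("pairwise PCC basics and zero-variance exclusion", {
  set.seed(1)
  x <- rnorm(10)
  v <- rbind(a = x, b = -x, const = rep(2, 10))
  colnames(v) <- sprintf("c%d", 1:10)
  mat <- toy_matrix(v - min(v))
  r <- pairwise_pcc(mat, rownames(v), colnames(v))
  expect_equal(unname(diag(r)), c(1, 1))
  expect_equal(r["a", "b"], -1)
  expect_false("const" %in% rownames(r))
  expect_identical(attr(r, "excluded"), "const")
  expect_error(pairwise_pcc(mat, rownames(v), colnames(v)[1:2]), "3 cells")
})

test_that("complete-linkage cut reproduces hand-computed merges", {
  # all pairs at 0.9: a single cluster of 3
  p1 <- matrix(0.9, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(p1) <- 1
  expect_identical(cut_clusters(p1), list(c("a", "b", "c")))

  # pairs (ab, ac, bc) = (0.9, 0.9, 0.5): complete linkage merges {a,b} at
  # 0.1, then c joins at max(0.1, 0.5) = 0.5 > 0.3 cut -> no size-3 cluster
  p2 <- p1; p2["b", "c"] <- p2["c", "b"] <- 0.5
  expect_identical(cut_clusters(p2), list())

  # two blocks of 4 at 0.85 inside, 0 between: exactly the two blocks
  p3 <- matrix(0, 8, 8, dimnames = list(letters[1:8], letters[1:8]))
  p3[1:4, 1:4] <- 0.85; p3[5:8, 5:8] <- 0.85; diag(p3) <- 1
  cl <- cut_clusters(p3)
  expect_length(cl, 2)
  expect_setequal(vapply(cl, paste, "", collapse = ""),
                  c("abcd", "efgh"))
})

test_that("every retained cluster pair sits above the correlation threshold", {
  set.seed(7)
  for (i in 1:20) {
    n <- 12
    v <- matrix(rnorm(n * n), n)  # random symmetric correlation-ish matrix
    r <- stats::cov2cor(crossprod(v) + diag(n))
    dimnames(r) <- list(sprintf("g%d", 1:n), sprintf("g%d", 1:n))
    for (cl in cut_clusters(r, threshold = 0.7, min_size = 2)) {
      sub <- r[cl, cl]
      expect_gte(min(sub[upper.tri(sub)]), 0.7)
    }
  }
})

test_that("SVM AUC: separable, null, constant-feature and determinism", {
  set.seed(3)
  stage <- rep(c("primordial", "primary"), each = 15)
  v <- matrix(rnorm(5 * 30, 5, 1), 5, 30,
              dimnames = list(sprintf("G%d", 1:5), sprintf("c%d", 1:30)))
  v[, 16:30] <- v[, 16:30] + 3  # +3 sd shift on every gene
  mat <- toy_matrix(pmax(v, 0), stage = stage)
  sep <- cluster_auc(mat, rownames(v), colnames(v), reps = 20, seed = 1)
  expect_gte(sep$mean_auc, 0.95)

  # permuted labels concentrate near 0.5
  set.seed(11)
  perm <- sample(stage)
  nul <- cluster_auc(mat, rownames(v), colnames(v),
                     labels = factor(perm, c("primordial", "primary")),
                     reps = 100, seed = 2)
  expect_gte(nul$mean_auc, 0.40)
  expect_lte(nul$mean_auc, 0.60)

  # single constant feature: all decision values tie -> AUC 1/2
  cm <- toy_matrix(matrix(1, 1, 30,
                          dimnames = list("flat", sprintf("c%d", 1:30))),
                   stage = stage)
  flat <- cluster_auc(cm, "flat", sprintf("c%d", 1:30), reps = 5, seed = 1)
  expect_equal(flat$mean_auc, 0.5)

  # same seed reproduces the whole repetition vector
  again <- cluster_auc(mat, rownames(v), colnames(v), reps = 20, seed = 1)
  expect_identical(sep$auc_per_repetition, again$auc_per_repetition)

  expect_error(cluster_auc(mat, rownames(v), colnames(v)[1:15], seed = 1),
               "two classes")
})

test_that("rank AUC matches pROC on random scores with ties", {
  skip_if_not_installed("pROC")
  set.seed(5)
  for (i in 1:10) {
    y <- rep(c(0, 1), each = 20)
    s <- round(rnorm(40, y), 1)  # rounding induces ties
    ours <- lncPFA:::auc_rank(s, y == 1)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("cluster building respects AUC gate and minimum size", {
  sim <- simulate_dataset(simulation_config(seed = 4))
  m <- sim$expression
  pairs <- call_cerna_pairs(sim$interactions,
                            genes_of_biotype(m, "lncRNA"),
                            genes_of_biotype(m, "protein_coding"))
  # unattainable bound: nothing retained
  suppressMessages({
    none <- build_target_clusters(m, pairs, "follicle", auc_min = 1.01,
                                  reps = 5, seed = 1)
  })
  expect_length(none, 0)
  # an lncRNA with fewer than 3 targets yields no cluster
  two <- pairs[pairs$lncRNA == pairs$lncRNA[1], ][1:2, ]
  suppressMessages({
    small <- build_target_clusters(m, two, "follicle", reps = 5, seed = 1)
  })
  expect_length(small, 0)
})

test_that("planted clusters are recovered with high fidelity", {
  skip_if_not_installed("mclust")
  sim <- simulate_dataset(simulation_config(seed = 6))
  m <- sim$expression
  pairs <- call_cerna_pairs(sim$interactions,
                            genes_of_biotype(m, "lncRNA"),
                            genes_of_biotype(m, "protein_coding"))
  suppressMessages({
    cl <- build_target_clusters(m, pairs, "follicle", reps = 25, seed = 9)
  })
  expect_gt(length(cl), 0)
  planted <- sim$truth$planted_clusters[
    sim$truth$planted_de_lnc$follicle]
  # each planted lncRNA has >= 1 retained cluster matching one of its
  # planted clusters at Jaccard >= 0.8
  for (L in names(planted)) {
    own <- cl[vapply(cl, `[[`, "", "lncRNA") == L]
    jac <- 0
    for (x in own) for (pg in planted[[L]])
      jac <- max(jac, length(intersect(x$genes, pg)) /
                        length(union(x$genes, pg)))
    expect_gte(jac, 0.8)
  }
})
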