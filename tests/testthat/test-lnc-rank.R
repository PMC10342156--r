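test_that("overlap tail shares the ceRNA kernel and handles boundaries", {
  uni <- sprintf("g%02d", 1:20)
  cl <- uni[1:5]; sp <- uni[1:5]
  expect_equal(overlap_pvalue(cl, sp, uni), 1 / 15504, tolerance = 1e-12)
  # exactly the ceRNA tail on the same (m, t, n, r)
  expect_identical(overlap_pvalue(cl, sp, uni),
                   shared_mirna_pvalue(20, 5, 5, 5))
  # zero overlap and certain event both give q = 1
  expect_identical(overlap_pvalue(uni[1:4], uni[5:8], uni), 1)
  expect_identical(overlap_pvalue(uni[1:3], uni, uni), 1)
  expect_error(overlap_pvalue(c("zz"), sp, uni), "outside the universe")
})

test_that("entropy of an overlap p-value", {
  expect_identical(entropy_score(1), 0)
  expect_equal(entropy_score(0.01), 2)
  expect_equal(entropy_score(1e-5), 5)
  expect_error(entropy_score(0), "\\(0, 1\\]")
  expect_error(entropy_score(1.2), "\\(0, 1\\]")
})

test_that("LR score: averaging, q = 1 contribution, deduplication", {
  one <- data.frame(subpathway_id = "s1", q = 0.1, P = 2)
  expect_equal(lr_score(one)$LR, 2)
  two <- data.frame(subpathway_id = c("s1", "s2"), q = c(0.1, 0.01),
                    P = c(2, 1))
  expect_equal(lr_score(two)$LR, (1 * 2 + 2 * 1) / 2)
  # q = 1 contributes nothing regardless of P
  with1 <- data.frame(subpathway_id = c("s1", "s2"), q = c(0.1, 1),
                      P = c(2, 50))
  expect_equal(lr_score(with1)$LR, 1)
  expect_identical(lr_score(with1)$n_links, 2L)
  # several clusters hitting one subpathway count once, smallest q wins
  dup <- data.frame(subpathway_id = c("s1", "s1", "s2"),
                    q = c(0.1, 0.001, 0.01), P = c(2, 2, 1))
  sc <- lr_score(dup)
  expect_identical(sc$n_links, 2L)
  expect_equal(sc$LR, (3 * 2 + 2 * 1) / 2)
  # invariant to row order
  expect_equal(lr_score(dup[c(3, 1, 2), ])$LR, sc$LR)
  expect_error(lr_score(dup[0, ]), "at least one link")
})

test_that("dropping a below-average link raises the mean LR", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    links <- data.frame(subpathway_id = sprintf("s%d", 1:n),
                        q = stats::runif(n, 0.001, 0.5),
                        P = stats::rnorm(n, 2))
    full <- lr_score(links)
    contrib <- entropy_score(links$q) * links$P
    low <- which.min(contrib)
    if (contrib[low] < full$LR) {
      reduced <- lr_score(links[-low, ])
      expect_gt(reduced$LR, full$LR)
    }
  }
})

test_that("network assembly links planted clusters to their subpathways", {
  sim <- simulate_dataset(simulation_config(seed = 10))
  m <- sim$expression
  tr <- sim$truth
  # take the planted clusters directly as TargetCluster stand-ins
  clusters <- list()
  for (mod in tr$planted_modules[vapply(tr$planted_modules, `[[`, "",
                                        "lineage") == "follicle"])
    clusters[[length(clusters) + 1L]] <-
      structure(list(lncRNA = mod$lncRNA, cluster_index = mod$cluster_index,
                     genes = mod$cluster_genes, mean_auc = 1),
                class = "TargetCluster")
  sp <- unlist(lapply(sim$pathways, extract_k_clique_subpathways),
               recursive = FALSE)
  a <- cells_for(m, "follicle", "primordial")
  b <- cells_for(m, "follicle", "primary")
  act <- subpathway_activity_table(m, sp, a, b, B = 200, seed = 1)
  uni <- intersect(genes_of_biotype(m, "protein_coding"),
                   unique(unlist(lapply(sim$pathways, `[[`, "nodes"))))
  net <- assemble_network(clusters, act, sp, uni, poi = tr$poi_genes)
  # every planted follicle (lncRNA, pathway) link is present
  got <- unique(paste(net$links$lncRNA,
                      sub("_[0-9]+$", "", net$links$subpathway_id)))
  planted <- tr$planted_links[tr$planted_links$lncRNA %in%
                                tr$planted_de_lnc$follicle, ]
  expect_true(all(paste(planted$lncRNA, planted$pathway_id) %in% got))
  # ranks ordered by descending LR
  expect_true(all(diff(net$ranks$LR) <= 1e-12))
  # poi genes appear in annotations, and edges carry the three types
  expect_true(any(nzchar(net$links$poi_overlap)))
  expect_setequal(unique(vapply(net$network$edges, `[[`, "", "type")),
                  c("targets", "member_of", "overlaps_poi"))

  # alpha_link = 0 empties the network; empty poi removes poi edges
  none <- assemble_network(clusters, act, sp, uni, alpha_link = 0)
  expect_identical(nrow(none$links), 0L)
  nopoi <- assemble_network(clusters, act, sp, uni, poi = character())
  expect_false(any(vapply(nopoi$network$edges, `[[`, "", "type") ==
                     "overlaps_poi"))
})

test_that("knockdown direction summary and exact sign test", {
  ctrl <- matrix(5, 6, 4, dimnames = list(sprintf("G%d", 1:6),
                                          sprintf("c%d", 1:4)))
  # knockdown identical to control: nothing is down, p = 1
  same <- knockdown_direction_summary(ctrl, ctrl, rownames(ctrl))
  expect_identical(same$fraction_down, 0)
  expect_identical(same$sign_test_p, 1)
  # all six genes down: fraction 1, p = (1/2)^6
  kd <- ctrl - 1
  down <- knockdown_direction_summary(ctrl, kd, rownames(ctrl))
  expect_identical(down$fraction_down, 1)
  expect_equal(down$sign_test_p, (1 / 2)^6, tolerance = 1e-12)
  expect_error(knockdown_direction_summary(ctrl, kd, "absent"),
               "no shared")
})
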