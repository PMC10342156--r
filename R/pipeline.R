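#' Write a simulated input bundle to disk
#'
#' Emits the expression TSV with its metadata TSVs, the interaction TSV,
#' the pathway edge-list TSV, the POI gene list as GMT, the ground truth
#' as JSON and a run manifest (configuration + seed) as JSON.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             cell_metadata = file.path(dir, "cell_metadata.tsv"),
             gene_metadata = file.path(dir, "gene_metadata.tsv"),
             interactions = file.path(dir, "interactions.tsv"),
             pathway_edges = file.path(dir, "pathway_edges.tsv"),
             poi = file.path(dir, "poi_genes.gmt"),
             ground_truth = file.path(dir, "ground_truth.json"),
             manifest = file.path(dir, "manifest.json"))
  write_expression_table(sim$expression, paths["expression"],
                         paths["cell_metadata"], paths["gene_metadata"])
  write_interaction_table(sim$interactions, paths["interactions"])
  write_pathway_edges(sim$pathways, paths["pathway_edges"])
  write_gene_sets_gmt(list(POI = sim$truth$poi_genes), paths["poi"],
                      description = c(POI = "simulated disease gene list"))
  jsonlite::write_json(sim$truth, paths["ground_truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(list(config = unclass(sim$config)),
                       paths["manifest"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full lncRNA-subpathway pipeline on simulated data
#'
#' End-to-end, per lineage: expressed-feature filtering, stage-wise
#' Wilcoxon differential expression of lncRNAs, ceRNA pair calling,
#' stage-discriminative target clustering, subpathway extraction and
#' activity/permutation scoring, cell-type specificity and per-cell ssGSEA
#' profiles, and the lncRNA-subpathway network with LR ranks and POI
#' annotation. All result tables are written as TSV (network and manifest
#' as JSON); with a fixed seed the outputs are byte-identical across runs.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed driving the simulation and every stochastic
#'   stage.
#' @param cfg Simulation configuration; defaults to
#'   `simulation_config(seed = seed)`.
#' @param lineages Lineages to analyse.
#' @param k,min_size Subpathway extraction parameters.
#' @param B Activity permutations.
#' @param reps SVM cross-validation repetitions.
#' @param alpha,alpha_link,alpha_dyn Significance thresholds (ceRNA calls,
#'   overlap links, dynamic subpathways).
#' @return Invisibly, a list with the per-lineage results and the paths of
#'   every file written.
#' @export
run_pipeline <- function(out_dir, seed = 1L,
                         cfg = simulation_config(seed = seed),
                         lineages = c("follicle", "granulosa"),
                         k = 4, min_size = 3, B = 1000, reps = 100,
                         alpha = 0.05, alpha_link = 0.05,
                         alpha_dyn = 0.05) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_dataset(cfg)
  paths <- write_simulation(sim, file.path(out_dir, "inputs"))
  mat <- sim$expression

  subpathways <- unlist(lapply(sim$pathways, extract_k_clique_subpathways,
                               k = k, min_size = min_size),
                        recursive = FALSE)
  write_gene_sets_gmt(
    stats::setNames(lapply(subpathways, `[[`, "genes"),
                    vapply(subpathways, `[[`, "", "subpathway_id")),
    file.path(out_dir, "subpathways.gmt"))

  pathway_nodes <- unique(unlist(lapply(sim$pathways, `[[`, "nodes")))
  results <- list()
  for (lin in lineages) {
    message("lineage ", lin, ": filtering features")
    report <- select_expressed_features(mat, lin)
    write_tsv(report$diagnostics,
              file.path(out_dir, paste0("expressed_features_", lin, ".tsv")))

    a_cells <- cells_for(mat, lineage = lin, stage = "primordial")
    b_cells <- cells_for(mat, lineage = lin, stage = "primary")
    lnc_feats <- intersect(report$retained, genes_of_biotype(mat, "lncRNA"))
    de <- wilcoxon_de(mat, a_cells, b_cells, features = lnc_feats)
    write_tsv(de, file.path(out_dir, paste0("de_lncRNA_", lin, ".tsv")))

    pc_feats <- intersect(report$retained,
                          genes_of_biotype(mat, "protein_coding"))
    pairs <- call_cerna_pairs(sim$interactions, lnc_feats, pc_feats,
                              alpha = alpha)
    write_tsv(pairs, file.path(out_dir, paste0("cerna_pairs_", lin, ".tsv")))

    clusters <- build_target_clusters(mat, pairs, lin, reps = reps,
                                      seed = cfg$seed + 100L)
    cl_df <- do.call(rbind, c(list(data.frame(
      lncRNA = character(), cluster_index = integer(), gene = character(),
      mean_auc = numeric())),
      lapply(clusters, function(cl)
        data.frame(lncRNA = cl$lncRNA, cluster_index = cl$cluster_index,
                   gene = cl$genes, mean_auc = cl$mean_auc))))
    write_tsv(cl_df, file.path(out_dir, paste0("clusters_", lin, ".tsv")))

    activity <- subpathway_activity_table(mat, subpathways, a_cells, b_cells,
                                          B = B, seed = cfg$seed + 200L)
    write_tsv(activity, file.path(out_dir, paste0("activity_", lin, ".tsv")))

    cell_types <- interaction(droplevels(mat$cell_lineage),
                              droplevels(mat$cell_stage), sep = ":")
    spec <- pathway_specificity(mat, subpathways, cell_types)
    write_tsv(data.frame(subpathway_id = rownames(spec$specificity),
                         spec$specificity, check.names = FALSE),
              file.path(out_dir, paste0("specificity_", lin, ".tsv")))

    ssg <- ssgsea_scores(
      subset_expression(mat, cells = cells_for(mat, lineage = lin)),
      stats::setNames(lapply(subpathways, `[[`, "genes"),
                      vapply(subpathways, `[[`, "", "subpathway_id")))
    write_tsv(data.frame(subpathway_id = rownames(ssg), ssg,
                         check.names = FALSE),
              file.path(out_dir, paste0("ssgsea_", lin, ".tsv")))

    universe <- intersect(pc_feats, pathway_nodes)
    net <- assemble_network(clusters, activity, subpathways, universe,
                            alpha_link = alpha_link, alpha_dyn = alpha_dyn,
                            poi = sim$truth$poi_genes)
    write_tsv(net$links, file.path(out_dir, paste0("links_", lin, ".tsv")))
    write_tsv(net$ranks, file.path(out_dir, paste0("ranks_", lin, ".tsv")))
    jsonlite::write_json(net$network,
                         file.path(out_dir, paste0("network_", lin, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    results[[lin]] <- list(report = report, de = de, pairs = pairs,
                           clusters = clusters, activity = activity,
                           specificity = spec, network = net)
  }
  invisible(list(sim = sim, subpathways = subpathways, results = results,
                 out_dir = out_dir))
}
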