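#' Run the full synthetic co-occurrence analysis pipeline
#'
#' Simulates a treatment-structured cross-domain community, then runs every
#' analysis stage: abundance/prevalence filtering, Spearman edge inference,
#' network assembly, the topology panel, stability (robustness and the
#' natural-connectivity decay curve), module detection with Zi-Pi role
#' classification, keystone abundance summaries, alpha/beta diversity
#' (ACE, Gini-Simpson, rarefaction, Bray-Curtis, ANOSIM), per-treatment
#' networks, treatment summaries with LSD letters, the Pearson
#' environment-vs-topology panel and LMG relative importance of soil
#' variables for plant growth. When \code{out_dir} is given every result is
#' also written to disk (TSV/CSV/GraphML/JSON).
#'
#' @param design A [study_design()]; the default emulates a 4x3
#'   phosphorus-addition experiment with 505 + 87 retained taxa.
#' @param out_dir Optional output directory (created if missing).
#' @param rho2_threshold,alpha Edge retention thresholds, see
#'   [spearman_edges()].
#' @param robustness_fraction Fraction of nodes removed for robustness.
#' @param robustness_reps Random-removal replicates.
#' @param decay_step Node-removal increment of the decay curve.
#' @param anosim_permutations Permutations for the ANOSIM test.
#' @param module_method Passed to [detect_modules()].
#' @param seed Seed for the stochastic analysis stages (removal orders,
#'   permutations); the simulation itself uses \code{design$seed}.
#' @return Invisible list with all intermediate and final results.
#' @export
run_pipeline <- function(design = study_design(),
                         out_dir = NULL,
                         rho2_threshold = 0.9,
                         alpha = 0.05,
                         robustness_fraction = 0.5,
                         robustness_reps = 50,
                         decay_step = 25,
                         anosim_permutations = 999,
                         module_method = "greedy",
                         seed = 1L) {
  sim <- simulate_counts(design)
  metadata <- simulate_env_and_traits(design)

  filtered <- filter_taxa(sim$table)
  edges <- spearman_edges(filtered, rho2_threshold = rho2_threshold,
                          alpha = alpha)
  net <- build_network(edges, sim$taxonomy)
  topo <- topology_summary(net)
  stab <- robustness(net, fraction = robustness_fraction,
                     n_reps = robustness_reps, seed = seed)
  decay <- connectivity_decay_curve(net, step = decay_step, n_reps = 10,
                                    seed = seed + 1L)
  modules <- detect_modules(net, method = module_method, seed = seed)
  roles <- classify_nodes(zi_pi(net, modules))
  roles$domain <- igraph::V(net)$domain[match(roles$node, igraph::V(net)$name)]
  key_ab <- keystone_abundance(roles, sim$table, sim$taxonomy, metadata)

  alpha_div <- alpha_diversity(filtered)
  depth_grid <- unique(round(seq(1, min(colSums(sim$table)), length.out = 12)))
  raref <- do.call(rbind, lapply(colnames(sim$table), function(s) {
    cbind(sample_id = s, rarefaction_curve(sim$table[, s], depth_grid))
  }))
  bc <- bray_curtis(filtered)
  community_test <- anosim(bc, metadata$treatment,
                           n_perm = anosim_permutations, seed = seed + 2L)

  per_treatment <- lapply(design$treatment_labels, function(tr) {
    treatment_network(sim$table, metadata, sim$taxonomy, tr,
                      rho2_threshold = rho2_threshold, alpha = alpha)
  })
  names(per_treatment) <- design$treatment_labels
  topo_by_treatment <- do.call(rbind, lapply(per_treatment, topology_summary))
  topo_by_treatment <- cbind(treatment = design$treatment_labels,
                             topo_by_treatment)
  rownames(topo_by_treatment) <- NULL
  robust_by_treatment <- vapply(per_treatment, function(g) {
    robustness(g, fraction = robustness_fraction, n_reps = robustness_reps,
               seed = seed)$robustness_mean
  }, numeric(1))

  env_vars <- c("pH", "EC", "AP", "AN", "AK", "TP", "TN", "TC", "CN")
  env_means <- stats::aggregate(metadata[, env_vars],
                                list(treatment = metadata$treatment), mean)
  env_means <- env_means[match(design$treatment_labels, env_means$treatment), ]
  topo_num <- topo_by_treatment[, c("edges", "nodes", "positive_pct",
                                    "edge_density", "average_degree",
                                    "average_path_length")]
  topo_num$robustness <- robust_by_treatment
  env_topo_cor <- pearson_matrix(env_means[, env_vars], topo_num)

  summaries <- treatment_summary(metadata,
                                 variables = c(env_vars, "stem_number",
                                               "biomass", "height"))
  importance <- lapply(c("stem_number", "biomass", "height"), function(tr) {
    lmg_importance(metadata[[tr]],
                   metadata[, c("pH", "EC", "AP", "AN", "AK", "TP")])
  })
  names(importance) <- c("stem_number", "biomass", "height")

  res <- list(simulation = sim, metadata = metadata, filtered = filtered,
              edges = edges, network = net, topology = topo,
              stability = stab, decay_curve = decay, modules = modules,
              roles = roles, keystone_abundance = key_ab,
              alpha_diversity = alpha_div, rarefaction = raref,
              bray_curtis = bc, anosim = community_test,
              per_treatment_networks = per_treatment,
              topology_by_treatment = topo_by_treatment,
              robustness_by_treatment = robust_by_treatment,
              env_topology_correlation = env_topo_cor,
              treatment_summaries = summaries,
              importance = importance)

  if (!is.null(out_dir)) .write_pipeline_outputs(res, out_dir)
  invisible(res)
}

.write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  write_asv_table(res$simulation$table, fp("asv_table.tsv"))
  write_taxonomy(res$simulation$taxonomy, fp("taxonomy.tsv"))
  write_metadata(res$metadata, fp("metadata.tsv"))
  write_asv_table(res$filtered, fp("asv_table_filtered.tsv"))
  write_network(res$network, fp("network_edges.csv"), format = "edgelist")
  write_network(.attach_roles(res$network, res$roles, res$modules),
                fp("network.graphml"), format = "graphml")
  write_metrics_json(res$topology, fp("topology.json"))
  utils::write.table(res$topology_by_treatment, fp("topology_by_treatment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$decay_curve, fp("connectivity_decay.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_metrics_json(list(natural_connectivity = res$stability$natural_connectivity_full,
                          robustness_mean = res$stability$robustness_mean,
                          robustness_se = res$stability$robustness_se,
                          n_reps = res$stability$n_reps),
                     fp("stability.json"))
  utils::write.table(res$roles, fp("node_roles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$keystone_abundance, fp("keystone_abundance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$alpha_diversity, fp("alpha_diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$rarefaction, fp("rarefaction.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$bray_curtis, fp("bray_curtis.tsv"),
                     sep = "\t", quote = FALSE, row.names = TRUE,
                     col.names = NA)
  write_metrics_json(list(R = res$anosim$statistic, p = res$anosim$p_value,
                          permutations = res$anosim$n_perm),
                     fp("anosim.json"))
  utils::write.table(res$treatment_summaries, fp("treatment_summaries.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(env = rownames(res$env_topology_correlation$r),
               res$env_topology_correlation$r, check.names = FALSE),
    fp("env_topology_pearson_r.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(env = rownames(res$env_topology_correlation$stars),
               res$env_topology_correlation$stars, check.names = FALSE),
    fp("env_topology_pearson_stars.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  imp <- do.call(rbind, lapply(names(res$importance), function(nm) {
    data.frame(response = nm,
               predictor = names(res$importance[[nm]]$shares),
               share = as.numeric(res$importance[[nm]]$shares),
               r_squared = res$importance[[nm]]$r_squared,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(imp, fp("relative_importance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

.attach_roles <- function(net, roles, modules) {
  idx <- match(igraph::V(net)$name, roles$node)
  net <- igraph::set_vertex_attr(net, "module", value = roles$module[idx])
  net <- igraph::set_vertex_attr(net, "zi", value = roles$zi[idx])
  net <- igraph::set_vertex_attr(net, "pi", value = roles$pi[idx])
  igraph::set_vertex_attr(net, "role", value = as.character(roles$role[idx]))
}
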