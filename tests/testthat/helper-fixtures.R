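# Small study designs and toy graphs used across the test files.

# compact 3-module design: 120 bacteria + 30 fungi in three mixed-domain
# modules (2 fungal hubs each) over 300 background taxa
small_design <- function(seed, latent = 0.95, anti = 0, n_background = 300) {
  bac <- sprintf("ASV_B%04d", 1:120)
  fun <- sprintf("ASV_F%03d", 1:30)
  mods <- lapply(0:2, function(m) {
    members <- c(bac[(m * 40 + 1):(m * 40 + 40)],
                 fun[(m * 10 + 1):(m * 10 + 10)])
    module_spec(members, latent_correlation = latent,
                hub_taxa = fun[(m * 10 + 1):(m * 10 + 2)],
                anti_fraction = anti)
  })
  study_design(n_bacteria = 120, n_fungi = 30, n_background = n_background,
               modules = mods, seed = seed)
}

# one-module design with many samples, used for correlation-target checks;
# 100 independent ballast taxa keep the module a minor share of the
# composition (a module holding most of the reads would cancel its own
# shared factor in the per-sample renormalization)
one_module_design <- function(seed, latent, n_replicates = 25,
                              n_members = 20, hubs = FALSE) {
  bac <- sprintf("ASV_B%04d", seq_len(n_members))
  mod <- module_spec(bac,
                     latent_correlation = latent,
                     hub_taxa = if (hubs) bac[1:2] else character())
  study_design(n_bacteria = n_members + 100, n_fungi = 2, n_background = 0,
               n_replicates = n_replicates, modules = list(mod), seed = seed)
}

toy_taxonomy <- function(ids, domain = "bacteria", phylum = "Proteobacteria") {
  data.frame(taxon_id = ids,
             domain = rep_len(domain, length(ids)),
             phylum = rep_len(phylum, length(ids)),
             stringsAsFactors = FALSE)
}

# undirected graph from an edge matrix given as c(a1,b1, a2,b2, ...)
toy_graph <- function(pairs, n = NULL) {
  g <- igraph::make_graph(as.character(pairs), directed = FALSE)
  if (!is.null(n) && igraph::vcount(g) < n) {
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  }
  g
}

# closed-form natural connectivity of the complete graph K_n
# (eigenvalues n-1 once and -1 with multiplicity n-1)
nc_complete <- function(n) {
  log((exp(n - 1) + (n - 1) * exp(-1)) / n)
}

# seed-stable RNG context for property loops
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(code)
}
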