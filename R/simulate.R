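# Latent log-abundance profiles: each taxon's across-sample profile is
# standardized (mean 0, sd 1), which pins its geometric-mean abundance at its
# base proportion while leaving ranks -- and therefore Spearman correlations
# -- untouched. Module members load on a shared per-sample factor with
# loading sqrt(rho_i); hubs load more strongly.
.latent_profiles <- function(design) {
  n_s <- length(design$sample_ids)
  taxa <- c(design$bacteria_ids, design$fungi_ids, design$background_ids)
  g <- matrix(stats::rnorm(length(taxa) * n_s), length(taxa), n_s,
              dimnames = list(taxa, design$sample_ids))
  for (mod in design$modules) {
    f <- stats::rnorm(n_s)
    members <- mod$member_taxa
    # members load downward from the module target so planted hubs (whose
    # loading exceeds the target) carry systematically stronger couplings
    rho_i <- stats::runif(length(members),
                          mod$latent_correlation - 2 * mod$loading_spread,
                          mod$latent_correlation)
    names(rho_i) <- members
    rho_i[mod$hub_taxa] <- mod$hub_correlation
    sgn <- rep(1, length(members))
    non_hub <- setdiff(members, mod$hub_taxa)
    n_anti <- floor(mod$anti_fraction * length(non_hub))
    if (n_anti > 0) {
      sgn[match(sample(non_hub, n_anti), members)] <- -1
    }
    l <- sqrt(rho_i)
    g[members, ] <- sgn * l * rep(f, each = length(members)) +
      sqrt(1 - rho_i) * g[members, ]
  }
  out <- t(apply(g, 1L, function(x) as.numeric(scale(x))))
  dimnames(out) <- dimnames(g)
  out
}

.base_proportions <- function(design) {
  n_ret <- design$n_bacteria + design$n_fungi
  w_ret <- stats::runif(n_ret, 0.95, 1.05)
  # each background taxon holds ~1e-5 of total reads (two orders of
  # magnitude under the 0.1% abundance filter) regardless of pool size
  bg_mass <- min(design$n_background * 1e-5, 0.5)
  retained_mass <- 1 - bg_mass
  p_ret <- retained_mass * w_ret / sum(w_ret)
  if (design$n_background > 0) {
    w_bg <- stats::runif(design$n_background, 0.5, 1.5)
    p_bg <- bg_mass * w_bg / sum(w_bg)
  } else {
    p_bg <- numeric()
  }
  stats::setNames(c(p_ret, p_bg),
                  c(design$bacteria_ids, design$fungi_ids, design$background_ids))
}

.synthetic_taxonomy <- function(design) {
  bac_phyla <- c("Proteobacteria", "Actinobacteriota", "Acidobacteriota",
                 "Chloroflexi", "Gemmatimonadota", "Bacteroidota",
                 "Myxococcota", "Verrucomicrobiota")
  fun_phyla <- c("Ascomycota", "Basidiomycota", "Mortierellomycota",
                 "Glomeromycota", "Chytridiomycota")
  taxa <- c(design$bacteria_ids, design$fungi_ids, design$background_ids)
  domain <- c(rep("bacteria", design$n_bacteria),
              rep("fungi", design$n_fungi),
              rep(c("bacteria", "fungi"),
                  length.out = design$n_background))
  hub_ids <- unlist(lapply(design$modules, `[[`, "hub_taxa"))
  phylum <- character(length(taxa))
  is_f <- domain == "fungi"
  phylum[!is_f] <- sample(bac_phyla, sum(!is_f), replace = TRUE,
                          prob = c(30, 20, 15, 10, 8, 8, 5, 4))
  phylum[is_f] <- sample(fun_phyla, sum(is_f), replace = TRUE,
                         prob = c(55, 20, 12, 8, 5))
  # planted hubs are fungal keystone candidates; keep them in the four
  # phyla where keystones concentrate
  key_phyla <- c("Ascomycota", "Basidiomycota", "Mortierellomycota",
                 "Glomeromycota")
  phylum[match(hub_ids, taxa)] <- sample(key_phyla, length(hub_ids),
                                         replace = TRUE)
  data.frame(taxon_id = taxa,
             domain = domain,
             kingdom = ifelse(is_f, "Fungi", "Bacteria"),
             phylum = phylum,
             class = "", order = "", family = "",
             genus = paste0("g_", seq_along(taxa)),
             stringsAsFactors = FALSE)
}

#' Simulate a treatment-structured cross-domain ASV count table
#'
#' Draws a taxa x samples count matrix from a compositional log-normal/
#' multinomial model. Retained taxa receive near-uniform base proportions
#' comfortably above the default abundance filter; background taxa sit two
#' orders of magnitude below it. Within-module taxa share a latent per-sample
#' factor so that their pairwise Spearman correlations approach the module's
#' \code{latent_correlation}; planted hubs load on the factor more strongly.
#' Per-sample counts are multinomial at \code{sequencing_depth}.
#'
#' @param design A [study_design()] object.
#' @return List of class \code{asv_simulation} with elements
#'   \describe{
#'     \item{table}{integer count matrix (taxa x samples) with dimnames,}
#'     \item{taxonomy}{data frame of taxon_id, domain and ranks,}
#'     \item{truth}{ground truth: \code{retained_ids}, \code{background_ids},
#'       \code{module_of} (named module index for module members),
#'       \code{hub_ids}.}
#'   }
#'   Identical designs (including seed) give bit-identical output.
#' @examples
#' d <- study_design(n_bacteria = 30, n_fungi = 10, n_background = 50,
#'                   modules = NULL, seed = 7)
#' sim <- simulate_counts(d)
#' dim(sim$table)
#' @export
simulate_counts <- function(design) {
  stopifnot(inherits(design, "study_design"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(design$seed)

  base_p <- .base_proportions(design)
  g <- .latent_profiles(design)
  taxonomy <- .synthetic_taxonomy(design)

  a <- base_p * exp(design$dispersion * g)
  eff <- design$treatment_effects$taxa
  if (!is.null(eff)) {
    for (tx in colnames(eff)) {
      a[tx, ] <- a[tx, ] * eff[match(design$treatment_of_sample,
                                     design$treatment_labels), tx]
    }
  }
  counts <- vapply(seq_along(design$sample_ids), function(j) {
    as.integer(stats::rmultinom(1L, size = design$sequencing_depth,
                                prob = a[, j]))
  }, integer(nrow(a)))
  dimnames(counts) <- list(rownames(a), design$sample_ids)

  module_of <- integer(0)
  for (m in seq_along(design$modules)) {
    mem <- design$modules[[m]]$member_taxa
    module_of <- c(module_of, stats::setNames(rep(m, length(mem)), mem))
  }
  structure(
    list(table = counts,
         taxonomy = taxonomy,
         truth = list(retained_ids = c(design$bacteria_ids, design$fungi_ids),
                      background_ids = design$background_ids,
                      module_of = module_of,
                      hub_ids = unlist(lapply(design$modules, `[[`, "hub_taxa"))),
         design = design),
    class = "asv_simulation")
}

#' Simulate soil covariates and plant traits
#'
#' Generates per-sample soil physicochemical covariates (pH, EC, AP, AN, AK,
#' TP, TN, TC, and derived C/N) and per-plot plant traits (stem number,
#' biomass, plant height). Treatment means are baseline x multiplicative
#' shift (from \code{design$treatment_effects}); replicates add Gaussian
#' noise with fixed per-variable standard deviations.
#'
#' @param design A [study_design()] object with \code{n_replicates >= 2}.
#' @return Data frame (one row per sample) with columns \code{sample_id},
#'   \code{treatment}, the covariates, \code{CN}, and the traits.
#' @export
simulate_env_and_traits <- function(design) {
  stopifnot(inherits(design, "study_design"))
  if (design$n_replicates < 2) {
    stop("n_replicates must be >= 2: replicate variance is undefined for a single replicate",
         call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(design$seed + 1L)

  t_idx <- match(design$treatment_of_sample, design$treatment_labels)
  n <- length(design$sample_ids)
  env_mult <- design$treatment_effects$env
  trait_mult <- design$treatment_effects$traits

  env <- sapply(names(.env_baseline), function(v) {
    mu <- .env_baseline[[v]] * env_mult[t_idx, v]
    pmax(mu + stats::rnorm(n, 0, .env_sd[[v]]), .env_baseline[[v]] * 0.05)
  })
  traits <- sapply(names(.trait_baseline), function(v) {
    mu <- .trait_baseline[[v]] * trait_mult[t_idx, v]
    pmax(mu + stats::rnorm(n, 0, .trait_sd[[v]]), 0)
  })
  out <- data.frame(sample_id = design$sample_ids,
                    treatment = design$treatment_of_sample,
                    env,
                    CN = env[, "TC"] / env[, "TN"],
                    traits,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# save/restore the global RNG state so simulation calls do not perturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
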