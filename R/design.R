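#' Specify a planted correlation module
#'
#' A module is a set of taxa (possibly mixing bacteria and fungi) whose
#' log-scale abundance profiles share a latent per-sample factor, so that
#' their pairwise rank correlations across samples approach
#' \code{latent_correlation}. A subset of members can be designated as hubs:
#' hubs load on the shared factor more strongly than ordinary members, which
#' gives them systematically more supra-threshold correlations (higher degree
#' and within-module degree z-score) in the inferred network.
#'
#' @param member_taxa Character vector of taxon ids belonging to the module.
#' @param latent_correlation Target mean pairwise within-module Spearman
#'   correlation, in \[0, 1). Individual members receive loadings spread
#'   around this target (see \code{loading_spread}).
#' @param hub_taxa Subset of \code{member_taxa} planted as hubs.
#' @param loading_spread Controls the uniform downward spread of per-member
#'   squared loadings: members draw from
#'   \code{U(latent_correlation - 2*loading_spread, latent_correlation)}.
#'   Heterogeneous loadings are what make hub/non-hub degree differences
#'   detectable.
#' @param hub_correlation Squared loading assigned to hub members
#'   (close to 1; must exceed \code{latent_correlation}).
#' @param anti_fraction Fraction of non-hub members whose loading sign is
#'   flipped, producing negative within-module correlations (negative edges).
#' @return An object of class \code{module_spec}.
#' @seealso [study_design()], [simulate_counts()]
#' @export
module_spec <- function(member_taxa,
                        latent_correlation = 0.95,
                        hub_taxa = character(),
                        loading_spread = 0.05,
                        hub_correlation = 0.998,
                        anti_fraction = 0) {
  if (!is.character(member_taxa) || length(member_taxa) < 2L ||
      anyDuplicated(member_taxa)) {
    stop("invalid module_spec field 'member_taxa': need >= 2 distinct taxon ids",
         call. = FALSE)
  }
  if (!is.numeric(latent_correlation) || length(latent_correlation) != 1L ||
      latent_correlation < 0 || latent_correlation >= 1) {
    stop("invalid module_spec field 'latent_correlation': must lie in [0, 1)",
         call. = FALSE)
  }
  if (!all(hub_taxa %in% member_taxa)) {
    stop("invalid module_spec field 'hub_taxa': must be a subset of member_taxa",
         call. = FALSE)
  }
  if (hub_correlation <= latent_correlation || hub_correlation >= 1) {
    stop("invalid module_spec field 'hub_correlation': must lie in (latent_correlation, 1)",
         call. = FALSE)
  }
  if (anti_fraction < 0 || anti_fraction > 0.5) {
    stop("invalid module_spec field 'anti_fraction': must lie in [0, 0.5]",
         call. = FALSE)
  }
  structure(
    list(member_taxa = member_taxa,
         latent_correlation = latent_correlation,
         hub_taxa = hub_taxa,
         loading_spread = min(loading_spread, latent_correlation / 2),
         hub_correlation = hub_correlation,
         anti_fraction = anti_fraction),
    class = "module_spec")
}

# Soil covariate baselines for the control treatment and replicate-level
# standard deviations; values emulate a 0-20 cm calcic soil under a
# three-year phosphorus-addition experiment in an arid artificial
# Leymus chinensis grassland (pH ~8, EC in uS/cm, AP/AN/AK in mg/kg,
# TP/TN/TC in g/kg).
.env_baseline <- c(pH = 8.04, EC = 223.30, AP = 15.34, AN = 46.10,
                   AK = 171.91, TP = 0.74, TN = 1.05, TC = 18.20)
.env_sd <- c(pH = 0.05, EC = 42.0, AP = 4.9, AN = 6.8,
             AK = 19.6, TP = 0.08, TN = 0.07, TC = 0.90)
.trait_baseline <- c(stem_number = 551.70, biomass = 457.20, height = 54.68)
.trait_sd <- c(stem_number = 29.6, biomass = 32.9, height = 2.10)

# Per-treatment multiplicative shifts (rows P0..P3) on covariate and trait
# means: the phosphorus dose-response of the emulated experiment. AP rises
# by 58.02-137.61% over the control, AN by 2.45-22.47%, TP by up to 24.32%;
# stem number by 43.69-54.96%, biomass by 10.20-24.04%, height by
# 12.38-23.04%. pH, EC, TN are left essentially flat.
.default_env_mult <- rbind(
  P0 = c(pH = 1,        EC = 1,      AP = 1,      AN = 1,      AK = 1,      TP = 1,      TN = 1, TC = 1),
  P1 = c(pH = 1.0012,   EC = 0.8426, AP = 1.5802, AN = 1.0245, AK = 1.1496, TP = 1.10,   TN = 1, TC = 1.02),
  P2 = c(pH = 1.0050,   EC = 1.0176, AP = 1.6310, AN = 1.1746, AK = 1.1061, TP = 1.18,   TN = 1, TC = 1.04),
  P3 = c(pH = 1.0062,   EC = 0.8915, AP = 2.3761, AN = 1.2247, AK = 1.0329, TP = 1.2432, TN = 1, TC = 1.06))

.default_trait_mult <- rbind(
  P0 = c(stem_number = 1,      biomass = 1,      height = 1),
  P1 = c(stem_number = 1.4369, biomass = 1.1020, height = 1.1238),
  P2 = c(stem_number = 1.4691, biomass = 1.2248, height = 1.2137),
  P3 = c(stem_number = 1.5496, biomass = 1.2404, height = 1.2304))

#' Default multiplicative treatment effects
#'
#' Per-treatment multiplicative shifts applied to the means of environmental
#' covariates and plant traits (and, optionally, to designated taxa). The
#' four-treatment default encodes the dose-response of a phosphorus-addition
#' gradient (P0 control to P3 highest dose): available phosphorus roughly
#' 1.58-2.38x the control, available nitrogen up to 1.22x, stem number up to
#' 1.55x, with pH/EC/TN flat. For other treatment counts all shifts default
#' to 1 (pure null).
#'
#' @param n_treatments Number of treatment groups.
#' @return List with matrices \code{env} and \code{traits}
#'   (treatments x variables) and \code{taxa} (\code{NULL} or a
#'   treatments x taxa matrix of multipliers).
#' @export
default_treatment_effects <- function(n_treatments = 4) {
  if (n_treatments == 4) {
    list(env = .default_env_mult, traits = .default_trait_mult, taxa = NULL)
  } else {
    list(env = matrix(1, n_treatments, length(.env_baseline),
                      dimnames = list(NULL, names(.env_baseline))),
         traits = matrix(1, n_treatments, length(.trait_baseline),
                         dimnames = list(NULL, names(.trait_baseline))),
         taxa = NULL)
  }
}

.default_modules <- function(bacteria_ids, fungi_ids, n_modules = 6,
                             hubs_per_module = 2) {
  nb <- length(bacteria_ids)
  nf <- length(fungi_ids)
  bac_split <- split(bacteria_ids, cut(seq_len(nb), n_modules, labels = FALSE))
  fun_split <- split(fungi_ids, cut(seq_len(nf), n_modules, labels = FALSE))
  lapply(seq_len(n_modules), function(m) {
    members <- c(bac_split[[m]], fun_split[[m]])
    hubs <- utils::head(fun_split[[m]], hubs_per_module)
    # a sizeable anti-correlated minority in every module keeps module mass
    # roughly balanced across samples (limiting compositional coupling,
    # which would otherwise wash out negative rank correlations) and gives
    # the inferred network both edge signs
    module_spec(members, latent_correlation = 0.95, hub_taxa = hubs,
                anti_fraction = 0.3)
  })
}

#' Define a synthetic cross-domain study design
#'
#' Describes a treatment-structured amplicon study: treatments x replicates,
#' a retained community of bacterial and fungal taxa organised into planted
#' correlation modules with hub taxa, plus a large pool of low-abundance
#' background taxa destined to be removed by abundance filtering, and
#' treatment-linked shifts on soil covariates and plant traits. The default
#' mirrors a 4-treatment x 3-replicate phosphorus-addition gradient with 505
#' bacterial and 87 fungal retained taxa.
#'
#' @param n_treatments Number of treatment groups (default 4, labelled
#'   P0-P3).
#' @param n_replicates Replicates per treatment (>= 2; correlations are
#'   undefined otherwise).
#' @param n_bacteria,n_fungi Numbers of retained bacterial and fungal taxa.
#' @param n_background Number of low-abundance background taxa; each holds
#'   roughly 1e-5 of total reads, far below the default 0.1% abundance
#'   filter.
#' @param modules List of [module_spec()] objects over the retained taxon
#'   ids, or \code{NULL} for the default partition into 6 mixed-domain
#'   modules with 2 fungal hubs each.
#' @param sequencing_depth Reads per sample.
#' @param dispersion Log-scale volatility of per-sample abundance
#'   fluctuations. Ranks (hence Spearman correlations) are invariant to it;
#'   it controls how strongly count noise attenuates planted correlations
#'   and how far realised abundances stray from their targets.
#' @param treatment_effects As returned by [default_treatment_effects()].
#' @param seed Integer seed; all generator randomness derives from it.
#' @param treatment_labels Treatment group labels.
#' @return An object of class \code{study_design}.
#' @export
study_design <- function(n_treatments = 4,
                         n_replicates = 3,
                         n_bacteria = 505,
                         n_fungi = 87,
                         n_background = 2000,
                         modules = NULL,
                         sequencing_depth = 80000,
                         dispersion = 0.8,
                         treatment_effects = default_treatment_effects(n_treatments),
                         seed = 1L,
                         treatment_labels = paste0("P", seq_len(n_treatments) - 1L)) {
  for (fld in c("n_treatments", "n_replicates", "n_bacteria", "n_fungi")) {
    v <- get(fld)
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v)) {
      stop(sprintf("invalid study_design field '%s': must be a positive integer", fld),
           call. = FALSE)
    }
  }
  if (n_replicates < 2) {
    stop("invalid study_design field 'n_replicates': must be >= 2 (replicate variance and correlations are undefined otherwise)",
         call. = FALSE)
  }
  if (n_background < 0 || n_background != round(n_background)) {
    stop("invalid study_design field 'n_background': must be a non-negative integer",
         call. = FALSE)
  }
  if (!is.numeric(sequencing_depth) || sequencing_depth < 1) {
    stop("invalid study_design field 'sequencing_depth': must be positive",
         call. = FALSE)
  }
  if (!is.numeric(dispersion) || dispersion <= 0) {
    stop("invalid study_design field 'dispersion': must be positive", call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1L || abs(seed) >= 2^30) {
    stop("invalid study_design field 'seed': must be a single integer below 2^30",
         call. = FALSE)
  }
  if (length(treatment_labels) != n_treatments) {
    stop("invalid study_design field 'treatment_labels': length must equal n_treatments",
         call. = FALSE)
  }

  bacteria_ids <- sprintf("ASV_B%04d", seq_len(n_bacteria))
  fungi_ids <- sprintf("ASV_F%03d", seq_len(n_fungi))
  background_ids <- if (n_background > 0) {
    sprintf("ASV_X%04d", seq_len(n_background))
  } else character()

  if (is.null(modules)) {
    modules <- .default_modules(bacteria_ids, fungi_ids)
  }
  retained <- c(bacteria_ids, fungi_ids)
  all_members <- unlist(lapply(modules, `[[`, "member_taxa"))
  if (!all(all_members %in% retained)) {
    stop("invalid study_design field 'modules': member_taxa must be retained (bacterial or fungal) taxon ids",
         call. = FALSE)
  }
  if (anyDuplicated(all_members)) {
    stop("invalid study_design field 'modules': module memberships must be disjoint",
         call. = FALSE)
  }
  if (!all(vapply(treatment_effects$env, is.numeric, TRUE)) ||
      nrow(treatment_effects$env) != n_treatments ||
      nrow(treatment_effects$traits) != n_treatments) {
    stop("invalid study_design field 'treatment_effects': env and traits matrices must have n_treatments rows",
         call. = FALSE)
  }

  sample_ids <- paste0(rep(treatment_labels, each = n_replicates), "_",
                       rep(seq_len(n_replicates), times = n_treatments))
  structure(
    list(n_treatments = as.integer(n_treatments),
         n_replicates = as.integer(n_replicates),
         n_bacteria = as.integer(n_bacteria),
         n_fungi = as.integer(n_fungi),
         n_background = as.integer(n_background),
         modules = modules,
         sequencing_depth = sequencing_depth,
         dispersion = dispersion,
         treatment_effects = treatment_effects,
         seed = as.integer(seed),
         treatment_labels = treatment_labels,
         bacteria_ids = bacteria_ids,
         fungi_ids = fungi_ids,
         background_ids = background_ids,
         sample_ids = sample_ids,
         treatment_of_sample = rep(treatment_labels, each = n_replicates)),
    class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Synthetic cross-domain study design\n")
  cat(sprintf("  %d treatments x %d replicates (%d samples)\n",
              x$n_treatments, x$n_replicates, length(x$sample_ids)))
  cat(sprintf("  %d bacterial + %d fungal retained taxa, %d background taxa\n",
              x$n_bacteria, x$n_fungi, x$n_background))
  cat(sprintf("  %d planted modules, %d hub taxa; depth %g, dispersion %g, seed %d\n",
              length(x$modules),
              sum(lengths(lapply(x$modules, `[[`, "hub_taxa"))),
              x$sequencing_depth, x$dispersion, x$seed))
  invisible(x)
}
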