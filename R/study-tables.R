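#' Bundled summary tables from a phosphorus-addition grassland study
#'
#' Small published-style summary tables from a three-year
#' phosphorus-addition field experiment in an artificial *Leymus chinensis*
#' grassland (four phosphorus doses P0-P3, three replicate plots each),
#' shipped with the package so the treatment-effect and network-identity
#' routines can be exercised on real reported numbers:
#' \describe{
#'   \item{\code{"soil_properties"}}{treatment means +/- SE of pH, EC
#'     (uS/cm) and available P/N/K (mg/kg) in the 0-20 cm layer.}
#'   \item{\code{"plant_traits"}}{treatment means +/- SE of stem number
#'     (plants/m^2), biomass (g/m^2) and plant height (cm).}
#'   \item{\code{"alpha_diversity"}}{treatment means +/- SE of bacterial and
#'     fungal ACE and Gini-Simpson indices.}
#'   \item{\code{"network_topology"}}{the per-treatment topology panel of
#'     the bacterial-fungal cross-domain co-occurrence networks (edge/node
#'     counts by sign and domain, density, average degree, path length,
#'     centralizations).}
#'   \item{\code{"sequencing_yield"}}{total and high-quality read counts of
#'     the 16S and ITS sequencing runs.}
#' }
#'
#' @param name One of the table names above.
#' @return Data frame read from the package's \code{extdata}.
#' @examples
#' topo <- study_table("network_topology")
#' topology_ratios(topo$edges[1], topo$nodes[1], topo$num_pos_edges[1])
#' @export
study_table <- function(name = c("soil_properties", "plant_traits",
                                 "alpha_diversity", "network_topology",
                                 "sequencing_yield")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "coonet",
                      mustWork = TRUE)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
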