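#' Read an ASV/OTU count table from TSV
#'
#' Expects taxa as rows: first column taxon ids, header row of sample ids.
#' Cells must be non-negative numbers; they are coerced to integers.
#'
#' @param path Path to a tab-separated file.
#' @param transpose If \code{TRUE}, the file is samples x taxa and is
#'   transposed on read.
#' @return Integer matrix (taxa x samples) with taxon ids as rownames and
#'   sample ids as colnames; row and column order preserved from the file.
#' @export
read_asv_table <- function(path, transpose = FALSE) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate taxon ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(raw)[-1L])) {
    stop("duplicate sample ids in ", path, call. = FALSE)
  }
  m <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(array(as.numeric(m), dim(m)))) &
                   !is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric count at row '%s', column '%s' in %s",
                 ids[bad[1L]], colnames(m)[bad[2L]], path), call. = FALSE)
  }
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing count at row '%s', column '%s' in %s",
                 ids[bad[1L]], colnames(m)[bad[2L]], path), call. = FALSE)
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative count at row '%s', column '%s' in %s",
                 ids[bad[1L]], colnames(m)[bad[2L]], path), call. = FALSE)
  }
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  if (transpose) m <- t(m)
  m
}

#' Write an ASV count table to TSV
#'
#' @param table Count matrix (taxa x samples) with dimnames.
#' @param path Output path.
#' @param id_column Name for the first (taxon id) column.
#' @export
write_asv_table <- function(table, path, id_column = "taxon_id") {
  df <- data.frame(rownames(table), table, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy table from TSV
#'
#' Requires columns \code{taxon_id} and \code{domain}
#' (\code{bacteria}/\code{fungi}); rank columns (kingdom..genus) are kept if
#' present, other columns are preserved untouched.
#'
#' @param path Path to a tab-separated file.
#' @return Data frame keyed by \code{taxon_id}.
#' @export
read_taxonomy <- function(path) {
  tax <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("taxon_id", "domain") %in% colnames(tax))) {
    stop("taxonomy file must contain 'taxon_id' and 'domain' columns", call. = FALSE)
  }
  if (anyDuplicated(tax$taxon_id)) {
    stop("duplicate taxon ids in taxonomy file ", path, call. = FALSE)
  }
  bad <- setdiff(unique(tax$domain), c("bacteria", "fungi"))
  if (length(bad)) {
    stop("unknown domain label(s) in taxonomy: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  # rank columns that are entirely empty parse as logical NA; restore them
  for (j in seq_along(tax)) {
    if (is.logical(tax[[j]]) && all(is.na(tax[[j]]))) tax[[j]] <- ""
  }
  tax
}

#' @rdname read_taxonomy
#' @param taxonomy Data frame as returned by [read_taxonomy()].
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(taxonomy, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Requires columns \code{sample_id} and \code{treatment}; every other
#' column (soil covariates, plant traits, ...) is preserved as an opaque
#' numeric or character covariate.
#'
#' @param path Path to a tab-separated file.
#' @param table Optional count matrix; if given, metadata must cover all its
#'   samples.
#' @return Data frame, one row per sample.
#' @export
read_metadata <- function(path, table = NULL) {
  md <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "treatment") %in% colnames(md))) {
    stop("metadata file must contain 'sample_id' and 'treatment' columns",
         call. = FALSE)
  }
  if (anyDuplicated(md$sample_id)) {
    stop("duplicate sample ids in metadata file ", path, call. = FALSE)
  }
  if (!is.null(table)) validate_metadata(md, table)
  md
}

#' @rdname read_metadata
#' @param metadata Metadata data frame.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check that metadata covers a count table
#'
#' @param metadata Metadata data frame with a \code{sample_id} column.
#' @param table Count matrix whose colnames are sample ids.
#' @return Invisibly \code{TRUE}; errors listing any samples of
#'   \code{table} missing from \code{metadata}.
#' @export
validate_metadata <- function(metadata, table) {
  missing <- setdiff(colnames(table), metadata$sample_id)
  if (length(missing)) {
    stop("metadata is missing sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Export a co-occurrence network
#'
#' Writes either an edge-list CSV (columns \code{source}, \code{target},
#' \code{rho}, \code{p}, \code{sign}) or GraphML carrying the same edge
#' attributes plus any node attributes present (\code{domain},
#' \code{module}, \code{zi}, \code{pi}, \code{role}). Both formats load
#' directly into Cytoscape; [read_network()] reproduces the graph exactly.
#'
#' @param net An \code{igraph} network as built by [build_network()].
#' @param path Output path.
#' @param format \code{"edgelist"} (CSV) or \code{"graphml"}.
#' @export
write_network <- function(net, path, format = c("edgelist", "graphml")) {
  stopifnot(inherits(net, "igraph"))
  format <- match.arg(format)
  if (format == "edgelist") {
    el <- igraph::as_edgelist(net)
    df <- data.frame(source = el[, 1L], target = el[, 2L],
                     rho = igraph::E(net)$rho %||% rep(NA_real_, nrow(el)),
                     p = igraph::E(net)$p %||% rep(NA_real_, nrow(el)),
                     sign = igraph::E(net)$sign %||% rep(NA_character_, nrow(el)),
                     stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    igraph::write_graph(net, path, format = "graphml")
  }
  invisible(path)
}

#' Import a network written by [write_network()]
#'
#' @param path Path to the file.
#' @param format \code{"edgelist"} or \code{"graphml"}.
#' @return An \code{igraph} network.
#' @export
read_network <- function(path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    igraph::graph_from_data_frame(df, directed = FALSE)
  } else {
    igraph::read_graph(path, format = "graphml")
  }
}

#' Write a metrics report as JSON
#'
#' @param x Named list or one-row data frame of metrics.
#' @param path Output path.
#' @export
write_metrics_json <- function(x, path) {
  jsonlite::write_json(as.list(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
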