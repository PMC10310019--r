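#' Write / read a weighted edge list as TSV
#'
#' Plain three-column TSV (`node1`, `node2`, `weight`) for interoperability
#' with desktop graph tools.
#'
#' @param network A `weighted_network` or `mst_result`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  edges <- if (inherits(network, "weighted_network")) network$edges else network$edges
  readr::write_tsv(
    tibble::tibble(node1 = edges$from, node2 = edges$to,
                   weight = edges$weight),
    path)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  nodes <- sort(unique(c(df$node1, df$node2)))
  structure(list(nodes = nodes,
                 edges = tibble::tibble(from = df$node1, to = df$node2,
                                        weight = df$weight),
                 metadata = list()),
            class = "weighted_network")
}

#' Write an MI matrix as labelled CSV plus JSON metadata
#'
#' @param mi An `mi_matrix`.
#' @param path CSV path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_mi_matrix <- function(mi, path) {
  utils::write.csv(mi$values, path)
  jsonlite::write_json(
    list(band = as.character(mi$band), condition = mi$condition,
         group = mi$group, n_subjects = mi$n_subjects),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read an ASV count table from TSV
#'
#' Expects samples in rows (first column = sample id) and ASVs in columns.
#'
#' @param path TSV path.
#' @return Samples x ASVs integer matrix.
#' @export
read_asv_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "integer"
  m
}

#' Write an ASV count table as TSV
#'
#' @param counts Samples x ASVs matrix.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_asv_tsv <- function(counts, path) {
  df <- tibble::as_tibble(counts, rownames = "sample_id")
  readr::write_tsv(df, path)
  invisible(path)
}
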