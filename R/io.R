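# Tab-delimited readers and writers for the pipeline's tables. All files
# are UTF-8 TSV with a header row and no index column, so round trips are
# bit-exact.

#' Read / write a ranked DE table
#'
#' Columns: `gene_id`, `symbol`, `log2ratio`, `pvalue`,
#' `adjusted_pvalue`, `position`.
#'
#' @param de A DE-table tibble.
#' @param path File path.
#' @return `read_de_table` returns the validated tibble sorted by
#'   position; writers return `path` invisibly.
#' @export
write_de_table <- function(de, path) {
  readr::write_tsv(de, path)
  invisible(path)
}

#' @rdname write_de_table
#' @export
read_de_table <- function(path) {
  de <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_de_table(de)
  de[order(de$position), , drop = FALSE]
}

#' Read / write a gene-to-probe annotation map
#'
#' One `gene_id`/`probe_id` row per pair; genes absent from the file are
#' unmapped.
#'
#' @param ann Annotation tibble.
#' @param path File path.
#' @export
write_annotation <- function(ann, path) {
  readr::write_tsv(ann[, c("gene_id", "probe_id")], path)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read / write a gene signature
#'
#' Columns `probe_id` and `sign` (+1/-1).
#'
#' @param sig A [gene_signature()].
#' @param path File path.
#' @param name Query name given to the signature on read.
#' @export
write_signature <- function(sig, path) {
  readr::write_tsv(tibble(probe_id = sig$probe_id, sign = sig$sign), path)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path, name = "query") {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  gene_signature(x$probe_id, x$sign, name = name)
}

#' Read / write query results
#'
#' The on-disk header follows the field's reporting convention:
#' `refsetname setsize queryName queryLength setscore pvalue sig Per`
#' (`Per` is the perturbation-stability column).
#'
#' @param results A query result tibble.
#' @param path File path.
#' @export
write_results <- function(results, path) {
  out <- as_tibble(results)
  out <- rename(out, Per = "stability")
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  rename(x, stability = "Per")
}
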