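# From a ranked differential-expression table to a platform-mapped gene
# signature.
#
# DE tables arrive sorted by the source tool's own ranking (the `position`
# column); genes are mapped to platform probes through an annotation map
# that may leave genes unmapped or fan one gene out to several probes. The
# signature is the first m mapped probes encountered when walking the table
# in position order, each carrying the up/down status of its gene.

#' Create a gene signature
#'
#' @param probe_id Character vector of unique probe identifiers, in
#'   signature order (most important first).
#' @param sign Integer vector of +1/-1 regulation signs, one per probe.
#' @param name Query name carried into results.
#' @return A tibble of class `connmap_signature` with columns `probe_id`
#'   and `sign`.
#' @export
gene_signature <- function(probe_id, sign, name = "query") {
  probe_id <- as.character(probe_id)
  sign <- as.integer(sign)
  if (length(sign) == 1L) sign <- rep(sign, length(probe_id))
  if (anyDuplicated(probe_id)) {
    abort("Signature probes must be unique.", class = "connmap_error_signature")
  }
  if (length(sign) != length(probe_id) || !all(sign %in% c(-1L, 1L))) {
    abort("`sign` must be +1/-1, one per probe.",
          class = "connmap_error_signature")
  }
  out <- tibble(probe_id = probe_id, sign = sign)
  structure(out, class = c("connmap_signature", class(out)),
            query_name = name)
}

#' @export
print.connmap_signature <- function(x, ...) {
  cat("<gene signature> ", attr(x, "query_name"), ": ", nrow(x),
      " probes (", sum(x$sign > 0), " up, ", sum(x$sign < 0), " down)\n",
      sep = "")
  NextMethod()
}

query_name <- function(sig) {
  attr(sig, "query_name") %||% "query"
}

validate_de_table <- function(de) {
  need <- c("gene_id", "log2ratio", "position")
  if (!all(need %in% names(de))) {
    abort(paste0("DE table needs columns: ", paste(need, collapse = ", "), "."),
          class = "connmap_error_de")
  }
  if (!identical(sort(as.integer(de$position)), seq_len(nrow(de)))) {
    abort("DE table `position` must be 1..n without gaps.",
          class = "connmap_error_de")
  }
  invisible(de)
}

#' Map a ranked DE table to a platform gene signature
#'
#' Walks the DE table in `position` order. For each gene, all of its
#' annotated probes (in annotation order) that belong to the platform
#' universe are appended to the signature with sign = sign of the gene's
#' log2 ratio, until m probes have been collected; the cut may fall in the
#' middle of a multi-probe gene. Genes with no surviving probes are
#' skipped, so removing unmapped genes from the table does not change the
#' result.
#'
#' @param de DE table: data frame with columns `gene_id`, `log2ratio` and
#'   `position` (1..n, the source tool's ranking; `symbol`, `pvalue` and
#'   `adjusted_pvalue` may be present and are ignored here).
#' @param ann Annotation map: data frame with columns `gene_id` and
#'   `probe_id`, one row per gene-probe pair, rows in annotation order.
#'   Genes absent from `ann` are unmapped.
#' @param universe Platform probe universe (character vector).
#' @param m Signature length (>= 1).
#' @param name Query name carried into results.
#' @return A [gene_signature()] of exactly m probes.
#' @export
map_genes_to_probes <- function(de, ann, universe, m, name = "query") {
  validate_de_table(de)
  stopifnot(m >= 1)
  universe <- probe_universe(universe)
  de <- de[order(de$position), , drop = FALSE]
  probes_by_gene <- split(ann$probe_id, factor(ann$gene_id,
                                               levels = unique(ann$gene_id)))
  out_probe <- character(0)
  out_sign <- integer(0)
  for (i in seq_len(nrow(de))) {
    probes <- probes_by_gene[[de$gene_id[i]]]
    probes <- probes[probes %in% universe]
    probes <- setdiff(probes, out_probe)
    if (!length(probes)) next
    sgn <- if (de$log2ratio[i] < 0) -1L else 1L
    out_probe <- c(out_probe, probes)
    out_sign <- c(out_sign, rep(sgn, length(probes)))
    if (length(out_probe) >= m) break
  }
  if (length(out_probe) < m) {
    abort(
      paste0("Requested m = ", m, " signature probes but only ",
             length(out_probe), " are mappable to the platform."),
      class = "connmap_error_shortfall"
    )
  }
  gene_signature(out_probe[seq_len(m)], out_sign[seq_len(m)], name = name)
}

#' Restrict a probe list to a platform universe
#'
#' Keeps, in order, the probes that exist on the platform; idempotent.
#'
#' @param probes Character vector of probe identifiers.
#' @param universe Platform probe universe.
#' @return Character subsequence of `probes` (possibly empty).
#' @export
filter_to_platform <- function(probes, universe) {
  probes[probes %in% universe]
}

#' Find the minimal signature size meeting an FDR target
#'
#' For each candidate size m (ascending), builds the m-probe signature from
#' the DE table and queries the database; the estimated false discovery
#' rate is `alpha_family / n_sig` (expected false positives over declared
#' positives under the Bonferroni rule). The optimal size is the smallest m
#' with at least one significant connection and estimated FDR at or below
#' `cfg$fdr_target`. Grid values beyond the number of mappable probes are
#' dropped with a warning.
#'
#' @param de,ann,universe As in [map_genes_to_probes()] (`universe`
#'   defaults to the database's).
#' @param db A `ref_db`.
#' @param cfg A [query_config()].
#' @param m_grid Ascending integer grid of candidate sizes.
#' @param name Query name.
#' @return List with elements `m_star` (the optimal size), `signature` (the
#'   optimal-size signature), `results` (that size's query results) and
#'   `per_m` (audit tibble: one row per size tried, with `n_sig`,
#'   `fdr_est`, `met`). Errors with class `connmap_error_no_optimal_m`,
#'   carrying the audit tibble in its `per_m` field, if no size meets the
#'   target.
#' @export
optimize_signature_size <- function(de, ann, db, cfg,
                                    m_grid = seq(5L, 100L, by = 5L),
                                    name = "query") {
  stopifnot(!is.unsorted(m_grid, strictly = TRUE))
  mapped <- ann$probe_id[ann$gene_id %in% de$gene_id]
  n_mappable <- length(unique(filter_to_platform(mapped, db$universe)))
  keep <- m_grid <= n_mappable
  if (!all(keep)) {
    warn(paste0("Dropping signature sizes above the ", n_mappable,
                " mappable probes: ",
                paste(m_grid[!keep], collapse = ", ")))
    m_grid <- m_grid[keep]
  }
  if (!length(m_grid)) {
    abort("No candidate signature size is mappable.",
          class = "connmap_error_no_optimal_m")
  }
  rows <- vector("list", length(m_grid))
  for (i in seq_along(m_grid)) {
    m <- m_grid[i]
    sig <- map_genes_to_probes(de, ann, db$universe, m = m, name = name)
    res <- query_database(sig, db, cfg)
    n_sig <- sum(res$sig)
    fdr <- estimate_fdr(n_sig, cfg$alpha_family)
    rows[[i]] <- tibble(
      m = as.integer(m), n_sig = n_sig, fdr_est = fdr,
      met = n_sig >= 1L && fdr <= cfg$fdr_target
    )
    if (rows[[i]]$met) {
      per_m <- bind_rows(rows[!vapply(rows, is.null, logical(1))])
      return(list(m_star = as.integer(m), signature = sig, results = res,
                  per_m = per_m))
    }
  }
  per_m <- bind_rows(rows)
  abort(
    c("No signature size in the grid meets the FDR target.",
      i = paste0("Best estimated FDR: ",
                 format(min(per_m$fdr_est), digits = 3))),
    class = "connmap_error_no_optimal_m",
    per_m = per_m
  )
}
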