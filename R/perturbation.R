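# Single-gene-omission perturbation.
#
# A significant connection is trustworthy only if it does not hinge on any
# single signature gene. Each of the m leave-one-out variants of the
# signature (the omitted gene is restored before the next omission) is
# re-queried at its own length's Bonferroni threshold; a compound's
# stability is the fraction of variants under which it stays significant,
# so 1 means the connection survived every omission.

#' Leave-one-out variants of a gene signature
#'
#' @param sig A [gene_signature()] with at least 2 entries.
#' @return A list of m signatures; the i-th omits entry i (length m - 1,
#'   order otherwise preserved).
#' @export
perturb_signature <- function(sig) {
  m <- nrow(sig)
  if (m < 2L) {
    abort("Perturbation needs a signature of at least 2 probes.",
          class = "connmap_error_signature")
  }
  lapply(seq_len(m), function(i) {
    gene_signature(sig$probe_id[-i], sig$sign[-i],
                   name = paste0(query_name(sig), "_omit", i))
  })
}

#' Perturbation stability of significant connections
#'
#' Re-queries the database with every leave-one-out variant of the
#' signature (each variant gets its own seeded null stream at length
#' m - 1) and, for each compound significant in the base query, reports
#' the fraction of variants under which it remains significant.
#'
#' @param sig The base [gene_signature()].
#' @param db A `ref_db`.
#' @param cfg The [query_config()] used for the base query.
#' @param base Result of `query_database(sig, db, cfg)`.
#' @return A tibble with one row per base-significant compound:
#'   `compound`, `n_perturbations` (= m), `n_surviving`, `stability`.
#' @export
perturbation_stability <- function(sig, db, cfg, base) {
  sig_rows <- base[base$sig == 1L, , drop = FALSE]
  compounds <- sig_rows$refsetname
  m <- nrow(sig)
  if (!length(compounds)) {
    return(tibble(compound = character(0), n_perturbations = integer(0),
                  n_surviving = integer(0), stability = numeric(0)))
  }
  variants <- perturb_signature(sig)
  surviving <- setNames(integer(length(compounds)), compounds)
  for (i in seq_along(variants)) {
    cfg_i <- cfg
    cfg_i$seed <- as.integer(cfg$seed + i)
    res_i <- query_database(variants[[i]], db, cfg_i)
    hit <- res_i$sig[match(compounds, res_i$refsetname)]
    surviving <- surviving + hit
  }
  tibble(
    compound = compounds,
    n_perturbations = m,
    n_surviving = as.integer(surviving),
    stability = as.numeric(surviving) / m
  )
}

#' Merge a stability report into query results
#'
#' Fills the `stability` column of a query result from a
#' [perturbation_stability()] report; compounds not in the report (the
#' non-significant ones) keep `NA`.
#'
#' @param results A `connmap_query` tibble.
#' @param report A stability report tibble.
#' @return The results tibble with `stability` populated.
#' @export
add_stability <- function(results, report) {
  hit <- match(results$refsetname, report$compound)
  results$stability <- ifelse(is.na(hit), NA_real_, report$stability[hit])
  results
}
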