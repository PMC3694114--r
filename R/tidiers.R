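#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a connectivity query result
#'
#' @param x A `connmap_query`.
#' @param ... Unused.
#' @return A plain tibble, one row per compound reference set.
#' @export
tidy.connmap_query <- function(x, ...) {
  as_tibble(x)
}

#' One-row summary of a connectivity query
#'
#' @param x A `connmap_query`.
#' @param ... Unused.
#' @return Tibble with the number of sets tested, the Bonferroni
#'   threshold, the number of significant connections and the estimated
#'   FDR.
#' @export
glance.connmap_query <- function(x, ...) {
  cfg <- attr(x, "cfg")
  n_sig <- sum(x$sig)
  tibble(
    n_sets = nrow(x),
    query_length = x$queryLength[1],
    alpha_family = cfg$alpha_family,
    threshold = attr(x, "threshold"),
    n_random = cfg$n_random,
    n_sig = n_sig,
    fdr_est = estimate_fdr(n_sig, cfg$alpha_family)
  )
}
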