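# Comparing candidate lists across platforms.

#' Hypergeometric significance of an overlap between two candidate lists
#'
#' Tests whether two candidate-compound lists drawn from the same
#' D-compound database share more compounds than chance would give:
#' the upper-tail probability P(X >= n_overlap) for
#' X ~ Hypergeometric(D, n_A, n_B), computed by exact summation.
#'
#' @param list_a,list_b Character vectors of compound names
#'   (duplicate-free, both subsets of the database population).
#' @param population D, the number of compound sets in the database.
#' @return One-row tibble: `n_a`, `n_b`, `n_overlap`, `population`,
#'   `expected_overlap` (n_A n_B / D), `p_hyper`.
#' @export
overlap_significant <- function(list_a, list_b, population) {
  if (anyDuplicated(list_a) || anyDuplicated(list_b)) {
    abort("Candidate lists must be duplicate-free.",
          class = "connmap_error_overlap")
  }
  n_a <- length(list_a)
  n_b <- length(list_b)
  if (n_a > population || n_b > population) {
    abort("A candidate list cannot exceed the database population.",
          class = "connmap_error_overlap")
  }
  k <- length(intersect(list_a, list_b))
  # upper tail P(X >= k); phyper sums the exact mass function
  p <- phyper(k - 1, n_a, population - n_a, n_b, lower.tail = FALSE)
  tibble(
    n_a = n_a, n_b = n_b, n_overlap = k, population = as.integer(population),
    expected_overlap = n_a * n_b / population, p_hyper = p
  )
}

#' Sign concordance of shared compounds between two queries
#'
#' For the compounds common to two candidate lists, the fraction whose
#' setscores agree in direction across the two queries (both enhancing or
#' both suppressing).
#'
#' @param results_a,results_b Query result tibbles (columns `refsetname`,
#'   `setscore`).
#' @param compounds Character vector of shared compounds; each must be
#'   present in both results with a nonzero setscore.
#' @return Fraction in \[0, 1\], or `NA` for an empty overlap (direction
#'   concordance is undefined).
#' @export
sign_concordance <- function(results_a, results_b, compounds) {
  if (!length(compounds)) {
    return(NA_real_)
  }
  sa <- results_a$setscore[match(compounds, results_a$refsetname)]
  sb <- results_b$setscore[match(compounds, results_b$refsetname)]
  if (anyNA(sa) || anyNA(sb)) {
    miss <- compounds[is.na(sa) | is.na(sb)]
    abort(
      paste0("Compounds missing from a result list: ",
             paste(head(miss, 5), collapse = ", ")),
      class = "connmap_error_overlap"
    )
  }
  if (any(sa == 0) || any(sb == 0)) {
    abort("Zero setscore: direction undefined.",
          class = "connmap_error_overlap")
  }
  mean(sign(sa) == sign(sb))
}

#' Compare the stable candidate lists of two queries
#'
#' Takes two fully annotated query results (significance and stability
#' filled in), forms each platform's candidate list as the compounds with
#' `sig = 1` and full perturbation stability, and summarises their
#' agreement: overlap size, exact hypergeometric p-value, and sign
#' concordance on the shared compounds.
#'
#' @param results_a,results_b Query result tibbles with `sig` and
#'   `stability` columns populated.
#' @param population Database population D; defaults to the number of rows
#'   of `results_a` (one row per compound set).
#' @return List with `summary` (the [overlap_significant()] row plus
#'   `concordance`) and `shared` (side-by-side tibble of the shared
#'   compounds' setscores).
#' @export
compare_queries <- function(results_a, results_b,
                            population = nrow(results_a)) {
  stable <- function(res) {
    res$refsetname[res$sig == 1L & !is.na(res$stability) &
                     res$stability == 1]
  }
  a <- stable(results_a)
  b <- stable(results_b)
  shared <- intersect(a, b)
  out <- overlap_significant(a, b, population)
  out$concordance <- sign_concordance(results_a, results_b, shared)
  shared_tbl <- tibble(
    refsetname = shared,
    setscore_a = results_a$setscore[match(shared, results_a$refsetname)],
    setscore_b = results_b$setscore[match(shared, results_b$refsetname)]
  ) |> arrange(desc(abs(.data$setscore_a)))
  list(summary = out, shared = shared_tbl)
}
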