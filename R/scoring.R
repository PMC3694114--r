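# Connection scoring.
#
# The connection strength of an m-probe signature to a profile is the
# signed-rank inner product c = sum_i s(g_i) * R(g_i); dividing by the
# maximal attainable strength c_max = sum_{i=1..m} (N - i + 1) normalises
# it to a connection score C in [-1, 1]. C = 1 exactly when the signature
# probes occupy the top m rank magnitudes with matching signs; negative C
# means the compound's profile opposes the signature. A compound's setscore
# is the arithmetic mean of C over its replicate profiles. Significance
# comes from a randomization null: random signatures of the same length
# and sign composition, scored against the same reference set.

#' Query configuration
#'
#' @param alpha_family Family-wise expected-false-positive budget in
#'   (0, 1]. A connection is declared significant when its randomization
#'   p-value is at most `alpha_family / D` (Bonferroni over the D compound
#'   sets). The default 1.0 makes the per-set threshold 1/D and the
#'   estimated FDR `1 / n_sig`.
#' @param fdr_target FDR threshold used by the signature-size search
#'   (default 0.01).
#' @param n_random Number of random signatures drawn for the null
#'   (default 1e6). Must be at least `10 * D / alpha_family` so that
#'   p-values near the Bonferroni threshold are resolvable.
#' @param seed Integer seed; all randomization is reproducible from it.
#' @param sign_policy How random signatures get their signs; the query's
#'   own multiset of signs is preserved (`"preserve_query_signs"`, the only
#'   policy).
#' @param perturb_mode Single-gene perturbation flavour; `"omit"`
#'   (leave-one-out with restoration, the only implemented mode).
#' @return A list of class `query_config`.
#' @export
query_config <- function(alpha_family = 1, fdr_target = 0.01,
                         n_random = 1e6, seed = 1L,
                         sign_policy = "preserve_query_signs",
                         perturb_mode = "omit") {
  stopifnot(alpha_family > 0, alpha_family <= 1,
            fdr_target > 0, n_random >= 1, is.numeric(seed))
  sign_policy <- arg_match0(sign_policy, "preserve_query_signs")
  perturb_mode <- arg_match0(perturb_mode, "omit")
  structure(
    list(alpha_family = alpha_family, fdr_target = fdr_target,
         n_random = as.integer(n_random), seed = as.integer(seed),
         sign_policy = sign_policy, perturb_mode = perturb_mode),
    class = "query_config"
  )
}

check_cfg_resolvable <- function(cfg, d) {
  need <- 10 * d / cfg$alpha_family
  if (cfg$n_random < need) {
    abort(
      paste0("n_random = ", cfg$n_random, " cannot resolve p-values at the ",
             "Bonferroni threshold for D = ", d, " sets; need at least ",
             ceiling(need), "."),
      class = "connmap_error_config"
    )
  }
  invisible(cfg)
}

# Normalisation constant: maximal |c| for an m-probe signature on an
# N-probe platform.
c_max <- function(n, m) {
  sum(n - seq_len(m) + 1)
}

as_rank_vector <- function(profile) {
  if (is.data.frame(profile)) {
    setNames(as.numeric(profile$signed_rank), profile$probe_id)
  } else if (is.numeric(profile) && !is.null(names(profile))) {
    profile
  } else {
    abort("Profile must be a data frame (probe_id, signed_rank) or a named numeric vector.",
          class = "connmap_error_profile")
  }
}

signature_ranks <- function(sig, ranks) {
  hit <- match(sig$probe_id, names(ranks))
  if (anyNA(hit)) {
    abort(
      paste0("Signature probes absent from the profile universe: ",
             paste(head(sig$probe_id[is.na(hit)], 5), collapse = ", ")),
      class = "connmap_error_probe"
    )
  }
  ranks[hit]
}

#' Connection score of a signature against one reference profile
#'
#' @param sig A [gene_signature()].
#' @param profile A signed-rank profile: data frame with columns
#'   `probe_id`, `signed_rank` (as from [build_profile()]) or a named
#'   numeric vector over the whole universe.
#' @return The normalised connection score in \[-1, 1\].
#' @export
connection_score <- function(sig, profile) {
  ranks <- as_rank_vector(profile)
  r <- signature_ranks(sig, ranks)
  sum(sig$sign * r) / c_max(length(ranks), nrow(sig))
}

#' Setscore of a signature against a compound's reference set
#'
#' The arithmetic mean of the per-profile connection scores over the set's
#' replicate profiles; with a single profile it reduces to
#' [connection_score()].
#'
#' @param sig A [gene_signature()].
#' @param profiles The reference set: a list of profiles (each as accepted
#'   by [connection_score()]), or a probes x replicates matrix of signed
#'   ranks with probe row names.
#' @return The setscore in \[-1, 1\].
#' @export
set_score <- function(sig, profiles) {
  if (is.matrix(profiles)) {
    n <- nrow(profiles)
    rbar <- rowMeans(profiles)
    hit <- match(sig$probe_id, rownames(profiles))
    if (anyNA(hit)) {
      abort(
        paste0("Signature probes absent from the profile universe: ",
               paste(head(sig$probe_id[is.na(hit)], 5), collapse = ", ")),
        class = "connmap_error_probe"
      )
    }
    return(sum(sig$sign * rbar[hit]) / c_max(n, nrow(sig)))
  }
  if (!is.list(profiles) || !length(profiles)) {
    abort("Reference set must contain at least one profile.",
          class = "connmap_error_refset"
    )
  }
  mean(vapply(profiles, function(p) connection_score(sig, p), numeric(1)))
}

#' Randomization p-value of a signature-to-set connection
#'
#' Draws `cfg$n_random` random signatures (m distinct probes uniform over
#' the universe, carrying the query's multiset of signs), scores each
#' against the reference set with the same setscore rule, and returns the
#' add-one two-sided estimate
#' `p = (#\{|C_random| >= |C_observed|\} + 1) / (n_random + 1)`.
#'
#' @inheritParams set_score
#' @param cfg A [query_config()].
#' @return The estimated p-value in (0, 1\].
#' @export
estimate_pvalue <- function(sig, profiles, cfg) {
  if (is.matrix(profiles)) {
    rmat <- profiles
  } else {
    profs <- lapply(profiles, as_rank_vector)
    ids <- names(profs[[1]])
    rmat <- vapply(profs, function(p) unname(p[ids]), numeric(length(ids)))
    rownames(rmat) <- ids
  }
  n <- nrow(rmat)
  m <- nrow(sig)
  if (m >= n) {
    abort("Signature length must be smaller than the universe (degenerate null).",
          class = "connmap_error_config")
  }
  rbar <- rowMeans(rmat)
  hit <- match(sig$probe_id, rownames(rmat))
  if (anyNA(hit)) {
    abort(
      paste0("Signature probes absent from the profile universe: ",
             paste(head(sig$probe_id[is.na(hit)], 5), collapse = ", ")),
      class = "connmap_error_probe"
    )
  }
  c_obs <- sum(sig$sign * rbar[hit])
  idx <- null_probe_draws(cfg$n_random, m, n, stream_seed(cfg$seed, m))
  b <- null_tail_count(idx, sig$sign, rbar, abs(c_obs))
  (b + 1) / (cfg$n_random + 1)
}

#' Query a reference database with a gene signature
#'
#' Scores the signature against every compound reference set, estimates a
#' randomization p-value per set from one shared null stream (the same
#' `n_random` random signatures are scored against every set), and flags
#' significance at the Bonferroni threshold `alpha_family / D`.
#'
#' @param sig A [gene_signature()].
#' @param db A `ref_db`.
#' @param cfg A [query_config()].
#' @return A tibble of class `connmap_query`, one row per compound set,
#'   with columns `refsetname`, `setsize`, `queryName`, `queryLength`,
#'   `setscore`, `pvalue`, `sig` (0/1) and `stability` (NA until filled by
#'   [perturbation_stability()]).
#' @export
query_database <- function(sig, db, cfg) {
  stopifnot(inherits(db, "ref_db"))
  if (!nrow(sig)) {
    abort("Query signature is empty.", class = "connmap_error_signature")
  }
  d <- n_ref_sets(db)
  check_cfg_resolvable(cfg, d)
  n <- length(db$universe)
  m <- nrow(sig)
  if (m >= n) {
    abort("Signature length must be smaller than the universe (degenerate null).",
          class = "connmap_error_config")
  }
  hit <- match(sig$probe_id, db$universe)
  if (anyNA(hit)) {
    abort(
      paste0("Signature probes absent from the database universe: ",
             paste(head(sig$probe_id[is.na(hit)], 5), collapse = ", ")),
      class = "connmap_error_probe"
    )
  }
  rbar <- set_rank_means(db)                     # N x D
  cmax <- c_max(n, m)
  c_obs <- unname(drop(crossprod(rbar[hit, , drop = FALSE], sig$sign)))
  idx <- null_probe_draws(cfg$n_random, m, n, stream_seed(cfg$seed, m))
  pvals <- vapply(seq_len(ncol(rbar)), function(j) {
    b <- null_tail_count(idx, sig$sign, rbar[, j], abs(c_obs[j]))
    (b + 1) / (cfg$n_random + 1)
  }, numeric(1))
  sizes <- ref_sets(db)
  ord <- match(colnames(rbar), sizes$compound)
  thresh <- cfg$alpha_family / d
  out <- tibble(
    refsetname = colnames(rbar),
    setsize = as.integer(sizes$setsize[ord]),
    queryName = query_name(sig),
    queryLength = m,
    setscore = c_obs / cmax,
    pvalue = pvals,
    sig = as.integer(pvals <= thresh),
    stability = NA_real_
  )
  new_connmap_query(out, cfg = cfg, d = d, threshold = thresh)
}

new_connmap_query <- function(x, cfg, d, threshold) {
  structure(x, class = c("connmap_query", class(tibble())),
            cfg = cfg, D = d, threshold = threshold)
}

#' Estimated false discovery rate of a query
#'
#' Under the Bonferroni rule the expected number of false positives across
#' the D sets is at most `alpha_family`, so with `n_sig` declared
#' connections the estimated FDR is `alpha_family / n_sig` (infinite when
#' nothing is declared).
#'
#' @param n_sig Number of significant connections (>= 0).
#' @param alpha_family Family-wise expected-false-positive budget.
#' @return The FDR estimate; `Inf` when `n_sig` is 0.
#' @export
estimate_fdr <- function(n_sig, alpha_family = 1) {
  stopifnot(n_sig >= 0, alpha_family > 0)
  if (n_sig == 0) Inf else alpha_family / n_sig
}

#' Rank significant connections
#'
#' Keeps the significant rows and orders them the way candidate lists are
#' reported: perturbation stability descending, then setsize descending,
#' then absolute setscore descending, ties broken alphabetically by
#' compound. Direction (enhancing vs suppressing) is read off the sign of
#' the setscore.
#'
#' @param results A query result tibble with a populated `stability`
#'   column on its significant rows.
#' @return The ranked tibble of significant connections.
#' @export
rank_results <- function(results) {
  keep <- results[results$sig == 1L, , drop = FALSE]
  if (anyNA(keep$stability)) {
    abort("`stability` must be populated for all significant rows before ranking.",
          class = "connmap_error_rank")
  }
  keep |>
    arrange(desc(.data$stability), desc(.data$setsize),
            desc(abs(.data$setscore)), .data$refsetname)
}
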