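# Synthetic study generator.
#
# Emulates the two inputs the pipeline consumes so that every stage is
# testable without external downloads: (1) a reference database of signed
# rank profiles over a probe universe, with optional planted
# signature-compound connections of tunable strength; (2) a ranked
# differential-expression table with a strongly significant top tier,
# plus an annotation map with unmapped and multi-probe genes. Null
# profiles are uniform signed permutations; a planted profile starts from
# the signature occupying the top rank magnitudes with matching (or, for
# an inverse connection, flipped) signs and is then corrupted by swapping
# each planted probe with a uniformly chosen probe with probability
# 1 - strength, which preserves the permutation invariant at every
# strength.

#' Configuration for the synthetic-study generator
#'
#' @param N Probe-universe size. The desk-scale default (2,000) keeps test
#'   runs under a minute; `paper_scale = TRUE` switches to the HG-U133A
#'   universe size 22,283.
#' @param D Number of compound reference sets (desk-scale default 200;
#'   paper scale 1,309).
#' @param K_range Inclusive range of replicate counts per compound
#'   (default 1-8; paper scale up to 32).
#' @param planted Data frame with columns `compound`, `strength` (lambda
#'   in \[0, 1\]) and `direction` (+1/-1), one row per planted compound;
#'   `NULL` for a pure-null database.
#' @param sig_m Length of the planted signature.
#' @param n_genes,n_signal DE-table size and size of its significant top
#'   tier.
#' @param unmapped_frac Probability a gene has no platform probes.
#' @param multiprobe_frac Probability a mapped gene fans out to several
#'   probes.
#' @param multiprobe_probes Probe counts a multi-probe gene may take.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @param paper_scale If `TRUE`, override `N`, `D` and `K_range` with the
#'   full-database shape (N = 22,283, D = 1,309, setsizes 1-32).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(N = 2000, D = 200, K_range = c(1L, 8L),
                         planted = NULL, sig_m = 10L,
                         n_genes = 300L, n_signal = 40L,
                         unmapped_frac = 0.3, multiprobe_frac = 0.2,
                         multiprobe_probes = 2:3,
                         seed = 1L, paper_scale = FALSE) {
  if (paper_scale) {
    N <- 22283L
    D <- 1309L
    K_range <- c(1L, 32L)
  }
  if (!is.null(planted)) {
    planted <- as_tibble(planted)
    stopifnot(all(c("compound", "strength", "direction") %in% names(planted)),
              all(planted$strength >= 0 & planted$strength <= 1),
              all(planted$direction %in% c(-1, 1)),
              nrow(planted) <= D)
  }
  stopifnot(N >= 2, D >= 1, length(K_range) == 2, K_range[1] >= 1,
            K_range[2] >= K_range[1], sig_m >= 1, sig_m <= N,
            n_signal <= n_genes,
            unmapped_frac >= 0, unmapped_frac <= 1,
            multiprobe_frac >= 0, multiprobe_frac <= 1,
            unmapped_frac + multiprobe_frac <= 1)
  structure(
    list(N = as.integer(N), D = as.integer(D),
         K_range = as.integer(K_range), planted = planted,
         sig_m = as.integer(sig_m), n_genes = as.integer(n_genes),
         n_signal = as.integer(n_signal),
         unmapped_frac = unmapped_frac, multiprobe_frac = multiprobe_frac,
         multiprobe_probes = as.integer(multiprobe_probes),
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

synth_universe <- function(cfg) {
  sprintf("p%05d", seq_len(cfg$N))
}

# One uniform signed permutation of 1..N.
null_profile_ranks <- function(n) {
  sample.int(n) * sample(c(-1L, 1L), n, replace = TRUE)
}

# Planted profile: signature probes at magnitudes N..N-m+1 with signs
# direction * sign_i, remaining magnitudes randomly permuted over the rest;
# each planted probe then swapped with a uniform random probe with
# probability 1 - strength.
planted_profile_ranks <- function(n, sig_idx, sig_sign, strength, direction) {
  m <- length(sig_idx)
  ranks <- integer(n)
  ranks[sig_idx] <- as.integer(direction * sig_sign * (n - seq_len(m) + 1L))
  rest <- setdiff(seq_len(n), sig_idx)
  ranks[rest] <- sample(seq_len(n - m)) *
    sample(c(-1L, 1L), n - m, replace = TRUE)
  for (i in seq_len(m)) {
    if (runif(1) > strength) {
      j <- sample.int(n, 1)
      tmp <- ranks[sig_idx[i]]
      ranks[sig_idx[i]] <- ranks[j]
      ranks[j] <- tmp
    }
  }
  ranks
}

#' Generate a synthetic reference database with planted connections
#'
#' @param cfg A [synth_config()].
#' @param signature The signature to plant (a [gene_signature()] over the
#'   synthetic universe); if `NULL`, a random signature of length
#'   `cfg$sig_m` is drawn.
#' @return List with `db` (a `ref_db`) and `truth` (list: `signature`, the
#'   planted signature; `planted`, the per-compound strength/direction
#'   table, empty for a pure-null database).
#' @export
gen_reference_db <- function(cfg, signature = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  universe <- synth_universe(cfg)
  if (!is.null(signature) && nrow(signature) > cfg$N) {
    abort("Planted signature larger than the universe.",
          class = "connmap_error_synth")
  }
  planted <- cfg$planted %||%
    tibble(compound = character(0), strength = numeric(0),
           direction = numeric(0))
  withr::with_seed(cfg$seed, {
    if (is.null(signature)) {
      signature <- gene_signature(
        sample(universe, cfg$sig_m),
        sample(c(-1L, 1L), cfg$sig_m, replace = TRUE),
        name = "synthetic"
      )
    }
    sig_idx <- match(signature$probe_id, universe)
    if (anyNA(sig_idx)) {
      abort("Planted signature probes must belong to the synthetic universe.",
            class = "connmap_error_synth")
    }
    n_null <- cfg$D - nrow(planted)
    compounds <- c(planted$compound, sprintf("null_%04d", seq_len(n_null)))
    k_choices <- seq.int(cfg$K_range[1], cfg$K_range[2])
    sizes <- if (length(k_choices) == 1L) {
      rep(k_choices, cfg$D)
    } else {
      sample(k_choices, cfg$D, replace = TRUE)
    }
    cols <- vector("list", cfg$D)
    meta <- vector("list", cfg$D)
    for (d in seq_len(cfg$D)) {
      k <- sizes[d]
      prof <- matrix(0L, cfg$N, k)
      for (r in seq_len(k)) {
        prof[, r] <- if (d <= nrow(planted)) {
          planted_profile_ranks(cfg$N, sig_idx, signature$sign,
                                planted$strength[d], planted$direction[d])
        } else {
          null_profile_ranks(cfg$N)
        }
      }
      ids <- sprintf("%s_r%02d", compounds[d], seq_len(k))
      colnames(prof) <- ids
      cols[[d]] <- prof
      meta[[d]] <- tibble(profile_id = ids, compound = compounds[d])
    }
    ranks <- do.call(cbind, cols)
    rownames(ranks) <- universe
    db <- ref_db(ranks, bind_rows(meta))
  })
  list(db = db, truth = list(signature = signature, planted = planted))
}

#' Generate a ranked DE table and annotation map
#'
#' The table has a top tier of `n_signal` strongly significant genes
#' (large positive log2 ratios, p-values at or near zero — the first third
#' of the tier underflows to exactly 0 to exercise tie handling) above a
#' null remainder; positions are assigned by ascending p-value, sub-sorted
#' by descending absolute log2 ratio at equal p. The annotation map leaves
#' each gene unmapped with probability `unmapped_frac`, fans it out to
#' several probes with probability `multiprobe_frac`, and otherwise maps
#' it to one probe, drawing probes without replacement from the universe.
#'
#' @param cfg A [synth_config()].
#' @return List with `de` (tibble: `gene_id`, `symbol`, `log2ratio`,
#'   `pvalue`, `adjusted_pvalue`, `position`, sorted by position) and
#'   `ann` (tibble: `gene_id`, `probe_id`).
#' @export
gen_de_table <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  universe <- synth_universe(cfg)
  n <- cfg$n_genes
  ns <- cfg$n_signal
  withr::with_seed(cfg$seed, {
    gene_id <- sprintf("gene%04d", seq_len(n))
    symbol <- sprintf("G%04d", seq_len(n))
    lr <- c(rlnorm(ns, meanlog = log(3), sdlog = 0.3),
            stats::rnorm(n - ns, 0, 0.3))
    n_zero <- ceiling(ns / 3)
    p <- c(rep(0, n_zero), 10^(-runif(ns - n_zero, 20, 300)),
           runif(n - ns))
    u <- runif(n)
    msz <- if (length(cfg$multiprobe_probes) == 1L) {
      rep(cfg$multiprobe_probes, n)
    } else {
      sample(cfg$multiprobe_probes, n, replace = TRUE)
    }
    n_probes <- ifelse(
      u < cfg$unmapped_frac, 0L,
      ifelse(u < cfg$unmapped_frac + cfg$multiprobe_frac, msz, 1L)
    )
    if (sum(n_probes) > cfg$N) {
      abort("Annotation demands more probes than the universe holds.",
            class = "connmap_error_synth")
    }
    probes <- sample(universe, sum(n_probes))
    ann <- tibble(
      gene_id = rep(gene_id, n_probes),
      probe_id = probes
    )
    pos <- integer(n)
    pos[order(p, -abs(lr))] <- seq_len(n)
    de <- tibble(
      gene_id = gene_id, symbol = symbol, log2ratio = lr,
      pvalue = p, adjusted_pvalue = p.adjust(p, method = "BH"),
      position = pos
    ) |> arrange(.data$position)
  })
  list(de = de, ann = ann)
}

#' Generate a complete synthetic connectivity study
#'
#' Jointly configures the two generator halves so that the signature
#' obtained by mapping the DE table's top genes to the platform (length
#' `cfg$sig_m`) is exactly the signature planted in the reference
#' database.
#'
#' @param cfg A [synth_config()] with a non-`NULL` `planted` table.
#' @return List with `db`, `de`, `ann`, `signature` (the planted
#'   signature, identical to
#'   `map_genes_to_probes(de, ann, db$universe, cfg$sig_m)`) and `truth`.
#' @export
gen_connectivity_study <- function(cfg) {
  tabs <- gen_de_table(cfg)
  sig <- map_genes_to_probes(tabs$de, tabs$ann, synth_universe(cfg),
                             m = cfg$sig_m, name = "synthetic")
  gen <- gen_reference_db(cfg, signature = sig)
  list(db = gen$db, de = tabs$de, ann = tabs$ann, signature = sig,
       truth = gen$truth)
}
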