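# Shared fixtures and independent oracles, all built in code.

tiny_profile5 <- function() {
  tibble::tibble(probe_id = c("A", "B", "C", "D", "E"),
                 signed_rank = c(5L, -4L, 3L, -2L, 1L))
}

tiny_profile4 <- function() {
  tibble::tibble(probe_id = c("A", "B", "C", "D"),
                 signed_rank = c(4L, -3L, 2L, -1L))
}

lncap_de <- function() {
  read_de_table(system.file("extdata", "lncap_dht_deseq_top10.tsv",
                            package = "connmap"))
}

lncap_ann <- function() {
  read_annotation(system.file("extdata", "hgu133a_map_top10.tsv",
                              package = "connmap"))
}

# A universe holding the fixture's mapped probes plus some padding.
lncap_universe <- function() {
  c(lncap_ann()$probe_id, sprintf("pad_%03d", 1:30))
}

# Exhaustive randomization null: every m-subset of the universe crossed
# with every distinct assignment of the query's sign multiset. Independent
# of the sampling path in estimate_pvalue.
enum_pvalue_exact <- function(signs, rbar, c_abs_obs) {
  n <- length(rbar)
  m <- length(signs)
  kpos <- sum(signs > 0)
  subsets <- utils::combn(n, m)
  vals <- numeric(0)
  for (j in seq_len(ncol(subsets))) {
    s <- subsets[, j]
    if (kpos == 0L || kpos == m) {
      vals <- c(vals, abs(sum(signs * rbar[s])))
    } else {
      pos_choices <- utils::combn(m, kpos)
      for (q in seq_len(ncol(pos_choices))) {
        sg <- rep(-1, m)
        sg[pos_choices[, q]] <- 1
        vals <- c(vals, abs(sum(sg * rbar[s])))
      }
    }
  }
  mean(vals >= c_abs_obs - 1e-12)
}

# Known cross-platform candidate lists (compound, setsize, setscore per
# platform) used as a worked fixture for ranking and concordance.
candidate_pairs_fixture <- function() {
  tibble::tribble(
    ~refsetname,          ~setsize, ~score_ngs, ~score_array,
    "cotinine",            6L, -0.598, -0.377,
    "morantel",            5L, -0.557, -0.366,
    "tobramycin",          4L, -0.671, -0.348,
    "trioxysalen",         4L, -0.658, -0.383,
    "pentoxyverine",       4L, -0.601, -0.369,
    "levamisole",          4L, -0.569, -0.356,
    "trimetazidine",       4L, -0.552, -0.370,
    "chlorphenesin",       4L, -0.548, -0.398,
    "oxprenolol",          4L, -0.535, -0.336,
    "zomepirac",           4L, -0.533, -0.330,
    "lysergol",            4L, -0.505, -0.349,
    "fosfosal",            4L, -0.428, -0.280,
    "sertaconazole",       4L, -0.411, -0.256,
    "abamectin",           4L, -0.392, -0.245,
    "saquinavir",          4L, -0.359, -0.243,
    "ipratropium bromide", 3L, -0.564, -0.365,
    "furazolidone",        4L,  0.602,  0.344,
    "5186223",             1L,  0.701,  0.504
  )
}

# End-to-end run on a planted synthetic study; returns what the planted
# compound looked like in the ranked candidate list.
run_planted_pipeline <- function(seed, strength = 0.9, direction = -1,
                                 N = 2000, D = 200, K = 4, sig_m = 10,
                                 n_random = 2000) {
  cfg <- synth_config(
    N = N, D = D, K_range = c(K, K),
    planted = data.frame(compound = "planted", strength = strength,
                         direction = direction),
    sig_m = sig_m, seed = seed
  )
  study <- gen_connectivity_study(cfg)
  qcfg <- query_config(n_random = n_random, seed = seed)
  base <- query_database(study$signature, study$db, qcfg)
  rep <- perturbation_stability(study$signature, study$db, qcfg, base)
  ranked <- rank_results(add_stability(base, rep))
  planted_row <- ranked[ranked$refsetname == "planted", , drop = FALSE]
  list(
    ranked = ranked,
    top_is_planted = nrow(ranked) > 0 && ranked$refsetname[1] == "planted",
    planted_stability = if (nrow(planted_row)) planted_row$stability else NA,
    planted_setscore = if (nrow(planted_row)) planted_row$setscore else NA,
    base = base
  )
}

synth_universe_for_test <- function(cfg) {
  sprintf("p%05d", seq_len(cfg$N))
}
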