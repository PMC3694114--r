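test_that("connection score matches the signed-rank formula and its extremes", {
  prof <- tiny_profile5()
  # perfect match: top 2 magnitudes with matching signs
  expect_equal(connection_score(gene_signature(c("A", "B"), c(1, -1)), prof), 1)
  # hand evaluation: c = 5 - 4 = 1, c_max = 9
  expect_equal(connection_score(gene_signature(c("A", "B"), c(1, 1)), prof),
               1 / 9)
  # worst case is exactly -1
  expect_equal(connection_score(gene_signature(c("A", "B"), c(-1, 1)), prof),
               -1)
})

test_that("flipping all signature signs negates scores; bounds always hold", {
  withr::with_seed(3, {
    for (rep in 1:10) {
      n <- sample(6:30, 1)
      u <- sprintf("q%02d", seq_len(n))
      prof <- build_profile(tibble::tibble(probe_id = u,
                                           stat = stats::rnorm(n)), u)
      m <- sample(2:min(5, n - 1), 1)
      sig <- gene_signature(sample(u, m),
                            sample(c(-1L, 1L), m, replace = TRUE))
      flipped <- gene_signature(sig$probe_id, -sig$sign)
      s1 <- connection_score(sig, prof)
      expect_equal(connection_score(flipped, prof), -s1)
      expect_lte(abs(s1), 1)
    }
  })
})

test_that("setscore is the mean over replicate profiles and is invariant to duplication", {
  u <- c("A", "B", "C", "D", "E")
  p1 <- tibble::tibble(probe_id = u, signed_rank = c(5L, -4L, 3L, -2L, 1L))
  p2 <- tibble::tibble(probe_id = u, signed_rank = c(-1L, 2L, -5L, 4L, 3L))
  sig <- gene_signature(c("A", "C"), c(1, 1))
  s1 <- connection_score(sig, p1)
  s2 <- connection_score(sig, p2)
  expect_equal(set_score(sig, list(p1, p2)), (s1 + s2) / 2)
  expect_equal(set_score(sig, list(p1)), s1)
  # duplicating a profile within the set leaves the setscore unchanged
  expect_equal(set_score(sig, list(p1, p2, p1, p2)),
               set_score(sig, list(p1, p2)))
  # two profiles scoring 0.4 and -0.2 average to 0.1 by construction
  expect_equal(mean(c(0.4, -0.2)), 0.1)
  expect_error(set_score(sig, list()), class = "connmap_error_refset")
})

test_that("probe order on disk does not affect scores", {
  cfg <- synth_config(N = 50, D = 2, K_range = c(2, 2), seed = 13, sig_m = 5)
  gen <- gen_reference_db(cfg)
  sig <- gen$truth$signature
  ranks <- gen$db$ranks
  shuffled <- ranks[sample(nrow(ranks)), , drop = FALSE]
  expect_equal(set_score(sig, shuffled), set_score(sig, ranks))
})

test_that("sampled p-values match exhaustive enumeration on a 4-probe universe", {
  prof <- tiny_profile4()
  rbar <- setNames(as.numeric(prof$signed_rank), prof$probe_id)
  cfg <- query_config(n_random = 1e5, seed = 42)

  # |c_obs| = 6: only one of the 6 equal-signed pairs reaches it -> p = 1/6
  sig <- gene_signature(c("A", "C"), c(1, 1))
  p_exact <- enum_pvalue_exact(sig$sign, rbar, 6)
  expect_equal(p_exact, 1 / 6)
  p_hat <- estimate_pvalue(sig, list(prof), cfg)
  se <- sqrt(p_exact * (1 - p_exact) / cfg$n_random)
  expect_lt(abs(p_hat - p_exact), 3 * se + 2 / (cfg$n_random + 1))

  # |c_obs| = 1: every pair reaches it -> p = 1
  sig2 <- gene_signature(c("A", "B"), c(1, 1))
  expect_equal(enum_pvalue_exact(sig2$sign, rbar, 1), 1)
  p2 <- estimate_pvalue(sig2, list(prof), cfg)
  expect_equal(p2, 1, tolerance = 1e-4)
})

test_that("p-value estimation is reproducible from the seed and never zero", {
  prof <- tiny_profile5()
  sig <- gene_signature(c("A", "B"), c(1, -1))
  cfg <- query_config(n_random = 5000, seed = 77)
  p1 <- estimate_pvalue(sig, list(prof), cfg)
  p2 <- estimate_pvalue(sig, list(prof), cfg)
  expect_identical(p1, p2)
  expect_gt(p1, 0)   # add-one estimator floor
  # flipping all signs leaves the two-sided p-value unchanged
  p3 <- estimate_pvalue(gene_signature(sig$probe_id, -sig$sign),
                        list(prof), cfg)
  expect_identical(p3, p1)
})

test_that("database query flags the planted compound and respects Bonferroni", {
  cfg <- synth_config(
    N = 800, D = 20, K_range = c(2, 4),
    planted = data.frame(compound = "planted", strength = 1, direction = 1),
    sig_m = 8, seed = 19
  )
  gen <- gen_reference_db(cfg)
  q <- query_database(gen$truth$signature, gen$db,
                      query_config(n_random = 2000, seed = 2))
  planted <- q[q$refsetname == "planted", ]
  expect_equal(planted$sig, 1L)
  expect_equal(planted$setscore, 1)
  expect_true(all(abs(q$setscore[q$refsetname != "planted"]) <
                    abs(planted$setscore)))
  expect_equal(q$sig, as.integer(q$pvalue <= 1 / n_ref_sets(gen$db)))
  expect_error(
    query_database(gene_signature(character(0), integer(0)), gen$db,
                   query_config(n_random = 2000, seed = 2)),
    class = "connmap_error_signature"
  )
})

test_that("FDR estimate is alpha over the significant count, with a sentinel at zero", {
  expect_equal(estimate_fdr(271), 1 / 271)
  expect_equal(estimate_fdr(154), 1 / 154)
  expect_lte(estimate_fdr(271), 0.01)
  expect_lte(estimate_fdr(154), 0.01)
  expect_identical(estimate_fdr(0), Inf)
  expect_equal(estimate_fdr(10, alpha_family = 0.5), 0.05)
  # monotone decreasing in n_sig
  f <- vapply(1:20, estimate_fdr, numeric(1))
  expect_true(all(diff(f) < 0))
})

test_that("candidate ranking follows stability, setsize, |setscore|, name", {
  fx <- candidate_pairs_fixture()
  res <- tibble::tibble(
    refsetname = fx$refsetname, setsize = fx$setsize, queryName = "RNA-seq",
    queryLength = 10L, setscore = fx$score_ngs, pvalue = 1e-4, sig = 1L,
    stability = 1
  )
  ranked <- rank_results(res)
  expect_equal(
    ranked$refsetname,
    c("cotinine", "morantel", "tobramycin", "trioxysalen", "furazolidone",
      "pentoxyverine", "levamisole", "trimetazidine", "chlorphenesin",
      "oxprenolol", "zomepirac", "lysergol", "fosfosal", "sertaconazole",
      "abamectin", "saquinavir", "ipratropium bromide", "5186223")
  )

  # all keys equal -> alphabetical by compound
  tie <- res[1:3, ]
  tie$refsetname <- c("zeta", "alpha", "mid")
  tie$setsize <- 2L
  tie$setscore <- 0.4
  expect_equal(rank_results(tie)$refsetname, c("alpha", "mid", "zeta"))

  # a single significant row ranks as itself
  expect_equal(rank_results(res[1, ])$refsetname, "cotinine")

  # missing stability on a significant row is an error
  broken <- res
  broken$stability[2] <- NA
  expect_error(rank_results(broken), class = "connmap_error_rank")
})
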