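test_that("every generated profile is a valid signed-rank permutation", {
  cfg <- synth_config(
    N = 120, D = 8, K_range = c(1, 4),
    planted = data.frame(compound = c("p1", "p2"),
                         strength = c(0.5, 1), direction = c(1, -1)),
    sig_m = 6, seed = 17
  )
  gen <- gen_reference_db(cfg)     # ref_db() validates on construction
  for (j in seq_len(ncol(gen$db$ranks))) {
    expect_identical(unname(sort(abs(gen$db$ranks[, j]))), seq_len(120))
  }
  expect_equal(n_ref_sets(gen$db), 8)
  sizes <- ref_sets(gen$db)$setsize
  expect_true(all(sizes >= 1 & sizes <= 4))
})

test_that("a full-strength planting scores exactly +/-1 by construction", {
  for (dir in c(1, -1)) {
    cfg <- synth_config(
      N = 300, D = 3, K_range = c(2, 2),
      planted = data.frame(compound = "planted", strength = 1,
                           direction = dir),
      sig_m = 7, seed = 23
    )
    gen <- gen_reference_db(cfg)
    ids <- gen$db$meta$profile_id[gen$db$meta$compound == "planted"]
    for (id in ids) {
      prof <- tibble::tibble(probe_id = gen$db$universe,
                             signed_rank = gen$db$ranks[, id])
      expect_equal(connection_score(gen$truth$signature, prof), dir * 1)
    }
  }
})

test_that("a zero-strength planting is statistically indistinguishable from null", {
  pvals <- vapply(1:30, function(s) {
    cfg <- synth_config(
      N = 300, D = 1, K_range = c(2, 2),
      planted = data.frame(compound = "planted", strength = 0, direction = 1),
      sig_m = 5, seed = 1000 + s
    )
    gen <- gen_reference_db(cfg)
    ids <- gen$db$meta$profile_id[gen$db$meta$compound == "planted"]
    estimate_pvalue(gen$truth$signature, gen$db$ranks[, ids, drop = FALSE],
                    query_config(n_random = 1000, seed = s))
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("generation is byte-identical under the same seed", {
  cfg <- synth_config(N = 150, D = 5, K_range = c(1, 3), seed = 9,
                      sig_m = 5, n_genes = 50, n_signal = 10)
  t1 <- gen_de_table(cfg)
  t2 <- gen_de_table(cfg)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_de_table(t1$de, f1)
  write_de_table(t2$de, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  write_annotation(t1$ann, f1)
  write_annotation(t2$ann, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(gen_reference_db(cfg)$db$ranks,
                   gen_reference_db(cfg)$db$ranks)
})

test_that("DE table is position-ranked with the documented tie sub-sort", {
  cfg <- synth_config(N = 400, D = 2, K_range = c(1, 1), seed = 31,
                      n_genes = 80, n_signal = 20)
  de <- gen_de_table(cfg)$de
  expect_identical(sort(de$position), seq_len(80))
  expect_identical(de$position, seq_len(80))     # returned sorted
  expect_true(!is.unsorted(de$pvalue))           # position order follows p
  # at equal p (the underflow tier), larger |log2ratio| ranks first
  zero <- de[de$pvalue == 0, ]
  expect_gt(nrow(zero), 1)
  expect_true(!is.unsorted(rev(abs(zero$log2ratio))))
})

test_that("annotation shape follows the unmapped and multi-probe fractions", {
  cfg <- synth_config(N = 900, D = 2, K_range = c(1, 1), seed = 37,
                      n_genes = 600, n_signal = 30,
                      unmapped_frac = 0.3, multiprobe_frac = 0.2)
  tabs <- gen_de_table(cfg)
  counts <- table(factor(tabs$ann$gene_id, levels = tabs$de$gene_id))
  n_unmapped <- sum(counts == 0)
  n_multi <- sum(counts >= 2)
  # binomial 3-sigma bands around 600 * 0.3 and 600 * 0.2
  expect_lt(abs(n_unmapped - 180), 3 * sqrt(600 * 0.3 * 0.7))
  expect_lt(abs(n_multi - 120), 3 * sqrt(600 * 0.2 * 0.8))
  expect_false(anyDuplicated(tabs$ann$probe_id) > 0)
})

test_that("with three probes per gene a nine-probe signature spans three genes", {
  cfg <- synth_config(N = 200, D = 1, K_range = c(1, 1), seed = 43,
                      n_genes = 30, n_signal = 10,
                      unmapped_frac = 0, multiprobe_frac = 1,
                      multiprobe_probes = 3L, sig_m = 9)
  tabs <- gen_de_table(cfg)
  sig <- map_genes_to_probes(tabs$de, tabs$ann, synth_universe_for_test(cfg),
                             m = 9)
  genes <- tabs$ann$gene_id[match(sig$probe_id, tabs$ann$probe_id)]
  expect_equal(length(unique(genes)), 3)
})

test_that("planted setscore strength grows with the planting strength", {
  lambdas <- c(0, 0.25, 0.5, 0.75, 1)
  mean_abs <- vapply(lambdas, function(l) {
    scores <- vapply(1:20, function(s) {
      cfg <- synth_config(
        N = 500, D = 1, K_range = c(4, 4),
        planted = data.frame(compound = "planted", strength = l,
                             direction = 1),
        sig_m = 10, seed = 2000 + s
      )
      gen <- gen_reference_db(cfg)
      set_score(gen$truth$signature, gen$db$ranks)
    }, numeric(1))
    mean(abs(scores))
  }, numeric(1))
  expect_true(all(diff(mean_abs) > 0))
  expect_equal(mean_abs[5], 1)
})

test_that("jointly generated studies plant exactly the mapped signature", {
  cfg <- synth_config(
    N = 700, D = 10, K_range = c(2, 2),
    planted = data.frame(compound = "planted", strength = 1, direction = 1),
    sig_m = 8, seed = 47
  )
  study <- gen_connectivity_study(cfg)
  remapped <- map_genes_to_probes(study$de, study$ann, study$db$universe,
                                  m = 8)
  expect_equal(remapped$probe_id, study$signature$probe_id)
  expect_equal(remapped$sign, study$signature$sign)
  expect_equal(set_score(study$signature,
                         study$db$ranks[, study$db$meta$compound == "planted",
                                        drop = FALSE]),
               1)
})
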