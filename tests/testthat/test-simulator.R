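test_that("configuration invariants are enforced", {
  expect_error(sim_config(ado_rate = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(K_clones = 1, doublet_rate = 0.1),
               "at least 2 clones")
  expect_error(sim_config(clone_proportions = c(0.7, 0.5)), "sum to 1")
  expect_error(sim_config(mutations_per_edge = c(10, 10)), "length")
  expect_error(sim_config(mutations_per_edge = c(10, 10, 10)), "sum to")
  ok <- sim_config(n_snv = 4, n_sv = 6, mutations_per_edge = c(4, 3, 3))
  expect_s3_class(ok, "sim_config")
})

test_that("truth respects the clonal structure invariants", {
  tr <- simulate_truth(sim_config(seed = 11, K_clones = 3,
                                  clone_proportions = c(0.5, 0.3, 0.2)))
  # infinite sites: every assay on exactly one edge
  expect_true(all(tr$assays$edge %in% 0:3))
  # each clone's genotype = ancestral edge + its own private edge
  for (k in 1:3) {
    expect_identical(unname(tr$clone_genotypes[k, ]),
                     as.integer(tr$assays$edge %in% c(0L, k)))
  }
  # cell genotypes: singlets copy their clone, doublets take the union
  for (i in seq_len(nrow(tr$cells))) {
    expected <- tr$clone_genotypes[tr$cells$clone_a[i], ]
    if (tr$cells$is_doublet[i]) {
      expected <- pmax(expected, tr$clone_genotypes[tr$cells$clone_b[i], ])
      expect_true(tr$cells$clone_a[i] != tr$cells$clone_b[i])
    }
    expect_identical(unname(tr$cell_genotypes[i, ]), unname(expected))
  }
})

test_that("ancestral_sv_only keeps every SNV off the root edge", {
  tr <- simulate_truth(sim_config(seed = 12, ancestral_sv_only = TRUE))
  anc <- tr$assays$edge == 0L
  expect_true(all(tr$assays$class[anc] == "sv"))
  expect_gt(sum(anc), 0L)
  # with one clone and no noise sources, all cells share one genotype
  tr1 <- simulate_truth(sim_config(seed = 13, K_clones = 1,
                                   doublet_rate = 0))
  expect_identical(nrow(unique(tr1$cell_genotypes)), 1L)
})

test_that("fixed seed reproduces truth, observations and reads bit-identically", {
  cfg <- sim_config(seed = 14, n_cells = 12, n_snv = 6, n_sv = 4)
  t1 <- simulate_truth(cfg); t2 <- simulate_truth(cfg)
  expect_identical(t1, t2)
  s1 <- simulate_observations(t1, level = "reads")
  s2 <- simulate_observations(t2, level = "reads")
  expect_identical(s1$snv_counts, s2$snv_counts)
  expect_identical(s1$junction_counts, s2$junction_counts)
  expect_identical(s1$reads, s2$reads)
  # written outputs byte-identical
  d1 <- tempfile(); d2 <- tempfile()
  write_simulation(s1, d1); write_simulation(s2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in grep("\\.tsv$", f1, value = TRUE)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("noiseless high-depth data lets the filters recover truth exactly", {
  cfg <- sim_config(seed = 15, n_cells = 40, ado_rate = 0, fp_rate = 0,
                    doublet_rate = 0, poor_assay_fraction = 0,
                    depth_mean = 1000, error_vaf = 0)
  tr <- simulate_truth(cfg)
  sim <- simulate_observations(tr)
  sg <- sim_genotype_matrix(sim)
  expect_true(all(sg$qc$pass))
  expect_identical(unname(sg$gm$X),
                   unname(tr$cell_genotypes[rownames(sg$gm$X), ]))
  expect_true(all(sg$gm$mask == 0L))
})

test_that("realized dropout and junction-read statistics match the model", {
  cfg <- sim_config(seed = 16, n_cells = 500, fp_rate = 0,
                    doublet_rate = 0, poor_assay_fraction = 0)
  tr <- simulate_truth(cfg)
  sim <- simulate_observations(tr)
  # dropout frequency among truly-present entries within 3 binomial SDs
  present <- tr$cell_genotypes == 1L
  dropped <- present & sim$effective_genotypes == 0L
  n_present <- sum(present)
  p_hat <- sum(dropped) / n_present
  se <- sqrt(0.1 * 0.9 / n_present)
  expect_lt(abs(p_hat - 0.1), 3 * se)
  # junction-read counts for effectively-present SVs: mean within 3 SEs of 100
  sv_ids <- tr$assays$assay_id[tr$assays$class == "sv"]
  eff <- sim$effective_genotypes[, sv_ids]
  jc <- sim$junction_counts
  eff_flag <- eff[cbind(match(jc$cell_id, rownames(eff)),
                        match(jc$assay_id, colnames(eff)))] == 1L
  x <- jc$n_match_true[eff_flag]
  expect_lt(abs(mean(x) - 100), 3 * sqrt(100 / length(x)))
})

test_that("materialized reads reproduce the drawn junction counts exactly", {
  cfg <- sim_config(seed = 17, n_cells = 4, n_snv = 3, n_sv = 3,
                    n_background_reads = 20)
  tr <- simulate_truth(cfg)
  sim <- simulate_observations(tr, level = "reads")
  m <- sim_manifests(tr)
  for (cid in sim$cells$cell_id) {
    calls <- genotype_sv_cell(sim$reads[[cid]], m$junctions, cell_id = cid)
    want <- sim$junction_counts[sim$junction_counts$cell_id == cid, ]
    expect_identical(calls$n_match[match(want$assay_id, calls$assay_id)],
                     want$n_match_true)
  }
})
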