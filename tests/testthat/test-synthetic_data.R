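test_that("simulate_genome is deterministic and respects its constraints", {
  spec <- genome_spec(c(chrT = 1e5), n_genes = 10L)
  g1 <- simulate_genome(spec, 5L)
  g2 <- simulate_genome(spec, 5L)
  expect_identical(g1, g2)
  expect_true(all(g1$pos >= 0 & g1$pos < 1e5))
  expect_true(all(diff(g1$pos) >= 2000L))
  expect_error(simulate_genome(genome_spec(c(chrT = 1e4), n_genes = 10L), 1L),
               "infeasible")
  # strand fraction is near one half at scale
  big <- simulate_genome(genome_spec(), 6L)
  expect_lt(abs(mean(big$strand == "+") - 0.5), 0.05)
})

test_that("archetype constraints are validated", {
  expect_error(factor_archetype("X", "promoter", 0.5, 0.2, 0.2), "p_tss")
  expect_error(factor_archetype("X", "weird", 0.5, 0.3, 0.2))
  expect_error(ground_truth(modules = list(
    m = list(factors = "NOPE", size = 10L))))
})

test_that("simulated experiments honour archetypes and module exclusivity", {
  spec <- small_spec()
  truth <- small_truth()
  tss <- simulate_genome(spec, 30L)
  sim <- simulate_experiments(truth, tss, spec, 31L)
  expect_equal(nrow(sim$manifest), 8L)  # 4 factors x 2 cell types
  # peak counts match the archetype demand and all BEDs are valid
  for (id in names(sim$peaks)) {
    f <- sim$manifest$factor[sim$manifest$experiment_id == id]
    expect_equal(nrow(sim$peaks[[id]]), truth$archetypes[[f]]$n_peaks)
    expect_silent(validate_intervals(sim$peaks[[id]]))
  }
  # the shared factor reuses one region set across cell types
  expect_equal(sim$peaks[["CT.cellA.1"]], sim$peaks[["CT.cellB.1"]])
  # planted pair module: exact pattern recovered nearly in full per cell type
  for (ct in c("cellA", "cellB")) {
    fbm <- factor_binding_matrix(sim$manifest[sim$manifest$cell_type == ct, ],
                                 ct, sim$peaks)
    pc <- pattern_counts(fbm)
    expect_gte(pc$count[pc$pattern == "MA+MB"],
               0.95 * truth$modules$pair$size)
  }
})

test_that("realized location profiles track the archetype fractions", {
  spec <- small_spec()
  truth <- small_truth()
  tss <- simulate_genome(spec, 32L)
  sim <- simulate_experiments(truth, tss, spec, 33L)
  profs <- location_profiles(sim$manifest, tss, sim$peaks)
  pr <- profs[profs$factor == "PR", ][1L, ]
  # binomial tolerance at n = 150
  expect_lt(abs(pr$f_tss - 0.8), 0.1)
  ct <- profs[profs$factor == "CT", ][1L, ]
  expect_lt(abs(ct$f_tss - 0.1), 0.1)
})

test_that("replicates correlate above cross-factor pairs", {
  spec <- small_spec()
  truth <- small_truth(n_replicates = 2L)
  tss <- simulate_genome(spec, 34L)
  sim <- simulate_experiments(truth, tss, spec, 35L)
  bm <- build_binding_matrix(sim$manifest, sim$peaks)
  corr <- correlate_binding(bm)
  r_rep <- corr["PR.cellA.1", "PR.cellA.2"]
  cross <- corr["PR.cellA.1",
                setdiff(colnames(corr), c("PR.cellA.1", "PR.cellA.2"))]
  expect_gt(r_rep, max(cross))
})

test_that("simulate_gwas places hits at the requested enrichment", {
  spec <- small_spec()
  truth <- small_truth()
  tss <- simulate_genome(spec, 36L)
  sim <- simulate_experiments(truth, tss, spec, 37L)
  gw <- simulate_gwas(truth, sim$peaks, sim$manifest, spec, 38L)
  expect_equal(nrow(gw), truth$n_gwas_hits)
  expect_true(all(gw$pos >= 0))
  # empty table for zero hits
  t0 <- small_truth(); t0$n_gwas_hits <- 0L
  expect_equal(nrow(simulate_gwas(t0, sim$peaks, sim$manifest, spec, 39L)), 0L)
})

test_that("datasets are reproducible from the seed and round-trip to disk", {
  spec <- small_spec()
  truth <- small_truth()
  s1 <- simulate_dataset(9L, spec, truth)
  s2 <- simulate_dataset(9L, spec, truth)
  expect_identical(s1$peaks, s2$peaks)
  expect_identical(s1$gwas, s2$gwas)
  d <- withr::local_tempdir()
  s3 <- simulate_dataset(9L, spec, truth, out_dir = d)
  man <- read_manifest(file.path(d, "manifest.tsv"))
  expect_equal(man$experiment_id, s3$manifest$experiment_id)
  p <- read_peaks_bed(man$peak_path[1L])
  expect_equal(p[, c("chrom", "start", "end")],
               s3$peaks[[man$experiment_id[1L]]])
  tss_back <- read_tss_bed(file.path(d, "tss.bed"))
  s3_tss <- s3$tss[order(s3$tss$chrom, s3$tss$pos, s3$tss$gene_id), ]
  rownames(s3_tss) <- rownames(tss_back) <- NULL
  expect_equal(tss_back, s3_tss)
  gw <- suppressMessages(read_gwas_catalog(file.path(d, "gwas.tsv")))
  expect_equal(nrow(gw), nrow(s3$gwas))
  expect_equal(gw$pos, s3$gwas$pos)
  truth_json <- jsonlite::read_json(file.path(d, "ground_truth.json"))
  expect_equal(truth_json$seed, 9L)
  expect_equal(truth_json$truth$gwas_factor, "CT")
})
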