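test_that("cell-type selection counts distinct factors inclusively", {
  man <- data.frame(
    experiment_id = sprintf("e%02d", 1:13),
    cell_type = rep(c("six", "five"), c(7, 6)),
    factor = c(LETTERS[1:6], "A",          # 6 distinct, one replicated
               letters[1:5], "a"),         # 5 distinct
    species = "human", peak_path = NA)
  expect_equal(select_combinatorial_cell_types(man, 6L), "six")
  expect_equal(select_combinatorial_cell_types(man, 5L),
               c("six", "five"))
})

test_that("factor_binding_matrix collapses replicates by peak union", {
  set.seed(81)
  pA1 <- random_intervals(20); pA2 <- random_intervals(20)
  pB <- random_intervals(20)
  man <- fixture_manifest(list(eA1 = pA1, eA2 = pA2, eB = pB),
                          factors = c("A", "A", "B"))
  fbm <- factor_binding_matrix(man, "cellX",
                               list(eA1 = pA1, eA2 = pA2, eB = pB))
  expect_equal(colnames(fbm$occupancy), c("A", "B"))
  # column A marks exactly the regions overlapped by the union of A's peaks
  unionA <- rbind(pA1, pA2)
  want <- vapply(seq_len(nrow(fbm$regions)), function(i)
    any(unionA$chrom == fbm$regions$chrom[i] &
          unionA$start < fbm$regions$end[i] &
          unionA$end > fbm$regions$start[i]), TRUE)
  expect_equal(fbm$occupancy[, "A"] == 1L, want)
})

test_that("pattern_counts enumerates exact patterns", {
  occ <- matrix(c(1, 0, 1, 1,
                  0, 1, 1, 1), ncol = 2,
                dimnames = list(NULL, c("A", "B")))
  pc <- pattern_counts(occ)
  expect_equal(pc$count[pc$pattern == "A+B"], 2L)
  expect_equal(pc$count[pc$pattern == "A"], 1L)
  expect_equal(pc$count[pc$pattern == "B"], 1L)
  # N = 1: a single pattern carrying the column sum
  one <- matrix(1L, 7, 1, dimnames = list(NULL, "Z"))
  pc1 <- pattern_counts(one)
  expect_equal(pc1$count, 7L)
  # all-zero rows violate the matrix invariant
  expect_error(pattern_counts(rbind(occ, c(0, 0))), "all-zero")
})

test_that("pattern_counts matches a string-tally oracle on random matrices", {
  set.seed(82)
  occ <- matrix(rbinom(2000L, 1L, 0.4), 500L, 4L,
                dimnames = list(NULL, c("A", "B", "C", "D")))
  occ[rowSums(occ) == 0L, 1L] <- 1L
  pc <- pattern_counts(occ)
  keys <- apply(occ, 1L, paste, collapse = "")
  tal <- table(keys)
  for (i in seq_len(nrow(pc))) {
    key <- paste(as.integer(bitwAnd(pc$code[i], c(1L, 2L, 4L, 8L)) > 0L),
                 collapse = "")
    expect_equal(pc$count[i], as.integer(tal[[key]]))
  }
  expect_equal(sum(pc$count), nrow(occ))  # partition of the bound regions
})

test_that("randomization preserves column sums and fixes all-ones columns", {
  set.seed(83)
  occ <- matrix(rbinom(300L, 1L, 0.3), 100L, 3L)
  occ[, 3L] <- 1L
  for (i in 1:100) {
    r <- randomize_occupancy(occ)
    expect_identical(colSums(r), colSums(occ))
    expect_true(all(r[, 3L] == 1L))
  }
})

test_that("pairwise co-occurrence under randomization follows the hypergeometric null", {
  set.seed(84)
  M <- 200L; n1 <- 70L; n2 <- 40L
  occ <- matrix(0L, M, 2L)
  occ[seq_len(n1), 1L] <- 1L
  occ[seq_len(n2), 2L] <- 1L
  R <- 2000L
  both <- replicate(R, { r <- randomize_occupancy(occ); sum(r[, 1] & r[, 2]) })
  mu <- n1 * n2 / M
  v <- n1 * n2 * (M - n1) * (M - n2) / (M^2 * (M - 1))
  expect_lt(abs(mean(both) - mu), 3 * sqrt(v / R))
})

test_that("enrichment_test flags planted duplicate factors and stays calm otherwise", {
  set.seed(85)
  M <- 20000L
  occ <- matrix(0L, M, 4L, dimnames = list(NULL, c("A", "B", "C", "D")))
  shared <- sample.int(M, 200L)
  occ[shared, "A"] <- 1L
  occ[shared, "B"] <- 1L
  occ[sample.int(M, 2000L), "C"] <- 1L
  occ[sample.int(M, 2000L), "D"] <- 1L
  res <- enrichment_test(occ, n_rand = 100L, seed = 7L)
  top <- res[1L, ]
  expect_equal(top$pattern, "A+B")
  expect_gt(top$z, 10)
  expect_lt(top$p_bonf, 1e-10)
  # hypergeometric null mean for the duplicated pair: ~ n^2 / M = 2
  expect_lt(abs(top$null_mean - 200^2 / M), 1.5)
  # results are sorted by corrected p (log scale)
  expect_equal(res$log10_p_raw, sort(res$log10_p_raw))
})

test_that("a single factor is its own null (p = 1)", {
  occ <- matrix(0L, 50L, 1L, dimnames = list(NULL, "A"))
  occ[1:20, 1L] <- 1L
  res <- enrichment_test(occ[rowSums(occ) > 0, , drop = FALSE],
                         n_rand = 50L, seed = 1L)
  expect_equal(res$p_raw, 1)
  expect_true(res$degenerate)
})

test_that("combination_enrichment runs per eligible cell type", {
  set.seed(86)
  peaks <- lapply(1:6, function(i) random_intervals(30))
  names(peaks) <- sprintf("e%d", 1:6)
  man <- fixture_manifest(peaks, factors = c("F1", "F2", "F3", "F1", "F2", "F3"),
                          cell_types = rep(c("ctA", "ctB"), each = 3))
  res <- combination_enrichment(man, peaks, min_factors = 3L, n_rand = 20L,
                                seed = 5L)
  expect_setequal(unique(res$cell_type), c("ctA", "ctB"))
  expect_true(all(res$p_bonf >= res$p_raw - 1e-12))
  expect_true(all(res$p_bonf <= 1))
  # below the factor threshold nothing is tested
  expect_equal(nrow(suppressMessages(
    combination_enrichment(man, peaks, min_factors = 4L, n_rand = 5L,
                           seed = 1L))), 0L)
})
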