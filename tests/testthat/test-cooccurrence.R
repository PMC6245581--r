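test_that("build_binding_matrix covers the definitional cases", {
  p1 <- data.frame(chrom = "chr1", start = c(0L, 100L, 200L),
                   end = c(50L, 150L, 250L))
  man <- fixture_manifest(list(e1 = p1))
  bm <- build_binding_matrix(man, list(e1 = p1))
  expect_equal(dim(bm$occupancy), c(3L, 1L))
  expect_true(all(bm$occupancy == 1L))
  # identical peak files give identical columns
  man2 <- fixture_manifest(list(e1 = p1, e2 = p1))
  bm2 <- build_binding_matrix(man2, list(e1 = p1, e2 = p1))
  expect_equal(bm2$occupancy[, "e1"], bm2$occupancy[, "e2"])
  # zero-peak experiment kept as all-zero column, with a warning
  empty <- p1[0, ]
  man3 <- fixture_manifest(list(e1 = p1, e0 = empty))
  expect_warning(bm3 <- build_binding_matrix(man3, list(e1 = p1, e0 = empty)),
                 "zero peaks")
  expect_true(all(bm3$occupancy[, "e0"] == 0L))
})

test_that("matrix cells match a brute-force overlap scan on a 5-experiment fixture", {
  set.seed(51)
  peaks <- lapply(1:5, function(i) random_intervals(40))
  names(peaks) <- paste0("e", 1:5)
  man <- fixture_manifest(peaks)
  bm <- build_binding_matrix(man, peaks)
  for (j in seq_along(peaks)) {
    p <- peaks[[j]]
    want <- vapply(seq_len(nrow(bm$regions)), function(i)
      any(p$chrom == bm$regions$chrom[i] & p$start < bm$regions$end[i] &
            p$end > bm$regions$start[i]), TRUE)
    expect_equal(bm$occupancy[, j] == 1L, want)
  }
  # every region came from at least one peak
  expect_true(all(rowSums(bm$occupancy) >= 1L))
})

test_that("reference tracks overlay without creating regions", {
  set.seed(52)
  peaks <- list(e1 = random_intervals(30), e2 = random_intervals(30))
  bm <- build_binding_matrix(fixture_manifest(peaks), peaks)
  M <- nrow(bm$regions)
  # a track covering everything -> all ones
  full <- data.frame(chrom = c("chr1", "chr2"), start = 0L, end = 2000L)
  bm1 <- add_reference_track(bm, full, "FULL")
  expect_true(all(bm1$occupancy[, "FULL"] == 1L))
  expect_equal(nrow(bm1$regions), M)
  # empty track -> all zeros
  bm2 <- add_reference_track(bm, full[0, ], "EMPTY")
  expect_true(all(bm2$occupancy[, "EMPTY"] == 0L))
  # a point track matches the brute-force overlap
  pts <- data.frame(chrom = "chr1", pos = sample.int(2000L, 25) - 1L)
  bm3 <- add_reference_track(bm, pts, "PTS")
  want <- vapply(seq_len(M), function(i)
    any(pts$chrom == bm$regions$chrom[i] & pts$pos >= bm$regions$start[i] &
          pts$pos < bm$regions$end[i]), TRUE)
  expect_equal(bm3$occupancy[, "PTS"] == 1L, want)
  expect_error(add_reference_track(bm, pts, "e1"), "collides")
})

test_that("correlation equals the phi closed form and handles constants", {
  set.seed(53)
  occ <- matrix(rbinom(400L, 1L, 0.4), 100L, 4L,
                dimnames = list(NULL, paste0("e", 1:4)))
  occ[, 1] <- occ[, 2]                      # identical pair
  bm <- bm_from_occupancy(occ)
  corr <- correlate_binding(bm)
  expect_equal(corr["e1", "e2"], 1)
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(corr[i, j], oracle_phi(occ[, i] == 1L, occ[, j] == 1L),
                 tolerance = 1e-12)
  # complement of a non-constant column
  occ2 <- cbind(a = occ[, 3], b = 1L - occ[, 3])
  corr2 <- correlate_binding(bm_from_occupancy(occ2))
  expect_equal(corr2["a", "b"], -1)
  # constant column: 0 against others, 1 with itself
  occ3 <- cbind(occ[, 1:2], const = 1L)
  corr3 <- correlate_binding(bm_from_occupancy(occ3))
  expect_equal(corr3["const", "const"], 1)
  expect_equal(corr3["const", "e1"], 0)
})

test_that("correlation is equivariant under column permutation", {
  set.seed(54)
  occ <- matrix(rbinom(600L, 1L, 0.3), 100L, 6L,
                dimnames = list(NULL, paste0("e", 1:6)))
  corr <- correlate_binding(bm_from_occupancy(occ))
  perm <- sample(6L)
  corr_p <- correlate_binding(bm_from_occupancy(occ[, perm]))
  expect_equal(corr_p, corr[perm, perm])
})

test_that("duplicate experiments end up adjacent in the optimal leaf order", {
  set.seed(55)
  occ <- matrix(rbinom(1200L, 1L, 0.3), 200L, 6L)
  occ[, 2] <- occ[, 1]
  occ[, 4] <- occ[, 3]
  colnames(occ) <- c("a1", "a2", "b1", "b2", "c", "d")
  cc <- cluster_correlation(correlate_binding(bm_from_occupancy(occ)))
  ord <- cc$leaf_order
  expect_equal(abs(diff(match(c("a1", "a2"), ord))), 1L)
  expect_equal(abs(diff(match(c("b1", "b2"), ord))), 1L)
})

test_that("an obvious outlier merges last in complete linkage", {
  corr <- diag(4)
  corr[1, 2] <- corr[2, 1] <- 0.9
  corr[1, 3] <- corr[3, 1] <- 0.8
  corr[2, 3] <- corr[3, 2] <- 0.85
  corr[1:3, 4] <- corr[4, 1:3] <- -0.9
  colnames(corr) <- rownames(corr) <- paste0("e", 1:4)
  cc <- cluster_correlation(corr)
  # the last merge joins the outlier singleton to the rest
  last <- cc$hclust$merge[3, ]
  expect_true(-4 %in% last)
  expect_error(cluster_correlation(corr[1, 1, drop = FALSE]), ">= 2")
})

test_that("leaf order attains the exhaustive minimum for small N", {
  set.seed(56)
  for (n in c(4L, 6L, 7L)) {
    x <- matrix(rnorm(n * 6), n)
    corr <- cor(t(x))
    colnames(corr) <- rownames(corr) <- paste0("e", seq_len(n))
    cc <- cluster_correlation(corr)
    best <- min(vapply(oracle_tree_orders(cc$hclust),
                       adjacent_distance_sum, 0, dmat = cc$dist))
    expect_equal(adjacent_distance_sum(cc$order, cc$dist), best,
                 tolerance = 1e-12)
  }
})

test_that("subsetting keeps selected columns and drops empty rows", {
  set.seed(57)
  peaks <- lapply(1:4, function(i) random_intervals(30))
  names(peaks) <- paste0("e", 1:4)
  man <- fixture_manifest(peaks, factors = c("F1", "F1", "F2", "F2"),
                          cell_types = c("ctA", "ctA", "ctB", "ctB"))
  bm <- build_binding_matrix(man, peaks)
  # identity subset
  all_bm <- subset_binding_matrix(bm, cell_type = c("ctA", "ctB"))
  expect_equal(all_bm$occupancy, bm$occupancy)
  # one cell type: kept rows are exactly those bound in that cell type
  a <- subset_binding_matrix(bm, cell_type = "ctA")
  want_rows <- rowSums(bm$occupancy[, c("e1", "e2")]) > 0L
  expect_equal(nrow(a$regions), sum(want_rows))
  expect_equal(a$occupancy,
               bm$occupancy[want_rows, c("e1", "e2"), drop = FALSE])
  expect_error(subset_binding_matrix(bm, factor = "NOPE"), "valid")
})

test_that("binding-matrix export/import round trip", {
  set.seed(58)
  peaks <- list(e1 = random_intervals(25), e2 = random_intervals(25))
  man <- fixture_manifest(peaks)
  bm <- build_binding_matrix(man, peaks)
  bm <- add_reference_track(bm, data.frame(chrom = "chr1", pos = 100L), "TSS")
  d <- withr::local_tempdir()
  export_binding_matrix(bm, d)
  back <- import_binding_matrix(d, man)
  expect_equal(back$regions, bm$regions)
  expect_equal(back$occupancy, bm$occupancy)
  expect_equal(back$is_reference, bm$is_reference)
})
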