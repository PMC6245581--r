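test_that("mark_gwas_regions uses half-open semantics and records traits", {
  regions <- data.frame(chrom = "chr1", start = c(100L, 300L),
                        end = c(200L, 400L))
  hits <- data.frame(chrom = "chr1", pos = c(150L, 200L, 399L),
                     trait = c("t1", "t2", "t3"))
  mk <- mark_gwas_regions(regions, hits)
  expect_equal(mk$marked, c(TRUE, TRUE))
  # pos 200 marks nothing by itself: region 1 is [100, 200)
  mk1 <- mark_gwas_regions(regions, hits[2, ])
  expect_equal(mk1$marked, c(FALSE, FALSE))
  # ... but a 1 bp window pulls it into region 1
  mk2 <- mark_gwas_regions(regions, hits[2, ], window = 1L)
  expect_equal(mk2$marked, c(TRUE, FALSE))
  expect_equal(sort(mk$traits$trait), c("t1", "t3"))
})

test_that("marking matches a brute-force double loop", {
  set.seed(91)
  regions <- merge_intervals(random_intervals(100))
  hits <- data.frame(chrom = sample(c("chr1", "chr2"), 30, TRUE),
                     pos = sample.int(2000L, 30) - 1L,
                     trait = sample(c("t1", "t2"), 30, TRUE))
  mk <- mark_gwas_regions(regions, hits)
  want <- vapply(seq_len(nrow(regions)), function(i)
    any(hits$chrom == regions$chrom[i] & hits$pos >= regions$start[i] &
          hits$pos < regions$end[i]), TRUE)
  expect_equal(mk$marked, want)
})

test_that("hypergeometric tail is exact on hand-checked values", {
  expect_equal(hypergeometric_overlap(10, 4, 5, 0), 1)
  expect_equal(hypergeometric_overlap(10, 4, 5, 4), 6 / 252,
               tolerance = 1e-14)
  # vectorized over k, monotone non-increasing
  p <- hypergeometric_overlap(100, 20, 30, 0:20)
  expect_equal(p, sort(p, decreasing = TRUE))
  expect_error(hypergeometric_overlap(10, 11, 5, 1), "require")
  expect_error(hypergeometric_overlap(10, 4, 5, 5), "k")
})

test_that("hypergeometric tail matches direct summation and phyper", {
  set.seed(92)
  for (rep in 1:50) {
    U <- sample(5:60, 1)
    K <- sample(0:U, 1)
    n <- sample(0:U, 1)
    k <- 0:min(K, n)
    got <- hypergeometric_overlap(U, K, n, k)
    want <- oracle_hyper_tail(U, K, n, k)
    expect_equal(got, want, tolerance = 1e-12)
    expect_equal(got, phyper(k - 1, K, U - K, n, lower.tail = FALSE),
                 tolerance = 1e-12)
    # symmetry of the 2x2 margins
    expect_equal(got, hypergeometric_overlap(U, n, K, k), tolerance = 1e-12)
  }
})

test_that("log-space tail survives extreme parameters", {
  # the probability itself underflows double precision; the log form does not
  lp <- hypergeometric_overlap(5e5, 1e4, 2e4, 2000, log_p = TRUE)
  expect_true(is.finite(lp))
  expect_lt(lp, -700)
  expect_equal(lp, phyper(1999, 1e4, 5e5 - 1e4, 2e4, lower.tail = FALSE,
                          log.p = TRUE), tolerance = 1e-9)
})

test_that("test_gwas_overlap scores every experiment with Bonferroni control", {
  set.seed(93)
  occ <- matrix(rbinom(500L, 1L, 0.3), 100L, 5L,
                dimnames = list(NULL, sprintf("e%d", 1:5)))
  occ[rowSums(occ) == 0L, 1L] <- 1L
  bm <- bm_from_occupancy(occ)
  marked <- logical(100L); marked[1:20] <- TRUE
  res <- test_gwas_overlap(bm, marked)
  expect_equal(nrow(res), 5L)
  expect_equal(res$p_bonf, pmin(1, res$p_raw * 5))
  expect_true(all(res$k <= pmin(res$K, res$n)))
  expect_equal(res$fraction, res$k / res$n)
  # an experiment binding exactly the marked regions has the smallest p
  occ2 <- cbind(occ, exact = as.integer(marked))
  res2 <- test_gwas_overlap(bm_from_occupancy(occ2), marked)
  expect_equal(res2$experiment_id[1L], "exact")
  # no overlaps anywhere -> all p = 1, nothing significant
  res3 <- test_gwas_overlap(bm, rep(FALSE, 100L))
  expect_true(all(res3$p_bonf == 1))
  expect_false(any(res3$significant))
})

test_that("trait breakdown counts bound regions per trait", {
  occ <- matrix(c(1L, 1L, 0L,
                  0L, 1L, 1L), ncol = 2,
                dimnames = list(NULL, c("e1", "e2")))
  bm <- bm_from_occupancy(occ)
  hits <- data.frame(chrom = "chr1",
                     pos = c(bm$regions$start[1] + 5L,
                             bm$regions$start[2] + 5L,
                             bm$regions$start[2] + 6L),
                     trait = c("asthma", "asthma", "height"))
  mk <- mark_gwas_regions(bm$regions, hits)
  bd <- gwas_trait_breakdown(bm, mk)
  e1 <- bd[bd$experiment_id == "e1", ]
  expect_equal(e1$n_regions[e1$trait == "asthma"], 2L)
  expect_equal(e1$n_regions[e1$trait == "height"], 1L)
  e2 <- bd[bd$experiment_id == "e2", ]
  expect_equal(e2$n_regions[e2$trait == "asthma"], 1L)
})
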