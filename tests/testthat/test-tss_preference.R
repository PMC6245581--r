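test_that("location_profile fractions and grouping", {
  p <- location_profile(rep(0L, 10), "all_tss")
  expect_equal(c(p$f_tss, p$f_up, p$f_down), c(1, 0, 0))
  expect_equal(p$group, "balanced")
  # 55% downstream -> downstream-biased
  d <- c(rep(1000L, 55), rep(-1000L, 25), rep(0L, 20))
  expect_equal(location_profile(d)$group, "downstream-biased")
  # exactly 50% is not biased
  d <- c(rep(-1L, 50), rep(1L, 50))
  expect_equal(location_profile(d)$group, "balanced")
  # NA distances are excluded from the denominator
  p <- location_profile(c(0L, 0L, NA, 2L))
  expect_equal(p$n_peaks, 3L)
  expect_equal(p$f_tss, 2 / 3)
  expect_error(location_profile(c(NA_integer_, NA_integer_), "eX"), "eX")
})

test_that("profiles recover generator fractions within binomial error", {
  set.seed(61)
  n <- 1000L
  cls <- sample(c("tss", "up", "down"), n, replace = TRUE,
                prob = c(0.3, 0.5, 0.2))
  d <- ifelse(cls == "tss", 0L, ifelse(cls == "up", -sample.int(5000L, n, TRUE),
                                       sample.int(5000L, n, TRUE)))
  p <- location_profile(d)
  expect_lt(abs(p$f_tss - 0.3), 0.05)
  expect_lt(abs(p$f_up - 0.5), 0.05)
  expect_lt(abs(p$f_down - 0.2), 0.05)
})

test_that("sort_profiles separates biased groups and sorts by f_tss", {
  set.seed(62)
  mk <- function(id, tss, up, down) {
    g <- if (up > 0.5) "upstream-biased" else if (down > 0.5)
      "downstream-biased" else "balanced"
    data.frame(experiment_id = id, n_peaks = 100L, f_tss = tss, f_up = up,
               f_down = down, group = g)
  }
  profs <- rbind(mk("a", 0.8, 0.1, 0.1), mk("b", 0.2, 0.4, 0.4),
                 mk("c", 0.5, 0.25, 0.25), mk("u", 0.1, 0.6, 0.3))
  s <- sort_profiles(profs)
  expect_equal(s$main$experiment_id, c("a", "c", "b"))
  expect_equal(s$upstream$experiment_id, "u")
  # random profiles: main list strictly matches a descending sort
  r <- do.call(rbind, lapply(1:50, function(i) {
    f <- runif(3); f <- f / sum(f)
    mk(sprintf("e%02d", i), f[1], f[2], f[3])
  }))
  s2 <- sort_profiles(r)
  expect_equal(s2$main$f_tss, sort(s2$main$f_tss, decreasing = TRUE))
  expect_equal(nrow(s2$main) + nrow(s2$upstream) + nrow(s2$downstream),
               nrow(r))
})

test_that("compare_species reproduces closed-form least squares", {
  mk <- function(f, v, sp) data.frame(experiment_id = paste0(f, sp), factor = f,
                                      f_tss = v)
  pa <- rbind(mk("F1", 0.1, "h"), mk("F2", 0.5, "h"), mk("F3", 0.9, "h"))
  pb <- rbind(mk("f1", 0.1, "m"), mk("f2", 0.5, "m"), mk("f3", 0.8, "m"))
  sc <- compare_species(pa, pb)
  # normal equations on the 3 medians
  x <- c(0.1, 0.5, 0.9); y <- c(0.1, 0.5, 0.8)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(sc$slope, slope, tolerance = 1e-12)
  expect_equal(sc$intercept, mean(y) - slope * mean(x), tolerance = 1e-12)
  expect_equal(sc$pearson_r, cor(x, y), tolerance = 1e-12)
  expect_equal(sc$n_factors, 3L)
  # identical fractions -> identity fit
  sc2 <- compare_species(pa, pa)
  expect_equal(sc2$pearson_r, 1)
  expect_equal(sc2$slope, 1, tolerance = 1e-12)
  expect_equal(sc2$intercept, 0, tolerance = 1e-12)
  # single-experiment factor has MAD 0
  expect_true(all(sc$per_factor$mad_a == 0))
})

test_that("compare_species matching is case-insensitive and collision-safe", {
  mk <- function(f, v) data.frame(experiment_id = paste0(f, v), factor = f,
                                  f_tss = v)
  pa <- rbind(mk("CFOS", 0.2), mk("MAX", 0.6), mk("CTCF", 0.1))
  pb <- rbind(mk("cFos", 0.25), mk("Max", 0.5), mk("Ctcf", 0.15))
  expect_equal(compare_species(pa, pb)$n_factors, 3L)
  expect_error(compare_species(rbind(pa, mk("cfos", 0.3)), pb), "CFOS")
  expect_error(compare_species(pa[1:2, ], pb), ">= 3 factors")
})

test_that("swapping species keeps r and inverts the regression", {
  set.seed(63)
  mk <- function(f, v) data.frame(experiment_id = f, factor = f, f_tss = v)
  x <- runif(8); y <- pmin(1, pmax(0, 0.8 * x + rnorm(8, 0, 0.05)))
  fs <- sprintf("F%d", 1:8)
  pa <- do.call(rbind, Map(mk, fs, x))
  pb <- do.call(rbind, Map(mk, paste0(tolower(fs)), y))
  ab <- compare_species(pa, pb)
  ba <- compare_species(pb, pa)
  expect_equal(ab$pearson_r, ba$pearson_r, tolerance = 1e-12)
  # product of the two regression slopes equals r^2
  expect_equal(ab$slope * ba$slope, ab$pearson_r^2, tolerance = 1e-12)
})

test_that("location_profiles is invariant to peak order", {
  set.seed(64)
  peaks <- list(e1 = random_intervals(60))
  tss <- random_tss(15)
  tss <- tss[!duplicated(tss$gene_id), ]
  man <- fixture_manifest(peaks)
  p1 <- location_profiles(man, tss, peaks)
  shuffled <- list(e1 = peaks$e1[sample(nrow(peaks$e1)), ])
  p2 <- location_profiles(man, tss, shuffled)
  expect_equal(p1[, c("f_tss", "f_up", "f_down")],
               p2[, c("f_tss", "f_up", "f_down")])
})
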