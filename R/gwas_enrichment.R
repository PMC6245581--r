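# Overlap of experiment peak sets with GWAS disease-associated loci, tested
# per experiment with a Bonferroni-corrected hypergeometric test, plus
# per-trait overlap breakdowns.

#' Mark merged regions containing GWAS hits
#'
#' A region is marked iff at least one hit position (optionally extended by a
#' symmetric window) falls inside it; half-open semantics, so a hit at
#' `pos == end` does not mark the region. A region with several hits counts
#' once for the test but retains the full trait set for reporting.
#'
#' @param regions Sorted disjoint regions (from [merge_intervals()]).
#' @param hits GWAS hit data frame (`chrom`, `pos`, `trait`).
#' @param window Symmetric extension of each hit in bp (default 0: hits are
#'   points).
#' @return List with `marked` (logical per region) and `traits` (data frame of
#'   unique `region` index / `trait` pairs).
#' @export
mark_gwas_regions <- function(regions, hits, window = 0L) {
  q <- data.frame(chrom = hits$chrom, start = hits$pos, end = hits$pos + 1L)
  rng <- .overlap_ranges(regions, q, margin = as.integer(window))
  marked <- logical(nrow(regions))
  traits <- data.frame(region = integer(), trait = character())
  if (nrow(rng)) {
    reps <- rng$i2 - rng$i1 + 1L
    ridx <- unlist(Map(seq.int, rng$i1, rng$i2))
    marked[ridx] <- TRUE
    traits <- unique(data.frame(region = ridx,
                                trait = rep(hits$trait[rng$q], reps),
                                stringsAsFactors = FALSE))
  }
  list(marked = marked, traits = traits)
}

#' Upper-tail hypergeometric overlap probability
#'
#' `P(X >= k)` where `X ~ Hypergeometric(U, K, n)`: drawing `n` regions from a
#' universe of `U` of which `K` are marked. Accumulated in log space
#' (`lchoose` + log-sum-exp) for numerical stability at extreme tails.
#' Vectorized over `k`.
#'
#' @param U Universe size.
#' @param K Marked regions in the universe.
#' @param n Regions drawn (bound by the experiment).
#' @param k Overlap count(s).
#' @param log_p Return the natural-log tail probability (exact even where the
#'   probability itself underflows double precision).
#' @return Probability vector (or log-probability), same length as `k`.
#' @export
hypergeometric_overlap <- function(U, K, n, k, log_p = FALSE) {
  if (K > U || n > U || K < 0 || n < 0 || U < 0)
    stop("require 0 <= K <= U and 0 <= n <= U")
  if (any(k > pmin(K, n)) || any(k < 0))
    stop("require 0 <= k <= min(K, n)")
  mx <- min(K, n)
  i <- 0:mx
  lt <- lchoose(K, i) + lchoose(U - K, n - i) - lchoose(U, n)
  # suffix log-sum-exp: suf[j] = log P(X >= j - 1)
  suf <- numeric(mx + 1L)
  acc <- -Inf
  for (j in (mx + 1L):1L) {
    a <- max(acc, lt[j]); b <- min(acc, lt[j])
    acc <- if (is.infinite(a) && a < 0) -Inf else a + log1p(exp(b - a))
    suf[j] <- acc
  }
  if (log_p) pmin(0, suf[k + 1L]) else pmin(1, exp(suf[k + 1L]))
}

#' Test every experiment for GWAS-locus over-representation
#'
#' Universe = the merged regions of the dataset (all regions bound by at least
#' one experiment). For each non-reference experiment: `n` = regions bound,
#' `k` = bound regions containing a hit, tested against `K` marked regions out
#' of `U`, Bonferroni-corrected by the number of experiments tested.
#'
#' @param bm A `BindingMatrix`.
#' @param marks Output of [mark_gwas_regions()] on `bm$regions` (or a logical
#'   vector).
#' @param alpha Family-wise significance level for the `significant` flag
#'   (default 0.05).
#' @return A `GWASResult` data frame: `experiment_id`, `factor`, `cell_type`,
#'   `n`, `k`, `K`, `U`, `fraction`, `p_raw`, `p_bonf`, `significant`, sorted
#'   by `p_bonf`.
#' @export
test_gwas_overlap <- function(bm, marks, alpha = 0.05) {
  stopifnot(inherits(bm, "BindingMatrix"))
  marked <- if (is.list(marks)) marks$marked else marks
  stopifnot(length(marked) == nrow(bm$regions))
  occ <- bm$occupancy[, !bm$is_reference, drop = FALSE]
  U <- nrow(occ)
  K <- sum(marked)
  ids <- colnames(occ)
  n <- colSums(occ > 0L)
  k <- colSums(occ > 0L & marked)
  p_raw <- vapply(seq_along(ids), function(j)
    hypergeometric_overlap(U, K, n[j], k[j]), 0)
  n_tests <- length(ids)
  p_bonf <- pmin(1, p_raw * n_tests)
  m <- bm$experiments
  out <- data.frame(experiment_id = ids,
                    factor = m$factor[match(ids, m$experiment_id)],
                    cell_type = m$cell_type[match(ids, m$experiment_id)],
                    n = n, k = k, K = K, U = U,
                    fraction = ifelse(n > 0, k / n, NA_real_),
                    p_raw = p_raw, p_bonf = p_bonf,
                    significant = p_bonf < alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$p_bonf, out$experiment_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("GWASResult", "data.frame")
  out
}

#' Per-trait overlap breakdown for selected experiments
#'
#' For each experiment, counts the bound regions overlapping hits of each
#' trait (a region overlapping hits of several traits contributes to each
#' trait once).
#'
#' @param bm A `BindingMatrix`.
#' @param marks Output of [mark_gwas_regions()] (needs the `traits` element).
#' @param experiment_ids Experiments to break down (default: all).
#' @return Data frame `experiment_id`, `trait`, `n_regions`.
#' @export
gwas_trait_breakdown <- function(bm, marks, experiment_ids = NULL) {
  stopifnot(is.list(marks), !is.null(marks$traits))
  occ <- bm$occupancy[, !bm$is_reference, drop = FALSE]
  if (is.null(experiment_ids)) experiment_ids <- colnames(occ)
  tr <- marks$traits
  out <- do.call(rbind, lapply(experiment_ids, function(e) {
    bound <- which(occ[, e] > 0L)
    sub <- tr[tr$region %in% bound, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    counts <- table(sub$trait)
    data.frame(experiment_id = e, trait = names(counts),
               n_regions = as.integer(counts), stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(experiment_id = character(), trait = character(),
                      n_regions = integer())
  rownames(out) <- NULL
  out[order(out$experiment_id, -out$n_regions), , drop = FALSE]
}
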