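# Combinatorial co-binding: exact binding-pattern counts per cell type,
# scored against marginal-preserving randomizations of the regions x factors
# binary matrix.

#' Cell types eligible for combinatorial analysis
#'
#' @param manifest Manifest data frame.
#' @param min_factors Minimum number of **distinct factors** studied in the
#'   cell type (default 6, inclusive). Replicate experiments of one factor
#'   count once.
#' @return Character vector of cell types, sorted by distinct-factor count
#'   descending.
#' @export
select_combinatorial_cell_types <- function(manifest, min_factors = 6L) {
  counts <- vapply(split(manifest$factor, manifest$cell_type),
                   function(f) length(unique(f)), 0L)
  names(sort(counts[counts >= min_factors], decreasing = TRUE))
}

#' Factor-level binding matrix for one cell type
#'
#' Replicate experiments of the same factor in the cell type are collapsed by
#' the union of their peaks, so columns are distinct factors. Regions are the
#' merged peak-containing regions of the cell type; every region is bound by
#' at least one factor by construction.
#'
#' @param manifest Manifest data frame.
#' @param cell_type Cell type to analyse.
#' @param peaks Optional named list of peak data frames per experiment id.
#' @return A `BindingMatrix` whose columns are factors.
#' @export
factor_binding_matrix <- function(manifest, cell_type, peaks = NULL) {
  m <- manifest[manifest$cell_type == cell_type, , drop = FALSE]
  if (nrow(m) == 0L) stop("no experiments in cell type ", cell_type)
  if (is.null(peaks)) {
    peaks <- lapply(m$peak_path, read_peaks_bed)
    names(peaks) <- m$experiment_id
  }
  factors <- sort(unique(m$factor))
  fpeaks <- lapply(factors, function(f) {
    ids <- m$experiment_id[m$factor == f]
    do.call(rbind, lapply(peaks[ids], function(p)
      p[, c("chrom", "start", "end"), drop = FALSE]))
  })
  names(fpeaks) <- factors
  fmanifest <- data.frame(experiment_id = factors, factor = factors,
                          cell_type = cell_type, species = m$species[1L],
                          peak_path = NA_character_, stringsAsFactors = FALSE)
  build_binding_matrix(fmanifest, fpeaks)
}

# integer bitmask codes per row; factor j contributes 2^(j-1)
.pattern_codes <- function(occ) {
  n <- ncol(occ)
  if (n > 30L) stop("more than 30 factors: bitmask patterns not supported")
  drop(occ %*% (2L^(seq_len(n) - 1L)))
}

#' Decode a pattern bitmask into factor names
#'
#' @param code Integer bitmask(s).
#' @param factors Factor names in column order.
#' @return Character vector, factor names joined by `"+"`.
#' @export
pattern_label <- function(code, factors) {
  vapply(code, function(cc)
    paste(factors[bitwAnd(cc, 2L^(seq_along(factors) - 1L)) > 0L],
          collapse = "+"), "")
}

#' Exact binding-pattern counts
#'
#' Each region contributes to exactly one pattern: the exact subset of factors
#' binding it ("occupied only by ..."). Patterns with zero regions are omitted
#' from the result but still belong to the Bonferroni family of `2^N - 1`
#' nonempty patterns.
#'
#' @param bm A factor-level `BindingMatrix` (columns = factors).
#' @param allow_empty Tolerate all-zero rows, excluding them as the empty
#'   pattern (default `FALSE`: in a pipeline matrix every region is bound and
#'   an empty row is an invariant violation).
#' @return Data frame `code` (bitmask), `pattern` (factor names joined by
#'   `"+"`), `count`, sorted by count descending. Attribute `n_factors` holds
#'   N.
#' @export
pattern_counts <- function(bm, allow_empty = FALSE) {
  occ <- if (inherits(bm, "BindingMatrix"))
    bm$occupancy[, !bm$is_reference, drop = FALSE] else bm
  codes <- .pattern_codes(occ)
  if (any(codes == 0L)) {
    if (!allow_empty)
      stop("all-zero row: every region must be bound by >= 1 factor")
    codes <- codes[codes != 0L]
  }
  tab <- table(codes)
  code <- as.integer(names(tab))
  out <- data.frame(code = code,
                    pattern = pattern_label(code, colnames(occ)),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$code), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_factors") <- ncol(occ)
  attr(out, "factors") <- colnames(occ)
  out
}

#' Marginal-preserving randomization of an occupancy matrix
#'
#' Each column independently receives a uniform random permutation of its
#' entries over the rows, i.e. each factor's bound-region set becomes a
#' uniform random subset of the same size: column sums are exactly preserved.
#' Rows may become all-zero; they count as the empty pattern and are excluded
#' from the `2^N - 1` nonempty patterns.
#'
#' @param occ Binary matrix (regions x factors).
#' @return Randomized matrix of the same dimensions and column sums.
#' @export
randomize_occupancy <- function(occ) {
  M <- nrow(occ)
  out <- matrix(0L, M, ncol(occ), dimnames = dimnames(occ))
  for (j in seq_len(ncol(occ))) {
    nj <- sum(occ[, j] > 0L)
    if (nj > 0L) out[sample.int(M, nj), j] <- 1L
  }
  out
}

#' Score exact binding patterns against a randomization null
#'
#' Counts each observed exact pattern in `n_rand` marginal-preserving
#' randomizations, and computes z = (observed - null mean) / null sd and an
#' upper-tail standard-normal p-value, Bonferroni-corrected by the family of
#' all `2^N - 1` nonempty patterns. The normal-tail p on the randomization
#' moments (rather than an empirical rank, floored at 1/(n_rand+1)) is what
#' makes extremely small p-values expressible from 100 randomizations.
#'
#' When the null sd is 0 the normal tail is undefined; the p-value then falls
#' back to the add-one empirical rank: `1/(n_rand + 1)` when the observed
#' count exceeds the constant null count (the randomizations cannot resolve
#' anything smaller), and 1 otherwise. Such patterns carry
#' `degenerate = TRUE`.
#'
#' Tail probabilities are carried in log space (`log10_p_raw`), so patterns
#' whose p-value underflows double precision still rank correctly; the sort
#' order is corrected p ascending (on the log scale), then observed count
#' descending.
#'
#' @param bm Factor-level `BindingMatrix` or plain binary matrix. All-zero
#'   rows are tolerated here (they count as the empty pattern and contribute
#'   only to the universe size).
#' @param n_rand Number of randomizations (default 100).
#' @param seed Mandatory seed for the randomization ensemble.
#' @return A `PatternResult` data frame: `pattern`, `observed`, `null_mean`,
#'   `null_sd`, `z`, `p_raw`, `log10_p_raw`, `p_bonf`, `degenerate`.
#'   Attribute `null_counts` holds the n_rand x patterns count matrix.
#' @export
enrichment_test <- function(bm, n_rand = 100L, seed) {
  if (missing(seed)) stop("seed is required for the randomization ensemble")
  occ <- if (inherits(bm, "BindingMatrix"))
    bm$occupancy[, !bm$is_reference, drop = FALSE] else bm
  obs <- pattern_counts(occ, allow_empty = TRUE)
  N <- ncol(occ)
  family <- 2^N - 1
  set.seed(seed)
  csums <- colSums(occ > 0L)
  null_counts <- matrix(0L, n_rand, nrow(obs))
  for (r in seq_len(n_rand)) {
    rnd <- randomize_occupancy(occ)
    stopifnot(identical(colSums(rnd > 0L), csums))  # marginal preservation
    codes <- .pattern_codes(rnd)
    hit <- match(codes, obs$code)
    null_counts[r, ] <- tabulate(hit[!is.na(hit)], nbins = nrow(obs))
  }
  null_mean <- colMeans(null_counts)
  null_sd <- apply(null_counts, 2L, stats::sd)
  z <- (obs$count - null_mean) / null_sd
  lp <- stats::pnorm(z, lower.tail = FALSE, log.p = TRUE)
  degenerate <- null_sd == 0
  lp[degenerate & obs$count <= null_mean] <- 0
  lp[degenerate & obs$count > null_mean] <- -log(n_rand + 1)
  z[degenerate] <- ifelse(obs$count[degenerate] > null_mean[degenerate],
                          Inf, ifelse(obs$count[degenerate] < null_mean[degenerate],
                                      -Inf, 0))
  p_bonf <- pmin(1, exp(lp + log(family)))
  out <- data.frame(pattern = obs$pattern, observed = obs$count,
                    null_mean = null_mean, null_sd = null_sd, z = z,
                    p_raw = exp(lp), log10_p_raw = lp / log(10),
                    p_bonf = p_bonf, degenerate = degenerate,
                    stringsAsFactors = FALSE)
  out <- out[order(out$log10_p_raw, -out$observed), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "null_counts") <- null_counts
  attr(out, "n_factors") <- N
  class(out) <- c("PatternResult", "data.frame")
  out
}

#' Combinatorial enrichment across all eligible cell types
#'
#' Builds the factor-level matrix of each cell type with at least
#' `min_factors` distinct factors and runs [enrichment_test()] on each.
#'
#' @param manifest Manifest data frame.
#' @param peaks Optional named list of peak data frames per experiment id.
#' @param min_factors Distinct-factor threshold (default 6).
#' @param n_rand Randomizations per cell type (default 100).
#' @param seed Base seed; cell types get consecutive derived seeds.
#' @return Data frame stacking per-cell-type `PatternResult`s with a
#'   `cell_type` column.
#' @export
combination_enrichment <- function(manifest, peaks = NULL, min_factors = 6L,
                                   n_rand = 100L, seed) {
  if (missing(seed)) stop("seed is required")
  cts <- select_combinatorial_cell_types(manifest, min_factors)
  if (length(cts) == 0L) {
    message("combination_enrichment: no cell type with >= ", min_factors,
            " factors")
    return(data.frame())
  }
  out <- lapply(seq_along(cts), function(i) {
    fbm <- factor_binding_matrix(manifest, cts[i], peaks)
    res <- enrichment_test(fbm, n_rand = n_rand, seed = seed + i - 1L)
    cbind(cell_type = cts[i], as.data.frame(res))
  })
  do.call(rbind, out)
}
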