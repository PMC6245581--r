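# Interval primitives: merge, nearest-TSS annotation with signed distance,
# and overlap marking of a sorted disjoint region set. These reimplement,
# with pinned-down semantics, the two genome-arithmetic operations the
# pipeline needs (interval union and closest-feature with strand-aware sign).

#' Merge genomic intervals
#'
#' Computes the union of the input intervals per chromosome. Two intervals are
#' merged iff they overlap or are bookended (`end == start`), matching the
#' default of the classical merge tool, so the set of covered bases is
#' preserved and the output is sorted and disjoint.
#'
#' @param df Interval data frame (`chrom`, `start`, `end`); may be unsorted
#'   and span several chromosomes. Extra columns are dropped.
#' @return Data frame `chrom`, `start`, `end` of merged regions, sorted by
#'   (chrom, start).
#' @export
merge_intervals <- function(df) {
  if (nrow(df) == 0L)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  df <- validate_intervals(df, "merge_intervals")
  df <- df[order(df$chrom, df$start, df$end), c("chrom", "start", "end")]
  new_chrom <- c(TRUE, df$chrom[-1L] != df$chrom[-nrow(df)])
  # running maximum end within chromosome: reset the cummax at chromosome
  # boundaries by offsetting with a large per-chromosome base
  grp <- cumsum(new_chrom)
  run_end <- stats::ave(df$end, grp, FUN = cummax)
  prev_end <- c(-1L, run_end[-nrow(df)])
  # a new merged region starts when start > previous running end (strictly:
  # bookended intervals, start == prev_end, do merge)
  new_region <- new_chrom | (df$start > prev_end)
  rid <- cumsum(new_region)
  out <- data.frame(
    chrom = df$chrom[new_region],
    start = df$start[new_region],
    end = as.integer(tapply(df$end, rid, max)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Annotate regions with their nearest TSS and signed distance
#'
#' For each region, finds the TSS minimizing the unsigned distance, defined as
#' 0 when the region contains the TSS position (`start <= pos < end`) and
#' otherwise as the distance from the TSS to the nearest covered base
#' (`min(|pos - start|, |pos - (end - 1)|)`). The sign is gene-strand-aware:
#' negative means the region lies upstream (5') of the gene, positive
#' downstream (3'). Ties between equidistant TSS are broken by the
#' lexicographically smaller `gene_id`. Regions on chromosomes with no TSS get
#' `nearest_gene = NA` and `d = NA` (excluded downstream, with a logged count).
#'
#' @param regions Interval data frame (`chrom`, `start`, `end`).
#' @param tss TSS table (`gene_id`, `chrom`, `pos`, `strand`).
#' @return Data frame with the region columns plus `nearest_gene` and `d`
#'   (signed integer bp), rows in the order of `regions`.
#' @export
nearest_tss <- function(regions, tss) {
  regions <- validate_intervals(as.data.frame(regions), "nearest_tss regions")
  stopifnot(all(c("gene_id", "chrom", "pos", "strand") %in% names(tss)))
  n <- nrow(regions)
  gene <- rep(NA_character_, n)
  d <- rep(NA_integer_, n)
  tss_by_chrom <- split(tss, tss$chrom)
  idx_by_chrom <- split(seq_len(n), regions$chrom)
  for (ch in names(idx_by_chrom)) {
    ii <- idx_by_chrom[[ch]]
    tt <- tss_by_chrom[[ch]]
    if (is.null(tt) || nrow(tt) == 0L) next
    tt <- tt[order(tt$pos, tt$gene_id), , drop = FALSE]
    pos <- tt$pos
    st <- regions$start[ii]
    en <- regions$end[ii]
    # first TSS with pos >= start, last TSS with pos < end
    j1 <- findInterval(st - 1L, pos) + 1L
    j2 <- findInterval(en - 1L, pos)
    for (q in seq_along(ii)) {
      if (j1[q] <= j2[q]) {
        # containment: distance 0; tie-break over all contained TSS
        cand <- j1[q]:j2[q]
        g <- min(tt$gene_id[cand])
        gene[ii[q]] <- g
        d[ii[q]] <- 0L
        next
      }
      # nearest on each side: j2[q] is the rightmost TSS left of the region,
      # j1[q] (= j2[q] + 1) the leftmost TSS right of it
      best <- Inf; cand <- integer()
      if (j2[q] >= 1L) {
        dl <- st[q] - pos[j2[q]]
        best <- dl
        cand <- which(pos == pos[j2[q]])
      }
      if (j1[q] <= length(pos)) {
        dr <- pos[j1[q]] - (en[q] - 1L)
        if (dr < best) {
          best <- dr
          cand <- which(pos == pos[j1[q]])
        } else if (dr == best) {
          cand <- c(cand, which(pos == pos[j1[q]]))
        }
      }
      k <- cand[order(tt$gene_id[cand])[1L]]
      gene[ii[q]] <- tt$gene_id[k]
      # sign: region left of TSS is upstream for '+' genes (negative d)
      region_left <- en[q] - 1L < pos[k]
      upstream <- if (tt$strand[k] == "+") region_left else !region_left
      d[ii[q]] <- as.integer(if (upstream) -best else best)
    }
  }
  n_missing <- sum(is.na(d))
  if (n_missing > 0L)
    message("nearest_tss: ", n_missing,
            " region(s) on chromosomes without any TSS (d = NA)")
  out <- regions[, c("chrom", "start", "end")]
  out$nearest_gene <- gene
  out$d <- d
  out
}

# Flags regions (sorted, disjoint, as produced by merge_intervals) that are
# overlapped by >= 1 query interval. Overlap means >= 1 shared base; an
# optional margin widens the queries symmetrically. Internal workhorse for
# matrix construction, reference tracks and GWAS marking.
.overlap_flags <- function(regions, query, margin = 0L) {
  hits <- .overlap_ranges(regions, query, margin)
  marked <- logical(nrow(regions))
  if (nrow(hits)) {
    # delta-encoding of the covered region-index ranges
    delta <- integer(nrow(regions) + 1L)
    tab1 <- tabulate(hits$i1, nbins = nrow(regions) + 1L)
    tab2 <- tabulate(hits$i2 + 1L, nbins = nrow(regions) + 1L)
    delta <- tab1 - tab2
    marked <- cumsum(delta)[seq_len(nrow(regions))] > 0L
  }
  marked
}

# For each query interval, the contiguous range [i1, i2] of region indices it
# overlaps (global row indices into `regions`); queries with no overlap are
# omitted. Regions must be sorted by (chrom, start) and disjoint per
# chromosome.
.overlap_ranges <- function(regions, query, margin = 0L) {
  if (nrow(query) == 0L || nrow(regions) == 0L)
    return(data.frame(q = integer(), i1 = integer(), i2 = integer()))
  res_q <- integer(0); res_i1 <- integer(0); res_i2 <- integer(0)
  reg_idx <- split(seq_len(nrow(regions)), regions$chrom)
  q_idx <- split(seq_len(nrow(query)), query$chrom)
  for (ch in names(q_idx)) {
    ri <- reg_idx[[ch]]
    if (is.null(ri)) next
    qi <- q_idx[[ch]]
    st <- regions$start[ri]; en <- regions$end[ri]
    qs <- query$start[qi] - margin; qe <- query$end[qi] + margin
    # first region with end > qs; last region with start < qe
    i1 <- findInterval(qs, en) + 1L
    i2 <- findInterval(qe - 1L, st)
    ok <- i1 <= i2
    if (any(ok)) {
      res_q <- c(res_q, qi[ok])
      res_i1 <- c(res_i1, ri[1L] - 1L + i1[ok])
      res_i2 <- c(res_i2, ri[1L] - 1L + i2[ok])
    }
  }
  data.frame(q = res_q, i1 = res_i1, i2 = res_i2)
}

#' Which merged regions are overlapped by a set of intervals or points
#'
#' @param regions Sorted disjoint regions (e.g. from [merge_intervals()]).
#' @param query Interval data frame, or a point set with columns `chrom`,
#'   `pos` (treated as 1-bp intervals).
#' @param margin Symmetric extension of the queries in bp (default 0).
#' @return Logical vector over the rows of `regions`.
#' @export
overlaps_regions <- function(regions, query, margin = 0L) {
  if (!"start" %in% names(query) && "pos" %in% names(query))
    query <- data.frame(chrom = query$chrom, start = query$pos,
                        end = query$pos + 1L)
  .overlap_flags(regions, query, margin = as.integer(margin))
}

#' Classify regions by TSS proximity
#'
#' @param d Signed distances from [nearest_tss()].
#' @param proximal_bp Proximal threshold; `|d| < proximal_bp` (default 1000).
#' @param distal_bp Distal threshold; `|d| >= distal_bp` (default 10000).
#' @return Factor with levels `proximal`, `intermediate`, `distal` (`NA` where
#'   `d` is `NA`). Distances in between the thresholds are `intermediate`.
#' @export
proximity_class <- function(d, proximal_bp = 1000L, distal_bp = 10000L) {
  out <- rep(NA_character_, length(d))
  out[!is.na(d) & abs(d) < proximal_bp] <- "proximal"
  out[!is.na(d) & abs(d) >= distal_bp] <- "distal"
  out[!is.na(d) & is.na(out)] <- "intermediate"
  factor(out, levels = c("proximal", "intermediate", "distal"))
}
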