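# Regions x experiments binary occupancy matrix, correlation (phi) heatmap
# clustering with complete linkage and optimal leaf ordering, reference
# tracks, and factor / cell-type subsetting.

#' Build the regions x experiments binary occupancy matrix
#'
#' Merges the union of all peak sets into non-overlapping peak-containing
#' regions and sets cell (i, j) to 1 iff at least one peak of experiment j
#' shares at least one base with region i. Experiments with zero peaks are
#' kept as all-zero columns with a warning.
#'
#' @param manifest Manifest data frame (see [read_manifest()]).
#' @param peaks Named list of interval data frames, one per `experiment_id`.
#'   If `NULL`, peaks are read from `manifest$peak_path`.
#' @return A `BindingMatrix`: list with `regions` (merged intervals),
#'   `occupancy` (integer M x N matrix, colnames = experiment ids),
#'   `experiments` (manifest rows) and `is_reference` (logical per column).
#' @export
build_binding_matrix <- function(manifest, peaks = NULL) {
  validate_manifest(manifest)
  if (nrow(manifest) < 1L) stop("manifest has no experiments")
  if (length(unique(manifest$species)) > 1L)
    stop("all experiments in one matrix must be from the same species")
  if (is.null(peaks)) {
    peaks <- lapply(manifest$peak_path, read_peaks_bed)
    names(peaks) <- manifest$experiment_id
  }
  miss <- setdiff(manifest$experiment_id, names(peaks))
  if (length(miss)) stop("peaks missing for experiments: ",
                         paste(miss, collapse = ", "))
  peaks <- peaks[manifest$experiment_id]
  all_peaks <- do.call(rbind, lapply(peaks, function(p)
    p[, c("chrom", "start", "end"), drop = FALSE]))
  regions <- merge_intervals(all_peaks)
  occ <- matrix(0L, nrow = nrow(regions), ncol = nrow(manifest),
                dimnames = list(NULL, manifest$experiment_id))
  for (j in seq_along(peaks)) {
    if (nrow(peaks[[j]]) == 0L) {
      warning("experiment ", manifest$experiment_id[j],
              " has zero peaks; kept as all-zero column")
      next
    }
    occ[, j] <- as.integer(.overlap_flags(regions, peaks[[j]]))
  }
  structure(list(regions = regions, occupancy = occ, experiments = manifest,
                 is_reference = rep(FALSE, ncol(occ))),
            class = "BindingMatrix")
}

#' @export
print.BindingMatrix <- function(x, ...) {
  cat("BindingMatrix:", nrow(x$regions), "regions x",
      sum(!x$is_reference), "experiments",
      if (any(x$is_reference))
        paste0("(+", sum(x$is_reference), " reference track(s))") else "",
      "\n")
  invisible(x)
}

#' Append a reference track column
#'
#' Adds one column flagged as a reference track (e.g. TSS locations or CpG
#' islands), set to 1 where the track overlaps a region. Reference tracks
#' never create regions and are excluded from correlation clustering, density
#' and enrichment computations; they are display overlays.
#'
#' @param bm A `BindingMatrix`.
#' @param track Interval data frame or point set (`chrom`, `pos`).
#' @param label Column label; must not collide with an experiment id.
#' @return The augmented `BindingMatrix`.
#' @export
add_reference_track <- function(bm, track, label) {
  stopifnot(inherits(bm, "BindingMatrix"))
  if (label %in% colnames(bm$occupancy))
    stop("reference track label collides with an existing column: ", label)
  col <- as.integer(overlaps_regions(bm$regions, track))
  bm$occupancy <- cbind(bm$occupancy, col)
  colnames(bm$occupancy)[ncol(bm$occupancy)] <- label
  bm$is_reference <- c(bm$is_reference, TRUE)
  bm
}

#' Pairwise column correlation of a binding matrix
#'
#' Pearson correlation between occupancy columns, which on binary data equals
#' the phi coefficient. Constant (all-zero or all-one) columns are assigned
#' correlation 0 with every other column and 1 with themselves, so no sample
#' is dropped silently.
#'
#' @param bm A `BindingMatrix`.
#' @param include_reference Correlate reference-track columns too (default
#'   `FALSE`: experiments only).
#' @return Symmetric N x N correlation matrix with unit diagonal.
#' @export
correlate_binding <- function(bm, include_reference = FALSE) {
  stopifnot(inherits(bm, "BindingMatrix"))
  occ <- bm$occupancy[, !bm$is_reference | include_reference, drop = FALSE]
  if (ncol(occ) < 2L) stop("need >= 2 columns to correlate")
  corr <- suppressWarnings(stats::cor(occ))
  corr[is.na(corr)] <- 0
  diag(corr) <- 1
  corr
}

#' Complete-linkage clustering of a correlation matrix with optimal leaf order
#'
#' Distance between two experiments is the Euclidean distance between their
#' rows of the correlation matrix. The dendrogram is built by complete-linkage
#' agglomeration and its leaves are re-ordered, consistently with the tree, to
#' minimize the sum of distances between adjacent leaves (optimal leaf
#' ordering by dynamic programming over subtree orientations). For more than
#' `max_olo` leaves the unoptimized dendrogram order is kept, with a warning.
#'
#' @param corr Symmetric correlation matrix with column names.
#' @param max_olo Leaf-count cap for the ordering optimization (default 2000).
#' @return A `CorrelationClustering`: list with `corr`, `hclust`, `leaf_order`
#'   (column names in display order) and `dist` (the leaf distance matrix).
#' @export
cluster_correlation <- function(corr, max_olo = 2000L) {
  n <- ncol(corr)
  if (n < 2L) stop("need >= 2 experiments to cluster")
  dd <- stats::dist(corr)
  hc <- stats::hclust(dd, method = "complete")
  dm <- as.matrix(dd)
  if (n <= max_olo) {
    ord <- olo_order(hc, dm)
  } else {
    warning("more than ", max_olo, " leaves; keeping unoptimized dendrogram order")
    ord <- hc$order
  }
  structure(list(corr = corr, hclust = hc, leaf_order = colnames(corr)[ord],
                 order = ord, dist = dm),
            class = "CorrelationClustering")
}

#' @export
print.CorrelationClustering <- function(x, ...) {
  cat("CorrelationClustering of", ncol(x$corr), "experiments;",
      "adjacent-leaf distance sum =",
      format(adjacent_distance_sum(x$order, x$dist)), "\n")
  invisible(x)
}

#' Sum of distances between adjacent leaves of an ordering
#'
#' @param ord Integer permutation of leaf indices.
#' @param dmat Full distance matrix between leaves.
#' @return The objective minimized by optimal leaf ordering.
#' @export
adjacent_distance_sum <- function(ord, dmat) {
  if (length(ord) < 2L) return(0)
  sum(dmat[cbind(ord[-length(ord)], ord[-1L])])
}

#' Optimal leaf ordering of a dendrogram
#'
#' Dynamic program over subtree orientations: for every internal node and
#' every admissible pair of end leaves, the minimal adjacent-distance cost of
#' an ordering of that subtree is computed from the children's tables; the
#' global optimum is backtracked into a leaf permutation consistent with the
#' tree.
#'
#' @param hc An `hclust` object.
#' @param dmat Full distance matrix between the leaves (same order as
#'   `hc$labels`).
#' @return Integer permutation of leaves attaining the minimum adjacent
#'   distance sum over all orders consistent with the tree.
#' @export
olo_order <- function(hc, dmat) {
  n <- nrow(dmat)
  if (n == 1L) return(1L)
  merge <- hc$merge
  leaves <- vector("list", nrow(merge))   # leaf indices per internal node
  tabs <- vector("list", nrow(merge))     # cost tables: list(L, R, C, A, B)
  node_leaves <- function(v) if (v < 0L) -v else leaves[[v]]
  # expanded cost lookup for a child: cost of ordering child subtree with end
  # leaves (u, v); for a leaf child this is 0 iff u == v
  child_cost <- function(v) {
    if (v < 0L) return(matrix(0, 1L, 1L, dimnames = list(-v, -v)))
    t <- tabs[[v]]
    lv <- c(t$L, t$R)
    m <- matrix(Inf, length(lv), length(lv), dimnames = list(lv, lv))
    m[as.character(t$L), as.character(t$R)] <- t$C
    m[as.character(t$R), as.character(t$L)] <- t(t$C)
    m
  }
  for (k in seq_len(nrow(merge))) {
    L <- node_leaves(merge[k, 1L])
    R <- node_leaves(merge[k, 2L])
    leaves[[k]] <- c(L, R)
    EL <- child_cost(merge[k, 1L])       # |L| x |L|, Inf where not an end pair
    ER <- child_cost(merge[k, 2L])
    C <- matrix(Inf, length(L), length(R), dimnames = list(L, R))
    A <- matrix(NA_integer_, length(L), length(R))
    B <- matrix(NA_integer_, length(L), length(R))
    dLR <- dmat[L, R, drop = FALSE]
    for (li in seq_along(L)) {
      # t[a] = cost of left subtree ordered l .. a
      t <- EL[as.character(L[li]), as.character(L), drop = TRUE]
      # s[b] = min_a t[a] + d(a, b), with argmin
      tmp <- t + dLR                      # |L| x |R|
      aidx <- max.col(-t(tmp), ties.method = "first")   # per b, best a
      s <- tmp[cbind(aidx, seq_along(R))]
      for (ri in seq_along(R)) {
        u <- s + ER[as.character(R), as.character(R[ri]), drop = TRUE]
        bi <- which.min(u)
        C[li, ri] <- u[bi]
        A[li, ri] <- aidx[bi]
        B[li, ri] <- bi
      }
    }
    tabs[[k]] <- list(L = L, R = R, C = C, A = A, B = B)
  }
  root <- nrow(merge)
  best <- which(tabs[[root]]$C == min(tabs[[root]]$C), arr.ind = TRUE)[1L, ]
  order_node <- function(v, l, r) {
    if (v < 0L) return(-v)
    t <- tabs[[v]]
    li <- match(l, t$L); ri <- match(r, t$R)
    if (is.na(li) || is.na(ri)) {
      # flipped orientation: endpoints given right-to-left
      return(rev(order_node(v, r, l)))
    }
    a <- t$L[t$A[li, ri]]
    b <- t$R[t$B[li, ri]]
    c(order_node(hc$merge[v, 1L], l, a), order_node(hc$merge[v, 2L], b, r))
  }
  order_node(root, tabs[[root]]$L[best[1L]], tabs[[root]]$R[best[2L]])
}

#' Subset a binding matrix by cell type and/or factor
#'
#' Keeps the selected experiment columns (reference tracks are always kept)
#' and drops rows that have no remaining non-reference occupancy, matching the
#' per-panel heatmaps obtained by sample sub-selection.
#'
#' @param bm A `BindingMatrix`.
#' @param cell_type,factor Optional character vectors of values to keep.
#' @return The subset `BindingMatrix`.
#' @export
subset_binding_matrix <- function(bm, cell_type = NULL, factor = NULL) {
  stopifnot(inherits(bm, "BindingMatrix"))
  m <- bm$experiments
  keep <- rep(TRUE, nrow(m))
  if (!is.null(cell_type)) {
    bad <- setdiff(cell_type, unique(m$cell_type))
    if (length(bad)) stop("unknown cell type(s): ", paste(bad, collapse = ", "),
                          "; valid: ", paste(unique(m$cell_type), collapse = ", "))
    keep <- keep & m$cell_type %in% cell_type
  }
  if (!is.null(factor)) {
    bad <- setdiff(factor, unique(m$factor))
    if (length(bad)) stop("unknown factor(s): ", paste(bad, collapse = ", "),
                          "; valid: ", paste(unique(m$factor), collapse = ", "))
    keep <- keep & m$factor %in% factor
  }
  if (!any(keep)) stop("selection is empty")
  exp_cols <- which(!bm$is_reference)[keep]
  cols <- c(exp_cols, which(bm$is_reference))
  occ <- bm$occupancy[, cols, drop = FALSE]
  rows <- rowSums(occ[, seq_len(sum(keep)), drop = FALSE]) > 0L
  structure(list(regions = bm$regions[rows, , drop = FALSE],
                 occupancy = occ[rows, , drop = FALSE],
                 experiments = m[keep, , drop = FALSE],
                 is_reference = c(rep(FALSE, sum(keep)),
                                  rep(TRUE, sum(bm$is_reference)))),
            class = "BindingMatrix")
}

#' Subset binding-matrix rows
#'
#' Row filter keeping all columns (used for proximal/distal splits); columns
#' that become all-zero are retained — they are only treated specially at
#' correlation time.
#'
#' @param bm A `BindingMatrix`.
#' @param rows Logical or integer row index.
#' @return The row-subset `BindingMatrix`.
#' @export
subset_regions <- function(bm, rows) {
  stopifnot(inherits(bm, "BindingMatrix"))
  bm$regions <- bm$regions[rows, , drop = FALSE]
  bm$occupancy <- bm$occupancy[rows, , drop = FALSE]
  bm
}

#' Export a binding matrix to disk
#'
#' Writes `regions.bed` (merged regions), `occupancy.mtx` (sparse triplet
#' MatrixMarket) and `columns.tsv` (experiment metadata and reference flags).
#'
#' @param bm A `BindingMatrix`.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
export_binding_matrix <- function(bm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "regions.bed")
  write_bed(bm$regions, p1)
  p2 <- file.path(dir, "occupancy.mtx")
  Matrix::writeMM(Matrix::Matrix(bm$occupancy, sparse = TRUE), p2)
  p3 <- file.path(dir, "columns.tsv")
  cols <- data.frame(column = colnames(bm$occupancy),
                     is_reference = bm$is_reference)
  meta <- bm$experiments[match(cols$column, bm$experiments$experiment_id),
                         c("factor", "cell_type", "species")]
  cols <- cbind(cols, meta)
  utils::write.table(cols, p3, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2, p3))
}

#' Read back an exported binding matrix
#'
#' @param dir Directory written by [export_binding_matrix()].
#' @param manifest Manifest data frame for the experiment columns.
#' @return A `BindingMatrix`.
#' @export
import_binding_matrix <- function(dir, manifest) {
  regions <- read_peaks_bed(file.path(dir, "regions.bed"))
  occ <- as.matrix(Matrix::readMM(file.path(dir, "occupancy.mtx")))
  storage.mode(occ) <- "integer"
  cols <- utils::read.delim(file.path(dir, "columns.tsv"),
                            stringsAsFactors = FALSE)
  colnames(occ) <- cols$column
  structure(list(regions = regions[, c("chrom", "start", "end")],
                 occupancy = occ,
                 experiments = manifest[match(
                   cols$column[!cols$is_reference], manifest$experiment_id), ,
                   drop = FALSE],
                 is_reference = cols$is_reference),
            class = "BindingMatrix")
}

#' Write a square correlation matrix as TSV
#'
#' @param corr Correlation matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_correlation <- function(corr, path) {
  df <- data.frame(experiment_id = rownames(corr), corr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot a clustered correlation heatmap
#'
#' Static heatmap of the correlation matrix in optimal leaf order, with
#' optional factor / cell-type annotations and reference-track overlap
#' fractions shown as row annotations.
#'
#' @param cc A `CorrelationClustering`.
#' @param bm Optional `BindingMatrix` supplying annotations.
#' @param filename Optional output file (png); `NULL` plots to the device.
#' @return The `pheatmap` object, invisibly.
#' @export
plot_correlation_heatmap <- function(cc, bm = NULL, filename = NA) {
  ord <- cc$leaf_order
  mat <- cc$corr[ord, ord]
  ann <- NA
  if (!is.null(bm)) {
    m <- bm$experiments
    ann <- data.frame(factor = m$factor, cell_type = m$cell_type,
                      row.names = m$experiment_id)
    if (any(bm$is_reference)) {
      occ <- bm$occupancy
      for (rc in colnames(occ)[bm$is_reference]) {
        frac <- vapply(m$experiment_id, function(e) {
          b <- occ[, e] > 0L
          if (!any(b)) return(0)
          mean(occ[b, rc] > 0L)
        }, 0)
        ann[[paste0("f_", rc)]] <- frac[rownames(ann)]
      }
    }
    ann <- ann[ord, , drop = FALSE]
  }
  ph <- pheatmap::pheatmap(mat, cluster_rows = FALSE, cluster_cols = FALSE,
                           annotation_row = ann, border_color = NA,
                           filename = filename, silent = !is.na(filename))
  invisible(ph)
}
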