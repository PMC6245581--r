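# Promoter-proximal vs distal re-clustering and transcription-factor binding
# hotspots: per-cell-type TF density and k-means clustering of density
# profiles across cell types.

#' Cell types with enough experiments
#'
#' @param manifest Manifest data frame.
#' @param min_experiments Strict lower bound: cell types with **more than**
#'   this many experiments are kept (default 30).
#' @return Character vector of cell types, sorted by experiment count
#'   descending. May be empty (logged).
#' @export
select_cell_types <- function(manifest, min_experiments = 30L) {
  counts <- table(manifest$cell_type)
  keep <- counts[counts > min_experiments]
  if (length(keep) == 0L)
    message("select_cell_types: no cell type exceeds ", min_experiments,
            " experiments")
  names(sort(keep, decreasing = TRUE))
}

#' Split a binding matrix into promoter-proximal and distal region sets
#'
#' Proximal regions lie at `|d| < proximal_bp` from the nearest TSS, distal
#' regions at `|d| >= distal_bp`; regions in between (and regions with
#' undefined distance) belong to neither set. Columns are never dropped here;
#' all-zero columns are only treated specially at correlation time.
#'
#' @param bm A `BindingMatrix`.
#' @param annotations Output of [nearest_tss()] on `bm$regions` (row-aligned).
#' @param proximal_bp,distal_bp Thresholds in bp (defaults 1000 and 10000).
#' @return List with `proximal` and `distal` `BindingMatrix` objects and the
#'   `class` vector over the input rows.
#' @export
split_by_proximity <- function(bm, annotations, proximal_bp = 1000L,
                               distal_bp = 10000L) {
  stopifnot(inherits(bm, "BindingMatrix"),
            nrow(annotations) == nrow(bm$regions))
  cl <- proximity_class(annotations$d, proximal_bp, distal_bp)
  list(proximal = subset_regions(bm, !is.na(cl) & cl == "proximal"),
       distal = subset_regions(bm, !is.na(cl) & cl == "distal"),
       class = cl)
}

#' Transcription-factor density per region and cell type
#'
#' Density of region i in cell type c is the number of the cell type's
#' experiments with a peak in region i divided by the cell type's total number
#' of experiments, a value in [0, 1]. Reference-track columns are excluded
#' from numerator and denominator.
#'
#' @param bm A `BindingMatrix`.
#' @param cell_types Cell types to include (default: all in the matrix, in
#'   [select_cell_types()] order with `min_experiments = 0`).
#' @return A `DensityMatrix`: list with `regions`, `density` (M x C matrix,
#'   colnames = cell types) and `n_experiments` per cell type.
#' @export
tf_density <- function(bm, cell_types = NULL) {
  stopifnot(inherits(bm, "BindingMatrix"))
  m <- bm$experiments
  if (is.null(cell_types)) cell_types <- select_cell_types(m, 0L)
  cell_types <- cell_types[cell_types %in% m$cell_type]
  if (length(cell_types) == 0L) stop("no cell type with any experiment")
  occ <- bm$occupancy[, !bm$is_reference, drop = FALSE]
  dens <- vapply(cell_types, function(ct) {
    cols <- m$experiment_id[m$cell_type == ct]
    rowSums(occ[, cols, drop = FALSE]) / length(cols)
  }, numeric(nrow(occ)))
  dens <- matrix(dens, nrow = nrow(occ),
                 dimnames = list(NULL, cell_types))
  structure(list(regions = bm$regions, density = dens,
                 n_experiments = vapply(cell_types, function(ct)
                   sum(m$cell_type == ct), 0L)),
            class = "DensityMatrix")
}

#' @export
print.DensityMatrix <- function(x, ...) {
  cat("DensityMatrix:", nrow(x$density), "regions x", ncol(x$density),
      "cell types\n")
  invisible(x)
}

# k-means++ (D^2-weighted) center initialization
.kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- numeric(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums((x - matrix(x[centers[1L], ], n, ncol(x), byrow = TRUE))^2)
  j <- 2L
  while (j <= k) {
    if (all(d2 == 0)) stop("fewer than k distinct points for k-means")
    centers[j] <- sample.int(n, 1L, prob = d2)
    dn <- rowSums((x - matrix(x[centers[j], ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, dn)
    j <- j + 1L
  }
  x[centers, , drop = FALSE]
}

#' k-means clustering of TF-density hotspots
#'
#' Lloyd k-means with k-means++ seeding, `n_init` restarts keeping the best
#' total within-cluster sum of squares; deterministic given `(k, seed)`.
#' Clusters are relabelled in decreasing order of their mean total density
#' (sum over cell types), so cluster 1 is the strongest hotspot cluster.
#'
#' @param dm A `DensityMatrix` (or a plain numeric matrix).
#' @param k Number of clusters (>= 2, <= number of regions).
#' @param seed Mandatory random seed.
#' @param n_init Number of seeding restarts (default 10).
#' @param iter_max Lloyd iteration cap per restart (default 100).
#' @param annotations Optional [nearest_tss()] annotations of the regions; if
#'   given, each cluster's proximity composition (fractions of regions
#'   upstream / at / downstream of the nearest TSS) is reported.
#' @return A `HotspotClusters`: list with `k`, `assignment` (per region),
#'   `centers` (k x C), `sizes`, `tot_withinss` and optionally `composition`.
#' @export
cluster_hotspots <- function(dm, k = 6L, seed, n_init = 10L, iter_max = 100L,
                             annotations = NULL) {
  x <- if (inherits(dm, "DensityMatrix")) dm$density else as.matrix(dm)
  if (missing(seed)) stop("seed is required for k-means")
  if (k < 2L) stop("k must be >= 2")
  if (nrow(x) < k) stop("fewer regions (", nrow(x), ") than clusters (", k, ")")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_init)) {
    centers <- .kmeanspp_centers(x, k)
    km <- suppressWarnings(stats::kmeans(x, centers = centers,
                                         iter.max = iter_max,
                                         algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  # relabel clusters by decreasing mean total density
  strength <- rowSums(best$centers)
  relabel <- order(strength, decreasing = TRUE)
  map <- integer(k); map[relabel] <- seq_len(k)
  assignment <- map[best$cluster]
  centers <- best$centers[relabel, , drop = FALSE]
  rownames(centers) <- seq_len(k)
  out <- list(k = k, assignment = assignment, centers = centers,
              sizes = tabulate(assignment, nbins = k),
              tot_withinss = best$tot.withinss)
  if (!is.null(annotations)) {
    stopifnot(nrow(annotations) == nrow(x))
    comp <- t(vapply(seq_len(k), function(cl) {
      d <- annotations$d[assignment == cl]
      d <- d[!is.na(d)]
      if (length(d) == 0L) return(c(f_up = NA_real_, f_tss = NA_real_,
                                    f_down = NA_real_))
      c(f_up = mean(d < 0), f_tss = mean(d == 0), f_down = mean(d > 0))
    }, c(f_up = 0, f_tss = 0, f_down = 0)))
    out$composition <- data.frame(cluster = seq_len(k), size = out$sizes, comp)
  }
  structure(out, class = "HotspotClusters")
}

#' @export
print.HotspotClusters <- function(x, ...) {
  cat("HotspotClusters: k =", x$k, "; sizes:",
      paste(x$sizes, collapse = ", "),
      "; tot.withinss =", format(x$tot_withinss, digits = 4), "\n")
  invisible(x)
}

#' Per-cluster summary of hotspot clusters
#'
#' @param hc A `HotspotClusters`.
#' @param drop_lowest Drop the weakest (lowest mean total density) cluster
#'   from the summary, as large lowly-bound background clusters are usually
#'   removed from display for clarity (default `FALSE`).
#' @return Data frame: cluster, size, mean density per cell type, and the
#'   proximity composition when available.
#' @export
hotspot_summary <- function(hc, drop_lowest = FALSE) {
  df <- data.frame(cluster = seq_len(hc$k), size = hc$sizes,
                   hc$centers, check.names = FALSE)
  if (!is.null(hc$composition))
    df <- cbind(df, hc$composition[, c("f_up", "f_tss", "f_down")])
  if (drop_lowest) df <- df[-hc$k, , drop = FALSE]
  df
}
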