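# Brute-force oracles and fixture builders shared across the suite.
# Oracles are deliberately naive (per-base masks, O(n*m) scans, direct
# summation) and independent of the package's implementations.

# interval union via a per-base boolean mask on a small genome
oracle_merge <- function(df, chrom_len = 2000L) {
  out <- NULL
  for (ch in sort(unique(df$chrom))) {
    mask <- logical(chrom_len)
    sub <- df[df$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(sub)))
      mask[(sub$start[i] + 1L):sub$end[i]] <- TRUE
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (any(keep))
      out <- rbind(out, data.frame(chrom = ch, start = starts[keep] - 1L,
                                   end = ends[keep],
                                   stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

# exhaustive nearest-TSS scan: unsigned distance to the nearest covered base,
# sign from gene strand and which side of the TSS the region lies on
oracle_nearest <- function(regions, tss) {
  gene <- character(nrow(regions)); d <- integer(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    tt <- tss[tss$chrom == regions$chrom[i], , drop = FALSE]
    if (nrow(tt) == 0L) { gene[i] <- NA; d[i] <- NA; next }
    st <- regions$start[i]; en <- regions$end[i]
    dist <- ifelse(tt$pos >= st & tt$pos < en, 0L,
                   pmin(abs(tt$pos - st), abs(tt$pos - (en - 1L))))
    best <- min(dist)
    cand <- which(dist == best)
    k <- cand[order(tt$gene_id[cand])[1L]]
    gene[i] <- tt$gene_id[k]
    if (best == 0L) { d[i] <- 0L; next }
    region_left <- (en - 1L) < tt$pos[k]
    upstream <- if (tt$strand[k] == "+") region_left else !region_left
    d[i] <- if (upstream) -best else best
  }
  data.frame(nearest_gene = gene, d = d, stringsAsFactors = FALSE)
}

# phi coefficient closed form for two binary vectors
oracle_phi <- function(x, y) {
  M <- length(x)
  n1 <- sum(x); n2 <- sum(y); n11 <- sum(x & y)
  (M * n11 - n1 * n2) / sqrt(n1 * (M - n1) * n2 * (M - n2))
}

# all leaf orders consistent with an hclust tree (2^(N-1) of them)
oracle_tree_orders <- function(hc) {
  rec <- function(v) {
    if (v < 0) return(list(-v))
    L <- rec(hc$merge[v, 1]); R <- rec(hc$merge[v, 2])
    out <- list()
    for (a in L) for (b in R) out <- c(out, list(c(a, b)), list(c(b, a)))
    out
  }
  rec(nrow(hc$merge))
}

# direct-summation hypergeometric upper tail (ratio of choose(), linear space)
oracle_hyper_tail <- function(U, K, n, k) {
  mx <- min(K, n)
  terms <- choose(K, 0:mx) * choose(U - K, n - (0:mx)) / choose(U, n)
  suf <- rev(cumsum(rev(terms)))
  pmin(1, suf[k + 1L])
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), chrom_len = 2000L,
                             max_width = 60L) {
  start <- sample.int(chrom_len - max_width, n, replace = TRUE) - 1L
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_width, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

random_tss <- function(n, chroms = c("chr1", "chr2"), chrom_len = 2000L) {
  data.frame(gene_id = sprintf("g%03d", sample.int(999, n)),
             chrom = sample(chroms, n, replace = TRUE),
             pos = sample.int(chrom_len, n, replace = TRUE) - 1L,
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# minimal manifest around an in-memory peak list
fixture_manifest <- function(peaks, factors = NULL, cell_types = NULL,
                             species = "human") {
  ids <- names(peaks)
  data.frame(experiment_id = ids,
             factor = if (is.null(factors)) ids else factors,
             cell_type = if (is.null(cell_types)) "cellX" else cell_types,
             species = species, peak_path = NA_character_,
             stringsAsFactors = FALSE)
}

# planted combinatorial matrix: factors 1..3 share `size` exclusive rows,
# every factor additionally binds `n_extra` rows outside the planted block
plant_triple_matrix <- function(M = 20000L, N = 8L, size = 1000L,
                                n_extra = 1000L, n_other = 2000L) {
  occ <- matrix(0L, M, N, dimnames = list(NULL, LETTERS[1:N]))
  occ[seq_len(size), 1:3] <- 1L
  rest <- (size + 1L):M
  for (j in 1:3) occ[sample(rest, n_extra), j] <- 1L
  for (j in 4:N) occ[sample(rest, n_other), j] <- 1L
  occ
}

# independent-columns matrix with no planted structure
independent_matrix <- function(M = 20000L, N = 8L, n_per = 2000L) {
  occ <- matrix(0L, M, N, dimnames = list(NULL, LETTERS[1:N]))
  for (j in seq_len(N)) occ[sample.int(M, n_per), j] <- 1L
  occ
}

# BindingMatrix scaffold around a bare occupancy matrix (synthetic regions)
bm_from_occupancy <- function(occ, cell_types = "cellX") {
  M <- nrow(occ)
  regions <- data.frame(chrom = "chr1",
                        start = seq_len(M) * 1000L,
                        end = seq_len(M) * 1000L + 200L)
  ids <- colnames(occ)
  man <- data.frame(experiment_id = ids, factor = ids,
                    cell_type = rep_len(cell_types, length(ids)),
                    species = "human", peak_path = NA_character_,
                    stringsAsFactors = FALSE)
  structure(list(regions = regions, occupancy = occ, experiments = man,
                 is_reference = rep(FALSE, ncol(occ))),
            class = "BindingMatrix")
}

# small, fast ground truth for pipeline-level tests
small_spec <- function() genome_spec(c(chrT1 = 2e6, chrT2 = 2e6),
                                     n_genes = 200L)

small_truth <- function(n_replicates = 1L) {
  arch <- list(
    factor_archetype("PR", "promoter", 0.8, 0.1, 0.1, n_peaks = 150L),
    factor_archetype("CT", "distal_shared", 0.1, 0.45, 0.45, n_peaks = 150L),
    factor_archetype("MA", "distal_cell_specific", 0.1, 0.45, 0.45,
                     n_peaks = 250L, co_module = "pair"),
    factor_archetype("MB", "distal_cell_specific", 0.1, 0.45, 0.45,
                     n_peaks = 250L, co_module = "pair"))
  names(arch) <- vapply(arch, `[[`, "", "name")
  ground_truth(archetypes = arch, cell_types = c("cellA", "cellB"),
               modules = list(pair = list(factors = c("MA", "MB"),
                                          size = 100L, exclusive = TRUE,
                                          per_cell_type = TRUE)),
               gwas_factor = "CT", gwas_ratio = 3, n_gwas_hits = 400L,
               n_replicates = n_replicates, pool_size = 300L)
}
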