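# Synthetic ChIP-seq compendium generator with planted ground truth.
#
# Emulates the statistical structure the analysis stages assume: multiple
# cell types; factor archetypes with distinct TSS-proximity preferences
# (promoter-biased, distal, downstream-/upstream-biased); a CTCF-like factor
# whose binding is shared across cell types; cell-type-specific distal
# binding; planted exact co-binding modules; and a planted GWAS-enriched
# factor. Every dataset is reproducible from (seed, ground truth) and the
# truth record is serialized alongside the data.

#' Genome specification for simulation
#'
#' @param chromosomes Named integer vector of chromosome lengths (default 3
#'   chromosomes of 10 Mb).
#' @param n_genes Number of genes (default 1000).
#' @param min_tss_spacing Minimum distance between consecutive TSS in bp
#'   (default 2000).
#' @return A `GenomeSpec` list.
#' @export
genome_spec <- function(chromosomes = c(chrS1 = 1e7, chrS2 = 1e7, chrS3 = 1e7),
                        n_genes = 1000L, min_tss_spacing = 2000L) {
  stopifnot(all(chromosomes > 0), n_genes >= 1L, min_tss_spacing >= 0L)
  structure(list(chromosomes = chromosomes, n_genes = as.integer(n_genes),
                 min_tss_spacing = as.integer(min_tss_spacing)),
            class = "GenomeSpec")
}

#' Simulate gene TSS positions
#'
#' Genes are allocated to chromosomes proportionally to length; TSS positions
#' are uniform subject to the minimum spacing; strands are Bernoulli(1/2).
#' Deterministic given the seed.
#'
#' @param spec A [genome_spec()].
#' @param seed Random seed.
#' @return TSS table (`gene_id`, `chrom`, `pos`, `strand`).
#' @export
simulate_genome <- function(spec, seed) {
  set.seed(seed)
  lens <- spec$chromosomes
  n <- spec$n_genes
  s <- spec$min_tss_spacing
  alloc <- diff(round(c(0, cumsum(lens) / sum(lens) * n)))
  tss <- do.call(rbind, lapply(seq_along(lens), function(ci) {
    g <- alloc[ci]
    if (g == 0L) return(NULL)
    L <- lens[ci]
    free <- L - (g - 1L) * s
    if (free < g)
      stop("TSS spacing infeasible: ", g, " genes with spacing ", s,
           " on a chromosome of ", L, " bp")
    x <- sort(sample.int(free, g)) - 1L
    data.frame(chrom = names(lens)[ci],
               pos = as.integer(x + (seq_len(g) - 1L) * s),
               stringsAsFactors = FALSE)
  }))
  tss$gene_id <- sprintf("gene%04d", seq_len(nrow(tss)))
  tss$strand <- sample(c("+", "-"), nrow(tss), replace = TRUE)
  tss[, c("gene_id", "chrom", "pos", "strand")]
}

#' Define a factor archetype
#'
#' @param name Factor symbol.
#' @param kind One of `promoter`, `distal_shared`, `distal_cell_specific`,
#'   `downstream_biased`, `upstream_biased`.
#' @param p_tss,p_up,p_down Target location fractions (must sum to 1).
#' @param n_peaks Peaks per experiment (planted module regions count towards
#'   this total for module members).
#' @param width_meanlog,width_sdlog Log-normal peak width parameters
#'   (defaults: median 300 bp, sigma_log 0.4).
#' @param cell_types Cell types expressing the factor (`NULL` = all).
#' @param co_module Optional module id the factor belongs to.
#' @return A `FactorArchetype` list.
#' @export
factor_archetype <- function(name, kind, p_tss, p_up, p_down,
                             n_peaks = 1000L,
                             width_meanlog = log(300), width_sdlog = 0.4,
                             cell_types = NULL, co_module = NA_character_) {
  kinds <- c("promoter", "distal_shared", "distal_cell_specific",
             "downstream_biased", "upstream_biased")
  stopifnot(kind %in% kinds, n_peaks >= 1L,
            abs(p_tss + p_up + p_down - 1) < 1e-9)
  structure(list(name = name, kind = kind, p_tss = p_tss, p_up = p_up,
                 p_down = p_down, n_peaks = as.integer(n_peaks),
                 width_meanlog = width_meanlog, width_sdlog = width_sdlog,
                 cell_types = cell_types, co_module = co_module),
            class = "FactorArchetype")
}

#' Default factor archetypes
#'
#' Eight factors emulating the classes seen in real compendia: two
#' promoter-biased factors (RNAPII-like), a shared distal factor (CTCF-like),
#' a downstream-biased factor (ZNF274-like), an upstream-biased factor
#' (RNA-polymerase-III-like), and three cell-type-specific distal factors
#' forming a planted exclusive co-binding triple.
#'
#' @return Named list of [factor_archetype()] objects.
#' @export
default_archetypes <- function() {
  a <- list(
    factor_archetype("PROM1", "promoter", 0.80, 0.10, 0.10, n_peaks = 1700L),
    factor_archetype("PROM2", "promoter", 0.70, 0.15, 0.15, n_peaks = 1700L),
    factor_archetype("CTCFL", "distal_shared", 0.10, 0.45, 0.45, n_peaks = 1700L),
    factor_archetype("DOWNB", "downstream_biased", 0.15, 0.25, 0.60, n_peaks = 1700L),
    factor_archetype("UPSB", "upstream_biased", 0.15, 0.60, 0.25, n_peaks = 1700L),
    factor_archetype("MODA", "distal_cell_specific", 0.05, 0.475, 0.475,
                     n_peaks = 2700L, co_module = "triple"),
    factor_archetype("MODB", "distal_cell_specific", 0.05, 0.475, 0.475,
                     n_peaks = 2700L, co_module = "triple"),
    factor_archetype("MODC", "distal_cell_specific", 0.05, 0.475, 0.475,
                     n_peaks = 2700L, co_module = "triple"))
  names(a) <- vapply(a, `[[`, "", "name")
  a
}

#' Default ground truth
#'
#' @param archetypes List of [factor_archetype()]s (default
#'   [default_archetypes()]).
#' @param cell_types Cell types (default `cellA`, `cellB`, `cellC`).
#' @param modules Planted co-binding modules: named list of
#'   `list(factors, size, exclusive, per_cell_type)`.
#' @param gwas_factor Factor whose peaks are GWAS-enriched.
#' @param gwas_ratio Target per-bp enrichment ratio inside the planted
#'   factor's peaks (1 = uniform).
#' @param n_gwas_hits Number of GWAS hits to simulate.
#' @param n_replicates Replicate experiments per (factor, cell type).
#' @param species Species label written to the manifest.
#' @param pool_size Per-cell-type, per-direction size of the distal enhancer
#'   pool that cell-type-specific factors draw from.
#' @return A `GroundTruth` list.
#' @export
ground_truth <- function(archetypes = default_archetypes(),
                         cell_types = c("cellA", "cellB", "cellC"),
                         modules = list(triple = list(
                           factors = c("MODA", "MODB", "MODC"),
                           size = 1000L, exclusive = TRUE,
                           per_cell_type = TRUE)),
                         gwas_factor = "CTCFL", gwas_ratio = 3,
                         n_gwas_hits = 2000L, n_replicates = 1L,
                         species = "human", pool_size = 2600L) {
  for (m in modules)
    stopifnot(all(m$factors %in% names(archetypes)), m$size >= 1L)
  if (!is.null(gwas_factor)) stopifnot(gwas_factor %in% names(archetypes))
  structure(list(archetypes = archetypes, cell_types = cell_types,
                 modules = modules, gwas_factor = gwas_factor,
                 gwas_ratio = gwas_ratio, n_gwas_hits = as.integer(n_gwas_hits),
                 n_replicates = as.integer(n_replicates), species = species,
                 pool_size = as.integer(pool_size)),
            class = "GroundTruth")
}

.sample_widths <- function(n, meanlog, sdlog) {
  pmax(50L, as.integer(round(stats::rlnorm(n, meanlog, sdlog))))
}

# Place n peaks of a given location class ("tss", "up", "down"), validated
# against the realized nearest-TSS sign and an optional forbidden region set
# (1 bp margin, so bookended merges are also impossible). Rejection
# resampling keeps the realized location profile on target.
.place_class_peaks <- function(n, class, tss, chrom_lens, meanlog, sdlog,
                               forbidden = NULL, offset_range = c(1e3, 1e5)) {
  if (n == 0L)
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  out <- NULL
  remaining <- n
  rounds <- 0L
  while (remaining > 0L && rounds < 80L) {
    rounds <- rounds + 1L
    k <- remaining
    anc <- tss[sample.int(nrow(tss), k, replace = TRUE), , drop = FALSE]
    w <- .sample_widths(k, meanlog, sdlog)
    if (class == "tss") {
      center <- anc$pos
    } else {
      off <- as.integer(round(exp(stats::runif(
        k, log(offset_range[1L]), log(offset_range[2L])))))
      left <- (class == "up") == (anc$strand == "+")
      center <- anc$pos + ifelse(left, -off, off)
    }
    start <- as.integer(center - w %/% 2L)
    end <- start + w
    len <- chrom_lens[anc$chrom]
    ok <- start >= 0L & end <= len
    cand <- data.frame(chrom = anc$chrom, start = start, end = end,
                       stringsAsFactors = FALSE)[ok, , drop = FALSE]
    if (nrow(cand) == 0L) next
    d <- suppressMessages(nearest_tss(cand, tss))$d
    keep <- switch(class,
                   tss = !is.na(d) & d == 0L,
                   up = !is.na(d) & d < 0L,
                   down = !is.na(d) & d > 0L)
    if (!is.null(forbidden) && nrow(forbidden) > 0L) {
      hit <- .overlap_ranges(forbidden, cand, margin = 1L)
      keep[unique(hit$q)] <- FALSE
    }
    out <- rbind(out, cand[keep, , drop = FALSE])
    remaining <- n - nrow(out)
  }
  if (remaining > 0L)
    stop("peak placement did not converge for class '", class, "'")
  rownames(out) <- NULL
  out
}

# Place `size` mutually non-overlapping distal regions (realized |d| >=
# min_abs_d) avoiding a forbidden set.
.place_distal_regions <- function(size, tss, chrom_lens, meanlog, sdlog,
                                  min_abs_d = 10000L, forbidden = NULL) {
  out <- NULL
  rounds <- 0L
  while ((is.null(out) || nrow(out) < size) && rounds < 100L) {
    rounds <- rounds + 1L
    k <- size - if (is.null(out)) 0L else nrow(out)
    ci <- sample.int(length(chrom_lens), k, replace = TRUE,
                     prob = chrom_lens / sum(chrom_lens))
    w <- .sample_widths(k, meanlog, sdlog)
    center <- as.integer(floor(stats::runif(k) * (chrom_lens[ci] - 2L * w))) + w
    cand <- data.frame(chrom = names(chrom_lens)[ci],
                       start = as.integer(center - w %/% 2L),
                       end = as.integer(center - w %/% 2L + w),
                       stringsAsFactors = FALSE)
    cand <- cand[cand$start >= 0L, , drop = FALSE]
    d <- suppressMessages(nearest_tss(cand, tss))$d
    keep <- !is.na(d) & abs(d) >= min_abs_d
    avoid <- rbind(forbidden, out)
    if (!is.null(avoid) && nrow(avoid) > 0L) {
      avoid <- merge_intervals(avoid)
      hit <- .overlap_ranges(avoid, cand, margin = 1L)
      keep[unique(hit$q)] <- FALSE
    }
    cand <- cand[keep, , drop = FALSE]
    # also drop within-batch mutual overlaps (greedy, keep first)
    if (nrow(cand) > 1L) {
      o <- order(cand$chrom, cand$start)
      cand <- cand[o, , drop = FALSE]
      same <- c(FALSE, cand$chrom[-1L] == cand$chrom[-nrow(cand)])
      prev_end <- c(-1L, cummax(cand$end[-nrow(cand)]))
      cand <- cand[!(same & cand$start <= prev_end + 1L), , drop = FALSE]
    }
    out <- rbind(out, cand)
  }
  if (is.null(out) || nrow(out) < size)
    stop("module region demand exceeds genome capacity")
  out <- out[seq_len(size), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate all experiments of a ground truth
#'
#' Generates the peak set of every (factor, cell type, replicate) so that the
#' realized TSS-location profile matches the archetype fractions in
#' expectation: TSS peaks are centered on a sampled TSS; upstream/downstream
#' peaks are offset log-uniformly in [1 kb, 100 kb] on the strand-correct
#' side, with rejection resampling against the realized nearest-TSS sign.
#' `distal_shared` factors reuse one fixed peak set across cell types;
#' `distal_cell_specific` factors draw their distal peaks from a per-cell-type
#' enhancer pool (disjoint across cell types); co-module members additionally
#' carry the module's planted regions, which no other peak may overlap when
#' the module is exclusive. Replicates re-sample 90% of the first replicate's
#' peaks and draw the remainder fresh.
#'
#' @param truth A [ground_truth()].
#' @param tss TSS table from [simulate_genome()].
#' @param spec The [genome_spec()].
#' @param seed Random seed.
#' @return List with `manifest` (peak_path `NA` until written), `peaks`
#'   (named list), `modules` (planted region sets per module and cell type)
#'   and `pools`.
#' @export
simulate_experiments <- function(truth, tss, spec, seed) {
  set.seed(seed)
  lens <- spec$chromosomes
  arch <- truth$archetypes
  cts <- truth$cell_types
  ml <- arch[[1L]]$width_meanlog; sl <- arch[[1L]]$width_sdlog

  # 1. planted module regions (distal), mutually exclusive across modules
  modules <- list()
  forbidden <- NULL
  for (mn in names(truth$modules)) {
    m <- truth$modules[[mn]]
    member_cts <- Reduce(union, lapply(m$factors, function(f) {
      ac <- arch[[f]]$cell_types
      if (is.null(ac)) cts else ac
    }))
    per_ct <- if (isTRUE(m$per_cell_type)) member_cts else "shared"
    modules[[mn]] <- lapply(stats::setNames(per_ct, per_ct), function(ct) {
      regs <- .place_distal_regions(m$size, tss, lens, ml, sl,
                                    forbidden = forbidden)
      forbidden <<- rbind(forbidden, regs)
      regs
    })
  }
  exclusive <- NULL
  for (mn in names(truth$modules))
    if (isTRUE(truth$modules[[mn]]$exclusive))
      exclusive <- rbind(exclusive, do.call(rbind, modules[[mn]]))
  if (!is.null(exclusive)) exclusive <- merge_intervals(exclusive)

  # 2. per-cell-type distal enhancer pools (disjoint across cell types by
  # independent placement; avoided regions keep them off the planted modules)
  need_pool <- any(vapply(arch, function(a)
    a$kind == "distal_cell_specific", TRUE))
  pools <- list()
  if (need_pool) {
    for (ct in cts) {
      pools[[ct]] <- list(
        up = .place_class_peaks(truth$pool_size, "up", tss, lens, ml, sl,
                                forbidden = exclusive),
        down = .place_class_peaks(truth$pool_size, "down", tss, lens, ml, sl,
                                  forbidden = exclusive))
    }
  }

  # 3. shared (CTCF-like) factor-level peak sets
  shared_sets <- list()
  for (a in arch) {
    if (a$kind != "distal_shared") next
    counts <- drop(stats::rmultinom(1L, a$n_peaks, c(a$p_tss, a$p_up, a$p_down)))
    shared_sets[[a$name]] <- rbind(
      .place_class_peaks(counts[1L], "tss", tss, lens, a$width_meanlog,
                         a$width_sdlog, forbidden = exclusive),
      .place_class_peaks(counts[2L], "up", tss, lens, a$width_meanlog,
                         a$width_sdlog, forbidden = exclusive),
      .place_class_peaks(counts[3L], "down", tss, lens, a$width_meanlog,
                         a$width_sdlog, forbidden = exclusive))
  }

  draw_free_peaks <- function(a, ct, n_free) {
    counts <- drop(stats::rmultinom(1L, n_free, c(a$p_tss, a$p_up, a$p_down)))
    ptss <- .place_class_peaks(counts[1L], "tss", tss, lens, a$width_meanlog,
                               a$width_sdlog, forbidden = exclusive)
    if (a$kind == "distal_cell_specific") {
      pool <- pools[[ct]]
      up <- pool$up[sample.int(nrow(pool$up), counts[2L]), , drop = FALSE]
      down <- pool$down[sample.int(nrow(pool$down), counts[3L]), , drop = FALSE]
      rbind(ptss, up, down)
    } else {
      rbind(ptss,
            .place_class_peaks(counts[2L], "up", tss, lens, a$width_meanlog,
                               a$width_sdlog, forbidden = exclusive),
            .place_class_peaks(counts[3L], "down", tss, lens, a$width_meanlog,
                               a$width_sdlog, forbidden = exclusive))
    }
  }

  base_peaks <- function(a, ct) {
    mod_regs <- NULL
    if (!is.na(a$co_module)) {
      mm <- modules[[a$co_module]]
      mod_regs <- if (isTRUE(truth$modules[[a$co_module]]$per_cell_type))
        mm[[ct]] else mm[["shared"]]
    }
    n_mod <- if (is.null(mod_regs)) 0L else nrow(mod_regs)
    if (a$kind == "distal_shared") {
      free <- shared_sets[[a$name]]
    } else {
      free <- draw_free_peaks(a, ct, max(0L, a$n_peaks - n_mod))
    }
    rbind(mod_regs, free)
  }

  manifest <- NULL
  peaks <- list()
  for (a in arch) {
    a_cts <- if (is.null(a$cell_types)) cts else a$cell_types
    for (ct in a_cts) {
      b <- base_peaks(a, ct)
      for (r in seq_len(truth$n_replicates)) {
        id <- sprintf("%s.%s.%d", a$name, ct, r)
        if (r == 1L) {
          p <- b
        } else {
          n_keep <- floor(0.9 * nrow(b))
          p <- rbind(b[sample.int(nrow(b), n_keep), , drop = FALSE],
                     draw_free_peaks(a, ct, nrow(b) - n_keep))
        }
        peaks[[id]] <- .sort_intervals(p)
        manifest <- rbind(manifest, data.frame(
          experiment_id = id, factor = a$name, cell_type = ct,
          species = truth$species, peak_path = NA_character_,
          stringsAsFactors = FALSE))
      }
    }
  }
  list(manifest = manifest, peaks = peaks, modules = modules, pools = pools)
}

#' Simulate a GWAS hit table
#'
#' Places a fraction of hits inside the planted factor's peak regions so the
#' per-bp hit density there exceeds the rest of the genome by the target
#' ratio; the remaining hits are uniform outside. Traits are drawn from a
#' small fixed vocabulary. A ratio of 1 yields a genome-wide uniform table.
#'
#' @param truth A [ground_truth()].
#' @param peaks Named list of simulated peak sets (for the planted factor).
#' @param manifest Simulated manifest.
#' @param spec The [genome_spec()].
#' @param seed Random seed.
#' @return GWAS hit data frame (`chrom`, `pos`, `trait`), 0-based positions.
#' @export
simulate_gwas <- function(truth, peaks, manifest, spec, seed) {
  set.seed(seed)
  H <- truth$n_gwas_hits
  traits <- c("breast carcinoma", "inflammatory bowel disease",
              "childhood obesity", "type 2 diabetes",
              "coronary artery disease", "rheumatoid arthritis", "asthma",
              "schizophrenia", "height", "ulcerative colitis")
  if (H == 0L)
    return(data.frame(chrom = character(), pos = integer(),
                      trait = character()))
  lens <- spec$chromosomes
  L <- sum(lens)
  planted <- NULL
  if (!is.null(truth$gwas_factor)) {
    ids <- manifest$experiment_id[manifest$factor == truth$gwas_factor]
    planted <- merge_intervals(do.call(rbind, lapply(
      peaks[ids], function(p) p[, c("chrom", "start", "end")])))
  }
  Lp <- if (is.null(planted)) 0 else sum(planted$end - planted$start)
  r <- truth$gwas_ratio
  f <- if (Lp > 0) r * Lp / (L - Lp + r * Lp) else 0
  n_in <- stats::rbinom(1L, H, f)
  uniform_pos <- function(k) {
    ci <- sample.int(length(lens), k, replace = TRUE, prob = lens / sum(lens))
    data.frame(chrom = names(lens)[ci],
               pos = as.integer(floor(stats::runif(k) * lens[ci])),
               stringsAsFactors = FALSE)
  }
  hits <- NULL
  if (n_in > 0L) {
    wts <- planted$end - planted$start
    ri <- sample.int(nrow(planted), n_in, replace = TRUE, prob = wts)
    hits <- data.frame(chrom = planted$chrom[ri],
                       pos = planted$start[ri] + as.integer(
                         floor(stats::runif(n_in) * wts[ri])),
                       stringsAsFactors = FALSE)
  }
  n_out <- H - n_in
  while (n_out > 0L) {
    cand <- uniform_pos(n_out)
    if (!is.null(planted)) {
      q <- data.frame(chrom = cand$chrom, start = cand$pos,
                      end = cand$pos + 1L)
      inside <- unique(.overlap_ranges(planted, q)$q)
      if (length(inside)) cand <- cand[-inside, , drop = FALSE]
    }
    hits <- rbind(hits, cand)
    n_out <- H - nrow(hits)
  }
  hits$trait <- sample(traits, H, replace = TRUE)
  hits <- hits[order(hits$chrom, hits$pos), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Simulate a full dataset
#'
#' Orchestrates [simulate_genome()], [simulate_experiments()] and
#' [simulate_gwas()] under per-stage seeds derived from one base seed, and
#' optionally writes every artifact (manifest TSV, per-experiment BEDs, TSS
#' BED, GWAS table in catalog dialect, ground truth JSON) to a directory.
#'
#' @param seed Base seed.
#' @param spec A [genome_spec()].
#' @param truth A [ground_truth()].
#' @param out_dir Optional output directory.
#' @return List with `spec`, `truth`, `tss`, `manifest`, `peaks`, `gwas`,
#'   `modules`, and `paths` when written.
#' @export
simulate_dataset <- function(seed, spec = genome_spec(),
                             truth = ground_truth(), out_dir = NULL) {
  tss <- simulate_genome(spec, seed)
  sim <- simulate_experiments(truth, tss, spec, seed + 1L)
  gwas <- simulate_gwas(truth, sim$peaks, sim$manifest, spec, seed + 2L)
  out <- list(spec = spec, truth = truth, tss = tss,
              manifest = sim$manifest, peaks = sim$peaks, gwas = gwas,
              modules = sim$modules, seed = seed)
  if (!is.null(out_dir)) out$paths <- write_dataset(out, out_dir)
  out
}

#' Write a simulated dataset to disk
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(file.path(dir, "peaks"), recursive = TRUE, showWarnings = FALSE)
  man <- sim$manifest
  man$peak_path <- file.path("peaks", paste0(man$experiment_id, ".bed"))
  for (i in seq_len(nrow(man)))
    write_bed(sim$peaks[[man$experiment_id[i]]],
              file.path(dir, man$peak_path[i]))
  p_man <- file.path(dir, "manifest.tsv")
  write_manifest(man, p_man)
  p_tss <- file.path(dir, "tss.bed")
  write_tss_bed(sim$tss, p_tss)
  p_gwas <- file.path(dir, "gwas.tsv")
  write_gwas_catalog(sim$gwas, p_gwas)
  p_truth <- file.path(dir, "ground_truth.json")
  truth <- sim$truth
  truth$archetypes <- lapply(truth$archetypes, unclass)
  jsonlite::write_json(
    list(seed = sim$seed,
         genome = list(chromosomes = as.list(sim$spec$chromosomes),
                       n_genes = sim$spec$n_genes,
                       min_tss_spacing = sim$spec$min_tss_spacing),
         truth = unclass(truth),
         modules = lapply(sim$modules, function(mm) lapply(mm, identity))),
    p_truth, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(manifest = p_man, tss = p_tss, gwas = p_gwas,
              ground_truth = p_truth))
}
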