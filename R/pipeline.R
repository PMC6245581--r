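# Staged pipeline driver: simulate -> matrix -> heatmap -> tss-annotate ->
# hotspots -> combos -> gwas, with a flat key=value config, per-stage derived
# seeds, dependency checking, a resolved-config echo and a JSON summary.

.PIPELINE_STAGES <- c("simulate", "matrix", "heatmap", "tss", "hotspots",
                      "combos", "gwas")

#' Default pipeline configuration
#'
#' All thresholds the analysis uses, with the compendium-scale defaults:
#' proximal < 1 kb, distal >= 10 kb, cell types with more than 30 experiments
#' for the density analysis, at least 6 distinct factors for the combinatorial
#' analysis, 100 randomizations, k = 6 density clusters, alpha = 0.05, GWAS
#' window 0 bp.
#'
#' @param out_dir Output directory.
#' @param seed Base seed; every stochastic stage derives its own seed from it.
#' @param ... Overrides of any default key.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(out_dir = "chipcooc_out", seed = 1L, ...) {
  cfg <- list(
    out_dir = out_dir,
    manifest = NULL, tss = NULL, gwas = NULL,
    proximal_bp = 1000L, distal_bp = 10000L,
    min_experiments_per_cell_type = 30L,
    min_factors_combinatorial = 6L,
    n_rand = 100L, kmeans_k = 6L, kmeans_n_init = 10L,
    alpha = 0.05, gwas_window = 0L,
    heatmap_png = TRUE,
    seed = as.integer(seed))
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_config(cfg)
}

#' Validate a pipeline configuration
#'
#' @param cfg Config list.
#' @return The config, with numeric keys coerced, or an error.
#' @export
validate_config <- function(cfg) {
  num <- c("proximal_bp", "distal_bp", "min_experiments_per_cell_type",
           "min_factors_combinatorial", "n_rand", "kmeans_k", "kmeans_n_init",
           "gwas_window", "seed")
  for (k in num) cfg[[k]] <- as.integer(cfg[[k]])
  cfg$alpha <- as.numeric(cfg$alpha)
  if (cfg$proximal_bp <= 0L || cfg$distal_bp <= 0L || cfg$n_rand <= 0L ||
      cfg$kmeans_k <= 0L || cfg$alpha <= 0 || cfg$alpha > 1)
    stop("config validation: thresholds must be positive and alpha in (0, 1]")
  if (cfg$proximal_bp > cfg$distal_bp)
    stop("config validation: proximal_bp must not exceed distal_bp")
  if (is.na(cfg$seed)) stop("config validation: seed is required")
  cfg
}

#' Read a flat key=value config file
#'
#' Lines of the form `key = value` (or `key=value`); `#` comments and blank
#' lines ignored. Values are coerced by [validate_config()].
#'
#' @param path Config file path.
#' @param ... Overrides applied after reading.
#' @return Config list.
#' @export
read_pipeline_config <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_0-9]+)\\s*=\\s*(.*)$", lines))
  if (any(lengths(kv) != 3L)) stop("malformed config line: ",
                                   lines[which(lengths(kv) != 3L)[1L]])
  keys <- vapply(kv, `[[`, "", 2L)
  vals <- trimws(vapply(kv, `[[`, "", 3L))
  vals <- lapply(vals, function(v) {
    if (v %in% c("TRUE", "FALSE", "true", "false")) return(as.logical(toupper(v)))
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
  names(vals) <- keys
  args <- vals
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(pipeline_config, args)
}

# deterministic per-stage seed derived from the base seed and the stage name
.stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 131L + h) %% (2^31 - 1))
}

.stage_log <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

.artifact <- function(cfg, ...) file.path(cfg$out_dir, ...)

# stage dependency table: files that must exist before a stage runs, and the
# stage to run first
.stage_deps <- function(cfg, stage) {
  mat <- .artifact(cfg, "matrix", "occupancy.mtx")
  ann <- .artifact(cfg, "tss", "region_annotations.tsv")
  switch(stage,
         simulate = character(),
         matrix = character(),
         heatmap = c(matrix = mat),
         tss = c(matrix = mat),
         hotspots = c(matrix = mat, tss = ann),
         combos = c(matrix = mat),
         gwas = c(matrix = mat),
         stop("unknown stage: ", stage))
}

# resolve input paths: explicit config keys win; otherwise the simulate
# stage's outputs under out_dir/data are used
.resolve_inputs <- function(cfg) {
  dd <- .artifact(cfg, "data")
  if (is.null(cfg$manifest)) cfg$manifest <- file.path(dd, "manifest.tsv")
  if (is.null(cfg$tss)) cfg$tss <- file.path(dd, "tss.bed")
  if (is.null(cfg$gwas)) cfg$gwas <- file.path(dd, "gwas.tsv")
  cfg
}

.write_stage_files <- function(cfg, stage, files) {
  manifest_path <- .artifact(cfg, paste0(stage, ".files.txt"))
  root <- paste0(sub("/+$", "", cfg$out_dir), "/")
  rel <- sub(root, "", unname(files), fixed = TRUE)
  writeLines(sort(rel), manifest_path)
  invisible(files)
}

.load_matrix <- function(cfg) {
  manifest <- read_manifest(cfg$manifest)
  import_binding_matrix(.artifact(cfg, "matrix"), manifest)
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (synthetic dataset under `out_dir/data`), `matrix`
#' (occupancy matrix), `heatmap` (correlation + clustering), `tss` (region
#' and peak annotation, location profiles, species comparison when two species
#' are present), `hotspots` (proximal/distal correlations, TF density, k-means
#' clusters), `combos` (combinatorial enrichment), `gwas` (GWAS overlap
#' tests), or `all` (topological order). Each stage writes its artifacts under
#' `out_dir`, a list of produced files, and the fully resolved config.
#'
#' @param stage Stage name.
#' @param cfg Config from [pipeline_config()] / [read_pipeline_config()].
#' @return Character vector of produced files, invisibly.
#' @export
run_stage <- function(stage, cfg) {
  cfg <- validate_config(cfg)
  if (stage == "all") {
    res <- lapply(.PIPELINE_STAGES, run_stage, cfg = cfg)
    return(invisible(unlist(res)))
  }
  if (!stage %in% .PIPELINE_STAGES) stop("unknown stage: ", stage)
  cfg <- .resolve_inputs(cfg)
  deps <- .stage_deps(cfg, stage)
  gone <- !file.exists(deps)
  if (any(gone))
    stop("stage '", stage, "' needs artifacts from stage '",
         names(deps)[gone][1L], "'; run that stage first (missing ",
         deps[gone][1L], ")")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  echo <- file.path(cfg$out_dir, "config_resolved.txt")
  writeLines(paste0(names(cfg), " = ",
                    vapply(cfg, function(v)
                      if (is.null(v)) "" else paste(v, collapse = ","), "")),
             echo)
  files <- switch(stage,
                  simulate = .stage_simulate(cfg),
                  matrix = .stage_matrix(cfg),
                  heatmap = .stage_heatmap(cfg),
                  tss = .stage_tss(cfg),
                  hotspots = .stage_hotspots(cfg),
                  combos = .stage_combos(cfg),
                  gwas = .stage_gwas(cfg))
  .write_stage_files(cfg, stage, files)
  .update_summary(cfg)
  invisible(files)
}

#' Run the full pipeline
#'
#' @param cfg Config list.
#' @param stages Stages to run (default `"all"`).
#' @return Produced files, invisibly.
#' @export
run_pipeline <- function(cfg, stages = "all") {
  if (identical(stages, "all")) return(run_stage("all", cfg))
  invisible(unlist(lapply(stages, run_stage, cfg = cfg)))
}

.stage_simulate <- function(cfg) {
  .stage_log("simulate", "generating synthetic dataset (seed ",
             .stage_seed(cfg$seed, "simulate"), ")")
  sim <- simulate_dataset(.stage_seed(cfg$seed, "simulate"),
                          out_dir = .artifact(cfg, "data"))
  .stage_log("simulate", nrow(sim$manifest), " experiments, ",
             nrow(sim$tss), " genes, ", nrow(sim$gwas), " GWAS hits")
  c(sim$paths, .artifact(cfg, "data", "peaks"))
}

.stage_matrix <- function(cfg) {
  manifest <- read_manifest(cfg$manifest)
  bm <- build_binding_matrix(manifest)
  if (file.exists(cfg$tss)) {
    tss <- read_tss_bed(cfg$tss)
    bm <- add_reference_track(bm, tss, "TSS")
  }
  .stage_log("matrix", nrow(bm$regions), " merged regions x ",
             sum(!bm$is_reference), " experiments")
  export_binding_matrix(bm, .artifact(cfg, "matrix"))
}

.stage_heatmap <- function(cfg) {
  bm <- .load_matrix(cfg)
  corr <- correlate_binding(bm)
  cc <- cluster_correlation(corr)
  dir.create(.artifact(cfg, "heatmap"), showWarnings = FALSE)
  p1 <- .artifact(cfg, "heatmap", "correlation.tsv")
  write_correlation(corr, p1)
  p2 <- .artifact(cfg, "heatmap", "leaf_order.tsv")
  utils::write.table(data.frame(position = seq_along(cc$leaf_order),
                                experiment_id = cc$leaf_order),
                     p2, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(p1, p2)
  if (isTRUE(cfg$heatmap_png)) {
    p3 <- .artifact(cfg, "heatmap", "heatmap.png")
    plot_correlation_heatmap(cc, bm, filename = p3)
    files <- c(files, p3)
  }
  .stage_log("heatmap", "clustered ", ncol(corr), " experiments")
  files
}

.stage_tss <- function(cfg) {
  bm <- .load_matrix(cfg)
  tss <- read_tss_bed(cfg$tss)
  dir.create(.artifact(cfg, "tss"), showWarnings = FALSE)
  ann <- nearest_tss(bm$regions, tss)
  p1 <- .artifact(cfg, "tss", "region_annotations.tsv")
  utils::write.table(ann, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- read_manifest(cfg$manifest)
  profiles <- location_profiles(manifest, tss)
  p2 <- .artifact(cfg, "tss", "profiles.tsv")
  write_profiles(profiles, p2)
  ord <- sort_profiles(profiles)
  p3 <- .artifact(cfg, "tss", "profiles_sorted.tsv")
  write_profiles(rbind(ord$upstream, ord$main, ord$downstream), p3)
  files <- c(p1, p2, p3)
  sp <- unique(manifest$species)
  if (length(sp) == 2L) {
    pa <- profiles[profiles$species == sp[1L], ]
    pb <- profiles[profiles$species == sp[2L], ]
    shared <- length(intersect(toupper(pa$factor), toupper(pb$factor)))
    if (shared >= 3L) {
      sc <- compare_species(pa, pb)
      p4 <- .artifact(cfg, "tss", "species_comparison.tsv")
      utils::write.table(cbind(sc$per_factor,
                               pearson_r = sc$pearson_r,
                               slope = sc$slope, intercept = sc$intercept),
                         p4, sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, p4)
    } else {
      .stage_log("tss", "fewer than 3 shared factors; species comparison skipped")
    }
  }
  .stage_log("tss", nrow(profiles), " profiles; ",
             sum(is.na(ann$d)), " regions without TSS excluded")
  files
}

.stage_hotspots <- function(cfg) {
  bm <- .load_matrix(cfg)
  ann <- utils::read.delim(.artifact(cfg, "tss", "region_annotations.tsv"),
                           stringsAsFactors = FALSE)
  dir.create(.artifact(cfg, "hotspots"), showWarnings = FALSE)
  files <- character()
  halves <- split_by_proximity(bm, ann, cfg$proximal_bp, cfg$distal_bp)
  .stage_log("hotspots", sum(halves$class == "proximal", na.rm = TRUE),
             " proximal / ", sum(halves$class == "distal", na.rm = TRUE),
             " distal regions of ", nrow(bm$regions))
  for (side in c("proximal", "distal")) {
    sub <- halves[[side]]
    if (nrow(sub$regions) == 0L) next
    p <- .artifact(cfg, "hotspots", paste0(side, "_correlation.tsv"))
    write_correlation(correlate_binding(sub), p)
    files <- c(files, p)
  }
  cts <- select_cell_types(bm$experiments, cfg$min_experiments_per_cell_type)
  if (length(cts) == 0L) {
    .stage_log("hotspots", "no eligible cell type; density clustering skipped")
    return(files)
  }
  dm <- tf_density(bm, cts)
  p1 <- .artifact(cfg, "hotspots", "density.tsv")
  utils::write.table(data.frame(dm$regions, dm$density, check.names = FALSE),
                     p1, sep = "\t", quote = FALSE, row.names = FALSE)
  hc <- cluster_hotspots(dm, k = cfg$kmeans_k,
                         seed = .stage_seed(cfg$seed, "hotspots"),
                         n_init = cfg$kmeans_n_init, annotations = ann)
  p2 <- .artifact(cfg, "hotspots", "clusters.bed")
  write_bed(data.frame(dm$regions, name = hc$assignment), p2)
  p3 <- .artifact(cfg, "hotspots", "cluster_summary.tsv")
  utils::write.table(hotspot_summary(hc), p3, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  .stage_log("hotspots", "k = ", hc$k, " clusters over ", length(cts),
             " cell types")
  c(files, p1, p2, p3)
}

.stage_combos <- function(cfg) {
  manifest <- read_manifest(cfg$manifest)
  res <- combination_enrichment(manifest,
                                min_factors = cfg$min_factors_combinatorial,
                                n_rand = cfg$n_rand,
                                seed = .stage_seed(cfg$seed, "combos"))
  dir.create(.artifact(cfg, "combos"), showWarnings = FALSE)
  p <- .artifact(cfg, "combos", "combinations.tsv")
  utils::write.table(res, p, sep = "\t", quote = FALSE, row.names = FALSE)
  .stage_log("combos", nrow(res), " patterns tested across ",
             length(unique(res$cell_type)), " cell types")
  p
}

.stage_gwas <- function(cfg) {
  bm <- .load_matrix(cfg)
  hits <- read_gwas_catalog(cfg$gwas)
  marks <- mark_gwas_regions(bm$regions, hits, window = cfg$gwas_window)
  res <- test_gwas_overlap(bm, marks, alpha = cfg$alpha)
  dir.create(.artifact(cfg, "gwas"), showWarnings = FALSE)
  p1 <- .artifact(cfg, "gwas", "gwas_results.tsv")
  utils::write.table(res, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  sig <- res$experiment_id[res$significant]
  bd <- gwas_trait_breakdown(bm, marks,
                             if (length(sig)) sig else character())
  p2 <- .artifact(cfg, "gwas", "trait_breakdown.tsv")
  utils::write.table(bd, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  .stage_log("gwas", sum(res$significant), " of ", nrow(res),
             " experiments significant at alpha = ", cfg$alpha)
  c(p1, p2)
}

# aggregate machine-readable summary of whatever artifacts exist so far
.update_summary <- function(cfg) {
  s <- list(seed = cfg$seed)
  f <- .artifact(cfg, "matrix", "regions.bed")
  if (file.exists(f)) {
    s$n_regions <- length(readLines(f))
    cols <- utils::read.delim(.artifact(cfg, "matrix", "columns.tsv"))
    s$n_experiments <- sum(!cols$is_reference)
  }
  f <- .artifact(cfg, "combos", "combinations.tsv")
  if (file.exists(f)) {
    cmb <- utils::read.delim(f)
    s$n_patterns_tested <- nrow(cmb)
    s$n_patterns_significant <- sum(cmb$p_bonf < cfg$alpha)
    if (nrow(cmb)) {
      top <- cmb[order(cmb$log10_p_raw, -cmb$observed), ][1L, ]
      s$top_pattern <- paste0(top$cell_type, ":", top$pattern)
      s$top_pattern_observed <- top$observed
      s$top_pattern_p_bonf <- top$p_bonf
    }
  }
  f <- .artifact(cfg, "gwas", "gwas_results.tsv")
  if (file.exists(f)) {
    gw <- utils::read.delim(f)
    s$n_gwas_significant <- sum(gw$significant)
    s$gwas_top_experiment <- gw$experiment_id[1L]
  }
  jsonlite::write_json(s, .artifact(cfg, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(s)
}
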