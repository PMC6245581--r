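# Per-experiment TSS-proximity preference profiles: fractions of peaks
# overlapping / upstream of / downstream of the nearest TSS, the three-group
# classification, display ordering, and the cross-species per-factor
# comparison.

#' Location profile of one experiment
#'
#' From the signed nearest-TSS distances of an experiment's peaks, computes
#' the fraction of peaks overlapping a TSS (`d == 0`), upstream (`d < 0`) and
#' downstream (`d > 0`) of the nearest TSS. Peaks with undefined distance
#' (chromosome without TSS) are excluded from all three fractions. The
#' experiment is classified `upstream-biased` if `f_up > 0.5`,
#' `downstream-biased` if `f_down > 0.5`, else `balanced`.
#'
#' @param d Signed distances (from [nearest_tss()]) of one experiment's peaks.
#' @param experiment_id Identifier used in the result and in error messages.
#' @return One-row data frame: `experiment_id`, `n_peaks`, `f_tss`, `f_up`,
#'   `f_down`, `group`.
#' @export
location_profile <- function(d, experiment_id = "experiment") {
  d <- d[!is.na(d)]
  if (length(d) == 0L)
    stop("no peaks with defined TSS distance for ", experiment_id)
  f_tss <- mean(d == 0L)
  f_up <- mean(d < 0L)
  f_down <- mean(d > 0L)
  group <- if (f_up > 0.5) "upstream-biased"
           else if (f_down > 0.5) "downstream-biased"
           else "balanced"
  data.frame(experiment_id = experiment_id, n_peaks = length(d),
             f_tss = f_tss, f_up = f_up, f_down = f_down, group = group,
             stringsAsFactors = FALSE)
}

#' Location profiles for all experiments of a manifest
#'
#' Annotates every experiment's peaks with the nearest TSS and stacks the
#' per-experiment profiles, carrying factor / cell-type / species metadata.
#'
#' @param manifest Manifest data frame.
#' @param tss TSS table.
#' @param peaks Optional named list of peak data frames (read from
#'   `peak_path` when `NULL`).
#' @return Data frame of profiles, one row per experiment.
#' @export
location_profiles <- function(manifest, tss, peaks = NULL) {
  if (is.null(peaks)) {
    peaks <- lapply(manifest$peak_path, read_peaks_bed)
    names(peaks) <- manifest$experiment_id
  }
  out <- do.call(rbind, lapply(manifest$experiment_id, function(e) {
    ann <- nearest_tss(peaks[[e]], tss)
    location_profile(ann$d, e)
  }))
  cbind(out, manifest[match(out$experiment_id, manifest$experiment_id),
                      c("factor", "cell_type", "species"), drop = FALSE],
        row.names = NULL)
}

#' Display ordering of location profiles
#'
#' Experiments with more than 50% of peaks upstream or downstream of the
#' nearest TSS are set aside in separate lists; the remaining (balanced)
#' experiments are sorted by decreasing fraction of peaks overlapping a TSS.
#'
#' @param profiles Data frame of profiles (from [location_profiles()]).
#' @return List with elements `main` (balanced, sorted by `f_tss` descending),
#'   `upstream` and `downstream`.
#' @export
sort_profiles <- function(profiles) {
  main <- profiles[profiles$group == "balanced", , drop = FALSE]
  main <- main[order(-main$f_tss, main$experiment_id), , drop = FALSE]
  list(main = main,
       upstream = profiles[profiles$group == "upstream-biased", , drop = FALSE],
       downstream = profiles[profiles$group == "downstream-biased", , drop = FALSE])
}

#' Cross-species comparison of TSS-overlap fractions per factor
#'
#' For each factor present in both species (matched by case-insensitive
#' symbol equality), takes the median and the unscaled median absolute
#' deviation of `f_tss` across that factor's experiments within each species,
#' then reports the Pearson correlation of the per-factor medians and the
#' ordinary least-squares regression of the second species on the first.
#'
#' @param profiles_a,profiles_b Profile data frames (with `factor` column) for
#'   the two species, e.g. human and mouse.
#' @return A `SpeciesComparison`: list with `per_factor` data frame
#'   (`factor`, `f_tss_a`, `f_tss_b`, `mad_a`, `mad_b`), `pearson_r`, `slope`,
#'   `intercept`, `n_factors`.
#' @export
compare_species <- function(profiles_a, profiles_b) {
  norm_check <- function(p, lab) {
    key <- toupper(p$factor)
    amb <- tapply(p$factor, key, function(x) length(unique(x)) > 1L)
    if (any(amb))
      stop("factor name collisions after case-normalization in ", lab, ": ",
           paste(names(amb)[amb], collapse = ", "))
    key
  }
  ka <- norm_check(profiles_a, "first species")
  kb <- norm_check(profiles_b, "second species")
  shared <- intersect(unique(ka), unique(kb))
  if (length(shared) < 3L)
    stop("need >= 3 factors shared between species (found ", length(shared), ")")
  med_mad <- function(p, key, f) {
    x <- p$f_tss[key == f]
    c(med = stats::median(x), mad = stats::mad(x, constant = 1))
  }
  a <- t(vapply(shared, function(f) med_mad(profiles_a, ka, f), c(med = 0, mad = 0)))
  b <- t(vapply(shared, function(f) med_mad(profiles_b, kb, f), c(med = 0, mad = 0)))
  fit <- stats::lm(b[, "med"] ~ a[, "med"])
  structure(list(
    per_factor = data.frame(factor = shared,
                            f_tss_a = a[, "med"], f_tss_b = b[, "med"],
                            mad_a = a[, "mad"], mad_b = b[, "mad"],
                            row.names = NULL, stringsAsFactors = FALSE),
    pearson_r = stats::cor(a[, "med"], b[, "med"]),
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    n_factors = length(shared)),
    class = "SpeciesComparison")
}

#' @export
print.SpeciesComparison <- function(x, ...) {
  cat("SpeciesComparison over", x$n_factors, "shared factors: r =",
      format(x$pearson_r, digits = 3), "; slope =",
      format(x$slope, digits = 3), "\n")
  invisible(x)
}

#' Scatter plot of the cross-species comparison
#'
#' Per-factor medians with MAD ranges as grey crosses, the least-squares line
#' in blue, and the identity line dotted red.
#'
#' @param sc A `SpeciesComparison`.
#' @param filename Optional png output path.
#' @param xlab,ylab Axis labels.
#' @return `NULL`, invisibly.
#' @export
plot_species_comparison <- function(sc, filename = NULL,
                                    xlab = "fraction of peaks at TSS, species A",
                                    ylab = "fraction of peaks at TSS, species B") {
  if (!is.null(filename)) grDevices::png(filename, 700, 700)
  pf <- sc$per_factor
  graphics::plot(pf$f_tss_a, pf$f_tss_b, xlim = c(0, 1), ylim = c(0, 1),
                 pch = 19, xlab = xlab, ylab = ylab,
                 main = sprintf("cor = %.2f", sc$pearson_r))
  graphics::segments(pf$f_tss_a - pf$mad_a, pf$f_tss_b,
                     pf$f_tss_a + pf$mad_a, pf$f_tss_b, col = "grey")
  graphics::segments(pf$f_tss_a, pf$f_tss_b - pf$mad_b,
                     pf$f_tss_a, pf$f_tss_b + pf$mad_b, col = "grey")
  graphics::abline(sc$intercept, sc$slope, col = "blue")
  graphics::abline(0, 1, col = "red", lty = 3)
  if (!is.null(filename)) grDevices::dev.off()
  invisible(NULL)
}

#' Write profiles as TSV
#'
#' @param profiles Profile data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  cols <- intersect(c("experiment_id", "factor", "cell_type", "species",
                      "n_peaks", "f_up", "f_tss", "f_down", "group"),
                    names(profiles))
  utils::write.table(profiles[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
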