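# Readers and writers for every on-disk artifact the pipeline touches.
# All coordinates inside the package are 0-based half-open; readers convert
# on entry, writers on exit.

# Fixed alias table for chromosome-name normalization.
.CHROM_ALIASES <- c(MT = "chrM", mt = "chrM", M = "chrM")

#' Normalize chromosome names
#'
#' Adds a leading `"chr"` where absent (`"1"` becomes `"chr1"`) and maps
#' mitochondrial aliases (`"MT"` to `"chrM"`) through a fixed table. Case of
#' the remainder of the name is preserved.
#'
#' @param x Character vector of chromosome names.
#' @return Character vector of normalized names.
#' @export
normalize_chrom <- function(x) {
  x <- as.character(x)
  hit <- x %in% names(.CHROM_ALIASES)
  x[hit] <- .CHROM_ALIASES[x[hit]]
  no_chr <- !startsWith(x, "chr")
  x[no_chr] <- paste0("chr", x[no_chr])
  x
}

.sort_intervals <- function(df) {
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Validate a set of genomic intervals
#'
#' Checks the interval invariants: integer coordinates, `0 <= start < end`.
#'
#' @param df Data frame with columns `chrom`, `start`, `end`.
#' @param what Label used in error messages.
#' @return `df`, invisibly, with coordinates as integers.
#' @export
validate_intervals <- function(df, what = "intervals") {
  stopifnot(is.data.frame(df), all(c("chrom", "start", "end") %in% names(df)))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (anyNA(df$start) || anyNA(df$end))
    stop(what, ": non-integer coordinates")
  if (any(df$start < 0L))
    stop(what, ": negative start coordinate")
  if (any(df$start >= df$end))
    stop(what, ": intervals must satisfy start < end (zero-length or inverted interval)")
  invisible(df)
}

#' Read a BED file of peaks
#'
#' Accepts BED3 or wider, tab-separated, with optional `track`/`browser`/`#`
#' header lines. Coordinates in BED are already 0-based half-open and are kept
#' as such. Zero-length intervals (`start == end`) are rejected: peaks are
#' non-empty regions. Columns beyond the third are preserved as opaque
#' annotation columns.
#'
#' @param path Path to a BED file.
#' @return Data frame with columns `chrom` (normalized), `start`, `end`
#'   (integer, 0-based half-open), plus any extra BED columns, sorted by
#'   (chrom, start, end). An empty file yields a zero-row data frame.
#' @export
read_peaks_bed <- function(path) {
  if (!file.exists(path)) stop("peak file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !(grepl("^(track|browser)\\b", lines) | startsWith(lines, "#") |
              lines == "")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L))
    stop("malformed BED line ", lineno[which(nf < 3L)[1L]], " in ", path,
         ": fewer than 3 fields")
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed BED line ", lineno[bad[1L]], " in ", path,
         ": non-integer coordinates")
  bad <- which(start >= end | start < 0L)
  if (length(bad))
    stop("malformed BED line ", lineno[bad[1L]], " in ", path,
         ": requires 0 <= start < end")
  df <- data.frame(chrom = normalize_chrom(chrom), start = start, end = end,
                   stringsAsFactors = FALSE)
  for (j in seq_len(max(nf) - 3L)) {
    df[[paste0("X", j + 3L)]] <-
      vapply(parts, function(p) if (length(p) >= j + 3L) p[[j + 3L]] else NA_character_, "")
  }
  .sort_intervals(df)
}

#' Write intervals as BED
#'
#' Inverse of [read_peaks_bed()]: writes tab-separated BED with the package's
#' 0-based half-open coordinates untouched, so read/write round-trips are
#' bit-exact on coordinates.
#'
#' @param df Interval data frame (columns `chrom`, `start`, `end`, plus any
#'   extra columns written verbatim after the first three).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  df <- validate_intervals(df, "write_bed")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an experiment manifest
#'
#' The manifest is a TSV with header and columns `experiment_id`, `factor`,
#' `cell_type`, `species`, `peak_path`. Relative `peak_path` entries are
#' resolved against the manifest's directory.
#'
#' @param path Path to the manifest TSV.
#' @param check_paths Verify that every `peak_path` exists (default `TRUE`).
#' @return Data frame of manifest rows.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("experiment_id", "factor", "cell_type", "species", "peak_path")
  miss <- setdiff(req, names(m))
  if (length(miss)) stop("manifest is missing columns: ", paste(miss, collapse = ", "))
  validate_manifest(m)
  rel <- !grepl("^(/|[A-Za-z]:)", m$peak_path)
  m$peak_path[rel] <- file.path(dirname(path), m$peak_path[rel])
  if (check_paths) {
    gone <- !file.exists(m$peak_path)
    if (any(gone)) stop("peak files not found: ",
                        paste(m$peak_path[gone], collapse = ", "))
  }
  m
}

#' Validate manifest invariants
#'
#' @param m Manifest data frame.
#' @return `m`, invisibly.
#' @export
validate_manifest <- function(m) {
  if (anyDuplicated(m$experiment_id))
    stop("duplicate experiment_id in manifest: ",
         paste(unique(m$experiment_id[duplicated(m$experiment_id)]), collapse = ", "))
  if (any(!nzchar(m$factor)) || any(!nzchar(m$cell_type)))
    stop("manifest factor and cell_type must be non-empty")
  invisible(m)
}

#' Derive one TSS per gene from transcript records
#'
#' Each gene gets a single transcription start site at the median of its
#' transcripts' start positions; for an even transcript count the lower of the
#' two middle values is used, so the reported TSS always lies on an observed
#' transcript start. For minus-strand transcripts the start site is the 3'-most
#' covered base (`end - 1` in half-open coordinates). Input may instead carry a
#' precomputed `pos` column (one row per transcript TSS).
#'
#' @param tx Data frame with columns `gene_id`, `chrom`, `strand` and either
#'   `pos` (0-based transcript TSS) or `start`/`end` (0-based half-open
#'   transcript extents).
#' @return TSS table: data frame `gene_id`, `chrom`, `pos`, `strand`, one row
#'   per gene, sorted by (chrom, pos).
#' @export
derive_tss_table <- function(tx) {
  stopifnot(all(c("gene_id", "chrom", "strand") %in% names(tx)))
  if (!all(tx$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (!"pos" %in% names(tx)) {
    tx <- validate_intervals(tx, "transcripts")
    tx$pos <- ifelse(tx$strand == "+", tx$start, tx$end - 1L)
  }
  tx$pos <- as.integer(tx$pos)
  if (any(tx$pos < 0L)) stop("TSS position must be >= 0")
  bad <- tapply(tx$strand, tx$gene_id, function(s) length(unique(s)) > 1L)
  if (any(bad))
    stop("genes with transcripts on both strands: ",
         paste(names(bad)[bad], collapse = ", "))
  bad <- tapply(tx$chrom, tx$gene_id, function(s) length(unique(s)) > 1L)
  if (any(bad))
    stop("genes with transcripts on several chromosomes: ",
         paste(names(bad)[bad], collapse = ", "))
  lower_median <- function(x) sort(x)[(length(x) + 1L) %/% 2L]
  agg <- do.call(rbind, lapply(split(tx, tx$gene_id), function(g) {
    data.frame(gene_id = g$gene_id[1L], chrom = normalize_chrom(g$chrom[1L]),
               pos = lower_median(g$pos), strand = g$strand[1L],
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg[order(agg$chrom, agg$pos, agg$gene_id), , drop = FALSE]
}

#' Read a TSS table from 6-column BED
#'
#' Dialect: `chrom  pos  pos+1  gene_id  score  strand`.
#'
#' @param path Path to the BED file.
#' @return TSS table (`gene_id`, `chrom`, `pos`, `strand`).
#' @export
read_tss_bed <- function(path) {
  b <- read_peaks_bed(path)
  if (ncol(b) < 6L) stop("TSS BED needs 6 columns (name = gene_id, strand in column 6)")
  tss <- data.frame(gene_id = b[[4L]], chrom = b$chrom, pos = b$start,
                    strand = b[[6L]], stringsAsFactors = FALSE)
  if (!all(tss$strand %in% c("+", "-"))) stop("TSS BED column 6 must be '+' or '-'")
  if (anyDuplicated(tss$gene_id)) stop("duplicate gene_id in TSS BED")
  tss[order(tss$chrom, tss$pos, tss$gene_id), , drop = FALSE]
}

#' Write a TSS table as 6-column BED
#'
#' @param tss TSS table as returned by [derive_tss_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tss_bed <- function(tss, path) {
  df <- data.frame(chrom = tss$chrom, start = tss$pos, end = tss$pos + 1L,
                   name = tss$gene_id, score = 0L, strand = tss$strand)
  write_bed(df, path)
}

#' Read a GWAS-catalog-style hit table
#'
#' Expects a tab-separated table with header containing the columns `CHR_ID`,
#' `CHR_POS` and `DISEASE/TRAIT` (GWAS-catalog dialect, 1-based positions).
#' Positions are converted to 0-based points. Rows with a missing or
#' non-numeric position, or with a multi-mapping chromosome field (several
#' chromosomes separated by `;` or `x`), are dropped; the drop count is
#' attached as attribute `n_dropped` and logged.
#'
#' @param path Path to the table.
#' @param p_threshold Optional upper bound applied to a `P-VALUE` column when
#'   present (the "high-confidence" filter is left to configuration).
#' @return Data frame `chrom`, `pos` (0-based), `trait`, with attribute
#'   `n_dropped`.
#' @export
read_gwas_catalog <- function(path, p_threshold = NULL) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("CHR_ID", "CHR_POS", "DISEASE/TRAIT")
  miss <- setdiff(req, names(g))
  if (length(miss)) stop("GWAS table is missing columns: ",
                         paste(miss, collapse = ", "))
  n0 <- nrow(g)
  pos <- suppressWarnings(as.numeric(g$CHR_POS))
  multi <- grepl("[;x]", g$CHR_ID) | grepl("[;x]", as.character(g$CHR_POS))
  keep <- !is.na(pos) & !multi & nzchar(as.character(g$CHR_ID))
  if (!is.null(p_threshold) && "P-VALUE" %in% names(g)) {
    pv <- suppressWarnings(as.numeric(g[["P-VALUE"]]))
    keep <- keep & !is.na(pv) & pv <= p_threshold
  }
  g <- g[keep, , drop = FALSE]
  out <- data.frame(chrom = normalize_chrom(g$CHR_ID),
                    pos = as.integer(pos[keep] - 1),
                    trait = g[["DISEASE/TRAIT"]],
                    stringsAsFactors = FALSE)
  if (any(out$pos < 0L)) stop("GWAS position below 1 in 1-based input")
  n_dropped <- n0 - nrow(out)
  if (n_dropped > 0L)
    message("read_gwas_catalog: dropped ", n_dropped, " of ", n0, " rows")
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write GWAS hits in catalog dialect
#'
#' Inverse of [read_gwas_catalog()]: writes `CHR_ID` (without the `chr`
#' prefix), 1-based `CHR_POS`, and `DISEASE/TRAIT`.
#'
#' @param hits Data frame `chrom`, `pos` (0-based), `trait`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gwas_catalog <- function(hits, path) {
  out <- data.frame(CHR_ID = sub("^chr", "", hits$chrom),
                    CHR_POS = hits$pos + 1L,
                    check.names = FALSE, stringsAsFactors = FALSE)
  out[["DISEASE/TRAIT"]] <- hits$trait
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a manifest TSV
#'
#' @param m Manifest data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(m, path) {
  validate_manifest(m)
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
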