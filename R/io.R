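# On-disk formats: BED6+2 peaks, counts TSV with a sample-name grammar,
# library TSV, truth TSV, bedGraph tracks, and the flat pipeline config.

#' Read a BED6+2 peak file
#'
#' Expected columns: chrom, start, end, name, score (-log10 FDR), strand,
#' summit (absolute, 0-based), cell_line. Coordinates are 0-based half-open
#' on disk and converted to 1-based closed \link[GenomicRanges]{GRanges}.
#' Malformed lines are reported with their line numbers.
#'
#' @param path file path.
#' @return a \link[GenomicRanges]{GRanges} with metadata columns
#'   \code{name}, \code{fdr}, \code{summit} (1-based absolute),
#'   \code{cell_line}.
#' @export
readBedPeaks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  ln <- which(keep)
  if (!length(ln)) stop("no records in ", path)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 8)
  if (length(bad))
    stop("line ", ln[bad[1]], ": expected 8 tab-separated fields")
  m <- do.call(rbind, fields)
  start0 <- as.numeric(m[, 2]); end0 <- as.numeric(m[, 3])
  score <- as.numeric(m[, 5]); summit0 <- as.numeric(m[, 7])
  bad <- which(is.na(start0) | is.na(end0) | is.na(score) | is.na(summit0))
  if (length(bad)) stop("line ", ln[bad[1]], ": non-numeric coordinate or score")
  bad <- which(end0 <= start0)
  if (length(bad))
    stop("line ", ln[bad[1]], ": end <= start (", m[bad[1], 2], " >= ", m[bad[1], 3], ")")
  bad <- which(summit0 < start0 | summit0 >= end0)
  if (length(bad)) stop("line ", ln[bad[1]], ": summit outside interval")
  strand <- m[, 6]
  strand[strand == "."] <- "*"
  GenomicRanges::GRanges(m[, 1], IRanges::IRanges(start0 + 1, end0),
    strand = strand, name = m[, 4], fdr = 10^(-score),
    summit = as.integer(summit0 + 1), cell_line = m[, 8])
}

#' Write peaks as BED6+2
#'
#' Inverse of \code{\link{readBedPeaks}}: 0-based half-open coordinates,
#' score = -log10(FDR), absolute 0-based summit, cell line.
#'
#' @param peaks a \link[GenomicRanges]{GRanges} with \code{name},
#'   \code{fdr}, \code{summit}, \code{cell_line} metadata.
#' @param path output path.
#' @export
writeBedPeaks <- function(peaks, path) {
  strand <- as.character(GenomicRanges::strand(peaks))
  strand[strand == "*"] <- "."
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s\t%d\t%s",
    as.character(GenomicRanges::seqnames(peaks)),
    GenomicRanges::start(peaks) - 1L, GenomicRanges::end(peaks),
    peaks$name, format(-log10(peaks$fdr), digits = 10, trim = TRUE),
    strand, peaks$summit - 1L, peaks$cell_line)
  writeLines(lines, path)
  invisible(path)
}

.sampleNameRe <- "^(.+)_rep([0-9]+)_day([0-9]+)$"

#' Write a screen count matrix as TSV
#'
#' One \code{guide_id} column followed by one column per sample, named
#' \code{<cellline>_rep<int>_day<int>} so the metadata round-trips through
#' the header.
#'
#' @param se a \linkS4class{ScreenExperiment}.
#' @param path output path.
#' @export
writeCountsTSV <- function(se, path) {
  counts <- SummarizedExperiment::assay(se)
  df <- data.frame(guide_id = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a screen count matrix from TSV
#'
#' Parses sample metadata (cell line, replicate, day) from the column-name
#' grammar \code{<cellline>_rep<int>_day<int>}.
#'
#' @param path file path.
#' @param lineages optional named map cell line -> lineage.
#' @return a \linkS4class{ScreenExperiment}.
#' @export
readCountsTSV <- function(path, lineages = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(df)[1] != "guide_id") stop("first column must be guide_id")
  cn <- colnames(df)[-1]
  ok <- grepl(.sampleNameRe, cn)
  if (!all(ok))
    stop("sample column(s) not matching <cellline>_rep<int>_day<int>: ",
         paste(cn[!ok], collapse = ", "))
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$guide_id
  cl <- sub(.sampleNameRe, "\\1", cn)
  rep <- as.integer(sub(.sampleNameRe, "\\2", cn))
  day <- as.integer(sub(.sampleNameRe, "\\3", cn))
  lin <- if (!is.null(lineages)) unname(lineages[cl]) else NULL
  ScreenExperiment(counts, cellLine = cl, replicate = rep, day = day,
                   lineage = lin)
}

#' Write / read a designed library as TSV
#'
#' @param library a \linkS4class{GuideLibrary}.
#' @param path file path.
#' @export
writeGuideLibrary <- function(library, path) {
  write.table(as.data.frame(guideInfo(library)), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGuideLibrary
#' @export
readGuideLibrary <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  for (col in c("protospacer", "strand", "chrom", "union_id", "control_class"))
    if (col %in% colnames(df)) df[[col]][df[[col]] == "NA"] <- NA
  GuideLibrary(df)
}

#' Write / read a bedGraph signal track
#'
#' 0-based half-open intervals with a numeric score, via rtracklayer.
#'
#' @param track a \link[GenomicRanges]{GRanges} with a \code{score} column.
#' @param path file path.
#' @export
writeBedGraph <- function(track, path) {
  rtracklayer::export.bedGraph(track, path)
  invisible(path)
}

#' @rdname writeBedGraph
#' @export
readBedGraph <- function(path) {
  rtracklayer::import.bedGraph(path)
}

.pipelineDefaults <- function() list(
  out_dir = "pipeline_out",
  do_simulate = TRUE, do_design = TRUE, do_analyze = TRUE, do_signal = TRUE,
  seed = 7, n_regions = 500, guides_per_region = 10,
  replicates = 2, timepoints = c(0, 8, 15, 22),
  depth = 1000, dispersion = 0.05, depth_sd = 0.1, share_day0 = TRUE,
  frac_common = 0.2, frac_lineage = 0.15,
  knee_neglogfdr = 50, sig_fraction = 0.25, shared_fraction = 0.6,
  n_nt = 496, n_pl = 1030, n_hs = 419, n_yt = 605,
  window = 300, min_gap = 20, knots = 20, df = 15,
  pool_cutoff_hi = 50, pool_cutoff_lo = 20,
  norm_target = 1000, alpha_p = 0.05, lfc_thresh = 1, fdr_thresh = 0.05,
  half_window = 2000, n_bins = 100, hi_pct = 98, lo_pct = 1, k = 2,
  counts_path = "", library_path = "")

#' Create a pipeline configuration
#'
#' All tunables of the simulate / design / analyze / signal stages as a
#' validated flat configuration. Unknown keys are rejected.
#'
#' @param ... configuration keys overriding the defaults (see
#'   \code{pipelineConfig()} for the full set).
#' @return a named list of class \code{"PipelineConfig"}.
#' @examples
#' cfg <- pipelineConfig(n_regions = 100, seed = 3)
#' @export
pipelineConfig <- function(...) {
  cfg <- .pipelineDefaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "PipelineConfig")
}

#' Write / read a pipeline configuration
#'
#' Flat \code{key = value} text representation; vectors are
#' comma-separated; round-trips losslessly. Unknown keys are rejected on
#' read.
#'
#' @param cfg a configuration from \code{\link{pipelineConfig}}.
#' @param path file path.
#' @export
writePipelineConfig <- function(cfg, path) {
  fmt <- vapply(cfg, function(v) {
    if (is.numeric(v)) paste(format(v, digits = 17, trim = TRUE, scientific = FALSE),
                             collapse = ",")
    else if (is.logical(v)) paste(v, collapse = ",")
    else paste(v, collapse = ",")
  }, character(1))
  writeLines(paste0(names(cfg), " = ", fmt), path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  kv <- regmatches(lines, regexec("^([a-z0-9_]+) *= *(.*)$", lines))
  bad <- which(lengths(kv) != 3)
  if (length(bad)) stop("malformed config line ", bad[1], ": ", lines[bad[1]])
  keys <- vapply(kv, `[`, character(1), 2)
  vals <- vapply(kv, `[`, character(1), 3)
  defaults <- .pipelineDefaults()
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- defaults
  for (i in seq_along(keys)) {
    ref <- defaults[[keys[i]]]
    parts <- strsplit(vals[i], ",", fixed = TRUE)[[1]]
    cfg[[keys[i]]] <-
      if (is.numeric(ref)) as.numeric(parts)
      else if (is.logical(ref)) as.logical(parts)
      else if (!length(parts)) "" else parts
  }
  structure(cfg, class = "PipelineConfig")
}
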