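# End-to-end orchestration: simulate -> design -> analyze -> signal.

.cfgToSim <- function(cfg) {
  screenSimConfig(
    nRegions = cfg$n_regions, guidesPerRegion = cfg$guides_per_region,
    replicates = cfg$replicates, timepoints = cfg$timepoints,
    depth = cfg$depth, dispersion = cfg$dispersion, depthSd = cfg$depth_sd,
    shareDay0 = cfg$share_day0, fracCommon = cfg$frac_common,
    fracLineage = cfg$frac_lineage, nNT = cfg$n_nt, nPL = cfg$n_pl,
    nHS = cfg$n_hs, nYT = cfg$n_yt, kneeNeglogFdr = cfg$knee_neglogfdr,
    sigFraction = cfg$sig_fraction, sharedFraction = cfg$shared_fraction,
    seed = cfg$seed)
}

.randomProtospacers <- function(n, seed) {
  set.seed(seed)
  ps <- character(0)
  while (length(ps) < n) {
    cand <- vapply(seq_len(n - length(ps) + 16), function(i)
      paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = ""),
      character(1))
    cand <- cand[!grepl("GAAGAC|GTCTTC", cand)]
    ps <- unique(c(ps, cand))
  }
  ps[seq_len(n)]
}

# Synthetic per-base occupancy tracks around consensus summits: triangular
# bumps whose height depends on a region-level profile, one bedGraph-style
# GRanges per mark. Gives the signal stage realistic structure (two region
# classes with distinct mark profiles).
.makeSignalTracks <- function(consensus, seed, halfWindow = 2000) {
  set.seed(seed)
  n <- length(consensus)
  promoterLike <- runif(n) < 0.5
  marks <- list(
    rpb1   = ifelse(promoterLike, 8, 1),
    h3k4me3 = ifelse(promoterLike, 10, 0.5),
    h3k4me1 = ifelse(promoterLike, 1.5, 9))
  bumpw <- 500L
  lapply(marks, function(height) {
    h <- height * runif(n, 0.7, 1.3)
    starts <- consensus$summit - bumpw
    GenomicRanges::GRanges(GenomicRanges::seqnames(consensus),
      IRanges::IRanges(pmax(1L, starts), consensus$summit + bumpw),
      score = h)
  })
}

#' Run the full synthetic tiling-screen pipeline
#'
#' Executes the enabled stages in order simulate -> design -> analyze ->
#' signal, writing every output file under \code{cfg$out_dir} and returning
#' a manifest of files with content hashes. All randomness flows from
#' \code{cfg$seed}; two runs with equal configurations produce identical
#' files.
#'
#' @param cfg a \code{\link{pipelineConfig}}.
#' @param quiet suppress stage logging.
#' @return (invisibly) a list with the manifest data.frame and the in-memory
#'   stage results.
#' @export
runPipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- function(...) if (!quiet) message("[pipeline] ", ...)
  files <- character(0)
  res <- list()
  sim <- .cfgToSim(cfg)

  peaks <- NULL; consensus <- NULL; library <- NULL
  if (cfg$do_simulate) {
    log("simulate: ", sim@nRegions, " regions, seed ", sim@seed)
    peaks <- simulatePeaks(sim)
    for (cl in names(peaks)) {
      f <- file.path(cfg$out_dir, paste0("peaks_", cl, ".bed"))
      writeBedPeaks(peaks[[cl]], f)
      files <- c(files, f)
    }
    res$peaks <- peaks
  }

  if (cfg$do_design) {
    if (is.null(peaks)) stop("design stage needs simulated peaks (enable do_simulate)")
    cutoffs <- vapply(peaks, function(g)
      selectPeakCutoff(g$fdr, knots = cfg$knots, df = cfg$df), numeric(1))
    log("design: per-cell-line cutoffs ",
        paste(sprintf("%s=%.1f", names(cutoffs), cutoffs), collapse = ", "))
    retained <- lapply(names(peaks), function(cl) {
      g <- peaks[[cl]]
      g[-log10(g$fdr) > cutoffs[cl]]
    })
    names(retained) <- names(peaks)
    consensus <- unionPeaks(retained)
    log("design: ", length(consensus), " consensus regions after union")
    win <- cfg$window
    seqlen <- as.integer(2 * win + 200)
    seqs <- simulateSequences(length(consensus), seqlen, seed = cfg$seed + 3,
                              minPAM = cfg$guides_per_region, window = win)
    cands <- list()
    for (i in seq_along(consensus)) {
      seqStart <- consensus$summit[i] - seqlen %/% 2 + 1L
      cand <- enumerateCandidates(as.character(seqs[[i]]),
        summit = consensus$summit[i], window = win, seqStart = seqStart)
      cands[[consensus$union_id[i]]] <- filterCandidates(cand, minGap = cfg$min_gap)
    }
    controls <- list(
      NT = .randomProtospacers(cfg$n_nt, cfg$seed + 4),
      PL = .randomProtospacers(cfg$n_pl, cfg$seed + 5),
      HS = .randomProtospacers(cfg$n_hs, cfg$seed + 6),
      YT = .randomProtospacers(cfg$n_yt, cfg$seed + 7))
    library <- assembleLibrary(consensus, cands,
      poolCutoffs = c(cfg$pool_cutoff_hi, cfg$pool_cutoff_lo),
      controls = controls)
    log("design: library of ", nGuides(library), " guides")
    f <- file.path(cfg$out_dir, "library.tsv")
    writeGuideLibrary(library, f); files <- c(files, f)
    f <- file.path(cfg$out_dir, "oligos.fasta")
    Biostrings::writeXStringSet(emitOligos(library), f); files <- c(files, f)
    res$consensus <- consensus; res$library <- library
  }

  if (cfg$do_analyze) {
    if (is.null(library)) {
      if (!nzchar(cfg$library_path) || !nzchar(cfg$counts_path))
        stop("analyze stage needs a library and counts ",
             "(enable do_design/do_simulate or set library_path/counts_path)")
      library <- readGuideLibrary(cfg$library_path)
      se <- readCountsTSV(cfg$counts_path)
      truth <- NULL
    } else {
      screen <- simulateScreen(library, sim)
      se <- screen$se; truth <- screen$truth
      f <- file.path(cfg$out_dir, "counts.tsv")
      writeCountsTSV(se, f); files <- c(files, f)
      f <- file.path(cfg$out_dir, "truth.tsv")
      write.table(truth, f, sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, f)
    }
    log("analyze: ", nrow(se), " guides x ", ncol(se), " samples")
    e <- guideInfo(library)
    nt <- e$guide_id[!is.na(e$control_class) & e$control_class == "NT"]
    norm <- normalizeToControls(se, nt, target = cfg$norm_target)
    fitness <- fitFitnessAll(norm, library)
    f <- file.path(cfg$out_dir, "fitness.tsv")
    write.table(fitness, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
    lineages <- setNames(sim@lineages, sim@cellLines)
    hits <- callHitsSecondary(fitness, lineages, alphaP = cfg$alpha_p)
    f <- file.path(cfg$out_dir, "hits.tsv")
    write.table(hits, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
    reps <- guideLFC(norm, perReplicate = TRUE)
    lastDay <- max(reps$day)
    primA <- sim@cellLines[1]; primB <- sim@cellLines[3]
    diffTab <- differentialLineage(
      reps[reps$cell_line == primA & reps$day == lastDay, ],
      reps[reps$cell_line == primB & reps$day == lastDay, ],
      lfcThresh = cfg$lfc_thresh, fdrThresh = cfg$fdr_thresh)
    f <- file.path(cfg$out_dir, "differential.tsv")
    write.table(diffTab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
    if (!is.null(consensus)) {
      for (cl in unique(fitness$cell_line)) {
        sub <- fitness[fitness$cell_line == cl, ]
        idx <- match(sub$union_id, consensus$union_id)
        gr <- consensus[idx[!is.na(idx)]]
        gr$score <- -log10(pmax(sub$p[!is.na(idx)], 1e-300))
        S4Vectors::mcols(gr) <- S4Vectors::mcols(gr)[, "score", drop = FALSE]
        f <- file.path(cfg$out_dir, paste0("fitness_neglogp_", cl, ".bedGraph"))
        writeBedGraph(GenomicRanges::sort(gr), f); files <- c(files, f)
      }
    }
    res$se <- se; res$truth <- truth; res$fitness <- fitness
    res$hits <- hits; res$differential <- diffTab
  }

  if (cfg$do_signal) {
    if (is.null(consensus)) stop("signal stage needs consensus regions (enable do_design)")
    log("signal: binned occupancy over ", length(consensus), " regions")
    tracks <- .makeSignalTracks(consensus, seed = cfg$seed + 8,
                                halfWindow = cfg$half_window)
    summits <- GenomicRanges::GRanges(GenomicRanges::seqnames(consensus),
      IRanges::IRanges(consensus$summit, width = 1))
    names(summits) <- consensus$union_id
    mats <- lapply(tracks, function(tr)
      clipScale(binSignal(tr, summits, halfWindow = cfg$half_window,
                          nBins = cfg$n_bins),
                hiPct = cfg$hi_pct, loPct = cfg$lo_pct))
    clus <- clusterRegions(mats, k = cfg$k, seed = cfg$seed + 9)
    ord <- match(clus$region, signalRegions(mats[[1]]))
    mat <- cbind(clus[, c("region", "cluster")],
                 as.data.frame(signalValues(mats[[1]])[ord, , drop = FALSE]))
    colnames(mat) <- c("region", "cluster",
                       sprintf("bin_%04d", seq_len(cfg$n_bins)))
    f <- file.path(cfg$out_dir, "signal_matrix.tsv")
    write.table(mat, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
    covT <- coverageAt(summits, tracks, halfwidth = 250)
    cc <- logRankCorrelation(covT)
    f <- file.path(cfg$out_dir, "signal_correlation.tsv")
    write.table(data.frame(track = rownames(cc), cc), f, sep = "\t",
                quote = FALSE, row.names = FALSE)
    files <- c(files, f)
    res$signal <- mats; res$clusters <- clus; res$correlation <- cc
  }

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  f <- file.path(cfg$out_dir, "manifest.tsv")
  write.table(manifest, f, sep = "\t", quote = FALSE, row.names = FALSE)
  log("done: ", nrow(manifest), " output files")
  res$manifest <- manifest
  invisible(res)
}
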