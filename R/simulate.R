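# Synthetic-data generators: peak sets, sequences, screen count matrices
# and the ground-truth tables used by the recovery tests.

#' Simulate per-cell-line peak sets
#'
#' Generates one peak set per cell line over a synthetic chromosome. The
#' -log10(FDR) of each region is drawn from a two-component Gaussian mixture:
#' a low-significance background (mean \code{bgMean}, sd \code{bgSd}) and a
#' high-significance component centered at \code{kneeNeglogFdr} (sd
#' \code{sigSd}, mixing weight \code{sigFraction}), so that the ECDF of the
#' pooled values has a knee at \code{kneeNeglogFdr}. A \code{sharedFraction}
#' of regions is present with identical intervals in every cell line; the
#' remainder appear in a random non-empty subset of cell lines.
#'
#' @param config a \linkS4class{ScreenSimConfig}.
#' @return a named list of \link[GenomicRanges]{GRanges}, one per cell line,
#'   with metadata columns \code{name}, \code{fdr}, \code{summit} (absolute,
#'   1-based) and \code{cell_line}.
#' @examples
#' peaks <- simulatePeaks(screenSimConfig(nRegions = 20, seed = 1))
#' peaks[[1]]
#' @export
simulatePeaks <- function(config) {
  stopifnot(is(config, "ScreenSimConfig"))
  n <- config@nRegions
  if (n < 10) stop("nRegions must be >= 10")
  set.seed(config@seed)
  width <- round(runif(n, 600, 1200))
  gap <- 3000
  # leading margin so summit-centered windows never underflow the chromosome
  start <- 4000 + cumsum(c(1, width[-n] + gap))
  end <- start + width - 1
  sig <- runif(n) < config@sigFraction
  nShared <- round(config@sharedFraction * n)
  cls <- config@cellLines
  membership <- matrix(TRUE, n, length(cls), dimnames = list(NULL, cls))
  if (nShared < n) {
    for (i in seq(nShared + 1, n)) {
      keep <- runif(length(cls)) < 0.5
      if (!any(keep)) keep[sample.int(length(cls), 1)] <- TRUE
      membership[i, ] <- keep
    }
  }
  out <- lapply(cls, function(cl) {
    idx <- which(membership[, cl])
    nl <- ifelse(sig[idx],
                 rnorm(length(idx), config@kneeNeglogFdr, config@sigSd),
                 rnorm(length(idx), config@bgMean, config@bgSd))
    nl <- pmax(nl, 0.01)
    summit <- start[idx] + floor(runif(length(idx)) * width[idx])
    gr <- GenomicRanges::GRanges("chrS",
      IRanges::IRanges(start[idx], end[idx]),
      name = sprintf("region_%05d", idx),
      fdr = 10^(-nl), summit = summit, cell_line = cl)
    gr
  })
  names(out) <- cls
  out
}

#' Simulate genome-like locus sequences with guaranteed PAM density
#'
#' Generates uppercase ACGT sequences by i.i.d. sampling at a given GC
#' fraction, rejection-sampling each locus until at least \code{minPAM}
#' NGG protospacer-adjacent motifs (on either strand) fall within
#' \code{window} bp of the locus midpoint.
#'
#' @param nLoci number of sequences.
#' @param length sequence length in bp; must be >= 700 so a +/-300 bp design
#'   window fits around the midpoint.
#' @param seed integer seed.
#' @param gc GC fraction in (0, 1); with no G or C no PAM can exist and the
#'   generation fails.
#' @param minPAM minimum number of PAM occurrences required near the midpoint.
#' @param window half-width (bp) of the midpoint window checked for PAMs.
#' @return a \link[Biostrings]{DNAStringSet} named \code{locus_1 ...}.
#' @examples
#' simulateSequences(2, 800, seed = 1)
#' @export
simulateSequences <- function(nLoci, length, seed = 1, gc = 0.41,
                              minPAM = 10, window = 300) {
  if (length < 700) stop("length must be >= 700 (must host a +/-300 bp window)")
  if (gc <= 0) stop("gc fraction must be positive: with no G/C no NGG PAM can occur")
  if (gc >= 1) stop("gc fraction must be < 1")
  set.seed(seed)
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  mid <- floor(length / 2)
  lo <- max(1, mid - window); hi <- min(length, mid + window)
  one <- function() {
    for (try in 1:200) {
      s <- paste(sample(names(prob), length, replace = TRUE, prob = prob),
                 collapse = "")
      sub <- substr(s, lo, hi)
      npam <- length(gregexpr("(?=GG)", sub, perl = TRUE)[[1]]) +
              length(gregexpr("(?=CC)", sub, perl = TRUE)[[1]])
      # gregexpr returns -1 (length 1) when there is no match
      if (npam >= minPAM + 2) return(s)
    }
    stop("could not generate a locus with enough PAM sites; raise gc or length")
  }
  seqs <- vapply(seq_len(nLoci), function(i) one(), character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- sprintf("locus_%d", seq_len(nLoci))
  out
}

#' Assign ground-truth fitness effects to a designed library
#'
#' Plants the true per-day fitness score alpha for every guide in every cell
#' line. Experimental regions are partitioned into common hits (negative
#' alpha in all models), single-lineage hits (negative alpha in the two
#' models of one lineage only) and neutral regions; all guides of a region
#' share its alpha. Non-targeting controls have alpha = 0 everywhere;
#' pan-lethal controls draw alpha from \code{alphaPanLethal} in every model;
#' pathway (HS) and target-gene (YT) controls draw from \code{alphaControl}.
#'
#' @param library a \linkS4class{GuideLibrary}.
#' @param config a \linkS4class{ScreenSimConfig}.
#' @return a data.frame with one row per guide: \code{guide_id},
#'   \code{union_id}, \code{control_class}, \code{category} (common /
#'   lineage-<name> / none) and one \code{alpha_<cellLine>} column per model.
#' @export
assignTruth <- function(library, config) {
  stopifnot(is(library, "GuideLibrary"), is(config, "ScreenSimConfig"))
  e <- as.data.frame(guideInfo(library))
  set.seed(config@seed + 1L)
  cls <- config@cellLines
  lins <- unique(config@lineages)
  regions <- unique(e$union_id[is.na(e$control_class)])
  nreg <- length(regions)
  cat_reg <- rep("none", nreg); names(cat_reg) <- regions
  if (nreg) {
    nC <- round(config@fracCommon * nreg)
    nL <- round(config@fracLineage * nreg)
    pick <- sample(regions)
    cat_reg[pick[seq_len(nC)]] <- "common"
    used <- nC
    for (ln in lins) {
      if (nL) cat_reg[pick[used + seq_len(nL)]] <- paste0("lineage-", ln)
      used <- used + nL
    }
  }
  alphaReg <- matrix(0, nreg, length(cls), dimnames = list(regions, cls))
  for (r in regions) {
    a <- runif(1, config@alphaHit[1], config@alphaHit[2])
    if (cat_reg[r] == "common") alphaReg[r, ] <- a
    else if (startsWith(cat_reg[r], "lineage-")) {
      ln <- sub("^lineage-", "", cat_reg[r])
      alphaReg[r, config@lineages == ln] <- a
    }
  }
  alpha <- matrix(0, nrow(e), length(cls),
                  dimnames = list(e$guide_id, cls))
  exper <- is.na(e$control_class)
  alpha[exper, ] <- alphaReg[e$union_id[exper], , drop = FALSE]
  isPL <- !is.na(e$control_class) & e$control_class == "PL"
  alpha[isPL, ] <- runif(sum(isPL), config@alphaPanLethal[1], config@alphaPanLethal[2])
  isCtl <- !is.na(e$control_class) & e$control_class %in% c("HS", "YT")
  alpha[isCtl, ] <- runif(sum(isCtl), config@alphaControl[1], config@alphaControl[2])
  out <- data.frame(guide_id = e$guide_id, union_id = e$union_id,
                    control_class = e$control_class,
                    category = ifelse(exper, cat_reg[e$union_id], "none"),
                    stringsAsFactors = FALSE)
  for (cl in cls) out[[paste0("alpha_", cl)]] <- alpha[, cl]
  out
}

#' Simulate a pooled CRISPRi dropout screen
#'
#' Draws guide counts from a negative-binomial model around exponential
#' dropout: the expected count of guide \eqn{g} in cell line \eqn{c} at day
#' \eqn{t} is \eqn{depth \cdot e^{\alpha_{gc} t} \cdot s} where \eqn{s} is a
#' per-sample depth factor (log-normal, sd \code{depthSd}; day-0 samples have
#' \eqn{s = 1}). The count variance is \eqn{\mu + \mu^2 \cdot dispersion}.
#' When \code{shareDay0} is TRUE the day-0 draw of each replicate represents
#' the library representation of one infected pool and is shared across cell
#' lines.
#'
#' @param library a \linkS4class{GuideLibrary}.
#' @param config a \linkS4class{ScreenSimConfig}.
#' @param truth optional truth table from \code{\link{assignTruth}}; generated
#'   from \code{config} if missing.
#' @return a list with elements \code{se} (a \linkS4class{ScreenExperiment})
#'   and \code{truth} (the truth data.frame).
#' @examples
#' lib <- GuideLibrary(data.frame(
#'   guide_id = paste0("g", 1:4), protospacer = strrep("ACGT", 5),
#'   strand = "+", chrom = "chrS", target_pos = 1:4 * 50,
#'   union_id = "R1", distance_to_summit = 0, pool = "pool1",
#'   control_class = NA))
#' sim <- simulateScreen(lib, screenSimConfig(nRegions = 10, seed = 2))
#' sim$se
#' @export
simulateScreen <- function(library, config, truth = NULL) {
  stopifnot(is(library, "GuideLibrary"), is(config, "ScreenSimConfig"))
  if (nGuides(library) == 0) stop("library is empty")
  if (is.null(truth)) truth <- assignTruth(library, config)
  e <- as.data.frame(guideInfo(library))
  acols <- paste0("alpha_", config@cellLines)
  if (!all(acols %in% colnames(truth)))
    stop("truth table lacks alpha columns for some cell lines")
  if (!all(e$guide_id %in% truth$guide_id))
    stop("missing truth alpha for some guides")
  truth <- truth[match(e$guide_id, truth$guide_id), ]
  if (any(is.na(truth[acols]))) stop("missing truth alpha for some guides")
  set.seed(config@seed + 2L)
  ng <- nrow(e); reps <- seq_len(config@replicates)
  tps <- config@timepoints; cls <- config@cellLines
  disp <- config@dispersion
  rcounts <- function(mu) {
    if (disp > 0) rnbinom(length(mu), mu = mu, size = 1 / disp) else rpois(length(mu), mu)
  }
  # day-0 library representation, one draw per replicate (per infection)
  day0 <- vapply(reps, function(r) rcounts(rep(config@depth, ng)), numeric(ng))
  cols <- list(); meta <- list()
  for (cl in cls) {
    lin <- config@lineages[match(cl, cls)]
    alpha <- truth[[paste0("alpha_", cl)]]
    d0cl <- if (config@shareDay0) day0 else
      vapply(reps, function(r) rcounts(rep(config@depth, ng)), numeric(ng))
    for (r in reps) {
      nm <- sprintf("%s_rep%d_day0", cl, r)
      cols[[nm]] <- d0cl[, r]
      meta[[nm]] <- list(cl, r, 0, lin)
    }
    for (t in tps[tps > 0]) {
      for (r in reps) {
        sf <- if (config@depthSd > 0) rlnorm(1, 0, config@depthSd) else 1
        mu <- config@depth * exp(alpha * t) * sf
        nm <- sprintf("%s_rep%d_day%d", cl, r, t)
        cols[[nm]] <- rcounts(mu)
        meta[[nm]] <- list(cl, r, t, lin)
      }
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- e$guide_id
  md <- do.call(rbind, lapply(meta, function(x)
    data.frame(cell_line = x[[1]], replicate = x[[2]], day = x[[3]],
               lineage = x[[4]], stringsAsFactors = FALSE)))
  se <- ScreenExperiment(counts, cellLine = md$cell_line,
                         replicate = md$replicate, day = md$day,
                         lineage = md$lineage)
  list(se = se, truth = truth)
}
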