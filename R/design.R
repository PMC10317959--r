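# Tiling library design: significance-cutoff selection on the peak FDR ECDF,
# peak union, candidate sgRNA enumeration and filtering, pool assembly,
# oligo emission, and validation-library design from primary-screen stats.

.BBSI <- c("GAAGAC", "GTCTTC")
.FLANK5 <- "GCCATCCAGAAGACTTACCG"
.FLANK3 <- "GTTTCCGTCTTCACGACTGC"

# Locate the knee of a smoothed curve: the highest +to- sign change of the
# second derivative whose preceding positive lobe carries non-negligible
# mass (relative to the largest lobe). d2 is F'' on an equispaced grid, so a
# +to- crossing is a mode of the underlying density and the lobe area is the
# density rise into that mode; the relative threshold discards tail wiggles
# of the spline.
.pickKnee <- function(grid, d2, relTol = 0.02) {
  h <- grid[2] - grid[1]
  s <- sign(d2)
  cross <- which(s[-1] * s[-length(s)] < 0)
  modes <- cross[d2[cross] > 0]
  if (!length(modes)) return(NA_real_)
  lobe <- vapply(modes, function(i) {
    j <- i
    while (j > 1 && d2[j - 1] > 0) j <- j - 1
    sum(d2[j:i]) * h
  }, numeric(1))
  keep <- modes[lobe >= relTol * max(lobe)]
  if (!length(keep)) return(NA_real_)
  i <- max(keep)
  grid[i] + h * abs(d2[i]) / (abs(d2[i]) + abs(d2[i + 1]))
}

#' Select a peak-significance cutoff from the knee of the FDR ECDF
#'
#' Computes the empirical cumulative distribution of -log10(FDR), fits a
#' cubic smoothing spline (knot count and effective degrees of freedom as
#' parameters), evaluates its second derivative on a dense grid and returns
#' the -log10(FDR) of the inflection point nearest the high-significance
#' tail. Peaks above the returned threshold are the "retained" peaks.
#'
#' The ECDF is evaluated on a uniform grid over the data range before spline
#' fitting, and an inflection is accepted only if the second-derivative lobe
#' preceding it carries at least \code{relTol} of the mass of the largest
#' lobe; this discards spurious sign changes from spline wiggle in the
#' sparse upper tail.
#'
#' @param fdr peak FDR values in (0, 1]; at least 100 are required.
#' @param knots number of spline knots.
#' @param df effective degrees of freedom of the smoothing spline.
#' @param nGrid size of the dense evaluation grid.
#' @param relTol relative mass threshold for accepting an inflection.
#' @return the cutoff on the -log10(FDR) scale.
#' @examples
#' set.seed(1)
#' nl <- c(rnorm(4500, 10, 3), rnorm(500, 60, 5))
#' selectPeakCutoff(10^-pmax(nl, 0.01))
#' @export
selectPeakCutoff <- function(fdr, knots = 20, df = 15, nGrid = 2001,
                             relTol = 0.02) {
  if (length(fdr) < 100) stop("need at least 100 FDR values")
  if (any(fdr <= 0 | fdr > 1)) stop("FDR values must lie in (0, 1]")
  x <- sort(-log10(fdr))
  if (diff(range(x)) < 1e-8)
    stop("no knee: all FDR values are (nearly) identical")
  gx <- seq(x[1], x[length(x)], length.out = 401)
  Fh <- ecdf(x)(gx)
  fit <- stats::smooth.spline(gx, Fh, nknots = knots, df = df)
  grid <- seq(x[1], x[length(x)], length.out = nGrid)
  d2 <- stats::predict(fit, grid, deriv = 2)$y
  knee <- .pickKnee(grid, d2, relTol)
  if (is.na(knee))
    stop("no knee: the smoothed ECDF has no qualifying inflection point")
  knee
}

#' Merge per-cell-line peak sets into consensus peaks
#'
#' Overlapping peaks (>= 1 bp, transitively) are merged across all cell
#' lines. Each consensus peak spans the envelope of its members, takes the
#' summit of the member with the smallest FDR, and records the minimum FDR
#' and the contributing cell lines. Stable \code{union_id}s are assigned in
#' sorted coordinate order.
#'
#' @param peaksets a list of \link[GenomicRanges]{GRanges} (one per cell
#'   line) with metadata columns \code{fdr}, \code{summit}, \code{cell_line}.
#' @return a \link[GenomicRanges]{GRanges} of consensus peaks with metadata
#'   columns \code{union_id}, \code{summit}, \code{best_fdr},
#'   \code{cell_lines} (comma-separated) and \code{n_members}.
#' @export
unionPeaks <- function(peaksets) {
  if (is.null(names(peaksets))) names(peaksets) <- seq_along(peaksets)
  if (!length(peaksets)) stop("need at least one peakset")
  all <- suppressWarnings(do.call(c, unname(lapply(peaksets, function(g) {
    stopifnot(all(c("fdr", "summit", "cell_line") %in% colnames(S4Vectors::mcols(g))))
    if (any(GenomicRanges::width(g) < 1)) stop("malformed interval (width < 1)")
    if (any(g$summit < GenomicRanges::start(g) | g$summit > GenomicRanges::end(g)))
      stop("malformed peak: summit outside interval")
    g
  }))))
  merged <- GenomicRanges::reduce(all, min.gapwidth = 0L)
  merged <- GenomicRanges::sort(merged)
  hits <- GenomicRanges::findOverlaps(all, merged)
  idx <- S4Vectors::subjectHits(hits)
  best <- tapply(seq_along(idx), idx, function(ii) {
    qi <- S4Vectors::queryHits(hits)[ii]
    qi[which.min(all$fdr[qi])]
  })
  ord <- as.integer(names(best))
  mcols <- S4Vectors::DataFrame(
    union_id = sprintf("UID%06d", seq_along(merged)),
    summit = NA_integer_, best_fdr = NA_real_,
    cell_lines = NA_character_, n_members = 0L)
  mcols$summit[ord] <- all$summit[unlist(best)]
  mcols$best_fdr[ord] <- all$fdr[unlist(best)]
  memb <- tapply(S4Vectors::queryHits(hits), idx, function(qi)
    paste(sort(unique(all$cell_line[qi])), collapse = ","))
  nm <- tapply(S4Vectors::queryHits(hits), idx, length)
  mcols$cell_lines[ord] <- as.character(memb)
  mcols$n_members[ord] <- as.integer(nm)
  S4Vectors::mcols(merged) <- mcols
  merged
}

.revcomp <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

#' Enumerate candidate sgRNAs around a peak summit
#'
#' Scans both strands of a locus sequence for NGG PAMs and emits the 20-nt
#' protospacer immediately 5' of each PAM. The target position of a
#' candidate is the PAM-proximal side of the canonical SpCas9 cut site
#' (between protospacer bases 17 and 18, i.e. 3 bp from the PAM); candidates
#' whose target position lies more than \code{window} bp from the summit are
#' excluded.
#'
#' @param sequence locus sequence (character or \link[Biostrings]{DNAString});
#'   must cover \code{[summit - window - 25, summit + window + 25]}.
#' @param summit absolute summit coordinate (1-based).
#' @param window search half-width in bp.
#' @param seqStart absolute coordinate of the first base of \code{sequence}.
#' @return a \linkS4class{DataFrame} sorted by \code{target_pos} with columns
#'   \code{protospacer}, \code{strand}, \code{target_pos},
#'   \code{distance_to_summit}, \code{bbsi_free}, \code{offtarget_unique},
#'   \code{spacing_ok}.
#' @examples
#' seqc <- paste(rep("A", 750), collapse = "")
#' substr(seqc, 400, 402) <- "AGG"
#' enumerateCandidates(seqc, summit = 375, seqStart = 1)
#' @export
enumerateCandidates <- function(sequence, summit, window = 300, seqStart = 1) {
  if (window < 0) stop("window must be >= 0")
  s <- toupper(as.character(sequence))
  n <- nchar(s)
  if (seqStart > summit - window - 25 || seqStart + n - 1 < summit + window + 25)
    stop("sequence too short: must cover [summit - window - 25, summit + window + 25]")
  res <- list()
  # plus strand: PAM = N G G at q..q+2 (local), protospacer at q-20..q-1
  gg <- gregexpr("(?=GG)", s, perl = TRUE)[[1]]
  gg <- gg[gg > 0]
  for (p in gg) {
    q <- p - 1  # N of the PAM
    if (q < 21) next
    proto <- substr(s, q - 20, q - 1)
    tpos <- seqStart - 1 + (q - 3)  # protospacer base 18 (cut-site boundary)
    res[[length(res) + 1]] <- list(proto, "+", tpos)
  }
  # minus strand: CCN at q..q+2 on the plus strand; protospacer is the
  # reverse complement of q+3..q+22
  cc <- gregexpr("(?=CC)", s, perl = TRUE)[[1]]
  cc <- cc[cc > 0]
  for (q in cc) {
    if (q + 22 > n) next
    proto <- .revcomp(substr(s, q + 3, q + 22))
    tpos <- seqStart - 1 + (q + 5)  # protospacer base 18 on the minus strand
    res[[length(res) + 1]] <- list(proto, "-", tpos)
  }
  if (!length(res))
    return(S4Vectors::DataFrame(protospacer = character(), strand = character(),
      target_pos = integer(), distance_to_summit = integer(),
      bbsi_free = logical(), offtarget_unique = logical(), spacing_ok = logical()))
  df <- S4Vectors::DataFrame(
    protospacer = vapply(res, `[[`, character(1), 1),
    strand = vapply(res, `[[`, character(1), 2),
    target_pos = as.integer(vapply(res, `[[`, numeric(1), 3)))
  df$distance_to_summit <- df$target_pos - as.integer(summit)
  df <- df[abs(df$distance_to_summit) <= window, , drop = FALSE]
  df$bbsi_free <- !grepl(paste(.BBSI, collapse = "|"), df$protospacer)
  df$offtarget_unique <- rep(TRUE, nrow(df))
  df$spacing_ok <- rep(NA, nrow(df))
  df[order(df$target_pos, df$strand), , drop = FALSE]
}

#' Filter candidate sgRNAs: restriction sites, uniqueness, spacing
#'
#' Removes candidates whose protospacer contains a BbsI recognition site
#' (GAAGAC or GTCTTC) or that are flagged as non-unique, then applies a
#' greedy left-to-right spacing pass that keeps a candidate only if its
#' target position exceeds the last kept one by more than \code{minGap} bp.
#'
#' @param cands candidate table from \code{\link{enumerateCandidates}},
#'   sorted by \code{target_pos}.
#' @param minGap minimum spacing (exclusive) between consecutive kept guides.
#' @return the retained subset with \code{spacing_ok = TRUE}.
#' @export
filterCandidates <- function(cands, minGap = 20) {
  if (nrow(cands) == 0) return(cands)
  if (is.unsorted(cands$target_pos)) stop("candidates must be sorted by target_pos")
  keep <- cands$bbsi_free & cands$offtarget_unique
  cands <- cands[keep, , drop = FALSE]
  if (nrow(cands) == 0) return(cands)
  kept <- logical(nrow(cands))
  last <- -Inf
  for (i in seq_len(nrow(cands))) {
    if (cands$target_pos[i] - last > minGap) {
      kept[i] <- TRUE
      last <- cands$target_pos[i]
    }
  }
  out <- cands[kept, , drop = FALSE]
  out$spacing_ok <- TRUE
  out
}

#' Assemble a two-pool tiling library with control pools
#'
#' Consensus peaks beyond the stricter -log10(FDR) cutoff go to pool 1,
#' peaks between the two cutoffs to pool 2, and peaks below the looser
#' cutoff are excluded. Control guides are appended with their class labels
#' (NT / PL / HS / YT), each class forming its own pool.
#'
#' @param consensus consensus peaks from \code{\link{unionPeaks}}.
#' @param candidates a named list (by \code{union_id}) of filtered candidate
#'   tables from \code{\link{filterCandidates}}.
#' @param poolCutoffs numeric(2): the stricter and looser cutoffs on the
#'   -log10(FDR) scale.
#' @param controls named list of 20-nt control protospacer vectors; names
#'   are control classes (e.g. NT, PL, HS, YT) and must not share guides.
#' @return a \linkS4class{GuideLibrary}.
#' @export
assembleLibrary <- function(consensus, candidates, poolCutoffs = c(92, 49),
                            controls = list()) {
  if (length(poolCutoffs) != 2 || poolCutoffs[1] <= poolCutoffs[2])
    stop("poolCutoffs must be (stricter, looser) with stricter > looser")
  if (length(controls) > 1) {
    allc <- unlist(controls, use.names = FALSE)
    if (anyDuplicated(allc)) stop("control classes share guides (must be disjoint)")
  }
  rows <- list()
  nl <- -log10(consensus$best_fdr)
  pool <- ifelse(nl > poolCutoffs[1], "pool1",
          ifelse(nl > poolCutoffs[2], "pool2", NA))
  for (i in seq_along(consensus)) {
    if (is.na(pool[i])) next
    uid <- consensus$union_id[i]
    cand <- candidates[[uid]]
    if (is.null(cand) || nrow(cand) == 0) next
    rows[[length(rows) + 1]] <- data.frame(
      guide_id = sprintf("%s_sg%03d", uid, seq_len(nrow(cand))),
      protospacer = cand$protospacer, strand = cand$strand,
      chrom = as.character(GenomicRanges::seqnames(consensus))[i],
      target_pos = cand$target_pos, union_id = uid,
      distance_to_summit = cand$distance_to_summit,
      pool = pool[i], control_class = NA_character_,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    warning("no experimental guides passed the pool cutoffs; library holds controls only")
  exp_df <- if (length(rows)) do.call(rbind, rows) else NULL
  ctl_rows <- lapply(names(controls), function(cl) {
    ps <- controls[[cl]]
    data.frame(guide_id = sprintf("%s_sg%04d", cl, seq_along(ps)),
               protospacer = ps, strand = NA_character_, chrom = NA_character_,
               target_pos = NA_integer_, union_id = NA_character_,
               distance_to_summit = NA_integer_, pool = cl, control_class = cl,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(list(exp_df), ctl_rows))
  # drop duplicate protospacers within a pool, keeping the first
  dup <- unsplit(lapply(split(df$protospacer, df$pool), duplicated), df$pool)
  if (any(dup)) {
    message("dropping ", sum(dup), " duplicate protospacers within pools")
    df <- df[!dup, , drop = FALSE]
  }
  GuideLibrary(df)
}

#' Emit 60-nt cloning oligos for a library
#'
#' Each oligo is the 20-nt protospacer flanked by fixed cloning arms that
#' carry the BbsI sites used for Golden Gate assembly:
#' \code{GCCATCCAGAAGACTTACCG + protospacer + GTTTCCGTCTTCACGACTGC}.
#'
#' @param library a \linkS4class{GuideLibrary}.
#' @return a \link[Biostrings]{DNAStringSet} of 60-nt oligos named by
#'   \code{guide_id}, in library order.
#' @export
emitOligos <- function(library) {
  e <- guideInfo(library)
  if (nrow(e) == 0) return(Biostrings::DNAStringSet())
  if (any(is.na(e$protospacer) | nchar(e$protospacer) != 20L))
    stop("all protospacers must be present and exactly 20 nt")
  out <- Biostrings::DNAStringSet(paste0(.FLANK5, e$protospacer, .FLANK3))
  names(out) <- e$guide_id
  out
}

#' Call validation-library hits from primary-screen guide statistics
#'
#' A guide is "depleting" in a cell line if its log2 fold change is negative
#' and its depletion p-value is below \code{pDeplete}. A region is a
#' lineage-specific hit if, in exactly one of the two cell lines, it has at
#' least \code{minLineage} depleting guides with at least one below
#' \code{pSig}; it is a common hit if it has at least \code{minCommon}
#' depleting guides with at least one below \code{pSig} in both cell lines.
#'
#' @param primaryStats data.frame with columns \code{guide_id},
#'   \code{union_id}, \code{cell_line}, \code{log2FC}, \code{p}; exactly two
#'   cell lines.
#' @param pDeplete,pSig p-value thresholds for "depleting" and "significant".
#' @param minLineage,minCommon minimum depleting-guide counts.
#' @return a data.frame per region: \code{union_id}, \code{category}
#'   (\code{common}, \code{lineage-<cell line>}, or \code{none}) and
#'   per-cell-line depleting/significant guide counts.
#' @export
callValidationHits <- function(primaryStats, pDeplete = 0.1, pSig = 0.05,
                               minLineage = 2, minCommon = 3) {
  need <- c("guide_id", "union_id", "cell_line", "log2FC", "p")
  miss <- setdiff(need, colnames(primaryStats))
  if (length(miss)) stop("primaryStats lacks columns: ", paste(miss, collapse = ", "))
  if (any(is.na(primaryStats$p)) || any(is.na(primaryStats$log2FC)))
    stop("missing p or log2FC in primaryStats")
  if (any(primaryStats$p < 0 | primaryStats$p > 1)) stop("p must lie in [0, 1]")
  cls <- sort(unique(primaryStats$cell_line))
  if (length(cls) != 2) stop("primaryStats must contain exactly two cell lines")
  primaryStats$depleting <- primaryStats$log2FC < 0 & primaryStats$p < pDeplete
  primaryStats$sig <- primaryStats$depleting & primaryStats$p < pSig
  agg <- aggregate(cbind(depleting, sig) ~ union_id + cell_line,
                   data = primaryStats, FUN = sum)
  regions <- sort(unique(primaryStats$union_id))
  get <- function(cl, col) {
    v <- setNames(rep(0L, length(regions)), regions)
    sub <- agg[agg$cell_line == cl, ]
    v[sub$union_id] <- sub[[col]]
    v
  }
  d1 <- get(cls[1], "depleting"); s1 <- get(cls[1], "sig")
  d2 <- get(cls[2], "depleting"); s2 <- get(cls[2], "sig")
  lin1 <- d1 >= minLineage & s1 >= 1
  lin2 <- d2 >= minLineage & s2 >= 1
  common <- (d1 >= minCommon & s1 >= 1) & (d2 >= minCommon & s2 >= 1)
  category <- ifelse(common, "common",
              ifelse(lin1 & !lin2, paste0("lineage-", cls[1]),
              ifelse(lin2 & !lin1, paste0("lineage-", cls[2]), "none")))
  data.frame(union_id = regions, category = category,
             depleting_1 = as.integer(d1), sig_1 = as.integer(s1),
             depleting_2 = as.integer(d2), sig_2 = as.integer(s2),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Design a validation library from primary-screen statistics
#'
#' Calls region hits with \code{\link{callValidationHits}} and, for every
#' hit region, carries forward the \code{topK} depleting guides with the
#' most negative log2 fold change (ties broken by smaller p, then by guide
#' id). For lineage-specific hits only the hit cell line's statistics rank
#' the guides; for common hits the stronger (more negative) log2FC across
#' the two cell lines is used.
#'
#' @inheritParams callValidationHits
#' @param topK guides carried per hit region.
#' @return a \linkS4class{GuideLibrary} with pool \code{"validation"}; the
#'   hit table is stored in \code{metadata(guideInfo(x))$hits}.
#' @export
designValidationLibrary <- function(primaryStats, topK = 4, pDeplete = 0.1,
                                    pSig = 0.05, minLineage = 2, minCommon = 3) {
  hits <- callValidationHits(primaryStats, pDeplete, pSig, minLineage, minCommon)
  hitReg <- hits[hits$category != "none", ]
  cls <- sort(unique(primaryStats$cell_line))
  rows <- list()
  for (i in seq_len(nrow(hitReg))) {
    uid <- hitReg$union_id[i]; cat <- hitReg$category[i]
    sub <- primaryStats[primaryStats$union_id == uid, ]
    inCl <- if (cat == "common") cls else sub("^lineage-", "", cat)
    sub <- sub[sub$cell_line %in% inCl, ]
    dep <- sub[sub$log2FC < 0 & sub$p < pDeplete, ]
    if (!nrow(dep)) next
    # per guide: strongest depletion across the hit cell lines
    score <- aggregate(cbind(log2FC, p) ~ guide_id, data = dep, FUN = min)
    ord <- order(score$log2FC, score$p, score$guide_id)
    sel <- score$guide_id[ord][seq_len(min(topK, nrow(score)))]
    g <- primaryStats[match(sel, primaryStats$guide_id), ]
    rows[[length(rows) + 1]] <- data.frame(
      guide_id = sel,
      protospacer = if ("protospacer" %in% colnames(primaryStats))
        g$protospacer else NA_character_,
      strand = NA_character_, chrom = NA_character_, target_pos = NA_integer_,
      union_id = uid, distance_to_summit = NA_integer_,
      pool = "validation", control_class = NA_character_,
      stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(guide_id = character(), protospacer = character(),
               strand = character(), chrom = character(),
               target_pos = integer(), union_id = character(),
               distance_to_summit = integer(), pool = character(),
               control_class = character(), stringsAsFactors = FALSE)
  lib <- GuideLibrary(df)
  S4Vectors::metadata(lib@entries)$hits <- hits
  lib
}
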