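# Screen count normalization, per-guide statistics, and the exponential
# fitness model.

.assayMat <- function(se) {
  a <- SummarizedExperiment::assay(se)
  if (is.null(rownames(a))) stop("count matrix must have guide rownames")
  a
}

#' Normalize counts so that control guides have median \code{target}
#'
#' Per sample, all counts are scaled by \code{target / median(control
#' counts)}, so the control median is exactly \code{target} afterwards and
#' within-sample guide ratios are unchanged. This is the normalization used
#' for compact validation screens.
#'
#' @param se a \linkS4class{ScreenExperiment}.
#' @param controlIds guide ids of the control pool (e.g. non-targeting).
#' @param target the post-normalization control median.
#' @return a \linkS4class{ScreenExperiment} with a real-valued counts assay.
#' @export
normalizeToControls <- function(se, controlIds, target = 1000) {
  if (!length(controlIds)) stop("controlIds must be non-empty")
  counts <- .assayMat(se)
  if (!all(controlIds %in% rownames(counts)))
    stop("some controlIds are absent from the count matrix")
  med <- apply(counts[controlIds, , drop = FALSE], 2, median)
  if (any(med == 0))
    stop("control counts have zero median in sample(s): ",
         paste(colnames(counts)[med == 0], collapse = ", "))
  # multiply before dividing so the median control scales to target exactly
  norm <- sweep(counts * target, 2, med, `/`)
  out <- se
  SummarizedExperiment::assay(out) <- norm
  S4Vectors::metadata(out)$normalization <- "control-median"
  out
}

#' TMM scaling factors for a screen count matrix
#'
#' Between-sample scaling factors by the trimmed mean of M-values method
#' (the normalization used for full-scale tiling screens), computed with
#' edgeR. The reference sample is the one whose upper quartile is closest
#' to the mean upper quartile; factors are normalized to geometric mean 1.
#'
#' @param se a \linkS4class{ScreenExperiment} or a count matrix.
#' @param trimM,trimA trim fractions for the log-ratio (M) and
#'   log-abundance (A) values.
#' @return named per-sample scaling factors.
#' @export
tmmFactors <- function(se, trimM = 0.3, trimA = 0.05) {
  counts <- if (is(se, "SummarizedExperiment")) .assayMat(se) else se
  if (ncol(counts) < 2) stop("need at least 2 samples")
  if (all(counts == 0)) stop("counts are all zero")
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = trimM, sumTrim = trimA)
  names(f) <- colnames(counts)
  f
}

#' Apply TMM normalization to a screen
#'
#' Scales each sample by its effective library size (library size times TMM
#' factor), rescaled so the mean effective library size is preserved.
#'
#' @inheritParams tmmFactors
#' @return a \linkS4class{ScreenExperiment} with a real-valued counts assay.
#' @export
tmmNormalize <- function(se, trimM = 0.3, trimA = 0.05) {
  counts <- .assayMat(se)
  f <- tmmFactors(counts, trimM, trimA)
  eff <- colSums(counts) * f
  norm <- sweep(counts, 2, mean(eff) / eff, `*`)
  out <- se
  SummarizedExperiment::assay(out) <- norm
  S4Vectors::metadata(out)$normalization <- "TMM"
  out
}

.resolvePseudocount <- function(counts, pseudocount) {
  if (is.numeric(pseudocount)) return(pseudocount)
  switch(match.arg(pseudocount, c("min.nonzero", "none")),
         min.nonzero = min(counts[counts > 0]),
         none = 0)
}

#' Per-guide log2 fold changes versus day 0
#'
#' For every guide, cell line and post-day-0 timepoint, computes
#' \code{log2((x_t + c) / (x_0 + c))} within each replicate (day-0 and
#' later samples are matched by cell line and replicate), with pseudocount
#' \code{c} equal to the smallest nonzero count in the matrix by default.
#'
#' @param se a (normalized) \linkS4class{ScreenExperiment}.
#' @param pseudocount \code{"min.nonzero"} (default), \code{"none"}, or a
#'   number.
#' @param perReplicate if TRUE, return one row per replicate; otherwise
#'   replicates are averaged.
#' @return a data.frame with columns \code{guide_id}, \code{cell_line},
#'   \code{day}, (\code{replicate} if \code{perReplicate}), \code{lfc}.
#' @export
guideLFC <- function(se, pseudocount = "min.nonzero", perReplicate = FALSE) {
  counts <- .assayMat(se)
  cd <- SummarizedExperiment::colData(se)
  c0 <- .resolvePseudocount(counts, pseudocount)
  out <- list()
  for (cl in unique(cd$cell_line)) {
    for (r in unique(cd$replicate[cd$cell_line == cl])) {
      j0 <- which(cd$cell_line == cl & cd$replicate == r & cd$day == 0)
      if (length(j0) != 1)
        stop("cell line ", cl, " replicate ", r, " needs exactly one day-0 sample")
      for (t in sort(unique(cd$day[cd$cell_line == cl & cd$day > 0]))) {
        jt <- which(cd$cell_line == cl & cd$replicate == r & cd$day == t)
        if (!length(jt)) next
        out[[length(out) + 1]] <- data.frame(
          guide_id = rownames(counts), cell_line = cl, replicate = r, day = t,
          lfc = log2((counts[, jt[1]] + c0) / (counts[, j0] + c0)),
          row.names = NULL, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  if (perReplicate) return(res)
  agg <- aggregate(lfc ~ guide_id + cell_line + day, data = res, FUN = mean)
  agg[order(agg$cell_line, agg$day, agg$guide_id), ]
}

#' Per-guide depletion test across replicates
#'
#' Two-sided one-sample t-test of the replicate log2 fold changes against 0,
#' per guide and cell line. With zero replicate variance the p-value is set
#' to 1 when the mean is 0 and floored near 0 (and flagged) otherwise.
#'
#' @param lfcReps replicate-level table from
#'   \code{guideLFC(..., perReplicate = TRUE)}, restricted to one timepoint.
#' @return a data.frame: \code{guide_id}, \code{cell_line}, \code{log2FC}
#'   (mean), \code{t}, \code{p}, \code{n}, \code{flag}.
#' @export
guideDepletionTest <- function(lfcReps) {
  if (length(unique(lfcReps$day)) > 1)
    stop("restrict lfcReps to a single timepoint before testing")
  sp <- split(lfcReps$lfc, list(lfcReps$guide_id, lfcReps$cell_line), drop = TRUE)
  key <- do.call(rbind, strsplit(names(sp), ".", fixed = TRUE))
  n <- lengths(sp)
  if (any(n < 2)) stop("need >= 2 replicates per guide and cell line")
  m <- vapply(sp, mean, numeric(1))
  s <- vapply(sp, sd, numeric(1))
  tt <- m / (s / sqrt(n))
  p <- 2 * pt(-abs(tt), df = n - 1)
  flag <- s == 0
  p[flag & m == 0] <- 1
  p[flag & m != 0] <- .Machine$double.xmin
  tt[flag & m == 0] <- 0
  data.frame(guide_id = key[, 1], cell_line = key[, 2], log2FC = m,
             t = tt, p = p, n = as.integer(n), flag = flag,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-guide statistics at one timepoint
#'
#' Convenience wrapper: replicate-level log2 fold changes at \code{day}
#' followed by the replicate depletion t-test, returning the per-guide
#' statistics table used for validation-library design.
#'
#' @param se a (normalized) \linkS4class{ScreenExperiment}.
#' @param day the timepoint to test (default: the last day).
#' @param library optional \linkS4class{GuideLibrary}; if given, a
#'   \code{union_id} column is added.
#' @inheritParams guideLFC
#' @return a data.frame with columns \code{guide_id}, \code{union_id} (if a
#'   library is given), \code{cell_line}, \code{log2FC}, \code{p}.
#' @export
guideStats <- function(se, day = NULL, library = NULL,
                       pseudocount = "min.nonzero") {
  cd <- SummarizedExperiment::colData(se)
  if (is.null(day)) day <- max(cd$day)
  reps <- guideLFC(se, pseudocount, perReplicate = TRUE)
  res <- guideDepletionTest(reps[reps$day == day, ])
  if (!is.null(library)) {
    e <- guideInfo(library)
    res$union_id <- e$union_id[match(res$guide_id, e$guide_id)]
  }
  res
}

# OLS of ln(x) = intercept_g + alpha * t with one intercept per guide and a
# single shared slope; returns the slope, its standard error and p-value.
.olsFitness <- function(y, guide, t) {
  g <- as.integer(factor(guide))
  ng <- max(g)
  X <- matrix(0, length(y), ng + 1L)
  X[cbind(seq_along(y), g)] <- 1
  X[, ng + 1L] <- t
  colnames(X) <- c(paste0("g", seq_len(ng)), "t")
  fit <- lm.fit(X, y)
  p <- ncol(X); n <- length(y)
  alpha <- unname(fit$coefficients["t"])
  dfree <- n - p
  if (dfree <= 0) return(list(alpha = alpha, se = NA_real_, p = NA_real_,
                              n = n, df = dfree))
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / dfree
  R <- qr.R(fit$qr)
  XtXinv <- chol2inv(R)
  se <- sqrt(sigma2 * XtXinv[p, p])
  if (se < 1e-12) {
    pval <- if (abs(alpha) < 1e-12) 1 else 0
  } else {
    pval <- 2 * pt(-abs(alpha / se), df = dfree)
  }
  list(alpha = alpha, se = se, p = pval, n = n, df = dfree)
}

#' Fit the exponential fitness model for one region
#'
#' Stacks all (guide, replicate, timepoint) observations of a region and
#' fits \eqn{\ln(x_t) = b_g + \alpha t} by ordinary least squares, with one
#' intercept per guide and a single shared per-day fitness score
#' \eqn{\alpha}; day-0 observations enter at \eqn{t = 0}. A negative
#' \eqn{\alpha} means growth inhibition.
#'
#' @param counts numeric matrix of normalized counts (guides x samples) for
#'   one region in one cell line, or a vector for a single guide.
#' @param days numeric vector of harvest days, one per column.
#' @param pseudocount added to counts before the log; default 0 (observations
#'   that are not positive after the pseudocount are dropped).
#' @param includeDay0 if FALSE, day-0 observations are excluded and the
#'   intercepts absorb the baseline.
#' @return a data.frame row: \code{alpha}, \code{se}, \code{p},
#'   \code{n_points}, \code{df}.
#' @examples
#' x <- rbind(1000 * exp(-0.1 * c(0, 8, 15, 22)))
#' fitFitness(x, c(0, 8, 15, 22))
#' @export
fitFitness <- function(counts, days, pseudocount = 0, includeDay0 = TRUE) {
  if (is.vector(counts)) counts <- matrix(counts, nrow = 1)
  if (ncol(counts) != length(days)) stop("days must match columns of counts")
  if (all(counts == 0)) stop("all-zero region")
  x <- counts + pseudocount
  guide <- rep(seq_len(nrow(counts)), times = ncol(counts))
  t <- rep(days, each = nrow(counts))
  y <- as.vector(x)
  ok <- y > 0
  if (!includeDay0) ok <- ok & t > 0
  if (length(unique(t[ok])) < 2)
    stop("need at least 2 distinct timepoints with positive counts")
  res <- .olsFitness(log(y[ok]), guide[ok], t[ok])
  data.frame(alpha = res$alpha, se = res$se, p = res$p,
             n_points = res$n, df = res$df)
}

#' Fit the fitness model for every region and cell line
#'
#' Runs \code{\link{fitFitness}} on the guides of each consensus region,
#' separately per cell line, using the region assignment of a designed
#' library. Control guides (no \code{union_id}) are skipped.
#'
#' @param se a normalized \linkS4class{ScreenExperiment}.
#' @param library a \linkS4class{GuideLibrary} mapping guides to regions.
#' @param pseudocount \code{"min.nonzero"}, \code{"none"} or a number,
#'   resolved on the whole matrix and passed to every fit.
#' @param includeDay0 see \code{\link{fitFitness}}.
#' @return a data.frame: \code{union_id}, \code{cell_line}, \code{alpha},
#'   \code{se}, \code{p}, \code{n_points}, \code{df}.
#' @export
fitFitnessAll <- function(se, library, pseudocount = "min.nonzero",
                          includeDay0 = TRUE) {
  counts <- .assayMat(se)
  cd <- SummarizedExperiment::colData(se)
  c0 <- .resolvePseudocount(counts, pseudocount)
  e <- guideInfo(library)
  exper <- e[!is.na(e$union_id), , drop = FALSE]
  regions <- split(as.character(exper$guide_id), as.character(exper$union_id))
  out <- vector("list", length(regions) * length(unique(cd$cell_line)))
  k <- 0
  for (cl in unique(cd$cell_line)) {
    j <- which(cd$cell_line == cl)
    dj <- cd$day[j]
    for (uid in names(regions)) {
      g <- intersect(regions[[uid]], rownames(counts))
      if (!length(g)) next
      fit <- tryCatch(
        fitFitness(counts[g, j, drop = FALSE], dj, pseudocount = c0,
                   includeDay0 = includeDay0),
        error = function(err) NULL)
      if (is.null(fit)) next
      k <- k + 1
      out[[k]] <- cbind(data.frame(union_id = uid, cell_line = cl,
                                   stringsAsFactors = FALSE), fit)
    }
  }
  do.call(rbind, out[seq_len(k)])
}
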