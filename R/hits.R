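# Differential guide comparison between lineages and secondary-screen
# region-level hit calling.

#' Differential guide depletion between two cell lines
#'
#' Per guide, the difference in log2 fold change between cell lines A and B
#' at a matched timepoint is tested with a pooled two-sample t-test across
#' replicates, corrected by Benjamini-Hochberg across guides. A guide is
#' differential if \code{|delta| > lfcThresh} and \code{FDR < fdrThresh};
#' it is labeled with the cell line showing the stronger depletion.
#'
#' @param lfcA,lfcB replicate-level log2FC tables (from
#'   \code{guideLFC(..., perReplicate = TRUE)}) for the two cell lines,
#'   restricted to one timepoint; identical guide universes required.
#' @param lfcThresh,fdrThresh differential thresholds.
#' @return a data.frame per guide: \code{guide_id}, \code{lfc_a},
#'   \code{lfc_b}, \code{delta}, \code{t}, \code{p}, \code{fdr},
#'   \code{differential}, \code{lineage}.
#' @export
differentialLineage <- function(lfcA, lfcB, lfcThresh = 1, fdrThresh = 0.05) {
  for (x in list(lfcA, lfcB))
    if (length(unique(x$day)) > 1) stop("restrict inputs to a single timepoint")
  gA <- sort(unique(lfcA$guide_id)); gB <- sort(unique(lfcB$guide_id))
  if (!identical(gA, gB)) stop("guide universes disagree between the two tables")
  spA <- split(lfcA$lfc, lfcA$guide_id)[gA]
  spB <- split(lfcB$lfc, lfcB$guide_id)[gA]
  nA <- lengths(spA); nB <- lengths(spB)
  if (any(nA < 2) || any(nB < 2)) stop("need >= 2 replicates per guide")
  mA <- vapply(spA, mean, numeric(1)); mB <- vapply(spB, mean, numeric(1))
  vA <- vapply(spA, var, numeric(1)); vB <- vapply(spB, var, numeric(1))
  delta <- mA - mB
  dfree <- nA + nB - 2
  sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / dfree
  sedelta <- sqrt(sp2 * (1 / nA + 1 / nB))
  tt <- delta / sedelta
  p <- 2 * pt(-abs(tt), df = dfree)
  p[sedelta == 0 & delta == 0] <- 1
  p[sedelta == 0 & delta != 0] <- .Machine$double.xmin
  fdr <- p.adjust(p, method = "BH")
  nameA <- if ("cell_line" %in% colnames(lfcA)) lfcA$cell_line[1] else "A"
  nameB <- if ("cell_line" %in% colnames(lfcB)) lfcB$cell_line[1] else "B"
  diffr <- abs(delta) > lfcThresh & fdr < fdrThresh
  data.frame(guide_id = gA, lfc_a = mA, lfc_b = mB, delta = delta,
             t = tt, p = p, fdr = fdr, differential = diffr,
             lineage = ifelse(!diffr, NA_character_,
                              ifelse(delta < 0, nameA, nameB)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call common and lineage-specific region hits across four models
#'
#' A region "scores" in a model when its fitness score is negative with
#' p below \code{alphaP}. Regions scoring in at least three of the four
#' models are common hits; regions scoring in both models of one lineage
#' and in neither model of the other are lineage-specific; everything else
#' is \code{none}.
#'
#' @param fitness fitness table from \code{\link{fitFitnessAll}} covering
#'   four cell lines (two per lineage).
#' @param lineages named character vector mapping cell line to lineage.
#' @param alphaP p-value threshold for scoring.
#' @return a data.frame per region: \code{union_id}, \code{category}
#'   (\code{common} / \code{lineage-<name>} / \code{none}),
#'   \code{n_scoring}, \code{scoring_models}.
#' @export
callHitsSecondary <- function(fitness, lineages, alphaP = 0.05) {
  cls <- sort(unique(fitness$cell_line))
  miss <- setdiff(cls, names(lineages))
  if (length(miss)) stop("no lineage label for: ", paste(miss, collapse = ", "))
  lineages <- lineages[cls]
  if (length(cls) != 4 || length(unique(lineages)) != 2 ||
      any(table(lineages) != 2))
    stop("expected 4 models, two per lineage")
  fitness$scores <- fitness$alpha < 0 & fitness$p < alphaP
  regions <- sort(unique(fitness$union_id))
  S <- matrix(FALSE, length(regions), length(cls),
              dimnames = list(regions, cls))
  S[cbind(match(fitness$union_id, regions),
          match(fitness$cell_line, cls))] <- fitness$scores
  lins <- unique(lineages)
  inL <- lapply(lins, function(l) rowSums(S[, lineages == l, drop = FALSE]))
  names(inL) <- lins
  nsc <- rowSums(S)
  category <- rep("none", length(regions))
  spec1 <- inL[[1]] == 2 & inL[[2]] == 0
  spec2 <- inL[[2]] == 2 & inL[[1]] == 0
  category[spec1] <- paste0("lineage-", lins[1])
  category[spec2] <- paste0("lineage-", lins[2])
  category[nsc >= 3] <- "common"
  data.frame(union_id = regions, category = category,
             n_scoring = as.integer(nsc),
             scoring_models = apply(S, 1, function(r)
               paste(cls[r], collapse = ",")),
             row.names = NULL, stringsAsFactors = FALSE)
}
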