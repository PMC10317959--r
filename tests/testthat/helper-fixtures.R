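# Shared fixtures and independent oracles, built in code at test time.

# Small designed library: nRegions experimental regions with nGuides guides
# each, plus a non-targeting pool.
makeTestLibrary <- function(nRegions = 5, nGuides = 4, nNT = 20) {
  bases <- c("A", "C", "G", "T")
  mkps <- function(n, seed) {
    set.seed(seed)
    ps <- unique(vapply(seq_len(n * 3), function(i)
      paste(sample(bases, 20, replace = TRUE), collapse = ""), character(1)))
    ps <- ps[!grepl("GAAGAC|GTCTTC", ps)]
    ps[seq_len(n)]
  }
  uid <- sprintf("UID%06d", seq_len(nRegions))
  exp_df <- data.frame(
    guide_id = paste0(rep(uid, each = nGuides), "_sg",
                      sprintf("%03d", rep(seq_len(nGuides), nRegions))),
    protospacer = mkps(nRegions * nGuides, 11),
    strand = "+", chrom = "chrS",
    target_pos = seq_len(nRegions * nGuides) * 50L,
    union_id = rep(uid, each = nGuides),
    distance_to_summit = 0L, pool = "pool1", control_class = NA_character_,
    stringsAsFactors = FALSE)
  if (nNT > 0) {
    nt_df <- data.frame(
      guide_id = sprintf("NT_sg%04d", seq_len(nNT)),
      protospacer = mkps(nNT, 12), strand = NA_character_, chrom = NA_character_,
      target_pos = NA_integer_, union_id = NA_character_,
      distance_to_summit = NA_integer_, pool = "NT", control_class = "NT",
      stringsAsFactors = FALSE)
    exp_df <- rbind(exp_df, nt_df)
  }
  GuideLibrary(exp_df)
}

# NB counts for one region in one cell line: guides x (replicates x days)
# around exponential dropout; returns list(counts, days).
simRegionCounts <- function(alpha, nGuides = 4, reps = 2,
                            days = c(0, 8, 15, 22), depth = 1000,
                            dispersion = 0.05) {
  cols <- expand.grid(rep = seq_len(reps), day = days)
  mu <- outer(rep(depth, nGuides), exp(alpha * cols$day))
  counts <- matrix(
    if (dispersion > 0) rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    else rpois(length(mu), mu),
    nrow = nGuides)
  list(counts = counts, days = cols$day)
}

# Independent knee oracle: finite differences of a noiseless two-component
# Gaussian mixture CDF on a dense grid; highest +to- sign change of F''
# whose preceding positive lobe carries non-negligible mass.
kneeOracleMixture <- function(w1, m1, s1, m2, s2, lo = 0, hi = 90,
                              n = 1e4, relTol = 0.02) {
  g <- seq(lo, hi, length.out = n)
  Fc <- w1 * pnorm(g, m1, s1) + (1 - w1) * pnorm(g, m2, s2)
  h <- g[2] - g[1]
  d2 <- diff(diff(Fc)) / h^2
  gg <- g[2:(n - 1)]
  s <- sign(d2)
  cross <- which(s[-1] * s[-length(s)] < 0)
  modes <- cross[d2[cross] > 0]
  lobe <- vapply(modes, function(i) {
    j <- i
    while (j > 1 && d2[j - 1] > 0) j <- j - 1
    sum(d2[j:i]) * h
  }, numeric(1))
  keep <- modes[lobe >= relTol * max(lobe)]
  i <- max(keep)
  gg[i] + h * abs(d2[i]) / (abs(d2[i]) + abs(d2[i + 1]))
}

# Independent OLS oracle via explicit normal equations.
olsSlopeOracle <- function(y, guide, t) {
  X <- cbind(model.matrix(~ 0 + factor(guide)), t)
  beta <- solve(crossprod(X), crossprod(X, y))
  beta[length(beta)]
}

# Brute-force interval merge (transitive >= 1 bp overlap) on a single
# chromosome; returns a matrix of merged (start, end).
mergeOracle <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]; out <- NULL
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) me <- max(me, end[i])
    else { out <- rbind(out, c(ms, me)); ms <- start[i]; me <- end[i] }
  }
  rbind(out, c(ms, me))
}

# bedGraph-style constant track over one chromosome.
constantTrack <- function(value, len = 10000, chrom = "chrS") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(1, len), score = value)
}
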