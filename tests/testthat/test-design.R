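test_that("peak cutoff lands at the high-significance knee of a mixture", {
  set.seed(3)
  n <- 5000
  nl <- ifelse(runif(n) < 0.1, rnorm(n, 60, 5), rnorm(n, 10, 3))
  nl <- pmax(nl, 0.01)
  cut <- selectPeakCutoff(10^(-nl))
  oracle <- kneeOracleMixture(0.9, 10, 3, 60, 5)
  expect_lt(abs(cut - oracle), 2)
})

test_that("peak cutoff degenerate and invariance cases", {
  expect_error(selectPeakCutoff(rep(0.5, 200)), "no knee")
  expect_error(selectPeakCutoff(runif(50)), "at least 100")
  expect_error(selectPeakCutoff(c(runif(200), 2)), "\\(0, 1\\]")
  set.seed(7)
  nl <- pmax(ifelse(runif(2000) < 0.2, rnorm(2000, 45, 4), rnorm(2000, 8, 2)), 0.01)
  fdr <- 10^(-nl)
  # reordering the values (a relabeling preserving -log10 ordering and
  # spacing) leaves the cutoff unchanged
  expect_equal(selectPeakCutoff(fdr), selectPeakCutoff(sample(fdr)))
})

test_that("peak union merges transitively and keeps the best summit", {
  mk <- function(s, e, fdr, summit, cl)
    GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e), fdr = fdr,
                           summit = summit, cell_line = cl)
  # two identical peaks from two cell lines -> one consensus with 2 members
  u <- unionPeaks(list(a = mk(100, 200, 1e-5, 150, "a"),
                       b = mk(100, 200, 1e-9, 160, "b")))
  expect_length(u, 1)
  expect_equal(u$cell_lines, "a,b")
  expect_equal(u$summit, 160)      # member with the smaller fdr
  expect_equal(u$best_fdr, 1e-9)
  # three disjoint peaks stay separate
  u <- unionPeaks(list(a = mk(c(1, 500, 900), c(100, 600, 950),
                              rep(1e-3, 3), c(50, 550, 920), "a")))
  expect_length(u, 3)
  # chain A-B-C with A, C disjoint merges into one envelope
  u <- unionPeaks(list(a = mk(c(1, 80, 160), c(100, 180, 260),
                              c(1e-3, 1e-8, 1e-4), c(50, 120, 200), "a")))
  expect_length(u, 1)
  expect_equal(GenomicRanges::start(u), 1)
  expect_equal(GenomicRanges::end(u), 260)
  expect_equal(u$summit, 120)
  orc <- mergeOracle(c(1, 80, 160), c(100, 180, 260))
  expect_equal(unname(orc[1, ]), c(1, 260))
})

test_that("peak union is idempotent and order-invariant", {
  set.seed(11)
  mkrand <- function(cl) {
    s <- sort(sample.int(5000, 40))
    GenomicRanges::GRanges("chr1", IRanges::IRanges(s, s + sample(30:200, 40, TRUE)),
      fdr = 10^(-runif(40, 1, 80)), summit = s + 10, cell_line = cl)
  }
  ps <- list(a = mkrand("a"), b = mkrand("b"), c = mkrand("c"))
  u1 <- unionPeaks(ps)
  # idempotence: union of its own output is itself
  self <- u1
  S4Vectors::mcols(self) <- S4Vectors::DataFrame(
    fdr = u1$best_fdr, summit = u1$summit, cell_line = "u")
  u2 <- unionPeaks(list(self))
  expect_equal(GenomicRanges::granges(u2), GenomicRanges::granges(u1))
  # input order only relabels union_ids
  u3 <- unionPeaks(ps[c("c", "a", "b")])
  expect_equal(GenomicRanges::granges(u3), GenomicRanges::granges(u1))
  expect_equal(u3$best_fdr, u1$best_fdr)
})

test_that("candidate enumeration scans both strands around the summit", {
  # one AGG PAM on the plus strand in an otherwise PAM-free sequence
  base <- strrep("A", 750)
  s <- base
  substr(s, 400, 402) <- "TGG"  # PAM at 400-402, protospacer 380..399
  cand <- enumerateCandidates(s, summit = 375, window = 300, seqStart = 1)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$strand, "+")
  expect_equal(cand$protospacer, strrep("A", 20))
  expect_equal(cand$target_pos, 397)   # base 18 of the protospacer
  # all-A sequence has no PAM at all
  expect_equal(nrow(enumerateCandidates(base, 375, 300, 1)), 0)
  # CCN on the plus strand = PAM on the minus strand
  s2 <- base
  substr(s2, 400, 402) <- "CCT"
  cand2 <- enumerateCandidates(s2, summit = 375, window = 300, seqStart = 1)
  expect_equal(nrow(cand2), 1)
  expect_equal(cand2$strand, "-")
  expect_equal(cand2$protospacer, strrep("T", 20))
  expect_equal(cand2$target_pos, 405)
  # planted PAM at a known offset from the summit is found there
  s3 <- base
  substr(s3, 495, 497) <- "AGG"   # offset +120 from summit 375
  cand3 <- enumerateCandidates(s3, summit = 375, window = 300, seqStart = 1)
  expect_equal(cand3$distance_to_summit, 117)  # cut site 3 bp 5' of the PAM
  # window exclusion and short-sequence error
  far <- enumerateCandidates(s3, summit = 375, window = 100, seqStart = 1)
  expect_equal(nrow(far), 0)
  expect_error(enumerateCandidates(strrep("A", 100), 50, 300, 1), "too short")
})

test_that("genomic coordinates offset through seqStart", {
  s <- strrep("A", 750)
  substr(s, 400, 402) <- "TGG"
  cand <- enumerateCandidates(s, summit = 10375, window = 300, seqStart = 10001)
  expect_equal(cand$target_pos, 10397)
  expect_equal(cand$distance_to_summit, 22)
})

test_that("candidate filtering removes BbsI sites and enforces spacing", {
  mk <- function(pos, proto = strrep("A", 20)) S4Vectors::DataFrame(
    protospacer = proto, strand = "+", target_pos = as.integer(pos),
    distance_to_summit = as.integer(pos), bbsi_free = !grepl("GAAGAC|GTCTTC", proto),
    offtarget_unique = TRUE, spacing_ok = NA)
  # BbsI site in the protospacer (either orientation) is removed
  bad1 <- mk(10, paste0("GAAGAC", strrep("A", 14)))
  bad2 <- mk(40, paste0(strrep("A", 14), "GTCTTC"))
  good <- mk(80)
  out <- filterCandidates(rbind(bad1, bad2, good))
  expect_equal(nrow(out), 1)
  expect_equal(out$target_pos, 80L)
  # greedy pass over positions 0,10,...,290 keeps 0,30,...,270
  dense <- do.call(rbind, lapply(seq(0, 290, 10), mk))
  kept <- filterCandidates(dense, minGap = 20)
  expect_equal(kept$target_pos, as.integer(seq(0, 270, 30)))
  expect_true(all(diff(kept$target_pos) > 20))
  # single candidate is kept unchanged
  expect_equal(nrow(filterCandidates(mk(5))), 1)
  # unsorted input is an error
  expect_error(filterCandidates(rbind(mk(100), mk(10))), "sorted")
  # non-unique guides are dropped
  amb <- mk(10); amb$offtarget_unique <- FALSE
  expect_equal(nrow(filterCandidates(rbind(amb, mk(50)))), 1)
})

test_that("library assembly splits pools by significance cutoffs", {
  mkcons <- function(fdr) {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 500), c(100, 600)))
    gr$union_id <- c("UID000001", "UID000002")
    gr$summit <- c(50L, 550L)
    gr$best_fdr <- fdr
    gr
  }
  cand <- S4Vectors::DataFrame(protospacer = c(strrep("A", 20), strrep("C", 20)),
    strand = "+", target_pos = c(40L, 80L), distance_to_summit = c(-10L, 30L),
    bbsi_free = TRUE, offtarget_unique = TRUE, spacing_ok = TRUE)
  cands <- list(UID000001 = cand, UID000002 = cand)
  # fdr 1e-100 with cutoffs (92, 49) -> pool 1; 1e-60 -> pool 2
  lib <- assembleLibrary(mkcons(c(1e-100, 1e-60)), cands, poolCutoffs = c(92, 49))
  e <- guideInfo(lib)
  expect_equal(unique(e$pool[e$union_id == "UID000001"]), "pool1")
  expect_equal(unique(e$pool[e$union_id == "UID000002"]), "pool2")
  # fdr 1e-10 is below both cutoffs -> excluded
  lib2 <- assembleLibrary(mkcons(c(1e-100, 1e-10)), cands, poolCutoffs = c(92, 49))
  expect_false("UID000002" %in% guideInfo(lib2)$union_id)
  # no experimental peak retained -> controls only, with a warning
  expect_warning(
    lib3 <- assembleLibrary(mkcons(c(1e-2, 1e-3)), cands, poolCutoffs = c(92, 49),
      controls = list(NT = c(strrep("G", 20), strrep("T", 20)))),
    "controls only")
  expect_equal(nGuides(lib3), 2)
  expect_true(all(guideInfo(lib3)$control_class == "NT"))
  # overlapping control classes are rejected
  expect_error(assembleLibrary(mkcons(c(1e-100, 1e-60)), cands,
    controls = list(NT = strrep("G", 20), PL = strrep("G", 20))), "disjoint")
  expect_error(assembleLibrary(mkcons(c(1e-100, 1e-60)), cands,
                               poolCutoffs = c(49, 92)), "stricter")
})

test_that("oligos carry the printed flanks and round-trip the protospacer", {
  lib <- makeTestLibrary(nRegions = 2, nGuides = 3, nNT = 2)
  oligos <- emitOligos(lib)
  expect_equal(length(oligos), nGuides(lib))
  expect_true(all(Biostrings::width(oligos) == 60))
  sq <- as.character(oligos)
  expect_true(all(startsWith(sq, "GCCATCCAGAAGACTTACCG")))
  expect_true(all(endsWith(sq, "GTTTCCGTCTTCACGACTGC")))
  expect_equal(unname(substr(sq, 21, 40)), guideInfo(lib)$protospacer)
  # explicit flank check on a known protospacer
  lib1 <- GuideLibrary(data.frame(guide_id = "g1", protospacer = strrep("A", 20),
    strand = "+", chrom = "c", target_pos = 1L, union_id = "U1",
    distance_to_summit = 0L, pool = "pool1", control_class = NA))
  expect_equal(as.character(emitOligos(lib1))[[1]],
    paste0("GCCATCCAGAAGACTTACCG", strrep("A", 20), "GTTTCCGTCTTCACGACTGC"))
  # empty library and malformed protospacer
  expect_length(emitOligos(GuideLibrary(guideInfo(lib)[0, ])), 0)
  bad <- data.frame(guide_id = "g1", protospacer = strrep("A", 19),
    strand = "+", chrom = "c", target_pos = 1L, union_id = "U1",
    distance_to_summit = 0L, pool = "pool1", control_class = NA)
  expect_error(GuideLibrary(bad), "exactly 20")
})

test_that("validation hit rules follow the depleting-guide thresholds", {
  mkstats <- function(uid, cl, p, lfc = rep(-1, length(p)),
                      gid = sprintf("%s_g%02d", uid, seq_along(p)))
    data.frame(guide_id = gid, union_id = uid, cell_line = cl,
               log2FC = lfc, p = p, stringsAsFactors = FALSE)
  neutral <- function(uid) rbind(
    mkstats(uid, "A", rep(0.9, 5)), mkstats(uid, "B", rep(0.9, 5)))
  # 5 depleting guides in one cell line only -> lineage hit with 4 guides
  st <- rbind(mkstats("R1", "A", c(0.01, 0.04, 0.08, 0.09, 0.2)),
              mkstats("R1", "B", rep(0.9, 5)))
  hits <- callValidationHits(st)
  expect_equal(hits$category, "lineage-A")
  lib <- designValidationLibrary(st)
  expect_equal(sum(guideInfo(lib)$union_id == "R1"), 4)
  # one depleting guide, however significant, is not a hit
  st2 <- rbind(mkstats("R2", "A", c(0.001, 0.5, 0.6)),
               mkstats("R2", "B", rep(0.9, 3)))
  expect_equal(callValidationHits(st2)$category, "none")
  # two depleting guides but none below 0.05 is not a hit
  st3 <- rbind(mkstats("R3", "A", c(0.06, 0.09)), mkstats("R3", "B", rep(0.9, 2)))
  expect_equal(callValidationHits(st3)$category, "none")
  # p = 0.049 vs 0.051 at the significance boundary
  st4 <- rbind(mkstats("R4", "A", c(0.049, 0.08)), mkstats("R4", "B", rep(0.9, 2)))
  expect_equal(callValidationHits(st4)$category, "lineage-A")
  st5 <- rbind(mkstats("R5", "A", c(0.051, 0.08)), mkstats("R5", "B", rep(0.9, 2)))
  expect_equal(callValidationHits(st5)$category, "none")
  # 3 depleting with one significant in both cell lines -> common
  st6 <- rbind(mkstats("R6", "A", c(0.01, 0.08, 0.09)),
               mkstats("R6", "B", c(0.02, 0.07, 0.09)))
  expect_equal(callValidationHits(st6)$category, "common")
  # 3 depleting in one cell line, 2 in the other: neither rule fires
  st7 <- rbind(mkstats("R7", "A", c(0.01, 0.08, 0.09)),
               mkstats("R7", "B", c(0.02, 0.07, 0.9)))
  expect_equal(callValidationHits(st7)$category, "none")
  # positive log2FC guides never count as depleting
  st8 <- rbind(mkstats("R8", "A", c(0.01, 0.02, 0.03), lfc = c(1, 1, -1)),
               mkstats("R8", "B", rep(0.9, 3)))
  expect_equal(callValidationHits(st8)$category, "none")
})

test_that("validation library carries min(topK, depleting) top guides", {
  mkstats <- function(uid, cl, p, lfc)
    data.frame(guide_id = sprintf("%s_g%02d", uid, seq_along(p)),
               union_id = uid, cell_line = cl, log2FC = lfc, p = p,
               stringsAsFactors = FALSE)
  # 3 depleting guides -> all 3 carried (fewer than topK)
  st <- rbind(mkstats("R1", "A", c(0.01, 0.04, 0.08, 0.9), c(-2, -1, -0.5, -3)),
              mkstats("R1", "B", rep(0.9, 4), rep(-1, 4)))
  lib <- designValidationLibrary(st, topK = 4)
  expect_equal(sum(guideInfo(lib)$union_id == "R1"), 3)
  # 6 depleting guides -> the 4 most negative log2FC are selected
  st2 <- rbind(mkstats("R2", "A", rep(0.01, 6), c(-6, -5, -4, -3, -2, -1)),
               mkstats("R2", "B", rep(0.9, 6), rep(-1, 6)))
  lib2 <- designValidationLibrary(st2, topK = 4)
  expect_setequal(guideInfo(lib2)$guide_id,
                  c("R2_g01", "R2_g02", "R2_g03", "R2_g04"))
  expect_error(callValidationHits(st2[, -5]), "lacks columns")
})

test_that("validation design recovers planted hits on synthetic screens", {
  recov <- vapply(1:5, function(seed) {
    lib <- makeTestLibrary(nRegions = 60, nGuides = 10, nNT = 100)
    cfg <- screenSimConfig(nRegions = 60, seed = seed, depthSd = 0,
                           fracCommon = 0.2, fracLineage = 0.15)
    sim <- simulateScreen(lib, cfg)
    nt <- grep("^NT", rownames(sim$se), value = TRUE)
    norm <- normalizeToControls(sim$se, nt)
    # primary screen: one model per lineage
    st <- guideStats(norm, day = 22, library = lib)
    st <- st[st$cell_line %in% c("meso1", "uveal1"), ]
    names(st)[names(st) == "log2FC"] <- "log2FC"
    hits <- callValidationHits(st[, c("guide_id", "union_id", "cell_line",
                                      "log2FC", "p")])
    tr <- sim$truth[!duplicated(sim$truth$union_id) &
                    !is.na(sim$truth$union_id), ]
    planted <- tr$union_id[tr$category != "none"]
    called <- hits$union_id[hits$category != "none"]
    mean(planted %in% called)
  }, numeric(1))
  expect_gte(mean(recov), 0.95)
})
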