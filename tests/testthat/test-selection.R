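## two clusters of the same guide on separate chromosomes, so windows
## isolate them cleanly: 10 copies on chrA, 6 on chrB
twoClusterFixture <- function(seed = 51) {
    set.seed(seed + 1000L)
    spacer <- randomSpacer()
    generateFixture(
        c(chrA = 6000L, chrB = 6000L),
        plants = list(
            plantSpec(spacer, "TGG", copiesOnTarget = 10L,
                      clusterChrom = "chrA", clusterStart = 500L,
                      clusterEnd = 4500L),
            plantSpec(spacer, "AGG", copiesOnTarget = 6L,
                      clusterChrom = "chrB", clusterStart = 500L,
                      clusterEnd = 4500L)),
        seed = seed)
}

selectFor <- function(fx, guide, nBins, k = 6000, minHits = 5L) {
    ht <- findAllHits(fx$genome, guide, maxMismatches = 0L)
    windows <- broadGuide:::.genomeWindows(fx$genome, k, k / 10)
    assigned <- assignHits(ht, windows, minHits = minHits)
    selectBins(ht, assigned, nBins = nBins, windowSize = k)
}

test_that("greedy bin choice targets the densest cluster first", {
    fx <- twoClusterFixture()
    guide <- plantGuide(fx)

    one <- selectFor(fx, guide, nBins = 1L)
    expect_identical(nrow(one$report), 1L)
    expect_identical(one$report$onTargets, 10L)
    expect_identical(one$report$offTargets, 6L)
    expect_identical(as.character(GenomeInfoDb::seqnames(one$bins)), "chrA")

    two <- selectFor(fx, guide, nBins = 2L)
    expect_identical(two$report$onTargets, 16L)
    expect_identical(two$report$offTargets, 0L)
    expect_gt(two$report$score, one$report$score)
    expect_identical(two$report$score, 1)   # all perfect, all on-target

    ## more bins than clusters: everything chosen, shortfall flagged
    three <- selectFor(fx, guide, nBins = 3L)
    expect_identical(three$report$offTargets, 0L)
    expect_true(three$report$binShortfall)
    expect_identical(length(three$bins), 2L)
})

test_that("selected bins never overlap and conserve h + o == t", {
    for (seed in 52:54) {
        fx <- twoClusterFixture(seed)
        sel <- selectFor(fx, plantGuide(fx), nBins = 2L)
        b <- sel$bins
        expect_true(all(GenomicRanges::countOverlaps(b, b) == 1L))
        r <- sel$report
        expect_identical(r$onTargets + r$offTargets, r$totalHits)
    }
})

test_that("ranking orders by score, then on-target hits, then sequence", {
    rep0 <- data.frame(
        guide = c("CCC", "AAA", "BBB", "DDD"),
        score = c(0.5, 0.9, 0.9, 0.5),
        onTargets = c(8L, 12L, 12L, 8L),
        stringsAsFactors = FALSE)
    ranked <- rankGuides(rep0)
    expect_identical(ranked$guide, c("AAA", "BBB", "CCC", "DDD"))
    expect_identical(ranked$rank, 1:4)
    ## permutation: every plan appears exactly once
    expect_setequal(ranked$guide, rep0$guide)

    tie <- data.frame(guide = c("A", "B"), score = c(0.7, 0.7),
                      onTargets = c(8L, 12L), stringsAsFactors = FALSE)
    expect_identical(rankGuides(tie)$guide, c("B", "A"))
})

test_that("pooling merges bins by overlap and the configured gap", {
    bins <- GenomicRanges::GRanges("c1",
        IRanges::IRanges(start = c(1, 50, 300), end = c(100, 150, 400)),
        guide = c("gA", "gB", "gC"), nHits = c(5L, 6L, 7L),
        W = c(5, 6, 7))
    pooled <- poolGuides(bins, mergeGap = 0L)
    expect_identical(length(pooled), 2L)
    expect_identical(S4Vectors::mcols(pooled)$guides, c("gA,gB", "gC"))
    expect_identical(S4Vectors::mcols(pooled)$totalHits, c(11L, 7L))

    ## identical bins from two guides give a single two-guide region
    same <- GenomicRanges::GRanges("c1",
        IRanges::IRanges(start = c(10, 10), end = c(60, 60)),
        guide = c("g1", "g2"), nHits = c(5L, 5L), W = c(5, 5))
    p2 <- poolGuides(same)
    expect_identical(length(p2), 1L)
    expect_identical(S4Vectors::mcols(p2)$nGuides, 2L)

    ## a large enough merge gap joins the distant bins too
    p3 <- poolGuides(bins, mergeGap = 200L)
    expect_identical(length(p3), 1L)

    ## pooling loses no bins: the union of regions covers every bin
    ov <- GenomicRanges::findOverlaps(bins, pooled, type = "within")
    expect_identical(length(unique(S4Vectors::queryHits(ov))), length(bins))
})

test_that("greedy selection equals an independent greedy oracle", {
    greedyOracle <- function(df, nBins) {
        df <- df[order(-df$W, df$ws, df$chrom), , drop = FALSE]
        keep <- list()
        for (i in seq_len(nrow(df))) {
            if (length(keep) >= nBins) break
            ok <- !any(vapply(keep, function(kk)
                kk$chrom == df$chrom[i] && df$ws[i] <= kk$we &&
                df$we[i] >= kk$ws, logical(1)))
            if (ok) keep[[length(keep) + 1L]] <- df[i, ]
        }
        do.call(rbind, keep)
    }
    set.seed(406)
    for (r in 1:25) {
        n <- sample(3:12, 1)
        df <- data.frame(chrom = sample(c("c1", "c2"), n, TRUE),
                         ws = sample(seq(1, 5000, 50), n),
                         W = sample(1:20, n, TRUE) + 0)
        df$we <- df$ws + 999L
        nBins <- sample(1:3, 1)
        norm <- function(d) {
            d <- d[order(d$chrom, d$ws), c("chrom", "ws", "we", "W")]
            rownames(d) <- NULL
            d
        }
        expect_identical(norm(broadGuide:::.greedyBins(df, nBins)),
                         norm(greedyOracle(df, nBins)))
    }
})

test_that("region mode counts outside copies as off-targets", {
    set.seed(501)
    spacer <- randomSpacer()
    fx <- generateFixture(
        c(chrA = 6000L, chrB = 4000L),
        plants = list(plantSpec(spacer, "TGG", copiesOnTarget = 6L,
                                copiesOffTarget = 3L,
                                clusterChrom = "chrA",
                                clusterStart = 500L, clusterEnd = 3000L,
                                offTargetChroms = "chrB")),
        seed = 61)
    regions <- GenomicRanges::GRanges("chrA", IRanges::IRanges(1, 3500))
    res <- restrictToRegions(fx$genome, regions, maxMismatches = 0L,
                             minHits = 5L)
    r <- reportTable(res)
    row <- r[r$guide == plantGuide(fx), ]
    expect_identical(row$onTargets, 6L)
    expect_identical(row$offTargets, 3L)
    expect_identical(row$totalHits, 9L)
})

test_that("a region spanning a whole chromosome reproduces the global hits", {
    fx <- quickFixture(seed = 62, onTarget = 6L)
    regions <- GenomicRanges::GRanges("chrA",
        IRanges::IRanges(1, Biostrings::width(fx$genome)[1]))
    res <- restrictToRegions(fx$genome, regions, maxMismatches = 0L,
                             minHits = 5L)
    ## whole-genome candidate set restricted to chrA-origin guides
    cs <- scanCandidates(fx$genome, PamSpec("NGG"), 20L)
    org <- candidateOrigins(cs)
    chrAguides <- unique(S4Vectors::mcols(org)$fullSeq[
        as.character(GenomeInfoDb::seqnames(org)) == "chrA"])
    regionGuides <- hitCounts(res@hitTable)$guide
    expect_setequal(regionGuides, chrAguides)
    ## per-guide total hit counts agree with a direct whole-genome mapping
    guide <- plantGuide(fx)
    expect_identical(
        hitCounts(res@hitTable)$t[regionGuides == guide],
        hitCounts(findAllHits(fx$genome, guide, 0L))$t)
})

test_that("a region without PAM sites yields an empty, well-formed report", {
    g <- Biostrings::DNAStringSet(c(chrA = strrep("AT", 2000)))
    regions <- GenomicRanges::GRanges("chrA", IRanges::IRanges(1, 1000))
    res <- restrictToRegions(g, regions)
    expect_identical(nrow(reportTable(res)), 0L)
    expect_identical(length(guideBins(res)), 0L)
})

test_that("malformed BED input fails with a clear error", {
    bed <- withr::local_tempfile(fileext = ".bed")
    writeLines(c("chrA\t0\t100", "chrA\tnotanumber\t200"), bed)
    expect_error(readRegionsBed(bed), "malformed|BED")
    g <- Biostrings::DNAStringSet(c(chrA = strrep("ACGT", 100)))
    writeLines("chrZ\t0\t100", bed)
    expect_error(readRegionsBed(bed, g), "unknown chromosome")
})
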