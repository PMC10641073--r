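test_that("planted exact copies are all found with perfect scores", {
    fx <- quickFixture(seed = 21, onTarget = 5L)
    ht <- findAllHits(fx$genome, plantGuide(fx), maxMismatches = 0L)
    df <- hitDF(ht)
    expect_identical(nrow(df), 5L)
    expect_true(all(df$score == 1))
    expect_identical(hitCounts(ht)$t, 5L)
    ## loci equal the manifest exactly
    copies <- fx$manifest$plants[[1]]$copies
    expect_identical(df[, c("chrom", "start", "strand")],
                     {
                         m <- copies[order(copies$chrom, copies$start),
                                     c("chrom", "start", "strand")]
                         rownames(m) <- NULL
                         m
                     })
})

test_that("divergent copies score (L - 2n)/L under the mismatch budget", {
    fx <- quickFixture(seed = 22, onTarget = 7L,
                       profile = c(0L, 0L, 0L, 0L, 0L, 2L, 2L))
    ht <- findAllHits(fx$genome, plantGuide(fx), maxMismatches = 3L)
    df <- hitDF(ht)
    expect_identical(nrow(df), 7L)
    expect_identical(sum(df$mismatches == 0L), 5L)
    expect_identical(sum(df$mismatches == 2L), 2L)
    expect_equal(df$score[df$mismatches == 2L], rep(19 / 23, 2))
    ## a zero-budget search keeps only the exact copies: nested predicates
    ht0 <- findAllHits(fx$genome, plantGuide(fx), maxMismatches = 0L)
    df0 <- hitDF(ht0)
    key <- function(d) paste(d$chrom, d$start, d$strand)
    expect_true(all(key(df0) %in% key(df)))
})

test_that("hit counts are monotone non-decreasing in the mismatch budget", {
    fx <- quickFixture(seed = 23, onTarget = 6L, offTarget = 3L,
                       profile = c(0L, 0L, 1L, 1L, 2L, 3L, 0L, 2L, 3L))
    counts <- vapply(0:3, function(mm)
        hitCounts(findAllHits(fx$genome, plantGuide(fx), mm))$t,
        integer(1))
    expect_true(all(diff(counts) >= 0L))
    expect_identical(counts[1], 3L)   # the three exact copies
    expect_identical(counts[4], 9L)   # every planted copy
})

test_that("mapper equals the brute-force oracle on seeded fixtures", {
    for (seed in 31:36) {
        mm <- seed %% 4L
        fx <- quickFixture(seed = seed, onTarget = 4L, offTarget = 2L,
                           profile = pmin(rep(c(0L, mm), 3L), 3L))
        guide <- plantGuide(fx)
        expect_identical(hitDF(findAllHits(fx$genome, guide, mm)),
                         hitDF(bruteForceHits(fx$genome, guide, mm)),
                         info = seed)
    }
})

test_that("PAM verification is exact at the locus and at chromosome edges", {
    g <- Biostrings::DNAStringSet(c(chrA = paste0(
        strrep("A", 10), "CATCATCATCATCATCATCA", "AGG", strrep("A", 7))))
    guide <- paste0("CATCATCATCATCATCATCA", "AGG")
    hit <- GenomicRanges::GRanges("chrA", IRanges::IRanges(11, 33), "+")
    expect_true(verifyPamAtLocus(g, hit, PamSpec("NGG")))
    ## shifted by one: PAM slice no longer AGG
    bad <- GenomicRanges::GRanges("chrA", IRanges::IRanges(12, 34), "+")
    expect_false(verifyPamAtLocus(g, bad, PamSpec("NGG")))
    ## footprint running past the chromosome end
    edge <- GenomicRanges::GRanges("chrA", IRanges::IRanges(19, 41), "+")
    expect_false(verifyPamAtLocus(g, edge, PamSpec("NGG")))
})

test_that("SAM export/import round-trips the internal hits", {
    fx <- quickFixture(seed = 24, onTarget = 5L, offTarget = 2L,
                       profile = c(0L, 0L, 0L, 1L, 2L, 0L, 1L))
    cs <- scanCandidates(fx$genome, PamSpec("NGG"), spacerLen = 20L)
    ht <- findAllHits(fx$genome, plantGuide(fx), maxMismatches = 3L)
    sam <- withr::local_tempfile(fileext = ".sam")
    exportSamHits(ht, fx$genome, sam)
    back <- importSamHits(sam, cs, fx$genome, maxMismatches = 3L)
    a <- hitDF(ht); b <- hitDF(back)
    expect_identical(a, b)
    gr <- hitRanges(back)
    expect_true(all(S4Vectors::mcols(gr)$gaps == 0L))
    expect_identical(
        S4Vectors::mcols(gr)$matches + S4Vectors::mcols(gr)$mismatches,
        rep(23L, length(gr)))
})

test_that("gapped SAM records yield m, n, g from CIGAR and NM", {
    spacer <- "GATTACAGATTACAGATTAC"
    guide <- paste0(spacer, "TGG")
    ## reference carries one extra base inside the protospacer: 24-base span
    refSite <- paste0(substring(spacer, 1, 10), "A",
                      substring(spacer, 11, 20), "TGG")
    g <- Biostrings::DNAStringSet(c(chrA = paste0("CCCC", refSite, "CCCC")))
    ## a clean mini-genome provides the candidate set for name resolution
    gcs <- Biostrings::DNAStringSet(c(m = paste0("AAAA", guide, "AAAA")))
    cs <- scanCandidates(gcs, PamSpec("NGG"), spacerLen = 20L)

    sam <- withr::local_tempfile(fileext = ".sam")
    writeLines(c("@HD\tVN:1.6\tSO:unsorted",
                 sprintf("@SQ\tSN:chrA\tLN:%d", 8 + nchar(refSite)),
                 sprintf("%s\t0\tchrA\t5\t255\t10M1D13M\t*\t0\t0\t%s\t*\tNM:i:1",
                         guide, guide)), sam)
    ht <- importSamHits(sam, cs, g, maxMismatches = 3L)
    gr <- hitRanges(ht)
    expect_identical(length(gr), 1L)
    expect_identical(S4Vectors::mcols(gr)$gaps, 1L)
    expect_identical(S4Vectors::mcols(gr)$mismatches, 0L)
    expect_identical(S4Vectors::mcols(gr)$matches, 23L)
    expect_equal(S4Vectors::mcols(gr)$score, 22 / 23)
    expect_identical(BiocGenerics::start(gr), 5L)
    expect_identical(BiocGenerics::end(gr), 28L)   # 24-base footprint
})

test_that("unmapped and unresolvable SAM records contribute nothing", {
    fx <- quickFixture(seed = 25, onTarget = 3L)
    cs <- scanCandidates(fx$genome, PamSpec("NGG"), spacerLen = 20L)
    sam <- withr::local_tempfile(fileext = ".sam")
    writeLines(c("@HD\tVN:1.6\tSO:unsorted",
                 sprintf("@SQ\tSN:chrA\tLN:%d",
                         Biostrings::width(fx$genome)[1]),
                 sprintf("@SQ\tSN:chrB\tLN:%d",
                         Biostrings::width(fx$genome)[2]),
                 ## unmapped flag
                 sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t*",
                         plantGuide(fx), plantGuide(fx)),
                 ## name that resolves to no guide
                 "whoAmI\t0\tchrA\t100\t255\t23M\t*\t0\t0\t*\t*\tNM:i:0"),
               sam)
    expect_warning(ht <- importSamHits(sam, cs, fx$genome), "unresolvable")
    expect_identical(length(hitRanges(ht)), 0L)
})

test_that("enumeration stops at the hit cap and flags saturation", {
    fx <- quickFixture(seed = 26, onTarget = 6L)
    ht <- findAllHits(fx$genome, plantGuide(fx), maxMismatches = 0L,
                      hitCap = 3L)
    expect_identical(hitCounts(ht)$t, 3L)
    expect_true(hitCounts(ht)$saturated)
    full <- findAllHits(fx$genome, plantGuide(fx), maxMismatches = 0L)
    expect_false(hitCounts(full)$saturated)
})
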