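## Brute-force extraction oracle: slide over every position and strand,
## check PAM membership, N-freedom and GC by direct string operations.
oracleScan <- function(genome, pattern = "NGG", P = 20L, gcMin = 0,
                       gcMax = 1) {
    q <- nchar(pattern); L <- P + q
    rows <- list()
    for (ch in names(genome)) {
        s <- as.character(genome[[ch]])
        n <- nchar(s)
        if (n < L) next
        for (st in seq_len(n - L + 1L)) {
            slice <- substring(s, st, st + L - 1L)
            if (grepl("N", slice)) next
            gc <- gcContent(slice)
            if (gc < gcMin || gc > gcMax) next
            for (strand in c("+", "-")) {
                oriented <- if (strand == "+") slice else revComp(slice)
                if (iupacMatch(pattern,
                               substring(oriented, P + 1L, L))) {
                    rows[[length(rows) + 1L]] <- data.frame(
                        chrom = ch, start = st, strand = strand,
                        fullSeq = oriented, stringsAsFactors = FALSE)
                }
            }
        }
    }
    df <- if (length(rows)) do.call(rbind, rows) else
        data.frame(chrom = character(0), start = integer(0),
                   strand = character(0), fullSeq = character(0))
    df[order(df$chrom, df$start, df$strand), , drop = FALSE]
}

csDF <- function(cs) {
    org <- candidateOrigins(cs)
    df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(org)),
                     start = BiocGenerics::start(org),
                     strand = as.character(BiocGenerics::strand(org)),
                     fullSeq = S4Vectors::mcols(org)$fullSeq,
                     stringsAsFactors = FALSE)
    df <- df[order(df$chrom, df$start, df$strand), , drop = FALSE]
    rownames(df) <- NULL
    df
}

test_that("extraction matches the exhaustive scan oracle", {
    ## tiny hand-checked genome: exactly one forward NGG site, none on the
    ## reverse strand (no C anywhere for the CCN complement)
    g <- Biostrings::DNAStringSet(c(chrA = "TTTTTTTTTTAGGTTTT"))
    cs <- scanCandidates(g, PamSpec("NGG"), spacerLen = 10L)
    got <- csDF(cs)
    expect_identical(got, data.frame(chrom = "chrA", start = 1L,
                                     strand = "+",
                                     fullSeq = "TTTTTTTTTTAGG",
                                     stringsAsFactors = FALSE))
    orc <- oracleScan(g, "NGG", P = 10L)
    rownames(orc) <- NULL
    expect_identical(got, orc)

    set.seed(301)
    for (r in 1:5) {
        seqs <- c(
            c1 = paste(sample(c("A", "C", "G", "T"), 400, TRUE),
                       collapse = ""),
            c2 = paste(sample(c("A", "C", "G", "T", "N"), 250, TRUE,
                              prob = c(.24, .24, .24, .24, .04)),
                       collapse = ""))
        g <- Biostrings::DNAStringSet(seqs)
        for (pat in c("NGG", "TTTV")) {
            cs <- scanCandidates(g, PamSpec(pat), spacerLen = 12L)
            orc <- oracleScan(g, pat, P = 12L)
            rownames(orc) <- NULL
            expect_identical(csDF(cs), orc, info = paste(r, pat))
        }
    }
})

test_that("a genome without G or C has no NGG candidates", {
    g <- Biostrings::DNAStringSet(c(chrA = strrep("AT", 200)))
    cs <- scanCandidates(g, PamSpec("NGG"), spacerLen = 12L)
    expect_identical(length(candidateOrigins(cs)), 0L)
})

test_that("planted exact copies collapse into one guide with R origins", {
    fx <- quickFixture(seed = 5, onTarget = 5L)
    cs <- scanCandidates(fx$genome, PamSpec("NGG"), spacerLen = 20L)
    gt <- guideTable(cs)
    expect_identical(gt$nOrigins[gt$fullSeq == plantGuide(fx)], 5L)
})

test_that("extraction is strand symmetric", {
    set.seed(302)
    g <- Biostrings::DNAStringSet(c(
        c1 = paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")))
    grc <- Biostrings::reverseComplement(g)
    names(grc) <- names(g)
    a <- sort(S4Vectors::mcols(candidateOrigins(
        scanCandidates(g, PamSpec("NGG"), 12L)))$fullSeq)
    b <- sort(S4Vectors::mcols(candidateOrigins(
        scanCandidates(grc, PamSpec("NGG"), 12L)))$fullSeq)
    expect_identical(a, b)
})

test_that("candidate counts shrink monotonically as the GC band narrows", {
    set.seed(303)
    g <- Biostrings::DNAStringSet(c(
        c1 = paste(sample(c("A", "C", "G", "T"), 800, TRUE), collapse = "")))
    bands <- list(c(0, 1), c(0.1, 0.9), c(0.25, 0.75), c(0.4, 0.6),
                  c(0.5, 0.5))
    counts <- vapply(bands, function(b)
        length(candidateOrigins(scanCandidates(g, PamSpec("NGG"), 12L,
                                               b[1], b[2]))), integer(1))
    expect_true(all(diff(counts) <= 0L))
})

test_that("re-slicing the genome at an origin reproduces the sequence", {
    fx <- quickFixture(seed = 6, onTarget = 5L)
    cs <- scanCandidates(fx$genome, PamSpec("NGG"), spacerLen = 20L)
    org <- candidateOrigins(cs)
    set.seed(304)
    idx <- sample(length(org), min(50L, length(org)))
    for (i in idx) {
        ch <- as.character(GenomeInfoDb::seqnames(org))[i]
        slice <- substring(as.character(fx$genome[[ch]]),
                           BiocGenerics::start(org)[i],
                           BiocGenerics::end(org)[i])
        if (as.character(BiocGenerics::strand(org))[i] == "-")
            slice <- revComp(slice)
        expect_identical(slice, S4Vectors::mcols(org)$fullSeq[i])
    }
})

test_that("the pre-filter report tallies occurrences and unique guides", {
    g <- Biostrings::DNAStringSet(c(chrA = strrep("AT", 100)))
    empty <- prefilterReport(scanCandidates(g, PamSpec("NGG"), 12L))
    expect_identical(empty$passOccurrences, 0L)
    expect_identical(empty$passUnique, 0L)

    fx <- quickFixture(seed = 7, onTarget = 4L)
    cs <- scanCandidates(fx$genome, PamSpec("NGG"), spacerLen = 20L)
    pr <- prefilterReport(cs)
    expect_identical(pr$passOccurrences, length(candidateOrigins(cs)))
    expect_identical(pr$passUnique, length(cs))
    expect_gte(pr$preFilterOccurrences, pr$passOccurrences)

    ## GC-filtered scan reports the unfiltered totals as pre-filter counts
    cs2 <- scanCandidates(fx$genome, PamSpec("NGG"), 20L, gcMin = 0.5)
    pr2 <- prefilterReport(cs2)
    expect_identical(pr2$preFilterOccurrences, pr$preFilterOccurrences)
    expect_lte(pr2$passOccurrences, pr2$preFilterOccurrences)
})

test_that("candidate FASTA export encodes resolvable loci", {
    fx <- quickFixture(seed = 8, onTarget = 3L)
    cs <- scanCandidates(fx$genome, PamSpec("NGG"), spacerLen = 20L)
    fa <- withr::local_tempfile(fileext = ".fa")
    exportCandidatesFasta(cs, fa)
    back <- Biostrings::readDNAStringSet(fa)
    expect_identical(length(back), length(candidateOrigins(cs)))
    expect_match(names(back)[1], "^[^:]+:\\d+-\\d+:[+-]$")
    expect_identical(as.character(back[[1]]),
                     S4Vectors::mcols(candidateOrigins(cs))$fullSeq[1])
})
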