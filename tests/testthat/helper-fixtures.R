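## Shared helpers: random guides, quick fixtures, hit-set comparison.

randomSpacer <- function(n = 20L) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## canonical data.frame view of a hit table, for set comparisons
hitDF <- function(ht) {
    gr <- hitRanges(ht)
    df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                     start = BiocGenerics::start(gr),
                     strand = as.character(BiocGenerics::strand(gr)),
                     mismatches = S4Vectors::mcols(gr)$mismatches,
                     score = S4Vectors::mcols(gr)$score,
                     stringsAsFactors = FALSE)
    df[order(df$chrom, df$start, df$strand), , drop = FALSE] |>
        (\(x) { rownames(x) <- NULL; x })()
}

## fixture with one clustered plant and optional scattered copies
quickFixture <- function(seed, spacer = NULL, onTarget = 6L, offTarget = 0L,
                         profile = NULL, chromA = 8000L, chromB = 4000L,
                         clusterStart = 1000L, clusterEnd = 4000L) {
    if (is.null(spacer)) {
        set.seed(seed + 77L)
        spacer <- randomSpacer()
    }
    generateFixture(
        c(chrA = chromA, chrB = chromB),
        plants = list(plantSpec(spacer, "TGG", copiesOnTarget = onTarget,
                                copiesOffTarget = offTarget,
                                mismatchProfile = profile,
                                clusterChrom = "chrA",
                                clusterStart = clusterStart,
                                clusterEnd = clusterEnd)),
        seed = seed)
}

plantGuide <- function(fx, i = 1L) fx$manifest$plants[[i]]$fullSeq
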