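## Multi-mapping: all genomic alignments of each candidate guide.

.newHitTable <- function(gr, perGuide, maxMismatches, hitCap) {
    ## canonical ordering makes every downstream output deterministic
    o <- order(S4Vectors::mcols(gr)$guide,
               as.integer(match(GenomeInfoDb::seqnames(gr),
                                GenomeInfoDb::seqlevels(gr))),
               BiocGenerics::start(gr),
               as.character(BiocGenerics::strand(gr)))
    gr <- gr[o]
    perGuide <- perGuide[order(perGuide$guide), , drop = FALSE]
    rownames(perGuide) <- NULL
    new("HitTable", hits = gr, perGuide = perGuide,
        maxMismatches = as.integer(maxMismatches),
        hitCap = as.integer(hitCap))
}

.emptyHitGRanges <- function(genome) {
    gr <- GenomicRanges::GRanges()
    GenomeInfoDb::seqlevels(gr) <- names(genome)
    GenomeInfoDb::seqlengths(gr) <- Biostrings::width(genome)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        guide = character(0), matches = integer(0), mismatches = integer(0),
        gaps = integer(0), pamOk = logical(0), score = numeric(0))
    gr
}

#' Find all genomic hits of each candidate guide
#'
#' End-to-end, ungapped search on both strands: a locus is a hit when the
#' protospacer aligns with at most \code{maxMismatches} substitutions and
#' the adjacent PAM matches the pattern exactly (IUPAC degeneracy only,
#' zero PAM mismatches). Uses pigeonhole seeding: the protospacer is split
#' into \code{maxMismatches + 1} exact seed chunks looked up in a k-mer
#' index of the genome, and seed matches are verified by direct
#' comparison. Enumeration per guide stops at \code{hitCap}
#' (\code{saturated} flag). Gapped alignment is available through
#' [importSamHits()].
#'
#' Per-hit scores follow (m - n - g)/L with m the matched bases over the
#' full L-base footprint (the exactly-matched PAM included), n the
#' protospacer substitutions and g = 0 for this ungapped mapper.
#'
#' @param genome a \code{DNAStringSet}.
#' @param guides a [CandidateSet-class], or a character vector of full
#'   guide sequences (protospacer+PAM in guide orientation), in which case
#'   \code{pam} and \code{spacerLen} describe their layout.
#' @param maxMismatches substitution budget in the protospacer, 0--3.
#' @param hitCap per-guide cap on enumerated hits (default 10000).
#' @param pam,spacerLen only used when \code{guides} is a character vector.
#' @return a [HitTable-class]. Guides without hits keep a row with t = 0 in
#'   [hitCounts()].
#' @export
findAllHits <- function(genome, guides, maxMismatches = 3L, hitCap = 10000L,
                        pam = PamSpec("NGG"), spacerLen = 20L) {
    stopifnot(is(genome, "DNAStringSet"))
    maxMismatches <- as.integer(maxMismatches)
    hitCap <- as.integer(hitCap)
    if (maxMismatches < 0L || maxMismatches > 3L)
        stop("maxMismatches must be between 0 and 3")
    if (hitCap < 1L) stop("hitCap must be >= 1")

    if (is(guides, "CandidateSet")) {
        pam <- guides@pamSpec
        spacerLen <- guides@spacerLen
        gt <- guideTable(guides)
        fullSeqs <- gt$fullSeq
        spacers <- gt$protospacer
    } else {
        fullSeqs <- as.character(guides)
        q <- pamLength(pam)
        spacers <- if (pamSide(pam) == "3prime")
            substring(fullSeqs, 1L, spacerLen)
        else substring(fullSeqs, q + 1L, q + spacerLen)
    }
    L <- spacerLen + pamLength(pam)

    perGuide <- data.frame(guide = fullSeqs,
                           t = rep(0L, length(fullSeqs)),
                           saturated = rep(FALSE, length(fullSeqs)),
                           stringsAsFactors = FALSE)
    if (length(fullSeqs) == 0L)
        return(.newHitTable(.emptyHitGRanges(genome), perGuide,
                            maxMismatches, hitCap))

    uspacer <- sort(unique(spacers))
    res <- .pigeonholeMap(as.character(genome), uspacer, pamPattern(pam),
                          pamSide(pam) == "3prime", maxMismatches, hitCap)

    ## expand per-protospacer hits to every guide sharing that protospacer
    map <- data.table::data.table(guide = fullSeqs,
                                  spIdx = match(spacers, uspacer))
    hitsDT <- data.table::data.table(
        spIdx = res$guide, chrom = names(genome)[res$chrom],
        start0 = res$start0, strand = ifelse(res$strand == 0L, "+", "-"),
        mismatches = res$mismatches)
    joined <- merge(map, hitsDT, by = "spIdx", allow.cartesian = TRUE)

    if (nrow(joined) == 0L) {
        gr <- .emptyHitGRanges(genome)
    } else {
        gr <- GenomicRanges::GRanges(
            seqnames = joined$chrom,
            ranges = IRanges::IRanges(start = joined$start0 + 1L,
                                      width = L),
            strand = joined$strand,
            guide = joined$guide,
            matches = L - joined$mismatches,
            mismatches = joined$mismatches,
            gaps = 0L, pamOk = TRUE,
            score = (L - 2 * joined$mismatches) / L)
        GenomeInfoDb::seqlevels(gr) <- names(genome)
        GenomeInfoDb::seqlengths(gr) <- Biostrings::width(genome)
        tt <- joined[, list(t = .N), by = "guide"]
        perGuide$t <- tt$t[match(perGuide$guide, tt$guide)]
        perGuide$t[is.na(perGuide$t)] <- 0L
    }
    perGuide$saturated <- res$saturated[match(spacers, uspacer)][
        match(perGuide$guide, fullSeqs)]
    perGuide$saturated[is.na(perGuide$saturated)] <- FALSE
    .newHitTable(gr, perGuide, maxMismatches, hitCap)
}

#' Verify the PAM at a hit locus
#'
#' Re-slices the genome at each hit footprint and checks that the PAM part
#' (strand-adjusted) matches the pattern exactly. Loci whose footprint
#' leaves no room for the PAM inside the chromosome return \code{FALSE}.
#'
#' @param genome a \code{DNAStringSet}.
#' @param hit a \code{GRanges} of full-footprint hit loci (protospacer +
#'   PAM), stranded.
#' @param pam a [PamSpec-class].
#' @return logical vector, one value per locus.
#' @export
verifyPamAtLocus <- function(genome, hit, pam = PamSpec("NGG")) {
    stopifnot(is(genome, "DNAStringSet"), is(hit, "GRanges"))
    if (length(hit) == 0L) return(logical(0))
    chrom <- as.character(GenomeInfoDb::seqnames(hit))
    lens <- setNames(Biostrings::width(genome), names(genome))
    st <- BiocGenerics::start(hit)
    en <- BiocGenerics::end(hit)
    ok <- chrom %in% names(genome) & st >= 1L &
        !is.na(lens[chrom]) & en <= lens[chrom]
    out <- logical(length(hit))
    if (!any(ok)) return(out)
    seqStrs <- as.character(genome)
    slice <- substring(seqStrs[chrom[ok]], st[ok], en[ok])
    minus <- as.character(BiocGenerics::strand(hit))[ok] == "-"
    slice[minus] <- revComp(slice[minus])
    q <- pamLength(pam)
    Ls <- nchar(slice)
    pamSeq <- if (pamSide(pam) == "3prime")
        substring(slice, Ls - q + 1L, Ls) else substring(slice, 1L, q)
    out[ok] <- iupacMatch(pamPattern(pam), pamSeq)
    out
}

.parseCigar <- function(cigar) {
    ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))
    t(vapply(ops, function(x) {
        len <- as.integer(sub("[A-Z=]$", "", x))
        op <- sub("^\\d+", "", x)
        c(aligned = sum(len[op %in% c("M", "=", "X")]),
          ins = sum(len[op == "I"]),
          del = sum(len[op %in% c("D", "N")]))
    }, integer(3)))
}

#' Import guide alignments from a SAM file
#'
#' Accepts alignments produced by an external end-to-end aligner (or by
#' [exportSamHits()]). Read names must resolve to guides of \code{cs}:
#' either a full guide sequence or an occurrence header written by
#' [exportCandidatesFasta()] (\code{chrom:start-end:strand}). Matches,
#' mismatches and gaps are derived from the CIGAR string and the NM tag
#' (g = inserted + deleted bases, n = NM - g, m = aligned bases - n);
#' gapped alignments are accepted here. The PAM is re-verified against the
#' genome before a record is accepted.
#'
#' @param path SAM file.
#' @param cs the [CandidateSet-class] the reads came from.
#' @param genome the \code{DNAStringSet} the alignments refer to.
#' @param maxMismatches discard alignments with more substitutions.
#' @param hitCap recorded in the result (imports are not truncated).
#' @return a [HitTable-class].
#' @export
importSamHits <- function(path, cs, genome, maxMismatches = 3L,
                          hitCap = 10000L) {
    stopifnot(is(cs, "CandidateSet"), is(genome, "DNAStringSet"))
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
    param <- Rsamtools::ScanBamParam(
        what = c("qname", "flag", "rname", "pos", "cigar"), tag = "NM")
    rec <- Rsamtools::scanBam(bam, param = param)[[1]]

    keep <- !bitwAnd(rec$flag, 4L)          # mapped records only
    qname <- rec$qname[keep]

    ## resolve read names to guides
    org <- candidateOrigins(cs)
    byLocus <- setNames(S4Vectors::mcols(org)$fullSeq, .formatLoci(org))
    fullSeqs <- unique(S4Vectors::mcols(org)$fullSeq)
    guide <- ifelse(qname %in% fullSeqs, qname, byLocus[qname])
    unresolved <- is.na(guide)
    if (any(unresolved))
        warning(sum(unresolved),
                " SAM record(s) with unresolvable read names skipped")

    use <- which(keep)[!unresolved]
    guide <- guide[!unresolved]
    perGuide <- data.frame(guide = sort(fullSeqs), t = 0L,
                           saturated = FALSE, stringsAsFactors = FALSE)
    if (length(use) == 0L)
        return(.newHitTable(.emptyHitGRanges(genome), perGuide,
                            maxMismatches, hitCap))

    cig <- .parseCigar(rec$cigar[use])
    nm <- rec$tag$NM[keep][!unresolved]
    nm[is.na(nm)] <- 0L
    g <- unname(cig[, "ins"] + cig[, "del"])
    n <- unname(pmax(0L, nm - g))
    m <- unname(cig[, "aligned"] - n)
    refSpan <- unname(cig[, "aligned"] + cig[, "del"])
    strand <- ifelse(bitwAnd(rec$flag[use], 16L), "-", "+")
    L <- nchar(guide)

    gr <- GenomicRanges::GRanges(
        seqnames = as.character(rec$rname[use]),
        ranges = IRanges::IRanges(start = rec$pos[use], width = refSpan),
        strand = strand, guide = guide,
        matches = as.integer(m), mismatches = as.integer(n),
        gaps = as.integer(g), pamOk = FALSE,
        score = (m - n - g) / L)
    GenomeInfoDb::seqlevels(gr) <- names(genome)
    GenomeInfoDb::seqlengths(gr) <- Biostrings::width(genome)

    S4Vectors::mcols(gr)$pamOk <- verifyPamAtLocus(genome, gr, cs@pamSpec)
    gr <- gr[S4Vectors::mcols(gr)$pamOk &
             S4Vectors::mcols(gr)$mismatches <= maxMismatches]
    key <- paste(S4Vectors::mcols(gr)$guide,
                 GenomeInfoDb::seqnames(gr), BiocGenerics::start(gr),
                 BiocGenerics::strand(gr))
    gr <- gr[!duplicated(key)]

    tt <- table(S4Vectors::mcols(gr)$guide)
    perGuide$t <- as.integer(tt[perGuide$guide])
    perGuide$t[is.na(perGuide$t)] <- 0L
    .newHitTable(gr, perGuide, maxMismatches, hitCap)
}

#' Export a hit table as SAM
#'
#' Writes the internal mapper's hits in SAM format (ungapped, CIGAR
#' \code{<L>M}, NM = substitution count) so they can be compared with
#' external aligner output or re-imported with [importSamHits()].
#'
#' @param ht a [HitTable-class].
#' @param genome the \code{DNAStringSet} the hits refer to.
#' @param path output SAM path.
#' @return \code{path}, invisibly.
#' @export
exportSamHits <- function(ht, genome, path) {
    stopifnot(is(ht, "HitTable"), is(genome, "DNAStringSet"))
    gr <- hitRanges(ht)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("@HD\tVN:1.6\tSO:unsorted", con)
    for (i in seq_along(genome))
        writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(genome)[i],
                           Biostrings::width(genome)[i]), con)
    if (length(gr)) {
        mc <- S4Vectors::mcols(gr)
        minus <- as.character(BiocGenerics::strand(gr)) == "-"
        seqs <- mc$guide
        seqs[minus] <- revComp(seqs[minus])
        writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                           mc$guide, ifelse(minus, 16L, 0L),
                           as.character(GenomeInfoDb::seqnames(gr)),
                           BiocGenerics::start(gr), nchar(mc$guide),
                           seqs, mc$mismatches), con)
    }
    invisible(path)
}
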