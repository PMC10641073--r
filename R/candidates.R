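## Candidate extraction: every PAM-anchored protospacer on both strands,
## including overlapping occurrences.

## Per-chromosome scan. Works on the plain character level with cumulative
## sums so the cost is O(n) per pattern position regardless of how many
## sites match. Returns a data.table of 1-based site starts with strand and
## oriented sequences.
.scanChrom <- function(seqStr, chrom, pam, spacerLen, gcMin, gcMax) {
    P <- spacerLen
    q <- nchar(pamPattern(pam))
    L <- P + q
    n <- nchar(seqStr)
    if (n < L) {
        warning("chromosome '", chrom, "' shorter than guide length ",
                L, "; skipped")
        return(NULL)
    }
    v <- strsplit(seqStr, "")[[1]]
    sets <- .iupacSets()
    starts <- seq_len(n - L + 1L)

    patF <- strsplit(pamPattern(pam), "")[[1]]
    patR <- strsplit(as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(pamPattern(pam)))), "")[[1]]
    ## offset of the PAM inside the site footprint, per strand
    offF <- if (pamSide(pam) == "3prime") P else 0L
    offR <- if (pamSide(pam) == "3prime") 0L else P

    matchAt <- function(pat, off) {
        ok <- rep(TRUE, length(starts))
        for (j in seq_along(pat))
            ok <- ok & (v[starts + off + (j - 1L)] %in% sets[[pat[j]]])
        ok
    }
    okF <- matchAt(patF, offF)
    okR <- matchAt(patR, offR)

    csN <- c(0L, cumsum(v == "N"))
    csGC <- c(0L, cumsum(v %in% c("G", "C")))
    noN <- (csN[starts + L] - csN[starts]) == 0L
    gc <- (csGC[starts + L] - csGC[starts]) / L
    gcOK <- gc >= gcMin & gc <= gcMax

    keepF <- okF & noN & gcOK
    keepR <- okR & noN & gcOK
    if (!any(keepF) && !any(keepR)) return(NULL)

    one <- function(keep, strand) {
        st <- starts[keep]
        if (!length(st)) return(NULL)
        slice <- substring(seqStr, st, st + L - 1L)
        fullSeq <- if (strand == "+") slice else revComp(slice)
        data.table::data.table(chrom = chrom, start = st, end = st + L - 1L,
                               strand = strand, fullSeq = fullSeq,
                               gc = gc[keep])
    }
    data.table::rbindlist(list(one(keepF, "+"), one(keepR, "-")))
}

#' Extract all PAM-anchored candidate guides from a genome
#'
#' Scans both strands of every chromosome for protospacers flanked by the
#' PAM pattern, keeping overlapping occurrences. Sites overlapping an
#' \code{N} are discarded; the GC filter (bounds inclusive) applies to the
#' full protospacer+PAM sequence. Identical full sequences from different
#' loci collapse into a single guide with multiple origins.
#'
#' @param genome a \code{DNAStringSet} from [readGenome()].
#' @param pam a [PamSpec-class] (default Cas9 \code{NGG}, 3').
#' @param spacerLen protospacer length in bases (default 20).
#' @param gcMin,gcMax GC-content bounds on the full sequence, in \[0, 1\].
#' @return a [CandidateSet-class].
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "TTTTAGGTTTT"))
#' scanCandidates(g, PamSpec("NGG"), spacerLen = 4)
#' @export
scanCandidates <- function(genome, pam = PamSpec("NGG"), spacerLen = 20L,
                           gcMin = 0, gcMax = 1) {
    stopifnot(is(genome, "DNAStringSet"), is(pam, "PamSpec"))
    spacerLen <- as.integer(spacerLen)
    if (spacerLen < 10L)
        stop("protospacer length must be at least 10")
    if (!(gcMin >= 0 && gcMin <= gcMax && gcMax <= 1))
        stop("require 0 <= gcMin <= gcMax <= 1")

    P <- spacerLen
    q <- pamLength(pam)
    seqStrs <- as.character(genome)
    parts <- lapply(names(genome), function(ch)
        .scanChrom(seqStrs[[ch]], ch, pam, spacerLen, 0, 1))
    all <- data.table::rbindlist(parts)

    preOcc <- if (is.null(all) || nrow(all) == 0L) 0L else nrow(all)
    preUniq <- if (preOcc == 0L) 0L else length(unique(all$fullSeq))
    if (preOcc > 0L)
        all <- all[all$gc >= gcMin & all$gc <= gcMax, ]

    if (is.null(all) || nrow(all) == 0L) {
        gr <- GenomicRanges::GRanges()
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            fullSeq = character(0), protospacer = character(0),
            pam = character(0), gc = numeric(0))
    } else {
        data.table::setorderv(all, c("chrom", "start", "strand"))
        spacer <- if (pamSide(pam) == "3prime")
            substring(all$fullSeq, 1L, P)
        else substring(all$fullSeq, q + 1L, q + P)
        pamSeq <- if (pamSide(pam) == "3prime")
            substring(all$fullSeq, P + 1L, P + q)
        else substring(all$fullSeq, 1L, q)
        gr <- GenomicRanges::GRanges(
            seqnames = all$chrom,
            ranges = IRanges::IRanges(start = all$start, end = all$end),
            strand = all$strand,
            fullSeq = all$fullSeq, protospacer = spacer, pam = pamSeq,
            gc = all$gc)
        GenomeInfoDb::seqlevels(gr) <- names(genome)
        GenomeInfoDb::seqlengths(gr) <- Biostrings::width(genome)
    }
    S4Vectors::metadata(gr)$preFilter <-
        list(occurrences = preOcc, uniqueSeqs = preUniq)
    new("CandidateSet", origins = gr, pamSpec = pam, spacerLen = spacerLen,
        gcBounds = c(gcMin, gcMax))
}

#' Candidate pre-filter summary
#'
#' Occurrence and unique-sequence tallies before and after the GC filter,
#' in the spirit of a pre-filtered gRNA count table. "Occurrences" counts
#' genomic loci; "unique" counts distinct full sequences.
#'
#' @param cs a [CandidateSet-class].
#' @return a one-row \code{data.frame}.
#' @export
prefilterReport <- function(cs) {
    stopifnot(is(cs, "CandidateSet"))
    pre <- S4Vectors::metadata(cs@origins)$preFilter
    if (is.null(pre)) pre <- list(occurrences = NA_integer_,
                                  uniqueSeqs = NA_integer_)
    data.frame(preFilterOccurrences = pre$occurrences,
               preFilterUnique = pre$uniqueSeqs,
               passOccurrences = length(cs@origins),
               passUnique = length(cs),
               gcMin = cs@gcBounds[1], gcMax = cs@gcBounds[2])
}

#' Export candidate occurrences as FASTA
#'
#' One record per genomic occurrence; headers encode the locus as
#' \code{chrom:start-end:strand} (1-based inclusive) so external aligner
#' output can be resolved back to guides by [importSamHits()].
#'
#' @param cs a [CandidateSet-class].
#' @param path output FASTA path.
#' @return \code{path}, invisibly.
#' @export
exportCandidatesFasta <- function(cs, path) {
    stopifnot(is(cs, "CandidateSet"))
    gr <- cs@origins
    seqs <- Biostrings::DNAStringSet(S4Vectors::mcols(gr)$fullSeq)
    names(seqs) <- .formatLoci(gr)
    Biostrings::writeXStringSet(seqs, path)
    invisible(path)
}
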