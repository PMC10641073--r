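## S4 classes shared across the pipeline stages.

#' PAM specification
#'
#' Describes the protospacer-adjacent motif required next to every candidate
#' protospacer: an IUPAC pattern (e.g. \code{"NGG"} for SpCas9,
#' \code{"TTTV"} for Cas12a) and the side of the protospacer it sits on.
#' The PAM is always matched exactly (IUPAC degeneracy only, no mismatch
#' budget); a genomic \code{N} is matched by nothing except a pattern
#' \code{N}.
#'
#' @slot pattern single IUPAC string.
#' @slot side \code{"3prime"} (Cas9-style, PAM downstream of the
#'   protospacer) or \code{"5prime"} (Cas12a-style, PAM upstream).
#'
#' @examples
#' PamSpec("NGG")
#' PamSpec("TTTV", side = "5prime")
#' @export
setClass("PamSpec", representation(pattern = "character", side = "character"))

setValidity("PamSpec", function(object) {
    msg <- NULL
    if (length(object@pattern) != 1L || is.na(object@pattern) ||
        nchar(object@pattern) < 1L)
        msg <- c(msg, "'pattern' must be a single non-empty string")
    else {
        chars <- strsplit(object@pattern, "")[[1]]
        bad <- setdiff(chars, names(Biostrings::IUPAC_CODE_MAP))
        if (length(bad))
            msg <- c(msg, paste0("invalid IUPAC code(s) in PAM pattern: ",
                                 paste(unique(bad), collapse = ", ")))
    }
    if (length(object@side) != 1L || !object@side %in% c("3prime", "5prime"))
        msg <- c(msg, "'side' must be \"3prime\" or \"5prime\"")
    if (is.null(msg)) TRUE else msg
})

#' @param pattern IUPAC motif string.
#' @param side \code{"3prime"} or \code{"5prime"}.
#' @rdname PamSpec-class
#' @export
PamSpec <- function(pattern = "NGG", side = c("3prime", "5prime")) {
    side <- match.arg(side)
    new("PamSpec", pattern = toupper(pattern), side = side)
}

#' @rdname PamSpec-class
#' @param object,x a \code{PamSpec}.
#' @export
setGeneric("pamPattern", function(x) standardGeneric("pamPattern"))
#' @rdname PamSpec-class
#' @export
setMethod("pamPattern", "PamSpec", function(x) x@pattern)

#' @rdname PamSpec-class
#' @export
setGeneric("pamSide", function(x) standardGeneric("pamSide"))
#' @rdname PamSpec-class
#' @export
setMethod("pamSide", "PamSpec", function(x) x@side)

#' @rdname PamSpec-class
#' @export
setGeneric("pamLength", function(x) standardGeneric("pamLength"))
#' @rdname PamSpec-class
#' @export
setMethod("pamLength", "PamSpec", function(x) nchar(x@pattern))

setMethod("show", "PamSpec", function(object) {
    cat("PamSpec: ", object@pattern, " (", object@side, ", ",
        nchar(object@pattern), " nt)\n", sep = "")
})


#' Candidate guide set
#'
#' All PAM-anchored candidate protospacers extracted from a genome.
#' \code{origins} holds one range per genomic occurrence (the full
#' protospacer+PAM footprint) with metadata columns \code{fullSeq},
#' \code{protospacer}, \code{pam} (the realized PAM at that locus) and
#' \code{gc}; identical full sequences at different loci share a
#' \code{fullSeq} and collapse into one guide.
#'
#' @slot origins \code{GRanges} of genomic occurrences.
#' @slot pamSpec the [PamSpec-class] used for extraction.
#' @slot spacerLen protospacer length in bases.
#' @slot gcBounds numeric length-2, the GC filter applied at extraction.
#'
#' @seealso [scanCandidates()], [guideTable()], [prefilterReport()]
#' @export
setClass("CandidateSet",
         representation(origins = "GRanges", pamSpec = "PamSpec",
                        spacerLen = "integer", gcBounds = "numeric"))

setValidity("CandidateSet", function(object) {
    msg <- NULL
    need <- c("fullSeq", "protospacer", "pam", "gc")
    if (!all(need %in% colnames(S4Vectors::mcols(object@origins))))
        msg <- c(msg, paste("origins must carry mcols:",
                            paste(need, collapse = ", ")))
    if (length(object@spacerLen) != 1L || object@spacerLen < 1L)
        msg <- c(msg, "'spacerLen' must be a single positive integer")
    if (length(object@gcBounds) != 2L || object@gcBounds[1] > object@gcBounds[2])
        msg <- c(msg, "'gcBounds' must be c(min, max) with min <= max")
    if (is.null(msg)) TRUE else msg
})

#' @rdname CandidateSet-class
#' @param x a \code{CandidateSet}.
#' @export
setGeneric("candidateOrigins", function(x) standardGeneric("candidateOrigins"))
#' @rdname CandidateSet-class
#' @export
setMethod("candidateOrigins", "CandidateSet", function(x) x@origins)

#' @rdname CandidateSet-class
#' @export
setGeneric("guideTable", function(x) standardGeneric("guideTable"))
#' @rdname CandidateSet-class
#' @export
setMethod("guideTable", "CandidateSet", function(x) {
    mc <- S4Vectors::mcols(x@origins)
    dt <- data.table::data.table(fullSeq = mc$fullSeq,
                                 protospacer = mc$protospacer,
                                 gc = mc$gc)
    out <- dt[, list(protospacer = protospacer[1L], gc = gc[1L],
                     nOrigins = .N), by = "fullSeq"]
    data.table::setorderv(out, "fullSeq")
    as.data.frame(out)
})

setMethod("length", "CandidateSet",
          function(x) length(unique(S4Vectors::mcols(x@origins)$fullSeq)))

setMethod("show", "CandidateSet", function(object) {
    cat("CandidateSet:", length(object@origins), "occurrences,",
        length(object), "unique guides\n")
    cat("  PAM ", object@pamSpec@pattern, " (", object@pamSpec@side,
        "), protospacer ", object@spacerLen, " nt, GC in [",
        object@gcBounds[1], ", ", object@gcBounds[2], "]\n", sep = "")
})


#' Table of genomic hits for a set of guides
#'
#' One range per alignment of a guide (full protospacer+PAM footprint),
#' with metadata columns \code{guide} (the guide's full sequence),
#' \code{matches}, \code{mismatches}, \code{gaps}, \code{pamOk} and
#' \code{score}, the per-hit score (matches - mismatches - gaps) / L.
#' \code{perGuide} summarizes the total hit count t per guide and whether
#' enumeration stopped at the hit cap (\code{saturated}).
#'
#' @slot hits \code{GRanges} of alignments.
#' @slot perGuide \code{data.frame} with columns guide, t, saturated.
#' @slot maxMismatches the mismatch budget used.
#' @slot hitCap per-guide cap on enumerated hits.
#'
#' @seealso [findAllHits()], [importSamHits()]
#' @export
setClass("HitTable",
         representation(hits = "GRanges", perGuide = "data.frame",
                        maxMismatches = "integer", hitCap = "integer"))

setValidity("HitTable", function(object) {
    msg <- NULL
    need <- c("guide", "matches", "mismatches", "gaps", "pamOk", "score")
    if (!all(need %in% colnames(S4Vectors::mcols(object@hits))))
        msg <- c(msg, paste("hits must carry mcols:",
                            paste(need, collapse = ", ")))
    else {
        key <- paste(S4Vectors::mcols(object@hits)$guide,
                     GenomeInfoDb::seqnames(object@hits),
                     BiocGenerics::start(object@hits),
                     BiocGenerics::strand(object@hits))
        if (anyDuplicated(key))
            msg <- c(msg, "duplicate (guide, chrom, start, strand) hits")
    }
    if (!all(c("guide", "t", "saturated") %in% colnames(object@perGuide)))
        msg <- c(msg, "perGuide needs columns guide, t, saturated")
    if (is.null(msg)) TRUE else msg
})

#' @rdname HitTable-class
#' @param x a \code{HitTable}.
#' @export
setGeneric("hitRanges", function(x) standardGeneric("hitRanges"))
#' @rdname HitTable-class
#' @export
setMethod("hitRanges", "HitTable", function(x) x@hits)

#' @rdname HitTable-class
#' @export
setGeneric("hitCounts", function(x) standardGeneric("hitCounts"))
#' @rdname HitTable-class
#' @export
setMethod("hitCounts", "HitTable", function(x) x@perGuide)

setMethod("length", "HitTable", function(x) length(x@hits))

setMethod("show", "HitTable", function(object) {
    cat("HitTable:", length(object@hits), "hits for",
        nrow(object@perGuide), "guides (max mismatches",
        object@maxMismatches, ")\n")
    nsat <- sum(object@perGuide$saturated)
    if (nsat) cat("  ", nsat, "guide(s) saturated at hit cap",
                  object@hitCap, "\n")
})


#' Result of a broadGuide run
#'
#' Holds the ranked per-guide report, the selected target bins, the pooled
#' multi-guide regions, the underlying hit table and the run configuration.
#'
#' @slot report ranked \code{data.frame}, one row per retained guide.
#' @slot bins \code{GRanges} of selected target bins (mcol \code{guide},
#'   \code{W}, \code{nHits}).
#' @slot pooled \code{GRanges} of merged regions across guides.
#' @slot hitTable the [HitTable-class] the scores were computed from.
#' @slot config the validated run configuration (a named list).
#'
#' @seealso [runBroadGuide()], [reportTable()], [writeReport()]
#' @export
setClass("BroadGuideResult",
         representation(report = "data.frame", bins = "GRanges",
                        pooled = "GRanges", hitTable = "HitTable",
                        config = "list"))

#' @rdname BroadGuideResult-class
#' @param x a \code{BroadGuideResult}.
#' @export
setGeneric("reportTable", function(x) standardGeneric("reportTable"))
#' @rdname BroadGuideResult-class
#' @export
setMethod("reportTable", "BroadGuideResult", function(x) x@report)

#' @rdname BroadGuideResult-class
#' @export
setGeneric("guideBins", function(x) standardGeneric("guideBins"))
#' @rdname BroadGuideResult-class
#' @export
setMethod("guideBins", "BroadGuideResult", function(x) x@bins)

#' @rdname BroadGuideResult-class
#' @export
setGeneric("pooledRegions", function(x) standardGeneric("pooledRegions"))
#' @rdname BroadGuideResult-class
#' @export
setMethod("pooledRegions", "BroadGuideResult", function(x) x@pooled)

#' @rdname BroadGuideResult-class
#' @export
setGeneric("runConfig", function(x) standardGeneric("runConfig"))
#' @rdname BroadGuideResult-class
#' @export
setMethod("runConfig", "BroadGuideResult", function(x) x@config)

setMethod("show", "BroadGuideResult", function(object) {
    cat("BroadGuideResult:", nrow(object@report), "ranked guides,",
        length(object@bins), "target bins,",
        length(object@pooled), "pooled regions\n")
    if (nrow(object@report)) {
        top <- utils::head(object@report, 3L)
        cat("  top guides:\n")
        for (i in seq_len(nrow(top)))
            cat(sprintf("   %2d. %s  S=%.4f  h=%d o=%d\n", top$rank[i],
                        top$guide[i], top$score[i], top$onTargets[i],
                        top$offTargets[i]))
    }
})
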