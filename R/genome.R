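## Genome ingestion, coordinate conventions, IUPAC matching.
##
## Coordinates are 0-based half-open internally (the `start0`/`end0`
## convention used in intermediate tables); GRanges objects use the usual
## 1-based closed Bioconductor convention and user-facing reports print
## 1-based inclusive coordinates.

## Allowed-base sets per IUPAC code. A genomic N is matched by nothing
## except a pattern N (unknown sequence must not satisfy a concrete motif).
.iupacSets <- function() {
    sets <- strsplit(Biostrings::IUPAC_CODE_MAP, "")
    sets[["N"]] <- c("A", "C", "G", "T", "N")
    sets
}

#' Read a (multi-)FASTA genome
#'
#' Sequences are uppercased; IUPAC ambiguity codes are normalized to
#' \code{N}; any character that is not a nucleotide code is a fatal error
#' naming the offending record. Record order is preserved.
#'
#' @param path path to a FASTA file (gzip accepted).
#' @return a [Biostrings::DNAStringSet] over the alphabet \{A,C,G,T,N\}.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtACGT", ">chr2", "NNNRN"), fa)
#' g <- readGenome(fa)
#' width(g)
#' @export
readGenome <- function(path) {
    if (!file.exists(path)) stop("genome FASTA not found: ", path)
    raw <- Biostrings::readBStringSet(path)
    if (length(raw) == 0L) stop("empty FASTA file: ", path)
    nm <- sub("\\s.*$", "", names(raw))
    if (any(!nzchar(nm))) stop("FASTA record with empty name in ", path)
    if (anyDuplicated(nm))
        stop("duplicate FASTA record name(s): ",
             paste(unique(nm[duplicated(nm)]), collapse = ", "))
    seqs <- toupper(as.character(raw))
    ## ambiguity codes (incl. gap-free IUPAC letters) become N; anything
    ## else is not nucleotide sequence
    seqs <- gsub("[MRWSYKVHDB]", "N", seqs)
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad)) {
        ex <- regmatches(seqs[bad][1L], regexpr("[^ACGTN]", seqs[bad][1L]))
        stop("non-nucleotide character '", ex, "' in FASTA record '",
             nm[bad][1L], "'")
    }
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- nm
    out
}

#' Reverse complement of a DNA string
#'
#' @param seq character vector over \{A,C,G,T,N\}; \code{N} maps to
#'   \code{N}.
#' @return character vector of reverse complements.
#' @examples
#' revComp("AAAC")   # "GTTT"
#' @export
revComp <- function(seq) {
    if (any(grepl("[^ACGTN]", seq)))
        stop("revComp: sequence contains characters outside {A,C,G,T,N}")
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Match a DNA string against an IUPAC pattern
#'
#' Position-wise exact matching under IUPAC degeneracy: position i matches
#' iff the sequence base is in the pattern code's allowed set. A genomic
#' \code{N} matches only a pattern \code{N}.
#'
#' @param pattern single IUPAC string.
#' @param seq character vector of sequences, each the same length as
#'   \code{pattern}.
#' @return logical vector.
#' @examples
#' iupacMatch("NGG", c("AGG", "AGT"))   # TRUE FALSE
#' iupacMatch("TTTV", "TTTG")           # TRUE
#' @export
iupacMatch <- function(pattern, seq) {
    stopifnot(length(pattern) == 1L)
    pattern <- toupper(pattern)
    pchars <- strsplit(pattern, "")[[1]]
    sets <- .iupacSets()
    if (any(!pchars %in% names(sets)))
        stop("invalid IUPAC code in pattern: ", pattern)
    if (length(seq) == 0L) return(logical(0))
    if (any(nchar(seq) != nchar(pattern)))
        stop("iupacMatch: pattern and sequence lengths differ")
    sm <- do.call(rbind, strsplit(toupper(seq), ""))
    ok <- rep(TRUE, length(seq))
    for (j in seq_along(pchars))
        ok <- ok & sm[, j] %in% sets[[pchars[j]]]
    ok
}

#' GC content of DNA strings
#'
#' Fraction (G + C) / length; \code{N} counts toward the length but is
#' neither G nor C.
#'
#' @param seq character vector of non-empty DNA strings.
#' @return numeric vector in \[0, 1\].
#' @examples
#' gcContent(c("GGCC", "ATAT", "ACGT"))   # 1 0 0.5
#' @export
gcContent <- function(seq) {
    if (any(!nzchar(seq)) || any(is.na(seq)))
        stop("gcContent: empty sequence")
    nchar(gsub("[^GCgc]", "", seq)) / nchar(seq)
}

#' Read a BED file of regions
#'
#' BED3/BED6 accepted. Returns a GRanges (1-based closed, as usual for
#' Bioconductor); input BED is 0-based half-open.
#'
#' @param path path to a BED file.
#' @param genome optional \code{DNAStringSet}; when given, regions are
#'   checked against chromosome names and bounds.
#' @return a \code{GRanges}.
#' @export
readRegionsBed <- function(path, genome = NULL) {
    if (!file.exists(path)) stop("BED file not found: ", path)
    gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                   error = function(e)
                       stop("malformed BED file ", path, ": ",
                            conditionMessage(e)))
    if (!is.null(genome)) {
        bad <- !as.character(GenomeInfoDb::seqnames(gr)) %in% names(genome)
        if (any(bad))
            stop("BED region references unknown chromosome: ",
                 paste(unique(as.character(
                     GenomeInfoDb::seqnames(gr))[bad]), collapse = ", "))
        lens <- setNames(Biostrings::width(genome), names(genome))
        if (any(BiocGenerics::end(gr) >
                lens[as.character(GenomeInfoDb::seqnames(gr))]))
            stop("BED region extends beyond chromosome end")
    }
    gr
}

## "chrom:start-end:strand" with 1-based inclusive coordinates, the format
## used in the report's hit-coordinate column.
.formatLoci <- function(gr) {
    if (length(gr) == 0L) return(character(0))
    sprintf("%s:%d-%d:%s", as.character(GenomeInfoDb::seqnames(gr)),
            BiocGenerics::start(gr), BiocGenerics::end(gr),
            as.character(BiocGenerics::strand(gr)))
}
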