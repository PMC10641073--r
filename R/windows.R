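## Sliding-window assignment and the window / aggregate scores.

#' Sliding windows over a chromosome
#'
#' Windows of size \code{k} advanced by \code{step}, in 0-based half-open
#' arithmetic: full windows \code{[i*step, i*step + k)} while they fit;
#' when they do not already reach the chromosome end, one final window
#' clipped at the end is added if it is at least \code{step} long (a
#' chromosome shorter than \code{k} yields the single window
#' \code{[0, len)}). The union of windows covers the chromosome whenever
#' \code{step <= k/2}.
#'
#' @param chromLen chromosome length in bases.
#' @param k window size in bases.
#' @param step advance in bases, \code{0 < step <= k}.
#' @param chrom chromosome name used in the returned \code{GRanges}.
#' @return a \code{GRanges} (1-based closed coordinates).
#' @examples
#' tileWindows(100, k = 50, step = 25)
#' @export
tileWindows <- function(chromLen, k, step = max(1L, k %/% 10L),
                        chrom = "chr") {
    chromLen <- as.numeric(chromLen)
    k <- as.numeric(k); step <- as.numeric(step)
    if (chromLen < 1) stop("chromLen must be >= 1")
    if (!(step > 0 && step <= k)) stop("require 0 < step <= k")
    if (chromLen < k) {
        starts0 <- 0; ends0 <- chromLen
    } else {
        nFull <- floor((chromLen - k) / step) + 1
        starts0 <- (seq_len(nFull) - 1) * step
        ends0 <- starts0 + k
        lastEnd <- (nFull - 1) * step + k
        tail0 <- nFull * step
        if (lastEnd < chromLen && chromLen - tail0 >= step) {
            starts0 <- c(starts0, tail0)
            ends0 <- c(ends0, chromLen)
        }
    }
    GenomicRanges::GRanges(chrom,
        IRanges::IRanges(start = starts0 + 1, end = ends0))
}

.genomeWindows <- function(genome, k, step) {
    grl <- lapply(names(genome), function(ch)
        tileWindows(Biostrings::width(genome)[match(ch, names(genome))],
                    k, step, chrom = ch))
    gr <- suppressWarnings(do.call(c, grl))
    GenomeInfoDb::seqlevels(gr) <- names(genome)
    GenomeInfoDb::seqlengths(gr) <- Biostrings::width(genome)
    gr
}

#' Assign hits to windows and keep multi-hit windows
#'
#' A hit belongs to a window iff its start position lies inside the
#' half-open window interval. Per guide, windows holding fewer than
#' \code{minHits} (or more than \code{maxHits}) hits are dropped; guides
#' left without any retained window disappear from the result.
#'
#' @param ht a [HitTable-class].
#' @param windows \code{GRanges} of windows (e.g. from [tileWindows()]).
#' @param minHits minimum hits per retained window (default 5).
#' @param maxHits optional upper bound (default unlimited).
#' @return a \code{GRanges} of retained (guide, window) pairs with mcols
#'   \code{guide}, \code{nHits} and \code{W} (the window score).
#' @export
assignHits <- function(ht, windows, minHits = 5L, maxHits = Inf) {
    stopifnot(is(ht, "HitTable"), is(windows, "GRanges"))
    if (minHits < 1L) stop("minHits must be >= 1")
    gr <- hitRanges(ht)
    if (length(gr) == 0L || length(windows) == 0L)
        return(GenomicRanges::GRanges(guide = character(0),
                                      nHits = integer(0), W = numeric(0)))
    pts <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(gr),
        IRanges::IRanges(start = BiocGenerics::start(gr), width = 1L))
    ov <- GenomicRanges::findOverlaps(pts, windows, ignore.strand = TRUE)
    if (length(ov) == 0L)
        return(GenomicRanges::GRanges(guide = character(0),
                                      nHits = integer(0), W = numeric(0)))
    dt <- data.table::data.table(
        guide = S4Vectors::mcols(gr)$guide[S4Vectors::queryHits(ov)],
        win = S4Vectors::subjectHits(ov),
        score = S4Vectors::mcols(gr)$score[S4Vectors::queryHits(ov)])
    agg <- dt[, list(nHits = .N, W = sum(score)), by = c("guide", "win")]
    agg <- agg[agg$nHits >= minHits & agg$nHits <= maxHits, ]
    if (nrow(agg) == 0L)
        return(GenomicRanges::GRanges(guide = character(0),
                                      nHits = integer(0), W = numeric(0)))
    out <- windows[agg$win]
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
        guide = agg$guide, nHits = agg$nHits, W = agg$W)
    o <- order(S4Vectors::mcols(out)$guide,
               as.integer(match(GenomeInfoDb::seqnames(out),
                                GenomeInfoDb::seqlevels(out))),
               BiocGenerics::start(out))
    out[o]
}

#' Window score
#'
#' The sum over contained hits of the per-hit score
#' \eqn{(m - n - g)/L}: linear in the matches, penalizing mismatches and
#' gaps equally at every position.
#'
#' @param hitScores numeric vector of per-hit scores of the hits in the
#'   window.
#' @return the exact sum.
#' @examples
#' windowScore(c(1, (20 - 3)/23))
#' @export
windowScore <- function(hitScores) {
    if (length(hitScores) == 0L) stop("window has no hits")
    sum(hitScores)
}

## population standard deviation
.sdPop <- function(x) {
    n <- length(x)
    if (n < 2L) return(0)
    sqrt(sum((x - mean(x))^2) / n)
}

#' Evenness of hit positions within a window
#'
#' Ratio of the positional standard deviation of the hits to the standard
#' deviation of a uniform distribution over the window (\eqn{k/\sqrt{12}}),
#' capped at 1. All hits at one position give 0; hits spread uniformly give
#' values near 1.
#'
#' @param positions hit start positions (any common origin; the measure is
#'   translation invariant).
#' @param k window size in bases.
#' @return evenness in \[0, 1\].
#' @export
evenness <- function(positions, k) {
    if (length(positions) < 1L) stop("evenness needs at least one hit")
    min(1, .sdPop(positions) / (k / sqrt(12)))
}

#' Dispersion of hits within a window
#'
#' Population standard deviation of the hit start positions, in bases.
#' Fewer than two hits give 0 with attribute \code{degenerate = TRUE}.
#'
#' @param positions hit start positions.
#' @return standard deviation in bases.
#' @export
dispersionSd <- function(positions) {
    out <- .sdPop(positions)
    attr(out, "degenerate") <- length(positions) < 2L
    out
}

#' Aggregate gRNA score
#'
#' \deqn{S = w_E E + (h/t)(W_{on}/h) - (o/t)(W_{off}/o)}
#' i.e. the evenness term plus the hit-count-weighted mean per-hit score in
#' the target bins minus the mean per-hit score outside them; a term with
#' zero hits contributes 0. With \code{evennessWeight = 0} the score is
#' bounded in \[-1, +1\]: +1 for a guide whose hits are all perfect and all
#' on-target, -1 for all-perfect all-off-target.
#'
#' @param t,h,o total, on-target and off-target hit counts (t = h + o).
#' @param WOn,WOff summed per-hit scores inside / outside the target bins.
#' @param E evenness in \[0, 1\].
#' @param evennessWeight weight on the evenness term (default 0).
#' @return the aggregate score S (vectorized).
#' @examples
#' aggregateScore(t = 4, h = 3, o = 1, WOn = 3, WOff = 1, E = 0)  # 0.5
#' @export
aggregateScore <- function(t, h, o, WOn, WOff, E = 0, evennessWeight = 0) {
    if (any(t < 1L)) stop("aggregate score undefined for t = 0")
    if (any(t != h + o)) stop("require t == h + o")
    onTerm <- ifelse(h > 0L, (h / t) * (WOn / h), 0)
    offTerm <- ifelse(o > 0L, (o / t) * (WOff / o), 0)
    evennessWeight * E + onTerm - offTerm
}
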