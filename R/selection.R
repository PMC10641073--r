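## Target-bin selection, guide ranking, multi-guide pooling, and the
## region-restricted mode.

## Greedy choice of up to nBins non-overlapping windows with highest W;
## ties broken by leftmost start, then chromosome name. Deterministic and
## matches the disjoint-cluster structure the windows come from.
.greedyBins <- function(wdt, nBins) {
    o <- order(-wdt$W, wdt$ws, wdt$chrom)
    wdt <- wdt[o, , drop = FALSE]
    chosen <- integer(0)
    for (i in seq_len(nrow(wdt))) {
        if (length(chosen) >= nBins) break
        ok <- TRUE
        for (j in chosen) {
            if (wdt$chrom[i] == wdt$chrom[j] &&
                wdt$ws[i] <= wdt$we[j] && wdt$we[i] >= wdt$ws[j]) {
                ok <- FALSE; break
            }
        }
        if (ok) chosen <- c(chosen, i)
    }
    wdt[chosen, , drop = FALSE]
}

## Per-guide score breakdown against a set of chosen bins.
.scoreAgainstBins <- function(gh, bins, k, evennessWeight) {
    ## gh: data.table of the guide's hits (chrom, pos, score, mismatches,
    ## locus); bins: data.frame (chrom, ws, we, ...) non-overlapping
    binIdx <- rep(NA_integer_, nrow(gh))
    for (b in seq_len(nrow(bins))) {
        inB <- gh$chrom == bins$chrom[b] & gh$pos >= bins$ws[b] &
            gh$pos <= bins$we[b]
        binIdx[inB] <- b
    }
    on <- !is.na(binIdx)
    t <- nrow(gh); h <- sum(on); o <- t - h
    WOn <- sum(gh$score[on]); WOff <- sum(gh$score[!on])
    offsets <- gh$pos[on] - bins$ws[binIdx[on]]
    E <- if (h > 0L) evenness(offsets, k) else 0
    topPos <- gh$pos[on & binIdx == 1L]
    disp <- as.numeric(dispersionSd(topPos))
    S <- aggregateScore(t, h, o, WOn, WOff, E, evennessWeight)
    mmTab <- tabulate(gh$mismatches + 1L, nbins = 4L)
    list(t = t, h = h, o = o, WOn = WOn, WOff = WOff, E = E,
         dispersion = disp, S = S, mm = mmTab, on = on)
}

#' Select target bins and score every guide against them
#'
#' For each guide retained by window filtering, greedily picks the
#' non-overlapping windows with highest window score W (ties to the
#' leftmost start) up to \code{nBins}, then recomputes on/off-target hit
#' counts, evenness, dispersion and the aggregate score S against the
#' union of chosen bins. Off-target hits are all hits falling outside
#' every chosen bin.
#'
#' @param ht a [HitTable-class].
#' @param assigned retained (guide, window) pairs from [assignHits()].
#' @param nBins number of target bins per guide (>= 1).
#' @param windowSize the window size k, used to normalize evenness.
#' @param evennessWeight weight on the evenness term of S (default 0).
#' @return a list with \code{report} (unranked per-guide
#'   \code{data.frame}) and \code{bins} (\code{GRanges} of chosen bins
#'   with mcols \code{guide}, \code{nHits}, \code{W}). Guides with fewer
#'   than \code{nBins} qualifying windows keep a shorter plan and are
#'   flagged in column \code{binShortfall}.
#' @export
selectBins <- function(ht, assigned, nBins = 1L, windowSize,
                       evennessWeight = 0) {
    stopifnot(is(ht, "HitTable"), is(assigned, "GRanges"))
    nBins <- as.integer(nBins)
    if (nBins < 1L) stop("nBins must be >= 1")
    emptyRep <- data.frame(
        guide = character(0), score = numeric(0), evenness = numeric(0),
        onTargets = integer(0), offTargets = integer(0),
        totalHits = integer(0), sumWOn = numeric(0), sumWOff = numeric(0),
        dispersion = numeric(0), mm0 = integer(0), mm1 = integer(0),
        mm2 = integer(0), mm3 = integer(0), saturated = logical(0),
        binShortfall = logical(0), bins = character(0),
        hits = character(0), stringsAsFactors = FALSE)
    if (length(assigned) == 0L)
        return(list(report = emptyRep,
                    bins = GenomicRanges::GRanges(guide = character(0),
                        nHits = integer(0), W = numeric(0))))

    gr <- hitRanges(ht)
    hitsDT <- data.table::data.table(
        guide = S4Vectors::mcols(gr)$guide,
        chrom = as.character(GenomeInfoDb::seqnames(gr)),
        pos = BiocGenerics::start(gr),
        score = S4Vectors::mcols(gr)$score,
        mismatches = S4Vectors::mcols(gr)$mismatches,
        locus = .formatLoci(gr))
    winDT <- data.table::data.table(
        guide = S4Vectors::mcols(assigned)$guide,
        chrom = as.character(GenomeInfoDb::seqnames(assigned)),
        ws = BiocGenerics::start(assigned),
        we = BiocGenerics::end(assigned),
        nHits = S4Vectors::mcols(assigned)$nHits,
        W = S4Vectors::mcols(assigned)$W)
    sat <- setNames(hitCounts(ht)$saturated, hitCounts(ht)$guide)

    guides <- sort(unique(winDT$guide))
    rows <- vector("list", length(guides))
    binRows <- vector("list", length(guides))
    for (i in seq_along(guides)) {
        g <- guides[i]
        bins <- .greedyBins(as.data.frame(winDT[winDT$guide == g, ]), nBins)
        gh <- hitsDT[hitsDT$guide == g, ]
        sb <- .scoreAgainstBins(gh, bins, windowSize, evennessWeight)
        binStr <- paste(sprintf("%s:%d-%d", bins$chrom, bins$ws, bins$we),
                        collapse = ";")
        rows[[i]] <- data.frame(
            guide = g, score = sb$S, evenness = sb$E,
            onTargets = sb$h, offTargets = sb$o, totalHits = sb$t,
            sumWOn = sb$WOn, sumWOff = sb$WOff,
            dispersion = sb$dispersion,
            mm0 = sb$mm[1], mm1 = sb$mm[2], mm2 = sb$mm[3], mm3 = sb$mm[4],
            saturated = isTRUE(sat[g]),
            binShortfall = nrow(bins) < nBins,
            bins = binStr,
            hits = paste(gh$locus, collapse = ";"),
            stringsAsFactors = FALSE)
        binRows[[i]] <- data.frame(chrom = bins$chrom, ws = bins$ws,
                                   we = bins$we, guide = g,
                                   nHits = bins$nHits, W = bins$W,
                                   stringsAsFactors = FALSE)
    }
    report <- do.call(rbind, rows)
    bdf <- do.call(rbind, binRows)
    binsGR <- GenomicRanges::GRanges(bdf$chrom,
        IRanges::IRanges(start = bdf$ws, end = bdf$we),
        guide = bdf$guide, nHits = bdf$nHits, W = bdf$W)
    sl <- GenomeInfoDb::seqlevels(hitRanges(ht))
    if (length(sl)) {
        GenomeInfoDb::seqlevels(binsGR) <- sl
        GenomeInfoDb::seqlengths(binsGR) <-
            GenomeInfoDb::seqlengths(hitRanges(ht))
    }
    list(report = report, bins = binsGR)
}

#' Rank guide plans
#'
#' Descending aggregate score S; ties broken by higher on-target hit
#' count, then lexicographically by guide sequence. Ranks are 1..n.
#'
#' @param report per-guide report from [selectBins()].
#' @return the report ordered with a \code{rank} column first.
#' @export
rankGuides <- function(report) {
    if (nrow(report) == 0L)
        return(cbind(rank = integer(0), report))
    o <- order(-report$score, -report$onTargets, report$guide)
    report <- report[o, , drop = FALSE]
    rownames(report) <- NULL
    cbind(rank = seq_len(nrow(report)), report)
}

#' Pool target bins across guides
#'
#' Bins from different guides are merged into one region when they overlap
#' or lie within \code{mergeGap} bases of each other (\code{mergeGap = 0}:
#' strict overlap only). Each pooled region lists its contributing guides
#' and the summed on-target hits of the contributing bins.
#'
#' @param bins \code{GRanges} of bins with mcols \code{guide} and
#'   \code{nHits} (from [selectBins()]).
#' @param mergeGap maximum gap in bases for merging (default 0).
#' @return \code{GRanges} of pooled regions with mcols \code{guides}
#'   (comma-separated), \code{nGuides} and \code{totalHits}.
#' @export
poolGuides <- function(bins, mergeGap = 0L) {
    stopifnot(is(bins, "GRanges"))
    if (length(bins) == 0L)
        return(GenomicRanges::GRanges(guides = character(0),
                                      nGuides = integer(0),
                                      totalHits = integer(0)))
    gapw <- if (mergeGap > 0L) as.integer(mergeGap) + 1L else 0L
    pooled <- GenomicRanges::reduce(bins, min.gapwidth = gapw,
                                    ignore.strand = TRUE)
    ov <- GenomicRanges::findOverlaps(bins, pooled, ignore.strand = TRUE)
    gl <- split(S4Vectors::mcols(bins)$guide[S4Vectors::queryHits(ov)],
                S4Vectors::subjectHits(ov))
    hl <- split(S4Vectors::mcols(bins)$nHits[S4Vectors::queryHits(ov)],
                S4Vectors::subjectHits(ov))
    idx <- as.integer(names(gl))
    guides <- character(length(pooled)); nh <- integer(length(pooled))
    guides[idx] <- vapply(gl, function(x)
        paste(sort(unique(x)), collapse = ","), character(1))
    nh[idx] <- vapply(hl, function(x) as.integer(sum(x)), integer(1))
    S4Vectors::mcols(pooled) <- S4Vectors::DataFrame(
        guides = guides,
        nGuides = lengths(lapply(strsplit(guides, ","), unique)),
        totalHits = nh)
    pooled
}

#' Region-restricted guide design
#'
#' Candidates are extracted only inside the supplied regions; their hits
#' and off-targets are then searched against the whole genome. On-target
#' hits are the hits falling inside the supplied regions (which act as the
#' target bins); everything else is off-target.
#'
#' @param genome a \code{DNAStringSet}.
#' @param regions a \code{GRanges} or path to a BED file.
#' @param pam,spacerLen,gcMin,gcMax candidate extraction parameters, as in
#'   [scanCandidates()].
#' @param maxMismatches,hitCap mapping parameters, as in [findAllHits()].
#' @param minHits minimum on-target hits for a guide to be reported.
#' @param evennessWeight weight on the evenness term of S.
#' @return a [BroadGuideResult-class] (ranked report; bins are the
#'   supplied regions that a guide actually hits).
#' @export
restrictToRegions <- function(genome, regions, pam = PamSpec("NGG"),
                              spacerLen = 20L, gcMin = 0, gcMax = 1,
                              maxMismatches = 3L, hitCap = 10000L,
                              minHits = 5L, evennessWeight = 0) {
    stopifnot(is(genome, "DNAStringSet"))
    if (is.character(regions))
        regions <- readRegionsBed(regions, genome)
    stopifnot(is(regions, "GRanges"))
    lens <- setNames(Biostrings::width(genome), names(genome))
    if (any(BiocGenerics::end(regions) >
            lens[as.character(GenomeInfoDb::seqnames(regions))]) ||
        any(BiocGenerics::start(regions) < 1L))
        stop("regions extend beyond genome bounds")

    cs <- scanCandidates(genome, pam, spacerLen, gcMin, gcMax)
    org <- candidateOrigins(cs)
    within <- IRanges::overlapsAny(org, regions, type = "within",
                                   ignore.strand = TRUE)
    cs@origins <- org[within]

    ht <- findAllHits(genome, cs, maxMismatches, hitCap)
    gr <- hitRanges(ht)

    ## the supplied regions are the bins; score each guide against them
    rdf <- data.frame(
        chrom = as.character(GenomeInfoDb::seqnames(regions)),
        ws = BiocGenerics::start(regions),
        we = BiocGenerics::end(regions), stringsAsFactors = FALSE)
    hitsDT <- data.table::data.table(
        guide = S4Vectors::mcols(gr)$guide,
        chrom = as.character(GenomeInfoDb::seqnames(gr)),
        pos = BiocGenerics::start(gr),
        score = S4Vectors::mcols(gr)$score,
        mismatches = S4Vectors::mcols(gr)$mismatches,
        locus = .formatLoci(gr))
    sat <- setNames(hitCounts(ht)$saturated, hitCounts(ht)$guide)

    guides <- sort(unique(hitsDT$guide))
    rows <- list(); binRows <- list()
    for (g in guides) {
        gh <- hitsDT[hitsDT$guide == g, ]
        binIdx <- rep(NA_integer_, nrow(gh))
        for (b in seq_len(nrow(rdf))) {
            inB <- gh$chrom == rdf$chrom[b] & gh$pos >= rdf$ws[b] &
                gh$pos <= rdf$we[b]
            binIdx[inB] <- b
        }
        on <- !is.na(binIdx)
        h <- sum(on)
        if (h < minHits) next
        t <- nrow(gh); o <- t - h
        WOn <- sum(gh$score[on]); WOff <- sum(gh$score[!on])
        wk <- rdf$we - rdf$ws + 1L
        ## evenness per region, hit-weighted; dispersion in busiest region
        usedBins <- sort(unique(binIdx[on]))
        Es <- vapply(usedBins, function(b)
            evenness(gh$pos[on & binIdx == b] - rdf$ws[b], wk[b]),
            numeric(1))
        nB <- vapply(usedBins, function(b) sum(binIdx[on] == b), integer(1))
        E <- sum(Es * nB) / h
        busiest <- usedBins[which.max(nB)]
        disp <- as.numeric(dispersionSd(gh$pos[on & binIdx == busiest]))
        S <- aggregateScore(t, h, o, WOn, WOff, E, evennessWeight)
        mm <- tabulate(gh$mismatches + 1L, nbins = 4L)
        binStr <- paste(sprintf("%s:%d-%d", rdf$chrom[usedBins],
                                rdf$ws[usedBins], rdf$we[usedBins]),
                        collapse = ";")
        rows[[g]] <- data.frame(
            guide = g, score = S, evenness = E, onTargets = h,
            offTargets = o, totalHits = t, sumWOn = WOn, sumWOff = WOff,
            dispersion = disp, mm0 = mm[1], mm1 = mm[2], mm2 = mm[3],
            mm3 = mm[4], saturated = isTRUE(sat[g]), binShortfall = FALSE,
            bins = binStr, hits = paste(gh$locus, collapse = ";"),
            stringsAsFactors = FALSE)
        binRows[[g]] <- data.frame(
            chrom = rdf$chrom[usedBins], ws = rdf$ws[usedBins],
            we = rdf$we[usedBins], guide = g, nHits = nB,
            W = vapply(usedBins, function(b)
                sum(gh$score[on & binIdx == b]), numeric(1)),
            stringsAsFactors = FALSE)
    }
    report <- if (length(rows))
        do.call(rbind, c(unname(rows), list(make.row.names = FALSE)))
    else NULL
    if (is.null(report))
        report <- selectBins(ht, GenomicRanges::GRanges(
            guide = character(0), nHits = integer(0),
            W = numeric(0)), 1L, 1)$report
    gcMap <- guideTable(cs)
    report$gc <- gcMap$gc[match(report$guide, gcMap$fullSeq)]
    report <- rankGuides(report)

    bdf <- do.call(rbind, binRows)
    if (is.null(bdf)) {
        binsGR <- GenomicRanges::GRanges(guide = character(0),
                                         nHits = integer(0), W = numeric(0))
    } else {
        binsGR <- GenomicRanges::GRanges(bdf$chrom,
            IRanges::IRanges(start = bdf$ws, end = bdf$we),
            guide = bdf$guide, nHits = bdf$nHits, W = bdf$W)
        GenomeInfoDb::seqlevels(binsGR) <- names(genome)
        GenomeInfoDb::seqlengths(binsGR) <- Biostrings::width(genome)
    }
    cfg <- list(mode = "region", pam = pamPattern(pam),
                pamSide = pamSide(pam), spacerLen = spacerLen,
                gcMin = gcMin, gcMax = gcMax,
                maxMismatches = maxMismatches, hitCap = hitCap,
                minHits = minHits, evennessWeight = evennessWeight,
                nRegions = length(regions))
    new("BroadGuideResult", report = report, bins = binsGR,
        pooled = poolGuides(binsGR), hitTable = ht, config = cfg)
}
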