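## Orchestration: validated run configuration, whole-pipeline runs, staged
## execution over cached intermediates, and the report/BED/log writers.

#' Validated run configuration
#'
#' Collects and validates every pipeline parameter before any stage runs.
#' The configuration is serialized verbatim into the JSON run log.
#'
#' @param genome path to a FASTA file, or a \code{DNAStringSet}.
#' @param pam PAM pattern (IUPAC string) or a [PamSpec-class].
#' @param pamSide \code{"3prime"} or \code{"5prime"} (ignored when
#'   \code{pam} is already a \code{PamSpec}).
#' @param spacerLen protospacer length (default 20).
#' @param gcMin,gcMax GC bounds on the full guide sequence.
#' @param maxMismatches protospacer substitution budget, 0--3.
#' @param hitCap per-guide cap on enumerated hits (default 10000).
#' @param windowSize target window size k in bases (e.g. 50000).
#' @param step sliding-window advance (default \code{windowSize/10}).
#' @param minHits minimum hits for a retained window (default 5).
#' @param maxHits optional per-window upper bound (default unlimited).
#' @param nBins number of target bins per guide (default 1).
#' @param evennessWeight weight of the evenness term in S (default 0, which
#'   keeps S in \[-1, +1\]).
#' @param mergeGap gap tolerated when pooling bins across guides.
#' @param regions optional BED path or \code{GRanges}: design guides only
#'   inside these regions (off-targets still genome-wide).
#' @param threads accepted and logged; all stages produce canonically
#'   ordered output, so the value never changes any output byte.
#' @param seed recorded in the log; no pipeline stage consumes randomness.
#' @param outPrefix when set, every stage writes its intermediate and the
#'   final report/BED/log files under this prefix.
#' @return a validated configuration (class \code{BroadGuideConfig}).
#' @export
broadGuideConfig <- function(genome, pam = "NGG",
                             pamSide = c("3prime", "5prime"),
                             spacerLen = 20L, gcMin = 0, gcMax = 1,
                             maxMismatches = 3L, hitCap = 10000L,
                             windowSize = 50000L, step = NULL,
                             minHits = 5L, maxHits = Inf, nBins = 1L,
                             evennessWeight = 0, mergeGap = 0L,
                             regions = NULL, threads = 1L, seed = NULL,
                             outPrefix = NULL) {
    pamSide <- match.arg(pamSide)
    if (!is(pam, "PamSpec")) pam <- PamSpec(pam, pamSide)
    spacerLen <- as.integer(spacerLen)
    if (spacerLen < 10L) stop("spacerLen must be at least 10")
    if (!(gcMin >= 0 && gcMin <= gcMax && gcMax <= 1))
        stop("require 0 <= gcMin <= gcMax <= 1")
    maxMismatches <- as.integer(maxMismatches)
    if (maxMismatches < 0L || maxMismatches > 3L)
        stop("maxMismatches must be in 0..3")
    if (hitCap < 1L) stop("hitCap must be >= 1")
    windowSize <- as.numeric(windowSize)
    if (windowSize < 1) stop("windowSize must be >= 1")
    if (is.null(step)) step <- max(1, floor(windowSize / 10))
    if (!(step > 0 && step <= windowSize))
        stop("require 0 < step <= windowSize")
    if (minHits < 1L) stop("minHits must be >= 1")
    if (maxHits < minHits) stop("maxHits must be >= minHits")
    if (nBins < 1L) stop("nBins must be >= 1")
    if (evennessWeight < 0) stop("evennessWeight must be >= 0")
    if (mergeGap < 0L) stop("mergeGap must be >= 0")
    if (threads < 1L) stop("threads must be >= 1")
    cfg <- list(genome = genome, pam = pam, spacerLen = spacerLen,
                gcMin = gcMin, gcMax = gcMax,
                maxMismatches = maxMismatches,
                hitCap = as.integer(hitCap), windowSize = windowSize,
                step = step, minHits = as.integer(minHits),
                maxHits = maxHits, nBins = as.integer(nBins),
                evennessWeight = evennessWeight,
                mergeGap = as.integer(mergeGap), regions = regions,
                threads = as.integer(threads), seed = seed,
                outPrefix = outPrefix)
    class(cfg) <- "BroadGuideConfig"
    cfg
}

.cfgGenome <- function(cfg) {
    if (is(cfg$genome, "DNAStringSet")) cfg$genome
    else readGenome(cfg$genome)
}

## ---- intermediate files ------------------------------------------------

.stageFiles <- function(prefix) {
    list(candidates = paste0(prefix, ".candidates.tsv"),
         guides = paste0(prefix, ".guides.tsv"),
         hits = paste0(prefix, ".hits.tsv"),
         windows = paste0(prefix, ".windows.tsv"),
         retained = paste0(prefix, ".retained.tsv"),
         report = paste0(prefix, ".report.tsv"),
         bins = paste0(prefix, ".bins.bed"),
         pooled = paste0(prefix, ".pooled.bed"),
         runlog = paste0(prefix, ".runlog.json"))
}

.writeIntermediate <- function(df, path, stage) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# broadguide-intermediate stage=%s schema=1",
                       stage), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

.readIntermediate <- function(path, stage, predecessor) {
    if (!file.exists(path))
        stop("missing intermediate '", basename(path),
             "': run stage '", predecessor, "' first")
    first <- readLines(path, n = 1L)
    want <- sprintf("# broadguide-intermediate stage=%s schema=1", stage)
    if (!identical(first, want))
        stop("stale or foreign intermediate '", basename(path),
             "': regenerate it with stage '", predecessor, "'")
    utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE)
}

.hitTableFromDF <- function(hdf, gdf, genome, maxMismatches, hitCap) {
    if (nrow(hdf) == 0L) {
        gr <- .emptyHitGRanges(genome)
    } else {
        gr <- GenomicRanges::GRanges(hdf$chrom,
            IRanges::IRanges(start = hdf$start, end = hdf$end),
            strand = hdf$strand, guide = hdf$guide,
            matches = as.integer(hdf$matches),
            mismatches = as.integer(hdf$mismatches),
            gaps = as.integer(hdf$gaps), pamOk = as.logical(hdf$pamOk),
            score = hdf$score)
        GenomeInfoDb::seqlevels(gr) <- names(genome)
        GenomeInfoDb::seqlengths(gr) <- Biostrings::width(genome)
    }
    .newHitTable(gr, gdf[, c("guide", "t", "saturated")],
                 maxMismatches, hitCap)
}

## ---- whole-pipeline run ------------------------------------------------

#' Run the whole guide-design pipeline
#'
#' extract -> map -> window -> score -> select -> pool, in memory; when
#' \code{outPrefix} is set in the configuration, each stage's intermediate
#' and the final report, BED and JSON log files are written so stages can
#' later be re-run individually with [runStage()]. Identical configuration
#' and genome produce byte-identical output files.
#'
#' @param config a configuration from [broadGuideConfig()], or arguments
#'   forwarded to it.
#' @param ... forwarded to [broadGuideConfig()] when \code{config} is not
#'   already a configuration.
#' @return a [BroadGuideResult-class].
#' @examples
#' fx <- generateFixture(c(chrA = 6000),
#'     plants = list(plantSpec("ACGTACGTGGATCCTTAACC", "TGG",
#'                             copiesOnTarget = 6, clusterStart = 500,
#'                             clusterEnd = 2500)), seed = 7)
#' res <- runBroadGuide(fx$genome, windowSize = 2000, minHits = 5,
#'                      maxMismatches = 1)
#' reportTable(res)[1, c("guide", "score", "onTargets", "offTargets")]
#' @export
runBroadGuide <- function(config = NULL, ...) {
    cfg <- if (is(config, "BroadGuideConfig")) config
           else broadGuideConfig(config, ...)
    genome <- .cfgGenome(cfg)

    if (!is.null(cfg$regions)) {
        res <- restrictToRegions(genome, cfg$regions, cfg$pam,
                                 cfg$spacerLen, cfg$gcMin, cfg$gcMax,
                                 cfg$maxMismatches, cfg$hitCap,
                                 cfg$minHits, cfg$evennessWeight)
        res@config <- .serializableConfig(cfg)
        if (!is.null(cfg$outPrefix)) .writeOutputs(res, cfg)
        return(res)
    }

    cs <- scanCandidates(genome, cfg$pam, cfg$spacerLen, cfg$gcMin,
                         cfg$gcMax)
    ht <- findAllHits(genome, cs, cfg$maxMismatches, cfg$hitCap)
    windows <- .genomeWindows(genome, cfg$windowSize, cfg$step)
    assigned <- assignHits(ht, windows, cfg$minHits, cfg$maxHits)
    sel <- selectBins(ht, assigned, cfg$nBins, cfg$windowSize,
                      cfg$evennessWeight)
    report <- sel$report
    gcMap <- guideTable(cs)
    report$gc <- if (nrow(report))
        gcMap$gc[match(report$guide, gcMap$fullSeq)] else numeric(0)
    report <- rankGuides(report)
    pooled <- poolGuides(sel$bins, cfg$mergeGap)

    res <- new("BroadGuideResult", report = report, bins = sel$bins,
               pooled = pooled, hitTable = ht,
               config = .serializableConfig(cfg))
    if (!is.null(cfg$outPrefix)) {
        .writeStageCandidates(cs, cfg)
        .writeStageHits(ht, cfg)
        .writeStageWindows(ht, windows, cfg)
        .writeStageRetained(assigned, cfg)
        .writeOutputs(res, cfg)
    }
    res
}

.serializableConfig <- function(cfg) {
    out <- unclass(cfg)
    out$mode <- if (is.null(cfg$regions)) "genome" else "region"
    out$pamSide <- pamSide(cfg$pam)
    out$pam <- pamPattern(cfg$pam)
    out$genome <- if (is.character(cfg$genome)) cfg$genome
                  else paste0("<in-memory DNAStringSet of ",
                              length(cfg$genome), " sequences>")
    if (is(out$regions, "GRanges"))
        out$regions <- paste0("<GRanges of ", length(cfg$regions),
                              " regions>")
    if (is.infinite(out$maxHits)) out$maxHits <- "unlimited"
    out
}

## ---- stage writers / staged execution ---------------------------------

.writeStageCandidates <- function(cs, cfg) {
    f <- .stageFiles(cfg$outPrefix)
    org <- candidateOrigins(cs)
    df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(org)),
                     start = BiocGenerics::start(org),
                     end = BiocGenerics::end(org),
                     strand = as.character(BiocGenerics::strand(org)),
                     fullSeq = S4Vectors::mcols(org)$fullSeq,
                     protospacer = S4Vectors::mcols(org)$protospacer,
                     pam = S4Vectors::mcols(org)$pam,
                     gc = S4Vectors::mcols(org)$gc)
    .writeIntermediate(df, f$candidates, "extract")
}

.writeStageHits <- function(ht, cfg) {
    f <- .stageFiles(cfg$outPrefix)
    gr <- hitRanges(ht)
    df <- data.frame(guide = S4Vectors::mcols(gr)$guide,
                     chrom = as.character(GenomeInfoDb::seqnames(gr)),
                     start = BiocGenerics::start(gr),
                     end = BiocGenerics::end(gr),
                     strand = as.character(BiocGenerics::strand(gr)),
                     matches = S4Vectors::mcols(gr)$matches,
                     mismatches = S4Vectors::mcols(gr)$mismatches,
                     gaps = S4Vectors::mcols(gr)$gaps,
                     pamOk = S4Vectors::mcols(gr)$pamOk,
                     score = S4Vectors::mcols(gr)$score)
    .writeIntermediate(df, f$hits, "map")
    .writeIntermediate(hitCounts(ht), f$guides, "map")
}

.writeStageWindows <- function(ht, windows, cfg) {
    ## all (guide, window) pairs before min/max-hit retention
    f <- .stageFiles(cfg$outPrefix)
    all <- assignHits(ht, windows, minHits = 1L)
    df <- data.frame(guide = S4Vectors::mcols(all)$guide,
                     chrom = as.character(GenomeInfoDb::seqnames(all)),
                     start = BiocGenerics::start(all),
                     end = BiocGenerics::end(all),
                     nHits = S4Vectors::mcols(all)$nHits,
                     W = S4Vectors::mcols(all)$W)
    .writeIntermediate(df, f$windows, "window")
}

.writeStageRetained <- function(assigned, cfg) {
    f <- .stageFiles(cfg$outPrefix)
    df <- data.frame(guide = S4Vectors::mcols(assigned)$guide,
                     chrom = as.character(GenomeInfoDb::seqnames(assigned)),
                     start = BiocGenerics::start(assigned),
                     end = BiocGenerics::end(assigned),
                     nHits = S4Vectors::mcols(assigned)$nHits,
                     W = S4Vectors::mcols(assigned)$W)
    .writeIntermediate(df, f$retained, "score")
}

#' Run a single pipeline stage over cached intermediates
#'
#' Stages read their predecessor's intermediate files under the
#' configuration's \code{outPrefix} and write their own, so expensive
#' early stages (extraction, mapping) need not be re-run when only
#' downstream parameters change. A missing or foreign intermediate is a
#' fatal error naming the stage that must be run first.
#'
#' @param stage one of \code{"extract"}, \code{"map"}, \code{"window"},
#'   \code{"score"}, \code{"select"}, \code{"pool"}, \code{"region"}.
#' @param config a [broadGuideConfig()] with \code{outPrefix} set.
#' @return the stage's main object, invisibly (CandidateSet, HitTable,
#'   window \code{GRanges}, or [BroadGuideResult-class]).
#' @export
runStage <- function(stage = c("extract", "map", "window", "score",
                               "select", "pool", "region"), config) {
    stage <- match.arg(stage)
    cfg <- config
    stopifnot(is(cfg, "BroadGuideConfig"))
    if (is.null(cfg$outPrefix))
        stop("staged execution needs 'outPrefix' in the configuration")
    f <- .stageFiles(cfg$outPrefix)
    genome <- .cfgGenome(cfg)

    if (stage == "extract") {
        cs <- scanCandidates(genome, cfg$pam, cfg$spacerLen, cfg$gcMin,
                             cfg$gcMax)
        .writeStageCandidates(cs, cfg)
        return(invisible(cs))
    }
    if (stage == "region") {
        if (is.null(cfg$regions))
            stop("stage 'region' needs 'regions' in the configuration")
        res <- runBroadGuide(cfg)
        return(invisible(res))
    }

    readCS <- function() {
        df <- .readIntermediate(f$candidates, "extract", "extract")
        if (nrow(df) == 0L) {
            gr <- GenomicRanges::GRanges()
            S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
                fullSeq = character(0), protospacer = character(0),
                pam = character(0), gc = numeric(0))
        } else {
            gr <- GenomicRanges::GRanges(df$chrom,
                IRanges::IRanges(start = df$start, end = df$end),
                strand = df$strand, fullSeq = df$fullSeq,
                protospacer = df$protospacer, pam = df$pam, gc = df$gc)
            GenomeInfoDb::seqlevels(gr) <- names(genome)
            GenomeInfoDb::seqlengths(gr) <- Biostrings::width(genome)
        }
        new("CandidateSet", origins = gr, pamSpec = cfg$pam,
            spacerLen = cfg$spacerLen,
            gcBounds = c(cfg$gcMin, cfg$gcMax))
    }
    readHT <- function() {
        hdf <- .readIntermediate(f$hits, "map", "map")
        gdf <- .readIntermediate(f$guides, "map", "map")
        .hitTableFromDF(hdf, gdf, genome, cfg$maxMismatches, cfg$hitCap)
    }
    readWindows <- function(path, stageName, pred) {
        df <- .readIntermediate(path, stageName, pred)
        gr <- GenomicRanges::GRanges(
            if (nrow(df)) df$chrom else character(0),
            IRanges::IRanges(start = df$start, end = df$end),
            guide = df$guide, nHits = as.integer(df$nHits), W = df$W)
        if (length(gr)) {
            GenomeInfoDb::seqlevels(gr) <- names(genome)
            GenomeInfoDb::seqlengths(gr) <- Biostrings::width(genome)
        }
        gr
    }

    if (stage == "map") {
        ht <- findAllHits(genome, readCS(), cfg$maxMismatches, cfg$hitCap)
        .writeStageHits(ht, cfg)
        return(invisible(ht))
    }
    if (stage == "window") {
        ht <- readHT()
        windows <- .genomeWindows(genome, cfg$windowSize, cfg$step)
        .writeStageWindows(ht, windows, cfg)
        return(invisible(windows))
    }
    if (stage == "score") {
        all <- readWindows(f$windows, "window", "window")
        keep <- S4Vectors::mcols(all)$nHits >= cfg$minHits &
            S4Vectors::mcols(all)$nHits <= cfg$maxHits
        .writeStageRetained(all[keep], cfg)
        return(invisible(all[keep]))
    }
    if (stage == "select") {
        ht <- readHT()
        assigned <- readWindows(f$retained, "score", "score")
        sel <- selectBins(ht, assigned, cfg$nBins, cfg$windowSize,
                          cfg$evennessWeight)
        report <- sel$report
        cs <- readCS()
        gcMap <- guideTable(cs)
        report$gc <- if (nrow(report))
            gcMap$gc[match(report$guide, gcMap$fullSeq)] else numeric(0)
        report <- rankGuides(report)
        res <- new("BroadGuideResult", report = report, bins = sel$bins,
                   pooled = poolGuides(sel$bins, cfg$mergeGap),
                   hitTable = ht, config = .serializableConfig(cfg))
        .writeOutputs(res, cfg)
        return(invisible(res))
    }
    ## pool: re-derive pooled regions from the written bins BED
    if (!file.exists(f$bins))
        stop("missing intermediate '", basename(f$bins),
             "': run stage 'select' first")
    bins <- rtracklayer::import(f$bins, format = "BED")
    S4Vectors::mcols(bins)$guide <- S4Vectors::mcols(bins)$name
    S4Vectors::mcols(bins)$nHits <- 0L
    pooled <- poolGuides(bins, cfg$mergeGap)
    .writePooledBed(pooled, f$pooled)
    invisible(pooled)
}

## ---- output writers ----------------------------------------------------

.fmt4 <- function(x) sprintf("%.4f", x)

#' Write the ranked guide report as TSV
#'
#' One row per guide: sequence, aggregate score, GC content, on/off-target
#' hit counts, evenness, dispersion, summed window scores, the per-hit
#' mismatch histogram, saturation flag, selected bin coordinates and all
#' hit coordinates (\code{chrom:start-end:strand}, 1-based inclusive,
#' semicolon-joined). Floating point values are fixed at 4 decimals so
#' reruns are byte-identical.
#'
#' @param report a ranked report \code{data.frame} (from
#'   [reportTable()]), or a [BroadGuideResult-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeReport <- function(report, path) {
    if (is(report, "BroadGuideResult")) report <- reportTable(report)
    cols <- c("rank", "guide", "score", "gc", "onTargets", "offTargets",
              "totalHits", "evenness", "dispersion", "sumWOn", "sumWOff",
              "mm0", "mm1", "mm2", "mm3", "saturated", "binShortfall",
              "bins", "hits")
    out <- report[, cols, drop = FALSE]
    for (cc in c("score", "gc", "evenness", "dispersion", "sumWOn",
                 "sumWOff"))
        out[[cc]] <- .fmt4(out[[cc]])
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

.bedScore <- function(S) as.integer(pmin(1000, pmax(0,
    round((S + 1) / 2 * 1000))))

.writeBinsBed <- function(bins, report, path) {
    gr <- bins
    sMap <- setNames(report$score, report$guide)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        name = S4Vectors::mcols(bins)$guide,
        score = .bedScore(sMap[S4Vectors::mcols(bins)$guide]))
    BiocGenerics::strand(gr) <- "*"
    rtracklayer::export(gr, path, format = "BED")
    invisible(path)
}

.writePooledBed <- function(pooled, path) {
    gr <- pooled
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        name = S4Vectors::mcols(pooled)$guides,
        score = pmin(1000L, S4Vectors::mcols(pooled)$totalHits))
    BiocGenerics::strand(gr) <- "*"
    rtracklayer::export(gr, path, format = "BED")
    invisible(path)
}

.writeOutputs <- function(res, cfg) {
    f <- .stageFiles(cfg$outPrefix)
    writeReport(res, f$report)
    .writeBinsBed(res@bins, res@report, f$bins)
    .writePooledBed(res@pooled, f$pooled)
    log <- list(tool = "broadGuide",
                version = as.character(utils::packageVersion("broadGuide")),
                config = .serializableConfig(cfg),
                nGuidesReported = nrow(res@report),
                nBinsSelected = length(res@bins),
                nPooledRegions = length(res@pooled))
    jsonlite::write_json(log, f$runlog, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    invisible(f)
}
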