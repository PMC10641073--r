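## Synthetic genomes with planted repeat families of known copy number,
## divergence and clustering, plus the brute-force mapping oracle. These
## stand in for the natural repeat families (Alu/LINE-1/MITE-like) that
## make real genomes multi-targetable, with exactly known ground truth.

#' Specification of one planted repeat family
#'
#' Describes a protospacer, the concrete PAM to plant next to it, how many
#' copies go inside the on-target cluster interval and how many elsewhere,
#' and the per-copy substitution counts.
#'
#' @param protospacer DNA string over A/C/G/T.
#' @param pam concrete PAM realization planted at every copy (no
#'   degeneracy; e.g. \code{"TGG"}).
#' @param copiesOnTarget copies placed inside the cluster interval.
#' @param copiesOffTarget copies placed outside it (default 0).
#' @param mismatchProfile integer vector of per-copy substitution counts
#'   (0--3), length \code{copiesOnTarget + copiesOffTarget}; defaults to
#'   all zeros. Substitutions are placed at random protospacer positions,
#'   never in the PAM.
#' @param clusterChrom chromosome holding the cluster (default: first).
#' @param clusterStart,clusterEnd 1-based inclusive bounds of the cluster
#'   interval.
#' @param offTargetChroms optional chromosome names to restrict off-target
#'   placement to (default: anywhere outside the cluster).
#' @return a \code{PlantSpec} (validated list).
#' @export
plantSpec <- function(protospacer, pam = "TGG", copiesOnTarget,
                      copiesOffTarget = 0L, mismatchProfile = NULL,
                      clusterChrom = NULL, clusterStart, clusterEnd,
                      offTargetChroms = NULL) {
    if (grepl("[^ACGT]", protospacer))
        stop("protospacer must be plain A/C/G/T")
    if (grepl("[^ACGT]", pam))
        stop("planted PAM must be a concrete A/C/G/T realization")
    nCopies <- copiesOnTarget + copiesOffTarget
    if (nCopies < 1L) stop("at least one copy required")
    if (is.null(mismatchProfile))
        mismatchProfile <- rep(0L, nCopies)
    if (length(mismatchProfile) != nCopies)
        stop("mismatchProfile must have one entry per copy")
    if (any(mismatchProfile < 0L | mismatchProfile > nchar(protospacer)))
        stop("invalid substitution count in mismatchProfile")
    if (clusterStart >= clusterEnd) stop("clusterStart must be < clusterEnd")
    structure(list(protospacer = protospacer, pam = pam,
                   copiesOnTarget = as.integer(copiesOnTarget),
                   copiesOffTarget = as.integer(copiesOffTarget),
                   mismatchProfile = as.integer(mismatchProfile),
                   clusterChrom = clusterChrom,
                   clusterStart = as.integer(clusterStart),
                   clusterEnd = as.integer(clusterEnd),
                   offTargetChroms = offTargetChroms),
              class = "PlantSpec")
}

.mutateSpacer <- function(spacer, nSub) {
    if (nSub == 0L) return(spacer)
    v <- strsplit(spacer, "")[[1]]
    at <- sample.int(length(v), nSub)
    for (i in at)
        v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
    paste(v, collapse = "")
}

#' Generate a synthetic genome with planted repeat families
#'
#' Background sequence is i.i.d. with the requested GC content; each plant
#' copy is embedded with exactly its specified number of protospacer
#' substitutions (never in the PAM), on a random strand, 3'-PAM layout.
#' Copies never overlap each other. After planting, the background is
#' rejection-checked: any spurious exact occurrence of a planted
#' protospacer (either strand) outside the planted copies is destroyed by
#' a single-base change, so the manifest is exact ground truth.
#' The same seed reproduces the genome byte for byte.
#'
#' @param chromSizes named integer vector of chromosome lengths.
#' @param plants list of [plantSpec()] objects.
#' @param backgroundGC background GC fraction (default 0.5).
#' @param seed integer seed; the global RNG state is restored on exit.
#' @param maxTries placement attempts per copy before giving up.
#' @return a list with \code{genome} (\code{DNAStringSet}) and
#'   \code{manifest}: chromosome sizes, background GC, seed, and for each
#'   plant the realized copies (chrom, 1-based start/end of the full
#'   footprint, strand, substitution count, on-target flag).
#' @export
generateFixture <- function(chromSizes, plants = list(), backgroundGC = 0.5,
                            seed = 1L, maxTries = 1000L) {
    if (is.null(names(chromSizes)) || any(!nzchar(names(chromSizes))))
        stop("chromSizes must be a named vector")
    oldSeed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(oldSeed))
        assign(".Random.seed", oldSeed, envir = globalenv()))
    set.seed(seed)

    p <- c(AT = (1 - backgroundGC) / 2, GC = backgroundGC / 2)
    chroms <- lapply(chromSizes, function(n)
        sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c(p[1], p[1], p[2], p[2])))

    occupied <- lapply(chromSizes, function(n) matrix(0L, 0L, 2L))
    overlaps <- function(ch, s, e) {
        occ <- occupied[[ch]]
        nrow(occ) > 0L && any(s <= occ[, 2L] & e >= occ[, 1L])
    }
    claim <- function(ch, s, e)
        occupied[[ch]] <<- rbind(occupied[[ch]], c(s, e))

    manifestPlants <- vector("list", length(plants))
    for (pi in seq_along(plants)) {
        pl <- plants[[pi]]
        stopifnot(inherits(pl, "PlantSpec"))
        L <- nchar(pl$protospacer) + nchar(pl$pam)
        cChrom <- if (is.null(pl$clusterChrom)) names(chromSizes)[1]
                  else pl$clusterChrom
        if (!cChrom %in% names(chromSizes))
            stop("cluster chromosome not in chromSizes: ", cChrom)
        if (pl$clusterEnd - L + 1L < pl$clusterStart ||
            pl$clusterEnd > chromSizes[[cChrom]])
            stop("cluster interval cannot hold a full copy")

        nCopies <- pl$copiesOnTarget + pl$copiesOffTarget
        onT <- c(rep(TRUE, pl$copiesOnTarget),
                 rep(FALSE, pl$copiesOffTarget))
        rows <- vector("list", nCopies)
        for (ci in seq_len(nCopies)) {
            placed <- FALSE
            for (tr in seq_len(maxTries)) {
                if (onT[ci]) {
                    ch <- cChrom
                    s <- sample(pl$clusterStart:(pl$clusterEnd - L + 1L), 1L)
                } else {
                    pool <- if (is.null(pl$offTargetChroms))
                        names(chromSizes) else pl$offTargetChroms
                    ch <- if (length(pool) == 1L) pool
                          else sample(pool, 1L,
                                      prob = as.numeric(chromSizes[pool]))
                    s <- sample.int(chromSizes[[ch]] - L + 1L, 1L)
                    ## off-target copies stay clear of the cluster
                    if (ch == cChrom && s <= pl$clusterEnd &&
                        s + L - 1L >= pl$clusterStart) next
                }
                e <- s + L - 1L
                if (overlaps(ch, s, e)) next
                strand <- sample(c("+", "-"), 1L)
                mutated <- .mutateSpacer(pl$protospacer,
                                         pl$mismatchProfile[ci])
                site <- paste0(mutated, pl$pam)
                ins <- if (strand == "+") site else revComp(site)
                chroms[[ch]][s:e] <- strsplit(ins, "")[[1]]
                claim(ch, s, e)
                rows[[ci]] <- data.frame(chrom = ch, start = s, end = e,
                                         strand = strand,
                                         nSub = pl$mismatchProfile[ci],
                                         onTarget = onT[ci],
                                         stringsAsFactors = FALSE)
                placed <- TRUE
                break
            }
            if (!placed)
                stop("could not place copy ", ci, " of plant ", pi,
                     " after ", maxTries, " tries")
        }
        copies <- do.call(rbind, rows)
        manifestPlants[[pi]] <- list(
            protospacer = pl$protospacer, pam = pl$pam,
            fullSeq = paste0(pl$protospacer, pl$pam),
            clusterChrom = cChrom, clusterStart = pl$clusterStart,
            clusterEnd = pl$clusterEnd, copies = copies)
    }

    ## destroy spurious exact protospacer copies arising in the background
    for (pi in seq_along(manifestPlants)) {
        mp <- manifestPlants[[pi]]
        P <- nchar(mp$protospacer)
        expect <- mp$copies
        for (ch in names(chroms)) {
            s <- paste(chroms[[ch]], collapse = "")
            for (pat in c(mp$protospacer, revComp(mp$protospacer))) {
                hit <- gregexpr(pat, s, fixed = TRUE)[[1]]
                hit <- hit[hit > 0L]
                for (hs in hit) {
                    he <- hs + P - 1L
                    inPlanted <- any(vapply(manifestPlants, function(q)
                        any(q$copies$chrom == ch &
                            hs >= q$copies$start & he <= q$copies$end),
                        logical(1)))
                    if (inPlanted) next
                    ## flip one background base inside the occurrence
                    free <- setdiff(hs:he, unlist(lapply(manifestPlants,
                        function(q) {
                            cc <- q$copies[q$copies$chrom == ch, ]
                            unlist(mapply(seq, cc$start, cc$end,
                                          SIMPLIFY = FALSE))
                        })))
                    if (!length(free))
                        stop("cannot break spurious protospacer copy")
                    at <- free[1L]
                    chroms[[ch]][at] <- sample(setdiff(c("A", "C", "G", "T"),
                                                       chroms[[ch]][at]), 1L)
                    s <- paste(chroms[[ch]], collapse = "")
                }
            }
        }
    }

    genome <- Biostrings::DNAStringSet(vapply(chroms, paste,
                                              character(1), collapse = ""))
    names(genome) <- names(chromSizes)
    list(genome = genome,
         manifest = list(chromSizes = as.list(chromSizes),
                         backgroundGC = backgroundGC, seed = seed,
                         plants = manifestPlants))
}

#' Write a fixture to disk
#'
#' FASTA genome plus a JSON manifest of the planted ground truth.
#'
#' @param fx a fixture from [generateFixture()].
#' @param prefix output path prefix (writes \code{<prefix>.fa} and
#'   \code{<prefix>.manifest.json}).
#' @return named character vector of the two paths, invisibly.
#' @export
writeFixture <- function(fx, prefix) {
    fa <- paste0(prefix, ".fa")
    js <- paste0(prefix, ".manifest.json")
    Biostrings::writeXStringSet(fx$genome, fa)
    jsonlite::write_json(fx$manifest, js, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    invisible(c(fasta = fa, manifest = js))
}

#' Brute-force mapping oracle
#'
#' Tests every position on both strands by direct character comparison:
#' a locus is reported when the protospacer differs at no more than
#' \code{maxMismatches} positions, the PAM matches the pattern under IUPAC
#' degeneracy, and the footprint contains no N. Intended for genomes up to
#' about 1 Mb; authoritative in equivalence tests against [findAllHits()].
#'
#' @param genome a \code{DNAStringSet}.
#' @param guide a single full guide sequence (protospacer+PAM, guide
#'   orientation).
#' @param maxMismatches substitution budget in the protospacer.
#' @param pam a [PamSpec-class].
#' @return a [HitTable-class] for this one guide.
#' @export
bruteForceHits <- function(genome, guide, maxMismatches = 3L,
                           pam = PamSpec("NGG")) {
    stopifnot(is(genome, "DNAStringSet"), length(guide) == 1L)
    q <- pamLength(pam)
    L <- nchar(guide)
    P <- L - q
    spacer <- if (pamSide(pam) == "3prime") substring(guide, 1L, P)
              else substring(guide, q + 1L, L)
    spacerF <- strsplit(spacer, "")[[1]]
    spacerR <- strsplit(revComp(spacer), "")[[1]]
    patF <- strsplit(pamPattern(pam), "")[[1]]
    patR <- strsplit(as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(pamPattern(pam)))), "")[[1]]
    sets <- .iupacSets()
    spOffF <- if (pamSide(pam) == "3prime") 0L else q
    spOffR <- if (pamSide(pam) == "3prime") q else 0L
    pamOffF <- if (pamSide(pam) == "3prime") P else 0L
    pamOffR <- if (pamSide(pam) == "3prime") 0L else P

    rows <- list()
    for (ch in names(genome)) {
        v <- strsplit(as.character(genome[[ch]]), "")[[1]]
        n <- length(v)
        if (n < L) next
        starts <- seq_len(n - L + 1L)
        csN <- c(0L, cumsum(v == "N"))
        clean <- (csN[starts + L] - csN[starts]) == 0L

        for (strand in c("+", "-")) {
            sp <- if (strand == "+") spacerF else spacerR
            spOff <- if (strand == "+") spOffF else spOffR
            pamOff <- if (strand == "+") pamOffF else pamOffR
            pat <- if (strand == "+") patF else patR
            mm <- integer(length(starts))
            for (j in seq_len(P))
                mm <- mm + (v[starts + spOff + j - 1L] != sp[j])
            pamOk <- rep(TRUE, length(starts))
            for (j in seq_len(q))
                pamOk <- pamOk &
                    (v[starts + pamOff + j - 1L] %in% sets[[pat[j]]])
            keep <- clean & pamOk & mm <= maxMismatches
            if (any(keep))
                rows[[paste(ch, strand)]] <- data.frame(
                    chrom = ch, start = starts[keep],
                    strand = strand, mismatches = mm[keep],
                    stringsAsFactors = FALSE)
        }
    }
    df <- if (length(rows)) do.call(rbind, rows) else NULL
    perGuide <- data.frame(guide = guide,
                           t = if (is.null(df)) 0L else nrow(df),
                           saturated = FALSE, stringsAsFactors = FALSE)
    if (is.null(df)) {
        gr <- .emptyHitGRanges(genome)
    } else {
        gr <- GenomicRanges::GRanges(df$chrom,
            IRanges::IRanges(start = df$start, width = L),
            strand = df$strand, guide = guide,
            matches = L - df$mismatches, mismatches = df$mismatches,
            gaps = 0L, pamOk = TRUE,
            score = (L - 2 * df$mismatches) / L)
        GenomeInfoDb::seqlevels(gr) <- names(genome)
        GenomeInfoDb::seqlengths(gr) <- Biostrings::width(genome)
    }
    .newHitTable(gr, perGuide, maxMismatches, .Machine$integer.max)
}
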