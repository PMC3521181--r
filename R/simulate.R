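#' @importFrom Biostrings QualityScaledDNAStringSet PhredQuality
#'   writeQualityScaledXStringSet
#' @importFrom stats rpois
#' @importFrom utils write.table
NULL

#' Construct simulation parameters
#'
#' @param readLength,qvFloor,qvMax,qvDecayStart,noiseRate,pBadBase,pBadBlock,pBestGivenOk,blockLead,minStem
#'   See \linkS4class{SimParams} for meanings and defaults.
#' @return A \linkS4class{SimParams} object.
#' @examples
#' SimParams()
#' SimParams(pBadBlock = 0.5)
#' @export
SimParams <- function(readLength = 35L, qvFloor = 7L, qvMax = 34L,
                      qvDecayStart = 4L, noiseRate = 1, pBadBase = 0.02,
                      pBadBlock = 0.85, pBestGivenOk = 0.5, blockLead = 2L,
                      minStem = 16L) {
    new("SimParams", readLength = as.integer(readLength),
        qvFloor = as.integer(qvFloor), qvMax = as.integer(qvMax),
        qvDecayStart = as.integer(qvDecayStart), noiseRate = noiseRate,
        pBadBase = pBadBase, pBadBlock = pBadBlock,
        pBestGivenOk = pBestGivenOk, blockLead = as.integer(blockLead),
        minStem = as.integer(minStem))
}

setMethod("show", "SimParams", function(object) {
    cat("SimParams: readLength", object@readLength,
        "| QV floor/max", object@qvFloor, "/", object@qvMax,
        "| decay", object@qvDecayStart, "| blockLead", object@blockLead,
        "| minStem", object@minStem, "\n  pBadBase", object@pBadBase,
        "| pBadBlock", object@pBadBlock, "\n")
})

# First blocked read position for each insert, NA when no qualifying
# palindrome. The hairpin stem makes the template inaccessible from
# blockLead bases before the palindrome through the read end: ligation
# cannot re-initiate past a hairpin.
.blockStarts <- function(inserts, params) {
    vapply(as.character(inserts), function(s) {
        hits <- scanPalindromes(s, minLen = params@minStem)
        if (!length(hits)) return(NA_integer_)
        bs <- max(1L, BiocGenerics::start(hits)[1L] - params@blockLead)
        if (bs > params@readLength) NA_integer_ else bs
    }, integer(1), USE.NAMES = FALSE)
}

#' Hairpin-blocking window of a template
#'
#' If the template insert contains a perfect palindrome of at least
#' \code{minStem} bases, sequencing is blocked from \code{blockLead} bases
#' before the palindrome start through the read end (positions are 1-based
#' read/template coordinates). Returns \code{NULL} when no qualifying
#' palindrome exists or the window starts beyond the read.
#'
#' @param template A single-template \linkS4class{TemplateSet}, or a DNA
#'   sequence (character/DNAString) taken as the insert.
#' @param params A \linkS4class{SimParams}.
#' @return Integer vector \code{c(start, end)} or \code{NULL}.
#' @examples
#' tmpl <- ditagTemplates(1, jitterProbs = c(1, 0, 0), bothStrands = FALSE,
#'                        seed = 1)
#' blockWindow(tmpl, SimParams())  # c(17, 35): palindrome at 19 minus lead 2
#' @export
blockWindow <- function(template, params = SimParams()) {
    insert <- if (is(template, "TemplateSet")) {
        if (length(template) != 1L)
            stop("'template' must contain exactly one template")
        as.character(template@inserts[[1L]])
    } else .asDnaChar(template, "template")
    bs <- .blockStarts(DNAStringSet(insert), params)
    if (is.na(bs)) NULL else c(bs, params@readLength)
}

# Deterministic per-position QV target before noise: qvMax on clean
# positions, a linear ramp across the decay region, exactly qvFloor inside
# the block.
.qvTarget <- function(pos, blockStart, params) {
    if (is.na(blockStart) || pos < blockStart - params@qvDecayStart)
        return(params@qvMax)
    if (pos >= blockStart) return(params@qvFloor)
    k <- pos - (blockStart - params@qvDecayStart) + 1L
    as.integer(round(params@qvMax -
        (params@qvMax - params@qvFloor) * k / (params@qvDecayStart + 1)))
}

# Hairpin-proximity weight of a template position for bead failure:
# 0 well before the block, a quadratic onset across the decay region
# (probe footprints begin to clash with a breathing stem), 1 inside the
# blocked window. Position 0 is the adaptor base and never blocked.
.beadWeight <- function(pos, blockStart, params) {
    if (is.na(blockStart) || pos < 1L) return(0)
    if (pos >= blockStart) return(1)
    onset <- blockStart - params@qvDecayStart
    if (pos < onset) return(0)
    ((pos - onset + 1) / (params@qvDecayStart + 1))^2
}

#' Simulate sequencing-by-ligation reads
#'
#' Draws one read per template under the hairpin-blocking model. Positions
#' before the blocked window report the true template base with high
#' quality (near \code{qvMax}, with a mild linear decay beginning
#' \code{qvDecayStart} positions before the block); positions inside the
#' window report an i.i.d. uniform random base at exactly the floor QV.
#' Bead status is drawn independently per (primer, cycle): failure
#' probability \code{pBadBase} when the interrogated dinucleotide is clear
#' of the hairpin, \code{pBadBlock} inside the blocked window, with a
#' smooth onset across the decay region; non-failed beads are "best" with
#' probability \code{pBestGivenOk}, else "good".
#'
#' @param templates A \linkS4class{TemplateSet}; inserts must be at least
#'   \code{readLength} bp.
#' @param params A \linkS4class{SimParams}.
#' @param nCycles Ligation cycles per primer (default 7).
#' @param blockingEnabled Logical; FALSE disables the hairpin model (clean
#'   control reads).
#' @param seed Optional integer seed; a fixed seed makes the run
#'   bit-reproducible.
#' @return An \linkS4class{SblReadSet}.
#' @examples
#' tmpl <- ditagTemplates(5, jitterProbs = c(1, 0, 0), seed = 1)
#' reads <- simulateReads(tmpl, SimParams(), seed = 2)
#' readQvs(reads)[1, ]
#' @export
simulateReads <- function(templates, params = SimParams(), nCycles = 7L,
                          blockingEnabled = TRUE, seed = NULL) {
    stopifnot(is(templates, "TemplateSet"))
    n <- length(templates)
    if (n == 0L) stop("'templates' is empty")
    L <- params@readLength
    if (any(width(templates@inserts) < L))
        stop("all template inserts must be at least readLength (", L, ") bp")
    if (!is.null(seed)) set.seed(seed)

    truth <- as.matrix(Biostrings::subseq(templates@inserts, 1L, L))
    blockStart <- if (blockingEnabled) .blockStarts(templates@inserts, params)
                  else rep(NA_integer_, n)

    # base calls: truth outside the window, uniform random inside
    posMat <- matrix(rep(seq_len(L), each = n), nrow = n)
    blocked <- !is.na(blockStart) & posMat >= blockStart
    bases <- truth
    nb <- sum(blocked)
    if (nb) bases[blocked] <- sample(c("A", "C", "G", "T"), nb, replace = TRUE)

    # quality values: deterministic floor inside the window, noisy
    # target elsewhere
    target <- matrix(params@qvMax, nrow = n, ncol = L)
    for (i in which(!is.na(blockStart)))
        target[i, ] <- vapply(seq_len(L), .qvTarget, integer(1),
                              blockStart = blockStart[i], params = params)
    qvs <- target - matrix(rpois(n * L, params@noiseRate), nrow = n)
    qvs <- pmax(qvs, params@qvFloor)
    qvs[blocked] <- params@qvFloor
    mode(qvs) <- "integer"

    # bead status per (primer, cycle)
    pairs <- expand.grid(cycle = seq_len(nCycles), primer = 1:5)[, c("primer", "cycle")]
    nPair <- nrow(pairs)
    bead <- matrix(0L, nrow = n, ncol = nPair)
    colnames(bead) <- paste0("P", pairs$primer, "C", pairs$cycle)
    for (k in seq_len(nPair)) {
        pp <- primerPositions(pairs$primer[k], pairs$cycle[k])
        w <- vapply(blockStart, function(bs)
            max(.beadWeight(pp[1L], bs, params), .beadWeight(pp[2L], bs, params)),
            numeric(1))
        pBad <- params@pBadBase + w * (params@pBadBlock - params@pBadBase)
        bad <- runif(n) < pBad
        best <- runif(n) < params@pBestGivenOk
        bead[, k] <- ifelse(bad, 3L, ifelse(best, 1L, 2L))
    }

    ids <- sprintf("T%05d", seq_len(n))
    readSeqs <- DNAStringSet(apply(bases, 1L, paste, collapse = ""))
    names(readSeqs) <- ids
    new("SblReadSet", bases = readSeqs, qvs = qvs, beadStatus = bead,
        templateId = ids, truthBlockStart = blockStart)
}

#' @rdname simulateReads
#' @param template A single-template \linkS4class{TemplateSet}.
#' @export
simulateRead <- function(template, params = SimParams(), nCycles = 7L,
                         blockingEnabled = TRUE, seed = NULL) {
    if (length(template) != 1L)
        stop("'template' must contain exactly one template")
    simulateReads(template, params, nCycles, blockingEnabled, seed)
}

#' Simulate a library and write its outputs
#'
#' Convenience wrapper around [simulateReads()] that also writes the reads
#' as base-space FASTQ (Phred+33) and the aggregated bead-status table as
#' TSV into \code{outDir}. Optionally also emits a color-space
#' csfasta/.qual pair.
#'
#' @param templates A \linkS4class{TemplateSet}.
#' @param params A \linkS4class{SimParams}.
#' @param outDir Output directory (created if needed); \code{NULL} skips
#'   file output.
#' @param prefix File name prefix (default "sim").
#' @param csfasta Logical; also write color-space files (default FALSE).
#' @param ... Passed on to [simulateReads()] (e.g. \code{seed},
#'   \code{blockingEnabled}).
#' @return The \linkS4class{SblReadSet}, invisibly when files are written.
#' @export
simulateLibrary <- function(templates, params = SimParams(), outDir = NULL,
                            prefix = "sim", csfasta = FALSE, ...) {
    reads <- simulateReads(templates, params, ...)
    if (is.null(outDir)) return(reads)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeReadsFastq(reads, file.path(outDir, paste0(prefix, ".fastq")))
    write.table(beadStatusCounts(reads),
                file.path(outDir, paste0(prefix, "_beads.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (csfasta)
        writeCsfasta(reads, file.path(outDir, paste0(prefix, ".csfasta")))
    invisible(reads)
}

#' Write reads as FASTQ
#'
#' Base-space FASTQ with Phred+33 quality encoding.
#'
#' @param x An \linkS4class{SblReadSet}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeReadsFastq <- function(x, path) {
    stopifnot(is(x, "SblReadSet"))
    qstr <- apply(x@qvs, 1L, function(q) intToUtf8(q + 33L))
    qs <- QualityScaledDNAStringSet(x@bases, PhredQuality(qstr))
    writeQualityScaledXStringSet(qs, path)
    invisible(path)
}

#' Write reads as color-space csfasta (plus .qual)
#'
#' Double-encodes each read from the leading primer base and writes the
#' legacy csfasta format together with a matching space-separated .qual
#' file.
#'
#' @param x An \linkS4class{SblReadSet}.
#' @param path Output csfasta path; the .qual file replaces the extension.
#' @param primerBase Adaptor base preceding position 1 (default "T").
#' @return \code{path}, invisibly.
#' @export
writeCsfasta <- function(x, path, primerBase = "T") {
    stopifnot(is(x, "SblReadSet"))
    ids <- x@templateId
    cs <- vapply(as.character(x@bases), encodeColorspace, character(1),
                 primerBase = primerBase, USE.NAMES = FALSE)
    writeLines(paste0(">", ids, "\n", primerBase, cs), path)
    qualPath <- sub("\\.[^.]*$", ".qual", path)
    writeLines(paste0(">", ids, "\n",
                      apply(x@qvs, 1L, paste, collapse = " ")), qualPath)
    invisible(path)
}

#' Aggregate bead status over reads
#'
#' @param x An \linkS4class{SblReadSet}.
#' @return data.frame with one row per (primer, cycle): counts
#'   \code{nBest}, \code{nGood}, \code{nBad}.
#' @seealso [beadRatioTable()] for fractions and interrogated positions.
#' @export
beadStatusCounts <- function(x) {
    stopifnot(is(x, "SblReadSet"))
    cn <- colnames(x@beadStatus)
    primer <- as.integer(sub("^P([0-9]+)C.*$", "\\1", cn))
    cycle <- as.integer(sub("^P[0-9]+C([0-9]+)$", "\\1", cn))
    data.frame(primer = primer, cycle = cycle,
               nBest = colSums(x@beadStatus == 1L),
               nGood = colSums(x@beadStatus == 2L),
               nBad = colSums(x@beadStatus == 3L),
               row.names = NULL)
}

#' @describeIn SblReadSet-class base calls.
#' @param x An SblReadSet.
#' @export
setMethod("readBases", "SblReadSet", function(x) x@bases)
#' @describeIn SblReadSet-class quality-value matrix (reads x positions).
#' @export
setMethod("readQvs", "SblReadSet", function(x) x@qvs)
#' @describeIn SblReadSet-class bead-status matrix (1 best, 2 good, 3 bad).
#' @export
setMethod("beadStatus", "SblReadSet", function(x) x@beadStatus)
#' @describeIn SblReadSet-class source template identifiers.
#' @export
setMethod("templateIds", "SblReadSet", function(x) x@templateId)
#' @describeIn SblReadSet-class ground-truth first blocked position.
#' @export
setMethod("truthBlockStart", "SblReadSet", function(x) x@truthBlockStart)
#' @describeIn SblReadSet-class number of reads.
#' @export
setMethod("length", "SblReadSet", function(x) length(x@bases))

#' @describeIn SblReadSet-class subset reads.
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "SblReadSet", function(x, i, j, ..., drop = TRUE)
    new("SblReadSet", bases = x@bases[i],
        qvs = x@qvs[i, , drop = FALSE],
        beadStatus = x@beadStatus[i, , drop = FALSE],
        templateId = x@templateId[i],
        truthBlockStart = x@truthBlockStart[i]))

setMethod("show", "SblReadSet", function(object) {
    n <- length(object)
    cat("SblReadSet of", n, "reads",
        if (n) paste0("(", width(object@bases)[1L], " bp)"), "\n")
    if (n) cat("  blocked reads:", sum(!is.na(object@truthBlockStart)),
               "| mean QV:", round(mean(object@qvs), 2), "\n")
})
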