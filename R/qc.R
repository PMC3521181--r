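#' Construct a QC configuration
#'
#' @param rejectN,homopolymerMinRun,primerPatterns,primerMinMatch,qvCutoff,dropReads
#'   See \linkS4class{QcConfig} for meanings and defaults.
#' @return A \linkS4class{QcConfig}.
#' @examples
#' QcConfig()
#' QcConfig(qvCutoff = 8L, dropReads = TRUE)
#' @export
QcConfig <- function(rejectN = TRUE, homopolymerMinRun = 15L,
                     primerPatterns = NULL, primerMinMatch = 15L,
                     qvCutoff = NA_integer_, dropReads = FALSE) {
    if (is.null(primerPatterns)) {
        s <- ditagSequences()
        primerPatterns <- c(s$m13Forward, s$m13Reverse,
                            revComp(s$m13Forward), revComp(s$m13Reverse))
    }
    new("QcConfig", rejectN = rejectN,
        homopolymerMinRun = as.integer(homopolymerMinRun),
        primerPatterns = vapply(primerPatterns, .checkDna, character(1),
                                what = "primer pattern", USE.NAMES = FALSE),
        primerMinMatch = as.integer(primerMinMatch),
        qvCutoff = as.integer(qvCutoff), dropReads = dropReads)
}

.QC_REASONS <- c("pass", "has_n", "homopolymer", "primer", "qv")

# all substrings of length k of the primer patterns, deduplicated
.primerKmers <- function(config) {
    k <- config@primerMinMatch
    unique(unlist(lapply(config@primerPatterns, function(p) {
        n <- nchar(p)
        if (n < k) character(0) else substring(p, 1:(n - k + 1), k:n)
    })))
}

#' Apply the QC filters to reads
#'
#' Evaluates the filters in fixed order -- N content, homopolymer run,
#' primer contamination, (optional) mean quality -- and attributes each
#' failed read to its first failing rule.
#'
#' @param x An \linkS4class{SblReadSet}, \linkS4class{DNAStringSet} or
#'   character vector of read sequences (the quality rule requires an
#'   SblReadSet).
#' @param config A \linkS4class{QcConfig}.
#' @return data.frame with logical \code{keep} and factor \code{reason}
#'   (levels pass, has_n, homopolymer, primer, qv).
#' @examples
#' filterReads(c("GGCAATGGCACCATCGCTAAA", strrep("A", 35)), QcConfig())
#' @export
filterReads <- function(x, config = QcConfig()) {
    seqs <- if (is(x, "SblReadSet")) as.character(x@bases)
            else if (is(x, "XStringSet")) as.character(x)
            else vapply(x, .checkDna, character(1), what = "read",
                        USE.NAMES = FALSE)
    n <- length(seqs)
    reason <- rep("pass", n)
    undecided <- rep(TRUE, n)

    if (config@rejectN) {
        hit <- undecided & grepl("N", seqs, fixed = TRUE)
        reason[hit] <- "has_n"; undecided[hit] <- FALSE
    }
    hpRe <- sprintf("([ACGT])\\1{%d,}", config@homopolymerMinRun - 1L)
    hit <- undecided & grepl(hpRe, seqs)
    reason[hit] <- "homopolymer"; undecided[hit] <- FALSE

    kmers <- .primerKmers(config)
    if (length(kmers) && any(undecided)) {
        prHit <- rep(FALSE, n)
        for (km in kmers)
            prHit <- prHit | grepl(km, seqs, fixed = TRUE)
        hit <- undecided & prHit
        reason[hit] <- "primer"; undecided[hit] <- FALSE
    }
    if (!is.na(config@qvCutoff) && config@dropReads && is(x, "SblReadSet")) {
        hit <- undecided & rowMeans(x@qvs) < config@qvCutoff
        reason[hit] <- "qv"; undecided[hit] <- FALSE
    }
    data.frame(keep = reason == "pass",
               reason = factor(reason, levels = .QC_REASONS))
}

#' Run quality control on a read set
#'
#' Applies [filterReads()] and returns the surviving reads (original order
#' preserved) together with a conservation-checked summary: the raw count
#' always equals qualified plus the per-reason rejection counts.
#'
#' @param x An \linkS4class{SblReadSet}.
#' @param config A \linkS4class{QcConfig}.
#' @return List with elements \code{qualified} (an SblReadSet) and
#'   \code{summary} (a \linkS4class{QcSummary}).
#' @export
runQc <- function(x, config = QcConfig()) {
    stopifnot(is(x, "SblReadSet"))
    res <- filterReads(x, config)
    rejected <- vapply(setdiff(.QC_REASONS, "pass"), function(r)
        sum(res$reason == r), numeric(1))
    summary <- new("QcSummary", nRaw = length(x),
                   nQualified = sum(res$keep), rejected = rejected)
    list(qualified = x[which(res$keep)], summary = summary)
}

#' Mask low-quality positions
#'
#' Replaces base calls with N wherever the quality value is strictly below
#' the cutoff; quality values and read lengths are untouched. With the
#' default simulation (floor QV 7 inside the blocked window), a cutoff of 8
#' masks every in-block position while a cutoff of 7 or below masks none of
#' them -- the dichotomy that makes the faulty palindromic region visible
#' only at cutoffs at or below the floor.
#'
#' @param x An \linkS4class{SblReadSet}.
#' @param cutoff Integer >= 0; positions with \code{qv < cutoff} are masked.
#' @return The masked \linkS4class{SblReadSet}.
#' @export
applyQvCutoff <- function(x, cutoff) {
    stopifnot(is(x, "SblReadSet"))
    if (length(cutoff) != 1L || is.na(cutoff) || cutoff < 0)
        stop("'cutoff' must be a single integer >= 0")
    mask <- x@qvs < cutoff
    if (!any(mask)) return(x)
    chars <- as.matrix(x@bases)
    chars[mask] <- "N"
    masked <- DNAStringSet(apply(chars, 1L, paste, collapse = ""))
    names(masked) <- names(x@bases)
    initialize(x, bases = masked)
}

#' @describeIn QcSummary-class raw read count.
#' @param x A QcSummary.
#' @export
setMethod("nRaw", "QcSummary", function(x) x@nRaw)
#' @describeIn QcSummary-class qualified read count.
#' @export
setMethod("nQualified", "QcSummary", function(x) x@nQualified)
#' @describeIn QcSummary-class named per-reason rejection counts.
#' @export
setMethod("rejectedCounts", "QcSummary", function(x) x@rejected)

setMethod("show", "QcSummary", function(object) {
    cat("QcSummary: raw", object@nRaw, "| qualified", object@nQualified, "\n")
    rej <- object@rejected[object@rejected > 0]
    if (length(rej))
        cat("  rejected:", paste(names(rej), rej, sep = "=", collapse = ", "), "\n")
})
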