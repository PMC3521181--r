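#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement width
#' @importClassesFrom Biostrings DNAString DNAStringSet
NULL

#' DitagConstruct: a palindromic ditag sequencing construct
#'
#' Holds the three segments of a ditag construct -- a 5' tag, a central
#' perfect palindrome, and a 3' tag -- together with the assembled full
#' sequence. The default construct is the 61-bp molecule used throughout
#' this package: Tag1 (18 bp) + 26-bp palindrome + Tag2 (17 bp).
#'
#' @slot tag1 \linkS4class{DNAString}, the 5' tag.
#' @slot palindrome \linkS4class{DNAString}, the central palindrome; must
#'   equal its own reverse complement.
#' @slot tag2 \linkS4class{DNAString}, the 3' tag.
#' @slot full \linkS4class{DNAString}, the concatenation tag1+palindrome+tag2.
#'
#' @seealso [buildConstruct()], [defaultConstruct()]
#' @exportClass DitagConstruct
setClass("DitagConstruct",
         representation(tag1 = "DNAString", palindrome = "DNAString",
                        tag2 = "DNAString", full = "DNAString"))

setValidity("DitagConstruct", function(object) {
    msg <- character(0)
    full <- paste0(as.character(object@tag1), as.character(object@palindrome),
                   as.character(object@tag2))
    if (!identical(full, as.character(object@full)))
        msg <- c(msg, "'full' must equal tag1 + palindrome + tag2")
    pal <- as.character(object@palindrome)
    if (nchar(pal) == 0L || nchar(pal) %% 2L != 0L ||
        !identical(pal, as.character(reverseComplement(object@palindrome))))
        msg <- c(msg, "'palindrome' must be a non-empty even-length sequence equal to its own reverse complement")
    if (length(msg)) msg else TRUE
})

#' TemplateSet: single-stranded library templates
#'
#' One or more single-stranded template molecules as presented to the
#' sequencer. Each insert is a digestion fragment in sequencing orientation;
#' the end offsets record how many extra bases beyond the canonical
#' (zero-jitter) fragment boundary are present at each end.
#'
#' @slot inserts \linkS4class{DNAStringSet} of template inserts (sequencing
#'   orientation, 5' to 3').
#' @slot fivePrimeOffset integer, extra bases at the 5' end relative to the
#'   canonical fragment (0, 1 or 2).
#' @slot threePrimeOffset integer, extra bases at the 3' end.
#' @slot origin character, \code{"A"} (fragment top strand) or \code{"B"}
#'   (reverse complement).
#' @slot trueTag character, ground-truth leading tag label (\code{"tag1"},
#'   \code{"tag2"} or \code{NA}) used as the oracle in classification tests.
#'
#' @seealso [mmeiDigest()], [ditagTemplates()]
#' @exportClass TemplateSet
setClass("TemplateSet",
         representation(inserts = "DNAStringSet",
                        fivePrimeOffset = "integer",
                        threePrimeOffset = "integer",
                        origin = "character",
                        trueTag = "character"))

setValidity("TemplateSet", function(object) {
    n <- length(object@inserts)
    msg <- character(0)
    if (length(object@fivePrimeOffset) != n || length(object@threePrimeOffset) != n ||
        length(object@origin) != n || length(object@trueTag) != n)
        msg <- c(msg, "all per-template slots must have one entry per insert")
    if (n && any(!object@origin %in% c("A", "B")))
        msg <- c(msg, "'origin' entries must be \"A\" or \"B\"")
    if (n && any(object@fivePrimeOffset < 0L | object@threePrimeOffset < 0L))
        msg <- c(msg, "end offsets must be non-negative")
    if (length(msg)) msg else TRUE
})

#' SimParams: parameters of the ligation-sequencing simulator
#'
#' Tunable parameters of the hairpin-blocking read model. Defaults encode the
#' study conditions of the palindromic library: instrument floor quality
#' value 7, blocking beginning 2 bp before the palindrome, a 4-position
#' quality decay ramp, and per-(primer, cycle) bead-failure probabilities of
#' 0.02 outside and 0.85 inside the blocked window.
#'
#' @slot readLength integer, bases reported per read (template positions
#'   1..readLength); default 35.
#' @slot qvFloor integer, instrument floor quality value (default 7).
#' @slot qvMax integer, quality ceiling for clean positions (default 34).
#' @slot qvDecayStart integer, number of positions before the block over
#'   which mean quality ramps down linearly (default 4).
#' @slot noiseRate numeric, Poisson rate of the small downward quality
#'   jitter applied outside the blocked window (default 1).
#' @slot pBadBase numeric, bead-failure probability per (primer, cycle) when
#'   the interrogated dinucleotide is clear of the hairpin (default 0.02).
#' @slot pBadBlock numeric, bead-failure probability inside the blocked
#'   window (default 0.85).
#' @slot pBestGivenOk numeric, probability that a non-failed bead is "best"
#'   rather than "good" (default 0.5).
#' @slot blockLead integer, bases before the palindrome start at which
#'   blocking begins (default 2).
#' @slot minStem integer, minimum palindrome length (full stem, bp) required
#'   to trigger blocking (default 16).
#'
#' @seealso [SimParams()], [simulateReads()]
#' @exportClass SimParams
setClass("SimParams",
         representation(readLength = "integer", qvFloor = "integer",
                        qvMax = "integer", qvDecayStart = "integer",
                        noiseRate = "numeric", pBadBase = "numeric",
                        pBadBlock = "numeric", pBestGivenOk = "numeric",
                        blockLead = "integer", minStem = "integer"))

setValidity("SimParams", function(object) {
    msg <- character(0)
    probs <- c(object@pBadBase, object@pBadBlock, object@pBestGivenOk)
    if (any(probs < 0 | probs > 1)) msg <- c(msg, "probabilities must lie in [0, 1]")
    if (object@qvFloor >= object@qvMax) msg <- c(msg, "qvFloor must be < qvMax")
    if (object@readLength < 1L) msg <- c(msg, "readLength must be positive")
    if (object@qvDecayStart < 0L) msg <- c(msg, "qvDecayStart must be >= 0")
    if (object@blockLead < 0L) msg <- c(msg, "blockLead must be >= 0")
    if (object@minStem < 4L || object@minStem %% 2L != 0L)
        msg <- c(msg, "minStem must be an even integer >= 4")
    if (length(msg)) msg else TRUE
})

#' SblReadSet: simulated sequencing-by-ligation reads
#'
#' Container for simulated reads: base calls, per-position quality values,
#' per-(primer, cycle) bead status, and ground-truth annotation from the
#' simulator.
#'
#' @slot bases \linkS4class{DNAStringSet} of equal-width base calls
#'   (template positions 1..readLength).
#' @slot qvs integer matrix, reads x positions.
#' @slot beadStatus integer matrix, reads x (primer, cycle) pairs coded
#'   1 = best, 2 = good, 3 = bad; columns named \code{"P<p>C<c>"}.
#' @slot templateId character, identifier of the source template.
#' @slot truthBlockStart integer, first blocked read position per read
#'   (\code{NA} when no blocking applied).
#'
#' @seealso [simulateReads()], [readBases()], [readQvs()], [beadStatus()]
#' @exportClass SblReadSet
setClass("SblReadSet",
         representation(bases = "DNAStringSet", qvs = "matrix",
                        beadStatus = "matrix", templateId = "character",
                        truthBlockStart = "integer"))

setValidity("SblReadSet", function(object) {
    n <- length(object@bases)
    msg <- character(0)
    if (n && length(unique(width(object@bases))) != 1L)
        msg <- c(msg, "all reads must have equal width")
    if (nrow(object@qvs) != n)
        msg <- c(msg, "qvs must have one row per read")
    if (n && ncol(object@qvs) != width(object@bases)[1L])
        msg <- c(msg, "qvs must have one column per read position")
    if (nrow(object@beadStatus) != n)
        msg <- c(msg, "beadStatus must have one row per read")
    if (length(object@templateId) != n || length(object@truthBlockStart) != n)
        msg <- c(msg, "templateId and truthBlockStart must have one entry per read")
    if (length(msg)) msg else TRUE
})

#' QcConfig: read quality-control configuration
#'
#' Settings for the sequential QC filters: reads containing N, reads with a
#' long single-base run (polyA/T/G/C), reads sharing a long exact substring
#' with a PCR primer, and (optionally) reads with mean quality below a
#' cutoff. Rules are applied in that fixed order; the first failure is the
#' recorded rejection reason.
#'
#' @slot rejectN logical, reject reads containing N (default TRUE).
#' @slot homopolymerMinRun integer, minimum single-base run length treated
#'   as a polyA/T/G/C failure (default 15).
#' @slot primerPatterns character, primer sequences screened against reads;
#'   default: the two M13 PCR primers and their reverse complements.
#' @slot primerMinMatch integer, minimum exact shared substring length for a
#'   primer failure (default 15).
#' @slot qvCutoff integer, quality cutoff; \code{NA} disables quality-based
#'   rejection/masking.
#' @slot dropReads logical, if TRUE reads with mean QV below \code{qvCutoff}
#'   are rejected by [filterReads()]; if FALSE the cutoff is only used for
#'   position masking via [applyQvCutoff()] (default FALSE).
#'
#' @seealso [QcConfig()], [runQc()], [applyQvCutoff()]
#' @exportClass QcConfig
setClass("QcConfig",
         representation(rejectN = "logical", homopolymerMinRun = "integer",
                        primerPatterns = "character", primerMinMatch = "integer",
                        qvCutoff = "integer", dropReads = "logical"))

setValidity("QcConfig", function(object) {
    msg <- character(0)
    if (object@homopolymerMinRun < 5L)
        msg <- c(msg, "homopolymerMinRun must be >= 5")
    if (length(object@primerPatterns) &&
        object@primerMinMatch > min(nchar(object@primerPatterns)))
        msg <- c(msg, "primerMinMatch must not exceed the shortest primer length")
    if (length(msg)) msg else TRUE
})

#' QcSummary: accounting of a QC run
#'
#' @slot nRaw numeric, reads seen.
#' @slot nQualified numeric, reads passing all filters.
#' @slot rejected named numeric, rejection counts per reason
#'   (\code{has_n}, \code{homopolymer}, \code{primer}, \code{qv}).
#'
#' @seealso [runQc()]
#' @exportClass QcSummary
setClass("QcSummary",
         representation(nRaw = "numeric", nQualified = "numeric",
                        rejected = "numeric"))

setValidity("QcSummary", function(object) {
    if (!isTRUE(all.equal(object@nRaw, object@nQualified + sum(object@rejected))))
        "conservation violated: nRaw must equal nQualified + sum(rejected)"
    else TRUE
})

#' TagPatterns: anchored tag-matching patterns
#'
#' The tag sequences against which read prefixes are classified, in
#' as-sequenced orientation: Tag1 as printed, Tag2 as its reverse complement
#' (the strand actually read). Matching is anchored at the read start;
#' \code{maxMismatch} Hamming mismatches are tolerated ("partial" matches).
#'
#' @slot tag1 character, 5'-anchored Tag1 pattern (default 18-mer
#'   GGCAATGGCACCATCGCT).
#' @slot tag2 character, 5'-anchored as-read Tag2 pattern (default 17-mer
#'   AACCTCAGCGGTCGTGG).
#' @slot maxMismatch integer, Hamming tolerance (default 1; 0 = exact only).
#'
#' @seealso [TagPatterns()], [classifyReads()]
#' @exportClass TagPatterns
setClass("TagPatterns",
         representation(tag1 = "character", tag2 = "character",
                        maxMismatch = "integer"))

#' LibraryStats: library-level read statistics
#'
#' Raw/qualified read counts and tag-containing counts, with percentages
#' (relative to qualified reads, half-up rounded to 2 decimals) derived by
#' accessors.
#'
#' @slot rawReads numeric count.
#' @slot qualifiedReads numeric count.
#' @slot tag1Reads numeric count.
#' @slot tag2Reads numeric count.
#'
#' @seealso [libraryStats()], [statsTable()]
#' @exportClass LibraryStats
setClass("LibraryStats",
         representation(rawReads = "numeric", qualifiedReads = "numeric",
                        tag1Reads = "numeric", tag2Reads = "numeric"))

setValidity("LibraryStats", function(object) {
    counts <- c(object@rawReads, object@qualifiedReads,
                object@tag1Reads, object@tag2Reads)
    if (any(counts < 0)) "counts must be non-negative" else TRUE
})

#' QvProfile: per-position mean quality profile
#'
#' @slot meanQv numeric, arithmetic mean QV per read position.
#' @slot nReads numeric, number of reads profiled.
#' @slot qvFloor integer, instrument floor QV used by breakpoint detection.
#'
#' @seealso [perPositionQv()], [detectBreakpoint()]
#' @exportClass QvProfile
setClass("QvProfile",
         representation(meanQv = "numeric", nReads = "numeric",
                        qvFloor = "integer"))
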