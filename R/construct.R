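#' @importFrom Biostrings matchPattern
#' @importFrom stats runif
NULL

#' Reference sequences of the palindromic ditag system
#'
#' All fixed sequences used by the default construct and simulation
#' pipeline: the two E. coli-derived tags (Tag2 both as printed on the
#' construct top strand and in the as-sequenced orientation), the 26-bp
#' central palindrome, the MmeI recognition hexamer, and the two M13 PCR
#' primers used to amplify the cloned insert.
#'
#' @return Named list of character sequences: \code{tag1}, \code{palindrome},
#'   \code{tag2}, \code{tag2AsRead}, \code{mmeISite}, \code{m13Forward},
#'   \code{m13Reverse}.
#' @examples
#' ditagSequences()$tag1
#' @export
ditagSequences <- function() {
    list(tag1 = "GGCAATGGCACCATCGCT",
         palindrome = "AGTCGGAGTCTGCGCAGACTCCGACT",
         tag2 = "CCACGACCGCTGAGGTT",
         tag2AsRead = "AACCTCAGCGGTCGTGG",
         mmeISite = "TCCGAC",
         m13Forward = "GTTTTCCCAGTCACGAC",
         m13Reverse = "TCACACAGGAAACAGCTATGAC")
}

#' Assemble a palindromic ditag construct
#'
#' Concatenates tag1 + palindrome + tag2 (5' to 3') into a
#' \linkS4class{DitagConstruct}. The middle segment must be a perfect
#' palindrome; by default the segment lengths must be the 18/26/17 bp of
#' the reference construct (set \code{strict = FALSE} to assemble other
#' geometries).
#'
#' @param tag1,palindrome,tag2 DNA sequences (character or DNAString);
#'   defaults are the reference sequences.
#' @param strict Logical; enforce lengths 18/26/17 (default TRUE).
#' @return A \linkS4class{DitagConstruct}.
#' @examples
#' cons <- buildConstruct()
#' nchar(as.character(fullSeq(cons)))  # 61
#' @export
buildConstruct <- function(tag1 = ditagSequences()$tag1,
                           palindrome = ditagSequences()$palindrome,
                           tag2 = ditagSequences()$tag2,
                           strict = TRUE) {
    tag1 <- .asDnaChar(tag1, "tag1")
    palindrome <- .asDnaChar(palindrome, "palindrome")
    tag2 <- .asDnaChar(tag2, "tag2")
    if (!isPalindrome(palindrome))
        stop("middle segment is not a perfect palindrome")
    if (strict && !identical(c(nchar(tag1), nchar(palindrome), nchar(tag2)),
                             c(18L, 26L, 17L)))
        stop("expected segment lengths 18/26/17 bp; use strict = FALSE ",
             "for other constructs")
    new("DitagConstruct",
        tag1 = DNAString(tag1), palindrome = DNAString(palindrome),
        tag2 = DNAString(tag2), full = DNAString(paste0(tag1, palindrome, tag2)))
}

#' @rdname buildConstruct
#' @export
defaultConstruct <- function() buildConstruct()

#' @describeIn DitagConstruct-class the assembled full sequence.
#' @param x A DitagConstruct.
#' @export
setMethod("fullSeq", "DitagConstruct", function(x) x@full)
#' @describeIn DitagConstruct-class the 5' tag.
#' @export
setMethod("tag1Seq", "DitagConstruct", function(x) x@tag1)
#' @describeIn DitagConstruct-class the 3' tag.
#' @export
setMethod("tag2Seq", "DitagConstruct", function(x) x@tag2)
#' @describeIn DitagConstruct-class the central palindrome.
#' @export
setMethod("palindromeSeq", "DitagConstruct", function(x) x@palindrome)

setMethod("show", "DitagConstruct", function(object) {
    cat("DitagConstruct of", length(object@full), "bp\n")
    cat("  tag1      :", as.character(object@tag1), "\n")
    cat("  palindrome:", as.character(object@palindrome), "\n")
    cat("  tag2      :", as.character(object@tag2), "\n")
})

#' Locate MmeI recognition sites on both strands
#'
#' Finds every occurrence of the MmeI hexamer TCCGAC on the plus strand and
#' of its reverse complement GTCGGA (a minus-strand site) and reports each
#' by the 1-based plus-strand position of the hexamer's first base.
#'
#' @param x A DNA sequence (character or DNAString).
#' @return data.frame with columns \code{start}, \code{end} (1-based
#'   inclusive, plus-strand coordinates of the hexamer) and \code{strand}
#'   (\code{"+"} or \code{"-"}), ordered by start.
#' @examples
#' findMmeISites(fullSeq(defaultConstruct()))  # minus at 20, plus at 38
#' @export
findMmeISites <- function(x) {
    x <- .asDnaChar(x)
    subject <- DNAString(x)
    fwd <- matchPattern(ditagSequences()$mmeISite, subject)
    rev <- matchPattern(revComp(ditagSequences()$mmeISite), subject)
    out <- data.frame(
        start = c(BiocGenerics::start(fwd), BiocGenerics::start(rev)),
        end = c(BiocGenerics::end(fwd), BiocGenerics::end(rev)),
        strand = c(rep("+", length(fwd)), rep("-", length(rev))),
        stringsAsFactors = FALSE)
    out[order(out$start), , drop = FALSE]
}

#' Default PCR amplicon carrying the ditag construct
#'
#' The amplified insert as presented to MmeI: M13 forward primer, the 61-bp
#' construct, then the reverse complement of the M13 reverse primer
#' (100 bp in total). Vector sequence between primer and insert is omitted;
#' only the flank lengths matter to digestion, and both flanks exceed the
#' enzyme's reach plus maximal jitter.
#'
#' @return Single character string (100 bp).
#' @export
defaultAmplicon <- function() {
    s <- ditagSequences()
    paste0(s$m13Forward, as.character(fullSeq(defaultConstruct())),
           revComp(s$m13Reverse))
}

# Cut coordinate ("after plus-strand position k") for one MmeI site.
# MmeI is a type IIS enzyme reaching downstream of its hexamer; cutOffset is
# the blunt post-end-repair distance in nt, jitter the additive imprecision.
.mmeiCutAfter <- function(start, end, strand, cutOffset, jitter) {
    if (strand == "+") end + cutOffset + jitter
    else start - 1L - cutOffset - jitter
}

#' Simulate MmeI digestion of an amplicon
#'
#' Models type IIS digestion: for each recognition site a blunt cut is
#' placed \code{cutOffset} + jitter nucleotides downstream of the hexamer
#' along the site's strand, with the jitter drawn independently per end
#' from \code{jitterProbs} over \{0, +1, +2\} (additive imprecision only,
#' matching the enzyme's documented at-most +2 bp length variation). The
#' fragments between consecutive cuts are returned as single-stranded
#' templates; terminal flanks (before the first and after the last cut)
#' are discarded. Each fragment is emitted either as its top strand
#' (\code{origin "A"}) or as its reverse complement (\code{origin "B"})
#' with equal probability when \code{bothStrands} is TRUE, since ligation
#' sequencing templates either strand.
#'
#' End offsets are recorded relative to the canonical (zero-jitter)
#' fragment: \code{fivePrimeOffset} is the number of extra bases at the
#' sequenced 5' end.
#'
#' @param amplicon DNA sequence to digest.
#' @param n Number of independent digestion replicates (templates drawn).
#' @param cutOffset Integer cut distance(s) downstream of the hexamer,
#'   recycled across sites in start order (default 18).
#' @param jitterProbs Probabilities of jitter 0, +1, +2 (must sum to 1).
#' @param bothStrands Logical; emit both strands with equal probability
#'   (default TRUE). FALSE emits top strands only.
#' @param seed Optional integer seed for reproducibility.
#' @return A \linkS4class{TemplateSet} with one template per replicate (per
#'   interior fragment). If the amplicon contains no site, an empty set is
#'   returned with a warning.
#' @seealso [ditagTemplates()] for the reference-construct pipeline.
#' @export
mmeiDigest <- function(amplicon, n = 1L, cutOffset = 18L,
                       jitterProbs = c(0.6, 0.3, 0.1),
                       bothStrands = TRUE, seed = NULL) {
    amplicon <- .asDnaChar(amplicon, "amplicon")
    if (abs(sum(jitterProbs) - 1) > 1e-9 || any(jitterProbs < 0))
        stop("'jitterProbs' must be non-negative and sum to 1")
    if (!is.null(seed)) set.seed(seed)
    sites <- findMmeISites(amplicon)
    if (nrow(sites) < 2L) {
        warning(if (nrow(sites)) "single MmeI site: cuts yield flanks only, no interior fragment"
                else "no MmeI site found in amplicon")
        return(.emptyTemplateSet())
    }
    cutOffset <- as.integer(rep_len(cutOffset, nrow(sites)))
    ampLen <- nchar(amplicon)
    canon <- vapply(seq_len(nrow(sites)), function(i)
        .mmeiCutAfter(sites$start[i], sites$end[i], sites$strand[i],
                      cutOffset[i], 0L), numeric(1))
    nSites <- nrow(sites)
    canonOrd <- sort(canon)
    inserts <- character(0); off5 <- integer(0); off3 <- integer(0)
    origin <- character(0)
    for (r in seq_len(n)) {
        jit <- sample(0:2, nSites, replace = TRUE, prob = jitterProbs)
        cuts <- vapply(seq_len(nSites), function(i)
            .mmeiCutAfter(sites$start[i], sites$end[i], sites$strand[i],
                          cutOffset[i], jit[i]), numeric(1))
        cuts <- sort(pmin(pmax(cuts, 0L), ampLen))
        for (k in seq_len(nSites - 1L)) {   # interior fragments only
            frag <- substr(amplicon, cuts[k] + 1L, cuts[k + 1L])
            extra5 <- as.integer(canonOrd[k] - cuts[k])        # leftward
            extra3 <- as.integer(cuts[k + 1L] - canonOrd[k + 1L])  # rightward
            if (bothStrands && runif(1) < 0.5) {
                inserts <- c(inserts, revComp(frag)); origin <- c(origin, "B")
                off5 <- c(off5, extra3); off3 <- c(off3, extra5)
            } else {
                inserts <- c(inserts, frag); origin <- c(origin, "A")
                off5 <- c(off5, extra5); off3 <- c(off3, extra3)
            }
        }
    }
    n <- length(inserts)
    new("TemplateSet", inserts = DNAStringSet(inserts),
        fivePrimeOffset = off5, threePrimeOffset = off3,
        origin = origin, trueTag = rep(NA_character_, n))
}

.emptyTemplateSet <- function()
    new("TemplateSet", inserts = DNAStringSet(), fivePrimeOffset = integer(0),
        threePrimeOffset = integer(0), origin = character(0),
        trueTag = character(0))

#' Draw library templates from the reference palindromic construct
#'
#' Stage-1 generator of the synthetic pipeline: digests the default M13
#' amplicon with MmeI and returns \code{n} single-stranded templates. The
#' construct geometry pins the canonical cut distances at 19 nt on the Tag1
#' side (the extra T plus the 18-bp tag) and 18 nt on the Tag2 side (extra
#' T plus the 17-bp tag), both within the enzyme's documented 18-20 nt
#' reach, so the zero-jitter fragment is exactly the printed 61-bp
#' construct. Ground-truth leading-tag labels are attached (\code{"tag1"}
#' for top-strand templates, \code{"tag2"} for reverse-complement ones).
#'
#' @param n Number of templates.
#' @param jitterProbs Digestion jitter distribution over \{0, +1, +2\}.
#' @param bothStrands Logical; FALSE restricts to Tag1-led templates.
#' @param seed Optional integer seed.
#' @return A \linkS4class{TemplateSet}.
#' @examples
#' tmpl <- ditagTemplates(3, jitterProbs = c(1, 0, 0), seed = 1)
#' width(insertSeqs(tmpl))  # all 61 with zero jitter
#' @export
ditagTemplates <- function(n, jitterProbs = c(0.6, 0.3, 0.1),
                           bothStrands = TRUE, seed = NULL) {
    tset <- mmeiDigest(defaultAmplicon(), n = n, cutOffset = c(19L, 18L),
                       jitterProbs = jitterProbs, bothStrands = bothStrands,
                       seed = seed)
    tset@trueTag <- ifelse(tset@origin == "A", "tag1", "tag2")
    validObject(tset)
    tset
}

#' @describeIn TemplateSet-class insert sequences (sequencing orientation).
#' @param x A TemplateSet.
#' @export
setMethod("insertSeqs", "TemplateSet", function(x) x@inserts)
#' @describeIn TemplateSet-class data.frame of per-template 5'/3' end
#'   offsets relative to the canonical fragment.
#' @export
setMethod("endOffsets", "TemplateSet", function(x)
    data.frame(fivePrime = x@fivePrimeOffset, threePrime = x@threePrimeOffset))
#' @describeIn TemplateSet-class strand of origin ("A" top, "B" bottom).
#' @export
setMethod("templateOrigin", "TemplateSet", function(x) x@origin)
#' @describeIn TemplateSet-class ground-truth leading tag labels.
#' @export
setMethod("trueTag", "TemplateSet", function(x) x@trueTag)

#' @describeIn TemplateSet-class number of templates.
#' @export
setMethod("length", "TemplateSet", function(x) length(x@inserts))

#' @describeIn TemplateSet-class subset templates.
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "TemplateSet", function(x, i, j, ..., drop = TRUE)
    new("TemplateSet", inserts = x@inserts[i],
        fivePrimeOffset = x@fivePrimeOffset[i],
        threePrimeOffset = x@threePrimeOffset[i],
        origin = x@origin[i], trueTag = x@trueTag[i]))

setMethod("show", "TemplateSet", function(object) {
    cat("TemplateSet of", length(object), "templates\n")
    if (length(object)) {
        w <- width(object@inserts)
        cat("  insert widths:", min(w), "-", max(w), "bp\n")
        cat("  origin A/B:", sum(object@origin == "A"), "/",
            sum(object@origin == "B"), "\n")
    }
})
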